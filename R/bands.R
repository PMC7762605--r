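#' Default band tables for synthetic cohorts
#'
#' Gaussian band definitions (`centre`, `fwhm` in cm^-1, `base_amplitude` in
#' AU for the wildtype class, `class_delta` in AU per unit effect scale,
#' added in the mutated class). The tissue table encodes the difference
#' pattern expected from 2HG accumulation and an Amide I sub-band shift: a
#' negative excursion of the alpha-helix-like component near 1660 cm^-1, a
#' positive beta-sheet-like component near 1615 cm^-1, and elevated
#' intensity at the eight 2HG-associated centres (1589, 1450, 1416, 1344,
#' 1311, 1267, 1236, 1203 cm^-1). The whole-serum table is dominated by
#' Amide I/II with only small class effects; the filtrate table is sparse,
#' with a glycerine-like confounder band near 1030 cm^-1 carried equally by
#' both classes and class effects concentrated in the C-O stretch region.
#'
#' @param scenario `"tissue"`, `"whole_serum"` or `"filtrate"`
#' @return tibble with columns `centre`, `fwhm`, `base_amplitude`,
#'   `class_delta`.
#' @export
default_band_table <- function(scenario = c("tissue", "whole_serum",
                                            "filtrate")) {
  scenario <- match.arg(scenario)
  switch(scenario,
    tissue = tibble::tribble(
      ~centre, ~fwhm, ~base_amplitude, ~class_delta,
      3290,   120,  0.45,  0,      # Amide A, N-H stretch
      2925,    45,  0.20,  0,      # CH2 asymmetric stretch
      2855,    35,  0.10,  0,      # CH2 symmetric stretch
      1740,    25,  0.12, -0.10,   # lipid C=O ester, lower in mutated
      1660,    45,  0.90, -1.00,   # Amide I alpha-helix-like component
      1615,    25,  0.35,  0.80,   # Amide I beta-sheet-like component (sharp)
      1589,    20,  0.18,  0.45,   # 2HG-associated
      1550,    45,  0.55, -0.20,   # Amide II
      1450,    28,  0.22,  0.40,   # 2HG-associated / CH bending
      1416,    24,  0.14,  0.35,   # 2HG-associated
      1344,    24,  0.12,  0.35,   # 2HG-associated
      1311,    24,  0.12,  0.30,   # 2HG-associated
      1300,    35,  0.20,  0.10,   # Amide III
      1267,    24,  0.12,  0.30,   # 2HG-associated
      1236,    26,  0.16,  0.30,   # 2HG-associated / PO2- asym
      1230,    35,  0.18,  0.05,   # nucleic acid PO2-
      1203,    24,  0.10,  0.25,   # 2HG-associated
      1080,    40,  0.20,  0,      # PO2- symmetric / carbohydrate
      1030,    30,  0.12,  0       # C-O stretch
    ),
    whole_serum = tibble::tribble(
      ~centre, ~fwhm, ~base_amplitude, ~class_delta,
      3290,   130,  0.40,  0,
      2960,    40,  0.12,  0,
      1650,    50,  1.00,  0.010,  # Amide I, dominant
      1545,    45,  0.60, -0.008,  # Amide II
      1450,    30,  0.18,  0.005,
      1400,    30,  0.15,  0,
      1310,    35,  0.10,  0.004,
      1240,    35,  0.10,  0,
      1080,    40,  0.08,  0.004,
      1030,    30,  0.06,  0
    ),
    filtrate = tibble::tribble(
      ~centre, ~fwhm, ~base_amplitude, ~class_delta,
      3350,   150,  0.15,  0,
      1740,    20,  0.05,  0.012,   # lipid C=O
      1650,    50,  0.25,  0.015,   # residual small-protein Amide I
      1550,    45,  0.12,  0.008,
      1450,    25,  0.08,  0.008,
      1172,    18,  0.10,  0.030,   # C-O / C-OH stretch, class-informative
      1124,    18,  0.12,  0.035,   # C-O stretch, class-informative
      1080,    25,  0.10,  0.010,
      1030,    22,  0.45,  0,       # glycerine-like confounder, both classes
      950,     18,  0.12,  0,
      850,     16,  0.10,  0
    )
  )
}

#' Built-in wavenumber assignment table
#'
#' Tentative vibrational-mode assignments used to annotate difference-spectrum
#' extrema and importance tables.
#'
#' @return tibble with columns `wavenumber` (cm^-1) and `assignment`.
#' @export
band_assignments <- function() {
  tibble::tribble(
    ~wavenumber, ~assignment,
    1740.5, "Lipids; C = O stretch",
    1660,   "Amide I; alpha-helix component",
    1615,   "Amide I; beta-sheet component",
    1612.5, "Amide I; C = O and C-N stretch, N-H bending",
    1588.5, "Amide I; C = O and C-N stretch, N-H bending",
    1548.5, "Amide II; N-H bending, C-N stretching",
    1468.5, "Lipids/Proteins; CH2 bending",
    1444.5, "Lipids; CH2 bending",
    1416,   "COO- symmetric stretch",
    1344,   "CH2/CH3 wagging",
    1311,   "Amide III; C-N stretch, N-H bending",
    1300,   "Amide III; C-N stretch, N-H bending",
    1267,   "Amide III; C-N stretch",
    1236,   "Asymmetric PO2- stretch",
    1203,   "Amide III / CH2 wagging",
    1188.5, "DNA; Symmetric PO2- stretch",
    1180.5, "CH2 twisting",
    1172.5, "C-O, C-OH stretch",
    1164.5, "C-C, C-O and C-OH stretch",
    1132.5, "C-O and C-C stretch",
    1124.5, "C-O stretch",
    1116.5, "RNA; C-OH stretch",
    1080,   "Symmetric PO2- stretch; carbohydrates",
    1028.5, "Carbohydrate; C-O stretch",
    1030,   "Glycerine / carbohydrate; C-O stretch",
    1020.5, "Glycogen; C-O stretch",
    950,    "Phosphorylated molecules; C-O stretch",
    850,    "Ring vibrations; tyrosine"
  )
}
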