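#' @importFrom generics tidy glance augment
#' @importFrom ggplot2 autoplot
#' @importFrom rlang .data
#' @importFrom stats predict approx cov mahalanobis prcomp qchisq quantile
#'   rbinom rnorm runif sd setNames var glm binomial coef
#' @importFrom utils head
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# Deterministic child seed from a master seed and a stage name; stays < 2^31.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) %% 1000003L) * 2017L + h %% 1000003L
}

# Run code with a local RNG state so library calls never perturb user RNG.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Round half away from zero
#'
#' Presentation rounding for percentage tables: 69.05 becomes 69.1 at one
#' decimal (base `round()` rounds half to even). Applied only at report
#' time, never inside computations.
#'
#' @param x numeric vector
#' @param digits decimal places (default 1)
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Index of grid point nearest to a target wavenumber.
nearest_index <- function(grid, at) which.min(abs(grid - at))
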