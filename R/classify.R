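#' Group-aware stratified train/test split
#'
#' Splits at the level of the grouping unit (tissue core or patient), never
#' the spectrum, so no group contributes to both sides. Groups are sampled
#' without replacement within each class, with the training count per class
#' rounded to the nearest integer of `fraction_train` times the class size.
#'
#' @param meta metadata tibble with `group_id` and `class_label` columns
#' @param fraction_train training fraction (default 0.7)
#' @param seed RNG seed
#' @return a `split_plan` list: `train_groups`, `test_groups`, `seed`,
#'   `fraction_train`.
#' @export
grouped_split <- function(meta, fraction_train = 0.7, seed = 1) {
  groups <- dplyr::distinct(tibble::as_tibble(meta),
                            .data$group_id, .data$class_label)
  if (anyDuplicated(groups$group_id)) {
    stop("a group carries more than one class label", call. = FALSE)
  }
  counts <- table(groups$class_label)
  if (length(counts) < 2 || any(counts < 2)) {
    stop("grouped split needs >= 2 groups in each of two classes",
         call. = FALSE)
  }
  # nearest-integer stratification with largest-remainder tie-breaking, so
  # the overall train count stays at round(fraction * n_groups)
  by_class <- split(groups$group_id, groups$class_label)
  exact <- vapply(by_class, length, 0L) * fraction_train
  n_train_cls <- floor(exact)
  short <- round(fraction_train * nrow(groups)) - sum(n_train_cls)
  if (short > 0) {
    bump <- order(exact - floor(exact), decreasing = TRUE)[seq_len(short)]
    n_train_cls[bump] <- n_train_cls[bump] + 1
  }
  n_train_cls <- pmin(pmax(n_train_cls, 1L),
                      vapply(by_class, length, 0L) - 1L)
  train_groups <- with_seed(seed, {
    unlist(lapply(seq_along(by_class), function(i) {
      sample(by_class[[i]], n_train_cls[i])
    }), use.names = FALSE)
  })
  structure(list(train_groups = sort(train_groups),
                 test_groups = sort(setdiff(groups$group_id, train_groups)),
                 fraction_train = fraction_train, seed = seed),
            class = "split_plan")
}

#' Class-imbalance sampling on training spectra
#'
#' * `up`: minority rows resampled with replacement to the majority count.
#' * `down`: majority rows subsampled to the minority count.
#' * `smote`: minority class augmented to the majority count by convex
#'   combinations `x + u (x_nn - x)` with `u ~ U(0, 1)` and `x_nn` one of the
#'   `k` nearest minority neighbours (Euclidean).
#' * `none`: identity.
#'
#' Sampling must be applied after the train/test split, on training spectra
#' only.
#'
#' @param x numeric feature matrix (rows = spectra)
#' @param labels character/factor class labels, two classes
#' @param method `"none"`, `"up"`, `"down"` or `"smote"`
#' @param seed RNG seed
#' @param k SMOTE neighbour count
#' @return list with balanced `x` and `labels`.
#' @export
apply_sampling <- function(x, labels, method = c("none", "up", "down",
                                                 "smote"), seed = 1, k = 5) {
  method <- match.arg(method)
  labels <- as.character(labels)
  if (method == "none") return(list(x = x, labels = labels))
  counts <- sort(table(labels))
  if (length(counts) != 2) stop("sampling needs exactly two classes",
                                call. = FALSE)
  minority <- names(counts)[1]
  majority <- names(counts)[2]
  i_min <- which(labels == minority)
  i_maj <- which(labels == majority)
  with_seed(seed, {
    if (method == "up") {
      add <- sample(i_min, counts[2] - counts[1], replace = TRUE)
      list(x = rbind(x, x[add, , drop = FALSE]),
           labels = c(labels, labels[add]))
    } else if (method == "down") {
      keep <- c(sample(i_maj, counts[1]), i_min)
      list(x = x[keep, , drop = FALSE], labels = labels[keep])
    } else {
      if (length(i_min) < 2) stop("SMOTE needs >= 2 minority spectra",
                                  call. = FALSE)
      xm <- x[i_min, , drop = FALSE]
      k_use <- min(k, nrow(xm) - 1)
      d <- as.matrix(dist(xm))
      diag(d) <- Inf
      nn <- t(apply(d, 1, function(row) order(row)[seq_len(k_use)]))
      n_new <- counts[2] - counts[1]
      base_i <- sample(nrow(xm), n_new, replace = TRUE)
      synth <- t(vapply(base_i, function(i) {
        j <- nn[i, sample(k_use, 1)]
        u <- runif(1)
        xm[i, ] + u * (xm[j, ] - xm[i, ])
      }, numeric(ncol(x))))
      list(x = rbind(x, synth), labels = c(labels, rep(minority, n_new)))
    }
  })
}

#' Specify a classifier
#'
#' @param family `"lda"` (shrinkage-regularised linear discriminant),
#'   `"plsda"` (latent-projection regression with a logistic link on the
#'   response score), `"rf"` (random forest, Gini splitting) or `"svm"`
#'   (radial kernel, probability calibration)
#' @param sampling class-imbalance sampling method passed to
#'   [apply_sampling()]
#' @param ... family hyperparameters: `ncomp` (plsda, default 10, capped at
#'   `min(n - 1, p)`), `ntree` / `mtry` (rf, defaults 500 and `sqrt(p)`),
#'   `cost` / `gamma` (svm, defaults 1 and `1/(p * var)`), `shrinkage`
#'   (lda, default `"auto"`)
#' @return a `classifier_spec`.
#' @export
classifier_spec <- function(family = c("lda", "plsda", "rf", "svm"),
                            sampling = c("none", "up", "down", "smote"),
                            ...) {
  family <- match.arg(family)
  sampling <- match.arg(sampling)
  structure(list(family = family, sampling = sampling, opts = list(...)),
            class = "classifier_spec")
}

#' @export
format.classifier_spec <- function(x, ...) {
  paste0(x$family, if (x$sampling != "none") paste0("+", x$sampling))
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat("<classifier_spec>", format(x), "\n")
  invisible(x)
}

# Ledoit-Wolf-style automatic shrinkage of a pooled covariance toward the
# scaled identity; keeps LDA well-posed when features outnumber samples.
shrink_covariance <- function(centred, n_eff) {
  p <- ncol(centred)
  s <- crossprod(centred) / n_eff
  mu <- sum(diag(s)) / p
  target <- diag(mu, p)
  d2 <- sum((s - target)^2)
  if (d2 < .Machine$double.eps) return(list(sigma = s, lambda = 0))
  b2 <- sum(rowSums(centred^2)^2) / n_eff^2 - sum(s^2) / n_eff
  lambda <- max(0, min(1, b2 / d2))
  list(sigma = (1 - lambda) * s + lambda * target, lambda = lambda)
}

#' Train a binary spectral classifier
#'
#' Fits one of the four supported families on a training matrix and exposes
#' a common `predict()` returning positive-class (`"mutated"`) probabilities
#' in \[0, 1\]. LDA uses a pooled covariance shrunk toward the scaled
#' identity with automatic intensity (class-frequency priors); PLS-DA
#' regresses a 0/1 response on latent components and calibrates a logistic
#' link on the fitted score; random forest and SVM delegate to
#' \pkg{randomForest} and \pkg{e1071} with probability output enabled.
#'
#' @param x training matrix (rows = spectra)
#' @param labels two-class labels; `"mutated"` is the positive class
#' @param spec a [classifier_spec()]
#' @param seed RNG seed (rf/svm internals)
#' @return a `gliospec_model`; use `predict(model, newx)` for probabilities.
#' @export
train_classifier <- function(x, labels, spec = classifier_spec("lda"),
                             seed = 1) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop("training needs exactly two classes",
                                 call. = FALSE)
  if (any(table(labels) < 2)) stop("training needs >= 2 spectra per class",
                                   call. = FALSE)
  if (!all(is.finite(x))) stop("training matrix contains non-finite values",
                               call. = FALSE)
  positive <- if ("mutated" %in% classes) "mutated" else classes[2]
  y <- as.integer(labels == positive)
  fit <- with_seed(seed, switch(spec$family,
    lda = fit_lda_shrink(x, y),
    plsda = fit_plsda(x, y, ncomp = spec$opts$ncomp %||% 10),
    rf = randomForest::randomForest(
      x = x, y = factor(y, levels = c(0, 1)),
      ntree = spec$opts$ntree %||% 500,
      mtry = spec$opts$mtry %||% max(1, floor(sqrt(ncol(x))))),
    svm = e1071::svm(x = x, y = factor(y, levels = c(0, 1)),
                     kernel = "radial", cost = spec$opts$cost %||% 1,
                     gamma = spec$opts$gamma %||%
                       (1 / (ncol(x) * max(mean(apply(x, 2, var)), 1e-12))),
                     probability = TRUE, scale = FALSE)
  ))
  structure(list(family = spec$family, fit = fit, positive = positive,
                 classes = classes, p = ncol(x)),
            class = "gliospec_model")
}

fit_lda_shrink <- function(x, y) {
  mu0 <- colMeans(x[y == 0, , drop = FALSE])
  mu1 <- colMeans(x[y == 1, , drop = FALSE])
  centred <- rbind(sweep(x[y == 0, , drop = FALSE], 2, mu0),
                   sweep(x[y == 1, , drop = FALSE], 2, mu1))
  sc <- shrink_covariance(centred, n_eff = nrow(x) - 2)
  ridge <- sc$sigma + diag(1e-10 * max(diag(sc$sigma)), ncol(x))
  w <- solve(ridge, mu1 - mu0)
  # log posterior odds: w'x + b with class-frequency priors
  b <- -0.5 * sum(w * (mu1 + mu0)) + log(mean(y == 1) / mean(y == 0))
  list(w = w, b = b, lambda = sc$lambda)
}

fit_plsda <- function(x, y, ncomp) {
  ncomp <- max(1, min(ncomp, nrow(x) - 1, ncol(x)))
  colnames(x) <- paste0("V", seq_len(ncol(x)))
  pls <- mixOmics::pls(x, y, ncomp = ncomp, mode = "regression", scale = FALSE)
  score <- predict(pls, x)$predict[, 1, ncomp]
  link <- suppressWarnings(glm(y ~ score, family = binomial()))
  list(pls = pls, link = coef(link), ncomp = ncomp)
}

#' @export
predict.gliospec_model <- function(object, newx, ...) {
  newx <- as.matrix(newx)
  if (ncol(newx) != object$p) stop("feature count mismatch", call. = FALSE)
  prob <- switch(object$family,
    lda = stats::plogis(drop(newx %*% object$fit$w) + object$fit$b),
    plsda = {
      colnames(newx) <- paste0("V", seq_len(ncol(newx)))
      score <- predict(object$fit$pls, newx)$predict[, 1, object$fit$ncomp]
      stats::plogis(object$fit$link[1] + object$fit$link[2] * score)
    },
    rf = predict(object$fit, newx, type = "prob")[, "1"],
    svm = {
      pr <- predict(object$fit, newx, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    }
  )
  unname(pmin(pmax(as.numeric(prob), 0), 1))
}

#' @export
print.gliospec_model <- function(x, ...) {
  cat(sprintf("<gliospec_model> family=%s, %d features, positive class '%s'\n",
              x$family, x$p, x$positive))
  invisible(x)
}

#' Aggregate per-spectrum probabilities to group-level calls
#'
#' Groups (tissue cores, or patients for serum) are called from their member
#' spectra either by majority vote over per-spectrum hard calls at threshold
#' `p`, or from the mean positive-class probability compared against `p`.
#' Exact ties on the vote (even splits, or probabilities equal to `p`) fall
#' back to the mean-probability rule, which is deterministic and consistent
#' with the ROC threshold sweep.
#'
#' @param probs per-spectrum positive-class probabilities
#' @param meta metadata tibble aligned to `probs`, with `group_id` and
#'   `class_label`
#' @param mode `"majority_vote"` or `"mean_prob"`
#' @param threshold probability threshold `p`
#' @return tibble with one row per group: `group_id`, `score` (mean
#'   probability), `vote_fraction`, `n_member_spectra`, `call`,
#'   `class_label`.
#' @export
aggregate_group <- function(probs, meta, mode = c("majority_vote",
                                                  "mean_prob"),
                            threshold = 0.5) {
  mode <- match.arg(mode)
  meta <- tibble::as_tibble(meta)
  if (length(probs) != nrow(meta)) {
    stop("every spectrum needs a group assignment", call. = FALSE)
  }
  if (nrow(meta) == 0) stop("empty group table", call. = FALSE)
  out <- tibble::tibble(group_id = meta$group_id,
                        class_label = meta$class_label, prob = probs) |>
    dplyr::summarise(
      score = mean(.data$prob),
      vote_fraction = mean(.data$prob > threshold),
      n_tied = sum(.data$prob == threshold),
      n_member_spectra = dplyr::n(),
      class_label = .data$class_label[1],
      .by = "group_id"
    )
  call_mean <- ifelse(out$score >= threshold, "mutated", "wildtype")
  if (mode == "mean_prob") {
    out$call <- call_mean
  } else {
    n_pos <- out$vote_fraction * out$n_member_spectra
    n_neg <- out$n_member_spectra - n_pos - out$n_tied
    out$call <- ifelse(n_pos > n_neg, "mutated",
                       ifelse(n_neg > n_pos, "wildtype", call_mean))
  }
  out$n_tied <- NULL
  out |> dplyr::relocate("class_label", .after = "call")
}

#' Gini feature importance from a random forest model
#'
#' Per-wavenumber impurity (Gini) decrease summed over all nodes of the
#' forest, sorted descending — the importance layout used to report the most
#' discriminating spectral regions.
#'
#' @param model a `gliospec_model` with `family = "rf"`
#' @param grid wavenumber grid matching the training features
#' @param top_k rows to keep (default 15)
#' @return tibble with `wavenumber`, `sum_gini`, `rank`, `assignment`
#'   (nearest entry of [band_assignments()], `NA` beyond 12 cm^-1).
#' @export
gini_importance <- function(model, grid, top_k = 15) {
  if (!inherits(model, "gliospec_model") || model$family != "rf") {
    stop("gini_importance needs a random forest gliospec_model",
         call. = FALSE)
  }
  imp <- randomForest::importance(model$fit, type = 2)[, 1]
  if (length(grid) != length(imp)) stop("grid length mismatch", call. = FALSE)
  assign_tbl <- band_assignments()
  out <- tibble::tibble(wavenumber = as.numeric(grid),
                        sum_gini = unname(imp)) |>
    dplyr::arrange(dplyr::desc(.data$sum_gini)) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    head(top_k)
  near <- vapply(out$wavenumber, function(w) {
    i <- which.min(abs(assign_tbl$wavenumber - w))
    if (abs(assign_tbl$wavenumber[i] - w) <= 12) assign_tbl$assignment[i]
    else NA_character_
  }, character(1))
  out$assignment <- near
  out
}
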