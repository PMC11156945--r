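# Normative modeling of odor identification against age: RANSAC quadratic
# fit, per-subject deviation scores, and per-odorant identification rates.

#' RANSAC quadratic fit of smell-identification score against age
#'
#' Repeatedly fits `score = a0 + a1*age + a2*age^2` by least squares on a
#' random subset of `sample_size` subjects, classifies every subject as an
#' inlier when the absolute residual is at most `threshold` points, and keeps
#' the model with the most inliers (ties broken by the first iteration found
#' under the seeded RNG). The returned coefficients are refit on the winning
#' consensus inlier set, which stabilizes them; the best minimal-sample
#' coefficients are also kept.
#'
#' @param ages,scores Numeric vectors of equal length.
#' @param n_iter Number of random subsets (default 5000).
#' @param sample_size Subjects per subset (default 20).
#' @param threshold Inlier residual bound, score points (default 6).
#' @param seed Integer seed.
#' @return Object of class `ransac_fit`: `coeffs` (refit on inliers),
#'   `coeffs_minimal` (best subset fit), `inlier_mask`, `n_inliers`,
#'   `threshold`, `n_iter`, `sample_size`, `n_skipped` (singular subsets).
#' @export
fit_ransac_quadratic <- function(ages, scores, n_iter = 5000L, sample_size = 20L,
                                 threshold = 6, seed = NULL) {
  stopifnot(length(ages) == length(scores))
  if (any(!is.finite(ages)) || any(!is.finite(scores))) {
    stop("ages and scores must be finite", call. = FALSE)
  }
  n <- length(ages)
  if (n < sample_size) stop("need at least `sample_size` subjects", call. = FALSE)
  X <- cbind(1, ages, ages^2)
  with_seed(seed, {
    best_n <- -1L
    best_coef <- NULL
    best_mask <- NULL
    n_skipped <- 0L
    for (it in seq_len(n_iter)) {
      idx <- sample.int(n, sample_size)
      fit <- tryCatch(qr.coef(qr(X[idx, , drop = FALSE]), scores[idx]),
                      error = function(e) NULL)
      if (is.null(fit) || anyNA(fit)) { n_skipped <- n_skipped + 1L; next }
      resid <- scores - as.vector(X %*% fit)
      mask <- abs(resid) <= threshold
      n_in <- sum(mask)
      if (n_in > best_n) {
        best_n <- n_in; best_coef <- fit; best_mask <- mask
      }
    }
    if (is.null(best_coef)) stop("all RANSAC iterations degenerate", call. = FALSE)
    refit <- qr.coef(qr(X[best_mask, , drop = FALSE]), scores[best_mask])
    if (anyNA(refit)) refit <- best_coef
    final_mask <- abs(scores - as.vector(X %*% refit)) <= threshold
    structure(list(coeffs = stats::setNames(as.vector(refit), c("a0", "a1", "a2")),
                   coeffs_minimal = stats::setNames(as.vector(best_coef),
                                                    c("a0", "a1", "a2")),
                   inlier_mask = final_mask,
                   n_inliers = sum(final_mask),
                   threshold = threshold, n_iter = n_iter,
                   sample_size = sample_size, n_skipped = n_skipped,
                   seed = seed),
              class = "ransac_fit")
  })
}

#' @export
print.ransac_fit <- function(x, ...) {
  cat("<ransac_fit> score =", signif(x$coeffs[1], 4), "+",
      signif(x$coeffs[2], 4), "* age +", signif(x$coeffs[3], 4), "* age^2;",
      x$n_inliers, "inliers (threshold", x$threshold, "points)\n")
  invisible(x)
}

#' Predict normative scores from a RANSAC fit
#'
#' @param object A `ransac_fit`.
#' @param ages Ages at which to evaluate the curve.
#' @param ... Unused.
#' @return Predicted scores.
#' @export
predict.ransac_fit <- function(object, ages, ...) {
  as.vector(cbind(1, ages, ages^2) %*% object$coeffs)
}

#' Deviation of each subject from the normative aging curve
#'
#' Observed minus predicted; negative values mean odor identification worse
#' than the age norm.
#'
#' @param fit A `ransac_fit`.
#' @param ages,scores Subject data.
#' @return Numeric vector of deviations, score points.
#' @export
deviation_scores <- function(fit, ages, scores) {
  scores - predict(fit, ages)
}

#' Per-odorant identification rates
#'
#' @param table Subject table with the 40 binary `odorant_*` columns.
#' @param sort Return rates sorted decreasingly (the usual bar-plot order)?
#' @return Named numeric vector of identification fractions in `[0, 1]`; the
#'   attribute `"order"` records the sort permutation when sorted.
#' @export
odorant_rates <- function(table, sort = FALSE) {
  cols <- odorant_cols()
  missing <- setdiff(cols, names(table))
  if (length(missing)) stop("missing odorant columns: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  rates <- colMeans(as.matrix(table[cols]))
  if (sort) {
    o <- order(rates, decreasing = TRUE)
    rates <- rates[o]
    attr(rates, "order") <- o
  }
  rates
}
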