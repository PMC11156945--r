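# Shared fixtures and independent oracles used across test files.

quick_cohort <- function(n = 60, seed = 1, ...) {
  generate_cohort(cohort_spec(n_subjects = n, seed = seed, ...))
}

noise_volume <- function(n, d = c(10, 10, 10), seed = NULL, voxdim = c(2, 2, 2)) {
  if (!is.null(seed)) set.seed(seed)
  volume_set(matrix(rnorm(n * prod(d)), n), dim = d, voxdim = voxdim)
}

default_covariates <- c("age", "sex", "apoe4", "smoking")

# independent partial-correlation oracle: residualize on the conditioning
# set with lm, then correlate
pcor_resid <- function(x, y, Z = NULL) {
  if (is.null(Z) || NCOL(Z) == 0) return(stats::cor(x, y))
  Z <- as.matrix(Z)
  stats::cor(stats::resid(stats::lm(x ~ Z)), stats::resid(stats::lm(y ~ Z)))
}

fisher_p <- function(r, n, q) {
  2 * stats::pnorm(-sqrt(n - q - 3) * abs(atanh(r)))
}

# brute-force conditional-independence skeleton: an edge survives iff no
# subset of all remaining nodes separates its endpoints
brute_skeleton <- function(data, alpha = 0.05) {
  data <- as.matrix(data)
  p <- ncol(data); n <- nrow(data)
  adj <- matrix(TRUE, p, p)
  diag(adj) <- FALSE
  for (i in seq_len(p - 1)) for (j in seq(i + 1, p)) {
    others <- setdiff(seq_len(p), c(i, j))
    for (sz in 0:length(others)) {
      subsets <- if (sz == 0) list(integer(0)) else if (length(others) == 1)
        list(others) else utils::combn(others, sz, simplify = FALSE)
      sep <- FALSE
      for (S in subsets) {
        r <- pcor_resid(data[, i], data[, j],
                        if (length(S)) data[, S, drop = FALSE] else NULL)
        if (fisher_p(r, n, length(S)) > alpha) { sep <- TRUE; break }
      }
      if (sep) { adj[i, j] <- adj[j, i] <- FALSE; break }
    }
  }
  adj
}

# row-wise z-score without scale() attributes
rowz <- function(m) {
  t(apply(m, 1, function(r) (r - mean(r)) / stats::sd(r)))
}

# pairwise ranking AUC of planted edges against score
edge_auc <- function(score, label) {
  pos <- score[label]; neg <- score[!label]
  (mean(outer(pos, neg, ">")) + 0.5 * mean(outer(pos, neg, "==")))
}
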