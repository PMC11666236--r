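#' @importFrom stats pnorm pwilcox rnbinom rpois runif rlnorm rnorm rbinom
#'   p.adjust chisq.test fisher.test phyper prcomp sd qpois
#' @importFrom methods as is
NULL

# Two-sided Wilcoxon rank-sum p-value and U statistic for one gene.
# Exact null distribution (stats::pwilcox) when both groups are small and the
# values carry no ties -- this equals the exhaustive permutation distribution.
# Otherwise the tie-corrected normal approximation with continuity correction,
# matching stats::wilcox.test(exact = FALSE, correct = TRUE).
rank_sum_one <- function(x, idx_a, idx_b) {
  na <- length(idx_a)
  nb <- length(idx_b)
  r <- rank(c(x[idx_a], x[idx_b]))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  n <- na + nb
  nties <- table(r)
  has_ties <- any(nties > 1)
  if (!has_ties && na < 50 && nb < 50) {
    p <- if (u > na * nb / 2) {
      2 * pwilcox(u - 1, na, nb, lower.tail = FALSE)
    } else {
      2 * pwilcox(u, na, nb)
    }
    p <- min(1, p)
  } else {
    z <- u - na * nb / 2
    sigma2 <- (na * nb / 12) *
      ((n + 1) - sum(nties^3 - nties) / (n * (n - 1)))
    if (sigma2 <= 0) return(c(u = u, p = 1))
    corr <- sign(z) * 0.5
    z <- (z - corr) / sqrt(sigma2)
    p <- 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE))
    p <- min(1, p)
  }
  c(u = u, p = p)
}

# Rank-sum scan across the rows (genes) of a matrix.
rank_sum_scan <- function(mat, idx_a, idx_b) {
  mat <- as.matrix(mat)
  out <- matrix(NA_real_, nrow = nrow(mat), ncol = 2,
                dimnames = list(rownames(mat), c("u", "p")))
  for (i in seq_len(nrow(mat))) {
    out[i, ] <- rank_sum_one(mat[i, ], idx_a, idx_b)
  }
  out
}

# log2 fold-change of group means on the de-logged normalised scale
# (counts per target_sum), stabilised by a small pseudocount.
log2_fc_means <- function(norm, idx_a, idx_b, pseudocount = 1e-4) {
  ma <- Matrix::rowMeans(expm1(norm[, idx_a, drop = FALSE]))
  mb <- Matrix::rowMeans(expm1(norm[, idx_b, drop = FALSE]))
  log2((ma + pseudocount) / (mb + pseudocount))
}

# Row variances for a sparse or dense matrix without densifying.
row_vars <- function(x) {
  m <- Matrix::rowMeans(x)
  m2 <- Matrix::rowMeans(x^2)
  n <- ncol(x)
  stats::setNames(pmax(0, (m2 - m^2) * n / (n - 1)), rownames(x))
}

# Negative-binomial mean giving a target detection probability P(X > 0) = p
# at dispersion `size`: solves (size / (size + mu))^size = 1 - p.
mu_from_detection <- function(p, size) {
  stopifnot(all(p >= 0), all(p < 1))
  size * ((1 - p)^(-1 / size) - 1)
}

# Zero-truncated Poisson draws by inversion; deterministic under set.seed.
rztpois <- function(n, lambda) {
  p0 <- exp(-lambda)
  qpois(p0 + runif(n) * (1 - p0), lambda)
}

split_ids <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
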