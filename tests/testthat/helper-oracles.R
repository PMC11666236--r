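# Independent brute-force oracles used across the suite. These are kept
# deliberately naive (enumeration, closed forms from choose()) so they
# never share code with the implementation paths they check.

# Two-sided exhaustive-permutation rank-sum p-value: enumerate every
# assignment of the pooled values into groups of the observed sizes and
# count assignments at least as extreme (|U - E[U]|) as observed.
perm_rank_sum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  na <- length(x)
  r <- rank(pooled)
  mu <- na * (n - na) / 2
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combs <- utils::combn(n, na)
  us <- apply(combs, 2, function(ii) sum(r[ii]) - na * (na + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Two-sided Fisher p by hypergeometric enumeration over all tables with
# the observed margins, from choose() products.
enum_fisher_p <- function(a, b, c2, d) {
  r1 <- a + b; c1 <- a + c2; n <- a + b + c2 + d
  as <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- choose(r1, as) * choose(n - r1, c1 - as) / choose(n, c1)
  sum(probs[probs <= probs[as == a] * (1 + 1e-7)])
}

# One-sided (over-representation) enumeration oracle.
enum_hyper_upper_p <- function(overlap, n_set, n_universe, n_drawn) {
  as <- max(0, n_set + n_drawn - n_universe):min(n_set, n_drawn)
  probs <- choose(n_set, as) * choose(n_universe - n_set, n_drawn - as) /
    choose(n_universe, n_drawn)
  sum(probs[as >= overlap])
}

# Direct Benjamini-Hochberg from the definition on sorted p-values.
direct_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

# Tiny deterministic count matrix with mitochondrial genes, for QC and
# normalisation unit tests.
toy_counts <- function() {
  m <- rbind(
    GJA4     = c(5, 0, 2, 1),
    DLL4     = c(4, 1, 0, 0),
    RUNX1    = c(0, 6, 1, 2),
    BG1      = c(1, 2, 3, 4),
    `MT-ND1` = c(1, 1, 1, 3))
  colnames(m) <- paste0("cell", 1:4)
  methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}

# Small two-population expression matrix; population A expresses the S
# markers, population B the T markers, on a shared noisy baseline.
two_pop_counts <- function(n_per = 60, n_genes = 40, shift_genes = 5,
                           shift_mean = 6, seed = 42) {
  set.seed(seed)
  genes <- c(sprintf("S%02d", seq_len(shift_genes)),
             sprintf("T%02d", seq_len(shift_genes)),
             sprintf("G%02d", seq_len(n_genes - 2 * shift_genes)))
  mu <- matrix(0.5, n_genes, 2 * n_per, dimnames = list(genes, NULL))
  if (shift_genes > 0) {
    a_cells <- seq_len(n_per)
    mu[seq_len(shift_genes), a_cells] <- shift_mean
    mu[shift_genes + seq_len(shift_genes), -a_cells] <- shift_mean
  }
  x <- matrix(rnbinom(length(mu), mu = as.vector(mu), size = 2),
              nrow = n_genes,
              dimnames = list(genes, sprintf("c%03d", seq_len(2 * n_per))))
  list(counts = methods::as(Matrix::Matrix(x, sparse = TRUE),
                            "CsparseMatrix"),
       truth = rep(c("A", "B"), each = n_per))
}

# Small simulation config for fast module tests.
small_sim_config <- function(seed = 1, n_cells = 400, n_genes = 600, ...) {
  sim_config(seed = seed, n_cells_per_library = n_cells,
             n_genes = n_genes, ...)
}

# Effect-free configuration: no activation, no expansion, no effector
# induction, no biased guide sampling.
null_sim_config <- function(seed, n_cells = 500, n_genes = 600) {
  tg <- default_targets()
  tg$activation_fold <- 1
  sim_config(seed = seed, n_cells_per_library = n_cells,
             n_genes = n_genes, targets = tg,
             arterial_expansion_fold_NT = 1,
             arterial_expansion_fold_AGM = 1,
             effector_induction_fold = 1,
             driver_arterial_weight = 1)
}

# Planted truth helpers for a perturb_sim.
truth_guides <- function(sim) {
  lapply(strsplit(sim$truth$cells$guides, ";", fixed = TRUE), sort)
}
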