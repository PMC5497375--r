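# Independent oracles used to cross-check the package's computations.
# These deliberately re-derive every quantity from first principles
# (textbook formulas, pair counting, exhaustive set algebra) and never
# call the implementation they verify.

# Adjusted Rand index by explicit pair counting over all object pairs.
oracle_ari <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  n11 <- n10 <- n01 <- n00 <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (sa && !sb) n10 <- n10 + 1
      else if (!sa && sb) n01 <- n01 + 1
      else n00 <- n00 + 1
    }
  }
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) return(1)
  2 * (n11 * n00 - n10 * n01) / den
}

# Exact upper-tail hypergeometric P(X >= k) by direct convolution sum.
# For N <= 30 every binomial coefficient and partial sum is an integer
# below 2^53, so double arithmetic is exact up to the single final
# division.
oracle_hyper_upper <- function(k, K, N, n) {
  i <- seq(max(k, 0, n - (N - K)), min(K, n))
  if (length(i) == 0 || min(K, n) < k) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Benjamini-Hochberg step-up by its definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# Pearson correlation, its t transform and two-sided p, from the
# textbook formulas.
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  list(r = r, t = t, p = p)
}

# Welch and Student two-sample t statistics from the textbook formulas.
oracle_ttest <- function(a, b, variant = "welch") {
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  if (variant == "welch") {
    se2 <- va / na + vb / nb
    t <- (mean(b) - mean(a)) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    t <- (mean(b) - mean(a)) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  }
  list(t = t, p = 2 * stats::pt(-abs(t), df = df), df = df)
}

# Pearson chi-square on the 2x2 table via sum((O - E)^2 / E).
oracle_chisq_2x2 <- function(n1, k1, n2, k2) {
  obs <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2)
  exp_ <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  stat <- sum((obs - exp_)^2 / exp_)
  list(chi_square = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

# Build a coexpr_network object directly from an edge data.frame, for
# unit tests of the hub/pivot stage that need a hand-crafted topology.
make_network <- function(edges, nodes = NULL) {
  if (is.null(edges$sign)) edges$sign <- "correlated"
  structure(
    list(edges = edges, tested = edges,
         nodes = sort(unique(c(edges$gene_a, edges$gene_b, nodes))),
         n_tested = nrow(edges), n_skipped_missing = 0,
         n_skipped_constant = 0, q_cutoff = 0.01),
    class = "coexpr_network"
  )
}

# Small expression-matrix builder.
make_em <- function(values, stage, units = "TPM", lengths = NULL) {
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  }
  expression_matrix(values, stage = stage, units = units, lengths = lengths)
}

# Random feasible three-set Venn specification (exclusive regions drawn
# directly, so feasibility holds by construction).
random_venn_spec <- function() {
  r <- stats::rpois(7, lambda = 15)   # A, B, C, AB, AC, BC, ABC exclusive
  list(
    sizes = c(r[1] + r[4] + r[5] + r[7],
              r[2] + r[4] + r[6] + r[7],
              r[3] + r[5] + r[6] + r[7]),
    pairwise = c(r[4] + r[7], r[5] + r[7], r[6] + r[7]),
    triple = r[7],
    union = sum(r)
  )
}
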