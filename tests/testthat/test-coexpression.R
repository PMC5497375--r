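test_that("PPI loading drops self-interactions and merges orientations", {
  df <- data.frame(gene_a = c("A", "B", "A"), gene_b = c("B", "A", "A"),
                   interaction_type = c("physical", "genetic", "physical"))
  net <- suppressMessages(load_ppi(df))
  expect_identical(nrow(net), 1L)
  expect_identical(net$interaction_type, "physical")  # first record wins
  expect_identical(attr(net, "n_self_dropped"), 1L)
  expect_identical(attr(net, "n_duplicates_dropped"), 1L)

  empty <- suppressMessages(load_ppi(df[0, ]))
  expect_identical(nrow(empty), 0L)

  expect_error(suppressMessages(
    load_ppi(data.frame(gene_a = c("A", NA), gene_b = c("B", "C")))
  ), "line")
})

test_that("PPI dedup agrees with a set-based oracle on a large random table", {
  set.seed(6)
  ids <- paste0("G", 1:60)
  a <- sample(ids, 1000, replace = TRUE)
  b <- sample(ids, 1000, replace = TRUE)
  net <- suppressMessages(load_ppi(data.frame(gene_a = a, gene_b = b)))
  keep <- a != b
  oracle_n <- length(unique(paste(pmin(a[keep], b[keep]),
                                  pmax(a[keep], b[keep]))))
  expect_identical(nrow(net), oracle_n)
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  set.seed(7)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_false(is.unsorted(q[order(p)]))   # monotone in sorted order
    expect_true(all(q >= p))
  }
})

test_that("edge correlation annotates PPI edges with exact PCC statistics", {
  set.seed(8)
  n_samples <- 9
  stage <- rep(c("a", "b", "c"), each = 3)
  base <- rnorm(n_samples)
  v <- rbind(
    g1 = base, g2 = base,                   # identical profiles: r = 1
    g3 = rnorm(n_samples), g4 = rnorm(n_samples),
    g5 = rep(2, n_samples)                  # constant gene
  )
  colnames(v) <- paste0("s", 1:n_samples)
  em <- make_em(2^v, stage = stage)
  ppi <- data.frame(gene_a = c("g1", "g3", "g3"),
                    gene_b = c("g2", "g4", "g5"))
  net <- edge_correlation(ppi, em, q_cutoff = 0.01)

  expect_identical(net$n_skipped_constant, 1L)
  e12 <- net$tested[net$tested$gene_a == "g1", ]
  expect_equal(e12$r, 1, tolerance = 1e-12)
  expect_identical(e12$p, 0)
  expect_identical(e12$sign, "correlated")
  expect_true("g1" %in% net$nodes && "g2" %in% net$nodes)
})

test_that("PCC and its t-transform match the direct-formula oracle", {
  set.seed(9)
  n_samples <- 12
  v <- matrix(rnorm(100 * n_samples), 100, n_samples,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:n_samples)))
  em <- make_em(2^v, stage = rep(c("a", "b", "c", "d"), each = 3))
  pairs <- matrix(sample(rownames(v), 100), ncol = 2)
  ppi <- data.frame(gene_a = pairs[, 1], gene_b = pairs[, 2])
  net <- edge_correlation(ppi, em, q_cutoff = 1)
  expect_identical(nrow(net$tested), 50L)
  for (i in seq_len(50)) {
    o <- oracle_pearson(2^v[net$tested$gene_a[i], ],
                        2^v[net$tested$gene_b[i], ])
    expect_equal(net$tested$r[i], o$r, tolerance = 1e-10)
    expect_equal(net$tested$p[i], o$p, tolerance = 1e-10)
  }
  expect_equal(net$tested$q, oracle_bh(net$tested$p), tolerance = 1e-12)
})

test_that("correlation is symmetric and invariant to sample order", {
  set.seed(10)
  v <- matrix(rexp(2 * 8), 2, 8,
              dimnames = list(c("g1", "g2"), paste0("s", 1:8)))
  em <- make_em(v, stage = rep(c("a", "b"), each = 4))
  r_ab <- edge_correlation(data.frame(gene_a = "g1", gene_b = "g2"), em,
                           q_cutoff = 1)$tested$r
  r_ba <- edge_correlation(data.frame(gene_a = "g2", gene_b = "g1"), em,
                           q_cutoff = 1)$tested$r
  perm <- sample(8)
  em_perm <- make_em(v[, perm], stage = rep(c("a", "b"), each = 4)[perm])
  r_perm <- edge_correlation(data.frame(gene_a = "g1", gene_b = "g2"),
                             em_perm, q_cutoff = 1)$tested$r
  expect_equal(r_ab, r_ba, tolerance = 1e-12)
  expect_equal(r_ab, r_perm, tolerance = 1e-12)
})

test_that("the retained edge set shrinks as the cutoff tightens", {
  set.seed(11)
  v <- matrix(rnorm(40 * 10), 40, 10,
              dimnames = list(paste0("g", 1:40), paste0("s", 1:10)))
  # make some genes correlated so cutoffs bite
  v[2, ] <- v[1, ] + rnorm(10, 0, 0.3)
  v[4, ] <- v[3, ] + rnorm(10, 0, 0.6)
  em <- make_em(2^v, stage = rep(c("a", "b"), each = 5))
  ppi <- data.frame(gene_a = paste0("g", seq(1, 39, 2)),
                    gene_b = paste0("g", seq(2, 40, 2)))
  cuts <- c(1, 0.1, 0.01, 0)
  retained <- lapply(cuts, function(qc) {
    e <- edge_correlation(ppi, em, q_cutoff = qc)$edges
    paste(e$gene_a, e$gene_b)
  })
  for (i in 2:4) expect_true(all(retained[[i]] %in% retained[[i - 1]]))
  expect_length(retained[[4]], 0)   # q = 0 retains nothing here
})

test_that("degenerate networks are rejected up front", {
  em <- make_em(matrix(1:4, 2, 2), stage = c("a", "a"))
  expect_error(edge_correlation(data.frame(gene_a = "g1", gene_b = "g2"),
                                em), "3 samples")
  em3 <- make_em(matrix(rexp(6), 2, 3), stage = c("a", "a", "a"))
  expect_error(edge_correlation(data.frame(gene_a = "x1", gene_b = "x2"),
                                em3), "share no gene")
})

test_that("null-edge p-values are calibrated at the nominal level", {
  set.seed(12)
  n_edges <- 2000
  v <- matrix(rnorm(2 * n_edges * 10), 2 * n_edges, 10,
              dimnames = list(paste0("g", 1:(2 * n_edges)), paste0("s", 1:10)))
  em <- make_em(2^v, stage = rep(c("a", "b"), each = 5))
  ppi <- data.frame(gene_a = paste0("g", seq(1, 2 * n_edges, 2)),
                    gene_b = paste0("g", seq(2, 2 * n_edges, 2)))
  p <- edge_correlation(ppi, em, q_cutoff = 1)$tested$p
  mc_sd <- sqrt(0.05 * 0.95 / n_edges)
  expect_lt(abs(mean(p <= 0.05) - 0.05), 3 * mc_sd)
})
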