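test_that("two-sample t equals the textbook formulas", {
  r <- two_sample_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_identical(c(r$t, r$p), c(0, 1))

  set.seed(20)
  for (i in 1:100) {
    a <- rnorm(sample(3:8, 1))
    b <- rnorm(sample(3:8, 1), mean = runif(1, -1, 1))
    for (variant in c("welch", "student")) {
      got <- two_sample_ttest(a, b, variant)
      want <- oracle_ttest(a, b, variant)
      expect_equal(got$t, want$t, tolerance = 1e-10)
      expect_equal(got$p, want$p, tolerance = 1e-10)
      expect_equal(got$df, want$df, tolerance = 1e-10)
    }
  }

  # degenerate variance conventions
  expect_identical(two_sample_ttest(c(2, 2), c(2, 2))$p, 1)
  expect_warning(r0 <- two_sample_ttest(c(1, 1), c(2, 2)), "zero variance")
  expect_identical(r0$p, 0)
  expect_error(two_sample_ttest(1, c(1, 2)), ">= 2")
})

test_that("stage contrasts apply the dual fold-change + FDR rule", {
  sim <- generate_stage_expression(
    n_genes = 60, modules = list(c(5, 0.9)), n_pivots = 0,
    de_spec = list(list(stage_a = "4cell", stage_b = "8cell", n_de = 10,
                        fold_change = 3)),
    noise_sd = 0.1, seed = 22
  )
  de <- stage_de(sim$expression, "4cell", "8cell")
  truth <- sim$truth$de_genes[["4cell_vs_8cell"]]
  hit <- de[match(truth$gene, de$gene), ]
  expect_true(all(hit$significant))
  expect_identical(hit$direction, truth$direction)
  expect_true(all(de$fold_change >= 1))
  # significant implies both thresholds
  expect_true(all(de$q[de$significant] < 0.05))
  expect_true(all(de$fold_change[de$significant] > 1.4))
})

test_that("a gene identical across groups is a clean negative", {
  v <- matrix(c(5, 5, 5, 5, 5, 5,
                1, 2, 3, 9, 10, 11), 2, 6, byrow = TRUE,
              dimnames = list(c("flat", "moves"), paste0("s", 1:6)))
  em <- make_em(v, stage = rep(c("a", "b"), each = 3))
  de <- suppressWarnings(stage_de(em, "a", "b"))
  flat <- de[de$gene == "flat", ]
  expect_identical(flat$fold_change, 1)
  expect_identical(flat$direction, "none")
  expect_false(flat$significant)
})

test_that("a fold change of exactly 1.4 never passes the strict cutoff", {
  v <- matrix(c(rep(10, 3), rep(14, 3)), 1, 6,
              dimnames = list("edge", paste0("s", 1:6)))
  em <- make_em(v, stage = rep(c("a", "b"), each = 3))
  de <- suppressWarnings(stage_de(em, "a", "b"))
  expect_identical(de$fold_change, 1.4)
  expect_false(de$significant)   # p may be 0; the FC rule is strict
})

test_that("planted directions are reproduced exactly at zero noise", {
  sim <- generate_stage_expression(
    n_genes = 40, modules = list(), n_pivots = 0,
    de_spec = list(list(stage_a = "zygote", stage_b = "morula", n_de = 12,
                        fold_change = 2)),
    noise_sd = 0, seed = 23
  )
  de <- suppressWarnings(stage_de(sim$expression, "zygote", "morula"))
  truth <- sim$truth$de_genes[["zygote_vs_morula"]]
  expect_identical(de$direction[match(truth$gene, de$gene)],
                   truth$direction)
})

test_that("group sizes below two replicates are rejected", {
  v <- matrix(rexp(6), 2, 3, dimnames = list(c("g1", "g2"),
                                             c("s1", "s2", "s3")))
  em <- make_em(v, stage = c("a", "a", "b"))
  expect_error(stage_de(em, "a", "b"), "2 replicates")
})

test_that("null contrasts are calibrated and BH controls false discoveries", {
  set.seed(24)
  n_genes <- 2000
  v <- matrix(2^rnorm(n_genes * 6, 5), n_genes, 6,
              dimnames = list(sprintf("g%04d", 1:n_genes), paste0("s", 1:6)))
  em <- make_em(v, stage = rep(c("a", "b"), each = 3))
  de <- stage_de(em, "a", "b")
  mc_sd <- sqrt(0.05 * 0.95 / n_genes)
  expect_lt(abs(mean(de$p <= 0.05) - 0.05), 4 * mc_sd)

  # under the global null every BH discovery is false: the average
  # false-discovery proportion stays at or below the nominal level
  fdp <- vapply(1:50, function(s) {
    set.seed(24 + s)
    v <- matrix(2^rnorm(400 * 6, 5), 400, 6,
                dimnames = list(sprintf("g%03d", 1:400), paste0("s", 1:6)))
    d <- stage_de(make_em(v, stage = rep(c("a", "b"), each = 3)), "a", "b",
                  fc_cutoff = 0)
    n_rej <- sum(d$q < 0.05)
    if (n_rej > 0) 1 else 0
  }, numeric(1))
  expect_lte(mean(fdp), 0.05 + 3 * sqrt(0.05 * 0.95 / 50))
})

test_that("cross-dataset overlap intersects and ranks shared significants", {
  mk_de <- function(genes, sig, q, fc) {
    structure(
      data.frame(gene = genes, mean_a = 1, mean_b = 1, fold_change = fc,
                 direction = "up", t = 0, p = q, q = q, significant = sig,
                 stringsAsFactors = FALSE),
      class = c("de_result", "data.frame")
    )
  }
  a <- mk_de(c("g1", "g2", "g3", "g4"), c(TRUE, TRUE, TRUE, FALSE),
             c(0.001, 0.04, 0.01, 0.2), c(5, 2, 3, 1))
  b <- mk_de(c("g1", "g2", "g3", "g4"), c(TRUE, TRUE, FALSE, TRUE),
             c(0.03, 0.002, 0.5, 0.01), c(2, 6, 1, 4))

  # default ranking: worst-of-the-two q, ascending
  got <- cross_dataset_overlap(a, b)
  key <- pmax(a$q[1:2], b$q[1:2])
  expect_identical(got, c("g1", "g2")[order(key)])

  # fold-change ranking: worst-of-the-two FC, descending
  got_fc <- cross_dataset_overlap(a, b, rank_by = "max_fc")
  key_fc <- pmin(a$fold_change[1:2], b$fold_change[1:2])
  expect_identical(got_fc, c("g1", "g2")[order(-key_fc)])

  # disjoint significant sets
  expect_length(cross_dataset_overlap(
    mk_de("g1", TRUE, 0.01, 3),
    mk_de("g1", FALSE, 0.9, 1)
  ), 0)
  expect_error(cross_dataset_overlap(mk_de("g1", TRUE, 0.01, 2),
                                     mk_de("zz", TRUE, 0.01, 2)),
               "share no gene")
})

test_that("ddCt fold changes follow the analytic formula", {
  expect_identical(ddct_relative_expression(20, 15, 22, 17), 1)
  expect_identical(ddct_relative_expression(20, 16, 22, 17), 2)
  expect_identical(ddct_relative_expression(24, 17, 22, 17), 0.25)

  # replicate batch against a spreadsheet-style hand computation
  set.seed(25)
  ct_t <- rnorm(9, 24, 0.3)
  ct_h <- rnorm(9, 15, 0.2)
  cal_t <- 25; cal_h <- 15.5
  got <- ddct_relative_expression(ct_t, ct_h, cal_t, cal_h)
  hand <- 2^(-((ct_t - ct_h) - (cal_t - cal_h)))
  expect_equal(got, hand, tolerance = 1e-12)
  expect_equal(mean(got), mean(hand))
  expect_error(ddct_relative_expression(NA, 1, 1, 1), "finite")
})
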