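test_that("TPM normalisation follows its closed form", {
  # single gene: everything collapses to one million
  em1 <- make_em(matrix(7, 1, 2), stage = c("a", "a"), units = "counts",
                 lengths = c(g1 = 500))
  expect_equal(unname(compute_tpm(em1)$values[1, ]), c(1e6, 1e6))

  # two genes, equal counts and lengths: an even split
  em2 <- make_em(matrix(4, 2, 2), stage = c("a", "a"), units = "counts",
                 lengths = c(g1 = 100, g2 = 100))
  expect_equal(unname(compute_tpm(em2)$values[, 1]), c(5e5, 5e5))

  # hand-evaluated example: counts 10/20/30 on equal lengths
  em3 <- make_em(matrix(c(10, 20, 30), 3, 1), stage = "a", units = "counts",
                 lengths = c(g1 = 1000, g2 = 1000, g3 = 1000))
  expect_equal(unname(compute_tpm(em3)$values[, 1]),
               c(166666.67, 333333.33, 500000.00), tolerance = 1e-6)

  # unequal lengths: rate normalisation, computed by the definition
  em4 <- make_em(matrix(c(10, 10), 2, 1), stage = "a", units = "counts",
                 lengths = c(g1 = 100, g2 = 400))
  expect_equal(unname(compute_tpm(em4)$values[, 1]), c(8e5, 2e5))
})

test_that("TPM columns sum to one million; zero columns warn", {
  set.seed(1)
  vals <- matrix(rpois(60, 50), 10, 6)
  lens <- stats::setNames(sample(200:2000, 10), paste0("g", 1:10))
  em <- make_em(vals, stage = rep(c("a", "b"), each = 3), units = "counts",
                lengths = lens)
  tpm <- compute_tpm(em)
  expect_equal(unname(colSums(tpm$values)), rep(1e6, 6), tolerance = 1e-6)

  vals[, 2] <- 0
  em0 <- make_em(vals, stage = rep(c("a", "b"), each = 3), units = "counts",
                 lengths = lens)
  expect_warning(tpm0 <- compute_tpm(em0), "all-zero")
  expect_equal(unname(tpm0$values[, 2]), rep(0, 10))
})

test_that("expressed-gene filter applies strict stage-wise rules", {
  # TPM 2 throughout one stage: kept
  v <- matrix(0.5, 2, 6)
  v[1, 1:3] <- 2
  em <- make_em(v, stage = rep(c("a", "b"), each = 3))
  expect_identical(filter_expressed(em), "g1")

  # exactly at the threshold everywhere: dropped (strict >)
  em_edge <- make_em(matrix(1, 1, 6), stage = rep(c("a", "b"), each = 3))
  expect_length(filter_expressed(em_edge), 0)

  # exhaustive check of all 2^3 replicate indicator patterns with 3
  # replicates in a single stage: kept iff expressed in >= 2 of 3
  for (bits in 0:7) {
    pattern <- as.integer(intToBits(bits))[1:3]
    v <- matrix(ifelse(pattern == 1, 5, 0.1), nrow = 1)
    em_p <- make_em(v, stage = rep("a", 3))
    expect_identical(length(filter_expressed(em_p)) == 1L, sum(pattern) >= 2,
                     info = paste("pattern", bits))
  }
})

test_that("filter is monotone in its threshold", {
  set.seed(2)
  em <- make_em(matrix(rexp(200, 1 / 2), 20, 10),
                stage = rep(c("a", "b"), each = 5))
  kept <- lapply(c(0.5, 1, 2, 4), function(th) filter_expressed(em, th))
  for (i in 2:4) expect_true(all(kept[[i]] %in% kept[[i - 1]]))
})

test_that("probe collapse picks the most expressed probe per gene", {
  v <- matrix(c(1, 2, 3,    # p1 mean 2
                5, 9, 7,    # p2 mean 7
                4, 5, 6),   # p3 mean 5
              3, 3, byrow = TRUE,
              dimnames = list(c("p1", "p2", "p3"), c("s1", "s2", "s3")))
  em <- make_em(v, stage = c("a", "a", "b"))
  map <- data.frame(probe = c("p1", "p2", "p3"),
                    gene = c("GENEA", "GENEA", "GENEB"))
  out <- collapse_probes(em, map)
  expect_identical(rownames(out$values), c("GENEA", "GENEB"))
  expect_equal(unname(out$values["GENEA", ]), c(5, 9, 7))   # p2 wins
  expect_equal(unname(out$values["GENEB", ]), c(4, 5, 6))   # single probe

  # tie on the mean: lexicographically smallest probe id
  v_tie <- v
  v_tie["p1", ] <- v_tie["p2", c(3, 1, 2)]   # same mean, different order
  em_tie <- make_em(v_tie, stage = c("a", "a", "b"))
  out_tie <- collapse_probes(em_tie, map)
  expect_equal(unname(out_tie$values["GENEA", ]),
               unname(v_tie["p1", ]))

  expect_error(collapse_probes(em, map[1:2, ]), "p3")
})

test_that("probe collapse matches a brute-force argmax oracle", {
  set.seed(3)
  probes <- sprintf("pr%02d", 1:20)
  genes <- sample(paste0("gene", 1:6), 20, replace = TRUE)
  v <- matrix(rexp(20 * 4, 1 / 10), 20, 4,
              dimnames = list(probes, paste0("s", 1:4)))
  em <- make_em(v, stage = c("a", "a", "b", "b"))
  map <- data.frame(probe = probes, gene = genes)
  out <- collapse_probes(em, map)
  expect_identical(nrow(out$values), length(unique(genes)))
  for (g in unique(genes)) {
    rows <- probes[genes == g]
    best <- rows[which.max(rowMeans(v[rows, , drop = FALSE]))]
    expect_equal(unname(out$values[g, ]), unname(v[best, ]), info = g)
  }
})

test_that("detection filter keeps detected probes by default", {
  v <- matrix(1, 4, 3, dimnames = list(paste0("p", 1:4), paste0("s", 1:3)))
  em <- make_em(v, stage = c("a", "a", "b"))
  all_detected <- matrix(0, 4, 3)
  expect_identical(nrow(detection_filter(em, all_detected)$values), 4L)
  none_detected <- matrix(1, 4, 3)
  expect_identical(nrow(detection_filter(em, none_detected)$values), 0L)

  set.seed(4)
  dp <- matrix(runif(4 * 3), 4, 3)
  out <- detection_filter(em, dp, alpha = 0.05, min_samples = 1)
  keep_oracle <- apply(dp, 1, function(row) any(row < 0.05))
  expect_identical(rownames(out$values), rownames(v)[keep_oracle])

  # literal polarity: retain probes NOT detected
  out_lit <- detection_filter(em, dp, keep_detected = FALSE)
  keep_lit <- apply(dp, 1, function(row) sum(row <= 0.05) < 1)
  expect_identical(rownames(out_lit$values), rownames(v)[keep_lit])

  expect_error(detection_filter(em, dp[1:2, ]), "shape")
})

test_that("quantile normalisation equalises column distributions", {
  # already-identical columns are a fixed point
  v <- matrix(c(1, 5, 9), 3, 4, dimnames = list(paste0("g", 1:3),
                                                paste0("s", 1:4)))
  em <- make_em(v, stage = rep("a", 4))
  expect_equal(quantile_normalize(em)$values, v)

  # hand-evaluated 2x2 case
  v2 <- matrix(c(1, 3, 4, 2), 2, 2,
               dimnames = list(c("g1", "g2"), c("s1", "s2")))
  em2 <- make_em(v2, stage = c("a", "a"))
  out2 <- quantile_normalize(em2)$values
  expect_equal(unname(out2[, 1]), c(1.5, 3.5))
  expect_equal(unname(out2[, 2]), c(3.5, 1.5))

  # column means equalised on arbitrary input
  set.seed(5)
  v3 <- matrix(rlnorm(50 * 6), 50, 6)
  em3 <- make_em(v3, stage = rep(c("a", "b"), each = 3))
  out3 <- quantile_normalize(em3)$values
  expect_equal(diff(range(colMeans(out3))), 0, tolerance = 1e-10)

  expect_error(quantile_normalize(make_em(matrix(1:3, 3, 1), stage = "a")),
               "2 samples")
})
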