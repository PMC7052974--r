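make_counts <- function(m, genes = NULL) {
  n <- nrow(m)
  if (is.null(genes)) genes <- rep(sprintf("g%03d", seq_len(ceiling(n / 2))),
                                   each = 2)[seq_len(n)]
  screen_counts(data.frame(guide_id = sprintf("sg%03d", seq_len(n)),
                           gene_id = genes, stringsAsFactors = FALSE), m)
}

test_that("screen_counts validates its inputs", {
  m <- matrix(1:6, 3, dimnames = list(NULL, c("lib_R1_1", "t1_R1_1")))
  cm <- make_counts(m)
  expect_s3_class(cm, "screen_counts")
  expect_equal(dim(cm), c(3L, 2L))
  g <- data.frame(guide_id = c("a", "a", "b"), gene_id = "x")
  expect_error(screen_counts(g, m), "duplicate")
  m2 <- m; m2[1] <- -1
  expect_error(make_counts(m2), "non-negative")
})

test_that("size normalization equalizes treatment totals to the reference", {
  m <- matrix(c(500, 300, 200, 1000, 600, 400), ncol = 2,
              dimnames = list(NULL, c("ref", "trt")))
  out <- size_normalize(m, "ref")
  expect_equal(out[, "ref"], m[, "ref"])
  expect_equal(out[, "trt"], m[, "trt"] / 2)
  expect_equal(sum(out[, "trt"]), sum(out[, "ref"]))
  # equal totals: unchanged
  m3 <- cbind(ref = c(10, 20), trt = c(20, 10))
  expect_equal(size_normalize(m3, "ref"), m3)
  expect_error(size_normalize(cbind(ref = c(0, 0), trt = c(1, 1)), "ref"),
               "degenerate")
})

test_that("lfc follows the pseudocount formula and its symmetries", {
  expect_equal(lfc(0, 0), 0)
  expect_equal(lfc(7, 3), 1)
  expect_equal(lfc(3, 7), -1)
  # antisymmetry under swapping treatment and reference
  set.seed(5)
  a <- rpois(50, 30); b <- rpois(50, 30)
  expect_equal(lfc(a, b), -lfc(b, a))
  expect_error(lfc(-1, 3), "non-negative")
})

test_that("normalization then lfc is invariant to treatment scaling", {
  set.seed(6)
  ref <- rpois(500, 200)
  trt <- rpois(500, 200)
  m1 <- cbind(ref = ref, trt = trt)
  m2 <- cbind(ref = ref, trt = trt * 5)
  l1 <- lfc(size_normalize(m1, "ref")[, "trt"], ref)
  l2 <- lfc(size_normalize(m2, "ref")[, "trt"], ref)
  expect_equal(l1, l2, tolerance = 1e-12)
})

test_that("library_width uses interpolated type-7 percentiles", {
  expect_equal(library_width(rep(7, 20)), 1)
  # 11-point vector with exact order-statistic percentiles
  v <- c(50, 100, 150, 200, 250, 300, 350, 400, 450, 500, 550)
  expect_equal(library_width(v), 5)  # p90/p10 = 500/100
  expect_equal(library_width(seq(100, 200, by = 10)), 190 / 110,
               tolerance = 1e-12)
  # scale invariance
  set.seed(7)
  x <- rlnorm(1000, 5, 0.5)
  expect_equal(library_width(3.7 * x), library_width(x), tolerance = 1e-12)
  expect_error(library_width(c(0, 0, 0, 1, 2, 3, 4, 5, 6, 7, 8, 9)), "0")
  expect_error(library_width(1:5), "at least 10")
})

test_that("tail_fractions is symmetric for symmetric LFCs and zero for zero", {
  n <- 500
  ref <- seq_len(n) * 10
  cm <- make_counts(cbind(lib_R1_1 = ref, t1_R1_1 = ref, t1_R2_1 = ref))
  lf <- lfc_matrix(cm)
  tf <- tail_fractions(lf)
  expect_equal(unname(tf$overall), c(0, 0))
  # hand-built symmetric LFCs: equal +-2 tails
  lf2 <- lf
  lf2[] <- 0
  lf2[1:100, ] <- 2
  lf2[101:200, ] <- -2
  tf2 <- tail_fractions(lf2)
  expect_equal(tf2$overall[["frac_neg"]], tf2$overall[["frac_pos"]])
  expect_equal(tf2$overall[["frac_neg"]], 0.2)
  expect_error(tail_fractions(lf, guides = integer(0)), "empty")
})

test_that("tail fractions per quintile follow reference abundance", {
  # depleted guides concentrated in the lowest-abundance fifth
  n <- 1000
  ref <- seq_len(n)
  m <- cbind(lib_R1_1 = ref, t1_R1_1 = ref)
  cm <- make_counts(m)
  lf <- lfc_matrix(cm)
  lf[1:150, 1] <- -3
  tf <- tail_fractions(lf)
  expect_equal(tf$by_quintile$frac_neg[1], 0.75)
  expect_equal(tf$by_quintile$frac_neg[5], 0)
  expect_equal(sum(tf$by_quintile$n), n)
})

test_that("replicate_correlation detects duplication and independence", {
  n <- 10000
  set.seed(8)
  a <- rnorm(n)
  cm <- make_counts(cbind(lib_R1_1 = rep(100L, n), t1_R1_1 = rep(1L, n),
                          t1_R2_1 = rep(1L, n)))
  lf <- lfc_matrix(cm)
  lf[, 1] <- a; lf[, 2] <- a
  expect_equal(replicate_correlation(lf)$mean_r, 1)
  lf[, 2] <- rnorm(n)
  expect_lt(abs(replicate_correlation(lf)$mean_r), 0.05)
})

test_that("collapse_technical sums technical replicates per sample", {
  m <- cbind(lib_R1_1 = c(1, 2), lib_R1_2 = c(3, 4),
             t1_R1_1 = c(5, 6), t1_R1_2 = c(7, 8), t1_R2_1 = c(9, 10))
  cm <- make_counts(m)
  cc <- collapse_technical(cm)
  expect_equal(colnames(cc$counts), c("lib_R1", "t1_R1", "t1_R2"))
  expect_equal(unname(cc$counts[, "lib_R1"]), c(4, 6))
  expect_equal(unname(cc$counts[, "t1_R1"]), c(12, 14))
  expect_equal(unname(cc$counts[, "t1_R2"]), c(9, 10))
})

test_that("wider libraries lower replicate correlation of LFCs", {
  r <- vapply(c(2.5, 17), function(w) {
    sim <- quiet_sim(small_params(lib_width = w, cov_cells = 100,
                                  rng_seed = 31))
    replicate_correlation(lfc_matrix(sim$counts))$mean_r
  }, numeric(1))
  expect_gt(r[1], r[2])
})
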