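toy_truth <- c(g1 = "negative", g2 = "negative", g3 = "neutral",
               g4 = "negative", g5 = "neutral", g6 = "neutral")

test_that("precision_recall enumerates the toy curve by hand", {
  # positives at ranking positions 1, 2 and 4
  pr <- precision_recall(names(toy_truth), toy_truth, "negative")
  expect_equal(pr$precision, c(1, 1, 2/3, 3/4, 3/5, 3/6))
  expect_equal(pr$recall, c(1/3, 2/3, 2/3, 1, 1, 1))
  # perfect ranking: precision 1 until recall 1
  perfect <- c("g1", "g2", "g4", "g3", "g5", "g6")
  prp <- precision_recall(perfect, toy_truth, "negative")
  expect_equal(prp$precision[1:3], rep(1, 3))
  expect_equal(prp$recall[3], 1)
  # reversed ranking: precision at full recall equals prevalence
  rev_pr <- precision_recall(rev(perfect), toy_truth, "negative")
  expect_equal(rev_pr$precision[6], 0.5)
  expect_error(precision_recall(names(toy_truth), toy_truth, "missing"),
               "no genes")
  expect_error(precision_recall(c("gX"), toy_truth), "missing")
})

test_that("recall_at_precision takes the best qualifying prefix", {
  pr <- precision_recall(names(toy_truth), toy_truth, "negative")
  expect_equal(recall_at_precision(pr, 0.95), 2/3)
  expect_equal(recall_at_precision(pr, 0.7), 1)
  expect_equal(recall_at_precision(pr, 1), 2/3)
  perfect <- precision_recall(c("g1", "g2", "g4", "g3", "g5", "g6"),
                              toy_truth, "negative")
  expect_equal(recall_at_precision(perfect, 0.99), 1)
  # nothing qualifies
  bad <- precision_recall(c("g3", "g5", "g6", "g1", "g2", "g4"),
                          toy_truth, "negative")
  expect_equal(recall_at_precision(bad, 0.99), 0)
})

test_that("cells_required is the coverage product", {
  expect_equal(cells_required(100000, 500), 5e7)
  expect_equal(cells_required(1, 1), 1)
  expect_equal(cells_required(50000, 400), 2e7)
})

test_that("sweep_tail_fractions records per-cell seeds and repeats", {
  p <- tiny_params()
  res <- suppressMessages(
    sweep_tail_fractions(p, "cov_cells", c(100, 800), n_repeats = 2))
  expect_equal(nrow(res), 4)
  expect_equal(unique(res$param), "cov_cells")
  expect_true(all(res$frac_neg >= 0 & res$frac_neg <= 1))
  expect_equal(anyDuplicated(res$seed), 0)
  # re-running a cell from its stored seed reproduces the metric
  p2 <- unclass(p)
  p2$cov_cells <- res$value[1]
  p2$rng_seed <- res$seed[1]
  sim <- quiet_sim(do.call(sim_params, p2))
  expect_equal(neutral_tail_fractions(sim)[["frac_neg"]], res$frac_neg[1])
})

test_that("asymmetry grows as cell-splitting coverage falls", {
  p <- small_params()
  res <- suppressMessages(
    sweep_tail_fractions(p, "cov_cells", c(100, 400, 1500), n_repeats = 2))
  m <- tapply(res$frac_neg, res$value, mean)
  m <- m[order(as.numeric(names(m)))]
  expect_true(all(diff(m) <= 0))
  # negative tail always exceeds the positive tail
  expect_true(all(res$frac_neg >= res$frac_pos))
})

test_that("PCR and transduction coverage matter far less than cell coverage", {
  p <- small_params()
  cells <- suppressMessages(
    sweep_tail_fractions(p, "cov_cells", c(100, 1500), n_repeats = 2))
  pcr <- suppressMessages(
    sweep_tail_fractions(p, "cov_pcr", c(100, 1500), n_repeats = 2))
  spread <- function(d) {
    m <- tapply(d$frac_neg, d$value, mean)
    max(m) - min(m)
  }
  expect_gt(spread(cells), 3 * spread(pcr))
})

test_that("recommend_coverage picks the smallest adequate coverage", {
  # deterministic stand-in recall: grows with coverage, shrinks with width
  fake_recall <- function(params, seed) {
    min(1, params$cov_cells / (100 * params$lib_width))
  }
  rec <- recommend_coverage(5, c(100, 300, 500, 700), target_recall = 0.9,
                            params = tiny_params(), n_repeats = 2,
                            recall_fun = fake_recall)
  expect_s3_class(rec, "coverage_recommendation")
  expect_equal(rec$recommended, 500)
  expect_output(print(rec), "recommended coverage: 500")
  # unattainable target reported as NA with the best recall achieved
  rec2 <- recommend_coverage(20, c(100, 300), target_recall = 0.9,
                             params = tiny_params(), n_repeats = 1,
                             recall_fun = fake_recall)
  expect_true(is.na(rec2$recommended))
  expect_equal(rec2$max_recall, 0.15)
  expect_output(print(rec2), "unattainable")
  # recommendation is monotone in library width under a monotone metric
  recs <- vapply(c(2.5, 5, 10), function(w) {
    r <- recommend_coverage(w, c(100, 300, 500, 700, 1100),
                            target_recall = 0.9, params = tiny_params(),
                            n_repeats = 1, recall_fun = fake_recall)
    if (is.na(r$recommended)) Inf else r$recommended
  }, numeric(1))
  expect_true(all(diff(recs) >= 0))
})

test_that("lower splitting coverage degrades symmetric-null recall", {
  rec <- vapply(c(100, 400), function(cc) {
    p <- small_params(cov_cells = cc, rng_seed = 61)
    res <- suppressMessages(benchmark_recall(
      p, n_repeats = 2, precision_level = 0.95,
      fit_args = list(n_strata = 5, n_perm = 150, xi_fixed = 1)))
    mean(res$recall)
  }, numeric(1))
  expect_lt(rec[1], rec[2])
})

test_that("benchmark_recall runs the simulate-analyse-score cycle", {
  p <- small_params(rng_seed = 71)
  res <- suppressMessages(
    benchmark_recall(p, n_repeats = 2, precision_level = 0.9,
                     fit_args = list(n_strata = 4, n_perm = 100)))
  expect_equal(nrow(res), 2)
  expect_true(all(res$recall >= 0 & res$recall <= 1))
  # at this scale and precision the planted essentials are detectable
  expect_gt(mean(res$recall), 0.3)
})
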