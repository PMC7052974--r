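test_that("generate_library reproduces the target width and lognormal mean", {
  p <- sim_params(rng_seed = 3)
  lib <- generate_library(p)
  expect_equal(nrow(lib), 50000)
  expect_equal(unname(table(lib$gene_id)[1]), 4)
  w <- library_width(lib$plasmid_abundance)
  expect_gt(w, 7.5 * 0.9)
  expect_lt(w, 7.5 * 1.1)
  # lognormal mean identity exp(mu + sigma^2/2)
  expect_equal(mean(lib$plasmid_abundance),
               exp(5 + sigma_for_width(7.5)^2 / 2), tolerance = 0.02)
})

test_that("a width-1 library is a constant pool of round(e^5) copies", {
  lib <- generate_library(tiny_params(lib_width = 1))
  expect_true(all(lib$plasmid_abundance == 148))
})

test_that("assign_fitness partitions genes per the stated fractions", {
  p <- sim_params(rng_seed = 8)
  f <- assign_fitness(p)
  expect_equal(nrow(f), 12500)
  expect_equal(sum(f$fitness_class == "negative"), 1250)
  expect_equal(sum(f$fitness_class == "positive"), 125)
  expect_true(all(f$epsilon[f$fitness_class == "neutral"] == 0))
  expect_true(all(f$epsilon %in% seq(0, 0.2, by = 0.01)))
  beta <- growth_factor(72, 30)
  neg <- f$fitness_class == "negative"
  pos <- f$fitness_class == "positive"
  expect_equal(f$growth_rate[neg], beta * (1 - f$epsilon[neg]))
  expect_equal(f$growth_rate[pos], beta * (1 + f$epsilon[pos]))
  expect_true(all(f$growth_rate[f$fitness_class == "neutral"] == beta))
  # an epsilon of 0 makes a "negative" gene behave exactly neutrally
  eps0 <- neg & f$epsilon == 0
  expect_true(any(eps0))
  expect_true(all(f$growth_rate[eps0] == beta))
})

test_that("all-neutral assignment leaves every growth rate at baseline", {
  f <- assign_fitness(tiny_params(freq_negfc = 0, freq_posfc = 0))
  expect_true(all(f$fitness_class == "neutral"))
  expect_equal(unique(f$growth_rate), growth_factor(72, 30))
})

test_that("grow_pool doubles, truncates, and keeps extinction absorbing", {
  expect_equal(grow_pool(0, log(2)), 0)
  expect_equal(grow_pool(100, log(2)), 200)
  # truncation after multiplying by e^beta (148 * 2^2.4 = 781.1...)
  expect_equal(grow_pool(148, growth_factor(72, 30)), 781)
  # vectorized per-guide rates; never decreases counts for beta >= 0
  x <- c(0, 3, 17, 400)
  g <- grow_pool(x, c(0, 0.1, 1, 2))
  expect_true(all(g >= x))
  expect_equal(g[1], 0)
})

test_that("subsample_pool honours exhaustive, zero and overdraw contracts", {
  pool <- c(10, 0, 25, 5)
  expect_equal(subsample_pool(pool, sum(pool)), pool)
  expect_equal(subsample_pool(pool, 0), rep(0, 4))
  set.seed(1)
  s <- subsample_pool(pool, 20)
  expect_true(all(s <= pool))
  expect_equal(sum(s), 20)
  expect_equal(s[2], 0)
  # overdraw: cap returns the pool, multinomial resamples to n_draws
  expect_equal(subsample_pool(pool, 100, overdraw = "cap"), pool)
  expect_message(m <- subsample_pool(pool, 100), "multinomial")
  expect_equal(sum(m), 100)
  expect_error(subsample_pool(c(0, 0), 5, stage = "t0"), "t0")
  expect_error(subsample_pool(pool, -1), ">= 0")
})

test_that("subsample_pool matches closed-form hypergeometric moments", {
  # two-guide pool (60, 40), 50 draws: mean 30, var 50*.6*.4*(50/99)
  set.seed(42)
  x <- vapply(seq_len(50000), function(i) subsample_pool(c(60, 40), 50)[1],
              numeric(1))
  expect_equal(mean(x), 30, tolerance = 0.005)
  expect_equal(var(x), 50 * 0.6 * 0.4 * (50 / 99), tolerance = 0.03)
  # marginal expectation n_draws * p_g for a larger pool
  set.seed(43)
  pool <- c(500, 1500, 3000)
  s <- rowMeans(vapply(seq_len(4000), function(i) subsample_pool(pool, 1000),
                       numeric(3)))
  expect_equal(s, 1000 * pool / sum(pool), tolerance = 0.02)
})

test_that("simulate_screen emits the full sample layout with equal depth", {
  p <- tiny_params()
  sim <- quiet_sim(p)
  cn <- colnames(sim$counts$counts)
  expect_equal(cn, c("lib_R1_1", "t0_R1_1", "t1_R1_1", "t1_R2_1"))
  # sequencing depth: min(cov_pcr * n, pool) under without-replacement,
  # cov_pcr * n when the multinomial fallback applied
  expect_true(all(colSums(sim$counts$counts) == p$cov_pcr * p$n_sgrnas))
  expect_equal(nrow(sim$truth), 200)
  expect_setequal(unique(sim$truth$fitness_class),
                  c("neutral", "negative", "positive"))
})

test_that("same seed reproduces the screen; different seeds differ", {
  p <- tiny_params()
  a <- quiet_sim(p)
  b <- quiet_sim(p)
  expect_identical(a$counts$counts, b$counts$counts)
  p2 <- tiny_params(rng_seed = 999)
  c2 <- quiet_sim(p2)
  expect_false(identical(a$counts$counts, c2$counts$counts))
})

test_that("without splittings, T1 equals T0 up to sequencing noise", {
  p <- small_params(n_splittings = 0, freq_negfc = 0, freq_posfc = 0)
  sim <- quiet_sim(p)
  lf <- lfc_matrix(sim$counts, reference = "t0_R1_1",
                   treatments = c("t1_R1_1", "t1_R2_1"))
  # T1 sequencing draws come from the same pool as T0 sequencing
  expect_lt(abs(mean(unclass(lf))), 0.02)
  expect_lt(sd(unclass(lf)), 0.25)
})

test_that("abundance width broadens monotonically over splitting rounds", {
  p <- small_params(cov_cells = 100, freq_negfc = 0, freq_posfc = 0)
  sim <- quiet_sim(p, track_pools = TRUE)
  widths <- apply(sim$split_pools, 2, library_width)
  expect_equal(length(widths), p$n_splittings)
  expect_true(all(diff(widths) > 0))
  # and the initial pool is narrower than after the first bottleneck
  expect_gt(widths[1], library_width(sim$library$plasmid_abundance))
})

test_that("negative-gene guides are already depleted at T0", {
  # mean LFC(T0 vs library) lower for negative guides, more so for fast
  # growth (small tau)
  gap <- vapply(c(30, 90), function(tau) {
    sim <- quiet_sim(small_params(dupl_time = tau, rng_seed = 77))
    lf <- lfc_matrix(sim$counts, treatments = "t0_R1_1")
    cls <- sim$library$fitness_class
    mean(unclass(lf)[cls == "neutral", ]) -
      mean(unclass(lf)[cls == "negative", ])
  }, numeric(1))
  expect_gt(gap[1], 0)
  expect_gt(gap[2], 0)
  expect_gt(gap[1], gap[2])
})

test_that("an empty pool raises a simulation-collapse error with its stage", {
  # draws of zero cells at transduction collapse the pool immediately
  p <- tiny_params(lib_width = 1)
  lib <- generate_library(p)
  expect_error(subsample_pool(rep(0, 10), 5, stage = "split_1_2"),
               "split_1_2")
})

test_that("replicate LFC signs agree barely above chance for neutral guides", {
  # biological replicates share the transduced pool and the plasmid
  # reference column, so their LFCs carry a common noise component;
  # the per-replicate bottleneck noise still dominates, keeping the
  # sign correlation small (it would be ~1 for real fitness effects)
  p <- small_params(freq_negfc = 0, freq_posfc = 0)
  sim <- quiet_sim(p)
  lf <- unclass(lfc_matrix(sim$counts))
  r <- cor(sign(lf[, 1]), sign(lf[, 2]))
  expect_lt(abs(r), 0.25)
  # by contrast, strongly depleted guides agree in sign almost always
  p2 <- small_params(freq_negfc = 0.1)
  sim2 <- quiet_sim(p2)
  lf2 <- unclass(lfc_matrix(sim2$counts))
  strong <- sim2$library$fitness_class == "negative" &
    sim2$library$epsilon >= 0.1
  agree <- mean(sign(lf2[strong, 1]) == sign(lf2[strong, 2]))
  expect_gt(agree, 0.9)
})
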