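test_that("configuration enumeration counts, order, and cap", {
  cfgs <- enumerate_configurations(2, 2)
  expect_length(cfgs, 4L)
  expect_identical(cfgs[[1]], integer(0))
  expect_identical(cfgs[2:4], list(1L, 2L, c(1L, 2L)))

  expect_length(enumerate_configurations(10, 2), 56L)  # 1 + 10 + 45
  expect_length(enumerate_configurations(3, 1), 4L)

  # deterministic order: by size then lexicographic
  cfgs <- enumerate_configurations(4, 3)
  sizes <- lengths(cfgs)
  expect_true(!is.unsorted(sizes))
  expect_identical(cfgs[sizes == 2L][[1]], c(1L, 2L))

  expect_error(enumerate_configurations(200, 5, cap = 5e6), "cap")
})

test_that("log Bayes factor matches hand-derived values", {
  expect_identical(log_bayes_factor(integer(0), make_region(5, matrix(1)), 1), 0)
  # single causal, z = 5, W = 1: -log(2)/2 + 25/4
  expect_equal(log_bayes_factor(1, make_region(5, matrix(1)), 1),
               -0.5 * log(2) + 25 / 4, tolerance = 1e-12)
  # perfect-LD pair, z = (5,5): the Lemma-2 form handles the singular block
  reg <- make_region(c(5, 5), matrix(1, 2, 2))
  expect_equal(log_bayes_factor(1:2, reg, 1), -0.5 * log(3) + 25 / 3,
               tolerance = 1e-12)
  expect_error(log_bayes_factor(c(1, 1), reg, 1), "unique")
})

test_that("Lemma-2 form agrees with the direct density-ratio oracle", {
  for (case in 1:20) {
    n <- 2 + (case %% 7)                      # n in 2..8
    ld <- random_corr(n, seed = 1000 + case)
    set.seed(2000 + case)
    reg <- make_region(rnorm(n, sd = 3), ld, id = paste0("o", case))
    W <- c(0.5, 1, 2)[1 + case %% 3]
    for (config in list(1L, c(1L, 2L), seq_len(min(n, 3L)))) {
      got <- log_bayes_factor(config, reg, W)
      want <- direct_log_bf_oracle(config, reg, W)
      expect_equal(got, want, tolerance = 1e-8)
    }
  }
})

test_that("BF depends only on the causal sub-block (Lemma 1)", {
  ld <- random_corr(6, seed = 7)
  set.seed(8)
  z <- rnorm(6, sd = 2)
  reg <- make_region(z, ld)
  ref <- log_bayes_factor(c(2L, 4L), reg, 1)
  z2 <- z
  z2[c(1, 3, 5, 6)] <- rnorm(4, sd = 5)       # perturb non-causal only
  expect_identical(log_bayes_factor(c(2L, 4L), make_region(z2, ld), 1), ref)
})

test_that("independence additivity: log BF sums over singletons when LD = I", {
  set.seed(11)
  z <- rnorm(5, sd = 3)
  reg <- make_region(z, diag(5))
  singles <- vapply(1:5, function(i) log_bayes_factor(i, reg, 1), numeric(1))
  for (config in list(c(1L, 3L), c(2L, 4L, 5L), 1:5))
    expect_equal(log_bayes_factor(config, reg, 1), sum(singles[config]),
                 tolerance = 1e-10)
})

test_that("pairwise closed form matches its substitutions and the generic BF", {
  for (W in c(0.25, 1, 3))
    expect_equal(pairwise_mismatch_bf(0, 0, W), -0.5 * log(1 + 2 * W),
                 tolerance = 1e-12)
  expect_equal(pairwise_mismatch_bf(5, 5, 1), -0.5 * log(3) + 25 / 3,
               tolerance = 1e-12)
  # a=6, b=0: the W(a-b)^2 mismatch term contributes half the exponent
  expect_equal(pairwise_mismatch_bf(6, 0, 1), -0.5 * log(3) + 12,
               tolerance = 1e-12)
  set.seed(42)
  for (i in 1:25) {
    a <- rnorm(1, sd = 4); b <- rnorm(1, sd = 4); W <- runif(1, 0.1, 5)
    reg <- make_region(c(a, b), matrix(1, 2, 2))
    expect_equal(pairwise_mismatch_bf(a, b, W),
                 log_bayes_factor(1:2, reg, W), tolerance = 1e-10)
  }
})

test_that("store build: symmetric null region, pruning thresholds", {
  reg <- make_region(c(0, 0, 0), diag(3))
  st <- build_bf_store(reg, model_config(W = 1, d = 2, t = Inf))
  expect_identical(st$config_count_total, 7L)
  expect_identical(st$log_bf[1], 0)
  sizes <- lengths(st$configs)
  expect_equal(st$log_bf[sizes == 1L], rep(-0.5 * log(2), 3), tolerance = 1e-12)
  expect_equal(st$log_bf[sizes == 2L], rep(-log(2), 3), tolerance = 1e-12)
  expect_false(st$pruned)

  # t = 0: only the arg-max configuration and the null survive
  reg2 <- make_region(c(8, 1, -2), diag(3))
  st0 <- build_bf_store(reg2, model_config(d = 2, t = 0))
  expect_true(st0$pruned)
  expect_identical(st0$configs[[1]], integer(0))
  expect_equal(max(st0$log_bf), st0$max_log_bf)
  expect_true(all(st0$log_bf == 0 | st0$log_bf == st0$max_log_bf))

  # pruning invariant: every retained BF within t orders of magnitude of max
  st12 <- build_bf_store(make_region(c(12, 11, 0, 1, -1), random_corr(5, 3)),
                         model_config(d = 3, t = 12))
  expect_true(all(st12$log_bf >= st12$max_log_bf - 12 * log(10) |
                    seq_along(st12$log_bf) == 1L))
})

test_that("pruning leaves posteriors unchanged to >= 5 significant digits
           even when most configurations are dropped", {
  for (j in 1:3) {
    sim <- simulate_ld_panel(25, 500, 0.9, seed = 100 + j)
    set.seed(200 + j)
    causal <- sort(sample.int(25, 2))
    zs <- simulate_zscores(sim$ld, causal, lambda = c(10, 10), seed = 300 + j)
    reg <- make_region(zs$z, sim$ld, id = paste0("pr", j))
    exh <- build_bf_store(reg, model_config(d = 3, t = Inf))
    pru <- build_bf_store(reg, model_config(d = 3, t = 12))
    expect_lt(pru$config_count_retained, exh$config_count_retained)
    prior <- rep(1 / 25, 25)
    dg <- mapply(agree_digits,
                 variant_posteriors(exh, prior)$marginal,
                 variant_posteriors(pru, prior)$marginal)
    expect_gte(min(dg), 5)
  }
})

test_that("store serialization round-trips", {
  reg <- make_region(c(4, -1, 2, 0), random_corr(4, 5))
  st <- build_bf_store(reg, model_config(d = 3, t = 12))
  path <- file.path(tempdir(), "store.tsv")
  write_bf_store(st, path)
  back <- read_bf_store(path)
  expect_identical(back$configs, st$configs)
  expect_equal(back$log_bf, st$log_bf, tolerance = 1e-15)
  expect_identical(back$n, st$n)
  expect_identical(back$d, st$d)
  p <- rep(0.1, 4)
  expect_equal(variant_posteriors(back, p)$marginal,
               variant_posteriors(st, p)$marginal, tolerance = 1e-15)
})
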