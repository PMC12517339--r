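make_dataset <- function(n_regions = 40, seed = 9, E = c(-2.5, 1.5), W = 9,
                         rho = 0.3, region_size = 8, n_decoys = 0) {
  simulate_annotated_dataset(n_regions, region_size = region_size, E = E,
                             W = W, rho = rho, n_samples = 150,
                             n_decoys = n_decoys, seed = seed)
}

test_that("total log likelihood: empty list, single-term sum, cache equivalence", {
  expect_identical(total_log_likelihood(list(), list(), numeric(0)), 0)

  # region whose only retained configuration is the null: ll = log q0
  reg <- make_region(0, matrix(1))
  st <- build_bf_store(reg, model_config(t = 0))    # argmax is the null here
  expect_identical(st$config_count_retained, 1L)
  A <- annotation_matrix(matrix(0, 1, 0))
  E0 <- -2
  q0 <- 1 - plogis(E0)
  expect_equal(total_log_likelihood(list(st), list(A), E0), log(q0),
               tolerance = 1e-12)

  # value invariant to precomputed-vs-fresh stores at t = Inf
  ds <- make_dataset(5)
  p1 <- lapply(ds$regions, build_bf_store, params = model_config(W = 9, t = Inf))
  p2 <- lapply(ds$regions, build_bf_store, params = model_config(W = 9, t = Inf))
  E <- c(-2, 0.5)
  expect_identical(total_log_likelihood(p1, ds$amats, E),
                   total_log_likelihood(p2, ds$amats, E))
})

test_that("em_fit: zero iterations, sign of enrichment, monotone likelihood", {
  ds <- make_dataset(30)
  stores <- lapply(ds$regions, build_bf_store, params = model_config(W = 9))

  f0 <- em_fit(stores, ds$amats, columns = 1:2, init_E = c(-1.5, 0.25),
               max_iter = 0L)
  expect_identical(unname(f0$E), c(-1.5, 0.25))
  expect_identical(f0$trace$iterations, 0L)

  # annotation covering the high-Z variant of a clean region: E1 > 0
  reg <- make_region(c(10, 0), diag(2))
  stc <- build_bf_store(reg, model_config())
  Ac <- annotation_matrix(matrix(c(1, 0), 2, dimnames = list(NULL, "hit")))
  fc <- suppressWarnings(em_fit(list(stc), list(Ac), columns = 1:2))
  expect_gt(fc$E[[2]], 0)

  # annotation orthogonal to the signal across many regions: E1 <= 0
  ds2 <- make_dataset(60, seed = 13)
  stores2 <- lapply(ds2$regions, build_bf_store, params = model_config(W = 9))
  anti <- lapply(seq_along(ds2$amats), function(j) {
    A <- ds2$amats[[j]]
    z <- abs(ds2$regions[[j]]$z)
    cover <- as.numeric(rank(z, ties.method = "first") <= 2) # lowest-|z| pair
    annotation_matrix(matrix(cover, ncol = 1,
                             dimnames = list(NULL, "cold")))
  })
  fa <- suppressWarnings(em_fit(stores2, anti, columns = 1:2))
  expect_lte(fa$E[[2]], 0)

  # EM monotonicity of the trace
  fit <- suppressWarnings(em_fit(stores, ds$amats, columns = 1:2))
  expect_true(all(diff(fit$trace$log_likelihood) >= -1e-9))
})

test_that("intercept-only fit reproduces uniform-prior posteriors exactly", {
  ds <- make_dataset(10, seed = 17)
  stores <- lapply(ds$regions, build_bf_store, params = model_config(W = 9))
  fit <- em_fit(stores, ds$amats, columns = 1L)
  p0 <- plogis(fit$E[[1]])
  for (j in c(1L, 5L)) {
    n <- stores[[j]]$n
    a <- variant_posteriors(stores[[j]],
                            region_priors(ds$amats[[j]][, 1, drop = FALSE],
                                          fit$E[[1]]))$marginal
    b <- variant_posteriors(stores[[j]], rep(p0, n))$marginal
    expect_identical(a, b)
  }
})

test_that("likelihood-ratio p-values match the chi-square oracle", {
  expect_identical(lrt_annotation(-10, -10), 1)
  expect_equal(lrt_annotation(-10 + 3.8415 / 2, -10), 0.05, tolerance = 1e-3)
  expect_equal(lrt_annotation(0, -10), pchisq(20, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(lrt_annotation(0, -10), 7.74e-6, tolerance = 1e-2)
  expect_error(lrt_annotation(-11, -10), "negative")
})

test_that("annotation scan: ranking, skips, and determinism", {
  ds <- make_dataset(60, seed = 23, E = c(-3, 2), n_decoys = 6)
  stores <- lapply(ds$regions, build_bf_store, params = model_config(W = 9))
  # add an empty track and a duplicate of the true track
  amats <- lapply(ds$amats, function(A) {
    annotation_matrix(cbind(A[, -1, drop = FALSE],
                            empty = 0, twin = A[, "true_track"]))
  })
  scan <- suppressWarnings(scan_annotations(stores, amats))
  expect_s3_class(scan, "annotation_scan")
  expect_identical(scan$status[scan$track == "empty"], "no_overlap")
  ok <- scan[scan$status == "ok", ]
  # enriched track (and its twin) outrank every decoy
  expect_true(all(ok$track[1:2] %in% c("true_track", "twin")))
  expect_equal(ok$pvalue[ok$track == "true_track"],
               ok$pvalue[ok$track == "twin"], tolerance = 1e-12)
  expect_equal(ok$E1[ok$track == "true_track"],
               ok$E1[ok$track == "twin"], tolerance = 1e-12)
  expect_identical(ok$prior_odds, exp(ok$E1))
  expect_true(!is.unsorted(ok$pvalue))

  scan2 <- suppressWarnings(scan_annotations(stores, amats))
  expect_identical(scan$pvalue, scan2$pvalue)
})
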