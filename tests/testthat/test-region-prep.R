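test_that("sumstats normalization orients z to the alt allele", {
  rows <- data.frame(
    chrom = "1", pos = c(100L, 200L, 300L, 400L),
    ref = c("A", "A", "A", "A"), alt = c("G", "G", "T", "G"),
    effect_allele = c("G", "A", "G", "G"),
    beta = c(0.1, 0.1, 0.1, 0.1), se = c(0.05, 0.05, 0.05, -1),
    pvalue = rep(0.01, 4), stringsAsFactors = FALSE)
  out <- normalize_sumstats(rows)
  expect_equal(out$z[out$pos == 100], 2, tolerance = 1e-12)
  expect_equal(out$z[out$pos == 200], -2, tolerance = 1e-12)  # effect = ref
  dropped <- attr(out, "dropped")
  expect_setequal(dropped$reason, c("allele mismatch", "non-positive se"))
  expect_false(300 %in% out$pos)

  # A/T pair flagged as strand-ambiguous, kept
  amb <- normalize_sumstats(data.frame(
    chrom = "1", pos = 1L, ref = "A", alt = "T", effect_allele = "T",
    z = 1, pvalue = 0.5))
  expect_true(amb$ambiguous)

  expect_error(normalize_sumstats(rows[c(1, 1), ]), "duplicate")
})

test_that("LD from dosages matches a naive two-pass oracle", {
  set.seed(51)
  panel <- matrix(sample(0:2, 200 * 10, replace = TRUE), 200, 10,
                  dimnames = list(NULL, paste0("v", 1:10)))
  ld <- compute_ld(panel)
  naive <- function(x, y) {
    mx <- mean(x); my <- mean(y)
    sum((x - mx) * (y - my)) /
      sqrt(sum((x - mx)^2) * sum((y - my)^2))
  }
  for (pair in list(c(1, 2), c(3, 9), c(5, 5)))
    expect_equal(ld[pair[1], pair[2]],
                 naive(panel[, pair[1]], panel[, pair[2]]), tolerance = 1e-12)

  dup <- cbind(panel, v11 = panel[, 1], v12 = 2 - panel[, 1])
  ld2 <- compute_ld(dup)
  expect_equal(ld2["v1", "v11"], 1, tolerance = 1e-12)
  expect_equal(ld2["v1", "v12"], -1, tolerance = 1e-12)

  expect_error(compute_ld(cbind(panel, mono = 1)), "mono")
})

test_that("greedy LD pruning keeps strongest pairwise-independent tags", {
  vars <- data.frame(variant_id = c("A", "B", "C"),
                     pvalue = c(1e-10, 1e-9, 1e-8 * 0.999))
  ld <- diag(3)
  ld[1, 2] <- ld[2, 1] <- sqrt(0.8)
  ld[1, 3] <- ld[3, 1] <- sqrt(0.1)
  ld[2, 3] <- ld[3, 2] <- sqrt(0.1)
  expect_identical(ld_prune(vars, ld), c(1L, 3L))

  all1 <- matrix(1, 3, 3)
  expect_identical(ld_prune(vars, all1), 1L)   # smallest p wins

  none <- data.frame(variant_id = "A", pvalue = 0.5)
  expect_identical(ld_prune(none, matrix(1)), integer(0))
})

test_that("LD expansion is a union over tags containing the tags", {
  ld <- diag(4)
  ld[1, 2] <- ld[2, 1] <- sqrt(0.8)
  ld[1, 3] <- ld[3, 1] <- sqrt(0.71)
  expect_identical(ld_expand(1L, ld), 1:3)       # strict > 0.7 keeps 0.71
  expect_identical(ld_expand(4L, ld), 4L)
  ld[4, 2] <- ld[2, 4] <- sqrt(0.9)
  expect_identical(ld_expand(c(1L, 4L), ld), 1:4) # shared variant counted once
})

test_that("region bounds respect window and flank-count clips", {
  link_ld <- function(n, linked) {
    ld <- diag(n)
    for (i in linked) for (j in linked) if (i != j) ld[i, j] <- 0.95
    ld
  }
  # window clip: linked variant 1.3 Mbp away is excluded from the bounds
  n <- 30L
  vars <- data.frame(chrom = "1", pos = seq_len(n) * 100000L)
  linked <- c(15L, 14L, 16L, 28L)
  iv <- define_region(15L, linked, vars, link_ld(n, linked))
  expect_identical(iv$start, vars$pos[14L])
  expect_identical(iv$end, vars$pos[16L])

  # count clip: boundary with > max_flank_variants between it and the tag
  n2 <- 50L
  vars2 <- data.frame(chrom = "1", pos = seq_len(n2) * 100L)
  linked2 <- c(10L, 13L, 40L)
  iv2 <- define_region(10L, linked2, vars2, link_ld(n2, linked2),
                       max_flank_variants = 5L)
  expect_identical(iv2$start, vars2$pos[10L])
  expect_identical(iv2$end, vars2$pos[13L])   # 2 intervening <= 5; 29 > 5
})

test_that("interval merging and exclusion windows", {
  mk <- function(s, e, tag = 1L)
    structure(list(chrom = "1", start = s, end = e, tag = tag,
                   merged = FALSE), class = "region_interval")
  m <- merge_regions(list(mk(100, 200), mk(150, 300, 2L)))
  expect_length(m, 1L)
  expect_identical(c(m[[1]]$start, m[[1]]$end), c(100, 300))
  expect_true(m[[1]]$merged)

  t2 <- merge_regions(list(mk(100, 200), mk(201, 300, 2L)))
  expect_length(t2, 2L)                  # touching, 1-based inclusive: no merge
  expect_false(any(vapply(t2, `[[`, logical(1), "merged")))

  s1 <- merge_regions(list(mk(5, 9)))
  expect_length(s1, 1L)
  expect_false(s1[[1]]$merged)

  ivs <- list(mk(26e6, 27e6), mk(100, 200))
  kept <- exclude_regions(ivs, hla_exclusion("1"))
  expect_length(kept, 1L)
  expect_identical(kept[[1]]$start, 100)
  expect_match(attr(kept, "excluded")$reason, "exclusion")
  kept2 <- exclude_regions(ivs, hla_exclusion("6"))   # other chromosome
  expect_length(kept2, 2L)
  expect_identical(exclude_regions(ivs, NULL), ivs)
})

test_that("annotation matrix honors BED half-open boundaries", {
  vars <- data.frame(chrom = "1", pos = c(150L, 200L, 201L, 99L))
  bed <- data.frame(chrom = "1", start = 100, end = 200, name = "x")
  A <- build_annotation_matrix(vars, list(tr = bed))
  expect_identical(colnames(A), c("(intercept)", "tr"))
  expect_identical(unname(A[, "tr"]), c(1, 1, 0, 0))
  expect_identical(unname(A[, 1]), rep(1, 4))

  off <- build_annotation_matrix(vars, list(
    tr = data.frame(chrom = "2", start = 0, end = 1e6, name = "y")))
  expect_identical(unname(off[, 2]), rep(0, 4))
})

test_that("BED reader validates lines and bundle IO round-trips", {
  p <- file.path(tempdir(), "bad.bed")
  writeLines(c("1\t10\t20\tok", "1\t30"), p)
  expect_error(read_bed(p), "line 2")
  writeLines(c("1\t10\t20", "1\t50\t40"), p)
  expect_error(read_bed(p), "line 2")
  writeLines("1\t10\t20\tname1", p)
  bed <- read_bed(p)
  expect_identical(bed$start, 10)

  ld <- random_corr(4, seed = 61)
  set.seed(62)
  reg <- make_region(rnorm(4), ld, id = "rt")
  A <- annotation_matrix(matrix(c(1, 0, 1, 0), 4,
                                dimnames = list(NULL, "tk")))
  dir <- file.path(tempdir(), "bundles")
  prefix <- write_region_bundle(reg, A, dir)
  back <- read_region_bundle(prefix)
  expect_identical(back$region$variants, reg$variants)
  expect_identical(back$region$z, reg$z)
  expect_identical(unname(back$region$ld), unname(reg$ld))
  expect_identical(unname(back$amat), unname(A))
})
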