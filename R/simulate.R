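#' Per-stream seed derivation
#'
#' Counter-based fan-out of one user seed into independent substreams, so
#' that changing the number of regions never shifts the draws of earlier
#' regions. Kept below 2^31 - 1.
#' @noRd
substream_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(counter) * 2654435761)
             %% 2147483647)
}

#' Simulate a genotype dosage panel with AR(1) LD decay
#'
#' Latent-Gaussian haplotype model: each haplotype is a draw from a
#' multivariate normal with AR(1) correlation `rho^|i-j|`, thresholded at
#' the quantile matching a per-variant minor-allele frequency drawn
#' uniformly from `maf_range`; two haplotypes sum to the diploid dosage.
#' This gives a controllable LD decay standing in for a real reference
#' genotype panel. The returned LD matrix is the empirical signed
#' correlation of the dosage columns.
#'
#' @param n_variants number of variants.
#' @param n_samples number of diploid samples (default 500).
#' @param rho AR(1) latent correlation between adjacent variants, in
#'   \[0, 1) (default 0.9).
#' @param maf_range minor-allele frequency range, within (0, 0.5\]
#'   (default c(0.05, 0.5)).
#' @param seed integer seed; identical seeds give identical panels.
#' @return list with `panel` (samples x variants dosage matrix), `ld`
#'   (empirical correlation), `maf` (the drawn frequencies).
#' @export
simulate_ld_panel <- function(n_variants, n_samples = 500, rho = 0.9,
                              maf_range = c(0.05, 0.5), seed = 1L) {
  stopifnot(rho >= 0, rho < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  for (attempt in 1:10) {
    set.seed(substream_seed(seed, attempt - 1L))
    maf <- stats::runif(n_variants, maf_range[1], maf_range[2])
    thr <- stats::qnorm(1 - maf)
    hap <- function() {
      lat <- matrix(stats::rnorm(n_samples * n_variants), n_samples)
      if (rho > 0 && n_variants > 1L) {
        sc <- sqrt(1 - rho^2)
        for (j in 2:n_variants)
          lat[, j] <- rho * lat[, j - 1L] + sc * lat[, j]
      }
      sweep(lat, 2L, thr, `>`) * 1
    }
    panel <- hap() + hap()
    if (all(apply(panel, 2L, stats::var) > 0)) {
      colnames(panel) <- paste0("v", seq_len(n_variants))
      return(list(panel = panel, ld = compute_ld(panel), maf = maf))
    }
  }
  stop("monomorphic variant persisted after 10 resampling attempts; ",
       "raise n_samples or maf_range[1]")
}

#' Simulate GWAS Z-scores from the summary-statistic likelihood
#'
#' One draw of `Z ~ N(Sigma (Lambda o C), Sigma)`: the mean is the LD
#' matrix times the causal effect vector, the noise has the LD matrix as
#' covariance. Sampling uses the eigendecomposition so that singular LD
#' (perfect proxies) is handled without repair beyond clipping negative
#' eigenvalues above `-1e-8` to zero.
#'
#' @param ld signed correlation matrix.
#' @param config integer vector of causal indices (1-based; may be empty).
#' @param lambda effect sizes: either a numeric vector of
#'   `length(config)` fixed effects, or NULL to draw each from `N(0, W)`.
#' @param W effect-size prior variance used when drawing `lambda`.
#' @param seed integer seed, or NULL to use the current RNG state.
#' @return list with `z` (numeric vector) and `lambda` (full-length
#'   effect vector, nonzero only at `config`).
#' @export
simulate_zscores <- function(ld, config = integer(0), lambda = NULL,
                             W = 1, seed = NULL) {
  n <- nrow(ld)
  config <- as.integer(config)
  if (length(config) && (min(config) < 1L || max(config) > n))
    stop("causal config index out of range")
  if (!is.null(seed)) set.seed(substream_seed(seed, 0L))
  lam_full <- numeric(n)
  if (length(config)) {
    if (is.null(lambda)) lambda <- stats::rnorm(length(config), 0, sqrt(W))
    stopifnot(length(lambda) == length(config))
    lam_full[config] <- lambda
  }
  eg <- eigen(ld, symmetric = TRUE)
  if (min(eg$values) < -1e-8)
    stop("LD matrix is not positive semidefinite (min eigenvalue ",
         format(min(eg$values)), ")")
  sdev <- sqrt(pmax(eg$values, 0))
  z <- drop(ld %*% lam_full) +
    drop(eg$vectors %*% (sdev * stats::rnorm(n)))
  list(z = z, lambda = lam_full)
}

#' Simulate a fully annotated multi-region dataset
#'
#' The test bed for enrichment estimation. Per region: an LD panel is
#' simulated; one "true" annotation track covers a random ~`coverage`
#' fraction of variants; each variant's causal status is drawn
#' independently with probability `plogis(E0 + E1 * A_i)` (redrawn until
#' at most `d` causal variants, so the model's configuration space
#' contains the truth); causal effects are `N(0, W)`; Z-scores follow the
#' summary-statistic likelihood. Decoy tracks with no enrichment are laid
#' down the same way but ignored when placing causal variants.
#'
#' @param n_regions number of regions.
#' @param region_size variants per region (default 10).
#' @param E true enrichment coefficients `c(E0, E1)` (default
#'   `c(-3, 2)`: baseline prior ~0.047, about one expected causal variant
#'   per 10-variant region at 20% coverage).
#' @param coverage fraction of variants covered by each track
#'   (default 0.2).
#' @param n_decoys number of unenriched decoy tracks (default 0).
#' @param rho,n_samples,maf_range passed to [simulate_ld_panel()].
#' @param W effect-size prior variance (default 1).
#' @param d maximum causal variants per region (default 2).
#' @param seed integer master seed.
#' @return list with `regions` (list of [region_data]), `amats` (list of
#'   [annotation_matrix], columns: intercept, "true_track", decoys),
#'   `truth` (class `synthetic_truth`: per-region causal configs, lambda,
#'   the true `E`, the seed).
#' @export
simulate_annotated_dataset <- function(n_regions, region_size = 10L,
                                       E = c(-3, 2), coverage = 0.2,
                                       n_decoys = 0L, rho = 0.9,
                                       n_samples = 500L,
                                       maf_range = c(0.05, 0.5),
                                       W = 1, d = 2L, seed = 1L) {
  p_in <- stats::plogis(E[1] + E[2])
  p_out <- stats::plogis(E[1])
  expected <- region_size * (coverage * p_in + (1 - coverage) * p_out)
  if (expected > 5 * d)
    stop("expected causal count per region (", signif(expected, 3),
         ") far exceeds d = ", d, "; lower E0")
  regions <- vector("list", n_regions)
  amats <- vector("list", n_regions)
  configs <- vector("list", n_regions)
  lambdas <- vector("list", n_regions)
  track_names <- c("true_track",
                   if (n_decoys > 0) paste0("decoy_", seq_len(n_decoys)))
  n_cov <- max(1L, round(coverage * region_size))
  for (j in seq_len(n_regions)) {
    sim <- simulate_ld_panel(region_size, n_samples, rho, maf_range,
                             seed = substream_seed(seed, 3L * j))
    set.seed(substream_seed(seed, 3L * j + 1L))
    A <- matrix(0, region_size, 1L + n_decoys,
                dimnames = list(NULL, track_names))
    A[sample.int(region_size, n_cov), 1L] <- 1
    if (n_decoys > 0)
      for (k in seq_len(n_decoys))
        A[sample.int(region_size, n_cov), k + 1L] <- 1
    p_causal <- stats::plogis(E[1] + E[2] * A[, 1L])
    repeat {
      causal <- which(stats::runif(region_size) < p_causal)
      if (length(causal) <= d) break
    }
    zs <- simulate_zscores(sim$ld, causal, lambda = NULL, W = W,
                           seed = substream_seed(seed, 3L * j + 2L))
    rid <- sprintf("sim_region_%03d", j)
    pos <- seq_len(region_size) * 1000L
    regions[[j]] <- region_data(
      rid,
      data.frame(variant_id = paste0(rid, "_v", seq_len(region_size)),
                 chrom = "1", pos = pos, ref = "A", alt = "G",
                 stringsAsFactors = FALSE),
      zs$z, sim$ld)
    amats[[j]] <- annotation_matrix(A)
    configs[[j]] <- causal
    lambdas[[j]] <- zs$lambda
  }
  list(regions = regions, amats = amats,
       truth = structure(list(configs = configs, lambda = lambdas,
                              E = E, W = W, d = d, seed = seed),
                         class = "synthetic_truth"))
}

#' Write a simulated dataset as region bundles + BED tracks + manifest
#'
#' Emits exactly the on-disk formats the pipeline consumes: one region
#' bundle per region, one BED file per track (intervals of the covered
#' variants), a track manifest TSV, and the ground truth as JSON.
#'
#' @param dataset result of [simulate_annotated_dataset()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_simulated_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bdir <- file.path(dir, "bundles")
  for (j in seq_along(dataset$regions))
    write_region_bundle(dataset$regions[[j]], dataset$amats[[j]], bdir)
  tdir <- file.path(dir, "tracks")
  dir.create(tdir, showWarnings = FALSE)
  tracks <- colnames(dataset$amats[[1]])[-1L]
  manifest <- data.frame(track_id = tracks,
                         path = file.path("tracks", paste0(tracks, ".bed")),
                         label = tracks, stringsAsFactors = FALSE)
  for (k in seq_along(tracks)) {
    rows <- list()
    for (j in seq_along(dataset$regions)) {
      reg <- dataset$regions[[j]]
      hit <- which(dataset$amats[[j]][, k + 1L] > 0)
      if (length(hit))
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = reg$variants$chrom[hit],
          start = reg$variants$pos[hit] - 1L,   # 0-based half-open
          end = reg$variants$pos[hit],
          name = tracks[k], stringsAsFactors = FALSE)
    }
    bed <- if (length(rows)) do.call(rbind, rows)
           else data.frame(chrom = character(0), start = numeric(0),
                           end = numeric(0), name = character(0))
    utils::write.table(bed, file.path(dir, manifest$path[k]), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  utils::write.table(manifest, file.path(dir, "tracks.manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(E = dataset$truth$E, W = dataset$truth$W, d = dataset$truth$d,
         seed = dataset$truth$seed,
         configs = lapply(dataset$truth$configs, function(ix) ix - 1L)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Construct an LD-mismatch test region
#'
#' A small region (default 8 variants, weak AR(1) background LD) carrying
#' a perfectly correlated variant pair (positions 6 and 7) whose Z-scores
#' are set to `a` and `b`. With a correct LD matrix perfect correlation
#' would force equal Z-scores; setting `a != b` reproduces the
#' meta-analysis mismatch scenario in which one haplotype member's
#' evidence is missing from part of the cohorts. Background variants draw
#' null Z-scores from the region's LD.
#'
#' @param a,b Z-scores of the mismatched pair.
#' @param n_variants region size (default 8; must be >= 2).
#' @param rho background AR(1) correlation (default 0.2).
#' @param seed integer seed for the background draws.
#' @return a [region_data]; the perfectly correlated pair sits at indices
#'   `min(6, n_variants - 1)` and the next one (6 and 7 at the default
#'   size), recorded in attribute `"pair"`.
#' @export
make_mismatch_region <- function(a, b, n_variants = 8L, rho = 0.2,
                                 seed = 1L) {
  stopifnot(n_variants >= 2L)
  i <- min(6L, n_variants - 1L)      # the pair: variants i and i+1
  base_n <- n_variants - 1L
  base <- rho^abs(outer(seq_len(base_n), seq_len(base_n), `-`))
  # duplicate column i -> perfect proxy pair (i, i+1), PSD by construction
  dup <- c(seq_len(i), i, if (i < base_n) (i + 1L):base_n)
  ld <- base[dup, dup]
  diag(ld) <- 1
  zs <- simulate_zscores(ld, integer(0), seed = substream_seed(seed, 0L))
  z <- zs$z
  z[i] <- a
  z[i + 1L] <- b
  rid <- sprintf("mismatch_a%g_b%g", a, b)
  reg <- region_data(
    rid,
    data.frame(variant_id = paste0("m_v", seq_len(n_variants)),
               chrom = "1", pos = seq_len(n_variants) * 1000L,
               ref = "A", alt = "G", stringsAsFactors = FALSE),
    z, ld)
  attr(reg, "pair") <- c(i, i + 1L)
  reg
}
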