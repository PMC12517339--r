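#' Assemble a region data object
#'
#' A region is one analysis locus: an ordered variant table, the vector of
#' GWAS Z-scores (effect of the alternative allele), and the signed LD
#' correlation matrix between the variants. The three pieces must share one
#' variant order; that order is the coordinate system for every downstream
#' computation (configurations, posteriors, credible sets).
#'
#' @param region_id character scalar identifying the locus.
#' @param variants data.frame with columns `variant_id`, `chrom`, `pos`
#'   (1-based integer), `ref`, `alt`, one row per variant, in region order.
#' @param z numeric vector of Z-scores, length `nrow(variants)`.
#' @param ld square numeric matrix of signed Pearson correlations, same
#'   order as `variants`; must be symmetric with unit diagonal and entries
#'   in \[-1, 1\].
#' @return An object of class `region_data`.
#' @export
region_data <- function(region_id, variants, z, ld) {
  stopifnot(is.character(region_id), length(region_id) == 1L)
  req <- c("variant_id", "chrom", "pos", "ref", "alt")
  if (!is.data.frame(variants) || !all(req %in% names(variants)))
    stop("variants must be a data.frame with columns ",
         paste(req, collapse = ", "))
  n <- nrow(variants)
  if (n < 1L) stop("a region needs at least one variant")
  z <- as.numeric(z)
  if (length(z) != n) stop("length(z) != number of variants")
  if (!all(is.finite(z))) stop("non-finite Z-scores in region ", region_id)
  ld <- as.matrix(ld)
  if (!is.numeric(ld) || nrow(ld) != n || ncol(ld) != n)
    stop("ld must be an n x n numeric matrix (n = ", n, ")")
  if (max(abs(ld - t(ld))) > 1e-8) stop("ld matrix is not symmetric")
  if (max(abs(diag(ld) - 1)) > 1e-6) stop("ld diagonal must be 1")
  if (min(ld) < -1 - 1e-8 || max(ld) > 1 + 1e-8)
    stop("ld entries must lie in [-1, 1]")
  # snap tiny float excursions so |r| <= 1 exactly
  ld[ld > 1] <- 1
  ld[ld < -1] <- -1
  dimnames(ld) <- list(variants$variant_id, variants$variant_id)
  structure(
    list(region_id = region_id,
         variants = as.data.frame(variants)[, req],
         z = z, ld = ld, n = n),
    class = "region_data")
}

#' @export
print.region_data <- function(x, ...) {
  cat(sprintf("<region_data> %s: %d variants, chrom %s, pos %s-%s\n",
              x$region_id, x$n, x$variants$chrom[1],
              format(min(x$variants$pos), scientific = FALSE),
              format(max(x$variants$pos), scientific = FALSE)))
  invisible(x)
}

#' Model configuration
#'
#' Tunable parameters of the Bayesian model and its reporting thresholds.
#'
#' @param W nonnegative effect-size prior variance. `W = 1` balances
#'   sensitivity against LD-mismatch robustness and is the shipped default.
#' @param d maximum number of causal variants per configuration (default 2;
#'   supported up to 5, values above 5 are allowed with a warning but are
#'   combinatorially expensive).
#' @param t store-pruning threshold in orders of magnitude: configurations
#'   whose Bayes factor is more than `t` orders of magnitude below the
#'   largest are dropped from the store (default 12; `Inf` disables pruning).
#' @param credible_level cumulative normalized posterior mass a credible set
#'   must reach (default 0.9).
#' @param top_posterior_threshold region prioritization cut on the top
#'   variant posterior (default 0.5).
#' @param delta_flag_threshold posterior increase over the null model that
#'   flags a region/context (default 0.2).
#' @param config_cap refuse to enumerate more configurations than this
#'   (default 5e6).
#' @return An object of class `model_config`.
#' @export
model_config <- function(W = 1, d = 2L, t = 12, credible_level = 0.9,
                         top_posterior_threshold = 0.5,
                         delta_flag_threshold = 0.2,
                         config_cap = 5e6) {
  stopifnot(is.numeric(W), length(W) == 1L, W >= 0,
            is.numeric(d), length(d) == 1L, d >= 1,
            is.numeric(t), length(t) == 1L, t >= 0,
            credible_level > 0, credible_level <= 1)
  d <- as.integer(d)
  if (d > 5L)
    warning("d = ", d, " > 5: runtime and memory grow steeply; ",
            "values up to 5 are the supported range")
  structure(
    list(W = W, d = d, t = t, credible_level = credible_level,
         top_posterior_threshold = top_posterior_threshold,
         delta_flag_threshold = delta_flag_threshold,
         config_cap = config_cap),
    class = "model_config")
}

#' Annotation overlap matrix
#'
#' Binary variant-by-track matrix with a leading all-ones intercept column.
#' The intercept carries the baseline log-odds of causality so that a
#' variant outside every track still has a well-defined (small) prior; the
#' annotation-free null model is then simply the intercept-only model.
#'
#' @param overlaps n x N_A binary matrix (0/1) of variant-track overlaps;
#'   column names are track labels. May have zero columns.
#' @return n x (1 + N_A) matrix of class `annotation_matrix`; column 1 is
#'   named `"(intercept)"`.
#' @export
annotation_matrix <- function(overlaps) {
  overlaps <- as.matrix(overlaps)
  if (length(overlaps) && !all(overlaps %in% c(0, 1)))
    stop("annotation overlaps must be binary (0/1)")
  if (is.null(colnames(overlaps)) && ncol(overlaps) > 0)
    colnames(overlaps) <- paste0("track", seq_len(ncol(overlaps)))
  A <- cbind(`(intercept)` = 1, overlaps)
  storage.mode(A) <- "double"
  class(A) <- c("annotation_matrix", class(A))
  A
}

is_annotation_matrix <- function(x) inherits(x, "annotation_matrix")

logit <- function(p) log(p) - log1p(-p)

#' Stable log-sum-exp
#' @noRd
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
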