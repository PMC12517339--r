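#' Normalize GWAS summary statistics to alt-allele Z-scores
#'
#' Resolves reference/alternative alleles and orients every effect to the
#' alternative allele: `z = beta/se` (or the supplied `z`), with the sign
#' flipped when the stated effect allele is the reference allele. Rows
#' whose effect allele matches neither `ref` nor `alt`, or with `se <= 0`,
#' are dropped with a recorded reason; duplicated `(chrom, pos, ref, alt)`
#' keys are an error. Strand-ambiguous A/T and C/G variants are kept but
#' flagged (no allele-frequency information is available to resolve
#' strand).
#'
#' @param rows data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `effect_allele`, `pvalue`, and either `beta` + `se` or `z`.
#' @return data.frame with columns `variant_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `z`, `pvalue`, `ambiguous`; attribute `"dropped"` is a
#'   data.frame of removed rows with a `reason` column.
#' @export
normalize_sumstats <- function(rows) {
  req <- c("chrom", "pos", "ref", "alt", "effect_allele", "pvalue")
  if (!all(req %in% names(rows)))
    stop("sumstats must have columns ", paste(req, collapse = ", "),
         " and either beta+se or z")
  has_z <- "z" %in% names(rows)
  has_bse <- all(c("beta", "se") %in% names(rows))
  if (!has_z && !has_bse)
    stop("sumstats need either a z column or beta and se columns")
  rows <- as.data.frame(rows)
  n <- nrow(rows)
  reason <- character(n)
  ok <- rep(TRUE, n)

  mism <- rows$effect_allele != rows$ref & rows$effect_allele != rows$alt
  reason[mism] <- "allele mismatch"
  ok[mism] <- FALSE

  if (has_z) {
    z <- as.numeric(rows$z)
  } else {
    se <- as.numeric(rows$se)
    bad_se <- ok & (!is.finite(se) | se <= 0)
    reason[bad_se] <- "non-positive se"
    ok[bad_se] <- FALSE
    z <- as.numeric(rows$beta) / se
  }
  bad_z <- ok & !is.finite(z)
  reason[bad_z] <- "non-finite z"
  ok[bad_z] <- FALSE

  flip <- rows$effect_allele == rows$ref
  z <- ifelse(flip, -z, z)

  key <- paste(rows$chrom, rows$pos, rows$ref, rows$alt, sep = ":")
  if (anyDuplicated(key[ok]))
    stop("duplicate variant keys in sumstats: ",
         paste(utils::head(unique(key[ok][duplicated(key[ok])]), 3),
               collapse = ", "))
  pair <- paste0(toupper(rows$ref), "/", toupper(rows$alt))
  ambiguous <- pair %in% c("A/T", "T/A", "C/G", "G/C")

  out <- data.frame(
    variant_id = key, chrom = as.character(rows$chrom),
    pos = as.integer(rows$pos), ref = rows$ref, alt = rows$alt,
    z = z, pvalue = as.numeric(rows$pvalue), ambiguous = ambiguous,
    stringsAsFactors = FALSE)[ok, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  dropped <- cbind(rows[!ok, , drop = FALSE], reason = reason[!ok])
  attr(out, "dropped") <- dropped
  out
}

#' Signed LD correlation matrix from a genotype dosage panel
#'
#' Pearson correlation of alt-allele dosage columns; the signed matrix is
#' used directly as the model's LD matrix and its square provides every
#' r-squared threshold.
#'
#' @param panel samples x variants numeric matrix of dosages in \[0, 2\],
#'   with variant keys as column names.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
compute_ld <- function(panel) {
  panel <- as.matrix(panel)
  if (nrow(panel) < 2L) stop("LD computation needs at least 2 samples")
  v <- apply(panel, 2L, stats::var)
  if (any(v == 0))
    stop("zero-variance (monomorphic) variant(s) in panel: ",
         paste(utils::head(colnames(panel)[v == 0], 3), collapse = ", "))
  r <- stats::cor(panel)
  diag(r) <- 1
  r[r > 1] <- 1; r[r < -1] <- -1
  r
}

#' Greedy LD pruning of genome-wide significant variants
#'
#' Significant variants (`pvalue < p_threshold`) are visited in order of
#' ascending p-value (ties by position in the input); each visit takes the
#' best remaining variant as a tag and discards all remaining variants
#' with `r^2 > r2_threshold` to it. The returned tags are pairwise
#' independent at the threshold.
#'
#' @param variants data.frame with `variant_id` and `pvalue`, aligned with
#'   the rows of `ld`.
#' @param ld signed correlation matrix over `variants`.
#' @param p_threshold genome-wide significance cut (default 5e-8).
#' @param r2_threshold squared-correlation pruning cut (default 0.7).
#' @return integer vector of tag row indices into `variants` (ordered by
#'   selection, i.e. ascending p).
#' @export
ld_prune <- function(variants, ld, p_threshold = 5e-8, r2_threshold = 0.7) {
  stopifnot(nrow(variants) == nrow(ld))
  sig <- which(variants$pvalue < p_threshold)
  if (!length(sig)) return(integer(0))
  sig <- sig[order(variants$pvalue[sig], sig)]
  tags <- integer(0)
  remaining <- sig
  while (length(remaining)) {
    tag <- remaining[1L]
    tags <- c(tags, tag)
    r2 <- ld[tag, remaining]^2
    remaining <- remaining[r2 <= r2_threshold]
  }
  r2t <- ld[tags, tags, drop = FALSE]^2
  diag(r2t) <- 0
  stopifnot(all(r2t <= r2_threshold))   # pairwise independence, by construction
  tags
}

#' LD expansion of tag variants
#'
#' The candidate causal set: every variant with `r^2 > r2_threshold` to at
#' least one tag, plus the tags themselves.
#'
#' @param tags integer tag indices (rows of `ld`).
#' @param ld signed correlation matrix over all variants.
#' @param r2_threshold linkage cut (default 0.7, strict `>`).
#' @return sorted integer vector of candidate indices (a superset of
#'   `tags`).
#' @export
ld_expand <- function(tags, ld, r2_threshold = 0.7) {
  if (!length(tags)) return(integer(0))
  linked <- which(apply(ld[tags, , drop = FALSE]^2 > r2_threshold, 2L, any))
  sort(unique(c(tags, linked)))
}

#' Define the LD block of one tag variant
#'
#' Region bounds are the leftmost and rightmost candidate variants linked
#' to the tag (`r^2 > r2_threshold`), each restricted to lie within
#' `window` bp of the tag and to have at most `max_flank_variants`
#' variants between it and the tag. Every variant inside the final bounds
#' belongs to the region, linked or not.
#'
#' @param tag integer index of the tag variant (row of `variants`).
#' @param candidates integer indices of LD-expanded candidates.
#' @param variants data.frame with `chrom` and `pos`, sorted by position
#'   within chromosome, aligned with `ld`.
#' @param ld signed correlation matrix.
#' @param r2_threshold linkage cut (default 0.7).
#' @param window maximum bp distance from tag to a boundary (default 1e6).
#' @param max_flank_variants maximum variants between a boundary variant
#'   and the tag (default 1000).
#' @return list of class `region_interval`: `chrom`, `start`, `end`
#'   (1-based inclusive), `tag`, `merged = FALSE`.
#' @export
define_region <- function(tag, candidates, variants, ld,
                          r2_threshold = 0.7, window = 1e6,
                          max_flank_variants = 1000L) {
  stopifnot(tag %in% candidates)
  chrom <- variants$chrom[tag]
  tag_pos <- variants$pos[tag]
  same <- candidates[variants$chrom[candidates] == chrom]
  linked <- same[same == tag | ld[tag, same]^2 > r2_threshold]
  # clip: within window bp and with <= max_flank_variants variants between
  # the boundary and the tag (counted over ALL variants on the chromosome)
  chrom_idx <- which(variants$chrom == chrom)
  rank_in_chrom <- match(linked, chrom_idx)
  tag_rank <- match(tag, chrom_idx)
  keep <- abs(variants$pos[linked] - tag_pos) <= window &
    pmax(abs(rank_in_chrom - tag_rank) - 1L, 0L) <= max_flank_variants
  linked <- linked[keep]
  structure(list(chrom = chrom,
                 start = min(variants$pos[linked]),
                 end = max(variants$pos[linked]),
                 tag = tag, merged = FALSE),
            class = "region_interval")
}

#' Merge overlapping region intervals
#'
#' Standard interval merge per chromosome, 1-based inclusive coordinates;
#' touching-but-not-overlapping intervals (end + 1 == start) stay
#' separate. A merged output interval remembers that it came from more
#' than one LD block.
#'
#' @param intervals list of `region_interval` objects.
#' @return list of disjoint `region_interval` objects sorted by chromosome
#'   then start; `merged` is TRUE when at least two inputs were merged,
#'   and `tags` collects the member tag indices.
#' @export
merge_regions <- function(intervals) {
  if (!length(intervals)) return(list())
  chroms <- vapply(intervals, `[[`, character(1), "chrom")
  out <- list()
  for (ch in unique(chroms)) {
    ivs <- intervals[chroms == ch]
    ivs <- ivs[order(vapply(ivs, `[[`, numeric(1), "start"),
                     vapply(ivs, `[[`, numeric(1), "end"))]
    cur <- ivs[[1L]]
    cur$tags <- cur$tag
    n_in <- 1L
    for (iv in ivs[-1L]) {
      if (iv$start <= cur$end) {      # strict overlap in 1-based inclusive
        cur$end <- max(cur$end, iv$end)
        cur$tags <- c(cur$tags, iv$tag)
        n_in <- n_in + 1L
      } else {
        cur$merged <- n_in > 1L
        out <- c(out, list(cur))
        cur <- iv
        cur$tags <- cur$tag
        n_in <- 1L
      }
    }
    cur$merged <- n_in > 1L
    out <- c(out, list(cur))
  }
  out
}

#' Drop regions overlapping exclusion intervals
#'
#' @param intervals list of `region_interval` objects.
#' @param exclusions data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive). See [hla_exclusion()] for the conventional HLA default.
#' @return list of kept intervals; attribute `"excluded"` records dropped
#'   ones with the matching exclusion window.
#' @export
exclude_regions <- function(intervals, exclusions) {
  if (is.null(exclusions) || !nrow(exclusions))
    return(intervals)
  keep <- logical(length(intervals))
  why <- character(length(intervals))
  for (i in seq_along(intervals)) {
    iv <- intervals[[i]]
    hit <- exclusions$chrom == iv$chrom &
      exclusions$start <= iv$end & exclusions$end >= iv$start
    keep[i] <- !any(hit)
    if (any(hit))
      why[i] <- sprintf("overlaps exclusion %s:%d-%d", iv$chrom,
                        exclusions$start[which(hit)[1]],
                        exclusions$end[which(hit)[1]])
  }
  out <- intervals[keep]
  attr(out, "excluded") <- data.frame(
    chrom = vapply(intervals[!keep], `[[`, character(1), "chrom"),
    start = vapply(intervals[!keep], `[[`, numeric(1), "start"),
    end = vapply(intervals[!keep], `[[`, numeric(1), "end"),
    reason = why[!keep], stringsAsFactors = FALSE)
  out
}

#' Conventional HLA exclusion window
#'
#' The extended MHC region on chromosome 6, whose long-range LD makes
#' fine-mapping unreliable. Shipped as data, not hardcoded: callers pass
#' it (or their own table) to [exclude_regions()].
#'
#' @param chrom chromosome label used by the input data (default "6").
#' @return one-row data.frame (`chrom`, `start`, `end`).
#' @export
hla_exclusion <- function(chrom = "6") {
  data.frame(chrom = chrom, start = 25e6, end = 34e6,
             stringsAsFactors = FALSE)
}

#' Read a BED track
#'
#' BED3 or BED3+name, 0-based half-open as per the BED convention.
#' Malformed lines are an error naming the line number.
#'
#' @param path BED file path.
#' @return data.frame with `chrom`, `start` (0-based), `end` (exclusive),
#'   `name`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), name = character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    f <- parts[[i]]
    if (length(f) < 3L)
      stop("malformed BED line ", i, " in ", path, ": fewer than 3 fields")
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e) || s < 0 || e <= s)
      stop("malformed BED line ", i, " in ", path,
           ": start/end must be numeric with 0 <= start < end")
  }
  data.frame(
    chrom = vapply(parts, `[[`, character(1), 1L),
    start = vapply(parts, function(f) as.numeric(f[2]), numeric(1)),
    end = vapply(parts, function(f) as.numeric(f[3]), numeric(1)),
    name = vapply(parts, function(f) if (length(f) >= 4L) f[4] else ".",
                  character(1)),
    stringsAsFactors = FALSE)
}

#' Build the annotation overlap matrix for a set of variants
#'
#' A variant (1-based position) overlaps a BED interval (0-based
#' half-open) when `pos - 1` lies in `[start, end)`. Overlaps are computed
#' with GenomicRanges; an all-ones intercept column is prepended.
#'
#' @param variants data.frame with `chrom` and `pos` (1-based).
#' @param tracks named list of BED data.frames (as from [read_bed()]).
#' @return an [annotation_matrix] with one column per track.
#' @export
build_annotation_matrix <- function(variants, tracks) {
  n <- nrow(variants)
  vr <- GenomicRanges::GRanges(
    seqnames = as.character(variants$chrom),
    ranges = IRanges::IRanges(start = variants$pos, width = 1L))
  overlaps <- matrix(0, nrow = n, ncol = length(tracks),
                     dimnames = list(NULL, names(tracks)))
  for (k in seq_along(tracks)) {
    bed <- tracks[[k]]
    if (!nrow(bed)) next
    tr <- GenomicRanges::GRanges(
      seqnames = as.character(bed$chrom),
      # BED [start, end) in 0-based == [start+1, end] in 1-based inclusive
      ranges = IRanges::IRanges(start = bed$start + 1L, end = bed$end))
    # disjoint seqlevels (track absent from these chromosomes) is a valid
    # all-zero column, not a user error
    overlaps[, k] <- as.numeric(suppressWarnings(
      GenomicRanges::countOverlaps(vr, tr, ignore.strand = TRUE)) > 0L)
  }
  annotation_matrix(overlaps)
}
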