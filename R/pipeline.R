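#' Pipeline run configuration
#'
#' Paths, model parameters, and reporting thresholds for [run_pipeline()].
#' Defaults are the shipped analysis conventions: genome-wide significance
#' 5e-8, LD threshold r^2 = 0.7, 1 Mbp / 1000-variant block bounds,
#' annotation significance cut 0.01, region prioritization at top
#' posterior > 0.5, null-comparison flag at posterior increase >= 0.2.
#'
#' @param sumstats path to a GWAS summary-statistics TSV (header: chrom,
#'   pos, ref, alt, effect_allele, pvalue, and beta+se or z; gzip
#'   accepted), or an equivalent data.frame.
#' @param panel path to a genotype dosage TSV (rows samples, columns
#'   variant keys `chrom:pos:ref:alt`), or an equivalent matrix. Stands in
#'   for a reference genotype panel as the LD source.
#' @param tracks path to a track manifest TSV (`track_id`, `path`,
#'   `label`; BED paths relative to the manifest), or a named list of BED
#'   data.frames.
#' @param out_dir output directory.
#' @param params a [model_config].
#' @param p_gwas genome-wide significance threshold (default 5e-8).
#' @param r2 LD pruning/expansion threshold on r^2 (default 0.7).
#' @param window region half-width bound in bp (default 1e6).
#' @param max_flank maximum variants between a region boundary and its tag
#'   (default 1000).
#' @param ann_p annotation significance cut for context-specific reports
#'   (default 0.01).
#' @param exclusions data.frame of exclusion intervals (`chrom`, `start`,
#'   `end`), e.g. [hla_exclusion()]; NULL for none.
#' @param seed integer seed echoed into the run summary (the analysis
#'   itself is deterministic).
#' @return object of class `run_config`.
#' @export
run_config <- function(sumstats, panel, tracks, out_dir,
                       params = model_config(), p_gwas = 5e-8, r2 = 0.7,
                       window = 1e6, max_flank = 1000L, ann_p = 0.01,
                       exclusions = NULL, seed = 1L) {
  stopifnot(inherits(params, "model_config"),
            p_gwas > 0, p_gwas < 1, r2 > 0, r2 <= 1, window > 0)
  structure(list(sumstats = sumstats, panel = panel, tracks = tracks,
                 out_dir = out_dir, params = params, p_gwas = p_gwas,
                 r2 = r2, window = window,
                 max_flank = as.integer(max_flank), ann_p = ann_p,
                 exclusions = exclusions, seed = as.integer(seed)),
            class = "run_config")
}

read_track_manifest <- function(tracks) {
  if (is.list(tracks) && !is.data.frame(tracks) && !is.character(tracks))
    return(tracks)                           # already a named list of BEDs
  path <- tracks
  man <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  stopifnot(all(c("track_id", "path") %in% names(man)))
  out <- list()
  for (i in seq_len(nrow(man))) {
    bed_path <- man$path[i]
    if (!file.exists(bed_path))
      bed_path <- file.path(dirname(path), man$path[i])
    if (!file.exists(bed_path))
      stop("track '", man$track_id[i], "': BED file not found at ",
           man$path[i])
    out[[man$track_id[i]]] <- read_bed(bed_path)
  }
  out
}

#' Run the end-to-end analysis pipeline
#'
#' Normalize sumstats -> compute LD from the panel -> prune significant
#' variants to tags -> LD-expand -> define and merge LD blocks -> apply
#' exclusions -> assemble per-region bundles -> build Bayes factor stores
#' (once) -> fit the null model and scan every annotation -> compute
#' context-specific posteriors, credible sets and null-model deltas ->
#' write reports. Deterministic given fixed inputs and seed.
#'
#' @param config a [run_config].
#' @return run summary list (also written as `run_summary.json`), with
#'   stage counts and the paths of every report.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) message("[bts] ", sprintf(...))

  raw <- if (is.data.frame(config$sumstats)) config$sumstats
         else utils::read.table(config$sumstats, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
  ss <- normalize_sumstats(raw)
  log_msg("sumstats: %d rows in, %d variants kept, %d dropped",
          nrow(raw), nrow(ss), nrow(attr(ss, "dropped")))

  panel <- if (is.matrix(config$panel)) config$panel
           else as.matrix(utils::read.table(config$panel, sep = "\t",
                                            header = TRUE,
                                            check.names = FALSE))
  in_panel <- ss$variant_id %in% colnames(panel)
  if (any(!in_panel))
    log_msg("%d variants absent from the genotype panel were dropped",
            sum(!in_panel))
  ss <- ss[in_panel, , drop = FALSE]
  rownames(ss) <- NULL
  tracks <- read_track_manifest(config$tracks)

  regions_rows <- list()
  regions <- list()
  amats <- list()
  n_sig_total <- 0L
  n_tags_total <- 0L
  bdir <- file.path(out_dir, "bundles")

  for (ch in unique(ss$chrom)) {
    sub <- ss[ss$chrom == ch, , drop = FALSE]
    ld <- compute_ld(panel[, sub$variant_id, drop = FALSE])
    tags <- ld_prune(sub, ld, config$p_gwas, config$r2)
    n_sig_total <- n_sig_total + sum(sub$pvalue < config$p_gwas)
    n_tags_total <- n_tags_total + length(tags)
    if (!length(tags)) next
    candidates <- ld_expand(tags, ld, config$r2)
    blocks <- lapply(tags, define_region, candidates = candidates,
                     variants = sub, ld = ld, r2_threshold = config$r2,
                     window = config$window,
                     max_flank_variants = config$max_flank)
    merged <- merge_regions(blocks)
    kept <- exclude_regions(merged, config$exclusions)
    excl <- attr(kept, "excluded")
    if (!is.null(excl) && nrow(excl))
      for (i in seq_len(nrow(excl)))
        regions_rows[[length(regions_rows) + 1L]] <- data.frame(
          region_id = sprintf("region_%s_%d_%d", ch, excl$start[i],
                              excl$end[i]),
          chrom = ch, start = excl$start[i], end = excl$end[i],
          n_variants = NA_integer_, n_tags = NA_integer_, merged = NA,
          excluded_reason = excl$reason[i], stringsAsFactors = FALSE)
    for (iv in kept) {
      member <- which(sub$pos >= iv$start & sub$pos <= iv$end)
      rid <- sprintf("region_%s_%d_%d", ch, iv$start, iv$end)
      reg <- region_data(rid, sub[member, c("variant_id", "chrom", "pos",
                                            "ref", "alt")],
                         sub$z[member],
                         ld[member, member, drop = FALSE])
      am <- build_annotation_matrix(reg$variants, tracks)
      write_region_bundle(reg, am, bdir)
      regions[[length(regions) + 1L]] <- reg
      amats[[length(amats) + 1L]] <- am
      regions_rows[[length(regions_rows) + 1L]] <- data.frame(
        region_id = rid, chrom = ch, start = iv$start, end = iv$end,
        n_variants = reg$n, n_tags = length(iv$tags),
        merged = iv$merged, excluded_reason = "",
        stringsAsFactors = FALSE)
    }
  }
  regions_df <- if (length(regions_rows)) do.call(rbind, regions_rows)
                else data.frame(region_id = character(0), chrom = character(0),
                                start = numeric(0), end = numeric(0),
                                n_variants = integer(0), n_tags = integer(0),
                                merged = logical(0),
                                excluded_reason = character(0))
  utils::write.table(regions_df, file.path(out_dir, "regions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_msg("regions: %d significant variants, %d tags, %d regions kept",
          n_sig_total, n_tags_total, length(regions))

  summary <- list(
    seed = config$seed,
    n_sumstat_rows = nrow(raw), n_variants_normalized = nrow(ss),
    n_significant = n_sig_total, n_tags = n_tags_total,
    n_regions = length(regions),
    n_regions_excluded = sum(nzchar(regions_df$excluded_reason)),
    n_tracks = length(tracks),
    params = unclass(config$params))

  if (length(regions)) {
    res <- analyze_regions(regions, amats, config$params,
                           config$ann_p, out_dir,
                           regions_df = regions_df)
    summary <- c(summary, res[c("n_tracks_scanned", "n_tracks_skipped",
                                "n_tracks_significant", "contexts")])
  } else {
    log_msg("no genome-wide significant signals; nothing to analyze")
    summary$n_tracks_scanned <- 0L
    write_reports(scan = NULL, results = list(), params = config$params,
                  out_dir = out_dir, regions_df = regions_df)
  }
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Model estimation and reporting over prebuilt regions
#'
#' The analysis core shared by [run_pipeline()] and the `scan` CLI
#' subcommand: builds every Bayes factor store once, fits the null model,
#' scans all annotation tracks, and computes posteriors, credible sets and
#' null-model deltas for the null context plus each significant track.
#'
#' @param regions list of [region_data] objects.
#' @param amats aligned list of [annotation_matrix] objects.
#' @param params a [model_config].
#' @param ann_p annotation significance cut for context-specific posterior
#'   reports (default 0.01).
#' @param out_dir output directory for reports (NULL to skip writing).
#' @param regions_df optional regions table for referential checks.
#' @return list with `scan` (the [scan_annotations()] table), `results`
#'   (per region: posterior sets and credible sets per context), and
#'   reporting counts.
#' @export
analyze_regions <- function(regions, amats, params = model_config(),
                            ann_p = 0.01, out_dir = NULL,
                            regions_df = NULL) {
  stopifnot(length(regions) == length(amats))
  stores <- lapply(regions, build_bf_store, params = params)
  scan <- scan_annotations(stores, amats)
  null_fit <- attr(scan, "null_fit")
  ok <- scan$status == "ok" & !is.na(scan$pvalue)
  sig_tracks <- scan$track[ok & scan$pvalue < ann_p]
  contexts <- c("null", sig_tracks)

  results <- vector("list", length(regions))
  names(results) <- vapply(regions, `[[`, character(1), "region_id")
  for (j in seq_along(regions)) {
    A <- amats[[j]]
    per_context <- list()
    p_null <- region_priors(A[, 1L, drop = FALSE], null_fit$E)
    ps_null <- variant_posteriors(stores[[j]], p_null, context = "null")
    per_context[["null"]] <- list(
      posteriors = ps_null,
      credible = credible_set(ps_null, params$credible_level),
      delta = rep(0, stores[[j]]$n), flagged = FALSE)
    for (tr in sig_tracks) {
      row <- scan[scan$track == tr, ]
      col <- match(tr, colnames(A))
      p_tr <- region_priors(A[, c(1L, col), drop = FALSE],
                            c(row$E0, row$E1))
      ps <- variant_posteriors(stores[[j]], p_tr, context = tr)
      dl <- delta_vs_null(ps, ps_null, params$delta_flag_threshold)
      per_context[[tr]] <- list(
        posteriors = ps,
        credible = credible_set(ps, params$credible_level),
        delta = dl$delta, flagged = dl$flagged)
    }
    results[[j]] <- list(region = regions[[j]], amat = A,
                         contexts = per_context)
  }
  counts <- list(n_tracks_scanned = sum(scan$status != "no_overlap"),
                 n_tracks_skipped = sum(scan$status == "no_overlap"),
                 n_tracks_significant = length(sig_tracks),
                 contexts = contexts)
  if (!is.null(out_dir))
    write_reports(scan, results, params, out_dir, regions_df)
  c(list(scan = scan, results = results), counts)
}
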