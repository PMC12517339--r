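fmt6 <- function(x) {
  ifelse(is.na(x), "NA", formatC(signif(x, 6), format = "g", digits = 6))
}

#' Write the tabular analysis reports
#'
#' Four TSVs with stable row ordering and floats at 6 significant digits:
#'
#' * `annotations.tsv` — the enrichment scan, sorted by p-value.
#' * `region_by_context.tsv` — long-format (region, track, top_posterior,
#'   delta_flag, merged_flag), restricted to regions whose top posterior
#'   exceeds the prioritization threshold in that context; the
#'   annotation-free model appears as context `"null"`.
#' * `variants.tsv` — per variant per context: posterior, null posterior,
#'   delta, credible-set membership, annotation overlap.
#' * `credible_sets.tsv` — region, context, set size, members, achieved
#'   cumulative mass.
#'
#' @param scan an `annotation_scan` table (or NULL when nothing was
#'   scanned).
#' @param results per-region context results as produced by
#'   [analyze_regions()].
#' @param params a [model_config] (thresholds for prioritization and
#'   delta flags).
#' @param out_dir output directory.
#' @param regions_df optional regions table (used for the merged flag and
#'   referential checks).
#' @return named vector of report paths, invisibly.
#' @export
write_reports <- function(scan, results, params, out_dir,
                          regions_df = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(annotations = file.path(out_dir, "annotations.tsv"),
             region_by_context = file.path(out_dir, "region_by_context.tsv"),
             variants = file.path(out_dir, "variants.tsv"),
             credible_sets = file.path(out_dir, "credible_sets.tsv"))

  stab <- if (is.null(scan)) {
    data.frame(track = character(0), E0 = character(0), E1 = character(0),
               prior_odds = character(0), loglik_null = character(0),
               loglik_alt = character(0), lrt_stat = character(0),
               pvalue = character(0), n_regions_overlapped = integer(0),
               status = character(0))
  } else {
    data.frame(track = scan$track, E0 = fmt6(scan$E0), E1 = fmt6(scan$E1),
               prior_odds = fmt6(scan$prior_odds),
               loglik_null = fmt6(scan$loglik_null),
               loglik_alt = fmt6(scan$loglik_alt),
               lrt_stat = fmt6(scan$lrt_stat), pvalue = fmt6(scan$pvalue),
               n_regions_overlapped = scan$n_regions_overlapped,
               status = scan$status, stringsAsFactors = FALSE)
  }
  utils::write.table(stab, paths["annotations"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  merged_of <- function(rid) {
    if (is.null(regions_df)) return(NA)
    m <- regions_df$merged[match(rid, regions_df$region_id)]
    if (length(m)) m else NA
  }
  rbc <- list(); vtab <- list(); cstab <- list()
  for (rid in names(results)) {
    res <- results[[rid]]
    reg <- res$region
    if (!is.null(regions_df) && !rid %in% regions_df$region_id)
      stop("report integrity: region ", rid, " missing from regions table")
    for (ctx in names(res$contexts)) {
      rc <- res$contexts[[ctx]]
      ps <- rc$posteriors
      if (ps$top_posterior > params$top_posterior_threshold)
        rbc[[length(rbc) + 1L]] <- data.frame(
          region = rid, track = ctx,
          top_posterior = fmt6(ps$top_posterior),
          delta_flag = rc$flagged, merged_flag = merged_of(rid),
          stringsAsFactors = FALSE)
      in_cs <- seq_len(reg$n) %in% rc$credible$indices
      overlap <- if (ctx == "null") rep(0, reg$n)
                 else res$amat[, match(ctx, colnames(res$amat))]
      vtab[[length(vtab) + 1L]] <- data.frame(
        region = rid, context = ctx, variant_id = reg$variants$variant_id,
        chrom = reg$variants$chrom, pos = reg$variants$pos,
        z = fmt6(reg$z),
        posterior = fmt6(ps$marginal),
        null_posterior = fmt6(res$contexts[["null"]]$posteriors$marginal),
        delta = fmt6(rc$delta),
        in_credible_set = in_cs,
        annotation_overlap = as.integer(overlap),
        stringsAsFactors = FALSE)
      cstab[[length(cstab) + 1L]] <- data.frame(
        region = rid, context = ctx,
        size = length(rc$credible$indices),
        members = paste(reg$variants$variant_id[rc$credible$indices],
                        collapse = ","),
        mass = fmt6(rc$credible$mass), stringsAsFactors = FALSE)
    }
  }
  bind_or_empty <- function(rows, proto) {
    if (length(rows)) do.call(rbind, rows) else proto
  }
  rbc_df <- bind_or_empty(rbc, data.frame(
    region = character(0), track = character(0),
    top_posterior = character(0), delta_flag = logical(0),
    merged_flag = logical(0)))
  vdf <- bind_or_empty(vtab, data.frame(
    region = character(0), context = character(0),
    variant_id = character(0), chrom = character(0), pos = integer(0),
    z = character(0), posterior = character(0),
    null_posterior = character(0), delta = character(0),
    in_credible_set = logical(0), annotation_overlap = integer(0)))
  csdf <- bind_or_empty(cstab, data.frame(
    region = character(0), context = character(0), size = integer(0),
    members = character(0), mass = character(0)))

  # referential integrity: one row per (region, context, variant)
  if (nrow(vdf) &&
      anyDuplicated(vdf[, c("region", "context", "variant_id")]))
    stop("report integrity: duplicated variant rows")
  utils::write.table(rbc_df, paths["region_by_context"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(vdf, paths["variants"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(csdf, paths["credible_sets"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
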