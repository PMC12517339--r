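#' Write a region bundle to disk
#'
#' Three plain-text files per region under `dir`:
#' `<id>.z.tsv` (variant_id, chrom, pos, ref, alt, z),
#' `<id>.ld.tsv` (square tab-separated matrix, row order = z file), and
#' `<id>.annotations.tsv` (binary matrix, header = track names; the
#' intercept column is an internal construct and is never stored).
#'
#' @param region a [region_data] object.
#' @param amat an [annotation_matrix] for the region (or NULL to skip the
#'   annotations file).
#' @param dir output directory (created if missing).
#' @return the file prefix `file.path(dir, region$region_id)`, invisibly.
#' @export
write_region_bundle <- function(region, amat = NULL, dir) {
  stopifnot(inherits(region, "region_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prefix <- file.path(dir, region$region_id)
  ztab <- cbind(region$variants, z = sprintf("%.17g", region$z))
  utils::write.table(ztab, paste0(prefix, ".z.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(matrix(sprintf("%.17g", region$ld), region$n),
                     paste0(prefix, ".ld.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(amat) && ncol(amat) > 1L) {
    stopifnot(is_annotation_matrix(amat), nrow(amat) == region$n)
    utils::write.table(amat[, -1L, drop = FALSE],
                       paste0(prefix, ".annotations.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(prefix)
}

#' Read a region bundle
#'
#' @param prefix path prefix as produced by [write_region_bundle()] (i.e.
#'   `<dir>/<region_id>`).
#' @return list with `region` (a [region_data]) and `amat` (an
#'   [annotation_matrix], or NULL when no annotations file exists).
#' @export
read_region_bundle <- function(prefix) {
  ztab <- utils::read.table(paste0(prefix, ".z.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE,
                            colClasses = c("character", "character",
                                           "integer", "character",
                                           "character", "numeric"))
  ld <- as.matrix(utils::read.table(paste0(prefix, ".ld.tsv"),
                                    header = FALSE))
  region <- region_data(basename(prefix), ztab[, 1:5], ztab$z, ld)
  apath <- paste0(prefix, ".annotations.tsv")
  amat <- NULL
  if (file.exists(apath)) {
    atab <- utils::read.table(apath, sep = "\t", header = TRUE,
                              check.names = FALSE)
    amat <- annotation_matrix(as.matrix(atab))
  }
  list(region = region, amat = amat)
}
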