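#' Enumerate causal configurations
#'
#' All subsets of the region's variants of size at most `d`, the candidate
#' causal configurations. The null (empty) configuration comes first; the
#' rest are ordered by size, then lexicographically — a deterministic order
#' used for store serialization.
#'
#' @param n number of variants in the region.
#' @param d maximum configuration size.
#' @param cap refuse enumeration when the configuration count
#'   `sum(choose(n, 0:d))` exceeds this (default 5e6).
#' @return list of integer vectors (1-based variant indices, increasing);
#'   element 1 is `integer(0)`, the null configuration.
#' @export
enumerate_configurations <- function(n, d, cap = 5e6) {
  stopifnot(n >= 1, d >= 1)
  n <- as.integer(n); d <- as.integer(d)
  total <- configuration_count(n, d)
  if (total > cap)
    stop(sprintf(paste0(
      "enumerating %s configurations (n = %d, d = %d) exceeds the cap of %s; ",
      "lower d, split the region, or raise config_cap if you really mean it"),
      format(total, big.mark = ","), n, d, format(cap, big.mark = ",")))
  out <- vector("list", total)
  out[[1L]] <- integer(0)
  k <- 1L
  for (l in seq_len(min(d, n))) {
    cmb <- utils::combn(n, l)        # columns already in lexicographic order
    for (j in seq_len(ncol(cmb))) {
      k <- k + 1L
      out[[k]] <- cmb[, j]
    }
  }
  out
}

#' Total number of configurations of size <= d among n variants
#' @noRd
configuration_count <- function(n, d) {
  sum(choose(n, 0:min(d, n)))
}

#' Sparse configuration-by-variant incidence matrix
#'
#' Row c has ones at the variant indices of configuration c. Marginal
#' posteriors and incremental configuration priors are matrix products
#' against this incidence.
#' @noRd
config_incidence <- function(configs, n) {
  len <- lengths(configs)
  nc <- length(configs)
  if (as.numeric(nc) * n <= 2e5) {   # dense is faster for small regions
    M <- matrix(0, nc, n)
    M[cbind(rep.int(seq_len(nc), len), unlist(configs, use.names = FALSE))] <- 1
    return(M)
  }
  Matrix::sparseMatrix(
    i = rep.int(seq_len(nc), len),
    j = unlist(configs, use.names = FALSE),
    x = 1,
    dims = c(nc, n))
}

incidence_prod <- function(M, v) {       # M %*% v as a plain vector
  if (is.matrix(M)) drop(M %*% v) else as.vector(M %*% v)
}

incidence_crossprod <- function(M, v) {  # t(M) %*% v as a plain vector
  if (is.matrix(M)) drop(crossprod(M, v)) else as.vector(Matrix::crossprod(M, v))
}
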