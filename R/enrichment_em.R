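#' Total log relative likelihood across regions
#'
#' Sum over regions of `log sum_C BF_C P(C | E, A)`. This is the data
#' likelihood relative to the all-null configuration: the constant
#' `P(Z | C0)` factors are omitted because they cancel in every
#' likelihood-ratio test and every EM update.
#'
#' @param stores list of `bf_store` objects, one per region.
#' @param amats list of [annotation_matrix] objects aligned with `stores`.
#' @param E enrichment coefficient vector, length `ncol(amats[[j]])`.
#' @param columns optional integer subset of annotation columns (must
#'   include column 1, the intercept); `E` is then of that length.
#' @return numeric scalar.
#' @export
total_log_likelihood <- function(stores, amats, E, columns = NULL) {
  check_aligned(stores, amats)
  total <- 0
  for (j in seq_along(stores)) {
    A <- amats[[j]]
    if (!is.null(columns)) A <- A[, columns, drop = FALSE]
    p <- region_priors(A, E)
    w <- stores[[j]]$log_bf + store_config_log_priors(stores[[j]], p)
    total <- total + logsumexp(w)
  }
  total
}

check_aligned <- function(stores, amats) {
  if (length(stores) != length(amats))
    stop("stores and annotation matrices differ in length")
  for (j in seq_along(stores))
    if (stores[[j]]$n != nrow(amats[[j]]))
      stop("region ", stores[[j]]$region_id,
           ": store has ", stores[[j]]$n, " variants but annotation matrix has ",
           nrow(amats[[j]]), " rows")
  invisible(TRUE)
}

#' EM estimation of enrichment coefficients
#'
#' Alternates an E-step — per-variant marginal causal posteriors under the
#' current coefficients, reusing the cached Bayes factor stores — with an
#' M-step — a weighted Newton logistic regression of the expected causal
#' status (the marginal posterior) on the selected annotation columns.
#' Iterates until the total log likelihood changes by less than `tol` or
#' `max_iter` is reached. The M-step solves its logistic problem exactly,
#' so the total likelihood is non-decreasing across iterations; a decrease
#' beyond numerical tolerance aborts with a diagnostic. The one exception
#' is coefficient capping under separation: a capped M-step is no longer
#' the exact maximizer, so if it decreases the likelihood the fit stops
#' at the previous (saturated) coefficients instead of aborting.
#'
#' @param stores list of `bf_store` objects.
#' @param amats list of [annotation_matrix] objects aligned with `stores`.
#' @param columns integer columns of the annotation matrices to use; must
#'   include 1 (the intercept). Default: intercept only.
#' @param init_E starting coefficients (length `length(columns)`). Default:
#'   intercept at `logit(1/median region size)` (about one expected causal
#'   variant per region), zero elsewhere.
#' @param max_iter maximum EM iterations (default 100; 0 returns `init_E`
#'   unchanged).
#' @param tol absolute convergence tolerance on the total log likelihood
#'   (default 1e-6).
#' @param coef_cap coefficient magnitude cap against separation (default
#'   20); hitting it warns once.
#' @return list with `E` (named by column), `trace` (an `em_trace`:
#'   per-iteration log likelihood, `converged`, `iterations`), and
#'   `log_likelihood` (final value).
#' @export
em_fit <- function(stores, amats, columns = 1L, init_E = NULL,
                   max_iter = 100L, tol = 1e-6, coef_cap = 20) {
  check_aligned(stores, amats)
  if (length(stores) < 1L) stop("em_fit needs at least one region")
  columns <- as.integer(columns)
  if (!1L %in% columns)
    stop("`columns` must include column 1, the intercept")
  if (is.null(init_E)) {
    med_n <- stats::median(vapply(stores, function(s) s$n, numeric(1)))
    init_E <- c(logit(1 / max(med_n, 2)), rep(0, length(columns) - 1L))
  }
  if (length(init_E) != length(columns))
    stop("init_E has length ", length(init_E), " but ", length(columns),
         " columns were selected")
  Asub <- lapply(amats, function(A) {
    A <- A[, columns, drop = FALSE]
    attr(A, "class") <- NULL
    A
  })
  X <- do.call(rbind, Asub)
  E <- init_E
  est <- em_estep(stores, Asub, E)
  ll <- est$ll
  trace_ll <- numeric(0)
  converged <- FALSE
  iters <- 0L
  if (max_iter >= 1L) {
    for (it in seq_len(max_iter)) {
      iters <- it
      # M-step: weighted logistic of the expected causal status on X
      E_prev <- E
      E <- weighted_logistic(X, est$m, start = E, cap = coef_cap)
      capped <- isTRUE(attr(E, "capped"))
      attr(E, "capped") <- NULL
      # E-step under the new E doubles as the likelihood evaluation
      est <- em_estep(stores, Asub, E)
      ll_new <- est$ll
      trace_ll <- c(trace_ll, ll_new)
      if (ll_new < ll - 1e-7 * (1 + abs(ll))) {
        if (capped) {
          # the cap made the M-step inexact: saturate at the previous point
          E <- E_prev
          trace_ll <- trace_ll[-length(trace_ll)]
          converged <- TRUE
          break
        }
        stop(sprintf(paste0(
          "EM log likelihood decreased (%.10g -> %.10g) at iteration %d; ",
          "this indicates a numerical problem in the M-step"),
          ll, ll_new, it))
      }
      if (abs(ll_new - ll) < tol) {
        ll <- ll_new
        converged <- TRUE
        break
      }
      ll <- ll_new
    }
  }
  names(E) <- colnames(amats[[1]])[columns]
  list(E = E,
       trace = structure(list(log_likelihood = trace_ll,
                              converged = converged, iterations = iters),
                         class = "em_trace"),
       log_likelihood = ll)
}

#' Fused E-step: marginal posteriors and total log likelihood in one pass
#' @noRd
em_estep <- function(stores, Asub, E) {
  ll <- 0
  ms <- vector("list", length(stores))
  for (j in seq_along(stores)) {
    st <- stores[[j]]
    p <- region_priors(Asub[[j]], E)
    lodds <- log(p) - log1p(-p)
    w <- st$log_bf + sum(log1p(-p)) + incidence_prod(st$incidence, lodds)
    mx <- max(w)
    u <- exp(w - mx)
    su <- sum(u)
    ll <- ll + mx + log(su)
    ms[[j]] <- incidence_crossprod(st$incidence, u) / su
  }
  list(m = unlist(ms, use.names = FALSE), ll = ll)
}

#' Newton/IRLS logistic regression with fractional responses
#' @noRd
weighted_logistic <- function(X, y, start, cap = 20,
                              max_iter = 25L, grad_tol = 1e-8) {
  E <- start
  capped <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% E)
    p <- stats::plogis(eta)
    g <- drop(crossprod(X, y - p))
    if (max(abs(g)) < grad_tol) break
    wgt <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(X * wgt, X)
    step <- tryCatch(solve(H, g), error = function(e)
      solve(H + diag(1e-8, ncol(X)), g))
    # dampen runaway Newton steps (near-separation)
    smax <- max(abs(step))
    if (smax > 10) step <- step * (10 / smax)
    E <- E + step
    if (any(abs(E) > cap)) {
      E <- pmin(pmax(E, -cap), cap)
      capped <- TRUE
    }
  }
  if (capped)
    warning("logistic coefficient capped at |E| = ", cap,
            " (annotation nearly separates expected causal status)")
  attr(E, "capped") <- capped
  E
}

#' Likelihood-ratio test for an annotation
#'
#' Chi-square upper-tail p-value at `2 * (loglik_with - loglik_without)`
#' with `df` degrees of freedom (one per tested annotation coefficient).
#'
#' @param loglik_with,loglik_without total log likelihoods of the nested
#'   fits.
#' @param df degrees of freedom (default 1).
#' @return p-value in \[0, 1\].
#' @export
lrt_annotation <- function(loglik_with, loglik_without, df = 1L) {
  stopifnot(df >= 1)
  stat <- 2 * (loglik_with - loglik_without)
  if (stat < -1e-6)
    stop("negative LRT statistic (", format(stat),
         "): the annotated fit did not converge to at least the null fit")
  stats::pchisq(max(stat, 0), df = df, lower.tail = FALSE)
}

#' Per-annotation enrichment scan
#'
#' Fits the intercept-only (null) model once, then for each annotation
#' track an intercept + track model, and records coefficients, prior odds
#' `exp(E1)`, and the likelihood-ratio p-value. Tracks overlapping no
#' variant in any region are skipped with status `"no_overlap"`; a failing
#' fit marks its track `"failed"` rather than aborting the scan. Results
#' are sorted by p-value ascending.
#'
#' @param stores list of `bf_store` objects.
#' @param amats list of [annotation_matrix] objects aligned with `stores`,
#'   all sharing one column set.
#' @param max_iter,tol passed to [em_fit()].
#' @return data.frame of class `annotation_scan` with columns `track`,
#'   `E0`, `E1`, `prior_odds`, `loglik_null`, `loglik_alt`, `lrt_stat`,
#'   `pvalue`, `n_regions_overlapped`, `status`; attribute `null_fit`
#'   carries the intercept-only fit.
#' @export
scan_annotations <- function(stores, amats, max_iter = 100L, tol = 1e-6) {
  check_aligned(stores, amats)
  tracks <- colnames(amats[[1]])[-1L]
  null_fit <- em_fit(stores, amats, columns = 1L,
                     max_iter = max_iter, tol = tol)
  rows <- vector("list", length(tracks))
  for (k in seq_along(tracks)) {
    col <- k + 1L
    overlap_regions <- sum(vapply(
      amats, function(A) any(A[, col] > 0), logical(1)))
    row <- list(track = tracks[k], E0 = NA_real_, E1 = NA_real_,
                prior_odds = NA_real_, loglik_null = null_fit$log_likelihood,
                loglik_alt = NA_real_, lrt_stat = NA_real_,
                pvalue = NA_real_, n_regions_overlapped = overlap_regions,
                status = "ok")
    if (overlap_regions == 0L) {
      row$status <- "no_overlap"
    } else {
      fit <- tryCatch(
        em_fit(stores, amats, columns = c(1L, col),
               init_E = c(null_fit$E[[1]], 0),
               max_iter = max_iter, tol = tol),
        error = function(e) e)
      if (inherits(fit, "error")) {
        row$status <- paste0("failed: ", conditionMessage(fit))
      } else {
        row$E0 <- fit$E[[1]]; row$E1 <- fit$E[[2]]
        row$prior_odds <- exp(fit$E[[2]])
        row$loglik_alt <- fit$log_likelihood
        row$lrt_stat <- max(0, 2 * (fit$log_likelihood -
                                      null_fit$log_likelihood))
        row$pvalue <- lrt_annotation(fit$log_likelihood,
                                     null_fit$log_likelihood, df = 1L)
      }
    }
    rows[[k]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$pvalue, out$track, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "null_fit") <- null_fit
  class(out) <- c("annotation_scan", class(out))
  out
}
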