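#' Two-sided p-value for a Pearson correlation
#'
#' Standard t-test for a correlation coefficient:
#' \code{t = r sqrt((n - 2) / (1 - r^2))} on n - 2 degrees of freedom, where
#' n is the number of points the correlation was computed on. For delay-
#' realigned pairs n is the post-shift overlap length T - |delay|, not T:
#' the correlation is computed on the shifted segments, and using T would
#' anti-conservatively inflate the degrees of freedom. |r| = 1 gives p = 0.
#'
#' @param r correlation in [-1, 1] (\code{NA} allowed, returns \code{NA}).
#' @param n integer number of points used to compute r; n >= 3.
#' @return two-sided p-value in [0, 1].
#' @export
correlation_pvalue <- function(r, n) {
  if (is.na(r)) return(NA_real_)
  if (n < 3) stop("'n' must be at least 3")
  if (abs(r) > 1 + 1e-12) stop("'r' must lie in [-1, 1]")
  r <- max(min(r, 1), -1)
  if (abs(r) == 1) return(0)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment. \code{NA} entries (undefined
#' correlations from zero-variance segments) are preserved as \code{NA} and
#' excluded from the correction.
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @return vector of adjusted p-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Classify a delay as negative, none or positive
#'
#' Three-way partition of the signed integer delay: positive delays mean the
#' reference changes expression prior to the query, negative delays mean the
#' reference changes after the query, zero means simultaneous change.
#'
#' @param delay signed integer delay (vectorised; \code{NA} allowed).
#' @return character vector with levels "negative", "none", "positive".
#' @export
classify_delay <- function(delay) {
  out <- ifelse(is.na(delay), NA_character_,
                ifelse(delay > 0, "positive",
                       ifelse(delay < 0, "negative", "none")))
  as.character(out)
}

#' Screen all reference/query pairs for delayed co-expression
#'
#' Runs the delay-estimation pipeline (see [dynomics()]) over every
#' reference x query pair (or a restricted pair list, e.g. orthologous
#' pairs), computes a correlation p-value on each realigned overlap, applies
#' Benjamini-Hochberg FDR correction across the screened pairs, and flags
#' associations. A pair is associated when its realigned correlation passes
#' the threshold under the chosen sign filter and its FDR-adjusted p-value
#' is below \code{alpha}.
#'
#' Pairs are processed independently, and the output row order (reference
#' then query, in input order) does not depend on evaluation order.
#' Zero-variance trajectories yield a flagged record with
#' \code{associated = FALSE}; they are never dropped silently, so record
#' counts are reproducible.
#'
#' @param refs numeric matrix of reference trajectories (rows = molecules,
#'   columns = time points, rownames = ids), or a single numeric vector.
#' @param queries numeric matrix of query trajectories on the same time
#'   grid, or a single numeric vector.
#' @param pairs optional two-column data.frame (reference_id, query_id)
#'   restricting the screen to the listed pairs.
#' @param corr_threshold association requires |r| (or signed r, see
#'   \code{sign_filter}) strictly above this value; default 0.9, keeping
#'   only highly concordant trajectories.
#' @param alpha FDR level; default 0.05.
#' @param sign_filter "both" flags |r| > threshold; "positive" requires
#'   r > threshold; "negative" requires r < -threshold (e.g. to screen for
#'   direct miRNA-mRNA inhibition).
#' @param window stage-2 lag search half-width, see [refine_delay()].
#' @param fdr_scope "global" corrects once over the full screened pair list
#'   (default); "per_reference" corrects separately within each reference.
#' @return an object of class \code{"dynomics_screen"}: a data.frame with
#'   columns \code{reference_id}, \code{query_id}, \code{delay},
#'   \code{correlation}, \code{p_value}, \code{fdr}, \code{delay_class},
#'   \code{associated}, \code{status} ("ok" or "zero_variance").
#' @examples
#' t <- 1:14
#' refs <- rbind(a = cos(2 * pi * (t - 1) / 14))
#' queries <- rbind(b = cos(2 * pi * (t - 3) / 14),
#'                  c = rep(1, 14))
#' screen_associations(refs, queries, corr_threshold = 0.8)
#' @export
screen_associations <- function(refs, queries, pairs = NULL,
                                corr_threshold = 0.9, alpha = 0.05,
                                sign_filter = c("both", "positive",
                                                "negative"),
                                window = 1L,
                                fdr_scope = c("global", "per_reference")) {
  sign_filter <- match.arg(sign_filter)
  fdr_scope <- match.arg(fdr_scope)
  refs <- as_trajectory_matrix(refs, "ref")
  queries <- as_trajectory_matrix(queries, "query")
  if (ncol(refs) != ncol(queries))
    stop("reference and query matrices must share the same number of ",
         "time points (got ", ncol(refs), " and ", ncol(queries), ")")

  if (is.null(pairs)) {
    pairs <- expand.grid(query_id = rownames(queries),
                         reference_id = rownames(refs),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    pairs <- pairs[, c("reference_id", "query_id")]
    # reference-major order, input order within
    pairs <- pairs[order(match(pairs$reference_id, rownames(refs)),
                         match(pairs$query_id, rownames(queries))), ]
  } else {
    pairs <- as.data.frame(pairs)[, 1:2]
    names(pairs) <- c("reference_id", "query_id")
    missing_r <- setdiff(pairs$reference_id, rownames(refs))
    missing_q <- setdiff(pairs$query_id, rownames(queries))
    if (length(missing_r) || length(missing_q))
      stop("pair list names ids absent from the matrices: ",
           paste(c(missing_r, missing_q), collapse = ", "))
  }
  rownames(pairs) <- NULL
  n_pairs <- nrow(pairs)

  delay <- integer(n_pairs); corr <- numeric(n_pairs)
  pval <- numeric(n_pairs); status <- character(n_pairs)
  for (i in seq_len(n_pairs)) {
    fit <- dynomics(refs[pairs$reference_id[i], ],
                    queries[pairs$query_id[i], ], window = window)
    if (isTRUE(fit$degenerate)) {
      delay[i] <- NA_integer_; corr[i] <- NA_real_; pval[i] <- NA_real_
      status[i] <- "zero_variance"
    } else {
      delay[i] <- fit$delta_star; corr[i] <- fit$r_star
      pval[i] <- fit$p_value
      status[i] <- "ok"
    }
  }

  fdr <- if (fdr_scope == "global") bh_fdr(pval) else
    stats::ave(pval, pairs$reference_id, FUN = bh_fdr)

  pass_r <- switch(sign_filter,
                   both = abs(corr) > corr_threshold,
                   positive = corr > corr_threshold,
                   negative = corr < -corr_threshold)
  associated <- !is.na(corr) & pass_r & !is.na(fdr) & fdr < alpha

  out <- data.frame(reference_id = pairs$reference_id,
                    query_id = pairs$query_id,
                    delay = delay, correlation = corr, p_value = pval,
                    fdr = fdr, delay_class = classify_delay(delay),
                    associated = associated, status = status,
                    stringsAsFactors = FALSE)
  class(out) <- c("dynomics_screen", "data.frame")
  attr(out, "parameters") <- list(corr_threshold = corr_threshold,
                                  alpha = alpha, sign_filter = sign_filter,
                                  window = window, fdr_scope = fdr_scope)
  out
}

as_trajectory_matrix <- function(m, prefix) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (is.null(rownames(m)))
    rownames(m) <- paste0(prefix, seq_len(nrow(m)))
  if (anyDuplicated(rownames(m)))
    stop("duplicate ids: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  if (ncol(m) < 4) stop("trajectories need at least 4 time points")
  if (any(!is.finite(m))) stop("matrix contains non-finite values")
  m
}

#' @export
print.dynomics_screen <- function(x, ...) {
  p <- attr(x, "parameters")
  cat(sprintf(
    "Delayed co-expression screen: %d pairs, %d associated (|r| > %g, FDR < %g, sign = %s)\n",
    nrow(x), sum(x$associated), p$corr_threshold, p$alpha, p$sign_filter))
  if (any(x$status != "ok"))
    cat(sprintf("  %d pairs flagged (zero variance)\n",
                sum(x$status != "ok")))
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("  ... ", nrow(x) - 10, " more rows\n")
  invisible(x)
}

#' @export
summary.dynomics_screen <- function(object, ...) {
  assoc <- object[object$associated, , drop = FALSE]
  cat(sprintf("%d of %d pairs associated (%.1f%%)\n", nrow(assoc),
              nrow(object), 100 * nrow(assoc) / max(nrow(object), 1)))
  if (nrow(assoc)) {
    tab <- table(factor(assoc$delay_class,
                        levels = c("negative", "none", "positive")))
    cat("delay classes among associated pairs",
        "(positive = reference prior to query):\n")
    print(tab)
  }
  invisible(object)
}

#' Plot the delay/correlation landscape of a screen
#'
#' @param x a \code{"dynomics_screen"} object.
#' @param ... passed to \code{plot}.
#' @export
plot.dynomics_screen <- function(x, ...) {
  ok <- x$status == "ok"
  plot(jitter(x$delay[ok]), x$correlation[ok],
       col = ifelse(x$associated[ok], "red", "grey40"),
       pch = 16, cex = 0.6, xlab = "estimated delay (time units)",
       ylab = "realigned correlation", ...)
  graphics::abline(h = c(-1, 1) * attr(x, "parameters")$corr_threshold,
                   lty = 2)
  invisible(x)
}
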