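#' Symmetric percent difference
#'
#' `100 * (a - b) / ((a + b) / 2)`.
#'
#' @param a,b numeric vectors.
#' @return Percent difference(s).
#' @export
percent_difference <- function(a, b) 100 * (a - b) / ((a + b) / 2)

#' Compare tract-specific and tractometry bundle MTR across realizations
#'
#' Takes one matrix of bundle MTR values per method (bundles in rows,
#' realizations -- subjects or scan repetitions -- in columns) and reports:
#' per-bundle realization means and the symmetric percent difference between
#' methods; scan-rescan repeatability per method
#' (`100 * |m1 - m2| / mean(m1, m2)` between the first two realizations);
#' and two-tailed paired t-tests between every pair of bundles within each
#' method (pairing across realizations). Zero-variance differences are
#' flagged as degenerate rather than reported as infinite t statistics.
#'
#' @param tract_specific,tractometry numeric matrices (bundles x
#'   realizations) with matching dimnames.
#' @return Object of class `mt_method_comparison`: `bundles` data frame
#'   (means, percent difference, scan-rescan percent difference per method),
#'   `bundle_tests` data frame of paired t-tests, and `n_realizations`.
#' @export
compare_methods <- function(tract_specific, tractometry) {
  ts <- as.matrix(tract_specific); tm <- as.matrix(tractometry)
  stopifnot(all(dim(ts) == dim(tm)))
  if (is.null(rownames(ts))) rownames(ts) <- paste0("bundle", seq_len(nrow(ts)))
  n_real <- ncol(ts)
  m_ts <- rowMeans(ts); m_tm <- rowMeans(tm)
  rescan <- function(m) {
    if (ncol(m) < 2) return(rep(NA_real_, nrow(m)))
    100 * abs(m[, 1] - m[, 2]) / ((m[, 1] + m[, 2]) / 2)
  }
  bundles <- data.frame(bundle = rownames(ts),
                        tract_specific = m_ts, tractometry = m_tm,
                        pct_difference = percent_difference(m_ts, m_tm),
                        rescan_pct_tract_specific = rescan(ts),
                        rescan_pct_tractometry = rescan(tm),
                        row.names = NULL)
  tests <- NULL
  if (n_real >= 2 && nrow(ts) >= 2) {
    pairs <- utils::combn(nrow(ts), 2)
    tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      i <- pairs[1, k]; j <- pairs[2, k]
      one <- function(m, method) {
        d <- m[i, ] - m[j, ]
        degenerate_row <- data.frame(bundle_a = rownames(ts)[i],
                                     bundle_b = rownames(ts)[j],
                                     method = method, t = NA_real_,
                                     df = n_real - 1, p = NA_real_,
                                     degenerate = TRUE)
        if (stats::sd(d) <= 1e-10 * max(abs(d), 1))
          return(degenerate_row)
        tt <- tryCatch(stats::t.test(m[i, ], m[j, ], paired = TRUE),
                       error = function(e) NULL)
        if (is.null(tt)) return(degenerate_row)
        data.frame(bundle_a = rownames(ts)[i], bundle_b = rownames(ts)[j],
                   method = method, t = unname(tt$statistic),
                   df = unname(tt$parameter), p = tt$p.value,
                   degenerate = FALSE)
      }
      rbind(one(ts, "tract_specific"), one(tm, "tractometry"))
    }))
  }
  structure(list(bundles = bundles, bundle_tests = tests,
                 n_realizations = n_real),
            class = "mt_method_comparison")
}

#' @export
print.mt_method_comparison <- function(x, ...) {
  cat("Method comparison over", x$n_realizations, "realization(s)\n")
  print(x$bundles, row.names = FALSE, digits = 4)
  if (!is.null(x$bundle_tests)) {
    cat("Paired t-tests between bundles:\n")
    print(x$bundle_tests, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
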