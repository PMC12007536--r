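#' Macromolecular MTR of a protocol
#'
#' Simulated magnetization transfer ratio attributable to the macromolecular
#' pool: the MTR `1 - S_on/S_off` of the full two-pool tissue minus the MTR of
#' the same tissue with the bound-pool fraction set to zero (free pool only).
#' The subtraction removes the direct-saturation contribution of the water
#' pool, which is present in both acquisitions and carries no macromolecular
#' information.
#'
#' @param protocol an [sequence_protocol()].
#' @param tissue a [two_pool_tissue()].
#' @param ... passed to [steady_state_signal()].
#' @return Macromolecular MTR (dimensionless).
#' @export
simulated_mtr <- function(protocol, tissue, ...) {
  mtr_one <- function(tis) {
    s_off <- as.numeric(steady_state_signal(protocol, tis, with_prep = FALSE, ...))
    if (s_off <= 0) stop("simulated_mtr: non-positive MT-off signal")
    s_on <- as.numeric(steady_state_signal(protocol, tis, with_prep = TRUE, ...))
    1 - s_on / s_off
  }
  if (tissue$M0b == 0) return(0)
  free <- tissue
  free$M0b <- 0
  mtr_one(tissue) - mtr_one(free)
}

#' MTR efficiency of a protocol
#'
#' Macromolecular MTR per unit total (dual) acquisition time, evaluated with
#' FA_MT set to the maximum allowed by the SAR model. Protocols whose dual
#' scan time exceeds `max_scan_time` are flagged infeasible.
#'
#' @inheritParams simulated_mtr
#' @param sar a [sar_model()].
#' @return List with `efficiency` (1/s; `NA` if infeasible), `mtr`, `fa_mt`
#'   (degrees), `scan_time_s` and `feasible`.
#' @export
mtr_efficiency <- function(protocol, tissue, sar = default_sar_model(), ...) {
  fa <- sar_constrained_fa(protocol, sar)
  protocol$prep$fa_mt <- fa
  t_scan <- scan_time(protocol)
  feasible <- t_scan <= protocol$max_scan_time
  if (!feasible)
    return(list(efficiency = NA_real_, mtr = NA_real_, fa_mt = fa,
                scan_time_s = t_scan, feasible = FALSE))
  mtr <- simulated_mtr(protocol, tissue, ...)
  list(efficiency = mtr / t_scan, mtr = mtr, fa_mt = fa,
       scan_time_s = t_scan, feasible = TRUE)
}

#' Exhaustive protocol search for MTR efficiency
#'
#' Evaluates [mtr_efficiency()] over the Cartesian grid of the supplied
#' parameter vectors, holding everything else at `base_protocol`. Ties at the
#' maximum are broken toward smaller FA_MT, then smaller offset.
#'
#' @param space named list of parameter vectors; any of `offset_hz`, `tr_mt`,
#'   `n_pulses`, `tau`, `polarity`.
#' @param tissue a [two_pool_tissue()].
#' @param sar a [sar_model()].
#' @param base_protocol template [sequence_protocol()] supplying the fixed
#'   parameters.
#' @param ... passed to [steady_state_signal()].
#' @return Object of class `mt_efficiency_grid`: a data frame of grid points
#'   (parameters, `fa_mt`, `mtr`, `scan_time_s`, `efficiency`, `feasible`)
#'   with the argmax row in attribute `optimum`.
#' @export
optimize_protocol <- function(space, tissue, sar = default_sar_model(),
                              base_protocol = sequence_protocol(), ...) {
  stopifnot(is.list(space), length(space) > 0,
            all(names(space) %in% c("offset_hz", "tr_mt", "n_pulses", "tau",
                                    "polarity")))
  grid <- expand.grid(space, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    proto <- base_protocol
    for (nm in names(grid)) {
      if (nm == "tr_mt") proto$tr_mt <- grid[i, nm]
      else proto$prep[[nm]] <- grid[i, nm]
    }
    res[[i]] <- mtr_efficiency(proto, tissue, sar, ...)
  }
  out <- cbind(grid, do.call(rbind, lapply(res, function(r)
    data.frame(fa_mt = r$fa_mt, mtr = r$mtr, scan_time_s = r$scan_time_s,
               efficiency = r$efficiency, feasible = r$feasible))))
  feas <- which(out$feasible)
  if (length(feas) == 0) stop("optimize_protocol: no feasible grid point")
  off_key <- if (is.null(out$offset_hz)) rep(0, length(feas)) else
    out$offset_hz[feas]
  best <- feas[order(-out$efficiency[feas], out$fa_mt[feas], off_key)][1]
  structure(out, optimum = out[best, , drop = FALSE],
            class = c("mt_efficiency_grid", "data.frame"))
}

#' @export
print.mt_efficiency_grid <- function(x, ...) {
  cat("MTR-efficiency grid:", nrow(x), "protocols,",
      sum(x$feasible), "feasible\n")
  opt <- attr(x, "optimum")
  cat("Optimum:\n")
  print.data.frame(opt, row.names = FALSE)
  invisible(x)
}
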