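#' Group streamlines into node-pair bundles
#'
#' A streamline enters the bundle of the (unordered) pair of nodes it
#' connects. Streamlines with zero weight in either the MT-on or the MT-off
#' fit are excluded (weights below `zero_tol` times the maximum weight of
#' that fit count as zero), as are streamlines that do not connect two
#' distinct nodes.
#'
#' @param x_on,x_off per-streamline weights from the two fits.
#' @param node_pairs integer matrix (n x 2) of node ids per streamline
#'   (0 or `NA` = unassigned endpoint).
#' @param zero_tol relative zero-weight threshold.
#' @return Named list mapping `"a-b"` (a < b) to integer streamline ids.
#' @export
group_streamlines <- function(x_on, x_off, node_pairs, zero_tol = 1e-12) {
  node_pairs <- as.matrix(node_pairs)
  stopifnot(length(x_on) == length(x_off), nrow(node_pairs) == length(x_on))
  thr_on <- zero_tol * max(x_on, 0)
  thr_off <- zero_tol * max(x_off, 0)
  a <- node_pairs[, 1]; b <- node_pairs[, 2]
  connected <- !is.na(a) & !is.na(b) & a > 0 & b > 0 & a != b
  keep <- connected & x_on > thr_on & x_off > thr_off
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste0(lo, "-", hi)
  split(which(keep), key[keep])
}

#' Tract-specific MTR of one bundle
#'
#' The bundle MT-on and MT-off "volumes" are the sums over member
#' streamlines of weight times arc length, and
#' `MTR = 1 - vol_on / vol_off`.
#'
#' @param ids streamline ids of the bundle.
#' @param lengths per-streamline arc lengths (mm).
#' @param x_on,x_off per-streamline weights.
#' @return List with `vol_on`, `vol_off`, `mtr`, `n`.
#' @export
bundle_mtr <- function(ids, lengths, x_on, x_off) {
  vol_on <- sum(lengths[ids] * x_on[ids])
  vol_off <- sum(lengths[ids] * x_off[ids])
  if (vol_off <= 0)
    return(list(vol_on = vol_on, vol_off = vol_off, mtr = NA_real_,
                n = length(ids), valid = FALSE))
  list(vol_on = vol_on, vol_off = vol_off, mtr = 1 - vol_on / vol_off,
       n = length(ids), valid = TRUE)
}

#' Per-bundle tract-specific MTR table
#'
#' Applies the grouping rule and the bundle MTR formula to a dual fit.
#'
#' @param fit an [dual_fit()] result.
#' @param node_pairs integer matrix (n x 2) of node ids per streamline.
#' @param zero_tol relative zero-weight threshold for the grouping rule.
#' @return data.frame with `node_a`, `node_b`, `n_streamlines`, `vol_on`,
#'   `vol_off`, `mtr`; bundles with `vol_off = 0` are excluded.
#' @export
bundle_table <- function(fit, node_pairs, zero_tol = 1e-12) {
  stopifnot(inherits(fit, "mt_dual_fit"))
  w <- coef(fit)
  groups <- group_streamlines(w[, "x_on"], w[, "x_off"], node_pairs, zero_tol)
  if (length(groups) == 0)
    return(data.frame(node_a = integer(), node_b = integer(),
                      n_streamlines = integer(), vol_on = numeric(),
                      vol_off = numeric(), mtr = numeric()))
  rows <- lapply(names(groups), function(key) {
    nodes <- as.integer(strsplit(key, "-", fixed = TRUE)[[1]])
    r <- bundle_mtr(groups[[key]], fit$lengths, w[, "x_on"], w[, "x_off"])
    if (!r$valid) return(NULL)
    data.frame(node_a = nodes[1], node_b = nodes[2], n_streamlines = r$n,
               vol_on = r$vol_on, vol_off = r$vol_off, mtr = r$mtr)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  out[order(out$node_a, out$node_b), , drop = FALSE]
}

#' Connectome matrices from a bundle table
#'
#' @param bundles a [bundle_table()] data frame.
#' @param n_nodes total node count.
#' @param node_labels optional character vector of node names.
#' @return Object of class `mt_connectome`: symmetric `vol_on`, `vol_off`
#'   and `mtr` matrices (absent edges: 0 volume, `NaN` MTR).
#' @export
build_connectome <- function(bundles, n_nodes, node_labels = NULL) {
  stopifnot(all(bundles$node_a <= n_nodes), all(bundles$node_b <= n_nodes))
  if (anyDuplicated(bundles[, c("node_a", "node_b")]))
    stop("duplicate node pair in bundle table")
  if (is.null(node_labels)) node_labels <- paste0("node", seq_len(n_nodes))
  von <- matrix(0, n_nodes, n_nodes, dimnames = list(node_labels, node_labels))
  voff <- von
  mtr <- matrix(NaN, n_nodes, n_nodes,
                dimnames = list(node_labels, node_labels))
  for (r in seq_len(nrow(bundles))) {
    a <- bundles$node_a[r]; b <- bundles$node_b[r]
    von[a, b] <- von[b, a] <- bundles$vol_on[r]
    voff[a, b] <- voff[b, a] <- bundles$vol_off[r]
    mtr[a, b] <- mtr[b, a] <- bundles$mtr[r]
  }
  structure(list(n_nodes = n_nodes, node_labels = node_labels,
                 vol_on = von, vol_off = voff, mtr = mtr),
            class = "mt_connectome")
}

#' @export
print.mt_connectome <- function(x, ...) {
  n_edges <- sum(is.finite(x$mtr[upper.tri(x$mtr)]))
  cat("Connectome:", x$n_nodes, "nodes,", n_edges, "edges with defined MTR\n")
  invisible(x)
}

#' Write / read a connectome matrix as CSV
#'
#' Values are written as decimal text with 17 significant digits, so a
#' write/read round trip is bit-exact for doubles. The header row carries the
#' node labels.
#'
#' @param mat numeric matrix with dimnames.
#' @param path CSV file path.
#' @export
write_connectome_csv <- function(mat, path) {
  txt <- apply(mat, 1, function(r)
    paste(formatC(r, digits = 17, format = "g"), collapse = ","))
  writeLines(c(paste(colnames(mat), collapse = ","), txt), path)
}

#' @rdname write_connectome_csv
#' @return `read_connectome_csv`: the matrix.
#' @export
read_connectome_csv <- function(path) {
  lines <- readLines(path)
  labels <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  vals <- do.call(rbind, lapply(lines[-1], function(l)
    as.numeric(strsplit(l, ",", fixed = TRUE)[[1]])))
  dimnames(vals) <- list(labels, labels)
  vals
}
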