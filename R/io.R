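#' Write streamlines to an MRtrix TCK file
#'
#' Text header, little-endian float32 triplet stream, one NaN triplet
#' between streamlines, one Inf triplet terminator. Coordinates are written
#' as given (mm).
#'
#' @param tractogram list of vertex matrices (n x 3).
#' @param path output file.
#' @export
write_tck <- function(tractogram, path) {
  stopifnot(all(vapply(tractogram, function(p) ncol(as.matrix(p)) == 3,
                       logical(1))))
  header <- function(offset)
    paste0("mrtrix tracks\ndatatype: Float32LE\ncount: ",
           length(tractogram), "\nfile: . ", offset, "\nEND\n")
  # fixed-point iteration on the header length (the offset appears in it)
  off <- nchar(header(0))
  repeat {
    new_off <- nchar(header(off))
    if (new_off == off) break
    off <- new_off
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header(off), con, eos = NULL)
  for (pts in tractogram) {
    writeBin(as.numeric(t(as.matrix(pts))), con, size = 4, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an MRtrix TCK file
#'
#' @param path TCK file.
#' @return List of float32-precision vertex matrices (mm).
#' @export
read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!identical(magic, "mrtrix tracks"))
    stop("not a TCK file (magic line is ", deparse(magic), ")")
  offset <- NA; count <- NA
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("TCK header has no END line")
    if (line == "END") break
    kv <- strsplit(line, ":", fixed = TRUE)[[1]]
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = ":"))
    if (key == "file") offset <- as.integer(rev(strsplit(val, " ")[[1]])[1])
    if (key == "count") count <- as.integer(val)
    if (key == "datatype" && val != "Float32LE")
      stop("unsupported TCK datatype: ", val)
  }
  if (is.na(offset)) stop("TCK header lacks a 'file' offset")
  sz <- file.info(path)$size
  seek(con, offset)
  n_float <- (sz - offset) / 4
  if (n_float != floor(n_float) || n_float < 3)
    stop("truncated TCK float stream at byte offset ", offset,
         " (", sz - offset, " data bytes)")
  raw <- readBin(con, "numeric", n = n_float, size = 4, endian = "little")
  m <- matrix(raw, ncol = 3, byrow = TRUE)
  is_sep <- is.nan(m[, 1])
  is_end <- is.infinite(m[, 1])
  endi <- which(is_end)
  if (length(endi) == 0)
    stop("TCK stream lacks the Inf terminator (truncated after byte ",
         sz, ")")
  m <- m[seq_len(endi[1] - 1), , drop = FALSE]
  is_sep <- is_sep[seq_len(endi[1] - 1)]
  grp <- cumsum(c(0, utils::head(is_sep, -1))) + 1
  keep <- !is_sep
  out <- if (any(keep)) {
    unname(lapply(split(seq_len(nrow(m))[keep], grp[keep]), function(i)
      m[i, , drop = FALSE]))
  } else list()
  if (!is.na(count) && length(out) != count)
    warning("TCK count field (", count, ") disagrees with parsed streamlines (",
            length(out), ")")
  out
}

#' Write a 4D volume plus gradient scheme
#'
#' NIfTI-1 volume with isotropic pixdim, FSL-style `bval` (one row) and
#' `bvec` (three rows) text files.
#'
#' @param volume 4D array.
#' @param voxel_size voxel size (mm).
#' @param path_nii output NIfTI path (`.nii` or `.nii.gz`).
#' @param scheme an [acquisition_scheme()]; omit to write the volume only.
#' @export
write_dwi <- function(volume, voxel_size, path_nii, scheme = NULL) {
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- c(rep(voxel_size, 3), 1)
  RNifti::writeNifti(img, path_nii)
  if (!is.null(scheme)) {
    base <- sub("\\.nii(\\.gz)?$", "", path_nii)
    writeLines(paste(scheme$bvals, collapse = " "), paste0(base, ".bval"))
    writeLines(apply(t(scheme$bvecs), 1, paste, collapse = " "),
               paste0(base, ".bvec"))
  }
  invisible(path_nii)
}

#' Read a 4D DWI volume with its gradient scheme
#'
#' @param path_nii NIfTI file.
#' @param path_bval,path_bvec FSL bval/bvec text files (bvec: 3 rows of N).
#' @return List with `volume` (4D array), `scheme`
#'   ([acquisition_scheme()]), `voxel_size` and the RNifti `image`.
#' @export
read_dwi <- function(path_nii, path_bval, path_bvec) {
  img <- RNifti::readNifti(path_nii)
  vol <- array(as.numeric(img), dim(img))
  bvals <- scan(path_bval, quiet = TRUE)
  bvec_rows <- lapply(readLines(path_bvec), function(l)
    as.numeric(strsplit(trimws(l), "[ \t]+")[[1]]))
  bvec_rows <- bvec_rows[vapply(bvec_rows, length, integer(1)) > 0]
  if (length(bvec_rows) != 3) stop("bvec file must have 3 rows")
  bvecs <- t(do.call(rbind, bvec_rows))
  if (length(bvals) != dim(vol)[4] || nrow(bvecs) != dim(vol)[4])
    stop("volume count (", dim(vol)[4], ") does not match bval/bvec length (",
         length(bvals), "/", nrow(bvecs), ")")
  list(volume = vol, scheme = acquisition_scheme(bvals, bvecs),
       voxel_size = RNifti::pixdim(img)[1], image = img)
}

#' Write a phantom's ground truth table
#' @param phantom an [make_crossing_phantom()] result.
#' @param path CSV path.
#' @export
write_ground_truth <- function(phantom, path) {
  utils::write.csv(phantom$truth, path, row.names = FALSE)
  invisible(path)
}
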