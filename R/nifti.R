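# Minimal NIfTI-1 reader/writer.
#
# No NIfTI package is available in the target R library, so the package
# carries a deliberately small codec: single-file .nii (optionally
# .nii.gz), little- or big-endian headers, datatypes uint8/int16/int32/
# float32/float64, scl_slope/scl_inter honoured on read. Orientation is
# limited to a diagonal sform built from the voxel size - sufficient for
# the package's own volumes; it is not a general-purpose NIfTI library.

NIFTI_DTYPES <- data.frame(
  code = c(2L, 4L, 8L, 16L, 64L),
  what = c("integer", "integer", "integer", "numeric", "numeric"),
  size = c(1L, 2L, 4L, 4L, 8L),
  signed = c(FALSE, TRUE, TRUE, TRUE, TRUE)
)

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a 3D/4D array as a NIfTI-1 file
#'
#' Float64 data, little-endian, single-file `.nii` (gzipped when the
#' path ends in `.gz`), diagonal sform from `voxel_size_mm`.
#'
#' @param data numeric array, 2 to 4 dimensions.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param voxel_size_mm voxel dimensions, recycled/truncated to the
#'   array rank.
#' @param datatype "float64" (default) or "float32".
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, voxel_size_mm = c(1, 1, 1),
                        datatype = c("float64", "float32")) {
  datatype <- match.arg(datatype)
  dt_code <- if (datatype == "float64") 64L else 16L
  dt_size <- if (datatype == "float64") 8L else 4L
  d <- dim(data) %||% length(data)
  if (length(d) < 2L || length(d) > 4L) {
    stop("only 2D-4D arrays are supported", call. = FALSE)
  }
  ndim <- length(d)
  dim8 <- c(ndim, d, rep(1L, 7 - length(d)))
  vox <- rep(voxel_size_mm, length.out = 4)
  pixdim8 <- c(1, vox[seq_len(min(length(d), 4))],
               rep(1, 7 - min(length(d), 4)))

  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4,
                             endian = "little")
  wc <- function(s, n) {
    r <- charToRaw(s)
    writeBin(c(r, raw(n - length(r))), con)
  }
  wi(348L, 4)                      # sizeof_hdr
  writeBin(raw(35), con)           # data_type..regular
  writeBin(as.raw(0L), con)        # dim_info
  wi(dim8, 2)                      # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2)        # intent_p1-3, intent_code
  wi(dt_code, 2); wi(dt_size * 8L, 2); wi(0L, 2)  # datatype,bitpix,slice_start
  wf(pixdim8)                      # pixdim[8]
  wf(352); wf(1); wf(0)            # vox_offset, scl_slope, scl_inter
  wi(0L, 2); writeBin(raw(2), con) # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0, 0))                # cal_max, cal_min, slice_dur, toffset
  wi(c(0L, 0L), 4)                 # glmax, glmin
  wc("pvsdwi", 80); wc("", 24)     # descrip, aux_file
  wi(c(0L, 1L), 2)                 # qform_code, sform_code
  wf(c(0, 0, 0, 0, 0, 0))          # quatern b,c,d + qoffset x,y,z
  wf(c(vox[1], 0, 0, 0))           # srow_x
  wf(c(0, vox[2], 0, 0))           # srow_y
  wf(c(0, 0, vox[3], 0))           # srow_z
  wc("", 16)                       # intent_name
  wc("n+1", 4)                     # magic
  writeBin(raw(4), con)            # no extensions
  writeBin(as.numeric(data), con, size = dt_size, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 file
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return List with `data` (array), `dim`, `voxel_size_mm`,
#'   `datatype_code`.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) stop("truncated NIfTI header", call. = FALSE)
  endian <- "little"
  parse_i <- function(off, size, n = 1L) {
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n,
            size = size, endian = endian)
  }
  parse_f <- function(off, n = 1L) {
    readBin(hdr[(off + 1):(off + 4 * n)], "numeric", n = n, size = 4,
            endian = endian)
  }
  if (parse_i(0, 4) != 348L) {
    endian <- "big"
    if (parse_i(0, 4) != 348L) {
      stop("not a NIfTI-1 file (bad sizeof_hdr)", call. = FALSE)
    }
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) {
    stop("not a NIfTI-1 file (bad magic)", call. = FALSE)
  }
  dim8 <- parse_i(40, 2, 8)
  ndim <- dim8[1]
  if (ndim < 1 || ndim > 4) stop("unsupported dimensionality ", ndim,
                                 call. = FALSE)
  d <- dim8[2:(1 + ndim)]
  dt <- parse_i(70, 2)
  spec <- NIFTI_DTYPES[NIFTI_DTYPES$code == dt, ]
  if (nrow(spec) == 0) stop("unsupported NIfTI datatype code ", dt,
                            call. = FALSE)
  pixdim <- parse_f(76, 8)
  vox_offset <- parse_f(108)
  slope <- parse_f(112); inter <- parse_f(116)
  seek(con, where = vox_offset, origin = "start")
  n <- prod(d)
  data <- readBin(con, spec$what, n = n, size = spec$size,
                  signed = spec$signed, endian = endian)
  if (length(data) < n) stop("truncated NIfTI data section", call. = FALSE)
  data <- as.numeric(data)
  if (is.finite(slope) && slope != 0 && !(slope == 1 && inter == 0)) {
    if (!is.finite(inter)) inter <- 0
    data <- data * slope + inter
  }
  dim(data) <- d
  list(data = data, dim = d,
       voxel_size_mm = pixdim[2:(1 + min(ndim, 3))],
       datatype_code = dt)
}

#' Read / write FSL-style b-tables
#'
#' bval: one whitespace-separated row of b-values. bvec: three rows
#' (x, y, z components), one column per volume; b0 columns are zero
#' vectors.
#'
#' @param bvals numeric vector; `bvecs` matrix with one row per volume.
#' @param path file path.
#' @return Readers return a numeric vector / an n x 3 matrix.
#' @export
write_bval <- function(bvals, path) {
  writeLines(paste(format(bvals, trim = TRUE, scientific = FALSE),
                   collapse = " "), path)
  invisible(path)
}

#' @rdname write_bval
#' @export
write_bvec <- function(bvecs, path) {
  bvecs <- as.matrix(bvecs)
  stopifnot(ncol(bvecs) == 3L)
  lines <- apply(t(bvecs), 1, function(r) {
    paste(sprintf("%.17g", r), collapse = " ")
  })
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_bval
#' @export
read_bval <- function(path) {
  if (!file.exists(path)) {
    stop("missing bval sidecar: ", path, call. = FALSE)
  }
  as.numeric(scan(path, quiet = TRUE))
}

#' @rdname write_bval
#' @export
read_bvec <- function(path) {
  if (!file.exists(path)) {
    stop("missing bvec sidecar: ", path, call. = FALSE)
  }
  rows <- lapply(readLines(path), function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  })
  rows <- rows[vapply(rows, length, 1L) > 0]
  if (length(rows) != 3L) {
    stop("bvec file must have 3 rows (x, y, z): ", path, call. = FALSE)
  }
  t(do.call(rbind, rows))
}

#' Write / read a DWI volume with sidecars
#'
#' `write_dwi` writes `<stem>.nii` plus `<stem>.bval` and `<stem>.bvec`
#' (FSL dialect). `read_dwi` reads them back and validates that the
#' b-table length matches the number of volumes. The round trip is
#' lossless (float64 data).
#'
#' @param dwi a [dwi_volume()].
#' @param stem path without extension.
#' @return `read_dwi` returns a [dwi_volume()]; `write_dwi` the stem,
#'   invisibly.
#' @export
write_dwi <- function(dwi, stem) {
  stopifnot(inherits(dwi, "dwi_volume"))
  write_nifti(dwi$data, paste0(stem, ".nii"), dwi$voxel_size_mm)
  write_bval(dwi$bvals, paste0(stem, ".bval"))
  write_bvec(dwi$bvecs, paste0(stem, ".bvec"))
  invisible(stem)
}

#' @rdname write_dwi
#' @export
read_dwi <- function(stem) {
  nii_path <- if (file.exists(paste0(stem, ".nii"))) {
    paste0(stem, ".nii")
  } else paste0(stem, ".nii.gz")
  nii <- read_nifti(nii_path)
  bvals <- read_bval(paste0(stem, ".bval"))
  bvecs <- read_bvec(paste0(stem, ".bvec"))
  nvol <- if (length(nii$dim) == 4L) nii$dim[4] else 1L
  if (length(bvals) != nvol || nrow(bvecs) != nvol) {
    stop(sprintf(
      "b-table mismatch: %d volumes but %d bvals / %d bvecs",
      nvol, length(bvals), nrow(bvecs)), call. = FALSE)
  }
  data <- nii$data
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  vox <- rep(nii$voxel_size_mm, length.out = 3)
  dwi_volume(data, bvals, bvecs, vox, meta = list(source = nii_path))
}

#' Write ground truth as NIfTI maps
#'
#' Label map as int-valued float NIfTI, tensors as a 6-volume NIfTI in
#' the packing Dxx, Dxy, Dxz, Dyy, Dyz, Dzz.
#'
#' @param gt a `ground_truth`.
#' @param stem path without extension; writes `<stem>_labels.nii` and
#'   `<stem>_tensors.nii`.
#' @return The stem, invisibly.
#' @export
write_ground_truth <- function(gt, stem) {
  stopifnot(inherits(gt, "ground_truth"))
  vox <- c(gt$spec$fov_mm / gt$spec$matrix, gt$spec$slice_thickness_mm)
  lab <- array(as.numeric(gt$label_map), c(dim(gt$label_map), 1))
  write_nifti(lab, paste0(stem, "_labels.nii"), vox)
  tm <- gt$tensor_map
  tm[is.na(tm)] <- 0
  d <- dim(tm)
  write_nifti(array(tm, c(d[1], d[2], 1, 6)),
              paste0(stem, "_tensors.nii"), vox)
  invisible(stem)
}
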