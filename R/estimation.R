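# Pseudo-diffusion estimation: per-direction D*, log-linear tensor fit,
# eigen-decomposition, FA/MD, masking, smoothing, ellipsoid export.

#' Per-direction pseudo-diffusion coefficient
#'
#' Inverts S = S0 exp(-b D*) to D* = ln(S0/S)/b for a single direction.
#' Signals above S0 give a negative D*; these are returned as-is so that
#' ROI means stay unbiased, but can be flagged by the caller. Vectorised
#' over `S` and `S0`.
#'
#' @param S diffusion-weighted signal (> 0).
#' @param S0 non-weighted signal (> 0).
#' @param b b-value, s/mm^2 (> 0).
#' @return D* in mm^2/s; NA where S or S0 is non-positive.
#' @examples
#' estimate_dstar(0.4988, 1, 107)  # ~0.0065
#' @export
estimate_dstar <- function(S, S0, b) {
  if (length(b) != 1L || !is.finite(b) || b <= 0) {
    stop("b must be a single positive value", call. = FALSE)
  }
  n <- max(length(S), length(S0))
  dims <- if (length(S) == n) dim(S) else dim(S0)
  S <- rep_len(S, n); S0 <- rep_len(S0, n)
  ok <- S > 0 & S0 > 0
  d <- rep(NA_real_, n)
  d[ok] <- log(S0[ok] / S[ok]) / b
  dim(d) <- dims
  d
}

#' Build a b-matrix from b-values and directions
#'
#' Default rank-1 construction B_i = b_i g_i g_i'. Externally calculated
#' b-matrices (e.g. including imaging-gradient cross terms) can be
#' passed to [fit_tensor()] directly instead.
#'
#' @param bvals numeric vector, s/mm^2.
#' @param bvecs matrix of unit row 3-vectors (zero rows allowed for b0).
#' @return List of 3 x 3 matrices, one per volume.
#' @export
build_bmatrix <- function(bvals, bvecs) {
  bvecs <- as.matrix(bvecs)
  stopifnot(length(bvals) == nrow(bvecs), ncol(bvecs) == 3L)
  lapply(seq_along(bvals), function(i) bvals[i] * tcrossprod(bvecs[i, ]))
}

# Design row for the 6-element packing (Dxx,Dxy,Dxz,Dyy,Dyz,Dzz):
# ln(S0/S) = Bxx Dxx + 2 Bxy Dxy + 2 Bxz Dxz + Byy Dyy + 2 Byz Dyz + Bzz Dzz
bmatrix_design <- function(bmatrix) {
  t(vapply(bmatrix, function(B) {
    c(B[1, 1], 2 * B[1, 2], 2 * B[1, 3], B[2, 2], 2 * B[2, 3], B[3, 3])
  }, numeric(6)))
}

#' Log-linear least-squares tensor fit
#'
#' Solves ln(S0/S_i) = sum_jk B_i,jk D_jk for the six unique tensor
#' elements by ordinary least squares. With only two amplitudes per
#' direction (b0 and one b) this matches the two-point acquisition
#' design; weighted or nonlinear variants are out of scope.
#'
#' @param signals per-direction signals (> 0), length >= 6.
#' @param S0 the non-weighted signal (> 0).
#' @param bmatrix list of per-direction 3 x 3 b-matrices (s/mm^2), or a
#'   matrix of unit row 3-vectors together with `b` to use the default
#'   rank-1 construction.
#' @param b scalar b-value when `bmatrix` is given as directions.
#' @return 3 x 3 symmetric tensor, mm^2/s.
#' @examples
#' D <- tensor_from_fa_md(0.5, 0.004, c(0, 1, 0))
#' g <- default_directions()
#' s <- apply(g, 1, function(gi) dwi_signal(1, 107, gi, D))
#' max(abs(fit_tensor(s, 1, g, b = 107) - D))  # ~1e-19
#' @export
fit_tensor <- function(signals, S0, bmatrix, b = NULL) {
  if (is.matrix(bmatrix) || is.data.frame(bmatrix)) {
    if (is.null(b)) stop("supply b when bmatrix is a direction matrix",
                         call. = FALSE)
    bmatrix <- build_bmatrix(rep(b, nrow(bmatrix)), bmatrix)
  }
  if (length(signals) < 6L) {
    stop("at least 6 diffusion-weighted measurements are required",
         call. = FALSE)
  }
  if (length(signals) != length(bmatrix)) {
    stop("signals and bmatrix lengths differ", call. = FALSE)
  }
  if (any(signals <= 0) || S0 <= 0) {
    stop("all signals and S0 must be > 0", call. = FALSE)
  }
  X <- bmatrix_design(bmatrix)
  qx <- qr(X)
  if (qx$rank < 6L) {
    stop("rank-deficient direction design (rank ", qx$rank,
         " < 6): directions are coplanar or duplicated", call. = FALSE)
  }
  y <- log(S0 / signals)
  vec6_to_tensor(qr.coef(qx, y))
}

# Sign convention: first component with |v_i| > tol is made >= 0.
fix_eigvec_sign <- function(v, tol = 1e-12) {
  i <- which(abs(v) > tol)
  if (length(i) && v[i[1]] < 0) v <- -v
  v
}

#' Sorted eigen-decomposition of a symmetric tensor
#'
#' Eigenvalues in descending order. The first two eigenvectors obey the
#' sign convention "first non-zero component >= 0"; the third is their
#' cross product, so the triad is always right-handed and maps are
#' reproducible.
#'
#' @param tensor 3 x 3 symmetric matrix.
#' @return List with `values` (length 3, descending) and `vectors`
#'   (3 x 3, columns are eigenvectors).
#' @export
eig_sorted <- function(tensor) {
  tensor <- as.matrix(tensor)
  if (any(abs(tensor - t(tensor)) > 1e-10 * max(1, max(abs(tensor))))) {
    stop("tensor must be symmetric", call. = FALSE)
  }
  ev <- eigen((tensor + t(tensor)) / 2, symmetric = TRUE)
  v1 <- fix_eigvec_sign(ev$vectors[, 1])
  v2 <- fix_eigvec_sign(ev$vectors[, 2])
  v3 <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  list(values = ev$values, vectors = cbind(v1, v2, v3, deparse.level = 0))
}

#' Fractional anisotropy from eigenvalues
#'
#' FA = sqrt(3/2) sqrt(sum (l_i - MD)^2 / sum l_i^2), clipped to [0, 1].
#'
#' @param l1 leading eigenvalue, or a length-3 vector of all three.
#' @param l2,l3 remaining eigenvalues if `l1` is scalar.
#' @return FA in [0, 1]; NA for an all-zero tensor.
#' @examples
#' fractional_anisotropy(2e-3, 1e-3, 1e-3)  # 0.408
#' @export
fractional_anisotropy <- function(l1, l2 = NULL, l3 = NULL) {
  l <- if (is.null(l2)) l1 else c(l1, l2, l3)
  stopifnot(length(l) == 3L)
  ss <- sum(l^2)
  if (ss == 0) return(NA_real_)
  md <- mean(l)
  fa <- sqrt(1.5 * sum((l - md)^2) / ss)
  min(max(fa, 0), 1)
}

#' Mean diffusivity from eigenvalues
#'
#' (l1 + l2 + l3) / 3, equal to trace(D)/3 and rotation invariant.
#' @inheritParams fractional_anisotropy
#' @return MD in the eigenvalue units.
#' @export
mean_diffusivity <- function(l1, l2 = NULL, l3 = NULL) {
  l <- if (is.null(l2)) l1 else c(l1, l2, l3)
  stopifnot(length(l) == 3L)
  mean(l)
}

#' Intensity threshold mask from a b0 image
#'
#' Retains voxels whose b0 intensity exceeds a cutoff, removing signal
#' that does not principally derive from fluid-filled compartments. The
#' long-TE contrast makes fluid voxels roughly an order of magnitude
#' brighter than parenchyma, so a high-percentile cutoff isolates them.
#'
#' @param b0 2D (or higher) non-negative array.
#' @param method "percentile" (default) or "otsu".
#' @param probs percentile level for the default method (0.9).
#' @param cutoff explicit intensity cutoff overriding `method`
#'   (e.g. 0 keeps every positive voxel).
#' @return Logical array, TRUE where `b0 > cutoff`.
#' @export
threshold_mask <- function(b0, method = c("percentile", "otsu"),
                           probs = 0.9, cutoff = NULL) {
  method <- match.arg(method)
  if (any(b0 < 0)) stop("b0 must be non-negative", call. = FALSE)
  if (is.null(cutoff)) {
    if (diff(range(b0)) == 0) {
      warning("constant image: empty mask", call. = FALSE)
      return(array(FALSE, dim = dim(b0) %||% length(b0)))
    }
    cutoff <- switch(method,
      percentile = stats::quantile(b0, probs = probs, names = FALSE),
      otsu = otsu_threshold(b0)
    )
  }
  b0 > cutoff
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Otsu's between-class variance maximisation on a 256-bin histogram.
otsu_threshold <- function(x) {
  r <- range(x)
  breaks <- seq(r[1], r[2], length.out = 257)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), nbins = 256)
  w <- h / sum(h)
  mids <- (breaks[-1] + breaks[-257]) / 2
  cw <- cumsum(w)
  cm <- cumsum(w * mids)
  mt <- cm[256]
  bcv <- (mt * cw - cm)^2 / (cw * (1 - cw))
  bcv[!is.finite(bcv)] <- 0
  # the low class includes the whole argmax bin, so the cutoff is that
  # bin's upper edge
  breaks[which.max(bcv) + 1]
}

#' Edge-preserving smoothing of a scalar map
#'
#' Median filter of square radius `radius`, applied only at voxels of
#' `mask` and using only in-mask neighbours, so fluid/parenchyma edges
#' are never mixed. Radius 0 is the identity.
#'
#' @param map 2D numeric matrix.
#' @param radius non-negative integer neighbourhood radius.
#' @param mask logical matrix; NULL smooths everywhere.
#' @return Smoothed matrix (same dim; out-of-mask voxels untouched).
#' @export
smooth_edge_preserving <- function(map, radius = 1L, mask = NULL) {
  if (radius < 0) stop("radius must be >= 0", call. = FALSE)
  radius <- as.integer(radius)
  if (radius == 0L) return(map)
  if (is.null(mask)) mask <- array(TRUE, dim(map))
  stopifnot(identical(dim(map), dim(mask)))
  out <- map
  idx <- which(mask, arr.ind = TRUE)
  nr <- nrow(map); nc <- ncol(map)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    ii <- max(1L, i - radius):min(nr, i + radius)
    jj <- max(1L, j - radius):min(nc, j + radius)
    nb <- map[ii, jj][mask[ii, jj]]
    out[i, j] <- stats::median(nb)
  }
  out
}

#' Whole-volume tensor fit
#'
#' Fits the pseudo-diffusion tensor at every voxel of a [dwi_volume()]
#' inside `mask` (default: [threshold_mask()] on the mean b0) and
#' derives eigensystems, FA and MD. The fit is the same log-linear
#' solve as [fit_tensor()], vectorised with a single pseudo-inverse
#' because the design is shared across voxels.
#'
#' Voxels whose fitted tensor has a negative eigenvalue are flagged
#' FALSE in `valid_mask` and their eigenvalues clipped to 1e-12 for
#' FA/MD; low-b, low-SNR fits can be non-PSD.
#'
#' @param dwi a [dwi_volume()].
#' @param mask logical matrix (x by y), or NULL for the default.
#' @param bmatrix optional list of per-volume 3 x 3 b-matrices (one per
#'   diffusion-weighted volume, b0 volumes excluded) overriding the
#'   rank-1 default.
#' @param smooth_radius median-filter radius applied to FA and MD maps
#'   (0 = no smoothing).
#' @return Object of class `tensor_fit`: `tensor_map` (x, y, 6 packing
#'   Dxx,Dxy,Dxz,Dyy,Dyz,Dzz), `eigenvalues` (x, y, 3 descending),
#'   `eigenvectors` (x, y, 3, 3), `fa_map`, `md_map`, `residual` (RMS
#'   log residual), `valid_mask`, `mask`.
#' @export
fit_dti <- function(dwi, mask = NULL, bmatrix = NULL, smooth_radius = 0L) {
  stopifnot(inherits(dwi, "dwi_volume"))
  nx <- dim(dwi$data)[1]; ny <- dim(dwi$data)[2]
  is_b0 <- dwi$bvals == 0
  if (!any(is_b0)) stop("no b0 volume present", call. = FALSE)
  if (sum(!is_b0) < 6L) {
    stop("at least 6 diffusion-weighted volumes are required", call. = FALSE)
  }
  b0 <- apply(dwi$data[, , 1, is_b0, drop = FALSE], c(1, 2), mean)
  if (is.null(mask)) mask <- threshold_mask(b0)
  if (is.null(bmatrix)) {
    bmatrix <- build_bmatrix(dwi$bvals[!is_b0],
                             dwi$bvecs[!is_b0, , drop = FALSE])
  }
  X <- bmatrix_design(bmatrix)
  qx <- qr(X)
  if (qx$rank < 6L) {
    stop("rank-deficient direction design (rank ", qx$rank,
         " < 6): directions are coplanar or duplicated", call. = FALSE)
  }
  pinv <- solve(crossprod(X), t(X))            # 6 x ndir

  vox <- which(mask & b0 > 0)
  dwi_mat <- matrix(dwi$data[, , 1, !is_b0], nx * ny, sum(!is_b0))
  S <- dwi_mat[vox, , drop = FALSE]
  S[S <= 0] <- NA_real_
  Y <- log(b0[vox] / S)                        # nvox x ndir
  Dv <- Y %*% t(pinv)                          # nvox x 6
  resid <- Y - Dv %*% t(X)
  rms <- sqrt(rowMeans(resid^2))

  tensor_map <- array(NA_real_, c(nx, ny, 6))
  evals <- array(NA_real_, c(nx, ny, 3))
  evecs <- array(NA_real_, c(nx, ny, 3, 3))
  fa <- matrix(NA_real_, nx, ny)
  md <- matrix(NA_real_, nx, ny)
  residual <- matrix(NA_real_, nx, ny)
  valid <- matrix(FALSE, nx, ny)

  for (k in seq_along(vox)) {
    v <- Dv[k, ]
    if (anyNA(v)) next
    es <- eig_sorted(vec6_to_tensor(v))
    l <- es$values
    ok <- all(l >= 0)
    l_clip <- pmax(l, 1e-12)
    ij <- arrayInd(vox[k], c(nx, ny))
    i <- ij[1]; j <- ij[2]
    tensor_map[i, j, ] <- v
    evals[i, j, ] <- l
    evecs[i, j, , ] <- es$vectors
    fa[i, j] <- fractional_anisotropy(l_clip)
    md[i, j] <- mean_diffusivity(l_clip)
    residual[i, j] <- rms[k]
    valid[i, j] <- ok
  }
  if (smooth_radius > 0L) {
    fa <- smooth_edge_preserving(fa, smooth_radius, mask & !is.na(fa))
    md <- smooth_edge_preserving(md, smooth_radius, mask & !is.na(md))
  }
  structure(list(tensor_map = tensor_map, eigenvalues = evals,
                 eigenvectors = evecs, fa_map = fa, md_map = md,
                 residual = residual, valid_mask = valid, mask = mask),
            class = "tensor_fit")
}

#' @export
print.tensor_fit <- function(x, ...) {
  n <- sum(x$mask)
  cat(sprintf("Pseudo-diffusion tensor fit: %d voxels in mask, %d valid\n",
              n, sum(x$valid_mask)))
  cat(sprintf("  FA  %.3f (median over valid)\n",
              stats::median(x$fa_map[x$valid_mask], na.rm = TRUE)))
  cat(sprintf("  MD  %.5f mm^2/s (median over valid)\n",
              stats::median(x$md_map[x$valid_mask], na.rm = TRUE)))
  invisible(x)
}

#' Tensor ellipsoid glyph parameters
#'
#' One row per valid voxel: voxel indices (0-based, x readout / y
#' phase), semi-axes proportional to the eigenvalues, orientation as a
#' unit quaternion (w, x, y, z) of the eigenvector triad, and an RGB
#' colour from the absolute components of the principal eigenvector
#' (red = x, green = y, blue = z, the standard DTI convention).
#'
#' @param fit a `tensor_fit` from [fit_dti()].
#' @return data.frame with columns i, j, a1, a2, a3, qw, qx, qy, qz,
#'   r, g, b.
#' @export
tensor_ellipsoids <- function(fit) {
  stopifnot(inherits(fit, "tensor_fit"))
  idx <- which(fit$valid_mask, arr.ind = TRUE)
  rows <- lapply(seq_len(nrow(idx)), function(k) {
    i <- idx[k, 1]; j <- idx[k, 2]
    l <- pmax(fit$eigenvalues[i, j, ], 0)
    R <- fit$eigenvectors[i, j, , ]
    q <- rotmat_to_quat(R)
    v1 <- abs(R[, 1])
    data.frame(i = i - 1L, j = j - 1L,
               a1 = l[1], a2 = l[2], a3 = l[3],
               qw = q[1], qx = q[2], qy = q[3], qz = q[4],
               r = v1[1], g = v1[2], b = v1[3])
  })
  do.call(rbind, rows) %||% data.frame()
}

# Shepperd's method; R must be a rotation (right-handed orthonormal).
rotmat_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, s / 4, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, s / 4,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, s / 4)
  }
  q / sqrt(sum(q^2))
}

#' Per-direction D* maps from a DWI volume
#'
#' Applies [estimate_dstar()] voxelwise for every diffusion-weighted
#' volume against the mean b0.
#'
#' @param dwi a [dwi_volume()].
#' @param mask logical matrix or NULL for [threshold_mask()] on b0.
#' @return List with `dstar` (x, y, ndir array), `bvecs` (ndir x 3),
#'   `mask`.
#' @export
dstar_maps <- function(dwi, mask = NULL) {
  stopifnot(inherits(dwi, "dwi_volume"))
  is_b0 <- dwi$bvals == 0
  if (!any(is_b0)) stop("no b0 volume present", call. = FALSE)
  b0 <- apply(dwi$data[, , 1, is_b0, drop = FALSE], c(1, 2), mean)
  if (is.null(mask)) mask <- threshold_mask(b0)
  ids <- which(!is_b0)
  out <- array(NA_real_, c(dim(b0), length(ids)))
  for (k in seq_along(ids)) {
    s <- dwi$data[, , 1, ids[k]]
    d <- estimate_dstar(pmax(s, .Machine$double.eps), b0,
                        dwi$bvals[ids[k]])
    d[!mask | b0 <= 0] <- NA_real_
    out[, , k] <- d
  }
  list(dstar = out, bvecs = dwi$bvecs[ids, , drop = FALSE], mask = mask)
}
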