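# Tissue/fluid compartments and axially symmetric tensor construction.

#' Define a tissue or fluid compartment
#'
#' A compartment couples a T2 (for the long-TE contrast), an equilibrium
#' signal and a 3 x 3 symmetric positive semi-definite pseudo-diffusion
#' tensor. `principal_axis` is a convenience copy of the leading
#' eigenvector and is validated against the tensor.
#'
#' @param name label.
#' @param T2 transverse relaxation time, ms (> 0).
#' @param S0 equilibrium signal, arbitrary units (>= 0).
#' @param Dstar 3 x 3 symmetric PSD tensor, mm^2/s.
#' @param principal_axis unit 3-vector; NULL to take the leading
#'   eigenvector of `Dstar`.
#' @return Object of class `compartment`.
#' @export
compartment <- function(name, T2, S0, Dstar, principal_axis = NULL) {
  if (T2 <= 0) stop("T2 must be > 0", call. = FALSE)
  if (S0 < 0) stop("S0 must be >= 0", call. = FALSE)
  Dstar <- as.matrix(Dstar)
  if (any(abs(Dstar - t(Dstar)) > 1e-15)) {
    stop("Dstar must be symmetric", call. = FALSE)
  }
  ev <- eigen(Dstar, symmetric = TRUE)
  if (any(ev$values < -1e-15)) {
    stop("Dstar must be positive semi-definite", call. = FALSE)
  }
  lead <- ev$vectors[, 1]
  if (is.null(principal_axis)) {
    principal_axis <- fix_eigvec_sign(lead)
  } else {
    principal_axis <- as.numeric(principal_axis)
    if (abs(abs(sum(principal_axis * lead)) - 1) > 1e-6 &&
        diff(range(ev$values[1:2])) > 1e-12 * max(ev$values)) {
      stop("principal_axis must equal the leading eigenvector of Dstar",
           call. = FALSE)
    }
  }
  structure(list(name = name, T2 = T2, S0 = S0, Dstar = Dstar,
                 principal_axis = principal_axis),
            class = "compartment")
}

#' Axially symmetric tensor from FA, MD and an axis
#'
#' Solves for eigenvalues (l_par, l_perp, l_perp) matching a target
#' fractional anisotropy and mean diffusivity, then orients the long
#' axis along `axis`. Closed form: with d = l_par - MD,
#' d = MD * FA * sqrt(3 / (9/4 - 3/2 FA^2)) and l_perp = (3 MD - l_par)/2.
#' Only prolate (l_par > l_perp) solutions are produced, matching
#' elongated fluid channels.
#'
#' @param fa target fractional anisotropy in [0, 1).
#' @param md target mean diffusivity, mm^2/s (> 0).
#' @param axis unit 3-vector for the principal direction.
#' @return 3 x 3 symmetric PSD tensor with the requested FA and MD.
#' @examples
#' D <- tensor_from_fa_md(0.44, 0.0042, c(1, 0, 0))
#' fractional_anisotropy(eig_sorted(D)$values)  # 0.44
#' @export
tensor_from_fa_md <- function(fa, md, axis) {
  if (fa < 0 || fa >= 1) stop("fa must be in [0, 1)", call. = FALSE)
  if (md <= 0) stop("md must be > 0", call. = FALSE)
  axis <- as.numeric(axis)
  axis <- axis / sqrt(sum(axis^2))
  d <- md * fa * sqrt(3 / (2.25 - 1.5 * fa^2))
  l_par <- md + d
  l_perp <- (3 * md - l_par) / 2
  diag(l_perp, 3) + (l_par - l_perp) * tcrossprod(axis)
}

#' Default compartment table for the ventral-slice phantom
#'
#' T2 values: fluid (CSF, perivascular, ventricle) 111 ms; grey matter
#' 38 ms; blood 30 ms (9.4 T literature values). Pseudo-diffusion
#' defaults: perivascular FA 0.44 / MD 0.0042 mm^2/s and subarachnoid FA
#' 0.60 / MD 0.0065 mm^2/s (in-vivo ROI means, used as ground truth);
#' third ventricle isotropic 0.003 mm^2/s; parenchyma isotropic 7e-4
#' (tissue ADC scale); blood isotropic 0.05 (fast, incoherent flow).
#' Axes given here are placeholders - the geometry builder re-orients
#' perivascular tensors along the local vessel tangent and subarachnoid
#' tensors along the caudal-rostral axis.
#'
#' @return Named list of [compartment()] objects:
#'   parenchyma, blood, subarachnoid, pvs, ventricle.
#' @export
default_compartments <- function() {
  ax_y <- c(0, 1, 0)
  list(
    parenchyma  = compartment("parenchyma", T2 = 38, S0 = 100,
                              Dstar = diag(7e-4, 3)),
    blood       = compartment("blood", T2 = 30, S0 = 100,
                              Dstar = diag(0.05, 3)),
    subarachnoid = compartment("subarachnoid", T2 = 111, S0 = 100,
                               Dstar = tensor_from_fa_md(0.60, 0.0065, ax_y)),
    pvs         = compartment("pvs", T2 = 111, S0 = 100,
                              Dstar = tensor_from_fa_md(0.44, 0.0042, ax_y)),
    ventricle   = compartment("ventricle", T2 = 111, S0 = 100,
                              Dstar = diag(0.003, 3))
  )
}

# 6-element packing used for tensor maps: Dxx, Dxy, Dxz, Dyy, Dyz, Dzz.
tensor_to_vec6 <- function(D) {
  c(D[1, 1], D[1, 2], D[1, 3], D[2, 2], D[2, 3], D[3, 3])
}

vec6_to_tensor <- function(v) {
  matrix(c(v[1], v[2], v[3],
           v[2], v[4], v[5],
           v[3], v[5], v[6]), 3, 3)
}
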