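# Digital single-slice phantom of the ventral rat brain: subarachnoid
# CSF over the Circle of Willis, two MCA branches flanked by
# perivascular tracts, third ventricle, parenchyma and blood, with
# per-compartment T2 and ground-truth pseudo-diffusion tensors.

PHANTOM_SCENARIOS <- c("baseline", "pulsation", "diastole", "dobutamine",
                       "postmortem")

# Integer labels of the ground-truth map.
PHANTOM_LABELS <- c(background = 0L, parenchyma = 1L, blood = 2L,
                    subarachnoid = 3L, pvs = 4L, ventricle = 5L)

#' Specification of the digital ventral-slice phantom
#'
#' Geometry is schematic: a parenchymal ellipse, a circular Circle of
#' Willis (CoW) arterial ring, two middle-cerebral-artery (MCA) branches
#' as smooth quadratic curves diverging left/right from the ring, each
#' flanked on both sides by a perivascular (PVS) tract; a midline
#' caudal-rostral subarachnoid CSF band crossing the CoW mid-section;
#' and a third-ventricle ellipse. Distances in mm, origin at the image
#' centre, x = left-right (readout), y = caudal(-)/rostral(+) (phase).
#'
#' Scenario gains act on the PVS leading eigenvalue: `pulsation_gain`
#' (default 4.0, i.e. ~300% greater than diastole) and
#' `dobutamine_gain` (default 1.65, a 65% increase over baseline).
#' `postmortem_factor` (default 0.1) scales all fluid-compartment
#' tensors; the true post-mortem reduction is qualitative only, so this
#' is a free parameter.
#'
#' @param matrix image matrix size, 2 integers (default 128 x 128).
#' @param fov_mm field of view, mm (default 25 x 25).
#' @param slice_thickness_mm slice thickness, metadata only.
#' @param compartments named list from [default_compartments()].
#' @param scenario one of baseline, pulsation, diastole, dobutamine,
#'   postmortem.
#' @param pulsation_gain,dobutamine_gain,postmortem_factor scenario
#'   multipliers (> 0).
#' @param noise_sigma Rician channel noise sigma in signal units.
#' @param seed integer seed for noise generation.
#' @param pvs_halfwidth_mm PVS tract half-width beyond the vessel lumen.
#' @param lumen_halfwidth_mm vessel lumen half-width.
#' @param cow_centre,cow_radius CoW ring centre (mm) and radius.
#' @param sa_halfwidth_mm,sa_extent_mm subarachnoid band half-width and
#'   caudal/rostral y-extent (2 values).
#' @param ventricle_centre,ventricle_semi third-ventricle ellipse
#'   centre and semi-axes, mm.
#' @param brain_semi parenchyma ellipse semi-axes, mm.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(matrix = c(128L, 128L), fov_mm = c(25, 25),
                         slice_thickness_mm = 1.0,
                         compartments = default_compartments(),
                         scenario = "baseline",
                         pulsation_gain = 4.0, dobutamine_gain = 1.65,
                         postmortem_factor = 0.1,
                         noise_sigma = 0, seed = 1L,
                         pvs_halfwidth_mm = 0.35,
                         lumen_halfwidth_mm = 0.2,
                         cow_centre = c(0, -4), cow_radius = 2.2,
                         sa_halfwidth_mm = 1.1,
                         sa_extent_mm = c(-8.5, -0.5),
                         ventricle_centre = c(0, 4.0),
                         ventricle_semi = c(0.8, 1.8),
                         brain_semi = c(11, 12)) {
  scenario <- match.arg(scenario, PHANTOM_SCENARIOS)
  if (pulsation_gain <= 0 || dobutamine_gain <= 0 || postmortem_factor <= 0) {
    stop("scenario gains must be > 0", call. = FALSE)
  }
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (pvs_halfwidth_mm <= 0 || lumen_halfwidth_mm <= 0) {
    stop("degenerate geometry: tract/lumen half-widths must be > 0",
         call. = FALSE)
  }
  structure(list(
    matrix = as.integer(matrix), fov_mm = fov_mm,
    slice_thickness_mm = slice_thickness_mm, compartments = compartments,
    scenario = scenario, pulsation_gain = pulsation_gain,
    dobutamine_gain = dobutamine_gain, postmortem_factor = postmortem_factor,
    noise_sigma = noise_sigma, seed = as.integer(seed),
    pvs_halfwidth_mm = pvs_halfwidth_mm,
    lumen_halfwidth_mm = lumen_halfwidth_mm,
    cow_centre = cow_centre, cow_radius = cow_radius,
    sa_halfwidth_mm = sa_halfwidth_mm, sa_extent_mm = sa_extent_mm,
    ventricle_centre = ventricle_centre, ventricle_semi = ventricle_semi,
    brain_semi = brain_semi
  ), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "Phantom: %dx%d, FOV %gx%g mm, scenario '%s', noise sigma %g, seed %d\n",
    x$matrix[1], x$matrix[2], x$fov_mm[1], x$fov_mm[2], x$scenario,
    x$noise_sigma, x$seed))
  invisible(x)
}

# Quadratic Bezier sampled at n points; control points are 2 x 3.
bezier2 <- function(p0, p1, p2, n = 200L) {
  t <- seq(0, 1, length.out = n)
  cbind((1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1],
        (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2])
}

# MCA branch centrelines: start on the CoW ring at +-45 degrees and
# curve laterally-rostrally (morphology of the ventral view).
mca_polylines <- function(spec) {
  c0 <- spec$cow_centre; r <- spec$cow_radius
  s <- sqrt(0.5)
  right <- bezier2(c0 + r * c(s, s), c(4.5, 0.5), c(6.5, 5.5))
  left <- right
  left[, 1] <- -left[, 1]
  list(right = right, left = left)
}

# Distance from voxel-centre grid points to a polyline, with the tangent
# (unit, by central finite differences) at the nearest polyline sample.
polyline_distance <- function(px, py, poly) {
  n <- nrow(poly)
  d2 <- outer(px, poly[, 1], "-")^2 + outer(py, poly[, 2], "-")^2
  j <- max.col(-d2, ties.method = "first")
  jm <- pmax(j - 1L, 1L); jp <- pmin(j + 1L, n)
  tx <- poly[jp, 1] - poly[jm, 1]
  ty <- poly[jp, 2] - poly[jm, 2]
  nrm <- sqrt(tx^2 + ty^2)
  list(dist = sqrt(d2[cbind(seq_along(px), j)]),
       tangent = cbind(tx / nrm, ty / nrm))
}

# Voxel-centre coordinates in mm, origin at the image centre.
voxel_grid <- function(spec) {
  nx <- spec$matrix[1]; ny <- spec$matrix[2]
  px <- spec$fov_mm[1] / nx; py <- spec$fov_mm[2] / ny
  x <- (seq_len(nx) - (nx + 1) / 2) * px
  y <- (seq_len(ny) - (ny + 1) / 2) * py
  list(x = rep(x, times = ny), y = rep(y, each = nx), nx = nx, ny = ny,
       pix = c(px, py))
}

#' Build the phantom geometry and ground truth
#'
#' Assigns every voxel exactly one compartment label (nearest-label, no
#' partial-volume mixing) and constructs the per-voxel ground-truth
#' tensor field: perivascular tensors have their principal axis along
#' the local MCA tangent, subarachnoid tensors along the caudal-rostral
#' (+y) axis; other compartments are isotropic.
#'
#' @param spec a [phantom_spec()].
#' @return Object of class `ground_truth` with `label_map` (x by y
#'   integer matrix, see `PHANTOM_LABELS`), `tensor_map` (x, y, 6
#'   packing Dxx,Dxy,Dxz,Dyy,Dyz,Dzz), `tangent_map` (x, y, 3; NA off
#'   PVS/subarachnoid), `labels`, `spec`.
#' @export
build_geometry <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- voxel_grid(spec)
  lab <- rep(PHANTOM_LABELS[["background"]], g$nx * g$ny)

  inside_brain <- (g$x / spec$brain_semi[1])^2 +
    (g$y / spec$brain_semi[2])^2 <= 1
  lab[inside_brain] <- PHANTOM_LABELS[["parenchyma"]]

  sa <- abs(g$x) <= spec$sa_halfwidth_mm &
    g$y >= spec$sa_extent_mm[1] & g$y <= spec$sa_extent_mm[2] &
    inside_brain
  lab[sa] <- PHANTOM_LABELS[["subarachnoid"]]

  vent <- ((g$x - spec$ventricle_centre[1]) / spec$ventricle_semi[1])^2 +
    ((g$y - spec$ventricle_centre[2]) / spec$ventricle_semi[2])^2 <= 1
  lab[vent & inside_brain] <- PHANTOM_LABELS[["ventricle"]]

  # CoW arterial ring (blood).
  rr <- sqrt((g$x - spec$cow_centre[1])^2 + (g$y - spec$cow_centre[2])^2)
  ring <- abs(rr - spec$cow_radius) <= spec$lumen_halfwidth_mm

  branches <- mca_polylines(spec)
  tangent <- matrix(NA_real_, g$nx * g$ny, 3)
  pvs <- rep(FALSE, g$nx * g$ny)
  lumen <- ring
  for (br in branches) {
    pd <- polyline_distance(g$x, g$y, br)
    in_lumen <- pd$dist <= spec$lumen_halfwidth_mm
    in_pvs <- pd$dist > spec$lumen_halfwidth_mm &
      pd$dist <= spec$lumen_halfwidth_mm + spec$pvs_halfwidth_mm
    lumen <- lumen | in_lumen
    new_pvs <- in_pvs & !pvs
    tangent[new_pvs, 1:2] <- pd$tangent[new_pvs, ]
    tangent[new_pvs, 3] <- 0
    pvs <- pvs | in_pvs
  }
  pvs <- pvs & !lumen & inside_brain
  lab[pvs] <- PHANTOM_LABELS[["pvs"]]
  lab[lumen & inside_brain] <- PHANTOM_LABELS[["blood"]]
  tangent[lab != PHANTOM_LABELS[["pvs"]], ] <- NA_real_
  tangent[lab == PHANTOM_LABELS[["subarachnoid"]], ] <-
    rep(c(0, 1, 0), each = sum(lab == PHANTOM_LABELS[["subarachnoid"]]))

  if (!any(lab == PHANTOM_LABELS[["pvs"]])) {
    stop("degenerate geometry: no perivascular voxels", call. = FALSE)
  }

  # Per-voxel tensors (6-element packing).
  tmap <- matrix(NA_real_, g$nx * g$ny, 6)
  comp <- spec$compartments
  for (nm in names(comp)) {
    sel <- lab == PHANTOM_LABELS[[nm]]
    if (!any(sel)) next
    if (nm %in% c("pvs", "subarachnoid")) {
      ax <- tangent[sel, , drop = FALSE]
      es <- eig_sorted(comp[[nm]]$Dstar)
      l_par <- es$values[1]; l_perp <- es$values[2]
      idx <- which(sel)
      for (k in seq_along(idx)) {
        t3 <- ax[k, ]
        D6 <- c(l_perp + (l_par - l_perp) * t3[1]^2,
                (l_par - l_perp) * t3[1] * t3[2],
                (l_par - l_perp) * t3[1] * t3[3],
                l_perp + (l_par - l_perp) * t3[2]^2,
                (l_par - l_perp) * t3[2] * t3[3],
                l_perp + (l_par - l_perp) * t3[3]^2)
        tmap[idx[k], ] <- D6
      }
    } else {
      tmap[sel, ] <- rep(tensor_to_vec6(comp[[nm]]$Dstar),
                         each = sum(sel))
    }
  }

  structure(list(
    label_map = matrix(lab, g$nx, g$ny),
    tensor_map = array(tmap, c(g$nx, g$ny, 6)),
    tangent_map = array(tangent, c(g$nx, g$ny, 3)),
    labels = PHANTOM_LABELS, spec = spec
  ), class = "ground_truth")
}

#' Apply a physiological scenario to the ground truth
#'
#' * `pulsation`: PVS leading eigenvalue multiplied by `pulsation_gain`
#'   relative to diastole (default 4.0, i.e. ~300% greater during
#'   arterial pulsation).
#' * `dobutamine`: PVS leading eigenvalue multiplied by
#'   `dobutamine_gain` relative to baseline (default 1.65).
#' * `postmortem`: all fluid-compartment tensors (subarachnoid, PVS,
#'   ventricle) scaled by `postmortem_factor`.
#' * `baseline` / `diastole`: unchanged.
#'
#' @param gt a `ground_truth` from [build_geometry()].
#' @param spec the [phantom_spec()] carrying the scenario and gains.
#' @return Modified `ground_truth`.
#' @export
apply_scenario <- function(gt, spec) {
  stopifnot(inherits(gt, "ground_truth"), inherits(spec, "phantom_spec"))
  scenario <- match.arg(spec$scenario, PHANTOM_SCENARIOS)
  if (scenario %in% c("baseline", "diastole")) return(gt)
  nx <- dim(gt$tensor_map)[1]; ny <- dim(gt$tensor_map)[2]
  tmap <- matrix(gt$tensor_map, nx * ny, 6)
  lab <- as.vector(gt$label_map)
  if (scenario %in% c("pulsation", "dobutamine")) {
    gain <- if (scenario == "pulsation") spec$pulsation_gain
            else spec$dobutamine_gain
    idx <- which(lab == gt$labels[["pvs"]])
    for (k in idx) {
      es <- eig_sorted(vec6_to_tensor(tmap[k, ]))
      v1 <- es$vectors[, 1]
      D <- vec6_to_tensor(tmap[k, ]) +
        (gain - 1) * es$values[1] * tcrossprod(v1)
      tmap[k, ] <- tensor_to_vec6(D)
    }
  } else if (scenario == "postmortem") {
    fluid <- lab %in% gt$labels[c("subarachnoid", "pvs", "ventricle")]
    tmap[fluid, ] <- tmap[fluid, ] * spec$postmortem_factor
  }
  gt$tensor_map <- array(tmap, c(nx, ny, 6))
  gt
}

#' Add Rician noise to a signal array
#'
#' Magnitude-MRI noise: out = sqrt((x + n1)^2 + n2^2) with n1, n2 ~
#' N(0, sigma). Reproducible under `seed`; the caller's RNG state is
#' left untouched.
#'
#' @param data numeric array of noiseless signal.
#' @param sigma channel noise standard deviation (>= 0).
#' @param seed integer seed.
#' @return Array of the same shape.
#' @export
add_rician_noise <- function(data, sigma, seed) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (sigma == 0) return(data)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  n <- length(data)
  n1 <- stats::rnorm(n, 0, sigma)
  n2 <- stats::rnorm(n, 0, sigma)
  out <- sqrt((data + n1)^2 + n2^2)
  dim(out) <- dim(data)
  out
}

#' Noise sigma for a target b0 SNR in CSF-like fluid
#'
#' SNR is defined on the b0 image in the fluid compartments:
#' sigma = S0_eff(fluid) / SNR with S0_eff the T2-attenuated steady
#' state signal of the subarachnoid compartment.
#'
#' @param spec a [phantom_spec()].
#' @param params an [acq_params()].
#' @param snr target SNR (> 0).
#' @return sigma in signal units.
#' @export
sigma_for_b0_snr <- function(spec, params, snr) {
  stopifnot(snr > 0)
  csf <- spec$compartments$subarachnoid
  steady_state_scale(csf$S0, params$TR, params$TE_eff, csf$T2) / snr
}

#' 4D DWI volume container
#'
#' @param data 4D array (x, y, slices, volumes), non-negative.
#' @param bvals numeric vector, one b-value per volume, s/mm^2.
#' @param bvecs matrix of per-volume 3-vectors (zero rows for b0).
#' @param voxel_size_mm length-3 voxel size.
#' @param meta named list of provenance (seed, scenario, ...).
#' @return Object of class `dwi_volume`.
#' @export
dwi_volume <- function(data, bvals, bvecs, voxel_size_mm,
                       meta = list()) {
  data <- as.array(data)
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  stopifnot(length(dim(data)) == 4L)
  bvecs <- as.matrix(bvecs)
  if (length(bvals) != dim(data)[4] || nrow(bvecs) != dim(data)[4]) {
    stop("bvals/bvecs length must equal the number of volumes",
         call. = FALSE)
  }
  if (!any(bvals == 0)) stop("at least one b0 volume required",
                             call. = FALSE)
  if (any(data < 0)) stop("signal data must be non-negative", call. = FALSE)
  nrm <- sqrt(rowSums(bvecs^2))
  if (any(bvals > 0 & abs(nrm - 1) > 1e-6)) {
    stop("diffusion-weighted bvecs must be unit-norm", call. = FALSE)
  }
  structure(list(data = data, bvals = as.numeric(bvals), bvecs = bvecs,
                 voxel_size_mm = voxel_size_mm, meta = meta),
            class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("DWI volume: %d x %d x %d, %d volumes (%d b0), b = %s\n",
              d[1], d[2], d[3], d[4], sum(x$bvals == 0),
              paste(unique(x$bvals), collapse = "/")))
  invisible(x)
}

#' Render a DWI volume from the phantom ground truth
#'
#' Each voxel's noiseless signal is the T2/TR-scaled equilibrium signal
#' of its compartment times exp(-b g' D g) with the voxel's ground-truth
#' tensor; one b0 volume is prepended. Rician noise with
#' `spec$noise_sigma` and `spec$seed` is applied at the end.
#'
#' @param gt `ground_truth` (scenario already applied).
#' @param params an [acq_params()]; its direction set and effective
#'   b-value define the volumes.
#' @param spec the [phantom_spec()].
#' @return A [dwi_volume()] with `1 + nrow(directions)` volumes.
#' @export
render_dwi <- function(gt, params, spec) {
  stopifnot(inherits(gt, "ground_truth"), inherits(params, "acq_params"))
  dirs <- params$directions
  if (nrow(dirs) == 0L) stop("directions must be non-empty", call. = FALSE)
  b <- acq_bvalue(params)
  nx <- dim(gt$tensor_map)[1]; ny <- dim(gt$tensor_map)[2]
  lab <- as.vector(gt$label_map)

  s0eff <- rep(0, nx * ny)
  for (nm in names(spec$compartments)) {
    cp <- spec$compartments[[nm]]
    sel <- lab == gt$labels[[nm]]
    s0eff[sel] <- steady_state_scale(cp$S0, params$TR, params$TE_eff, cp$T2)
  }

  tmap <- matrix(gt$tensor_map, nx * ny, 6)
  tmap[is.na(tmap)] <- 0
  nvol <- 1L + nrow(dirs)
  data <- array(0, c(nx, ny, 1, nvol))
  data[, , 1, 1] <- s0eff
  for (k in seq_len(nrow(dirs))) {
    gv <- dirs[k, ]
    q <- tmap[, 1] * gv[1]^2 + tmap[, 4] * gv[2]^2 + tmap[, 6] * gv[3]^2 +
      2 * (tmap[, 2] * gv[1] * gv[2] + tmap[, 3] * gv[1] * gv[3] +
             tmap[, 5] * gv[2] * gv[3])
    data[, , 1, k + 1] <- s0eff * exp(-b * q)
  }
  if (spec$noise_sigma > 0) {
    data <- add_rician_noise(data, spec$noise_sigma, spec$seed)
  }
  bvals <- c(0, rep(b, nrow(dirs)))
  bvecs <- rbind(c(0, 0, 0), dirs)
  vox <- c(spec$fov_mm / spec$matrix, spec$slice_thickness_mm)
  dwi_volume(data, bvals, bvecs, vox,
             meta = list(seed = spec$seed, scenario = spec$scenario,
                         noise_sigma = spec$noise_sigma))
}

#' One-call phantom simulation
#'
#' [build_geometry()] + [apply_scenario()] + [render_dwi()].
#'
#' @param spec a [phantom_spec()].
#' @param params an [acq_params()].
#' @return List with `dwi` ([dwi_volume()]) and `truth`
#'   (`ground_truth`).
#' @export
simulate_phantom <- function(spec = phantom_spec(),
                             params = acq_params()) {
  gt <- apply_scenario(build_geometry(spec), spec)
  list(dwi = render_dwi(gt, params, spec), truth = gt)
}
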