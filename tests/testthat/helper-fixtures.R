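# Shared fixtures. The default geometry is expensive enough (~1 s) to
# build once per test run and reuse; everything derived from it is
# deterministic.

.fixture_env <- new.env(parent = emptyenv())

default_truth <- function() {
  if (is.null(.fixture_env$truth)) {
    .fixture_env$truth <- build_geometry(phantom_spec())
  }
  .fixture_env$truth
}

default_params <- function() acq_params()

noiseless_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    spec <- phantom_spec()
    .fixture_env$sim <- list(
      dwi = render_dwi(default_truth(), default_params(), spec),
      spec = spec
    )
  }
  .fixture_env$sim
}

label_mask <- function(gt, name) gt$label_map == gt$labels[[name]]

# Unpack the 6-element map ordering (Dxx,Dxy,Dxz,Dyy,Dyz,Dzz).
vec6_to_tensor <- function(v) {
  matrix(c(v[1], v[2], v[3], v[2], v[4], v[5], v[3], v[5], v[6]), 3, 3)
}

# Random symmetric PSD tensor on the pseudo-diffusion scale (mm^2/s).
random_psd_tensor <- function(scale = 5e-3) {
  A <- matrix(stats::rnorm(9), 3, 3)
  Q <- qr.Q(qr(A))
  l <- sort(stats::runif(3, 0.05, 1), decreasing = TRUE) * scale
  Q %*% diag(l) %*% t(Q)
}

# Random rotation matrix (Haar via QR with sign fix).
random_rotation <- function() {
  A <- matrix(stats::rnorm(9), 3, 3)
  Q <- qr.Q(qr(A))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

random_unit_vec <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# Random full-rank direction set of n unit vectors (resampled until the
# 6-element design has rank 6).
random_direction_set <- function(n = 6L) {
  repeat {
    g <- t(replicate(n, random_unit_vec()))
    X <- t(apply(g, 1, function(v) {
      c(v[1]^2, 2 * v[1] * v[2], 2 * v[1] * v[3], v[2]^2,
        2 * v[2] * v[3], v[3]^2)
    }))
    if (qr(X)$rank == 6L) return(g)
  }
}

# Angle in degrees between two directions (sign-blind).
axis_angle_deg <- function(a, b) {
  acos(min(1, abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2)))) * 180 / pi
}

# ROI-mean leading eigenvalue of a fitted scenario phantom; used by the
# scenario-contrast tests.
fitted_pvs_lambda1 <- function(scenario, seed, sigma, mask) {
  spec <- phantom_spec(scenario = scenario, noise_sigma = sigma,
                       seed = seed)
  sim <- simulate_phantom(spec, default_params())
  fit <- fit_dti(sim$dwi, mask = mask)
  roi_mean(fit$eigenvalues[, , 1], mask)
}
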