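# Digital ventral-slice phantom: geometry, ground-truth tensors,
# physiological scenarios, Rician noise, rendering.

test_that("default geometry contains all six compartments", {
  gt <- default_truth()
  expect_setequal(unique(as.vector(gt$label_map)), 0:5)
  # perivascular tracts flank vessels without touching the lumen
  expect_gt(sum(label_mask(gt, "pvs")), 100)
  expect_gt(sum(label_mask(gt, "blood")), 50)
})

test_that("PVS ground-truth tensors are aligned with the vessel tangent", {
  gt <- default_truth()
  idx <- which(label_mask(gt, "pvs"), arr.ind = TRUE)
  for (k in sample(nrow(idx), 40)) {
    i <- idx[k, 1]; j <- idx[k, 2]
    D <- vec6_to_tensor(gt$tensor_map[i, j, ])
    v1 <- eig_sorted(D)$vectors[, 1]
    expect_lt(axis_angle_deg(v1, gt$tangent_map[i, j, ]), 1e-6)
  }
})

test_that("ground-truth tensors reproduce the target FA and MD", {
  gt <- default_truth()
  for (case in list(list("pvs", 0.44, 0.0042),
                    list("subarachnoid", 0.60, 0.0065))) {
    idx <- which(label_mask(gt, case[[1]]), arr.ind = TRUE)
    i <- idx[1, 1]; j <- idx[1, 2]
    l <- eig_sorted(vec6_to_tensor(gt$tensor_map[i, j, ]))$values
    expect_equal(fractional_anisotropy(l), case[[2]], tolerance = 1e-10)
    expect_equal(mean_diffusivity(l), case[[3]], tolerance = 1e-10)
  }
  # subarachnoid principal axis is caudal-rostral (+y)
  idx <- which(label_mask(gt, "subarachnoid"), arr.ind = TRUE)
  l1 <- eig_sorted(vec6_to_tensor(
    gt$tensor_map[idx[1, 1], idx[1, 2], ]))$vectors[, 1]
  expect_lt(axis_angle_deg(l1, c(0, 1, 0)), 1e-6)
})

test_that("scenarios rescale the ground truth as specified", {
  gt <- default_truth()
  pvs_idx <- which(label_mask(gt, "pvs"), arr.ind = TRUE)[1, ]
  l1_of <- function(g) {
    eig_sorted(vec6_to_tensor(g$tensor_map[pvs_idx[1], pvs_idx[2], ]))$values[1]
  }
  base <- l1_of(gt)

  same <- apply_scenario(gt, phantom_spec(scenario = "baseline"))
  expect_identical(same$tensor_map, gt$tensor_map)
  dia <- apply_scenario(gt, phantom_spec(scenario = "diastole"))
  expect_identical(dia$tensor_map, gt$tensor_map)

  puls <- apply_scenario(gt, phantom_spec(scenario = "pulsation"))
  expect_equal(l1_of(puls) / base, 4.0, tolerance = 1e-10)
  # i.e. 300% greater during pulsation than diastole
  expect_equal(percent_change(base, l1_of(puls)), 300, tolerance = 1e-8)

  dob <- apply_scenario(gt, phantom_spec(scenario = "dobutamine"))
  expect_equal(l1_of(dob) / base, 1.65, tolerance = 1e-10)

  pm <- apply_scenario(gt, phantom_spec(scenario = "postmortem"))
  expect_equal(l1_of(pm) / base, 0.1, tolerance = 1e-10)
  # non-fluid compartments untouched post mortem
  par_idx <- which(label_mask(gt, "parenchyma"), arr.ind = TRUE)[1, ]
  expect_identical(pm$tensor_map[par_idx[1], par_idx[2], ],
                   gt$tensor_map[par_idx[1], par_idx[2], ])

  expect_error(phantom_spec(scenario = "systole"), "arg")
  expect_error(phantom_spec(pulsation_gain = 0), "gains")
  expect_error(phantom_spec(pvs_halfwidth_mm = 0), "degenerate")
})

test_that("Rician noise is reproducible, seed-isolated and unbiased", {
  x <- matrix(runif(100), 10, 10)
  expect_identical(add_rician_noise(x, 0, 1), x)
  a <- add_rician_noise(x, 0.5, 42)
  b <- add_rician_noise(x, 0.5, 42)
  expect_identical(a, b)
  expect_false(identical(a, add_rician_noise(x, 0.5, 43)))

  # zero signal: Rayleigh mean sigma * sqrt(pi/2)
  z <- add_rician_noise(rep(0, 2e5), 2, 7)
  expect_equal(mean(z), 2 * sqrt(pi / 2), tolerance = 0.01)

  # caller's RNG stream is untouched
  set.seed(99); r1 <- rnorm(3)
  set.seed(99); invisible(add_rician_noise(x, 1, 5)); r2 <- rnorm(3)
  expect_identical(r1, r2)
  expect_error(add_rician_noise(x, -1, 1), "sigma")
})

test_that("rendering reproduces the compartment attenuation design", {
  sim <- noiseless_sim()
  gt <- default_truth()
  b0 <- sim$dwi$data[, , 1, 1]
  s0 <- 100
  expect_equal(b0[label_mask(gt, "pvs")][1] / s0, 0.278, tolerance = 1e-2)
  expect_equal(b0[label_mask(gt, "subarachnoid")][1] / s0, 0.278,
               tolerance = 1e-2)
  expect_equal(b0[label_mask(gt, "parenchyma")][1] / s0, 0.024,
               tolerance = 1e-2)
  expect_equal(b0[label_mask(gt, "blood")][1] / s0, 0.009,
               tolerance = 1e-2)
  # CSF-like > parenchyma > blood ordering
  expect_gt(b0[label_mask(gt, "pvs")][1], b0[label_mask(gt, "parenchyma")][1])
  expect_gt(b0[label_mask(gt, "parenchyma")][1], b0[label_mask(gt, "blood")][1])
  expect_equal(dim(sim$dwi$data)[4], 1 + nrow(default_params()$directions))
})

test_that("b0 volume does not depend on the direction set", {
  gt <- default_truth()
  spec <- phantom_spec()
  d1 <- render_dwi(gt, acq_params(directions = rbind(c(1, 0, 0))), spec)
  d2 <- render_dwi(gt, acq_params(directions = rbind(c(0, 1, 0),
                                                     c(0, 0, 1))), spec)
  expect_identical(d1$data[, , 1, 1], d2$data[, , 1, 1])
})

test_that("signal is lower with the gradient parallel to the tract", {
  gt <- default_truth()
  spec <- phantom_spec()
  idx <- which(label_mask(gt, "pvs"), arr.ind = TRUE)
  i <- idx[1, 1]; j <- idx[1, 2]
  tang <- gt$tangent_map[i, j, ]
  perp <- c(-tang[2], tang[1], 0)
  dwi <- render_dwi(gt, acq_params(directions = rbind(tang, perp)), spec)
  expect_lt(dwi$data[i, j, 1, 2], dwi$data[i, j, 1, 3])
})

test_that("identical spec and seed give a bit-identical volume", {
  spec <- phantom_spec(noise_sigma = 0.5, seed = 123,
                       matrix = c(48L, 48L))
  p <- acq_params()
  a <- simulate_phantom(spec, p)
  b <- simulate_phantom(spec, p)
  expect_identical(a$dwi$data, b$dwi$data)
  expect_identical(a$truth$tensor_map, b$truth$tensor_map)
})

test_that("scenario ordering of ground-truth parallel diffusivity holds", {
  gt <- default_truth()
  mean_l1 <- function(scen) {
    g <- apply_scenario(gt, phantom_spec(scenario = scen))
    idx <- which(label_mask(g, "pvs"))
    tm <- matrix(g$tensor_map, ncol = 6)
    mean(vapply(idx, function(k) {
      eig_sorted(vec6_to_tensor(tm[k, ]))$values[1]
    }, 1))
  }
  l <- vapply(c("pulsation", "baseline", "diastole", "postmortem"),
              mean_l1, 1)
  expect_gt(l[["pulsation"]], l[["baseline"]])
  expect_equal(l[["baseline"]], l[["diastole"]])
  expect_lt(l[["postmortem"]], min(l[1:3]))
})

test_that("dwi_volume validates its contract", {
  d <- array(1, c(4, 4, 1, 2))
  expect_error(dwi_volume(d, c(0, 107, 107), rbind(0, c(1, 0, 0))),
               "volumes")
  expect_error(dwi_volume(d, c(107, 107),
                          rbind(c(1, 0, 0), c(1, 0, 0))), "b0")
  expect_error(dwi_volume(d, c(0, 107), rbind(c(0, 0, 0), c(1, 1, 0))),
               "unit-norm")
  expect_error(dwi_volume(d - 2, c(0, 107),
                          rbind(c(0, 0, 0), c(1, 0, 0))), "non-negative")
})
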