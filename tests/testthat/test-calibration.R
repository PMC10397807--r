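test_that("seed models are deterministic, distinct and folded", {
  sys <- tiny_system()
  cfg <- fit_config(seed = 42, timestep = 0.02)
  seeds <- generate_seed_models(sys$model, sys$topology, n_seeds = 7,
                                config = cfg, spacing = 1)
  expect_length(seeds, 7L)
  seeds2 <- generate_seed_models(sys$model, sys$topology, n_seeds = 7,
                                 config = cfg, spacing = 1)
  expect_identical(lapply(seeds, `[[`, "coords"),
                   lapply(seeds2, `[[`, "coords"))
  prs <- utils::combn(7, 2)
  for (c in seq_len(ncol(prs)))
    expect_gt(rmsd(seeds[[prs[1, c]]], seeds[[prs[2, c]]]), 0)
  # thermal snapshots stay folded: modest stereo score, near the reference
  for (s in seeds) {
    expect_lt(stereo_score(s, sys$topology)$total, 3)
    expect_lt(rmsd(s, sys$model), 2)
  }
  expect_error(generate_seed_models(sys$model, sys$topology, n_seeds = 1,
                                    config = cfg), ">= 2")
})

test_that("a degenerate one-pixel grid selects that pixel", {
  sys <- tiny_system()
  cfg <- fit_config(seed = 5, timestep = 0.02, max_time = 4,
                    temperature = 0, k_start = 500, tau = 1e6, k_cap = 1e7)
  seeds <- generate_seed_models(sys$model, sys$topology, n_seeds = 2,
                                config = fit_config(seed = 5,
                                                    timestep = 0.02),
                                spacing = 1)
  cal <- run_pixel_scan(seeds, sys$topology, sys$maps$full,
                        pixel_grid = 0.86, config = cfg)
  expect_equal(cal$selected_pixel, 0.86)
  expect_equal(dim(cal$scores), c(2L, 1L))
  expect_equal(cal$n_runs, 2L)
  tab <- as.data.frame(cal)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$pixel_size, 0.86)
})

test_that("the scan schedule enumerates every seed x pixel combination", {
  sys <- tiny_system()
  cfg <- fit_config(seed = 1)
  seeds <- rep(list(sys$model), 3)
  sched <- run_pixel_scan(seeds, sys$topology, sys$maps$full,
                          pixel_grid = c(0.80, 0.82, 0.84, 0.86),
                          config = cfg, dry_run = TRUE)
  expect_equal(nrow(sched), 12L)
  expect_equal(sort(unique(sched$seed_index)), 1:3)
  expect_equal(sort(unique(sched$pixel_size)), c(0.80, 0.82, 0.84, 0.86))
  expect_false(any(duplicated(sched[c("seed_index", "pixel_size")])))
  expect_equal(anyDuplicated(sched$run_seed), 0L)
})

test_that("rg diagnostic is identity for the reference trajectory", {
  sys <- tiny_system()
  coords <- replicate(4, sys$model$coords, simplify = FALSE)
  traj <- fake_trajectory(c(0.5, 0.6, 0.7, 0.7), rep(1, 4),
                          coords_list = coords, model = sys$model)
  rg <- rg_diagnostic(traj, sys$model)
  expect_true(all(abs(rg$ratios - 1) < 1e-12))
  expect_equal(dim(rg$ratios), c(4L, 3L))
})

test_that("rg diagnostic composes rg_about_axis frame by frame", {
  sys <- tiny_system()
  set.seed(71)
  coords <- lapply(1:3, function(i)
    sys$model$coords + matrix(rnorm(3 * n_atoms(sys$model), sd = 0.3),
                              n_atoms(sys$model), 3))
  traj <- fake_trajectory(c(0.5, 0.6, 0.7), rep(1, 3),
                          coords_list = coords, model = sys$model)
  normal <- c(0.2, -0.3, 0.93)
  rg <- rg_diagnostic(traj, sys$model, membrane_normal = normal)
  for (fr in 1:3) for (axi in 1:3) {
    m <- denfit:::set_coords(sys$model, coords[[fr]])
    expect_equal(unname(rg$ratios[fr, axi]),
                 rg_about_axis(m, rg$axes[axi, ]) /
                   rg_about_axis(sys$model, rg$axes[axi, ]),
                 tolerance = 1e-12)
  }
  # frame axes: orthonormal, right-handed, third along the normal
  expect_equal(unname(rg$axes %*% t(rg$axes)), diag(3), tolerance = 1e-12)
  expect_equal(det(rg$axes), 1, tolerance = 1e-12)
  expect_equal(as.vector(rg$axes[3, ]), normal / sqrt(sum(normal^2)),
               tolerance = 1e-12)
})

test_that("uniformly scaled models give rg ratios exactly s on every axis", {
  sys <- tiny_system()
  s <- 1.034
  com <- center_of_mass(sys$model)
  scaled <- denfit:::set_coords(sys$model,
                                sweep(sweep(sys$model$coords, 2, com) * s,
                                      2, com, "+"))
  traj <- fake_trajectory(c(0.5, 0.6, 0.6), rep(1, 3),
                          coords_list = list(sys$model$coords,
                                             scaled$coords, scaled$coords),
                          model = sys$model)
  rg <- rg_diagnostic(traj, sys$model)
  expect_equal(unname(rg$ratios[2, ]), rep(s, 3), tolerance = 1e-12)
  expect_equal(unname(rg$ratios[1, ]), rep(1, 3), tolerance = 1e-12)
})

test_that("rg diagnostic rejects mismatched models", {
  sys <- tiny_system()
  coords <- list(sys$model$coords)
  traj <- fake_trajectory(0.5, 1, coords_list = coords, model = sys$model)
  small <- denfit:::subset_atoms(sys$model, 1:10)
  expect_error(rg_diagnostic(traj, small), "atom counts")
})
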