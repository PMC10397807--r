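test_that("adaptive force scaling follows its closed form", {
  cfg <- fit_config(seed = 1, k_start = 10, tau = 4, feedback_interval = 4,
                    k_cap = 1e8)
  # flat similarity over one interval of length tau: k grows by e
  expect_equal(adaptive_force_update(10, 0.5, 0.5, cfg), 10 * exp(1),
               tolerance = 1e-12)
  # improvement shrinks k, never to zero or below
  k <- 10
  for (i in 1:50) {
    k2 <- adaptive_force_update(k, 0.5 + i * 1e-3, 0.5 + (i - 1) * 1e-3,
                                cfg)
    expect_lt(k2, k)
    expect_gt(k2, 0)
    k <- k2
  }
  # n stalled updates equal k_start * exp(n dt/tau) until the cap
  cfg2 <- fit_config(seed = 1, k_start = 10, tau = 4, feedback_interval = 2,
                     k_cap = 1e6)
  k <- 10
  for (n in 1:20) {
    k <- adaptive_force_update(k, 0.3, 0.3, cfg2)
    expect_equal(k, min(10 * exp(n * 2 / 4), 1e6), tolerance = 1e-12)
  }
})

test_that("fit_config validates its invariants", {
  expect_error(fit_config(), "required")
  expect_error(fit_config(seed = 1, k_start = 0), "k_start")
  expect_error(fit_config(seed = 1, k_cap = 5, k_start = 10), "k_cap")
  expect_error(fit_config(seed = 1, tau = -1), "tau")
  expect_error(fit_config(seed = 1, timestep = 0), "timestep")
  cfg <- fit_config(seed = 7)
  expect_equal(cfg$k_start, 10)
  expect_equal(cfg$tau, 4)
  expect_equal(cfg$eval_stride, 2)
  expect_equal(cfg$temperature, 300)
  expect_equal(cfg$resolution_threshold, 2.88)
  expect_equal(cfg$max_time, 3000)
})

test_that("alignment is a fixed point for an already-optimal model", {
  blob <- rand_blob()
  tgt <- normalize_map(model_to_map(blob, blob_grid()))
  ali <- rigid_body_align(blob, tgt)
  expect_lt(rotation_angle_deg(ali$rotation), 0.5)
  expect_lt(sqrt(sum(ali$translation^2)), 0.1)
  expect_equal(ali$cc, ali$cc_initial, tolerance = 1e-6)
})

test_that("local alignment recovers a small displacement", {
  blob <- rand_blob()
  tgt <- normalize_map(model_to_map(blob, blob_grid()))
  moved <- translate_model(blob, c(1.2, -0.8, 0.5))
  ali <- rigid_body_align(moved, tgt, global = FALSE)
  expect_lt(rmsd(ali$model, blob), 0.2)
  expect_gt(ali$cc, ali$cc_initial)
})

test_that("alignment fails loudly when model and map cannot overlap", {
  blob <- rand_blob()
  tgt <- normalize_map(model_to_map(blob, blob_grid()))
  far <- translate_model(blob, c(500, 500, 500))
  expect_error(rigid_body_align(far, tgt, global = FALSE), "overlap")
})

test_that("a fit started at the optimum stays there (noiseless)", {
  sys <- tiny_system()
  g <- density_map(array(0, rep(32, 3)), sys$spec$pixel_size)
  self_target <- normalize_map(model_to_map(sys$model, g))
  cfg <- fit_config(seed = 3, temperature = 0, timestep = 0.02,
                    max_time = 8)
  traj <- run_fit(sys$model, sys$topology, self_target, cfg)
  tab <- as.data.frame(traj)
  expect_gte(tab$similarity[nrow(tab)] + 1e-12, tab$similarity[1])
  expect_gte(tab$similarity[1], 0.999)
  drift <- rmsd(frame_model(traj, length(traj$frames)), sys$model)
  expect_lt(drift, 0.5)
})

test_that("fits are bitwise reproducible from the config seed", {
  sys <- tiny_system()
  cfg <- fit_config(seed = 17, timestep = 0.02, max_time = 6)
  start <- perturb_model(sys$model, 1.5, seed = 2)
  t1 <- run_fit(start, sys$topology, sys$target, cfg)
  t2 <- run_fit(start, sys$topology, sys$target, cfg)
  expect_identical(lapply(t1$frames, `[[`, "coords"),
                   lapply(t2$frames, `[[`, "coords"))
  t3 <- run_fit(start, sys$topology, sys$target,
                fit_config(seed = 18, timestep = 0.02, max_time = 6))
  expect_false(identical(t1$frames[[2]]$coords, t3$frames[[2]]$coords))
})

test_that("log k changes by exactly +-dt_fb/tau per feedback interval", {
  sys <- tiny_system()
  cfg <- fit_config(seed = 9, timestep = 0.02, max_time = 8,
                    feedback_interval = 2, tau = 4)
  start <- perturb_model(sys$model, 1.5, seed = 3)
  traj <- run_fit(start, sys$topology, sys$target, cfg)
  k <- vapply(traj$frames, `[[`, numeric(1), "k")
  steps <- diff(log(k))
  steps <- steps[abs(steps) > 1e-12]  # frames recorded every interval here
  expect_true(all(abs(abs(steps) - 2 / 4) < 1e-9))
})

test_that("similarity at termination beats the start for perturbed fits", {
  sys <- tiny_system()
  ok <- vapply(1:5, function(s) {
    start <- perturb_model(sys$model, 2, seed = 200 + s)
    cfg <- fit_config(seed = s, timestep = 0.02, max_time = 10)
    tab <- as.data.frame(run_fit(start, sys$topology, sys$target, cfg))
    tab$similarity[nrow(tab)] >= tab$similarity[1]
  }, logical(1))
  expect_true(all(ok))
})

test_that("absurd force constants terminate as force blow-up", {
  sys <- tiny_system()
  cfg <- fit_config(seed = 4, timestep = 0.5, max_time = 50,
                    k_start = 5e5, k_cap = 1e6, temperature = 0)
  traj <- run_fit(perturb_model(sys$model, 2, seed = 1), sys$topology,
                  sys$target, cfg)
  expect_true(traj$termination_reason %in% c("force_blowup", "k_cap"))
  expect_gte(length(traj$frames), 1L)
})

test_that("trajectories export as a multi-model PDB plus a metric log", {
  sys <- tiny_system()
  cfg <- fit_config(seed = 2, timestep = 0.02, max_time = 4)
  traj <- run_fit(sys$model, sys$topology, sys$target, cfg)
  pdb <- tempfile(fileext = ".pdb")
  log <- tempfile(fileext = ".tsv")
  write_trajectory(traj, pdb_path = pdb, log_path = log)
  lines <- readLines(pdb)
  expect_equal(sum(grepl("^MODEL", lines)), length(traj$frames))
  expect_equal(sum(grepl("^ENDMDL", lines)), length(traj$frames))
  expect_equal(sum(grepl("^ATOM", lines)),
               length(traj$frames) * n_atoms(sys$model))
  tab <- utils::read.delim(log)
  expect_equal(nrow(tab), length(traj$frames))
  expect_equal(tab$k, vapply(traj$frames, `[[`, numeric(1), "k"))
})

test_that("minimization relaxes a stretched bond to its reference length", {
  m <- atomic_model(rbind(c(0, 0, 0), c(1.5, 0, 0)), "C")
  topo <- build_topology(m, bond_cutoff = 1.8)
  m2 <- denfit:::set_coords(m, rbind(c(0, 0, 0), c(1.6, 0, 0)))
  out <- energy_minimize(m2, topo, restrain_heavy = FALSE,
                         force_tol = 1e-6)
  d <- sqrt(sum((out$coords[1, ] - out$coords[2, ])^2))
  expect_equal(d, 1.5, tolerance = 1e-4)
  expect_lt(attr(out, "max_force"), 1e-6)
})

test_that("restrained minimization respects the strain-energy bound", {
  sys <- tiny_system()
  start <- perturb_model(sys$model, 0.8, seed = 6)
  ra <- denfit:::restraint_args(start, sys$topology)
  e0 <- denfit:::restraint_forces(start$coords, ra)$energy
  k_pos <- 1000
  out <- energy_minimize(start, sys$topology, restrain_heavy = TRUE,
                         k_pos = k_pos, force_tol = 1e-3)
  moved <- sqrt(rowSums((out$coords - start$coords)^2))
  expect_lt(max(moved), sqrt(2 * e0 / k_pos))
})

test_that("minimization never worsens the stereo score on clash-free input", {
  sys <- tiny_system()
  start <- perturb_model(sys$model, 1.0, seed = 8)
  sc0 <- stereo_score(start, sys$topology)
  out <- energy_minimize(start, sys$topology, restrain_heavy = FALSE,
                         force_tol = 1e-3)
  sc1 <- stereo_score(out, sys$topology)
  expect_lte(sc1$total, sc0$total + 1e-9)
})
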