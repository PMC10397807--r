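# Shared fixtures: a small barrel system (cached; every test that mutates it
# must copy), random blobs, and rotation helpers.

.fixture_cache <- new.env(parent = emptyenv())

tiny_spec <- function(...) {
  fixture_spec(n_strands = 6, strand_length = 6, radius = 6, box = 32, ...)
}

# barrel + topology + maps at the default 0.86 A/pixel, built once
tiny_system <- function() {
  if (is.null(.fixture_cache$sys)) {
    spec <- tiny_spec()
    sys <- make_toy_barrel(spec)
    sys$spec <- spec
    sys$maps <- make_target_maps(sys$model, spec)
    sys$target <- normalize_map(sys$maps$full)
    .fixture_cache$sys <- sys
  }
  .fixture_cache$sys
}

# asymmetric blob centred in a 32^3, 0.86 A/pixel box
rand_blob <- function(n = 20, seed = 99, sd = 4) {
  set.seed(seed)
  atomic_model(matrix(rnorm(3 * n, sd = sd), n, 3) + 0.86 * 32 / 2, "C")
}

blob_grid <- function() density_map(array(0, rep(32, 3)), 0.86)

set_coords_ <- function(model, coords) denfit:::set_coords(model, coords)

rotation_angle_deg <- function(R) {
  acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

rotate_about_com <- function(model, R) {
  com <- center_of_mass(model)
  set_coords_(model, sweep(sweep(model$coords, 2, com) %*% t(R), 2, com,
                           "+"))
}

translate_model <- function(model, t) {
  set_coords_(model, sweep(model$coords, 2, t, "+"))
}

# minimal hand-built trajectory carrying just fsc_avg/quality/time
fake_trajectory <- function(fsc_avg, quality, coords_list = NULL,
                            model = NULL) {
  frames <- lapply(seq_along(fsc_avg), function(i) {
    list(time = 2 * (i - 1),
         coords = if (is.null(coords_list)) NULL else coords_list[[i]],
         similarity = NA_real_, fsc_avg = fsc_avg[i], quality = quality[i],
         k = 10)
  })
  structure(list(frames = frames, config = NULL,
                 termination_reason = "max_time", model = model),
            class = "fit_trajectory")
}
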