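test_that("cross-correlation identities and the textbook-formula oracle", {
  set.seed(41)
  a <- density_map(array(rnorm(16^3), rep(16, 3)), 1)
  b <- density_map(array(rnorm(16^3), rep(16, 3)), 1)
  expect_equal(cross_correlation(a, a), 1, tolerance = 1e-12)
  neg <- a; neg$grid <- -a$grid
  expect_equal(cross_correlation(a, neg), -1, tolerance = 1e-12)
  va <- as.vector(a$grid); vb <- as.vector(b$grid)
  oracle <- mean((va - mean(va)) * (vb - mean(vb))) /
    sqrt(mean((va - mean(va))^2) * mean((vb - mean(vb))^2))
  expect_equal(cross_correlation(a, b), oracle, tolerance = 1e-12)
  small <- density_map(array(rnorm(8^3), rep(8, 3)), 1)
  expect_error(cross_correlation(a, small), "shapes")
  flat <- density_map(array(1, rep(16, 3)), 1)
  expect_error(cross_correlation(a, flat), "constant")
})

test_that("FSC is 1 for identical maps and -1 for sign-flipped maps", {
  set.seed(42)
  m <- density_map(array(rnorm(24^3, mean = 1), rep(24, 3)), 0.9)
  cv <- fsc_curve(m, m)
  expect_true(all(abs(cv$fsc - 1) < 1e-9, na.rm = TRUE))
  expect_false(anyNA(cv$fsc))  # nonzero mean: even the DC shell has power
  expect_true(all(diff(cv$shell_freq) > 0))
  expect_equal(cv$shell_freq[1], 0)
  neg <- m; neg$grid <- -m$grid
  expect_true(all(abs(fsc_curve(m, neg)$fsc + 1) < 1e-9, na.rm = TRUE))
})

test_that("independent noise maps decorrelate in every shell", {
  set.seed(43)
  a <- density_map(array(rnorm(64^3), rep(64, 3)), 1)
  b <- density_map(array(rnorm(64^3), rep(64, 3)), 1)
  cv <- fsc_curve(a, b)
  expect_true(all(abs(cv$fsc) <= 1 + 1e-9, na.rm = TRUE))
  expect_lt(abs(mean(cv$fsc, na.rm = TRUE)), 0.1)
})

test_that("FSC requires compatible cubic grids", {
  a <- density_map(array(rnorm(8 * 8 * 12), c(8, 8, 12)), 1)
  expect_error(fsc_curve(a, a), "cubic")
  b <- density_map(array(rnorm(8^3), rep(8, 3)), 1)
  b2 <- density_map(array(rnorm(8^3), rep(8, 3)), 1.5)
  expect_error(fsc_curve(b, b2), "voxel")
})

test_that("fsc_average is the hand-summed mean over included shells", {
  curve <- data.frame(shell_freq = c(0, 0.1, 0.2, 0.3),
                      fsc = c(1, 1, 0, 0), n_voxels = c(1, 10, 20, 30))
  class(curve) <- c("fsc_curve", "data.frame")
  attr(curve, "nyquist") <- 0.5
  expect_equal(fsc_average(curve, resolution_threshold = 1 / 0.15), 1)
  expect_equal(fsc_average(curve, resolution_threshold = 1 / 0.3), 0.5)
  set.seed(44)
  curve$fsc <- runif(4, -1, 1)
  expect_equal(fsc_average(curve, 1 / 0.3), mean(curve$fsc))
  expect_error(fsc_average(curve, 1 / 0.6), "Nyquist")
  # identical maps average to 1 at any admissible threshold
  m <- density_map(array(rnorm(16^3, mean = 2), rep(16, 3)), 0.86)
  expect_equal(fsc_average(fsc_curve(m, m), 2.88), 1, tolerance = 1e-9)
})

test_that("fsc_average is invariant to positive rescaling of either map", {
  set.seed(45)
  sys <- tiny_system()
  a <- model_to_map(sys$model, sys$target)
  b <- sys$maps$full
  s1 <- fsc_average(fsc_curve(a, b), 2.88)
  a2 <- a; a2$grid <- 4.2 * a$grid
  b2 <- b; b2$grid <- 0.3 * b$grid
  expect_equal(fsc_average(fsc_curve(a2, b2), 2.88), s1, tolerance = 1e-10)
})

test_that("local quality is zero when model matches and halves agree", {
  set.seed(46)
  g <- array(rnorm(32^3), rep(32, 3))
  m <- density_map(g, 0.86)
  sys <- tiny_system()
  lq <- local_quality(m, m, m, m, window = 7, model = sys$model)
  expect_true(all(lq$q == 0))
  expect_equal(lq$mean_q, 0)
  expect_equal(lq$frac_above, 0)
  expect_equal(lq$frac_below, 0)
})

test_that("a model of pure noise scores negative local quality", {
  set.seed(47)
  full <- density_map(array(rnorm(32^3), rep(32, 3)), 0.86)
  noise <- density_map(array(rnorm(32^3), rep(32, 3)), 0.86)
  sys <- tiny_system()
  lq <- local_quality(noise, full, full, full, window = 9,
                      model = sys$model)
  expect_lt(lq$mean_q, 0)
})

test_that("banded fractions match a sliding-window recomputation", {
  set.seed(48)
  sys <- tiny_system()
  signal <- model_to_map(sys$model, sys$target)$grid
  noise_m <- array(rnorm(32^3, sd = 0.05), rep(32, 3))
  half1 <- density_map(signal + array(rnorm(32^3, sd = 0.05), rep(32, 3)), 0.86)
  half2 <- density_map(signal + array(rnorm(32^3, sd = 0.05), rep(32, 3)), 0.86)
  full <- density_map(signal + array(rnorm(32^3, sd = 0.035), rep(32, 3)), 0.86)
  # mosaic model map: follows the signal in the lower half of the box,
  # unrelated noise in the upper half
  mosaic <- signal
  mosaic[, , 17:32] <- noise_m[, , 17:32]
  model_map <- density_map(mosaic, 0.86)
  lq <- local_quality(model_map, full, half1, half2, window = 9,
                      model = sys$model)
  # oracle: reimplement the windowed score with independent code
  w <- 9L; h <- 4L
  oracle_q <- vapply(seq_len(nrow(lq$centers)), function(r) {
    ctr <- pmin(pmax(lq$centers[r, ], 1L + h), 32L - h)
    ix <- (ctr[1] - h):(ctr[1] + h)
    iy <- (ctr[2] - h):(ctr[2] + h)
    iz <- (ctr[3] - h):(ctr[3] + h)
    win_fsc <- function(ga, gb) {
      fa <- fft(ga[ix, iy, iz]); fb <- fft(gb[ix, iy, iz])
      ii <- c(0:(w %/% 2), -((w - 1) %/% 2):-1)
      rad <- round(sqrt(outer(outer(ii^2, ii^2, "+"), ii^2, "+")))
      keep <- rad <= w %/% 2
      vals <- vapply(0:(w %/% 2), function(s) {
        sel <- keep & rad == s
        num <- sum(Re(fa[sel] * Conj(fb[sel])))
        den <- sqrt(sum(Mod(fa[sel])^2) * sum(Mod(fb[sel])^2))
        if (den > 1e-14 * max(Mod(fa)^2)) num / den else NA_real_
      }, numeric(1))
      mean(vals[!is.na(vals)])
    }
    win_fsc(model_map$grid, full$grid) - win_fsc(half1$grid, half2$grid)
  }, numeric(1))
  expect_equal(lq$q, oracle_q, tolerance = 1e-9)
  expect_equal(lq$frac_above, mean(oracle_q > 0.5))
  expect_equal(lq$frac_below, mean(oracle_q < -0.5))
  # the mosaic separates: atoms in the noise half score worse
  upper <- sys$model$coords[, 3] > 0.86 * 16
  expect_gt(mean(lq$q[!upper]), mean(lq$q[upper]))
})

test_that("stereo score is zero at the reference geometry", {
  sys <- tiny_system()
  sc <- stereo_score(sys$model, sys$topology)
  expect_equal(sc$total, 0, tolerance = 1e-12)
  expect_equal(sc$bond_rms, 0, tolerance = 1e-12)
  expect_equal(sc$clash_per_1000, 0)
  # total is recomputable from components
  expect_equal(sc$total,
               sum(unlist(sc$weights) *
                     c(sc$bond_rms, sc$angle_rms, sc$clash_per_1000)))
})

test_that("a single stretched bond scores its deviation under unit weight", {
  m <- atomic_model(rbind(c(0, 0, 0), c(1.5, 0, 0)), "C")
  topo <- build_topology(m, bond_cutoff = 1.8)
  m2 <- denfit:::set_coords(m, rbind(c(0, 0, 0), c(1.6, 0, 0)))
  sc <- stereo_score(m2, topo, weights = c(1, 0, 0))
  expect_equal(sc$total, 0.1, tolerance = 1e-9)
})

test_that("clash counting matches a brute-force pair scan", {
  set.seed(49)
  n <- 100
  m <- atomic_model(matrix(runif(3 * n, 0, 14), n, 3), "C")
  topo <- build_topology(m, bond_cutoff = 1.9)
  sc <- stereo_score(m, topo)
  exkey <- if (nrow(topo$excluded_pairs))
    paste(topo$excluded_pairs[, 1], topo$excluded_pairs[, 2]) else character(0)
  cnt <- 0L
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((m$coords[i, ] - m$coords[j, ])^2))
    lim <- topo$repulsion_radius[i] + topo$repulsion_radius[j] - 0.4
    if (d < lim && !(paste(i, j) %in% exkey)) cnt <- cnt + 1L
  }
  expect_equal(sc$clash_per_1000, 1000 * cnt / n)
})

test_that("stereo score is invariant under rigid-body transforms", {
  sys <- tiny_system()
  start <- perturb_model(sys$model, 1, seed = 5)
  sc0 <- stereo_score(start, sys$topology)
  moved <- translate_model(rotate_about_com(start, rot_z(73)), c(4, -2, 9))
  sc1 <- stereo_score(moved, sys$topology)
  expect_equal(sc1$total, sc0$total, tolerance = 1e-9)
})

test_that("a missing external scorer raises the optional-dependency error", {
  sys <- tiny_system()
  f <- tempfile(fileext = ".pdb")
  write_model(sys$model, f)
  expect_error(external_goap(f, "/nonexistent/goap-binary"),
               class = "denfit_optional_dependency")
  expect_error(external_goap(f, "/nonexistent/goap-binary"),
               "optional dependency")
})

test_that("radius of gyration about an axis follows the definition", {
  m <- atomic_model(rbind(c(1, 0, 0), c(-1, 0, 0)), "C")
  m$coords <- m$coords  # unit masses not needed; equal masses suffice
  expect_equal(rg_about_axis(m, c(1, 0, 0)), 0, tolerance = 1e-12)
  expect_equal(rg_about_axis(m, c(0, 0, 1)), 1, tolerance = 1e-12)
  # homogeneity: scaling coordinates scales every axis Rg
  set.seed(50)
  r <- rand_blob(20, seed = 50)
  s <- 1.7
  rs <- denfit:::set_coords(r, r$coords * s)
  for (ax in list(c(1, 0, 0), c(0, 1, 1), c(1, 2, 3))) {
    expect_equal(rg_about_axis(rs, ax), s * rg_about_axis(r, ax),
                 tolerance = 1e-12)
    # direct-formula oracle
    u <- ax / sqrt(sum(ax^2))
    x <- sweep(r$coords, 2, colSums(r$coords * r$mass) / sum(r$mass))
    d2 <- rowSums(x^2) - as.vector(x %*% u)^2
    expect_equal(rg_about_axis(r, ax),
                 sqrt(sum(r$mass * d2) / sum(r$mass)), tolerance = 1e-12)
  }
  expect_error(rg_about_axis(r, c(0, 0, 0)), "nonzero")
})
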