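# Synthetic-data generators: determinism and ground-truth round-trips.

test_that("generators are deterministic given a seed", {
  sp <- trajectory_spec(N = 21, mu_deg = 40, kappa = 8, n_frames = 5, seed = 9)
  t1 <- make_poloidal_trajectory(sp)
  t2 <- make_poloidal_trajectory(sp)
  expect_identical(t1$truth_deg, t2$truth_deg)
  expect_identical(t1$trajectory$frames, t2$trajectory$frames)
  s1 <- random_afm_scene(2, 2, 2, image_px = 150, seed = 5)
  s2 <- random_afm_scene(2, 2, 2, image_px = 150, seed = 5)
  expect_identical(unclass(s1$image), unclass(s2$image))
  expect_identical(s1$truth, s2$truth)
  p1 <- make_position_series(noise_sd = 0.2, seed = 13)
  p2 <- make_position_series(noise_sd = 0.2, seed = 13)
  expect_identical(p1$series$value, p2$series$value)
  # generators do not disturb the caller's RNG stream
  set.seed(1); a <- runif(1)
  set.seed(1); invisible(make_poloidal_trajectory(sp)); b <- runif(1)
  expect_identical(a, b)
})

test_that("measured poloidal angles equal the drawn ground truth", {
  sp <- trajectory_spec(N = 105, mu_deg = 35.9, kappa = vonmises_kappa(18),
                        n_frames = 300, seed = 21)
  out <- make_poloidal_trajectory(sp)
  ser <- poloidal_series(out$trajectory, 0)
  expect_lt(max(abs(wrap_angle(ser$phi_deg - out$truth_deg))), 1e-3)
  # x column is consistent with the angles
  expect_true(all(abs(ser$x_A) <= 12))
  expect_gt(stats::cor(cos(ser$phi_deg * pi / 180), ser$x_A), 0.99)
})

test_that("degenerate and uniform concentrations behave as limits", {
  spd <- trajectory_spec(N = 105, mu_deg = 123, kappa = 1e8, n_frames = 40,
                         seed = 2)
  ser <- poloidal_series(make_poloidal_trajectory(spd)$trajectory, 0)
  expect_lt(max(abs(ser$phi_deg - 123)), 0.1)
  spu <- trajectory_spec(N = 105, mu_deg = 0, kappa = 0, n_frames = 5000,
                         seed = 3)
  seru <- poloidal_series(make_poloidal_trajectory(spu)$trajectory, 0)
  expect_lt(circular_mean_sd(seru$phi_deg)$rbar, 0.05)
})

test_that("bimodal mixtures produce two poloidal modes", {
  sp <- trajectory_spec(N = 105, mu_deg = 0, kappa = vonmises_kappa(10),
                        n_frames = 600, seed = 4,
                        mixture = list(mu2_deg = 120, weight2 = 0.5))
  out <- make_poloidal_trajectory(sp)
  h <- mean_centered_histogram(out$truth_deg, bins = 36)
  peaks <- h$mids[h$counts > 0.5 * max(h$counts)]
  expect_gt(diff(range(peaks)), 60)
})

test_that("afm scene ground truth matches the constructed geometry", {
  centred <- random_afm_scene(0, 0, 1, image_px = 120, pixel_nm = 0.5,
                              blob_offset_frac = 0, noise_sd = 0, seed = 7)
  expect_lt(centred$truth$true_delta_nm, 0.3)
  rim <- random_afm_scene(0, 0, 1, image_px = 120, pixel_nm = 0.5,
                          blob_offset_frac = 1, noise_sd = 0, seed = 7)
  expect_gt(rim$truth$true_delta_nm, 0.4)
  expect_false(any(rim$truth$overlap))
  # noiseless scene: the analysis pipeline recovers the composition exactly
  sc <- random_afm_scene(3, 4, 5, image_px = 300, noise_sd = 0, seed = 10)
  tab <- region_table(segment_molecules(sc$image, 0.35), sc$image,
                      default_afm_thresholds())
  expect_identical(as.integer(table(factor(tab$class,
    c("dna", "protein", "complex")))), c(3L, 4L, 5L))
  # overlapping molecules are flagged
  feats <- data.frame(molecule = c(1, 2), type = "blob",
                      x_nm = c(20, 22), y_nm = 20, height_nm = 4,
                      radius_nm = 1.2, width_nm = NA)
  expect_warning(out <- make_afm_scene(afm_scene_spec(80, 0.5, feats)),
                 "overlap")
  expect_true(all(out$truth$overlap))
})

test_that("position-series generator plants recoverable sinusoids", {
  clean <- make_position_series(amplitude = 1.4, peak_bp = 6.8, offset = 2,
                                noise_sd = 0)
  fit <- fit_fixed_period_sinusoid(clean$series)
  expect_equal(fit$peak_bp, 6.8, tolerance = 1e-9)
  expect_equal(fit$amplitude, 1.4, tolerance = 1e-9)
  a <- make_position_series(peak_bp = 1.3, noise_sd = 0, label = "a")
  b <- make_position_series(peak_bp = 6.8, noise_sd = 0, label = "b")
  lag <- phase_lag(fit_fixed_period_sinusoid(a$series),
                   fit_fixed_period_sinusoid(b$series))
  expect_equal(lag$lag_bp, 5.5, tolerance = 1e-9)
  expect_identical(lag$lag_deg_display, 189)
  noisy <- make_position_series(noise_sd = 0.2, n_replicates = 30, seed = 2)
  expect_true(all(noisy$series$sd > 0))
})

test_that("sequence series keep the core fixed and slide the marked dT", {
  ser <- make_sequence_series(seed = 6)
  expect_true(all(nchar(ser$sequence) == 105))
  expect_equal(diff(ser$tracked_nt), rep(2, 6))
  core <- attr(ser, "core")
  for (i in seq_len(nrow(ser))) {
    p <- ser$insert_position[i]
    rebuilt <- paste0(substr(ser$sequence[i], 1, p),
                      substr(ser$sequence[i], p + 21, 105))
    expect_identical(rebuilt, core)
    expect_identical(substr(ser$sequence[i], ser$tracked_nt[i] + 1,
                            ser$tracked_nt[i] + 1), "T")
  }
  f <- withr::local_tempfile(fileext = ".fa")
  write_sequence_series(ser, f)
  back <- Biostrings::readDNAStringSet(f)
  expect_identical(as.character(back[[3]]), ser$sequence[3])
})
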