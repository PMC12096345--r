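# Device simulator: absorbance composition, channel physics,
# auto-integration, scan assembly and the raw-scan text format.

test_that("total_absorbance is additive, linear, zero for blanks", {
  pool <- compound_pool()
  wl <- seq(200, 650, by = 25)

  expect_equal(total_absorbance(sample_spec(), wl), rep(0, length(wl)))

  s1 <- make_sample(diazepam = 0.3)
  s2 <- make_sample(diazepam = 0.6)
  expect_equal(total_absorbance(s2, wl), 2 * total_absorbance(s1, wl))

  # mixture equals the independently computed per-component sum at every
  # wavelength (oracle: evaluate epsilon curves directly)
  mix <- make_sample(diazepam = 0.3, caffeine = 0.8)
  oracle <- 1 * (pool$diazepam$absorption(wl) * 0.3 +
                 pool$caffeine$absorption(wl) * 0.8)
  expect_equal(total_absorbance(mix, wl), oracle, tolerance = 1e-12)
  expect_equal(total_absorbance(mix, wl),
               total_absorbance(s1, wl) + total_absorbance(make_sample(caffeine = 0.8), wl))

  expect_error(total_absorbance(s1, 120), "outside")
  expect_error(total_absorbance(s1, 700), "outside")
})

test_that("fluorophore invariants hold for the whole packaged pool", {
  pool <- compound_pool()
  grid <- seq(185, 655, by = 0.05)
  for (fl in pool) {
    eps <- fl$absorption(grid)
    expect_true(all(eps >= 0), info = fl$name)
    f <- fl$emission_profile(grid)
    area <- sum((f[-1] + f[-length(f)]) / 2 * diff(grid))
    expect_equal(area, 1, tolerance = 1e-6)
    # Stokes shift: emission mass redward of the absorption maximum
    expect_gt(sum(grid * f) / sum(f), grid[which.max(eps)])
  }
})

test_that("simulate_channel: blank gives the reflected line only", {
  cfg <- quiet_device()
  sp <- simulate_channel(sample_spec(), 4, cfg, integration_time = 100)
  axis <- cfg$emission_axis
  lam <- cfg$led_wavelengths[5]
  off_line <- abs(axis - lam) > 4 * cfg$led_bandwidth_fwhm
  expect_lt(max(sp$intensities[off_line]), 1e-6 * max(sp$intensities))
  expect_equal(axis[which.max(sp$intensities)], lam, tolerance = 0.5)
})

test_that("simulate_channel: noiseless blank peak is t*b*power*baseline", {
  cfg <- quiet_device(reflectance_path_factor = 3.7)  # k_r irrelevant at c=0
  sp <- simulate_channel(sample_spec(solvent_baseline = 0.77), 0, cfg,
                         integration_time = 50, brightness = 0.5)
  # LED centre coincides with an axis point only approximately; evaluate at
  # the exact centre via the analytic rate
  peak <- max(sp$intensities)
  expect_equal(peak, 50 * 0.5 * cfg$led_power[1] * 0.77 *
                 max(hsfkit:::gauss_peak(cfg$emission_axis,
                                         cfg$led_wavelengths[1],
                                         cfg$led_bandwidth_fwhm)),
               tolerance = 1e-12)
})

test_that("dilute limit matches the linearized inner-filter oracle", {
  # fluorescence amplitude ~ ln(10) A phi f(lambda) for A -> 0
  fl <- fluorophore_spec("dilute", list(c(300, 20, 1)), list(c(500, 40, 1)),
                         quantum_yield = 0.5)
  conc <- 0.005   # A(300) = 0.005
  smp <- sample_spec(list(list(fl, conc)))
  cfg <- quiet_device(secondary_filter_factor = 0, led_power = 1,
                      emission_gain = 1,
                      led_wavelengths = c(seq(255, 290, length.out = 8),
                                          300, seq(320, 400, length.out = 3)))
  A_ex <- total_absorbance(smp, 300)
  expect_lte(A_ex, 0.01)
  sp <- simulate_channel(smp, 8, cfg, integration_time = 1)
  axis <- cfg$emission_axis
  band <- abs(axis - 500) < 60
  peak_sim <- max(sp$intensities[band])
  peak_lin <- max(log(10) * A_ex * 0.5 * fl$emission_profile(axis[band]))
  expect_equal(peak_sim, peak_lin, tolerance = 0.012)
})

test_that("simulate_channel argument errors", {
  smp <- make_sample(diazepam = 0.5)
  cfg <- quiet_device()
  expect_error(simulate_channel(smp, 12, cfg, 1), "led_index")
  expect_error(simulate_channel(smp, 0, cfg, 0), "positive")
  expect_error(simulate_channel(smp, 0, cfg, -5), "positive")
})

test_that("auto_integrate reaches 80% +/- 2% saturation on a linear detector", {
  cfg <- quiet_device()
  smp <- make_sample(alprazolam = 0.2)
  sp <- auto_integrate(smp, 2, cfg, seed = 1)
  frac <- max(sp$intensities) / cfg$saturation_level
  expect_gte(frac, 0.78)
  expect_lte(frac, 0.82)
  expect_false(sp$target_unreached)
})

test_that("auto_integrate is a fixed point when already at target", {
  cfg0 <- quiet_device()
  smp <- make_sample(diazepam = 0.5)
  # oracle: compute the exact exposure that puts the peak at the target
  rate <- max(hsfkit:::channel_rate(smp, 3, cfg0))
  t_star <- cfg0$target_saturation_fraction * cfg0$saturation_level / rate
  cfg <- quiet_device(start_integration = t_star)
  sp <- auto_integrate(smp, 3, cfg, seed = 1)
  expect_equal(sp$iterations, 1L)
  expect_equal(sp$integration_time, t_star, tolerance = 1e-9)
})

test_that("auto_integrate flags weak emitters capped at max_integration", {
  cfg <- quiet_device(max_integration = 10)
  smp <- make_sample(lactose = 0.01)   # nearly dark
  sp <- auto_integrate(smp, 6, cfg, seed = 1)
  expect_true(sp$target_unreached)
  expect_lt(max(sp$intensities), 0.8 * cfg$saturation_level)
  # oracle: exhaustive sweep of allowed exposures confirms unreachability
  peaks <- vapply(seq(0.1, 10, length.out = 50), function(t)
    max(simulate_channel(smp, 6, cfg, t)$intensities), 0)
  expect_true(all(peaks < 0.78 * cfg$saturation_level))
})

test_that("auto_integrate survives an all-dark sample", {
  cfg <- quiet_device()
  sp <- auto_integrate(sample_spec(solvent_baseline = 0), 0, cfg, seed = 1)
  expect_true(sp$target_unreached)
  expect_equal(max(sp$intensities), 0)
})

test_that("acquire_scan emits the device dialect and is seed-deterministic", {
  cfg <- device_config()
  smp <- make_sample(etizolam = 0.6)
  sc1 <- acquire_scan(smp, cfg, seed = 11)
  expect_s3_class(sc1, "hsf_scan")
  expect_equal(nrow(sc1), 18192L)
  expect_equal(ncol(sc1), 5L)
  expect_equal(names(sc1), c("led_index", "emission_nm", "intensity",
                             "integration_time", "brightness"))
  # 12 contiguous blocks of 1516, constant in the nonspectral fields
  expect_equal(unique(table(sc1$led_index)), 1516L)
  for (li in 0:11) {
    blk <- sc1[sc1$led_index == li, ]
    expect_equal(length(unique(blk$integration_time)), 1L)
    expect_equal(length(unique(blk$brightness)), 1L)
  }
  sc2 <- acquire_scan(smp, cfg, seed = 11)
  expect_identical(sc1$intensity, sc2$intensity)
  expect_identical(sc1$integration_time, sc2$integration_time)
  sc3 <- acquire_scan(smp, cfg, seed = 12)
  expect_false(identical(sc1$intensity, sc3$intensity))
})

test_that("reflectance monotonicity: more absorber, weaker reflected line", {
  cfg <- quiet_device()
  pool <- compound_pool()
  # LED nearest the alprazolam absorption maximum
  li <- which.min(abs(cfg$led_wavelengths - pool$alprazolam$absorption_max_nm)) - 1L
  refl_peak <- function(conc) {
    sc <- acquire_scan(make_sample(alprazolam = conc), cfg, seed = 5)
    blk <- sc[sc$led_index == li, ]
    norm <- blk$intensity / (blk$integration_time * blk$brightness)
    line <- abs(blk$emission_nm - cfg$led_wavelengths[li + 1L]) <
      cfg$led_bandwidth_fwhm
    max(norm[line])
  }
  peaks <- vapply(c(0.1, 0.2, 0.6, 1.2), refl_peak, 0)
  expect_equal(peaks, sort(peaks, decreasing = TRUE))
  # the printed low/high contrast: 0.6 mg/mL strictly below 0.2 mg/mL
  expect_lt(peaks[3], peaks[2])
})

test_that("emission peak saturates with concentration (concave, bounded)", {
  cfg <- quiet_device()
  pool <- compound_pool()
  li <- which.min(abs(cfg$led_wavelengths - 315)) - 1L  # diazepam abs max
  peak_at <- function(cc, cfg2) {
    sp <- simulate_channel(make_sample(diazepam = cc), li, cfg2, 1)
    axis <- cfg2$emission_axis
    band <- abs(axis - 355) < 40 &
      abs(axis - cfg2$led_wavelengths[li + 1L]) > 2 * cfg2$led_bandwidth_fwhm
    max(sp$intensities[band])
  }
  # concave growth-then-saturation over the measured range (~up to 4x the
  # highest band concentration)
  concs <- c(0.25, 0.5, 1, 2, 4, 8)
  fl_peak <- vapply(concs, peak_at, 0, cfg2 = cfg)
  expect_true(all(diff(diff(fl_peak)) < 1e-9))
  expect_lt(max(fl_peak[5:6]), max(fl_peak))   # growth has stopped
  # without secondary re-absorption the peak tends to the finite limit
  # phi * f(lambda) (fully absorbed excitation)
  cfg0 <- quiet_device(secondary_filter_factor = 0, emission_gain = 1)
  pool <- compound_pool()
  lim <- 0.18 * max(pool$diazepam$emission_profile(cfg0$emission_axis))
  expect_equal(peak_at(64, cfg0), lim, tolerance = 0.01)
  expect_true(all(vapply(concs, peak_at, 0, cfg2 = cfg0) <= lim * 1.0001))
})

test_that("dilute mixtures are additive within 2% (noiseless)", {
  cfg <- quiet_device(secondary_filter_factor = 0.5)
  pool <- compound_pool()
  # total A < 0.02 everywhere
  c1 <- 0.004; c2 <- 0.004
  mix <- make_sample(bromazolam = c1, metonitazene = c2)
  wlmax <- max(total_absorbance(mix, cfg$emission_axis))
  expect_lt(wlmax, 0.02)
  for (li in c(1L, 3L, 5L)) {
    line <- abs(cfg$emission_axis - cfg$led_wavelengths[li + 1L]) <
      3 * cfg$led_bandwidth_fwhm
    f_mix <- simulate_channel(mix, li, cfg, 1)$intensities
    f_1 <- simulate_channel(make_sample(bromazolam = c1), li, cfg, 1)$intensities
    f_2 <- simulate_channel(make_sample(metonitazene = c2), li, cfg, 1)$intensities
    blank <- simulate_channel(sample_spec(), li, cfg, 1)$intensities
    lhs <- (f_mix - blank)[!line]
    rhs <- (f_1 - blank + f_2 - blank)[!line]
    keep <- rhs > 1e-4 * max(rhs)
    expect_lt(max(abs(lhs[keep] - rhs[keep]) / rhs[keep]), 0.02)
  }
})

test_that("blank scans show no emission band above 3x noise floor", {
  cfg <- device_config()
  sc <- acquire_scan(sample_spec(), cfg, seed = 9)
  for (li in 0:11) {
    blk <- sc[sc$led_index == li, ]
    off <- abs(blk$emission_nm - cfg$led_wavelengths[li + 1L]) >
      4 * cfg$led_bandwidth_fwhm
    expect_lt(stats::median(blk$intensity[off]), 3 * cfg$noise_floor)
  }
})

test_that("scan text round trip is lossless to 6 significant digits", {
  cfg <- device_config()
  sc <- acquire_scan(make_sample(caffeine = 0.25), cfg, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_scan(sc, path)
  back <- read_scan(path)
  expect_equal(back$intensity, sc$intensity, tolerance = 1e-5)
  expect_identical(back$led_index, sc$led_index)

  # header-driven parsing: permuted column order reads identically
  df <- utils::read.csv(path)
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df[, c(3, 1, 5, 2, 4)], path2, row.names = FALSE)
  expect_equal(read_scan(path2)$intensity, back$intensity)

  # missing channel is reported by led_index
  path3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df[df$led_index != 7, ], path3, row.names = FALSE)
  expect_error(read_scan(path3), "7")
})

test_that("device config JSON round trip", {
  cfg <- device_config(led_bandwidth_fwhm = 9, noise_floor = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_device_config(cfg, path)
  back <- read_device_config(path)
  expect_equal(back$led_wavelengths, cfg$led_wavelengths)
  expect_equal(back$emission_axis, cfg$emission_axis)
  expect_equal(back$noise_floor, 3)
})

test_that("device config invariants are enforced", {
  expect_error(device_config(led_wavelengths = seq(255, 400, length.out = 11)),
               "12")
  expect_error(device_config(led_wavelengths = c(seq(255, 390, length.out = 11), 410)),
               "\\[255, 400\\]")
  expect_error(device_config(target_saturation_fraction = 1.2), "\\(0, 1\\)")
  expect_error(device_config(led_wavelengths = rep(300, 12)), "increasing")
})
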