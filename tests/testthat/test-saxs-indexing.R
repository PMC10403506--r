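test_that("d_spacing inverts the Bragg relation and rejects bad q", {
  expect_equal(d_spacing(2 * pi / 50), 50)
  expect_equal(d_spacing(2 * pi), 1)
  # the monoolein (110) spacing implies its peak position and back
  expect_equal(d_spacing(2 * pi / 105), 105)
  expect_error(d_spacing(0), "domain error")
  expect_error(d_spacing(-0.1), "domain error")
})

test_that("reflection sequences carry the characteristic ratio series", {
  pn <- reflection_sequence("Pn3m", 6)
  expect_equal(pn$factor, sqrt(c(2, 3, 4, 6, 8, 9)))
  im <- reflection_sequence("Im3m", 3)
  expect_equal(im$factor, sqrt(c(2, 4, 6)))
  hx <- reflection_sequence("HexagonalP6mm", 3)
  expect_equal(hx$factor, sqrt(c(1, 3, 4)))
  la <- reflection_sequence("Lamellar", 3)
  expect_equal(la$factor, c(1, 2, 3))
  ia <- reflection_sequence("Ia3d", 2)
  expect_equal(ia$factor, sqrt(c(6, 8)))
  # strictly increasing factors for every supported phase
  for (ph in c("Pn3m", "Im3m", "Ia3d", "HexagonalP6mm", "Lamellar")) {
    expect_true(all(diff(reflection_sequence(ph, 6)$factor) > 0), info = ph)
  }
  expect_error(reflection_sequence("Fd3m", 3), "unsupported phase")
  expect_error(reflection_sequence("Pn3m", 0), "positive count")
})

test_that("topographic prominence matches an independent reference", {
  # frozen from scipy.signal.peak_prominences on the same series
  x <- 0:59
  y <- sin(x * 0.7) * (1 + 0.5 * sin(x * 0.13)) + 0.02 * x
  peaks <- c(3, 12, 21, 30, 39, 48, 57)
  expect_equal(
    llcchar:::.prominence(y, peaks),
    c(1.1521197102, 2.7840170845, 2.0687840931, 1.1078957203,
      1.0686709657, 1.9947841369, 2.0176388731),
    tolerance = 1e-9)
})

test_that("peak detection recovers generated centres and ignores flats", {
  prof <- gen_saxs_profile("Pn3m", a = 70, noise_sd = 0.05, seed = 11)
  pk <- detect_peaks(prof)
  expect_equal(nrow(pk), 6)
  # within half a peak width of the stored truth
  expect_true(all(abs(pk$q - prof$truth$peaks$q) <
                    0.5 * prof$truth$peak_sigma))

  flat <- scattering_profile(seq(0.05, 0.3, length.out = 200),
                             rep(5, 200))
  expect_equal(nrow(detect_peaks(flat)), 0)

  q <- seq(0.05, 0.3, length.out = 400)
  single <- scattering_profile(q, 10 * exp(-(q - 0.1)^2 / (2 * 0.004^2)))
  got <- detect_peaks(single, background_model = "none")
  expect_equal(nrow(got), 1)
  expect_equal(got$q, 0.1, tolerance = 1e-3)

  expect_error(scattering_profile(numeric(0), numeric(0)), "invalid input")
})

test_that("exact ratio series are assigned to the right phase", {
  r_pn <- assign_phase(sqrt(c(2, 3, 4, 6, 8, 9)) * 0.09)
  expect_identical(r_pn$top, "Pn3m")
  expect_equal(r_pn$ranking$n_matched[1], 6)

  r_hex <- assign_phase(c(1, sqrt(3), 2) * 0.145)
  expect_identical(r_hex$top, "HexagonalP6mm")

  r_im <- assign_phase(sqrt(c(2, 4, 6)) * 0.06)
  expect_identical(r_im$top, "Im3m")

  single <- assign_phase(0.1)
  expect_true(single$ambiguous)
  expect_true(is.na(single$top))
  expect_true(all(single$ranking$n_matched == 1))

  expect_error(assign_phase(c(0.1, 0.14), ratio_tolerance = 0.5),
               "ratio_tolerance")
})

test_that("assignment survives a spurious leading peak", {
  q <- exact_peak_q("Im3m", 120)
  r <- assign_phase(c(0.6 * q[1], q))
  expect_identical(r$top, "Im3m")
  expect_equal(r$ranking$n_matched[1], 3)
})

test_that("lattice fits reproduce the cryo-EM-derived anchor values", {
  # phytantriol cubosome: d110 = 50 A under Pn3m
  a_pn <- fit_lattice(force_index(2 * pi / 50, "Pn3m"))
  expect_equal(a_pn$a, 70.7, tolerance = 1e-3)
  expect_true(is.na(a_pn$intercept))
  # monoolein cubosome: d110 = 105 A under Im3m
  a_im <- fit_lattice(force_index(2 * pi / 105, "Im3m"))
  expect_equal(a_im$a, 148.5, tolerance = 1e-3)
})

test_that("noise-free profiles round-trip the lattice parameter exactly", {
  prof <- gen_saxs_profile("Pn3m", a = 70, noise_sd = 0, background = c(0, 2),
                           background_const = 0, seed = 1)
  pk <- detect_peaks(prof, background_model = "none")
  fit <- fit_lattice(assign_phase(pk)$assignments[["Pn3m"]])
  expect_equal(fit$a, 70, tolerance = 1e-4)
  expect_lt(abs(fit$intercept), 1e-4)
  expect_true(fit$qc_pass)
  expect_gt(fit$r_squared, 0.999999)
})

test_that("indexed peaks satisfy d * factor = per-peak a for cubics", {
  q <- exact_peak_q("Pn3m", 87.3)
  fit <- fit_lattice(force_index(q, "Pn3m"))
  d <- d_spacing(q)
  f <- reflection_sequence("Pn3m", length(q))$factor
  expect_equal(d * f, fit$per_peak_a, tolerance = 1e-9)
})

test_that("assignment and fitted a are scale-equivariant", {
  q <- exact_peak_q("Pn3m", 70)
  base <- fit_lattice(assign_phase(q)$assignments[["Pn3m"]])
  for (c_scale in c(0.25, 3.7)) {
    r <- assign_phase(q * c_scale)
    expect_identical(r$top, "Pn3m")
    fit <- fit_lattice(r$assignments[["Pn3m"]])
    expect_equal(fit$a, base$a / c_scale, tolerance = 1e-9)
  }
})

test_that("deliberate mis-indexing degrades the intercept QC", {
  q <- exact_peak_q("Pn3m", 70)
  ai_good <- force_index(q, "Pn3m")
  ai_bad <- force_index(q, "Im3m")
  good <- fit_lattice(ai_good)
  bad <- fit_lattice(ai_bad)
  expect_lt(abs(good$intercept), 0.005)
  expect_gt(abs(bad$intercept), 0.005)
  expect_gt(ai_bad$rms_ratio_residual, ai_good$rms_ratio_residual)
  expect_false(bad$qc_pass)
})

test_that("fit_lattice validates its input", {
  expect_error(fit_lattice(list(phase = "Pn3m")), "phase_assignment")
  broken <- force_index(c(0.1, 0.14), "Pn3m")
  broken$phase <- "NotAPhase"
  expect_error(fit_lattice(broken), "unsupported phase")
  empty <- force_index(0.1, "Pn3m")
  empty$indexed <- empty$indexed[0, ]
  expect_error(fit_lattice(empty), "no indexed peaks")
})

test_that("noisy profiles round-trip phase and lattice parameter", {
  for (ph in c("Pn3m", "Im3m", "HexagonalP6mm")) {
    for (s in 1:15) {
      a <- spread_a(s)
      prof <- gen_saxs_profile(ph, a = a, noise_sd = 0.1, seed = s)
      r <- assign_phase(detect_peaks(prof))
      expect_identical(r$top, ph, info = sprintf("%s a=%g seed=%d", ph, a, s))
      fit <- fit_lattice(r$assignments[[ph]])
      expect_lt(abs(fit$a - a) / a, 0.01)
    }
  }
})

test_that("water-channel radii follow the phase-specific relations", {
  hex <- water_channel_radius("HexagonalP6mm", a = 50, l_c = 13)
  expect_equal(hex$r_w, 12)
  pn <- water_channel_radius("Pn3m", a = 70.7, l_c = 13)
  expect_equal(pn$r_w, 0.391 * 70.7 - 13, tolerance = 1e-12)
  expect_equal(pn$r_w, 14.64, tolerance = 1e-3)
  # zero-radius boundary for the primitive cubic
  z <- water_channel_radius("Im3m", a = 18 / 0.305, l_c = 18)
  expect_equal(z$r_w, 0, tolerance = 1e-12)
  expect_warning(neg <- water_channel_radius("Pn3m", a = 30, l_c = 13),
                 "negative")
  expect_true(neg$negative)
  expect_error(water_channel_radius("Lamellar", 50, 13), "unsupported phase")
})

test_that("r_w is monotone in a and in chain length", {
  for (ph in c("Pn3m", "Im3m", "HexagonalP6mm")) {
    a_grid <- seq(60, 150, by = 10)
    rw_a <- vapply(a_grid, function(a)
      suppressWarnings(water_channel_radius(ph, a, 13)$r_w), numeric(1))
    expect_true(all(diff(rw_a) > 0), info = ph)
    lc_grid <- seq(10, 20, by = 2)
    rw_l <- vapply(lc_grid, function(l)
      suppressWarnings(water_channel_radius(ph, 100, l)$r_w), numeric(1))
    expect_true(all(diff(rw_l) < 0), info = ph)
  }
})

test_that("lipid chain-length registry holds the standard approximations", {
  expect_equal(lipid_chain_length("monoolein"), 18)
  expect_equal(lipid_chain_length("phytantriol"), 13)
})

test_that("profiles and peak lists round-trip through text files", {
  prof <- gen_saxs_profile("Im3m", a = 120, seed = 3)
  f <- tempfile(fileext = ".dat")
  write_saxs_profile(prof, f)
  back <- read_saxs_profile(f)
  expect_equal(back$q, prof$q, tolerance = 1e-7)
  expect_equal(back$intensity, prof$intensity, tolerance = 1e-6)

  pf <- tempfile(fileext = ".txt")
  writeLines(c("# peaks", "0.0889", "0.1257"), pf)
  pl <- read_peak_list(pf)
  expect_equal(pl$q, c(0.0889, 0.1257))
  expect_equal(pl$d, 2 * pi / c(0.0889, 0.1257))
  unlink(c(f, pf))
})
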