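test_that("a pure cosine produces a Friedel pair at 1/period", {
  px <- 2
  n <- 128
  x <- (seq_len(n) - 1) * px
  img <- micrograph(outer(rep(1, n), cos(2 * pi * x / 50)), pixel_size = px)
  sp <- power_spectrum(img)
  spots <- detect_spots(sp)
  expect_equal(nrow(spots), 1)  # one unique pair
  expect_lt(abs(spots$radius - 1 / 50), sp$df)
})

test_that("square and hexagonal patterns yield the expected spot geometry", {
  sq <- gen_lattice_image("square", d = 50, pixel_size = 2, size = 256,
                          seed = 1)
  s_sq <- detect_spots(power_spectrum(sq))
  expect_equal(nrow(s_sq), 2)  # two radius-degenerate pairs
  gap <- abs(diff(sort(s_sq$angle)))
  expect_equal(gap, pi / 2, tolerance = 0.05)

  hx <- gen_lattice_image("hexagonal", d = 60, pixel_size = 2, size = 256,
                          seed = 2)
  s_hx <- detect_spots(power_spectrum(hx))
  expect_equal(nrow(s_hx), 3)
  ang <- sort(s_hx$angle)
  gaps <- diff(c(ang, ang[1] + pi))
  expect_true(all(abs(gaps - pi / 3) < 0.05))
})

test_that("white noise yields no spots across seeds", {
  for (s in 1:20) {
    img <- micrograph(matrix(stats::rnorm(128^2, 100, 10), 128, 128),
                      pixel_size = 2)
    expect_equal(nrow(detect_spots(power_spectrum(img))), 0,
                 info = sprintf("seed %d", s))
  }
})

test_that("first- and second-order rings report the sqrt(2) ratio", {
  img <- gen_lattice_image("hexagonal", d = 105, pixel_size = 4, size = 256,
                           harmonics = data.frame(ratio = sqrt(2),
                                                  amplitude = 0.5),
                           seed = 3)
  spots <- detect_spots(power_spectrum(img))
  expect_gte(nrow(spots), 6)
  est <- lattice_from_spots(spots, "hexagonal", phase_hint = "Im3m")
  expect_equal(est$order_ratio, sqrt(2), tolerance = 0.02 * sqrt(2))
  expect_true(est$pattern_ok)
})

test_that("projection mappings reproduce the anchor lattice parameters", {
  sq <- gen_lattice_image("square", d = 50, pixel_size = 2, size = 256,
                          seed = 4)
  est <- lattice_from_spots(detect_spots(power_spectrum(sq)), "square",
                            phase_hint = "Pn3m")
  expect_equal(est$a, 70.7, tolerance = 0.01 * 70.7)

  hx <- gen_lattice_image("hexagonal", d = 105, pixel_size = 4, size = 512,
                          harmonics = data.frame(ratio = sqrt(2),
                                                 amplitude = 0.5),
                          seed = 5)
  est2 <- lattice_from_spots(detect_spots(power_spectrum(hx)), "hexagonal",
                             phase_hint = "Im3m")
  expect_equal(est2$a, 148.5, tolerance = 0.02 * 148.5)
  # without a hint, the sqrt(2) secondary ring identifies the primitive cubic
  est3 <- lattice_from_spots(detect_spots(power_spectrum(hx)), "hexagonal")
  expect_identical(est3$phase_assumed, "Im3m")

  # plain hexagonal phase: a = 2*d10/sqrt(3)
  p6 <- gen_lattice_image("hexagonal", d = 43.3, pixel_size = 2, size = 256,
                          seed = 6)
  est4 <- lattice_from_spots(detect_spots(power_spectrum(p6)), "hexagonal")
  expect_identical(est4$phase_assumed, "HexagonalP6mm")
  expect_equal(est4$a, 50, tolerance = 0.02 * 50)

  expect_error(lattice_from_spots(detect_spots(power_spectrum(sq)),
                                  "hexagonal"), "at least 3")
})

test_that("spacing recovery holds across d, pixel size and orientation", {
  ok <- 0
  n_trials <- 30
  set.seed(7)
  for (i in seq_len(n_trials)) {
    px <- stats::runif(1, 1, 4)
    d <- stats::runif(1, max(20, 2.5 * px), 120)
    proj <- if (i %% 2 == 0) "square" else "hexagonal"
    size <- max(128, 2^ceiling(log2(8 * d / px)))
    img <- gen_lattice_image(proj, d = d, pixel_size = px, size = size,
                             orientation = stats::runif(1, 0, pi / 2),
                             noise_sd = 0.2, seed = i)
    est <- lattice_from_spots(detect_spots(power_spectrum(img)), proj)
    df <- 1 / (size * px)
    if (abs(1 / est$d - 1 / d) <= df || abs(est$d - d) <= 0.02 * d) {
      ok <- ok + 1
    }
  }
  expect_gte(ok / n_trials, 0.95)
})

test_that("recovered spacing is rotation invariant", {
  base <- gen_lattice_image("square", d = 40, pixel_size = 2, size = 256,
                            seed = 8)
  d0 <- lattice_from_spots(detect_spots(power_spectrum(base)), "square")$d
  rot <- gen_lattice_image("square", d = 40, pixel_size = 2, size = 256,
                           orientation = 0.61, seed = 8)
  d1 <- lattice_from_spots(detect_spots(power_spectrum(rot)), "square")$d
  expect_lt(abs(d1 - d0) / d0, 0.02)
})

test_that("spectral and line-profile spacings agree on a clean image", {
  img <- gen_lattice_image("square", d = 50, pixel_size = 2, size = 256,
                           seed = 9)
  sp <- power_spectrum(img)
  d_spec <- lattice_from_spots(detect_spots(sp), "square")$d
  lp <- line_profile_spacing(img, start = c(1, 128), end = c(256, 128))
  expect_true(lp$ok)
  expect_lte(abs(1 / lp$spacing - 1 / d_spec), sp$df)
})

test_that("line profiles handle periodic, noisy and flat inputs", {
  img <- gen_lattice_image("square", d = 50, pixel_size = 2, size = 256,
                           seed = 10)
  lp <- line_profile_spacing(img, start = c(1, 100), end = c(256, 100))
  expect_equal(lp$spacing, 50, tolerance = 2 / 50)  # within one pixel (2 A)
  expect_equal(lp$mean_peak_to_peak, 50, tolerance = 0.05)

  noisy <- gen_lattice_image("square", d = 50, pixel_size = 2, size = 256,
                             noise_sd = 0.05, seed = 11)
  lp2 <- line_profile_spacing(noisy, start = c(1, 60), end = c(256, 60))
  expect_equal(lp2$spacing, 50, tolerance = 2 / 50)

  flat <- micrograph(matrix(7, 128, 128), pixel_size = 2)
  lp3 <- line_profile_spacing(flat, start = c(1, 64), end = c(128, 64))
  expect_false(lp3$ok)
  expect_true(is.na(lp3$spacing))

  expect_error(line_profile_spacing(flat, c(1, 1), c(2, 2)), "too short")
})

test_that("micrographs round-trip through PNG and TIFF readers", {
  img <- gen_lattice_image("square", d = 50, pixel_size = 2, size = 64,
                           mean_level = 3, amplitude = 1, seed = 12)
  norm <- (img$pixels - min(img$pixels)) /
    (max(img$pixels) - min(img$pixels))
  fp <- tempfile(fileext = ".png")
  png::writePNG(norm, fp)
  back <- read_micrograph(fp, pixel_size = 2)
  expect_equal(dim(back$pixels), c(64, 64))
  expect_gt(stats::cor(as.numeric(back$pixels), as.numeric(norm)), 0.999)
  ft <- tempfile(fileext = ".tif")
  tiff::writeTIFF(norm, ft)
  back2 <- read_micrograph(ft, pixel_size = 2)
  expect_gt(stats::cor(as.numeric(back2$pixels), as.numeric(norm)), 0.999)
  unlink(c(fp, ft))
})

test_that("small images are refused for spectral analysis", {
  tiny <- micrograph(matrix(1, 32, 32), pixel_size = 2)
  expect_error(power_spectrum(tiny), "64x64")
  expect_error(micrograph(matrix(1, 4, 4), pixel_size = -1), "pixel_size")
})

test_that("particle-class tallies convert counts to percentages", {
  t <- tally_particle_classes(c(llc = 180, vesicle = 20))
  expect_equal(t$percentage, c(90, 10))
  expect_equal(sum(t$count), 200)
  expect_error(tally_particle_classes(c(10, 20)), "named")
})
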