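test_that("delta-I reproduces the generator's lumen/background contrast", {
  g <- gen_guv_image(radius = 20, lumen_mean = 200, background_mean = 100,
                     seed = 1)
  m <- delta_i(g)
  expect_equal(m$delta_i, 100, tolerance = 1e-9)
  expect_true(m$delivered)

  tie <- gen_guv_image(radius = 20, lumen_mean = 150, background_mean = 150,
                       seed = 1)
  mt <- delta_i(tie)
  expect_equal(mt$delta_i, 0)
  expect_false(mt$delivered)  # strict inequality at the threshold

  neg <- gen_guv_image(radius = 20, lumen_mean = 120, background_mean = 150,
                       noise_sd = 5, seed = 2)
  mn <- delta_i(neg)
  expect_lt(mn$delta_i, 0)
  expect_false(mn$delivered)
})

test_that("delta-I is offset invariant and scales linearly", {
  g <- gen_guv_image(radius = 18, lumen_mean = 180, background_mean = 110,
                     membrane_amplitude = 60, noise_sd = 8, seed = 3)
  base <- delta_i(g)
  shifted <- g
  shifted$pixels <- g$pixels + 37.5
  expect_equal(delta_i(shifted)$delta_i, base$delta_i, tolerance = 1e-9)
  scaled <- g
  scaled$pixels <- g$pixels * 2.5
  expect_equal(delta_i(scaled)$delta_i, 2.5 * base$delta_i,
               tolerance = 1e-9)
})

test_that("measured delta-I stays within two noise-SD of the truth", {
  for (s in 1:25) {
    g <- gen_guv_image(radius = 15, lumen_mean = 160, background_mean = 100,
                       noise_sd = 10, seed = s)
    m <- delta_i(g)
    expect_lt(abs(m$delta_i - 60), 2 * 10, label = sprintf("seed %d", s))
  }
})

test_that("region geometry is validated", {
  g <- gen_guv_image(radius = 25, lumen_mean = 200, background_mean = 100,
                     size = 64, seed = 4)
  expect_error(delta_i(g), "clipped")  # annulus at 1.5R exceeds a 64-px frame
  expect_error(delta_i(g, inner_fraction = 1.3), "overlap")
  expect_error(gen_guv_image(radius = 40, lumen_mean = 1,
                             background_mean = 0, size = 64, seed = 1),
               "geometry overflow")
})

test_that("intensity profiles show the lumen plateau and membrane ring", {
  g <- gen_guv_image(radius = 20, lumen_mean = 200, background_mean = 100,
                     size = 160, seed = 5)
  p <- intensity_profile(g, angle = 0)
  expect_false(attr(p, "truncated"))
  um <- g$pixel_size
  inside <- abs(p$position) < 0.5 * 20 * um
  outside <- abs(p$position) > 1.2 * 20 * um
  expect_equal(mean(p$intensity[inside]), 200, tolerance = 1e-6)
  expect_equal(mean(p$intensity[outside]), 100, tolerance = 1e-6)

  flat <- guv_image(matrix(42, 128, 128), 0.2, c(64, 64), 20)
  pf <- intensity_profile(flat)
  expect_true(all(pf$intensity == 42))

  ring <- gen_guv_image(radius = 20, lumen_mean = 100, background_mean = 100,
                        membrane_amplitude = 80, size = 160, seed = 6)
  pr <- intensity_profile(ring, angle = 0)
  peaks <- pr$position[order(pr$intensity, decreasing = TRUE)[1:2]]
  expect_equal(sort(abs(peaks)), rep(20 * um, 2), tolerance = 0.1)
})

test_that("histograms conserve counts and report delivered fractions", {
  same <- data.frame(delta_i = rep(100, 10))
  h1 <- aggregate_histogram(same, bin_width = 10)
  expect_equal(sum(h1$counts), 10)
  expect_equal(sum(h1$counts > 0), 1)
  expect_equal(unname(h1$delivered_fraction["all"]), 1)

  mix <- data.frame(delta_i = c(rep(100, 5), rep(-50, 5)))
  h2 <- aggregate_histogram(mix, bin_width = 25)
  expect_equal(sum(h2$counts), 10)
  expect_equal(unname(h2$delivered_fraction["all"]), 0.5)

  expect_error(aggregate_histogram(data.frame(delta_i = numeric(0))),
               "at least one")
})

test_that("a two-population cohort separates into a bimodal histogram", {
  ms <- list()
  grp <- character(0)
  set.seed(42)
  for (i in 1:32) {
    g <- gen_guv_image(radius = 15, lumen_mean = stats::rnorm(1, 180, 15),
                       background_mean = 100, noise_sd = 10, seed = i)
    ms[[length(ms) + 1]] <- delta_i(g)
    grp <- c(grp, "small")
  }
  for (i in 1:32) {
    g <- gen_guv_image(radius = 15, lumen_mean = stats::rnorm(1, 70, 10),
                       background_mean = 100, noise_sd = 10, seed = 100 + i)
    ms[[length(ms) + 1]] <- delta_i(g)
    grp <- c(grp, "large")
  }
  h <- aggregate_histogram(ms, group = grp)
  expect_equal(h$n, 64)
  expect_equal(unname(h$delivered_fraction["small"]), 1)
  expect_equal(unname(h$delivered_fraction["large"]), 0)
  # the two group distributions occupy disjoint bin ranges
  occ_small <- range(which(h$counts_by_group["small", ] > 0))
  occ_large <- range(which(h$counts_by_group["large", ] > 0))
  expect_gt(occ_small[1], occ_large[2])
})

test_that("GUV annotation tables are validated on read", {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(image = "a.png", cx = 64, cy = 64, r = 20,
                              group = "small"), f, row.names = FALSE)
  ann <- read_guv_annotations(f)
  expect_equal(nrow(ann), 1)
  utils::write.csv(data.frame(x = 1), f, row.names = FALSE)
  expect_error(read_guv_annotations(f), "columns")
  unlink(f)
})
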