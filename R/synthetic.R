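# Seeded synthetic-data generators. Every generator attaches its ground
# truth so recovery tests need no re-derivation, takes a mandatory seed,
# and restores the caller's RNG state.

# Bragg-peak position for one reflection.
.q_position <- function(family, factor, a) {
  switch(family,
    cubic     = 2 * pi * factor / a,
    hexagonal = 4 * pi * factor / (sqrt(3) * a),
    lamellar  = 2 * pi * factor / a)
}

#' Generate a synthetic 1D scattering profile
#'
#' Places Gaussian Bragg peaks at the allowed reflection positions of the
#' phase (`q = 2*pi*factor/a` for cubic, `q = 4*pi*factor/(sqrt(3)*a)` for
#' hexagonal), on a power-law-plus-constant baseline, with additive Gaussian
#' noise proportional to the local noise-free signal. Peak amplitudes decay
#' with order as `factor_1/factor`.
#'
#' @param phase Phase name understood by [reflection_sequence()].
#' @param a Lattice parameter (Å).
#' @param n_reflections Number of reflections to generate.
#' @param peak_sigma Gaussian peak width in q (Å⁻¹).
#' @param amplitude First-order peak amplitude (AU).
#' @param background `c(amplitude, exponent)` of the `A*q^-p` baseline term.
#' @param background_const Constant baseline offset (AU).
#' @param noise_sd Noise standard deviation relative to the local signal
#'   (so SNR = 1/noise_sd at the peak tops); 0 for noise-free.
#' @param q_range `c(min, max)` q window (Å⁻¹); `NULL` chooses a window
#'   covering all reflections. A supplied window that cuts off reflections
#'   is an error listing the offending indices.
#' @param n_points Number of q samples.
#' @param seed Mandatory RNG seed.
#' @return A [scattering_profile()] whose `truth` holds the phase, `a`, and
#'   a reflection table with exact peak centres.
#' @export
gen_saxs_profile <- function(phase, a, n_reflections = NULL,
                             peak_sigma = 0.002, amplitude = 100,
                             background = c(0.2, 2), background_const = 1,
                             noise_sd = 0.05, q_range = NULL,
                             n_points = 1200, seed) {
  if (!.is_scalar_num(a) || a <= 0) stop("a must be positive", call. = FALSE)
  if (is.null(n_reflections)) {
    n_reflections <- switch(phase, Pn3m = 6L, Im3m = 3L,
                            HexagonalP6mm = 3L, 4L)
  }
  refl <- reflection_sequence(phase, n_reflections)
  family <- attr(refl, "family")
  refl$q <- .q_position(family, refl$factor, a)
  if (is.null(q_range)) {
    q_range <- c(max(0.55 * min(refl$q), 8 * peak_sigma),
                 max(refl$q) * 1.08 + 8 * peak_sigma)
  } else {
    outside <- refl$q < q_range[1] + 3 * peak_sigma |
               refl$q > q_range[2] - 3 * peak_sigma
    if (any(outside)) {
      stop(sprintf(
        "reflections outside q_range: %s",
        paste(sprintf("(%d%d%d)", refl$h[outside], refl$k[outside],
                      refl$l[outside]), collapse = ", ")), call. = FALSE)
    }
  }
  q <- seq(q_range[1], q_range[2], length.out = n_points)
  amps <- amplitude * refl$factor[1] / refl$factor
  signal <- background[1] * q^(-background[2]) + background_const
  for (i in seq_len(nrow(refl))) {
    signal <- signal +
      amps[i] * exp(-(q - refl$q[i])^2 / (2 * peak_sigma^2))
  }
  intensity <- if (noise_sd > 0) {
    .with_seed(seed, pmax(signal + stats::rnorm(n_points, 0,
                                                noise_sd * signal), 0))
  } else signal
  scattering_profile(
    q, intensity,
    label = sprintf("synthetic %s a=%.4g", phase, a),
    truth = list(phase = phase, a = a, peaks = refl,
                 peak_sigma = peak_sigma, amplitudes = amps,
                 noise_sd = noise_sd, seed = seed))
}

# ---- micrograph-like lattice images --------------------------------------

#' Construct a micrograph container
#'
#' Row-major grayscale grid with the origin at the top-left and y increasing
#' downward; `pixel_size` calibrates both axes in Å per pixel.
#'
#' @param pixels Numeric matrix of intensities.
#' @param pixel_size Å per pixel, positive.
#' @param label Free text.
#' @param truth Optional generator ground truth.
#' @return Object of class `micrograph`.
#' @export
micrograph <- function(pixels, pixel_size, label = "", truth = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("invalid input: pixels must be a numeric matrix", call. = FALSE)
  }
  if (!.is_scalar_num(pixel_size) || pixel_size <= 0) {
    stop("invalid input: pixel_size must be positive", call. = FALSE)
  }
  structure(list(pixels = pixels, pixel_size = pixel_size, label = label,
                 truth = truth), class = "micrograph")
}

#' Read a grayscale TIFF or PNG as a micrograph
#'
#' Multi-channel images are averaged to one grayscale plane.
#'
#' @param path Image file (`.tif`, `.tiff` or `.png`).
#' @inheritParams micrograph
#' @return A [micrograph()].
#' @export
read_micrograph <- function(path, pixel_size, label = basename(path)) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop(sprintf("unsupported image format: %s", ext), call. = FALSE))
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  micrograph(img, pixel_size, label = label)
}

#' Generate a synthetic periodic lattice image
#'
#' Sums plane-wave cosine sets emulating a projected lattice: two orthogonal
#' waves for a square pattern (a cubic phase viewed along \[001\]) or three
#' waves at 60 degrees for a hexagonal pattern (\[111\] of a cubic, or the
#' tubule axis of the inverse hexagonal phase). Optional harmonic sets add
#' higher-order reflections at a chosen radius ratio (e.g. `sqrt(2)` for the
#' secondary ring of a primitive cubic projection).
#'
#' @param projection `"square"` or `"hexagonal"`.
#' @param d Plane spacing (Å); the first-order spectral spots sit at radius
#'   `1/d` Å⁻¹. Must exceed `2*pixel_size` (Nyquist).
#' @param pixel_size Å per pixel.
#' @param size Image side (pixels), at least 64.
#' @param orientation Rotation of the wave set (radians).
#' @param amplitude First-order cosine amplitude.
#' @param mean_level Constant offset (keeps intensities positive).
#' @param harmonics Optional data frame with columns `ratio`, `amplitude`
#'   and optionally `angle_offset` (radians; defaults to half the pattern's
#'   angular period).
#' @param noise_sd Additive Gaussian noise SD (absolute units).
#' @param seed Mandatory RNG seed (used only when `noise_sd > 0`).
#' @return A [micrograph()] with `truth` holding `d`, `nu = 1/d`,
#'   projection, orientation and harmonic layout.
#' @export
gen_lattice_image <- function(projection = c("square", "hexagonal"), d,
                              pixel_size, size = 256, orientation = 0,
                              amplitude = 1, mean_level = 10,
                              harmonics = NULL, noise_sd = 0, seed = 1) {
  projection <- match.arg(projection)
  if (!.is_scalar_num(d) || d <= 0) stop("d must be positive", call. = FALSE)
  if (d <= 2 * pixel_size) {
    stop(sprintf("sub-Nyquist spacing: d = %.3g A needs pixel_size < %.3g A",
                 d, d / 2), call. = FALSE)
  }
  if (size < 64) stop("image side must be at least 64 px", call. = FALSE)
  angles0 <- switch(projection,
    square = c(0, pi / 2),
    hexagonal = c(0, pi / 3, 2 * pi / 3))
  half_period <- switch(projection, square = pi / 4, hexagonal = pi / 6)
  x <- (seq_len(size) - 1) * pixel_size
  X <- matrix(x, size, size, byrow = TRUE)
  Y <- matrix(x, size, size)
  wave_set <- function(nu, amp, offset) {
    out <- 0
    for (th in angles0 + orientation + offset) {
      out <- out + amp * cos(2 * pi * nu * (X * cos(th) + Y * sin(th)))
    }
    out
  }
  img <- mean_level + wave_set(1 / d, amplitude, 0)
  if (!is.null(harmonics) && nrow(harmonics)) {
    for (i in seq_len(nrow(harmonics))) {
      off <- if ("angle_offset" %in% names(harmonics)) {
        harmonics$angle_offset[i]
      } else half_period
      img <- img + wave_set(harmonics$ratio[i] / d, harmonics$amplitude[i],
                            off)
    }
  }
  if (noise_sd > 0) {
    img <- .with_seed(seed,
                      img + matrix(stats::rnorm(size^2, 0, noise_sd),
                                   size, size))
  }
  micrograph(img, pixel_size,
             label = sprintf("synthetic %s lattice d=%.4g", projection, d),
             truth = list(projection = projection, d = d, nu = 1 / d,
                          orientation = orientation, harmonics = harmonics,
                          noise_sd = noise_sd, seed = seed))
}

# ---- GUV images -----------------------------------------------------------

#' Construct a GUV image container
#'
#' @param pixels Numeric matrix (green-channel intensities).
#' @param pixel_size Microns per pixel.
#' @param centre `c(x, y)` centre in pixel coordinates (x = column).
#' @param radius Vesicle radius in pixels, greater than 5; the circle must
#'   lie fully inside the image.
#' @param label Free text.
#' @param truth Optional generator ground truth.
#' @return Object of class `guv_image`.
#' @export
guv_image <- function(pixels, pixel_size, centre, radius, label = "",
                      truth = NULL) {
  if (!is.matrix(pixels)) stop("pixels must be a matrix", call. = FALSE)
  if (!.is_scalar_num(radius) || radius <= 5) {
    stop("radius must exceed 5 px", call. = FALSE)
  }
  if (centre[1] - radius < 1 || centre[1] + radius > ncol(pixels) ||
      centre[2] - radius < 1 || centre[2] + radius > nrow(pixels)) {
    stop("geometry overflow: circle not fully inside the image",
         call. = FALSE)
  }
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 centre = as.numeric(centre), radius = radius,
                 label = label, truth = truth), class = "guv_image")
}

#' Generate a synthetic GUV confocal-like image
#'
#' A disc of lumen intensity, a Gaussian membrane ring at the radius, and a
#' uniform background elsewhere, with optional additive Gaussian noise.
#'
#' @param radius Vesicle radius (px).
#' @param lumen_mean,background_mean Mean intensities (AU).
#' @param membrane_amplitude Ring amplitude added at the rim (AU).
#' @param membrane_sigma Ring width (px).
#' @param noise_sd Additive Gaussian noise SD (AU).
#' @param size Image side (px).
#' @param centre `c(x, y)` centre (px); defaults to the image middle.
#' @param pixel_size Microns per pixel.
#' @param seed Mandatory RNG seed (used when `noise_sd > 0`).
#' @return A [guv_image()] with `truth` carrying the generating means.
#' @export
gen_guv_image <- function(radius, lumen_mean, background_mean,
                          membrane_amplitude = 0, membrane_sigma = 1.5,
                          noise_sd = 0, size = 128, centre = NULL,
                          pixel_size = 0.2, seed = 1) {
  if (is.null(centre)) centre <- c((size + 1) / 2, (size + 1) / 2)
  X <- matrix(seq_len(size), size, size, byrow = TRUE)
  Y <- matrix(seq_len(size), size, size)
  dist <- sqrt((X - centre[1])^2 + (Y - centre[2])^2)
  img <- ifelse(dist <= radius, lumen_mean, background_mean)
  if (membrane_amplitude != 0) {
    img <- img + membrane_amplitude *
      exp(-(dist - radius)^2 / (2 * membrane_sigma^2))
  }
  if (noise_sd > 0) {
    img <- .with_seed(seed,
                      img + matrix(stats::rnorm(size^2, 0, noise_sd),
                                   size, size))
  }
  guv_image(img, pixel_size, centre, radius,
            label = sprintf("synthetic GUV r=%g px", radius),
            truth = list(lumen_mean = lumen_mean,
                         background_mean = background_mean,
                         membrane_amplitude = membrane_amplitude,
                         noise_sd = noise_sd, seed = seed))
}

# ---- assay tables ---------------------------------------------------------

#' Generate a noisy linear standard curve
#'
#' Beer–Lambert-style response `intercept + slope*concentration`, with
#' multiplicative Gaussian noise on the response.
#'
#' @param concentrations Concentration grid (µM or mM).
#' @param slope Response per concentration unit (AU).
#' @param intercept Blank response (AU).
#' @param noise_sd Relative noise SD on each response.
#' @param seed Mandatory RNG seed (used when `noise_sd > 0`).
#' @return Data frame `concentration`, `response` with a `truth` attribute.
#' @export
gen_standard_curve <- function(concentrations, slope, intercept = 0,
                               noise_sd = 0, seed = 1) {
  resp <- intercept + slope * concentrations
  if (noise_sd > 0) {
    resp <- .with_seed(seed,
                       resp * (1 + stats::rnorm(length(resp), 0, noise_sd)))
  }
  out <- data.frame(concentration = concentrations, response = resp)
  attr(out, "truth") <- list(slope = slope, intercept = intercept,
                             noise_sd = noise_sd, seed = seed)
  out
}

#' Generate a synthetic dye-release time course
#'
#' Passive first-order release toward a plateau, followed by an immediate
#' jump to the full-release fluorescence when the surfactant is added.
#'
#' @param times Sampling times (minutes), increasing.
#' @param F0 Initial fluorescence (AU).
#' @param passive_plateau Plateau approached by passive release (AU).
#' @param rate First-order release rate (1/min).
#' @param triton_time Time of surfactant addition (min); samples at or after
#'   it read `F_triton`.
#' @param F_triton Post-surfactant fluorescence (AU), the full-release level.
#' @param noise_sd Relative noise SD.
#' @param seed Mandatory RNG seed (used when `noise_sd > 0`).
#' @return A [release_trace()] with a `truth` attribute.
#' @export
gen_release_trace <- function(times, F0, passive_plateau, rate,
                              triton_time, F_triton, noise_sd = 0,
                              seed = 1) {
  fl <- F0 + (passive_plateau - F0) * (1 - exp(-rate * times))
  fl[times >= triton_time] <- F_triton
  if (noise_sd > 0) {
    fl <- .with_seed(seed, fl * (1 + stats::rnorm(length(fl), 0, noise_sd)))
  }
  tr <- release_trace(times, fl, F0 = F0, F_triton = F_triton)
  attr(tr, "truth") <- list(F0 = F0, passive_plateau = passive_plateau,
                            rate = rate, triton_time = triton_time,
                            F_triton = F_triton, noise_sd = noise_sd,
                            seed = seed)
  tr
}

# ---- microfluidic flow regime ---------------------------------------------

#' Flow-rate ratio and total flow rate of the focusing regime
#'
#' The hydrodynamic-focusing regime is summarised by the flow-rate ratio
#' `FRR = Q_buffer / Q_ethanol` between the aqueous and ethanolic streams
#' and the total flow rate `TFR = Q_buffer + Q_ethanol`.
#'
#' @param Q_buffer,Q_ethanol Stream flow rates (µL/min), both positive.
#' @return Object of class `flow_regime` with `Q_buffer`, `Q_ethanol`,
#'   `FRR`, `TFR`.
#' @export
#' @examples
#' flow_regime(400, 20)  # FRR 20, TFR 420
flow_regime <- function(Q_buffer, Q_ethanol) {
  if (!.is_scalar_num(Q_buffer) || Q_buffer <= 0 ||
      !.is_scalar_num(Q_ethanol) || Q_ethanol <= 0) {
    stop("domain error: flow rates must be positive", call. = FALSE)
  }
  structure(list(Q_buffer = Q_buffer, Q_ethanol = Q_ethanol,
                 FRR = Q_buffer / Q_ethanol, TFR = Q_buffer + Q_ethanol),
            class = "flow_regime")
}

#' @export
print.flow_regime <- function(x, ...) {
  cat(sprintf("<flow_regime> FRR = %.3g, TFR = %.4g uL/min\n", x$FRR, x$TFR))
  invisible(x)
}
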