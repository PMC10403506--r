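# Lattice-spacing estimation from periodic 2D images: windowed power
# spectrum, Friedel-paired spot detection, projection-model interpretation
# and real-space line profiles.

.hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))

.fftshift2 <- function(m) {
  nr <- nrow(m)
  nc <- ncol(m)
  ri <- c((floor(nr / 2) + 1):nr, 1:floor(nr / 2))
  ci <- c((floor(nc / 2) + 1):nc, 1:floor(nc / 2))
  m[ri, ci]
}

#' Power spectrum of a micrograph
#'
#' Applies a 2D window, takes the discrete Fourier transform, and returns
#' the zero-frequency-centred magnitude with axes calibrated in cycles per
#' Angstrom (so a plane spacing d produces spots at radius `1/d`).
#'
#' @param image A [micrograph()]; both sides must be at least 64 px.
#' @param window `"hann"` (default; suppresses edge-discontinuity streaks)
#'   or `"none"`.
#' @return Object of class `power_spectrum`: `magnitude` matrix, `fx`/`fy`
#'   frequency axes (Å⁻¹; fy increases downward like image y), `df`
#'   (reciprocal-space pixel, Å⁻¹) and `pixel_size`.
#' @export
power_spectrum <- function(image, window = c("hann", "none")) {
  stopifnot(inherits(image, "micrograph"))
  window <- match.arg(window)
  px <- image$pixel_size
  m <- image$pixels
  nr <- nrow(m)
  nc <- ncol(m)
  if (nr < 64 || nc < 64) {
    stop("invalid input: image must be at least 64x64 for spectral analysis",
         call. = FALSE)
  }
  if (window == "hann") m <- m * outer(.hann(nr), .hann(nc))
  mag <- .fftshift2(Mod(stats::fft(m)))
  fy <- (seq_len(nr) - 1 - floor(nr / 2)) / (nr * px)
  fx <- (seq_len(nc) - 1 - floor(nc / 2)) / (nc * px)
  structure(list(magnitude = mag, fx = fx, fy = fy,
                 df = 1 / (min(nr, nc) * px), pixel_size = px),
            class = "power_spectrum")
}

#' Detect Friedel-paired spots in a power spectrum
#'
#' Local spectral maxima outside a central exclusion disc are thresholded
#' (relative to the strongest off-centre magnitude, and against a
#' noise floor of 10x the median magnitude so pure noise yields no spots),
#' refined by a 3x3 magnitude centroid, and paired by Friedel symmetry
#' (partner at angle + pi within angular/radial tolerance). Unpaired maxima
#' are discarded; one spot is reported per pair.
#'
#' @param spectrum A [power_spectrum()].
#' @param prominence Minimum magnitude as a fraction of the strongest
#'   off-centre magnitude (default 0.1).
#' @param exclusion_radius Central disc to ignore (Å⁻¹); default
#'   `2/(side * pixel_size)`, i.e. two reciprocal pixels around DC.
#' @param noise_floor Minimum magnitude in multiples of the median
#'   off-centre magnitude (default 10).
#' @param angle_tol Friedel angular tolerance (radians; default 5 degrees).
#' @param radius_tol Friedel relative radial tolerance (default 0.05).
#' @param max_candidates Strongest maxima considered before pairing.
#' @return Data frame of class `spectrum_spots` with `radius` (Å⁻¹),
#'   `angle` (radians in \[0, pi)) and `magnitude`, sorted by radius.
#'   May be empty.
#' @export
detect_spots <- function(spectrum, prominence = 0.1, exclusion_radius = NULL,
                         noise_floor = 10, angle_tol = 5 * pi / 180,
                         radius_tol = 0.05, max_candidates = 40) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  mag <- spectrum$magnitude
  nr <- nrow(mag)
  nc <- ncol(mag)
  FX <- matrix(spectrum$fx, nr, nc, byrow = TRUE)
  FY <- matrix(spectrum$fy, nr, nc)
  R <- sqrt(FX^2 + FY^2)
  if (is.null(exclusion_radius)) exclusion_radius <- 2 * spectrum$df
  outside <- R >= exclusion_radius
  if (!any(outside)) return(.empty_spots())
  thr <- max(prominence * max(mag[outside]),
             noise_floor * stats::median(mag[outside]))
  # 8-neighbourhood local maxima in the interior
  core <- mag[2:(nr - 1), 2:(nc - 1)]
  is_max <- core >= mag[1:(nr - 2), 2:(nc - 1)] &
            core >= mag[3:nr,       2:(nc - 1)] &
            core >= mag[2:(nr - 1), 1:(nc - 2)] &
            core >= mag[2:(nr - 1), 3:nc] &
            core >= mag[1:(nr - 2), 1:(nc - 2)] &
            core >= mag[1:(nr - 2), 3:nc] &
            core >= mag[3:nr,       1:(nc - 2)] &
            core >= mag[3:nr,       3:nc] &
            core > thr &
            outside[2:(nr - 1), 2:(nc - 1)]
  idx <- which(is_max, arr.ind = TRUE)
  if (!nrow(idx)) return(.empty_spots())
  idx <- idx + 1L  # back to full-matrix indices
  o <- order(mag[idx], decreasing = TRUE)
  idx <- idx[o[seq_len(min(nrow(idx), max_candidates))], , drop = FALSE]
  # centroid refinement over the 3x3 neighbourhood
  cand <- t(apply(idx, 1, function(rc) {
    rr <- (rc[1] - 1):(rc[1] + 1)
    cc <- (rc[2] - 1):(rc[2] + 1)
    w <- mag[rr, cc]
    fx <- sum(w * matrix(spectrum$fx[cc], 3, 3, byrow = TRUE)) / sum(w)
    fy <- sum(w * spectrum$fy[rr]) / sum(w)
    c(fx = fx, fy = fy, magnitude = mag[rc[1], rc[2]])
  }))
  radius <- sqrt(cand[, "fx"]^2 + cand[, "fy"]^2)
  angle <- atan2(cand[, "fy"], cand[, "fx"]) %% (2 * pi)
  used <- rep(FALSE, nrow(cand))
  spots <- list()
  for (i in seq_len(nrow(cand))) {
    if (used[i]) next
    # angular distance to the Friedel partner position of i
    dang <- abs(((angle - (angle[i] + pi)) + pi) %% (2 * pi) - pi)
    drad <- abs(radius - radius[i]) / pmax(radius, radius[i])
    j <- which(!used & seq_along(used) != i & dang <= angle_tol &
                 drad <= radius_tol)
    if (!length(j)) next
    j <- j[which.max(cand[j, "magnitude"])]
    used[c(i, j)] <- TRUE
    spots[[length(spots) + 1L]] <- data.frame(
      radius = mean(radius[c(i, j)]),
      angle = angle[i] %% pi,
      magnitude = mean(cand[c(i, j), "magnitude"]))
  }
  if (!length(spots)) return(.empty_spots())
  out <- do.call(rbind, spots)
  out <- out[order(out$radius), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("spectrum_spots", "data.frame")
  out
}

.empty_spots <- function() {
  out <- data.frame(radius = numeric(0), angle = numeric(0),
                    magnitude = numeric(0))
  class(out) <- c("spectrum_spots", "data.frame")
  out
}

# Cluster sorted spot radii into orders: a new cluster starts where the
# radius jumps by more than `gap` relative to the cluster mean.
.radius_clusters <- function(radius, gap = 0.15) {
  cl <- integer(length(radius))
  cl[1] <- 1L
  for (i in seq_along(radius)[-1]) {
    ref <- mean(radius[cl == cl[i - 1]])
    cl[i] <- if (radius[i] > ref * (1 + gap)) cl[i - 1] + 1L else cl[i - 1]
  }
  cl
}

#' Lattice spacing and parameter from detected spots
#'
#' Groups spots into first- and higher-order radius clusters; the plane
#' spacing is `d = 1/mean(first-order radii)`. The lattice parameter
#' follows the projection/phase mapping: a square pattern of a cubic phase
#' viewed along \[001\] (or a hexagonal \[111\] pattern of Im3m identified by
#' its `sqrt(2)` secondary ring) has first-order \{110\} spots, so
#' `a = d*sqrt(2)`; the inverse hexagonal phase gives `a = 2*d/sqrt(3)`.
#' Pattern geometry (4 spots at 90 degrees, or 6 at 60) is tested within an
#' angular tolerance and reported as `pattern_ok`; inconsistent geometry
#' still reports values.
#'
#' @param spots A `spectrum_spots` data frame from [detect_spots()].
#' @param projection `"square"` (needs >= 2 pairs) or `"hexagonal"`
#'   (needs >= 3 pairs).
#' @param phase_hint Optional `"Pn3m"`, `"Im3m"` or `"HexagonalP6mm"`.
#'   When absent, a square pattern is read as a cubic \[001\] projection and
#'   a hexagonal pattern as Im3m if a `sqrt(2)` second ring is present,
#'   otherwise as the inverse hexagonal phase.
#' @param angle_tol Angular tolerance (radians) for the geometry test.
#' @return List of class `lattice_estimate`: `d` (Å), `a` (Å),
#'   `pattern_ok`, `order_ratio` (second/first radius or `NA`),
#'   `n_first_order`, `phase_assumed`.
#' @export
lattice_from_spots <- function(spots, projection = c("square", "hexagonal"),
                               phase_hint = NULL,
                               angle_tol = 8 * pi / 180) {
  projection <- match.arg(projection)
  need <- if (projection == "square") 2L else 3L
  if (nrow(spots) < need) {
    stop(sprintf("need at least %d spot pairs for a %s pattern", need,
                 projection), call. = FALSE)
  }
  cl <- .radius_clusters(spots$radius)
  first <- spots[cl == 1L, , drop = FALSE]
  d <- 1 / mean(first$radius)
  order_ratio <- if (any(cl == 2L)) {
    mean(spots$radius[cl == 2L]) / mean(first$radius)
  } else NA_real_
  ang <- sort(first$angle)
  gaps <- diff(c(ang, ang[1] + pi))
  pattern_ok <- if (projection == "square") {
    nrow(first) == 2L && all(abs(gaps - pi / 2) <= angle_tol)
  } else {
    nrow(first) == 3L && all(abs(gaps - pi / 3) <= angle_tol)
  }
  if (is.null(phase_hint)) {
    phase_hint <- if (projection == "square") {
      "cubic[001]"
    } else if (!is.na(order_ratio) && abs(order_ratio - sqrt(2)) < 0.05 * sqrt(2)) {
      "Im3m"
    } else {
      "HexagonalP6mm"
    }
  }
  a <- switch(phase_hint,
    Pn3m = , Im3m = , `cubic[001]` = d * sqrt(2),
    HexagonalP6mm = 2 * d / sqrt(3),
    NA_real_)
  structure(list(d = d, a = a, pattern_ok = pattern_ok,
                 order_ratio = order_ratio, n_first_order = nrow(first),
                 phase_assumed = phase_hint),
            class = "lattice_estimate")
}

#' @export
print.lattice_estimate <- function(x, ...) {
  cat(sprintf(
    "<lattice_estimate> d = %.2f A, a = %.2f A (%s), pattern %s%s\n",
    x$d, x$a, x$phase_assumed, if (x$pattern_ok) "ok" else "INCONSISTENT",
    if (!is.na(x$order_ratio)) sprintf(", order ratio %.3f", x$order_ratio)
    else ""))
  invisible(x)
}

#' Periodic spacing along a grayscale line profile
#'
#' Interpolates the image along a segment, removes a linear trend, and takes
#' the dominant period from the first autocorrelation peak (parabolically
#' refined). The mean peak-to-peak distance of the profile maxima is also
#' reported. An aperiodic profile (no autocorrelation peak above the
#' threshold) gives a no-period result rather than an error.
#'
#' @param image A [micrograph()].
#' @param start,end `c(x, y)` segment end points in pixel coordinates.
#' @param step Sampling step along the segment (px).
#' @param acf_threshold Minimum autocorrelation at the period (default 0.2).
#' @return List of class `line_profile_spacing`: `spacing` (Å or `NA`),
#'   `mean_peak_to_peak` (Å or `NA`), `ok` flag, `profile` data frame
#'   (`position` in Å along the segment, `intensity`).
#' @export
line_profile_spacing <- function(image, start, end, step = 0.5,
                                 acf_threshold = 0.2) {
  stopifnot(inherits(image, "micrograph"))
  len <- sqrt(sum((end - start)^2))
  if (len < 8 * step) stop("segment too short", call. = FALSE)
  t <- seq(0, len, by = step)
  xs <- start[1] + t / len * (end[1] - start[1])
  ys <- start[2] + t / len * (end[2] - start[2])
  prof <- .interp2(image$pixels, xs, ys)
  out <- list(spacing = NA_real_, mean_peak_to_peak = NA_real_, ok = FALSE,
              profile = data.frame(position = t * image$pixel_size,
                                   intensity = prof))
  class(out) <- "line_profile_spacing"
  if (stats::sd(prof) < .Machine$double.eps^0.5) return(out)
  res <- stats::resid(stats::lm(prof ~ t))
  ac <- as.numeric(stats::acf(res, lag.max = floor(length(res) * 0.8),
                              plot = FALSE, demean = TRUE)$acf)
  n <- length(ac)
  locmax <- which(ac[2:(n - 1)] > ac[1:(n - 2)] &
                  ac[2:(n - 1)] >= ac[3:n]) + 1L
  locmax <- locmax[locmax > 2 & ac[locmax] >= acf_threshold]
  if (!length(locmax)) return(out)
  lag <- locmax[1]
  off <- .parabolic_offset(ac[lag - 1], ac[lag], ac[lag + 1])
  out$spacing <- (lag - 1 + off) * step * image$pixel_size
  # peak-to-peak on a lightly smoothed profile
  sm <- stats::filter(prof, rep(1 / 5, 5), sides = 2)
  sm[is.na(sm)] <- prof[is.na(sm)]
  pk <- which(sm[2:(length(sm) - 1)] > sm[1:(length(sm) - 2)] &
              sm[2:(length(sm) - 1)] >= sm[3:length(sm)]) + 1L
  if (length(pk) >= 2) {
    out$mean_peak_to_peak <- mean(diff(pk)) * step * image$pixel_size
  }
  out$ok <- TRUE
  out
}

#' Tally manually classified particle counts
#'
#' The split between liquid-crystalline particles and plain lamellar
#' vesicles on micrographs is a manual count; this helper turns labelled
#' counts into percentages.
#'
#' @param counts Named integer vector of per-class counts.
#' @return Data frame with `class`, `count`, `percentage`.
#' @export
#' @examples
#' tally_particle_classes(c(llc = 180, vesicle = 20))
tally_particle_classes <- function(counts) {
  if (is.null(names(counts)) || any(counts < 0)) {
    stop("counts must be a named non-negative vector", call. = FALSE)
  }
  data.frame(class = names(counts), count = as.integer(counts),
             percentage = 100 * as.numeric(counts) / sum(counts),
             row.names = NULL)
}
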