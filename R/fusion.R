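# GUV payload-delivery quantification: line intensity profiles, the
# inner-minus-outer intensity statistic, and per-group histograms.

#' Intensity profile through a GUV centre
#'
#' Samples the image along a chord through the annotated centre spanning
#' `span` vesicle radii, by bilinear interpolation. Positions are reported
#' relative to the centre in microns. If the chord exits the image it is
#' truncated and flagged.
#'
#' @param image A [guv_image()].
#' @param angle Chord direction (radians; 0 = horizontal).
#' @param span Chord length in multiples of the radius (default 3).
#' @param step Sampling step (px).
#' @return Data frame `position` (µm, centred), `intensity`, with attribute
#'   `truncated`.
#' @export
intensity_profile <- function(image, angle = 0, span = 3, step = 0.5) {
  stopifnot(inherits(image, "guv_image"))
  if (span < 3) stop("chord must span at least 3 radii", call. = FALSE)
  half <- span / 2 * image$radius
  t <- seq(-half, half, by = step)
  xs <- image$centre[1] + t * cos(angle)
  ys <- image$centre[2] + t * sin(angle)
  inside <- xs >= 1 & xs <= ncol(image$pixels) &
            ys >= 1 & ys <= nrow(image$pixels)
  truncated <- !all(inside)
  t <- t[inside]
  out <- data.frame(position = t * image$pixel_size,
                    intensity = .interp2(image$pixels, xs[inside],
                                         ys[inside]))
  attr(out, "truncated") <- truncated
  out
}

#' Inner-minus-outer GUV intensity statistic
#'
#' Averages the image over an inner disc (a fraction of the vesicle radius,
#' avoiding the membrane ring) and over a background annulus outside the
#' vesicle; their difference is the delivery statistic. A strictly positive
#' difference scores a delivery event; zero or negative does not.
#'
#' @param image A [guv_image()].
#' @param inner_fraction Inner-disc radius as a fraction of the vesicle
#'   radius (default 0.5).
#' @param annulus `c(inner, outer)` annulus radii in multiples of the
#'   vesicle radius (default 1.2–1.5); the outer circle must lie inside the
#'   image.
#' @param threshold Delivery decision threshold (AU, default 0; the
#'   comparison is strict).
#' @return Object of class `fusion_measurement`: `inner_mean`, `outer_mean`,
#'   `delta_i`, `delivered`, `threshold`.
#' @export
delta_i <- function(image, inner_fraction = 0.5, annulus = c(1.2, 1.5),
                    threshold = 0) {
  stopifnot(inherits(image, "guv_image"))
  if (inner_fraction <= 0 || inner_fraction >= annulus[1]) {
    stop("regions must not overlap: inner_fraction < annulus[1]",
         call. = FALSE)
  }
  if (annulus[1] >= annulus[2]) stop("annulus must have inner < outer",
                                     call. = FALSE)
  R <- image$radius
  cx <- image$centre[1]
  cy <- image$centre[2]
  if (cx - annulus[2] * R < 1 || cx + annulus[2] * R > ncol(image$pixels) ||
      cy - annulus[2] * R < 1 || cy + annulus[2] * R > nrow(image$pixels)) {
    stop("annulus clipped by image border", call. = FALSE)
  }
  X <- matrix(seq_len(ncol(image$pixels)), nrow(image$pixels),
              ncol(image$pixels), byrow = TRUE)
  Y <- matrix(seq_len(nrow(image$pixels)), nrow(image$pixels),
              ncol(image$pixels))
  dist <- sqrt((X - cx)^2 + (Y - cy)^2)
  inner_mean <- mean(image$pixels[dist <= inner_fraction * R])
  outer_mean <- mean(image$pixels[dist >= annulus[1] * R &
                                    dist <= annulus[2] * R])
  di <- inner_mean - outer_mean
  structure(list(inner_mean = inner_mean, outer_mean = outer_mean,
                 delta_i = di, delivered = di > threshold,
                 threshold = threshold),
            class = "fusion_measurement")
}

#' @export
print.fusion_measurement <- function(x, ...) {
  cat(sprintf("<fusion_measurement> dI = %+.2f AU (%s)\n", x$delta_i,
              if (x$delivered) "delivered" else "not delivered"))
  invisible(x)
}

# Coerce a list of fusion_measurement (optionally named groups) or a data
# frame into the canonical measurement table.
.as_measurement_df <- function(measurements, group = NULL) {
  if (is.data.frame(measurements)) {
    df <- measurements
    if (!"delta_i" %in% names(df)) {
      stop("measurements need a delta_i column", call. = FALSE)
    }
    if (!"delivered" %in% names(df)) df$delivered <- df$delta_i > 0
    if (!"group" %in% names(df)) df$group <- rep_len("all", nrow(df))
    return(df)
  }
  df <- data.frame(
    delta_i = vapply(measurements, `[[`, 0, "delta_i"),
    delivered = vapply(measurements, `[[`, TRUE, "delivered"))
  df$group <- if (!is.null(group)) rep_len(group, nrow(df)) else "all"
  df
}

#' Histogram of delivery statistics with per-group delivered fractions
#'
#' Bins pooled delta-I values (Freedman–Diaconis bin width by default) and
#' reports per-group counts and the fraction of measurements scored as
#' delivery events.
#'
#' @param measurements A list of [delta_i()] results or a data frame with
#'   columns `delta_i`, optionally `delivered` and `group`.
#' @param bin_width Bin width (AU); `NULL` uses Freedman–Diaconis on the
#'   pooled values.
#' @param group Optional group labels (recycled) when `measurements` is a
#'   list.
#' @return List of class `delta_i_histogram`: `breaks`, `counts` (pooled),
#'   `counts_by_group` (matrix, groups x bins), `delivered_fraction`
#'   (named), `n`.
#' @export
aggregate_histogram <- function(measurements, bin_width = NULL,
                                group = NULL) {
  df <- .as_measurement_df(measurements, group)
  if (!nrow(df)) stop("need at least one measurement", call. = FALSE)
  x <- df$delta_i
  if (is.null(bin_width)) {
    iqr <- stats::IQR(x)
    bin_width <- if (iqr > 0) 2 * iqr / length(x)^(1 / 3) else
      max(diff(range(x)) / 10, 1)
  }
  lo <- floor(min(x) / bin_width) * bin_width
  breaks <- seq(lo, max(x) + bin_width, by = bin_width)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE, right = FALSE)
  groups <- unique(df$group)
  cbg <- t(vapply(groups, function(g) {
    graphics::hist(x[df$group == g], breaks = breaks, plot = FALSE,
                   right = FALSE)$counts
  }, numeric(length(h$counts))))
  rownames(cbg) <- groups
  frac <- vapply(groups, function(g) mean(df$delivered[df$group == g]),
                 numeric(1))
  structure(list(breaks = h$breaks, counts = h$counts,
                 counts_by_group = cbg,
                 delivered_fraction = stats::setNames(frac, groups),
                 n = nrow(df)),
            class = "delta_i_histogram")
}

#' @export
print.delta_i_histogram <- function(x, ...) {
  cat(sprintf("<delta_i_histogram> n = %d, %d bins\n", x$n,
              length(x$counts)))
  for (g in names(x$delivered_fraction)) {
    cat(sprintf("  %s: delivered fraction %.2f\n", g,
                x$delivered_fraction[[g]]))
  }
  invisible(x)
}

#' Read a GUV annotation table
#'
#' CSV with columns `image`, `cx`, `cy`, `r` (pixel centre/radius) and
#' `group` label, as produced by manual annotation of confocal images.
#'
#' @param path CSV path.
#' @return Data frame with the five required columns.
#' @export
read_guv_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image", "cx", "cy", "r", "group")
  if (!all(need %in% names(df))) {
    stop(sprintf("annotation file must have columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  df
}
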