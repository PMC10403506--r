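#' Construct a 1D scattering profile
#'
#' A scattering profile holds a strictly increasing momentum-transfer grid
#' `q` (in inverse Angstrom) and the measured intensity at each point
#' (arbitrary units). All SAXS indexing operations start from this container.
#'
#' @param q Numeric vector of momentum-transfer values (Å⁻¹), strictly
#'   increasing, all positive.
#' @param intensity Numeric vector of non-negative intensities, same length
#'   as `q`.
#' @param label Free-text sample label.
#' @param truth Optional list of generator ground truth (used by the
#'   synthetic-data module); `NULL` for measured data.
#' @return An object of class `scattering_profile`.
#' @export
scattering_profile <- function(q, intensity, label = "", truth = NULL) {
  if (length(q) == 0L || length(intensity) == 0L) {
    stop("invalid input: empty profile", call. = FALSE)
  }
  if (length(q) != length(intensity)) {
    stop("invalid input: q and intensity lengths differ", call. = FALSE)
  }
  if (any(!is.finite(q)) || any(q <= 0)) {
    stop("invalid input: q values must be finite and positive", call. = FALSE)
  }
  if (any(diff(q) <= 0)) {
    stop("invalid input: q values must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    stop("invalid input: intensities must be finite and non-negative",
         call. = FALSE)
  }
  structure(list(q = as.numeric(q), intensity = as.numeric(intensity),
                 label = label, truth = truth),
            class = "scattering_profile")
}

#' @export
print.scattering_profile <- function(x, ...) {
  cat(sprintf("<scattering_profile> %s: %d points, q in [%.4g, %.4g] 1/A\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$q), min(x$q), max(x$q)))
  if (!is.null(x$truth)) {
    cat(sprintf("  synthetic truth: %s, a = %.4g A, %d reflections\n",
                x$truth$phase, x$truth$a, nrow(x$truth$peaks)))
  }
  invisible(x)
}

#' Read a two-column q/intensity profile from a text file
#'
#' Accepts whitespace- or comma-separated columns; lines starting with `#`
#' are comments. The first column is q (Å⁻¹), the second intensity (AU).
#'
#' @param path File path.
#' @param label Sample label; defaults to the file name.
#' @return A [scattering_profile()].
#' @export
read_saxs_profile <- function(path, label = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("invalid input: empty profile file", call. = FALSE)
  sep <- if (grepl(",", lines[[1]])) "," else ""
  tab <- utils::read.table(text = lines, sep = sep, header = FALSE,
                           col.names = c("q", "intensity"),
                           colClasses = "numeric", fill = FALSE)
  scattering_profile(tab$q, tab$intensity, label = label)
}

#' Write a scattering profile as two-column text
#'
#' @param profile A [scattering_profile()].
#' @param path Output file path.
#' @export
write_saxs_profile <- function(profile, path) {
  stopifnot(inherits(profile, "scattering_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s", profile$label), con)
  writeLines("# q_invA intensity_AU", con)
  writeLines(sprintf("%.8g %.8g", profile$q, profile$intensity), con)
  invisible(path)
}

#' Read a plain Bragg-peak position list (one q per line)
#'
#' @param path File path; `#` comment lines allowed.
#' @return A `bragg_peaks` data frame with columns `q`, `prominence`
#'   (`NA` for externally supplied lists) and `d = 2*pi/q`.
#' @export
read_peak_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  q <- as.numeric(lines)
  if (any(is.na(q))) stop("invalid input: non-numeric peak entries", call. = FALSE)
  bragg_peaks(q)
}

#' Assemble a Bragg-peak table from peak positions
#'
#' @param q Peak positions (Å⁻¹), all positive.
#' @param prominence Optional unitless peak-quality values.
#' @param height Optional background-subtracted peak heights.
#' @return Data frame of class `bragg_peaks`, sorted by ascending q, with the
#'   derived interplanar spacing `d = 2*pi/q` (Å).
#' @export
bragg_peaks <- function(q, prominence = NA_real_, height = NA_real_) {
  if (length(q) && (any(!is.finite(q)) || any(q <= 0))) {
    stop("invalid input: peak q must be finite and positive", call. = FALSE)
  }
  ord <- order(q)
  out <- data.frame(q = as.numeric(q)[ord],
                    prominence = rep_len(as.numeric(prominence), length(q))[ord],
                    height = rep_len(as.numeric(height), length(q))[ord],
                    d = 2 * pi / as.numeric(q)[ord])
  class(out) <- c("bragg_peaks", "data.frame")
  out
}

#' Interplanar spacing from a Bragg-peak position
#'
#' The scattering vector relates the peak position to the lattice-plane
#' spacing as `d = 2*pi/q`.
#'
#' @param q Peak position(s) in Å⁻¹; must be positive.
#' @return Spacing(s) in Å.
#' @export
#' @examples
#' d_spacing(2 * pi / 50)  # 50 A
d_spacing <- function(q) {
  if (any(!is.finite(q)) || any(q <= 0)) {
    stop("domain error: q must be positive", call. = FALSE)
  }
  2 * pi / q
}
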