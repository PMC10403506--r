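# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# Generators take mandatory seeds; nothing in the package touches the global
# RNG without going through here.
.with_seed <- function(seed, code) {
  if (missing(seed) || is.null(seed) || !is.numeric(seed) ||
      length(seed) != 1L || !is.finite(seed)) {
    stop("a single finite numeric `seed` is required", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  code
}

# Bilinear interpolation of matrix `m` at fractional (x = column, y = row)
# coordinates, 1-based. Coordinates are clamped to the grid.
.interp2 <- function(m, x, y) {
  nr <- nrow(m)
  nc <- ncol(m)
  x <- pmin(pmax(x, 1), nc)
  y <- pmin(pmax(y, 1), nr)
  x0 <- pmin(floor(x), nc - 1L)
  y0 <- pmin(floor(y), nr - 1L)
  dx <- x - x0
  dy <- y - y0
  i00 <- cbind(y0, x0)
  i01 <- cbind(y0, x0 + 1)
  i10 <- cbind(y0 + 1, x0)
  i11 <- cbind(y0 + 1, x0 + 1)
  m[i00] * (1 - dx) * (1 - dy) + m[i01] * dx * (1 - dy) +
    m[i10] * (1 - dx) * dy + m[i11] * dx * dy
}

# Quadratic (three-point) sub-grid refinement of an extremum position.
# Returns the fractional offset in [-0.5, 0.5] from the central sample.
.parabolic_offset <- function(ym1, y0, yp1) {
  denom <- ym1 - 2 * y0 + yp1
  if (!is.finite(denom) || abs(denom) < .Machine$double.eps) return(0)
  off <- 0.5 * (ym1 - yp1) / denom
  max(min(off, 0.5), -0.5)
}

.is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Coefficient of determination without summary.lm's perfect-fit warning.
.r_squared <- function(fit, y) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot <= 0) return(NA_real_)
  1 - sum(stats::resid(fit)^2) / ss_tot
}
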