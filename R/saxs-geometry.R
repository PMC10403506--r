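# Water-channel geometry of the inverse mesophases.

#' Approximate lipid chain lengths (Å)
#'
#' Registry of liquid-disordered chain lengths used when deriving
#' water-channel radii: monoolein (C18) about 18 Å, phytantriol about 13 Å.
#'
#' @param lipid `"monoolein"` or `"phytantriol"`.
#' @return Chain length in Å.
#' @export
lipid_chain_length <- function(lipid = c("monoolein", "phytantriol")) {
  lipid <- match.arg(lipid)
  c(monoolein = 18, phytantriol = 13)[[lipid]]
}

#' Water-channel radius of an inverse mesophase
#'
#' For the bicontinuous cubics the radius follows the minimal-surface
#' relations `r_w = 0.391*a - l_c` (Pn3m, double diamond) and
#' `r_w = 0.305*a - l_c` (Im3m, primitive). For the inverse hexagonal phase
#' the close-packed tubule geometry gives `r_w = a/2 - l_min` with
#' `l_min = l_c`.
#'
#' @param phase_name `"Pn3m"`, `"Im3m"` or `"HexagonalP6mm"`.
#' @param a Lattice parameter (Å), positive.
#' @param l_c Lipid chain length (Å), positive; see [lipid_chain_length()].
#' @return Object of class `channel_geometry` with fields `phase`, `a`,
#'   `l_c`, `r_w` (Å) and `negative` flag. A negative radius is reported,
#'   with a warning, rather than suppressed.
#' @export
#' @examples
#' water_channel_radius("HexagonalP6mm", a = 50, l_c = 13)$r_w  # 12 A
water_channel_radius <- function(phase_name, a, l_c) {
  if (!.is_scalar_num(a) || a <= 0) stop("a must be positive", call. = FALSE)
  if (!.is_scalar_num(l_c) || l_c <= 0) {
    stop("l_c must be positive", call. = FALSE)
  }
  coef <- switch(phase_name,
    Pn3m = 0.391,
    Im3m = 0.305,
    HexagonalP6mm = 0.5,
    stop(sprintf("unsupported phase for water-channel geometry: %s",
                 phase_name), call. = FALSE))
  r_w <- coef * a - l_c
  if (r_w < 0) {
    warning(sprintf("negative water-channel radius (%.2f A) for %s",
                    r_w, phase_name))
  }
  structure(list(phase = phase_name, a = a, l_c = l_c, r_w = r_w,
                 negative = r_w < 0),
            class = "channel_geometry")
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf("<channel_geometry> %s: a = %.2f A, l_c = %.1f A, r_w = %.2f A%s\n",
              x$phase, x$a, x$l_c, x$r_w,
              if (x$negative) " (negative!)" else ""))
  invisible(x)
}
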