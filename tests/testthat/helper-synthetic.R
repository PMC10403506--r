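# Exact Bragg-peak positions for a phase/lattice pair, straight from the
# closed-form reflection positions (independent of the detection path).
exact_peak_q <- function(phase, a, n = NULL) {
  if (is.null(n)) n <- switch(phase, Pn3m = 6L, Im3m = 3L,
                              HexagonalP6mm = 3L, 4L)
  refl <- reflection_sequence(phase, n)
  if (attr(refl, "family") == "hexagonal") {
    4 * pi * refl$factor / (sqrt(3) * a)
  } else {
    2 * pi * refl$factor / a
  }
}

# Deterministic spread of lattice parameters over [50, 150] for seed loops.
spread_a <- function(s) 50 + ((s * 37) %% 101)
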