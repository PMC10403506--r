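# Mesophase indexing: allowed-reflection sequences, peak detection,
# spacing-ratio phase assignment and lattice-parameter regression.

# Allowed reflections per phase, in increasing spacing-factor order.
# Cubic factor: sqrt(h^2+k^2+l^2); 2D hexagonal: sqrt(h^2+h*k+k^2);
# lamellar: the integer order. The leading members reproduce the
# characteristic sequences sqrt2:sqrt3:sqrt4:sqrt6:sqrt8:sqrt9 (Pn3m),
# sqrt2:sqrt4:sqrt6 (Im3m), 1:sqrt3:sqrt4 (p6mm) and sqrt6:sqrt8 (Ia3d).
.reflection_table <- function(phase) {
  tabs <- list(
    Pn3m = data.frame(
      h = c(1, 1, 2, 2, 2, 2, 3, 3, 2),
      k = c(1, 1, 0, 1, 2, 2, 1, 1, 2),
      l = c(0, 1, 0, 1, 0, 1, 0, 1, 2)),
    Im3m = data.frame(
      h = c(1, 2, 2, 2, 3, 2, 3, 4),
      k = c(1, 0, 1, 2, 1, 2, 2, 0),
      l = c(0, 0, 1, 0, 0, 2, 1, 0)),
    Ia3d = data.frame(
      h = c(2, 2, 3, 4, 4, 3, 4, 4),
      k = c(1, 2, 2, 0, 2, 3, 2, 3),
      l = c(1, 0, 1, 0, 0, 2, 2, 1)),
    HexagonalP6mm = data.frame(
      h = c(1, 1, 2, 2, 3, 2, 3, 4),
      k = c(0, 1, 0, 1, 0, 2, 1, 0),
      l = c(0, 0, 0, 0, 0, 0, 0, 0)),
    Lamellar = data.frame(h = 1:8, k = 0, l = 0)
  )
  if (!phase %in% names(tabs)) {
    stop(sprintf("unsupported phase: %s", phase), call. = FALSE)
  }
  tab <- tabs[[phase]]
  tab$factor <- switch(.phase_family(phase),
    cubic     = sqrt(tab$h^2 + tab$k^2 + tab$l^2),
    hexagonal = sqrt(tab$h^2 + tab$h * tab$k + tab$k^2),
    lamellar  = as.numeric(tab$h))
  tab
}

.phase_family <- function(phase) {
  switch(phase,
    Pn3m = , Im3m = , Ia3d = "cubic",
    HexagonalP6mm = "hexagonal",
    Lamellar = "lamellar",
    stop(sprintf("unsupported phase: %s", phase), call. = FALSE))
}

#' Allowed-reflection sequence for a mesophase
#'
#' Returns the first `n_reflections` allowed reflections of the phase in
#' increasing spacing-factor order. For the cubic space groups the spacing
#' factor is `sqrt(h^2 + k^2 + l^2)`, for the 2D hexagonal plane group p6mm
#' it is `sqrt(h^2 + h*k + k^2)` (so (10), (11), (20) sit at 1, sqrt(3),
#' sqrt(4)), and for a lamellar stack it is the diffraction order.
#'
#' @param phase_name One of `"Pn3m"`, `"Im3m"`, `"Ia3d"`,
#'   `"HexagonalP6mm"`, `"Lamellar"`.
#' @param n_reflections Number of leading reflections to return.
#' @return Data frame of class `phase_candidate` with columns `h`, `k`, `l`,
#'   `factor`, and attributes `phase` and `family`.
#' @export
#' @examples
#' reflection_sequence("Pn3m", 6)$factor^2  # 2 3 4 6 8 9
reflection_sequence <- function(phase_name, n_reflections) {
  if (!.is_scalar_num(n_reflections) || n_reflections < 1) {
    stop("n_reflections must be a positive count", call. = FALSE)
  }
  tab <- .reflection_table(phase_name)
  n <- min(as.integer(n_reflections), nrow(tab))
  if (n < n_reflections) {
    warning(sprintf("only %d reflections tabulated for %s", n, phase_name))
  }
  out <- tab[seq_len(n), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, phase = phase_name, family = .phase_family(phase_name),
            class = c("phase_candidate", "data.frame"))
}

# ---- background model and peak detection ---------------------------------

# Fit a power-law + constant baseline I = A*q^-p + c to lower-envelope
# anchor points (per-bin low quantile) in log space, so narrow Bragg peaks
# do not pull the baseline up and the decades-spanning low-q region does not
# dominate. A final ratio recalibration (low quantile of I/baseline, which
# for signal-proportional noise tracks the quantile bias of the anchors)
# removes the proportional offset. Falls back to a constant (median) if the
# fit fails.
.fit_background <- function(q, intensity, n_bins = 20, probs = 0.3) {
  n <- length(q)
  bins <- cut(seq_len(n), breaks = min(n_bins, max(2L, n %/% 10L)),
              labels = FALSE)
  anchor <- vapply(split(seq_len(n), bins), function(idx) {
    i <- idx[which.min(abs(intensity[idx] -
                             stats::quantile(intensity[idx], probs)))]
    c(q[i], intensity[i])
  }, numeric(2))
  aq <- anchor[1, ]
  ai <- pmax(anchor[2, ], .Machine$double.eps)
  c0 <- max(min(ai) / 2, .Machine$double.eps)
  ll <- stats::coef(stats::lm(log(pmax(ai - c0, .Machine$double.eps)) ~
                                log(aq)))
  obj <- function(par) {
    bgv <- exp(par[1]) * aq^(-par[2]) + exp(par[3])
    sum((log(ai) - log(bgv))^2)
  }
  opt <- tryCatch(
    stats::optim(c(ll[[1]], -ll[[2]], log(c0)), obj,
                 control = list(maxit = 500)),
    error = function(e) NULL)
  if (is.null(opt) || !all(is.finite(opt$par))) {
    return(rep(stats::median(intensity), n))
  }
  bg <- exp(opt$par[1]) * q^(-opt$par[2]) + exp(opt$par[3])
  ratio <- intensity / bg
  s <- stats::quantile(ratio, 0.35, names = FALSE)
  if (is.finite(s) && s > 0) bg <- bg * s
  bg
}

# Topographic prominence of local maxima `peaks` (indices) of `y`:
# height above the higher of the two key saddles separating the peak from
# the nearest higher ground (or the record minimum to the series edge).
.prominence <- function(y, peaks) {
  vapply(peaks, function(p) {
    left_hi <- which(y[seq_len(p - 1)] > y[p])
    lmin <- if (length(left_hi)) min(y[(max(left_hi) + 1):(p - 1)]) else
      min(y[seq_len(p)])
    right_hi <- which(y[(p + 1):length(y)] > y[p]) + p
    rmin <- if (length(right_hi)) min(y[(p + 1):(min(right_hi) - 1)]) else
      min(y[p:length(y)])
    y[p] - max(lmin, rmin)
  }, numeric(1))
}

#' Detect Bragg peaks in a scattering profile
#'
#' Subtracts a baseline, lightly smooths the residual with a moving
#' average, finds local maxima, and keeps those whose topographic
#' prominence exceeds `min_prominence` times the maximum
#' baseline-subtracted intensity. Maxima closer together than the smoothing
#' window are merged (the more prominent survives), and peak positions are
#' refined to sub-grid precision by three-point parabolic interpolation.
#'
#' @param profile A [scattering_profile()].
#' @param min_prominence Minimum peak prominence as a fraction of the
#'   maximum baseline-subtracted intensity (unitless, in (0, 1]).
#' @param background_model `"powerlaw"` (default; `A*q^-p + c` fitted to
#'   per-bin low-quantile anchors) or `"none"`.
#' @param smooth Moving-average window (odd number of samples); `NULL`
#'   scales with the grid (about 1/130 of the points). Use 1 to disable.
#' @param snr_min Minimum peak prominence in multiples of the local noise
#'   level (rolling MAD of the smoothing residual); guards against noise
#'   bumps in regions where the baseline, and hence the local noise of a
#'   signal-proportional noise process, is large.
#' @return A [bragg_peaks()] data frame sorted by ascending q; empty if no
#'   peak clears the prominence threshold.
#' @export
detect_peaks <- function(profile, min_prominence = 0.05,
                         background_model = c("powerlaw", "none"),
                         smooth = NULL, snr_min = 5) {
  stopifnot(inherits(profile, "scattering_profile"))
  background_model <- match.arg(background_model)
  if (!.is_scalar_num(min_prominence) || min_prominence <= 0) {
    stop("min_prominence must be positive", call. = FALSE)
  }
  q <- profile$q
  y <- profile$intensity
  if (length(y) < 3L) return(bragg_peaks(numeric(0)))
  bg <- if (background_model == "powerlaw") .fit_background(q, y) else 0
  ys <- y - bg
  n <- length(ys)
  if (is.null(smooth)) smooth <- max(3L, round(n / 130) %/% 2L * 2L + 1L)
  local_sd <- rep(0, n)
  if (smooth > 1L && n > smooth) {
    sm <- stats::filter(ys, rep(1 / smooth, smooth), sides = 2)
    sm[is.na(sm)] <- ys[is.na(sm)]
    resid <- ys - as.numeric(sm)
    w <- min(n %/% 2L * 2L - 1L, 101L)
    if (w >= 3L) {
      local_sd <- 1.4826 * stats::runmed(abs(resid), w,
                                         endrule = "constant")
    }
    ys <- as.numeric(sm)
  }
  cand <- which(ys[2:(n - 1)] > ys[1:(n - 2)] &
                ys[2:(n - 1)] >= ys[3:n]) + 1L
  if (!length(cand) || max(ys) <= 0) return(bragg_peaks(numeric(0)))
  prom <- .prominence(ys, cand)
  rel <- prom / max(ys)
  keep <- which(rel >= min_prominence & prom >= snr_min * local_sd[cand])
  if (!length(keep)) return(bragg_peaks(numeric(0)))
  cand <- cand[keep]
  rel <- rel[keep]
  # merge maxima within one smoothing window of a stronger neighbour
  ord <- order(rel, decreasing = TRUE)
  taken <- logical(0)
  sel <- integer(0)
  for (i in ord) {
    if (!length(sel) || all(abs(cand[i] - cand[sel]) > smooth)) {
      sel <- c(sel, i)
    }
  }
  sel <- sel[order(cand[sel])]
  cand <- cand[sel]
  rel <- rel[sel]
  # refine each centre by an intensity-weighted centroid of the raw
  # baseline-subtracted signal over the peak's upper half (cut at 40% of
  # the apex), which averages the point noise a 3-point parabola cannot
  yraw <- y - bg
  q_ref <- vapply(cand, function(i) {
    cut <- 0.4 * ys[i]
    lo <- i
    while (lo > 1L && ys[lo - 1] >= cut && i - lo < 4L * smooth) lo <- lo - 1L
    hi <- i
    while (hi < n && ys[hi + 1] >= cut && hi - i < 4L * smooth) hi <- hi + 1L
    w <- pmax(yraw[lo:hi], 0)
    if (sum(w) <= 0) return(q[i])
    sum(q[lo:hi] * w) / sum(w)
  }, numeric(1))
  bragg_peaks(q_ref, prominence = rel, height = ys[cand])
}

# ---- ratio matching -------------------------------------------------------

# Greedy two-pointer match of observed peak ratios against a candidate's
# expected factor ratios. The anchor (the "first matched peak", assigned to
# the candidate's first reflection) is chosen among the first few observed
# peaks by best match count; peaks before the anchor count as unmatched
# (spurious), expected reflections may be skipped (absent orders), and
# later observed peaks may also go unmatched.
.match_candidate <- function(q, candidate, tol, max_anchor = 4L) {
  f <- candidate$factor
  e <- f / f[1]
  K <- length(q)
  J <- length(e)
  best <- NULL
  for (k0 in seq_len(min(K, max_anchor))) {
    r <- q / q[k0]
    match_obs <- k0
    match_exp <- 1L
    k <- k0 + 1L
    j <- 2L
    while (k <= K && j <= J) {
      dev <- r[k] / e[j] - 1
      if (abs(dev) <= tol) {
        match_obs <- c(match_obs, k)
        match_exp <- c(match_exp, j)
        k <- k + 1L
        j <- j + 1L
      } else if (dev > 0) {
        j <- j + 1L
      } else {
        k <- k + 1L
      }
    }
    devs <- r[match_obs] / e[match_exp] - 1
    cand_fit <- list(match_obs = match_obs, match_exp = match_exp,
                     devs = devs,
                     rms = if (length(devs) > 1) sqrt(mean(devs^2)) else Inf)
    if (is.null(best) ||
        length(cand_fit$match_obs) > length(best$match_obs) ||
        (length(cand_fit$match_obs) == length(best$match_obs) &&
           signif(cand_fit$rms, 9) < signif(best$rms, 9))) {
      best <- cand_fit
    }
  }
  match_obs <- best$match_obs
  match_exp <- best$match_exp
  devs <- best$devs
  indexed <- cbind(
    data.frame(q = q[match_obs]),
    candidate[match_exp, c("h", "k", "l", "factor"), drop = FALSE])
  rownames(indexed) <- NULL
  list(phase = attr(candidate, "phase"),
       family = attr(candidate, "family"),
       indexed = indexed,
       n_matched = length(match_obs),
       rms_ratio_residual = if (length(devs)) sqrt(mean(devs^2)) else NA_real_,
       n_skipped = if (length(match_exp)) max(match_exp) - length(match_exp)
                   else 0L,
       n_candidate_reflections = J)
}

.as_assignment <- function(m) {
  structure(m[c("phase", "family", "indexed", "n_matched",
                "rms_ratio_residual", "n_skipped")],
            class = "phase_assignment")
}

#' Assign a mesophase by Bragg-peak spacing ratios
#'
#' Normalises observed peak positions by the first peak and greedily matches
#' successive ratios to each candidate phase's allowed spacing-factor
#' sequence within a relative tolerance. Candidates are ranked by number of
#' matched peaks (descending), then RMS ratio residual (ascending, compared
#' at 9 significant digits), then fewest skipped candidate reflections
#' (simpler indexing wins).
#'
#' @param peaks A [bragg_peaks()] data frame or numeric vector of peak q.
#' @param candidates Character vector of phase names, or a list of
#'   [reflection_sequence()] candidates. Default Pn3m, Im3m, HexagonalP6mm.
#' @param ratio_tolerance Maximum relative deviation per matched ratio;
#'   default 0.02 separates sqrt(6) from sqrt(8) at realistic precision.
#' @param min_peaks Minimum matched peaks for a confident assignment
#'   (default 3); below this the result is flagged ambiguous.
#' @param n_reflections Reflections drawn per named candidate (default 8).
#' @return Object of class `phase_ranking`: list with `ranking` (data frame),
#'   `assignments` (named list of `phase_assignment`), `top` (phase name or
#'   `NA`), and `ambiguous` flag.
#' @export
assign_phase <- function(peaks,
                         candidates = c("Pn3m", "Im3m", "HexagonalP6mm"),
                         ratio_tolerance = 0.02, min_peaks = 3,
                         n_reflections = 8) {
  if (is.numeric(peaks)) peaks <- bragg_peaks(peaks)
  if (!.is_scalar_num(ratio_tolerance) || ratio_tolerance <= 0 ||
      ratio_tolerance > 0.1) {
    stop("ratio_tolerance must be in (0, 0.1]", call. = FALSE)
  }
  if (is.character(candidates)) {
    candidates <- lapply(candidates, reflection_sequence,
                         n_reflections = n_reflections)
  }
  q <- sort(peaks$q)
  if (length(q) == 0L) {
    return(structure(list(ranking = data.frame(), assignments = list(),
                          top = NA_character_, ambiguous = TRUE),
                     class = "phase_ranking"))
  }
  matches <- lapply(candidates, .match_candidate, q = q, tol = ratio_tolerance)
  ranking <- data.frame(
    phase = vapply(matches, `[[`, "", "phase"),
    n_matched = vapply(matches, `[[`, 0L, "n_matched"),
    rms_ratio_residual = vapply(matches, `[[`, 0, "rms_ratio_residual"),
    n_skipped = vapply(matches, `[[`, 0L, "n_skipped"),
    n_candidate_reflections = vapply(matches, `[[`, 0L,
                                     "n_candidate_reflections"))
  rms_key <- signif(ranking$rms_ratio_residual, 9)
  rms_key[is.na(rms_key)] <- Inf
  ord <- order(-ranking$n_matched, rms_key, ranking$n_skipped,
               ranking$n_candidate_reflections)
  ranking <- ranking[ord, , drop = FALSE]
  rownames(ranking) <- NULL
  matches <- matches[ord]
  ambiguous <- ranking$n_matched[1] < min_peaks
  if (nrow(ranking) > 1) {
    tie <- ranking$n_matched[1] == ranking$n_matched[2] &&
      isTRUE(all.equal(rms_key[ord][1], rms_key[ord][2])) &&
      ranking$n_skipped[1] == ranking$n_skipped[2]
    ambiguous <- ambiguous || tie
  }
  structure(list(
    ranking = ranking,
    assignments = stats::setNames(lapply(matches, .as_assignment),
                                  ranking$phase),
    top = if (ambiguous) NA_character_ else ranking$phase[1],
    ambiguous = ambiguous), class = "phase_ranking")
}

#' @export
print.phase_ranking <- function(x, ...) {
  cat("<phase_ranking>",
      if (x$ambiguous) "AMBIGUOUS" else sprintf("top: %s", x$top), "\n")
  if (nrow(x$ranking)) print(x$ranking, ...)
  invisible(x)
}

#' Force an indexing of peaks onto a candidate's leading reflections
#'
#' Maps the i-th observed peak to the i-th allowed reflection of the phase,
#' with no ratio gating. Used to probe deliberate mis-indexing: an incorrect
#' forced assignment degrades the regression intercept and the RMS ratio
#' residual relative to the correct phase on the same peaks.
#'
#' @param peaks A [bragg_peaks()] data frame or numeric vector of peak q.
#' @param phase_name Candidate phase name.
#' @return A `phase_assignment`.
#' @export
force_index <- function(peaks, phase_name) {
  if (is.numeric(peaks)) peaks <- bragg_peaks(peaks)
  q <- sort(peaks$q)
  cand <- reflection_sequence(phase_name, length(q))
  if (nrow(cand) < length(q)) {
    stop("not enough tabulated reflections to index all peaks", call. = FALSE)
  }
  e <- cand$factor / cand$factor[1]
  devs <- (q / q[1]) / e - 1
  indexed <- cbind(data.frame(q = q),
                   cand[, c("h", "k", "l", "factor"), drop = FALSE])
  rownames(indexed) <- NULL
  structure(list(phase = phase_name, family = attr(cand, "family"),
                 indexed = indexed, n_matched = length(q),
                 rms_ratio_residual = sqrt(mean(devs^2)),
                 n_skipped = 0L),
            class = "phase_assignment")
}

# ---- lattice regression ---------------------------------------------------

.a_from_q <- function(family, factor, q) {
  switch(family,
    cubic     = 2 * pi * factor / q,
    hexagonal = 4 * pi * factor / (sqrt(3) * q),
    lamellar  = 2 * pi * factor / q)
}

.a_from_slope <- function(family, slope) {
  switch(family,
    cubic     = 2 * pi / slope,
    hexagonal = 4 * pi / (sqrt(3) * slope),
    lamellar  = 2 * pi / slope)
}

#' Fit the lattice parameter from an indexed peak set
#'
#' Per-peak lattice parameters follow `a = 2*pi*sqrt(h^2+k^2+l^2) / q` for
#' cubic phases and `a = 4*pi*sqrt(h^2+h*k+k^2) / (sqrt(3)*q)` for the 2D
#' hexagonal phase. The pooled estimate comes from the slope of an ordinary
#' least-squares regression of q on the spacing factor with a free
#' intercept; a near-zero intercept is the quality-control evidence that the
#' phase was assigned correctly.
#'
#' @param assignment A `phase_assignment` (from [assign_phase()]'s
#'   `assignments` or [force_index()]).
#' @param intercept_qc Absolute intercept (Å⁻¹) below which the fit passes
#'   QC; default 0.005.
#' @return Object of class `lattice_fit`: `a` (Å), `per_peak_a`, `slope`,
#'   `intercept` (Å⁻¹; `NA` with a single peak), `r_squared`, `qc_pass`.
#' @export
fit_lattice <- function(assignment, intercept_qc = 0.005) {
  if (!inherits(assignment, "phase_assignment")) {
    stop("invalid assignment: expected a phase_assignment", call. = FALSE)
  }
  family <- .phase_family(assignment$phase)  # errors on unknown phase
  idx <- assignment$indexed
  if (is.null(idx) || nrow(idx) < 1L) {
    stop("invalid assignment: no indexed peaks", call. = FALSE)
  }
  per_peak <- .a_from_q(family, idx$factor, idx$q)
  if (nrow(idx) == 1L) {
    out <- list(phase = assignment$phase, a = per_peak,
                per_peak_a = per_peak, slope = idx$q / idx$factor,
                intercept = NA_real_, r_squared = NA_real_, qc_pass = NA)
  } else {
    fit <- stats::lm(q ~ factor, data = idx)
    cf <- stats::coef(fit)
    out <- list(phase = assignment$phase,
                a = .a_from_slope(family, cf[["factor"]]),
                per_peak_a = per_peak,
                slope = cf[["factor"]],
                intercept = cf[["(Intercept)"]],
                r_squared = .r_squared(fit, idx$q),
                qc_pass = abs(cf[["(Intercept)"]]) < intercept_qc)
  }
  structure(out, class = "lattice_fit")
}

#' @export
print.lattice_fit <- function(x, ...) {
  cat(sprintf("<lattice_fit> %s: a = %.2f A (%d peaks)\n",
              x$phase, x$a, length(x$per_peak_a)))
  if (!is.na(x$intercept)) {
    cat(sprintf("  intercept %.3g 1/A (QC %s), R^2 = %.6f\n", x$intercept,
                if (isTRUE(x$qc_pass)) "pass" else "FAIL", x$r_squared))
  }
  invisible(x)
}
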