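# Sample-level report assembly: cross-technique comparison and a
# serialisable characterisation report.

#' Compare lattice-parameter estimates from two techniques
#'
#' Absolute and relative difference between a scattering-derived and an
#' image-derived lattice parameter (or any two positive estimates); the
#' relative difference is scaled by the mean of the two.
#'
#' @param saxs_a,fft_a Estimates (Å), both positive.
#' @return List with `abs_diff` (Å) and `rel_diff_pct` (%).
#' @export
#' @examples
#' compare_estimates(148.5, 142.6)
compare_estimates <- function(saxs_a, fft_a) {
  if (!.is_scalar_num(saxs_a) || saxs_a <= 0 ||
      !.is_scalar_num(fft_a) || fft_a <= 0) {
    stop("both estimates must be positive", call. = FALSE)
  }
  d <- abs(saxs_a - fft_a)
  list(abs_diff = d, rel_diff_pct = 100 * d / mean(c(saxs_a, fft_a)))
}

# Flatten component results into plain lists for serialisation.
.report_component <- function(x) {
  if (is.null(x)) return("absent")
  if (inherits(x, "lattice_fit")) {
    return(list(phase = x$phase, a = x$a, intercept = x$intercept,
                r_squared = x$r_squared, qc_pass = x$qc_pass))
  }
  if (inherits(x, "channel_geometry")) {
    return(list(phase = x$phase, a = x$a, l_c = x$l_c, r_w = x$r_w))
  }
  if (inherits(x, "lattice_estimate")) {
    return(list(d = x$d, a = x$a, order_ratio = x$order_ratio,
                pattern_ok = x$pattern_ok,
                phase_assumed = x$phase_assumed))
  }
  if (inherits(x, "fusion_measurement")) {
    return(list(inner_mean = x$inner_mean, outer_mean = x$outer_mean,
                delta_i = x$delta_i, delivered = x$delivered))
  }
  x
}

#' Assemble a per-sample characterisation report
#'
#' Combines the scattering, image, assay and fusion results for one sample
#' into a single structure in the shape of a cross-technique comparison
#' table. Missing components are marked `"absent"`, never fabricated. The
#' body is hashed (MD5 of its canonical JSON) so identical inputs yield an
#' identical report; no timestamp enters the hashed body.
#'
#' @param sample Sample label (required).
#' @param saxs A [fit_lattice()] result, a list, or `NULL`.
#' @param geometry A [water_channel_radius()] result or `NULL`.
#' @param fft A [lattice_from_spots()] result or `NULL`.
#' @param assays Named list of assay numbers or `NULL`.
#' @param fusion A [delta_i()] result, aggregate list, or `NULL`.
#' @param provenance Named list of input files, seeds and settings.
#' @return Object of class `sample_report`.
#' @export
build_report <- function(sample, saxs = NULL, geometry = NULL, fft = NULL,
                         assays = NULL, fusion = NULL,
                         provenance = list()) {
  if (!is.character(sample) || length(sample) != 1L || !nzchar(sample)) {
    stop("sample label required", call. = FALSE)
  }
  components <- list(saxs = saxs, geometry = geometry, fft = fft,
                     assays = assays, fusion = fusion)
  labels <- unlist(lapply(components, function(x) {
    if (is.list(x) && !is.null(x$sample)) x$sample else NULL
  }))
  if (length(labels) && any(labels != sample)) {
    stop("conflicting sample labels across components", call. = FALSE)
  }
  if (all(vapply(components, is.null, TRUE))) {
    stop("at least one component result required", call. = FALSE)
  }
  body <- list(schema = "llcchar/sample_report/1",
               sample = sample,
               saxs = .report_component(saxs),
               geometry = .report_component(geometry),
               fft = .report_component(fft),
               assays = .report_component(assays),
               fusion = .report_component(fusion),
               provenance = provenance)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(body, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  body$config_hash <- unname(tools::md5sum(tmp))
  structure(body, class = "sample_report")
}

#' Serialise a sample report to JSON (and optional flat text)
#'
#' Identical report bodies serialise to byte-identical JSON.
#'
#' @param report A [build_report()] result.
#' @param path Output JSON path.
#' @param text_path Optional path for a human-readable rendering.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, text_path = NULL) {
  stopifnot(inherits(report, "sample_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  if (!is.null(text_path)) {
    writeLines(utils::capture.output(print(report)), text_path)
  }
  invisible(path)
}

#' @export
print.sample_report <- function(x, ...) {
  cat(sprintf("== characterisation report: %s ==\n", x$sample))
  show <- function(name, comp) {
    if (identical(comp, "absent")) {
      cat(sprintf("  %-8s absent\n", name))
    } else {
      vals <- vapply(comp, function(v) {
        if (is.numeric(v)) sprintf("%.4g", v) else as.character(v)
      }, "")
      cat(sprintf("  %-8s %s\n", name,
                  paste(names(comp), vals, sep = "=", collapse = ", ")))
    }
  }
  show("saxs", x$saxs)
  show("geometry", x$geometry)
  show("fft", x$fft)
  show("assays", x$assays)
  show("fusion", x$fusion)
  cat(sprintf("  hash     %s\n", x$config_hash))
  invisible(x)
}
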