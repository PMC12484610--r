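#' Force-curve container
#'
#' Bundles the raw time series of a single AFM force-spectroscopy
#' measurement: piezo z-position, cantilever deflection, the calibrated
#' cantilever spring constant, and per-sample segment labels
#' (`approach`, `dwell`, `retract`). All quantities are SI
#' (seconds, meters, N/m). Deflection converts to force through Hooke's law,
#' F = k * deflection (see [force_from_deflection()]).
#'
#' @param time Numeric vector of timestamps in seconds, strictly increasing.
#' @param piezo_z Numeric vector of piezo extension in meters; extension
#'   toward the sample is positive.
#' @param deflection Numeric vector of cantilever deflection in meters.
#' @param spring_constant Cantilever spring constant in N/m (> 0).
#' @param segment Character vector of per-sample labels, each one of
#'   `"approach"`, `"dwell"`, `"retract"`. The approach and dwell segments,
#'   when present, must each be a single contiguous run.
#' @param meta Optional list of metadata (probe radius, trigger force,
#'   source identifier, simulation ground truth, ...).
#'
#' @return An object of class `force_curve`.
#' @export
#' @examples
#' t <- seq(0, 1, length.out = 32)
#' fc <- force_curve(t, piezo_z = 2e-6 * t, deflection = rep(0, 32), 0.02,
#'                   segment = rep("approach", 32))
#' fc
force_curve <- function(time, piezo_z, deflection, spring_constant,
                        segment, meta = list()) {
  n <- length(time)
  if (n < 16L) gm_stop("force curve must have at least 16 samples")
  if (length(piezo_z) != n || length(deflection) != n || length(segment) != n) {
    gm_stop("time, piezo_z, deflection and segment must have equal length")
  }
  if (!is.numeric(time) || any(!is.finite(time)) || any(diff(time) <= 0)) {
    gm_stop("time must be finite and strictly increasing")
  }
  check_scalar(spring_constant, "spring_constant", positive = TRUE)
  segment <- as.character(segment)
  bad <- setdiff(unique(segment), c("approach", "dwell", "retract"))
  if (length(bad)) {
    gm_stop("unknown segment label(s): ", paste(bad, collapse = ", "))
  }
  for (seg in c("approach", "dwell")) {
    idx <- which(segment == seg)
    if (length(idx) && any(diff(idx) != 1L)) {
      gm_stop("segment '", seg, "' must be one contiguous run")
    }
  }
  structure(
    list(time = as.numeric(time), piezo_z = as.numeric(piezo_z),
         deflection = as.numeric(deflection), spring_constant = spring_constant,
         segment = segment, meta = meta),
    class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  segs <- table(x$segment)
  cat("<force_curve> ", length(x$time), " samples (",
      paste(names(segs), unname(segs), sep = ": ", collapse = ", "),
      ")\n", sep = "")
  cat("  spring constant: ", format(x$spring_constant), " N/m; duration ",
      format(max(x$time) - min(x$time), digits = 4), " s\n", sep = "")
  invisible(x)
}

# indices of a named segment; errors (naming the segment) when required
segment_indices <- function(curve, seg, required = FALSE) {
  idx <- which(curve$segment == seg)
  if (required && !length(idx)) gm_stop(seg, " segment required")
  idx
}

#' Probe geometry for a spherical AFM tip
#'
#' @param radius Sphere radius in meters; the default is half the diameter of
#'   the 5.24 micrometer silica beads typically glued to tipless cantilevers
#'   for whole-cell stiffness measurements.
#' @return An object of class `probe_geometry`.
#' @export
probe_geometry <- function(radius = 2.62e-6) {
  check_scalar(radius, "radius", positive = TRUE)
  structure(list(radius = radius), class = "probe_geometry")
}

#' Convert cantilever deflection to force
#'
#' Applies Hooke's law elementwise: F = k * deflection, with k the calibrated
#' cantilever spring constant carried by the curve.
#'
#' @param curve A [force_curve()].
#' @return Numeric vector of forces in newtons, same length as the curve.
#' @export
force_from_deflection <- function(curve) {
  stopifnot(inherits(curve, "force_curve"))
  bad <- which(!is.finite(curve$deflection))
  if (length(bad)) {
    gm_stop("non-finite deflection at index(es): ",
            paste(utils::head(bad, 10L), collapse = ", "),
            if (length(bad) > 10L) " ..." else "")
  }
  curve$spring_constant * curve$deflection
}

#' Read a force curve from a delimited text file
#'
#' Expects a header row and the columns `time_s`, `z_m`, `deflection_m`,
#' `segment` (values `approach`/`dwell`/`retract`), all SI units, one file
#' per curve. Comma- and tab-delimited files are both accepted (chosen by
#' file extension: `.tsv`/`.tab` means tab).
#'
#' @param path File path.
#' @param spring_constant Cantilever spring constant in N/m.
#' @param meta Optional metadata list; a `source` entry defaulting to the
#'   file name is added.
#' @return A [force_curve()].
#' @export
read_force_curve <- function(path, spring_constant, meta = list()) {
  df <- read_table(path, schema = c(time_s = "numeric", z_m = "numeric",
                                    deflection_m = "numeric",
                                    segment = "character"))
  meta$source <- meta$source %||% basename(path)
  force_curve(df$time_s, df$z_m, df$deflection_m, spring_constant,
              segment = df$segment, meta = meta)
}

#' Write a force curve to CSV
#'
#' Inverse of [read_force_curve()]; writes `time_s`, `z_m`, `deflection_m`,
#' `segment`.
#'
#' @param curve A [force_curve()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_force_curve <- function(curve, path) {
  stopifnot(inherits(curve, "force_curve"))
  write_table(data.frame(time_s = curve$time, z_m = curve$piezo_z,
                         deflection_m = curve$deflection,
                         segment = curve$segment,
                         stringsAsFactors = FALSE),
              path)
}
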