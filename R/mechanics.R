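#' Hertz force for a sphere indenting an elastic half-space
#'
#' Evaluates the Hertzian contact force
#' \deqn{F = \frac{4}{3} E^* \sqrt{r d^3}}
#' for a rigid sphere of radius `r` indenting an elastic half-space of
#' apparent Young's modulus `e_star` to depth `d`. Only the compressive
#' branch is defined; negative indentation is an error.
#'
#' @param e_star Apparent Young's modulus in Pa (>= 0).
#' @param probe A [probe_geometry()].
#' @param d Indentation depth(s) in meters (>= 0); vectorized.
#' @return Force(s) in newtons.
#' @export
#' @examples
#' hertz_force(1000, probe_geometry(), 2e-6)  # ~6.10e-9 N
hertz_force <- function(e_star, probe, d) {
  stopifnot(inherits(probe, "probe_geometry"))
  check_scalar(e_star, "e_star", nonneg = TRUE)
  if (any(!is.finite(d)) || any(d < 0)) {
    gm_stop("indentation d must be finite and >= 0 (no tensile branch)")
  }
  (4 / 3) * e_star * sqrt(probe$radius * d^3)
}

#' Estimate the tip-sample contact point of an approach segment
#'
#' Implements the classical two-line construction: a least-squares line
#' through the first `baseline_fraction` of approach samples (the flat,
#' undeformed baseline) and a second line through the last
#' `contact_fraction` (where the cantilever is in firm contact with the
#' cell). The contact point is the z at which the two lines intersect,
#' mapped to the nearest approach sample. The baseline line's value at that
#' z gives the deflection offset subtracted before computing forces and
#' indentations downstream.
#'
#' @param curve A [force_curve()] with an approach segment of >= 16 samples.
#' @param baseline_fraction Fraction of approach samples (from the start)
#'   used for the baseline line. Default 0.3.
#' @param contact_fraction Fraction of approach samples (from the end) used
#'   for the contact line. Default 0.2. `baseline_fraction +
#'   contact_fraction` must be in (0, 1].
#' @return An object of class `contact_point` with fields `index` (into the
#'   full curve), `z_contact`, `deflection_offset`, `method`, and the
#'   baseline line coefficients used by [refine_contact_point()].
#' @export
estimate_contact_point <- function(curve, baseline_fraction = 0.3,
                                   contact_fraction = 0.2) {
  stopifnot(inherits(curve, "force_curve"))
  check_scalar(baseline_fraction, "baseline_fraction", positive = TRUE)
  check_scalar(contact_fraction, "contact_fraction", positive = TRUE)
  if (baseline_fraction + contact_fraction > 1) {
    gm_stop("baseline_fraction + contact_fraction must be <= 1")
  }
  app <- segment_indices(curve, "approach", required = TRUE)
  if (length(app) < 16L) gm_stop("approach segment must have >= 16 samples")
  z <- curve$piezo_z[app]
  defl <- curve$deflection[app]
  n <- length(app)
  nb <- max(2L, floor(baseline_fraction * n))
  nc <- max(2L, floor(contact_fraction * n))
  base_fit <- stats::lm.fit(cbind(1, z[seq_len(nb)]),
                            defl[seq_len(nb)])$coefficients
  cont_fit <- stats::lm.fit(cbind(1, z[(n - nc + 1L):n]),
                            defl[(n - nc + 1L):n])$coefficients
  dslope <- cont_fit[2L] - base_fit[2L]
  scale <- max(abs(cont_fit[2L]), abs(base_fit[2L]), 1e-12)
  if (!is.finite(dslope) || abs(dslope) < 1e-9 * scale) {
    gm_stop("no contact detected: baseline and contact lines are parallel")
  }
  z_star <- (base_fit[1L] - cont_fit[1L]) / dslope
  if (z_star < min(z) || z_star > max(z)) {
    gm_stop("no contact detected: line intersection outside the approach z range")
  }
  i_local <- which.min(abs(z - z_star))
  contact_point(index = app[i_local], z_contact = z[i_local],
                deflection_offset = base_fit[1L] + base_fit[2L] * z[i_local],
                method = "two-line", baseline = unname(base_fit))
}

# constructor kept internal-facing; all fields documented on
# estimate_contact_point()
contact_point <- function(index, z_contact, deflection_offset, method,
                          baseline = NULL) {
  structure(list(index = as.integer(index), z_contact = z_contact,
                 deflection_offset = deflection_offset, method = method,
                 baseline = baseline),
            class = "contact_point")
}

#' @export
print.contact_point <- function(x, ...) {
  cat("<contact_point> index ", x$index, " (", x$method, "), z = ",
      format(x$z_contact, digits = 6), " m\n", sep = "")
  invisible(x)
}

#' Fit the Hertz contact model to the post-contact approach region
#'
#' Computes per-sample indentation as piezo travel past contact minus the
#' change in cantilever deflection,
#' d = (z - z_c) - (deflection - deflection_offset), clipped at zero, and
#' fits `F = (4/3) E* sqrt(r d^3)` to the baseline-corrected forces
#' `F = k (deflection - deflection_offset)` over the approach samples past
#' the contact index. The model is linear in E*, so the least-squares
#' solution is computed in closed form and clipped at zero.
#'
#' @param curve A [force_curve()].
#' @param contact A `contact_point` (from [estimate_contact_point()] or
#'   [refine_contact_point()]).
#' @param probe A [probe_geometry()].
#' @return An object of class `hertz_fit` with fields `e_star` (Pa),
#'   `contact`, `max_indentation` (m), `rss` (N^2), `n_points`, `converged`.
#' @export
fit_hertz <- function(curve, contact, probe) {
  stopifnot(inherits(curve, "force_curve"), inherits(contact, "contact_point"),
            inherits(probe, "probe_geometry"))
  app <- segment_indices(curve, "approach", required = TRUE)
  post <- app[app > contact$index]
  if (length(post) < 8L) {
    gm_stop("fewer than 8 post-contact approach samples")
  }
  dz <- curve$piezo_z[post] - contact$z_contact
  ddefl <- curve$deflection[post] - contact$deflection_offset
  d <- pmax(dz - ddefl, 0)
  f <- curve$spring_constant * ddefl
  phi <- (4 / 3) * sqrt(probe$radius * d^3)
  denom <- sum(phi^2)
  e_star <- if (denom > 0) max(0, sum(phi * f) / denom) else 0
  resid <- f - e_star * phi
  structure(list(e_star = e_star, contact = contact,
                 max_indentation = max(d), rss = sum(resid^2),
                 n_points = length(post), converged = TRUE),
            class = "hertz_fit")
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat("<hertz_fit> E* = ", format(x$e_star, digits = 5), " Pa over ",
      x$n_points, " points; max indentation ",
      format(x$max_indentation, digits = 4), " m; RSS ",
      format(x$rss, digits = 4), " N^2\n", sep = "")
  invisible(x)
}

#' Refine a contact-point estimate by residual minimization
#'
#' Iteratively tests candidate contact points around the current estimate:
#' every approach sample within `window` of the estimate is used as a trial
#' contact point (deflection offset taken from the stored baseline line at
#' that z), a Hertz fit is performed for each, and the candidate with the
#' minimal residual sum of squares wins. When the minimum falls on the edge
#' of the window the search re-centers there and repeats, so the refinement
#' descends to a local RSS minimum even if the two-line estimate was off by
#' more than one window width. The returned fit's RSS never exceeds the RSS
#' at the starting estimate.
#'
#' @param curve A [force_curve()].
#' @param estimate A `contact_point` starting estimate.
#' @param probe A [probe_geometry()].
#' @param window Half-width of the candidate window in samples (>= 0).
#'   `window = 0` returns the input estimate with its Hertz fit.
#' @param max_recenter Maximum number of window re-centerings. Default 20.
#' @return A list with elements `contact` (refined `contact_point`, method
#'   `"refined"`) and `fit` (its [fit_hertz()] result).
#' @export
refine_contact_point <- function(curve, estimate, probe, window = 25L,
                                 max_recenter = 20L) {
  stopifnot(inherits(curve, "force_curve"),
            inherits(estimate, "contact_point"),
            inherits(probe, "probe_geometry"))
  if (!is.numeric(window) || length(window) != 1L || window < 0) {
    gm_stop("window must be a single count >= 0")
  }
  window <- as.integer(window)
  app <- segment_indices(curve, "approach", required = TRUE)
  # candidates must leave >= 8 post-contact samples
  feasible <- app[app <= app[length(app)] - 8L]
  base <- estimate$baseline
  candidate_at <- function(i) {
    z_c <- curve$piezo_z[i]
    off <- if (!is.null(base)) base[1L] + base[2L] * z_c else curve$deflection[i]
    contact_point(index = i, z_contact = z_c, deflection_offset = off,
                  method = "refined", baseline = base)
  }
  center <- estimate$index
  best <- NULL
  for (pass in seq_len(max(1L, max_recenter))) {
    lo <- center - window
    hi <- center + window
    cand <- feasible[feasible >= lo & feasible <= hi]
    if ((lo < min(feasible) || hi > max(feasible)) && pass == 1L &&
        window > 0L) {
      gm_warn("refinement window clipped to the approach segment")
    }
    if (!length(cand)) {
      cand <- feasible[which.min(abs(feasible - center))]
    }
    fits <- lapply(cand, function(i) fit_hertz(curve, candidate_at(i), probe))
    rss <- vapply(fits, function(f) f$rss, numeric(1))
    k <- which.min(rss)
    pick <- list(contact = fits[[k]]$contact, fit = fits[[k]])
    if (!is.null(best) && best$fit$rss <= pick$fit$rss) break
    best <- pick
    if (window == 0L || (cand[k] != min(cand) && cand[k] != max(cand))) break
    center <- cand[k]  # minimum on the window edge: re-center and continue
  }
  # keep the original estimate if it was (somehow) better
  if (estimate$index %in% feasible) {
    f0 <- fit_hertz(curve, candidate_at(estimate$index), probe)
    if (f0$rss < best$fit$rss) best <- list(contact = f0$contact, fit = f0)
  }
  best
}

#' Evaluate the standard-linear-solid relaxation model
#'
#' Force relaxation of a standard linear solid (an elastic spring in
#' parallel with two Maxwell elements) during a constant-position dwell:
#' \deqn{F(t) = C + (F_0 - C)\,[A e^{-(t - t_0)\lambda_1} +
#'       (1 - A) e^{-(t - t_0)\lambda_2}]}
#' `C` is the decay asymptote, `F0` the initial force at the start of the
#' dwell, `A` the weight of the fast component, and `lambda1 >= lambda2`
#' the fast and slow relaxation rate constants.
#'
#' @param fit An `sls_fit` (or any list carrying `c`, `f0`, `a`, `lambda1`,
#'   `lambda2`, `t0`).
#' @param t Time(s) in seconds, all `>= t0`.
#' @return Force(s) in newtons.
#' @export
sls_model_eval <- function(fit, t) {
  if (any(t < fit$t0)) gm_stop("t must be >= t0")
  sls_force(t, fit$c, fit$f0, fit$a, fit$lambda1, fit$lambda2, fit$t0)
}

# bare closed form, used by the fitter and the simulator
sls_force <- function(t, c0, f0, a, l1, l2, t0) {
  dt <- t - t0
  c0 + (f0 - c0) * (a * exp(-dt * l1) + (1 - a) * exp(-dt * l2))
}

#' Fit the biexponential SLS relaxation model to a dwell segment
#'
#' Nonlinear least squares of the standard-linear-solid relaxation curve
#' (see [sls_model_eval()]) to the force recorded while the piezo is held
#' at constant position. `t0` is fixed at the first dwell timestamp; the
#' five free parameters are `C`, `F0`, `A`, `lambda1`, `lambda2`.
#' Optimization uses Levenberg-Marquardt (via \pkg{minpack.lm}) with box
#' constraints `0 <= A <= 1`, rates > 0, started from a small grid of
#' log-spaced rate-pair guesses (from 10/duration up to half the sampling
#' rate) with `A = 0.5`, `F0` at the first dwell sample and `C` at the
#' last-decile mean; the best-RSS start wins. After optimization the labels
#' are normalized so that `lambda1 >= lambda2` (swapping the rates and
#' replacing `A` by `1 - A` when needed). Optimizer failure is reported via
#' `converged = FALSE` rather than an error.
#'
#' @param dwell_time Dwell timestamps in seconds (32 or more samples
#'   spanning at least 1 s recommended; fewer than 6 samples is an error).
#' @param dwell_force Forces in newtons, finite.
#' @param rss_threshold Residual-sum-of-squares quality bound in N^2;
#'   `quality_ok` is set when the fitted RSS falls below it. Default 5e-17.
#' @param n_starts Number of log-spaced rate guesses forming the start grid.
#' @return An object of class `sls_fit` with fields `c`, `f0`, `a`,
#'   `lambda1`, `lambda2`, `t0`, `rss`, `converged`, `quality_ok`.
#' @export
fit_sls_relaxation <- function(dwell_time, dwell_force,
                               rss_threshold = 5e-17, n_starts = 6L) {
  n <- length(dwell_time)
  if (length(dwell_force) != n) gm_stop("time and force lengths differ")
  if (n < 6L) gm_stop("fewer dwell samples than model parameters")
  if (any(!is.finite(dwell_force))) gm_stop("dwell forces must be finite")
  check_scalar(rss_threshold, "rss_threshold", positive = TRUE)
  span <- dwell_time[n] - dwell_time[1L]
  if (span <= 0) gm_stop("dwell time must be increasing")
  if (stats::sd(dwell_force) == 0) {
    gm_stop("degenerate input: constant dwell force, relaxation rates unidentifiable")
  }
  t0 <- dwell_time[1L]
  srate <- (n - 1L) / span
  c0 <- mean(dwell_force[dwell_time >= dwell_time[n] - span / 10])
  f00 <- dwell_force[1L]
  rates <- exp(seq(log(10 / span), log(max(srate / 2, 20 / span)),
                   length.out = n_starts))
  resid_fn <- function(p) {
    sls_force(dwell_time, p[1L], p[2L], p[3L], p[4L], p[5L], t0) - dwell_force
  }
  lower <- c(-Inf, -Inf, 0, 1e-9, 1e-9)
  upper <- c(Inf, Inf, 1, Inf, Inf)
  best <- NULL
  pairs <- which(upper.tri(diag(n_starts)), arr.ind = TRUE)
  for (r in seq_len(nrow(pairs))) {
    start <- c(c0, f00, 0.5, rates[pairs[r, 2L]], rates[pairs[r, 1L]])
    res <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = start, lower = lower, upper = upper, fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(res)) next
    rss <- sum(res$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(par = res$par, rss = rss)
  }
  if (is.null(best)) {
    return(structure(list(c = NA_real_, f0 = NA_real_, a = NA_real_,
                          lambda1 = NA_real_, lambda2 = NA_real_, t0 = t0,
                          rss = NA_real_, converged = FALSE,
                          quality_ok = FALSE),
                     class = "sls_fit"))
  }
  p <- best$par
  if (p[4L] < p[5L]) {  # enforce lambda1 >= lambda2 (swap + A -> 1 - A)
    p <- c(p[1L], p[2L], 1 - p[3L], p[5L], p[4L])
  }
  structure(list(c = p[1L], f0 = p[2L], a = p[3L], lambda1 = p[4L],
                 lambda2 = p[5L], t0 = t0, rss = best$rss, converged = TRUE,
                 quality_ok = best$rss < rss_threshold),
            class = "sls_fit")
}

#' @export
print.sls_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<sls_fit> not converged\n")
    return(invisible(x))
  }
  cat("<sls_fit> lambda1 = ", format(x$lambda1, digits = 5),
      " 1/s, lambda2 = ", format(x$lambda2, digits = 5),
      " 1/s, A = ", format(x$a, digits = 4),
      "; RSS ", format(x$rss, digits = 4), " N^2",
      if (x$quality_ok) " (quality ok)" else "", "\n", sep = "")
  invisible(x)
}

#' Mechanics analysis configuration
#'
#' @param probe_radius_m Spherical probe radius (m).
#' @param baseline_fraction,contact_fraction Contact-line fit windows, see
#'   [estimate_contact_point()].
#' @param refine_window Contact refinement half-width in samples.
#' @param rss_threshold_n2 SLS quality bound in N^2.
#' @param baseline_correction Subtract the fitted baseline line from the
#'   whole deflection channel before analysis (off by default; the standard
#'   workflow applies no drift correction).
#' @return A list of class `mechanics_config`.
#' @export
mechanics_config <- function(probe_radius_m = 2.62e-6,
                             baseline_fraction = 0.3, contact_fraction = 0.2,
                             refine_window = 25L, rss_threshold_n2 = 5e-17,
                             baseline_correction = FALSE) {
  structure(list(probe_radius_m = probe_radius_m,
                 baseline_fraction = baseline_fraction,
                 contact_fraction = contact_fraction,
                 refine_window = as.integer(refine_window),
                 rss_threshold_n2 = rss_threshold_n2,
                 baseline_correction = isTRUE(baseline_correction)),
            class = "mechanics_config")
}

#' Extract the per-cell mechanical triple from one force curve
#'
#' Chains contact-point estimation, Hertz refinement and the SLS dwell fit
#' into the per-cell record used throughout downstream analysis: apparent
#' Young's modulus E* plus the fast and slow viscous rate constants
#' lambda1, lambda2. A failure in one stage leaves that stage's values `NA`
#' but preserves the others (with the error message in the diagnostics).
#'
#' @param curve A [force_curve()] with both approach and dwell segments.
#' @param probe A [probe_geometry()]; defaults to the config radius.
#' @param config A [mechanics_config()].
#' @param cell_id Identifier for the record; defaults to the curve's
#'   `meta$source` or `"cell"`.
#' @return A one-row data frame (class `mechanical_record`) with columns
#'   `cell_id`, `e_star_pa`, `lambda1_per_s`, `lambda2_per_s`, `hertz_rss`,
#'   `sls_rss`, `hertz_converged`, `sls_converged`, `sls_quality_ok`,
#'   `error`.
#' @export
analyze_curve <- function(curve, probe = NULL, config = mechanics_config(),
                          cell_id = NULL) {
  stopifnot(inherits(curve, "force_curve"))
  probe <- probe %||% probe_geometry(config$probe_radius_m)
  cell_id <- cell_id %||% (curve$meta$source %||% "cell")
  segment_indices(curve, "approach", required = TRUE)
  segment_indices(curve, "dwell", required = TRUE)
  errors <- character(0)
  if (config$baseline_correction) {
    curve <- subtract_baseline(curve, config$baseline_fraction)
  }
  hertz <- NULL
  contact <- tryCatch(
    estimate_contact_point(curve, config$baseline_fraction,
                           config$contact_fraction),
    error = function(e) { errors <<- c(errors, conditionMessage(e)); NULL })
  if (!is.null(contact)) {
    hertz <- tryCatch(
      refine_contact_point(curve, contact, probe,
                           window = config$refine_window)$fit,
      error = function(e) { errors <<- c(errors, conditionMessage(e)); NULL })
  }
  sls <- NULL
  dwell <- segment_indices(curve, "dwell")
  offset <- if (!is.null(contact)) contact$deflection_offset else 0
  sls <- tryCatch(
    fit_sls_relaxation(curve$time[dwell],
                       curve$spring_constant *
                         (curve$deflection[dwell] - offset),
                       rss_threshold = config$rss_threshold_n2),
    error = function(e) { errors <<- c(errors, conditionMessage(e)); NULL })
  out <- data.frame(
    cell_id = cell_id,
    e_star_pa = if (!is.null(hertz) && hertz$converged) hertz$e_star else NA_real_,
    lambda1_per_s = if (!is.null(sls) && sls$converged) sls$lambda1 else NA_real_,
    lambda2_per_s = if (!is.null(sls) && sls$converged) sls$lambda2 else NA_real_,
    hertz_rss = if (!is.null(hertz)) hertz$rss else NA_real_,
    sls_rss = if (!is.null(sls)) sls$rss else NA_real_,
    hertz_converged = !is.null(hertz) && hertz$converged,
    sls_converged = !is.null(sls) && sls$converged,
    sls_quality_ok = !is.null(sls) && isTRUE(sls$quality_ok),
    error = if (length(errors)) paste(errors, collapse = "; ") else "",
    stringsAsFactors = FALSE)
  class(out) <- c("mechanical_record", class(out))
  out
}

#' Batch-analyze a list of force curves
#'
#' @param curves List of [force_curve()] objects (or a directory path of
#'   per-curve CSV files, in which case `spring_constant` must be given).
#' @param probe,config,spring_constant See [analyze_curve()] and
#'   [read_force_curve()].
#' @return Data frame of per-cell mechanical records.
#' @export
analyze_curves <- function(curves, probe = NULL, config = mechanics_config(),
                           spring_constant = NULL) {
  if (is.character(curves) && length(curves) == 1L && dir.exists(curves)) {
    files <- list.files(curves, pattern = "\\.(csv|tsv)$", full.names = TRUE)
    if (is.null(spring_constant)) {
      gm_stop("spring_constant is required for directory batch mode")
    }
    curves <- lapply(files, read_force_curve, spring_constant = spring_constant)
  }
  out <- do.call(rbind, lapply(seq_along(curves), function(i) {
    analyze_curve(curves[[i]], probe = probe, config = config,
                  cell_id = curves[[i]]$meta$source %||%
                    paste0("cell_", i))
  }))
  rownames(out) <- NULL
  out
}

# optional linear drift correction: subtract the baseline line fitted on the
# first `fraction` of the approach from the entire deflection channel
subtract_baseline <- function(curve, fraction = 0.3) {
  app <- segment_indices(curve, "approach", required = TRUE)
  nb <- max(2L, floor(fraction * length(app)))
  co <- stats::lm.fit(cbind(1, curve$piezo_z[app[seq_len(nb)]]),
                      curve$deflection[app[seq_len(nb)]])$coefficients
  curve$deflection <- curve$deflection - (co[1L] + co[2L] * curve$piezo_z)
  curve
}
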