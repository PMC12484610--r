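#' Configuration for the forward force-curve simulator
#'
#' Defaults mirror a typical whole-cell AFM measurement with a beaded
#' cantilever: 2 um/s approach, 5 nN force trigger, 10 s constant-position
#' dwell, a 5.24 um silica bead (radius 2.62 um) and a spring constant
#' inside the usual 10-25 pN/nm calibration range.
#'
#' @param e_star Apparent Young's modulus of the simulated cell (Pa).
#' @param lambda1,lambda2 Fast and slow relaxation rate constants (1/s),
#'   `lambda1 >= lambda2 > 0`.
#' @param a Fast-component weight in `[0, 1]`.
#' @param f_trigger Approach force trigger (N). Default 5e-9.
#' @param c_fraction Relaxation asymptote C as a fraction of the trigger
#'   force, in `[0, 1)`. Default 0.2 (C = 1 nN at the 5 nN trigger).
#' @param approach_velocity Piezo approach velocity (m/s). Default 2e-6.
#' @param dwell_duration Dwell length (s). Default 10.
#' @param sampling_rate Sampling rate (Hz). Default 200.
#' @param spring_constant Cantilever spring constant (N/m). Default 0.02.
#' @param probe_radius Bead radius (m). Default 2.62e-6.
#' @param contact_z Piezo z at which the probe first touches the cell (m);
#'   sets the baseline length. Default 2e-6.
#' @param noise_sd Additive i.i.d. Gaussian force noise SD (N). Default 0.
#' @param seed Integer RNG seed for the noise.
#' @return A list of class `curve_sim_config`.
#' @export
curve_sim_config <- function(e_star = 2000, lambda1 = 5, lambda2 = 0.2,
                             a = 0.5, f_trigger = 5e-9, c_fraction = 0.2,
                             approach_velocity = 2e-6, dwell_duration = 10,
                             sampling_rate = 200, spring_constant = 0.02,
                             probe_radius = 2.62e-6, contact_z = 2e-6,
                             noise_sd = 0, seed = 1L) {
  check_scalar(e_star, "e_star", nonneg = TRUE)
  check_scalar(lambda1, "lambda1", positive = TRUE)
  check_scalar(lambda2, "lambda2", positive = TRUE)
  if (lambda1 < lambda2) gm_stop("lambda1 must be >= lambda2")
  check_scalar(a, "a")
  if (a < 0 || a > 1) gm_stop("a must lie in [0, 1]")
  check_scalar(f_trigger, "f_trigger", positive = TRUE)
  check_scalar(c_fraction, "c_fraction", nonneg = TRUE)
  if (c_fraction >= 1) gm_stop("c_fraction must be < 1")
  check_scalar(approach_velocity, "approach_velocity", positive = TRUE)
  check_scalar(dwell_duration, "dwell_duration", positive = TRUE)
  check_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  check_scalar(spring_constant, "spring_constant", positive = TRUE)
  check_scalar(probe_radius, "probe_radius", positive = TRUE)
  check_scalar(contact_z, "contact_z", positive = TRUE)
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  structure(as.list(environment()), class = "curve_sim_config")
}

#' Simulate an AFM force curve from the forward Hertz + SLS model
#'
#' Builds the approach segment by advancing the piezo at the configured
#' velocity and solving, per sample, the implicit contact balance
#' `d + F(d)/k = z - z_c` with `F(d) = (4/3) E* sqrt(r d^3)` (the cantilever
#' deflection F/k subtracts from the piezo travel available for
#' indentation), until the force trigger is reached; the dwell segment then
#' follows the standard-linear-solid relaxation with `F0` equal to the
#' trigger force and asymptote `C = c_fraction * f_trigger`. Additive
#' Gaussian force noise (converted to deflection through k) is applied to
#' the whole curve under the configured seed, and the ground-truth
#' parameters are recorded in `meta$truth`.
#'
#' @param config A [curve_sim_config()].
#' @return A [force_curve()] with contiguous `approach` and `dwell`
#'   segments and simulation ground truth in `meta$truth` (including the
#'   true contact sample index).
#' @export
simulate_force_curve <- function(config) {
  stopifnot(inherits(config, "curve_sim_config"))
  cf <- config
  if (cf$e_star <= 0) {
    gm_stop("trigger unreachable: e_star = 0 produces no contact force")
  }
  k <- cf$spring_constant
  r <- cf$probe_radius
  alpha <- (4 / 3) * cf$e_star * sqrt(r)   # F = alpha * d^(3/2)
  d_trig <- (cf$f_trigger / alpha)^(2 / 3)
  z_trig <- cf$contact_z + d_trig + cf$f_trigger / k
  dz <- cf$approach_velocity / cf$sampling_rate
  z <- seq(0, z_trig, by = dz)
  if (z_trig - z[length(z)] > dz / 2) z <- c(z, z_trig) else z[length(z)] <- z_trig
  # implicit solve for indentation: g(d) = d + alpha d^(3/2)/k - s = 0
  s <- pmax(z - cf$contact_z, 0)
  d <- s
  for (i in 1:60) {
    g <- d + alpha * d^1.5 / k - s
    gp <- 1 + 1.5 * alpha * sqrt(d) / k
    d <- pmax(d - g / gp, 0)
  }
  f_app <- alpha * d^1.5
  t_app <- z / cf$approach_velocity
  t_trig <- t_app[length(t_app)]
  n_dwell <- max(2L, round(cf$dwell_duration * cf$sampling_rate))
  t_dwell <- t_trig + seq_len(n_dwell) / cf$sampling_rate
  f_dwell <- sls_force(t_dwell, cf$c_fraction * cf$f_trigger, cf$f_trigger,
                       cf$a, cf$lambda1, cf$lambda2, t_trig)
  time <- c(t_app, t_dwell)
  force <- c(f_app, f_dwell)
  if (cf$noise_sd > 0) {
    force <- force + with_seed(cf$seed, stats::rnorm(length(force), 0,
                                                     cf$noise_sd))
  }
  segment <- c(rep("approach", length(t_app)), rep("dwell", n_dwell))
  truth <- list(e_star = cf$e_star, lambda1 = cf$lambda1,
                lambda2 = cf$lambda2, a = cf$a,
                c = cf$c_fraction * cf$f_trigger, f0 = cf$f_trigger,
                t0 = t_trig, contact_z = cf$contact_z,
                contact_index = which.min(abs(z - cf$contact_z)),
                d_trigger = d_trig)
  force_curve(time = time,
              piezo_z = c(z, rep(z_trig, n_dwell)),
              deflection = force / k,
              spring_constant = k,
              segment = segment,
              meta = list(probe_radius = r, trigger_force = cf$f_trigger,
                          source = paste0("sim_seed", cf$seed),
                          truth = truth, config = unclass(cf)))
}
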