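test_that("force_from_deflection applies Hooke's law and validates input", {
  n <- 20
  fc <- force_curve(seq_len(n), seq_len(n) * 1e-8, rep(250e-9, n), 0.02,
                    rep("approach", n))
  expect_equal(force_from_deflection(fc), rep(5e-9, n))
  fc$deflection <- rep(0, n)
  expect_equal(force_from_deflection(fc), rep(0, n))
  # homogeneity: doubling deflection doubles force everywhere
  fc$deflection <- stats::runif(n)
  f1 <- force_from_deflection(fc)
  fc2 <- fc
  fc2$deflection <- 2 * fc$deflection
  expect_equal(force_from_deflection(fc2), 2 * f1)
  fc$deflection[c(3, 7)] <- NaN
  expect_error(force_from_deflection(fc), "index.*3.*7")
})

test_that("force_curve enforces its invariants", {
  n <- 20
  expect_error(force_curve(rev(seq_len(n)), seq_len(n), seq_len(n), 0.02,
                           rep("approach", n)), "increasing")
  expect_error(force_curve(seq_len(8), seq_len(8), seq_len(8), 0.02,
                           rep("approach", 8)), "16")
  expect_error(force_curve(seq_len(n), seq_len(n), seq_len(n), -1,
                           rep("approach", n)), "spring_constant")
  # approach must be contiguous
  seg <- rep("approach", n)
  seg[10] <- "dwell"
  expect_error(force_curve(seq_len(n), seq_len(n), seq_len(n), 0.02, seg),
               "contiguous")
})

test_that("hertz_force matches the closed form and its scaling laws", {
  pr <- probe_geometry()
  expect_equal(pr$radius, 2.62e-6)
  expect_equal(hertz_force(1000, pr, 0), 0)
  # independent numeric evaluation of (4/3) E* sqrt(r d^3)
  expect_equal(hertz_force(1000, pr, 2e-6),
               (4 / 3) * 1000 * sqrt(2.62e-6 * (2e-6)^3))
  expect_equal(hertz_force(1000, pr, 2e-6), 6.10e-9, tolerance = 1e-3)
  # d^(3/2) scaling: doubling d multiplies F by 2 sqrt(2)
  expect_equal(hertz_force(1000, pr, 4e-6),
               2 * sqrt(2) * hertz_force(1000, pr, 2e-6))
  expect_error(hertz_force(1000, pr, -1e-9), "tensile")
})

test_that("two-line contact estimate finds known contact and is offset-invariant", {
  fc <- quick_curve(noise_sd = 0)
  truth <- fc$meta$truth$contact_index
  est <- estimate_contact_point(fc)
  # the two-line construction is a coarse initializer: on a convex Hertz
  # approach its intersection lands past true contact, within the default
  # refinement window; the refinement stage recovers the exact sample
  expect_lte(abs(est$index - truth), 25)
  refined <- refine_contact_point(fc, est, probe_geometry())
  expect_equal(refined$contact$index, truth)
  # adding a constant deflection offset moves neither line intersection
  fc2 <- fc
  fc2$deflection <- fc$deflection + 3e-8
  est2 <- estimate_contact_point(fc2)
  expect_equal(est2$index, est$index)
  expect_equal(est2$z_contact, est$z_contact)
  # flat curve that never contacts
  expect_error(estimate_contact_point(flat_curve()), "no contact")
})

test_that("refinement recovers the exact contact point and never raises RSS", {
  fc <- quick_curve(noise_sd = 0)
  truth <- fc$meta$truth$contact_index
  est <- estimate_contact_point(fc)
  pr <- probe_geometry()
  # start deliberately 3 samples off; window 10 must recover exactly
  off <- est
  off$index <- truth + 3L
  off$z_contact <- fc$piezo_z[off$index]
  ref <- refine_contact_point(fc, off, pr, window = 10)
  expect_equal(ref$contact$index, truth)
  f_init <- fit_hertz(fc, off, pr)
  expect_lte(ref$fit$rss, f_init$rss)
  # window = 0 returns the starting estimate with its fit
  ref0 <- refine_contact_point(fc, off, pr, window = 0)
  expect_equal(ref0$contact$index, off$index)
  expect_equal(ref0$fit$rss, f_init$rss)
  # on a noisy curve refinement still never increases RSS vs the start
  fcn <- quick_curve(noise_sd = 5e-11, seed = 7)
  estn <- estimate_contact_point(fcn)
  refn <- refine_contact_point(fcn, estn, pr)
  expect_lte(refn$fit$rss, fit_hertz(fcn, estn, pr)$rss)
})

test_that("Hertz fit is forward/inverse consistent and linear in E*", {
  fc <- quick_curve(e_star = 1000, noise_sd = 0)
  pr <- probe_geometry()
  est <- estimate_contact_point(fc)
  fit <- refine_contact_point(fc, est, pr)$fit
  expect_equal(fit$e_star, 1000, tolerance = 1e-3)
  expect_gte(fit$max_indentation, 0)
  # linearity in E*: doubling every force at fixed indentation (spring
  # constant doubled, deflections unchanged) doubles the fitted modulus
  fc2 <- fc
  fc2$spring_constant <- 2 * fc$spring_constant
  fit2 <- fit_hertz(fc2, fit$contact, pr)
  expect_equal(fit2$e_star, 2 * fit_hertz(fc, fit$contact, pr)$e_star,
               tolerance = 1e-12)
  # zero post-contact force means zero modulus
  fc0 <- fc
  fc0$deflection <- rep(0, length(fc0$deflection))
  ct <- fit$contact
  expect_equal(fit_hertz(fc0, ct, pr)$e_star, 0)
  # too few post-contact samples is an error
  late <- ct
  late$index <- max(which(fc$segment == "approach")) - 3L
  late$z_contact <- fc$piezo_z[late$index]
  expect_error(fit_hertz(fc, late, pr), "8 post-contact")
})

test_that("SLS model evaluation honors its boundary conditions", {
  fit <- list(c = 1e-9, f0 = 5e-9, a = 0.6, lambda1 = 5, lambda2 = 0.2,
              t0 = 0)
  expect_equal(sls_model_eval(fit, 0), 5e-9)       # F(t0) = F0
  expect_equal(sls_model_eval(fit, 1e6), 1e-9)     # asymptote C
  # independent numeric evaluation at t = 1
  expect_equal(sls_model_eval(fit, 1),
               1e-9 + 4e-9 * (0.6 * exp(-5) + 0.4 * exp(-0.2)))
  expect_equal(sls_model_eval(fit, 1), 2.326e-9, tolerance = 1e-3)
  expect_error(sls_model_eval(fit, -0.5), "t0")
})

test_that("SLS fit recovers noiseless parameters and normalizes labels", {
  t <- seq(0, 10, by = 0.01)
  f <- 1e-9 + 4e-9 * (0.6 * exp(-5 * t) + 0.4 * exp(-0.2 * t))
  fit <- fit_sls_relaxation(t, f)
  expect_true(fit$converged)
  expect_equal(fit$c, 1e-9, tolerance = 1e-4)
  expect_equal(fit$f0, 5e-9, tolerance = 1e-4)
  expect_equal(fit$a, 0.6, tolerance = 1e-4)
  expect_equal(fit$lambda1, 5, tolerance = 1e-4)
  expect_equal(fit$lambda2, 0.2, tolerance = 1e-4)
  expect_gte(fit$lambda1, fit$lambda2)
  # label-exchange symmetry: swapping (lambda1, A) with (lambda2, 1-A)
  # generates the identical trace, so the fit returns the same labels
  f_swapped <- 1e-9 + 4e-9 * (0.4 * exp(-0.2 * t) + 0.6 * exp(-5 * t))
  expect_equal(f_swapped, f)
  fit2 <- fit_sls_relaxation(t, f_swapped)
  expect_equal(fit2$lambda1, fit$lambda1, tolerance = 1e-6)
  expect_equal(fit2$a, fit$a, tolerance = 1e-6)
  # degenerate inputs
  expect_error(fit_sls_relaxation(t, rep(2e-9, length(t))), "constant")
  expect_error(fit_sls_relaxation(t[1:4], f[1:4]), "fewer")
})

test_that("equal rates collapse the SLS model to a single exponential", {
  t <- seq(0, 10, by = 0.01)
  f <- 1e-9 + 4e-9 * exp(-0.5 * t)  # lambda1 = lambda2 = 0.5, A arbitrary
  fit <- fit_sls_relaxation(t, f)
  expect_true(fit$converged)
  # best single-exponential RSS is 0 here; biexponential must match it
  expect_lt(fit$rss, 1e-22)
})

test_that("SLS fit is invariant to a constant time shift (t0 absorbs it)", {
  t <- seq(0, 8, by = 0.01)
  f <- 2e-9 + 3e-9 * (0.4 * exp(-4 * t) + 0.6 * exp(-0.3 * t))
  f1 <- fit_sls_relaxation(t, f)
  f2 <- fit_sls_relaxation(t + 123.4, f)
  expect_equal(f2$t0 - f1$t0, 123.4)
  expect_equal(f2$lambda1, f1$lambda1, tolerance = 1e-6)
  expect_equal(f2$lambda2, f1$lambda2, tolerance = 1e-6)
  expect_equal(f2$a, f1$a, tolerance = 1e-6)
})

test_that("analyze_curve chains the stages and is deterministic", {
  fc <- quick_curve(e_star = 1500, lambda1 = 4, lambda2 = 0.3, a = 0.5,
                    noise_sd = 0)
  rec <- analyze_curve(fc)
  expect_equal(rec$e_star_pa, 1500, tolerance = 1e-3)
  expect_equal(rec$lambda1_per_s, 4, tolerance = 1e-3)
  expect_equal(rec$lambda2_per_s, 0.3, tolerance = 1e-3)
  expect_true(rec$hertz_converged && rec$sls_converged)
  # no internal randomness: identical rerun
  expect_identical(analyze_curve(fc), rec)
  # dwell segment is required, and named in the error
  app <- fc$segment == "approach"
  fc_app <- force_curve(fc$time[app], fc$piezo_z[app], fc$deflection[app],
                        fc$spring_constant, fc$segment[app])
  expect_error(analyze_curve(fc_app), "dwell")
})

test_that("batch analysis returns one record per curve", {
  curves <- lapply(1:3, function(i) quick_curve(e_star = 1000 * i, seed = i))
  recs <- analyze_curves(curves)
  expect_equal(nrow(recs), 3)
  expect_equal(recs$e_star_pa, c(1000, 2000, 3000), tolerance = 1e-3)
})
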