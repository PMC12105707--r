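test_that("parameter sets validate their domains", {
  expect_error(core_shell_cylinder(R_core = -1), "R_core")
  expect_error(core_shell_cylinder(t_shell = 0), "t_shell")
  expect_error(core_shell_cylinder(scale = -0.1), "scale")
  expect_error(sans_intensity(core_shell_cylinder(), c(0.1, -0.2)), "q")
})

test_that("contrast-matched shell reduces to a solid cylinder", {
  p <- core_shell_cylinder(R_core = 8, t_shell = 25, L = 600,
                           sld_core = 2.0, sld_shell = 6.36,
                           sld_solvent = 6.36, scale = 0.002,
                           background = 0.1)
  q <- default_q_grid(40)
  got <- sans_intensity(p, q)
  Vt <- pi * (8 + 25)^2 * (600 + 50)
  ref <- solid_cylinder_intensity(q, R = 8, L = 600,
                                  contrast = 2.0 - 6.36,
                                  scale = 0.002, background = 0.1,
                                  V_norm = Vt)
  expect_equal(got, ref, tolerance = 1e-6)
})

test_that("the q->0 limit approaches the closed-form forward amplitude", {
  p <- core_shell_cylinder()
  Vc <- pi * p$R_core^2 * p$L
  Vt <- pi * (p$R_core + p$t_shell)^2 * (p$L + 2 * p$t_shell)
  forward <- 1e-4 * p$scale / Vt *
    ((p$sld_core - p$sld_shell) * Vc +
     (p$sld_shell - p$sld_solvent) * Vt)^2 + p$background
  got <- sans_intensity(p, 1e-4)
  expect_lt(abs(got - forward) / (forward - p$background), 1e-3)
})

test_that("intensity scales linearly and never drops below background", {
  p <- core_shell_cylinder()
  q <- default_q_grid(60)
  I1 <- sans_intensity(p, q)
  p2 <- p; p2$scale <- 2 * p$scale
  I2 <- sans_intensity(p2, q)
  expect_equal(I2 - p$background, 2 * (I1 - p$background),
               tolerance = 1e-12)
  expect_true(all(I1 >= p$background))
})

test_that("doubling the orientation quadrature changes nothing material", {
  p <- core_shell_cylinder()
  q <- exp(seq(log(1e-3), log(0.5), length.out = 50))
  n_default <- max(76L, ceiling(0.8 * max(q) * (p$L / 2 + p$t_shell)))
  a <- sans_intensity(p, q)                        # default resolution
  b <- sans_intensity(p, q, n_quad = 2L * n_default)
  expect_lt(max(abs(a - b) / (a - p$background + 1e-300)), 1e-4)
})

test_that("curve synthesis is exact at zero noise and seed-reproducible", {
  p <- core_shell_cylinder()
  q <- default_q_grid(50)
  clean <- synthesize_sans_curve(p, q, rel_noise = 0)
  expect_equal(clean$I, sans_intensity(p, q))
  expect_null(clean$dI)

  a <- synthesize_sans_curve(p, q, 0.05, seed = 14)
  b <- synthesize_sans_curve(p, q, 0.05, seed = 14)
  expect_identical(a$I, b$I)
  expect_equal(a$dI, 0.05 * sans_intensity(p, q))
})

test_that("the true model scores a reduced chi-square near one", {
  p <- core_shell_cylinder()
  curve <- synthesize_sans_curve(p, default_q_grid(100), 0.05, seed = 23)
  r <- (curve$I - sans_intensity(p, curve$q)) / curve$dI
  chisq_red <- sum(r^2) / 100
  expect_gt(chisq_red, 0.7)
  expect_lt(chisq_red, 1.3)
})

test_that("a noiseless curve refits its generating dimensions within 1%", {
  truth <- core_shell_cylinder()
  curve <- synthesize_sans_curve(truth, rel_noise = 0)
  init <- truth
  for (nm in c("R_core", "t_shell", "L", "scale", "background"))
    init[[nm]] <- init[[nm]] * 1.5
  fit <- suppressWarnings(fit_sans_cylinder(curve, init))
  expect_lt(abs(fit$params$R_core - truth$R_core) / truth$R_core, 0.01)
  expect_lt(abs(fit$params$t_shell - truth$t_shell) / truth$t_shell, 0.01)
  expect_lt(abs(fit$params$L - truth$L) / truth$L, 0.01)
})

test_that("5%-noise curves refit radius and shell within 10% (median)", {
  truth <- core_shell_cylinder()
  init <- truth
  for (nm in c("R_core", "t_shell", "L", "scale", "background"))
    init[[nm]] <- init[[nm]] * 1.4
  err_R <- err_t <- chis <- numeric(6)
  for (s in 1:6) {
    curve <- synthesize_sans_curve(truth, rel_noise = 0.05, seed = s)
    fit <- fit_sans_cylinder(curve, init)
    err_R[s] <- abs(fit$params$R_core - truth$R_core) / truth$R_core
    err_t[s] <- abs(fit$params$t_shell - truth$t_shell) / truth$t_shell
    chis[s] <- fit$chisq_red
  }
  expect_lt(median(err_R), 0.10)
  expect_lt(median(err_t), 0.10)
  expect_lt(median(chis), 2)
})

test_that("fully fixed fits just evaluate the model", {
  truth <- core_shell_cylinder()
  curve <- synthesize_sans_curve(truth, rel_noise = 0.05, seed = 4)
  fit <- fit_sans_cylinder(curve, truth,
                           fixed = names(unclass(truth)))
  expect_identical(unclass(fit$params), unclass(truth))
  direct <- sum(((curve$I - sans_intensity(truth, curve$q)) /
                   curve$dI)^2) / nrow(curve)
  expect_equal(fit$chisq_red, direct, tolerance = 1e-12)
})

test_that("degenerate uncertainties fall back to an unweighted fit", {
  truth <- core_shell_cylinder()
  curve <- synthesize_sans_curve(truth, rel_noise = 0.02, seed = 5)
  curve$dI[3] <- 0
  expect_warning(fit_sans_cylinder(curve, truth), "degenerate")
})

test_that("curve files round-trip through CSV", {
  truth <- core_shell_cylinder()
  curve <- synthesize_sans_curve(truth, default_q_grid(30), 0.05, seed = 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sans_curve(curve, path)
  back <- read_sans_curve(path)
  expect_equal(back$q, curve$q)
  expect_equal(back$I, curve$I)
  expect_equal(back$dI, curve$dI)
})
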