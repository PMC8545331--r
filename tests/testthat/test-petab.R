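# PEtab loading, condition mapping, likelihood and aggregated objective.

test_that("a minimal bundle loads with the right counts", {
  pr <- load_bundle("decay")
  expect_s3_class(pr, "estimation_problem")
  expect_length(pr$conditions, 1)
  expect_equal(nrow(pr$measurements), 8)
  expect_setequal(estimated_ids(pr), c("k1", "sigma_noise"))
  # estimated noise parameter was added to the dynamic parameter vector
  expect_true("sigma_noise" %in% names(pr$model$parameters))
})

test_that("dangling references are reported as PEtab format errors", {
  d <- tempfile()
  generate_fixture("decay", d, seed = 1, petab = TRUE)
  meas <- read.delim(file.path(d, "measurements.tsv"))
  meas$observableId[1] <- "obs_ghost"
  write.table(meas, file.path(d, "measurements.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  err <- tryCatch(load_petab(file.path(d, "problem.yaml")),
                  error = function(e) e)
  expect_s3_class(err, "odesens_petab_format_error")
  expect_match(conditionMessage(err), "obs_ghost", fixed = TRUE)
})

test_that("condition overrides of species initial values reach x0", {
  d <- tempfile()
  generate_fixture("decay", d, seed = 1, petab = TRUE)
  cond <- data.frame(conditionId = "c0", A = 2.5)
  write.table(cond, file.path(d, "conditions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  pr <- load_petab(file.path(d, "problem.yaml"))
  ac <- apply_condition(pr, "c0")
  expect_equal(unname(ac$x0["A"]), 2.5)
  expect_true(ac$x0_override[["A"]])
})

test_that("apply_condition back-transforms scales and applies overrides", {
  pr <- load_bundle("decay")
  # log10 scale: estimation value 0 -> linear 1.0
  ac <- apply_condition(pr, "c0", c(k1 = 0, sigma_noise = log10(0.1)))
  expect_equal(unname(ac$p["k1"]), 1.0)
  expect_equal(unname(ac$p["sigma_noise"]), 0.1)
  # no overrides: nominal values pass through
  ac2 <- apply_condition(pr, "c0")
  expect_equal(unname(ac2$p["k1"]), 1.0)
  expect_false(any(ac2$p_overridden))
  expect_error(apply_condition(pr, "missing_condition"), "unknown condition")
})

test_that("negloglik matches hand-computed values", {
  # zero residual, sigma 1
  expect_equal(negloglik(1, data.frame(measurement = 1), 1),
               0.5 * log(2 * pi), tolerance = 1e-14)
  # residual equal to sigma adds exactly 0.5
  expect_equal(negloglik(1.5, data.frame(measurement = 1), 0.5) -
                 negloglik(1, data.frame(measurement = 1), 0.5),
               0.5, tolerance = 1e-12)
  # three-point toy table against a hand-computed sum
  y <- c(1.2, 0.7, 2.0); ybar <- c(1.0, 0.9, 1.8); s <- c(1, 2, 0.5)
  hand <- sum(0.5 * ((y - ybar) / s)^2 + 0.5 * log(2 * pi * s^2))
  expect_equal(negloglik(y, data.frame(measurement = ybar), s), hand,
               tolerance = 1e-12)
  expect_error(negloglik(1, data.frame(measurement = 1), 0), "positive")
  expect_error(negloglik(c(1, NA), data.frame(measurement = c(1, 1)), 1),
               "missing")
})

test_that("log-normal noise applies the transform plus the log(ybar) term", {
  meas <- data.frame(measurement = 2, noiseDistribution = "log-normal")
  got <- negloglik(2.5, meas, 0.3)
  hand <- 0.5 * ((log(2.5) - log(2)) / 0.3)^2 +
    0.5 * log(2 * pi * 0.3^2) + log(2)
  expect_equal(got, hand, tolerance = 1e-12)
})

test_that("without preeq/presim the pipeline reduces to a plain simulation", {
  pr <- load_bundle("decay")
  eq <- equilibrate_and_simulate(pr, "c0", nominal_p_est(pr),
                                 timepoints = c(0, 1))
  ac <- apply_condition(pr, "c0")
  tr <- simulate_model(pr$compiled, ac$p, ac$k, timepoints = c(0, 1))
  expect_identical(eq$trajectory$x, tr$x)
})

test_that("pre-equilibration then production shutoff follows the closed form", {
  pr <- load_bundle("synthesis_degradation")
  # preeq at (a=2, b=4) -> x(0) = 0.5; main condition pins a = 0.5:
  # x(t) = 1/8 + 3/8 exp(-4 t)
  tt <- c(0, 0.25, 0.5, 1)
  eq <- equilibrate_and_simulate(pr, "main_cond", nominal_p_est(pr),
                                 timepoints = tt,
                                 preeq_id = "preeq_cond")
  expect_equal(unname(eq$trajectory$x[1, 1]), 0.5, tolerance = 1e-7)
  ref <- 0.125 + 0.375 * exp(-4 * tt)
  expect_lt(mixed_err(eq$trajectory$x[, 1], ref), 1e-7)
})

test_that("pre-equilibrated sensitivities start from the steady-state solve", {
  pr <- load_bundle("synthesis_degradation")
  eq <- equilibrate_and_simulate(pr, "main_cond", nominal_p_est(pr),
                                 timepoints = c(0, 0.5),
                                 preeq_id = "preeq_cond",
                                 want_sensitivities = TRUE)
  s_star <- eq$preeq$s_star
  expect_lt(mixed_err(eq$sx[1, , ], s_star), 1e-12)
  # and the preeq steady-state sensitivities follow the long-time limit
  cm_pre <- eq$preeq$cm
  fs <- forward_sensitivities(cm_pre, eq$preeq$ac$p, eq$preeq$ac$k,
                              timepoints = c(0, 1e6))
  expect_lt(mixed_err(s_star, fs$sx[2, , ]), 1e-5)
})

test_that("pre-simulation advances the initial state for the stated duration", {
  pr <- load_bundle("decay")
  eq <- equilibrate_and_simulate(pr, "c0", nominal_p_est(pr),
                                 timepoints = c(0, 1),
                                 presim_id = "c0", presim_time = 0.5)
  expect_equal(unname(eq$trajectory$x[1, 1]), exp(-0.5), tolerance = 1e-7)
})

test_that("duplicating a condition doubles value and gradient", {
  d <- tempfile()
  generate_fixture("conversion", d, seed = 1, petab = TRUE)
  pr1 <- load_petab(file.path(d, "problem.yaml"))
  g1 <- objective_and_gradient(pr1, method = "forward")
  cond <- read.delim(file.path(d, "conditions.tsv"))
  cond <- rbind(cond, data.frame(conditionId = "c1"))
  write.table(cond, file.path(d, "conditions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  meas <- read.delim(file.path(d, "measurements.tsv"))
  meas2 <- meas; meas2$simulationConditionId <- "c1"
  write.table(rbind(meas, meas2), file.path(d, "measurements.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  pr2 <- load_petab(file.path(d, "problem.yaml"))
  g2 <- objective_and_gradient(pr2, method = "forward")
  expect_equal(g2$value, 2 * g1$value, tolerance = 1e-12)
  expect_equal(g2$gradient, 2 * g1$gradient, tolerance = 1e-12)
})

test_that("permuting measurement rows changes no reported digit", {
  d <- tempfile()
  generate_fixture("conversion", d, seed = 3, petab = TRUE)
  pr <- load_petab(file.path(d, "problem.yaml"))
  g <- objective_and_gradient(pr, method = "forward")
  meas <- read.delim(file.path(d, "measurements.tsv"))
  set.seed(99)
  write.table(meas[sample(nrow(meas)), ], file.path(d, "measurements.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  pr_perm <- load_petab(file.path(d, "problem.yaml"))
  g_perm <- objective_and_gradient(pr_perm, method = "forward")
  expect_identical(g$value, g_perm$value)
  expect_identical(g$gradient, g_perm$gradient)
})

test_that("forward and adjoint agree across a multi-condition problem", {
  pr <- load_bundle("synthesis_degradation")
  cfg <- solver_config(rtol = 1e-11, atol = 1e-15)
  gf <- objective_and_gradient(pr, method = "forward", cfg = cfg)
  ga <- objective_and_gradient(pr, method = "adjoint", cfg = cfg)
  expect_lt(abs(gf$value - ga$value) / max(1, abs(gf$value)), 1e-10)
  expect_lt(rel_diff(gf$gradient, ga$gradient), 1e-4)
})

test_that("the estimation-scale gradient obeys the log10 chain rule", {
  d <- tempfile()
  generate_fixture("conversion", d, seed = 5, petab = TRUE)
  pr_lin <- load_petab(file.path(d, "problem.yaml"))
  g_lin <- objective_and_gradient(pr_lin, method = "forward")
  pars <- read.delim(file.path(d, "parameters.tsv"))
  pars$parameterScale <- "log10"
  write.table(pars, file.path(d, "parameters.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  pr_log <- load_petab(file.path(d, "problem.yaml"))
  g_log <- objective_and_gradient(pr_log,
                                  p_est = log10(c(k1 = 1, k2 = 2)),
                                  method = "forward")
  p_lin <- c(1, 2)
  expect_lt(mixed_err(g_log$gradient, g_lin$gradient * p_lin * log(10)),
            1e-12)
})

test_that("failing conditions follow the configured policy", {
  d <- tempfile()
  generate_fixture("decay", d, seed = 1, petab = TRUE)
  pr <- load_petab(file.path(d, "problem.yaml"))
  bad_p <- c(k1 = 20, sigma_noise = -1)   # log10: k1 = 1e20 is unintegrable
  cfg <- solver_config(max_steps = 100)
  expect_error(objective_and_gradient(pr, bad_p, cfg = cfg,
                                      on_failure = "error"),
               "failed for condition")
  g <- objective_and_gradient(pr, bad_p, cfg = cfg, on_failure = "inf")
  expect_identical(g$value, Inf)
  expect_true(all(is.na(g$gradient)))
})
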