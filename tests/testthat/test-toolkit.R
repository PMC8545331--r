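# Fixture catalogue, CLI and result serialization.

test_that("analytic fixture references satisfy the ODE residual check", {
  for (nm in c("decay", "conversion", "synthesis_degradation",
               "linear_chain")) {
    fx <- fixture_model(nm, n = 4)
    cm <- compile_functions(fx$model)
    for (tq in c(0.1, 0.7, 1.9)) {
      xq <- fx$analytic$x(tq)
      resid <- fx$analytic$dx(tq) - cm$f(xq, fx$p_true, numeric(0), tq)
      expect_lt(max(abs(resid)), 1e-10, label = sprintf("%s t=%g", nm, tq))
    }
  }
})

test_that("fixture analytic solutions match simulation across sampled times", {
  tt <- seq(0, 3, length.out = 50)
  cfg <- solver_config(rtol = 1e-8)
  for (nm in c("decay", "conversion", "linear_chain")) {
    fx <- fixture_model(nm, n = 4)
    cm <- compile_functions(fx$model)
    tr <- simulate_model(cm, fx$p_true, timepoints = tt, cfg = cfg)
    err <- max(vapply(seq_along(tt), function(i)
      mixed_err(tr$x[i, ], fx$analytic$x(tt[i])), numeric(1L)))
    expect_lt(err, 10 * cfg$rtol, label = nm)
  }
})

test_that("linear_chain has a lower-bidiagonal Jacobian", {
  fx <- fixture_model("linear_chain", n = 4)
  expect_length(fx$model$states, 4)
  expect_length(fx$model$parameters, 4)
  cm <- compile_functions(fx$model)
  J <- jacobian_at(cm, x = rep(1, 4), p = fx$p_true)
  expect_true(all(J[upper.tri(J)] == 0))
  expect_true(all(diag(J) < 0))
  expect_true(all(J[cbind(2:4, 1:3)] > 0))
  expect_equal(sum(J != 0), 7)
})

test_that("the same seed reproduces byte-identical measurement tables", {
  d1 <- tempfile(); d2 <- tempfile()
  generate_fixture("decay", d1, seed = 7, petab = TRUE)
  generate_fixture("decay", d2, seed = 7, petab = TRUE)
  expect_identical(readLines(file.path(d1, "measurements.tsv")),
                   readLines(file.path(d2, "measurements.tsv")))
  d3 <- tempfile()
  generate_fixture("decay", d3, seed = 8, petab = TRUE)
  expect_false(identical(readLines(file.path(d1, "measurements.tsv")),
                         readLines(file.path(d3, "measurements.tsv"))))
})

test_that("generated fixtures round-trip through the importers", {
  d <- tempfile()
  generate_fixture("linear_chain", d, n = 4)
  m <- import_sbml(file.path(d, "model.xml"))
  expect_length(m$states, 4)
  expect_error(generate_fixture("no_such_model", tempfile()))
  expect_error(fixture_model("linear_chain", n = 1), "n >= 2")
})

test_that("cli simulate runs, writes results, and maps failures to exit codes", {
  d <- tempfile()
  generate_fixture("decay", d)
  out <- file.path(d, "run")
  txt <- capture.output(
    code <- cli_main(c("simulate", file.path(d, "model.xml"),
                       "--times", "0,0.5,1", "--out", out)))
  expect_identical(code, 0L)
  expect_match(paste(txt, collapse = " "), "0.3678794")
  tab <- read.delim(paste0(out, ".tsv"))
  expect_equal(nrow(tab), 3)
  res <- jsonlite::read_json(paste0(out, ".json"))
  expect_named(res, c("meta", "trajectory"))
  expect_identical(suppressMessages(
    cli_main(c("simulate", "/no/such.xml", "--times", "0,1"))), 2L)
  expect_identical(suppressMessages(
    cli_main(c("simulate", file.path(d, "model.xml"),
               "--times", "0,1e6", "--maxsteps", "5"))), 1L)
  expect_identical(suppressMessages(cli_main(character(0))), 2L)
  expect_identical(suppressMessages(cli_main("frobnicate")), 2L)
})

test_that("cli check-gradient passes on a healthy bundle and fails when broken", {
  yaml <- petab_bundle_path("conversion")
  txt <- capture.output(
    code <- cli_main(c("check-gradient", yaml, "--method", "both")))
  expect_identical(code, 0L)
  expect_match(paste(txt, collapse = "\n"), "rel_diff")
  # threshold 0 can never pass (finite-difference noise is nonzero)
  expect_identical(suppressMessages(
    cli_main(c("check-gradient", yaml, "--method", "forward",
               "--threshold", "0"))), 1L)
})

test_that("a corrupted observable-derivative evaluator is caught by the check", {
  pr <- load_petab(petab_bundle_path("conversion"))
  expect_true(check_gradient(pr, methods = "forward")$ok)
  pr_bad <- pr
  dims <- pr$compiled$dims
  pr_bad$compiled$dhdp <- function(x, p, k, t)
    Matrix::Matrix(1, dims$n_y, dims$n_p, sparse = TRUE)  # fault injection
  expect_false(check_gradient(pr_bad, methods = "forward")$ok)
})

test_that("cli gradient and petab-eval print and export the objective", {
  yaml <- petab_bundle_path("decay")
  out <- tempfile(fileext = ".json")
  txt <- capture.output(
    code <- cli_main(c("gradient", yaml, "--method", "adjoint",
                       "--out", out)))
  expect_identical(code, 0L)
  res <- jsonlite::read_json(out)
  expect_identical(res$method, "adjoint")
  expect_setequal(names(res$gradient), c("k1", "sigma_noise"))
  txt2 <- capture.output(code2 <- cli_main(c("petab-eval", yaml)))
  expect_identical(code2, 0L)
  expect_match(paste(txt2, collapse = " "), "log-likelihood")
})

test_that("cli steady-state and make-fixture work end to end", {
  d <- tempfile()
  txt <- capture.output(
    code <- cli_main(c("make-fixture", "synthesis_degradation",
                       "--dir", d)))
  expect_identical(code, 0L)
  txt2 <- capture.output(
    code2 <- cli_main(c("steady-state", file.path(d, "model.xml"))))
  expect_identical(code2, 0L)
  expect_match(paste(txt2, collapse = " "), "X=0.5")
})

test_that("config files mirror flags and explicit flags win", {
  d <- tempfile()
  generate_fixture("decay", d)
  cfgf <- file.path(d, "cfg.yaml")
  yaml::write_yaml(list(times = "0,1", rtol = "1e-6"), cfgf)
  code <- cli_main(c("simulate", file.path(d, "model.xml"),
                     "--config", cfgf))
  expect_identical(code, 0L)
  # flag overrides config: an unusable --times from the flag must error
  expect_identical(suppressMessages(
    cli_main(c("simulate", file.path(d, "model.xml"), "--config", cfgf,
               "--times", "oops"))), 2L)
})

test_that("results files carry trajectory, sensitivity and gradient groups", {
  fx <- fixture_model("conversion")
  cm <- compile_functions(fx$model)
  fs <- forward_sensitivities(cm, fx$p_true, timepoints = c(0, 1, 2))
  gr <- structure(list(value = 1.5, gradient = c(k1 = 0.1, k2 = -0.2),
                       method = "forward"), class = "gradient_result")
  f <- tempfile(fileext = ".json")
  write_results_json(f, meta = list(run = "test"), traj = fs$trajectory,
                     sens = fs, gradient = gr)
  res <- jsonlite::read_json(f)
  expect_setequal(names(res),
                  c("meta", "trajectory", "sensitivities", "gradient"))
  expect_length(res$trajectory$time, 3)
  expect_length(res$sensitivities$sx, 3)
  expect_equal(res$gradient$value, 1.5)
})
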