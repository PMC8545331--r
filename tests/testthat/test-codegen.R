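# Symbolic partials, sparsity patterns, compiled evaluators and runtime
# sparse assembly of total derivatives.

test_that("derive_partials matches hand derivatives on small models", {
  fx <- fixture_model("decay")
  pds <- derive_partials(fx$model)
  expect_true(exprs_numerically_equal(pds$dfdx[[1, 1]], quote(-k1)))
  expect_true(exprs_numerically_equal(pds$dfdp[[1, 1]], quote(-A)))

  cv <- fixture_model("conversion")
  pc <- derive_partials(cv$model)
  env <- list(k1 = 1, k2 = 2, A = 0.3, B = 0.7)
  expect_equal(eval_sym_matrix_subst(pc$dfdx, env),
               matrix(c(-1, 1, 2, -2), 2, 2))
})

test_that("observable partials have the expected structure and patterns", {
  m <- ode_model(states = c("x1", "x2"),
                 rhs = list(quote(-k1 * x1), quote(-k2 * x2)),
                 x0 = list(x1 = 1, x2 = 1),
                 parameters = c(k1 = 1, k2 = 2),
                 observables = list(total = quote(x1 + x2)),
                 sigmas = list(total = 1))
  pds <- derive_partials(m)
  expect_equal(eval_sym_matrix_subst(pds$dhdx, list(x1 = 5, x2 = 7)),
               matrix(c(1, 1), 1, 2))
  expect_equal(nrow(pds$patterns$dhdp), 0)   # h does not touch p directly
  expect_equal(nrow(pds$patterns$dsigmadp), 0)
})

test_that("sparsity patterns are structural nonzeros after simplification", {
  sm <- matrix(list(quote(-k), quote(k), 0, 0), 2, 2)
  expect_equal(sparsity_pattern(sm),
               data.frame(row = c(1, 2), col = c(1, 1)))
  expect_equal(nrow(sparsity_pattern(matrix(list(0, 0), 1, 2))), 0)
  # x - x simplifies to zero; k stays
  sm2 <- matrix(list(quote(x - x), quote(k)), 1, 2)
  expect_equal(sparsity_pattern(sm2), data.frame(row = 1, col = 2))
})

test_that("compiled evaluators agree with symbolic substitution to 1e-12", {
  set.seed(11)
  for (nm in c("conversion", "lotka_volterra", "linear_chain")) {
    fx <- fixture_model(nm)
    m <- fx$model
    pds <- derive_partials(m)
    cm <- compile_functions(m, pds)
    for (rep in 1:20) {
      x <- stats::runif(length(m$states), 0.1, 2)
      p <- stats::runif(length(m$parameters), 0.1, 2)
      env <- model_env(m, x, p)
      expect_lt(mixed_err(cm$f(x, p, numeric(0), 0),
                          eval_exprs_subst(m$rhs, env)), 1e-12)
      for (mat in c("dfdx", "dfdp", "dhdx", "dhdp")) {
        dense <- as.matrix(cm[[mat]](x, p, numeric(0), 0))
        oracle <- eval_sym_matrix_subst(pds[[mat]], env)
        expect_lt(mixed_err(dense, oracle), 1e-12)
      }
    }
  }
})

test_that("evaluators are pure and sparse output honors the declared pattern", {
  fx <- fixture_model("conversion")
  cm <- compile_functions(fx$model)
  a <- cm$dfdx(c(1, 0), c(1, 2), numeric(0), 0)
  b <- cm$dfdx(c(1, 0), c(1, 2), numeric(0), 0)
  expect_identical(a, b)
  sm <- Matrix::summary(a)
  got <- data.frame(row = sm$i, col = sm$j)
  got <- got[order(got$row, got$col), ]
  pat <- cm$patterns$dfdx[order(cm$patterns$dfdx$row, cm$patterns$dfdx$col), ]
  expect_equal(unname(as.matrix(got)), unname(as.matrix(pat)))
})

test_that("entries outside the pattern evaluate to exactly zero", {
  set.seed(7)
  fx <- fixture_model("lotka_volterra")
  pds <- derive_partials(fx$model)
  for (mat in c("dfdx", "dfdp", "dhdp")) {
    sm <- pds[[mat]]
    pat <- pds$patterns[[mat]]
    inside <- paste(pat$row, pat$col)
    for (i in seq_len(nrow(sm))) for (j in seq_len(ncol(sm))) {
      if (paste(i, j) %in% inside) next
      for (rep in 1:100) {
        env <- model_env(fx$model, stats::runif(2, 0, 5),
                         stats::runif(3, 0, 5))
        expect_identical(eval(sm[[i, j]], env, baseenv()) + 0, 0)
      }
    }
  }
})

test_that("assemble_output_sensitivity equals dense arithmetic to 1e-13", {
  expect_equal(assemble_output_sensitivity(
    Matrix::Matrix(matrix(c(1, 1), 1, 2), sparse = TRUE),
    matrix(c(0.5, -0.5), 2, 1),
    Matrix::Matrix(matrix(0, 1, 1), sparse = TRUE)),
    matrix(0, 1, 1))
  set.seed(3)
  for (rep in 1:25) {
    n_y <- sample(1:4, 1); n_x <- sample(1:5, 1); n_p <- sample(1:4, 1)
    dhdx <- matrix(stats::rnorm(n_y * n_x) *
                     stats::rbinom(n_y * n_x, 1, 0.6), n_y, n_x)
    sx <- matrix(stats::rnorm(n_x * n_p), n_x, n_p)
    dhdp <- matrix(stats::rnorm(n_y * n_p) *
                     stats::rbinom(n_y * n_p, 1, 0.4), n_y, n_p)
    got <- assemble_output_sensitivity(
      methods::as(Matrix::Matrix(dhdx, sparse = TRUE), "generalMatrix"), sx,
      methods::as(Matrix::Matrix(dhdp, sparse = TRUE), "generalMatrix"))
    ref <- dhdx %*% sx + dhdp   # dense-arithmetic oracle
    expect_lt(mixed_err(got, ref), 1e-13)
  }
  expect_error(assemble_output_sensitivity(matrix(0, 1, 2),
                                           matrix(0, 3, 1),
                                           matrix(0, 1, 1)),
               "shape mismatch")
})

test_that("runtime-assembled dy/dp obeys the chain rule against a dense oracle", {
  set.seed(21)
  fx <- fixture_model("lotka_volterra")
  m <- fx$model
  pds <- derive_partials(m)
  cm <- compile_functions(m, pds)
  for (rep in 1:10) {
    x <- stats::runif(2, 0.2, 2); p <- stats::runif(3, 0.2, 2)
    sx <- matrix(stats::rnorm(2 * 3), 2, 3)
    got <- assemble_output_sensitivity(cm$dhdx(x, p, numeric(0), 0), sx,
                                       cm$dhdp(x, p, numeric(0), 0))
    env <- model_env(m, x, p)
    ref <- eval_sym_matrix_subst(pds$dhdx, env) %*% sx +
      eval_sym_matrix_subst(pds$dhdp, env)
    expect_lt(mixed_err(got, ref), 1e-12)
  }
})

test_that("non-differentiable expressions are reported with the expression", {
  m <- ode_model(states = "A", rhs = list(quote(-k1 * round(A))),
                 x0 = list(A = 1), parameters = c(k1 = 1))
  expect_error(derive_partials(m), "round")
})

test_that("the partials report lists every structural nonzero", {
  fx <- fixture_model("conversion")
  pds <- derive_partials(fx$model)
  f <- tempfile(fileext = ".txt")
  lines <- write_partials_report(pds, f)
  expect_true(file.exists(f))
  expect_true(any(grepl("dfdx", lines)))
  expect_equal(sum(grepl("^  \\[", lines)),
               sum(vapply(pds$patterns, nrow, integer(1L))))
})
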