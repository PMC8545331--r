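# Fixture-model catalogue with analytic references.
#
# Each fixture exercises a distinct failure mode of the math core:
#   decay                — linear, scalar, closed-form solution/sensitivity
#   conversion           — conserved total, singular Jacobian at equilibrium
#   synthesis_degradation— nontrivial steady state, two-phase experiments
#   lotka_volterra       — nonlinear, oscillatory
#   linear_chain(n)      — banded linear system, matrix-exponential reference
# Analytic state references for the linear fixtures use the matrix
# exponential; sensitivities use the block-triangular augmented exponential
# expm([[A, (dA/dp_j) ], [0, A]]) — exact linear algebra, independent of any
# ODE integration.

# x(t) and dx/dp_j(t) of dx/dt = A x, x(0) = x0, via augmented expm.
linear_analytic <- function(A, dA_list, x0, dx0dp = NULL) {
  n <- nrow(A)
  n_p <- length(dA_list)
  if (is.null(dx0dp)) dx0dp <- matrix(0, n, n_p)
  list(
    x = function(t) as.numeric(Matrix::expm(A * t) %*% x0),
    dx = function(t) as.numeric(A %*% (Matrix::expm(A * t) %*% x0)),
    sx = function(t) {
      out <- matrix(0, n, n_p)
      for (j in seq_len(n_p)) {
        M <- rbind(cbind(A, dA_list[[j]]), cbind(matrix(0, n, n), A))
        z <- as.numeric(Matrix::expm(M * t) %*% c(dx0dp[, j], x0))
        out[, j] <- z[seq_len(n)]
      }
      out
    }
  )
}

#' Construct a fixture model with analytic references
#'
#' @param name one of `"decay"`, `"conversion"`, `"synthesis_degradation"`,
#'   `"lotka_volterra"`, `"linear_chain"`.
#' @param n chain length for `linear_chain` (>= 2).
#' @return list with `model` (observing every state with unit noise),
#'   `p_true` (named defaults), and where closed forms exist `analytic`
#'   with callables `x(t)`, `dx(t)` (time derivative) and `sx(t)`
#'   (`n_x x n_p` state sensitivities).
#' @export
fixture_model <- function(name = c("decay", "conversion",
                                   "synthesis_degradation",
                                   "lotka_volterra", "linear_chain"),
                          n = 4L) {
  name <- match.arg(name)
  out <- switch(name,
    decay = {
      p <- c(k1 = 1)
      m <- ode_model(states = "A", rhs = list(quote(-(k1 * A))),
                     x0 = list(A = 1), parameters = p,
                     stoichiometry = matrix(-1, 1, 1,
                                            dimnames = list("A", "r_decay")),
                     fluxes = list(quote(k1 * A)), name = "decay")
      analytic <- list(
        x = function(t) exp(-p[["k1"]] * t),
        dx = function(t) -p[["k1"]] * exp(-p[["k1"]] * t),
        sx = function(t) matrix(-t * exp(-p[["k1"]] * t), 1, 1))
      list(model = m, p_true = p, analytic = analytic)
    },
    conversion = {
      p <- c(k1 = 1, k2 = 2)
      S <- matrix(c(-1, 1, 1, -1), 2, 2,
                  dimnames = list(c("A", "B"), c("r_fwd", "r_rev")))
      m <- ode_model(states = c("A", "B"),
                     rhs = reactions_to_odes(S, list(quote(k1 * A),
                                                     quote(k2 * B))),
                     x0 = list(A = 1, B = 0), parameters = p,
                     stoichiometry = S,
                     fluxes = list(quote(k1 * A), quote(k2 * B)),
                     name = "conversion")
      A <- function(pp) matrix(c(-pp[1], pp[1], pp[2], -pp[2]), 2, 2)
      analytic <- linear_analytic(
        A(p), list(matrix(c(-1, 1, 0, 0), 2, 2),
                   matrix(c(0, 0, 1, -1), 2, 2)), c(1, 0))
      list(model = m, p_true = p, analytic = analytic)
    },
    synthesis_degradation = {
      p <- c(a = 2, b = 4)
      S <- matrix(c(1, -1), 1, 2,
                  dimnames = list("X", c("r_syn", "r_deg")))
      m <- ode_model(states = "X",
                     rhs = reactions_to_odes(S, list(quote(a), quote(b * X))),
                     x0 = list(X = 0), parameters = p,
                     stoichiometry = S,
                     fluxes = list(quote(a), quote(b * X)),
                     name = "synthesis_degradation")
      analytic <- list(
        x = function(t) p[["a"]] / p[["b"]] * (1 - exp(-p[["b"]] * t)),
        dx = function(t) p[["a"]] * exp(-p[["b"]] * t),
        sx = function(t) {
          a <- p[["a"]]; b <- p[["b"]]
          cbind((1 - exp(-b * t)) / b,
                -a / b^2 * (1 - exp(-b * t)) + a * t * exp(-b * t) / b)
        })
      list(model = m, p_true = p, analytic = analytic)
    },
    lotka_volterra = {
      p <- c(alpha = 1.5, beta = 1, delta = 3)
      S <- matrix(c(1, 0, -1, 1, 0, -1), 2, 3,
                  dimnames = list(c("prey", "predator"),
                                  c("r_birth", "r_predation", "r_death")))
      v <- list(quote(alpha * prey), quote(beta * prey * predator),
                quote(delta * predator))
      m <- ode_model(states = c("prey", "predator"),
                     rhs = reactions_to_odes(S, v),
                     x0 = list(prey = 1, predator = 1), parameters = p,
                     stoichiometry = S, fluxes = v,
                     name = "lotka_volterra")
      list(model = m, p_true = p, analytic = NULL)
    },
    linear_chain = {
      n <- as.integer(n)
      if (n < 2L) stop("linear_chain needs n >= 2", call. = FALSE)
      states <- sprintf("X%d", seq_len(n))
      kn <- sprintf("k%d", seq_len(n))
      p <- stats::setNames(0.5 + 0.25 * seq_len(n), kn)
      S <- matrix(0, n, n, dimnames = list(states,
                                           sprintf("r%d", seq_len(n))))
      v <- vector("list", n)
      for (i in seq_len(n)) {
        S[i, i] <- -1
        if (i < n) S[i + 1L, i] <- 1
        v[[i]] <- call("*", as.name(kn[i]), as.name(states[i]))
      }
      x0 <- stats::setNames(as.list(c(1, rep(0, n - 1L))), states)
      m <- ode_model(states = states, rhs = reactions_to_odes(S, v),
                     x0 = x0, parameters = p, stoichiometry = S,
                     fluxes = v, name = sprintf("linear_chain_%d", n))
      Amat <- matrix(0, n, n)
      dA <- vector("list", n)
      for (i in seq_len(n)) {
        Amat[i, i] <- -p[[i]]
        if (i < n) Amat[i + 1L, i] <- p[[i]]
        dAi <- matrix(0, n, n)
        dAi[i, i] <- -1
        if (i < n) dAi[i + 1L, i] <- 1
        dA[[i]] <- dAi
      }
      analytic <- linear_analytic(Amat, dA, c(1, rep(0, n - 1L)))
      list(model = m, p_true = p, analytic = analytic)
    })
  obsnames <- paste0("obs_", out$model$states)
  out$model <- set_observables(
    out$model,
    stats::setNames(lapply(out$model$states, as.name), obsnames),
    stats::setNames(rep(list(1), length(obsnames)), obsnames))
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Generate fixture model files (SBML, optionally a PEtab bundle)
#'
#' Writes a valid SBML document for the named fixture and, when requested,
#' a PEtab v1 bundle (YAML + condition/observable/measurement/parameter
#' TSVs) with synthetic measurements drawn from the model at its default
#' parameters under the stated noise, using the recorded seed. The same
#' seed yields byte-identical tables.
#'
#' @param name fixture name (see [fixture_model()]).
#' @param dir output directory (created if needed).
#' @param seed integer RNG seed for the synthetic measurements.
#' @param petab also write the PEtab bundle.
#' @param n chain length for `linear_chain`.
#' @return invisibly, a list with file paths (`sbml`, and `yaml` if a
#'   bundle was written).
#' @export
generate_fixture <- function(name, dir, seed = 1L, petab = FALSE, n = 4L) {
  fx <- fixture_model(name, n = n)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sbml_path <- file.path(dir, "model.xml")
  m_bare <- fx$model
  m_bare$observables <- list(); m_bare$sigmas <- list()
  write_sbml(m_bare, sbml_path)
  paths <- list(sbml = sbml_path)
  if (!petab) return(invisible(paths))

  cm <- compile_functions(fx$model)
  p_true <- fx$p_true
  bundle <- switch(name,
    decay = list(
      times = seq(0.5, 4, by = 0.5), states = "A", sigma = 0.1,
      noise_formula = "sigma_noise",
      parameters = data.frame(
        parameterId = c("k1", "sigma_noise"),
        parameterScale = c("log10", "log10"),
        lowerBound = c(1e-3, 1e-3), upperBound = c(1e3, 1e2),
        nominalValue = c(1, 0.1), estimate = c(1L, 1L)),
      conditions = data.frame(conditionId = "c0"),
      preeq = ""),
    conversion = list(
      times = seq(0.25, 3, by = 0.25), states = c("A", "B"), sigma = 0.05,
      noise_formula = "0.05",
      parameters = data.frame(
        parameterId = c("k1", "k2"),
        parameterScale = c("lin", "lin"),
        lowerBound = c(1e-3, 1e-3), upperBound = c(1e2, 1e2),
        nominalValue = c(1, 2), estimate = c(1L, 1L)),
      conditions = data.frame(conditionId = "c0"),
      preeq = ""),
    synthesis_degradation = list(
      times = seq(0, 2, by = 0.25), states = "X", sigma = 0.05,
      noise_formula = "0.05",
      parameters = data.frame(
        parameterId = c("a", "b"),
        parameterScale = c("lin", "log10"),
        lowerBound = c(1e-3, 1e-2), upperBound = c(1e2, 1e2),
        nominalValue = c(2, 4), estimate = c(1L, 1L)),
      conditions = data.frame(conditionId = c("preeq_cond", "main_cond"),
                              a = c(NA, 0.5)),
      preeq = "preeq_cond"),
    lotka_volterra = list(
      times = seq(0.25, 2.5, length.out = 10), states = c("prey", "predator"),
      sigma = 0.05, noise_formula = "0.05",
      parameters = data.frame(
        parameterId = c("alpha", "beta", "delta"),
        parameterScale = rep("log10", 3),
        lowerBound = rep(1e-2, 3), upperBound = rep(1e2, 3),
        nominalValue = c(1.5, 1, 3), estimate = rep(1L, 3)),
      conditions = data.frame(conditionId = "c0"),
      preeq = ""),
    stop("no PEtab bundle defined for fixture '", name, "'", call. = FALSE))

  obs_ids <- paste0("obs_", bundle$states)
  observables <- data.frame(
    observableId = obs_ids,
    observableFormula = bundle$states,
    noiseFormula = bundle$noise_formula,
    noiseDistribution = "normal")

  # simulate the data-generating condition
  sim_cond <- bundle$conditions$conditionId[nrow(bundle$conditions)]
  p_sim <- p_true
  x_init <- NULL
  if (nzchar(bundle$preeq)) {
    ss <- find_steady_state(cm, p_true)
    x_init <- ss$x_ss
    ov <- bundle$conditions[bundle$conditions$conditionId == sim_cond, ]
    for (cc in setdiff(names(ov), "conditionId"))
      if (!is.na(ov[[cc]])) p_sim[cc] <- ov[[cc]]
  }
  tp <- sort(unique(c(0, bundle$times)))
  traj <- simulate_model(cm, p_sim, x_init = x_init, timepoints = tp)

  set.seed(as.integer(seed))
  rows <- list()
  for (s in seq_along(bundle$states)) {
    yi <- traj$x[match(bundle$times, tp), match(bundle$states[s],
                                                fx$model$states)]
    ybar <- yi + stats::rnorm(length(yi), sd = bundle$sigma)
    rows[[s]] <- data.frame(
      observableId = obs_ids[s],
      simulationConditionId = sim_cond,
      time = bundle$times,
      measurement = round(ybar, 10))
  }
  meas <- do.call(rbind, rows)
  if (nzchar(bundle$preeq)) meas$preequilibrationConditionId <- bundle$preeq

  write_tsv(bundle$conditions, file.path(dir, "conditions.tsv"))
  write_tsv(observables, file.path(dir, "observables.tsv"))
  write_tsv(meas, file.path(dir, "measurements.tsv"))
  write_tsv(bundle$parameters, file.path(dir, "parameters.tsv"))
  yaml_path <- file.path(dir, "problem.yaml")
  yaml::write_yaml(list(
    format_version = 1L,
    parameter_file = "parameters.tsv",
    problems = list(list(
      sbml_files = list("model.xml"),
      condition_files = list("conditions.tsv"),
      measurement_files = list("measurements.tsv"),
      observable_files = list("observables.tsv")))), yaml_path)
  paths$yaml <- yaml_path
  invisible(paths)
}
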