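# Parameter sensitivities: forward, adjoint and steady-state methods.
#
# Forward: the state ODE is augmented with one linear ODE per parameter,
# ds_j/dt = J s_j + df/dp_j, and the whole system is integrated jointly; a
# single Jacobian evaluation per step is shared across all parameter blocks.
# Adjoint: one backward integration of dlambda/dt = -J^T lambda with jumps
# at datapoints plus a quadrature over lambda^T df/dp; cost is nearly
# independent of the parameter count. Steady-state: the implicit-function
# linear solve J s* = -df/dp at an equilibrium.

#' Forward sensitivity analysis
#'
#' Integrates the augmented system `dx/dt = f`,
#' `ds_j/dt = J s_j + df/dp_j` for every dynamic parameter `j` jointly with
#' the state, and assembles the output sensitivities
#' `dy/dp = dh/dx . sx + dh/dp` at every requested timepoint.
#'
#' @param cm a `compiled_model`.
#' @param p,k parameter vectors.
#' @param x_init initial state (default `x0(p, k)`).
#' @param sx_init initial state sensitivity, `n_x x n_p`
#'   (default `dx0/dp(p, k)`).
#' @param timepoints strictly increasing output times.
#' @param cfg a [solver_config()].
#' @return object of class `forward_sensitivities` with `trajectory`, `sx`
#'   (array timepoints x n_x x n_p) and `sy` (timepoints x n_y x n_p).
#' @export
forward_sensitivities <- function(cm, p, k = numeric(0), x_init = NULL,
                                  sx_init = NULL, timepoints,
                                  cfg = solver_config()) {
  if (is.unsorted(timepoints, strictly = TRUE))
    stop("timepoints must be strictly increasing", call. = FALSE)
  n_x <- cm$dims$n_x; n_p <- cm$dims$n_p; n_y <- cm$dims$n_y
  if (is.null(x_init)) x_init <- cm$x0(p, k)
  if (is.null(sx_init)) sx_init <- as.matrix(cm$dx0dp(p, k))
  sx_init <- as.matrix(sx_init)
  if (!all(dim(sx_init) == c(n_x, n_p)))
    stop("sx_init must be ", n_x, " x ", n_p, call. = FALSE)

  t0 <- timepoints[1L]; tM <- timepoints[length(timepoints)]
  grid <- if (length(timepoints) == 1L) timepoints else
    sort(unique(c(timepoints, seq(t0, tM, length.out = cfg$interp_points))))
  y0 <- c(x_init, as.numeric(sx_init))
  n_aug <- n_x * (1L + n_p)

  rhs <- function(t, z, parms) {
    x <- z[seq_len(n_x)]
    sx <- matrix(z[-seq_len(n_x)], n_x, n_p)
    J <- cm$dfdx(x, p, k, t)
    dxdt <- cm$f(x, p, k, t)
    dsdt <- as.matrix(J %*% sx + cm$dfdp(x, p, k, t))
    list(c(dxdt, as.numeric(dsdt)))
  }
  # Newton iteration matrix: block-diagonal with the state Jacobian repeated
  # per parameter block (the standard simultaneous-corrector approximation).
  jac <- function(t, z, parms) {
    x <- z[seq_len(n_x)]
    J <- as.matrix(cm$dfdx(x, p, k, t))
    Jaug <- matrix(0, n_aug, n_aug)
    for (b in 0:n_p) {
      idx <- b * n_x + seq_len(n_x)
      Jaug[idx, idx] <- J
    }
    Jaug
  }
  pat <- cm$patterns$dfdx
  aug_pattern <- do.call(rbind, lapply(0:n_p, function(b)
    data.frame(row = pat$row + b * n_x, col = pat$col + b * n_x)))

  if (length(grid) == 1L) {
    zmat <- matrix(y0, 1L, n_aug)
    stats <- c(steps = 0, rhs_evals = 0, jac_evals = 0)
  } else {
    res <- integrate_ode(function(t, z, parms) rhs(t, z, parms),
                         function(t, z) jac(t, z, NULL),
                         y0, grid, cfg, sparse_pattern = aug_pattern)
    zmat <- unname(res$out[, -1L, drop = FALSE])
    stats <- res$stats
  }

  sel <- match(timepoints, grid)
  M <- length(timepoints)
  x_out <- zmat[sel, seq_len(n_x), drop = FALSE]
  colnames(x_out) <- cm$ids$states
  xdot <- t(vapply(seq_along(grid), function(i)
    cm$f(zmat[i, seq_len(n_x)], p, k, grid[i]), numeric(n_x)))
  if (n_x == 1L) xdot <- matrix(xdot, ncol = 1L)

  y_out <- matrix(NA_real_, M, n_y, dimnames = list(NULL, cm$ids$observables))
  sx <- array(NA_real_, c(M, n_x, n_p),
              dimnames = list(NULL, cm$ids$states, cm$ids$parameters))
  sy <- array(NA_real_, c(M, n_y, n_p),
              dimnames = list(NULL, cm$ids$observables, cm$ids$parameters))
  for (i in seq_len(M)) {
    xi <- x_out[i, ]
    ti <- timepoints[i]
    y_out[i, ] <- cm$h(xi, p, k, ti)
    sxi <- matrix(zmat[sel[i], -seq_len(n_x)], n_x, n_p)
    sx[i, , ] <- sxi
    if (n_y > 0L)
      sy[i, , ] <- assemble_output_sensitivity(cm$dhdx(xi, p, k, ti), sxi,
                                               cm$dhdp(xi, p, k, ti))
  }
  traj <- structure(list(times = timepoints, x = x_out, y = y_out,
                         stats = stats,
                         interp = make_interpolant(grid,
                           zmat[, seq_len(n_x), drop = FALSE], xdot),
                         p = p, k = k, cfg = cfg),
                    class = "ode_trajectory")
  structure(list(trajectory = traj, sx = sx, sy = sy),
            class = "forward_sensitivities")
}

#' Steady-state sensitivities via the implicit function theorem
#'
#' At an equilibrium `f(x*, p, k) = 0` with nonsingular Jacobian, solves
#' `J s* = -df/dp` columnwise (one factorization, `n_p` solves). A singular
#' Jacobian (conservation laws) triggers the fallback: the augmented
#' forward system is simulated to convergence; the result's
#' `"method"` attribute records which path was taken.
#'
#' @param cm a `compiled_model`.
#' @param ss a `steady_state` (from [find_steady_state()]).
#' @param p,k parameter vectors.
#' @param cfg a [solver_config()]; its `linear_solver` selects dense or
#'   sparse direct factorization.
#' @param x_init,sx_init initial conditions used only by the simulation
#'   fallback (defaults: model `x0`, `dx0dp`).
#' @return `n_x x n_p` matrix `s* = dx*/dp` with attribute `method`
#'   (`"linear_solve"` or `"simulation"`).
#' @export
steadystate_sensitivities <- function(cm, ss, p, k = numeric(0),
                                      cfg = solver_config(),
                                      x_init = NULL, sx_init = NULL) {
  if (ss$residual_norm >= 1)
    stop("steady state has not converged (residual_norm >= 1)", call. = FALSE)
  x_ss <- ss$x_ss
  dfdp <- as.matrix(cm$dfdp(x_ss, p, k, 0))
  s_star <- tryCatch({
    if (cfg$linear_solver == "sparse") {
      J <- cm$dfdx(x_ss, p, k, 0)
      as.matrix(Matrix::solve(J, -dfdp))
    } else {
      J <- as.matrix(cm$dfdx(x_ss, p, k, 0))
      if (rcond(J) < 1e-12) stop("singular Jacobian")
      solve(J, -dfdp)
    }
  }, error = function(e) NULL)
  if (!is.null(s_star) && all(is.finite(s_star))) {
    dimnames(s_star) <- list(cm$ids$states, cm$ids$parameters)
    attr(s_star, "method") <- "linear_solve"
    return(s_star)
  }
  # Singular Jacobian: simulate the augmented system until the sensitivities
  # stop moving.
  if (is.null(x_init)) x_init <- cm$x0(p, k)
  if (is.null(sx_init)) sx_init <- as.matrix(cm$dx0dp(p, k))
  x_cur <- x_init; sx_cur <- as.matrix(sx_init)
  span <- 10; t_total <- 0
  sx_prev <- NULL
  while (t_total < 1e8) {
    fs <- forward_sensitivities(cm, p, k, x_init = x_cur, sx_init = sx_cur,
                                timepoints = c(0, span), cfg = cfg)
    M <- length(fs$trajectory$times)
    x_cur <- fs$trajectory$x[M, ]
    sx_cur <- matrix(fs$sx[M, , ], cm$dims$n_x, cm$dims$n_p)
    t_total <- t_total + span
    if (!is.null(sx_prev) &&
        max(abs(sx_cur - sx_prev)) <= 1e-9 * max(1, max(abs(sx_cur))) &&
        wrms_norm(cm$f(x_cur, p, k, 0), x_cur, cfg) < 1) {
      dimnames(sx_cur) <- list(cm$ids$states, cm$ids$parameters)
      attr(sx_cur, "method") <- "simulation"
      return(sx_cur)
    }
    sx_prev <- sx_cur
    span <- span * 10
  }
  steady_state_failure("augmented-system fallback did not converge",
                       singular = TRUE)
}

#' Adjoint gradient of a discrete-data negative log-likelihood
#'
#' Computes the objective value and its gradient with respect to the
#' dynamic parameters without per-parameter forward equations: the adjoint
#' state is integrated backward from the last datapoint with
#' `dlambda/dt = -J^T lambda`, receiving a jump `(dg_i/dx)^T` at every
#' datapoint, while the quadrature `q = int lambda^T df/dp dt` accumulates;
#' the gradient is `q` plus the direct observable/noise terms plus
#' `lambda(t0)^T dx0/dp`.
#'
#' @param cm a `compiled_model`.
#' @param p,k parameter vectors.
#' @param x_init initial state (default `x0(p, k)`).
#' @param datapoints data.frame with columns `time`, `observable`
#'   (observable id), `measurement`, and optionally `sigma` (numeric noise
#'   override; `NA` uses the model noise formula) and `distribution`
#'   (`"normal"` default, or `"log-normal"`).
#' @param cfg a [solver_config()].
#' @param dx0dp optional `n_x x n_p` matrix replacing the model's
#'   `dx0/dp(p, k)` in the initial-condition term (used for
#'   pre-equilibrated initial states).
#' @return object of class `gradient_result`: `value`, `gradient` (length
#'   `n_p`, linear parameter scale), `method = "adjoint"`, and an `adjoint`
#'   record with `lambda0`, `quadrature` and the per-datapoint `jumps`.
#' @export
adjoint_gradient <- function(cm, p, k = numeric(0), x_init = NULL,
                             datapoints, cfg = solver_config(),
                             dx0dp = NULL) {
  n_x <- cm$dims$n_x; n_p <- cm$dims$n_p
  dp <- as.data.frame(datapoints)
  if (!all(c("time", "observable", "measurement") %in% names(dp)))
    stop("datapoints needs columns time, observable, measurement",
         call. = FALSE)
  if (!"sigma" %in% names(dp)) dp$sigma <- NA_real_
  if (!"distribution" %in% names(dp)) dp$distribution <- "normal"
  obs_idx <- match(dp$observable, cm$ids$observables)
  if (anyNA(obs_idx))
    stop("unknown observable id(s): ",
         paste(unique(dp$observable[is.na(obs_idx)]), collapse = ", "),
         call. = FALSE)

  t_start <- 0
  if (any(dp$time < t_start))
    stop("datapoint outside the simulated span (t < 0)", call. = FALSE)
  times <- sort(unique(c(t_start, dp$time)))
  traj <- simulate_model(cm, p, k, x_init = x_init, timepoints = times,
                         cfg = cfg)
  sigma_model <- cm$sigma(p, k)
  dsig <- as.matrix(cm$dsigmadp(p, k))

  # pointwise contributions
  value <- 0
  direct <- numeric(n_p)
  dgdx_at <- vector("list", length(times))   # accumulated (dg/dx)^T per time
  for (i in seq_len(nrow(dp))) {
    ti <- match(dp$time[i], times)
    oi <- obs_idx[i]
    y_i <- traj$y[ti, oi]
    sig <- if (is.finite(dp$sigma[i])) dp$sigma[i] else sigma_model[oi]
    pt <- nll_point(y_i, dp$measurement[i], sig, dp$distribution[i])
    value <- value + pt$g
    xi <- traj$x[ti, ]
    dhdx_i <- as.matrix(cm$dhdx(xi, p, k, dp$time[i]))[oi, ]
    dhdp_i <- as.matrix(cm$dhdp(xi, p, k, dp$time[i]))[oi, ]
    direct <- direct + pt$dgdy * dhdp_i
    if (!is.finite(dp$sigma[i]))
      direct <- direct + pt$dgdsigma * dsig[oi, ]
    contrib <- pt$dgdy * dhdx_i
    dgdx_at[[ti]] <- if (is.null(dgdx_at[[ti]])) contrib
                     else dgdx_at[[ti]] + contrib
  }

  # backward sweep
  lambda <- numeric(n_x)
  q <- numeric(n_p)
  jumps <- list()
  itp <- traj$interp
  dp_times_idx <- rev(seq_along(times))
  for (pos in seq_along(dp_times_idx)) {
    ti <- dp_times_idx[pos]
    if (!is.null(dgdx_at[[ti]])) {
      lambda <- lambda + dgdx_at[[ti]]
      jumps[[length(jumps) + 1L]] <-
        data.frame(time = times[ti], norm = sqrt(sum(dgdx_at[[ti]]^2)))
    }
    t_hi <- times[ti]
    t_lo <- if (ti > 1L) times[ti - 1L] else t_start
    if (t_hi - t_lo > 1e-14) {
      rhs <- function(tau, z, parms) {
        t_cur <- t_hi - tau
        xt <- interp_eval(itp, t_cur)
        lam <- z[seq_len(n_x)]
        Jt <- Matrix::t(cm$dfdx(xt, p, k, t_cur))
        Bt <- Matrix::t(cm$dfdp(xt, p, k, t_cur))
        list(c(as.numeric(Jt %*% lam), as.numeric(Bt %*% lam)))
      }
      jac <- function(tau, z) {
        t_cur <- t_hi - tau
        xt <- interp_eval(itp, t_cur)
        Jt <- t(as.matrix(cm$dfdx(xt, p, k, t_cur)))
        Bt <- t(as.matrix(cm$dfdp(xt, p, k, t_cur)))
        rbind(cbind(Jt, matrix(0, n_x, n_p)),
              cbind(Bt, matrix(0, n_p, n_p)))
      }
      res <- tryCatch(
        integrate_ode(rhs, jac, c(lambda, q), c(0, t_hi - t_lo), cfg),
        error = function(e)
          integration_failure(paste0("adjoint (backward) phase: ",
                                     conditionMessage(e))))
      zend <- res$out[nrow(res$out), -1L]
      lambda <- zend[seq_len(n_x)]
      q <- zend[-seq_len(n_x)]
    }
  }

  if (is.null(dx0dp)) dx0dp <- as.matrix(cm$dx0dp(p, k))
  gradient <- unname(as.numeric(q + direct + as.numeric(t(dx0dp) %*% lambda)))
  names(gradient) <- cm$ids$parameters
  structure(list(value = as.numeric(value), gradient = gradient, method = "adjoint",
                 adjoint = list(lambda0 = lambda, quadrature = q,
                                jumps = if (length(jumps))
                                  do.call(rbind, jumps) else NULL),
                 trajectory = traj),
            class = "gradient_result")
}

#' @export
print.gradient_result <- function(x, ...) {
  cat(sprintf("<gradient_result (%s): value = %.8g>\n", x$method, x$value))
  print(x$gradient)
  invisible(x)
}

#' Finite-difference gradient (testing oracle)
#'
#' Standard forward or central finite differences of a scalar objective on
#' the parameter scale it is called with. Used by the gradient-check CLI
#' and the regression tests, never by the production gradient paths.
#'
#' @param objective function of a numeric parameter vector returning a
#'   scalar.
#' @param p evaluation point.
#' @param scheme `"central"` (default) or `"forward"`.
#' @param step step size per coordinate; default `1e-5 * max(|p_j|, 1)`.
#' @return numeric gradient vector.
#' @export
finite_difference_gradient <- function(objective, p,
                                       scheme = c("central", "forward"),
                                       step = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(step)) step <- 1e-5 * pmax(abs(p), 1)
  step <- rep_len(step, length(p))
  if (any(step <= 0)) stop("step must be positive", call. = FALSE)
  g <- numeric(length(p))
  f0 <- if (scheme == "forward") objective(p) else NA_real_
  for (j in seq_along(p)) {
    e <- numeric(length(p)); e[j] <- step[j]
    g[j] <- if (scheme == "central")
      (objective(p + e) - objective(p - e)) / (2 * step[j])
    else
      (objective(p + e) - f0) / step[j]
  }
  names(g) <- names(p)
  g
}
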