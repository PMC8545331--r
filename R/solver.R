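# Stiff/nonstiff ODE integration and steady-state solving.
#
# Integration is delegated to deSolve: the default method is a
# variable-order, variable-step implicit multistep (BDF) integrator using the
# analytic Jacobian evaluator from the compiled model in its nonlinear
# solves; the nonstiff option is an Adams-type method. Linear algebra inside
# the implicit steps is configurable: dense (full analytic Jacobian) or
# sparse (lsodes with the declared Jacobian sparsity). Steady states are
# found by damped Newton with a long-simulation fallback using the weighted
# RMS convergence criterion of the underlying solver family.

#' Solver configuration
#'
#' @param rtol relative integration tolerance.
#' @param atol absolute integration tolerance.
#' @param max_steps maximum internal solver steps per call.
#' @param linear_solver `"dense"`, `"sparse"` or `"iterative"` (the latter
#'   is not supported and raises an error when used).
#' @param method `"stiff_multistep"` (BDF, default) or
#'   `"nonstiff_multistep"` (Adams).
#' @param ss_tol_factor steady-state tolerance multiplier applied to
#'   rtol/atol in the weighted RMS residual criterion.
#' @param newton_max_iters maximum damped-Newton iterations.
#' @param interp_points number of grid nodes (in addition to requested
#'   output times) carried by the cubic Hermite interpolant used for
#'   adjoint replay.
#' @param ss_t_max simulated-time cap for the steady-state fallback.
#' @return object of class `solver_config`.
#' @export
solver_config <- function(rtol = 1e-8, atol = 1e-12, max_steps = 1e5,
                          linear_solver = c("dense", "sparse", "iterative"),
                          method = c("stiff_multistep", "nonstiff_multistep"),
                          ss_tol_factor = 10, newton_max_iters = 20L,
                          interp_points = 201L, ss_t_max = 1e10) {
  linear_solver <- match.arg(linear_solver)
  method <- match.arg(method)
  stopifnot(rtol > 0, atol > 0, max_steps >= 1, ss_tol_factor > 0,
            newton_max_iters >= 1)
  structure(list(rtol = rtol, atol = atol, max_steps = as.integer(max_steps),
                 linear_solver = linear_solver, method = method,
                 ss_tol_factor = ss_tol_factor,
                 newton_max_iters = as.integer(newton_max_iters),
                 interp_points = as.integer(interp_points),
                 ss_t_max = ss_t_max),
            class = "solver_config")
}

integration_failure <- function(msg, time = NA_real_) {
  stop(errorCondition(paste0("integration failure: ", msg,
                             if (is.finite(time)) sprintf(" (at t = %g)", time)),
                      time = time,
                      class = c("odesens_integration_failure")))
}

# Weighted RMS residual norm used for steady-state detection.
wrms_norm <- function(fval, x, cfg) {
  w <- cfg$atol * cfg$ss_tol_factor + cfg$rtol * cfg$ss_tol_factor * abs(x)
  sqrt(mean((fval / w)^2))
}

# Low-level deSolve driver shared by simulate_model and the sensitivity
# module. `rhs` / `jac` operate on the full integration vector.
integrate_ode <- function(rhs, jac, y0, times, cfg, sparse_pattern = NULL) {
  if (cfg$linear_solver == "iterative")
    stop("linear_solver = 'iterative' is not supported", call. = FALSE)
  warn <- character(0)
  out <- withCallingHandlers({
    if (cfg$method == "nonstiff_multistep") {
      deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                   method = "adams", rtol = cfg$rtol, atol = cfg$atol,
                   maxsteps = cfg$max_steps)
    } else if (cfg$linear_solver == "sparse" && !is.null(sparse_pattern)) {
      n <- length(y0)
      inz <- unique(rbind(unname(as.matrix(sparse_pattern)),
                          cbind(seq_len(n), seq_len(n))))
      inz <- inz[order(inz[, 2L], inz[, 1L]), , drop = FALSE]
      jacvec <- function(t, y, j, parms) jac(t, y)[, j]
      if (nrow(inz) < 2L) {
        # degenerate single-entry pattern: let lsodes detect the structure
        deSolve::lsodes(y = y0, times = times, func = rhs, parms = NULL,
                        sparsetype = "sparseint", rtol = cfg$rtol,
                        atol = cfg$atol, maxsteps = cfg$max_steps)
      } else {
        deSolve::lsodes(y = y0, times = times, func = rhs, parms = NULL,
                        jacvec = jacvec, sparsetype = "sparseusr", inz = inz,
                        rtol = cfg$rtol, atol = cfg$atol,
                        maxsteps = cfg$max_steps)
      }
    } else {
      deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                   method = "bdf", jacfunc = function(t, y, parms) jac(t, y),
                   jactype = "fullusr", rtol = cfg$rtol, atol = cfg$atol,
                   maxsteps = cfg$max_steps)
    }
  }, warning = function(w) {
    warn <<- c(warn, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  istate <- attr(out, "istate")
  if (nrow(out) < length(times) || anyNA(out[, -1L]) ||
      (!is.null(istate) && istate[1L] < 0)) {
    t_fail <- if (nrow(out) >= 1L) out[nrow(out), 1L] else times[1L]
    integration_failure(
      paste(c("solver did not reach the final time", warn), collapse = "; "),
      time = t_fail)
  }
  stats <- c(steps = unname(istate[2L]), rhs_evals = unname(istate[3L]),
             jac_evals = unname(istate[14L]))
  list(out = out, stats = stats)
}

# Cubic Hermite interpolant over solver output nodes (value + derivative at
# node ends); C1, valid across the whole simulated span.
make_interpolant <- function(times, x, xdot) {
  structure(list(times = times, x = x, xdot = xdot),
            class = "hermite_interpolant")
}

interp_eval <- function(itp, tq) {
  tt <- itp$times
  n <- length(tt)
  if (tq <= tt[1L]) return(itp$x[1L, ])
  if (tq >= tt[n]) return(itp$x[n, ])
  i <- findInterval(tq, tt)
  h <- tt[i + 1L] - tt[i]
  s <- (tq - tt[i]) / h
  h00 <- (1 + 2 * s) * (1 - s)^2
  h10 <- s * (1 - s)^2
  h01 <- s^2 * (3 - 2 * s)
  h11 <- s^2 * (s - 1)
  h00 * itp$x[i, ] + h10 * h * itp$xdot[i, ] +
    h01 * itp$x[i + 1L, ] + h11 * h * itp$xdot[i + 1L, ]
}

#' Simulate a compiled model
#'
#' Integrates `dx/dt = f(x, p, k, t)` from the first requested timepoint
#' with the configured (stiff by default) multistep method, using the
#' analytic Jacobian in the implicit solves, and evaluates the observables
#' at every requested timepoint. A cubic Hermite interpolant spanning the
#' whole interval is attached for adjoint replay.
#'
#' @param cm a `compiled_model`.
#' @param p numeric dynamic parameter vector.
#' @param k numeric fixed parameter vector.
#' @param x_init initial state; defaults to the model's `x0(p, k)`.
#' @param timepoints sorted, strictly increasing output times.
#' @param cfg a [solver_config()].
#' @return object of class `ode_trajectory` with fields `times`, `x`
#'   (times x n_x), `y` (times x n_y), `stats`, `interp`, `p`, `k`.
#' @export
simulate_model <- function(cm, p, k = numeric(0), x_init = NULL, timepoints,
                           cfg = solver_config()) {
  if (is.unsorted(timepoints, strictly = TRUE))
    stop("timepoints must be strictly increasing", call. = FALSE)
  if (is.null(x_init)) x_init <- cm$x0(p, k)
  if (length(x_init) != cm$dims$n_x)
    stop("x_init must have length ", cm$dims$n_x, call. = FALSE)

  t0 <- timepoints[1L]; tM <- timepoints[length(timepoints)]
  grid <- if (length(timepoints) == 1L) timepoints else
    sort(unique(c(timepoints, seq(t0, tM, length.out = cfg$interp_points))))

  if (length(grid) == 1L) {
    xmat <- matrix(x_init, 1L, cm$dims$n_x)
    xdot <- matrix(cm$f(x_init, p, k, t0), 1L, cm$dims$n_x)
    stats <- c(steps = 0, rhs_evals = 1, jac_evals = 0)
  } else {
    rhs <- function(t, y, parms) list(cm$f(y, p, k, t))
    jac <- function(t, y) as.matrix(cm$dfdx(y, p, k, t))
    res <- integrate_ode(rhs, jac, x_init, grid, cfg,
                         sparse_pattern = cm$patterns$dfdx)
    xmat <- unname(res$out[, -1L, drop = FALSE])
    stats <- res$stats
    xdot <- t(vapply(seq_along(grid),
                     function(i) cm$f(xmat[i, ], p, k, grid[i]),
                     numeric(cm$dims$n_x)))
    if (cm$dims$n_x == 1L) xdot <- matrix(xdot, ncol = 1L)
  }

  sel <- match(timepoints, grid)
  x_out <- xmat[sel, , drop = FALSE]
  colnames(x_out) <- cm$ids$states
  y_out <- matrix(NA_real_, length(timepoints), cm$dims$n_y,
                  dimnames = list(NULL, cm$ids$observables))
  for (i in seq_along(timepoints))
    y_out[i, ] <- cm$h(x_out[i, ], p, k, timepoints[i])

  structure(list(times = timepoints, x = x_out, y = y_out, stats = stats,
                 interp = make_interpolant(grid, xmat, xdot),
                 p = p, k = k, cfg = cfg),
            class = "ode_trajectory")
}

#' @export
print.ode_trajectory <- function(x, ...) {
  cat(sprintf("<ode_trajectory: %d timepoints over [%g, %g], %d states, %d outputs>\n",
              length(x$times), x$times[1L], x$times[length(x$times)],
              ncol(x$x), ncol(x$y)))
  invisible(x)
}

#' Evaluate the Jacobian df/dx at a point
#'
#' @param cm a `compiled_model`.
#' @param x,p,k,t evaluation point.
#' @param form `"dense"` (base matrix) or `"sparse"` (`dgCMatrix`).
#' @return the Jacobian in the requested representation.
#' @export
jacobian_at <- function(cm, x, p, k = numeric(0), t = 0,
                        form = c("dense", "sparse")) {
  form <- match.arg(form)
  J <- cm$dfdx(x, p, k, t)
  if (form == "dense") as.matrix(J) else J
}

steady_state_failure <- function(msg, singular = FALSE) {
  cls <- c(if (singular) "odesens_singular_jacobian",
           "odesens_steady_state_failure")
  stop(errorCondition(paste0("steady-state failure: ", msg), class = cls))
}

#' Find a steady state f(x, p, k) = 0
#'
#' Tries damped Newton with the analytic Jacobian first (step halving down
#' to 2^-8); if Newton stalls or the Jacobian is singular (typical for
#' models with conservation laws), falls back to simulating with expanding
#' time horizons until the weighted RMS residual criterion is met, then
#' polishes with Newton where possible.
#'
#' @param cm a `compiled_model`.
#' @param p,k parameter vectors.
#' @param x_guess starting state; defaults to `x0(p, k)`.
#' @param cfg a [solver_config()].
#' @return object of class `steady_state` with `x_ss`, `residual_norm`
#'   (weighted RMS of f, < 1 on success), `method_used` (`newton`,
#'   `simulation` or `newton_after_simulation`), `t_reached` and a
#'   `singular_jacobian` flag.
#' @export
find_steady_state <- function(cm, p, k = numeric(0), x_guess = NULL,
                              cfg = solver_config()) {
  if (is.null(x_guess)) x_guess <- cm$x0(p, k)
  fx <- function(x) cm$f(x, p, k, 0)
  Jx <- function(x) as.matrix(cm$dfdx(x, p, k, 0))
  singular_seen <- FALSE

  newton <- function(x) {
    for (it in seq_len(cfg$newton_max_iters)) {
      fv <- fx(x)
      r <- wrms_norm(fv, x, cfg)
      if (r < 1) return(list(x = x, resid = r, ok = TRUE))
      J <- Jx(x)
      delta <- tryCatch(solve(J, -fv), error = function(e) NULL)
      if (is.null(delta) || anyNA(delta) || any(!is.finite(delta))) {
        singular_seen <<- TRUE
        return(list(ok = FALSE, singular = TRUE))
      }
      alpha <- 1
      accepted <- FALSE
      while (alpha >= 2^-8) {
        x_new <- x + alpha * delta
        r_new <- wrms_norm(fx(x_new), x_new, cfg)
        if (is.finite(r_new) && r_new < r) {
          x <- x_new; accepted <- TRUE; break
        }
        alpha <- alpha / 2
      }
      if (!accepted) return(list(ok = FALSE, singular = FALSE))
    }
    fv <- fx(x)
    r <- wrms_norm(fv, x, cfg)
    list(x = x, resid = r, ok = r < 1)
  }

  nres <- newton(x_guess)
  if (isTRUE(nres$ok))
    return(structure(list(x_ss = nres$x, residual_norm = nres$resid,
                          method_used = "newton", t_reached = NA_real_,
                          singular_jacobian = FALSE),
                     class = "steady_state"))

  # simulation fallback with expanding horizons
  x <- x_guess
  t_total <- 0
  span <- 1
  while (t_total < cfg$ss_t_max) {
    traj <- tryCatch(
      simulate_model(cm, p, k, x_init = x, timepoints = c(0, span),
                     cfg = cfg),
      error = function(e) e)
    if (inherits(traj, "error"))
      steady_state_failure(
        paste0("simulation fallback failed: ", conditionMessage(traj)),
        singular = singular_seen)
    x <- traj$x[nrow(traj$x), ]
    t_total <- t_total + span
    r <- wrms_norm(fx(x), x, cfg)
    if (r < 1) {
      polish <- newton(x)
      if (isTRUE(polish$ok) && polish$resid < r)
        return(structure(list(x_ss = polish$x, residual_norm = polish$resid,
                              method_used = "newton_after_simulation",
                              t_reached = t_total,
                              singular_jacobian = singular_seen),
                         class = "steady_state"))
      return(structure(list(x_ss = x, residual_norm = r,
                            method_used = "simulation", t_reached = t_total,
                            singular_jacobian = singular_seen),
                       class = "steady_state"))
    }
    span <- span * 10
  }
  steady_state_failure(
    sprintf("no steady state within t = %g", cfg$ss_t_max),
    singular = singular_seen)
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("<steady_state via %s: residual_norm = %.3g%s>\n",
              x$method_used, x$residual_norm,
              if (is.finite(x$t_reached))
                sprintf(", t_reached = %g", x$t_reached) else ""))
  invisible(x)
}
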