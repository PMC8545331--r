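# Symbolic ODE model container.
#
# A model is the tuple (x, p, k, f, x0, h, sigma, S, v): states with initial
# expressions, dynamic parameters with nominal values, fixed parameters
# (condition-settable constants, including compartment sizes), the right-hand
# side f(x, p, k, t), observables h(x, p, k, t) with noise formulas
# sigma(p, k), and — when built from reactions — the stoichiometric matrix S
# and flux vector v with f = S v.

TIME_SYMBOL <- "t"

#' Construct a symbolic ODE model
#'
#' @param states character vector of state (species) identifiers.
#' @param rhs list of language objects, one per state: dx/dt = f(x, p, k, t).
#' @param x0 named list (per state) of initial-value expressions or numbers.
#' @param parameters named numeric vector of dynamic parameters `p` with
#'   nominal values.
#' @param fixed named numeric vector of fixed parameters `k`
#'   (condition-settable constants; includes compartment sizes).
#' @param observables named list of observable expressions `h(x, p, k, t)`.
#' @param sigmas named list of noise-scale expressions `sigma(p, k)`, one per
#'   observable (state-dependent noise is not supported).
#' @param stoichiometry optional numeric matrix, species x reactions.
#' @param fluxes optional list of kinetic-law expressions, one per reaction.
#' @param name model identifier.
#' @return an object of class `ode_model`.
#' @export
ode_model <- function(states, rhs, x0, parameters,
                      fixed = numeric(0), observables = list(),
                      sigmas = list(), stoichiometry = NULL, fluxes = NULL,
                      name = "model") {
  rhs <- lapply(rhs, simplify_expr)
  x0 <- x0[states]
  m <- structure(list(
    name = name,
    states = as.character(states),
    rhs = rhs,
    x0 = x0,
    parameters = parameters,
    fixed = fixed,
    observables = observables,
    sigmas = sigmas,
    stoichiometry = stoichiometry,
    fluxes = fluxes
  ), class = "ode_model")
  diags <- validate_model(m)
  if (length(diags))
    stop("invalid model: ", paste(diags, collapse = "; "), call. = FALSE)
  m
}

#' @export
print.ode_model <- function(x, ...) {
  cat(sprintf("<ode_model '%s': %d states, %d parameters, %d fixed, %d observables>\n",
              x$name, length(x$states), length(x$parameters),
              length(x$fixed), length(x$observables)))
  invisible(x)
}

#' Validate a model's symbol bookkeeping
#'
#' Checks that identifiers are unique and disjoint, that every free symbol in
#' rhs, x0, observables and noise formulas is declared among states, dynamic
#' parameters, fixed parameters or the reserved time symbol `t`, and that
#' dimensions agree. Diagnostics are data: an empty character vector means
#' the model is valid.
#'
#' @param m an `ode_model`.
#' @return character vector of diagnostic messages (empty if valid).
#' @export
validate_model <- function(m) {
  diags <- character(0)
  ids <- c(m$states, names(m$parameters), names(m$fixed))
  dup <- unique(ids[duplicated(ids)])
  for (d in dup)
    diags <- c(diags, sprintf("duplicate identifier '%s'", d))
  obs_dup <- unique(names(m$observables)[duplicated(names(m$observables))])
  for (d in obs_dup)
    diags <- c(diags, sprintf("duplicate observable id '%s'", d))
  if (any(names(m$observables) %in% ids))
    diags <- c(diags, sprintf(
      "observable id collides with model identifier: %s",
      paste(intersect(names(m$observables), ids), collapse = ", ")))
  if (length(m$rhs) != length(m$states))
    diags <- c(diags, sprintf("rhs has length %d but there are %d states",
                              length(m$rhs), length(m$states)))
  if (!setequal(names(m$x0), m$states) || length(m$x0) != length(m$states))
    diags <- c(diags, "x0 must have exactly one entry per state")
  declared <- c(ids, TIME_SYMBOL)
  check_syms <- function(e, where) {
    unknown <- setdiff(free_symbols(e), declared)
    vapply(unknown, function(s)
      sprintf("undeclared symbol '%s' in %s", s, where), character(1L))
  }
  for (i in seq_along(m$rhs))
    diags <- c(diags, check_syms(m$rhs[[i]], sprintf("rhs[%s]", m$states[i])))
  for (s in names(m$x0))
    diags <- c(diags, check_syms(m$x0[[s]], sprintf("x0[%s]", s)))
  for (o in names(m$observables))
    diags <- c(diags, check_syms(m$observables[[o]],
                                 sprintf("observable '%s'", o)))
  for (o in names(m$sigmas)) {
    e <- m$sigmas[[o]]
    diags <- c(diags, check_syms(e, sprintf("noise formula '%s'", o)))
    bad <- intersect(free_symbols(e), m$states)
    if (length(bad))
      diags <- c(diags, sprintf(
        "noise formula '%s' depends on state(s) %s; state-dependent noise is not supported",
        o, paste(bad, collapse = ", ")))
  }
  unname(diags)
}

#' Assemble the ODE right-hand side from stoichiometry and fluxes
#'
#' Computes `f_i = sum_j S[i, j] * v[j]` symbolically, flattening sums and
#' dropping zero terms but performing no aggressive simplification.
#'
#' @param S numeric stoichiometric matrix (species x reactions).
#' @param v list of flux (kinetic-law) expressions, one per reaction.
#' @return list of rhs expressions, one per species.
#' @export
reactions_to_odes <- function(S, v) {
  S <- as.matrix(S)
  if (ncol(S) != length(v))
    stop("stoichiometry has ", ncol(S), " columns but ", length(v),
         " fluxes were given", call. = FALSE)
  lapply(seq_len(nrow(S)), function(i) {
    acc <- 0
    for (j in seq_along(v)) {
      s_ij <- S[i, j]
      if (s_ij == 0) next
      term <- if (s_ij == 1) v[[j]]
              else if (s_ij == -1) call("-", v[[j]])
              else call("*", s_ij, v[[j]])
      acc <- if (is_zero_expr(acc)) term else {
        if (is.call(term) && identical(term[[1L]], as.name("-")) &&
            length(term) == 2L)
          call("-", acc, term[[2L]])
        else
          call("+", acc, term)
      }
    }
    simplify_expr(acc)
  })
}

#' Attach observables and noise formulas to a model
#'
#' @param m an `ode_model`.
#' @param observables named list of expressions (or formula strings)
#'   `h(x, p, k, t)`.
#' @param sigmas named list of noise-scale expressions `sigma(p, k)`; a
#'   single unnamed value is recycled across observables.
#' @return the updated model (re-validated).
#' @export
set_observables <- function(m, observables, sigmas = list()) {
  as_expr <- function(v) if (is.character(v)) parse_formula(v) else v
  observables <- lapply(observables, as_expr)
  if (length(sigmas) == 1L && is.null(names(sigmas)))
    sigmas <- stats::setNames(rep(sigmas, length(observables)),
                              names(observables))
  sigmas <- lapply(sigmas, as_expr)
  m$observables <- observables
  m$sigmas <- sigmas
  diags <- validate_model(m)
  if (length(diags))
    stop("invalid observables: ", paste(diags, collapse = "; "),
         call. = FALSE)
  m
}

# Dimensions helper used throughout.
model_dims <- function(m) {
  list(n_x = length(m$states), n_p = length(m$parameters),
       n_k = length(m$fixed), n_y = length(m$observables))
}
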