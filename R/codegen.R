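# Symbolic partial derivatives and compiled numeric evaluators.
#
# The central performance design: every partial derivative of the model
# (df/dx, df/dp, dx0/dp, dh/dx, dh/dp, dsigma/dp) is derived symbolically
# exactly once; total derivatives such as dy/dp are never derived
# symbolically but assembled at runtime from the partials by sparse matrix
# multiplication and addition. Sparse carriers are CSC (Matrix::dgCMatrix)
# with a fixed canonical entry order, so repeated evaluations are
# bit-reproducible.

sym_mat <- function(nr, nc, dimnames = NULL) {
  m <- matrix(vector("list", nr * nc), nr, nc, dimnames = dimnames)
  for (i in seq_len(nr * nc)) m[[i]] <- 0
  m
}

#' Structural sparsity pattern of a symbolic matrix
#'
#' An entry belongs to the pattern iff bounded symbolic simplification does
#' not reduce it to the zero expression; entries not provably zero stay in
#' the pattern (conservative-exact). Ordering is row-major and deterministic.
#'
#' @param sm a matrix of language objects (mode list).
#' @return data.frame with integer columns `row`, `col`.
#' @export
sparsity_pattern <- function(sm) {
  nr <- nrow(sm); nc <- ncol(sm)
  rows <- integer(0); cols <- integer(0)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!is_zero_expr(simplify_expr(sm[[i, j]]))) {
      rows <- c(rows, i); cols <- c(cols, j)
    }
  }
  data.frame(row = rows, col = cols)
}

#' Derive all first-order partial derivatives of a model
#'
#' Symbolically differentiates the right-hand side, initial values,
#' observables and noise formulas with respect to states and dynamic
#' parameters, and records the structural sparsity pattern of each matrix.
#'
#' @param m a validated `ode_model`.
#' @return object of class `partial_derivatives` with symbolic matrices
#'   `dfdx` (the Jacobian), `dfdp`, `dx0dp`, `dhdx`, `dhdp`, `dsigmadp` and
#'   a `patterns` list.
#' @export
derive_partials <- function(m) {
  diags <- validate_model(m)
  if (length(diags))
    stop("model is invalid: ", paste(diags, collapse = "; "), call. = FALSE)
  d <- model_dims(m)
  pnames <- names(m$parameters)
  obs <- names(m$observables)

  dmat <- function(exprs, wrt) {
    sm <- sym_mat(length(exprs), length(wrt))
    for (i in seq_along(exprs)) for (j in seq_along(wrt))
      sm[[i, j]] <- diff_expr(exprs[[i]], wrt[j])
    sm
  }
  dfdx <- dmat(m$rhs, m$states)
  dfdp <- dmat(m$rhs, pnames)
  dx0dp <- dmat(m$x0, pnames)
  dhdx <- dmat(m$observables[obs], m$states)
  dhdp <- dmat(m$observables[obs], pnames)
  dsigmadp <- dmat(m$sigmas[obs], pnames)

  mats <- list(dfdx = dfdx, dfdp = dfdp, dx0dp = dx0dp,
               dhdx = dhdx, dhdp = dhdp, dsigmadp = dsigmadp)
  structure(c(mats, list(patterns = lapply(mats, sparsity_pattern),
                         dims = d)),
            class = "partial_derivatives")
}

# Substitution map sending model symbols to positional vector lookups
# (states -> x[[i]], dynamic parameters -> p[[i]], fixed -> k[[i]]). The
# reserved time symbol stays `t` and binds to the evaluator argument.
index_map <- function(m) {
  map <- list()
  for (i in seq_along(m$states))
    map[[m$states[i]]] <- bquote(x[[.(i)]])
  for (i in seq_along(m$parameters))
    map[[names(m$parameters)[i]]] <- bquote(p[[.(i)]])
  for (i in seq_along(m$fixed))
    map[[names(m$fixed)[i]]] <- bquote(k[[.(i)]])
  map
}

# Compile a list of expressions into one pure vector-valued closure.
compile_vector_fn <- function(exprs, map, args = c("x", "p", "k", "t")) {
  n <- length(exprs)
  if (n == 0L) {
    f <- function() numeric(0)
    formals(f) <- stats::setNames(rep(alist(x = ), length(args)), args)
    environment(f) <- baseenv()
    return(f)
  }
  body_exprs <- lapply(exprs, function(e) subst_expr(simplify_expr(e), map))
  body <- as.call(c(list(as.name("c")), body_exprs))
  f <- function() NULL
  formals(f) <- stats::setNames(rep(alist(x = ), length(args)), args)
  body(f) <- body
  environment(f) <- baseenv()
  f
}

# Compile a symbolic matrix into a closure returning a dgCMatrix honoring
# the declared pattern (explicit zeros kept if a pattern entry evaluates to
# zero numerically at some point).
compile_sparse_fn <- function(sm, pattern, map, args = c("x", "p", "k", "t")) {
  nr <- nrow(sm); nc <- ncol(sm)
  env <- new.env(parent = baseenv())
  env$.i <- pattern$row
  env$.j <- pattern$col
  env$.dims <- c(nr, nc)
  env$sparseMatrix <- Matrix::sparseMatrix
  if (nrow(pattern) == 0L) {
    f <- function() sparseMatrix(i = integer(0), j = integer(0),
                                 x = numeric(0), dims = .dims)
  } else {
    entries <- lapply(seq_len(nrow(pattern)), function(r)
      subst_expr(simplify_expr(sm[[pattern$row[r], pattern$col[r]]]), map))
    vals_call <- as.call(c(list(as.name("c")), entries))
    f <- function() NULL
    body(f) <- bquote(sparseMatrix(i = .i, j = .j, x = .(vals_call),
                                   dims = .dims))
  }
  formals(f) <- stats::setNames(rep(alist(x = ), length(args)), args)
  environment(f) <- env
  f
}

#' Compile a model and its partial derivatives to numeric evaluators
#'
#' Produces pure closures for `f`, `x0`, `h`, `sigma` and for every partial
#' derivative matrix; matrix evaluators return compressed sparse column
#' (`dgCMatrix`) values on exactly the declared structural pattern.
#'
#' @param m a validated `ode_model`.
#' @param pds result of [derive_partials()]; derived if missing.
#' @return object of class `compiled_model` with evaluator functions
#'   `f(x, p, k, t)`, `x0(p, k)`, `h(x, p, k, t)`, `sigma(p, k)`,
#'   `dfdx(x, p, k, t)`, `dfdp(x, p, k, t)`, `dx0dp(p, k)`,
#'   `dhdx(x, p, k, t)`, `dhdp(x, p, k, t)`, `dsigmadp(p, k)`, plus
#'   `dims`, `ids`, `patterns` and the source `model`.
#' @export
compile_functions <- function(m, pds = derive_partials(m)) {
  map <- index_map(m)
  d <- model_dims(m)
  obs <- names(m$observables)
  xpkt <- c("x", "p", "k", "t")
  pk <- c("p", "k")
  cm <- structure(list(
    f = compile_vector_fn(m$rhs, map, xpkt),
    x0 = compile_vector_fn(m$x0[m$states], map, pk),
    h = compile_vector_fn(m$observables[obs], map, xpkt),
    sigma = compile_vector_fn(m$sigmas[obs], map, pk),
    dfdx = compile_sparse_fn(pds$dfdx, pds$patterns$dfdx, map, xpkt),
    dfdp = compile_sparse_fn(pds$dfdp, pds$patterns$dfdp, map, xpkt),
    dx0dp = compile_sparse_fn(pds$dx0dp, pds$patterns$dx0dp, map, pk),
    dhdx = compile_sparse_fn(pds$dhdx, pds$patterns$dhdx, map, xpkt),
    dhdp = compile_sparse_fn(pds$dhdp, pds$patterns$dhdp, map, xpkt),
    dsigmadp = compile_sparse_fn(pds$dsigmadp, pds$patterns$dsigmadp, map, pk),
    patterns = pds$patterns,
    dims = d,
    ids = list(states = m$states, parameters = names(m$parameters),
               fixed = names(m$fixed), observables = obs),
    model = m,
    partials = pds
  ), class = "compiled_model")
  cm
}

#' @export
print.compiled_model <- function(x, ...) {
  cat(sprintf("<compiled_model '%s': n_x=%d n_p=%d n_k=%d n_y=%d>\n",
              x$model$name, x$dims$n_x, x$dims$n_p, x$dims$n_k, x$dims$n_y))
  invisible(x)
}

#' Assemble an output sensitivity from partials at runtime
#'
#' Computes the total derivative `dy/dp = dh/dx . sx + dh/dp` by sparse
#' matrix multiplication and addition; no total derivative is ever derived
#' symbolically.
#'
#' @param dhdx numeric sparse or dense matrix, `n_y x n_x`.
#' @param sx numeric dense matrix of state sensitivities, `n_x x n_p`.
#' @param dhdp numeric sparse or dense matrix, `n_y x n_p`.
#' @return dense numeric matrix `n_y x n_p`.
#' @export
assemble_output_sensitivity <- function(dhdx, sx, dhdp) {
  sx <- as.matrix(sx)
  if (ncol(dhdx) != nrow(sx) || nrow(dhdx) != nrow(dhdp) ||
      ncol(sx) != ncol(dhdp))
    stop("shape mismatch: dhdx is ", nrow(dhdx), "x", ncol(dhdx),
         ", sx is ", nrow(sx), "x", ncol(sx),
         ", dhdp is ", nrow(dhdp), "x", ncol(dhdp), call. = FALSE)
  as.matrix(dhdx %*% sx + dhdp)
}

#' Dump symbolic partials and sparsity patterns to a text report
#'
#' @param pds a `partial_derivatives` object.
#' @param file path of the plain-text report to write.
#' @return invisibly, the report lines.
#' @export
write_partials_report <- function(pds, file) {
  lines <- character(0)
  for (nm in c("dfdx", "dfdp", "dx0dp", "dhdx", "dhdp", "dsigmadp")) {
    sm <- pds[[nm]]
    pat <- pds$patterns[[nm]]
    lines <- c(lines, sprintf("== %s (%d x %d, %d structural nonzeros)",
                              nm, nrow(sm), ncol(sm), nrow(pat)))
    if (nrow(pat))
      lines <- c(lines, vapply(seq_len(nrow(pat)), function(r)
        sprintf("  [%d,%d] = %s", pat$row[r], pat$col[r],
                expr_to_string(sm[[pat$row[r], pat$col[r]]])),
        character(1L)))
  }
  writeLines(lines, file)
  invisible(lines)
}
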