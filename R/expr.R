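# Symbolic expression utilities.
#
# Model mathematics are carried as R language objects (names, numbers and
# calls). Differentiation is delegated to stats::D; on top of it sit a
# bounded-effort simplifier (constant folding plus algebraic identities) used
# for zero recognition, a capture-avoiding-enough substitution helper, and a
# numeric-probe equality check used by tests.

#' @keywords internal
is_num <- function(e) is.numeric(e) && length(e) == 1L

is_zero_expr <- function(e) is_num(e) && e == 0
is_one_expr <- function(e) is_num(e) && e == 1

# Functions whose calls may be constant-folded when all arguments are numeric.
.foldable_fns <- c("+", "-", "*", "/", "^", "exp", "log", "sqrt", "sin",
                   "cos", "tan", "abs", "(")

#' Simplify a symbolic expression (bounded effort)
#'
#' Recursively applies constant folding and elementary identities
#' (`x + 0`, `x * 0`, `x * 1`, `x / 1`, `x^0`, `x^1`, `a - a`, double
#' negation, parenthesis stripping). The goal is reliable recognition of
#' structural zeros, not canonical forms: an expression that does not
#' simplify to the number 0 is treated as structurally nonzero.
#'
#' @param e a language object (name, number, or call).
#' @return the simplified language object.
#' @export
simplify_expr <- function(e) {
  if (is_num(e) || is.name(e)) return(e)
  if (!is.call(e)) return(e)
  op <- as.character(e[[1L]])
  args <- lapply(as.list(e)[-1L], simplify_expr)

  if (op == "(") return(args[[1L]])

  if (op %in% .foldable_fns && all(vapply(args, is_num, logical(1L)))) {
    val <- eval(as.call(c(as.name(op), args)), baseenv())
    if (is.finite(val)) return(val)
  }

  if (op == "+" && length(args) == 2L) {
    if (is_zero_expr(args[[1L]])) return(args[[2L]])
    if (is_zero_expr(args[[2L]])) return(args[[1L]])
  }
  if (op == "-" && length(args) == 1L) {
    a <- args[[1L]]
    if (is_num(a)) return(-a)
    if (is.call(a) && identical(a[[1L]], as.name("-")) && length(a) == 2L)
      return(a[[2L]])
    return(call("-", a))
  }
  if (op == "-" && length(args) == 2L) {
    if (is_zero_expr(args[[2L]])) return(args[[1L]])
    if (is_zero_expr(args[[1L]])) return(simplify_expr(call("-", args[[2L]])))
    if (identical(args[[1L]], args[[2L]])) return(0)
  }
  if (op == "*") {
    if (is_zero_expr(args[[1L]]) || is_zero_expr(args[[2L]])) return(0)
    if (is_one_expr(args[[1L]])) return(args[[2L]])
    if (is_one_expr(args[[2L]])) return(args[[1L]])
  }
  if (op == "/") {
    if (is_zero_expr(args[[1L]])) return(0)
    if (is_one_expr(args[[2L]])) return(args[[1L]])
  }
  if (op == "^") {
    if (is_zero_expr(args[[2L]])) return(1)
    if (is_one_expr(args[[2L]])) return(args[[1L]])
  }
  as.call(c(e[[1L]], args))
}

#' Differentiate a symbolic expression
#'
#' Thin wrapper over [stats::D()] that simplifies the result and reports
#' non-differentiable expressions by name.
#'
#' @param e language object.
#' @param var variable name (string) to differentiate with respect to.
#' @return simplified derivative as a language object.
#' @export
diff_expr <- function(e, var) {
  d <- tryCatch(
    stats::D(e, var),
    error = function(err) {
      stop("cannot differentiate expression '", expr_to_string(e),
           "' with respect to '", var, "': ", conditionMessage(err),
           call. = FALSE)
    }
  )
  simplify_expr(d)
}

#' Substitute symbols in an expression
#'
#' @param e language object.
#' @param map named list mapping symbol names to replacement language
#'   objects or numbers.
#' @return the expression with every occurrence replaced.
#' @export
subst_expr <- function(e, map) {
  if (length(map) == 0L) return(e)
  do.call(substitute, list(e, map))
}

#' Free symbols of an expression
#'
#' @param e language object.
#' @return character vector of symbol names (excluding function names).
#' @export
free_symbols <- function(e) all.vars(e)

expr_to_string <- function(e) paste(deparse(e), collapse = " ")

#' Numeric-probe equality of two expressions
#'
#' Evaluates both expressions at `n` random points for their combined free
#' symbols and checks relative agreement. Used by tests for round-trip and
#' chain-rule checks; not part of the zero-recognition path, which is purely
#' symbolic.
#'
#' @param a,b language objects.
#' @param n number of probe points.
#' @param tol relative tolerance.
#' @param seed RNG seed for reproducible probes.
#' @return TRUE/FALSE.
#' @export
exprs_numerically_equal <- function(a, b, n = 20L, tol = 1e-10, seed = 1L) {
  syms <- union(free_symbols(a), free_symbols(b))
  set.seed(seed)
  for (i in seq_len(n)) {
    env <- as.list(stats::setNames(stats::runif(length(syms), 0.1, 2), syms))
    va <- eval(a, env, baseenv())
    vb <- eval(b, env, baseenv())
    if (!isTRUE(abs(va - vb) <= tol * max(1, abs(va), abs(vb)))) return(FALSE)
  }
  TRUE
}

# Parse a scalar formula string into a language object, rejecting anything
# that is not a single arithmetic expression.
parse_formula <- function(s) {
  p <- tryCatch(parse(text = s, keep.source = FALSE),
                error = function(e) stop("cannot parse formula '", s, "': ",
                                         conditionMessage(e), call. = FALSE))
  if (length(p) != 1L)
    stop("formula '", s, "' is not a single expression", call. = FALSE)
  e <- p[[1L]]
  bad <- intersect(all.names(e), c("<-", "=", ";", "{", "function", "for",
                                   "while", "repeat", "[", "[[", "$"))
  if (length(bad))
    stop("formula '", s, "' contains unsupported construct '", bad[1L], "'",
         call. = FALSE)
  e
}
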