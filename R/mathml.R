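# MathML (SBML subset) <-> R expression conversion.
#
# Covers the content-MathML constructs used by kinetic laws of ODE reaction
# networks: numbers, identifiers, the time csymbol, n-ary plus/times, minus,
# divide, power/root, exp/ln/log and elementary trig. Delay csymbols and
# piecewise are reported as unsupported constructs.

.mathml_unary <- c(exp = "exp", ln = "log", abs = "abs",
                   sin = "sin", cos = "cos", tan = "tan",
                   sinh = "sinh", cosh = "cosh", tanh = "tanh",
                   arcsin = "asin", arccos = "acos", arctan = "atan")

mathml_to_expr <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "math") {
    kids <- xml2::xml_children(node)
    if (length(kids) != 1L)
      stop("MathML <math> must contain exactly one expression", call. = FALSE)
    return(mathml_to_expr(kids[[1L]]))
  }
  if (nm == "cn") {
    type <- xml2::xml_attr(node, "type")
    txts <- trimws(xml2::xml_text(node))
    if (!is.na(type) && type %in% c("e-notation", "rational")) {
      parts <- strsplit(txts, "\\s+")[[1L]]
      parts <- as.numeric(parts[nzchar(parts)])
      if (length(parts) != 2L)
        stop("malformed <cn type='", type, "'>", call. = FALSE)
      return(if (type == "e-notation") parts[1L] * 10^parts[2L]
             else parts[1L] / parts[2L])
    }
    v <- suppressWarnings(as.numeric(txts))
    if (is.na(v)) stop("malformed <cn> value '", txts, "'", call. = FALSE)
    return(v)
  }
  if (nm == "ci") return(as.name(trimws(xml2::xml_text(node))))
  if (nm == "csymbol") {
    url <- xml2::xml_attr(node, "definitionURL")
    if (grepl("time", url, fixed = TRUE)) return(as.name(TIME_SYMBOL))
    if (grepl("avogadro", url, fixed = TRUE)) return(6.02214179e23)
    if (grepl("delay", url, fixed = TRUE))
      stop("unsupported MathML csymbol 'delay'", call. = FALSE)
    stop("unsupported MathML csymbol '", url, "'", call. = FALSE)
  }
  if (nm == "pi") return(pi)
  if (nm == "exponentiale") return(exp(1))
  if (nm == "piecewise")
    stop("unsupported MathML construct 'piecewise'", call. = FALSE)
  if (nm == "apply") {
    kids <- xml2::xml_children(node)
    op <- xml2::xml_name(kids[[1L]])
    # <degree>/<logbase> qualifiers carry their operand as a child
    get_arg <- function(n) {
      if (xml2::xml_name(n) %in% c("degree", "logbase"))
        mathml_to_expr(xml2::xml_children(n)[[1L]])
      else mathml_to_expr(n)
    }
    args <- lapply(kids[-1L], get_arg)
    qual <- vapply(kids[-1L], function(n)
      xml2::xml_name(n) %in% c("degree", "logbase"), logical(1L))
    nary <- function(fun, args) Reduce(function(a, b) call(fun, a, b), args)
    if (op == "plus") {
      if (length(args) == 0L) return(0)
      return(nary("+", args))
    }
    if (op == "times") {
      if (length(args) == 0L) return(1)
      return(nary("*", args))
    }
    if (op == "minus")
      return(if (length(args) == 1L) call("-", args[[1L]])
             else nary("-", args))
    if (op == "divide") return(call("/", args[[1L]], args[[2L]]))
    if (op == "power") return(call("^", args[[1L]], args[[2L]]))
    if (op == "root") {
      if (any(qual)) {
        deg <- args[[which(qual)[1L]]]
        rad <- args[[which(!qual)[1L]]]
        return(call("^", rad, call("/", 1, deg)))
      }
      return(call("sqrt", args[[1L]]))
    }
    if (op == "log") {
      if (any(qual)) {
        base <- args[[which(qual)[1L]]]
        x <- args[[which(!qual)[1L]]]
        return(call("/", call("log", x), call("log", base)))
      }
      return(call("/", call("log", args[[1L]]), call("log", 10)))
    }
    if (op %in% names(.mathml_unary))
      return(call(.mathml_unary[[op]], args[[1L]]))
    stop("unsupported MathML operator '", op, "'", call. = FALSE)
  }
  stop("unsupported MathML construct '", nm, "'", call. = FALSE)
}

# R expression -> content MathML string (used by the SBML export helper).
expr_to_mathml <- function(e) {
  paste0('<math xmlns="http://www.w3.org/1998/Math/MathML">',
         expr_to_mathml_node(e), "</math>")
}

expr_to_mathml_node <- function(e) {
  if (is_num(e)) {
    if (e == round(e) && abs(e) < 1e15)
      return(sprintf('<cn type="integer"> %d </cn>', as.integer(e)))
    return(sprintf("<cn> %.17g </cn>", e))
  }
  if (is.name(e)) {
    s <- as.character(e)
    if (s == TIME_SYMBOL)
      return(paste0('<csymbol encoding="text" definitionURL=',
                    '"http://www.sbml.org/sbml/symbols/time"> t </csymbol>'))
    return(sprintf("<ci> %s </ci>", s))
  }
  if (!is.call(e)) stop("cannot serialize to MathML: ", expr_to_string(e))
  op <- as.character(e[[1L]])
  args <- as.list(e)[-1L]
  if (op == "(") return(expr_to_mathml_node(args[[1L]]))
  inner <- paste(vapply(args, expr_to_mathml_node, character(1L)),
                 collapse = "")
  tag <- switch(op,
    "+" = "plus", "*" = "times", "/" = "divide", "^" = "power",
    "-" = "minus",
    "exp" = "exp", "log" = "ln", "sqrt" = "root", "abs" = "abs",
    "sin" = "sin", "cos" = "cos", "tan" = "tan",
    stop("cannot serialize operator '", op, "' to MathML", call. = FALSE))
  sprintf("<apply><%s/>%s</apply>", tag, inner)
}
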