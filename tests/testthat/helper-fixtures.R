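# Shared test helpers: independent oracles and small model builders.

# Maximum mixed absolute/relative deviation (floor 1 on the reference).
mixed_err <- function(a, ref) {
  a <- as.numeric(a); ref <- as.numeric(ref)
  max(abs(a - ref) / pmax(1, abs(ref)))
}

# Pairwise relative difference on components above a magnitude floor.
rel_diff <- function(a, b, floor = 1e-8) {
  a <- as.numeric(a); b <- as.numeric(b)
  sel <- pmax(abs(a), abs(b)) > floor
  if (!any(sel)) return(0)
  max(abs(a[sel] - b[sel]) / pmax(abs(a[sel]), abs(b[sel])))
}

# Independent oracle for compiled evaluators: per-entry eval of the symbolic
# expression in a named environment (no index substitution, no c() fusion).
eval_exprs_subst <- function(exprs, env) {
  vapply(exprs, function(e) eval(e, env, baseenv()), numeric(1L))
}

eval_sym_matrix_subst <- function(sm, env) {
  out <- matrix(0, nrow(sm), ncol(sm))
  for (i in seq_len(nrow(sm))) for (j in seq_len(ncol(sm)))
    out[i, j] <- eval(sm[[i, j]], env, baseenv())
  out
}

model_env <- function(m, x, p, k = numeric(0), t = 0) {
  env <- c(as.list(stats::setNames(x, m$states)),
           as.list(stats::setNames(p, names(m$parameters))),
           as.list(stats::setNames(k, names(m$fixed))))
  env$t <- t
  env
}

# Random stable linear system dx/dt = A x + B p as a symbolic model.
random_linear_model <- function(n, n_p, seed) {
  set.seed(seed)
  M <- matrix(stats::rnorm(n * n), n, n)
  A <- -(M %*% t(M) + diag(n))   # symmetric negative definite -> stable
  B <- matrix(stats::rnorm(n * n_p), n, n_p)
  states <- sprintf("x%d", seq_len(n))
  pn <- sprintf("p%d", seq_len(n_p))
  rhs <- lapply(seq_len(n), function(i) {
    acc <- 0
    for (j in seq_len(n))
      acc <- call("+", acc, call("*", A[i, j], as.name(states[j])))
    for (j in seq_len(n_p))
      acc <- call("+", acc, call("*", B[i, j], as.name(pn[j])))
    simplify_expr(acc)
  })
  m <- ode_model(states = states, rhs = rhs,
                 x0 = stats::setNames(as.list(stats::runif(n)), states),
                 parameters = stats::setNames(stats::runif(n_p, 0.5, 1.5), pn),
                 name = sprintf("linear_%d", seed))
  list(model = m, A = A, B = B)
}

# PEtab bundle in a session-scoped temp dir (generated once per fixture).
petab_bundle_path <- local({
  cache <- new.env()
  function(name, seed = 1L) {
    key <- paste(name, seed)
    if (is.null(cache[[key]])) {
      d <- file.path(tempdir(), paste0("odesens_", name, "_", seed))
      generate_fixture(name, d, seed = seed, petab = TRUE)
      cache[[key]] <- file.path(d, "problem.yaml")
    }
    cache[[key]]
  }
})

load_bundle <- local({
  cache <- new.env()
  function(name, seed = 1L) {
    key <- paste(name, seed)
    if (is.null(cache[[key]]))
      cache[[key]] <- load_petab(petab_bundle_path(name, seed))
    cache[[key]]
  }
})

# Minimal SBML documents for importer error-path tests.
sbml_with <- function(extra) {
  sprintf('<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">
  <model id="m">
    <listOfCompartments>
      <compartment id="cell" size="1" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="A" compartment="cell" initialConcentration="1" boundaryCondition="false" constant="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="k1" value="1" constant="true"/>
    </listOfParameters>
    %s
    <listOfReactions>
      <reaction id="r1" reversible="false">
        <listOfReactants>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply><times/><ci>k1</ci><ci>A</ci></apply>
          </math>
        </kineticLaw>
      </reaction>
    </listOfReactions>
  </model>
</sbml>', extra)
}
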