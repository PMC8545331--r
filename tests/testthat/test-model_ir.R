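# SBML import, reaction-to-ODE assembly and model validation.

test_that("a one-species decay document imports to x=[A], p=[k1], f=[-k1*A]", {
  m <- import_sbml(sbml_with(""))
  expect_identical(m$states, "A")
  expect_identical(names(m$parameters), "k1")
  expect_true(exprs_numerically_equal(m$rhs[[1]], quote(-(k1 * A))))
  expect_equal(m$x0$A, 1)
  expect_identical(names(m$fixed), "cell")
})

test_that("a conversion reaction imports with correct stoichiometry and rhs", {
  fx <- fixture_model("conversion")
  m <- import_sbml(write_sbml(fx$model))
  expect_equal(unname(m$stoichiometry),
               matrix(c(-1, 1, 1, -1), 2, 2))
  expect_true(exprs_numerically_equal(m$rhs[[1]], quote(-k1 * A + k2 * B)))
  expect_true(exprs_numerically_equal(m$rhs[[2]], quote(k1 * A - k2 * B)))
})

test_that("unsupported constructs are rejected with errors naming them", {
  cases <- list(
    event = "<listOfEvents><event id=\"e1\"/></listOfEvents>",
    algebraicRule = "<listOfRules><algebraicRule><math xmlns=\"http://www.w3.org/1998/Math/MathML\"><ci>A</ci></math></algebraicRule></listOfRules>",
    functionDefinition = "<listOfFunctionDefinitions><functionDefinition id=\"f\"/></listOfFunctionDefinitions>")
  for (construct in names(cases)) {
    err <- tryCatch(import_sbml(sbml_with(cases[[construct]])),
                    error = function(e) e)
    expect_s3_class(err, "odesens_unsupported_feature")
    expect_match(conditionMessage(err), construct, fixed = TRUE)
  }
  # delay csymbol inside math
  delay_math <- sbml_with(paste0(
    '<listOfRules><rateRule variable="A">',
    '<math xmlns="http://www.w3.org/1998/Math/MathML">',
    '<csymbol definitionURL="http://www.sbml.org/sbml/symbols/delay"> d </csymbol>',
    "</math></rateRule></listOfRules>"))
  expect_error(import_sbml(delay_math), "delay",
               class = "odesens_unsupported_feature")
  # fast reaction
  fast <- sub('<reaction id="r1" reversible="false">',
              '<reaction id="r1" reversible="false" fast="true">',
              sbml_with(""), fixed = TRUE)
  expect_error(import_sbml(fast), "fast",
               class = "odesens_unsupported_feature")
})

test_that("malformed documents raise a structural error", {
  expect_error(import_sbml("<notsbml/>"),
               class = "odesens_malformed_document")
  expect_error(import_sbml("<sbml level=\"3\"><nomodel/></sbml>"),
               class = "odesens_malformed_document")
  expect_error(import_sbml("not xml at all <"),
               class = "odesens_malformed_document")
})

test_that("reactions_to_odes assembles f = S v with zero rows preserved", {
  f <- reactions_to_odes(matrix(c(-1, 1), 2, 1), list(quote(k1 * A)))
  expect_true(exprs_numerically_equal(f[[1]], quote(-(k1 * A))))
  expect_true(exprs_numerically_equal(f[[2]], quote(k1 * A)))
  f2 <- reactions_to_odes(matrix(c(-1, 0), 2, 1), list(quote(k1 * A)))
  expect_identical(f2[[2]], 0)
  expect_error(reactions_to_odes(matrix(0, 2, 2), list(quote(k1))),
               "2 columns")
})

test_that("validate_model reports undeclared symbols and duplicates as data", {
  m <- fixture_model("conversion")$model
  expect_length(validate_model(m), 0)
  m_bad <- m
  m_bad$observables$obs_Z <- quote(Z + A)
  d <- validate_model(m_bad)
  expect_true(any(grepl("'Z'", d)))
  m_dup <- m
  m_dup$parameters <- c(m_dup$parameters, k1 = 3)
  expect_true(any(grepl("'k1'", validate_model(m_dup))))
})

test_that("programmatic models round-trip through SBML export/import", {
  for (nm in c("decay", "conversion", "synthesis_degradation",
               "lotka_volterra")) {
    fx <- fixture_model(nm)
    m0 <- fx$model
    m0$observables <- list(); m0$sigmas <- list()
    m1 <- import_sbml(write_sbml(m0))
    expect_identical(m1$states, m0$states)
    expect_setequal(names(m1$parameters), names(m0$parameters))
    for (i in seq_along(m0$states)) {
      expect_true(exprs_numerically_equal(m1$rhs[[i]], m0$rhs[[i]]),
                  info = sprintf("%s rhs[%d]", nm, i))
      expect_true(exprs_numerically_equal(m1$x0[[m0$states[i]]],
                                          m0$x0[[m0$states[i]]]))
    }
  }
})

test_that("imported reaction networks satisfy f == S v symbolically", {
  for (nm in c("conversion", "lotka_volterra", "linear_chain")) {
    m <- import_sbml(write_sbml(local({
      fx <- fixture_model(nm)
      fx$model$observables <- list(); fx$model$sigmas <- list()
      fx$model
    })))
    f_sv <- reactions_to_odes(m$stoichiometry, m$fluxes)
    for (i in seq_along(m$rhs))
      expect_true(exprs_numerically_equal(m$rhs[[i]], f_sv[[i]]),
                  info = sprintf("%s state %d", nm, i))
  }
})

test_that("boundary species get zero stoichiometry rows", {
  xml <- sub('boundaryCondition="false"', 'boundaryCondition="true"',
             sbml_with(""), fixed = TRUE)
  m <- import_sbml(xml)
  expect_identical(m$rhs[[1]], 0)
  expect_equal(unname(m$stoichiometry["A", ]), 0)
})

test_that("initial assignments override plain initial values", {
  ia <- paste0('<listOfInitialAssignments><initialAssignment symbol="A">',
               '<math xmlns="http://www.w3.org/1998/Math/MathML">',
               '<apply><times/><cn> 2 </cn><ci>k1</ci></apply>',
               "</math></initialAssignment></listOfInitialAssignments>")
  m <- import_sbml(sbml_with(ia))
  expect_true(exprs_numerically_equal(m$x0$A, quote(2 * k1)))
})

test_that("amount-based initial values are converted to concentrations", {
  xml <- sbml_with("")
  xml <- sub('size="1"', 'size="2"', xml, fixed = TRUE)
  xml <- sub('initialConcentration="1"', 'initialAmount="3"', xml,
             fixed = TRUE)
  m <- import_sbml(xml)
  expect_equal(m$x0$A, 1.5)
  expect_equal(unname(m$fixed["cell"]), 2)
  # kinetic law divided by the (constant) compartment size
  expect_true(exprs_numerically_equal(m$fluxes[[1]], quote(k1 * A / 2)))
})

test_that("assignment rules on parameters are substituted symbolically", {
  ar <- paste0('<listOfParameters><parameter id="ktot" value="0"/></listOfParameters>',
               '<listOfRules><assignmentRule variable="ktot">',
               '<math xmlns="http://www.w3.org/1998/Math/MathML">',
               '<apply><times/><cn> 2 </cn><ci>k1</ci></apply>',
               "</math></assignmentRule></listOfRules>")
  xml <- sub("<listOfReactions>",
             paste0(ar, "<listOfReactions>"), sbml_with(""), fixed = TRUE)
  xml <- sub("<ci>k1</ci><ci>A</ci>", "<ci>ktot</ci><ci>A</ci>", xml,
             fixed = TRUE)
  m <- import_sbml(xml)
  expect_false("ktot" %in% names(m$parameters))
  expect_true(exprs_numerically_equal(m$rhs[[1]], quote(-(2 * k1 * A))))
})
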