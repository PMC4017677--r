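# SBML import/export.

model_equal <- function(a, b) {
  expect_setequal(a$rxns$id, b$rxns$id)
  expect_setequal(a$mets$id, b$mets$id)
  idx <- match(a$rxns$id, b$rxns$id)
  expect_equal(a$rxns$lb, b$rxns$lb[idx])
  expect_equal(a$rxns$ub, b$rxns$ub[idx])
  expect_equal(a$rxns$subsystem, b$rxns$subsystem[idx])
  for (r in a$rxns$id) {
    sa <- a$S[, r]; sa <- sa[sa != 0]
    sb <- b$S[, r]; sb <- sb[sb != 0]
    expect_equal(sa[order(names(sa))], sb[order(names(sb))])
    expect_identical(a$gpr_trees[[r]], b$gpr_trees[[r]])
  }
  expect_setequal(a$genes, b$genes)
}

test_that("write/read round-trips the didactic and random models", {
  for (m in list(toy_network()$model,
                 random_reference(fixture_spec(seed = 4,
                                               n_reactions = 12))$model)) {
    f <- tempfile(fileext = ".xml")
    write_sbml(m, f)
    m2 <- read_sbml(f)
    model_equal(m, m2)
    # second round trip is exact
    f2 <- tempfile(fileext = ".xml")
    write_sbml(m2, f2)
    model_equal(m2, read_sbml(f2))
  }
})

test_that("round trip preserves the curated core network with boundary-free ids", {
  m <- core_model()
  f <- tempfile(fileext = ".xml")
  write_sbml(m, f)
  m2 <- read_sbml(f)
  model_equal(m, m2)
  expect_true(any(reversible(m2)))
  expect_equal(sum(m2$rxns$is_exchange), sum(m$rxns$is_exchange))
})

test_that("boundary species round-trip as boundaryCondition species", {
  m <- gem_model(list(
    UP = list(stoich = c(`A_ext[b]` = -1, `A[c]` = 1), ub = 10),
    R1 = list(stoich = c(`A[c]` = -1, `B[c]` = 1), gpr = "G1"),
    OUT = list(stoich = c(`B[c]` = -1, `B_ext[b]` = 1), ub = 10)),
    boundary = c("A_ext[b]", "B_ext[b]"), id = "toy3")
  f <- tempfile(fileext = ".xml")
  write_sbml(m, f)
  txt <- readLines(f)
  expect_true(any(grepl('boundaryCondition="true"', txt)))
  m2 <- read_sbml(f)
  expect_equal(nrow(m2$mets), 2)
  expect_equal(nrow(m2$boundary_mets), 2)
  expect_true(all(m2$rxns$is_exchange == c(TRUE, FALSE, TRUE)))
  model_equal(m, m2)
})

test_that("fbc gene associations parse into the expected rule tree", {
  m <- gem_model(list(
    R1 = list(stoich = c(`A[c]` = -1, `B[c]` = 1),
              gpr = "(G1 and G2) or G3"),
    EX_A = list(stoich = c(`A[c]` = 1)),
    EX_B = list(stoich = c(`B[c]` = -1))))
  f <- tempfile(fileext = ".xml")
  write_sbml(m, f)
  m2 <- read_sbml(f)
  expect_identical(m2$gpr_trees[["R1"]], parse_gpr("(G1 and G2) or G3"))
})

test_that("SBML Level 2 with kineticLaw bounds and notes is accepted", {
  l2 <- '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
 <model id="l2toy">
  <listOfSpecies>
   <species id="A" compartment="c" boundaryCondition="false"/>
   <species id="B" compartment="c" boundaryCondition="false"/>
   <species id="A_b" compartment="e" boundaryCondition="true"/>
  </listOfSpecies>
  <listOfReactions>
   <reaction id="UP" reversible="false">
    <listOfReactants><speciesReference species="A_b"/></listOfReactants>
    <listOfProducts><speciesReference species="A"/></listOfProducts>
    <kineticLaw><listOfParameters>
      <parameter id="LOWER_BOUND" value="0"/>
      <parameter id="UPPER_BOUND" value="10"/>
    </listOfParameters></kineticLaw>
   </reaction>
   <reaction id="R1" reversible="true">
    <notes><body xmlns="http://www.w3.org/1999/xhtml">
      <p>GENE_ASSOCIATION: (G1 and G2) or G3</p>
      <p>SUBSYSTEM: toyway</p>
    </body></notes>
    <listOfReactants><speciesReference species="A"/></listOfReactants>
    <listOfProducts><speciesReference species="B" stoichiometry="2"/></listOfProducts>
   </reaction>
  </listOfReactions>
 </model>
</sbml>'
  f <- tempfile(fileext = ".xml")
  writeLines(l2, f)
  m <- read_sbml(f)
  expect_equal(m$rxns$lb, c(0, -1000))
  expect_equal(m$rxns$ub, c(10, 1000))
  expect_equal(unname(m$S["B", "R1"]), 2)
  expect_identical(m$gpr_trees[["R1"]], parse_gpr("(G1 and G2) or G3"))
  expect_equal(m$rxns$subsystem[2], "toyway")
  expect_equal(nrow(m$boundary_mets), 1)
})

test_that("malformed SBML and dangling references raise clear errors", {
  expect_error(read_sbml(tempfile()), "no such file")
  f <- tempfile(fileext = ".xml")
  writeLines("<sbml><model>", f)
  expect_error(read_sbml(f), "malformed")
  bad <- '<?xml version="1.0"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
 <model id="bad"><listOfSpecies><species id="A" compartment="c"/></listOfSpecies>
 <listOfReactions><reaction id="R1" reversible="false">
  <listOfReactants><speciesReference species="GHOST"/></listOfReactants>
  <listOfProducts><speciesReference species="A"/></listOfProducts>
 </reaction></listOfReactions></model></sbml>'
  writeLines(bad, f)
  expect_error(read_sbml(f), "GHOST")
})
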