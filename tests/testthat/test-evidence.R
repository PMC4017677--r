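# Ordinal evidence, imputation, and score propagation.

ev_fixture <- function() {
  evidence_matrix(matrix(c(
    "strong",   "strong",  "weak",    NA,
    NA,         "strong",  "strong",  "weak",
    "negative", NA,        NA,        NA,
    NA,         NA,        NA,        NA),
    nrow = 4, byrow = TRUE,
    dimnames = list(paste0("G", 1:4), paste0("S", 1:4))))
}

test_that("evidence_matrix validates and encodes symbols", {
  ev <- ev_fixture()
  expect_equal(unname(ev["G1", "S1"]), 3L)
  expect_true(is.na(ev["G2", "S1"]))
  expect_error(evidence_matrix(matrix("loud", 1, 1,
                                      dimnames = list("G", "S"))),
               "unknown evidence symbol")
  expect_error(evidence_matrix(matrix(7L, 1, 1,
                                      dimnames = list("G", "S"))), "0..3")
})

test_that("evidence TSV round-trips", {
  ev <- ev_fixture()
  f <- tempfile(fileext = ".tsv")
  write_evidence(ev, f)
  expect_identical(unclass(read_evidence(f)), unclass(ev))
})

test_that("ordinal_median applies the stated tie rule", {
  expect_equal(ordinal_median(c(3, 3, 1)), 3)   # odd count: middle value
  expect_equal(ordinal_median(c(3, 1)), 2)      # integral midpoint kept
  expect_equal(ordinal_median(c(3, 2)), 2)      # fractional midpoint floors
  expect_equal(ordinal_median(c(0, 1, 2, 3)), 1)
  expect_equal(ordinal_median(2), 2)
})

test_that("impute_missing fills only missing cells of the target sample", {
  ev <- ev_fixture()
  imp <- impute_missing(ev, "S1")
  expect_equal(unname(imp["G1", "S1"]), 3L)            # measured: untouched
  expect_equal(unname(imp["G2", "S1"]),
               ordinal_median(c(3L, 3L, 1L)))          # cohort median
  expect_true(is.na(imp["G4", "S1"]))                  # no cohort data
  expect_identical(imp[, "S2"], ev[, "S2"])            # other samples intact
  # idempotent
  expect_identical(unclass(impute_missing(imp, "S1")), unclass(imp))
  # no cohort at all
  single <- evidence_matrix(matrix(3L, 2, 1,
                                   dimnames = list(c("G1", "G2"), "S1")))
  expect_error(impute_missing(single, "S1"), "cohort")
})

test_that("gene_scores applies the level mapping, missing included", {
  ev <- ev_fixture()
  gs <- gene_scores(ev, "S2")
  expect_equal(unname(gs[c("G1", "G2")]), c(20, 20))
  expect_equal(unname(gs["G3"]), -2)   # missing cell
  gs1 <- gene_scores(ev, "S1")
  expect_equal(unname(gs1["G3"]), -8)  # negative stain
  # custom binary mapping
  bin <- gene_scores(ev, "S2", score_mapping(1, 1, 1, -1, -1))
  expect_setequal(unique(bin), c(1, -1))
  expect_error(gene_scores(ev, "S2", c(strong = 1)), "mapping must define")
  expect_error(gene_scores(ev, "NOPE"), "unknown sample")
})

test_that("reaction_scores aggregates OR as max and AND as min", {
  m <- gem_model(list(
    R1 = list(stoich = c(`A[c]` = -1, `B[c]` = 1), gpr = "G1"),
    R2 = list(stoich = c(`B[c]` = -1, `C[c]` = 1), gpr = "G1 or G2"),
    R3 = list(stoich = c(`C[c]` = -1, `D[c]` = 1),
              gpr = "(G1 and G2) or G3"),
    R4 = list(stoich = c(`D[c]` = -1, `E[c]` = 1))))
  gs <- c(G1 = 20, G2 = -8, G3 = 10)
  rs <- reaction_scores(m, gs)
  expect_equal(unname(rs["R1"]), 20)
  expect_equal(unname(rs["R2"]), max(-8, 20))
  expect_equal(unname(rs["R3"]), max(min(20, -8), 10))   # = 10, by hand
  expect_equal(unname(rs["R4"]), 0)                      # spontaneous
  expect_equal(unname(reaction_scores(m, gs,
                                      spontaneous_score = 5)["R4"]), 5)
  # uncovered rule gene falls back to the missing score
  rs2 <- reaction_scores(m, c(G1 = 20, G2 = -8), default_score = -2)
  expect_equal(unname(rs2["R3"]), max(min(20, -8), -2))
})

test_that("reaction_scores is monotone and sign-matches boolean GPR", {
  m <- gem_model(list(
    R1 = list(stoich = c(`A[c]` = -1, `B[c]` = 1),
              gpr = "(G1 and G2) or (G3 and G4)")))
  set.seed(33)
  for (i in 1:20) {
    gs <- setNames(runif(4, -10, 10), paste0("G", 1:4))
    base <- reaction_scores(m, gs)
    bump <- gs; g <- sample(4, 1); bump[g] <- bump[g] + runif(1, 0, 5)
    expect_gte(reaction_scores(m, bump)[["R1"]], base[["R1"]])
    # binary mapping: score sign equals boolean evaluation
    det <- setNames(sample(c(TRUE, FALSE), 4, replace = TRUE),
                    paste0("G", 1:4))
    sgn <- reaction_scores(m, ifelse(det, 1, -1))[["R1"]]
    bool <- (det[["G1"]] && det[["G2"]]) || (det[["G3"]] && det[["G4"]])
    expect_identical(sgn > 0, bool)
  }
})
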