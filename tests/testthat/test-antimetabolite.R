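# Metabolite blocking and the antimetabolite screen.

test_that("block_metabolite constrains exactly the consuming directions", {
  m <- gem_model(list(
    R1 = list(stoich = c(`A[c]` = -1, `X[c]` = -1, `Y[c]` = 1)),
    R2 = list(stoich = c(`A[c]` = -1, `X[c]` = 1), lb = -1000),
    R3 = list(stoich = c(`Y[c]` = -1, `Z[c]` = 1))))
  # absent name: bound-identical copy
  expect_identical(block_metabolite(m, "nothing")$rxns, m$rxns)
  b <- block_metabolite(m, "X")
  # irreversible forward consumer fixed at zero
  expect_equal(unname(unlist(b$rxns[b$rxns$id == "R1", c("lb", "ub")])),
               c(0, 0))
  # reversible reaction producing X forward: only the backward
  # (X-consuming) direction is closed
  expect_equal(unname(unlist(b$rxns[b$rxns$id == "R2", c("lb", "ub")])),
               c(0, 1000))
  # untouched reaction, stoichiometry and the input model unchanged
  expect_equal(unname(unlist(b$rxns[b$rxns$id == "R3", c("lb", "ub")])),
               c(0, 1000))
  expect_identical(b$S, m$S)
  expect_equal(m$rxns$ub[1], 1000)
})

test_that("blocking equals physically deleting the consuming directions", {
  p <- make_screen_panel()
  models <- c(p$tumors, p$healthy)
  for (m in models) {
    for (met in unique(m$mets$name)) {
      blocked <- block_metabolite(m, met)
      deleted <- tryCatch(oracle_delete_consuming(m, met),
                          error = function(e) NULL)
      if (is.null(deleted)) next
      for (t in p$tasks) {
        expect_identical(check_task(blocked, t)$feasible,
                         check_task(deleted, t)$feasible,
                         info = paste(m$id, met, t$id))
      }
    }
  }
})

test_that("task_survival composes blocking with task checking", {
  p <- make_screen_panel()
  t1 <- p$tumors$T1
  base <- as.data.frame(check_tasks(t1, p$tasks))
  # blocking a dead-end product leaves the pass pattern unchanged
  surv_bio <- as.data.frame(task_survival(t1, "BIO", p$tasks))
  expect_identical(surv_bio$passed, base$passed)
  # blocking the choke point kills growth
  surv_q <- as.data.frame(task_survival(t1, "Q", p$tasks))
  expect_false(surv_q$passed[surv_q$task_id == "GROWTH"])
  # a bypassed metabolite does not kill growth in the model with the bypass
  surv_x <- as.data.frame(task_survival(t1, "X", p$tasks))
  expect_true(surv_x$passed[surv_x$task_id == "GROWTH"])
})

test_that("screen_antimetabolites classifies the planted panel correctly", {
  p <- make_screen_panel()
  sc <- screen_antimetabolites(p$tumors, p$healthy, p$tasks, "GROWTH",
                               pool_exclusion = "pool")
  r <- sc$results
  expect_identical(sort(r$metabolite), p$expected$universe)
  expect_setequal(r$metabolite[r$verdict == "effective_all"],
                  p$expected$effective_all)
  expect_setequal(r$metabolite[r$verdict == "effective_subset"],
                  p$expected$effective_subset)
  expect_setequal(r$metabolite[r$verdict == "ineffective"],
                  p$expected$ineffective)
  expect_setequal(r$metabolite[r$toxicity_flag], p$expected$toxic)
  expect_setequal(r$metabolite[r$excluded_as_pool], p$expected$pool)
  expect_setequal(proposed_antimetabolites(sc), p$expected$proposals)
  # verdict counts partition the screened universe
  expect_equal(sum(r$verdict == "effective_all") +
                 sum(r$verdict == "effective_subset") +
                 sum(r$verdict == "ineffective"), nrow(r))
  # per-model disabling columns are present and consistent
  expect_equal(r$n_tumor_disabled,
               rowSums(as.matrix(r[, names(p$tumors)])))
  # the energy/redox failure behind the toxicity flag is recorded
  hf <- sc$healthy_failures
  expect_true(any(hf$metabolite == "P2" & hf$model == "H1" &
                    hf$category == "energy_and_redox"))
})

test_that("a generic-model screen can propose what the panel rejects", {
  p <- make_screen_panel()
  personal <- screen_antimetabolites(p$tumors, p$healthy, p$tasks, "GROWTH",
                                     pool_exclusion = "pool")
  generic <- screen_antimetabolites(list(generic = p$generic), p$healthy,
                                    p$tasks, "GROWTH",
                                    pool_exclusion = "pool")
  expect_setequal(screen_discrepancy(generic, personal),
                  p$expected$generic_false_positive)
})

test_that("degenerate and empty panels are handled explicitly", {
  p <- make_screen_panel()
  expect_error(screen_antimetabolites(list(), p$healthy, p$tasks, "GROWTH"),
               "empty tumour panel")
  expect_error(screen_antimetabolites(p$tumors, p$healthy, p$tasks, "NOPE"),
               "not in the task list")
  # a tumour model that cannot grow is skipped with a warning
  dead <- subset_model(p$tumors$T2, c("EX_S", "R1"))
  expect_warning(
    sc <- screen_antimetabolites(c(p$tumors, list(dead = dead)),
                                 list(), p$tasks, "GROWTH"),
    "skipped")
  expect_identical(sc$skipped_tumors, "dead")
  expect_length(sc$tumor_models, 3)
})

test_that("per-compartment screening distinguishes instances", {
  m <- gem_model(list(
    EX_S = list(stoich = c(`S[s]` = 1)),
    T1 = list(stoich = c(`S[s]` = -1, `S[c]` = 1)),
    R1 = list(stoich = c(`S[c]` = -1, `BIO[c]` = 1)),
    EX_B = list(stoich = c(`BIO[c]` = -1))), id = "T")
  growth <- metabolic_task("GROWTH", category = "growth",
                           inputs = data.frame(met = "S[s]"),
                           outputs = data.frame(met = "BIO"))
  sc <- screen_antimetabolites(list(T = m), list(), list(growth), "GROWTH",
                               by_compartment = TRUE)
  r <- sc$results
  expect_true(all(c("S[s]", "S[c]") %in% r$metabolite))
  expect_equal(r$verdict[r$metabolite == "S[c]"], "effective_all")
})

test_that("adding blocks never makes an infeasible task feasible", {
  p <- make_screen_panel()
  for (m in c(p$tumors["T1"], p$healthy["H1"])) {
    mets <- unique(m$mets$name)
    for (m1 in mets) {
      b1 <- block_metabolite(m, m1)
      f1 <- vapply(check_tasks(b1, p$tasks), `[[`, logical(1), "feasible")
      for (m2 in mets) {
        f2 <- vapply(check_tasks(block_metabolite(b1, m2), p$tasks),
                     `[[`, logical(1), "feasible")
        expect_true(all(f2 <= f1))
      }
    }
  }
})
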