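# The three reconstruction steps and the fitting wrapper.

test_that("find_essential_reactions: unique paths are essential, redundant ones not", {
  chain <- gem_model(list(
    EX_A = list(stoich = c(`A[c]` = 1)),
    R1 = list(stoich = c(`A[c]` = -1, `B[c]` = 1)),
    R2 = list(stoich = c(`B[c]` = -1, `C[c]` = 1)),
    EX_C = list(stoich = c(`C[c]` = -1))))
  t_chain <- metabolic_task("C_from_A", inputs = data.frame(met = "A"),
                            outputs = data.frame(met = "C"))
  expect_setequal(find_essential_reactions(chain, list(t_chain)),
                  c("R1", "R2"))

  par2 <- gem_model(list(
    EX_A = list(stoich = c(`A[c]` = 1)),
    R1 = list(stoich = c(`A[c]` = -1, `B[c]` = 1)),
    R2 = list(stoich = c(`A[c]` = -1, `B[c]` = 1)),
    EX_B = list(stoich = c(`B[c]` = -1))))
  t_par <- metabolic_task("B_from_A", inputs = data.frame(met = "A"),
                          outputs = data.frame(met = "B"))
  expect_length(find_essential_reactions(par2, list(t_par)), 0)

  # an infeasible reference is a hard error naming the task
  t_bad <- metabolic_task("D_from_A", inputs = data.frame(met = "A"),
                          outputs = data.frame(met = "D"))
  expect_error(find_essential_reactions(chain, list(t_bad)), "D_from_A")
})

test_that("the flux-support prefilter is equivalent to the plain sweep", {
  for (sd in 1:6) {
    fx <- random_reference(fixture_spec(seed = sd, n_reactions = 13,
                                        n_tasks = 2,
                                        reversible_fraction = 0.3))
    fast <- find_essential_reactions(fx$model, fx$tasks, use_prefilter = TRUE)
    slow <- find_essential_reactions(fx$model, fx$tasks, use_prefilter = FALSE)
    expect_identical(fast, slow)
  }
})

test_that("selection with all-positive scores keeps every usable reaction", {
  fx <- random_reference(fixture_spec(seed = 2, n_reactions = 12,
                                      planted_fraction = 8 / 12))
  m <- fx$model
  w <- setNames(rep(5, nrow(m$rxns)), m$rxns$id)
  sel <- solve_selection_milp(m, w, character())
  source_oracle <- oracle_selection(m, w, character(), tinit_options())
  expect_equal(sel$objective, source_oracle$objective)
  expect_setequal(sel$selected, source_oracle$selected)
  expect_equal(sel$objective, sum(w[sel$selected]))
})

test_that("selection matches the brute-force optimum on mixed-sign fixtures", {
  for (sd in 1:6) {
    fx <- random_reference(fixture_spec(seed = sd, n_reactions = 12,
                                        n_tasks = 2,
                                        reversible_fraction = 0.3))
    m <- fx$model
    set.seed(sd + 400)
    w <- setNames(round(runif(nrow(m$rxns), -10, 10), 1), m$rxns$id)
    w[m$rxns$is_exchange] <- 0
    req <- find_essential_reactions(m, fx$tasks)
    sel <- solve_selection_milp(m, w, req)
    ora <- oracle_selection(m, w, req, tinit_options())
    expect_equal(sel$objective, ora$objective, tolerance = 1e-6)
    expect_true(all(req %in% sel$selected))
  }
})

test_that("forbidding bidirectional flux excludes disconnected reversible loops", {
  # a lone reversible conversion pair, unconnected to everything else,
  # can activate itself by running forward and backward simultaneously —
  # exactly the artifact the bidirectional-flux constraint removes
  m <- gem_model(list(
    EX_A = list(stoich = c(`A[c]` = 1)),
    R1 = list(stoich = c(`A[c]` = -1, `B[c]` = 1)),
    EX_B = list(stoich = c(`B[c]` = -1)),
    LOOP = list(stoich = c(`L1[c]` = -1, `L2[c]` = 1), lb = -1000)))
  w <- c(EX_A = 0, R1 = 5, EX_B = 0, LOOP = 5)
  with_rule <- solve_selection_milp(m, w, character(),
                                    tinit_options(forbid_bidirectional_flux = TRUE))
  without_rule <- solve_selection_milp(m, w, character(),
                                       tinit_options(forbid_bidirectional_flux = FALSE))
  expect_false("LOOP" %in% with_rule$selected)
  expect_true("LOOP" %in% without_rule$selected)
})

test_that("net production can rescue otherwise dead-end reactions, at a penalty", {
  m <- gem_model(list(
    EX_A = list(stoich = c(`A[c]` = 1)),
    R1 = list(stoich = c(`A[c]` = -1, `D[c]` = 1))))  # D has no sink
  w <- c(EX_A = 0, R1 = 5)
  strict <- solve_selection_milp(m, w, character(),
                                 tinit_options(allow_net_production = FALSE))
  loose <- solve_selection_milp(m, w, character(),
                                tinit_options(allow_net_production = TRUE,
                                              net_production_penalty = 1))
  expect_false("R1" %in% strict$selected)
  expect_true("R1" %in% loose$selected)
  expect_lt(loose$objective, 5)   # accumulation was penalised
})

test_that("gapfill_task returns a minimum addition set", {
  toy <- toy_network()
  m <- toy$model
  # already feasible -> nothing to add
  expect_length(gapfill_task(m$rxns$id, m, toy$tasks[[1]]), 0)
  # draft missing one chain link -> exactly that link
  draft <- setdiff(m$rxns$id, "R2")
  expect_identical(gapfill_task(draft, m, toy$tasks[[1]]), "R2")
  # pruned network needs the lower-most red reaction for task 2
  expect_identical(gapfill_task(toy$expected$selected, m, toy$tasks[[2]]),
                   "R5")
  # an impossible task is an error
  t_bad <- metabolic_task("X_from_A", inputs = data.frame(met = "A"),
                          outputs = data.frame(met = "XX"))
  expect_error(gapfill_task(draft, m, t_bad), "absent")
})

test_that("gap-fill cardinality equals the brute-force minimum", {
  for (sd in 1:5) {
    fx <- random_reference(fixture_spec(seed = sd, n_reactions = 12,
                                        n_tasks = 2))
    m <- fx$model
    set.seed(sd)
    nonex <- m$rxns$id[!m$rxns$is_exchange]
    draft <- setdiff(m$rxns$id, sample(nonex, 2))
    for (t in fx$tasks) {
      if (t$should_fail) next
      expect_length(gapfill_task(draft, m, t), oracle_gapfill(draft, m, t))
    }
  }
})

test_that("tinit reproduces the didactic network outcome end to end", {
  toy <- toy_network()
  fit <- tinit(toy$model, toy$scores, toy$tasks)
  expect_s3_class(fit, "tinit_fit")
  expect_setequal(fit$required_reactions, toy$expected$required)
  expect_setequal(fit$selected_reactions, toy$expected$final)
  expect_identical(fit$gapfilled_reactions$E_from_B, "R5")
  expect_length(intersect(toy$expected$dotted_removed,
                          fit$selected_reactions), 0)
  expect_true(all(vapply(fit$task_report, `[[`, logical(1), "passed")))
  expect_equal(fit$objective_value, 40)
  # required-inclusion invariant
  expect_true(all(fit$required_reactions %in% fit$selected_reactions))
  # print/summary methods run
  expect_output(print(fit), "reactions selected")
  expect_output(print(summary(fit)), "gap-filled per task")
})

test_that("tinit recovers a planted context model from evidence", {
  fx <- random_reference(fixture_spec(seed = 42, n_reactions = 14,
                                      n_tasks = 2))
  ev <- simulate_evidence(fx$model, fx$planted, fx$spec)
  imp <- impute_missing(ev, "S1")
  rs <- reaction_scores(fx$model, gene_scores(imp, "S1"))
  fit <- tinit(fx$model, rs, fx$tasks)
  expect_setequal(fit$selected_reactions, fx$planted)
  # tasks can be excluded from the essential step without losing
  # functionality (gap-filling still enforces them)
  fit2 <- tinit(fx$model, rs, fx$tasks,
                exclude_from_essential = fx$tasks[[1]]$id)
  expect_true(all(vapply(fit2$task_report, `[[`, logical(1), "passed")))
})
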