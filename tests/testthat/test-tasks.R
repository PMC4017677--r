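# Task parsing and closed-system feasibility checking.

chain_model <- function() {
  gem_model(list(
    EX_A = list(stoich = c(`A[c]` = 1), ub = 10),
    R1 = list(stoich = c(`A[c]` = -1, `B[c]` = 1)),
    EX_B = list(stoich = c(`B[c]` = -1), ub = 10)))
}

write_task_tsv <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

test_that("parse_task_table reads the row-group dialect", {
  f <- write_task_tsv(c(
    "TASK_ID\tDESCRIPTION\tCATEGORY\tSHOULD_FAIL\tIN\tIN_LB\tIN_UB\tOUT\tOUT_LB\tOUT_UB\tEQU",
    "T1\tglucose to ATP\tenergy_and_redox\tFALSE\tglucose[s]\t0\t1\t\t\t\tatp[c] + h2o[c] => adp[c] + pi[c]",
    "\t\t\t\to2[s]\t\t\tco2[s]\t0\t1000\t",
    "SF1\tfree lunch control\tenergy_and_redox\tTRUE\t\t\t\t\t\t\tatp[c] => adp[c]"))
  tasks <- parse_task_table(f)
  expect_length(tasks, 2)
  t1 <- tasks[[1]]
  expect_equal(t1$id, "T1")
  expect_equal(nrow(t1$inputs), 2)        # continuation row folded in
  expect_equal(t1$inputs$ub, c(1, 1000))  # defaults applied
  expect_equal(nrow(t1$outputs), 1)
  expect_length(t1$equations, 1)
  expect_equal(t1$equations[[1]]$lhs, c(`atp[c]` = 1, `h2o[c]` = 1))
  # a should_fail task without outputs is legal
  expect_true(tasks[[2]]$should_fail)
  expect_equal(nrow(tasks[[2]]$outputs), 0)
})

test_that("unknown columns and orphan continuation rows are schema errors", {
  f <- write_task_tsv(c("TASK_ID\tWHAT\tIN", "T1\tx\tglc"))
  expect_error(parse_task_table(f), "unknown task-table column")
  f2 <- write_task_tsv(c("TASK_ID\tIN\tOUT", "\tglc\tpyr"))
  expect_error(parse_task_table(f2), "continuation")
})

test_that("the shipped task library parses to 56 tasks in four categories", {
  lib <- parse_task_table(system.file("extdata", "tasks_core56.tsv",
                                      package = "tinitr"))
  expect_length(lib, 56)
  cats <- vapply(lib, `[[`, character(1), "category")
  expect_setequal(unique(cats),
                  c("energy_and_redox", "internal_conversions",
                    "substrate_utilization", "biosynthesis_of_products"))
  expect_gte(sum(vapply(lib, `[[`, logical(1), "should_fail")), 2)
  growth <- parse_task_table(system.file("extdata", "task_growth.tsv",
                                         package = "tinitr"))
  expect_length(growth, 1)
  expect_equal(growth[[1]]$category, "growth")
  expect_length(c(lib, growth), 57)
})

test_that("check_task decides feasibility on a closed system", {
  m <- chain_model()
  t_ok <- metabolic_task("B_from_A", inputs = data.frame(met = "A"),
                         outputs = data.frame(met = "B"))
  r <- check_task(m, t_ok)
  expect_true(r$feasible)
  expect_true(r$passed)
  expect_gte(r$witness_flux[["R1"]], 1e-4)

  # required output whose metabolite does not exist -> unmapped, not error
  t_bad <- metabolic_task("C_from_A", inputs = data.frame(met = "A"),
                          outputs = data.frame(met = "C"))
  r2 <- check_task(m, t_bad)
  expect_false(r2$feasible)
  expect_match(r2$reason, "unmapped")

  # a merely permitted uptake of an absent metabolite is a no-op
  t_perm <- metabolic_task("B_from_A_or_C",
                           inputs = data.frame(met = c("A", "C")),
                           outputs = data.frame(met = "B"))
  expect_true(check_task(m, t_perm)$feasible)

  # model exchanges are closed: without task inputs nothing can run
  t_closed <- metabolic_task("B_from_nothing",
                             outputs = data.frame(met = "B"))
  expect_false(check_task(m, t_closed)$feasible)
})

test_that("should_fail tasks pass exactly when infeasible", {
  m <- chain_model()
  t_sf <- metabolic_task("no_free_B", should_fail = TRUE,
                         outputs = data.frame(met = "B"))
  r <- check_task(m, t_sf)
  expect_false(r$feasible)
  expect_true(r$passed)
  t_sf2 <- metabolic_task("B_from_A_sf", should_fail = TRUE,
                          inputs = data.frame(met = "A"),
                          outputs = data.frame(met = "B"))
  expect_false(check_task(m, t_sf2)$passed)
})

test_that("compartment-pooled task metabolites aggregate over instances", {
  m <- gem_model(list(
    T1 = list(stoich = c(`glc[s]` = -1, `glc[c]` = 1)),
    R1 = list(stoich = c(`glc[c]` = -1, `pyr[c]` = 1))))
  # bare name: uptake may enter either compartment instance
  t <- metabolic_task("pyr_from_glc", inputs = data.frame(met = "glc"),
                      outputs = data.frame(met = "pyr"))
  expect_true(check_task(m, t)$feasible)
  # restricting to the extracellular instance forces the transporter
  t2 <- metabolic_task("pyr_from_glc_s",
                       inputs = data.frame(met = "glc[s]"),
                       outputs = data.frame(met = "pyr"))
  expect_true(check_task(m, t2)$feasible)
})

test_that("check_tasks preserves order, isolates tasks, and is deterministic", {
  fx <- random_reference(fixture_spec(seed = 11, n_reactions = 12,
                                      n_tasks = 3))
  expect_length(check_tasks(fx$model, list()), 0)
  rep1 <- check_tasks(fx$model, fx$tasks)
  expect_identical(vapply(rep1, `[[`, character(1), "task_id"),
                   vapply(fx$tasks, `[[`, character(1), "id"))
  # permuting the task list permutes, but never changes, the outcomes
  perm <- rev(seq_along(fx$tasks))
  rep2 <- check_tasks(fx$model, fx$tasks[perm])
  df1 <- as.data.frame(rep1)
  df2 <- as.data.frame(rep2)
  expect_identical(df1[order(df1$task_id), c("task_id", "passed")],
                   df2[order(df2$task_id), c("task_id", "passed")],
                   ignore_attr = TRUE)
  # re-running is bit-identical
  expect_identical(as.data.frame(check_tasks(fx$model, fx$tasks)), df1)
})

test_that("feasibility is monotone in the reaction set", {
  for (sd in 1:5) {
    fx <- random_reference(fixture_spec(seed = sd, n_reactions = 12,
                                        n_tasks = 2))
    m <- fx$model
    sub <- subset_model(m, fx$planted)
    for (t in fx$tasks) {
      if (t$should_fail) next
      if (check_task(sub, t)$feasible)
        expect_true(check_task(m, t)$feasible)
    }
  }
})

test_that("closure: removing all inputs makes production tasks infeasible", {
  for (sd in 1:5) {
    fx <- random_reference(fixture_spec(seed = sd, n_reactions = 12,
                                        n_tasks = 2))
    for (t in fx$tasks) {
      if (t$should_fail) next
      t0 <- t
      t0$inputs <- t$inputs[0, ]
      expect_false(check_task(fx$model, t0)$feasible)
    }
  }
})

test_that("write_task_table round-trips through parse_task_table", {
  tasks <- c(parse_task_table(system.file("extdata", "tasks_core56.tsv",
                                          package = "tinitr"))[1:5],
             toy_network()$tasks)
  f <- tempfile(fileext = ".tsv")
  write_task_table(tasks, f)
  back <- parse_task_table(f)
  expect_length(back, length(tasks))
  for (i in seq_along(tasks)) {
    expect_identical(back[[i]]$id, tasks[[i]]$id)
    expect_identical(back[[i]]$category, tasks[[i]]$category)
    expect_equal(back[[i]]$inputs, tasks[[i]]$inputs)
    expect_equal(back[[i]]$outputs, tasks[[i]]$outputs)
    expect_equal(back[[i]]$equations, tasks[[i]]$equations)
  }
})
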