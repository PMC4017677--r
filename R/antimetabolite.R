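#' Block all consumption of a metabolite
#'
#' Emulates an antimetabolite: the analog inhibits every enzyme that uses
#' the metabolite as a substrate, so every consuming reaction direction
#' (pooled over compartments, see [consuming_reactions()]) is constrained
#' to zero flux.  Forward consumers lose their forward direction (upper
#' bound 0; a fully irreversible consumer is fixed at `[0, 0]`), and
#' reversible reactions that consume the metabolite when running
#' backwards lose the backward direction (lower bound 0).  Stoichiometry
#' is untouched and the input model is not modified.
#'
#' @param model a `gem_model`.
#' @param metabolite_name compartment-agnostic metabolite name.
#' @return a new `gem_model` with adjusted bounds (bound-identical to the
#'   input when nothing matches).
#' @export
block_metabolite <- function(model, metabolite_name) {
  hits <- consuming_reactions(model, metabolite_name)
  if (length(hits) == 0L) return(model)
  idx <- match(names(hits), model$rxns$id)
  for (k in seq_along(hits)) {
    i <- idx[k]
    if (hits[k] %in% c("forward", "both"))
      model$rxns$ub[i] <- min(model$rxns$ub[i], 0)
    if (hits[k] %in% c("reverse", "both"))
      model$rxns$lb[i] <- max(model$rxns$lb[i], 0)
    if (model$rxns$lb[i] > model$rxns$ub[i]) {   # forced-flux consumer
      model$rxns$lb[i] <- 0
      model$rxns$ub[i] <- 0
    }
  }
  model
}

#' Task survival under metabolite blocking
#'
#' Convenience composition: which tasks can the model still perform once
#' all consumption of `metabolite_name` is blocked?
#'
#' @inheritParams block_metabolite
#' @param tasks list of [metabolic_task()] objects.
#' @param options a [solver_options()].
#' @return a `task_report` (see [check_tasks()]).
#' @export
task_survival <- function(model, metabolite_name, tasks,
                          options = solver_options()) {
  check_tasks(block_metabolite(model, metabolite_name), tasks, options)
}

#' Antimetabolite screen over tumour and healthy model panels
#'
#' For every compartment-agnostic metabolite name occurring in the tumour
#' panel, blocks its consumption in each model and records (i) the tumour
#' models whose growth task becomes infeasible — the efficacy readout —
#' and (ii) every healthy-model task that the blocking newly breaks — the
#' toxicity readout.  Candidates whose blocking breaks an
#' energy-and-redox task in *any* healthy model are flagged toxic (such
#' tasks are central to all cells, proliferating or not); metabolites
#' matching `pool_exclusion` patterns (e.g. fatty-acid pool species) are
#' flagged and removed from the proposal list.
#'
#' @param tumor_models list of `gem_model` objects (the patient panel).
#' @param healthy_models list of `gem_model` objects (may be empty).
#' @param tasks list of [metabolic_task()] objects; must contain the
#'   growth task.
#' @param growth_task_id id of the growth/biomass task used for the
#'   efficacy readout.
#' @param pool_exclusion character vector of regular expressions matched
#'   against metabolite names; matches are excluded as pool metabolites.
#' @param by_compartment screen each `name[compartment]` instance
#'   separately instead of pooling compartments (off by default, the
#'   compartment-agnostic behaviour).
#' @param options a [solver_options()].
#' @return an object of class `antimet_screen` with components `results`
#'   (one row per metabolite: `metabolite`, `n_tumor_disabled`, per-model
#'   disabling flags, `verdict` in effective_all / effective_subset /
#'   ineffective, `toxicity_flag`, `excluded_as_pool`),
#'   `healthy_failures` (long data frame of newly failing healthy tasks),
#'   and bookkeeping fields.
#' @export
screen_antimetabolites <- function(tumor_models, healthy_models = list(),
                                   tasks, growth_task_id,
                                   pool_exclusion = character(),
                                   by_compartment = FALSE,
                                   options = solver_options()) {
  if (length(tumor_models) == 0L)
    stop("empty tumour panel: nothing to screen")
  task_ids <- vapply(tasks, `[[`, character(1), "id")
  if (!growth_task_id %in% task_ids)
    stop("growth task '", growth_task_id, "' not in the task list")
  growth_task <- tasks[[match(growth_task_id, task_ids)]]
  if (is.null(names(tumor_models)))
    names(tumor_models) <- vapply(tumor_models, `[[`, character(1), "id")
  if (length(healthy_models) && is.null(names(healthy_models)))
    names(healthy_models) <- vapply(healthy_models, `[[`, character(1), "id")

  # degenerate tumour models (growth infeasible unblocked) are skipped
  grows <- vapply(tumor_models, function(m)
    check_task(m, growth_task, options)$feasible, logical(1))
  if (any(!grows))
    warning("tumour model(s) cannot grow unblocked and are skipped: ",
            paste(names(tumor_models)[!grows], collapse = ", "))
  active_tumors <- tumor_models[grows]
  if (length(active_tumors) == 0L)
    stop("no tumour model passes the growth task; screen is undefined")

  met_key <- function(m) {
    if (by_compartment)
      paste0(m$mets$name, "[", m$mets$compartment, "]")
    else m$mets$name
  }
  universe <- sort(unique(unlist(lapply(active_tumors, met_key))))

  # healthy baselines: only tasks passing unblocked can be newly broken
  healthy_base <- lapply(healthy_models, function(m)
    vapply(check_tasks(m, tasks, options), `[[`, logical(1), "passed"))

  n_t <- length(active_tumors)
  res <- data.frame(metabolite = universe, stringsAsFactors = FALSE)
  disabled <- matrix(FALSE, length(universe), n_t,
                     dimnames = list(universe, names(active_tumors)))
  hf <- list()
  toxic <- setNames(logical(length(universe)), universe)

  for (mi in seq_along(universe)) {
    met <- universe[mi]
    for (tm in names(active_tumors)) {
      m <- active_tumors[[tm]]
      if (length(consuming_reactions(m, met)) == 0L) next
      disabled[mi, tm] <-
        !check_task(block_metabolite(m, met), growth_task, options)$feasible
    }
    for (hm in names(healthy_models)) {
      m <- healthy_models[[hm]]
      if (length(consuming_reactions(m, met)) == 0L) next
      blocked <- check_tasks(block_metabolite(m, met), tasks, options)
      passed <- vapply(blocked, `[[`, logical(1), "passed")
      newly_broken <- healthy_base[[hm]] & !passed
      if (any(newly_broken)) {
        cats <- vapply(tasks, `[[`, character(1), "category")
        hf[[length(hf) + 1L]] <-
          data.frame(metabolite = met, model = hm,
                     task_id = task_ids[newly_broken],
                     category = cats[newly_broken],
                     stringsAsFactors = FALSE)
        if (any(cats[newly_broken] == "energy_and_redox"))
          toxic[mi] <- TRUE
      }
    }
  }

  healthy_failures <- if (length(hf)) do.call(rbind, hf) else
    data.frame(metabolite = character(), model = character(),
               task_id = character(), category = character(),
               stringsAsFactors = FALSE)

  n_disabled <- rowSums(disabled)
  verdict <- ifelse(n_disabled == n_t, "effective_all",
                    ifelse(n_disabled > 0, "effective_subset", "ineffective"))
  excluded <- rep(FALSE, length(universe))
  for (p in pool_exclusion)
    excluded <- excluded | grepl(p, universe)

  res$n_tumor_disabled <- as.integer(n_disabled)
  res <- cbind(res, as.data.frame(disabled, optional = TRUE))
  res$verdict <- verdict
  res$toxicity_flag <- as.logical(toxic)
  res$excluded_as_pool <- excluded
  row.names(res) <- NULL

  structure(list(results = res,
                 healthy_failures = healthy_failures,
                 tumor_models = names(active_tumors),
                 healthy_models = names(healthy_models),
                 skipped_tumors = names(tumor_models)[!grows],
                 growth_task_id = growth_task_id,
                 by_compartment = by_compartment),
            class = "antimet_screen")
}

#' Proposed antimetabolites from a screen
#'
#' Candidates effective in the whole tumour panel, not flagged toxic to
#' healthy energy/redox metabolism, and not excluded as pool metabolites.
#'
#' @param screen an `antimet_screen`.
#' @param verdict minimal efficacy verdict to accept
#'   (`"effective_all"` by default, or `"effective_subset"` to include
#'   patient-specific candidates).
#' @return character vector of metabolite names.
#' @export
proposed_antimetabolites <- function(screen,
                                     verdict = c("effective_all",
                                                 "effective_subset")) {
  stopifnot(inherits(screen, "antimet_screen"))
  verdict <- match.arg(verdict)
  ok <- switch(verdict,
               effective_all = screen$results$verdict == "effective_all",
               effective_subset = screen$results$n_tumor_disabled > 0)
  ok <- ok & !screen$results$toxicity_flag & !screen$results$excluded_as_pool
  screen$results$metabolite[ok]
}

#' Metabolites a generic-model screen proposes that a personalised panel
#' rejects
#'
#' Compares a screen run on a single generic (population-average) model
#' with a screen run on the personalised panel: returns the candidates
#' the generic screen calls effective that are *not* effective in every
#' personalised model — the false positives a generic model would
#' produce.
#'
#' @param generic_screen an `antimet_screen` over the generic model
#'   (a panel of one).
#' @param personal_screen an `antimet_screen` over the personalised
#'   panel.
#' @return character vector of metabolite names.
#' @export
screen_discrepancy <- function(generic_screen, personal_screen) {
  stopifnot(inherits(generic_screen, "antimet_screen"),
            inherits(personal_screen, "antimet_screen"))
  g <- generic_screen$results
  p <- personal_screen$results
  g_eff <- g$metabolite[g$verdict == "effective_all"]
  p_all <- p$metabolite[p$verdict == "effective_all"]
  setdiff(g_eff, p_all)
}

#' @export
print.antimet_screen <- function(x, ...) {
  r <- x$results
  cat("antimet_screen: ", nrow(r), " metabolites x ",
      length(x$tumor_models), " tumour / ", length(x$healthy_models),
      " healthy models\n", sep = "")
  cat("  effective in all tumours: ", sum(r$verdict == "effective_all"),
      "  (", sum(r$verdict == "effective_all" & !r$toxicity_flag &
                   !r$excluded_as_pool), " after toxicity/pool filters)\n",
      sep = "")
  cat("  effective in a subset:    ", sum(r$verdict == "effective_subset"),
      "\n  ineffective:              ", sum(r$verdict == "ineffective"),
      "\n  toxicity-flagged: ", sum(r$toxicity_flag),
      "; pool-excluded: ", sum(r$excluded_as_pool), "\n", sep = "")
  invisible(x)
}

#' @export
summary.antimet_screen <- function(object, ...) {
  r <- object$results
  s <- list(n_screened = nrow(r),
            n_effective_all = sum(r$verdict == "effective_all"),
            n_effective_subset = sum(r$verdict == "effective_subset"),
            n_ineffective = sum(r$verdict == "ineffective"),
            n_toxic = sum(r$toxicity_flag),
            n_pool = sum(r$excluded_as_pool),
            proposals = proposed_antimetabolites(object),
            skipped_tumors = object$skipped_tumors)
  class(s) <- "summary.antimet_screen"
  s
}

#' @export
print.summary.antimet_screen <- function(x, ...) {
  cat("Antimetabolite screen: ", x$n_screened, " metabolites\n", sep = "")
  cat("  effective_all ", x$n_effective_all,
      " | effective_subset ", x$n_effective_subset,
      " | ineffective ", x$n_ineffective, "\n", sep = "")
  cat("  toxicity-flagged ", x$n_toxic, " | pool-excluded ", x$n_pool,
      "\n", sep = "")
  cat("  proposed: ", if (length(x$proposals))
    paste(x$proposals, collapse = ", ") else "(none)", "\n", sep = "")
  if (length(x$skipped_tumors))
    cat("  skipped degenerate tumour model(s): ",
        paste(x$skipped_tumors, collapse = ", "), "\n", sep = "")
  invisible(x)
}
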