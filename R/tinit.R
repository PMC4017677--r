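#' Task-essential reactions of a reference network
#'
#' Step one of task-driven reconstruction: find every reaction whose
#' removal from the reference network makes at least one task infeasible.
#' These reactions must appear in any functional context-specific model
#' (note that this is *not* the smallest set able to perform the tasks —
#' isozymes and alternative pathways make redundant reactions
#' non-essential).  `should_fail` control tasks are ignored: removing
#' reactions can never make an infeasible conversion feasible.
#'
#' @param reference a `gem_model`; must itself pass every
#'   non-`should_fail` task.
#' @param tasks list of [metabolic_task()] objects.
#' @param options a [solver_options()].
#' @param use_prefilter narrow the candidate set to reactions that can
#'   carry flux in some task solution before sweeping (provably
#'   equivalent to the plain sweep: a reaction that cannot carry flux
#'   under a task's constraints cannot change that task's feasibility).
#' @return character vector of essential reaction ids, in model order.
#' @export
find_essential_reactions <- function(reference, tasks,
                                     options = solver_options(),
                                     use_prefilter = TRUE) {
  stopifnot(inherits(reference, "gem_model"))
  tasks <- Filter(function(t) !t$should_fail, tasks)
  if (length(tasks) == 0L) return(character())
  eps <- options$activation_epsilon
  n <- nrow(reference$rxns)

  lps <- lapply(tasks, function(t) build_task_lp(reference, t, eps))
  feas <- function(lp, drop_col = NULL) {
    lo <- lp$lb; hi <- lp$ub
    if (!is.null(drop_col)) lo[drop_col] <- hi[drop_col] <- 0
    # reversible equations: enumerate orientations
    rev_idx <- which(lp$eq_rev)
    if (length(rev_idx) == 0L)
      return(lp_feasible(lp$A, lp$dir, lp$rhs, lo, hi))
    combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(rev_idx)))
    for (ci in seq_len(nrow(combos))) {
      l2 <- lo; h2 <- hi
      flip <- unlist(combos[ci, ], use.names = FALSE)
      for (j in seq_along(rev_idx)) {
        col <- lp$eq_cols[rev_idx[j]]
        if (flip[j]) { l2[col] <- -1000; h2[col] <- -eps }
      }
      ans <- lp_feasible(lp$A, lp$dir, lp$rhs, l2, h2)
      if (ans$feasible) return(ans)
    }
    ans
  }

  failing <- character()
  base <- vector("list", length(tasks))
  for (k in seq_along(tasks)) {
    if (!is.null(lps[[k]]$unmapped)) {
      failing <- c(failing, tasks[[k]]$id)
      next
    }
    base[[k]] <- feas(lps[[k]])
    if (!base[[k]]$feasible) failing <- c(failing, tasks[[k]]$id)
  }
  if (length(failing))
    stop("reference model fails task(s): ", paste(failing, collapse = ", "),
         " — gap-filling cannot help, the reference is the universe")

  # candidate reactions per task
  tol <- 1e-7
  candidates <- vector("list", length(tasks))
  for (k in seq_along(tasks)) {
    lp <- lps[[k]]
    if (!use_prefilter) {
      candidates[[k]] <- which(!(lp$lb[seq_len(n)] == 0 &
                                 lp$ub[seq_len(n)] == 0))
      next
    }
    active <- abs(base[[k]]$x[seq_len(n)]) > tol
    # accumulate: maximise |flux| of each still-unseen reaction, folding in
    # every reaction active in the optimiser's witness
    for (j in seq_len(n)) {
      if (active[j]) next
      if (lp$lb[j] == 0 && lp$ub[j] == 0) next    # closed exchange
      cc <- numeric(ncol(lp$A)); cc[j] <- 1
      for (sgn in c(TRUE, FALSE)) {
        if (sgn && lp$ub[j] <= 0) next
        if (!sgn && lp$lb[j] >= 0) next
        sol <- lp_solve(cc, lp$A, lp$dir, lp$rhs, lp$lb, lp$ub,
                        maximize = sgn)
        if (sol$status == "optimal" && abs(sol$objval) > tol) {
          active <- active | (abs(sol$x[seq_len(n)]) > tol)
          break
        }
      }
    }
    candidates[[k]] <- which(active)
  }

  essential <- logical(n)
  for (k in seq_along(tasks)) {
    for (j in candidates[[k]]) {
      if (essential[j]) next
      if (!feas(lps[[k]], drop_col = j)$feasible) essential[j] <- TRUE
    }
  }
  reference$rxns$id[essential]
}

# ---- selection MILP -------------------------------------------------------

# Build and solve the INIT network-selection MILP.  Internal layout:
# columns [vF (n), vB (n), y-block, accumulation-block], with y-block
# holding one binary per irreversible reaction and either one (joint) or
# two (directional) binaries per reversible reaction.
#' Score-maximising network selection
#'
#' Step two of task-driven reconstruction: selects the reaction subset
#' maximising the summed evidence score over included reactions, subject
#' to every included reaction carrying flux (at least
#' `activation_epsilon`, at most `big_M`) in one common steady-state flux
#' distribution, with the `required` reactions forced into the solution.
#' With `forbid_bidirectional_flux` (the default) a reversible reaction
#' may be used in only one direction in the witness, which keeps
#' disconnected two-reaction loops out of the solution; with
#' `allow_net_production` internal metabolites may accumulate, at a
#' penalty per unit.
#'
#' @param reference a `gem_model`.
#' @param scores named numeric vector of per-reaction evidence scores
#'   covering every reaction of `reference`.
#' @param required character vector of reaction ids that must be selected.
#' @param options a [tinit_options()].
#' @return list with `selected` (character vector of reaction ids, model
#'   order), `objective` (the attained score sum, net of any accumulation
#'   penalty) and `flux` (the witness flux vector).
#' @export
solve_selection_milp <- function(reference, scores, required = character(),
                                 options = tinit_options()) {
  stopifnot(inherits(reference, "gem_model"))
  n <- nrow(reference$rxns)
  rid <- reference$rxns$id
  missing_scores <- setdiff(rid, names(scores))
  if (length(missing_scores))
    stop("scores missing for reaction(s): ",
         paste(missing_scores, collapse = ", "))
  w <- as.numeric(scores[rid])
  bad_req <- setdiff(required, rid)
  if (length(bad_req))
    stop("required reaction(s) not in model: ",
         paste(bad_req, collapse = ", "))
  req <- rid %in% required

  so <- options$solver
  eps <- so$activation_epsilon
  M <- so$big_M
  nm <- nrow(reference$mets)

  ubF <- pmin(pmax(reference$rxns$ub, 0), M)
  ubB <- pmin(pmax(-reference$rxns$lb, 0), M)
  lbF <- pmax(reference$rxns$lb, 0)
  lbB <- pmax(-reference$rxns$ub, 0)
  is_rev <- ubF > 0 & ubB > 0
  split_bin <- is_rev & options$forbid_bidirectional_flux

  # y-block layout
  ny <- n + sum(split_bin)            # one extra binary per split reaction
  yF_idx <- integer(n)                # binary governing the forward part
  yB_idx <- integer(n)                # binary governing the backward part
  pos <- 0L
  for (i in seq_len(n)) {
    pos <- pos + 1L
    yF_idx[i] <- pos
    if (split_bin[i]) {
      pos <- pos + 1L
      yB_idx[i] <- pos
    } else {
      yB_idx[i] <- yF_idx[i]
    }
  }
  stopifnot(pos == ny)

  nacc <- if (options$allow_net_production) nm else 0L
  nv <- 2L * n
  ntot <- nv + ny + nacc
  col_vF <- seq_len(n)
  col_vB <- n + seq_len(n)
  col_y <- nv + seq_len(ny)
  col_acc <- if (nacc) nv + ny + seq_len(nacc) else integer(0)

  rows <- list()
  add_row <- function(cols, vals, dir, rhs)
    rows[[length(rows) + 1L]] <<- list(cols = cols, vals = vals,
                                       dir = dir, rhs = rhs)

  # steady state: S (vF - vB) - acc = 0
  for (mrow in seq_len(nm)) {
    nz <- which(reference$S[mrow, ] != 0)
    co <- reference$S[mrow, nz]
    cols <- c(col_vF[nz], col_vB[nz])
    vals <- c(co, -co)
    if (nacc) { cols <- c(cols, col_acc[mrow]); vals <- c(vals, -1) }
    add_row(cols, vals, "=", 0)
  }

  eps_coupled <- w > 0 | req     # use is enforced for these when selected
  for (i in seq_len(n)) {
    if (split_bin[i]) {
      add_row(c(col_vF[i], col_y[yF_idx[i]]), c(1, -ubF[i]), "<=", 0)
      add_row(c(col_vB[i], col_y[yB_idx[i]]), c(1, -ubB[i]), "<=", 0)
      if (eps_coupled[i]) {
        add_row(c(col_vF[i], col_y[yF_idx[i]]), c(1, -eps), ">=", 0)
        add_row(c(col_vB[i], col_y[yB_idx[i]]), c(1, -eps), ">=", 0)
      }
      add_row(col_y[c(yF_idx[i], yB_idx[i])], c(1, 1), "<=", 1)
      if (req[i])
        add_row(col_y[c(yF_idx[i], yB_idx[i])], c(1, 1), "=", 1)
    } else if (is_rev[i]) {
      add_row(c(col_vF[i], col_vB[i], col_y[yF_idx[i]]),
              c(1, 1, -M), "<=", 0)
      if (eps_coupled[i])
        add_row(c(col_vF[i], col_vB[i], col_y[yF_idx[i]]),
                c(1, 1, -eps), ">=", 0)
      if (req[i]) add_row(col_y[yF_idx[i]], 1, "=", 1)
    } else {
      vcol <- if (ubF[i] > 0 || ubB[i] == 0) col_vF[i] else col_vB[i]
      cap <- if (vcol == col_vF[i]) ubF[i] else ubB[i]
      add_row(c(vcol, col_y[yF_idx[i]]), c(1, -max(cap, eps)), "<=", 0)
      if (eps_coupled[i])
        add_row(c(vcol, col_y[yF_idx[i]]), c(1, -eps), ">=", 0)
      if (req[i]) add_row(col_y[yF_idx[i]], 1, "=", 1)
    }
  }

  A <- matrix(0, length(rows), ntot)
  dirv <- character(length(rows))
  rhsv <- numeric(length(rows))
  for (r in seq_along(rows)) {
    A[r, rows[[r]]$cols] <- rows[[r]]$vals
    dirv[r] <- rows[[r]]$dir
    rhsv[r] <- rows[[r]]$rhs
  }

  lo <- c(lbF, lbB, rep(0, ny), rep(0, nacc))
  hi <- c(ubF, ubB, rep(1, ny), rep(M, nacc))

  obj <- numeric(ntot)
  for (i in seq_len(n)) {
    obj[col_y[yF_idx[i]]] <- obj[col_y[yF_idx[i]]] + w[i]
    if (split_bin[i]) obj[col_y[yB_idx[i]]] <- obj[col_y[yB_idx[i]]] + w[i]
  }
  if (nacc) obj[col_acc] <- -options$net_production_penalty

  int_tol <- min(1e-6, eps / M / 10)
  sol <- milp_solve(obj, A, dirv, rhsv, lo, hi, binary = col_y,
                    maximize = TRUE, mip_gap = so$mip_gap,
                    time_limit = so$time_limit_seconds, int_tol = int_tol)
  if (sol$status == "infeasible")
    stop("selection MILP infeasible; check that the required reactions ",
         "can carry flux in the reference model")
  objective <- sol$objval
  x <- sol$x

  if (options$deterministic_ties && sol$status == "optimal") {
    # secondary lexicographic objective: among score-optimal selections,
    # prefer the one using lower reaction indices
    tol <- 1e-6 * max(1, abs(objective))
    A2 <- rbind(A, obj)
    dir2 <- c(dirv, ">=")
    rhs2 <- c(rhsv, objective - tol)
    obj2 <- numeric(ntot)
    for (i in seq_len(n)) {
      obj2[col_y[yF_idx[i]]] <- obj2[col_y[yF_idx[i]]] + i
      if (split_bin[i]) obj2[col_y[yB_idx[i]]] <- obj2[col_y[yB_idx[i]]] + i
    }
    sol2 <- milp_solve(obj2, A2, dir2, rhs2, lo, hi, binary = col_y,
                       maximize = FALSE, mip_gap = so$mip_gap,
                       time_limit = so$time_limit_seconds, int_tol = int_tol)
    if (sol2$status == "optimal") x <- sol2$x
  }

  ysel <- logical(n)
  for (i in seq_len(n)) {
    ysel[i] <- x[col_y[yF_idx[i]]] > 0.5 ||
      (split_bin[i] && x[col_y[yB_idx[i]]] > 0.5)
  }
  flux <- setNames(x[col_vF] - x[col_vB], rid)
  list(selected = rid[ysel], objective = objective, flux = flux)
}

# ---- gap filling ----------------------------------------------------------

#' Minimal gap-filling for one task
#'
#' Finds a minimum-cardinality set of reference reactions outside the
#' draft whose addition makes the task feasible (empty when the draft
#' already performs it).  Solved as a MILP: binaries gate the candidate
#' reactions, and the number switched on is minimised subject to the task
#' LP being satisfiable.
#'
#' @param draft character vector of reaction ids currently in the model.
#' @param reference a `gem_model`; the task must be feasible here.
#' @param task a [metabolic_task()].
#' @param options a [tinit_options()].
#' @return character vector of added reaction ids (possibly empty).
#' @export
gapfill_task <- function(draft, reference, task, options = tinit_options()) {
  stopifnot(inherits(reference, "gem_model"),
            inherits(task, "metabolic_task"))
  so <- options$solver
  rid <- reference$rxns$id
  stopifnot(all(draft %in% rid))
  lp <- build_task_lp(reference, task, so$activation_epsilon)
  if (!is.null(lp$unmapped))
    stop("task '", task$id, "' references metabolite '", lp$unmapped,
         "' absent from the reference model")
  n <- lp$n_model
  in_draft <- rid %in% draft

  feas_with <- function(closed) {
    lo <- lp$lb; hi <- lp$ub
    lo[closed] <- hi[closed] <- 0
    rev_idx <- which(lp$eq_rev)
    if (length(rev_idx) == 0L)
      return(lp_feasible(lp$A, lp$dir, lp$rhs, lo, hi)$feasible)
    combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(rev_idx)))
    for (ci in seq_len(nrow(combos))) {
      l2 <- lo; h2 <- hi
      flip <- unlist(combos[ci, ], use.names = FALSE)
      for (j in seq_along(rev_idx)) {
        col <- lp$eq_cols[rev_idx[j]]
        if (flip[j]) { l2[col] <- -1000; h2[col] <- -so$activation_epsilon }
      }
      if (lp_feasible(lp$A, lp$dir, lp$rhs, l2, h2)$feasible) return(TRUE)
    }
    FALSE
  }

  if (feas_with(which(!in_draft))) return(character(0))
  if (!feas_with(integer(0)))
    stop("task '", task$id, "' is infeasible even in the full reference")

  cand <- which(!in_draft & !(lp$lb[seq_len(n)] == 0 & lp$ub[seq_len(n)] == 0))
  k <- length(cand)
  ntot <- ncol(lp$A) + k
  ybin <- ncol(lp$A) + seq_len(k)

  rows_extra <- list()
  for (j in seq_len(k)) {
    i <- cand[j]
    if (lp$ub[i] > 0)
      rows_extra[[length(rows_extra) + 1L]] <-
        list(cols = c(i, ybin[j]), vals = c(1, -lp$ub[i]), dir = "<=", rhs = 0)
    if (lp$lb[i] < 0)
      rows_extra[[length(rows_extra) + 1L]] <-
        list(cols = c(i, ybin[j]), vals = c(1, -lp$lb[i]), dir = ">=", rhs = 0)
  }
  A <- cbind(lp$A, matrix(0, nrow(lp$A), k))
  for (er in rows_extra) {
    row <- numeric(ntot); row[er$cols] <- er$vals
    A <- rbind(A, row)
  }
  dirv <- c(lp$dir, vapply(rows_extra, `[[`, character(1), "dir"))
  rhsv <- c(lp$rhs, vapply(rows_extra, `[[`, numeric(1), "rhs"))
  lo <- c(lp$lb, rep(0, k)); hi <- c(lp$ub, rep(1, k))

  solve_once <- function(obj, A, dirv, rhsv) {
    rev_idx <- which(lp$eq_rev)
    combos <- if (length(rev_idx))
      expand.grid(rep(list(c(FALSE, TRUE)), length(rev_idx)))
    else data.frame(row.names = 1)
    best <- NULL
    for (ci in seq_len(nrow(combos))) {
      l2 <- lo; h2 <- hi
      if (length(rev_idx)) {
        flip <- unlist(combos[ci, ], use.names = FALSE)
        for (j in seq_along(rev_idx)) {
          col <- lp$eq_cols[rev_idx[j]]
          if (flip[j]) { l2[col] <- -1000; h2[col] <- -so$activation_epsilon }
        }
      }
      sol <- milp_solve(obj, A, dirv, rhsv, l2, h2, binary = ybin,
                        mip_gap = so$mip_gap,
                        time_limit = so$time_limit_seconds,
                        int_tol = min(1e-6, so$activation_epsilon /
                                        so$big_M / 10))
      if (sol$status == "optimal" &&
          (is.null(best) || sol$objval < best$objval - 1e-9))
        best <- sol
    }
    best
  }

  obj <- numeric(ntot); obj[ybin] <- 1
  sol <- solve_once(obj, A, dirv, rhsv)
  if (is.null(sol))
    stop("gap-filling MILP unexpectedly infeasible for task '", task$id, "'")

  if (options$deterministic_ties) {
    kstar <- round(sum(sol$x[ybin]))
    row <- numeric(ntot); row[ybin] <- 1
    A2 <- rbind(A, row)
    obj2 <- numeric(ntot); obj2[ybin] <- cand
    sol2 <- solve_once(obj2, A2, c(dirv, "="), c(rhsv, kstar))
    if (!is.null(sol2)) sol <- sol2
  }
  rid[cand[sol$x[ybin] > 0.5]]
}

# ---- the full three-step algorithm ---------------------------------------

#' Task-driven reconstruction of a context-specific metabolic model
#'
#' Fits a functional context-specific model to per-reaction evidence
#' scores in three steps: (1) identify the task-essential reactions of
#' the reference network, (2) solve the score-maximising selection MILP
#' with those reactions forced in, (3) test each task in sequence on the
#' selected network and gap-fill minimally where a task fails.  The
#' returned model passes every task by construction.
#'
#' @param reference a `gem_model`: the reference network (the universe of
#'   reactions).
#' @param scores named numeric vector of per-reaction evidence scores
#'   (positive = evidence for inclusion), as produced by
#'   [reaction_scores()].
#' @param tasks list of [metabolic_task()] objects the final model must
#'   perform.
#' @param options a [tinit_options()].
#' @param exclude_from_essential character vector of task ids to skip
#'   during step-1 essential-reaction identification (they still drive
#'   gap-filling); by default every task, including any growth task,
#'   participates in both.
#' @return an object of class `tinit_fit` with components
#'   `selected_reactions`, `required_reactions`, `gapfilled_reactions`
#'   (ordered list of per-task additions), `objective_value`,
#'   `task_report`, and `model` (the final `gem_model`).
#' @seealso [find_essential_reactions()], [solve_selection_milp()],
#'   [gapfill_task()]
#' @export
tinit <- function(reference, scores, tasks, options = tinit_options(),
                  exclude_from_essential = character()) {
  stopifnot(inherits(reference, "gem_model"), inherits(options, "tinit_options"))
  ess_tasks <- Filter(function(t) !(t$id %in% exclude_from_essential), tasks)
  required <- find_essential_reactions(reference, ess_tasks, options$solver)
  sel <- solve_selection_milp(reference, scores, required, options)

  current <- sel$selected
  gapfilled <- list()
  for (t in tasks) {
    if (t$should_fail) next
    added <- gapfill_task(current, reference, t, options)
    gapfilled[[t$id]] <- added
    current <- union(current, added)
  }
  current <- reference$rxns$id[reference$rxns$id %in% current]
  final <- subset_model(reference, current)
  report <- check_tasks(final, tasks, options$solver)
  if (!all(vapply(report, `[[`, logical(1), "passed")))
    warning("reconstructed model does not pass all tasks; this indicates ",
            "a solver tolerance problem")

  structure(list(selected_reactions = current,
                 required_reactions = required,
                 gapfilled_reactions = gapfilled,
                 objective_value = sel$objective,
                 task_report = report,
                 model = final,
                 reference_id = reference$id,
                 n_reference = nrow(reference$rxns),
                 options = options),
            class = "tinit_fit")
}

#' @export
print.tinit_fit <- function(x, ...) {
  cat("tinit_fit: ", length(x$selected_reactions), "/", x$n_reference,
      " reactions selected from reference '", x$reference_id, "'\n", sep = "")
  nadd <- sum(lengths(x$gapfilled_reactions))
  cat("  required (task-essential): ", length(x$required_reactions),
      "; gap-filled: ", nadd, "; objective: ",
      format(x$objective_value, digits = 6), "\n", sep = "")
  df <- as.data.frame(x$task_report)
  cat("  tasks passed: ", sum(df$passed), "/", nrow(df), "\n", sep = "")
  invisible(x)
}

#' @export
summary.tinit_fit <- function(object, ...) {
  df <- as.data.frame(object$task_report)
  s <- list(n_selected = length(object$selected_reactions),
            n_reference = object$n_reference,
            n_required = length(object$required_reactions),
            gapfilled = object$gapfilled_reactions,
            objective = object$objective_value,
            tasks_by_category = table(df$category, df$passed),
            all_passed = all(df$passed))
  class(s) <- "summary.tinit_fit"
  s
}

#' @export
print.summary.tinit_fit <- function(x, ...) {
  cat("Task-driven reconstruction\n")
  cat("  selected ", x$n_selected, " of ", x$n_reference,
      " reference reactions (", x$n_required, " task-essential)\n", sep = "")
  cat("  selection objective: ", format(x$objective, digits = 6), "\n",
      sep = "")
  added <- x$gapfilled[lengths(x$gapfilled) > 0]
  if (length(added)) {
    cat("  gap-filled per task:\n")
    for (id in names(added))
      cat("    ", id, ": ", paste(added[[id]], collapse = ", "), "\n",
          sep = "")
  } else {
    cat("  no gap-filling needed\n")
  }
  cat("  all tasks passed: ", x$all_passed, "\n", sep = "")
  invisible(x)
}
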