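TASK_CATEGORIES <- c("energy_and_redox", "internal_conversions",
                     "substrate_utilization", "biosynthesis_of_products",
                     "growth", "other")

#' Define a metabolic task
#'
#' A metabolic task states a functionality contract: given the permitted
#' uptakes (`inputs`) the network must be able to sustain the required
#' productions (`outputs`) and/or enforced net conversions (`equations`)
#' at steady state in an otherwise closed system.  Tasks drive both the
#' reconstruction (the resulting model must pass all of them) and the
#' readout of the antimetabolite screen.
#'
#' @param id task identifier.
#' @param description free-text description.
#' @param category one of `r paste0('"', TASK_CATEGORIES, '"', collapse = ", ")`.
#' @param should_fail negative-control flag: the task passes only if the
#'   stated conversion is *infeasible* (e.g. ATP from nothing).
#' @param inputs data frame with columns `met`, `lb`, `ub`: permitted
#'   uptakes.  `met` is a metabolite id, `"name[compartment]"`, or a bare
#'   compartment-agnostic name (all instances pooled).  Missing bounds
#'   default to `[0, 1000]`.
#' @param outputs data frame with columns `met`, `lb`, `ub`: required (or
#'   permitted, when `lb = 0`) productions.  A missing lower bound
#'   (`NA`) is replaced by the solver's `activation_epsilon` at check
#'   time; missing upper bounds default to `1000`.
#' @param equations list of enforced net conversions, each a list with
#'   `lhs`/`rhs` (named numeric vectors of positive coefficients) and
#'   `reversible`; compiled to a temporary lumped reaction that must carry
#'   at least `activation_epsilon` flux.
#' @return an object of class `metabolic_task`.
#' @export
metabolic_task <- function(id, description = "", category = "other",
                           should_fail = FALSE, inputs = NULL,
                           outputs = NULL, equations = NULL) {
  category <- match.arg(category, TASK_CATEGORIES)
  norm_io <- function(x, default_lb) {
    if (is.null(x) || NROW(x) == 0L)
      return(data.frame(met = character(), lb = numeric(), ub = numeric(),
                        stringsAsFactors = FALSE))
    x <- as.data.frame(x, stringsAsFactors = FALSE)
    stopifnot("met" %in% names(x))
    if (is.null(x$lb)) x$lb <- default_lb
    if (is.null(x$ub)) x$ub <- 1000
    x$lb[is.na(x$lb) & !is.na(default_lb)] <- default_lb
    x$ub[is.na(x$ub)] <- 1000
    bad <- !is.na(x$lb) & x$lb > x$ub
    if (any(bad)) stop("task '", id, "': bounds out of order for ",
                       paste(x$met[bad], collapse = ", "))
    x[c("met", "lb", "ub")]
  }
  inputs <- norm_io(inputs, 0)
  outputs <- norm_io(outputs, NA_real_)   # NA lb -> activation_epsilon
  equations <- equations %||% list()
  if (!should_fail && nrow(outputs) == 0L && length(equations) == 0L)
    stop("task '", id, "' has no outputs and no equations (and is not a ",
         "should_fail control)")
  structure(list(id = id, description = description, category = category,
                 should_fail = isTRUE(should_fail), inputs = inputs,
                 outputs = outputs, equations = equations),
            class = "metabolic_task")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.metabolic_task <- function(x, ...) {
  cat("metabolic_task '", x$id, "' (", x$category,
      if (x$should_fail) ", should FAIL" else "", ")\n", sep = "")
  if (nzchar(x$description)) cat("  ", x$description, "\n", sep = "")
  if (nrow(x$inputs))
    cat("  in : ", paste0(x$inputs$met, " [", x$inputs$lb, ", ",
                          x$inputs$ub, "]", collapse = "; "), "\n", sep = "")
  if (nrow(x$outputs))
    cat("  out: ", paste0(x$outputs$met, " [",
                          ifelse(is.na(x$outputs$lb), "eps", x$outputs$lb),
                          ", ", x$outputs$ub, "]", collapse = "; "),
        "\n", sep = "")
  for (eq in x$equations)
    cat("  equ: ", format_equation(eq), "\n", sep = "")
  invisible(x)
}

format_equation <- function(eq) {
  side <- function(v) paste(ifelse(v == 1, names(v),
                                   paste(v, names(v))), collapse = " + ")
  paste(side(eq$lhs), if (isTRUE(eq$reversible)) "<=>" else "=>",
        side(eq$rhs))
}

parse_equation <- function(text) {
  reversible <- grepl("<=>", text, fixed = TRUE)
  parts <- strsplit(text, "<=>|=>")[[1]]
  if (length(parts) != 2L)
    stop("cannot parse equation '", text, "'", call. = FALSE)
  side <- function(s) {
    terms <- strsplit(s, "+", fixed = TRUE)[[1]]
    terms <- trimws(terms)
    terms <- terms[nzchar(terms)]
    coefs <- numeric(0)
    for (tm in terms) {
      mm <- regmatches(tm, regexec("^([0-9.]+)\\s+(.*)$", tm))[[1]]
      if (length(mm) == 3L) {
        coefs[mm[3]] <- as.numeric(mm[2])
      } else {
        coefs[tm] <- 1
      }
    }
    coefs
  }
  list(lhs = side(parts[1]), rhs = side(parts[2]), reversible = reversible)
}

#' Read a task table
#'
#' Parses the plain-text task dialect: UTF-8 CSV or TSV (separator
#' auto-detected from the header) with columns `TASK_ID`, `DESCRIPTION`,
#' `CATEGORY`, `SHOULD_FAIL`, `IN`, `IN_LB`, `IN_UB`, `OUT`, `OUT_LB`,
#' `OUT_UB`, `EQU`.  A row with an empty `TASK_ID` (or one repeating the
#' previous id) continues the previous task, so a task with several
#' inputs/outputs spans several rows — the spreadsheet-like layout used
#' for task lists in practice.  Metabolite names are *not* resolved
#' against any model here; unmapped names surface at check time.
#'
#' @param path file path.
#' @return list of [metabolic_task()] objects.
#' @export
parse_task_table <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = c("NA", ""))
  want <- c("TASK_ID", "DESCRIPTION", "CATEGORY", "SHOULD_FAIL",
            "IN", "IN_LB", "IN_UB", "OUT", "OUT_LB", "OUT_UB", "EQU")
  unknown <- setdiff(names(df), want)
  if (length(unknown))
    stop("unknown task-table column(s): ", paste(unknown, collapse = ", "))
  for (col in setdiff(want, names(df))) df[[col]] <- NA_character_

  tasks <- list()
  cur <- NULL
  flush <- function() {
    if (is.null(cur)) return()
    tasks[[length(tasks) + 1L]] <<- metabolic_task(
      id = cur$id, description = cur$description, category = cur$category,
      should_fail = cur$should_fail,
      inputs = if (length(cur$in_met))
        data.frame(met = cur$in_met, lb = cur$in_lb, ub = cur$in_ub,
                   stringsAsFactors = FALSE),
      outputs = if (length(cur$out_met))
        data.frame(met = cur$out_met, lb = cur$out_lb, ub = cur$out_ub,
                   stringsAsFactors = FALSE),
      equations = cur$equ)
  }
  num <- function(x, default) if (is.na(x)) default else as.numeric(x)
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    new_task <- !is.na(row$TASK_ID) && nzchar(row$TASK_ID) &&
      (is.null(cur) || row$TASK_ID != cur$id)
    if (new_task) {
      flush()
      cur <- list(id = row$TASK_ID,
                  description = if (is.na(row$DESCRIPTION)) "" else row$DESCRIPTION,
                  category = if (is.na(row$CATEGORY)) "other" else row$CATEGORY,
                  should_fail = !is.na(row$SHOULD_FAIL) &&
                    tolower(row$SHOULD_FAIL) %in% c("true", "1", "yes"),
                  in_met = character(), in_lb = numeric(), in_ub = numeric(),
                  out_met = character(), out_lb = numeric(),
                  out_ub = numeric(), equ = list())
    }
    if (is.null(cur))
      stop("task table starts with a continuation row (empty TASK_ID)")
    if (!is.na(row$IN)) {
      cur$in_met <- c(cur$in_met, row$IN)
      cur$in_lb <- c(cur$in_lb, num(row$IN_LB, 0))
      cur$in_ub <- c(cur$in_ub, num(row$IN_UB, 1000))
    }
    if (!is.na(row$OUT)) {
      cur$out_met <- c(cur$out_met, row$OUT)
      cur$out_lb <- c(cur$out_lb, num(row$OUT_LB, NA_real_))
      cur$out_ub <- c(cur$out_ub, num(row$OUT_UB, 1000))
    }
    if (!is.na(row$EQU)) cur$equ <- c(cur$equ, list(parse_equation(row$EQU)))
  }
  flush()
  tasks
}

#' Write a task table
#'
#' Serialises tasks back to the plain-text dialect read by
#' [parse_task_table()]; multi-input/output tasks span continuation rows.
#'
#' @param tasks list of [metabolic_task()] objects.
#' @param path output file path.
#' @param sep field separator (tab by default).
#' @return `path`, invisibly.
#' @export
write_task_table <- function(tasks, path, sep = "\t") {
  rows <- list()
  for (t in tasks) {
    nrows <- max(1, nrow(t$inputs), nrow(t$outputs), length(t$equations))
    for (i in seq_len(nrows)) {
      rows[[length(rows) + 1L]] <- data.frame(
        TASK_ID = if (i == 1) t$id else "",
        DESCRIPTION = if (i == 1) t$description else "",
        CATEGORY = if (i == 1) t$category else "",
        SHOULD_FAIL = if (i == 1) as.character(t$should_fail) else "",
        IN = if (i <= nrow(t$inputs)) t$inputs$met[i] else "",
        IN_LB = if (i <= nrow(t$inputs)) t$inputs$lb[i] else "",
        IN_UB = if (i <= nrow(t$inputs)) t$inputs$ub[i] else "",
        OUT = if (i <= nrow(t$outputs)) t$outputs$met[i] else "",
        OUT_LB = if (i <= nrow(t$outputs)) {
          if (is.na(t$outputs$lb[i])) "" else t$outputs$lb[i]
        } else "",
        OUT_UB = if (i <= nrow(t$outputs)) t$outputs$ub[i] else "",
        EQU = if (i <= length(t$equations))
          format_equation(t$equations[[i]]) else "",
        stringsAsFactors = FALSE)
    }
  }
  utils::write.table(do.call(rbind, rows), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Assemble the task LP.  Returns either list(unmapped = <name>) when a task
# metabolite cannot be resolved, or the LP pieces: the model's reactions
# with exchanges closed, temporary uptake/sink columns (pooled over
# compartment instances via collector rows), and one lumped column per
# equation whose orientation may need enumeration when reversible.
build_task_lp <- function(model, task, eps) {
  n <- nrow(model$rxns)
  nm <- nrow(model$mets)
  lb <- ifelse(model$rxns$is_exchange, 0, model$rxns$lb)
  ub <- ifelse(model$rxns$is_exchange, 0, model$rxns$ub)
  A <- model$S
  extra_rows <- list()   # each: list(coefs = named numeric over columns, dir, rhs)
  cols <- list()         # each: numeric(nm) metabolite coefficients
  col_lb <- col_ub <- numeric(0)
  col_tag <- character(0)

  add_io <- function(spec, sign, default_lb) {
    for (k in seq_len(nrow(spec))) {
      ref <- spec$met[k]
      idx <- resolve_met(model, ref)
      lo <- spec$lb[k]; hi <- spec$ub[k]
      if (is.na(lo)) lo <- default_lb
      if (length(idx) == 0L) {
        # a merely *permitted* flow (lb <= 0) of an absent metabolite is a
        # no-op; only a required flow of an unmapped metabolite is fatal
        if (lo <= 0) next
        return(ref)
      }
      if (length(idx) == 1L) {
        v <- numeric(nm); v[idx] <- sign
        cols[[length(cols) + 1L]] <<- v
        col_lb <<- c(col_lb, lo); col_ub <<- c(col_ub, hi)
        col_tag <<- c(col_tag, paste0("io:", ref))
      } else {
        first <- length(cols) + 1L
        for (j in idx) {
          v <- numeric(nm); v[j] <- sign
          cols[[length(cols) + 1L]] <<- v
          col_lb <<- c(col_lb, 0); col_ub <<- c(col_ub, hi)
          col_tag <<- c(col_tag, paste0("io:", ref))
        }
        span <- seq(first, length(cols))
        if (lo > 0)
          extra_rows[[length(extra_rows) + 1L]] <<-
            list(cols = span, dir = ">=", rhs = lo)
        if (is.finite(hi))
          extra_rows[[length(extra_rows) + 1L]] <<-
            list(cols = span, dir = "<=", rhs = hi)
      }
    }
    NULL
  }

  bad <- add_io(task$inputs, +1, 0)
  if (!is.null(bad)) return(list(unmapped = bad))
  bad <- add_io(task$outputs, -1, eps)
  if (!is.null(bad)) return(list(unmapped = bad))

  eq_cols <- integer(0)
  eq_rev <- logical(0)
  for (eq in task$equations) {
    v <- numeric(nm)
    for (side in c("lhs", "rhs")) {
      sgn <- if (side == "lhs") -1 else 1
      for (ref in names(eq[[side]])) {
        idx <- resolve_met(model, ref)
        if (length(idx) == 0L) return(list(unmapped = ref))
        if (length(idx) > 1L)
          stop("equation metabolite '", ref, "' is ambiguous in model '",
               model$id, "'; qualify it as name[compartment]", call. = FALSE)
        v[idx] <- v[idx] + sgn * eq[[side]][[ref]]
      }
    }
    cols[[length(cols) + 1L]] <- v
    col_lb <- c(col_lb, eps); col_ub <- c(col_ub, 1000)
    col_tag <- c(col_tag, "equ")
    eq_cols <- c(eq_cols, n + length(cols))
    eq_rev <- c(eq_rev, isTRUE(eq$reversible))
  }

  ncol_extra <- length(cols)
  Afull <- cbind(A, if (ncol_extra) do.call(cbind, cols) else NULL)
  dir <- rep("=", nm)
  rhs <- rep(0, nm)
  for (er in extra_rows) {
    row <- numeric(ncol(Afull))
    row[n + er$cols] <- 1     # er$cols index into the temporary columns
    Afull <- rbind(Afull, row)
    dir <- c(dir, er$dir)
    rhs <- c(rhs, er$rhs)
  }
  list(A = Afull, dir = dir, rhs = rhs,
       lb = c(lb, col_lb), ub = c(ub, col_ub),
       n_model = n, eq_cols = eq_cols, eq_rev = eq_rev)
}

#' Check one metabolic task against a model
#'
#' Constructs the task LP — all exchange reactions closed, temporary
#' uptake reactions for the task inputs, temporary sinks for its outputs,
#' lumped flux-forced reactions for its equations, steady state on every
#' internal metabolite — and tests feasibility.  A task metabolite that
#' does not exist in the model makes the task infeasible with reason
#' `"unmapped metabolite"` rather than raising an error, so draft models
#' missing metabolites are handled uniformly.
#'
#' @param model a `gem_model`.
#' @param task a [metabolic_task()].
#' @param options a [solver_options()].
#' @return an object of class `task_result`: list with `task_id`,
#'   `feasible`, `passed` (`feasible` XOR `should_fail`), `reason` and
#'   `witness_flux` (named flux vector over model reactions when
#'   feasible).
#' @export
check_task <- function(model, task, options = solver_options()) {
  stopifnot(inherits(model, "gem_model"), inherits(task, "metabolic_task"))
  lp <- build_task_lp(model, task, options$activation_epsilon)
  if (!is.null(lp$unmapped)) {
    feasible <- FALSE
    res <- structure(list(task_id = task$id, feasible = FALSE,
                          passed = task$should_fail,
                          reason = paste0("unmapped metabolite '",
                                          lp$unmapped, "'"),
                          witness_flux = NULL),
                     class = "task_result")
    return(res)
  }

  # enumerate orientations of reversible equations (2^k combinations,
  # k = number of reversible equations; in practice 0 or 1)
  rev_idx <- which(lp$eq_rev)
  combos <- if (length(rev_idx)) {
    expand.grid(rep(list(c(FALSE, TRUE)), length(rev_idx)))
  } else {
    data.frame(row.names = 1)
  }
  feasible <- FALSE
  witness <- NULL
  for (ci in seq_len(nrow(combos))) {
    lo <- lp$lb; hi <- lp$ub
    if (length(rev_idx)) {
      flip <- unlist(combos[ci, ], use.names = FALSE)
      for (j in seq_along(rev_idx)) {
        col <- lp$eq_cols[rev_idx[j]]
        if (flip[j]) { lo[col] <- -1000; hi[col] <- -options$activation_epsilon }
      }
    }
    ans <- lp_feasible(lp$A, lp$dir, lp$rhs, lo, hi)
    if (ans$feasible) {
      feasible <- TRUE
      witness <- setNames(ans$x[seq_len(lp$n_model)], model$rxns$id)
      break
    }
  }
  structure(list(task_id = task$id, feasible = feasible,
                 passed = feasible != task$should_fail,
                 reason = if (feasible) NA_character_ else "infeasible",
                 witness_flux = witness),
            class = "task_result")
}

#' Check a list of tasks
#'
#' Runs [check_task()] for each task independently (temporary reactions
#' never leak between checks) and collects the results.
#'
#' @param model a `gem_model`.
#' @param tasks list of [metabolic_task()] objects.
#' @param options a [solver_options()].
#' @return an object of class `task_report` (list of `task_result`),
#'   order-preserving; see [as.data.frame.task_report()].
#' @export
check_tasks <- function(model, tasks, options = solver_options()) {
  res <- lapply(tasks, function(t) check_task(model, t, options))
  cats <- vapply(tasks, function(t) t$category, character(1))
  structure(res, categories = cats, class = "task_report")
}

#' @export
as.data.frame.task_report <- function(x, ...) {
  data.frame(task_id = vapply(x, `[[`, character(1), "task_id"),
             category = attr(x, "categories") %||%
               rep(NA_character_, length(x)),
             feasible = vapply(x, `[[`, logical(1), "feasible"),
             passed = vapply(x, `[[`, logical(1), "passed"),
             reason = vapply(x, `[[`, character(1), "reason"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
print.task_report <- function(x, ...) {
  df <- as.data.frame(x)
  cat("task_report: ", sum(df$passed), "/", nrow(df), " tasks passed\n",
      sep = "")
  if (any(!df$passed)) {
    bad <- df[!df$passed, ]
    cat("failed:\n")
    for (i in seq_len(nrow(bad)))
      cat("  ", bad$task_id[i], " (", bad$category[i], "): ",
          bad$reason[i], "\n", sep = "")
  }
  invisible(x)
}

#' @export
print.task_result <- function(x, ...) {
  cat("task '", x$task_id, "': ",
      if (x$feasible) "feasible" else "infeasible",
      if (x$passed) " [passed]" else " [FAILED]",
      if (!is.na(x$reason) && !x$feasible) paste0(" (", x$reason, ")") else "",
      "\n", sep = "")
  invisible(x)
}
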