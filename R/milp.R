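#' Solve a small mixed-integer linear program
#'
#' Branch-and-bound over [lp_solve()] relaxations for programs whose
#' integer variables are binary.  Depth-first search, branching on the
#' most fractional binary, exploring the branch nearest the relaxed value
#' first; fully deterministic for a fixed input.
#'
#' @inheritParams lp_solve
#' @param binary integer indices of binary variables (their bounds must
#'   lie within `[0, 1]`).
#' @param mip_gap relative optimality gap below which nodes are pruned.
#' @param time_limit soft wall-clock limit in seconds (`NULL` = none);
#'   when hit, the best incumbent found so far is returned with status
#'   `"time_limit"`.
#' @param int_tol integrality tolerance; must be set below
#'   `epsilon / big_M` whenever big-M coupling constraints tie binaries to
#'   epsilon-bounded continuous variables, otherwise the relaxation can
#'   pass a fractional `y = epsilon/M` off as integral.
#' @return list with `status` (`"optimal"`, `"infeasible"`,
#'   `"time_limit"`), `x` and `objval`.
#' @keywords internal
#' @export
milp_solve <- function(obj, A, dir, rhs, lb, ub, binary = integer(0),
                       maximize = FALSE, mip_gap = 1e-6, time_limit = NULL,
                       int_tol = 1e-6) {
  n <- length(obj)
  binary <- as.integer(binary)
  stopifnot(all(binary >= 1L), all(binary <= n))
  t0 <- proc.time()[["elapsed"]]

  # internally minimise
  cmin <- if (maximize) -obj else obj

  best_obj <- Inf
  best_x <- NULL
  timed_out <- FALSE

  # node: list(lb, ub)
  stack <- list(list(lb = lb, ub = ub))
  while (length(stack) > 0L) {
    if (!is.null(time_limit) &&
        proc.time()[["elapsed"]] - t0 > time_limit) {
      timed_out <- TRUE
      break
    }
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL

    rel <- lp_solve(cmin, A, dir, rhs, node$lb, node$ub)
    if (rel$status %in% c("maxiter", "singular"))
      stop("LP relaxation failed (", rel$status, "); the program is ",
           "numerically difficult at this size")
    if (rel$status != "optimal") next
    bound <- rel$objval
    if (is.finite(best_obj) &&
        bound >= best_obj - mip_gap * max(1, abs(best_obj)) - 1e-9) next

    frac <- abs(rel$x[binary] - round(rel$x[binary]))
    if (length(binary) == 0L || max(frac) <= int_tol) {
      x <- rel$x
      x[binary] <- round(x[binary])
      best_obj <- bound
      best_x <- x
      next
    }
    bvar <- binary[which.max(frac)]
    val <- rel$x[bvar]
    lo1 <- node$lb; hi1 <- node$ub
    lo2 <- node$lb; hi2 <- node$ub
    hi1[bvar] <- 0   # branch var = 0
    lo2[bvar] <- 1   # branch var = 1
    children <- list(list(lb = lo1, ub = hi1), list(lb = lo2, ub = hi2))
    # push the farther branch first so the nearer one is explored next
    if (val >= 0.5) children <- children[c(1, 2)] else children <- children[c(2, 1)]
    stack <- c(stack, children)
  }

  if (is.null(best_x)) {
    return(list(status = if (timed_out) "time_limit" else "infeasible",
                x = NULL, objval = NA_real_))
  }
  list(status = if (timed_out) "time_limit" else "optimal",
       x = best_x,
       objval = if (maximize) -best_obj else best_obj)
}
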