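#' Solve a small dense linear program
#'
#' Minimises (or maximises) `obj' x` subject to general linear constraints
#' `A x (<=, =, >=) rhs` and box bounds `lb <= x <= ub`.  Backed by a dense
#' two-phase primal simplex; intended for the small programs that arise in
#' task checking and network selection, not for large-scale optimisation.
#'
#' @param obj numeric objective coefficients.
#' @param A constraint matrix (dense), one row per constraint.
#' @param dir character vector of constraint directions, each one of
#'   `"<="`, `"="`, `">="`.
#' @param rhs right-hand side values.
#' @param lb,ub variable bounds; infinite bounds are capped internally at
#'   `1e7`, well above any flux magnitude used in this package.
#' @param maximize solve a maximisation instead of a minimisation.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"maxiter"`), `x` (solution vector, `NULL` unless optimal) and
#'   `objval`.
#' @keywords internal
#' @export
lp_solve <- function(obj, A, dir, rhs, lb, ub, maximize = FALSE) {
  n <- length(obj)
  A <- matrix(as.numeric(A), ncol = n)
  m <- nrow(A)
  stopifnot(length(dir) == m, length(rhs) == m,
            length(lb) == n, length(ub) == n)

  BIG <- 1e5
  lb <- pmax(lb, -BIG)
  ub <- pmin(ub, BIG)

  # convert inequality rows to equalities with slack/surplus columns
  ineq <- which(dir != "=")
  k <- length(ineq)
  if (k > 0L) {
    S <- matrix(0, m, k)
    for (j in seq_len(k)) {
      S[ineq[j], j] <- if (dir[ineq[j]] == "<=") 1 else -1
    }
    A <- cbind(A, S)
    obj2 <- c(obj, rep(0, k))
    lb2 <- c(lb, rep(0, k))
    ub2 <- c(ub, rep(BIG, k))
  } else {
    obj2 <- obj; lb2 <- lb; ub2 <- ub
  }

  cc <- if (maximize) -obj2 else obj2
  res <- .cpp_lp_dense(cc, A, as.numeric(rhs), lb2, ub2)
  status <- switch(as.character(res$status),
                   "0" = "optimal", "1" = "infeasible",
                   "2" = "unbounded", "3" = "maxiter", "4" = "singular")
  if (status != "optimal") {
    return(list(status = status, x = NULL, objval = NA_real_))
  }
  x <- res$x[seq_len(n)]
  objval <- sum(obj * x)
  list(status = status, x = x, objval = objval)
}

#' Test feasibility of a linear system
#'
#' Convenience wrapper around [lp_solve()] with a zero objective.
#'
#' @inheritParams lp_solve
#' @return list with logical `feasible` and, when feasible, a witness `x`.
#' @keywords internal
lp_feasible <- function(A, dir, rhs, lb, ub) {
  res <- lp_solve(rep(0, length(lb)), A, dir, rhs, lb, ub)
  list(feasible = identical(res$status, "optimal"), x = res$x)
}
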