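#' Numerical options for the LP/MILP machinery
#'
#' @param activation_epsilon minimum absolute flux (model flux units) for a
#'   reaction to count as used; couples the selection binaries to flux and
#'   sets the default lower bound on task product sinks.
#' @param big_M flux magnitude cap used in the binary-flux coupling
#'   constraints; must comfortably exceed any attainable flux.
#' @param mip_gap relative optimality tolerance for branch-and-bound.
#' @param time_limit_seconds optional soft wall-clock limit for a single
#'   MILP solve (`NULL` for none).
#' @param random_seed optional seed recorded with the options (the solver
#'   itself is deterministic; the seed is consumed by generators that take
#'   a `solver_options` object).
#' @return an object of class `solver_options`.
#' @export
solver_options <- function(activation_epsilon = 1e-4,
                           big_M = 1000,
                           mip_gap = 1e-6,
                           time_limit_seconds = NULL,
                           random_seed = NULL) {
  stopifnot(activation_epsilon > 0, big_M > activation_epsilon, mip_gap >= 0)
  structure(list(activation_epsilon = activation_epsilon,
                 big_M = big_M,
                 mip_gap = mip_gap,
                 time_limit_seconds = time_limit_seconds,
                 random_seed = random_seed),
            class = "solver_options")
}

#' Options for task-driven network reconstruction
#'
#' @param allow_net_production allow net accumulation of internal
#'   metabolites during network selection (the behaviour of the original
#'   INIT formulation); accumulation is penalised in the objective.
#' @param forbid_bidirectional_flux forbid a reversible reaction from
#'   carrying flux in both directions simultaneously in the selection
#'   witness; prevents thermodynamically spurious two-reaction loops that
#'   are disconnected from the rest of the network from being selected.
#' @param net_production_penalty objective penalty per unit of allowed net
#'   accumulation (only used when `allow_net_production = TRUE`).
#' @param deterministic_ties break ties between equally optimal selections
#'   with a secondary lexicographic objective (prefer lower reaction
#'   index), making results reproducible across runs.
#' @param solver a [solver_options()] object.
#' @return an object of class `tinit_options`.
#' @export
tinit_options <- function(allow_net_production = FALSE,
                          forbid_bidirectional_flux = TRUE,
                          net_production_penalty = 1,
                          deterministic_ties = TRUE,
                          solver = solver_options()) {
  stopifnot(net_production_penalty >= 0, inherits(solver, "solver_options"))
  structure(list(allow_net_production = isTRUE(allow_net_production),
                 forbid_bidirectional_flux = isTRUE(forbid_bidirectional_flux),
                 net_production_penalty = net_production_penalty,
                 deterministic_ties = isTRUE(deterministic_ties),
                 solver = solver),
            class = "tinit_options")
}
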