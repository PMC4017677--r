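# Brute-force oracles, independent of the branch-and-bound code paths:
# exhaustive subset enumeration with per-subset feasibility LPs.

# Can every eps-forced reaction of the subset carry activating flux in one
# common steady-state distribution?  Directions of eps-forced reversible
# reactions are enumerated explicitly (the no-bidirectional-flux rule);
# without that rule an eps-forced reversible reaction can always activate
# itself through a cancelling forward/backward pair, so it is
# unconstrained.
oracle_subset_feasible <- function(model, in_set, forced, options) {
  eps <- options$solver$activation_epsilon
  n <- nrow(model$rxns)
  lb <- model$rxns$lb
  ub <- model$rxns$ub
  lb[!in_set] <- 0
  ub[!in_set] <- 0
  rev <- lb < 0 & ub > 0

  forced <- forced & in_set
  if (!options$forbid_bidirectional_flux) forced <- forced & !rev

  fwd_only <- which(forced & !rev & ub > 0)
  bwd_only <- which(forced & !rev & ub <= 0)
  lb[fwd_only] <- pmax(lb[fwd_only], eps)
  lb2 <- lb; ub2 <- ub
  ub2[bwd_only] <- pmin(ub2[bwd_only], -eps)

  free_rev <- which(forced & rev)
  combos <- if (length(free_rev))
    expand.grid(rep(list(c(1, -1)), length(free_rev)))
  else data.frame(row.names = 1)
  for (ci in seq_len(nrow(combos))) {
    lo <- lb2; hi <- ub2
    if (length(free_rev)) {
      dirs <- unlist(combos[ci, ], use.names = FALSE)
      for (j in seq_along(free_rev)) {
        i <- free_rev[j]
        if (dirs[j] > 0) lo[i] <- max(lo[i], eps) else hi[i] <- min(hi[i], -eps)
      }
    }
    if (any(lo > hi)) next
    ans <- tinitr:::lp_feasible(model$S, rep("=", nrow(model$S)),
                                rep(0, nrow(model$S)), lo, hi)
    if (ans$feasible) return(TRUE)
  }
  FALSE
}

# Exhaustive optimum of the network-selection problem (score sum over
# flux-consistent subsets containing the required set).  Only defined for
# allow_net_production = FALSE.
oracle_selection <- function(model, scores, required = character(),
                             options = tinit_options()) {
  stopifnot(!options$allow_net_production)
  n <- nrow(model$rxns)
  stopifnot(n <= 16)
  rid <- model$rxns$id
  w <- as.numeric(scores[rid])
  req <- rid %in% required
  forced_base <- w > 0 | req

  best <- -Inf
  best_set <- NULL
  for (mask in seq_len(2^n) - 1L) {
    in_set <- bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0
    if (any(req & !in_set)) next
    # reactions with a forced-flux bound can never be excluded
    if (any(!in_set & (model$rxns$lb > 0 | model$rxns$ub < 0))) next
    obj <- sum(w[in_set])
    if (obj <= best) next
    if (oracle_subset_feasible(model, in_set, forced_base, options)) {
      best <- obj
      best_set <- rid[in_set]
    }
  }
  list(objective = best, selected = best_set)
}

# Exhaustive minimum-cardinality gap-fill: try candidate addition subsets
# in order of increasing size until the task becomes feasible.
oracle_gapfill <- function(draft, reference, task,
                           options = tinit_options()) {
  rid <- reference$rxns$id
  closed_model <- function(keep) {
    m <- reference
    drop <- !(rid %in% keep)
    m$rxns$lb[drop] <- 0
    m$rxns$ub[drop] <- 0
    m
  }
  feas <- function(keep)
    check_task(closed_model(keep), task, options$solver)$feasible
  if (feas(draft)) return(0L)
  cand <- setdiff(rid[!reference$rxns$is_exchange], draft)
  for (k in seq_along(cand)) {
    sets <- utils::combn(cand, k, simplify = FALSE)
    for (g in sets) if (feas(c(draft, g))) return(k)
  }
  stop("oracle: task infeasible even with all candidates")
}

# Rebuild a model with the consuming directions of a metabolite physically
# deleted (irreversible consumers removed, reversible ones restricted),
# for the blocking-equivalence check.
oracle_delete_consuming <- function(model, metabolite_name) {
  hits <- consuming_reactions(model, metabolite_name)
  m <- model
  drop <- character()
  for (r in names(hits)) {
    i <- match(r, m$rxns$id)
    if (hits[[r]] %in% c("forward", "both")) {
      if (m$rxns$lb[i] >= 0 || hits[[r]] == "both") drop <- c(drop, r)
      else m$rxns$ub[i] <- 0
    }
    if (hits[[r]] == "reverse") m$rxns$lb[i] <- 0
  }
  keep <- setdiff(m$rxns$id, drop)
  if (length(keep) == 0L) stop("oracle: deletion empties the model")
  sub <- subset_model(m, keep)
  sub
}
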