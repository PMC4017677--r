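#' Didactic toy network with a known reconstruction outcome
#'
#' A hand-coded nine-internal-reaction network built so that every step
#' of task-driven reconstruction is visible: two tasks ("D from A",
#' "E from B"), positively scored ("green") reactions forming the
#' preferred routes, negatively scored ("red") reactions of which a
#' removable ("dotted") subset never survives selection, and one red
#' reaction — the only remaining route to E once the network is pruned —
#' that must come back through gap-filling.  A permitted uptake of C
#' provides the shortcut that makes the second task feasible before
#' pruning, which is exactly why no reaction on the B-to-E route is
#' task-essential.
#'
#' @return list with components `model` (a `gem_model`), `tasks` (two
#'   [metabolic_task()]s), `scores` (named score vector) and `expected`
#'   (list: `required`, `selected`, `dotted_removed`, `gapfilled`,
#'   `final` — the reaction sets the algorithm must produce).
#' @export
toy_network <- function() {
  rxn <- function(from, to) {
    st <- c(-1, 1)
    names(st) <- paste0(c(from, to), "[c]")
    st
  }
  model <- gem_model(list(
    EX_A = list(stoich = c(`A[c]` = 1)),
    EX_B = list(stoich = c(`B[c]` = 1)),
    EX_C = list(stoich = c(`C[c]` = 1)),
    EX_D = list(stoich = c(`D[c]` = -1)),
    EX_E = list(stoich = c(`E[c]` = -1)),
    R1 = list(stoich = rxn("A", "P"), gpr = "gA1"),
    R2 = list(stoich = rxn("P", "D"), gpr = "gA2"),
    R3 = list(stoich = rxn("B", "M"), gpr = "gB1"),
    R4 = list(stoich = rxn("M", "D"), gpr = "gM1"),
    R5 = list(stoich = rxn("M", "E"), gpr = "gR1"),
    R6 = list(stoich = rxn("C", "N"), gpr = "gR2"),
    R7 = list(stoich = rxn("N", "E"), gpr = "gG3"),
    R8 = list(stoich = rxn("D", "F"), gpr = "gR3"),
    R9 = list(stoich = rxn("F", "E"), gpr = "gR4")),
    id = "toy")

  scores <- c(EX_A = 0, EX_B = 0, EX_C = 0, EX_D = 0, EX_E = 0,
              R1 = 10, R2 = 10, R3 = 10, R4 = 10, R7 = 10,
              R5 = -15, R6 = -15, R8 = -15, R9 = -15)

  tasks <- list(
    metabolic_task("D_from_A", "production of D from A",
                   category = "biosynthesis_of_products",
                   inputs = data.frame(met = "A", lb = 0, ub = 10),
                   outputs = data.frame(met = "D", lb = NA, ub = 10)),
    metabolic_task("E_from_B", "production of E from B (C uptake permitted)",
                   category = "biosynthesis_of_products",
                   inputs = data.frame(met = c("B", "C"), lb = 0, ub = 10),
                   outputs = data.frame(met = "E", lb = NA, ub = 10)))

  expected <- list(
    required = c("R1", "R2"),
    selected = c("EX_A", "EX_B", "EX_D", "R1", "R2", "R3", "R4"),
    dotted_removed = c("R6", "R8", "R9"),
    gapfilled = "R5",
    final = c("EX_A", "EX_B", "EX_D", "R1", "R2", "R3", "R4", "R5"))

  list(model = model, tasks = tasks, scores = scores, expected = expected)
}

#' Specification for a random planted-network fixture
#'
#' @param seed integer seed; every generator taking a `fixture_spec` is a
#'   pure function of it.
#' @param n_reactions total number of reactions (planted chains, their
#'   exchanges, and distractors).
#' @param n_tasks number of planted conversion tasks (one chain each).
#' @param planted_fraction fraction of reactions belonging to the planted
#'   context model's internal chains.
#' @param reversible_fraction probability that a planted chain reaction
#'   is reversible.
#' @param evidence_missing_rate per-cell probability of a missing
#'   evidence value in the simulated cohort.
#' @param n_samples cohort size for evidence simulation.
#' @param include_should_fail add a negative-control task (production
#'   from nothing) to the task list.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1, n_reactions = 12, n_tasks = 2,
                         planted_fraction = 0.5, reversible_fraction = 0.2,
                         evidence_missing_rate = 0.1, n_samples = 6,
                         include_should_fail = TRUE) {
  stopifnot(n_reactions >= 3, n_tasks >= 1,
            planted_fraction > 0, planted_fraction <= 1,
            reversible_fraction >= 0, reversible_fraction <= 1,
            evidence_missing_rate >= 0, evidence_missing_rate <= 1,
            n_samples >= 1)
  structure(list(seed = as.integer(seed), n_reactions = n_reactions,
                 n_tasks = n_tasks, planted_fraction = planted_fraction,
                 reversible_fraction = reversible_fraction,
                 evidence_missing_rate = evidence_missing_rate,
                 n_samples = n_samples,
                 include_should_fail = isTRUE(include_should_fail)),
            class = "fixture_spec")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Generate a random reference network with a planted context model
#'
#' Builds, deterministically from the seed, a reference network
#' containing (i) a planted context model — one substrate-to-product
#' conversion chain per task, plus the matching exchange reactions —
#' that satisfies every generated task, and (ii) distractor reactions
#' (dead ends, redundant parallel routes, cross-chain shortcuts) that are
#' never needed.  Planted chain reactions carry single-gene rules
#' (`gP*`), distractors carry their own genes (`gD*`), exchanges are
#' spontaneous; scoring the planted genes positive and the distractor
#' genes negative therefore makes the planted context the unique optimum
#' of network selection.
#'
#' @param spec a [fixture_spec()].
#' @return list with `model` (a `gem_model`), `planted` (character
#'   vector: the context model's reaction ids), `tasks` (list of
#'   [metabolic_task()]), and `spec`.
#' @export
random_reference <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  k <- spec$n_tasks
  p <- max(k, round(spec$planted_fraction * spec$n_reactions))
  d <- spec$n_reactions - p - 2L * k
  if (d < 0)
    stop("unsatisfiable fixture spec: ", spec$n_reactions,
         " reactions cannot hold ", p, " planted chain reactions plus ",
         2 * k, " exchanges; increase n_reactions or lower ",
         "planted_fraction/n_tasks")

  with_seed(spec$seed, {
    lens <- rep(p %/% k, k)
    if (p %% k) lens[seq_len(p %% k)] <- lens[seq_len(p %% k)] + 1L
    reactions <- list()
    planted <- character()
    chain_mets <- list()
    for (ci in seq_len(k)) {
      mets <- c(sprintf("I%d[c]", ci),
                if (lens[ci] > 1)
                  sprintf("M%d_%d[c]", ci, seq_len(lens[ci] - 1L)),
                sprintf("O%d[c]", ci))
      chain_mets[[ci]] <- mets
      ex_in <- sprintf("EX_I%d", ci)
      ex_out <- sprintf("EX_O%d", ci)
      reactions[[ex_in]] <- list(stoich = setNames(1, mets[1]))
      reactions[[ex_out]] <- list(stoich = setNames(-1, mets[length(mets)]))
      planted <- c(planted, ex_in, ex_out)
      for (j in seq_len(lens[ci])) {
        rid <- sprintf("P%d_%d", ci, j)
        st <- setNames(c(-1, 1), mets[c(j, j + 1L)])
        rev <- runif(1) < spec$reversible_fraction
        reactions[[rid]] <- list(stoich = st, lb = if (rev) -1000 else 0,
                                 ub = 1000, gpr = sprintf("gP%d_%d", ci, j),
                                 subsystem = sprintf("chain%d", ci))
        planted <- c(planted, rid)
      }
    }

    all_chain_mets <- unlist(chain_mets)
    for (di in seq_len(max(d, 0))) {
      rid <- sprintf("D%d", di)
      type <- (di - 1L) %% 3L
      if (type == 0L) {                      # dead end
        src <- sample(all_chain_mets, 1)
        st <- setNames(c(-1, 1), c(src, sprintf("X%d[c]", di)))
      } else if (type == 1L) {               # redundant parallel route
        ci <- sample(k, 1)
        j <- sample(lens[ci], 1)
        st <- setNames(c(-1, 1), chain_mets[[ci]][c(j, j + 1L)])
      } else if (k > 1L) {                    # cross-chain shortcut
        ci <- sample(k, 1)
        others <- setdiff(seq_len(k), ci)
        cj <- others[sample.int(length(others), 1)]
        st <- setNames(c(-1, 1), c(chain_mets[[ci]][1],
                                   chain_mets[[cj]][lens[cj] + 1L]))
      } else {                                 # single chain: dead end
        src <- sample(all_chain_mets, 1)
        st <- setNames(c(-1, 1), c(src, sprintf("X%d[c]", di)))
      }
      reactions[[rid]] <- list(stoich = st, gpr = sprintf("gD%d", di),
                               subsystem = "distractor")
    }

    model <- gem_model(reactions, id = sprintf("fixture_seed%d", spec$seed))

    cats <- c("energy_and_redox", "internal_conversions",
              "substrate_utilization", "biosynthesis_of_products")
    tasks <- lapply(seq_len(k), function(ci) {
      metabolic_task(sprintf("T%d", ci),
                     sprintf("production of O%d from I%d", ci, ci),
                     category = cats[(ci - 1L) %% 4L + 1L],
                     inputs = data.frame(met = sprintf("I%d", ci),
                                         lb = 0, ub = 1000),
                     outputs = data.frame(met = sprintf("O%d", ci),
                                          lb = NA, ub = 1000))
    })
    if (spec$include_should_fail)
      tasks[[length(tasks) + 1L]] <- metabolic_task(
        "SF_nothing", "production of O1 from nothing (negative control)",
        category = "energy_and_redox", should_fail = TRUE,
        outputs = data.frame(met = "O1", lb = NA, ub = 1000))

    list(model = model, planted = planted, tasks = tasks, spec = spec)
  })
}

#' Simulate a cohort evidence matrix for a planted fixture
#'
#' Genes backing planted reactions are detected (strong / moderate /
#' weak, with a per-gene baseline and per-sample wobble), distractor
#' genes stain negative, and missing cells are injected at the spec's
#' rate — while guaranteeing each gene is observed in at least one
#' sample, so cohort median imputation is always defined.  Deterministic
#' in `spec$seed`.
#'
#' @param model a `gem_model` from [random_reference()].
#' @param planted character vector of planted reaction ids.
#' @param spec the [fixture_spec()] used to build the model.
#' @return an [evidence_matrix()] (genes x `spec$n_samples`).
#' @export
simulate_evidence <- function(model, planted, spec) {
  stopifnot(inherits(model, "gem_model"), inherits(spec, "fixture_spec"))
  genes <- model$genes
  if (length(genes) == 0L) stop("model has no gene rules")
  planted_genes <- unique(unlist(
    lapply(model$gpr_trees[planted], gpr_genes)))

  with_seed(spec$seed + 104729L, {
    base <- ifelse(genes %in% planted_genes,
                   sample(1:3, length(genes), replace = TRUE,
                          prob = c(0.2, 0.3, 0.5)),
                   0L)
    lv <- matrix(NA_integer_, length(genes), spec$n_samples,
                 dimnames = list(genes, sprintf("S%d", seq_len(spec$n_samples))))
    for (s in seq_len(spec$n_samples)) {
      wobble <- ifelse(base > 0 & runif(length(genes)) < 0.2,
                       pmin(3L, pmax(1L, base +
                                       sample(c(-1L, 1L), length(genes),
                                              replace = TRUE))),
                       base)
      miss <- runif(length(genes)) < spec$evidence_missing_rate
      lv[, s] <- ifelse(miss, NA_integer_, wobble)
    }
    all_missing <- rowSums(!is.na(lv)) == 0L
    lv[all_missing, 1L] <- base[all_missing]
    evidence_matrix(lv)
  })
}

#' Planted tumour/healthy screening panels
#'
#' Hand-constructed model panels with known antimetabolite-screen
#' outcomes, used throughout the package's tests and examples.  Tumour
#' growth requires three precursors: P2 via the choke metabolite Q, P via
#' X (with tumour T1 alone carrying a bypass route through B), and L via
#' the pool-patterned metabolite `fa_pool`; biomass is exported.  Healthy
#' models run an energy task — H1 routes it through P2 (so blocking P2 is
#' planted toxic), H2 converts its fuel directly.
#'
#' @return list with `tumors` (three `gem_model`s), `healthy` (two),
#'   `generic` (the bypass-free population model), `tasks` (growth,
#'   energy and precursor tasks) and `expected` (the planted screen
#'   classifications).
#' @export
screen_panel <- function() {
  rxn <- function(from, to) setNames(c(-1, 1), paste0(c(from, to), "[c]"))

  tumor_core <- list(
    EX_S = list(stoich = c(`S[c]` = 1)),
    R1 = list(stoich = rxn("S", "Q"), gpr = "g1"),
    R2 = list(stoich = rxn("Q", "P2"), gpr = "g2"),
    R6 = list(stoich = rxn("S", "X"), gpr = "g6"),
    R7 = list(stoich = rxn("X", "P"), gpr = "g7"),
    R15 = list(stoich = rxn("S", "fa_pool"), gpr = "g15"),
    R16 = list(stoich = rxn("fa_pool", "L"), gpr = "g16"),
    R3 = list(stoich = c(`P[c]` = -1, `P2[c]` = -1, `L[c]` = -1,
                         `BIO[c]` = 1), gpr = "g3"),
    EX_BIO = list(stoich = c(`BIO[c]` = -1)))

  t1 <- gem_model(c(tumor_core, list(
    R8 = list(stoich = rxn("S", "B"), gpr = "g8"),
    R9 = list(stoich = rxn("B", "P"), gpr = "g9"))), id = "T1")
  t2 <- gem_model(tumor_core, id = "T2")
  t3 <- gem_model(tumor_core, id = "T3")
  generic <- gem_model(tumor_core, id = "generic")

  h1 <- gem_model(list(
    EX_R = list(stoich = c(`R[c]` = 1)),
    R10 = list(stoich = rxn("R", "P2"), gpr = "h10"),
    R11 = list(stoich = rxn("P2", "E"), gpr = "h11"),
    EX_E = list(stoich = c(`E[c]` = -1))), id = "H1")
  h2 <- gem_model(list(
    EX_R = list(stoich = c(`R[c]` = 1)),
    R12 = list(stoich = rxn("R", "E"), gpr = "h12"),
    EX_E = list(stoich = c(`E[c]` = -1))), id = "H2")

  tasks <- list(
    metabolic_task("GROWTH", "biomass production from substrate",
                   category = "growth",
                   inputs = data.frame(met = "S", lb = 0, ub = 10),
                   outputs = data.frame(met = "BIO", lb = NA, ub = 1000)),
    metabolic_task("ENERGY", "energy product from fuel",
                   category = "energy_and_redox",
                   inputs = data.frame(met = "R", lb = 0, ub = 10),
                   outputs = data.frame(met = "E", lb = NA, ub = 1000)),
    metabolic_task("PREC", "precursor synthesis from substrate",
                   category = "internal_conversions",
                   inputs = data.frame(met = "S", lb = 0, ub = 10),
                   outputs = data.frame(met = "P", lb = NA, ub = 1000)))

  list(tumors = list(T1 = t1, T2 = t2, T3 = t3),
       healthy = list(H1 = h1, H2 = h2),
       generic = generic,
       tasks = tasks,
       expected = list(
         universe = sort(c("S", "Q", "P", "P2", "X", "B", "fa_pool",
                           "L", "BIO")),
         effective_all = sort(c("S", "Q", "P", "P2", "L", "fa_pool")),
         effective_subset = "X",
         ineffective = sort(c("B", "BIO")),
         toxic = "P2",
         pool = "fa_pool",
         proposals = sort(c("S", "Q", "P", "L")),
         generic_false_positive = "X"))
}
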