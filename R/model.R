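#' Construct a genome-scale metabolic model
#'
#' Builds a stoichiometric model object from a list of reaction
#' definitions.  Boundary species are removed from the stoichiometry at
#' construction time (the constraint-based convention): a reaction that
#' touched a boundary species becomes an exchange reaction with one-sided
#' stoichiometry, and the removed links are retained so that SBML export
#' can reconstruct them.
#'
#' @param reactions named list; each element is a list with fields
#'   `stoich` (named numeric vector, names are metabolite ids, negative =
#'   substrate, positive = product), and optionally `lb`, `ub` (flux
#'   bounds; when omitted they default to `[-1000, 1000]` if `reversible =
#'   TRUE` and `[0, 1000]` otherwise), `reversible` (only consulted when
#'   bounds are omitted), `gpr` (gene-association rule string) and
#'   `subsystem`.
#' @param id model identifier.
#' @param metabolites optional data frame with columns `id` and any of
#'   `name`, `compartment`, `boundary` overriding the values derived from
#'   metabolite ids.
#' @param boundary character vector of metabolite ids to treat as
#'   boundary/external species (in addition to any flagged via
#'   `metabolites$boundary`).
#' @param compartment_patterns regular expressions used to split a trailing
#'   compartment tag off a metabolite id; the first capture group is the
#'   compartment.  The default recognises both the `"glc[c]"` and the
#'   `"glc_c"` dialects.
#' @param default_compartment compartment assigned when no tag is found.
#' @return an object of class `gem_model` with components `id`, `mets`
#'   (data frame: `id`, `name`, `compartment`), `rxns` (data frame: `id`,
#'   `lb`, `ub`, `subsystem`, `gpr`, `is_exchange`), `S` (dense
#'   stoichiometric matrix, metabolites x reactions), `genes`,
#'   `gpr_trees`, `boundary_mets` and `boundary_links`.
#' @examples
#' m <- gem_model(list(
#'   EX_A = list(stoich = c(`A[c]` = 1), ub = 10),
#'   R1   = list(stoich = c(`A[c]` = -1, `B[c]` = 1), gpr = "G1"),
#'   EX_B = list(stoich = c(`B[c]` = -1), ub = 10)))
#' m
#' @export
gem_model <- function(reactions, id = "model", metabolites = NULL,
                      boundary = character(),
                      compartment_patterns = c("\\[([A-Za-z0-9]+)\\]$",
                                               "_([a-z])$"),
                      default_compartment = "c") {
  if (length(reactions) == 0L) stop("a model needs at least one reaction")
  rids <- names(reactions)
  if (is.null(rids) || anyNA(rids) || any(!nzchar(rids)))
    stop("all reactions must be named")
  if (anyDuplicated(rids))
    stop("duplicate reaction ids: ",
         paste(unique(rids[duplicated(rids)]), collapse = ", "))

  getf <- function(x, f, d) if (!is.null(x[[f]])) x[[f]] else d
  all_mids <- unique(unlist(lapply(reactions, function(r) names(r$stoich))))
  if (is.null(all_mids)) stop("reactions carry no stoichiometry")

  split_id <- function(mid) {
    for (p in compartment_patterns) {
      mm <- regmatches(mid, regexec(p, mid))[[1]]
      if (length(mm) == 2L)
        return(c(sub(p, "", mid), mm[2]))
    }
    c(mid, default_compartment)
  }
  parts <- t(vapply(all_mids, split_id, character(2)))
  mets <- data.frame(id = all_mids, name = parts[, 1],
                     compartment = parts[, 2],
                     stringsAsFactors = FALSE, row.names = NULL)
  is_bound <- mets$id %in% boundary
  if (!is.null(metabolites)) {
    stopifnot(is.data.frame(metabolites), "id" %in% names(metabolites))
    idx <- match(mets$id, metabolites$id)
    for (col in c("name", "compartment")) {
      if (col %in% names(metabolites)) {
        src <- metabolites[[col]][idx]
        mets[[col]] <- ifelse(is.na(idx) | is.na(src), mets[[col]], src)
      }
    }
    if ("boundary" %in% names(metabolites)) {
      fb <- metabolites$boundary[idx]
      is_bound <- is_bound | (!is.na(idx) & !is.na(fb) & fb)
    }
  }

  boundary_mets <- mets[is_bound, , drop = FALSE]
  mets <- mets[!is_bound, , drop = FALSE]
  row.names(mets) <- NULL
  if (nrow(mets) == 0L) stop("model has no internal metabolites")
  dup <- duplicated(paste(mets$name, mets$compartment, sep = "\r"))
  if (any(dup))
    stop("duplicate (name, compartment) pairs: ",
         paste(unique(paste0(mets$name[dup], "[", mets$compartment[dup], "]")),
               collapse = ", "))

  S <- matrix(0, nrow(mets), length(reactions),
              dimnames = list(mets$id, rids))
  blinks <- list()
  lb <- ub <- numeric(length(reactions))
  gprs <- subsys <- character(length(reactions))
  for (i in seq_along(reactions)) {
    r <- reactions[[i]]
    st <- r$stoich
    if (is.null(st) || length(st) == 0L || is.null(names(st)))
      stop("reaction '", rids[i], "' has empty stoichiometry")
    if (anyDuplicated(names(st)))
      stop("reaction '", rids[i], "' lists a metabolite twice")
    rev_flag <- isTRUE(getf(r, "reversible", FALSE))
    lb[i] <- getf(r, "lb", if (rev_flag) -1000 else 0)
    ub[i] <- getf(r, "ub", 1000)
    if (lb[i] > ub[i])
      stop("reaction '", rids[i], "' has lower bound above upper bound")
    gprs[i] <- getf(r, "gpr", "")
    subsys[i] <- getf(r, "subsystem", "")
    on_bound <- names(st) %in% boundary_mets$id
    if (any(on_bound))
      blinks[[length(blinks) + 1L]] <-
        data.frame(rxn = rids[i], met = names(st)[on_bound],
                   coef = unname(st[on_bound]), stringsAsFactors = FALSE)
    st <- st[!on_bound]
    if (length(st) == 0L)
      stop("reaction '", rids[i],
           "' involves only boundary species; nothing remains after ",
           "boundary removal")
    S[names(st), i] <- st
  }
  boundary_links <- if (length(blinks)) do.call(rbind, blinks) else
    data.frame(rxn = character(), met = character(), coef = numeric(),
               stringsAsFactors = FALSE)

  one_sided <- apply(S, 2, function(col) all(col >= 0) || all(col <= 0))
  touches_boundary <- rids %in% boundary_links$rxn
  rxns <- data.frame(id = rids, lb = lb, ub = ub, subsystem = subsys,
                     gpr = gprs, is_exchange = one_sided | touches_boundary,
                     stringsAsFactors = FALSE, row.names = NULL)

  gpr_trees <- lapply(gprs, parse_gpr)
  names(gpr_trees) <- rids
  genes <- sort(unique(unlist(lapply(gpr_trees, gpr_genes))))
  if (is.null(genes)) genes <- character()

  m <- structure(list(id = id, mets = mets, rxns = rxns, S = S,
                      genes = genes, gpr_trees = gpr_trees,
                      boundary_mets = boundary_mets,
                      boundary_links = boundary_links),
                 class = "gem_model")
  validate_gem_model(m)
}

#' Validate the internal consistency of a `gem_model`
#'
#' Checks referential integrity (stoichiometry rows match the metabolite
#' table, gene rules reference listed genes), uniqueness of identifiers
#' and well-ordered bounds.  Called by every constructor/manipulator;
#' exposed for testing custom-built objects.
#'
#' @param m a `gem_model`.
#' @return `m`, invisibly usable, after passing all checks.
#' @export
validate_gem_model <- function(m) {
  stopifnot(inherits(m, "gem_model"))
  if (anyDuplicated(m$rxns$id)) stop("duplicate reaction ids")
  if (anyDuplicated(m$mets$id)) stop("duplicate metabolite ids")
  if (!identical(rownames(m$S), m$mets$id) ||
      !identical(colnames(m$S), m$rxns$id))
    stop("stoichiometric matrix dimnames disagree with met/rxn tables")
  if (any(m$rxns$lb > m$rxns$ub)) stop("lower bound above upper bound")
  if (any(colSums(m$S != 0) == 0))
    stop("reaction(s) with empty stoichiometry: ",
         paste(m$rxns$id[colSums(m$S != 0) == 0], collapse = ", "))
  rule_genes <- unlist(lapply(m$gpr_trees, gpr_genes))
  if (length(rule_genes) && !all(rule_genes %in% m$genes))
    stop("gene rule references unlisted gene(s): ",
         paste(setdiff(rule_genes, m$genes), collapse = ", "))
  m
}

#' Reversibility flags for all reactions
#' @param model a `gem_model`.
#' @return named logical vector, `TRUE` where `lb < 0 & ub > 0`.
#' @export
reversible <- function(model) {
  setNames(model$rxns$lb < 0 & model$rxns$ub > 0, model$rxns$id)
}

#' Restrict a model to a set of reactions
#'
#' Returns the submodel containing exactly `reaction_ids`, the metabolites
#' they touch and the genes their rules reference.
#'
#' @param model a `gem_model`.
#' @param reaction_ids character vector of reaction ids to keep (any
#'   order; duplicates ignored).
#' @return a `gem_model`.
#' @export
subset_model <- function(model, reaction_ids) {
  reaction_ids <- unique(as.character(reaction_ids))
  missing_ids <- setdiff(reaction_ids, model$rxns$id)
  if (length(missing_ids))
    stop("unknown reaction id(s): ", paste(missing_ids, collapse = ", "))
  keep <- model$rxns$id %in% reaction_ids     # preserve model order
  S <- model$S[, keep, drop = FALSE]
  met_keep <- rowSums(S != 0) > 0
  S <- S[met_keep, , drop = FALSE]
  rxns <- model$rxns[keep, , drop = FALSE]
  row.names(rxns) <- NULL
  mets <- model$mets[met_keep, , drop = FALSE]
  row.names(mets) <- NULL
  gpr_trees <- model$gpr_trees[keep]
  genes <- sort(unique(unlist(lapply(gpr_trees, gpr_genes))))
  if (is.null(genes)) genes <- character()
  bl <- model$boundary_links[model$boundary_links$rxn %in% rxns$id, ,
                             drop = FALSE]
  row.names(bl) <- NULL
  bm <- model$boundary_mets[model$boundary_mets$id %in% bl$met, ,
                            drop = FALSE]
  row.names(bm) <- NULL
  m <- structure(list(id = model$id, mets = mets, rxns = rxns, S = S,
                      genes = genes, gpr_trees = gpr_trees,
                      boundary_mets = bm, boundary_links = bl),
                 class = "gem_model")
  if (nrow(rxns)) validate_gem_model(m) else m
}

# Resolve a task/screen metabolite reference to internal metabolite indices.
# Accepts an exact metabolite id, "name[compartment]", or a bare
# compartment-agnostic name (matching every compartment instance).
resolve_met <- function(model, ref) {
  hit <- which(model$mets$id == ref)
  if (length(hit)) return(hit)
  mm <- regmatches(ref, regexec("^(.*)\\[([A-Za-z0-9]+)\\]$", ref))[[1]]
  if (length(mm) == 3L)
    return(which(model$mets$name == mm[2] & model$mets$compartment == mm[3]))
  which(model$mets$name == ref)
}

#' Reactions consuming a metabolite, pooled over compartments
#'
#' Identifies, for a compartment-agnostic metabolite name, every reaction
#' direction in which any compartment instance of that metabolite is
#' consumed: reactions with a negative coefficient consume it in the
#' forward direction, and reversible reactions with a positive coefficient
#' consume it when running in reverse.
#'
#' @param model a `gem_model`.
#' @param metabolite_name compartment-agnostic metabolite name (or
#'   `"name[compartment]"` to restrict to one instance).
#' @return named character vector mapping reaction id to `"forward"`,
#'   `"reverse"` or `"both"`; empty when nothing matches.
#' @export
consuming_reactions <- function(model, metabolite_name) {
  midx <- resolve_met(model, metabolite_name)
  if (length(midx) == 0L) return(setNames(character(), character()))
  sub <- model$S[midx, , drop = FALSE]
  rev <- reversible(model)
  fwd <- colSums(sub < 0) > 0
  bwd <- colSums(sub > 0) > 0 & rev
  dir <- ifelse(fwd & bwd, "both", ifelse(fwd, "forward",
                ifelse(bwd, "reverse", NA_character_)))
  keep <- !is.na(dir)
  setNames(dir[keep], model$rxns$id[keep])
}

#' @export
print.gem_model <- function(x, ...) {
  cat("gem_model '", x$id, "': ", nrow(x$rxns), " reactions, ",
      nrow(x$mets), " metabolites, ", length(x$genes), " genes\n", sep = "")
  cat("  compartments: ",
      paste(sort(unique(x$mets$compartment)), collapse = ", "),
      "; exchange reactions: ", sum(x$rxns$is_exchange),
      "; reversible: ", sum(reversible(x)), "\n", sep = "")
  invisible(x)
}

#' @export
summary.gem_model <- function(object, ...) {
  s <- list(id = object$id,
            n_reactions = nrow(object$rxns),
            n_metabolites = nrow(object$mets),
            n_genes = length(object$genes),
            n_exchange = sum(object$rxns$is_exchange),
            n_reversible = sum(reversible(object)),
            compartments = sort(unique(object$mets$compartment)),
            subsystems = sort(unique(object$rxns$subsystem[
              nzchar(object$rxns$subsystem)])))
  class(s) <- "summary.gem_model"
  s
}

#' @export
print.summary.gem_model <- function(x, ...) {
  cat("Genome-scale metabolic model '", x$id, "'\n", sep = "")
  cat("  reactions:    ", x$n_reactions,
      " (", x$n_exchange, " exchange, ", x$n_reversible, " reversible)\n",
      sep = "")
  cat("  metabolites:  ", x$n_metabolites, " in compartment(s) ",
      paste(x$compartments, collapse = ", "), "\n", sep = "")
  cat("  genes:        ", x$n_genes, "\n", sep = "")
  if (length(x$subsystems))
    cat("  subsystems:   ", paste(x$subsystems, collapse = ", "), "\n",
        sep = "")
  invisible(x)
}
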