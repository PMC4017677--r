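SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

# SBML SIds must match [A-Za-z_][A-Za-z0-9_]*; encode every other byte as
# __<ascii>__ (the COBRA community escaping convention), decode on read.
sid_encode <- function(x) {
  vapply(x, function(s) {
    chars <- strsplit(s, "")[[1]]
    ok <- grepl("[A-Za-z0-9_]", chars)
    chars[!ok] <- vapply(chars[!ok], function(ch)
      sprintf("__%d__", utf8ToInt(ch)), character(1))
    out <- paste(chars, collapse = "")
    if (grepl("^[0-9]", out)) out <- paste0("_", out)
    out
  }, character(1), USE.NAMES = FALSE)
}

sid_decode <- function(x) {
  vapply(x, function(s) {
    while (grepl("__([0-9]+)__", s)) {
      m <- regmatches(s, regexec("__([0-9]+)__", s))[[1]]
      s <- sub(m[1], intToUtf8(as.integer(m[2])), s, fixed = TRUE)
    }
    s
  }, character(1), USE.NAMES = FALSE)
}

xfind <- function(node, name)
  xml2::xml_find_all(node, paste0(".//*[local-name()='", name, "']"))

xfind1 <- function(node, name)
  xml2::xml_find_first(node, paste0(".//*[local-name()='", name, "']"))

# attribute lookup tolerant of namespace prefixes
xattr <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (!is.na(v)) return(v)
  at <- xml2::xml_attrs(node)
  hit <- grep(paste0("(^|:)", name, "$"), names(at))
  if (length(hit)) at[[hit[1]]] else NA_character_
}

#' Read a metabolic model from SBML
#'
#' Supports SBML Level 3 Version 1 with the `fbc` flux-bounds /
#' gene-association package (the primary dialect) and SBML Level 2 with
#' bounds in `kineticLaw` parameters and legacy `GENE_ASSOCIATION` notes.
#' Boundary species (`boundaryCondition="true"`) are removed from the
#' stoichiometry, turning the reactions that touch them into exchange
#' reactions, following the constraint-based convention.  Bounds omitted
#' by the file default to `[-1000, 1000]` for reversible and `[0, 1000]`
#' for irreversible reactions.
#'
#' @param path path to an SBML file.
#' @return a `gem_model`.
#' @export
read_sbml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("malformed SBML in '", path, "': ", conditionMessage(e),
         call. = FALSE))
  model_node <- xfind1(doc, "model")
  if (inherits(model_node, "xml_missing"))
    stop("malformed SBML: no <model> element in '", path, "'")
  model_id <- xattr(model_node, "id")
  if (is.na(model_id)) model_id <- "model"

  sp_nodes <- xfind(model_node, "species")
  if (length(sp_nodes) == 0L) stop("malformed SBML: no species defined")
  sp_id <- vapply(sp_nodes, function(s) xattr(s, "id"), character(1))
  sp_name <- vapply(sp_nodes, function(s) xattr(s, "name"), character(1))
  sp_comp <- vapply(sp_nodes, function(s) xattr(s, "compartment"),
                    character(1))
  sp_bound <- vapply(sp_nodes, function(s) {
    isTRUE(tolower(xattr(s, "boundaryCondition")) == "true")
  }, logical(1))
  mid <- sid_decode(sp_id)
  mname <- ifelse(is.na(sp_name) | !nzchar(sp_name),
                  sub("\\[[^][]*\\]$", "", mid), sp_name)
  mets <- data.frame(id = mid, name = mname,
                     compartment = ifelse(is.na(sp_comp), "c", sp_comp),
                     boundary = sp_bound, stringsAsFactors = FALSE)

  # fbc parameters for flux bounds
  par_nodes <- xfind(model_node, "parameter")
  par_val <- setNames(
    vapply(par_nodes, function(p) as.numeric(xattr(p, "value")), numeric(1)),
    vapply(par_nodes, function(p) xattr(p, "id"), character(1)))

  # fbc gene products: map SBML id -> label (the gene identifier)
  gp_nodes <- xfind(model_node, "geneProduct")
  gp_label <- setNames(
    vapply(gp_nodes, function(g) {
      lab <- xattr(g, "label")
      if (is.na(lab) || !nzchar(lab)) sid_decode(xattr(g, "id")) else lab
    }, character(1)),
    vapply(gp_nodes, function(g) xattr(g, "id"), character(1)))

  assoc_to_rule <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      ref <- xattr(node, "geneProduct")
      g <- if (ref %in% names(gp_label)) gp_label[[ref]] else sid_decode(ref)
      return(g)
    }
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, assoc_to_rule, character(1))
    if (nm == "and") paste0("(", paste(parts, collapse = " and "), ")")
    else if (nm == "or") paste0("(", paste(parts, collapse = " or "), ")")
    else if (length(parts)) parts[1] else ""
  }

  rx_nodes <- xfind(model_node, "reaction")
  if (length(rx_nodes) == 0L) stop("malformed SBML: no reactions defined")
  reactions <- list()
  for (rn in rx_nodes) {
    rid <- sid_decode(xattr(rn, "id"))
    st <- numeric(0)
    for (side in c("listOfReactants", "listOfProducts")) {
      side_node <- xfind1(rn, side)
      if (inherits(side_node, "xml_missing")) next
      sgn <- if (side == "listOfReactants") -1 else 1
      for (sr in xfind(side_node, "speciesReference")) {
        sp <- xattr(sr, "species")
        if (!sp %in% sp_id)
          stop("integrity error: reaction '", rid,
               "' references unknown species '", sp, "'")
        coef <- as.numeric(xattr(sr, "stoichiometry"))
        if (is.na(coef)) coef <- 1
        key <- mid[match(sp, sp_id)]
        st[key] <- (if (key %in% names(st)) st[[key]] else 0) + sgn * coef
      }
    }
    st <- st[st != 0]

    rev_attr <- tolower(xattr(rn, "reversible"))
    reversible <- is.na(rev_attr) || rev_attr == "true"
    lb <- ub <- NA_real_
    lb_ref <- xattr(rn, "lowerFluxBound")
    ub_ref <- xattr(rn, "upperFluxBound")
    if (!is.na(lb_ref) && lb_ref %in% names(par_val)) lb <- par_val[[lb_ref]]
    if (!is.na(ub_ref) && ub_ref %in% names(par_val)) ub <- par_val[[ub_ref]]
    if (is.na(lb) || is.na(ub)) {   # L2: kineticLaw parameters
      for (p in xfind(rn, "parameter")) {
        pid <- toupper(xattr(p, "id"))
        if (pid == "LOWER_BOUND") lb <- as.numeric(xattr(p, "value"))
        if (pid == "UPPER_BOUND") ub <- as.numeric(xattr(p, "value"))
      }
    }
    if (is.na(lb)) lb <- if (reversible) -1000 else 0
    if (is.na(ub)) ub <- 1000

    gpr <- ""
    assoc <- xfind1(rn, "geneProductAssociation")
    if (!inherits(assoc, "xml_missing")) {
      kids <- xml2::xml_children(assoc)
      if (length(kids)) gpr <- assoc_to_rule(kids[[1]])
    }
    subsystem <- ""
    notes <- xfind1(rn, "notes")
    if (!inherits(notes, "xml_missing")) {
      paras <- vapply(xfind(notes, "p"), xml2::xml_text, character(1))
      if (length(paras) == 0L)
        paras <- strsplit(xml2::xml_text(notes), "\n")[[1]]
      for (line in paras) {
        mga <- regmatches(line, regexec("GENE_ASSOCIATION:\\s*(.*)$",
                                        line))[[1]]
        if (!nzchar(gpr) && length(mga) == 2L) gpr <- trimws(mga[2])
        msu <- regmatches(line, regexec("SUBSYSTEM:\\s*(.*)$", line))[[1]]
        if (length(msu) == 2L) subsystem <- trimws(msu[2])
      }
    }
    reactions[[rid]] <- list(stoich = st, lb = lb, ub = ub, gpr = gpr,
                             subsystem = subsystem)
  }

  gem_model(reactions, id = model_id, metabolites = mets,
            boundary = mets$id[mets$boundary])
}

#' Write a metabolic model to SBML Level 3 + fbc
#'
#' Emits SBML Level 3 Version 1 with the `fbc` version 2 package: flux
#' bounds as shared parameters, gene associations as
#' `fbc:geneProductAssociation` trees, subsystems in reaction notes.
#' Boundary species removed at load are re-materialised with
#' `boundaryCondition="true"`, so [read_sbml()] inverts this function.
#'
#' @param model a `gem_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  stopifnot(inherits(model, "gem_model"))
  doc <- xml2::xml_new_root(
    "sbml", xmlns = SBML_CORE_NS, "xmlns:fbc" = SBML_FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mnode <- xml2::xml_add_child(doc, "model", id = sid_encode(model$id),
                               "fbc:strict" = "false")

  comps <- sort(unique(c(model$mets$compartment,
                         model$boundary_mets$compartment)))
  lc <- xml2::xml_add_child(mnode, "listOfCompartments")
  for (cp in comps)
    xml2::xml_add_child(lc, "compartment", id = sid_encode(cp),
                        constant = "true")

  ls <- xml2::xml_add_child(mnode, "listOfSpecies")
  write_species <- function(df, boundary) {
    for (i in seq_len(nrow(df)))
      xml2::xml_add_child(
        ls, "species", id = sid_encode(df$id[i]), name = df$name[i],
        compartment = sid_encode(df$compartment[i]),
        boundaryCondition = if (boundary) "true" else "false",
        hasOnlySubstanceUnits = "false", constant = "false")
  }
  write_species(model$mets, FALSE)
  if (nrow(model$boundary_mets)) write_species(model$boundary_mets, TRUE)

  bounds <- sort(unique(c(model$rxns$lb, model$rxns$ub)))
  par_id <- setNames(sprintf("FB_%d", seq_along(bounds)),
                     sprintf("%.17g", bounds))
  lp <- xml2::xml_add_child(mnode, "listOfParameters")
  for (i in seq_along(bounds))
    xml2::xml_add_child(lp, "parameter", id = par_id[[i]],
                        value = sprintf("%.17g", bounds[i]),
                        constant = "true", sboTerm = "SBO:0000626")

  add_assoc <- function(parent, tree) {
    if (is.character(tree)) {
      xml2::xml_add_child(parent, "fbc:geneProductRef",
                          "fbc:geneProduct" = sid_encode(tree))
    } else {
      node <- xml2::xml_add_child(parent, paste0("fbc:", tree$op))
      for (a in tree$args) add_assoc(node, a)
    }
  }

  lr <- xml2::xml_add_child(mnode, "listOfReactions")
  bl <- model$boundary_links
  for (i in seq_len(nrow(model$rxns))) {
    r <- model$rxns[i, ]
    rnode <- xml2::xml_add_child(
      lr, "reaction", id = sid_encode(r$id),
      reversible = if (r$lb < 0) "true" else "false", fast = "false",
      "fbc:lowerFluxBound" = par_id[[sprintf("%.17g", r$lb)]],
      "fbc:upperFluxBound" = par_id[[sprintf("%.17g", r$ub)]])
    if (nzchar(r$subsystem)) {
      notes <- xml2::xml_add_child(rnode, "notes")
      body <- xml2::xml_add_child(notes, "body",
                                  xmlns = "http://www.w3.org/1999/xhtml")
      xml2::xml_add_child(body, "p", paste0("SUBSYSTEM: ", r$subsystem))
    }
    st <- model$S[, i]
    st <- st[st != 0]
    extra <- bl[bl$rxn == r$id, , drop = FALSE]
    st <- c(st, setNames(extra$coef, extra$met))
    reac <- st[st < 0]; prod <- st[st > 0]
    if (length(reac)) {
      rl <- xml2::xml_add_child(rnode, "listOfReactants")
      for (sp in names(reac))
        xml2::xml_add_child(rl, "speciesReference",
                            species = sid_encode(sp),
                            stoichiometry = sprintf("%.17g", -reac[[sp]]),
                            constant = "true")
    }
    if (length(prod)) {
      pl <- xml2::xml_add_child(rnode, "listOfProducts")
      for (sp in names(prod))
        xml2::xml_add_child(pl, "speciesReference",
                            species = sid_encode(sp),
                            stoichiometry = sprintf("%.17g", prod[[sp]]),
                            constant = "true")
    }
    tree <- model$gpr_trees[[i]]
    if (!is.null(tree)) {
      ga <- xml2::xml_add_child(rnode, "fbc:geneProductAssociation")
      add_assoc(ga, tree)
    }
  }

  if (length(model$genes)) {
    lg <- xml2::xml_add_child(mnode, "fbc:listOfGeneProducts")
    for (g in model$genes)
      xml2::xml_add_child(lg, "fbc:geneProduct", "fbc:id" = sid_encode(g),
                          "fbc:label" = g)
  }

  xml2::write_xml(doc, path)
  invisible(path)
}
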