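#' Read a constraint-based model from SBML or JSON
#'
#' Supports SBML Level 3 with the `fbc` (flux balance constraints) package,
#' and the COBRA-style JSON schema. Format is inferred from the file
#' extension unless given. Reaction bounds are resolved from `fbc`
#' bound-parameter references; subsystem and gene-association annotations
#' are taken from `fbc:geneProductAssociation` / COBRA-style notes fields
#' when present.
#'
#' @param path file path.
#' @param format `"sbml"`, `"json"`, or `NULL` to infer from the extension
#'   (`.xml`/`.sbml` vs `.json`).
#' @return a validated `gem`.
#' @export
read_gem <- function(path, format = NULL) {
  if (!file.exists(path)) stop("model file not found: ", path)
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     xml = , sbml = "sbml",
                     json = "json",
                     stop("cannot infer model format from extension of ", path))
  }
  format <- match.arg(format, c("sbml", "json"))
  m <- switch(format, sbml = read_gem_sbml(path), json = read_gem_json(path))
  validate_gem(m)
  m
}

#' Write a model to SBML or JSON
#'
#' Round-trip counterpart of [read_gem()]: a written model re-read through
#' `read_gem` reproduces stoichiometric coefficients and bounds exactly
#' (numbers are serialized with enough digits to round-trip the doubles).
#'
#' @param model a `gem`.
#' @param path output path.
#' @param format `"sbml"`, `"json"`, or `NULL` to infer from the extension.
#' @return `path`, invisibly.
#' @export
write_gem <- function(model, path, format = NULL) {
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     xml = , sbml = "sbml",
                     json = "json",
                     stop("cannot infer model format from extension of ", path))
  }
  format <- match.arg(format, c("sbml", "json"))
  switch(format,
         sbml = write_gem_sbml(model, path),
         json = write_gem_json(model, path))
  invisible(path)
}

## ---- COBRA-style JSON ----

read_gem_json <- function(path) {
  doc <- jsonlite::read_json(path)
  mets <- data.frame(
    id = vapply(doc$metabolites, function(x) x$id, ""),
    name = vapply(doc$metabolites, function(x) x$name %||% "", ""),
    formula = vapply(doc$metabolites, function(x) x$formula %||% "", ""),
    charge = vapply(doc$metabolites, function(x) as.integer(x$charge %||% 0L), 0L),
    compartment = vapply(doc$metabolites, function(x) x$compartment %||% "", ""),
    stringsAsFactors = FALSE)
  reactions <- lapply(doc$reactions, function(r) {
    st <- unlist(r$metabolites)
    miss <- setdiff(names(st), mets$id)
    if (length(miss)) {
      stop("reaction ", r$id, " references undeclared metabolite(s): ",
           paste(miss, collapse = ", "))
    }
    list(id = r$id, name = r$name %||% "", mets = st,
         lb = r$lower_bound %||% -1000, ub = r$upper_bound %||% 1000,
         subsystem = r$subsystem %||% "",
         gene_association = r$gene_reaction_rule %||% "",
         objective_coef = r$objective_coefficient %||% 0)
  })
  comps <- names(doc$compartments %||% list())
  m <- gem_from_reactions(doc$id %||% basename(path), reactions, mets = mets)
  if (length(comps)) m$compartments <- comps
  m
}

write_gem_json <- function(model, path) {
  mets <- lapply(seq_len(nrow(model$mets)), function(i) {
    r <- model$mets[i, ]
    list(id = r$id, name = r$name, compartment = r$compartment,
         formula = r$formula, charge = r$charge)
  })
  rxns <- lapply(seq_len(nrow(model$rxns)), function(j) {
    col <- model$S[, j]
    nz <- which(col != 0)
    st <- as.list(col[nz])
    names(st) <- model$mets$id[nz]
    r <- model$rxns[j, ]
    list(id = r$id, name = r$name, metabolites = st,
         lower_bound = r$lb, upper_bound = r$ub,
         gene_reaction_rule = r$gene_association,
         subsystem = r$subsystem,
         objective_coefficient = r$objective_coef)
  })
  comps <- as.list(stats::setNames(model$compartments, model$compartments))
  doc <- list(id = model$id, metabolites = mets, reactions = rxns,
              compartments = comps, version = "1")
  # I(17) = 17 significant digits: doubles survive the round trip exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
}

## ---- SBML Level 3 + FBC v2 ----

SBML_NS <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
             fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")

read_gem_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("unparsable SBML file ", path,
                                           ": ", conditionMessage(e)))
  mdl <- xml2::xml_find_first(doc, ".//s:model", SBML_NS)
  if (inherits(mdl, "xml_missing")) stop("no <model> element in ", path)

  att <- function(node, name) xml2::xml_attr(node, name)
  num_attr <- function(node, name, default = NA_real_) {
    v <- att(node, name)
    if (is.na(v)) default else as.numeric(v)
  }

  params <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", SBML_NS)
  pvals <- stats::setNames(vapply(params, num_attr, 0, name = "value"),
                           vapply(params, att, "", name = "id"))

  sp <- xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", SBML_NS)
  if (!length(sp)) stop("SBML model declares no species")
  mets <- data.frame(
    id = vapply(sp, att, "", name = "id"),
    name = vapply(sp, function(n) att(n, "name") %|na|% "", ""),
    formula = vapply(sp, function(n) {
      xml2::xml_attr(n, "fbc:chemicalFormula", SBML_NS) %|na|% ""
    }, ""),
    charge = vapply(sp, function(n) {
      as.integer(xml2::xml_attr(n, "fbc:charge", SBML_NS) %|na|% "0")
    }, 0L),
    compartment = vapply(sp, function(n) att(n, "compartment") %|na|% "", ""),
    stringsAsFactors = FALSE)

  obj_coefs <- list()
  active <- xml2::xml_attr(
    xml2::xml_find_first(mdl, ".//fbc:listOfObjectives", SBML_NS),
    "fbc:activeObjective", SBML_NS)
  objs <- xml2::xml_find_all(mdl, ".//fbc:listOfObjectives/fbc:objective", SBML_NS)
  for (o in objs) {
    oid <- xml2::xml_attr(o, "fbc:id", SBML_NS)
    if (!is.na(active) && length(objs) > 1 && !identical(oid, active)) next
    fos <- xml2::xml_find_all(o, ".//fbc:fluxObjective", SBML_NS)
    for (fo in fos) {
      obj_coefs[[xml2::xml_attr(fo, "fbc:reaction", SBML_NS)]] <-
        as.numeric(xml2::xml_attr(fo, "fbc:coefficient", SBML_NS))
    }
  }

  rx <- xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", SBML_NS)
  reactions <- lapply(rx, function(n) {
    rid <- att(n, "id")
    refs <- function(xp, sgn) {
      nodes <- xml2::xml_find_all(n, xp, SBML_NS)
      st <- sgn * vapply(nodes, num_attr, 0, name = "stoichiometry",
                         default = 1)
      names(st) <- vapply(nodes, att, "", name = "species")
      st
    }
    st <- c(refs("./s:listOfReactants/s:speciesReference", -1),
            refs("./s:listOfProducts/s:speciesReference", 1))
    st <- tapply(st, names(st), sum)   # merge duplicate species refs
    miss <- setdiff(names(st), mets$id)
    if (length(miss)) {
      stop("reaction ", rid, " references undeclared metabolite(s): ",
           paste(miss, collapse = ", "))
    }
    lbref <- xml2::xml_attr(n, "fbc:lowerFluxBound", SBML_NS)
    ubref <- xml2::xml_attr(n, "fbc:upperFluxBound", SBML_NS)
    rev <- identical(att(n, "reversible"), "true")
    lb <- if (!is.na(lbref) && lbref %in% names(pvals)) pvals[[lbref]]
          else if (rev) -1000 else 0
    ub <- if (!is.na(ubref) && ubref %in% names(pvals)) pvals[[ubref]] else 1000
    gpa <- xml2::xml_find_first(n, ".//fbc:geneProductAssociation", SBML_NS)
    gene <- if (inherits(gpa, "xml_missing")) "" else gpr_text(gpa)
    notes <- vapply(
      xml2::xml_find_all(n, "./s:notes//*[local-name()='p']", SBML_NS),
      xml2::xml_text, character(1))
    subsystem <- notes_field(notes, "SUBSYSTEM")
    if (!nzchar(gene)) gene <- notes_field(notes, "GENE_ASSOCIATION")
    list(id = rid, name = att(n, "name") %|na|% "",
         mets = stats::setNames(as.numeric(st), names(st)),
         lb = lb, ub = ub, subsystem = subsystem, gene_association = gene,
         objective_coef = obj_coefs[[rid]] %||% 0)
  })

  comps <- vapply(
    xml2::xml_find_all(mdl, ".//s:listOfCompartments/s:compartment", SBML_NS),
    att, "", name = "id")
  m <- gem_from_reactions(att(mdl, "id") %|na|% basename(path),
                          reactions, mets = mets)
  if (length(comps)) m$compartments <- comps
  m
}

# flatten an fbc gene-product association subtree to boolean text
gpr_text <- function(node) {
  nm <- xml2::xml_name(node)
  kids <- xml2::xml_children(node)
  if (nm == "geneProductRef") return(xml2::xml_attr(node, "fbc:geneProduct"))
  parts <- vapply(kids, gpr_text, character(1))
  parts <- parts[nzchar(parts)]
  if (nm == "and") return(paste0("(", paste(parts, collapse = " and "), ")"))
  if (nm == "or") return(paste0("(", paste(parts, collapse = " or "), ")"))
  paste(parts, collapse = " ")
}

# notes is a character vector of <p> texts like "SUBSYSTEM: Glycolysis"
notes_field <- function(notes, key) {
  hit <- grep(paste0("^\\s*", key, "\\s*:"), notes, value = TRUE)
  if (!length(hit)) return("")
  trimws(sub(paste0("^\\s*", key, "\\s*:\\s*"), "", hit[1]))
}

write_gem_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  # one shared parameter per distinct bound value
  bvals <- sort(unique(c(model$rxns$lb, model$rxns$ub)))
  pid <- stats::setNames(sprintf("bnd_%d", seq_along(bvals)), fmt_num(bvals))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="', SBML_NS[["s"]], '" xmlns:fbc="', SBML_NS[["fbc"]],
           '" level="3" version="1" fbc:required="false">'),
    sprintf('  <model id="%s" fbc:strict="true">', esc(model$id)),
    '    <listOfCompartments>',
    sprintf('      <compartment id="%s" constant="true"/>',
            esc(model$compartments)),
    '    </listOfCompartments>',
    '    <listOfParameters>',
    sprintf('      <parameter id="%s" value="%s" constant="true"/>',
            pid, names(pid)),
    '    </listOfParameters>',
    '    <listOfSpecies>',
    sprintf(paste0('      <species id="%s" name="%s" compartment="%s"',
                   ' hasOnlySubstanceUnits="false" boundaryCondition="false"',
                   ' constant="false" fbc:charge="%d" fbc:chemicalFormula="%s"/>'),
            esc(model$mets$id), esc(model$mets$name),
            esc(model$mets$compartment), model$mets$charge,
            esc(model$mets$formula)),
    '    </listOfSpecies>',
    '    <listOfReactions>')
  for (j in seq_len(nrow(model$rxns))) {
    r <- model$rxns[j, ]
    col <- model$S[, j]
    nz <- which(col != 0)
    ref <- function(idx) {
      sprintf(paste0('          <speciesReference species="%s"',
                     ' stoichiometry="%s" constant="true"/>'),
              esc(model$mets$id[idx]), fmt_num(abs(col[idx])))
    }
    lines <- c(lines, sprintf(
      paste0('      <reaction id="%s" name="%s" reversible="%s" fast="false"',
             ' fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">'),
      esc(r$id), esc(r$name), if (r$lb < 0) "true" else "false",
      pid[[fmt_num(r$lb)]], pid[[fmt_num(r$ub)]]))
    if (nzchar(r$subsystem) || nzchar(r$gene_association)) {
      lines <- c(lines,
        '        <notes><body xmlns="http://www.w3.org/1999/xhtml">',
        if (nzchar(r$subsystem))
          sprintf('          <p>SUBSYSTEM: %s</p>', esc(r$subsystem)),
        if (nzchar(r$gene_association))
          sprintf('          <p>GENE_ASSOCIATION: %s</p>',
                  esc(r$gene_association)),
        '        </body></notes>')
    }
    if (any(col[nz] < 0)) {
      lines <- c(lines, '        <listOfReactants>',
                 ref(nz[col[nz] < 0]), '        </listOfReactants>')
    }
    if (any(col[nz] > 0)) {
      lines <- c(lines, '        <listOfProducts>',
                 ref(nz[col[nz] > 0]), '        </listOfProducts>')
    }
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>')
  objs <- which(model$rxns$objective_coef != 0)
  if (length(objs)) {
    lines <- c(lines,
      '    <fbc:listOfObjectives fbc:activeObjective="obj">',
      '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
      '        <fbc:listOfFluxObjectives>',
      sprintf(paste0('          <fbc:fluxObjective fbc:reaction="%s"',
                     ' fbc:coefficient="%s"/>'),
              esc(model$rxns$id[objs]),
              fmt_num(model$rxns$objective_coef[objs])),
      '        </fbc:listOfFluxObjectives>',
      '      </fbc:objective>',
      '    </fbc:listOfObjectives>')
  }
  lines <- c(lines, '  </model>', '</sbml>')
  writeLines(lines, path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
`%|na|%` <- function(a, b) if (length(a) != 1 || is.na(a)) b else a
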