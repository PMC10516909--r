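#' Construct a constraint-based metabolic model
#'
#' A `gem` object holds the stoichiometric matrix `S` (metabolites x
#' reactions, sparse), per-metabolite annotations, per-reaction bounds in
#' mmol gDW^-1 h^-1, subsystem and gene-association annotations, and the
#' objective coefficients. It is the container every other function in the
#' package operates on.
#'
#' @param id model identifier.
#' @param mets data.frame with columns `id`, `name`, `formula`, `charge`,
#'   `compartment`; one row per metabolite.
#' @param rxns data.frame with columns `id`, `name`, `lb`, `ub`, `subsystem`,
#'   `gene_association`, `objective_coef`; one row per reaction.
#' @param S stoichiometric matrix, `nrow(mets)` x `nrow(rxns)`, dense or
#'   sparse; coerced to a sparse `Matrix`. Row/column order must match
#'   `mets`/`rxns`.
#' @param compartments character vector of compartment ids; defaults to the
#'   distinct compartments seen in `mets`.
#' @return an object of class `gem`.
#' @export
gem <- function(id, mets, rxns, S, compartments = NULL) {
  mets <- as.data.frame(mets, stringsAsFactors = FALSE)
  rxns <- as.data.frame(rxns, stringsAsFactors = FALSE)
  for (col in c("name", "formula", "compartment")) {
    if (is.null(mets[[col]])) mets[[col]] <- ""
  }
  if (is.null(mets$charge)) mets$charge <- 0L
  for (col in c("name", "subsystem", "gene_association")) {
    if (is.null(rxns[[col]])) rxns[[col]] <- ""
  }
  if (is.null(rxns$objective_coef)) rxns$objective_coef <- 0
  S <- Matrix::Matrix(S, sparse = TRUE)
  dimnames(S) <- list(mets$id, rxns$id)
  if (is.null(compartments)) {
    compartments <- unique(mets$compartment[nzchar(mets$compartment)])
  }
  m <- structure(
    list(id = id, mets = mets, rxns = rxns, S = S,
         compartments = compartments),
    class = "gem")
  validate_gem(m)
  m
}

#' Validate a metabolic model's structural invariants
#'
#' Checks that ids are unique, the stoichiometric matrix has dimensions
#' |metabolites| x |reactions|, every reaction references only declared
#' metabolites (implied by the matrix dimnames) and `lb <= ub` for every
#' reaction. Called by [gem()] and the model readers.
#'
#' @param m a `gem` object.
#' @return `m`, invisibly, if valid; otherwise an error.
#' @export
validate_gem <- function(m) {
  stopifnot(inherits(m, "gem"))
  if (anyDuplicated(m$mets$id)) {
    stop("duplicate metabolite ids: ",
         paste(unique(m$mets$id[duplicated(m$mets$id)]), collapse = ", "))
  }
  if (anyDuplicated(m$rxns$id)) {
    stop("duplicate reaction ids: ",
         paste(unique(m$rxns$id[duplicated(m$rxns$id)]), collapse = ", "))
  }
  if (nrow(m$S) != nrow(m$mets) || ncol(m$S) != nrow(m$rxns)) {
    stop("stoichiometric matrix is ", nrow(m$S), " x ", ncol(m$S),
         " but model declares ", nrow(m$mets), " metabolites and ",
         nrow(m$rxns), " reactions")
  }
  bad <- which(m$rxns$lb > m$rxns$ub)
  if (length(bad)) {
    stop("lower bound exceeds upper bound for reaction(s): ",
         paste(m$rxns$id[bad], collapse = ", "))
  }
  invisible(m)
}

#' Build a model from a list of reaction descriptions
#'
#' Convenience constructor used by the readers and the toy-fixture
#' generators: each reaction is a list with an id, a named stoichiometry
#' vector (metabolite id -> coefficient; negative = consumed), bounds and
#' optional annotations. Metabolites are declared implicitly by their first
#' appearance unless `mets` supplies annotations.
#'
#' @param id model identifier.
#' @param reactions list of lists with elements `id`, `mets` (named numeric),
#'   `lb`, `ub`, and optionally `name`, `subsystem`, `gene_association`,
#'   `objective_coef`.
#' @param mets optional metabolite annotation data.frame (see [gem()]).
#' @return a `gem` object.
#' @export
gem_from_reactions <- function(id, reactions, mets = NULL) {
  rxn_ids <- vapply(reactions, `[[`, character(1), "id")
  met_ids <- unique(unlist(lapply(reactions, function(r) names(r$mets))))
  if (!is.null(mets)) {
    missing <- setdiff(met_ids, mets$id)
    if (length(missing)) {
      stop("reaction references undeclared metabolite(s): ",
           paste(missing, collapse = ", "))
    }
    met_ids <- mets$id
  }
  grab <- function(field, default) {
    vapply(reactions, function(r) {
      v <- r[[field]]
      if (is.null(v)) default else v
    }, FUN.VALUE = default)
  }
  rxns <- data.frame(
    id = rxn_ids,
    name = grab("name", ""),
    lb = grab("lb", -1000),
    ub = grab("ub", 1000),
    subsystem = grab("subsystem", ""),
    gene_association = grab("gene_association", ""),
    objective_coef = grab("objective_coef", 0),
    stringsAsFactors = FALSE)
  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (k in seq_along(reactions)) {
    st <- reactions[[k]]$mets
    idx <- match(names(st), met_ids)
    i <- c(i, idx); j <- c(j, rep.int(k, length(st))); x <- c(x, unname(st))
  }
  S <- Matrix::sparseMatrix(i = i, j = j, x = x,
                            dims = c(length(met_ids), length(reactions)))
  if (is.null(mets)) {
    mets <- data.frame(id = met_ids, name = met_ids, formula = "",
                       charge = 0L, compartment = "c",
                       stringsAsFactors = FALSE)
  }
  gem(id, mets, rxns, S)
}

#' @export
print.gem <- function(x, ...) {
  cat("<gem> ", x$id, ": ", nrow(x$mets), " metabolites, ",
      nrow(x$rxns), " reactions, ", length(x$compartments),
      " compartment(s)\n", sep = "")
  obj <- x$rxns$id[x$rxns$objective_coef != 0]
  if (length(obj)) cat("  objective:", paste(obj, collapse = " + "), "\n")
  invisible(x)
}

#' Human-readable reaction equation
#'
#' Renders a reaction's stoichiometry as e.g. `"A + 2 B --> C"`, with
#' `"<=>"` for reversible reactions (negative lower bound). This is the text
#' stored in the report tables' `Var10` column.
#'
#' @param m a `gem`.
#' @param reaction_id reaction id.
#' @return a single string.
#' @export
reaction_equation <- function(m, reaction_id) {
  j <- match_reaction(m, reaction_id)
  col <- m$S[, j]
  nz <- which(col != 0)
  side <- function(idx, sgn) {
    if (!length(idx)) return("")
    coefs <- abs(col[idx])
    paste(ifelse(coefs == 1, m$mets$id[idx],
                 paste(fmt_num(coefs), m$mets$id[idx])),
          collapse = " + ")
  }
  lhs <- side(nz[col[nz] < 0])
  rhs <- side(nz[col[nz] > 0])
  arrow <- if (m$rxns$lb[j] < 0) "<=>" else "-->"
  paste(lhs, arrow, rhs)
}

match_reaction <- function(m, reaction_id) {
  j <- match(reaction_id, m$rxns$id)
  if (is.na(j)) stop("unknown reaction id: ", reaction_id)
  j
}

#' Convert wet cell weight to dry cell weight
#'
#' Empirical gravimetric conversion for yeast biomass samples:
#' DCW = 0.3 x WCW.
#'
#' @param wcw wet cell weight in g L^-1 (non-negative, vectorised).
#' @return dry cell weight in g L^-1.
#' @examples
#' dcw_from_wcw(10)   # 3
#' @export
dcw_from_wcw <- function(wcw) {
  if (any(wcw < 0)) stop("wet cell weight must be non-negative")
  0.3 * wcw
}

# shortest decimal representation that round-trips the double exactly
fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    s <- format(v, digits = 15, scientific = FALSE)
    if (as.numeric(s) == v) return(s)
    sprintf("%.17g", v)
  }, character(1))
}
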