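# In-memory representation of a metabolic network: stoichiometric matrix,
# per-reaction flux bounds and objective coefficients, and gene-reaction
# association rules. Objects are value-semantic: manipulation functions
# return modified copies; mutable state lives only in the solver layer.

#' MetabolicModel class
#'
#' A constraint-based metabolic network model. Rows of the sparse
#' stoichiometric matrix `S` are metabolites, columns are reactions; a
#' negative coefficient means consumption, positive production. Flux bounds
#' are in mmol/gDW/h by convention (numerically unitless). A reaction is
#' reversible exactly when its lower bound is negative; the flag is derived,
#' never stored, so it can never contradict the bounds. The gene list is the
#' union of genes appearing in any GPR rule.
#'
#' @slot model_id short text label.
#' @slot metabolites ordered metabolite identifiers, compartment encoded as a
#'   `[x]` suffix (e.g. `"glc[e]"`).
#' @slot reactions ordered reaction identifiers.
#' @slot S sparse stoichiometric matrix (metabolites x reactions).
#' @slot lower_bound,upper_bound per-reaction flux bounds.
#' @slot objective_coef per-reaction linear objective coefficients.
#' @slot gpr per-reaction parsed [gpr_rule][parse_gpr()] objects.
#' @slot gpr_text per-reaction canonical rule text.
#' @slot genes ordered (sorted) gene identifiers.
#' @slot subsystem per-reaction optional subsystem label.
#' @slot reaction_name,metabolite_name optional display names.
#' @slot extra extra per-reaction columns carried through TSV round-trips.
#' @aliases MetabolicModel
#' @export
setClass("MetabolicModel", slots = c(
  model_id = "character",
  metabolites = "character",
  reactions = "character",
  S = "dgCMatrix",
  lower_bound = "numeric",
  upper_bound = "numeric",
  objective_coef = "numeric",
  gpr = "list",
  gpr_text = "character",
  genes = "character",
  subsystem = "character",
  reaction_name = "character",
  metabolite_name = "character",
  extra = "data.frame"
))

setValidity("MetabolicModel", function(object) {
  n <- length(object@reactions)
  m <- length(object@metabolites)
  msgs <- character(0)
  if (ncol(object@S) != n) msgs <- c(msgs, "ncol(S) != number of reactions")
  if (nrow(object@S) != m) msgs <- c(msgs, "nrow(S) != number of metabolites")
  for (sl in c("lower_bound", "upper_bound", "objective_coef", "gpr", "gpr_text",
               "subsystem", "reaction_name")) {
    if (length(slot(object, sl)) != n) msgs <- c(msgs, paste0("length(", sl, ") != number of reactions"))
  }
  if (length(object@metabolite_name) != m) msgs <- c(msgs, "length(metabolite_name) != number of metabolites")
  if (anyDuplicated(object@reactions)) msgs <- c(msgs, "duplicate reaction identifiers")
  if (anyDuplicated(object@metabolites)) msgs <- c(msgs, "duplicate metabolite identifiers")
  if (any(object@lower_bound > object@upper_bound)) {
    bad <- object@reactions[object@lower_bound > object@upper_bound]
    msgs <- c(msgs, paste0("lower bound exceeds upper bound for: ", paste(bad, collapse = ", ")))
  }
  used <- sort(unique(unlist(lapply(object@gpr, gpr_genes))))
  if (!identical(used, object@genes)) {
    msgs <- c(msgs, "gene list must equal the set of genes referenced by GPR rules")
  }
  if (nrow(object@extra) > 0 && nrow(object@extra) != n) {
    msgs <- c(msgs, "extra column table must have one row per reaction")
  }
  if (length(msgs)) msgs else TRUE
})

as_dgc <- function(S) {
  methods::as(methods::as(methods::as(S, "dMatrix"), "generalMatrix"), "CsparseMatrix")
}

#' Construct a metabolic model
#'
#' Low-level constructor; most users build models through [read_tsv_model()],
#' [add_reaction()] or the fixture generators. GPR rules are parsed and the
#' gene list derived from them; all class invariants are checked.
#'
#' @param model_id short label.
#' @param S stoichiometric matrix (dense or sparse), metabolites x reactions.
#' @param metabolites,reactions identifier vectors matching the dimensions of `S`.
#' @param lower_bound,upper_bound,objective_coef per-reaction numeric vectors
#'   (scalars are recycled). Defaults: bounds `[0, 1000]`, objective `0`.
#' @param gpr character vector of per-reaction GPR rule texts (`""` = none).
#' @param subsystem,reaction_name,metabolite_name optional annotation vectors.
#' @param extra optional data.frame of extra per-reaction columns.
#' @return a [MetabolicModel] object.
#' @examples
#' m <- metabolic_model("toy",
#'   S = matrix(c(-1, 1, 0, 0, -1, 1), nrow = 3),
#'   metabolites = c("a[c]", "b[c]", "c[c]"),
#'   reactions = c("R1", "R2"), gpr = c("g1", ""))
#' reactions(m)
#' @export
metabolic_model <- function(model_id, S, metabolites, reactions,
                            lower_bound = 0, upper_bound = 1000,
                            objective_coef = 0, gpr = "",
                            subsystem = NA_character_,
                            reaction_name = NA_character_,
                            metabolite_name = NA_character_,
                            extra = data.frame()) {
  n <- length(reactions)
  m <- length(metabolites)
  rec <- function(x, len, what) {
    if (length(x) == 1L) x <- rep(x, len)
    if (length(x) != len) fk_dimension_error(paste0(what, " must have length ", len))
    x
  }
  gpr_txt <- as.character(rec(gpr, n, "gpr"))
  gpr_txt[is.na(gpr_txt)] <- ""
  rules <- lapply(gpr_txt, parse_gpr)
  obj <- methods::new("MetabolicModel",
    model_id = as.character(model_id),
    metabolites = as.character(metabolites),
    reactions = as.character(reactions),
    S = as_dgc(Matrix::drop0(
      if (inherits(S, "Matrix")) S
      else if (is.matrix(S)) Matrix::Matrix(S, sparse = TRUE)
      else Matrix::Matrix(S, nrow = m, ncol = n, sparse = TRUE))),
    lower_bound = as.numeric(rec(lower_bound, n, "lower_bound")),
    upper_bound = as.numeric(rec(upper_bound, n, "upper_bound")),
    objective_coef = as.numeric(rec(objective_coef, n, "objective_coef")),
    gpr = rules,
    gpr_text = vapply(rules, unparse_gpr, character(1)),
    genes = sort(unique(unlist(lapply(rules, gpr_genes)))) %||% character(0),
    subsystem = as.character(rec(subsystem, n, "subsystem")),
    reaction_name = as.character(rec(reaction_name, n, "reaction_name")),
    metabolite_name = as.character(rec(metabolite_name, m, "metabolite_name")),
    extra = extra
  )
  obj
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @describeIn metabolic_model reaction identifiers.
#' @param model a [MetabolicModel].
#' @export
reactions <- function(model) model@reactions

#' @describeIn metabolic_model metabolite identifiers.
#' @export
metabolites <- function(model) model@metabolites

#' @describeIn metabolic_model gene identifiers (sorted).
#' @export
model_genes <- function(model) model@genes

#' @describeIn metabolic_model sparse stoichiometric matrix with dimnames.
#' @export
stoichiometry <- function(model) {
  S <- model@S
  dimnames(S) <- list(model@metabolites, model@reactions)
  S
}

#' @describeIn metabolic_model per-reaction reversibility, derived as
#'   `lower_bound < 0`.
#' @export
reversible <- function(model) model@lower_bound < 0

#' @describeIn metabolic_model named per-reaction objective coefficients.
#' @export
objective_coefficients <- function(model) {
  stats::setNames(model@objective_coef, model@reactions)
}

#' @describeIn metabolic_model named per-reaction bounds as a two-column matrix.
#' @export
flux_bounds <- function(model) {
  cbind(lower = stats::setNames(model@lower_bound, model@reactions),
        upper = model@upper_bound)
}

setMethod("show", "MetabolicModel", function(object) {
  cat("MetabolicModel '", object@model_id, "': ",
      length(object@reactions), " reactions, ",
      length(object@metabolites), " metabolites, ",
      length(object@genes), " genes\n", sep = "")
  nz <- length(object@S@x)
  cat("  S: ", nrow(object@S), " x ", ncol(object@S), " (", nz, " nonzeros), ",
      sum(object@lower_bound < 0), " reversible, ",
      sum(object@objective_coef != 0), " objective reaction(s)\n", sep = "")
})

rxn_index <- function(model, rxn_ids) {
  idx <- match(rxn_ids, model@reactions)
  if (anyNA(idx)) {
    fk_lookup_error(paste0("unknown reaction(s): ",
                           paste(rxn_ids[is.na(idx)], collapse = ", ")))
  }
  idx
}
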