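# Manipulation of metabolic models. All functions return a modified copy.

#' Add a reaction to a model
#'
#' Appends a new column to the stoichiometric matrix. Metabolites in `stoich`
#' that are not yet part of the model are appended as new rows; genes in
#' `gpr_text` not yet in the gene list extend it.
#'
#' @param model a [MetabolicModel].
#' @param rxn_id new reaction identifier (must not already exist).
#' @param stoich named numeric vector, metabolite identifier to signed
#'   stoichiometric coefficient.
#' @param lb,ub flux bounds (`lb <= ub`).
#' @param obj objective coefficient (default 0).
#' @param gpr_text GPR rule text (default none).
#' @param subsystem,name optional annotation.
#' @return the extended model.
#' @examples
#' m <- make_chain_model()
#' m2 <- add_reaction(m, "EX_B", c("B[c]" = -1), lb = 0, ub = 1000)
#' length(reactions(m2)) - length(reactions(m))
#' @export
add_reaction <- function(model, rxn_id, stoich, lb = 0, ub = 1000, obj = 0,
                         gpr_text = "", subsystem = NA_character_,
                         name = NA_character_) {
  if (rxn_id %in% model@reactions) {
    fk_identifier_error(paste0("reaction '", rxn_id, "' already exists"))
  }
  if (lb > ub) fk_bound_error(paste0("lb > ub for reaction '", rxn_id, "'"))
  if (!is.numeric(stoich) || is.null(names(stoich)) || any(!nzchar(names(stoich)))) {
    fk_usage_error("stoich must be a named numeric vector")
  }
  rule <- parse_gpr(gpr_text)  # syntax errors propagate before any change

  new_mets <- setdiff(names(stoich), model@metabolites)
  mets <- c(model@metabolites, new_mets)
  S_old <- model@S
  if (length(new_mets)) {
    S_old <- rbind(S_old, Matrix::Matrix(0, length(new_mets), ncol(S_old), sparse = TRUE))
  }
  newcol <- Matrix::sparseMatrix(
    i = match(names(stoich), mets), j = rep(1L, length(stoich)),
    x = as.numeric(stoich), dims = c(length(mets), 1L))
  S_new <- cbind(S_old, newcol)

  extra <- model@extra
  if (nrow(extra) > 0) extra <- rbind(extra, extra[1, , drop = FALSE][NA, , drop = FALSE])

  metabolic_model(
    model_id = model@model_id,
    S = S_new, metabolites = mets, reactions = c(model@reactions, rxn_id),
    lower_bound = c(model@lower_bound, lb),
    upper_bound = c(model@upper_bound, ub),
    objective_coef = c(model@objective_coef, obj),
    gpr = c(model@gpr_text, unparse_gpr(rule)),
    subsystem = c(model@subsystem, subsystem),
    reaction_name = c(model@reaction_name, name),
    metabolite_name = c(model@metabolite_name, rep(NA_character_, length(new_mets))),
    extra = extra
  )
}

#' Change flux bounds of named reactions
#'
#' Only the named reactions are touched; `NULL` leaves the corresponding
#' bound unchanged. Reversibility (derived from the lower bound) follows
#' automatically.
#'
#' @param model a [MetabolicModel].
#' @param rxn_ids reaction identifiers.
#' @param lb,ub new bounds, recycled to `length(rxn_ids)`; `NULL` = keep.
#' @return the modified model.
#' @export
change_bounds <- function(model, rxn_ids, lb = NULL, ub = NULL) {
  if (length(rxn_ids) == 0L) return(model)
  idx <- rxn_index(model, rxn_ids)
  new_lb <- model@lower_bound
  new_ub <- model@upper_bound
  if (!is.null(lb)) new_lb[idx] <- rep_len(as.numeric(lb), length(idx))
  if (!is.null(ub)) new_ub[idx] <- rep_len(as.numeric(ub), length(idx))
  if (any(new_lb[idx] > new_ub[idx])) {
    bad <- rxn_ids[new_lb[idx] > new_ub[idx]]
    fk_bound_error(paste0("lb > ub for reaction(s): ", paste(bad, collapse = ", ")))
  }
  model@lower_bound <- new_lb
  model@upper_bound <- new_ub
  methods::validObject(model)
  model
}

#' Replace the linear objective
#'
#' Sets the objective coefficients to the entries of `coef_map` and all other
#' coefficients to zero.
#'
#' @param model a [MetabolicModel].
#' @param coef_map named numeric vector, reaction id to coefficient. An empty
#'   vector yields the all-zero objective.
#' @return the modified model.
#' @export
change_objective <- function(model, coef_map) {
  obj <- rep(0, length(model@reactions))
  if (length(coef_map)) {
    idx <- rxn_index(model, names(coef_map))
    obj[idx] <- as.numeric(coef_map)
  }
  model@objective_coef <- obj
  model
}

#' Find exchange reactions
#'
#' Exchange (boundary) reactions are exactly those whose stoichiometric
#' column has a single nonzero entry. By the sign convention used throughout
#' (BiGG style), positive flux through an exchange written `"a[e] <==>"` is
#' secretion and negative flux is uptake.
#'
#' @param model a [MetabolicModel].
#' @return character vector of reaction identifiers.
#' @export
find_exchange_reactions <- function(model) {
  nnz <- Matrix::colSums(model@S != 0)
  model@reactions[nnz == 1]
}

#' Set the modelled growth environment via exchange lower bounds
#'
#' Sets the lower bound (maximal uptake, as a negative number) of each listed
#' exchange reaction and *closes* every exchange not listed (`lb = 0`).
#' Closing unlisted exchanges is a deliberate design choice: the resulting
#' environment is exactly the one given, regardless of what was open before.
#' Non-exchange reactions are untouched.
#'
#' @param model a [MetabolicModel].
#' @param uptake_map named numeric vector, exchange reaction id to new lower
#'   bound (e.g. `c(EX_glc = -10)`). May be empty (closes all exchanges).
#' @return the modified model.
#' @export
change_uptake <- function(model, uptake_map) {
  ex <- find_exchange_reactions(model)
  keys <- names(uptake_map) %||% character(0)
  bad <- setdiff(keys, ex)
  if (length(bad)) {
    fk_usage_error(paste0("not exchange reaction(s): ", paste(bad, collapse = ", ")))
  }
  closed <- setdiff(ex, keys)
  if (length(closed)) model <- change_bounds(model, closed, lb = 0)
  if (length(keys)) model <- change_bounds(model, keys, lb = as.numeric(uptake_map))
  model
}

#' Validate a model and report findings
#'
#' Non-throwing structural diagnosis: invariant violations are reported as
#' `error` findings, suspicious but legal structures (dead-end metabolites,
#' unused metabolites, empty reaction columns) as `warning` findings.
#' A dead-end metabolite is one whose row carries entries of only one sign,
#' i.e. it is only ever produced or only ever consumed.
#'
#' @param model a [MetabolicModel].
#' @return a `validation_report`: data.frame with columns `level`, `code`,
#'   `id`, `message`.
#' @export
validate_model <- function(model) {
  out <- list()
  add <- function(level, code, id, msg) {
    out[[length(out) + 1L]] <<- data.frame(level = level, code = code, id = id,
                                           message = msg, stringsAsFactors = FALSE)
  }
  bad <- which(model@lower_bound > model@upper_bound)
  for (j in bad) add("error", "bounds_crossed", model@reactions[j],
                     sprintf("lower bound %g exceeds upper bound %g",
                             model@lower_bound[j], model@upper_bound[j]))
  if (anyDuplicated(model@reactions)) {
    add("error", "duplicate_reaction", model@reactions[duplicated(model@reactions)][1],
        "duplicate reaction identifier")
  }
  if (anyDuplicated(model@metabolites)) {
    add("error", "duplicate_metabolite", model@metabolites[duplicated(model@metabolites)][1],
        "duplicate metabolite identifier")
  }
  used <- sort(unique(unlist(lapply(model@gpr, gpr_genes))))
  for (g in setdiff(model@genes, used)) add("error", "orphan_gene", g,
                                            "gene listed but referenced by no rule")
  for (g in setdiff(used, model@genes)) add("error", "missing_gene", g,
                                            "gene referenced by a rule but not listed")
  S <- model@S
  for (i in seq_along(model@metabolites)) {
    row <- S[i, ]
    nz <- row[row != 0]
    if (length(nz) == 0) {
      add("warning", "unused_metabolite", model@metabolites[i],
          "metabolite participates in no reaction")
    } else if (all(nz > 0) || all(nz < 0)) {
      # exchange-only participation is fine; dead end = internal one-way
      cols <- which(row != 0)
      is_ex <- Matrix::colSums(S[, cols, drop = FALSE] != 0) == 1
      rev_ex <- model@lower_bound[cols] < 0
      if (!any(is_ex & rev_ex)) {
        add("warning", "dead_end", model@metabolites[i],
            if (all(nz > 0)) "metabolite is only produced" else "metabolite is only consumed")
      }
    }
  }
  empty <- which(Matrix::colSums(S != 0) == 0)
  for (j in empty) add("warning", "empty_reaction", model@reactions[j],
                       "reaction has an all-zero stoichiometric column")
  rep <- if (length(out)) do.call(rbind, out) else
    data.frame(level = character(0), code = character(0), id = character(0),
               message = character(0), stringsAsFactors = FALSE)
  class(rep) <- c("validation_report", "data.frame")
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("validation: no findings\n")
  } else {
    cat("validation:", sum(x$level == "error"), "error(s),",
        sum(x$level == "warning"), "warning(s)\n")
    NextMethod()
  }
  invisible(x)
}
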