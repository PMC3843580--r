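# High-level batch analyses. Each analysis builds its optimisation problem
# once, then loops over perturbations by editing the shared handle in place
# (knockout = pin variable bounds to zero; FVA = swap the objective;
# robustness / phase plane = pin a flux), restoring the handle after every
# solve. Results equal a fresh build per perturbation; the shared handle only
# makes the loop cheap.

ko_set_label <- function(set) paste(set, collapse = "+")

apply_ko <- function(handle, vars) {
  old <- get_var_bounds(handle, vars)
  set_var_bounds(handle, vars, 0, 0)
  old
}

restore_ko <- function(handle, vars, old) {
  set_var_bounds(handle, vars, old[, "lower"], old[, "upper"])
}

deletion_loop <- function(model, sets, algorithm, backend, lethal_fraction,
                          affected_fun, ...) {
  alg <- get_algorithm(algorithm)
  wt_flux <- NULL
  if (alg$needs_reference) {
    wt_sol <- optimize_problem(build_mtf(model, backend = backend))
    if (wt_sol$status != "optimal") {
      fk_usage_error(paste0("wild-type reference solve failed: ", wt_sol$status))
    }
    wt_flux <- wt_sol$fluxes
  }
  prob <- alg$builder(model, wt_flux = wt_flux, backend = backend, ...)
  # mtf needs its optimum row re-pinned to the knockout's own FBA optimum
  fba_prob <- if (algorithm == "mtf") build_fba(model, backend = backend) else NULL

  wt <- optimize_problem(prob)
  rows <- vector("list", length(sets))
  for (k in seq_along(sets)) {
    set <- sets[[k]]
    aff <- affected_fun(set)
    idx <- match(aff, model@reactions)
    vars <- if (length(idx)) unlist(lapply(idx, prob$ko_vars)) else integer(0)
    old <- if (length(vars)) apply_ko(prob$handle, vars) else NULL
    skip <- FALSE
    if (!is.null(fba_prob)) {
      fvars <- idx
      fold <- if (length(fvars)) apply_ko(fba_prob$handle, fvars) else NULL
      fsol <- solve_problem(fba_prob$handle)
      if (length(fvars)) restore_ko(fba_prob$handle, fvars, fold)
      if (fsol$status == "optimal") {
        set_row_limits(prob$handle, prob$opt_row,
                       fsol$objective - mtf_epsilon(fsol$objective), Inf)
      } else {
        sol <- structure(list(algorithm = "mtf", status = fsol$status,
                              objective = NA_real_, fluxes = NULL,
                              biomass = NA_real_), class = "opt_solution")
        skip <- TRUE
      }
    }
    if (!skip) sol <- optimize_problem(prob)
    if (length(vars)) restore_ko(prob$handle, vars, old)
    lethal <- (sol$status == "optimal" &&
                 sol$biomass < lethal_fraction * wt$biomass) ||
              sol$status == "infeasible"
    rows[[k]] <- data.frame(
      set = ko_set_label(set), status = sol$status,
      objective = sol$objective, biomass = sol$biomass,
      affected = paste(aff, collapse = ";"), lethal = lethal,
      stringsAsFactors = FALSE)
  }
  if (!is.null(fba_prob)) {
    set_row_limits(prob$handle, prob$opt_row,
                   prob$extras$z_opt - mtf_epsilon(prob$extras$z_opt), Inf)
  }
  structure(list(algorithm = algorithm,
                 wild_type = list(status = wt$status, objective = wt$objective,
                                  biomass = wt$biomass),
                 lethal_fraction = lethal_fraction,
                 results = do.call(rbind, rows),
                 problem = prob),
            class = "deletion_result")
}

#' Simulate all k-wise gene deletions
#'
#' Enumerates every combination of `combinations` genes (lexicographically
#' over sorted gene identifiers), maps each gene set to the reactions its
#' loss disables via the GPR rules, pins those reactions to zero flux on the
#' shared problem handle, solves with the chosen algorithm, and restores the
#' handle. A knockout is flagged lethal when its biomass value drops below
#' `lethal_fraction` of the wild type (or the problem becomes infeasible).
#' No lethal-subset pruning is performed: a pair containing a lethal single
#' knockout is still solved, for exact parity with exhaustive enumeration.
#'
#' For MOMA / linear MOMA / ROOM the wild-type reference flux distribution is
#' computed once (minimal-total-flux) and reused for all knockout sets.
#'
#' @param model a [MetabolicModel].
#' @param combinations number of genes deleted simultaneously (1 = single
#'   knockouts, 2 = all pairs, ...).
#' @param algorithm registered algorithm name: `"fba"` (default), `"mtf"`,
#'   `"moma"`, `"lmoma"` or `"room"`.
#' @param gene_subset optional subset of genes to screen.
#' @param lethal_fraction biomass fraction of wild type below which a
#'   knockout counts as lethal (default 0.01).
#' @param backend a solver backend.
#' @param ... passed to the algorithm builder (e.g. `delta` for ROOM).
#' @return a `deletion_result`: wild-type record plus one row per gene set
#'   with `set`, `status`, `objective`, `biomass`, `affected`, `lethal`.
#' @examples
#' del <- gene_deletion(make_chain_model(), combinations = 2)
#' del$results$lethal  # the pair g1+g2 is lethal
#' @export
gene_deletion <- function(model, combinations = 1, algorithm = "fba",
                          gene_subset = NULL, lethal_fraction = 0.01,
                          backend = reference_backend(), ...) {
  genes <- sort(if (is.null(gene_subset)) model@genes else unique(gene_subset))
  combinations <- as.integer(combinations)
  if (combinations < 1) fk_usage_error("combinations must be >= 1")
  if (combinations > length(genes)) {
    fk_usage_error(sprintf("combinations (%d) exceeds gene count (%d)",
                           combinations, length(genes)))
  }
  cmb <- utils::combn(genes, combinations, simplify = FALSE)
  res <- deletion_loop(model, cmb, algorithm, backend, lethal_fraction,
                       affected_fun = function(set)
                         suppressMessages(affected_reactions(model, set)), ...)
  res$combinations <- combinations
  res$unit <- "genes"
  res
}

#' Simulate deletions of reactions (flux knockouts)
#'
#' Like [gene_deletion()] but pinning named reaction columns to zero flux
#' directly, bypassing the GPR layer. A plain character vector is treated as
#' the list of all single-reaction deletions.
#'
#' @param model a [MetabolicModel].
#' @param reaction_sets list of reaction-id tuples, or a character vector of
#'   single reactions; `NULL` = all single-reaction deletions.
#' @inheritParams gene_deletion
#' @return a `deletion_result`.
#' @export
flux_deletion <- function(model, reaction_sets = NULL, algorithm = "fba",
                          lethal_fraction = 0.01,
                          backend = reference_backend(), ...) {
  if (is.null(reaction_sets)) reaction_sets <- model@reactions
  if (is.character(reaction_sets)) reaction_sets <- as.list(reaction_sets)
  for (set in reaction_sets) rxn_index(model, set)  # fail fast on unknown ids
  res <- deletion_loop(model, reaction_sets, algorithm, backend, lethal_fraction,
                       affected_fun = function(set) set, ...)
  res$unit <- "reactions"
  res
}

#' Flux variability analysis
#'
#' Computes, for each reaction, the minimal and maximal flux compatible with
#' the model objective being held at at least `gamma` times its optimum:
#' first an FBA solve fixes `z_opt`, then the constraint
#' `objective_coef . v >= gamma * z_opt - eps` is added and the handle's
#' objective is swapped to each reaction in turn (one minimisation, one
#' maximisation per reaction on the same handle).
#'
#' @param model a [MetabolicModel].
#' @param gamma fraction of the optimum to hold, in `(0, 1]` (default 1).
#' @param reactions optional subset of reaction ids (default all).
#' @param backend a solver backend.
#' @return an `fva_result`: list with `gamma`, `wt_objective`, `wt_status`
#'   and `results` (data.frame `reaction`, `min`, `max`).
#' @export
flux_variability <- function(model, gamma = 1.0, reactions = NULL,
                             backend = reference_backend()) {
  if (!is.numeric(gamma) || gamma <= 0 || gamma > 1) {
    fk_usage_error("gamma must lie in (0, 1]")
  }
  rxns <- if (is.null(reactions)) model@reactions else
    model@reactions[rxn_index(model, reactions)]
  fsol <- solve_problem(build_fba(model, backend)$handle)
  if (fsol$status != "optimal") {
    return(structure(list(gamma = gamma, wt_objective = NA_real_,
                          wt_status = fsol$status,
                          results = data.frame(reaction = character(0),
                                               min = numeric(0), max = numeric(0))),
                     class = "fva_result"))
  }
  z <- fsol$objective
  n <- length(model@reactions)
  tr <- model_row_triplets(model)
  nzc <- which(model@objective_coef != 0)
  eps <- 1e-6 * max(1, abs(z))
  spec <- problem_spec(
    n_vars = n, lb = model@lower_bound, ub = model@upper_bound,
    obj = model@objective_coef, sense = "max",
    row_i = c(tr$i, rep(tr$m + 1L, length(nzc))),
    row_j = c(tr$j, nzc),
    row_v = c(tr$v, model@objective_coef[nzc]),
    row_lb = c(rep(0, tr$m), gamma * z - eps),
    row_ub = c(rep(0, tr$m), Inf))
  h <- build_problem(spec, backend)
  idx <- match(rxns, model@reactions)
  lo <- hi <- numeric(length(idx))
  for (k in seq_along(idx)) {
    e <- replace(numeric(n), idx[k], 1)
    set_objective(h, e, "min")
    smin <- solve_problem(h)
    set_objective(h, e, "max")
    smax <- solve_problem(h)
    lo[k] <- if (smin$status == "optimal") smin$objective else NA_real_
    hi[k] <- if (smax$status == "optimal") smax$objective else NA_real_
  }
  set_objective(h, model@objective_coef, "max")
  structure(list(gamma = gamma, wt_objective = z, wt_status = "optimal",
                 results = data.frame(reaction = rxns, min = lo, max = hi,
                                      stringsAsFactors = FALSE)),
            class = "fva_result")
}

#' Robustness analysis
#'
#' Scans a control reaction over a range of pinned flux values and records
#' the FBA optimum at each point; infeasible points are recorded with an
#' absent (`NA`) objective and the scan continues.
#'
#' @param model a [MetabolicModel].
#' @param control_rxn reaction whose flux is pinned.
#' @param n_points number of equally spaced points (>= 2, default 20).
#' @param flux_range optional `c(lo, hi)`; defaults to the control reaction's
#'   bounds.
#' @param backend a solver backend.
#' @return a `robustness_result` data.frame with columns `flux`, `objective`,
#'   `status`; the control reaction id and wild-type optimum are attached as
#'   attributes.
#' @export
robustness <- function(model, control_rxn, n_points = 20, flux_range = NULL,
                       backend = reference_backend()) {
  j <- rxn_index(model, control_rxn)
  n_points <- as.integer(n_points)
  if (n_points < 2) fk_usage_error("n_points must be >= 2")
  if (is.null(flux_range)) flux_range <- c(model@lower_bound[j], model@upper_bound[j])
  if (length(flux_range) != 2 || flux_range[1] > flux_range[2]) {
    fk_usage_error("flux_range must be c(lo, hi) with lo <= hi")
  }
  prob <- build_fba(model, backend)
  pts <- seq(flux_range[1], flux_range[2], length.out = n_points)
  obj <- rep(NA_real_, n_points)
  status <- character(n_points)
  old <- get_var_bounds(prob$handle, j)
  for (k in seq_along(pts)) {
    set_var_bounds(prob$handle, j, pts[k], pts[k])
    sol <- solve_problem(prob$handle)
    status[k] <- sol$status
    if (sol$status == "optimal") obj[k] <- sol$objective
  }
  set_var_bounds(prob$handle, j, old[, "lower"], old[, "upper"])
  out <- data.frame(flux = pts, objective = obj, status = status,
                    stringsAsFactors = FALSE)
  attr(out, "control_rxn") <- control_rxn
  class(out) <- c("robustness_result", "data.frame")
  out
}

#' Phenotypic phase plane analysis
#'
#' Pins the fluxes of two control reactions to every point of a grid, solves
#' FBA, and records the optimum together with the two control-constraint
#' shadow prices (dual values). Points with the same dual pair (after
#' rounding at 1e-6) belong to the same metabolic phase; the phase label
#' changes exactly where the shadow prices change.
#'
#' @param model a [MetabolicModel].
#' @param rxn_a,rxn_b the two control reactions.
#' @param grid_a,grid_b numeric vectors of pinned flux values.
#' @param backend a solver backend.
#' @return a `phpp_result` data.frame with columns `va`, `vb`, `objective`,
#'   `dual_a`, `dual_b`, `phase` (integer label, `NA` where infeasible).
#' @export
phenotypic_phase_plane <- function(model, rxn_a, rxn_b, grid_a, grid_b,
                                   backend = reference_backend()) {
  ja <- rxn_index(model, rxn_a)
  jb <- rxn_index(model, rxn_b)
  if (!length(grid_a) || !length(grid_b)) fk_usage_error("grids must be non-empty")
  n <- length(model@reactions)
  tr <- model_row_triplets(model)
  m <- tr$m
  spec <- problem_spec(
    n_vars = n, lb = model@lower_bound, ub = model@upper_bound,
    obj = model@objective_coef, sense = "max",
    row_i = c(tr$i, m + 1L, m + 2L),
    row_j = c(tr$j, ja, jb),
    row_v = c(tr$v, 1, 1),
    row_lb = c(rep(0, m), grid_a[1], grid_b[1]),
    row_ub = c(rep(0, m), grid_a[1], grid_b[1]))
  h <- build_problem(spec, backend)
  pts <- expand.grid(va = grid_a, vb = grid_b, KEEP.OUT.ATTRS = FALSE)
  res <- data.frame(pts, objective = NA_real_, dual_a = NA_real_,
                    dual_b = NA_real_, phase = NA_integer_)
  keys <- character(0)
  for (k in seq_len(nrow(pts))) {
    set_row_limits(h, m + 1L, pts$va[k], pts$va[k])
    set_row_limits(h, m + 2L, pts$vb[k], pts$vb[k])
    sol <- solve_problem(h)
    if (sol$status != "optimal") next
    da <- sol$row_duals[m + 1L]
    db <- sol$row_duals[m + 2L]
    res$objective[k] <- sol$objective
    res$dual_a[k] <- da
    res$dual_b[k] <- db
    key <- sprintf("%.6f|%.6f", round(da, 6), round(db, 6))
    if (!key %in% keys) keys <- c(keys, key)
    res$phase[k] <- match(key, keys)
  }
  class(res) <- c("phpp_result", "data.frame")
  res
}

# ---- result export -----------------------------------------------------

#' Tabular view of an analysis result
#' @param result a result object (`deletion_result`, `fva_result`,
#'   `robustness_result`, `phpp_result`, `opt_solution` or
#'   `validation_report`).
#' @return a data.frame with a fixed, documented column order.
#' @export
report_table <- function(result) UseMethod("report_table")

#' @export
report_table.deletion_result <- function(result) result$results

#' @export
report_table.fva_result <- function(result) {
  df <- result$results
  df$gamma <- result$gamma
  df
}

#' @export
report_table.robustness_result <- function(result) as.data.frame(result)

#' @export
report_table.phpp_result <- function(result) as.data.frame(result)

#' @export
report_table.opt_solution <- function(result) {
  if (is.null(result$fluxes)) {
    return(data.frame(reaction = character(0), flux = numeric(0)))
  }
  data.frame(reaction = names(result$fluxes), flux = unname(result$fluxes),
             stringsAsFactors = FALSE)
}

#' @export
report_table.validation_report <- function(result) as.data.frame(result)

#' Write an analysis result as TSV or JSON
#'
#' Column order is the one documented for [report_table()]; numbers are
#' rendered as the shortest decimal that parses back to the identical value,
#' so identical results produce byte-identical files. The JSON form mirrors
#' the TSV fields row by row.
#'
#' @param result a result object accepted by [report_table()].
#' @param path output file path, or `""` for standard output (TSV only).
#' @param format `"tsv"` or `"json"`.
#' @return `invisible(path)`.
#' @export
write_report <- function(result, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- report_table(result)
  if (format == "tsv") {
    out <- df
    for (cl in names(out)) {
      if (is.numeric(out[[cl]])) out[[cl]] <- fmt_num(out[[cl]])
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", digits = NA, na = "null")
  }
  invisible(path)
}
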