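# Constraint-based analysis algorithms, each expressed as a formal
# optimisation problem over a metabolic model. A builder maps a model (plus
# reference data where needed) to a problem handle together with a variable
# layout, so solutions can be mapped back to per-reaction fluxes and batch
# analyses know which variables to pin for a knockout. New algorithms are
# registered by name and become available to gene_deletion() unchanged.

model_row_triplets <- function(model) {
  tr <- Matrix::summary(model@S)
  list(i = tr$i, j = tr$j, v = tr$x, m = nrow(model@S))
}

algorithm_problem <- function(algorithm, model, handle, flux_extract, ko_vars,
                              wt_flux = NULL, opt_row = NA_integer_, extras = list()) {
  structure(list(algorithm = algorithm, model = model, handle = handle,
                 n_rxn = length(model@reactions), flux_extract = flux_extract,
                 ko_vars = ko_vars, wt_flux = wt_flux, opt_row = opt_row,
                 extras = extras),
            class = "algorithm_problem")
}

#' Build a flux-balance analysis problem
#'
#' FBA: maximise `objective_coef . v` subject to the steady-state condition
#' `S v = 0` and the flux bounds `lb <= v <= ub`.
#'
#' @param model a [MetabolicModel].
#' @param backend a solver backend.
#' @return an `algorithm_problem` (solve with [optimize_problem()]).
#' @examples
#' sol <- optimize_problem(build_fba(make_chain_model()))
#' sol$objective  # 10
#' @export
build_fba <- function(model, backend = reference_backend()) {
  tr <- model_row_triplets(model)
  spec <- problem_spec(
    n_vars = length(model@reactions),
    lb = model@lower_bound, ub = model@upper_bound,
    obj = model@objective_coef, sense = "max",
    row_i = tr$i, row_j = tr$j, row_v = tr$v,
    row_lb = rep(0, tr$m), row_ub = rep(0, tr$m))
  algorithm_problem("fba", model, build_problem(spec, backend),
                    flux_extract = function(x) x,
                    ko_vars = function(j) j)
}

mtf_epsilon <- function(z) 1e-6 * max(1, abs(z))

#' Build a minimal-total-flux problem
#'
#' Among flux distributions attaining (within a small slack) a given FBA
#' objective value `z_opt`, find the one with the smallest total absolute
#' flux. Formulated as an LP by splitting `v = p - q` with `p, q >= 0` and
#' minimising `sum(p + q)`; the FBA optimum is pinned by the inequality
#' `objective_coef . v >= z_opt - eps` with `eps = 1e-6 * max(1, |z_opt|)`
#' (an inequality with slack rather than a strict equality, for numerical
#' robustness).
#'
#' @param model a [MetabolicModel].
#' @param z_opt the FBA optimum to pin; computed by a fresh FBA solve when
#'   omitted.
#' @param backend a solver backend.
#' @return an `algorithm_problem`; its solved objective is the minimal total
#'   absolute flux.
#' @export
build_mtf <- function(model, z_opt = NULL, backend = reference_backend()) {
  if (is.null(z_opt)) {
    fsol <- solve_problem(build_fba(model, backend)$handle)
    if (fsol$status != "optimal") {
      fk_usage_error(paste0("cannot derive z_opt: FBA status ", fsol$status))
    }
    z_opt <- fsol$objective
  }
  n <- length(model@reactions)
  tr <- model_row_triplets(model)
  m <- tr$m
  cc <- model@objective_coef
  nzc <- which(cc != 0)
  # rows: S(p - q) = 0 | lb <= p - q <= ub | c'(p - q) >= z - eps
  row_i <- c(tr$i, tr$i,
             seq_len(n) + m, seq_len(n) + m,
             rep(m + n + 1L, 2L * length(nzc)))
  row_j <- c(tr$j, tr$j + n,
             seq_len(n), seq_len(n) + n,
             nzc, nzc + n)
  row_v <- c(tr$v, -tr$v,
             rep(1, n), rep(-1, n),
             cc[nzc], -cc[nzc])
  eps <- mtf_epsilon(z_opt)
  spec <- problem_spec(
    n_vars = 2L * n,
    lb = rep(0, 2L * n),
    ub = c(pmax(model@upper_bound, 0), pmax(-model@lower_bound, 0)),
    obj = rep(1, 2L * n), sense = "min",
    row_i = row_i, row_j = row_j, row_v = row_v,
    row_lb = c(rep(0, m), model@lower_bound, z_opt - eps),
    row_ub = c(rep(0, m), model@upper_bound, Inf))
  algorithm_problem("mtf", model, build_problem(spec, backend),
                    flux_extract = function(x) x[seq_len(n)] - x[seq_len(n) + n],
                    ko_vars = function(j) c(j, j + n),
                    opt_row = m + n + 1L,
                    extras = list(z_opt = z_opt))
}

#' Build a MOMA problem (minimisation of metabolic adjustment)
#'
#' Predicts the flux state after a perturbation as the feasible flux vector
#' closest (in squared Euclidean distance) to a wild-type reference:
#' minimise `sum((v - w)^2)` subject to `S v = 0` and the current bounds.
#' A QP-capable backend is required.
#'
#' @param model a [MetabolicModel] (typically with knockout bounds applied,
#'   or applied later through the handle).
#' @param wt_flux wild-type reference flux vector (one value per reaction);
#'   the minimal-total-flux distribution is the conventional choice.
#' @param backend a solver backend with the `qp` capability.
#' @return an `algorithm_problem`; its solved objective is the squared
#'   distance to `wt_flux`.
#' @export
build_moma <- function(model, wt_flux, backend = reference_backend()) {
  n <- length(model@reactions)
  if (length(wt_flux) != n) {
    fk_dimension_error("wt_flux must have one value per reaction")
  }
  tr <- model_row_triplets(model)
  spec <- problem_spec(
    n_vars = n, lb = model@lower_bound, ub = model@upper_bound,
    obj = -2 * wt_flux, sense = "min",
    Q = 2 * diag(n), obj_const = sum(wt_flux^2),
    row_i = tr$i, row_j = tr$j, row_v = tr$v,
    row_lb = rep(0, tr$m), row_ub = rep(0, tr$m))
  algorithm_problem("moma", model, build_problem(spec, backend),
                    flux_extract = function(x) x,
                    ko_vars = function(j) j,
                    wt_flux = wt_flux)
}

#' Build a linear MOMA problem
#'
#' L1 variant of MOMA, solvable as an LP: with deviation variables
#' `d+ , d- >= 0` and `v - w = d+ - d-`, minimise `sum(d+ + d-)`, i.e. the
#' L1 distance between the perturbed flux state and the wild-type reference.
#' No additional constraint on the biomass value is imposed.
#'
#' @inheritParams build_moma
#' @param backend a solver backend.
#' @return an `algorithm_problem`; its solved objective is the L1 distance.
#' @export
build_lmoma <- function(model, wt_flux, backend = reference_backend()) {
  n <- length(model@reactions)
  if (length(wt_flux) != n) {
    fk_dimension_error("wt_flux must have one value per reaction")
  }
  tr <- model_row_triplets(model)
  m <- tr$m
  # vars: v (n), d+ (n), d- (n); rows: S v = 0 ; v - d+ + d- = w
  row_i <- c(tr$i, seq_len(n) + m, seq_len(n) + m, seq_len(n) + m)
  row_j <- c(tr$j, seq_len(n), seq_len(n) + n, seq_len(n) + 2L * n)
  row_v <- c(tr$v, rep(1, n), rep(-1, n), rep(1, n))
  spec <- problem_spec(
    n_vars = 3L * n,
    lb = c(model@lower_bound, rep(0, 2L * n)),
    ub = c(model@upper_bound, rep(Inf, 2L * n)),
    obj = c(rep(0, n), rep(1, 2L * n)), sense = "min",
    row_i = row_i, row_j = row_j, row_v = row_v,
    row_lb = c(rep(0, m), wt_flux), row_ub = c(rep(0, m), wt_flux))
  algorithm_problem("lmoma", model, build_problem(spec, backend),
                    flux_extract = function(x) x[seq_len(n)],
                    ko_vars = function(j) j,
                    wt_flux = wt_flux)
}

#' Build a ROOM problem (regulatory on/off minimisation)
#'
#' Minimises the *number* of reactions whose flux changes significantly
#' relative to a wild-type reference. A flux counts as unchanged when it lies
#' within `[w - delta*|w| - epsilon, w + delta*|w| + epsilon]`. Binary
#' indicators `y_j` with big-M rows release a flux from its window when
#' `y_j = 1`; the MILP minimises `sum(y)`. Defaults `delta = 0.03`,
#' `epsilon = 0.001` follow the original ROOM method.
#'
#' @inheritParams build_moma
#' @param delta relative significance threshold.
#' @param epsilon absolute significance threshold.
#' @param relaxed if `TRUE`, solve the LP relaxation (`y` continuous in
#'   `[0, 1]`) instead of the MILP; must be requested explicitly.
#' @param backend a solver backend with the `milp` capability (unless
#'   `relaxed`).
#' @return an `algorithm_problem`; its solved objective is the (integer)
#'   count of significantly changed fluxes, or its relaxation.
#' @export
build_room <- function(model, wt_flux, delta = 0.03, epsilon = 0.001,
                       relaxed = FALSE, backend = reference_backend()) {
  n <- length(model@reactions)
  if (length(wt_flux) != n) {
    fk_dimension_error("wt_flux must have one value per reaction")
  }
  w <- wt_flux
  wu <- w + delta * abs(w) + epsilon
  wl <- w - delta * abs(w) - epsilon
  lb <- model@lower_bound; ub <- model@upper_bound
  tr <- model_row_triplets(model)
  m <- tr$m
  # rows: S v = 0 ; v_j - y_j (ub_j - wu_j) <= wu_j ; v_j - y_j (lb_j - wl_j) >= wl_j
  row_i <- c(tr$i,
             seq_len(n) + m, seq_len(n) + m,
             seq_len(n) + m + n, seq_len(n) + m + n)
  row_j <- c(tr$j,
             seq_len(n), seq_len(n) + n,
             seq_len(n), seq_len(n) + n)
  row_v <- c(tr$v,
             rep(1, n), -(ub - wu),
             rep(1, n), -(lb - wl))
  spec <- problem_spec(
    n_vars = 2L * n,
    lb = c(lb, rep(0, n)), ub = c(ub, rep(1, n)),
    obj = c(rep(0, n), rep(1, n)), sense = "min",
    kind = c(rep("continuous", n), rep(if (relaxed) "continuous" else "binary", n)),
    row_i = row_i, row_j = row_j, row_v = row_v,
    row_lb = c(rep(0, m), rep(-Inf, n), wl),
    row_ub = c(rep(0, m), wu, rep(Inf, n)))
  algorithm_problem("room", model, build_problem(spec, backend),
                    flux_extract = function(x) x[seq_len(n)],
                    ko_vars = function(j) j,
                    wt_flux = wt_flux,
                    extras = list(delta = delta, epsilon = epsilon, relaxed = relaxed))
}

#' Solve an algorithm problem and map the solution back to fluxes
#'
#' Runs the solver on the built problem, extracts per-reaction fluxes from
#' the variable layout, and evaluates the model's own objective (the biomass
#' value) at the returned fluxes. Fluxes with magnitude below 1e-9 are
#' reported as exactly zero. Solver statuses (infeasible, unbounded, ...)
#' are returned in the result, never raised.
#'
#' @param prob an `algorithm_problem` from one of the builders.
#' @return an `opt_solution`: list with `algorithm`, `status`, `objective`
#'   (algorithm-specific: biomass for FBA, total absolute flux for mtf,
#'   squared / L1 distance for MOMA / linear MOMA, change count for ROOM),
#'   `fluxes` (named, one per reaction) and `biomass`.
#' @export
optimize_problem <- function(prob) {
  stopifnot(inherits(prob, "algorithm_problem"))
  sol <- solve_problem(prob$handle)
  if (sol$status == "optimal") {
    fluxes <- prob$flux_extract(sol$x)
    fluxes[abs(fluxes) < 1e-9] <- 0
    names(fluxes) <- prob$model@reactions
    biomass <- sum(prob$model@objective_coef * fluxes)
    objective <- sol$objective
    if (prob$algorithm == "room" && !isTRUE(prob$extras$relaxed)) {
      objective <- round(objective)
    }
  } else {
    fluxes <- NULL; biomass <- NA_real_; objective <- NA_real_
  }
  structure(list(algorithm = prob$algorithm, status = sol$status,
                 objective = objective, fluxes = fluxes, biomass = biomass),
            class = "opt_solution")
}

#' @export
print.opt_solution <- function(x, ...) {
  cat("opt_solution [", x$algorithm, "]: ", x$status, sep = "")
  if (x$status == "optimal") {
    cat(", objective ", format(x$objective), ", biomass ", format(x$biomass), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Run FBA on a model
#' @param model a [MetabolicModel].
#' @param backend a solver backend.
#' @return an `opt_solution`.
#' @export
fba <- function(model, backend = reference_backend()) {
  optimize_problem(build_fba(model, backend))
}

#' Run minimal-total-flux FBA on a model
#' @inheritParams fba
#' @return an `opt_solution` whose `objective` is the minimal total absolute
#'   flux at the FBA optimum.
#' @export
mtf <- function(model, backend = reference_backend()) {
  optimize_problem(build_mtf(model, backend = backend))
}

# ---- algorithm registry ------------------------------------------------

.algorithms <- new.env(parent = emptyenv())

#' Register a constraint-based algorithm by name
#'
#' Registered algorithms are selectable by text key in [gene_deletion()] and
#' [flux_deletion()] without changes there. The builder receives
#' `(model, wt_flux, backend, ...)`; `needs_reference` declares whether a
#' wild-type reference flux vector must be computed (once per batch) and
#' passed in.
#'
#' @param name text key (e.g. `"fba"`).
#' @param builder function `(model, wt_flux, backend, ...)` returning an
#'   `algorithm_problem`.
#' @param needs_reference whether the algorithm needs a wild-type flux
#'   reference.
#' @return `invisible(name)`.
#' @export
register_algorithm <- function(name, builder, needs_reference = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, is.function(builder))
  assign(name, list(builder = builder, needs_reference = needs_reference),
         envir = .algorithms)
  invisible(name)
}

#' @rdname register_algorithm
#' @export
list_algorithms <- function() sort(ls(.algorithms))

get_algorithm <- function(name) {
  if (!exists(name, envir = .algorithms, inherits = FALSE)) {
    fk_registry_error(paste0("unknown algorithm '", name, "'; registered: ",
                             paste(list_algorithms(), collapse = ", ")))
  }
  get(name, envir = .algorithms, inherits = FALSE)
}

register_algorithm("fba",
  function(model, wt_flux = NULL, backend = reference_backend(), ...)
    build_fba(model, backend = backend))
register_algorithm("mtf",
  function(model, wt_flux = NULL, backend = reference_backend(), ...)
    build_mtf(model, backend = backend, ...))
register_algorithm("moma",
  function(model, wt_flux, backend = reference_backend(), ...)
    build_moma(model, wt_flux, backend = backend, ...),
  needs_reference = TRUE)
register_algorithm("lmoma",
  function(model, wt_flux, backend = reference_backend(), ...)
    build_lmoma(model, wt_flux, backend = backend, ...),
  needs_reference = TRUE)
register_algorithm("room",
  function(model, wt_flux, backend = reference_backend(), ...)
    build_room(model, wt_flux, backend = backend, ...),
  needs_reference = TRUE)
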