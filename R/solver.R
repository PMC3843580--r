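# Solver-independent optimisation-problem layer: describe a problem once
# (problem_spec), build it into a mutable handle against a backend
# (build_problem), then edit bounds / objective / row limits in place and
# re-solve many times. Batch analyses depend on the contract that a sequence
# of edits + solves yields the same objectives as rebuilding from scratch.

#' Describe an optimisation problem
#'
#' A linear (optionally quadratic, optionally mixed-binary) program over
#' `n_vars` variables with range constraints `row_lb <= R x <= row_ub`
#' (equality rows have equal limits). The constraint matrix is given in
#' sparse triplet form. With a quadratic term the objective is
#' `0.5 x'Qx + obj'x + obj_const`, otherwise `obj'x + obj_const`.
#'
#' @param n_vars number of decision variables.
#' @param lb,ub variable bounds (recycled; `±Inf` allowed).
#' @param obj linear objective coefficients.
#' @param sense `"max"` or `"min"`.
#' @param kind per-variable kind, `"continuous"` or `"binary"`.
#' @param Q optional symmetric positive-semidefinite matrix (`n_vars` square).
#' @param obj_const constant objective offset.
#' @param row_i,row_j,row_v constraint triplets (row index, column, value).
#' @param row_lb,row_ub per-row lower/upper limits.
#' @return a `problem_spec` object.
#' @export
problem_spec <- function(n_vars, lb = -Inf, ub = Inf, obj = 0,
                         sense = c("max", "min"), kind = "continuous",
                         Q = NULL, obj_const = 0,
                         row_i = integer(0), row_j = integer(0), row_v = numeric(0),
                         row_lb = numeric(0), row_ub = numeric(0)) {
  sense <- match.arg(sense)
  n_vars <- as.integer(n_vars)
  rec <- function(x, what, len = n_vars) {
    if (length(x) == 1L) x <- rep(x, len)
    if (length(x) != len) fk_dimension_error(paste0(what, " must have length ", len))
    x
  }
  lb <- as.numeric(rec(lb, "lb")); ub <- as.numeric(rec(ub, "ub"))
  obj <- as.numeric(rec(obj, "obj"))
  kind <- rec(kind, "kind")
  if (!all(kind %in% c("continuous", "binary"))) {
    fk_usage_error("kind must be 'continuous' or 'binary'")
  }
  if (any(lb > ub)) fk_bound_error("variable lb > ub in problem spec")
  n_rows <- length(row_lb)
  if (length(row_ub) != n_rows) fk_dimension_error("row_lb / row_ub length mismatch")
  if (any(row_lb > row_ub)) fk_bound_error("row lower limit exceeds upper limit")
  if (length(row_i) != length(row_j) || length(row_i) != length(row_v)) {
    fk_dimension_error("row triplets must have equal lengths")
  }
  if (length(row_i) && (max(row_i) > n_rows || min(row_i) < 1)) {
    fk_index_error("row triplet index out of range")
  }
  if (length(row_j) && (max(row_j) > n_vars || min(row_j) < 1)) {
    fk_index_error("column triplet index out of range")
  }
  if (!is.null(Q)) {
    Q <- as.matrix(Q)
    if (nrow(Q) != n_vars || ncol(Q) != n_vars) {
      fk_dimension_error("Q must be square of size n_vars")
    }
  }
  structure(list(n_vars = n_vars, lb = lb, ub = ub, obj = obj, sense = sense,
                 kind = kind, Q = Q, obj_const = as.numeric(obj_const),
                 n_rows = n_rows,
                 R = Matrix::sparseMatrix(i = as.integer(row_i), j = as.integer(row_j),
                                          x = as.numeric(row_v),
                                          dims = c(n_rows, n_vars)),
                 row_lb = as.numeric(row_lb), row_ub = as.numeric(row_ub)),
            class = "problem_spec")
}

#' The reference solver backend
#'
#' The backend contract is a name plus capability flags (`lp`, `qp`, `milp`);
#' additional backends (commercial LP/QP/MILP kits) can be plugged in by
#' providing the same contract. The reference backend solves LPs with the
#' package's bounded-variable two-phase simplex (dense, with duals and basis
#' reuse), QPs through an active-set quadratic programming routine, and MILPs
#' through branch-and-bound on the LP relaxation.
#'
#' @return a `flux_backend` object.
#' @export
reference_backend <- function() {
  structure(list(name = "reference",
                 capabilities = c(lp = TRUE, qp = TRUE, milp = TRUE)),
            class = "flux_backend")
}

#' Get a backend by name
#' @param name backend name; only `"reference"` ships with the package.
#' @return a `flux_backend`.
#' @export
get_backend <- function(name = "reference") {
  if (identical(name, "reference")) return(reference_backend())
  fk_registry_error(paste0("unknown solver backend: ", name))
}

#' Build a mutable problem handle
#'
#' Transfers a [problem_spec()] into a backend once; subsequent analyses
#' modify the handle in place ([set_var_bounds()], [set_objective()],
#' [set_row_limits()]) and re-solve with [solve_problem()], which reuses the
#' previous optimal basis as a warm start. Basis reuse never changes returned
#' objective values (beyond 1e-9); it only shortens the solve.
#'
#' @param spec a `problem_spec`.
#' @param backend a `flux_backend`; capabilities must cover the spec
#'   (quadratic objective needs `qp`, binary variables need `milp`).
#' @return a `problem_handle` (an environment; single-owner, not thread-safe).
#' @export
build_problem <- function(spec, backend = reference_backend()) {
  stopifnot(inherits(spec, "problem_spec"))
  caps <- backend$capabilities
  if (!is.null(spec$Q) && !isTRUE(caps[["qp"]])) {
    fk_capability_error(paste0("backend '", backend$name, "' lacks capability: qp (quadratic objective)"))
  }
  if (any(spec$kind == "binary") && !isTRUE(caps[["milp"]])) {
    fk_capability_error(paste0("backend '", backend$name, "' lacks capability: milp (binary variables)"))
  }
  if (!isTRUE(caps[["lp"]])) {
    fk_capability_error(paste0("backend '", backend$name, "' lacks capability: lp"))
  }
  h <- new.env(parent = emptyenv())
  h$n_vars <- spec$n_vars
  h$lb <- spec$lb; h$ub <- spec$ub
  h$obj <- spec$obj; h$sense <- spec$sense
  h$kind <- spec$kind
  h$Q <- spec$Q; h$obj_const <- spec$obj_const
  h$R <- spec$R; h$row_lb <- spec$row_lb; h$row_ub <- spec$row_ub
  h$n_rows <- spec$n_rows
  h$backend <- backend
  h$basis <- NULL; h$at <- NULL
  class(h) <- c("problem_handle", "environment")
  h
}

check_handle <- function(handle) {
  if (!inherits(handle, "problem_handle")) fk_usage_error("not a problem handle")
}

#' Edit variable bounds in place
#' @param handle a `problem_handle`.
#' @param indices variable indices (1-based).
#' @param lb,ub new bounds, recycled over `indices`.
#' @return `invisible(handle)`.
#' @export
set_var_bounds <- function(handle, indices, lb, ub) {
  check_handle(handle)
  indices <- as.integer(indices)
  if (length(indices) == 0) return(invisible(handle))
  if (any(indices < 1) || any(indices > handle$n_vars)) {
    fk_index_error("variable index out of range")
  }
  lb <- rep_len(as.numeric(lb), length(indices))
  ub <- rep_len(as.numeric(ub), length(indices))
  if (any(lb > ub)) fk_bound_error("lb > ub in set_var_bounds")
  handle$lb[indices] <- lb
  handle$ub[indices] <- ub
  invisible(handle)
}

#' Read current variable bounds from a handle
#' @param handle a `problem_handle`.
#' @param indices variable indices.
#' @return two-column matrix `lower`, `upper`.
#' @export
get_var_bounds <- function(handle, indices) {
  check_handle(handle)
  cbind(lower = handle$lb[indices], upper = handle$ub[indices])
}

#' Replace the linear objective in place
#' @param handle a `problem_handle`.
#' @param obj full-length coefficient vector.
#' @param sense optional new sense (`"max"`/`"min"`).
#' @return `invisible(handle)`.
#' @export
set_objective <- function(handle, obj, sense = NULL) {
  check_handle(handle)
  if (length(obj) != handle$n_vars) {
    fk_dimension_error(paste0("objective must have length ", handle$n_vars))
  }
  handle$obj <- as.numeric(obj)
  if (!is.null(sense)) {
    if (!sense %in% c("max", "min")) fk_usage_error("sense must be 'max' or 'min'")
    handle$sense <- sense
  }
  invisible(handle)
}

#' Edit constraint-row limits in place
#' @param handle a `problem_handle`.
#' @param rows row indices.
#' @param lower,upper new limits, recycled; equality rows use equal limits.
#' @return `invisible(handle)`.
#' @export
set_row_limits <- function(handle, rows, lower, upper) {
  check_handle(handle)
  rows <- as.integer(rows)
  if (any(rows < 1) || any(rows > handle$n_rows)) fk_index_error("row index out of range")
  lower <- rep_len(as.numeric(lower), length(rows))
  upper <- rep_len(as.numeric(upper), length(rows))
  if (any(lower > upper)) fk_bound_error("row lower limit exceeds upper limit")
  handle$row_lb[rows] <- lower
  handle$row_ub[rows] <- upper
  invisible(handle)
}

#' Solve the problem currently held by a handle
#'
#' Dispatches on problem class: MILP when any variable is binary, QP when a
#' quadratic objective is present, LP otherwise. Backend failures surface as
#' a `"numeric_failure"` status, infeasibility and unboundedness as their own
#' statuses, never as an R error.
#'
#' @param handle a `problem_handle`.
#' @return a `solver_solution`: list with `status` (`optimal`, `infeasible`,
#'   `unbounded`, `limit`, `numeric_failure`), `objective`, primal values `x`,
#'   and for LPs `row_duals` (sensitivity of the optimum to each row's limit).
#' @export
solve_problem <- function(handle) {
  check_handle(handle)
  if (any(handle$kind == "binary")) return(solve_milp(handle))
  if (!is.null(handle$Q)) return(solve_qp(handle))
  solve_lp(handle)
}

solver_solution <- function(status, objective = NA_real_, x = NULL,
                            row_duals = NULL, iterations = NA_integer_) {
  structure(list(status = status, objective = objective, x = x,
                 row_duals = row_duals, iterations = iterations),
            class = "solver_solution")
}

#' @export
print.solver_solution <- function(x, ...) {
  cat("solver_solution:", x$status,
      if (!is.na(x$objective)) paste0("objective ", format(x$objective)), "\n")
  invisible(x)
}

# LP path: append one slack per row (R x - s = 0, row limits become slack
# bounds) so the slack columns always provide an invertible cold basis.
solve_lp <- function(handle, lb = handle$lb, ub = handle$ub, warm = TRUE) {
  n <- handle$n_vars; nr <- handle$n_rows
  if (nr > 0) {
    A <- cbind(as.matrix(handle$R), -diag(nr))
    b <- rep(0, nr)
    lbe <- c(lb, handle$row_lb); ube <- c(ub, handle$row_ub)
    obj <- c(handle$obj, rep(0, nr))
  } else {
    A <- matrix(0, 0, n); b <- numeric(0)
    lbe <- lb; ube <- ub; obj <- handle$obj
  }
  res <- simplex_solve(obj, A, b, lbe, ube, sense = handle$sense,
                       basis0 = if (warm) handle$basis else NULL,
                       at0 = if (warm) handle$at else NULL)
  if (identical(res$status, "optimal") && warm) {
    handle$basis <- res$basis
    handle$at <- res$at
  }
  solver_solution(res$status,
                  objective = if (identical(res$status, "optimal"))
                    res$objective + handle$obj_const else NA_real_,
                  x = if (!is.null(res$x)) res$x[seq_len(n)] else NULL,
                  row_duals = if (nr > 0 && identical(res$status, "optimal"))
                    res$duals else NULL,
                  iterations = res$iterations)
}

# QP path: LP feasibility pre-check with the simplex (clean statuses), then
# an active-set QP solve on the dense formulation.
solve_qp <- function(handle) {
  if (handle$sense != "min") {
    fk_capability_error("quadratic objectives support minimisation only")
  }
  feas <- local({
    saved_obj <- handle$obj; saved_Q <- handle$Q; saved_sense <- handle$sense
    handle$obj <- rep(0, handle$n_vars); handle$Q <- NULL
    on.exit({ handle$obj <- saved_obj; handle$Q <- saved_Q; handle$sense <- saved_sense })
    solve_lp(handle, warm = FALSE)
  })
  if (feas$status != "optimal") return(solver_solution(feas$status))

  n <- handle$n_vars
  R <- as.matrix(handle$R)
  eq <- handle$n_rows > 0 & handle$row_lb == handle$row_ub & is.finite(handle$row_lb)
  Aeq <- if (any(eq)) R[eq, , drop = FALSE] else NULL
  beq <- if (any(eq)) handle$row_lb[eq] else NULL
  Ai <- NULL; bi <- NULL
  addi <- function(rows, rhs) {
    Ai <<- rbind(Ai, rows); bi <<- c(bi, rhs)
  }
  for (i in which(!eq)) {
    if (is.finite(handle$row_ub[i])) addi(R[i, , drop = FALSE], handle$row_ub[i])
    if (is.finite(handle$row_lb[i])) addi(-R[i, , drop = FALSE], -handle$row_lb[i])
  }
  fu <- which(is.finite(handle$ub))
  for (j in fu) addi(t(as.matrix(replace(numeric(n), j, 1))), handle$ub[j])
  fl <- which(is.finite(handle$lb))
  for (j in fl) addi(t(as.matrix(replace(numeric(n), j, -1))), -handle$lb[j])

  if (is.null(Ai) && is.null(Aeq)) {  # unconstrained: stationary point
    x <- tryCatch(-solve(as.matrix(handle$Q), handle$obj), error = function(e) NULL)
    if (is.null(x)) return(solver_solution("numeric_failure"))
    fval <- 0.5 * sum(x * (as.matrix(handle$Q) %*% x)) + sum(handle$obj * x)
    return(solver_solution("optimal", objective = fval + handle$obj_const,
                           x = as.numeric(x)))
  }
  out <- tryCatch(
    pracma::quadprog(as.matrix(handle$Q), handle$obj, A = Ai, b = bi,
                     Aeq = Aeq, beq = beq),
    error = function(e) NULL)
  if (is.null(out) || !isTRUE(out$eflag == 1)) {
    return(solver_solution("numeric_failure"))
  }
  solver_solution("optimal", objective = out$fval + handle$obj_const, x = out$xmin)
}

# MILP path: depth-first branch-and-bound on the LP relaxation of the
# binary variables, best-bound pruning, most-fractional branching.
solve_milp <- function(handle, int_tol = 1e-6, max_nodes = 100000L) {
  bin <- which(handle$kind == "binary")
  base_lb <- handle$lb; base_ub <- handle$ub
  base_lb[bin] <- pmax(base_lb[bin], 0)
  base_ub[bin] <- pmin(base_ub[bin], 1)
  sgn <- if (handle$sense == "min") 1 else -1  # compare in min space
  best <- NULL; best_min <- Inf
  stack <- list(list(lb = base_lb, ub = base_ub))
  nodes <- 0L
  saw_infeasible_root <- NULL
  while (length(stack)) {
    nodes <- nodes + 1L
    if (nodes > max_nodes) return(solver_solution("limit"))
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    rel <- solve_lp(handle, lb = node$lb, ub = node$ub, warm = FALSE)
    if (nodes == 1L && rel$status %in% c("infeasible", "unbounded", "numeric_failure")) {
      saw_infeasible_root <- rel$status
    }
    if (rel$status != "optimal") next
    rel_min <- sgn * rel$objective
    if (rel_min >= best_min - 1e-9) next
    frac <- abs(rel$x[bin] - round(rel$x[bin]))
    if (all(frac <= int_tol)) {
      best <- rel
      best_min <- rel_min
      next
    }
    jb <- bin[which.max(frac)]
    xv <- rel$x[jb]
    lo <- node; lo$ub[jb] <- 0; lo$lb[jb] <- 0
    hi <- node; hi$lb[jb] <- 1; hi$ub[jb] <- 1
    # explore the side nearer the relaxation value first (stack = LIFO)
    if (xv >= 0.5) stack <- c(stack, list(lo), list(hi))
    else stack <- c(stack, list(hi), list(lo))
  }
  if (is.null(best)) {
    return(solver_solution(saw_infeasible_root %||% "infeasible"))
  }
  solver_solution("optimal", objective = best$objective, x = best$x,
                  iterations = nodes)
}
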