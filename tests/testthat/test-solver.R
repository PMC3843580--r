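lp_only_backend <- function() {
  structure(list(name = "lp_only",
                 capabilities = c(lp = TRUE, qp = FALSE, milp = FALSE)),
            class = "flux_backend")
}

test_that("a built handle reproduces its spec's optimum", {
  h <- build_problem(problem_spec(1, lb = 0, ub = 5, obj = 1, sense = "max"))
  expect_equal(solve_problem(h)$objective, 5)

  spec <- problem_spec(1, lb = 0, ub = 1, obj = 1, sense = "min", kind = "binary")
  expect_error(build_problem(spec, lp_only_backend()), class = "fk_capability_error")
  err <- tryCatch(build_problem(spec, lp_only_backend()), condition = function(e) e)
  expect_match(conditionMessage(err), "milp")

  # min x^2 - 2x, x free -> -1 at x = 1
  hq <- build_problem(problem_spec(1, obj = -2, sense = "min", Q = matrix(2)))
  sq <- solve_problem(hq)
  expect_equal(sq$objective, -1, tolerance = 1e-7)
  expect_equal(sq$x, 1, tolerance = 1e-6)
})

test_that("bound edits are local, reversible and validated", {
  h <- build_problem(problem_spec(2, lb = 0, ub = c(5, 7), obj = c(1, 1)))
  base <- solve_problem(h)$objective
  set_var_bounds(h, 1, 0, 2)
  expect_equal(solve_problem(h)$objective, 9)
  set_var_bounds(h, 1, 0, 5)
  expect_identical(solve_problem(h)$objective, base)

  set_var_bounds(h, 1, 0, 0)
  expect_equal(solve_problem(h)$objective, 7)
  set_var_bounds(h, 1, 0, 5)

  expect_error(set_var_bounds(h, 3, 0, 1), class = "fk_index_error")
  expect_error(set_var_bounds(h, 1, 2, 1), class = "fk_bound_error")
  expect_equal(solve_problem(h)$status, "optimal")  # handle still solvable
})

test_that("objective edits swap sense and reject dimension mismatches", {
  h <- build_problem(problem_spec(1, lb = 0, ub = 5, obj = 1, sense = "max"))
  set_objective(h, 1, sense = "min")
  expect_equal(solve_problem(h)$objective, 0)
  set_objective(h, 0)
  expect_equal(solve_problem(h)$objective, 0)
  expect_error(set_objective(h, c(1, 2)), class = "fk_dimension_error")
})

test_that("row-limit edits relax and restore the feasible set", {
  # max x subject to x - y = 0, y <= 3
  spec <- problem_spec(2, lb = 0, ub = c(10, 3), obj = c(1, 0),
                       row_i = c(1, 1), row_j = c(1, 2), row_v = c(1, -1),
                       row_lb = 0, row_ub = 0)
  h <- build_problem(spec)
  base <- solve_problem(h)$objective
  expect_equal(base, 3)
  set_row_limits(h, 1, 0, 2)   # allow x - y in [0, 2]: x can reach 5
  expect_gte(solve_problem(h)$objective, base)
  set_row_limits(h, 1, 0, 0)
  expect_identical(solve_problem(h)$objective, base)
  expect_error(set_row_limits(h, 2, 0, 0), class = "fk_index_error")
})

test_that("solver statuses are faithful and never raised as errors", {
  # x <= 0.5 by bound, x >= 1 by row: empty feasible set
  h <- build_problem(problem_spec(1, lb = 0, ub = 0.5, obj = 1,
                                  row_i = 1, row_j = 1, row_v = 1,
                                  row_lb = 1, row_ub = Inf))
  expect_identical(solve_problem(h)$status, "infeasible")

  h2 <- build_problem(problem_spec(1, lb = 0, ub = Inf, obj = 1, sense = "max"))
  expect_identical(solve_problem(h2)$status, "unbounded")

  spec3 <- problem_spec(1, lb = 0, ub = 1, obj = 0,
                        row_i = 1, row_j = 1, row_v = 1, row_lb = 2, row_ub = 3)
  expect_identical(solve_problem(build_problem(spec3))$status, "infeasible")
})

test_that("random LPs match the independent tableau oracle", {
  set.seed(11)
  compared <- 0
  for (i in 1:60) {
    n <- sample(3:6, 1); m <- sample(1:3, 1)
    R <- matrix(sample(-3:3, m * n, TRUE), m, n)
    lb <- rep(0, n); ub <- runif(n, 1, 20)
    obj <- round(runif(n, -5, 5), 2)
    spec <- problem_spec(n, lb = lb, ub = ub, obj = obj, sense = "max",
                         row_i = rep(seq_len(m), each = n),
                         row_j = rep(seq_len(n), m),
                         row_v = as.vector(t(R)),
                         row_lb = rep(0, m), row_ub = rep(0, m))
    mine <- solve_problem(build_problem(spec))
    oracle <- oracle_lp(obj, R, rep(0, m), rep(0, m), lb, ub, sense = "max")
    if (oracle$status != "optimal") next
    compared <- compared + 1
    expect_identical(mine$status, "optimal")
    expect_equal(mine$objective, oracle$objective, tolerance = 1e-7)
  }
  expect_gte(compared, 30)
})

test_that("row duals predict the optimum's sensitivity to row limits", {
  ch <- make_chain_model()
  # pin EX_A via an extra row and check d(objective)/d(pin) via the dual
  tr <- Matrix::summary(stoichiometry(ch))
  m <- length(metabolites(ch))
  spec <- problem_spec(4, lb = ch@lower_bound, ub = ch@upper_bound,
                       obj = ch@objective_coef, sense = "max",
                       row_i = c(tr$i, m + 1L), row_j = c(tr$j, 1L),
                       row_v = c(tr$x, 1), row_lb = c(rep(0, m), -6),
                       row_ub = c(rep(0, m), -6))
  h <- build_problem(spec)
  s1 <- solve_problem(h)
  dual <- s1$row_duals[m + 1L]
  delta <- 0.5
  set_row_limits(h, m + 1L, -6 + delta, -6 + delta)
  s2 <- solve_problem(h)
  expect_equal(s2$objective - s1$objective, dual * delta, tolerance = 1e-9)
})

test_that("strong duality holds for optimal LPs", {
  # objective equals dual objective reconstructed from row duals and
  # reduced costs on active variable bounds
  for (model in list(make_chain_model(), make_branched_model(), make_core_model())) {
    prob <- build_fba(model)
    sol <- solve_problem(prob$handle)
    expect_identical(sol$status, "optimal")
    R <- as.matrix(stoichiometry(model))
    y <- sol$row_duals
    rc <- model@objective_coef - as.vector(crossprod(R, y))
    x <- sol$x
    on_lb <- abs(x - model@lower_bound) < 1e-9
    on_ub <- abs(x - model@upper_bound) < 1e-9 & !on_lb
    interior <- !on_lb & !on_ub
    # interior variables must have zero reduced cost
    expect_lt(max(abs(rc[interior]), 0), 1e-6)
    dual_obj <- sum(rc[on_lb] * model@lower_bound[on_lb]) +
      sum(rc[on_ub] * model@upper_bound[on_ub])
    expect_equal(sol$objective, dual_obj, tolerance = 1e-6)
  }
})

test_that("edit sequences on one handle equal fresh builds per edit", {
  m <- make_core_model()
  prob <- build_fba(m)
  set.seed(5)
  n <- length(reactions(m))
  for (step in 1:25) {
    j <- sample(n, 1)
    new_ub <- runif(1, 0, 12)
    set_var_bounds(prob$handle, j, 0, new_ub)
    shared <- solve_problem(prob$handle)
    fresh_model <- change_bounds(m, reactions(m)[j], lb = 0, ub = new_ub)
    fresh <- solve_problem(build_fba(fresh_model)$handle)
    expect_identical(shared$status, fresh$status)
    if (shared$status == "optimal") {
      expect_equal(shared$objective, fresh$objective, tolerance = 1e-7)
    }
    m <- fresh_model  # edits accumulate on both routes
  }
})

test_that("re-solving an unchanged handle is deterministic", {
  h <- build_fba(make_core_model())$handle
  s1 <- solve_problem(h)
  s2 <- solve_problem(h)
  expect_identical(s1$status, s2$status)
  expect_identical(s1$objective, s2$objective)
  expect_lte(s2$iterations, s1$iterations)  # warm start cannot be slower here
})

test_that("branch-and-bound solves small integer programs exactly", {
  # max 3 y1 + 2 y2, y binary, y1 + y2 <= 1
  spec <- problem_spec(2, lb = 0, ub = 1, obj = c(3, 2), sense = "max",
                       kind = "binary",
                       row_i = c(1, 1), row_j = c(1, 2), row_v = c(1, 1),
                       row_lb = -Inf, row_ub = 1)
  sol <- solve_problem(build_problem(spec))
  expect_equal(sol$objective, 3)
  expect_equal(sol$x, c(1, 0), tolerance = 1e-6)

  # fractional relaxation forced integer: max y1+y2, 2y1+2y2 <= 3 -> 1
  spec2 <- problem_spec(2, lb = 0, ub = 1, obj = c(1, 1), sense = "max",
                        kind = "binary",
                        row_i = c(1, 1), row_j = c(1, 2), row_v = c(2, 2),
                        row_lb = -Inf, row_ub = 3)
  expect_equal(solve_problem(build_problem(spec2))$objective, 1)
})

test_that("the QP path reports infeasibility cleanly", {
  spec <- problem_spec(1, lb = 2, ub = 3, obj = 0, sense = "min",
                       Q = matrix(2), row_i = 1, row_j = 1, row_v = 1,
                       row_lb = 0, row_ub = 0)
  expect_identical(solve_problem(build_problem(spec))$status, "infeasible")
})
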