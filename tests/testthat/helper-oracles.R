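# Independent oracles used to cross-check the package's solvers and
# algorithm formulations. These deliberately use different machinery than
# the implementation: boot::simplex (classic tableau simplex over
# non-negative variables) for LPs, Dykstra's alternating projections for the
# MOMA quadratic program, and exhaustive binary-pattern enumeration for ROOM.

# generic dense LP oracle:
#   sense (max/min) obj'x  s.t.  row_lb <= R x <= row_ub, lb <= x <= ub
# requires finite lb (variables are shifted to be non-negative).
oracle_lp <- function(obj, R, row_lb, row_ub, lb, ub, sense = "max",
                      n_iter = 1000) {
  stopifnot(all(is.finite(lb)))
  n <- length(obj)
  shift <- lb
  A1 <- NULL; b1 <- numeric(0)   # <=
  A2 <- NULL; b2 <- numeric(0)   # >=
  A3 <- NULL; b3 <- numeric(0)   # ==
  add_le <- function(a, b) {
    if (b >= 0) { A1 <<- rbind(A1, a); b1 <<- c(b1, b) }
    else        { A2 <<- rbind(A2, -a); b2 <<- c(b2, -b) }
  }
  add_ge <- function(a, b) add_le(-a, -b)
  if (!is.null(R) && nrow(R) > 0) {
    for (r in seq_len(nrow(R))) {
      a <- R[r, ]
      off <- sum(a * shift)
      if (is.finite(row_lb[r]) && row_lb[r] == row_ub[r]) {
        b <- row_lb[r] - off
        if (b >= 0) { A3 <- rbind(A3, a); b3 <- c(b3, b) }
        else        { A3 <- rbind(A3, -a); b3 <- c(b3, -b) }
      } else {
        if (is.finite(row_ub[r])) add_le(a, row_ub[r] - off)
        if (is.finite(row_lb[r])) add_ge(a, row_lb[r] - off)
      }
    }
  }
  for (j in which(is.finite(ub))) {
    add_le(replace(numeric(n), j, 1), ub[j] - shift[j])
  }
  a <- if (sense == "max") obj else -obj
  out <- tryCatch(
    boot::simplex(a = a, A1 = A1, b1 = b1, A2 = A2, b2 = b2, A3 = A3, b3 = b3,
                  maxi = TRUE, n.iter = n_iter),
    error = function(e) NULL)
  if (is.null(out) || out$solved != 1 || is.na(out$value)) {
    status <- if (!is.null(out) && !is.na(out$solved) && out$solved == -1)
      "infeasible" else "failed"
    return(list(status = status, objective = NA_real_, x = NULL))
  }
  val <- unname(out$value) + sum(a * shift)
  if (sense != "max") val <- -val
  list(status = "optimal", objective = val, x = unname(out$soln) + shift)
}

model_S_dense <- function(model) as.matrix(stoichiometry(model))

# FBA oracle: max c'v, S v = 0, bounds
oracle_fba <- function(model) {
  S <- model_S_dense(model)
  oracle_lp(model@objective_coef, S, rep(0, nrow(S)), rep(0, nrow(S)),
            model@lower_bound, model@upper_bound, sense = "max")
}

# minimal-total-flux oracle: independent dense split formulation
oracle_mtf <- function(model, z_opt, eps = 1e-6 * max(1, abs(z_opt))) {
  S <- model_S_dense(model)
  n <- ncol(S); m <- nrow(S)
  cc <- model@objective_coef
  # vars (p, q) >= 0, v = p - q
  R <- rbind(cbind(S, -S),
             cbind(diag(n), -diag(n)),
             c(cc, -cc))
  row_lb <- c(rep(0, m), model@lower_bound, z_opt - eps)
  row_ub <- c(rep(0, m), model@upper_bound, Inf)
  oracle_lp(rep(1, 2 * n), R, row_lb, row_ub,
            lb = rep(0, 2 * n),
            ub = c(pmax(model@upper_bound, 0), pmax(-model@lower_bound, 0)),
            sense = "min")
}

# linear MOMA oracle: dense (v, d+, d-) formulation
oracle_lmoma <- function(model, w) {
  S <- model_S_dense(model)
  n <- ncol(S); m <- nrow(S)
  R <- rbind(cbind(S, matrix(0, m, 2 * n)),
             cbind(diag(n), -diag(n), diag(n)))
  row_lb <- c(rep(0, m), w)
  row_ub <- c(rep(0, m), w)
  big <- max(1e4, 10 * max(abs(model@lower_bound), abs(model@upper_bound), abs(w)))
  oracle_lp(c(rep(0, n), rep(1, 2 * n)), R, row_lb, row_ub,
            lb = c(model@lower_bound, rep(0, 2 * n)),
            ub = c(model@upper_bound, rep(big, 2 * n)),
            sense = "min")
}

# MOMA oracle: the perturbed optimum is the Euclidean projection of the
# wild-type flux vector onto {v : S v = 0, lb <= v <= ub}; Dykstra's
# alternating-projection algorithm computes that projection using only an
# affine projector and box clamping.
oracle_moma_dykstra <- function(model, w, max_iter = 50000, tol = 1e-12) {
  S <- model_S_dense(model)
  # affine projector onto the null space of S (pseudo-inverse via SVD)
  sv <- svd(S)
  pos <- sv$d > max(dim(S)) * .Machine$double.eps * max(sv$d, 1)
  V1 <- sv$v[, pos, drop = FALSE]
  proj_null <- function(x) x - V1 %*% crossprod(V1, x)
  lb <- model@lower_bound; ub <- model@upper_bound
  x <- as.numeric(w)
  p <- numeric(length(x)); q <- numeric(length(x))
  for (it in seq_len(max_iter)) {
    y <- as.numeric(proj_null(x + p))
    p <- x + p - y
    x_new <- pmin(pmax(y + q, lb), ub)
    q <- y + q - x_new
    if (sqrt(sum((x_new - x)^2)) < tol && it > 10) { x <- x_new; break }
    x <- x_new
  }
  list(status = "optimal", objective = sum((x - w)^2), x = x)
}

# feasibility of {S v = 0, lo <= v <= hi} by Dykstra alternating projections:
# iterates converge into the intersection iff it is non-empty.
oracle_feasible_dykstra <- function(S, lo, hi, max_iter = 4000, tol = 1e-7) {
  if (any(lo > hi)) return(FALSE)
  if (all(lo <= 0 & hi >= 0)) return(TRUE)   # v = 0 works
  sv <- svd(S)
  pos <- sv$d > max(dim(S)) * .Machine$double.eps * max(sv$d, 1)
  V1 <- sv$v[, pos, drop = FALSE]
  x <- pmin(pmax(0, lo), hi)
  p <- numeric(length(x)); q <- numeric(length(x))
  for (it in seq_len(max_iter)) {
    y <- as.numeric(x + p - V1 %*% crossprod(V1, x + p))
    p <- x + p - y
    x_new <- pmin(pmax(y + q, lo), hi)
    q <- y + q - x_new
    conv <- sqrt(sum((x_new - x)^2)) < 1e-12
    x <- x_new
    if (conv && it > 20) break
  }
  max(abs(S %*% x)) < tol && all(x >= lo - tol) && all(x <= hi + tol)
}

# ROOM oracle: enumerate all on/off patterns (n <= ~12), checking
# feasibility of each pattern's flux windows; minimal pattern weight wins.
oracle_room_enum <- function(model, w, delta = 0.03, epsilon = 0.001) {
  S <- model_S_dense(model)
  n <- ncol(S)
  stopifnot(n <= 12)
  wu <- w + delta * abs(w) + epsilon
  wl <- w - delta * abs(w) - epsilon
  lb <- model@lower_bound; ub <- model@upper_bound
  best <- Inf
  for (count in 0:n) {
    if (count >= best) break
    for (set in if (count == 0) list(integer(0)) else
         utils::combn(n, count, simplify = FALSE)) {
      lo <- pmax(lb, wl); hi <- pmin(ub, wu)
      lo[set] <- lb[set]; hi[set] <- ub[set]
      if (oracle_feasible_dykstra(S, lo, hi)) { best <- count; break }
    }
    if (best == count) break
  }
  list(status = if (is.finite(best)) "optimal" else "infeasible",
       objective = if (is.finite(best)) best else NA_real_)
}

# small random models for oracle sweeps (<= 12 reactions)
random_small_model <- function(seed, max_rxns = 12) {
  repeat {
    m <- make_random_model(n_internal = 3, n_paths = 2, seed = seed)
    if (length(reactions(m)) <= max_rxns) return(m)
    seed <- seed + 1000L
  }
}

# random GPR rule text generator for property tests
random_gpr_text <- function(genes = paste0("g", 1:6), depth = 0) {
  if (depth > 2 || stats::runif(1) < 0.4) {
    return(sample(genes, 1))
  }
  op <- sample(c(" and ", " or "), 1)
  k <- sample(2:3, 1)
  args <- vapply(seq_len(k), function(i) random_gpr_text(genes, depth + 1),
                 character(1))
  paste0("(", paste(args, collapse = op), ")")
}

# independent GPR evaluation: translate to an R logical expression and eval
eval_gpr_via_r <- function(text, knocked_out, genes) {
  if (!nzchar(trimws(text))) return(TRUE)
  expr <- gsub("\\band\\b", "&", text, ignore.case = TRUE)
  expr <- gsub("\\bor\\b", "|", expr, ignore.case = TRUE)
  env <- new.env()
  for (g in genes) assign(g, !(g %in% knocked_out), envir = env)
  isTRUE(eval(parse(text = expr), envir = env))
}

expect_model_equal <- function(m1, m2) {
  expect_identical(reactions(m1), reactions(m2))
  expect_setequal(metabolites(m1), metabolites(m2))
  S1 <- as.matrix(stoichiometry(m1))
  S2 <- as.matrix(stoichiometry(m2))[metabolites(m1), , drop = FALSE]
  expect_identical(unname(S1), unname(S2))
  expect_identical(m1@lower_bound, m2@lower_bound)
  expect_identical(m1@upper_bound, m2@upper_bound)
  expect_identical(m1@objective_coef, m2@objective_coef)
  expect_identical(m1@gpr_text, m2@gpr_text)
  expect_identical(m1@genes, m2@genes)
}
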