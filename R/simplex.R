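# Bounded-variable two-phase primal simplex.
#
# Solves   min / max  c'x   s.t.  A x = b,  lb <= x <= ub
# with dense linear algebra. This is the engine behind the reference backend:
# it is intended for the moderate dimensions of curated and generated fixture
# models (hundreds of variables), not for genome-scale production solves.
# It returns row duals and the final basis so that batch analyses can warm-start
# consecutive re-solves of a slightly modified problem.

#' @keywords internal
simplex_solve <- function(obj, A, b, lb, ub, sense = c("min", "max"),
                          basis0 = NULL, at0 = NULL,
                          tol = 1e-9, feas_tol = 1e-8, max_iter = 20000L) {
  sense <- match.arg(sense)
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(lb) == n, length(ub) == n, length(b) == m)
  if (any(lb > ub + tol)) {
    return(list(status = "infeasible", objective = NA_real_, x = NULL,
                duals = NULL, basis = NULL, at = NULL, iterations = 0L))
  }
  cc <- if (sense == "max") -obj else obj

  if (m == 0L) return(simplex_bounds_only(cc, lb, ub, sense, n))

  # augment with artificial columns (bounds [0,0]) so a cold start always has
  # an invertible basis; phase 1 drives any residual held by them to zero
  Aext <- cbind(A, diag(m))
  lbe <- c(lb, rep(0, m)); ube <- c(ub, rep(0, m))
  ce <- c(cc, rep(0, m))
  N <- n + m

  # nonbasic rest position: finite lower bound, else finite upper, else free@0
  rest_at <- function(j) if (is.finite(lbe[j])) -1L else if (is.finite(ube[j])) 1L else 0L
  nb_value <- function(j, at) ifelse(at == -1L, lbe[j], ifelse(at == 1L, ube[j], 0))

  basis <- NULL
  at <- integer(N)  # position code for nonbasic vars; ignored for basic
  if (!is.null(basis0) && length(basis0) == m && !anyDuplicated(basis0) &&
      all(basis0 >= 1L) && all(basis0 <= n)) {
    ok <- !inherits(tryCatch(solve(Aext[, basis0, drop = FALSE]),
                             error = function(e) e), "error")
    if (ok) {
      basis <- as.integer(basis0)
      at[seq_len(N)] <- vapply(seq_len(N), rest_at, integer(1))
      if (!is.null(at0) && length(at0) == n) at[seq_len(n)] <- as.integer(at0)
      # bounds may have moved since at0 was recorded; re-anchor to finite ones
      for (j in setdiff(seq_len(n), basis)) {
        if (at[j] == -1L && !is.finite(lbe[j])) at[j] <- rest_at(j)
        if (at[j] ==  1L && !is.finite(ube[j])) at[j] <- rest_at(j)
      }
    }
  }
  if (is.null(basis)) {
    basis <- (n + 1L):(n + m)
    at[seq_len(N)] <- vapply(seq_len(N), rest_at, integer(1))
  }

  bland_after <- max(1000L, as.integer(max_iter / 2))
  iter <- 0L

  repeat {
    iter <- iter + 1L
    if (iter > max_iter) {
      return(list(status = "limit", objective = NA_real_, x = NULL,
                  duals = NULL, basis = basis[basis <= n], at = at[seq_len(n)],
                  iterations = iter))
    }
    nonbasic <- setdiff(seq_len(N), basis)
    Bmat <- Aext[, basis, drop = FALSE]
    vN <- nb_value(nonbasic, at[nonbasic])
    rhs <- b - if (length(nonbasic)) as.vector(Aext[, nonbasic, drop = FALSE] %*% vN) else 0
    xB <- tryCatch(as.vector(solve(Bmat, rhs)), error = function(e) NULL)
    if (is.null(xB)) {
      return(list(status = "numeric_failure", objective = NA_real_, x = NULL,
                  duals = NULL, basis = NULL, at = NULL, iterations = iter))
    }
    lbB <- lbe[basis]; ubB <- ube[basis]
    below <- xB < lbB - feas_tol
    above <- xB > ubB + feas_tol
    phase <- if (any(below) || any(above)) 1L else 2L

    cB <- if (phase == 1L) (-as.numeric(below) + as.numeric(above)) else ce[basis]
    y <- tryCatch(as.vector(solve(t(Bmat), cB)), error = function(e) NULL)
    if (is.null(y)) {
      return(list(status = "numeric_failure", objective = NA_real_, x = NULL,
                  duals = NULL, basis = NULL, at = NULL, iterations = iter))
    }
    cN <- if (phase == 1L) numeric(length(nonbasic)) else ce[nonbasic]
    rN <- cN - if (length(nonbasic)) as.vector(crossprod(Aext[, nonbasic, drop = FALSE], y)) else numeric(0)

    fixed <- ube[nonbasic] - lbe[nonbasic] <= tol
    atN <- at[nonbasic]
    can_up <- !fixed & (atN == -1L | atN == 0L) & rN < -tol
    can_dn <- !fixed & (atN ==  1L | atN == 0L) & rN >  tol
    cand <- which(can_up | can_dn)

    if (!length(cand)) {
      if (phase == 1L) {
        return(list(status = "infeasible", objective = NA_real_, x = NULL,
                    duals = NULL, basis = basis[basis <= n], at = at[seq_len(n)],
                    iterations = iter))
      }
      # optimal: assemble solution
      x <- numeric(N)
      x[nonbasic] <- vN
      x[basis] <- xB
      obj_val <- sum(ce * x)
      duals <- y
      if (sense == "max") { obj_val <- -obj_val; duals <- -duals }
      return(list(status = "optimal", objective = obj_val, x = x[seq_len(n)],
                  duals = duals, basis = basis[basis <= n],
                  at = at[seq_len(n)], iterations = iter))
    }

    if (iter <= bland_after) {
      k <- cand[which.max(abs(rN[cand]))]
    } else {
      k <- cand[which.min(nonbasic[cand])]  # Bland's rule: anti-cycling
    }
    q <- nonbasic[k]
    sigma <- if (can_up[k]) 1 else -1
    vq <- nb_value(q, at[q])

    d <- tryCatch(as.vector(solve(Bmat, Aext[, q])), error = function(e) NULL)
    if (is.null(d)) {
      return(list(status = "numeric_failure", objective = NA_real_, x = NULL,
                  duals = NULL, basis = NULL, at = NULL, iterations = iter))
    }

    # ratio test: entering variable's own opposite bound ...
    t_own <- if (sigma > 0) ube[q] - vq else vq - lbe[q]
    # ... and blocking limits from basic variables (xB changes by -sigma*d*t)
    delta <- -sigma * d
    lim <- rep(Inf, m)
    tgt <- integer(m)  # bound the blocking basic lands on: -1 lb, +1 ub
    for (i in seq_len(m)) {
      if (below[i]) {                       # infeasible below its lb
        if (delta[i] > tol) { lim[i] <- (lbB[i] - xB[i]) / delta[i]; tgt[i] <- -1L }
      } else if (above[i]) {                # infeasible above its ub
        if (delta[i] < -tol) { lim[i] <- (ubB[i] - xB[i]) / delta[i]; tgt[i] <- 1L }
      } else if (delta[i] > tol) {
        if (is.finite(ubB[i])) { lim[i] <- (ubB[i] - xB[i]) / delta[i]; tgt[i] <- 1L }
      } else if (delta[i] < -tol) {
        if (is.finite(lbB[i])) { lim[i] <- (lbB[i] - xB[i]) / delta[i]; tgt[i] <- -1L }
      }
    }
    lim[lim < 0] <- 0  # degeneracy
    i_min <- if (m) which.min(lim) else NA_integer_
    t_blk <- if (m) lim[i_min] else Inf
    t_step <- min(t_own, t_blk)

    if (!is.finite(t_step)) {
      if (phase == 2L) {
        return(list(status = "unbounded", objective = NA_real_, x = NULL,
                    duals = NULL, basis = basis[basis <= n], at = at[seq_len(n)],
                    iterations = iter))
      }
      return(list(status = "numeric_failure", objective = NA_real_, x = NULL,
                  duals = NULL, basis = NULL, at = NULL, iterations = iter))
    }

    if (t_own <= t_blk) {
      at[q] <- if (sigma > 0) 1L else -1L   # bound flip, basis unchanged
    } else {
      leave <- basis[i_min]
      at[leave] <- tgt[i_min]
      basis[i_min] <- q
    }
  }
}

# objective over a box only (no equality rows)
#' @keywords internal
simplex_bounds_only <- function(cc, lb, ub, sense, n) {
  x <- numeric(n)
  for (j in seq_len(n)) {
    if (cc[j] > 0) {
      if (!is.finite(lb[j])) {
        return(list(status = "unbounded", objective = NA_real_, x = NULL,
                    duals = NULL, basis = integer(0), at = NULL, iterations = 0L))
      }
      x[j] <- lb[j]
    } else if (cc[j] < 0) {
      if (!is.finite(ub[j])) {
        return(list(status = "unbounded", objective = NA_real_, x = NULL,
                    duals = NULL, basis = integer(0), at = NULL, iterations = 0L))
      }
      x[j] <- ub[j]
    } else {
      x[j] <- min(max(0, lb[j]), ub[j])
    }
  }
  obj <- sum(cc * x)
  if (sense == "max") obj <- -obj
  list(status = "optimal", objective = obj, x = x, duals = numeric(0),
       basis = integer(0), at = ifelse(is.finite(lb), -1L, ifelse(is.finite(ub), 1L, 0L)),
       iterations = 0L)
}
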