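# Deterministic synthetic models with analytically known optima. These stand
# in for packaged genome-scale datasets: small enough to verify by hand or
# by brute force, yet exercising every code path (reversible exchanges,
# isoenzymes, enzyme complexes, alternative routes, overflow branches).

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(expr)
}

model_from_rows <- function(model_id, rows) {
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(abbreviation = r$id,
               equation = r$eq,
               lowbnd = if (is.null(r$lb)) NA_real_ else r$lb,
               uppbnd = if (is.null(r$ub)) NA_real_ else r$ub,
               obj_coef = if (is.null(r$obj)) 0 else r$obj,
               rule = if (is.null(r$rule)) "" else r$rule,
               stringsAsFactors = FALSE)
  }))
  n <- nrow(df)
  eqs <- lapply(df$equation, parse_reaction_equation)
  lb <- ifelse(is.na(df$lowbnd),
               vapply(eqs, function(e) if (e$reversible) -1000 else 0, numeric(1)),
               df$lowbnd)
  ub <- ifelse(is.na(df$uppbnd), 1000, df$uppbnd)
  mets <- unique(unlist(lapply(eqs, function(e) names(e$stoich))))
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_len(n)) {
    st <- eqs[[j]]$stoich
    ii <- c(ii, match(names(st), mets)); jj <- c(jj, rep(j, length(st)))
    xx <- c(xx, as.numeric(st))
  }
  metabolic_model(model_id, Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                                 dims = c(length(mets), n)),
                  metabolites = mets, reactions = df$abbreviation,
                  lower_bound = lb, upper_bound = ub,
                  objective_coef = df$obj_coef, gpr = df$rule)
}

#' Linear chain fixture model
#'
#' Four reactions moving a substrate from the environment into biomass:
#' `EX_A` (`A[e] <==>`, uptake-limited), transport `T_A`, conversion `R1`
#' (isoenzymes `g1 or g2`) and the biomass drain `BIO`. The FBA optimum
#' equals the uptake limit; every optimal flux route is unique, so FVA at
#' gamma 1 gives point intervals.
#'
#' @param uptake maximal substrate uptake (non-negative; default 10).
#' @return a [MetabolicModel].
#' @export
make_chain_model <- function(uptake = 10) {
  if (!is.numeric(uptake) || uptake < 0) fk_usage_error("uptake must be >= 0")
  model_from_rows("chain", list(
    list(id = "EX_A", eq = "A[e] <==>", lb = -uptake, ub = 1000),
    list(id = "T_A",  eq = "A[e] --> A[c]"),
    list(id = "R1",   eq = "A[c] --> B[c]", rule = "g1 or g2"),
    list(id = "BIO",  eq = "B[c] -->", obj = 1)
  ))
}

#' Branched fixture model
#'
#' A source feeding two alternative routes to biomass: the direct reaction
#' `R1` (gene `g1`) and a two-step bypass `R2a`/`R2b` (genes `g2`, `g3`).
#' FBA optimum 10; the minimal-total-flux solution routes everything through
#' `R1` (total flux 30 versus 40 over the bypass), which makes the fixture's
#' knockout responses analytically tractable for MOMA / linear MOMA / ROOM.
#'
#' @return a [MetabolicModel].
#' @export
make_branched_model <- function() {
  model_from_rows("branched", list(
    list(id = "S_A",  eq = "--> A[c]", ub = 10),
    list(id = "R1",   eq = "A[c] --> B[c]", rule = "g1"),
    list(id = "R2a",  eq = "A[c] --> C[c]", rule = "g2"),
    list(id = "R2b",  eq = "C[c] --> B[c]", rule = "g3"),
    list(id = "BIO",  eq = "B[c] -->", obj = 1)
  ))
}

#' Two-substrate fixture model
#'
#' Two sources with different biomass yields (1 and 2 per unit), used by the
#' phenotypic phase plane tests: with both source fluxes pinned to `(va, vb)`
#' the optimum is `va + 2 vb` and the two shadow prices differ.
#'
#' @return a [MetabolicModel].
#' @export
make_two_substrate_model <- function() {
  model_from_rows("two_substrate", list(
    list(id = "S_A", eq = "--> A[c]", ub = 10),
    list(id = "S_B", eq = "--> B[c]", ub = 10),
    list(id = "RA",  eq = "A[c] --> P[c]"),
    list(id = "RB",  eq = "B[c] --> (2) P[c]"),
    list(id = "BIO", eq = "P[c] -->", obj = 1)
  ))
}

#' Random feasible-by-construction model
#'
#' Generates a path network: each of `n_paths` chains converts a bounded
#' source through a random number (1 to `n_internal`) of unit steps into the
#' biomass metabolite. Source capacities are drawn from `[1, 10]`; internal
#' steps of the first path are fully open so the FBA optimum is strictly
#' positive by construction, other paths get random capacities in `[1, 10]`.
#' Internal steps carry random one- or two-gene rules. The same seed yields
#' a bit-identical model.
#'
#' Arbitrary random stoichiometric matrices are avoided deliberately: they
#' are usually infeasible or unbounded, while path networks always admit a
#' positive, boundable optimum.
#'
#' @param n_internal maximal chain length (>= 1).
#' @param n_paths number of parallel source-to-biomass paths (>= 1).
#' @param seed RNG seed; the caller's RNG state is left untouched.
#' @return a [MetabolicModel].
#' @export
make_random_model <- function(n_internal, n_paths, seed = 1) {
  if (n_internal < 1 || n_paths < 1) {
    fk_usage_error("n_internal and n_paths must be >= 1")
  }
  with_seed(seed, {
    rows <- list()
    gene_n <- 0L
    new_rule <- function() {
      k <- sample.int(2L, 1L)
      ids <- paste0("g", gene_n + seq_len(k))
      gene_n <<- gene_n + k
      if (k == 1L) ids else paste(ids, collapse = paste0(" ", sample(c("and", "or"), 1L), " "))
    }
    for (p in seq_len(n_paths)) {
      cap <- round(stats::runif(1, 1, 10), 3)
      L <- sample.int(n_internal, 1L)
      mets <- c(sprintf("P%d_%d[c]", p, seq_len(L)), "X[c]")
      rows[[length(rows) + 1L]] <- list(id = sprintf("SRC_%d", p),
                                        eq = paste0("--> ", mets[1]),
                                        lb = 0, ub = cap)
      for (k in seq_len(L)) {
        step_ub <- if (p == 1L) 1000 else round(stats::runif(1, 1, 10), 3)
        rows[[length(rows) + 1L]] <- list(
          id = sprintf("R%d_%d", p, k),
          eq = paste0(mets[k], " --> ", mets[k + 1L]),
          lb = 0, ub = step_ub, rule = new_rule())
      }
    }
    rows[[length(rows) + 1L]] <- list(id = "BIO", eq = "X[c] -->", obj = 1,
                                      lb = 0, ub = 1000)
    model_from_rows(sprintf("random_s%d", seed), rows)
  })
}

#' Curated core-like fixture model
#'
#' A deterministic, glycolysis-shaped network with exactly 30 genes:
#' a carbon chain from a limited substrate uptake through a gene-bearing
#' transporter, an eight-step backbone with a three-step bypass rejoining
#' downstream, an overflow branch secreting a by-product, a second
#' (nitrogen-like) assimilation chain, and a biomass synthesis step
#' combining the two precursors. Rules mix single genes, isoenzyme pairs
#' (`or`) and two-subunit complexes (`and`). The wild-type FBA optimum is 10
#' (both substrate uptakes limit at 10 with unit yields).
#'
#' @return a [MetabolicModel].
#' @export
make_core_model <- function() {
  rows <- list(
    list(id = "EX_GLC", eq = "GLC[e] <==>", lb = -10, ub = 1000),
    list(id = "GLCt",   eq = "GLC[e] --> C1[c]", rule = "g1 and g2"),
    list(id = "A1", eq = "C1[c] --> C2[c]", rule = "g3 or g4"),
    list(id = "A2", eq = "C2[c] --> C3[c]", rule = "g5"),
    list(id = "A3", eq = "C3[c] --> C4[c]", rule = "g6 and g7"),
    list(id = "A4", eq = "C4[c] --> C5[c]", rule = "g8"),
    list(id = "A5", eq = "C5[c] --> C6[c]", rule = "g9 or g10"),
    list(id = "A6", eq = "C6[c] --> C7[c]", rule = "g11"),
    list(id = "A7", eq = "C7[c] --> C8[c]", rule = "g12 and g13"),
    list(id = "A8", eq = "C8[c] --> PRE1[c]", rule = "g14"),
    # bypass around A3..A5: C3 -> D1 -> D2 -> C6
    list(id = "B1", eq = "C3[c] --> D1[c]", rule = "g15"),
    list(id = "B2", eq = "D1[c] --> D2[c]", rule = "g16"),
    list(id = "B3", eq = "D2[c] --> C6[c]", rule = "g17 or g18"),
    # overflow: C5 -> AC -> secreted
    list(id = "OV1",   eq = "C5[c] --> AC[c]", rule = "g19"),
    list(id = "ACt",   eq = "AC[c] --> AC[e]", rule = "g20"),
    list(id = "EX_AC", eq = "AC[e] <==>", lb = 0, ub = 1000),
    # nitrogen-like assimilation chain
    list(id = "EX_NH4", eq = "NH4[e] <==>", lb = -10, ub = 1000),
    list(id = "NH4t", eq = "NH4[e] --> N1[c]", rule = "g21"),
    list(id = "N1",   eq = "N1[c] --> N2[c]", rule = "g22"),
    list(id = "N2",   eq = "N2[c] --> N3[c]", rule = "g23 or g24"),
    list(id = "N3",   eq = "N3[c] --> N4[c]", rule = "g25"),
    list(id = "N4",   eq = "N4[c] --> N5[c]", rule = "g26 and g27"),
    list(id = "N5",   eq = "N5[c] --> PRE2[c]", rule = "g28"),
    list(id = "BIOSYN", eq = "PRE1[c] + PRE2[c] --> BM[c]", rule = "g29 and g30"),
    list(id = "BIO", eq = "BM[c] -->", obj = 1)
  )
  model_from_rows("core30", rows)
}
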