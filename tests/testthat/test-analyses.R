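test_that("single and pairwise gene deletions on the chain fixture", {
  ch <- make_chain_model()
  d1 <- gene_deletion(ch, combinations = 1)
  expect_identical(nrow(d1$results), 2L)
  expect_false(any(d1$results$lethal))      # g1 or g2: isoenzymes
  expect_equal(d1$results$biomass, c(10, 10), tolerance = 1e-9)
  expect_equal(d1$wild_type$biomass, 10, tolerance = 1e-9)

  d2 <- gene_deletion(ch, combinations = 2)
  expect_identical(nrow(d2$results), 1L)    # C(2,2) = 1
  expect_identical(d2$results$set, "g1+g2")
  expect_true(d2$results$lethal)
  expect_equal(d2$results$biomass, 0, tolerance = 1e-9)
})

test_that("pairwise deletions on the branched fixture find the synthetic lethals", {
  d <- gene_deletion(make_branched_model(), combinations = 2)
  expect_identical(nrow(d$results), 3L)
  expect_identical(d$results$set, c("g1+g2", "g1+g3", "g2+g3"))
  expect_identical(d$results$lethal, c(TRUE, TRUE, FALSE))
  expect_equal(d$results$biomass[3], 10, tolerance = 1e-9)
})

test_that("gene deletion validates its inputs", {
  ch <- make_chain_model()
  expect_error(gene_deletion(ch, combinations = 3), class = "fk_usage_error")
  expect_error(gene_deletion(ch, combinations = 0), class = "fk_usage_error")
  expect_error(gene_deletion(ch, algorithm = "nope"), class = "fk_registry_error")
})

test_that("genes outside every rule behave as wild type", {
  ch <- make_chain_model()
  d <- suppressMessages(gene_deletion(ch, gene_subset = c("g1", "zz")))
  row <- d$results[d$results$set == "zz", ]
  expect_false(row$lethal)
  expect_equal(row$biomass, d$wild_type$biomass, tolerance = 1e-9)
  expect_identical(row$affected, "")
})

test_that("gene deletion works under every registered algorithm", {
  br <- make_branched_model()
  for (alg in c("fba", "mtf", "moma", "lmoma", "room")) {
    d <- gene_deletion(br, combinations = 1, algorithm = alg)
    expect_identical(nrow(d$results), 3L)
    expect_identical(d$algorithm, alg)
    # g1 knockout reroutes; g2/g3 knockouts keep the wild-type route alive
    g1 <- d$results[d$results$set == "g1", ]
    expect_identical(g1$status, "optimal")
    expect_identical(g1$affected, "R1")
    if (alg %in% c("fba", "mtf")) {
      expect_equal(g1$biomass, 10, tolerance = 1e-4)
    }
    if (alg == "moma") expect_equal(g1$objective, 200, tolerance = 1e-3)
    if (alg == "lmoma") expect_equal(g1$objective, 30, tolerance = 1e-3)
    if (alg == "room") expect_equal(g1$objective, 3)
  }
})

test_that("reaction deletions pin columns directly", {
  ch <- make_chain_model()
  d <- flux_deletion(ch, "R1")
  expect_equal(d$results$biomass, 0, tolerance = 1e-9)
  expect_true(d$results$lethal)

  br <- make_branched_model()
  d2 <- flux_deletion(br, "R2a")
  expect_equal(d2$results$biomass, 10, tolerance = 1e-9)
  expect_false(d2$results$lethal)

  d3 <- flux_deletion(br)   # all singletons
  expect_identical(nrow(d3$results), length(reactions(br)))
  expect_true(all(d3$results$biomass <= d3$wild_type$biomass + 1e-6))
  expect_error(flux_deletion(br, "nope"), class = "fk_lookup_error")
})

test_that("knockout effects are monotone in the knocked-out gene set", {
  set.seed(17)
  for (i in 1:30) {
    m <- random_small_model(i)
    gs <- model_genes(m)
    if (length(gs) < 2) next
    k1 <- sample(gs, sample.int(length(gs) - 1, 1))
    k2 <- union(k1, sample(setdiff(gs, k1), 1))
    b1 <- fba(change_bounds(m, affected_reactions(m, k1), lb = 0, ub = 0))$objective
    b2 <- fba(change_bounds(m, affected_reactions(m, k2), lb = 0, ub = 0))$objective
    expect_lte(b2, b1 + 1e-6)
  }
})

test_that("FVA at gamma 1 gives point intervals on the fully coupled chain", {
  fv <- flux_variability(make_chain_model())
  expect_identical(fv$results$reaction, reactions(make_chain_model()))
  expect_true(all(abs(fv$results$max - fv$results$min) < 1e-4))
  expect_equal(fv$results$min[fv$results$reaction == "EX_A"], -10, tolerance = 1e-4)
  expect_true(all(fv$results$min <= fv$results$max + 1e-6))
})

test_that("FVA intervals contain the wild-type optimal fluxes and widen with gamma", {
  br <- make_branched_model()
  fv <- flux_variability(br)
  wt <- fba(br)$fluxes
  for (k in seq_len(nrow(fv$results))) {
    expect_gte(wt[fv$results$reaction[k]] + 1e-6, fv$results$min[k])
    expect_lte(wt[fv$results$reaction[k]] - 1e-6, fv$results$max[k])
  }
  r1 <- fv$results[fv$results$reaction == "R1", ]
  expect_equal(c(r1$min, r1$max), c(0, 10), tolerance = 1e-4)
  sa <- fv$results[fv$results$reaction == "S_A", ]
  expect_equal(c(sa$min, sa$max), c(10, 10), tolerance = 1e-4)

  half <- flux_variability(make_chain_model(), gamma = 0.5)
  ex <- half$results[half$results$reaction == "EX_A", ]
  expect_equal(c(ex$min, ex$max), c(-10, -5), tolerance = 1e-4)
  expect_error(flux_variability(br, gamma = 0), class = "fk_usage_error")
})

test_that("robustness scans ramp linearly and survive infeasible points", {
  rb <- robustness(make_chain_model(), "EX_A", n_points = 11,
                   flux_range = c(-10, 0))
  expect_equal(rb$objective, seq(10, 0), tolerance = 1e-6)

  # positive EX_A would secrete substrate that nothing produces: infeasible
  rb2 <- robustness(make_chain_model(), "EX_A", n_points = 4,
                    flux_range = c(-2, 4))
  expect_true(any(rb2$status == "infeasible"))
  expect_true(any(rb2$status == "optimal"))
  expect_true(all(is.na(rb2$objective[rb2$status == "infeasible"])))

  br <- make_branched_model()
  rb3 <- robustness(br, "R1", n_points = 11, flux_range = c(0, 10))
  expect_equal(rb3$objective, rep(10, 11), tolerance = 1e-6)  # bypass compensates
  expect_error(robustness(br, "nope"), class = "fk_lookup_error")
  expect_error(robustness(br, "R1", n_points = 1), class = "fk_usage_error")
})

test_that("the phase plane records objectives and shadow prices on the grid", {
  ts <- make_two_substrate_model()
  pp <- phenotypic_phase_plane(ts, "S_A", "S_B", c(0, 5, 10), c(0, 5, 10))
  expect_identical(nrow(pp), 9L)
  expect_equal(pp$objective, pp$va + 2 * pp$vb, tolerance = 1e-6)
  expect_equal(unique(pp$dual_a), 1, tolerance = 1e-6)
  expect_equal(unique(pp$dual_b), 2, tolerance = 1e-6)
  expect_identical(unique(pp$phase), 1L)   # yields constant: a single phase

  p0 <- phenotypic_phase_plane(ts, "S_A", "S_B", 0, 0)
  expect_identical(nrow(p0), 1L)
  expect_equal(p0$objective, 0, tolerance = 1e-9)
})

test_that("batch analyses leave the shared handle exactly restored", {
  br <- make_branched_model()
  d <- gene_deletion(br, combinations = 2)
  after <- solve_problem(d$problem$handle)
  expect_identical(after$status, "optimal")
  expect_equal(after$objective, d$wild_type$objective, tolerance = 1e-12)

  # and for an mtf screen, which also edits the optimum row
  dm <- gene_deletion(br, combinations = 1, algorithm = "mtf")
  after2 <- solve_problem(dm$problem$handle)
  expect_equal(after2$objective, dm$wild_type$objective, tolerance = 1e-9)
})

test_that("shared-handle deletions equal fresh problems per knockout", {
  m <- make_random_model(4, 3, seed = 23)
  for (alg in c("fba", "lmoma")) {
    shared <- gene_deletion(m, combinations = 1, algorithm = alg)
    wt_ref <- if (alg == "lmoma") mtf(m)$fluxes else NULL
    for (k in seq_len(nrow(shared$results))) {
      g <- shared$results$set[k]
      ko <- change_bounds(m, affected_reactions(m, g), lb = 0, ub = 0)
      fresh <- optimize_problem(
        if (alg == "fba") build_fba(ko) else build_lmoma(ko, wt_ref))
      expect_identical(shared$results$status[k], fresh$status)
      if (fresh$status == "optimal") {
        expect_equal(shared$results$objective[k], fresh$objective,
                     tolerance = 1e-7)
      }
    }
  }
})

test_that("reports render identically through TSV and JSON", {
  d <- gene_deletion(make_branched_model(), combinations = 2)
  tf <- withr::local_tempfile(fileext = ".tsv")
  jf <- withr::local_tempfile(fileext = ".json")
  write_report(d, tf, "tsv")
  write_report(d, jf, "json")
  tsv <- utils::read.delim(tf, stringsAsFactors = FALSE)
  js <- jsonlite::fromJSON(jf)
  expect_identical(names(tsv), names(js))
  expect_equal(tsv$objective, js$objective, tolerance = 1e-12)
  expect_identical(tsv$set, js$set)
  expect_identical(tsv$lethal, js$lethal)

  fv <- flux_variability(make_chain_model())
  write_report(fv, tf, "tsv")
  cols <- names(utils::read.delim(tf))
  expect_identical(cols, c("reaction", "min", "max", "gamma"))
})
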