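test_that("construction derives genes from rules and enforces invariants", {
  m <- make_chain_model()
  expect_identical(model_genes(m), c("g1", "g2"))
  expect_identical(reversible(m), c(TRUE, FALSE, FALSE, FALSE))
  expect_error(
    metabolic_model("bad", matrix(1, 1, 1), "a[c]", "R1",
                    lower_bound = 5, upper_bound = 1),
    "lower bound")
  expect_error(
    metabolic_model("bad", matrix(1, 2, 2), c("a[c]", "a[c]"), c("R1", "R2")),
    "duplicate")
})

test_that("add_reaction appends columns, metabolites and genes consistently", {
  two <- metabolic_model("two", matrix(c(1, -1), 2, 1,
                         dimnames = NULL), c("A[c]", "B[c]"), "R1",
                         lower_bound = 0, upper_bound = 10)
  two <- add_reaction(two, "S_A", c("A[c]" = 1), lb = 0, ub = 10)
  m <- add_reaction(two, "BIO", c("B[c]" = -1), lb = 0, ub = 1000, obj = 1)
  expect_length(reactions(m), 3)
  expect_identical(sum(objective_coefficients(m) != 0), 1L)
  expect_length(metabolites(m), 2)   # only existing metabolites reused

  m2 <- add_reaction(m, "R9", c("B[c]" = -1, "NEW[c]" = 1), gpr_text = "g9")
  expect_identical(setdiff(model_genes(m2), model_genes(m)), "g9")
  expect_identical(setdiff(metabolites(m2), metabolites(m)), "NEW[c]")

  expect_error(add_reaction(m, "BIO", c("B[c]" = -1)), class = "fk_identifier_conflict")
  expect_error(add_reaction(m, "Rx", c("B[c]" = -1), lb = 5, ub = 1),
               class = "fk_bound_error")
  expect_error(add_reaction(m, "Rx", c("B[c]" = -1), gpr_text = "(g1 and"),
               class = "fk_syntax_error")
})

test_that("adding a zero-forced reaction leaves the FBA optimum unchanged", {
  set.seed(7)
  for (s in 1:10) {
    m <- random_small_model(s)
    base <- fba(m)$objective
    mets <- metabolites(m)
    m2 <- add_reaction(m, "EXTRA", setNames(c(-1, 1), sample(mets, 2)),
                       lb = 0, ub = 0)
    expect_equal(fba(m2)$objective, base, tolerance = 1e-9)
  }
})

test_that("manipulation ops are pure with respect to unrelated fields", {
  m <- make_branched_model()
  m2 <- change_bounds(m, "R1", lb = 0, ub = 5)
  expect_identical(m2@objective_coef, m@objective_coef)
  expect_identical(m2@gpr_text, m@gpr_text)
  expect_identical(m2@S, m@S)
  expect_identical(m2@upper_bound[-2], m@upper_bound[-2])
  m3 <- change_objective(m, c(R1 = 1))
  expect_identical(m3@lower_bound, m@lower_bound)
  expect_identical(m3@S, m@S)
})

test_that("change_bounds updates only named columns and the derived flag", {
  m <- make_chain_model()
  expect_identical(change_bounds(m, character(0)), m)
  m2 <- change_bounds(m, "R1", lb = 0, ub = 0)
  expect_equal(fba(m2)$objective, 0)
  m3 <- change_bounds(m, "R1", lb = -5)
  expect_true(reversible(m3)[reactions(m3) == "R1"])
  expect_error(change_bounds(m, "nope", lb = 0), class = "fk_lookup_error")
  expect_error(change_bounds(m, "R1", lb = 10, ub = 1), class = "fk_bound_error")
})

test_that("change_objective stores coefficients verbatim and zeroes the rest", {
  m <- make_branched_model()
  m1 <- change_objective(m, c(BIO = 1))
  expect_identical(unname(objective_coefficients(m1)[c("BIO", "R1")]), c(1, 0))
  m2 <- change_objective(m, setNames(numeric(0), character(0)))
  expect_true(all(objective_coefficients(m2) == 0))
  expect_equal(fba(m2)$objective, 0)
  m3 <- change_objective(m, c(R1 = 1, R2a = -1))
  expect_identical(unname(objective_coefficients(m3)[c("R1", "R2a")]), c(1, -1))
  expect_error(change_objective(m, c(nope = 1)), class = "fk_lookup_error")
})

test_that("exchange reactions are the single-entry columns", {
  ch <- make_chain_model()
  expect_setequal(find_exchange_reactions(ch), c("EX_A", "BIO"))
  m <- metabolic_model("no_ex", matrix(c(-1, 1), 2, 1), c("a[c]", "b[c]"), "R1")
  expect_identical(find_exchange_reactions(m), character(0))
  ch2 <- add_reaction(ch, "EX_B", c("B[c]" = -1), lb = -1000, ub = 1000)
  expect_setequal(find_exchange_reactions(ch2), c("EX_A", "BIO", "EX_B"))
})

test_that("change_uptake sets listed exchanges and closes the rest", {
  ch <- make_chain_model()
  expect_equal(fba(change_uptake(ch, c(EX_A = -10)))$objective, 10)
  expect_equal(fba(change_uptake(ch, c(EX_A = -5)))$objective, 5)
  expect_equal(fba(change_uptake(ch, setNames(numeric(0), character(0))))$objective, 0)
  expect_error(change_uptake(ch, c(R1 = -10)), class = "fk_usage_error")
})

test_that("validate_model reports findings without throwing", {
  expect_identical(nrow(validate_model(make_chain_model())), 0L)
  m <- make_chain_model()
  lb <- m@lower_bound
  lb[2] <- 2000
  slot(m, "lower_bound", check = FALSE) <- lb
  rep <- validate_model(m)
  expect_identical(rep$code[rep$level == "error"], "bounds_crossed")
  expect_identical(rep$id[rep$level == "error"], "T_A")

  dead <- metabolic_model("dead", matrix(c(-1, 1, 0, -1), 2, 2),
                          c("A[c]", "B[c]"), c("R1", "EX_B"))
  rep2 <- validate_model(dead)
  expect_true("dead_end" %in% rep2$code)
  expect_true("A[c]" %in% rep2$id[rep2$code == "dead_end"])
})

test_that("every fixture passes validation with zero errors", {
  fixtures <- list(make_chain_model(), make_branched_model(),
                   make_two_substrate_model(), make_core_model(),
                   make_random_model(4, 3, seed = 11))
  for (m in fixtures) {
    rep <- validate_model(m)
    expect_identical(sum(rep$level == "error"), 0L)
  }
})
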