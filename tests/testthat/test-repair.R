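test_that("candidate compounds satisfy all three criteria", {
  pt <- make_fixture("TOY-PAIR-T")
  expect_identical(candidate_transport_compounds(pt$pair), "N")
  pv <- make_fixture("TOY-PAIR-V")
  expect_identical(candidate_transport_compounds(pv$pair), "A")
  px <- make_fixture("TOY-PAIR-X")
  # D is excluded: no cytoplasmic form anywhere in the namespace
  expect_false("D" %in% candidate_transport_compounds(px$pair))
})

test_that("universal transport rescues exactly the transport-deficient pair", {
  pt <- make_fixture("TOY-PAIR-T")
  fixed <- add_universal_transport(pt$pair, "N")
  expect_equal(maximize_pair_growth(fixed)$objective, 10, tolerance = 1e-9)
  # a redundant route never changes the optimum
  pv <- make_fixture("TOY-PAIR-V")
  aug <- add_universal_transport(pv$pair, "A")
  expect_equal(maximize_pair_growth(aug)$objective,
               maximize_pair_growth(pv$pair)$objective, tolerance = 1e-9)
  # the empty set is the identity
  same <- add_universal_transport(pt$pair, character(0))
  expect_equal(endofba:::.growth_value(maximize_pair_growth(same)),
               endofba:::.growth_value(maximize_pair_growth(pt$pair)),
               tolerance = 1e-12)
  expect_error(add_universal_transport(pt$pair, "ZZZ"), "not candidate")
})

test_that("adding any transport never decreases pair growth", {
  for (s in 1:5) {
    gp <- generate_pair_with_defect(
      generator_params(seed = 600 + s), "transport_deficient")
    g0 <- endofba:::.growth_value(maximize_pair_growth(gp$pair))
    cand <- candidate_transport_compounds(gp$pair)
    for (b in cand) {
      g1 <- endofba:::.growth_value(
        maximize_pair_growth(add_universal_transport(gp$pair, b)))
      expect_gte(g1, g0 - 1e-9)
    }
  }
})

test_that("nonviability causes are diagnosed by staged repair", {
  pt <- make_fixture("TOY-PAIR-T")
  d <- diagnose_nonviability(pt$pair)
  expect_true(d$cause_transport); expect_false(d$cause_access)
  px <- make_fixture("TOY-PAIR-X")
  d <- diagnose_nonviability(px$pair)
  expect_false(d$cause_transport); expect_true(d$cause_access)
  expect_true(d$resolved)
  # combined defect: both flags
  gb <- generate_pair_with_defect(generator_params(seed = 77), "both")
  d <- diagnose_nonviability(gb$pair)
  expect_true(d$cause_transport); expect_true(d$cause_access)
  # viable pair: precondition breach
  pv <- make_fixture("TOY-PAIR-V")
  expect_error(diagnose_nonviability(pv$pair), "viable")
})

test_that("greedy elimination returns an irreducible rescuing set", {
  pt <- make_fixture("TOY-PAIR-T")
  for (s in c(1, 7, 23)) {
    expect_identical(minimal_transport_set(pt$pair, s), "N")
  }
  # two redundant rescuers: a singleton is returned, either member works
  pr <- make_fixture("TOY-PAIR-R")
  seen <- unique(vapply(1:12, function(s)
    minimal_transport_set(pr$pair, s), character(1)))
  expect_true(all(seen %in% c("N1", "N2")))
  for (b in c("N1", "N2"))
    expect_true(pair_is_viable(add_universal_transport(pr$pair, b))$viable)
  expect_false(single_specificity(pr$pair)$single_specific)
  expect_true(single_specificity(pt$pair)$single_specific)
})

test_that("minimal sets are irreducible and minimum-cardinality on random instances", {
  for (s in 1:10) {
    n_missing <- 1L + s %% 2L
    gp <- generate_pair_with_defect(
      generator_params(seed = 700 + s), "transport_deficient",
      n_missing = n_missing)
    ms <- minimal_transport_set(gp$pair, order_seed = s)
    expect_identical(ms, gp$truth$rescuing_compounds)
    expect_true(is_irreducible_fix(gp$pair, ms))
    expect_true(is_minimum_cardinality(gp$pair, ms))
  }
})

test_that("strip-and-repair recovers exactly the deleted transport", {
  for (s in 1:10) {
    gp <- generate_pair_with_defect(generator_params(seed = 800 + s),
                                    "none")
    x <- gp$truth$endo_substrates[1]     # shared by construction
    host2 <- delete_reaction(gp$host, paste0("TR_", x))
    pair2 <- build_pair(host2, gp$endo)
    expect_false(pair_is_viable(pair2)$viable)
    expect_identical(minimal_transport_set(pair2, order_seed = s), x)
  }
})

test_that("repair on an access-deficient pair fails its precondition", {
  px <- make_fixture("TOY-PAIR-X")
  expect_error(minimal_transport_set(px$pair), "not fixable")
})
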