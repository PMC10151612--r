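test_that("the nested pair system reproduces hand-derived growth", {
  fx <- make_fixture("TOY-PAIR-V")
  sol <- maximize_pair_growth(fx$pair)
  expect_equal(sol$objective, 10, tolerance = 1e-9)
  # equal-growth constraint: the two biomass fluxes coincide exactly
  expect_equal(sol$fluxes[fx$pair$biomass_host],
               sol$fluxes[fx$pair$biomass_endo], tolerance = 1e-9)
  # joint environment doubles the substrate pool
  i <- match("A", fx$pair$joint_env$base_id)
  expect_equal(fx$pair$joint_env$lower[i], -20)
})

test_that("a transport-deficient pair is nonviable", {
  fx <- make_fixture("TOY-PAIR-T")
  expect_equal(endofba:::.growth_value(maximize_pair_growth(fx$pair)), 0,
               tolerance = 1e-9)
  expect_false(pair_is_viable(fx$pair)$viable)
})

test_that("orphan endosymbiont compounds get flagged zero rows", {
  fx <- make_fixture("TOY-PAIR-X")
  expect_identical(fx$pair$orphans, "D")
  i <- match("D[orphan]", rownames(fx$pair$A))
  expect_false(is.na(i))
  expect_equal(fx$pair$row_lb[i], 0)
  expect_equal(fx$pair$row_ub[i], 0)
  expect_false(pair_is_viable(fx$pair)$viable)
})

test_that("pairs from different collections are rejected", {
  a <- toy_prepared("TOY-A")
  s <- externalize_environment(
    generate_model(generator_params(seed = 3))$model)
  expect_error(build_pair(a, s), "same collection")
})

test_that("configuration assessment classifies unordered pairs", {
  a <- toy_prepared("TOY-A")
  h <- harmonize_namespace(list(a, toy_prepared("TOY-A2")))
  expect_identical(assess_configurations(h[[1]], h[[2]])$class, "both")
  h2 <- harmonize_namespace(list(a, toy_prepared("TOY-C")))
  out <- assess_configurations(h2[[1]], h2[[2]])
  # A-hosts-C fails (orphan D); C-hosts-A works: A maps onto C's cytoplasm
  expect_false(out$pair_AB_viable)
  expect_true(out$pair_BA_viable)
  expect_identical(out$class, "only_one")
  # two transport-deficient directions -> neither
  h3 <- harmonize_namespace(list(a, toy_prepared("TOY-B")))
  expect_identical(assess_configurations(h3[[1]], h3[[2]])$class, "neither")
})

test_that("forcing the endosymbiont off recovers the host solo optimum", {
  fx <- make_fixture("TOY-PAIR-V")
  pair <- fx$pair
  ne <- pair$n_endo
  pair$lb[pair$n_host + seq_len(ne)] <- 0
  pair$ub[pair$n_host + seq_len(ne)] <- 0
  i <- match(".equal_growth", rownames(pair$A))
  pair$row_lb[i] <- -1e6; pair$row_ub[i] <- 1e6
  solo <- maximize_growth(fx$host, pair$joint_env)$objective
  expect_equal(maximize_pair_growth(pair)$objective, solo,
               tolerance = 1e-9)
})

test_that("pair growth never exceeds the host solo optimum in the joint environment", {
  # endosymbiont biomass strictly consumes host-cytoplasm resources in
  # these chain fixtures, the structural source of the fitness cost
  for (s in 1:6) {
    gp <- generate_pair_with_defect(generator_params(seed = 400 + s),
                                    "none")
    solo <- maximize_growth(gp$host, gp$pair$joint_env)$objective
    expect_lte(maximize_pair_growth(gp$pair)$objective, solo + 1e-8)
  }
})

test_that("building both orientations leaves the inputs untouched", {
  h <- harmonize_namespace(list(toy_prepared("TOY-A"),
                                toy_prepared("TOY-B")))
  before <- list(h[[1]], h[[2]])
  p1 <- build_pair(h[[1]], h[[2]])
  p2 <- build_pair(h[[2]], h[[1]])
  expect_identical(h[[1]], before[[1]])
  expect_identical(h[[2]], before[[2]])
  expect_identical(p1$host$id, p2$endo$id)
})
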