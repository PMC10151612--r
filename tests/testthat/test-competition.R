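test_that("perturbation enumeration lists exactly the consumable compounds", {
  env <- met_environment(c("A", "N", "U"), c(-20, -10, 0), c(0, 0, 5))
  expect_identical(enumerate_perturbations(env), c("A", "N"))
  expect_identical(enumerate_perturbations(met_environment()), character(0))
})

test_that("removal zeroes uptake only and is idempotent", {
  env <- met_environment(c("A", "N"), c(-20, -10), c(0, 3))
  p1 <- perturb(env, "A")
  expect_equal(p1$lower[p1$base_id == "A"], 0)
  expect_equal(p1$upper[p1$base_id == "N"], 3)
  expect_identical(perturb(p1, "A"), p1)
  expect_error(perturb(env, "Z"), "not in environment")
})

test_that("the scenario classifier is total, exhaustive and mutually exclusive", {
  combos <- expand.grid(p = c(TRUE, FALSE), h = c(TRUE, FALSE),
                        e = c(TRUE, FALSE))
  labels <- mapply(classify_scenario, combos$p, combos$h, combos$e)
  expect_length(unique(labels), 8)
  expect_setequal(labels, scenario_levels())
  expect_identical(classify_scenario(TRUE, TRUE, TRUE), "all_viable")
  expect_identical(classify_scenario(FALSE, FALSE, FALSE), "all_nonviable")
  expect_identical(classify_scenario(FALSE, FALSE, TRUE),
                   "only_endo_viable")
})

test_that("the survival screen reproduces hand-solved outcomes", {
  pt <- make_fixture("TOY-PAIR-T")
  fixed <- add_universal_transport(pt$pair, "N")
  scr <- survival_screen(fixed, pt$host, pt$endo)
  expect_setequal(scr$records$removed_compound, c("A", "N"))
  recA <- scr$records[scr$records$removed_compound == "A", ]
  # without A: pair and host die, the ancestral endosymbiont (on N) lives
  expect_identical(recA$scenario, "only_endo_viable")
  recN <- scr$records[scr$records$removed_compound == "N", ]
  expect_identical(recN$scenario, "only_host_viable")
  rob <- setNames(scr$robustness$proportion, scr$robustness$metabolism)
  expect_equal(rob[["pair"]], 0)
  expect_equal(rob[["host"]], 0.5)
  expect_equal(rob[["endo"]], 0.5)
})

test_that("an inert compound's removal leaves everyone viable", {
  pv <- make_fixture("TOY-PAIR-V")
  env <- merge_environments(pv$pair$joint_env,
                            met_environment("U", -5, 0))
  scr <- survival_screen(pv$pair, pv$host, pv$endo, env)
  recU <- scr$records[scr$records$removed_compound == "U", ]
  expect_identical(recU$scenario, "all_viable")
  recA <- scr$records[scr$records$removed_compound == "A", ]
  expect_identical(recA$scenario, "all_nonviable")  # sole substrate
})

test_that("robustness proportions are invariant to perturbation order", {
  gp <- generate_pair_with_defect(generator_params(seed = 5), "none")
  scr <- survival_screen(gp$pair, gp$host, gp$endo)
  env <- gp$pair$joint_env
  rev_env <- met_environment(rev(env$base_id), rev(env$lower),
                             rev(env$upper))
  scr2 <- survival_screen(gp$pair, gp$host, gp$endo, rev_env)
  expect_equal(sort(scr$robustness$proportion),
               sort(scr2$robustness$proportion))
})

test_that("relative fitness arithmetic and classification", {
  expect_equal(pairwise_relative_fitness(10, 10)$advantage, 0)
  expect_identical(pairwise_relative_fitness(10, 10)$class, "equal")
  expect_equal(pairwise_relative_fitness(5, 10)$advantage, -0.5)
  expect_identical(pairwise_relative_fitness(5, 10)$class, "slower")
  expect_equal(pairwise_relative_fitness(11.89, 10)$advantage, 0.189)
  expect_identical(pairwise_relative_fitness(11.89, 10)$class, "faster")
  und <- pairwise_relative_fitness(5, 1e-5)
  expect_false(und$defined)
  expect_true(is.na(und$advantage))
})

test_that("community two-step growth separates unique from degenerate partitions", {
  cu <- make_fixture("TOY-COMM-U")
  res <- community_growth(cu$host, cu$endo, cu$pair, cu$shared_env)
  expect_equal(res$z, 40, tolerance = 1e-9)
  ent <- res$entities
  expect_equal(ent$max[ent$entity == "host"], 20, tolerance = 1e-9)
  expect_equal(ent$min[ent$entity == "host"], 20, tolerance = 1e-9)
  expect_equal(ent$max[ent$entity == "endo"], 20, tolerance = 1e-9)
  expect_equal(ent$max[ent$entity == "pair"], 0, tolerance = 1e-9)
  expect_true(res$unique)
  # all step-2 optima within z; min <= max
  expect_true(all(ent$max <= res$z + 1e-8))
  expect_true(all(ent$min <= ent$max + 1e-9))
  # unique partition: entity maxima themselves reproduce z
  expect_equal(sum(ent$max), res$z, tolerance = 1e-8)

  cn <- make_fixture("TOY-COMM-N")
  res2 <- community_growth(cn$host, cn$endo, cn$pair, cn$shared_env)
  expect_equal(res2$z, 20, tolerance = 1e-9)
  expect_false(res2$unique)
  e2 <- res2$entities
  expect_gt((e2$max[1] - e2$min[1]) / e2$max[1], 0.10)
})

test_that("a single-entity community reduces to the solo optimum", {
  # pair entity contributes nothing when nonviable; host alone attains z
  ct <- make_fixture("TOY-PAIR-T")
  res <- community_growth(ct$host, ct$endo, ct$pair)
  solo_h <- maximize_growth(ct$host, ct$pair$joint_env)$objective
  solo_e <- maximize_growth(ct$endo, ct$pair$joint_env)$objective
  expect_equal(res$z, solo_h + solo_e, tolerance = 1e-8)
  expect_equal(res$entities$max[res$entities$entity == "pair"], 0,
               tolerance = 1e-9)
})
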