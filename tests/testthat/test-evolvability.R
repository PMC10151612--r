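test_that("bound relaxation follows the magnitude formula", {
  expect_equal(as.numeric(mutate_bounds(c(0, 5), 1000)), c(0, 5000))
  expect_equal(as.numeric(mutate_bounds(c(-2, 3), 1000)), c(-2000, 3000))
  expect_equal(as.numeric(mutate_bounds(c(-2, 3), 1)), c(-2, 3))
  # a strictly positive lower bound flips sign and is flagged
  out <- mutate_bounds(c(1, 3), 10)
  expect_equal(as.numeric(out), c(-10, 30))
  expect_true(isTRUE(attr(out, "flipped_lower")))
})

test_that("scans find the binding transport and only it", {
  mm <- toy_prepared("TOY-MUT")
  sc <- scan_mutations(mm)
  expect_equal(unique(sc$baseline), 5, tolerance = 1e-9)
  expect_identical(sc$reaction[sc$beneficial], "TA")
  expect_equal(sc$mutated[sc$reaction == "TA"], 10, tolerance = 1e-9)
  expect_equal(sc$mutated[sc$reaction == "R1"], 5, tolerance = 1e-9)
  # fully environment-limited chain: no reaction is binding
  ma <- toy_prepared("TOY-A")
  expect_false(any(scan_mutations(ma)$beneficial))
})

test_that("pair-context mutations help the pair but not past the mutated ancestor", {
  h <- harmonize_namespace(list(toy_prepared("TOY-MUT"),
                                toy_prepared("TOY-A2")))
  pair <- build_pair(h[[1]], h[[2]])
  env <- pair$joint_env
  anc <- scan_mutations(h[[1]], "host", env)
  prs <- scan_mutations(pair, "host", env)
  ta_anc <- anc[anc$reaction == "TA", ]
  ta_pair <- prs[prs$reaction == "TA", ]
  expect_true(ta_anc$beneficial)
  expect_true(ta_pair$beneficial)
  expect_lte(ta_pair$mutated, ta_anc$mutated + 1e-9)
})

test_that("tightening bounds shrinks growth; relaxing the bottleneck restores it", {
  m <- toy_prepared("TOY-A")
  mt <- tighten_all_bounds(m, 100)
  expect_equal(maximize_growth(mt, environment_of(m))$objective, 1,
               tolerance = 1e-9)
  expect_error(tighten_all_bounds(m, 1), "> 1")
  # single-bottleneck chain: tighten x100 then mutate x100 recovers 10
  c0 <- toy_prepared("TOY-C")
  ct <- tighten_all_bounds(c0, 100)
  sc <- scan_mutations(ct, env = environment_of(c0), factor = 100)
  expect_equal(max(sc$mutated), 10, tolerance = 1e-9)
  expect_identical(sc$reaction[which.max(sc$mutated)], "RD")
})

test_that("no mutation ever decreases growth and bounds are restored after scans", {
  for (s in 1:6) {
    gm <- generate_model(generator_params(seed = 900 + s,
                                          transport_bound = 5))
    m <- externalize_environment(gm$model)
    before <- m$reactions
    sc <- scan_mutations(m)
    expect_true(all(sc$mutated >= sc$baseline - 1e-6 * pmax(sc$baseline, 1)))
    expect_identical(m$reactions, before)  # reset integrity
    expect_equal(maximize_growth(m)$objective, sc$baseline[1],
                 tolerance = 1e-12)
  }
  gp <- generate_pair_with_defect(generator_params(seed = 950,
                                                   transport_bound = 5),
                                  "none")
  for (ctx in c("host", "endo")) {
    sc <- scan_mutations(gp$pair, ctx)
    expect_true(all(sc$mutated >= sc$baseline - 1e-6 * pmax(sc$baseline, 1)))
  }
})

test_that("pair scans of identical models reflect the nested asymmetry", {
  # environment-limited copy pair: no bound binds, both scans all-neutral
  h <- harmonize_namespace(list(toy_prepared("TOY-A"),
                                toy_prepared("TOY-A2")))
  pair <- build_pair(h[[1]], h[[2]])
  sh <- scan_mutations(pair, "host")
  se <- scan_mutations(pair, "endo")
  expect_equal(sh$mutated[match(se$reaction, sh$reaction)], se$mutated,
               tolerance = 1e-8)
  # bound-limited copy pair: the host transport carries both organisms'
  # demand, the endosymbiont transport only its own, so relaxing the host
  # copy helps while relaxing the endosymbiont copy cannot
  hm <- harmonize_namespace(list(toy_prepared("TOY-MUT"),
                                 toy_prepared("TOY-MUT")))
  hm[[2]]$id <- "TOY-MUT-copy"
  pm <- build_pair(hm[[1]], hm[[2]])
  sh <- scan_mutations(pm, "host")
  se <- scan_mutations(pm, "endo")
  expect_equal(sh$baseline[1], 2.5, tolerance = 1e-9)  # 2*growth <= 5
  expect_equal(sh$mutated[sh$reaction == "TA"], 5, tolerance = 1e-9)
  expect_equal(se$mutated[se$reaction == "TA"], 2.5, tolerance = 1e-9)
})

test_that("evolvability comparison bookkeeping matches the scans", {
  gp <- generate_pair_with_defect(generator_params(seed = 33,
                                                   transport_bound = 5),
                                  "none")
  cmp <- compare_evolvability(gp$pair, gp$host, gp$endo)
  # every context scanned every reaction of its entity
  expect_equal(sum(cmp$scans$context == "ancestral_host"),
               nrow(gp$host$reactions))
  expect_equal(sum(cmp$scans$context == "pair_host_reaction"),
               nrow(gp$host$reactions))
  expect_equal(nrow(cmp$paired_host), nrow(gp$host$reactions))
  # pair never reaches past its ancestors here
  expect_true(all(cmp$max_growth[["pair"]] <=
                    pmax(cmp$max_growth[["host"]],
                         cmp$max_growth[["endo"]]) + 1e-9))
})

test_that("the sign-rank implementation agrees with the reference test", {
  withr::with_seed(42, {
    for (i in 1:6) {
      x <- round(rnorm(12, 1), 2); y <- round(rnorm(12), 2)
      ours <- signrank_test(x, y)
      ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
      expect_equal(ours$statistic, unname(ref$statistic))
      expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
    }
    # tied / larger samples: normal approximation path
    x <- sample(0:3, 40, replace = TRUE); y <- sample(0:3, 40, TRUE)
    ours <- signrank_test(x, y)
    ref <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                              correct = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-6)
  })
})

test_that("the ANOVA implementation matches the classical reference", {
  g <- list(c(1, 2, 3), c(2, 3, 4), c(5, 6, 10))
  ours <- oneway_anova(g)
  df <- data.frame(y = unlist(g), grp = rep(letters[1:3], each = 3))
  ref <- summary(stats::aov(y ~ grp, df))[[1]]
  expect_equal(ours$F, ref[["F value"]][1], tolerance = 1e-10)
  expect_equal(ours$p_value, ref[["Pr(>F)"]][1], tolerance = 1e-10)
  # identical groups: F = 0, p = 1
  same <- oneway_anova(list(c(.5, .5, .5), c(.5, .5, .5)))
  expect_equal(same$F, 0); expect_equal(same$p_value, 1)
  # zero within-group variance: degenerate, p floored at 0
  deg <- oneway_anova(list(c(.5, .5, .5), c(.9, .9, .9)))
  expect_true(is.infinite(deg$F)); expect_true(deg$degenerate)
  expect_equal(deg$p_value, 0)
})
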