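test_that("toy TSV fixtures load with the expected structure", {
  m <- make_fixture("TOY-A")$model
  expect_s3_class(m, "metabolic_model")
  expect_equal(nrow(m$compounds), 3)
  core <- m$reactions[!m$reactions$is_exchange, ]
  expect_equal(nrow(core), 3)
  expect_identical(m$reactions$id[m$biomass], "BIO")
  expect_identical(m$reactions$id[m$reactions$is_exchange], "EX_A")
})

test_that("a model with two objective reactions is rejected", {
  m <- make_fixture("TOY-A")$model
  rx <- m$reactions
  rx$is_biomass[1] <- TRUE
  expect_error(metabolic_model(m$id, m$compounds, rx, m$S),
               "exactly one biomass")
  expect_error(metabolic_model(m$id,
                               transform(m$compounds, compartment = "z"),
                               m$reactions, m$S), "compartment")
})

test_that("toy TSV and SBML round-trips preserve stoichiometry and bounds", {
  m <- make_fixture("TOY-MUT")$model
  for (dialect in c("toy_tsv", "sbml_fbc")) {
    path <- tempfile(fileext = if (dialect == "sbml_fbc") ".xml" else ".tsv")
    write_model(m, path, dialect)
    m2 <- load_model(path, dialect)
    expect_identical(m2$compounds$key, m$compounds$key)
    expect_identical(m2$reactions$id, m$reactions$id)
    expect_equal(m2$reactions$lb, m$reactions$lb)
    expect_equal(m2$reactions$ub, m$reactions$ub)
    expect_equal(as.matrix(m2$S), as.matrix(m$S), ignore_attr = TRUE)
    expect_identical(m2$biomass, m$biomass)
    unlink(path)
  }
})

test_that("written SBML is readable by an independent SBML+FBA stack", {
  m <- make_fixture("TOY-A")$model
  path <- tempfile(fileext = ".xml")
  write_model(m, path, "sbml_fbc")
  out <- tempfile()
  script <- sprintf('
import cobra, json
m = cobra.io.read_sbml_model("%s")
sol = m.optimize()
json.dump({"n_rxn": len(m.reactions), "n_met": len(m.metabolites),
           "growth": sol.objective_value}, open("%s", "w"))
', path, out)
  rc <- system2("python", c("-c", shQuote(script)), stdout = FALSE,
                stderr = FALSE)
  expect_identical(rc, 0L)
  ref <- jsonlite::read_json(out)
  expect_equal(ref$n_rxn, 4)
  expect_equal(ref$n_met, 3)
  expect_equal(ref$growth, 10, tolerance = 1e-6)
})

test_that("harmonization shares rows, is idempotent and order-independent", {
  a <- toy_prepared("TOY-A"); b <- toy_prepared("TOY-B")
  h1 <- harmonize_namespace(list(a, b))
  expect_identical(h1[[1]]$compounds$key, h1[[2]]$compounds$key)
  expect_equal(nrow(h1[[1]]$compounds), 6)
  # same row for the same compound in both models
  expect_identical(match("A[e]", h1[[1]]$compounds$key),
                   match("A[e]", h1[[2]]$compounds$key))
  # idempotent
  h2 <- harmonize_namespace(h1)
  expect_identical(h2[[1]]$compounds$key, h1[[1]]$compounds$key)
  expect_equal(as.matrix(h2[[1]]$S), as.matrix(h1[[1]]$S))
  # order-independent row maps
  h3 <- harmonize_namespace(list(b, a))
  expect_identical(h3[[2]]$compounds$key, h1[[1]]$compounds$key)
  expect_equal(as.matrix(h3[[2]]$S), as.matrix(h1[[1]]$S))
  # growth is unchanged by harmonization
  expect_equal(maximize_growth(h1[[1]])$objective,
               maximize_growth(a)$objective, tolerance = 1e-9)
  expect_error(harmonize_namespace(list(a, generate_model(
    generator_params(seed = 1))$model)), "single collection")
})

test_that("externalization transfers exchange bounds and preserves growth", {
  raw <- make_fixture("TOY-A")$model
  ext <- externalize_environment(raw)
  i <- match("A[e]", ext$compounds$key)
  expect_equal(ext$env_lower[i], -10)
  expect_equal(ext$env_upper[i], 0)
  expect_false(any(ext$reactions$is_exchange))
  expect_equal(maximize_growth(raw)$objective,
               maximize_growth(ext)$objective, tolerance = 1e-9)
  # duplicate exchanges: bounds summed with a warning
  dup <- raw
  dup$S <- cbind(dup$S, dup$S[, 4, drop = FALSE])
  ex2 <- dup$reactions[4, ]; ex2$id <- "EX_A_2"
  ex2$lb <- -5; dup$reactions$lb[4] <- -5
  dup <- metabolic_model(dup$id, dup$compounds, rbind(dup$reactions, ex2),
                         dup$S)
  expect_warning(de <- externalize_environment(dup), "summed")
  expect_equal(de$env_lower[match("A[e]", de$compounds$key)], -10)
})

test_that("a model with no exchange reactions is nonviable after externalization", {
  raw <- make_fixture("TOY-A")$model
  noex <- delete_reaction(raw, "EX_A")
  ext <- externalize_environment(noex)
  expect_true(all(ext$env_lower == 0))
  expect_false(is_viable(ext)$viable)
})

test_that("externalization preserves the optimum on random models", {
  for (s in 1:10) {
    raw <- generate_model(generator_params(seed = s))$model
    g_raw <- maximize_growth(raw)$objective
    g_ext <- maximize_growth(externalize_environment(raw))$objective
    expect_equal(g_ext, g_raw, tolerance = 1e-8)
  }
})

test_that("endosymbiont partition conserves every coefficient", {
  prep <- prepare_collection(list(make_fixture("TOY-A")$model,
                                  make_fixture("TOY-C")$model))
  for (m in prep) {
    part <- partition_for_endosymbiont(m)
    expect_equal(nrow(part$S_E) + nrow(part$S_EtoH), nrow(m$S))
    # reassemble: each reaction's column split across the two blocks
    # carries exactly the original coefficients
    for (k in seq_len(ncol(m$S))) {
      orig <- m$S[, k]
      back <- numeric(length(orig))
      names(back) <- m$compounds$key
      e_keys <- m$compounds$key[m$compounds$compartment == "e"]
      back[rownames(part$S_E)] <- part$S_E[, k]
      back[e_keys] <- part$S_EtoH[, k]
      expect_equal(unname(back), unname(as.numeric(orig)))
    }
  }
  # orphan detection: D has no cytoplasmic row anywhere
  expect_identical(partition_for_endosymbiont(prep[[2]])$orphans, "D")
})

test_that("environment merging sums bounds and is commutative/associative", {
  e1 <- met_environment("A", -10, 0)
  e2 <- met_environment("N", -10, 0)
  m12 <- merge_environments(e1, e2)
  expect_setequal(m12$base_id, c("A", "N"))
  expect_equal(m12$lower, c(-10, -10))
  dbl <- merge_environments(e1, e1)
  expect_equal(dbl$lower, -20)
  e3 <- met_environment(c("A", "Z"), c(-2, -5), c(0, 1))
  lhs <- merge_environments(merge_environments(e1, e2), e3)
  rhs <- merge_environments(e1, merge_environments(e2, e3))
  expect_identical(lhs, rhs)
  expect_identical(merge_environments(e1, e2), merge_environments(e2, e1))
  expect_error(met_environment("A", 1, 2), "lower <= 0 <= upper")
})

test_that("each ancestor stays viable in the merged environment", {
  a <- toy_prepared("TOY-A"); b <- toy_prepared("TOY-B")
  joint <- merge_environments(environment_of(a), environment_of(b))
  h <- harmonize_namespace(list(a, b))
  expect_true(is_viable(h[[1]], joint)$viable)
  expect_true(is_viable(h[[2]], joint)$viable)
})

test_that("shared reaction fraction is the Jaccard index over reaction ids", {
  a <- make_fixture("TOY-A")$model
  b <- make_fixture("TOY-B")$model
  a2 <- make_fixture("TOY-A2")$model
  expect_equal(shared_reaction_fraction(a, a), 1.0)
  expect_equal(shared_reaction_fraction(a, a2), 1.0)  # identical copy
  expect_equal(shared_reaction_fraction(a, b), 0.0)
  # {r1,r2,r3} vs {r2,r3,r4} -> 2/4
  mk <- function(id, ids) {
    S <- Matrix::sparseMatrix(i = rep(1, length(ids)),
                              j = seq_along(ids), x = -1,
                              dims = c(1, length(ids)))
    metabolic_model(id, data.frame(base_id = "P", compartment = "c"),
                    data.frame(id = ids, lb = 0, ub = 1,
                               is_biomass = seq_along(ids) == 1,
                               is_exchange = FALSE), S)
  }
  expect_equal(shared_reaction_fraction(mk("x", c("r1", "r2", "r3")),
                                        mk("y", c("r2", "r3", "r4"))), 0.5)
})
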