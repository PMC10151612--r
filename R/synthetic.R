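#' Parameters for the synthetic network generator
#'
#' The generator emulates the structural features of curated genome-scale
#' model collections that the analyses depend on: multi-compartment models
#' with a biomass reaction, flux bounds, and an implicit environment that
#' guarantees baseline viability. Substrates are drawn from a shared
#' universe so that independently generated models overlap in compounds and
#' reactions, as models within a real collection do.
#'
#' @param n_env_substrates substrates per model (>= 1).
#' @param pathway_depth internal conversion steps from cytoplasmic
#'   substrate to biomass precursor (>= 1).
#' @param redundancy extra random shortcut reactions (1:1 conversions within
#'   a substrate's pathway, so no mass is created and the optimum stays at
#'   its closed form).
#' @param availability environmental availability per substrate
#'   (mmol gDW^-1 h^-1 scale; default 10).
#' @param bound flux bound magnitude for internal reactions (default 100).
#' @param transport_bound flux bound for substrate uptake transports;
#'   defaults to `bound` (environment-limited regime, as in collections
#'   whose growth is limited by nutrient availability). Setting it below
#'   `availability` gives the bound-limited regime in which
#'   bound-relaxation mutations can be beneficial.
#' @param biomass_bound upper bound of the biomass reaction (default 1000).
#' @param universe_size size of the shared substrate universe (default 8).
#' @param n_inert_env inert environmental compounds per model: available in
#'   the environment but consumed by no reaction, emulating the nutrient
#'   richness of curated model environments (default 2, drawn from a shared
#'   pool of 4).
#' @param seed integer; fully determines the generated model.
#' @param collection collection tag.
#' @return List of class `generator_params`.
#' @export
generator_params <- function(n_env_substrates = 3, pathway_depth = 2,
                             redundancy = 1, availability = 10,
                             bound = 100, transport_bound = bound,
                             biomass_bound = 1000, universe_size = 8,
                             n_inert_env = 2, seed = 1L,
                             collection = "synthetic") {
  stopifnot(n_env_substrates >= 1, pathway_depth >= 1, redundancy >= 0,
            availability > 0, bound > 0, transport_bound > 0,
            universe_size >= n_env_substrates)
  structure(list(n_env_substrates = n_env_substrates,
                 pathway_depth = pathway_depth, redundancy = redundancy,
                 availability = availability, bound = bound,
                 transport_bound = transport_bound,
                 biomass_bound = biomass_bound,
                 universe_size = universe_size,
                 n_inert_env = as.integer(n_inert_env),
                 seed = as.integer(seed),
                 collection = collection), class = "generator_params")
}

.substrate_universe <- function(p) sprintf("M%02d", seq_len(p$universe_size))
.orphan_universe <- function() sprintf("Q%02d", 1:4)
.inert_universe <- function() sprintf("W%02d", 1:4)

# chain compound name for substrate X at depth k (k = 0 is X itself)
.chain_cpd <- function(x, k) ifelse(k == 0, x, paste0(x, "p", k))

# Build one model from an explicit substrate specification. `substrates`
# are transported substrates; `orphan_substrates` are consumed directly
# from the extracellular compartment (no cytoplasmic form is ever created).
.build_synthetic <- function(id, substrates, p, orphan_substrates = character(0),
                             rng_seed = p$seed) {
  depth <- p$pathway_depth
  inert <- if (p$n_inert_env > 0)
    withr_seed(substream_seed(rng_seed, "inert"),
               sample(.inert_universe(), min(p$n_inert_env, 4)))
  else character(0)
  cpds <- list()
  add_cpd <- function(base, comp) cpds[[length(cpds) + 1L]] <<- c(base, comp)
  rxn <- list()
  add_rxn <- function(id, stoich, lb, ub, biomass = FALSE, exch = FALSE)
    rxn[[length(rxn) + 1L]] <<- list(id = id, st = stoich, lb = lb, ub = ub,
                                     bio = biomass, ex = exch)
  precursors <- character(0)
  # bounds are mildly heterogeneous so that one constraint binds uniquely
  # (as in real networks, where flux magnitudes differ across reactions):
  # the first substrate's transport carries the smallest bound.
  for (i in seq_along(substrates)) {
    x <- substrates[i]
    add_cpd(x, "e"); add_cpd(x, "c")
    for (k in seq_len(depth)) add_cpd(.chain_cpd(x, k), "c")
    add_rxn(paste0("TR_", x),
            setNames(c(-1, 1), c(cpd_key(x, "e"), cpd_key(x, "c"))),
            0, p$transport_bound * (1 + (i - 1) / 4))
    for (k in seq_len(depth))
      add_rxn(paste0("CNV_", x, "_", k),
              setNames(c(-1, 1), cpd_key(c(.chain_cpd(x, k - 1),
                                           .chain_cpd(x, k)), "c")),
              0, p$bound * (1 + k / 4))
    precursors <- c(precursors, cpd_key(.chain_cpd(x, depth), "c"))
  }
  for (o in orphan_substrates) {
    add_cpd(o, "e"); add_cpd(paste0(o, "prec"), "c")
    add_rxn(paste0("MEM_", o),
            setNames(c(-1, 1), c(cpd_key(o, "e"),
                                 cpd_key(paste0(o, "prec"), "c"))),
            0, p$bound)
    precursors <- c(precursors, cpd_key(paste0(o, "prec"), "c"))
  }
  add_rxn(paste0("BIOMASS_", id), setNames(rep(-1, length(precursors)),
                                           precursors),
          0, p$biomass_bound, biomass = TRUE)
  if (p$redundancy > 0 && depth >= 2) {
    withr_seed(substream_seed(rng_seed, "shortcuts"), {
      for (s in seq_len(p$redundancy)) {
        x <- sample(substrates, 1)
        ks <- sort(sample(0:depth, 2))
        add_rxn(sprintf("SC_%s_%d_%d_%d", x, ks[1], ks[2], s),
                setNames(c(-1, 1), cpd_key(c(.chain_cpd(x, ks[1]),
                                             .chain_cpd(x, ks[2])), "c")),
                0, p$bound)
      }
    })
  }
  for (w in inert) add_cpd(w, "e")
  for (x in c(substrates, orphan_substrates, inert))
    add_rxn(paste0("EX_", x), setNames(-1, cpd_key(x, "e")),
            -p$availability, 0, exch = TRUE)
  cpd_df <- unique(data.frame(base_id = vapply(cpds, `[`, "", 1),
                              compartment = vapply(cpds, `[`, "", 2),
                              stringsAsFactors = FALSE))
  keys <- cpd_key(cpd_df$base_id, cpd_df$compartment)
  tri <- do.call(rbind, lapply(seq_along(rxn), function(k) {
    st <- rxn[[k]]$st
    cbind(match(names(st), keys), k, as.numeric(st))
  }))
  S <- Matrix::sparseMatrix(i = tri[, 1], j = tri[, 2], x = tri[, 3],
                            dims = c(length(keys), length(rxn)))
  reactions <- data.frame(id = vapply(rxn, function(r) r$id, ""),
                          lb = vapply(rxn, function(r) r$lb, 0),
                          ub = vapply(rxn, function(r) r$ub, 0),
                          is_biomass = vapply(rxn, function(r) r$bio, TRUE),
                          is_exchange = vapply(rxn, function(r) r$ex, TRUE),
                          stringsAsFactors = FALSE)
  metabolic_model(id, cpd_df, reactions, S, collection = p$collection)
}

#' Generate a random viable metabolic model
#'
#' Builds a guaranteed-viable backbone: each substrate is taken up,
#' converted through a linear pathway, and feeds one biomass precursor; the
#' biomass reaction consumes one unit of each precursor, so the closed-form
#' maximum growth is `min(availability, transport_bound)` (the chain bounds
#' are never binding at the defaults). Optional shortcut reactions add
#' redundancy without changing the optimum. The model is verified against
#' its closed form by FBA before being returned; on failure the seed is
#' perturbed and generation retried (at most 10 times).
#'
#' @param params a [generator_params()].
#' @param id model identifier (default derived from the seed).
#' @return List: `model` (raw `metabolic_model`), `truth` (list with
#'   `expected_solo_growth`, `substrates`, `defect = "none"`).
#' @export
generate_model <- function(params, id = sprintf("SYN%06d", params$seed)) {
  stopifnot(inherits(params, "generator_params"))
  expected <- min(params$availability, params$transport_bound,
                  1.25 * params$bound)
  for (attempt in 0:9) {
    sd <- substream_seed(params$seed, "model", attempt)
    subs <- withr_seed(sd, sample(.substrate_universe(params),
                                  params$n_env_substrates))
    model <- .build_synthetic(id, subs, params, rng_seed = sd)
    g <- .growth_value(maximize_growth(externalize_environment(model)))
    if (abs(g - expected) <= 1e-6 * max(1, expected))
      return(list(model = model,
                  truth = list(expected_solo_growth = expected,
                               substrates = subs, defect = "none",
                               rescuing_compounds = character(0))))
    warning("generated model failed closed-form verification; retrying")
  }
  stop("could not generate a verified model after 10 attempts")
}

#' Generate a host-endosymbiont pair with a known defect
#'
#' Emulates the two structural causes of endosymbiosis nonviability.
#' `"none"`: the endosymbiont's substrates are a subset of the host's, so
#' every required compound can reach the host cytoplasm and the pair is
#' viable. `"transport_deficient"`: `n_missing` endosymbiont substrates are
#' replaced by substrates the host does not transport; the pair is
#' nonviable and exactly those compounds (recorded in
#' `rescuing_compounds`) must be granted host transport.
#' `"access_deficient"`: the endosymbiont consumes one compound that exists
#' nowhere in cytoplasmic form, so only direct environment access can
#' rescue the pair. `"both"` applies both edits.
#'
#' @param params a [generator_params()].
#' @param defect one of `"none"`, `"transport_deficient"`,
#'   `"access_deficient"`, `"both"`.
#' @param n_missing number of host-untransportable substrates for the
#'   transport defect (default 1).
#' @return List: `host`, `endo` (prepared models), `pair`
#'   (`endosymbiosis_model`), `truth` (defect, rescuing_compounds,
#'   orphan_compounds, expected growths).
#' @export
generate_pair_with_defect <- function(params,
                                      defect = c("none",
                                                 "transport_deficient",
                                                 "access_deficient", "both"),
                                      n_missing = 1L) {
  stopifnot(inherits(params, "generator_params"))
  defect <- match.arg(defect)
  sd <- substream_seed(params$seed, paste0("pair_", defect))
  universe <- .substrate_universe(params)
  n_sub <- params$n_env_substrates
  draw <- withr_seed(sd, {
    host_subs <- sample(universe, n_sub)
    n_endo <- max(1L, n_sub - 1L)
    endo_subs <- sample(host_subs, n_endo)
    missing <- character(0)
    if (defect %in% c("transport_deficient", "both")) {
      pool <- setdiff(universe, host_subs)
      if (length(pool) < n_missing)
        stop("substrate universe too small for the requested defect")
      missing <- sample(pool, n_missing)
      endo_subs <- c(sample(endo_subs,
                            max(0L, length(endo_subs) - n_missing)),
                     missing)
    }
    orphan <- if (defect %in% c("access_deficient", "both"))
      sample(.orphan_universe(), 1) else character(0)
    list(host_subs = host_subs, endo_subs = endo_subs,
         missing = missing, orphan = orphan)
  })
  host <- .build_synthetic(sprintf("HOST%06d", params$seed), draw$host_subs,
                           params, rng_seed = substream_seed(sd, "host"))
  endo <- .build_synthetic(sprintf("ENDO%06d", params$seed), draw$endo_subs,
                           params, orphan_substrates = draw$orphan,
                           rng_seed = substream_seed(sd, "endo"))
  prep <- prepare_collection(list(host, endo))
  pair <- build_pair(prep[[1]], prep[[2]])
  a <- params$availability; tb <- params$transport_bound
  # closed-form pair growth for the defect-free case: per host substrate,
  # the host transport (position-scaled bound) carries host demand plus
  # endosymbiont demand when shared; endosymbiont-internal transports and
  # conversions carry one growth unit each; availability gives one unit per
  # consumer by construction of the joint environment.
  expected_pair_growth <- if (defect == "none") {
    demand <- 1 + as.integer(draw$host_subs %in% draw$endo_subs)
    tb_host <- tb * (1 + (seq_along(draw$host_subs) - 1) / 4)
    tb_endo <- tb * (1 + (seq_along(draw$endo_subs) - 1) / 4)
    min(c(a, tb_host / demand, tb_endo, 1.25 * params$bound))
  } else 0
  list(host = prep[[1]], endo = prep[[2]], pair = pair,
       truth = list(defect = defect, rescuing_compounds = sort(draw$missing),
                    orphan_compounds = draw$orphan,
                    host_substrates = draw$host_subs,
                    endo_substrates = draw$endo_subs,
                    expected_solo_growth = min(a, tb, 1.25 * params$bound),
                    expected_pair_growth = expected_pair_growth))
}

#' Generate a collection of random viable models
#'
#' Builds `n_models` independent viable models over one shared substrate
#' universe, with per-model substrate counts sampled uniformly from
#' 1 to `params$n_env_substrates`. Over a small universe this yields
#' partial substrate overlap between random pairs, and hence a mid-range
#' fraction of viable endosymbiosis configurations, the regime the survey
#' statistics are designed for.
#'
#' @param n_models number of models (>= 2).
#' @param params a [generator_params()]; its `seed` is ignored in favor of
#'   per-model substreams of `seed`.
#' @param seed root seed.
#' @return List of raw `metabolic_model`s.
#' @export
generate_collection <- function(n_models,
                                params = generator_params(universe_size = 3),
                                seed = 1L) {
  stopifnot(n_models >= 2)
  lapply(seq_len(n_models), function(i) {
    sd_i <- substream_seed(seed, "collection_model", i)
    k <- withr_seed(substream_seed(sd_i, "nsub"),
                    sample.int(params$n_env_substrates, 1))
    p_i <- params
    p_i$seed <- sd_i
    p_i$n_env_substrates <- k
    generate_model(p_i, id = sprintf("SYN%04d", i))$model
  })
}

#' Delete a reaction from a model
#'
#' Model surgery used by the strip-and-repair analyses: removes one
#' (non-biomass) reaction column.
#'
#' @param model a `metabolic_model`.
#' @param rxn_id reaction identifier.
#' @return The reduced model.
#' @export
delete_reaction <- function(model, rxn_id) {
  k <- match(rxn_id, model$reactions$id)
  if (is.na(k)) stop("unknown reaction: ", rxn_id)
  if (model$reactions$is_biomass[k]) stop("cannot delete the biomass reaction")
  metabolic_model(model$id, model$compounds,
                  model$reactions[-k, , drop = FALSE],
                  model$S[, -k, drop = FALSE], collection = model$collection,
                  env_lower = model$env_lower, env_upper = model$env_upper,
                  externalized = model$externalized)
}

# hand-written toy model definitions (exact rational coefficients)
.toy_model <- function(name) {
  tsv <- switch(name,
    "TOY-A" = c("# model TOY-A toy", "[compounds]",
                "A\te", "A\tc", "B\tc", "[reactions]",
                "TA\tA[e]\t-1", "TA\tA[c]\t1",
                "R1\tA[c]\t-1", "R1\tB[c]\t1",
                "BIO\tB[c]\t-1",
                "[bounds]", "TA\t0\t100", "R1\t0\t100", "BIO\t0\t1000",
                "[environment]", "A\t-10\t0", "[biomass]", "BIO"),
    "TOY-A2" = c("# model TOY-A2 toy", "[compounds]",
                 "A\te", "A\tc", "B\tc", "[reactions]",
                 "TA\tA[e]\t-1", "TA\tA[c]\t1",
                 "R1\tA[c]\t-1", "R1\tB[c]\t1",
                 "BIO\tB[c]\t-1",
                 "[bounds]", "TA\t0\t100", "R1\t0\t100", "BIO\t0\t1000",
                 "[environment]", "A\t-10\t0", "[biomass]", "BIO"),
    "TOY-B" = c("# model TOY-B toy", "[compounds]",
                "N\te", "N\tc", "P\tc", "[reactions]",
                "TB\tN[e]\t-1", "TB\tN[c]\t1",
                "R1B\tN[c]\t-1", "R1B\tP[c]\t1",
                "BIOB\tP[c]\t-1",
                "[bounds]", "TB\t0\t100", "R1B\t0\t100", "BIOB\t0\t1000",
                "[environment]", "N\t-10\t0", "[biomass]", "BIOB"),
    # TOY-C consumes D directly from its extracellular compartment (D has
    # no cytoplasmic form anywhere); it also carries an A uptake channel it
    # does not need itself, so it can host an A-consuming endosymbiont.
    "TOY-C" = c("# model TOY-C toy", "[compounds]",
                "D\te", "G\tc", "A\te", "A\tc", "[reactions]",
                "RD\tD[e]\t-1", "RD\tG[c]\t1",
                "TCA\tA[e]\t-1", "TCA\tA[c]\t1",
                "BIOC\tG[c]\t-1",
                "[bounds]", "RD\t0\t100", "TCA\t0\t100", "BIOC\t0\t1000",
                "[environment]", "D\t-10\t0", "[biomass]", "BIOC"),
    "TOY-MUT" = c("# model TOY-MUT toy", "[compounds]",
                  "A\te", "A\tc", "B\tc", "[reactions]",
                  "TA\tA[e]\t-1", "TA\tA[c]\t1",
                  "R1\tA[c]\t-1", "R1\tB[c]\t1",
                  "BIO\tB[c]\t-1",
                  "[bounds]", "TA\t0\t5", "R1\t0\t100", "BIO\t0\t1000",
                  "[environment]", "A\t-10\t0", "[biomass]", "BIO"),
    "TOY-R" = c("# model TOY-R toy", "[compounds]",
                "N1\te", "N1\tc", "N2\te", "N2\tc", "P\tc", "[reactions]",
                "TN1\tN1[e]\t-1", "TN1\tN1[c]\t1",
                "TN2\tN2[e]\t-1", "TN2\tN2[c]\t1",
                "RN1\tN1[c]\t-1", "RN1\tP[c]\t1",
                "RN2\tN2[c]\t-1", "RN2\tP[c]\t1",
                "BIOR\tP[c]\t-1",
                "[bounds]", "TN1\t0\t100", "TN2\t0\t100", "RN1\t0\t100",
                "RN2\t0\t100", "BIOR\t0\t1000",
                "[environment]", "N1\t-10\t0", "N2\t-10\t0",
                "[biomass]", "BIOR"),
    stop("unknown fixture: ", name))
  path <- tempfile(fileext = ".tsv")
  writeLines(tsv, path)
  on.exit(unlink(path))
  load_model(path, "toy_tsv")
}

.toy_pair <- function(host_name, endo_name, shared_env = NULL) {
  prep <- prepare_collection(list(.toy_model(host_name),
                                  .toy_model(endo_name)))
  list(host = prep[[1]], endo = prep[[2]],
       pair = build_pair(prep[[1]], prep[[2]], joint_env = shared_env))
}

#' Construct a named analytic fixture
#'
#' Hand-built toy networks with hand-derived optima, used throughout the
#' test suite. Single-model names return `list(model, truth)` with the raw
#' model; pair names return `list(host, endo, pair, truth)` with prepared
#' models; community names additionally carry `shared_env`.
#'
#' Available fixtures: `TOY-A` (linear chain on substrate A, growth 10),
#' `TOY-A2` (identical copy), `TOY-B` (same shape on N), `TOY-C` (consumes
#' D directly from the extracellular compartment; D has no cytoplasmic
#' form), `TOY-MUT` (`TOY-A` with transport bound 5, growth 5), `TOY-R`
#' (two redundant substrate routes), `TOY-PAIR-V` (viable pair, growth 10),
#' `TOY-PAIR-T` (transport-deficient pair, rescued by N), `TOY-PAIR-X`
#' (access-deficient pair), `TOY-PAIR-R` (two redundant rescuers),
#' `TOY-COMM-U` (community with unique growth partition, z = 40),
#' `TOY-COMM-N` (non-unique partition, z = 20).
#'
#' @param name fixture name.
#' @return List as described above.
#' @export
make_fixture <- function(name) {
  single <- list(
    "TOY-A" = 10, "TOY-A2" = 10, "TOY-B" = 10, "TOY-C" = 10,
    "TOY-MUT" = 5, "TOY-R" = 20)
  if (name %in% names(single))
    return(list(model = .toy_model(name),
                truth = list(expected_solo_growth = single[[name]])))
  switch(name,
    "TOY-PAIR-V" = c(.toy_pair("TOY-A", "TOY-A2"),
                     list(truth = list(expected_pair_growth = 10,
                                       defect = "none"))),
    "TOY-PAIR-T" = c(.toy_pair("TOY-A", "TOY-B"),
                     list(truth = list(expected_pair_growth = 0,
                                       defect = "transport_deficient",
                                       rescuing_compounds = "N",
                                       expected_repaired_growth = 10))),
    "TOY-PAIR-X" = c(.toy_pair("TOY-A", "TOY-C"),
                     list(truth = list(expected_pair_growth = 0,
                                       defect = "access_deficient",
                                       orphan_compounds = "D"))),
    "TOY-PAIR-R" = c(.toy_pair("TOY-A", "TOY-R"),
                     list(truth = list(expected_pair_growth = 0,
                                       defect = "transport_deficient",
                                       rescuing_compounds = c("N1", "N2")))),
    "TOY-COMM-U" = {
      env <- met_environment(c("A", "N"), -20, 0)
      fx <- .toy_pair("TOY-A", "TOY-B", shared_env = env)
      c(fx, list(shared_env = env,
                 truth = list(z = 40, host = 20, endo = 20, pair = 0,
                              unique = TRUE)))
    },
    "TOY-COMM-N" = {
      env <- met_environment("A", -20, 0)
      fx <- .toy_pair("TOY-A", "TOY-A2", shared_env = env)
      c(fx, list(shared_env = env,
                 truth = list(z = 20, unique = FALSE)))
    },
    stop("unknown fixture: ", name))
}
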