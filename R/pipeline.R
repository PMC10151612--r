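#' Batched sampling design for pair surveys
#'
#' Pairs are sampled with replacement over unordered model pairs (the two
#' directed configurations are both evaluated); self-pairings of one model
#' instance are excluded. Splitting into batches estimates sampling
#' variation of the reported fractions.
#'
#' @param n_batches number of batches (default 100).
#' @param batch_size pairs per batch (default 1000).
#' @param seed root seed; all randomness flows from it via named substreams.
#' @return List of class `batch_design`.
#' @export
batch_design <- function(n_batches = 100, batch_size = 1000, seed = 1L) {
  stopifnot(n_batches >= 1, batch_size >= 1)
  structure(list(n_batches = as.integer(n_batches),
                 batch_size = as.integer(batch_size),
                 n_pairs = as.integer(n_batches * batch_size),
                 seed = as.integer(seed)), class = "batch_design")
}

# externalize all models once; returns list with collection tag attached
.prep_models <- function(collection) {
  stopifnot(length(collection) >= 2)
  lapply(collection, function(m)
    if (m$externalized) m else externalize_environment(m))
}

# harmonize a duo and build the directed pair (host first)
.duo_pair <- function(mA, mB) {
  h <- harmonize_namespace(list(mA, mB))
  build_pair(h[[1]], h[[2]])
}

#' Survey endosymbiosis viability over a model collection
#'
#' Samples unordered pairs in batches, evaluates both directed
#' configurations of each pair in the joint environment, and reports
#' per-batch viable-configuration fractions plus the neither/only-one/both
#' configuration classes.
#'
#' @param collection list of `metabolic_model`s (one collection).
#' @param design a [batch_design()].
#' @param tolerance viability cutoff.
#' @return `summary_stats` list: `kind`, `records` (one row per sampled
#'   pair), `per_batch`, `viable_fraction` (mean over batches),
#'   `class_fractions`, `design`, `collection`.
#' @export
run_viability_survey <- function(collection, design,
                                 tolerance = VIABILITY_TOL) {
  models <- .prep_models(collection)
  n <- length(models)
  recs <- list()
  for (b in seq_len(design$n_batches)) {
    sd <- substream_seed(design$seed, "viability_sampling", b)
    idx <- withr_seed(sd, t(vapply(seq_len(design$batch_size),
                                   function(i) sample.int(n, 2),
                                   integer(2))))
    for (k in seq_len(nrow(idx))) {
      i <- idx[k, 1]; j <- idx[k, 2]
      pAB <- pair_is_viable(.duo_pair(models[[i]], models[[j]]),
                            tolerance = tolerance)
      pBA <- pair_is_viable(.duo_pair(models[[j]], models[[i]]),
                            tolerance = tolerance)
      cls <- c("neither", "only_one", "both")[pAB$viable + pBA$viable + 1L]
      recs[[length(recs) + 1L]] <- data.frame(
        batch = b, host = models[[i]]$id, endo = models[[j]]$id,
        viable_AB = pAB$viable, viable_BA = pBA$viable,
        growth_AB = pAB$growth, growth_BA = pBA$growth, class = cls,
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, recs)
  per_batch <- do.call(rbind, lapply(split(records, records$batch),
    function(d) data.frame(
      batch = d$batch[1],
      viable_fraction = mean(c(d$viable_AB, d$viable_BA)),
      frac_neither = mean(d$class == "neither"),
      frac_only_one = mean(d$class == "only_one"),
      frac_both = mean(d$class == "both"))))
  rownames(per_batch) <- NULL
  structure(list(
    kind = "viability", records = records, per_batch = per_batch,
    viable_fraction = mean(per_batch$viable_fraction),
    viable_fraction_sd = stats::sd(per_batch$viable_fraction),
    class_fractions = c(neither = mean(per_batch$frac_neither),
                        only_one = mean(per_batch$frac_only_one),
                        both = mean(per_batch$frac_both)),
    design = design, collection = models[[1]]$collection),
    class = "summary_stats")
}

# sample viable directed pairs; returns list of built pair contexts
.sample_viable_pairs <- function(models, n_wanted, seed, stream,
                                 tolerance = VIABILITY_TOL,
                                 require_slower = FALSE,
                                 max_attempts = 50 * n_wanted) {
  n <- length(models)
  out <- list()
  attempt <- 0L
  while (length(out) < n_wanted && attempt < max_attempts) {
    attempt <- attempt + 1L
    ij <- withr_seed(substream_seed(seed, stream, attempt),
                     sample.int(n, 2))
    pair <- .duo_pair(models[[ij[1]]], models[[ij[2]]])
    pv <- pair_is_viable(pair, tolerance = tolerance)
    if (!pv$viable) next
    host_g <- .growth_value(maximize_growth(pair$host, pair$joint_env))
    endo_g <- .growth_value(maximize_growth(pair$endo, pair$joint_env))
    if (require_slower &&
        !(pv$growth < host_g && pv$growth < endo_g)) next
    out[[length(out) + 1L]] <- list(pair = pair, growth = pv$growth,
                                    host_growth = host_g,
                                    endo_growth = endo_g)
  }
  out
}

#' Survey survival and growth competition over a model collection
#'
#' Samples viable directed pairs per batch and, for each, runs the
#' single-compound perturbation screen against both ancestors, the pairwise
#' growth-rate comparisons in the joint environment, and the shared
#' two-step community growth computation (non-unique partitions are
#' excluded from community statistics and counted).
#'
#' @inheritParams run_viability_survey
#' @return `summary_stats` list with per-pair `records`, `per_batch`
#'   fractions, pooled `scenario_frequencies`, `identical_fraction`,
#'   `host_faster_fraction`, `endo_faster_fraction`,
#'   `community_pair_slower_than_both`, `n_nonunique_excluded`.
#' @export
run_competition_survey <- function(collection, design,
                                   tolerance = VIABILITY_TOL) {
  models <- .prep_models(collection)
  recs <- list(); scen <- integer(0)
  for (b in seq_len(design$n_batches)) {
    ctxs <- .sample_viable_pairs(models, design$batch_size, design$seed,
                                 paste0("competition_b", b), tolerance)
    for (ctx in ctxs) {
      pair <- ctx$pair
      scr <- survival_screen(pair, pair$host, pair$endo,
                             tolerance = tolerance)
      sc_tab <- table(factor(scr$records$scenario,
                             levels = scenario_levels()))
      scen <- if (length(scen)) scen + as.integer(sc_tab) else
        as.integer(sc_tab)
      rfh <- pairwise_relative_fitness(ctx$growth, ctx$host_growth,
                                       tolerance)
      rfe <- pairwise_relative_fitness(ctx$growth, ctx$endo_growth,
                                       tolerance)
      comm <- community_growth(pair$host, pair$endo, pair)
      rob <- setNames(scr$robustness$proportion, scr$robustness$metabolism)
      recs[[length(recs) + 1L]] <- data.frame(
        batch = b, host = pair$host$id, endo = pair$endo$id,
        pair_growth = ctx$growth, host_growth = ctx$host_growth,
        endo_growth = ctx$endo_growth,
        robustness_pair = rob[["pair"]], robustness_host = rob[["host"]],
        robustness_endo = rob[["endo"]],
        n_perturbations = nrow(scr$records),
        identical_fraction = if (nrow(scr$records)) mean(
          scr$records$scenario %in% c("all_viable", "all_nonviable")) else NA,
        vs_host_class = rfh$class, vs_host_advantage = rfh$advantage,
        vs_endo_class = rfe$class, vs_endo_advantage = rfe$advantage,
        community_feasible = comm$feasible, community_z = comm$z,
        community_unique = comm$unique,
        community_pair = comm$entities$max[comm$entities$entity == "pair"],
        community_host = comm$entities$max[comm$entities$entity == "host"],
        community_endo = comm$entities$max[comm$entities$entity == "endo"],
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, recs)
  if (is.null(records)) stop("no viable pairs found in the collection")
  uniq <- records[records$community_unique & records$community_feasible, ,
                  drop = FALSE]
  per_batch <- do.call(rbind, lapply(split(records, records$batch),
    function(d) data.frame(
      batch = d$batch[1], n_pairs = nrow(d),
      identical_fraction = mean(d$identical_fraction, na.rm = TRUE),
      host_faster_fraction = mean(d$vs_host_class == "slower"),
      endo_faster_fraction = mean(d$vs_endo_class == "slower"))))
  rownames(per_batch) <- NULL
  scen_freq <- scen / max(1L, sum(scen))
  names(scen_freq) <- scenario_levels()
  structure(list(
    kind = "competition", records = records, per_batch = per_batch,
    scenario_frequencies = scen_freq,
    identical_fraction = mean(records$identical_fraction, na.rm = TRUE),
    host_faster_fraction = mean(records$vs_host_class == "slower"),
    endo_faster_fraction = mean(records$vs_endo_class == "slower"),
    community_pair_slower_than_both = if (nrow(uniq)) mean(
      uniq$community_pair < pmin(uniq$community_host,
                                 uniq$community_endo) - 1e-9 |
        (uniq$community_pair < tolerance &
           pmin(uniq$community_host, uniq$community_endo) >= tolerance))
      else NA_real_,
    n_nonunique_excluded = sum(!records$community_unique |
                                 !records$community_feasible),
    design = design, collection = models[[1]]$collection),
    class = "summary_stats")
}

#' Survey evolvability of slower-than-ancestor endosymbioses
#'
#' Samples viable pairs that grow more slowly than both ancestors, scans
#' all single bound-relaxation mutations in the four contexts, and
#' aggregates beneficial-mutation counts, paired sign-rank comparisons
#' against the ancestors, and exceed-ancestor fractions.
#'
#' @inheritParams run_viability_survey
#' @param factor bound-relaxation factor (default 1000).
#' @return `summary_stats` list with per-pair `records`, sign-rank results
#'   (`signrank_host`, `signrank_endo`), pooled
#'   `exceeds_host_fraction` / `exceeds_endo_fraction` (over beneficial
#'   pair mutations), and `any_pair_max_exceeds_ancestors`.
#' @export
run_evolvability_survey <- function(collection, design, factor = 1000,
                                    tolerance = VIABILITY_TOL) {
  models <- .prep_models(collection)
  recs <- list(); pooled_exc_h <- c(0L, 0L); pooled_exc_e <- c(0L, 0L)
  for (b in seq_len(design$n_batches)) {
    ctxs <- .sample_viable_pairs(models, design$batch_size, design$seed,
                                 paste0("evolvability_b", b), tolerance,
                                 require_slower = TRUE)
    for (ctx in ctxs) {
      pair <- ctx$pair
      cmp <- compare_evolvability(pair, pair$host, pair$endo,
                                  factor = factor)
      nb <- cmp$n_beneficial
      get0n <- function(nm) if (nm %in% names(nb)) nb[[nm]] else 0
      pb <- cmp$scans[cmp$scans$beneficial &
                        startsWith(cmp$scans$context, "pair_"), ,
                      drop = FALSE]
      pooled_exc_h <- pooled_exc_h +
        c(sum(pb$mutated > cmp$ancestor_growth[["host"]]), nrow(pb))
      pooled_exc_e <- pooled_exc_e +
        c(sum(pb$mutated > cmp$ancestor_growth[["endo"]]), nrow(pb))
      recs[[length(recs) + 1L]] <- data.frame(
        batch = b, host = pair$host$id, endo = pair$endo$id,
        pair_growth = ctx$growth, host_growth = ctx$host_growth,
        endo_growth = ctx$endo_growth,
        nb_ancestral_host = get0n("ancestral_host"),
        nb_ancestral_endo = get0n("ancestral_endo"),
        nb_pair_host = get0n("pair_host_reaction"),
        nb_pair_endo = get0n("pair_endo_reaction"),
        exceeds_host_fraction = cmp$exceeds_host_fraction,
        exceeds_endo_fraction = cmp$exceeds_endo_fraction,
        max_growth_pair = cmp$max_growth[["pair"]],
        max_growth_host = cmp$max_growth[["host"]],
        max_growth_endo = cmp$max_growth[["endo"]],
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, recs)
  if (is.null(records))
    stop("no slower-than-ancestors viable pairs found")
  structure(list(
    kind = "evolvability", records = records,
    signrank_host = signrank_test(records$nb_pair_host,
                                  records$nb_ancestral_host),
    signrank_endo = signrank_test(records$nb_pair_endo,
                                  records$nb_ancestral_endo),
    exceeds_host_fraction = if (pooled_exc_h[2] > 0)
      pooled_exc_h[1] / pooled_exc_h[2] else NA_real_,
    exceeds_endo_fraction = if (pooled_exc_e[2] > 0)
      pooled_exc_e[1] / pooled_exc_e[2] else NA_real_,
    any_pair_max_exceeds_ancestors = any(
      records$max_growth_pair > pmax(records$max_growth_host,
                                     records$max_growth_endo) + 1e-9),
    design = design, collection = models[[1]]$collection),
    class = "summary_stats")
}

#' Compare per-batch viable fractions across collections
#'
#' One-way ANOVA (from the sum-of-squares definitions, see
#' [oneway_anova()]) over the per-batch viable-configuration fractions of
#' two or more viability surveys. Collections with fewer than two batches
#' are excluded with a warning.
#'
#' @param stats_list list of viability `summary_stats`.
#' @return List: `anova` (see [oneway_anova()]), `collections`, `means`.
#' @export
summarize_across_collections <- function(stats_list) {
  ok <- vapply(stats_list, function(s)
    nrow(s$per_batch) >= 2, logical(1))
  if (any(!ok))
    warning("excluding ", sum(!ok), " collection(s) with < 2 batches")
  stats_list <- stats_list[ok]
  if (length(stats_list) < 2)
    stop("need at least two collections with >= 2 batches")
  groups <- lapply(stats_list, function(s) s$per_batch$viable_fraction)
  list(anova = oneway_anova(groups),
       collections = vapply(stats_list, function(s) s$collection, ""),
       means = vapply(stats_list, function(s) s$viable_fraction, 0))
}

#' @export
print.summary_stats <- function(x, ...) {
  cat("<summary_stats>", x$kind, "survey on collection", x$collection,
      "\n pairs:", nrow(x$records), " batches:", x$design$n_batches, "\n")
  invisible(x)
}

#' Write survey outputs as tidy CSV plus a JSON summary
#'
#' Writes `records.csv` (one row per sampled pair), `batches.csv` when the
#' survey has per-batch fractions, and `summary.json` with the aggregate
#' quantities, using fixed formatting so identical surveys produce
#' byte-identical files.
#'
#' @param stats a `summary_stats` object.
#' @param dir output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_survey_csv <- function(stats, dir) {
  stopifnot(inherits(stats, "summary_stats"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  fmt <- function(d) {
    num <- vapply(d, is.numeric, logical(1))
    d[num] <- lapply(d[num], function(v) format(v, digits = 12, trim = TRUE,
                                                scientific = FALSE))
    d
  }
  f <- file.path(dir, "records.csv")
  write.csv(fmt(stats$records), f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)
  if (!is.null(stats$per_batch)) {
    f <- file.path(dir, "batches.csv")
    write.csv(fmt(stats$per_batch), f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  summ <- stats[setdiff(names(stats), c("records", "per_batch", "design"))]
  summ$seed <- stats$design$seed
  summ$n_batches <- stats$design$n_batches
  summ$batch_size <- stats$design$batch_size
  f <- file.path(dir, "summary.json")
  jsonlite::write_json(summ, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, f)
  invisible(files)
}
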