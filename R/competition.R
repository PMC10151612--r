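#' Enumerate single-compound environmental perturbations
#'
#' Every compound the environment makes available for uptake (negative lower
#' bound) can be removed, one at a time.
#'
#' @param env a [met_environment()].
#' @return Character vector of base ids, each listed once.
#' @export
enumerate_perturbations <- function(env) {
  sort(env$base_id[env$lower < 0])
}

#' Remove one compound from an environment
#'
#' Removal zeroes only the uptake side (`lower := 0`): an absent compound
#' cannot be consumed, but cells may still secrete it, so the upper bound is
#' untouched. Removal is idempotent.
#'
#' @param env a [met_environment()].
#' @param compound base id present in `env`.
#' @return The perturbed environment.
#' @export
perturb <- function(env, compound) {
  i <- match(compound, env$base_id)
  if (is.na(i)) stop("compound not in environment: ", compound)
  env$lower[i] <- 0
  env
}

#' Classify a viability triple into one of eight scenarios
#'
#' The three booleans (pair, ancestral host, ancestral endosymbiont viable)
#' partition outcomes into eight exhaustive, mutually exclusive classes: all
#' viable, all nonviable, and six mixed patterns.
#'
#' @param pair_viable,host_viable,endo_viable logicals.
#' @return Scenario label (character).
#' @export
classify_scenario <- function(pair_viable, host_viable, endo_viable) {
  stopifnot(is.logical(pair_viable), is.logical(host_viable),
            is.logical(endo_viable))
  code <- paste0(as.integer(pair_viable), as.integer(host_viable),
                 as.integer(endo_viable))
  unname(c("111" = "all_viable",         "000" = "all_nonviable",
           "011" = "only_pair_nonviable", "101" = "only_host_nonviable",
           "110" = "only_endo_nonviable", "100" = "only_pair_viable",
           "010" = "only_host_viable",    "001" = "only_endo_viable")[code])
}

#' All eight scenario labels
#' @export
scenario_levels <- function() {
  c("all_viable", "all_nonviable", "only_pair_nonviable",
    "only_host_nonviable", "only_endo_nonviable", "only_pair_viable",
    "only_host_viable", "only_endo_viable")
}

#' Survival screen under single-compound environmental degradation
#'
#' For each removable compound of the joint environment, re-evaluates the
#' viability of the endosymbiosis and of both ancestral metabolisms in the
#' perturbed environment, classifies the scenario, and summarizes robustness
#' (proportion of perturbations survived) per metabolism.
#'
#' @param pair an `endosymbiosis_model`.
#' @param host,endo the ancestral `metabolic_model`s.
#' @param env the joint [met_environment()]; defaults to the pair's.
#' @param tolerance viability cutoff.
#' @return List of class `survival_screen`: `records` (one row per
#'   perturbation: `removed_compound`, three viability flags, `scenario`)
#'   and `robustness` (per metabolism: survived, total, proportion).
#' @export
survival_screen <- function(pair, host, endo, env = pair$joint_env,
                            tolerance = VIABILITY_TOL) {
  compounds <- enumerate_perturbations(env)
  rec <- lapply(compounds, function(b) {
    penv <- perturb(env, b)
    pv <- pair_is_viable(pair, penv, tolerance = tolerance)$viable
    hv <- is_viable(host, penv, tolerance = tolerance)$viable
    ev <- is_viable(endo, penv, tolerance = tolerance)$viable
    data.frame(removed_compound = b, pair_viable = pv, host_viable = hv,
               endo_viable = ev,
               scenario = classify_scenario(pv, hv, ev),
               stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, rec)
  if (is.null(records))
    records <- data.frame(removed_compound = character(0),
                          pair_viable = logical(0), host_viable = logical(0),
                          endo_viable = logical(0), scenario = character(0))
  n <- nrow(records)
  robustness <- data.frame(
    metabolism = c("pair", "host", "endo"),
    survived = c(sum(records$pair_viable), sum(records$host_viable),
                 sum(records$endo_viable)),
    total = n)
  robustness$proportion <- ifelse(robustness$total > 0,
                                  robustness$survived / robustness$total, NA)
  structure(list(records = records, robustness = robustness),
            class = "survival_screen")
}

#' Relative fitness of a focal versus a reference growth rate
#'
#' `advantage = (focal - reference) / reference`, classified as faster,
#' slower, or equal at a relative tolerance of `1e-6`. Undefined (flagged)
#' when the reference is below the viability tolerance.
#'
#' @param focal,reference growth rates measured in the same environment.
#' @param tolerance viability cutoff for the reference.
#' @return List of class `relative_fitness`: `advantage`, `class`
#'   (`"faster"`, `"slower"`, `"equal"` or `NA`), `defined`.
#' @export
pairwise_relative_fitness <- function(focal, reference,
                                      tolerance = VIABILITY_TOL) {
  if (!is.finite(reference) || reference < tolerance)
    return(structure(list(advantage = NA_real_, class = NA_character_,
                          defined = FALSE), class = "relative_fitness"))
  adv <- (focal - reference) / reference
  cls <- if (abs(adv) <= 1e-6) "equal" else if (adv > 0) "faster" else "slower"
  structure(list(advantage = adv, class = cls, defined = TRUE),
            class = "relative_fitness")
}

# Assemble the shared-environment community LP over three entities (host,
# endo, pair), pooling extracellular consumption against one set of
# environment bounds. Returns the LP pieces plus objective columns.
.community_lp <- function(host, endo, pair, shared_env) {
  eH <- host$compounds$compartment == "e"
  keysH <- host$compounds$key
  # block columns: host entity | endo entity | pair entity
  nH <- nrow(host$reactions); nE <- nrow(endo$reactions); nP <- ncol(pair$A)
  # shared extracellular rows: union of e-keys across the namespace
  e_keys <- keysH[eH]                     # harmonized => same for endo
  # rows: shared e rows; host internal; endo internal; pair non-e rows (+eq)
  int_keysH <- keysH[!eH]
  pair_keys <- rownames(pair$A)
  pair_is_e <- pair_keys %in% e_keys
  tri <- list()
  add_block <- function(M, row_names, col_off, row_map) {
    Tm <- as(M, "TsparseMatrix")
    ri <- row_map[row_names[Tm@i + 1L]]
    tri[[length(tri) + 1L]] <<- cbind(ri, Tm@j + 1L + col_off, Tm@x)
  }
  row_keys <- c(paste0("env:", e_keys), paste0("H:", int_keysH),
                paste0("E:", int_keysH), paste0("P:", pair_keys[!pair_is_e]))
  n_row <- length(row_keys) + 1L          # +1 community-sum row (added later)
  map_host <- setNames(match(
    ifelse(eH, paste0("env:", keysH), paste0("H:", keysH)), row_keys), keysH)
  map_endo <- setNames(match(
    ifelse(eH, paste0("env:", keysH), paste0("E:", keysH)), row_keys), keysH)
  map_pair <- setNames(match(
    ifelse(pair_is_e, paste0("env:", pair_keys), paste0("P:", pair_keys)),
    row_keys), pair_keys)
  add_block(host$S, keysH, 0L, map_host)
  add_block(endo$S, keysH, nH, map_endo)
  add_block(pair$A, pair_keys, nH + nE, map_pair)
  tri <- do.call(rbind, tri)
  A <- Matrix::sparseMatrix(i = tri[, 1], j = tri[, 2], x = tri[, 3],
                            dims = c(length(row_keys), nH + nE + nP))
  rownames(A) <- row_keys
  row_lb <- numeric(length(row_keys)); row_ub <- row_lb
  base_of_e <- sub("\\[e\\]$", "", sub("^env:", "", row_keys))
  idx <- match(base_of_e, shared_env$base_id)
  hit <- which(startsWith(row_keys, "env:") & !is.na(idx))
  row_lb[hit] <- shared_env$lower[idx[hit]]
  row_ub[hit] <- shared_env$upper[idx[hit]]
  bio <- c(host$biomass, nH + endo$biomass, nH + nE + pair$biomass_host)
  keep <- Matrix::rowSums(A != 0) > 0 | row_lb > 0 | row_ub < 0
  list(A = A[keep, , drop = FALSE], row_lb = row_lb[keep],
       row_ub = row_ub[keep],
       lb = c(host$reactions$lb, endo$reactions$lb, pair$lb),
       ub = c(host$reactions$ub, endo$reactions$ub, pair$ub),
       biomass = bio)
}

#' Two-step community growth in a shared environment
#'
#' Step 1 maximizes the summed biomass flux of the three co-occurring
#' entities (ancestral host, ancestral endosymbiont, host-endosymbiont
#' pair), with their extracellular consumption pooled against one set of
#' environment bounds; the optimum is `z`. Step 2 maximizes and minimizes
#' each entity's biomass flux with the community total held at `z`, to
#' detect non-unique growth partitions. An entity's growth is unique when
#' its range is within 10% of its maximum (entities with maximum 0 count as
#' unique), and the community result is unique when all three entities are.
#'
#' @param host,endo prepared ancestral `metabolic_model`s.
#' @param pair the `endosymbiosis_model` built from them.
#' @param shared_env the shared [met_environment()] (the joint environment
#'   by default).
#' @param backend LP backend.
#' @return List of class `community_growth`: `z`, `entities` (data.frame
#'   with max/min biomass per entity), `unique`, `feasible`.
#' @export
community_growth <- function(host, endo, pair,
                             shared_env = pair$joint_env,
                             backend = c("simplex", "boot")) {
  backend <- match.arg(backend)
  lp <- .community_lp(host, endo, pair, shared_env)
  n <- ncol(lp$A)
  obj_sum <- numeric(n); obj_sum[lp$biomass] <- 1
  s1 <- solve_lp(obj_sum, lp$A, lp$row_lb, lp$row_ub, lp$lb, lp$ub,
                 maximize = TRUE, backend = backend)
  ent_names <- c("host", "endo", "pair")
  if (!identical(s1$status, "optimal")) {
    entities <- data.frame(entity = ent_names, max = 0, min = 0,
                           unique = TRUE)
    return(structure(list(z = 0, entities = entities, unique = TRUE,
                          feasible = FALSE), class = "community_growth"))
  }
  z <- s1$objective
  A2 <- rbind(lp$A, Matrix::Matrix(obj_sum, nrow = 1, sparse = TRUE))
  rl2 <- c(lp$row_lb, z); ru2 <- c(lp$row_ub, z)
  opt <- function(i, maximize) {
    obj <- numeric(n); obj[lp$biomass[i]] <- 1
    s <- solve_lp(obj, A2, rl2, ru2, lp$lb, lp$ub, maximize = maximize,
                  backend = backend)
    if (identical(s$status, "optimal")) s$objective else NA_real_
  }
  mx <- vapply(1:3, opt, numeric(1), maximize = TRUE)
  mn <- vapply(1:3, opt, numeric(1), maximize = FALSE)
  uni <- ifelse(mx <= 1e-9, TRUE, (mx - mn) / mx <= 0.10)
  entities <- data.frame(entity = ent_names, max = mx, min = mn,
                         unique = uni)
  structure(list(z = z, entities = entities, unique = all(uni),
                 feasible = TRUE), class = "community_growth")
}

#' @export
print.community_growth <- function(x, ...) {
  cat("<community_growth> z:", format(x$z, digits = 6),
      " unique:", x$unique, "\n")
  print(x$entities)
  invisible(x)
}
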