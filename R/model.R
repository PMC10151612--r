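#' @useDynLib endofba, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods as is
#' @importFrom stats runif setNames
#' @importFrom utils head write.csv
NULL

cpd_key <- function(base_id, compartment) paste0(base_id, "[", compartment, "]")

.valid_compartments <- c("c", "e", "p")

#' Construct a metabolic model
#'
#' Low-level constructor for the package's central container: a stoichiometric
#' system over compounds identified by `(base_id, compartment)` with flux
#' bounds per reaction and, once externalized, per-compound environment bounds
#' on compound derivatives.
#'
#' @param id model identifier.
#' @param compounds data.frame with columns `base_id`, `compartment`
#'   (`"c"`, `"e"` or `"p"`); row order fixes the row order of `S`.
#' @param reactions data.frame with columns `id`, `lb`, `ub`, `is_biomass`,
#'   `is_exchange`.
#' @param S compounds x reactions stoichiometric matrix (coerced to sparse).
#' @param collection collection tag; models are only ever paired within one
#'   collection.
#' @param env_lower,env_upper per-compound derivative bounds (externalized
#'   models); defaults to all zero.
#' @param externalized logical; `TRUE` once exchange reactions have been
#'   replaced by environment bounds.
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, compounds, reactions, S,
                            collection = "default",
                            env_lower = NULL, env_upper = NULL,
                            externalized = FALSE) {
  stopifnot(is.data.frame(compounds), is.data.frame(reactions))
  compounds$base_id <- as.character(compounds$base_id)
  compounds$compartment <- as.character(compounds$compartment)
  if (!all(compounds$compartment %in% .valid_compartments))
    stop("unknown compartment code: ",
         paste(setdiff(compounds$compartment, .valid_compartments),
               collapse = ", "))
  compounds$key <- cpd_key(compounds$base_id, compounds$compartment)
  if (anyDuplicated(compounds$key))
    stop("duplicate (base_id, compartment) in compound namespace")
  reactions$id <- as.character(reactions$id)
  if (anyDuplicated(reactions$id)) stop("duplicate reaction ids")
  if (is.null(reactions$is_exchange)) reactions$is_exchange <- FALSE
  S <- as(as(Matrix::Matrix(S, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  stopifnot(nrow(S) == nrow(compounds), ncol(S) == nrow(reactions))
  dimnames(S) <- list(compounds$key, reactions$id)
  if (sum(reactions$is_biomass) != 1L)
    stop("model must have exactly one biomass reaction, found ",
         sum(reactions$is_biomass))
  if (any(reactions$lb > reactions$ub))
    stop("reaction lower bound exceeds upper bound")
  empty <- Matrix::colSums(S != 0) == 0
  if (any(empty))
    stop("reaction with empty stoichiometry: ",
         paste(reactions$id[empty], collapse = ", "))
  if (is.null(env_lower)) env_lower <- numeric(nrow(compounds))
  if (is.null(env_upper)) env_upper <- numeric(nrow(compounds))
  structure(list(id = id, collection = collection,
                 compounds = compounds[, c("key", "base_id", "compartment")],
                 reactions = reactions[, c("id", "lb", "ub",
                                           "is_biomass", "is_exchange")],
                 S = S, biomass = which(reactions$is_biomass),
                 env_lower = as.numeric(env_lower),
                 env_upper = as.numeric(env_upper),
                 externalized = isTRUE(externalized)),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model>", x$id, " [", x$collection, "]\n",
      " compounds: ", nrow(x$compounds),
      "  reactions: ", nrow(x$reactions),
      "  biomass: ", x$reactions$id[x$biomass],
      if (x$externalized) "  (externalized)" else "  (raw)", "\n", sep = "")
  invisible(x)
}

#' Environment: per-compound availability bounds
#'
#' An environment is a set of extracellular compounds with bounds on their
#' concentration derivatives: a negative lower bound permits net consumption
#' (uptake) by cells, a positive upper bound permits net accumulation
#' (secretion). Every entry must satisfy `lower <= 0 <= upper`.
#'
#' @param base_id character vector of compound identifiers (extracellular).
#' @param lower,upper derivative bounds, recycled to the length of `base_id`.
#' @return Object of class `met_environment` (a data.frame).
#' @export
met_environment <- function(base_id = character(), lower = numeric(),
                            upper = numeric()) {
  env <- data.frame(base_id = as.character(base_id),
                    lower = rep_len(as.numeric(lower), length(base_id)),
                    upper = rep_len(as.numeric(upper), length(base_id)),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(env$base_id)) stop("duplicate compound in environment")
  if (any(env$lower > 0) || any(env$upper < 0))
    stop("environment bounds must satisfy lower <= 0 <= upper")
  class(env) <- c("met_environment", "data.frame")
  env
}

#' Extract the environment of an externalized model
#'
#' @param model an externalized `metabolic_model`.
#' @param keep_zero keep extracellular compounds whose bounds are both zero.
#' @return A [met_environment()].
#' @export
environment_of <- function(model, keep_zero = FALSE) {
  stopifnot(inherits(model, "metabolic_model"))
  if (!model$externalized)
    stop("model must be externalized before extracting its environment")
  is_e <- model$compounds$compartment == "e"
  sel <- is_e & (keep_zero | model$env_lower != 0 | model$env_upper != 0)
  met_environment(model$compounds$base_id[sel],
                  model$env_lower[sel], model$env_upper[sel])
}

#' Merge two environments by elementwise bound summation
#'
#' The joint environment of two metabolisms sums the per-compound derivative
#' bounds, so each ancestor remains independently viable in the merged
#' environment (summing intervals that contain zero only relaxes constraints).
#' Compounds present in a single input carry the other's implicit `(0, 0)`.
#'
#' @param envA,envB [met_environment()] objects.
#' @return Merged [met_environment()].
#' @export
merge_environments <- function(envA, envB) {
  ids <- sort(union(envA$base_id, envB$base_id))
  la <- setNames(rep(0, length(ids)), ids); ua <- la
  la[envA$base_id] <- envA$lower; ua[envA$base_id] <- envA$upper
  lb <- setNames(rep(0, length(ids)), ids); ub <- lb
  lb[envB$base_id] <- envB$lower; ub[envB$base_id] <- envB$upper
  met_environment(ids, la + lb, ua + ub)
}

#' Harmonize compound namespaces across models of one collection
#'
#' Rebuilds every model on the union namespace (the sorted set of all
#' `(base_id, compartment)` pairs seen) so that the same row corresponds to
#' the same compound across models. Stoichiometry, bounds and environment
#' vectors are carried over; rows a model never references are zero.
#'
#' @param models list of `metabolic_model` objects sharing one collection tag.
#' @return List of models on the shared namespace.
#' @export
harmonize_namespace <- function(models) {
  stopifnot(length(models) >= 1)
  tags <- unique(vapply(models, function(m) m$collection, character(1)))
  if (length(tags) != 1)
    stop("models must come from a single collection, found: ",
         paste(tags, collapse = ", "))
  allc <- unique(do.call(rbind, lapply(models, function(m)
    m$compounds[, c("base_id", "compartment")])))
  allc <- allc[order(cpd_key(allc$base_id, allc$compartment)), , drop = FALSE]
  rownames(allc) <- NULL
  keys <- cpd_key(allc$base_id, allc$compartment)
  lapply(models, function(m) {
    idx <- match(m$compounds$key, keys)
    Tm <- as(m$S, "TsparseMatrix")
    S <- Matrix::sparseMatrix(i = idx[Tm@i + 1L], j = Tm@j + 1L, x = Tm@x,
                              dims = c(length(keys), ncol(m$S)))
    el <- numeric(length(keys)); eu <- numeric(length(keys))
    el[idx] <- m$env_lower; eu[idx] <- m$env_upper
    metabolic_model(m$id, allc, m$reactions, S, collection = m$collection,
                    env_lower = el, env_upper = eu,
                    externalized = m$externalized)
  })
}

#' Replace exchange reactions by environment bounds
#'
#' Each exchange (source/sink) reaction must touch exactly one extracellular
#' compound with coefficient +/-1. Its flux bounds are transferred,
#' sign-adjusted, to the compound's derivative bounds (negative lower bound =
#' permitted uptake) and the column is removed: with the exchange flux
#' eliminated, steady state of the compound row relaxes to
#' `env_lower <= sum_k S[j,k] x_k <= env_upper`, which leaves the maximum
#' growth unchanged. Duplicate exchanges for one compound have their bounds
#' summed (with a warning). Internal compounds keep `[0, 0]` (steady state).
#'
#' @param model a raw `metabolic_model` with flagged exchange reactions.
#' @return The externalized model.
#' @export
externalize_environment <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  if (model$externalized) return(model)
  ex <- which(model$reactions$is_exchange)
  el <- numeric(nrow(model$compounds)); eu <- numeric(nrow(model$compounds))
  for (k in ex) {
    col <- model$S[, k]
    nz <- which(col != 0)
    if (length(nz) != 1)
      stop("exchange reaction ", model$reactions$id[k],
           " touches ", length(nz), " compounds (expected 1)")
    if (model$compounds$compartment[nz] != "e")
      stop("exchange reaction ", model$reactions$id[k],
           " touches a non-extracellular compound")
    coef <- col[nz]
    if (abs(abs(coef) - 1) > 1e-12)
      stop("exchange reaction ", model$reactions$id[k],
           " must have coefficient +/-1")
    l <- model$reactions$lb[k]; u <- model$reactions$ub[k]
    # steady state of the row gives c'_rest = -coef * r
    if (coef < 0) { lo <- l; hi <- u } else { lo <- -u; hi <- -l }
    if (el[nz] != 0 || eu[nz] != 0)
      warning("duplicate exchange for ", model$compounds$key[nz],
              "; bounds summed")
    el[nz] <- el[nz] + lo
    eu[nz] <- eu[nz] + hi
  }
  if (any(el > 0) || any(eu < 0))
    stop("externalized environment violates lower <= 0 <= upper")
  keep <- setdiff(seq_len(nrow(model$reactions)), ex)
  metabolic_model(model$id, model$compounds,
                  model$reactions[keep, , drop = FALSE],
                  model$S[, keep, drop = FALSE],
                  collection = model$collection,
                  env_lower = el, env_upper = eu, externalized = TRUE)
}

#' Harmonize and externalize a set of models
#'
#' Convenience wrapper: externalize each model, then harmonize the namespace.
#'
#' @param models list of raw `metabolic_model` objects.
#' @return List of prepared models on a shared namespace.
#' @export
prepare_collection <- function(models) {
  harmonize_namespace(lapply(models, externalize_environment))
}

#' Partition a model for its role as endosymbiont
#'
#' An endosymbiont's extracellular compartment is its host's cytoplasm. The
#' stoichiometric matrix is split by rows: compounds strictly inside the
#' endosymbiont (its `c` and `p` compartments) form `S_E`, whose rows stay
#' private and balanced; extracellular rows are re-mapped to the
#' corresponding `base_id[c]` rows of the shared namespace and form
#' `S_EtoH`. An extracellular compound whose `base_id` has no cytoplasmic row
#' anywhere in the namespace is kept on a flagged fresh orphan row --
#' structural evidence that the endosymbiont may need direct environment
#' access.
#'
#' @param model a prepared (harmonized, externalized) `metabolic_model`.
#' @return List with sparse matrices `S_E` (rownames = private keys) and
#'   `S_EtoH` (rownames = host-side target keys), plus `orphans`, the base
#'   ids mapped to orphan rows.
#' @export
partition_for_endosymbiont <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  if (!model$externalized) stop("partition requires an externalized model")
  comp <- model$compounds
  internal <- comp$compartment %in% c("c", "p")
  S_E <- model$S[internal, , drop = FALSE]
  rownames(S_E) <- comp$key[internal]
  ext <- which(comp$compartment == "e")
  target <- cpd_key(comp$base_id[ext], "c")
  known <- target %in% comp$key
  target[!known] <- paste0(comp$base_id[ext][!known], "[orphan]")
  S_EtoH <- model$S[ext, , drop = FALSE]
  rownames(S_EtoH) <- target
  list(S_E = S_E, S_EtoH = S_EtoH,
       orphans = comp$base_id[ext][!known])
}

#' Fraction of reactions shared between two models
#'
#' Jaccard index of the two reaction-id sets; a simple predictor of whether a
#' pairing forms a viable endosymbiosis.
#'
#' @param modelA,modelB `metabolic_model` objects.
#' @return Numeric in `[0, 1]`.
#' @export
shared_reaction_fraction <- function(modelA, modelB) {
  a <- modelA$reactions$id[!modelA$reactions$is_exchange]
  b <- modelB$reactions$id[!modelB$reactions$is_exchange]
  u <- union(a, b)
  if (length(u) == 0) return(0)
  length(intersect(a, b)) / length(u)
}
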