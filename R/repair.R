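# internal: append extra reaction columns to a pair system
.augment_pair <- function(pair, cols, ids, lb, ub) {
  if (!length(ids)) return(pair)
  pair$A <- cbind(pair$A, cols)
  pair$lb <- c(pair$lb, lb)
  pair$ub <- c(pair$ub, ub)
  pair$col_ids <- c(pair$col_ids, ids)
  pair$extra <- c(pair$extra, ids)
  pair
}

.pair_row <- function(pair, key) match(key, rownames(pair$A))

#' Candidate compounds for transport repair
#'
#' A compound is a candidate for host transport repair when (1) it is
#' available in the joint environment in nonzero amount, (2) it exists in
#' both extracellular and cytoplasmic compartments somewhere in the shared
#' namespace of host and endosymbiont, and (3) the endosymbiont has at least
#' one reaction involving it.
#'
#' @param pair an `endosymbiosis_model`.
#' @return Character vector of base ids.
#' @export
candidate_transport_compounds <- function(pair) {
  stopifnot(inherits(pair, "endosymbiosis_model"))
  env <- pair$joint_env
  avail <- env$base_id[env$lower < 0]
  comp <- pair$host$compounds            # shared namespace after harmonizing
  has_e <- avail %in% comp$base_id[comp$compartment == "e"]
  has_c <- avail %in% comp$base_id[comp$compartment == "c"]
  endo_used <- Matrix::rowSums(pair$endo$S != 0) > 0
  used_bases <- unique(pair$endo$compounds$base_id[endo_used])
  sort(avail[has_e & has_c & avail %in% used_bases])
}

#' Add universal host transport reactions
#'
#' Adds one reversible transport column per compound, moving it between the
#' host's extracellular and cytoplasm rows (bypassing any periplasm), with
#' symmetric bounds of the conventional "effectively unbounded" magnitude.
#' The original pair is not modified.
#'
#' @param pair an `endosymbiosis_model`.
#' @param compounds base ids, a subset of
#'   [candidate_transport_compounds()].
#' @param bound transport flux magnitude (default 1000).
#' @return Augmented `endosymbiosis_model`.
#' @export
add_universal_transport <- function(pair, compounds, bound = 1000) {
  stopifnot(inherits(pair, "endosymbiosis_model"))
  compounds <- unique(as.character(compounds))
  if (!length(compounds)) return(pair)
  cand <- candidate_transport_compounds(pair)
  bad <- setdiff(compounds, cand)
  if (length(bad))
    stop("not candidate transport compounds: ", paste(bad, collapse = ", "))
  n_row <- nrow(pair$A)
  tri <- do.call(rbind, lapply(seq_along(compounds), function(k) {
    b <- compounds[k]
    re <- .pair_row(pair, cpd_key(b, "e"))
    rc <- .pair_row(pair, cpd_key(b, "c"))
    rbind(c(re, k, -1), c(rc, k, 1))
  }))
  cols <- Matrix::sparseMatrix(i = tri[, 1], j = tri[, 2], x = tri[, 3],
                               dims = c(n_row, length(compounds)))
  .augment_pair(pair, cols, paste0("TRANSPORT_", compounds),
                rep(-bound, length(compounds)), rep(bound, length(compounds)))
}

# internal: grant the endosymbiont direct environment access on its orphan
# rows (compounds with no cytoplasmic form anywhere in the namespace).
.add_environment_access <- function(pair, bound = 1000) {
  env <- pair$joint_env
  orphans <- intersect(pair$orphans, env$base_id[env$lower < 0])
  if (!length(orphans)) return(pair)
  n_row <- nrow(pair$A)
  tri <- do.call(rbind, lapply(seq_along(orphans), function(k) {
    b <- orphans[k]
    re <- .pair_row(pair, cpd_key(b, "e"))
    ro <- .pair_row(pair, paste0(b, "[orphan]"))
    rbind(c(re, k, -1), c(ro, k, 1))
  }))
  cols <- Matrix::sparseMatrix(i = tri[, 1], j = tri[, 2], x = tri[, 3],
                               dims = c(n_row, length(orphans)))
  .augment_pair(pair, cols, paste0("ACCESS_", orphans),
                rep(-bound, length(orphans)), rep(bound, length(orphans)))
}

#' Diagnose why an endosymbiosis is nonviable
#'
#' Applies the staged repair protocol: first grant the host universal
#' transport of all candidate compounds; if the pair is then viable the
#' cause is missing transport. Otherwise additionally grant the endosymbiont
#' direct environment access on its orphan rows (compounds that exist
#' nowhere in cytoplasmic form); viability under the combination marks the
#' access cause, and an access-only rescue attempt determines whether
#' missing transport was *also* a cause, so the two flags are not mutually
#' exclusive.
#'
#' @param pair a nonviable `endosymbiosis_model`.
#' @param tolerance viability cutoff.
#' @return List of class `repair_diagnosis`: `cause_transport`,
#'   `cause_access`, `resolved` (viable under the combined fix),
#'   `candidate_compounds`.
#' @export
diagnose_nonviability <- function(pair, tolerance = VIABILITY_TOL) {
  if (pair_is_viable(pair, tolerance = tolerance)$viable)
    stop("pair is viable; nothing to diagnose")
  cand <- candidate_transport_compounds(pair)
  with_t <- add_universal_transport(pair, cand)
  v_t <- pair_is_viable(with_t, tolerance = tolerance)$viable
  if (v_t)
    return(structure(list(cause_transport = TRUE, cause_access = FALSE,
                          resolved = TRUE, candidate_compounds = cand),
                     class = "repair_diagnosis"))
  v_ta <- pair_is_viable(.add_environment_access(with_t),
                         tolerance = tolerance)$viable
  v_a <- pair_is_viable(.add_environment_access(pair),
                        tolerance = tolerance)$viable
  structure(list(cause_transport = v_ta && !v_a, cause_access = v_ta,
                 resolved = v_ta, candidate_compounds = cand),
            class = "repair_diagnosis")
}

#' @export
print.repair_diagnosis <- function(x, ...) {
  cat("<repair_diagnosis> transport:", x$cause_transport,
      " access:", x$cause_access, " resolved:", x$resolved, "\n")
  invisible(x)
}

#' Estimate a minimal transport-compound set
#'
#' Starting from all candidate compounds (which must make the pair viable),
#' attempts to drop compounds one at a time in a seeded random order,
#' keeping each removal that preserves viability. The returned set is
#' irreducible: the pair is viable with it, and removing any single member
#' breaks viability. Greedy elimination yields an irreducible set, not a
#' guaranteed global minimum; the survey layer reports the smallest
#' cardinality over several restarts.
#'
#' @param pair a transport-fixable nonviable `endosymbiosis_model`.
#' @param order_seed integer seed for the elimination order.
#' @param tolerance viability cutoff.
#' @return Character vector of base ids (possibly empty only if the pair
#'   was viable without any transport, which the precondition excludes).
#' @export
minimal_transport_set <- function(pair, order_seed = 1L,
                                  tolerance = VIABILITY_TOL) {
  cand <- candidate_transport_compounds(pair)
  viable_with <- function(set) {
    pair_is_viable(add_universal_transport(pair, set),
                   tolerance = tolerance)$viable
  }
  if (!viable_with(cand))
    stop("pair is not fixable by transport additions alone")
  keep <- cand
  order <- withr_seed(order_seed, sample(cand))
  for (b in order) {
    trial <- setdiff(keep, b)
    if (viable_with(trial)) keep <- trial
  }
  sort(keep)
}

#' Is the single rescuing compound specific?
#'
#' For pairs fixable by transporting a single compound, scans every
#' candidate singleton and reports whether exactly one compound alone
#' restores viability.
#'
#' @param pair a nonviable, transport-fixable `endosymbiosis_model`.
#' @param tolerance viability cutoff.
#' @return List: `single_specific` (logical), `rescuers` (all singleton
#'   rescuing compounds).
#' @export
single_specificity <- function(pair, tolerance = VIABILITY_TOL) {
  cand <- candidate_transport_compounds(pair)
  ok <- vapply(cand, function(b)
    pair_is_viable(add_universal_transport(pair, b),
                   tolerance = tolerance)$viable, logical(1))
  list(single_specific = sum(ok) == 1L, rescuers = cand[ok])
}
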