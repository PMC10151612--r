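#' Build a nested host-endosymbiont model
#'
#' Assembles the block linear system for an endosymbiosis: the endosymbiont's
#' extracellular compartment is the host's cytoplasm. Rows are the host
#' namespace (extracellular rows carry the joint environment, internal rows
#' steady state), plus private endosymbiont-internal rows (`S_E y = 0`), plus
#' flagged orphan rows, plus one equal-growth row enforcing that host and
#' endosymbiont biomass fluxes coincide. Columns are host reactions followed
#' by endosymbiont reactions; the endosymbiont's extracellular rows are
#' re-mapped onto host cytoplasm rows (`S_EtoH`).
#'
#' @param host,endo prepared (harmonized, externalized) `metabolic_model`s
#'   from one collection.
#' @param joint_env optional [met_environment()]; defaults to
#'   [merge_environments()] of the two ancestral environments.
#' @return Object of class `endosymbiosis_model`.
#' @export
build_pair <- function(host, endo, joint_env = NULL) {
  stopifnot(inherits(host, "metabolic_model"),
            inherits(endo, "metabolic_model"))
  if (!identical(host$collection, endo$collection))
    stop("host and endosymbiont must come from the same collection")
  if (!host$externalized || !endo$externalized)
    stop("both models must be externalized")
  if (!identical(host$compounds$key, endo$compounds$key))
    stop("host and endosymbiont must share a harmonized namespace; ",
         "run harmonize_namespace() first")
  if (is.null(joint_env))
    joint_env <- merge_environments(environment_of(host),
                                    environment_of(endo))
  part <- partition_for_endosymbiont(endo)
  host_keys <- host$compounds$key
  endo_rows <- rownames(part$S_E)          # private copies
  orphan_keys <- setdiff(rownames(part$S_EtoH), host_keys)
  row_keys <- c(host_keys, paste0("endo:", endo_rows), orphan_keys)
  n_row <- length(row_keys)
  nH <- nrow(host$reactions); nE <- nrow(endo$reactions)

  tr <- function(M, rows_to) {       # triplets of M with rows re-indexed
    Tm <- as(M, "TsparseMatrix")
    cbind(rows_to[Tm@i + 1L], Tm@j + 1L, Tm@x)
  }
  triH <- tr(host$S, match(host_keys, row_keys))
  triE <- tr(part$S_E, match(paste0("endo:", endo_rows), row_keys))
  triEH <- tr(part$S_EtoH, match(rownames(part$S_EtoH), row_keys))
  tri <- rbind(cbind(triH[, 1], triH[, 2], triH[, 3]),
               cbind(triE[, 1], triE[, 2] + nH, triE[, 3]),
               cbind(triEH[, 1], triEH[, 2] + nH, triEH[, 3]))
  A <- Matrix::sparseMatrix(i = tri[, 1], j = tri[, 2], x = tri[, 3],
                            dims = c(n_row, nH + nE))
  rownames(A) <- row_keys
  # row bounds: joint env on extracellular rows, zero elsewhere
  row_lb <- numeric(n_row); row_ub <- numeric(n_row)
  is_e <- c(host$compounds$compartment == "e",
            rep(FALSE, length(endo_rows) + length(orphan_keys)))
  idx <- match(host$compounds$base_id, joint_env$base_id)
  hit <- which(is_e[seq_along(host_keys)] & !is.na(idx))
  row_lb[hit] <- joint_env$lower[idx[hit]]
  row_ub[hit] <- joint_env$upper[idx[hit]]
  # equal growth: x_lambda_H - y_lambda_E = 0
  eq <- numeric(nH + nE)
  eq[host$biomass] <- 1; eq[nH + endo$biomass] <- -1
  A <- rbind(A, Matrix::Matrix(eq, nrow = 1, sparse = TRUE))
  rownames(A)[n_row + 1L] <- ".equal_growth"
  row_lb <- c(row_lb, 0); row_ub <- c(row_ub, 0)
  structure(list(
    host = host, endo = endo, joint_env = joint_env,
    A = A, row_lb = row_lb, row_ub = row_ub,
    lb = c(host$reactions$lb, endo$reactions$lb),
    ub = c(host$reactions$ub, endo$reactions$ub),
    col_ids = c(paste0("host:", host$reactions$id),
                paste0("endo:", endo$reactions$id)),
    n_host = nH, n_endo = nE,
    biomass_host = host$biomass, biomass_endo = nH + endo$biomass,
    orphans = part$orphans, extra = character(0)),
    class = "endosymbiosis_model")
}

#' @export
print.endosymbiosis_model <- function(x, ...) {
  cat("<endosymbiosis_model> host:", x$host$id, " endo:", x$endo$id,
      "\n rows:", nrow(x$A), " cols:", ncol(x$A),
      if (length(x$orphans)) paste0(" orphans: ",
                                    paste(x$orphans, collapse = ",")) else "",
      if (length(x$extra)) paste0(" extra: ",
                                  paste(x$extra, collapse = ",")) else "",
      "\n")
  invisible(x)
}

# LP pieces for a pair, optionally under a perturbed environment.
.pair_lp <- function(pair, env = NULL) {
  rl <- pair$row_lb; ru <- pair$row_ub
  if (!is.null(env)) {
    host_keys <- pair$host$compounds$key
    is_e <- pair$host$compounds$compartment == "e"
    rl[seq_along(host_keys)][is_e] <- 0
    ru[seq_along(host_keys)][is_e] <- 0
    idx <- match(pair$host$compounds$base_id, env$base_id)
    hit <- which(is_e & !is.na(idx))
    rl[hit] <- env$lower[idx[hit]]
    ru[hit] <- env$upper[idx[hit]]
  }
  touched <- Matrix::rowSums(pair$A != 0) > 0
  keep <- touched | rl > 0 | ru < 0
  list(A = pair$A[keep, , drop = FALSE], row_lb = rl[keep],
       row_ub = ru[keep])
}

#' Maximize the shared growth rate of an endosymbiosis
#'
#' Maximizes the host biomass flux subject to the nested block constraints
#' and the equal-growth condition; the reported objective equals both
#' biomass fluxes.
#'
#' @param pair an `endosymbiosis_model`.
#' @param env optional [met_environment()] replacing the joint environment
#'   (used by perturbation screens).
#' @param backend LP backend, see [solve_lp()].
#' @return A `flux_solution`; `fluxes` concatenates host then endosymbiont
#'   reaction fluxes.
#' @export
maximize_pair_growth <- function(pair, env = NULL,
                                 backend = c("simplex", "boot")) {
  stopifnot(inherits(pair, "endosymbiosis_model"))
  lp <- .pair_lp(pair, env)
  obj <- numeric(ncol(pair$A)); obj[pair$biomass_host] <- 1
  solve_lp(obj, lp$A, lp$row_lb, lp$row_ub, pair$lb, pair$ub,
           maximize = TRUE, backend = match.arg(backend))
}

#' Viability of an endosymbiosis
#'
#' @inheritParams maximize_pair_growth
#' @param tolerance viability cutoff (default [VIABILITY_TOL]).
#' @return A `viability_report` (see [is_viable()]).
#' @export
pair_is_viable <- function(pair, env = NULL, tolerance = VIABILITY_TOL,
                           backend = c("simplex", "boot")) {
  sol <- maximize_pair_growth(pair, env, backend = match.arg(backend))
  growth <- .growth_value(sol)
  structure(list(growth = growth, viable = growth >= tolerance,
                 tolerance = tolerance,
                 solver_error = identical(sol$status, "failed")),
            class = "viability_report")
}

#' Assess both configurations of a species pair
#'
#' Evaluates the two directed endosymbioses (A hosts B, B hosts A) in the
#' joint environment and classifies the unordered pair.
#'
#' @param A,B prepared `metabolic_model`s from one collection.
#' @param tolerance viability cutoff.
#' @return List of class `configuration_outcome`: `pair_AB_viable`,
#'   `pair_BA_viable`, `growth_AB`, `growth_BA`, and `class` (one of
#'   `"neither"`, `"only_one"`, `"both"`).
#' @export
assess_configurations <- function(A, B, tolerance = VIABILITY_TOL) {
  vAB <- pair_is_viable(build_pair(A, B), tolerance = tolerance)
  vBA <- pair_is_viable(build_pair(B, A), tolerance = tolerance)
  n <- vAB$viable + vBA$viable
  structure(list(pair_AB_viable = vAB$viable, pair_BA_viable = vBA$viable,
                 growth_AB = vAB$growth, growth_BA = vBA$growth,
                 class = c("neither", "only_one", "both")[n + 1L]),
            class = "configuration_outcome")
}
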