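#' Viability tolerance used throughout
#'
#' A metabolism counts as viable when its maximum growth rate is at or above
#' this tolerance (0.001). This biological cutoff is distinct from, and much
#' larger than, the solver's feasibility tolerance (~1e-9); the two are never
#' conflated.
#' @export
VIABILITY_TOL <- 0.001

# Assemble LP pieces for a single externalized model under an environment.
# Rows untouched by any reaction and satisfiable at zero are dropped (an
# exact reduction: such rows read "lo <= 0 <= hi").
.model_lp <- function(model, env = NULL) {
  rl <- model$env_lower; ru <- model$env_upper
  if (!model$externalized) {
    rl <- numeric(nrow(model$compounds)); ru <- rl
  } else if (!is.null(env)) {
    rl <- numeric(nrow(model$compounds)); ru <- rl
    is_e <- model$compounds$compartment == "e"
    idx <- match(model$compounds$base_id, env$base_id)
    hit <- is_e & !is.na(idx)
    rl[hit] <- env$lower[idx[hit]]
    ru[hit] <- env$upper[idx[hit]]
  }
  touched <- Matrix::rowSums(model$S != 0) > 0
  keep <- touched | rl > 0 | ru < 0
  list(A = model$S[keep, , drop = FALSE], row_lb = rl[keep],
       row_ub = ru[keep], lb = model$reactions$lb, ub = model$reactions$ub)
}

#' Maximize the growth rate of a single metabolism
#'
#' Solves the flux-balance linear program: maximize the biomass flux subject
#' to `env_lower <= S x <= env_upper` on compound rows (internal compounds at
#' steady state `[0, 0]`) and the reaction flux bounds. For a raw model
#' (exchange reactions still present) all compound rows are balanced at zero
#' and the environment lives in the exchange bounds.
#'
#' @param model a `metabolic_model`.
#' @param env optional [met_environment()] overriding the model's own
#'   environment (externalized models only).
#' @param backend LP backend, see [solve_lp()].
#' @return A `flux_solution` whose `objective` is the maximum biomass flux.
#' @export
maximize_growth <- function(model, env = NULL,
                            backend = c("simplex", "boot")) {
  stopifnot(inherits(model, "metabolic_model"))
  lp <- .model_lp(model, env)
  obj <- numeric(nrow(model$reactions)); obj[model$biomass] <- 1
  solve_lp(obj, lp$A, lp$row_lb, lp$row_ub, lp$lb, lp$ub,
           maximize = TRUE, backend = match.arg(backend))
}

.growth_value <- function(sol) {
  if (identical(sol$status, "optimal")) sol$objective else 0
}

#' Binary viability of a metabolism
#'
#' Viable means maximum growth at or above `tolerance`. An infeasible LP is
#' treated as growth 0 (nonviable), so the predicate is total; solver
#' failures are additionally flagged in `solver_error`.
#'
#' @inheritParams maximize_growth
#' @param tolerance viability cutoff (default [VIABILITY_TOL]).
#' @return List of class `viability_report`: `growth`, `viable`, `tolerance`,
#'   `solver_error`.
#' @export
is_viable <- function(model, env = NULL, tolerance = VIABILITY_TOL,
                      backend = c("simplex", "boot")) {
  sol <- maximize_growth(model, env, backend = match.arg(backend))
  growth <- .growth_value(sol)
  structure(list(growth = growth, viable = growth >= tolerance,
                 tolerance = tolerance,
                 solver_error = identical(sol$status, "failed")),
            class = "viability_report")
}

#' @export
print.viability_report <- function(x, ...) {
  cat("<viability_report> growth:", format(x$growth, digits = 6),
      if (x$viable) "(viable)" else "(nonviable)", "\n")
  invisible(x)
}
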