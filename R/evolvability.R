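#' Relax the flux bounds of one reaction
#'
#' A bound-relaxation mutation multiplies a reaction's bounds by a factor:
#' `lower := -factor * |lower|`, `upper := factor * upper`, effectively
#' removing the reaction as a limiting constraint. For the rare reaction
#' with a strictly positive lower bound the formula flips the lower bound's
#' sign; such reactions are flagged.
#'
#' @param bounds numeric length-2 vector `c(lower, upper)`.
#' @param factor relaxation factor, `>= 1` (default 1000).
#' @return Length-2 numeric with attribute `flipped_lower` when the lower
#'   bound changed sign.
#' @export
mutate_bounds <- function(bounds, factor = 1000) {
  stopifnot(length(bounds) == 2, factor >= 1)
  out <- c(-factor * abs(bounds[1]), factor * bounds[2])
  if (bounds[1] > 0) attr(out, "flipped_lower") <- TRUE
  out
}

#' Tighten all reaction bounds
#'
#' Divides every reaction's bounds by `factor`. Used to put collections
#' whose growth is environment-limited rather than bound-limited into a
#' regime where bound-relaxation mutations can have an effect.
#'
#' @param model a `metabolic_model`.
#' @param factor division factor, strictly `> 1` (default 100).
#' @return The tightened model.
#' @export
tighten_all_bounds <- function(model, factor = 100) {
  stopifnot(inherits(model, "metabolic_model"))
  if (!(factor > 1)) stop("tightening factor must be > 1")
  model$reactions$lb <- model$reactions$lb / factor
  model$reactions$ub <- model$reactions$ub / factor
  model
}

#' Scan all single bound-relaxation mutations
#'
#' For each reaction in the chosen context, relaxes its bounds by `factor`,
#' recomputes the optimal growth, and restores the bounds. Relaxation can
#' never decrease the optimum, so each mutation is neutral or beneficial
#' (relative growth increase above `1e-6`); solver failures are recorded
#' per-reaction, never fatal.
#'
#' @param entity a `metabolic_model` or an `endosymbiosis_model`.
#' @param context for pairs, `"host"` or `"endo"`: which block's reactions
#'   to mutate (ignored for single models).
#' @param env environment for growth evaluation (defaults to the entity's).
#' @param factor relaxation factor (default 1000).
#' @param tolerance relative increase above which a mutation counts as
#'   beneficial.
#' @return data.frame with one row per reaction: `reaction`, `context`,
#'   `baseline`, `mutated`, `beneficial`, `solver_error`.
#' @export
scan_mutations <- function(entity, context = c("host", "endo"),
                           env = NULL, factor = 1000, tolerance = 1e-6) {
  context <- match.arg(context)
  if (inherits(entity, "metabolic_model")) {
    base_sol <- maximize_growth(entity, env)
    baseline <- .growth_value(base_sol)
    ids <- entity$reactions$id
    eval_mut <- function(k) {
      m <- entity
      nb <- mutate_bounds(c(m$reactions$lb[k], m$reactions$ub[k]), factor)
      m$reactions$lb[k] <- nb[1]; m$reactions$ub[k] <- nb[2]
      maximize_growth(m, env)
    }
    ctx <- if (identical(context, "host")) "ancestral_host" else
      "ancestral_endo"
  } else if (inherits(entity, "endosymbiosis_model")) {
    base_sol <- maximize_pair_growth(entity, env)
    baseline <- .growth_value(base_sol)
    cols <- if (context == "host") seq_len(entity$n_host) else
      entity$n_host + seq_len(entity$n_endo)
    ids <- sub("^(host|endo):", "", entity$col_ids[cols])
    eval_mut <- function(k) {
      p <- entity
      j <- cols[k]
      nb <- mutate_bounds(c(p$lb[j], p$ub[j]), factor)
      p$lb[j] <- nb[1]; p$ub[j] <- nb[2]
      maximize_pair_growth(p, env)
    }
    ctx <- paste0("pair_", context, "_reaction")
  } else stop("entity must be a metabolic_model or endosymbiosis_model")
  rows <- lapply(seq_along(ids), function(k) {
    sol <- eval_mut(k)
    g <- .growth_value(sol)
    data.frame(reaction = ids[k], context = ctx, baseline = baseline,
               mutated = g,
               beneficial = (g - baseline) > tolerance * max(baseline, 1e-12),
               solver_error = identical(sol$status, "failed"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare evolvability of a pair against its ancestors
#'
#' Runs the four mutation scans (ancestral host, ancestral endosymbiont,
#' pair host-reactions, pair endosymbiont-reactions) in one environment and
#' aggregates: beneficial counts per context, per-reaction paired
#' differences against the matching ancestor, the fraction of
#' pair-beneficial mutations whose mutated pair growth exceeds each
#' ancestor's unmutated growth, and the maximum growth reached by any single
#' mutation per entity.
#'
#' @param pair an `endosymbiosis_model`.
#' @param host,endo the ancestral models.
#' @param env shared environment (defaults to the pair's joint environment).
#' @param factor relaxation factor.
#' @return List of class `evolvability_comparison`: `scans` (all four scan
#'   tables bound together), `n_beneficial`, `paired_host`, `paired_endo`
#'   (per-reaction beneficial indicators, pair vs ancestor),
#'   `exceeds_host_fraction`, `exceeds_endo_fraction`, `max_growth`.
#' @export
compare_evolvability <- function(pair, host, endo,
                                 env = pair$joint_env, factor = 1000) {
  sc_h <- scan_mutations(host, "host", env, factor)
  sc_e <- scan_mutations(endo, "endo", env, factor)
  sc_ph <- scan_mutations(pair, "host", env, factor)
  sc_pe <- scan_mutations(pair, "endo", env, factor)
  scans <- rbind(sc_h, sc_e, sc_ph, sc_pe)
  n_beneficial <- vapply(split(scans$beneficial, scans$context), sum,
                         numeric(1))
  paired <- function(anc, prs) {
    shared <- intersect(anc$reaction, prs$reaction)
    data.frame(reaction = shared,
               ancestor = anc$beneficial[match(shared, anc$reaction)],
               pair = prs$beneficial[match(shared, prs$reaction)])
  }
  host_growth <- .growth_value(maximize_growth(host, env))
  endo_growth <- .growth_value(maximize_growth(endo, env))
  pair_ben <- rbind(sc_ph, sc_pe)
  pair_ben <- pair_ben[pair_ben$beneficial, , drop = FALSE]
  frac_exceed <- function(ref) {
    if (!nrow(pair_ben)) return(NA_real_)
    mean(pair_ben$mutated > ref)
  }
  max_growth <- c(host = max(sc_h$mutated), endo = max(sc_e$mutated),
                  pair = max(c(sc_ph$mutated, sc_pe$mutated)))
  structure(list(
    scans = scans, n_beneficial = n_beneficial,
    paired_host = paired(sc_h, sc_ph), paired_endo = paired(sc_e, sc_pe),
    exceeds_host_fraction = frac_exceed(host_growth),
    exceeds_endo_fraction = frac_exceed(endo_growth),
    ancestor_growth = c(host = host_growth, endo = endo_growth),
    max_growth = max_growth), class = "evolvability_comparison")
}
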