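# shared helpers: prepared toy models and small random-LP generators

toy_prepared <- function(name) {
  externalize_environment(make_fixture(name)$model)
}

# random bounded LP with a known-feasible interior point
random_lp <- function(n = 10, m = 6, seed = 1) {
  withr::with_seed(seed, {
    A <- matrix(round(rnorm(m * n) * (runif(m * n) < 0.5), 2), m, n)
    lb <- round(runif(n, -4, 0), 2)
    ub <- lb + round(runif(n, 0.5, 6), 2)
    x0 <- lb + runif(n) * (ub - lb)
    act <- as.numeric(A %*% x0)
    eqrow <- runif(m) < 0.4
    rl <- ifelse(eqrow, act, act - runif(m, 0, 4))
    ru <- ifelse(eqrow, act, act + runif(m, 0, 4))
    list(obj = round(rnorm(n), 2), A = A, rl = rl, ru = ru, lb = lb, ub = ub)
  })
}

# brute-force check that `set` is a minimum-cardinality transport fix:
# enumerate all strictly smaller subsets of the candidates
is_minimum_cardinality <- function(pair, set,
                                   cand = candidate_transport_compounds(pair)) {
  k <- length(set)
  if (k == 0) return(TRUE)
  for (size in 0:(k - 1)) {
    subs <- utils::combn(cand, size, simplify = FALSE)
    for (s in subs) {
      if (pair_is_viable(add_universal_transport(pair, s))$viable)
        return(FALSE)
    }
  }
  TRUE
}

is_irreducible_fix <- function(pair, set) {
  if (!pair_is_viable(add_universal_transport(pair, set))$viable)
    return(FALSE)
  for (b in set) {
    if (pair_is_viable(add_universal_transport(pair, setdiff(set, b)))$viable)
      return(FALSE)
  }
  TRUE
}
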