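#' Solve a bounded linear program
#'
#' Solver abstraction used by every flux-balance computation in the package:
#' maximize (or minimize) `obj %*% x` subject to `row_lb <= A x <= row_ub`
#' and `lb <= x <= ub`. All bounds must be finite; flux-balance models use
#' finite "effectively unbounded" magnitudes (conventionally 100--1000), so a
#' finite box is not a restriction in practice and guarantees a bounded
#' optimum.
#'
#' Two interchangeable backends satisfy the contract: `"simplex"`, the
#' package's compiled bounded-variable two-phase simplex (default), and
#' `"boot"`, which reformulates onto [boot::simplex()] (nonnegative variables,
#' bounds as extra rows) and is retained as an independent cross-check.
#'
#' @param obj numeric objective coefficients, one per column of `A`.
#' @param A constraint matrix (dense or `Matrix` sparse; coerced to dense).
#' @param row_lb,row_ub row activity bounds.
#' @param lb,ub variable bounds.
#' @param maximize logical; maximize (default) or minimize.
#' @param backend `"simplex"` or `"boot"`.
#' @return A `flux_solution`: list with `status` (`"optimal"`, `"infeasible"`,
#'   `"unbounded"`, `"failed"`), `objective`, and `fluxes`.
#' @export
solve_lp <- function(obj, A, row_lb, row_ub, lb, ub, maximize = TRUE,
                     backend = c("simplex", "boot")) {
  backend <- match.arg(backend)
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(lb) == n, length(ub) == n,
            length(row_lb) == m, length(row_ub) == m)
  if (any(lb > ub)) stop("variable lower bound exceeds upper bound")
  if (any(row_lb > row_ub)) stop("row lower bound exceeds upper bound")
  res <- switch(backend,
    simplex = .simplex_solve(A, as.numeric(row_lb), as.numeric(row_ub),
                             as.numeric(lb), as.numeric(ub), as.numeric(obj),
                             isTRUE(maximize)),
    boot = .solve_lp_boot(obj, A, row_lb, row_ub, lb, ub, maximize))
  structure(list(status = res$status,
                 objective = if (identical(res$status, "optimal"))
                   res$objective else NA_real_,
                 fluxes = if (identical(res$status, "optimal"))
                   as.numeric(res$x) else rep(NA_real_, n)),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status:", x$status,
      " objective:", format(x$objective, digits = 8), "\n")
  invisible(x)
}

# boot::simplex backend. Variables are shifted to s = x - lb >= 0; upper
# bounds and two-sided rows become inequality rows with nonnegative RHS
# (boot::simplex requires b >= 0, so rows are negated as needed).
.solve_lp_boot <- function(obj, A, row_lb, row_ub, lb, ub, maximize) {
  if (any(!is.finite(lb)) || any(!is.finite(ub)) ||
      any(!is.finite(row_lb)) || any(!is.finite(row_ub)))
    stop("boot backend requires finite bounds")
  n <- ncol(A)
  shift <- as.numeric(A %*% lb)
  rows_le <- list(); rhs_le <- numeric(0)   # R s <= b
  rows_eq <- list(); rhs_eq <- numeric(0)   # R s  = b
  add_le <- function(r, b) {
    if (b >= 0) { rows_le[[length(rows_le) + 1L]] <<- r
                  rhs_le <<- c(rhs_le, b) }
    else { # r s <= b < 0  <=>  -r s >= -b handled as A2 via negation later
      rows_le[[length(rows_le) + 1L]] <<- r
      rhs_le <<- c(rhs_le, b)
    }
  }
  for (i in seq_len(nrow(A))) {
    lo <- row_lb[i] - shift[i]; hi <- row_ub[i] - shift[i]
    if (abs(hi - lo) < 1e-12) { rows_eq[[length(rows_eq) + 1L]] <- A[i, ]
                                rhs_eq <- c(rhs_eq, lo) }
    else { add_le(A[i, ], hi); add_le(-A[i, ], -lo) }
  }
  span <- ub - lb
  for (j in which(is.finite(span))) {
    r <- numeric(n); r[j] <- 1
    add_le(r, span[j])
  }
  A1 <- NULL; b1 <- NULL; A2 <- NULL; b2 <- NULL
  if (length(rows_le)) {
    M <- do.call(rbind, rows_le); b <- rhs_le
    neg <- b < 0
    if (any(!neg)) { A1 <- M[!neg, , drop = FALSE]; b1 <- b[!neg] }
    if (any(neg))  { A2 <- -M[neg, , drop = FALSE]; b2 <- -b[neg] }
  }
  A3 <- NULL; b3 <- NULL
  if (length(rows_eq)) {
    M <- do.call(rbind, rows_eq); b <- rhs_eq
    neg <- b < 0
    M[neg, ] <- -M[neg, , drop = FALSE]; b[neg] <- -b[neg]
    A3 <- M; b3 <- b
  }
  out <- tryCatch(
    boot::simplex(a = obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                  A3 = A3, b3 = b3, maxi = isTRUE(maximize),
                  n.iter = 50 * (n + nrow(A)) + 2000),
    error = function(e) NULL)
  if (is.null(out)) return(list(status = "failed", x = NULL, objective = NA))
  if (out$solved == -1) return(list(status = "infeasible", x = NULL,
                                    objective = NA))
  if (out$solved != 1) return(list(status = "failed", x = NULL,
                                   objective = NA))
  x <- as.numeric(out$soln) + lb
  list(status = "optimal", x = x, objective = sum(obj * x))
}
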