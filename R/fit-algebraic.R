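#' Exact global least-squares fit of the torsional coefficients
#'
#' Solves the normal equations of the shared-coefficient design system:
#' with design matrix `B` and target `y`, the objective
#' \eqn{F(K) = \|BK - y\|^2} is a convex quadratic, so the stationarity
#' conditions give the linear system \eqn{W K = C} with \eqn{W = B^T B},
#' \eqn{C = B^T y}, whose solution is the global minimizer. No starting
#' values, step sizes or temperature schedules are involved: the optimum
#' is exact.
#'
#' When `W` is singular (a rank-deficient design, e.g. scans that never
#' move some dihedral type) the minimum-norm least-squares solution is
#' returned and `diagnostics$singular` is set instead of failing.
#'
#' A warning is emitted when any fitted `|k|` exceeds 20 kJ/mol: large
#' torsional coefficients are known to destabilise MD integration, which
#' is the motivation for the bounded variant.
#'
#' @param system a [build_design_system()] result.
#' @return an object of class `torsion_fit`: fitted [fourier_params]
#'   (`$params`), residual sum of squares (`$objective`, kJ^2/mol^2),
#'   `$method = "global"`, and `$diagnostics` (condition number of `W`,
#'   rank, singularity flag).
#' @examples
#' ds <- generate_dataset(dmph_typing(), example_params(), seed = 1)
#' fit <- solve_global(build_design_system(ds))
#' fit$objective        # ~0: noiseless data are reproduced exactly
#' @seealso [solve_bounded()], [mc_fit()], [torsion_fit()]
#' @export
solve_global <- function(system) {
  check_system(system)
  B <- system$B
  y <- system$y
  if (nrow(B) < ncol(B)) {
    warning("fewer conformers (", nrow(B), ") than parameters (", ncol(B),
            "); the fit is underdetermined", call. = FALSE)
  }
  W <- crossprod(B)
  C <- crossprod(B, y)
  ev <- eigen(W, symmetric = TRUE, only.values = TRUE)$values
  tol <- max(dim(W)) * .Machine$double.eps * max(ev)
  rank <- sum(ev > tol)
  singular <- rank < ncol(W)
  condition <- if (singular) Inf else max(ev) / min(ev)
  if (!singular) {
    K <- as.numeric(solve(chol(W), solve(t(chol(W)), C)))
  } else {
    ## minimum-norm solution through the pseudo-inverse of W
    s <- svd(W)
    keep <- s$d > tol
    K <- as.numeric(s$v[, keep, drop = FALSE] %*%
                      ((t(s$u[, keep, drop = FALSE]) %*% C) / s$d[keep]))
  }
  make_fit(system, K, method = "global",
           diagnostics = list(condition = condition, rank = rank,
                              singular = singular, iterations = NA_integer_))
}

#' Bounded ("local") least-squares fit with box constraints on coefficients
#'
#' Minimizes the same residual sum of squares as [solve_global()] subject
#' to \eqn{-T \le k \le T} for every Fourier coefficient (the offset, when
#' present, stays unconstrained). The problem is a convex box-constrained
#' quadratic program, solved by cyclic coordinate descent: each coordinate
#' update is the exact 1-D minimizer clipped to the box, which converges to
#' the unique constrained optimum. The solver warm-starts from the clipped
#' global solution, so when no bound is active it returns the global
#' solution unchanged.
#'
#' The default `T = 20` kJ/mol reflects the coefficient range beyond which
#' torsional terms tend to destabilise MD integration.
#'
#' @param system a [build_design_system()] result.
#' @param T box half-width in kJ/mol, positive.
#' @param tol convergence tolerance on the largest coordinate change per
#'   sweep, kJ/mol.
#' @param max_sweeps iteration cap.
#' @return a `torsion_fit` with `$method = "local"` and `$bound_T = T`.
#'   Its objective is never below the global objective, and equals it when
#'   all constraints are inactive.
#' @export
solve_bounded <- function(system, T = 20, tol = 1e-12, max_sweeps = 50000L) {
  check_system(system)
  if (length(T) != 1L || !is.finite(T) || T <= 0) {
    stop_input("'T' must be a positive bound in kJ/mol")
  }
  B <- system$B
  y <- system$y
  p <- ncol(B)
  W <- crossprod(B)
  C <- as.numeric(crossprod(B, y))
  bounded <- rep(TRUE, p)
  if (system$has_offset) bounded[p] <- FALSE

  gfit <- suppressWarnings(solve_global(system))
  K <- fit_coef_vector(gfit, system)
  if (all(abs(K[bounded]) <= T)) {
    gfit$method <- "local"
    gfit$bound_T <- T
    return(gfit)
  }
  K[bounded] <- pmin(pmax(K[bounded], -T), T)

  d <- diag(W)
  scale <- max(abs(K), 1)
  iters <- 0L
  for (sweep in seq_len(max_sweeps)) {
    delta_max <- 0
    for (i in seq_len(p)) {
      if (d[i] <= 0) next                 # column identically zero
      ki_new <- K[i] + (C[i] - sum(W[i, ] * K)) / d[i]
      if (bounded[i]) ki_new <- min(max(ki_new, -T), T)
      delta <- abs(ki_new - K[i])
      if (delta > delta_max) delta_max <- delta
      K[i] <- ki_new
    }
    iters <- sweep
    if (delta_max <= tol * scale) break
  }
  fit <- make_fit(system, K, method = "local",
                  diagnostics = list(condition = gfit$diagnostics$condition,
                                     rank = gfit$diagnostics$rank,
                                     singular = gfit$diagnostics$singular,
                                     iterations = iters))
  fit$bound_T <- T
  fit
}

check_system <- function(system) {
  if (!inherits(system, "design_system")) {
    stop_input("'system' must be a design_system (see build_design_system)")
  }
  if (nrow(system$B) < 1L) stop_input("empty design system")
  if (all(system$B == 0)) {
    stop_input("degenerate system: design matrix is identically zero")
  }
}

## assemble a torsion_fit from the stacked coefficient vector K
## (type-major, term-minor, optional trailing offset)
make_fit <- function(system, K, method, diagnostics) {
  nc <- n_coef(system)
  offset <- if (system$has_offset) K[nc + 1L] else 0
  kmat <- matrix(K[seq_len(nc)], nrow = system$typing$n_types,
                 ncol = system$n_terms, byrow = TRUE)
  params <- fourier_params(kmat, offset = offset)
  resid <- as.numeric(system$B %*% K) - system$y
  fit <- structure(
    list(
      params = params,
      objective = sum(resid^2),
      method = method,
      bound_T = NULL,
      diagnostics = diagnostics,
      typing = system$typing,
      n_terms = system$n_terms,
      has_offset = system$has_offset,
      n_conformers = nrow(system$B)
    ),
    class = "torsion_fit"
  )
  if (method == "global" && any(abs(kmat) > 20)) {
    warning("fitted |k| exceeds 20 kJ/mol; such large torsional ",
            "coefficients can destabilise MD simulations -- consider ",
            "solve_bounded()", call. = FALSE)
  }
  fit
}

## stacked coefficient vector of a fit, in the column order of the system
fit_coef_vector <- function(fit, system) {
  K <- as.numeric(t(fit$params$k))
  if (system$has_offset) K <- c(K, fit$params$offset)
  K
}
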