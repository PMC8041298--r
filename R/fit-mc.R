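#' Monte Carlo schedule
#'
#' Hyperparameters for the Metropolis baseline fitter [mc_fit()]. The
#' temperature factor sets the scale of the acceptance probability for
#' uphill moves: large early temperatures let the chain escape shallow
#' basins (delaying premature convergence), while cooling towards `T_end`
#' turns the walk into a descent. Temperatures share the units of the
#' objective (kJ^2/mol^2).
#'
#' @param n_iter number of proposals, at least 1.
#' @param T_start,T_end starting and final temperature factors;
#'   `T_start >= T_end > 0`. Cooling is geometric.
#' @param proposal_sigma standard deviation of the Gaussian perturbation
#'   applied to one randomly chosen coefficient per step, kJ/mol.
#' @param seed integer RNG seed; fixed seed gives a bit-identical run.
#' @param bounds optional box half-width (kJ/mol) applied to all Fourier
#'   coefficients (never the offset); `NULL` for unconstrained.
#' @param init `"zeros"` starts from the zero vector, `"random"` from
#'   uniform draws in the box (or in \eqn{[-20, 20]} when unbounded).
#' @return an object of class `mc_schedule`.
#' @export
mc_schedule <- function(n_iter = 50000L, T_start = 100, T_end = 0.01,
                        proposal_sigma = 2, seed = 1L, bounds = NULL,
                        init = c("zeros", "random")) {
  if (!is_count(n_iter)) stop_input("'n_iter' must be a positive integer")
  if (!is.finite(T_start) || !is.finite(T_end) || T_end <= 0 ||
      T_start < T_end) {
    stop_input("temperatures must satisfy T_start >= T_end > 0")
  }
  if (!is.finite(proposal_sigma) || proposal_sigma <= 0) {
    stop_input("'proposal_sigma' must be positive")
  }
  if (!is.null(bounds) && (!is.finite(bounds) || bounds <= 0)) {
    stop_input("'bounds' must be NULL or a positive box half-width")
  }
  structure(
    list(n_iter = as.integer(n_iter), T_start = T_start, T_end = T_end,
         proposal_sigma = proposal_sigma, seed = as.integer(seed),
         bounds = bounds, init = match.arg(init)),
    class = "mc_schedule"
  )
}

#' Metropolis acceptance probability
#'
#' The transition rule of the Monte Carlo fitter: a proposal that does not
#' increase the objective is always accepted; an uphill move by `dF > 0`
#' is accepted with probability `exp(-dF / T)`.
#'
#' @param dF objective change of the proposal (new minus current).
#' @param T temperature factor, positive; same units as the objective.
#' @return acceptance probability in `[0, 1]`, vectorized over `dF`.
#' @examples
#' mc_accept_probability(-5, 10)   # downhill: 1
#' mc_accept_probability(10, 10)   # uphill by one temperature: exp(-1)
#' @export
mc_accept_probability <- function(dF, T) {
  if (any(!is.finite(T)) || any(T <= 0)) {
    stop_input("'T' must be a positive temperature factor")
  }
  ifelse(dF <= 0, 1, exp(-dF / T))
}

#' Monte Carlo baseline fit of the torsional coefficients
#'
#' Stochastic minimizer of the same residual sum of squares as
#' [solve_global()], included as the baseline the exact algebraic solution
#' is compared against. Each step perturbs one uniformly chosen coefficient
#' by a centred Gaussian and accepts by the Metropolis rule
#' ([mc_accept_probability()]) under a geometrically cooled temperature.
#' The best visited point (not the final chain state) is returned, so the
#' running-best objective is non-increasing. The run is exactly
#' reproducible for a fixed schedule seed and can never beat the exact
#' solution: `objective(mc) >= objective(global)` always.
#'
#' @param system a [build_design_system()] result.
#' @param schedule an [mc_schedule()].
#' @param init optional numeric starting coefficient vector (stacked
#'   type-major with trailing offset if present), overriding
#'   `schedule$init`.
#' @param trace logical; keep the per-iteration trace (iteration,
#'   objective, temperature, accepted) as `$trace`.
#' @return a `torsion_fit` with `$method = "monte_carlo"` and the accepted
#'   proposal count in `$diagnostics$iterations`.
#' @export
mc_fit <- function(system, schedule = mc_schedule(), init = NULL,
                   trace = FALSE) {
  check_system(system)
  if (!inherits(schedule, "mc_schedule")) {
    stop_input("'schedule' must be an mc_schedule")
  }
  B <- system$B
  y <- system$y
  p <- ncol(B)
  bounded <- rep(!is.null(schedule$bounds), p)
  if (system$has_offset) bounded[p] <- FALSE
  box <- if (is.null(schedule$bounds)) Inf else schedule$bounds

  with_local_seed(schedule$seed, {
    K <- if (!is.null(init)) {
      if (length(init) != p) stop_input("'init' must have length ", p)
      as.numeric(init)
    } else if (schedule$init == "zeros") {
      rep(0, p)
    } else {
      r <- stats::runif(p, -min(box, 20), min(box, 20))
      if (system$has_offset) r[p] <- 0
      r
    }
    if (any(bounded & abs(K) > box)) {
      K <- ifelse(bounded, pmin(pmax(K, -box), box), K)
    }

    resid <- as.numeric(B %*% K) - y
    F_cur <- sum(resid^2)
    K_best <- K
    F_best <- F_cur
    n_iter <- schedule$n_iter
    ratio <- schedule$T_end / schedule$T_start
    accepted <- 0L
    tr <- if (trace) matrix(NA_real_, n_iter, 4L,
                            dimnames = list(NULL, c("iteration", "objective",
                                                    "temperature",
                                                    "accepted"))) else NULL

    for (it in seq_len(n_iter)) {
      Temp <- schedule$T_start *
        ratio^(if (n_iter > 1L) (it - 1) / (n_iter - 1) else 1)
      i <- sample.int(p, 1L)
      dk <- stats::rnorm(1L, 0, schedule$proposal_sigma)
      ki_new <- K[i] + dk
      if (bounded[i]) ki_new <- min(max(ki_new, -box), box)
      resid_new <- resid + B[, i] * (ki_new - K[i])
      F_new <- sum(resid_new^2)
      acc <- F_new <= F_cur || stats::runif(1L) < exp(-(F_new - F_cur) / Temp)
      if (acc) {
        K[i] <- ki_new
        resid <- resid_new
        F_cur <- F_new
        accepted <- accepted + 1L
        if (F_cur < F_best) {
          F_best <- F_cur
          K_best <- K
        }
      }
      if (trace) tr[it, ] <- c(it, F_cur, Temp, as.numeric(acc))
    }

    fit <- make_fit(system, K_best, method = "monte_carlo",
                    diagnostics = list(condition = NA_real_, rank = NA_integer_,
                                       singular = FALSE, iterations = accepted))
    fit$bound_T <- schedule$bounds
    fit$schedule <- schedule
    if (trace) fit$trace <- as.data.frame(tr)
    fit
  })
}
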