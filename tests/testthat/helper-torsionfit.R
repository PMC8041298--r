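## Shared fixtures and independent oracles for the test suite.
## Oracles deliberately use different algorithmic routes than the package:
## QR factorisation (lm.fit / qr.solve) against the package's normal
## equations, and optim's L-BFGS-B against the package's coordinate descent.

deg2rad_test <- function(x) x * pi / 180

## small random typing: n_types types, each with 1..3 instances
rand_typing <- function(n_types, seed) {
  withr::with_seed(seed, {
    mult <- sample(1:3, n_types, replace = TRUE)
    dihedral_typing(rep(seq_len(n_types), times = mult))
  })
}

## random small design system built through the generator (random coupling)
rand_system <- function(seed, n_types = 2, n_terms = 4, noise_sd = 1,
                        grid_step = 30, include_offset = TRUE) {
  typing <- rand_typing(n_types, seed)
  true_k <- withr::with_seed(seed + 1000L,
    matrix(stats::runif(n_types * n_terms, -5, 5), n_types, n_terms))
  ds <- generate_dataset(typing, fourier_params(true_k),
                         grid_step = grid_step, coupling = "random",
                         noise_sd = noise_sd, seed = seed)
  build_design_system(ds, n_terms = n_terms, include_offset = include_offset)
}

## QR-based unconstrained least-squares oracle (independent of the
## package's Cholesky-on-normal-equations route)
oracle_global_objective <- function(system) {
  fit <- stats::lm.fit(system$B, system$y)
  sum(fit$residuals^2)
}

## box-constrained oracle via L-BFGS-B on the quadratic objective
oracle_bounded <- function(system, T) {
  B <- system$B
  y <- system$y
  p <- ncol(B)
  lower <- rep(-T, p)
  upper <- rep(T, p)
  if (system$has_offset) {
    lower[p] <- -Inf
    upper[p] <- Inf
  }
  f <- function(K) sum((B %*% K - y)^2)
  gr <- function(K) as.numeric(2 * crossprod(B, B %*% K - y))
  o <- stats::optim(rep(0, p), f, gr, method = "L-BFGS-B",
                    lower = lower, upper = upper,
                    control = list(maxit = 5000, factr = 10))
  o$value
}

## brute force for a 2-parameter unconstrained problem: dense grid search
## followed by exact 1-D coordinate refinement (no matrix solve involved)
oracle_brute_2param <- function(B, y, span = 30, step = 0.5,
                                refine_sweeps = 200) {
  f <- function(K) sum((B %*% K - y)^2)
  grid <- seq(-span, span, by = step)
  best <- c(0, 0)
  best_f <- f(best)
  for (a in grid) {
    for (b in grid) {
      v <- f(c(a, b))
      if (v < best_f) {
        best_f <- v
        best <- c(a, b)
      }
    }
  }
  ## exact line minimum along each axis: quadratic in one variable
  K <- best
  for (s in seq_len(refine_sweeps)) {
    for (i in 1:2) {
      r <- y - B %*% K + B[, i] * K[i]
      K[i] <- sum(B[, i] * r) / sum(B[, i]^2)
    }
  }
  list(K = K, objective = f(K))
}

## DMPH-like noiseless dataset used in several places
dmph_dataset <- function(noise_sd = 0, seed = 1L) {
  generate_dataset(dmph_typing(), example_params(), noise_sd = noise_sd,
                   seed = seed)
}
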