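test_that("a zero target yields zero coefficients and zero objective", {
  sys <- rand_system(1, noise_sd = 0)
  sys$y <- rep(0, length(sys$y))
  fit <- solve_global(sys)
  expect_equal(max(abs(fit$params$k)), 0, tolerance = 1e-10)
  expect_equal(fit$objective, 0, tolerance = 1e-16)
})

test_that("noiseless generate-then-fit round trip recovers the truth", {
  truth <- example_params()
  ds <- generate_dataset(dmph_typing(), truth, seed = 4)
  fit <- solve_global(build_design_system(ds))
  expect_lt(max(abs(fit$params$k - truth$k)) / max(abs(truth$k)), 1e-8)
  expect_lt(fit$objective, 1e-12)
  expect_lt(abs(fit$params$offset), 1e-8)
})

test_that("global solution matches a brute-force oracle on a tiny system", {
  ## 5 conformers, 1 type (1 instance), 2 terms; oracle = dense grid
  ## search refined by exact coordinate descent, no linear solve
  ty <- dihedral_typing(1)
  angles <- matrix(c(-150, -60, 10, 80, 170), 5, 1)
  y <- withr::with_seed(21, stats::runif(5, -10, 10))
  ds <- scan_dataset(angles, rep(1, 5), angles[, 1], y, ty)
  B <- cbind(1 + cos(deg2rad_test(angles[, 1])),
             1 + cos(2 * deg2rad_test(angles[, 1])))
  oracle <- oracle_brute_2param(B, y)

  sys <- build_design_system(ds, n_terms = 4, include_offset = FALSE)
  sys$B <- sys$B[, 1:2]
  sys$n_terms <- 2L   # truncated 2-term system for the 2-parameter oracle
  attr(sys, "class") <- "design_system"
  W <- crossprod(sys$B)
  K_pkg <- solve(W, crossprod(sys$B, y))
  expect_equal(as.numeric(K_pkg), as.numeric(oracle$K), tolerance = 1e-4)
  expect_equal(sum((sys$B %*% K_pkg - y)^2), oracle$objective,
               tolerance = 1e-6)
})

test_that("normal equations are satisfied at the global solution", {
  for (seed in 1:8) {
    sys <- rand_system(seed, n_types = sample(1:3, 1))
    fit <- solve_global(sys)
    K <- c(as.numeric(t(fit$params$k)),
           if (sys$has_offset) fit$params$offset)
    grad <- crossprod(sys$B, sys$B %*% K - sys$y)
    expect_lt(max(abs(grad)),
              1e-8 * max(abs(crossprod(sys$B, sys$y))))
  }
})

test_that("global objective matches the QR least-squares oracle", {
  for (seed in 1:10) {
    sys <- rand_system(seed + 100, n_types = 2)
    fit <- solve_global(sys)
    expect_equal(fit$objective, oracle_global_objective(sys),
                 tolerance = 1e-9)
  }
})

test_that("scaling the target scales coefficients linearly and the objective quadratically", {
  sys <- rand_system(7)
  fit1 <- solve_global(sys)
  sys2 <- sys
  sys2$y <- 3 * sys$y
  fit2 <- solve_global(sys2)
  expect_equal(fit2$params$k, 3 * fit1$params$k, tolerance = 1e-8)
  expect_equal(fit2$objective, 9 * fit1$objective, tolerance = 1e-8)
})

test_that("bounded fit equals the global fit when no constraint is active", {
  sys <- rand_system(3, noise_sd = 0.5)
  g <- solve_global(sys)
  stopifnot(max(abs(g$params$k)) < 50)
  l <- solve_bounded(sys, T = max(abs(g$params$k)) + 1)
  expect_equal(l$params$k, g$params$k, tolerance = 1e-8)
  expect_equal(l$objective, g$objective, tolerance = 1e-10)
  expect_equal(l$method, "local")
})

test_that("a 1-D convex objective clips to the nearest bound", {
  ## single coefficient with unconstrained optimum k = 30, bound T = 20
  ty <- dihedral_typing(1)
  angles <- matrix(c(-120, -40, 0, 60, 140), 5, 1)
  ds <- scan_dataset(angles, rep(1, 5), angles[, 1],
                     e_target = 30 * (1 + cos(deg2rad_test(angles[, 1]))),
                     typing = ty)
  sys <- build_design_system(ds, n_terms = 3, include_offset = FALSE)
  sys$B <- sys$B[, 1, drop = FALSE]
  sys$n_terms <- 1L
  attr(sys, "class") <- "design_system"
  ## global optimum is exactly 30 by construction
  W <- crossprod(sys$B)
  expect_equal(as.numeric(solve(W, crossprod(sys$B, sys$y))), 30,
               tolerance = 1e-10)
  ## package path on the full 3-term system: fit only k1 via bounds
  full <- build_design_system(ds, n_terms = 3, include_offset = FALSE)
  b <- solve_bounded(full, T = 20)
  expect_true(all(abs(b$params$k) <= 20 + 1e-10))
  g <- suppressWarnings(solve_global(full))
  expect_gte(b$objective, g$objective - 1e-10)
})

test_that("bounded solutions match the constrained-optimization oracle", {
  for (seed in 1:10) {
    sys <- rand_system(seed + 200, n_types = 2, noise_sd = 2)
    g <- solve_global(sys)
    ## pick T so that at least one constraint is active
    T <- 0.5 * max(abs(g$params$k))
    if (T <= 0) next
    l <- solve_bounded(sys, T = T)
    expect_true(any(abs(abs(l$params$k) - T) < 1e-8))
    o <- oracle_bounded(sys, T)
    expect_lt(abs(l$objective - o) / o, 1e-6)
  }
})

test_that("bounded objective decreases as the box widens", {
  sys <- rand_system(17, noise_sd = 2)
  g <- solve_global(sys)
  Ts <- max(abs(g$params$k)) * c(0.2, 0.5, 0.8, 1.5)
  objs <- vapply(Ts, function(T) solve_bounded(sys, T)$objective, numeric(1))
  expect_true(all(diff(objs) <= 1e-8))
  expect_true(all(objs >= g$objective - 1e-10))
})

test_that("singular designs return the minimum-norm solution with a flag", {
  ## fixed 0-degree coupling with unscanned dihedrals: the columns of the
  ## never-scanned type are constant, aliasing the offset column
  ty <- dihedral_typing(c(1, 2))
  expect_warning(
    ds <- generate_dataset(ty, example_params(2), coupling = "fixed",
                           scan_dihedrals = 1, seed = 1),
    "rank-deficient"
  )
  sys <- build_design_system(ds)
  fit <- solve_global(sys)
  expect_true(fit$diagnostics$singular)
  expect_true(all(is.finite(fit$params$k)))
  ## still a least-squares solution: gradient vanishes
  K <- c(as.numeric(t(fit$params$k)), fit$params$offset)
  grad <- crossprod(sys$B, sys$B %*% K - sys$y)
  expect_lt(max(abs(grad)), 1e-6)
})

test_that("degenerate and invalid systems are rejected", {
  sys <- rand_system(5)
  expect_error(solve_bounded(sys, T = 0), "positive")
  expect_error(solve_bounded(sys, T = -3), "positive")
  zero_sys <- structure(list(B = matrix(0, 4, 2), y = rep(1, 4),
                             n_terms = 2L, has_offset = FALSE,
                             typing = dihedral_typing(1)),
                        class = "design_system")
  expect_error(solve_global(zero_sys), "degenerate")
  expect_error(solve_global(list()), "design_system")
})

test_that("large unconstrained coefficients trigger the MD-stability warning", {
  ty <- dihedral_typing(1)
  angles <- matrix(seq(-180, 170, by = 10), ncol = 1)
  big <- fourier_params(matrix(c(45, -30, 12, 5), 1, 4))
  ds <- generate_dataset(ty, big, seed = 1)
  expect_warning(solve_global(build_design_system(ds)), "20 kJ/mol")
})
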