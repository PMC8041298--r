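#' Generate a synthetic dihedral-scan dataset with known ground truth
#'
#' Emulates the structure of a relaxed quantum-chemical dihedral scan: for
#' each scanned dihedral, one conformer per grid angle on the half-open
#' grid \eqn{[-180, 180)} (36 conformers at the default 10-degree step),
#' with every other dihedral of the molecule taking a coupled value, and a
#' target torsional energy computed from known ground-truth coefficients
#' plus optional Gaussian noise. Because the generating coefficients are
#' known, solver accuracy and parameter recovery are directly checkable.
#'
#' Coupling modes for the off-scan angles:
#' \describe{
#'   \item{`"smooth"` (default)}{a fixed per-instance baseline plus a small
#'     deterministic sinusoid of the scan angle, imitating a relaxed scan
#'     where constraining one dihedral drags the others along smooth
#'     paths.}
#'   \item{`"fixed"`}{held at constant reference values (`fixed_angles`,
#'     default all 0). With this mode, dihedral types that are never
#'     scanned produce constant design columns and the system becomes
#'     rank-deficient.}
#'   \item{`"random"`}{independent uniform draws in \eqn{[-180, 180)}.}
#' }
#'
#' The generator checks the rank of the implied design system and warns
#' when it is deficient (the exact fit is then non-unique).
#'
#' @param typing a [dihedral_typing].
#' @param true_params a [fourier_params] with one row per type; the ground
#'   truth.
#' @param grid_step scan grid step in degrees; must divide 360 (default 10,
#'   giving 36 points per scan).
#' @param coupling `"smooth"`, `"fixed"` or `"random"`.
#' @param noise_sd standard deviation of Gaussian noise added to the
#'   target energies, kJ/mol (default 0).
#' @param seed integer seed controlling the noise and the `"random"`
#'   coupling; identical seeds give byte-identical datasets.
#' @param scan_dihedrals which dihedral instances to scan (default: all).
#' @param fixed_angles reference values for `coupling = "fixed"`, length
#'   `n_dihedrals` (default all 0).
#' @return a [scan_dataset] with `length(scan_dihedrals) * 360 / grid_step`
#'   records.
#' @examples
#' ds <- generate_dataset(dmph_typing(), example_params(), seed = 1)
#' length(ds)    # 15 dihedrals x 36 grid points = 540 conformers
#' @export
generate_dataset <- function(typing, true_params, grid_step = 10,
                             coupling = c("smooth", "fixed", "random"),
                             noise_sd = 0, seed = 1L,
                             scan_dihedrals = NULL, fixed_angles = NULL) {
  coupling <- match.arg(coupling)
  if (!inherits(typing, "dihedral_typing")) {
    stop_input("'typing' must be a dihedral_typing")
  }
  if (!inherits(true_params, "fourier_params")) {
    stop_input("'true_params' must be a fourier_params")
  }
  if (true_params$n_types != typing$n_types) {
    stop_input("'true_params' has ", true_params$n_types,
               " types but typing has ", typing$n_types)
  }
  if (!is.finite(grid_step) || grid_step <= 0 || 360 %% grid_step != 0) {
    stop_input("'grid_step' must be a positive divisor of 360 degrees")
  }
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop_input("'noise_sd' must be non-negative")
  }
  nd <- typing$n_dihedrals
  if (is.null(scan_dihedrals)) scan_dihedrals <- seq_len(nd)
  if (any(scan_dihedrals < 1) || any(scan_dihedrals > nd)) {
    stop_input("'scan_dihedrals' indices must lie in 1..", nd)
  }
  if (is.null(fixed_angles)) fixed_angles <- rep(0, nd)
  if (length(fixed_angles) != nd) {
    stop_input("'fixed_angles' must have one value per dihedral instance")
  }
  grid <- seq(-180, 180 - grid_step, by = grid_step)
  n_per_scan <- length(grid)
  n_rec <- length(scan_dihedrals) * n_per_scan

  ## deterministic per-instance coupling geometry (independent of the seed)
  base <- normalize_angle(137.5 * seq_len(nd))
  harm <- 1 + (seq_len(nd) %% 2L)
  phase <- 2 * pi * seq_len(nd) / nd

  with_local_seed(seed, {
    angles <- matrix(0, n_rec, nd)
    scanned <- integer(n_rec)
    scan_angle <- numeric(n_rec)
    ids <- character(n_rec)
    row <- 0L
    for (d in scan_dihedrals) {
      for (a in grid) {
        row <- row + 1L
        phi <- switch(coupling,
          smooth = normalize_angle(
            base + 25 * sin(harm * deg2rad(a) + phase + 0.3 * d)),
          fixed = fixed_angles,
          random = stats::runif(nd, -180, 180)
        )
        phi[d] <- a
        angles[row, ] <- phi
        scanned[row] <- d
        scan_angle[row] <- a
        ids[row] <- sprintf("d%02d_%+04d", d, a)
      }
    }
    e <- fourier_energy(true_params, angles, typing)
    if (noise_sd > 0) e <- e + stats::rnorm(n_rec, 0, noise_sd)
    ds <- scan_dataset(angles, scanned, scan_angle, e, typing,
                       conformer_id = ids)
    sys <- build_design_system(ds, n_terms = true_params$n_terms,
                               include_offset = TRUE)
    r <- qr(sys$B)$rank
    if (r < ncol(sys$B)) {
      warning("rank-deficient design (rank ", r, " < ", ncol(sys$B),
              " columns); coefficients of unscanned or constant dihedral ",
              "types are not identifiable", call. = FALSE)
    }
    ds
  })
}
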