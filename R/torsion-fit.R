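#' Fit torsional Fourier coefficients to a dihedral-scan dataset
#'
#' The main fitting interface. Builds the shared-coefficient design system
#' from the dataset and dispatches to the requested solver:
#' \describe{
#'   \item{`"global"`}{the exact least-squares solution of the normal
#'     equations ([solve_global()]); the optimum of the residual sum of
#'     squares, found algebraically with no tuning parameters.}
#'   \item{`"local"`}{the same objective with box constraints
#'     \eqn{|k| \le T} on every coefficient ([solve_bounded()]); use when
#'     unconstrained coefficients grow large enough to destabilise MD.}
#'   \item{`"mc"`}{a Metropolis Monte Carlo baseline ([mc_fit()]); included
#'     for comparison, it can at best reach the global optimum.}
#' }
#'
#' @param dataset a [scan_dataset] (see [read_scan_csv()] or
#'   [generate_dataset()]).
#' @param n_terms Fourier terms per dihedral type, 3 or 4 (default 4).
#' @param method `"global"`, `"local"` or `"mc"`.
#' @param bound box half-width `T` in kJ/mol for `method = "local"`
#'   (default 20).
#' @param include_offset fit a global additive constant absorbing the
#'   arbitrary difference between the reference and MM energy zeros
#'   (default `TRUE`; the constant is reported but never exported as a
#'   force-field parameter).
#' @param schedule an [mc_schedule()] for `method = "mc"`.
#' @param ... passed on to the solver.
#' @return an object of class `torsion_fit` carrying the fitted
#'   [fourier_params], the objective (residual sum of squares, kJ^2/mol^2),
#'   solver diagnostics, and the dataset (enabling [predict()],
#'   [residuals()], [plot()] and the per-scan RMSD report of [summary()]).
#' @examples
#' ds <- generate_dataset(dmph_typing(), example_params(),
#'                        noise_sd = 0.5, seed = 42)
#' fit <- torsion_fit(ds)
#' summary(fit)
#' coef(fit)
#' @export
torsion_fit <- function(dataset, n_terms = 4L,
                        method = c("global", "local", "mc"),
                        bound = 20, include_offset = TRUE,
                        schedule = mc_schedule(), ...) {
  method <- match.arg(method)
  system <- build_design_system(dataset, n_terms = n_terms,
                                include_offset = include_offset)
  fit <- switch(method,
    global = solve_global(system, ...),
    local = solve_bounded(system, T = bound, ...),
    mc = mc_fit(system, schedule = schedule, ...)
  )
  fit$dataset <- dataset
  fit$call <- match.call()
  fit
}

#' @export
print.torsion_fit <- function(x, digits = 4, ...) {
  label <- c(global = "exact global least squares",
             local = "bounded least squares",
             monte_carlo = "Metropolis Monte Carlo")[[x$method]]
  cat("Torsional coefficient fit (", label, ")\n", sep = "")
  cat("  ", x$typing$n_types, "dihedral types x", x$n_terms, "terms =",
      x$typing$n_types * x$n_terms, "shared parameters;",
      x$n_conformers, "conformers\n")
  if (!is.null(x$bound_T)) {
    cat("  coefficient bound: |k| <=", x$bound_T, "kJ/mol\n")
  }
  cat("  objective (residual sum of squares):",
      format(x$objective, digits = digits), "kJ^2/mol^2\n")
  if (x$has_offset) {
    cat("  fitted energy offset:", format(x$params$offset, digits = digits),
        "kJ/mol\n")
  }
  if (isTRUE(x$diagnostics$singular)) {
    cat("  NOTE: singular normal equations; minimum-norm solution\n")
  }
  cat("\nCoefficients (kJ/mol):\n")
  print(round(coef(x), digits))
  invisible(x)
}

#' @export
coef.torsion_fit <- function(object, ...) {
  k <- object$params$k
  if (!is.null(object$typing$type_labels)) {
    rownames(k) <- object$typing$type_labels
  }
  k
}

#' Predict torsional energies from a fitted model
#'
#' @param object a `torsion_fit`.
#' @param newdata a [scan_dataset], an angle matrix (rows = conformers,
#'   columns = dihedral instances, degrees), or `NULL` for the training
#'   conformers.
#' @param ... unused.
#' @return numeric vector of model torsional energies, kJ/mol.
#' @export
predict.torsion_fit <- function(object, newdata = NULL, ...) {
  angles <- if (is.null(newdata)) {
    if (is.null(object$dataset)) {
      stop_input("no dataset stored in the fit; supply 'newdata'")
    }
    object$dataset$angles
  } else if (inherits(newdata, "scan_dataset")) {
    newdata$angles
  } else {
    as.matrix(newdata)
  }
  fourier_energy(object$params, angles, object$typing)
}

#' @export
fitted.torsion_fit <- function(object, ...) predict(object)

#' @export
residuals.torsion_fit <- function(object, ...) {
  if (is.null(object$dataset)) {
    stop_input("no dataset stored in the fit")
  }
  object$dataset$e_target - fitted(object)
}

#' @export
summary.torsion_fit <- function(object, ...) {
  out <- list(fit = object,
              rb = fourier_to_rb(object$params),
              report = if (!is.null(object$dataset)) {
                scan_report(object$dataset, object)
              })
  class(out) <- "summary.torsion_fit"
  out
}

#' @export
print.summary.torsion_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nRyckaert-Bellemans equivalent (kJ/mol):\n")
  Cm <- x$rb$C
  if (!is.null(x$fit$typing$type_labels)) {
    rownames(Cm) <- x$fit$typing$type_labels
  }
  print(round(Cm, digits))
  if (!is.null(x$report)) {
    cat("\n")
    print(x$report, digits = digits)
  }
  invisible(x)
}

#' Plot reconstructed torsional profiles against the reference
#'
#' One panel per scanned dihedral: the target torsional energies along the
#' scan grid and the fitted model profile, both shifted so their minimum is
#' zero (energy zeros are arbitrary).
#'
#' @param x a `torsion_fit` carrying its dataset.
#' @param which integer vector of scanned-dihedral indices to plot
#'   (default: all).
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, `x`.
#' @export
plot.torsion_fit <- function(x, which = NULL, ...) {
  if (is.null(x$dataset)) stop_input("no dataset stored in the fit")
  ds <- x$dataset
  scans <- sort(unique(ds$scanned_dihedral))
  if (!is.null(which)) scans <- intersect(scans, which)
  if (length(scans) == 0L) stop_input("nothing to plot")
  model <- fitted(x)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(scans)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (d in scans) {
    sel <- ds$scanned_dihedral == d
    ord <- order(ds$scan_angle[sel])
    ang <- ds$scan_angle[sel][ord]
    ref <- ds$e_target[sel][ord]
    fitv <- model[sel][ord]
    graphics::matplot(ang, cbind(ref - min(ref), fitv - min(fitv)),
                      type = c("p", "l"), pch = 1, lty = 1,
                      col = c("grey40", "firebrick"),
                      xlab = "scan angle (deg)", ylab = "energy (kJ/mol)",
                      main = paste0("dihedral ", d), ...)
  }
  invisible(x)
}

#' Simulate scan datasets from a fitted torsional model
#'
#' Generates synthetic dihedral-scan datasets whose ground truth is the
#' fitted coefficient set, using the same scan layout machinery as
#' [generate_dataset()].
#'
#' @param object a `torsion_fit`.
#' @param nsim number of datasets.
#' @param seed integer seed; dataset `i` uses `seed + i - 1`.
#' @param noise_sd Gaussian noise on the simulated target energies, kJ/mol.
#' @param ... passed to [generate_dataset()].
#' @return a list of [scan_dataset] objects of length `nsim`.
#' @export
simulate.torsion_fit <- function(object, nsim = 1, seed = 1L,
                                 noise_sd = 0, ...) {
  lapply(seq_len(nsim), function(i) {
    generate_dataset(object$typing, object$params, noise_sd = noise_sd,
                     seed = seed + i - 1L, ...)
  })
}
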