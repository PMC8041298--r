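#' Root-mean-square deviation between two energy profiles
#'
#' Scores a reconstructed torsional energy profile against a reference.
#' Because the absolute zeros of reference and model energies are
#' arbitrary, profiles are by default aligned first: each is shifted so
#' its minimum is zero, making the score invariant to constant offsets.
#'
#' @param fitted numeric vector of model energies, kJ/mol.
#' @param reference numeric vector of reference energies, same length >= 2.
#' @param align shift each profile to a zero minimum first (default
#'   `TRUE`).
#' @return RMSD in kJ/mol.
#' @examples
#' profile_rmsd(c(0, 1, 4), c(2, 3, 6))        # 0: same shape
#' profile_rmsd(c(0, 0, 0), c(1, 1, 1), align = FALSE)   # 1
#' @export
profile_rmsd <- function(fitted, reference, align = TRUE) {
  if (length(fitted) != length(reference)) {
    stop_input("profiles must have equal length (got ", length(fitted),
               " and ", length(reference), ")")
  }
  if (length(fitted) < 2L) {
    stop_input("profiles must contain at least 2 points")
  }
  if (align) {
    fitted <- fitted - min(fitted)
    reference <- reference - min(reference)
  }
  sqrt(mean((fitted - reference)^2))
}

#' Per-scan RMSD report for a fitted torsional model
#'
#' Groups the dataset's conformers by scanned dihedral, reconstructs the
#' model torsional energy of each conformer from the fitted coefficients,
#' and scores each scan's profile against the target energies with
#' [profile_rmsd()] (minimum-aligned by default). The overall figure of
#' merit is the unweighted average of the per-scan RMSDs.
#'
#' @param dataset a [scan_dataset].
#' @param fit a `torsion_fit` (or bare [fourier_params]) dimensioned for
#'   the dataset's typing.
#' @param align passed to [profile_rmsd()].
#' @return an object of class `scan_report`: a data frame with columns
#'   `scanned_dihedral`, `type_label`, `n_points`, `rmsd_kj_mol`, plus an
#'   `average_rmsd` attribute.
#' @examples
#' ds <- generate_dataset(dmph_typing(), example_params(), seed = 7)
#' rep <- scan_report(ds, torsion_fit(ds))
#' attr(rep, "average_rmsd")   # ~0 on noiseless data
#' @export
scan_report <- function(dataset, fit, align = TRUE) {
  if (!inherits(dataset, "scan_dataset")) {
    stop_input("'dataset' must be a scan_dataset")
  }
  params <- if (inherits(fit, "torsion_fit")) fit$params else fit
  if (!inherits(params, "fourier_params")) {
    stop_input("'fit' must be a torsion_fit or fourier_params")
  }
  typing <- dataset$typing
  if (params$n_types != typing$n_types) {
    stop_input("fit has ", params$n_types, " types but dataset typing has ",
               typing$n_types)
  }
  model <- fourier_energy(params, dataset$angles, typing)
  scans <- sort(unique(dataset$scanned_dihedral))
  labels <- if (is.null(typing$type_labels)) {
    paste0("type", typing$type_of)
  } else {
    typing$type_labels[typing$type_of]
  }
  rows <- lapply(scans, function(d) {
    sel <- dataset$scanned_dihedral == d
    data.frame(
      scanned_dihedral = d,
      type_label = labels[d],
      n_points = sum(sel),
      rmsd_kj_mol = profile_rmsd(model[sel], dataset$e_target[sel],
                                 align = align),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "average_rmsd") <- mean(out$rmsd_kj_mol)
  class(out) <- c("scan_report", "data.frame")
  out
}

#' @export
print.scan_report <- function(x, digits = 4, ...) {
  cat("Per-scan profile RMSD (kJ/mol):\n")
  df <- as.data.frame(unclass(x), stringsAsFactors = FALSE)
  df$rmsd_kj_mol <- round(df$rmsd_kj_mol, digits)
  print(df, row.names = FALSE)
  cat("average RMSD across scans:",
      format(attr(x, "average_rmsd"), digits = digits), "kJ/mol\n")
  invisible(x)
}

#' Write a scan report as CSV
#'
#' The per-scan table followed by a summary line
#' (`average,,,<value>`).
#'
#' @param report a [scan_report()] result.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_scan_report <- function(report, path) {
  df <- as.data.frame(unclass(report), stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  writeLines(sprintf("average,,,%.*g", 15, attr(report, "average_rmsd")),
             con)
  invisible(path)
}
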