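#' Dihedral-scan dataset
#'
#' The fitting evidence: one record per conformer of a relaxed dihedral
#' scan. Each record stores the value of \emph{every} dihedral angle in the
#' molecule (scans are conjugated -- constraining one dihedral moves the
#' others) together with the target torsional energy, defined as the
#' reference (typically quantum-mechanical) total energy minus the molecular
#' mechanics energy computed with all torsional coefficients set to zero.
#'
#' @param angles numeric matrix (`n_records` x `n_dihedrals`), degrees; the
#'   value of every dihedral in each conformer. Values of exactly +180 are
#'   normalized to -180; anything else outside \eqn{[-180, 180)} is an error.
#' @param scanned_dihedral integer vector; for each record, the 1-based
#'   index of the dihedral that was constrained during the scan.
#' @param scan_angle numeric vector, degrees; the constrained value. Must
#'   match `angles[k, scanned_dihedral[k]]` to 1e-6 degrees.
#' @param e_target numeric vector, kJ/mol; the torsional target energy.
#' @param typing a [dihedral_typing].
#' @param conformer_id optional character vector of unique record ids;
#'   generated when missing.
#' @return an object of class `scan_dataset`.
#' @seealso [generate_dataset()], [read_scan_csv()], [torsion_fit()]
#' @export
scan_dataset <- function(angles, scanned_dihedral, scan_angle, e_target,
                         typing, conformer_id = NULL) {
  if (!inherits(typing, "dihedral_typing")) {
    stop_input("'typing' must be a dihedral_typing object")
  }
  angles <- as.matrix(angles)
  n <- nrow(angles)
  if (n < 1L) stop_input("dataset must contain at least one record")
  if (ncol(angles) != typing$n_dihedrals) {
    stop_input("angle matrix has ", ncol(angles),
               " columns but typing declares ", typing$n_dihedrals,
               " dihedral instances")
  }
  if (length(scanned_dihedral) != n || length(scan_angle) != n ||
      length(e_target) != n) {
    stop_input("'scanned_dihedral', 'scan_angle' and 'e_target' must each ",
               "have one value per record")
  }
  if (any(scanned_dihedral < 1) || any(scanned_dihedral > typing$n_dihedrals)) {
    stop_input("'scanned_dihedral' indices must lie in 1..",
               typing$n_dihedrals)
  }
  if (any(!is.finite(angles))) {
    bad <- which(!is.finite(angles), arr.ind = TRUE)[1L, ]
    stop_input("non-finite angle in record ", bad[1L])
  }
  if (any(!is.finite(e_target))) {
    stop_input("non-finite target energy in record ",
               which(!is.finite(e_target))[1L])
  }
  ## +180 is the same torsion as -180; fold it rather than reject it
  angles[angles == 180] <- -180
  scan_angle[scan_angle == 180] <- -180
  out_of_range <- which(angles < -180 | angles >= 180, arr.ind = TRUE)
  if (nrow(out_of_range) > 0L) {
    stop_input("angle outside [-180, 180) in record ", out_of_range[1L, 1L],
               ", dihedral ", out_of_range[1L, 2L])
  }
  sc <- angles[cbind(seq_len(n), scanned_dihedral)]
  off <- which(abs(sc - scan_angle) > 1e-6)
  if (length(off) > 0L) {
    stop_input("record ", off[1L], ": scan_angle (", scan_angle[off[1L]],
               ") does not match the stored angle of the scanned dihedral (",
               sc[off[1L]], ")")
  }
  if (is.null(conformer_id)) {
    conformer_id <- sprintf("c%04d", seq_len(n))
  }
  conformer_id <- as.character(conformer_id)
  if (anyDuplicated(conformer_id)) {
    stop_input("duplicate conformer_id: ",
               conformer_id[anyDuplicated(conformer_id)])
  }
  dimnames(angles) <- list(NULL, paste0("phi_", seq_len(ncol(angles))))
  structure(
    list(
      typing = typing,
      conformer_id = conformer_id,
      scanned_dihedral = as.integer(scanned_dihedral),
      scan_angle = as.numeric(scan_angle),
      e_target = as.numeric(e_target),
      angles = angles
    ),
    class = "scan_dataset"
  )
}

#' @export
print.scan_dataset <- function(x, ...) {
  cat("Dihedral-scan dataset:", length(x$e_target), "conformers,",
      x$typing$n_dihedrals, "dihedrals (", x$typing$n_types, "types )\n")
  scans <- sort(unique(x$scanned_dihedral))
  cat("  scanned dihedrals:", paste(scans, collapse = ", "), "\n")
  cat(sprintf("  target energy range: %.3f .. %.3f kJ/mol\n",
              min(x$e_target), max(x$e_target)))
  invisible(x)
}

#' @export
length.scan_dataset <- function(x) length(x$e_target)

#' Coerce a scan dataset to a data frame
#'
#' One row per conformer: id, scanned dihedral, scan angle, target energy,
#' then one `phi_i` column per dihedral instance (degrees). This is also
#' the on-disk CSV layout used by [write_scan_csv()].
#'
#' @param x a `scan_dataset`.
#' @param ... unused.
#' @return a `data.frame`.
#' @export
as.data.frame.scan_dataset <- function(x, ...) {
  data.frame(
    conformer_id = x$conformer_id,
    scanned_dihedral = x$scanned_dihedral,
    scan_angle = x$scan_angle,
    e_target = x$e_target,
    x$angles,
    stringsAsFactors = FALSE
  )
}
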