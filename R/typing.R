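#' Dihedral typing: grouping of dihedral instances into shared types
#'
#' Force fields assign one set of torsional coefficients per dihedral
#' \emph{type} (an equivalence class of atom-type quadruples), while a
#' molecule contains many dihedral \emph{instances} of each type. A
#' `dihedral_typing` records, for each instance, which type it belongs to,
#' so that all instances of a type share one coefficient set during fitting.
#'
#' @param type_of integer vector of length `n_dihedrals`; element `i` is the
#'   1-based type index of dihedral instance `i`. Every type index from 1 to
#'   `max(type_of)` must be used by at least one instance.
#' @param type_labels optional character vector of length `n_types` with
#'   atom-type quadruple labels such as `"CT-OS-P-OS"`. Required for GROMACS
#'   `.itp` export.
#' @return an object of class `dihedral_typing` with fields `n_dihedrals`,
#'   `n_types`, `type_of`, `type_labels` and `multiplicity` (instances per
#'   type; the multiplicities always sum to `n_dihedrals`).
#' @examples
#' ## three instances, two types, the first type used twice
#' dihedral_typing(c(1, 1, 2), c("CT-OS-P-OS", "HC-CT-OS-P"))
#' @seealso [dmph_typing()] for the dimethyl phosphoric acid example.
#' @export
dihedral_typing <- function(type_of, type_labels = NULL) {
  if (length(type_of) < 1L) {
    stop_input("'type_of' must contain at least one dihedral instance")
  }
  if (any(!is.finite(type_of)) || any(type_of != round(type_of)) ||
      any(type_of < 1)) {
    stop_input("'type_of' must be positive integer type indices")
  }
  type_of <- as.integer(type_of)
  n_types <- max(type_of)
  used <- tabulate(type_of, nbins = n_types)
  if (any(used == 0L)) {
    stop_input("every type index in 1..", n_types,
               " must be used; unused: ",
               paste(which(used == 0L), collapse = ", "))
  }
  if (!is.null(type_labels)) {
    if (length(type_labels) != n_types) {
      stop_input("'type_labels' must have one label per type (",
                 n_types, "), got ", length(type_labels))
    }
    type_labels <- as.character(type_labels)
  }
  structure(
    list(
      n_dihedrals = length(type_of),
      n_types = n_types,
      type_of = type_of,
      type_labels = type_labels,
      multiplicity = used
    ),
    class = "dihedral_typing"
  )
}

#' @export
print.dihedral_typing <- function(x, ...) {
  cat("Dihedral typing:", x$n_dihedrals, "instances in", x$n_types,
      "types\n")
  lab <- if (is.null(x$type_labels)) paste0("type ", seq_len(x$n_types)) else
    x$type_labels
  for (g in seq_len(x$n_types)) {
    cat(sprintf("  %-14s x%d  (instances %s)\n", lab[g], x$multiplicity[g],
                paste(which(x$type_of == g), collapse = ", ")))
  }
  invisible(x)
}

#' Dihedral typing of dimethyl phosphoric acid (DMPH)
#'
#' The 15 dihedral angles of protonated dimethyl phosphoric acid fall into
#' six atom-type quadruple classes with multiplicities 2, 2, 2, 6, 1 and 2:
#' CT-OS-P-OS (2), CT-OS-P-O2 (2), CT-OS-P-OH (2), HC-CT-OS-P (6),
#' HO-OH-P-O2 (1) and HO-OH-P-OS (2). With four Fourier terms per type this
#' gives the molecule's 24 torsional parameters.
#'
#' @return a [dihedral_typing] for the 15 DMPH dihedrals.
#' @examples
#' ty <- dmph_typing()
#' ty$multiplicity    # 2 2 2 6 1 2
#' @export
dmph_typing <- function() {
  dihedral_typing(
    type_of = rep(1:6, times = c(2L, 2L, 2L, 6L, 1L, 2L)),
    type_labels = c("CT-OS-P-OS", "CT-OS-P-O2", "CT-OS-P-OH",
                    "HC-CT-OS-P", "HO-OH-P-O2", "HO-OH-P-OS")
  )
}
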