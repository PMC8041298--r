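#' Assemble the shared-coefficient design system
#'
#' Builds the linear least-squares system whose solution is the set of
#' Fourier torsional coefficients. The basis function for term `j` at a
#' dihedral angle `phi` is `1 + cos(j * phi)`; because all instances of a
#' dihedral type share one coefficient, the design column for (type `g`,
#' term `j`) is the \emph{sum} of `1 + cos(j * phi_i)` over the instances
#' `i` belonging to `g`. The target vector holds the per-conformer
#' torsional energies.
#'
#' The reference and molecular-mechanics energy scales have unrelated
#' zeros, so by default a trailing all-ones column is appended and its
#' coefficient absorbs the arbitrary additive constant; it is reported as
#' `offset` by the fitters and never exported as a force-field parameter.
#'
#' @param dataset a [scan_dataset].
#' @param n_terms number of Fourier terms per type, 3 or 4.
#' @param include_offset append the all-ones offset column (default `TRUE`).
#' @return an object of class `design_system`: a list with the design
#'   matrix `B` (`n_records` x `n_types * n_terms (+1)`, columns ordered
#'   type-major then term), target `y` (kJ/mol), `n_terms`, `has_offset`
#'   and the `typing`. Every non-offset entry lies in
#'   `[0, 2 * multiplicity(type)]`.
#' @examples
#' ds <- generate_dataset(dmph_typing(), example_params(), seed = 1)
#' sys <- build_design_system(ds, n_terms = 4, include_offset = FALSE)
#' dim(sys$B)   # 540 records x 24 shared parameters
#' @export
build_design_system <- function(dataset, n_terms = 4L, include_offset = TRUE) {
  if (!inherits(dataset, "scan_dataset")) {
    stop_input("'dataset' must be a scan_dataset")
  }
  if (!is_count(n_terms) || !(n_terms %in% c(3L, 4L))) {
    stop_input("'n_terms' must be 3 or 4")
  }
  n_terms <- as.integer(n_terms)
  typing <- dataset$typing
  phi <- deg2rad(dataset$angles)          # n_records x n_dihedrals
  n_rec <- nrow(phi)
  n_cols <- typing$n_types * n_terms + as.integer(include_offset)
  B <- matrix(0, n_rec, n_cols)
  cn <- character(n_cols)
  col <- 0L
  for (g in seq_len(typing$n_types)) {
    members <- which(typing$type_of == g)
    for (j in seq_len(n_terms)) {
      col <- col + 1L
      A <- 1 + cos(j * phi[, members, drop = FALSE])
      B[, col] <- rowSums(A)
      cn[col] <- sprintf("k[%d,%d]", g, j)
    }
  }
  if (include_offset) {
    B[, n_cols] <- 1
    cn[n_cols] <- "offset"
  }
  colnames(B) <- cn
  structure(
    list(
      B = B,
      y = dataset$e_target,
      n_terms = n_terms,
      has_offset = isTRUE(include_offset),
      typing = typing
    ),
    class = "design_system"
  )
}

#' @export
print.design_system <- function(x, ...) {
  cat("Torsional design system:", nrow(x$B), "conformers x", ncol(x$B),
      "columns\n")
  cat("  ", x$typing$n_types, "types x", x$n_terms, "terms",
      if (x$has_offset) "+ offset column" else "", "\n")
  invisible(x)
}

## number of fitted coefficients excluding the offset column
n_coef <- function(system) {
  system$typing$n_types * system$n_terms
}
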