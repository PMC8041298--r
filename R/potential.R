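#' Fourier torsional parameters
#'
#' Coefficients of the truncated cosine series
#' \deqn{V(\phi) = \sum_{j=1}^{m} k_j \,(1 + \cos j\phi), \quad m \in \{3,4\},}
#' one row of coefficients per dihedral type (kJ/mol). An optional scalar
#' `offset` (kJ/mol) carries the fitted additive constant that aligns the
#' reference and molecular-mechanics energy zeros; it is not a force-field
#' parameter.
#'
#' @param k numeric matrix (`n_types` x `n_terms`), `n_terms` 3 or 4, all
#'   values finite.
#' @param offset scalar kJ/mol, default 0.
#' @return an object of class `fourier_params`.
#' @examples
#' fourier_params(matrix(c(1, 0, 0.5, 0), 1, 4))
#' @export
fourier_params <- function(k, offset = 0) {
  k <- as.matrix(k)
  if (!(ncol(k) %in% c(3L, 4L))) {
    stop_input("'k' must have 3 or 4 columns (Fourier terms), got ", ncol(k))
  }
  if (any(!is.finite(k))) stop_input("coefficients must be finite")
  if (length(offset) != 1L || !is.finite(offset)) {
    stop_input("'offset' must be a finite scalar")
  }
  storage.mode(k) <- "double"
  dimnames(k) <- list(paste0("type", seq_len(nrow(k))),
                      paste0("j", seq_len(ncol(k))))
  structure(
    list(n_types = nrow(k), n_terms = ncol(k), k = k,
         offset = as.numeric(offset)),
    class = "fourier_params"
  )
}

#' @export
print.fourier_params <- function(x, digits = 4, ...) {
  cat("Fourier torsional coefficients (kJ/mol),", x$n_types, "types x",
      x$n_terms, "terms\n")
  print(round(x$k, digits))
  if (x$offset != 0) cat("offset:", format(x$offset, digits = digits),
                         "kJ/mol\n")
  invisible(x)
}

#' Ryckaert-Bellemans torsional parameters
#'
#' Coefficients `C0..C5` (kJ/mol) of the polynomial
#' \deqn{V(\phi) = \sum_{n=0}^{5} C_n \cos^n\psi, \quad \psi = \phi - 180^\circ,}
#' the torsional representation used by MD engines such as GROMACS
#' (dihedral function type 3). Any parameter set converted from a 4-term
#' Fourier set has `C5 = 0` exactly.
#'
#' @param C numeric matrix (`n_types` x 6).
#' @param offset scalar kJ/mol carried through from the Fourier fit so the
#'   Fourier/RB energy identity holds; written to `.itp` files only as a
#'   comment.
#' @return an object of class `rb_params`.
#' @export
rb_params <- function(C, offset = 0) {
  C <- as.matrix(C)
  if (ncol(C) != 6L) stop_input("'C' must have 6 columns (C0..C5)")
  if (any(!is.finite(C))) stop_input("coefficients must be finite")
  storage.mode(C) <- "double"
  dimnames(C) <- list(paste0("type", seq_len(nrow(C))), paste0("C", 0:5))
  structure(
    list(n_types = nrow(C), C = C, offset = as.numeric(offset)),
    class = "rb_params"
  )
}

#' @export
print.rb_params <- function(x, digits = 4, ...) {
  cat("Ryckaert-Bellemans coefficients (kJ/mol),", x$n_types, "types\n")
  print(round(x$C, digits))
  if (x$offset != 0) cat("offset:", format(x$offset, digits = digits),
                         "kJ/mol\n")
  invisible(x)
}

#' Torsional energy of a conformer in the Fourier basis
#'
#' Sums `k[type(i), j] * (1 + cos(j * phi_i))` over every dihedral instance
#' `i` and term `j`, plus the offset.
#'
#' @param params a [fourier_params] with one coefficient row per type.
#' @param angles numeric vector of length `n_dihedrals` (one conformer) or a
#'   matrix with one conformer per row; degrees.
#' @param typing a [dihedral_typing] matching `params` and `angles`.
#' @return energy in kJ/mol; a vector with one value per conformer.
#' @examples
#' ty <- dihedral_typing(1)
#' p <- fourier_params(matrix(c(1, 0, 0, 0), 1, 4))
#' fourier_energy(p, 0, ty)    # 1 + cos(0) = 2 kJ/mol
#' @export
fourier_energy <- function(params, angles, typing) {
  check_energy_args(params$n_types, angles, typing)
  angles <- if (is.matrix(angles)) angles else matrix(angles, nrow = 1L)
  phi <- deg2rad(angles)
  e <- rep(params$offset, nrow(phi))
  for (j in seq_len(params$n_terms)) {
    kj <- params$k[typing$type_of, j]        # coefficient per instance
    e <- e + (1 + cos(j * phi)) %*% kj
  }
  as.numeric(e)
}

#' Torsional energy of a conformer in the Ryckaert-Bellemans basis
#'
#' Evaluates the degree-5 polynomial in `cos(phi - 180)` for each dihedral
#' instance and sums over instances, plus the carried offset.
#'
#' @inheritParams fourier_energy
#' @param params an [rb_params].
#' @return energy in kJ/mol; a vector with one value per conformer.
#' @export
rb_energy <- function(params, angles, typing) {
  check_energy_args(params$n_types, angles, typing)
  angles <- if (is.matrix(angles)) angles else matrix(angles, nrow = 1L)
  cpsi <- cos(deg2rad(angles - 180))
  e <- rep(params$offset, nrow(cpsi))
  pow <- matrix(1, nrow(cpsi), ncol(cpsi))
  for (n in 0:5) {
    Cn <- params$C[typing$type_of, n + 1L]
    e <- e + pow %*% Cn
    if (n < 5) pow <- pow * cpsi
  }
  as.numeric(e)
}

check_energy_args <- function(n_types, angles, typing) {
  if (!inherits(typing, "dihedral_typing")) {
    stop_input("'typing' must be a dihedral_typing")
  }
  if (n_types != typing$n_types) {
    stop_input("parameter set has ", n_types, " types but typing has ",
               typing$n_types)
  }
  nd <- if (is.matrix(angles)) ncol(angles) else length(angles)
  if (nd != typing$n_dihedrals) {
    stop_input("angle vector length ", nd, " does not match the ",
               typing$n_dihedrals, " dihedral instances of the typing")
  }
}

#' Convert Fourier torsional coefficients to Ryckaert-Bellemans form
#'
#' Under the half-turn substitution \eqn{\psi = \phi - 180^\circ} each
#' cosine term `1 + cos(j phi)` becomes a polynomial in `cos(psi)`
#' (Chebyshev expansion with alternating sign), giving the exact linear map
#' \deqn{C_0 = k_1 + k_3 + 2k_4,\; C_1 = -k_1 + 3k_3,\; C_2 = 2k_2 - 8k_4,}
#' \deqn{C_3 = -4k_3,\; C_4 = 8k_4,\; C_5 = 0.}
#' The constant term is preserved exactly (constants never affect forces),
#' so `rb_energy()` on the result reproduces `fourier_energy()` at every
#' angle to machine precision. Three-term sets are zero-padded with
#' `k4 = 0`.
#'
#' @param params a [fourier_params].
#' @return an [rb_params] with the same number of types and the offset
#'   carried through.
#' @examples
#' p <- fourier_params(matrix(c(1, 0, 0, 0), 1, 4))
#' fourier_to_rb(p)$C    # 1 + cos(phi) = 1 - cos(psi):  C = (1,-1,0,0,0,0)
#' @export
fourier_to_rb <- function(params) {
  if (!inherits(params, "fourier_params")) {
    stop_input("'params' must be a fourier_params")
  }
  k <- params$k
  if (ncol(k) == 3L) k <- cbind(k, 0)
  C <- cbind(
    k[, 1L] + k[, 3L] + 2 * k[, 4L],
    -k[, 1L] + 3 * k[, 3L],
    2 * k[, 2L] - 8 * k[, 4L],
    -4 * k[, 3L],
    8 * k[, 4L],
    0
  )
  rb_params(C, offset = params$offset)
}

#' Convert Ryckaert-Bellemans coefficients back to the Fourier basis
#'
#' Inverts the linear map of [fourier_to_rb()]. The map from four Fourier
#' coefficients to `C1..C4` is triangular and invertible; `C5` must be zero
#' (a nonzero `C5` has no 4-term Fourier preimage). Any constant left over
#' after matching `C0` is moved into the `offset`, so the energy identity
#' holds in both directions.
#'
#' @param params an [rb_params] with `C5 = 0` (to 1e-9 kJ/mol).
#' @return a [fourier_params] with 4 terms.
#' @export
rb_to_fourier <- function(params) {
  if (!inherits(params, "rb_params")) {
    stop_input("'params' must be an rb_params")
  }
  C <- params$C
  if (any(abs(C[, 6L]) > 1e-9)) {
    stop_input("C5 must be zero: a degree-5 cosine polynomial has no ",
               "4-term Fourier representation")
  }
  k4 <- C[, 5L] / 8
  k3 <- -C[, 4L] / 4
  k2 <- (C[, 3L] + 8 * k4) / 2
  k1 <- 3 * k3 - C[, 2L]
  k <- cbind(k1, k2, k3, k4)
  ## constant not matched by the k's goes to the offset
  residual_const <- sum(C[, 1L] - (k1 + k3 + 2 * k4))
  fourier_params(k, offset = params$offset + residual_const)
}

#' Example DMPH-like ground-truth coefficients
#'
#' A fixed, reproducible 6-type, 4-term coefficient set with magnitudes
#' typical of OPLS-style torsions (within a few kJ/mol), used as ground
#' truth in examples and synthetic scans.
#'
#' @param n_types number of dihedral types (default 6, as in DMPH).
#' @param n_terms Fourier terms per type, 3 or 4.
#' @return a [fourier_params].
#' @export
example_params <- function(n_types = 6L, n_terms = 4L) {
  ## deterministic low-discrepancy fill in [-6, 6] kJ/mol
  idx <- seq_len(n_types * n_terms)
  vals <- 6 * sin(idx * 2.399963)            # golden-angle stride, |k| <= 6
  fourier_params(matrix(round(vals, 3), n_types, n_terms, byrow = TRUE))
}
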