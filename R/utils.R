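#' @keywords internal
"_PACKAGE"

## Angles are degrees at every user-facing surface; radians only inside
## trigonometric kernels.

deg2rad <- function(x) x * pi / 180

#' Normalize angles to the half-open interval [-180, 180)
#'
#' Dihedral angles are periodic with period 360 degrees; the package stores
#' them on the half-open domain \eqn{[-180, 180)} so that +180 and -180 (the
#' same conformation) have a single representation.
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector of the same length, each value in \eqn{[-180, 180)}.
#' @examples
#' normalize_angle(c(180, -180, 190, 360, -725))
#' @export
normalize_angle <- function(x) {
  ((x + 180) %% 360) - 180
}

## Run an expression with a locally seeded RNG, restoring the caller's
## random state afterwards. seed = NULL leaves the global stream untouched.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

stop_input <- function(...) {
  stop(..., call. = FALSE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}
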