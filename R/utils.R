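#' @importFrom rlang %||% .data
#' @importFrom stats fft lm median pf quantile rnorm runif sd var
NULL

#' Derive a reproducible substream seed
#'
#' Expands one global seed into independent per-unit seeds via a small
#' multiplicative-congruential hash, so that simulating subject 7 gives the
#' same draws whether or not subjects 1..6 were simulated first.  All
#' arithmetic stays below 2^53 so the double-precision modulo is exact; the
#' result is always in `[1, 2^31 - 2]`.
#'
#' @param seed integer global seed.
#' @param ... integer indices identifying the substream (stage, subject,
#'   trial, condition, ...).
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (idx in c(...)) {
    h <- (h * 69069 + as.numeric(idx) + 1) %% m
  }
  as.integer(h + 1)
}

clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))

#' Rotation matrix taking a vector to the vertical axis
#'
#' Returns the minimal rotation (Rodrigues' formula, axis = v x e3) that maps
#' the direction of `v` onto (0, 0, 1).  Used by both the simulator (to tilt
#' the gravity vector) and the calibration stage (to undo the tilt); because
#' both use the minimal rotation, the two compose to the identity exactly.
#'
#' @param v numeric length-3 vector (need not be unit length).
#' @return a 3 x 3 rotation matrix.
#' @keywords internal
rotation_to_vertical <- function(v) {
  u <- v / sqrt(sum(v^2))
  cth <- u[3]
  if (cth > 1 - 1e-12) {
    return(diag(3))
  }
  if (cth < -1 + 1e-12) {
    # antipodal: rotate pi about the x axis
    return(diag(c(1, -1, -1)))
  }
  axis <- c(u[2], -u[1], 0)           # u x e3
  axis <- axis / sqrt(sum(axis^2))
  th <- acos(cth)
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

rotation_about_horizontal <- function(psi, theta) {
  # rotation by angle theta about the horizontal axis (cos psi, sin psi, 0)
  axis <- c(cos(psi), sin(psi), 0)
  K <- matrix(c(0, 0, axis[2],
                0, 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}
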