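# Internal numeric and condition helpers shared across modules.

#' @importFrom stats dnorm median rnorm runif
#' @importFrom utils modifyList
NULL

# Round half away from zero (R's round() is banker's rounding).
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

clip <- function(x, lo, hi) {
  pmin(pmax(x, lo), hi)
}

# Classed conditions so callers can distinguish failure modes.
stainkit_error <- function(subclass, message, call = sys.call(-1), ...) {
  stop(structure(
    class = c(paste0("stainkit_", subclass), "stainkit_error", "error", "condition"),
    list(message = message, call = call, ...)
  ))
}

stainkit_warning <- function(subclass, message, ...) {
  warning(structure(
    class = c(paste0("stainkit_", subclass), "stainkit_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library functions never perturb user-level randomness.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# Angle in degrees between two 3-vectors (used throughout tests and QC).
#' Angular distance between two stain vectors
#'
#' Returns the angle, in degrees, between two 3-vectors in optical-density
#' space. Used to quantify stain-vector estimation error against ground truth.
#'
#' @param a,b Numeric 3-vectors (need not be unit length).
#' @return Angle in degrees in \code{[0, 180]}.
#' @export
angle_between <- function(a, b) {
  ca <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(clip(ca, -1, 1)) * 180 / pi
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) {
    stainkit_error("degenerate_vector", "cannot normalize a (near-)zero vector")
  }
  v / n
}
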