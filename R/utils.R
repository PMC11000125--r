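#' @keywords internal
"_PACKAGE"

## Angle conventions used throughout: public interfaces take and report
## degrees (counter-clockwise positive); internals work in radians.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap an angle in degrees to (-180, 180]
#'
#' Circular differences between centroid angles must live on a single branch;
#' the convention here is the half-open interval (-180, 180].
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector wrapped to (-180, 180].
#' @export
wrap_angle_deg <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

#' Circular difference a - b in degrees, wrapped to (-180, 180]
#'
#' @param a,b numeric vectors of angles in degrees.
#' @return wrapped difference in degrees.
#' @export
circ_diff_deg <- function(a, b) wrap_angle_deg(a - b)

#' Circular mean of angles in degrees
#'
#' Resultant-vector mean; returns NA for an empty input or a zero resultant.
#'
#' @param x numeric vector of angles in degrees.
#' @return scalar mean angle in (-180, 180].
#' @export
circ_mean_deg <- function(x) {
  if (length(x) == 0L) return(NA_real_)
  s <- mean(sin(deg2rad(x)))
  c <- mean(cos(deg2rad(x)))
  if (s == 0 && c == 0) return(NA_real_)
  wrap_angle_deg(rad2deg(atan2(s, c)))
}

## Mean resultant length of angles given in radians (0 = uniform, 1 = point mass).
circ_resultant <- function(theta) {
  sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
}

## Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
## caller's stream afterwards. seed = NULL uses (and advances) the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

## Deterministically derive a child seed from a master seed and a label,
## keeping the result in [1, 2^31 - 2].
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((abs(master) * 7919 + h * 104729 + 12345) %% (2^31 - 3) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
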