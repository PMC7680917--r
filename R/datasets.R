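#' Geometry of the equal-area flag disk
#'
#' The "sun" of the Japanese-flag problem: a disk centred at (0.5, 0.5) whose
#' default radius `(2*pi)^(-1/2)` makes its area exactly half of the unit
#' square, so a constant or random classifier scores 50%.
#'
#' @param radius Disk radius in unit-square coordinates.
#' @param center Numeric length-2 centre.
#' @return An object of class `flag_geometry`.
#' @export
flag_geometry <- function(radius = (2 * pi)^(-0.5), center = c(0.5, 0.5)) {
  stopifnot(radius > 0, length(center) == 2L)
  structure(list(radius = radius, center = as.numeric(center)),
            class = "flag_geometry")
}

#' Disk label of a point
#'
#' `g = 1` (red/sun) iff the point lies inside or on the disk boundary.
#' Vectorised over `x` and `y`.
#'
#' @param x,y Coordinates in the closed unit interval.
#' @param geom A [flag_geometry()].
#' @return Integer label(s) in {0, 1}.
#' @export
disk_label <- function(x, y, geom = flag_geometry()) {
  stopifnot(all(x >= 0 & x <= 1), all(y >= 0 & y <= 1))
  as.integer((x - geom$center[1])^2 + (y - geom$center[2])^2 <=
               geom$radius^2)
}

#' Sample a labeled Japanese-flag dataset
#'
#' Draws `n` i.i.d. uniform points in the unit square and labels them with
#' [disk_label()]. Reproducible for a given seed; the global RNG state is
#' left untouched.
#'
#' @param n Number of records (>= 1).
#' @param seed Integer seed.
#' @param geom A [flag_geometry()].
#' @return A `data.frame` with columns `x`, `y`, `g` and attributes
#'   `generator`, `n`, `seed`.
#' @export
sample_flag <- function(n, seed, geom = flag_geometry()) {
  stopifnot(n >= 1)
  pts <- with_local_seed(seed, matrix(stats::runif(2 * n), ncol = 2))
  d <- data.frame(x = pts[, 1], y = pts[, 2])
  d$g <- disk_label(d$x, d$y, geom)
  attr(d, "generator") <- "japan"
  attr(d, "n") <- as.integer(n)
  attr(d, "seed") <- as.integer(seed)
  d
}

#' Boundary polynomials of the horned region
#'
#' The region of the unit square that the optimised three-oscillator network
#' classifies as "sun" is, in the rotated coordinates `p = x - y`,
#' `s = x + y`, bounded by two even polynomials of degree 14. These
#' functions return their printed coefficients for powers 0, 2, ..., 14.
#'
#' @return Numeric vector of 8 coefficients.
#' @export
horned_upper_coef <- function() {
  c(1.49928, 5.56776, -81.5484, 503.745, -2275.64, 7512.65, -14690.6,
    11764.8)
}

#' @rdname horned_upper_coef
#' @export
horned_lower_coef <- function() {
  c(0.432601, 1.65454, -2.0677, -107.24, 1120.59, -3887.3, 5377.69,
    -2552.69)
}

#' Evaluate an even boundary polynomial
#'
#' Horner evaluation of `sum_k coef[k] * p^(2*(k-1))` for `p` in [-1, 1].
#' Vectorised over `p`.
#'
#' @param coef Coefficients for powers 0, 2, ..., of `p`.
#' @param p Rotated abscissa `x - y`, in [-1, 1].
#' @return Value(s) of the polynomial (the rotated ordinate `s = x + y`).
#' @export
eval_boundary <- function(coef, p) {
  stopifnot(all(p >= -1 & p <= 1))
  p2 <- p * p
  out <- rep(coef[length(coef)], length(p))
  for (k in rev(seq_len(length(coef) - 1L))) {
    out <- out * p2 + coef[k]
  }
  out
}

#' Horned-region label of a point
#'
#' `g = 1` iff `F_D(x - y) <= x + y <= F_U(x - y)` with boundaries counted
#' inside. Vectorised.
#'
#' @param x,y Coordinates in the unit square.
#' @param upper,lower Coefficient vectors of the upper and lower boundary
#'   polynomials.
#' @return Integer label(s) in {0, 1}.
#' @export
horned_label <- function(x, y, upper = horned_upper_coef(),
                         lower = horned_lower_coef()) {
  stopifnot(all(x >= 0 & x <= 1), all(y >= 0 & y <= 1))
  p <- x - y
  s <- x + y
  as.integer(s >= eval_boundary(lower, p) & s <= eval_boundary(upper, p))
}

#' Sample a labeled horned-region dataset
#'
#' @inheritParams sample_flag
#' @param upper,lower Boundary polynomial coefficients.
#' @return A `data.frame` with columns `x`, `y`, `g`.
#' @export
sample_horned <- function(n, seed, upper = horned_upper_coef(),
                          lower = horned_lower_coef()) {
  stopifnot(n >= 1)
  pts <- with_local_seed(seed, matrix(stats::runif(2 * n), ncol = 2))
  d <- data.frame(x = pts[, 1], y = pts[, 2])
  d$g <- horned_label(d$x, d$y, upper, lower)
  attr(d, "generator") <- "horned"
  attr(d, "n") <- as.integer(n)
  attr(d, "seed") <- as.integer(seed)
  d
}

#' French-flag stripe label
#'
#' Three vertical stripes of the unit square: blue for `x < 1/3`, white for
#' `1/3 <= x < 2/3`, red for `x >= 2/3` (half-open stripes, right edge
#' closed). Vectorised.
#'
#' @param x Coordinate in [0, 1].
#' @return Factor with levels `blue`, `white`, `red`.
#' @export
french_flag_label <- function(x) {
  stopifnot(all(x >= 0 & x <= 1))
  cls <- ifelse(x < 1 / 3, "blue", ifelse(x < 2 / 3, "white", "red"))
  factor(cls, levels = c("blue", "white", "red"))
}

#' Sample a French-flag dataset
#'
#' @inheritParams sample_flag
#' @return A `data.frame` with columns `x`, `class`.
#' @export
sample_french_flag <- function(n, seed) {
  stopifnot(n >= 1)
  x <- with_local_seed(seed, stats::runif(n))
  d <- data.frame(x = x, class = french_flag_label(x))
  attr(d, "generator") <- "france"
  attr(d, "n") <- as.integer(n)
  attr(d, "seed") <- as.integer(seed)
  d
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
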