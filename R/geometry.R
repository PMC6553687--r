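#' Wrap angles onto the circle
#'
#' `wrap_angle()` maps angles in degrees onto `[0, 360)`;
#' `wrap_signed()` maps onto the signed convention `(-180, 180]` used for
#' divergence angles, so that an angular step of exactly half a turn is
#' reported as `+180`, never `-180`.
#'
#' @param theta numeric vector of angles in degrees.
#' @return numeric vector of wrapped angles in degrees.
#' @export
#' @examples
#' wrap_angle(-90)    # 270
#' wrap_signed(270)   # -90
#' wrap_signed(180)   # 180 (not -180)
wrap_angle <- function(theta) theta %% 360

#' @rdname wrap_angle
#' @export
wrap_signed <- function(theta) {
  w <- theta %% 360
  w[w > 180] <- w[w > 180] - 360
  w
}

#' Apex geometry of the shoot apical meristem
#'
#' The apex is described by the radius `R0` of the circle on which new
#' primordia appear, the flatness `N = sin(psi/2)` of the conical surface
#' (`N = 1` is a flat disc), and the initial radial velocity `V0` of a
#' primordium. Lengths are measured in units of `R0` and times are
#' standardized by `V0/R0`, so the defaults `R0 = 1`, `V0 = 1` lose no
#' generality: all model behaviour is governed by the dimensionless
#' parameters of the inhibition models.
#'
#' @param R0 radius of the primordium-formation circle (default 1).
#' @param N flatness in `(0, 1]`; `N = 1` means a planar apex.
#' @param V0 initial radial velocity (default 1).
#' @return an object of class `apex_model`.
#' @export
apex_model <- function(R0 = 1, N = 1, V0 = 1) {
  stopifnot(is.numeric(R0), length(R0) == 1L, R0 > 0,
            is.numeric(N), length(N) == 1L, N > 0, N <= 1,
            is.numeric(V0), length(V0) == 1L, V0 > 0)
  structure(list(R0 = R0, N = N, V0 = V0), class = "apex_model")
}

#' @export
print.apex_model <- function(x, ...) {
  cat(sprintf("<apex_model> R0 = %g, N = %g (psi = %.1f deg), V0 = %g\n",
              x$R0, x$N, 2 * asin(x$N) * 180 / pi, x$V0))
  invisible(x)
}

#' Radial distance of a primordium from the apex centre
#'
#' Primordia drift away from the centre with a radial velocity proportional
#' to their radial distance (exponential growth of the apex), so a
#' primordium born at standardized time `birth_time` sits at
#' `R0 * exp(now - birth_time)` at time `now`.
#'
#' @param birth_time standardized birth time(s).
#' @param now current standardized time.
#' @param apex an [apex_model()].
#' @return radial distance(s), same length as `birth_time`.
#' @export
radial_distance <- function(birth_time, now, apex = apex_model()) {
  age <- now - birth_time
  if (any(age < -1e-12)) {
    stop("negative primordium age: 'now' precedes a birth time (sequencing bug)")
  }
  apex$R0 * exp(pmax(age, 0))
}

#' Planar chord distance between two points on the apex
#'
#' Law-of-cosines Euclidean distance in the plane of a flat apex, used by
#' the discrete (one-per-plastochron) models.
#'
#' @param r1,r2 radial distances (>= 0).
#' @param theta1,theta2 azimuths in degrees.
#' @return distance(s); vectorized over all arguments.
#' @export
planar_distance <- function(r1, theta1, r2, theta2) {
  stopifnot(all(r1 >= 0), all(r2 >= 0))
  dtheta <- (theta1 - theta2) * pi / 180
  d2 <- r1^2 + r2^2 - 2 * r1 * r2 * cos(dtheta)
  sqrt(pmax(d2, 0))
}

#' Conical distance between two points on the apex
#'
#' Separation of two points `(r, theta)` on the conical apex surface of
#' flatness `N = sin(psi/2)`, used by the continuous-time models. Several
#' readings of the distance are supported through `radial_term`, all of the
#' form `d^2 = RF * (r1 - r2)^2 + AF * r1 r2 * (1 - cos(theta1 - theta2))`:
#'
#' * `"euclid"` (default): `RF = 1`, `AF = 2 N^2` — the true Euclidean
#'   chord between the two points of the cone in 3-D. This is the reading
#'   that reproduces the published pattern maps (at `N = 1` it is the
#'   planar chord, and on the formation circle `r1 = r2 = R0` it gives
#'   `2 N R0 sin(dtheta/2)`, the chord of the cone's cross-section).
#' * `"times_n"`: `RF = N`, `AF = 2 N` — `sqrt(N)` times the planar chord,
#'   one literal reading of the published formula (note it makes `N`
#'   redundant: it only rescales the inhibition range).
#' * `"over_n"`: `RF = 1/N`, `AF = 2 N` — the other literal reading.
#' * `"plain"`: `RF = 1`, `AF = 2 N` — radial term unweighted.
#'
#' @inheritParams planar_distance
#' @param N flatness in `(0, 1]`.
#' @param radial_term one of `"euclid"`, `"times_n"`, `"over_n"`, `"plain"`.
#' @return distance(s); vectorized.
#' @export
conical_distance <- function(r1, theta1, r2, theta2, N = 1,
                             radial_term = c("euclid", "times_n", "over_n",
                                             "plain")) {
  stopifnot(all(r1 >= 0), all(r2 >= 0), N > 0, N <= 1)
  radial_term <- match.arg(radial_term)
  dtheta <- (theta1 - theta2) * pi / 180
  rf <- switch(radial_term, euclid = 1, times_n = N, over_n = 1 / N, plain = 1)
  af <- switch(radial_term, euclid = 2 * N^2, 2 * N)
  sqrt(pmax(rf * (r1 - r2)^2 + af * r1 * r2 * (1 - cos(dtheta)), 0))
}
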