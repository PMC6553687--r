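#' Logistic age factors of the expanded models
#'
#' In the expanded models the inhibitory power of a primordium is not
#' constant but follows a logistic curve of its age:
#' `F(age) = 1 / (1 + exp(-rate * (age - timing)))`. The power increases
#' with age when `rate > 0`, decreases when `rate < 0`, and is constant at
#' `0.5` when `rate = 0`. `age_factor_edc1()` takes the age in plastochron
#' units (discrete model); `age_factor_edc2()` takes standardized time
#' (continuous model). Both are the same function with different unit
#' conventions.
#'
#' @param age primordium age (plastochron units or standardized time).
#' @param a,A rate of the age-dependent change.
#' @param b,B timing (midpoint) of the change, same units as `age`.
#' @return value(s) in `(0, 1)`.
#' @export
age_factor_edc1 <- function(age, a, b) {
  1 / (1 + exp(-a * (age - b)))
}

#' @rdname age_factor_edc1
#' @export
age_factor_edc2 <- function(age, A, B) {
  1 / (1 + exp(-A * (age - B)))
}

#' Distance-decay kernels of the inhibitory effect
#'
#' `decay_dc1()` is the power-law kernel `k * d^(-eta)` of the discrete
#' models. `decay_dc2()` is the threshold kernel of the continuous models,
#' a monotonically decreasing, downward-convex function of the dimensionless
#' distance `x = d / d0` that equals the threshold `Es` exactly at `x = 1`:
#' `E(x) = Es * (coth(alpha x) - 1) / (coth(alpha) - 1)`.
#' It is evaluated in the numerically stable form
#' `Es * expm1(2 alpha) / expm1(2 alpha x)`, which avoids the underflow of
#' `1/tanh` at large `alpha * x` (where `E -> 0`) and overflows gracefully
#' to `0` rather than `NaN`.
#'
#' @param d distance (> 0).
#' @param eta positive decay exponent.
#' @param k proportionality coefficient.
#' @param x dimensionless distance `d / d0` (> 0).
#' @param alpha steepness parameter.
#' @param Es threshold (default 1).
#' @return inhibition strength(s).
#' @export
decay_dc1 <- function(d, eta, k = 1) {
  if (any(d <= 0)) stop("decay_dc1: distance must be positive (coincident points?)")
  k * d^(-eta)
}

#' @rdname decay_dc1
#' @export
decay_dc2 <- function(x, alpha, Es = 1) {
  if (any(x <= 0)) stop("decay_dc2: dimensionless distance must be positive")
  Es * expm1(2 * alpha) / expm1(2 * alpha * x)
}

#' Inhibitory field of the discrete (planar) models
#'
#' Sums, over all preceding primordia, the power-law inhibition each exerts
#' on a point of the primordium-formation circle, optionally weighted by the
#' logistic age factor of the expanded model. Primordium `m` of age
#' `age[m]` plastochrons sits at radius `exp(G * age[m])` (in units of
#' `R0`), so the field at azimuth `theta` is
#' `I(theta) = k * sum_m F(age_m) (1 + e^(2 G age_m) - 2 e^(G age_m)
#' cos(theta - theta_m))^(-eta/2)`.
#'
#' @param theta_deg azimuths (degrees) at which to evaluate the field.
#' @param prim_theta azimuths (degrees) of the preceding primordia.
#' @param prim_age ages of the preceding primordia in plastochron units.
#' @param params a [dc1_params()] or [edc1_params()] record; the age factor
#'   is identically 1 for the plain model.
#' @return numeric vector of field strengths, one per `theta_deg`.
#' @export
field_dc1 <- function(theta_deg, prim_theta, prim_age, params) {
  if (length(prim_theta) == 0L) stop("field_dc1: no preceding primordia")
  stopifnot(length(prim_theta) == length(prim_age))
  rho <- exp(params$G * prim_age)
  w <- if (inherits(params, "edc1_params")) {
    age_factor_edc1(prim_age, params$a, params$b)
  } else {
    rep(1, length(prim_age))
  }
  dth <- outer(prim_theta, theta_deg, function(pm, th) (th - pm) * pi / 180)
  d2 <- 1 + rho^2 - 2 * rho * cos(dth)  # rows: primordia, cols: grid
  params$k * colSums(w * d2^(-params$eta / 2))
}

#' Inhibitory field of the continuous-time (conical) models
#'
#' Sums the threshold-kernel inhibition of all existing primordia at points
#' of the primordium-formation circle (radius `R0 = 1`), using the modified
#' conical distance, optionally weighted by the logistic age factor of the
#' expanded model. A primordium of age zero at the query angle contributes
#' divergent (infinite) inhibition there: the kernel has a pole at zero
#' distance, which is what excludes immediate re-initiation at an occupied
#' angle. No distance cutoff is applied: contributions beyond the nominal
#' range `d0` are small but retained, as truncating them would change
#' multi-primordium landscapes.
#'
#' @param theta_deg azimuths (degrees) at which to evaluate the field.
#' @param prim_theta azimuths (degrees) of existing primordia.
#' @param prim_birth standardized birth times of existing primordia.
#' @param now current standardized time (>= all birth times).
#' @param params a [dc2_params()] or [edc2_params()] record.
#' @param radial_term reading of the radial term of the conical distance,
#'   see [conical_distance()]; defaults to the one recorded in `params`.
#' @return numeric vector of field strengths, one per `theta_deg`;
#'   `Inf` where a zero-age primordium coincides with the query angle.
#' @export
field_dc2 <- function(theta_deg, prim_theta, prim_birth, now, params,
                      radial_term = params$radial_term) {
  stopifnot(length(prim_theta) == length(prim_birth))
  if (any(prim_birth > now + 1e-12)) stop("field_dc2: primordium born after 'now'")
  gamma_now <- if (!is.null(params$ramp)) {
    r <- params$ramp
    (r$Gamma_i + r$Gamma_f) / 2 -
      (r$Gamma_i - r$Gamma_f) / 2 * tanh((now - r$t_i) / r$tau)
  } else {
    params$Gamma
  }
  d0 <- gamma_now * params$N
  r_m <- exp(pmax(now - prim_birth, 0))
  w <- if (inherits(params, "edc2_params")) {
    age_factor_edc2(now - prim_birth, params$A, params$B)
  } else {
    rep(1, length(prim_birth))
  }
  acc <- numeric(length(theta_deg))
  for (m in seq_along(prim_theta)) {
    d <- conical_distance(1, theta_deg, r_m[m], prim_theta[m], params$N,
                          radial_term = radial_term)
    e <- ifelse(d == 0, Inf,
                params$Es * expm1(2 * params$alpha) /
                  expm1(2 * params$alpha * d / d0))
    acc <- acc + w[m] * e
  }
  acc
}
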