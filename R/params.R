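#' Parameter records for the four inhibition models
#'
#' Constructors for the parameter sets of the two classical inhibitory-field
#' models and their age-dependent expansions:
#'
#' * `dc1_params()` — discrete model on a planar apex: one primordium per
#'   plastochron, inhibition decaying as a power `eta` of distance, growth
#'   per plastochron `G = V0 T / R0` (the log of Richards' plastochron
#'   ratio), proportionality coefficient `k`.
#' * `edc1_params()` — the same geometry with a logistic age factor
#'   `F(age) = 1 / (1 + exp(-a (age - b)))` multiplying each primordium's
#'   inhibitory power; `a` is the rate and `b` the timing (in plastochron
#'   units) of the age-dependent change. `eta` defaults to 2 for this model.
#' * `dc2_params()` — continuous-time threshold model on a conical apex:
#'   steepness `alpha` of the decline of the inhibitory effect near the
#'   threshold, inhibition range `Gamma = d0 / (R0 N)` relative to apex
#'   size, flatness `N`, and threshold `Es` (fixed at 1 throughout).
#' * `edc2_params()` — adds the logistic age factor with rate `A` and
#'   timing `B` in standardized-time units, and optionally a [gamma_ramp()]
#'   making the inhibition range depend on elapsed simulation time.
#'
#' @param eta positive distance-decay exponent.
#' @param G positive growth per plastochron.
#' @param k positive proportionality coefficient.
#' @param a,b rate and timing (plastochron units) of the age factor.
#' @param alpha positive steepness of the threshold decline.
#' @param Gamma positive inhibition range over apex size.
#' @param N flatness in `(0, 1]`.
#' @param Es inhibition threshold (default 1).
#' @param A,B rate and timing (standardized time) of the age factor.
#' @param ramp optional [gamma_ramp()] schedule for `Gamma`.
#' @param radial_term reading of the conical distance, see
#'   [conical_distance()]; the default Euclidean chord (`"euclid"`)
#'   reproduces the published pattern maps.
#' @return a parameter record of class `dc1_params`, `edc1_params`,
#'   `dc2_params` or `edc2_params` (the expanded classes inherit from the
#'   plain ones).
#' @export
dc1_params <- function(eta, G, k = 1) {
  stopifnot(is.numeric(eta), eta > 0, is.numeric(G), G > 0,
            is.numeric(k), k > 0)
  structure(list(eta = eta, G = G, k = k),
            class = c("dc1_params", "phyllo_params"))
}

#' @rdname dc1_params
#' @export
edc1_params <- function(G, a, b, eta = 2, k = 1) {
  p <- dc1_params(eta = eta, G = G, k = k)
  p$a <- a
  p$b <- b
  class(p) <- c("edc1_params", class(p))
  p
}

#' @rdname dc1_params
#' @export
dc2_params <- function(alpha, Gamma, N, Es = 1, ramp = NULL,
                       radial_term = c("euclid", "over_n", "times_n", "plain")) {
  stopifnot(is.numeric(alpha), alpha > 0, is.numeric(Gamma), Gamma > 0,
            is.numeric(N), N > 0, N <= 1, is.numeric(Es), Es > 0)
  radial_term <- match.arg(radial_term)
  if (!is.null(ramp)) stopifnot(inherits(ramp, "gamma_ramp"))
  structure(list(alpha = alpha, Gamma = Gamma, N = N, Es = Es,
                 d0 = Gamma * N, ramp = ramp, radial_term = radial_term),
            class = c("dc2_params", "phyllo_params"))
}

#' @rdname dc1_params
#' @export
edc2_params <- function(alpha, Gamma, N, A, B, Es = 1, ramp = NULL,
                        radial_term = c("euclid", "over_n", "times_n", "plain")) {
  p <- dc2_params(alpha = alpha, Gamma = Gamma, N = N, Es = Es, ramp = ramp,
                  radial_term = radial_term)
  stopifnot(is.numeric(A), is.numeric(B))
  p$A <- A
  p$B <- B
  class(p) <- c("edc2_params", class(p))
  p
}

#' Time-dependent inhibition-range schedule
#'
#' A smooth ramp of the inhibition range `Gamma` with elapsed simulation
#' time, `Gamma(t) = (Gi + Gf)/2 - (Gi - Gf)/2 * tanh((t - ti)/tau)`,
#' used to ease the continuous-time system into a stable pattern from a
#' strongly inhibited start.
#'
#' @param Gamma_i,Gamma_f initial and final range values (positive).
#' @param t_i centre of the ramp (standardized simulation time).
#' @param tau positive time constant of the ramp.
#' @return an object of class `gamma_ramp`.
#' @export
gamma_ramp <- function(Gamma_i = 50, Gamma_f = 2.8, t_i = 0.2, tau = 0.3) {
  stopifnot(Gamma_i > 0, Gamma_f > 0, tau > 0)
  structure(list(Gamma_i = Gamma_i, Gamma_f = Gamma_f, t_i = t_i, tau = tau),
            class = "gamma_ramp")
}

#' @export
print.phyllo_params <- function(x, ...) {
  cat(sprintf("<%s>\n", class(x)[1]))
  flat <- x[!vapply(x, is.list, logical(1))]
  cat(paste0("  ", names(flat), " = ",
             vapply(flat, function(v) format(v, digits = 6), character(1)),
             collapse = "\n"), "\n")
  if (!is.null(x$ramp)) {
    r <- x$ramp
    cat(sprintf("  Gamma ramp: %g -> %g around t = %g (tau = %g)\n",
                r$Gamma_i, r$Gamma_f, r$t_i, r$tau))
  }
  invisible(x)
}

model_tag <- function(params) {
  if (inherits(params, "edc1_params")) "EDC1"
  else if (inherits(params, "dc1_params")) "DC1"
  else if (inherits(params, "edc2_params")) "EDC2"
  else if (inherits(params, "dc2_params")) "DC2"
  else stop("not a phyllofield parameter record")
}
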