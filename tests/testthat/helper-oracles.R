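# Independent brute-force field evaluations, composed point by point from
# the geometric primitives rather than the vectorized/compiled field code.

brute_field_dc1 <- function(theta_deg, prim_theta, prim_age, params) {
  w <- if (inherits(params, "edc1_params")) {
    age_factor_edc1(prim_age, params$a, params$b)
  } else rep(1, length(prim_age))
  r <- exp(params$G * prim_age)
  acc <- numeric(length(theta_deg))
  for (m in seq_along(prim_theta)) {
    d <- planar_distance(1, theta_deg, r[m], prim_theta[m])
    acc <- acc + w[m] * decay_dc1(d, params$eta, params$k)
  }
  acc
}

brute_field_dc2 <- function(theta_deg, prim_theta, prim_birth, now, params) {
  w <- if (inherits(params, "edc2_params")) {
    age_factor_edc2(now - prim_birth, params$A, params$B)
  } else rep(1, length(prim_birth))
  r <- exp(now - prim_birth)
  acc <- numeric(length(theta_deg))
  for (m in seq_along(prim_theta)) {
    d <- conical_distance(1, theta_deg, r[m], prim_theta[m], params$N,
                          radial_term = params$radial_term)
    e <- numeric(length(d))
    e[d == 0] <- Inf
    e[d > 0] <- decay_dc2(d[d > 0] / params$d0, params$alpha, params$Es)
    acc <- acc + w[m] * e
  }
  acc
}

# synthetic trace from a divergence-angle motif (tiled until n primordia)
make_cycle_trace <- function(motif, n = 40, plastochron = 0.2,
                             theta0 = 0, model = "dc2") {
  ang <- rep_len(motif, n - 1)
  pls <- rep_len(plastochron, n - 1)
  params <- if (model == "dc2") dc2_params(alpha = 1, Gamma = 2, N = 1) else
    dc1_params(eta = 2, G = pls[1])
  phyllofield:::new_trace(theta = cumsum(c(theta0, ang)),
                          birth_time = cumsum(c(0, pls)),
                          min_field = rep(NA_real_, n),
                          params = params, settings = sim_settings())
}

round_to <- function(x, unit) unit * round(x / unit)

# 100-primordium runs reused across acceptance checks (computed once)
acc_cache <- new.env(parent = emptyenv())
acc_run <- function(key, fun) {
  if (is.null(acc_cache[[key]])) acc_cache[[key]] <- fun()
  acc_cache[[key]]
}
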