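#' Artificial normal-orixate primordium arrangements
#'
#' Builds the idealized primordium arrangement of normal orixate
#' phyllotaxis: divergence angles cycling through exactly
#' `180, 90, -180, -90` degrees, so all primordia lie on two orthogonal
#' axes and every fourth primordium is collinear with the incipient one,
#' which sits at 0 degrees. The incipient primordium is *not* part of the
#' arrangement; its (prospective) initiation time is `t = 0` and birth
#' times of the preceding primordia are negative.
#'
#' Two geometrical situations are distinguished by the divergence angle
#' between the incipient primordium and the last existing one:
#' `situation_1` has it at +/-90 degrees, `situation_2` at 180 degrees.
#'
#' For the continuous-time models the standardized plastochron oscillates
#' between a short value for opposite pairs (divergence 180) and a long
#' value for adjacent pairs (divergence +/-90), `plastochrons = c(0.1,
#' 0.325)` by default. For the discrete models set
#' `unit_plastochron = TRUE`: ages are then whole plastochron units
#' (1, 2, 3, ...), the discrete model's constant-interval assumption.
#'
#' @param n number of preceding primordia (>= 5 advised; the field
#'   contributions decay geometrically with age).
#' @param plastochrons length-2 numeric, `c(short, long)`: standardized
#'   plastochron of the opposite (180) and adjacent (90) pairs.
#' @param situation `"situation_1"` or `"situation_2"`.
#' @param unit_plastochron if `TRUE`, use constant unit plastochrons
#'   (discrete-model convention) instead of `plastochrons`.
#' @return an object of class `phyllo_arrangement`: list with `theta`,
#'   `birth_time` (both oldest first), `situation`, `incipient_theta = 0`.
#' @export
make_normal_orixate <- function(n, plastochrons = c(0.1, 0.325),
                                situation = c("situation_1", "situation_2"),
                                unit_plastochron = FALSE) {
  situation <- match.arg(situation)
  stopifnot(n >= 5, length(plastochrons) == 2, all(plastochrons > 0))
  short <- plastochrons[1]; long <- plastochrons[2]
  # walking backwards from the incipient primordium at 0 degrees:
  # angles and pair plastochrons repeat with period 4
  if (situation == "situation_1") {
    theta_back <- c(90, 270, 180, 0)     # divergence to incipient: -90
    step_back <- c(long, short, long, short)
  } else {
    theta_back <- c(180, 270, 90, 0)     # divergence to incipient: 180
    step_back <- c(short, long, short, long)
  }
  j <- seq_len(n)
  theta <- theta_back[((j - 1) %% 4) + 1]
  ages <- if (unit_plastochron) j else cumsum(step_back[((j - 1) %% 4) + 1])
  structure(list(theta = rev(theta), birth_time = rev(-ages),
                 situation = situation, incipient_theta = 0,
                 unit_plastochron = unit_plastochron),
            class = "phyllo_arrangement")
}

#' @export
print.phyllo_arrangement <- function(x, ...) {
  cat(sprintf("<phyllo_arrangement> normal orixate, %d primordia, %s\n",
              length(x$theta), x$situation))
  cat("  last angles (deg):",
      paste(utils::tail(x$theta, 5), collapse = ", "),
      "| incipient at", x$incipient_theta, "\n")
  invisible(x)
}

#' Inhibition landscape of a fixed arrangement
#'
#' Evaluates the inhibitory field of an artificial arrangement on the
#' primordium-formation circle at time `now` (default 0, the prospective
#' initiation time of the incipient primordium), and locates all local
#' minima and maxima of the circular profile.
#'
#' @param arr a [make_normal_orixate()] arrangement (or any list with
#'   `theta` and `birth_time`).
#' @param params any of the four parameter records; discrete-model records
#'   interpret ages in plastochron units.
#' @param now evaluation time.
#' @param angle_resolution grid spacing in degrees.
#' @return list with `theta`, `field`, and data.frames `minima` and
#'   `maxima` (`theta`, `value`).
#' @export
inhibition_landscape <- function(arr, params, now = 0,
                                 angle_resolution = 0.1) {
  n_grid <- round(360 / angle_resolution)
  grid <- (seq_len(n_grid) - 1) * angle_resolution
  I <- if (inherits(params, "dc1_params")) {
    field_dc1(grid, arr$theta, now - arr$birth_time, params)
  } else {
    field_dc2(grid, arr$theta, arr$birth_time, now, params)
  }
  nxt <- c(I[-1], I[1]); prv <- c(I[n_grid], I[-n_grid])
  is_min <- I < prv & I <= nxt
  is_max <- I > prv & I >= nxt
  list(theta = grid, field = I,
       minima = data.frame(theta = grid[is_min], value = I[is_min]),
       maxima = data.frame(theta = grid[is_max], value = I[is_max]))
}

# unit-plastochron ages on the +90 / -90 axes for each situation
orixate_axis_ages <- function(situation, n_prev) {
  j <- seq_len(n_prev)
  if (situation == "situation_1") {
    list(at90 = j[(j - 1) %% 4 == 0], at270 = j[(j - 1) %% 4 == 1])
  } else {
    list(at90 = j[(j - 1) %% 4 == 2], at270 = j[(j - 1) %% 4 == 1])
  }
}

# analytic d I / d theta at theta = 0 for the discrete-model field of a
# normal orixate arrangement with unit plastochrons; only primordia on the
# +/-90 axes contribute (the 0/180 axis terms are even in theta)
edc1_stationarity <- function(a, b, G, eta = 2, k = 1,
                              situation = "situation_1", n_prev = 100,
                              age_factor = TRUE) {
  ax <- orixate_axis_ages(situation, n_prev)
  w_of <- function(j) {
    rho <- exp(G * j)
    f <- if (age_factor) age_factor_edc1(j, a, b) else 1
    f * rho * (1 + rho^2)^(-(eta + 2) / 2)
  }
  k * eta * (sum(w_of(ax$at90)) - sum(w_of(ax$at270)))
}

# vectorized stationarity residual on an (a, b) raster
edc1_stationarity_grid <- function(a_vec, b_vec, G, eta = 2,
                                   situation = "situation_1", n_prev = 100) {
  ax <- orixate_axis_ages(situation, n_prev)
  R <- matrix(0, length(a_vec), length(b_vec))
  w_of <- function(j) {
    rho <- exp(G * j)
    rho * (1 + rho^2)^(-(eta + 2) / 2)
  }
  for (j in c(ax$at90, ax$at270)) {
    s <- if (j %in% ax$at90) 1 else -1
    Fj <- 1 / (1 + exp(outer(a_vec, b_vec - j)))
    R <- R + s * w_of(j) * Fj
  }
  eta * R
}

# analytic d2 I / d theta2 at theta = 0 for the same arrangement
edc1_curvature <- function(a, b, G, eta = 2, k = 1,
                           situation = "situation_1", n_prev = 100,
                           age_factor = TRUE) {
  j <- seq_len(n_prev)
  theta_back <- if (situation == "situation_1") c(90, 270, 180, 0) else
    c(180, 270, 90, 0)
  th <- theta_back[((j - 1) %% 4) + 1] * pi / 180
  rho <- exp(G * j)
  f <- if (age_factor) age_factor_edc1(j, a, b) else rep(1, n_prev)
  q <- 1 + rho^2 - 2 * rho * cos(th)
  k * sum(f * (-eta * rho * cos(th) * q^(-(eta + 2) / 2) +
               eta * (eta + 2) * rho^2 * sin(th)^2 * q^(-(eta + 4) / 2)))
}

#' Solve the stationarity condition of the expanded discrete model
#'
#' For normal orixate phyllotaxis to persist under the discrete
#' (one-per-plastochron) expanded model, the angular derivative of the
#' inhibitory field must vanish at the incipient position. With the
#' arrangement on orthogonal axes only the primordia at +/-90 degrees
#' contribute to the derivative, and the condition balances their
#' age-weighted contributions. For each rate `a` of the age factor this
#' root-solves for the timing `b`; points with no root in `b_range` are
#' omitted, so a curve need not span the whole `a` grid.
#'
#' @param G growth per plastochron.
#' @param situation `"situation_1"` or `"situation_2"`.
#' @param a_grid rates to scan.
#' @param b_range search interval for `b` (plastochron units).
#' @param eta decay exponent (2 for the expanded discrete model).
#' @param n_prev number of preceding primordia kept in the sum; the
#'   omitted tail contributes less than 1e-10 for the default.
#' @return a `condition_curve`: data.frame with columns `a`, `b`,
#'   `residual`, and attributes `G`, `situation`.
#' @export
solve_edc1_condition <- function(G, situation = c("situation_1", "situation_2"),
                                 a_grid = seq(-20, 20, by = 0.1),
                                 b_range = c(0, 20), eta = 2, n_prev = 100) {
  situation <- match.arg(situation)
  rows <- lapply(a_grid, function(a) {
    f <- function(b) edc1_stationarity(a, b, G, eta, situation = situation,
                                       n_prev = n_prev)
    bs <- seq(b_range[1], b_range[2], by = 0.05)
    vals <- vapply(bs, f, numeric(1))
    sc <- which(vals[-1] * vals[-length(vals)] < 0)
    if (length(sc) == 0) return(NULL)
    # all root branches; the residual oscillates in b with decaying amplitude
    roots <- vapply(sc, function(i)
      uniroot(f, c(bs[i], bs[i + 1]), tol = 1e-13)$root, numeric(1))
    data.frame(a = a, b = roots, residual = vapply(roots, f, numeric(1)))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(a = numeric(), b = numeric(),
                                      residual = numeric())
  structure(out, G = G, situation = situation, eta = eta, n_prev = n_prev,
            class = c("condition_curve", "data.frame"))
}

#' Intersect the condition curves of the two situations
#'
#' Normal orixate phyllotaxis requires the stationarity condition to hold
#' in both geometrical situations simultaneously; the parameter sets
#' achieving this are the crossings of the two condition curves. Crossings
#' of the piecewise-linear curves are refined by a two-variable Newton
#' solve on both situations' residuals.
#'
#' @param c1,c2 `condition_curve`s for the two situations at the same `G`.
#' @return data.frame with columns `a`, `b`, `residual_1`, `residual_2`,
#'   and a logical attribute `degenerate` set when the curves coincide
#'   everywhere.
#' @export
find_intersections <- function(c1, c2) {
  stopifnot(inherits(c1, "condition_curve"), inherits(c2, "condition_curve"),
            isTRUE(all.equal(attr(c1, "G"), attr(c2, "G"))))
  G <- attr(c1, "G"); eta <- attr(c1, "eta"); n_prev <- attr(c1, "n_prev")
  s1 <- attr(c1, "situation"); s2 <- attr(c2, "situation")
  empty <- data.frame(a = numeric(), b = numeric(),
                      residual_1 = numeric(), residual_2 = numeric())
  if (nrow(c1) == 0 || nrow(c2) == 0) return(structure(empty, degenerate = FALSE))
  same <- nrow(c1) == nrow(c2) && all(c1$a == c2$a) &&
    all(abs(c1$b - c2$b) < 1e-10)
  if (same) {
    out <- data.frame(a = c1$a, b = c1$b,
                      residual_1 = c1$residual, residual_2 = c2$residual)
    return(structure(out, degenerate = TRUE))
  }
  # both zero curves on a common (a, b) raster; a crossing lives in any cell
  # where both residual surfaces change sign, then Newton-refined
  a_vec <- sort(unique(c(c1$a, c2$a)))
  b_vec <- seq(max(0.01, min(c(c1$b, c2$b)) - 1), max(c(c1$b, c2$b)) + 1,
               by = 0.05)
  R1 <- edc1_stationarity_grid(a_vec, b_vec, G, eta, s1, n_prev)
  R2 <- edc1_stationarity_grid(a_vec, b_vec, G, eta, s2, n_prev)
  na <- length(a_vec); nb <- length(b_vec)
  sgn_change <- function(R) {
    s <- sign(R)
    (s[-na, -nb] * s[-1, -nb] <= 0) | (s[-na, -nb] * s[-na, -1] <= 0) |
      (s[-na, -nb] * s[-1, -1] <= 0)
  }
  amp <- function(R) pmax(abs(R[-na, -nb]), abs(R[-1, -nb]),
                          abs(R[-na, -1]), abs(R[-1, -1]))
  cells <- which(sgn_change(R1) & sgn_change(R2) &
                 amp(R1) > 1e-12 & amp(R2) > 1e-12, arr.ind = TRUE)
  res2d <- function(x) c(
    edc1_stationarity(x[1], x[2], G, eta, situation = s1, n_prev = n_prev),
    edc1_stationarity(x[1], x[2], G, eta, situation = s2, n_prev = n_prev))
  rows <- apply(cells, 1, function(ij) {
    x <- c(mean(a_vec[ij[1] + 0:1]), mean(b_vec[ij[2] + 0:1]))
    for (it in 1:60) {
      r <- res2d(x)
      if (max(abs(r)) < 1e-13) break
      h <- 1e-6
      J <- cbind((res2d(x + c(h, 0)) - res2d(x - c(h, 0))) / (2 * h),
                 (res2d(x + c(0, h)) - res2d(x - c(0, h))) / (2 * h))
      step <- tryCatch(solve(J, r), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) return(NULL)
      step <- pmin(pmax(step, -1), 1)  # damp: surfaces are steep in places
      x <- x - step
    }
    r <- res2d(x)
    if (max(abs(r)) > 1e-8) return(NULL)
    data.frame(a = x[1], b = x[2], residual_1 = r[1], residual_2 = r[2])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else empty
  if (nrow(out)) {
    key <- paste(round(out$a, 3), round(out$b, 3))
    out <- out[!duplicated(key), , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, degenerate = FALSE)
}

#' Stationarity scan of the plain discrete model
#'
#' Normal orixate phyllotaxis cannot persist under the plain discrete
#' model: with a constant inhibitory power the age-weighted contributions
#' of the +/-90-degree primordia can never balance in both geometrical
#' situations with the field at a minimum. This scans a parameter grid and
#' reports, for each `(eta, G)`, the stationarity residuals of both
#' situations and the field curvatures at the incipient position, as a
#' numerical surrogate of the analytic impossibility argument: no grid
#' point should show both residuals near zero together with positive
#' curvature (a genuine minimum).
#'
#' @param eta_grid,G_grid parameter grids.
#' @param n_prev preceding primordia kept in the sums.
#' @return data.frame with columns `eta`, `G`, `residual_1`, `residual_2`,
#'   `curvature_1`, `curvature_2`.
#' @export
dc1_orixate_scan <- function(eta_grid, G_grid, n_prev = 100) {
  grid <- expand.grid(eta = eta_grid, G = G_grid, KEEP.OUT.ATTRS = FALSE)
  one <- function(eta, G) {
    c(residual_1 = edc1_stationarity(0, 0, G, eta, situation = "situation_1",
                                     n_prev = n_prev, age_factor = FALSE),
      residual_2 = edc1_stationarity(0, 0, G, eta, situation = "situation_2",
                                     n_prev = n_prev, age_factor = FALSE),
      curvature_1 = edc1_curvature(0, 0, G, eta, situation = "situation_1",
                                   n_prev = n_prev, age_factor = FALSE),
      curvature_2 = edc1_curvature(0, 0, G, eta, situation = "situation_2",
                                   n_prev = n_prev, age_factor = FALSE))
  }
  vals <- t(mapply(one, grid$eta, grid$G))
  cbind(grid, as.data.frame(vals))
}

#' Write condition curves and intersections to CSV
#'
#' @param curves list of `condition_curve`s.
#' @param path CSV path; rows carry `G`, `situation`, `a`, `b`, `residual`.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path) {
  rows <- lapply(curves, function(cc) {
    if (nrow(cc) == 0) return(NULL)
    data.frame(G = attr(cc, "G"), situation = attr(cc, "situation"),
               a = cc$a, b = cc$b, residual = cc$residual)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
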