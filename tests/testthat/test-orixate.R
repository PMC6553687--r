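test_that("normal orixate arrangements are built to specification", {
  arr <- make_normal_orixate(8, c(0.1, 0.325), "situation_1")
  # four orthogonal rays
  expect_setequal(unique(arr$theta), c(0, 90, 180, 270))
  # divergence angles read back as the (180, 90, -180, -90) cycle
  dv <- abs(wrap_signed(diff(c(arr$theta, 0))))
  expect_true(all(dv %in% c(90, 180)))
  expect_equal(sum(dv == 90), 4)
  # standardized plastochrons oscillate as prescribed:
  # short on opposite (180) pairs, long on adjacent (90) pairs
  pls <- diff(c(arr$birth_time, 0))
  expect_equal(sort(unique(round(pls, 10))), c(0.1, 0.325))
  expect_true(all(abs(pls[dv == 180] - 0.1) < 1e-9))
  expect_true(all(abs(pls[dv == 90] - 0.325) < 1e-9))
  # the two situations end on the prescribed divergence to the incipient
  expect_equal(abs(wrap_signed(0 - utils::tail(arr$theta, 1))), 90)
  arr2 <- make_normal_orixate(8, c(0.1, 0.325), "situation_2")
  expect_equal(abs(wrap_signed(0 - utils::tail(arr2$theta, 1))), 180)
  # discrete-model convention: whole-plastochron ages
  arrd <- make_normal_orixate(6, situation = "situation_1",
                              unit_plastochron = TRUE)
  expect_equal(arrd$birth_time, -(6:1))
})

test_that("landscapes: symmetry and extrema accounting", {
  # a mirror-symmetric arrangement gives a profile symmetric about its axis
  arr <- list(theta = c(90, 270, 180), birth_time = c(-1, -1, -2))
  ls <- inhibition_landscape(arr, dc2_params(alpha = 2, Gamma = 2, N = 1 / 3),
                             angle_resolution = 0.5)
  prof <- ls$field
  n <- length(prof)
  expect_equal(prof[2:n], rev(prof[2:n]), tolerance = 1e-12)
  # discrete-model landscape agrees with the direct field evaluation
  arrd <- make_normal_orixate(30, situation = "situation_1",
                              unit_plastochron = TRUE)
  p <- edc1_params(G = 0.5, a = 1.5, b = 4.5)
  lsd <- inhibition_landscape(arrd, p, angle_resolution = 1)
  expect_equal(lsd$field,
               brute_field_dc1(lsd$theta, arrd$theta, -arrd$birth_time, p),
               tolerance = 1e-9)
  # minima and maxima alternate on the circle
  expect_equal(nrow(lsd$minima), nrow(lsd$maxima))
})

test_that("stationarity residual matches a central difference of the field", {
  arr <- make_normal_orixate(100, situation = "situation_2",
                             unit_plastochron = TRUE)
  p <- edc1_params(G = 0.6, a = 1.2, b = 3.7)
  h <- 0.01
  num <- (brute_field_dc1(h, arr$theta, -arr$birth_time, p) -
          brute_field_dc1(-h, arr$theta, -arr$birth_time, p)) /
         (2 * h * pi / 180)
  ana <- phyllofield:::edc1_stationarity(1.2, 3.7, 0.6,
                                         situation = "situation_2")
  expect_equal(ana, num, tolerance = 1e-6)
  # curvature against a second difference
  num2 <- (brute_field_dc1(h, arr$theta, -arr$birth_time, p) -
           2 * brute_field_dc1(0, arr$theta, -arr$birth_time, p) +
           brute_field_dc1(-h, arr$theta, -arr$birth_time, p)) /
          (h * pi / 180)^2
  ana2 <- phyllofield:::edc1_curvature(1.2, 3.7, 0.6,
                                       situation = "situation_2")
  expect_equal(ana2, num2, tolerance = 1e-4)
})

test_that("condition curves: solver contract and tail truncation", {
  cc <- solve_edc1_condition(0.5, "situation_1", a_grid = seq(0.5, 3, 0.25))
  expect_gt(nrow(cc), 0)
  expect_true(all(abs(cc$residual) < 1e-8))
  # doubling the preceding-primordium count leaves the residuals unchanged
  # at the truncation tolerance
  for (i in sample(nrow(cc), 3)) {
    r200 <- phyllofield:::edc1_stationarity(cc$a[i], cc$b[i], 0.5,
                                            situation = "situation_1",
                                            n_prev = 200)
    expect_lt(abs(r200 - cc$residual[i]), 1e-9)
  }
  # refining the b search reproduces curve points
  cc2 <- solve_edc1_condition(0.5, "situation_1", a_grid = cc$a[1],
                              b_range = c(max(0, cc$b[1] - 1), cc$b[1] + 1))
  expect_lt(min(abs(cc2$b - cc$b[1])), 1e-4)
})

test_that("curve intersections: refinement and degenerate handling", {
  c1 <- solve_edc1_condition(0.5, "situation_1", a_grid = seq(1, 2, 0.1))
  c2 <- solve_edc1_condition(0.5, "situation_2", a_grid = seq(1, 2, 0.1))
  xs <- find_intersections(c1, c2)
  expect_gt(nrow(xs), 0)
  expect_true(all(abs(xs$residual_1) < 1e-8 & abs(xs$residual_2) < 1e-8))
  # identical curves flag as degenerate (every point is a crossing)
  self <- find_intersections(c1, c1)
  expect_true(attr(self, "degenerate"))
  expect_equal(nrow(self), nrow(c1))
})

test_that("plain-model scan: odd symmetry and half-scaling", {
  sc <- dc1_orixate_scan(c(1, 2, 4), c(0.1, 0.3, 0.6), n_prev = 80)
  expect_equal(nrow(sc), 9)
  # the expanded model at a = 0 halves the plain residual exactly
  r_half <- phyllofield:::edc1_stationarity(0, 0, 0.3, eta = 2,
                                            situation = "situation_1",
                                            n_prev = 80, age_factor = TRUE)
  r_plain <- sc$residual_1[sc$eta == 2 & sc$G == 0.3]
  expect_equal(r_half, 0.5 * r_plain, tolerance = 1e-12)
  # situation-1 residual has a fixed sign over the grid (the age-weighted
  # +/-90 contributions can never balance without an age factor)
  expect_true(all(sc$residual_1 > 0) || all(sc$residual_1 < 0))
})

test_that("landscape minima match simulator insertions", {
  p <- dc2_params(alpha = 4, Gamma = 2.4, N = 1 / 3)
  st <- sim_settings(angle_resolution = 0.5, dt = 0.002, max_primordia = 14,
                     prune = FALSE)
  tr <- run_dc2(p, st)
  pr <- tr$primordia
  j <- 12
  arr <- list(theta = pr$theta[1:(j - 1)], birth_time = pr$birth_time[1:(j - 1)])
  ls <- inhibition_landscape(arr, p, now = pr$birth_time[j],
                             angle_resolution = 0.5)
  gmin <- ls$minima$theta[which.min(ls$minima$value)]
  expect_lt(abs(wrap_signed(gmin - pr$theta[j])), 0.5 + 1e-9)
})

test_that("curve writer emits one row per solution point", {
  c1 <- solve_edc1_condition(0.5, "situation_1", a_grid = seq(1, 1.5, 0.25))
  path <- file.path(tempdir(), "curves.csv")
  write_curves(list(c1), path)
  out <- read.csv(path)
  expect_equal(nrow(out), nrow(c1))
  expect_equal(out$situation[1], "situation_1")
  unlink(path)
})
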