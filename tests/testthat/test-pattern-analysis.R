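test_that("divergence series extraction", {
  tr <- make_cycle_trace(180, n = 2)
  ds <- divergence_series(tr)
  expect_equal(ds$angle, 180)  # half-turn reports as +180, never -180
  tr2 <- make_cycle_trace(c(120, -30), n = 20, plastochron = c(0.1, 0.3))
  ds2 <- divergence_series(tr2)
  expect_equal(ds2$angle, rep_len(c(120, -30), 19))
  expect_equal(ds2$plastochron, rep_len(c(0.1, 0.3), 19))
  lone <- phyllofield:::new_trace(0, 0, NA_real_,
                                  dc2_params(alpha = 1, Gamma = 2, N = 1),
                                  sim_settings())
  expect_error(divergence_series(lone), "at least 2")
})

test_that("period detection classifies exact motif tilings", {
  cases <- list(
    list(motif = 137.5, category = "regular_alternate", cycle = 1),
    list(motif = c(170, 100), category = "two_cycle_alternate", cycle = 2),
    list(motif = c(165, -91, -165, 91), category = "four_cycle_alternate",
         cycle = 4),
    list(motif = c(180, 0, 0, 0, 0), category = "x_cycle_alternate", cycle = 5),
    list(motif = c(180, 0, 0, 0, 0, 0), category = "x_cycle_alternate",
         cycle = 6))
  for (cs in cases) {
    pc <- classify_pattern(make_cycle_trace(cs$motif, n = 50))
    expect_equal(pc$category, cs$category)
    expect_equal(pc$cycle_length, cs$cycle)
  }
  # a period-4 sequence without the (p, q, -p, -q) sign pattern is not a
  # tetrastichous four-cycle
  pc <- classify_pattern(make_cycle_trace(c(165, 91, 120, 80), n = 50))
  expect_equal(pc$category, "other")
  # distichous wobble across the +/-180 seam is a regular alternate pattern
  pc <- classify_pattern(make_cycle_trace(c(179.5, -179.8), n = 50))
  expect_equal(pc$category, "regular_alternate")
  expect_error(classify_pattern(make_cycle_trace(137.5, n = 5)), "window")
})

test_that("classification is invariant under rotation and mirroring", {
  motif <- c(165, -91, -165, 91)
  base <- classify_pattern(make_cycle_trace(motif, n = 50))
  rot <- classify_pattern(make_cycle_trace(motif, n = 50, theta0 = 77.7))
  mir <- classify_pattern(make_cycle_trace(-motif, n = 50))
  for (pc in list(rot, mir)) {
    expect_equal(pc$category, base$category)
    expect_equal(pc$mean_divergence, base$mean_divergence)
    expect_equal(pc$angle_ratio, base$angle_ratio)
  }
})

test_that("node grouping and whorled classification", {
  # discrete-engine traces have strictly increasing birth times
  tr <- make_cycle_trace(137.5, n = 20)
  expect_true(all(group_nodes(tr)$sizes == 1))
  # synthetic decussate: opposite pairs, successive pairs rotated 90 deg
  k <- 8
  theta <- as.vector(t(cbind(seq(0, by = 90, length.out = k),
                             seq(180, by = 90, length.out = k))))
  birth <- rep(seq(0, by = 0.5, length.out = k), each = 2)
  dec <- phyllofield:::new_trace(theta, birth, rep(NA_real_, 2 * k),
                                 dc2_params(alpha = 1, Gamma = 2, N = 1),
                                 sim_settings())
  nodes <- group_nodes(dec)
  expect_equal(nodes$sizes, rep(2L, k))
  pc <- classify_pattern(dec)
  expect_equal(pc$category, "decussate")
  expect_equal(pc$primordia_per_node, 2L)
  expect_equal(pc$node_rotation, 90)
  # synthetic tricussate: whorls of three rotated by 60 deg
  theta3 <- as.vector(t(outer(seq(0, by = 60, length.out = k),
                              c(0, 120, 240), "+")))
  birth3 <- rep(seq(0, by = 0.5, length.out = k), each = 3)
  tri <- phyllofield:::new_trace(theta3, birth3, rep(NA_real_, 3 * k),
                                 dc2_params(alpha = 1, Gamma = 2, N = 1),
                                 sim_settings())
  pc3 <- classify_pattern(tri)
  expect_equal(pc3$category, "tricussate")
  expect_equal(pc3$node_rotation, 60)
})

test_that("cycle ratios", {
  tr <- make_cycle_trace(c(180, 90, -180, -90), n = 41,
                         plastochron = c(0.1, 0.325, 0.1, 0.325))
  pc <- classify_pattern(tr)
  expect_equal(pc$category, "four_cycle_alternate")
  rs <- ratio_stats(pc)
  expect_equal(unname(rs["angle_ratio"]), 0.5)
  expect_equal(unname(rs["plastochron_ratio"]), 0.1 / 0.325, tolerance = 1e-9)
  # equal alternating angles give ratio 1
  pc2 <- classify_pattern(make_cycle_trace(c(150, -150), n = 30))
  expect_equal(pc2$angle_ratio, 1)
  expect_error(ratio_stats(classify_pattern(make_cycle_trace(137.5, n = 30))),
               "two-cycle")
})

test_that("colour legend encoding", {
  # 180-degree regular alternate with equal plastochrons: red, full
  # saturation, pure colour
  pc <- classify_pattern(make_cycle_trace(180, n = 30))
  col <- color_encode(pc)
  expect_equal(unname(col), c(0, 1, 0.5))
  # near-zero divergence maps to cyan
  pc0 <- classify_pattern(make_cycle_trace(0.5, n = 30))
  expect_equal(unname(color_encode(pc0)["hue"]), (180 - 0.5) / 360)
  # mid ratios map to mid saturation and mid-high lightness
  tr <- make_cycle_trace(c(160, 80, -160, -80), n = 41,
                         plastochron = c(0.1, 0.2, 0.1, 0.2))
  col4 <- color_encode(classify_pattern(tr))
  expect_equal(unname(col4["saturation"]), 0.5)
  expect_equal(unname(col4["lightness"]), 1 - 0.5 * 0.5)
  # every category has a colour, all components in range
  cats <- c("regular_alternate", "two_cycle_alternate", "four_cycle_alternate",
            "x_cycle_alternate", "decussate", "tricussate", "other_whorled",
            "other")
  for (cat in cats) {
    pc <- structure(list(category = cat, mean_divergence = 120,
                         angle_ratio = 0.7, plastochron_ratio = 0.4),
                    class = "pattern_class")
    col <- color_encode(pc)
    expect_true(all(col >= 0 & col <= 1), info = cat)
  }
  # HSL conversion endpoints
  expect_equal(hsl_to_rgb(0, 1, 0.5), c(1, 0, 0))
  expect_equal(hsl_to_rgb(0.5, 1, 0.5), c(0, 1, 1))
  expect_equal(hsl_to_rgb(0.3, 0.4, 1), c(1, 1, 1))
})

test_that("classification report writer", {
  path <- file.path(tempdir(), "report.csv")
  unlink(path)
  pc <- classify_pattern(make_cycle_trace(c(170, 100), n = 30))
  write_classification(pc, path, label = "run1")
  write_classification(pc, path, label = "run2")
  rep <- read.csv(path)
  expect_equal(nrow(rep), 2)
  expect_equal(rep$category, rep("two_cycle_alternate", 2))
  expect_true(all(c("hue", "saturation", "lightness") %in% names(rep)))
  unlink(path)
})
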