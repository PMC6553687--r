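#' Divergence-angle and plastochron series of a trace
#'
#' For consecutive primordia `m` and `m+1`, the divergence angle is the
#' signed azimuthal difference wrapped into `(-180, 180]` (an exact
#' half-turn reports as `+180`), and the standardized plastochron is the
#' birth-time difference `t_{m+1} - t_m = ln(r_m / r_{m+1})`, the log of
#' Richards' plastochron ratio. For the discrete engine every plastochron
#' equals `G` exactly.
#'
#' @param trace a `phyllo_trace`.
#' @return a data.frame with one row per consecutive pair: `angle` (signed
#'   degrees) and `plastochron` (standardized time, >= 0).
#' @export
divergence_series <- function(trace) {
  pr <- trace$primordia
  if (nrow(pr) < 2) stop("divergence_series: need at least 2 primordia")
  data.frame(angle = wrap_signed(diff(pr$theta)),
             plastochron = diff(pr$birth_time))
}

#' Group primordia into nodes of simultaneous insertion
#'
#' Primordia inserted at the same simulation time step share a birth time
#' and form one node (a whorl if the node has more than one member).
#'
#' @param trace a `phyllo_trace`.
#' @param tol birth-time tolerance; defaults to a quarter time step.
#' @return a list with `node` (node id per primordium, in birth order) and
#'   `sizes` (member count per node).
#' @export
group_nodes <- function(trace, tol = NULL) {
  pr <- trace$primordia
  if (is.null(tol)) {
    tol <- if (trace$model %in% c("DC2", "EDC2")) trace$settings$dt / 4 else 1e-9
  }
  node <- cumsum(c(TRUE, diff(pr$birth_time) > tol))
  list(node = node, sizes = as.integer(table(node)))
}

circ_phase_mean <- function(x) {
  ref <- x[1]
  wrap_signed(ref + mean(wrap_signed(x - ref)))
}

# smallest period c in `periods` under which `x` repeats circularly within
# `tol` degrees, with at least two full repeats inside the window
detect_period <- function(x, periods, tol) {
  L <- length(x)
  for (c in sort(periods)) {
    if (2 * c > L) next
    if (all(abs(wrap_signed(x[seq_len(L - c) + c] - x[seq_len(L - c)])) <= tol))
      return(c)
  }
  NA_integer_
}

is_x_motif <- function(phase_means, zero_tol) {
  a <- abs(phase_means)
  sum(abs(a - 180) < zero_tol) == 1 && sum(a < zero_tol) == length(a) - 1
}

#' Classify the phyllotactic pattern of a trace
#'
#' Implements the pattern taxonomy used for the colour-legend maps. If
#' either of the last two insertion nodes holds more than one primordium
#' the pattern is whorled: node pairs of 2/2 with an inter-node rotation of
#' 90 +/- `whorl_tol` degrees are decussate, 3/3 with 60 +/- `whorl_tol`
#' are tricussate, other stable equal counts are `other_whorled`, and
#' unstable counts are `other`. Otherwise the pattern is alternate and the
#' last `window - 1` divergence angles are searched for the smallest cycle
#' (at least two full repeats, angles compared circularly within `tol`):
#' cycle 1 is a regular alternate pattern (constant divergence), cycle 2 a
#' two-cycle, and cycle 4 with sign pattern `(p, q, -p, -q)` a
#' tetrastichous four-cycle. Cycles whose motif is one near-180-degree step
#' followed by near-zero steps (within `zero_tol`) are x-cycle patterns;
#' for cycles longer than 4 the search window widens to the last
#' `x_window` angles, since two repeats of a long cycle cannot fit in the
#' standard window. Anything else is `other`.
#'
#' @param trace a `phyllo_trace` with at least `window` primordia.
#' @param window number of trailing primordia judged (default 9, i.e. 8
#'   divergence angles).
#' @param tol angle tolerance in degrees for cycle detection (default 2).
#' @param zero_tol tolerance for counting an angle as "0" or "180" in the
#'   x-cycle motif (default 10).
#' @param whorl_tol tolerance on the inter-node rotation of whorls.
#' @param x_window window (in angles) for long-cycle detection (default 30).
#' @return an object of class `pattern_class`: list with `category`,
#'   `cycle_length`, `representative_angles`, `representative_plastochrons`,
#'   `mean_divergence`, `angle_ratio`, `plastochron_ratio`,
#'   `primordia_per_node`, `node_rotation`.
#' @export
classify_pattern <- function(trace, window = 9, tol = 2, zero_tol = 10,
                             whorl_tol = 10, x_window = 30) {
  pr <- trace$primordia
  if (nrow(pr) < window) stop("classify_pattern: trace shorter than the window")
  out <- list(category = "other", cycle_length = NA_integer_,
              representative_angles = NULL, representative_plastochrons = NULL,
              mean_divergence = NA_real_, angle_ratio = NA_real_,
              plastochron_ratio = NA_real_, primordia_per_node = NA_integer_,
              node_rotation = NA_real_)
  class(out) <- "pattern_class"

  nodes <- group_nodes(trace)
  ns <- nodes$sizes
  last2 <- utils::tail(ns, 2)
  if (any(last2 > 1)) {
    if (last2[1] == last2[2]) {
      out$primordia_per_node <- last2[1]
      k <- length(ns)
      ang_of <- function(node_id) pr$theta[nodes$node == node_id]
      a_prev <- ang_of(k - 1)
      a_last <- ang_of(k)
      rot <- min(abs(wrap_signed(outer(a_last, a_prev, "-"))))
      out$node_rotation <- rot
      if (last2[1] == 2 && abs(rot - 90) <= whorl_tol) {
        out$category <- "decussate"
      } else if (last2[1] == 3 && abs(rot - 60) <= whorl_tol) {
        out$category <- "tricussate"
      } else {
        out$category <- "other_whorled"
      }
    } else {
      out$category <- "other"
    }
    return(out)
  }

  ds <- divergence_series(trace)
  ang <- utils::tail(ds$angle, window - 1)
  pls <- utils::tail(ds$plastochron, window - 1)
  cyc <- detect_period(ang, 1:4, tol)

  fill_cycle <- function(a, p, c) {
    phases <- ((seq_along(a) - 1) %% c) + 1
    m_ang <- vapply(split(a, phases), circ_phase_mean, numeric(1))
    m_pls <- vapply(split(p, phases), mean, numeric(1))
    list(ang = unname(m_ang), pls = unname(m_pls))
  }

  if (!is.na(cyc)) {
    ph <- fill_cycle(ang, pls, cyc)
    out$cycle_length <- cyc
    out$representative_angles <- ph$ang
    out$representative_plastochrons <- ph$pls
    out$mean_divergence <- mean(abs(ph$ang))
    out$plastochron_ratio <- min(ph$pls) / max(ph$pls)
    if (cyc >= 2 && is_x_motif(ph$ang, zero_tol)) {
      out$category <- "x_cycle_alternate"
      out$angle_ratio <- min(abs(ph$ang)) / max(abs(ph$ang))
      return(out)
    }
    if (cyc == 1) {
      out$category <- "regular_alternate"
      out$angle_ratio <- 1
    } else if (cyc == 2) {
      out$category <- "two_cycle_alternate"
      out$angle_ratio <- min(abs(ph$ang)) / max(abs(ph$ang))
    } else if (cyc == 4 &&
               abs(wrap_signed(ph$ang[1] + ph$ang[3])) <= tol &&
               abs(wrap_signed(ph$ang[2] + ph$ang[4])) <= tol) {
      out$category <- "four_cycle_alternate"
      out$angle_ratio <- min(abs(ph$ang[1:2])) / max(abs(ph$ang[1:2]))
    } else {
      out$category <- "other"
    }
    return(out)
  }

  # long cycles: widen the window (the standard one cannot hold two repeats)
  angw <- utils::tail(ds$angle, x_window)
  plsw <- utils::tail(ds$plastochron, x_window)
  cyc <- detect_period(angw, 5:floor(length(angw) / 2), tol)
  if (!is.na(cyc)) {
    ph <- fill_cycle(angw, plsw, cyc)
    out$cycle_length <- cyc
    out$representative_angles <- ph$ang
    out$representative_plastochrons <- ph$pls
    out$mean_divergence <- mean(abs(ph$ang))
    out$plastochron_ratio <- min(ph$pls) / max(ph$pls)
    if (is_x_motif(ph$ang, zero_tol)) {
      out$category <- "x_cycle_alternate"
      out$angle_ratio <- min(abs(ph$ang)) / max(abs(ph$ang))
    } else {
      out$category <- "other"
    }
  }
  out
}

#' @export
print.pattern_class <- function(x, ...) {
  cat(sprintf("<pattern_class> %s", x$category))
  if (!is.na(x$cycle_length)) cat(sprintf(" (cycle %d)", x$cycle_length))
  cat("\n")
  if (!is.null(x$representative_angles)) {
    cat("  angles (deg):",
        paste(sprintf("%.1f", x$representative_angles), collapse = ", "), "\n")
    cat(sprintf("  mean |divergence| = %.1f deg\n", x$mean_divergence))
  }
  if (!is.na(x$angle_ratio))
    cat(sprintf("  angle ratio = %.3f, plastochron ratio = %.3f\n",
                x$angle_ratio, x$plastochron_ratio))
  if (!is.na(x$primordia_per_node))
    cat(sprintf("  primordia per node = %d, node rotation = %.1f deg\n",
                x$primordia_per_node, x$node_rotation))
  invisible(x)
}

#' Small/large ratios of a two- or four-cycle pattern
#'
#' Returns the ratio of the absolute values of the two alternating
#' divergence angles and the ratio of the two alternating plastochrons
#' (both small/large, in `[0, 1]`), the coordinates of the published
#' pattern scatter plots.
#'
#' @param pc a `pattern_class`.
#' @return named numeric vector `c(angle_ratio, plastochron_ratio)`.
#' @export
ratio_stats <- function(pc) {
  stopifnot(inherits(pc, "pattern_class"))
  if (!pc$category %in% c("two_cycle_alternate", "four_cycle_alternate")) {
    stop("ratio_stats: defined for two-cycle and four-cycle patterns only")
  }
  c(angle_ratio = pc$angle_ratio, plastochron_ratio = pc$plastochron_ratio)
}

#' Colour-legend encoding of a pattern class
#'
#' Maps a classified pattern to an HSL colour following the published
#' legend: alternate patterns take a hue running linearly from cyan at a
#' mean absolute divergence of 0 degrees to red at 180 degrees, lightness
#' encodes the plastochron ratio (ratio 0 is full lightness, ratio 1 the
#' pure colour), and saturation encodes the angle ratio (ratio 1 is full
#' saturation). x-cycle patterns are black; whorled and residual classes
#' take fixed reserved colours (decussate purple, tricussate green,
#' other whorled light grey, other dark grey).
#'
#' @param pc a `pattern_class`.
#' @return named numeric vector `c(hue, saturation, lightness)`, each in
#'   `[0, 1]`.
#' @export
color_encode <- function(pc) {
  stopifnot(inherits(pc, "pattern_class"))
  fixed <- switch(pc$category,
                  x_cycle_alternate = c(0, 0, 0),
                  decussate = c(0.8, 1, 0.35),
                  tricussate = c(1 / 3, 1, 0.35),
                  other_whorled = c(0, 0, 0.75),
                  other = c(0, 0, 0.25),
                  NULL)
  if (!is.null(fixed)) {
    return(c(hue = fixed[1], saturation = fixed[2], lightness = fixed[3]))
  }
  hue <- (180 - pc$mean_divergence) / 360  # 180 deg -> red (0), 0 deg -> cyan (0.5)
  c(hue = hue,
    saturation = pc$angle_ratio,
    lightness = 1 - 0.5 * pc$plastochron_ratio)
}

#' Convert HSL colour components to sRGB
#'
#' @param h,s,l hue, saturation and lightness in `[0, 1]`.
#' @return numeric vector `c(r, g, b)` in `[0, 1]`.
#' @export
hsl_to_rgb <- function(h, s, l) {
  c_ <- (1 - abs(2 * l - 1)) * s
  hp <- (h %% 1) * 6
  x <- c_ * (1 - abs(hp %% 2 - 1))
  rgb1 <- if (hp < 1) c(c_, x, 0) else if (hp < 2) c(x, c_, 0) else
          if (hp < 3) c(0, c_, x) else if (hp < 4) c(0, x, c_) else
          if (hp < 5) c(x, 0, c_) else c(c_, 0, x)
  m <- l - c_ / 2
  pmin(pmax(rgb1 + m, 0), 1)
}

#' Write a one-row classification report
#'
#' Appends (or creates) a CSV with one row per trace: category, cycle
#' length, representative angles, ratios and the HSL colour.
#'
#' @param pc a `pattern_class`.
#' @param path CSV path.
#' @param label optional run label for the first column.
#' @return the report row, invisibly.
#' @export
write_classification <- function(pc, path, label = "") {
  col <- color_encode(pc)
  row <- data.frame(label = label,
                    category = pc$category,
                    cycle_length = pc$cycle_length,
                    angles = paste(round(pc$representative_angles, 2),
                                   collapse = ";"),
                    mean_divergence = pc$mean_divergence,
                    angle_ratio = pc$angle_ratio,
                    plastochron_ratio = pc$plastochron_ratio,
                    primordia_per_node = pc$primordia_per_node,
                    hue = col[["hue"]], saturation = col[["saturation"]],
                    lightness = col[["lightness"]])
  utils::write.table(row, path, sep = ",", row.names = FALSE,
                     col.names = !file.exists(path), append = file.exists(path))
  invisible(row)
}
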