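#' Simulation settings
#'
#' Settings shared by the two simulation engines. The defaults are the
#' standard protocol used throughout: an angular grid of 0.1 degrees on the
#' primordium-formation circle, a time step of 0.001 standardized time units
#' for the continuous engine, and runs of 100 primordia.
#'
#' @param angle_resolution angular grid spacing in degrees; must divide 360.
#' @param dt time step of the continuous-time engine (standardized time).
#' @param max_primordia number of primordia at which a run stops.
#' @param initial_condition `"single"` (one primordium at 0 degrees) or
#'   `"two_at_120"` (two primordia 120 degrees apart, both age 0).
#' @param tie_break `"ccw"` or `"cw"`: scan order of the angular grid when
#'   several grid points share the field minimum. Chirality of emergent
#'   spirals is physically arbitrary; flipping this yields the mirror trace.
#' @param prune logical; skip primordia whose maximum possible contribution
#'   to the field is below `prune_tol * Es` (continuous engine only). The
#'   pruned tail only recedes further, so this does not affect insertions at
#'   the stated tolerance; disable for oracle comparisons.
#' @param prune_tol relative pruning tolerance.
#' @param t_max guard on total simulated time (continuous engine).
#' @param seed reserved; both engines are deterministic.
#' @return an object of class `sim_settings`.
#' @export
sim_settings <- function(angle_resolution = 0.1, dt = 0.001,
                         max_primordia = 100,
                         initial_condition = c("single", "two_at_120"),
                         tie_break = c("ccw", "cw"),
                         prune = TRUE, prune_tol = 1e-12,
                         t_max = 2000, seed = NULL) {
  initial_condition <- match.arg(initial_condition)
  tie_break <- match.arg(tie_break)
  n_grid <- round(360 / angle_resolution)
  stopifnot(abs(n_grid * angle_resolution - 360) < 1e-9,
            dt > 0, max_primordia >= 10)
  structure(list(angle_resolution = angle_resolution, dt = dt,
                 max_primordia = as.integer(max_primordia),
                 initial_condition = initial_condition,
                 tie_break = tie_break, prune = prune,
                 prune_tol = prune_tol, t_max = t_max, seed = seed),
            class = "sim_settings")
}

new_trace <- function(theta, birth_time, min_field, params, settings) {
  n <- length(theta)
  tr <- data.frame(index = seq_len(n),
                   theta = wrap_angle(theta),
                   birth_time = birth_time,
                   min_field = min_field)
  structure(list(primordia = tr,
                 model = model_tag(params),
                 params = params,
                 settings = settings),
            class = "phyllo_trace")
}

#' @export
print.phyllo_trace <- function(x, ...) {
  n <- nrow(x$primordia)
  cat(sprintf("<phyllo_trace> %s, %d primordia\n", x$model, n))
  if (n >= 2) {
    ds <- divergence_series(x)
    k <- min(8, length(ds$angle))
    cat("  last divergence angles (deg):",
        paste(sprintf("%.1f", utils::tail(ds$angle, k)), collapse = ", "), "\n")
    cat("  last plastochrons:",
        paste(sprintf("%.3f", utils::tail(ds$plastochron, k)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Run the discrete one-per-plastochron simulator (planar apex)
#'
#' Starting from a single seed primordium at 0 degrees, each iteration
#' evaluates the inhibitory field [field_dc1()] on the angular grid of the
#' primordium-formation circle and places the next primordium at the global
#' field minimum (first minimum in grid scan order on exact ties). All
#' existing primordia then recede by one plastochron of growth. Birth times
#' are recorded in standardized units, `G` per plastochron, so that the log
#' plastochron ratio `ln(r_m / r_{m+1})` equals `G` exactly.
#'
#' @param params a [dc1_params()] or [edc1_params()] record.
#' @param settings a [sim_settings()] object.
#' @return a `phyllo_trace`.
#' @export
run_dc1 <- function(params, settings = sim_settings()) {
  stopifnot(inherits(params, "dc1_params"))
  res <- settings$angle_resolution
  n_grid <- round(360 / res)
  grid <- (seq_len(n_grid) - 1) * res
  nmax <- settings$max_primordia
  theta <- numeric(nmax)
  theta[1] <- 0
  scan <- if (settings$tie_break == "ccw") seq_len(n_grid) else rev(seq_len(n_grid))
  minf <- rep(NA_real_, nmax)
  for (n in 2:nmax) {
    ages <- (n - 1):1
    I <- field_dc1(grid, theta[seq_len(n - 1)], ages, params)
    arg <- scan[which.min(I[scan])]
    theta[n] <- grid[arg]
    minf[n] <- I[arg]
  }
  new_trace(theta, (seq_len(nmax) - 1) * params$G, minf, params, settings)
}

#' Run the continuous-time threshold simulator (conical apex)
#'
#' Advances standardized time in fixed steps; whenever the inhibitory field
#' [field_dc2()] on the primordium-formation circle falls below the
#' threshold `Es` somewhere, a primordium is formed immediately at the
#' minimising grid angle, and the check repeats within the same step so that
#' several primordia can arise simultaneously at distinct angles (a whorl).
#' The engine is compiled; it reproduces the R-level field definition
#' exactly up to the optional far-primordium pruning.
#'
#' @param params a [dc2_params()] or [edc2_params()] record (`Es = 1`).
#' @param settings a [sim_settings()] object.
#' @return a `phyllo_trace`.
#' @export
run_dc2 <- function(params, settings = sim_settings()) {
  stopifnot(inherits(params, "dc2_params"))
  init <- switch(settings$initial_condition,
                 single = list(theta = 0, t = 0),
                 two_at_120 = list(theta = c(0, 120), t = c(0, 0)))
  ramp <- params$ramp
  ext <- inherits(params, "edc2_params")
  out <- dc2_engine(init$theta, init$t,
                    params$alpha, params$N, params$Es,
                    params$Gamma, !is.null(ramp),
                    if (is.null(ramp)) 0 else ramp$Gamma_i,
                    if (is.null(ramp)) 0 else ramp$Gamma_f,
                    if (is.null(ramp)) 0 else ramp$t_i,
                    if (is.null(ramp)) 1 else ramp$tau,
                    ext,
                    if (ext) params$A else 0,
                    if (ext) params$B else 0,
                    settings$angle_resolution, settings$dt,
                    settings$max_primordia,
                    settings$prune, settings$prune_tol, settings$t_max,
                    if (settings$tie_break == "ccw") 1L else -1L,
                    switch(params$radial_term, times_n = params$N,
                           over_n = 1 / params$N, euclid = 1, plain = 1),
                    switch(params$radial_term,
                           euclid = 2 * params$N^2, 2 * params$N))
  new_trace(out$theta, out$birth_time, out$min_field, params, settings)
}

#' Run a model given any parameter record
#'
#' Dispatches to [run_dc1()] or [run_dc2()] on the class of `params`.
#'
#' @inheritParams run_dc1
#' @return a `phyllo_trace`.
#' @export
run_model <- function(params, settings = sim_settings()) {
  if (inherits(params, "dc1_params")) run_dc1(params, settings)
  else run_dc2(params, settings)
}

#' Check near-equivalence of the expanded and plain continuous models
#'
#' With a very fast age factor (`A` large, `B = 0`) the inhibitory power of
#' every primordium of positive age is essentially constant, and the
#' expanded continuous model collapses onto the plain one. This runs both
#' with identical settings and reports whether the primordium angle
#' sequences agree within one grid step (and the counts match).
#'
#' @param params a [dc2_params()] record.
#' @param settings a [sim_settings()] object.
#' @param A rate used for the expanded run (default 1000).
#' @return `TRUE` or `FALSE`.
#' @export
equivalence_check_edc2_dc2 <- function(params, settings = sim_settings(),
                                       A = 1000) {
  stopifnot(inherits(params, "dc2_params"), !inherits(params, "edc2_params"))
  tr1 <- run_dc2(params, settings)
  p2 <- edc2_params(alpha = params$alpha, Gamma = params$Gamma, N = params$N,
                    A = A, B = 0, Es = params$Es)
  tr2 <- run_dc2(p2, settings)
  a1 <- tr1$primordia$theta
  a2 <- tr2$primordia$theta
  if (length(a1) != length(a2)) return(FALSE)
  dtheta <- abs(wrap_signed(a1 - a2))
  all(dtheta <= settings$angle_resolution + 1e-9)
}

#' Write and read simulation traces
#'
#' `write_trace()` stores the primordium table as CSV (columns `index`,
#' `birth_time`, `theta_deg`, `r_over_R0` at the final time, and
#' `min_field_at_birth`) with a JSON sidecar (`<path>.json`) holding the
#' model tag, parameters and settings for reproducibility. `read_trace()`
#' restores a `phyllo_trace` from the pair.
#'
#' @param trace a `phyllo_trace`.
#' @param path CSV file path.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` a
#'   `phyllo_trace`.
#' @export
write_trace <- function(trace, path) {
  pr <- trace$primordia
  t_end <- max(pr$birth_time)
  df <- data.frame(index = pr$index,
                   birth_time = pr$birth_time,
                   theta_deg = pr$theta,
                   r_over_R0 = exp(t_end - pr$birth_time),
                   min_field_at_birth = pr$min_field)
  write.csv(df, path, row.names = FALSE)
  side <- list(model = trace$model,
               params = unclass(trace$params),
               settings = unclass(trace$settings))
  if (!is.null(side$params$ramp)) side$params$ramp <- unclass(side$params$ramp)
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  params <- switch(side$model,
    DC1 = dc1_params(eta = side$params$eta, G = side$params$G, k = side$params$k),
    EDC1 = edc1_params(G = side$params$G, a = side$params$a, b = side$params$b,
                       eta = side$params$eta, k = side$params$k),
    DC2 = dc2_params(alpha = side$params$alpha, Gamma = side$params$Gamma,
                     N = side$params$N, Es = side$params$Es),
    EDC2 = edc2_params(alpha = side$params$alpha, Gamma = side$params$Gamma,
                       N = side$params$N, A = side$params$A, B = side$params$B,
                       Es = side$params$Es,
                       ramp = if (!is.null(side$params$ramp))
                         do.call(gamma_ramp, side$params$ramp)),
    stop("unknown model tag in sidecar"))
  st <- side$settings
  settings <- sim_settings(angle_resolution = st$angle_resolution, dt = st$dt,
                           max_primordia = st$max_primordia,
                           initial_condition = st$initial_condition,
                           tie_break = st$tie_break, prune = st$prune,
                           prune_tol = st$prune_tol, t_max = st$t_max)
  new_trace(df$theta_deg, df$birth_time, df$min_field_at_birth,
            params, settings)
}

#' Polar map of the inhibitory field over the apical region
#'
#' Evaluates `ln I` on a rectangular raster of (radius, angle), the format
#' of the published contour maps, at a given time for the primordia of a
#' trace (or any primordium set). Radii at or beyond a primordium position
#' show the divergence of the kernel as large values.
#'
#' @param trace a `phyllo_trace` from the continuous-time engine.
#' @param now evaluation time; defaults to the final birth time.
#' @param r_max outer radius of the map (units of `R0`).
#' @param n_r number of radial samples.
#' @param n_theta number of angular samples over 360 degrees.
#' @return an object of class `phyllo_map`: list with `log_field`
#'   (`n_r` x `n_theta` matrix), `radius`, `theta`.
#' @export
inhibition_map <- function(trace, now = NULL, r_max = 5, n_r = 100,
                           n_theta = 360) {
  pr <- trace$primordia
  if (is.null(now)) now <- max(pr$birth_time)
  params <- trace$params
  keep <- pr$birth_time <= now
  th_p <- pr$theta[keep]
  r_p <- exp(now - pr$birth_time[keep])
  w <- if (inherits(params, "edc2_params")) {
    age_factor_edc2(now - pr$birth_time[keep], params$A, params$B)
  } else rep(1, sum(keep))
  radius <- seq(r_max / n_r, r_max, length.out = n_r)
  theta <- (seq_len(n_theta) - 1) * 360 / n_theta
  d0 <- params$Gamma * params$N
  M <- matrix(0, n_r, n_theta)
  for (m in seq_along(th_p)) {
    d <- outer(radius, theta, function(r, th)
      conical_distance(r, th, r_p[m], th_p[m], params$N,
                       radial_term = params$radial_term))
    e <- params$Es * expm1(2 * params$alpha) / expm1(2 * params$alpha * d / d0)
    e[d == 0] <- Inf
    M <- M + w[m] * e
  }
  structure(list(log_field = log(M), radius = radius, theta = theta),
            class = "phyllo_map")
}

#' Write a field map as a plain-text matrix and a PNG image
#'
#' @param map a `phyllo_map` from [inhibition_map()].
#' @param txt_path path for the tab-separated matrix of `ln I` (rows =
#'   radii, columns = angles); `NULL` to skip.
#' @param png_path path for a grayscale PNG rendering (values clipped to
#'   `clip`); `NULL` to skip.
#' @param clip symmetric clipping range for the PNG, in `ln I` units.
#' @return invisibly, the map.
#' @export
write_map <- function(map, txt_path = NULL, png_path = NULL, clip = c(-3, 3)) {
  if (!is.null(txt_path)) {
    utils::write.table(round(map$log_field, 6), txt_path, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(png_path)) {
    z <- map$log_field
    z[!is.finite(z)] <- clip[2]
    z <- pmin(pmax(z, clip[1]), clip[2])
    img <- (z - clip[1]) / diff(clip)
    png::writePNG(img, png_path)
  }
  invisible(map)
}
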