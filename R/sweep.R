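#' Parameter-sweep grid specification
#'
#' Describes a sweep over one or two model parameters with all others
#' fixed, the layout of the published bifurcation maps. Axis values are
#' given explicitly (e.g. `seq(0.05, 1, length.out = 11)`); the published
#' maps use 101 or 201 values per axis, which is also supported but slow
#' at desk scale — record the chosen density and scale in the provenance.
#'
#' @param model one of `"DC1"`, `"EDC1"`, `"DC2"`, `"EDC2"`.
#' @param axes named list of 1 or 2 numeric vectors; names must be
#'   parameters of the model's constructor (e.g. `G`, `eta` for `DC1`).
#' @param fixed named list of the remaining parameters.
#' @param settings a [sim_settings()].
#' @return an object of class `sweep_grid`.
#' @export
sweep_grid <- function(model, axes, fixed = list(),
                       settings = sim_settings()) {
  model <- match.arg(model, c("DC1", "EDC1", "DC2", "EDC2"))
  stopifnot(is.list(axes), length(axes) %in% 1:2, !is.null(names(axes)),
            all(vapply(axes, is.numeric, logical(1))))
  structure(list(model = model, axes = axes, fixed = fixed,
                 settings = settings),
            class = "sweep_grid")
}

build_params <- function(model, values) {
  switch(model,
         DC1 = do.call(dc1_params, values),
         EDC1 = do.call(edc1_params, values),
         DC2 = do.call(dc2_params, values),
         EDC2 = do.call(edc2_params, values))
}

#' Run a parameter sweep
#'
#' Simulates, classifies and colour-encodes every grid point. Grid points
#' are independent, so the result does not depend on evaluation order; a
#' failing simulation flags its row (`ok = FALSE`) without stopping the
#' sweep.
#'
#' @param grid a [sweep_grid()].
#' @param quiet suppress the per-point progress messages.
#' @return a `sweep_result`: data.frame with the axis columns, pattern
#'   summary columns (`category`, `cycle_length`, `mean_divergence`,
#'   `angle_ratio`, `plastochron_ratio`), colour columns (`hue`,
#'   `saturation`, `lightness`) and `ok`; the grid and a provenance record
#'   (package version, timestamp) are attached as attributes.
#' @export
run_sweep <- function(grid, quiet = TRUE) {
  stopifnot(inherits(grid, "sweep_grid"))
  pts <- expand.grid(grid$axes, KEEP.OUT.ATTRS = FALSE)
  n <- nrow(pts)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    vals <- c(as.list(pts[i, , drop = FALSE]), grid$fixed)
    row <- tryCatch({
      params <- build_params(grid$model, vals)
      tr <- run_model(params, grid$settings)
      pc <- classify_pattern(tr)
      col <- color_encode(pc)
      data.frame(category = pc$category, cycle_length = pc$cycle_length,
                 mean_divergence = pc$mean_divergence,
                 angle_ratio = pc$angle_ratio,
                 plastochron_ratio = pc$plastochron_ratio,
                 hue = col[["hue"]], saturation = col[["saturation"]],
                 lightness = col[["lightness"]], ok = TRUE)
    }, error = function(e) {
      data.frame(category = "error", cycle_length = NA_integer_,
                 mean_divergence = NA_real_, angle_ratio = NA_real_,
                 plastochron_ratio = NA_real_, hue = NA_real_,
                 saturation = NA_real_, lightness = NA_real_, ok = FALSE)
    })
    rows[[i]] <- row
    if (!quiet) message(sprintf("[%d/%d] %s", i, n, row$category))
  }
  out <- cbind(pts, do.call(rbind, rows))
  structure(out, grid = grid,
            provenance = list(package = "phyllofield",
                              version = as.character(utils::packageVersion("phyllofield")),
                              n_points = n,
                              timestamp = format(Sys.time(), tz = "UTC")),
            class = c("sweep_result", "data.frame"))
}

#' Render a two-axis sweep as a colour map
#'
#' One pixel block per grid point, coloured by the pattern colour code;
#' the first axis runs left to right, the second bottom to top.
#'
#' @param result a `sweep_result` from a 2-axis sweep.
#' @param path PNG output path.
#' @param block pixel block size per grid point.
#' @return the RGB array, invisibly.
#' @export
render_map <- function(result, path = NULL, block = 8) {
  grid <- attr(result, "grid")
  if (length(grid$axes) != 2)
    stop("render_map: needs a 2-axis sweep; plot 1-axis results as a profile")
  n1 <- length(grid$axes[[1]]); n2 <- length(grid$axes[[2]])
  img <- array(0, dim = c(n2, n1, 3))
  for (i in seq_len(nrow(result))) {
    r <- result[i, ]
    col <- if (isTRUE(r$ok)) hsl_to_rgb(r$hue, r$saturation, r$lightness)
           else c(1, 0, 1)  # flagged rows in magenta
    i1 <- match(r[[1]], grid$axes[[1]])
    i2 <- match(r[[2]], grid$axes[[2]])
    img[n2 - i2 + 1, i1, ] <- col
  }
  big <- img[rep(seq_len(n2), each = block), rep(seq_len(n1), each = block), ,
             drop = FALSE]
  if (!is.null(path)) png::writePNG(big, path)
  invisible(img)
}
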