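# Pseudo-color rendering of maps.  Invalid pixels are transparent -- gaps are
# shown, never inpainted.  The value range and palette travel with the raster
# as attributes so the value-to-color mapping is invertible.

#' Render a map as a pseudo-color raster
#'
#' @param map An `activation_map`, `parameter_map`, `vector_field` (its speed
#'   is rendered) or a plain numeric matrix.
#' @param colormap Palette name understood by [grDevices::hcl.colors()]
#'   (default `"viridis"`).
#' @param n_colors Number of palette bins (default 256).
#' @param range Value range mapped onto the palette; defaults to the range of
#'   the valid values.  A degenerate range (min = max) yields a single-color
#'   render, not an error.
#' @param overlay Optional base frame (H x W matrix, e.g. one frame of the
#'   recording) rendered in grayscale underneath the map.
#' @param overlay_alpha Opacity of the map over the base frame in [0, 1];
#'   `0` returns the base frame unchanged.  Default 1.
#' @param isochrone_step Optional contour interval (time units): pixels where
#'   the value crosses a multiple of the step relative to a 4-neighbour are
#'   drawn black, tracing isochrones.
#' @return An H x W x 4 RGBA array (values in [0, 1]) of class `map_render`,
#'   with attributes `range`, `colormap`, `n_colors`, `palette` and
#'   `isochrone_step` that make the color mapping invertible.  Write it with
#'   [png::writePNG()] or via [write_outputs()].
#' @export
render_map <- function(map, colormap = "viridis", n_colors = 256L,
                       range = NULL, overlay = NULL, overlay_alpha = 1,
                       isochrone_step = NULL) {
  vals <- map_values(map)
  H <- nrow(vals); W <- ncol(vals)
  valid <- is.finite(vals)
  if (is.null(range)) {
    range <- if (any(valid)) base::range(vals[valid]) else c(0, 0)
  }
  if (overlay_alpha < 0 || overlay_alpha > 1)
    pm_input_error("overlay_alpha must be in [0, 1]")
  pal <- grDevices::hcl.colors(n_colors, colormap)
  rgb_pal <- grDevices::col2rgb(pal) / 255

  out <- array(0, dim = c(H, W, 4L))
  if (any(valid)) {
    span <- range[2L] - range[1L]
    idx <- if (span > 0) {
      pmin(n_colors, pmax(1L, 1L + floor((vals[valid] - range[1L]) / span * (n_colors - 1L) + 0.5)))
    } else {
      rep(1L, sum(valid))  # degenerate range: single color
    }
    for (ch in 1:3) {
      plane <- matrix(0, H, W)
      plane[valid] <- rgb_pal[ch, idx]
      out[, , ch] <- plane
    }
    a <- matrix(0, H, W); a[valid] <- overlay_alpha
    out[, , 4L] <- a
  }

  if (!is.null(isochrone_step)) {
    if (isochrone_step <= 0) pm_input_error("isochrone_step must be positive")
    lev <- floor(vals / isochrone_step)
    edge <- matrix(FALSE, H, W)
    edge[-H, ] <- edge[-H, ] | (lev[-H, ] != lev[-1L, ])
    edge[, -W] <- edge[, -W] | (lev[, -W] != lev[, -1L])
    edge <- edge & valid
    for (ch in 1:3) { p <- out[, , ch]; p[edge] <- 0; out[, , ch] <- p }
    a <- out[, , 4L]; a[edge] <- 1; out[, , 4L] <- a
  }

  if (!is.null(overlay)) {
    overlay <- as.matrix(overlay)
    if (!all(dim(overlay) == c(H, W)))
      pm_input_error("overlay frame size does not match the map")
    rng_o <- base::range(overlay, finite = TRUE)
    base_gray <- if (diff(rng_o) > 0) (overlay - rng_o[1L]) / diff(rng_o)
                 else matrix(0.5, H, W)
    a <- out[, , 4L]
    blended <- array(0, dim = c(H, W, 4L))
    for (ch in 1:3) blended[, , ch] <- a * out[, , ch] + (1 - a) * base_gray
    blended[, , 4L] <- 1
    out <- blended
  }

  structure(out, class = "map_render",
            range = range, colormap = colormap, n_colors = n_colors,
            palette = pal, isochrone_step = isochrone_step)
}

#' Invert a rendered color back to its value bin
#'
#' Utility to check round-tripping of the value-to-color mapping: given a
#' render and a pixel, returns the center of the value bin its color encodes.
#'
#' @param render A `map_render` from [render_map()].
#' @param i,j Pixel row and column.
#' @return The bin-center value, or `NA` for transparent (invalid) pixels.
#' @export
render_value_at <- function(render, i, j) {
  if (render[i, j, 4L] == 0) return(NA_real_)
  pal <- grDevices::col2rgb(attr(render, "palette")) / 255
  col <- c(render[i, j, 1L], render[i, j, 2L], render[i, j, 3L])
  k <- which.min(colSums((pal - col)^2))
  rng <- attr(render, "range")
  n <- attr(render, "n_colors")
  if (diff(rng) == 0) return(rng[1L])
  rng[1L] + (k - 1L) / (n - 1L) * diff(rng)
}
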