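# Keypoint-logit heatmap rendering: per-channel min-max normalization of the
# network's logit grids to [0, 1], per-pixel max combination across the six
# keypoint channels, and colormapped alpha blending onto the radiograph.
# Grids arrive as a simple JSON tensor (producing them from a network is out
# of scope); rasters are plain arrays, read/written as PNG.

#' Construct a heatmap grid
#'
#' A `height x width x 6` array of keypoint logits aligned to an image
#' region, channels in schema order.
#'
#' @param logits Numeric `h x w x 6` array, finite values only.
#' @param origin Pixel offset `c(x, y)` of the grid's top-left corner within
#'   the target image (0-based).
#' @return Object of class `heatmap_grid`.
#' @export
heatmap_grid <- function(logits, origin = c(0, 0)) {
  if (length(dim(logits)) != 3L || dim(logits)[3L] != 6L) {
    stop("logits must be a height x width x 6 array", call. = FALSE)
  }
  if (any(!is.finite(logits))) {
    stop("logit grid contains non-finite values", call. = FALSE)
  }
  structure(
    list(logits = logits, origin = as.numeric(origin)),
    class = "heatmap_grid"
  )
}

#' Normalize logits to the unit interval
#'
#' Per-channel min-max scaling to `[0, 1]`: the channel minimum maps to 0
#' and the maximum to 1, so the stated output range is achieved exactly for
#' arbitrary logits. A constant channel maps to all zeros — a channel with
#' no signal should not paint the image. A sigmoid squash is available as
#' an alternative for callers whose logits are calibrated log-odds.
#'
#' @param grid A [heatmap_grid()].
#' @param method `"minmax"` (default) or `"sigmoid"`.
#' @return A `heatmap_grid` with values in `[0, 1]`.
#' @export
normalize_logits <- function(grid, method = c("minmax", "sigmoid")) {
  method <- match.arg(method)
  stopifnot(inherits(grid, "heatmap_grid"))
  out <- grid$logits
  if (method == "sigmoid") {
    out <- 1 / (1 + exp(-out))
  } else {
    for (ch in 1:6) {
      v <- out[, , ch]
      rng <- range(v)
      out[, , ch] <- if (rng[1L] == rng[2L]) {
        0 * v
      } else {
        (v - rng[1L]) / (rng[2L] - rng[1L])
      }
    }
  }
  heatmap_grid(out, grid$origin)
}

#' Combine the six keypoint channels into one map
#'
#' Per-pixel maximum across channels, so each pixel shows its best
#' keypoint likelihood and disjoint hotspots all survive.
#'
#' @param grid A normalized [heatmap_grid()].
#' @return A `height x width` matrix.
#' @export
combine_channels <- function(grid) {
  stopifnot(inherits(grid, "heatmap_grid"))
  apply(grid$logits, c(1L, 2L), max)
}

as_rgb_array <- function(image) {
  if (is.matrix(image)) {
    array(rep(image, 3L), dim = c(dim(image), 3L))
  } else if (length(dim(image)) == 3L && dim(image)[3L] >= 3L) {
    image[, , 1:3, drop = FALSE]
  } else {
    stop("image must be a grayscale matrix or an RGB(A) array", call. = FALSE)
  }
}

#' Superimpose a keypoint heatmap on a radiograph
#'
#' Normalizes the grid, combines the channels, maps intensity through a
#' colormap and alpha-blends onto the image; the blend strength scales with
#' the heatmap intensity, so zero-intensity pixels leave the radiograph
#' untouched. Optionally also returns the six per-channel panels.
#'
#' @param image Grayscale matrix or RGB array with values in `[0, 1]`.
#' @param grid A [heatmap_grid()]; must fit inside the image at its origin.
#' @param colormap A palette name understood by [grDevices::hcl.colors()];
#'   default `"viridis"` (perceptually uniform).
#' @param alpha Maximum blend opacity in `[0, 1]`.
#' @param per_channel If `TRUE`, also emit one overlay per keypoint channel.
#' @return Object of class `rendered_overlay`: list with `raster`
#'   (`h x w x 3` array), `legend` (colormap, alpha, per-channel ranges) and
#'   optionally `channels`.
#' @export
render_overlay <- function(image, grid, colormap = "viridis", alpha = 0.5,
                           per_channel = FALSE) {
  stopifnot(inherits(grid, "heatmap_grid"), alpha >= 0, alpha <= 1)
  img <- as_rgb_array(image)
  gh <- dim(grid$logits)[1L]
  gw <- dim(grid$logits)[2L]
  x0 <- grid$origin[1L]
  y0 <- grid$origin[2L]
  if (x0 < 0 || y0 < 0 || x0 + gw > dim(img)[2L] || y0 + gh > dim(img)[1L]) {
    stop("heatmap region lies outside the image bounds", call. = FALSE)
  }
  ranges <- t(apply(grid$logits, 3L, range))
  norm <- normalize_logits(grid)
  pal <- t(grDevices::col2rgb(grDevices::hcl.colors(256L, colormap))) / 255
  blend_map <- function(intensity) {
    out <- img
    rows <- y0 + seq_len(gh)
    cols <- x0 + seq_len(gw)
    idx <- pmin(255L, pmax(0L, as.integer(round(intensity * 255)))) + 1L
    a <- alpha * intensity
    for (c3 in 1:3) {
      patch <- img[rows, cols, c3]
      colv <- matrix(pal[idx, c3], gh, gw)
      out[rows, cols, c3] <- (1 - a) * patch + a * colv
    }
    out
  }
  overlay <- blend_map(combine_channels(norm))
  result <- list(
    raster = overlay,
    legend = list(
      colormap = colormap, alpha = alpha,
      channel_ranges = stats::setNames(
        as.data.frame(ranges), c("min", "max")
      )
    )
  )
  if (per_channel) {
    result$channels <- lapply(1:6, function(ch) {
      blend_map(norm$logits[, , ch])
    })
    names(result$channels) <- keypoint_schema()$names
  }
  structure(result, class = "rendered_overlay")
}

#' @export
print.rendered_overlay <- function(x, ...) {
  d <- dim(x$raster)
  cat(sprintf(
    "<rendered_overlay> %d x %d raster, colormap %s, alpha %.2f\n",
    d[2L], d[1L], x$legend$colormap %||% "-", x$legend$alpha %||% 1
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write heatmap grids as JSON tensors
#'
#' The on-disk dialect is a JSON object with `height`, `width`, `channels`,
#' `origin` and a row-major `values` array, small enough to ship as a text
#' fixture.
#'
#' @param path File path.
#' @param grid A [heatmap_grid()].
#' @return `read_heatmap_grid` returns a `heatmap_grid`; `write_heatmap_grid`
#'   returns `path` invisibly.
#' @export
read_heatmap_grid <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  arr <- aperm(
    array(
      as.numeric(doc$values),
      dim = c(doc$channels, doc$width, doc$height)
    ),
    c(3L, 2L, 1L)
  )
  heatmap_grid(arr, as.numeric(doc$origin))
}

#' @rdname read_heatmap_grid
#' @export
write_heatmap_grid <- function(grid, path) {
  stopifnot(inherits(grid, "heatmap_grid"))
  d <- dim(grid$logits)
  doc <- list(
    height = d[1L], width = d[2L], channels = d[3L],
    origin = grid$origin,
    values = as.numeric(aperm(grid$logits, c(3L, 2L, 1L)))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write rasters as PNG
#'
#' @param path File path.
#' @param image Grayscale matrix or RGB array in `[0, 1]`.
#' @return `read_raster` returns an array; `write_raster` returns `path`
#'   invisibly.
#' @export
read_raster <- function(path) png::readPNG(path)

#' @rdname read_raster
#' @export
write_raster <- function(image, path) {
  png::writePNG(image, path)
  invisible(path)
}
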