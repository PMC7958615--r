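# Annotated prediction overlays: bounding box, the six keypoints, the three
# midpoints, the two measured segments and a burned-in text readout of the
# bone-loss percentage, severity and detection score. All drawing is pure
# array arithmetic (text via a small embedded 3x5 bitmap font), so renders
# are byte-identical for identical inputs on any platform.

put_pixel <- function(img, x, y, col) {
  h <- dim(img)[1L]
  w <- dim(img)[2L]
  xi <- round(x) + 1L
  yi <- round(y) + 1L
  keep <- xi >= 1L & xi <= w & yi >= 1L & yi <= h
  for (c3 in 1:3) {
    img[cbind(yi[keep], xi[keep], c3)] <- col[c3]
  }
  img
}

draw_disk <- function(img, x, y, radius, col) {
  off <- seq(-radius, radius)
  grid <- expand.grid(dx = off, dy = off)
  grid <- grid[grid$dx^2 + grid$dy^2 <= radius^2, ]
  put_pixel(img, x + grid$dx, y + grid$dy, col)
}

draw_line <- function(img, x0, y0, x1, y1, col) {
  n <- max(2L, ceiling(max(abs(x1 - x0), abs(y1 - y0))) + 1L)
  t <- seq(0, 1, length.out = n)
  put_pixel(img, x0 + t * (x1 - x0), y0 + t * (y1 - y0), col)
}

draw_rect <- function(img, bbox, col) {
  x0 <- bbox[1L]
  y0 <- bbox[2L]
  x1 <- bbox[1L] + bbox[3L]
  y1 <- bbox[2L] + bbox[4L]
  img <- draw_line(img, x0, y0, x1, y0, col)
  img <- draw_line(img, x1, y0, x1, y1, col)
  img <- draw_line(img, x1, y1, x0, y1, col)
  draw_line(img, x0, y1, x0, y0, col)
}

# 3 x 5 bitmap glyphs, rows top to bottom, '1' = ink
glyph_font <- function() {
  list(
    "0" = c("111", "101", "101", "101", "111"),
    "1" = c("010", "110", "010", "010", "111"),
    "2" = c("111", "001", "111", "100", "111"),
    "3" = c("111", "001", "111", "001", "111"),
    "4" = c("101", "101", "111", "001", "001"),
    "5" = c("111", "100", "111", "001", "111"),
    "6" = c("111", "100", "111", "101", "111"),
    "7" = c("111", "001", "001", "010", "010"),
    "8" = c("111", "101", "111", "101", "111"),
    "9" = c("111", "101", "111", "001", "111"),
    "." = c("000", "000", "000", "000", "010"),
    "%" = c("101", "001", "010", "100", "101"),
    "(" = c("010", "100", "100", "100", "010"),
    ")" = c("010", "001", "001", "001", "010"),
    " " = c("000", "000", "000", "000", "000"),
    "a" = c("010", "101", "111", "101", "101"),
    "d" = c("110", "101", "101", "101", "110"),
    "e" = c("111", "100", "111", "100", "111"),
    "l" = c("100", "100", "100", "100", "111"),
    "m" = c("101", "111", "101", "101", "101"),
    "n" = c("110", "101", "101", "101", "101"),
    "o" = c("111", "101", "101", "101", "111"),
    "r" = c("110", "101", "110", "101", "101"),
    "s" = c("011", "100", "010", "001", "110"),
    "t" = c("111", "010", "010", "010", "010"),
    "v" = c("101", "101", "101", "101", "010"),
    "y" = c("101", "101", "010", "010", "010")
  )
}

draw_text <- function(img, text, x, y, col, scale = 2L) {
  font <- glyph_font()
  cx <- x
  for (ch in strsplit(text, "")[[1L]]) {
    g <- font[[ch]]
    if (!is.null(g)) {
      for (row in 1:5) {
        bits <- strsplit(g[row], "")[[1L]]
        for (colb in 1:3) {
          if (bits[colb] == "1") {
            px <- cx + (colb - 1L) * scale + rep(seq_len(scale) - 1L, scale)
            py <- y + (row - 1L) * scale +
              rep(seq_len(scale) - 1L, each = scale)
            img <- put_pixel(img, px, py, col)
          }
        }
      }
    }
    cx <- cx + 4L * scale
  }
  img
}

#' Render an annotated prediction
#'
#' Draws the detection box, the six predicted keypoints (one color per
#' left/right landmark pair), the apex/top/bone-level midpoints, the two
#' measured segments (total length and defect length), and a burned-in label
#' of the form `"25.0% early (0.93)"` — bone-loss percentage, severity class
#' and detection score.
#'
#' @param image Grayscale matrix or RGB array in `[0, 1]`.
#' @param pred An [implant_prediction()].
#' @param measurement The matching [measure_bone_loss()] result.
#' @param text_scale Integer pixel size multiplier for the bitmap font.
#' @return A `rendered_overlay` whose `legend` records the label text and
#'   color assignments.
#' @export
render_prediction <- function(image, pred, measurement, text_scale = 2L) {
  stopifnot(
    inherits(pred, "implant_prediction"),
    inherits(measurement, "bone_loss_measurement")
  )
  img <- as_rgb_array(image)
  col_box <- c(0.1, 0.9, 0.2)
  col_pairs <- list(
    bone_level = c(1, 0.25, 0.25),
    apex = c(0.25, 0.45, 1),
    implant_top = c(1, 0.85, 0.1)
  )
  col_mid <- c(1, 1, 1)
  col_total <- c(0.2, 0.9, 0.9)
  col_defect <- c(1, 0.3, 1)
  img <- draw_rect(img, pred$bbox, col_box)
  mp <- measurement$midpoints
  img <- draw_line(
    img, mp$apex["x"], mp$apex["y"], mp$top["x"], mp$top["y"], col_total
  )
  img <- draw_line(
    img, mp$top["x"], mp$top["y"], mp$bone_level["x"], mp$bone_level["y"],
    col_defect
  )
  kp <- unclass(pred$keypoints)
  pair_of <- c(1L, 1L, 2L, 2L, 3L, 3L)
  for (i in 1:6) {
    img <- draw_disk(img, kp[i, "x"], kp[i, "y"], 3L, col_pairs[[pair_of[i]]])
  }
  for (m in mp) {
    img <- draw_disk(img, m["x"], m["y"], 1L, col_mid)
  }
  label <- sprintf(
    "%.1f%% %s (%.2f)", measurement$percentage, measurement$severity,
    pred$box_score
  )
  tx <- max(0, round(pred$bbox[1L]))
  ty <- max(0, round(pred$bbox[2L]) - 6L * text_scale)
  img <- draw_text(img, label, tx, ty, col_box, scale = text_scale)
  structure(
    list(
      raster = img,
      legend = list(
        label = label,
        colors = c(
          list(box = col_box, midpoint = col_mid, total = col_total,
               defect = col_defect),
          col_pairs
        )
      )
    ),
    class = "rendered_overlay"
  )
}
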