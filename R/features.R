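# The seven per-image metrics: prominent color, per-color percentages,
# number of colors, saturation, brightness, color fill, image coverage.
# Color percentages are shares of *classified drawn* pixels; white (the
# blank canvas) and unclassified pixels are excluded from both numerator and
# denominator, so the seven shares always total 100.

blank_canvas_error <- function(source_id = "") {
  stop(structure(
    class = c("blank_canvas_error", "error", "condition"),
    list(message = paste0("blank canvas: no drawn pixels",
                          if (nzchar(source_id)) paste0(" (", source_id, ")")),
         call = NULL)
  ))
}

#' Per-color percentages of a drawing
#'
#' For each of the seven expressive colors, the percentage of classified
#' drawn pixels carrying that color. White pixels (blank canvas) and drawn
#' pixels matching no palette range are excluded from numerator and
#' denominator, so the seven percentages sum to exactly 100.
#'
#' @param img An `hsv_image`.
#' @param palette A `color_palette`.
#' @return Named numeric vector over [expressive_colors()], summing to 100.
#' @export
color_percentages <- function(img, palette = default_palette()) {
  cls <- classify_pixels(img, palette)
  counts <- color_counts(cls)
  tot <- sum(counts)
  if (tot == 0L) blank_canvas_error(attr(img, "source_id") %||% "")
  100 * counts / tot
}

color_counts <- function(cls) {
  cols <- expressive_colors()
  counts <- vapply(cols, function(cc) sum(cls == cc), integer(1))
  names(counts) <- cols
  counts
}

#' Prominent color of a drawing
#'
#' The color with the largest percentage; ties are broken by the fixed
#' palette order ([expressive_colors()]).
#'
#' @param pct Named percentage vector as returned by [color_percentages()].
#' @return A single color name.
#' @export
prominent_color <- function(pct) {
  cols <- expressive_colors()
  pct <- pct[cols]
  cols[which.max(pct)]   # which.max takes the first maximum = palette order
}

#' Number of colors used
#'
#' Counts colors whose share of the drawn area exceeds `min_share` percent.
#' The threshold discards trace amounts (e.g. JPEG edge artifacts).
#'
#' @param pct Named percentage vector.
#' @param min_share Minimal share (percent) for a color to count; default 1.
#' @return Integer count.
#' @export
count_colors <- function(pct, min_share = 1.0) {
  sum(pct[expressive_colors()] > min_share)
}

#' Mean saturation and brightness over drawn pixels
#'
#' Arithmetic means of the S and V channels over the drawn (non-white)
#' pixels, rescaled from 0-255 to percent.
#'
#' @param img An `hsv_image`.
#' @param mask Logical drawn-pixel mask (see [drawn_mask()]).
#' @return Named numeric vector `c(saturation_pct, brightness_pct)`.
#' @export
saturation_brightness <- function(img, mask) {
  stopifnot(inherits(img, "hsv_image"), is.logical(mask))
  if (!any(mask)) blank_canvas_error(attr(img, "source_id") %||% "")
  s <- img[, , 2L][mask]
  v <- img[, , 3L][mask]
  c(saturation_pct = mean(s) / 255 * 100,
    brightness_pct = mean(v) / 255 * 100)
}

#' Color fill percentage
#'
#' The proportion of the canvas occupied by drawn pixels.
#'
#' @param mask Logical drawn-pixel mask.
#' @return Percentage in [0, 100].
#' @export
color_fill <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  100 * sum(mask) / length(mask)
}

#' Image coverage percentage
#'
#' The proportion of the canvas enclosed by the drawing's outer extent,
#' counting interior blank holes as covered. Background is flood-filled from
#' the grid border over non-drawn cells (4-connectivity); every cell the
#' flood does not reach is covered. Always at least [color_fill()].
#'
#' @param mask Logical drawn-pixel mask.
#' @return Percentage in [0, 100].
#' @export
image_coverage <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  reach <- flood_background(mask)
  100 * sum(!reach) / length(mask)
}

# Cells of !mask reachable from the border by 4-connected steps.
# Vectorized propagation: vertical runs are flooded wholesale (a run is
# reachable iff any of its cells is), horizontal growth one step per pass;
# iterate to a fixed point.
flood_background <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  bg <- !mask
  # vertical run ids over the column-major layout
  v <- as.vector(bg)
  first_row <- rep(c(TRUE, rep(FALSE, h - 1L)), w)
  start <- v & (first_row | !c(FALSE, v[-length(v)]))
  runid <- cumsum(start)
  runid[!v] <- 0L
  nrun <- max(runid)

  reach <- matrix(FALSE, h, w)
  reach[1L, ] <- bg[1L, ]; reach[h, ] <- bg[h, ]
  reach[, 1L] <- bg[, 1L]; reach[, w] <- bg[, w]
  if (!any(reach)) return(reach)
  repeat {
    before <- sum(reach)
    if (nrun > 0L) {
      rv <- as.vector(reach)
      hitrun <- rowsum(as.numeric(rv[v]), runid[v]) > 0
      rv[v] <- hitrun[runid[v], 1L]
      reach <- matrix(rv, h, w)
    }
    if (w > 1L) {
      reach <- reach |
        (cbind(FALSE, reach[, -w, drop = FALSE]) & bg) |
        (cbind(reach[, -1L, drop = FALSE], FALSE) & bg)
    }
    if (sum(reach) == before) break
  }
  reach
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the full feature vector of one drawing
#'
#' Composes pixel classification and all per-image metrics into a one-row
#' data frame (the drawing's feature vector).
#'
#' @param img A `raster_image` (or an `hsv_image` already converted).
#' @param palette A `color_palette`.
#' @param n_colors_min_share Share threshold (percent) for [count_colors()].
#' @return One-row data frame with columns `source_id`, `prominent_color`,
#'   `pct_<color>` for the seven expressive colors, `n_colors`,
#'   `saturation_pct`, `brightness_pct`, `color_fill_pct`,
#'   `image_coverage_pct`, `unclassified_pct`.
#' @export
extract_features <- function(img, palette = default_palette(),
                             n_colors_min_share = 1.0) {
  hsv <- if (inherits(img, "hsv_image")) img else rgb_to_hsv_opencv(img)
  sid <- attr(hsv, "source_id") %||% ""
  mask <- drawn_mask(hsv, palette)
  if (!any(mask)) blank_canvas_error(sid)
  cls <- classify_pixels(hsv, palette)
  counts <- color_counts(cls)
  tot <- sum(counts)
  if (tot == 0L) blank_canvas_error(sid)
  pct <- 100 * counts / tot
  sb <- saturation_brightness(hsv, mask)
  n_drawn <- sum(mask)
  uncls <- sum(cls == "unclassified")
  out <- data.frame(
    source_id = sid,
    prominent_color = prominent_color(pct),
    stringsAsFactors = FALSE
  )
  for (cc in expressive_colors()) out[[paste0("pct_", cc)]] <- unname(pct[cc])
  out$n_colors <- count_colors(pct, n_colors_min_share)
  out$saturation_pct <- unname(sb["saturation_pct"])
  out$brightness_pct <- unname(sb["brightness_pct"])
  out$color_fill_pct <- color_fill(mask)
  out$image_coverage_pct <- image_coverage(mask)
  out$unclassified_pct <- 100 * uncls / n_drawn
  out
}
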