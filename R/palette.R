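# Named HSV color ranges on the OpenCV scale (H 0-180, S/V 0-255) and the
# fixed precedence used to resolve range overlaps during classification.

#' Expressive color names
#'
#' The seven color categories available for drawing, excluding white (the
#' blank canvas). Order is the canonical palette order, also used to break
#' ties when picking a prominent color.
#'
#' @return Character vector of seven color names.
#' @export
expressive_colors <- function() {
  c("red", "yellow", "green", "blue", "purple", "gray", "black")
}

#' Default HSV color palette
#'
#' Nine inclusive HSV ranges on the OpenCV scale covering eight color names
#' (red is split across the two ends of the hue circle). The hue intervals of
#' the six chromatic ranges partition 0-180. `eval_order` is the precedence
#' with which overlapping ranges are resolved: achromatic ranges first
#' (black, white, gray), then chromatic ones, so that dark ambiguous pixels
#' (V <= 70) are always called black.
#'
#' @return A `color_palette`: a data frame with columns `name`, `h_lo`,
#'   `s_lo`, `v_lo`, `h_hi`, `s_hi`, `v_hi`, `eval_order`, one row per range.
#' @export
default_palette <- function() {
  pal <- data.frame(
    name = c("red", "red", "yellow", "green", "blue", "purple",
             "gray", "black", "white"),
    h_lo = c(0, 146, 11, 37, 84, 125, 0, 0, 0),
    s_lo = c(53, 53, 46, 46, 53, 53, 0, 0, 0),
    v_lo = c(46, 46, 53, 53, 46, 46, 71, 0, 230),
    h_hi = c(10, 180, 36, 83, 124, 145, 180, 180, 180),
    s_hi = c(255, 255, 255, 255, 255, 255, 25, 255, 30),
    v_hi = c(255, 255, 255, 255, 255, 255, 229, 70, 255),
    # precedence: black, white, gray, red(low), red(high), yellow, green,
    # blue, purple
    eval_order = c(4, 5, 6, 7, 8, 9, 3, 1, 2),
    stringsAsFactors = FALSE
  )
  validate_palette(pal)
}

validate_palette <- function(pal) {
  req <- c("name", "h_lo", "s_lo", "v_lo", "h_hi", "s_hi", "v_hi",
           "eval_order")
  if (!all(req %in% names(pal))) {
    stop("palette must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(pal) != 9L) stop("palette must have exactly 9 range rows")
  if (!setequal(pal$name, c(expressive_colors(), "white"))) {
    stop("palette must cover the 7 expressive colors plus white")
  }
  if (sum(pal$name == "red") != 2L) {
    stop("red must appear twice (hue wraparound)")
  }
  lo <- as.matrix(pal[, c("h_lo", "s_lo", "v_lo")])
  hi <- as.matrix(pal[, c("h_hi", "s_hi", "v_hi")])
  if (any(lo > hi)) stop("palette lower bounds must not exceed upper bounds")
  if (any(pal$h_lo < 0) || any(pal$h_hi > 180)) {
    stop("hue bounds must lie in [0, 180]")
  }
  if (any(lo < 0) || any(hi[, 2:3] > 255)) {
    stop("S/V bounds must lie in [0, 255]")
  }
  if (!setequal(pal$eval_order, seq_len(9L))) {
    stop("eval_order must be a permutation of 1..9")
  }
  class(pal) <- c("color_palette", "data.frame")
  pal
}

#' Read / write a palette as a plain-text table
#'
#' @param path CSV file with the palette columns of [default_palette()].
#' @return `read_palette` returns a validated `color_palette`;
#'   `write_palette` invisibly returns `path`.
#' @export
read_palette <- function(path) {
  pal <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_palette(pal)
}

#' @rdname read_palette
#' @param palette A `color_palette`.
#' @export
write_palette <- function(palette, path) {
  utils::write.csv(as.data.frame(palette), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# rows of `pal` sorted by classification precedence
palette_in_eval_order <- function(pal) {
  pal[order(pal$eval_order), , drop = FALSE]
}

white_range <- function(pal) {
  pal[pal$name == "white", , drop = FALSE][1L, ]
}

#' Classify HSV pixels into palette colors
#'
#' Each pixel is assigned the first range (in `eval_order` precedence) whose
#' bounds contain it, inclusively on both ends; pixels matching no range are
#' `"unclassified"`.
#'
#' @param hsv An `hsv_image`, or an n x 3 matrix of (H, S, V) rows on the
#'   OpenCV scale.
#' @param palette A `color_palette`.
#' @return Character vector of color names (length = number of pixels).
#' @export
classify_pixels <- function(hsv, palette = default_palette()) {
  m <- as_hsv_matrix(hsv)
  if (any(m[, 1L] < 0 | m[, 1L] > 180 | m[, 2L] < 0 | m[, 2L] > 255 |
          m[, 3L] < 0 | m[, 3L] > 255)) {
    stop("HSV components out of OpenCV scale (H 0-180, S/V 0-255)")
  }
  ord <- palette_in_eval_order(palette)
  res <- rep(NA_character_, nrow(m))
  for (i in seq_len(nrow(ord))) {
    r <- ord[i, ]
    hit <- is.na(res) &
      m[, 1L] >= r$h_lo & m[, 1L] <= r$h_hi &
      m[, 2L] >= r$s_lo & m[, 2L] <= r$s_hi &
      m[, 3L] >= r$v_lo & m[, 3L] <= r$v_hi
    res[hit] <- r$name
  }
  res[is.na(res)] <- "unclassified"
  res
}

#' Drawn-pixel mask
#'
#' A pixel is "drawn" when it is not inside the white (blank canvas) range.
#'
#' @param img An `hsv_image`.
#' @param palette A `color_palette`.
#' @return Logical matrix with the image's dimensions; `TRUE` = drawn.
#' @export
drawn_mask <- function(img, palette = default_palette()) {
  stopifnot(inherits(img, "hsv_image"))
  w <- white_range(palette)
  h <- img[, , 1L]; s <- img[, , 2L]; v <- img[, , 3L]
  white <- h >= w$h_lo & h <= w$h_hi & s >= w$s_lo & s <= w$s_hi &
    v >= w$v_lo & v <= w$v_hi
  !white
}

as_hsv_matrix <- function(hsv) {
  if (inherits(hsv, "hsv_image") || (is.array(hsv) && length(dim(hsv)) == 3L)) {
    d <- dim(hsv)
    m <- matrix(as.numeric(hsv), d[1L] * d[2L], 3L)
  } else if (is.matrix(hsv) && ncol(hsv) == 3L) {
    m <- hsv
  } else if (is.numeric(hsv) && length(hsv) == 3L) {
    m <- matrix(hsv, 1L, 3L)
  } else {
    stop("expected an hsv_image, an n x 3 matrix, or an (H,S,V) triple")
  }
  m
}
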