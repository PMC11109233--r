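# Reading/writing raster drawings and RGB -> HSV conversion on the OpenCV
# scale (H halved to 0-180, S and V stretched to 0-255).

#' Construct a raster image
#'
#' @param pixels Integer array `h x w x 3` with RGB channels in 0-255.
#' @param source_id Opaque identifier (e.g. participant/emotion tag).
#' @return A `raster_image` (integer array with a `source_id` attribute).
#' @export
raster_image <- function(pixels, source_id = "") {
  d <- dim(pixels)
  if (length(d) != 3L || d[3L] != 3L) stop("pixels must be an h x w x 3 array")
  if (d[1L] < 1L || d[2L] < 1L) stop("image must be at least 1 x 1")
  if (any(pixels < 0) || any(pixels > 255) || any(pixels != round(pixels))) {
    stop("channels must be integers in [0, 255]")
  }
  storage.mode(pixels) <- "integer"
  structure(pixels, source_id = source_id, class = "raster_image")
}

#' Load a drawing from disk
#'
#' Reads a JPEG or PNG file into an 8-bit RGB grid. Grayscale images are
#' expanded to three channels; an alpha channel, if present, is composited
#' over a white canvas (the blank-canvas convention).
#'
#' @param path Path to a `.png`, `.jpg` or `.jpeg` file.
#' @param source_id Identifier stored on the image; defaults to the file
#'   name without extension.
#' @return A `raster_image`.
#' @export
load_image <- function(path, source_id = NULL) {
  if (!file.exists(path)) stop("image file not found: ", path)
  if (is.null(source_id)) {
    source_id <- sub("\\.[^.]*$", "", basename(path))
  }
  ext <- tolower(sub(".*\\.", "", path))
  arr <- tryCatch(
    switch(ext,
           png = png::readPNG(path),
           jpg = ,
           jpeg = jpeg::readJPEG(path),
           stop("unsupported image format: ", ext)),
    error = function(e) {
      stop("cannot decode image '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (length(dim(arr)) == 2L) {            # grayscale
    arr <- array(rep(arr, 3L), c(dim(arr), 3L))
  }
  nc <- dim(arr)[3L]
  if (nc == 2L) {                          # gray + alpha
    a <- arr[, , 2L]
    g <- arr[, , 1L] * a + (1 - a)
    arr <- array(rep(g, 3L), c(dim(arr)[1:2], 3L))
  } else if (nc == 4L) {                   # RGBA over white
    a <- arr[, , 4L]
    rgb <- arr[, , 1:3, drop = FALSE]
    for (k in 1:3) rgb[, , k] <- rgb[, , k] * a + (1 - a)
    arr <- rgb
  } else if (nc != 3L) {
    stop("cannot decode image '", path, "': unexpected channel count ", nc)
  }
  raster_image(round(arr[, , 1:3, drop = FALSE] * 255), source_id = source_id)
}

#' Save a drawing as PNG
#'
#' PNG is lossless, so a save/load round trip preserves pixels bit-exactly.
#'
#' @param img A `raster_image`.
#' @param path Output path (`.png`).
#' @return Invisibly, `path`.
#' @export
save_image <- function(img, path) {
  stopifnot(inherits(img, "raster_image"))
  png::writePNG(unclass(img) / 255, path)
  invisible(path)
}

#' Convert RGB to HSV on the OpenCV scale
#'
#' Standard hexcone conversion with OpenCV's 8-bit packing: H = round(H_deg /
#' 2) in 0-180, S and V scaled to 0-255 and rounded. A hue that rounds to
#' 180 at the red wraparound is kept as 180 (the upper red range includes
#' it). Achromatic pixels (R = G = B) get S = 0 and H = 0.
#'
#' @param img A `raster_image`.
#' @return An `hsv_image`: integer array `h x w x 3` of (H, S, V).
#' @export
rgb_to_hsv_opencv <- function(img) {
  stopifnot(inherits(img, "raster_image"))
  d <- dim(img)
  hsv <- .hexcone_hsv(as.vector(img[, , 1L]), as.vector(img[, , 2L]),
                      as.vector(img[, , 3L]))
  out <- array(0L, d)
  out[, , 1L] <- hsv$h
  out[, , 2L] <- hsv$s
  out[, , 3L] <- hsv$v
  structure(out, source_id = attr(img, "source_id"), class = "hsv_image")
}

# vectorized hexcone conversion on the OpenCV integer scale; the single
# place channel arithmetic happens, so the renderer and the extractor can
# never disagree by a rounding ulp
.hexcone_hsv <- function(r, g, b) {
  rp <- r / 255; gp <- g / 255; bp <- b / 255
  v <- pmax(rp, gp, bp)
  mn <- pmin(rp, gp, bp)
  dd <- v - mn
  s <- ifelse(v == 0, 0, dd / v)
  hdeg <- numeric(length(v))
  sel <- dd > 0 & v == rp
  hdeg[sel] <- 60 * ((gp[sel] - bp[sel]) / dd[sel])
  sel2 <- dd > 0 & v == gp & v != rp
  hdeg[sel2] <- 60 * ((bp[sel2] - rp[sel2]) / dd[sel2]) + 120
  sel3 <- dd > 0 & v == bp & v != rp & v != gp
  hdeg[sel3] <- 60 * ((rp[sel3] - gp[sel3]) / dd[sel3]) + 240
  hdeg[hdeg < 0] <- hdeg[hdeg < 0] + 360
  list(h = as.integer(round(hdeg / 2)),
       s = as.integer(round(s * 255)),
       v = as.integer(round(v * 255)))
}
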