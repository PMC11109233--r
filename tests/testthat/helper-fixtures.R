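# Shared fixtures and independent oracles, all built in code.

# scalar hexcone RGB -> OpenCV-HSV oracle, independent of grDevices
naive_hsv_opencv <- function(r, g, b) {
  rp <- r / 255; gp <- g / 255; bp <- b / 255
  v <- max(rp, gp, bp)
  mn <- min(rp, gp, bp)
  s <- if (v == 0) 0 else (v - mn) / v
  if (v == mn) {
    hdeg <- 0
  } else {
    d <- v - mn
    hdeg <- if (v == rp) {
      60 * ((gp - bp) / d)
    } else if (v == gp) {
      60 * ((bp - rp) / d) + 120
    } else {
      60 * ((rp - gp) / d) + 240
    }
    if (hdeg < 0) hdeg <- hdeg + 360
  }
  c(h = round(hdeg / 2), s = round(s * 255), v = round(v * 255))
}

# uniform image of one RGB color
flat_image <- function(rgb, w = 4L, h = 4L, source_id = "flat") {
  arr <- array(0L, c(h, w, 3L))
  for (k in 1:3) arr[, , k] <- rgb[k]
  raster_image(arr, source_id = source_id)
}

# image from a matrix of palette color names ("white" = canvas); paints
# saturated mid-range representatives of each color range
name_grid_image <- function(names_mat, source_id = "grid") {
  reps <- list(red = c(255L, 0L, 0L), yellow = c(255L, 255L, 0L),
               green = c(0L, 255L, 0L), blue = c(0L, 0L, 255L),
               purple = c(128L, 0L, 255L), gray = c(150L, 150L, 150L),
               black = c(0L, 0L, 0L), white = c(255L, 255L, 255L))
  h <- nrow(names_mat); w <- ncol(names_mat)
  arr <- array(255L, c(h, w, 3L))
  for (i in seq_len(h)) for (j in seq_len(w)) {
    arr[i, j, ] <- reps[[names_mat[i, j]]]
  }
  raster_image(arr, source_id = source_id)
}

# brute-force containment classification against all nine ranges in
# evaluation-order precedence (independent of classify_pixels internals)
brute_classify <- function(hsv, pal) {
  pal <- pal[order(pal$eval_order), ]
  for (i in seq_len(nrow(pal))) {
    r <- pal[i, ]
    if (hsv[1] >= r$h_lo && hsv[1] <= r$h_hi &&
        hsv[2] >= r$s_lo && hsv[2] <= r$s_hi &&
        hsv[3] >= r$v_lo && hsv[3] <= r$v_hi) {
      return(r$name)
    }
  }
  "unclassified"
}

# recursive-free scanline flood fill oracle for small masks (4-connectivity)
flood_oracle <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  reach <- matrix(FALSE, h, w)
  queue <- list()
  push <- function(i, j) queue[[length(queue) + 1L]] <<- c(i, j)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if ((i == 1L || i == h || j == 1L || j == w) && !mask[i, j]) push(i, j)
  }
  while (length(queue)) {
    cur <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    i <- cur[1L]; j <- cur[2L]
    if (reach[i, j] || mask[i, j]) next
    reach[i, j] <- TRUE
    if (i > 1L && !reach[i - 1L, j] && !mask[i - 1L, j]) push(i - 1L, j)
    if (i < h && !reach[i + 1L, j] && !mask[i + 1L, j]) push(i + 1L, j)
    if (j > 1L && !reach[i, j - 1L] && !mask[i, j - 1L]) push(i, j - 1L)
    if (j < w && !reach[i, j + 1L] && !mask[i, j + 1L]) push(i, j + 1L)
  }
  100 * sum(!reach) / length(mask)
}

# hollow square-outline mask: 10x10 with a closed 6x6 outline
ring_mask <- function() {
  m <- matrix(FALSE, 10L, 10L)
  m[3:8, 3] <- TRUE; m[3:8, 8] <- TRUE
  m[3, 3:8] <- TRUE; m[8, 3:8] <- TRUE
  m
}

# small calibrated profile set shared across generator tests (calibration
# results are cached inside the package for the session)
calibrated_profiles <- function() {
  lapply(default_emotion_profiles(), calibrate_profile)
}
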