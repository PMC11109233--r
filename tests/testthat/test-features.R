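# mixed drawing used across feature tests: 30 red / 20 blue / 50 white on
# a 10x10 canvas
mixed_drawing <- function() {
  nm <- matrix("white", 10L, 10L)
  nm[1:3, ] <- "red"                 # 30 px
  nm[4:5, ] <- "blue"                # 20 px
  name_grid_image(nm, source_id = "mixed")
}

test_that("color percentages are shares of classified drawn pixels", {
  hsv <- rgb_to_hsv_opencv(mixed_drawing())
  pct <- color_percentages(hsv)
  expect_equal(unname(pct["red"]), 60)
  expect_equal(unname(pct["blue"]), 40)
  expect_equal(sum(pct), 100)

  nm <- matrix("white", 4L, 4L)
  nm[1, 1] <- "red"
  expect_equal(unname(color_percentages(
    rgb_to_hsv_opencv(name_grid_image(nm)))["red"]), 100)

  nm <- matrix(c("red", "yellow", "green", "blue"), 2L, 2L)
  pct <- color_percentages(rgb_to_hsv_opencv(name_grid_image(nm)))
  expect_equal(unname(pct[c("red", "yellow", "green", "blue")]),
               rep(25, 4L))
})

test_that("blank canvases raise a typed error", {
  white <- rgb_to_hsv_opencv(flat_image(c(255L, 255L, 255L), 5L, 5L))
  expect_error(color_percentages(white), class = "blank_canvas_error")
  expect_error(extract_features(flat_image(c(255L, 255L, 255L), 5L, 5L)),
               class = "blank_canvas_error")
})

test_that("prominent color takes the maximum with palette-order ties", {
  pct <- c(red = 60, yellow = 0, green = 0, blue = 40, purple = 0,
           gray = 0, black = 0)
  expect_equal(prominent_color(pct), "red")
  pct2 <- c(red = 50, yellow = 0, green = 0, blue = 50, purple = 0,
            gray = 0, black = 0)
  expect_equal(prominent_color(pct2), "red")    # tie: palette order
  pct3 <- c(red = 0, yellow = 0, green = 0, blue = 30, purple = 0,
            gray = 30, black = 40)
  expect_equal(prominent_color(pct3), "black")
})

test_that("count_colors applies the minimum-share threshold", {
  pct <- c(red = 60, yellow = 0, green = 0, blue = 40, purple = 0,
           gray = 0, black = 0)
  expect_equal(count_colors(pct), 2L)
  expect_equal(count_colors(c(red = 100, yellow = 0, green = 0, blue = 0,
                              purple = 0, gray = 0, black = 0)), 1L)
  expect_equal(count_colors(c(red = 99.5, yellow = 0.5, green = 0,
                              blue = 0, purple = 0, gray = 0, black = 0),
                            min_share = 1.0), 1L)
  expect_equal(count_colors(c(red = 99.5, yellow = 0.5, green = 0,
                              blue = 0, purple = 0, gray = 0, black = 0),
                            min_share = 0.4), 2L)
})

test_that("saturation/brightness are means over drawn pixels", {
  img <- array(0L, c(2L, 2L, 3L))
  img[1, 1, ] <- c(255L, 0L, 0L)     # S=255 V=255
  img[1, 2, ] <- c(255L, 0L, 0L)
  img[2, 1, ] <- c(150L, 150L, 150L) # S=0 V=150
  img[2, 2, ] <- c(150L, 150L, 150L)
  hsv <- rgb_to_hsv_opencv(raster_image(img))
  mask <- matrix(TRUE, 2L, 2L)
  sb <- saturation_brightness(hsv, mask)
  expect_equal(unname(sb["saturation_pct"]), mean(c(255, 255, 0, 0)) / 255 * 100)
  expect_equal(unname(sb["brightness_pct"]),
               mean(c(255, 255, 150, 150)) / 255 * 100)
  expect_error(saturation_brightness(hsv, matrix(FALSE, 2L, 2L)),
               class = "blank_canvas_error")
})

test_that("fill and coverage behave on hand-built masks", {
  expect_equal(color_fill(matrix(FALSE, 10L, 10L)), 0)
  expect_equal(color_fill(matrix(c(rep(TRUE, 50), rep(FALSE, 50)),
                                 10L, 10L)), 50)
  expect_equal(color_fill(matrix(TRUE, 10L, 10L)), 100)

  # closed 6x6 outline on 10x10: 20 drawn, 36 covered
  rm <- ring_mask()
  expect_equal(color_fill(rm), 20)
  expect_equal(image_coverage(rm), 36)

  # solid blob: coverage equals fill
  blob <- matrix(FALSE, 10L, 10L)
  blob[3:7, 3:7] <- TRUE
  expect_equal(image_coverage(blob), color_fill(blob))
  expect_equal(image_coverage(matrix(FALSE, 8L, 8L)), 0)

  # diagonal gap: 4-connected background leaks through it
  diag_gap <- matrix(FALSE, 5L, 5L)
  diag_gap[2, 3] <- TRUE; diag_gap[3, 2] <- TRUE   # touching corners only
  diag_gap[3, 4] <- TRUE; diag_gap[4, 3] <- TRUE
  expect_equal(image_coverage(diag_gap), color_fill(diag_gap) + 100 / 25)
})

test_that("coverage agrees with independent flood-fill oracles", {
  set.seed(99)
  for (rep in 1:25) {
    m <- matrix(runif(144) < 0.45, 12L, 12L)
    expect_equal(image_coverage(m), flood_oracle(m))
  }
  skip_if_not_installed("EBImage")
  for (rep in 1:10) {
    m <- matrix(runif(400) < 0.4, 20L, 20L)
    filled <- EBImage::fillHull(EBImage::Image(m * 1))
    expect_equal(image_coverage(m),
                 100 * sum(filled > 0) / length(m))
  }
})

test_that("fill never exceeds coverage on random masks", {
  set.seed(5)
  for (rep in 1:50) {
    m <- matrix(runif(256) < runif(1, 0.1, 0.9), 16L, 16L)
    expect_lte(color_fill(m), image_coverage(m))
  }
})

test_that("metrics are invariant under transposition and rotation", {
  img <- mixed_drawing()
  rotate90 <- function(a) {
    out <- array(0L, c(dim(a)[2L], dim(a)[1L], 3L))
    for (k in 1:3) out[, , k] <- t(a[, , k])[, dim(a)[1L]:1]
    raster_image(out)
  }
  transp <- function(a) {
    out <- array(0L, c(dim(a)[2L], dim(a)[1L], 3L))
    for (k in 1:3) out[, , k] <- t(a[, , k])
    raster_image(out)
  }
  f0 <- extract_features(img)
  metric_cols <- setdiff(names(f0), "source_id")
  for (variant in list(rotate90(img), transp(img))) {
    fv <- extract_features(variant)
    expect_equal(fv[metric_cols], f0[metric_cols],
                 ignore_attr = TRUE)
  }
})

test_that("extract_features composes the per-metric operations", {
  f <- extract_features(mixed_drawing())
  expect_equal(f$prominent_color, "red")
  expect_equal(f$pct_red, 60)
  expect_equal(f$pct_blue, 40)
  expect_equal(f$n_colors, 2L)
  expect_equal(f$saturation_pct, 100)
  expect_equal(f$brightness_pct, 100)
  expect_equal(f$color_fill_pct, 50)
  expect_equal(f$image_coverage_pct, 50)
  expect_equal(f$unclassified_pct, 0)
  expect_equal(f$source_id, "mixed")
})

test_that("percentage sums are exact for random classified drawings", {
  set.seed(21)
  cols <- c(expressive_colors(), "white")
  for (rep in 1:20) {
    nm <- matrix(sample(cols, 64L, replace = TRUE), 8L, 8L)
    nm[1, 1] <- "red"    # guarantee a drawn pixel
    f <- extract_features(name_grid_image(nm))
    tot <- sum(unlist(f[paste0("pct_", expressive_colors())]))
    expect_equal(tot, 100, tolerance = 1e-12)
  }
})
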