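# Seeded synthetic "emotion drawings" with known ground truth.
#
# Geometry: canvas cells are ordered in concentric square (Chebyshev) rings
# around the center. The coverage region is the first C cells of that
# spiral; the interior hole is the first H = C - F cells, so the drawn
# region is a thick annulus. Any 4-connected path from the border into the
# hole must cross a fully drawn ring, so border flood-fill recovers the
# coverage region exactly and fill/coverage are pixel-count exact by
# construction.
#
# Color: drawn cells are split among the seven expressive colors by
# largest-remainder rounding of the sampled shares. Each color is painted
# with RGB triples whose min and max channels are set exactly, so the
# OpenCV-scale V equals the chosen value and S equals round(d/v*255) with
# chroma d = v - min; per-color (s, v) levels are chosen by water-filling
# so the drawn-pixel means hit the sampled saturation/brightness targets.

# ---- spiral cell ordering ------------------------------------------------

# cached per canvas size: cells in ring-by-angle order plus ring bookkeeping
spiral_layout <- function(w, h) {
  key <- paste0("spiral|", w, "x", h)
  hit <- .emodraw_cache[[key]]
  if (!is.null(hit)) return(hit)
  cx <- floor(w / 2); cy <- floor(h / 2)
  x <- rep(0:(w - 1L), each = h)
  y <- rep.int(0:(h - 1L), w)
  d <- pmax(abs(x - cx), abs(y - cy))
  min_border_d <- min(cx, cy, w - 1L - cx, h - 1L - cy)
  ang <- atan2(y - cy, x - cx)
  ord0 <- order(d, ang)
  d_sorted <- d[ord0]
  ringsize <- tabulate(d_sorted + 1L)
  cum <- cumsum(ringsize)                    # cells with ring <= r at cum[r+1]
  segstart <- c(0L, cum[-length(cum)])       # 0-based start of each ring block
  rank0 <- seq_along(ord0) - 1L - segstart[d_sorted + 1L]
  out <- list(ord0 = ord0, d_sorted = d_sorted, ringsize = ringsize,
              cum = cum, segstart = segstart, rank0 = rank0,
              min_border_d = min_border_d)
  .emodraw_cache[[key]] <- out
  out
}

# spiral order with a per-drawing rotation of each ring (theta in [0,1))
spiral_order <- function(layout, theta) {
  shift <- floor(theta * layout$ringsize)
  len <- layout$ringsize[layout$d_sorted + 1L]
  newrank <- (layout$rank0 + shift[layout$d_sorted + 1L]) %% len
  layout$ord0[layout$segstart[layout$d_sorted + 1L] + newrank + 1L]
}

# ---- composition sampling ------------------------------------------------

#' Sample drawing ground truth from an emotion profile
#'
#' Color shares come from truncated normals at the calibrated latent
#' locations, clipped at zero and renormalized to 100; the prominent color
#' is drawn from the profile's multinomial and swapped into the maximal
#' share. Saturation, brightness, fill and coverage are truncated normals
#' clipped to the percent scale (fill is floored at 2% so a drawing is
#' never blank), with coverage >= fill enforced by resampling. Styles are
#' independent Bernoullis.
#'
#' @param profile A calibrated `emotion_profile` (uncalibrated profiles are
#'   calibrated on the fly; see [calibrate_profile()]).
#' @param n Number of drawings to sample.
#' @param fill_floor Minimal fill percentage.
#' @param antithetic Pair the underlying normal deviates (z, -z): the
#'   marginal distribution of every drawing is unchanged while cohort
#'   means concentrate much more tightly on the calibrated population
#'   values (standard Monte Carlo variance reduction).
#' @param stratify_prominent Assign prominent colors by balanced
#'   (largest-remainder) multinomial counts, randomly permuted, instead of
#'   independent draws; again identical marginals, exact cohort
#'   proportions.
#' @return Data frame with columns `emotion`, `share_<color>`, `prominent`,
#'   `saturation`, `brightness`, `fill`, `coverage` and the five style
#'   indicators. Draws from the current RNG stream.
#' @export
sample_composition <- function(profile, n = 1L, fill_floor = 2,
                               antithetic = TRUE,
                               stratify_prominent = TRUE) {
  profile <- calibrate_profile(profile, fill_floor = fill_floor)
  cstar <- if (stratify_prominent && n > 1L) {
    .stratified_categories(n, profile$prominent_probs)
  } else NULL
  shares <- .compose_shares(profile$share_loc, profile$share_scale,
                            profile$prominent_probs, n,
                            antithetic = antithetic, cstar = cstar)
  sl <- profile$scalar_loc
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  Z <- .z_antithetic(n, 4L, antithetic)
  sat <- clip(sl["saturation"] + profile$saturation[2L] * Z[, 1L], 0, 100)
  bri <- clip(sl["brightness"] + profile$brightness[2L] * Z[, 2L], 0, 100)
  fil <- clip(sl["fill"] + profile$fill[2L] * Z[, 3L], fill_floor, 100)
  cov <- clip(sl["coverage"] + profile$coverage[2L] * Z[, 4L], 0, 100)
  for (tries in 1:100) {
    bad <- which(cov < fil)
    if (!length(bad)) break
    fil[bad] <- clip(stats::rnorm(length(bad), sl["fill"],
                                  profile$fill[2L]), fill_floor, 100)
    cov[bad] <- clip(stats::rnorm(length(bad), sl["coverage"],
                                  profile$coverage[2L]), 0, 100)
  }
  cov <- pmax(cov, fil)
  out <- data.frame(emotion = rep(profile$emotion, n),
                    stringsAsFactors = FALSE)
  for (cc in expressive_colors()) {
    out[[paste0("share_", cc)]] <- shares[, cc]
  }
  out$prominent <- expressive_colors()[max.col(shares,
                                               ties.method = "first")]
  out$saturation <- sat
  out$brightness <- bri
  out$fill <- fil
  out$coverage <- cov
  for (cc in style_categories()) {
    out[[cc]] <- stats::rbinom(n, 1L, profile$style_probs[cc])
  }
  out
}

# ---- painting ------------------------------------------------------------

# classification-safe (s, v) boxes per color; chromatic colors need
# v >= 71 to escape the black range and gray must stay below the white
# value threshold
.sv_boxes <- function() {
  data.frame(
    color = c("red", "yellow", "green", "blue", "purple", "gray", "black"),
    s_lo = c(53, 46, 46, 53, 53, 0, 0),
    s_hi = c(255, 255, 255, 255, 255, 25, 255),
    v_lo = c(71, 71, 71, 71, 71, 71, 0),
    v_hi = c(255, 255, 255, 255, 255, 229, 70),
    stringsAsFactors = FALSE
  )
}

# choose per-color values in [lo, hi] whose count-weighted mean matches
# `target`; when the target lies outside the feasible band it is projected
# onto the nearest bound
waterfill <- function(n, lo, hi, target) {
  x <- pmin(pmax(target, lo), hi)
  projected <- FALSE
  for (it in 1:25) {
    resid <- target * sum(n) - sum(n * x)
    if (abs(resid) < 1e-9) break
    free <- if (resid > 0) x < hi - 1e-12 else x > lo + 1e-12
    if (!any(free)) { projected <- TRUE; break }
    x[free] <- x[free] + resid / sum(n[free])
    x <- pmin(pmax(x, lo), hi)
  }
  attr(x, "projected") <- projected
  x
}

# achieved S of a pixel with max channel v and chroma d, evaluated through
# the package's own converter so renderer and extractor agree exactly
.s_achieved <- function(v, d) .hexcone_hsv(v, v - d, v - d)$s

# chroma bounds that keep the achieved S inside [s_lo, s_hi]
.d_bounds <- function(v, s_lo, s_hi) {
  if (v == 0L) return(c(0L, 0L))
  d_lo <- max(0L, as.integer(ceiling((s_lo - 0.5) * v / 255)))
  while (.s_achieved(v, d_lo) < s_lo && d_lo < v) d_lo <- d_lo + 1L
  d_hi <- min(v, as.integer(floor((s_hi + 0.5) * v / 255)))
  while (d_hi > 0L && .s_achieved(v, d_hi) > s_hi) d_hi <- d_hi - 1L
  c(d_lo, max(d_lo, d_hi))
}

# RGB rows for `m` pixels of one color at value v, chroma d
.hue_rgb <- function(color, v, d, m_px) {
  m <- v - d
  row <- switch(color,
    red    = c(v, m + round(d / 6), m),
    yellow = c(v, m + round(0.8 * d), m),
    green  = c(m, v, m),
    blue   = c(m, m, v),
    purple = c(m + round(d / 2), m, v),
    gray   = c(v, m, m),
    black  = c(v, m, m))
  matrix(rep(as.integer(row), each = m_px), m_px, 3L)
}

# paint `count` pixels of `color` targeting mean S = sbar, mean V = vbar
# (0-255 scale); returns RGB rows plus the exact achieved channel sums
.paint_block <- function(color, count, sbar, vbar, box) {
  v0 <- max(box$v_lo, min(box$v_hi, floor(vbar)))
  n_hi <- 0L
  if (v0 + 1L <= box$v_hi) {
    n_hi <- max(0L, min(count, as.integer(round((vbar - v0) * count))))
  }
  groups <- rbind(c(v0, count - n_hi), c(v0 + 1L, n_hi))
  rgb <- matrix(integer(0), 0L, 3L)
  sumS <- 0; sumV <- 0
  for (g in seq_len(nrow(groups))) {
    v <- groups[g, 1L]; m <- groups[g, 2L]
    if (m == 0L) next
    db <- .d_bounds(v, box$s_lo, box$s_hi)
    if (v == 0L) {
      rgb <- rbind(rgb, matrix(0L, m, 3L))
      next
    }
    # bracket the target with the two nearest achievable S levels
    d0 <- max(db[1L], min(db[2L], floor(sbar * v / 255)))
    while (d0 > db[1L] && .s_achieved(v, d0) > sbar) d0 <- d0 - 1L
    d1 <- d0
    while (d1 < db[2L] && .s_achieved(v, d1) < sbar) d1 <- d1 + 1L
    S0 <- .s_achieved(v, d0); S1 <- .s_achieved(v, d1)
    if (S1 > S0) {
      k <- max(0L, min(m, as.integer(round(m * (sbar - S0) / (S1 - S0)))))
    } else k <- 0L
    if (m - k > 0L) {
      rgb <- rbind(rgb, .hue_rgb(color, v, d0, m - k))
      sumS <- sumS + (m - k) * S0
    }
    if (k > 0L) {
      rgb <- rbind(rgb, .hue_rgb(color, v, d1, k))
      sumS <- sumS + k * S1
    }
    sumV <- sumV + m * v
  }
  list(rgb = rgb, sumS = sumS, sumV = sumV)
}

# ---- rendering -----------------------------------------------------------

#' Render one synthetic drawing
#'
#' Paints an annular blob whose hole-filled extent matches the ground-truth
#' coverage and whose drawn area matches the fill, partitions drawn pixels
#' among colors by the sampled shares, and picks per-color saturation/value
#' levels so the drawn-pixel means hit the sampled targets. Count-based
#' metrics (shares, fill, coverage) are pixel-exact; saturation/brightness
#' targets incompatible with the color mix (e.g. high brightness with a
#' large black share) are projected onto the feasible set and flagged.
#'
#' @param gt One row of [sample_composition()] output (or an equivalent
#'   list with shares, fill, coverage, saturation, brightness).
#' @param canvas `c(width, height)`, at least 64 x 64.
#' @param palette A `color_palette` (used only for color naming order).
#' @param theta Ring-rotation parameter in [0, 1); drawn from the current
#'   RNG stream by default.
#' @param source_id Identifier stored on the image.
#' @return List with `image` (a `raster_image`) and `achieved`, the
#'   pixel-exact ground-truth feature row (same columns as
#'   [extract_features()], plus `sv_projected` and `fill_adjusted` flags).
#' @export
render_drawing <- function(gt, canvas = c(256L, 256L),
                           palette = default_palette(),
                           theta = stats::runif(1L), source_id = "synthetic") {
  w <- as.integer(canvas[1L]); h <- as.integer(canvas[2L])
  if (w < 64L || h < 64L) stop("canvas must be at least 64 x 64")
  total <- w * h
  C <- max(1L, round(gt$coverage / 100 * total))
  F_ <- max(1L, round(gt$fill / 100 * total))
  if (F_ > C) F_ <- C
  layout <- spiral_layout(w, h)
  ord <- spiral_order(layout, theta %% 1)
  H <- C - F_
  fill_adjusted <- FALSE
  if (H > 0L) {
    # a hole ending in ring r is sealed iff ring r+1 is fully drawn and no
    # border cell lies inside it (border flood-fill cannot cross a full
    # Chebyshev ring, and must not start inside the hole)
    sealed <- function(r) {
      r + 1L <= layout$min_border_d &&
        r + 2L <= length(layout$cum) &&
        layout$cum[r + 2L] <= C
    }
    r_H <- layout$d_sorted[H]
    if (!sealed(r_H)) {
      rs <- 0:(length(layout$cum) - 2L)
      ok <- rs[vapply(rs, sealed, logical(1))]
      H <- if (length(ok)) min(H, layout$cum[max(ok) + 1L]) else 0L
      fill_adjusted <- TRUE
      F_ <- C - H
    }
  }
  drawn_idx <- ord[(H + 1L):C]

  cols <- expressive_colors()
  shares <- vapply(cols, function(cc) gt[[paste0("share_", cc)]], numeric(1))
  q <- shares * F_ / 100
  counts <- floor(q)
  rem <- F_ - sum(counts)
  if (rem > 0L) {
    add <- order(-(q - counts))[seq_len(rem)]
    counts[add] <- counts[add] + 1L
  }
  counts <- as.integer(counts)
  names(counts) <- cols

  boxes <- .sv_boxes()
  present <- counts > 0L
  Ts <- gt$saturation / 100 * 255
  Tv <- gt$brightness / 100 * 255
  bsub <- boxes[match(cols[present], boxes$color), ]
  vbar <- waterfill(counts[present], bsub$v_lo, bsub$v_hi, Tv)
  sbar <- waterfill(counts[present], bsub$s_lo, bsub$s_hi, Ts)
  sv_projected <- isTRUE(attr(vbar, "projected")) ||
    isTRUE(attr(sbar, "projected"))

  img <- array(255L, c(h, w, 3L))
  pos <- 0L
  sumS <- 0; sumV <- 0
  pidx <- seq_len(sum(present))
  if (length(pidx) > 1L) pidx <- sample(pidx)
  for (ci in pidx) {
    cc <- cols[present][ci]
    m <- counts[present][ci]
    blk <- .paint_block(cc, m, sbar[ci], vbar[ci],
                        boxes[boxes$color == cc, ])
    cells <- drawn_idx[(pos + 1L):(pos + m)]
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[cells] <- blk$rgb[, ch]
      img[, , ch] <- plane
    }
    sumS <- sumS + blk$sumS
    sumV <- sumV + blk$sumV
    pos <- pos + m
  }

  achieved_pct <- 100 * counts / F_
  achieved <- data.frame(
    source_id = source_id,
    prominent_color = cols[which.max(achieved_pct)],
    stringsAsFactors = FALSE
  )
  for (cc in cols) achieved[[paste0("pct_", cc)]] <- unname(achieved_pct[cc])
  achieved$n_colors <- sum(achieved_pct > 1.0)
  achieved$saturation_pct <- sumS / F_ / 255 * 100
  achieved$brightness_pct <- sumV / F_ / 255 * 100
  achieved$color_fill_pct <- 100 * F_ / total
  achieved$image_coverage_pct <- 100 * C / total
  achieved$unclassified_pct <- 0
  achieved$sv_projected <- sv_projected
  achieved$fill_adjusted <- fill_adjusted

  list(image = raster_image(img, source_id = source_id),
       achieved = achieved)
}

# ---- cohorts -------------------------------------------------------------

#' Generate a synthetic drawing cohort
#'
#' `n_per_emotion` participants, each contributing one drawing per emotion
#' profile (the study layout). Fully reproducible from `seed`. When `dir`
#' is given, drawings are written as `p<participant>_<emotion>.png`
#' together with `features_ground_truth.csv` (pixel-exact achieved
#' features), `style_labels.csv`, `targets.csv` (the sampled ground truth)
#' and a `manifest.csv` recording seed, canvas and cohort size.
#'
#' @param profiles Named list of `emotion_profile`s.
#' @param n_per_emotion Participants per emotion.
#' @param seed Integer seed.
#' @param dir Output directory (created if missing); `NULL` keeps
#'   everything in memory.
#' @param canvas Canvas dimensions.
#' @param palette A `color_palette`.
#' @param keep_images Return the `raster_image`s (memory-heavy for large
#'   cohorts); defaults to `TRUE` only when no `dir` is given.
#' @return List with `features` (achieved ground truth incl. `emotion`),
#'   `targets` (sampled ground truth), `styles`, `images` (or `NULL`),
#'   `dir`, `seed`.
#' @export
generate_cohort <- function(profiles = default_emotion_profiles(),
                            n_per_emotion = 10L, seed = 1L, dir = NULL,
                            canvas = c(256L, 256L),
                            palette = default_palette(),
                            keep_images = is.null(dir)) {
  stopifnot(n_per_emotion >= 1L)
  profiles <- lapply(profiles, calibrate_profile)
  if (!is.null(dir) && !dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }
  set.seed(seed)
  # per-emotion batches so the sampler can stratify and pair deviates
  gt_all <- lapply(profiles, sample_composition, n = n_per_emotion)
  feats <- list(); targs <- list(); stys <- list(); imgs <- list()
  k <- 0L
  for (i in seq_len(n_per_emotion)) {
    for (nm in names(profiles)) {
      k <- k + 1L
      pr <- profiles[[nm]]
      sid <- sprintf("p%03d_%s", i, pr$emotion)
      gt <- gt_all[[nm]][i, , drop = FALSE]
      rd <- render_drawing(gt, canvas = canvas, palette = palette,
                           source_id = sid)
      if (!is.null(dir)) {
        save_image(rd$image, file.path(dir, paste0(sid, ".png")))
      }
      if (keep_images) imgs[[sid]] <- rd$image
      f <- rd$achieved
      f$emotion <- pr$emotion
      feats[[k]] <- f
      gt$source_id <- sid
      targs[[k]] <- gt
      stys[[k]] <- data.frame(source_id = sid,
                              gt[style_categories()],
                              stringsAsFactors = FALSE)
    }
  }
  features <- do.call(rbind, feats)
  targets <- do.call(rbind, targs)
  styles <- do.call(rbind, stys)
  if (!is.null(dir)) {
    utils::write.csv(features, file.path(dir, "features_ground_truth.csv"),
                     row.names = FALSE)
    utils::write.csv(styles, file.path(dir, "style_labels.csv"),
                     row.names = FALSE)
    utils::write.csv(targets, file.path(dir, "targets.csv"),
                     row.names = FALSE)
    manifest <- data.frame(
      key = c("seed", "n_per_emotion", "canvas_w", "canvas_h", "emotions"),
      value = c(seed, n_per_emotion, canvas[1L], canvas[2L],
                paste(names(profiles), collapse = ";")))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  invisible(list(features = features, targets = targets, styles = styles,
                 images = if (keep_images) imgs else NULL,
                 dir = dir, seed = seed))
}
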