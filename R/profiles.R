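# Per-emotion generative profiles: target moments for the color
# composition, scalar metrics and style prevalences, plus the multinomial
# over prominent colors. Composition shares are drawn from truncated
# normals and renormalized to 100; because clipping at zero and
# renormalizing bias the raw means, the latent locations are calibrated by
# stochastic fixed-point iteration so that the *population* means of the
# generated shares match the target moments.

#' Construct an emotion profile
#'
#' @param emotion Emotion name.
#' @param color_mean,color_sd Named numeric vectors over
#'   [expressive_colors()]: target mean and SD of each color's percentage
#'   share (means must total 100).
#' @param prominent_probs Named probability vector over the colors: the
#'   multinomial from which each drawing's prominent color is drawn.
#' @param saturation,brightness,fill,coverage Length-2 vectors
#'   `c(mean, sd)` on the percent scale.
#' @param style_probs Named Bernoulli rates for the five depiction styles.
#' @return An `emotion_profile` list.
#' @export
emotion_profile <- function(emotion, color_mean, color_sd, prominent_probs,
                            saturation, brightness, fill, coverage,
                            style_probs) {
  cols <- expressive_colors()
  color_mean <- color_mean[cols]; color_sd <- color_sd[cols]
  prominent_probs <- prominent_probs[cols]
  stopifnot(!anyNA(color_mean), !anyNA(color_sd), !anyNA(prominent_probs),
            all(color_sd >= 0), all(prominent_probs >= 0),
            abs(sum(prominent_probs) - 1) < 1e-6)
  if (all(color_mean == 0)) stop("degenerate profile: all-zero color mix")
  for (v in list(saturation, brightness, fill, coverage)) {
    stopifnot(length(v) == 2L, v[2L] >= 0)
  }
  stopifnot(all(style_probs >= 0 & style_probs <= 1),
            setequal(names(style_probs), style_categories()))
  structure(list(
    emotion = emotion,
    color_mean = color_mean, color_sd = color_sd,
    prominent_probs = prominent_probs,
    saturation = saturation, brightness = brightness,
    fill = fill, coverage = coverage,
    style_probs = style_probs[style_categories()],
    share_loc = NULL,             # filled by calibrate_profile()
    share_scale = NULL,
    scalar_loc = NULL
  ), class = "emotion_profile")
}

#' Default emotion profiles
#'
#' The four study conditions: per-emotion color-share means and SDs,
#' saturation/brightness/fill/coverage moments, prominent-color
#' multinomials (modal probabilities with the remaining mass spread
#' proportionally to the color-share means) and style prevalences.
#'
#' @return Named list of four `emotion_profile`s
#'   (anger, happiness, sadness, fear).
#' @export
default_emotion_profiles <- function() {
  cols <- expressive_colors()
  mk <- function(emotion, mean, sd, modal_color, modal_p, sat, bri, fil,
                 cov, sty) {
    names(mean) <- cols; names(sd) <- cols
    pp <- numeric(7); names(pp) <- cols
    rest <- setdiff(cols, modal_color)
    pp[modal_color] <- modal_p
    pp[rest] <- (1 - modal_p) * mean[rest] / sum(mean[rest])
    names(sty) <- style_categories()
    emotion_profile(emotion, mean, sd, pp, sat, bri, fil, cov, sty)
  }
  list(
    anger = mk("anger",
      mean = c(72.27, 5.10, 0.58, 4.21, 1.59, 4.64, 11.61),
      sd   = c(35.72, 15.97, 5.65, 17.92, 10.85, 17.37, 26.51),
      modal_color = "red", modal_p = 0.7311,
      sat = c(65.62, 21.46), bri = c(60.34, 17.46),
      fil = c(30.73, 18.45), cov = c(87.17, 11.22),
      sty = c(0.4945, 0.0824, 0.4780, 0.0275, 0.2143)),
    happiness = mk("happiness",
      mean = c(21.92, 49.90, 7.65, 6.29, 1.81, 3.34, 9.09),
      sd   = c(34.77, 44.21, 20.92, 20.89, 9.60, 15.69, 25.01),
      modal_color = "yellow", modal_p = 0.478,
      sat = c(68.52, 21.24), bri = c(75.44, 14.93),
      fil = c(25.14, 15.30), cov = c(87.23, 9.35),
      sty = c(0.4780, 0.1264, 0.4615, 0.0714, 0.1648)),
    sadness = mk("sadness",
      mean = c(3.26, 4.44, 3.34, 51.66, 3.80, 17.85, 15.65),
      sd   = c(14.86, 17.00, 15.58, 44.32, 16.70, 34.34, 30.58),
      modal_color = "blue", modal_p = 0.512,
      sat = c(63.94, 25.18), bri = c(59.47, 18.21),
      fil = c(26.77, 19.28), cov = c(85.38, 10.47),
      sty = c(0.4780, 0.1374, 0.3077, 0.1154, 0.2198)),
    fear = mk("fear",
      mean = c(8.14, 4.20, 6.76, 10.49, 10.06, 26.43, 33.92),
      sd   = c(22.44, 15.72, 22.55, 26.89, 27.64, 39.90, 42.98),
      modal_color = "black", modal_p = 0.407,
      sat = c(47.33, 32.46), bri = c(48.78, 23.02),
      fil = c(35.49, 23.47), cov = c(85.25, 12.67),
      sty = c(0.4176, 0.2253, 0.2418, 0.1429, 0.2857))
  )
}

# antithetic standard-normal deviates: pairs (z, -z), identical marginals,
# strongly negatively correlated sample means
.z_antithetic <- function(n, k, antithetic) {
  if (!antithetic || n < 2L) {
    return(matrix(stats::rnorm(n * k), n, k))
  }
  half <- ceiling(n / 2)
  Z <- matrix(stats::rnorm(half * k), half, k)
  rbind(Z, -Z)[seq_len(n), , drop = FALSE]
}

# one generator pass for calibration / sampling of composition shares:
# truncated normals clipped at 0, renormalized to 100, conditioned (by
# rejection) on the drawn prominent color being the maximal share. Rows
# whose natural maximum still disagrees after `max_rounds` redraws fall
# back to swapping the prominent share with the maximum, so the prominent
# color is always the sampled one. `cstar` allows stratified prominent
# assignment; `antithetic` pairs the underlying normal deviates.
.compose_shares <- function(loc, sd, prom, n, antithetic = FALSE,
                            cstar = NULL, max_rounds = 12L) {
  K <- length(loc)
  draw_base <- function(m, anti) {
    Z <- .z_antithetic(m, K, anti)
    X <- sweep(sweep(Z, 2L, sd, `*`), 2L, loc, `+`)
    X[X < 0] <- 0
    s <- rowSums(X)
    for (tries in 1:100) {
      bad <- which(s == 0)
      if (!length(bad)) break
      X[bad, ] <- matrix(
        pmax(stats::rnorm(length(bad) * K, rep(loc, each = length(bad)),
                          rep(sd, each = length(bad))), 0),
        length(bad), K)
      s <- rowSums(X)
    }
    if (any(s == 0)) stop("degenerate profile: shares persistently all-zero")
    X / s * 100
  }
  X <- draw_base(n, antithetic)
  if (is.null(cstar)) {
    cstar <- sample.int(K, n, replace = TRUE, prob = prom)
  }
  active <- which(max.col(X, ties.method = "first") != cstar)
  if (any(sd > 0)) {
    # pool-based rejection: draw bulk proposals, bucket them by natural
    # maximum, and hand them out to rows still waiting for that category
    for (round in seq_len(max_rounds)) {
      if (!length(active)) break
      pool <- draw_base(max(n, 512L), FALSE)
      pmax_c <- max.col(pool, ties.method = "first")
      for (c in unique(cstar[active])) {
        want <- active[cstar[active] == c]
        have <- which(pmax_c == c)
        take <- min(length(want), length(have))
        if (take > 0L) {
          X[want[seq_len(take)], ] <- pool[have[seq_len(take)], ,
                                           drop = FALSE]
          active <- setdiff(active, want[seq_len(take)])
        }
      }
    }
  }
  if (length(active)) {   # fallback for (near-)unattainable prominents
    imax <- max.col(X[active, , drop = FALSE], ties.method = "first")
    i <- cbind(active, cstar[active]); j <- cbind(active, imax)
    tmp <- X[i]; X[i] <- X[j]; X[j] <- tmp
  }
  colnames(X) <- names(loc)
  X
}

# balanced multinomial assignment: category counts by largest remainder of
# n * prob, randomly permuted; marginally each draw follows `prob`
.stratified_categories <- function(n, prob) {
  K <- length(prob)
  q <- n * prob / sum(prob)
  counts <- floor(q)
  rem <- n - sum(counts)
  if (rem > 0L) {
    add <- order(-(q - counts))[seq_len(rem)]
    counts[add] <- counts[add] + 1L
  }
  v <- rep.int(seq_len(K), counts)
  if (length(v) > 1L) v <- sample(v)
  v
}

.emodraw_cache <- new.env(parent = emptyenv())

#' Calibrate a profile's latent locations
#'
#' Fixed-point iteration with common random numbers. First the latent
#' share locations: simulate `n_sim` composition draws from the full
#' generative map (truncate at zero, renormalize to 100, prominent swap),
#' compare population means of the resulting shares to the target color
#' means, and shift the latent normal locations by the discrepancy; the
#' latent scales stay at the target SDs. Then the latent
#' saturation/brightness/fill/coverage locations: the renderer projects
#' each drawing's saturation and brightness onto the feasible band implied
#' by its color mix (black pixels cannot be bright, gray pixels cannot be
#' saturated), so the calibration replicates that clamp on the simulated
#' compositions and shifts the locations until the *post-projection*
#' population means match the targets. The target moments themselves are
#' untouched; only the latent `share_loc` / `share_scale` / `scalar_loc`
#' are set. Results are cached per profile and the caller's RNG state is
#' preserved.
#'
#' @param profile An `emotion_profile`.
#' @param n_sim Monte Carlo size per iteration.
#' @param max_iter,tol Iteration controls (tol in percentage points).
#' @param fill_floor Minimal fill percentage (as in
#'   [sample_composition()]).
#' @return The profile with `share_loc`, `share_scale` and `scalar_loc`
#'   filled.
#' @export
calibrate_profile <- function(profile, n_sim = 20000L, max_iter = 200L,
                              tol = 0.05, fill_floor = 2) {
  stopifnot(inherits(profile, "emotion_profile"))
  if (!is.null(profile$share_loc) && !is.null(profile$scalar_loc)) {
    return(profile)
  }
  key <- paste(c(profile$emotion, profile$color_mean, profile$color_sd,
                 profile$prominent_probs, profile$saturation,
                 profile$brightness, profile$fill, profile$coverage,
                 n_sim, max_iter, tol, fill_floor),
               collapse = "|")
  hit <- .emodraw_cache[[key]]
  if (!is.null(hit)) {
    profile$share_loc <- hit$share_loc
    profile$share_scale <- hit$share_scale
    profile$scalar_loc <- hit$scalar_loc
    return(profile)
  }
  target <- profile$color_mean
  prom <- profile$prominent_probs
  loc <- target
  scl <- profile$color_sd
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  best <- Inf; best_loc <- loc; stall <- 0L
  for (it in seq_len(max_iter)) {
    set.seed(190823L)   # common random numbers: deterministic fixed point
    mu <- colMeans(.compose_shares(loc, scl, prom, n_sim))
    err <- target - mu
    e <- max(abs(err))
    if (e < best - 1e-3) {
      best <- e; best_loc <- loc; stall <- 0L
    } else {
      stall <- stall + 1L
    }
    if (e < tol || stall >= 15L) break
    loc <- loc + err
  }
  loc <- best_loc

  # scalar metrics: simulate one composition batch, derive each drawing's
  # feasible saturation/brightness band from its mix, and calibrate the
  # latent normal locations against the clamped means
  set.seed(190824L)
  W <- .compose_shares(loc, scl, prom, n_sim) / 100
  boxes <- .sv_boxes()
  b <- boxes[match(colnames(W), boxes$color), ]
  s_lo <- as.vector(W %*% b$s_lo) / 255 * 100
  s_hi <- as.vector(W %*% b$s_hi) / 255 * 100
  v_lo <- as.vector(W %*% b$v_lo) / 255 * 100
  v_hi <- as.vector(W %*% b$v_hi) / 255 * 100
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  cal_scalar <- function(tgt, sdv, lo, hi, seed) {
    lc <- tgt
    for (it in seq_len(max_iter)) {
      set.seed(seed)
      x <- clip(stats::rnorm(n_sim, lc, sdv), 0, 100)
      ach <- clip(x, lo, hi)
      err <- tgt - mean(ach)
      if (abs(err) < tol) break
      lc <- lc + err
    }
    lc
  }
  sat_loc <- cal_scalar(profile$saturation[1L], profile$saturation[2L],
                        s_lo, s_hi, 190825L)
  bri_loc <- cal_scalar(profile$brightness[1L], profile$brightness[2L],
                        v_lo, v_hi, 190826L)
  # fill/coverage: joint process with the coverage >= fill resampling
  fil_loc <- profile$fill[1L]; cov_loc <- profile$coverage[1L]
  for (it in seq_len(max_iter)) {
    set.seed(190827L)
    fs <- clip(stats::rnorm(n_sim, fil_loc, profile$fill[2L]),
               fill_floor, 100)
    cs <- clip(stats::rnorm(n_sim, cov_loc, profile$coverage[2L]), 0, 100)
    for (tries in 1:100) {
      bad <- which(cs < fs)
      if (!length(bad)) break
      fs[bad] <- clip(stats::rnorm(length(bad), fil_loc, profile$fill[2L]),
                      fill_floor, 100)
      cs[bad] <- clip(stats::rnorm(length(bad), cov_loc,
                                   profile$coverage[2L]), 0, 100)
    }
    cs <- pmax(cs, fs)
    ef <- profile$fill[1L] - mean(fs)
    ec <- profile$coverage[1L] - mean(cs)
    if (max(abs(ef), abs(ec)) < tol) break
    fil_loc <- fil_loc + ef
    cov_loc <- cov_loc + ec
  }
  scalar_loc <- c(saturation = sat_loc, brightness = bri_loc,
                  fill = fil_loc, coverage = cov_loc)
  .emodraw_cache[[key]] <- list(share_loc = loc, share_scale = scl,
                                scalar_loc = scalar_loc)
  profile$share_loc <- loc
  profile$share_scale <- scl
  profile$scalar_loc <- scalar_loc
  profile
}
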