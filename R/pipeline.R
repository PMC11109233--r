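# Pipeline orchestration: extract features from a directory of drawings,
# join style annotations, run the cross-emotion statistics and the
# classifier, and serialize a report bundle. Emotion labels come from the
# filename suffix (`<participant>_<emotion>.png`) or a manifest column,
# never from image content.

#' Extract features for a directory of drawings
#'
#' Runs [extract_features()] on every readable JPEG/PNG in `dir` (or on an
#' explicit vector of `paths`). Unreadable or blank images are collected in
#' a rejects table instead of aborting the run.
#'
#' @param dir Directory of drawings, or `NULL` when `paths` is given.
#' @param paths Explicit file paths (overrides `dir`).
#' @param palette A `color_palette`.
#' @param n_colors_min_share Threshold for [count_colors()].
#' @param emotion_from_filename Parse the emotion as the substring after
#'   the last underscore of the file name.
#' @return List with `features` (one row per readable drawing, with an
#'   `emotion` column when parsed) and `rejects` (path + reason).
#' @export
extract_cohort <- function(dir = NULL, paths = NULL,
                           palette = default_palette(),
                           n_colors_min_share = 1.0,
                           emotion_from_filename = TRUE) {
  if (is.null(paths)) {
    if (is.null(dir)) stop("give either dir or paths")
    paths <- sort(list.files(dir, pattern = "\\.(png|jpe?g)$",
                             ignore.case = TRUE, full.names = TRUE))
  }
  if (!length(paths)) stop("no readable images found")
  rows <- list(); rej <- list()
  for (p in paths) {
    f <- tryCatch({
      img <- load_image(p)
      extract_features(img, palette, n_colors_min_share)
    }, error = function(e) e)
    if (inherits(f, "error")) {
      rej[[length(rej) + 1L]] <- data.frame(
        path = p, reason = conditionMessage(f), stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- f
    }
  }
  features <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(features) && emotion_from_filename) {
    features$emotion <- sub(".*_", "", features$source_id)
  }
  rejects <- if (length(rej)) do.call(rbind, rej) else
    data.frame(path = character(0), reason = character(0))
  list(features = features, rejects = rejects)
}

#' Write a feature table as CSV
#'
#' @param features Feature data frame.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

.metric_columns <- function() {
  c(paste0("pct_", expressive_colors()), "n_colors", "saturation_pct",
    "brightness_pct", "color_fill_pct", "image_coverage_pct")
}

#' Cross-emotion analysis and emotion classification
#'
#' Reproduces the analysis stage on a feature table: per-emotion means and
#' SDs with one-way ANOVA F tests for every metric, the prominent-color
#' distribution with a chi-square test of independence, style prevalence
#' (when annotations are given), and the multinomial-logit emotion
#' classifier with its fit statistics and classification table. With
#' `bootstrap_B > 0`, percentile bootstrap intervals for the coefficients
#' are added.
#'
#' @param features Feature data frame with an `emotion` column.
#' @param styles Optional style-label data frame.
#' @param ref_emotion Reference outcome level of the classifier.
#' @param prominent_ref Reference level of the prominent-color dummies.
#' @param bootstrap_B Bootstrap resamples (0 = skip).
#' @param seed Seed for the bootstrap.
#' @return List with `composition` (Table-style mean/SD/F/p summary),
#'   `prominent` (percentages per emotion plus chi-square), `styles`
#'   (prevalence table or `NULL`), `model`, `classification`,
#'   `fit_stats`, `bootstrap` (or `NULL`), `seed`.
#' @export
analyze_features <- function(features, styles = NULL,
                             ref_emotion = "happiness",
                             prominent_ref = "red",
                             bootstrap_B = 0L, seed = 1L) {
  stopifnot("emotion" %in% names(features))
  emos <- unique(features$emotion)

  # Table-3-style summary: mean (SD) per emotion + one-way ANOVA
  comp <- list()
  for (m in .metric_columns()) {
    groups <- split(features[[m]], features$emotion)[emos]
    an <- oneway_anova(groups)
    row <- data.frame(metric = m, stringsAsFactors = FALSE)
    for (e in emos) {
      row[[paste0(e, "_mean")]] <- mean(groups[[e]])
      row[[paste0(e, "_sd")]] <- stats::sd(groups[[e]])
    }
    row$F <- an$statistic
    row$p <- an$p.value
    comp[[m]] <- row
  }
  composition <- do.call(rbind, comp)
  rownames(composition) <- NULL

  # Figure-3-style prominent-color distribution + chi-square
  tab <- table(factor(features$emotion, levels = emos),
               factor(features$prominent_color,
                      levels = expressive_colors()))
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  chi <- chisq_independence(tab)
  prominent <- list(counts = tab,
                    percent = 100 * prop.table(tab, margin = 1L),
                    chisq = chi)

  style_prev <- NULL
  if (!is.null(styles)) {
    style_prev <- style_prevalence(
      styles, features[, c("source_id", "emotion")])
  }

  dm <- build_design_matrix(features, styles, prominent_ref = prominent_ref)
  ref <- if (ref_emotion %in% levels(dm$y)) ref_emotion else levels(dm$y)[1L]
  model <- tryCatch(fit_multinomial_logit(dm$X, dm$y, ref = ref),
                    error = function(e) {
                      warning("emotion classifier unavailable: ",
                              conditionMessage(e), call. = FALSE)
                      NULL
                    })
  ct <- NULL
  fit_stats <- NULL
  boot <- NULL
  if (!is.null(model)) {
    ct <- classification_table(model, dm$X, dm$y)
    fit_stats <- list(
      log_likelihood = model$log_likelihood,
      null_log_likelihood = model$null_log_likelihood,
      lr_chi2 = model$lr_chi2,
      df = model$df,
      p = stats::pchisq(model$lr_chi2, model$df, lower.tail = FALSE),
      nagelkerke_r2 = model$nagelkerke_r2,
      overall_pct_correct = ct$overall_pct,
      converged = model$converged,
      n = model$n)
    if (bootstrap_B > 0L) {
      boot <- bootstrap_fit(dm$X, dm$y, B = bootstrap_B, seed = seed,
                            ref = ref)
    }
  }
  list(composition = composition, prominent = prominent,
       styles = style_prev, model = model, classification = ct,
       fit_stats = fit_stats, bootstrap = boot, seed = seed)
}

#' Serialize an analysis bundle
#'
#' Writes the composition summary, prominent-color distribution, style
#' prevalence, model coefficients and classification table as CSV, and the
#' fit statistics (plus the run seed) as JSON.
#'
#' @param bundle Output of [analyze_features()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of written paths.
#' @export
save_report <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  wr <- function(x, name) {
    p <- file.path(dir, name)
    utils::write.csv(x, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(bundle$composition, "composition_summary.csv")
  pm <- as.data.frame.matrix(bundle$prominent$percent)
  pm <- cbind(emotion = rownames(pm), pm)
  wr(pm, "prominent_colors.csv")
  if (!is.null(bundle$styles)) wr(bundle$styles, "style_prevalence.csv")
  if (!is.null(bundle$model$coefficients)) {
    co <- as.data.frame(bundle$model$coefficients)
    co <- cbind(outcome = rownames(co), co)
    wr(co, "model_coefficients.csv")
  }
  if (!is.null(bundle$classification)) {
    ct <- as.data.frame.matrix(bundle$classification$table)
    ct <- cbind(observed = rownames(ct), ct,
                percent_correct = bundle$classification$per_class_pct)
    wr(ct, "classification_table.csv")
  }
  if (!is.null(bundle$bootstrap)) {
    bi <- as.data.frame(bundle$bootstrap$intervals)
    bi <- cbind(coefficient = rownames(bi), bi,
                estimate = bundle$bootstrap$estimate)
    wr(bi, "bootstrap_intervals.csv")
  }
  p <- file.path(dir, "fit_stats.json")
  jsonlite::write_json(c(bundle$fit_stats, list(seed = bundle$seed)),
                       p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  invisible(paths)
}
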