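# Human-coded depiction-style labels (facial, body, symbolic, narrative,
# abstract) and inter-rater agreement. Styles are rater judgments, never
# computed from pixels.

style_categories <- function() {
  c("facial", "body", "symbolic", "narrative", "abstract")
}

#' Read depiction-style annotations
#'
#' Reads a CSV with header `source_id,facial,body,symbolic,narrative,
#' abstract`; the five indicator cells must be 0 or 1 (tangible styles may
#' co-occur; `abstract` marks ambiguous expressions).
#'
#' @param path CSV file path.
#' @return Data frame of validated labels (possibly 0 rows).
#' @export
read_style_annotations <- function(path) {
  labs <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("source_id", style_categories())
  if (!all(req %in% names(labs))) {
    stop("annotation CSV must have columns: ", paste(req, collapse = ", "))
  }
  labs <- labs[, req, drop = FALSE]
  for (cc in style_categories()) {
    x <- labs[[cc]]
    if (nrow(labs) > 0L &&
        (!is.numeric(x) || any(is.na(x)) || any(!x %in% c(0, 1)))) {
      stop("column '", cc, "' must contain only 0/1 indicators")
    }
    labs[[cc]] <- as.integer(x)
  }
  labs
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement between two categorical rating vectors. When
#' expected agreement is 1 (both raters constant on the same category) kappa
#' is undefined and `NA` is returned with `degenerate = TRUE`.
#'
#' @param r1,r2 Rating vectors of equal length (factors or characters).
#' @return List with `kappa`, `percent_agreement`, `p_expected`,
#'   `degenerate`.
#' @export
cohen_kappa <- function(r1, r2) {
  stopifnot(length(r1) == length(r2), length(r1) >= 2L)
  lev <- sort(unique(c(as.character(r1), as.character(r2))))
  t1 <- factor(as.character(r1), levels = lev)
  t2 <- factor(as.character(r2), levels = lev)
  tab <- table(t1, t2)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < 1e-12) {
    return(list(kappa = NA_real_, percent_agreement = 100 * po,
                p_expected = pe, degenerate = TRUE))
  }
  list(kappa = (po - pe) / (1 - pe), percent_agreement = 100 * po,
       p_expected = pe, degenerate = FALSE)
}

#' Fleiss' kappa for three or more raters
#'
#' @param ratings Matrix or data frame, rows = items, columns = raters,
#'   cells = categorical codes.
#' @return List with `kappa`, `per_category` kappa, `percent_agreement`
#'   (mean proportion of agreeing rater pairs per item, in percent) and
#'   `degenerate`.
#' @export
fleiss_kappa <- function(ratings) {
  ratings <- as.matrix(ratings)
  stopifnot(nrow(ratings) >= 2L, ncol(ratings) >= 2L)
  m <- ncol(ratings)
  lev <- sort(unique(as.character(ratings)))
  counts <- vapply(lev, function(l) rowSums(ratings == l),
                   numeric(nrow(ratings)))
  counts <- matrix(counts, nrow = nrow(ratings))
  colnames(counts) <- lev
  pj <- colSums(counts) / (nrow(counts) * m)
  pi_i <- (rowSums(counts^2) - m) / (m * (m - 1))
  pbar <- mean(pi_i)
  pe <- sum(pj^2)
  if (abs(1 - pe) < 1e-12) {
    return(list(kappa = NA_real_, per_category = setNames(
      rep(NA_real_, length(lev)), lev),
      percent_agreement = 100 * pbar, degenerate = TRUE))
  }
  # category-wise kappa (Fleiss 1971)
  qj <- 1 - pj
  kj <- vapply(seq_along(lev), function(j) {
    num <- sum(counts[, j]^2) - nrow(counts) * m * pj[j] *
      (1 + (m - 1) * pj[j])
    den <- nrow(counts) * m * (m - 1) * pj[j] * qj[j]
    if (den == 0) NA_real_ else num / den
  }, numeric(1))
  names(kj) <- lev
  list(kappa = (pbar - pe) / (1 - pe), per_category = kj,
       percent_agreement = 100 * pbar, degenerate = FALSE)
}

#' Inter-rater agreement for a rating table
#'
#' For two raters, Cohen's kappa (overall plus one-vs-rest per category);
#' for three or more, Fleiss' kappa. Raw percent agreement is reported
#' alongside and never conflated with kappa.
#'
#' @param table Data frame or matrix, rows = drawings, columns = raters.
#' @return List with `method`, `overall` kappa, `per_category`,
#'   `percent_agreement`, `degenerate`.
#' @export
inter_rater_kappa <- function(table) {
  tab <- as.matrix(table)
  if (ncol(tab) < 2L) stop("need at least two raters")
  if (nrow(tab) < 2L) stop("need at least two rated items")
  if (ncol(tab) == 2L) {
    ov <- cohen_kappa(tab[, 1L], tab[, 2L])
    lev <- sort(unique(as.character(tab)))
    per <- vapply(lev, function(l) {
      cohen_kappa(tab[, 1L] == l, tab[, 2L] == l)$kappa
    }, numeric(1))
    names(per) <- lev
    list(method = "cohen", overall = ov$kappa, per_category = per,
         percent_agreement = ov$percent_agreement,
         degenerate = ov$degenerate)
  } else {
    fl <- fleiss_kappa(tab)
    list(method = "fleiss", overall = fl$kappa,
         per_category = fl$per_category,
         percent_agreement = fl$percent_agreement,
         degenerate = fl$degenerate)
  }
}

#' Depiction-style prevalence by emotion
#'
#' Percentage of drawings carrying each style indicator, per emotion.
#'
#' @param labels Data frame of style labels (see
#'   [read_style_annotations()]).
#' @param emotions Data frame with columns `source_id`, `emotion`.
#' @return Data frame: rows = style categories, one column of percentages
#'   per emotion, plus an `n` attribute with per-emotion counts. Unknown
#'   `source_id`s are dropped with a warning.
#' @export
style_prevalence <- function(labels, emotions) {
  stopifnot(all(c("source_id", "emotion") %in% names(emotions)))
  idx <- match(labels$source_id, emotions$source_id)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " annotation row(s) with unknown source_id ",
            "dropped")
    labels <- labels[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  emo <- emotions$emotion[idx]
  levs <- unique(emotions$emotion)
  out <- data.frame(style = style_categories(), stringsAsFactors = FALSE)
  ns <- integer(0)
  for (e in levs) {
    sel <- emo == e
    n <- sum(sel)
    ns[e] <- n
    out[[e]] <- vapply(style_categories(), function(cc) {
      if (n == 0L) 0 else 100 * sum(labels[[cc]][sel]) / n
    }, numeric(1))
  }
  attr(out, "n") <- ns
  out
}
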