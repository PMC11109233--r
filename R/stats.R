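# Cross-emotion comparisons and the multinomial-logit emotion classifier:
# Pearson chi-square, one-way ANOVA, Newton-Raphson maximum likelihood with
# step-halving, Nagelkerke pseudo R-squared, case-resampling bootstrap and
# the observed-by-predicted classification table.

#' Pearson chi-square test of independence
#'
#' @param tab An r x c matrix of counts.
#' @return List with `statistic`, `df`, `p.value`, `expected`.
#' @export
chisq_independence <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero marginal total: drop empty rows/columns first")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = unname(ht$p.value), expected = ht$expected)
}

#' One-way analysis of variance
#'
#' Between/within mean-square F ratio across groups. With zero within-group
#' variance and equal means the statistic is 0 by convention.
#'
#' @param groups List of numeric vectors, one per group (each of length
#'   at least 2).
#' @return List with `statistic`, `df1`, `df2`, `p.value`.
#' @export
oneway_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stop("each group needs at least 2 observations")
  }
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  n <- length(y); k <- nlevels(g)
  gm <- tapply(y, g, mean)
  ssb <- sum(tapply(y, g, length) * (gm - mean(y))^2)
  ssw <- sum((y - gm[g])^2)
  df1 <- k - 1L; df2 <- n - k
  if (ssw == 0) {
    f <- if (ssb == 0) 0 else Inf
  } else {
    f <- (ssb / df1) / (ssw / df2)
  }
  list(statistic = f, df1 = df1, df2 = df2,
       p.value = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Build the emotion-classification design matrix
#'
#' Predictors follow the published model: dummy indicators for the
#' prominent-color categorical (reference level dropped; dummy coding is
#' what removes the exact collinearity of compositional percentages summing
#' to 100), saturation, brightness, number of colors, color fill, image
#' coverage, and the five style indicators when available. Constant columns
#' (e.g. dummies of colors never prominent) are dropped.
#'
#' @param features Feature data frame (see [extract_features()]) with an
#'   `emotion` column.
#' @param styles Optional data frame of style labels joined by `source_id`.
#' @param prominent_ref Reference level of the prominent-color factor.
#' @return List with `X` (numeric predictor matrix, no intercept), `y`
#'   (factor outcome) and `source_id`.
#' @export
build_design_matrix <- function(features, styles = NULL,
                                prominent_ref = "red") {
  stopifnot("emotion" %in% names(features))
  cols <- expressive_colors()
  lev <- c(prominent_ref, setdiff(cols, prominent_ref))
  pc <- factor(features$prominent_color, levels = lev)
  dm <- stats::model.matrix(~pc)[, -1L, drop = FALSE]
  colnames(dm) <- sub("^pc", "prominent_", colnames(dm))
  X <- cbind(dm,
             saturation_pct = features$saturation_pct,
             brightness_pct = features$brightness_pct,
             n_colors = features$n_colors,
             color_fill_pct = features$color_fill_pct,
             image_coverage_pct = features$image_coverage_pct)
  if (!is.null(styles)) {
    idx <- match(features$source_id, styles$source_id)
    if (anyNA(idx)) {
      warning(sum(is.na(idx)), " drawing(s) without style labels; ",
              "style indicators filled with 0")
    }
    for (cc in style_categories()) {
      v <- styles[[cc]][idx]
      v[is.na(v)] <- 0L
      X <- cbind(X, v)
      colnames(X)[ncol(X)] <- paste0("style_", cc)
    }
  }
  keep <- apply(X, 2L, function(col) stats::var(col) > 0)
  X <- X[, keep, drop = FALSE]
  list(X = X, y = factor(features$emotion), source_id = features$source_id)
}

#' Fit a multinomial logistic regression by Newton-Raphson
#'
#' Maximizes the multinomial log-likelihood with a softmax link by full
#' Newton steps with step-halving (the log-likelihood never decreases
#' across iterations). Coefficients are log-odds of each outcome level
#' against the reference level. Convergence is declared when the largest
#' score component falls below `tol_score` or the relative log-likelihood
#' change falls below `tol_ll`. Coefficients diverging beyond `coef_bound`
#' flag (quasi-)separation and the fit is marked non-converged.
#'
#' @param X Numeric predictor matrix (no intercept column; one is added).
#' @param y Factor outcome with at least two levels, all present.
#' @param ref Reference level; default `"happiness"` when present,
#'   otherwise the first factor level.
#' @param max_iter,tol_score,tol_ll,coef_bound Newton controls.
#' @return An `emotion_model`: list with `coefficients` ((K-1) x (p+1)
#'   matrix), `log_likelihood`, `null_log_likelihood`, `lr_chi2`, `df`,
#'   `nagelkerke_r2`, `fitted` (n x K probability matrix), `vcov`,
#'   `converged`, `separation`, `n_iter`, `ll_trace`, `levels`, `ref`, `n`.
#' @export
fit_multinomial_logit <- function(X, y, ref = NULL, max_iter = 100L,
                                  tol_score = 1e-8, tol_ll = 1e-10,
                                  coef_bound = 30) {
  X <- as.matrix(X)
  y <- droplevels(factor(y))
  K <- nlevels(y)
  if (K < 2L) stop("outcome must have at least two observed levels")
  if (is.null(ref)) {
    ref <- if ("happiness" %in% levels(y)) "happiness" else levels(y)[1L]
  }
  if (!ref %in% levels(y)) stop("reference level '", ref, "' not in outcome")
  y <- stats::relevel(y, ref = ref)
  n <- length(y)
  Xi <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xi)
  if (n <= p) stop("need more observations than parameters")
  Ymat <- outer(as.integer(y), seq_len(K), `==`) * 1   # n x K indicators

  npar <- (K - 1L) * p
  beta <- matrix(0, K - 1L, p,
                 dimnames = list(levels(y)[-1L], colnames(Xi)))
  probs_of <- function(b) {
    eta <- cbind(0, Xi %*% t(b))        # ref column fixed at 0
    eta <- eta - apply(eta, 1L, max)
    ex <- exp(eta)
    ex / rowSums(ex)
  }
  ll_of <- function(P) sum(log(pmax(P[Ymat == 1], 1e-300)))

  P <- probs_of(beta)
  ll <- ll_of(P)
  ll_trace <- ll
  converged <- FALSE
  separation <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    R <- Ymat[, -1L, drop = FALSE] - P[, -1L, drop = FALSE]
    score <- as.vector(crossprod(Xi, R))   # p x (K-1), stacked by class
    if (max(abs(score)) < tol_score) { converged <- TRUE; break }
    H <- matrix(0, npar, npar)
    for (j in seq_len(K - 1L)) {
      for (k in j:(K - 1L)) {
        wjk <- P[, j + 1L] * ((j == k) - P[, k + 1L])
        blk <- crossprod(Xi, Xi * wjk)
        rj <- (j - 1L) * p + seq_len(p)
        rk <- (k - 1L) * p + seq_len(p)
        H[rj, rk] <- blk
        if (j != k) H[rk, rj] <- t(blk)
      }
    }
    step <- tryCatch(solve(H, score), error = function(e) {
      solve(H + diag(1e-8, npar), score)
    })
    # step-halving: never accept a decrease of the log-likelihood
    lambda <- 1
    repeat {
      cand <- beta + matrix(lambda * step, K - 1L, p, byrow = TRUE)
      Pc <- probs_of(cand)
      llc <- ll_of(Pc)
      if (llc >= ll - 1e-12 || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    beta <- cand; P <- Pc
    dl <- llc - ll
    ll <- llc
    ll_trace <- c(ll_trace, ll)
    if (max(abs(beta)) > coef_bound) { separation <- TRUE; break }
    if (abs(dl) < tol_ll * (abs(ll) + 1)) { converged <- TRUE; break }
  }
  if (it == max_iter && !converged) converged <- FALSE

  if (separation) {
    warning("(quasi-)separation detected: coefficients did not stabilize; ",
            "standard errors withheld", call. = FALSE)
  }
  # null model: intercept-only, closed form at class proportions
  pk <- colMeans(Ymat)
  ll0 <- sum(colSums(Ymat) * log(pk))
  vc <- NULL
  if (!separation) {
    H <- matrix(0, npar, npar)
    for (j in seq_len(K - 1L)) {
      for (k in j:(K - 1L)) {
        wjk <- P[, j + 1L] * ((j == k) - P[, k + 1L])
        blk <- crossprod(Xi, Xi * wjk)
        rj <- (j - 1L) * p + seq_len(p)
        rk <- (k - 1L) * p + seq_len(p)
        H[rj, rk] <- blk
        if (j != k) H[rk, rj] <- t(blk)
      }
    }
    vc <- tryCatch(solve(H), error = function(e) NULL)
  }
  structure(list(
    coefficients = beta,
    log_likelihood = ll,
    null_log_likelihood = ll0,
    lr_chi2 = 2 * (ll - ll0),
    df = (K - 1L) * (p - 1L),
    nagelkerke_r2 = nagelkerke_r2(max(ll, ll0), ll0, n),
    fitted = P,
    vcov = vc,
    converged = converged && !separation,
    separation = separation,
    n_iter = it,
    ll_trace = ll_trace,
    levels = levels(y),
    ref = ref,
    n = n,
    xnames = colnames(Xi)
  ), class = "emotion_model")
}

#' Predict from a fitted emotion model
#'
#' @param object An `emotion_model`.
#' @param newdata Predictor matrix with the columns used at fit time
#'   (no intercept).
#' @param type `"probs"` for the n x K probability matrix (rows sum to 1)
#'   or `"class"` for the argmax class.
#' @param ... Unused.
#' @export
predict.emotion_model <- function(object, newdata, type = c("probs", "class"),
                                  ...) {
  type <- match.arg(type)
  Xi <- cbind(1, as.matrix(newdata))
  eta <- cbind(0, Xi %*% t(object$coefficients))
  eta <- eta - apply(eta, 1L, max)
  ex <- exp(eta)
  P <- ex / rowSums(ex)
  colnames(P) <- object$levels
  if (type == "probs") return(P)
  factor(object$levels[max.col(P, ties.method = "first")],
         levels = object$levels)
}

#' Nagelkerke pseudo R-squared
#'
#' `[1 - exp(2 (L0 - L1) / n)] / [1 - exp(2 L0 / n)]`, the Cox-Snell index
#' rescaled to attain 1 at a saturated fit.
#'
#' @param ll Full-model log-likelihood.
#' @param ll0 Null (intercept-only) log-likelihood.
#' @param n Number of observations.
#' @return Value in [0, 1].
#' @export
nagelkerke_r2 <- function(ll, ll0, n) {
  if (ll < ll0 - 1e-8) {
    stop("full-model log-likelihood below null: impossible for nested MLE")
  }
  cs <- 1 - exp(2 * (ll0 - ll) / n)
  mx <- 1 - exp(2 * ll0 / n)
  if (mx == 0) return(0)
  min(max(cs / mx, 0), 1)
}

#' Bootstrap confidence intervals for model coefficients
#'
#' Case-resampling bootstrap: rows are resampled with replacement, the
#' model is refitted, and 2.5/97.5 percentile intervals are formed per
#' coefficient. Non-convergent resamples are counted and excluded.
#'
#' @param X,y,ref As in [fit_multinomial_logit()].
#' @param B Number of resamples (the published analysis used 5000).
#' @param seed Integer seed; identical seeds give identical intervals.
#' @return List with `intervals` (matrix: coefficient x c(lower, upper)),
#'   `estimate`, `B`, `n_nonconverged`, `seed`.
#' @export
bootstrap_fit <- function(X, y, B = 1000L, seed = 1L, ref = NULL) {
  stopifnot(B >= 1L)
  X <- as.matrix(X)
  y <- factor(y)
  fit0 <- fit_multinomial_logit(X, y, ref = ref)
  est <- as.vector(t(fit0$coefficients))
  nm <- as.vector(t(outer(rownames(fit0$coefficients), fit0$xnames,
                          paste, sep = ":")))
  names(est) <- nm
  set.seed(seed)
  n <- length(y)
  keep <- matrix(NA_real_, B, length(est))
  bad <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    fb <- tryCatch(
      fit_multinomial_logit(X[idx, , drop = FALSE], y[idx], ref = fit0$ref),
      error = function(e) NULL)
    if (is.null(fb) || !fb$converged ||
        !identical(dim(fb$coefficients), dim(fit0$coefficients))) {
      bad <- bad + 1L
    } else {
      keep[b, ] <- as.vector(t(fb$coefficients))
    }
  }
  ok <- stats::complete.cases(keep)
  ints <- t(apply(keep[ok, , drop = FALSE], 2L, stats::quantile,
                  probs = c(0.025, 0.975), names = FALSE))
  dimnames(ints) <- list(nm, c("lower", "upper"))
  list(intervals = ints, estimate = est, B = B,
       n_nonconverged = bad, seed = seed)
}

#' Observed-by-predicted classification table
#'
#' In-sample (apparent) accuracy: the fitted model predicts the argmax
#' class on its own data, matching the convention of standard multinomial
#' regression software output.
#'
#' @param model An `emotion_model`.
#' @param X Predictor matrix used at fit time.
#' @param y Observed outcome factor.
#' @return List with `table` (observed x predicted counts), `per_class_pct`
#'   correct, `overall_pct` correct.
#' @export
classification_table <- function(model, X, y) {
  pred <- predict(model, X, type = "class")
  y <- factor(y, levels = model$levels)
  tab <- table(observed = y, predicted = pred)
  per <- ifelse(rowSums(tab) > 0, 100 * diag(tab) / rowSums(tab), NA_real_)
  list(table = tab,
       per_class_pct = per,
       overall_pct = 100 * sum(diag(tab)) / sum(tab))
}
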