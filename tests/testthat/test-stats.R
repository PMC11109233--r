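# simulate from a known multinomial-logit model; beta is (K-1) x (1+p)
# (intercept first)
simulate_mlogit <- function(n, beta, levels, seed) {
  set.seed(seed)
  p <- ncol(beta) - 1L
  X <- matrix(stats::rnorm(n * p), n, p)
  colnames(X) <- paste0("x", seq_len(p))
  eta <- cbind(0, cbind(1, X) %*% t(beta))
  P <- exp(eta) / rowSums(exp(eta))
  y <- factor(levels[apply(P, 1L, function(p) sample.int(length(p), 1L,
                                                         prob = p))],
              levels = levels)
  list(X = X, y = y)
}

test_that("chi-square independence matches hand computations", {
  r <- chisq_independence(matrix(c(10, 10, 10, 10), 2L))
  expect_equal(r$statistic, 0)
  expect_equal(r$df, 1L)

  r2 <- chisq_independence(matrix(c(20, 5, 5, 20), 2L))
  expect_equal(r2$statistic, 18)   # expected all 12.5

  set.seed(2)
  tab <- matrix(rpois(16, 30) + diag(4L) * 50, 4L)
  r3 <- chisq_independence(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(r3$statistic, sum((tab - E)^2 / E))
  expect_equal(r3$df, 9L)

  expect_error(chisq_independence(matrix(c(0, 0, 3, 4), 2L,
                                         byrow = TRUE)),
               "zero marginal")
})

test_that("one-way ANOVA matches the squared-t identity and base R", {
  expect_equal(oneway_anova(list(c(1, 2, 3), c(1, 2, 3)))$statistic, 0)

  set.seed(4)
  g1 <- rnorm(20L, 0); g2 <- rnorm(25L, 0.8)
  an <- oneway_anova(list(g1, g2))
  tt <- stats::t.test(g1, g2, var.equal = TRUE)
  expect_equal(an$statistic, unname(tt$statistic)^2)
  expect_equal(an$p.value, tt$p.value)

  g3 <- rnorm(15L, 0.3)
  an3 <- oneway_anova(list(g1, g2, g3))
  ref <- stats::oneway.test(y ~ g, data.frame(
    y = c(g1, g2, g3),
    g = rep(letters[1:3], c(20L, 25L, 15L))), var.equal = TRUE)
  expect_equal(an3$statistic, unname(ref$statistic))
  expect_equal(an3$p.value, ref$p.value)
})

test_that("binary logit slope equals the 2x2 log odds-ratio", {
  # contingency counts: x=0 -> 30/10, x=1 -> 12/28 (yes/no)
  x <- c(rep(0, 40L), rep(1, 40L))
  y <- factor(c(rep("yes", 30L), rep("no", 10L),
                rep("yes", 12L), rep("no", 28L)), levels = c("no", "yes"))
  fit <- fit_multinomial_logit(cbind(x = x), y, ref = "no")
  lor <- log((12 * 10) / (28 * 30))
  expect_equal(unname(fit$coefficients["yes", "x"]), lor,
               tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("null-data fits collapse to zero slopes and zero LR", {
  set.seed(10)
  X <- cbind(a = rnorm(400L), b = rnorm(400L))
  y <- factor(sample(c("anger", "happiness", "sadness", "fear"), 400L,
                     replace = TRUE))
  fit <- fit_multinomial_logit(X, y)
  expect_lt(max(abs(fit$coefficients[, c("a", "b")])), 0.35)
  expect_lt(fit$lr_chi2, qchisq(0.999, fit$df))
  expect_lt(fit$nagelkerke_r2, 0.05)
})

test_that("fitted probabilities are proper and the likelihood ascends", {
  set.seed(11)
  beta <- rbind(c(0.3, 1.2, -0.5), c(-0.2, -0.8, 0.9))
  sim <- simulate_mlogit(500L, beta, c("a", "b", "c"), seed = 11)
  fit <- fit_multinomial_logit(sim$X, sim$y, ref = "a")
  expect_equal(unname(rowSums(fit$fitted)), rep(1, 500L),
               tolerance = 1e-12)
  expect_true(all(diff(fit$ll_trace) >= -1e-9))
  expect_true(fit$converged)
})

test_that("the fitter agrees with nnet::multinom", {
  skip_if_not_installed("nnet")
  set.seed(12)
  beta <- rbind(c(0.5, 1.0, -0.7), c(-0.4, 0.3, 0.8))
  sim <- simulate_mlogit(600L, beta, c("a", "b", "c"), seed = 12)
  fit <- fit_multinomial_logit(sim$X, sim$y, ref = "a")
  nn <- nnet::multinom(y ~ x1 + x2,
                       data = data.frame(y = sim$y, sim$X),
                       trace = FALSE, reltol = 1e-14)
  expect_equal(unname(fit$coefficients), unname(coef(nn)),
               tolerance = 1e-4)
  expect_equal(fit$log_likelihood, -nn$value, tolerance = 1e-6)
})

test_that("known-model coefficients are recovered within 3 SEs", {
  beta <- rbind(c(0.4, 0.9, -0.6), c(-0.3, -0.5, 0.7),
                c(0.1, 0.2, 0.4))
  sim <- simulate_mlogit(2000L, beta, c("a", "b", "c", "d"), seed = 77)
  fit <- fit_multinomial_logit(sim$X, sim$y, ref = "a")
  se <- sqrt(diag(fit$vcov))
  est <- as.vector(t(fit$coefficients))
  truth <- as.vector(t(beta))
  expect_true(all(abs(est - truth) <= 3 * se))
})

test_that("Nagelkerke R2 spans its bounds and recomputes from parts", {
  expect_equal(nagelkerke_r2(-100, -100, 50L), 0)
  expect_equal(nagelkerke_r2(0, -80, 100L), 1)
  expect_error(nagelkerke_r2(-120, -100, 50L), "below null")
  ll <- -70.5; ll0 <- -130.2; n <- 200L
  expect_equal(nagelkerke_r2(ll, ll0, n),
               (1 - exp(2 * (ll0 - ll) / n)) / (1 - exp(2 * ll0 / n)))
})

test_that("classification table counts match an enumerated fixture", {
  # 8 rows, separable in x: the fitted model predicts by sign of x
  X <- cbind(x = c(-2, -1.5, -1, -0.5, 0.5, 1, 1.5, 2))
  y <- factor(c("a", "a", "a", "b", "a", "b", "b", "b"),
              levels = c("a", "b"))
  fit <- fit_multinomial_logit(X, y, ref = "a", coef_bound = 1e6)
  ct <- classification_table(fit, X, y)
  pred <- predict(fit, X, type = "class")
  expect_equal(as.vector(ct$table),
               as.vector(table(y, pred)))
  expect_equal(ct$overall_pct, 100 * mean(pred == y))
  expect_equal(unname(rowSums(ct$table)), unname(table(y)),
               ignore_attr = TRUE)

  # chance level on balanced null data
  set.seed(14)
  Xn <- cbind(z = rnorm(800L))
  yn <- factor(rep(c("a", "b", "c", "d"), each = 200L))
  fitn <- fit_multinomial_logit(Xn, yn, ref = "a")
  ctn <- classification_table(fitn, Xn, yn)
  expect_lt(abs(ctn$overall_pct - 25), 10)
})

test_that("well-separated clusters give near-perfect apparent accuracy", {
  set.seed(15)
  n <- 150L
  X <- rbind(cbind(rnorm(n, -6), rnorm(n, 0)),
             cbind(rnorm(n, 6), rnorm(n, 0)),
             cbind(rnorm(n, 0), rnorm(n, 6)))
  colnames(X) <- c("x1", "x2")
  y <- factor(rep(c("a", "b", "c"), each = n))
  fit <- fit_multinomial_logit(X, y, ref = "a", coef_bound = 1e6)
  ct <- classification_table(fit, X, y)
  expect_gt(ct$overall_pct, 95)
})

test_that("bootstrap intervals are seeded and degenerate at B=1", {
  set.seed(16)
  beta <- rbind(c(0.2, 1.5), c(-0.4, -1.0))
  sim <- simulate_mlogit(300L, beta[, 1:2, drop = FALSE],
                         c("a", "b", "c"), seed = 16)
  X <- sim$X[, 1L, drop = FALSE]
  b1 <- bootstrap_fit(X, sim$y, B = 30L, seed = 5L, ref = "a")
  b2 <- bootstrap_fit(X, sim$y, B = 30L, seed = 5L, ref = "a")
  expect_identical(b1$intervals, b2$intervals)
  b3 <- bootstrap_fit(X, sim$y, B = 30L, seed = 6L, ref = "a")
  expect_false(identical(b1$intervals, b3$intervals))
})

test_that("bootstrap intervals for a strong effect exclude zero", {
  beta <- rbind(c(0.0, 2.0), c(0.0, -2.0))
  sim <- simulate_mlogit(400L, beta, c("a", "b", "c"), seed = 18)
  X <- sim$X[, 1L, drop = FALSE]
  bt <- bootstrap_fit(X, sim$y, B = 200L, seed = 7L, ref = "a")
  ints <- bt$intervals
  expect_gt(ints["b:x1", "lower"], 0)
  expect_lt(ints["c:x1", "upper"], 0)
})

test_that("design matrix dummy-codes prominence and drops constants", {
  feats <- data.frame(
    source_id = sprintf("p%02d_x", 1:8),
    emotion = rep(c("anger", "happiness"), 4L),
    prominent_color = c("red", "yellow", "red", "blue",
                        "red", "yellow", "blue", "red"),
    saturation_pct = runif(8, 40, 90),
    brightness_pct = runif(8, 40, 90),
    n_colors = sample(1:3, 8L, TRUE),
    color_fill_pct = runif(8, 10, 50),
    image_coverage_pct = runif(8, 60, 95))
  dm <- build_design_matrix(feats, prominent_ref = "red")
  expect_true(all(c("prominent_yellow", "prominent_blue") %in%
                  colnames(dm$X)))
  expect_false("prominent_red" %in% colnames(dm$X))
  expect_false("prominent_green" %in% colnames(dm$X))  # never prominent
  expect_false(any(apply(dm$X, 2L, stats::var) == 0))
})
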