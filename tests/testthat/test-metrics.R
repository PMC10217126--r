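# Metrics: confusion counts, rate identities, ROC/AUR/EER oracles.

test_that("confusion counts follow the >= threshold rule and preserve totals", {
  cc <- confusion_counts(c(0.9, 0.1), c(1, 0), 0.5)
  expect_equal(unclass(cc)[c("tp", "tn", "fp", "fn")],
               list(tp = 1L, tn = 1L, fp = 0L, fn = 0L), ignore_attr = TRUE)
  # all-suspicious predictor
  cc2 <- confusion_counts(rep(1, 10), rep(c(1, 0), 5), 0.5)
  expect_equal(cc2$fp, 5)
  expect_equal(cc2$fn, 0)
  # brute-force recount on random cases
  set.seed(1)
  for (i in 1:20) {
    s <- runif(50); y <- runif(50) > 0.5; th <- runif(1)
    cc3 <- confusion_counts(s, y, th)
    expect_equal(cc3$tp, sum(s >= th & y))
    expect_equal(cc3$tn, sum(s < th & !y))
    expect_equal(cc3$tp + cc3$tn + cc3$fp + cc3$fn, 50)
  }
  expect_error(confusion_counts(1:3 / 3, c(0, 1)), class = "mwtomo_bad_input")
})

test_that("rates equal their defining ratios and complement identities hold", {
  r <- classification_rates(structure(list(tp = 95, fn = 5, fp = 0, tn = 100),
                                      class = "mwt_confusion"))
  expect_equal(r$tpr, 0.95)
  expect_equal(r$fpr, 0)
  expect_equal(r$tnr, 1)
  set.seed(2)
  for (i in 1:25) {
    cc <- structure(as.list(setNames(sample(1:50, 4), c("tp", "tn", "fp", "fn"))),
                    class = "mwt_confusion")
    r <- classification_rates(cc)
    expect_identical(r$tpr + r$fnr, 1)
    expect_identical(r$fpr + r$tnr, 1)
  }
  expect_error(classification_rates(structure(list(tp = 0, fn = 0, fp = 1, tn = 1),
                                              class = "mwt_confusion")),
               class = "mwtomo_degenerate_class")
})

test_that("ROC endpoints, perfect separation, and degenerate input", {
  roc <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(roc$aur, 1)
  expect_equal(roc$eer, 0)
  expect_equal(roc$points$fpr[1], 0)
  expect_equal(roc$points$tpr[1], 0)
  expect_equal(utils::tail(roc$points$fpr, 1), 1)
  expect_equal(utils::tail(roc$points$tpr, 1), 1)
  expect_error(roc_curve(c(0.1, 0.9), c(1, 1)), class = "mwtomo_degenerate_class")
})

test_that("AUR equals the Mann-Whitney statistic and matches pROC", {
  skip_if_not_installed("pROC")
  set.seed(3)
  for (i in 1:10) {
    n1 <- sample(20:60, 1); n0 <- sample(20:60, 1)
    s <- c(rnorm(n1, 0.6, 0.3), rnorm(n0, 0.4, 0.3))
    s <- pmin(pmax(s, 0), 1)
    s <- round(s, 2)                       # force ties
    y <- c(rep(1, n1), rep(0, n0))
    roc <- roc_curve(s, y)
    u <- stats::wilcox.test(s[y == 1], s[y == 0], exact = FALSE)$statistic
    expect_equal(roc$aur, unname(u) / (n1 * n0), tolerance = 1e-12)
    expect_equal(roc$aur,
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
  }
})

test_that("labels independent of scores give chance-level AUR", {
  set.seed(4)
  s <- runif(10000)
  y <- runif(10000) > 0.5
  expect_lt(abs(roc_curve(s, y)$aur - 0.5), 0.02)
})

test_that("AUR is invariant under strictly monotone score transformations", {
  set.seed(5)
  s <- runif(300); y <- runif(300) > 0.4
  a0 <- roc_curve(s, y)$aur
  expect_equal(roc_curve(stats::qlogis(s * 0.98 + 0.01), y)$aur, a0)
  expect_equal(roc_curve(s^3, y)$aur, a0)
})

test_that("interpolated EER matches a direct bisection on the rates", {
  eer_bisect <- function(s, y) {
    f <- function(th) {
      cc <- confusion_counts(s, y, th)
      r <- classification_rates(cc)
      r$fpr - r$fnr
    }
    lo <- 0; hi <- 1
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (f(mid) >= 0) lo <- mid else hi <- mid
    }
    cc <- confusion_counts(s, y, lo)
    r <- classification_rates(cc)
    c(r$fpr, r$fnr)
  }
  set.seed(6)
  s <- c(stats::rbeta(400, 4, 2), stats::rbeta(400, 2, 4))
  y <- rep(c(1, 0), each = 400)
  roc <- roc_curve(s, y)
  rates <- eer_bisect(s, y)
  # the bisection brackets the crossing; the interpolated EER lies between
  expect_gte(roc$eer, min(rates) - 1e-6)
  expect_lte(roc$eer, max(rates) + 1e-6)
  expect_lt(abs(roc$eer - mean(rates)), 0.01)
})

test_that("threshold metrics compose confusion counts and rates", {
  set.seed(7)
  s <- runif(200); y <- runif(200) > 0.5
  tm <- threshold_metrics(s, y, 0.5)
  cc <- confusion_counts(s, y, 0.5)
  expect_equal(tm$accuracy, (cc$tp + cc$tn) / 200)
  r <- classification_rates(cc)
  expect_equal(tm$sensitivity, r$tpr)
  expect_equal(tm$specificity, r$tnr)
  # perfect scores
  expect_equal(threshold_metrics(y * 1, y, 0.5)$accuracy, 1)
  # all-suspicious on balanced labels
  tm2 <- threshold_metrics(rep(1, 100), rep(c(0, 1), 50), 0.5)
  expect_equal(tm2$accuracy, 0.5)
  expect_equal(tm2$sensitivity, 1)
  expect_equal(tm2$specificity, 0)
})

test_that("roc tidiers expose points and summary", {
  s <- c(0.9, 0.7, 0.3, 0.2); y <- c(1, 0, 1, 0)
  roc <- roc_curve(s, y)
  expect_named(tidy(roc), c("threshold", "fpr", "tpr"))
  expect_named(glance(roc), c("aur", "eer", "eer_threshold", "n_pos", "n_neg"))
})
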