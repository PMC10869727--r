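test_that("concordance index handles perfect ordering, ties and censoring", {
  d <- tibble::tibble(time_days = c(5, 10, 15, 20), event = rep(1L, 4),
                      score = c(4, 3, 2, 1))
  expect_equal(concordance_index(d), 1)
  expect_equal(concordance_index(d, score = -d$score), 0)
  expect_equal(concordance_index(d, score = rep(1, 4)), 0.5)
  expect_error(
    concordance_index(tibble::tibble(time_days = 1, event = 0L, score = 1)),
    "no comparable pairs"
  )
})

test_that("concordance matches the exhaustive pair oracle, with and without horizons", {
  set.seed(21)
  for (rep in 1:30) {
    d <- random_instance(10, tied = rep %% 2 == 0)
    if (sum(d$event) == 0) next
    expect_equal(concordance_index(d),
                 oracle_cindex(d$time_days, d$event, d$score))
    h <- stats::median(d$time_days)
    ci_h <- tryCatch(concordance_index(d, horizon_days = h),
                     error = function(e) NA_real_)
    or_h <- tryCatch(oracle_cindex(d$time_days, d$event, d$score, h),
                     error = function(e) NA_real_)
    if (is.finite(or_h)) expect_equal(ci_h, or_h)
  }
})

test_that("concordance is complementary under score negation", {
  set.seed(22)
  for (rep in 1:10) {
    d <- random_instance(15)
    if (sum(d$event) == 0) next
    expect_equal(
      concordance_index(d) + concordance_index(d, score = -d$score), 1
    )
  }
})

test_that("Kaplan-Meier reproduces hand-computed product limits", {
  plain <- tibble::tibble(time_days = 1:4, event = rep(1L, 4))
  km <- km_estimate(plain)
  expect_equal(km$survival, c(0.75, 0.5, 0.25, 0))
  # censoring between events: 3/4, then 3/4 * 1/2, then 0
  cens <- tibble::tibble(time_days = c(1, 2, 3, 4),
                         event = c(1L, 0L, 1L, 1L))
  km2 <- km_estimate(cens)
  expect_equal(km2$time, c(1, 3, 4))
  expect_equal(km2$survival, c(3 / 4, 3 / 8, 0))
  all_cens <- tibble::tibble(time_days = 1:5, event = rep(0L, 5))
  expect_equal(nrow(km_estimate(all_cens)), 0)
  expect_error(km_estimate(tibble::tibble(time_days = double(),
                                          event = integer())), "empty")
})

test_that("Kaplan-Meier equals one minus the empirical CDF without censoring", {
  set.seed(23)
  t <- sample(1:50, 30, replace = TRUE)
  d <- tibble::tibble(time_days = t, event = 1L)
  km <- km_estimate(d)
  ecdf_surv <- 1 - ecdf(t)(km$time)
  expect_equal(km$survival, ecdf_surv)
})

test_that("Kaplan-Meier agrees with the survival package under censoring", {
  skip_if_not_installed("survival")
  set.seed(24)
  d <- random_instance(80, tied = TRUE)
  km <- km_estimate(d)
  sf <- survival::survfit(survival::Surv(time_days, event) ~ 1, data = d)
  ref <- summary(sf, times = km$time)
  expect_equal(km$survival, ref$surv, tolerance = 1e-12)
})

test_that("log-rank statistic is null for exchangeable groups and needs 2+ groups", {
  d <- tibble::tibble(
    time_days = rep(c(2, 4, 6, 8), 2),
    event = rep(c(1L, 0L, 1L, 1L), 2),
    grp = rep(c("a", "b"), each = 4)
  )
  lr <- logrank_test(d, grp)
  expect_lt(lr$chi_square, 1e-10)
  expect_equal(lr$df, 1L)
  expect_gt(lr$p_value, 0.999)
  expect_error(logrank_test(dplyr::mutate(d, grp = "a"), grp), "two groups")
  expect_error(
    logrank_test(dplyr::mutate(d, event = 0L), grp),
    "at least one event"
  )
})

test_that("log-rank matches the survival package on 2- and 3-group problems", {
  skip_if_not_installed("survival")
  set.seed(25)
  for (k in 2:3) {
    n <- 30 * k
    grp <- rep(letters[1:k], each = 30)
    rate <- 0.05 * 3^(match(grp, letters) - 1)
    t <- rexp(n, rate)
    cens <- runif(n, 0, 40)
    d <- tibble::tibble(
      time_days = ceiling(pmax(pmin(t, cens), 0.5)),
      event = as.integer(t <= cens),
      grp = grp
    )
    lr <- logrank_test(d, grp)
    ref <- survival::survdiff(survival::Surv(time_days, event) ~ grp,
                              data = d)
    expect_equal(lr$chi_square, unname(ref$chisq), tolerance = 1e-6)
    expect_equal(lr$df, k - 1L)
  }
})

test_that("log-rank is invariant under group relabeling", {
  set.seed(26)
  d <- random_instance(60)
  d$grp <- sample(c("x", "y", "z"), 60, replace = TRUE)
  a <- logrank_test(d, grp)
  relabeled <- c(x = "z", y = "x", z = "y")[d$grp]
  b <- logrank_test(dplyr::mutate(d, grp = relabeled), grp)
  expect_equal(a$chi_square, b$chi_square, tolerance = 1e-10)
})

test_that("quantile stratification reproduces exact clinical stratum sizes", {
  set.seed(27)
  scores <- rnorm(388)
  d <- tibble::tibble(subject_id = as.character(1:388), score = scores)
  s <- stratify_by_quantiles(d, c(0.5, 0.75))
  expect_equal(unname(table(s$stratum)), c(194L, 97L, 97L),
               ignore_attr = TRUE)
  s2 <- stratify_by_quantiles(d, 0.5)
  expect_equal(unname(table(s2$stratum)), c(194L, 194L), ignore_attr = TRUE)
  four <- tibble::tibble(score = c(0.1, 0.4, 0.2, 0.9))
  s4 <- stratify_by_quantiles(four, 0.5)
  expect_equal(unname(table(s4$stratum)), c(2L, 2L), ignore_attr = TRUE)
  expect_error(
    stratify_by_quantiles(tibble::tibble(score = rep(1, 10)), 0.5),
    "degenerate score distribution"
  )
  tied <- stratify_by_quantiles(tibble::tibble(score = rep(1, 10)), 0.5,
                                tie_policy = "stable_order")
  expect_equal(unname(table(tied$stratum)), c(5L, 5L), ignore_attr = TRUE)
})

test_that("horizon labels implement both censoring policies", {
  d <- tibble::tibble(
    subject_id = c("event_early", "event_late", "censored_early",
                   "censored_late"),
    time_days = c(500, 1500, 500, 1500),
    event = c(1L, 1L, 0L, 0L)
  )
  default <- horizon_labels(d, 1000)
  expect_equal(default$label, c(1L, 0L, NA, 0L))
  expect_equal(default$included, c(TRUE, TRUE, FALSE, TRUE))
  lenient <- horizon_labels(d, 1000, policy = "censored_as_negative")
  expect_equal(lenient$label, c(1L, 0L, 0L, 0L))
  expect_true(all(lenient$included))
  expect_error(horizon_labels(d, -5), "positive")
})

test_that("ROC by threshold sweep matches the Mann-Whitney oracle", {
  sep <- tibble::tibble(label = c(1, 1, 0, 0), score = c(4, 3, 2, 1))
  expect_equal(roc_auc(roc_curve(sep)), 1)
  flat <- tibble::tibble(label = c(1, 0, 1, 0), score = rep(2, 4))
  expect_equal(roc_auc(roc_curve(flat)), 0.5)
  set.seed(28)
  for (rep in 1:20) {
    d <- tibble::tibble(label = rbinom(8, 1, 0.5),
                        score = sample(1:4, 8, replace = TRUE))
    if (length(unique(d$label)) < 2) next
    r <- roc_curve(d)
    expect_equal(roc_auc(r), oracle_auc(d$label, d$score))
    expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
    expect_equal(unlist(r[1, ]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(r[nrow(r), ]), c(fpr = 1, tpr = 1))
  }
  expect_error(roc_curve(tibble::tibble(label = c(1, 1), score = 1:2)),
               "both classes")
})

test_that("the stratified ROC has three segments and matches the ordinal-score ROC", {
  set.seed(29)
  for (rep in 1:20) {
    n <- 60
    stratum <- factor(sample(c("low", "intermediate", "high"), n, TRUE),
                      levels = c("low", "intermediate", "high"),
                      ordered = TRUE)
    p_event <- c(low = 0.1, intermediate = 0.3, high = 0.6)[as.character(stratum)]
    label <- rbinom(n, 1, p_event)
    if (length(unique(label)) < 2) next
    d <- tibble::tibble(stratum = stratum, label = label)
    sr <- stratified_roc(d)
    expect_equal(nrow(sr), 4)
    ord <- roc_curve(tibble::tibble(label = label,
                                    score = as.integer(stratum)))
    expect_equal(roc_auc(sr), roc_auc(ord), tolerance = 1e-12)
  }
})

test_that("stratified ROC vertex geometry is correct when only the high stratum has events", {
  stratum <- factor(rep(c("low", "intermediate", "high"), each = 10),
                    levels = c("low", "intermediate", "high"),
                    ordered = TRUE)
  label <- as.integer(stratum == "high" & seq_along(stratum) %% 2 == 0)
  d <- tibble::tibble(stratum = stratum, label = label)
  sr <- stratified_roc(d)
  n_neg <- sum(label == 0)
  expect_equal(sr$tpr[2], 1)                       # all events are in "high"
  expect_equal(sr$fpr[2], sum(stratum == "high" & label == 0) / n_neg)
  expect_error(
    stratified_roc(tibble::tibble(
      stratum = factor(rep(c("a", "b"), 5)), label = rep(c(0, 1), 5)
    )),
    "3 ordered strata"
  )
})

test_that("event-rate percentages use half-away-from-zero rounding", {
  d <- tibble::tibble(
    endpoint = c("non_fatal_mi", "mace", "total_cv", "none"),
    count = c(72, 119, 58, 0),
    size = c(1540, 1540, 388, 500)
  )
  out <- event_rate_summary(d)
  expect_equal(out$percentage, c(4.68, 7.73, 14.95, 0))
  expect_error(
    event_rate_summary(tibble::tibble(count = 5, size = 4)),
    "exceeds"
  )
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(-0.125, 2), -0.13)
})

test_that("estimators are permutation-equivariant in subject order", {
  set.seed(30)
  d <- random_instance(40)
  d$grp <- sample(c("a", "b"), 40, replace = TRUE)
  perm <- sample(40)
  dp <- d[perm, ]
  expect_equal(concordance_index(d), concordance_index(dp))
  expect_equal(km_estimate(d), km_estimate(dp[, c("time_days", "event")]),
               ignore_attr = TRUE)
  expect_equal(logrank_test(d, grp)$chi_square,
               logrank_test(dp, grp)$chi_square)
  expect_equal(partial_log_likelihood(d),
               partial_log_likelihood(dp, dp$score))
})
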