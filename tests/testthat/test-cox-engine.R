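test_that("partial log likelihood matches closed forms and the enumeration oracle", {
  # single subject with an event: log of its own exp cancels
  one <- tibble::tibble(time_days = 5, event = 1L, score = 2.3)
  expect_equal(partial_log_likelihood(one), 0)
  # symmetric two-subject risk set
  two <- tibble::tibble(time_days = c(1, 2), event = c(1L, 0L),
                        score = c(0, 0))
  expect_equal(partial_log_likelihood(two), -log(2))
  # three subjects, both event terms enumerated independently
  three <- tibble::tibble(time_days = c(1, 2, 3), event = c(1L, 1L, 0L),
                          score = c(1.0, 0.5, -0.5))
  expect_equal(
    partial_log_likelihood(three),
    oracle_pll(three$time_days, three$event, three$score),
    tolerance = 1e-12
  )
  # no events -> 0
  cens <- tibble::tibble(time_days = c(1, 2), event = c(0L, 0L),
                         score = c(1, -1))
  expect_equal(partial_log_likelihood(cens), 0)
  expect_error(partial_log_likelihood(two, c(1, NA)), "non-finite")
  expect_error(partial_log_likelihood(two, 1), "length mismatch")
})

test_that("partial likelihood agrees with enumeration on random tied and untied instances", {
  set.seed(11)
  for (rep in 1:50) {
    d <- random_instance(sample(2:20, 1), tied = rep %% 2 == 0)
    expect_equal(
      partial_log_likelihood(d),
      oracle_pll(d$time_days, d$event, d$score),
      tolerance = 1e-9
    )
  }
})

test_that("the likelihood is location-invariant and non-positive", {
  set.seed(12)
  for (rep in 1:20) {
    d <- random_instance(sample(3:15, 1), tied = rep %% 3 == 0)
    base <- partial_log_likelihood(d)
    shifted <- partial_log_likelihood(d, d$score + 37.5)
    expect_equal(base, shifted, tolerance = 1e-8)
    expect_lte(base, 1e-12)
  }
})

test_that("the score gradient matches symmetry, censoring and finite differences", {
  two <- tibble::tibble(time_days = c(1, 2), event = c(1L, 0L),
                        score = c(0, 0))
  expect_equal(partial_likelihood_gradient(two), c(0.5, -0.5))
  cens <- tibble::tibble(time_days = 1:4, event = rep(0L, 4),
                         score = rnorm(4))
  expect_equal(partial_likelihood_gradient(cens), rep(0, 4))
  set.seed(13)
  for (rep in 1:20) {
    d <- random_instance(12, tied = rep %% 2 == 0)
    g <- partial_likelihood_gradient(d)
    fd <- oracle_pll_gradient_fd(d, d$score)
    expect_equal(g, fd, tolerance = 1e-6)
  }
})

test_that("fit_cox returns zero effect for exchangeable groups", {
  d <- tibble::tibble(
    time_days = rep(c(1, 3, 5, 7), 2),
    event = rep(c(1L, 1L, 0L, 1L), 2),
    z = rep(c(0, 1), each = 4)
  )
  fit <- fit_cox(d, "z")
  expect_lt(abs(fit$coefficients), 1e-6)
  expect_true(fit$converged)
})

test_that("fit_cox matches a one-dimensional golden-section maximizer", {
  # note: six uncensored subjects with z = (1,1,1,0,0,0) and times 1..6 have
  # a monotone likelihood (the three earliest events all carry z = 1), so a
  # finite maximizer requires interleaving the groups
  d <- tibble::tibble(time_days = 1:6, event = rep(1L, 6),
                      z = c(1, 0, 1, 0, 1, 0))
  fit <- fit_cox(d, "z")
  zc <- d$z - mean(d$z)
  obj <- function(beta) partial_log_likelihood(d, zc * beta)
  gold <- stats::optimize(obj, c(-10, 10), maximum = TRUE)$maximum
  expect_equal(unname(fit$coefficients), gold, tolerance = 1e-4)
})

test_that("fit_cox agrees with the survival package to 1e-4 on random instances", {
  skip_if_not_installed("survival")
  set.seed(14)
  for (rep in 1:20) {
    n <- sample(30:80, 1)
    x <- rnorm(n)
    t <- rexp(n, 0.05 * exp(0.6 * x))
    cens <- runif(n, 0, 40)
    d <- tibble::tibble(
      time_days = pmax(pmin(t, cens), 1e-3),
      event = as.integer(t <= cens),
      x = (x - mean(x)) / sd(x)
    )
    if (sum(d$event) < 2) next
    if (rep %% 2 == 0) d$time_days <- ceiling(d$time_days)
    fit <- fit_cox(d, "x")
    ref <- survival::coxph(survival::Surv(time_days, event) ~ x, data = d,
                           ties = "breslow")
    expect_equal(unname(fit$coefficients), unname(coef(ref)),
                 tolerance = 1e-4)
    expect_equal(unname(fit$standard_errors),
                 unname(sqrt(diag(vcov(ref)))), tolerance = 1e-4)
  }
})

test_that("fit_cox also matches the reference on multivariate fits", {
  skip_if_not_installed("survival")
  set.seed(15)
  n <- 150
  X <- cbind(rnorm(n), rbinom(n, 1, 0.4), rnorm(n))
  t <- rexp(n, 0.05 * exp(X %*% c(0.5, -0.8, 0.2)))
  cens <- runif(n, 0, 40)
  d <- tibble::tibble(
    time_days = pmax(pmin(t, cens), 1e-3),
    event = as.integer(t <= cens),
    x1 = X[, 1], x2 = X[, 2], x3 = X[, 3]
  )
  fit <- fit_cox(d, c("x1", "x2", "x3"))
  ref <- survival::coxph(
    survival::Surv(time_days, event) ~ x1 + x2 + x3, data = d,
    ties = "breslow"
  )
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-4)
  expect_equal(unname(fit$wald_p),
               unname(summary(ref)$coefficients[, "Pr(>|z|)"]),
               tolerance = 1e-3)
})

test_that("cox_fit objects satisfy their invariants and tidy/glance contracts", {
  set.seed(16)
  d <- random_instance(60)
  names(d)[3] <- "x"
  fit <- fit_cox(d, "x")
  expect_true(all(fit$hazard_ratios > 0))
  expect_true(fit$ci95_low < fit$hazard_ratios &&
                fit$hazard_ratios < fit$ci95_high)
  expect_lte(fit$n_events, fit$n_subjects)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "hazard_ratio",
                     "conf.low", "conf.high", "p.value"))
  expect_equal(td$hazard_ratio, exp(td$estimate))
  gl <- glance(fit)
  expect_equal(gl$n_subjects, 60)
  expect_gte(gl$log_partial_likelihood, gl$log_partial_likelihood_null)
})

test_that("fit_cox errors on degenerate inputs", {
  d <- tibble::tibble(time_days = 1:5, event = rep(0L, 5), x = rnorm(5))
  expect_error(fit_cox(d, "x"), "no events")
  d2 <- tibble::tibble(time_days = 1:5, event = c(1L, 0L, 1L, 0L, 1L),
                       x = rnorm(5))
  d2$y <- d2$x
  expect_error(fit_cox(d2, c("x", "y")), "full rank")
})

test_that("subgroup forests restrict correctly and flag degenerate subgroups", {
  set.seed(17)
  n <- 120
  d <- tibble::tibble(
    time_days = rexp(n, 0.05),
    event = rbinom(n, 1, 0.5),
    score = rnorm(n),
    grp = rep("everyone", n)
  )
  forest <- subgroup_forest(d, grp, include_overall = FALSE)
  direct <- fit_cox(
    dplyr::mutate(d, z = (score - mean(score)) / sd(score)), "z"
  )
  expect_equal(forest$hr, unname(direct$hazard_ratios), tolerance = 1e-10)

  d$grp[1:30] <- "quiet"
  d$event[1:30] <- 0L
  forest2 <- subgroup_forest(d, grp, include_overall = TRUE)
  quiet <- forest2[forest2$subgroup == "quiet", ]
  expect_false(quiet$estimable)
  expect_true(is.na(quiet$hr))
  expect_equal(forest2$subgroup[1], "all")
})

test_that("injected subgroup effect sizes are recovered in the right order", {
  ordered_ok <- 0
  for (seed in 1:20) {
    set.seed(seed * 31)
    sim_group <- function(beta, n) {
      sev <- runif(n)
      t <- rexp(n, 4.1e-5 * exp(beta * sev))
      tibble::tibble(
        time_days = pmin(t, 1825),
        event = as.integer(t < 1825),
        score = sev
      )
    }
    d <- dplyr::bind_rows(
      dplyr::mutate(sim_group(0.5, 400), grp = "mild"),
      dplyr::mutate(sim_group(1.5, 400), grp = "severe")
    )
    forest <- subgroup_forest(d, grp, include_overall = FALSE)
    hr <- forest$hr[match(c("mild", "severe"), forest$subgroup)]
    if (all(forest$estimable) && hr[1] < hr[2]) ordered_ok <- ordered_ok + 1
  }
  expect_gte(ordered_ok, 18)
})
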