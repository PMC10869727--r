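# Cox partial-likelihood machinery, written from scratch.
#
# The log partial likelihood over a cohort (or a mini-batch) is
#   log L = sum_i delta_i [ f_i - log sum_{j in R(t_i)} exp(f_j) ],
# where R(t_i) = {j : t_j >= t_i} is the risk set at the i-th event time.
# Ties are handled in Breslow's form: tied events share one denominator,
# which is exactly what the sum above evaluates to when times coincide.

resolve_scores <- function(data, quo, n) {
  scores <- rlang::eval_tidy(quo, data)
  if (!is.numeric(scores)) abort("scores must be numeric")
  if (length(scores) != n) abort("length mismatch between scores and outcomes")
  if (any(!is.finite(scores))) abort("non-finite score")
  as.double(scores)
}

# Shared risk-set bookkeeping: subjects sorted by descending time with, for
# every position, the index of the last position sharing its time (so tied
# subjects enter the same risk set).
risk_set_order <- function(time) {
  ord <- order(time, decreasing = TRUE)
  ts <- time[ord]
  runs <- rle(ts)
  ends <- cumsum(runs$lengths)
  last_tied <- rep(ends, runs$lengths)
  first_tied <- rep(ends - runs$lengths + 1L, runs$lengths)
  list(ord = ord, ts = ts, last_tied = last_tied, first_tied = first_tied)
}

#' Cox log partial likelihood of a score vector
#'
#' Evaluates the Breslow-tie log partial likelihood of per-subject risk
#' scores against right-censored outcomes, with log-sum-exp stabilization
#' inside every risk-set denominator. A cohort with no events scores 0.
#'
#' @param data Tibble with columns `time_days` and `event`, one row per
#'   subject.
#' @param score Column of `data` (tidy-eval) or a numeric vector holding the
#'   per-subject scores f(x_i), aligned with `data` rows.
#' @return The log partial likelihood (a single double, <= 0 whenever every
#'   risk set is non-empty).
#' @examples
#' d <- tibble::tibble(time_days = c(1, 2), event = c(1, 0), score = c(0, 0))
#' partial_log_likelihood(d)  # -log(2)
#' @export
partial_log_likelihood <- function(data, score = score) {
  assert_outcomes(data)
  f <- resolve_scores(data, rlang::enquo(score), nrow(data))
  if (sum(data$event) == 0) return(0)
  rs <- risk_set_order(data$time_days)
  fs <- f[rs$ord]
  ev <- data$event[rs$ord] == 1
  m <- max(fs)
  cum <- cumsum(exp(fs - m))
  denom <- m + log(cum[rs$last_tied])
  sum(fs[ev] - denom[ev])
}

#' Gradient of the log partial likelihood in the scores
#'
#' Analytic derivative of [partial_log_likelihood()] with respect to each
#' subject's score:
#' `d logL / d f_k = delta_k - sum over events i with k in R(t_i) of
#' exp(f_k) / sum_{j in R(t_i)} exp(f_j)`.
#'
#' @inheritParams partial_log_likelihood
#' @return Numeric vector aligned with `data` rows; identically zero for an
#'   all-censored cohort.
#' @export
partial_likelihood_gradient <- function(data, score = score) {
  assert_outcomes(data)
  f <- resolve_scores(data, rlang::enquo(score), nrow(data))
  n <- nrow(data)
  if (sum(data$event) == 0) return(numeric(n))
  rs <- risk_set_order(data$time_days)
  fs <- f[rs$ord]
  ev <- data$event[rs$ord] == 1
  m <- max(fs)
  w <- exp(fs - m)
  S0 <- cumsum(w)[rs$last_tied]        # risk-set sums, one per subject slot
  # each event at (descending) position q contributes 1/S0(q); subject k is
  # in that event's risk set iff t_k >= t_q, i.e. for all events at or after
  # the start of k's tied block, so the multiplier is a suffix sum of 1/S0
  inv <- ifelse(ev, 1 / S0, 0)
  suffix_inv <- rev(cumsum(rev(inv)))
  g_sorted <- (ev * 1) - w * suffix_inv[rs$first_tied]
  g <- numeric(n)
  g[rs$ord] <- g_sorted
  g
}

#' Fit a Cox proportional-hazards model by Newton-Raphson
#'
#' Maximizes the Breslow-tie log partial likelihood over coefficient vectors
#' for the given covariate columns, using full Newton steps with step
#' halving. Standard errors come from the inverse observed information;
#' hazard ratios and their 95% confidence intervals use the normal quantile
#' 1.959964. Diverging coefficients (|beta| above `beta_bound`) are treated
#' as separation and flagged via `converged = FALSE`.
#'
#' @param data Tibble with `time_days`, `event` and the covariate columns.
#' @param covariates Character vector of covariate column names.
#' @param max_iter Maximum Newton iterations.
#' @param tol Convergence threshold on the score norm (max |U|).
#' @param ridge Optional ridge penalty added to the information (default 0,
#'   so oracle comparisons are exact); use a small value to rescue separated
#'   data sets.
#' @param beta_bound Divergence guard on max |beta|.
#' @return An object of class `cox_fit`; see [tidy.cox_fit()] and
#'   [glance.cox_fit()].
#' @export
fit_cox <- function(data, covariates, max_iter = 50, tol = 1e-9,
                    ridge = 0, beta_bound = 50) {
  assert_outcomes(data)
  assert_cols(data, covariates)
  X <- as.matrix(data[covariates])
  if (!is.numeric(X)) abort("covariates must be numeric")
  if (anyNA(X)) abort("covariates contain missing values")
  n <- nrow(X)
  p <- ncol(X)
  n_events <- sum(data$event)
  if (n_events < 1) abort("no events: the partial likelihood is constant")
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)

  rs <- risk_set_order(data$time_days)
  Xs <- Xc[rs$ord, , drop = FALSE]
  ev_pos <- which(data$event[rs$ord] == 1)

  loglik_at <- function(beta) {
    partial_log_likelihood(data, as.vector(Xc %*% beta)) -
      0.5 * ridge * sum(beta^2)
  }

  # pair index for the p x p flattening of S2 cumulative sums
  pair_a <- rep(seq_len(p), times = p)
  pair_b <- rep(seq_len(p), each = p)

  score_info <- function(beta) {
    eta <- as.vector(Xs %*% beta)
    m <- max(eta)
    w <- exp(eta - m)
    cw <- cumsum(w)
    cwx <- apply(Xs * w, 2, cumsum)
    if (p == 1) cwx <- matrix(cwx, ncol = 1)
    cwxx <- vapply(seq_len(p * p), function(q) {
      cumsum(w * Xs[, pair_a[q]] * Xs[, pair_b[q]])
    }, numeric(n))
    U <- numeric(p)
    I <- matrix(0, p, p)
    for (k in ev_pos) {
      r <- rs$last_tied[k]
      S0 <- cw[r]
      xbar <- cwx[r, ] / S0
      U <- U + Xs[k, ] - xbar
      S2 <- matrix(cwxx[r, ], p, p)
      I <- I + S2 / S0 - tcrossprod(xbar)
    }
    list(U = U - ridge * beta, I = I + diag(ridge, p))
  }

  beta <- numeric(p)
  ll <- loglik_at(beta)
  ll0 <- ll
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    si <- score_info(beta)
    if (max(abs(si$U)) < tol) {
      converged <- TRUE
      break
    }
    step <- tryCatch(solve(si$I, si$U), error = function(e) {
      abort("singular information matrix: covariates not full rank")
    })
    # step halving keeps the likelihood monotone
    alpha <- 1
    repeat {
      cand <- beta + alpha * step
      ll_cand <- loglik_at(cand)
      if (ll_cand >= ll - 1e-12 || alpha < 1e-4) break
      alpha <- alpha / 2
    }
    beta <- cand
    ll <- ll_cand
    if (max(abs(beta)) > beta_bound) {
      warn("diverging coefficients: possible separation; fit flagged as non-converged")
      break
    }
  }
  if (!converged && iter == max_iter) {
    si <- score_info(beta)
    converged <- max(abs(si$U)) < sqrt(tol)
  }
  info <- score_info(beta)$I
  se <- sqrt(diag(solve(info)))
  z <- 1.959964
  names(beta) <- names(se) <- covariates
  structure(list(
    coefficients = beta,
    standard_errors = se,
    hazard_ratios = exp(beta),
    ci95_low = exp(beta - z * se),
    ci95_high = exp(beta + z * se),
    wald_p = 2 * pnorm(-abs(beta / se)),
    log_partial_likelihood = ll,
    log_partial_likelihood_null = ll0,
    converged = converged,
    iterations = iter,
    n_subjects = n,
    n_events = n_events,
    center = center
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit (%d subjects, %d events)\n",
              x$n_subjects, x$n_events))
  print(tidy(x))
  invisible(x)
}

#' Tidy a Cox fit
#'
#' @param x A `cox_fit` object.
#' @param ... Unused.
#' @return One row per coefficient: `term`, `estimate` (log hazard ratio),
#'   `std.error`, `hazard_ratio`, `conf.low`, `conf.high` (95%, on the HR
#'   scale) and `p.value` (Wald).
#' @method tidy cox_fit
#' @export
tidy.cox_fit <- function(x, ...) {
  tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$standard_errors),
    hazard_ratio = unname(x$hazard_ratios),
    conf.low = unname(x$ci95_low),
    conf.high = unname(x$ci95_high),
    p.value = unname(x$wald_p)
  )
}

#' Summarize a Cox fit in one row
#'
#' @param x A `cox_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: log partial likelihood at the optimum and at
#'   zero, subject and event counts, convergence flag, iteration count.
#' @method glance cox_fit
#' @export
glance.cox_fit <- function(x, ...) {
  tibble(
    log_partial_likelihood = x$log_partial_likelihood,
    log_partial_likelihood_null = x$log_partial_likelihood_null,
    n_subjects = x$n_subjects,
    n_events = x$n_events,
    converged = x$converged,
    iterations = x$iterations
  )
}

#' Subgroup hazard-ratio forest
#'
#' Fits one single-covariate Cox model of the risk score per subgroup and
#' collects hazard ratios with 95% confidence intervals, the rows of a
#' forest plot. The score enters either standardized on the full input
#' cohort (`standardized_continuous`, HR per standard deviation) or as a
#' top-quartile indicator (`binary_top_quartile`, threshold from the
#' full-cohort type-1 empirical quantile). Subgroups with no events, or in
#' which the coding is constant, are reported with `estimable = FALSE`
#' rather than raising an error.
#'
#' @param data Tibble with `time_days`, `event`, a score column and a
#'   subgroup label column.
#' @param subgroup Subgroup label column (tidy-eval).
#' @param score Score column (tidy-eval); default `score`.
#' @param score_coding `"standardized_continuous"` or
#'   `"binary_top_quartile"`.
#' @param include_overall Prepend an `"all"` row fitted on the full cohort.
#' @return A tibble with columns `subgroup`, `n`, `n_events`, `hr`,
#'   `ci_low`, `ci_high`, `p`, `estimable`.
#' @export
subgroup_forest <- function(data, subgroup, score = score,
                            score_coding = c("standardized_continuous",
                                             "binary_top_quartile"),
                            include_overall = TRUE) {
  score_coding <- match.arg(score_coding)
  assert_outcomes(data)
  s <- resolve_scores(data, rlang::enquo(score), nrow(data))
  labels <- as.character(rlang::eval_tidy(rlang::enquo(subgroup), data))
  coded <- switch(score_coding,
    standardized_continuous = {
      if (sd(s) == 0) abort("degenerate score distribution")
      (s - mean(s)) / sd(s)
    },
    binary_top_quartile = as.double(s > quantile_type1(s, 0.75))
  )
  d <- dplyr::mutate(data, .coded_score = coded, .subgroup = labels)
  groups <- unique(labels)
  if (include_overall) {
    d_all <- dplyr::mutate(d, .subgroup = "all")
    d <- dplyr::bind_rows(d_all, d)
    groups <- c("all", groups)
  }
  purrr::map_dfr(groups, function(g) {
    sub <- d[d$.subgroup == g, ]
    ne <- sum(sub$event)
    base <- tibble(subgroup = g, n = nrow(sub), n_events = ne,
                   hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                   p = NA_real_, estimable = FALSE)
    if (ne == 0 || sd(sub$.coded_score) == 0) return(base)
    fit <- tryCatch(
      fit_cox(sub, ".coded_score"),
      error = function(e) NULL
    )
    if (is.null(fit)) return(base)
    dplyr::mutate(base,
      hr = unname(fit$hazard_ratios),
      ci_low = unname(fit$ci95_low),
      ci_high = unname(fit$ci95_high),
      p = unname(fit$wald_p),
      estimable = TRUE
    )
  })
}
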