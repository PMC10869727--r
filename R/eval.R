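# Risk-stratification evaluation protocol: concordance, Kaplan-Meier,
# log-rank, quantile stratification, horizon classification and ROC curves.

#' Harrell's concordance index
#'
#' Fraction of comparable subject pairs in which the higher risk score
#' belongs to the subject with the earlier event. A pair (i, j) is
#' comparable when i has an event and either `t_i < t_j`, or `t_i <= t_j`
#' with j censored. Score ties count 1/2. With `horizon_days` set, pairs
#' whose earlier time exceeds the horizon are excluded (truncated C-index).
#'
#' @param data Tibble with `time_days`, `event` and the score column.
#' @param score Score column (tidy-eval) or numeric vector.
#' @param horizon_days Optional truncation horizon in days.
#' @return The concordance index in \[0, 1\].
#' @export
concordance_index <- function(data, score = score, horizon_days = NULL) {
  assert_outcomes(data)
  s <- resolve_scores(data, rlang::enquo(score), nrow(data))
  t <- data$time_days
  d <- data$event
  idx <- which(d == 1)
  if (!is.null(horizon_days)) idx <- idx[t[idx] <= horizon_days]
  num <- 0
  den <- 0
  for (i in idx) {
    comparable <- (t > t[i]) | (t == t[i] & d == 0)
    comparable[i] <- FALSE
    m <- sum(comparable)
    if (m == 0) next
    num <- num + sum(s[i] > s[comparable]) + 0.5 * sum(s[i] == s[comparable])
    den <- den + m
  }
  if (den == 0) abort("no comparable pairs")
  num / den
}

#' Kaplan-Meier product-limit estimate
#'
#' @param data Tibble with `time_days` and `event`.
#' @return A tibble of class `km_curve`, one row per distinct event time:
#'   `time`, `n_at_risk`, `n_events`, `survival`. An all-censored input
#'   yields zero rows (the survival curve stays at 1).
#' @export
km_estimate <- function(data) {
  if (nrow(data) == 0) abort("empty input")
  assert_outcomes(data)
  t <- data$time_days
  d <- data$event
  ev_times <- sort(unique(t[d == 1]))
  n_at_risk <- vapply(ev_times, function(u) sum(t >= u), double(1))
  n_events <- vapply(ev_times, function(u) sum(t == u & d == 1), double(1))
  surv <- cumprod(1 - n_events / n_at_risk)
  out <- tibble(
    time = ev_times,
    n_at_risk = as.integer(n_at_risk),
    n_events = as.integer(n_events),
    survival = surv
  )
  class(out) <- c("km_curve", class(out))
  out
}

#' Kaplan-Meier curves per stratum
#'
#' @param data Tibble with `time_days`, `event` and a grouping column.
#' @param group Grouping column (tidy-eval).
#' @return A `km_curve` tibble with an additional `stratum` column.
#' @export
km_by_group <- function(data, group) {
  labels <- as.character(rlang::eval_tidy(rlang::enquo(group), data))
  out <- purrr::map_dfr(unique(labels), function(g) {
    dplyr::mutate(km_estimate(data[labels == g, ]), stratum = g,
                  .before = 1)
  })
  class(out) <- c("km_curve", class(out))
  out
}

#' K-group log-rank test
#'
#' Standard log-rank statistic: at every distinct event time the observed
#' events per group are compared with their hypergeometric expectation given
#' the risk-set sizes; the covariance uses the hypergeometric form with tied
#' events across groups handled jointly. The statistic is chi-squared with
#' `k - 1` degrees of freedom.
#'
#' @param data Tibble with `time_days` and `event`.
#' @param group Grouping column (tidy-eval) with at least two levels.
#' @return A one-row tibble: `chi_square`, `df`, `p_value`.
#' @export
logrank_test <- function(data, group) {
  assert_outcomes(data)
  labels <- as.character(rlang::eval_tidy(rlang::enquo(group), data))
  groups <- sort(unique(labels))
  k <- length(groups)
  if (k < 2) abort("log-rank test requires at least two groups")
  if (sum(data$event) == 0) abort("log-rank test requires at least one event")
  t <- data$time_days
  d <- data$event
  g <- match(labels, groups)
  ev_times <- sort(unique(t[d == 1]))
  OmE <- numeric(k)
  V <- matrix(0, k, k)
  for (u in ev_times) {
    at_risk <- t >= u
    n <- sum(at_risk)
    dt <- sum(t == u & d == 1)
    ng <- vapply(seq_len(k), function(q) sum(at_risk & g == q), double(1))
    dg <- vapply(seq_len(k), function(q) sum(t == u & d == 1 & g == q),
                 double(1))
    e <- dt * ng / n
    OmE <- OmE + dg - e
    if (n > 1) {
      frac <- ng / n
      Vt <- dt * (n - dt) / (n - 1) * (diag(frac) - tcrossprod(frac))
      V <- V + Vt
    }
  }
  idx <- seq_len(k - 1)
  chi <- tryCatch(
    as.numeric(t(OmE[idx]) %*% solve(V[idx, idx, drop = FALSE], OmE[idx])),
    error = function(e) abort("singular log-rank covariance (degenerate groups)")
  )
  tibble(
    chi_square = chi,
    df = k - 1L,
    p_value = pchisq(chi, df = k - 1, lower.tail = FALSE)
  )
}

#' Stratify subjects by score quantiles
#'
#' Cuts the score distribution at the given empirical quantiles (type-1
#' inverse CDF, so a 388-subject cohort splits exactly 194/194 at the
#' median and 194/97/97 with cuts (0.5, 0.75)). Tied scores are rejected
#' under the default strict policy; `tie_policy = "stable_order"` breaks
#' ties by input order instead.
#'
#' @param data Tibble with the score column.
#' @param cut_quantiles Ascending quantiles in (0, 1); default `c(0.5,
#'   0.75)` for the low / intermediate / high split.
#' @param score Score column (tidy-eval).
#' @param tie_policy `"strict"` or `"stable_order"`.
#' @return `data` with an added ordered-factor `stratum` column; the score
#'   thresholds are attached as attribute `cut_thresholds`.
#' @export
stratify_by_quantiles <- function(data, cut_quantiles = c(0.5, 0.75),
                                  score = score,
                                  tie_policy = c("strict", "stable_order")) {
  tie_policy <- match.arg(tie_policy)
  s <- resolve_scores(data, rlang::enquo(score), nrow(data))
  if (length(cut_quantiles) < 1 || is.unsorted(cut_quantiles, strictly = TRUE) ||
      any(cut_quantiles <= 0) || any(cut_quantiles >= 1)) {
    abort("cut_quantiles must be strictly ascending within (0, 1)")
  }
  if (tie_policy == "strict" && anyDuplicated(s)) {
    abort("degenerate score distribution: tied scores (use tie_policy = 'stable_order')")
  }
  n <- length(s)
  r <- rank(s, ties.method = "first")
  bounds <- ceiling(n * cut_quantiles)
  stratum_idx <- 1L + vapply(r, function(ri) sum(ri > bounds), integer(1))
  levels <- stratum_levels(length(cut_quantiles))
  out <- dplyr::mutate(
    data,
    stratum = factor(levels[stratum_idx], levels = levels, ordered = TRUE)
  )
  attr(out, "cut_quantiles") <- cut_quantiles
  attr(out, "cut_thresholds") <- sort(s)[bounds]
  out
}

stratum_levels <- function(n_cuts) {
  switch(as.character(n_cuts),
    "1" = c("below_median", "above_median"),
    "2" = c("low", "intermediate", "high"),
    paste0("stratum_", seq_len(n_cuts + 1))
  )
}

#' Binary outcome labels at a time horizon
#'
#' Converts time-to-event outcomes into horizon classification labels:
#' positive if the event occurred at or before the horizon, negative if the
#' subject was followed event-free beyond it. Subjects censored before the
#' horizon have unknown status; the default policy excludes them, while
#' `"censored_as_negative"` counts them as negatives (classification
#' disregarding censoring).
#'
#' @param data Tibble with `time_days` and `event`.
#' @param horizon_days Positive horizon in days.
#' @param policy `"exclude_censored_before_horizon"` (default) or
#'   `"censored_as_negative"`.
#' @return `data` with added columns `label` (integer 0/1, `NA` when
#'   excluded) and `included` (logical).
#' @export
horizon_labels <- function(data, horizon_days,
                           policy = c("exclude_censored_before_horizon",
                                      "censored_as_negative")) {
  policy <- match.arg(policy)
  assert_outcomes(data)
  if (horizon_days <= 0) abort("horizon_days must be positive")
  t <- data$time_days
  d <- data$event
  label <- dplyr::case_when(
    d == 1 & t <= horizon_days ~ 1L,
    t >= horizon_days ~ 0L,
    policy == "censored_as_negative" ~ 0L,
    .default = NA_integer_
  )
  dplyr::mutate(data, label = label, included = !is.na(label))
}

new_roc <- function(points, auc, kind) {
  out <- points
  class(out) <- c("mpisurv_roc", class(out))
  attr(out, "auc") <- auc
  attr(out, "kind") <- kind
  out
}

#' ROC curve by threshold sweep
#'
#' Sweeps every distinct score as a classification threshold and traces
#' (FPR, TPR) from (0, 0) to (1, 1); the area under the curve is computed
#' by the trapezoid rule and equals the normalized Mann-Whitney U
#' statistic (ties counted 1/2).
#'
#' @param data Tibble with the label and score columns.
#' @param label Binary label column (tidy-eval); rows with `NA` labels are
#'   dropped (e.g. the exclusions of [horizon_labels()]).
#' @param score Score column (tidy-eval).
#' @return A tibble of class `mpisurv_roc` with columns `fpr`, `tpr`;
#'   the AUC is available via [roc_auc()].
#' @export
roc_curve <- function(data, label = label, score = score) {
  y <- rlang::eval_tidy(rlang::enquo(label), data)
  s <- rlang::eval_tidy(rlang::enquo(score), data)
  keep <- !is.na(y)
  y <- y[keep]
  s <- as.double(s[keep])
  if (!all(y %in% c(0, 1))) abort("labels must be binary")
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) abort("both classes must be present")
  ord <- order(s, decreasing = TRUE)
  ys <- y[ord]
  ss <- s[ord]
  # collapse tied scores into single sweep steps
  last_of_tie <- c(ss[-1] != ss[-length(ss)], TRUE)
  tpr <- cumsum(ys == 1)[last_of_tie] / n_pos
  fpr <- cumsum(ys == 0)[last_of_tie] / n_neg
  points <- tibble(fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(points$fpr) * (head(points$tpr, -1) + points$tpr[-1]) / 2)
  new_roc(points, auc, "threshold_sweep")
}

#' Area under an ROC curve
#'
#' @param x An object returned by [roc_curve()] or [stratified_roc()].
#' @return The AUC as a double.
#' @export
roc_auc <- function(x) {
  attr(x, "auc")
}

#' Three-segment ROC of an ordinal risk stratification
#'
#' ROC of a three-level (low / intermediate / high) stratification used as
#' an ordinal classifier: three straight segments joined at two turning
#' points, the operating points of the "high only positive" and "high +
#' intermediate positive" thresholds. Identical in AUC to [roc_curve()]
#' applied to the stratum index as a score.
#'
#' @param data Tibble with a 3-level ordered `stratum` column (see
#'   [stratify_by_quantiles()]) and a binary label column.
#' @param label Binary label column (tidy-eval); `NA` labels are dropped.
#' @param stratum Stratum column (tidy-eval); must have exactly 3 levels.
#' @return A tibble of class `mpisurv_roc` with the four curve vertices.
#' @export
stratified_roc <- function(data, label = label, stratum = stratum) {
  y <- rlang::eval_tidy(rlang::enquo(label), data)
  st <- rlang::eval_tidy(rlang::enquo(stratum), data)
  keep <- !is.na(y)
  y <- y[keep]
  st <- st[keep]
  if (!is.factor(st)) st <- factor(st)
  if (nlevels(st) != 3) abort("stratified ROC requires exactly 3 ordered strata")
  if (!all(y %in% c(0, 1))) abort("labels must be binary")
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) abort("both classes must be present")
  lev <- levels(st)
  vertex <- function(positive_levels) {
    pos_call <- st %in% positive_levels
    c(fpr = sum(pos_call & y == 0) / n_neg,
      tpr = sum(pos_call & y == 1) / n_pos)
  }
  v1 <- vertex(lev[3])            # high only
  v2 <- vertex(lev[2:3])         # high + intermediate
  points <- tibble(
    fpr = c(0, unname(v1["fpr"]), unname(v2["fpr"]), 1),
    tpr = c(0, unname(v1["tpr"]), unname(v2["tpr"]), 1)
  )
  auc <- sum(diff(points$fpr) * (head(points$tpr, -1) + points$tpr[-1]) / 2)
  new_roc(points, auc, "stratified_3level")
}

#' Event-rate summary table
#'
#' Tabulates per-endpoint event counts against cohort sizes as percentages,
#' rounded half away from zero to two decimals (the convention of clinical
#' event tables).
#'
#' @param data Tibble with columns `count` and `size` (any other columns,
#'   e.g. `endpoint` or `cohort`, are carried through).
#' @return `data` with an added `percentage` column.
#' @examples
#' event_rate_summary(tibble::tibble(endpoint = "MACE", count = 119,
#'                                   size = 1540))  # 7.73
#' @export
event_rate_summary <- function(data) {
  assert_cols(data, c("count", "size"), "event-rate table")
  if (any(data$count > data$size)) abort("count exceeds cohort size")
  if (any(data$count < 0) || any(data$size <= 0)) {
    abort("counts must be non-negative and sizes positive")
  }
  dplyr::mutate(data,
                percentage = round_half_up(100 * .data$count / .data$size, 2))
}
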