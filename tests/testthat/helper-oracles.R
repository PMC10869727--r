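# Independent oracles, deliberately naive: direct enumeration, double
# loops, finite differences. They share no code with the implementation.

# Term-by-term Cox log partial likelihood (Breslow ties).
oracle_pll <- function(time, event, f) {
  total <- 0
  for (i in seq_along(time)) {
    if (event[i] == 1) {
      risk <- which(time >= time[i])
      total <- total + f[i] - log(sum(exp(f[risk])))
    }
  }
  total
}

oracle_pll_gradient_fd <- function(data, f, eps = 1e-6) {
  vapply(seq_along(f), function(k) {
    up <- f
    dn <- f
    up[k] <- up[k] + eps
    dn[k] <- dn[k] - eps
    (partial_log_likelihood(data, up) - partial_log_likelihood(data, dn)) /
      (2 * eps)
  }, double(1))
}

# Exhaustive pair enumeration for Harrell's C.
oracle_cindex <- function(time, event, score, horizon = NULL) {
  num <- 0
  den <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    if (event[i] != 1) next
    if (!is.null(horizon) && time[i] > horizon) next
    for (j in seq_len(n)) {
      if (j == i) next
      comparable <- (time[j] > time[i]) ||
        (time[j] == time[i] && event[j] == 0)
      if (!comparable) next
      den <- den + 1
      if (score[i] > score[j]) {
        num <- num + 1
      } else if (score[i] == score[j]) {
        num <- num + 0.5
      }
    }
  }
  num / den
}

# Mann-Whitney AUC by concordant-pair counting.
oracle_auc <- function(label, score) {
  pos <- score[label == 1]
  neg <- score[label == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Random censored survival instance with distinct or tied times.
random_instance <- function(n, tied = FALSE, rate = 0.1) {
  t <- stats::rexp(n, rate)
  if (tied) t <- ceiling(t)
  tibble::tibble(
    time_days = t + if (tied) 0 else 0,
    event = stats::rbinom(n, 1, 0.6),
    score = stats::rnorm(n)
  )
}

# Fast phantom config used across tests.
tiny_phantom <- function(n, seed, beta_true = 1.5, ...) {
  phantom_config(n_subjects = n, layout = "reduced", slice_size = 32L,
                 beta_true = beta_true, seed = seed, ...)
}

tiny_net <- function(...) {
  network_config("image_only", input_channels = 8L, input_size = 32L,
                 architecture_scale = "tiny", ...)
}
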