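# End-to-end survival training: a convolutional residual network maps a
# subject's tomogram stack to a scalar log-relative-hazard score, and the
# network is optimized by mini-batch gradient steps on the negative Cox
# log partial likelihood with risk sets restricted to the batch.

#' Network configuration for a risk scorer
#'
#' @param mode `"image_only"`, `"clinical_only"` or `"combined"`. In
#'   combined mode clinical covariates are concatenated to the pooled image
#'   features as extra input nodes of the score head.
#' @param input_channels Number of slices per study; slices enter as input
#'   channels of the 2D convolutional stem (default 96, the full clinical
#'   layout).
#' @param input_size Slice height/width in pixels.
#' @param architecture_scale `"tiny"` (3 residual stages, the desk-scale
#'   default), `"small"`, or `"resnet50-like"` (deeper/wider; not exercised
#'   by the test suite).
#' @param clinical_cols Character vector naming the clinical covariate
#'   columns; required non-empty for `clinical_only` and `combined`.
#' @param clinical_hidden Hidden-layer widths of the clinical subnetwork
#'   used in `clinical_only` mode; `integer(0)` gives a purely linear
#'   scorer, which makes the trainer equivalent to classical Cox
#'   regression.
#' @return A `network_config` list.
#' @export
network_config <- function(mode = c("image_only", "clinical_only", "combined"),
                           input_channels = 96L,
                           input_size = 32L,
                           architecture_scale = c("tiny", "small",
                                                  "resnet50-like"),
                           clinical_cols = character(),
                           clinical_hidden = 8L) {
  mode <- match.arg(mode)
  architecture_scale <- match.arg(architecture_scale)
  if (mode %in% c("clinical_only", "combined") && length(clinical_cols) < 1) {
    abort(sprintf("%s mode requires at least one clinical covariate", mode))
  }
  if (mode != "clinical_only" && input_channels < 1) {
    abort("image modes require input_channels >= 1")
  }
  structure(list(
    mode = mode,
    input_channels = as.integer(input_channels),
    input_size = as.integer(input_size),
    architecture_scale = architecture_scale,
    clinical_cols = clinical_cols,
    clinical_hidden = as.integer(clinical_hidden)
  ), class = "network_config")
}

#' Training configuration
#'
#' Defaults follow the reference training recipe: Adam, batch size 16,
#' learning rate 1e-4, 70 epochs, fivefold cross-validation, model
#' selection by the highest validation C-index among the 1000/2000/3000-day
#' horizons.
#'
#' @param batch_size Mini-batch size (>= 2; risk sets are intra-batch).
#' @param learning_rate Adam learning rate.
#' @param epochs Number of passes over the training subjects.
#' @param k_folds Cross-validation folds.
#' @param horizons_days Strictly increasing evaluation horizons in days.
#' @param seed Integer seed; initialization and shuffling derive substreams
#'   from it.
#' @param min_events_per_batch Batches with fewer events are skipped for
#'   the parameter update (a zero-event batch carries no likelihood
#'   signal).
#' @param stratify_batches Spread events across batches by stratified
#'   shuffling instead of plain shuffling.
#' @param selection `"max"` (default) or `"mean"` of the per-horizon
#'   validation C-indices when ranking folds.
#' @return A `training_config` list.
#' @export
training_config <- function(batch_size = 16L, learning_rate = 1e-4,
                            epochs = 70L, k_folds = 5L,
                            horizons_days = c(1000, 2000, 3000),
                            seed = 1L, min_events_per_batch = 1L,
                            stratify_batches = FALSE,
                            selection = c("max", "mean")) {
  selection <- match.arg(selection)
  if (batch_size < 2) abort("batch_size must be >= 2")
  if (is.unsorted(horizons_days, strictly = TRUE)) {
    abort("horizons_days must be strictly increasing")
  }
  structure(list(
    batch_size = as.integer(batch_size),
    learning_rate = learning_rate,
    epochs = as.integer(epochs),
    k_folds = as.integer(k_folds),
    horizons_days = horizons_days,
    seed = as.integer(seed),
    min_events_per_batch = as.integer(min_events_per_batch),
    stratify_batches = isTRUE(stratify_batches),
    selection = selection
  ), class = "training_config")
}

config_hash <- function(config) {
  sprintf("%08x", derive_seed(7L, paste(deparse(config), collapse = "")))
}

#' Build an (untrained) risk-score network
#'
#' Constructs the network for a [network_config()]: a stack of residual
#' convolutional stages with progressive downsampling, global average
#' pooling and a single linear score head for image modes; a small fully
#' connected network in clinical-only mode. Weights use seeded He
#' initialization.
#'
#' @param config A [network_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `risk_scorer`.
#' @export
build_risk_network <- function(config, seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  clin_dim <- length(config$clinical_cols)
  arch <- if (config$mode != "clinical_only") {
    image_arch(config$architecture_scale, config$input_channels)
  }
  params <- with_seed(derive_seed(seed, "init"), {
    p <- list()
    if (!is.null(arch)) {
      p <- init_image_params(arch)
      head_dim <- arch$feat_dim +
        if (config$mode == "combined") clin_dim else 0L
    } else {
      d_in <- clin_dim
      for (h in seq_along(config$clinical_hidden)) {
        d_out <- config$clinical_hidden[h]
        p[[sprintf("fc%d.W", h)]] <- he_init(d_in, d_out)
        p[[sprintf("fc%d.b", h)]] <- numeric(d_out)
        d_in <- d_out
      }
      head_dim <- d_in
    }
    p[["head.W"]] <- he_init(head_dim, 1L, gain = 1)
    p[["head.b"]] <- 0
    p
  })
  structure(list(
    params = params,
    config = config,
    arch = arch,
    history = NULL,
    provenance = list(seed = as.integer(seed),
                      config_hash = config_hash(config),
                      trained = FALSE)
  ), class = "risk_scorer")
}

#' @export
print.risk_scorer <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf(
    "<risk_scorer> mode=%s scale=%s, %d parameters, %s\n",
    x$config$mode,
    if (is.null(x$arch)) "fc" else x$config$architecture_scale,
    n_par,
    if (x$provenance$trained) "trained" else "untrained"
  ))
  invisible(x)
}

# Forward pass over a batch. `x` is the (H, W, C, N) image array (or NULL),
# `clin` the N x D clinical matrix (or NULL). Returns scores and caches.
scorer_forward <- function(scorer, x, clin) {
  cfg <- scorer$config
  params <- scorer$params
  if (cfg$mode == "clinical_only") {
    h <- clin
    caches <- list(inputs = list())
    nh <- length(cfg$clinical_hidden)
    for (k in seq_len(nh)) {
      caches$inputs[[k]] <- h
      pre <- sweep(h %*% params[[sprintf("fc%d.W", k)]], 2,
                   params[[sprintf("fc%d.b", k)]], "+")
      caches$pre[[k]] <- pre
      h <- relu(pre)
    }
    feat <- h
    fw <- NULL
  } else {
    fw <- image_forward(params, scorer$arch, x)
    feat <- if (cfg$mode == "combined") cbind(fw$feat, clin) else fw$feat
    caches <- list()
  }
  scores <- as.vector(feat %*% params[["head.W"]] + params[["head.b"]])
  list(scores = scores, feat = feat, fw = fw, caches = caches)
}

scorer_backward <- function(scorer, fwd, dscores) {
  cfg <- scorer$config
  params <- scorer$params
  dscores <- matrix(dscores, ncol = 1)
  grads <- list(
    "head.W" = crossprod(fwd$feat, dscores),
    "head.b" = sum(dscores)
  )
  dfeat <- dscores %*% t(params[["head.W"]])
  if (cfg$mode == "clinical_only") {
    nh <- length(cfg$clinical_hidden)
    dh <- dfeat
    for (k in rev(seq_len(nh))) {
      dpre <- dh * (fwd$caches$pre[[k]] > 0)
      grads[[sprintf("fc%d.W", k)]] <- crossprod(fwd$caches$inputs[[k]], dpre)
      grads[[sprintf("fc%d.b", k)]] <- colSums(dpre)
      dh <- dpre %*% t(params[[sprintf("fc%d.W", k)]])
    }
  } else {
    img_dim <- scorer$arch$feat_dim
    dimg <- dfeat[, seq_len(img_dim), drop = FALSE]
    img_grads <- image_backward(params, scorer$arch, dimg, fwd$fw)
    grads <- c(grads, img_grads)
  }
  grads
}

#' Negative batch partial-likelihood loss
#'
#' The training loss: the negated Cox log partial likelihood with risk sets
#' restricted to the batch. Identical (bit for bit) to
#' `-partial_log_likelihood()` on the same inputs; a batch with no events
#' contributes 0 and no parameter update.
#'
#' @inheritParams partial_log_likelihood
#' @return The loss (a double >= 0 whenever every risk set is non-empty).
#' @export
survival_loss <- function(data, score = score) {
  -partial_log_likelihood(data, {{ score }})
}

assemble_image_batch <- function(studies, config) {
  hw <- config$input_size
  ch <- config$input_channels
  # batch layout is channels-last: (H, W, N, C)
  x <- array(0, c(hw, hw, length(studies), ch))
  for (i in seq_along(studies)) {
    s <- studies[[i]]$slices
    d <- dim(s)
    if (d[1] != hw || d[2] != hw || d[3] != ch) {
      abort(sprintf(
        "study layout mismatch: got %dx%dx%d, network expects %dx%dx%d",
        d[1], d[2], d[3], hw, hw, ch
      ))
    }
    x[, , i, ] <- s
  }
  x
}

clinical_matrix <- function(data, config) {
  if (length(config$clinical_cols) == 0) return(NULL)
  assert_cols(data, config$clinical_cols, "clinical covariates")
  m <- as.matrix(data[config$clinical_cols])
  storage.mode(m) <- "double"
  if (anyNA(m)) abort("clinical covariates contain missing values")
  m
}

epoch_batches <- function(n, events, batch_size, stratify, seed) {
  with_seed(seed, {
    if (stratify) {
      ev <- sample(which(events == 1))
      ce <- sample(which(events == 0))
      n_batches <- max(1L, n %/% batch_size)
      slots <- rep(seq_len(n_batches), length.out = length(ev))
      batches <- split(ev, slots)
      fill <- split(ce, rep(seq_len(n_batches), length.out = length(ce)))
      order <- unlist(lapply(seq_len(n_batches), function(b) {
        c(batches[[as.character(b)]] %||% integer(0),
          fill[[as.character(b)]] %||% integer(0))
      }), use.names = FALSE)
    } else {
      order <- sample.int(n)
    }
    split(order, ceiling(seq_along(order) / batch_size))
  })
}

#' Train a risk-score network end to end
#'
#' Runs mini-batch optimization of the negative batch partial likelihood
#' with the Adam optimizer. All randomness (initialization, shuffling)
#' derives from `train_config$seed`, so a re-run with the same inputs and
#' configuration reproduces the final parameters exactly.
#'
#' @param data Tibble with `subject_id`, `time_days`, `event`, a `study`
#'   list column of [tomogram_study()] objects for image modes, and the
#'   clinical covariate columns named in `net_config` if used.
#' @param net_config A [network_config()].
#' @param train_config A [training_config()].
#' @return A trained `risk_scorer` with a per-epoch `history` tibble
#'   (`epoch`, `mean_loss` per event, `n_batches`).
#' @export
train_model <- function(data, net_config, train_config = training_config()) {
  assert_outcomes(data)
  if (sum(data$event) < 1) abort("no events in the training data")
  n <- nrow(data)
  scorer <- build_risk_network(net_config,
                               seed = derive_seed(train_config$seed, "init"))
  clin <- clinical_matrix(data, net_config)
  studies <- if (net_config$mode != "clinical_only") {
    assert_cols(data, "study", "training data")
    data$study
  } else {
    NULL
  }
  state <- adam_init(scorer$params)
  history <- vector("list", train_config$epochs)
  for (epoch in seq_len(train_config$epochs)) {
    batches <- epoch_batches(
      n, data$event, train_config$batch_size,
      train_config$stratify_batches,
      derive_seed(train_config$seed, paste0("epoch", epoch))
    )
    total_loss <- 0
    total_events <- 0L
    used <- 0L
    for (idx in batches) {
      if (length(idx) < 2) next
      n_ev <- sum(data$event[idx])
      if (n_ev < train_config$min_events_per_batch) next
      x <- if (!is.null(studies)) {
        assemble_image_batch(studies[idx], net_config)
      }
      cb <- if (!is.null(clin)) clin[idx, , drop = FALSE]
      fwd <- scorer_forward(scorer, x, cb)
      bdata <- data[idx, c("time_days", "event")]
      loss <- -partial_log_likelihood(bdata, fwd$scores)
      if (!is.finite(loss)) {
        abort(sprintf("non-finite loss at epoch %d; aborting training", epoch))
      }
      dscores <- -partial_likelihood_gradient(bdata, fwd$scores)
      grads <- scorer_backward(scorer, fwd, dscores)
      upd <- adam_step(scorer$params, grads, state,
                       train_config$learning_rate)
      scorer$params <- upd$params
      state <- upd$state
      total_loss <- total_loss + loss
      total_events <- total_events + n_ev
      used <- used + 1L
    }
    history[[epoch]] <- tibble(
      epoch = epoch,
      mean_loss = if (total_events > 0) total_loss / total_events else NA_real_,
      n_batches = used
    )
  }
  scorer$history <- dplyr::bind_rows(history)
  scorer$train_config <- train_config
  scorer$provenance <- list(
    seed = train_config$seed,
    config_hash = config_hash(list(net_config, train_config)),
    trained = TRUE
  )
  scorer
}

#' Score a cohort with a trained network
#'
#' Deterministic inference: one finite risk score per subject, independent
#' of batch composition and subject order.
#'
#' @param scorer A `risk_scorer` (see [train_model()]).
#' @param data Tibble with `subject_id` plus the inputs the scorer's
#'   configuration requires (`study` list column and/or clinical columns).
#' @param batch_size Inference batch size (memory knob only).
#' @return A tibble with columns `subject_id` and `score`.
#' @export
score_cohort <- function(scorer, data, batch_size = 32L) {
  stopifnot(inherits(scorer, "risk_scorer"))
  cfg <- scorer$config
  assert_cols(data, "subject_id")
  clin <- clinical_matrix(data, cfg)
  studies <- if (cfg$mode != "clinical_only") {
    assert_cols(data, "study", "scoring data")
    data$study
  }
  n <- nrow(data)
  scores <- numeric(n)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    x <- if (!is.null(studies)) assemble_image_batch(studies[idx], cfg)
    cb <- if (!is.null(clin)) clin[idx, , drop = FALSE]
    scores[idx] <- scorer_forward(scorer, x, cb)$scores
  }
  if (any(!is.finite(scores))) abort("non-finite score produced")
  tibble(subject_id = data$subject_id, score = scores)
}

#' Fivefold cross-validation with horizon C-index model selection
#'
#' Partitions the training cohort into `k_folds` folds (or honors an
#' existing `fold` column), trains one scorer per fold on the remaining
#' folds, evaluates the truncated concordance index on the held-out fold at
#' each horizon, and selects the fold whose scorer maximizes the selection
#' statistic (the maximum across horizons by default, the mean as an
#' alternative).
#'
#' @inheritParams train_model
#' @return An object of class `crossval_report`: per-fold scorers, a
#'   `metrics` tibble (`fold`, `horizon_days`, `c_index`), `selected_fold`
#'   and the selection value.
#' @export
crossval <- function(data, net_config, train_config = training_config()) {
  assert_outcomes(data)
  k <- train_config$k_folds
  if (k < 2) abort("k_folds must be >= 2")
  if (!"fold" %in% names(data)) {
    perm <- with_seed(derive_seed(train_config$seed, "folds"),
                      sample.int(nrow(data)))
    data$fold <- integer(nrow(data))
    data$fold[perm] <- rep_len(seq_len(k), nrow(data))
  }
  scorers <- vector("list", k)
  metrics <- vector("list", k)
  for (f in seq_len(k)) {
    train <- data[data$fold != f, ]
    valid <- data[data$fold == f, ]
    if (sum(train$event) < 1) abort(sprintf("fold %d has no training events", f))
    fold_cfg <- train_config
    fold_cfg$seed <- derive_seed(train_config$seed, paste0("fold", f))
    scorers[[f]] <- train_model(train, net_config, fold_cfg)
    sc <- score_cohort(scorers[[f]], valid)
    vd <- dplyr::mutate(valid, score = sc$score)
    metrics[[f]] <- purrr::map_dfr(train_config$horizons_days, function(h) {
      ci <- tryCatch(
        concordance_index(vd, horizon_days = h),
        error = function(e) NA_real_
      )
      tibble(fold = f, horizon_days = h, c_index = ci)
    })
  }
  metrics <- dplyr::bind_rows(metrics)
  agg <- metrics |>
    dplyr::group_by(.data$fold) |>
    dplyr::summarise(stat = {
      v <- .data$c_index[!is.na(.data$c_index)]
      if (length(v) == 0) {
        -Inf  # fold with no evaluable horizon (e.g. no comparable pairs)
      } else {
        switch(train_config$selection, max = max(v), mean = mean(v))
      }
    }, .groups = "drop")
  best <- agg$fold[which.max(agg$stat)]
  structure(list(
    scorers = scorers,
    metrics = metrics,
    fold_assignments = data[c("subject_id", "fold")],
    selected_fold = best,
    selection_value = max(agg$stat),
    selection_rule = train_config$selection
  ), class = "crossval_report")
}

#' @export
print.crossval_report <- function(x, ...) {
  cat(sprintf(
    "<crossval_report> %d folds; selected fold %d (%s horizon C-index %.3f)\n",
    length(x$scorers), x$selected_fold, x$selection_rule, x$selection_value
  ))
  invisible(x)
}

#' Tidy a cross-validation report
#'
#' @param x A `crossval_report`.
#' @param ... Unused.
#' @return The per-fold, per-horizon C-index tibble.
#' @method tidy crossval_report
#' @export
tidy.crossval_report <- function(x, ...) {
  x$metrics
}

#' One-row summary of a cross-validation report
#'
#' @param x A `crossval_report`.
#' @param ... Unused.
#' @return Tibble with `k_folds`, `selected_fold`, `selection_rule`,
#'   `selection_value`.
#' @method glance crossval_report
#' @export
glance.crossval_report <- function(x, ...) {
  tibble(
    k_folds = length(x$scorers),
    selected_fold = x$selected_fold,
    selection_rule = x$selection_rule,
    selection_value = x$selection_value
  )
}

#' Select the best scorer from a cross-validation report
#'
#' @param report A `crossval_report`.
#' @return The `risk_scorer` of the selected fold.
#' @export
selected_scorer <- function(report) {
  report$scorers[[report$selected_fold]]
}

#' Save / load a trained scorer
#'
#' Checkpoints are a single JSON file carrying the network configuration,
#' all parameter arrays (full precision) and provenance (seed and
#' configuration hash); the round trip restores bit-identical scores.
#'
#' @param scorer A `risk_scorer`.
#' @param path Checkpoint path (`.json`).
#' @return `path` (for `save_scorer`); a `risk_scorer` (for `load_scorer`).
#' @export
save_scorer <- function(scorer, path) {
  payload <- list(
    config = unclass(scorer$config),
    provenance = scorer$provenance,
    params = lapply(scorer$params, function(p) {
      list(dim = if (is.null(dim(p))) length(p) else dim(p),
           data = as.vector(p))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_scorer
#' @export
load_scorer <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- payload$config
  config <- network_config(
    mode = cfg$mode,
    input_channels = if (is.null(cfg$input_channels)) 1L else cfg$input_channels,
    input_size = cfg$input_size,
    architecture_scale = cfg$architecture_scale,
    clinical_cols = as.character(cfg$clinical_cols %||% character()),
    clinical_hidden = as.integer(cfg$clinical_hidden %||% integer())
  )
  params <- lapply(payload$params, function(p) {
    if (length(p$dim) > 1) array(p$data, dim = p$dim) else as.vector(p$data)
  })
  arch <- if (config$mode != "clinical_only") {
    image_arch(config$architecture_scale, config$input_channels)
  }
  structure(list(
    params = params,
    config = config,
    arch = arch,
    history = NULL,
    provenance = as.list(payload$provenance)
  ), class = "risk_scorer")
}
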