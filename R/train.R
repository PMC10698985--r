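#' Training configuration
#'
#' Defaults are the reference training settings: Adam with default
#' moment parameters, learning rate 0.001, batch size 64, at most 50
#' epochs, decision threshold 0.5, and early stopping when the trailing
#' 3-epoch mean of the monitored loss strictly increases for 5
#' consecutive epochs.
#'
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param max_epochs Epoch cap.
#' @param trailing_window Epochs averaged by the stopping rule.
#' @param patience Consecutive increases of the trailing mean that stop
#'   training.
#' @param threshold Decision threshold on the predicted probability.
#' @param seed Integer seed for initialization, shuffling and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 64,
                         max_epochs = 50, trailing_window = 3,
                         patience = 5, threshold = 0.5, seed = 1) {
  stopifnot(learning_rate > 0, batch_size >= 2, max_epochs >= 1,
            trailing_window >= 1, patience >= 1,
            threshold > 0, threshold < 1)
  structure(list(optimizer = "adam", learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 trailing_window = as.integer(trailing_window),
                 patience = as.integer(patience),
                 threshold = threshold, seed = as.integer(seed)),
            class = "train_config")
}

#' Mean binary cross-entropy loss
#'
#' \eqn{-\frac{1}{n}\sum [y \log y_{pred} + (1-y)\log(1-y_{pred})]} with
#' predictions clipped to `[eps, 1-eps]` before the logarithm.
#'
#' @param y 0/1 labels.
#' @param y_pred Predicted probabilities.
#' @param eps Clipping constant (default 1e-7).
#' @return Scalar loss.
#' @export
cross_entropy_loss <- function(y, y_pred, eps = 1e-7) {
  if (length(y) != length(y_pred)) {
    stop("labels and predictions differ in length", call. = FALSE)
  }
  p <- pmin(pmax(y_pred, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Early stopping rule
#'
#' Returns `TRUE` when the trailing-window mean of the monitored loss
#' (mean of the most recent `window` epochs, or of all epochs while
#' fewer are available) has strictly increased for `patience`
#' consecutive epochs, or when `max_epochs` epochs have elapsed. Ties do
#' not count as increases.
#'
#' @param loss_history Per-epoch monitored losses so far.
#' @param max_epochs Epoch cap (default 50).
#' @param window Trailing window (default 3).
#' @param patience Required consecutive increases (default 5).
#' @return Logical.
#' @export
early_stop_check <- function(loss_history, max_epochs = 50, window = 3,
                             patience = 5) {
  n <- length(loss_history)
  if (n >= max_epochs) return(TRUE)
  if (n < patience + 1) return(FALSE)
  trail <- vapply(seq_len(n), function(k) {
    mean(loss_history[max(1, k - window + 1):k])
  }, 0)
  inc <- diff(trail)
  all(tail(inc, patience) > 0)
}

# ---- Adam -----------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gnm <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gnm
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gnm^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train a base network
#'
#' Full training loop for one base classifier: featurizes the training
#' records, builds the M-way balanced subset plan on the training
#' labels (unless balancing is disabled), then iterates epochs
#' round-robin over the subsets with fresh per-epoch negative
#' subsampling, minimizing mean binary cross-entropy with Adam.
#' Validation loss (inference mode) is monitored by the early-stopping
#' rule; without a validation set, training loss is monitored.
#'
#' @param records Training records (list of [protein_record]).
#' @param fmod Feature module index (0, 1 or 2).
#' @param net_cfg A [net_config]; its `fmod` must match.
#' @param train_cfg A [train_config].
#' @param val_records Optional validation records.
#' @param plan Optional pre-built [build_balanced_subsets] plan.
#' @param balance Set `FALSE` to train on the full (imbalanced) training
#'   set every epoch.
#' @param verbose Print per-epoch losses.
#' @return List with `model` (trained [base_net]) and `history` (data
#'   frame: epoch, subset, train_loss, val_loss, stopped).
#' @export
train_base_net <- function(records, fmod,
                           net_cfg = net_config(fmod = fmod),
                           train_cfg = train_config(),
                           val_records = NULL, plan = NULL,
                           balance = TRUE, verbose = FALSE) {
  if (length(records) == 0) stop("empty training set", call. = FALSE)
  stopifnot(inherits(net_cfg, "net_config"), net_cfg$fmod == fmod)
  feats <- featurize_records(records, fmod, net_cfg$window, net_cfg$params)
  vfeats <- if (!is.null(val_records)) {
    featurize_records(val_records, fmod, net_cfg$window, net_cfg$params)
  }
  if (balance && is.null(plan)) {
    plan <- build_balanced_subsets(feats$y, seed = train_cfg$seed)
  }
  model <- net_init(net_cfg, seed = train_cfg$seed)
  opt <- adam_init(model$params)
  history <- data.frame(epoch = integer(), subset = integer(),
                        train_loss = numeric(), val_loss = numeric(),
                        stopped = logical())
  monitored <- numeric(0)
  set.seed(train_cfg$seed)          # batch shuffling + dropout stream
  N <- length(feats$y)
  for (epoch in seq_len(train_cfg$max_epochs)) {
    if (balance) {
      sid <- ((epoch - 1L) %% plan$M) + 1L
      idx <- epoch_subsample(plan, sid, epoch, seed = train_cfg$seed)
    } else {
      sid <- 0L
      idx <- seq_len(N)
    }
    idx <- idx[sample.int(length(idx))]
    losses <- numeric(0)
    at <- 1L
    while (at <= length(idx)) {
      bi <- idx[at:min(length(idx), at + train_cfg$batch_size - 1L)]
      at <- at + train_cfg$batch_size
      if (length(bi) < 2) next      # batch-norm needs at least 2 samples
      res <- forward_batch(model, feats$X[bi, , , drop = FALSE],
                           feats$mask[bi, , drop = FALSE],
                           feats$ftr[bi, , drop = FALSE],
                           training = TRUE, keep_cache = TRUE)
      model <- res$model            # updated batch-norm running stats
      yb <- feats$y[bi]
      losses <- c(losses, cross_entropy_loss(yb, res$prob))
      dlogit <- (res$prob - yb) / length(yb)
      grads <- backward_batch(model, res$cache, dlogit)
      upd <- adam_step(model$params, grads, opt, train_cfg$learning_rate)
      model$params <- upd$params
      opt <- upd$state
    }
    train_loss <- mean(losses)
    val_loss <- if (!is.null(vfeats)) {
      cross_entropy_loss(vfeats$y, eval_probs(model, vfeats))
    } else NA_real_
    monitored <- c(monitored, if (is.na(val_loss)) train_loss else val_loss)
    stop_now <- early_stop_check(monitored, train_cfg$max_epochs,
                                 train_cfg$trailing_window,
                                 train_cfg$patience)
    history <- rbind(history,
                     data.frame(epoch = epoch, subset = sid,
                                train_loss = train_loss,
                                val_loss = val_loss, stopped = stop_now))
    if (verbose) {
      message(sprintf("epoch %2d (subset %d): train %.4f  val %s", epoch,
                      sid, train_loss,
                      if (is.na(val_loss)) "-" else sprintf("%.4f",
                                                            val_loss)))
    }
    if (stop_now) break
  }
  model$trained <- TRUE
  list(model = model, history = history)
}

#' Write a per-epoch training log as TSV
#'
#' @param history The `history` data frame from [train_base_net].
#' @param path Output path.
#' @export
write_training_log <- function(history, path) {
  write.table(history, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
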