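SUPPORTED_RULES <- c("logistic_regression", "decision_tree", "random_forest",
                     "nearest_neighbor", "voting", "averaging", "linear_mse")

#' Collect base-model meta-features
#'
#' Column j holds base model j's predicted site probability for every
#' residue of `records`, in fixed feature-module order (0, 1, 2)
#' regardless of training order.
#'
#' @param base_models List of three trained [base_net] objects, one per
#'   feature module.
#' @param records List of [protein_record] objects.
#' @return Numeric matrix, n_residues x 3.
#' @export
collect_meta_features <- function(base_models, records) {
  if (length(base_models) != 3) {
    stop("exactly 3 base models are required (one per feature module)",
         call. = FALSE)
  }
  fmods <- vapply(base_models, function(m) m$config$fmod, 0L)
  if (!setequal(fmods, 0:2)) {
    stop("base models must cover feature modules 0, 1 and 2", call. = FALSE)
  }
  if (!all(vapply(base_models, `[[`, TRUE, "trained"))) {
    stop("all base models must be trained", call. = FALSE)
  }
  ord <- order(fmods)
  cols <- lapply(base_models[ord], function(m) {
    predict(m, records)$score
  })
  mf <- do.call(cbind, cols)
  colnames(mf) <- paste0("fmod", 0:2)
  mf
}

#' Fit the stacking meta-learner
#'
#' Fits the named decision rule on base-model probabilities (normally
#' collected on the held-out validation split). `voting` and
#' `averaging` need no fit and return empty parameters.
#'
#' @param meta_features n x 3 matrix from [collect_meta_features].
#' @param labels 0/1 labels, length n.
#' @param rule One of `"logistic_regression"` (default),
#'   `"decision_tree"`, `"random_forest"`, `"nearest_neighbor"`,
#'   `"voting"`, `"averaging"`, `"linear_mse"` (least-squares linear
#'   combination).
#' @return Rule-specific parameter object (class `meta_params`).
#' @export
fit_meta_learner <- function(meta_features, labels,
                             rule = "logistic_regression") {
  if (!rule %in% SUPPORTED_RULES) {
    stop("unsupported stacking rule: '", rule, "' (supported: ",
         paste(SUPPORTED_RULES, collapse = ", "), ")", call. = FALSE)
  }
  if (rule %in% c("voting", "averaging")) {
    return(structure(list(rule = rule, fit = NULL), class = "meta_params"))
  }
  labels <- as.integer(labels)
  mf <- as.matrix(meta_features)
  if (length(labels) != nrow(mf)) {
    stop("labels and meta-features differ in length", call. = FALSE)
  }
  if (length(unique(labels)) < 2) {
    stop("meta-learner '", rule, "' needs both classes in the labels",
         call. = FALSE)
  }
  fit <- switch(rule,
    logistic_regression = {
      g <- glm.fit(cbind(1, mf), labels, family = binomial())
      co <- g$coefficients
      co[is.na(co)] <- 0                 # aliased (collinear) columns
      list(coef = co)
    },
    linear_mse = {
      l <- lm.fit(cbind(1, mf), labels)
      co <- l$coefficients
      co[is.na(co)] <- 0
      list(coef = co)
    },
    decision_tree = {
      if (!requireNamespace("rpart", quietly = TRUE)) {
        stop("rule 'decision_tree' requires the rpart package",
             call. = FALSE)
      }
      d <- as.data.frame(mf)
      d$y <- factor(labels, levels = c(0, 1))
      list(tree = rpart::rpart(y ~ ., data = d, method = "class"))
    },
    random_forest = {
      if (!requireNamespace("randomForest", quietly = TRUE)) {
        stop("rule 'random_forest' requires the randomForest package",
             call. = FALSE)
      }
      list(forest = randomForest::randomForest(
        x = as.data.frame(mf), y = factor(labels, levels = c(0, 1))))
    },
    nearest_neighbor = {
      if (!requireNamespace("class", quietly = TRUE)) {
        stop("rule 'nearest_neighbor' requires the class package",
             call. = FALSE)
      }
      list(train_x = mf, train_y = labels, k = 5L)
    })
  structure(list(rule = rule, fit = fit), class = "meta_params")
}

# rule-specific probability (or call, for voting) from meta-features
apply_meta_rule <- function(meta_params, mf, threshold = 0.5) {
  mf <- as.matrix(mf)
  rule <- meta_params$rule
  fit <- meta_params$fit
  switch(rule,
    averaging = list(score = rowMeans(mf),
                     call = as.integer(rowMeans(mf) >= threshold)),
    voting = {
      votes <- rowSums(mf >= threshold)
      # even-count ties break toward the positive class (unreachable
      # with three base models)
      list(score = rep(NA_real_, nrow(mf)),
           call = as.integer(votes >= ncol(mf) / 2))
    },
    logistic_regression = {
      s <- plogis(as.numeric(cbind(1, mf) %*% fit$coef))
      list(score = s, call = as.integer(s >= threshold))
    },
    linear_mse = {
      s <- as.numeric(cbind(1, mf) %*% fit$coef)
      list(score = s, call = as.integer(s >= threshold))
    },
    decision_tree = {
      s <- predict(fit$tree, newdata = as.data.frame(mf))[, "1"]
      list(score = as.numeric(s), call = as.integer(s >= threshold))
    },
    random_forest = {
      s <- predict(fit$forest, newdata = as.data.frame(mf),
                   type = "prob")[, "1"]
      list(score = as.numeric(s), call = as.integer(s >= threshold))
    },
    nearest_neighbor = {
      kn <- class::knn(fit$train_x, mf,
                       factor(fit$train_y, levels = c(0, 1)),
                       k = fit$k, prob = TRUE)
      pwin <- attr(kn, "prob")
      s <- ifelse(kn == "1", pwin, 1 - pwin)
      list(score = as.numeric(s), call = as.integer(s >= threshold))
    })
}

#' Train a stacked ensemble of three base networks
#'
#' Trains one base network per feature module (0, 1, 2) on the training
#' records with M-way balanced subsets, collects the three predicted
#' probabilities on the validation records, and fits the meta decision
#' rule on them.
#'
#' @param train_records Training records; feature module 2 requires each
#'   record to carry a PSSM.
#' @param val_records Validation records (meta-learner training data).
#' @param rule Stacking rule (see [fit_meta_learner]).
#' @param window Context window half-width shared by the base networks.
#' @param train_cfg A [train_config].
#' @param params [feature_params].
#' @param threshold Final decision threshold (default 0.5).
#' @param verbose Print progress.
#' @return An object of class `stacked_ensemble`.
#' @export
train_stacked_ensemble <- function(train_records, val_records,
                                   rule = "logistic_regression",
                                   window = 32,
                                   train_cfg = train_config(),
                                   params = feature_params(),
                                   threshold = 0.5, verbose = FALSE) {
  base_models <- lapply(0:2, function(fm) {
    if (verbose) message("training base network for feature module ", fm)
    cfg <- net_config(window = window, fmod = fm, params = params)
    train_base_net(train_records, fm, net_cfg = cfg, train_cfg = train_cfg,
                   val_records = val_records, verbose = verbose)$model
  })
  mf <- collect_meta_features(base_models, val_records)
  labels <- unlist(lapply(val_records, `[[`, "labels"))
  meta <- fit_meta_learner(mf, labels, rule)
  structure(list(base_models = base_models, rule = rule,
                 meta_parameters = meta, threshold = threshold),
            class = "stacked_ensemble")
}

#' Predict with a stacked ensemble
#'
#' Computes the three base probabilities per residue and combines them
#' with the ensemble's decision rule; the call is 1 when the combined
#' score reaches the threshold (for voting: the majority of thresholded
#' base calls, with no combined probability emitted).
#'
#' @param ensemble A [train_stacked_ensemble] result (or a manually
#'   assembled `stacked_ensemble`).
#' @param records List of [protein_record] objects.
#' @return Data frame with `id`, `position` (1-based), `score` (NA for
#'   voting) and `call`.
#' @export
ensemble_predict <- function(ensemble, records) {
  stopifnot(inherits(ensemble, "stacked_ensemble"))
  mf <- collect_meta_features(ensemble$base_models, records)
  res <- apply_meta_rule(ensemble$meta_parameters, mf, ensemble$threshold)
  ref <- predict(ensemble$base_models[[1]], records)
  data.frame(id = ref$id, position = ref$position,
             score = res$score, call = res$call, stringsAsFactors = FALSE)
}

#' Save / load a stacked ensemble bundle
#'
#' The bundle directory holds one checkpoint per base network, the meta
#' parameters and a manifest.
#'
#' @param ensemble A `stacked_ensemble`.
#' @param dir Bundle directory.
#' @return `save_ensemble` returns `dir` invisibly; `load_ensemble`
#'   returns the restored ensemble.
#' @export
save_ensemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in ensemble$base_models) {
    save_model(m, file.path(dir, paste0("base_fmod", m$config$fmod, ".rds")))
  }
  saveRDS(ensemble$meta_parameters, file.path(dir, "meta.rds"))
  manifest <- c(paste0("rule\t", ensemble$rule),
                paste0("threshold\t", ensemble$threshold))
  writeLines(manifest, file.path(dir, "manifest.tsv"))
  invisible(dir)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(dir) {
  base_models <- lapply(0:2, function(fm) {
    load_model(file.path(dir, paste0("base_fmod", fm, ".rds")))
  })
  meta <- readRDS(file.path(dir, "meta.rds"))
  manifest <- read.delim(file.path(dir, "manifest.tsv"), header = FALSE,
                         row.names = 1)
  structure(list(base_models = base_models,
                 rule = manifest["rule", 1],
                 meta_parameters = meta,
                 threshold = as.numeric(manifest["threshold", 1])),
            class = "stacked_ensemble")
}
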