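# three quickly trained tiny base models, shared across blocks
tiny_bases <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    sc <- synthetic_config(n_sequences = 16, seed = 21)
    recs <- attach_mock_pssms(generate_dataset(sc), sc)
    models <- lapply(0:2, function(fm) {
      train_base_net(recs, fm,
                     net_cfg = tiny_net_config(fmod = fm, W = 3),
                     train_cfg = train_config(max_epochs = 2,
                                              seed = 21))$model
    })
    cache <<- list(models = models, records = recs)
    cache
  }
})

test_that("meta-features are base probabilities in fixed module order", {
  tb <- tiny_bases()
  some <- tb$records[1:3]
  mf <- collect_meta_features(tb$models, some)
  n <- sum(vapply(some, function(r) nchar(r$sequence), 0L))
  expect_identical(dim(mf), c(n, 3L))
  expect_true(all(mf > 0 & mf < 1))
  # column order follows the module index, not the list order
  mf_rev <- collect_meta_features(rev(tb$models), some)
  expect_equal(mf_rev, mf)
  # deterministic in evaluation mode
  expect_identical(collect_meta_features(tb$models, some), mf)
  untrained <- tb$models
  untrained[[2]]$trained <- FALSE
  expect_error(collect_meta_features(untrained, some), "trained")
  expect_error(collect_meta_features(tb$models[1:2], some), "exactly 3")
})

test_that("meta-learners fit their named rules and reject others", {
  # linearly separable meta-features -> perfect logistic training accuracy
  mf <- rbind(matrix(runif(60, 0, 0.3), 20, 3),
              matrix(runif(60, 0.7, 1), 20, 3))
  y <- rep(c(0, 1), each = 20)
  meta <- suppressWarnings(fit_meta_learner(mf, y, "logistic_regression"))
  pred <- ppistack:::apply_meta_rule(meta, mf)
  expect_identical(pred$call, as.integer(y))

  avg <- fit_meta_learner(mf, y, "averaging")
  expect_null(avg$fit)
  expect_error(fit_meta_learner(mf, y, "boosting"), "unsupported")
  expect_error(fit_meta_learner(mf, rep(1, 40), "logistic_regression"),
               "both classes")
})

test_that("averaging and voting follow their arithmetic definitions", {
  meta_avg <- fit_meta_learner(NULL, NULL, "averaging")
  one <- matrix(c(0.2, 0.4, 0.6), 1)
  r <- ppistack:::apply_meta_rule(meta_avg, one)
  expect_equal(r$score, 0.4)
  expect_identical(r$call, 0L)
  meta_vote <- fit_meta_learner(NULL, NULL, "voting")
  r <- ppistack:::apply_meta_rule(meta_vote, matrix(c(0.9, 0.8, 0.1), 1))
  expect_identical(r$call, 1L)
  expect_true(is.na(r$score))          # voting emits no probability
  r0 <- ppistack:::apply_meta_rule(meta_vote, matrix(c(0.9, 0.2, 0.1), 1))
  expect_identical(r0$call, 0L)
  # both are invariant to base-model ordering
  mf <- ppistack:::with_seed(5, matrix(runif(30), 10, 3))
  for (perm in list(c(2, 1, 3), c(3, 2, 1))) {
    expect_equal(ppistack:::apply_meta_rule(meta_avg, mf[, perm])$score,
                 ppistack:::apply_meta_rule(meta_avg, mf)$score)
    expect_identical(ppistack:::apply_meta_rule(meta_vote, mf[, perm])$call,
                     ppistack:::apply_meta_rule(meta_vote, mf)$call)
  }
})

test_that("logistic stacking sits at the convex optimum", {
  mf <- ppistack:::with_seed(8, matrix(runif(150), 50, 3))
  y <- ppistack:::with_seed(9,
    rbinom(50, 1, plogis(2 * mf[, 1] + mf[, 2] - 1.5)))
  meta <- fit_meta_learner(mf, y, "logistic_regression")
  # independent iterative re-fit of the same convex objective
  beta <- numeric(4)
  Xd <- cbind(1, mf)
  for (it in 1:200) {                      # Newton-Raphson from scratch
    p <- plogis(as.numeric(Xd %*% beta))
    Wd <- p * (1 - p)
    H <- crossprod(Xd * Wd, Xd)
    beta <- beta + solve(H, crossprod(Xd, y - p))
  }
  probs_pkg <- ppistack:::apply_meta_rule(meta, mf)$score
  probs_ora <- plogis(as.numeric(Xd %*% beta))
  expect_equal(probs_pkg, probs_ora, tolerance = 1e-6)
})

test_that("identical base models preserve the single-model ranking", {
  tb <- tiny_bases()
  m0 <- tb$models[[1]]
  clones <- list(m0, tb$models[[2]], tb$models[[3]])
  # force all three columns to the module-0 scores
  some <- tb$records[1:4]
  s <- predict(m0, some)$score
  mf <- cbind(s, s, s)
  # labels positively associated with the shared score
  y <- ppistack:::with_seed(60, rbinom(length(s), 1,
                                       plogis(10 * (s - median(s)))))
  meta_avg <- fit_meta_learner(NULL, NULL, "averaging")
  expect_identical(order(ppistack:::apply_meta_rule(meta_avg, mf)$score),
                   order(s))
  meta_lr <- fit_meta_learner(mf, y, "logistic_regression")
  sc <- ppistack:::apply_meta_rule(meta_lr, mf)$score
  expect_identical(order(sc), order(s))
})

test_that("alternative trainable rules produce scored calls", {
  skip_if_not_installed("rpart")
  skip_if_not_installed("randomForest")
  skip_if_not_installed("class")
  mf <- ppistack:::with_seed(10, matrix(runif(240), 80, 3))
  y <- as.integer(rowMeans(mf) > 0.5)
  for (rule in c("decision_tree", "random_forest", "nearest_neighbor",
                 "linear_mse")) {
    meta <- fit_meta_learner(mf, y, rule)
    r <- ppistack:::apply_meta_rule(meta, mf)
    expect_length(r$score, 80)
    expect_true(all(r$call %in% 0:1))
  }
})

test_that("ensemble bundles round-trip through disk", {
  tb <- tiny_bases()
  mf <- collect_meta_features(tb$models, tb$records)
  y <- unlist(lapply(tb$records, `[[`, "labels"))
  ens <- structure(list(base_models = tb$models,
                        rule = "logistic_regression",
                        meta_parameters = fit_meta_learner(
                          mf, y, "logistic_regression"),
                        threshold = 0.5),
                   class = "stacked_ensemble")
  pred <- ensemble_predict(ens, tb$records[1:2])
  expect_true(all(c("id", "position", "score", "call") %in% names(pred)))
  d <- withr::local_tempdir()
  save_ensemble(ens, d)
  back <- load_ensemble(d)
  pred2 <- ensemble_predict(back, tb$records[1:2])
  expect_equal(pred2$score, pred$score)
  expect_identical(back$rule, "logistic_regression")
})
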