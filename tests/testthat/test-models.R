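separable_data <- function(n_per = 40, n_participants = 8, seed = 2) {
  sleepstager:::with_seed(seed, {
    y <- factor(sample(c("A", "B"), n_per * n_participants, replace = TRUE))
    X <- cbind(x1 = ifelse(y == "A", 1, -1) + rnorm(length(y), 0, 0.05),
               x2 = rnorm(length(y)))
    list(X = X, y = y,
         ids = rep(sprintf("p%02d", seq_len(n_participants)),
                   each = n_per))
  })
}

test_that("grouped folds partition participants evenly and reproducibly", {
  f <- make_grouped_folds(sprintf("p%d", 1:10), 5, 1)
  expect_length(f, 5)
  expect_true(all(lengths(f) == 2))
  f11 <- make_grouped_folds(sprintf("p%d", 1:11), 5, 1)
  expect_equal(unname(sort(lengths(f11), decreasing = TRUE)),
               c(3L, 2L, 2L, 2L, 2L))
  expect_setequal(unlist(f11), sprintf("p%d", 1:11))
  expect_identical(make_grouped_folds(letters[1:10], 5, 7),
                   make_grouped_folds(letters[1:10], 5, 7))
  expect_error(make_grouped_folds(letters[1:3], 5, 1), "exceeds")
})

test_that("a tree ensemble separates linearly separable data perfectly", {
  d <- separable_data()
  m <- fit_ml(d$X, d$y, d$ids, search_spec("gboost", budget = 1, seed = 1))
  pred <- predict(m, d$X)
  expect_equal(mcc(confusion(as.character(d$y), as.character(pred))), 1)
  expect_error(fit_ml(d$X, factor(rep("A", nrow(d$X))), d$ids,
                      search_spec("gboost", budget = 1)), "single class")
})

test_that("in-fold standardization parameters come from training rows
           only", {
  d <- separable_data()
  spec <- search_spec("svm", budget = 1, seed = 3,
                      space = list(cost = 1, k_best = Inf))
  m <- fit_ml(d$X, d$y, d$ids, spec)
  folds <- m$metadata$folds
  for (fi in seq_along(folds)) {
    tr_rows <- !(d$ids %in% folds[[fi]])
    expect_equal(m$metadata$fold_preproc[[fi]]$center,
                 colMeans(d$X[tr_rows, ]), tolerance = 1e-12)
    expect_equal(m$metadata$fold_preproc[[fi]]$scale,
                 apply(d$X[tr_rows, ], 2, sd), tolerance = 1e-12)
  }
  # perturbing held-out rows must not change fitted fold parameters
  d2 <- d
  val_rows <- d$ids %in% folds[[1]]
  d2$X[val_rows, ] <- d2$X[val_rows, ] + 100
  m2 <- fit_ml(d2$X, d2$y, d2$ids, spec)
  expect_equal(m2$metadata$fold_preproc[[1]]$center,
               m$metadata$fold_preproc[[1]]$center, tolerance = 1e-12)
  expect_equal(m2$metadata$fold_preproc[[1]]$scale,
               m$metadata$fold_preproc[[1]]$scale, tolerance = 1e-12)
})

test_that("select-k-best ranks discriminative features first", {
  d <- separable_data()
  Z <- sleepstager:::standardize_apply(d$X,
                                       sleepstager:::standardize_fit(d$X))
  sel <- sleepstager:::select_k_best(Z, d$y, 1)
  expect_equal(sel, 1L)
})

test_that("prediction realigns named columns and handles empty input", {
  d <- separable_data()
  m <- fit_ml(d$X, d$y, d$ids,
              search_spec("random_forest", budget = 1, seed = 2))
  shuffled <- d$X[, c("x2", "x1")]
  expect_equal(as.character(predict(m, shuffled)),
               as.character(predict(m, d$X)))
  empty <- predict(m, d$X[0, , drop = FALSE])
  expect_length(empty, 0)
  expect_equal(levels(empty), m$classes)
  expect_error(predict(m, d$X[, "x1", drop = FALSE]), "missing")
})

test_that("every classical family trains and predicts on a small task", {
  d <- separable_data(n_per = 25, n_participants = 6, seed = 4)
  for (alg in c("svm", "mlp", "adaboost", "random_forest", "gboost")) {
    spec <- search_spec(alg, budget = 1, k_folds = 2, seed = 5,
                        space = switch(alg,
                                       adaboost = list(n_rounds = 10,
                                                       depth = 1),
                                       default_space(alg)))
    m <- fit_ml(d$X, d$y, d$ids, spec)
    pred <- predict(m, d$X)
    acc <- mean(as.character(pred) == as.character(d$y))
    expect_gt(acc, 0.9)
  }
})

test_that("sequence windows are centered, participant-pure and padded", {
  n <- 60
  X <- matrix(seq_len(n * 2), n, 2,
              dimnames = list(NULL, c("a", "b")))
  y <- factor(rep(c("A", "B"), n / 2))
  ids <- rep(c("p1", "p2"), each = n / 2)
  ds <- make_sequences(X, y, ids, length_minutes = 10)
  expect_equal(ds$length_epochs, 20L)
  expect_equal(dim(ds$windows), c(n, 20L, 2L))
  # no window mixes participants: row 31 (first of p2) has only p2 data
  expect_true(all(ds$mask[31, 1:10] == FALSE))
  # interior center of p1 is fully masked-in
  expect_true(all(ds$mask[15, ]))
  # padded slots are exactly zero
  expect_true(all(ds$windows[1, 1:10, ] == 0))
  # z-normalization stats reusable
  ds2 <- make_sequences(X, y, ids, 10, norm_stats = ds$norm_stats)
  expect_equal(ds2$windows, ds$windows)
})

test_that("the recurrent model learns a center-determined task and
           checkpoints deterministically", {
  sleepstager:::with_seed(1, {
    n <- 800; f <- 3
    X <- matrix(rnorm(n * f), n, f,
                dimnames = list(NULL, paste0("x", 1:f)))
    y <- factor(ifelse(X[, 1] > 0, "A", "B"))
    ids <- rep(sprintf("p%02d", 1:10), each = n / 10)
    assign("seq_fixture", list(X = X, y = y, ids = ids),
           envir = globalenv())
  })
  fx <- get("seq_fixture", envir = globalenv())
  tr_sel <- fx$ids %in% sprintf("p%02d", 1:8)
  tr <- make_sequences(fx$X[tr_sel, ], fx$y[tr_sel], fx$ids[tr_sel], 10)
  va <- make_sequences(fx$X[!tr_sel, ], fx$y[!tr_sel], fx$ids[!tr_sel],
                       10, norm_stats = tr$norm_stats)
  m <- fit_sequence_model(tr, va, hidden = 16, epochs = 20, seed = 5)
  pred <- predict(m, va)
  expect_gt(mcc(confusion(as.character(va$labels), as.character(pred))),
            0.95)
  # zero epochs returns initial weights
  m0 <- fit_sequence_model(tr, va, hidden = 16, epochs = 0, seed = 5)
  expect_equal(m0$metadata$epochs, 0)
  expect_s3_class(predict(m0, va), "factor")
  # determinism under a fixed seed
  m1 <- fit_sequence_model(tr, va, hidden = 8, epochs = 3, seed = 9)
  m2 <- fit_sequence_model(tr, va, hidden = 8, epochs = 3, seed = 9)
  expect_identical(m1$est$par, m2$est$par)
  # shared participants between train and validation are rejected
  expect_error(fit_sequence_model(tr, tr), "share participants")
  rm("seq_fixture", envir = globalenv())
})
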