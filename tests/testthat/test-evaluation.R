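# independent binary MCC oracle, straight from the confusion-matrix cells
mcc_binary_oracle <- function(cm) {
  tn <- cm[1, 1]; fp <- cm[1, 2]; fn <- cm[2, 1]; tp <- cm[2, 2]
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

test_that("confusion matrices count true/predicted pairs", {
  cm <- confusion(c("W", "S", "S"), c("S", "S", "S"), c("W", "S"))
  expect_equal(unclass(cm),
               matrix(c(0L, 0L, 1L, 2L), 2, 2,
                      dimnames = list(true = c("W", "S"),
                                      predicted = c("W", "S"))))
  ident <- confusion(c("A", "B", "A"), c("A", "B", "A"), c("A", "B"))
  expect_true(all(ident[row(ident) != col(ident)] == 0))
  empty <- confusion(character(0), character(0), c("A", "B"))
  expect_equal(sum(empty), 0)
  expect_error(confusion("X", "A", c("A", "B")), "unknown label")
  expect_error(confusion(c("A", "B"), "A", c("A", "B")), "length")
})

test_that("MCC reproduces the worked binary value and degenerate rules", {
  cm <- matrix(c(4, 2, 1, 3), 2, 2)  # TN=4, FN=2, FP=1, TP=3
  expect_equal(mcc(cm), 10 / sqrt(600), tolerance = 1e-12)
  perfect <- diag(c(5, 3, 2))
  expect_equal(mcc(perfect), 1)
  onecol <- matrix(c(0, 0, 5, 5), 2, 2)  # everything predicted one class
  expect_equal(mcc(onecol), 0)
})

test_that("multiclass MCC equals the binary formula on 2x2 matrices", {
  for (seed in 1:200) {
    cm <- sleepstager:::with_seed(seed,
      matrix(rpois(4, lambda = 8), 2, 2))
    expect_equal(mcc(cm), mcc_binary_oracle(cm), tolerance = 1e-12)
  }
})

test_that("MCC and macro metrics are invariant to class reordering", {
  cm <- matrix(c(30, 4, 2, 5, 40, 6, 1, 3, 50), 3, 3,
               dimnames = list(true = c("A", "B", "C"),
                               predicted = c("A", "B", "C")))
  perm <- c(3, 1, 2)
  cmp <- cm[perm, perm]
  expect_equal(mcc(cm), mcc(cmp), tolerance = 1e-12)
  m1 <- metrics(cm); m2 <- metrics(cmp)
  for (f in names(m1)) expect_equal(m1[[f]], m2[[f]], tolerance = 1e-12)
})

test_that("the metric suite matches hand arithmetic on a binary matrix", {
  cm <- confusion(c(rep("WAKE", 5), rep("SLEEP", 5)),
                  c(rep("WAKE", 4), "SLEEP", "WAKE", "WAKE",
                    rep("SLEEP", 3)),
                  c("WAKE", "SLEEP"))
  m <- metrics(cm)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$f1, 2 / 3)
  expect_equal(m$accuracy, 0.7)
  perf <- metrics(diag(c(3L, 4L)))
  expect_equal(unname(unlist(perf)), rep(1, 6), tolerance = 1e-12)
})

test_that("MCC is 1 exactly when the matrix is diagonal (small exhaustive)", {
  for (a in 0:2) for (b in 0:2) for (c_ in 0:2) for (d in 0:2) {
    cm <- matrix(c(a, c_, b, d), 2, 2)
    if (sum(cm) == 0) next
    if (abs(mcc(cm) - 1) < 1e-12) expect_true(b == 0 && c_ == 0)
    if (b == 0 && c_ == 0 && a > 0 && d > 0) expect_equal(mcc(cm), 1)
  }
})

test_that("per-participant tables aggregate with a sort-based oracle", {
  y <- rep(c("W", "S"), 50)
  p <- y; p[c(3, 10, 41)] <- ifelse(y[c(3, 10, 41)] == "W", "S", "W")
  single <- per_participant(y, p, rep("only", 100))
  expect_equal(nrow(single$table), 1L)
  expect_equal(single$table$accuracy, metrics(confusion(y, p))$accuracy)
  twice <- per_participant(c(y, y), c(p, p), rep(c("a", "b"), each = 100))
  expect_equal(twice$table$mcc[1], twice$table$mcc[2])
  expect_equal(twice$summary$iqr[1], 0)
  # 20 simulated participants vs independent sort-based median/IQR
  accs <- sleepstager:::with_seed(5, runif(20))
  yy <- unlist(lapply(accs, function(a)
    c(rep("W", 50), rep("S", 50))))
  pp <- unlist(lapply(accs, function(a) {
    flip <- sleepstager:::with_seed(round(a * 1e6), runif(100) < a)
    truth <- c(rep("W", 50), rep("S", 50))
    ifelse(flip, ifelse(truth == "W", "S", "W"), truth)
  }))
  ids <- rep(sprintf("p%02d", 1:20), each = 100)
  res <- per_participant(yy, pp, ids)
  acc_sorted <- sort(res$table$accuracy)
  expect_equal(res$summary$median[res$summary$metric == "accuracy"],
               median(acc_sorted))
  expect_equal(res$summary$iqr[res$summary$metric == "accuracy"],
               quantile(acc_sorted, 0.75, names = FALSE) -
                 quantile(acc_sorted, 0.25, names = FALSE))
})

test_that("rank-sum comparisons apply Bonferroni and star notation", {
  expect_warning(same <- compare_conditions(rep(1, 5), rep(1, 5), 1),
                 "identical")
  expect_equal(same$p_adjusted, 1)
  expect_equal(same$stars, "")
  sep <- compare_conditions(1:10, 11:20, 1)
  expect_equal(unname(sep$statistic), 0)
  expect_lt(sep$p_raw, 0.001)
  expect_equal(sep$stars, "***")
  # Bonferroni multiplication
  a <- c(1, 2, 3, 4, 10); b <- c(5, 6, 7, 8, 9)
  one <- compare_conditions(a, b, 1)
  four <- compare_conditions(a, b, 4)
  expect_equal(four$p_adjusted, min(1, one$p_raw * 4))
  expect_error(compare_conditions(numeric(0), 1:3), "non-empty")
})
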