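test_that("stratified folds are disjoint, exhaustive, and balanced", {
  d <- data.frame(y = rep(c("a", "b", "c"), times = c(40, 35, 25)),
                  x = "v", stringsAsFactors = FALSE)
  folds <- stratified_kfold(d, "y", 5, seed = 3)
  test_idx <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_equal(test_idx, seq_len(100))
  sizes <- vapply(folds, function(f) length(f$test), 1L)
  expect_lte(diff(range(sizes)), 1)
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_equal(sort(c(f$train, f$test)), seq_len(100))
    props <- table(factor(d$y[f$test], levels = c("a", "b", "c")))
    expect_true(all(abs(props - c(8, 7, 5)) <= 1))
  }
  expect_identical(stratified_kfold(d, "y", 5, seed = 3), folds)
  expect_false(identical(stratified_kfold(d, "y", 5, seed = 4), folds))
  # leave-one-out on a balanced toy set
  small <- data.frame(y = rep(c("a", "b"), 3), stringsAsFactors = FALSE)
  suppressWarnings(loo <- stratified_kfold(small, "y", 6, seed = 1))
  expect_true(all(vapply(loo, function(f) length(f$test), 1L) == 1))
  expect_error(stratified_kfold(small, "y", 7, seed = 1),
               class = "gbn_stratification")
})

test_that("instance classification factorises like naive Bayes", {
  net <- build_fixture("naive4", seed = 5)
  row <- ancestral_sample(net, 1, seed = 51)
  post <- classify_instance(net, "Class", row)
  # posterior proportional to prior times per-feature likelihoods
  prior <- infer_posterior(net, "Class")
  lik <- vapply(net$variables$Class, function(cl) {
    prod(vapply(paste0("F", 1:4), function(f) {
      net$cpts[[f]]$prob[row[[f]][1], cl]
    }, 1.0))
  }, 1.0)
  manual <- prior * lik
  expect_equal(unname(post), unname(manual / sum(manual)), tolerance = 1e-12)
  expect_equal(post, brute_force_posterior(net, "Class",
                                           unlist(row[1, paste0("F", 1:4)])),
               tolerance = 1e-10)
})

test_that("metrics match hand-computed values on a six-record set", {
  # binary problem, hand-built confusion matrix:
  # truth:  pos pos pos pos neg neg ; pred: pos pos neg pos neg pos
  prob <- rbind(c(0.9, 0.1), c(0.8, 0.2), c(0.4, 0.6),
                c(0.7, 0.3), c(0.2, 0.8), c(0.6, 0.4))
  colnames(prob) <- c("pos", "neg")
  truth <- c("pos", "pos", "pos", "pos", "neg", "neg")
  rec <- prediction_records(truth, prob)
  m <- compute_metrics(rec)
  # accuracy: 4 of 6 correct
  expect_equal(m$accuracy, 100 * 4 / 6)
  # pos: TP=3 FP=1 FN=1 -> F1 = 6/8; neg: TP=1 FP=1 FN=1 -> F1 = 1/2
  expect_equal(m$f_measure, (4 / 6) * 0.75 + (2 / 6) * 0.5)
  # AUC (pos scores .9 .8 .4 .7 vs .2 .6): pairs won 7/8
  expect_equal(m$auc, (4 / 6) * (7 / 8) + (2 / 6) * (7 / 8))
  # macro flag
  expect_equal(compute_metrics(rec, macro = TRUE)$f_measure,
               mean(c(0.75, 0.5)))
})

test_that("perfect and uninformative predictors hit the metric endpoints", {
  truth <- rep(c("a", "b"), each = 10)
  perfect <- prediction_records(truth, {
    p <- matrix(0, 20, 2, dimnames = list(NULL, c("a", "b")))
    p[cbind(seq_len(20), match(truth, c("a", "b")))] <- 1
    p
  })
  m <- compute_metrics(perfect)
  expect_equal(m$accuracy, 100)
  expect_equal(m$f_measure, 1)
  expect_equal(m$auc, 1)
  flat <- prediction_records(truth, matrix(0.5, 20, 2,
                                           dimnames = list(NULL, c("a", "b"))))
  expect_equal(compute_metrics(flat)$auc, 0.5)
  one_class <- prediction_records(rep("a", 5),
                                  matrix(c(1, 0)[c(1, 1, 1, 1, 1, 2, 2, 2, 2, 2)],
                                         5, 2, dimnames = list(NULL, c("a", "b"))))
  expect_error(compute_metrics(one_class), class = "gbn_degenerate_input")
})

test_that("metrics are invariant to record order", {
  prob <- withr::with_seed(5, {
    m <- matrix(runif(60), 30, 2)
    m / rowSums(m)
  })
  colnames(prob) <- c("a", "b")
  truth <- rep(c("a", "b"), 15)
  m1 <- compute_metrics(prediction_records(truth, prob))
  perm <- withr::with_seed(6, sample(30))
  m2 <- compute_metrics(prediction_records(truth[perm], prob[perm, ]))
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("binary AUC equals the pairwise Mann-Whitney count", {
  withr::with_seed(11, {
    n <- 150
    truth <- sample(c("a", "b"), n, replace = TRUE, prob = c(0.4, 0.6))
    pa <- runif(n)
    prob <- cbind(a = pa, b = 1 - pa)
    rec <- prediction_records(truth, prob)
    auc <- compute_metrics(rec)$auc
    # direct pairwise count with half-credit ties, per class, weighted
    direct <- vapply(c("a", "b"), function(cl) {
      s <- prob[, cl]
      pos <- s[truth == cl]; neg <- s[truth != cl]
      cmp <- outer(pos, neg, function(x, y) (x > y) + 0.5 * (x == y))
      mean(cmp)
    }, 1.0)
    w <- c(mean(truth == "a"), mean(truth == "b"))
    expect_equal(auc, sum(w * direct), tolerance = 1e-12)
  })
})

test_that("cross-validation pools every row exactly once and is seeded", {
  net <- build_fixture("naive4", seed = 2)
  d <- ancestral_sample(net, 600, seed = 22)
  ev1 <- evaluate_models(d, "Class", models = c("nb"), k = 5, seed = 9)
  ev2 <- evaluate_models(d, "Class", models = c("nb"), k = 5, seed = 9)
  expect_equal(as.data.frame(ev1), as.data.frame(ev2))
  rec <- attr(ev1, "records")$nb
  expect_equal(length(rec$truth), nrow(d))
  expect_true(all(abs(rowSums(rec$prob) - 1) <= 1e-9))
  expect_true(ev1$accuracy > 100 / 3)  # beats chance on its own fixture
})

test_that("label permutation drops accuracy to the majority-class rate", {
  net <- build_fixture("naive4", seed = 4)
  d <- ancestral_sample(net, 1500, seed = 44)
  d$Class <- withr::with_seed(45, sample(d$Class))
  ev <- evaluate_models(d, "Class", models = c("nb"), k = 5, seed = 10)
  maj <- 100 * max(table(d$Class)) / nrow(d)
  # permuted labels carry no signal; accuracy within simulation error of the
  # best constant classifier (a few points of slack at n = 1500)
  expect_lt(abs(ev$accuracy - maj), 6)
})
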