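test_that("five-fold splits partition positives and unlabelled pairs", {
  study <- tiny_study(m = 20, n = 5, seed = 2, q = 0.1, reveal = 1)
  ds <- study$dataset  # exactly 10 known positives
  folds <- split_5fold(ds, seed = 9)
  pos_keys <- pair_key_of(which(ds$A == 1, arr.ind = TRUE))
  unl_keys <- pair_key_of(which(ds$A == 0, arr.ind = TRUE))
  test_pos_keys <- lapply(folds, function(f) pair_key_of(f$test_pos))
  test_unl_keys <- lapply(folds, function(f) pair_key_of(f$test_unl))
  expect_setequal(unlist(test_pos_keys), pos_keys)
  expect_setequal(unlist(test_unl_keys), unl_keys)
  expect_equal(sum(lengths(test_pos_keys)), length(pos_keys))  # disjoint
  expect_equal(sum(lengths(test_unl_keys)), length(unl_keys))
  for (f in folds) {
    expect_length(intersect(pair_key_of(f$test_pos),
                            pair_key_of(f$train_pos)), 0)
    expect_true(all(f$A_train[f$test_pos] == 0))
    expect_true(all(f$A_train[f$train_pos] == 1))
  }
  # 10 positives -> five test subsets of 2
  sizes <- vapply(folds, function(f) nrow(f$test_pos), 0L)
  expect_equal(sort(sizes), rep(sum(ds$A) / 5, 5))
})

test_that("rank index follows its closed forms", {
  expect_equal(rank_index(c(10, 9:1), positive = 1), 0.1)
  expect_equal(rank_index(c(1, 10:2), positive = 1), 1.0)
  for (N in c(4, 9)) {
    expect_equal(rank_index(stats::runif(N), positive = seq_len(N)),
                 (N + 1) / (2 * N))
  }
  expect_error(rank_index(1:5, positive = integer()), "empty positive")
  # a uniformly random ranking concentrates near 1/2
  set.seed(99)
  ri <- replicate(200, rank_index(stats::rnorm(50), positive = sample(50, 10)))
  expect_equal(mean(ri), (50 + 1) / (2 * 50), tolerance = 0.02)
})

test_that("AUC matches the Mann-Whitney statistic; AUPR integrates the PR curve", {
  expect_equal(auc_aupr(c(3, 2, 1, 0), c(1, 1, 0, 0))$auc, 1)
  set.seed(17)
  for (i in 1:50) {
    n <- sample(10:40, 1)
    scores <- stats::rnorm(n)
    if (i %% 3 == 0) scores <- round(scores)  # exercise ties
    labels <- stats::rbinom(n, 1, 0.4)
    if (sum(labels) %in% c(0, n)) labels[c(1, n)] <- c(0, 1)
    met <- auc_aupr(scores, labels)
    expect_equal(met$auc, auc_oracle(scores, labels))
    rev_ <- auc_aupr(-scores, labels)
    expect_equal(rev_$auc, 1 - met$auc)
  }
  # label-independent scores give AUC near 1/2 (Monte-Carlo, seeded)
  set.seed(31)
  big <- auc_aupr(stats::rnorm(4000), stats::rbinom(4000, 1, 0.3))
  expect_equal(big$auc, 0.5, tolerance = 0.03)
  # hand-integrated PR curve: scores 4,3,2,1 with labels 1,0,1,0
  expect_equal(auc_aupr(c(4, 3, 2, 1), c(1, 0, 1, 0))$aupr,
               0.5 * 1 + 0.5 * (2 / 3))
  expect_error(auc_aupr(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("per-disease top-percent flags obey rank and monotone invariance", {
  sc <- matrix(stats::rnorm(50), 10, 5,
               dimnames = list(paste0("p", 1:10), paste0("d", 1:5)))
  fl <- top_percent_flags(sc, "d2", q = 0.1)
  expect_length(fl, 1)
  expect_equal(fl, names(which.max(sc[, "d2"])))
  expect_length(top_percent_flags(sc, "d1", q = 1), 10)
  expect_equal(top_percent_flags(exp(sc), "d3", q = 0.3),
               top_percent_flags(sc, "d3", q = 0.3))
})

test_that("no test-fold positive influences any training artifact", {
  study <- tiny_study(m = 16, n = 5, seed = 8, q = 0.2)
  ds <- study$dataset
  cfg <- tiny_config(rf_estimators = 60L, epochs = 10L)
  pos <- which(ds$A == 1, arr.ind = TRUE)
  unl <- which(ds$A == 0, arr.ind = TRUE)
  flip <- pos[1, , drop = FALSE]           # the test positive to flip
  test_pos <- pos[1:3, , drop = FALSE]
  train_pos <- pos[-(1:3), , drop = FALSE]
  test_unl <- unl[1:5, , drop = FALSE]
  train_unl <- unl[-(1:5), , drop = FALSE]
  artifacts <- function(A_full) {
    A_train <- A_full
    A_train[test_pos] <- 0
    ds2 <- ds; ds2$A <- A_train
    S_p <- pirna_similarity(ds2, config = cfg)
    S_d <- disease_similarity(ds2, study$ontology, config = cfg)
    rn <- select_negatives("spy", train_pos, train_unl, S_p, S_d, cfg,
                           seed = 1)
    model <- pda_train(ds, study$ontology, cfg, positives = train_pos,
                       negatives = rn$pairs, A_train = A_train)
    list(S_p = S_p, S_d = S_d, rn = rn$pairs, loss = model$loss_trace)
  }
  A_flipped <- ds$A
  A_flipped[flip] <- 0                     # as if the pair were never known
  a1 <- artifacts(ds$A)
  a2 <- artifacts(A_flipped)
  expect_identical(a1$S_p, a2$S_p)
  expect_identical(a1$S_d, a2$S_d)
  expect_identical(a1$rn, a2$rn)
  expect_identical(a1$loss, a2$loss)
})

test_that("cross-validation is deterministic and honours the PU method switch", {
  study <- tiny_study(m = 16, n = 5, seed = 4, q = 0.2)
  cfg <- tiny_config(rf_estimators = 40L, epochs = 15L, seed = 2)
  r1 <- run_cv(study$dataset, study$ontology, cfg, pul_method = "none",
               folds = 1L)
  r2 <- run_cv(study$dataset, study$ontology, cfg, pul_method = "none",
               folds = 1L)
  expect_identical(r1$mean, r2$mean)
  expect_s3_class(r1$per_fold, "data.frame")
  expect_true(all(r1$mean[c("auc", "aupr")] >= 0 &
                  r1$mean[c("auc", "aupr")] <= 1))
  # with no PU selection every training unlabelled pair is a negative
  folds <- split_5fold(study$dataset, seed = cfg$seed)
  expect_equal(r1$per_fold$n_reliable_neg, nrow(folds[[1]]$train_unl))
})
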