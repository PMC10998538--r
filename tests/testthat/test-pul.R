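test_that("pair features concatenate similarity rows", {
  S_p <- matrix(c(1, .5, .5, 1), 2, 2)
  S_d <- diag(2)
  expect_equal(drop(pair_features(S_p, S_d, cbind(1, 2))), c(1, .5, 0, 1))
  prs <- rbind(c(1, 1), c(1, 2))
  F2 <- pair_features(S_p, S_d, prs)
  expect_equal(ncol(F2), 4)
  expect_equal(F2[1, 1:2], F2[2, 1:2])
  expect_error(pair_features(S_p, S_d, cbind(3, 1)), "out of range")
})

# separable toy: two blocks of piRNAs with distinct similarity rows; block 1
# pairs are positive, block 2 pairs unlabelled true negatives
separable_toy <- function(n_pos = 10, n_unl = n_pos) {
  m <- n_pos + n_unl
  S_p <- matrix(0.05, m, m)
  S_p[seq_len(n_pos), seq_len(n_pos)] <- 0.9
  S_p[(n_pos + 1):m, (n_pos + 1):m] <- 0.6
  diag(S_p) <- 1
  S_d <- diag(2); S_d[S_d == 0] <- 0.3
  positives <- cbind(seq_len(n_pos), 1L)
  unlabelled <- cbind((n_pos + 1L):m, 1L)
  list(S_p = S_p, S_d = S_d, positives = positives, unlabelled = unlabelled)
}

test_that("spy selection keeps pairs scoring below every spy", {
  toy <- separable_toy()
  cfg <- tiny_config(rf_estimators = 200L)
  rn <- spy_select(toy$positives, toy$unlabelled, toy$S_p, toy$S_d, cfg,
                   seed = 0)
  expect_equal(nrow(rn$pairs), 10)
  expect_true(all(attr(rn, "posteriors")[
    pair_key_of(toy$unlabelled) %in% pair_key_of(rn$pairs)] <
      attr(rn, "threshold")))
  # empty unlabelled set returns an empty selection
  empty <- spy_select(toy$positives, toy$unlabelled[0, , drop = FALSE],
                      toy$S_p, toy$S_d, cfg)
  expect_equal(nrow(empty$pairs), 0)
})

test_that("spy selection with exchangeable classes honours its threshold contract", {
  # positives and unlabelled drawn from one distribution: the selection is
  # then exactly the set of unlabelled pairs scoring below the weakest spy
  m_half <- 12
  set.seed(2)
  S_p <- matrix(0.5, 2 * m_half, 2 * m_half) +
    matrix(rnorm((2 * m_half)^2, sd = 0.02), 2 * m_half)
  S_p <- (S_p + t(S_p)) / 2; diag(S_p) <- 1
  S_d <- diag(2)
  unl <- cbind((m_half + 1L):(2L * m_half), 1L)
  rn <- spy_select(cbind(seq_len(m_half), 1L), unl,
                   S_p, S_d, tiny_config(rf_estimators = 200L), seed = 1)
  below <- attr(rn, "posteriors") < attr(rn, "threshold")
  expect_identical(pair_key_of(rn$pairs),
                   pair_key_of(unl[below, , drop = FALSE]))
})

test_that("three-cluster score partition returns the middle mode", {
  scores <- c(runif(20, 0.88, 0.92), runif(25, 0.48, 0.52),
              runif(30, 0.08, 0.12))
  cl <- pdaLink:::cluster_scores_3(scores)
  expect_false(cl$degenerate)
  expect_setequal(cl$middle, 21:45)
  # degenerate: identical scores fall back to the lowest tertile, flagged
  cld <- pdaLink:::cluster_scores_3(rep(0.5, 9))
  expect_true(cld$degenerate)
  expect_length(cld$middle, 3)
})

test_that("bagging selection stays inside the unlabelled set", {
  toy <- separable_toy(n_pos = 8, n_unl = 20)
  cfg <- tiny_config(rf_estimators = 100L)
  rn <- bagging_select(toy$positives, toy$unlabelled, toy$S_p, toy$S_d, cfg,
                       seed = 3)
  expect_true(all(pair_key_of(rn$pairs) %in% pair_key_of(toy$unlabelled)))
  expect_length(intersect(pair_key_of(rn$pairs),
                          pair_key_of(toy$positives)), 0)
  expect_length(attr(rn, "scores"), nrow(toy$unlabelled))
})

test_that("two-step confirms separable negatives and excludes promoted pairs", {
  toy <- separable_toy()
  cfg <- tiny_config(rf_estimators = 200L, two_step_iters = 3L)
  rn <- two_step_select(toy$positives, toy$unlabelled, toy$S_p, toy$S_d,
                        cfg, seed = 0)
  expect_true(all(pair_key_of(rn$pairs) %in% pair_key_of(toy$unlabelled)))
  expect_gte(nrow(rn$pairs), 8)  # the dissimilar block is confirmed negative
  expect_error(two_step_select(toy$positives[0, , drop = FALSE],
                               toy$unlabelled, toy$S_p, toy$S_d, cfg),
               "non-empty")
})

test_that("the union merges pair sets and provenance", {
  a <- pdaLink:::new_rn_set(cbind(1L, 1L), "spy")
  b <- pdaLink:::new_rn_set(cbind(2L, 1L), "bagging")
  c0 <- pdaLink:::new_rn_set(matrix(integer(), 0, 2), "two_step")
  u <- combine_union(list(a, b, c0))
  expect_equal(nrow(u$pairs), 2)
  expect_setequal(u$method, c("spy", "bagging", "two_step"))
  expect_equal(combine_union(list(a, a))$pairs, a$pairs)
  expect_gte(nrow(u$pairs), max(nrow(a$pairs), nrow(b$pairs), nrow(c0$pairs)))
})

test_that("no selector ever returns a known positive (fuzz)", {
  for (seed in 1:2) {
    study <- gen_study(m = 20, n = 5, q = 0.2, reveal = 0.8, seed = seed)
    ds <- study$dataset
    cfg <- tiny_config(rf_estimators = 60L)
    S_p <- pirna_similarity(ds, config = cfg)
    S_d <- disease_similarity(ds, study$ontology, config = cfg)
    pos <- which(ds$A == 1, arr.ind = TRUE)
    unl <- which(ds$A == 0, arr.ind = TRUE)
    for (meth in c("spy", "bagging", "two_step", "combined")) {
      rn <- select_negatives(meth, pos, unl, S_p, S_d, cfg, seed = seed)
      expect_length(intersect(pair_key_of(rn$pairs), pair_key_of(pos)), 0)
      expect_true(all(pair_key_of(rn$pairs) %in% pair_key_of(unl)))
    }
  }
})
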