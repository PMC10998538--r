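test_that("graph convolution layer matches hand-computed cases", {
  H <- matrix(c(1, 2, -1, 0), 2, 2)
  expect_equal(gcn_layer(diag(2), H, diag(2)),
               matrix(c(1, 2, 0, 0), 2, 2))
  A_h <- matrix(1, 2, 2)
  expect_equal(gcn_layer(A_h, matrix(c(2, 0, 0, 2), 2, 2), diag(2)),
               matrix(1, 2, 2))
  expect_equal(gcn_layer(diag(2), H, matrix(0, 2, 2)), matrix(0, 2, 2))
  expect_error(gcn_layer(matrix(0, 2, 2), H, diag(2)), "zero-degree")
})

test_that("symmetric-normalised adjacency has spectral radius at most 1", {
  for (seed in 1:3) {
    study <- gen_study(m = 12, n = 5, q = 0.2, seed = seed)
    ds <- study$dataset
    S_p <- fuse_mean(seq_similarity(ds$pirnas), gip_similarity(ds$A))
    S_d <- fuse_mean(semantic_similarity(study$ontology, ds$diseases),
                     gip_similarity(t(ds$A)))
    Ahat <- pdaLink:::normalize_adjacency(build_hetero(S_p, ds$A, S_d))
    ev <- eigen(Ahat, symmetric = TRUE, only.values = TRUE)$values
    expect_lte(max(abs(ev)), 1 + 1e-10)
  }
})

test_that("scaled dot-product attention: degenerate keys and weight rows", {
  V <- matrix(c(3, 1, 4, 1), 1, 4)
  out <- scaled_dot_attention(matrix(rnorm(12), 3, 4),
                              matrix(rnorm(4), 1, 4), V, d_k = 4)
  for (r in 1:3) expect_equal(unname(out[r, ]), drop(V))

  # two keys with equal logits average the value rows
  K <- rbind(rep(0, 4), rep(0, 4))
  V2 <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  out2 <- scaled_dot_attention(matrix(rnorm(8), 2, 4), K, V2, d_k = 4)
  attributes(out2) <- list(dim = dim(out2))
  expect_equal(out2, rbind(c(.5, .5, 0, 0), c(.5, .5, 0, 0)))

  W <- attr(scaled_dot_attention(matrix(rnorm(20), 5, 4),
                                 matrix(rnorm(12), 3, 4),
                                 matrix(rnorm(12), 3, 4), 4), "weights")
  expect_equal(unname(rowSums(W)), rep(1, 5))
  expect_error(scaled_dot_attention(V, V, V, 0), "positive")
})

test_that("multi-head attention reduces to single-head block algebra", {
  set.seed(21)
  d <- 4
  Q <- matrix(rnorm(20), 5, d); K <- matrix(rnorm(12), 3, d)
  V <- matrix(rnorm(12), 3, d)
  # h = 1 with identity maps is plain scaled dot-product attention
  p1 <- list(Wq = diag(d), Wk = diag(d), Wv = diag(d), Wo = diag(d), h = 1L)
  expect_equal(multi_head(Q, K, V, p1),
               {a <- scaled_dot_attention(Q, K, V, d); attributes(a) <- list(dim = dim(a)); a})
  # h = 2 with duplicated per-head maps and averaged output projection
  B <- matrix(rnorm(d * 2), d, 2)
  C <- cbind(diag(2), diag(2))
  p2 <- list(Wq = cbind(B, B), Wk = cbind(B, B), Wv = cbind(B, B),
             Wo = rbind(C, C) / 2, h = 2L)
  head1 <- scaled_dot_attention(Q %*% B, K %*% B, V %*% B, 2)
  attributes(head1) <- list(dim = dim(head1))
  expect_equal(multi_head(Q, K, V, p2), head1 %*% C)
  expect_equal(nrow(multi_head(Q, K, V, p1)), nrow(Q))
})

test_that("pair encoders: residual path, shapes, and layer-norm contract", {
  set.seed(31)
  d <- 6
  H_p <- matrix(rnorm(30), 5, d); H_d <- matrix(rnorm(18), 3, d)
  zeroed <- function() list(Wq = diag(d), Wk = diag(d), Wv = diag(d),
                            Wo = matrix(0, d, d), h = 2L)
  params <- list(att_p = zeroed(), att_d = zeroed(),
                 ln_p = list(gamma = rep(1, d), beta = rep(0, d)),
                 ln_d = list(gamma = rep(1, d), beta = rep(0, d)))
  enc <- encode_pair(H_p, H_d, params)
  expect_equal(enc$pirna, layer_norm(H_p, rep(1, d), rep(0, d)))
  expect_equal(dim(enc$pirna), dim(H_p))
  expect_equal(dim(enc$disease), dim(H_d))
  # standardised rows before the affine map
  Z <- layer_norm(H_p, rep(1, d), rep(0, d))
  expect_equal(unname(rowMeans(Z)), rep(0, 5))
  expect_equal(unname(apply(Z, 1, function(r) mean(r^2))), rep(1, 5),
               tolerance = 1e-3)
})

test_that("inner-product scores follow the matrix product", {
  expect_equal(score_pairs(matrix(c(1, 0), 1, 2), matrix(c(0, 1), 1, 2))[1, 1], 0)
  u <- matrix(c(1, 0), 1, 2)
  expect_equal(score_pairs(u, u)[1, 1], 1)
  F_p <- matrix(rnorm(6), 2, 3); F_d <- matrix(rnorm(6), 2, 3)
  expect_equal(score_pairs(F_p, F_d), F_p %*% t(F_d))
  expect_equal(sigmoid(0), 0.5)
})

test_that("analytic gradients match finite differences", {
  study <- tiny_study(m = 8, n = 4, seed = 3, q = 0.2)
  cfg <- run_config(embed_dim = 8, n_heads = 2, word_dim = 6, n_filters = 4,
                    word_epochs = 2, epochs = 3, seed = 7)
  ds <- study$dataset
  S_p <- pirna_similarity(ds, config = cfg)
  S_d <- disease_similarity(ds, study$ontology, config = cfg)
  Ahat <- pdaLink:::normalize_adjacency(build_hetero(S_p, ds$A, S_d))
  vocab <- train_kmer_embeddings(
    lapply(ds$pirnas$sequence, tokenize_kmers, k = 3), d_w = 6,
    epochs = 2, seed = 7)
  mats <- lapply(ds$pirnas$sequence,
                 function(s) kmer_matrix(tokenize_kmers(s, 3), vocab))
  prep <- pdaLink:::textcnn_precompute(mats, cfg$kernel_sizes)
  Y <- ds$A; mask <- matrix(1, nrow(ds$A), ncol(ds$A))
  inputs <- list(Ahat = Ahat, H0_d = unname(S_d), prep = prep,
                 m = nrow(ds$A), n = ncol(ds$A), Y = Y, mask = mask,
                 config = cfg)
  params <- pdaLink:::init_model_params(6, 4, cfg, 7)
  fwd <- pdaLink:::model_forward(inputs, params)
  gr <- pdaLink:::model_backward(inputs, params, fwd)
  nudge <- function(p, path, idx, delta) {
    if (!length(path)) { p[idx] <- p[idx] + delta; return(p) }
    p[[path[[1]]]] <- nudge(p[[path[[1]]]], path[-1], idx, delta)
    p
  }
  checks <- list(
    list(list("cnn", "conv", "3", "W"), 5), list(list("cnn", "W_fc"), 10),
    list(list("W_proj"), 7), list(list("b_proj"), 2),
    list(list("gcn", 1L), 4), list(list("gcn", 2L), 11),
    list(list("att_p", "Wv"), 13), list(list("att_p", "Wo"), 21),
    list(list("att_d", "Wq"), 3), list(list("ln_p", "gamma"), 2),
    list(list("ln_d", "beta"), 4))
  for (ck in checks) {
    path <- ck[[1]]; idx <- ck[[2]]
    f <- function(delta)
      pdaLink:::model_forward(inputs, nudge(params, path, idx, delta))$loss
    numeric_g <- (f(1e-5) - f(-1e-5)) / 2e-5
    analytic_g <- Reduce(function(p, k) p[[k]], path, gr)[idx]
    expect_equal(analytic_g, numeric_g, tolerance = 1e-4,
                 label = paste(unlist(path), collapse = "."))
  }
})

test_that("training reduces the loss, overfits a separable toy, and is deterministic", {
  study <- tiny_study(m = 20, n = 5, seed = 13, q = 0.25, reveal = 1)
  cfg <- tiny_config(epochs = 300L, lr = 5e-3, seed = 5)
  m1 <- pda_train(study$dataset, study$ontology, cfg)
  expect_lt(m1$final_loss, m1$loss_trace[1] / 10)
  # near-perfect training AUC on a consistent planted labelling; exact
  # memorisation is impossible by design: the fixed graph convolution
  # averages near-identical piRNAs together
  lab <- as.vector(study$dataset$A)
  expect_gt(auc_aupr(as.vector(m1$scores), lab)$auc, 0.9)
  cfg2 <- tiny_config(epochs = 20L, seed = 5)
  expect_identical(pda_train(study$dataset, study$ontology, cfg2)$final_loss,
                   pda_train(study$dataset, study$ontology, cfg2)$final_loss)
  expect_error(
    pda_train(study$dataset, study$ontology, cfg2,
              positives = matrix(integer(), 0, 2)),
    "empty positive")
  expect_error(
    pda_train(study$dataset, study$ontology, cfg2,
              positives = cbind(1L, 1L), negatives = cbind(1L, 1L)),
    "overlap")
})
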