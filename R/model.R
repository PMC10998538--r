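# Heterogeneous graph convolution, multi-head cross-attention encoders and
# inner-product decoder, trained end-to-end (including the text encoder)
# with binary cross-entropy and Adam. Forward and backward passes are
# written out explicitly; gradients are verified against finite differences
# in the test suite.

# ---- building blocks (exported) --------------------------------------------

# symmetric normalization D^{-1/2} A_h D^{-1/2}
normalize_adjacency <- function(A_h) {
  d <- rowSums(A_h)
  if (any(d <= 0)) stop("zero-degree node in heterogeneous graph")
  s <- 1 / sqrt(d)
  A_h * outer(s, s)
}

#' One graph-convolution layer
#'
#' `H' = ReLU(D^{-1/2} A_h D^{-1/2} H W)` where `D` is the degree matrix of
#' the heterogeneous adjacency `A_h`. The unit-diagonal similarity blocks of
#' `A_h` guarantee strictly positive degrees, so no self-loops are added.
#'
#' @param A_h heterogeneous adjacency matrix (see [build_hetero()]).
#' @param H node-embedding matrix, one row per node.
#' @param W trainable weight matrix.
#' @param activate apply the ReLU nonlinearity (default `TRUE`).
#' @return The next layer's node embeddings.
#' @export
gcn_layer <- function(A_h, H, W, activate = TRUE) {
  Z <- normalize_adjacency(A_h) %*% H %*% W
  if (activate) pmax(Z, 0) else Z
}

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d_k)) V` with a row-wise softmax. The attention
#' weight matrix is attached as attribute `"weights"`.
#'
#' @param Qp,Kp,Vp projected query, key and value matrices.
#' @param d_k key dimension used for scaling.
#' @return The attended value matrix (one row per query row).
#' @export
scaled_dot_attention <- function(Qp, Kp, Vp, d_k) {
  if (d_k <= 0) stop("d_k must be positive")
  W <- softmax_rows(Qp %*% t(Kp) / sqrt(d_k))
  out <- W %*% Vp
  attr(out, "weights") <- W
  out
}

softmax_rows <- function(L) {
  L <- L - apply(L, 1L, max)
  E <- exp(L)
  E / rowSums(E)
}

#' Multi-head attention
#'
#' `Concat(head_1, ..., head_h) W_O` with
#' `head_i = Attention(Q W_i^Q, K W_i^K, V W_i^V)`. Per-head projections are
#' stored as column blocks of the full `d x d` matrices `Wq`, `Wk`, `Wv`.
#'
#' @param Q,K,V query, key and value matrices (`d` columns each).
#' @param params list with `Wq`, `Wk`, `Wv`, `Wo` (`d x d`) and head count
#'   `h`; `h` must divide `d`.
#' @return The `nrow(Q) x d` attended feature matrix.
#' @export
multi_head <- function(Q, K, V, params) {
  d <- ncol(Q); h <- params$h
  if (d %% h != 0L) stop("head count must divide the feature dimension")
  d_k <- d %/% h
  out <- matrix(0, nrow(Q), d)
  for (i in seq_len(h)) {
    cols <- ((i - 1L) * d_k + 1L):(i * d_k)
    head_i <- scaled_dot_attention(Q %*% params$Wq[, cols, drop = FALSE],
                                   K %*% params$Wk[, cols, drop = FALSE],
                                   V %*% params$Wv[, cols, drop = FALSE],
                                   d_k)
    out[, cols] <- head_i
  }
  out %*% params$Wo
}

#' Row-wise layer normalisation
#'
#' Each row is standardised to mean 0 and variance 1, then scaled and
#' shifted by the learned `gamma` and `beta`.
#'
#' @param X matrix to normalise (rows are feature vectors).
#' @param gamma,beta affine parameters, length `ncol(X)`.
#' @param eps variance floor.
#' @return The normalised matrix.
#' @export
layer_norm <- function(X, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(X)
  Xc <- X - mu
  v <- rowMeans(Xc^2)
  xhat <- Xc * (1 / sqrt(v + eps))
  xhat * rep(gamma, each = nrow(X)) + rep(beta, each = nrow(X))
}

#' Cross-attention pair encoders
#'
#' The piRNA encoder attends piRNA queries over disease keys/values; the
#' disease encoder is the mirror image. Each encoder adds the attended
#' features back onto the original features (residual) and applies layer
#' normalisation.
#'
#' @param H_p,H_d piRNA and disease blocks of the final GCN layer.
#' @param params list with attention parameter sets `att_p`, `att_d` (see
#'   [multi_head()]) and layer-norm parameters `ln_p`, `ln_d` (`gamma`,
#'   `beta` each).
#' @return List with elements `pirna` and `disease`: the encoded feature
#'   matrices.
#' @export
encode_pair <- function(H_p, H_d, params) {
  Zp <- H_p + multi_head(H_p, H_d, H_d, params$att_p)
  Zd <- H_d + multi_head(H_d, H_p, H_p, params$att_d)
  list(pirna = layer_norm(Zp, params$ln_p$gamma, params$ln_p$beta),
       disease = layer_norm(Zd, params$ln_d$gamma, params$ln_d$beta))
}

#' Inner-product association scores
#'
#' @param F_p,F_d encoded piRNA and disease feature matrices with equal
#'   feature dimension.
#' @return The `m x n` score matrix `F_p F_d'`; higher means more likely
#'   associated. `sigmoid()` maps scores to probabilities.
#' @export
score_pairs <- function(F_p, F_d) {
  if (ncol(F_p) != ncol(F_d)) stop("feature dimensions differ")
  F_p %*% t(F_d)
}

#' @rdname score_pairs
#' @param x numeric scores.
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- parameter container ----------------------------------------------------

glorot <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
}

# all trainable parameters; `n` is the disease count (width of H0),
# d = embed_dim is the GCN/attention width
init_model_params <- function(d_w, n, config, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  d <- config$embed_dim
  cnn <- textcnn_init(d_w, config$n_filters, config$kernel_sizes, d,
                      seed = seed + 1L)
  gcn <- vector("list", config$gcn_layers)
  in_dim <- n
  for (l in seq_len(config$gcn_layers)) {
    gcn[[l]] <- glorot(in_dim, d)
    in_dim <- d
  }
  att <- function() list(Wq = glorot(d, d), Wk = glorot(d, d),
                         Wv = glorot(d, d), Wo = glorot(d, d))
  list(cnn = cnn,
       W_proj = glorot(d, n), b_proj = numeric(n),
       gcn = gcn,
       att_p = c(att(), h = config$n_heads),
       att_d = c(att(), h = config$n_heads),
       ln_p = list(gamma = rep(1, d), beta = numeric(d)),
       ln_d = list(gamma = rep(1, d), beta = numeric(d)))
}

# ---- forward / backward -----------------------------------------------------

# inputs: list(Ahat, H0_d (n x n), prep (im2col stacks), m, n, Y, mask, config)
model_forward <- function(inputs, params) {
  cfg <- inputs$config
  m <- inputs$m; n <- inputs$n
  fwd_cnn <- textcnn_forward(inputs$prep, params$cnn)
  xr <- pmax(fwd_cnn$x, 0)
  H0_p <- xr %*% params$W_proj + rep(params$b_proj, each = m)
  H <- rbind(H0_p, inputs$H0_d)
  L <- length(params$gcn)
  Zs <- vector("list", L); Hs <- vector("list", L + 1L)
  Hs[[1L]] <- H
  for (l in seq_len(L)) {
    Z <- inputs$Ahat %*% Hs[[l]] %*% params$gcn[[l]]
    act <- l < L || cfg$final_relu
    Zs[[l]] <- Z
    Hs[[l + 1L]] <- if (act) pmax(Z, 0) else Z
  }
  HL <- Hs[[L + 1L]]
  Hp <- HL[seq_len(m), , drop = FALSE]
  Hd <- HL[m + seq_len(n), , drop = FALSE]
  ca_p <- mha_forward(Hp, Hd, Hd, params$att_p)
  ca_d <- mha_forward(Hd, Hp, Hp, params$att_d)
  Zp <- Hp + ca_p$out
  Zd <- Hd + ca_d$out
  ln_p <- ln_forward(Zp, params$ln_p$gamma, params$ln_p$beta)
  ln_d <- ln_forward(Zd, params$ln_d$gamma, params$ln_d$beta)
  S <- ln_p$Y %*% t(ln_d$Y)
  # stable BCE with logits, averaged over labelled pairs
  n_lab <- sum(inputs$mask)
  sp <- pmax(S, 0) + log1p(exp(-abs(S)))
  loss <- sum((sp - inputs$Y * S) * inputs$mask) / n_lab
  list(loss = loss, S = S, P = sigmoid(S),
       cache = list(fwd_cnn = fwd_cnn, xr = xr, Hs = Hs, Zs = Zs,
                    Hp = Hp, Hd = Hd, ca_p = ca_p, ca_d = ca_d,
                    ln_p = ln_p, ln_d = ln_d, n_lab = n_lab))
}

mha_forward <- function(Q, K, V, params) {
  d <- ncol(Q); h <- params$h; d_k <- d %/% h
  heads <- vector("list", h)
  Cc <- matrix(0, nrow(Q), d)
  for (i in seq_len(h)) {
    cols <- ((i - 1L) * d_k + 1L):(i * d_k)
    Qp <- Q %*% params$Wq[, cols, drop = FALSE]
    Kp <- K %*% params$Wk[, cols, drop = FALSE]
    Vp <- V %*% params$Wv[, cols, drop = FALSE]
    A_w <- softmax_rows(Qp %*% t(Kp) / sqrt(d_k))
    Cc[, cols] <- A_w %*% Vp
    heads[[i]] <- list(Qp = Qp, Kp = Kp, Vp = Vp, A_w = A_w, cols = cols)
  }
  list(out = Cc %*% params$Wo, Cc = Cc, heads = heads, d_k = d_k)
}

mha_backward <- function(Q, K, V, params, fwd, dout) {
  d_k <- fwd$d_k
  dWo <- crossprod(fwd$Cc, dout)
  dCc <- dout %*% t(params$Wo)
  dQ <- matrix(0, nrow(Q), ncol(Q))
  dK <- matrix(0, nrow(K), ncol(K))
  dV <- matrix(0, nrow(V), ncol(V))
  dWq <- matrix(0, nrow(params$Wq), ncol(params$Wq))
  dWk <- dWq; dWv <- dWq
  for (hd in fwd$heads) {
    dhead <- dCc[, hd$cols, drop = FALSE]
    dVp <- crossprod(hd$A_w, dhead)
    dA <- dhead %*% t(hd$Vp)
    dL <- hd$A_w * (dA - rowSums(dA * hd$A_w))
    dL <- dL / sqrt(d_k)
    dQp <- dL %*% hd$Kp
    dKp <- crossprod(dL, hd$Qp)
    dWq[, hd$cols] <- crossprod(Q, dQp)
    dWk[, hd$cols] <- crossprod(K, dKp)
    dWv[, hd$cols] <- crossprod(V, dVp)
    dQ <- dQ + dQp %*% t(params$Wq[, hd$cols, drop = FALSE])
    dK <- dK + dKp %*% t(params$Wk[, hd$cols, drop = FALSE])
    dV <- dV + dVp %*% t(params$Wv[, hd$cols, drop = FALSE])
  }
  list(grads = list(Wq = dWq, Wk = dWk, Wv = dWv, Wo = dWo),
       dQ = dQ, dK = dK, dV = dV)
}

ln_forward <- function(X, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(X)
  Xc <- X - mu
  v <- rowMeans(Xc^2)
  inv_std <- 1 / sqrt(v + eps)
  xhat <- Xc * inv_std
  Y <- xhat * rep(gamma, each = nrow(X)) + rep(beta, each = nrow(X))
  list(Y = Y, xhat = xhat, inv_std = inv_std)
}

ln_backward <- function(fwd, gamma, dY) {
  dgamma <- colSums(dY * fwd$xhat)
  dbeta <- colSums(dY)
  dxhat <- dY * rep(gamma, each = nrow(dY))
  dX <- fwd$inv_std *
    (dxhat - rowMeans(dxhat) - fwd$xhat * rowMeans(dxhat * fwd$xhat))
  list(grads = list(gamma = dgamma, beta = dbeta), dX = dX)
}

model_backward <- function(inputs, params, fwd) {
  cfg <- inputs$config
  m <- inputs$m; n <- inputs$n
  ch <- fwd$cache
  dS <- (fwd$P - inputs$Y) * inputs$mask / ch$n_lab
  dFp <- dS %*% ch$ln_d$Y
  dFd <- crossprod(dS, ch$ln_p$Y)
  bp <- ln_backward(ch$ln_p, params$ln_p$gamma, dFp)
  bd <- ln_backward(ch$ln_d, params$ln_d$gamma, dFd)
  dHp <- bp$dX   # residual path
  dHd <- bd$dX
  ap <- mha_backward(ch$Hp, ch$Hd, ch$Hd, params$att_p, ch$ca_p, bp$dX)
  ad <- mha_backward(ch$Hd, ch$Hp, ch$Hp, params$att_d, ch$ca_d, bd$dX)
  dHp <- dHp + ap$dQ + ad$dK + ad$dV
  dHd <- dHd + ap$dK + ap$dV + ad$dQ
  dH <- rbind(dHp, dHd)
  L <- length(params$gcn)
  dgcn <- vector("list", L)
  for (l in rev(seq_len(L))) {
    act <- l < L || cfg$final_relu
    dZ <- if (act) dH * (ch$Zs[[l]] > 0) else dH
    AH <- inputs$Ahat %*% ch$Hs[[l]]
    dgcn[[l]] <- crossprod(AH, dZ)
    dH <- inputs$Ahat %*% (dZ %*% t(params$gcn[[l]]))
  }
  dH0_p <- dH[seq_len(m), , drop = FALSE]
  dW_proj <- crossprod(ch$xr, dH0_p)
  db_proj <- colSums(dH0_p)
  dxr <- dH0_p %*% t(params$W_proj)
  dx <- dxr * (ch$fwd_cnn$x > 0)
  dcnn <- textcnn_backward(inputs$prep, params$cnn, ch$fwd_cnn, dx)
  list(cnn = dcnn, W_proj = dW_proj, b_proj = db_proj, gcn = dgcn,
       att_p = ap$grads, att_d = ad$grads,
       ln_p = bp$grads, ln_d = bd$grads)
}

# ---- Adam -------------------------------------------------------------------

# state and updates mirror the *gradient* structure, so metadata fields in
# the parameter list (kernel sizes etc.) are left untouched
zeros_like <- function(g) {
  if (is.list(g)) lapply(g, zeros_like) else g * 0
}

adam_step <- function(p, g, m, v, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  if (is.list(g)) {
    for (nm in names(g)) {
      res <- adam_step(p[[nm]], g[[nm]], m[[nm]], v[[nm]], lr, t,
                       beta1, beta2, eps)
      p[[nm]] <- res$p; m[[nm]] <- res$m; v[[nm]] <- res$v
    }
    return(list(p = p, m = m, v = v))
  }
  m <- beta1 * m + (1 - beta1) * g
  v <- beta2 * v + (1 - beta2) * g^2
  p <- p - lr * (m / (1 - beta1^t)) / (sqrt(v / (1 - beta2^t)) + eps)
  list(p = p, m = m, v = v)
}

# ---- training ---------------------------------------------------------------

#' Train the association model
#'
#' Builds the heterogeneous graph from the (training) adjacency, embeds the
#' piRNA sequences, and trains the full network — text encoder, graph
#' convolution, cross-attention encoders and inner-product decoder — by
#' minimising binary cross-entropy over the labelled pairs with Adam.
#' Everything is seeded and single-threaded, so a repeated call returns
#' bit-identical parameters.
#'
#' @param dataset an [association_dataset()].
#' @param ontology a [disease_ontology()].
#' @param config a [run_config()].
#' @param positives 2-column index matrix of positive training pairs
#'   (row, column of `A`); defaults to all ones of `A_train`.
#' @param negatives 2-column index matrix of negative training pairs
#'   (e.g. a reliable-negative set); defaults to all zero pairs of
#'   `A_train`. Must be disjoint from `positives`.
#' @param A_train adjacency used for the graph, the interaction-profile
#'   kernels and the loss; defaults to `dataset$A`. In cross-validation
#'   pass the adjacency with test-fold positives zeroed.
#' @param seq_sim,sem_sim optional precomputed sequence / semantic
#'   similarity matrices (they do not depend on `A_train`).
#' @param vocab optional pre-trained [train_kmer_embeddings()] result.
#' @param snapshot_epochs integer vector of epochs at which the full
#'   probability matrix is recorded (used for reporting windows).
#' @return An object of class `pda_model`: trained parameters, the loss
#'   trace, the similarity matrices used, final `scores` and `prob`
#'   matrices, and any requested snapshots.
#' @export
pda_train <- function(dataset, ontology, config = run_config(),
                      positives = NULL, negatives = NULL, A_train = NULL,
                      seq_sim = NULL, sem_sim = NULL, vocab = NULL,
                      snapshot_epochs = integer()) {
  A <- if (is.null(A_train)) dataset$A else A_train
  m <- nrow(A); n <- ncol(A)
  if (is.null(positives)) positives <- which(A == 1, arr.ind = TRUE)
  if (is.null(negatives)) negatives <- which(A == 0, arr.ind = TRUE)
  positives <- as.matrix(positives); negatives <- as.matrix(negatives)
  if (nrow(positives) == 0L) stop("empty positive training set")
  key <- function(ij) paste(ij[, 1], ij[, 2])
  if (length(intersect(key(positives), key(negatives))))
    stop("positives and negatives overlap")

  S_p <- pirna_similarity(replace_A(dataset, A), seq_sim, config)
  S_d <- disease_similarity(replace_A(dataset, A), ontology, sem_sim, config)
  Ahat <- normalize_adjacency(build_hetero(S_p, A, S_d))
  if (is.null(vocab)) {
    corpus <- lapply(dataset$pirnas$sequence, tokenize_kmers, k = config$kmer_k)
    vocab <- train_kmer_embeddings(corpus, d_w = config$word_dim,
                                   window = config$word_window,
                                   epochs = config$word_epochs,
                                   seed = config$seed)
  }
  mats <- lapply(dataset$pirnas$sequence,
                 function(s) kmer_matrix(tokenize_kmers(s, config$kmer_k), vocab))
  prep <- textcnn_precompute(mats, config$kernel_sizes)

  Y <- matrix(0, m, n); mask <- matrix(0, m, n)
  Y[positives] <- 1
  mask[positives] <- 1; mask[negatives] <- 1
  inputs <- list(Ahat = Ahat, H0_d = unname(S_d), prep = prep, m = m, n = n,
                 Y = Y, mask = mask, config = config)
  params <- init_model_params(config$word_dim, n, config, config$seed)
  mstate <- NULL; vstate <- NULL
  trace <- numeric(config$epochs)
  snaps <- list()
  for (ep in seq_len(config$epochs)) {
    fwd <- model_forward(inputs, params)
    trace[ep] <- fwd$loss
    if (ep %in% snapshot_epochs) {
      P <- fwd$P; dimnames(P) <- dimnames(A)
      snaps[[as.character(ep)]] <- P
    }
    grads <- model_backward(inputs, params, fwd)
    if (is.null(mstate)) { mstate <- zeros_like(grads); vstate <- zeros_like(grads) }
    res <- adam_step(params, grads, mstate, vstate, config$lr, ep)
    params <- res$p; mstate <- res$m; vstate <- res$v
  }
  fwd <- model_forward(inputs, params)
  scores <- fwd$S; prob <- fwd$P
  dimnames(scores) <- dimnames(A); dimnames(prob) <- dimnames(A)
  structure(list(params = params, vocab = vocab, config = config,
                 loss_trace = trace, final_loss = fwd$loss,
                 S_p = S_p, S_d = S_d, inputs = inputs,
                 scores = scores, prob = prob, snapshots = snaps),
            class = "pda_model")
}

replace_A <- function(dataset, A) {
  dataset$A <- A
  dataset
}

#' @export
print.pda_model <- function(x, ...) {
  cat(sprintf(
    "pda_model: %d piRNAs x %d diseases, %d epochs, final loss %.4f\n",
    nrow(x$scores), ncol(x$scores), length(x$loss_trace), x$final_loss))
  invisible(x)
}

#' Predict association scores from a trained model
#'
#' The model is transductive: it scores every piRNA-disease pair of the
#' graph it was trained on.
#'
#' @param object a [pda_train()] result.
#' @param ... unused.
#' @return List with `scores` (inner products) and `prob` (sigmoid
#'   probabilities), both `m x n` with id dimnames.
#' @export
predict.pda_model <- function(object, ...) {
  list(scores = object$scores, prob = object$prob)
}
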