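# Sequence embedding: overlapping 3-mer tokenization, skip-gram vectors for
# the 3-mer vocabulary (negative sampling, written here because the model is
# trained end-to-end with the rest of the network and the vocabulary is tiny),
# and a convolutional text encoder with kernel sizes {1, 3, 5} and global
# max pooling.

#' Tokenize a sequence into overlapping k-mers
#'
#' @param sequence a sequence string.
#' @param k k-mer length (3 by default).
#' @return Character vector of the `L - k + 1` consecutive k-mers in order.
#' @examples
#' tokenize_kmers("ATTGCAT", 3)  # ATT TTG TGC GCA CAT
#' @export
tokenize_kmers <- function(sequence, k = 3L) {
  L <- nchar(sequence)
  if (L < k)
    stop("sequence of length ", L, " cannot be tokenized into ", k, "-mers")
  starts <- seq_len(L - k + 1L)
  substring(sequence, starts, starts + k - 1L)
}

#' Train skip-gram embeddings for a k-mer corpus
#'
#' Trains word2vec skip-gram vectors with negative sampling over the token
#' lists of all piRNA sequences (each sequence is one sentence, each k-mer
#' one word). Negative targets are drawn from the unigram distribution
#' raised to the 3/4 power. Training is single-threaded and fully
#' deterministic for a fixed seed.
#'
#' @param corpus list of character vectors (one token list per sequence).
#' @param d_w embedding dimension (64 by default).
#' @param window symmetric context window in tokens.
#' @param epochs passes over the pair list.
#' @param negative negative samples per context pair.
#' @param lr initial SGD learning rate (linearly decayed to 1/10th).
#' @param seed RNG seed.
#' @return An object of class `kmer_vocab`: list with `k` (token length
#'   inferred from the corpus), `vectors` (vocabulary x `d_w` matrix with
#'   k-mer rownames) and `counts`.
#' @export
train_kmer_embeddings <- function(corpus, d_w = 64L, window = 5L,
                                  epochs = 5L, negative = 5L, lr = 0.05,
                                  seed = 1L) {
  if (!length(corpus) || !length(unlist(corpus)))
    stop("empty corpus")
  tokens <- unlist(corpus, use.names = FALSE)
  vocab <- sort(unique(tokens))
  V <- length(vocab)
  counts <- table(factor(tokens, levels = vocab))
  # context pairs (center, context) across all sentences
  ctr <- list(); ctx <- list(); p <- 0L
  for (sent in corpus) {
    idx <- match(sent, vocab)
    L <- length(idx)
    if (L < 2L) next
    for (off in seq_len(min(window, L - 1L))) {
      p <- p + 1L
      ctr[[p]] <- c(idx[seq_len(L - off)], idx[(off + 1L):L])
      ctx[[p]] <- c(idx[(off + 1L):L], idx[seq_len(L - off)])
    }
  }
  centers <- unlist(ctr); contexts <- unlist(ctx)
  npair <- length(centers)
  if (!npair) stop("corpus has no context pairs (sentences too short)")
  uni <- as.numeric(counts)^0.75
  uni <- uni / sum(uni)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  W_in <- matrix(stats::runif(V * d_w, -0.5, 0.5) / d_w, V, d_w)
  W_out <- matrix(0, V, d_w)
  batch <- 256L
  total_steps <- epochs * npair
  done <- 0
  for (ep in seq_len(epochs)) {
    perm <- sample.int(npair)
    negs <- matrix(sample.int(V, npair * negative, replace = TRUE, prob = uni),
                   npair, negative)
    for (b0 in seq(1L, npair, by = batch)) {
      bi <- perm[b0:min(b0 + batch - 1L, npair)]
      cur_lr <- lr * (1 - 0.9 * done / total_steps)
      tc <- centers[bi]
      targets <- cbind(contexts[bi], negs[bi, , drop = FALSE])
      Wb <- W_in[tc, , drop = FALSE]
      dWb <- 0
      for (kcol in seq_len(ncol(targets))) {
        tk <- targets[, kcol]
        Wo <- W_out[tk, , drop = FALSE]
        s <- rowSums(Wb * Wo)
        g <- 1 / (1 + exp(-s)) - (kcol == 1L)   # sigmoid(s) - label
        dWb <- dWb + g * Wo
        upd <- rowsum(g * Wb, tk)
        ids <- as.integer(rownames(upd))
        W_out[ids, ] <- W_out[ids, ] - cur_lr * upd
      }
      upd <- rowsum(dWb, tc)
      ids <- as.integer(rownames(upd))
      W_in[ids, ] <- W_in[ids, ] - cur_lr * upd
      done <- done + length(bi)
    }
  }
  rownames(W_in) <- vocab
  structure(list(k = nchar(vocab[1]), vectors = W_in,
                 counts = as.integer(counts)),
            class = "kmer_vocab")
}

#' @export
print.kmer_vocab <- function(x, ...) {
  cat(sprintf("kmer_vocab: %d %d-mers, %d-dimensional vectors\n",
              nrow(x$vectors), x$k, ncol(x$vectors)))
  invisible(x)
}

#' Look up the token-vector matrix of one sequence
#'
#' @param tokens character vector of k-mers (see [tokenize_kmers()]).
#' @param vocab a [train_kmer_embeddings()] result.
#' @return An `L x d_w` matrix; tokens absent from the vocabulary map to
#'   zero rows.
#' @export
kmer_matrix <- function(tokens, vocab) {
  idx <- match(tokens, rownames(vocab$vectors))
  M <- matrix(0, length(tokens), ncol(vocab$vectors))
  hit <- !is.na(idx)
  M[hit, ] <- vocab$vectors[idx[hit], , drop = FALSE]
  M
}

# save/restore global RNG state so seeded helpers do not perturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Initialise text-encoder weights
#'
#' The encoder applies, for each kernel size, a 1-D convolution over token
#' positions followed by ReLU and global max pooling, concatenates the
#' pooled maps and projects them linearly to `embed_dim`.
#'
#' @param d_w token-vector dimension.
#' @param n_filters filters per kernel size.
#' @param kernel_sizes integer kernel widths (tokens).
#' @param embed_dim output feature dimension.
#' @param seed RNG seed for the Glorot-style initialisation.
#' @return A list of class `textcnn_weights` with per-size convolution
#'   weights `conv[[s]]$W` (`s*d_w x n_filters`) and biases, plus the
#'   projection `W_fc`, `b_fc`.
#' @export
textcnn_init <- function(d_w, n_filters = 128L, kernel_sizes = c(1L, 3L, 5L),
                         embed_dim = 128L, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  conv <- lapply(kernel_sizes, function(s) {
    fan_in <- s * d_w
    list(W = matrix(stats::rnorm(fan_in * n_filters,
                                 sd = sqrt(2 / (fan_in + n_filters))),
                    fan_in, n_filters),
         b = numeric(n_filters))
  })
  names(conv) <- as.character(kernel_sizes)
  pooled_dim <- n_filters * length(kernel_sizes)
  structure(list(conv = conv, kernel_sizes = as.integer(kernel_sizes),
                 n_filters = as.integer(n_filters), d_w = as.integer(d_w),
                 W_fc = matrix(stats::rnorm(pooled_dim * embed_dim,
                                            sd = sqrt(2 / (pooled_dim + embed_dim))),
                               pooled_dim, embed_dim),
                 b_fc = numeric(embed_dim)),
            class = "textcnn_weights")
}

#' Encode one token-vector matrix with the text encoder
#'
#' @param token_vectors `L x d_w` matrix of token vectors. Sequences with
#'   fewer tokens than the largest kernel are zero-padded on the right.
#' @param weights a [textcnn_init()] weight list.
#' @return A numeric vector of length `embed_dim`.
#' @export
textcnn_encode <- function(token_vectors, weights) {
  X <- as.matrix(token_vectors)
  if (ncol(X) != weights$d_w)
    stop("token vectors have dimension ", ncol(X), ", weights expect ",
         weights$d_w)
  L_pad <- max(nrow(X), max(weights$kernel_sizes))
  prep <- textcnn_precompute(list(X), weights$kernel_sizes, L_pad)
  fwd <- textcnn_forward(prep, weights)
  drop(fwd$x)
}

# im2col stacks shared across the training loop: for each kernel size s,
# a ((n_seq * P_s) x (s * d_w)) matrix whose rows are the flattened windows,
# sequence-major, position within sequence contiguous.
textcnn_precompute <- function(token_mats, kernel_sizes, L_pad = NULL) {
  d_w <- ncol(token_mats[[1]])
  if (is.null(L_pad))
    L_pad <- max(vapply(token_mats, nrow, 0L), max(kernel_sizes))
  padded <- lapply(token_mats, function(X) {
    if (nrow(X) < L_pad) X <- rbind(X, matrix(0, L_pad - nrow(X), d_w))
    X
  })
  sizes <- lapply(kernel_sizes, function(s) {
    P <- L_pad - s + 1L
    Xc <- matrix(0, length(padded) * P, s * d_w)
    for (i in seq_along(padded)) {
      X <- padded[[i]]
      for (t in seq_len(P)) {
        Xc[(i - 1L) * P + t, ] <- as.vector(t(X[t:(t + s - 1L), , drop = FALSE]))
      }
    }
    list(Xc = Xc, P = P, s = s)
  })
  names(sizes) <- as.character(kernel_sizes)
  list(sizes = sizes, n_seq = length(token_mats), L_pad = L_pad, d_w = d_w)
}

# batched forward pass; keeps argmax positions for backpropagation
textcnn_forward <- function(prep, weights) {
  m <- prep$n_seq
  pooled <- list(); tstar <- list()
  for (s in names(prep$sizes)) {
    sz <- prep$sizes[[s]]
    C <- sz$Xc %*% weights$conv[[s]]$W
    C <- C + rep(weights$conv[[s]]$b, each = nrow(C))
    R <- pmax(C, 0)
    cur <- matrix(0, m, ncol(R))
    ts <- matrix(0L, m, ncol(R))
    for (t in seq_len(sz$P)) {
      v <- R[seq(t, by = sz$P, length.out = m), , drop = FALSE]
      upd <- v > cur
      ts[upd] <- t
      cur[upd] <- v[upd]
    }
    pooled[[s]] <- cur
    tstar[[s]] <- ts
  }
  pooled_all <- do.call(cbind, pooled)
  x <- pooled_all %*% weights$W_fc
  x <- x + rep(weights$b_fc, each = m)
  list(x = x, pooled = pooled_all, tstar = tstar)
}

# backward pass: gradient of the loss w.r.t. encoder weights given dx.
# Token vectors are treated as fixed inputs (the skip-gram vocabulary is
# pre-trained), so no gradient flows into them.
textcnn_backward <- function(prep, weights, fwd, dx) {
  m <- prep$n_seq
  grads <- list(W_fc = crossprod(fwd$pooled, dx), b_fc = colSums(dx),
                conv = list())
  dpooled <- dx %*% t(weights$W_fc)
  off <- 0L
  for (s in names(prep$sizes)) {
    sz <- prep$sizes[[s]]
    F_ <- weights$n_filters
    dp <- dpooled[, (off + 1L):(off + F_), drop = FALSE]
    off <- off + F_
    ts <- fwd$tstar[[s]]
    valid <- which(ts > 0L)           # pooled value > 0, ReLU passes
    dR <- matrix(0, m * sz$P, F_)
    if (length(valid)) {
      ri <- ((valid - 1L) %% m)       # 0-based sequence index
      ci <- ((valid - 1L) %/% m) + 1L # filter index
      rows <- ri * sz$P + ts[valid]
      dR[cbind(rows, ci)] <- dp[valid]
    }
    grads$conv[[s]] <- list(W = crossprod(sz$Xc, dR), b = colSums(dR))
  }
  grads
}

#' Encode every piRNA sequence into a feature matrix
#'
#' Tokenizes each sequence, looks up the skip-gram token vectors and runs
#' the text encoder, producing one fixed-length feature vector per piRNA.
#'
#' @param pirnas piRNA record data frame.
#' @param vocab a [train_kmer_embeddings()] result.
#' @param weights a [textcnn_init()] weight list.
#' @return An `m x embed_dim` matrix with piRNA ids as rownames.
#' @export
sequence_features <- function(pirnas, vocab, weights) {
  mats <- lapply(pirnas$sequence,
                 function(s) kmer_matrix(tokenize_kmers(s, vocab$k), vocab))
  prep <- textcnn_precompute(mats, weights$kernel_sizes)
  x <- textcnn_forward(prep, weights)$x
  rownames(x) <- pirnas$id
  x
}
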