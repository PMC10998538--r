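# Independent oracles, written before the implementations they check and
# kept free of package internals.

# quadratic-time Smith-Waterman dynamic programme (linear gap penalty)
sw_oracle <- function(a, b, match = 2, mismatch = -1, gap = -1) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  H <- matrix(0, length(x) + 1L, length(y) + 1L)
  best <- 0
  for (i in seq_along(x)) {
    for (j in seq_along(y)) {
      s <- if (x[i] == y[j]) match else mismatch
      H[i + 1L, j + 1L] <- max(0, H[i, j] + s, H[i, j + 1L] + gap,
                               H[i + 1L, j] + gap)
      best <- max(best, H[i + 1L, j + 1L])
    }
  }
  best
}

# exhaustive-path semantic similarity: the contribution of ancestor t to
# disease d is max over directed paths d -> t of theta^length(path),
# enumerated explicitly (feasible for DAGs of <= 10 nodes)
sem_contrib_oracle <- function(edges, disease, theta = 0.5) {
  # edges: data.frame(child, parent)
  paths_from <- function(node) {
    out <- list(node)
    for (p in edges$parent[edges$child == node]) {
      for (tail in paths_from(p)) out <- c(out, list(c(node, tail)))
    }
    out
  }
  w <- list()
  for (path in paths_from(disease)) {
    t <- path[length(path)]
    val <- theta^(length(path) - 1L)
    if (is.null(w[[t]]) || val > w[[t]]) w[[t]] <- val
  }
  unlist(w)
}

sem_sim_oracle <- function(edges, di, dj, theta = 0.5) {
  wi <- sem_contrib_oracle(edges, di, theta)
  wj <- sem_contrib_oracle(edges, dj, theta)
  shared <- intersect(names(wi), names(wj))
  (sum(wi[shared]) + sum(wj[shared])) / (sum(wi) + sum(wj))
}

# Mann-Whitney AUC by brute force over all positive-negative score pairs
auc_oracle <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  cmp <- outer(sp, sn, function(p, n) (p > n) + 0.5 * (p == n))
  mean(cmp)
}

# random sequence over the DNA alphabet
rand_seq <- function(L) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                              collapse = "")

# random rooted DAG edge list on n nodes (node 1 is the root)
rand_dag_edges <- function(n) {
  child <- character(); parent <- character()
  ids <- paste0("t", seq_len(n))
  for (i in seq_len(n)[-1]) {
    ps <- sample.int(i - 1L, sample.int(min(2L, i - 1L), 1L))
    child <- c(child, rep(ids[i], length(ps)))
    parent <- c(parent, ids[ps])
  }
  data.frame(child = child, parent = parent)
}

# small config keeping unit-test model runs fast
tiny_config <- function(...) {
  args <- list(embed_dim = 16L, n_heads = 2L, word_dim = 8L, n_filters = 8L,
               word_epochs = 2L, epochs = 40L, rf_estimators = 100L,
               n_bags = 5L, bag_rounds = 2L, two_step_iters = 2L)
  over <- list(...)
  args[names(over)] <- over
  do.call(run_config, args)
}

# small planted study shared by model/evaluation tests
tiny_study <- function(m = 30L, n = 6L, seed = 11L, q = 0.15, reveal = 0.8) {
  gen_study(m = m, n = n, q = q, reveal = reveal, seed = seed)
}

pair_key_of <- function(pairs) paste(pairs[, 1], pairs[, 2], sep = ":")
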