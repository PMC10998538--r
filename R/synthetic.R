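# Synthetic datasets with the statistical structure the predictor assumes:
# random piRNA-length DNA sequences, a random rooted disease DAG, and a
# planted low-rank association matrix of which only a fraction is observed —
# the hidden remainder plays the role of the true positives buried in the
# unlabelled set.

#' Generate random piRNA records
#'
#' Sequences are i.i.d. uniform over `{A,C,G,T}` with lengths uniform on
#' `len_range` (24-35 nt by default, the piRNA length regime).
#'
#' @param m number of sequences.
#' @param len_range integer length range, inclusive.
#' @param seed RNG seed.
#' @return A piRNA record data frame with ids `p0001, p0002, ...`.
#' @export
gen_sequences <- function(m, len_range = c(24L, 35L), seed = 1L) {
  if (m == 0L) return(pirna_records(character(), character())[0, ])
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lens <- sample(len_range[1]:len_range[2], m, replace = TRUE)
  seqs <- vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""), "")
  pirna_records(sprintf("p%04d", seq_len(m)), seqs)
}

#' Generate a random rooted disease DAG
#'
#' Terms are created in order; the first is the root and every later term
#' receives one or two parents among the earlier terms, so the graph is
#' acyclic by construction and has a single root.
#'
#' @param n number of disease terms.
#' @param max_parents maximum parents per non-root term (1 or 2 drawn
#'   uniformly when 2).
#' @param seed RNG seed.
#' @return A [disease_ontology()] with terms `D01, D02, ...`.
#' @export
gen_ontology <- function(n, max_parents = 2L, seed = 1L) {
  ids <- sprintf("D%02d", seq_len(n))
  if (n <= 1L) return(disease_ontology(nodes = ids))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  child <- character(); parent <- character()
  for (i in 2:n) {
    np <- sample.int(min(max_parents, i - 1L), 1L)
    ps <- sample.int(i - 1L, np)
    child <- c(child, rep(ids[i], np))
    parent <- c(parent, ids[ps])
  }
  disease_ontology(data.frame(child = child, parent = parent), nodes = ids)
}

#' Generate a planted low-rank association dataset
#'
#' Draws non-negative latent factors `U` (`m x r`) and `V` (`n x r`), forms
#' noisy scores `U V' + noise`, marks the top `q * m * n` scores as true
#' associations, and reveals a fraction of them as the observed adjacency;
#' the unrevealed associations remain hidden positives inside the
#' unlabelled set. The low-rank planting gives the graph model a
#' recoverable signal; `uniform = TRUE` instead plants positives uniformly
#' at random (a null structure with nothing to recover beyond the profiles).
#'
#' @param pirnas piRNA record data frame (rows of the matrix).
#' @param diseases character vector of disease ids (columns).
#' @param r latent rank.
#' @param q fraction of all pairs that are true associations (the observed
#'   density is about `reveal * q`).
#' @param reveal fraction of true associations revealed as observed.
#' @param noise standard deviation of the Gaussian score noise.
#' @param uniform plant positives uniformly instead of low-rank.
#' @param seed RNG seed.
#' @return List with `dataset` (the observed [association_dataset()]),
#'   `truth` (binary `m x n` matrix of all true associations, a superset of
#'   the observed adjacency) and `hidden` (index matrix of the unrevealed
#'   true associations).
#' @export
gen_associations <- function(pirnas, diseases, r = 3L, q = 0.08,
                             reveal = 0.7, noise = 0.1, uniform = FALSE,
                             seed = 1L) {
  m <- nrow(pirnas); n <- length(diseases)
  n_true <- round(q * m * n)
  if (n_true < 1L) stop("q * m * n must be at least 1")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (uniform) {
    truth_idx <- sample.int(m * n, n_true)
  } else {
    U <- matrix(abs(stats::rnorm(m * r)), m, r)
    V <- matrix(abs(stats::rnorm(n * r)), n, r)
    sc <- tcrossprod(U, V) + noise * stats::rnorm(m * n)
    truth_idx <- order(sc, decreasing = TRUE)[seq_len(n_true)]
  }
  truth <- matrix(0, m, n, dimnames = list(sort(pirnas$id), sort(diseases)))
  truth[truth_idx] <- 1
  revealed <- sample(truth_idx, round(reveal * n_true))
  A_obs <- matrix(0, m, n)
  A_obs[revealed] <- 1
  obs_idx <- which(A_obs == 1, arr.ind = TRUE)
  # dataset ordering is lexicographic by id; ids are generated pre-sorted
  edges <- data.frame(pirna = rownames(truth)[obs_idx[, 1]],
                      disease = colnames(truth)[obs_idx[, 2]])
  dataset <- association_dataset(pirnas, diseases, edges)
  hidden <- which(truth == 1 & dataset$A == 0, arr.ind = TRUE)
  list(dataset = dataset, truth = truth, hidden = hidden)
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper tying together [gen_sequences()], [gen_ontology()]
#' and [gen_associations()] under one seed.
#'
#' @param m,n numbers of piRNAs and diseases.
#' @param q,reveal,r,noise,uniform see [gen_associations()].
#' @param len_range see [gen_sequences()].
#' @param seed RNG seed; sub-stages derive distinct seeds from it.
#' @return List with `dataset`, `ontology`, `truth`, `hidden`.
#' @export
gen_study <- function(m = 200L, n = 15L, q = 0.08, reveal = 0.7, r = 3L,
                      noise = 0.1, uniform = FALSE,
                      len_range = c(24L, 35L), seed = 1L) {
  pirnas <- gen_sequences(m, len_range, seed = seed)
  ontology <- gen_ontology(n, seed = seed + 1L)
  assoc <- gen_associations(pirnas, ontology$nodes, r = r, q = q,
                            reveal = reveal, noise = noise,
                            uniform = uniform, seed = seed + 2L)
  list(dataset = assoc$dataset, ontology = ontology,
       truth = assoc$truth, hidden = assoc$hidden)
}
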