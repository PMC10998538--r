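# Similarity networks: sequence (Smith-Waterman), interaction-profile (GIP),
# ontology semantic similarity, their fusion, and the heterogeneous block
# matrix fed to the graph convolution.

#' Smith-Waterman local alignment score
#'
#' Best local-alignment score between two DNA sequences under a simple
#' match/mismatch substitution scheme and a linear gap penalty. The score is
#' 0 when no positive-scoring local alignment exists. Alignment is delegated
#' to [Biostrings::pairwiseAlignment()].
#'
#' @param seq_a,seq_b sequences over `{A,C,G,T}`.
#' @param match,mismatch,gap scoring parameters; `mismatch` and `gap` are
#'   penalties and must be negative, `match` positive.
#' @return A single non-negative alignment score.
#' @examples
#' sw_raw_score("ACGT", "ACGA")  # 6: local alignment of "ACG"
#' @export
sw_raw_score <- function(seq_a, seq_b, match = 2, mismatch = -1, gap = -1) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  stopifnot(match > 0, mismatch < 0, gap < 0)
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = TRUE)
  sc <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seq_a), Biostrings::DNAString(seq_b),
    type = "local", substitutionMatrix = submat,
    gapOpening = 0, gapExtension = -gap, scoreOnly = TRUE)
  max(sc, 0)
}

#' Normalised Smith-Waterman sequence similarity matrix
#'
#' `M[i, j] = SW(i, j) / sqrt(SW(i, i) * SW(j, j))`, so that self-similarity
#' is 1 for any positive match score. Symmetric with entries in `[0, 1]`.
#'
#' @param pirnas piRNA record data frame (see [pirna_records()]).
#' @param match,mismatch,gap Smith-Waterman scoring (see [sw_raw_score()]).
#' @return An m x m similarity matrix with piRNA ids as dimnames.
#' @export
seq_similarity <- function(pirnas, match = 2, mismatch = -1, gap = -1) {
  stopifnot(match > 0, mismatch < 0, gap < 0)
  seqs <- Biostrings::DNAStringSet(pirnas$sequence)
  names(seqs) <- pirnas$id
  m <- length(seqs)
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = TRUE)
  SW <- matrix(0, m, m, dimnames = list(pirnas$id, pirnas$id))
  for (j in seq_len(m)) {
    sc <- Biostrings::pairwiseAlignment(
      seqs[j:m], seqs[[j]], type = "local", substitutionMatrix = submat,
      gapOpening = 0, gapExtension = -gap, scoreOnly = TRUE)
    SW[j:m, j] <- pmax(sc, 0)
    SW[j, j:m] <- SW[j:m, j]
  }
  self <- diag(SW)  # = match * length for each sequence, always > 0
  M <- SW / sqrt(outer(self, self))
  diag(M) <- 1
  M
}

#' Gaussian interaction-profile (GIP) kernel similarity
#'
#' Similarity between the rows of a binary interaction-profile matrix:
#' `M[i, j] = exp(-lambda * ||row_i - row_j||^2)` with the bandwidth
#' `lambda = 1 / mean_k(||row_k||^2)` adapted to the data. For disease
#' profiles pass the transposed adjacency matrix.
#'
#' @param profile_matrix numeric matrix; each row is an entity's
#'   interaction profile.
#' @return A square similarity matrix over the rows, entries in `(0, 1]`,
#'   unit diagonal.
#' @export
gip_similarity <- function(profile_matrix) {
  P <- as.matrix(profile_matrix)
  norms2 <- rowSums(P^2)
  if (mean(norms2) == 0)
    stop("GIP undefined: zero mean profile norm")
  lambda <- 1 / mean(norms2)
  # squared distances via the Gram matrix
  G <- tcrossprod(P)
  D2 <- outer(norms2, norms2, `+`) - 2 * G
  D2[D2 < 0] <- 0
  M <- exp(-lambda * D2)
  diag(M) <- 1
  dimnames(M) <- list(rownames(P), rownames(P))
  M
}

#' Semantic contribution of ancestor terms to a disease
#'
#' Computes the decayed contribution of every term in the ancestor closure
#' of `disease`: the disease itself contributes 1, and every other ancestor
#' contributes `theta` times the maximum contribution among its children
#' within the closure.
#'
#' @param ontology a [disease_ontology()].
#' @param disease a term id in the ontology.
#' @param theta decay parameter in `(0, 1)`; 0.5 by default.
#' @return A named numeric vector over the disease and all its ancestors.
#' @examples
#' ont <- disease_ontology(data.frame(child = c("d", "a"), parent = c("a", "r")))
#' semantic_contribution(ont, "d")  # d = 1, a = 0.5, r = 0.25
#' @export
semantic_contribution <- function(ontology, disease, theta = 0.5) {
  if (!disease %in% ontology$nodes)
    stop("unknown disease term: ", disease)
  w <- c(1); names(w) <- disease
  frontier <- disease
  # breadth-first up the parent edges; max-decay update until fixed point
  while (length(frontier)) {
    nxt <- character()
    for (t in frontier) {
      for (p in ontology$parents[[t]]) {
        cand <- theta * w[[t]]
        if (is.na(w[p]) || cand > w[[p]]) {
          w[p] <- cand
          nxt <- c(nxt, p)
        }
      }
    }
    frontier <- unique(nxt)
  }
  w
}

#' Ontology semantic similarity between diseases
#'
#' Wang-style DAG similarity: for diseases `i` and `j` with ancestor
#' closures `T_i`, `T_j` and contribution maps `S_i`, `S_j` (see
#' [semantic_contribution()]),
#' `M[i, j] = sum_{t in T_i ^ T_j} (S_i(t) + S_j(t)) / (sum S_i + sum S_j)`.
#' Diseases absent from the ontology fall back to a Kronecker-delta row
#' (similar only to themselves), with a warning.
#'
#' @param ontology a [disease_ontology()].
#' @param diseases character vector of disease ids.
#' @param theta decay parameter.
#' @return An n x n symmetric similarity matrix, unit diagonal.
#' @export
semantic_similarity <- function(ontology, diseases, theta = 0.5) {
  n <- length(diseases)
  known <- diseases %in% ontology$nodes
  if (any(!known))
    warning("diseases missing from the ontology get delta similarity rows: ",
            paste(diseases[!known], collapse = ", "))
  contribs <- vector("list", n)
  contribs[known] <- lapply(diseases[known], semantic_contribution,
                            ontology = ontology, theta = theta)
  totals <- vapply(contribs, function(w) if (is.null(w)) 1 else sum(w), 0)
  M <- diag(1, n)
  dimnames(M) <- list(diseases, diseases)
  if (n < 2L) return(M)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (!known[i] || !known[j]) next
      shared <- intersect(names(contribs[[i]]), names(contribs[[j]]))
      num <- sum(contribs[[i]][shared]) + sum(contribs[[j]][shared])
      M[i, j] <- M[j, i] <- num / (totals[i] + totals[j])
    }
  }
  M
}

#' Fuse two similarity matrices by their elementwise mean
#'
#' @param M1,M2 similarity matrices of identical shape and id order.
#' @return The elementwise mean; the unit diagonal is preserved.
#' @export
fuse_mean <- function(M1, M2) {
  if (!all(dim(M1) == dim(M2)))
    stop("shape mismatch: ", paste(dim(M1), collapse = "x"), " vs ",
         paste(dim(M2), collapse = "x"))
  if (!is.null(rownames(M1)) && !is.null(rownames(M2)) &&
      !identical(rownames(M1), rownames(M2)))
    stop("id order mismatch between similarity matrices")
  (M1 + M2) / 2
}

#' Integrated piRNA similarity (sequence + GIP)
#'
#' @param dataset an [association_dataset()]; its adjacency provides the
#'   interaction profiles.
#' @param seq_sim optional precomputed [seq_similarity()] matrix (it does
#'   not depend on the adjacency, so it can be shared across CV folds).
#' @param config a [run_config()] supplying the alignment scoring.
#' @return The fused m x m piRNA similarity matrix.
#' @export
pirna_similarity <- function(dataset, seq_sim = NULL, config = run_config()) {
  if (is.null(seq_sim))
    seq_sim <- seq_similarity(dataset$pirnas, config$sw_match,
                              config$sw_mismatch, config$sw_gap)
  fuse_mean(seq_sim, gip_similarity(dataset$A))
}

#' Integrated disease similarity (semantic + GIP)
#'
#' @param dataset an [association_dataset()].
#' @param ontology a [disease_ontology()].
#' @param sem_sim optional precomputed [semantic_similarity()] matrix.
#' @param config a [run_config()] supplying `theta`.
#' @return The fused n x n disease similarity matrix.
#' @export
disease_similarity <- function(dataset, ontology, sem_sim = NULL,
                               config = run_config()) {
  if (is.null(sem_sim))
    sem_sim <- semantic_similarity(ontology, dataset$diseases, config$theta)
  fuse_mean(sem_sim, gip_similarity(t(dataset$A)))
}

#' Assemble the heterogeneous block matrix
#'
#' Builds the `(m + n) x (m + n)` adjacency of the heterogeneous
#' piRNA-disease graph: `[[S_p, A], [A', S_d]]`.
#'
#' @param S_p m x m piRNA similarity matrix.
#' @param A m x n binary association matrix.
#' @param S_d n x n disease similarity matrix.
#' @return The symmetric block matrix.
#' @export
build_hetero <- function(S_p, A, S_d) {
  m <- nrow(A); n <- ncol(A)
  if (!all(dim(S_p) == c(m, m)) || !all(dim(S_d) == c(n, n)))
    stop("dimension mismatch: S_p must be ", m, "x", m,
         " and S_d must be ", n, "x", n)
  rbind(cbind(S_p, A), cbind(t(A), S_d))
}
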