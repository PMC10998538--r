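# Cross-validation protocol and metrics. Positives and unlabelled pairs are
# each partitioned into five folds; within a fold, every training-time
# quantity (interaction-profile kernels, initial embeddings, reliable
# negatives, the loss) is computed from the adjacency with the test-fold
# positives zeroed, so no test information leaks into training.

#' Split a dataset into five cross-validation folds
#'
#' Positive pairs and unlabelled pairs are shuffled (seeded) and split into
#' `k` near-equal subsets. Each fold records its train/test pair sets and
#' the masked training adjacency `A_train` with test-fold positives zeroed.
#'
#' @param dataset an [association_dataset()].
#' @param k number of folds (5 by default).
#' @param seed RNG seed for the shuffles.
#' @return List of `k` folds, each a list with `test_pos`, `train_pos`,
#'   `test_unl`, `train_unl` (2-column index matrices) and `A_train`.
#' @export
split_5fold <- function(dataset, k = 5L, seed = 1L) {
  pos <- which(dataset$A == 1, arr.ind = TRUE)
  unl <- which(dataset$A == 0, arr.ind = TRUE)
  if (nrow(pos) < k || nrow(unl) < k)
    stop("need at least ", k, " positive and ", k, " unlabelled pairs")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold_pos <- rep_len(seq_len(k), nrow(pos))[sample.int(nrow(pos))]
  fold_unl <- rep_len(seq_len(k), nrow(unl))[sample.int(nrow(unl))]
  lapply(seq_len(k), function(i) {
    test_pos <- pos[fold_pos == i, , drop = FALSE]
    A_train <- dataset$A
    A_train[test_pos] <- 0
    list(fold = i,
         test_pos = test_pos,
         train_pos = pos[fold_pos != i, , drop = FALSE],
         test_unl = unl[fold_unl == i, , drop = FALSE],
         train_unl = unl[fold_unl != i, , drop = FALSE],
         A_train = A_train)
  })
}

#' Rank index of the positive test pairs
#'
#' All test pairs are ranked by score in descending order (ties receive
#' their average rank); the rank index is the mean over positive test pairs
#' of `rank / n_test`. A perfect model that ranks every positive first
#' approaches `(n_pos + 1) / (2 n_test)`; lower is better.
#'
#' @param scores numeric vector of scores for every test pair.
#' @param positive logical vector (or integer index) marking the positive
#'   test pairs within `scores`.
#' @return The rank index, a value in `(0, 1]`.
#' @export
rank_index <- function(scores, positive) {
  if (is.logical(positive)) positive <- which(positive)
  if (!length(positive)) stop("empty positive test set")
  if (length(setdiff(positive, seq_along(scores))))
    stop("positive indices outside the test set")
  r <- rank(-scores, ties.method = "average")
  mean(r[positive]) / length(scores)
}

#' ROC and precision-recall areas
#'
#' AUC is computed from the Mann-Whitney rank statistic; AUPR by step
#' integration of the precision-recall curve over distinct score
#' thresholds (ties grouped).
#'
#' @param scores numeric score vector.
#' @param labels binary labels (0/1 or logical) of the same length.
#' @return Named list with `auc` and `aupr`.
#' @export
auc_aupr <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0L || nn == 0L)
    stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
  # PR curve over distinct thresholds, descending
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  cum_tp <- cumsum(y); cum_fp <- cumsum(1 - y)
  last <- c(s[-1] != s[-length(s)], TRUE)   # last element of each tie group
  tp <- cum_tp[last]; fp <- cum_fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / np
  drec <- diff(c(0, rec))
  list(auc = auc, aupr = sum(drec * prec))
}

#' Per-disease top-percentile flags
#'
#' Flags the piRNAs whose score for `disease` ranks in the top `q` fraction
#' (top `ceiling(q * m)` ranks) within that disease's column.
#'
#' @param scores `m x n` score matrix with piRNA/disease dimnames.
#' @param disease a disease id (column of `scores`).
#' @param q fraction in `(0, 1]`; 0.1 by default.
#' @return Character vector of flagged piRNA ids.
#' @export
top_percent_flags <- function(scores, disease, q = 0.1) {
  if (q <= 0 || q > 1) stop("q must be in (0, 1]")
  col <- scores[, disease]
  k <- ceiling(q * length(col))
  names(sort(col, decreasing = TRUE))[seq_len(k)]
}

#' Run the cross-validation protocol
#'
#' For each fold: zero the test-fold positives out of the adjacency,
#' rebuild the interaction-profile kernels and fused similarities from the
#' masked adjacency, select reliable negatives from the training pools,
#' train the model, score all test pairs (test positives labelled 1, test
#' unlabelled 0), and compute AUC, AUPR and the rank index. Metrics are
#' averaged over the final `report_window` training epochs of each fold,
#' then summarised as mean and variance across folds.
#'
#' @param dataset an [association_dataset()].
#' @param ontology a [disease_ontology()].
#' @param config a [run_config()].
#' @param pul_method negative-selection method passed to
#'   [select_negatives()]; `"none"` trains against all training unlabelled
#'   pairs.
#' @param folds which folds to run (default all 5); running a subset is
#'   useful for quick held-out evaluations.
#' @param k number of folds.
#' @param keep_negatives also return the reliable-negative pair sets
#'   selected in each fold (element `negatives`).
#' @return An object of class `metric_report`: per-fold metric data frame
#'   and the across-fold `mean` and `variance` of `auc`, `aupr` and
#'   `rank_index`.
#' @export
run_cv <- function(dataset, ontology, config = run_config(),
                   pul_method = "combined", folds = NULL, k = 5L,
                   keep_negatives = FALSE) {
  splits <- split_5fold(dataset, k = k, seed = config$seed)
  if (is.null(folds)) folds <- seq_len(k)
  seq_sim <- seq_similarity(dataset$pirnas, config$sw_match,
                            config$sw_mismatch, config$sw_gap)
  sem_sim <- semantic_similarity(ontology, dataset$diseases, config$theta)
  corpus <- lapply(dataset$pirnas$sequence, tokenize_kmers, k = config$kmer_k)
  vocab <- train_kmer_embeddings(corpus, d_w = config$word_dim,
                                 window = config$word_window,
                                 epochs = config$word_epochs,
                                 seed = config$seed)
  window <- max(1L, min(config$report_window, config$epochs))
  snap_eps <- (config$epochs - window + 1L):config$epochs
  per_fold <- lapply(folds, function(i) {
    fold <- splits[[i]]
    ds_tr <- replace_A(dataset, fold$A_train)
    S_p <- pirna_similarity(ds_tr, seq_sim, config)
    S_d <- disease_similarity(ds_tr, ontology, sem_sim, config)
    rn <- select_negatives(pul_method, fold$train_pos, fold$train_unl,
                           S_p, S_d, config)
    model <- pda_train(dataset, ontology, config,
                       positives = fold$train_pos, negatives = rn$pairs,
                       A_train = fold$A_train, seq_sim = seq_sim,
                       sem_sim = sem_sim, vocab = vocab,
                       snapshot_epochs = snap_eps)
    test_pairs <- rbind(fold$test_pos, fold$test_unl)
    lab <- rep(c(1, 0), c(nrow(fold$test_pos), nrow(fold$test_unl)))
    per_epoch <- vapply(model$snapshots, function(P) {
      sc <- P[test_pairs]
      met <- auc_aupr(sc, lab)
      c(met$auc, met$aupr, rank_index(sc, lab == 1))
    }, numeric(3))
    avg <- rowMeans(per_epoch)
    list(row = data.frame(fold = i, auc = avg[1], aupr = avg[2],
                          rank_index = avg[3],
                          n_reliable_neg = nrow(rn$pairs)),
         negatives = if (keep_negatives) rn$pairs)
  })
  tab <- do.call(rbind, lapply(per_fold, `[[`, "row"))
  met <- tab[, c("auc", "aupr", "rank_index")]
  structure(list(per_fold = tab,
                 mean = colMeans(met),
                 variance = apply(met, 2, stats::var),
                 pul_method = pul_method,
                 negatives = if (keep_negatives)
                   lapply(per_fold, `[[`, "negatives")),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("metric_report (%s PU selection, %d fold(s)):\n",
              x$pul_method, nrow(x$per_fold)))
  for (nm in names(x$mean))
    cat(sprintf("  %-10s %.4f (var %.5f)\n", nm, x$mean[[nm]],
                if (is.na(x$variance[[nm]])) 0 else x$variance[[nm]]))
  invisible(x)
}

#' Spy-fraction sweep
#'
#' Re-runs [run_cv()] with the combined PU method at a series of spy
#' fractions.
#'
#' @param dataset,ontology,config as in [run_cv()].
#' @param fractions spy fractions to evaluate.
#' @param folds folds to run per fraction.
#' @return Data frame with one row per fraction: mean AUC, AUPR and rank
#'   index.
#' @export
sweep_spy <- function(dataset, ontology, config = run_config(),
                      fractions = seq(0.01, 0.10, by = 0.01), folds = NULL) {
  rows <- lapply(fractions, function(f) {
    cfg <- config; cfg$spy_frac <- f
    rep_ <- run_cv(dataset, ontology, cfg, pul_method = "combined",
                   folds = folds)
    data.frame(spy_frac = f, auc = rep_$mean[["auc"]],
               aupr = rep_$mean[["aupr"]],
               rank_index = rep_$mean[["rank_index"]])
  })
  do.call(rbind, rows)
}
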