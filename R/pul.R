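# Reliable-negative selection from the unlabelled pair set: spy technique,
# positive-unlabelled bagging and two-step relabelling, plus their union.
# Random forests are fitted with ranger (500 trees by default, seeded,
# single-threaded).

#' Pair feature vectors from the similarity matrices
#'
#' The feature of pair `(i, j)` is the concatenation of the `i`-th row of
#' the fused piRNA similarity matrix and the `j`-th row of the fused
#' disease similarity matrix, giving a vector of length `m + n`.
#'
#' @param S_p m x m piRNA similarity matrix.
#' @param S_d n x n disease similarity matrix.
#' @param pairs 2-column index matrix of `(piRNA, disease)` pairs.
#' @return A `nrow(pairs) x (m + n)` feature matrix.
#' @export
pair_features <- function(S_p, S_d, pairs) {
  pairs <- as.matrix(pairs)
  if (nrow(pairs) &&
      (max(pairs[, 1]) > nrow(S_p) || max(pairs[, 2]) > nrow(S_d) ||
       min(pairs) < 1))
    stop("pair index out of range")
  cbind(S_p[pairs[, 1], , drop = FALSE], S_d[pairs[, 2], , drop = FALSE])
}

rf_fit <- function(X, y, n_trees, seed) {
  X <- unname(as.matrix(X))
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  # ranger interprets seed 0 as "seed from the clock"; shift to stay
  # deterministic for every caller-supplied seed
  ranger::ranger(x = X, y = factor(y, levels = c(0, 1)),
                 num.trees = n_trees, probability = TRUE,
                 seed = as.integer(seed) + 1L, num.threads = 1L)
}

rf_prob <- function(fit, X) {
  X <- unname(as.matrix(X))
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  stats::predict(fit, X, num.threads = 1L)$predictions[, "1"]
}

pair_key <- function(pairs) paste(pairs[, 1], pairs[, 2], sep = ":")

new_rn_set <- function(pairs, method) {
  pairs <- as.matrix(pairs)
  colnames(pairs) <- c("pirna", "disease")
  structure(list(pairs = pairs, method = method), class = "reliable_negatives")
}

#' @export
print.reliable_negatives <- function(x, ...) {
  cat(sprintf("reliable_negatives: %d pairs (%s)\n", nrow(x$pairs),
              paste(x$method, collapse = "+")))
  invisible(x)
}

#' Spy-based reliable-negative selection
#'
#' Plants a random 5% (by default) of the positive pairs as spies inside
#' the unlabelled set, trains a random forest treating everything unlabelled
#' (spies included) as negative, and keeps the unlabelled pairs whose
#' posterior probability of being positive falls below the lowest spy
#' posterior. Spies are only used for calibration; the returned set never
#' contains a known positive.
#'
#' @param positives,unlabelled 2-column index matrices of pairs.
#' @param S_p,S_d fused similarity matrices supplying the pair features.
#' @param config a [run_config()] (`spy_frac`, `rf_estimators`).
#' @param seed RNG seed.
#' @return A `reliable_negatives` object; attribute `threshold` records the
#'   minimum spy posterior.
#' @export
spy_select <- function(positives, unlabelled, S_p, S_d,
                       config = run_config(), seed = config$seed) {
  positives <- as.matrix(positives); unlabelled <- as.matrix(unlabelled)
  if (nrow(unlabelled) == 0L)
    return(new_rn_set(unlabelled, "spy"))
  n_spy <- ceiling(config$spy_frac * nrow(positives))
  if (n_spy < 1L)
    stop("zero spies; increase spy_frac")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  spy_idx <- sample.int(nrow(positives), n_spy)
  X_pos <- pair_features(S_p, S_d, positives[-spy_idx, , drop = FALSE])
  X_spy <- pair_features(S_p, S_d, positives[spy_idx, , drop = FALSE])
  X_unl <- pair_features(S_p, S_d, unlabelled)
  fit <- rf_fit(rbind(X_pos, X_unl, X_spy),
                c(rep(1, nrow(X_pos)), rep(0, nrow(X_unl) + nrow(X_spy))),
                config$rf_estimators, seed)
  thr <- min(rf_prob(fit, X_spy))
  post <- rf_prob(fit, X_unl)
  out <- new_rn_set(unlabelled[post < thr, , drop = FALSE], "spy")
  attr(out, "threshold") <- thr
  attr(out, "posteriors") <- post
  out
}

#' PU-bagging reliable-negative selection
#'
#' In each of `bag_rounds` rounds, fits `n_bags` bootstrap random forests,
#' each trained on the positives versus an equally sized random draw of
#' unlabelled pairs, and scores the out-of-bag unlabelled pairs; the
#' per-round out-of-bag averages are averaged across rounds. The averaged
#' scores are sorted and partitioned into three clusters by 1-D k-means
#' (quantile-initialised, deterministic); the middle cluster is returned.
#'
#' @inheritParams spy_select
#' @return A `reliable_negatives` object; attribute `scores` carries the
#'   averaged probabilities, attribute `degenerate` flags the fallback when
#'   fewer than three score clusters exist.
#' @export
bagging_select <- function(positives, unlabelled, S_p, S_d,
                           config = run_config(), seed = config$seed) {
  positives <- as.matrix(positives); unlabelled <- as.matrix(unlabelled)
  nu <- nrow(unlabelled)
  if (nu == 0L) return(new_rn_set(unlabelled, "bagging"))
  if (nu < nrow(positives))
    stop("PU bagging needs at least as many unlabelled pairs as positives")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  X_pos <- pair_features(S_p, S_d, positives)
  X_unl <- pair_features(S_p, S_d, unlabelled)
  y <- c(rep(1, nrow(X_pos)), rep(0, nrow(X_pos)))
  round_means <- matrix(NA_real_, nu, config$bag_rounds)
  for (r in seq_len(config$bag_rounds)) {
    ssum <- numeric(nu); scnt <- integer(nu)
    for (b in seq_len(config$n_bags)) {
      sub_seed <- seed + 1000L * r + b
      set.seed(sub_seed)
      bag <- sample.int(nu, nrow(X_pos), replace = nrow(X_pos) > nu)
      fit <- rf_fit(rbind(X_pos, X_unl[bag, , drop = FALSE]), y,
                    config$rf_estimators, sub_seed)
      oob <- setdiff(seq_len(nu), bag)
      if (length(oob)) {
        ssum[oob] <- ssum[oob] + rf_prob(fit, X_unl[oob, , drop = FALSE])
        scnt[oob] <- scnt[oob] + 1L
      }
    }
    round_means[scnt > 0L, r] <- ssum[scnt > 0L] / scnt[scnt > 0L]
  }
  scores <- rowMeans(round_means, na.rm = TRUE)
  if (anyNA(scores)) {
    warning("some unlabelled pairs were never out-of-bag; ",
            "imputing their score as the mean of scored pairs")
    scores[is.na(scores)] <- mean(scores, na.rm = TRUE)
  }
  cl <- cluster_scores_3(scores)
  out <- new_rn_set(unlabelled[cl$middle, , drop = FALSE], "bagging")
  attr(out, "scores") <- scores
  attr(out, "degenerate") <- cl$degenerate
  out
}

# deterministic 1-D 3-means on scores (quantile initialisation); returns the
# indices of the middle-centroid cluster. With fewer than three distinct
# values the partition is degenerate and the lowest tertile of the sorted
# order is returned, flagged.
cluster_scores_3 <- function(scores) {
  if (length(unique(scores)) < 3L) {
    ord <- order(scores)
    third <- ord[seq_len(ceiling(length(scores) / 3))]
    return(list(middle = third, degenerate = TRUE))
  }
  centers <- stats::quantile(scores, c(1, 3, 5) / 6, names = FALSE)
  if (anyDuplicated(centers))
    centers <- centers + c(-1, 0, 1) * 1e-9
  km <- stats::kmeans(scores, centers = matrix(centers, 3, 1))
  mid <- order(km$centers[, 1])[2]
  list(middle = which(km$cluster == mid), degenerate = FALSE)
}

#' Two-step reliable-negative selection
#'
#' Starts from the assumption that every unlabelled pair is negative, then
#' iterates: fit a random forest on the current labelling, promote
#' unlabelled pairs scoring above the highest current-positive score to
#' positives, and confirm as negative the pairs scoring below the lowest
#' current-positive score. Pair posteriors are the forest's out-of-bag
#' estimates — every pair is a training point here, and resubstitution
#' scores saturate at the class label, which would make the positive-score
#' range vacuous. After the final iteration the explicitly confirmed
#' negatives are returned; promoted pairs never appear in the output.
#'
#' @inheritParams spy_select
#' @return A `reliable_negatives` object.
#' @export
two_step_select <- function(positives, unlabelled, S_p, S_d,
                            config = run_config(), seed = config$seed) {
  positives <- as.matrix(positives); unlabelled <- as.matrix(unlabelled)
  if (nrow(positives) == 0L || nrow(unlabelled) == 0L)
    stop("two-step selection needs non-empty positive and unlabelled sets")
  X_pos <- pair_features(S_p, S_d, positives)
  X_unl <- pair_features(S_p, S_d, unlabelled)
  np <- nrow(X_pos); nu <- nrow(X_unl)
  lab_unl <- rep(0, nu)          # current training labels of unlabelled pairs
  confirmed <- rep(FALSE, nu)    # explicitly confirmed negatives
  for (it in seq_len(config$two_step_iters)) {
    fit <- rf_fit(rbind(X_pos, X_unl), c(rep(1, np), lab_unl),
                  config$rf_estimators, seed + it)
    oob <- fit$predictions[, "1"]
    s_pos <- c(oob[seq_len(np)], oob[np + which(lab_unl == 1)])
    s_unl <- oob[np + seq_len(nu)]
    lab_unl[s_unl > max(s_pos)] <- 1
    confirmed <- s_unl < min(s_pos) & lab_unl == 0
  }
  if (!any(confirmed))
    warning("two-step confirmed no negatives")
  new_rn_set(unlabelled[confirmed, , drop = FALSE], "two_step")
}

#' Union of reliable-negative sets
#'
#' @param sets list of `reliable_negatives` objects.
#' @return A `reliable_negatives` object whose pairs are the set union,
#'   with merged provenance.
#' @export
combine_union <- function(sets) {
  pairs <- do.call(rbind, lapply(sets, `[[`, "pairs"))
  if (is.null(pairs)) pairs <- matrix(integer(), 0, 2)
  pairs <- pairs[!duplicated(pair_key(pairs)), , drop = FALSE]
  new_rn_set(pairs, unlist(lapply(sets, `[[`, "method")))
}

#' Run one or all PU selection methods
#'
#' @param method `"spy"`, `"bagging"`, `"two_step"`, `"combined"` (union of
#'   the three) or `"none"` (every unlabelled pair is treated as negative).
#' @inheritParams spy_select
#' @return A `reliable_negatives` object.
#' @export
select_negatives <- function(method = c("combined", "spy", "bagging",
                                        "two_step", "none"),
                             positives, unlabelled, S_p, S_d,
                             config = run_config(), seed = config$seed) {
  method <- match.arg(method)
  switch(method,
    none = new_rn_set(as.matrix(unlabelled), "none"),
    spy = spy_select(positives, unlabelled, S_p, S_d, config, seed),
    bagging = bagging_select(positives, unlabelled, S_p, S_d, config, seed),
    two_step = two_step_select(positives, unlabelled, S_p, S_d, config, seed),
    combined = combine_union(list(
      spy_select(positives, unlabelled, S_p, S_d, config, seed),
      bagging_select(positives, unlabelled, S_p, S_d, config, seed),
      two_step_select(positives, unlabelled, S_p, S_d, config, seed))))
}
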