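#' @keywords internal
"_PACKAGE"

# ---- piRNA records ----------------------------------------------------------

#' Construct a validated set of piRNA records
#'
#' A piRNA record is an identifier plus a DNA-alphabet sequence. RNA input is
#' accepted: `U` is normalised to `T` and case is folded to upper. Sequences
#' must be at least 3 nt long (shorter sequences cannot be tokenized into
#' 3-mers) and identifiers must be unique and non-empty.
#'
#' @param id character vector of identifiers.
#' @param sequence character vector of sequences over `{A,C,G,T,U}` (any case).
#' @return A `data.frame` with columns `id` and `sequence`, one row per piRNA.
#' @examples
#' pirna_records(c("p1", "p2"), c("AUUGCAU", "acgtacgt"))
#' @export
pirna_records <- function(id, sequence) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  sequence <- gsub("U", "T", sequence, fixed = TRUE)
  if (length(id) != length(sequence))
    stop("id and sequence must have equal length")
  if (any(!nzchar(id)))
    stop("piRNA ids must be non-empty")
  dup <- unique(id[duplicated(id)])
  if (length(dup))
    stop("duplicate piRNA ids: ", paste(utils::head(dup, 5), collapse = ", "))
  bad <- grepl("[^ACGT]", sequence)
  if (any(bad))
    stop("sequences contain characters outside {A,C,G,T,U}: ",
         paste(utils::head(id[bad], 5), collapse = ", "))
  short <- nchar(sequence) < 3
  if (any(short))
    stop("sequences shorter than 3 nt (cannot be 3-mer tokenized): ",
         paste(utils::head(id[short], 5), collapse = ", "))
  data.frame(id = id, sequence = sequence, stringsAsFactors = FALSE)
}

#' Read piRNA sequences from a FASTA file
#'
#' @param path path to a FASTA file.
#' @return A `data.frame` of piRNA records in file order (see
#'   [pirna_records()] for normalisation rules).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  # keep only the first whitespace-delimited token of each header
  ids <- sub("\\s.*$", "", names(set))
  pirna_records(ids, as.character(set))
}

#' Write piRNA records to a FASTA file
#'
#' @param pirnas a piRNA record data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(pirnas, path) {
  set <- Biostrings::DNAStringSet(pirnas$sequence)
  names(set) <- pirnas$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# ---- disease ontology -------------------------------------------------------

#' Construct a disease ontology from parent edges
#'
#' The ontology is a rooted directed acyclic graph of disease terms given as
#' `(child, parent)` pairs. Terms appearing only as parents are created
#' implicitly. Cycles are rejected.
#'
#' @param parent_edges two-column `data.frame` (or matrix) of
#'   `(child, parent)` term ids; may have zero rows.
#' @param nodes optional character vector of additional isolated terms.
#' @return An object of class `disease_ontology`: a list with elements
#'   `nodes` (character), `edges` (child/parent data frame), `parents`
#'   (named list: term -> character vector of parents), `children` (the
#'   reverse map) and `roots`.
#' @export
disease_ontology <- function(parent_edges = NULL, nodes = NULL) {
  if (is.null(parent_edges) || NROW(parent_edges) == 0L) {
    edges <- data.frame(child = character(), parent = character(),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(child = as.character(parent_edges[[1]]),
                        parent = as.character(parent_edges[[2]]),
                        stringsAsFactors = FALSE)
    edges <- unique(edges)
    if (any(edges$child == edges$parent))
      stop("ontology cycle detected: ",
           edges$child[edges$child == edges$parent][1], " -> itself")
  }
  all_nodes <- sort(unique(c(edges$child, edges$parent, as.character(nodes))))
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                       vertices = all_nodes)
    if (!igraph::is_dag(g)) {
      # name one cycle: any nontrivial strongly connected component
      comp <- igraph::components(g, mode = "strong")
      bad <- names(comp$membership)[comp$membership ==
                                      which(comp$csize > 1)[1]]
      stop("ontology cycle detected among terms: ",
           paste(bad, collapse = " -> "))
    }
  }
  parents <- split(edges$parent, factor(edges$child, levels = all_nodes))
  children <- split(edges$child, factor(edges$parent, levels = all_nodes))
  roots <- all_nodes[lengths(parents) == 0L]
  structure(list(nodes = all_nodes, edges = edges, parents = parents,
                 children = children, roots = roots),
            class = "disease_ontology")
}

#' @export
print.disease_ontology <- function(x, ...) {
  cat(sprintf("disease_ontology: %d terms, %d parent edges, %d root(s)\n",
              length(x$nodes), nrow(x$edges), length(x$roots)))
  invisible(x)
}

#' Read a disease ontology from TSV or OBO
#'
#' Two dialects are supported: a headerless two-column TSV of
#' `child<TAB>parent` term ids, or a minimal OBO file (only `[Term]`, `id:`
#' and `is_a:` lines are interpreted). An empty file yields an empty
#' ontology.
#'
#' @param path file path.
#' @param format `"auto"` (default; OBO if the file contains a `[Term]`
#'   stanza), `"tsv"` or `"obo"`.
#' @return A [disease_ontology()] object.
#' @export
read_ontology <- function(path, format = c("auto", "tsv", "obo")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto")
    format <- if (any(grepl("^\\[Term\\]", lines))) "obo" else "tsv"
  if (format == "obo") {
    return(parse_obo_lines(lines))
  }
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(disease_ontology())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L))
    stop("ontology TSV must have two tab-separated columns (child, parent)")
  disease_ontology(data.frame(child = vapply(parts, `[`, "", 1L),
                              parent = vapply(parts, `[`, "", 2L)))
}

# minimal OBO: [Term] stanzas with id: and is_a: lines
parse_obo_lines <- function(lines) {
  term_starts <- grep("^\\[Term\\]", lines)
  if (!length(term_starts)) return(disease_ontology())
  bounds <- c(term_starts, length(lines) + 1L)
  child <- parent <- character()
  nodes <- character()
  for (i in seq_along(term_starts)) {
    block <- lines[bounds[i]:(bounds[i + 1L] - 1L)]
    id <- sub("^id:\\s*", "", grep("^id:", block, value = TRUE))
    if (!length(id)) next
    id <- trimws(id[1])
    nodes <- c(nodes, id)
    isa <- sub("^is_a:\\s*", "", grep("^is_a:", block, value = TRUE))
    isa <- trimws(sub("\\s*!.*$", "", isa))
    child <- c(child, rep(id, length(isa)))
    parent <- c(parent, isa)
  }
  disease_ontology(data.frame(child = child, parent = parent), nodes = nodes)
}

#' Write an ontology as a child-parent TSV
#'
#' @param ontology a [disease_ontology()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ontology <- function(ontology, path) {
  utils::write.table(ontology$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- association dataset ----------------------------------------------------

#' Construct a piRNA-disease association dataset
#'
#' Holds the ordered piRNA records, ordered disease ids and the binary
#' association (adjacency) matrix `A` with `A[i, j] = 1` when piRNA `i` is
#' associated with disease `j`. Rows and columns are ordered
#' lexicographically by id so that repeated loads are bit-identical.
#'
#' @param pirnas piRNA record data frame (see [pirna_records()]).
#' @param diseases character vector of disease ids.
#' @param edges two-column data frame of `(pirna_id, disease_id)` known
#'   associations; duplicates are collapsed. May have zero rows.
#' @return An object of class `association_dataset`: list with `pirnas`,
#'   `diseases`, and binary matrix `A` (dimnames = ids).
#' @export
association_dataset <- function(pirnas, diseases, edges = NULL) {
  pirnas <- pirnas[order(pirnas$id), , drop = FALSE]
  rownames(pirnas) <- NULL
  diseases <- sort(unique(as.character(diseases)))
  if (!length(diseases)) stop("at least one disease id is required")
  m <- nrow(pirnas); n <- length(diseases)
  A <- matrix(0, m, n, dimnames = list(pirnas$id, diseases))
  if (!is.null(edges) && NROW(edges) > 0L) {
    pid <- as.character(edges[[1]]); did <- as.character(edges[[2]])
    unknown_p <- setdiff(unique(pid), pirnas$id)
    unknown_d <- setdiff(unique(did), diseases)
    if (length(unknown_p) || length(unknown_d))
      stop("edges reference unknown ids: ",
           paste(utils::head(c(unknown_p, unknown_d), 10), collapse = ", "))
    A[cbind(match(pid, pirnas$id), match(did, diseases))] <- 1
  }
  structure(list(pirnas = pirnas, diseases = diseases, A = A),
            class = "association_dataset")
}

#' @export
print.association_dataset <- function(x, ...) {
  cat(sprintf(
    "association_dataset: %d piRNAs x %d diseases, %d known associations (density %.4f)\n",
    nrow(x$A), ncol(x$A), sum(x$A), mean(x$A)))
  invisible(x)
}

#' Fraction of piRNA-disease pairs with a known association
#'
#' @param dataset an [association_dataset()].
#' @return `sum(A) / (m * n)`.
#' @export
association_density <- function(dataset) {
  mean(dataset$A)
}

#' Read known associations from a TSV edge list
#'
#' The file is a headerless two-column TSV `pirna_id<TAB>disease_id`.
#' Duplicate edges collapse to a single association; every id must be
#' present in `pirnas` / `diseases`.
#'
#' @param path file path.
#' @param pirnas piRNA record data frame defining the row universe.
#' @param diseases character vector defining the column universe.
#' @return An [association_dataset()].
#' @export
read_associations <- function(path, pirnas, diseases) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(association_dataset(pirnas, diseases))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L))
    stop("association TSV must have two tab-separated columns")
  edges <- data.frame(pirna = vapply(parts, `[`, "", 1L),
                      disease = vapply(parts, `[`, "", 2L))
  association_dataset(pirnas, diseases, edges)
}

#' Write the known associations of a dataset as a TSV edge list
#'
#' @param dataset an [association_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(dataset, path) {
  idx <- which(dataset$A == 1, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  edges <- data.frame(pirna = rownames(dataset$A)[idx[, 1]],
                      disease = colnames(dataset$A)[idx[, 2]])
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- labelled matrix TSV ----------------------------------------------------

#' Read/write a labelled dense matrix as TSV
#'
#' Matrices (similarity matrices, score matrices) are stored as TSV with a
#' header row of column ids and a first column of row ids.
#'
#' @param M numeric matrix with dimnames.
#' @param path file path.
#' @return `write_matrix_tsv`: `path`, invisibly. `read_matrix_tsv`: the
#'   matrix.
#' @export
write_matrix_tsv <- function(M, path) {
  df <- data.frame(id = rownames(M), M, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df[[1]]
  M
}

# ---- run configuration ------------------------------------------------------

#' Pipeline configuration
#'
#' Collects the tunable parameters of the whole pipeline with the default
#' values used throughout: 3-mer tokenization, 128-dimensional piRNA
#' embedding, two attention heads, 5% spies, 500-tree random forests,
#' 30 bagging bootstraps over 5 rounds, 5 two-step iterations, semantic
#' decay 0.5 and a 2-layer graph convolution.
#'
#' @param kmer_k k-mer length for tokenization.
#' @param embed_dim piRNA embedding dimension (also the GCN/attention width).
#' @param n_heads number of attention heads; must divide `embed_dim`.
#' @param spy_frac fraction of positives planted as spies.
#' @param rf_estimators trees per random forest.
#' @param n_bags bootstrap classifiers per PU-bagging round.
#' @param bag_rounds PU-bagging rounds whose scores are averaged.
#' @param two_step_iters two-step relabelling iterations.
#' @param theta semantic-similarity decay parameter.
#' @param gcn_layers number of graph-convolution layers.
#' @param word_dim skip-gram vector dimension for 3-mers.
#' @param word_window skip-gram context window.
#' @param word_epochs skip-gram training epochs.
#' @param n_filters convolution filters per kernel size in the text encoder.
#' @param kernel_sizes convolution kernel sizes (in tokens).
#' @param lr Adam learning rate.
#' @param epochs training epochs for the graph model.
#' @param final_relu apply ReLU after the last GCN layer.
#' @param sw_match,sw_mismatch,sw_gap Smith-Waterman scoring parameters.
#' @param report_window number of final epochs whose metrics are averaged
#'   when reporting cross-validation performance.
#' @param seed integer seed used for every stochastic stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(kmer_k = 3L, embed_dim = 128L, n_heads = 2L,
                       spy_frac = 0.05, rf_estimators = 500L, n_bags = 30L,
                       bag_rounds = 5L, two_step_iters = 5L, theta = 0.5,
                       gcn_layers = 2L, word_dim = 64L, word_window = 5L,
                       word_epochs = 5L, n_filters = 128L,
                       kernel_sizes = c(1L, 3L, 5L), lr = 1e-3,
                       epochs = 200L, final_relu = TRUE,
                       sw_match = 2, sw_mismatch = -1, sw_gap = -1,
                       report_window = 5L, seed = 1L) {
  cfg <- list(kmer_k = as.integer(kmer_k), embed_dim = as.integer(embed_dim),
              n_heads = as.integer(n_heads), spy_frac = spy_frac,
              rf_estimators = as.integer(rf_estimators),
              n_bags = as.integer(n_bags), bag_rounds = as.integer(bag_rounds),
              two_step_iters = as.integer(two_step_iters), theta = theta,
              gcn_layers = as.integer(gcn_layers),
              word_dim = as.integer(word_dim),
              word_window = as.integer(word_window),
              word_epochs = as.integer(word_epochs),
              n_filters = as.integer(n_filters),
              kernel_sizes = as.integer(kernel_sizes), lr = lr,
              epochs = as.integer(epochs), final_relu = isTRUE(final_relu),
              sw_match = sw_match, sw_mismatch = sw_mismatch, sw_gap = sw_gap,
              report_window = as.integer(report_window),
              seed = as.integer(seed))
  if (cfg$spy_frac <= 0 || cfg$spy_frac >= 1)
    stop("spy_frac must be in (0, 1)")
  if (cfg$embed_dim %% cfg$n_heads != 0L)
    stop("n_heads must divide embed_dim")
  counts <- c(cfg$kmer_k, cfg$embed_dim, cfg$n_heads, cfg$rf_estimators,
              cfg$n_bags, cfg$bag_rounds, cfg$two_step_iters, cfg$gcn_layers,
              cfg$word_dim, cfg$n_filters, cfg$epochs, cfg$report_window)
  if (any(counts <= 0L)) stop("all count parameters must be positive")
  if (cfg$theta <= 0 || cfg$theta >= 1) stop("theta must be in (0, 1)")
  class(cfg) <- "run_config"
  cfg
}
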