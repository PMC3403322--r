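#' Filter annotations to well-populated (leaf) GO terms
#'
#' Restricts an annotation table to the terms the method trains on: by
#' default leaf terms only (the functionally most specific level) carrying
#' at least `min_proteins` distinct proteins — terms with fewer than 5
#' proteins are screened out.
#'
#' @param annotations annotation data frame (`protein_id`, `go_term`).
#' @param go_graph a [go_graph].
#' @param min_proteins minimum distinct proteins per retained term.
#' @param leaf_only keep leaf terms only.
#' @return The filtered annotation data frame (possibly empty, with a
#'   warning).
#' @export
filter_go_terms <- function(annotations, go_graph, min_proteins = 5,
                            leaf_only = TRUE) {
  stopifnot(inherits(go_graph, "go_graph"))
  keep_terms <- unique(annotations$go_term)
  if (leaf_only) {
    leaves <- unlist(lapply(unique(go_graph$namespace), function(ns)
      go_leaves(go_graph, ns)), use.names = FALSE)
    keep_terms <- intersect(keep_terms, leaves)
  }
  counts <- vapply(keep_terms, function(t)
    length(.ann_proteins(annotations, t)), integer(1))
  keep_terms <- keep_terms[counts >= min_proteins]
  out <- annotations[annotations$go_term %in% keep_terms, , drop = FALSE]
  if (nrow(out) == 0) .warn("no annotations survive the GO-term filter")
  rownames(out) <- NULL
  out
}

#' Greedy sequence redundancy filter
#'
#' A lightweight stand-in for CD-HIT-style redundancy removal: sequences
#' are visited longest first; each joins the first existing cluster whose
#' representative it matches above the identity threshold, otherwise it
#' founds a new cluster. Identity is estimated as the fraction of shared
#' k-mers (k = 5 by default) relative to the k-mer set of the shorter
#' sequence — a cheap, monotone proxy, not a CD-HIT replica. Exactly
#' identical sequences always collapse; otherwise membership requires
#' estimated identity strictly above the threshold (so at threshold 1 only
#' exact duplicates collapse).
#'
#' @param sequences named character vector of protein sequences.
#' @param identity_threshold clustering threshold in `[0, 1]`; 0.80 is the
#'   operating default.
#' @param k k-mer length of the identity estimate.
#' @return Character vector of representative ids (one per cluster, in
#'   cluster-founding order).
#' @export
redundancy_filter <- function(sequences, identity_threshold = 0.80, k = 5L) {
  if (length(sequences) == 0) .stop("no sequences to filter")
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    .stop("sequences must be named")
  }
  kmers <- function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    unique(substring(s, 1:(n - k + 1), k:n))
  }
  ord <- order(-nchar(sequences), names(sequences))
  reps <- character()
  rep_kmers <- list()
  for (i in ord) {
    id <- names(sequences)[i]
    s <- sequences[[i]]
    ks <- kmers(s)
    joined <- FALSE
    for (j in seq_along(reps)) {
      rs <- sequences[[reps[j]]]
      if (identical(s, rs)) { joined <- TRUE; break }
      denom <- min(length(ks), length(rep_kmers[[j]]))
      if (denom == 0) next
      ident <- length(intersect(ks, rep_kmers[[j]])) / denom
      if (ident > identity_threshold) { joined <- TRUE; break }
    }
    if (!joined) {
      reps <- c(reps, id)
      rep_kmers[[length(reps)]] <- ks
    }
  }
  reps
}

#' Build a labeled protein-pair dataset
#'
#' Enumerates the positive universe (unordered protein pairs sharing at
#' least one GO term) and the negative universe (pairs sharing none) from
#' an annotation table, then samples `n_pos` and `n_neg` pairs uniformly
#' without replacement. Pairs are stored in canonical orientation
#' (`protein_i < protein_j`), so no pair occurs twice in either direction.
#'
#' @param annotations annotation data frame.
#' @param n_pos,n_neg numbers of positive / negative pairs to draw.
#' @param seed integer seed making the draw reproducible.
#' @return An object of class `pair_dataset`: data frame `protein_i`,
#'   `protein_j`, `label` with attributes `n_pos`, `n_neg`, `seed`.
#' @export
make_pair_dataset <- function(annotations, n_pos, n_neg, seed = 1L) {
  proteins <- sort(unique(annotations$protein_id))
  if (length(proteins) < 2) .stop("need at least two annotated proteins")
  term_sets <- lapply(proteins, function(p) .ann_terms(annotations, p))
  names(term_sets) <- proteins
  n <- length(proteins)
  idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  shares <- vapply(seq_len(nrow(idx)), function(r) {
    length(intersect(term_sets[[idx[r, 1]]], term_sets[[idx[r, 2]]])) > 0
  }, logical(1))
  pos_idx <- idx[shares, , drop = FALSE]
  neg_idx <- idx[!shares, , drop = FALSE]
  if (nrow(pos_idx) < n_pos || nrow(neg_idx) < n_neg) {
    .stop(sprintf(paste0("insufficient pairs: %d positive and %d negative ",
                         "available, %d and %d requested"),
                  nrow(pos_idx), nrow(neg_idx), n_pos, n_neg))
  }
  set.seed(seed)
  pos_take <- pos_idx[sample(nrow(pos_idx), n_pos), , drop = FALSE]
  neg_take <- neg_idx[sample(nrow(neg_idx), n_neg), , drop = FALSE]
  out <- data.frame(
    protein_i = proteins[c(pos_take[, 1], neg_take[, 1])],
    protein_j = proteins[c(pos_take[, 2], neg_take[, 2])],
    label = rep(c(1L, 0L), c(n_pos, n_neg)))
  attr(out, "n_pos") <- n_pos
  attr(out, "n_neg") <- n_neg
  attr(out, "seed") <- seed
  class(out) <- c("pair_dataset", "data.frame")
  out
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a uniformly chosen positive outscores a uniformly
#' chosen negative, with ties counted one half; computed from midranks.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels, both classes present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) .stop("scores and labels differ in length")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) .stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Stratified k-fold cross-validation of the mapping engine
#'
#' Partitions a labeled pair dataset into `folds` folds, each with an equal
#' share of positive and negative pairs, trains the mapping engine on the
#' remaining folds and evaluates accuracy (at threshold 0.5) and AUC on the
#' held-out fold; each pair is validated exactly once. Pairs — not proteins
#' — are partitioned, so a protein may appear on both sides of a split (a
#' known leakage caveat of this protocol).
#'
#' @param dataset a [make_pair_dataset()] result (or any data frame with
#'   `protein_i`, `protein_j`, `label`).
#' @param responses response matrix covering every protein of the dataset.
#' @param spec a [kernel_spec].
#' @param engine `"least_squares"` or `"svm"`.
#' @param folds number of folds (default 5).
#' @param reg regularization; `NULL` for the per-fold default.
#' @param seed integer seed for the fold shuffle.
#' @param threshold classification threshold for the accuracy column.
#' @return An object of class `cv_report`: list with `per_fold` (data
#'   frame `fold`, `accuracy`, `auc`), `mean_accuracy`, `mean_auc`,
#'   `fold_of` (fold id per pair), and the settings used.
#' @export
cross_validate <- function(dataset, responses, spec = kernel_spec("gaussian"),
                           engine = c("least_squares", "svm"), folds = 5L,
                           reg = NULL, seed = 1L, threshold = 0.5) {
  engine <- match.arg(engine)
  n <- nrow(dataset)
  if (folds < 2 || folds > n) .stop("'folds' must be between 2 and the dataset size")
  set.seed(seed)
  fold_of <- integer(n)
  for (lab in c(0L, 1L)) {
    idx <- which(dataset$label == lab)
    fold_of[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  per <- data.frame(fold = seq_len(folds), accuracy = NA_real_, auc = NA_real_)
  for (f in seq_len(folds)) {
    train_ps <- pair_set(responses, dataset[fold_of != f, , drop = FALSE])
    val_ps <- pair_set(responses, dataset[fold_of == f, , drop = FALSE])
    model <- suppressMessages(
      train_mapping(train_ps, spec = spec, engine = engine, reg = reg))
    s <- score_pairs(model, val_ps)
    y <- dataset$label[fold_of == f]
    per$accuracy[f] <- mean(as.integer(s >= threshold) == y)
    per$auc[f] <- auc(s, y)
  }
  structure(list(per_fold = per, mean_accuracy = mean(per$accuracy),
                 mean_auc = mean(per$auc), fold_of = fold_of,
                 settings = list(spec = spec, engine = engine, folds = folds,
                                 reg = reg, seed = seed, threshold = threshold)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%s engine, %s kernel)\n",
              x$settings$folds, x$settings$engine, x$settings$spec$family))
  print(x$per_fold, row.names = FALSE)
  cat(sprintf("mean accuracy %.4f, mean AUC %.4f\n", x$mean_accuracy, x$mean_auc))
  invisible(x)
}

#' Fraction of positively classified pairs by GO edge distance
#'
#' Measures classification specificity: pair groups keyed by the GO edge
#' distance between the two proteins' terms are scored with a trained
#' model, and the fraction classified positive (score >= threshold) is
#' reported per level. With distance-structured data the fraction should
#' decay as the edge distance grows.
#'
#' @param model a trained [mapping_model][train_mapping].
#' @param responses response matrix.
#' @param pair_groups named list of data frames (`protein_i`, `protein_j`),
#'   one per distance level; names are the level labels.
#' @param threshold classification threshold.
#' @return Named numeric vector of fractions in `[0, 1]`; empty levels are
#'   omitted with a warning.
#' @export
specificity_by_distance <- function(model, responses, pair_groups,
                                    threshold = 0.5) {
  .check_threshold(threshold)
  out <- numeric(0)
  for (lev in names(pair_groups)) {
    g <- pair_groups[[lev]]
    if (is.null(g) || nrow(g) == 0) {
      .warn("distance level '", lev, "' has no pairs; omitted")
      next
    }
    lab <- classify_pairs(model, pair_set(responses, g), threshold)
    out[lev] <- mean(lab)
  }
  out
}

#' Accuracy as a function of the decision threshold
#'
#' Sweeps the classification threshold over a grid and reports accuracy at
#' each value; the first-best threshold is attached as attribute
#' `best_threshold`.
#'
#' @param model a trained [mapping_model][train_mapping].
#' @param dataset labeled pair data frame.
#' @param responses response matrix.
#' @param grid thresholds in (0, 1).
#' @return Data frame `threshold`, `accuracy` with attribute
#'   `best_threshold`.
#' @export
threshold_sweep <- function(model, dataset, responses,
                            grid = seq(0.1, 0.9, by = 0.1)) {
  for (g in grid) .check_threshold(g)
  s <- score_pairs(model, pair_set(responses, dataset))
  accs <- vapply(grid, function(th)
    mean(as.integer(s >= th) == dataset$label), numeric(1))
  out <- data.frame(threshold = grid, accuracy = accs)
  attr(out, "best_threshold") <- grid[which.max(accs)]
  out
}

#' Write / read labeled pair datasets as TSV
#'
#' @param dataset pair data frame (`protein_i`, `protein_j`, `label`).
#' @param path file path.
#' @return `read_pair_dataset`: the data frame; `write_pair_dataset`:
#'   `path`, invisibly.
#' @export
write_pair_dataset <- function(dataset, path) {
  write.table(dataset, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pair_dataset
#' @export
read_pair_dataset <- function(path) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("protein_i", "protein_j", "label")
  if (!all(need %in% names(tab))) {
    .stop("pair dataset lacks column(s): ",
          paste(setdiff(need, names(tab)), collapse = ", "))
  }
  tab
}
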