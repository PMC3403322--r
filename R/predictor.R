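#' Rank base-set proteins against a query
#'
#' Scores every protein of the pre-annotated base set against the query via
#' f(N(query, base)) and sorts descending — the threshold-free mode of GO
#' assignment, where the query inherits terms from its top-ranked
#' neighbours. Ties are broken deterministically by protein id.
#'
#' @param query_response a [neural_response][compute_response] for the
#'   query, or a 1-row response matrix.
#' @param base_responses response matrix of the base set (rows = proteins).
#' @param model a trained [mapping_model][train_mapping].
#' @return Data frame with columns `rank`, `protein_id`, `score`, ordered
#'   by non-increasing score.
#' @export
rank_base <- function(query_response, base_responses, model) {
  if (inherits(query_response, "neural_response")) {
    q <- query_response$values
  } else {
    q <- drop(query_response)
  }
  if (is.null(dim(base_responses)) || nrow(base_responses) == 0) {
    .stop("empty base set")
  }
  if (length(q) != ncol(base_responses)) {
    .stop("query and base responses use different template libraries")
  }
  V <- matrix(q, nrow(base_responses), length(q), byrow = TRUE) - base_responses
  ps <- structure(list(V = V,
                       A = matrix(q, nrow(base_responses), length(q), byrow = TRUE),
                       B = base_responses,
                       labels = rep(NA, nrow(V)),
                       pairs = data.frame(protein_i = "query",
                                          protein_j = rownames(base_responses))),
                  class = "pair_set")
  s <- score_pairs(model, ps)
  ord <- order(-s, rownames(base_responses))
  data.frame(rank = seq_along(ord),
             protein_id = rownames(base_responses)[ord],
             score = s[ord])
}

#' Assign GO terms from a ranked base list
#'
#' Walks the ranked proteins collecting up to `k` distinct GO terms. For a
#' protein annotated with several terms, leaf terms are preferred (they are
#' the most specific); when only non-leaf candidates remain and sequence
#' diversity counts are supplied, the least-diverse term is taken, since
#' diversity is inversely related to specificity. The confidence attached
#' to a term is the f score of the best-ranked protein contributing it.
#'
#' @param ranked output of [rank_base()].
#' @param annotations annotation data frame (`protein_id`, `go_term`).
#' @param go_graph a [go_graph] used for leaf detection.
#' @param k maximum number of distinct terms to assign (default 5).
#' @param leaf_only when `TRUE`, a protein's leaf terms shadow its
#'   non-leaf terms.
#' @param diversity optional named numeric: representative-sequence counts
#'   per term, used as the tie-break among non-leaf candidates.
#' @param query_id id recorded on the result.
#' @return An object of class `prediction_result`: list with `query_id`,
#'   `ranked`, and `terms` (data frame `go_term`, `confidence`,
#'   `protein_id`, `leaf`).
#' @export
assign_go <- function(ranked, annotations, go_graph, k = 5, leaf_only = TRUE,
                      diversity = NULL, query_id = NA_character_) {
  stopifnot(inherits(go_graph, "go_graph"))
  if (nrow(ranked) == 0) .stop("empty ranking")
  leaves <- unlist(lapply(unique(go_graph$namespace), function(ns)
    go_leaves(go_graph, ns)), use.names = FALSE)
  out <- data.frame(go_term = character(), confidence = numeric(),
                    protein_id = character(), leaf = logical())
  for (r in seq_len(nrow(ranked))) {
    if (nrow(out) >= k) break
    p <- ranked$protein_id[r]
    terms <- .ann_terms(annotations, p)
    if (length(terms) == 0) {
      .warn("ranked protein '", p, "' has no annotation; skipped")
      next
    }
    leaf_terms <- intersect(terms, leaves)
    cand <- if (leaf_only && length(leaf_terms)) sort(leaf_terms) else sort(terms)
    if (length(cand) > 1 && !all(cand %in% leaves) && !is.null(diversity)) {
      known <- cand[cand %in% names(diversity)]
      if (length(known)) cand <- known[which.min(diversity[known])]
    }
    for (term in cand) {
      if (nrow(out) >= k) break
      if (term %in% out$go_term) next
      out <- rbind(out, data.frame(go_term = term, confidence = ranked$score[r],
                                   protein_id = p, leaf = term %in% leaves))
    }
  }
  structure(list(query_id = query_id, ranked = ranked, terms = out, k = k),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("prediction_result <%s>: %d GO term(s) from %d ranked proteins\n",
              x$query_id, nrow(x$terms), nrow(x$ranked)))
  if (nrow(x$terms)) {
    for (i in seq_len(nrow(x$terms))) {
      cat(sprintf("  %s  f = %.4f  via %s%s\n", x$terms$go_term[i],
                  x$terms$confidence[i], x$terms$protein_id[i],
                  if (x$terms$leaf[i]) "  [leaf]" else ""))
    }
  }
  invisible(x)
}

#' Threshold-based GO assignment
#'
#' The threshold-dependent alternative to [rank_base()] + [assign_go()]:
#' every base protein whose score reaches the threshold is labeled 1, and
#' the query inherits the GO terms of all positively labeled proteins.
#'
#' @inheritParams rank_base
#' @param threshold decision threshold in (0, 1).
#' @return Data frame `protein_id`, `score`, `label`, in base-set order.
#' @export
threshold_assign <- function(query_response, base_responses, model,
                             threshold = 0.5) {
  .check_threshold(threshold)
  ranked <- rank_base(query_response, base_responses, model)
  ranked <- ranked[order(ranked$protein_id), ]
  data.frame(protein_id = ranked$protein_id, score = ranked$score,
             label = as.integer(ranked$score >= threshold))
}

#' GO-motif association scores
#'
#' Ranks the motifs mapped to a GO term by `s = NM * AS`, where NM is the
#' number of (non-redundant) proteins of the term hit by the motif, and AS
#' is the motif's alignment strength — by default the mean over those
#' proteins of the per-protein maximal hit score. The product trades off a
#' motif's overrepresentation against its alignment strength. Apply
#' [redundancy_filter()] to the annotations before calling if redundancy
#' matters.
#'
#' @param annotations annotation data frame restricted to the proteins of
#'   interest.
#' @param hits a hit table.
#' @param go_term the GO term whose motif mapping is scored.
#' @param strength how per-protein maxima aggregate into AS: `"mean"`
#'   (default), `"median"` or `"max"`.
#' @return Data frame `motif_id`, `NM`, `AS`, `s`, sorted by `s`
#'   descending (ties by motif id).
#' @export
go_motif_scores <- function(annotations, hits, go_term,
                            strength = c("mean", "median", "max")) {
  strength <- match.arg(strength)
  agg <- switch(strength, mean = mean, median = stats::median, max = max)
  proteins <- .ann_proteins(annotations, go_term)
  if (length(proteins) == 0) .stop("no proteins annotated to ", go_term)
  h <- hits[hits$protein_id %in% proteins, , drop = FALSE]
  if (nrow(h) == 0) {
    return(data.frame(motif_id = character(), NM = integer(), AS = numeric(),
                      s = numeric()))
  }
  # per (protein, motif) maximal score, then aggregate over proteins
  per <- stats::aggregate(score ~ protein_id + template_id, data = h, FUN = max)
  out <- do.call(rbind, lapply(split(per, per$template_id), function(d) {
    data.frame(motif_id = d$template_id[1], NM = nrow(d), AS = agg(d$score))
  }))
  out$s <- out$NM * out$AS
  out <- out[order(-out$s, out$motif_id), ]
  rownames(out) <- NULL
  out
}
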