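#' Synthetic fixture configuration
#'
#' Parameters of the synthetic data generator that emulates the structure
#' the method consumes: a template library with a valid initial kernel, a
#' toy GO tree, per-term protein sets, and per-protein template hits in
#' which proteins of one GO term share a signature template subset.
#'
#' `signal` is the mean hit score on a protein's signature templates;
#' `noise` controls the background: every non-signature template receives a
#' spurious hit with probability `min(1, noise/signal)` (1 when
#' `signal = 0`), with mean score `noise`. Hit scores are drawn from a
#' gamma distribution with shape 16 (standard deviation a quarter of the
#' mean), resembling the positive, right-skewed spread of alignment bit
#' scores. With `signal/noise` around 10 the classes are cleanly separable;
#' at `signal == noise` every coordinate of every response is an
#' independent draw from one distribution, the class structure vanishes by
#' exchangeability, and classification sits at chance.
#'
#' @param m number of templates in the library.
#' @param n_terms number of leaf GO terms receiving proteins.
#' @param proteins_per_term proteins annotated to each term (>= 5, so the
#'   default GO-term filter retains every term).
#' @param signal mean signature hit score (>= 0).
#' @param noise background rate/scale (>= 0); 0 disables background hits.
#' @param templates_per_term nominal signature size per term (<= m).
#' @param depth,branching shape of the toy GO tree the fixture is built on
#'   (see [gen_go_toy()]); the tree must offer at least `n_terms` leaves.
#' @param seed integer seed; all generator randomness flows from it.
#' @return An object of class `fixture_config`.
#' @export
fixture_config <- function(m = 40L, n_terms = 4L, proteins_per_term = 8L,
                           signal = 10, noise = 1, templates_per_term = 4L,
                           depth = 2L, branching = 2L, seed = 1L) {
  if (proteins_per_term < 5) .stop("'proteins_per_term' must be >= 5")
  if (templates_per_term > m) .stop("'templates_per_term' must be <= m")
  if (signal < 0 || noise < 0) .stop("'signal' and 'noise' must be >= 0")
  if (m < 2) .stop("'m' must be >= 2")
  if (branching^depth < n_terms) {
    .stop(sprintf("a depth-%d, branching-%d tree has %d leaves; n_terms = %d",
                  depth, branching, branching^depth, n_terms))
  }
  structure(list(m = as.integer(m), n_terms = as.integer(n_terms),
                 proteins_per_term = as.integer(proteins_per_term),
                 signal = signal, noise = noise,
                 templates_per_term = as.integer(templates_per_term),
                 depth = as.integer(depth), branching = as.integer(branching),
                 seed = as.integer(seed)),
            class = "fixture_config")
}

#' Preset fixture configurations
#'
#' `"easy"` is the default configuration (signal/noise = 10): terms are
#' cleanly separable and the full pipeline should recover them almost
#' perfectly. `"hard"` sets `signal == noise`, making background hits
#' indistinguishable from signature hits so accuracy approaches chance; it
#' also spreads its pairs over a larger protein pool (8 terms x 18
#' proteins), because cross-validation partitions pairs rather than
#' proteins, and with few proteins the co-membership structure of the
#' training pairs alone can reconstruct held-out labels. Keeping each
#' protein in only a couple of sampled pairs mirrors the corpus-scale
#' regime in which that pair-level protocol is honest.
#'
#' @param preset `"easy"` or `"hard"`.
#' @param seed integer seed.
#' @return A [fixture_config].
#' @export
fixture_preset <- function(preset = c("easy", "hard"), seed = 1L) {
  preset <- match.arg(preset)
  switch(preset,
         easy = fixture_config(seed = seed),
         hard = fixture_config(m = 60L, n_terms = 8L, proteins_per_term = 18L,
                               signal = 5, noise = 5, depth = 3L, seed = seed))
}

#' @export
print.fixture_config <- function(x, ...) {
  cat(sprintf(paste0("fixture_config: m = %d, %d terms x %d proteins, ",
                     "signal %g / noise %g, %d signature templates, seed %d\n"),
              x$m, x$n_terms, x$proteins_per_term, x$signal, x$noise,
              x$templates_per_term, x$seed))
  invisible(x)
}

#' Generate a template library with a valid initial kernel
#'
#' Draws a random Gram matrix `S = t(A) %*% A + eps * I` (A standard
#' normal, m x m), which is positive definite by construction with minimum
#' eigenvalue at least `eps`; diagonal entries are then raised to the
#' largest off-diagonal of their row where needed (which preserves both
#' properties), so the result always passes [validate_similarity()].
#'
#' @param config a [fixture_config].
#' @param eps diagonal loading (> 0).
#' @return List with elements `library` (a [template_library]) and
#'   `similarity` (a [template_similarity]).
#' @export
gen_library_and_matrix <- function(config, eps = 1e-6) {
  stopifnot(inherits(config, "fixture_config"))
  if (eps <= 0) .stop("'eps' must be positive")
  set.seed(config$seed)
  m <- config$m
  lib <- template_library(sprintf("T%03d", seq_len(m)))
  A <- matrix(rnorm(m * m), m, m)
  S <- crossprod(A) + diag(eps, m)
  off_max <- apply(S - diag(diag(S)), 1, max)
  diag(S) <- pmax(diag(S), off_max)
  list(library = lib, similarity = template_similarity(lib, S))
}

#' Generate a toy GO tree
#'
#' A complete rooted tree of the given depth and branching factor in the
#' molecular_function namespace, with `is_a` edges child-to-parent. Leaves
#' sit at maximal depth, so any two leaves are separated by an even edge
#' distance determined by their lowest common ancestor.
#'
#' @param depth tree depth (>= 1; the root is depth 0).
#' @param branching children per internal node (>= 2).
#' @return List with `graph` (a [go_graph]) and `leaves` (ids of the
#'   deepest level, sorted).
#' @export
gen_go_toy <- function(depth = 2L, branching = 2L) {
  if (depth < 1) .stop("'depth' must be >= 1")
  if (branching < 2) .stop("'branching' must be >= 2")
  n_nodes <- sum(branching^(0:depth))
  ids <- sprintf("GO:%07d", seq_len(n_nodes))
  # node i's children are at branching*(i-1)+2 ... branching*i+1 (heap layout)
  edges <- do.call(rbind, lapply(seq_len(n_nodes), function(i) {
    kids <- (branching * (i - 1) + 2):(branching * i + 1)
    kids <- kids[kids <= n_nodes]
    if (length(kids) == 0) return(NULL)
    data.frame(child = ids[kids], parent = ids[i])
  }))
  g <- go_graph(ids, edges, rep("molecular_function", n_nodes))
  first_leaf <- sum(branching^(0:(depth - 1))) + 1L
  list(graph = g, leaves = sort(ids[first_leaf:n_nodes]))
}

# internal: ancestor chain of a term up to the root (term first)
.go_ancestry <- function(g, term) {
  chain <- term
  repeat {
    parents <- g$edges$parent[g$edges$child == chain[length(chain)]]
    if (length(parents) == 0) break
    chain <- c(chain, parents[1])
  }
  chain
}

#' Generate annotations and clustered template hits
#'
#' Populates the leaf terms of a toy GO graph with proteins and gives each
#' protein hits on its term's signature templates (scores around `signal`)
#' plus random background hits (around `noise`). Signature templates are
#' allocated per tree node and a leaf's signature is the union of the
#' blocks along its root path, so two terms share signature templates in
#' proportion to the depth of their common ancestor: the number of shared
#' templates decreases linearly with the edge distance between the terms,
#' which makes classification specificity decay with GO distance.
#'
#' @param config a [fixture_config]; `config$m` must cover one block per
#'   tree node (the function errors otherwise, stating the minimum).
#' @param go_graph a [go_graph] from [gen_go_toy()] (any single-namespace
#'   DAG with enough leaves works).
#' @return List with `annotations` (data frame), `hits` (hit table),
#'   `signatures` (named list: template ids per used term).
#' @export
gen_hits <- function(config, go_graph) {
  stopifnot(inherits(config, "fixture_config"), inherits(go_graph, "go_graph"))
  ns <- unique(go_graph$namespace)[1]
  leaves <- go_leaves(go_graph, ns)
  if (length(leaves) < config$n_terms) {
    .stop(sprintf("graph has %d leaf terms, config wants %d", length(leaves),
                  config$n_terms))
  }
  used <- leaves[seq_len(config$n_terms)]
  depth <- length(.go_ancestry(go_graph, used[1])) - 1L
  w <- max(1L, ceiling(config$templates_per_term / (depth + 1)))
  nodes <- sort(go_graph$terms)
  if (config$m < length(nodes) * w) {
    .stop(sprintf("m = %d templates cannot host %d node blocks of width %d; need m >= %d",
                  config$m, length(nodes), w, length(nodes) * w))
  }
  block_of <- stats::setNames(lapply(seq_along(nodes), function(i)
    sprintf("T%03d", ((i - 1) * w + 1):(i * w))), nodes)
  signatures <- stats::setNames(lapply(used, function(t)
    unlist(block_of[.go_ancestry(go_graph, t)], use.names = FALSE)), used)
  all_templates <- sprintf("T%03d", seq_len(config$m))
  set.seed(config$seed + 1L)
  ann <- list()
  hits <- list()
  shape <- 16
  for (t in used) {
    for (i in seq_len(config$proteins_per_term)) {
      pid <- sprintf("P%s_%02d", sub("GO:", "", t), i)
      ann[[length(ann) + 1L]] <- data.frame(protein_id = pid, go_term = t)
      if (config$signal > 0) {
        hits[[length(hits) + 1L]] <- data.frame(
          protein_id = pid, template_id = signatures[[t]],
          score = rgamma(length(signatures[[t]]), shape = shape,
                         rate = shape / config$signal))
      }
      if (config$noise > 0) {
        p_bg <- if (config$signal > 0) min(1, config$noise / config$signal) else 1
        bg_pool <- setdiff(all_templates, signatures[[t]])
        bg <- bg_pool[runif(length(bg_pool)) < p_bg]
        if (length(bg) > 0) {
          hits[[length(hits) + 1L]] <- data.frame(
            protein_id = pid, template_id = bg,
            score = rgamma(length(bg), shape = shape, rate = shape / config$noise))
        }
      }
    }
  }
  annotations <- do.call(rbind, ann)
  hit_tab <- if (length(hits)) do.call(rbind, hits) else .empty_hits()
  rownames(annotations) <- NULL
  rownames(hit_tab) <- NULL
  list(annotations = annotations, hits = hit_tab, signatures = signatures)
}

#' Write a complete synthetic fixture to disk
#'
#' Materializes one configuration as the exact file formats the readers
#' consume: `library.tsv`, `matrix.tsv`, `go.obo`, `annotations.tsv`,
#' `hits.tsv`. Output is byte-identical for identical configurations.
#'
#' @param config a [fixture_config]; the toy GO tree uses the config's
#'   `depth` and `branching`.
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(config, dir) {
  stopifnot(inherits(config, "fixture_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lm <- gen_library_and_matrix(config)
  toy <- gen_go_toy(config$depth, config$branching)
  gh <- gen_hits(config, toy$graph)
  paths <- c(library = file.path(dir, "library.tsv"),
             matrix = file.path(dir, "matrix.tsv"),
             obo = file.path(dir, "go.obo"),
             annotations = file.path(dir, "annotations.tsv"),
             hits = file.path(dir, "hits.tsv"))
  write_library(lm$library, paths[["library"]])
  write_similarity(lm$similarity, paths[["matrix"]])
  write_obo(toy$graph, paths[["obo"]])
  write_annotations(gh$annotations, paths[["annotations"]])
  write_hit_table(gh$hits, paths[["hits"]])
  invisible(paths)
}
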