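# Shared fixtures and independent oracles for the test suite.

# --- tiny GO graphs -------------------------------------------------------

# chain: A is_a B is_a C (A is the leaf)
toy_chain <- function() {
  go_graph(terms = c("GO:0000001", "GO:0000002", "GO:0000003"),
           edges = data.frame(child = c("GO:0000001", "GO:0000002"),
                              parent = c("GO:0000002", "GO:0000003")),
           namespace = rep("molecular_function", 3))
}

# star: three children under one root
toy_star <- function() {
  go_graph(terms = sprintf("GO:%07d", 1:4),
           edges = data.frame(child = sprintf("GO:%07d", 2:4),
                              parent = "GO:0000001"),
           namespace = rep("molecular_function", 4))
}

obo_text <- function(g) {
  f <- tempfile(fileext = ".obo")
  write_obo(g, f)
  f
}

# --- independent distance oracle (plain BFS, no igraph) -------------------

bfs_distance <- function(edges, from, to) {
  if (identical(from, to)) return(0)
  adj <- list()
  add <- function(a, b) adj[[a]] <<- c(adj[[a]], b)
  for (r in seq_len(nrow(edges))) {
    add(edges$child[r], edges$parent[r])
    add(edges$parent[r], edges$child[r])
  }
  frontier <- from
  seen <- from
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    frontier <- setdiff(unique(unlist(adj[frontier])), seen)
    if (to %in% frontier) return(d)
    if (length(frontier) == 0) return(Inf)
    seen <- c(seen, frontier)
  }
  Inf
}

# --- brute-force AUC oracle ----------------------------------------------

brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# --- independent ridge solve for the least-squares engine -----------------

ridge_oracle <- function(G, reg, y) {
  n <- nrow(G)
  qr.solve(G + diag(reg, n), y)
}

# --- random pair sets -----------------------------------------------------

random_pair_set <- function(n, m, seed = 1) {
  set.seed(seed)
  V <- matrix(rnorm(n * m), n, m, dimnames = list(NULL, sprintf("T%03d", 1:m)))
  A <- matrix(rnorm(n * m), n, m, dimnames = dimnames(V))
  structure(list(V = V, A = A, B = A - V,
                 labels = rep(NA, n),
                 pairs = data.frame(protein_i = sprintf("p%03d", 1:n),
                                    protein_j = sprintf("q%03d", 1:n))),
            class = "pair_set")
}

# a linearly separable labeled pair set: positives cluster at the origin
# (same-term pairs have near-identical responses), negatives far away
separable_pair_set <- function(n_pos = 20, n_neg = 20, m = 8, seed = 1,
                               spread = 0.1, shift = 5) {
  set.seed(seed)
  V <- rbind(matrix(rnorm(n_pos * m, 0, spread), n_pos, m),
             matrix(rnorm(n_neg * m, shift, spread), n_neg, m))
  colnames(V) <- sprintf("T%03d", 1:m)
  structure(list(V = V, A = V, B = matrix(0, n_pos + n_neg, m),
                 labels = rep(c(1, 0), c(n_pos, n_neg)),
                 pairs = data.frame(protein_i = sprintf("a%03d", seq_len(n_pos + n_neg)),
                                    protein_j = sprintf("b%03d", seq_len(n_pos + n_neg)),
                                    label = rep(c(1, 0), c(n_pos, n_neg)))),
            class = "pair_set")
}

# --- full synthetic pipeline fixture (built once per test run) ------------

make_fixture <- function(preset = "easy", seed = 1) {
  cfg <- fixture_preset(preset, seed = seed)
  lm <- gen_library_and_matrix(cfg)
  toy <- gen_go_toy(cfg$depth, cfg$branching)
  gh <- gen_hits(cfg, toy$graph)
  R <- compute_responses(gh$hits, lm$library,
                         protein_ids = sort(unique(gh$annotations$protein_id)))
  list(cfg = cfg, lib = lm$library, sim = lm$similarity, toy = toy,
       ann = gh$annotations, hits = gh$hits, signatures = gh$signatures, R = R)
}

fx_easy <- make_fixture("easy", 1)

# all protein pairs whose annotated terms are separated by GO edge distance d
pairs_at_distance <- function(fx, d, n = 50, seed = 5) {
  ann <- fx$ann
  terms <- sort(unique(ann$go_term))
  prot_of <- split(ann$protein_id, ann$go_term)
  out <- list()
  for (i in seq_along(terms)) for (j in i:length(terms)) {
    if (go_edge_distance(fx$toy$graph, terms[i], terms[j]) != d) next
    cmb <- if (i == j) t(combn(prot_of[[terms[i]]], 2)) else
      as.matrix(expand.grid(prot_of[[terms[i]]], prot_of[[terms[j]]],
                            stringsAsFactors = FALSE))
    out[[length(out) + 1]] <- data.frame(protein_i = as.character(cmb[, 1]),
                                         protein_j = as.character(cmb[, 2]))
  }
  df <- do.call(rbind, out)
  set.seed(seed)
  df[sample(nrow(df), min(n, nrow(df))), , drop = FALSE]
}

# CHD1 worked-example inputs shipped with the package
chd1_library <- function() {
  read_library(system.file("extdata", "chd1_library.tsv", package = "nrprof"))
}
chd1_hits <- function() {
  parse_hit_table(system.file("extdata", "chd1_hits.tsv", package = "nrprof"))
}
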