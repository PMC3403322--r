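test_that("filter_go_terms screens small and non-leaf terms", {
  g <- toy_star()  # leaves: GO:0000002..4
  ann <- rbind(
    data.frame(protein_id = sprintf("p%02d", 1:4), go_term = "GO:0000002"),
    data.frame(protein_id = sprintf("q%02d", 1:5), go_term = "GO:0000003"),
    data.frame(protein_id = sprintf("r%02d", 1:9), go_term = "GO:0000001"))
  out <- filter_go_terms(ann, g)
  # 4 proteins < 5 -> dropped; exactly 5 -> kept; internal term -> dropped
  expect_equal(unique(out$go_term), "GO:0000003")
  out2 <- filter_go_terms(ann, g, leaf_only = FALSE)
  expect_setequal(unique(out2$go_term), c("GO:0000003", "GO:0000001"))
  expect_warning(filter_go_terms(ann[1, ], g), "no annotations")
})

test_that("redundancy_filter collapses near-identical sequences only", {
  seqs <- c(a = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
            b = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ")
  expect_length(redundancy_filter(seqs), 1)

  set.seed(1)
  rand <- function(n) paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                   n, replace = TRUE), collapse = "")
  unrelated <- c(x = rand(40), y = rand(40))
  expect_length(redundancy_filter(unrelated, 0.8), 2)

  # threshold 1: only exact duplicates collapse
  near <- c(a = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
            b = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVA",  # one substitution
            c = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ")
  reps <- redundancy_filter(near, 1.0)
  expect_length(reps, 2)
  # ... while at 0.8 the near-duplicate joins too
  expect_length(redundancy_filter(near, 0.8), 1)

  expect_error(redundancy_filter(character()), "no sequences")
})

test_that("make_pair_dataset labels audit against the annotations", {
  fx <- fx_easy
  ds <- make_pair_dataset(fx$ann, 80, 80, seed = 3)
  expect_equal(sum(ds$label == 1), 80)
  expect_equal(sum(ds$label == 0), 80)
  share <- function(i, j) {
    length(intersect(fx$ann$go_term[fx$ann$protein_id == i],
                     fx$ann$go_term[fx$ann$protein_id == j])) > 0
  }
  for (r in seq_len(nrow(ds))) {
    expect_equal(share(ds$protein_i[r], ds$protein_j[r]), ds$label[r] == 1)
  }
  # no duplicates in either orientation
  keys <- paste(pmin(ds$protein_i, ds$protein_j),
                pmax(ds$protein_i, ds$protein_j))
  expect_false(anyDuplicated(keys) > 0)
  # reproducibility
  expect_identical(ds, make_pair_dataset(fx$ann, 80, 80, seed = 3))

  # a single term with 3 proteins has exactly C(3,2) positive pairs
  tiny <- data.frame(protein_id = c("a", "b", "c"), go_term = "GO:0000001")
  expect_error(make_pair_dataset(tiny, 4, 0, seed = 1), "3 positive")

  expect_error(make_pair_dataset(fx$ann, 1e6, 1, seed = 1), "insufficient")
})

test_that("auc implements the tie-aware Mann-Whitney probability", {
  expect_equal(auc(c(10, 9, 2, 1), c(1, 1, 0, 0)), 1)
  expect_equal(auc(c(1, 1, 1, 1), c(1, 0, 1, 0)), 0.5)
  # positives {0.9, 0.3}, negative {0.8}: one concordant of two pairs
  expect_equal(auc(c(0.9, 0.8, 0.3), c(1, 0, 1)), 0.5)
  expect_error(auc(c(1, 2), c(1, 1)), "both classes")
})

test_that("auc agrees with brute-force concordance counting (property)", {
  set.seed(23)
  for (trial in 1:100) {
    n <- sample(4:200, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # force some ties
    expect_equal(auc(scores, labels), brute_auc(scores, labels))
  }
})

test_that("auc agrees with an independent ROC library", {
  skip_if_not_installed("pROC")
  set.seed(31)
  scores <- runif(60)
  labels <- sample(0:1, 60, replace = TRUE, prob = c(0.4, 0.6))
  expect_equal(auc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))))
})

test_that("cross-validation is perfect on the separable easy fixture", {
  fx <- fx_easy
  ds <- make_pair_dataset(fx$ann, 100, 100, seed = 1)
  cv <- cross_validate(ds, fx$R, seed = 1)
  expect_gte(cv$mean_accuracy, 0.95)
  expect_gte(cv$mean_auc, 0.98)
  # folds partition the dataset with balanced labels
  expect_setequal(cv$fold_of, 1:5)
  expect_equal(as.vector(table(cv$fold_of)), rep(40L, 5))
  for (f in 1:5) {
    expect_equal(sum(ds$label[cv$fold_of == f]), 20)
  }
  expect_error(cross_validate(ds[1:4, ], fx$R, folds = 10), "folds")
})

test_that("label-shuffled cross-validation sits at chance", {
  fx <- fx_easy
  ds <- make_pair_dataset(fx$ann, 100, 100, seed = 2)
  set.seed(2)
  ds$label <- sample(ds$label)
  cv <- cross_validate(ds, fx$R, seed = 2)
  expect_gt(cv$mean_auc, 0.4)
  expect_lt(cv$mean_auc, 0.6)
})

test_that("threshold_sweep reports accuracy per threshold and the argmax", {
  fx <- fx_easy
  ds <- make_pair_dataset(fx$ann, 100, 100, seed = 4)
  model <- suppressMessages(train_mapping(pair_set(fx$R, ds)))
  sw <- threshold_sweep(model, ds, fx$R)
  expect_equal(sw$threshold, seq(0.1, 0.9, by = 0.1))
  # separable fixture: flat accuracy-1 region around 0.5
  expect_true(all(sw$accuracy[sw$threshold >= 0.3 & sw$threshold <= 0.7] == 1))
  expect_true(attr(sw, "best_threshold") %in% sw$threshold)

  # degenerate scorer: accuracy equals the positive fraction everywhere
  flat <- model
  flat$coef <- model$coef * 0
  flat$intercept <- 5  # clipped to 1 for every pair
  sw2 <- threshold_sweep(flat, ds, fx$R)
  expect_equal(sw2$accuracy, rep(mean(ds$label), 9))

  sw3 <- threshold_sweep(model, ds, fx$R, grid = 0.5)
  expect_equal(nrow(sw3), 1)
})

test_that("specificity decays with GO edge distance on the structured fixture", {
  fx <- fx_easy
  ds <- make_pair_dataset(fx$ann, 100, 100, seed = 1)
  model <- suppressMessages(train_mapping(pair_set(fx$R, ds)))
  groups <- list("0" = pairs_at_distance(fx, 0),
                 "2" = pairs_at_distance(fx, 2),
                 "4" = pairs_at_distance(fx, 4))
  frac <- specificity_by_distance(model, fx$R, groups)
  expect_true(all(frac >= 0 & frac <= 1))
  expect_true(all(diff(frac) <= 0))
  expect_gt(frac[["0"]], frac[["4"]])

  # empty level omitted with a warning; single-pair level is 0 or 1
  groups$empty <- groups$`0`[0, ]
  groups$single <- groups$`0`[1, ]
  expect_warning(frac2 <- specificity_by_distance(model, fx$R, groups), "omitted")
  expect_false("empty" %in% names(frac2))
  expect_true(frac2[["single"]] %in% c(0, 1))
})

test_that("signature sharing decreases with term distance in the generator", {
  fx <- fx_easy
  sig <- fx$signatures
  terms <- names(sig)
  ov <- dd <- numeric(0)
  for (i in seq_along(terms)) for (j in seq_along(terms)) {
    if (i >= j) next
    dd <- c(dd, go_edge_distance(fx$toy$graph, terms[i], terms[j]))
    ov <- c(ov, length(intersect(sig[[terms[i]]], sig[[terms[j]]])))
  }
  # overlap is a non-increasing function of distance
  expect_true(all(diff(ov[order(dd)]) <= 0))
})

test_that("recovery improves monotonically with the signal level", {
  accs <- vapply(c(1, 4, 10), function(sig) {
    cfg <- fixture_config(signal = sig, noise = 1, seed = 3)
    lm <- gen_library_and_matrix(cfg)
    toy <- gen_go_toy(cfg$depth, cfg$branching)
    gh <- gen_hits(cfg, toy$graph)
    R <- compute_responses(gh$hits, lm$library)
    ds <- make_pair_dataset(gh$annotations, 100, 100, seed = 3)
    cross_validate(ds, R, seed = 3)$mean_accuracy
  }, numeric(1))
  expect_true(all(diff(accs) >= -0.01))
  expect_gt(accs[3], accs[1])
})
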