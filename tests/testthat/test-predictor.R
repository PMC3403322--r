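# a model trained on the easy synthetic fixture, shared across tests
fit_easy_model <- function() {
  ds <- make_pair_dataset(fx_easy$ann, 100, 100, seed = 1)
  train_mapping(pair_set(fx_easy$R, ds), kernel_spec("gaussian", sigma = NULL))
}
easy_model <- suppressMessages(fit_easy_model())

test_that("rank_base returns the base set sorted by f with lexical tie-break", {
  fx <- fx_easy
  q <- rownames(fx$R)[1]
  base <- fx$R[rownames(fx$R) != q, ]
  ranked <- rank_base(fx$R[q, ], base, easy_model)
  expect_setequal(ranked$protein_id, rownames(base))
  expect_true(all(diff(ranked$score) <= 0))
  expect_equal(ranked$rank, seq_len(nrow(ranked)))
  # same-term proteins dominate the top of the list
  same_term <- fx$ann$protein_id[fx$ann$go_term == fx$ann$go_term[
    fx$ann$protein_id == q]]
  expect_true(all(ranked$protein_id[1:3] %in% same_term))

  # a base protein identical to the query maximizes f (zero pair); with the
  # query as its own one-protein base set it is trivially rank 1
  base2 <- rbind(base, fx$R[q, , drop = FALSE])
  rownames(base2)[nrow(base2)] <- "twin"
  r_twin <- rank_base(fx$R[q, ], base2, easy_model)
  expect_equal(r_twin$score[r_twin$protein_id == "twin"], max(r_twin$score))
  solo <- rank_base(fx$R[q, ], fx$R[q, , drop = FALSE], easy_model)
  expect_equal(solo$protein_id, q)
  expect_equal(solo$rank, 1L)

  # ties broken by protein id
  twin2 <- rbind(zzz = fx$R[q, ], aaa = fx$R[q, ])
  r2 <- rank_base(fx$R[q, ], twin2, easy_model)
  expect_equal(r2$protein_id, c("aaa", "zzz"))

  expect_error(rank_base(fx$R[q, ], fx$R[0, ], easy_model), "empty base")
})

test_that("assign_go prefers leaf terms and respects the top-k budget", {
  g <- toy_star()  # GO:0000001 root; 2..4 leaves
  ranked <- data.frame(rank = 1:2, protein_id = c("pA", "pB"),
                       score = c(0.9, 0.4))
  ann <- data.frame(protein_id = c("pA", "pA", "pB"),
                    go_term = c("GO:0000002", "GO:0000001", "GO:0000003"))
  res <- assign_go(ranked, ann, g)
  # the leaf term shadows the internal term of the rank-1 protein
  expect_equal(res$terms$go_term[1], "GO:0000002")
  expect_false("GO:0000001" %in% res$terms$go_term)
  expect_equal(res$terms$confidence[1], 0.9)

  # k budget
  res1 <- assign_go(ranked, ann, g, k = 1)
  expect_equal(nrow(res1$terms), 1)

  # unannotated rank-1 protein is skipped with a warning
  ann2 <- ann[ann$protein_id != "pA", ]
  expect_warning(res2 <- assign_go(ranked, ann2, g), "no annotation")
  expect_equal(res2$terms$go_term, "GO:0000003")
})

test_that("assign_go uses sequence diversity among non-leaf candidates", {
  # chain: GO:0000001 (leaf) <- 2 <- 3; protein annotated to two internals
  g <- toy_chain()
  ranked <- data.frame(rank = 1, protein_id = "pA", score = 0.8)
  ann <- data.frame(protein_id = "pA", go_term = c("GO:0000002", "GO:0000003"))
  res <- assign_go(ranked, ann, g, leaf_only = FALSE,
                   diversity = c("GO:0000002" = 3, "GO:0000003" = 10))
  expect_equal(res$terms$go_term, "GO:0000002")
})

test_that("terms shared by several top proteins appear once at max confidence", {
  g <- toy_star()
  ranked <- data.frame(rank = 1:3, protein_id = c("p1", "p2", "p3"),
                       score = c(0.9, 0.8, 0.7))
  ann <- data.frame(protein_id = c("p1", "p2", "p3"), go_term = "GO:0000002")
  res <- assign_go(ranked, ann, g)
  expect_equal(nrow(res$terms), 1)
  expect_equal(res$terms$confidence, 0.9)
})

test_that("threshold_assign agrees with cutting the ranking at the threshold", {
  fx <- fx_easy
  q <- rownames(fx$R)[1]
  base <- fx$R[rownames(fx$R) != q, ]
  ta <- threshold_assign(fx$R[q, ], base, easy_model, threshold = 0.5)
  ranked <- rank_base(fx$R[q, ], base, easy_model)
  positives <- sort(ranked$protein_id[ranked$score >= 0.5])
  expect_equal(sort(ta$protein_id[ta$label == 1]), positives)
  # threshold sweep consistency: near-zero threshold labels everything
  ta_low <- threshold_assign(fx$R[q, ], base, easy_model, threshold = 1e-9)
  expect_true(all(ta_low$label == 1))
})

test_that("go_motif_scores implements s = NM x AS with descending order", {
  ann <- data.frame(protein_id = c("p1", "p2", "p3", "p4", "p5"),
                    go_term = "GO:0000001")
  hits <- data.frame(
    protein_id = c("p1", "p2", "p3", "p1", "p1"),
    template_id = c("a", "a", "a", "a", "b"),
    score = c(2, 3, 4, 1, 10))
  out <- go_motif_scores(ann, hits, "GO:0000001")
  # motif a: three proteins, per-protein maxima {2,3,4} -> NM=3, AS=3, s=9
  a <- out[out$motif_id == "a", ]
  expect_equal(a$NM, 3); expect_equal(a$AS, 3); expect_equal(a$s, 9)
  # motif b: one of five proteins, score 10 -> s = 10, ranked first
  expect_equal(out$motif_id, c("b", "a"))
  expect_equal(out$s, c(10, 9))

  expect_error(go_motif_scores(ann, hits, "GO:9999999"), "no proteins")
})

test_that("association scores are homogeneous of degree one in the hit scores", {
  fx <- fx_easy
  term <- fx$ann$go_term[1]
  ann_t <- fx$ann[fx$ann$go_term == term, ]
  s1 <- go_motif_scores(ann_t, fx$hits, term)
  doubled <- fx$hits
  doubled$score <- doubled$score * 2
  s2 <- go_motif_scores(ann_t, doubled, term)
  expect_equal(s2$motif_id, s1$motif_id)
  expect_equal(s2$NM, s1$NM)
  expect_equal(s2$AS, 2 * s1$AS)
  expect_equal(s2$s, 2 * s1$s)
})
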