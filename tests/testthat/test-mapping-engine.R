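mk_pair <- function(v, a = v, b = a - v) {
  m <- length(v)
  ids <- sprintf("T%03d", seq_len(m))
  structure(list(id_i = "x", id_j = "y",
                 values = setNames(v, ids), a = setNames(a, ids),
                 b = setNames(b, ids), label = NA),
            class = "pair_response")
}

test_that("kernel_eval computes the closed forms", {
  gau <- kernel_spec("gaussian", sigma = 1)
  a <- mk_pair(c(1, 0)); b <- mk_pair(c(0, 1))
  expect_equal(kernel_eval(gau, a, a), 1)
  expect_equal(kernel_eval(gau, a, b), exp(-2))

  lin <- kernel_spec("linear")
  expect_equal(kernel_eval(lin, mk_pair(c(1, 2)), mk_pair(c(3, -1))), 1)

  # expanded variant sums the two component inner products
  exp_spec <- kernel_spec("linear", linear_variant = "expanded")
  pa <- mk_pair(c(1, 1), a = c(2, 0), b = c(1, -1))
  pb <- mk_pair(c(0, 1), a = c(1, 1), b = c(1, 0))
  expect_equal(kernel_eval(exp_spec, pa, pb),
               sum(c(2, 0) * c(1, 1)) + sum(c(1, -1) * c(1, 0)))

  expect_error(kernel_spec("gaussian", sigma = -1), "positive")
})

test_that("gaussian kernel is symmetric, bounded, and degenerates to 1 as sigma grows", {
  set.seed(5)
  a <- mk_pair(rnorm(6)); b <- mk_pair(rnorm(6))
  for (s in c(0.5, 2, 10)) {
    sp <- kernel_spec("gaussian", sigma = s)
    k1 <- kernel_eval(sp, a, b)
    expect_equal(k1, kernel_eval(sp, b, a))
    expect_gt(k1, 0); expect_lte(k1, 1)
  }
  expect_equal(kernel_eval(kernel_spec("gaussian", sigma = 1e8), a, b), 1,
               tolerance = 1e-10)
})

test_that("gram matrices are symmetric, unit-diagonal and PSD (gaussian)", {
  one <- gram_matrix(kernel_spec("gaussian", sigma = 2), random_pair_set(1, 4))
  expect_equal(one, matrix(1, 1, 1))
  for (seed in 1:5) {
    ps <- random_pair_set(n = sample(5:50, 1), m = 6, seed = seed)
    G <- gram_matrix(kernel_spec("gaussian", sigma = 3), ps)
    expect_equal(G, t(G))
    expect_equal(unname(diag(G)), rep(1, nrow(G)))
    expect_gte(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values), -1e-9)
  }
})

test_that("least-squares training matches an independent ridge solve", {
  for (seed in 1:5) {
    n <- sample(10:50, 1)
    ps <- separable_pair_set(n_pos = ceiling(n / 2), n_neg = floor(n / 2),
                             seed = seed)
    spec <- kernel_spec("gaussian", sigma = 4)
    reg <- 0.05
    model <- train_mapping(ps, spec = spec, engine = "least_squares", reg = reg)
    G <- gram_matrix(spec, ps)
    alpha <- ridge_oracle(G, reg, ps$labels)
    expect_equal(model$coef, unname(alpha), tolerance = 1e-8)
    # and training scores reproduce the oracle's clipped predictions
    expect_equal(score_pairs(model, ps),
                 pmin(pmax(as.numeric(G %*% alpha), 0), 1), tolerance = 1e-8)
  }
})

test_that("training input validation catches degenerate cases", {
  ps <- separable_pair_set()
  one_class <- ps; one_class$labels[] <- 1; one_class$pairs$label <- 1
  expect_error(train_mapping(one_class, kernel_spec("gaussian", sigma = 1)),
               "each class")
  # duplicate pairs + reg = 0 make the system singular
  dup <- ps
  dup$V <- rbind(ps$V, ps$V); dup$A <- rbind(ps$A, ps$A); dup$B <- rbind(ps$B, ps$B)
  dup$labels <- c(ps$labels, ps$labels)
  dup$pairs <- rbind(ps$pairs, ps$pairs)
  expect_error(train_mapping(dup, kernel_spec("gaussian", sigma = 1),
                             reg = 0), "reg > 0")
})

test_that("heavy regularization shrinks least-squares scores toward the label mean", {
  ps <- separable_pair_set(n_pos = 10, n_neg = 10)
  model <- train_mapping(ps, kernel_spec("gaussian", sigma = 4), reg = 1e6)
  s <- score_pairs(model, ps)
  # scores collapse toward 0 (ridge shrinkage of G alpha ~ y/reg)
  expect_lt(diff(range(s)), 0.05)
})

test_that("scores stay in [0,1] and the classify boundary is inclusive", {
  ps <- separable_pair_set(seed = 3)
  model <- train_mapping(ps, kernel_spec("gaussian", sigma = 4))
  probe <- random_pair_set(1000, ncol(ps$V), seed = 11)
  s <- score_pairs(model, probe)
  expect_true(all(s >= 0 & s <= 1))

  # positives (clustered at the origin) score high; the zero pair itself too
  expect_true(all(score_pairs(model, ps)[ps$labels == 1] >= 0.5))
  zero <- mk_pair(rep(0, ncol(ps$V)))
  expect_gte(score_pairs(model, zero), 0.5)

  fake <- model
  fake$coef <- model$coef * 0  # all scores exactly 0 -> threshold test
  expect_equal(classify_pairs(fake, zero, threshold = 0.5), 0L)
  # boundary inclusive: a clipped score of exactly 1 >= any threshold, and
  # classify agrees everywhere with the >= rule on raw scores
  s0 <- score_pairs(model, ps)
  expect_equal(classify_pairs(model, ps),
               as.integer(s0 >= 0.5))
})

test_that("threshold sweep of positive counts is monotone non-increasing", {
  ps <- separable_pair_set(seed = 9)
  model <- train_mapping(ps, kernel_spec("gaussian", sigma = 4))
  counts <- vapply(seq(0.1, 0.9, by = 0.1), function(th)
    sum(classify_pairs(model, ps, th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("negating every pair leaves gaussian-kernel scores unchanged", {
  ps <- separable_pair_set(seed = 4)
  neg <- ps
  neg$V <- -ps$V
  tmp <- neg$A; neg$A <- neg$B; neg$B <- tmp
  spec <- kernel_spec("gaussian", sigma = 4)
  m1 <- train_mapping(ps, spec, reg = 0.1)
  m2 <- train_mapping(neg, spec, reg = 0.1)
  expect_equal(score_pairs(m1, ps), score_pairs(m2, neg), tolerance = 1e-10)
})

test_that("the SVM engine separates the separable fixture and calibrates to [0,1]", {
  ps <- separable_pair_set(seed = 2)
  model <- train_mapping(ps, kernel_spec("gaussian", sigma = 4), engine = "svm",
                         seed = 1)
  s <- score_pairs(model, ps)
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(classify_pairs(model, ps), as.integer(ps$labels))
})

test_that("sigma defaults to the median pairwise distance heuristic", {
  ps <- separable_pair_set(seed = 6)
  expect_message(model <- train_mapping(ps, kernel_spec("gaussian")),
                 "median pairwise distance")
  expect_equal(model$spec$sigma, median(dist(ps$V)))
})

test_that("models round-trip through the text archive", {
  for (engine in c("least_squares", "svm")) {
    ps <- separable_pair_set(seed = 8)
    model <- train_mapping(ps, kernel_spec("gaussian", sigma = 3),
                           engine = engine, seed = 1)
    f <- tempfile()
    save_model(model, f)
    back <- load_model(f)
    probe <- random_pair_set(50, ncol(ps$V), seed = 13)
    expect_equal(score_pairs(back, probe), score_pairs(model, probe),
                 tolerance = 1e-12)
    expect_equal(back$engine, model$engine)
    expect_equal(back$spec$sigma, model$spec$sigma)
  }
  # expanded linear models keep their component blocks
  ps <- separable_pair_set(seed = 8)
  model <- train_mapping(ps, kernel_spec("linear", linear_variant = "expanded"),
                         reg = 1)
  f <- tempfile()
  save_model(model, f)
  back <- load_model(f)
  expect_equal(score_pairs(back, ps), score_pairs(model, ps), tolerance = 1e-12)
})
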