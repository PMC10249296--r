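test_that("the worked S1/S2 example re-ranks exactly as hand-executed", {
  s <- c(0.9, 0.1, 0.8, 0.2, 0.7, 0.3)
  expect_identical(apply_s1(1:6, s, 0.5, 0), c(1L, 3L, 5L, 6L, 4L, 2L))
  expect_identical(apply_s2(1:6, s, 0.5, 0), c(1L, 3L, 2L, 5L, 4L, 6L))
})

test_that("degenerate parameter settings collapse to the documented orders", {
  set.seed(10)
  for (i in 1:20) {
    n <- sample(1:12, 1)
    ranks <- sample(n)
    s <- round(rnorm(n), 2)
    expect_identical(apply_s1(ranks, s, 0, sample(0:3, 1)),
                     order(ranks))                       # p = 0: identity
    expect_identical(apply_s2(ranks, s, 0, sample(0:3, 1)), order(ranks))
    expect_identical(apply_s1(ranks, s, 1, 0), order(-s, ranks))  # pure score sort
  }
})

test_that("both strategies always return permutations and preserve the head", {
  set.seed(20)
  for (i in 1:200) {
    n <- sample(1:15, 1)
    ranks <- sample(n)
    s <- sample(round(rnorm(max(2, n %/% 2)), 1), n, replace = TRUE)  # force ties
    p <- runif(1); k <- sample(0:5, 1)
    for (f in list(apply_s1, apply_s2)) {
      out <- f(ranks, s, p, k)
      expect_identical(sort(out), seq_len(n))
    }
    out1 <- apply_s1(ranks, s, p, k)
    kk <- min(k, n)
    if (kk > 0) expect_identical(ranks[out1[seq_len(kk)]], seq_len(kk))
  }
})

test_that("the demotion set grows monotonically in p", {
  demoted_set <- function(ranks, s, p, k) {
    out <- apply_s1(ranks, s, p, k)
    ne <- sum(ranks > k)
    m <- floor(p * ne)
    if (m == 0) integer(0) else sort(utils::tail(out, m))
  }
  set.seed(30)
  for (i in 1:50) {
    n <- sample(2:12, 1)
    ranks <- sample(n)
    s <- round(rnorm(n), 1)
    k <- sample(0:2, 1)
    ps <- sort(runif(4))
    sets <- lapply(ps, function(p) demoted_set(ranks, s, p, k))
    for (j in 2:4) expect_true(all(sets[[j - 1]] %in% sets[[j]]))
  }
})

test_that("S2 respects unanimity of the first place", {
  set.seed(40)
  for (i in 1:50) {
    n <- sample(2:10, 1)
    ranks <- sample(n)
    s <- rnorm(n)
    p <- runif(1); k <- sample(0:2, 1)
    s1 <- apply_s1(ranks, s, p, k)
    s2 <- apply_s2(ranks, s, p, k)
    first_orig <- which(ranks == 1)
    if (s1[1] == first_orig) expect_identical(s2[1], first_orig)
  }
})

test_that("random instances match the brute-force oracles exactly", {
  set.seed(50)
  for (i in 1:150) {
    n <- sample(1:20, 1)
    ranks <- sample(n)
    s <- sample(round(rnorm(max(2, n %/% 2)), 1), n, replace = TRUE)
    p <- sample(c(0, runif(1), 1), 1)
    k <- sample(0:4, 1)
    expect_identical(apply_s1(ranks, s, p, k), oracle_s1(ranks, s, p, k))
    expect_identical(apply_s2(ranks, s, p, k), oracle_s2(ranks, s, p, k))
  }
})

test_that("S2(1, 0) equals the ascending sort of rank + score-rank", {
  set.seed(60)
  for (i in 1:100) {
    n <- sample(2:25, 1)
    ranks <- sample(n)
    s <- rnorm(n)
    score_rank <- integer(n)
    score_rank[order(-s, ranks)] <- seq_len(n)
    expect_identical(apply_s2(ranks, s, 1, 0), order(ranks + score_rank, ranks))
  }
})

test_that("top-k accuracy counts recorded positions with misses", {
  pos <- c(1, 2, 3, 11)
  tab <- top_k_accuracy(pos, ks = c(1, 3, 10))
  expect_equal(tab$accuracy, c(0.25, 0.75, 0.75))
  expect_equal(top_k_accuracy(c(1, 1, 1), 1:5)$accuracy, rep(1, 5))
  # missing recorded candidates are misses at every k
  expect_equal(top_k_accuracy(c(1, NA), ks = 5)$accuracy, 0.5)
  expect_true(all(diff(top_k_accuracy(sample(1:20, 50, TRUE), 1:20)$accuracy) >= 0))
  expect_error(top_k_accuracy(numeric(0)), class = "rr_usage_error")
})

test_that("final accuracy position is the smallest saturating cutoff", {
  expect_equal(final_accuracy_position(c(1, 2, 2, 5), 10), 5)
  expect_equal(final_accuracy_position(c(1, 1, 1), 10), 1)
  # a re-rank pulling the deepest recorded item forward lowers the position
  pos_before <- c(rep(1, 10), 44)
  pos_after <- c(rep(1, 10), 37)
  expect_equal(final_accuracy_position(pos_before, 50), 44)
  expect_equal(final_accuracy_position(pos_after, 50), 37)
})

test_that("identity re-ranking reproduces the original accuracies", {
  d <- generate_dataset(synth_config(n_products = 15, seed = 70))
  set.seed(3)
  m <- init_ranker(encoder_config(hidden = 8, layers = 1, readout_steps = 1))
  scored <- score_predictions(m, d$lists)
  before <- top_k_accuracy(scored, c(1, 3, 5))
  rr <- rerank_predictions(scored, rerank_config("S1", p = 0, k = 0))
  expect_equal(top_k_accuracy(rr, c(1, 3, 5)), before)
})

test_that("grid search returns the argmax cell and the full table", {
  d <- generate_dataset(separable_synth_config(30, seed = 80))
  set.seed(9)
  m <- init_ranker(encoder_config(hidden = 8, layers = 1, readout_steps = 1))
  scored <- score_predictions(m, d$lists)
  gs <- grid_search_rerank(scored, p_grid = c(0, 1), k_grid = c(0, 1),
                           objective_k = 5)
  expect_equal(nrow(gs$table), 4)
  expect_equal(gs$best_accuracy, max(gs$table$accuracy))
  gs0 <- grid_search_rerank(scored, p_grid = 0, k_grid = 0, objective_k = 5)
  expect_equal(gs0$best$p, 0)
  expect_equal(gs0$best_accuracy,
               top_k_accuracy(scored, 5)$accuracy)
  one <- grid_search_rerank(scored[1], p_grid = c(0, 0.5), k_grid = 0,
                            objective_k = 1)
  expect_equal(nrow(one$table), 2)
  expect_error(grid_search_rerank(scored, numeric(0), 0, 1),
               class = "rr_usage_error")
})
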