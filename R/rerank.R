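# Re-ranking strategies S1(p, k) and S2(p, k) and the evaluation statistics
# (top-k accuracy, final-accuracy position, grid search).
#
# S1 demotes the candidates whose ranking scores are among the bottom ratio p
# (computed over the candidates below the preserved top-k head) to the end of
# the list, re-ordered by score; S2 sorts by the sum of the original rank and
# the S1 rank, giving the original ranking more weight. All tie-breaks fall
# back to the original rank, making every permutation deterministic.

#' Re-ranking configuration
#'
#' @param strategy `"S1"` or `"S2"`
#' @param p demotion ratio in `[0, 1]`
#' @param k preserved-head size (top-k original ranks kept in place)
#' @param pool `"tail"` computes the demotion-set size as `floor(p * n')`
#'   over the `n'` candidates below the head; `"all"` uses `floor(p * n)`
#' @return a `rerank_config`
#' @export
rerank_config <- function(strategy = c("S2", "S1"), p = 1.0, k = 0L,
                          pool = c("tail", "all")) {
  strategy <- match.arg(strategy)
  pool <- match.arg(pool)
  if (p < 0 || p > 1) rr_usage_error("p must be in [0, 1]")
  if (k < 0) rr_usage_error("k must be >= 0")
  structure(list(strategy = strategy, p = p, k = as.integer(k), pool = pool),
            class = "rerank_config")
}

check_rerank_args <- function(original_ranks, rr_scores, p, k) {
  n <- length(original_ranks)
  if (n < 1L) rr_usage_error("empty candidate list")
  if (length(rr_scores) != n)
    rr_usage_error("original_ranks and rr_scores length mismatch")
  if (!setequal(original_ranks, seq_len(n)))
    rr_usage_error("original_ranks must be a permutation of 1..n")
  if (p < 0 || p > 1) rr_usage_error("p must be in [0, 1]")
  if (k < 0) rr_usage_error("k must be >= 0")
}

#' Re-rank one candidate list with strategy S1(p, k)
#'
#' The `floor(p * n')` candidates with the lowest ranking scores among the
#' `n'` candidates at original rank > k are moved to the end of the list,
#' re-ordered by score (descending: a better score earns a better final
#' position). Score ties at the demotion boundary keep (do not demote) the
#' candidate with the better original rank; ties inside the demoted block are
#' broken by original rank ascending. The top-k original positions are
#' preserved exactly.
#'
#' @param original_ranks integer permutation of 1..n (rank of each item)
#' @param rr_scores ranking scores aligned with `original_ranks`
#' @param p demotion ratio in `[0, 1]`
#' @param k preserved-head size
#' @param pool `"tail"` (default) or `"all"`, see [rerank_config()]
#' @return integer vector: item indices (into the input vectors) in final
#'   order — a permutation of 1..n
#' @export
apply_s1 <- function(original_ranks, rr_scores, p, k = 0L, pool = "tail") {
  check_rerank_args(original_ranks, rr_scores, p, k)
  n <- length(original_ranks)
  eligible <- which(original_ranks > k)
  ne <- length(eligible)
  m <- if (identical(pool, "all")) min(floor(p * n), ne) else floor(p * ne)
  # demote the m lowest-scored eligibles; on ties demote the worse original
  # rank first (keep the better one)
  ord <- eligible[order(rr_scores[eligible], -original_ranks[eligible])]
  demoted <- if (m > 0L) ord[seq_len(m)] else integer(0)
  head_items <- setdiff(order(original_ranks), c(eligible))
  head_items <- head_items[order(original_ranks[head_items])]
  mid <- setdiff(eligible, demoted)
  mid <- mid[order(original_ranks[mid])]
  tail_items <- demoted[order(-rr_scores[demoted], original_ranks[demoted])]
  c(head_items, mid, tail_items)
}

#' Re-rank one candidate list with strategy S2(p, k)
#'
#' The final order is ascending in (original rank + S1 rank); ties are broken
#' by original rank ascending. Compared to S1 the original ranking weighs
#' more.
#'
#' @inheritParams apply_s1
#' @return integer vector of item indices in final order
#' @export
apply_s2 <- function(original_ranks, rr_scores, p, k = 0L, pool = "tail") {
  s1 <- apply_s1(original_ranks, rr_scores, p, k, pool)
  n <- length(s1)
  pos1 <- integer(n)
  pos1[s1] <- seq_len(n)
  order(original_ranks + pos1, original_ranks)
}

apply_strategy <- function(original_ranks, rr_scores, config) {
  f <- if (config$strategy == "S1") apply_s1 else apply_s2
  f(original_ranks, rr_scores, config$p, config$k, config$pool)
}

#' Re-rank scored prediction lists
#'
#' Applies the configured strategy to every list, using the `rr_score` field
#' set by [score_predictions()] (unscorable candidates carry `-Inf` and so
#' sink to the bottom of any demoted block).
#'
#' @param lists scored `prediction_list`s
#' @param config a `rerank_config`
#' @return the lists with candidates re-ordered and a `final_rank` field set;
#'   the original ranks are retained on each candidate
#' @export
rerank_predictions <- function(lists, config = rerank_config()) {
  lapply(lists, function(pl) {
    ranks <- vapply(pl$candidates, function(r) r$original_rank, integer(1))
    scores <- vapply(pl$candidates, function(r) {
      s <- r$rr_score
      if (is.null(s)) rr_usage_error("candidates are not scored; run score_predictions first")
      s
    }, numeric(1))
    perm <- apply_strategy(ranks, scores, config)
    pl$candidates <- pl$candidates[perm]
    for (i in seq_along(pl$candidates)) pl$candidates[[i]]$final_rank <- i
    pl
  })
}

#' Final positions of the recorded candidates
#'
#' Position of the recorded candidate in each list's current order (`NA`
#' when the list has none — such lists count as misses at every k).
#'
#' @param lists list of `prediction_list`
#' @return integer vector, one entry per list
#' @export
recorded_positions <- function(lists) {
  vapply(lists, function(pl) {
    rec <- which(vapply(pl$candidates, function(r) isTRUE(r$is_recorded), logical(1)))
    if (length(rec) != 1L) NA_integer_ else rec
  }, integer(1))
}

#' Top-k accuracy
#'
#' Fraction of products whose recorded candidate sits at position <= k in
#' the current candidate order; monotone nondecreasing in k. Lists without a
#' recorded candidate count as misses.
#'
#' @param lists list of `prediction_list` (current order = ranking under test),
#'   or an integer vector of recorded positions
#' @param ks integer cutoffs
#' @return data.frame with columns `k`, `accuracy`
#' @export
top_k_accuracy <- function(lists, ks = c(1, 3, 5, 10)) {
  pos <- if (is.numeric(lists)) lists else {
    if (length(lists) == 0L) rr_usage_error("empty input")
    recorded_positions(lists)
  }
  if (length(pos) == 0L) rr_usage_error("empty input")
  data.frame(k = as.integer(ks),
             accuracy = vapply(ks, function(k) mean(!is.na(pos) & pos <= k),
                               numeric(1)))
}

#' Final-accuracy position
#'
#' The smallest k at which top-k accuracy reaches the top-`K_max` accuracy:
#' past this position the ranking cannot improve up to `K_max`, so it bounds
#' the per-step search space a multi-step planner must explore.
#'
#' @param lists list of `prediction_list` or vector of recorded positions
#' @param K_max maximum cutoff considered (must not exceed the shortest list)
#' @return integer position in 1..K_max
#' @export
final_accuracy_position <- function(lists, K_max) {
  pos <- if (is.numeric(lists)) lists else {
    if (length(lists) == 0L) rr_usage_error("empty input")
    if (K_max > min(lengths(lapply(lists, `[[`, "candidates"))))
      rr_usage_error("K_max exceeds the shortest candidate list")
    recorded_positions(lists)
  }
  if (length(pos) == 0L) rr_usage_error("empty input")
  acc_at <- function(k) sum(!is.na(pos) & pos <= k)
  target <- acc_at(K_max)
  for (k in seq_len(K_max)) if (acc_at(k) == target) return(as.integer(k))
  as.integer(K_max)
}

#' Grid search over re-ranking parameters
#'
#' Exhaustively evaluates every (p, k) cell of the grid on scored validation
#' lists and returns the configuration maximizing top-`objective_k` accuracy
#' (ties resolved toward the identity: smaller p, then smaller k).
#'
#' @param lists scored `prediction_list`s (validation split)
#' @param p_grid numeric vector of demotion ratios
#' @param k_grid integer vector of preserved-head sizes
#' @param objective_k the k whose accuracy is maximized
#' @param strategy `"S1"` or `"S2"`
#' @return list with `best` (a `rerank_config`), `best_accuracy`, and
#'   `table` (one row per grid cell)
#' @export
grid_search_rerank <- function(lists, p_grid = seq(0, 1, by = 0.1),
                               k_grid = 0:2, objective_k = 5L,
                               strategy = "S2") {
  if (length(p_grid) == 0L || length(k_grid) == 0L) rr_usage_error("empty grid")
  if (length(lists) == 0L) rr_usage_error("empty input")
  rows <- list()
  for (p in p_grid) for (k in k_grid) {
    cfg <- rerank_config(strategy, p, k)
    rr <- rerank_predictions(lists, cfg)
    acc <- top_k_accuracy(rr, objective_k)$accuracy
    rows[[length(rows) + 1L]] <- data.frame(strategy = strategy, p = p, k = k,
                                            accuracy = acc)
  }
  tab <- do.call(rbind, rows)
  best_row <- tab[order(-tab$accuracy, tab$p, tab$k), ][1, ]
  list(best = rerank_config(strategy, best_row$p, best_row$k),
       best_accuracy = best_row$accuracy, table = tab)
}

#' Evaluation report for a re-ranking run
#'
#' Compares the original ranking with the re-ranked one: per-k accuracies,
#' final-accuracy positions, the number of products whose recorded rank
#' improved, and the mean changed-bond count overall and on the improved
#' subset (the subset statistic is what ties re-ranking gains to reactions
#' with a greater degree of structural change).
#'
#' @param scored_lists scored lists in original order
#' @param config a `rerank_config`
#' @param ks top-k cutoffs to report
#' @param K_max cutoff for the final-accuracy position (default: shortest list)
#' @param changed_bonds optional precomputed per-list changed-bond count of
#'   the recorded candidate (computed here when missing)
#' @return a report list (JSON-serializable)
#' @export
evaluate_rerank <- function(scored_lists, config = rerank_config(),
                            ks = c(1, 3, 5, 10), K_max = NULL,
                            changed_bonds = NULL) {
  if (length(scored_lists) == 0L) rr_usage_error("empty input")
  nmin <- min(lengths(lapply(scored_lists, `[[`, "candidates")))
  if (is.null(K_max)) K_max <- nmin
  if (K_max > nmin) rr_usage_error("K_max exceeds the shortest candidate list")
  before <- recorded_positions(scored_lists)
  reranked <- rerank_predictions(scored_lists, config)
  after <- recorded_positions(reranked)
  improved <- !is.na(before) & !is.na(after) & after < before

  if (is.null(changed_bonds)) {
    changed_bonds <- vapply(scored_lists, function(pl) {
      rec <- which(vapply(pl$candidates, function(r) isTRUE(r$is_recorded), logical(1)))
      if (length(rec) != 1L || !pl$candidates[[rec]]$scorable) return(NA_real_)
      changed_bond_count(annotate_changes(pl$candidates[[rec]]))
    }, numeric(1))
  }

  list(
    strategy = config$strategy, p = config$p, k = config$k,
    n_products = length(scored_lists),
    top_k = list(
      original = top_k_accuracy(before, ks),
      reranked = top_k_accuracy(after, ks)),
    final_accuracy_position = list(
      original = final_accuracy_position(before, K_max),
      reranked = final_accuracy_position(after, K_max)),
    n_recorded_improved = sum(improved),
    mean_changed_bonds = list(
      all = mean(changed_bonds, na.rm = TRUE),
      improved_subset = if (any(improved)) mean(changed_bonds[improved], na.rm = TRUE)
                        else NA_real_)
  )
}
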