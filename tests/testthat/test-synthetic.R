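test_that("the generator is byte-deterministic under a fixed seed", {
  c1 <- synth_config(n_products = 12, seed = 5)
  d1 <- generate_dataset(c1)
  d2 <- generate_dataset(c1)
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$candidate_truth, d2$candidate_truth)
  smi <- function(d) lapply(d$lists, function(pl)
    vapply(pl$candidates, function(r)
      paste(vapply(r$reactants, mol_to_smiles, character(1)), collapse = "."),
      character(1)))
  expect_identical(smi(d1), smi(d2))
})

test_that("every list has the configured size and exactly one recorded candidate", {
  d <- generate_dataset(synth_config(n_products = 40, candidates = 8, seed = 6))
  expect_length(d$lists, 40)
  for (pl in d$lists) {
    expect_length(pl$candidates, 8)
    expect_equal(sum(vapply(pl$candidates, function(r) isTRUE(r$is_recorded),
                            logical(1))), 1)
    ranks <- vapply(pl$candidates, function(r) r$original_rank, integer(1))
    expect_identical(ranks, 1:8)
  }
})

test_that("all generated candidates satisfy the reaction-record invariants", {
  d <- generate_dataset(synth_config(n_products = 25, seed = 8))
  for (pl in d$lists) {
    pmaps <- NULL
    for (r in pl$candidates) {
      expect_true(r$scorable)
      pm <- r$product$map[r$product$map > 0]
      rm <- unlist(lapply(r$reactants, function(m) m$map[m$map > 0]))
      expect_true(all(pm %in% rm))
      expect_false(any(duplicated(rm[rm %in% pm])))
      # every candidate must reparse from its own serialization
      rt <- parse_mapped_reaction(paste0(
        paste(vapply(r$reactants, mol_to_smiles, character(1)), collapse = "."),
        ">>", mol_to_smiles(r$product)))
      expect_equal(n_atoms(rt$product), n_atoms(r$product))
    }
  }
})

test_that("identity decoys plant zero changed bonds, recorded the template count", {
  d <- generate_dataset(synth_config(n_products = 25, seed = 9))
  for (pi in seq_along(d$lists)) {
    pl <- d$lists[[pi]]
    cats <- d$candidate_truth[d$candidate_truth$product == pi, ]
    for (ci in seq_along(pl$candidates)) {
      cat_i <- cats$category[cats$rank == ci]
      cb <- changed_bond_count(annotate_changes(pl$candidates[[ci]]))
      if (cat_i == "identity") expect_equal(cb, 0)
      if (cat_i == "recorded")
        expect_equal(cb, d$truth$planted_changed_bonds[pi])
    }
  }
})

test_that("decoy leaving groups are inflated relative to the recorded ones", {
  d <- generate_dataset(separable_synth_config(20, seed = 12))
  leaving_total <- function(r) {
    a <- annotate_changes(r)
    nrow(a$leaving_atoms)
  }
  for (pi in seq_along(d$lists)) {
    pl <- d$lists[[pi]]
    cats <- d$candidate_truth[d$candidate_truth$product == pi, ]
    rec <- which(vapply(pl$candidates, function(r) isTRUE(r$is_recorded), logical(1)))
    lrec <- leaving_total(pl$candidates[[rec]])
    for (ci in seq_along(pl$candidates)) {
      cat_i <- cats$category[cats$rank == ci]
      if (cat_i %in% c("spurious", "overlarge"))
        expect_gt(leaving_total(pl$candidates[[ci]]), lrec)
    }
  }
})

test_that("wrong-site perturbations disconnect a different site", {
  # one wrong-site decoy per product: distinct alternative sites are few
  d <- generate_dataset(synth_config(n_products = 30, candidates = 2, seed = 14,
                                     decoy_mix = c(wrong_site = 1, spurious = 0,
                                                   identity = 0, overlarge = 0),
                                     two_site_prob = 1))
  checked <- 0
  for (pi in seq_along(d$lists)) {
    pl <- d$lists[[pi]]
    cats <- d$candidate_truth[d$candidate_truth$product == pi, ]
    rec <- which(vapply(pl$candidates, function(r) isTRUE(r$is_recorded), logical(1)))
    rec_key <- canonical_candidate_key(pl$candidates[[rec]])
    rec_centers <- annotate_changes(pl$candidates[[rec]])$center_maps
    for (ci in which(cats$category[order(cats$rank)] == "wrong_site")) {
      cand <- pl$candidates[[ci]]
      expect_false(identical(canonical_candidate_key(cand), rec_key))
      centers <- annotate_changes(cand)$center_maps
      expect_false(setequal(centers, rec_centers))
      checked <- checked + 1
    }
  }
  expect_gt(checked, 10)
})

test_that("single-site products raise a skip signal for wrong-site decoys", {
  r <- parse_mapped_reaction(FIX_ESTER)
  expect_error(perturb_wrong_site(r, seed = 1), class = "rr_skip_signal")
})

test_that("at beta = 0 the recorded original rank is uniform", {
  d <- generate_dataset(synth_config(n_products = 2000, beta = 0, seed = 17))
  tab <- table(factor(d$truth$recorded_rank, levels = 1:10))
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 0.01)
})

test_that("high beta pushes recorded candidates of rare templates to low ranks", {
  d <- generate_dataset(synth_config(n_products = 400, beta = 2, seed = 18))
  mean_rank <- tapply(d$truth$recorded_rank, d$truth$template, mean)
  # rare templates (namine, cc) must rank worse than the dominant one (ester)
  expect_gt(mean_rank[["cc"]], mean_rank[["ester"]])
  expect_gt(mean_rank[["namine"]], mean_rank[["ester"]])
  # and the overall top-1 rate of the original ranking is low
  expect_lt(mean(d$truth$recorded_rank == 1), 0.3)
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(candidates = 1), class = "rr_usage_error")
  expect_error(synth_config(template_mix = c(ester = -1, amide = 2,
                                             namine = 0, cc = 0)),
               class = "rr_usage_error")
  expect_error(synth_config(template_mix = c(bogus = 1)),
               class = "rr_usage_error")
})
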