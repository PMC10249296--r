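test_that("fixture reactions annotate exactly as the bond-diff oracle says", {
  # identity: nothing changes
  a <- annotate_changes(parse_mapped_reaction(FIX_IDENTITY))
  expect_equal(nrow(a$broken) + nrow(a$formed) + nrow(a$order_changed), 0)
  expect_length(a$center_maps, 0)
  expect_equal(nrow(a$leaving_atoms), 0)
  expect_true(all(unlist(a$neighborhood_counts) == 0))
  expect_equal(changed_bond_count(a), 0)

  # esterification
  a <- annotate_changes(parse_mapped_reaction(FIX_ESTER))
  expect_equal(unname(a$broken), matrix(c(4L, 6L), 1), ignore_attr = TRUE)
  expect_equal(unname(a$formed), matrix(c(2L, 4L), 1), ignore_attr = TRUE)
  expect_equal(a$center_maps, c(2L, 4L, 6L))
  expect_equal(nrow(a$leaving_atoms), 1)
  lv <- a$leaving_atoms
  expect_identical(
    parse_mapped_reaction(FIX_ESTER)$reactants[[lv[1, 1]]]$element[lv[1, 2]], "O")
  expect_equal(changed_bond_count(a), 2)

  # amination: broken C-Br, formed C-N, Br leaves
  r <- parse_mapped_reaction(FIX_AMINATION)
  a <- annotate_changes(r)
  expect_equal(unname(a$broken), matrix(c(1L, 2L), 1), ignore_attr = TRUE)
  expect_equal(unname(a$formed), matrix(c(1L, 3L), 1), ignore_attr = TRUE)
  expect_equal(changed_bond_count(a), 2)
  expect_identical(r$reactants[[a$leaving_atoms[1, 1]]]$element[a$leaving_atoms[1, 2]],
                   "Br")

  # order change counts each pair once
  a <- annotate_changes(parse_mapped_reaction(FIX_ORDER_CHANGE))
  expect_equal(nrow(a$order_changed), 2)
  expect_equal(nrow(a$broken) + nrow(a$formed), 0)
  expect_equal(changed_bond_count(a), 2)

  for (fx in c(FIX_IDENTITY, FIX_ESTER, FIX_AMINATION, FIX_ORDER_CHANGE, FIX_AMIDE))
    expect_annotation_matches_oracle(parse_mapped_reaction(fx))
})

test_that("kekule vs aromatic drawings of the same ring do not register as changes", {
  r <- parse_mapped_reaction(
    "[CH3:7][c:1]1[cH:2][cH:3][cH:4][cH:5][cH:6]1>>[CH3:7][C:1]1=[CH:2][CH:3]=[CH:4][CH:5]=[CH:6]1")
  a <- annotate_changes(r)
  expect_equal(changed_bond_count(a), 0)
})

test_that("neighborhood counts follow BFS truncated at the radius", {
  r <- parse_mapped_reaction(FIX_ESTER)
  a1 <- annotate_changes(r, radius = 1)
  # product: CH3:1-O:2-C:4(=O:5)-CH3:3; centers are maps 2 and 4
  # at radius 1: atom 1 sees {2}; atom 2 sees {4}; atom 4 sees {2}; 5 sees {4}
  pmaps <- r$product$map
  cnt <- a1$neighborhood_counts$product
  expect_equal(cnt[pmaps == 1], 1)
  expect_equal(cnt[pmaps == 2], 1)
  expect_equal(cnt[pmaps == 4], 1)
  expect_equal(cnt[pmaps == 5], 1)
  a2 <- annotate_changes(r, radius = 2)
  cnt2 <- a2$neighborhood_counts$product
  expect_equal(cnt2[pmaps == 1], 2)  # maps 2 and 4 both within 2 bonds
  expect_true(all(cnt2 >= cnt))
})

test_that("map relabeling leaves change statistics invariant", {
  set.seed(101)
  for (fx in c(FIX_ESTER, FIX_AMINATION, FIX_ORDER_CHANGE)) {
    r <- parse_mapped_reaction(fx)
    a0 <- annotate_changes(r)
    maps <- sort(unique(c(r$product$map, unlist(lapply(r$reactants, `[[`, "map")))))
    maps <- maps[maps > 0]
    for (i in 1:10) {
      perm <- stats::setNames(sample(50, length(maps)), maps)
      a <- annotate_changes(relabel_record_maps(r, perm))
      expect_equal(changed_bond_count(a), changed_bond_count(a0))
      expect_length(a$center_maps, length(a0$center_maps))
      expect_equal(nrow(a$leaving_atoms), nrow(a0$leaving_atoms))
    }
  }
})

test_that("swapping reactants and product swaps broken and formed", {
  # needs a reaction whose two sides cover the same map set
  fwd <- parse_mapped_reaction(FIX_ORDER_CHANGE)
  rev <- retroranker:::make_reaction_record(product = fwd$reactants[[1]],
                                            reactants = list(fwd$product))
  af <- annotate_changes(fwd); ar <- annotate_changes(rev)
  expect_equal(af$broken, ar$formed)
  expect_equal(af$formed, ar$broken)
  expect_equal(af$order_changed, ar$order_changed)
})

test_that("random mapped reactions agree with the bond-diff oracle", {
  set.seed(2024)
  for (i in 1:60) expect_annotation_matches_oracle(random_mapped_reaction(12L))
})

test_that("mean changed bonds aggregates per group with an 'all' row", {
  r2 <- parse_mapped_reaction(FIX_ESTER)     # 2 changed
  r0 <- parse_mapped_reaction(FIX_IDENTITY)  # 0 changed
  tab <- mean_changed_bonds(list(r2, r0))
  expect_equal(tab$mean_changed_bonds[tab$group == "all"], 1.0)
  tab1 <- mean_changed_bonds(list(r2))
  expect_equal(tab1$mean_changed_bonds, 2.0)
  tabg <- mean_changed_bonds(list(r2, r0, r2), group_by = c("x", "y", "x"))
  expect_equal(tabg$mean_changed_bonds[tabg$group == "x"], 2.0)
  expect_equal(tabg$mean_changed_bonds[tabg$group == "y"], 0.0)
  expect_true("all" %in% tabg$group)
  expect_error(mean_changed_bonds(list()), class = "rr_usage_error")
})

test_that("generator-planted changed-bond counts are recovered exactly", {
  d <- generate_dataset(synth_config(n_products = 30, seed = 7))
  counts <- vapply(seq_along(d$lists), function(pi) {
    pl <- d$lists[[pi]]
    rec <- which(vapply(pl$candidates, function(r) isTRUE(r$is_recorded), logical(1)))
    changed_bond_count(annotate_changes(pl$candidates[[rec]]))
  }, numeric(1))
  expect_equal(counts, as.numeric(d$truth$planted_changed_bonds))
  expect_equal(mean(counts), mean(d$truth$planted_changed_bonds))
})

test_that("annotate_reaction_file writes one JSON object per reaction", {
  inf <- tempfile(fileext = ".txt")
  outf <- tempfile(fileext = ".jsonl")
  writeLines(c("# fixtures", FIX_ESTER, FIX_IDENTITY), inf)
  annotate_reaction_file(inf, outf)
  lines <- readLines(outf)
  expect_length(lines, 2)
  o1 <- jsonlite::fromJSON(lines[1])
  expect_equal(o1$changed_bond_count, 2)
  expect_equal(sort(o1$center_atoms), c(2, 4, 6))
})
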