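test_that("feature widths equal the sum of schema widths", {
  sch <- reaction_feature_schema()
  expect_equal(sch$d_atom, sum(sch$atom$width))
  expect_equal(sch$d_bond, sum(sch$bond$width))
  r <- parse_mapped_reaction(FIX_ESTER)
  a <- annotate_changes(r)
  v <- atom_feature_vector(r$reactants[[1]], 1, a, "reactant", 1)
  expect_length(v, sch$d_atom)
  b <- bond_feature_vector(a$normalized$product, 1, a)
  expect_length(b, sch$d_bond)
})

test_that("change-feature slots are zero in an identity reaction", {
  r <- parse_mapped_reaction(FIX_IDENTITY)
  a <- annotate_changes(r)
  sch <- reaction_feature_schema()
  mol_width <- sum(sch$atom$width[1:6])
  for (i in seq_len(n_atoms(r$product))) {
    v <- atom_feature_vector(r$product, i, a, "product")
    change_part <- unname(v[(mol_width + 1):sch$d_atom])
    # reacted-neighbor one-hot encodes "0 neighbors" as its first slot
    expect_equal(change_part, c(0, 1, 0, 0, 0, 0, 0, 0))
  }
})

test_that("the leaving oxygen of the esterification carries its flags", {
  r <- parse_mapped_reaction(FIX_ESTER)
  a <- annotate_changes(r)
  acid <- r$reactants[[2]]
  o6 <- which(acid$map == 6)
  v <- atom_feature_vector(acid, o6, a, "reactant", 2)
  sch <- reaction_feature_schema()
  nm <- rep(sch$atom$name, sch$atom$width)
  expect_equal(unname(v[nm == "is_center"]), 1)
  expect_equal(unname(v[nm == "is_leaving"]), 1)
  expect_equal(unname(v[nm == "leaving_size"]), 1)
  # product side: leaving slots are structurally zero
  vprod <- atom_feature_vector(r$product, 1, a, "product")
  expect_equal(unname(vprod[nm == "is_leaving"]), 0)
  expect_equal(unname(vprod[nm == "leaving_size"]), 0)
})

test_that("changed-bond flags sit on the diffed bonds only", {
  r <- parse_mapped_reaction(FIX_ESTER)
  a <- annotate_changes(r)
  acid <- a$normalized$reactants[[2]]
  sch <- reaction_feature_schema()
  nm <- rep(sch$bond$name, sch$bond$width)
  for (b in seq_len(nrow(acid$bonds))) {
    key <- paste(sort(acid$map[acid$bonds[b, ]]), collapse = "-")
    v <- bond_feature_vector(acid, b, a)
    expect_equal(unname(v[nm == "is_changed"]), as.numeric(key == "4-6"))
  }
  prod <- a$normalized$product
  for (b in seq_len(nrow(prod$bonds))) {
    key <- paste(sort(prod$map[prod$bonds[b, ]]), collapse = "-")
    v <- bond_feature_vector(prod, b, a)
    expect_equal(unname(v[nm == "is_changed"]), as.numeric(key == "2-4"))
  }
})

test_that("aromatic ring bonds get the aromatic slot, ring and conjugation flags", {
  r <- parse_mapped_reaction("[CH3:7][c:1]1[cH:2][cH:3][cH:4][cH:5][cH:6]1>>[CH3:7][c:1]1[cH:2][cH:3][cH:4][cH:5][cH:6]1")
  a <- annotate_changes(r)
  mol <- a$normalized$product
  sch <- reaction_feature_schema()
  nm <- rep(sch$bond$name, sch$bond$width)
  arom <- which(mol$bond_order == "aromatic")
  expect_gt(length(arom), 0)
  for (b in arom) {
    v <- bond_feature_vector(mol, b, a)
    expect_equal(unname(v[nm == "order_onehot"]), c(0, 0, 0, 1))
    expect_equal(unname(v[nm == "in_ring"]), 1)
    expect_equal(unname(v[nm == "conjugated"]), 1)
  }
})

test_that("reactant fragments merge into one disconnected graph", {
  r <- parse_mapped_reaction(FIX_ESTER)
  g <- build_reaction_graphs(r)
  expect_equal(nrow(g$reactant$x), 6)  # 2 + 4 heavy atoms
  expect_equal(nrow(g$product$x), 5)
  # no edge crosses the fragment boundary (fragment 1 = atoms 1..2)
  expect_true(all((g$reactant$edges[, 1] <= 2) == (g$reactant$edges[, 2] <= 2)))
  # deterministic featurization
  g2 <- build_reaction_graphs(parse_mapped_reaction(FIX_ESTER))
  expect_identical(g, g2)
})

test_that("atom permutations permute feature rows without changing their multiset", {
  set.seed(5)
  r <- parse_mapped_reaction(FIX_ESTER)
  g <- build_reaction_graphs(r)
  r2 <- r
  r2$product <- permute_mol_atoms(r$product, sample(n_atoms(r$product)))
  g2 <- build_reaction_graphs(r2)
  rows1 <- apply(g$product$x, 1, paste, collapse = ",")
  rows2 <- apply(g2$product$x, 1, paste, collapse = ",")
  expect_identical(sort(rows1), sort(rows2))
})

test_that("same product, different candidates differ in product-side change features", {
  ester <- parse_mapped_reaction(FIX_ESTER)
  # a second candidate for a closely related product: identity no-op
  ident <- retroranker:::make_reaction_record(ester$product, list(ester$product))
  g1 <- build_reaction_graphs(ester)
  g2 <- build_reaction_graphs(ident)
  # molecular part identical, change part different
  sch <- reaction_feature_schema()
  mol_width <- sum(sch$atom$width[1:6])
  expect_identical(g1$product$x[, 1:mol_width], g2$product$x[, 1:mol_width])
  expect_false(identical(g1$product$x[, (mol_width + 1):sch$d_atom],
                         g2$product$x[, (mol_width + 1):sch$d_atom]))
})

test_that("out-of-range indices raise usage errors", {
  r <- parse_mapped_reaction(FIX_IDENTITY)
  a <- annotate_changes(r)
  expect_error(atom_feature_vector(r$product, 99, a, "product"),
               class = "rr_usage_error")
  expect_error(bond_feature_vector(r$product, 99, a), class = "rr_usage_error")
})

test_that("the schema dump round-trips with a stable hash", {
  f <- tempfile(fileext = ".json")
  write_feature_schema(f)
  obj <- jsonlite::fromJSON(f)
  expect_identical(obj$hash, unname(schema_hash()))
  expect_equal(sum(obj$atom$width), reaction_feature_schema()$d_atom)
})
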