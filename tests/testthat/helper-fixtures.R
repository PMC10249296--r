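# Shared fixtures and independent oracles used across the suite.

# ---- fixture reactions ---------------------------------------------------

FIX_IDENTITY <- "[CH3:1][OH:2]>>[CH3:1][OH:2]"
FIX_ESTER <- "[CH3:1][OH:2].[CH3:3][C:4](=[O:5])[OH:6]>>[CH3:1][O:2][C:4](=[O:5])[CH3:3]"
FIX_AMINATION <- "[CH2:1]([CH3:4])[Br:2].[NH2:3][CH3:5]>>[CH2:1]([CH3:4])[NH:3][CH3:5]"
FIX_ORDER_CHANGE <- "[CH3:1][C:2](=[O:3])[CH3:4]>>[CH2:1]=[C:2]([OH:3])[CH3:4]"
# amide cleavage of the same product skeleton as the ester fixture, used for
# the "same product, different candidates -> different change features" check
FIX_AMIDE <- "[CH3:1][NH2:2].[CH3:3][C:4](=[O:5])[OH:6]>>[CH3:1][NH:2][C:4](=[O:5])[CH3:3]"

# ---- independent bond-multiset diff oracle ------------------------------

# Builds per-side data.frames of map-keyed bonds and diffs them with merge();
# deliberately a different code path from annotate_changes.
oracle_bond_diff <- function(record) {
  side_table <- function(mols) {
    rows <- list()
    for (m in mols) {
      m <- retroranker:::aromatize_rings(m)
      if (nrow(m$bonds) == 0L) next
      for (b in seq_len(nrow(m$bonds))) {
        i <- m$bonds[b, 1]; j <- m$bonds[b, 2]
        if (m$map[i] > 0L && m$map[j] > 0L) {
          rows[[length(rows) + 1L]] <- data.frame(
            lo = min(m$map[i], m$map[j]), hi = max(m$map[i], m$map[j]),
            ord = m$bond_order[b], stringsAsFactors = FALSE)
        }
      }
    }
    if (length(rows) == 0L)
      return(data.frame(lo = integer(0), hi = integer(0), ord = character(0)))
    unique(do.call(rbind, rows))
  }
  R <- side_table(record$reactants)
  P <- side_table(list(record$product))
  mg <- merge(R, P, by = c("lo", "hi"), all = TRUE, suffixes = c(".r", ".p"))
  broken <- mg[is.na(mg$ord.p), c("lo", "hi")]
  formed <- mg[is.na(mg$ord.r), c("lo", "hi")]
  order_ch <- mg[!is.na(mg$ord.r) & !is.na(mg$ord.p) & mg$ord.r != mg$ord.p,
                 c("lo", "hi")]
  centers <- sort(unique(c(broken$lo, broken$hi, formed$lo, formed$hi,
                           order_ch$lo, order_ch$hi)))
  pmaps <- record$product$map[record$product$map > 0L]
  n_leaving <- sum(vapply(record$reactants, function(m)
    sum(m$map == 0L | !(m$map %in% pmaps)), numeric(1)))
  list(broken = broken[order(broken$lo, broken$hi), , drop = FALSE],
       formed = formed[order(formed$lo, formed$hi), , drop = FALSE],
       order_changed = order_ch[order(order_ch$lo, order_ch$hi), , drop = FALSE],
       centers = centers, n_leaving = n_leaving,
       n_changed = nrow(broken) + nrow(formed) + nrow(order_ch))
}

expect_annotation_matches_oracle <- function(record, radius = 1L) {
  a <- annotate_changes(record, radius)
  o <- oracle_bond_diff(record)
  as_int_pairs <- function(m) matrix(as.integer(as.matrix(m)), ncol = 2)
  expect_equal(as_int_pairs(a$broken), as_int_pairs(o$broken))
  expect_equal(as_int_pairs(a$formed), as_int_pairs(o$formed))
  expect_equal(as_int_pairs(a$order_changed), as_int_pairs(o$order_changed))
  expect_equal(a$center_maps, o$centers)
  expect_equal(nrow(a$leaving_atoms), o$n_leaving)
  expect_equal(changed_bond_count(a), o$n_changed)
}

# ---- brute-force re-ranking oracles -------------------------------------

# Literal hand-execution of the S1 post-condition using explicit repeated
# selection with pairwise comparators (no order()).
oracle_s1 <- function(ranks, scores, p, k) {
  n <- length(ranks)
  eligible <- which(ranks > k)
  m <- floor(p * length(eligible))
  demoted <- integer(0)
  pool <- eligible
  while (length(demoted) < m) {
    worst <- pool[1]
    for (x in pool[-1]) {
      if (scores[x] < scores[worst] ||
          (scores[x] == scores[worst] && ranks[x] > ranks[worst])) worst <- x
    }
    demoted <- c(demoted, worst)
    pool <- setdiff(pool, worst)
  }
  out <- integer(0)
  for (r in sort(ranks)) {          # head + non-demoted, original order
    item <- which(ranks == r)
    if (!(item %in% demoted)) out <- c(out, item)
  }
  rest <- demoted
  while (length(rest) > 0L) {
    best <- rest[1]
    for (x in rest[-1]) {
      if (scores[x] > scores[best] ||
          (scores[x] == scores[best] && ranks[x] < ranks[best])) best <- x
    }
    out <- c(out, best)
    rest <- setdiff(rest, best)
  }
  out
}

oracle_s2 <- function(ranks, scores, p, k) {
  s1 <- oracle_s1(ranks, scores, p, k)
  pos1 <- integer(length(s1)); pos1[s1] <- seq_along(s1)
  sums <- ranks + pos1
  out <- integer(0)
  rest <- seq_along(ranks)
  while (length(rest) > 0L) {
    best <- rest[1]
    for (x in rest[-1]) {
      if (sums[x] < sums[best] ||
          (sums[x] == sums[best] && ranks[x] < ranks[best])) best <- x
    }
    out <- c(out, best)
    rest <- setdiff(rest, best)
  }
  out
}

# ---- structural helpers --------------------------------------------------

permute_mol_atoms <- function(mol, perm) {
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  b <- mol$bonds
  if (nrow(b) > 0L) {
    b2 <- cbind(inv[b[, 1]], inv[b[, 2]])
    b <- cbind(a = pmin(b2[, 1], b2[, 2]), b = pmax(b2[, 1], b2[, 2]))
  }
  retroranker:::new_mapped_molecule(mol$element[perm], mol$charge[perm],
                                    mol$hcount[perm], mol$aromatic[perm],
                                    mol$map[perm], b, mol$bond_order)
}

relabel_record_maps <- function(record, perm_of_maps) {
  # perm_of_maps: named int vector old -> new over all map numbers in use
  relabel <- function(m) {
    m$map <- ifelse(m$map > 0L, perm_of_maps[as.character(m$map)], 0L)
    m$map <- as.integer(m$map)
    m
  }
  record$product <- relabel(record$product)
  record$reactants <- lapply(record$reactants, relabel)
  record
}

# random mapped reaction on <= max_atoms heavy atoms: random reactant graph,
# product = random graph over a subset of the reactant maps
random_mapped_reaction <- function(max_atoms = 12L) {
  n <- sample(3:max_atoms, 1)
  els <- sample(c("C", "N", "O"), n, replace = TRUE, prob = c(0.7, 0.15, 0.15))
  random_graph_mol <- function(els, maps) {
    n <- length(els)
    bonds <- NULL; orders <- character(0)
    if (n > 1L) {
      for (i in 2:n) {   # random spanning tree
        j <- sample(i - 1L, 1)
        bonds <- rbind(bonds, cbind(a = j, b = i))
        orders <- c(orders, sample(c("single", "double"), 1, prob = c(0.85, 0.15)))
      }
    } else bonds <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("a", "b")))
    m <- retroranker:::new_mapped_molecule(els, rep(0L, n), rep(NA_integer_, n),
                                           rep(FALSE, n), as.integer(maps),
                                           bonds, orders)
    m$hcount <- retroranker:::compute_hcounts(m)
    m
  }
  # split reactant atoms into 1-2 fragments
  nfrag <- if (n >= 5L) sample(1:2, 1) else 1L
  sizes <- if (nfrag == 2L) { s1 <- sample(2:(n - 2L), 1); c(s1, n - s1) } else n
  maps <- sample(n)  # maps 1..n in random order
  reactants <- list(); off <- 0L
  for (sz in sizes) {
    reactants[[length(reactants) + 1L]] <-
      random_graph_mol(els[(off + 1L):(off + sz)], maps[(off + 1L):(off + sz)])
    off <- off + sz
  }
  # product: random subset of maps (>= 2), fresh random graph
  np <- sample(2:n, 1)
  pm <- sample(maps, np)
  pel <- els[match(pm, maps)]
  product <- random_graph_mol(pel, pm)
  retroranker:::make_reaction_record(product, reactants)
}

# small synthetic datasets reused by several tests (separable decoys)
separable_synth_config <- function(n_products, seed,
                                   beta = 2, candidates = 10L) {
  synth_config(n_products = n_products, candidates = candidates,
               decoy_mix = c(wrong_site = 0, spurious = 0.4,
                             identity = 0.2, overlarge = 0.4),
               beta = beta, seed = seed)
}

graphs_to_store_entry <- function(g) {
  list(xr = g$reactant$x, er = g$reactant$edges, fr = g$reactant$ef,
       xp = g$product$x, ep = g$product$edges, fp = g$product$ef)
}
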