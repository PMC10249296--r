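# Seeded generator of toy atom-mapped retrosynthesis prediction lists.
#
# Each product is assembled from random fragments around one (or two)
# disconnectable linkages drawn from four reaction templates; the recorded
# reactant set is obtained by applying the inverse template as a graph
# rewrite with atom maps assigned at rewrite time (no external atom-mapping
# model is ever needed). Decoys are chemical perturbations of the recorded
# disconnection; the original ranking is drawn from a frequency-bias model in
# which a candidate's upstream score is its (pseudo-)template frequency
# raised to the bias strength beta times log-normal noise — at beta = 0 the
# recorded rank is uniform, at high beta recorded reactants of rare templates
# sink to low ranks, which is exactly the bias re-ranking targets.

SYNTH_FRAGMENTS <- list(
  list(smiles = "C", attach = 1L),           # methyl
  list(smiles = "CC", attach = 1L),          # ethyl
  list(smiles = "CCC", attach = 1L),         # n-propyl
  list(smiles = "C(C)C", attach = 1L),       # isopropyl
  list(smiles = "CCCC", attach = 1L),        # n-butyl
  list(smiles = "C(C)(C)C", attach = 1L),    # tert-butyl
  list(smiles = "c1ccccc1", attach = 1L),    # phenyl
  list(smiles = "Cc1ccccc1", attach = 1L),   # benzyl
  list(smiles = "c1ccc(C)cc1", attach = 1L), # p-tolyl
  list(smiles = "C1CCCCC1", attach = 1L)     # cyclohexyl
)

SYNTH_LINKERS <- list(
  list(smiles = "CC", attach = c(1L, 2L)),        # ethylene
  list(smiles = "CCC", attach = c(1L, 3L)),       # propylene
  list(smiles = "c1ccccc1", attach = c(1L, 4L))   # 1,4-phenylene
)

SYNTH_TEMPLATES <- c("ester", "amide", "namine", "cc")

#' Synthetic dataset configuration
#'
#' Defaults describe a small frequency-biased benchmark: ester hydrolysis
#' dominates the template mix the way common reaction classes dominate patent
#' data, and decoys cover the characteristic failure modes of data-driven
#' models (wrong-site disconnections, spurious or oversized leaving groups,
#' no-op candidates).
#'
#' @param n_products number of product molecules
#' @param candidates candidates per product (>= 2, includes the recorded one)
#' @param template_mix named nonnegative weights over
#'   `c("ester", "amide", "namine", "cc")`
#' @param decoy_mix named nonnegative weights over
#'   `c("wrong_site", "spurious", "identity", "overlarge")`
#' @param beta frequency-bias strength (0 = unbiased original ranking)
#' @param noise_sd log-normal noise of the upstream score model
#' @param two_site_prob probability a product carries a second disconnectable
#'   linkage (needed for wrong-site decoys)
#' @param seed RNG seed
#' @return a `synth_config`
#' @export
synth_config <- function(n_products = 100L, candidates = 10L,
                         template_mix = c(ester = 0.55, amide = 0.25,
                                          namine = 0.12, cc = 0.08),
                         decoy_mix = c(wrong_site = 0.2, spurious = 0.3,
                                       identity = 0.15, overlarge = 0.35),
                         beta = 2, noise_sd = 0.35,
                         two_site_prob = 0.5, seed = 1L) {
  if (candidates < 2L) rr_usage_error("need at least 2 candidates per product")
  if (any(template_mix < 0) || sum(template_mix) <= 0)
    rr_usage_error("template_mix must be nonnegative with positive sum")
  if (!all(names(template_mix) %in% SYNTH_TEMPLATES))
    rr_usage_error("unknown template in template_mix")
  if (any(decoy_mix < 0) || sum(decoy_mix) <= 0)
    rr_usage_error("decoy_mix must be nonnegative with positive sum")
  structure(list(n_products = as.integer(n_products),
                 candidates = as.integer(candidates),
                 template_mix = template_mix / sum(template_mix),
                 decoy_mix = decoy_mix / sum(decoy_mix),
                 beta = beta, noise_sd = noise_sd,
                 two_site_prob = two_site_prob, seed = as.integer(seed)),
            class = "synth_config")
}

# ---- molecule graph construction helpers --------------------------------

empty_mol <- function() {
  new_mapped_molecule(character(0), integer(0), integer(0), logical(0),
                      integer(0),
                      matrix(integer(0), ncol = 2, dimnames = list(NULL, c("a", "b"))),
                      character(0))
}

mol_append <- function(mol, other) {
  off <- n_atoms(mol)
  mol$element <- c(mol$element, other$element)
  mol$charge <- c(mol$charge, other$charge)
  mol$hcount <- c(mol$hcount, other$hcount)
  mol$aromatic <- c(mol$aromatic, other$aromatic)
  mol$map <- c(mol$map, other$map)
  if (nrow(other$bonds) > 0L) {
    mol$bonds <- rbind(mol$bonds, other$bonds + off)
    mol$bond_order <- c(mol$bond_order, other$bond_order)
  }
  list(mol = mol, offset = off)
}

mol_add_atom <- function(mol, element, map = 0L, aromatic = FALSE) {
  mol$element <- c(mol$element, element)
  mol$charge <- c(mol$charge, 0L)
  mol$hcount <- c(mol$hcount, NA_integer_)
  mol$aromatic <- c(mol$aromatic, aromatic)
  mol$map <- c(mol$map, as.integer(map))
  mol
}

mol_add_bond <- function(mol, i, j, order = "single") {
  mol$bonds <- rbind(mol$bonds, cbind(a = min(i, j), b = max(i, j)))
  mol$bond_order <- c(mol$bond_order, order)
  mol
}

# recompute implicit hydrogens and refresh the source SMILES
finalize_mol <- function(mol) {
  mol$hcount <- rep(NA_integer_, n_atoms(mol))
  mol$hcount <- compute_hcounts(mol)
  mol$source_smiles <- mol_to_smiles(mol)
  mol
}

subset_mol <- function(mol, atoms) {
  atoms <- sort(atoms)
  remap <- integer(n_atoms(mol)); remap[atoms] <- seq_along(atoms)
  keep <- which(mol$bonds[, 1] %in% atoms & mol$bonds[, 2] %in% atoms)
  bonds <- mol$bonds[keep, , drop = FALSE]
  if (nrow(bonds) > 0L) {
    bonds <- cbind(a = remap[bonds[, 1]], b = remap[bonds[, 2]])
  }
  new_mapped_molecule(mol$element[atoms], mol$charge[atoms], mol$hcount[atoms],
                      mol$aromatic[atoms], mol$map[atoms],
                      bonds, mol$bond_order[keep])
}

frag_mol <- local({
  cache <- new.env(parent = emptyenv())
  function(spec) {
    key <- spec$smiles
    if (is.null(cache[[key]])) cache[[key]] <- parse_smiles(spec$smiles)
    cache[[key]]
  }
})

# ---- product assembly and template rewrites -----------------------------

# Attach linkage atoms of `template` between the current molecule (at atom
# `left_at`) and fragment B; returns mol, site descriptor, B's attach index.
attach_linkage <- function(mol, left_at, template, bfrag) {
  if (template == "ester") {
    mol <- mol_add_atom(mol, "C"); cC <- n_atoms(mol)
    mol <- mol_add_atom(mol, "O"); cO <- n_atoms(mol)
    mol <- mol_add_atom(mol, "O"); eO <- n_atoms(mol)
    mol <- mol_add_bond(mol, left_at, cC)
    mol <- mol_add_bond(mol, cC, cO, "double")
    mol <- mol_add_bond(mol, cC, eO)
    ap <- mol_append(mol, frag_mol(bfrag))
    mol <- ap$mol; batt <- ap$offset + bfrag$attach[1]
    mol <- mol_add_bond(mol, eO, batt)
    site <- list(type = "ester", C = cC, O = eO)
  } else if (template == "amide") {
    mol <- mol_add_atom(mol, "C"); cC <- n_atoms(mol)
    mol <- mol_add_atom(mol, "O"); cO <- n_atoms(mol)
    mol <- mol_add_atom(mol, "N"); aN <- n_atoms(mol)
    mol <- mol_add_bond(mol, left_at, cC)
    mol <- mol_add_bond(mol, cC, cO, "double")
    mol <- mol_add_bond(mol, cC, aN)
    ap <- mol_append(mol, frag_mol(bfrag))
    mol <- ap$mol; batt <- ap$offset + bfrag$attach[1]
    mol <- mol_add_bond(mol, aN, batt)
    site <- list(type = "amide", C = cC, N = aN)
  } else if (template == "namine") {
    mol <- mol_add_atom(mol, "N"); aN <- n_atoms(mol)
    mol <- mol_add_bond(mol, left_at, aN)
    ap <- mol_append(mol, frag_mol(bfrag))
    mol <- ap$mol; batt <- ap$offset + bfrag$attach[1]
    mol <- mol_add_bond(mol, aN, batt)
    site <- list(type = "namine", N = aN, C = batt)
  } else {  # cc
    ap <- mol_append(mol, frag_mol(bfrag))
    mol <- ap$mol; batt <- ap$offset + bfrag$attach[1]
    mol <- mol_add_bond(mol, left_at, batt)
    site <- list(type = "cc", Ca = left_at, Cb = batt)
  }
  list(mol = mol, site = site, batt = batt)
}

# Build a product molecule. Returns product (maps = atom indices), the
# recorded-site descriptor, and all site descriptors.
build_product <- function(template, two_site) {
  afrag <- SYNTH_FRAGMENTS[[sample.int(length(SYNTH_FRAGMENTS), 1)]]
  bfrag <- SYNTH_FRAGMENTS[[sample.int(length(SYNTH_FRAGMENTS), 1)]]
  mol <- parse_smiles(afrag$smiles)
  aatt <- afrag$attach[1]
  sites <- list()
  if (!two_site) {
    al <- attach_linkage(mol, aatt, template, bfrag)
    mol <- al$mol
    sites <- list(al$site)
  } else {
    t2 <- sample(c("ester", "amide", "namine"), 1)
    if (t2 == template && identical(afrag$smiles, bfrag$smiles)) {
      repeat {
        bfrag <- SYNTH_FRAGMENTS[[sample.int(length(SYNTH_FRAGMENTS), 1)]]
        if (!identical(afrag$smiles, bfrag$smiles)) break
      }
    }
    linker <- SYNTH_LINKERS[[sample.int(length(SYNTH_LINKERS), 1)]]
    al1 <- attach_linkage(mol, aatt, template, linker)
    mol <- al1$mol
    linker_right <- al1$batt - linker$attach[1] + linker$attach[2]
    al2 <- attach_linkage(mol, linker_right, t2, bfrag)
    mol <- al2$mol
    sites <- list(al1$site, al2$site)
  }
  mol$map <- seq_len(n_atoms(mol))
  mol <- finalize_mol(mol)
  list(product = mol, recorded_site = sites[[1]], sites = sites)
}

# Apply the inverse template at a site: split the linkage bond, add fresh
# leaving atoms with fresh map numbers. Returns the reactant molecules.
cleave_site <- function(product, site, fresh_start) {
  split_pair <- switch(site$type,
    ester = c(site$C, site$O),
    amide = c(site$C, site$N),
    namine = c(site$N, site$C),
    cc = c(site$Ca, site$Cb))
  keep <- !(pmin(product$bonds[, 1], product$bonds[, 2]) == min(split_pair) &
            pmax(product$bonds[, 1], product$bonds[, 2]) == max(split_pair))
  cut <- product
  cut$bonds <- product$bonds[keep, , drop = FALSE]
  cut$bond_order <- product$bond_order[keep]
  comp <- induced_components(cut, seq_len(n_atoms(cut)))
  mols <- lapply(sort(unique(comp)), function(ci) subset_mol(cut, which(comp == ci)))
  find_mol_with <- function(atom) which(vapply(mols, function(m)
    product$map[atom] %in% m$map, logical(1)))

  add_fresh <- function(mi, to_map, element) {
    m <- mols[[mi]]
    at <- which(m$map == to_map)
    m <- mol_add_atom(m, element, map = fresh_start)
    fresh_start <<- fresh_start + 1L
    m <- mol_add_bond(m, at, n_atoms(m))
    mols[[mi]] <<- m
    invisible(NULL)
  }

  if (site$type %in% c("ester", "amide")) {
    add_fresh(find_mol_with(site$C), product$map[site$C], "O")
  } else if (site$type == "namine") {
    add_fresh(find_mol_with(site$C), product$map[site$C], "Br")
  } else {
    add_fresh(find_mol_with(site$Ca), product$map[site$Ca], "Br")
    add_fresh(find_mol_with(site$Cb), product$map[site$Cb], "Br")
  }
  lapply(mols, finalize_mol)
}

# Detect disconnectable heteroatom linkages on a product graph (ester, amide,
# secondary-amine); used by the wrong-site perturbation.
find_sites <- function(mol) {
  nb <- neighbor_list(mol)
  ords <- mol$bond_order
  bond_between <- function(i, j)
    which(pmin(mol$bonds[, 1], mol$bonds[, 2]) == min(i, j) &
          pmax(mol$bonds[, 1], mol$bonds[, 2]) == max(i, j))
  has_dbl_O <- function(c_at) {
    any(vapply(nb[[c_at]], function(x) {
      mol$element[x] == "O" && ords[bond_between(c_at, x)] == "double"
    }, logical(1)))
  }
  sites <- list()
  for (i in seq_len(n_atoms(mol))) {
    el <- mol$element[i]
    if (el == "O" && !mol$aromatic[i] && length(nb[[i]]) == 2L) {
      cs <- nb[[i]][mol$element[nb[[i]]] == "C"]
      for (c_at in cs) if (has_dbl_O(c_at))
        sites[[length(sites) + 1L]] <- list(type = "ester", C = c_at, O = i)
    } else if (el == "N" && !mol$aromatic[i]) {
      cs <- nb[[i]][mol$element[nb[[i]]] == "C"]
      carbonyl <- vapply(cs, has_dbl_O, logical(1))
      if (any(carbonyl)) {
        for (c_at in cs[carbonyl])
          sites[[length(sites) + 1L]] <- list(type = "amide", C = c_at, N = i)
      } else if (length(cs) >= 2L && mol$hcount[i] >= 1L) {
        for (c_at in cs)
          sites[[length(sites) + 1L]] <- list(type = "namine", N = i, C = c_at)
      }
    }
  }
  sites
}

site_key <- function(site) {
  at <- sort(unlist(site[names(site) != "type"]))
  paste(site$type, paste(at, collapse = "-"))
}

#' Wrong-site perturbation of a reaction record
#'
#' Builds a decoy candidate that disconnects a different site of the product
#' than the recorded reactants do: the characteristic selectivity failure of
#' frequency-biased models. Raises a skip signal (condition class
#' `rr_skip_signal`) when the product has no alternative disconnectable site.
#'
#' @param record a scorable `reaction_record`
#' @param seed RNG seed for the site choice
#' @return a new `reaction_record` (not recorded)
#' @export
perturb_wrong_site <- function(record, seed = 1L) {
  set.seed(seed)
  product <- record$product
  ann <- annotate_changes(record)
  sites <- find_sites(product)
  if (length(sites) == 0L) rr_skip("no disconnectable site found")
  centered <- vapply(sites, function(s) {
    at <- unlist(s[names(s) != "type"])
    any(product$map[at] %in% ann$center_maps)
  }, logical(1))
  alt <- sites[!centered]
  if (length(alt) == 0L) rr_skip("no alternative disconnection site")
  site <- alt[[sample.int(length(alt), 1)]]
  fresh <- max(c(product$map, unlist(lapply(record$reactants, function(m) m$map)))) + 1L
  reactants <- cleave_site(product, site, fresh)
  make_reaction_record(product, reactants, original_rank = record$original_rank,
                       is_recorded = FALSE)
}

# attach an unmapped carbon chain (optionally branched) to the leaving atom
# of a recorded disconnection, inflating the leaving group
inflate_leaving <- function(reactants, product_maps, len, branch = FALSE) {
  fresh_idx <- NULL
  for (mi in seq_along(reactants)) {
    m <- reactants[[mi]]
    lv <- which(!(m$map %in% product_maps) & m$map > 0L)
    if (length(lv) > 0L) { fresh_idx <- c(mi, lv[1]); break }
  }
  if (is.null(fresh_idx)) rr_skip("no leaving atom to inflate")
  m <- reactants[[fresh_idx[1]]]
  at <- fresh_idx[2]
  if (m$element[at] == "Br") m$element[at] <- "O"
  prev <- at
  for (ci in seq_len(len)) {
    m <- mol_add_atom(m, "C")
    m <- mol_add_bond(m, prev, n_atoms(m))
    prev <- n_atoms(m)
    if (branch && ci == 2L) {
      m <- mol_add_atom(m, "C")
      m <- mol_add_bond(m, prev, n_atoms(m))
    }
  }
  reactants[[fresh_idx[1]]] <- finalize_mol(m)
  reactants
}

# internal structural key (writer-based, map-stripped, sorted fragments);
# used for within-product decoy deduplication during generation
struct_key <- function(reactants) {
  paste(sort(vapply(reactants, mol_to_smiles, character(1),
                    include_maps = FALSE)), collapse = ".")
}

#' Generate a synthetic retrosynthesis prediction dataset
#'
#' See [synth_config()] for the generative model. Every candidate list
#' contains exactly one recorded candidate; all candidates are valid
#' atom-mapped reaction records by construction.
#'
#' @param config a `synth_config`
#' @return list with `lists` (the `prediction_list`s), `truth` (per-product
#'   data.frame: template, two_site, recorded original rank, planted
#'   changed-bond count) and `candidate_truth` (per-candidate category)
#' @export
generate_dataset <- function(config = synth_config()) {
  set.seed(config$seed)
  tmix <- config$template_mix
  dmix <- config$decoy_mix
  want_wrong <- dmix[["wrong_site"]] > 0
  lists <- vector("list", config$n_products)
  truth <- vector("list", config$n_products)
  cand_truth <- list()
  rec_smiles <- character(config$n_products)

  for (pi in seq_len(config$n_products)) {
    template <- sample(names(tmix), 1, prob = tmix)
    two_site <- want_wrong && stats::runif(1) < config$two_site_prob
    built <- NULL
    for (try in 1:20) {
      built <- tryCatch(build_product(template, two_site),
                        rr_error = function(e) NULL)
      if (!is.null(built)) break
    }
    if (is.null(built)) rr_generation_error("could not build a product molecule")
    product <- built$product
    nmap <- n_atoms(product)
    planted <- if (template == "cc") 3L else 2L

    recorded_reactants <- cleave_site(product, built$recorded_site, nmap + 1L)
    recorded <- make_reaction_record(product, recorded_reactants, is_recorded = TRUE)
    used_keys <- struct_key(recorded_reactants)

    decoys <- list()
    categories <- character(0)
    guard <- 0L
    while (length(decoys) < config$candidates - 1L) {
      guard <- guard + 1L
      if (guard > 200L)
        rr_generation_error(sprintf("could not build %d distinct decoys (product %d)",
                                    config$candidates - 1L, pi))
      op <- sample(names(dmix), 1, prob = dmix)
      cand <- tryCatch({
        if (op == "identity") {
          list(reactants = list(product), cat = "identity")
        } else if (op == "wrong_site") {
          ws <- perturb_wrong_site(recorded, seed = config$seed * 131L + pi * 17L + guard)
          list(reactants = ws$reactants, cat = "wrong_site")
        } else if (op == "spurious") {
          list(reactants = inflate_leaving(recorded_reactants, product$map,
                                           len = sample(3:6, 1),
                                           branch = stats::runif(1) < 0.5),
               cat = "spurious")
        } else {
          list(reactants = inflate_leaving(recorded_reactants, product$map,
                                           len = sample(7:10, 1),
                                           branch = stats::runif(1) < 0.5),
               cat = "overlarge")
        }
      }, rr_skip_signal = function(e) NULL)
      if (is.null(cand)) next
      k <- struct_key(cand$reactants)
      if (k %in% used_keys) next
      used_keys <- c(used_keys, k)
      decoys[[length(decoys) + 1L]] <- make_reaction_record(
        product, cand$reactants, is_recorded = FALSE)
      categories <- c(categories, cand$cat)
    }

    # frequency-bias rank model: upstream score = template-frequency^beta
    # times log-normal noise; decoys mimic a pseudo-template drawn from the
    # same mix (frequent patterns are produced often, hence rank high)
    all_cands <- c(list(recorded), decoys)
    all_cats <- c("recorded", categories)
    freqs <- c(tmix[[template]],
               tmix[sample(names(tmix), length(decoys), replace = TRUE, prob = tmix)])
    scores <- as.numeric(freqs)^config$beta *
      exp(stats::rnorm(length(all_cands), 0, config$noise_sd))
    ranks <- rank(-scores, ties.method = "first")
    for (i in seq_along(all_cands)) {
      all_cands[[i]]$original_rank <- as.integer(ranks[i])
      all_cands[[i]]$upstream_score <- scores[i]
    }
    lists[[pi]] <- new_prediction_list(mol_to_smiles(product), all_cands)
    rec_smiles[pi] <- paste(vapply(recorded_reactants, mol_to_smiles, character(1),
                                   include_maps = FALSE), collapse = ".")
    truth[[pi]] <- data.frame(product = pi, template = template,
                              two_site = two_site,
                              recorded_rank = as.integer(ranks[1]),
                              planted_changed_bonds = planted)
    cand_truth[[pi]] <- data.frame(product = pi,
                                   rank = as.integer(ranks),
                                   category = all_cats)
  }

  keys <- canonical_keys(rec_smiles)
  for (pi in seq_len(config$n_products)) lists[[pi]]$recorded_key <- keys[pi]

  list(lists = lists,
       truth = do.call(rbind, truth),
       candidate_truth = do.call(rbind, cand_truth))
}
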