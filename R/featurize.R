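# Featurization: reaction record + change annotation -> paired numeric
# graphs. Atom features concatenate molecule-level descriptors with
# reaction-change descriptors; the layout is declared data (the feature
# schema) so a trained model can verify compatibility via a schema hash.

ELEMENT_VOCAB <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B",
                   "Si", "Se", "Sn", "Li", "Na", "K", "Mg", "Zn", "Cu", "Fe")

#' The atom/bond feature schema
#'
#' Ordered list of (feature name, width) for both node and edge features.
#' Counts are encoded as clipped one-hots rather than raw integers so that
#' feature scales are bounded; numeric slots (formal charge, leaving-group
#' size) are the only unbounded entries.
#'
#' @return a list with `atom` and `bond` data frames, the element vocabulary,
#'   and total widths `d_atom`, `d_bond`
#' @export
reaction_feature_schema <- function() {
  atom <- data.frame(
    name = c("element_onehot", "degree_onehot", "formal_charge", "aromatic",
             "hcount_onehot", "in_ring",
             "is_center", "reacted_neighbors_onehot", "is_leaving", "leaving_size"),
    width = c(length(ELEMENT_VOCAB) + 1L, 6L, 1L, 1L, 5L, 1L, 1L, 5L, 1L, 1L),
    stringsAsFactors = FALSE
  )
  bond <- data.frame(
    name = c("order_onehot", "in_ring", "conjugated", "is_changed"),
    width = c(4L, 1L, 1L, 1L),
    stringsAsFactors = FALSE
  )
  list(atom = atom, bond = bond,
       element_vocab = ELEMENT_VOCAB,
       d_atom = sum(atom$width), d_bond = sum(bond$width))
}

#' Hash of a feature schema
#'
#' MD5 over the canonical JSON form of the schema; stored in model
#' checkpoints and compared before scoring so that a model is never fed
#' graphs laid out under a different schema.
#'
#' @param schema a schema from [reaction_feature_schema()]
#' @return character MD5 hash
#' @export
schema_hash <- local({
  cache <- new.env(parent = emptyenv())
  function(schema = reaction_feature_schema()) {
    js <- as.character(jsonlite::toJSON(list(atom = schema$atom, bond = schema$bond,
                                             vocab = schema$element_vocab), digits = NA))
    if (!is.null(cache[[js]])) return(cache[[js]])
    tf <- tempfile(fileext = ".json")
    on.exit(unlink(tf))
    writeLines(js, tf)
    h <- unname(tools::md5sum(tf))
    cache[[js]] <- h
    h
  }
})

onehot_rows <- function(idx, width) {
  m <- matrix(0, nrow = length(idx), ncol = width)
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

# Per-molecule node feature matrix (n_atoms x d_atom).
# side: "reactant" or "product"; ri: index of the molecule among the
# reactants (ignored on the product side).
featurize_molecule_atoms <- function(mol, annotation, side, ri = 1L,
                                     schema = reaction_feature_schema()) {
  n <- n_atoms(mol)
  el <- match(mol$element, schema$element_vocab, nomatch = length(schema$element_vocab) + 1L)
  deg <- pmin(atom_degrees(mol), 5L) + 1L
  hc <- pmin(mol$hcount, 4L) + 1L
  rb <- ring_bonds(mol)
  in_ring <- rep(0, n)
  if (any(rb)) in_ring[unique(as.vector(mol$bonds[rb, , drop = FALSE]))] <- 1

  is_center <- as.numeric(mol$map %in% annotation$center_maps)
  if (side == "reactant") {
    nbc <- annotation$neighborhood_counts$reactants[[ri]]
    lv <- annotation$leaving_size$reactants[[ri]]
  } else {
    nbc <- annotation$neighborhood_counts$product
    lv <- annotation$leaving_size$product
  }
  nbc1 <- pmin(nbc, 4L) + 1L
  is_leaving <- as.numeric(lv > 0)

  cbind(
    onehot_rows(el, length(schema$element_vocab) + 1L),
    onehot_rows(deg, 6L),
    mol$charge,
    as.numeric(mol$aromatic),
    onehot_rows(hc, 5L),
    in_ring,
    is_center,
    onehot_rows(nbc1, 5L),
    is_leaving,
    lv
  )
}

# Per-molecule bond feature matrix (n_bonds x d_bond), using the aromatized
# form stored on the annotation so "is_changed" matches the diffed keys.
featurize_molecule_bonds <- function(mol, annotation,
                                     schema = reaction_feature_schema()) {
  m <- nrow(mol$bonds)
  if (m == 0L)
    return(matrix(0, nrow = 0L, ncol = schema$d_bond))
  ord <- match(mol$bond_order, c("single", "double", "triple", "aromatic"))
  rb <- as.numeric(ring_bonds(mol))
  multi <- mol$bond_order %in% c("double", "triple", "aromatic")
  mcount <- integer(n_atoms(mol))
  for (b in which(multi)) {
    mcount[mol$bonds[b, 1]] <- mcount[mol$bonds[b, 1]] + 1L
    mcount[mol$bonds[b, 2]] <- mcount[mol$bonds[b, 2]] + 1L
  }
  conj <- vapply(seq_len(m), function(b) {
    i <- mol$bonds[b, 1]; j <- mol$bonds[b, 2]
    o <- mol$bond_order[b]
    if (o == "aromatic") return(1)
    if (o == "single") return(as.numeric(mcount[i] >= 1L && mcount[j] >= 1L))
    as.numeric(mcount[i] >= 2L || mcount[j] >= 2L)
  }, numeric(1))
  changed_keys <- c(annotation$broken_keys, annotation$formed_keys,
                    annotation$order_changed_keys)
  ka <- mol$map[mol$bonds[, 1]]; kb <- mol$map[mol$bonds[, 2]]
  key <- paste(pmin(ka, kb), pmax(ka, kb), sep = "-")
  is_changed <- as.numeric(ka > 0L & kb > 0L & key %in% changed_keys)
  cbind(onehot_rows(ord, 4L), rb, conj, is_changed)
}

#' Atom feature vector for one atom
#'
#' @param molecule a `mapped_molecule` belonging to the record the annotation
#'   was computed from
#' @param atom_index 1-based atom index
#' @param annotation the record's `change_annotation`
#' @param side `"reactant"` or `"product"`
#' @param reactant_index which reactant `molecule` is (reactant side only)
#' @return numeric vector of length `d_atom`
#' @export
atom_feature_vector <- function(molecule, atom_index, annotation,
                                side = c("reactant", "product"),
                                reactant_index = 1L) {
  side <- match.arg(side)
  if (atom_index < 1L || atom_index > n_atoms(molecule))
    rr_usage_error("atom index out of range")
  X <- featurize_molecule_atoms(molecule, annotation, side, reactant_index)
  X[atom_index, ]
}

#' Bond feature vector for one bond
#'
#' @param molecule a `mapped_molecule`
#' @param bond_index 1-based row of `molecule$bonds`
#' @param annotation the record's `change_annotation`
#' @return numeric vector of length `d_bond`
#' @export
bond_feature_vector <- function(molecule, bond_index, annotation) {
  if (bond_index < 1L || bond_index > nrow(molecule$bonds))
    rr_usage_error("bond index out of range")
  Fm <- featurize_molecule_bonds(molecule, annotation)
  Fm[bond_index, ]
}

#' Build the paired numeric graphs for a reaction record
#'
#' Multiple reactant molecules are merged into a single disconnected
#' reactant-side graph (no inter-fragment edges); the product forms the other
#' graph. Both share one feature schema. Molecules are taken in their
#' aromatized form so bond-order features agree with the change annotation.
#'
#' @param record a `reaction_record`
#' @param annotation its `change_annotation` (computed if missing)
#' @param radius neighborhood radius when `annotation` is computed here
#' @return a `featurized_reaction_graph`: `reactant` and `product`, each with
#'   `x` (nodes x d_atom), `edges` (bonds x 2), `ef` (bonds x d_bond), plus
#'   `schema` and `schema_hash`
#' @export
build_reaction_graphs <- function(record, annotation = NULL, radius = 1L) {
  if (!inherits(record, "reaction_record") || !record$scorable)
    rr_usage_error("build_reaction_graphs needs a scorable reaction_record")
  if (is.null(annotation)) annotation <- annotate_changes(record, radius)
  schema <- reaction_feature_schema()

  rmols <- annotation$normalized$reactants
  pmol <- annotation$normalized$product

  xs <- list(); es <- list(); fs <- list()
  offset <- 0L
  for (ri in seq_along(rmols)) {
    m <- rmols[[ri]]
    xs[[ri]] <- featurize_molecule_atoms(m, annotation, "reactant", ri, schema)
    if (nrow(m$bonds) > 0L) {
      es[[ri]] <- m$bonds + offset
      fs[[ri]] <- featurize_molecule_bonds(m, annotation, schema)
    }
    offset <- offset + n_atoms(m)
  }
  redges <- if (length(es) > 0L) do.call(rbind, es) else
    matrix(integer(0), ncol = 2)
  ref <- if (length(fs) > 0L) do.call(rbind, fs) else
    matrix(0, nrow = 0L, ncol = schema$d_bond)

  structure(list(
    reactant = list(x = do.call(rbind, xs), edges = redges, ef = ref),
    product = list(x = featurize_molecule_atoms(pmol, annotation, "product", 1L, schema),
                   edges = pmol$bonds,
                   ef = featurize_molecule_bonds(pmol, annotation, schema)),
    schema = schema,
    schema_hash = schema_hash(schema)
  ), class = "featurized_reaction_graph")
}

#' @export
print.featurized_reaction_graph <- function(x, ...) {
  cat(sprintf("<featurized_reaction_graph> reactants %d nodes / %d bonds, product %d nodes / %d bonds, d_atom=%d d_bond=%d\n",
              nrow(x$reactant$x), nrow(x$reactant$edges),
              nrow(x$product$x), nrow(x$product$edges),
              ncol(x$reactant$x), ncol(x$reactant$ef)))
  invisible(x)
}

#' Write a feature schema to JSON
#'
#' Dumped alongside serialized graph sets and model checkpoints so that
#' consumers can verify schema compatibility.
#'
#' @param path output path
#' @param schema schema to dump
#' @export
write_feature_schema <- function(path, schema = reaction_feature_schema()) {
  js <- jsonlite::toJSON(list(atom = schema$atom, bond = schema$bond,
                              vocab = schema$element_vocab,
                              hash = schema_hash(schema)),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(as.character(js), path)
  invisible(path)
}
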