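# Potential-reaction-change annotation derived from the atom map of a
# reaction record: broken/formed/order-changed bonds keyed by map-number
# pairs, reaction-center atoms, leaving-group atoms, and per-atom
# reacted-neighborhood counts.
#
# Both sides are passed through the conservative aromatic-perception pass
# before diffing so that kekule-structure flips of the same ring do not
# register as changes.

bond_map_table <- function(mols) {
  keys <- character(0); ords <- character(0)
  for (m in mols) {
    if (nrow(m$bonds) == 0L) next
    a <- m$map[m$bonds[, 1]]; b <- m$map[m$bonds[, 2]]
    keep <- a > 0L & b > 0L
    if (!any(keep)) next
    lo <- pmin(a[keep], b[keep]); hi <- pmax(a[keep], b[keep])
    k <- paste(lo, hi, sep = "-")
    new <- !(k %in% keys)
    keys <- c(keys, k[new]); ords <- c(ords, m$bond_order[keep][new])
  }
  stats::setNames(ords, keys)
}

key_to_pairs <- function(keys) {
  if (length(keys) == 0L) return(matrix(integer(0), ncol = 2,
                                        dimnames = list(NULL, c("a", "b"))))
  sp <- do.call(rbind, strsplit(keys, "-", fixed = TRUE))
  m <- matrix(as.integer(sp), ncol = 2, dimnames = list(NULL, c("a", "b")))
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

#' Annotate the potential reaction changes of a reaction record
#'
#' Diffs the map-number-keyed bond sets of the two sides to find broken bonds
#' (present in the reactants only), formed bonds (product only) and
#' order-changed bonds (both sides, different order after aromatization).
#' Reaction-center atoms are the map numbers incident to any of these.
#' Leaving-group atoms are reactant heavy atoms whose map number is 0 or
#' absent from the product. Reacted-neighborhood counts are breadth-first
#' counts of center atoms within `radius` bonds of each atom, excluding the
#' atom itself.
#'
#' @param record a `reaction_record`
#' @param radius positive integer neighborhood radius (default 1)
#' @return a `change_annotation` with fields `broken`, `formed`,
#'   `order_changed` (2-column map-pair matrices), `center_maps`,
#'   `leaving_atoms` (matrix of reactant index, atom index), per-side
#'   `neighborhood_counts` and `leaving_size`, and the changed-bond key sets
#' @export
annotate_changes <- function(record, radius = 1L) {
  if (!inherits(record, "reaction_record") || !record$scorable)
    rr_usage_error("annotate_changes needs a scorable reaction_record")
  radius <- as.integer(radius)
  if (is.na(radius) || radius < 1L) rr_usage_error("radius must be a positive integer")

  reactants <- lapply(record$reactants, aromatize_rings)
  product <- aromatize_rings(record$product)

  rb <- bond_map_table(reactants)
  pb <- bond_map_table(list(product))

  broken_keys <- setdiff(names(rb), names(pb))
  formed_keys <- setdiff(names(pb), names(rb))
  both <- intersect(names(rb), names(pb))
  order_keys <- both[rb[both] != pb[both]]

  changed_keys <- c(broken_keys, formed_keys, order_keys)
  center_maps <- sort(unique(as.integer(unlist(
    strsplit(changed_keys, "-", fixed = TRUE)))))

  pmaps <- product$map[product$map > 0L]
  leaving <- do.call(rbind, lapply(seq_along(reactants), function(ri) {
    m <- reactants[[ri]]
    idx <- which(m$map == 0L | !(m$map %in% pmaps))
    if (length(idx) == 0L) return(NULL)
    cbind(reactant = ri, atom = idx)
  }))
  if (is.null(leaving))
    leaving <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("reactant", "atom")))

  nb_counts <- function(mol) {
    centers <- which(mol$map %in% center_maps)
    n <- n_atoms(mol)
    cnt <- integer(n)
    if (length(centers) == 0L || n == 0L) return(cnt)
    nb <- neighbor_list(mol)
    for (i in seq_len(n)) {
      d <- bfs_within(nb, i, radius)
      d[i] <- Inf  # exclude the atom itself
      cnt[i] <- sum(is.finite(d[centers]))
    }
    cnt
  }

  leave_sizes <- lapply(seq_along(reactants), function(ri) {
    m <- reactants[[ri]]
    sizes <- integer(n_atoms(m))
    sel <- leaving[leaving[, "reactant"] == ri, "atom"]
    if (length(sel) > 0L) {
      comp <- induced_components(m, sel)
      tab <- table(comp[sel])
      sizes[sel] <- as.integer(tab[as.character(comp[sel])])
    }
    sizes
  })

  structure(list(
    broken = key_to_pairs(broken_keys),
    formed = key_to_pairs(formed_keys),
    order_changed = key_to_pairs(order_keys),
    broken_keys = broken_keys, formed_keys = formed_keys,
    order_changed_keys = order_keys,
    center_maps = center_maps,
    leaving_atoms = leaving,
    neighborhood_counts = list(
      reactants = lapply(reactants, nb_counts),
      product = nb_counts(product)),
    leaving_size = list(
      reactants = leave_sizes,
      product = integer(n_atoms(product))),
    radius = radius,
    normalized = list(reactants = reactants, product = product)
  ), class = "change_annotation")
}

#' @export
print.change_annotation <- function(x, ...) {
  cat(sprintf(paste0("<change_annotation> broken %d, formed %d, order-changed %d; ",
                     "center atoms %d, leaving atoms %d (radius %d)\n"),
              nrow(x$broken), nrow(x$formed), nrow(x$order_changed),
              length(x$center_maps), nrow(x$leaving_atoms), x$radius))
  invisible(x)
}

#' Number of changed bonds of an annotated reaction
#'
#' Broken plus newly constructed plus order-changed bonds; an order change on
#' one atom pair counts once.
#'
#' @param annotation a `change_annotation`
#' @return nonnegative integer
#' @export
changed_bond_count <- function(annotation) {
  nrow(annotation$broken) + nrow(annotation$formed) + nrow(annotation$order_changed)
}

#' Mean changed-bond count over a dataset
#'
#' The per-group arithmetic mean of [changed_bond_count()]; the `"all"` group
#' (whole dataset) is always included. This is the dataset-level statistic
#' used to relate re-ranking gains to the degree of structural change of a
#' reaction class.
#'
#' @param records list of `reaction_record`
#' @param group_by optional character/factor vector of per-record labels
#' @param radius neighborhood radius forwarded to [annotate_changes()]
#' @return data.frame with columns `group`, `mean_changed_bonds`, `n`
#' @export
mean_changed_bonds <- function(records, group_by = NULL, radius = 1L) {
  if (length(records) == 0L) rr_usage_error("empty dataset")
  counts <- vapply(records, function(r) changed_bond_count(annotate_changes(r, radius)),
                   numeric(1))
  out <- data.frame(group = "all", mean_changed_bonds = mean(counts),
                    n = length(counts), stringsAsFactors = FALSE)
  if (!is.null(group_by)) {
    if (length(group_by) != length(records))
      rr_usage_error("group_by must match the dataset length")
    agg <- tapply(counts, as.character(group_by), mean)
    ns <- tapply(counts, as.character(group_by), length)
    out <- rbind(out, data.frame(group = names(agg),
                                 mean_changed_bonds = as.numeric(agg),
                                 n = as.integer(ns), stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Annotate a plain-text reaction file into JSON Lines
#'
#' Reads one mapped reaction SMILES per line and writes one JSON object per
#' reaction with the annotation fields (bond sets as map-number pairs,
#' center atoms, leaving atoms, neighborhood counts, changed-bond count).
#'
#' @param infile plain-text reaction file (`#` comments allowed)
#' @param outfile output JSON-Lines path
#' @param radius neighborhood radius
#' @export
annotate_reaction_file <- function(infile, outfile, radius = 1L) {
  records <- read_reaction_file(infile)
  con <- file(outfile, open = "wt")
  on.exit(close(con))
  for (r in records) {
    a <- annotate_changes(r, radius)
    obj <- list(
      reaction = r$source,
      broken_bonds = unname(apply(a$broken, 1, function(p) as.list(p))),
      formed_bonds = unname(apply(a$formed, 1, function(p) as.list(p))),
      order_changed_bonds = unname(apply(a$order_changed, 1, function(p) as.list(p))),
      center_atoms = a$center_maps,
      leaving_atoms = unname(apply(a$leaving_atoms, 1, function(p) as.list(p))),
      changed_bond_count = changed_bond_count(a)
    )
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null"), con)
  }
  invisible(outfile)
}
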