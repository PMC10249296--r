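# Reaction-level I/O: atom-mapped reaction SMILES, canonical candidate keys,
# and the JSON-Lines prediction/label file format.

#' Parse an atom-mapped reaction SMILES into a reaction record
#'
#' The string must contain the reactants and the product separated by `>>`
#' (or a three-part `reactants>reagents>product` form, in which case the
#' reagent field is discarded: the ranking model only ever sees reactants and
#' product). Every nonzero atom-map number on the product must occur in
#' exactly one reactant; reactant-only map numbers mark leaving-group atoms
#' and are allowed.
#'
#' @param rxn_smiles reaction SMILES, e.g. `"[CH3:1][OH:2]>>..."`
#' @param original_rank positive integer provenance rank (default 1)
#' @param upstream_score optional confidence from the upstream model
#' @param is_recorded logical or `NA` (unknown)
#' @return a `reaction_record`: product, list of reactant molecules, provenance
#' @export
parse_mapped_reaction <- function(rxn_smiles, original_rank = 1L,
                                  upstream_score = NA_real_, is_recorded = NA) {
  if (!is.character(rxn_smiles) || length(rxn_smiles) != 1L)
    rr_parse_error("reaction SMILES must be a single string")
  parts <- strsplit(rxn_smiles, ">", fixed = TRUE)[[1]]
  # "a>>b" splits to c("a","","b"); "a>r>b" to c("a","r","b")
  if (length(parts) != 3L)
    rr_parse_error(sprintf("expected 'reactants>>product' with one '>>': '%s'", rxn_smiles))
  react_smiles <- parts[1]; prod_smiles <- parts[3]
  if (!nzchar(react_smiles) || !nzchar(prod_smiles))
    rr_parse_error("empty reactant or product field")

  reactants <- lapply(split_fragments(react_smiles), parse_smiles)
  product <- parse_smiles(prod_smiles)
  make_reaction_record(product, reactants, original_rank, upstream_score,
                       is_recorded, source = rxn_smiles)
}

make_reaction_record <- function(product, reactants, original_rank = 1L,
                                 upstream_score = NA_real_, is_recorded = NA,
                                 source = NA_character_) {
  if (length(reactants) == 0L) rr_parse_error("reaction needs at least one reactant")
  pmaps <- product$map[product$map > 0L]
  if (length(pmaps) == 0L)
    rr_mapping_error("product has no mapped atoms")
  rmaps <- unlist(lapply(reactants, function(m) m$map[m$map > 0L]))
  missing <- setdiff(pmaps, rmaps)
  if (length(missing) > 0L)
    rr_mapping_error(sprintf(
      "product map number(s) %s absent from reactants",
      paste(missing, collapse = ", ")))
  counts <- table(rmaps)[as.character(pmaps)]
  if (any(counts > 1L))
    rr_mapping_error("a product map number occurs in more than one reactant atom")
  structure(list(
    product = product, reactants = reactants,
    original_rank = as.integer(original_rank),
    upstream_score = as.numeric(upstream_score),
    is_recorded = is_recorded,
    scorable = TRUE,
    source = source
  ), class = "reaction_record")
}

# Sentinel record for candidates whose SMILES failed to parse upstream: kept
# in the list (re-ranking must stay a permutation of the original list) and
# scored at the documented minimum (-Inf) at inference time.
unscorable_record <- function(raw, original_rank, upstream_score = NA_real_) {
  structure(list(
    product = NULL, reactants = NULL,
    original_rank = as.integer(original_rank),
    upstream_score = as.numeric(upstream_score),
    is_recorded = FALSE, scorable = FALSE, source = raw
  ), class = "reaction_record")
}

#' @export
print.reaction_record <- function(x, ...) {
  if (!x$scorable) {
    cat(sprintf("<reaction_record> UNSCORABLE (rank %d): %s\n", x$original_rank, x$source))
  } else {
    cat(sprintf("<reaction_record> rank %d, %d reactant(s), product %d atoms%s\n",
                x$original_rank, length(x$reactants), n_atoms(x$product),
                if (isTRUE(x$is_recorded)) ", recorded" else ""))
  }
  invisible(x)
}

reaction_to_smiles <- function(record, include_maps = TRUE) {
  paste0(
    paste(vapply(record$reactants, mol_to_smiles, character(1),
                 include_maps = include_maps), collapse = "."),
    ">>", mol_to_smiles(record$product, include_maps = include_maps))
}

# ---- canonical candidate keys -------------------------------------------

# Canonicalize a vector of single-fragment SMILES through OpenBabel. One
# batched call on the happy path; OpenBabel aborts a batch at the first
# invalid molecule, so on a line-count mismatch we retry fragment by fragment
# and mark failures NA.
ob_canonical <- function(frags) {
  if (length(frags) == 0L) return(character(0))
  parse_out <- function(out, expected) {
    lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
    lines <- trimws(sub("\t.*$", "", lines))
    lines <- lines[nzchar(lines)]
    if (length(lines) == expected) lines else NULL
  }
  out <- tryCatch(suppressWarnings(
    ChemmineOB::convertFormat("SMI", "CAN",
                              paste0(paste(frags, collapse = "\n"), "\n"))),
    error = function(e) "")
  res <- parse_out(out, length(frags))
  if (!is.null(res)) return(res)
  vapply(frags, function(f) {
    out1 <- tryCatch(suppressWarnings(
      ChemmineOB::convertFormat("SMI", "CAN", paste0(f, "\n"))),
      error = function(e) "")
    r <- parse_out(out1, 1L)
    if (is.null(r)) NA_character_ else r
  }, character(1), USE.NAMES = FALSE)
}

# Canonical keys for a character vector of (multi-fragment) SMILES: maps
# stripped, each fragment canonicalized, fragments sorted lexicographically
# and joined with ".". NA for unparseable entries.
canonical_keys <- function(smiles_vec) {
  if (length(smiles_vec) == 0L) return(character(0))
  frags <- strsplit(strip_atom_maps(smiles_vec), ".", fixed = TRUE)
  lens <- lengths(frags)
  flat <- unlist(frags, use.names = FALSE)
  can <- rep(NA_character_, length(flat))
  ok <- !is.na(flat) & nzchar(flat)
  if (any(ok)) {
    uniq <- unique(flat[ok])
    uc <- ob_canonical(uniq)
    can[ok] <- uc[match(flat[ok], uniq)]
  }
  idx <- rep(seq_along(smiles_vec), lens)
  vapply(seq_along(smiles_vec), function(i) {
    k <- can[idx == i]
    if (length(k) == 0L || anyNA(k)) return(NA_character_)
    paste(sort(k), collapse = ".")
  }, character(1))
}

#' Canonical identity key for a candidate reactant set
#'
#' Atom-map numbers are stripped, each fragment is canonicalized (OpenBabel
#' canonical SMILES, which also harmonizes kekule vs aromatic forms), and the
#' fragments are sorted and joined with `"."`. Equal multisets of molecules
#' yield equal keys regardless of fragment order or atom numbering, which is
#' what makes recorded-match testing by string identity sound.
#'
#' @param reactants a list of `mapped_molecule`s, a `reaction_record`, or a
#'   SMILES string of dot-joined fragments
#' @return a single character key (`NA` if any fragment fails to parse)
#' @export
canonical_candidate_key <- function(reactants) {
  smi <- if (inherits(reactants, "reaction_record")) {
    if (!reactants$scorable) return(NA_character_)
    paste(vapply(reactants$reactants, mol_to_smiles, character(1),
                 include_maps = FALSE), collapse = ".")
  } else if (is.character(reactants)) {
    reactants
  } else {
    paste(vapply(reactants, mol_to_smiles, character(1),
                 include_maps = FALSE), collapse = ".")
  }
  canonical_keys(smi)
}

# ---- prediction lists ---------------------------------------------------

new_prediction_list <- function(product_smiles, candidates, recorded_key = NA_character_) {
  ranks <- vapply(candidates, function(r) r$original_rank, integer(1))
  if (!identical(sort(ranks), seq_along(candidates)))
    rr_format_error(sprintf(
      "candidate ranks must be 1..n without gaps (got %s)",
      paste(sort(ranks), collapse = ",")))
  candidates <- candidates[order(ranks)]
  rec <- vapply(candidates, function(r) isTRUE(r$is_recorded), logical(1))
  if (sum(rec) > 1L)
    rr_format_error("more than one candidate marked as recorded")
  structure(list(
    product_smiles = product_smiles,
    recorded_key = recorded_key,
    candidates = candidates
  ), class = "prediction_list")
}

#' @export
print.prediction_list <- function(x, ...) {
  cat(sprintf("<prediction_list> %s: %d candidates, recorded at original rank %s\n",
              x$product_smiles, length(x$candidates),
              {
                p <- recorded_original_rank(x)
                if (is.na(p)) "-" else p
              }))
  invisible(x)
}

recorded_original_rank <- function(plist) {
  rec <- vapply(plist$candidates, function(r) isTRUE(r$is_recorded), logical(1))
  if (!any(rec)) return(NA_integer_)
  plist$candidates[[which(rec)]]$original_rank
}

#' Read prediction lists from a JSON-Lines file
#'
#' One product per line:
#' `{"product": smiles, "recorded": smiles-or-null,
#'   "candidates": [{"rank": int, "reactants": smiles, "score": float-or-null}, ...]}`.
#' Ranks are 1-based and contiguous. When a `recorded` field is present,
#' `is_recorded` is assigned by canonical-key match against each candidate;
#' candidates whose SMILES fail to parse are retained as unscorable sentinels
#' so that re-ranking remains a permutation of the original list.
#'
#' @param path file path
#' @return list of `prediction_list`
#' @export
read_predictions <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    if (is.null(obj$product) || is.null(obj$candidates))
      rr_format_error("prediction line missing 'product' or 'candidates'")
    recorded_key <- if (!is.null(obj$recorded)) canonical_keys(obj$recorded) else NA_character_
    cands <- lapply(obj$candidates, function(cd) {
      rank <- as.integer(cd$rank)
      sc <- if (is.null(cd$score)) NA_real_ else as.numeric(cd$score)
      rec <- tryCatch({
        if (grepl(">>", cd$reactants, fixed = TRUE)) {
          parse_mapped_reaction(cd$reactants, original_rank = rank, upstream_score = sc)
        } else {
          reactants <- lapply(split_fragments(cd$reactants), parse_smiles)
          product <- parse_smiles(obj$product)
          if (sum(product$map > 0L) == 0L) {
            # unmapped input: identity maps on the product are not implied;
            # keep molecules, mark mapping as absent
            structure(list(product = product, reactants = reactants,
                           original_rank = rank, upstream_score = sc,
                           is_recorded = NA, scorable = TRUE,
                           source = cd$reactants), class = "reaction_record")
          } else {
            make_reaction_record(product, reactants, rank, sc, NA, cd$reactants)
          }
        }
      }, rr_error = function(e) unscorable_record(cd$reactants, rank, sc))
      if (!is.null(cd$rr_score)) rec$rr_score <- as.numeric(cd$rr_score)
      rec
    })
    if (!is.na(recorded_key)) {
      keys <- vapply(cands, function(r)
        if (r$scorable) canonical_candidate_key(r) else NA_character_, character(1))
      hits <- which(!is.na(keys) & keys == recorded_key)
      if (length(hits) > 1L)
        rr_format_error(sprintf("duplicate recorded candidate in list for %s", obj$product))
      for (i in seq_along(cands)) cands[[i]]$is_recorded <- FALSE
      if (length(hits) == 1L) cands[[hits]]$is_recorded <- TRUE
    }
    new_prediction_list(obj$product, cands, recorded_key)
  })
}

#' Write prediction lists to a JSON-Lines file
#'
#' Inverse of [read_predictions()]; candidate order and reactant strings are
#' preserved byte-for-byte for scorable candidates parsed from this package's
#' own serializer. An `rr_score` field is included when present.
#'
#' @param lists list of `prediction_list`
#' @param path output file path
#' @export
write_predictions <- function(lists, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (pl in lists) {
    cands <- lapply(pl$candidates, function(r) {
      # re-ranked lists are written under their new ranking (the re-ranked
      # order is the ranking a consumer evaluates); the provenance rank is
      # kept in original_rank
      out <- list(
        rank = if (!is.null(r$final_rank)) r$final_rank else r$original_rank,
        reactants = if (r$scorable)
          paste(vapply(r$reactants, mol_to_smiles, character(1)), collapse = ".")
        else r$source,
        score = if (is.na(r$upstream_score)) NULL else r$upstream_score
      )
      if (!is.null(r$final_rank)) out$original_rank <- r$original_rank
      if (!is.null(r$rr_score) && is.finite(r$rr_score)) out$rr_score <- r$rr_score
      out
    })
    rec_idx <- which(vapply(pl$candidates, function(r) isTRUE(r$is_recorded), logical(1)))
    recorded <- if (length(rec_idx) == 1L) {
      r <- pl$candidates[[rec_idx]]
      paste(vapply(r$reactants, mol_to_smiles, character(1),
                   include_maps = FALSE), collapse = ".")
    } else NULL
    obj <- list(product = pl$product_smiles, recorded = recorded, candidates = cands)
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null", digits = NA), con)
  }
  invisible(path)
}

#' Read one reaction SMILES per line (plain text, `#` comments allowed)
#' @param path file path
#' @return list of `reaction_record`
#' @export
read_reaction_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  lapply(lines, parse_mapped_reaction)
}
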