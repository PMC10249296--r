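# Atom-mapped SMILES <-> molecular graph.
#
# A `mapped_molecule` is the unit both encoder branches consume: a heavy-atom
# graph whose atoms optionally carry atom-map numbers (`[CH3:1]`). Hydrogens
# are implicit throughout; all counts in this package are over heavy atoms.
#
# The parser covers the SMILES subset produced by retrosynthesis toolchains:
# organic-subset atoms, bracket atoms with charge/H-count/map, ring closures
# (including %nn), branches, dots, bond symbols - = # : / \. Stereo markers
# are accepted and ignored (see Non-goals in the vignette).

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
AROMATIC_SUBSET <- c("b", "c", "n", "o", "p", "s")

# default valence lists used for implicit hydrogen counts
.valences <- list(
  B = 3L, C = 4L, N = c(3L, 5L), O = 2L, P = c(3L, 5L),
  S = c(2L, 4L, 6L), F = 1L, Cl = 1L, Br = 1L, I = 1L
)

.bond_value <- c(single = 1, double = 2, triple = 3, aromatic = 1.5)

new_mapped_molecule <- function(element, charge, hcount, aromatic, map,
                                bonds, bond_order, source_smiles = NA_character_) {
  structure(list(
    element = element, charge = as.integer(charge), hcount = as.integer(hcount),
    aromatic = aromatic, map = as.integer(map),
    bonds = bonds, bond_order = bond_order,
    source_smiles = source_smiles
  ), class = "mapped_molecule")
}

#' Number of heavy atoms of a molecule
#' @param mol a `mapped_molecule`
#' @return integer atom count
#' @export
n_atoms <- function(mol) length(mol$element)

#' @export
print.mapped_molecule <- function(x, ...) {
  cat(sprintf("<mapped_molecule> %d atoms, %d bonds, %d mapped\n",
              n_atoms(x), nrow(x$bonds), sum(x$map > 0L)))
  cat("  ", mol_to_smiles(x), "\n", sep = "")
  invisible(x)
}

#' Parse a (possibly atom-mapped) SMILES string into a molecular graph
#'
#' Supports the organic subset, bracket atoms with isotope (ignored), explicit
#' hydrogen counts, formal charges and atom-map numbers, ring-bond closures,
#' branches and multi-fragment strings joined by `.`. Chirality and
#' directional bond markers are dropped.
#'
#' @param smiles a single SMILES string
#' @return a `mapped_molecule`; disconnected fragments share one graph
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) || !nzchar(smiles))
    rr_parse_error("empty or non-string SMILES input")
  s <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(s)

  element <- character(); charge <- integer(); hcount <- integer()
  aromatic <- logical(); map <- integer()
  ba <- integer(); bb <- integer(); bsym <- character()

  prev <- NA_integer_
  stack <- integer(0)
  pending <- ""            # pending bond symbol before next atom / ring digit
  ring_open <- list()      # closure number -> list(atom, sym)

  add_atom <- function(el, ch, hc, ar, mp) {
    element[length(element) + 1L] <<- el
    charge[length(charge) + 1L] <<- ch
    hcount[length(hcount) + 1L] <<- hc
    aromatic[length(aromatic) + 1L] <<- ar
    map[length(map) + 1L] <<- mp
    idx <- length(element)
    if (!is.na(prev)) {
      ba[length(ba) + 1L] <<- prev; bb[length(bb) + 1L] <<- idx
      bsym[length(bsym) + 1L] <<- pending
    }
    pending <<- ""
    prev <<- idx
    idx
  }

  close_ring <- function(num) {
    key <- as.character(num)
    if (is.null(ring_open[[key]])) {
      if (is.na(prev)) rr_parse_error("ring-bond digit before any atom")
      ring_open[[key]] <<- list(atom = prev, sym = pending)
    } else {
      op <- ring_open[[key]]
      sym <- pending
      if (nzchar(op$sym) && nzchar(sym) && op$sym != sym)
        rr_parse_error(sprintf("conflicting bond symbols on ring closure %s", key))
      if (!nzchar(sym)) sym <- op$sym
      if (op$atom == prev) rr_parse_error("ring bond to self")
      ba[length(ba) + 1L] <<- op$atom; bb[length(bb) + 1L] <<- prev
      bsym[length(bsym) + 1L] <<- sym
      ring_open[[key]] <<- NULL
    }
    pending <<- ""
  }

  i <- 1L
  while (i <= n) {
    ch <- s[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && s[j] != "]") j <- j + 1L
      if (j > n) rr_parse_error("unterminated bracket atom")
      body <- paste0(s[(i + 1L):(j - 1L)], collapse = "")
      at <- parse_bracket_atom(body, smiles)
      add_atom(at$element, at$charge, at$hcount, at$aromatic, at$map)
      i <- j + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      if (nzchar(pending)) rr_parse_error("two consecutive bond symbols")
      pending <- if (ch %in% c("/", "\\")) "-" else ch
      i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) rr_parse_error("branch start before any atom")
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) rr_parse_error("unmatched ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == ".") {
      prev <- NA_integer_
      pending <- ""
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      close_ring(as.integer(ch))
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("[0-9]", s[i + 1L]) || !grepl("[0-9]", s[i + 2L]))
        rr_parse_error("'%' ring closure needs two digits")
      close_ring(as.integer(paste0(s[i + 1L], s[i + 2L])))
      i <- i + 3L
    } else {
      # organic subset atom, possibly two characters (Cl, Br)
      two <- if (i < n) paste0(ch, s[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(two, 0L, NA_integer_, FALSE, 0L)
        i <- i + 2L
      } else if (ch %in% ORGANIC_SUBSET) {
        add_atom(ch, 0L, NA_integer_, FALSE, 0L)
        i <- i + 1L
      } else if (ch %in% AROMATIC_SUBSET) {
        add_atom(toupper(ch), 0L, NA_integer_, TRUE, 0L)
        i <- i + 1L
      } else {
        rr_parse_error(sprintf("unexpected character '%s' in SMILES '%s'", ch, smiles))
      }
    }
  }
  if (length(ring_open) > 0L)
    rr_parse_error(sprintf("%d unmatched ring bond(s) in '%s'", length(ring_open), smiles))
  if (length(stack) > 0L) rr_parse_error(sprintf("unmatched '(' in '%s'", smiles))
  if (length(element) == 0L) rr_parse_error("SMILES contains no atoms")

  # resolve bond orders
  order <- character(length(ba))
  for (b in seq_along(ba)) {
    order[b] <- switch(bsym[b],
      "-" = "single", "=" = "double", "#" = "triple", ":" = "aromatic",
      if (aromatic[ba[b]] && aromatic[bb[b]]) "aromatic" else "single")
  }
  bonds <- cbind(a = pmin(ba, bb), b = pmax(ba, bb))
  if (anyDuplicated(paste(bonds[, 1], bonds[, 2])))
    rr_parse_error(sprintf("duplicate bond between one atom pair in '%s'", smiles))

  mp <- map[map > 0L]
  if (anyDuplicated(mp))
    rr_mapping_error(sprintf("duplicate atom-map number within one molecule: '%s'", smiles))

  mol <- new_mapped_molecule(element, charge, hcount, aromatic, map,
                             bonds, order, smiles)
  mol$hcount <- compute_hcounts(mol)
  mol
}

parse_bracket_atom <- function(body, full) {
  cs <- strsplit(body, "", fixed = TRUE)[[1]]
  i <- 1L; n <- length(cs)
  while (i <= n && grepl("[0-9]", cs[i])) i <- i + 1L  # isotope, ignored
  if (i > n) rr_parse_error(sprintf("bracket atom without element in '%s'", full))
  aromatic <- FALSE
  if (grepl("[A-Z]", cs[i])) {
    el <- cs[i]; i <- i + 1L
    if (i <= n && grepl("[a-z]", cs[i]) && cs[i] != "c" &&
        paste0(el, cs[i]) %in% c("Cl", "Br", "Si", "Se", "Sn", "Li", "Na", "Mg",
                                 "Al", "Ca", "Fe", "Cu", "Zn", "Pd", "Ag", "Pt")) {
      el <- paste0(el, cs[i]); i <- i + 1L
    }
  } else if (cs[i] %in% c(AROMATIC_SUBSET, "a")) {
    el <- toupper(cs[i]); aromatic <- TRUE; i <- i + 1L
    if (el == "S" && i <= n && cs[i] == "e") { el <- "Se"; i <- i + 1L }
  } else {
    rr_parse_error(sprintf("invalid element in bracket atom [%s]", body))
  }
  while (i <= n && cs[i] == "@") i <- i + 1L  # chirality, ignored
  hc <- 0L
  if (i <= n && cs[i] == "H") {
    i <- i + 1L; hc <- 1L
    d <- ""
    while (i <= n && grepl("[0-9]", cs[i])) { d <- paste0(d, cs[i]); i <- i + 1L }
    if (nzchar(d)) hc <- as.integer(d)
  }
  ch <- 0L
  if (i <= n && cs[i] %in% c("+", "-")) {
    sgn <- if (cs[i] == "+") 1L else -1L
    k <- 1L; i <- i + 1L
    while (i <= n && cs[i] == cs[i - 1L] && cs[i] %in% c("+", "-")) { k <- k + 1L; i <- i + 1L }
    d <- ""
    while (i <= n && grepl("[0-9]", cs[i])) { d <- paste0(d, cs[i]); i <- i + 1L }
    ch <- if (nzchar(d)) sgn * as.integer(d) else sgn * k
  }
  mp <- 0L
  if (i <= n && cs[i] == ":") {
    d <- ""
    i <- i + 1L
    while (i <= n && grepl("[0-9]", cs[i])) { d <- paste0(d, cs[i]); i <- i + 1L }
    if (!nzchar(d)) rr_parse_error(sprintf("':' without map number in [%s]", body))
    mp <- as.integer(d)
  }
  if (i <= n) rr_parse_error(sprintf("trailing characters in bracket atom [%s]", body))
  list(element = el, charge = ch, hcount = hc, aromatic = aromatic, map = mp)
}

# Bond-order sum seen by each atom (aromatic bonds count 1.5)
atom_bond_sums <- function(mol) {
  v <- numeric(n_atoms(mol))
  if (nrow(mol$bonds) > 0L) {
    w <- .bond_value[mol$bond_order]
    for (b in seq_len(nrow(mol$bonds))) {
      v[mol$bonds[b, 1]] <- v[mol$bonds[b, 1]] + w[b]
      v[mol$bonds[b, 2]] <- v[mol$bonds[b, 2]] + w[b]
    }
  }
  v
}

# Implicit H for organic-subset atoms parsed without brackets (hcount NA);
# bracket atoms keep their explicit count.
compute_hcounts <- function(mol) {
  hc <- mol$hcount
  todo <- which(is.na(hc))
  if (length(todo) == 0L) return(hc)
  sums <- atom_bond_sums(mol)
  for (i in todo) {
    vl <- .valences[[mol$element[i]]]
    if (is.null(vl)) { hc[i] <- 0L; next }
    need <- ceiling(sums[i])
    fit <- vl[vl >= need]
    hc[i] <- if (length(fit) == 0L) 0L else as.integer(fit[1] - need)
  }
  hc
}

default_hcount <- function(mol, i) {
  vl <- .valences[[mol$element[i]]]
  if (is.null(vl)) return(0L)
  need <- ceiling(atom_bond_sums(mol)[i])
  fit <- vl[vl >= need]
  if (length(fit) == 0L) 0L else as.integer(fit[1] - need)
}

neighbor_list <- function(mol) {
  nb <- vector("list", n_atoms(mol))
  if (nrow(mol$bonds) > 0L) {
    for (b in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds[b, 1]; j <- mol$bonds[b, 2]
      nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
    }
  }
  nb
}

#' Serialize a molecular graph to SMILES
#'
#' Deterministic depth-first writer; atoms are emitted in DFS order from the
#' first atom of each fragment, so serialize-parse-serialize is a fixed point.
#'
#' @param mol a `mapped_molecule`
#' @param include_maps write `:n` atom-map suffixes (default `TRUE`)
#' @return SMILES string, fragments joined by `.`
#' @export
mol_to_smiles <- function(mol, include_maps = TRUE) {
  na <- n_atoms(mol)
  if (na == 0L) return("")
  nb <- neighbor_list(mol)
  bond_idx <- new.env(parent = emptyenv())
  if (nrow(mol$bonds) > 0L)
    for (b in seq_len(nrow(mol$bonds)))
      assign(paste(mol$bonds[b, 1], mol$bonds[b, 2]), b, envir = bond_idx)
  get_bond <- function(i, j) get(paste(min(i, j), max(i, j)), envir = bond_idx)

  hsums <- atom_bond_sums(mol)
  sums_need <- ceiling(hsums)
  implicit_default <- vapply(seq_len(na), function(i) {
    vl <- .valences[[mol$element[i]]]
    if (is.null(vl)) return(0L)
    fit <- vl[vl >= sums_need[i]]
    if (length(fit) == 0L) 0L else as.integer(fit[1] - sums_need[i])
  }, integer(1))

  atom_token <- function(i) {
    el <- mol$element[i]
    sym <- if (mol$aromatic[i]) tolower(el) else el
    plain <- el %in% ORGANIC_SUBSET && mol$charge[i] == 0L &&
      (!include_maps || mol$map[i] == 0L) && mol$hcount[i] == implicit_default[i] &&
      !(mol$aromatic[i] && !tolower(el) %in% AROMATIC_SUBSET)
    if (plain) return(sym)
    h <- mol$hcount[i]
    hpart <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
    cpart <- if (mol$charge[i] == 0L) "" else {
      sgn <- if (mol$charge[i] > 0L) "+" else "-"
      k <- abs(mol$charge[i])
      if (k == 1L) sgn else paste0(sgn, k)
    }
    mpart <- if (include_maps && mol$map[i] > 0L) paste0(":", mol$map[i]) else ""
    paste0("[", sym, hpart, cpart, mpart, "]")
  }

  bond_token <- function(b) {
    o <- mol$bond_order[b]
    a1 <- mol$bonds[b, 1]; a2 <- mol$bonds[b, 2]
    both_ar <- mol$aromatic[a1] && mol$aromatic[a2]
    switch(o,
      single = if (both_ar) "-" else "",
      double = "=", triple = "#",
      aromatic = if (both_ar) "" else ":")
  }

  visited <- logical(na)
  used <- logical(nrow(mol$bonds))
  out_frags <- character(0)
  ring_num <- 0L
  ring_digit <- function() {
    ring_num <<- ring_num + 1L
    if (ring_num < 10L) as.character(ring_num) else paste0("%", ring_num)
  }

  for (root in seq_len(na)) {
    if (visited[root]) next
    # classify edges via DFS: tree edges and ring (back) edges
    ring_at <- vector("list", na)  # atom -> list of (digit, bond symbol)
    order_children <- vector("list", na)
    stk <- list(list(atom = root, parent = NA_integer_))
    visited[root] <- TRUE
    dfs_stack <- c(root)
    parent <- rep(NA_integer_, na)
    # iterative DFS to mark tree structure
    st <- c(root)
    while (length(st) > 0L) {
      u <- st[length(st)]
      adv <- FALSE
      for (v in nb[[u]]) {
        b <- get_bond(u, v)
        if (used[b]) next
        if (!visited[v]) {
          visited[v] <- TRUE; used[b] <- TRUE; parent[v] <- u
          order_children[[u]] <- c(order_children[[u]], v)
          st <- c(st, v); adv <- TRUE
          break
        } else {
          used[b] <- TRUE  # ring closure
          d <- ring_digit()
          bt <- bond_token(b)
          ring_at[[u]] <- c(ring_at[[u]], list(list(d = d, s = bt)))
          ring_at[[v]] <- c(ring_at[[v]], list(list(d = d, s = bt)))
        }
      }
      if (!adv) st <- st[-length(st)]
    }
    emit <- function(u) {
      tok <- atom_token(u)
      for (r in ring_at[[u]]) tok <- paste0(tok, r$s, r$d)
      kids <- order_children[[u]]
      if (length(kids) > 0L) {
        parts <- vapply(kids, function(v) {
          paste0(bond_token(get_bond(u, v)), emit(v))
        }, character(1))
        if (length(parts) > 1L)
          tok <- paste0(tok, paste0("(", parts[-length(parts)], ")", collapse = ""))
        tok <- paste0(tok, parts[length(parts)])
      }
      tok
    }
    out_frags <- c(out_frags, emit(root))
  }
  paste(out_frags, collapse = ".")
}

# Split a multi-fragment SMILES into one string per fragment (top-level dots;
# dots cannot occur inside brackets).
split_fragments <- function(smiles) {
  strsplit(smiles, ".", fixed = TRUE)[[1]]
}

# Strip atom-map numbers from a SMILES string without parsing it fully:
# remove ":<digits>" occurring immediately before "]".
strip_atom_maps <- function(smiles) {
  gsub(":[0-9]+\\]", "]", smiles)
}

# --- small graph utilities reused by several modules ---------------------

# heavy-atom degree vector
atom_degrees <- function(mol) {
  d <- integer(n_atoms(mol))
  if (nrow(mol$bonds) > 0L) {
    t1 <- tabulate(mol$bonds[, 1], nbins = n_atoms(mol))
    t2 <- tabulate(mol$bonds[, 2], nbins = n_atoms(mol))
    d <- t1 + t2
  }
  d
}

# logical per-bond: bond participates in a cycle (not a bridge)
ring_bonds <- function(mol) {
  m <- nrow(mol$bonds)
  if (m == 0L) return(logical(0))
  g <- igraph::graph_from_edgelist(mol$bonds[, 1:2, drop = FALSE], directed = FALSE)
  br <- igraph::bridges(g)
  res <- rep(TRUE, m)
  res[as.integer(br)] <- FALSE
  res
}

# BFS distances from a set of source atoms, capped at `radius`
bfs_within <- function(nb, sources, radius) {
  n <- length(nb)
  dist <- rep(Inf, n)
  dist[sources] <- 0
  frontier <- sources
  d <- 0
  while (length(frontier) > 0L && d < radius) {
    d <- d + 1
    nxt <- integer(0)
    for (u in frontier) for (v in nb[[u]]) if (dist[v] > d) { dist[v] <- d; nxt <- c(nxt, v) }
    frontier <- unique(nxt)
  }
  dist
}

# connected components over an induced atom subset; returns per-atom component
# id (NA outside the subset)
induced_components <- function(mol, subset) {
  comp <- rep(NA_integer_, n_atoms(mol))
  if (length(subset) == 0L) return(comp)
  inset <- logical(n_atoms(mol)); inset[subset] <- TRUE
  nb <- neighbor_list(mol)
  cid <- 0L
  for (s in subset) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    q <- s; comp[s] <- cid
    while (length(q) > 0L) {
      u <- q[1]; q <- q[-1]
      for (v in nb[[u]]) if (inset[v] && is.na(comp[v])) { comp[v] <- cid; q <- c(q, v) }
    }
  }
  comp
}

# Conservative aromatic perception used to harmonize kekule vs aromatic input
# before bond diffing: marks 6-rings with perfectly alternating single/double
# bonds, and 5-rings with two double bonds plus one saturated N/O/S, as
# aromatic. Already-aromatic input is left untouched.
aromatize_rings <- function(mol) {
  m <- nrow(mol$bonds)
  if (m == 0L) return(mol)
  rb <- ring_bonds(mol)
  if (!any(rb)) return(mol)
  g <- igraph::graph_from_edgelist(mol$bonds[, 1:2, drop = FALSE], directed = FALSE)
  nb <- neighbor_list(mol)
  bond_id <- function(i, j) which((mol$bonds[, 1] == min(i, j)) & (mol$bonds[, 2] == max(i, j)))

  # candidate rings: fundamental cycles of length 5 or 6
  cyc <- fundamental_cycles(mol)
  for (ring in cyc) {
    len <- length(ring)
    if (!len %in% c(5L, 6L)) next
    ring_b <- integer(len)
    for (t in seq_len(len)) {
      i <- ring[t]; j <- ring[if (t == len) 1L else t + 1L]
      b <- bond_id(i, j)
      if (length(b) != 1L) { ring_b <- NULL; break }
      ring_b[t] <- b
    }
    if (is.null(ring_b)) next
    ord <- mol$bond_order[ring_b]
    if (all(ord == "aromatic")) next
    if (any(!ord %in% c("single", "double"))) next
    nd <- sum(ord == "double")
    ok <- FALSE
    if (len == 6L && nd == 3L) {
      # alternation: no two adjacent ring bonds share an order
      ok <- all(ord != c(ord[-1], ord[1]))
    } else if (len == 5L && nd == 2L) {
      # pyrrole/furan/thiophene pattern: the atom with two ring single bonds
      # must be N, O or S
      sat <- ring[vapply(seq_len(len), function(t) {
        b1 <- ring_b[if (t == 1L) len else t - 1L]; b2 <- ring_b[t]
        ord1 <- mol$bond_order[b1]; ord2 <- mol$bond_order[b2]
        ord1 == "single" && ord2 == "single"
      }, logical(1))]
      ok <- length(sat) == 1L && mol$element[sat] %in% c("N", "O", "S")
    }
    if (ok) {
      mol$bond_order[ring_b] <- "aromatic"
      mol$aromatic[ring] <- TRUE
    }
  }
  mol
}

# fundamental cycle basis from a DFS spanning forest; each cycle returned as
# an ordered atom vector
fundamental_cycles <- function(mol) {
  na <- n_atoms(mol)
  nb <- neighbor_list(mol)
  parent <- rep(NA_integer_, na)
  depth <- rep(NA_integer_, na)
  visited <- logical(na)
  cycles <- list()
  seen_edge <- new.env(parent = emptyenv())
  ekey <- function(i, j) paste(min(i, j), max(i, j))
  for (root in seq_len(na)) {
    if (visited[root]) next
    visited[root] <- TRUE; depth[root] <- 0L
    st <- c(root)
    while (length(st) > 0L) {
      u <- st[length(st)]
      adv <- FALSE
      for (v in nb[[u]]) {
        k <- ekey(u, v)
        if (!is.null(seen_edge[[k]])) next
        if (!visited[v]) {
          seen_edge[[k]] <- TRUE
          visited[v] <- TRUE; parent[v] <- u; depth[v] <- depth[u] + 1L
          st <- c(st, v); adv <- TRUE
          break
        } else {
          seen_edge[[k]] <- TRUE
          # back edge u-v: cycle = path u..v through parents
          path_u <- u; path_v <- v
          pu <- u; pv <- v
          while (depth[pu] > depth[pv]) { pu <- parent[pu]; path_u <- c(path_u, pu) }
          while (depth[pv] > depth[pu]) { pv <- parent[pv]; path_v <- c(path_v, pv) }
          while (pu != pv) {
            pu <- parent[pu]; path_u <- c(path_u, pu)
            pv <- parent[pv]; path_v <- c(path_v, pv)
          }
          cyc <- c(path_u, rev(path_v[-length(path_v)]))
          cycles[[length(cycles) + 1L]] <- cyc
        }
      }
      if (!adv) st <- st[-length(st)]
    }
  }
  cycles
}
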