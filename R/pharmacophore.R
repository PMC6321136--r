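# Pharmacophore module: potential pharmacophore points (PPPs), 3-point
# triplet enumeration with distance binning, canonical triplet keys, and
# modal (multi-conformer union) fingerprints.

# Type codes in canonical order. The ordering is part of the key
# canonicalization contract and must not change between versions.
PPP_TYPES <- c(donor = "D", acceptor = "A", positive = "P",
               negative = "N", aromatic = "R", lipophilic = "L")

#' Default potential-pharmacophore-point rule table
#'
#' Conventional feature definitions over element, connectivity, formal
#' charge and ring perception:
#' * donor: N or O carrying at least one hydrogen (explicit or implicit);
#' * acceptor: any O; N with a free lone pair (amide and positively
#'   charged/quaternary nitrogens excluded);
#' * positive: formally positive atoms; aliphatic amine N; the sp2 N of
#'   amidine/guanidine C=N groups;
#' * negative: formally negative atoms; the ionizable O of carboxylic,
#'   sulfonic and phosphonic acid groups;
#' * aromatic: one point per aromatic ring, placed at the ring centroid;
#' * lipophilic: uncharged carbon with no N/O/S or charged neighbour.
#'
#' Each flag can be toggled off to edit the table; the structure is
#' serialized verbatim into run configs and manifests.
#'
#' @return A list of rule switches with class `ligfish_ppp_rules`.
#' @export
default_ppp_rules <- function() {
  structure(list(
    schema_version = 1L,
    types = names(PPP_TYPES),
    exclude_amide_n_acceptor = TRUE,
    amine_positive = TRUE,
    amidine_positive = TRUE,
    acid_negative = TRUE
  ), class = "ligfish_ppp_rules")
}

#' Distance-binning specification for triplet edges
#'
#' Edges are binned into half-open intervals `[i*width, (i+1)*width)`;
#' any triplet with an edge at or beyond `max_distance` is discarded.
#' Defaults (1 Angstrom bins on \[0, 20)) give a bounded key space at the
#' granularity customary for pharmacophore triplet fingerprints.
#'
#' @param width Bin width in Angstroms (> 0).
#' @param max_distance Upper distance cutoff in Angstroms (> width).
#' @return A list with class `ligfish_binning`.
#' @export
distance_binning <- function(width = 1.0, max_distance = 20.0) {
  stopifnot(width > 0, max_distance > width)
  structure(list(schema_version = 1L, width = width, max_distance = max_distance),
            class = "ligfish_binning")
}

STD_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
                 Cl = 1, Br = 1, I = 1)
MAX_VALENCE <- c(B = 3, C = 4, N = 4, O = 3, F = 1, Si = 4, P = 5, S = 6,
                 Cl = 1, Br = 1, I = 1)

# Perception context: everything the rule predicates look at.
#' @noRd
perceive <- function(conf) {
  at <- conf$atoms
  bd <- conf$bonds
  n <- nrow(at)
  nbrs <- rep(list(integer()), n)
  bord <- rep(list(numeric()), n)
  if (nrow(bd)) {
    for (k in seq_len(nrow(bd))) {
      i <- bd$a1[k]; j <- bd$a2[k]; o <- bd$order[k]
      nbrs[[i]] <- c(nbrs[[i]], j); bord[[i]] <- c(bord[[i]], o)
      nbrs[[j]] <- c(nbrs[[j]], i); bord[[j]] <- c(bord[[j]], o)
    }
  }
  is_h <- at$element == "H"
  # bond-order sum with aromatic (order 4) counted as 1.5
  osum <- vapply(bord, function(o) sum(ifelse(o == 4, 1.5, o)), numeric(1))
  stdv <- unname(STD_VALENCE[at$element])
  maxv <- unname(MAX_VALENCE[at$element])
  eff <- stdv + ifelse(at$element %in% c("N", "P", "O", "S"), at$charge, 0)
  bad <- which(!is_h & !is.na(maxv) & osum > maxv + at$charge)
  if (length(bad))
    stop_ligfish(sprintf("valence/bond inconsistency at atom %d of compound '%s'",
                         bad[1], conf$compound_id), "ligfish_parse_error")
  n_exp_h <- vapply(seq_len(n), function(i) sum(is_h[nbrs[[i]]]), numeric(1))
  n_imp_h <- ifelse(is.na(stdv), 0, pmax(0, eff - osum))
  list(
    atoms = at, bonds = bd, nbrs = nbrs, bord = bord, is_h = is_h,
    h_count = n_exp_h + n_imp_h,
    rings = find_rings(n, bd, max_size = 8L)
  )
}

# Small-ring perception: for every bond, the shortest cycle through it
# (BFS in the graph minus that bond). Adequate for feature placement; not
# a full SSSR implementation.
#' @noRd
find_rings <- function(n, bonds, max_size = 8L) {
  if (nrow(bonds) == 0L || n < 3L) return(list())
  adj <- rep(list(integer()), n)
  for (k in seq_len(nrow(bonds))) {
    adj[[bonds$a1[k]]] <- c(adj[[bonds$a1[k]]], bonds$a2[k])
    adj[[bonds$a2[k]]] <- c(adj[[bonds$a2[k]]], bonds$a1[k])
  }
  rings <- list()
  seen <- character()
  for (k in seq_len(nrow(bonds))) {
    s <- bonds$a1[k]; t <- bonds$a2[k]
    # BFS from s to t avoiding the direct edge
    prev <- rep(NA_integer_, n)
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    q <- s
    while (length(q) && is.na(dist[t])) {
      v <- q[1L]; q <- q[-1L]
      for (w in adj[[v]]) {
        if ((v == s && w == t) || (v == t && w == s)) next
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L; prev[w] <- v; q <- c(q, w)
        }
      }
    }
    if (is.na(dist[t]) || dist[t] + 1L > max_size) next
    path <- t
    while (path[1L] != s) path <- c(prev[path[1L]], path)
    key <- paste(sort(path), collapse = ",")
    if (!(key %in% seen)) { seen <- c(seen, key); rings[[length(rings) + 1L]] <- path }
  }
  rings
}

#' @noRd
ring_is_aromatic <- function(ring, ctx) {
  at <- ctx$atoms
  if (!all(at$element[ring] %in% c("C", "N", "O", "S"))) return(FALSE)
  if (!(length(ring) %in% c(5L, 6L))) return(FALSE)
  in_ring <- function(i, j) {
    k <- which((ctx$bonds$a1 == i & ctx$bonds$a2 == j) |
               (ctx$bonds$a1 == j & ctx$bonds$a2 == i))
    if (length(k)) ctx$bonds$order[k[1L]] else NA_integer_
  }
  edges <- cbind(ring, c(ring[-1L], ring[1L]))
  orders <- apply(edges, 1L, function(e) in_ring(e[1L], e[2L]))
  if (anyNA(orders)) return(FALSE)
  if (all(orders == 4L)) return(TRUE)               # explicit aromatic bonds
  sum(orders == 2L) == length(ring) %/% 2L          # alternating Kekule form
}

#' Assign potential pharmacophore points to a conformer
#'
#' Converts heavy atoms (and aromatic-ring centroids) of a 3D conformer
#' into typed feature points. An atom may yield more than one point (for
#' example a protonated amine N is both a donor and a positive centre);
#' hydrogens never yield points.
#'
#' @param conf A [conformer()] object.
#' @param rules A rule table from [default_ppp_rules()].
#' @return Data frame with columns `type` (one of donor, acceptor,
#'   positive, negative, aromatic, lipophilic), `x`, `y`, `z`, and list
#'   column `source_atoms` (1-based atom indices).
#' @export
assign_ppps <- function(conf, rules = default_ppp_rules()) {
  stopifnot(inherits(conf, "ligfish_conformer"))
  at <- conf$atoms
  heavy <- which(at$element != "H")
  empty <- data.frame(type = character(), x = numeric(), y = numeric(),
                      z = numeric())
  empty$source_atoms <- list()
  if (length(heavy) == 0L) return(empty)
  ctx <- perceive(conf)

  res_type <- character(); res_atom <- list(); res_xyz <- NULL
  add <- function(type, atoms_idx, xyz) {
    res_type <<- c(res_type, type)
    res_atom[[length(res_atom) + 1L]] <<- atoms_idx
    res_xyz <<- rbind(res_xyz, xyz)
  }
  elem <- at$element
  chg <- at$charge
  hvy_nbrs <- function(i) ctx$nbrs[[i]][!ctx$is_h[ctx$nbrs[[i]]]]
  has_dbl_o <- function(i) {           # i has a double-bonded O neighbour
    nb <- ctx$nbrs[[i]]; ord <- ctx$bord[[i]]
    any(elem[nb] == "O" & ord == 2)
  }
  is_amide_n <- function(i) {
    any(vapply(hvy_nbrs(i), function(j) elem[j] == "C" && has_dbl_o(j), logical(1)))
  }

  arom_rings <- Filter(function(r) ring_is_aromatic(r, ctx), ctx$rings)
  arom_atoms <- unique(unlist(arom_rings))

  for (i in heavy) {
    xyz <- as.numeric(at[i, c("x", "y", "z")])
    e <- elem[i]
    if (e %in% c("N", "O")) {
      if ("donor" %in% rules$types && ctx$h_count[i] > 0)
        add("donor", i, xyz)
      if ("acceptor" %in% rules$types) {
        ok <- if (e == "O") TRUE
              else chg[i] <= 0 &&
                   !(rules$exclude_amide_n_acceptor && is_amide_n(i)) &&
                   length(ctx$nbrs[[i]]) < 4L
        if (isTRUE(ok)) add("acceptor", i, xyz)
      }
    }
    if ("positive" %in% rules$types) {
      pos <- chg[i] > 0
      if (!pos && rules$amine_positive && e == "N" && chg[i] == 0 &&
          all(ctx$bord[[i]] == 1) && !(i %in% arom_atoms) && !is_amide_n(i))
        pos <- TRUE
      if (!pos && rules$amidine_positive && e == "N") {
        # sp2 N double-bonded to a C that carries another N
        nb <- ctx$nbrs[[i]]; ord <- ctx$bord[[i]]
        cs <- nb[elem[nb] == "C" & ord == 2]
        pos <- any(vapply(cs, function(cc)
          sum(elem[hvy_nbrs(cc)] == "N") >= 2L, logical(1)))
      }
      if (pos) add("positive", i, xyz)
    }
    if ("negative" %in% rules$types) {
      neg <- chg[i] < 0
      if (!neg && rules$acid_negative && e == "O" && chg[i] == 0 &&
          ctx$h_count[i] > 0) {
        # hydroxyl O on a C/S/P centre that also bears a double-bonded O
        nb <- hvy_nbrs(i)
        neg <- any(vapply(nb, function(j)
          elem[j] %in% c("C", "S", "P") && has_dbl_o(j), logical(1)))
      }
      if (neg) add("negative", i, xyz)
    }
    if ("lipophilic" %in% rules$types && e == "C" && chg[i] == 0) {
      nb <- hvy_nbrs(i)
      if (!any(elem[nb] %in% c("N", "O", "S") | chg[nb] != 0))
        add("lipophilic", i, xyz)
    }
  }
  if ("aromatic" %in% rules$types) {
    for (r in arom_rings) {
      cen <- colMeans(at[r, c("x", "y", "z")])
      add("aromatic", r, as.numeric(cen))
    }
  }
  if (length(res_type) == 0L) return(empty)
  out <- data.frame(type = res_type,
                    x = res_xyz[, 1L], y = res_xyz[, 2L], z = res_xyz[, 3L])
  out$source_atoms <- res_atom
  rownames(out) <- NULL
  out
}

#' Canonical triplet key from three typed points
#'
#' A triplet is the cyclic sequence of (type, opposite-edge bin) pairs;
#' relabelling the three points permutes the sequence by a rotation or
#' reflection, so the canonical form is the lexicographically smallest of
#' the six such variants (types ordered donor < acceptor < positive <
#' negative < aromatic < lipophilic, then bin). Canonicalization is
#' idempotent by construction.
#'
#' @param types Integer vector (length 3) of type indices into the
#'   canonical type order, or character type names.
#' @param bins Integer vector (length 3): `bins[i]` is the distance bin of
#'   the edge opposite point `i`.
#' @return Single string `T1T2T3:b1,b2,b3`.
#' @export
triplet_key <- function(types, bins) {
  if (is.character(types)) types <- match(types, names(PPP_TYPES))
  stopifnot(length(types) == 3L, length(bins) == 3L, !anyNA(types))
  perms <- list(c(1L, 2L, 3L), c(2L, 3L, 1L), c(3L, 1L, 2L),
                c(1L, 3L, 2L), c(3L, 2L, 1L), c(2L, 1L, 3L))
  best <- NULL
  for (p in perms) {
    cand <- c(rbind(types[p], bins[p]))  # t1 b1 t2 b2 t3 b3
    if (is.null(best) || lex_lt(cand, best)) best <- cand
  }
  sprintf("%s%s%s:%d,%d,%d",
          PPP_TYPES[best[1L]], PPP_TYPES[best[3L]], PPP_TYPES[best[5L]],
          best[2L], best[4L], best[6L])
}

#' @noRd
lex_lt <- function(a, b) {
  d <- a - b
  i <- which(d != 0)
  length(i) > 0 && d[i[1L]] < 0
}

#' Enumerate canonical triplet keys from a set of pharmacophore points
#'
#' Considers every unordered triple of points, bins the three pairwise
#' distances, and canonicalizes. Triples with any edge at or beyond the
#' binning cutoff are dropped; fewer than three points yield an empty set.
#' Degenerate geometry (collinear or coincident points) is kept: a triplet
#' is defined by its distances, not by area.
#'
#' @param ppps Data frame from [assign_ppps()] (columns `type`, `x`, `y`,
#'   `z`).
#' @param binning A [distance_binning()] spec.
#' @return Sorted character vector of unique canonical keys.
#' @export
enumerate_triplets <- function(ppps, binning = distance_binning()) {
  n <- nrow(ppps)
  if (is.null(n) || n < 3L) return(character())
  xyz <- as.matrix(ppps[, c("x", "y", "z")])
  types <- match(ppps$type, names(PPP_TYPES))
  if (anyNA(types)) stop_ligfish("unknown PPP type", "ligfish_schema_error")
  d <- as.matrix(stats::dist(xyz))
  triples <- combn(n, 3L)
  keys <- character(ncol(triples))
  keep <- logical(ncol(triples))
  for (k in seq_len(ncol(triples))) {
    i <- triples[1L, k]; j <- triples[2L, k]; l <- triples[3L, k]
    e <- c(d[j, l], d[i, l], d[i, j])  # edge opposite i, j, l
    if (any(e >= binning$max_distance)) next
    keep[k] <- TRUE
    keys[k] <- triplet_key(types[c(i, j, l)], as.integer(floor(e / binning$width)))
  }
  sort(unique(keys[keep]))
}

#' Modal fingerprint: union of per-conformer triplet fingerprints
#'
#' Every conformer of the compound is converted to pharmacophore points
#' and triplet keys independently; the modal fingerprint is the set union,
#' so it is invariant to conformer order and duplication and can only grow
#' when conformers are added.
#'
#' @param conformers List of [conformer()] objects, all with the same
#'   `compound_id` (1 to 10 of them).
#' @param rules,binning Rule table and distance binning.
#' @return Object of class `ligfish_modal_fp`: list with `compound_id` and
#'   sorted character `keys`.
#' @export
modal_fingerprint <- function(conformers, rules = default_ppp_rules(),
                              binning = distance_binning()) {
  stopifnot(length(conformers) >= 1L)
  ids <- unique(vapply(conformers, function(cf) cf$compound_id, character(1)))
  if (length(ids) != 1L)
    stop_ligfish(sprintf("mixed compound_ids in conformer list: %s",
                         paste(ids, collapse = ", ")), "ligfish_schema_error")
  if (length(conformers) > 10L) conformers <- conformers[1:10]
  keys <- sort(unique(unlist(lapply(conformers, function(cf)
    enumerate_triplets(assign_ppps(cf, rules), binning)))))
  structure(list(compound_id = ids, keys = keys), class = "ligfish_modal_fp")
}

#' Modal fingerprints for a whole SDF ensemble
#'
#' @param confs Named list as returned by [read_sdf()].
#' @param rules,binning Rule table and distance binning.
#' @return Named list mapping compound_id to its sorted key vector — the
#'   working fingerprint representation used by the modeling modules.
#' @export
modal_fingerprints <- function(confs, rules = default_ppp_rules(),
                               binning = distance_binning()) {
  lapply(confs, function(cc) modal_fingerprint(cc, rules, binning)$keys)
}

#' Fold a sparse key set to fixed-width bit positions
#'
#' Interoperability export only: internal modeling always uses the exact
#' sparse keys (folding introduces collisions).
#'
#' @param keys Character vector of canonical triplet keys.
#' @param n_bits Width of the folded fingerprint.
#' @return Sorted unique integer bit positions in `[0, n_bits)`.
#' @export
fold_fingerprint <- function(keys, n_bits = 1024L) {
  h <- vapply(keys, function(k) {
    v <- utf8ToInt(k)
    acc <- 0
    for (c in v) acc <- (acc * 31 + c) %% n_bits
    acc
  }, numeric(1))
  sort(unique(as.integer(h)))
}

#' @export
print.ligfish_modal_fp <- function(x, ...) {
  cat(sprintf("<modal fingerprint: %s, %d triplet keys>\n",
              x$compound_id, length(x$keys)))
  invisible(x)
}
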