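# Minimal MDL SDF (V2000) reader.
#
# None of the pre-installed R packages parse MOL/SDF, so this reader covers
# exactly what the pharmacophore module needs: element symbols, 3D
# coordinates, bonds with orders, and formal charges (atom-block charge
# codes overridden by M  CHG lines). Records sharing a title line are
# treated as conformers of the same compound, in file order.

#' Construct a conformer object
#'
#' A conformer is one 3D geometry of a compound: a table of heavy and
#' hydrogen atoms with coordinates in Angstroms, and a bond list.
#'
#' @param compound_id Character scalar identifying the compound.
#' @param atoms Data frame with columns `element`, `x`, `y`, `z` and
#'   optionally `charge` (formal charge, default 0).
#' @param bonds Data frame with columns `a1`, `a2` (1-based atom indices)
#'   and `order` (1, 2, 3, or 4 for aromatic).
#' @param conformer_index Non-negative integer position of this geometry
#'   within the compound's conformer ensemble.
#' @return An object of class `ligfish_conformer`.
#' @export
conformer <- function(compound_id, atoms, bonds, conformer_index = 0L) {
  if (!is.character(compound_id) || length(compound_id) != 1L || !nzchar(compound_id))
    stop_ligfish("compound_id must be a non-empty string", "ligfish_parse_error")
  atoms <- as.data.frame(atoms)
  if (is.null(atoms$charge)) atoms$charge <- 0L
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (nrow(atoms) > 0 && !all(is.finite(coords)))
    stop_ligfish(sprintf("non-finite coordinates in compound '%s'", compound_id),
                 "ligfish_parse_error")
  bonds <- as.data.frame(bonds)
  if (nrow(bonds) > 0) {
    idx <- c(bonds$a1, bonds$a2)
    if (any(idx < 1L | idx > nrow(atoms)))
      stop_ligfish(sprintf("bond atom index out of range in compound '%s'", compound_id),
                   "ligfish_parse_error")
    if (any(bonds$a1 == bonds$a2))
      stop_ligfish(sprintf("self-bond in compound '%s'", compound_id),
                   "ligfish_parse_error")
  }
  structure(
    list(compound_id = compound_id, atoms = atoms, bonds = bonds,
         conformer_index = as.integer(conformer_index)),
    class = "ligfish_conformer"
  )
}

#' Read a multi-record SDF file into conformer ensembles
#'
#' Records are grouped by their title line (line 1 of each molblock): all
#' records with the same title become conformers of one compound, numbered
#' in file order. At most `max_conformers` geometries are retained per
#' compound (further records are silently dropped, mirroring the common
#' practice of capping conformer ensembles at 10).
#'
#' @param path Path to an SDF file (V2000 connection tables).
#' @param max_conformers Per-compound conformer cap (default 10).
#' @return Named list: for each compound_id, a list of
#'   [conformer()] objects.
#' @export
read_sdf <- function(path, max_conformers = 10L) {
  if (!file.exists(path))
    stop_ligfish(sprintf("file not found: %s", path), "ligfish_io_error")
  lines <- readLines(path, warn = FALSE)
  # split on records terminated by $$$$
  ends <- grep("^\\$\\$\\$\\$\\s*$", lines)
  if (length(ends) == 0L) ends <- length(lines)
  starts <- c(1L, head(ends, -1L) + 1L)
  out <- list()
  for (k in seq_along(starts)) {
    block <- lines[starts[k]:ends[k]]
    block <- block[!grepl("^\\$\\$\\$\\$\\s*$", block)]
    if (all(!nzchar(trimws(block)))) next
    conf <- parse_molblock(block)
    id <- conf$compound_id
    n_have <- length(out[[id]])
    if (n_have >= max_conformers) next
    conf$conformer_index <- n_have
    out[[id]] <- c(out[[id]], list(conf))
  }
  out
}

#' @noRd
parse_molblock <- function(block) {
  if (length(block) < 4L)
    stop_ligfish("truncated molblock", "ligfish_parse_error")
  title <- trimws(block[1L])
  if (!nzchar(title)) title <- "unnamed"
  counts <- block[4L]
  n_atoms <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  n_bonds <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(n_atoms) || is.na(n_bonds))
    stop_ligfish(sprintf("bad counts line in compound '%s'", title), "ligfish_parse_error")
  atom_lines <- block[4L + seq_len(n_atoms)]
  bond_lines <- block[4L + n_atoms + seq_len(n_bonds)]

  x <- as.numeric(substr(atom_lines, 1L, 10L))
  y <- as.numeric(substr(atom_lines, 11L, 20L))
  z <- as.numeric(substr(atom_lines, 21L, 30L))
  element <- trimws(substr(atom_lines, 32L, 34L))
  chg_code <- suppressWarnings(as.integer(substr(atom_lines, 37L, 39L)))
  chg_code[is.na(chg_code)] <- 0L
  # legacy charge codes: 1 -> +3, 2 -> +2, 3 -> +1, 5 -> -1, 6 -> -2, 7 -> -3
  code_map <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)
  charge <- ifelse(chg_code %in% names(code_map) == FALSE, 0L,
                   code_map[as.character(chg_code)])
  charge <- as.integer(ifelse(is.na(charge), 0L, charge))

  a1 <- suppressWarnings(as.integer(substr(bond_lines, 1L, 3L)))
  a2 <- suppressWarnings(as.integer(substr(bond_lines, 4L, 6L)))
  order <- suppressWarnings(as.integer(substr(bond_lines, 7L, 9L)))
  if (n_bonds > 0 && (anyNA(a1) || anyNA(a2) || anyNA(order)))
    stop_ligfish(sprintf("bad bond block in compound '%s'", title), "ligfish_parse_error")

  # M  CHG lines override atom-block charges entirely (MDL semantics)
  prop <- block[grepl("^M  CHG", block)]
  if (length(prop)) {
    charge[] <- 0L
    for (ln in prop) {
      f <- as.integer(strsplit(trimws(substring(ln, 7L)), "\\s+")[[1]])
      n <- f[1L]
      for (i in seq_len(n)) charge[f[2L * i]] <- f[2L * i + 1L]
    }
  }

  conformer(title,
            data.frame(element = element, x = x, y = y, z = z, charge = charge,
                       stringsAsFactors = FALSE),
            if (n_bonds > 0)
              data.frame(a1 = a1, a2 = a2, order = order)
            else data.frame(a1 = integer(), a2 = integer(), order = integer()))
}
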