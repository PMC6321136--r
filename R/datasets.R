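# Datasets module: labelled bioassay datasets, recurrent stratified
# 70/30 resampling, and TSV plumbing for all tabular artifacts.

#' Construct a labelled activity dataset
#'
#' @param dataset_id Dataset identifier (e.g. a bioassay accession).
#' @param compound_id Character vector of unique compound identifiers.
#' @param label Parallel vector of activity labels; accepted tokens
#'   (case-insensitive, whitespace-trimmed): "active"/"inactive", "1"/"0".
#' @return Object of class `ligfish_dataset` with fields `dataset_id`,
#'   `records` (data frame compound_id/label), `na` (actives count) and
#'   `ni` (inactives count).
#' @export
activity_dataset <- function(dataset_id, compound_id, label) {
  stopifnot(length(compound_id) == length(label))
  compound_id <- as.character(compound_id)
  dup <- unique(compound_id[duplicated(compound_id)])
  if (length(dup))
    stop_ligfish(sprintf("duplicate compound_id(s) in dataset '%s': %s",
                         dataset_id, paste(dup, collapse = ", ")),
                 "ligfish_schema_error")
  label <- normalize_labels(label)
  structure(list(
    dataset_id = as.character(dataset_id),
    records = data.frame(compound_id = compound_id, label = label,
                         stringsAsFactors = FALSE),
    na = sum(label == "active"),
    ni = sum(label == "inactive")
  ), class = "ligfish_dataset")
}

#' @noRd
normalize_labels <- function(label) {
  tok <- tolower(trimws(as.character(label)))
  map <- c(active = "active", inactive = "inactive", `1` = "active", `0` = "inactive")
  out <- unname(map[tok])
  bad <- which(is.na(out))
  if (length(bad))
    stop_ligfish(sprintf("unknown label token(s) at position(s) %s: %s",
                         paste(bad, collapse = ", "),
                         paste(unique(tok[bad]), collapse = ", ")),
                 "ligfish_schema_error")
  out
}

#' @export
print.ligfish_dataset <- function(x, ...) {
  cat(sprintf("<activity dataset '%s': %d actives, %d inactives>\n",
              x$dataset_id, x$na, x$ni))
  invisible(x)
}

#' Recurrent stratified 70/30 split plan
#'
#' Draws `n_repeats` independent stratified partitions of a labelled
#' dataset: each repeat places round-half-up(train_fraction * Na) actives
#' and round-half-up(train_fraction * Ni) inactives in the training set
#' and the remainder in the validation set. Repeat `r` uses RNG seed
#' `seed + r`, so plans are reproducible and repeats independent. If after
#' all repeats some compound never entered a validation set (out-of-sample
#' score calibration needs at least one validation appearance per
#' compound), the whole plan is re-drawn with an incremented master seed,
#' up to 5 times, then the function errors.
#'
#' @param dataset An [activity_dataset()]; both classes need >= 2 members.
#' @param seed Integer master seed.
#' @param n_repeats Number of repeats (protocol default 30).
#' @param train_fraction Training fraction (default 0.70).
#' @return Object of class `ligfish_split_plan`: list with `seed`,
#'   `n_repeats`, `train_fraction` and `assignments`, a list of logical
#'   vectors (TRUE = train) named by compound_id.
#' @export
stratified_split <- function(dataset, seed, n_repeats = 30L,
                             train_fraction = 0.70) {
  stopifnot(inherits(dataset, "ligfish_dataset"))
  if (dataset$na < 2L || dataset$ni < 2L)
    stop_ligfish(sprintf(
      "dataset '%s' needs >= 2 compounds per class for stratified splitting (Na=%d, Ni=%d)",
      dataset$dataset_id, dataset$na, dataset$ni), "ligfish_degenerate_error")
  lab <- dataset$records$label
  ids <- dataset$records$compound_id
  idx_a <- which(lab == "active")
  idx_i <- which(lab == "inactive")
  n_tr_a <- round_half_up(train_fraction * length(idx_a))
  n_tr_i <- round_half_up(train_fraction * length(idx_i))
  # guarantee non-empty validation strata
  n_tr_a <- min(n_tr_a, length(idx_a) - 1L)
  n_tr_i <- min(n_tr_i, length(idx_i) - 1L)

  draw_plan <- function(master) {
    lapply(seq_len(n_repeats), function(r) {
      with_seed(master + r, {
        tr <- logical(length(ids))
        tr[sample(idx_a, n_tr_a)] <- TRUE
        tr[sample(idx_i, n_tr_i)] <- TRUE
        names(tr) <- ids
        tr
      })
    })
  }
  master <- as.integer(seed)
  # full validation coverage is only enforceable when the repeats can in
  # principle visit every compound (e.g. a single repeat never can)
  feasible <- n_repeats * (length(idx_a) - n_tr_a) >= length(idx_a) &&
              n_repeats * (length(idx_i) - n_tr_i) >= length(idx_i)
  for (attempt in 0:5) {
    if (attempt == 5L)
      stop_ligfish("could not cover every compound in a validation set after 5 re-draws",
                   "ligfish_degenerate_error")
    assignments <- draw_plan(master + attempt)
    if (!feasible) break
    val_counts <- Reduce(`+`, lapply(assignments, function(tr) !tr))
    if (all(val_counts >= 1L)) break
  }
  structure(list(seed = master + attempt, n_repeats = as.integer(n_repeats),
                 train_fraction = train_fraction, assignments = assignments),
            class = "ligfish_split_plan")
}

# ---- TSV plumbing ----------------------------------------------------------

#' Read / write activity label tables
#'
#' Tab-separated with header `compound_id<TAB>label`; labels normalized as
#' in [activity_dataset()].
#'
#' @param path File path.
#' @param dataset_id Dataset id to attach on read (default: file base name).
#' @return [activity_dataset()] for the reader.
#' @export
read_activity_tsv <- function(path, dataset_id = NULL) {
  if (!file.exists(path))
    stop_ligfish(sprintf("file not found: %s", path), "ligfish_io_error")
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("compound_id", "label")
  if (!all(need %in% names(df)))
    stop_ligfish(sprintf("missing column(s) %s in %s",
                         paste(setdiff(need, names(df)), collapse = ", "), path),
                 "ligfish_schema_error")
  tok <- tolower(trimws(as.character(df$label)))
  off <- which(!tok %in% c("active", "inactive", "1", "0"))
  if (length(off))  # +1: header line
    stop_ligfish(sprintf("unknown label token at line(s) %s of %s",
                         paste(off + 1L, collapse = ", "), path),
                 "ligfish_schema_error")
  activity_dataset(dataset_id %||% sub("\\.[^.]*$", "", basename(path)),
                   df$compound_id, df$label)
}

#' @rdname read_activity_tsv
#' @param dataset An [activity_dataset()] to write.
#' @export
write_activity_tsv <- function(dataset, path) {
  write.table(dataset$records, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read / write fingerprint tables
#'
#' Tab-separated with header; one row per compound:
#' `compound_id<TAB>key1;key2;...`, keys in sorted order so output is
#' deterministic.
#'
#' @param fps Named list mapping compound_id to a character key vector.
#' @param path File path.
#' @return The named list of key vectors for the reader.
#' @export
write_fingerprint_tsv <- function(fps, path) {
  ids <- names(fps)
  lines <- vapply(seq_along(fps), function(i)
    paste0(ids[i], "\t", paste(sort(fps[[i]]), collapse = ";")), character(1))
  writeLines(c("compound_id\tkeys", lines), path)
  invisible(path)
}

#' @rdname write_fingerprint_tsv
#' @export
read_fingerprint_tsv <- function(path) {
  if (!file.exists(path))
    stop_ligfish(sprintf("file not found: %s", path), "ligfish_io_error")
  lines <- readLines(path)
  if (length(lines) < 1L || !identical(lines[1L], "compound_id\tkeys"))
    stop_ligfish(sprintf("bad fingerprint header in %s", path), "ligfish_schema_error")
  lines <- lines[-1L]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop_ligfish(sprintf("duplicate compound_id(s) in %s: %s", path,
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")),
                 "ligfish_schema_error")
  fps <- lapply(parts, function(p) {
    if (length(p) < 2L || !nzchar(p[2L])) character()
    else sort(strsplit(p[2L], ";", fixed = TRUE)[[1L]])
  })
  names(fps) <- ids
  fps
}

#' Read / write dataset-to-activity-class maps
#'
#' Tab-separated with header `dataset_id<TAB>class_id`; a dataset may
#' appear under several classes (multi-membership).
#'
#' @param path File path.
#' @param map Data frame with columns dataset_id, class_id.
#' @return Data frame for the reader.
#' @export
read_class_map_tsv <- function(path) {
  if (!file.exists(path))
    stop_ligfish(sprintf("file not found: %s", path), "ligfish_io_error")
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("dataset_id", "class_id") %in% names(df)))
    stop_ligfish(sprintf("class map %s must have dataset_id and class_id columns", path),
                 "ligfish_schema_error")
  df
}

#' @rdname read_class_map_tsv
#' @export
write_class_map_tsv <- function(map, path) {
  write.table(map[, c("dataset_id", "class_id")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Import a PubChem Bioassay activity CSV
#'
#' Convenience importer: keeps rows whose PUBCHEM_ACTIVITY_OUTCOME is
#' "Active" or "Inactive" (all other outcomes dropped), compound ids taken
#' from PUBCHEM_CID. Never required by the core pipeline.
#'
#' @param path CSV file path.
#' @param dataset_id Dataset id (default: file base name).
#' @return An [activity_dataset()].
#' @export
read_pubchem_csv <- function(path, dataset_id = NULL) {
  if (!file.exists(path))
    stop_ligfish(sprintf("file not found: %s", path), "ligfish_io_error")
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("PUBCHEM_CID", "PUBCHEM_ACTIVITY_OUTCOME")
  if (!all(need %in% names(df)))
    stop_ligfish(sprintf("missing column(s) %s in %s",
                         paste(setdiff(need, names(df)), collapse = ", "), path),
                 "ligfish_schema_error")
  keep <- df$PUBCHEM_ACTIVITY_OUTCOME %in% c("Active", "Inactive")
  df <- df[keep, , drop = FALSE]
  df <- df[!duplicated(df$PUBCHEM_CID), , drop = FALSE]
  activity_dataset(dataset_id %||% sub("\\.[^.]*$", "", basename(path)),
                   df$PUBCHEM_CID, df$PUBCHEM_ACTIVITY_OUTCOME)
}
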