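# Model bundle IO: portable JSON serialization of fitted ensembles
# (metadata + member parameters + per-compound OOF tables). Numbers are
# written at full precision so a reloaded ensemble reproduces scores
# bit-for-bit.

#' Save / load a fitted ensemble as a JSON bundle
#'
#' @param ensemble A `ligfish_ensemble`.
#' @param path Output `.json` path.
#' @return The path (save) or the restored ensemble (load).
#' @export
save_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "ligfish_ensemble"))
  members <- lapply(ensemble$members, function(m) {
    base <- list(method = m$method, repeat_index = m$repeat_index,
                 vocab = as.list(m$vocab))
    if (m$method == "svm_linear")
      c(base, list(w = unname(m$w), b = m$b, selected_cost = m$selected_cost))
    else
      c(base, list(w1 = unname(m$w1), w0 = unname(m$w0), prior = m$prior,
                   alpha = m$alpha))
  })
  obj <- list(
    schema_version = 1L, format = "ligfish_ensemble",
    dataset_id = ensemble$dataset_id, method = ensemble$method,
    n_members = ensemble$n_members, split_seed = ensemble$split_seed,
    compound_id = names(ensemble$labels), labels = unname(ensemble$labels),
    oof_scores = unname(ensemble$oof_scores),
    oof_mean = unname(ensemble$oof_mean), oof_sd = unname(ensemble$oof_sd),
    members = members
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) {
  if (!file.exists(path))
    stop_ligfish(sprintf("file not found: %s", path), "ligfish_io_error")
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(obj$format, "ligfish_ensemble"))
    stop_ligfish(sprintf("not an ensemble bundle: %s", path), "ligfish_schema_error")
  ids <- obj$compound_id
  members <- lapply(obj$members, function(m) {
    m$vocab <- unlist(m$vocab)
    if (m$method == "svm_linear") m$w <- stats::setNames(m$w, m$vocab)
    else { m$w1 <- stats::setNames(m$w1, m$vocab); m$w0 <- stats::setNames(m$w0, m$vocab) }
    m
  })
  structure(list(
    dataset_id = obj$dataset_id, method = obj$method, members = members,
    n_members = obj$n_members, split_seed = obj$split_seed,
    labels = stats::setNames(obj$labels, ids),
    oof_scores = stats::setNames(lapply(obj$oof_scores, as.numeric), ids),
    oof_mean = stats::setNames(obj$oof_mean, ids),
    oof_sd = stats::setNames(obj$oof_sd, ids)
  ), class = "ligfish_ensemble")
}
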