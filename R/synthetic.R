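# Synthetic-data module: seeded generators producing fingerprints,
# labelled datasets, geometric point clouds and whole class collections
# with the statistical structure the modeling stack assumes, so every
# stage is testable without external downloads. Synthetic fingerprints
# bypass the pharmacophore module on purpose (direct key sets) so that
# machine-learning and calibration tests do not depend on chemistry
# perception; point clouds exercise the geometry path separately.

#' Specification for a synthetic fingerprint dataset
#'
#' Actives and inactives share a key space of `n_bits` keys; the first
#' `n_signal_bits` keys are "signal" keys set with probability
#' `p_signal_active` in actives and `p_signal_inactive` in inactives, all
#' remaining keys fire at the `p_background` rate in both classes.
#' Defaults state a strongly separable screening dataset: 50 + 50
#' compounds, 20 signal keys at 0.9 vs 0.1, 5% background.
#'
#' @param n_active,n_inactive Class sizes.
#' @param n_bits Key-space size.
#' @param n_signal_bits Number of class-discriminating keys (<= n_bits).
#' @param p_signal_active,p_signal_inactive,p_background Bernoulli rates.
#' @param seed Integer seed.
#' @return List with class `ligfish_fp_spec`.
#' @export
fingerprint_spec <- function(n_active = 50L, n_inactive = 50L, n_bits = 200L,
                             n_signal_bits = 20L, p_signal_active = 0.9,
                             p_signal_inactive = 0.1, p_background = 0.05,
                             seed = 1L) {
  p <- c(p_signal_active, p_signal_inactive, p_background)
  stopifnot(all(p >= 0 & p <= 1), n_signal_bits <= n_bits,
            n_active >= 1, n_inactive >= 1)
  structure(as.list(environment()), class = "ligfish_fp_spec")
}

#' Generate a synthetic fingerprint dataset
#'
#' @param spec A [fingerprint_spec()].
#' @param dataset_id Dataset id for the generated [activity_dataset()].
#' @param id_prefix Prefix for generated compound ids.
#' @param signal_bits Optional explicit signal-key indices (defaults to
#'   the first `n_signal_bits` of the key space); used by
#'   [gen_class_collection()] to plant shared or disjoint signals.
#' @return List with `fingerprints` (named list of key vectors),
#'   `dataset` (an [activity_dataset()]) and `signal_bits`.
#' @export
gen_fingerprint_dataset <- function(spec, dataset_id = "synthetic",
                                    id_prefix = "cpd",
                                    signal_bits = NULL) {
  stopifnot(inherits(spec, "ligfish_fp_spec"))
  all_keys <- sprintf("k%05d", seq_len(spec$n_bits))
  if (is.null(signal_bits)) signal_bits <- seq_len(spec$n_signal_bits)
  stopifnot(length(signal_bits) == spec$n_signal_bits,
            all(signal_bits >= 1 & signal_bits <= spec$n_bits))
  bg_bits <- setdiff(seq_len(spec$n_bits), signal_bits)
  n <- spec$n_active + spec$n_inactive
  lab <- rep(c("active", "inactive"), c(spec$n_active, spec$n_inactive))
  ids <- sprintf("%s%04d", id_prefix, seq_len(n))
  fps <- with_seed(spec$seed, {
    lapply(seq_len(n), function(i) {
      p_sig <- if (lab[i] == "active") spec$p_signal_active else spec$p_signal_inactive
      on_sig <- signal_bits[runif(length(signal_bits)) < p_sig]
      on_bg <- bg_bits[runif(length(bg_bits)) < spec$p_background]
      sort(all_keys[c(on_sig, on_bg)])
    })
  })
  names(fps) <- ids
  list(fingerprints = fps,
       dataset = activity_dataset(dataset_id, ids, lab),
       signal_bits = signal_bits)
}

#' Generate a random typed point cloud
#'
#' Uniform points in a cube, each assigned one of the six pharmacophore
#' types; used to exercise triplet enumeration against brute-force
#' oracles without any chemistry.
#'
#' @param n_points Number of points (>= 0).
#' @param type_distribution Sampling probabilities over the six types
#'   (default uniform).
#' @param box_size Cube edge length in Angstroms.
#' @param seed Integer seed.
#' @return Data frame with columns `type`, `x`, `y`, `z` compatible with
#'   [enumerate_triplets()].
#' @export
gen_point_cloud_molecule <- function(n_points, type_distribution = NULL,
                                     box_size = 10, seed = 1L) {
  stopifnot(n_points >= 0)
  types <- names(PPP_TYPES)
  pr <- type_distribution %||% rep(1 / 6, 6)
  stopifnot(length(pr) == 6L)
  if (n_points == 0L)
    return(data.frame(type = character(), x = numeric(), y = numeric(),
                      z = numeric()))
  with_seed(seed, data.frame(
    type = sample(types, n_points, replace = TRUE, prob = pr),
    x = runif(n_points, 0, box_size),
    y = runif(n_points, 0, box_size),
    z = runif(n_points, 0, box_size),
    stringsAsFactors = FALSE
  ))
}

#' Specification for a synthetic activity-class collection
#'
#' A fraction of the classes is "planted active": the actives of their
#' member models share their signal keys with the query compounds, so a
#' correct pipeline ranks those classes on top. The remaining (null)
#' classes use per-class signal keys disjoint from the query signal, so
#' queries look inactive to them. Defaults state 20 classes, 25% planted,
#' 1-4 models per class, 27 query compounds (a typical natural-product
#' series), and per-model datasets drawn from `fp` (default 20 + 20
#' compounds to keep a full collection trainable on one CPU).
#'
#' @param n_classes Number of activity classes.
#' @param models_per_class Integer range c(lo, hi).
#' @param fraction_planted_active Fraction of classes sharing the query
#'   signal.
#' @param n_query Number of query compounds.
#' @param fp A [fingerprint_spec()] template for the per-model datasets.
#' @param seed Integer seed.
#' @return List with class `ligfish_class_spec`.
#' @export
class_collection_spec <- function(n_classes = 20L, models_per_class = c(1L, 4L),
                                  fraction_planted_active = 0.25,
                                  n_query = 27L,
                                  fp = fingerprint_spec(n_active = 20L,
                                                        n_inactive = 20L,
                                                        n_bits = 400L),
                                  seed = 1L) {
  stopifnot(n_classes >= 2, fraction_planted_active >= 0,
            fraction_planted_active <= 1, length(models_per_class) == 2L)
  structure(as.list(environment()), class = "ligfish_class_spec")
}

#' Generate a synthetic activity-class collection
#'
#' @param spec A [class_collection_spec()].
#' @return List with `datasets` (list of [activity_dataset()]),
#'   `fingerprints` (named list covering all modeled compounds),
#'   `query_fps` (fingerprints of the query compounds), `class_map`
#'   (data frame dataset_id/class_id) and `truth` (data frame class_id /
#'   label with labels probable_active / probable_inactive).
#' @export
gen_class_collection <- function(spec) {
  stopifnot(inherits(spec, "ligfish_class_spec"))
  fp <- spec$fp
  n_planted <- max(1L, round_half_up(spec$fraction_planted_active * spec$n_classes))
  planted <- seq_len(n_planted)
  query_signal <- seq_len(fp$n_signal_bits)
  all_keys <- sprintf("k%05d", seq_len(fp$n_bits))
  non_query_bits <- setdiff(seq_len(fp$n_bits), query_signal)

  # query compounds look like actives of the planted classes
  q <- with_seed(spec$seed, {
    lapply(seq_len(spec$n_query), function(i) {
      on_sig <- query_signal[runif(length(query_signal)) < fp$p_signal_active]
      on_bg <- non_query_bits[runif(length(non_query_bits)) < fp$p_background]
      sort(all_keys[c(on_sig, on_bg)])
    })
  })
  names(q) <- sprintf("query%03d", seq_len(spec$n_query))

  structure_seed <- spec$seed + 10000L
  layout <- with_seed(structure_seed, {
    n_models <- sample(seq(spec$models_per_class[1L], spec$models_per_class[2L]),
                       spec$n_classes, replace = TRUE)
    null_sigs <- lapply(seq_len(spec$n_classes), function(c)
      sort(sample(non_query_bits, fp$n_signal_bits)))
    list(n_models = n_models, null_sigs = null_sigs)
  })

  datasets <- list(); fps <- list(); map <- NULL
  model_no <- 0L
  for (c in seq_len(spec$n_classes)) {
    cid <- sprintf("class%02d", c)
    sig <- if (c %in% planted) query_signal else layout$null_sigs[[c]]
    for (m in seq_len(layout$n_models[c])) {
      model_no <- model_no + 1L
      did <- sprintf("assay%03d", model_no)
      mspec <- fp
      mspec$seed <- spec$seed + 100L * model_no
      g <- gen_fingerprint_dataset(mspec, dataset_id = did,
                                   id_prefix = paste0(did, "_c"),
                                   signal_bits = sig)
      datasets[[did]] <- g$dataset
      fps <- c(fps, g$fingerprints)
      map <- rbind(map, data.frame(dataset_id = did, class_id = cid,
                                   stringsAsFactors = FALSE))
    }
  }
  truth <- data.frame(
    class_id = sprintf("class%02d", seq_len(spec$n_classes)),
    label = ifelse(seq_len(spec$n_classes) %in% planted,
                   "probable_active", "probable_inactive"),
    stringsAsFactors = FALSE)
  list(datasets = datasets, fingerprints = fps, query_fps = q,
       class_map = map, truth = truth)
}
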