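# Independent brute-force oracles used across test files.

# AUC as explicit pair counting: P(score_a > score_i) + 0.5 P(=)
oracle_auc <- function(scores, labels) {
  a <- scores[labels == "active"]; i <- scores[labels == "inactive"]
  tot <- 0
  for (x in a) for (y in i) tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(a) * length(i))
}

# brute-force count of point triples whose pairwise distances all fall
# below the cutoff
oracle_triple_count <- function(xyz, max_distance) {
  n <- nrow(xyz)
  if (n < 3) return(0L)
  d <- as.matrix(dist(xyz))
  cnt <- 0L
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n)
    if (d[i, j] < max_distance && d[i, k] < max_distance && d[j, k] < max_distance)
      cnt <- cnt + 1L
  cnt
}

# canonical key oracle: minimum serialized string over all 3! point orders,
# built independently of triplet_key()'s rotation/reflection walk
oracle_key <- function(types, bins) {
  code <- c(donor = "D", acceptor = "A", positive = "P",
            negative = "N", aromatic = "R", lipophilic = "L")
  ord <- c(D = 1, A = 2, P = 3, N = 4, R = 5, L = 6)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  best <- NULL; best_vec <- NULL
  for (p in perms) {
    tv <- code[types[p]]
    vec <- c(rbind(ord[tv], bins[p]))
    if (is.null(best_vec) ||
        (function(a, b) { d <- a - b; i <- which(d != 0); length(i) && d[i[1]] < 0 })(vec, best_vec)) {
      best_vec <- vec
      best <- sprintf("%s%s%s:%d,%d,%d", tv[1], tv[2], tv[3],
                      bins[p][1], bins[p][2], bins[p][3])
    }
  }
  best
}
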