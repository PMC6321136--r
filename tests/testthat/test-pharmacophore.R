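# Pharmacophore module: PPP assignment, triplet enumeration,
# canonicalization, modal union.

test_that("PPP assignment follows the default rule table", {
  # degenerate: no heavy atoms
  h2 <- conformer("h2", data.frame(element = c("H", "H"),
                                   x = c(0, 0.7), y = 0, z = 0),
                  data.frame(a1 = 1, a2 = 2, order = 1L))
  expect_equal(nrow(assign_ppps(h2)), 0L)

  # benzene: one aromatic centroid + six lipophilic carbons
  pp <- assign_ppps(benzene_conformer())
  expect_equal(sum(pp$type == "aromatic"), 1L)
  expect_equal(sum(pp$type == "lipophilic"), 6L)
  expect_equal(nrow(pp), 7L)
  cen <- pp[pp$type == "aromatic", c("x", "y", "z")]
  expect_equal(as.numeric(cen), c(0, 0, 0), tolerance = 1e-10)
  expect_setequal(pp$source_atoms[[which(pp$type == "aromatic")]], 1:6)

  # protonated primary amine: N is both donor and positive (multi-typing)
  pp <- assign_ppps(ethylamine_h_conformer())
  n_types <- pp$type[vapply(pp$source_atoms, function(a) 3 %in% a, logical(1))]
  expect_true(all(c("donor", "positive") %in% n_types))

  # amide N: donor but not acceptor; carbonyl O acceptor
  pp <- assign_ppps(acetamide_conformer())
  types_of <- function(i) pp$type[vapply(pp$source_atoms, function(a) i %in% a, logical(1))]
  expect_true("donor" %in% types_of(4))
  expect_false("acceptor" %in% types_of(4))
  expect_true("acceptor" %in% types_of(3))

  # carboxylic acid: ionizable hydroxyl O is negative
  pp <- assign_ppps(acetic_acid_conformer())
  types_of <- function(i) pp$type[vapply(pp$source_atoms, function(a) i %in% a, logical(1))]
  expect_true("negative" %in% types_of(4))
  expect_true("donor" %in% types_of(4))
})

test_that("malformed structures raise a parse error naming the compound", {
  bad <- conformer("badmol",
                   data.frame(element = c("O", "C", "C", "C"),
                              x = 0:3, y = 0, z = 0),
                   data.frame(a1 = c(1, 1, 1), a2 = c(2, 3, 4),
                              order = c(2L, 2L, 2L)))  # O with 3 double bonds
  expect_error(assign_ppps(bad), "badmol", class = "ligfish_parse_error")
  expect_error(conformer("x", data.frame(element = "C", x = NaN, y = 0, z = 0),
                         data.frame(a1 = integer(), a2 = integer(),
                                    order = integer())),
               class = "ligfish_parse_error")
})

test_that("triplet keys canonicalize like the brute-force permutation oracle", {
  # hand example: (donor, acceptor, lipophilic), distances 3.4 / 5.1 / 7.2
  tri <- triangle_ppps()
  keys <- enumerate_triplets(tri)
  expect_length(keys, 1L)
  # edge opposite p1 = |p2p3| = 5.1 -> bin 5; opposite p2 = 3.4 -> 3; opposite p3 = 7.2 -> 7
  expect_equal(keys, oracle_key(c("donor", "acceptor", "lipophilic"), c(5L, 3L, 7L)))
  # all 3! input orders give the identical canonical key
  for (p in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1), c(3, 1, 2), c(1, 3, 2)))
    expect_equal(enumerate_triplets(tri[p, ]), keys)
  # canonicalization is idempotent and matches the oracle on random triplets
  set.seed(11)
  for (r in 1:50) {
    tt <- sample(6, 3, replace = TRUE)
    bb <- sample(0:19, 3, replace = TRUE)
    k <- triplet_key(tt, bb)
    expect_equal(k, oracle_key(names(ligfish:::PPP_TYPES)[tt], bb))
  }
})

test_that("triplet enumeration counts, cutoff and degenerate inputs", {
  expect_equal(enumerate_triplets(triangle_ppps()[1:2, ]), character())
  # 6 random points in general position: C(6,3) = 20 candidate triples
  cloud <- gen_point_cloud_molecule(6, box_size = 8, seed = 3)
  expect_lte(length(enumerate_triplets(cloud)), 20L)
  # triples beyond the distance cutoff are dropped, count matches oracle
  for (s in 1:5) {
    cl <- gen_point_cloud_molecule(9, box_size = 30, seed = s)
    bn <- distance_binning(1, 20)
    cnt <- oracle_triple_count(cl[, c("x", "y", "z")], 20)
    expect_lte(length(enumerate_triplets(cl, bn)), cnt)
    if (cnt == choose(9, 3))
      expect_gt(length(enumerate_triplets(cl, bn)), 0)
  }
  # coincident points are kept with bin-0 edges
  co <- data.frame(type = c("donor", "donor", "acceptor"),
                   x = c(0, 0, 1), y = 0, z = 0)
  expect_length(enumerate_triplets(co), 1L)
})

test_that("brute-force triple-count oracle agrees for n up to 12", {
  for (n in c(4, 8, 12)) {
    cl <- gen_point_cloud_molecule(n, box_size = 5, seed = n)  # all pairs < 20 A
    expect_equal(oracle_triple_count(cl[, c("x", "y", "z")], 20), choose(n, 3))
    # distinct-type cloud in general position: every triple yields a key,
    # merged keys never exceed the candidate count
    expect_lte(length(enumerate_triplets(cl)), choose(n, 3))
  }
})

test_that("fingerprints are invariant to rigid motion and atom order", {
  bz <- benzene_conformer()
  fp0 <- enumerate_triplets(assign_ppps(bz))
  # exact 90-degree rotation + translation
  rot <- bz
  rot$atoms[, c("x", "y", "z")] <- rigid_motion(bz$atoms[, c("x", "y", "z")])
  expect_equal(enumerate_triplets(assign_ppps(rot)), fp0)
  # atom permutation (relabel ring)
  perm <- c(3, 1, 2, 6, 4, 5)
  inv <- order(perm)
  pa <- bz$atoms[perm, ]; rownames(pa) <- NULL
  pb <- data.frame(a1 = inv[bz$bonds$a1], a2 = inv[bz$bonds$a2],
                   order = bz$bonds$order)
  expect_equal(enumerate_triplets(assign_ppps(conformer("benzene", pa, pb))), fp0)
  # point clouds under rigid motion
  cl <- gen_point_cloud_molecule(10, seed = 5)
  cl2 <- cl; cl2[, c("x", "y", "z")] <- rigid_motion(cl[, c("x", "y", "z")])
  expect_equal(enumerate_triplets(cl2), enumerate_triplets(cl))
})

test_that("modal fingerprint is the union of conformer fingerprints", {
  bz1 <- benzene_conformer()
  bz2 <- benzene_conformer(shift = c(30, 0, 0))  # same geometry, same keys
  et <- ethylamine_h_conformer("benzene")        # different keys, same id

  single <- modal_fingerprint(list(bz1))
  expect_s3_class(single, "ligfish_modal_fp")
  expect_equal(single$keys, enumerate_triplets(assign_ppps(bz1)))

  # duplication is idempotent, order irrelevant
  expect_equal(modal_fingerprint(list(bz1, bz1, bz1))$keys, single$keys)
  both <- modal_fingerprint(list(bz1, et))
  expect_equal(modal_fingerprint(list(et, bz1))$keys, both$keys)

  # union arithmetic against set oracle
  a <- enumerate_triplets(assign_ppps(bz1))
  b <- enumerate_triplets(assign_ppps(et))
  expect_equal(both$keys, sort(union(a, b)))
  expect_length(both$keys, length(union(a, b)))

  # monotonicity: adding a conformer never removes keys
  expect_true(all(single$keys %in% both$keys))

  expect_error(modal_fingerprint(list(bz1, ethylamine_h_conformer("other"))),
               class = "ligfish_schema_error")
})

test_that("SDF round trip: records group into capped conformer ensembles", {
  bz <- benzene_conformer()
  blocks <- c(
    lapply(1:12, function(i) {
      at <- bz$atoms
      at$z <- at$z + 0.1 * i  # distinct geometries
      make_molblock("benzene", at, bz$bonds)
    }),
    list(make_molblock("etnh3",
                       data.frame(element = c("C", "C", "N"),
                                  x = c(0, 1.5, 2.3), y = c(0, 0, 1.2), z = 0),
                       data.frame(a1 = c(1, 2), a2 = c(2, 3), order = c(1L, 1L)),
                       charges = data.frame(atom = 3, charge = 1))))
  f <- tempfile(fileext = ".sdf")
  write_sdf_records(blocks, f)
  confs <- read_sdf(f)
  expect_named(confs, c("benzene", "etnh3"))
  expect_length(confs$benzene, 10L)  # cap at 10, file order
  expect_equal(vapply(confs$benzene, function(cc) cc$conformer_index, integer(1)), 0:9)
  expect_equal(confs$etnh3[[1]]$atoms$charge, c(0L, 0L, 1L))
  fps <- modal_fingerprints(confs)
  expect_named(fps, c("benzene", "etnh3"))
  expect_true(length(fps$benzene) > 0)
  expect_error(read_sdf(file.path(f, "nope")), class = "ligfish_io_error")
})

test_that("fold export is deterministic and bounded", {
  keys <- enumerate_triplets(gen_point_cloud_molecule(8, seed = 2))
  fb <- fold_fingerprint(keys, 256L)
  expect_true(all(fb >= 0 & fb < 256))
  expect_equal(fb, fold_fingerprint(keys, 256L))
  expect_lte(length(fb), length(keys))
})
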