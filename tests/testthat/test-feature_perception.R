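test_that("ring perception finds the smallest set of smallest rings", {
  expect_length(ring_perception(make_benzene()), 1L)
  expect_length(ring_perception(make_benzene())[[1]], 6L)
  expect_identical(ring_perception(make_hexane()), list())

  # naphthalene connectivity: two fused six-membered rings
  edges <- cbind(c(1, 2, 3, 4, 5, 6, 1, 7, 8, 9, 10),
                 c(2, 3, 4, 5, 6, 1, 7, 8, 9, 10, 6))
  naph <- molecule3d("naphthalene",
                     data.frame(element = "C", charge = 0L,
                                x = stats::rnorm(10), y = stats::rnorm(10),
                                z = stats::rnorm(10)),
                     data.frame(a1 = edges[, 1], a2 = edges[, 2],
                                order = 1L, aromatic = TRUE))
  rings <- ring_perception(naph)

  # oracle: exhaustively enumerate every simple cycle of the 10-atom graph;
  # the minimum cycle basis must be the two shortest (size-6) cycles
  all_cycles <- enumerate_cycles(10, edges)
  sizes <- sort(lengths(all_cycles))
  expect_identical(sizes, c(6L, 6L, 10L))
  expect_length(rings, 2L)
  ring_keys <- sort(vapply(rings, function(r) paste(sort(r), collapse = ","),
                           ""))
  oracle_keys <- sort(vapply(all_cycles[lengths(all_cycles) == 6],
                             function(r) paste(sort(r), collapse = ","), ""))
  expect_identical(ring_keys, oracle_keys)
})

test_that("benzene yields one aromatic centroid at the ring centre", {
  f <- suppressWarnings(perceive_features(make_benzene()))
  arom <- f[f$kind == "aromatic", ]
  expect_equal(nrow(arom), 1L)
  expect_equal(unlist(arom[, c("x", "y", "z")]), c(0, 0, 0),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("planarity fallback flags only flat flag-free rings as aromatic", {
  flat <- make_benzene(flags = FALSE)
  f <- suppressWarnings(perceive_features(flat))
  expect_equal(sum(f$kind == "aromatic"), 1L)

  bent <- flat
  bent$atoms$z <- c(0, 0.4, 0, 0.4, 0, 0.4)  # chair-like pucker
  f2 <- suppressWarnings(perceive_features(bent))
  expect_equal(sum(f2$kind == "aromatic"), 0L)
})

test_that("methanol gives one donor on the oxygen and no hydrophobic point", {
  f <- perceive_features(make_methanol())
  expect_equal(sum(f$kind == "donor"), 1L)
  d <- f[f$kind == "donor", ]
  expect_equal(unlist(d[, c("x", "y", "z")]), c(1.43, 0, 0),
               ignore_attr = TRUE)
  # lone carbon is adjacent to O, and cluster size 1 < 3 anyway
  expect_equal(sum(f$kind == "hydrophobic"), 0L)
})

test_that("n-hexane gives exactly one hydrophobic centroid (hand-derived)", {
  hex <- make_hexane()
  f <- suppressWarnings(perceive_features(hex))
  expect_equal(sum(f$kind == "hydrophobic"), 1L)
  h <- f[f$kind == "hydrophobic", ]
  # maximal-cluster rule by hand: all six carbons form one cluster,
  # point at their centroid
  expect_equal(unlist(h[, c("x", "y", "z")]),
               colMeans(as.matrix(hex$atoms[, c("x", "y", "z")])),
               ignore_attr = TRUE)
})

test_that("donor count equals N/O atoms with an explicit H neighbour", {
  set.seed(11)
  for (rep in 1:20) {
    # random chain of C/N/O with H decorations
    n_heavy <- sample(3:8, 1)
    el <- sample(c("C", "N", "O"), n_heavy, replace = TRUE)
    atoms <- data.frame(element = el, charge = 0L,
                        x = cumsum(stats::runif(n_heavy, 1.2, 1.6)),
                        y = stats::runif(n_heavy), z = stats::runif(n_heavy))
    bonds <- data.frame(a1 = seq_len(n_heavy - 1), a2 = 2:n_heavy,
                        order = 1L, aromatic = FALSE)
    has_h <- stats::runif(n_heavy) < 0.5
    for (i in which(has_h)) {
      atoms <- rbind(atoms, data.frame(element = "H", charge = 0L,
                                       x = atoms$x[i] + 0.9, y = atoms$y[i],
                                       z = atoms$z[i] + 0.5))
      bonds <- rbind(bonds, data.frame(a1 = i, a2 = nrow(atoms), order = 1L,
                                       aromatic = FALSE))
    }
    mol <- molecule3d("rand", atoms, bonds)
    f <- suppressWarnings(perceive_features(mol))
    expect_equal(sum(f$kind == "donor"),
                 sum(el %in% c("N", "O") & has_h))
  }
})

test_that("feature positions are equivariant under rigid motion", {
  set.seed(5)
  lib <- gen_labeled_library(example_query(),
                             generator_spec(seed = 3, n_actives = 3,
                                            n_decoys = 3))
  for (mol in lib$molecules) {
    R <- random_rotation()
    t <- stats::rnorm(3, sd = 4)
    f0 <- suppressWarnings(perceive_features(mol))
    moved <- mol
    xyz <- rigid_transform_points(
      as.matrix(mol$atoms[, c("x", "y", "z")]), R, t)
    moved$atoms$x <- xyz[, 1]; moved$atoms$y <- xyz[, 2]
    moved$atoms$z <- xyz[, 3]
    f1 <- suppressWarnings(perceive_features(moved))
    expect_identical(f1$kind, f0$kind)
    expect_equal(as.matrix(f1[, c("x", "y", "z")]),
                 rigid_transform_points(as.matrix(f0[, c("x", "y", "z")]),
                                        R, t),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("hydrophobic clusters are disjoint by maximality", {
  set.seed(9)
  lib <- gen_labeled_library(example_query(),
                             generator_spec(seed = 9, n_actives = 5,
                                            n_decoys = 5))
  for (mol in lib$molecules) {
    f <- suppressWarnings(perceive_features(mol))
    hyd <- f$atoms[f$kind == "hydrophobic"]
    all_atoms <- unlist(hyd)
    expect_false(anyDuplicated(all_atoms) > 0)
  }
})
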