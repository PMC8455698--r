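test_that("pairwise distances match an element-wise brute-force oracle", {
  mol <- molecule("two", c("C", "H"), rbind(c(0, 0, 0), c(0, 0, 1.5)))
  D <- pairwise_distances(mol)
  expect_equal(D[1, 2], 1.5)
  expect_equal(D, t(D))
  expect_equal(diag(D), rep(0, 2), ignore_attr = TRUE)

  set.seed(42)
  coords <- matrix(stats::rnorm(18, sd = 2), 6)
  mol6 <- molecule("six", c("C", "C", "N", "O", "H", "H"), coords)
  D6 <- pairwise_distances(mol6)
  for (i in 1:6) for (j in 1:6) {
    expect_equal(D6[i, j], sqrt(sum((coords[i, ] - coords[j, ])^2)),
                 tolerance = 1e-12)
  }
})

test_that("covalent-radius bond perception finds textbook bonds", {
  h2 <- molecule("h2", c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.74)))
  bg <- infer_bonds(h2)
  expect_equal(nrow(bg$edges), 1L)   # 0.74 <= 1.3 * (0.31 + 0.31)

  # single-atom molecule: no edges, and no valid pairs at all
  one <- molecule("one", "O", matrix(c(0, 0, 0), 1))
  expect_equal(nrow(infer_bonds(one)$edges), 0L)

  eth <- ethane_ideal()
  bg_eth <- infer_bonds(eth)
  expect_equal(nrow(bg_eth$edges), 7L)   # 1 C-C + 6 C-H
  # brute-force over all pairs with the radius rule (H-H contacts excluded
  # by the one-bond-per-hydrogen rule)
  D <- pairwise_distances(eth)
  r <- GAANN_COVALENT_RADII[eth$elements]
  naive <- which(upper.tri(D) & D <= 1.3 * outer(r, r, "+"), arr.ind = TRUE)
  hh <- eth$elements[naive[, 1]] == "H" & eth$elements[naive[, 2]] == "H"
  expect_setequal(paste(bg_eth$edges[, 1], bg_eth$edges[, 2]),
                  paste(naive[!hh, 1], naive[!hh, 2]))

  # a hydrogen with two in-range heavy partners keeps only the shorter bond
  hb <- molecule("bridge", c("O", "H", "O"),
                 rbind(c(0, 0, 0), c(0, 0, 0.98), c(0, 0, 2.1)))
  bgh <- suppressWarnings(infer_bonds(hb))
  h_edges <- bgh$edges[bgh$edges[, 1] == 2 | bgh$edges[, 2] == 2, , drop = FALSE]
  expect_equal(nrow(h_edges), 1L)
  expect_true(all(h_edges == c(1, 2)))

  disc <- molecule("far", c("C", "C"), rbind(c(0, 0, 0), c(0, 0, 9)))
  expect_warning(infer_bonds(disc), "disconnected")
})

test_that("bond angles reproduce closed-form geometries", {
  lin <- molecule("lin", c("C", "C", "C"),
                  rbind(c(-1.5, 0, 0), c(0, 0, 0), c(1.5, 0, 0)))
  expect_equal(bond_angle(lin, 1, 2, 3), 180)
  perp <- molecule("perp", c("C", "C", "C"),
                   rbind(c(1.5, 0, 0), c(0, 0, 0), c(0, 1.5, 0)))
  expect_equal(bond_angle(perp, 1, 2, 3), 90)
  met <- methane_ideal()
  expect_equal(bond_angle(met, 2, 1, 3), acos(-1 / 3) * 180 / pi,
               tolerance = 1e-6)
  expect_equal(bond_angle(met, 2, 1, 3), 109.4712, tolerance = 1e-4)
  # symmetric in the outer arms
  expect_equal(bond_angle(met, 2, 1, 3), bond_angle(met, 3, 1, 2))
  dup <- molecule("dup", c("C", "H"), rbind(c(0, 0, 0), c(0, 0, 1)))
  expect_error(bond_angle(dup, 1, 1, 2), "zero-length")
})

test_that("dihedral angles are unsigned and match constructed conformers", {
  cis <- ethane_ideal(torsion = 0)
  expect_equal(dihedral_angle(cis, 3, 1, 2, 6), 0, tolerance = 1e-6)
  trans <- ethane_ideal(torsion = 180)
  expect_equal(dihedral_angle(trans, 3, 1, 2, 6), 180, tolerance = 1e-6)
  stag <- ethane_ideal(torsion = 60)
  expect_equal(dihedral_angle(stag, 3, 1, 2, 6), 60, tolerance = 1e-6)
  # reversal symmetry
  expect_equal(dihedral_angle(stag, 3, 1, 2, 6), dihedral_angle(stag, 6, 2, 1, 3))
  # collinear path arm: degenerate, absent
  lin <- molecule("lin", c("C", "C", "C", "H"),
                  rbind(c(0, 0, 0), c(1.5, 0, 0), c(3, 0, 0), c(4, 1, 0)))
  expect_true(is.na(dihedral_angle(lin, 1, 2, 3, 4)))
})

test_that("geometric angles follow the nearest-neighbour construction", {
  # three collinear atoms, coupled pair = the two ends
  lin <- molecule("lin", c("H", "C", "H"),
                  rbind(c(0, 0, 0), c(0, 0, 1.2), c(0, 0, 2.4)))
  ga <- geometric_angles(lin, 1, 3)
  expect_equal(ga[["angle0"]], 0)    # neighbour and partner on the same ray
  expect_equal(ga[["angle1"]], 0)

  # right-angle tripod: vertex atom's nearest neighbour sits perpendicular
  # to its coupled partner
  tripod <- molecule("tri", c("H", "C", "H"),
                     rbind(c(0, 0, 1.0), c(0, 0, 0), c(1.1, 0, 0)))
  expect_equal(geometric_angles(tripod, 2, 3)[["angle0"]], 90, tolerance = 1e-9)

  # two atoms only: both angles absent
  two <- molecule("two", c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.74)))
  expect_true(all(is.na(geometric_angles(two, 1, 2))))

  # brute-force nearest-neighbour + bond-angle composition on a toy geometry
  set.seed(7)
  for (rep in 1:5) {
    coords <- matrix(stats::rnorm(15, sd = 1.4), 5)
    mol <- molecule("toy", c("C", "H", "N", "H", "O"), coords)
    D <- pairwise_distances(mol)
    ga <- geometric_angles(mol, 2, 4)
    nn <- function(i) { d <- D[i, ]; d[i] <- Inf; which.min(d) }
    exp0 <- if (nn(2) == 4) NA_real_ else bf_angle(coords[4, ], coords[2, ], coords[nn(2), ])
    exp1 <- if (nn(4) == 2) NA_real_ else bf_angle(coords[2, ], coords[4, ], coords[nn(4), ])
    expect_equal(ga[["angle0"]], exp0, tolerance = 1e-9)
    expect_equal(ga[["angle1"]], exp1, tolerance = 1e-9)
  }
})

test_that("coupling paths are shortest, tie-broken, and bounded", {
  eth <- ethane_ideal()
  bg <- infer_bonds(eth)
  expect_equal(coupling_path(bg, 1, 2), c(1, 2))            # bonded pair
  expect_equal(coupling_path(bg, 3, 6), c(3, 1, 2, 6))      # H..H across C-C
  expect_length(coupling_path(bg, 3, 6), 4L)                # 3 bonds
  disc <- suppressWarnings(infer_bonds(
    molecule("far", c("C", "H"), rbind(c(0, 0, 0), c(0, 0, 9)))))
  expect_null(coupling_path(disc, 1, 2))
  # lexicographic tie-break: two equivalent middle atoms -> smaller index
  sq <- structure(list(n_atoms = 4L,
                       edges = rbind(c(1L, 2L), c(1L, 3L), c(2L, 4L), c(3L, 4L)),
                       lengths = rep(1, 4),
                       adj = list(c(2L, 3L), c(1L, 4L), c(1L, 4L), c(2L, 3L))),
                  class = "bond_graph")
  expect_equal(coupling_path(sq, 1, 4), c(1, 2, 4))
})

test_that("path length equals the declared bond count on generated molecules", {
  sim <- tiny_sim(n = 6, seed = 21)
  for (i in seq_len(nrow(sim$dataset$records))) {
    r <- sim$dataset$records[i, ]
    bg <- sim$bonds[[r$molecule_name]]
    p <- coupling_path(bg, r$atom_index_0 + 1L, r$atom_index_1 + 1L)
    expect_equal(length(p) - 1L, as.integer(substring(r$type, 1, 1)))
  }
})

test_that("distances and angles are invariant under rigid motion", {
  set.seed(11)
  for (rep in 1:20) {
    sim <- simulate_dataset(synthetic_config(n_molecules = 1, seed = 100 + rep))
    mol <- sim$dataset$molecules[[1]]
    R <- rand_rotation()
    moved <- rigid_move(mol, R, stats::rnorm(3, sd = 5))
    expect_equal(pairwise_distances(moved), pairwise_distances(mol),
                 tolerance = 1e-9)
    n <- length(mol$elements)
    ijk <- sample(n, 3)
    expect_equal(bond_angle(moved, ijk[1], ijk[2], ijk[3]),
                 bond_angle(mol, ijk[1], ijk[2], ijk[3]), tolerance = 1e-9)
    if (n >= 4) {
      abcd <- sample(n, 4)
      d1 <- dihedral_angle(mol, abcd[1], abcd[2], abcd[3], abcd[4])
      d2 <- dihedral_angle(moved, abcd[1], abcd[2], abcd[3], abcd[4])
      if (!is.na(d1)) expect_equal(d2, d1, tolerance = 1e-7)
    }
  }
})

test_that("angle packs populate the path angle matching the coupling order", {
  eth <- ethane_ideal(torsion = 60)
  bg <- infer_bonds(eth)
  ap3 <- angle_pack(eth, bg, 3, 6, 3L)
  expect_equal(ap3$cos_dihedral, cos(60 * pi / 180), tolerance = 1e-6)
  expect_true(is.na(ap3$cos_bond_angle))
  ap2 <- angle_pack(eth, bg, 3, 4, 2L)   # geminal H-C-H
  expect_true(is.na(ap2$cos_dihedral))
  expect_equal(ap2$cos_bond_angle, -1 / 3, tolerance = 1e-6)
  # declared N disagreeing with the realisable path: angle absent
  apx <- angle_pack(eth, bg, 3, 6, 2L)
  expect_true(is.na(apx$cos_bond_angle) && is.na(apx$cos_dihedral))
})
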