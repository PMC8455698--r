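# Synthetic Karplus-labelled molecules: random acyclic heavy-atom skeletons
# (C/N/O) with hydrogens filling standard valences, and coupling labels tied
# to the true geometry — 3J through a Karplus law in the dihedral cosine,
# 2J affine in the bond-angle cosine, 1J affine in the bond length. Angle
# sensitivity is therefore present in the labels by construction, which is
# what the desk-scale recovery experiments probe.

#' Karplus-style label coefficients
#'
#' Laws used by the generator (all Hz):
#' * 3-bond: `J = A cos^2(phi) + B cos(phi) + C` in the path dihedral `phi`;
#'   defaults `(7, -1, 5)`, the classic vicinal-HH constants, used here as
#'   arbitrary ground truth.
#' * 2-bond: `J = a2 + b2 cos(theta)` in the path bond angle.
#' * 1-bond: `J = a1 + b1 (d - 1)` in the bond length `d` (Angstrom).
#' * per-partner-element offsets keep the CH/NH/HH flavours of each bond
#'   count distinguishable.
#'
#' @param j3 numeric `(A, B, C)`.
#' @param j2 numeric `(a2, b2)`.
#' @param j1 numeric `(a1, b1)`.
#' @param offsets named numeric, offset added for partner element.
#' @return List of class `"karplus_coeffs"`.
#' @export
karplus_coeffs <- function(j3 = c(A = 7, B = -1, C = 5),
                           j2 = c(a = -10, b = 6),
                           j1 = c(a = 180, b = -60),
                           offsets = c(C = 0, N = -5, H = 3)) {
  structure(list(j3 = j3, j2 = j2, j1 = j1, offsets = offsets),
            class = "karplus_coeffs")
}

#' Synthetic dataset configuration
#'
#' @param n_molecules number of molecules to generate.
#' @param heavy_range integer length-2, range of heavy-atom (C/N/O) counts.
#' @param angle_jitter_sd sd (degrees) of the random rotation applied to
#'   each ideal substituent direction.
#' @param length_jitter_sd sd (Angstrom) of the Gaussian perturbation of
#'   each bond length. Real bond lengths vary with environment; a nonzero
#'   value keeps interatomic distances tie-free (so nearest-neighbour
#'   constructions are well defined) and gives the 1-bond couplings, which
#'   are affine in bond length, a nondegenerate label distribution.
#' @param coeffs a [karplus_coeffs()].
#' @param noise_sd Gaussian label noise sd (Hz).
#' @param keep_types optional character vector restricting the emitted
#'   coupling types (e.g. `"3JHH"`).
#' @param heavy_bond_length heavy-heavy bond length (Angstrom).
#' @param h_bond_length X-H bond length (Angstrom).
#' @param test_fraction molecule fraction held out by [make_dataset()].
#' @param seed RNG seed.
#' @return List of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_molecules = 100L, heavy_range = c(2L, 6L),
                             angle_jitter_sd = 5, length_jitter_sd = 0.02,
                             coeffs = karplus_coeffs(),
                             noise_sd = 0.5, keep_types = NULL,
                             heavy_bond_length = 1.5, h_bond_length = 1.09,
                             test_fraction = 0.2, seed = 1L) {
  if (n_molecules < 1L) stop("n_molecules must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (heavy_range[1L] < 1L || heavy_range[2L] < heavy_range[1L]) {
    stop("invalid heavy_range")
  }
  structure(list(n_molecules = as.integer(n_molecules),
                 heavy_range = as.integer(heavy_range),
                 angle_jitter_sd = angle_jitter_sd,
                 length_jitter_sd = length_jitter_sd, coeffs = coeffs,
                 noise_sd = noise_sd, keep_types = keep_types,
                 heavy_bond_length = heavy_bond_length,
                 h_bond_length = h_bond_length,
                 test_fraction = test_fraction, seed = as.integer(seed)),
            class = "synthetic_config")
}

.unit <- function(v) v / sqrt(sum(v^2))

.rand_unit <- function() {
  repeat {
    v <- stats::rnorm(3L)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

# rotate v by `deg` degrees about a random axis (Rodrigues)
.jitter_dir <- function(v, sd_deg) {
  if (sd_deg <= 0) return(v)
  ang <- stats::rnorm(1L, 0, sd_deg) * pi / 180
  ax <- .unit(.cross3(v, .rand_unit()))
  .unit(v * cos(ang) + .cross3(ax, v) * sin(ang) + ax * sum(ax * v) * (1 - cos(ang)))
}

# the three tetrahedral directions around `anchor` at a random azimuth
.tetra_slots <- function(anchor) {
  a <- .unit(anchor)
  ref <- if (abs(a[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- .unit(.cross3(a, ref))
  v <- .cross3(a, u)
  phi0 <- stats::runif(1L, 0, 2 * pi)
  ct <- cos(109.471 * pi / 180); st <- sin(109.471 * pi / 180)
  lapply(phi0 + c(0, 2, 4) * pi / 3, function(phi)
    .unit(ct * a + st * (cos(phi) * u + sin(phi) * v)))
}

#' Generate one random molecule
#'
#' Grows an acyclic heavy-atom (C/N/O) skeleton with tetrahedral substituent
#' slots at random torsion azimuths, then fills the remaining valences
#' (C 4, N 3, O 2) with hydrogens. Each placed direction is perturbed by a
#' random rotation of `angle_jitter_sd` degrees. Uses the current RNG
#' stream; the result comes with its ground-truth bond graph.
#'
#' @param config a [synthetic_config()].
#' @param name molecule name.
#' @return List with `molecule` (a [molecule()]) and `bonds` (a
#'   `"bond_graph"` of the true bonds).
#' @export
generate_molecule <- function(config = synthetic_config(), name = "synth") {
  for (try in 1:50) {
    out <- .generate_once(config, name)
    D <- pairwise_distances(out$molecule)
    if (min(D[upper.tri(D)]) >= 0.8) return(out)
  }
  stop("failed to generate a clash-free molecule in 50 attempts")
}

.generate_once <- function(config, name) {
  nh <- if (config$heavy_range[1L] == config$heavy_range[2L]) {
    config$heavy_range[1L]
  } else {
    sample(config$heavy_range[1L]:config$heavy_range[2L], 1L)
  }
  elements <- sample(c("C", "N", "O"), nh, replace = TRUE,
                     prob = c(0.7, 0.2, 0.1))
  val <- .GAANN_VALENCE[elements]
  coords <- matrix(0, nh, 3L)
  # free substituent direction slots and already-used bond directions
  slots <- vector("list", nh)
  used <- vector("list", nh)
  degree <- rep(0L, nh)
  edges <- matrix(0L, 0L, 2L)

  take_slot <- function(a) {
    if (!length(slots[[a]])) {
      anchor <- if (length(used[[a]])) used[[a]][[1L]] else .rand_unit()
      fresh <- .tetra_slots(anchor)
      # drop regenerated slots that collide with an existing bond direction
      if (length(used[[a]])) {
        ok <- vapply(fresh, function(s)
          all(vapply(used[[a]], function(u) sum(s * u), 0) < cos(45 * pi / 180)),
          TRUE)
        fresh <- fresh[ok]
      }
      if (!length(fresh)) fresh <- list(.rand_unit())
      slots[[a]] <<- fresh
    }
    s <- slots[[a]][[1L]]
    slots[[a]][[1L]] <<- NULL
    s
  }

  slots[[1L]] <- list(.rand_unit())
  for (a in seq_len(nh)[-1L]) {
    cand <- which(degree[seq_len(a - 1L)] < val[seq_len(a - 1L)])
    p <- if (length(cand) == 1L) cand else sample(cand, 1L)
    dir <- .jitter_dir(take_slot(p), config$angle_jitter_sd)
    blen <- config$heavy_bond_length +
      if (config$length_jitter_sd > 0) stats::rnorm(1L, 0, config$length_jitter_sd) else 0
    coords[a, ] <- coords[p, ] + dir * blen
    used[[p]] <- c(used[[p]], list(dir))
    used[[a]] <- list(-dir)
    degree[p] <- degree[p] + 1L
    degree[a] <- degree[a] + 1L
    edges <- rbind(edges, c(min(p, a), max(p, a)))
    slots[[a]] <- .tetra_slots(-dir)
  }

  # hydrogens fill the remaining valences
  h_coords <- list(); h_parent <- integer()
  for (a in seq_len(nh)) {
    nfree <- val[a] - degree[a]
    if (nfree <= 0L) next
    for (j in seq_len(nfree)) {
      dir <- .jitter_dir(take_slot(a), config$angle_jitter_sd)
      used[[a]] <- c(used[[a]], list(dir))
      hlen <- config$h_bond_length +
        if (config$length_jitter_sd > 0) stats::rnorm(1L, 0, config$length_jitter_sd) else 0
      h_coords[[length(h_coords) + 1L]] <- coords[a, ] + dir * hlen
      h_parent <- c(h_parent, a)
    }
  }

  n_all <- nh + length(h_parent)
  all_coords <- rbind(coords, do.call(rbind, h_coords))
  all_elements <- c(elements, rep("H", length(h_parent)))
  if (length(h_parent)) {
    edges <- rbind(edges, cbind(h_parent, nh + seq_along(h_parent)))
  }
  mol <- molecule(name, all_elements, all_coords)
  o <- order(edges[, 1L], edges[, 2L])
  edges <- edges[o, , drop = FALSE]
  adj <- rep(list(integer()), n_all)
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1L]; j <- edges[e, 2L]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  D <- pairwise_distances(mol)
  bonds <- structure(list(n_atoms = n_all, edges = unname(edges),
                          lengths = D[edges],
                          adj = lapply(adj, sort)),
                     class = "bond_graph")
  list(molecule = mol, bonds = bonds)
}

#' Label all couplings of a molecule
#'
#' Enumerates atom pairs whose bond path has length 1-3 and which contain at
#' least one hydrogen, derives the coupling type from the bond count and the
#' endpoint elements (pairs outside the eight supported types are skipped),
#' and labels each pair by the bond-count-appropriate law evaluated on the
#' true geometry, plus Gaussian noise. The hydrogen atom is placed at
#' `atom_index_0`.
#'
#' @param mol a [molecule()].
#' @param bonds the molecule's `"bond_graph"`.
#' @param coeffs a [karplus_coeffs()].
#' @param noise_sd Gaussian noise sd (Hz); uses the current RNG stream.
#' @return data.frame of coupling records (0-based indices, champs dialect).
#' @export
label_couplings <- function(mol, bonds, coeffs = karplus_coeffs(),
                            noise_sd = 0) {
  n <- length(mol$elements)
  D <- pairwise_distances(mol)
  rows <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ei <- mol$elements[i]; ej <- mol$elements[j]
      if (ei != "H" && ej != "H") next
      path <- coupling_path(bonds, i, j, 3L)
      if (is.null(path)) next
      nb <- length(path) - 1L
      a0 <- i; a1 <- j
      if (ej == "H" && ei != "H") { a0 <- j; a1 <- i }
      partner <- mol$elements[a1]
      type <- sprintf("%dJH%s", nb, partner)
      if (!type %in% GAANN_COUPLING_TYPES) next
      base <- if (nb == 3L) {
        dih <- dihedral_angle(mol, path[1L], path[2L], path[3L], path[4L])
        if (is.na(dih)) next
        cp <- cos(dih * pi / 180)
        coeffs$j3[1L] * cp^2 + coeffs$j3[2L] * cp + coeffs$j3[3L]
      } else if (nb == 2L) {
        ct <- cos(bond_angle(mol, path[1L], path[2L], path[3L]) * pi / 180)
        coeffs$j2[1L] + coeffs$j2[2L] * ct
      } else {
        coeffs$j1[1L] + coeffs$j1[2L] * (D[i, j] - 1)
      }
      scc <- base + coeffs$offsets[[partner]] +
        if (noise_sd > 0) stats::rnorm(1L, 0, noise_sd) else 0
      rows[[length(rows) + 1L]] <-
        data.frame(molecule_name = mol$name,
                   atom_index_0 = a0 - 1L, atom_index_1 = a1 - 1L,
                   type = type, scc = scc, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(molecule_name = character(), atom_index_0 = integer(),
                      atom_index_1 = integer(), type = character(),
                      scc = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Simulate a labelled coupling dataset
#'
#' Generates `config$n_molecules` molecules and their coupling labels,
#' seeded by `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return List with `dataset` (an [scc_dataset()]) and `bonds` (named list
#'   of ground-truth bond graphs).
#' @export
simulate_dataset <- function(config = synthetic_config()) {
  .local_seed(config$seed, {
    mols <- vector("list", config$n_molecules)
    bonds <- vector("list", config$n_molecules)
    recs <- vector("list", config$n_molecules)
    nms <- sprintf("synth_%05d", seq_len(config$n_molecules))
    for (i in seq_len(config$n_molecules)) {
      gm <- generate_molecule(config, name = nms[i])
      mols[[i]] <- gm$molecule
      bonds[[i]] <- gm$bonds
      recs[[i]] <- label_couplings(gm$molecule, gm$bonds, config$coeffs,
                                   config$noise_sd)
    }
    names(mols) <- nms
    names(bonds) <- nms
    records <- do.call(rbind, recs)
    if (!is.null(config$keep_types)) {
      keep <- records$type %in% config$keep_types
      records <- records[keep, , drop = FALSE]
      with_rec <- unique(records$molecule_name)
      mols <- mols[with_rec]
      bonds <- bonds[with_rec]
    }
    rownames(records) <- NULL
    records$id <- seq_len(nrow(records)) - 1L
    list(dataset = scc_dataset(mols, records), bonds = bonds)
  })
}

#' Write a simulated dataset in the champs CSV dialect
#'
#' Emits `structures.csv`, `train.csv` and `test.csv` under `dir`, with a
#' deterministic molecule-level train/test split (`test.csv` omits the label
#' column).
#'
#' @param config a [synthetic_config()].
#' @param dir output directory (created if needed).
#' @return Invisibly, a list with the three file paths and the split.
#' @export
make_dataset <- function(config = synthetic_config(), dir) {
  sim <- simulate_dataset(config)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mols <- sim$dataset$molecules
  nms <- names(mols)
  n_test <- max(1L, round(config$test_fraction * length(nms)))
  test_m <- .local_seed(config$seed + 1L, sample(nms, n_test))
  train_m <- setdiff(nms, test_m)
  rec <- sim$dataset$records
  paths <- list(structures = file.path(dir, "structures.csv"),
                train = file.path(dir, "train.csv"),
                test = file.path(dir, "test.csv"))
  write_structures_csv(mols, paths$structures)
  tr <- rec[rec$molecule_name %in% train_m, , drop = FALSE]
  te <- rec[rec$molecule_name %in% test_m, , drop = FALSE]
  utils::write.csv(data.frame(id = tr$id, molecule_name = tr$molecule_name,
                              atom_index_0 = tr$atom_index_0,
                              atom_index_1 = tr$atom_index_1, type = tr$type,
                              scalar_coupling_constant = tr$scc),
                   paths$train, row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(id = te$id, molecule_name = te$molecule_name,
                              atom_index_0 = te$atom_index_0,
                              atom_index_1 = te$atom_index_1, type = te$type),
                   paths$test, row.names = FALSE, quote = FALSE)
  invisible(c(paths, list(train_molecules = train_m, test_molecules = test_m)))
}
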