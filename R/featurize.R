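# Feature engineering: the four raw feature blocks (atom, directed bond,
# coupling edge, molecule), z-score normalisation statistics, and the
# feature-layout manifest. Electronic/magnetic descriptors (charges,
# shielding) are deliberately out of scope: the features are purely
# geometric and compositional.

#' Feature configuration
#'
#' @param d_model hidden width of node states (even, default 128).
#' @param normalize z-score the scale-bearing feature slots?
#' @param use_angle_features include the angle cosines + presence flags in
#'   the coupling-edge block? (`FALSE` is the "no angle features" ablation
#'   arm: the slots are zeroed and the flags cleared.)
#' @param use_angle_attention compute the Karplus-form bond-angle attention
#'   weight on bond messages? (`FALSE` sets every weight to 1.)
#' @return List of class `"feature_config"`.
#' @export
feature_config <- function(d_model = 128L, normalize = TRUE,
                           use_angle_features = TRUE,
                           use_angle_attention = TRUE) {
  d_model <- as.integer(d_model)
  if (d_model < 2L || d_model %% 2L != 0L) stop("d_model must be even and >= 2")
  structure(list(d_model = d_model, normalize = isTRUE(normalize),
                 use_angle_features = isTRUE(use_angle_features),
                 use_angle_attention = isTRUE(use_angle_attention)),
            class = "feature_config")
}

.pair_onehot_names <- function() {
  as.vector(outer(GAANN_ELEMENTS, GAANN_ELEMENTS,
                  function(a, b) paste0("pair_", a, b)))
}

#' Feature layout
#'
#' The documented slot-by-slot layout of the four raw feature blocks. Scale
#' flags mark the slots that are z-scored under normalisation (one-hots,
#' flags and cosines are exempt).
#'
#' @return List of four data.frames (`atom`, `bond`, `coupling`, `molecule`)
#'   with columns `slot` and `scale`.
#' @export
feature_layout <- function() {
  atom <- data.frame(
    slot = c(paste0("el_", GAANN_ELEMENTS), "degree", "nbr_dist_mean", "nbr_dist_min"),
    scale = c(rep(FALSE, 5L), TRUE, TRUE, TRUE))
  bond <- data.frame(
    slot = c("length", "inv_length", .pair_onehot_names(), "n_nbr_angles", "mean_cos_theta"),
    scale = c(TRUE, TRUE, rep(FALSE, 25L), TRUE, FALSE))
  coupling <- data.frame(
    slot = c(paste0("type_", GAANN_COUPLING_TYPES), "dist", "inv_dist", "inv_dist3",
             "cos_dihedral", "has_dihedral", "cos_bond_angle", "has_bond_angle",
             "cos_angle0", "has_angle0", "cos_angle1", "has_angle1"),
    scale = c(rep(FALSE, 8L), TRUE, TRUE, TRUE, rep(FALSE, 8L)))
  molecule <- data.frame(
    slot = c(paste0("n_", GAANN_ELEMENTS), "n_bonds", "mean_pair_dist"),
    scale = c(rep(TRUE, 5L), TRUE, TRUE))
  list(atom = atom, bond = bond, coupling = coupling, molecule = molecule)
}

.layout_hash <- function(layout) {
  s <- paste(unlist(lapply(layout, function(b) paste(b$slot, b$scale))), collapse = "|")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 97 + 1)) %% .Machine$integer.max)
}

#' Write the feature-layout manifest
#'
#' Serialises the slot names, widths and scale flags as JSON, for emission
#' alongside cached features or checkpoints.
#'
#' @param path output path.
#' @param layout a layout as from [feature_layout()].
#' @return `path`, invisibly.
#' @export
write_layout_manifest <- function(path, layout = feature_layout()) {
  obj <- list(hash = .layout_hash(layout),
              blocks = lapply(layout, function(b)
                list(width = nrow(b), slots = b$slot, scale = b$scale)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# per-molecule geometry + raw blocks
.featurize_molecule <- function(mol, bg) {
  n <- length(mol$elements)
  D <- pairwise_distances(mol)
  el_idx <- match(mol$elements, GAANN_ELEMENTS)

  atom <- matrix(0, n, 8L)
  atom[cbind(seq_len(n), el_idx)] <- 1
  deg <- vapply(bg$adj, length, 1L)
  atom[, 6L] <- deg
  for (i in seq_len(n)) {
    nb <- bg$adj[[i]]
    if (length(nb)) {
      atom[i, 7L] <- mean(D[i, nb])
      atom[i, 8L] <- min(D[i, nb])
    }
  }

  ne <- nrow(bg$edges)
  E <- 2L * ne
  tail <- integer(E); head <- integer(E)
  if (ne) {
    tail <- c(bg$edges[, 1L], bg$edges[, 2L])
    head <- c(bg$edges[, 2L], bg$edges[, 1L])
  }
  bond <- matrix(0, E, 29L)
  S1 <- numeric(E); S2 <- numeric(E); M <- integer(E)
  for (e in seq_len(E)) {
    w <- tail[e]; v <- head[e]
    len <- D[w, v]
    bond[e, 1L] <- len
    bond[e, 2L] <- 1 / len
    bond[e, 2L + (el_idx[v] - 1L) * 5L + el_idx[w]] <- 1
    others <- setdiff(bg$adj[[v]], w)
    M[e] <- length(others)
    if (M[e]) {
      ct <- vapply(others, function(u) cos(bond_angle(mol, w, v, u) * pi / 180), 0)
      S1[e] <- sum(ct)
      S2[e] <- sum(ct^2)
      bond[e, 28L] <- M[e]
      bond[e, 29L] <- S1[e] / M[e]
    }
  }
  list(atom = atom, tail = tail, head = head, bond = bond,
       S1 = S1, S2 = S2, M = M, D = D, n_atoms = n)
}

#' Featurize a coupling dataset
#'
#' Builds the four raw feature blocks for every molecule and coupling record:
#'
#' * atom: element one-hot (5), bond degree, mean and min bonded-neighbour
#'   distance;
#' * directed bond: length, 1/length, ordered endpoint-element pair one-hot
#'   (25), number of neighbouring bond angles M, mean cos(theta); each
#'   undirected bond yields two directed edges (messages flow into the head
#'   atom) and carries the list statistics of its neighbour angles at the
#'   head, which also drive the bond-angle attention weight;
#' * coupling edge: type one-hot (8), coupled-atom distance d, 1/d, 1/d^3,
#'   and the angle cosines (dihedral, path bond angle, geometric angle0/1)
#'   each with a presence flag (absent values are imputed as cosine 0 with
#'   flag 0, so records are never dropped);
#' * molecule: element counts (5), bond count, mean pairwise distance.
#'
#' @param dataset an [scc_dataset()].
#' @param bonds optional named list of `"bond_graph"` objects (one per
#'   molecule); inferred with [infer_bonds()] when `NULL`.
#' @param config a [feature_config()].
#' @return An object of class `"featurized_graphs"`.
#' @export
featurize <- function(dataset, bonds = NULL, config = feature_config()) {
  stopifnot(inherits(dataset, "scc_dataset"))
  mol_names <- names(dataset$molecules)
  if (is.null(bonds)) {
    bonds <- lapply(dataset$molecules, infer_bonds)
  }
  if (!all(mol_names %in% names(bonds))) stop("bonds list incomplete")

  mols <- vector("list", length(mol_names))
  names(mols) <- mol_names
  mol_feat <- matrix(0, length(mol_names), 7L)
  for (k in seq_along(mol_names)) {
    nm <- mol_names[k]
    mol <- dataset$molecules[[nm]]
    fm <- .featurize_molecule(mol, bonds[[nm]])
    mols[[k]] <- fm
    el_idx <- match(mol$elements, GAANN_ELEMENTS)
    mol_feat[k, 1:5] <- tabulate(el_idx, 5L)
    mol_feat[k, 6L] <- nrow(bonds[[nm]]$edges)
    mol_feat[k, 7L] <- if (fm$n_atoms > 1L) mean(fm$D[upper.tri(fm$D)]) else 0
  }

  rec <- dataset$records
  R <- nrow(rec)
  cpl <- matrix(0, R, 19L)
  records <- data.frame(molecule_name = character(R), type = character(R),
                        a0 = integer(R), a1 = integer(R), mol_id = integer(R),
                        y = numeric(R), id = integer(R),
                        stringsAsFactors = FALSE)
  if (R) {
    parsed <- parse_coupling_type(rec$type)
    records$molecule_name <- rec$molecule_name
    records$type <- rec$type
    records$a0 <- rec$atom_index_0 + 1L
    records$a1 <- rec$atom_index_1 + 1L
    records$mol_id <- match(rec$molecule_name, mol_names)
    records$y <- rec$scc
    records$id <- rec$id
    for (i in seq_len(R)) {
      mid <- records$mol_id[i]
      mol <- dataset$molecules[[mid]]
      fm <- mols[[mid]]
      a0 <- records$a0[i]; a1 <- records$a1[i]
      d <- fm$D[a0, a1]
      cpl[i, match(rec$type[i], GAANN_COUPLING_TYPES)] <- 1
      cpl[i, 9L] <- d
      cpl[i, 10L] <- 1 / d
      cpl[i, 11L] <- 1 / d^3
      if (config$use_angle_features) {
        ap <- angle_pack(mol, bonds[[mid]], a0, a1, parsed$n_bonds[i], D = fm$D)
        vals <- unlist(ap, use.names = FALSE)
        pres <- as.numeric(!is.na(vals))
        vals[is.na(vals)] <- 0
        cpl[i, c(12L, 14L, 16L, 18L)] <- vals
        cpl[i, c(13L, 15L, 17L, 19L)] <- pres
      }
    }
  }

  structure(list(layout = feature_layout(),
                 mol_names = mol_names,
                 mols = mols,
                 mol_feat = mol_feat,
                 records = records,
                 cpl = cpl,
                 config = config,
                 normalized = FALSE),
            class = "featurized_graphs")
}

#' Normalisation statistics of a featurized dataset
#'
#' Per-slot means and standard deviations of the scale-flagged slots,
#' computed over all rows of each block (to be computed on the training set
#' and stored with the model). Non-scaled slots get mean 0 / sd 1.
#'
#' @param fg a `"featurized_graphs"` object.
#' @return List of per-block `mean` and `sd` vectors.
#' @export
feature_stats <- function(fg) {
  blockwise <- function(X, scale_flags) {
    mu <- rep(0, ncol(X)); sd <- rep(1, ncol(X))
    if (nrow(X)) {
      idx <- which(scale_flags)
      mu[idx] <- colMeans(X[, idx, drop = FALSE])
      s <- apply(X[, idx, drop = FALSE], 2L, stats::sd)
      s[!is.finite(s) | s < 1e-12] <- 1
      sd[idx] <- s
    }
    list(mean = mu, sd = sd)
  }
  atom_all <- do.call(rbind, lapply(fg$mols, `[[`, "atom"))
  bond_all <- do.call(rbind, lapply(fg$mols, `[[`, "bond"))
  list(atom = blockwise(atom_all, fg$layout$atom$scale),
       bond = blockwise(bond_all, fg$layout$bond$scale),
       coupling = blockwise(fg$cpl, fg$layout$coupling$scale),
       molecule = blockwise(fg$mol_feat, fg$layout$molecule$scale))
}

#' Apply normalisation statistics
#'
#' @param fg a `"featurized_graphs"` object.
#' @param stats statistics from [feature_stats()] (typically computed on the
#'   training split).
#' @return The normalised `"featurized_graphs"` object.
#' @export
normalize_features <- function(fg, stats) {
  zs <- function(X, st) sweep(sweep(X, 2L, st$mean, "-"), 2L, st$sd, "/")
  fg$mols <- lapply(fg$mols, function(fm) {
    fm$atom <- zs(fm$atom, stats$atom)
    fm$bond <- zs(fm$bond, stats$bond)
    fm
  })
  fg$cpl <- zs(fg$cpl, stats$coupling)
  fg$mol_feat <- zs(fg$mol_feat, stats$molecule)
  fg$normalized <- TRUE
  fg
}

#' Embed raw feature blocks to model dimensions
#'
#' Applies a parameter set's learned linear maps to one molecule's raw
#' blocks: atoms to length-`d_model` node states, directed bond and
#' coupling edges to `d_model x d_model/2` edge state matrices (the linear
#' output is reshaped row-major: element `(r, c)` of the matrix is output
#' slot `r * d_model/2 + c`), and the molecule block to the length-
#' `d_model/2` molecule feature.
#'
#' @param fg a `"featurized_graphs"` object.
#' @param params a `"gaann_params"` parameter set (see [gaann_init()]).
#' @param molecule_name molecule to embed (default: the first).
#' @return List with `node_states` (`n x d_model` matrix), `bond_edges`
#'   (list of `d_model x d_model/2` matrices, one per directed bond),
#'   `coupling_edges` (one per directed coupling edge: each record
#'   contributes both directions), and `f_mol` (length `d_model/2`).
#' @export
embed_features <- function(fg, params, molecule_name = fg$mol_names[1L]) {
  mi <- match(molecule_name, fg$mol_names)
  if (is.na(mi)) stop("unknown molecule: ", molecule_name)
  fm <- fg$mols[[mi]]
  d <- ncol(params$Wa); k <- d %/% 2L
  H <- sweep(fm$atom %*% params$Wa, 2L, params$ba, "+")
  blin <- sweep(fm$bond %*% params$Wb, 2L, params$bb, "+")
  bond_edges <- lapply(seq_len(nrow(blin)), function(e)
    matrix(blin[e, ], d, k, byrow = TRUE))
  rid <- which(fg$records$mol_id == mi)
  clin <- sweep(fg$cpl[rid, , drop = FALSE] %*% params$Wc, 2L, params$bc, "+")
  cpl_edges <- lapply(c(seq_along(rid), seq_along(rid)), function(e)
    matrix(clin[e, ], d, k, byrow = TRUE))
  list(node_states = H, bond_edges = bond_edges,
       coupling_edges = cpl_edges,
       f_mol = drop(fg$mol_feat[mi, ] %*% params$Wm) + params$bm)
}
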