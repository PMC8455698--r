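# Interatomic geometry: distance matrices, covalent-radius bond perception,
# bond/dihedral angles and the nearest-neighbour "geometric angles" used as
# coupling-edge features. Atom indices here are 1-based (R convention).

.cross3 <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

.clamp1 <- function(x) pmin(1, pmax(-1, x))

#' Pairwise interatomic distances
#'
#' @param mol a [molecule()].
#' @return Symmetric `n x n` matrix of Euclidean distances (Angstrom), zero
#'   diagonal.
#' @export
pairwise_distances <- function(mol) {
  as.matrix(stats::dist(mol$coords))
}

#' Infer chemical bonds from covalent radii
#'
#' Atoms `i`, `j` are bonded iff `d(i,j) <= scale * (r_i + r_j)`. Hydrogen is
#' limited to one bond (the shortest candidate is kept). A disconnected
#' molecule triggers a warning, not an error.
#'
#' @param mol a [molecule()].
#' @param radii named covalent radius table (Angstrom); defaults to
#'   [GAANN_COVALENT_RADII].
#' @param scale cutoff scale factor (default 1.3).
#' @return An object of class `"bond_graph"`: list with `n_atoms`, `edges`
#'   (`m x 2` matrix, `i < j`, 1-based), `lengths` (Angstrom) and `adj`
#'   (adjacency list of sorted neighbour indices).
#' @export
infer_bonds <- function(mol, radii = GAANN_COVALENT_RADII, scale = 1.3) {
  n <- length(mol$elements)
  r <- unname(radii[mol$elements])
  if (anyNA(r)) stop("missing covalent radius for some element")
  if (scale <= 0) stop("scale must be positive")
  D <- pairwise_distances(mol)
  cutoff <- outer(r, r, "+") * scale
  cand <- which(upper.tri(D) & D <= cutoff, arr.ind = TRUE)
  if (nrow(cand)) {
    len <- D[cand]
    # hydrogen keeps only its shortest candidate bond
    keep <- rep(TRUE, nrow(cand))
    for (h in which(mol$elements == "H")) {
      inv <- which(cand[, 1L] == h | cand[, 2L] == h)
      if (length(inv) > 1L) {
        best <- inv[order(len[inv], pmax(cand[inv, 1L], cand[inv, 2L]))][1L]
        keep[setdiff(inv, best)] <- FALSE
      }
    }
    cand <- cand[keep, , drop = FALSE]
    len <- len[keep]
    o <- order(cand[, 1L], cand[, 2L])
    cand <- cand[o, , drop = FALSE]
    len <- len[o]
  } else {
    len <- numeric()
  }
  adj <- rep(list(integer()), n)
  for (e in seq_len(nrow(cand))) {
    i <- cand[e, 1L]; j <- cand[e, 2L]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj <- lapply(adj, sort)
  bg <- structure(list(n_atoms = n,
                       edges = unname(cand[, 1:2, drop = FALSE]),
                       lengths = unname(len),
                       adj = adj),
                  class = "bond_graph")
  if (n > 1L && !.bg_connected(bg)) {
    warning("molecule '", mol$name, "' is disconnected under the bond cutoff")
  }
  bg
}

.bg_connected <- function(bg) {
  n <- bg$n_atoms
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- bg$adj[[v]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}

#' @export
print.bond_graph <- function(x, ...) {
  cat("<bond_graph> ", x$n_atoms, " atoms, ", nrow(x$edges), " bonds\n", sep = "")
  invisible(x)
}

#' Bond angle at a vertex
#'
#' Angle between the arms `j -> i` and `j -> k`.
#'
#' @param mol a [molecule()].
#' @param i,j,k 1-based atom indices, `j` is the vertex.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
bond_angle <- function(mol, i, j, k) {
  u <- mol$coords[i, ] - mol$coords[j, ]
  v <- mol$coords[k, ] - mol$coords[j, ]
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-12 || nv < 1e-12) stop("zero-length arm in bond_angle")
  acos(.clamp1(sum(u * v) / (nu * nv))) * 180 / pi
}

#' Unsigned dihedral angle
#'
#' Angle between the plane through atoms `(a, b, c)` and the plane through
#' `(b, c, d)`, computed from plane normals. Unsigned (range `[0, 180]`):
#' Karplus-type relations involve only `cos` of the dihedral, so the sign is
#' information-free here. Degenerate geometry (collinear arms) yields `NA`.
#'
#' @param mol a [molecule()].
#' @param a,b,c,d 1-based atom indices along the bond path.
#' @return Angle in degrees in `[0, 180]`, or `NA_real_` when degenerate.
#' @export
dihedral_angle <- function(mol, a, b, c, d) {
  p <- mol$coords
  b1 <- p[b, ] - p[a, ]
  b2 <- p[c, ] - p[b, ]
  b3 <- p[d, ] - p[c, ]
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  m1 <- sqrt(sum(n1^2)); m2 <- sqrt(sum(n2^2))
  if (m1 < 1e-10 || m2 < 1e-10) return(NA_real_)
  acos(.clamp1(sum(n1 * n2) / (m1 * m2))) * 180 / pi
}

#' Geometric angles of a coupled atom pair
#'
#' For coupled atoms `i0`, `i1`: `angle0` is centred at `i0` with arms to
#' `i1` and to `i0`'s nearest atom (by distance); `angle1` swaps the roles
#' (centred at `i1`, arms to `i0` and `i1`'s nearest atom). An angle is `NA`
#' when the nearest neighbour coincides with the coupled partner or the
#' molecule has fewer than 3 atoms.
#'
#' @param mol a [molecule()].
#' @param i0,i1 1-based atom indices of the coupled pair.
#' @param D optional precomputed distance matrix.
#' @return Named numeric vector `c(angle0 =, angle1 =)` in degrees.
#' @export
geometric_angles <- function(mol, i0, i1, D = NULL) {
  n <- length(mol$elements)
  if (n < 3L) return(c(angle0 = NA_real_, angle1 = NA_real_))
  if (is.null(D)) D <- pairwise_distances(mol)
  nearest <- function(i) {
    d <- D[i, ]
    d[i] <- Inf
    which.min(d)  # ties: smallest index
  }
  nn0 <- nearest(i0)
  nn1 <- nearest(i1)
  a0 <- if (nn0 == i1) NA_real_ else bond_angle(mol, i1, i0, nn0)
  a1 <- if (nn1 == i0) NA_real_ else bond_angle(mol, i0, i1, nn1)
  c(angle0 = a0, angle1 = a1)
}

#' Shortest bond path between two atoms
#'
#' Exhaustive shortest-path search on the bond graph up to `max_len` bonds
#' (the coupling-type bond counts are 1-3). Ties are broken by the
#' lexicographically smallest intermediate index sequence.
#'
#' @param bonds a `"bond_graph"`.
#' @param i0,i1 1-based atom indices.
#' @param max_len maximum path length in bonds (default 3).
#' @return Integer vector of atom indices from `i0` to `i1`, or `NULL` when
#'   no path of length `<= max_len` exists.
#' @export
coupling_path <- function(bonds, i0, i1, max_len = 3L) {
  adj <- bonds$adj
  if (i1 %in% adj[[i0]]) return(c(i0, i1))
  if (max_len < 2L) return(NULL)
  mid <- sort(intersect(adj[[i0]], adj[[i1]]))
  mid <- setdiff(mid, c(i0, i1))
  if (length(mid)) return(c(i0, mid[1L], i1))
  if (max_len < 3L) return(NULL)
  for (x in sort(adj[[i0]])) {
    if (x == i1) next
    for (y in sort(adj[[x]])) {
      if (y == i0 || y == x || y == i1) next
      if (i1 %in% adj[[y]]) return(c(i0, x, y, i1))
    }
  }
  if (max_len > 3L) {
    stop("coupling_path supports max_len <= 3")
  }
  NULL
}

#' Angle features of one coupling record
#'
#' Computes the cosines entering the coupling-edge feature block: the
#' dihedral cosine (3-bond couplings), the path bond-angle cosine (2-bond
#' couplings) and the two nearest-neighbour geometric-angle cosines. The
#' declared bond count of the coupling type decides which path angle is
#' populated; when the bond-graph path disagrees with the declared count the
#' path angle is absent (`NA`) rather than the record dropped.
#'
#' @param mol a [molecule()].
#' @param bonds a `"bond_graph"` for `mol`.
#' @param i0,i1 1-based atom indices of the coupled pair.
#' @param n_bonds declared bond count of the coupling type (1, 2 or 3).
#' @param D optional precomputed distance matrix.
#' @return List with `cos_dihedral`, `cos_bond_angle`, `cos_angle0`,
#'   `cos_angle1` (each a scalar, possibly `NA`).
#' @export
angle_pack <- function(mol, bonds, i0, i1, n_bonds, D = NULL) {
  path <- coupling_path(bonds, i0, i1, 3L)
  cos_dih <- NA_real_
  cos_ba <- NA_real_
  if (!is.null(path) && length(path) - 1L == n_bonds) {
    if (n_bonds == 3L) {
      dih <- dihedral_angle(mol, path[1L], path[2L], path[3L], path[4L])
      if (!is.na(dih)) cos_dih <- cos(dih * pi / 180)
    } else if (n_bonds == 2L) {
      cos_ba <- cos(bond_angle(mol, path[1L], path[2L], path[3L]) * pi / 180)
    }
  }
  ga <- geometric_angles(mol, i0, i1, D = D)
  list(cos_dihedral = cos_dih,
       cos_bond_angle = cos_ba,
       cos_angle0 = if (is.na(ga[["angle0"]])) NA_real_ else cos(ga[["angle0"]] * pi / 180),
       cos_angle1 = if (is.na(ga[["angle1"]])) NA_real_ else cos(ga[["angle1"]] * pi / 180))
}
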