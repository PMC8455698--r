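# Shared fixtures: ideal geometries built from first principles, independent
# brute-force oracles, and small simulated datasets.

# ideal ethane: C-C along +z, tetrahedral hydrogens; `torsion` sets the
# dihedral (degrees) between the first H on each carbon
ethane_ideal <- function(torsion = 60, cc = 1.54, ch = 1.09) {
  tet <- 109.4712206
  dz <- cos(tet * pi / 180)      # -1/3
  dr <- sin(tet * pi / 180)
  c1 <- c(0, 0, 0); c2 <- c(0, 0, cc)
  h <- function(center, phi_deg, zsign) {
    phi <- phi_deg * pi / 180
    center + ch * c(dr * cos(phi), dr * sin(phi), zsign * -dz)
  }
  coords <- rbind(c1, c2,
                  h(c1, 0, 1), h(c1, 120, 1), h(c1, 240, 1),
                  h(c2, torsion, -1), h(c2, torsion + 120, -1),
                  h(c2, torsion + 240, -1))
  molecule("ethane", c("C", "C", rep("H", 6)), coords)
}

# methane: C at origin, ideal tetrahedral H's
methane_ideal <- function(ch = 1.09) {
  dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  molecule("methane", c("C", rep("H", 4)), rbind(c(0, 0, 0), ch * dirs))
}

# signed-dihedral oracle via the atan2 formulation (independent of the
# package's normal-vector route); returns the unsigned angle in degrees
bf_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                         u[3] * v[1] - u[1] * v[3],
                         u[1] * v[2] - u[2] * v[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  m1 <- cr(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  abs(atan2(y, x) * 180 / pi)
}

bf_angle <- function(p1, p2, p3) {
  u <- p1 - p2; v <- p3 - p2
  acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
}

# average-rank computation by direct counting (O(n^2)), for the Spearman
# tie-handling oracle
bf_avg_rank <- function(x) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    1 + sum(x < x[i]) + (sum(x == x[i]) - 1) / 2
  }, 0)
}

bf_spearman <- function(x, y) {
  rx <- bf_avg_rank(x); ry <- bf_avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# a proper random rotation matrix
rand_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# apply a rigid motion to a molecule
rigid_move <- function(mol, R, t) {
  molecule(mol$name, mol$elements, mol$coords %*% t(R) +
             matrix(t, nrow(mol$coords), 3, byrow = TRUE))
}

tiny_sim <- function(n = 6, seed = 5, ...) {
  simulate_dataset(synthetic_config(n_molecules = n, seed = seed, ...))
}

small_mcfg <- function(d = 16, h = 2, seed = 1, ...) {
  model_config(d_model = d, heads = h, T_mp = 2,
               decoder_hidden = c(16L, 8L), seed = seed, ...)
}

# reference (un-batched) recomputation of the engine forward pass, built
# from the exported single-record operations; used to pin the compiled
# batched path to the documented contracts
reference_forward <- function(params, fg, mcfg) {
  d <- mcfg$d_model; k <- d %/% 2L
  preds <- rep(NA_real_, nrow(fg$records))
  conv_b <- list(weights = params$convA_b, bias = params$convb_b)
  conv_c <- list(weights = params$convA_c, bias = params$convb_c)
  mlp <- list(weights = lapply(seq_len(attr(params, "n_dec")),
                               function(l) params[[paste0("dec_W", l)]]),
              biases = lapply(seq_len(attr(params, "n_dec")),
                              function(l) params[[paste0("dec_b", l)]]))
  for (mi in seq_along(fg$mol_names)) {
    fm <- fg$mols[[mi]]
    rid <- which(fg$records$mol_id == mi)
    if (!length(rid)) next
    H <- sweep(fm$atom %*% params$Wa, 2L, params$ba, "+")
    blin <- sweep(fm$bond %*% params$Wb, 2L, params$bb, "+")
    bond_mats <- lapply(seq_len(nrow(blin)), function(e)
      matrix(blin[e, ], d, k, byrow = TRUE))
    attn <- ifelse(fm$M > 0,
                   (params$attn_coef[1] * fm$S2 + params$attn_coef[2] * fm$S1 +
                    params$attn_coef[3] * fm$M) / pmax(fm$M, 1), 1)
    if (!fg$config$use_angle_attention) attn <- rep(1, length(attn))
    a0 <- fg$records$a0[rid]; a1 <- fg$records$a1[rid]
    clin <- sweep(fg$cpl[rid, , drop = FALSE] %*% params$Wc, 2L, params$bc, "+")
    cpl_mats <- c(lapply(seq_along(rid), function(e)
                    matrix(clin[e, ], d, k, byrow = TRUE)),
                  lapply(seq_along(rid), function(e)
                    matrix(clin[e, ], d, k, byrow = TRUE)))
    ctail <- c(a0, a1); chead <- c(a1, a0)
    for (t in seq_len(mcfg$T_mp)) {
      H <- bond_mp_step(H, fm$tail, fm$head, bond_mats, attn, conv_b)
      H <- coupling_mp_step(H, ctail, chead, cpl_mats, conv_c)
    }
    toks <- sort(unique(c(a0, a1)))
    scale <- if (mcfg$scale_per_head) sqrt(d / mcfg$heads) else sqrt(d)
    Ftok <- H[toks, , drop = FALSE] +
      multi_head_attention(H[toks, , drop = FALSE],
                           list(Wq = params$Wq, Wk = params$Wk,
                                Wv = params$Wv, Wo = params$Wo),
                           mcfg$heads, scale = scale)
    fmol <- drop(fg$mol_feat[mi, ] %*% params$Wm) + params$bm
    for (j in seq_along(rid)) {
      fedge <- drop(fg$cpl[rid[j], ] %*% params$We) + params$be
      preds[rid[j]] <- decode_scc(Ftok[match(a0[j], toks), ],
                                  Ftok[match(a1[j], toks), ],
                                  fmol, mlp, f_edge = fedge)
    }
  }
  preds
}
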