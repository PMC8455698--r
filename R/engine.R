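# Batched forward/backward engine. Molecules in a batch are merged into one
# block-diagonal graph; each message-passing step (unfold of the tail
# states, Conv, elementwise product with the edge states, attention scaling,
# head-atom accumulation) runs as one fused compiled kernel over all
# directed edges. Self-attention is computed per molecule (attention never
# crosses molecules). Gradients are analytic; a finite-difference test pins
# every parameter block.

.local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.runif_mat <- function(nr, nc, fan_in, gain = 1) {
  s <- gain * sqrt(3) / sqrt(fan_in)
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

#' Initialise model parameters
#'
#' Uniform fan-in-scaled initialisation; the three bond-angle attention
#' coefficients start at `config$attn_init`. All randomness flows from
#' `config$seed`.
#'
#' @param config a [model_config()].
#' @param layout feature layout (defaults to [feature_layout()]).
#' @return Named list of parameter arrays (class `"gaann_params"`).
#' @export
gaann_init <- function(config, layout = feature_layout()) {
  d <- config$d_model; k <- d %/% 2L
  Fa <- nrow(layout$atom); Fb <- nrow(layout$bond)
  Fc <- nrow(layout$coupling); Fm <- nrow(layout$molecule)
  dec_in <- 2L * d + 2L * k
  sizes <- c(dec_in, config$decoder_hidden, 1L)
  .local_seed(config$seed, {
    p <- list(
      Wa = .runif_mat(Fa, d, Fa), ba = rep(0, d),
      # edge embeddings feed multiplicative messages; the gain balances the
      # residual stream against the message stream at initialisation
      Wb = .runif_mat(Fb, d * k, Fb, gain = config$edge_gain), bb = rep(0, d * k),
      Wc = .runif_mat(Fc, d * k, Fc, gain = config$edge_gain), bc = rep(0, d * k),
      convA_b = .runif_mat(k, k, k), convb_b = rep(0, k),
      convA_c = .runif_mat(k, k, k), convb_c = rep(0, k),
      attn_coef = as.numeric(config$attn_init),
      Wq = .runif_mat(d, d, d), Wk = .runif_mat(d, d, d),
      Wv = .runif_mat(d, d, d), Wo = .runif_mat(d, d, d),
      Wm = .runif_mat(Fm, k, Fm), bm = rep(0, k),
      # summary of the record's own coupling-edge features for the decoder
      We = .runif_mat(Fc, k, Fc), be = rep(0, k)
    )
    nlay <- length(sizes) - 1L
    for (l in seq_len(nlay)) {
      # zero-init the scalar output layer: optimisation starts from the
      # per-type mean prediction instead of an arbitrary large output
      p[[paste0("dec_W", l)]] <- if (l == nlay) {
        matrix(0, sizes[l], sizes[l + 1L])
      } else .runif_mat(sizes[l], sizes[l + 1L], sizes[l])
      p[[paste0("dec_b", l)]] <- rep(0, sizes[l + 1L])
    }
    structure(p, class = "gaann_params", n_dec = length(sizes) - 1L)
  })
}

# per-type target standardisation: the decoder learns on z-scored labels
# and predictions are mapped back to Hz. log(MAE_t / sd_t) = log(MAE_t) -
# log(sd_t), so the grouped training objective only shifts by a constant
# while the optimisation becomes well-conditioned across types.
.target_stats <- function(types, y) {
  ok <- !is.na(y)
  tys <- sort(unique(types[ok]))
  mu <- vapply(tys, function(t) mean(y[ok & types == t]), 0)
  sd <- vapply(tys, function(t) stats::sd(y[ok & types == t]), 0)
  sd[!is.finite(sd) | sd < 1e-8] <- 1
  list(types = tys, mean = mu, sd = sd,
       global_mean = mean(y[ok]), global_sd = max(stats::sd(y[ok]), 1e-8))
}

.target_map <- function(types, tstats) {
  if (is.null(tstats)) {
    return(list(mean = rep(0, length(types)), sd = rep(1, length(types))))
  }
  i <- match(types, tstats$types)
  m <- ifelse(is.na(i), tstats$global_mean, tstats$mean[i])
  s <- ifelse(is.na(i), tstats$global_sd, tstats$sd[i])
  list(mean = m, sd = s)
}

# merge a set of molecules (by position in fg$mol_names) into one batch
.build_batch <- function(fg, mol_ids, d, tstats = NULL) {
  k <- d %/% 2L
  mols <- fg$mols[mol_ids]
  n_at <- vapply(mols, `[[`, 1L, "n_atoms")
  offset <- c(0L, cumsum(n_at))[seq_along(mols)]
  A <- do.call(rbind, lapply(mols, `[[`, "atom"))
  n <- sum(n_at)

  b_tail <- integer(); b_head <- integer()
  for (i in seq_along(mols)) {
    b_tail <- c(b_tail, mols[[i]]$tail + offset[i])
    b_head <- c(b_head, mols[[i]]$head + offset[i])
  }
  Xb <- do.call(rbind, lapply(mols, `[[`, "bond"))
  S1 <- unlist(lapply(mols, `[[`, "S1"), use.names = FALSE)
  S2 <- unlist(lapply(mols, `[[`, "S2"), use.names = FALSE)
  M  <- unlist(lapply(mols, `[[`, "M"), use.names = FALSE)

  rid <- which(fg$records$mol_id %in% mol_ids)
  rec <- fg$records[rid, , drop = FALSE]
  loc_mol <- match(rec$mol_id, mol_ids)
  a0 <- rec$a0 + offset[loc_mol]
  a1 <- rec$a1 + offset[loc_mol]
  Xc <- fg$cpl[rid, , drop = FALSE]
  # two directed coupling edges per record, sharing the record's features
  c_tail <- c(a0, a1); c_head <- c(a1, a0)
  Xc2 <- rbind(Xc, Xc)

  tok_atoms <- sort(unique(c(a0, a1)))
  tok_of <- integer(n); tok_of[tok_atoms] <- seq_along(tok_atoms)
  tok_mol <- findInterval(tok_atoms - 1L, cumsum(n_at), left.open = FALSE) + 1L
  tok_ranges <- split(seq_along(tok_atoms), tok_mol)

  tm <- .target_map(rec$type, tstats)
  list(n = n, A = A,
       b_tail = b_tail, b_head = b_head, Xb = Xb, S1 = S1, S2 = S2, M = M,
       c_tail = c_tail, c_head = c_head, Xc2 = Xc2,
       rid = rid, y = rec$y, types = rec$type, Xc = Xc,
       t_mean = tm$mean, t_sd = tm$sd,
       rec_t0 = tok_of[a0], rec_t1 = tok_of[a1], rec_mol = loc_mol,
       tok_atoms = tok_atoms, tok_ranges = tok_ranges,
       Xm = fg$mol_feat[mol_ids, , drop = FALSE])
}

# edge embedding: E x d*k, row-major slots per edge (slot r*k + c holds
# element (r, c) of the edge's d x d/2 state matrix)
.edge_embed <- function(X, W, b) {
  lin <- X %*% W
  sweep(lin, 2L, b, "+")
}

# full pipeline on one batch; returns predictions and (optionally) a cache
# for the backward pass
.engine_forward <- function(params, batch, mcfg, use_angle_attention = TRUE,
                            keep = FALSE) {
  d <- mcfg$d_model; k <- d %/% 2L; h <- mcfg$heads
  scale <- if (mcfg$scale_per_head) sqrt(d / h) else sqrt(d)
  Tmp <- mcfg$T_mp
  n <- batch$n

  H <- batch$A %*% params$Wa
  H <- sweep(H, 2L, params$ba, "+")
  H0 <- H

  # edge embeddings, transposed once to (d*k x E) for the kernels
  EbT <- if (length(batch$b_tail)) {
    t(.edge_embed(batch$Xb, params$Wb, params$bb))
  } else matrix(0, d * k, 0L)
  EcT <- if (length(batch$c_tail)) {
    t(.edge_embed(batch$Xc2, params$Wc, params$bc))
  } else matrix(0, d * k, 0L)
  bt0 <- batch$b_tail - 1L; bh0 <- batch$b_head - 1L
  ct0 <- batch$c_tail - 1L; ch0 <- batch$c_head - 1L

  cf <- params$attn_coef
  attn <- if (length(batch$b_tail)) {
    if (use_angle_attention) {
      ifelse(batch$M > 0,
             (cf[1L] * batch$S2 + cf[2L] * batch$S1 + cf[3L] * batch$M) /
               pmax(batch$M, 1L),
             1)
    } else rep(1, length(batch$b_tail))
  } else numeric()

  mpf <- .cpp_mp_stack_forward(H, bt0, bh0, EbT, params$convA_b,
                               params$convb_b, attn, ct0, ch0, EcT,
                               params$convA_c, params$convb_c, Tmp)
  H <- mpf$H

  # self-attention over each molecule's coupled atoms
  ntok <- length(batch$tok_atoms)
  Htok <- H[batch$tok_atoms, , drop = FALSE]
  Q <- Htok %*% params$Wq
  K <- Htok %*% params$Wk
  V <- Htok %*% params$Wv
  O <- matrix(0, ntok, d)
  Ps <- list()
  dh <- d %/% h
  for (mname in names(batch$tok_ranges)) {
    rr <- batch$tok_ranges[[mname]]
    Pm <- vector("list", h)
    for (i in seq_len(h)) {
      cols <- ((i - 1L) * dh + 1L):(i * dh)
      S <- tcrossprod(Q[rr, cols, drop = FALSE], K[rr, cols, drop = FALSE]) / scale
      S <- S - apply(S, 1L, max)
      P <- exp(S); P <- P / rowSums(P)
      O[rr, cols] <- P %*% V[rr, cols, drop = FALSE]
      Pm[[i]] <- P
    }
    Ps[[mname]] <- Pm
  }
  # residual around the attention block: keeps each coupled atom's own
  # state in its attended feature (near-uniform initial attention would
  # otherwise collapse all tokens of a molecule onto their mean)
  Fout <- Htok + O %*% params$Wo

  Fm <- batch$Xm %*% params$Wm
  Fm <- sweep(Fm, 2L, params$bm, "+")
  Esum <- batch$Xc %*% params$We
  Esum <- sweep(Esum, 2L, params$be, "+")

  R <- length(batch$y)
  Z <- cbind(Fout[batch$rec_t0, , drop = FALSE],
             Fout[batch$rec_t1, , drop = FALSE],
             Esum,
             Fm[batch$rec_mol, , drop = FALSE])
  L <- attr(params, "n_dec")
  acts <- vector("list", L + 1L)
  acts[[1L]] <- Z
  lins <- vector("list", L)
  X <- Z
  for (l in seq_len(L)) {
    lin <- X %*% params[[paste0("dec_W", l)]]
    lin <- sweep(lin, 2L, params[[paste0("dec_b", l)]], "+")
    lins[[l]] <- lin
    X <- if (l < L) pmax(lin, 0) else lin
    acts[[l + 1L]] <- X
  }
  pred <- drop(acts[[L + 1L]]) * batch$t_sd + batch$t_mean

  out <- list(pred = pred)
  if (keep) {
    out$cache <- list(H0 = H0, Hins = mpf$Hins, EbT = EbT, EcT = EcT,
                      attn = attn,
                      Htok = Htok, Q = Q, K = K, V = V, O = O, Ps = Ps,
                      Fout = Fout, Fm = Fm, acts = acts, lins = lins,
                      scale = scale)
  }
  out
}

# gradient of the training loss at the predictions
.loss_grad <- function(pred, y, types, floor, pooled = FALSE,
                       method = "log_mae", t_sd = NULL) {
  r <- pred - y
  if (method == "mse") {
    # squared error on the per-type standardised scale: smooth, with
    # gradients that vanish at the optimum instead of staying sign-sized
    s <- if (is.null(t_sd)) rep(1, length(r)) else t_sd
    rs <- r / s
    return(list(loss = mean(rs^2), g = 2 * rs / (s * length(r))))
  }
  if (pooled) {
    mae <- mean(abs(r))
    if (mae <= floor) return(list(loss = log(floor), g = rep(0, length(r))))
    return(list(loss = log(mae), g = sign(r) / (length(r) * mae)))
  }
  tys <- unique(types)
  g <- numeric(length(r))
  loss <- 0
  for (ty in tys) {
    ii <- which(types == ty)
    mae <- mean(abs(r[ii]))
    if (mae <= floor) {
      loss <- loss + log(floor)
    } else {
      loss <- loss + log(mae)
      g[ii] <- sign(r[ii]) / (length(ii) * mae * length(tys))
    }
  }
  list(loss = loss / length(tys), g = g)
}

.zeros_like <- function(p) {
  g <- lapply(p, function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else rep(0, length(x)))
  attributes(g)$names <- names(p)
  g
}

.engine_backward <- function(params, batch, mcfg, cache, dpred,
                             use_angle_attention = TRUE) {
  d <- mcfg$d_model; k <- d %/% 2L; h <- mcfg$heads
  dh <- d %/% h
  Tmp <- mcfg$T_mp
  scale <- cache$scale
  g <- .zeros_like(params)

  # decoder (the chain rule picks up the per-type label scale)
  L <- attr(params, "n_dec")
  dX <- matrix(dpred * batch$t_sd, ncol = 1L)
  for (l in rev(seq_len(L))) {
    Wl <- params[[paste0("dec_W", l)]]
    g[[paste0("dec_W", l)]] <- crossprod(cache$acts[[l]], dX)
    g[[paste0("dec_b", l)]] <- colSums(dX)
    dX <- dX %*% t(Wl)
    if (l > 1L) dX <- dX * (cache$lins[[l - 1L]] > 0)
  }
  dZ <- dX

  ntok <- length(batch$tok_atoms)
  dFout <- matrix(0, ntok, d)
  acc0 <- rowsum(dZ[, seq_len(d), drop = FALSE], batch$rec_t0)
  dFout[as.integer(rownames(acc0)), ] <-
    dFout[as.integer(rownames(acc0)), ] + acc0
  acc1 <- rowsum(dZ[, d + seq_len(d), drop = FALSE], batch$rec_t1)
  dFout[as.integer(rownames(acc1)), ] <-
    dFout[as.integer(rownames(acc1)), ] + acc1
  dEsum <- dZ[, 2L * d + seq_len(k), drop = FALSE]
  g$We <- crossprod(batch$Xc, dEsum)
  g$be <- colSums(dEsum)
  dFm <- matrix(0, nrow(batch$Xm), k)
  accm <- rowsum(dZ[, 2L * d + k + seq_len(k), drop = FALSE], batch$rec_mol)
  dFm[as.integer(rownames(accm)), ] <- accm
  g$Wm <- crossprod(batch$Xm, dFm)
  g$bm <- colSums(dFm)

  # attention
  g$Wo <- crossprod(cache$O, dFout)
  dO <- dFout %*% t(params$Wo)
  dQ <- matrix(0, ntok, d); dK <- matrix(0, ntok, d); dV <- matrix(0, ntok, d)
  for (mname in names(batch$tok_ranges)) {
    rr <- batch$tok_ranges[[mname]]
    for (i in seq_len(h)) {
      cols <- ((i - 1L) * dh + 1L):(i * dh)
      P <- cache$Ps[[mname]][[i]]
      dOh <- dO[rr, cols, drop = FALSE]
      Vh <- cache$V[rr, cols, drop = FALSE]
      dP <- tcrossprod(dOh, Vh)
      dV[rr, cols] <- dV[rr, cols] + crossprod(P, dOh)
      dS <- P * (dP - rowSums(dP * P))
      dS <- dS / scale
      dQ[rr, cols] <- dQ[rr, cols] + dS %*% cache$K[rr, cols, drop = FALSE]
      dK[rr, cols] <- dK[rr, cols] + crossprod(dS, cache$Q[rr, cols, drop = FALSE])
    }
  }
  g$Wq <- crossprod(cache$Htok, dQ)
  g$Wk <- crossprod(cache$Htok, dK)
  g$Wv <- crossprod(cache$Htok, dV)
  dHtok <- dFout +  # attention residual
    dQ %*% t(params$Wq) + dK %*% t(params$Wk) + dV %*% t(params$Wv)

  dH <- matrix(0, batch$n, d)
  dH[batch$tok_atoms, ] <- dHtok

  # message passing, reverse order (one fused call over all iterations)
  bt0 <- batch$b_tail - 1L; bh0 <- batch$b_head - 1L
  ct0 <- batch$c_tail - 1L; ch0 <- batch$c_head - 1L
  mpb <- .cpp_mp_stack_backward(dH, cache$Hins, bt0, bh0, cache$EbT,
                                params$convA_b, params$convb_b, cache$attn,
                                ct0, ch0, cache$EcT, params$convA_c,
                                params$convb_c, Tmp, use_angle_attention)
  dH <- mpb$dH
  g$convA_b <- mpb$dconvA_b
  g$convb_b <- drop(mpb$dconvb_b)
  g$convA_c <- mpb$dconvA_c
  g$convb_c <- drop(mpb$dconvb_c)

  if (use_angle_attention && length(batch$b_tail)) {
    dattn_acc <- drop(mpb$dattn)
    nz <- batch$M > 0
    if (any(nz)) {
      Mn <- batch$M[nz]
      g$attn_coef <- c(sum(dattn_acc[nz] * batch$S2[nz] / Mn),
                       sum(dattn_acc[nz] * batch$S1[nz] / Mn),
                       sum(dattn_acc[nz]))
    }
  }

  if (length(batch$b_tail)) {
    g$Wb <- t(mpb$dEbT %*% batch$Xb)
    g$bb <- rowSums(mpb$dEbT)
  }
  if (length(batch$c_tail)) {
    g$Wc <- t(mpb$dEcT %*% batch$Xc2)
    g$bc <- rowSums(mpb$dEcT)
  }

  g$Wa <- crossprod(batch$A, dH)
  g$ba <- colSums(dH)
  g
}

#' Run the network forward over a featurized dataset
#'
#' Pipeline per molecule batch: embed the raw blocks, run `T_mp` iterations
#' of (bond message passing with angle attention, then coupling message
#' passing), apply per-molecule multi-head self-attention over the coupled
#' atoms, and decode each coupling record from the two attended atom
#' features plus the molecule feature.
#'
#' @param params a `"gaann_params"` parameter set.
#' @param fg a (normalised) `"featurized_graphs"` object.
#' @param mcfg the [model_config()] the parameters were built with.
#' @param batch_molecules molecules per evaluation batch (default 64).
#' @param target_stats optional per-type label standardisation (stored in a
#'   trained model); `NULL` leaves the decoder output unscaled.
#' @return Numeric vector of predicted SCCs (Hz), aligned with `fg$records`.
#' @export
gaann_forward <- function(params, fg, mcfg, batch_molecules = 64L,
                          target_stats = NULL) {
  preds <- rep(NA_real_, nrow(fg$records))
  ids <- seq_along(fg$mol_names)
  use_attn <- fg$config$use_angle_attention
  for (chunk in split(ids, ceiling(seq_along(ids) / batch_molecules))) {
    batch <- .build_batch(fg, chunk, mcfg$d_model, tstats = target_stats)
    if (!length(batch$y)) next
    fw <- .engine_forward(params, batch, mcfg, use_angle_attention = use_attn)
    preds[batch$rid] <- fw$pred
  }
  preds
}
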