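# The graph angle-attention network's operations in reference form:
# Karplus-form bond-angle attention, the zero-padded unfold "Conv", the two
# message-passing steps, scaled dot-product / multi-head self-attention, the
# MLP decoder and the grouped log-MAE metric. The batched training engine
# (engine.R) reuses these contracts; tests pin the two code paths together.

#' Model configuration
#'
#' @param d_model hidden width (even, divisible by `heads`; default 128).
#' @param heads number of self-attention heads (default 8).
#' @param T_mp message-passing iterations; each iteration runs one bond pass
#'   and one coupling pass (default 2).
#' @param decoder_hidden integer vector of MLP hidden layer sizes.
#' @param log_mae_floor floor inside `ln(max(MAE, floor))` (default 1e-9).
#' @param scale_per_head scale attention logits by `sqrt(d_model/heads)`
#'   instead of `sqrt(d_model)`? Default `FALSE` (scale by `sqrt(d_model)`).
#' @param attn_init initial bond-angle attention coefficients `(A', B', C')`;
#'   the defaults are the learned values reported for the full-scale model.
#' @param edge_gain initialisation gain of the edge-embedding maps (the
#'   multiplicative message pathway).
#' @param seed seed for parameter initialisation.
#' @return List of class `"model_config"`.
#' @export
model_config <- function(d_model = 128L, heads = 8L, T_mp = 2L,
                         decoder_hidden = c(128L, 64L),
                         log_mae_floor = 1e-9,
                         scale_per_head = FALSE,
                         attn_init = c(0.12, 0.99, 0.27),
                         edge_gain = 0.1,
                         seed = 1L) {
  d_model <- as.integer(d_model); heads <- as.integer(heads)
  if (d_model %% 2L != 0L) stop("d_model must be even")
  if (d_model %% heads != 0L) stop("d_model must be divisible by heads")
  if (T_mp < 1L) stop("T_mp must be >= 1")
  structure(list(d_model = d_model, heads = heads, T_mp = as.integer(T_mp),
                 decoder_hidden = as.integer(decoder_hidden),
                 log_mae_floor = log_mae_floor,
                 scale_per_head = isTRUE(scale_per_head),
                 attn_init = as.numeric(attn_init),
                 edge_gain = edge_gain,
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Bond-angle attention weight
#'
#' The Karplus-form scalar weight of a directed bond, averaged over the
#' angles between that bond and its neighbouring bonds at the head atom:
#' `attn = sum_i (A' cos^2 theta_i + B' cos theta_i + C') / M`. A terminal
#' bond with no neighbouring bonds (`M = 0`) gets the neutral weight 1.
#'
#' With the default coefficients `attn` is strictly decreasing in a single
#' neighbour angle on `[0, 180]` degrees, echoing the Karplus picture that
#' aligned orbitals couple most strongly.
#'
#' @param theta numeric vector of neighbouring bond angles, degrees.
#' @param coeffs numeric length-3 `(A', B', C')`; defaults to the learned
#'   values `(0.12, 0.99, 0.27)`.
#' @return Scalar attention weight.
#' @export
angle_attention <- function(theta, coeffs = c(0.12, 0.99, 0.27)) {
  M <- length(theta)
  if (M == 0L) return(1)
  ct <- cos(theta * pi / 180)
  sum(coeffs[1L] * ct^2 + coeffs[2L] * ct + coeffs[3L]) / M
}

#' Zero-padded unfold ("Conv") of a node vector
#'
#' Reshapes a length-`d` hidden vector into a `d x d/2` matrix by a stride-1
#' sliding window of width `d/2` with zero padding past the end (row `r`
#' holds `h[r], h[r+1], ..., h[r + d/2 - 1]`), then applies a learned
#' position-wise linear map shared across rows. With `weights = NULL` the
#' map is the identity, exposing the raw unfold.
#'
#' @param h numeric vector of even length `d`.
#' @param weights optional `d/2 x d/2` matrix applied on the right of each
#'   row.
#' @param bias optional length-`d/2` bias added to each row.
#' @return `d x d/2` matrix.
#' @export
conv_unfold <- function(h, weights = NULL, bias = NULL) {
  d <- length(h)
  if (d %% 2L != 0L) stop("h must have even length")
  k <- d %/% 2L
  hp <- c(h, rep(0, k))
  U <- matrix(0, d, k)
  for (r in seq_len(d)) U[r, ] <- hp[r:(r + k - 1L)]
  if (!is.null(weights)) {
    U <- U %*% weights
  }
  if (!is.null(bias)) {
    U <- sweep(U, 2L, bias, "+")
  }
  U
}

#' One bond message-passing step (reference implementation)
#'
#' Updates node states over directed bond edges:
#' `h_v <- h_v + sum_{w -> v} attn_e * rowSums(Conv(h_w) * e_vw)`,
#' where `*` inside is elementwise and the row sums reduce the
#' `d x d/2` product back to a length-`d` message. Atoms with no incoming
#' edges keep their state (residual identity).
#'
#' @param H `n x d` matrix of node states.
#' @param tail,head integer vectors of directed edge endpoints (messages
#'   flow from `tail` into `head`).
#' @param edge_mats list of `d x d/2` edge state matrices, one per edge.
#' @param attn numeric vector of per-edge attention scalars (recycled).
#' @param conv list with `weights` (`d/2 x d/2`) and `bias` (length `d/2`)
#'   of the Conv map.
#' @return Updated `n x d` matrix.
#' @export
bond_mp_step <- function(H, tail, head, edge_mats, attn = 1, conv = NULL) {
  attn <- rep_len(attn, length(tail))
  Hnew <- H
  for (e in seq_along(tail)) {
    CU <- conv_unfold(H[tail[e], ], weights = conv$weights, bias = conv$bias)
    if (!all(dim(CU) == dim(edge_mats[[e]]))) stop("edge matrix shape mismatch")
    msg <- attn[e] * rowSums(CU * edge_mats[[e]])
    Hnew[head[e], ] <- Hnew[head[e], ] + msg
  }
  Hnew
}

#' One coupling message-passing step (reference implementation)
#'
#' Identical to [bond_mp_step()] but over the coupling graph and without the
#' angle-attention factor (every edge weight is 1): the bond angles act
#' through chemical bonds, not through the virtual coupling edges.
#'
#' @inheritParams bond_mp_step
#' @return Updated `n x d` matrix.
#' @export
coupling_mp_step <- function(H, tail, head, edge_mats, conv = NULL) {
  bond_mp_step(H, tail, head, edge_mats, attn = 1, conv = conv)
}

#' Scaled dot-product attention
#'
#' `O = softmax(Q K^T / scale) V`, softmax taken over the rows. Tokens are
#' one molecule's coupled-atom states; attention never crosses molecules.
#'
#' @param Q,K,V numeric matrices with one row per token.
#' @param scale logit scale; defaults to `sqrt(ncol(Q))`.
#' @return List with `output` (same shape as `V`) and `weights` (the
#'   attention probability matrix, rows summing to 1).
#' @export
scaled_dot_attention <- function(Q, K, V, scale = sqrt(ncol(Q))) {
  if (nrow(Q) == 0L) stop("empty token set")
  S <- Q %*% t(K) / scale
  S <- S - apply(S, 1L, max)
  P <- exp(S)
  P <- P / rowSums(P)
  list(output = P %*% V, weights = P)
}

#' Multi-head self-attention (reference implementation)
#'
#' Projects the tokens into `h` subspaces with separate Q/K/V maps, runs
#' scaled dot-product attention per head, concatenates the head outputs and
#' applies the output map `W`.
#'
#' @param tokens `m x d` matrix of token states.
#' @param params list with `Wq`, `Wk`, `Wv`, `Wo` (`d x d` matrices; head
#'   `i` owns columns `((i-1)*d/h + 1):(i*d/h)` of the projections).
#' @param h number of heads (must divide `d`).
#' @param scale logit scale (default `sqrt(d)`).
#' @return `m x d` matrix of attended token features.
#' @export
multi_head_attention <- function(tokens, params, h, scale = sqrt(ncol(tokens))) {
  d <- ncol(tokens)
  if (d %% h != 0L) stop("head count must divide d_model")
  dh <- d %/% h
  Q <- tokens %*% params$Wq
  K <- tokens %*% params$Wk
  V <- tokens %*% params$Wv
  O <- matrix(0, nrow(tokens), d)
  for (i in seq_len(h)) {
    cols <- ((i - 1L) * dh + 1L):(i * dh)
    O[, cols] <- scaled_dot_attention(Q[, cols, drop = FALSE],
                                      K[, cols, drop = FALSE],
                                      V[, cols, drop = FALSE],
                                      scale = scale)$output
  }
  O %*% params$Wo
}

#' Decode a scalar coupling constant
#'
#' Decodes one coupling record from the concatenation of the attended
#' features of its two coupled atoms (length `d` each), an optional learned
#' summary of the record's own coupling-edge features (length `d/2`; the
#' virtual coupled edge is concatenated with the atoms before decoding) and
#' the molecule feature (length `d/2`), passed through a ReLU MLP with a
#' scalar linear output. The edge summary is essential for identifiability:
#' inside a symmetric rotor every per-atom aggregate is invariant under the
#' rotor symmetry, so gauche and trans pairs are indistinguishable from atom
#' features alone. The concatenation is ordered, so swapping the two atoms
#' changes the prediction in general; record canonicalisation (H first)
#' fixes the order.
#'
#' @param f_atom0,f_atom1 numeric length-`d` attended atom features.
#' @param f_mol numeric length-`d/2` molecule feature.
#' @param mlp list with `weights` (list of matrices) and `biases` (list of
#'   vectors); ReLU between layers, linear final layer.
#' @param f_edge optional length-`d/2` coupling-edge summary, concatenated
#'   between the atom and molecule features.
#' @return Predicted SCC in Hz (scalar).
#' @export
decode_scc <- function(f_atom0, f_atom1, f_mol, mlp, f_edge = NULL) {
  x <- c(f_atom0, f_atom1, f_edge, f_mol)
  L <- length(mlp$weights)
  for (l in seq_len(L)) {
    if (length(x) != nrow(mlp$weights[[l]])) stop("decoder input width mismatch")
    x <- drop(x %*% mlp$weights[[l]]) + mlp$biases[[l]]
    if (l < L) x <- pmax(x, 0)
  }
  drop(x)
}

#' Grouped log-MAE metric
#'
#' Per coupling type `t`: `MAE_t = mean |y - yhat|`; the score is the mean
#' over types present of `ln(max(MAE_t, floor))`. This grouping makes the
#' long-tailed 1J errors commensurable with the near-zero 2J/3J errors.
#' `pooled = TRUE` instead returns `ln` of the single pooled MAE.
#'
#' @param predictions numeric vector (Hz).
#' @param observed numeric vector (Hz).
#' @param types character vector of coupling types, same length.
#' @param floor MAE floor (default 1e-9).
#' @param pooled ignore the type grouping?
#' @return Object of class `"metric_report"`: list with `per_type_mae`,
#'   `per_type_log_mae`, `score`, `n`.
#' @export
grouped_log_mae <- function(predictions, observed, types,
                            floor = 1e-9, pooled = FALSE) {
  ok <- !is.na(observed)
  if (!any(ok)) stop("no labelled records to score")
  err <- abs(predictions[ok] - observed[ok])
  types <- types[ok]
  if (pooled) {
    mae <- mean(err)
    score <- log(max(mae, floor))
    per <- stats::setNames(mae, "pooled")
  } else {
    per <- c(tapply(err, types, mean))   # plain named vector
    score <- mean(log(pmax(per, floor)))
  }
  structure(list(per_type_mae = per,
                 per_type_log_mae = log(pmax(per, floor)),
                 score = score,
                 n = length(err)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report> grouped log(MAE) =", format(x$score, digits = 4),
      "over", x$n, "records\n")
  df <- data.frame(type = names(x$per_type_mae),
                   mae_hz = as.numeric(x$per_type_mae),
                   log_mae = as.numeric(x$per_type_log_mae))
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}
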