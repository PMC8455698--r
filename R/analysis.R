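# Interpretability analyses: Spearman rank correlation of the key coupling
# features against the SCC, and PCA embedding of the learned coupled-atom
# features.

#' Spearman correlation matrix of coupling features
#'
#' Rank correlation (average ranks for ties) between feature columns and,
#' optionally, the SCC target. Constant columns have no defined rank
#' correlation and are reported as `NA`.
#'
#' @param features data.frame or matrix of per-record features.
#' @param target optional numeric SCC vector, appended as column `"SCC"`.
#' @return Symmetric correlation matrix with unit diagonal (where defined).
#' @export
spearman_matrix <- function(features, target = NULL) {
  X <- as.matrix(features)
  if (!is.null(target)) X <- cbind(X, SCC = target)
  R <- suppressWarnings(stats::cor(X, method = "spearman"))
  const <- apply(X, 2L, function(v) all(v == v[1L]))
  dg <- diag(R)
  dg[!const] <- 1
  diag(R) <- dg
  R
}

#' Extract per-record feature table for correlation analysis
#'
#' Builds the table feeding [spearman_matrix()]: the coupled-atom distance
#' features and the four angle cosines of every record, straight from an
#' (unnormalised) featurized dataset.
#'
#' @param fg a `"featurized_graphs"` object (unnormalised).
#' @return data.frame with columns `dist`, `inv_dist`, `inv_dist3`,
#'   `cos_dihedral`, `cos_bond_angle`, `cos_angle0`, `cos_angle1`, `scc`.
#' @export
coupling_feature_table <- function(fg) {
  cn <- fg$layout$coupling$slot
  pick <- c("dist", "inv_dist", "inv_dist3", "cos_dihedral",
            "cos_bond_angle", "cos_angle0", "cos_angle1")
  df <- as.data.frame(fg$cpl[, match(pick, cn), drop = FALSE])
  names(df) <- pick
  df$scc <- fg$records$y
  df
}

#' PCA embedding of learned features
#'
#' Mean-centred projection onto the top-`k` principal axes, for visualising
#' how the encoder separates coupling types.
#'
#' @param X numeric matrix, one row per coupled-atom feature vector.
#' @param k number of components (default 2).
#' @return List with `coords` (`n x k` scores), `explained_variance`
#'   (length-`k` non-increasing variance ratios) and `rotation`.
#' @export
pca_embed <- function(X, k = 2L) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 samples for PCA")
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(k, ncol(pr$x))
  ratios <- pr$sdev^2 / sum(pr$sdev^2)
  list(coords = pr$x[, seq_len(k), drop = FALSE],
       explained_variance = ratios[seq_len(k)],
       rotation = pr$rotation[, seq_len(k), drop = FALSE])
}

#' Attended coupled-atom features of a dataset
#'
#' Runs the trained encoder and returns the post-attention feature vector of
#' each record's hydrogen atom (the decoder's `f_atom0` input), the usual
#' input to [pca_embed()].
#'
#' @param model a trained `"gaann_model"`.
#' @param dataset an [scc_dataset()].
#' @param bonds optional named list of bond graphs.
#' @return List with `features` (`n_records x d_model` matrix) and `types`.
#' @export
coupled_atom_embedding <- function(model, dataset, bonds = NULL) {
  fg <- featurize(dataset, bonds = bonds, config = model$feature_config)
  if (model$feature_config$normalize) fg <- normalize_features(fg, model$stats)
  mcfg <- model$model_config
  out <- matrix(NA_real_, nrow(fg$records), mcfg$d_model)
  ids <- seq_along(fg$mol_names)
  for (chunk in split(ids, ceiling(seq_along(ids) / 64L))) {
    batch <- .build_batch(fg, chunk, mcfg$d_model)
    if (!length(batch$y)) next
    fw <- .engine_forward(model$params, batch, mcfg,
                          use_angle_attention = model$feature_config$use_angle_attention,
                          keep = TRUE)
    out[batch$rid, ] <- fw$cache$Fout[batch$rec_t0, , drop = FALSE]
  }
  list(features = out, types = fg$records$type)
}
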