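# Training loop (Adam + one-cycle learning rate), evaluation, checkpoints
# and the angle-mechanism ablation. The training loss is the grouped
# log-MAE (the evaluation criterion itself, floored to stay finite); plain
# MAE is available as an alternative loss.

#' Training configuration
#'
#' @param epochs training epochs (default 144, the full-scale schedule;
#'   desk-scale experiments use far fewer).
#' @param max_lr peak learning rate of the one-cycle policy.
#' @param warmup fraction of steps spent ramping up to `max_lr`.
#' @param div_initial `max_lr / div_initial` is the starting rate.
#' @param div_final `max_lr / div_final` is the final annealed rate.
#' @param batch_size molecules per minibatch.
#' @param validation_fraction fraction of molecules held out for validation
#'   (split by molecule, never by record, to avoid leakage between coupling
#'   pairs of one molecule).
#' @param loss `"log_mae"` (the grouped evaluation criterion itself),
#'   `"mae"` (pooled plain MAE) or `"mse"` (squared error on the per-type
#'   standardised scale; the default — its gradients vanish at the optimum,
#'   where the sign-shaped MAE gradients keep a noise floor under Adam).
#' @param seed seed for the split and batch order.
#' @param device accepted for interface parity; only `"cpu"` is supported.
#' @return List of class `"train_config"`.
#' @export
train_config <- function(epochs = 144L, max_lr = 3e-3, warmup = 0.3,
                         div_initial = 10, div_final = 100,
                         batch_size = 16L, validation_fraction = 0.2,
                         loss = c("mse", "log_mae", "mae"), seed = 1L,
                         device = "cpu") {
  if (epochs < 1L) stop("epochs must be >= 1")
  if (validation_fraction < 0 || validation_fraction >= 1) {
    stop("validation_fraction must be in [0, 1)")
  }
  structure(list(epochs = as.integer(epochs), max_lr = max_lr,
                 warmup = warmup, div_initial = div_initial,
                 div_final = div_final, batch_size = as.integer(batch_size),
                 validation_fraction = validation_fraction,
                 loss = match.arg(loss), seed = as.integer(seed),
                 device = device),
            class = "train_config")
}

# one-cycle policy: linear warm-up to max_lr, cosine anneal down
.one_cycle_lr <- function(step, total, max_lr, warmup, div_initial, div_final) {
  w <- max(1, round(warmup * total))
  if (step <= w) {
    lo <- max_lr / div_initial
    lo + (max_lr - lo) * step / w
  } else {
    lo <- max_lr / div_final
    frac <- (step - w) / max(1, total - w)
    lo + (max_lr - lo) * (1 + cos(pi * frac)) / 2
  }
}

.adam_init <- function(params) {
  list(m = .zeros_like(params), v = .zeros_like(params), t = 0L)
}

.adam_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / b1t) / (sqrt(state$v[[nm]] / b2t) + eps)
  }
  list(params = params, state = state)
}

#' Train a graph angle-attention model
#'
#' Featurizes the dataset, splits molecules into train/validation, z-scores
#' the scale-bearing features with training-split statistics, and optimises
#' all parameters (including the three angle-attention coefficients) with
#' Adam under a one-cycle learning-rate schedule. The checkpointed
#' parameters are those with the best validation score.
#'
#' @param dataset a labelled [scc_dataset()].
#' @param model_cfg a [model_config()].
#' @param train_cfg a [train_config()].
#' @param feature_cfg optional [feature_config()]; defaults to angle
#'   features and angle attention on, at `model_cfg$d_model`.
#' @param bonds optional named list of bond graphs (else inferred).
#' @param init_model optional `"gaann_model"` to resume from (its parameters
#'   and normalisation statistics are reused).
#' @param verbose print per-epoch progress?
#' @return Object of class `"gaann_model"`: list with `params` (best),
#'   `final_params`, `model_config`, `feature_config`, `stats`, `layout`,
#'   `history` (data.frame epoch/train_loss/val_score/lr), `train_config`.
#' @export
gaann_train <- function(dataset, model_cfg = model_config(),
                        train_cfg = train_config(),
                        feature_cfg = NULL, bonds = NULL,
                        init_model = NULL, verbose = FALSE) {
  if (!nrow(dataset$records) || all(is.na(dataset$records$scc))) {
    stop("training requires labelled records")
  }
  if (is.null(feature_cfg)) {
    feature_cfg <- if (!is.null(init_model)) init_model$feature_config else
      feature_config(d_model = model_cfg$d_model)
  }
  fg <- featurize(dataset, bonds = bonds, config = feature_cfg)

  n_mol <- length(fg$mol_names)
  val_ids <- .local_seed(train_cfg$seed * 7919L + 13L, {
    nv <- round(train_cfg$validation_fraction * n_mol)
    if (nv > 0) sort(sample(n_mol, nv)) else integer()
  })
  train_ids <- setdiff(seq_len(n_mol), val_ids)
  if (!length(train_ids)) stop("empty training set after the validation split")

  stats <- if (!is.null(init_model)) init_model$stats else {
    fg_train_raw <- fg
    fg_train_raw$mols <- fg$mols[train_ids]
    keep <- fg$records$mol_id %in% train_ids
    fg_train_raw$cpl <- fg$cpl[keep, , drop = FALSE]
    fg_train_raw$mol_feat <- fg$mol_feat[train_ids, , drop = FALSE]
    feature_stats(fg_train_raw)
  }
  if (feature_cfg$normalize) fg <- normalize_features(fg, stats)

  params <- if (!is.null(init_model)) init_model$params else
    gaann_init(model_cfg, fg$layout)
  state <- .adam_init(params)

  tstats <- if (!is.null(init_model)) init_model$target_stats else {
    tr_rec <- fg$records$mol_id %in% train_ids
    .target_stats(fg$records$type[tr_rec], fg$records$y[tr_rec])
  }

  batches <- .local_seed(train_cfg$seed * 104729L + 1L, {
    perm <- sample(train_ids)
    split(perm, ceiling(seq_along(perm) / train_cfg$batch_size))
  })
  built <- lapply(batches, function(ids)
    .build_batch(fg, ids, model_cfg$d_model, tstats = tstats))
  built <- built[vapply(built, function(b) length(b$y) > 0L, TRUE)]
  val_batch <- if (length(val_ids))
    .build_batch(fg, val_ids, model_cfg$d_model, tstats = tstats) else NULL
  pooled <- train_cfg$loss == "mae"
  use_attn <- feature_cfg$use_angle_attention

  total_steps <- train_cfg$epochs * length(built)
  step <- 0L
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_score = numeric(), lr = numeric())
  best <- list(score = Inf, params = params)
  for (ep in seq_len(train_cfg$epochs)) {
    ep_loss <- 0
    for (b in built) {
      step <- step + 1L
      lr <- .one_cycle_lr(step, total_steps, train_cfg$max_lr,
                          train_cfg$warmup, train_cfg$div_initial,
                          train_cfg$div_final)
      fw <- .engine_forward(params, b, model_cfg,
                            use_angle_attention = use_attn, keep = TRUE)
      lg <- .loss_grad(fw$pred, b$y, b$types, model_cfg$log_mae_floor,
                       pooled = pooled, method = train_cfg$loss,
                       t_sd = b$t_sd)
      grads <- .engine_backward(params, b, model_cfg, fw$cache, lg$g,
                                use_angle_attention = use_attn)
      upd <- .adam_step(params, grads, state, lr)
      params <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + lg$loss
    }
    ep_loss <- ep_loss / length(built)
    val_score <- NA_real_
    if (!is.null(val_batch)) {
      vp <- .engine_forward(params, val_batch, model_cfg,
                            use_angle_attention = use_attn)$pred
      val_score <- grouped_log_mae(vp, val_batch$y, val_batch$types,
                                   floor = model_cfg$log_mae_floor)$score
      if (val_score < best$score) {
        best <- list(score = val_score, params = params)
      }
    }
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss,
                                   val_score = val_score, lr = lr))
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %s", ep, ep_loss,
                      ifelse(is.na(val_score), "-", sprintf("%.4f", val_score))))
    }
  }
  if (is.null(val_batch)) best$params <- params

  structure(list(params = best$params, final_params = params,
                 best_val_score = if (is.null(val_batch)) NA_real_ else best$score,
                 model_config = model_cfg, feature_config = feature_cfg,
                 train_config = train_cfg, stats = stats,
                 target_stats = tstats,
                 layout = fg$layout, layout_hash = .layout_hash(fg$layout),
                 history = hist,
                 val_molecules = fg$mol_names[val_ids]),
            class = "gaann_model")
}

#' @export
print.gaann_model <- function(x, ...) {
  cat("<gaann_model> d_model =", x$model_config$d_model,
      " heads =", x$model_config$heads, " T =", x$model_config$T_mp, "\n")
  cat("  trained", nrow(x$history), "epochs; best val score =",
      format(x$best_val_score, digits = 4), "\n")
  cat("  angle attention coefficients (A', B', C') =",
      paste(format(x$params$attn_coef, digits = 3), collapse = ", "), "\n")
  invisible(x)
}

#' Predict scalar coupling constants
#'
#' @param model a trained `"gaann_model"`.
#' @param dataset an [scc_dataset()] (labels optional).
#' @param bonds optional named list of bond graphs.
#' @return Numeric vector of predictions (Hz), one per record.
#' @export
gaann_predict <- function(model, dataset, bonds = NULL) {
  fg <- featurize(dataset, bonds = bonds, config = model$feature_config)
  if (model$feature_config$normalize) fg <- normalize_features(fg, model$stats)
  gaann_forward(model$params, fg, model$model_config,
                target_stats = model$target_stats)
}

#' Evaluate a model on a labelled dataset
#'
#' @inheritParams gaann_predict
#' @param pooled report pooled instead of per-type-grouped log MAE?
#' @return A `"metric_report"`.
#' @export
gaann_evaluate <- function(model, dataset, bonds = NULL, pooled = FALSE) {
  preds <- gaann_predict(model, dataset, bonds = bonds)
  grouped_log_mae(preds, dataset$records$scc, dataset$records$type,
                  floor = model$model_config$log_mae_floor, pooled = pooled)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is self-describing: it carries the model and feature
#' configuration, the feature-layout manifest with its hash, the
#' normalisation statistics and all parameters. Loading verifies the layout
#' hash against the current package's layout.
#'
#' @param model a `"gaann_model"`.
#' @param path file path.
#' @return `path` invisibly (save); the model (load).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "gaann_model")) stop("not a gaann checkpoint: ", path)
  if (!identical(model$layout_hash, .layout_hash(feature_layout()))) {
    stop("checkpoint feature layout does not match this package version")
  }
  model
}

#' Ablation of the angle mechanisms
#'
#' Trains four arms on identical data and seeds: `base` (no angle attention,
#' no angle features), `attn` (attention only), `feats` (angle features
#' only) and `full` (both). Reports per-epoch validation curves and final
#' (best-validation) scores per arm and seed.
#'
#' @param dataset a labelled [scc_dataset()].
#' @param model_cfg a [model_config()].
#' @param train_cfg a [train_config()].
#' @param seeds integer vector of seeds (each arm runs once per seed).
#' @param bonds optional named list of bond graphs.
#' @param verbose print progress?
#' @return Object of class `"ablation_report"`: list with `arms` (toggle
#'   table), `final` (data.frame arm/seed/score), `curves` (named list of
#'   epoch x seed validation-score matrices) and `summary` (median final
#'   score per arm).
#' @export
ablate <- function(dataset, model_cfg = model_config(),
                   train_cfg = train_config(), seeds = c(1L, 2L, 3L),
                   bonds = NULL, verbose = FALSE) {
  arms <- data.frame(arm = c("base", "attn", "feats", "full"),
                     use_angle_attention = c(FALSE, TRUE, FALSE, TRUE),
                     use_angle_features = c(FALSE, FALSE, TRUE, TRUE),
                     stringsAsFactors = FALSE)
  final <- data.frame(arm = character(), seed = integer(), score = numeric())
  curves <- list()
  for (a in seq_len(nrow(arms))) {
    cm <- matrix(NA_real_, train_cfg$epochs, length(seeds))
    for (s in seq_along(seeds)) {
      mc <- model_cfg; mc$seed <- seeds[s]
      tc <- train_cfg; tc$seed <- seeds[s]
      fc <- feature_config(d_model = mc$d_model,
                           use_angle_features = arms$use_angle_features[a],
                           use_angle_attention = arms$use_angle_attention[a])
      fit <- gaann_train(dataset, mc, tc, feature_cfg = fc, bonds = bonds)
      cm[, s] <- fit$history$val_score
      final <- rbind(final, data.frame(arm = arms$arm[a], seed = seeds[s],
                                       score = fit$best_val_score))
      if (verbose) {
        message(sprintf("arm %-5s seed %d  best val %.4f",
                        arms$arm[a], seeds[s], fit$best_val_score))
      }
    }
    curves[[arms$arm[a]]] <- cm
  }
  summary <- stats::aggregate(score ~ arm, final, stats::median)
  structure(list(arms = arms, final = final, curves = curves,
                 summary = summary, seeds = seeds),
            class = "ablation_report")
}

#' @export
print.ablation_report <- function(x, ...) {
  cat("<ablation_report> median best validation score per arm:\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Serialise / deserialise an ablation report
#'
#' @param report an `"ablation_report"`.
#' @param path JSON file path.
#' @return `path` invisibly (write); the report (read).
#' @export
write_ablation_report <- function(report, path) {
  obj <- list(arms = report$arms, final = report$final,
              curves = lapply(report$curves, function(m) unclass(as.data.frame(m))),
              seeds = report$seeds)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_ablation_report
#' @export
read_ablation_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  curves <- lapply(obj$curves, function(df) unname(as.matrix(as.data.frame(df))))
  final <- as.data.frame(obj$final)
  summary <- stats::aggregate(score ~ arm, final, stats::median)
  structure(list(arms = as.data.frame(obj$arms), final = final,
                 curves = curves, summary = summary, seeds = obj$seeds),
            class = "ablation_report")
}
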