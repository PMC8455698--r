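test_that("bond-angle attention matches its closed form", {
  expect_equal(angle_attention(90), 0.27, tolerance = 1e-12)
  expect_equal(angle_attention(0), 1.38, tolerance = 1e-12)
  expect_equal(angle_attention(c(0, 180)), 0.39, tolerance = 1e-12)
  expect_equal(angle_attention(numeric()), 1)   # terminal bond: neutral

  # equals the brute-force mean of per-angle Karplus terms
  set.seed(1)
  for (rep in 1:25) {
    th <- stats::runif(sample(1:5, 1), 0, 180)
    cf <- stats::rnorm(3)
    manual <- mean(sapply(th, function(t)
      cf[1] * cos(t * pi / 180)^2 + cf[2] * cos(t * pi / 180) + cf[3]))
    expect_equal(angle_attention(th, cf), manual, tolerance = 1e-12)
  }

  # strictly decreasing in a single angle under the default coefficients
  grid <- seq(0, 180, by = 1)
  vals <- sapply(grid, angle_attention)
  expect_true(all(diff(vals) < 0))
})

test_that("conv_unfold implements the zero-padded sliding window", {
  U <- conv_unfold(c(1, 2, 3, 4))
  expect_equal(U, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 0)))
  expect_equal(conv_unfold(rep(0, 6)), matrix(0, 6, 3))
  # last row always ends in d/2 - 1 zeros
  h <- c(5, 4, 3, 2, 9, 1)
  U6 <- conv_unfold(h)
  expect_equal(U6[6, ], c(1, 0, 0))
  # index oracle: U[r, c] = h[r + c - 1] (zero past the end)
  for (r in 1:6) for (c in 1:3) {
    expect_equal(U6[r, c], if (r + c - 1 <= 6) h[r + c - 1] else 0)
  }
  # the position-wise map acts on rows
  W <- matrix(c(1, 0, 2, 1), 2)
  expect_equal(conv_unfold(c(1, 2, 3, 4), weights = W, bias = c(0.5, -0.5)),
               rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 0)) %*% W +
                 matrix(c(0.5, -0.5), 4, 2, byrow = TRUE))
  expect_error(conv_unfold(1:3), "even")
})

test_that("message passing steps honour the residual and a hand-unrolled oracle", {
  d <- 4L; k <- 2L
  H <- rbind(c(1, 2, 3, 4), c(0.5, -1, 2, 0))
  e01 <- matrix(stats::rnorm(d * k, sd = 0.5), d, k)
  conv0 <- list(weights = matrix(0, k, k), bias = rep(0, k))
  # zero Conv: residual identity
  expect_equal(bond_mp_step(H, tail = 1L, head = 2L, list(e01), 0.7, conv0), H)
  # isolated atom (no incoming edge) unchanged
  convr <- list(weights = matrix(c(1, 0.5, -0.2, 2), k, k), bias = c(0.1, -0.3))
  H2 <- bond_mp_step(H, tail = 1L, head = 2L, list(e01), 0.7, convr)
  expect_equal(H2[1, ], H[1, ])
  # fully unrolled scalar computation of the message into atom 2
  Uref <- matrix(0, d, k)
  hp <- c(H[1, ], 0, 0)
  for (r in 1:d) for (c in 1:k) Uref[r, c] <- hp[r + c - 1]
  CU <- Uref %*% convr$weights
  CU <- CU + matrix(convr$bias, d, k, byrow = TRUE)
  msg <- 0.7 * rowSums(CU * e01)
  expect_equal(H2[2, ], H[2, ] + msg, tolerance = 1e-12)
  # coupling step is the attention-free special case
  expect_equal(coupling_mp_step(H, 1L, 2L, list(e01), convr),
               bond_mp_step(H, 1L, 2L, list(e01), attn = 1, conv = convr))
})

test_that("scaled dot-product attention has softmax structure", {
  set.seed(3)
  V <- matrix(stats::rnorm(8), 2, 4)
  one <- scaled_dot_attention(V[1, , drop = FALSE], V[1, , drop = FALSE],
                              V[1, , drop = FALSE])
  expect_equal(one$output, V[1, , drop = FALSE])   # softmax of one element
  Q <- matrix(stats::rnorm(12), 3, 4)
  K <- matrix(stats::rnorm(12), 3, 4)
  att <- scaled_dot_attention(Q, K, matrix(stats::rnorm(12), 3, 4))
  expect_equal(rowSums(att$weights), rep(1, 3), tolerance = 1e-6)
  # identical keys: uniform weights, output = mean of V rows
  Kc <- matrix(1, 3, 4)
  Vr <- matrix(stats::rnorm(12), 3, 4)
  attc <- scaled_dot_attention(Q, Kc, Vr)
  expect_equal(attc$output,
               matrix(colMeans(Vr), 3, 4, byrow = TRUE), tolerance = 1e-9)
  expect_error(scaled_dot_attention(Q[0, , drop = FALSE], K, Vr), "empty")
})

test_that("multi-head attention reduces, shapes, and unrolls correctly", {
  set.seed(5)
  d <- 4L
  toks <- matrix(stats::rnorm(12), 3, d)
  params <- list(Wq = matrix(stats::rnorm(16), d), Wk = matrix(stats::rnorm(16), d),
                 Wv = matrix(stats::rnorm(16), d), Wo = matrix(stats::rnorm(16), d))
  # h = 1 degenerates to scaled dot-product attention followed by Wo
  f1 <- multi_head_attention(toks, params, h = 1L)
  ref <- scaled_dot_attention(toks %*% params$Wq, toks %*% params$Wk,
                              toks %*% params$Wv, scale = sqrt(d))$output
  expect_equal(f1, ref %*% params$Wo, tolerance = 1e-12)
  # output width d per token
  f2 <- multi_head_attention(toks, params, h = 2L)
  expect_equal(dim(f2), c(3L, d))
  # two-head manual computation
  manual <- matrix(0, 3, d)
  for (i in 1:2) {
    cols <- ((i - 1) * 2 + 1):(i * 2)
    manual[, cols] <- scaled_dot_attention(
      (toks %*% params$Wq)[, cols], (toks %*% params$Wk)[, cols],
      (toks %*% params$Wv)[, cols], scale = sqrt(d))$output
  }
  expect_equal(f2, manual %*% params$Wo, tolerance = 1e-12)
  expect_error(multi_head_attention(toks, params, h = 3L), "divide")
})

test_that("the decoder MLP is an affine-ReLU stack over the concatenation", {
  d <- 4L
  f0 <- stats::rnorm(d); f1 <- stats::rnorm(d)
  fe <- stats::rnorm(d / 2); fm <- stats::rnorm(d / 2)
  width <- 2L * d + d   # with the edge summary
  mlp0 <- list(weights = list(matrix(0, width, 1)), biases = list(3.25))
  expect_equal(decode_scc(f0, f1, fm, mlp0, f_edge = fe), 3.25)
  # hand-set single hidden layer
  set.seed(8)
  W1 <- matrix(stats::rnorm(width * 3), width, 3); b1 <- stats::rnorm(3)
  W2 <- matrix(stats::rnorm(3), 3, 1); b2 <- 0.4
  mlp <- list(weights = list(W1, W2), biases = list(b1, b2))
  x <- c(f0, f1, fe, fm)
  expect_equal(decode_scc(f0, f1, fm, mlp, f_edge = fe),
               drop(pmax(drop(x %*% W1) + b1, 0) %*% W2) + b2,
               tolerance = 1e-12)
  # swapping the atoms changes the prediction in general
  expect_false(isTRUE(all.equal(decode_scc(f0, f1, fm, mlp, f_edge = fe),
                                decode_scc(f1, f0, fm, mlp, f_edge = fe))))
  expect_error(decode_scc(f0, f1, c(fm, 1), mlp, f_edge = fe), "width")
})

test_that("grouped log-MAE reproduces worked values and detects translations", {
  # one type, all absolute errors 1 Hz
  r1 <- grouped_log_mae(rep(2, 5), rep(1, 5), rep("3JHH", 5))
  expect_equal(r1$score, 0)
  # perfect predictions clamp at the floor
  r2 <- grouped_log_mae(1:4, 1:4, rep("1JHC", 4), floor = 1e-9)
  expect_equal(r2$score, log(1e-9))
  # two types with MAEs e and e^2 average to 1.5
  y <- rep(0, 4); p <- c(exp(1), exp(1), exp(2), exp(2))
  r3 <- grouped_log_mae(p, y, c("1JHC", "1JHC", "2JHH", "2JHH"))
  expect_equal(r3$score, 1.5, tolerance = 1e-12)
  expect_equal(unname(r3$per_type_mae), c(exp(1), exp(2)))
  # translation detectability: +c on one type's perfect predictions
  obs <- c(1, 2, 3, 4); prd <- obs
  types <- c("1JHC", "1JHC", "3JHH", "3JHH")
  prd[types == "3JHH"] <- prd[types == "3JHH"] + 0.37
  r4 <- grouped_log_mae(prd, obs, types)
  expect_equal(unname(r4$per_type_mae["3JHH"]), 0.37)
  # pooled variant
  r5 <- grouped_log_mae(p, y, c("1JHC", "1JHC", "2JHH", "2JHH"), pooled = TRUE)
  expect_equal(r5$score, log(mean(c(exp(1), exp(1), exp(2), exp(2)))))
  expect_error(grouped_log_mae(1, NA_real_, "1JHC"), "no labelled")
})

test_that("the batched engine agrees with the reference operation pipeline", {
  sim <- tiny_sim(n = 4, seed = 13)
  mc <- small_mcfg(d = 8, h = 2, seed = 2)
  fg <- featurize(sim$dataset, bonds = sim$bonds,
                  config = feature_config(d_model = 8))
  fg <- normalize_features(fg, feature_stats(fg))
  p <- gaann_init(mc)
  set.seed(31)  # randomise the zero-initialised output layer
  nd <- attr(p, "n_dec")
  p[[paste0("dec_W", nd)]][] <- stats::rnorm(length(p[[paste0("dec_W", nd)]]), sd = 0.3)
  pred_engine <- gaann_forward(p, fg, mc)
  pred_ref <- reference_forward(p, fg, mc)
  expect_equal(pred_engine, pred_ref, tolerance = 1e-9)
})

test_that("forward is deterministic, permutation invariant, and batch independent", {
  sim <- tiny_sim(n = 6, seed = 17)
  mc <- small_mcfg(d = 16, h = 2, seed = 3)
  fg <- featurize(sim$dataset, config = feature_config(d_model = 16))
  st <- feature_stats(fg)
  fg <- normalize_features(fg, st)
  p <- gaann_init(mc)
  set.seed(32)
  nd <- attr(p, "n_dec")
  p[[paste0("dec_W", nd)]][] <- stats::rnorm(length(p[[paste0("dec_W", nd)]]), sd = 0.3)

  pred1 <- gaann_forward(p, fg, mc)
  expect_identical(pred1, gaann_forward(p, fg, mc))   # determinism

  # batch-of-one equals the same molecule inside a batch-of-many
  pred_single <- gaann_forward(p, fg, mc, batch_molecules = 1L)
  expect_equal(pred_single, pred1, tolerance = 1e-10)

  # atom relabelling: permute one molecule's atoms and remap its records
  ds <- sim$dataset
  nm <- names(ds$molecules)[1]
  mol <- ds$molecules[[nm]]
  n <- length(mol$elements)
  set.seed(33)
  perm <- sample(n); inv <- order(perm)
  ds$molecules[[nm]] <- molecule(nm, mol$elements[perm], mol$coords[perm, ])
  sel <- ds$records$molecule_name == nm
  ds$records$atom_index_0[sel] <- inv[ds$records$atom_index_0[sel] + 1L] - 1L
  ds$records$atom_index_1[sel] <- inv[ds$records$atom_index_1[sel] + 1L] - 1L
  fg2 <- normalize_features(featurize(ds, config = feature_config(d_model = 16)), st)
  pred2 <- gaann_forward(p, fg2, mc)
  expect_equal(pred2, pred1, tolerance = 1e-5)
})

test_that("zeroed Conv maps leave node states at their embeddings", {
  sim <- tiny_sim(n = 3, seed = 19)
  mc <- small_mcfg(d = 8, h = 2, seed = 4)
  fg <- featurize(sim$dataset, config = feature_config(d_model = 8))
  fg <- normalize_features(fg, feature_stats(fg))
  p <- gaann_init(mc)
  p$convA_b[] <- 0; p$convb_b[] <- 0
  p$convA_c[] <- 0; p$convb_c[] <- 0
  batch <- gaann:::.build_batch(fg, seq_along(fg$mol_names), 8)
  fw <- gaann:::.engine_forward(p, batch, mc, keep = TRUE)
  H0 <- sweep(batch$A %*% p$Wa, 2, p$ba, "+")
  expect_equal(fw$cache$Htok, H0[batch$tok_atoms, ], tolerance = 0)
})

test_that("analytic gradients match finite differences for every block", {
  sim <- tiny_sim(n = 5, seed = 23)
  mc <- small_mcfg(d = 8, h = 2, seed = 5)
  fg <- featurize(sim$dataset, config = feature_config(d_model = 8))
  fg <- normalize_features(fg, feature_stats(fg))
  p <- gaann_init(mc)
  set.seed(34)
  nd <- attr(p, "n_dec")
  p[[paste0("dec_W", nd)]][] <- stats::rnorm(length(p[[paste0("dec_W", nd)]]), sd = 0.3)
  batch <- gaann:::.build_batch(fg, seq_along(fg$mol_names), 8)
  fw <- gaann:::.engine_forward(p, batch, mc, keep = TRUE)
  lg <- gaann:::.loss_grad(fw$pred, batch$y, batch$types, 1e-9,
                           method = "mse", t_sd = batch$t_sd)
  gr <- gaann:::.engine_backward(p, batch, mc, fw$cache, lg$g)
  loss_at <- function(pp) {
    f <- gaann:::.engine_forward(pp, batch, mc)
    gaann:::.loss_grad(f$pred, batch$y, batch$types, 1e-9,
                       method = "mse", t_sd = batch$t_sd)$loss
  }
  eps <- 1e-6
  set.seed(35)
  for (nm in names(p)) {
    idx <- sample(length(p[[nm]]), min(3, length(p[[nm]])))
    for (i in idx) {
      p1 <- p; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- p; p2[[nm]][i] <- p2[[nm]][i] - eps
      num <- (loss_at(p1) - loss_at(p2)) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})
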