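# gaann — graph angle-attention neural networks for NMR scalar coupling

NMR scalar coupling constants (J-couplings, in Hz) report the interaction
between two magnetic nuclei mediated by the bonding electrons, and are a
workhorse observable for solving molecular structures. Measuring them at
scale is expensive and computing them with DFT is slow, so data-driven
surrogates that predict J from 3-D structure alone are attractive. The
classic Karplus equation, `J = A cos²φ + B cosφ + C` in the dihedral angle
φ, ties vicinal (three-bond) couplings to geometry; this package builds that
angular prior into a graph neural network that handles all eight
hydrogen-containing coupling types (¹J_HC, ¹J_HN, ²J_HC, ²J_HH, ²J_HN,
³J_HC, ³J_HH, ³J_HN).

`gaann` is aimed at computational chemists and ML-for-chemistry researchers
who want a self-contained, CPU-friendly implementation of the model, its
feature engineering, and the experiments that probe what the angle
mechanisms contribute.

## The model

Each molecule is seen through two graphs over the same atoms: the chemical
**bond graph** and the **coupling graph** whose edges are the labelled
coupling pairs. Atoms carry hidden states `h_v ∈ R^d`; every directed edge
carries a learned state matrix `e_vw ∈ R^{d × d/2}` embedded from its raw
features. One encoder iteration runs

1. **Bond message passing with angle attention**
   `h_v ← h_v + Σ_{w→v} attn_vw · rowSums(Conv(h_w) ⊙ e_vw)`,
   where `Conv` is a zero-padded sliding-window unfold of `h_w` followed by
   a shared position-wise linear map, and the scalar weight of each directed
   bond is the Karplus-form mean over its neighbouring bond angles θᵢ at the
   head atom: `attn = Σᵢ (A′ cos²θᵢ + B′ cosθᵢ + C′) / M`. The three
   coefficients are learned globally and initialise at `(0.12, 0.99, 0.27)`.
2. **Coupling message passing** — the same update over the coupling graph,
   without the attention factor.

After `T` iterations, multi-head scaled dot-product self-attention
(`softmax(QKᵀ/√d) V` per molecule, applied residually) mixes the states of
the coupled atoms, and an MLP decodes each record from
`f_atom0 ⊕ f_atom1 ⊕ f_edge ⊕ f_mol` — the two attended atom features, a
learned summary of the record's own coupling-edge features (distance
powers and the angle cosines of the pair), and the molecule feature.
The evaluation criterion is the grouped log-MAE: the mean over coupling
types of `ln(MAE_type)`.

Coupling-edge features carry the geometry the Karplus picture says matters:
the dihedral cosine along the 3-bond path, the bond-angle cosine on 2-bond
paths, the coupled-atom distance (as d, 1/d, 1/d³), and the two
nearest-neighbour "geometric angles" of the pair.

Everything is implemented in base R matrices with hand-derived analytic
gradients (verified against finite differences in the test suite) and a
small set of Rcpp kernels for the message-passing inner loops; training
uses Adam under a one-cycle learning-rate policy.

## Worked example

Simulate a desk-scale dataset with Karplus-law labels, train a small model,
and evaluate it:

```r
library(gaann)

sc  <- synthetic_config(n_molecules = 100, noise_sd = 0,
                        keep_types = "3JHH", seed = 11)
sim <- simulate_dataset(sc)
sim$dataset
#> <scc_dataset> 92 molecules, 877 coupling records (877 labelled)
#> 3JHH
#>  877

fit <- gaann_train(sim$dataset,
                   model_config(d_model = 64, heads = 4, T_mp = 2,
                                decoder_hidden = c(64, 32), seed = 1),
                   train_config(epochs = 60, max_lr = 3e-3, batch_size = 8,
                                validation_fraction = 0.2, seed = 1),
                   bonds = sim$bonds)
fit
#> <gaann_model> d_model = 64  heads = 4  T = 2
#>   trained 60 epochs; best val score = -0.2339
#>   angle attention coefficients (A', B', C') = -0.1004,  1.2089,  0.0577

exp(fit$best_val_score)        # validation MAE in Hz
#> [1] 0.791424
sd(sim$dataset$records$scc)    # label spread for comparison
#> [1] 2.538278
```

The labels here follow `J = 7cos²φ − cosφ + 5 (+3)` Hz with φ the H–C–C–H
dihedral, so a validation MAE of ~0.8 Hz against a 2.5 Hz label spread means
the network has recovered most of the angular law from coordinates alone —
the coefficients it learned for the bond-angle attention drift from their
initial values as the data demand. `gaann_evaluate()` returns the per-type
MAE table and the grouped log-MAE; `ablate()` reruns training with the
angle attention and angle features switched off in all four combinations;
`spearman_matrix()` and `pca_embed()` reproduce the interpretability
analyses. A thin command-line wrapper
(`system.file("cli", "gaann.R", package = "gaann")`) exposes
`simulate / train / predict / evaluate / ablate / analyze` subcommands.

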