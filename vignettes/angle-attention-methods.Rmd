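---
title: "Angle-attention graph networks for scalar coupling: model, features, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Angle-attention graph networks for scalar coupling: model, features, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the method: the model and its
assumptions, the feature engineering, the synthetic data the desk-scale
experiments run on, the numerical choices, and the places where the design
was genuinely open and we had to decide. Nothing here states an empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The prediction problem

A scalar coupling constant (SCC) couples two magnetic nuclei through the
bonding electrons; its magnitude depends on the number of bonds `N` on the
path between the nuclei (the superscript in `^N J_AB`), on the elements
involved, and on geometry. For three-bond couplings the Karplus equation

\[ J = A\cos^2\varphi + B\cos\varphi + C \]

ties `J` to the dihedral angle between the terminal bonds of the path.
There is no comparably clean law for one- and two-bond couplings, but bond
lengths and bond angles carry the analogous information. The package
predicts the eight hydrogen-containing coupling types (`1JHC`, `1JHN`,
`2JHC`, `2JHH`, `2JHN`, `3JHC`, `3JHH`, `3JHN`) from 3-D structure alone:
no charges, no shielding tensors, no electronic-structure input. That
restriction is deliberate — the angular and distance geometry is the
hypothesis being tested, and the ablation machinery (below) quantifies what
the angle terms contribute.

## Model

Two graphs share one atom set: the chemical bond graph (perceived from
covalent radii, or supplied) and the coupling graph whose edges are the
labelled pairs. The encoder is:

1. **Embedding.** Raw atom features go through a linear map to
   `h_v ∈ R^d` (`d = d_model`); raw edge features of either graph go
   through a linear map to `d·d/2` values, reshaped row-major into the edge
   state `e_vw ∈ R^{d×d/2}`.
2. **Bond message passing with bond-angle attention.** For every directed
   bond `w→v`,

   \[ h_v \leftarrow h_v + \sum_{w \in N(v)} attn_{vw}\,
      \mathrm{rowSums}\!\big(\mathrm{Conv}(h_w) \odot e_{vw}\big), \]

   with \(attn = \frac{1}{M}\sum_{i=1}^{M} (A'\cos^2\theta_i +
   B'\cos\theta_i + C')\) over the `M` angles between the bond and its
   neighbouring bonds at the head atom. `A', B', C'` are three global
   learnable scalars initialised at `(0.12, 0.99, 0.27)`; a terminal bond
   with no neighbours gets the neutral weight 1. With the default
   coefficients `attn` is strictly decreasing in a single neighbour angle
   over `[0°, 180°]` (since `2A'cosθ + B' > 0` for all `cosθ ∈ [−1, 1]`),
   matching the picture that aligned orbitals couple most strongly.
3. **Coupling message passing** — the identical update over the coupling
   graph with `attn ≡ 1`: bond angles act through chemical bonds, not
   through the virtual coupling edges. Each labelled pair contributes two
   directed edges sharing one feature vector.
4. Steps 2–3 repeat `T` times (default 2).
5. **Self-attention** over each molecule's coupled atoms (the atoms that
   appear in at least one record): multi-head scaled dot-product attention
   `softmax(QKᵀ/scale)V`, heads in separate subspaces, concatenated and
   mapped by `W_O`, applied **residually**: `f = h + MHA(h)`.
6. **Decoder.** Each record is predicted by a ReLU MLP on
   `f_{atom0} \oplus f_{atom1} \oplus f_{edge} \oplus f_{mol}` — the two
   attended atom features (`d` each), a learned `d/2` summary of the
   record's own coupling-edge features, and the `d/2` molecule embedding.

**The Conv operation.** `Conv(h)` reshapes the length-`d` state to the
`d × d/2` edge shape by a stride-1 sliding window of width `d/2`, zero
padded past the end (row `r` holds `h[r..r+d/2−1]`), then applies one
learned `d/2 × d/2` linear map shared across rows ("position-wise" in the
transformer sense). The sum over the `d/2` window slots of
`Conv(h_w) ⊙ e_vw` reduces the matrix product back to a length-`d`
message; this row-sum contract is what makes the update dimensionally
consistent with the residual term.

### Design choices that were genuinely open

* **Residual attention.** The plain attention output at initialisation is
  close to a uniform average over a molecule's tokens, which collapses all
  coupled atoms onto their mean and erases the very distinctions the
  decoder needs. The residual form `h + MHA(h)` (standard transformer
  encoder practice) preserves token identity; without it the model cannot
  leave the per-molecule-mean prediction regime at desk scale.
* **The decoder sees the coupling edge.** The virtual coupled edge is
  concatenated with the two atom features before decoding. This is not an
  optional enrichment: per-atom aggregates are invariant under the internal
  symmetry of a rotor (for a methyl pair, the sums of Karplus terms over
  the three partners are the same for every hydrogen), so a decoder fed
  only atom states provably cannot distinguish gauche from trans pairs in
  an ethane-like molecule. The `d/2` edge summary restores
  identifiability; `decode_scc()` accepts it as an optional argument so the
  atoms-plus-molecule form remains available.
* **Attention logit scale.** The scale is `√d_model` by default
  (`scale_per_head = TRUE` switches to `√(d/h)`), since the per-head
  convention is the common alternative.
* **T.** "Two-layer message passing" and "after T iterations" admit several
  readings; `T_mp = 2` (two bond+coupling rounds) is the default, exposed
  in `model_config()`. Conv parameters are tied across iterations
  (separate maps for the bond and coupling layers).
* **Metric grouping.** `grouped_log_mae()` averages `ln(MAE_t)` over the
  coupling types present (with floor `1e-9`), the convention under which
  near-zero 2J/3J errors and large 1J errors are commensurable; a pooled
  variant is a flag.

## Training

Training is full analytic backpropagation (finite-difference-verified in
the tests) with Adam under a one-cycle learning-rate policy (linear warm-up
over 30% of steps, cosine anneal; the policy parameters are defaults in
`train_config()`, since only the policy itself, not its constants, is part
of the method). Validation splits are **by molecule**, never by record, so
coupling pairs of one molecule can never straddle the split. Two training
pragmatics matter at desk scale:

* **Loss.** The grouped log-MAE is the *evaluation* criterion, and is
  selectable as the training loss, but its gradient is a scaled sign — under
  Adam's per-parameter normalisation that leaves a persistent noise floor
  which, in small-data regimes, traps the model at the per-type-mean
  prediction. The default training loss is therefore squared error on
  per-type standardised labels (`loss = "mse"`); since
  `log(MAE/σ_t) = log MAE − log σ_t`, per-type standardisation shifts the
  grouped objective only by a constant.
* **Output parameterisation.** Labels are z-scored per coupling type
  (statistics from the training split, stored in the model); the final
  decoder layer is zero-initialised so optimisation starts exactly at the
  per-type mean. Predictions are mapped back to Hz before any metric.
* **Initialisation.** All weights are uniform with fan-in scaling from one
  seed. The edge-embedding maps get a gain of 0.1 (`edge_gain`): messages
  are multiplicative in the edge states, and this keeps the node-state
  stream near unit scale through `T = 2` iterations instead of growing by
  an order of magnitude per pass, which would let the atom blocks swamp
  the decoder's edge block.

## Synthetic data: what it emulates and what it does not

`simulate_dataset()` produces molecules and labels in the
champs-scalar-coupling CSV dialect so that every pipeline stage is testable
without downloads. Generator defaults define the desk-scale study
conditions:

* random acyclic heavy-atom skeletons of 2–6 C/N/O atoms (sampled 70/20/10),
  heavy–heavy bonds 1.5 Å, X–H bonds 1.09 Å, hydrogens filling standard
  valences (C 4, N 3, O 2);
* tetrahedral substituent slots at random torsion azimuths, each placed
  direction perturbed by a rotation of sd 5°, and every bond length
  perturbed by sd 0.02 Å. The length jitter removes a degeneracy real data
  never has — exactly tied interatomic distances (which would make
  nearest-neighbour constructions ambiguous under atom relabelling) and a
  zero-variance 1J label distribution;
* labels from the bond-count-appropriate law on the true geometry:
  `7cos²φ − cosφ + 5` Hz for 3J (the classic vicinal-HH constants, used
  here as arbitrary ground truth), `−10 + 6cosθ` for 2J, `180 − 60(d−1)`
  for 1J, plus per-partner-element offsets (C 0, N −5, H +3) and Gaussian
  noise of sd 0.5 Hz (0 where an experiment says noise-free).

Because the labels depend on angles *by construction*, angle sensitivity is
recoverable in principle, and the tests check that the model recovers it in
practice. What passing those tests does **not** show: anything about
conformer ensembles, rings and aromaticity (the generator grows trees
only), electronic substituent effects, or the accuracy attainable on real
DFT-labelled data — the synthetic labels are exactly the stated laws, so
the task is easier and cleaner than reality in every respect except its
deliberately small sample size.

## Desk-scale experiments

The acceptance machinery (`tests/testthat/test-acceptance.R`,
`scripts/acceptance.R`) runs, from scratch:

* **Karplus recovery.** 200 noise-free molecules restricted to `3JHH`; a
  small model (`d = 64`, 4 heads, `T = 2`, decoder 64/32) trained 40 epochs
  (batch 8, peak rate 3e-3, 20% of molecules held out), median over three
  seeds. Reported as the validation MAE relative to the label spread and to
  a constant-mean baseline.
* **Ablation.** The same data and seeds across four arms — angle attention
  and angle features each on/off. The `attn` toggle replaces every bond
  weight by 1; the `feats` toggle zeroes the angle cosines and presence
  flags in the coupling-edge block. Only the toggles differ; data, split,
  initialisation seed and schedule are shared. The full arm doubles as the
  recovery experiment.
* **Spearman echo.** On 2J data whose labels are affine in the bond-angle
  cosine, the rank correlation of `cos(bond angle)` with the SCC is
  compared against an injected independent decoy feature.

Problem sizes were chosen so the whole acceptance computation runs in
minutes on one CPU while leaving the statistical conclusions
unambiguous.

## Numerical notes and degenerate inputs

* Angles are computed through `acos` of a clamped cosine; dihedrals are
  unsigned (`[0°, 180°]`) because only `cos φ` enters features or labels.
* A degenerate dihedral (collinear path arm) or a nearest neighbour that
  coincides with the coupled partner yields an absent angle: the feature is
  imputed as cosine 0 with its presence flag cleared, and the record is
  kept.
* The bond-graph path length is cross-checked against the coupling type's
  declared bond count; on disagreement the declared count wins (the label
  defines the type) and the path angle is absent.
* Bond perception uses Cordero-style covalent radii
  (C 0.76, H 0.31, N 0.71, O 0.66, F 0.57 Å) with cutoff scale 1.3 —
  1.2 misses the 0.74 Å H–H bond — and at most one bond per hydrogen
  (shortest kept). Nearest-neighbour and path ties break toward the
  smallest atom index.
* `z`-scoring exempts one-hots, flags and cosines; zero-variance slots keep
  scale 1. Statistics always come from the training split and travel with
  the model.
* Checkpoints carry the model and feature configuration, the feature-layout
  manifest with a hash, the normalisation and label statistics, and all
  parameters; loading verifies the layout hash.

## Known limitations

* Tree molecules only; no rings, no bond orders, no aromaticity.
* The five-element alphabet (C, H, N, O, F) is enforced, not extended.
* Single model for all eight types — type identity enters only through the
  coupling-edge one-hot; there are no per-type specialist heads.
* The self-attention layer operates per molecule over coupled atoms only;
  uncoupled atoms influence predictions solely through message passing.
* Training is CPU-oriented and deterministic given seeds up to BLAS
  reduction order; there is no GPU path.
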