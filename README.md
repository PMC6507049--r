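# chargepatch

Charged-surface-patch solubility prediction and pH-dependent stability
analysis for protein engineering, in R.

Recombinant proteins over-expressed in *E. coli* often aggregate into
inclusion bodies, and soluble expression correlates inversely with the
size of the largest positively-charged patch on the protein surface.
`chargepatch` implements that predictor and the surrounding design loop
for charge engineering — the workflow used to design erythropoietin
variants with altered solubility:

* solvent-accessible **dot surfaces** (deterministic golden-spiral
  sampling, per-dot areas in Å²);
* screened-Coulomb (**Debye–Hückel**) potentials at surface dots,
  φ(p) = Σᵢ qᵢ e·exp(−κdᵢ)/(4πε₀εᵣdᵢ), in mV, with κ ∝ √I;
* **patch segmentation** at the ±25 mV contours into positive, negative
  and non-charged connected patches, and the solubility score
  ratio = posQmax / threshold (ratio > 1.0 ⇒ predicted insoluble);
* threshold **calibration** on labelled (patch size, soluble/insoluble)
  data by balanced-accuracy scan;
* in-silico **charge mutagenesis** by deterministic sidechain replacement
  and a systematic screen of patch residues (basic→Asp, any→Asp,
  acidic→Arg/Lys);
* protonation-state thermodynamics — exact 2^N enumeration and Metropolis
  **Monte Carlo titration** — giving the pH-dependent ionisable-group
  contribution to folded-state stability,
  pHstab = G_folded − G_unfolded at pH 7 (negative = favourable);
* an **orthologue survey** that threads homologue sequences onto a
  template backbone by sidechain replacement and tabulates per-model
  patch ratios and pHstab.

Because no experimental coordinates ship with the package, a clearly
labelled **synthetic** erythropoietin model (`epo_bundle_model()`: the
crystal-construct sequence on an idealised four-helix bundle, built
entirely in code) and a family of toy generators with closed-form
expectations (`make_toy()`) provide all inputs for the examples and the
test suite. See the vignette in `vignettes/` for the model, its
assumptions and its limitations.

## Worked example

```r
library(chargepatch)

# the synthetic EPO variant panel under one shared configuration,
# threshold anchored once on the wild type
panel <- epo_variant_profiles()
panel
#> Synthetic EPO variant panel (threshold 750.3 A^2)
#>        name posQmax ratio prediction
#>          WT    1118 1.490  insoluble
#>        E13K    1328 1.770  insoluble
#>        F48D    1044 1.391  insoluble
#>       R150D     817 1.089  insoluble
#>  F48D/R150D     654 0.871    soluble
```

posQmax is the area (Å²) of the largest connected surface region whose
potential exceeds +25 mV; the ratio divides it by the threshold. The
charge-swap variants move the score in the expected directions: adding a
positive charge at the patch rim (E13K) grows it, introducing or swapping
in negative charge (F48D, R150D and the double mutant) shrinks it, and
the double mutant crosses below 1.0, flipping the call to soluble.

Single-step use mirrors the pipeline:

```r
s    <- epo_bundle_model(mutations = "R150D")
surf <- link_neighbours(build_dot_surface(s))
phi  <- surface_potential(surf, s, es_params(ionic_strength = 0.15))
pat  <- segment_patches(surf, phi, structure = s)
solubility_profile(pat, threshold = 750)

# pH-dependent stability of the ionisable-group network
ph_stability_of(s, method = "mc", seed = 1)

# systematic screen: every Arg/Lys in the largest positive patch -> Asp
screen_patch_mutations(s, pat, threshold = 750)
```

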