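# rotasuite

How far do ribose ¹³C′ chemical shifts identify RNA backbone
conformations?

RNA backbone conformations cluster into 46 consensus *suite* rotamers,
defined over the seven torsions δ(i−1), ε(i−1), ζ(i−1), α(i), β(i), γ(i),
δ(i) of the sugar-to-sugar subunit, and into coarser rotamer families —
down to the four δδ families, which are exactly the ribose pucker pairs
(C3′-endo/C2′-endo at each of the two sugars).  `rotasuite` implements a
desk-scale pipeline that asks how well the five ribose carbon shifts
(C1′–C5′) classify suites into rotamers and families:

* a packaged rotamer **catalog** (46 ids, mean torsions, spreads,
  frequencies) and the seven **family schemes** (22 / 10 / 10 / 7 / 4
  families plus the two A-form splits);
* **suite geometry**: backbone dihedrals from PDB/mmCIF structures, suite
  assembly with chain-break handling, and nearest-rotamer assignment by
  circular torsion distance, `d = sqrt(Σ wrap(θ_k − μ_k)²)`;
* a **rigid-geometry Monte-Carlo sampler**: per-sequence dinucleotide
  templates, torsion draws from wrapped normals, clash elimination, and
  Shannon-entropy subsample-size selection
  (`S = −Σ P_i ln P_i` over 5° histogram bins, 80% cutoff);
* a **synthetic shielding generator** standing in for quantum-chemical
  data, with pucker-dominated effects, weak α/γ terms, sequence offsets
  and the 1.47 ppm experimental-like noise; referencing via
  `δ_comp = σ_ref − σ_comp` (simple σ_ref = 185.00 ppm, plus four
  fittable effective-reference schemes);
* **ROSUM** (rotamer substitution matrix) weighted scoring,
  `W[a,b] = exp(−d(a,b)²/2λ²)`, with a random-choice baseline
  calibration, and the three regimes — train-on-theory/test-on-experiment,
  LOO within theory, LOO within experiment — over NN, decision-tree,
  random-forest, MLP and SVM classifiers.

The packaged catalog is a **synthetic stand-in** (see the asset header and
the methods vignette): ids, family columns and the four printed
representative rows are the published values; the other 42 rows are
constructed to be structurally consistent.  Results on it demonstrate the
method's properties, not measurements of the real catalog.

## Worked example

```r
library(rotasuite)

cat46 <- load_catalog()
assign_rotamer(c(81, 212, 289, 295, 174, 54, 81), cat46)
#>   rotamer_id distance
#> 1         1a        0

res <- run_pipeline(demo_config(seed = 1))
subset(res$reports, regime == "exp_vs_theo",
       c(scheme_id, classifier, weighted_accuracy, f1))
```

At the demo scale (10 rotamers spanning all four pucker families, two
sequences, 40 conformers each, 1.47 ppm test noise) this prints, for the
one-shot train-on-theory regime:

```
   scheme_id classifier weighted_accuracy    f1
 1   rotamer         NN             0.846 0.277
 2   rotamer         DT             0.843 0.246
 3   rotamer         RF             0.850 0.261
 4   rotamer        MLP             0.844 0.241
 5   rotamer        SVM             0.855 0.305
 6   rotamer       RAND             0.806 0.110
 7        dd         NN             0.896 0.680
 8        dd         DT             0.878 0.627
 9        dd         RF             0.900 0.665
10        dd        MLP             0.911 0.727
11        dd        SVM             0.908 0.716
12        dd       RAND             0.780 0.277
```

Reading it: the 46-rotamer task is hard from five shifts (F1 ≈ 0.24–0.31),
the four pucker-pair (δδ) families are classified well by every learner
(F1 ≈ 0.63–0.73), and both beat the random baseline; the weighted accuracy
stays high throughout because ROSUM gives partial credit to near misses in
torsion space.  LOO within noiseless theory reaches F1 ≈ 1.0 for the δδ
families.  The numbered scripts under `analysis/` walk the same study
step by step (catalog → sampling/entropy → synthetic shifts → ROSUM →
classification → noise and sparsity experiments), writing their tables
under `results/`.

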