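# endocargo

Analysis pipeline for organelle-immunoprecipitation (Endo-IP / Lyso-IP)
quantitative proteomics, built for studies that capture intact endosomes
(via tagged EEA1) or lysosomes (via tagged TMEM192) and profile them by
multiplexed TMT mass spectrometry against untagged controls. The package
answers the questions such a study asks: which proteins are enriched in
the captured organelle, how the endosomal and lysosomal proteomes overlap
across cell states, how endolysosomal protein abundance evolves across
neuronal differentiation, which enriched plasma-membrane proteins are
candidate endocytic cargo, and which of those carry SNX27 (PDZ) or SNX17
(FERM) recycling sorting motifs that survive a structure-prediction
(ipTM) screen.

Every stage is driven by a synthetic-data generator with planted ground
truth — compartment-structured enrichment effects, a shared endolysosomal
core, endocytosed plasma-membrane cargo, planted sorting motifs — so the
whole pipeline is testable end to end without any external download.

## The statistics at the core

Per-protein enrichment (tagged vs control) uses empirical-Bayes variance
moderation: pooled two-group variances s²_g on d_g df are shrunk toward a
scaled-F prior (d₀, s₀²) fit by moment matching on log s²,

    s²_post = (d₀·s₀² + d_g·s²_g) / (d₀ + d_g)
    t = log2FC / sqrt(s²_post · (1/n_t + 1/n_c)),  df = d₀ + d_g

with Benjamini–Hochberg FDR and calls at log2FC ≥ 1.0 and q ≤ 0.01.
Candidate cargo = enriched ∧ (≥ 1 transmembrane segment) ∧ cell-membrane
annotation. Motif grammars: SNX27 = C-terminal [S/T]-x-Φ; SNX17 =
Φ-x-N-x-x-[Y/F], Φ = {A,V,L,I,M,F,W,Y}. Screen pass = ipTM strictly
> 0.6. Gene-set over-representation is hypergeometric (P[X ≥ k]) with BH.
See `vignettes/endocargo-methods.Rmd` for the full account.

## Worked example

The `analysis/` scripts run the whole study in order; each writes its
tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # synthetic study with ground truth
Rscript analysis/02_enrichment.R     # moderated enrichment calls
Rscript analysis/03_annotate_overlap.R
Rscript analysis/04_cluster_profiles.R
Rscript analysis/05_cargo.R
Rscript analysis/06_motif_screen.R
```

Output of the enrichment and cargo stages on the default seed:

```
[enrich] endo/iNeuron: 185/1500 enriched (d0 = 55.3, s0^2 = 0.118)
[enrich] replicate Endo-IPs: Jaccard 0.94, log2FC r 0.889
[cargo] 57 candidate cargo among 185 enriched proteins
[cargo] PM/TM universe 214, in Endo-IP 57 -> 26.6% (headline 27%)
[cargo] published counts give 30% (PM) and 20% (synaptic)
```

185 of 1,500 simulated proteins pass the enrichment cutoffs in the
iNeuron Endo-IP (the generator plants 193 true effects); 57 of the 214
plasma-membrane/TM proteins are called candidate cargo, close to the 30%
capture rate the generator plants; and from the published counts
(152 of 504 PM/TM proteins, 70 of 347 synaptic ones) `cargo_fraction()`
reproduces the 30% / 20% headline figures. The motif stage then reports:

```
[motif] screen summary (ipTM > 0.6):
  SNX27  candidate 155/168 peptides pass, 155/168 proteins
  SNX27  control     0/ 77 peptides pass,   0/ 77 proteins
[motif] top-10 logo IC at -3/[S/T] = 0.96, -1/Phi = 0.43
[motif] bottom-10 logo IC at -3/[S/T] = 0.38, -1/Phi = 0.19
```

Motif-bearing candidates pass the mock screen, motif-free controls do
not, and the top-10 logo concentrates information at the motif-defining
C-terminal positions.

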