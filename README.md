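# vsdflex

Sequence-based local flexibility profiling of voltage-sensor domains (VSDs).

## The problem

Voltage-gated ion channels and their relatives (K<sub>V</sub>, Na<sub>V</sub>,
Ca<sub>V</sub>, TRP, CNG, HCN, BK, Hv1 proton channels, voltage-sensing
phosphatases, …) share a four-helix voltage-sensor module, S1–S4. The third
helix, S3, is one of its most mobile elements, and its intrinsic flexibility —
predictable from amino acid composition alone — tracks how a channel is gated:
compositionally rigid S3 segments co-occur with strong temperature sensitivity
(high Q<sub>10</sub>) and with stretch-activation, while highly flexible S3
segments are typical of ligand-gated, weakly voltage-dependent channels.

`vsdflex` implements that analysis as a reusable pipeline for anyone studying
VSD sequence families:

1. **Consensus construction** — per-column residue frequencies, the three
   ranked consensus sequences of a family alignment, and sequence-logo
   matrices (Shannon information in bits, with the conventional side-chain
   color classes).
2. **Segment anchoring** — locate the conserved NxxD motif of S3 (and its
   FxxD and C/S-x-x-D family variants) and cut the three analysis windows:
   S3 (anchor → S3 C-end), S3–S4 (anchor → S4 C-end) and S1–S4 (whole VSD),
   using per-family boundary annotations.
3. **Flexibility indices** — map each residue to a normalized B-value,
   smooth over a 9-residue neighbor window, and summarize a segment by its
   mean B-factor `mBf` and the flexibility index `1/mBf` (larger = more
   flexible), with a cross-rank dispersion from the rank-1..3 consensus
   sequences. Families are categorized as rigid / intermediate / flexible.
4. **Charge-transfer-center geometry** — parse PDB/mmCIF structures and
   measure donor–acceptor distances (Lys Nζ; Arg guanidinium nitrogens; the
   Asp/Glu carboxylate oxygens), calling salt bridges at the inclusive
   4.0 Å cutoff, plus motif-anchored Cα superposition RMSD.
5. **Structure–function correlation** — join indices with the packaged
   channel table (gating charge per channel *e₀*, Q<sub>10</sub> of
   activation/inactivation kinetics, stretch-induced ΔV<sub>1/2</sub> shifts)
   and fit the modified single exponential

   f(x) = a · exp[ b / (x + c) ]

   by nonlinear least squares, alongside Spearman rank correlations with
   permutation p-values and an exact class–trait association test.
6. **Synthetic data** — generators for family alignments with implanted
   motifs, toy coordinate files with prescribed distances, and functional
   tables with known effect structure, so every stage can be validated
   against ground truth.

## Worked example

Three synthetic families spanning the flexibility range, profiled end-to-end:

```r
library(vsdflex)

root <- tempdir()
dir.create(file.path(root, "aln"), showWarnings = FALSE)
comps <- list(
  TRPVlike = uniform_composition(c("W", "F", "I", "V")),   # rigid side chains
  Kvlike   = uniform_composition(c("L", "A", "T", "G")),   # intermediate
  CNGlike  = uniform_composition(c("K", "S", "N", "E")))   # flexible
for (id in names(comps)) {
  spec <- family_spec(id, n_sequences = 60, length = 50,
                      composition = comps[[id]], implant_at = 10,
                      boundaries = list(s1_start = 2, s3_end = 26, s4_end = 48),
                      noise_rate = 0.02, seed = match(id, names(comps)))
  fam <- generate_family_alignment(spec)
  seqs <- apply(fam$alignment$seqs, 1, paste, collapse = "")
  writeLines(c(rbind(paste0(">", names(seqs)), seqs)),
             file.path(root, "aln", paste0(id, ".fasta")))
}
write.table(data.frame(family_id = names(comps), s1_start = 2, s3_end = 26,
                       s4_end = 48, motif_variant = "NxxD"),
            file.path(root, "boundaries.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

res <- run_pipeline(list(alignments_dir = file.path(root, "aln"),
                         boundaries = file.path(root, "boundaries.tsv"),
                         scale = "rigidity",
                         output_dir = file.path(root, "out"),
                         functional_table = "packaged", seed = 1,
                         log_level = "quiet"))
res$summary[res$summary$segment == "s3",
            c("family_id", "anchor", "start", "end", "mBf", "index", "dispersion")]
```

```
 family_id anchor start end    mBf  index dispersion
   CNGlike     10    10  27 0.9116 1.0970   0.005599
    Kvlike     10    10  27 0.9681 1.0330   0.015616
  TRPVlike     10    10  27 1.0424 0.9593   0.009635
```

The implanted NxxD anchor (column 10) and the annotated S3 window `[10, 27)`
are recovered for every family, and the index `1/mBf` orders the families
exactly as their generating compositions do: the charged/polar "CNG-like"
family is the most flexible (1.097), the aromatic/branched "TRPV-like" family
the most rigid (0.959). `dispersion` is the population standard deviation of
the index across the three ranked consensus sequences — a measure of how much
the family's residual composition heterogeneity moves the index.

Fitting the modified exponential to the packaged channel table (S3 indices
against family rank):

```r
fit_flexibility_curve(load_functional_table(), x_var = "rank")
#> <vsd_fit> f(x) = 0.7386 * exp(71.31 / (x + 84.46)); R^2 = 0.9362 (n = 24)
```

A thin command-line front end over the same functions ships at
`inst/scripts/vsdflex-pipeline.R` (subcommands `consensus`, `flexibility`,
`ctc-geometry`, `correlate`, `simulate`, `run-all`; exit codes 0/1/2 for
ok / stage failure / configuration error).

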