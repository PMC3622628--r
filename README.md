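# demixtx

Cell-type-specific transcript abundance estimation from mixed-tissue
RNA-seq.

## The problem

Many tissue samples are heterogeneous — a tumour biopsy is tumour cells
plus surrounding normal cells. Running a conventional transcript
quantifier on RNA-seq reads from such a sample estimates the abundance
profile of the *mixture*, which is then often misinterpreted as the
profile of the cell type of interest. `demixtx` deconvolves the two:
given single-end reads from a **pure sample** (cell type *a* only, e.g.
normal tissue) and from a **mixed sample** (cell types *a* and *b* at
proportions τᵃ + τᵇ = 1), it estimates per-transcript abundances of
*both* cell types, including the one never observed in isolation.

## The model in brief

Reads are generated by drawing a transcript with probability

    α_t = ρ_t · l̃_t / Σ_k ρ_k · l̃_k,
    l̃_t = Σ_{x=1..l_t} p(x) · (l_t − x + 1)

(relative abundance weighted by *effective length* under a normal
fragment-length distribution, default N(200, 80²)), then a start
position uniformly within the admissible range. Multi-mapping reads
contribute a mixture over their candidate alignments. The mixed sample's
sampling probabilities are the linear blend τᵃαᵃ + τᵇαᵇ (the exact
nonlinearity factors Λ concentrate within 1 ± 0.05 for catalogs of
hundreds of transcripts; they are exposed as a diagnostic). The mixing
proportions carry a strong Beta prior centred on a user-supplied
proportion (pseudo-counts ≈ 10× the mixed read count), and the MAP
estimate is computed by a constant-memory **online (stepwise) EM**: one
E-step, interpolation with step size 1/(n+2)^σ (0.5 < σ ≤ 1, default
0.85), and implicit M-step per read, with the per-read loop compiled.
Optional positional (bin-method) and sequence-specific (Markov-chain)
bias weights re-weight each alignment. See
`vignettes/transcript-mixture-deconvolution.Rmd` for the full account.

## Worked example

Simulate a 60-transcript world (τᵇ = 0.6, 20k reads per sample, 30% of
transcripts sharing homologous blocks so reads multi-map), then fit from
the files:

```r
library(demixtx)
dir <- tempfile("demo")
cfg <- sim_config(n_transcripts = 60, length_range = c(500, 3000),
                  n_reads_pure = 20000, n_reads_mixed = 20000,
                  tau_b = 0.6, ambiguity_spec = 0.3, seed = 1)
paths <- cmd_simulate(dir, cfg)
res <- cmd_run(run_config(ref = paths$ref, pure = paths$pure,
                          mixed = paths$mixed,
                          out = file.path(dir, "fit"),
                          prior_b = 0.6, seed = 1))
head(read.delim(res$abundance), 5)
```

```
  transcript_id length eff_length est_counts_a est_counts_b     rho_a    rho_b
1        tx0001   1516     1315.6        21.54       166.10 0.0009406 0.017199
2        tx0002   1178      977.6        11.03       211.97 0.0006485 0.029538
3        tx0003   2676     2475.6        28.73       552.84 0.0006666 0.030421
4        tx0004   1429     1228.6       187.90       130.10 0.0087860 0.014426
5        tx0005   2032     1831.6        57.27        26.24 0.0017961 0.001952
```

Each row is one transcript: its raw and effective length, the expected
number of reads attributed to each cell type across both samples
(`est_counts_a` pools the pure sample with the a-share of the mixed
sample; `est_counts_b` is the b-share of the mixed sample), and the
deconvolved relative abundances (each ρ column sums to 1). The summary
JSON reports the estimated mixing proportions — here `tau_b = 0.5999`
against a simulated truth of 0.60065 b-labelled reads — plus the
log-posterior trace tail and stream statistics.

The benchmark that motivates the method (deconvolved vs naive estimation
of cell b across mixing proportions 0.4–0.9) runs with:

```r
tab <- run_benchmark(config = sim_config(seed = 2024))
```

At the default scale (400 transcripts, 100k reads per sample) the
deconvolved cell-b Error Fraction beats the naive mixed-sample estimate
at every grid point (e.g. 0.32 vs 0.49 at τᵇ = 0.9, 0.68 vs 0.91 at
τᵇ = 0.4), while the cell-a Error Fraction stays flat within 4
percentage points.

## Command line

```sh
Rscript -e 'demixtx::demix_cli()' run \
    --ref ref.fa --pure pure.sam --mixed mixed.sam \
    --prior-b 0.6 --out prefix \
    [--beta-scale 10 --frag-mean 200 --frag-sd 80 --forget 0.85 \
     --bias --epochs 2 --tol 1e-6 --seed 1 --max-candidates 10]
```

writes `prefix.abundance.tsv` and `prefix.summary.json`. Subcommands
`simulate`, `benchmark` and `eval` wrap the generator, the grid
experiment and the Error Fraction metric; SAM input must be name-grouped
(aligner default order) and aligned to the transcript FASTA's ids.

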