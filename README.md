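# cisnat

Identification, classification and expression screening of sense/antisense
gene pairs from genome annotation.

## The problem

Many genes have a partner transcribed from the opposite strand — either
overlapping them (cis-natural antisense transcripts, cis-NATs) or starting
nearby without overlap, as in divergent transcription from bidirectional
promoters and convergent transcription at shared 3′ ends. These antisense
partners can regulate their sense gene, so a first step in studying them is a
comprehensive, strand-aware catalogue of sense/antisense pairs together with
their geometry and, when expression data exist, the co-expression of the two
partners.

`cisnat` builds that catalogue from a plain gene-level annotation table (an
Ensembl-style GTF or an equivalent CSV). For genes to analyse it needs only
`(chromosome, strand, start, end)` per gene, plus biotype and source
annotations for stratified analyses.

## The classification

Every opposite-strand, same-chromosome gene pair receives exactly one of
eight structural types, decided by membership of the antisense TSS/TES in the
sense gene's interval `S = [start, end]` (closed intervals throughout):

| type | rule |
|------|------|
| `EB` | antisense TSS and TES both in `S` (embedded) |
| `HH` | only the antisense TSS in `S` (head-to-head, 5′ overlap) |
| `TT` | only the antisense TES in `S` (tail-to-tail, 3′ overlap) |
| `FO` | neither anchor in `S` but the intervals intersect (fully overlapped) |
| `nHH` / `fHH` | disjoint, antisense on the 5′ side; gap ≤ 5 kb = nearby, else faraway |
| `nTT` / `fTT` | disjoint, antisense on the 3′ side; same 5 kb split |

Pairs are extracted in three modes: mode 1 returns all overlapping pairs;
mode 2 returns pairs whose antisense TSS offset relative to the sense TSS
(measured along the sense gene's transcription direction, negative =
upstream) lies in a signed window `[min, max]`; mode 3 does the same for TES
offsets. For a plus-strand sense gene with TSS *t*, the mode-2 window
`(-500, -1)` is exactly the closed coordinate condition
`t − 500 ≤ antisense TSS ≤ t − 1`.

Downstream layers profile divergent/convergent transcription in 500-bp offset
bins over ±5 kb (per-bin percentage of sense genes with an antisense anchor
in the bin, split by RNA-biotype combination), and screen sense/antisense
pairs for correlated expression over a TPM time course: Spearman rank
correlation per pair, count-based offset bins, a random same-chromosome pair
null, the Dwass–Steel–Critchlow–Fligner (Steel–Dwass) all-pairs rank test
between groups, and strict candidate cutoffs (rho > 0.9 positive,
rho < −0.7 negative).

## Worked example

The package ships seeded generators that plant pairs of every structural type
(so everything below is reproducible without downloads):

```r
library(cisnat)

sim   <- simulate_gene_table(n_per_type = 2, n_decoys = 10, seed = 42)
pairs <- find_antisense_pairs(sim$genes, mode = "tss", window = c(-5000, -1))
pairs[pairs$type == "nHH", c("sense_gene_id", "as_gene_id", "type", "as_tss_position")]
#> # A tibble: 4 × 4
#>   sense_gene_id as_gene_id   type  as_tss_position
#>   <chr>         <chr>        <chr>           <int>
#> 1 PLT_nHH_01_A  PLT_nHH_01_S nHH             -3619
#> 2 PLT_nHH_01_S  PLT_nHH_01_A nHH             -3619
#> 3 PLT_nHH_02_S  PLT_nHH_02_A nHH              -914
#> 4 PLT_nHH_02_A  PLT_nHH_02_S nHH              -914
```

The upstream window `(-5000, -1)` finds the two planted nearby head-to-head
(divergent) pairs and nothing else; each appears twice because a divergent
pair is upstream from *both* genes' perspectives, and `as_tss_position` is
the signed TSS-to-TSS distance (negative = upstream of the sense TSS).

Screening the same pairs against a simulated TPM time course:

```r
expr <- simulate_expression(sim$truth,
                            decoy_ids = grep("DCY", sim$genes$gene_id, value = TRUE),
                            time_points = 8, noise_sd = 0.05, seed = 43)
rec <- pair_correlations(pairs, expr)   # Spearman rho per pair
scr <- select_correlated(rec)           # strict cutoffs 0.9 / -0.7
scr
#> Correlation screen: 2 positive (rho > 0.9), 2 negative (rho < -0.7)
```

The two planted positively co-expressed pairs pass the positive cutoff and
the two anti-correlated plants the negative one (each pair contributes its
two orientations; the counts above are pair rows per direction).
`tidy(scr)` returns the candidate table with both genes' TPM profiles — the
matrix a candidate heatmap is drawn from — and `autoplot()` /
`plot_offset_distribution()` give quick ggplot views of binned profiles and
offset distributions.

Real annotations enter through `read_gtf_genes("anno.gtf.gz")` or
`read_gene_table("genes.csv")`, with `validate_gene_table()` enforcing unique
gene ids and well-formed coordinates, and `filter_gene_source()` restricting
to a curated annotation source. A thin command-line wrapper
(`inst/cli/cisnat.R`) exposes `gtf2csv`, `pairs`, `batch`, `profile`,
`correlate` and `simulate` subcommands; `run_extraction_jobs()` executes a
YAML list of extraction jobs in one call.

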