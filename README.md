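# degradomeR

Identification of miRNA cleavage targets from degradome (PARE) sequencing
data, for plant small-RNA researchers who have degradome tag libraries, a
transcript set and a mature-miRNA set, and want classified, normalised,
statistically annotated cleavage-target calls without external pipeline
binaries.

## The method

Plant miRNAs slice their mRNA targets between the bases pairing miRNA
nucleotides 10 and 11; the 3' fragment keeps a free 5' monophosphate, so
degradome sequencing reads are 20–21 nt tags whose 5' ends mark cleavage
positions at single-nucleotide resolution. The pipeline:

1. **Filter** reads to 20–21 nt with mean Phred ≥ 20.
2. **Map** exactly (sense strand only) onto transcripts, building per-library
   signature profiles `counts[transcript][position]`; multi-mapping reads
   count at every matching locus.
3. **Align** each miRNA against each transcript antiparallel with plant-style
   penalties — mismatch 1, G:U wobble 0.5, gap 1, doubled at miRNA positions
   2–13 — keeping sites with score ≤ 7 that pair (WC or G:U) at miRNA
   positions 10 *and* 11. The cleavage coordinate `C.Site` is the base
   pairing nt 10 (`end − 9` for gap-free duplexes).
4. **Call** every candidate site carrying ≥ 1 tag, with
   * a CleaveLand-style **category**: 4 if the site has exactly 1 read,
     else 0 (unique transcript maximum at the site), 1 (tied maximum),
     2 (above the median of covered positions), 3 (at/below it);
   * **TP100M** = `site_count × 1e8 / transcriptome-matched reads`;
   * an empirical **p-value** `p = (1 + k)/(1 + n)` from `n`
     composition-preserving miRNA shuffles, `k` = shuffles achieving an
     equally good (score, category) site anywhere in the transcript set;
   * a 5'UTR/CDS/3'UTR **location** when CDS coordinates are supplied.
5. **Compare** across libraries: shared vs tissue-specific (miRNA, target)
   pairs, and annotation-group set comparison between datasets.

A seeded synthetic-library generator with planted cleavage events
(`simulate_library()`) and packaged transcriptions of published soybean
seed-coat/cotyledon target tables (`load_fixture()`) make every stage
testable offline. See the methods vignette
(`vignettes/degradome-methods.Rmd`) for conventions and caveats.

## Worked example

```r
library(degradomeR)

cfg <- sim_config(n_transcripts = 6, transcript_len = c(600, 1200),
                  n_planted = 2, lambda_signal = 50, background_rate = 0.01,
                  n_decoys = 2, seed = 7)
sim  <- simulate_library(cfg)
prof <- build_profile(filter_reads(sim$library), sim$transcripts)
library_report(list(prof))
#>   library raw_reads len_selected transcriptome_matched
#> 1     sim       150          150                   150

calls <- call_targets(prof, sim$mirnas, sim$transcripts,
                      max_score = 7, n_shuffles = 100, seed = 7)
as.data.frame(calls)
#>   library     mirna target c_site location category   tp100m  p_value score
#> 1     sim sim-miR01  tx001    378  unknown        0 32666667 0.009901     0
#> 2     sim sim-miR02  tx002    451  unknown        0 27333333 0.009901     0

sim$truth
#>       mirna transcript site_start site_end c_site n_signal_reads
#> 1 sim-miR01      tx001        367      387    378             49
#> 2 sim-miR02      tx002        440      460    451             41
```

Both planted targets are recovered at their exact planted cleavage
coordinates (378 and 451) as category 0 (the site is the unique abundance
maximum on its transcript) with perfect-complement score 0. TP100M is large
because the toy library has only 150 mapped reads (49 × 1e8/150 ≈ 3.27e7);
p = 0.0099 is the smallest value attainable with 100 shuffles, meaning no
shuffled miRNA matched as well anywhere. The two decoy miRNAs produce no
calls. Locations are `unknown` because no CDS table was attached
(`attach_cds()` / `read_cds_table()`). `tplot_data(prof, "tx001", 378)`
gives the abundance-versus-position series behind a t-plot;
`plot()` draws it. `write_call_table()` writes the 8-column published table
schema, and `partition_by_tissue()` / `compare_annotation_sets()` implement
the cross-library set logic.

A command-line interface covers the same flow:
`exec/degradomer <simulate|map|call|compare> --flag value ...`
(JSON configs; see `?degradome_cli`).

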