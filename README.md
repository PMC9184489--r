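# sedadiag

Species assignment and authentication for target-enriched **sedimentary
ancient DNA** (sedaDNA).

Lake-sediment DNA archives record which plants grew around a lake thousands
of years ago, but for congeneric species pairs the signal is thin: after
hybridization capture of a chloroplast genome, roughly 1% of reads belong to
the target genus, the molecules are tens of base pairs long, and the two
species' chloroplast genomes differ only at a small panel of fixed
positions. The motivating system is the Siberian larches — *Larix gmelinii*
(with *L. cajanderi*) versus *L. sibirica*, whose complete chloroplast
genomes differ at 157 positions — but every component takes arbitrary
reference panels, motifs and label maps.

`sedadiag` is aimed at palaeogenomics practitioners who want this chain as
tested, seedable R functions rather than a stack of one-off shell pipelines:

- **Diagnostic-site discovery** — anchor-based whole-genome alignment of a
  labelled reference panel (unique 21-mer chaining + banded gap closure) and
  a fixed-difference caller: a site is a gap-free, `N`-free column where
  group A is fixed for one base, group B for another. Output in 1-based
  anchor coordinates.
- **K-mer confidence classification** — a canonical-k-mer LCA classifier
  with the confidence defined as path support over all queried k-mers; reads
  are kept for a target clade only at confidence ≥ 0.8 (conservative by
  design).
- **Assignment** — paired-end merging with adapter read-through handling,
  seeded semi-global mapping at unit edit costs (ambiguous multi-locus hits
  excluded), PCR-duplicate removal, per-site species calls and per-read
  majority votes, with optional masking of damage-confoundable
  (terminal, transition-site) observations, plus negative-control
  screening.
- **Damage authentication** — terminal C→T / G→A profiles and a bounded
  weighted fit of `f(i) = e + d0·exp(−λ·i)` with a bootstrap interval on
  `d0` and a verdict string.
- **Satellite-repeat profiling** — wraparound (phased) mapping against a
  tandem motif (e.g. a 173 bp larch satellite), per-position nucleotide
  frequencies, and a cross-sample constancy statistic (mean total-variation
  distance).
- **Synthetic data** — a fully seeded generator for all of the above:
  panels with implanted sites, lognormal fragment lengths, exponential
  terminal deamination, read-through pairs, PCR duplicates, repeat arrays,
  background reads, and truth tables for every read.

## Worked example

```r
library(sedadiag)

# a truth-labelled panel: 2 groups, 120 implanted diagnostic sites
gen <- generate_panel(c(gmelinii = 3, sibirica = 3), genome_len = 20000,
                      n_sites = 120, within_group_snps = 10, seed = 42)
aln   <- align_to_anchor(gen$panel, gen$anchor_id)
sites <- call_diagnostic_sites(aln, "gmelinii", "sibirica")
head(sites, 3)
#>   anchor_pos allele_A allele_B is_transition
#> 1        644        A        G          TRUE
#> 2        955        G        C         FALSE
#> 3       1172        G        A          TRUE
nrow(sites)    # 120 -- the implanted panel, rediscovered exactly

# a 70:30 species mixture with ancient-DNA damage, assigned back
cfg <- simulation_config(seed = 7, n_fragments = 5000,
                         mixture = c(gmelinii = 0.7, sibirica = 0.3),
                         background_frac = 0)
sim <- simulate_readset(cfg, gen$panel, sample_id = "demo")
mg  <- merge_pairs(sim$reads)
al  <- deduplicate(map_reads(mg$merged, gen$panel$seq[[gen$anchor_id]]))
m   <- aggregate_assignments(observe_sites(al, sites), "demo")
m
#> <species_assignment> sample demo: 120 covered sites; reads gmelinii=1188,
#>   sibirica=529, unassigned=6

prof <- profile_damage(al, gen$panel$seq[[gen$anchor_id]])
fit_damage(prof)
#> <damage_params> d0=0.2941 lambda=0.3079 e=0.01140 (rmse 5.90e-03, ok)
```

The recovered read share (1188 / (1188 + 529) ≈ 69%) matches the simulated
70:30 mixture; the fitted damage amplitude and decay recover the simulation
truth (`d0 = 0.3`, `λ = 0.3`), and `authenticate_damage()` labels the sample
`consistent with ancient`.

## The analysis workflow

Numbered drivers under `analysis/` run a complete simulated sediment-core
study and write their tables under `results/`:

| script | what it does |
|---|---|
| `00_download_references.R` | fetches the 20 GenBank chloroplast genomes and recomputes the real diagnostic-site panel (network required) |
| `01_simulate.R` | simulates five core samples (shifting species mixtures, age-graded damage, one blank control) plus repeat-array reads |
| `02_assign_species.R` | classification → merging → mapping → dedup → per-site species matrices; control screening |
| `03_damage_authentication.R` | damage profiles, exponential fits, verdicts per sample |
| `04_repeat_profiles.R` | wraparound repeat profiles and cross-sample constancy |
| `05_report.R` | joins everything into `results/summary.tsv` and checks recovery against the simulation truth |

`run_pipeline()` exposes the same chain as a single call for programmatic
use.

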