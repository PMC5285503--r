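# hhkmine

Mining proteomes for hybrid histidine kinases (HHKs) and plant-hormone
receptor homologs.

Fungal HHKs fuse a histidine kinase A (HisKA) domain, the histidine kinase
ATPase catalytic domain (HATPase_c) and a C-terminal receiver (REC) domain
on one polypeptide, with a variable N-terminal sensing region. Some of the
most interesting members carry the hallmarks of *plant* hormone receptors:
an ethylene-binding domain (EBD) of three transmembrane helices bearing
perception-essential residues, or a CHASE sensing domain flanked by two
transmembrane helices with a conserved threonine at the position homologous
to AHK4 residue 301 (serine also works). `hhkmine` is a reusable,
deterministic pipeline for finding and classifying such proteins in any
protein FASTA, for people who study two-component signaling, fungal
genomics, or hormone-receptor evolution.

The pipeline:

- **Domain scan** — position-specific scoring matrices (one per family:
  HisKA, HATPase_c, REC, GAF, PAS, HAMP, CHASE, PHY, EBD), scored as
  log2-odds bits against a Swiss-Prot-like background. Each profile's null
  is calibrated empirically: a Gumbel is fitted by moments to maximum
  window scores of random sequences, giving
  `E(s) = (m/m0) * exp(-(s - mu)/beta)`; hits are retained at `E < 1e-4`.
- **TM prediction** — Kyte-Doolittle hydropathy scanning (window 19,
  cutoff 1.6, minimum length 15).
- **Architecture grammar** — ethylene-receptor-like (EBD helix triple +
  residue diagnostics; subfamilies 1/2), cytokinin-receptor-like
  (TM-flanked CHASE), phytochrome (PAS-GAF-PHY), dual (two HisKA),
  group III (HAMP repeats), composition-labeled remainder; core
  truncations recorded independently; census against a 16-label group
  catalog.
- **Residue diagnostics** — global alignment (BLOSUM62, affine gaps) of
  the candidate sensing region to a packaged reference, mapping diagnostic
  positions to conserved / similar / mismatch / gap.
- **Phylogeny** — center-star alignment of the HisKA+HATPase_c cores,
  Poisson-corrected distances, neighbor joining, column-bootstrap supports,
  Newick output.
- **Synthetic proteomes** — a generator planting ground-truth architectures
  (and decoys) at configurable mutation rates, so the whole pipeline is
  exercisable end to end without downloads. All packaged seed alignments
  and receptor references are synthetic stand-ins (labelled `_synthetic`);
  swap in real references via `read_diagnostic_sets()` for real analyses.

## Worked example

```r
library(hhkmine)

profiles <- hhk_profiles(seed = 1)          # build + calibrate the PSSMs
specs <- tibble::tibble(
  class = c("cytokinin", "ethylene-sf1", "group-iii", "decoy-background"),
  count = c(2, 2, 2, 2), p_sub = 0.02)
syn <- synth_proteome(specs, profiles, seed = 7)

result <- run_hhk_pipeline(syn$proteins, profiles = profiles)
result
#> <hhk_result> 8 proteins, 34 domain hits, 13 TM helices
#> # A tibble: 4 × 2
#>   label                       n
#>   <chr>                   <int>
#> 1 cytokinin-receptor-like     2
#> 2 ethylene-receptor-like      2
#> 3 group-III                   2
#> 4 not-HHK                     2
glance(result)
#> # A tibble: 1 × 5
#>   n_proteins n_hhk n_ethylene n_cytokinin groups_present
#>        <int> <int>      <int>       <int>          <int>
#> 1          8     6          2           2              1
```

All six planted kinases come back under their planted labels at 2% noise,
and both decoys are rejected; `groups_present` counts catalog groups (the
receptor classes are not catalog groups — only the planted group III is).
`tidy(result)` returns the per-protein classification with its evidence
trail, `autoplot(result)` draws the architectures, and
`hhk_tree(result)` builds the bootstrap NJ tree of the classified kinases.

The residue diagnostics read the packaged cytokinin reference the way the
field numbers it — the diagnostic threonine sits at reference position 301:

```r
refs <- hhk_references()
region <- substr(refs$cytokinin$reference,
                 refs$cytokinin$region_start, refs$cytokinin$region_end)
subset(tidy(diagnose(region, refs$cytokinin)), ref_pos == 301)
#> # A tibble: 1 × 4
#>   ref_pos cand_pos cand_residue status
#>     <int>    <int> <chr>        <chr>
#> 1     301      206 T            conserved
```

A thin command-line wrapper (`inst/scripts/hhkmine`) exposes the same
stages as `simulate`, `scan`, `classify` and `tree` subcommands, writing
TSV/Newick outputs plus the resolved configuration next to them.

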