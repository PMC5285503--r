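---
title: "Mining proteomes for hybrid histidine kinases: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining proteomes for hybrid histidine kinases: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Hybrid histidine kinases (HHKs) are the sensory entry points of fungal
phosphorelay signaling: a single polypeptide carrying a histidine kinase A
(HisKA) dimerization/phosphoacceptor domain, the histidine kinase ATPase
catalytic domain (HATPase_c), and a C-terminal receiver (REC) domain, with a
highly variable N-terminal sensing region. Among the most striking HHKs in
early-diverging fungal lineages are homologs of the *plant* hormone
receptors: ethylene-receptor-like proteins, recognizable by an N-terminal
ethylene-binding domain (EBD) of three transmembrane helices carrying
residues essential for hormone perception, and cytokinin-receptor-like
proteins, recognizable by a CHASE sensing domain flanked by two
transmembrane helices, with a conserved threonine at the position
homologous to residue 301 of the *Arabidopsis* AHK4 receptor (serine also
supports perception there).

`hhkmine` turns the informal mining recipe for these proteins — homology
search at a fixed E-value cutoff, domain annotation, transmembrane-helix
prediction, architecture reading, residue checks, and a phylogeny of the
hits — into one reusable, deterministic, fully testable pipeline that needs
no external binaries or databases.

## Pipeline stages

### Domain detection: PSSMs with empirical E-values

Each domain family (HisKA, HATPase_c, REC, GAF, PAS, HAMP, CHASE, PHY, EBD)
is represented by a position-specific scoring matrix built from a small
seed alignment. Match columns are those with under 50% gaps; per-column
residue counts receive a flat pseudocount (default 0.5), are normalized and
divided by the background composition, and logged base 2, giving scores in
bits.

The background is the package's fixed Swiss-Prot-like residue composition,
not the seed's own composition. This matters: the null model of a proteome
scan must describe the *database being scanned*. A composition-biased seed
(a transmembrane domain, say, containing no tryptophan at all) would
otherwise assign absurdly large log-odds to residues it merely lacks, which
inverts the meaning of the score. The background is floored at $10^{-4}$
and renormalized, so no log-odds is infinite.

Scanning is ungapped: every window offset is scored, unknown residues
(`X`) contribute 0 at any column. E-values come from a null model
calibrated per profile: `n_shuffles` (default 500) random background
sequences of length 400 are scanned, the per-sequence maximum window score
is recorded, and a Gumbel distribution is fitted by the method of moments
($\beta = s\sqrt{6}/\pi$, $\mu = \bar{x} - \gamma\beta$). For a query
exposing $m$ windows,

$$E(s) = \frac{m}{m_0}\, e^{-(s-\mu)/\beta},$$

with $m_0$ the calibration window count. Hits are retained at
$E < 10^{-4}$, the conventional screening threshold for this kind of
genome mining. The moment fit is slightly conservative in the far tail,
which we prefer: the honesty check (background sequences scoring
$E < 10^{-3}$ at most twice the nominal rate over 10,000 trials) passes
with margin, and false architecture features are rarer than nominal.
Overlapping same-family candidate windows are reduced best-score-wins,
ties to the leftmost.

### Transmembrane helices: hydropathy scanning

A deterministic Kyte-Doolittle scanner stands in for HMM-based
transmembrane prediction: the sliding mean over an odd window (default 19
residues) is computed, maximal runs of centers above the cutoff (default
1.6 Kyte-Doolittle units) are expanded by half a window on each side, runs
separated by fewer than 5 residues are merged, and runs shorter than 15
residues are dropped. The reported `mean_hydropathy` is the *peak* window
mean inside the helix, so it is at least the calling cutoff by
construction (a full-span mean would be diluted by the half-window
expansion into the flanks). The downstream grammar consumes only helix
counts, order and spacing, which this scanner delivers reproducibly; exact
helix boundaries are parameter-sensitive and should not be over-read.

### Architecture grammar

Retained domain hits and helices are merged into one ordered track per
protein. Domains win over helices (a helix overlapped more than half its
length by a domain hit is suppressed) — with one deliberate exception: the
EBD profile hit never suppresses helices, because the EBD *is* a helix
triple and the grammar needs that geometric evidence; the profile hit is
corroborating only.

Classification rules, in priority order (all satisfied rules are recorded
as evidence; the first sets the label):

1. no HisKA hit: not an HHK;
2. truncation flags from the presence of HATPase_c and REC downstream of
   the first HisKA (`REC-missing`, or `HATPase-and-REC-missing` whenever
   HATPase_c is absent — the enumeration has no state for a REC without
   HATPase_c);
3. **ethylene-receptor-like**: a chain of three or more helices ahead of
   HisKA with inter-helix gaps of at most 40 residues (the three
   C-terminal-most form the EBD), *and* passing residue diagnostics;
   subfamily 2 when an extra chain helix sits N-terminal to the triple,
   else subfamily 1 (with a GAF domain between EBD and HisKA as supporting
   evidence);
4. **cytokinin-receptor-like**: a CHASE hit ahead of HisKA with one helix
   ending within 60 residues before it and one starting within 60 residues
   after it;
5. **phytochrome (VIII/Fph)**: PAS, GAF, PHY in that order ahead of HisKA;
6. **dual**: two or more retained HisKA hits;
7. **group III** (osmosensing): four or more HAMP hits ahead of HisKA;
8. otherwise `HHK-other`, labeled with its ordered sensing-domain
   composition.

Receptor evidence (rules 3-4) is the most specific geometry, which is why
it outranks the broader classes; a protein satisfying several rules keeps
all of them in its evidence column. The 40-residue EBD gap and the
60-residue CHASE flanks are configuration values chosen to match the
figure-scale geometry of real receptor architectures; both are adjustable
through `hhk_config()`.

The census compares classifications against a 16-label group catalog
(an editable TSV): three groups match by classifier label (III, VIII/Fph,
dual), the remainder by sensing-domain composition of `HHK-other`
proteins. The catalog is configuration, not a claim about any particular
published grouping.

### Residue diagnostics

A candidate sensing region (the EBD span, or the CHASE hit span ± 30
residues) is aligned globally (BLOSUM62, affine gaps open 11 / extend 1 —
the conventional protein parameterization) to a packaged reference region,
and diagnostic reference positions are mapped through the alignment:
`conserved` (primary residue), `similar` (in the allowed set), `mismatch`,
or `gap`. A report passes when at least 80% of the non-gap diagnostic
positions are conserved or similar; an alignment scoring below a floor
(default 50) is refused outright rather than misread. The cytokinin set
always contains position 301 with primary T and allowed {T, S}.

Both packaged references are **synthetic stand-ins** (files and ids are
labelled `_synthetic`): real receptor sequences are deliberately not
bundled. The synthetic AtAHK4 stand-in places its CHASE region at residues
126–315 so that the strictly conserved threonine column of the CHASE seed
falls exactly at position 301, preserving the field's residue-numbering
convention. Diagnostic positions for the EBD set live in its three helix
blocks (including a cysteine/histidine pair in helix II, mirroring where
the copper-binding residues of real ethylene receptors sit). Users with
real references can swap them in through `read_diagnostic_sets()`.

### Phylogeny

The tree stage is a deliberately simple, dependency-light stand-in for a
full phylogenomic analysis: a center-star multiple alignment of the
concatenated HisKA+HATPase_c regions (center = the sequence with the
highest summed pairwise alignment score, ties to the smallest id),
Poisson-corrected p-distances ($d = -\ln(1-p)$ over shared non-gap
columns), Saitou-Nei neighbor joining (via `ape::nj`), and column-bootstrap
supports (percent of replicates containing each bipartition of the
full-data tree, via `ape::prop.clades`). Negative NJ branch-length
estimates are clamped to zero with the deficit reported. Pairs with no
shared columns, or saturated pairs ($p = 1$), are errors naming the pair;
bootstrap replicates hitting such a pair are skipped, and more than 20%
skipped aborts the run.

Two consequences worth knowing. First, NJ is exact on additive matrices,
and the tests hold it to that (Robinson-Foulds distance 0 on 50 random
8-taxon additive matrices). Second, bipartitions subtended by zero-length
edges are not identifiable: a set of *identical* sequences can legally be
interleaved around the root by any distance method. The bootstrap
simulations therefore give clades a small (2%) within-clade divergence and
derive every clade independently from an unsampled common ancestor, so
that each true bipartition has a positive stem edge. Tie-breaking inside
`ape::nj` and `Biostrings::pairwiseAlignment` is deterministic but not
configurable; the package guarantees reproducibility (same input and seed,
same output), not any particular resolution of exact ties.

## The synthetic proteome generator

The generator is first-class, tested code, and defines the conditions
under which the pipeline's guarantees are stated. Planted proteins
concatenate, in a class's canonical order: domain blocks, transmembrane
21-mers drawn from a hydrophobic alphabet {L, I, V, F, A}, and
inter-element linkers of 30–40 residues drawn from a disorder-biased
alphabet (A, D, E, G, K, N, P, Q, R, S, T). The linker alphabet is a
realism decision with a practical edge: real inter-domain linkers are
hydrophilic and disordered, and a hydrophobic-free alphabet means the
hydropathy scanner cannot fire spuriously inside them. Background decoys
still use the full Swiss-Prot-like composition.

Each planted class descends from its own *class ancestor*: the profile
consensus carrying a deterministic 15% substitution load (seeded from the
class and family names), never touching diagnostic columns, and re-drawing
transmembrane columns within the hydrophobic alphabet. On top of that,
per-protein noise applies i.i.d. substitutions at the requested `p_sub`
(diagnostic positions are protected when `p_sub` is at most 0.05). The
ancestors are what give different classes distinguishable kinase cores —
and hence a meaningful phylogeny — while keeping every class detectable.

The seed alignments themselves are synthetic: 12 rows per family, an
ancestral consensus drawn position-wise (hydrophobic in transmembrane
blocks, disorder-biased in loops, background elsewhere; diagnostic columns
fixed), 15% per-row substitutions and 2% gaps. They are regenerated
deterministically by `synthetic_seed_bank()` and shipped as aligned FASTA
fixtures; a test asserts fixture and regeneration are identical.

What the generator does *not* emulate: real domain-length variation,
insertions and deletions (scanning is ungapped, so planted domains are
fixed-width), compositional drift along lineages, paralog interference,
and genuinely noisy domain boundaries. Passing the closed-loop tests
therefore demonstrates internal consistency of detector, grammar and
generator under realistic composition — not performance on real proteomes,
where divergence is structured rather than i.i.d.

## Numerical and design choices

- Retention threshold $E < 10^{-4}$; hydropathy window 19, cutoff 1.6,
  minimum helix 15, merge gap 5; EBD gap 40; CHASE flanks 60; diagnostic
  pass threshold 0.8; 100 bootstrap replicates. All live in
  `hhk_config()` and in every run's resolved-config output.
- Gumbel by moments rather than maximum likelihood: two closed-form
  moments from 500 maxima are stable and reproducible; the slight tail
  conservatism is acceptable and verified.
- Calibration, generation and bootstrap take explicit integer seeds and
  run inside `withr::with_seed`, so no call disturbs the caller's RNG
  stream and every result is reproducible byte for byte.
- Coordinates are 1-based inclusive everywhere, matching residue-numbering
  conventions (e.g. "threonine 301").
- Problem sizes in the shipped checks: 80 planted proteins plus 50 decoys
  for the closed loop; 50 proteins for scanner-oracle equivalence; 10,000
  background sequences for E-value honesty; 50 additive 8-taxon matrices
  and a 12-taxon bootstrap for the phylogeny stage. These sizes give the
  Monte-Carlo assertions comfortable margins while keeping a full run in
  tens of seconds.

## Known limitations

- Ungapped scanning cannot place domains with long insertions; boundaries
  are approximate by design, and the grammar is built to tolerate that.
- The hydropathy scanner has no topology model; subfamily-2 calls hinge on
  one extra N-terminal helix and are the most boundary-sensitive output.
- The diagnostics ship with synthetic references; conclusions about real
  receptors require swapping in real reference sequences and positions.
- Center-star alignment and NJ are adequate for closely related domain
  cores, not substitutes for model-based phylogenetics; bootstrap values
  on short cores saturate quickly and should be read comparatively.
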