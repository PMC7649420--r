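---
title: "Reference-free genetic dissection of small-RNA expression: models and methods"
author: "srnaqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free genetic dissection of small-RNA expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Small RNAs (sRNAs, 18–30 nt) are quantified by sequencing, but in a
genetically diverse mapping population roughly half of all sRNA reads fail
to align uniquely to a single reference genome — precisely because the
polymorphisms that make expression heritable also break the alignment. The
usual "align-then-quantify" strategy therefore silently discards much of the
signal. `srnaqtl` implements the reverse, *quantify-then-align* order: every
unique sRNA sequence (and every assembled sRNA cluster) is treated directly
as a quantitative trait, QTL mapping is done on a recombination-bin genetic
map with no reference genome involved, and only the traits with detected
QTLs are afterwards aligned to the two *parental* genomes to classify each
QTL as local (cis-acting) or distant (trans-acting) and to dissect the
mechanism — in particular, presence/absence and spacer-length variation in
long inverted repeats (LIRs) that act as hairpin-RNA precursors.

The package targets biparental immortalized-F2 (IMF2) designs: F2-like
genotypes produced by paired crosses of recombinant inbred lines (RILs), so
each genotype is reproducible and heterozygotes exist.

## Trait definitions

**s-traits.** Reads are collapsed to unique tag sequences per library
(U→T at ingest, 18–30 nt retained). Expression is reads per million:
$\mathrm{RPM}_{ij} = c_{ij} \cdot 10^6 / T_j$ with $T_j$ the library's total
clean read count, including tags later filtered out. A tag is an s-trait
when it is *present* (raw count ≥ 1) in strictly more than half the
population (49 of 98 qualifies; 48 does not). We chose count ≥ 1 as the
presence call because the collapsed-tag representation makes any observed
read evidence of presence; an RPM floor is a configurable alternative but
the default is the weaker criterion.

**sc-traits.** sRNA reads are assembled into precursor-fragment contigs by a
greedy seed-and-extend overlap assembler (minimum overlap 16 nt, assembler
floor 50 nt), contigs are merged into non-redundant clusters by
single-linkage overlap clustering (≥ 40 bp at ≥ 94% identity, either strand)
with a majority consensus, and clusters shorter than 60 bp are removed.
Reads are then counted against clusters with unique placement (exact match,
either strand, reads matching more than one cluster discarded), counts are
normalized by median-of-ratios size factors
$s_j = \mathrm{median}_i\, k_{ij} / (\prod_j k_{ij})^{1/m}$ (rows with any
zero excluded from the reference), and clusters with normalized value ≥ 6 in
strictly more than 25 of 98 individuals become sc-traits.

Assembler determinism is guaranteed by explicit tie-breaks: seeds are the
most abundant unused read, ties broken lexicographically; extension prefers
the longest overlap, then abundance, then the lexicographically smallest
read. Read input order is therefore irrelevant.

## The genetic map and the scan

RIL marker genotypes are collapsed into *bins*: runs of markers with no
recombination breakpoint in any RIL; the boundary between adjacent bins is a
detected recombination event. IMF2 genotypes per bin are deduced from the
cross table (P1×P1→P1, P2×P2→P2, otherwise HET). All QTL positions are bins;
no centimorgan estimation is attempted.

The scan is a composite-interval-mapping-style regression. Genotypes are
F2-coded (additive $x_a \in \{-1,0,+1\}$, dominance $x_d \in \{0,1,0\}$).
Per trait, up to $k = 3$ cofactor bins are chosen by forward selection on
the additive terms; at each tested bin $b$ the full model is

$$y = \mu + \sum_{c \in C \setminus W(b)} \beta_c x_a^{(c)}
      + \alpha\, x_a^{(b)} + \delta\, x_d^{(b)} + \varepsilon,$$

where $W(b)$ removes cofactors within 10 bins of $b$ on its chromosome, and
the reduced model drops the two bin terms. The statistic is
$\mathrm{LOD}_b = (n/2)\log_{10}(\mathrm{RSS}_0/\mathrm{RSS}_1)$, capped at
300 when the full model fits exactly; constant design columns (e.g. a bin
with no heterozygotes) are dropped before fitting. QTLs are local maxima
with LOD ≥ 5 (the threshold is inclusive); the support interval is the
contiguous run with LOD ≥ peak − 1.5. These defaults ($k$, window, drop)
approximate the default behaviour of standard CIM implementations; they are
configuration, not a claim of bit-compatibility with any external package.

Permutation thresholds permute the trait across individuals and take the
empirical $1-\alpha$ quantile of the genome-wide maximum LOD. With
cofactors, the set selected on the observed trait is held fixed across
permutations (re-selecting per permutation is prohibitively expensive and
standard single-QTL permutation practice likewise omits model re-selection);
because that choice is slightly anti-conservative, the package's own null
calibration experiment uses $k = 0$, where exchangeability makes the test
exactly calibrated.

**Hotspots.** A bin qualifies when the number of traits peaking there
exceeds $\max(m_0, q_{0.999}(\mathrm{Pois}(\bar\lambda)))$; consecutive
qualifying bins form one hotspot run. At genome scale a fixed count floor
(hundreds of traits) is the natural $m_0$; at synthetic scale the default
auto-scales as $m_0 = \lceil 0.05\, N_\mathrm{calls}\rceil$. The floor
matters: with many calls the per-bin 99.9% Poisson quantile alone still
yields a ~10–15% genome-wide false-hotspot rate, which the auto-scaled floor
suppresses.

## Alignment and local/distant resolution

Tags are aligned to both parental genomes on both strands, exact-match via a
preprocessed dictionary and optionally with one mismatch; "unique" mode
reports a hit only when exactly one 0-mismatch placement exists in that
genome. Cluster sequences are placed by near-exact matching with an
identity-derived mismatch/indel budget, filtered at ≥ 90% identity and
≥ 85% query coverage, multi-hit queries dropped. Coordinates are 1-based
inclusive throughout.

A QTL is *local* when any alignment of its trait lies on the peak bin's
chromosome within 1 Mb of the bin interval, *distant* when alignments exist
but none qualifies, *unresolved* when the trait does not align. The 1 Mb
window is configurable; an alternative support-interval rule (hit inside the
genomic span of the LOD-drop interval) is implemented. For multi-mapped
traits with a local QTL, alignments inside the local window are kept as
*authentic* and the rest discarded — this is what lets both arms of an
inverted repeat be retained while spurious repeat placements elsewhere are
dropped.

Note that on the scaled-down synthetic genomes (hundreds of kb per
chromosome) the 1 Mb window spans a whole chromosome, so the window rule
degenerates to same-chromosome; the distance semantics are unit-tested with
explicitly constructed alignments instead.

## Long inverted repeats

The finder seeds exact 15-mer matches between the sequence and its reverse
complement, groups seeds by anti-diagonal, and extends each run without gaps
under X-drop scoring (+1 match, −3 mismatch, drop 12), keeping every
position where the running score reaches a new maximum as a candidate
boundary; the reported arm is the longest left/right candidate combination
with identity ≥ 0.9. Records need arm ≥ 200 bp, spacer between 1 bp and
20 kb; nested or arm-overlapping records collapse to the longest-arm record
per locus. Identity is ungapped (matches / arm length): the generator plants
substitution variants only, and for substitution-divergent arms ungapped and
banded-gapped identity coincide; strongly indel-diverged arms would be
under-detected, a documented limitation.

A record is *hairpin-competent* when its spacer is ≤ 1 kb. Observed
hairpin-forming spacers in rice LIR loci are a few hundred bp while a
non-folding one is > 6 kb, so 1 kb sits between the two regimes with a wide
margin on both sides; it is configurable. Cross-genome comparison classifies
each matched locus as both-hairpin, one-hairpin (recording whether the other
parent carries a long-spacer copy, a single arm, or nothing), arm-lost
(structure present but no hairpin-competent copy) or absent.

LIR expression is quantified from mRNA reads matched exactly (either strand,
one placement per read) against the genotype-appropriate reference — P1
individuals against the P1 copy, P2 against P2, heterozygotes against both —
and reported as matched reads per million of the library total. Association
with genotype uses two-sided Wilcoxon rank-sum tests per genotype pair, and
per-trait Pearson correlations link sRNA and LIR expression; zero-variance
traits are reported as undefined rather than 0.

## The synthetic population

The generator is first-class code and defines the study conditions: two
parents with equal-length chromosomes (2 × 300 kb by default) differing by
SNPs at marker positions and by three planted LIR configurations — present
in parent 2 only (parent 1 retains a single arm), hairpin-competent in
parent 2 but spacer-expanded (5 kb) in parent 1, and intact in both; 200
RILs simulated to fixation with per-interval crossover probability 0.05
doubled by a configurable map-expansion factor (selfing generations
accumulate recombinations; the factor 2 is a conventional approximation);
98 IMF2s by paired crosses, each RIL used once. sRNA libraries carry ~300
neutral tags (expressed everywhere), ~80 cis tags per differential LIR tiled
from the expressing parent's arms, and 150 trans-controlled 24-nt tags tiled
from a 1-kb region shared by both parents but scaled ×3 by the genotype at a
"biogenesis" bin on the other chromosome; counts are negative-binomial
(dispersion 0.1) around genotype-dependent means times a uniform(0.7, 1.3)
library depth factor, plus 500 private background tags per library with
counts 1–3, reproducing the rare-tag skew of real data. Heterozygote means
are additive (the midpoint of the homozygote means). mRNA libraries are
error-free 100-bp substrings of the genotype-appropriate LIR locus at
Poisson depth matching planted per-genotype RPM levels, plus decoy reads
from a neutral region.

What the generator does *not* emulate — sequencing error, adapter artefacts,
transposon-derived repeat families, RNA folding kinetics, realistic genome
composition — bounds what passing tests show: they validate the statistical
machinery and the structural reasoning, not robustness to real-library
noise. Sequencing errors can be switched on (per-base substitution) to
exercise the 1-mismatch alignment path, but default off: the workflow's
intended inputs are pre-cleaned reads.

Problem sizes throughout (98 individuals, 200 bins, ~650 trait tags, 300-kb
chromosomes, 200-permutation thresholds in the calibration experiment) were
chosen so a complete end-to-end analysis runs comfortably on a laptop-class
single core while keeping every estimate's sampling error small relative to
the tested tolerances.

## Numerical and design choices

- **Ties and determinism.** All tie-breaks (assembler seed and extension,
  cofactor selection on equal RSS by lowest bin index, hotspot run
  grouping) are fixed; identical seeds give byte-identical outputs.
- **Rank deficiency.** Constant additive or dominance columns are dropped at
  the affected bin; the LOD comes from the remaining term.
- **Zero handling.** RPM of a zero count is exactly 0; size factors refuse
  matrices with no all-positive row unless the positive-entry fallback is
  requested explicitly (and then warn); chi-squared comparisons give
  zero-expected/positive-observed categories a 0.5 pseudo-expectation,
  keep them in the degrees of freedom, and flag them in the output.
- **Missing data.** Trait scans are complete-case per trait with n recorded;
  missing RIL genotypes are imputed from the bin consensus.
- **Assembly stages.** Per-library assembly followed by pooled assembly is
  supported (`assembly = "both"`), but the default is pooled-only: at
  synthetic scale the trait tags are shared across libraries, so
  per-library assemblies reproduce the pooled contigs and only add runtime.

## Known limitations

- The cofactor scan is Haley–Knott-style regression on bin genotypes, not
  EM interval mapping between markers; positions between bins are not
  tested.
- The LIR finder's ungapped arms under-detect indel-diverged repeats.
- The hotspot rule's Poisson baseline assumes exchangeable trait-to-bin
  assignment under the null; linked QTL architecture violates this at fine
  scales, which is why the count floor exists.
- `authenticate_alignments` implements the window rule plus cross-genome
  retention; it does not attempt probabilistic reassignment of multi-mapped
  reads.
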