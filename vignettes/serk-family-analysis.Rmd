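---
title: "Methods: dating tandem SERK duplications and classifying splice variants"
author: "serkdup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dating tandem SERK duplications and classifying splice variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serkdup)
```

# Scope

`serkdup` re-implements, as tested reusable code, the computational steps
behind the characterisation of a small tandemly duplicated SERK
(somatic embryogenesis receptor-like kinase) gene family: degenerate-primer
arithmetic, gene-model handling, intron-based molecular-clock dating of the
duplications, splice-variant classification with protein prediction, SERK
motif scanning with ProtParam-style statistics, and Pfaffl-corrected qPCR
quantification. The package is organised as an analysis: numbered drivers
under `analysis/` narrate each stage and write tables under `results/`,
while every computation lives in package functions that the test suite and
the acceptance script exercise directly.

Everything runs on synthetic or in-package data. The two kinds of published
inputs used are the printed degenerate primer sequences and the printed
chromosome-2 coordinate table, both bundled as plain text under
`inst/extdata/`.

# The molecular clock for duplication dating

After a duplication both copies accumulate mutations independently, so if a
pair of paralogues diverged $T$ years ago at per-lineage rate $\mu$
(substitutions/site/year), their expected per-site divergence is
$K = 2\mu T$, and the age estimate is

$$\hat T = \frac{\hat K}{2\mu}, \qquad \mu = 3\times10^{-10}.$$

Introns are the clock substrate because they are effectively neutral over
the few-Myr timescales involved. For each gene pair, intron $i$ of one gene
is aligned globally to intron $i$ of the other (the genes share an 11-exon
structure, so introns correspond by index), and counts are pooled across
introns before forming $\hat K$ — a length-weighted pooled estimator rather
than a mean of per-intron ratios, which reduces variance and yields one age
per pair.

## Alignment scoring

Alignments use match $+2$, mismatch $-3$, and an affine gap cost with open
5 and extension 2 — the published tool settings for this comparison. Those
settings are ambiguous about whether a maximal gap run of length $L$ costs
$5 + 2L$ or $5 + 2(L-1)$; both rules are implemented
(`alignment_params(gap_rule=)`), the default is `open_plus_L`
(existence-plus-per-base semantics), and the rule in force is recorded on
every result. The three-state affine dynamic programme breaks ties
deterministically (diagonal over vertical over horizontal), so outputs are
byte-stable. `N` scores as a mismatch against anything by default
(conservative), switchable to neutral. A brute-force enumerator
(`brute_force_align`, inputs $\le 8$ nt) provides an independent oracle in
the tests.

## Mutation counting

`count_mutations` reads alignment columns: substitutions are mismatch
columns; each *maximal gap run* counts as one mutational event contributing
one site, so with the default `mutation_mode = "subs_plus_indel_events"`,

$$\hat K = \frac{\text{substitutions} + \text{gap runs}}
               {\text{ungapped columns} + \text{gap runs}}.$$

The denominator convention is the single largest interpretive choice in the
pipeline — counting "substitutions and deletions" does not define the site
total — so the mode is explicit in the configuration and carried in the
output, and a substitutions-only mode is available. No multiple-hit
correction is applied by default (raw $p$), which is accurate to well under
1% at the shallow divergences involved ($p \approx 0.002$); a JC69 option
($K = -\tfrac34\ln(1 - \tfrac43 p)$) is provided and the tests verify the
two agree to $<1\%$ for $p < 0.005$.

## Event inference

Under a clock the pairwise ages are (noisy) ultrametric distances, and
average-linkage agglomeration (UPGMA) is the natural formalisation of
ordering duplication events by comparing pairwise differences: each merge
is one event whose time is the linkage age directly (no halving — that
already happened in the clock conversion). Ties break lexicographically by
member name so results are order-invariant. Departures from
ultrametricity are reported as a per-event coefficient of variation and
never silently repaired. `to_newick` serialises the event tree with branch
lengths in Myr.

## What the dating stage can and cannot recover

The published event times (3.25, 3.05, 2.65, 2.2 Myr) derive from GenBank
intron sequences plus manual alignment adjustment, neither reproducible at
desk scale; the synthetic generator therefore *defines* those times as
simulation truth and asks what the pipeline recovers. The information
content is modest and worth being explicit about: with $\mu T \sim 10^{-3}$
and $\sim$10 kb of introns per gene, a pair carries only 13–20 expected
mutational differences, i.e. 23–28% Poisson noise per pairwise age, while
adjacent event times differ by only 6–20%. Consequently single-run merge
orders are frequently wrong and single-run ages wobble by tens of percent —
`analysis/03_duplication_dating.R` reports this spread honestly. Properties
that do hold, and are tested: the pooled estimator is unbiased (checked at
$T = 3\times10^{7}$, where 20 replicates give a $\sim$1.7% standard error on
the mean, a 6$\sigma$ test of the 10% band); an exactly ultrametric input
matrix is recovered exactly; and the simulated p-distance converges to
$2\mu T$ (checked at 1 Mb, where counting noise is $\sim$1.6% against a 5%
band). Test problem sizes were chosen by these power considerations.

# The synthetic-data generators

`simulate_duplication_history` builds a caterpillar genealogy from the
event times (oldest splits first, matching a serial tandem-duplication
scenario), draws ancestral introns uniformly over A/C/G/T (10 introns,
lengths uniform 400–1600 nt by default), and evolves each lineage by exact
Jukes–Cantor transitions: over a branch of duration $t$ a site is resampled
uniformly over the four bases with probability $1 - e^{-4\mu t/3}$, so the
probability of an observed change is $\tfrac34(1 - e^{-4\mu t/3}) \approx
\mu t$ and pairwise divergence tends to $2\mu T$. Deletions are off by
default (the clock signal is substitutional) but available as Poisson
events with geometric lengths for exercising the indel-counting path. It
does not model rate heterogeneity, GC bias or codon structure — so passing
tests demonstrate correct arithmetic under the clock model, not robustness
to rate variation in real introns.

`make_sv_fixture` constructs the 11-exon splice-variant gene. Design
choices:

* CDS exon lengths 150, 150, 72, 75, 75, 96, 96, 96, 300, 300, 351 nt —
  all multiples of 3, so exon boundaries are codon boundaries and skipping
  the 72-nt exon 3 removes exactly 24 aa without a frameshift. The lengths
  are chosen so the predicted variant proteins match the published lengths
  (586, 271, 562, 247, 154 aa): this is a *constructed* correspondence (the
  real gene's sequence is not in the source material), which turns the
  published protein-length table into an end-to-end check of the splicing,
  mapping and translation arithmetic.
* Intron 5 opens with four non-stop codons then `TGA`; intron 8 opens with
  one non-stop codon then `TAA` — retained introns therefore introduce
  in-frame premature stops, in intron 5 or 8, exactly as observed.
* Exon and intron bodies are drawn from codons excluding stops *and* `ATG`;
  the only in-frame starts are the annotated start and a planted `ATG`
  opening exon 9. This makes the observed downstream "second transcript"
  deterministic: in every truncated variant the longest post-stop ORF opens
  at the exon-9 ATG and runs to the canonical stop (316 aa). Real exons
  contain internal methionines; the restriction trades that realism for a
  sharp, testable property.
* The seven transcripts are SV1 canonical; SV2 = intron 8 retained;
  SV3 = exon 3 skipped; SV4 = skip 3 + intron 8; SV5 = skip 3 + introns
  5, 6; SV6 = skip 3 + introns 5, 8; SV7 = skip 3 + intron 5. Which
  downstream introns SV5/SV6 retain is not enumerated in the source text;
  these assignments are representatives consistent with the shared
  intron-5 stop.

`simulate_qpcr` produces logistic-saturating curves
$F_c = P/(1 + (P/F_0 - 1)E^{-c})$ — exponential with factor $E$ while far
below the plateau $P$ — with optional multiplicative Gaussian noise, and
`simulate_ct_table` inverts the Pfaffl computation to plant known
fold-changes. All generators are byte-reproducible under a fixed seed.

# Splice-variant analysis

Transcript mapping is exact-segment matching: walking the genomic segments
(exon 1, intron 1, exon 2, ...) left to right, each exon is matched in full
or skipped in full, and an intron matched in full between two matched exons
is retained. This replaces spliced-alignment tools because the variants of
interest are whole-intron retentions and whole-exon skips in error-free
sequence; mismatches mid-segment raise a mapping error with the failing
offset rather than a partial alignment. A round-trip property test
(`splice` then `map_transcript` over random structures) guards the
inverse relationship.

The primary ORF starts at the *annotated* start codon mapped into the
variant — not the longest ORF — because all variants are read from the
canonical start. A premature termination codon is a stop whose genomic
position differs from the canonical stop (so the exon-3-skipping variant,
which ends at the canonical stop, is full-length-minus-24, not truncated),
and its retained-intron location is reported. The secondary ORF rule —
longest ATG-initiated ORF downstream of the primary stop, any frame — is a
recorded choice; the observation it emulates names a start in exon 9 but no
selection rule.

# Protein features

The leucine-zipper consensus is scanned strictly: Leu-X$_6$-Leu-X$_6$-
Leu-X$_6$-Leu with literal leucine (no Ile/Val substitutes), a 22-residue
window; `partial` status means some Leu-X$_6$-Leu stretch exists but no
full window. The SPP motif defaults to the literal tripeptide `SPP` and is
configurable, because the exact highlighted residues are not recoverable
from the source text. Molecular weight sums average residue masses plus one
water; pI solves net charge $= 0$ by bisection to 0.001 pH with the
Bjellqvist pKa set (residue-specific N-terminal pKa, C-terminus 3.55, side
chains D 4.05, E 4.45, H 5.98, C 9.0, Y 10.0, K 10.0, R 12.0), emulating
the ExPASy ProtParam tool. Tests pin the implementation against frozen
values from an independent implementation and against `seqinr::computePI`.

# qPCR quantification

Efficiency estimation is a simplified LinRegPCR: subtract the mean of the
first five cycles as baseline, then among all 4–6-point windows of
consecutive above-baseline readings choose the one maximising $r^2$ of
$\log_{10} F$ against cycle; $E = 10^{\text{slope}}$, clamped to
$[1, 2.2]$ with a warning. The original tool's iterative baseline
reconstruction is deliberately not implemented, so its published numbers
are not claimed — on noiseless synthetic curves the window fit recovers
$E$ within 0.01, within 0.05 at 1% multiplicative noise. Relative
expression follows Pfaffl,

$$\text{ratio} = \frac{E_\text{target}^{\Delta Ct_\text{target}}}
                      {E_\text{ref}^{\Delta Ct_\text{ref}}},
  \qquad \Delta Ct = Ct(\text{calibrator}) - Ct(\text{sample}),$$

normalised to a reference gene (GAPDH in the study design) and calibrated
to the week-0 timepoint, summarised as mean $\pm$ SE ($s/\sqrt{n}$) over
three biological repeats. Per-run mean efficiency is used in the ratio (the
per-well vs per-run choice is not documented in the source; per-run is the
default here). Published fold-changes are biological data and are not
claimed; the drivers plant fold-changes in the published ranges (4–5 and
12–20) and recover them.

# Degenerate primers and cluster geometry

Primer degeneracy is the product over positions of IUPAC ambiguity-set
sizes, and the specific 3' run is the maximal A/C/G/T suffix. In-silico PCR
matches the forward primer IUPAC-compatibly and the reverse primer as its
reverse complement downstream, zero mismatches (the study ran fixed-
annealing PCR; mismatch tolerance is out of scope), template `N`
permissive. The cluster span is $\max(\text{end}) - \min(\text{start})$
over the published kbp coordinates, rounded to integer kb; overlapping
annotations (the adjacent MtSERK3/MtSERK4 loci overlap by 0.4 kb) warn
rather than fail.

# Numerical and interface conventions

* Coordinates are GFF3 1-based inclusive externally; minus-strand genes are
  normalised at load (sequence reverse-complemented, exons remapped) so all
  downstream logic is strand-free. Intron $i$ lies between exons $i$ and
  $i+1$.
* Lowercase/softmasked input is uppercased on read; FASTA and GFF3
  round-trip bit-identically modulo line wrapping.
* All randomness flows through explicit `seed` arguments; two runs with the
  same configuration and seeds produce identical outputs.
* Problem sizes in tests (20–100 replicates, 1 Mb convergence checks,
  $\le 8$ nt brute-force oracles) were fixed a priori from the power
  analysis above.

# Known limitations

Beyond the single-run dating noise quantified above: no mismatch-tolerant
primer matching or melting temperatures; no cryptic splice sites or
NMD-target prediction; no signal-peptide/transmembrane/kinase-domain
prediction (external predictors are out of scope); no synonymous-site
dating, rate heterogeneity or bootstrap intervals; the LinRegPCR
simplification above. The published event times and expression
fold-changes are treated as simulation truths and plausible ranges
respectively, never as quantities this package claims to re-derive from
data.
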