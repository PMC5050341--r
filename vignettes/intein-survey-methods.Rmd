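---
title: "Detecting and classifying phage inteins: methods and design notes"
author: "inteinscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying phage inteins: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inteinscan)
```

## The problem

Inteins are protein segments that excise themselves from a host precursor
post-translationally and ligate the flanking segments (exteins) back
together. In mycobacteriophage genomes they concentrate in a small set of
host proteins — terminase large subunits, RecB-like nucleases,
recombination directionality factors, DNA methyltransferases — and tend to
sit inside or next to functional motifs such as the Walker A P-loop.
`inteinscan` is a desk-scale pipeline for surveying such genomes: it
detects intein-like elements, fixes their boundaries and key catalytic
residues, classifies them (class 1 versus class 3), annotates the optional
LAGLIDADG homing endonuclease (HEN), maps insertion sites into
reference-extein coordinates, screens for horizontal intein transfer, and
aggregates survey statistics.

## Detection model

Detection rests on the four conserved protein-splicing blocks A, B, F and
G. Each block is modelled as a gap-free position-specific scoring matrix
(PSSM) in bits,

$$S_{c,a} = \log_2 \frac{n_{c,a} + \kappa\, b_a}{(N + \kappa)\, b_a},$$

with residue counts $n_{c,a}$ from a seed alignment of $N$ sequences,
pseudocount mass $\kappa$ (default 2) distributed by the background
$b_a$ (default uniform 1/20). A full profile HMM would additionally model
insert states; for block-sized motifs (8–14 columns) a PSSM captures the
same residue logic while staying transparent and dependency-free, and an
external HMM engine can be substituted upstream without changing any later
stage. Residues outside the 20-letter alphabet score the background
expectation of 0 bits.

The packaged seed alignments are **synthetic, consensus-anchored
stand-ins**: eight sequences per block encoding the canonical residue
logic (block A nucleophile, the class 3 Trp–Cys–Thr triplet at B12/F4/G5,
the penultimate residue at G6 with its natural His/Gly/Lys/Ser variation,
the terminal Asn at G7, the +1 nucleophile at G8, and the LAGLIDADG cores
in HEN blocks C and E). They make no residue-level claim about any real
intein family; users with curated alignments should swap them in via
`buildPssm()`.

Window hits at or above `minScore` (default 8 bits) are chained by dynamic
programming under spacing constraints (defaults: A→B gap 30–120 residues,
B→F 0–450, F→G 5–60; gaps counted between block windows). The defaults
bracket known intein architectures — a compact N-terminal splicing region,
room for an endonuclease between B and F, a short F→G linker — and are
explicit configuration, not biological claims. The 8-bit threshold was
chosen so that random 1,000-residue background proteins produce fewer than
0.05 spurious block hits per model (the test suite verifies this by
simulation); a full false call additionally requires three compatible
blocks, which makes background call rates effectively zero.

A chain must contain blocks B, F and G. Block A is optional because
class 3 block A sequences diverge (they lack the position 1 nucleophile);
when A is absent the N-terminus is placed 10 residues upstream of block B
and the call is flagged `approximate_n_terminus`. The intein ends at block
G column 7; a terminal residue other than Asn/Gln demotes the call to
warning status rather than silently dropping it, since Gln cyclization is
a known natural variant and anything else is most likely a boundary error
worth inspecting.

Class assignment is rule-based: class 3 iff (B12, F4, G5) = (W, C, T);
otherwise class 1 iff position 1 is Cys/Ser/Thr; otherwise unknown. The
WCT rule fires first, because class 3 inteins may carry incidental
nucleophiles at position 1.

The HEN is sought only between block B's end and block F's start; it is
called present when blocks C and E (which carry the actual LAGLIDADG
motifs) both hit, C before E. A HEN-less intein whose B–F region is
shorter than `miniGap` (default 50 residues) is reported as a mini-intein.
The 50-residue default cleanly separates an embedded endonuclease
(hundreds of residues) from a bare inter-domain linker.

## Coordinates

All coordinates are 1-based inclusive, the native R and Bioconductor
(IRanges) convention, applied uniformly to calls, truth manifests, TSV and
GFF3 output. Using a single convention at every interface is the
off-by-one defence; the +1 extein residue always sits at `end + 1`.

## Insertion-site mapping

The host protein with the intein excised is globally aligned
(Needleman–Wunsch, BLOSUM62, affine gaps 11/1 — conventional protein
settings) to a reference extein; the insertion site is the reference
column aligned to the last N-extein residue. The mapping is invariant to
upstream padding of the host protein, which matters because ORF calling in
random intergenic DNA can legitimately extend a gene model upstream.
Site identity uses tolerance 0 — sites one residue apart are distinct,
as insertion sites genuinely occur at adjacent columns (e.g. on either
side of the invariant P-loop Lys) — and per-family site letters a, b, c, …
are assigned by ascending reference column, deterministically. A family is
accepted when the extein aligns at ≥ 25% identity over ≥ 50 columns; the
floor is an implementation choice surfaced in configuration, since highly
diverged exteins (a truncated ATPase domain, say) have no principled
universal cutoff.

The packaged reference exteins are synthetic: random sequences carrying a
qualitative motif layout (Walker A/B and C-motif for terminase-like
families, PD-(D/E)xK for the RecB-like nuclease, a metallophosphoesterase
motif for the RDF, active-site motifs elsewhere) with designated insertion
columns whose +1 residues are nucleophiles. They exist so that mapping and
labelling are testable offline; real surveys should supply curated
references in the same FASTA + motif-table format.

## Percent identity and transfer screening

Percent identity is 100 × identical columns / aligned columns **excluding
terminal gap overhangs**. Published intein identity values depend
strongly on this denominator choice, so it is declared in every report
header; numbers computed under other conventions are comparable only
approximately. Typical unrelated inteins share ≲ 30% identity; the
transfer flag threshold defaults to 35%, which separates
background-consistent values (~31%) from the 40–55% range that suggests
recent common ancestry. The threshold is configurable and deliberately
not set at 30%, where background variation would trip it.

Trees are built by neighbor joining on Poisson-corrected p-distances and
compared by Robinson–Foulds distance — a deliberate, declared substitution
for maximum-likelihood inference with SH-aLRT support: NJ+RF is
deterministic, dependency-light and adequate for the incongruence test,
which only asks a topological question. Monophyly on an unrooted tree is
evaluated as "some edge's removal separates exactly the focal taxa".
Incongruence = focal taxa (putative donor and recipient) monophyletic in
exactly one of the intein/extein trees; monophyletic in neither is
reported as "no signal" rather than evidence. The transfer verdict in
`hgtAnalyze()` requires both identity above threshold and tree
incongruence, which keeps the false-flag rate on no-transfer controls low.

## The synthetic-data generator

`simulateSurvey()` emulates the structure of a multi-cluster phage survey
with known ground truth; its defaults are the package's fixed study
conditions:

| parameter | default | rationale |
|---|---|---|
| clusters / rates | 60 genomes @ 0.9, 140 @ 0.05 | the intein-rich-vs-poor cluster contrast typical of such surveys |
| intein divergence | 0.15 subs/site from block consensus | a realistic within-family divergence that still leaves block signal |
| extein divergence | 0.05 from reference | congeneric host-protein variation; keeps family assignment unambiguous |
| class mix | 30% class 3 | class 3 is the minority class in phage surveys |
| HEN fraction | 0.5 | both HEN-bearing and mini-inteins well represented |
| penultimate mix | H .5 / G .25 / K .15 / S .1 | His canonical, with the naturally observed replacements |
| genes per genome | 4, spacers 60 nt | desk-scale genomes that still exercise ORF finding |

Substitutions are uniform over the 19 alternatives (Jukes–Cantor-like);
realism in the substitution process buys nothing for recovery tests and
the choice is isolated behind one helper. Key catalytic positions are set
exactly and never mutated, motif intervals and site nucleophiles are
frozen by default, and reverse translation uses one fixed codon per
residue under genetic code 11. Identical configurations (including seed)
produce byte-identical output.

What the generator does **not** emulate — and hence what passing recovery
tests do not show about real data: insertions/deletions within inteins or
exteins, compositional bias, block sequences diverged beyond the packaged
consensus logic, fragmented or mis-assembled genomes, and genuinely novel
intein architectures. Recovery rates on this generator are upper bounds
for real surveys.

`simulateHgt()` evolves exteins along one random tree (per-edge
substitution probability $1-e^{-\ell}$) and inteins along the same tree,
except that a transfer event replaces the recipient's intein with a copy
of the donor's at small divergence (default 0.05). Donor and recipient are
the most distant tip pair, making the transferred-intein signal maximally
discordant with the extein history. Mean root-to-tip depth defaults to
0.75 substitutions/site so that background intein identities sit in the
sub-30% regime where the identity flag stays quiet on controls.

## Numerical and degenerate-input choices

* Display percentages are rounded half-up to one decimal (88.7 style);
  all comparisons in code and tests use full precision.
* Logo information is $\log_2 20 - H$ bits with gaps excluded from the
  denominator (not a 21st symbol); no small-sample correction by default
  because group sizes vary wildly between sets, with a flag to enable
  Miller–Madow.
* $R^2$ on constant input is NaN with a warning, never silently 0.
* NJ branch lengths below zero are clamped to 0 with a warning.
* Chain ties break toward higher score, then leftmost start, then
  lexicographic block set — determinism over elegance.
* ORFs without an in-frame stop are dropped by default; nested ORFs
  sharing a stop are all reported, with `longestOrfs()` selecting the
  representative gene model.

## Problem sizes

The test suite and acceptance script run, as the package's chosen
evaluation sizes: 200 genomes / 200 planted inteins for recovery; 1,000
(tests) or 400 (script) background proteins of length 500 for the false
positive bound; 100 transfer + 100 control replicates for HGT detection;
500 randomized hit sets against the exhaustive chaining oracle; 50 random
pairs against an independent affine-gap alignment DP; additive matrices on
4–8 taxa for NJ correctness. All quantities reported by
`scripts/acceptance.R` are recomputed from scratch at run time.

## Known limitations

No class 2 chemistry (not observed in these phages), no splice-efficiency
prediction, no nucleotide-level homing-site cleavage simulation, no
maximum-likelihood phylogenetics or branch supports, no live GO/InterPro
annotation (a static family→category table stands in), and no alignment
uncertainty handling — the identity and site-mapping stages trust a single
optimal alignment.
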