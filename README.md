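# inteinscan

Inteins are self-splicing protein elements: they excise themselves from a
host precursor after translation and ligate the flanking exteins back
together, often carrying a LAGLIDADG homing endonuclease (HEN) that makes
them mobile at the DNA level. In bacteriophage genomes they cluster in a
handful of proteins — terminase large subunits, RecB-like nucleases,
recombination directionality factors, methyltransferases — and insert into
or next to functional motifs such as the Walker A P-loop.

`inteinscan` is an R package for surveying phage genomes (or any protein
set) for inteins, aimed at comparative genomicists who want a transparent,
offline, fully testable pipeline:

* **Detection** — position-specific scoring models (bits) for the conserved
  splicing blocks A, B, F, G, built from packaged (or user) seed
  alignments as
  `S[c,a] = log2((n[c,a] + κ·b[a]) / ((N + κ)·b[a]))`,
  scanned over every protein window and chained by dynamic programming
  under block-spacing constraints.
* **Boundary and residue calling** — intein position 1 (block A
  nucleophile), terminal Asn/Gln (block G column 7), penultimate residue
  (G6), the +1 extein nucleophile (G8), with non-canonical terminals kept
  as warning-status calls.
* **Classification** — class 3 iff the Trp-Cys-Thr triplet occupies block
  positions B12/F4/G5; otherwise class 1 iff position 1 is Cys/Ser/Thr.
* **HEN annotation** — LAGLIDADG blocks C/D/E/H sought only between blocks
  B and F; HEN-less inteins with a short B–F linker are mini-inteins.
* **Insertion-site mapping** — global alignment of the inteinless extein
  to reference families; sites labelled a, b, c, … per family by reference
  column, with functional-motif context (Walker A/B, C-motif, PD-(D/E)xK, …).
* **Transfer screening** — pairwise percent identity (terminal overhangs
  excluded from the denominator, stated in every header), a 35% flag
  threshold, neighbor-joining trees on Poisson-corrected distances, and an
  intein-versus-extein tree incongruence test.
* **Survey statistics** — per-cluster prevalence, inteins per 100 CDS,
  genome-size regression (R²), residue-conservation logos, and a
  penultimate-residue report.
* **Synthetic data** — a generator that plants class 1/3 inteins with
  known ground truth in multi-cluster genome sets, so every stage is
  testable without downloads.

## Worked example

Simulate a small two-cluster survey, scan the genomes, and summarize:

```r
library(inteinscan)

cfg  <- simConfig(seed = 7, clusters = c(C = 15L, B = 25L),
                  inteinRate = c(C = 0.9, B = 0.05))
sim  <- simulateSurvey(cfg)
scan <- runScan(genomes = sim$genomes)
head(scan$table[, c("protein_id", "start", "end", "intein_class",
                    "penultimate", "terminal", "plus_one", "hen")], 4)
#>         protein_id start end intein_class penultimate terminal plus_one   hen
#> 1 C_phage001_orf11   104 322       class1           G        N        C  TRUE
#> 2  C_phage002_orf6    94 229       class1           H        N        C FALSE
#> 3  C_phage003_orf2   204 422       class1           H        N        C  TRUE
#> 4 C_phage004_orf12   109 327       class1           G        N        C  TRUE
```

Each row is one accepted intein call: 1-based boundaries on the host
protein, splicing class, the penultimate residue (canonically His, here
sometimes Gly — a natural phage variant), the terminal Asn, the +1 extein
nucleophile, and whether a homing endonuclease was found between blocks B
and F.

```r
runSurvey(sim$manifest)$prevalence
#>   cluster n_total n_positive percent_positive percent_display
#> 1       B      25          1          4.00000             4.0
#> 2       C      15         14         93.33333            93.3
#> 3     ALL      40         15         37.50000            37.5

scoreRecovery(scan, sim$truth)[c("recall", "class_accuracy")]
#> recall 1  class accuracy 1   (15 planted inteins)
```

The prevalence table reproduces the survey style of reporting: an
intein-rich cluster against a poor one, plus an ALL row, with half-up
one-decimal display percentages alongside full-precision values. Against
the generator's truth manifest, every planted intein was recovered with
exact boundaries and the correct class.

A thin command-line wrapper with `scan`, `survey`, `transfer`, `logo` and
`simulate` subcommands ships in `inst/scripts/intein-survey.R`.

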