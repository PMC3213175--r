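---
title: "Screening trio alignments for de novo originated protein-coding genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening trio alignments for de novo originated protein-coding genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(denovoscreen)
library(dplyr)
```

## The problem

A de novo gene is a protein-coding gene born from previously non-coding
sequence, rather than by duplication, retroposition, or exon shuffling. On
the human lineage, the cleanest evidence for such a birth is a trio
comparison: a human coding sequence whose orthologous region exists in both
chimpanzee and orangutan but is *non-translatable* there, together with at
least one human-specific mutation that demonstrably completes the open
reading frame while both outgroups retain the ancestral, disrupting state.
Requiring the ancestral state in *both* outgroups is what separates a
genuine human-lineage gain from the confound of parallel loss — an
ancestrally intact gene independently broken on the chimpanzee and orangutan
branches.

`denovoscreen` implements this screen as a testable pipeline over gapped
human/chimp/orang alignments of candidate coding regions, plus the
surrounding analyses such candidate sets receive: coding-region expression
statistics from unique-read counts, lineage-specific substitution rates
under HKY85, alignment quality control, and the closing birth-rate
arithmetic.

## The screen

Each candidate travels through seven stages in fixed order, and every
decision is recorded in a per-gene filter ledger:

1. **Complete human ORF** — the annotated human start must be an ATG and
   translation from it must reach an in-frame stop.
2. **Minimum protein length** — human proteins shorter than
   `min_protein_aa` (default 100 aa) are excluded; very short ORFs arise
   too easily by chance to be trusted.
3. **Single copy** — evidence flags assert the gene has no close paralogs
   in human or the outgroups (duplicates would point to duplication, not de
   novo birth).
4. **Both outgroups disrupted** — see below.
5. **At least one enabling mutation** — see below.
6. **Transcription evidence** — an mRNA or EST hit.
7. **Translation evidence** — a proteomics peptide hit.

Stages 3, 6, and 7 consume precomputed boolean evidence columns; the
database searches that produce them (BLAST homology screens, mRNA/EST and
proteomics lookups, polymorphism scans) are outside this package's scope,
but keeping them as ledger stages preserves the complete audit trail. A
known ORF-disrupting polymorphism does not reject a gene; it is carried as
a fixation note, since such a gene is real but possibly not fixed in the
population.

### Disruption (stage 4)

The authoritative test is *translation of the ortholog's own degapped
sequence*, not a catalog of differences. The outgroup row is translated
from the position homologous to the human ATG; if no ATG sits there, the
entire provided region is searched for alternative ATG starts and the
longest resulting protein wins (ties to the 5'-most start). The ortholog is
**disrupted** when no complete ORF exists or the predicted protein is
shorter than `intact_fraction` (default 80%) of the human protein. A
complete ORF at or above that fraction makes the ortholog **intact enough**
— and the candidate is discarded, because an outgroup that still encodes
most of the protein is not convincingly non-coding. The boundary is
inclusive: exactly 80% counts as intact enough, the conservative reading.

Premature stops, frameshift-inducing indels (length not divisible by
three), and missing starts are still collected, but as explanatory
annotations. Deciding by translation rather than by the event list is what
resolves the awkward cases a difference catalog cannot: a compensated
+1/−1 indel pair restores the reading frame, so it must not count as
disrupting even though two "frameshift" events are present.

```{r}
sc <- generate_trio_scenario("intact_enough_85pct", seed = 1)
assess_ortholog(sc$trio, "chimp")
```

### Polarization (stage 5)

For every alignment column — and every contiguous gap run, treated as one
event — where chimpanzee and orangutan share a state that differs from
human, the human row is counterfactually reverted to that ancestral state
and re-translated with exactly the same anchored-then-rescue logic the
outgroups receive. If the reverted ORF is disrupted, the human-specific
change was singly sufficient for the completed frame: an **enabling
mutation**, classified by what its reversion breaks (`start_creation`,
`stop_removal`, or `frame_completion`).

Columns where the outgroups disagree, or where either carries `N`, are
unpolarizable and skipped; so are outgroup gap runs that only partially
overlap. Counterfactuals are applied one at a time — a gene that would need
two simultaneous human mutations reverted to break its ORF is not accepted.
This single-reversion rule is a deliberate, conservative choice; jointly
sufficient mutation sets are a known limitation.

```{r}
sc <- generate_trio_scenario("de_novo_stop_removal", seed = 1)
find_enabling_mutations(sc$trio)
```

## Thresholds

All numeric constants live in one object so a run is fully described by its
thresholds:

| parameter | default | units | role |
|---|---|---|---|
| `min_protein_aa` | 100 | aa | minimum human protein length |
| `intact_fraction` | 0.80 | ratio | outgroup ORF at/above this fraction of the human protein is intact enough |
| `qc_window_aa` | 5 | aa | sliding-window width for alignment QC |
| `qc_max_similarity` | 0.20 | ratio | window identity at/below this discards the ortholog pair |
| `max_lineage_rate` | 0.1 | subs/site | human or chimp branch above this discards the gene from rate summaries |
| `norm_scale` | 1e8 | — | display multiplier for normalized expression levels |
| `divergence_my_low`, `divergence_my_high` | 5, 6 | Myr | human–chimp divergence window for birth rates |

## Expression statistics

With exact transcript structures unknown for young genes, expression is
measured directly over the coding region: the number of unique-mapping
reads overlapping the CDS (by at least one nucleotide — multi-mapped reads
are never counted) divided by the coding length, `U/L`, and its
library-size-normalized form `(U/L)/V`, reported on a 1e-8 display scale.
Per tissue the package reports the pooled density `sum(U)/sum(L)` (pooled,
not the mean of per-gene ratios — both are computed and labeled), the
proportion of genes with any read, and the proportion of *expressed* genes
whose highest normalized level falls in that tissue. Genes with no reads
anywhere are excluded from the proportion-highest denominator but kept in
the proportion-expressed denominator; argmax ties break by the fixed
alphabetical tissue order, so the proportion-highest column always sums to
one. When a genome-wide background matrix is supplied, every statistic is
also emitted as a ratio to its background counterpart.

## Lineage-specific substitution rates

Rates are branch lengths on the unrooted three-taxon star tree under HKY85
(unequal base frequencies π, transition/transversion ratio κ), fitted by
maximum likelihood over gap- and N-free columns compressed into the 64
site patterns. The human and chimpanzee terminal branches are the
lineage-specific rates of interest; the orangutan branch absorbs the
outgroup path — the only identifiable parameterization with three taxa.

Numerical choices: base frequencies are empirical (counted from the
alignment, floored at 1e-6 and renormalized), not ML-optimized; no
molecular clock is imposed; transition probabilities use the exact
reversible-model eigendecomposition; optimization is bounded L-BFGS-B with
t ∈ [1e-9, 2], κ ∈ [0.05, 100], starting values t = 0.01, κ = 2,
log-likelihood tolerance 1e-8, and a 500-iteration cap. Identical
sequences fit to the t = 0 boundary. `jc_distance()` provides the JC69
closed form −(3/4)·log(1 − (4/3)p) as an analytic limit: with κ fixed at 1
and equal frequencies, the fitted human–chimp path length agrees with it to
well under 1e-3 at the divergences relevant here.

Summaries apply the rate filter — genes whose human *or* chimpanzee branch
exceeds 0.1 substitutions/site are discarded as likely misalignments or
non-orthologous regions — and report per-lineage mean ± SD, optionally next
to a genome-wide background set.

Alignment QC mirrors the ortholog prefilters such rate sets need: records
with ambiguous `X` residues are dropped, only the longest isoform alignment
per gene is kept, kept alignments under 100 aa are dropped, and a 5-aa
sliding window (step one column) discards pairs with any window identity at
or below 20%. "Similarity" is implemented as exact amino-acid identity — no
substitution matrix — with gaps counting as mismatches and windows running
over aligned columns; a similarity-matrix variant would be a defensible
alternative, and the identity choice is stated prominently for that reason.
The built-in `align_pair()` (global, affine gaps: match +1, mismatch −1,
gap open 4, gap extend 1, a length-L gap costing open + L·extend) is a
desk-scale utility for aligning ortholog pairs, not a reimplementation of a
progressive multiple aligner.

## Birth-rate arithmetic

Given `n` fixed de novo genes and a divergence window of 5–6 Myr, the
origination rate is `n/t` per bound — reported to three significant
figures — and, per gene, divided by the genome's protein-coding gene count
(30,000 here), reported to two significant figures:

```{r}
compute_birth_rate(59, 5, 6, n_genome_genes = 30000)
```

## What the synthetic data emulates — and what it does not

The generator is the package's ground truth. `generate_trio_scenario()`
builds 150-codon trios (protein 149 aa, comfortably above the 100-aa
floor) around a random ancestral CDS with no internal ATG in any frame,
then plants exactly one defining situation per kind: an ancestral in-frame
stop at ~40% of the protein reverted in human; an outgroup start codon
broken with no rescue ATG anywhere; a human-specific 1-nt insertion whose
removal shifts the frame; parallel loss at two different columns with
non-identical outgroup states; an identical intact trio; an outgroup
alternative start at ~15% leaving ≥80% of the protein; a premature stop at
~85%; and a gain shared by human and chimpanzee. Every emitted scenario is
self-checked through the classifier — generation fails rather than return a
mislabeled case — and uses a private RNG stream, so scenarios are pure
functions of `(kind, n_codons, seed)`.

`simulate_hky85()` evolves an ancestral sequence independently along the
three branches using exact HKY85 transition probabilities (per-branch
matrix exponential), with optional indels whose true alignment is retained
by construction; rate-fitting fixtures default to no indels since gapped
columns are dropped before fitting anyway. `simulate_expression()` draws
Poisson counts at given expected values; its defaults emulate the study
conditions the expression module targets — 53 genes over the 11-tissue
panel (adipose, whole brain, cerebral cortex, breast, colon, heart, liver,
lymph node, skeletal muscle, lung, testes), single-exon coding lengths of
300–1200 nt, libraries of roughly 10 million valid reads, and a mean
structure with most genes weakly expressed and testes (×3) and cerebral
cortex (×2) elevated, reflecting the tissue bias young genes show.

What passing tests therefore demonstrate: the engine's verdicts are exactly
right wherever truth is constructible — planted scenarios, enumeration
oracles, closed forms, simulation at known parameters. What they do not
demonstrate: performance on real genomic alignments, whose disruptions
co-occur, whose alignments err, and whose evidence databases are incomplete
in ways no generator reproduces. The scenario kinds are deliberately
unambiguous; real candidates near the 80% boundary or with tangled indel
histories will be harder than anything the generator emits.

## Problem sizes and runtime choices

The shipped verification suite uses sizes chosen to give tight statistical
checks at desk scale: 200 labeled scenarios across all eight kinds for
planted-truth recovery; 1,000 random 120–400-nt sequences for the
ORF-rescue enumeration oracle; 50 replicate 50-kb trios at
t = (0.02, 0.03, 0.05), κ = 4 for branch-length recovery (each replicate
within ±20%, the mean within three standard errors); a 100-kb simulation
for the JC69 limit; 53×11 expression matrices; and a few hundred random
pairs for the QC window filter. Site-pattern compression keeps each HKY
fit fast regardless of sequence length.

## Known limitations

- Alternative starts are ATG-only; non-ATG initiation (CTG/GTG) is not
  considered.
- One enabling mutation must be singly sufficient; jointly sufficient sets
  are not searched.
- The 80% comparison uses unaligned predicted protein lengths.
- Inputs must be single-exon (or pre-concatenated) coding regions on the
  coding strand; there is no splice modeling or liftover.
- Parsimony-by-identity polarization only; no probabilistic ancestral
  reconstruction, no dN/dS.
- The three-taxon star cannot separate the orangutan terminal branch from
  the internal branch; only the two ingroup terminals are interpretable as
  lineage rates.
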