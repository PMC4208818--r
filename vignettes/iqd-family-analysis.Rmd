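---
title: "Methods: genome-wide IQD gene-family analysis with iqdfam"
author: "iqdfam authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-wide IQD gene-family analysis with iqdfam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iqdfam)
```

# The problem

The IQ67-domain (IQD) proteins are a plant-specific family of
calmodulin-binding proteins defined by a 67-residue domain that carries a
characteristic arrangement of calmodulin-recruitment motifs. Genome-wide
surveys of this family — exemplified here by the 67-member soybean GmIQD
family — follow a standard recipe: detect family members from the motif
grammar, characterize gene structure (exon/intron organization and intron
phases), classify how duplicate pairs arose (tandem vs segmental), estimate
their divergence (Ka/Ks) and date the duplications, detect microsynteny
around the family loci, build a phylogeny, and profile expression across
tissues and stress treatments. `iqdfam` packages this recipe as tested,
reusable components, together with a synthetic-data generator that implants
every structure the pipeline is supposed to find, so the whole analysis can
be validated against known ground truth without downloading a genome.

# The motif grammar and the IQ67 domain caller

Four motif classes are scanned as regular expressions over the protein
alphabet, reported at all (possibly overlapping) positions:

| class        | pattern                          | length |
|--------------|----------------------------------|--------|
| IQ (strict)  | `IQxxxRGxxxR`                    | 11     |
| IQ (relaxed) | `[ILV]QxxxR xxxx [RK]`           | 11     |
| 1-5-10       | `[FILVW]x3[FILV]x4[FILVW]`       | 10     |
| 1-8-14       | `[FILVW]x6[FAILVW]x5[FILVW]`     | 14     |

Every strict IQ hit is by construction also a relaxed hit — the strict
pattern is a sub-language of the relaxed one — and the test suite asserts
this as a property.

A candidate IQ67 domain is any 67-residue window anchored at the first
residue of a relaxed-IQ hit. This anchoring convention is the simplest
deterministic one consistent with the family hallmark that domain codons
16/17 fall inside every member's domain. Overlapping candidate windows are
merged with the leftmost kept, which also collapses the windows that the
second and third IQ copies of a single domain would otherwise spawn.
`spacing_ok` records whether successive IQ hits are separated by the
canonical 11 and 15 intervening residues; because real members deviate
slightly, the comparison allows a tolerance (`spacing_tolerance`, default
±2 residues, configurable). Domain membership does not require the
Ca²⁺-dependent 1-5-10/1-8-14 overlap — the overlap is a family hallmark
that the caller reports, not a per-gene filter — and a single IQ copy
suffices by default (`min_iq_copies = 1`, matching the described 1–3 copy
range; raise it to demand the full three-copy arrangement).

Protein descriptors use average residue masses plus one water for the
molecular weight, and solve the isoelectric point by bisection of the
Henderson–Hasselbalch net-charge function on pH 0–14. The pKa set is
EMBOSS-style (N-terminus 8.6, C-terminus 3.6, K 10.8, R 12.5, H 6.5,
D 3.9, E 4.1, C 8.5, Y 10.1) and overridable: published pI tables rarely
state their constants, so small systematic offsets against other tools are
expected and the table is exposed rather than hidden.

# Gene structure and intron phases

Intron phase is defined on the coding sequence only (UTR exons are
ignored): an intron after `o` coding nucleotides has phase `o mod 3`; phase
0 falls exactly between two codons, phases 1 and 2 inside a codon. The
diagnostic family intron — phase 0, between IQ67-domain codons 16 and 17 —
is recognized exactly: for a domain starting at protein residue `d`, the
intron must sit at coding offset `3 × (d − 1 + 16)`. Genes whose domain is
encoded entirely in a terminal exon simply return `FALSE`; no exception is
made for them.

Paralog structure comparison reduces each gene to its intron phase vector.
Identical vectors are `conserved`; vectors at edit distance one (a single
intron inserted or deleted) are `gain_loss_candidate`, a reproducible
operationalization of qualitative single gain/loss calls; anything else is
`divergent`.

# Duplicate classification and dating

A pair is **tandem** when both genes share a chromosome, at most
`max_intervening` annotated genes lie strictly between them, and the span
from the 5'-most gene start to the 3'-most gene end is at most `window`
(defaults 5 genes / 100 kb). The literature on this family states the rule
once as "three or fewer" and once as "five or fewer" intervening genes; the
package defaults to the protocol value of 5 and exposes the flag, so either
reading is one argument away. Whether non-protein-coding annotations count
as intervening genes is likewise exposed (`coding_only`, default counts
all).

A non-tandem pair is **segmental** when its genes occupy the two partner
intervals of a duplicated chromosomal block (supplied as a block table, or
derived from the synteny module), and **other** (O) otherwise — e.g. pairs
produced by retrotransposition. Tandem takes precedence when both criteria
fire, since mutually exclusive S/T/O typing needs an order and physical
adjacency is the stronger signal. Family genes sitting on one half of a
block whose partner half contains no family gene are reported as
singletons with a lost sister.

Ka and Ks are estimated with the Nei–Gojobori (1986) counting method:
average synonymous (S) and nonsynonymous (N) site counts over both
sequences, pathway-averaged difference counts for codons differing at more
than one position, and a Jukes–Cantor correction
`d = −(3/4)·ln(1 − 4p/3)`. Conventions: mutations to stop codons are
excluded from the synonymous-site denominators; mutational pathways passing
through a stop codon are excluded from the averaging (with an unweighted
fallback over all pathways if every one is blocked); codon columns
containing gaps, ambiguity codes or stops are excluded from all counts,
which keeps the `S + N = 3 × codons` identity exact and testable. NG86 was
chosen over a maximum-likelihood codon model because it is fully specified,
hand-checkable (the test suite carries a worked single-substitution
example), and the dating surface consumes Ks values that are
estimator-independent inputs to the clock formula. Codon alignments are
produced by back-threading a global protein alignment (BLOSUM62, affine
gaps) onto the CDSs, with protein gaps becoming `---` triplets.

Duplication dates use the soybean synonymous clock:

\[ T = \frac{K_s}{2 \times 6.1 \times 10^{-9}} \times 10^{-6} \ \mathrm{Mya} \]

reported to two decimals by convention. Selection classes split at the
neutral boundary: Ka/Ks below 1 purifying, above 1 positive, equal to 1
(within 1e-9) neutral.

# Microsynteny

A synteny block around an anchor gene pair collects all genes within
100-kb flanks of each anchor, excludes genes tagged as retroelements or
transposons, collapses tandem arrays to one representative (reusing the
duplication module's tandem rule on homologous segment genes; anchors are
never collapsed away), and matches homologs between the two segments as
best non-self partners under Smith–Waterman local alignment (BLOSUM62,
affine gaps). A block is reported when at least three conserved pairs lie
in the windows; by default the anchor pair counts toward the three (the
alternative reading is one flag away). Five or more *flanking* (non-anchor)
matched pairs flag the block as originating from a large-scale duplication
event.

The homology gate replaces a BLASTP E-value cutoff with a raw score
threshold: a full E-value statistics stack is out of scope, and the
criterion is a binary gate. The default (150) was calibrated once on a
seeded null of 1300 unrelated random protein pairs (150–450 aa, generator
composition), whose local-alignment scores had mean ≈53 and maximum 121,
while duplicate pairs at the divergence this package models score well
above 1000; the threshold is configurable.

Synteny quality is

\[ Q = 100 \times \frac{2P}{G_a + G_b} \]

with `P` conserved pairs and `G_a`, `G_b` the segment gene counts after
exclusion and collapsing. The source literature names the statistic but
does not print the formula; this reading matches "the sum of the total
number of genes in both conserved gene regions" as the denominator, is
bounded by 100 on perfectly mirrored segments, and strictly decreases when
an unpaired gene is added — both asserted as tests. Orientation
(`same` vs `inverted`) is the sign of the rank correlation of paired gene
positions.

# Phylogenetics

Distances are uncorrected p-distances over the gap-free columns of a
user-supplied multiple protein alignment; no substitution model is imposed
because family surveys of this kind report NJ on full-length proteins
without naming one, and the distance function is configurable upstream.
Tree construction is Saitou–Nei neighbor joining, delegated to `ape::nj()`
behind the `nj_tree()` surface; the test suite verifies it against a
brute-force least-squares quartet oracle and against 20 random additive
6-taxon matrices, where NJ must recover the generating topology exactly.
Bootstrap support resamples alignment columns with replacement, rebuilds
the NJ tree per replicate, and reports for each original bipartition the
fraction of replicates containing it; replicates are drawn from a single
seed, so supports are exactly reproducible. Sister (cherry) pairs are leaf
pairs sharing an immediate ancestor with support at least `min_support`
(default 0.5 — "strong bootstrap support" is never quantified in this
literature, so the threshold is configuration, not dogma).

Multiple alignment itself is deliberately out of scope: the module accepts
an aligned FASTA produced by any standard aligner, and the package's own
global pairwise aligner exists for codon back-threading and synthetic
tests only.

# Expression and qPCR

RPKM is `count × 1e9 / (gene length in bp × library size)`. Hierarchical
clustering uses Pearson-correlation distance `1 − r` with complete linkage
— the combination conventionally used for tissue expression heat maps —
with two numerical conventions: genes with constant profiles, whose
correlation is undefined, are placed at distance 1 from everything (with a
warning) so the clustering stays total; and rows are ordered
alphabetically before clustering so the dendrogram is invariant to input
order. Tissue preference is the argmax condition, ties broken
alphabetically; a gene is additionally flagged single-tissue when its top
condition exceeds twice the runner-up (`dominance_ratio`, configurable).
Extracting expression groups from the dendrogram is left to the user via
`stats::cutree` (a `k` or height choice), since published group cuts of
such heat maps state no cut height.

qPCR quantification is textbook 2^-ΔΔCT: ΔCT = mean target CT − mean
reference CT per sample, ΔΔCT relative to the untreated 0-h control, fold
= 2^−ΔΔCT. The control therefore evaluates to exactly 1 — an identity the
acceptance checks exercise on noisy tables. Regulation calls use a
down-boundary of 0.5 (a fold of exactly 0.5 is *not* down) and an
up-boundary defaulting to 2: calling any fold above 1 "up" would label
noise, while the clearly induced genes in this family exceed 2-fold; the
threshold is exposed, and this deviation from the loosest possible reading
is deliberate. `down` requires all folds below the boundary, `up` requires
some fold above the up-boundary and none below the down-boundary,
`unchanged` everything in between, `mixed` otherwise.
Amplification-efficiency correction is not modelled.

# The synthetic-data generator

The generator is the package's ground-truth instrument, not a fixture: it
emulates the structures the pipeline measures.

* **Canonical domain template.** One deterministic 67-residue template:
  strict IQ at positions 1–11, 11 spacer residues carrying one 1-5-10
  motif, strict IQ at 23–33, 15 spacer residues carrying one 1-8-14 motif,
  strict IQ at 49–59, 8-residue tail. It satisfies the motif grammar at the
  canonical spacing with exactly three IQ copies. Flanking protein
  sequence is drawn from a fixed alphabet that excludes glutamine, so the
  implanted domains are provably the only relaxed-IQ anchors in a
  generated protein.
* **Gene models.** Each IQD gene carries the diagnostic phase-0 intron
  between domain codons 16 and 17 (plus any introns requested through
  `intron_plan`); background genes get 0–2 introns at arbitrary phases.
  CDSs are reverse-translated through a fixed codon-usage table with a
  mild bias toward A/T third positions, typical of plant genomes. Genes
  are laid out with randomized strands and intergenic gaps; introns are
  `GT…AG`-bounded.
* **Duplicates.** Tandem pairs are adjacent mutated copies; segmental
  blocks duplicate a run of one IQD anchor plus six collinear background
  genes onto another chromosome. Divergence is introduced by per-codon
  point substitutions — at most one per codon, never creating a stop —
  with the substitution counts chosen as the NG86 site counts times the
  Jukes–Cantor-inverted target proportions, so NG86 estimates on the pair
  recover `ka_target`/`ks_target` in expectation (the accept/reject
  variant of placing mutations against the site classification reduces to
  exactly this when one hit per codon is enforced). Nonsynonymous changes
  are excluded from the implanted domain codons, mirroring the purifying
  selection that keeps the domain recognizable in real paralogs; without
  this the "every implanted domain is recovered" invariant would be
  testing the mutation rate, not the scanner.
* **Expression and CT tables.** Designed tissue preferences become
  `baseline × fold` expected counts with optional negative-binomial noise;
  qPCR folds become −log₂(F) target-CT shifts against a constant
  reference CT with Gaussian cycle noise.

Default conditions are a scaled-down but realistic study: 5 chromosomes ×
500 kb, 8 IQD genes among 60 background genes, one tandem pair, two
segmental blocks with six collinear flanking genes each, and duplicate
divergence `ka = 0.03`, `ks = 0.12` — inside the Ka 0.017–0.067 /
Ks 0.078–0.219 range observed across the 31 soybean GmIQD paralog pairs.
Chromosome-scale soybean simulation is deliberately not attempted.

**What passing on synthetic data does and does not show.** The generator
produces substitution-only divergence (no indels, no gene conversion), no
UTRs or alternative transcripts, near-uniform amino-acid composition, and
noise-free coordinates. Success on it demonstrates that the detectors
implement their definitions correctly and recover known truth; it does not
demonstrate robustness to fragmented assemblies, annotation errors,
domain-eroding divergence, or compositional biases of real proteomes.

# Problem sizes and numerical choices

The test and acceptance workloads use the default synthetic genome
(~80 genes), 50-seed × 450-codon Ka/Ks recovery runs, 100-shuffle scanner
nulls, 20 random 6-taxon NJ recoveries, and 20-seed qPCR recovery — sizes
chosen so the full suite exercises every claim in well under typical CI
budgets while keeping Monte-Carlo standard errors far inside the asserted
tolerances. Other numerical conventions collected here: bisection tolerance
1e-6 pH units for pI; Ka/Ks reported to 4 decimals and dates to 2; NJ ties
resolved deterministically; bootstrap supports exactly reproducible per
seed; Jukes–Cantor correction refuses proportions ≥ 3/4 rather than
returning NaN.

# Known limitations

* Family membership is purely grammar-based; no profile-HMM confirmation
  or de-novo motif discovery is included.
* The homology gate is a raw alignment score, not an E-value; thresholds
  must be recalibrated for substantially different protein-length or
  composition regimes.
* NG86 underestimates divergence under strong transition/transversion bias
  compared to weighted-pathway or ML estimators; dates inherit any bias of
  the single-rate synonymous clock.
* Subfamily naming (I–IV/V) is label propagation from user-supplied
  references, not an intrinsic inference.
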