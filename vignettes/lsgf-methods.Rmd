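---
title: "Methods: lineage-specific gene family evolution in ciliates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lineage-specific gene family evolution in ciliates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(lsgfevo)
```

## The problem

Ciliates separate somatic and germline functions into distinct nuclei, and
their somatic genomes differ radically in architecture: extensive
fragmenters (EF) process the germline into thousands of gene-sized somatic
chromosomes, non-extensive fragmenters (NEF) keep multi-gene chromosomes,
Heterotrichea (HE) carry highly polyploid somatic genomes, and
Karyorelictea (KA) roughly diploid ones. `lsgfevo` implements a pipeline
for asking how these architectures relate to the birth, spread and
selective regimes of lineage-specific gene families (LSGFs) — families
restricted to the clade and typically young. Because real studies of this
kind hinge on heterogeneous transcriptome/genome collections that cannot be
shipped, the package pairs every analysis stage with a synthetic-data
generator that produces inputs with the same statistical structure and a
recorded ground truth, so the whole pipeline is testable end to end.

## Stages and their models

### ORF curation

Transcripts are scanned in all six frames for the largest complete ORF
(ATG start and in-frame stop required by default; a flag admits
transcript-edge-truncated ORFs). Stop codons come from the active genetic
code: most ciliates reassign TAA/TAG to glutamine (translation table 6,
the package default), *Euplotes* reads TGA as cysteine (table 10), and
custom 64-line tables can be loaded. ORFs shorter than 200 aa are dropped
(configurable). The terminal stop is excluded from the CDS, keeping CDS
length exactly 3x protein length.

Allelic variants — near-identical contigs retained by transcriptome
assemblers because ciliate somatic loci are biallelic and highly amplified
— are collapsed by greedy longest-first clustering at 97% identity over the
full length of the shorter sequence. We deliberately replace word-heuristic
clustering engines with exact pairwise alignment (global on the shorter
sequence, local on the longer): at the scale this package targets,
exactness is cheap and removes heuristic-dependent edge cases. Identity
counts gaps and ambiguous bases as mismatches; any codon containing an
ambiguous base translates to `X`, which never matches.

### Composition screening (GC3s and ENc)

Misassigned ORFs (food organisms, contaminants) usually betray themselves
by codon composition. For each ORF we compute:

* **GC3s** — the G+C fraction at third positions of codons from four-fold
  degenerate codon boxes (boxes whose four third-position variants are
  synonymous under the active code).
* **ENc** — Wright's effective number of codons, generalised to the active
  code. For amino acid $a$ with $k \ge 2$ synonymous codons, usage counts
  $n_i$, $n = \sum n_i$ and $p_i = n_i/n$, the homozygosity estimate is
  $F_a = (n\sum p_i^2 - 1)/(n - 1)$; class averages $\bar F_k$ give
  $\mathrm{ENc} = N_1 + \sum_k N_k/\bar F_k$. Degeneracy classes are
  recomputed per code — under table 6 glutamine is four-fold and the
  theoretical maximum is the code's sense-codon count (63), not 61.
  Amino acids with $n < 2$ or $F_a \le 0$ are treated as unobserved; a
  class with no observation is imputed from the nearest observed classes
  (Wright's convention, e.g. $\bar F_3$ from the mean of $\bar F_2$ and
  $\bar F_4$). The estimate is clamped at the theoretical maximum, which
  also absorbs the estimator's well-known upward overshoot at uniform
  usage.

Candidate lineage-specific ORFs are retained when their GC3s falls inside
the closed 10–90th percentile band (linear-interpolation quantiles) of a
conserved-gene reference GC3s vector supplied as a plain file. ENc is
computed and reported alongside, and can optionally be band-filtered too,
but the default retention rule is on GC3s only. The band is computed on
the pooled reference: the reference enters as a single cross-taxon vector
of conserved-family GC3s values, which makes pooling the only coherent
reading of the procedure here.

### Family refinement and sharing

Gene-family membership maps can come from any orthology tool; for
self-contained runs `cluster_orfs()` provides single-linkage components
over protein identity with a 4-mer word prefilter. Refinement applies, in
order: (1) a one-pass 50–150% band around the family's mean protein length
(computed once on the initial membership — the plain reading; iterating
the mean is a different, unstated procedure), then (2) ciliate proportion
>= 95%, member count >= 5, and >= 2 ciliate genera, with the first failed
criterion reported as the machine-readable rejection reason. The ciliate
proportion is evaluated after the band drop by default (a flag flips it;
the choice is genuinely open). Sharing summaries project membership onto a
binary taxon-presence matrix and report upset-style intersection counts
over architecture categories, per-category family counts and sizes, and
per-taxon counts.

### Dating births and mapping duplications

Because transcriptome data under-sample gene families, absence is
unreliable and losses would be grossly over-inferred. Births are therefore
dated by **Dollo parsimony** — a family is gained exactly once, at the MRCA
of the taxa possessing it, and the gain is attached to the branch
subtending that node. Losses are implemented (`dollo_loss_count`, minimal
maximal-dead-subtree count) but excluded from default reports.

Duplications are mapped by fixed-topology **LCA reconciliation**: each
gene-tree node maps to the LCA of its children's mappings, and a node is a
duplication exactly when its mapping equals a child's mapping. This
minimises duplications over all valid mappings. Unrooted gene trees are
midpoint-rooted by default (outgroup rooting is a flag). We deliberately do
not search topology space: the package trusts its input gene trees, which
is the major deviation from SPR-searching reconciliation engines, and is
stated as such. Losses are counted internally by the standard
depth-difference formula and again suppressed in reports.

### Group-level selection analyses

Gene-tree branches are partitioned by architecture category: terminal
branches by their taxon, internal branches labelled with a category iff
every descendant branch carries it, otherwise `unclassified`. Unclassified
branches are never tested; they receive their own nuisance omega
distribution.

The codon model is an MG94/GTR-type reversible Markov process on the sense
codons of the active code: single-nucleotide codon changes at rate
$\rho_{ab}\,\pi_j\,\omega^{\mathbb 1[\text{nonsyn}]}$, where $\pi$ is the
equilibrium codon frequency (F3x4 from the alignment by default) and
$\rho$ the six GTR exchangeabilities. All rate matrices share a single
scaling so branch lengths are expected neutral substitutions per codon.
Omega varies as a branch-site random effect: each branch x site draws
independently from its group's 3-category discrete distribution, so the
per-branch transition matrix is the category mixture — mixtures collapse
to the branch level and likelihoods follow from one pruning pass, computed
in C++ via symmetric eigendecomposition (the model's reversibility makes
the symmetrised rate matrix exact to diagonalise).

**Selection intensity (RELAX-style).** Every labelled group shares the
reference distribution raised to a group exponent $K_G$
($\omega_i \mapsto \omega_i^{K_G}$): $K<1$ relaxes, $K>1$ intensifies.
The reference group is EF if present, else NEF, else HE, else KA, and a
partition is testable when more than one group has more than one branch.
The null ($K_G = 1$ everywhere) is compared to the alternative ($K_G$ free
per non-reference group) by an LRT on $\chi^2_{|G|-1}$. A partitioned
descriptive model (free distribution per group) is fitted as a sanity
reference; the RELAX alternative is flagged adequate when its small-sample
corrected information criterion (AICc with the number of codon sites as
the effective sample size) does not exceed the descriptive model's. AICc
is our concrete reading of an otherwise unspecified "good fit" rule, and
is recorded as such.

**Episodic diversifying selection (BUSTED-style).** Per group, the
unconstrained model (top omega category free) is compared against the
constrained model (top category capped at 1). The null rests on a
boundary, so the LRT is referred to an even mixture of a point mass at
zero and $\chi^2_2$ — a conservative convention chosen because no degrees
of freedom are prescribed for this variant. An optional mean-1 3-category
synonymous rate multiplier implements site-to-site synonymous variation;
it is off by default and the LRT contract is unchanged either way.

P values are corrected by Benjamini–Hochberg FDR (`stats::p.adjust`)
across families; detection rates of the episodic screen are compared
within bins of `floor(branches/5)` because power grows with the number of
tested branches.

### Numerical choices

* Omega distributions are parameterised with nested logistic factors
  (ascending categories by construction) and softmax weights; the top
  category is `exp` (unconstrained) or logistic (constrained). Effective
  omegas are capped at $10^4$.
* $K$ is optimised on the log scale and clamped to $[10^{-3}, 50]$;
  boundary hits are flagged.
* Fits use multi-start Nelder–Mead: short exploratory runs from up to
  three documented starts, then a long refinement of the best
  (`reltol 1e-9`). The alternative always starts from the null optimum at
  $K = 1$ and the unconstrained model from the constrained solution, so
  nested LRTs cannot go negative; a refit from the nested start is forced
  if an optimizer ever reports otherwise.
* Branch lengths and $\rho$ are held fixed during the group tests
  (`estimate_branch_lengths()` provides the shared-omega first stage);
  this two-stage practice trades a small amount of variance for a large
  amount of speed and is the package default.
* Likelihood pruning rescales per site at every merge, so deep trees do
  not underflow; zero-length branches reduce exactly to the stationary
  distribution.

## The synthetic generator

`simulate_species_tree()` arranges the four categories clade-wise on the
backbone ((KA, HE), (NEF, EF)) — mirroring ciliate taxonomy, where the
Postciliodesmatophora (KA + HE) split precedes the NEF/EF divergence —
with exact largest-remainder apportionment of leaf counts and a flag for
random leaf-wise assignment. Branch lengths are exponential with mean 0.2
substitutions/site, a realistic depth for divergences this old and enough
signal for codon-model inference.

`simulate_family_histories()` samples one birth node per family over
branches proportionally to length (a synthetic root branch of mean edge
length admits root births), then runs Poisson losses (lineage-terminating)
and duplications (independent-copy-spawning) below it. Families that lose
every copy are flagged, not dropped. With length-weighted births and
lineage-terminating losses, most surviving families are young and born
near the tips, which is also the qualitative pattern such studies report;
absolute event-rate magnitudes (defaults 0.3/0.3 per unit branch length)
are not taken from any measured dataset and are documented as arbitrary.

Alignments evolve along the family's gene tree under group-specific
distributions $\omega_{\text{ref}}^{K_G}$, drawing a category per branch x
site; the state space is the sense codons, so stop codons can never occur.
Transcript emission wraps each CDS as `flank–ATG–CDS–stop–flank` with
20–60 nt random UTR-like flanks, injects allelic variants (at most 3%
divergence, below the 97% collapse threshold; stop-creating mutations are
skipped) with deterministic `round(rate x n)` apportionment, and
contaminant ORFs drawn codon-wise at a low GC3s target (0.25) against the
ciliate-like 0.70.

The conserved-family reference GC3s is drawn from a clamped normal
(mean 0.70, sd 0.08). The sd is deliberately larger than the ~0.04
binomial noise of a single ORF's GC3s at ~100 four-fold sites: the real
reference pools conserved families across many taxa with differing base
composition, so its spread exceeds any single taxon's. This is also what
makes a 10–90 reference band able to retain ~95% of genuine
single-taxon ORFs while rejecting low-GC contaminants.

What the generator does **not** emulate: assembly errors and chimeras,
rRNA contamination, expression-dependent transcript dropout,
genetic-code heterogeneity within a dataset, indels (alignments are
generated gapless), gene conversion between duplicates, and germline
scrambling mechanics. Passing the synthetic recovery tests therefore
demonstrates correctness of the algorithms under the model's assumptions,
not robustness to every artefact of real transcriptome collections.

## Validation and problem sizes

The test suite checks every stage against independent oracles: an
exhaustive (frame, start, stop) ORF scanner; analytic ENc limits (20 at
one-codon-per-amino-acid usage, 61 at uniform usage under the standard
code); exhaustive subset enumeration for Dollo births/losses (trees up to
8 leaves); a brute-force duplication minimiser over all valid
reconciliation mappings (exhaustive for small gene trees, sampled for 5–6
leaves); and full ancestral-state x omega-category summation for the
codon likelihood (3–4 taxa, relative tolerance 1e-8).

Statistical calibration uses 16-taxon, 300-codon simulations under the
ciliate code: the RELAX-style LRT's null rejection rate is required to sit
inside the exact binomial acceptance region at $\alpha = 0.05$ over 50
replicates, median $\hat K$ must fall on the correct side of 1 at
$K_{\text{true}} \in \{0.3, 2\}$ (20 replicates each), and the episodic
screen must stay at or below a 0.075 null rate (40 replicates) while
exceeding it under a planted $\omega_3 = 4$, weight 0.1 signal. Replicate
counts are the package's chosen compromise between statistical resolution
and a test suite that runs in minutes; calibration fixes branch lengths at
their true values, isolating the selection parameters under test.

## Limitations

* Fixed gene-tree topologies: reconciliation and selection inherit any
  gene-tree estimation error; there is no SPR correction.
* The likelihood optimiser is derivative-free; with very short alignments
  or tiny groups the K estimate can sit at its bounds (flagged).
* Dollo dating is conservative by construction: with real losses the
  inferred birth is never older than the truth.
* The composition screen assumes the host composition is strongly skewed
  relative to contaminants; hosts with unremarkable GC3s would need the
  external-hit-table input instead.
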