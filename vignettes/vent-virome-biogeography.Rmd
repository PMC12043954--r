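---
title: "Methods: comparative biogeography of hydrothermal vent viromes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative biogeography of hydrothermal vent viromes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventviromics)
library(dplyr)
```

This vignette is the package's own account of its methods: the models and
procedures each stage implements, the tunable parameters and why their
defaults are what they are, what the synthetic community generator emulates
(and what it deliberately does not), the numerical choices made where the
design was open, and the known limitations.

## The scientific setting

Deep-sea hydrothermal vents host viral communities in three habitat types:
buoyant **plumes** in the water column, mineral chimney **deposits**, and
low-temperature **diffuse flow**. Multi-site metagenomic surveys of such
systems produce viral scaffolds, viral bins (vMAGs), per-sample read-mapping
profiles, protein complements, annotations, and host predictions. The
recurring analytical questions are about *endemism*: is a virus (or a cluster
of related viruses, or a protein family) restricted to one site, shared
between sites of one vent field, or shared between fields separated by
hundreds to thousands of kilometres — and does virus abundance track the
abundance of the predicted microbial hosts across samples?

`ventviromics` implements that comparative layer. It does not identify
viruses, bin scaffolds, call taxonomy or genome quality, infer hosts, or map
reads; those upstream results are inputs (tibbles and FASTA files), and the
package's job is the screening, clustering, classification, and
compositional statistics that turn them into biogeographic statements.

## vMAG curation

A viral bin is kept as a single multi-scaffold genome only if none of three
screening rules fire:

* `redundant_protein_count >= 2` — high protein redundancy suggests the bin
  mixes strains or unrelated genomes;
* `lysogenic_scaffold_count >= 2` — two lysogenic scaffolds in one bin are
  more plausibly two proviruses than one genome;
* more than 10 member scaffolds — oversized bins are unreliable.

Dissolved bins return their scaffolds to the unbinned pool, each keeping its
own scaffold-level lifestyle. Kept bins are linked into one sequence with
1,500 bp runs of `N` between consecutive scaffolds (the convention expected
by single-sequence downstream tools), ordered by `scaffold_id` — linking
order is otherwise arbitrary, and sorting makes it reproducible. A bin
containing any lysogenic scaffold is designated lysogenic. The curation
ledger enforces two closure identities on every run: binned + unbinned
scaffolds = total scaffolds, and retained bins + unbinned units = total
units. "Redundant proteins" is consumed as an opaque per-bin count from the
binning tool; this package only applies the threshold.

## Fragment-mapping ANI with aligned fractions

Average nucleotide identity between two genomes is estimated by an explicit
fragment-mapping procedure rather than a sketching heuristic, so that its
contract can be stated (and tested) against an exact oracle:

1. The shorter genome (by non-N length) is cut into fragments of
   `fragment_length` (default 1,000 bp). N spacers of linked vMAGs are never
   inside a fragment, and tail pieces under 300 bp are dropped.
2. Each fragment is anchored on the longer genome by exact `k`-mer matches
   (default `k = 15`, probed every 25 bp); the modal anchor diagonal, if
   supported by at least two seeds, defines a target window (±100 bp pad)
   that is aligned global-locally (match +1, mismatch −1, gap open 6,
   extend 1).
3. A fragment counts as aligned when its identity (matches over alignment
   columns) is at least 70%. ANI is the mean identity of aligned fragments;
   each genome's aligned fraction (AF) is its aligned bases over its non-N
   length, in percent. Pairs with no aligned fragment yield no edge — two
   random 10 kb genomes essentially never share an exact 15-mer diagonal
   (per-position match probability $4^{-15}$), which is also why the
   all-vs-all driver can skip pairs sharing fewer than three sampled seeds
   without aligning anything.

The clustering edge weight corrects ANI by the *lowest* of the two aligned
fractions and rescales to $[0,1]$:

$$\mathrm{score} = \frac{\mathrm{ANI} \times \min(\mathrm{AF}_a,
\mathrm{AF}_b)}{100^2},$$

screened at `min_score = 0.70`. Reading the threshold on the normalized
$[0,1]$ scale is the dimensionally consistent interpretation of applying a
"70%" cut after AF correction. Only genomes of at least 3,000 non-N bp enter
pairing; shorter inputs are an error rather than a silent skip.

The estimator's accuracy contract is defined by an independent oracle —
identity of one global alignment of the whole pair — and, on
substitution-only synthetic pairs, by the known truth: for substitution
rates up to 0.15 the estimated ANI stays within 1.5 points of
$(1-\mathrm{rate})\times 100$ (measured max error ≈ 0.9 over the test
grid). Whether this estimator agrees numerically with any particular
sketching tool is untested and not claimed.

## Markov clustering

MCL is implemented from first principles on a dense column-stochastic flow
matrix: add a self-loop of weight 1 to every node, column-normalize, then
iterate **expansion** (matrix power, default 2), **inflation** (elementwise
power, default 2.0, then renormalize), and **pruning** of entries below
`1e-5` (renormalizing again) until the largest entrywise change falls below
`1e-6` or 100 iterations pass (non-convergence interprets the current
matrix and sets `converged = FALSE` with a warning). The defaults are the
reference implementation's documented defaults; the self-loop weight of 1
is on the same scale as the normalized edge scores (0.70–1.0).

Clusters are read from the limit matrix: rows with positive diagonal are
attractors; attractors with flow between them form one attractor system; a
node belongs to the systems whose attractors give it positive flow, and a
node caught by several systems joins the one holding the lexicographically
smallest attractor (a pure tie-break for determinism — overlap is rare and
the choice is otherwise arbitrary). Nodes whose column was fully pruned
follow their strongest row. Three properties are enforced by tests: the
output is a partition, clusters never span connected components, and the
number of clusters is non-decreasing in the inflation parameter (checked
empirically over an inflation grid on fixed random graphs). On
planted-partition graphs (3 blocks of 10, $p_{in}=0.9$, $p_{out}=0.02$) the
planted partition is recovered exactly.

Units that survive no screened edge enter the result as singletons; summary
statistics (and the survey-style headline counts) consider non-singleton
clusters.
The mean intra-cluster ANI is the arithmetic mean over *stored* member-pair
edges — member pairs the estimator produced no edge for are excluded rather
than imputed, and a multi-member cluster with no stored edge at all is
flagged instead of averaged. (An alternative per-genome weighting would be
defensible; the pairwise-edge mean is the recorded choice.)

Geographic classification is hierarchical: `inter_field` when members span
two or more vent fields, else `intra_field` when they span two or more
sites of one field, else `endemic_site`; `cross_habitat` flags clusters
mixing plume and deposit members.

## Protein sharing

All-vs-all protein similarity uses exact local alignment (BLOSUM62, gap
open 10, extend 0.5). An edge requires aligned-column identity ≥ 0.75 and
coverage ≥ 0.80 of *both* partners (aligned span over sequence length —
the bidirectional "cov-mode 0" convention). Identity over aligned columns,
rather than over full length, is the recorded reading of the 75% threshold.
Exact pairwise alignment is quadratic and intended for desk-scale inputs
(up to ~10⁴ proteins); the thresholds and the clustering rule, not search
heuristics, are the content here.

Greedy set-cover clustering repeatedly selects the unclustered protein with
the most unclustered neighbors (ties broken by lexicographically smallest
`protein_id`) and absorbs those neighbors as one cluster; isolated proteins
become singletons. The result is a deterministic partition.

Sharing statistics: a cluster is shared by a site group iff it has at least
one member from every site of the group, and

$$\mathrm{percent\_shared}(G) = \frac{\#\text{shared clusters}}
{\min_{s \in G} \#\text{clusters containing } s} \times 100,$$

undefined (flagged, not fabricated) when a site has no clusters.
Annotation resolution picks, per protein, the hit with the highest bit
score, then lowest e-value, then highest viral score; PHROG-style tables
are first filtered to coverage ≥ 0.80 and identity ≥ 0.75 and then resolved
by smallest e-value with bit score as tie-break. Normalized annotation
matrices divide per-site category counts by the site's total annotated,
clustered proteins, so rows sum to 1 wherever any annotation exists; the
label→category map is user-supplied, with a small default table of common
phage labels shipped as `inst/extdata/function_categories.tsv`.

## Detection and relative abundance

Covered-fraction detection consumes the mapper's per-sample covered
fractions (read alignment itself is out of scope): a unit is detected in a
sample when its genome is ≥ 3,000 bp and its covered fraction is ≥ 0.70,
both thresholds inclusive to match their "≥" definitions. N-spacer
positions of linked vMAGs are excluded from the covered-fraction
denominator by the upstream convention this package assumes (and by its own
simulator). Self-detections are flagged, not dropped, and the sharing
summary counts non-self events by field pair and by habitat relation, with
plume↔deposit crossings reported separately. Relative abundance is mapped
reads over the sample's total reads; detections are monotone non-increasing
in the covered-fraction threshold by construction, and at threshold 0
detection reduces to "any mapped coverage at all" for ≥ 3 kb units.

## Host ecology and proportionality

Host-genome contamination screening takes the strictest reading of "100%
identity and 100% coverage": an exact substring match of the full viral
sequence, checked on both strands (a nucleotide search is strand-agnostic,
so the reverse complement must count). Anything less — even one
substitution — is not contamination under this rule.

Virus abundance is aggregated by predicted host at a chosen taxon rank
parsed from GTDB-style lineage strings. A multi-host virus contributes its
full count to each matching group by default (mirroring per-group
read-mapping sums); an even `1/n` split is available by flag. Units without
the requested rank are skipped with a warning.

Congruence between a host group and "viruses infecting" that group is
quantified with the proportionality metric on clr-transformed per-sample
series:

$$\rho_p = 1 - \frac{\mathrm{var}(a_x - a_y)}
{\mathrm{var}(a_x) + \mathrm{var}(a_y)},
\qquad a = \mathrm{clr}(\text{counts} + \text{pseudocount}),$$

which is symmetric, bounded in $[-1,1]$, and equals
$2\,\mathrm{cov}(a_x,a_y)/(\mathrm{var}(a_x)+\mathrm{var}(a_y))$. Two open
choices are surfaced as parameters rather than guessed:

* **Composition.** The clr needs the whole composition. By default the
  composition is the supplied group series; passing the sample table appends
  a **remainder** component (total reads minus the summed groups, floored at
  zero), preserving closure over everything else mapped in the sample.
* **Zeros.** A pseudocount (default 0.5, the standard half-count) is added
  before the log; it is recorded in the output.

Two numerical caveats are worth knowing. First, with few components the clr
closure itself induces correlation between components — in particular,
comparing a *coupled* virus group against a different host group inherits a
noticeable negative bias, so the package's uncoupled control in the
synthetic tests is a group whose virus counts are drawn independently
(coupling 0), for which the induced term nearly cancels. Second,
$\hat\rho_p$ over 50 samples has a sampling spread of roughly ±0.14 for
uncoupled pairs, which is why the test suite fixes seeds and asserts
$|\hat\rho_p| < 0.3$ rather than a point value.

## Reporting

`build_report()` closes the accounting: complementary pairs are derived
when one member is missing (units = bins + unbinned; units = lytic +
lysogenic; host-assigned = single-host + multi-host), identities are
checked and violations reported as flags, and percentages are rounded
half-even at one decimal — the convention that makes printed-value checks
reproducible (e.g. `percent_of(19572, 63826)` is 30.7 and
`percent_of(40645, 84259)` is 48.2).

## The synthetic community generator

`simulate_community()` exists so every downstream stage has ground truth.
It emulates, with one sample per site:

* **Survey structure** — `n_fields` vent fields × `sites_per_field` sites;
  habitats drawn with probabilities 0.2 / 0.75 / 0.05 for plume / deposit /
  diffuse, mirroring a deposit-dominated survey with a minority of plumes
  and rare diffuse-flow samples; per-sample depths uniform on 2–8 million
  reads.
* **Planted relatedness** — each planted cluster is a *pair* of genomes
  (most real nucleotide clusters are pairs) mutated independently from a
  common ancestor at `divergence/2` per copy, so the expected pairwise
  divergence is `divergence` and the expected pairwise ANI is
  $(1-\mathrm{divergence})\times 100$. Substitutions only, no indels: this
  keeps true ANI analytically known and gives the estimator an exact
  oracle. Member sites are allocated by greatest remaining capacity with
  lexicographic tie-breaks, so feasibility depends only on total capacity
  and an infeasible request errors out. The divergence default is 0.05
  (~95% ANI), comfortably inside the 70–99% band such surveys observe; the
  cap of 0.30 keeps planted pairs above the 70% screen. Remaining genomes
  are endemic singletons of uniform random sequence — unrelated random
  genomes share essentially no 15-mers, so they cannot leak into clusters.
* **Lifestyles** — Bernoulli(`lysogenic_fraction`), default 0.05,
  reflecting the strong lytic dominance such surveys report.
* **Genome lengths** — uniform on `genome_length_range`, default 3–50 kb,
  the range the ≥ 3 kb clustering operates on.
* **Protein families** — each unit carries 3–6 private random proteins
  (100–300 aa) plus, with probability `shared_protein_family_fraction`, a
  copy of each of `n_core_protein_families` shared core families at 2%
  amino-acid divergence — ground truth for shared-cluster statistics.
* **Counts and detection** — `simulate_counts()` gives each unit a high
  covered fraction (0.9–1) and lognormal counts in its origin sample,
  "detects" planted-cluster members in their co-members' samples (0.8–1),
  and leaves other cells below 0.3 coverage with mostly zero counts.
  Host-coupled groups get per-sample host counts drawn lognormally and
  virus counts `coupling × host × exp(N(0, noise_sd))` split across the
  group's units; coupling 0 marks an uncoupled control. Per-sample sums are
  capped at the sample's depth, so the mapped-count marginal can never
  exceed it.

Everything derives from one integer seed, and identical configs produce
byte-identical artifacts.

**What passing tests on this generator do and do not show.** The generator
plants clean signals: substitution-only divergence (no indels, no
recombination, no mosaicism), sharp cluster boundaries, noise-free
membership truth, and idealized covered fractions. Real data add assembly
fragmentation, chimeras, strain mixtures, uneven coverage, and ambiguous
boundaries; recovery rates on synthetic communities are therefore upper
bounds on, not estimates of, real-data performance. Conversely, the
arithmetic layers (screening rules, normalization, sharing formulas,
accounting identities) are input-agnostic and transfer exactly. Headline
figures from any particular survey (cluster counts in the hundreds,
$\rho_p$ values like 0.90/0.67) depend on that survey's reads and are
deliberately not reproduction targets here.

## Problem sizes and test design

The shipped tests and the acceptance script run at desk scale, chosen so
signal is unambiguous while a full run stays fast: 10 kb genomes for
estimator checks (10 replicates × 4 substitution rates), 30-node graphs for
MCL recovery (50 planted-partition graphs), an 80-genome two-field
community (3 planted inter-field + 3 intra-field pairs at 8% divergence,
5–15 kb genomes) for end-to-end endemism, a 4-unit 2-site community with
all core families planted for protein-family recovery, and a 50-sample
community with couplings at noise 0.05/0.2/0.5 plus an uncoupled control
for proportionality. All randomness in tests is seed-fixed; derived
expectations were computed with independent oracles (global alignment
identity, BFS components, literal clr/variance formulas, hand simulation of
the greedy rule) before being frozen into assertions.

## Known limitations

* The ANI estimator assumes collinear genomes; large rearrangements would
  fragment anchoring and depress AF (appropriately, but this is untested
  against rearranged truth). Anchor windows that span an N spacer in the
  *target* genome treat spacer positions as mismatches-to-`A`, a slight
  identity distortion only possible in edge-spanning windows.
* Exact protein alignment is quadratic; very large protein sets need an
  external prefilter before `protein_similarity()`.
* MCL is dense-matrix and comfortable to a few thousand nodes; the
  screened ANI graphs of desk-scale datasets are far below that.
* The contamination screen's exact-match rule is intentionally strict; it
  will not flag near-identical (e.g. 99.9%) insertions.
* Lifestyle inference, host prediction, annotation searches, and read
  mapping are consumed, never computed; garbage in upstream tables passes
  through with only structural validation.
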