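---
title: "Methods: cross-tissue transcriptomic triage of druggable targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-tissue transcriptomic triage of druggable targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`targettriage` implements an in-silico prioritization chain for studies that
profile the same disease in two tissue compartments (for example lesional
skin and peripheral blood in chronic cutaneous lupus) and want to converge on
a small set of druggable candidate genes. This vignette documents the models,
their assumptions, the tunable parameters, and the design choices made where
the design was genuinely open. Every empirical statement here is one that the
test suite computes; nothing is quoted from external results.

## The statistical chain

### 1. Differential expression (`call_degs`)

Each gene is tested between two groups of log2 intensities with Welch's
unequal-variance two-sample t-test. The test choice is a design decision: for
tiny group sizes (5 vs 5 is the default design) and per-gene variances that
cannot be assumed equal, Welch is the robust textbook default, and the
vectorized implementation is cross-checked in the tests against `stats::t.test`
to 1e-6. Moderated-variance (empirical Bayes) testing is deliberately out of
scope: the pipeline's first gate is meant to be permissive and transparent.

Fold change uses the signed-ratio convention common in microarray tables:
with `d` the difference of group means on the log2 scale, `fc = 2^d` when
`d >= 0` and `-(2^-d)` otherwise, so halving of expression prints as `-2` and
no value lies strictly between -1 and 1.

The default gates are `p <= 0.05` and `|fc| >= 1.1`, both *closed*
thresholds, with **no multiple-testing correction**. This is intentional and
mirrors the two-stage logic of the study design the package emulates: a low
first hurdle keeps a large pool of weak signals, and stringency is applied
downstream by the positional and interactome statistics, which are the ones
that must survive chance. Probes mapping to one symbol are collapsed to the
record with the smallest p (ties: larger |fc|, then first probe id) — a
deterministic rule that favors the strongest signal.

### 2. Cross-tissue overlap (`overlap_profiles`)

The two tissue DEG lists are intersected on canonical (uppercase) gene
symbols and the intersection is partitioned into direction-concordant and
discordant subsets. Symbols, not probes, are the join key throughout the
package; alias resolution is out of scope, so symbol drift between inputs is
the user's responsibility.

### 3. Chromosomal hot spots (`scan_hotspots`)

The scan asks whether DEGs cluster along the gene order of a chromosome more
than a random scatter over the platform would allow. The null model is
hypergeometric: a stretch of `w` consecutive genes drawn from a platform of
`G` genes carrying `K` DEGs contains `X ~ Hypergeometric(G, K, w)` DEGs, and
a stretch is significant when `P(X >= k) <= 0.001` and `k >= 5` (closed
gates, no multiplicity correction — the fixed 0.001 gate *is* the family
control in this design).

Two implementation points matter:

* **Candidate pruning.** Only stretches whose first and last genes are DEGs
  are evaluated. This is loss-free: trimming any window to its outermost
  DEGs keeps `k` and shrinks `w`, which can only decrease the tail
  probability, so every significant window is represented by a significant
  DEG-endpoint run. The tests verify this against a brute-force scan of all
  O(G^2) windows.
* **Merging.** Overlapping or book-ended (gene-adjacent) significant runs
  merge into one maximal hot spot, which reports the minimum constituent
  window's `(w, k, p)`. Strand is read and stored but ignored: both strands
  share one positional order.

Cross-tissue hot-spot overlap is a base-pair intersection of spans on the
same chromosome under half-open semantics (`[100,200)` does not touch
`[200,300)`), with the shared DEG symbols reported per overlapping pair.

The original analysis tool behind this idea (dCHIP's "genome" feature) does
not disclose its stretch definition or null, so reproduced hot-spot
coordinates are not expected to match any particular historical output; the
hypergeometric draw from the platform universe is the standard
proximity-analysis null and is what this package documents and tests.

### 4. Interactome over-connectivity (`connectivity_stats`)

For a focal gene with `R` neighbors among `N` background genes, and an
experimental set of `n` genes, the number of neighbors falling in the
experimental set under random membership is `X ~ Hypergeometric(N, R, n)`.
The module reports the full record — `Actual`, `n`, `R`, `N`,
`Expected = nR/N`, `Ratio = Actual/Expected`, `z = (Actual - Expected)/sd`,
and the upper-tail `p` — so the evidence behind a call is always visible.

Conventions that the upstream literature leaves ambiguous are fixed here and
documented rather than inferred:

* the focal gene is excluded from its own `n` and `N` (no self-counting);
* neighbors are the union of in- and out-neighbors; direction and effect
  sign are retained for display but ignored for counting;
* self-loops never count toward degree;
* the background is explicit (network nodes restricted to the expression
  platform), so `N` is logged, not hidden inside a proprietary metabase.

"Shared over-connected" genes are those significant against **both** tissue
DEG sets. One-step expansion (`expand_network`) augments a seed set with
every node one directed edge away in either direction and induces the
subnetwork; hubs are ranked by distinct-neighbor degree, which makes the
handshake identity hold exactly and is tested on random graphs.

### 5. Gene-set over-representation (`enrich`)

One-sided hypergeometric tests against a user-supplied GMT collection,
conditioned on the platform universe (not the genome — the DEGs were drawn
from the array, so conditioning on the array is the correct null), with
Benjamini–Hochberg adjustment across tested sets. The EASE-style score
modification used by some public tools is intentionally not replicated.

### 6. qPCR relative quantification (`qpcr_fold_changes`)

Technical replicates are averaged on the Ct scale; `dCt` subtracts the
housekeeping gene (default ACTB) per sample; `ddCt` subtracts one control
reference sample, whose relative expression is therefore exactly 1; relative
expression is `2^-ddCt`. Group means and standard errors are presented on
the `2^-ddCt` scale (matching how such tables are usually printed), but the
case-vs-control test runs on the `dCt` scale, where Ct noise is
approximately additive and a location test is well calibrated. Global
per-sample Ct shifts cancel exactly, and the group p-value is invariant to
the reference choice — both are asserted as identities in the tests.
Amplification-efficiency correction is out of scope.

### 7. Multi-criterion triage (`score_candidates`)

Seven boolean criteria per candidate: (a) DEG in both tissues, (b) qPCR
direction concordant with the microarray (a sign comparison, deliberately
without a significance gate — expression trends count as confirmation),
(c) member of at least one enriched set at BH `q <= 0.05`, (d) over-connected
against both DEG sets at `p <= 0.05`, (e) hub (top decile of degree in the
expanded subnetwork — no published cutoff exists, so the decile is a
configurable default), (f) inside an overlapping cross-tissue hot spot, and
(g) carrying at least one drug link. The score-and-rank formalization
(score = criteria count; ties broken by mean over-connectivity z, then
symbol) is this package's addition: the source style of analysis applies the
criteria as a narrative checklist, and turning it into a total order is what
makes the procedure testable. Evidence channels that are not supplied
evaluate to FALSE and are flagged as not evaluated — absence of evidence
never silently passes a criterion. Receptor filtering requires the
conjunction *receptor class AND membrane-localized*, since the rationale is
accessibility of the extracellular domain to drugs.

## The synthetic world

The generators state one world and the tests live in it:

* expression: two groups of 5 samples, baselines uniform on log2 4–12,
  planted effects of 1 log2 unit (half up, half down), Gaussian noise
  sd 0.25 — a deliberately idealized microarray error model with no batch
  or probe-level artifacts;
* genome maps: evenly spaced non-overlapping genes (10 kb spacing), planted
  clusters placing k DEGs inside a window of consecutive ordinals;
* networks: Erdős–Rényi background of mean degree 10 with planted hubs wired
  into the experimental set; directions and signs random (cosmetic for the
  statistics, but they exercise the readers);
* qPCR: constant housekeeping Ct, targets shifted by `log2(fc)` cycles in
  cases, technical duplicates, Ct noise sd 0.3, 5 + 5 biological replicates.

A green test therefore establishes that the statistics recover what they
claim *under this stated world* — calibrated nulls, >= 95% planted-signal
recovery, exact small-universe agreement with enumeration oracles. It does
not establish anything about normalization, probe annotation, network
curation quality, or any other upstream step that real data would add.

The integration bundle (`simulate_bundle`) plants one gene that satisfies
all seven criteria — DEG in both tissues, inside a contiguous 7-gene
positional cluster shared by both profiles, wired as a hub into both DEG
sets, member of the loaded gene set, qPCR-concordant, membrane receptor with
drug links — among ~50 common DEGs that satisfy subsets. The cluster is
contiguous (7 DEGs in 7 consecutive genes) so that its scan p-value stays
well below the 0.001 gate even if the DEG caller drops a member or two.

## Numerical choices and degenerate inputs

* Hypergeometric tails come from `stats::phyper(k - 1, ..., lower.tail =
  FALSE)`; enumeration oracles in the tests confirm 1e-12 agreement on small
  universes and 20,000-draw permutation nulls confirm 3-SE agreement on a
  500-node background.
* Welch's test with zero variance in both groups returns `p = 1` when means
  are equal (null by convention) and `p = 0` otherwise.
* `z` is 0 when the hypergeometric sd is 0 and `Actual == Expected`;
  `Ratio` is NA (flagged undefined) when `Expected = 0`.
* An empty experimental set yields the degenerate record `Actual = 0, p = 1`.
* Ties are always broken deterministically (documented per function), so
  identical configurations produce byte-identical outputs; the pipeline
  itself draws no random numbers.

## Configuration and provenance

`run_pipeline()` takes a single JSON configuration (JSON rather than YAML
because the deployment environment guarantees a JSON parser); every
threshold defaults to the printed-gate values (0.05, 1.1, 5, 0.001, 0.05,
0.05, 0.9) and the effective values are echoed into `run_summary.json`
together with the count at every gate, so a run is auditable from its output
directory alone.

## Known limitations

* Headline counts from the motivating study (numbers of DEGs, hot spots and
  over-connected genes in the real lupus data) are not reproduction targets:
  they depend on raw deposited microarray data, a proprietary interactome
  and an undisclosed positional null, none of which ship here.
* The DEG module is unpaired-only; site-matched designs would need a paired
  test.
* Symbol-level joins assume consistent annotation across all inputs.
* The enrichment module tests over-representation only and does not
  propagate ontology graphs.
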