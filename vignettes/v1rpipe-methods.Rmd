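---
title: "Methods and design choices in v1rpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in v1rpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`v1rpipe` reimplements, as a tested pipeline, a three-part analysis of
vomeronasal type-1 receptor (V1R) gene-family evolution: repertoire
mining from genome assemblies, phylogenetically independent contrasts of
repertoire size against a binary lifestyle, and two-population genetics
of sequenced receptor loci. This vignette records the models, the
tunable parameters and their defaults, the numerical choices, and what
the synthetic generators do and do not emulate. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## 1. Repertoire mining

**Search model.** Each query protein is aligned locally (Smith–Waterman
via `Biostrings::pairwiseAlignment`) against all six translation frames
of every scaffold with BLOSUM62 and affine gap costs 11 (open) + 1
(extend) — the scoring system of protein–translated-DNA BLAST.
Significance uses the Karlin–Altschul formula
`E = K·m·n·exp(−λ·S)` with the standard gapped-BLOSUM62 constants
λ = 0.267, K = 0.041, query length `m` in residues and effective
database size `n` = total genome length × 2 strands / 3. The default
cutoff is `1e-5`. Multiple genes per frame are recovered by masking each
reported alignment with `*` and re-aligning. The engine is validated
against a brute-force Gotoh implementation in the test helpers; the
production path for large genomes is `read_blast_tab()`, which imports
the standard 12-column tabular format and feeds the identical
downstream pipeline (a cross-check test asserts identical candidates).

**Hit processing.** Hits spanning < 300 nt are discarded. Same-scaffold,
same-strand hits overlapping or within 50 nt merge into one locus
(union span; best e-value retained). The merge distance and the 3000-nt
extension window are configuration parameters; V1Rs are single-exon
genes of roughly 1 kb, so a small window suffices. Because the reverse
complement of a hydrophobic-rich ORF is often itself hydrophobic-rich,
weak antisense hits can appear over a real gene; overlapping
opposite-strand loci are therefore resolved greedily by e-value (one
candidate per genomic locus) before extension.

**ORF extension.** Extension is anchored on the best-evidence hit of
each locus rather than the merged union, because weaker overlapping hits
from other family members can overshoot the true gene ends. Walking
in-frame: upstream, the nearest in-frame stop codon (or scaffold edge or
assembly gap, a run of ≥ 10 `N`) bounds the search, and the first `ATG`
after that bound becomes the putative start — this generalizes
"nearest ATG upstream" to the common case where a local alignment
overshoots the true start by a few residues. Downstream from the locus
end, the first in-frame stop codon closes the ORF. In-frame stops inside
the resulting span are recorded as nonsense disruptions; differing
reading frames among a locus' merged hits are recorded as a frameshift.
Truncation causes (`scaffold_edge`, `assembly_gap`) are kept separate
from disruptions because they drive the partial-gene category.

**Classification.** *Intact*: ≥ 270 coding codons (the stop codon does
not count — the boundary is fixed and configurable), start and stop
present, no disruption, and exactly 7 predicted TM helices. *Partial*:
undisrupted, > 300 nt, exactly one of start/stop, and a truncation
cause — partial genes are not TM-checked (only full-length candidates
are). *Pseudogene*: > 300 nt with ≥ 1 disruption. Complete undisrupted
ORFs shorter than 270 codons, or full-length ORFs failing the 7-TM
check, fall into an explicit *short_complete* bucket rather than being
forced into pseudogene: the three published rules do not cover this
case, and silently re-labelling it would bias repertoire counts.
Remaining candidates (≤ 300 nt and not intact) are dropped.

**TM prediction.** The stand-in predictor is Kyte–Doolittle hydropathy
with window 19 and threshold 1.6; overlapping above-threshold windows
merge into helices reported at 19–25 residues (longer regions are
trimmed around their best window). This is deliberately simple — it is
calibrated on the synthetic constructs (designed with seven 22-residue
hydrophobic stretches) and is not a substitute for TMHMM/HMMTOP on real
proteins; `parse_topology_string()` accepts external per-residue
topologies for that purpose.

**Identity and naming.** A candidate is accepted only if its best local
alignment against a labelled reference panel (targets plus decoy GPCRs)
is a target with raw score ≥ 60; accepted candidates are named
`<best reference>-<ordinal>` in genomic order, mirroring best-hit-based
nomenclature.

## 2. Independent contrasts

The dated tree is built from a labelled topology and a node-age table
(branch length = parent age − child age; non-positive lengths are
errors). Contrasts follow Felsenstein's pruning algorithm exactly; the
implementation is validated against `ape::pic` to 1e-10 on random
trees. The binary lifestyle code (0 subterranean, 1 superterranean) is
treated as a continuous trait, as in the original analysis; no
threshold model is fitted. The headline statistic is Spearman's ρ of
the two contrast sets with a two-tailed t-approximation p (mid-ranks on
ties); an exhaustive permutation p is available for n ≤ 10 behind
`exact = TRUE` (factorial runtime). A through-origin least-squares
slope is reported as a secondary, unvalidated summary, since contrasts
have no intercept by construction — the published analysis reports only
ρ, so ρ is the only validated output. Polytomies are rejected rather
than resolved with zero-length branches (the intended tree is binary).
Near-constant inputs (range below 1e-10 relative) are rejected as
zero-variance rather than ranked, so a constant repertoire errors out
instead of returning rounding noise.

## 3. Population genetics

**Missing data.** Complete deletion: any column containing `N` or `-`
is excluded from the effective length and every statistic, matching the
common default of alignment-based popgen software. Diploid individuals
contribute two allele sequences (16 + 13 animals give n = 32/26).

**Diversity and neutrality.** π is the mean pairwise difference per
included site; θ_w = S/a₁ per site. Tajima's D uses the 1989 constants
(a₁, a₂, b₁, b₂, c₁, c₂, e₁, e₂); D is undefined and flagged when
S = 0, and sign(D) = sign(π·L_eff − S/a₁) is asserted as an invariant.
Fu & Li's D* uses the corrected no-outgroup formulation with constants
c_n, d_n, u_D*, v_D* and singletons defined observationally (a base
carried by exactly one allele, i.e. frequency classes 1 and n−1 in the
simulated null). There is no pre-installed independent D*
implementation in the test environment; the frozen expected values come
from an independently written transcription of the published constants,
plus sign-structure and null-calibration tests.

**Coalescent significance.** The null for both statistics is the
standard neutral coalescent for n alleles conditioned on the observed S
(mutations multinomial on total branch length — the conditioning used
by the "10,000 replicates" workflow), not on θ. The two-tailed p is
`2·min(P(sim ≤ obs), P(sim ≥ obs))` capped at 1. Both statistics share
one simulated genealogy set per locus. Under seeded neutral data the
measured type-I error at α = 0.05 is asserted to lie in 5% ± 2%; the
conditional-on-S null has a small negative mean for D (about −0.08 at
n = 16), which is expected for the statistic and does not distort the
rejection rate.

**Differentiation.** F_ST is Hudson/Slatkin/Maddison `1 − H_w/H_b` with
the two populations weighted equally in H_w — this estimator choice is
the single largest reproduction risk against published per-locus values
and is therefore pinned here. F_ST is undefined (flagged, not zero)
when a locus has no polymorphism, and also when H_b = 0. S_nn follows
Hudson (2000): per sequence, the fraction of nearest neighbours
(minimum distance, ties split fractionally) in the same population,
averaged; significance is by size-preserving label permutation,
one-tailed by the statistic's definition. The permutation p includes
the identity permutation — `(1 + #{perm ≥ obs})/(reps + 1)` — so it is
strictly positive and exact-valid. Locus-level Snn p-values are
BH-adjusted separately within the receptor family and the noncoding
family.

**Per-SNP tests.** SNPs are biallelic included columns
(multi-allelic columns are flagged and skipped); the reference allele
is the overall major allele. Coding effects translate the reference and
alternate codons in the consensus context; stop-gains are flagged
separately since they would contradict intact status. Fisher's exact
test uses allele-count (2N) tables — the comparison is of allele
frequencies — with the point-probability two-tailed rule (all tables
with point probability ≤ observed, within 1e-7 relative), which matches
`stats::fisher.test` and is asserted against it over table sweeps. The
FDR family pools all nonsynonymous SNPs across loci by default; a
per-locus family is available because the published description is
ambiguous on this point. Topology mapping uses the GPCR convention of
an extracellular N-terminus: with seven helices the flanking segments
are N-term, ICL1–3/ECL1–3 alternating, C-term; with any other count the
stand-in labels outside/TM/inside are used. Ligand-binding-site
inference is out of scope.

**Cross-locus summaries.** The per-locus π of the two populations is
compared by a paired two-tailed t-test; receptor vs noncoding π by a
Mann–Whitney U (normal approximation with tie correction; exact for
combined n ≤ 20 without ties); fractions of significant loci by the
same Fisher test as above. The four published Fisher p-values for
significant-D fractions (0.23, 1, 0.16, 0.65) are not reproducible from
the printed counts under the standard two-tailed definition (e.g. 3/18
vs 0/22 gives 0.0855); they are excluded from acceptance and not
asserted.

## 4. Synthetic data: the stated world

`simulate_genome()` implants back-translated copies (uniform synonymous
codon choice) of a deterministic synthetic V1R-like panel — 318-residue
proteins with seven 22-residue hydrophobic stretches, so the bundled TM
predictor finds exactly 7 helices — into uniform random background, at
least 2 kb apart, on both strands, across ≥ 2 scaffolds. Partial genes
lose their first 60 residues and are truncated alternately by a
scaffold edge (placed at position 0) or a 15-N assembly gap; pseudogenes
receive alternately a premature mid-gene stop or a 1-nt mid-gene
deletion (placed mid-gene so both flanks exceed the 300-bp hit filter);
decoys are unrelated proteins with the same TM architecture, which
tests that identity confirmation — not the TM count — rejects them. The
generator does **not** emulate repeats, GC structure, paralog clusters,
alternative codon usage or sequencing error, so a green truth-table
test establishes correctness of the classification logic, not
performance on real assemblies.

`simulate_bm_traits()` is exact Brownian motion (Normal increments,
variance σ²·branch length) with an optional additive lifestyle shift on
coded tips; contrasts of its output are asserted Normal(0, σ²) by
Shapiro–Wilk at α = 0.01 and a 10% variance band. `simulate_two_pop()`
is a structured coalescent with a clean split at `split_time` (units of
2N generations), no migration, equal deme sizes, and infinite-sites
mutations at rate θ/2 per lineage per unit time mapped to distinct
columns; `split_time = 0` is exact panmixia (used for all null
calibrations), and large splits drive F_ST towards 1. Sample sizes in
the examples mirror the study design (16 + 13 diploid animals); the
calibration defaults (θ = 4–6, L = 400–900) are ordinary values for
~1-kb nuclear loci.

## 5. Numerical and testing choices

* All Monte-Carlo routines take a `seed` and restore the caller's RNG
  state; generators are pure functions of seed and parameters
  (byte-identical reruns are asserted).
* Type-I calibrations in the acceptance suite run at 1000 loci
  (Tajima-D, with the null distribution cached per (n, S)) and 400
  replicates × 199 permutations (S_nn) to fit the stated 5-minute
  budget on one CPU; the 5% ± 2% acceptance band is unchanged by this
  scaling.
* The exhaustive Fisher-vs-oracle property runs the full 7⁴ grid of
  small tables plus 200 random tables with n ≤ 40, rather than every
  table with n ≤ 40, to keep the suite fast; tolerance 1e-9.
* Coordinates are 0-based half-open internally and 1-based inclusive in
  GFF3 output.
* Configuration is serialized as YAML into every output directory, so
  any run can be reproduced from its artifacts alone.

## 6. Known limitations

* The built-in search engine is quadratic per (query, frame) and meant
  for desk-scale genomes (≤ a few hundred kb); real assemblies should
  use the external tabular import path.
* The hydropathy TM predictor is a calibrated stand-in; real-data
  topology should come from TMHMM/HMMTOP via the adapter.
* Antisense-overlap resolution assumes receptor genes do not truly
  overlap on opposite strands, which holds for the synthetic world and
  for typical V1R clusters but is not guaranteed in general.
* The coalescent null ignores recombination and population structure
  within each population; published significance obtained under the
  same assumptions is comparable, but both share the assumption.
* Supplementary-table and accession-gated published values (the
  24-taxon contrast inputs; the deposited mole-rat alleles and the
  S. galili assembly) cannot be recomputed offline; the corresponding
  code paths are validated on synthetic data only.
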