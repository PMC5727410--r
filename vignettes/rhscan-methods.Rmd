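---
title: "Methods: detecting and comparing T6SS-associated Rhs toxin repertoires"
author: "rhscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and comparing T6SS-associated Rhs toxin repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhscan)
```

## The biological model

Rhs ("rearrangement hotspot") proteins are polymorphic toxins delivered by
type VI secretion systems (T6SS) in Gram-negative bacteria, prominently in
bee gut symbionts such as *Snodgrassella alvi*, where large Rhs repertoires
appear to mediate competition between strains sharing a host gut. An Rhs
protein has a conserved N-terminal region — a PAAR motif that docks the
protein onto the VgrG spike, plus a YD-repeat-rich core — and a
hypervariable C-terminal toxin domain. A conserved amino-acid motif of the
form DPXG-x18-DPXG sits at the end of the core; the toxin domain starts
immediately after it. A small immunity gene, whose product neutralises the
cognate toxin, lies immediately downstream of each intact toxin.

Under the *C-terminal displacement* model, recombination between conserved
cores swaps toxin domains in and out of expression-competent positions.
This leaves loci with a characteristic architecture that the package
detects and classifies: a large *lead* gene (PAAR + full core) at the 5'
end of each locus, followed by shorter *orphan* toxin genes (truncated
N-termini, no PAAR) with their immunity genes, occasionally a *toxinless*
core fragment at the 3' end, plus *pseudogenes* (nonsense-interrupted
copies) and *orphan immunity* genes whose toxin has been lost.

The package implements the full comparative workflow around this model:
ORF and Rhs-gene detection, core/toxin splitting at the motif,
toxin–immunity pairing, identity-threshold clustering of toxin domains
with a strain-by-toxin co-occurrence network, presence/absence screening
of T6SS loci and toxin/immunity pairs, and the supporting statistics (TPM,
rank correlation, ANOVA/Tukey, dN/dS, distance trees and Robinson–Foulds
congruence).

## The synthetic-data generator

Every stage is validated against simulated genomes with complete ground
truth (`simulation_config()` + `simulate_strains()`). The generator
implements the C-terminal displacement world directly:

* A pool of `pool_size` (default 50) toxin-domain *prototypes*, 120–900 nt
  of random coding sequence. Prototypes are redrawn until all pairwise
  identities fall below `cluster_threshold - separability_margin`
  (default 0.90 − 0.05), verified by alignment, so the planted cluster
  structure is recoverable by construction. Each prototype has a cognate
  immunity prototype (300–450 nt).
* A root genome layout: housekeeping marker genes, two 13-gene T6SS marker
  blocks, and three Rhs loci per strain (matching the three-locus,
  ~6-genes-per-locus architecture reported for the *S. alvi* type strain),
  each a lead gene followed by 3–5 orphans, each toxin followed by its
  immunity gene 30 nt downstream ("immediately downstream" is not
  quantified in the literature; 30 nt is configurable via `spacer_nt`).
* Evolution along a random bifurcating strain tree: every site mutates
  with probability `per_branch_substitution_rate` (default 0.002) per
  branch. With tree depths of roughly 5–7 branches this keeps copies of
  one prototype within a few percent of each other — comfortably inside
  the 90% clustering threshold — while leaving enough signal per branch
  for neighbour-joining to recover the topology from the ~10-kb marker
  concatenations. The defaults are chosen for testability; real
  within-pool divergences are not quantified in the source data.
* Tip-level events: horizontal import of a different pool domain
  (`p_hgt`, with the cognate immunity gene), toxin loss leaving an orphan
  immunity gene (`p_orphan_immunity`), and pseudogenising nonsense lesions
  (`p_pseudogenize`).

### Exactness devices

Three construction choices make detection ground truth unambiguous, and
are worth knowing when interpreting what passing tests show:

* Intergenic sequence is drawn from {A,C,T}. Without G there are no start
  codons outside genes on the forward strand, so each called ORF begins
  exactly at a planted ATG.
* Every gene is preceded by the 11-mer `TAAATAAATAA`, which places an
  in-frame stop in all three frames immediately upstream of the start
  codon.
* Mutations never touch start/stop codons or the conserved residues of
  the PAAR, YD-repeat and DPXG motifs, and substitutions that would create
  a stop codon are redirected. Prototypes are additionally rejected if
  they contain a PAAR or repeat match, or residues that would complete a
  spurious DPXG window across the motif–domain junction.

Pseudogenising lesions are planted in the 30-codon linker between the last
YD repeat and the DPXG motif. This makes a pseudogene detectable by a
single deterministic rule — an Rhs ORF lacking the motif whose in-frame
extension past its stop codon contains it — mirroring how a truncated Rhs
fragment with a downstream motif-bearing continuation would be read
manually. Lesions in orphaned immunity genes are planted at 72–85% of gene
length, so the fragment still clears the 70%-coverage homology screen
while the frame test flags it, matching the reported observation of
immunity-gene homologs carrying nonsense mutations in the absence of their
toxin.

What the generator deliberately does **not** emulate: sequencing error,
assembly fragmentation and contig-edge gene truncation, indels,
recombination breakpoints inside domains, G+C and codon-usage structure,
and genes overlapping or on opposite strands within a locus (whole loci
can be strand-flipped with `randomize_strand`). Perfect recall/precision
on simulated data therefore demonstrates the correctness of the
*algorithms*, not expected performance on real draft genomes, where the
degenerate motif scans stand in for profile-HMM searches and will be less
sensitive.

## Detection and delimitation

* `find_orfs()` scans all six frames for maximal start(ATG/GTG/TTG)-to-stop
  ORFs, one per stop codon per frame (the longest, i.e. from the first
  start after the previous stop). Coordinates are 1-based inclusive
  (GFF3 convention) on the forward strand.
* `scan_rhs_core()` counts overlapping matches of a degenerate 16-residue
  YD-repeat pattern (`..G..Y.YD..GRL..`); four or more matches (default)
  define an Rhs core. `detect_paar()` uses the `PAAR[PS]` core pattern.
  Both patterns are configurable; they are native stand-ins for the
  profile searches (TIGR03696, PF05488) a practitioner would run on real
  data, and precomputed domain tables can be substituted upstream.
* `locate_dpxg()` finds DPxG + 18 arbitrary residues + DPxG windows. The
  default mode tolerates one mismatch across the six conserved positions
  (D,P,G twice); `stringent` mode tolerates none. The quantitative
  tolerance operationalises an unquantified "more stringent match
  requirement". When several windows qualify, the most C-terminal wins —
  the motif marks the *end* of the core.
* `extract_cterm()` takes the in-frame suffix after the motif as the toxin
  domain ("after" meaning after the last residue of the second tetrad; an
  include-motif variant would shift every boundary by 26 residues and is
  deliberately not the default). Domains shorter than 40 nt (default) or
  200 nt (stringent) are dropped at extraction time, before any clustering.
* `assemble_loci()` groups consecutive Rhs genes within 5 kb (`max_gap_nt`;
  "locus" has no standard numeric definition, and the simulated inter-locus
  gaps of 6–8 kb sit well above it) and numbers genes 5'→3' in the
  orientation of the lead gene. `classify_architecture()` labels lead /
  orphan / toxinless / n_truncated / pseudogene; the `n_truncated` rule
  (repeat count below 60% of the locus lead's) is a stand-in for an
  unquantified "truncated N-terminal region" description.

## Pairing and orphan detection

Immunity genes share no sequence signature, so de-novo pairing is purely
positional: the nearest same-strand ORF starting within 200 nt
(`max_intergenic_nt`) downstream of a toxin's stop, not itself an Rhs
gene; ties go to the longer ORF. Co-orientation is assumed. Orphan
detection is homology-based against a reference immunity panel (local
alignment, 70% identity and 70% reference coverage): hits with no intact
toxin immediately upstream are orphans, and each is tested for
pseudogenisation by reading its frame for the homolog's length and looking
for stops before 90% of that length.

## Clustering and the co-occurrence network

Nucleotide identity between domains is defined as identical aligned
positions in the optimal ends-free (semi-global) alignment divided by the
shorter sequence's length (match +1, mismatch −1, linear gap −1 per
position, via `Biostrings::pairwiseAlignment`). The shorter-length
normalisation and greedy longest-first incremental clustering mirror
classic sequence-clustering tool semantics: sequences sorted by length
(ties by id), each joining the first representative at ≥ threshold
(a member at exactly the threshold joins), else founding a new cluster.
Membership is member-vs-representative, not all-pairs, which makes the
partition deterministic, order-invariant and O(n·k). Raw unaligned domain
sequences are clustered; no alignment-trimming step precedes it.

The network is a bipartite strain-by-cluster graph (igraph), edges
weighted by member count, strain nodes carrying species/host/region
labels; `sharing_stats()` summarises within-/between-species sharing and
per-region-pair disjointness.

## Screening

`best_hit()` is a Smith–Waterman local alignment (BLOSUM62, gap open 10 /
extend 1) of a query protein against a genome's ORF proteome; identity is
identities over alignment columns and coverage is the fraction of query
residues inside the aligned region. This replaces a translated
genome-vs-genome search: on ORF-complete genomes the two are equivalent,
and raw identity/coverage floors replace database-size-dependent E-values
because the decision thresholds in this workflow *are* the
identity/coverage cutoffs (50%/50% for T6SS presence, with per-query
overrides such as a 70% identity floor for the most conserved component;
70%/70% for toxin/immunity co-occurrence). A T6SS is called present when
≥ 80% of its core genes are present, partial when some are.
`interlocus_mean_identity()` averages identity × aligned-query-fraction
over genes with any hit above a permissive floor (identity 0.35, coverage
0.35 — chosen so that best local hits between unrelated proteins,
measured on random 150-residue pairs, essentially never qualify, while a
half-conserved homolog does; genes with no qualifying hit are skipped).

## Statistics

* **TPM**: counts/length, column-normalised to 10^6.
* **Spearman**: average-rank ties, two-sided p from the
  t-approximation `t = rho sqrt((n-2)/(1-rho^2))`; implemented for the
  position-vs-expression trend along a locus. Constant input reports NA
  rather than a fabricated value.
* **ANOVA + Tukey HSD**: base R `aov()`/`TukeyHSD()` (Tukey–Kramer for
  unequal n; the studentized-range distribution comes from `ptukey`).
* **dN/dS**: Nei–Gojobori (1986) counting with Jukes–Cantor correction, a
  self-contained surrogate for codon-ML model-0 estimation — adequate for
  the contrasts of interest here (ω below 1 versus near 1), not for
  branch- or site-level inference. Convention: mutations to stop codons
  are excluded from site denominators; pathways through stops are dropped
  when an alternative exists; codon columns with gaps, ambiguity codes or
  stops are skipped. ω is reported as undefined (with a reason) when
  dS = 0, when sequences are identical, or when p ≥ 3/4 saturates the
  correction — never fabricated. A single diverged codon often saturates;
  calibrations therefore run on long alignments.
* **Congruence**: p-distance matrices (gap/N sites excluded pairwise),
  Saitou–Nei neighbour joining (`ape::nj`), and Robinson–Foulds distance
  between unrooted trees (`ape::dist.topo`), as a distance-based surrogate
  for Bayesian/ML tree comparison: RF = 0 across marker sets is the
  vertical-descent signature, RF > 0 flags transfer.

## Validation scale and reproducibility

The package-level validation (test suite and `scripts/acceptance.R`) runs
the full chain on 20 strains with a 50-prototype pool (~100 kb per
genome, ~220 Rhs genes), congruence on ten 10-strain replicates, omega
calibration on 20 replicates of 1000 codons per regime (single-replicate
ω there has a standard deviation near 0.11, so calibration bands are
applied to the mean), ANOVA power on 200 replicates at n = 10 per group
(shift 20, σ = 5), and brute-force oracle comparisons on 100 random
inputs per operation (alignment scores and match counts against
forward/backward DP including all co-optimal alignments; ORF calls
against a plain six-frame scan of 5-kb contigs). Every random draw
derives from a single seed; rerunning any stage with the same
configuration reproduces its outputs byte-identically.

## Known limitations

* Motif scans are exact-pattern surrogates for profile-HMM searches;
  sensitivity on real, diverged genomes will be lower, and the optional
  precomputed-domain-table route should be preferred there.
* Identity is normalised by the shorter sequence, so a nested fragment
  scores 1.0 against its parent; this is intended (truncated domains
  should cluster with their full-length prototype) but means clusters are
  not transitive at the threshold boundary.
* NG86 is a counting method; it underestimates rates at high divergence
  and cannot detect episodic positive selection.
* The immunity-pairing rule is positional; divergently transcribed or
  distant immunity genes would be missed by design.
* Contig-edge effects are not modelled: presence calls on fragmented real
  assemblies can miss genes split across contigs.
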