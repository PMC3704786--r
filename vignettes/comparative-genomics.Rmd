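---
title: "Comparative genomics of multi-replicon bacterial genomes with novocomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative genomics of multi-replicon bacterial genomes with novocomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(novocomp)
```

# Scope

`novocomp` re-implements, as a reusable library, the comparative analysis
typically applied to a small set of related bacterial genomes — the kind of
study used to place *Novosphingobium* isolates taxonomically and to screen
them for niche-adaptation traits. Five analytical stages are covered:

1. **Genome signatures** — strand-symmetrized dinucleotide relative
   abundances ρ\*~XY~ and Karlin's genome dissimilarity δ\*(f,g);
2. **AAI** — average amino acid identity over reciprocal best hits (RBH);
3. **Pan-genome** — ortholog clustering at a conservative identity cutoff
   and partitioning into core, unique-core and singleton clusters, with
   plasmid-origin summaries;
4. **Trait screening** — homology screens for quorum-sensing (LuxI/LuxR)
   and marine-adaptation markers (ectoine cassette, Nqr sodium pump),
   residue-level motif checks (the LuxI Arg24/Phe28/Trp34 triad, the Rieske
   [2Fe-2S] His–Cys spacing), and proteome isoelectric points;
5. **Distance phylogenomics** — Poisson-corrected distances on pre-aligned
   proteins, neighbor joining, and column-bootstrap support.

A sixth, first-class module generates synthetic genomes with exact ground
truth so that every stage is testable without downloading assemblies.

# Models and definitions

## Dinucleotide signature

For a genome sequence *S* (all replicons), counts are accumulated over *S*
and its reverse complement; no counting window spans a replicon junction or
the forward/reverse seam, and windows containing an ambiguous base are
skipped. With symmetrized frequencies $f^*_X$ and $f^*_{XY}$,

$$\rho^*_{XY} = \frac{f^*_{XY}}{f^*_X\,f^*_Y}, \qquad
\delta^*(f,g) = \frac{1000}{16}\sum_{XY}\bigl|\rho^*_f(XY)-\rho^*_g(XY)\bigr|.$$

ρ\* ≈ 1 under base-composition independence. Symmetrization forces
$\rho^*_{XY}=\rho^*_{\widehat{XY}}$ (reverse complement) exactly, and δ\*
is 1/16 of an L1 distance, hence a true metric. Values are reported ×1000,
the conventional scale. A degenerate 0/0 ratio (a base absent from the
genome) is defined as 0 so that δ\*(f,f) = 0 holds on any input.
Representation classes follow the conventional bands (≤ 0.55 extreme
under-representation, (0.55, 0.78] under, (0.78, 1.23] normal,
(1.23, 1.30] over, > 1.30 extreme over); boundary values fall in the lower
class because the defining ranges are strict inequalities.

```{r signature}
g <- GenomeRecord("toy", c(chr = "AATT"), kind = "chromosome")
rhoValues(dinucProfile(g))[c("AA", "AT", "TA")]
```

## AAI

All-vs-all local protein alignment (Smith–Waterman, BLOSUM62, affine gaps
11/1 via `Biostrings::pairwiseAlignment`) in both directions; BLAST-style
E-values come from Karlin–Altschul statistics with the published gapped
BLOSUM62 constants (λ = 0.267, K = 0.041) on the query × database search
space. A raw-score prefilter (`scoreOnly`) precedes full alignment of the
pairs passing the E-value threshold, mirroring a BLASTP protocol. Hits are
kept at ≥ 30% identity, ≥ 70% coverage of the shorter sequence and
E ≤ 1e−6 (all configurable); AAI is the unweighted mean percent identity
over reciprocal best hits, with score ties broken by identity and then
lexicographically, so the result is deterministic and symmetric. Percent
identity is identities over aligned columns, internal gaps included (the
BLAST convention). One-way best-hit averaging is available behind a flag
(`oneWay = TRUE`) because published AAI protocols vary on this point; RBH
is the default.

## Pan-genome

Ortholog clusters are connected components of the cross-genome RBH graph at
65% identity, 70% overlap and E ≤ 1e−10. Overlap is measured against the
**longer** sequence by default — the stricter reading of "70% of the
protein sequence length" — with `overlapDenominator = "shorter"` available.
This is a deliberately simplified take on weighted conservation-of-gene-order
(CGO) orthology tools: gene order is consulted only where raw-score ties
leave a best hit ambiguous, in which case the candidate whose ±3-gene
neighborhood is most consistent with the query's neighborhood wins.
Because the full weighted scoring of those tools is not reproduced,
agreement with their cluster counts on real data is expected to be
approximate, not exact. Connected components can chain transitively; a
`strict = TRUE` mode re-validates all member pairs of multi-member clusters
and re-splits them, as a sensitivity check. Draft genomes without gene
order degrade to score-only tie-breaking with a notice, and plasmid-origin
singleton fractions are only computed for genomes whose replicons are
labelled (complete genomes), never for contig-only drafts.

## Trait screening

Screens keep hits with identity > 30% and E < 1e−6 against small curated
reference sets; an empty result is a meaningful negative (absence of the
Nqr sodium pump is evidence for an alternative osmoadaptation strategy).
The shipped reference sets are **synthetic reconstructions** — sequences
constructed to carry each family's diagnostic features (they are clearly
labelled as such in the manifest), because the original curated sets are
database downloads whose membership is not enumerable offline. Residue
checks are reference-anchored: a candidate synthase is globally aligned to
a designated reference and the residues in the columns of reference
positions 24/28/34 must be R/F/W. The Rieske site is matched as
C-X-H-X(n)-C-X-X-H with n allowed in 13–25, a range bracketing both the
canonical 17-residue spacing of Group II ring-hydroxylating dioxygenases
and the 19-residue variant with margin; the first match is reported and
extra matches are logged. The ectoine cassette is called complete when at
least one hit of each of EctA/EctB/EctC falls within a single 20-kb window
on one replicon. A LuxR "solo" is a LuxR-family hit with no LuxI hit within
±5 genes on its replicon — a homology-based surrogate for domain-signature
filtering; mobile-element flanking analysis is out of scope.

Isoelectric points solve the Henderson–Hasselbalch net-charge balance over
the N-terminus, C-terminus and D/E/C/Y/H/K/R side chains by bisection on
pH ∈ [0, 14] to 0.001. The default pKa table is the EMBOSS set, with an
alternative (`"sillero"`) selectable: published tables shift absolute pI by
up to ~0.2 units, so proteome medians should be compared across tools only
to within that tolerance.

## Distance phylogenomics

The module consumes pre-aligned protein FASTA (alignment and trimming are
external concerns). Distances use pairwise deletion — columns gapped in
either member of a pair are ignored — and the Poisson correction
$d = -\ln(1-p)$; a saturated pair ($p \ge 1$) yields an explicit infinite
distance rather than a silent value. Neighbor joining is Saitou–Nei
(via `ape::nj`) with negative branch estimates clamped to zero afterwards.
Bootstrap resamples alignment columns with replacement under a single
documented seed; supports are mapped onto the full-data NJ tree rather
than onto a majority-rule consensus (available via `consensusTree = TRUE`),
because support-on-best-tree is the more interpretable convention when the
full-data topology is the object of interest.

# The synthetic-data generator

`buildScenario()` emulates the statistical structure the analyses assume:

* **Nucleotide replicons** are first-order Markov chains. The expected
  signature of a chain is analytic — from the stationary distribution π,
  $q(XY)=\pi_X P_{XY}$, symmetrized with its reverse complement — so
  realized ρ\*/δ\* can be checked against exact ground truth
  (`expectedDinucProfile()`).
* **Ortholog families** draw an ancestor from the Robinson–Robinson
  background; each copy is independently substituted at a per-site rate
  solved from the target pairwise identity *t*, including the coincidence
  term for two copies substituting to the same residue:
  $t=(1-m)^2 + c\,m^2$ with replacement residues sampled from a
  BLOSUM62-conditional distribution.
* **Markers** are planted with controlled truth: LuxI-like sequences
  mutated from the reference with the triad protected (or deliberately
  broken), dioxygenase-like proteins with a chosen His–Cys spacing whose
  substitutions never introduce C or H (so the planted site stays the
  unique motif match), colocalized ectABC cassettes, and plasmid-assigned
  singletons.
* **Decoupling**: protein sequences are generated independently of the
  nucleotide replicons (CDS translations are written directly into the
  GenBank features). The signature analyses and the proteome analyses are
  likewise independent, so nothing downstream relies on translational
  consistency, and the two test families do not interact.

Generation is fully deterministic under the mandatory seed. The ground
truth records cluster membership for every protein, marker locations and
parameters, analytic ρ\*, and the *observable* plasmid-singleton fraction —
computed over all genes whose family has a single member genome-wide, since
genome-specific marker genes legitimately become singleton clusters too.

What the generator does **not** emulate: indels within families (members of
a family are equal length, which is also why the pipeline can concatenate
single-copy core families into a gap-free pseudo-alignment for its tree
stage), codon structure or translational consistency between CDS
coordinates and protein sequences, rearrangement/synteny beyond gene order,
horizontal transfer, and base-composition heterogeneity along a replicon.
Passing tests on these genomes therefore demonstrate correctness of the
statistics and of the planted-truth recovery, not performance on real
assemblies, where alignment quality, fragmented drafts and paralog
ambiguity dominate.

## The default study-shaped scenario

`defaultScenario(seed)` mirrors the shape of the motivating six-genome
study: a "marine pair" with near-identical signatures sharing a large
unique core and an ectoine cassette; five LuxI genes across four genomes
(the "epiphyte" carries exactly one); a plasmid-bearing genome whose
plasmid holds half of its declared singletons and which also carries a
LuxR solo; and dioxygenase markers with 17- and 19-residue Rieske spacings.
Problem sizes (10 core families, 6+2 unique-core families, 6 singletons per
genome, ~60-kb replicons, proteins of 120–250 aa) were chosen once as the
smallest configuration in which every stage has non-trivial work — multiple
Venn cells occupied, paralog tie-breaks possible, bootstrap splits
resolvable — while a full pipeline run stays comfortably interactive.

```{r pipeline, eval = FALSE}
sc <- buildScenario(defaultScenario(seed = 1))
res <- runPipeline(sc$genomes, config = pipelineConfig(seed = 1),
                   outputDir = "novocomp_out")
res$traits
```

# Numerical and design choices

* **Signature formulas**: the classic symmetrized-frequency definitions are
  used, since the ×1000 dissimilarity scale and the ρ\* axis conventions
  match that lineage; plasmids are included in per-strain profiles by
  default (`includePlasmids = FALSE` restricts to the chromosome, and both
  GC% variants are reported by `genomeStats()` since either convention
  appears in genome tables).
* **Degenerate bases**: IUPAC codes other than A/C/G/T are treated as N and
  excluded from both numerator and denominator of GC% and from signature
  windows — the statistics are defined over the unambiguous alphabet.
* **Coordinates**: GenBank 1-based inclusive spans are preserved in the
  CDS metadata; gene order indices are 0-based along each replicon.
* **E-value constants**: fixed at the published gapped BLOSUM62 11/1
  values and recorded in the hit tables (`bitscore`, `evalue`), so results
  are reproducible against the recorded parameters.
* **Tie-breaks**: every ranking (best hits, RBH, cluster ids, NJ input
  order) has a deterministic rule, so repeated runs are byte-identical.
* **Bisection tolerance** 0.001 pH: the charge curve is strictly monotone,
  so bisection is guaranteed; tests verify agreement with a dense-grid scan
  at a 1e−4 step.
* **Infeasible inputs fail loudly**: non-stochastic transition matrices,
  layouts whose genes exceed the replicon, all-gap alignment pairs and
  saturated distances are errors, not silent repairs.

# Limitations

* The aligner is exact Smith–Waterman on all pairs (with a score-only
  prefilter); it is intended for the proteome sizes of focused comparisons
  and synthetic studies, not for hundreds of genomes — there is no k-mer
  seeding stage.
* Pan-genome counts on real data are approximate relative to weighted-CGO
  tools, by design (see above).
* The GenBank reader covers the subset of the format the package emits
  (simple and complement spans, locus_tag/translation/pseudo/plasmid
  qualifiers); compound `join()` locations are rejected rather than
  mis-parsed.
* The tree stage requires pre-aligned input (or equal-length core families
  for the built-in concatenation); no alignment or trimming is performed.
* Nucleotide distances are limited to the p-distance
  (`correction = "p"`); protein Poisson correction is the primary mode.
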