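---
title: "Inferring protein-protein binding sites from homologous complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring protein-protein binding sites from homologous complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homsite)
```

## The inference model

Most solved protein structures are deposited without annotation of
which of their surface patches are biological interaction interfaces,
and a query structure of interest typically has no solved complex at
all. `homsite` annotates binding sites on a query protein by
*homology transfer*: the structural location and sequence pattern of a
protein-protein binding site tend to be conserved among close
homologs, so interfaces observed in solved complexes of the query's
homologs are evidence for equivalent interfaces on the query itself. A
single transferred interface may, however, be a lineage-specific
contact or a crystal-lattice artefact; the method therefore pools
*all* transferred sites, clusters the recurring ones, and ranks the
clusters by how conserved and how relevant to the query they are.
Recurrence across non-redundant homologs is the key signal separating
biological interfaces from crystal packing.

The pipeline is:

1. **Observed interfaces.** Within every neighbour complex, a residue
   of one domain is *in contact* with a partner domain when at least
   one of its heavy atoms lies within 4.0 Å (inclusive) of the
   partner's atoms; a domain pair *interacts* when at least one side
   has ≥ 5 contacting residues; the contacting residues of one side
   form a *binding site*. Domains default to whole chains unless a
   domain table is supplied.
2. **Homolog filtering and projection.** Each neighbour chain carries a
   residue-level alignment to the query (supplied, or computed by a
   global Needleman-Wunsch/Gotoh fallback). Neighbours below 30%
   identity (over aligned columns) are dropped; redundant neighbours
   are deliberately *kept*, because the same protein solved with
   different partners contributes distinct interfaces. A binding site
   is projected onto the query through the alignment and retained only
   if ≥ 75% of its residues have a query image. The query's own
   observed interfaces (if it is itself a complex) enter as a neighbour
   at identity 1. Alignments between two neighbours are composed
   *through the query*, never taken directly, so only query-relevant
   columns are compared.
3. **Site similarity.** Two projected sites are compared over the union
   of their query positions. With $\Delta_i = 0$ when either site lacks
   position $i$ and 1 otherwise, the raw score is
   $\sum_i \left[\Delta_i\,(H(a_i,b_i) + \omega) + (1-\Delta_i)\,w\right]$
   with BLOSUM62 $H$, position bonus $\omega = +1$ (residues occupying
   equivalent positions are rewarded even when dissimilar) and gap
   penalty $w = -4$. Raw scores become bit scores via
   $(\lambda\,raw - \ln K)/\ln 2$ and are normalized by the larger of
   the two self bit scores, so identical sites score exactly 1 and
   scores are comparable across interfaces of different size.
4. **Clustering.** Complete-linkage clustering on $d = 1 - S$; the cut
   is chosen by maximizing the pseudo-free-energy functional
   $F = \sum_C \frac{|C|}{N}\bar{s}_C + T \sum_C \frac{|C|}{N}
   \ln\frac{|C|}{N}$, where $\bar{s}_C$ is the mean pairwise similarity
   within cluster $C$ (1 for singletons). The energy-like term rewards
   tight clusters, the entropy-like term (always ≤ 0) penalizes
   fragmenting the description; $T = 0.05$ balances them.
5. **Classification and ranking.** A cluster with more than one
   non-redundant member (redundancy: ≥ 90% sequence identity) is
   *conserved*; otherwise it is a *singleton*, carries no score, and
   ranks at the bottom. Conserved clusters are ranked by the weighted
   sum of four Z-scores computed across conserved clusters:
   Shannon-negentropy conservation of the cluster alignment under
   Henikoff-Henikoff weights, mean interfacial contact count, the
   query's score against the cluster PSSM (profile-average
   construction, $M(p,b) = \sum_a f_w(p,a) H(a,b)$), and mean
   neighbour-query identity over the whole alignment.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `radius` | 4.0 Å | heavy-atom contact cutoff, boundary inclusive |
| `min_residues` | 5 | contacting residues required on one side |
| `min_identity` | 0.30 | neighbour identity over aligned columns |
| `min_aligned` | 0.75 | site residues that must map to the query |
| `position_bonus` | +1 | per aligned column |
| `gap_penalty` | -4 | per column with one side absent |
| `lambda`, `K` | 0.3176, 0.134 | ungapped BLOSUM62 statistics (nats, unitless) |
| `temperature` | 0.05 | balance of energy vs entropy in the cut selection |
| `redundancy_identity` | 0.90 | member redundancy threshold |
| `weights` | 1,1,1,1 | ranking weights (conservation, contacts, PSSM, identity) |

The original method's empirical ranking weights are unpublished, so all
four default to 1 and are exposed in `run_config()`. The bit-score
statistics $\lambda$ and $K$ are likewise not printed anywhere for this
scoring scheme; the ungapped BLOSUM62 values are used and both are
fields of `scoring_params()`.

## Numerical and design choices

* **Contact boundary** is inclusive (≤ 4.0 Å) with a `1e-9` squared-
  distance guard against floating-point noise; at exactly 4.00 Å a pair
  is a contact.
* **Contact counts** in the ranking are residue-pair counts by default;
  `contact_params(contact_count = "atom")` switches to atom pairs. The
  level used by the original service is not stated.
* **Distance transform** for clustering is $d = 1 - S$; similarity 1
  maps to distance 0 and similarities can be negative (disjoint sites),
  which simply yields distances above 1.
* **Cut candidates** are the $N$ dendrogram cuts, not all partitions;
  ties in $F$ go to fewer clusters; linkage ties are resolved
  deterministically by `stats::hclust`.
* **$\bar{s}_C$** is the mean over distinct member pairs (singletons:
  1); the entropy-like term uses natural log. Both choices are fixed in
  code in `select_partition()` and documented here because the source
  functional is described only in prose.
* **Gap handling**: conservation entropy treats the gap as a 21st
  symbol (an absent residue is information); PSSM columns renormalize
  gap mass away over residues (a profile column must be a convex
  combination of substitution rows). All-gap columns cannot occur in
  cluster alignments built from site unions.
* **Degenerate Z-scores**: with fewer than two conserved clusters, or
  zero spread in a component, the Z-score is defined as 0, keeping the
  combined score finite; order then falls back to cluster size and id.
* **Altlocs** keep the highest-occupancy conformer (ties: first in
  file); hydrogens, deuteriums and waters are removed at parse time;
  multi-model files contribute model 1 only; non-standard residues map
  to `X` and score through the matrix's wildcard row.
* **Identity denominator** is aligned columns, not full chain length
  (the alternative is one flag away in the code); supplied alignments
  are trusted as-is, since the structural-superposition engine that
  would re-verify them is outside this package's scope.
* **Affine gaps** in the alignment fallback cost
  `gap_open + L * gap_extend` for a run of length `L` (defaults
  -11/-1); traceback prefers diagonal, then up, then left, making the
  output deterministic.

## What the synthetic families emulate

`generate_family()` builds families of toy homodimers with *planted*
binding modes: straight chains with two pseudo-atoms per residue
(contact detection needs only distances, not stereochemistry), partner
atoms of planted interface residues at 2.8 Å and every other
inter-chain residue pair ≥ 6 Å, so the contact truth table is exact by
construction. Member sequences descend from a random ancestor, mutated
i.i.d. at `mutation_rate` (default 0.1) outside the planted interfaces.

Two generator choices need explanation because they define the study
conditions under which the end-to-end tests run:

* **Planted interface columns are strictly conserved by default**
  (`iface_rate_ratio = 0`). The method assumes binding sites are
  conserved among close homologs; at the toy scale of 8-9 residue
  sites, a single interface substitution lowers the normalized site
  similarity by roughly 0.10, which at $T = 0.05$ exceeds the entropy
  penalty for splitting the divergent member off, so families mutated
  inside their interfaces are not guaranteed to cluster as one mode
  per interface. (Real binding sites are larger, so a single
  substitution costs proportionally less; this is a small-site effect,
  not a property of real data.) The ratio is a `family_spec()` field
  for stress tests that deliberately leave this regime.
* **Members are redrawn until mutually non-redundant** (< 90% full-
  chain identity, bounded attempts, deterministic under the seed). At
  mutation rate 0.1 the expected member-member identity (~0.85, sd
  ~0.05 at length 60) straddles the 0.90 redundancy threshold, and the
  family's expected "conserved" labels must hold for the fixture's
  ground truth to be a truth.

The decoy member emulates a crystal-packing contact: one extra trimer
whose third chain touches chain A at residues disjoint from every
planted mode, with no alignment record for that chain — a one-off
interface that must end up in a singleton cluster and at the bottom of
the ranking.

What passing these tests does **not** show: performance on real
structures with flexible loops, partial occupancy interfaces,
non-trivial domain architectures, genuinely ambiguous binding-mode
overlaps, or homologs at the 30% identity floor where alignment error
dominates. The synthetic families have exact alignments and
well-separated modes by design; they validate the machinery, not the
biological error rate.

## Problem sizes used by the test suite

The default family is 8 members (plus decoy) of 60-residue chains,
giving 19 projected sites per run; oracle-equivalence checks run 1,000
random site pairs for the raw score, 10,000 for the normalized score,
100 random toy structures for contacts, and 200 random similarity
matrices (N ≤ 8) against exhaustive cut enumeration. These sizes keep
the whole suite under a minute while exercising every branch at
realistic combinatorial depth.

## Known limitations

* Structure superposition (and hence structure-based neighbour
  detection) is out of scope: alignments are inputs, or sequence-based
  fallbacks.
* Assembly/symmetry expansion of the asymmetric unit is not performed;
  interfaces present only in the biological assembly can still be
  *recovered* when homologs exhibit them, which is precisely the
  use-case the ranking supports.
* Only protein-protein interfaces are handled (no small molecules,
  nucleic acids, peptides or ions).
* Thermodynamic validation of assemblies (PISA-style) is treated as an
  external label source for evaluation, not reimplemented.
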