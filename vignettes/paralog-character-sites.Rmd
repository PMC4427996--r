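---
title: "Alignment decomposition and character-site detection for deeply divergent paralog pairs"
author: "ParalogSites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment decomposition and character-site detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ParalogSites)
```

## The problem

Aminoacyl-tRNA synthetase families occasionally contain two deeply
divergent forms: a *common* form spread across the three domains of life
and a *rare* form restricted to a few archaeal lineages, as in SerRS and
ThrRS. Two hypotheses compete for the rare forms' deep placement in gene
trees: genuine divergence predating the family's crown group, or a
long-branch-attraction (LBA) artifact in which a fast-evolving lineage
nested inside the common form is pulled towards the root. Tree inference
alone struggles here, because the branches involved are among the longest
in the tree. This package implements two tree-free computations that bear
on the question — clade-aware alignment decomposition and relaxed
character-site detection — together with a simulator that generates both
scenarios with known ground truth.

## Alignment decomposition

Two paralogous families align confidently to each other only over their
conserved core, while each family's own sub-alignment supports many more
reliable columns. Masking alone must discard those clade-specific columns;
decomposition keeps them. Given a mask of globally well-aligned columns
and one raw mask per clade (produced externally, e.g. by GUIDANCE, or by
the built-in surrogate scorer), `exclusivePartition()` makes the column
sets mutually exclusive — the shared mask is kept whole, each clade mask
loses columns already claimed by the shared mask or by an earlier clade —
and `decomposeAlignment()` concatenates them with per-column provenance.

Decisions worth knowing:

* **Column order** in the composite is: shared block first, then each
  clade's block in declared clade order, each ascending by original
  coordinate. Any order would do scientifically; this one is fixed so that
  identical inputs give byte-identical outputs, and the provenance table
  lets any other order be reconstructed.
* **Tie-break**: if two clade masks claim the same column, the first clade
  in declared order wins; removals are logged in the plan's `removed`
  slot.
* **Two modes**: `retain` copies residues verbatim for all taxa (the
  default, producing a single ordinary alignment); `gap-nonfocal` blanks
  taxa outside a clade at that clade's specific columns, on the argument
  that those columns are by construction unreliable outside the clade.
  Which convention a given published composite alignment used is usually
  not stated, so both are provided and recorded in the result.
* `informativeSites(plan, clade)` = shared + clade-specific counts: with
  masks of 107/129/217 columns this gives the 453-column composite with
  236 and 324 informative sites quoted in the README.

All user-facing coordinates are 1-based master-alignment coordinates, so
site labels like 598 can be quoted directly.

## The relaxed character-site definition

For ingroup $g$ (one family's rare or common form), sister group $s$ (the
other form of the same family) and outgroup $O$ (the entire other family),
a column is a **symplesiomorphy** for $g$ if some residue class $C$ has

$$\mathrm{share}_g(C) > t,\qquad \mathrm{share}_O(C) > t,\qquad
  \text{and } C \text{ absent from every taxon of } s,$$

with $t = 0.5$ strict, and a **synapomorphy** if $C$ clears the ingroup
threshold and is absent from all of $s$ *and* all of $O$. The relaxation
(majority share rather than perfect conservation) admits sites where
derived lineages have accumulated extra substitutions. Detection decisions
that the one-line definition leaves open are resolved as follows:

* **Denominators.** Shares are computed over non-gap, non-`X` residues.
  A group with more than half gaps at a column is ineligible there and the
  call is `none` (with a reason code). Non-gap denominators are the only
  choice under which heavily gapped columns cannot fake conservation.
  `X` counts as coverage but never as a residue.
* **Residue classes.** Physiochemically similar residues (defaults:
  K/R, D/E, L/M/I/V, F/Y/W, S/T) merge *opportunistically*: a class is
  considered only when at least two of its members actually occur in the
  group. A group that is 43% R + 37% K profiles as `R/K(80)`; a lone
  60% K stays `K(60)`.
* **Absence is absolute and residue-scoped by default**: one sister-group
  taxon carrying the defining residue vetoes the call regardless of group
  size. `absenceScope = "class"` extends the veto to the whole similarity
  class.
* **Outgroup pooling.** The outgroup share is taxon-weighted over both
  outgroup forms pooled (`pooled`, default). This reading is what allows a
  site whose rare-outgroup form is dominated by a different residue to
  still support a call when the larger common-outgroup form carries the
  defining residue strongly — the observed behaviour of site 1082 in the
  SerRS/ThrRS benchmark. A `per-form-majority` alternative requires the
  threshold within the larger outgroup form alone.
* **Weak calls.** A candidate that passes the ingroup threshold and the
  sister veto but fails the outgroup threshold is still reported — flagged
  `weak = TRUE` — when it is the outgroup's plurality class (the situation
  of the classically marginal 580D-type site). Weak calls never enter
  headline counts.
* **Priority and ties.** Candidates are tried in order of decreasing
  ingroup share (alphabetical on ties); a full symplesiomorphy beats a
  synapomorphy beats a weak call. All threshold comparisons use raw
  fractions; percentages are rounded half-up for display only.
* **Radicality.** Each call is labelled radical or conservative by
  comparing the defining class with the sister group's dominant class
  against physiochemical super-categories: aliphatic {A,V,L,I,M,C},
  aromatic {F,W,Y}, polar {S,T,N,Q,G}, positive {K,R,H}, negative {D,E},
  proline alone. Aromatics are kept apart from aliphatics so that an
  F-vs-L/M replacement counts as radical, matching how such differences at
  slowly evolving sites are usually read; D-vs-E remains conservative.

`evaluateSite()` classifies one column; `scanCharSites()` runs the same
kernel over all columns with precomputed group counts and returns calls,
per-ingroup counts and per-group profile strings; `summarizeCalls()` adds
the per-family mean conservation (the mean over a family's non-weak
symplesiomorphy calls of the defining class's within-ingroup percentage).

## The benchmark fixture

`makeCharSiteBenchmark()` builds, deterministically and entirely in code,
a four-group alignment (100 taxa per group by default) whose seven
designated columns realise the canonical SerRS/ThrRS character-site
profiles exactly — e.g. column "598" is 65 G + 35 A in common SerRS, 89 P
+ 11 C in rare SerRS, 86 P + 14 W in common ThrRS and 100 P in rare ThrRS
— embedded among 21 filler columns engineered to produce no call of any
kind (uniform columns, sub-threshold spreads, columns whose dominant class
is shared by all groups, gap-heavy and X-heavy columns). Remainder
residues within each designated column are chosen so no unintended class
clears the threshold and defining residues stay absent where they must be
absent. Two specifics deserve a note:

* At column "1082" the rare-ThrRS remainder is V (17 taxa), so the pooled
  ThrRS V share is $(86+17)/200 = 51.5\% > 50\%$ with equal group sizes.
  In the real data this margin comes from the common-ThrRS group simply
  being larger than the rare one; with the fixture's equal group sizes the
  remainder carries it instead. The printed dominant profile, E(83), is
  unchanged.
* Group sizes must be multiples of 100 so the percentage profiles are
  integer counts.

Scanning the fixture with defaults yields exactly 3 rare-SerRS and
4 common-SerRS symplesiomorphies, all radical, and a mean SerRS-type
conservation of 92% — the quantities `scripts/acceptance.R` recomputes.

## The simulator

`simulateAlignment()` evolves each column independently along a scenario
tree under a **uniform-exchange** amino-acid process: on a branch of
length $b$ a site with rate multiplier $r$ receives
$\mathrm{Poisson}(b\,r)$ substitutions, each replacing the residue by one
of the other 19 uniformly. This is a deliberate simplification of
empirical exchange models (LG and relatives): the character-site argument
depends only on slow sites and topology, and the uniform model has a
closed-form identity probability,
$P(\text{same after } t) = \tfrac{1}{20} + \tfrac{19}{20}
e^{-\frac{20}{19} t}$, which the test suite uses as an independent check
of the machinery. Realistic aaRS sequence evolution (site-specific
profiles, indels, alignment noise) is explicitly out of scope, so a
passing recovery test says the detector recovers planted signal under
this clean process — not that real alignments are this clean.

* **Topologies.** `deep_divergence` realises ((commonA, rareA),
  (commonB, rareB)) with the family split at the root; `lba` attaches the
  rareA clade on its own (typically long) stem *inside* the commonA
  clade. Groups are star clades with short terminal branches.
* **Defaults** (overridable per run): 8 taxa per group, stems of 1.0
  expected substitutions/site, family stems 0.5, terminal branches 0.05,
  200 columns, 30% slow sites with rate multiplier 0 (invariant). These
  are chosen to mimic the regime of interest — long stems separating
  internally conserved groups — at a size where hundreds of replicates
  run in minutes.
* **Planted sites** are placed in the slow class so their truth labels
  stay valid: a planted symplesiomorphy for $g$ roots the column at the
  defining residue and forces the *sister* stem to the background
  residue; a planted synapomorphy roots at the background and forces
  $g$'s own stem to the defining residue. Plantings that the topology
  makes impossible (a rareA symplesiomorphy, or a commonA synapomorphy,
  under `lba`) are rejected with an explanation.
* **Reproducibility.** Everything is driven by the config seed;
  `scenarioExperiment()` gives replicate $i$ the sub-seed `seed + i`, so
  replicates are independent and the whole experiment is reproducible.

The stem-length logic follows from where the defining substitution must
occur: a symplesiomorphy for $g$ records a change on the **sister**
group's stem, so its expected count scales with the sister stem length,
while a synapomorphy for $g$ scales with $g$'s own stem. Under `lba`,
rare-ingroup symplesiomorphies can arise only through convergent
substitutions and stay near zero; the test suite asserts both effects
with 100-replicate experiments (at 4 taxa per group and 150 columns, with
slow-class rate 0.3 so that stem substitutions at conserved sites are
possible) rather than assuming them.

## Numerical and degenerate-input choices

* Percent display rounds half away from zero; all comparisons use raw
  fractions.
* The strict `>` at the threshold means an exact 50% share is never a
  call; an exactly-half non-gap column is still eligible
  (`minNonGapFraction` is a `>=` bound).
* Empty masks are legal everywhere: a cutoff no column reaches produces
  an empty mask with a warning; a pipeline run with no masks at all skips
  decomposition (recorded in the manifest) and scans the master alignment.
* Ragged FASTA, duplicate ids, illegal characters, out-of-range scores
  and overlapping clade memberships are rejected at the I/O boundary with
  the offending taxon/line named; case is the only silent normalisation.
* The surrogate column scorer (mean pairwise identity x non-gap fraction)
  is a stand-in quality track for runs without external scores; it is not
  a GUIDANCE reimplementation and makes no bootstrap-stability claim.

## Known limitations

* The detector is alignment-based and tree-free by design; it does not
  map characters onto a tree, reconstruct ancestral sequences, or attach
  significance values to the counts — the counts themselves are the
  statistic.
* The simulator's uniform-exchange process and star-clade groups are
  idealisations; effects that depend on rate heterogeneity across
  lineages within a group, or on alignment error, are outside what the
  recovery tests can show.
* Score-table support covers per-column confidence values; block-removal
  masks produced by external tools can be supplied directly as site
  masks, and nothing is asserted about which convention any particular
  published analysis used.
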