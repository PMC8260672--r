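---
title: "Methods: classifying and comparing PRR repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying and comparing PRR repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prrsurvey)
```

# The problem

Pattern recognition receptors (PRRs) — Toll-like receptors (TLRs),
RIG-I-like receptors (RLRs), NOD-like receptors (NLRs) and C-type lectins
(CTLs) — are the sensing layer of innate immunity. In non-model animals they
are annotated not by homology to a single gene but by *domain architecture*:
a protein is a prototypical TLR because it carries leucine-rich repeats, a
transmembrane segment and a TIR domain, regardless of which exact TLR it
resembles. `prrsurvey` implements such a survey as a reusable, testable
pipeline: it consumes tabular outputs of standard tools (profile-HMM domain
tables, transmembrane-segment predictions, pairwise sequence-search tables),
applies explicit inclusion thresholds and classification rules, and feeds
the resulting per-species count matrix into comparative analyses.

# Inclusion thresholds

Two independent gates must both pass before a protein is classifiable:

1. **Search gate.** The whole-protein E-value against the receptor-family
   alignment query must be strictly below $10^{-4.9}$
   (`threshold_config()$search_evalue_max`, $\approx 1.2589\times10^{-5}$).
   The exponent is taken literally as a real number; no rounding.
2. **Per-domain filter.** Each domain hit is retained only if its
   *independent* per-domain E-value is strictly below $10^{-4.9}$ for
   non-repeat families, or below the relaxed $10^{-3}$ for repeat families
   (LRR, ankyrin, WD40, sushi, TPR, EGF, collagen by default — the repeat
   list is configuration, since no canonical enumeration exists).

Both comparisons are strict (`<`); the synthetic generator draws decoy
E-values log-uniformly in (threshold, 10 × threshold) precisely to stress
this boundary. We apply the per-domain threshold to the independent
(i-Evalue) column: the conditional E-value is an anti-conservative choice
for architecture calling because it is conditioned on the full-sequence hit.

**Clan confirmation and the helicase context exception.** A hit that failed
clan-level post-processing (`clan_confirmed = FALSE`) is dropped — except a
DExD/H-box helicase hit, which is rescued when the same protein carries a
retained RIG-I C-terminal repressor-domain hit. The biological rationale is
that in a phylogenetically distant lineage a genuine RLR helicase can score
below clan cutoffs while the flanking repressor domain secures the context.
The exception is deliberately local: no other clan-unconfirmed family can
ever be rescued, and the test suite asserts this over randomized fixtures.

**Overlap resolution.** Retained hits of the *same* family overlapping by
more than 50% of both spans are merged, keeping the lower E-value (profile
fragmentation is an HMM artifact and the rules count domain presence);
overlapping hits of different families are all kept. Coordinates are stored
0-based half-open internally, converting from the 1-based closed convention
of HMMER-style tables on read, so span lengths survive round trips.

# Classification rules and precedence

The nine categories are: prototypical TLR (TIR + LRR + TM), TLR-like
(TIR + TM), RIG-I/MDA5-like (helicase + CARD + C-terminal regulatory
domain), LGP2-like (helicase + repressor domain, *without* CARD — LGP2
lacks CARDs, and requiring their absence keeps the two RLR groups
disjoint), prototypical NLR (NACHT + LRR), NLR-like (NACHT), and three
CTL groups split by localization evidence: a transmembrane segment
(`CTL_TM`, which wins when both kinds of evidence are present — a TM
segment is direct evidence of membrane anchoring), one of fourteen
extracellular-indicative families (`CTL_EXTRACELLULAR`), or neither
(`CTL_UNKNOWN`). "LRR" and "TM" requirements are the weakest readings:
at least one retained LRR-family hit, at least one predicted helix.

Counts must be mutually exclusive, so multi-matching fusion proteins (e.g.
NACHT + TIR, which the cnidarian repertoires really contain) need a
deterministic resolution. We use a *gate cascade*: the first
receptor-defining domain present — TIR, then DExD/H helicase, then NACHT,
then CTLD — claims the protein for its branch, and if the branch's minimum
rules are not met the protein classifies `NONE` rather than falling through
to a later branch. This is the one reading under which a TIR-bearing
protein can never inflate the NLR or CTL counts; the categories every such
protein *would* satisfy are recorded in `also_matches`, so no information
is lost. Special architectures are flagged orthogonally: CTLD + collagen
(`MBL_LIKE`, the mannose-binding-lectin organization), LGP2-like + RNA
dependent RNA polymerase (`RDRP_FUSION`), and NACHT/CTLD fused to reverse
transcriptase, integrase or hAT dimerization domains
(`TRANSPOSON_DOMAIN`).

Domain-name vocabularies (which family names count as TIR, NACHT, CTLD,
...) ship as an overridable `prr_rules()` configuration because family
naming drifts across annotation releases; the mapping of "coagulation
factor Xa inhibitory domain" to the antistasin family is likewise a config
entry, as the name does not identify a unique accession.

# Downstream pathway survey

NF-kB candidates are typed by the most complete satisfied class:
Rel DNA-binding + Rel dimerization domains alone are sufficient
(`NFKB_MINIMAL` — cnidarian NF-kB is known to occur truncated), with
ankyrin repeats and then a death domain defining the fuller classes; an
IkB-alpha call requires "multiple" (read: at least 2) ankyrin repeats on a
protein retrieved by the IkB query. Complement families are required domain
multisets (C3: ≥2 macroglobulin + CUB + C345c; MASP: 2 CUB + sushi +
serine protease; Factor B/C2: sushi + von Willebrand factor + serine
protease; C6: thrombospondin + LDL-receptor class A + MACPF + sushi), with
MASP tested before Factor B/C2 because its rule is more specific.
Architectures missing exactly one required family are reported as partial
calls — the survey's "all C3 domains except C345c" observation must be
producible, not silently discarded.

Pathway membership uses reciprocal best hits: the strongest species protein
for a human query must return one of the member's query ids as its unique
strongest hit against the human proteome. "Strongest" is lowest E-value
with bitscore as tie-break; any residual tie yields *absent*, because
ambiguity is not evidence of orthology. (Descriptions of this procedure
sometimes say "highest" E-value; the only defensible reading is the
strongest, i.e. lowest, E-value, which is what we implement.)

# Ancestral state reconstruction

Receptor counts per type are treated as a continuous trait evolving by
Brownian motion on the species tree — untransformed, exactly as the
standard ML reconstruction of comparative-methods practice; we deliberately
do not substitute a phylogenetic count model, as fidelity to the standard
method is the point. Under Brownian motion, tips are multivariate normal
with covariance $\sigma^2 C$, $C_{ij}$ the shared root-to-MRCA path length.
The ML state at internal node $v$ equals the GLS root-state estimate after
re-rooting at $v$:

$$\hat a(v) = (\mathbf 1^\top C_v^{-1}\mathbf 1)^{-1}\,
  \mathbf 1^\top C_v^{-1} x,$$

where $C_v$ is obtained without literal re-rooting via
$C_v[i,j] = \tfrac12\bigl(d(v,i)+d(v,j)-d(i,j)\bigr)$ from unrooted path
distances; this handles multifurcations natively, so non-binary species
trees from orthology tools need no arbitrary resolution. The rate is
estimated as $\hat\sigma^2 = r^\top C^{-1} r / n$ at the original root, and
per-node variances use the conditional GLS formula
$\hat\sigma^2/(\mathbf 1^\top C_v^{-1}\mathbf 1)$ — conditional, not joint,
uncertainty, matching common tool behaviour while staying explicit.
Zero-length internal branches are collapsed to multifurcations; zero-length
*terminal* branches make $C$ singular and raise an error unless the caller
supplies an explicit minimum branch length — silent jittering would change
results without consent. The test suite verifies the estimates three ways:
against a numerical optimizer of the joint Brownian objective
$\sum_e (\Delta x_e)^2/\ell_e$ on 50 random small trees (agreement within
$10^{-5}$), against the reference comparative-methods implementation
(`phytools::fastAnc`), and against closed-form limits (constant tips,
star-tree means, affine equivariance).

# Ordination and trait models

The per-species count matrix (default: the four type totals) is analysed by
covariance PCA (`scale = FALSE`, matching an unstandardized analysis of
totals; a `scale` option and a nine-subcategory input are provided because
the interpretation "driven largely by CTLs and NLRs" is compatible with
either choice). Signs are fixed so each component's largest-magnitude
loading is positive.

Associations between the total PRR count and binary life-history traits are
quasi-Poisson GLMs, `total ~ trait`, one trait per model: clade, symbiosis,
coloniality and sessility overlap almost completely in this system, so a
joint model would be uninterpretable, and no multiplicity correction is
applied. The quasi-likelihood fit leaves point estimates identical to the
Poisson fit; the Pearson dispersion $\hat\phi$ scales the standard errors
by $\sqrt{\hat\phi}$ and p-values use the $t$ distribution with residual
degrees of freedom — the convention of the originating statistical
environment. For the clade model the contrast is anthozoa vs medusozoa and
outgroup species are dropped. The model list is an explicit argument: only
four study traits are named in the source material although five models are
mentioned, so we decline to invent a fifth and leave the list extensible.

# The synthetic study system

`simulate_survey()` is first-class, tested code, not a fixture dump. It
builds a 15-species system mirroring the real study's composition — one
sponge-like outgroup, six medusozoan-like and eight anthozoan-like species
(the published figure key lists exactly these fifteen) — with per-species
planted counts drawn once per seed from clade-typical ranges: anthozoans
with expanded NLR (up to ~90 NLR-like) and CTL (up to ~60 extracellular)
repertoires and 2–15 RIG-I/MDA5-like receptors; medusozoans with no RLRs
and no prototypical NLRs; a modest outgroup carrying the one LGP2-like
receptor. These ranges reproduce the magnitudes and clade contrasts of the
real repertoires (species totals roughly 40–600) and are fixed defaults,
not tuning knobs. Every species also receives near-miss decoys: TIR + LRR
without a TM segment, threshold-boundary E-values, clan-unconfirmed
helicases without repressor context, repeat hits above even the relaxed
threshold, and proteins failing the search gate. Planted architectures
satisfy exactly one rule; decoys satisfy none — so classification accuracy
on generator output is required to be exactly 100%, with no tolerance.

What the generator does *not* emulate: real HMM score distributions,
fragmented or chimeric gene models, clan structure beyond the boolean
flag, and annotation-release drift in family naming. Passing tests
therefore demonstrate the correctness of the rules and machinery, not the
accuracy of any upstream annotation; on real proteomes the counts inherit
the error of the gene models and HMM hits they are built from.

Brownian traits are simulated edge-by-edge with variance
$\sigma^2 \ell$ and recorded internal truth; overdispersed counts come
from a gamma–Poisson mixture with variance $\phi\mu$ (so $\phi = 1$ is
pure Poisson); reciprocal-hit tables plant mutual bests among one-way and
exact-tie decoys. All draws run under an isolated RNG seeded from the
caller's seed, so identical seeds give byte-identical bundles without
touching the session RNG.

# Problem sizes and numerical choices

The shipped test-and-validation configuration uses: the full 15-species
bundle (~1,800 proteins, ~5,000 domain hits) for end-to-end classification;
50 random trees of 3–6 tips for the ASR/oracle comparison (tolerance
$10^{-5}$, the optimizer's practical accuracy); 200 Brownian replicates on
a 15-tip tree for root-state bias; 500 replicates of $n = 200$
overdispersed counts ($\beta_1 = 0.5$, $\phi = 3$) for GLM coverage, with
the accepted band 92–98% for a nominal 95% interval; and PCA
reconstruction to $10^{-8}$. These sizes make the whole suite run in well
under a minute per stage while leaving Monte-Carlo error far below every
asserted tolerance. GLM convergence uses a deviance tolerance of
$10^{-10}$; ties anywhere in best-hit selection resolve to "absent", and
category ties cannot occur by construction of the gate cascade.

# Known limitations

* The rule set is only as good as the domain annotations; the pipeline
  never re-scores sequences and cannot rescue missed domains (except the
  one documented helicase context rule).
* Trait models are ordinary GLMs, not phylogenetic regressions; with 14–15
  species and strongly clade-confounded traits they describe association,
  not independent evolutionary events.
* ASR on count data assumes an unbounded continuous Brownian process;
  reconstructed states can be fractional and, on strongly trending data,
  mildly negative — they are expectations under the model, not realizable
  counts.
* Reciprocal best hit is a one-to-one orthology heuristic; lineage-specific
  expansions (the norm for cnidarian PRRs themselves) violate it, which is
  why it is used only for conserved downstream pathway members.
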