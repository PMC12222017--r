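---
title: "Comparative connectomics of neck-connective neurons: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative connectomics of neck-connective neurons: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neckmatch)
```

## The problem

The neck connective is the axon bundle joining the insect brain to the
ventral nerve cord (VNC); every descending command and every ascending
report passes through it. Electron-microscopy connectomes of the brain and
of male and female nerve cords are reconstructed independently, in
different coordinate spaces, from different animals and sexes. Comparing
them requires: (i) pairing each neuron with its mirror homologue within a
dataset, (ii) matching cell types across datasets after spatial
registration, (iii) rule-based anatomical annotation (soma side, neuropil
innervation codes, longitudinal tract), (iv) ranking neurons by how
directly sensory modalities reach them through the synaptic graph, (v)
thresholded connectivity analysis and stereotypy statistics, and (vi) a
decision cascade separating sex-specific and sexually dimorphic cell types
from biological variation and reconstruction artefacts.

`neckmatch` implements that pipeline as composable, tibble-first functions,
and ships a deterministic synthetic-connectome generator with planted
ground truth so every stage can be validated end to end without access to
any external connectome service.

## Morphological machinery

**Dotprops and NBLAST.** Skeletons are resampled along their cable
(default step 1 µm, the conventional scale for adult fly neurons) and
reduced to *dotprops*: points with unit tangents from a local PCA over the
`k = 5` nearest neighbours, plus a colinearity score
$\alpha = (\lambda_1 - \lambda_2)/(\lambda_1 + \lambda_2 + \lambda_3)$.
The raw NBLAST score of a query against a target sums, over query points, a
score of the nearest-target distance $d$ and absolute tangent dot product
$|u_q \cdot u_t|$. Published scoring tables are assets of specific
template brains, so the package default is the parametric surrogate

$$s(d, \mathrm{dp}) = \mathrm{dp} \cdot e^{-d^2 / 2\sigma^2} - c,
\qquad \sigma = 3\,\mu\mathrm{m},\; c = 0.1,$$

which reproduces the sign structure of the tabulated log-odds scores
(positive for close, aligned points; negative at distance). A tabulated
matrix can be supplied via `read_score_matrix()` and is used verbatim. All
matching operates on the *mean-normalized* score
$\tfrac12\,(\mathrm{raw}(a,b)/\mathrm{raw}(a,a) +
\mathrm{raw}(b,a)/\mathrm{raw}(b,b))$, which is symmetric and equals 1
exactly for identical morphologies. The inner loop is compiled; tests pin
it to a brute-force R oracle at $10^{-9}$.

**Mirroring and registration.** Left cohorts are mirrored across the
sagittal plane ($x' = 2\,\mathrm{mid}_x - x$, an exact involution) before
pairing. Cross-dataset registration is an unregularized 3-D thin-plate
spline with kernel $U(r) = r$ fitted to landmark pairs — the one-step
transform convention — so every landmark interpolates exactly and purely
affine deformations are recovered with vanishing warp coefficients. There
is no stiffness parameter by design; smoothing registrations are a
different tool.

**Clustering.** Similarity matrices are cut as dendrograms
(`stats::hclust`) on distance $1 - s$; the default linkage is Ward
(`ward.D2`), with average linkage the documented fallback. Determinism
comes from `hclust` itself given a fixed input.

## Pairing, matching and the dimorphism cascade

**Within-dataset pairing.** Mirrored-left versus right mean-normalized
NBLAST; mutual best matches with score ≥ `theta_pair = 0.4` become pairs.
Neurons whose top two candidates differ by less than `delta_group = 0.05`
are population-like and are merged with their candidates into groups rather
than forced into pairs. The 0.4/0.05 values formalize what is otherwise an
expert judgement; both are configuration.

**Cross-dataset matching.** Dataset A dotprops are carried into B's space
by the landmark spline; candidates are same-side pairs. The combined score
is $w_m \cdot \mathrm{morph} + w_c \cdot \mathrm{conn}$ with defaults
$w_m = 0.7, w_c = 0.3$: morphology leads and connectivity resolves
ambiguity, mirroring the order of the manual workflow. The connectivity
channel is the cosine similarity of type-level input/output fingerprints
(summed weight per partner type, normalized per direction — scale-free, so
comparable across datasets with different synapse recovery). Assignment is
greedy mutual-exclusive by descending combined score with floor
`theta_match = 0.3`; on well-separated score matrices this coincides with
the exhaustive optimal assignment (tested). Confidence 1–5 is assigned by
binning the combined score at 0.2/0.4/0.6/0.8; "high confidence" means
above 3, i.e. combined > 0.6.

**Dimorphism cascade.** Classification is per cell type, in a fixed order:
flagged neuropeptidergic / histaminergic-ascending / abdominal types are
excluded (their morphological variability is not sex-related or not
assessable); unmatched types that are not well reconstructed are
`reconstruction_issue`; unmatched, well-reconstructed types with a
left–right partner are `sex_specific`; matched types with mean morphology
score below `tau_d = 0.5` are `sexually_dimorphic`; matched types with
unequal member counts are `biological_variation`; the rest are
`matched_monomorphic`. Two deliberate formalizations of what is otherwise
manual review:

* *Well reconstructed* means: not flagged truncated, and skeleton node
  count at least `min_nodes = 50`.
* *Match credibility*: a match record enters the cascade as "matched" only
  if its connectivity similarity reaches `conn_floor = 0.3`, or its
  morphology score reaches `tau_d` with both endpoints well reconstructed.
  Without this, two leftover neurons from different unmatched pools can
  pair up on middling morphology alone, and — more subtly — a truncated
  fragment scores deceptively well against any full neuron sharing its
  tract, because the fragment-to-full direction of the mean-normalized
  score is near 1. A genuinely dimorphic homologue keeps its connectivity
  fingerprint even when its shape diverges, so it always has one strong
  channel.

A type that is unmatched, well reconstructed, but has no left–right partner
is recorded as `biological_variation` with rationale `one_side_missing`
(a one-sided count difference, not evidence of sex specificity).

New systematic names for unmatched types count downward from 999
(`new_type_names()`), keeping them disjoint from reference-dataset
numbering.

## Anatomical annotation rules

**Soma side**: left/right by soma x against the midline with a ±2 µm
center band; somaless neurons (typical for sensory ascending neurons) fall
back to their neck-plane crossing x; with neither, `unknown`.

**Brain neuropil code**: profile fractions use presynapses for ascending
and postsynapses for descending neurons (the dendritic arbour is what is
being localized). One label at ≥ 80%; `primary_secondary` when the top two
reach 80% together and each holds ≥ 5%; otherwise `multi`.

**Nerve-cord neuropil code**: role convention reversed per class; a single
two-letter code when one neuropil holds *more than* 80% (the wording is
strict there, and the package follows it literally — both thresholds are
configuration); else `ut` / `xl` when the upper-tectulum or leg-neuropil
region set sums past 80%; else `xn`; soma-only neurons are `XA`. The
published two-letter code list prints `hl` twice (haltere tectulum vs
hind leg); the default `vnc_code_map()` resolves the collision by giving
the haltere tectulum `ht` and is user-replaceable precisely because the
printed list is ambiguous. Pairs or groups with inconsistent codes are
reconciled by re-applying the rule to the member-mean fraction vector.

**Tracts**: the skeleton is reduced to its longest root-to-leaf neurite
from the nerve-cord entry point and assigned the tract whose centerline has
minimal mean closest-point distance. Tract meshes are dataset assets; with
explicit centerlines the cluster-then-label procedure collapses to
nearest-centerline assignment, which is what the package implements (the
NBLAST clustering step remains available for pre-grouping).

## Information-flow ranking

The upstream analysis delegates to a cited implementation whose exact
internals are not printed; the package provides a reconstruction of that
algorithm family and flags it as such. Per sensory modality, seeds activate
at step 0; at every later step each inactive neuron whose active-input
fraction (by synapse weight) is $f$ fires with probability
$\min(1, f/f_{\max})$, with $f_{\max} = 0.3$, 100 runs, 20 steps maximum —
all three exposed in configuration and *not* claimed to match the cited
implementation numerically. Unreached runs contribute `max_step + 1` so
type means stay defined. Two limits anchor correctness: with a single
100%-input chain the ranks equal hop counts exactly, and as
$f_{\max} \to 0$ the traversal reduces to breadth-first search (both
tested, plus an exact enumeration of the traversal distribution on a
6-node graph). Ranks are averaged by type and clustered on Euclidean
distance between rank vectors with a configurable dendrogram cut height.
Sensory descending neurons can be excluded via the `exclude` argument — a
caller-side filter, not hard-coded identities.

## Connectivity analysis

Partner graphs start from edges with weight ≥ 10 *and* percent of the focal
neuron's output > 0.5% — percent measured against the neuron's total output
in the dataset, not within the subgraph — then add back motor, sensory and
sensory-ascending partners at weight ≥ 5 (those classes make fewer synapses
per neuron and act as populations). The retained adjacency is converted to
input percent of the receiving neuron and averaged by type. Stereotypy
between hemispheres or datasets is summarized by Pearson's r (via
`stats::cor`) and the least-squares slope through the origin
$\sum ab / \sum a^2$; whether the published comparison used a free
intercept is not stated, so both slopes are computed and the through-origin
one is reported by default. Effective connectivity over 1..`max_hops` hops
sums products of input fractions along paths (signless; neurotransmitter
sign is out of scope). Synapse densities are counted in 5 µm voxels
anchored at the floor of the bounding box (deterministic,
translation-covariant), with the optional strict cleft-score > 50 filter.

## The synthetic generator: what it emulates, and what it does not

`generate_connectomes()` builds a female and a male VNC-like dataset from
one root seed (stage-specific substreams for types/wiring, morphology,
synapses and connectivity, so stages can be varied independently):

* **Geometry.** An 11-region box atlas partitioning a
  320 × 300 × 100 µm volume, with upper-tectulum and leg region sets; five
  gently curved longitudinal tracts per side.
* **Types.** 60 types by default: per type a template skeleton follows its
  tract from the neck entry to its target neuropil and grows a
  momentum-random-walk arbour there. Arbour cable is scaled to ~1.3× the
  main-neurite cable so that terminal arbours dominate total cable, as in
  real neurons — this also makes arbour differences decisive for NBLAST.
  Right member = template + 200 nm Gaussian node jitter; left member =
  mirrored template + jitter.
* **Cross-dataset warp.** The male dataset is the template warped by a
  diagonal affine plus low-frequency sinusoidal displacement (2–2.5 µm
  amplitude, one period per volume). The x component is a pure scale so the
  warp commutes with mirroring: both animals stay internally bilaterally
  symmetric, while the cross-dataset deformation is genuinely nonlinear. An
  80-point landmark lattice samples the warp; an unregularized thin-plate
  spline on it recovers the deformation to well under the NBLAST distance
  scale, making registration a real (not vacuous) step.
* **Planted categories.** 10% sex-specific types (half per sex, omitted
  from the other dataset), 10% dimorphic (arbour rotated ~1 rad, scaled
  1.3×, shifted 9 µm dorsoventrally in the male — past the `tau_d`
  threshold by construction, while connectivity stays shared), 5% with an
  extra member in one dataset (biological variation), 5% flagged
  neuropeptidergic (exclusions), and two types planted as reconstruction
  issues (absent from the male dataset, truncated to 30 nodes and flagged
  in the female one).
* **Synapses.** Each focal neuron gets 30 pre- and 30 postsynapses sampled
  inside its type's neuropil boxes at planted proportions (90/10 for
  single-code types; spread profiles for `ut`/`xl`/`xn`), uniform cleft
  scores in [0, 100].
* **Connectivity.** Four sensory modalities wired as layered chains:
  seed neurons (class SN) feed depth-1 types, which feed depth-2 types,
  and so on to depth 4, ipsilaterally, with type-level mean weights drawn
  once (shared by both datasets and sides) and member-level rounded
  Gaussian noise (σ = 2). Each neuron's input comes entirely from the
  previous layer, so planted depths equal traversal ranks in the
  deterministic regime. Deepest-layer types also contact motor neurons at
  weights straddling the add-back threshold.

Design choices a user should know: reconstruction-quality flags are planted
on dedicated categories rather than sprinkled at random — a truncated
sex-specific type is genuinely unclassifiable (that ambiguity is what the
`reconstruction_issue` label exists for), so random flag noise would only
blur the acceptance surface without testing any additional code path. The
synapse table and the edge list are generated independently (synapse
records localize annotation; edges carry counts), so their totals are not
mutually consistent — no pipeline stage compares them.

What the generator does *not* emulate: real arbour geometry and tiling,
synapse-position correlation with arbour cable, electrical compartments,
neurotransmitters, reconstruction-error morphology beyond truncation,
cross-type morphological similarity structure (real cell types form
continua within hemilineages), and dataset-scale (hundreds, not thousands,
of neurons). Passing recovery tests therefore demonstrates that the
pipeline's logic is correct under its stated assumptions — not that its
thresholds are tuned for any real dataset pair.

## Problem sizes and numerical choices

The default validation bundle is 60 types, ≈160 neurons per dataset
(≈320 total including sensory-seed and motor scaffolding), which a full
pipeline run processes in well under a minute; recovery statistics in the
test suite aggregate 10 generator seeds. Degenerate inputs are handled
explicitly: empty edge tables are legal (with a warning), isolated neurons
get zero fingerprints and cosine 0 by convention, zero-synapse profiles are
`unassigned` (or `XA` when soma-only), unreachable neurons carry the
`max_step + 1` sentinel, and ties in neuropil fractions break
alphabetically for determinism. The thin-plate spline refuses coplanar or
duplicate landmark systems rather than regularizing silently.

## Known limitations

* The parametric NBLAST score is a surrogate; absolute score values are not
  comparable to published tabulated-matrix scores (normalized scores are
  robust to this in practice, and the loader accepts real tables).
* Tract assignment needs centerlines; no mesh support.
* The traversal ranking is a reconstruction of a cited algorithm family;
  its numerical output should not be compared 1:1 with published rank
  values.
* Matching is greedy; for cohorts with heavy within-type ambiguity a global
  assignment (Hungarian) could differ — the pairing stage's grouping rule
  is the intended mechanism for those cases.
* `biological_variation` for one-side-missing types conflates several
  upstream causes (true absence, segmentation loss); with real data this
  category needs manual review, as its name suggests.
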