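---
title: "Statistical descriptors of RNA tertiary structures: methods and conventions"
author: "RNAStructStats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical descriptors of RNA tertiary structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RNAStructStats)
```

# Scope

RNAStructStats computes, for RNA 3D structures read from mmCIF or legacy PDB
coordinate files, four families of descriptors used throughout RNA modelling
and scoring-function work:

1. **Global size and shape** — radius of gyration, gyration-tensor
   eigenvalues, asphericity and the signed shape parameter.
2. **Base-local geometry** — an orthonormal reference frame on every
   nucleobase, cylindrical coordinates of one base in another's frame, and
   the edge sectors (Watson-Crick / Hoogsteen / sugar) they imply.
3. **Secondary-structure motifs** — canonical and non-canonical base pairs,
   stems, hairpin/bulge/internal/junction loops, with exact pseudoknot
   resolution.
4. **Atom-pair distance distributions** over an 85-type heavy-atom scheme,
   the raw material of distance-dependent statistical potentials.

A dataset layer aggregates per-structure results, fits the Flory-type
scaling of size with length and the linear growth of base-pair counts, and
summarises pair-geometry classes with Gaussians.

# The structure model

`readRNAStructure()` keeps only standard ribonucleotides (A, C, G, U) and
heavy atoms (C, N, O, P).  Equal masses are assumed for all heavy atoms in
every size/shape computation.  Conventions, applied in this order and
recorded in the object's processing log:

* **Model selection.** Multi-model (NMR) files contribute model 1 only.
* **Alternate locations.** The highest-occupancy conformer wins; ties break
  by altloc label order.
* **Modified nucleotides** are dropped by default.  With
  `mapModified = TRUE` a small table of common modifications (PSU, 2MG,
  5MC, ...) is mapped to the parent base, keeping only the parent's heavy
  atoms.  The default is conservative because the atom-typing scheme covers
  standard bases only, and the statistics here should not silently mix
  modified chemistry into standard-base classes.
* **Chain connectivity.** Residues keep author numbering plus a sequential
  internal index; covalent linkage is declared when O3'(i)-P(i+1) is at
  most 2.5 Å, which is how chain breaks are detected without trusting
  numbering gaps.

The 85-type scheme counts 12 backbone/ribose names shared by all bases plus
10 (A), 11 (G) and 8 (C, U) base atoms: 22 + 23 + 20 + 20 = 85.  OP3 and
hydrogens are deliberately untyped, which is what makes the count exactly 85.

# Size and shape

With atom positions $r_i$ and centre $r_0$, the squared radius of gyration
is $R_g^2 = \frac{1}{N}\sum_i (r_i - r_0)^2$.  The gyration tensor is the
second central moment $T = \frac{1}{N}\sum_i (r_i - r_0)(r_i - r_0)^T$,
algebraically identical to the pairwise double-sum form
$\frac{1}{2N^2}\sum_{ij}(r_i - r_j)(r_i - r_j)^T$; the test suite checks
the two routes against each other at $10^{-9}$ relative tolerance.  The
normalisation is chosen so that $\mathrm{tr}\,T = R_g^2$ — the printed
double-sum form without the $1/N^2$ factor would violate that identity, and
both shape statistics below are ratios that are unaffected by the choice.

With eigenvalues $\lambda_1 \ge \lambda_2 \ge \lambda_3$ and
$\bar\lambda = \mathrm{tr}\,T/3$:

$$\Delta = \frac{3}{2}\,\frac{\sum_i (\lambda_i-\bar\lambda)^2}{(\mathrm{tr}\,T)^2}
\in [0, 1], \qquad
S = 27\,\frac{\prod_i (\lambda_i-\bar\lambda)}{(\mathrm{tr}\,T)^3}
\in [-\tfrac14, 2].$$

$\Delta = 0$ and $S = 0$ for spherically symmetric clouds; a collinear rod
attains $\Delta = 1, S = 2$; a symmetric planar disc attains the lower
bound $S = -1/4$.  Both are invariant to rigid motion and uniform scaling.
All chains of a structure are pooled: the statistics describe the deposited
complex, not individual chains.  Numerics: eigenvalues are clamped at zero
below $10^{-12}\,\mathrm{tr}\,T$, and $\Delta$, $S$ are clipped to their
analytic ranges against round-off; an all-coincident point set is a
degenerate-geometry error rather than a silent 0/0.

# Base frames and cylindrical pair geometry

Each nucleobase (ring plus exocyclic heavy atoms; no sugar or phosphate) is
treated as a rigid group with origin at its heavy-atom centroid.  In-plane
vectors $u$ ($C8-N1$ in purines, $C4-N1$ in pyrimidines) and $v = N3-N1$
define the plane; the normal is $Z = \widehat{u \times v}$ for purines and
$\widehat{v \times u}$ for pyrimidines.  $X$ is the origin-to-anchor
direction projected orthogonal to $Z$ (Gram-Schmidt), with the anchor being
the Watson-Crick edge atom: N1 in purines, **N3** in pyrimidines.
$Y = Z \times X$ completes a right-handed orthonormal triad.

Two choices here were genuinely open and deserve justification:

* **The anchor.** Anchoring $X$ at N1 for every base reads naturally from
  the usual frame descriptions, but in pyrimidines N1 is the *glycosidic*
  nitrogen: the O→N1 direction points at the sugar, and the Watson-Crick
  partner of a pyrimidine would then sit near θ ≈ 226°, in the sugar
  sector.  No pair could ever be "Watson-Crick on both edges", which is
  the definition of canonical used throughout.  Anchoring at the WC edge
  atom of each base family makes θ ≈ 0 the WC locus for every base, which
  is what the sector partition assumes.
* **The normal's sign.** Taking $Z = \widehat{u\times v}$ for both families
  would flip the in-plane handedness of pyrimidine frames, swapping their
  Hoogsteen and sugar sectors.  The chosen orientation puts the
  Hoogsteen/C-H edge at positive θ (≈ 100°) and the sugar edge at ≈ 280°
  uniformly.

The position of base *j* in base *i*'s frame is reported as (ρ, θ, z):
ρ ≥ 0 in-plane, θ in [0, 360) measured from X towards Y (θ := 0 when
ρ = 0), z signed along the normal.  Edge sectors default to
WC = [0°, 60°) ∪ [300°, 360°), Hoogsteen = [60°, 180°),
Sugar = [180°, 300°); the boundaries centre the empirical edge loci
(0°, ~100°, ~280°) and keep the sugar-occluded band (180–260°) inside the
sugar sector.  They are configurable, and no claim is made that they match
any external tool's dotted lines bit for bit.

A consequence worth stating plainly: with the origin at the *base* centroid,
ideal Watson-Crick pairs sit at ρ ≈ 5.8–5.9 Å (the two base centroids of a
standard geometry G-C or A-U pair are 5.77–5.91 Å apart).  Conventions that
place the origin further towards the sugar report larger WC radii (≈ 7 Å);
with this package's origin the WC locus is just below 6 Å.

# Pair and stack detection

The built-in detector is a deliberately simple geometric heuristic — it is
*not* a re-implementation of a full annotation tool, and when DSSR JSON is
supplied the DSSR annotation wins.  A pair (i, j) requires, with defaults
in parentheses (all configurable via `pairDetectionParams()`):

* at least `hbMin` (2) contacts below `hbDist` (3.4 Å) between polar base
  heavy atoms of the two residues,
* inter-plane angle (between Z axes, folded to ≤ 90°) below `planeMax`
  (65°),
* |z| below `zPairMax` (2.5 Å) in **both** partners' frames.

Stacking requires |z| in [2.5, 4.5] Å in both frames, ρ ≤ 5 Å and planes
within 30°.  Multiplets are allowed at detection; the motif layer reduces
them to one canonical partner per residue by hydrogen-bond support.  A pair
is **canonical** iff its bases are C-G, A-U or G-U *and* both edges are
Watson-Crick; all other pairs are non-canonical and enter pair statistics
only.  Full Leontis-Westhof cis/trans labels are never invented by the
detector; they are preserved verbatim when DSSR JSON is ingested.

# Motif decomposition

Pseudoknots are resolved exactly: a maximum-cardinality crossing-free
subset of the canonical pairs is selected by interval dynamic programming
(ties broken deterministically towards the earlier-opening pair), and the
removed pairs are reported as pseudoknotted and drawn in extra bracket
tiers.  The test suite validates the DP against exhaustive enumeration on
a thousand random instances.

Stems are maximal runs of consecutively stacked pairs (i,j), (i+1,j-1), …
Single-pair "stems" are reported separately as lone pairs and excluded
from the stem-length histogram by default (annotation tools whose stem
histograms peak at 2 bp count stems of at least two pairs; the convention
is configurable).  Loops are classified by bordering stems: hairpin (1),
bulge (2, one side empty), internal (2), junction (≥ 3); loop length is
the total number of unpaired nucleotides without distinguishing 5'/3'
sides.  Exterior (dangling) residues belong to no loop.  Decomposition is
per chain; inter-chain pairs count in pair statistics but not in loop
decomposition.

# Distance statistics

Distances are computed between heavy atoms of different residues only,
excluding the single covalent inter-residue contact (the phosphodiester
O3'-P link), so every distance is non-bonded.  Histograms use half-open
bins of 0.1 Å (configurable) over [0, 100) Å; out-of-range distances are
dropped with a logged count.  The bin width is a package choice — fine
enough to resolve the ~5.8 Å nearest-neighbour P-P peak without imposing
smoothing.  Named extracts (nearest-neighbour, second-neighbour and paired
P-P) separate the three short-range P-P peaks that dataset-level
distributions show near 5.7, 11.2 and 18.4 Å.

# Dataset aggregation and fits

Per-structure rows (id, L, Rg, Δ, S, pair counts) are aggregated into a
`DatasetSummary`.  The size-length relation is fitted as
$R_g = a L^b$ by unweighted least squares in log-log space, both over all
lengths and restricted to L < 100; base-pair counts are fitted through the
origin ($N_{bp} = kL$).  On noiseless synthetic points the fits recover
generator constants to numerical precision, which is how they are tested.
Pair-geometry classes (keyed by LW label when available, else by base
combination and edge sectors) are summarised by independent per-coordinate
Gaussians; θ uses the circular mean and circular standard deviation
($\sqrt{-2\ln R}$), since pair classes straddle the 0°/360° seam.  Full
covariance is deliberately not fitted: class populations in small datasets
do not support 3×3 covariance estimation, and the marginal parameters are
what downstream potential-building consumes.

# Synthetic fixtures: what they do and do not show

`makeDuplex()` stacks idealised planar Watson-Crick (or wobble) base-pair
templates — standard planar base geometries, partner obtained by the dyad
flip (x, y, z) → (x, −y, −z) — with a per-step twist of 32.7° and rise of
2.81 Å (A-form convention; package constants, configurable).  The phosphate
is placed at 9 Å radius, giving a nearest-neighbour P-P distance of
≈ 5.8 Å, and O3' is placed to make the backbone covalently consistent.
The rest of the ribose is a schematic geometric trace.  `makeHairpin()`
closes a stem with loop residues on a wide outward arc whose bases cannot
pair; seeds jitter coordinates (0.01 Å) without changing annotation.
`makePointCloud()` provides the degenerate rod/disc/octahedron cases that
attain the analytic shape bounds, plus seeded uniform clouds.

Because each fixture carries its construction as machine-readable ground
truth, detector and decomposition tests assert *exact* agreement.  What
passing these tests shows: the geometry, detection and decomposition code
paths are internally consistent and exact on ideal geometry.  What they do
not show: performance on real crystallographic data — real structures have
propeller twist, buckle, non-planar pairs, modified residues and disorder,
and the simple detector will disagree with a full annotation tool near its
thresholds.  That is why DSSR ingestion is the preferred source for
dataset-scale statistics.

# Problem sizes used in the tests

The shipped test-suite and acceptance runs use fixture-scale problems
chosen to exercise every code path while keeping the whole suite fast on a
single CPU: 1,000 seeded 50-point clouds for the shape-bound sweep, 100
random structures (N ≤ 200) for the tensor-oracle comparison, 50 seeded
duplexes of 4–20 bp for detector precision/recall, and 1,000 random
instances of ≤ 12 pairs for the pseudoknot resolver versus exhaustive
search.

# Known limitations

* The detector assigns edges only via θ sectors; cis/trans orientation is
  out of scope by design.
* Coaxial stack calling, k-way junction topology families and 2D layout
  drawing are not implemented.
* Dataset curation (non-redundant set construction from external
  databases) is outside the tested scope of the package.
* Modified-nucleotide mapping covers a small common table, not the full
  modification universe.
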