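---
title: "Detecting protein cavities between two Gaussian surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting protein cavities between two Gaussian surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gausscavity)
```

## The model

A protein's molecular envelope can be described implicitly by a *Gaussian
surface*: the level set $F(\mathbf{x}) = c$ of a field that sums one
Gaussian kernel per atom,

$$F(\mathbf{x}) = \sum_{i=1}^{n}
  \exp\!\left[-\beta\left(\frac{\lVert\mathbf{x}-\mathbf{x}_i\rVert^2}
  {\rho_i^2} - 1\right)\right],$$

where $\mathbf{x}_i$ is the centre of atom $i$ and $\rho_i$ its kernel
radius. Each kernel equals $e^{\beta}$ at the atomic centre, exactly 1 on
the sphere of radius $\rho_i$, and decays smoothly outside, so for a single
atom with $c = 1$ the surface is exactly the van der Waals sphere; for many
atoms the kernels cooperate and the level set forms a smooth molecular
envelope.

`gausscavity` builds **two** such surfaces from the same structure:

* the **inner surface**, with $\rho_i = r_i$, the van der Waals radii —
  a smooth approximation of the molecular surface itself; and
* the **outer surface**, with $\rho_i = r_i + w$, every radius inflated by
  the water-probe radius $w$ — an envelope that closes over any depression
  too narrow for bulk solvent.

A surface cavity — a pocket where a ligand or a water molecule could sit —
is precisely the space *between* the two: outside the protein proper, yet
under the outer envelope. Working with the two analytic fields directly
(no triangulation, no ray scanning) makes the classification independent of
scanning directions, which is the chronic weakness of visibility-based grid
methods.

### Parameters

| parameter | symbol | default | units | meaning |
|---|---|---|---|---|
| isovalue | $c$ | 1.0 | — | level of the level set; with $\beta = 2.3$ the pair $(1.0, 2.3)$ closely approximates the solvent-excluded surface |
| decay | $\beta$ | 2.3 | — | kernel sharpness; larger values make the surface hug the atoms more tightly |
| probe | $w$ | 1.4 | Å | water-molecule radius added to every atomic radius for the outer surface |
| spacing | $\Delta$ | 1.0 | Å | voxel edge length of the detection grid |
| `eps`, `min_pts` | — | $\sqrt{3}\Delta$, 1 | Å, — | DBSCAN clustering of cavity voxels (see below) |

Van der Waals radii come from a Bondi-style table (C 1.70, N 1.55, O 1.52,
S 1.80, P 1.80, H 1.20 Å, halogens included; default 1.70 Å for anything
else), user-overridable through a key=value file — structure files do not
carry radii, and published grid detectors differ slightly in the set they
adopt, so the table is deliberately explicit and replaceable.

## The procedure

`detect_cavities()` runs seven deterministic stages:

1. **Domain.** The bounding box of the atomic centres, padded by $2R$ on
   every side ($R$ = largest atomic radius), so both surfaces fall strictly
   inside.
2. **Grid.** The box is split into cubic voxels of edge $\Delta$. Node
   counts use a ceiling rule — a fractional box is covered, never
   truncated — and the slack the ceiling introduces is split equally
   between the two sides of each axis. The centring matters: with
   one-sided slack the node set does not map onto itself under axis
   mirroring, and cavity voxel counts would change when the structure is
   merely reflected or axes are relabelled. With centring, signed axis
   permutations leave counts exactly invariant, and translating the
   molecule translates the grid rigidly with it.
3. **Fields.** $F_{in}$ and $F_{out}$ are evaluated at every node. The
   squared distance separates along the axes, so each atom's contribution
   is a rank-one product of per-axis exponential vectors; contributions are
   accumulated blockwise with dense matrix products, which makes exact
   summation over all atoms practical (a 3000-atom structure on a
   $71^3$-node grid takes about two seconds on one CPU core). An optional
   truncated mode skips contributions below $10^{-12}$ (beyond distance
   $\rho_i\sqrt{1 + \ln 10^{12}/\beta}$), with absolute error at any node
   bounded by $n \cdot 10^{-12}$; it is off by default and
   verified against exact summation in the tests.
4. **Flags.** Every voxel gets an 8-bit flag per field, one bit per corner:
   bit $k$ is 1 iff the field at corner $k$ is *strictly* below $c$. A
   point exactly on the surface therefore counts as inside — the convention
   that makes "flag 255 = entirely outside" unambiguous. Flag 255 means all
   eight corners outside the surface; flag 0, all inside.
5. **Intermediate voxels.** A voxel between the surfaces satisfies
   `flag_in == 255 && flag_out == 0`: entirely outside the protein surface
   and entirely inside the probe-inflated envelope.
6. **Cavity voxels.** An intermediate voxel is a cavity voxel only when its
   full 3×3×3 voxel neighbourhood is intermediate. At $\Delta = 1$ Å this
   guarantees a 3 Å cube of empty space — room for a water molecule of
   radius 1.4 Å. Voxels on the grid index boundary never qualify. This
   neighbourhood condition is the only minimum-size rule applied; no
   separate volume threshold exists (a 3×3×3 block at $\Delta = 1$ Å is
   27 Å³, so any accepted cavity already clears the few-Å³ scale at which
   one could sensibly speak of a minimum cavity).
7. **Clustering.** Cavity voxel centres are grouped with DBSCAN. The
   defaults `eps` $= \sqrt{3}\Delta$, `min_pts` $= 1$,
   `min_cluster_size` $= 1$ make clustering equal 26-connected component
   labelling — the natural "aggregate of adjacent voxels" notion of a
   cavity — and are verified against an independent connected-component
   oracle in the tests. Stricter settings (`min_pts`, `min_cluster_size`
   above 1) demote sparse clusters to *rejected* clusters, the "negative
   cavities" that the evaluation layer scores as TN/FN. Each accepted
   cavity reports the unweighted mean of its member voxel centres as its
   geometric centre and `n_voxels * spacing^3` as its volume.

Numerical conventions worth knowing:

* **Boundary convention.** $F = c$ counts as *inside* everywhere
  (`inside_surface()`, flags, masks), consistent with the strict `< c`
  rule for the outside bit.
* **DBSCAN radius tolerance.** A distance equal to `eps` counts as a
  neighbour within a relative tolerance of $10^{-9}$; without it, voxel
  centres across an exact cube diagonal ($\sqrt{3}\Delta$) would be lost
  to floating-point rounding of $(\sqrt{3})^2$.
* **Determinism.** Points are visited in lexicographic voxel-index order,
  neighbour expansions in ascending index order, and clusters are numbered
  by their smallest member index, so repeated runs are byte-identical
  (reports differ only in a timestamp field).
* **Corner indexing.** Bit $k$ of a flag corresponds to the corner offset
  $((k)\,\&\,1, (k\!>>\!1)\,\&\,1, (k\!>>\!2)\,\&\,1)$ — frozen so flags
  are testable, although only the values 0 and 255 drive the algorithm.

## The evaluation protocol

Given ground-truth cavity centres (plain TSV: `protein_id`, `cavity_id`,
`x`, `y`, `z`), predictions are scored per protein:

* **Overlap condition.** A predicted centre can match a ground-truth centre
  at Euclidean distance $d \le d_{max} = 4.0$ Å — the scale below which two
  pocket centres describe extensively overlapping cavities, given that a
  minimum-size cavity is itself ~3–4 Å across.
* **Matching.** Candidate pairs are sorted by ascending distance (ties by
  predicted then truth index) and accepted greedily while both members are
  unmatched. The assignment rule is a design choice: greedy nearest-first
  is deterministic and cheap, and on instances whose true centres are
  farther apart than $d_{max}$ — which distinct binding sites are, by
  construction of the overlap condition — it coincides with the exhaustive
  optimal one-to-one assignment (maximum matches, then minimum total
  distance), which the test suite verifies combinatorially. On artificially
  dense configurations (several truth centres within 4 Å of one another)
  greedy can drop a match that optimal assignment would keep; such
  configurations do not occur in curated binding-site ground truths.
* **Confusion counts.** Matched accepted cavities are TP, unmatched
  accepted are FP. The matching is then repeated between rejected clusters
  and still-unmatched truth centres: matches are FN (real cavities the
  detector demoted), the rest TN. TP distances are binned into
  $[0,1], ]1,2], ]2,3], ]3,4]$ Å (first bin closed, later bins left-open).
* **Metrics.** Sensitivity $S_v = TP/(TP+FN)$, specificity
  $S_c = TN/(TN+FP)$, accuracy $a = (TP+TN)/(TP+FP+FN+TN)$, detection rate
  $r_d = TP/C$ and undetected count $C_u = C - TP$, with $C$ the
  ground-truth cavity total. Zero denominators yield `NaN` with a warning,
  never an error — an evaluation with nothing rejected simply has no
  defined specificity.

`cmd_evaluate()` also accepts raw `c(TP, FP, TN, FN)` totals plus `C`, so
published benchmark tables can be re-derived without re-running any
detector; the test suite and the acceptance script use the published
apo-protein column (TP = 7697, FP = 1033, TN = 2045, FN = 393, C = 8150)
and holo column (TP = 17191, FP = 2460, TN = 3231, FN = 440, C = 17850)
this way.

## What the synthetic fixtures emulate — and what they do not

The package ships generators rather than data files, so every stage is
testable from first principles:

* `make_single_atom()` — the closed-form case. The inner isosurface at
  $c = 1$ is exactly the atomic sphere; for arbitrary $(c, \beta)$ it sits
  at $r\sqrt{1 - \ln c/\beta}$. Detection must find nothing: between the
  sphere of radius $r \le 2$ Å and its probe-inflated envelope there is a
  shell of radial thickness ~1.4 Å, and no 3 Å cube fits in it.
* `make_atom_pair()` — additivity and field-dominance checks.
* `make_open_cage()` — the designed pocket: pseudo-carbon atoms on five
  faces of a cube, one face open, ground truth at the origin. The default
  half-width of 4.5 Å was chosen so the interior clears the 3×3×3 minimum
  *and* the probe-inflated surfaces of opposing walls close over the whole
  pocket. The geometry is genuinely tight in an instructive way: widen the
  cage to half-width 5 Å and the pocket middle falls outside the outer
  envelope, the intermediate region thins to a shell, and the cavity
  vanishes — the same mechanism by which the method distinguishes enclosed
  pockets from open concavities. The wall lattice is laid out symmetrically
  (endpoints included, requested spacing shrunk to fit) so the fixture has
  the mirror symmetries the invariance tests rely on.
* `make_random_molecule()` — seeded uniform atoms with radii in the common
  van der Waals range 1.2–2.0 Å, the substrate for property tests and for
  `brute_force_cavity_voxels()`, an oracle that recomputes both masks by
  direct per-node summation and naive triple-loop neighbourhood checks,
  sharing no code with the pipeline.

These fixtures exercise the geometry of the algorithm exhaustively, but
they are not proteins: they have no chemistry, no realistic packing
density, no crystallographic artefacts (alternate conformers, missing
atoms, waters) beyond what the PDB reader's filters are tested with, and
their pockets are box-shaped. Passing tests therefore demonstrate that the
implementation computes the specified geometry correctly — not that any
particular biological cavity will be found, which additionally depends on
radius sets, heteroatom policy and clustering settings.

### Test problem sizes

The suite checks oracle equivalence on grids of roughly $17^3$–$25^3$
nodes (single atom, atom pair, open cage, and twenty 8-atom seeded random
molecules), the clustering oracle on fifty random $9^3$ masks, and the
matching oracle on forty instances of up to six centres a side — sizes
chosen so exhaustive and brute-force oracles stay exact while the whole
suite runs in well under a minute; the field evaluator itself scales to
thousands of atoms (see above).

## Known limitations

* Clustering parameters beyond the 26-connectivity defaults (and any
  minimum cluster size) are judgement calls; published voxel detectors do
  not agree on them, and cavity counts on real proteins are sensitive to
  the choice.
* The detector classifies whole voxels, so sub-voxel pocket features are
  invisible at $\Delta = 1$ Å; halving $\Delta$ multiplies nodes by 8.
* Only the first model of multi-model PDB files and only the blank/`A`
  alternate-location conformer are used; occupancy-weighted conformer
  merging is out of scope.
* The evaluation layer takes ground-truth centres as given; how a curated
  resource derived them (ligand atoms vs pocket residues) is outside its
  remit.

## A worked run

```{r}
cage <- make_open_cage()
det <- detect_cavities(cage$molecule)
det

sc <- score_detection(cavity_centers(det), cavity_centers(det, "rejected"),
                      cage$truth)
sc
```
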