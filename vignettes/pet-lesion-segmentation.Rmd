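---
title: "Optimal-surface segmentation of PET lesions: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal-surface segmentation of PET lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petoss)
```

# The segmentation model

`petoss` treats lesion delineation in FDG-PET as the search for a closed
surface around a user-supplied center point. The assumptions are:

* the lesion is *roughly spherical* — more complex shapes are handled by
  multiple seeds whose results are OR-merged, and by interactive
  refinement;
* the lesion is *hot*: uptake decreases, on average, from the interior
  toward background;
* the uptake level at which a trained reader would place the boundary
  depends on the lesion's contrast over its local background, not on a
  fixed percentage of the maximum.

## Geometry

A recursively subdivided octahedron, projected to the unit sphere,
supplies `n_column` near-uniform directions (level 4 gives 1026). Along
direction `p_i`, nodes `n_(i,j)` sit at radii `gap, 2*gap, ..., r` from
the center: the innermost node is one gap from the center and the
outermost exactly at `r`. Defaults `r = 60` mm, `gap = 1` mm
(`n_node = 60`) cover head-and-neck lesions with millimeter boundary
resolution; voxel spacing does not enter the graph geometry because all
positions are in physical millimeters and uptake is sampled by trilinear
interpolation. Points outside the scan sample 0, so columns leaving the
volume see background-like values rather than edge artifacts.

The surface selects exactly one node per column. A hard constraint
forbids adjacent columns (mesh-edge neighbors) from differing by more
than `sc = 5` levels; a soft penalty charges `sp = 0.005` per level of
difference per adjacent pair. `sc` bounds boundary roughness outright;
`sp` breaks ties toward smoother surfaces without fighting real
boundary detail.

## Shell statistics and the adaptive threshold

The radial uptake profile is measured robustly: the shell `Omega_j`
(all nodes at level `j`) is summarized by its median, so a minority of
columns pointing into a neighboring hot structure cannot distort the
profile. From the profile's central-difference gradient we locate

* `j_low`, the steepest descent, weighted by the linear center bias
  `(n_node - (j+1)) / n_node` that damps occasional outside objects
  appearing at large radii;
* `j_hi`, where the descent has leveled off — found on a
  running-maximum *modified gradient* that never decreases beyond
  `j_low`, at the first level reaching `min(0, max(grad_mod))`;
* `j_knee`, where the modified gradient has recovered three quarters of
  the way from its `j_low` value to its `j_hi` value; `kn` is the shell
  median there, the uptake at which the lesion fades into background
  (not background itself).

The innermost and outermost shells are excluded from every scan (they
represent degenerate solutions), and all argmin/argmax ties resolve to
the smallest index so results are deterministic. A profile with no
gradient at all (seed in homogeneous background) is a hard error rather
than a silent nonsense segmentation.

The threshold is `Th = kn + Th% * (pe - kn)` with
`Th% = 0.8 * exp(-0.15 * gamma^1.5)` and `gamma = pe/kn`: contrast 2
gives roughly a 50% threshold; higher contrast pushes the boundary
relatively closer to background (a "safety margin" reflecting clinical
tracing practice); lower contrast raises it moderately. Fixed 40%/50%
variants (`threshold_mode = "fixed40"/"fixed50"`) use the same
`(kn, pe)` scale and suit volume-estimation applications. `kn` is
clamped to `1e-6` when non-positive, which can happen on noise-free
synthetic backgrounds at exactly zero.

## Node costs

Above `Th` the cost rises linearly from 0 (at `Th`) to 1 at the center
uptake, so hotter-than-threshold tissue is increasingly expensive.
Below `Th` the cost is the right-to-left monotone increasing envelope
of the normalized uptake histogram of the spherical region: an uptake
value is as expensive as the *most common* uptake at or above it, which
makes common (background-like) values expensive while rare transition
values stay cheap. The histogram uses 100 bins over the occupied range
of the region resampled isotropically at 1 mm; the region median for
the rejection rule is computed over the same resampled set. Costs are
compared to `Th` with a `1e-12` tolerance for the exact-threshold
branch.

Rejection (+6, far above the 0–1 base range) applies to the three
innermost nodes of every column and, beyond the protected level, to
every node on a column whose running-minimum uptake has dropped below
the region median — once a column has crossed background, everything
further out on it stays rejected.

## Exact optimization

The constrained minimum is found via the standard optimal-surface
transformation to a minimum s-t cut: per-column weights are consecutive
cost differences with a strongly negative bottom weight, intracolumn
and hard-constraint arcs get effectively infinite capacity, and the
soft penalty becomes bidirectional arcs of capacity `sp` between
same-level nodes of adjacent columns. Two numerical choices matter:

* **Integer capacities.** All capacities are scaled by `2^24` and
  rounded, so max-flow arithmetic in doubles is exact and an arc's
  saturation is an exact comparison. This quantizes costs at about
  `6e-8` — far below any meaningful cost difference — and removes the
  floating-point tolerance that would otherwise make the residual-graph
  cut extraction unreliable on large graphs.
* **Deterministic tie-breaking.** Among co-optimal surfaces the
  *minimal* source side of the residual graph is taken. Optimal closed
  sets form a lattice, so this is simultaneously the componentwise- and
  lexicographically-smallest optimal level assignment — determinism
  without any cost perturbation.

Objectives are always recomputed from the selected levels with the
original (unquantized) costs. `resolve_with_updates()` is contractually
identical to a fresh solve; warm-starting is an internal optimization
left for future work.

An independent reference solver (`solve_surface_reference`) computes
the same minimum by min-sum variable elimination over the column
adjacency graph (greedy min-fill order; the elimination kernel is
compiled code because the 18-column validation graph already has
elimination width 8). The two implementations share no algorithmic
path and cross-check each other in the test suite on top of true
brute-force enumeration for 6-column graphs.

## Refinement

Global refinement replaces `Th` by the uptake under the user's point,
rebuilds the base costs and pins the nearest column to its nearest node
by adding 1000 to every other node on that column; repeated global
refinements override each other. Local refinement pins its column the
same way and searches columns within graph distance 5 for similar
uptake patterns (sum of absolute profile differences over a ±3-level
window, threshold 5% of the candidate's own profile magnitude, matched
level within the graph distance of the anchor level); matched columns
receive a triangular notch of depth 3 whose half-width grows with graph
distance — narrow certainty near the click, wide guidance further away.
The notch shape `-depth * max(0, 1 - |j - c|/(w + 1))` is this
package's concrete choice for the published qualitative description.
The ±3 window is clamped at column ends; columns already anchored by a
user point are never modified by later refinements, except that a new
anchor on the same column replaces its anchor level. Every action
snapshots the prior state, so undo is bit-exact by construction, and a
replayed action log reproduces the session exactly.

## Modes

*Label avoidance* rejects, on each column, every node from the first
contact with a foreign nonzero label outward — the new surface cannot
enter or skip over an existing segmentation.

*Splitting* separates adjacent lesions of similar uptake. Two
marker-based watersheds partition the supra-threshold region: "strong"
markers come from a 3 mm-smoothed field, "weak" markers from the raw
field (both flood the raw uptake in decreasing order, 26-connected,
deterministic). Once a column enters a strong basin other than the
seed's, that node and everything beyond it is rejected; weak foreign
basins add a half-strength bias. Making the strong penalty monotone
outward (rather than pure basin membership) is a deliberate
reconstruction: without it the surface can skip over the neighboring
lesion and close behind it through cheap below-threshold nodes, which
defeats the feature's purpose.

*Necrotic mode* handles cold-cored lesions with three changes:
recentering is disabled (the local maximum is on the rim, not the
center), the running-minimum rejection is disabled (it fires inside the
cold core), and two reconstructions close gaps the published
description leaves open: above-threshold costs are normalized by the
peak shell uptake instead of the (cold) center uptake, and a
rim-enclosure term rejects nodes on a column until the column's
running-maximum uptake has reached `Th`, so the surface must enclose
the hot rim rather than collapse into the core.

## Voxelization

Surfaces produced by the solver are star-shaped around the seed, so the
voxel-center-inside test is radial and exact: a voxel center is inside
iff its distance to the center does not exceed the intersection of its
direction ray with the containing mesh triangle's plane (tolerance
`1e-9` mm, so centers exactly on the surface count as inside). For
star-shaped closed meshes this is equivalent to parity ray casting but
has no edge/vertex degeneracies. Voxelization is followed by 6-connected
cleanup around the seed; one-voxel gaps within a label can optionally be
closed by a cross-element morphological closing restricted so different
labels are never bridged.

# The phantom generator

`generate_phantom()` emulates what the method needs from real PET:
spherical lesions of configurable radius and peak over a uniform
background, blurred by a Gaussian point-spread function
(`sigma = FWHM/2.3548`; clinical reconstructions smooth at roughly
5–7 mm FWHM), optional additive Gaussian noise with a fixed seed, and
optional cold cores. Ground truth is the pre-blur sphere mask. The
default grid is 96³ voxels at 2 mm, background 1.0, peaks 4–8.
`adjacent_pair_scene()` builds two 6 mm-radius equal-peak lesions at a
chosen center separation: 25 mm at FWHM 5 keeps them distinct, 14 mm at
FWHM 7 fuses them above threshold — the two regimes the splitting and
label-avoidance modes exist for.

What the phantoms deliberately do **not** emulate: textured anatomical
background, scanner-specific noise correlation, partial-volume effects
beyond Gaussian blur, and non-spherical lesions. Two consequences for
interpreting results:

* With a *uniform* background, the uptake histogram of the region is a
  spike: transition values between background and threshold are rare
  and therefore cheap under the envelope cost. The boundary then sits
  at the threshold crossing (the intended behavior) but tests on such
  phantoms cannot probe how the envelope term suppresses background
  heterogeneity in clinical images.
* Dice against a binary sphere truth saturates well below 1 by design:
  on the 10 mm / 4:1 / FWHM 5 phantom the adaptive threshold is ~1.87,
  whose isocontour lies at ~11.2 mm, so even a perfect
  threshold-following surface yields Dice ≈ 0.84. The measured 0.82 is
  the method working as designed (a deliberate margin below the 50%
  isocontour), not a failure to find the optimum — the solver's
  optimality is verified independently and exactly.

# Problem sizes and runtime choices

The validation suite exercises full-resolution graphs (1026 columns ×
60 nodes, a single max-flow over ~1.5 million arcs) for the end-to-end
phantom recovery, and smaller meshes (levels 0–3) where exhaustive or
dynamic-programming cross-checks are the point: brute-force enumeration
is feasible to 6 columns × 8 levels, the elimination reference to 18
columns. Two-lesion mode scenes run at mesh level 3 with `r = 40` mm.
These sizes keep the whole suite and the acceptance script in the
range of a few minutes on one CPU while still covering every code path
at clinically realistic resolution at least once.

# Known limitations

* Shapes far from star-shaped around the seed (strongly concave
  lesions) cannot be represented by one column graph; multiple seeds
  with OR-merging are the supported workaround.
* The histogram envelope assumes the background dominates the region's
  uptake mass; tiny fields of view around large lesions would weaken
  the below-threshold cost.
* Oblique (non-axis-aligned) scan orientations are rejected on read
  rather than resampled.
* `resolve_with_updates()` re-solves from scratch; for interactive
  latency on very large graphs a true warm start would be the first
  optimization to add.
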