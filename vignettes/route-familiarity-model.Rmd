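---
title: "A familiarity-based model of visual route navigation in ants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A familiarity-based model of visual route navigation in ants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antroute)
```

## The model

Desert ants such as *Melophorus bagoti* guide habitual foraging routes
visually, with low-resolution panoramic vision, and can do so without
compass or odometric input. `antroute` implements a parsimonious model of
how: because an ant faces the way it walks, every view experienced along a
route implicitly specifies a direction of travel. If the ant can judge how
*familiar* a view is, route guidance reduces to a scanning routine — look
around, and step towards the direction whose view is most familiar. The
same mechanism yields nest search when the memory also contains views from
a nest-centred learning walk.

The package implements the full pipeline:

1. **World** (`build_world`): flat black triangular patches form grass
   tussocks (26-patch inverted cones, randomly perturbed and rescaled)
   scattered uniformly over a central region, plus a distant panorama of
   flat trees and bushes at 20–50 m that provides a stable skyline frame.
2. **Vision** (`render_view`): from any pose, patch vertices are
   translated to the eye, converted to azimuth/elevation (radial distance
   discarded), rasterized into a binary high-resolution image of the
   silhouettes against the sky, and block-averaged down to a 17 × 90
   panorama of grey values in [0, 1] — 1530 pixels, roughly the ant's
   sampling resolution. Rotating the viewer by a multiple of the 4°
   column width is exactly a circular column shift of the image, the
   property that makes panoramas usable as a visual compass.
3. **Training routes** (`generate_training_route`): homeward paths are
   scaffolded by simulated path integration — a Gaussian over headings
   centred on the home bearing — multiplied by the proportion of visible
   sky in each direction raised to the 4th power (obstacle avoidance),
   renormalised and sampled; a 4 cm step is taken and a view is collected
   after every step, facing the direction of travel. **Learning walks**
   (`generate_learning_walk`) loop around the nest (0.5 m circular
   outbound arcs, straight inbound legs, samples every 2 cm); only the
   inbound legs give consistent nest-directed views, which is what later
   makes nest search work.
4. **Memory**: either a *perfect memory* (`view_store`) scoring a view by
   minus the minimum sum-squared pixel difference against every stored
   view (over all rotations, `perfect_familiarity`), or an *Infomax
   novelty network* (`infomax_init`, `train_route_network`) — a single
   fully connected layer of M novelty units trained by one ordered pass
   over the training views with the natural gradient of mutual
   information:
   h = W x, y = tanh(h), ΔW = (η/M)(W − (y + h) hᵀ W).
   The novelty response d = Σᵢ|hᵢ| is low for inputs well described by
   the learned components; familiarity is −d. Each view is presented
   once and discarded, so memory stays O(M·N) however long the route.
5. **Navigation** (`recapitulate`): at each step the agent renders its
   panorama, derives candidate views for each scan direction by exact
   column shifts, scores them with the memory, turns to the most familiar
   direction, adds Gaussian heading noise, and advances 10 cm. Scans are
   full 360° for the perfect memory and frontal 90° (centred on the
   previous direction of travel) for the network. `familiarity_map`
   runs the full scan over a grid to produce familiarity/heading maps.

## Parameters and defaults

| parameter | default | units | notes |
|---|---|---|---|
| panorama resolution | 17 × 90 | pixels | 4°/pixel, fixed |
| high-res raster | 40× (680 × 3600) | — | `oversample`, exact block multiple |
| vertical field of view | [0, 68] | deg | silhouettes above the horizon only |
| eye height | 0.01 | m | ant-scale viewpoint |
| tussock patches | 26 | — | fixed base model |
| tussock rim radius / height | 0.15–0.6 / 0.125–0.5 | m | template × scale draw |
| tussock density | 0.75 | m⁻² | experiment worlds; 0.05 sparse variant |
| panorama objects | 50 in [20, 50] | — / m | flat, facing the region |
| central region | 20 × 20 | m | nest at the centre |
| PI Gaussian σ | 15 | deg | training-route wobble |
| avoidance exponent | 4 | — | sky proportion power |
| training step / termination | 0.04 / 0.04 | m | one view per step |
| learning-walk radius / spacing / loops | 0.5 / 0.02 / 3 | m / m / — | alternating sweep sides |
| Infomax η / M | 0.01 / 1530 | — | M = N; M = 200 works and is cheaper |
| scan step / frontal width | 4 / 90 | deg | 90 or 23 candidates |
| recap step / heading noise σ | 0.10 / 10 | m / deg | noise added after choosing |
| goal radius / step cap | 0.20 / 5·L/0.1 | m / steps | success must be decidable |

Several of these are not constrained by the behavioural literature the
model draws on (raster size, vertical field of view, σ values, scan
widths, tussock geometry, region size, loop count); they are exposed as
configuration and the defaults above are this package's choices, made
once and used for every experiment.

## Numerical choices

**Rasterization** uses pixel-centre-in-triangle coverage on the
high-resolution binary raster (implemented as a per-column scanline fill,
exact for the convex triangles used everywhere); grey values come only
from the subsequent block average, mirroring the binary-then-average
scheme. Triangles crossing the ±180° azimuth seam are handled by
unwrapping each triangle's vertex azimuths to a contiguous interval and
wrapping column indices modulo 360°, which is equivalent to splitting at
the seam and is covered by a bit-exactness test against re-rendered
rotated poses. Patches degenerate at the eye point are skipped with a
warning. The projection treats triangle edges as straight in
azimuth–elevation space; near the zenith this is an approximation, but
the scene geometry (ground-based silhouettes within 68° of the horizon)
keeps it benign.

**Infomax input conditioning.** The natural-gradient update shrinks the
weight component along a presented input by a factor of roughly
η‖x‖². Feeding raw [0, 1] panoramas (‖x‖² in the hundreds) or per-view
standardised vectors (‖x‖² = N = 1530) makes this factor ≫ 2 at
η = 0.01, and the weights oscillate divergently to overflow within a few
presentations — we verified this numerically. Views are therefore
centred and scaled to unit Euclidean norm by default (`normalize_input =
"norm"`), giving a stable, scale-free 1% contraction per presentation;
`"sd"` and `"none"` remain available for experimentation. Conditioning
changes the numeric scale of the novelty score but not which of a scan's
candidates ranks most familiar.

**Tie-breaking** is deterministic everywhere: `perfect_familiarity`
prefers the smallest rotation magnitude then the earliest stored view;
the scan argmax prefers the smallest absolute turn then clockwise.

**Seeding.** Every experiment derives named sub-seeds (world, each
route, network init, each recapitulation) from one master seed, so any
result reproduces bit-exactly from its configuration.

## What the synthetic worlds do and do not capture

The generator emulates the visual structure of the model's target
habitat: near-field clutter whose silhouettes dominate and change quickly
with movement, against a stable distant skyline. It does not model
colour, texture, illumination, terrain relief, wind-blown motion, or the
actual trajectories of real foragers — the training routes here are
path-integration simulations, not digitised ant paths. Tests passing on
these worlds show that the algorithmic claims hold (rotational
equivariance, on-route guarantees, single-pass learning, route-memory
retention), not that performance numbers transfer quantitatively to any
real environment.

Success of a noisy recapitulation is a stochastic event whose probability
depends strongly on the interplay of clutter geometry, the width of the
learned route corridor and the heading-noise amplitude; with the defaults
above, the high-density (0.75 m⁻²) worlds sit deliberately near the limit
of single-run learnability, and repeated training runs are what make
recapitulation reliable.

## Problem sizes used in the tests

The test suite exercises every pathway at sizes chosen to keep a full run
in the tens of minutes on one core: the shared fixture is an 8 × 8 m
world with 6 tussocks, 12 panorama objects, a straight 1.6 m route and a
one-loop learning walk, rendered at 4× oversampling; the experience-curve
suite runs 10 master seeds at 4× oversampling with M = 200 novelty units
(success counts at these reduced sizes run below those at the full sizes;
the trend over training runs is what transfers); the learning-walk
contrast uses 10 fixture seeds; multi-route retention runs 5 seeds at the
full M = N = 1530 with 8× oversampling. The acceptance script
(`scripts/acceptance.R`) runs the experience-curve endpoint at 8×
oversampling with M = N = 1530.

## Known limitations

* The motor model is the scanning routine only; fine-grained ant
  kinematics (continuous scanning, saccades) are out of scope.
* Familiarity-gradient following (descending the familiarity surface
  rather than scanning) is not implemented.
* The navigator assumes a flat world; there is no terrain occlusion of
  the agent itself.
* Off-route behaviour far from the training corridor is undefined by
  design: the memory only ranks candidate views, and far from anything
  familiar those rankings approach chance, as the familiarity maps show.
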