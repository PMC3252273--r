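# antroute

Agent-based simulation of **visually guided route navigation in desert
ants**, for computational neuroethologists and roboticists studying
minimal mechanisms of insect navigation.

The core idea: because an ant faces the way it walks, the views
experienced along a habitual route implicitly define the actions needed
to retrace it. Navigation can then be recast as *familiarity search* — at
each step, scan candidate directions and move towards the view that best
matches what was seen during training. `antroute` implements the whole
loop in simulation:

* **procedural worlds** of flat black triangular patches: grass tussocks
  (26-patch inverted cones, perturbed and rescaled) at a chosen density,
  plus a distant panorama of trees and bushes at 20–50 m;
* an **ant-eye visual system**: spherical projection of the world from
  any pose, binary high-resolution rasterization of the silhouettes
  against the sky, and block-average down-sampling to a 17 × 90 panorama
  (N = 1530 pixels, values in [0, 1]);
* **training data**: homeward routes scaffolded by path integration
  (Gaussian over headings centred on the home bearing, modulated by the
  visible-sky proportion s(θ)⁴ for obstacle avoidance, 4 cm steps) and
  nest-centred **learning walks** (0.5 m loops, 2 cm sampling);
* two **route memories**:
  * *perfect memory* — familiarity of a view is −min SSD over all stored
    views and rotations (the rotational image difference function),
  * *Infomax novelty network* — a single-pass, natural-gradient
    familiarity discriminator: h = Wx, y = tanh(h),
    ΔW = (η/M)(W − (y + h)hᵀW), novelty d = Σ|hᵢ|, with constant O(M·N)
    memory however long the route;
* a **scanning navigator**: render once, derive each scan candidate by an
  exact column shift, move 10 cm towards the most familiar direction with
  Gaussian heading noise; plus familiarity/heading grid maps and scripted
  experiments (experience curves, blocked-nest learning-walk search,
  multiple-route retention).

## Worked example

```r
library(antroute)

# a miniature scenario: 8 x 8 m world, 6 tussocks, 12 panorama objects,
# a straight 1.6 m training route and a one-loop learning walk
fx <- make_fixture(seed = 2)
fx$world
#> <ant_world>
#>   region: 8 x 8 m, nest at (0, 0), seed 2
#>   objects: 6 tussocks, 0 landmarks, 12 panorama
#>   patches: 760

v <- render_view(fx$world, pose(0, -1.6, heading = 0), oversample = 4)
dim(v)          # the ant's view: 17 elevation rows x 90 azimuth columns
#> [1] 17 90

# perfect memory: store the route views, then recapitulate with noise
store <- view_store(fx$route$views)
rec <- recapitulate(fx$world, store, start = c(0, -1.6),
                    motor = motor_params(heading_noise_sd = 10),
                    seed = 21, oversample = 4)
rec
#> <recap_result> reached goal after 15 steps (min goal distance 0.138 m)

# Infomax: one ordered pass over walk + route views, then navigate with
# a frontal 90-degree scan
set.seed(9)
net <- infomax_init(n_input = 1530, n_novelty = 200)
net <- train_route_network(net, fx$views)
recapitulate(fx$world, net, start = c(0, -1.6),
             policy = scan_policy("frontal"),
             motor = motor_params(heading_noise_sd = 0),
             seed = 4, oversample = 4)
#> <recap_result> reached goal after 15 steps (min goal distance 0.187 m)
```

The recapitulation result reports whether the agent came within the goal
radius (0.20 m) of the nest, how many 10 cm steps it took, and its
closest approach. `familiarity_map()` produces the pseudocolour +
heading-quiver maps over a grid; `plot()` methods draw worlds, paths and
maps (training paths red, recapitulations black, by convention).

A thin command-line wrapper over the same functions is included at
`inst/scripts/antroute.R` (subcommands `world`, `route`, `walk`,
`train`/`recap` via `experiment`, `map`), writing OBJ worlds, TSV paths
and TSV familiarity maps.

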