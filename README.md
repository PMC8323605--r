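# msotrack

Identity-preserving tracking of multiple small aquatic organisms — zebrafish
larvae, *Artemia*, *Daphnia* — in time-lapse microscopy video.

Small organisms are hard to track automatically: they are a few hundred
pixels in size, they move in sudden bursts separated by long stationary
periods (activity below ~7.5% of frames), they overlap and occlude one
another, and realistic recordings are littered with bubbles and impurities
that segment like organisms. msotrack is built for exactly these
conditions. It is a pipeline of five stages, each usable on its own:

1. **Segmentation** — an adaptive per-pixel Gaussian-mixture background
   model. A pixel is background only once its matched mixture component's
   weight exceeds a threshold *c*<sub>f</sub>, so an organism that stops
   moving keeps being detected for about
   log(1 − *c*<sub>f</sub>)/log(1 − α) frames before it is absorbed (≈ 288
   frames at the defaults α = 0.001, *c*<sub>f</sub> = 0.25). Foreground
   masks are cleaned by median filtering, erosion with a flat diamond
   structuring element, and size-based noise removal; each 8-connected
   component yields one centroid detection.
2. **Association** — detections in consecutive frames are linked by
   minimum-total-cost one-to-one assignment (rectangular Kuhn–Munkres) on
   the Euclidean cost matrix *d*(S<sub>i</sub>, T<sub>j</sub>) =
   √((x<sub>j</sub>−x<sub>i</sub>)² + (y<sub>j</sub>−y<sub>i</sub>)²).
   A source whose distance to every target exceeds δ · median(*d*) is
   rejected as a segmentation noise fragment.
3. **Gap bridging** — trajectory fragments broken by mis-detection or
   occlusion are rejoined by the same assignment machinery, searching 2 to
   6 frames ahead; the missing positions are estimated by uniform linear
   interpolation, x<sub>miss</sub> = x<sub>s</sub> + (k/j)(x<sub>t</sub> −
   x<sub>s</sub>), and flagged.
4. **Kinematics** — per-transition velocity (px/s), acceleration (px/s²)
   and heading (radians), plus per-individual box-plot summaries.
5. **Evaluation** — CLEAR MOT metrics against ground truth:
   MOTP = Σ<sub>i,t</sub>|P<sub>i,t</sub> − GT<sub>i,t</sub>| /
   Σ<sub>t</sub>N<sub>t</sub> (mean position error, px; lower is better)
   and MOTA = 1 − Σ<sub>t</sub>(M<sub>t</sub> + FP<sub>t</sub> +
   SII<sub>t</sub>) / Σ<sub>t</sub>g<sub>t</sub> (1 is ideal; negative
   values are possible).

A synthetic-scene generator (`scene_config()`, `simulate_trajectories()`,
`make_crossing_pair()`, `render_frames()`) produces renderable scenes with
exact ground truth — bursty two-state Markov movement, engineered
crossings/occlusions, blinking noise fragments — and drives the entire test
suite. See the vignette `tracking-small-organisms` for the models, the
parameter rationale, and design decisions.

## Worked example

Simulate a Daphnia-scale scene (480 × 640 px, 14 fps, five bursty
organisms), track it, score it against its own ground truth, and summarise
locomotion:

```r
library(msotrack)

cfg    <- scene_config(n_organisms = 5, n_frames = 200, seed = 42)
gt     <- simulate_trajectories(cfg)
frames <- render_frames(gt, cfg)

res <- track_frames(frames)
res
#> track_result: 5 trajectories from 1000 detections (200 frames)
#>   5 fragments bridged over 0 joins; 0 detections rejected as noise

report <- evaluate_tracking(res$trajectories, gt, eval_config(gate = 22))
report
#> CLEAR MOT report over 200 frames (gate 22 px)
#>   MOTP: 0.0605 px   MOTA: 1.0000
#>   misses 0, false positives 0, identity swaps 0 (of 1000 ground-truth objects)

kin <- track_kinematics(res$trajectories, fs = cfg$frame_rate)
head(summarize_individuals(kin)[, c("track_id", "velocity_median",
                                    "velocity_mean", "velocity_max")])
#>   track_id velocity_median velocity_mean velocity_max
#> 1        1               0     11.391226     91.59051
#> 2        2               0      8.368409     82.52122
#> 3        3               0      7.203884     77.92715
#> 4        4               0      7.361453     86.90111
#> 5        5               0      6.633658     80.28064
```

Every organism keeps a single identity across all 200 frames; the mean
position error is 0.06 px and MOTA reaches its ideal value 1. The median
velocity of 0 px/s is the bursty phenotype: most transitions are
stationary, while peak dart speeds reach ~80–90 px/s. `plot(res$trajectories)`
draws the paths; `plot(kin, type = "box")` gives one velocity box per
individual.

Occlusions are handled the same way end to end: a crossing pair whose blobs
fully merge for up to 5 frames is recovered as two identities with zero
swaps, the hidden positions filled by flagged interpolated points
(`make_crossing_pair()` builds such scenes; see the acceptance tests).

## Command line

A thin CLI wraps the same functions (input: a directory of numbered PNGs or
a multi-page TIFF; AVI/MP4 must be extracted to frames first):

```sh
inst/cli/msotrack simulate --preset daphnia --seed 4 --out scene
inst/cli/msotrack track scene/frames --out out
inst/cli/msotrack evaluate out/tracks.csv scene/ground_truth.csv --gate 22 --out report.json
inst/cli/msotrack kinematics out/tracks.csv --fps 14 --out kin
```

Configuration files are flat dotted key–value documents
(`segmentation.alpha = 0.001`, `association.delta = 3`, …); every `track`
run echoes its configuration into the output directory. File schemas:
detections `frame,det_id,x,y`; tracks `track_id,frame,x,y,interpolated`;
ground truth `track_id,frame,x,y,visible`; all frames 0-based, x = column,
y = row.

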