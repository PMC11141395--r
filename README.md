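# bitecount

Rule-based bite counting from facial-landmark video data, for
eating-behavior researchers who need per-meal bite counts without
manual annotation.

Meal videos are reduced to a per-frame **mouth ratio** computed from a
468-point 3D face mesh — the Euclidean distance between the upper and
lower lip key points (mesh indices 0 and 17) divided by the distance
between the mouth corners (61 and 291):

    r_t = ||p_0 - p_17|| / ||p_61 - p_291||

The ratio is near 0 for a closed mouth and rises during a bite. After
per-participant z-score outlier removal and a trailing 5-frame moving
average, a bite is counted for every maximal run of consecutive frames
with `r_t > θ`: one mouth opening, one bite, however long it stays
open. The threshold `θ` is the model's only parameter. It is tuned per
participant against manually annotated counts by grid, random, or
Bayesian search, each cross-validated with `k = min(5, max(2, n))`
folds under the objective `-(1/n) Σ |predicted_i - annotated_i|`, and
transferred to unannotated participants as the leave-one-out mean of
the other participants' tuned thresholds.

Evaluation uses the pooled-count accuracy

    A = | 100 - 100 * |P - T| / T |   (percent)

applied to annotated (`T`) and predicted (`P`) bite totals per
participant or condition group — with the documented fold-back of the
absolute value when `P > 2T`, flagged with a warning because such a
score flatters a large over-count.

Because no landmark data ship with the package, a synthetic module
generates ratio traces, full 468-point landmark series and whole
annotated cohorts with known ground truth (planted bite onsets and the
separating threshold band), and every mechanism is tested against
those and against independent brute-force oracles.

## Worked example

```r
library(bitecount)

# a small annotated cohort with known ground truth
coh <- simulate_cohort(n_participants = 3, videos_per_participant = 5,
                       seed = 42)
fit <- fit_bite_counter(coh$series, coh$annotations, method = "random",
                        control = search_control(seed = 7))
fit
#> Rule-based bite counter (random threshold search)
#>   3 participant(s), 15 video(s)
#> Per-participant thresholds:
#>   P01   P02   P03
#> 0.286 0.286 0.286
summary(fit)
#> Bite-count accuracy by participant
#>  group annotated predicted accuracy foldback
#>    P01       211       211    100.0
#>    P02       174       174    100.0
#>    P03       137       137    100.0
#> Total: 522 annotated / 522 predicted
#> Mean accuracy 100.0 (sd 0.0)
```

Every participant's tuned threshold lands in their true separating
band (here the bands overlap, and the seeded candidate stream is shared
across participants, so the smallest perfect candidate — 0.286 — wins
for all three), and all 522 annotated bites are recovered exactly.
Detection on a single video gives timestamped events:

```r
sim <- simulate_ratio_trace(trace_config(n_bites = 4, seed = 3),
                            video_id = "demo")
detect_events(sim$series, bite_model(threshold = 0.45))
#> Bite detection for 'demo': 4 bite(s) at threshold 0.45
#>   onset_frame onset_time_s peak_ratio duration_frames
#> 1         532     17.73333  0.7402874              12
#> 2         682     22.73333  0.7593167              12
#> 3        1089     36.30000  0.7117755              13
#> 4        1477     49.23333  0.7797412              12
```

`accuracy` applied to published-scale totals:

```r
bite_accuracy(554, 524)   # 94.58484 -> reported as 94.6
round_half_up(suppressWarnings(bite_accuracy(502, 1334)))  # fold-back: 65.7
```

A thin command-line front end over the same functions is installed at
`inst/scripts/bitecount` (subcommands `detect`, `tune`, `transfer`,
`evaluate`, `simulate`).

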