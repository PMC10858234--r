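# spinefuse

Rule-based fusion, anatomical labeling and panoptic evaluation of
vertebral-body segmentations from lateral spinal X-rays.

## The problem

Automated segmentation of vertebral bodies on lateral spine radiographs is
usually done with one of two styles of network, and each fails in its own
characteristic way:

* a **semantic** segmenter (per-pixel foreground/background) cannot separate
  two vertebral bodies that nearly touch — narrowed disc spaces or
  syndesmophytes merge neighbours into one connected blob;
* an **instance** segmenter (per-object masks behind detected boxes) keeps
  objects separable but misses partially visible bodies at the film edge,
  because the box detector never fires on an incomplete shape.

`spinefuse` is for image-analysis practitioners who already have both kinds
of output (or any two segmentations with these failure profiles) and want a
single, separated, anatomically labeled set of vertebral masks plus honest
evaluation numbers. Everything is testable without images: a seeded
synthetic spine generator reproduces both failure modes.

## The method

Let `{Cᵘ}` be the candidate contours extracted from the semantic raster
(8-connected components, holes filled) and `{Cᵐ}` the instance masks. With

```
δ(Cᵢ, Cⱼ)   = area(Cᵢ ∩ Cⱼ) / max(area(Cᵢ), area(Cⱼ))     (agreement)
δₘ(Cᵘ, Cᵐ)  = area(Cᵘ ∩ Cᵐ) / area(Cᵐ)                     (instance coverage)
```

three rules build the final mask set (threshold `η = 0.6` by default):

1. **Agreement union** — cross-compare all pairs; greedily match one-to-one
   by descending δ; every pair with `δ > η` contributes the union of the two
   masks.
2. **Instance takeover** — a remaining pair with `δ < η` and `δₘ > η` flags
   a semantic blob spanning several instances; the instance mask is taken
   directly, splitting the blob.
3. **Pickup** — unused masks whose area lies within `λ·σ` of the mean kept
   area (`λ = 2` by default) are re-admitted, recovering bodies one source
   missed; a picked-up mask must not overlap a kept mask (IoU ≤ 0.25).

Kept masks are sorted top-to-bottom. Labeling anchors on a reference
vertebra the instance segmenter can recognize — cone-shaped **C2** at the
top of cervical films or triangular **S1** at the bottom of lumbar films —
and zips along the column: C2 → C3 … C7, T1, …, or S1 → L5 … L1, T12, ….

Evaluation reports per-class Dice and Panoptic Quality

```
PQ = Σ_{(p,g)∈TP} IoU(p,g) / (|TP| + ½|FP| + ½|FN|) = SQ × RQ
```

with true positives defined as same-label pairs above an IoU threshold
(0.7 and 0.8 by default), so identification errors are part of the score.

## Worked example

```r
library(spinefuse)

gt  <- generate_spine(spine_spec("cervical", 7, seed = 42))
cs  <- corruption_spec(p_merge = 0.2, p_drop = 0.2,
                       boundary_jitter_px = 1, seed = 5)
sem  <- corrupt_semantic(gt$masks, cs)   # merged-blob semantic raster
inst <- corrupt_instance(gt$masks, cs)   # instance list with drops

spine <- label_pipeline(sem, inst)
spine
#> <labeled_spine> reference: C2 (zip_down) | 7 labeled, 0 unlabeled
#>   C2 C3 C4 C5 C6 C7 T1
spine$ensemble
#> <spine_ensemble> 7 masks kept, 1 unused
#>   agreement unions: 4 | instance takeovers: 3 | pickups: 0
#>   kept-area mean 1480.4 px, sd 191.8 px (eta = 0.60, lambda = 2.0)

evaluate_spine(spine, gt$masks)
#> <spine_eval> overall Dice 0.958 over 7 classes
#>   per-class Dice: C2=0.93 C3=0.96 C4=0.97 C5=0.97 C6=0.96 C7=0.95 T1=0.95
#>   IoU>0.70: PQ 0.919 = SQ 0.919 x RQ 1.000
#>   IoU>0.80: PQ 0.919 = SQ 0.919 x RQ 1.000
```

The corrupted semantic raster had only 5 separable components (two merges)
and the instance list happened to keep all 7 bodies; the ensemble ends with
all 7 vertebrae separated — 4 by agreement, 3 taken from the instance side
out of merged blobs — every label correct, and mean Dice 0.96 against the
ground truth despite 1-px boundary jitter in both sources.

A command-line wrapper covering simulation, fusion, labeling and evaluation
is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "spinefuse", package = "spinefuse"))')
$CLI simulate --n 20 --seed 7 --out fixtures/
$CLI run --fixtures fixtures/ --out results/
```

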