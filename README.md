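# eagseg — enhanced area growth for lung tumour segmentation on CT

`eagseg` delineates lung tumours on CT slices (2D) and volumes (3D) by
seeded region growing, for people who need a transparent, tunable,
classical segmentation baseline: treatment-planning tooling, method
comparisons, or teaching.  The user supplies one click inside the
tumour and an expected maximum radius; everything else is automatic.

## The algorithm

Growth proceeds in level-synchronous "braids": level 0 is the seed
*s*; at each level every unexamined 8-neighbour (26 in 3D) *p* of the
current braid is accepted iff

```
|I(p) − c|  ≤  t ,        t = 0.20 · graythresh(region)
```

where `graythresh` is the Otsu grey-level threshold of the region's
256-bin histogram and *c* is the *comparison quantity*.  The baseline
("primary") algorithm keeps *c* fixed at the seed intensity `I(s)` and
takes the region to be the whole image.  The enhanced algorithm wraps
this kernel in:

1. **contrast augmentation** — a 1%/99% quantile stretch (`imadjust`);
2. **lung-field masking** — Otsu split, removal of border-connected
   air, morphological closing and hole filling; growth never leaves the
   lung, which stops leakage into the chest wall for juxtapleural
   tumours;
3. **radius constraint** — growth confined to twice the declared
   maximum radius around the seed;
4. **median tracking** — after each braid level, *c* is reset to the
   median of all accepted intensities, so the acceptance band follows a
   mass whose enhancement fades toward the margin;
5. **automatic local threshold** — *t* is recomputed on a disk/sphere
   around the first-pass tumour (radius = max boundary distance from
   the intensity-weighted centroid + 5 px) and growth is re-run;
6. **multi-start growth** — one random start per quadrant/octant of the
   mask plus its geometric centre (5 starts in 2D, 9 in 3D), each grown
   independently; the boundaries are combined by radial-mean
   interpolation about the common centre;
7. **edge refinement** — rays at 8 (2D) / 16 (3D) angles locate the
   boundary, candidates 3 px outward are regrown with a narrow 10%
   threshold, and a candidate subsection is joined only if
   `median(sub) > median(tumour) − 3·sd(tumour)` and
   `|sub| / |tumour| < 0.2`.

Segmentations are scored with the Dice coefficient
`C = 2|A∩B| / (|A|+|B|)` plus pixelwise recall and precision.

## Worked example

The package ships a chest-phantom simulator with exact ground truth, so
the whole pipeline can be exercised without data:

```r
library(eagseg)
ph  <- generate_phantom(phantom_spec(rng_seed = 42))
seg <- eag_segment(ph$image, seed = c(64, 93), max_radius = 12, rng_seed = 1)
summary(seg)
#> Enhanced area-growth segmentation of a 128x128 image
#> seed (64, 93), rng seed 1
#>   contrast         low_frac=0.01  high_frac=0.99
#>   lung_mask        components=2  pixels=4582
#>   seed             value=0.92925
#>   radius           max_radius=12  factor=2
#>   global_threshold grey_level=0.50391  threshold=0.10078
#>   growth           pixels=359  levels=13  final_compare_value=0.87609
#>   autothresh       local_grey_level=0.51953  threshold=0.10391  target_radius=16.033  pixels=359
#>   multistart       n_seeds=5  n_results=5  pixels=361
#>   refine           candidates=9  joined=0  pixels=361
#> final mask: 361 pixel(s); primary pass: 359 pixel(s)

overlap_scores(seg$final_mask, ph$tumor_truth)
#> <overlap_scores> dice 0.8837, recall 0.7917, precision 1.0000 (tp 361, fp 0, fn 95)

dice(primary_segment(ph$image, c(64, 93))$final_mask, ph$tumor_truth)
#> [1] 0.814
```

Reading the log: the global Otsu grey level is 0.504, so the working
acceptance half-width is 0.101; thirteen braid levels accept 359
pixels; the local target area (radius 16) yields a slightly higher grey
level; the five starts agree; no edge candidate passes both join rules
on this clean phantom.  The enhanced result (Dice 0.884, perfect
precision) beats the fixed-comparison baseline (0.814), which stops
early on this margin-tapered mass.  `plot(seg)` overlays the contour on
the image; `plot(seg$growth)` draws the frontier/cumulative braid
traces.

A shell interface wraps the same functions:

```sh
inst/cli/eag phantom --out demo/
inst/cli/eag segment demo/image.png --seed 64,93 --max-radius 12 --rng-seed 1 --out demo/mask.png
inst/cli/eag eval --pred demo/mask.png --truth demo/tumor_truth.png
# {"dice":0.8851,"recall":0.7939,"precision":1,...}
```

Seeds are 1-based `row,column[,slice]` array indices (`--help` on any
subcommand).

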