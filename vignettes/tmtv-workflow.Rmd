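---
title: "Measuring TMTV with the SUV4.0 benchmark workflow"
author: "tmtvbench authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring TMTV with the SUV4.0 benchmark workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmtvbench)
```

## The measurement model

Total metabolic tumor volume (TMTV) on baseline FDG-PET is defined here the
way the international benchmark workflow defines it: every voxel with
body-weight SUV of at least 4.0 is candidate tumor, candidates are grouped
into 3-D connected components, and components smaller than 3 cm³ are
discarded by the automated preselection. Everything a human reader then
does is one of three reproducible operations — deleting a whole component
with a click (physiologic uptake at stage 1, reactive spleen/marrow at
stage 2), erasing voxels with a hand-drawn mask where tumor and physiologic
uptake fuse (stage 3), or adding a full connected SUV ≥ 4 region with a
seed click and *no* volume threshold (stage 4). The TMTV recorded after
each stage gives TMTV1–TMTV4; TMTV4 is the final value.

Volume is always `voxel_count × voxel volume`, with no partial-volume or
mesh correction: this is the simplest convention consistent with applying a
"volume of at least 3 cm³" rule on a voxel grid, and it makes the
conservation identity `tmtv(cs) == voxelVolume(cs) * sum(mask > 0)` exact,
which the test suite exploits throughout.

Assumptions worth stating explicitly:

* **SUV normalization is body weight.** The threshold "4.0" is only
  meaningful for body-weight SUV; `suvFromActivity()` documents the exact
  decay-corrected formula used when converting activity concentrations.
* **Baseline scans only.** A fixed SUV 4.0 threshold is not expected to
  work on interim or end-of-treatment scans with faint residual uptake;
  nothing in the package addresses that setting.
* **Reader judgement is data, not code.** Whether diffuse splenic uptake
  belongs in the TMTV is a clinical decision that the benchmark found to be
  the dominant source of disagreement. The package deliberately does not
  automate it: decisions live in session files, and the phantom library
  ships both choices as separate scripted scenarios.

## Parameters and defaults

| Parameter | Default | Units | Why |
|---|---|---|---|
| `suvMin` | 4.0 | SUV | the benchmark delineation rule ("at least 4", inclusive) |
| `minVolume` | 3.0 | cm³ | preselection filter ("at least 3 cm³", inclusive) |
| `connectivity` | 26 | — | face+edge+corner adjacency; the common default in SUV-threshold MTV tools, merging diagonal bridges the way readers perceive single lesions. 6 and 18 are available. |
| `absTol` / `relTol` | 10 / 0.10 | cm³ / fraction | the benchmark agreement rule, as strict `<` comparisons |
| discrepancy `relThresh` / `absThresh` | 0.25 / 45 | — / cm³ | the published >25 % adjudication trigger, plus an absolute arm sized so that ~50–100 cm³ editing-related discrepancies are also captured |

Three design points were genuinely open and were settled as follows:

* **Strict vs inclusive tolerance comparison.** The agreement rule is
  phrased both as "less than 10 %" and "within 10 %" in common usage;
  strict `<` was adopted and is recorded in every report. Boundary-equal
  cases are practically nonexistent at float precision.
* **The 3 cm³ filter applies only at preselection.** After a stage-3 edit
  splits a component, sub-3 cm³ tumor fragments survive. Re-filtering would
  silently delete tumor the reader chose to keep, and the volume rule is
  described only for the automated preselection step.
* **Whole-component click semantics.** A stage-1/2 click removes the entire
  connected component under the point, with *exact* containment — no
  snapping to the nearest component, because silent snapping could remove
  the wrong structure. The stage-3 edit mask is the escape hatch when a
  physiologic structure is fused to tumor and whole-component removal would
  be wrong. Clicks are world-millimetre points resolved to the nearest
  voxel center.

Component labels are assigned in decreasing volume order (ties by scan
order) so reports are stable across runs; replaying a session is
bit-reproducible because no operation involves hidden state or randomness.

## The phantom generator

`rasterizePhantom()` paints analytic shapes (spheres, ellipsoids, boxes,
tubes) onto a voxel grid by voxel-center containment, with a painter's rule
(higher `paintOrder` wins; overlapping equal orders are an error). Testing
containment at voxel centers, with no antialiasing, keeps every truth
volume integer-voxel exact — which is what lets the acceptance tests demand
*zero* error between a replayed session and the rasterizer's bookkeeping.
Truth masks and volumes are recorded before any degradation.

The default grid is 128 × 128 × 160 voxels at 4 mm isotropic spacing:
whole-body extent at typical PET resolution, small enough that the full
eight-scenario suite replays in seconds. The background is soft tissue at
SUV 0.8, and a liver ellipsoid at SUV 3.0 is present in every scenario as
reference tissue so that the "diffuse splenic uptake > 1.5 × liver"
criterion is well defined (the diffuse-spleen scenarios paint the spleen at
SUV 4.8 = 1.6 × liver). Scanner degradation is modelled as a separable
Gaussian PSF (σ = FWHM/2.355 per axis, reflective boundaries — a uniform
field stays exactly uniform) followed by additive Gaussian noise clamped at
zero, fully determined by a seed. This emulates post-reconstruction image
statistics; Poisson projection noise and reconstruction algorithms are out
of scope.

The scenario library encodes the uptake patterns that drive reader
disagreement in practice: multifocal nodal disease; bulky mediastinal and
abdominal masses with diffuse marrow involvement; reactive spleen and
marrow removed at stage 2; diffuse splenic uptake at 1.6 × liver both with
and without matching marrow changes (kept vs removed, mirroring the reader
instruction that diffuse splenic uptake without similar marrow changes is
included); a retroperitoneal node fused to the right kidney requiring a
stage-3 edit; a paracardiac node fused to myocardium; and sub-3 cm³ lesions
restored at stage 4. Scripted TMTV4 values span ~10 to ~1700 cm³, covering
most of the small-to-bulky range reported for real baseline lymphoma
cohorts.

What passing these tests does *not* show: phantoms are piecewise-constant
with sharp analytic boundaries, no respiratory motion, no heterogeneous
tracer uptake, no anatomically realistic shapes. Exact clean-mode recovery
demonstrates that the segmentation and bookkeeping logic is correct, not
that the method segments real patients well — that is what the public
60-case benchmark distribution is for, which this package can consume but
does not ship.

## Numerical choices

* Connected-component labeling is a C++ breadth-first fill over 6/18/26
  neighbourhoods; tests compare its partition against an independently
  written pure-R flood fill on random volumes.
* SUV volumes are stored as float32 on disk (masks as uint16), matching
  scanner-export precision; in-memory arithmetic is double. The SUV 4.0
  comparison is inclusive, and 4.0 is exactly representable in float32, so
  thresholding is not perturbed by storage round trips.
* Volumes are reoriented to RAS+ on load so click coordinates are
  unambiguous; negative input SUVs (reconstruction noise) are clamped to
  zero with a warning.
* ICC(2,1) is computed from the two-way ANOVA mean-square decomposition
  with case-wise deletion of incomplete reader rows — the simplest
  defensible rule for panels where cases were read by 3 of 4 readers. A
  zero-variance panel is defined as ICC 1 with a warning. Calibration is
  checked on simulated 5000-case panels across case-variance fractions
  0.5/0.9/0.99 (recovered within 0.01 at a fixed seed).
* The blur/noise robustness property uses a 100 cm³ SUV-10 sphere under
  6 mm FWHM and 0.2 SUV noise across 20 seeds; recovered TMTV4 stays within
  a few percent of truth (the test bound is ±15 %), a desk-scale echo of
  why a fixed SUV 4.0 threshold is robust to reconstruction differences.
  Problem sizes throughout (10³ oracle volumes, 64³ fuzz phantoms, 96³
  robustness grid, 5000-case panels) were chosen as the smallest sizes at
  which each property is statistically meaningful.

## Known limitations

* No DICOM ingestion: NIfTI-1 is the sole mandatory format, as in research
  distributions of benchmark data; vendor-tag SUV derivation belongs to
  upstream converters.
* Physiologic-vs-tumor classification is not automated; a session file is
  required to reproduce a human measurement.
* `flagDiscrepancies()` thresholds are heuristics for adjudication
  triage, not clinical rules; the absolute 45 cm³ arm in particular is a
  package choice (made configurable) because no selection rule for
  adjudication was ever standardized.
* The CLI is a thin wrapper over the documented R functions; it does not
  download the public benchmark archive — that remains a manual step.
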