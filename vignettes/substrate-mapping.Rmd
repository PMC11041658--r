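---
title: "Mapping the arrhythmogenic substrate: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping the arrhythmogenic substrate: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`rvimap` computes the quantitative substrate metrics used in high-density
electroanatomical mapping of ventricular arrhythmia risk. This vignette is
the package's own account of the underlying models, the parameters that
matter, the numerical choices that were genuinely open, and what the
synthetic ground-truth generator does and does not emulate.

## The data model

A `surface_map` is a triangulated surface (vertices in mm) carrying
per-vertex local activation time (LAT) and local recovery time (LRT), both
in ms in a declared time reference (typically the pacing spike at 0 ms), and
a validity mask. The mask is the single mechanism for everything the
clinical workflow expresses by discarding sites: failed annotations,
rejected projections, outliers, and physically impossible entries (any
vertex with LRT ≤ LAT is invalidated at construction, since tissue cannot
recover before it activates). Every metric propagates invalidity rather than
fabricating values.

Distances are straight-line 3D Euclidean throughout. Clinical practice does
not state whether neighborhood searches are Euclidean or geodesic along the
surface; Euclidean is unambiguous, matches the established reentry
vulnerability index (RVI) methodology, and is what we default to. Geodesic
search would be a conservative extension (it can only shrink neighborhoods).
Units are fixed — mm, ms, m/s — exploiting that 1 mm/ms = 1 m/s.

## Electrogram annotation

Unipolar electrograms are annotated by slope rules: LAT at the most negative
first time-derivative within an activation window, LRT at the most positive
first time-derivative within a window spanning the whole T wave. Taking the
maximum upslope over the entire T window makes the recovery annotation
independent of T-wave polarity (the Wyatt convention): an upright T wave has
its steepest upslope on the ascending limb before the peak, an inverted one
on the terminal limb after the nadir, and both mark recovery.

Numerical choices:

- Derivatives are central finite differences on the raw trace. No smoothing
  is applied by default — the contract is the extremum rule itself, and the
  clinical systems filter upstream. A moving-average pre-smoothing of
  configurable width is available (`smooth_ms`); for noisy traces (around
  SNR 20 dB) we use 5 ms, which suppresses derivative noise by roughly the
  window width while leaving the annotation unbiased, because both synthetic
  deflections have derivative extrema that are locally symmetric in time.
- Ties between equal extremal slopes resolve to the earliest sample;
  determinism demands a rule and the earliest deflection is the
  electrophysiological convention for activation.
- An extremum on a window edge is flagged (the window probably missed the
  deflection); a flat window yields no annotation. Flagged sites stay in the
  map as invalid vertices.
- Windows are global per map, mirroring how mapping systems set one
  annotation window spanning the T wave for the whole acquisition.

Outlier screening (`flag_outliers`) formalizes "corrections limited to
isolated outliers": a vertex is flagged when its value deviates from the
median of its ring-1 mesh neighbors by more than `k` (default 5) times the
map-wide median absolute edge difference of the field. The scale is taken
over edges with center zero so that smooth fields — where neighbor
differences are real but consistent — produce a proportionate scale, and a
perfectly constant field yields scale zero without false flags. Vertices
with fewer than three valid neighbors are never flagged: insufficient
evidence.

## Conduction velocity by triangulation

Each mesh triangle yields one wavefront-speed estimate under a locally
planar wavefront assumption. With A the earliest-activated vertex (ties
broken by vertex index), edges a = AB, b = AC, c = BC, and activation
delays $t_a = \mathrm{LAT}(B) - \mathrm{LAT}(A)$,
$t_b = \mathrm{LAT}(C) - \mathrm{LAT}(A)$:

$$\theta = \arccos\frac{|a|^2+|b|^2-|c|^2}{2|a||b|},\qquad
\tan\alpha = \frac{t_b|a| - t_a|b|\cos\theta}{t_a|b|\sin\theta},\qquad
v = \frac{|a|\cos\alpha}{t_a}.$$

Design notes:

- Choosing A as the earliest vertex makes $t_a, t_b \ge 0$ and the
  evaluation sign-safe. $\alpha$ is evaluated with the two-argument
  arctangent so the quadrant is always correct; $|\alpha| \ge 90^\circ$
  (wavefront not exiting through edge a) is treated as inadmissible. Under
  the earliest-A convention with the activation-difference bound in force
  the denominator is strictly positive, so this guard cannot fire on valid
  input — it is retained as an invariant check.
- Admissibility applies the distance bound (3–20 mm) to **all three**
  pairwise vertex distances and the ≥ 3 ms bound to **all three** pairwise
  LAT differences — the strictest reading of "between vertices"; both
  bounds are configurable arguments. Rejected triangles carry a reason code
  (`distance_bound`, `dt_bound`, `invalid_lat`) instead of a speed.
- The method estimates speed **in the triangle's plane**. For a planar wave
  travelling tangentially to the surface the estimator is exact (the test
  suite verifies recovery to 1e−6 relative over randomized admissible
  triangles); a wave crossing the surface obliquely yields the apparent
  in-plane speed, which is the physically observable quantity on a mapped
  surface.
- Per-vertex CV for display is the arithmetic mean of admissible incident
  triangles; mapping systems display CV maps without stating their
  projection, and the unweighted mean is the least-assumption choice.
- Functional block is the set of admissible triangles with v below 0.2 m/s
  (the conventional cut), reported as total area (cm², summed triangle
  areas) and as connected components linked by shared edges. Area lives
  naturally on triangles, where the speed estimate lives.

## Reentry vulnerability index

After centering LRT on the map median ($\mathrm{LRT}' = \mathrm{LRT} -
\mathrm{median}\,\mathrm{LRT}$, the cycle-length correction),

$$\mathrm{RVI}_P = \min_{D \in N(P, 20\,\mathrm{mm})}
\left(\mathrm{LRT}'_P - \mathrm{LAT}_D\right),$$

and the global RVI is the 10th percentile of the valid per-vertex values.
Choices that were open:

- Only LRT is median-centered — the literal reading of the definition; LAT
  stays in the map's declared time reference, which the map metadata
  carries.
- The 20-mm bound is inclusive and excludes the center vertex itself.
- No percentile convention is standard in the mapping literature; we use
  linear interpolation between order statistics ($h = (n-1)q$, R's type 7),
  document it, expose it, and pin it with tests (the worked four-site
  example gives exactly −64.5 ms under this convention).
- The optimized implementation (per-vertex maximum donor LAT within the
  radius) is proven equal to a literal all-pairs minimum on randomized maps
  up to 2,000 vertices; exact equality holds because subtraction is
  monotone in floating point.
- Maps are analyzed per surface; whether clinical RVI excluded donor sites
  across anatomical boundaries is unstated, and per-surface analysis is the
  conservative reading.

Before/after comparison reports percent change as
$100\,(\mathrm{post}-\mathrm{pre})/|\mathrm{pre}|$; because lower RVI means
greater vulnerability, an algebraic increase of global RVI is reported as
improvement.

## The synthetic generator

The generator is the stand-in for animal maps and supplies exact ground
truth. Activation comes from a graph eikonal: Dijkstra relaxation over mesh
edges, an edge costing its length times the mean slowness of its endpoints
(equivalently, length over the harmonic mean of the endpoint speeds). Paths
confined to edges inflate arrival times by a bounded metrication factor —
at most about 8 % on the diagonal-split grids used here, verified against
the Euclidean lower bound in the tests — which is acceptable for ground
truth because analytic planar waves (`planar_wave_lat`) are used wherever
exactness matters. Repolarization is LRT = LAT + APD, with APD composed of
a base value, a linear gradient, and radially smooth patches
($\delta\cos^2(\pi r/2R)$, zero at the rim). Annotation noise is additive
independent Gaussian (defaults 2 ms LAT, 5 ms LRT).

Scenario presets fix the package's reference study conditions on a 27 × 27
sheet at 3 mm spacing (78 mm square, 729 vertices, 1,352 triangles) with a
plane-wave source at the left edge:

| parameter | `wt_s4` | `ts1_s4` | rationale |
|---|---|---|---|
| base CV | 0.9 m/s | 0.45 m/s | severe substrate ≈ halved conduction |
| APD | 240 ms | 320 ms | prolonged repolarization |
| slow patches | one 4 mm @ 0.3 m/s | two 10 mm @ 0.1 m/s | functional block only in disease |
| APD patches | −15 ms / 8 mm | −60 and +40 ms / 8 mm, co-located with slow patches | steep repolarization gradients where conduction fails |
| APD gradient | 0.3 ms/mm | (1.0, 0.5) ms/mm | dispersed repolarization |
| noise sd | 2 / 5 ms | 2 / 5 ms | annotation jitter |

The 3-mm spacing is the smallest compatible with the CV admissibility lower
bound (edges must be ≥ 3 mm) and sits at the clinical fill-threshold scale;
coarser meshes under-resolve 10-mm patches. These constants are package
conventions chosen to echo the qualitative disease contrasts (roughly
doubled activation time, much larger block area, lower global RVI, steeper
LRT gradients — which the acceptance tests confirm hold in 10/10 seeds);
they are not fitted to any animal dataset.

Synthetic electrograms place their derivative extrema analytically: the
depolarization wavelet is $-A\,u\,e^{-u^2/2}$ with $u = (t-\mathrm{LAT})/\sigma$
(an RS-shaped biphasic deflection, steepest downstroke exactly at LAT,
$A = 1$ mV, $\sigma = 4$ ms), and the T wave is a Gaussian of amplitude
0.4 mV and width 12 ms whose peak (upright) or nadir (inverted) is offset by
one width so the maximum upslope falls exactly at LRT. Noise is white
Gaussian, specified either as an sd in mV or as an SNR in dB relative to the
clean trace RMS.

What the generator does **not** emulate: fractionated or multi-component
electrograms, far-field ventricular signals, baseline wander, catheter
contact artifacts, curved-wavefront collision patterns beyond what the
eikonal produces, and sequential-acquisition beat-to-beat variability.
Passing the recovery tests therefore shows the annotation and metric rules
are implemented correctly and are robust to white noise at the stated SNR —
not that they are robust to every failure mode of clinical signals.

## Problem sizes and determinism

The test-suite and acceptance computations use 729-vertex preset maps,
randomized RVI maps of 500–2,000 vertices, 1,000 randomized CV triangles
and 200 noisy electrograms — sizes at which every property can be checked
against a brute-force oracle while the whole suite runs in well under a
minute. All stochastic steps take explicit seeds; generators save and
restore the session RNG state, so identical configurations are reproducible
byte-for-byte and library code never perturbs user randomness.

## Known limitations

- Graph-eikonal ground truth carries grid-dependent metrication error;
  quantitative block-area recovery is verified to 20 % of the analytic
  patch area, not better, and depends on mesh resolution.
- The block-area measure counts admissible triangles only; in regions where
  a wavefront runs parallel to many edges (activation differences < 3 ms)
  triangles drop out of the estimate by design, exactly as in the clinical
  method.
- Proprietary mapping-system exports are out of scope; the open JSON/CSV
  interchange schema documented in `read_map`/`write_map` replaces them.
- No inferential statistics across animals or maps are provided; the
  package computes per-map metrics and paired comparisons only.
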