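---
title: "Single-subject metabolic brain networks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-subject metabolic brain networks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metconn)
```

## The problem

Group-level metabolic covariance networks correlate regional FDG uptake
across subjects, so they cannot describe one patient's trajectory. When a
single subject is scanned serially — here, four FDG-PET acquisitions during
the development and recovery of a postoperative cerebellar mutism syndrome
(pCMS) — a network can instead be built from *within-subject change between
stages*. metconn implements that construction end to end: regional SUVR
quantification, an effect-size-based stage-pair connectivity matrix, a
threshold-swept binarized graph, metabolic dynamics of six functional
subnetworks, and a seed-based analysis of the dentato-rubro-thalamo-cortical
pathway (the proximal efferent cerebellar pathway, pECP, whose injury is the
leading candidate mechanism of pCMS).

## Parcellation and SUVR

Volumes are assumed to be spatially normalized already; the package starts
at an integer label image or at regional tables. The registry covers the 116
AAL structures plus four added structures — pons, left and right dentate
nucleus, and red nucleus — for 120 regions in total. The added structures
carry label ids ≥ 9000 because they have no AAL label; when only an AAL
label volume is available, their rows can be supplied at table level.

Voxel activity is converted to SUV (activity divided by injected dose per
body weight) and then to SUVR by dividing each regional mean SUV by the mean
SUV of the pons, the reference region; the pons SUVR is 1 by construction,
and any global scale factor in the activity volume cancels. Per region the
stage table stores the mean SUVR, the voxelwise SD (sample convention,
ddof = 1, configurable) and the voxel count. Background voxels (label 0) are
excluded everywhere.

## The connectivity model

For a comparison stage $k$ against a baseline stage $k_0$, each region's
standardized change is

$$z_i = \frac{\bar{x}_{k,i} - \bar{x}_{k_0,i}}{s_i},$$

and the effect-size difference between two regions is
$\mathrm{ESd}(i,j) = z_i - z_j$. Two regions that recover *concordantly*
have a small $|\mathrm{ESd}|$. The Fisher-type transform

$$R(i,j) = \frac{e^{2\,\mathrm{ESd}(i,j)} - 1}{e^{2\,\mathrm{ESd}(i,j)} + 1}
         = \tanh\!\big(\mathrm{ESd}(i,j)\big)$$

maps the statistic into $(-1, 1)$, and the final connectivity value is
$R'(i,j) = 1 - R(i,j)$, so that concordant change gives $R' \to 1$ and
discordant change $R' \to 0$.

Three choices in this construction are genuinely open, and the package makes
each explicit:

* **Sign policy.** The raw ESd is antisymmetric, and $\tanh$ of a negative
  value would push $R$ below 0, contradicting the intended bound
  $0 \le R < 1$ and the reading "small discordance = high connectivity".
  The default applies the transform to $|\mathrm{ESd}|$, which makes $R'$
  symmetric and confined to $[0, 1]$; the signed variant is retained as
  `sign_policy = "raw"` for audit (its values lie in $(0,2)$ and are not
  symmetric).
* **Dispersion source.** A single subject has no across-subject SD, so
  $s_i$ is a voxelwise SD. The default takes it from the baseline stage
  (`"baseline_voxel_sd"`); the comparison stage or the root-mean-square
  pooling of the two are alternatives. This is the main methodological
  ambiguity of the approach, which is why it is a visible argument rather
  than a buried constant.
* **Mask semantics.** Only *concurrently increasing* pairs
  ($\Delta_i > 0$ and $\Delta_j > 0$) are analysed, because binarizing
  negative covariation is not meaningful here. Masked pairs are set to 0 by
  default (`"zero_masked"`), so they can never survive a positive threshold;
  `"nan_masked"` keeps them visible as NA for auditing. Either way they are
  effectively excluded from every binarized network.

Binarization is strict ($R' > \tau$), self-edges are never produced, and the
edge-count curve is swept over $\tau \in \{0, 0.01, \dots, 1\}$ — 101
values — so $\tau = 1$ always yields the empty graph and the curve is
non-increasing. Display thresholds of 0.95 (cerebrum) and 0.65 (cerebellum)
ship as `display_thresholds()`. Stage pairs follow two schemes: every stage
against the first (`vs_first`, the stage-versus-baseline matrices) and each
stage against its predecessor (`consecutive`, used for the pathway
evolution).

## Subnetwork dynamics

Six functional subnetworks are defined in the registry: sensorimotor (SMN),
fronto-parietal (FPN), cingulo-opercular (CON), occipital (OCC: calcarine,
cuneus, occipital gyri, lingual, fusiform), default-mode (DMN) and the
cerebellum (all 26 regions whose names begin with "Cerebelum" or "Vermis").
Only the occipital and cerebellar memberships are fully determined by the
method's description; the other four are a reconstruction from standard AAL
assignments (FPN around the frontal operculum, inferior parietal lobule and
angular gyrus; CON around the midcingulate, hippocampus, amygdala and basal
ganglia), kept pairwise disjoint and fully configurable through the registry
file — the package's tests pin counts and disjointness, not any specific
membership.

Per (subnetwork, stage) the observations are the member regions' mean SUVR
values; stages are compared by one-way ANOVA with Tukey HSD post-hoc
contrasts, starred at adjusted $p < 0.05$ (\*) and $p < 0.01$ (\*\*).
Treating regions as independent observations is a statistical
simplification inherited from the design; the package documents it rather
than hiding it. The fully degenerate case (all groups constant and equal)
returns $F = 0$, $p = 1$ by convention, since the F statistic is 0/0 there.
At $k = 2$ groups the Tukey-adjusted p equals the plain two-sample ANOVA p,
which the tests verify against a closed form.

## Seed-based pathway accounting

The pECP analysis takes the dentate nuclei, red nucleus and both thalami as
seeds and the 76 cortical-target regions as endpoints. The target list is
not enumerated anywhere in the method's source material, and its reported
membership includes the putamen and olfactory cortex, so a purist
"cortex-only" rule cannot reproduce it; the packaged default is a documented
reconstruction — the 90 cerebral AAL regions minus the thalami (seeds),
insula, hippocampus, parahippocampus, amygdala, caudate and pallidum —
grouped into six lobes (frontal 24, paracentral 8, central core 8, parietal
10, temporal 12, occipital 14). Membership is config-driven; the invariants
are the count (76) and disjointness from seeds and reference.

A target is *connected to the thalamus* when the maximum $R'$ over the two
thalamic seeds strictly exceeds `tau_seed` (default 0.95, the cerebral
display threshold) — the rule itself is a reconstruction, since no explicit
definition exists. Between consecutive stage-pair results the package
reports two accountings: a four-way partition (stronger / weaker among
targets connected in both, newly connected, lost) and a *direction* for
every target connected in the later result regardless of earlier
connectivity. The second is the accounting that reproduces quoted fractions
with denominators equal to the later connected count (e.g. 29 weaker and 45
stronger of 74 connected); ties count as "weaker" (not further improving) by
default. "Continuously improving" targets are those whose direction is
stronger in every transition, reported over the full 76-target denominator.
The relay links (dentate–red nucleus, red nucleus–thalamus,
dentate–thalamus) are emitted as a per-link strength table instead of a
path-existence boolean, to avoid inventing a path-threshold rule.

## The synthetic-data generator

No patient scans are deposited, so validation runs on synthetic longitudinal
SUVR data with known structure. The generator's defaults define the study
conditions:

* 120 regions, 4 stages, baseline SUVR 1.0, voxelwise SD $s_i = 0.25$,
  100 voxels per region, measurement noise SD 0.05 on regional means
  (0 for the noise-free limit), pons fixed at SUVR 1 throughout.
* **Coupled pairs** (15 by default, drawn from the six subnetworks plus two
  thalamo-cortical pairs and a dentato-rubral pair) share exactly the same
  standardized trajectory: their ESd is 0 in the noise-free limit, forcing
  $R' = 1$. These pairs are the ground-truth edge set.
* **Decoupled recovering regions** (one or two singletons per subnetwork)
  sit on a ladder of standardized changes spaced by `decoupled_z_gap`
  (default 2 z units), rising linearly across stages, so no decoupled pair
  ever approaches the coupled pairs' connectivity: at the 0.95 threshold an
  edge requires $|\mathrm{ESd}| < \operatorname{artanh}(0.05) \approx 0.05$,
  and the smallest decoupled separation at any stage pair is two orders of
  magnitude larger.
* **Dipping regions** (the remaining FPN/OCC members) fall by about 0.35
  SUVR at stage 2 and only partially recover, with per-region distinct
  recovery slopes so that consecutive-scheme changes never collide within
  the binarization tolerance.
* **Everything else declines** monotonically to −0.3 SUVR by the final
  stage. The clear decline (≈ 4 noise SDs) is what keeps the
  concurrent-increase mask identifiable under noise: a truly flat region
  enters the mask on a noise coin-flip, and two such regions form a
  spuriously perfect edge — a genuine property of the method, not of the
  implementation. The subnetwork profiles (early monotone recovery for
  SMN/CON/DMN, dip-then-rise for FPN/OCC, a mild cerebellar rise carried by
  its ladder members) are qualitative; no numeric fidelity to any figure is
  claimed, and the ladder magnitudes are deliberately large for
  identifiability rather than physiological realism.

With noise off, binarization at $\tau = 0.95$ recovers exactly the coupled
pairs under both stage-pair schemes (precision = recall = 1). With noise on,
no fixed threshold is meaningful — the coupled pairs' $|\mathrm{ESd}|$
inflates to $\sqrt{2}\,\sigma_{\text{noise}}/s_i \approx 0.28$ — so noisy
recovery is scored by ranking: the top-$K$ pairs by $R'$, $K$ the number of
true pairs. At the default noise (0.05) the mean F1 over 50 seeds is about
0.98, and the package's acceptance bound is 0.9.

The voxel-level phantom closes the loop with the quantification module: each
region receives `n_voxels` voxels at N(mean·A0, voxel_sd·A0) with A0 the
dose-per-weight scale, the reference region held exactly at A0. Recovered
regional means then carry exactly the target region's sampling error
voxel_sd/sqrt(n_voxels); coverage of the 3-standard-error interval is
checked as a fraction over seeds (a 99.73% interval, tested against 0.99,
because demanding every draw inside a 3 SE band would itself be a
statistical error).

## Symptom grading

The pCMS severity grading is a categorical lookup, not text interpretation:
four anchors per domain (motoric: atonia, limb hypotonia, trunk hypotonia,
able to stand and walk; linguistic: mutism, speak words, sentence, fluent
speech; neurobehavioral: minimal response, emotional liability, liability
but controllable, irritable mood) map to scores 1–4. Between-anchor states
are deliberately left to the user. The timeline is a step function
(carry-forward lookup; days before the first entry are "unscored"), aligned
to the four PET acquisitions on postoperative days 7, 21, 36 and 93. The
packaged `demo_timeline()` is a reconstruction for demonstration, not
patient data.

## Numerical choices and problem sizes

* Strict inequalities throughout (binarization, seed connectivity) so the
  boundary cases are unambiguous: $\tau = 1$ gives the empty graph.
* Zero dispersion in any region aborts with the region's name — no silent
  epsilon is ever substituted.
* The connectivity matrices are 120×120 and every stage of the pipeline runs
  in seconds; the test suite uses 8–12-region ad-hoc atlases for the
  equation oracles, 50 seeds for the noisy-recovery bound and 100 seeds for
  phantom coverage, which keeps the full suite under half a minute.
* All outputs are plain text (TSV/CSV/JSON, BrainNet `.node`/`.edge`);
  pipeline runs are byte-reproducible for a fixed configuration.

## Limitations

* The cortical-target membership, the four cerebral subnetwork memberships,
  the connected-to-thalamus rule and the absolute-value sign policy are
  documented reconstructions; all are configurable, none is claimed to be
  the original operationalization.
* Passing the synthetic-recovery tests shows the implementation recovers
  structure *the generator planted* under its noise model (independent
  Gaussian noise on regional means); real longitudinal PET adds registration
  error, partial-volume effects, scanner drift and physiological
  correlation that the generator does not emulate.
* Regions are treated as independent observations in the subnetwork ANOVA,
  and no graph metrics beyond edge counts are computed; negative-covariation
  networks are out of scope by design.
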