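---
title: "A kinetic model of cell-free glucose-to-monoterpene biosynthesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A kinetic model of cell-free glucose-to-monoterpene biosynthesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(terpflux)
```

## The system

`terpflux` models a purified-enzyme batch reactor that converts glucose into
monoterpenes. Glycolysis (hexokinase through pyruvate kinase) supplies
pyruvate and regenerates ATP; a lumped pyruvate-dehydrogenase reaction
supplies acetyl-CoA; the mevalonate pathway condenses three acetyl-CoA into
isopentenyl pyrophosphate (IPP) at a cost of three ATP and two NADPH; an
isomerase and a prenyltransferase assemble geranyl pyrophosphate, and a
swappable terpene synthase (limonene, pinene or sabinene — all C10H16
isomers, 136.24 g/mol) releases the product plus pyrophosphate, which a
pyrophosphatase returns to the free-phosphate pool.

The stoichiometric design problem the system solves is cofactor closure.
Per 1.5 glucose, glycolysis delivers the 3 acetyl-CoA and net 3 ATP the
mevalonate pathway needs, but produces 6 NADH — an excess of reducing
equivalents, and of the wrong kind (the mevalonate pathway consumes NADPH).
A *molecular purge valve* at the glyceraldehyde-3-phosphate dehydrogenase
step resolves both: an NAD-dependent Gap and an NADP-specific mutant (mGap)
run in parallel, and a water-forming NADH oxidase (NoxE) discards surplus
NADH while leaving NADPH untouched. With a pyrophosphatase closing the
phosphate loop, every cofactor pool (ATP/ADP, NAD(H), NADP(H), CoA,
phosphate) is recycled in situ; the net conversion is

$$3\,\mathrm{Glc} + 4\,\mathrm{O_2} \;\longrightarrow\;
  \mathrm{C_{10}H_{16}} + 8\,\mathrm{CO_2} + 4\,\mathrm{H_2O},$$

which `net_conversion()` derives from the stoichiometric matrix rather than
asserting. The roster counts 27 protein catalysts over 23 kinetic reactions:
the pyruvate dehydrogenase complex contributes three subunits (AceE, AceF,
Lpd) to a single lumped reaction, and catalase plus glutathione reductase
are present only as a redox safeguard, with no kinetic reaction. This
enumeration is a reconstruction from the catalyst count and the assembly
narrative; the authoritative component list lives in supplementary material
not shipped here.

```{r}
model <- build_full_system("limonene", glucose_mM = 500)
model
net_conversion(mevalonate_module(model), "AcCoA", "IPP")
```

## Rate laws and parameters

Per-enzyme rate equations are not published in the main text, so the package
commits to a small, swappable library in the tradition of yeast-glycolysis
kinetic models: reversible multisubstrate Michaelis–Menten in the
convenience-kinetics form with a Haldane constraint (so net flux vanishes
exactly at the mass-action equilibrium) for the near-equilibrium steps
(Pgi, Fba, Tpi, Gap, mGap, Pgk, Pgm, Eno, PhaA, Idi), and products of
independent irreversible saturation terms for the committed steps (Hex, Pfk,
Pyk, Pdh, NoxE, Hmgs, Hmgr, Mvk, Pmvk, Mdc, Fpps, the synthase, PPase).
Multisubstrate saturation multiplies independent per-substrate terms — no
ternary-complex mechanisms — and there is no product inhibition beyond what
reversibility implies; both are deliberate parsimony choices and both are
sensitivity caveats. Water and dissolved oxygen take activity one: the vial
is open and stirred, so O2 is clamped at air saturation (0.25 mM) and water
is the solvent.

Units: concentrations are mM and time is seconds internally; enzyme
loadings are entered as U/ml (1 U/ml = 1 mM/min = 1/60 mM/s), the unit in
which preparations are titrated; titres are converted to g/l only at the
reporting boundary.

Km and Keq defaults are database-plausible values for the homologous
enzymes, shipped as an editable table (`inst/extdata/reactions.csv`) rather
than re-derived. Loadings (Vmax) were calibrated once, by the same
procedure the original study describes for its own model — adjusting
parameters until a 500 mM-glucose batch runs steadily to completion — and
then frozen. Three calibration choices deserve explanation because the
system genuinely fails without them:

* **ATP-regenerating kinases bind ADP tightly** (Km 10 µM). The batch
  starts with the adenine pool fully charged (4 mM ATP, no ADP), and the
  regenerating kinases keep it there, so free ADP sits in the low
  micromolar range. The phosphoglycerate-kinase equilibrium
  ($K_{eq} \approx 3200$) then forces 1,3-bisphosphoglycerate to
  millimolar levels; with weak ADP binding that inflation chokes both
  Gap-step dehydrogenases and the run dies by phosphate sequestration.
* **HMG-CoA reductase binds NADPH tightly** (Km 50 µM) and is loaded with
  headroom. Because the Gap and mGap reactions share substrates, products
  and (being the same chemistry) the same Keq, the NADPH/NADP ratio cannot
  thermodynamically exceed roughly
  $K_{eq}\,[\mathrm{GAP}][\mathrm{P_i}]/[\mathrm{BPG}]$ relative to the
  NADH/NAD ratio. A weak-affinity reductase lets NADPH climb to that
  ceiling, mGap loses its driving force, HMG-CoA traps the entire CoA pool
  and pyruvate dehydrogenase starves — an irreversible ratchet. A
  tight-binding reductase keeps NADPH low and mGap far from equilibrium.
* **NoxE is high-affinity** (Km 5 µM, consistent with the *L. lactis*
  enzyme) and in excess, which keeps the NADH/NAD ratio an order of
  magnitude below the NADPH/NADP ratio: the operational definition of the
  purge valve doing its job.

The mevalonate kinases (Mvk, Pmvk, Mdc, 0.12 U/ml each) are deliberately
loaded close to their stoichiometric requirement (two-thirds of the
hexokinase flux each). That is what gives hexokinase its interior optimum:
raise Hex a few-fold without them and phosphate drains into hexose
phosphates faster than the kinase block can release it downstream, ATP
collapses, and the reaction stalls — the canonical "turbo design" failure
of an ATP pay-in pathway.

## Simulation and auditing

`simulate_timecourse()` integrates the ODEs with `deSolve::ode` (lsoda),
rtol 1e-8 and atol 1e-12. The absolute tolerance sits below the default
1e-10 convention because pool species (free ADP, NADH) are dynamically
meaningful at ~1e-6 mM; with the looser floor the solver's small negative
undershoots exceed the -1e-9 mM audit threshold. Rate laws evaluate
`max(c, 0)`; concentrations below -1e-9 mM at output times abort the run as
an integration-quality error. Every trajectory carries a conservation audit
of the five structural moieties (adenine, NAD, NADP, CoA, transferable
phosphate — the NADP 2'-phosphate is structural and excluded); relative
drift beyond 1e-6 is an error, and observed drift is ~1e-13. Halving the
tolerances moves the endpoint titre by well under 0.1%.

`classify_outcome()` declares a run *completed* when the residual hexose
pool (glucose + hexose phosphates, the quantity the coupled glucose assay
reports) falls below 1% of its initial value, *stalled* when all fluxes are
quiescent with hexose remaining (reporting the stall time, the depleted
pools and the fraction of phosphate sequestered in hexose phosphates), and
*running* otherwise — a third label the binary completed/stalled contract
needed for trajectories that are merely unfinished at `t_end`.

A completed 500 mM batch converts consumed hexose to terpene at the 3:1
stoichiometry within 0.5%. The small deficit is real, not numerical error:
at the end of a batch the adenine pool relaxes to all-ATP, free ADP goes to
zero, and the phosphoglycerate-kinase step freezes with ~3 mM of
1,3-bisphosphoglycerate (plus ~0.5 mM HMG-CoA awaiting NADPH that no longer
has a source) locked upstream. A closed batch cannot flush its last
phosphorylated intermediates; the methods scripts report this residue
rather than hiding it.

## The computational experiments

* `scan_parameter()` reruns the batch over a logarithmic grid (10- or
  50-fold span, 20 steps by default; readout at 20,000 s) and classifies
  the response: hexokinase shows an interior maximum, pyruvate
  dehydrogenase and starting phosphate saturate above a threshold. Shape
  calls break ties toward *flat* below 2% relative spread, and treat an
  endpoint within 5% of the maximum as saturating, so a few-percent
  post-threshold droop does not masquerade as an optimum.
* `find_bottlenecks()` loads every enzyme at 250-fold excess over
  hexokinase, drops each in turn to 5-fold excess, and flags those whose
  run no longer completes, ranked by titre deficit. The probe glucose
  (25 mM) is chosen so the hexokinase-limited baseline just finishes in
  20,000 s, making a throttled enzyme's shortfall visible. Under the
  shipped parameterisation the flags are Pdh — whose reduction delays
  mevalonate-kinase ATP demand and lets phosphate sequester in hexose
  phosphates — plus mGap and Hmgr. The latter two are honest properties of
  this reconstruction: both NADPH-branch enzymes operate at deliberately
  low fractional saturation, so a 5-fold excess of nominal units is not
  enough effective capacity. The original study reports the Pdh flag; it
  could not have seen the other two unless its (unpublished) rate laws
  shared this feature. `respect_model_loadings = TRUE` additionally caps
  each probe at the enzyme's loading in the supplied model, which is how a
  deliberately crippled enzyme is detected (construct-and-detect).
* `knockout()` zeroes purge-valve components: removing NoxE abolishes
  production (endpoint below the analytic electron-pool bound of
  `no_purge_bounds()` — at most (NAD + NADP pools)/8 mM terpene, since each
  product requires eight net nicotinamide reductions and the reversible
  Gap pair can shuttle between the pools); removing mGap leaves no NADPH
  source at all, so the model endpoint is zero (the small positive signal
  the wet system shows reflects enzyme cross-reactivity outside this
  model's scope); removing Gap strands the system on the NADP pool.
* `rebalance_experiment()` scales Hex against the {Pfk, Mvk, Pmvk, Mdc}
  block: 5x Hex alone collapses the titre to ~8% of baseline, scaling the
  kinase block alongside recovers it completely (indeed overshoots, since
  the balanced system is kinase-limited).

## Synthetic assay data

`generate_assay_data()` emulates the study's measurement layout: triplicate
sampling over days of terpene titre (GC-FID), residual glucose as total
hexose + hexose phosphates (coupled enzymatic assay), ATP (luminescence)
and Pi (malachite green). Noise is multiplicative log-normal per
measurement, mean-unbiased (`meanlog = log(mu) - sdlog^2/2`), with default
CVs of 4% (titre), 5% (glucose), 7% (ATP) and 5% (Pi) — the printed
replicate standard deviations imply CVs of roughly 3–7% (e.g. 8.87 ± 0.59
is 6.7%), and the exact per-assay values are not published, so these
defaults are stated assumptions exposed as arguments. True zeros stay zero;
the same seed reproduces a dataset bit for bit, and the caller's RNG state
is left untouched.

What the generator does *not* emulate: systematic bias (extraction losses,
calibration drift — the near-quantitative reported yields justify their
omission), day-to-day batch effects, autocorrelated drift within a vial,
or enzyme inactivation over the week (the study reports multi-day
stability, so no decay term is included by default). Passing the recovery
tests therefore demonstrates that the analysis chain is unbiased under
honest replicate noise, not that it is robust to structured artefacts.

`recover_yield()` applies the study's own yield arithmetic per replicate —
glucose consumed is hexose at day 0 minus hexose at the final day; the
theoretical product is consumed glucose over three — and reports
mean ± s.d. (n = 3). Across 20 seeds at 5% CV the recovered yields are
unbiased within two pooled standard errors and per-seed 2-s.d. intervals
cover the truth ≥ 80% of the time.

## Problem sizes and what the numbers look like

The shipped analyses use 500 mM glucose for the completion run (~6.4 days
of simulated time, integrated in about a second), 250 mM/16 h for
knockouts and rebalancing, 25 mM/20,000 s for bottleneck probes, and 200 mM
over 0–5 days for assay emulation. A 200 mM batch finishes at 9.0 g/l
limonene (98.8% of theoretical) in about two simulated days; the measured
system reached 8.87 ± 0.59 g/l (97.6%) in five. The model runs faster and
cleaner than the bench system — it has no enzyme loss, no side reactions
and no product escape — so headline titres and day-scale kinetics are
design-level statements, not predictions; the reproducible quantities are
the stoichiometric ratios, the yield arithmetic and the qualitative
sensitivity structure.

## Known limitations

Lumped Pdh kinetics; no organic-overlay partitioning (product extraction is
assumed perfect and non-inhibiting); no enzyme-inactivation term; no
thiamine-pyrophosphate or 2,3-bisphosphoglycerate species (both treated as
saturating and folded into Vmax); Keq values on a mM basis over the
kinetically modelled species only; and the batch-end intermediate lock
described above. The calibrated loadings are one self-consistent
realisation of the published design constraints, not a fit to the
experimental curves.
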