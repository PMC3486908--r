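---
title: "Coupling whole-body PBPK models to liver metabolism with dynamic FBA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupling whole-body PBPK models to liver metabolism with dynamic FBA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`dfbalink` joins two model formalisms that live at different biological
scales. At the organism scale, a physiologically-based pharmacokinetic
(PBPK) model describes a compound's absorption, distribution,
metabolisation and excretion as mass balances over well-stirred organ
compartments connected by blood flow. At the cellular scale, a
stoichiometric network describes hepatocyte biochemistry, and flux
balance analysis (FBA)

$$\max_v \; f^\top v \quad \text{s.t.} \quad S v = 0,\;
lb \le v \le ub$$

selects a flux distribution $v$ that maximises a functional objective
$f^\top v$ (for example hepatic ammonia uptake or uric-acid production)
over the steady-state flux cone of the stoichiometric matrix $S$.

The coupling is dynamic FBA: metabolic adaptation is fast relative to
whole-body distribution, so within each coupling interval (1 min by
default) the intracellular fluxes are assumed at steady state and held
constant, and the two models exchange information at the interval
boundaries in two ways.

**Direct coupling** (feed-back). Each linked clearance or production
process runs through a five-step loop per interval: the PBPK kinetic
rate is evaluated at the current concentrations; offered as an exchange
bound to the network; FBA is solved; the resulting exchange flux
replaces the PBPK process rate; and the whole-body model is integrated
one step. When the network accepts the full offered rate the kinetic
law is left untouched, so an unperturbed coupled model is *exactly* the
PBPK model alone — the package treats this identity as an invariant and
tests it. When the network is impaired, the exchange flux drops below
the offered rate and the compound accumulates upstream.

**Indirect coupling** (feed-forward). The intracellular concentration
$I(t)$ of an inhibitor in the liver compartment reduces the relative
activity of an enzyme,

$$\mathrm{relE}(t) = \frac{1}{1 + I(t)/IC_{50}}, \qquad
v_E(t) \le \mathrm{relE}(t)\, \lvert v_E(0)\rvert ,$$

where $v_E(0)$ is the flux through the enzyme in the unperturbed
reference FBA solution of the same objective. Several same-site
inhibitors combine as $1/(1 + \sum_i I_i/IC_{50,i})$.

### Choices behind the inhibition law

The rate law is competitive inhibition under the convention that the
substrate sits at its Michaelis constant, which makes
$\mathrm{relE}(IC_{50}) = 1/2$ and ties $K_i = IC_{50}/2$ through the
Cheng–Prusoff relation $K_i = IC_{50}/(1 + S/K_m)$. A noncompetitive
variant is available behind the `model` switch of
`inhibition_params()`; at $S = K_m$ both laws coincide once expressed
through $IC_{50}$. The combination rule for allopurinol and oxypurinol
on xanthine oxidase assumes one shared binding site, which is the
natural reading for two purine analogs; no literature combination rule
is available at this granularity.

Applying the activity constraint as a *cap* on the flux magnitude
(rather than an equality) is deliberate: an equality can make
objectives infeasible that do not route through the inhibited enzyme at
all. An equality mode would only matter for fidelity experiments and is
not used by any shipped scenario. The reference flux $v_E(0)$ is
recomputed per objective, because a flux that is optimal for one liver
task need not appear in the reference solution of another.

## Units and the reference-volume basis

All whole-body rates — production, macroscopic clearances, and network
exchange fluxes — are expressed in µmol/L/min on one shared reference
volume (`volume_basis`, by default the total compartment volume of the
body model). This is the only normalisation under which a macroscopic
hepatic clearance rate and a hepatocyte-network exchange flux are
directly comparable numbers, and it mirrors how such rates are usually
printed (an overall ammonia production of 0.694 µmol/L/min against
hepatic and renal eliminations of 0.163 and 0.530, consistent with a
13:4 renal-to-hepatic mass split of roughly 17 g of ammonia turned
over per day). Organ volumes and blood flows only shape distribution
between compartments; concentrations are always local (amount divided
by compartment volume, in µM).

Distribution is perfusion-limited well-stirred: the effluent
concentration of a tissue for species $s$ is $C/K$ with $K$ the
tissue-to-blood partition coefficient, so a flow $Q$ from $i$ to $j$
carries $Q \, C_i/K_i$. Partition coefficients are user-supplied
parameters; the package does not predict them from physicochemistry.

## Numerical choices

* **Integrator.** Classic fixed-step RK4 on the coupling grid with
  automatic sub-stepping chosen so that the fastest linear rate
  $\lambda$ satisfies $\lambda h \le 0.6$ — comfortably inside the RK4
  stability region with fourth-order accuracy to spare. A fixed-step
  scheme is required by the method itself: exchange bounds must be
  piecewise-constant per coupling interval. The engine is checked
  against closed forms and against an adaptive stiff solver (`deSolve`)
  in the test suite. Amounts are clipped at zero (with a counted
  warning) because a discretised clearance can overshoot near zero.
* **Linear programming.** The FBA programs are solved by a dense
  two-phase simplex with Bland's rule, written for the small programs
  this package generates (tens of variables). Alternate optima are
  resolved by a second stage that fixes the objective at its optimum
  and minimises total absolute flux (parsimonious FBA via flux
  splitting), so the reported flux vector is unique and reproducible —
  flux-change classification depends on that. Feasibility tolerance is
  1e-9; reported fluxes are rounded to 1e-10 to suppress solver noise.
  The solver is validated in the tests against exhaustive vertex
  enumeration of the feasible polytope on small networks.
* **Warm reuse.** Along a trajectory the LP is re-solved only when a
  bound change could alter the optimum (the cached flux vector violates
  a new bound, or a binding bound moved outward). This is an exact
  criterion, not an approximation, and makes 21-day runs at 1-min
  resolution cheap once the system settles.
* **Steady states** are declared when the largest relative change of
  any amount over a 60-min window falls below a tolerance (default
  1e-6/h; the calibration utilities use 1e-7/h). Non-convergence is
  reported as a flag, not an error.
* **Calibration** is deterministic local least-squares
  (`stats::nlminb`) on summed squared relative residuals, started from
  the model's current parameters; no randomness is involved. A
  flat-objective diagnostic warns when a parameter does not move any
  target.

## The toy hepatocyte fixtures

The bundled networks are intentionally small enough to solve by hand.

**Ammonia detoxification** (`make_ammonia_network()`): an uptake
exchange feeds a lumped urea-cycle reaction (2 NH$_3$ + CO$_2$
$\to$ urea; it contains ornithine transcarbamylase, OTC, and carries
the `OTC` tag), glutamine synthesis via glutamate dehydrogenase plus
glutamine synthetase, and alanine transamination. Nitrogen balance
gives $\text{uptake} = 2\,\text{urea} + 2\,\text{gln} + \text{ala}$.
Two design choices matter:

* Glutamine carries **two** ammonia-derived nitrogens (glutamate is
  made de novo via GDH). With one-nitrogen accounting the impaired
  uptake would be 0.040 rather than the observed
  $2 \times 0.032 + 0.008 = 0.072$ µmol/L/min.
* The glutamine and alanine secretions are **fixed demands** (lower
  bound = upper bound = cap) rather than mere caps. The observed
  partitioning of hepatic ammonia nitrogen (~95% urea, ~5% glutamine,
  ~1% alanine) is a physiological output rate, and only the demand
  form reproduces it under a parsimonious uptake-maximising solution —
  a plain upper bound would be stripped to zero by the
  total-flux-minimising stage. Baseline caps are 0.008 and 0.002
  µmol/L/min (5% and 1% of the baseline uptake of 0.163 in molar
  terms, rounded as printed).

**Purine degradation** (`make_purine_network()`): hypoxanthine
$\to$ xanthine $\to$ uric acid, both steps tagged `XO` so one
inhibitable activity spans the chain.

**Robustness panel** (`make_gsh_panel()`): a branched network whose
twelve export objectives depend, by construction, on known subsets of
four inhibitable activities (THFDH, GDH, ATPS and two
glutathione-producing reactions tagged `GSH`). The constructed
dependency list is returned as ground truth, so a robustness scan can
be checked exactly rather than approximately.

## The case-study protocols

**Urea-cycle disorder.** The mean patient is calibrated so that the
healthy venous steady state hits 29 µM with the 13:4 renal:hepatic
elimination split; production is fixed at 0.694 µmol/L/min by the
daily mass balance (it is not identifiable from the steady state and
the split alone — any production scale could be compensated by the
clearance constants). Disease onset is at 24 h; OTC activity falls
linearly to zero over 4 days, a ramp chosen so that the new steady
state establishes itself around day 6.5 of the 21-day protocol; the
glutamine/alanine demands rise fourfold 6 h after onset (transcription
and translation delay). All protocol constants are arguments of
`ucd_protocol()`.

**Allopurinol therapy.** Gout is modelled purely as reduced renal
uric-acid clearance at unchanged production; the gouty and healthy
patients are calibrated to venous uric-acid steady states of 476 and
302 µM. Oral allopurinol (200 mg once daily for 35 days — the label
dose; the dosing interval is configurable since only the duration is
conventionally fixed) is absorbed first-order and oxidised by hepatic
xanthine oxidase to oxypurinol. The kinetic constants were chosen once
on pharmacological realism: whole-body half-lives of ~1.5 h for the
parent and ~21 h for oxypurinol (literature 18–30 h; the implied
~23 mL/min renal clearance puts the mean oxypurinol plasma level under
once-daily dosing near the observed ~45 µM), and liver partition
coefficients of 0.75 for both purine analogs (polar compounds
partition below unity). Xanthine-oxidase inhibition uses IC$_{50}$s of
13.4 µM (allopurinol) and 15.6 µM (oxypurinol). Uric-acid production
is direct-coupled to the network's uric-acid export under a
maximise-export objective, capped by the XO activity; renal uric-acid
excretion is first-order.

**Paracetamol overdose.** Three hepatic clearance pathways —
saturable glucuronidation and sulfation (Michaelis–Menten; sulfation
saturates first, so an overdose shifts disproportionately into the
toxic route) and first-order CYP2E1 N-hydroxylation — each form their
metabolite at yield 1. NAPQI is eliminated fast (glutathione
conjugation), and paracetamol cysteine is assumed
concentration-equivalent to NAPQI. Inhibition constants for THFDH,
GDH, ATPS and the glutathione-producing reactions are calibrated so
that the NAPQI peak after a lethal 15 g dose produces maximal
inhibitions of 25%, 25%, 60% and 80% of activity *lost*. The phrase
"reduced activity up to 25%" admits a second reading (reduced *to*
25%); both are implemented, `inhibition_reading = "lost"` is the
default because the glutathione statement ("depletion by up to 80%")
is unambiguous about direction and the four values are listed in one
breath. The objective panel is scanned at the paracetamol peak, the
NAPQI peak, and 24 h.

## The virtual population

`sample_population()` perturbs the ammonia production and the hepatic
and renal clearance constants independently per individual with
normal noise of 10% relative standard deviation, truncated at zero by
redrawing (rates cannot be negative; the choice of redraw over
clamping keeps the distribution shape intact at this CV, where the
truncation probability is ~1e-23 anyway). Independence across
parameters is an assumption; nothing in the biology forces production
and clearance variation to be uncorrelated, but no joint structure is
available to calibrate one. Endpoints are steady-state venous ammonia
concentrations — the healthy endpoint from the uncoupled model (exact
by the unperturbed-equivalence invariant) and the diseased endpoint
from the coupled model with OTC fully impaired and fourfold demands,
iterated to its own steady state. The two endpoint samples are
compared with the asymptotic two-sample Kolmogorov–Smirnov test
(`stats::ks.test`, `exact = FALSE`); the test suite checks the
asymptotic p-value against a 10,000-permutation estimate.

## What the fixtures do and do not show

Everything quantitative that the package reproduces — the healthy
29 µM venous steady state, the impaired uptake of 0.072 µmol/L/min,
the hyperammonemic ~34 µM endpoint, the ~69% uric-acid reduction —
lives on the toy networks, whose stoichiometry was constructed so that
these numbers are hand-checkable. A genome-scale reconstruction
differs in ways the toy networks deliberately do not emulate: internal
nitrogen sinks (which shift the baseline urea export from the toy
value 0.0725 to the genome-scale 0.070), alternate-optima structure
(which makes unchanged-flux percentages tolerance- and
solver-dependent), and the sheer number of liver objectives (the toy
panel has 12 constructed tasks, not 67 validated physiological ones).
Affected-objective *counts* on the toy panel are therefore checked
only for dose-monotonicity and set-recovery, never against
genome-scale counts. The SBML reader provides the genome-scale entry
path, but no genome-scale run is part of the test suite.

## Problem sizes

The shipped protocols run at full length: 21 simulated days at 1-min
coupling steps for the disease protocol (30,240 dFBA steps), 35 days
for the therapy protocol (50,400 steps), 100 + 100 virtual individuals
for the biomarker statistics, each iterated to steady state. The
whole-body fixture has 7 compartments; the toy networks have 4–35
reactions.

## Known limitations

* Intracellular metabolite pools are outside the formalism: a
  stoichiometric model cannot represent glutathione *depletion*
  mechanistically, only the phenomenological activity loss of
  glutathione-producing reactions.
* Sub-organ spaces (vascular/interstitial/intracellular) are supported
  by the types but the shipped fixtures lump them; intrahepatic
  concentrations therefore depend on a user-chosen partition
  coefficient and are not validated quantities.
* The drug PK fixtures are realistic in shape and scale but not fitted
  to any clinical time series; absolute concentration profiles are
  qualitative, and the scenarios validate steady states, ratios and
  orderings instead.
* One enzyme, one cap: competing substrates at one enzyme and
  regulatory (transcriptional) adaptation are not modelled.
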