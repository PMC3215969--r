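---
title: "Modeling electrically enhanced fermentation with electrofba"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling electrically enhanced fermentation with electrofba}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(electrofba)
```

## The problem

Anaerobic fermentation is redox-constrained: every NADH produced by
glycolysis must be reoxidized by reducing a partially oxidized intermediate
(ethanol, lactate, succinate, ...) that is then excreted. The stoichiometry
of the substrate therefore caps the yield of any product more reduced than
the substrate. Microbial electrosynthesis relaxes that cap by delivering
electrons from a cathode into the cell, where they regenerate NADH from
NAD+. `electrofba` implements the constraint-based (flux balance analysis)
treatment of this idea: it augments a stoichiometric model with the
electrode reactions, quantifies what the extra reducing power buys — ATP,
growth, product yield — and evaluates how growth-coupled strain designs and
batch operating strategies change when current is available.

## Flux balance analysis

A metabolic model is a stoichiometric matrix $S$ (metabolites × reactions)
with flux bounds $l \le v \le u$ (mmol/gDW-hr; the biomass reaction in
1/hr). FBA solves

$$\max_v \; c^\top v \quad \text{s.t.} \quad S v = 0, \; l \le v \le u,$$

with $c$ selecting one reaction (biomass, a product exchange, or the ATP
drain). `solve_fba()` solves this LP with the package's own
bounded-variable two-phase primal simplex (`R/lp.R`). Optimality and
pivoting tolerances are $10^{-9}$; steady state is asserted at
$\max|Sv| \le 10^{-6}$, comfortably below the 2–3 significant figures at
which results of this kind are reported. Dantzig pricing switches to
Bland's rule after a generous iteration budget so the degenerate vertices
typical of metabolic networks cannot cycle. The dense factor-per-iteration
design favours transparency and numerical robustness over raw speed; it is
sized for the networks the package computes on routinely (tens to a few
hundred reactions — the bundled synthetic networks solve in milliseconds, a
~100-reaction central-metabolism model in well under a second). For
genome-scale models (thousands of reactions) the I/O layer reads and writes
standard SBML/JSON so models augmented here can also be solved elsewhere;
solving them with the built-in simplex works but is slow.

The optimum of an LP is unique; the optimizing flux vector usually is not.
All reported flux distributions therefore come from `resolve_fluxes()`,
which re-solves with the objective pinned at its optimum and total absolute
flux minimized (the parsimonious criterion, implemented by splitting each
flux into positive and negative parts). Ties beyond parsimony are not
broken further; this is documented as a reporting convention, not a
biological claim.

## The electrode model

Two reactions represent the cathode (`add_electrode_reactions()`):

* an electron exchange `EX_e` (uptake only, bounded by
  `electron_uptake_max`), and
* a cytoplasmic NADH regeneration `NADHR`:
  $2\,e^- + \mathrm{NAD}^+ + \mathrm{H}^+ \rightarrow \mathrm{NADH}$,

the net reaction between an electrode and free cytoplasmic NAD+ through the
quinone pool. The electron species is new, formula-free and charge −1, and
occurs only in these two reactions, so electron uptake is always exactly
twice the regeneration flux. The default uptake bound is 30 mmol e-/gDW-hr,
equivalent to about 0.8 A/gDW — the magnitude of measured microbial
electron-transfer rates — and conversions between electron flux, per-mass
current and areal current density (via the (1.07 A/gDW, 1.143 A/m²)
biofilm correspondence) are provided by `flux_to_current()`,
`current_density()` and friends.

**Which proton?** The published reaction pair's proton compartment is not
machine-verifiable, so it is a parameter. The package default is the
*cytosolic* proton. The reasoning is mechanistic and was checked on a real
*E. coli* central-metabolism network: consuming a cytosolic proton per
NADH makes electron entry pull protons into the cell, which the
proton-translocating ATP synthase supplies while producing ATP — flipping
it from its fermentative ATPase mode (proton efflux at ATP expense) into
ATP synthesis. On that network the cytosolic choice yields the expected
phenotype (≈10% higher anaerobic growth on glucose, ATP synthase flux
reversing sign, ethanol flux nearly doubling while acetate collapses,
and a maximal-ATP gain of $e/16 \approx 1.9$ mmol/gDW-hr at $e = 30$,
because ATP synthase returns 3 of 4 translocated protons to the cytosol).
With a periplasmic proton and a freely exchangeable periplasmic pool, the
added reducing power is charge-neutral and buys nothing. Both options
remain selectable in `electrode_spec()`.

## Run conditions

A `condition()` bundles one experiment: named substrate uptakes (positive
magnitudes; exchange fluxes are negative for uptake), oxygen availability,
the electron-uptake bound, knockouts, and pathway additions.
`apply_condition()` opens the stated substrates, closes *other* organic
carbon exchanges for uptake (CO2, bicarbonate and formula-free species stay
open — the medium is otherwise unrestricted), closes oxygen uptake under
anaerobiosis, and never mutates its input. Substrate uptake rates follow an
equal-carbon basis of 60 C-mmol/gDW-hr: glucose, gluconate, sorbitol 10;
xylose 12; glycerol 20; maltose 5 mmol/gDW-hr; pyruvate, absent from the
stated list, gets 20 on the same basis. Electron uptake is a *bound*, not a
forced flux: the optimizer may use any rate between 0 and the bound, which
is why every enhancement result is a pure LP relaxation (enhanced optima
can never be worse, and envelopes at a larger bound contain those at a
smaller one pointwise). Where a fixed current matters — the electron-uptake
scan `optimal_electron_uptake()` — the exchange is pinned at each grid
value instead (default grid 0–30 in steps of 0.2, matching the one-decimal
precision such optima are reported with).

## SPEEQ: when does current help?

The degree of reduction used here is pyruvate-referenced bookkeeping, not
the classical elemental formula: NADH equivalents produced oxidizing a
substrate to pyruvate (or consumed making a product from pyruvate), per
carbon. The shipped panel stores the printed two-decimal values (xylose's
non-integer 1.67 NADH is taken as published) because those printed values
are the metric's operational definition; an optional network-based
recomputation was considered and rejected as a source of silent
disagreement. The substrate–product electron equivalence quotient

$$\mathrm{SPEEQ} = \frac{(\mathrm{NADH}/C)_{\text{substrate}}}{(\mathrm{NADH}/C)_{\text{product}}}$$

summarizes redox matching: quotients well below one mark conversions whose
yield is NADH-limited and thus electrically enhanceable.
`yield_improvement_grid()` computes, for each substrate–product pair, the
maximum theoretical yield (no biomass requirement) with the electrode
closed and at the stated bound. Yields are per mole of substrate taken up
by default; a per-total-incoming-carbon basis (substrate plus fixed CO2)
is available via `basis = "carbon"`. Products made through carboxylating,
NAD+-regenerating routes (anaplerotic ppc-style chemistry: succinate,
1,4-butanediol) beat the monotone SPEEQ trend because the extra NADH pushes
flux through CO2-incorporating reactions — carbon that never counts against
the substrate.

## Heterologous pathways

`pathway_library()` ships four routes with fixed, elementally balanced
stoichiometries (checked at construction against the formulas shipped with
each spec): 1,3-propanediol (B12-dependent glycerol dehydratase +
NADH-dependent oxidoreductase; 1 NADH per product), 1,4-butanediol
(succinyl-CoA → succinate semialdehyde → 4-hydroxybutyrate → 4HB-CoA →
4-hydroxybutanal → BDO; 4 NADH from succinyl-CoA), n-butanol (the
CoA-dependent condensation route; 4 NADH from 2 acetyl-CoA) and the
Wood-Ljungdahl pathway (CO2 → formate → formyl/methenyl/methylene/
methyl-THF; CO dehydrogenase + acetyl-CoA synthase; net
2 CO2 + 4 NADH + 1 ATP + CoA → acetyl-CoA). Two cofactor choices are fixed
and worth stating plainly: all reduction steps use NADH (not NADPH or
ferredoxin), and one ATP is spent at formyl-THF synthetase. CO2-only growth
predictions are sensitive to both; users reproducing acetogen physiology
should treat them as the package's documented convention, not settled
biochemistry. Growth-coupled knockout sets are *inputs*
(`strain_design()`); the shipped 3/5/10-knockout ethanol sets are labelled
examples in the style of published OptKnock-derived designs, not
authoritative reproductions. `coupling_report()` calls a design coupled
when the *minimum* product flux at maximal growth exceeds 1e-6 mmol/gDW-hr.

## Production envelopes and the two-phase strategy

`production_envelope()` fixes growth at each of 50 evenly spaced values
(default) on $[0, \mu_{max}]$ — $\mu_{max}$ included exactly, so coupling
at maximal growth is never an interpolation artifact — and records the
product flux range. Growth is fixed (equality), not bounded below; with a
free electron uptake inside its bound at every point, the envelope at a
larger bound provably contains the envelope at a smaller one.

`two_phase_productivity()` operationalizes the dynamic strategy — grow
first without current, then hold biomass and produce under current. It is
an operating-point calculator with closed-form integrals: exponential
growth at $\mu_{max}$ with the growth envelope's product rate until a
switch density, then constant-biomass production at the production
envelope's maximum-product point until the substrate pool runs out. No
ODE solver, no product inhibition, no maintenance decay. Switch-density
optimization is a grid search by the caller; on networks where the growth
and production optima differ, productivity (product per time) peaks at an
interior switch density.

## The synthetic network (and what it does not show)

`make_toy_model()` builds a minimal fermenter whose LP optima are known in
closed form (`toy_reference_optima()`): substrate uptake $U$ (default 10
mmol/gDW-hr, the study's glucose rate), lumped glycolysis producing $n$
NADH and $m$ ATP per substrate (defaults 2 and 2), a reduced product
consuming $k$ NADH (default 3 — redox-limited, the interesting regime), an
ATP-yielding oxidized product, a biomass drain with configurable ATP/NADH
demands (so both carbon-limited and redox-limited growth are
constructible), conserved NAD/NADH and ADP/ATP/Pi couples, and an
electron-uptake bound of 30. Closed forms cover the family
$k \ge \max(n, 1)$, biomass ATP demand ≥ 1, biomass NADH demand ≤ k; for
example the maximal reduced-product flux is $\min(U, (nU + e/2)/k)$, giving
the 20/3 → 10 (+50%) enhancement at the defaults. Degenerate corners
outside the family (e.g. $k < n$, where the network has no NADH sink and
every flux is zero) are covered in the tests by an independent brute-force
vertex enumeration of the flux polytope rather than by formulas. The
two-compartment variant adds a periplasm, an irreversible ATP synthase
(4 periplasmic H+ per ATP, protons returned to the cytosol) and an
H2-venting hydrogenase; cytosolic protons have no other source, so forcing
electron uptake $e$ forces ATP synthase flux of exactly $(e/2)/4$ — the
synthase-reversal mechanism reduced to linear algebra. An optional
carboxylating branch (precursor + CO2 + 3 NADH → 2-carbon product)
reproduces the above-trend yield gains of CO2-incorporating products.

The toy family is an oracle, not a simulation of *E. coli*: it has no
maintenance demand by default, no proton-coupled transport beyond the
synthase motif, integer stoichiometry, and a biomass "equation" of three
terms. Tests passing on it certify the solver, the augmentation mechanics
and the metric arithmetic — they say nothing about genome-scale numerical
difficulty or biological realism. The generator is deterministic; the only
randomness anywhere in the package's checks is the sampling of toy
configurations, under a fixed seed.

## Numerical conventions and degenerate inputs

* Exchange fluxes: negative = uptake; conditions store positive magnitudes.
* Infinite bounds are accepted and clamped internally at ±1e6; an optimum
  leaning on a clamp triggers a wider re-solve so genuinely unbounded LPs
  are reported as `unbounded`, never as a large number.
* Infeasible problems return `status = "infeasible"` with `NA` objective —
  never a silent zero. A lethal knockout set in `coupling_report()` is the
  one deliberate exception: it reports `mu_max = 0, coupled = FALSE`, which
  is the biologically meaningful answer.
* Fixed variables (knockouts) never enter the simplex basis; empty
  knockout sets are identity operations.
* Percent changes in `flux_change_summary()` are computed on parsimonious
  distributions only and the function refuses raw solver vertices.
* Yield denominators below 1e-9 mmol/gDW-hr give `NA` yields; grid records
  for infeasible pairs are flagged, never dropped.

## Interfaces

The package is function-first: tibble-returning verbs that chain with the
pipe, `autoplot()` methods for envelopes and SPEEQ grids, `tidy()`/
`glance()` for fits, TSV/JSON report writers and a `run_manifest()` for
reproducibility. Models move through SBML Level 3 (FBC) or BiGG-style
JSON; conditions, designs and pathways through YAML/constructors. The
repository's `scripts/acceptance.R` recomputes the headline quantities
from scratch and writes them as JSON.

## Known limitations

* No gene–protein–reaction rules: knockouts are reaction-level, as in the
  strain-design tables the package consumes.
* No thermodynamic/loopless constraints and no mediator electrochemistry
  (neutral red, methyl viologen kinetics, overpotentials are out of scope);
  the electrode is a stoichiometric electron source with a flux bound.
* Electron donation to an anode (the reverse operation) is not modeled.
* The built-in simplex is not a genome-scale workhorse; see above.
* Published genome-scale results of this kind depend on supplementary
  reaction lists (exact electrode pair, Wood-Ljungdahl cofactors, knockout
  sets) that are not independently verifiable; where those inputs matter
  the package exposes them as configuration with documented defaults
  rather than hard-coding one guess as truth.
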