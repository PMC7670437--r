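---
title: "Methods: sigma-profile activity models and pharmaceutical solid-liquid equilibria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sigma-profile activity models and pharmaceutical solid-liquid equilibria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cosmopharm)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, the
numerical choices, what the synthetic-data generator does and does not
emulate, and the design decisions taken where the underlying equations
left genuine freedom.

## 1. From cavity surface to sigma profile

A continuum-solvation (COSMO) calculation embeds a molecule in a virtual
conductor and reports, for every surface segment of the molecular cavity,
its position, area $A_n$ and screening-charge density $\sigma^*_n$, plus
the cavity's total area $A$ and volume $V$. `parse_cosmo_file()` reads two
text layouts — the Å-based layout this package writes, and an
atomic-unit layout (recognised by an `[au]` marker) converted at parse
time with 1 bohr = 0.52917721067 Å. Internally everything is Å, Å², Å³
and elementary charge. Parsing enforces three structural invariants: the
header area must agree with the segment-table sum within 2 %, every
segment must reference an existing atom, and the net surface charge must
vanish within 0.01 e — a conductor, by construction, neutralizes the
solute.

Raw charge densities are too granular to compare across molecules, so
they are smoothed over neighbouring segments with the Gaussian-distance
weight

$$\sigma_m =
  \frac{\sum_n \sigma^*_n\, f_{mn}}{\sum_n f_{mn}},\qquad
  f_{mn} = \frac{r_{ave}^2 r_n^2}{r_{ave}^2+r_n^2}
  \exp\!\left(-\frac{d_{mn}^2}{r_{ave}^2+r_n^2}\right),
  \qquad r_n = (A_n/\pi)^{1/2},$$

with the segment itself included ($d_{mm}=0$); dropping the self term
would make single-segment molecules ill-defined and biases $\sigma_m$ for
all others. The averaging radius defaults to $r_{ave} = 0.81764$ Å, the
value used with the public sigma-profile databases; it is a tunable
argument, and no decay-factor variant of later model generations is
offered — the averaging kernel above has none.

The sigma profile $p(\sigma)$ is the histogram of surface area over 51
grid points on $\sigma \in [-0.025, 0.025]$ e/Å² in 0.001 steps. A
segment's area is split linearly between the two bracketing grid points:
with $w = (\sigma-\sigma_{left})/0.001$, the left point receives
$(1-w)$ of the area and the right point $w$. (An orientation that gave
the left point the weight $w$ would contradict $w$'s own definition and
shift the profile's mean charge density; the standard interpolation used
here conserves it exactly.) Segments that average beyond the grid — rare,
but possible for exotic inputs — are clamped to the edge bins with a
warning rather than dropped, so area is never lost. Two conservation laws
hold by construction and are tested: $\sum_m p(\sigma_m) = 1$ and the
binned area equals the segment-table area.

### The hydrogen-bonding split

The revised activity model distinguishes three surface classes: hydroxyl
surface (OH), "other" hydrogen-bonding surface (OT: N, F, and hydrogens
bonded to N/F), and the non-hydrogen-bonding rest (NHB). Class membership
is decided per atom and inherited by its segments. Since the source
equations never state how bonding is detected, the package infers a
covalent bond when the interatomic distance is below 1.25 times the sum
of covalent radii — a conventional cutoff that is robust for organic
geometries. Oxygen and O-bonded hydrogen are OH; nitrogen, fluorine and
their hydrogens are OT; a hydrogen bonded to both takes OH.

In each bin the tagged area moves out of NHB with the Gaussian weight
$g(\sigma) = 1-\exp(-\sigma^2/\sigma_o^2)$, $\sigma_o = 0.007$ e/Å², and
is divided between OH and OT in proportion to the bin-wise tagged areas:

$$p^{OH}(\sigma) = g(\sigma)\,\frac{A^{OH}(\sigma)}{A_{total}},\qquad
  p^{OT}(\sigma) = g(\sigma)\,\frac{A^{OT}(\sigma)}{A_{total}},\qquad
  p^{NHB} = p - p^{OH} - p^{OT}.$$

A literal reading of the usual split formulas applies the
$A^{OH}/(A^{OH}+A^{OT})$ prefactor to the *total* $p(\sigma)$, which
would relocate untagged (NHB) area into the OH part whenever a bin mixes
classes; the form above moves only tagged area, agrees with the literal
form in single-class bins, and keeps the three parts summing to the
unsplit profile exactly — the invariant the tests freeze. Weakly charged
surface stays NHB even on tagged atoms ($g(0)=0$): a hydroxyl patch only
*counts* as hydrogen-bonding where its charge density is large enough to
act as donor or acceptor.

## 2. Activity models

All models share one interface: `lngamma(model, x, T)` returns
$\ln\gamma_i$ for the model's fixed component list. Compositions may
contain exact zeros; every infinite-dilution quantity in the package is
evaluated at $x_i = 0$ analytically (the ratios $\phi_i/x_i$ and
$\theta_i/\phi_i$ reduce to ratios of the pure-component parameters), not
by extrapolation.

### Segment activity coefficients

Both segment models add a Staverman–Guggenheim combinatorial term
(normalized volume $r_i = V_i/r_o$, area $q_i = A_i/q_o$, coordination
number $z = 10$) to a residual obtained from the self-consistent segment
equation

$$\ln\Gamma(\sigma_m) = -\ln \sum_n p(\sigma_n)\,\Gamma(\sigma_n)\,
  e^{-\Delta W(\sigma_m,\sigma_n)/RT},$$

solved by successive substitution with damping 0.5 — full (undamped)
updates can oscillate for strongly hydrogen-bonding profiles, while 0.5
converges in tens of iterations on every profile the generator can
produce. Convergence is declared when the undamped candidate changes by
less than $10^{-8}$ relatively (1000-iteration cap, error with the
residual otherwise); the candidate itself is returned, so the reported
solution satisfies the fixed point tighter than the stopping rule. The
mixture profile is the area-weighted average
$p_S = \sum_i x_i A_i p_i / \sum_i x_i A_i$ with *total* molecular areas
as weights — bin-wise area weights would double-count $p_i(\sigma)$,
which is already area per bin.

The original exchange energy is

$$\Delta W = \tfrac{\alpha'}{2}(\sigma_m+\sigma_n)^2 +
  c_{hb}\,\max(0, \sigma_{acc}-\sigma_{hb})\,\min(0, \sigma_{don}+\sigma_{hb}),$$

with defaults $a_{eff}=7.50$ Å², $\alpha' = 16466.72$,
$c_{hb}=85580.0$ kcal Å⁴/(mol e²), $\sigma_{hb}=0.0084$ e/Å²,
$q_o=79.53$ Å², $r_o=66.69$ Å³, $R=0.001987$ kcal/(mol K). These eight
constants are *configuration*: the study this package operationalizes
cites them from the literature rather than printing them, so
`cosmosac2002_params()` treats every one as an overridable default. The
hydrogen-bond term is non-positive (attractive) and active only when a
genuine donor ($\sigma < -\sigma_{hb}$) meets a genuine acceptor
($\sigma > +\sigma_{hb}$).

The revised model replaces the constant electrostatic coefficient with
$A_{ES} + B_{ES}/T^2$ ($A_{ES}=6525.69$, $B_{ES}=1.4859\times10^8$ in the
same units) and gives each OH/OT class pair its own hydrogen-bond
constant ($c_{OH\text{-}OH}=4013.78$, $c_{OT\text{-}OT}=932.31$,
$c_{OH\text{-}OT}=3016.43$), applied to $(\sigma_m-\sigma_n)^2$ for
opposite-signed pairs. Some transcriptions print this term with a
positive sign, which would make hydrogen bonding repulsive and cannot
produce association; the package defaults to the attractive sign
(`hb_sign = -1`) and retains the literal form behind the flag. With
$B_{ES}=0$, $A_{ES}=\alpha'/2$ and a profile that is entirely NHB, the
revised model reproduces the original exactly below the hb cutoff — a
degeneracy the tests exploit as a cross-check.

### Hansen-parameter Flory–Huggins

The semi-predictive route computes
$\chi_{ij} = \frac{V_i}{RT}[(\Delta\delta_d)^2 + 0.25(\Delta\delta_p)^2 +
0.25(\Delta\delta_h)^2]$ from Hansen parameters (δ² in MPa = J/cm³, V in
cm³/mol, R = 8.314 J/(mol K)) and inserts it into the multicomponent
activity expression

$$\ln\gamma_i = \ln\frac{\phi_i}{x_i} + 1 - \frac{\phi_i}{x_i}
  + 2V_i\sum_j \chi_{ij}\phi_j^2 - V_i\sum_j\sum_k \phi_j\phi_k\chi_{jk}.$$

Because $\chi_{ij}$ already contains $V_i$, the expression as written
multiplies by a molar volume twice. The shipped default, convention
`"per-volume"`, divides the kernel by $V_i$ (making it symmetric) before
the $V_i$-weighted sums, restoring dimensional consistency; convention
`"as-printed"` evaluates the expression literally, which yields
$\ln\gamma$ of order $10^3$ for aqueous drug systems. The calibration
that was meant to pick between the two — reproducing tabulated
Flory–Huggins partition coefficients — cannot: `fh_logkow_report()`
computes every reference compound under both conventions and shows that
neither lands within 0.05 of any tabulated value (the tabulated values
are uniformly negative, which would require the aqueous activity
coefficient to be *smaller* than the octanol one for hydrophobic drugs —
unreachable with a non-negative quadratic χ). The package therefore
reports the per-compound discrepancy openly instead of absorbing it, and
keeps the dimensionally consistent convention as default.

Two structural caveats, both frozen in tests rather than patched:

* **Thermodynamic consistency.** The doubled interaction term makes the
  expression non-derivable from a free energy, so it violates the
  Gibbs–Duhem relation at order χ (for equal molar volumes the residual
  is exactly $2V\kappa(2x_1-1)$ with κ the symmetric kernel). The two
  segment models, by contrast, pass a finite-difference Gibbs–Duhem check
  at $10^{-8}$.
* **Group-contribution composition.** `hansen_from_groups()` implements
  the composition rules literally, including
  $\delta_h = (\sum E_h)^{1/2}/\sum V$; group values are user input and
  the consistency identity $\delta_t^2 = \delta_d^2+\delta_p^2+\delta_h^2$
  is applied on top.

### The bundled parameter table

`bundled_hansen_table()` ships 42 hand-transcribed records (13 solvents,
29 drugs) with $\delta_t,\delta_d,\delta_p,\delta_h$, the Flory–Huggins
molar volume and the cavity-derived molar volume. Three drug rows
(salicylic acid, pentoxifylline, carvedilol) have typographically
ambiguous source digits; they carry `ambiguous = TRUE`, store the parse
that maximizes the $\delta_t$ consistency identity and molar-volume
plausibility, and are excluded from consistency-grade checks. The
identity itself holds to better than 0.015 MPa$^{0.5}$ on every
unambiguous drug row; four solvent rows (1-propanol, 2-propanol, acetone,
ethyl acetate) miss it by up to 0.1 because their one-decimal totals were
rounded independently of their components in the source — a property of
the table, not of the transcription, and the tests bound the two groups
separately.

## 3. Solid–liquid equilibria

Saturation of a solid in a (mixed) solvent solves

$$\ln x = \frac{\Delta H_m}{R}\Big(\frac{1}{T_m}-\frac{1}{T}\Big)
  - \frac{\Delta C_p}{R}\Big(1-\frac{T_m}{T}-\ln\frac{T}{T_m}\Big)
  - \ln\gamma(x)$$

by damped fixed point on $x$ (damping 0.5, tolerance $10^{-8}$, 500-step
cap), with the user-supplied *solute-free* solvent fractions rescaled by
$1-x$ at every iterate — the convention that keeps the solvent ratio
meaningful as the solubility grows. $\Delta C_p$ defaults to 0 (its term
vanishes at $T_m$ anyway and is rarely known); above the melting point
the ideal term exceeds 1 and the solver clamps to 1 with a warning. For
an ideal solution the first iterate is already exact, and the solver
agrees with a $10^6$-point scan of the residual to grid resolution — the
oracle the tests use.

`log_kow()` evaluates the solute at infinite dilution in pure water and
in the 27.5/72.5 mol% water/octanol phase and combines the two with the
total-concentration ratio $C_{o,W}/C_{o,O} = 0.151$, entirely in log
space so extreme activity coefficients cannot overflow. The water-rich
phase contains no octanol and no solute: true infinite dilution. The
temperature for tabletop partition calculations defaults to 298.15 K,
the ambient standard, since the reference values state none.

### Cocrystals

A cocrystal $A_aB_b$ dissolves congruently when the activity product
$K_{CC} = (x_A\gamma_A)^a(x_B\gamma_B)^b$ reaches its
temperature-specific solubility product — a solvent-independent constant,
so one measured saturation point (via `kcc_from_point()`) calibrates the
whole diagram. The two invariant points, where a pure solid and the
cocrystal saturate simultaneously, are found by deterministic bisection
along each solubility line, parameterized by the co-former fraction of
the solute-free liquid: a 1-D search along a curve both of whose
endpoints are physically constrained, which is markedly more robust than
2-D root finding and needs no starting guess. A coarse 40-point scan
brackets the sign change first; no bracket means no cocrystal region at
that temperature, and the error says so. The cocrystal line between the
invariant points re-solves the activity product for $x_B$ on an $x_A$
grid (inner damped fixed point, stopping on the log-residual below
$10^{-8}$, with one final undamped step so ideal systems return the
$x_B = K_{CC}/x_A$ hyperbola exactly). Note the geometry: a *larger*
$K_{CC}$ means a more soluble, less stable cocrystal, so the region
between the invariant points narrows as $K_{CC}$ grows and vanishes when
it reaches the product of the two pure-saturation activities — the
degenerate single-eutectic case.

`ternary_diagram()` assembles both solubility lines, the cocrystal line
and the invariant points; every exported point closes its mass balance to
$10^{-9}$ and satisfies its defining equation below $10^{-6}$.
Mass-fraction export requires user-supplied molar masses. The quick-look
`plot()` method draws the standard triangle with base graphics.

## 4. Error statistics

`aad_percent()` and `rmse()` are the usual mean absolute relative
deviation (in percent, undefined and refused for zero reference values)
and root-mean-square error. `fit_metrics()` returns the fit-style
goodness measures with the experimental series as reference:
$MSE = \lVert e\rVert^2/n$,
$NRMSE = 1 - \lVert e\rVert/\lVert \Omega_{exp}-\bar\Omega_{exp}\rVert$,
$NMSE = 1 - \lVert e\rVert^2/\lVert \Omega_{exp}-\bar\Omega_{exp}\rVert^2$
— the conventions in which 1 is a perfect fit and values go negative for
models worse than the reference mean, which is the only reading
consistent with negative published values of these measures. They obey
$NMSE = 1-(1-NRMSE)^2$ identically, and with a mean-centred reference all
three are invariant under a common shift of both series; both properties
are frozen in tests to catch silent convention drift.

## 5. What the synthetic generator emulates — and what it does not

`make_toy_molecule()` produces cavity surfaces that exercise every code
path of the pipeline: equal-area segments on a sphere, three charge
patterns (`neutral-apolar` stays strictly below the hb cutoff so
hydrogen-bond terms are provably zero; `donor-acceptor-pair` places
contiguous ±0.012 e/Å² polar caps — contiguous so the Gaussian averaging
cannot wash them below the cutoff; `uniform` for degenerate-input tests),
and optional O–H / N atoms under the caps so the OH/OT split activates.
Net charge is exactly neutralized; every toy passes the full molecule
validation. Determinism is per named seed, and the global RNG stream is
left untouched.

What the toys are *not*: quantum-derived surfaces. Real drug profiles
have asymmetric multi-modal peaks, areas spanning two orders of
magnitude, and charge-geometry correlations the sphere cannot produce.
Passing tests therefore demonstrate the correctness of the machinery —
conservation, convergence, limits, oracle equivalence — not predictive
accuracy for real molecules, which requires real COSMO files (the parser
accepts the public database layout for exactly that purpose).

`make_solubility_dataset()` emulates a literature solubility compilation
as the van 't Hoff curve of a known solid times multiplicative log-normal
noise $e^{\epsilon}$, $\epsilon \sim N(0, sd^2)$ — the natural error
model for quantities spanning decades, with
$E|e^\epsilon-1| \approx sd\sqrt{2/\pi}$ (about 8 % at $sd=0.1$), which
the statistics module recovers. The recovery check fits $\Delta H_m$ by
unweighted least squares on the no-intercept van 't Hoff line (melting
point known) and lands within two standard errors of the generating
value at $sd=0.05$, $n=20$ — the acceptance surface of the whole
analysis pipeline. Study conditions (26 kJ/mol, $T_m = 420$ K, 5 K
spacing over 278–373 K, 5 % noise) are typical of published drug
solubility work.

## 6. Problem sizes and determinism

Everything in the test suite and the acceptance script runs on fixed
51-bin profiles (153 stacked bins for the split model), toy molecules of
25–60 segments, 2–3-component mixtures, 20-point synthetic studies and
diagram grids of 5–25 points — sizes chosen so each model evaluation is
milliseconds and a full verification pass stays comfortably interactive
while still exercising every branch. The only randomness anywhere is the
seeded toy geometry and the seeded synthetic noise; every solver in the
package (segment fixed point, solubility fixed point, bisection, inner
cocrystal iteration) is deterministic with documented tolerances and
iteration caps, so identical inputs give identical results to the last
bit.

## 7. Known limitations

* The Flory–Huggins expression is used exactly as published, including
  its Gibbs–Duhem violation and its inability to reproduce the published
  partition-coefficient values it was paired with; both are documented
  and reported, not repaired.
* No dispersion-corrected or equation-of-state-combined segment-model
  variants, and no alternative averaging kernels with decay factors.
* The universal constants are literature defaults, not refitted; any
  mismatch with profiles generated under different quantum settings
  propagates directly into the activity coefficients.
* Hydrogen-bond classification is geometric (distance cutoff); unusual
  bonding situations (bridging hydrogens, charged species) may be
  misclassified.
* Cocrystal diagrams assume a single stoichiometric cocrystal phase;
  polymorphism, solvates and solid solutions are out of scope.
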