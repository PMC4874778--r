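---
title: "Mean-field thermodynamics of FG-nucleoporin assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mean-field thermodynamics of FG-nucleoporin assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgnupfield)
```

## The model

The nuclear pore complex is lined by intrinsically disordered FG
nucleoporins (FG nups) whose collective conformations -- and their response
to the soluble transport proteins (Karyopherins/Importins, NTF2) that ferry
cargo through the pore -- control nucleocytoplasmic transport.  This
package implements a deliberately minimal mean-field description of those
assemblies.  FG nups are flexible chains of `N` coarse-grained monomers of
volume $v_0 = l^3$ connected at Kuhn length $b$; transport proteins are
rigid particles of $\bar v = v/v_0$ monomer volumes.  Everything else is
folded into two dimensionless interaction parameters, both negative when
attractive:

* $\chi$ -- the effective protein--monomer attraction (per protein), and
* $\chi_{cr}$ -- the monomer--monomer cohesion.

The local state of any region is the pair of volume fractions
$(\psi, \phi)$ of monomers and proteins, with solvent filling
$1 - \psi - \phi$.  The mixing free-energy density, in $kT$ per monomer
volume, is

$$
f(\psi,\phi) = \frac{\phi}{\bar v}\ln\phi
 + (1-\psi-\phi)\ln(1-\psi-\phi)
 + \Big(\frac{1}{\bar v}-1\Big)(1-\phi)\ln(1-\phi)
 + \frac{\chi}{\bar v}\,\psi\phi
 + \frac{\chi_{cr}}{2}\,\psi^2 ,
$$

and bulk solutions of free chains add the translational entropy
$\psi\ln(\psi)/N$.  The third (asymmetric excluded-volume) term is kept
exactly in this form; alternative lattice-fluid expressions change numbers
slightly but not the behaviour repertoire.  All analytic derivatives --
the protein exchange chemical potential, the chain chemical potential and
the osmotic pressure -- are closed forms
(`chemical_potential_protein()`, `chemical_potential_polymer()`,
`osmotic_pressure()`), cross-checked in the test suite against central
finite differences and the Gibbs–Duhem relation.

**Normalization conventions.**  The protein chemical potential is reported
*per protein* (it is $\bar v\,\partial f/\partial\phi$), so matching an
ideal dilute reservoir of volume fraction $c$ reads exactly
$\mu = \ln c$, and $\partial\mu/\partial\chi = \psi$.  The chain potential
is reported *per monomer* with the $1/N$ translational term retained.
These choices are fixed package-wide; only differences of potentials enter
any equilibrium condition, so they are conventions, not physics.

## Grafted layers

A layer of chains grafted a distance $a$ apart (normalized grafting
density $\bar\sigma = (l/a)^2$) with uniform composition and normalized
height $\bar h = h/L$ has grand potential per unit area, in units of
$kT\,L/l^3$,

$$
\Omega(\bar h,\phi) = \frac{\bar\sigma\,\bar h^2}{2}\frac{l}{b}
 + \bar h\Big[f(\psi,\phi) - \frac{\phi\,\ln c}{\bar v}\Big],
 \qquad \psi\,\bar h = \bar\sigma\,\frac{l}{b},
$$

where the constraint expresses monomer conservation (each monomer occupies
contour $b$ and volume $l^3$, so a chain of contour $L$ carries $L/b$
monomers).  This dimensional reading is the unique one consistent with
both the conservation constraint and the ideal-brush limit: expanding the
solvent entropy for small $\psi$ and minimizing gives
$\bar h = (\bar\sigma l/2b)^{1/3}$, i.e. the classical exponent
$h \sim a^{-2/3}$.  The Gaussian stretching prefactor is kept at $1/2$;
`layer_params(elastic_prefactor = 3/2)` switches to the other common
convention, changing heights by a constant factor and nothing else.  The
reservoir osmotic work term $-\pi_c \bar h$ is omitted by default
($\pi_c = c/\bar v \lesssim 10^{-8}$ at micromolar concentrations);
`include_reservoir_work = TRUE` restores it.

`solve_layer_equilibrium()` minimizes $\Omega$ globally: a dense
logarithmic sweep over $\bar h$ with an inner one-dimensional minimization
over $\phi$ at each height (log-spaced scan plus local refinement),
followed by a Newton polish of the stationarity conditions to residuals
below $10^{-9}$.  Ties between degenerate minima resolve towards the
larger height.  The inner problem can have two competing minima -- that is
the cooperative penetration transition -- and the global scan, not a local
root, decides between them.  Response curves (`layer_response_curve()`)
additionally warm-start each solve from the previous concentration so a
continuous branch is followed; a first-order branch jump then appears as a
visible discontinuity rather than solver noise.

### The effective scaling exponent

`scaling_exponent_g()` fits $|d\ln\bar h / d\ln a|$ by least squares over
a configurable window, default $a/l \in [2, 10]$ with 25 log-spaced
points, matching the grafting distances of typical surface experiments
(2--10 nm at $l = 1$ nm).  Two properties of this estimator are worth
stating plainly, and both are computed by the test suite rather than
assumed:

* With strong cohesion ($\chi_{cr} = -2.5$) the layer is an
  incompressible melt of nearly constant $\psi$, so $\bar h \propto
  \bar\sigma$ and the fitted exponent is 2 to within half a percent.
* With no cohesion the value $2/3$ is the *asymptotic dilute* slope.  In
  the default window the layer is still appreciably dense at the close
  end ($\psi \approx 0.35$ at $a/l = 2$ for $b/l = 1.52$), higher-order
  terms of the solvent entropy steepen the local slope, and the fitted
  exponent is $\approx 0.71$.  It decays to $2/3$ (within 0.01) only for
  windows around $a/l \sim 40$ and beyond.  We keep the experimental
  window as the default and report the effective exponent as computed; the
  suite asserts the monotone convergence towards $2/3$ instead of forcing
  the asymptote onto the near window.

`fit_cohesion()` inverts the height curve for $\chi_{cr}$ by
least squares; recovery on synthetic curves is accurate to a few
hundredths, and to $\pm 0.15$ under 5% multiplicative height noise.  A
flat residual landscape (all points in the dilute-brush regime) is
flagged `non-identifiable` rather than returning a spurious optimum.

### Collapse/swelling phase diagrams

`layer_phase_diagram()` scans reservoir concentrations up to a bound
`c_max` (1 uM converted by the units module by default) for every
$(a, \chi)$ cell and classifies it as *collapse only*, *collapse and
swelling*, *swelling only* or *inert*, recording the deepest compaction
$h_{min}/h_0$, the concentration at which it occurs and the protein uptake
there.  Three qualitative facts are asserted by the acceptance tests: the
three regions coexist in the diagram; at zero attraction the column is
inert; and the smaller NTF2-sized particle ($\bar v = 40$) compacts the
layer at weaker attraction than a Karyopherin-sized one
($\bar v = 125$), because its insertion costs less chain entropy.

## Bulk phase separation

For free chains, `binary_critical_point()` solves
$\partial^2 f/\partial\psi^2 = \partial^3 f/\partial\psi^3 = 0$
numerically; the closed forms $\psi_c = 1/(1+\sqrt N)$ and
$|\chi_{cr,c}| = (1+\sqrt N)^2/N \to 1 + 2/\sqrt N$ serve as the test
oracle.  `binary_binodal()` parametrizes coexistence candidates by the
common chain chemical potential -- monotone on either side of the spinodal
-- and root-finds the osmotic-pressure mismatch, entirely in log
composition, since dilute branches scale like $e^{-O(N)}$.  Residuals of
both equalities are held below $10^{-9}$, and the test suite confirms the
result against an independent common-tangent (lower convex hull)
construction on a $10^5$-point grid.

`ternary_tie_line()` solves the five-equation system (equal chain
potential, equal protein potential, equal pressure, two lever-rule mass
balances) for the two phases and the dense-phase volume fraction.  The
multiple-root problem is resolved deterministically by continuation: the
protein-free binary binodal seeds the system and the overall protein
content is ramped up logarithmically with a damped Newton solve at each
step.  Compositions where the lever fraction leaves $(0,1)$, the phases
merge (within $10^{-6}$), or no protein-free coexistence exists are
reported as `single-phase` status, not errors; that includes the
re-dissolution regime where a large amount of attractive protein pulls the
system out of the two-phase region.  One protein species is treated per
tie-line, matching how partitioning experiments are run; multi-species
coexistence is out of scope.

`partition_report()` runs one tie-line per species against a common FG nup
background and calls each species *in* or *out* by
$\phi_{dense} > \phi_{dilute}$.  The default background is a cohesive
Nup98-like chain ($N = 167$ monomers of 1 nm, $\chi_{cr} = -1.5$) at 5 uM
with 1 uM protein.  The species table (`partitioning_species()`) mixes
measured quantities (NTF2 $\bar v = 40$, $\chi = -75$; Importin-beta
$\bar v = 125$, $\chi = -215$) with explicitly flagged assumptions: cargo
masses (GFP 27 kDa, IBB 10 kDa, MBP 42 kDa, ZsGreen 26 kDa) converted at
density 1.35 g/cm$^3$, a slightly weakened $\chi = -200$ for cargo
complexes standing in for direct cargo--chain repulsion, and a tetramer
with four times the Importin-beta volume-plus-cargo and four times its
$\chi$.  Under these assumptions the computed pattern is: carriers and the
tetramer partition in, both cargo complexes and the inert TEV-mCherry
control stay out.  The calls for the tetramer and the mid-sized complex
sit closest to the in/out boundary, so they are the ones most sensitive to
the assumed masses -- which is why the assumptions are config-overridable
rather than hard-coded truths.

## Single chains

An isolated chain occupies a sphere of radius $R$ (in Kuhn lengths) with
uniform interior fraction $\psi = N(l/b)^3 / \frac43\pi R^3$, and
minimizes $3R^2/2N + \frac43\pi R^3 f(\psi)$ with the protein-free $f$.
The elastic term is kept exactly as written with $R$ in Kuhn lengths;
the monomer volume then enters only through $(l/b)^3$ (default
$1/1.52$, i.e. a four-amino-acid monomer), which makes all reported
quantities independent of the absolute monomer size -- asserted in the
tests by rescaling $l$ and $b$ jointly.  Two consequences of taking the
printed form at face value deserve a note:

* The Gaussian term penalizes stretching only; compression is stabilized
  by the higher-order solvent-entropy terms.  The *amplitude* of
  $R/\sqrt N$ at $\chi_{cr} = 0$ is therefore below 1 in the studied
  $N$ range even though the *exponent* is the swollen-coil 3/5.  We treat
  the exponent, not the amplitude, as the physically meaningful output,
  and the theta-like point is identified by $\nu \approx 1/2$ at
  $\chi_{cr} = -1$ (where cohesion cancels the leading excluded-volume
  repulsion) rather than by $R/\sqrt N = 1$.
* For strong cohesion the interior fraction saturates at an
  $N$-independent value set by the zero of the osmotic pressure, giving
  the space-filling scaling $R \propto N^{1/3}$.

`scaling_exponent_nu()` fits $\nu$ over 8 log-spaced chain lengths in
$[40, 400]$, bracketing the 43--152-monomer range of the FG nup constructs
the model is meant to describe.  At $\chi_{cr} = -1.5$ the fitted
$\nu = 0.338$, at the collapsed-globule floor; `classify_coil()` maps
fitted exponents onto the empirical *extended* (0.52--0.54) and
*collapsed* (0.33--0.40) bands with a configurable $\pm 0.01$ tolerance.

## Units and scenarios

`protein_volume_from_mass()` converts masses at an assumed density of
1.35 g/cm$^3$ (midpoint of the 1.2--1.5 range for folded proteins);
`volume_fraction_to_molar()` and its inverse use a maximal packing
fraction, default $z = 0.625$ (random close packing), $z = 0.75$ in the
alternative binary-coexistence scenario.  `chi_from_binding()` maps
binding-site counts and per-site energies to $|\chi| = n\,\epsilon\,
e^{\epsilon}$; six sites of 2.5 kT give the Karyopherin-like
$|\chi| \approx 183$.  `fg_scenario()` freezes every parameter set used by
the worked analyses, each with a provenance note; values that are
assumptions (the cargo masses, the cohesion of the phase-diagram
scenarios) say so in the note.

## Numerical choices and limitations

* Logs are clamped at $10^{-300}$ only after explicit domain validation;
  $x\ln x$ is continuous at 0 by construction, and compositions with
  $\psi + \phi \ge 1$ raise domain (or, for layers, infeasibility) errors
  rather than being clipped.
* All optimizer results are cross-checked in the tests against independent
  oracles: exhaustive 2-D grids for layers, golden-section scans for
  coils, convex-hull tangent constructions for binodals and a
  tangent-plane stability check for ternary tie-lines.
* Problem sizes in the tests (grids of a few hundred points, 10-point
  concentration scans, a 3x3 phase-diagram) were chosen so the whole suite
  runs in under two minutes while still exercising every solver branch;
  the same functions scale to publication-resolution grids unchanged.
* The layer model assumes a uniform density profile and Gaussian
  elasticity: it is quantitatively reliable for moderately cohesive,
  moderately loaded layers and is read qualitatively elsewhere.  It has no
  kinetics -- adsorption lag, droplet coarsening and interfacial structure
  are outside the model.
* Ternary coexistence is seeded from the binary binodal, so
  protein-*induced* phase separation of a subcritically cohesive chain
  solution (possible in principle) is reported as `single-phase`; mapping
  that regime would need a different continuation anchor.
* Sequence heterogeneity is absent by design: one $\chi_{cr}$ per chain,
  one $\chi$ per protein species.
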