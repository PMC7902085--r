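---
title: "Markov state modelling of coarse-grained protein-protein association with gomsm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markov state modelling of coarse-grained protein-protein association with gomsm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gomsm)
```

## The model

`gomsm` studies reversible association of two proteins with a
residue-level coarse-grained (CG) Gō model: one bead per residue, and the
binding interface encoded as a handful of attractive 6-12 contacts

$$U_{\mathrm{G\bar o}}(r) \;=\; \varepsilon\left[\left(\frac{R_{\min}}{r}\right)^{12}
 - 2\left(\frac{R_{\min}}{r}\right)^{6}\right],$$

which attains its minimum $-\varepsilon$ exactly at $r = R_{\min}$ (the
$R_{\min}$ convention used by the NAMD/CHARMM toolchain; this is why the
curated contact distances can be stored verbatim as the potential's
minima).  The remaining terms of the energy are

* an intra-chain harmonic elastic network (cutoff 12 Å, $k =
  10\,\mathrm{kcal/mol/\AA^2}$ by default) that preserves each fold.  The
  literature model applies "RMSD restraints" with no printed force
  constant; an elastic network has equivalent intent, an analytic
  gradient, and is directly testable, so it is the implementation chosen
  here;
* per-bead harmonic tethers pinning chain A to its reference pose
  ($k = 10\,\mathrm{kcal/mol/\AA^2}$), fixing its position *and*
  orientation so the chain-chain centre-of-mass (COM) distance is a clean
  association coordinate;
* a flat-bottom spherical wall on the COM of the free chain B (radius
  $r_{\mathrm{cavity}} = 73.46$ Å by default, half-harmonic outside,
  $k = 10\,\mathrm{kcal/mol/\AA^2}$).  The cavity fixes the effective
  concentration $C = 1/V$ with
  $V = \tfrac{4}{3}\pi(r_{\mathrm{cavity}}^3 - r_{\mathrm{cut}}^3)$.
  Note that direct arithmetic on these radii gives $C \approx 1.07$ mM,
  not the 1 µM sometimes quoted for this geometry; the package always
  computes $C = 1/V$ and never hard-codes a nominal concentration;
* optionally an umbrella bias $U = \tfrac{k}{2}(d - d_0)^2$ on the COM-COM
  distance $d$.  Only "spring constants of 1 kcal/mol" are printed for the
  production umbrella campaign, so the $\tfrac12$ factor is a declared
  package convention, used consistently when bias energies are handed to
  TRAM.

All quantities are in Å, kcal/mol, amu and fs/ps/ns, with
$k_B = 0.0019872041$ kcal/(mol K), so $k_BT = 0.596$ kcal/mol at 300 K.

Dynamics are propagated with the BAOAB splitting of Langevin dynamics
(damping 1 ps$^{-1}$, 1-5 fs steps).  BAOAB was chosen over
velocity-Verlet-with-thermostat variants because its configurational
sampling bias is smallest at these time steps; the equipartition test in
the suite (variance $k_BT/k$ in a harmonic well, 5% tolerance at 2 fs)
documents the residual discretisation error.  All stochastic force terms
draw from R's RNG, so a seed fixes a trajectory bit-for-bit; umbrella
windows derive their seeds as `base_seed + window_index`, making campaigns
reproducible and order-independent.

## Featurization and discretisation

Trajectories are reduced to feature series: the COM distance, its inverse
square (an indirect reaction coordinate), selected inter-chain bead-pair
distances, and the minimum RMSD to the bound pose (Kabsch superposition).
Pair distances are pre-filtered to *long-lived contacts*: a pair is kept
if within 12 Å continuously for at least 1 ns in some single run.  The
lifetime rule uses a strict `< cutoff` comparison (boundary frames count
as unbound) and a run of $m$ consecutive frames counts $m \times$ the
frame interval of lifetime, so shortening the minimum lifetime or raising
the cutoff can only add pairs.

TICA then extracts the slowest linear combinations: with mean-free data
$r(t)$, the covariances $C(0)$ and $C(\tau)$ are accumulated with the
$1/(N-\tau-1)$ normalisation, $C(\tau)$ is symmetrised (the estimator is
otherwise asymmetric under finite sampling; symmetrisation guarantees a
real spectrum), and the generalized eigenproblem
$C(\tau)U = C(0)U\Lambda$ is solved after adding a ridge of
$10^{-8}\,\mathrm{tr}(C(0))/d$ to the diagonal of $C(0)$.  Eigenvectors
are normalised to unit $C(0)$-metric and the leading components (default
4) are kept; implied IC timescales are $-\tau\,\Delta t/\ln|\lambda_i|$.
The TICA lag and the downstream MSM lag are independent configuration
values: the source methodology does not state that they must coincide,
so the package does not couple them.

Feature space is discretised by k-means (k-means++ initialisation, Lloyd
iterations through `stats::kmeans`, nearest-centre assignment with ties
to the lowest index, deterministic per seed).  The number of microstates
can be chosen by the elbow criterion: the $k$ maximising the
perpendicular distance of $(k, \mathrm{inertia}_k)$ to the chord joining
the first and last candidate points; an exactly linear curve has no elbow
and the smallest interior $k$ is returned with a warning.

## MSM estimation and observables

Sliding-window transition counts at a fixed lag are restricted to the
largest strongly connected component; the reversible maximum-likelihood
transition matrix (detailed balance $\pi_i T_{ij} = \pi_j T_{ji}$) is
obtained by the standard self-consistent fixed-point iteration, converged
to $10^{-12}$ on $\pi$.  Sliding-window counting overstates the number of
independent observations; the package handles that by bootstrapping whole
trajectories for error bars rather than by subsampling counts.

From a model, the package computes implied timescales
$t_i = -\tau/\ln\lambda_i$ (eigenvalues $\ge 1$ are reported infinite and
flagged), PCCA+ metastable memberships (inner-simplex vertex search on
the dominant eigenvectors; small negative memberships are clipped and
rows renormalised), and set-to-set mean first passage times from the
first-step linear system, averaged over the source set with the
stationary distribution restricted and renormalised (the committor-free
convention; the methodology's source is silent on the weighting).

Binding observables follow from the stationary vector with a bound set
defined either by a COM-distance cutoff on each microstate's average COM
or by a two-state PCCA split:

$$K_{eq} = \frac{P_b}{P_u}V,\qquad
  \Delta G_b = -k_BT\ln\frac{P_b}{P_u},\qquad
  k_{on} = \frac{1}{\mathrm{MFPT_{on}}\,C},\qquad
  k_{off} = \frac{1}{\mathrm{MFPT_{off}}},$$

with rates converted to $\mathrm{\AA^3 s^{-1}}$ and $\mathrm{s^{-1}}$.
For any two-state model $k_{on}/k_{off} = K_{eq}$ exactly; for metastable
chains the identity holds to a few percent *provided the partition cuts
at the barrier midpoint* - if a barrier-top state is lumped asymmetrically
into one set, passages ending there are ~50% recrossings and the
corresponding MFPT is roughly halved (the test suite documents this with
a six-state double well).  This is precisely why the bound-state cutoff
optimiser below matters.  The binding constant can also be obtained from a
radial PMF as $K_{eq} = \int_0^{r_{cut}} 4\pi r^2 e^{-\beta W(r)}dr$
(trapezoidal quadrature; the caller must offset $W \to 0$ in the bulk,
and a tail exceeding $0.1\,k_BT$ triggers a warning).

## Bound-state cutoff

The cutoff $r_{\mathrm{cut}}$ separating bound from unbound ($h(t) = 1$
iff COM distance $\le r_{\mathrm{cut}}$; the boundary counts as bound) is
chosen to maximise the relaxation time of the indicator autocorrelation.
Autocorrelations are computed per trajectory (mean-subtracted,
variance-normalised) and aggregated with length weights - never with
products across trajectory boundaries, which would manufacture spurious
correlation.  A biexponential $A_1e^{-t/\tau_1} + A_2e^{-t/\tau_2}$ is
fitted by variable projection (amplitudes solved linearly at each
candidate timescale pair, timescales optimised by Nelder-Mead in log
space, initialised from log-linear fits of the curve's head and tail) and
reported with $\tau_1 \le \tau_2$.  The scan maximises $\tau_2$, the slow
relaxation interpreted as the bound-state lifetime; the literature's
optimum criterion says only that "the relaxation times are longest", and
both timescales peak together in practice, so maximising $\tau_2$ is the
package's choice, with both reported and ties resolved to the smaller
cutoff.

## TRAM

TRAM stitches unbiased and umbrella-biased discrete trajectories into one
unbiased model.  The published description of the methodology does not
print the estimator's equations, so `gomsm` implements the standard
self-consistent scheme derived from the multi-ensemble reversible
likelihood: with per-ensemble counts $c^k_{ij}$, state counts $N^k_i$ and
reduced biases $b^k(x)$, the stationarity conditions are

$$\nu_i^{k} \leftarrow \sum_j \frac{(c^k_{ij}+c^k_{ji})\,\nu^k_i e^{-f^k_j}}
   {\nu^k_i e^{-f^k_j} + \nu^k_j e^{-f^k_i}},\qquad
  R_i^k = \sum_j \frac{(c^k_{ij}+c^k_{ji})\,\nu^k_j e^{-f^k_i}}
   {\nu^k_i e^{-f^k_j} + \nu^k_j e^{-f^k_i}} + N^k_i - \sum_j c^k_{ji},$$

$$f_i^k \leftarrow -\ln \sum_{x \in i}
   \frac{e^{-b^k(x)}}{\sum_l R_i^l\, e^{f_i^l - b^l(x)}},\qquad
  \mu(x) = \Big[\sum_l R^l_{s(x)} e^{f^l_{s(x)} - b^l(x)}\Big]^{-1},$$

iterated in log space until the largest change in any $f^k_i$ falls below
the tolerance (default $10^{-10}\,k_BT$, capped at $10^5$ iterations with
an error carrying the last increment).  Two numerical details matter:

* the $e^{-f^k_i}$ factor in $R$ makes the update *gauge-invariant* under
  a uniform shift of all $f$; that neutral mode is pinned to min-zero
  each iteration and the final $\pi_i \propto \sum_{x\in i}\mu(x)$ is
  normalised explicitly.  (Omitting the factor couples the gauge mode
  with gain 2 and the iteration diverges - the package's test against the
  analytic birth-death chain would catch this immediately.)
* samples with identical (state, bias-row) pairs are collapsed into
  weighted samples first.  For state-wise-constant biases - every
  discrete-chain oracle - this reduces the per-iteration cost from
  O(frames) to O(states) without changing any result.

Cross-ensemble connectivity is checked on the union of symmetrised count
graphs; disconnected replica groups raise an error naming the groups.
With a single zero-bias ensemble TRAM reduces to the reversible MSM
estimator (asserted to $10^{-6}$ in the suite).  The kinetic model
reported for observables is the transition matrix of the unbiased
thermodynamic state together with the TRAM stationary vector.

## Sensitivity analysis and focused umbrella windows

For an estimated MSM the local sensitivity of the stationary distribution
is $\partial\pi_i/\partial T_{jk}$ under the row-compensation convention
(a perturbation of off-diagonal $T_{jk}$ is absorbed by $T_{jj}$, keeping
the matrix stochastic), computed with the fundamental matrix
$Z = (I - T + \mathbf{1}\pi)^{-1}$ as
$\pi_j(Z_{ki} - Z_{ji})$ and validated against central finite
differences.  Transition-matrix uncertainty is modelled as independent
per-row Dirichlet posteriors with parameters counts$+\alpha$, giving
$\mathrm{cov}[T_{ij}, T_{il}] = \bar T_{ij}(\delta_{jl} - \bar T_{il}) /
(c_i + \alpha n + 1)$ and zero across rows; the source methodology does
not state its covariance estimator, and the Dirichlet posterior is the
standard conjugate choice for multinomial transition counts and is cheap
to validate by resampling (the suite checks first-order variance
propagation against $5\times10^4$ Dirichlet draws).  The global
(variance-based, Sobol) sensitivity of each $\pi_i$ is the quadratic form
of the local sensitivities with that covariance.

States ranked by aggregate sensitivity are accumulated until a coverage
fraction (default 0.9) of the total is reached; the COM-distance range
they span, intersected with the candidate umbrella grid, yields the
focused window selection used for efficient TRAM refinement.  Ranking
ties are broken towards smaller average COM.

## The synthetic world

Because the production-scale dataset (tens of microseconds of CG MD) is
out of desk-scale reach, validation runs on two kinds of synthetic
systems whose ground truth is known:

* **Toy two-chain complexes** (`make_toy_complex()`): compact random
  blobs (packing radius $2.5\,n^{1/3}$ Å, 3 Å minimum bead separation),
  chain A tethered, chain B free in a 20 Å cavity, 3 contacts of
  1.5 kcal/mol placed between the closest interface beads of a
  constructed bound pose with each $R_{\min}$ set to its bound-pose
  distance.  These defaults were chosen once so that (i) the bound-pose
  COM separation (~10 Å) is well inside the cavity, leaving a genuine
  unbound volume, and (ii) the total contact energy (~4.5 kcal/mol ≈
  7.5 $k_BT$) yields dozens of association/dissociation events per 2 ns
  run, so all estimators see both states in minutes of CPU.  What the toy
  does *not* emulate: excluded volume between non-contact beads (the Gō
  model has none, so the free chain can pass through the tethered one),
  rugged binding pathways, and any orientational registration beyond the
  few contacts.  A green toy test therefore establishes the estimator
  machinery, not the biophysics of any particular complex.
* **Birth-death reference chains** (`birth_death_reference()`):
  nearest-neighbour Metropolis chains over printed state energies with
  analytic Boltzmann stationary vectors and MFPT tables (first-step
  recursion, verified internally against a dense solve to $10^{-10}$).
  Biased copies with per-state energy offsets provide exact TRAM oracles.

## Workflow recipes

`run_workflow()` reproduces the four model recipes at toy scale: `msm_6d`
(four TICA ICs of long-lived pair distances + minimum RMSD + COM
distance, unbiased data only), `tram_6d` (same features, unbiased +
umbrella data), `tram_1d` (COM distance only) and `tram_1d_inv` (squared
inverse COM distance).  All recipes share one simulation dataset,
cluster with one seed, define the bound set by average microstate COM
below `bound_rcut`, and report $K_{eq}$, $\Delta G_b$, $k_{on}$,
$k_{off}$ with trajectory-bootstrap errors (umbrella windows held fixed
while unbiased trajectories are resampled, which is where the dominant
uncertainty lives).  The acceptance suite asserts that the four recipes'
$K_{eq}$ agree pairwise within twice their combined bootstrap errors,
that adding a few umbrella windows to a deliberately short unbiased
dataset recovers the long-run free-energy profile within 0.3 kcal/mol
where the short-data MSM alone does not, that aggregate
$\pi$-sensitivity anti-correlates with average COM distance (Spearman,
$p < 0.01$), and that the cutoff scan recovers a constructed two-basin
boundary within ±2 Å.

One of these checks is a *known red* on the default toy world: the
sensitivity/COM anti-correlation.  In a large cavity whose unbound
probability is dispersed over many microstates and whose binding events
are rare on the trajectory scale, bound and intermediate states carry
both large $\pi$ and large $\pi$-variance, so sensitivity decays with
COM distance.  The desk-scale toy inverts one of those ingredients:
its 20 Å cavity holds only a modest, fast-mixing unbound region, so
per-state $\pi$ *grows* with COM (a pure volume effect) and the
well-sampled kinetics make the Dirichlet variance track $\pi^2$ —
Spearman $\rho$ comes out positive for the full-data model.
Undersampled preliminary models recover the negative sign but not
robustly at $p < 0.01$.  Reproducing the pattern faithfully requires a
rare-event toy (much larger cavity, deeper contacts, roughly two orders
of magnitude more simulation), which is outside the minutes-scale test
budget; the check is left asserting the anti-correlation and failing,
rather than weakened, because the discrepancy is a property of the
synthetic world, not of the sensitivity machinery (which is validated
against finite differences and Dirichlet resampling elsewhere in the
suite).

Workflow defaults (8 × 2 ns unbiased runs, 14 windows × 1.2 ns, 25
microstates, 50 ps lag, TRAM tolerance $5\times10^{-7}$, 12 bootstrap
replicates) are sized so the full four-recipe comparison completes in a
few minutes on one CPU; they are configuration, not method: every value
can be raised towards production scale through `default_config()` keys.

## Numerical choices and limitations

* Transition counting is sliding-window; statistical dependence between
  windows is absorbed by the trajectory bootstrap.
* The reversible MLE and TRAM are fixed-point iterations with linear
  convergence; tolerances are on the iterate change, not the likelihood.
* The biexponential fitter flags degenerate fits
  ($\tau_2/\tau_1 < 1.05$ or a vanishing amplitude) rather than failing.
* PCCA+ uses the inner-simplex construction without the subsequent
  membership optimisation; for the well-separated metastable structures
  targeted here the difference is below test tolerances.
* The elastic network is harmonic: large deformations of a chain are
  penalised quadratically, so unfolding is outside the model.
* `pmf_binding_constant()` continues the profile flat from its first
  grid point to $r = 0$; profiles should start within one grid spacing
  of zero.
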