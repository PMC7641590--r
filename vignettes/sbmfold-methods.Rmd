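---
title: "Methods: a rho-parameterized structure-based model for multidomain folding and binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a rho-parameterized structure-based model for multidomain folding and binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sbmfold)
```

## The model

`sbmfold` implements a coarse-grained structure-based model (SBM): an
energy function constructed entirely from a molecule's native structure,
whose global minimum is the native state.  One Cα bead represents each
amino acid; three beads (sugar, base, phosphate) represent each nucleotide.
The apo-protein potential is

$$V = V_\mathrm{bonded} + \epsilon_\mathrm{intra} V_\mathrm{intra}
      + \epsilon_\mathrm{inter} V_\mathrm{inter}
      + \epsilon_\mathrm{linker} V_\mathrm{linker},$$

with $\rho = \epsilon_\mathrm{inter}/\epsilon_\mathrm{intra}$ the single
control parameter and $\epsilon_\mathrm{linker} \equiv
\epsilon_\mathrm{inter}$ throughout: linker contacts are grouped with the
interdomain class because the linker interacts with all domains and its
contacts play the same global-assembly role.  Native contacts use the
12–10 well $V(r) = \epsilon[5(\sigma/r)^{12} - 6(\sigma/r)^{10}]$ with
depth $-\epsilon$ at the native distance $\sigma$.  For binding, the system
potential adds (i) a second intra-protein basin: contacts present only in
the bound-form structure (in DPO4 these sit at the F–LF interface and are
treated as a consequence of DNA binding), (ii) protein–partner native
contacts, and (iii) Debye–Hückel electrostatics; the partner (DNA) is held
frozen.  Arg and Lys carry +1, Asp and Glu −1, and each phosphate bead −1.

Reduced units are used everywhere: energies in units of
$\epsilon_\mathrm{intra}$, temperature with $k_B = 1$, time in $\tau$,
lengths in nm.

### Functional forms and constants

The source structure fixes every equilibrium value (bond lengths, angles,
dihedrals, contact distances); only the stiffnesses are model constants.
We use the common Cα-SBM choices, declared defaults rather than quantities
inherited from any particular study:

| term | form | default |
|---|---|---|
| bond | $K_b (r - r_0)^2$ | $K_b = 100\ \epsilon/\mathrm{nm}^2$ |
| angle | $K_a (\theta - \theta_0)^2$ | $K_a = 20\ \epsilon/\mathrm{rad}^2$ |
| dihedral | $K_d[(1-\cos\Delta\phi) + \tfrac12(1-\cos 3\Delta\phi)]$ | $K_d = 1\ \epsilon$ |
| excluded volume | $(\sigma_{ev}/r)^{12}$, non-contact pairs | $\sigma_{ev} = 0.4$ nm |
| electrostatics | $A q_i q_j e^{-r/\lambda_D}/r$ | $\lambda_D = 0.8$ nm |

The only electrostatic *contract* is the calibration: $A$ is chosen so two
unit opposite charges at 0.5 nm interact with energy exactly $-1$, i.e. the
strength of one native contact (`calibrate_dh()`).  The default Debye
length 0.8 nm corresponds to roughly 150 mM monovalent salt and is
configurable.  Electrostatics act between all charged pairs, including
native-contact pairs.

### Temperature rescaling and mapping

The folding temperature $T_f$ changes with $\rho$.  Kinetic comparisons
across $\rho$ are made at one physical temperature by multiplying the
apo-protein SBM terms by $T_f^{\rho_0}/T_f^{\rho}$
(`rescale_for_temperature()`); the rationale is that solvent effects in
SBMs are linear in temperature.  We apply the factor to the bonded,
intra, inter, linker and excluded-volume terms — the apo Hamiltonian — and
not to the binding, second-basin or electrostatic additions, which are
defined on top of it.  Experimental temperatures map onto the reduced
scale through $T(\mathrm{sim}) = T(\mathrm{exp}) \cdot
T_f(\mathrm{sim})/T_f(\mathrm{exp})$ (`map_temperature()`); with DPO4's
experimental melting point 369 K and simulated folding temperature 1.13,
the growth temperature 353 K maps to 1.08 and room temperature 300 K to
0.92, reported to two decimals alongside full precision.

## Sampling

The integrator is a BAOAB Langevin leapfrog (mass 1, friction $1/\tau$ by
default, default $dt = 5\times10^{-4}\,\tau$).  On the compact toy systems
used in the tests we run $dt = 0.0015$–$0.002\,\tau$, inside the stability
limit set by the contact-well curvature; the double-well runs use
$dt = 0.005\,\tau$.  All randomness flows through R's RNG, so a protocol
seed fixes the trajectory bit-for-bit.

*Replica exchange* attempts Metropolis swaps
$\min(1, e^{\Delta\beta\,\Delta E})$ between ladder neighbours (alternating
even/odd pairs) at a fixed interval, redrawing velocities from the
Maxwell–Boltzmann distribution afterwards; records are per-temperature
(ensemble view), which is what WHAM consumes.

*Umbrella sampling* biases the binding coordinate dRMS — the
root-mean-square deviation of protein–partner native-contact distances
from their native values, $\mathrm{dRMS} =
\sqrt{\tfrac1N \sum_{ij} (r_{ij} - \sigma_{ij})^2}$, which is zero at the
native pose and, unlike the fraction of formed interchain contacts,
distinguishes unbound configurations from one another.

*Metadynamics* deposits well-tempered Gaussian hills on the CV and
accumulates the acceleration factor; the per-run rescaled transition time
is $\sum dt\, e^{V_\mathrm{bias}(s_t)/k_BT}$ up to first arrival in the
target window.  The frequency-adaptive schedule is simplified to: the
deposition interval doubles each time the running acceleration factor
crosses a power of ten.  An optional static harmonic upper wall confines
the CV to the transition region (bound/intermediate states) so hills fill
the local basin instead of pushing the system out toward dissociation; the
wall is excluded from the acceleration factor.  Runs that never arrive are
flagged censored and excluded (but counted) in rate estimates.

## Thermodynamic analyses

*WHAM.*  Temperature WHAM iterates the standard self-consistent equations
on an energy histogram to estimate the density of states; the heat
capacity follows from energy moments, and the folding temperature is
reported as the $C_v$-peak temperature.  Free-energy surfaces at any
temperature use per-sample ensemble weights
$w_i \propto e^{-\beta E_i} / \sum_k N_k e^{f_k - \beta_k E_i}$, which
pools the whole ladder.  Umbrella WHAM solves the analogous equations on
the CV grid and reports per-window reconstruction residuals.  Histograms
that fail to overlap raise errors naming the gap.

*Reweighting across $\rho$.*  Because the density of states is independent
of $\rho$ and $E(\rho) - E(\rho_0) = (\rho/\rho_0 - 1)(E_\mathrm{inter} +
E_\mathrm{linker})$ exactly (every frame stores its energy decomposition),
equilibrium properties at any $\rho$ follow from the $\rho_0$ ensemble with
weights $e^{-\Delta E/k_BT}$ — no new simulation.  For samples already
equilibrated at the target temperature only the difference factor is
applied; for WHAM-pooled multi-temperature samples the full ensemble weight
at the target temperature is used.  The effective sample size is reported
and a warning raised when it falls below 10 % of the input.  The package's
acceptance suite cross-validates this machinery by comparing the
reweighted $F(Q)$ landscape at $\rho = 0.8$ against direct replica
exchange run at $\rho = 0.8$, bin by bin.

*Melting curves and cooperativity.*  Per element (domain or interface
contact subset), the folded probability $P_I(T) = P(Q_I \ge 0.75)$ across
the ladder is fitted with the two-parameter sigmoid
$P = 1/(1 + e^{(T - T_m)/w})$; flat curves are flagged degenerate and
excluded.  The thermodynamic coupling index of two elements is
$\mathrm{TCI} = -\ln\langle |P_I(T) - P_J(T)| \rangle$ with the average
over a uniform grid spanning the ladder, and the mean TCI pools the mean
absolute differences over all pairs before taking $-\ln$.  Identical
curves would diverge, so TCI is capped at $-\ln(1/(10\,G))$ for a grid of
$G$ points — finite, comparable, and clearly above any measurable
coupling.

*State stabilities and binding affinity.*  State free energies integrate
the Boltzmann weight over windows on the (Q total, Q inter) plane:
$\Delta F^S = -\ln(Z_S/Z_U)$, and $\Delta\Delta F^S(\rho) =
\Delta F^S(\rho) - \Delta F^S(\rho_0)$, which vanishes at $\rho_0$ by
construction.  The binding PMF over dRMS yields
$K_d = c_\mathrm{box}\, Z_\mathrm{unbound}/Z_\mathrm{bound}$ with
$c_\mathrm{box} = 1/(N_A V)$ the one-molecule box concentration — the
standard-state correction enters through the sampling volume.  The
four-state classifier uses dRMS windows: bound below 0.5 nm, intermediate
0.5–2.5 nm, encounter complex 2.5–10 nm, unbound beyond 10 nm.  The 10 nm
(unbound) and 2.5 nm (encounter) boundaries follow the study system's
definitions; the 0.5 nm bound/intermediate split is a package default,
chosen so the bound window brackets the native basin (dRMS ≈ 0.1 nm), and
is configurable.

## Kinetic analyses

Folding events are scored by the first passage of the total fraction of
native contacts Q to 0.75.  For the folding order, a protein with $n$
elements (for DPO4: four domains and four interfaces, hence eight folding
steps; the interface set defaults to F–P, P–T, T–LF and the linker group,
since the full enumeration is not fixed by the study text) defines $n$
steps; element $I$ folds at step $k$ if it is the $k$-th to cross the
threshold without later dropping below 0.67 of it before global folding —
the commitment fraction suppresses transient flickers.  The resulting
matrix $OP_k^I$ is column-stochastic with element-mean $1/n$ at every
step, so a fully deterministic order gives the one-hot dispersion
$\sigma_{OP} = \sqrt{(n-1)/n^2}$ ($\sqrt{7/64}$ for $n = 8$) and a fully
random order drives it to zero.

Backtracking — formation, breaking and re-formation of a contact subset en
route to the folded state — is detected by binning Q(inter) along the
monotonised Q(total) progress (running maximum, default bin 0.02) and
flagging local maxima followed by a drop of at least 0.05 with later
recovery; the count is non-increasing in the drop threshold by
construction.

Encounter-stage kinetics label each run started in the encounter complex
as evolved (reaches the intermediate state) or dissociated (escapes to the
unbound state); with rates taken as counts over observation time, the
encounter time is $k_\mathrm{Dis}/k_\mathrm{Evo} + 1$ — the mean number of
encounter attempts per successful evolution, which reduces to the
geometric-distribution mean $1/p$ for Bernoulli attempts.  Metadynamics
transition-time estimates average per-run rescaled times with a 50-sample
bootstrap error.

## Synthetic study systems

The generators produce every input the pipeline needs without downloads,
and their defaults are fixed once:

* **Toy multidomain protein** (`make_toy_multidomain()`): domains are
  serpentine walks through a 2×2×n grid at 0.55 nm spacing — genuinely
  three-dimensional compact cores, docked face-to-face at 0.62 nm with an
  arched flexible linker.  Intradomain contacts are all pairs within
  0.85 nm at sequence separation ≥ 3; interdomain contacts are the closest
  cross-domain pairs taken in distance order until the requested
  intra:inter ratio (default 5:1, echoing the strong intradomain bias of
  multidomain folds) is met, with an error if the geometry cannot realise
  the ratio within 20 %; two linker–domain contacts populate the linker
  class.  Geometry is deterministic — templates, not random walks — so the
  native structure is the energy minimum by construction; the seed only
  adds a 0.005 nm symmetry-breaking jitter.  The default size (two
  12-bead domains, 4-bead linker) melts between reduced temperatures 0.5
  and 0.9 with a broad heat-capacity peak: small toys trade transition
  sharpness for speed, so the reported $C_v$-peak temperature is a coarse
  locator rather than a sharp $T_f$.
* **Binding toy** (`make_toy_binding_system()`): the same protein plus a
  frozen rod of phosphate-like beads (charge −1); the closest
  protein–partner pairs become binding contacts, four protein beads facing
  the rod become Arg-like (+1), and a dual-basin option adds bound-form-only
  cross-domain contacts.  It reaches all four binding regimes at desk
  scale.
* **Harmonic chain** (`make_harmonic_chain()`): bonded-only, with
  closed forms ⟨PE⟩ = kT/2 per bond mode and bond-length variance
  kT/(2K).  The default 1.0 nm bond keeps the radial-measure correction to
  these forms well below the statistical resolution of the tests.
* **Double well** (`make_double_well()`): $V(x) = b(x^2-1)^2 + tx$, the
  analytic oracle for umbrella WHAM (exact PMF), replica-exchange
  occupancies (quadrature), and metadynamics rates (brute-force unbiased
  mean first passage).

What passing tests on these systems do **not** show: toy domains have no
sequence heterogeneity, no non-native interactions, no realistic DNA
geometry, and transition barriers far smaller than a 341-residue
polymerase's; results on them validate the machinery (estimators,
integrators, bookkeeping, closed-form limits), not biological conclusions
about any particular protein, which require the full-scale structures and
cluster-scale sampling.

## Numerical choices and problem sizes

WHAM iterations run to $10^{-8}$ (temperature) / $10^{-10}$ (umbrella)
free-energy tolerance in log space with log-sum-exp throughout; surfaces
are zeroed at their minimum (the lowest-CV convention is available).  The
contact-formation tolerance is $r < 1.2\,\sigma$.  Degenerate geometry
(collinear angle/dihedral frames) is guarded in the force kernels; an
energy-magnitude guard aborts diverging trajectories with a diagnostic.
The test and acceptance runs size their simulations for a single CPU: the
reweighting cross-check uses two 10-replica ladders of $1.2\times10^6$
steps; umbrella oracles use 15 windows of $1.5\times10^5$ 1D steps;
metadynamics rate checks use 20 runs against a 60-run unbiased reference;
the binding campaign uses 12 windows, 40 encounter runs and 8 metadynamics
runs.  These sizes were chosen so each estimator's sampling error sits
comfortably inside the tolerance it is checked against.

## Known limitations

Contact maps use an all-heavy-atom 0.45 nm cutoff (shadow-map style
algorithms are not implemented); nucleic bead charges sit only on
phosphates; the frozen-partner approximation removes partner flexibility
entirely; the frequency-adaptive metadynamics schedule is a simplified
power-of-ten rule; and WHAM is histogram-based (no MBAR generalisation
beyond the per-sample weights it needs).  The workbench drivers
(`cmd_build()`, `cmd_fold()`, `cmd_bind()`) expose the campaigns as
functions; there is no shell entry point, as the package is a library
rather than a command-line tool.
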