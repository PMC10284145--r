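---
title: "Computing absolute binding enthalpies with bindcalor: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing absolute binding enthalpies with bindcalor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindcalor)
```

## The model

The binding enthalpy of a ligand–protein complex is estimated by the direct
method as a difference of time-averaged potential energies over four
independent simulations,

$$\Delta H \;=\; \langle E\rangle_\mathrm{complex}
 + \langle E\rangle_\mathrm{solvent}
 - \langle E\rangle_\mathrm{receptor}
 - \langle E\rangle_\mathrm{ligand},$$

where the complex and pure-solvent boxes together form the bound state and
the apo-receptor and free-ligand boxes the unbound state. The estimator is
only meaningful under two bookkeeping assumptions, both enforced by the
package:

* **Atom balance.** Every chemical species must appear the same number of
  times on the bound and unbound sides; otherwise the difference of means
  contains the bulk energy of the excess atoms, which dwarfs the binding
  signal. `check_atom_balance()` verifies
  $n_\mathrm{complex} + n_\mathrm{solvent} = n_\mathrm{receptor} +
  n_\mathrm{ligand}$ per species, and the CLI refuses to combine
  unbalanced legs unless `--allow-imbalance` is given.
* **PV neglect.** The pressure–volume contribution at ambient pressure is
  orders of magnitude below the statistical error and is omitted with no
  option to include it.

The error of $\Delta H$ is the quadrature of the four leg SEMs. This
assumes independent legs, which holds by construction: each leg is a
separate simulation (set).

## Uncertainty by re-blocking

Potential-energy series from MD are strongly autocorrelated, so the naive
$s/\sqrt{n}$ underestimates the SEM. `blocking_curve()` implements the
standard blocking transform: level 0 is the raw series, and each subsequent
level averages consecutive non-overlapping pairs of blocks (an odd trailing
block is dropped, keeping block counts at exactly
$\lfloor N/2^b\rfloor$). The block SEM rises with block size until blocks
decorrelate; in the ideal case it plateaus, but plateau detection is hard
to automate, so `select_sem()` adopts the conservative convention of
reporting the **maximum SEM across levels**.

Numerical choices:

* `min_blocks` (default **8**, configurable down to 2): levels with fewer
  blocks are discarded before taking the maximum. A variance estimated
  from two or four blocks is itself so noisy that it would frequently and
  spuriously dominate the maximum; the floor keeps the conservative rule
  from becoming a noise amplifier. On i.i.d. data with this floor the
  selected SEM stays within a factor ~2 of the level-0 SEM (tested).
* Ties in the maximum go to the **lowest level** — the estimate backed by
  the most blocks.
* Replica pooling (`estimate_leg()`): the production design is ~20
  independent replicas per leg. Whether to block each replica separately
  and pool, or to block the concatenation, is genuinely open (both appear
  in practice), so both are implemented and the choice is recorded in the
  estimate's provenance string. The default is `per_replica` with
  $\mathrm{SEM} = \max\!\big(\tfrac{1}{R}\sqrt{\sum_i \mathrm{sem}_i^2},\;
  \mathrm{sd}(\bar E_i)/\sqrt{R}\big)$: when independent repeats disagree
  — exactly what happens when replicas are trapped in different loop
  states — the between-replica scatter is the honest error and must not be
  averaged away. Concatenation would also let blocks span replica
  boundaries, which fabricates decorrelation.
* No equilibration discard is applied by default (the upstream protocol
  equilibrates before production); `discard_frames` exists for raw traces.

## Loop states and their assignment

In BRD4-1 the ZA loop (residues 76–106 in author numbering, which the PDB
reader preserves without renumbering) occupies a crystal-like state ZA1 and
an outward alternative ZA2. Two backbone torsions act as the hinge: the ψ
of Asp88 (N-CA-C-N) moves between modal values of about 50° (ZA1) and −40°
(ZA2), and the φ of Asp96 (C-N-CA-C) between about −150° and −60°.

No numeric classification thresholds are published for these states, so
the package's defaults are the **midpoints of the modal values**:
ψ_cut = 5°, φ_cut = −105°. A frame is ZA1 iff ψ > ψ_cut *and* φ < φ_cut,
ZA2 iff ψ ≤ ψ_cut *and* φ ≥ −105°, and UNASSIGNED when the two hinges
disagree — disagreement is informative (mid-transition frames) and must
not be silently forced into either state. All cuts are configurable. An
independent RMSD classifier (`assign_states_rmsd()`, ZA2 iff loop backbone
RMSD to the crystal-like reference > 2.5 Å after a whole-backbone fit) is
provided as a cross-check, and `state_agreement()` reports how often the
two classifiers coincide.

Classification is strictly per frame on wrapped angles in (−180°, 180°];
circular means are never taken. Transition bookkeeping
(`transition_stats()`) applies a **minimum dwell** of 5 frames by default:
runs shorter than `min_dwell` inherit the previous persistent state. Real
transitions here are long-lived (tens of ns), while emission noise
flickers on the frame scale, so a small dwell floor removes flicker
without biasing occupancies. Times are reported in ns from the frame
spacing; a transition is timed at its first frame in the new state.

## Conditioning on loop state

`conditional_enthalpy()` restricts the **complex leg only** to frames of
the requested state. The receptor leg in principle should be conditioned
too, but the apo-state energy difference between the two loop conformations
is small compared with its own error, so the default leaves the receptor
leg unconditioned; `condition_receptor = TRUE` enables it for sensitivity
analysis. Two further rules:

* **Segment-wise blocking.** Conditioning produces non-contiguous runs of
  frames. Blocking is applied within each maximal single-state segment and
  the segment estimates are pooled weighted by length
  ($\hat\mu = \sum_i w_i \bar x_i$,
  $\mathrm{sem} = \sqrt{\sum_i (w_i\,\mathrm{sem}_i)^2}$,
  $w_i = n_i/N$). Concatenating segments before blocking would treat the
  splice points as decorrelated data. Segments shorter than `min_blocks`
  fall back to the naive $s/\sqrt{n}$ (zero for a single frame); they
  carry correspondingly small weight.
* **"Combined" is a frame pool.** When runs are started from both states
  (as done for complexes where both states contribute), the combined
  estimate pools all replicas and recomputes — it is *not* the average of
  the two conditional estimates. Pooling and the all-frames estimate on
  the union coincide exactly (tested as an identity). An
  occupancy-weighted average of the conditional estimates can be formed
  from the returned per-state objects as a diagnostic.

`infer_entropy_and_check()` closes the thermodynamic triangle: TΔS is
inferred as ΔH − ΔG and compared with any stored TΔS at a tolerance of
0.02 kcal/mol, which absorbs two-decimal rounding of the published tables.
One row of the shipped ITC benchmark table violates the identity as
printed (a sign ambiguity in its TΔS cell); the package flags that row and
deliberately does not correct it.

## The synthetic generator: what it emulates, what it does not

The estimators above are validated against a generator with known ground
truth:

* **Energies** are stationary AR(1),
  $E_t = \mu + \rho(E_{t-1}-\mu) + \varepsilon_t$, initialized from the
  stationary distribution. AR(1) is the minimal model with the feature
  that matters — autocorrelation — and it has a closed-form SEM of the
  mean, $\sigma\sqrt{(1+\rho)/((1-\rho)n)}$, which serves as an analytic
  oracle for the blocking code. Defaults (σ = 2 kcal/mol, ρ up to 0.95,
  20 replicas × 5000 frames) are chosen for estimator stress-testing; real
  traces have σ of hundreds of kcal/mol about means of thousands, but the
  estimators are exactly shift- and scale-equivariant (tested), so small-σ
  tests carry over.
* **Loop switching** is a hidden two-state Markov chain with per-frame
  switching probabilities, giving geometric dwell times (mean $1/k_{12}$,
  $1/k_{21}$ frames) and stationary ZA2 occupancy $k_{12}/(k_{12}+k_{21})$.
  While in ZA2 the energy gains a constant offset `delta_E`.
* **Dihedral emissions** are wrapped-normal around the per-state modal
  centers with circular sd $1/\sqrt{\kappa}$ rad — a von-Mises-like
  unimodal wrapped distribution honoring a concentration parameter
  (base R has no von Mises sampler, and for the κ values used the two are
  indistinguishable).
* **Seeding**: replica $r$ uses `seed + r`, so replicas are mutually
  independent yet individually reproducible.

The generator does **not** emulate: slow non-stationary drift
(equilibration transients), multi-exponential autocorrelation, more than
two conformational states, correlated errors between legs, force-field
systematics, or real 3-D geometry (geometry functions are tested on
constructed rigid-body fixtures instead). A green recovery test therefore
establishes that the estimators are unbiased and honestly calibrated *for
series with the assumed statistical structure* — not that a particular MD
protocol is converged.

## Benchmark metrics

* **R²** is the squared Pearson correlation, the conventional reading when
  accuracy is reported separately as RMSE; the coefficient of
  determination about the identity line is available as
  `r_squared(..., method = "identity")` for sensitivity (it can be
  negative).
* **Kendall τ** is the τ-b tie correction, computed by direct
  $O(n^2)$ pair enumeration — exact, and ample at benchmark sizes of ~10
  complexes.
* **Outliers** are predictions with absolute deviation strictly greater
  than 2.0 kcal/mol; the limit is drawn as a boundary, so a deviation of
  exactly 2.0 is not flagged.
* Unpaired systems are dropped pairwise with a warning, never imputed.

## Other numerical choices

* Energies are stored internally in kcal/mol; kJ/mol inputs are divided by
  exactly 4.184 (thermochemical calorie). XVG files default to kJ/mol
  (the writing engine's unit), CSV tables to kcal/mol; both overridable.
* Unicode minus (U+2212), as printed in journal tables, is accepted as a
  sign character everywhere numbers are parsed.
* The XVG frame spacing is inferred from the time stamps and checked for
  uniformity at 1e-6 relative tolerance rather than configured, so an
  accidentally subsampled trace fails loudly instead of silently skewing
  time-based quantities.
* Kabsch superposition enforces a proper rotation (det = +1) via the SVD
  sign correction; fewer than three non-collinear fit atoms is an error.
* RMSF uses one mean-structure iteration (fit all frames to the first
  frame, form the mean, refit to the mean) rather than iterating to
  convergence; the residual dependence on the initial frame is far below
  the fluctuation scale of interest and the choice is recorded here.
* Dihedrals follow the IUPAC sign convention (cis = 0°, trans = 180°),
  validated against an independent plane-normal oracle to 1e-9°.

## Known limitations

* Per-term energy decomposition (e.g. a coulombic breakdown of a state
  difference) is out of scope: per-term series are engine-specific.
* No automatic plateau detection on blocking curves; the max-SEM rule is
  conservative by design and can overestimate on short series.
* The PDB reader is minimal (fixed-column ATOM/HETATM, MODEL/ENDMDL); it
  is not a general mmCIF/PDB parser and expects a constant atom roster.
* Published per-complex calculated-enthalpy supplementary tables are not
  shipped, so the package's acceptance layer reproduces the worked
  per-complex deviation examples and all property-based recovery
  guarantees, but not the full printed benchmark RMSE/R² pairs.
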