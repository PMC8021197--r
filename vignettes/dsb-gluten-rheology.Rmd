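---
title: "Coarse-grained rheology of gluten-like protein networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained rheology of gluten-like protein networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsbmd)
```

## The model

`dsbmd` simulates dense systems of intrinsically disordered storage
proteins — wheat gluten being the motivating case — at one bead per
residue in implicit solvent.  Positions evolve by the Langevin equation

$$ m\,\ddot{\mathbf r}_i = \mathbf F_i - \gamma\,\dot{\mathbf r}_i +
   \boldsymbol\Gamma_i, $$

with damping $\gamma = 2m/\tau$ (well inside the overdamped regime) and
thermal white noise of variance $2\gamma k_BT$.  The intrinsic units are
the energy $\epsilon \approx 1.5$ kcal/mol, the nanometre, and the time
$\tau \approx 1$ ns; simulations run at $T = 0.3\,\epsilon/k_B$, roughly
room temperature.

The potential has five ingredients:

* **Bonds.** Consecutive beads interact through $V = k (r - r_b)^2$ with
  $k = 5000\ \epsilon/\mathrm{nm}^2$ and $r_b = 0.38$ nm.  The quadratic is
  used without a factor 1/2; the constant is configurable for anyone who
  prefers the other convention.
* **Local stiffness.** Bond-angle and dihedral terms distinguish glycine,
  proline and generic residues.  The shipped forms are smooth analytic
  surrogates for a statistical-coil ensemble (harmonic angles, one- and
  three-fold cosine dihedrals); they are *not* calibrated against a coil
  library and are expected to be replaced by users who have such tables.
* **Excluded volume.** A truncated-and-shifted repulsive Lennard-Jones
  term, zero at and beyond $r_o = 0.5$ nm, with
  $\sigma_0 = r_o\,0.5^{1/6}$, so $V(\sigma_0) = +1\ \epsilon$.  Pairs
  $(i, i+2)$ always interact through this term only, which effectively
  constrains the backbone angle from below.
* **Electrostatics.** A Debye–Hückel term with distance-proportional
  relative permittivity $\epsilon_r(r) = 40\,\mathrm{nm}^{-1}\,r$.  The
  statement "$\kappa = 40\ \mathrm{nm}^{-1}\,r$" admits two readings
  (screening constant or permittivity); we implement the permittivity
  reading and expose a separate Debye length (default 1 nm, cutoff 2 nm),
  so either behaviour can be dialled in.  Charges: +1 for Lys/Arg, −1 for
  Asp/Glu, His neutral.
* **Dynamic contacts.** The distinguishing feature of the model.  When two
  beads approach, local frames built from three consecutive beads supply a
  binormal $\hat h_i$ (the direction a backbone hydrogen bond could take)
  and a sidechain direction $-\hat n_i$ (opposite the curvature normal).
  Mutual binormal alignment with the connecting line makes a
  backbone–backbone (bb) contact, mutual sidechain alignment a
  sidechain–sidechain (ss) contact, and mixed alignment bs/sb.  Alignment
  uses $|\cos|\ge 0.5$ for binormals (a pseudo-vector; hydrogen bonds can
  form on either side) and the signed cosine for sidechains; the
  threshold is configurable because the calibrated values of the parent
  parameterisation are not public.  A contact forms when $r$ is below the
  Lennard-Jones minimum of its kind — 0.5 nm for bb, 0.68 nm for bs, a
  per-residue-pair table for ss — and its attraction
  $V = 4D((\sigma/r)^{12} - (\sigma/r)^6)$ switches on linearly over
  $10\,\tau$ ("adiabatically"), with bb contacts twice as deep
  ($D = 2\epsilon$).  Once a pair separates beyond $f\sigma_{attr}$ the
  contact fades out over the same $10\,\tau$ and disappears; we default to
  $f = 1.5$, with $f = 1.3$ available.  Per-residue slot budgets (2
  backbone slots; sidechain slots graded by residue size) limit how many
  contacts a bead can hold.  The per-pair ss distances and the slot
  budgets ship as an editable TSV (`inst/extdata/residue_params.tsv`);
  they are surrogate values graded by residue size, not the parent
  model's calibrated tables.
* **Disulfides.** A cysteine pair within 0.59 nm forms a reversible
  disulfide record with depth $4\epsilon$ and minimum 0.59 nm, switched
  like any other contact, except that a bonded cysteine cannot take a
  second partner until the bridge ruptures.
* **Static contacts.** Structured domains (declared per chain with a
  residue-pair/native-distance map) get permanently attractive Go-type
  contacts whose Lennard-Jones minimum is the native distance.  They never
  switch off, and they do not consume dynamic slots; for the coordination
  number they count as "made" while $r < f\sigma$.

While a dynamic contact is partially switched (weight $\lambda$), the pair
potential is the blend $(1-\lambda)V_{rep} + \lambda V_{attr}$, which is
continuous in time and reduces to pure excluded volume at $\lambda = 0$.

## Walls and the deformation protocol

The box is periodic in X and Y and bounded by flat walls at $Z = 0$
(fixed) and $Z = s$ (moving).  Every bead always feels the repulsive
(WCA) part of a Lennard-Jones wall potential of depth $4\epsilon$ with
minimum at $d_{min} = 0.5$ nm, so no residue can cross a wall.  When wall
attraction is enabled, a bead entering $d < 0.5$ nm acquires an
interaction centre anchored at its current X/Y position on the wall; the
attractive tail (the WCA complement, so the total is the full
$4\epsilon$ Lennard-Jones) then acts towards that centre and ramps up
over $10\,\tau$.  Anchors ride rigidly with their wall — vertically when
$s$ changes, horizontally under shear.  A bead farther than 2 nm from its
centre detaches and may re-attach elsewhere later.

The staged protocol mirrors how a protein melt would be prepared and
probed in a plate–plate rheometer:

1. self-avoiding-walk start at 0.1 residues/nm³ and 125 µs of dilute
   equilibration;
2. compression at 2 mm/s — all box dimensions shrink together, bead X/Y
   coordinates rescale affinely, the walls push in Z — to the gluten melt
   density $\rho_0 = 3.5$ residues/nm³, fixing the rest separation $s_0$;
3. 150 µs of equilibration, then wall attraction switches on for another
   150 µs;
4. either five oscillation cycles — the moving wall is first displaced to
   $s_0 - A$ (or shear offset $-A$) at the pulling speed, then driven as
   $s(t) = s_0 - A\cos\omega t$ (normal) or $s'(t) = -A\cos\omega t$
   (shear), with $A = 1$ nm and period 40 or 70 µs — or 100 µs of extra
   equilibration for the no-oscillation control;
5. 75 µs of equilibration during which the post-deformation observables
   (coordination number, inter-chain contacts, RMSF, shape, entanglements,
   cavities) are sampled;
6. uniaxial extension at 0.5 mm/s to $2 s_0$, recording the response
   force and the accumulated work.

All stage durations carry one global `scale` factor and the boundary
speeds are divided by it, so a desk-scale run (`scale = 1e-3`) traverses
the identical code path ~1000× faster.  The per-stage RNG streams derive
deterministically from one master seed, and stages before the oscillation
have mode-independent stream ids, so oscillated and control runs share
their trajectory bit-for-bit up to that point — the pairing the
oscillation-effect ratios rely on.

## Observables

The wall force is recorded per wall and component and block-averaged over
100 ns windows (scaled with the schedule) to suppress thermal noise.  For
the dynamic modulus we fit the drive and the force on the moving wall on
the in-phase/quadrature basis at the known drive frequency (a linear
least-squares fit, discarding the first period as transient — the length
of the discard window is our choice), form the complex ratio, and report

$$ G' = \frac{\phi_0}{\gamma_0}\cos\delta, \qquad
   G'' = \frac{\phi_0}{\gamma_0}\sin\delta, $$

with $\gamma_0 = A/s_0$, $\phi_0 = F_0/S$, $S = L_xL_y$ (held at the
undeformed wall area; the correction under shear tilt is second order in
the strain) and $\delta$ folded into $[0,\pi)$.  With forces in nN and
areas in nm² the stress unit is conveniently 1 nN/nm² = 1 GPa.

$F_{max}$ is the mean of the five largest block-averaged force samples
(one sample per averaging window, so a single spike cannot be counted
five times), with their standard deviation as the uncertainty; runs with
different seeds combine by inverse-variance weighting.  $W_{max}$ is the
maximum of the trapezoid integral $\int F\,ds$.

Chain shape uses the principal radii of inertia $R_1\le R_2\le R_3$
(square roots of inertia-tensor eigenvalues per unit mass) and the
distortion $w = (R_2 - \bar R)/\bar R$ with $\bar R = (R_1+R_3)/2$: 0 for
a sphere, 1 for a rod.  RMSF is the per-residue RMS deviation from the
time-mean position over the post-deformation window, after unwrapping
through the periodic boundaries and removing per-frame centre-of-mass
drift.

**Entanglements.** Each chain's path is contracted towards the straight
line between its fixed ends, with moves rejected if they would bring a
segment closer than a tube diameter (0.2 nm) to another chain's path;
per-sweep moves are capped well below the tube diameter so paths cannot
tunnel.  Self-collisions are deliberately ignored, which excludes
self-entanglements (knots) by construction.  After contraction, an
interior vertex with turning angle above 10° lying within 0.5 nm (twice
the bead radius) of another chain's path is a kink; consecutive kink
vertices count once, and $l_k$ is the total number of kink runs.  The
angle tolerance is exposed because published kink counters do not state
one.

**Cavities.** The box is covered with a 0.1 nm grid; a cell is *occupied*
if a probe of radius 0.38 nm centred there would overlap a bead (bead
hard-core radius 0.25 nm, half the excluded-volume cutoff), *exterior* if
probe-accessible and flood-connected to the periodic faces or the walls,
and *cavity* otherwise.  The three classes tile the box exactly; cavities
are the connected interior components.  Only the single grid orientation
is implemented (multi-rotation averaging is out of scope).

## Numerical choices

* **Integrator.** A Gear 5th-order predictor–corrector advances the
  conservative dynamics; friction and noise are applied afterwards as an
  exact Ornstein–Uhlenbeck velocity update
  $v \leftarrow e^{-\gamma\Delta t/m} v + \sqrt{(k_BT/m)(1-e^{-2\gamma\Delta t/m})}\,\xi$.
  We first tried feeding the stochastic force through the Gear corrector
  itself; the white noise contaminates the high-order derivative feedback
  and leaves a kinetic-temperature bias that does not vanish cleanly with
  the step size, whereas the splitting is exact for free particles
  (machine-precision velocity decay at $T = 0$, unbiased $\langle
  v^2\rangle$) and symplectic-grade for the stiff bond (energy drift
  $< 10^{-4}\,\epsilon$ over $10^4$ steps on a dimer).
* **Time step.** $\Delta t = 0.002\,\tau$.  With $k = 5000$ and $m = 1$
  the bond frequency gives $\omega\Delta t \approx 0.28$, inside the Gear
  stability region; $0.005\,\tau$ is demonstrably unstable for this bond
  stiffness, and the engine aborts with an explicit error if any
  corrector displacement exceeds half the excluded-volume cutoff.
* **Corrector coefficient.** $\alpha_0 = 3/16$, which on the stiff-bond
  dimer conserved energy several-fold better than the textbook
  position-only alternative 3/20.
* **Neighbour search.** A Verlet list with 0.3 nm skin, rebuilt when any
  bead has moved half a skin; results are contractually identical to the
  brute-force double loop (and tested against it through the registry
  ground-truth check).
* **Overlap safety.** The repulsive kernels continue linearly below
  0.1 nm (0.05 nm for walls) so forces stay finite during violent
  transients.
* **Degenerate geometry.** Collinear bead triples have no frame and form
  no directional contacts that step; chain ends never form dynamic
  contacts (disulfides, which need no frame, are exempt).
* **Compression partition.** The protocol shrinks X, Y and s
  simultaneously, preserving the aspect ratio; the source protocol does
  not specify the partition and this choice keeps the wall area
  representative throughout.
* **Oscillation endpoint.** After the final cycle the drive sits at its
  displaced position; the protocol returns the wall to the rest geometry
  at the pulling speed before the post-deformation equilibration, so
  oscillated and control runs are sampled in the same geometry.
* **Dilute-stage dimers.** Chains that happen to dimerise during the
  dilute equilibration are left alone; nothing in the pipeline assumes
  monomeric starting chains.

## What the toy generator does and does not emulate

`make_toy_sequences()` produces chains with a prescribed glutamine
fraction (default 35%, echoing the glutamine-richness of storage
proteins), a fixed cysteine count at deterministic positions, and
small neutral residues elsewhere.  It reproduces the *composition*
features the contact machinery cares about — many equivalent
hydrogen-bonding sidechains, a few disulfide-capable sites, no net
charge — but none of the sequence architecture of real gliadins or
glutenins (repeat motifs, terminal structured domains, chain-length
distributions).  Desk-scale runs with 4 × 50 residues at `scale = 1e-3`
therefore exercise every stage of the pipeline and produce a finite
positive $G'$ and $G''$, but their numerical values are not comparable
to production-scale systems: the oscillation frequency is effectively
1000× higher (deep in the viscous regime, so tan δ comes out larger),
the chains are too short to entangle appreciably, and a ~200-residue
box has strong finite-size noise.  Passing tests certify the mechanics
and the statistics pipeline, not agreement with any particular material.

Production-scale observables (coordination numbers around 6–7 at
$\rho_0 = 3.5$, moduli in the MPa decade at 14–25 kHz) require thousands
of residues evolved for hundreds of microseconds — days of CPU — and are
deliberately outside the test suite; the machinery to run them is this
same code at `scale = 1`.

## Worked example

```{r example, eval = FALSE}
chains <- make_toy_sequences(n_chains = 4, length = 50,
                             q_fraction = 0.35, c_count = 2, seed = 11)
topo   <- build_topology(chains)
sch    <- stage_schedule(scale = 1e-3, period_us = 40)
run    <- run_protocol(topo, sch, mode = "shear", seed = 1)

rheology_from_protocol(run)        # G', G'', tan delta
coordination_number(run$state_post_osc)
fmax(run$pull$curve$force_nN)      # characteristic maximum force
```

## Known limitations

* The angle/dihedral surrogates and the per-residue contact tables are
  uncalibrated placeholders; quantitative parity with the parent
  parameterisation requires substituting its tables.
* Entanglement counting is a geometric contraction heuristic; it is
  validated on constructed fixtures with known answers, not against a
  reference implementation of a published path-contraction code.
* The cavity classifier uses a single grid orientation, so cavity volumes
  carry a grid-alignment bias of a few percent.
* Electrostatics are modest in glutamine-rich systems; the
  distance-dependent-permittivity reading has not been validated against
  the alternative screening-constant reading.
* No barostat: density is controlled only through the compression stage.
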