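# dsbmd — coarse-grained rheology of gluten-like protein networks

Wheat gluten owes its viscoelasticity to a dense network of intrinsically
disordered storage proteins (glutenins and gliadins) held together by
transient hydrogen bonds, disulfide bridges and entanglements.  `dsbmd`
is an R package for simulating such networks with a one-bead-per-residue,
implicit-solvent Langevin model in which inter-residue contacts are
*dynamic*: they are born and die from the instantaneous backbone geometry
rather than a reference structure.  Local frames at each bead classify
candidate pairs into backbone–backbone, backbone–sidechain and
sidechain–sidechain contacts (plus reversible disulfides and optional
static Go contacts for structured domains), and each contact's
Lennard-Jones attraction switches on and off adiabatically over 10 τ.

On top of the engine sits a wall-driven rheology protocol — dilute
self-avoiding-walk start, compression to melt density (3.5 residues/nm³),
wall attachment, oscillatory shear or normal strain, uniaxial extension —
and an analysis suite: the dynamic shear modulus from

    G' = (phi0 / gamma0) cos(delta),   G'' = (phi0 / gamma0) sin(delta),

with stress amplitude `phi0 = F0/S`, strain amplitude `gamma0 = A/s0` and
phase lag `delta` fitted at the drive frequency; the characteristic
maximum force `F_max` (mean of the 5 largest smoothed force samples) and
work `W_max` of extension; coordination numbers and inter-chain contact
counts; RMSF; chain distortion `w = (R2 - (R1+R3)/2) / ((R1+R3)/2)` from
the radii of inertia; primitive-path entanglement counts; and grid-probe
cavity volumes.

The force loop, Gear 5th-order predictor–corrector integrator and the
contact registry are compiled (Rcpp); everything else is plain R.  See
`vignettes/dsb-gluten-rheology.Rmd` for the model, the parameter choices
and their rationale, and known limitations.

## Worked example

A desk-scale shear experiment: 4 glutamine-rich toy chains of 50 residues,
the full protocol at 1/1000 of the production time scale (about a minute
of wall clock):

```r
library(dsbmd)
chains <- make_toy_sequences(n_chains = 4, length = 50,
                             q_fraction = 0.35, c_count = 2, seed = 11)
topo   <- build_topology(chains)
sch    <- stage_schedule(scale = 1e-3, period_us = 40)
run    <- run_protocol(topo, sch, mode = "shear", seed = 1)

rheology_from_protocol(run)
#> G' = 35.9 MPa, G'' = 82.8 MPa, tan delta = 2.31 (delta = 1.162 rad)

coordination_number(run$state_post_osc)
#> [1] 3.31
interchain_contacts(run$state_post_osc)
#> [1] 92
fm <- fmax(run$pull$curve$force_nN)
c(F_max = fm$mean, se = fm$se, W_max = wmax(run$pull$curve$work))
#>     F_max        se     W_max
#> 2.9549136 0.5421152 4.6622249
```

`G' > 0` and `G'' > 0` say the desk-scale melt is a viscoelastic liquid:
it stores part of the oscillation energy elastically (transient bb/ss
hydrogen-bond contacts, a few disulfides) and dissipates the rest.
`tan δ > 1` — loss dominating storage — is expected here: the scaled
drive frequency is three orders of magnitude above a production run, deep
in the viscous regime, and 50-residue chains are too short to entangle.
The extension stage ends in rupture; `F_max` is the characteristic peak
resistance and `W_max` the total mechanical work to pull the walls to
twice their rest separation.

Production-scale systems (thousands of residues, `scale = 1`, days of
CPU) use the identical code path; only the composition and the scale
change.

A thin CLI over the same functions ships in `inst/cli/dsbmd.R`
(`simulate`, `fixtures`, `analyze` subcommands).

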