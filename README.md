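# ftszswitch

Structural and kinetic analysis of the FtsZ conformational switch — the
mechanism by which a *single-stranded* bacterial cytoskeletal filament can
assemble cooperatively and treadmill.

## Who this is for

Structural biologists and biophysicists working on FtsZ (or other
tubulin-superfamily, single-stranded cytomotive filaments) who want to

- classify coordinate models as **open** (filament) or **closed** (monomer)
  conformers by the interdomain rotation between the N-terminal GTP-binding
  domain (NTD) and the C-terminal GTPase-activation domain (CTD),
- quantify what separates the two states: all-versus-all Cα RMSD matrices,
  landmark-atom displacements, longitudinal-interface buried surface area
  (BSA), protofilament axial repeats, and
- explore the kinetic consequences of a polymerization-associated
  conformational switch with an exact stochastic simulator.

## The model in brief

**Structure.** Open and closed FtsZ differ by a rotation of the CTD relative
to the NTD of roughly 27° about an axis near helix H-7 (measured here by
fixed-domain superposition followed by a Kabsch fit of the moving domain:
angle = acos((tr **R** − 1)/2)). Structures are paired by sequence
(Needleman–Wunsch, BLOSUM62, affine gaps 11/1) and superposed by weighted
SVD with iterative outlier rejection (deviation > 2.0 × current RMS, up to 5
cycles). SASA is Shrake–Rupley with a deterministic golden-section sphere
sampling; BSA is reported in both the PISA half-sum and total conventions.

**Kinetics.** A filament is a string of subunits with per-subunit nucleotide
(NTP/NDP, tubulin-like: the nucleotide of subunit *i* forms interface *i*)
and conformation (open in polymer, closed as free monomer). In kT/c0-reduced
units, with switch cost `s = dG_switch ≥ 0` and interface energy `dG_X < 0`:

| reaction | rate |
|---|---|
| association at an end | `k_on·c` (× `end_asymmetry` at one end) |
| end loss over interface X | `k_on·c0·exp(dG_X + s)` |
| internal breakage of X | `k_on·c0·exp(dG_X)` |
| dimer nucleation | `k_on·c·exp(−s)` |
| hydrolysis / exchange | `k_hyd` per buried NTP, `k_exch` per exposed NDP |

End loss is `exp(s)`-fold faster than breakage (the departing monomer cashes
in the switch; broken-filament ends cannot), nucleation is `exp(−s)`-fold
disfavoured relative to elongation (two switches, one interface), and the
critical concentration is `c_crit = c0·exp(dG_interface_T + s)`. Setting
`s = 0` gives the rigid (isodesmic) control with no treadmilling and no
critical concentration. Trajectories are exact Gillespie realizations,
cross-checked against full CTMC enumeration for small closed systems.

## Worked example

```r
library(ftszswitch)

## a closed reference and an open conformer with a known 27 deg rotation
spec <- synth_spec(applied_angle = 27, noise_sigma = 0.2, seed = 1)
ref <- make_two_domain_structure(spec)
open_form <- perturb_conformation(ref$structure, ref$domains, spec)

interdomain_rotation(open_form, ref$structure, domains = ref$domains)
#> Interdomain motion: 27.02 deg about (-1.000, 0.009, -0.000), screw 0.15 A
classify_conformation(open_form, ref$structure, domains = ref$domains)
#> Conformation: open (27.02 deg vs closed reference, threshold 15.0)

## a synthetic crystal protofilament with a 44 A repeat, recovered
fil <- make_filament_crystal(ref$structure, repeat_length = 44, n = 3)
filament_repeat(select_atoms(fil, chain = "A"),
                select_atoms(fil, chain = "B"))$repeat_length
#> [1] 44

## treadmilling of a switch-bearing filament (reduced units)
traj <- run_ssa(sim_params(variant = "switch"), t_max = 250, seed = 1,
                init = make_sim_state(list(rep(1L, 30))))
traj
#> SSA trajectory: 263 events to t = 250 (t_max); 1 filament(s), 0+0 free monomers
measure_treadmilling(traj)[c("velocity", "ci")]
#> $velocity: 0.092   $ci: 0.050 0.134   (subunits/s; CI excludes zero)

## breakage suppression: with dG_switch = 2, internal NDP interfaces break
## e^2-fold more slowly than ends shed subunits
ratio <- breakage_vs_endloss(run_ssa(
  sim_params(variant = "switch", dG_switch = 2, dG_interface_T = -9,
             dG_interface_D = -2.5, k_hyd = 2, k_exch = 0, c_free = 0.01,
             end_asymmetry = 1, init_length = 300L), t_max = 5000, seed = 1))
round(c(ratio$ratio, ratio$ci), 3)
#> [1] 0.110 0.081 0.148    # exp(-2) = 0.135 inside the CI
```

The first two numbers say the generator's applied 27° opening is recovered
(27.02°) and correctly labelled open; the velocity CI excluding zero is
treadmilling with the sign tied to the filament's structural polarity
(swap the asymmetric end with `mirror_params()` and the velocity flips sign
exactly); the last line is the switch's breakage suppression, matching its
construction value e⁻².

A command-line front end wrapping the same functions is installed at
`inst/cli/ftszswitch` (subcommands `classify`, `rmsd-matrix`, `motion`,
`interface`, `repeat`, `simulate`, `synth`).

## Vignette

`vignettes/ftsz-switch-and-treadmilling.Rmd` documents the model and its
assumptions, every tunable parameter with units and defaults, the numerical
choices (rejection rule, sphere sampling, detailed-balance bookkeeping,
autocorrelation handling in the oracle comparisons), what the synthetic
generator does and does not emulate, and known limitations.
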