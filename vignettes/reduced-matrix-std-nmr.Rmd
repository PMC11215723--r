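---
title: "Reduced-matrix prediction of STD NMR initial slopes and epitope-based model scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced-matrix prediction of STD NMR initial slopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Saturation transfer difference (STD) NMR detects and maps low-affinity
protein–ligand binding: selectively saturating protein protons lets
magnetization flow through dipolar cross-relaxation into the bound ligand,
so the attenuation of each ligand resonance reports how close that proton
sits to the protein surface. Classified in relative terms across the
ligand protons, these intensities form the *binding epitope map*. The
least artifact-prone epitope quantity is the initial slope STD~0~ of the
saturation build-up curve,

$$\mathrm{STD}(t_\mathrm{sat}) = \mathrm{STD}^{max}\,
  \bigl(1 - e^{-k_\mathrm{sat} t_\mathrm{sat}}\bigr),
  \qquad \mathrm{STD}_0 = \mathrm{STD}^{max} \, k_\mathrm{sat},$$

because at $t_\mathrm{sat}\!\to\!0$ the differential T~1~ relaxation,
rebinding and saturation-extent biases that distort single-time epitopes
have not yet acted.

Full relaxation-and-exchange matrix treatments can predict whole build-up
curves from a 3D model, but they are expensive and need binding kinetics
as input, which makes scoring thousands of docking poses or MD frames
impractical. This package implements the *reduced matrix* shortcut: only
the cross-relaxation blocks into the directly saturated protein protons,
weighted by their thermal-equilibrium intensities, are needed to get the
initial slopes directly — seconds per structure, no kinetic parameters.

## The model

Protons are partitioned into the bound ligand (L′), the directly
saturated protein protons (E2 free / E2′ bound) and the remaining
unsaturated protein protons (E1/E1′). Under isotropic tumbling with
correlation time $\tau_c$, the pairwise dipolar cross-relaxation rate is

$$\sigma_{ij} = \frac{1}{10}\left(\frac{\mu_0}{4\pi}\right)^2
  \gamma_H^4 \hbar^2 \; r_{ij}^{-6}\,
  \bigl(6J(2\omega_0) - J(0)\bigr), \qquad
  J(\omega) = \frac{\tau_c}{1+\omega^2\tau_c^2},$$

negative in the slow-tumbling regime of protein complexes, which is what
drives saturation transfer. The reduced matrix **M** stacks the
cross-relaxation blocks into the saturated set, each multiplied by the
equilibrium intensity of those saturated spins (proportional to the
species concentration, $[\mathrm{PL}]$ for bound, free-protein
concentration for free). With the saturated protons modelled as clamped
at zero intensity from $t = 0$, the initial slope of ligand proton $k$ is
exactly the $k$-th row sum of the L′ block:

$$\mathrm{STD}_0^{cal,k} = -\frac{[\mathrm{PL}]}{[\mathrm{L}]_{tot}}
  \sum_{j \in E2'} \sigma_{kj}.$$

The $[\mathrm{PL}]$ factor comes from the 1:1 binding quadratic
$[\mathrm{PL}] = \bigl(P+L+K_d - \sqrt{(P+L+K_d)^2 - 4PL}\bigr)/2$; since
epitopes are reported relative to the strongest proton (= 100%), this
factor — and every other global scale — cancels, which is why the method
needs no absolute intensity calibration and no binding kinetics.
Agreement with an experimental epitope is quantified by the NOE R-factor

$$R = \sqrt{\frac{\sum_k W_k\,(\mathrm{STD}_0^{exp,k} -
  \mathrm{STD}_0^{cal,k})^2}{\sum_k W_k\,(\mathrm{STD}_0^{exp,k})^2}},
  \qquad W_k = 1,$$

computed on the relative (%) scale over the proton keys present in both
epitopes; $R < 0.3$ (strict) is classified as good agreement.

### Key physical approximation

Relayed (protein-mediated, spin-diffusion) saturation pathways are
second order in time and therefore absent from an initial slope by
construction. This is the essential simplification of the reduced
approach: it is exact at $t \to 0$ and degrades only for quantities read
off at finite saturation times. The package carries a full two-site
exchange Solomon-equation solver (`solve_buildup()`) precisely to keep
this approximation honest: on every test fixture the reduced epitope is
checked against Richardson-refined finite-difference slopes of the full
solver, and the two agree to much better than the 2% test tolerance.

## Parameters that matter

| parameter | units | default | role |
|---|---|---|---|
| `frequency_mhz` | MHz | 600 | proton Larmor frequency; enters $J(\omega)$ |
| `tau_c_ns` | ns | — | tumbling time of the bound complex; tens of ns for proteins; sets the magnitude (and sign regime) of $\sigma$ |
| `tau_c_free_ns` | ns | 0.5 | free-species tumbling, used only by the full-matrix oracle |
| `cutoff_angstrom` | Å | 10 | protein protons farther than this from every ligand proton are pruned (10–12 Å retains the protons that dominate transfer) |
| `protein_conc_uM`, `ligand_conc_uM`, `kd_uM` | µM | — | binding quadratic; only the derived $[\mathrm{PL}]$ enters, and only absolute slopes depend on it |
| `saturation` | — | `"methyls"` | protein protons clamped by the saturation train; the built-in rule covers the CH₃ dictionary (ALA, VAL, LEU, ILE, THR-CG2, MET, ACE/NME), or an explicit `resid:atomname` list |
| `methyl_averaging` | flag | off | replace the three rates of a methyl trio by their mean ($\langle r^{-6}\rangle$ averaging) for sensitivity analysis |

Because relative epitopes are scale-free, the results are insensitive to
$K_d$ and concentrations (they rescale every proton identically) and to
the spectral-density normalization convention; they *are* sensitive to
geometry ($r^{-6}$), to the saturated-proton selection, and to the cutoff
when it truncates genuinely contributing protons.

## Numerical choices

- **Spectral density convention.** Unnormalized Lorentzian
  $J(\omega)=\tau_c/(1+\omega^2\tau_c^2)$ with the 1/10 factor inside the
  dipolar constant; CODATA constants at full precision; distances
  converted Å→m before the $r^{-6}$ evaluation. Any self-consistent
  convention cancels in relative epitopes.
- **Sign.** $\mathrm{STD}_0 = -\,\text{row sum}$, so saturation transfer
  in the slow-tumbling ($\sigma<0$) regime is positive. If all computed
  slopes are $\le 0$ (fast-tumbling regime) the epitope is refused rather
  than silently renormalized.
- **Methyls** are three explicit point spins at their instantaneous
  coordinates; no internal-motion model is applied (relative epitopes are
  dominated by geometry, and the optional trio averaging bounds the
  sensitivity). THR HG1 is a hydroxyl proton and is never part of the
  methyl rule.
- **Exchangeable ligand protons** (OH/NH) remain spins but carry no
  epitope key by default, because their experimental STD values in H₂O
  are unreliable; assigning a key explicitly opts them back in.
- **Cutoff boundary**: a proton at exactly the cutoff distance is kept;
  pruning is idempotent and monotone, and in trajectory mode it is
  re-done per frame, so the binding-pocket composition may adapt along
  the trajectory. A frame whose pruned saturated set is empty is flagged
  *dissociated* — exactly the condition under which STD₀ is undefined —
  and receives no R-factor.
- **Exchange model in the oracle.** Hard clamp (saturated spins held at
  zero), intensities proportional to species concentrations, exchange
  rates $k_\text{on}[\cdot]$/$k_\text{off}$ satisfying detailed balance
  at the binding equilibrium, propagation by dense matrix exponential
  (`Matrix::expm`), capped at 40 spins. In this formulation the $t\to 0$
  slope is independent of the kinetics, so the reduced prediction holds
  across the whole $k_\text{off}$ ladder — the fast-exchange limit is a
  non-issue for initial slopes, though it matters for finite-time STD
  factors.
- **Build-up fitting** uses bounded `nls` (port) initialized at
  $\mathrm{STD}^{max}_0=\max(\mathrm{STD})$, $k_{sat,0}=1/t_{1/2}$ —
  robust for monotone saturating data.
- **Finite-difference slopes** use Richardson extrapolation
  $(4S(h)-S(2h))/(2h)$ with a guard $2h \le 0.01/\max|\lambda|$ on the
  generator spectrum, giving $O(h^2)$ accuracy verified by step-halving.

## Design decisions that were genuinely open

- **The L′ rows alone define the epitope.** The free-protein block
  ($R_{E1E2} I_{E2,0}$) and the bound unsaturated-protein block are
  assembled for completeness and oracle validation but have no effect on
  ligand rows; no reading of the reduced scheme in which they would
  enter an initial slope is consistent with the
  $\mathrm{STD}^{max}\cdot k_{sat}$ logic, and the oracle confirms the
  row-sum reading numerically.
- **Normalization of the ligand row** uses the *total* ligand
  concentration, which makes the reduced value equal by construction to
  the $t\to0$ slope of the pooled (free + bound) STD factor that the
  experiment and the oracle observe under fast exchange.
- **Saturated set per frame, not fixed at frame 0**, mirroring the
  per-frame pruning; the explicit-list mechanism covers protocols that
  saturate non-methyl protons.
- **Ligand identity is declared, not inferred**: the ligand is whatever
  the ligand file (or the ligand selection, in trajectory mode) says;
  no HETATM heuristics.
- **Trajectory formats.** AMBER-dialect ASCII topology (prmtop) + ASCII
  coordinate (mdcrd) files and multi-model PDB are read natively; binary
  trajectory containers are out of scope for this implementation —
  convert upstream. Frames are used as stored (no re-imaging), a
  documented precondition.

## What the synthetic world does and does not establish

The fixture generators (`make_spin_fixture()`, `make_buildup_fixture()`,
`make_trajectory_fixture()`) emulate small rigid spin systems with known
geometry — down to a miniature ALA–VAL–GLY/4-proton-ligand complex whose
methyl dictionary, pruning behaviour and docking-pose ranking are all
checkable against brute-force arithmetic computed independently of the
package's relaxation code. Benchmark solution conditions (600 MHz,
$\tau_c = 34.5$ ns, 20/1000 µM, $K_d = 2$ mM, cutoff 12 Å, all-methyl
saturation) follow a published sialidase–sugar study; build-up noise
(2% of $\mathrm{STD}^{max}$, 8 points) reflects typical experimental
scatter. A green suite therefore establishes internal correctness of the
relaxation algebra, the initial-slope identity, and the bookkeeping of
modes and trajectories. It does **not** establish accuracy against real
spectra: fixtures have no internal dynamics, no anisotropic tumbling, no
imperfect saturation, and scripted — not physical — motions. Scoring real
complexes requires protonated experimental structures and measured STD₀
tables, which must be supplied by the user.

## Known limitations

No anisotropic diffusion, chemical-shift-anisotropy or cross-correlated
relaxation; no partial saturation or saturation-frequency offset effects;
no ligand T₁ leakage term in the epitope; no fitting of $\tau_c$ or
$K_d$ to the data; single-site 1:1 binding only; the oracle is not a
full CORCEMA-ST reimplementation (no NOESY intensity conventions, spins
capped at 40). With very few matched protons the R-factor is prone to
false positives/negatives — the package warns below four matched keys.

## A worked example

```{r, eval = FALSE}
library(stdepitope)

params  <- relaxation_params(frequency_mhz = 600, tau_c_ns = 34.5,
                             cutoff = 12)
binding <- solve_binding(protein_total = 20, ligand_total = 1000,
                         kd = 2000)

fx  <- make_spin_fixture("mini_complex")
sys <- parse_complex(fx$protein_pdb, fx$ligand_pdb)
sys <- select_saturated(sys, "methyls")
sys <- apply_cutoff(sys, 12)

cal <- calculated_epitope(sys, params, binding)
exp <- epitope(c("H1", "H2", "H3", "H4"), c(10, 100, 14, 49))
noe_r_factor(exp, cal)
```
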