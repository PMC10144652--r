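---
title: "Computing ECD spectra of solvated chromophores with pmmcd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing ECD spectra of solvated chromophores with pmmcd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmmcd)
```

## The model

Electronic circular dichroism (ECD) of a flexible chromophore in solution is
notoriously sensitive to both the chromophore conformation and the
instantaneous solvent arrangement. `pmmcd` implements a post-processing
strategy that separates the two: the expensive quantum chemistry is done
once per representative conformation in the gas phase, and the solvent
enters afterwards, frame by frame, as a classical electrostatic
perturbation of that fixed electronic basis (the Perturbed Matrix Method,
PMM).

For a quantum center (QC) with unperturbed eigenstates
$\Phi^0_l$ and energies $E^0_l$, the embedded electronic Hamiltonian is
$\hat H = \hat H^0 + \hat V$, where the perturbation is expanded in
multipoles about the QC center of mass $\mathbf r_0$ and truncated at
dipole order,

$$\hat V \simeq \sum_n \left[ V(\mathbf r_0)
  - \mathbf E(\mathbf r_0)\cdot(\mathbf r_n - \mathbf r_0)\right] q_n .$$

Expressed in the unperturbed basis this collapses exactly to a matrix any
frame can afford to diagonalize:

$$H = \mathrm{diag}(E^0) + q_\mathrm{tot} V(\mathbf r_0)\, I
  - \mathbf E(\mathbf r_0)\cdot \tilde{\boldsymbol\mu}^0 ,$$

with the identity carrying the net charge times the potential and the three
Cartesian electric-dipole matrices $\tilde\mu^0_p$ carrying the field
coupling (the per-particle sum over nuclei and electrons folds into these
two operators at dipole order; nothing else survives the truncation).
$V(\mathbf r_0)$ and $\mathbf E(\mathbf r_0)$ are direct Coulomb sums over
the environment point charges, with no cutoff by default — post-processing
has no reason to inherit the simulation's cutoff machinery.

Diagonalizing $H$ gives perturbed eigenvalues and eigenvectors $c_i$; the
perturbed transition dipoles are basis rotations of the unperturbed
matrices, $[\tilde\mu_p]_{ij} = c_i^{*T}\tilde\mu^0_p c_j$ (and likewise
for the magnetic matrices $\tilde m^0_p$), and each ground-to-$k$
transition contributes a rotational strength

$$R_k = \mathrm{Im}\{\boldsymbol\mu_{0,k}\cdot \mathbf m_{0,k}\}$$

in cgs units. Over a trajectory, vertical excitation frequencies are
histogrammed into bins of reference frequency $\nu_\mathrm{ref}$, and the
molar circular dichroism is assembled per transition as

$$\Delta\varepsilon_{0,k}(\nu) = \sum_{\nu_\mathrm{ref}}
  \frac{(R_k)_{\nu_\mathrm{ref}}\,\nu}{2.296\times10^{-39}}\,
  \frac{n(\nu_\mathrm{ref})}{N}\,
  \frac{e^{-(\nu-\nu_\mathrm{ref})^2/2\sigma^2}}{\sqrt{2\pi\sigma^2}},
  \qquad \Delta\varepsilon(\nu) = \sum_k \Delta\varepsilon_{0,k}(\nu),$$

where $(R_k)_{\nu_\mathrm{ref}}$ is the bin-mean rotational strength,
$n(\nu_\mathrm{ref})/N$ the bin occupancy fraction, and the unit-normalized
Gaussian of width $\sigma$ supplies the broadening that the vertical-
transition treatment otherwise lacks. Two readings of the Gaussian
normalization ($\sqrt{2\pi\sigma^2}$ vs $2\pi\sigma^2$) differ only by a
global constant; the package adopts the unit-normalized Gaussian, which
makes the per-transition area
$\int (\Delta\varepsilon_{0,k}/\nu)\,d\nu =
(2.296\times10^{-39})^{-1}\sum_\mathrm{bins}(R_k)_{\nu_\mathrm{ref}}
n(\nu_\mathrm{ref})/N$ exactly $\sigma$-independent — a property the test
suite pins to 0.1%. UV absorption uses the identical machinery with the
dipole strength $|\mu_{0,k}|^2$ and the standard cgs extinction constant
$9.184\times10^{-39}$ (four times the CD constant), since the two sum
rules differ by exactly that factor.

## Conformational analysis

Flexible chromophores need more than one reference configuration (RC). The
package finds them by essential dynamics (ED): the trajectory is
mass-weighted superposed onto a reference structure (Kabsch SVD
superposition; the first frame by default), the $3N\times3N$ positional
covariance matrix is diagonalized, and frames are projected onto the two
leading eigenvectors — for monosaccharide-like systems these capture
essentially all conformational fluctuation, dominated by hydroxymethyl and
hydroxyl torsions. On that essential plane a 2-D histogram (60×60 cells
over the sampled range ±5% by default) yields relative Helmholtz free
energies

$$\Delta A_{i,j} = -k_B T \ln(P_j / P_i), \qquad
  k_B = 0.0083145~\mathrm{kJ\,mol^{-1}K^{-1}},\ T = 300~\mathrm K
  \ \text{by default},$$

anchored to zero at the most populated cell; unsampled cells stay marked
unsampled rather than carrying a number.

Basins are detected by ordered flooding of the sampled cells (a discrete
watershed, 8-neighbor connectivity by default). Two numerical choices here
are the package's own, because a visual description of basins does not fix
an algorithm:

* **persistence merging** — a local minimum that meets a deeper basin at a
  flooding level less than the basin threshold (3 kJ/mol by default) above
  its own floor is sampling noise, not a conformer, and is merged;
* **occupancy filter** — surviving basins holding under 5% of all frames
  are discarded; a conformational state worth a reference configuration
  holds at least a few percent of the sampling, and desk-scale histograms
  otherwise sprout spurious fringe islands.

RCs are then allocated to basins proportionally to basin occupancy (every
basin gets at least one; the caller errs if it asks for fewer RCs than
basins), each RC being the trajectory frame nearest to a low-free-energy
cell center on the plane. Each RC inherits a probability — the occupancy of
the basin cells nearest its own cell, renormalized over all RCs — and these
probabilities weight the per-RC spectra in the conformer sum, with an
experimentally known anomer ratio (e.g. 32:68 α:β for aqueous glucose,
38:62 for galactose) applied at the final mixing step.

The hydroxymethyl rotamer of each frame is classified from the
O6–C–C–O5-type dihedral by nearest center on the circle: TG at 0°, GG at
60°/240°, GT at 180°, with boundaries at the circular midpoints 30°, 120°,
210°, 300°. Per-cell dihedral summaries use circular means — GG spans both
60° and 240°, and arithmetic averaging across the wrap would corrupt the
maps.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `bin_width` | 250 | cm⁻¹ | excitation-frequency histogram resolution; fine enough that the binning is invisible under any plausible σ |
| `sigma_ev` | 0.15 | eV (≈1210 cm⁻¹) | Gaussian broadening; a user input here — the package deliberately does not estimate it |
| `bins` | 60 | cells/axis | essential-plane histogram; matches the free-energy map resolution the method needs |
| `basin_threshold` | 3 | kJ/mol | low-free-energy region around each basin floor from which RCs are drawn; also the persistence-merge level |
| `temperature` | 300 | K | enters only through $k_BT$ in the landscape |
| `min_dist` | 0.05 | nm | environment charge closer than this to the QC center is treated as a clash and is a hard error |
| `window` | 160–220 | nm | far-UV reporting window actually accessible to aqueous-phase experiments |
| `intensity_floor` | 1.0 | M⁻¹cm⁻¹ | per-transition report floor; weaker transitions are noise at this level of theory |

Units are atomic units for everything electronic (energies, dipoles,
fields) and nm for everything that comes from MD, with one conversion
layer (`R/constants.R`, CODATA 2018). Magnetic dipole matrices are stored
complex although physically purely imaginary, so `Im{μ·m}` needs no sign
bookkeeping; the validator enforces purely imaginary entries with
antisymmetric imaginary part — the matrix of a Hermitian, purely imaginary
operator over real unperturbed wavefunctions.

## Numerical choices and degenerate inputs

* Eigen-decompositions use LAPACK through `eigen(symmetric = TRUE)`;
  eigenvalues are returned ascending and each eigenvector is rephased so
  its largest-magnitude component is real positive (ties to the lowest
  index), making results deterministic across platforms.
* Eigenvalue order defines state identity per frame. No diabatic tracking
  is attempted: the spectrum assembly only needs ground-to-$k$ energies and
  strengths per frame, and degenerate pairs land in the same frequency bin,
  where their strengths sum naturally.
* The superposition rotation uses the SVD construction with a determinant
  guard, so reflections can never sneak in.
* An unperturbed-set file read/write cycle is bit-exact (17 significant
  digits in JSON).
* Zero-environment frames are legitimate inputs and reproduce unperturbed
  values to machine precision; an environment charge inside `min_dist` of
  the QC center aborts (or skips the frame under the permissive flag,
  which exists for corrupted-trajectory triage, not routine use).

## What the synthetic fixtures emulate — and what they do not

The package ships generators, not data. `mock_unperturbed_set()` builds a
randomized but structurally valid electronic set (17 states by default,
lowest excitation at 6.5 eV — the far-UV regime of a sugar-like
chromophore); `mock_solvent_frames()` surrounds the QC with neutral
three-charge groups (q = 0.4238 e, water-like geometry) in a spherical
shell, preserving the far-field multipole decay that real solvent shows;
`mock_conformational_trajectory()` drives one soft dihedral of an abstract
8-atom chain through a two-basin wrapped-Gaussian mixture (GG/GT-like
centers at 60°/180°, 60:40 weights by default) under random rigid motions,
with true basin labels returned for recovery tests.

These fixtures exercise every parser, validator and algorithm in the
package with known ground truth. They do **not** contain real water
structure, force-field energetics, polarization, or a real sugar — so
passing tests demonstrate the correctness of the machinery (Coulomb sums,
eigensolves, basis rotations, binning, free-energy estimation), not the
accuracy of any force field or functional. Against real inputs the
dominant error sources are upstream: the quality of the MD sampling and of
the TDDFT basis, neither of which this package computes. Vibronic
structure is out of scope by design; the Gaussian broadening stands in for
it only cosmetically. The dipole-order truncation of the perturbation is
known to degrade for large quantum centers where the field is inhomogeneous
across the QC; this package intentionally stops at dipole order.

## Problem sizes

The shipped tests and the acceptance script run the free-energy recovery
at 10⁵ trajectory frames, ED recovery at 2×10³ frames of 30 coordinates,
PMM checks at up to 17 states with a few hundred environment charges over
tens of frames, and the end-to-end pipeline at 2×10³ ED frames / 50 PMM
frames per RC — sizes chosen so the whole suite completes in about a
minute while every statistical tolerance retains comfortable margin.

## Known limitations

* No diabatization: state crossings along a trajectory swap labels; only
  binned, per-transition aggregates are meaningful.
* The basin detector is grid-based; basins narrower than a cell or split
  by sampling gaps need a finer grid or more frames, and the 5% occupancy
  filter deliberately refuses to call rare states basins.
* The GRO reader parses coordinates only (fixed columns, velocities
  ignored) and relies on a separate per-atom charge table; it is a
  convenience path, the XYZ-with-charges dialect is the primary format.
* The σ-broadening is user input; nothing in the package estimates it from
  the data.
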