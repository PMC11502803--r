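---
title: "Models and methods behind ctdphase"
author: "ctdphase authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ctdphase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ctdphase)
```

# Scope

`ctdphase` is a desk-scale toolkit for studying how the sequence of the RNA
polymerase II carboxy-terminal domain (CTD) controls its liquid-liquid phase
separation. The human CTD is 52 tandem repeats of the heptad consensus
Y1-S2-P3-T4-S5-P6-S7. In the sticker-and-spacer picture the tyrosines act as
stickers whose transient contacts crosslink chains into condensates, while
the serine/proline/threonine spacers tune those contacts through local
structure (SPXX beta-turns controlled by proline cis/trans isomerization)
and through phosphorylation, which deposits negative charge in the spacer
and dissolves condensates.

The package covers four layers:

1. construct building (consensus, substitution variants, phospho-states,
   proline isomer states, SPXX motif location);
2. a bead-per-residue coarse-grained simulator (single-chain and
   periodic-box condensed phase) plus reference polymer ensembles with
   known scaling exponents;
3. trajectory analyses (internal-distance scaling and the Flory exponent,
   radius of gyration, per-residue interaction-energy maps, beta-turn
   classification, contact-based chain clustering and dissolution metrics);
4. fluorescence-micrograph droplet quantification with a synthetic
   micrograph generator for ground-truth validation.

# The coarse-grained model

One bead per residue, 0.38 nm backbone bonds (harmonic,
k = 8000 kJ mol^-1 nm^-2). Nonbonded interactions are a 12-6 potential with
sigma = 0.47 nm, truncated and shifted to exactly zero at 1.1 nm. Pair well
depths are geometric means of per-type stickiness values, floored at a small
`eps_min` = 0.3 kJ/mol so every bead keeps excluded volume, and multiplied
by `solvation_scale` = 1/1.1 < 1. The latter mirrors, in direction and
magnitude, the common practice of strengthening protein-water attraction by
10% to reproduce the dimensions of disordered proteins: here, with implicit
solvent, enhanced solvation appears as uniformly weaker protein-protein
attraction.

The sticker hierarchy is Y > F > spacers > A: tyrosine is the strongest
sticker, phenylalanine somewhat weaker, the polar spacers weakly cohesive.
Pairs whose mixed well depth sits at the floor - anything involving
alanine, a phosphoserine backbone or a phospho side bead - interact through
the purely repulsive WCA form (the 12-6 core cut and shifted to zero at its
minimum): these beads are *fully* non-sticky, not merely weakly sticky,
while still carrying excluded volume. The defaults in `default_params()`
were calibrated once, before freezing the parameter file, so that the three
qualitative behaviours the model must reproduce hold at the default desk
scale (10 chains of 4 heptads): the consensus condenses from random
insertion and a preformed consensus condensate persists; the Y1A variant
neither condenses nor keeps a preformed condensate together; and phospho-S5
chains dissolve a preformed condensate. The parameter set carries a version
string that is logged with every run.

Electrostatics is Debye-Hueckel: phosphoserine side beads (one per
phosphorylated serine, bonded at 0.319 nm, the lengthened bond of the
all-atom phosphoserine geometry) carry -1e (the Q5-type bead) or -1.5e (the
D-type bead; the default, as the stronger parameterization suits the
desk-scale dissolution studies), screened with the analytic Debye length at
150 mM monovalent salt and 300 K (0.785 nm). This replaces the
reaction-field treatment of the reference coarse-grained protocol with a
closed form that is directly testable. The screened Coulomb term carries
its own cutoff (2.5 nm, about three Debye lengths) rather than sharing the
1.1 nm 12-6 truncation: a reaction field compensates charge interactions
beyond its cutoff, and truncating an uncompensated screened Coulomb at
1.1 nm would discard essentially all of the collective charge repulsion
that drives phospho-triggered dissolution. Phosphorylation also switches
the serine backbone bead to the non-sticky hydrophilic type `pS`: a
strongly hydrated residue, in implicit solvent, is one that has lost its
protein-protein attraction.

Proline (and hydroxyproline, code `O`) cis/trans states are fixed per run -
isomerization is orders of magnitude slower than the simulated time scales,
matching the practice of imposing isomer states. A cis proline in an SPXX
motif stabilizes the compact beta-turn; with one bead per residue there is
no backbone dihedral to restrain, so the model represents this as a stiff
harmonic restraint (k = 1500 kJ mol^-1 nm^-2, minimum 0.45 nm) on the
motif's Calpha1-Calpha4 analog distance - stiff because a fixed cis isomer
imposes the turn geometrically, not as a soft preference. Hydroxyproline shares proline's interaction parameters: its
main physical effect runs through the isomer equilibrium (it disfavours cis),
which the user expresses through `assign_proline_isomers()`, with at most a
minor residual effect of the extra hydroxyl.

## Dynamics

Underdamped Langevin dynamics with the BAOAB splitting; the kinetic
temperature is therefore directly testable against the 300 K target (the
suite asserts agreement within 3%). Defaults: timestep 0.02 ps against the
stiffest mode (bond period ~0.5 ps), friction 0.2 ps^-1 (a weak coupling
that thermostats reliably while letting chains diffuse quickly), bead mass
50 g/mol. The mass is a reduced coarse-grained mass: it only sets the pace
of exploration, not the sampled ensemble, and a light bead explores
configuration space faster at fixed wall time. Nonbonded forces use a
Verlet neighbour list (0.3 nm skin, displacement-triggered rebuilds);
single-shot energy evaluations use a linked-cell search or a fused O(n^2)
loop for small systems, and both agree with a brute-force double loop at
machine precision in the test suite. Runs are bit-reproducible from the
seed. NVT only, orthorhombic periodicity only; no barostat, no constraint
solver, no long-range electrostatics - none of which the desk-scale claims
need.

Multi-chain runs start either from random non-overlapping insertion (with
bounded retries, then an error) or from a supplied preformed configuration,
normally the final frame of a previous run - re-used verbatim, as nothing
more specific is known about how re-solvated preformed condensates were
positioned. `preformed_from()` maps a final frame onto a phosphorylated
topology by keeping backbone positions and attaching fresh side beads at
clearance-maximizing directions. A short pre-relaxation at a tenth of the
timestep, with per-bead forces clamped, removes insertion strain without
letting an unlucky overlap inject unbounded momentum;
analyses discard the first half of condensed-phase trajectories by default,
echoing the convention of analysing only the final part of production runs.

## Scale

Desk scale means: 10 chains of 4 heptads (30 beads per chain) in a 10-12 nm
periodic cube, 2e5 steps per production run, minutes per run on one core.
The reference protocol this stands in for - 52 repeats, 10-80 chains, a
45 nm box, 20 microseconds of Martini3 - differs by orders of magnitude in
every dimension. Consequences: all condensed-phase claims the package tests
are direction-of-effect claims (condenses vs disperses, persists vs
dissolves, more vs less compact), never numeric reproductions of the
reference trajectories; and the contact thresholds (20/50/80) carried over
from full-length chains sit high relative to what two 30-bead chains can
accumulate, making the largest-cluster series flicker more than it would at
full length.

# Reference ensembles

Every analysis stage is validated against generators with known ground
truth, none of which involve the simulator:

* **ideal**: Gaussian-step chains, rms step = b. The rms internal distance
  is b*sqrt(s) exactly, making this the parameter-recovery oracle for both
  fit modes.
* **saw**: cubic-lattice self-avoiding walks, decorrelated by the pivot
  algorithm (uniform over the 47 non-identity octahedral symmetries,
  hash-set self-avoidance check, with an explicit failure when the attempt
  budget is exhausted). True exponent ~0.588; tested against the idealized
  3/5 with a tolerance that covers the difference.
* **globule**: random contiguous windows of a 3-d Hilbert curve through a
  cube holding at least twice the requested bead count, plus +/-0.25
  lattice-unit jitter. A space-filling curve is used because it guarantees
  s consecutive beads occupy a region of linear size ~s^(1/3) at *every*
  scale; a random Hamiltonian path through a compact volume does not (its
  short-range statistics are diffusive, ~s^(1/2), before saturating), and
  a confined random walk saturates to the container size. Random windows
  give the ensemble genuine variability without breaking locality.
* **rod**: collinear beads, the nu = 1 edge case.

The bimodal SPXX turn-distance generator is a positive-truncated normal
mixture with components on either side of the 0.7 nm cutoff; its mixing
weight is the ground truth the classifier must recover (binomial error
~0.0014 at n = 1e5, tested at +/-0.01).

# Analysis conventions

**Internal distances.** `internal_distance_profile()` averages over all
pairs at each separation s and all conformations. The profile's `r` is the
root-mean-square distance by default. The scaling relation r(s) = b s^nu
with b the Kuhn length is exact for an ideal chain only under the rms
reading (the plain-mean prefactor is 0.921 b); rms is therefore the reading
under which the stated recovery targets (nu = 1/2 and b = 0.55 nm on ideal
chains) are simultaneously attainable, and the plain mean remains available
via `average = "mean"`.

**Flory fits.** Log-log least squares. Clamped ("paper") mode fixes
b = 0.55 nm and fits nu on separations strictly above 200 peptide bonds,
mirroring the full-length protocol; free mode fits both parameters and, on
scale-free reference ensembles, uses the full separation range - the
restriction to s > 200 exists to skip the non-universal short-range regime
of real chains, which synthetic scale-free ensembles do not have, and the
narrow window 200 < s < 365 would otherwise amplify intercept noise.
Replica-level scatter (`fit_flory_replicas()`) reproduces the
SD-over-replicas convention; single fits report the least-squares standard
error.

**Turn classification.** Compact means strictly less than 0.7 nm - a
distance exactly at the cutoff is extended. The AUC ratio (mass below over
mass above the cutoff) is computed from empirical counts, not a smoothed
density: no kernel was specified for the reference distributions, counts
are reproducible, and both converge to the same ratio. An all-compact
sample reports `auc_ratio = Inf` with an explicit flag.

**Energy maps.** Entry (i, j) is the time-averaged nonbonded pair energy
(12-6 plus electrostatics) between residues i and j, with phospho side
beads aggregated onto their residue; directly bonded pairs are excluded,
and pairs never within the cutoff are exactly zero. The map's grand sum
over i < j equals the trajectory-averaged nonbonded total - an invariant
the suite checks. Entries at or below -7.0 kJ/mol are flagged (inclusive
boundary: "matching or exceeding"). Averaging across replicas or
constructs is a separate, frame-count-weighted reduction
(`average_energy_maps()`), since both reductions are legitimate readings
of a replica-and-construct-averaged map.

**Clustering.** A contact is a bead pair from distinct chains strictly
within 0.6 nm under the minimum-image convention; chains join when their
pair count strictly exceeds the threshold (20/50/80). Both boundaries are
read literally from "within" and "more than". The cluster series counts
contacts between backbone beads - the model's uniform one-bead-per-residue
resolution. In the reference model every residue contributes several beads,
so counting all beads is neutral there; here only phosphoserines carry an
extra bead, and including it would mechanically inflate the contact counts
of exactly the constructs whose dissolution is under test
(`backbone_only = FALSE` restores all-bead counting). Membership is
pairwise-edge connected components - the order-independent reading of
"contacts with any other cluster member"; the aggregate reading (summed
contacts against a growing cluster) is available behind
`aggregate = TRUE`. Clustering is verified against exhaustive brute-force
connected components on random graphs of up to 12 chains.

# Droplet quantification

The micrograph pipeline re-implements a CellProfiler-style analysis:
normalize to [0, 1], global Otsu threshold (256-bin histogram, lowest
maximizer on ties - the classic formulation, since only the method is
named), connected components with a distance-transform watershed to split
touching droplets (the closest standard analog of the unspecified
declumping settings, and flagged in the segmentation object), an equivalent
diameter gate of 4-70 px applied at segmentation, then shape and intensity
filters: eccentricity <= 0.6 from the second-central-moment ellipse
(0 = circle, 1 = line segment; elongated aggregates are discarded) and
median pixel intensity in 0.1-1, applied to normalized intensities (the
range is read as a fraction of the display range). Areas convert at
0.010645 um^2 per pixel. "Droplet size" is reported as area in um^2
(the analysis computes Area and converts px to um^2); the equivalent
diameter is emitted alongside for the other reading.

Assay statistics treat the measurement, not the droplet, as the unit of
replication: the median droplet size per measurement, the mean +/- SD of
those (typically three) medians, and an unpaired two-sided t-test on the
medians - pooled variance by default, Welch behind a flag, as the test
variant is not further specified. Significance tiers: ns / * / ** / *** /
**** at 0.05 / 0.01 / 0.001 / 0.0001. Degenerate zero-variance groups are
handled explicitly (t = 0, p = 1 for equal means).

The synthetic generator renders droplets with sigmoidal-edge radial
profiles plus Gaussian noise and returns the rasterized ground truth.
What it does not emulate: optical blur and its correlated noise,
uneven illumination, out-of-focus droplets, fusing droplets mid-coalescence,
or camera artefacts. Passing end-to-end recovery on these images therefore
validates the measurement chain (thresholding, labelling, feature
extraction, unit conversion, statistics), not robustness to real microscopy
backgrounds. Otsu's single global threshold also needs the foreground to
carry a visible histogram mass; the generator's default densities are chosen
to resemble the droplet coverage of real assay images rather than the
nearly-empty field where any global threshold method degrades.

# Numerical choices and degenerate inputs

* Flory fitting refuses profiles with no separations above `min_sep`
  rather than silently fitting short-range structure.
* A constant image has no Otsu threshold: the pipeline warns and returns
  zero objects rather than fabricating a cut.
* `auc_ratio` with an empty extended class is `Inf` with a flag, never a
  division error.
* Cluster series on a single chain is an error, not a trivial answer.
* Zero-step runs return the initial configuration unchanged.
* Tie-breaks: Otsu takes the lowest maximizing cut; cluster labels are
  arbitrary but partitions are compared as partitions.
* The t-test falls back to exact limits (t = 0, p = 1, or +/-Inf, p = 0)
  when both groups have zero variance.

# Problem sizes

The suite and the acceptance script run at sizes chosen so the full battery
completes in minutes on one core while keeping every statistical tolerance
honest: 2000 ideal conformations of 366 beads for parameter recovery
(fitted-exponent scatter ~0.002), ~100-150 SAW and globule conformations,
1e5 mixture samples, 2048 x 2048 synthetic micrographs, and condensed-phase
runs of 10 x 4-heptad chains for 2e5 steps. These are the package's standard
demonstration conditions; longer runs only sharpen the same comparisons.

# Known limitations

* The simulator is an intentional analog of the reference coarse-grained
  protocol, not a re-implementation: no Martini bead chemistry, no
  reaction-field electrostatics, no barostat, no solvent beads. Its claims
  are qualitative orderings plus analysis-layer numerics.
* One bead per residue cannot express hydrogen bonds, secondary structure,
  or backbone/side-chain energy decompositions; analyses requiring
  atomistic detail (DSSP-style assignment, hydrogen-bond networks) are
  deliberately absent.
* Cis/trans isomerization never happens during a run; isomer states are
  inputs.
* The contact thresholds are tied to full-length chains; at desk scale the
  largest-cluster series is a noisy observable and only its level and
  trend are meaningful.
* FASTA cannot carry phospho or isomer annotations; they travel in a
  sidecar CSV.
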