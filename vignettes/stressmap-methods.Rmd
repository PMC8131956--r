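---
title: "Methods: comparative stress analysis of multidomain MD trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative stress analysis of multidomain MD trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Antibody Fab fragments unfold and aggregate along different routes
depending on the stress they experience.  Molecular-dynamics trajectories
of a Fab under a reference condition and under stress conditions (low pH,
elevated temperature) can reveal *where* deformation starts: in which of
the four immunoglobulin domains (VL, CL on the light chain; VH, CH1 on the
heavy chain), at which of the two inter-chain interfaces (VL–VH, CL–CH1),
in which β-strands, and whether the motion exposes aggregation-prone
regions (APRs) to solvent.  `stressmap` implements the full comparative
analysis as a reusable, tested pipeline, together with a synthetic
trajectory generator whose ground truth is known exactly, so every metric
can be validated at desk scale.

Throughout, residues are numbered continuously over both chains: the light
chain keeps its numbering (VL 1–108, CL 109–214) and the heavy chain
continues at 215 (VH 215–334, CH1 335–429).  Hinge residues 430–442 belong
to no domain; they are excluded from domain regions but retained in
whole-protein metrics.  All analyses use heavy atoms only — "all-atom"
metrics include side chains but never hydrogens, which are dropped on
reading.

## Metrics

**Superposition and deformation.**  Rigid-body fits use the Kabsch
algorithm (SVD of the weighted covariance with the determinant sign
correction, so only proper rotations are returned).  Per-domain RMSD fits
each frame on the domain's own heavy atoms before measuring, so
inter-domain motion never inflates a domain's deformation signal.
Windowed RMSF partitions frames into consecutive non-overlapping time
windows (default 10 ns; a frame landing exactly on a boundary joins the
preceding window), fits each frame to the static reference on the region's
atoms, and takes fluctuations about the *window-mean* coordinates; this
single-pass convention (rather than iterative re-fitting to the evolving
mean) is deterministic and standard practice.  Radius of gyration is the
mass-weighted RMS distance from the centre of mass, with masses from a
fixed element table (unknown elements fall back to carbon, with a
warning).

**Native contacts.**  A native contact is a heavy-atom pair within 4.5 Å
in the reference structure; intra-domain pairs separated by fewer than 3
residues are excluded as trivially bonded, while interface pairs keep all
cross-domain pairs (sequence separation is meaningless between chains).
Contact persistence uses the logistic soft cutoff

$$Q = \frac{1}{N}\sum_{ij} \frac{1}{1 + \exp\!\big[\beta\,(r_{ij} - \lambda\, r^0_{ij})\big]}$$

with β = 5 Å⁻¹ and λ = 1.8, the standard soft-cutoff constants of the
contact-analysis literature.  All four constants are configuration
parameters, never hard-coded call sites, so they can be matched to any
published variant.  Residue-level fractions average the per-pair score
over every pair a residue participates in.  Total contacts (native and
non-native alike) count cross-set pairs within 6.0 Å, the conventional
default of the tool this mirrors.

**Salt bridges.**  A bridge between an acidic residue (Asp OD1/OD2, Glu
OE1/OE2) and a basic residue (Lys NZ, Arg NE/NH1/NH2) is recorded in a
frame when *any* qualifying O–N pair is within 3.2 Å (boundary inclusive;
the residue-level any-atom rule matches how bridges are reported, e.g.
Glu195–Lys149).  His ND1/NE2 join the basic set only via the
`include_his` flag, because His participation depends on its protonation
state.  Occurrence is the percentage of frames in which a bridge is
formed; replicate tables are united (missing entries count 0), averaged,
and thresholded at 10% *on the replicate mean* — applying the threshold
per replicate before averaging is the other defensible reading, so the
threshold point is configurable.  Region counting buckets each retained
bridge as intra-domain, interface, or "other" (including hinge partners).

**β-strand occupancy.**  Secondary structure uses a minimal Kabsch–Sander
implementation: amide hydrogens are reconstructed on the heavy-atom model
(H = N + 1.00 Å × unit(C_prev − O_prev); chain-initial residues and
prolines are never donors), the electrostatic bond energy is
E = 27.888·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN) kcal/mol with a bond iff
E < −0.5 (strict), and β bridges follow the parallel/antiparallel rung
patterns.  Residues in ladders of at least two consecutive bridges are
labelled E; isolated bridges are not.  Only the E state is implemented —
helices, turns and bends map to "other" — because the comparative reports
use exclusively β occupancy.  A CA–CA < 9 Å prefilter accelerates the
pair search; at 9 Å the bond energy is far above the cutoff, so the
prefilter cannot change assignments.  Per-strand occupancy change between
conditions is *relative* percent change by default
(100·(occ_stress − occ_ref)/occ_ref); the wording "percentage
increase/decrease" is genuinely ambiguous between relative change and
percentage-point difference, so both are implemented and the output
labels which was used.  Strands never β in the reference report NA, not
infinities.

**Surface and packing.**  SASA is Shrake–Rupley with probe 1.4 Å, 960
quasi-uniform sphere points per atom (golden-spiral lattice,
deterministic), and vdW radii C 1.70, N 1.55, O 1.52, S 1.80 Å.  The dot
error on an isolated sphere is about 2% at the default count and shrinks
as the count grows; because the lattice is fixed in the laboratory frame,
rigid-motion invariance also holds to about the same tolerance.  APR
exposure change is the relative change of the time-mean summed SASA of
each APR, replicate-paired, with the reference condition as benchmark.
Occluded-surface packing (OSP) casts the outward normal from each surface
point until it meets a neighbouring vdW sphere; rays shorter than
RL_max = 2.8 Å (one water diameter) contribute 1 − RL/RL_max, giving a
0–1 packing score per atom, aggregated per residue by vdW-area weighting.
Rays start on the vdW sphere rather than the molecular surface of the
original occluded-surface program, which keeps the score bounded and
simple; absolute OSP values are therefore comparable within this
implementation only, and no published absolute packing value is treated
as a target.  Both kernels are small C++ routines; everything around them
is plain R.

**Sequence statistics.**  The mutational scan enumerates all 19
substitutions at every position (8398 mutations for a 442-residue Fab).
Stabilising calls from two external ΔΔG tables (e.g. FoldX- and
Rosetta-style scans; computing ΔΔG is out of scope, the tables are
inputs) are intersected with the convention *negative = stabilising* and
a strict threshold at 0 — whether the published fractions used a strict
or non-strict inequality is unstated, so strict is chosen and documented.
Alignment conservation is Shannon entropy per column in nats over the
21-symbol alphabet (20 amino acids + gap), bounded by ln 21 ≈ 3.04; the
nats convention is forced by that stated maximum.  Gap-only columns are
single-symbol columns with H = 0, not errors.  APR consensus marks a
residue when at least 3 of 4 predictor masks agree and converts maximal
runs into intervals.

## The synthetic mini-Fab and what it does (not) emulate

The generator builds an idealised four-domain "mini-Fab": each domain is a
two-strand antiparallel hairpin (two 10-residue strands joined by a
4-residue loop, 24 residues per domain, 96 in total); the light chain
(VL, CL) and heavy chain (VH, CH1) sheets face
each other 7 Å apart with pseudo-Cβ atoms forming the VL–VH and CL–CH1
interface contacts.  Strands are built by internal-coordinate (NeRF)
construction with standard bond geometry; the hairpin partner is the
two-fold-rotated copy whose offset is found by a deterministic grid search
maximising inter-strand Kabsch–Sander hydrogen bonds.  With the default
strand dihedrals (φ = −139°, ψ = +145°) this yields an 8-bond ladder and
interior residues assigned E; the textbook ψ = +135° produces no H-bonded
registry under a rigid two-fold pairing of twisted strands, which is why
+145° is the hairpin default here.

Each domain's loop is a designated APR, tucked behind a sparse shell of
occluder pseudo-atoms.  The shell density was chosen so the buried loops
keep a *moderate* reference exposure (about a third of their exposed
area): a near-zero baseline would make the relative exposure change
ill-conditioned (a few Å² of jitter bias moves a +700% change by tens of
points), whereas the moderate baseline with the default 5 Å displacement
ramp produces the doubling-scale (~+100%) change that recovery tests can
meaningfully check to a few percentage points.

Designed salt bridges carry real acidic/basic side-chain atoms placed at
their formed geometry (3.0 Å O–N).  Occupancy schedules are deterministic:
bridge *b* is "on" for the first round(p·n_frames) frames, its oxygens
placed relative to the (possibly rigidly moved) basic nitrogen, and bridge
atoms receive no jitter — so measured occurrences equal the schedule
exactly, which is what makes exact recovery assertions possible.  The
reference schedule spans 30–90% occupancy; the low-pH-like schedule
eliminates every glutamate bridge (mirroring the loss of all Glu bridges
under strong acidification, Glu having the higher side-chain pKa); the
high-temperature-like schedule halves all occupancies.

The three condition classes are:

* **reference** — i.i.d. Gaussian jitter (σ = 0.25 Å) about the base
  structure; stationary by construction;
* **low_ph_like** — the same jitter plus a linear displacement ramp
  (default 5 Å) of the target domain's loop (default CL) away from the
  partner sheet, plus the Glu-bridge elimination.  This deforms exactly
  one domain, breaks its loop contacts, and exposes its APR, while both
  interfaces stay intact;
* **high_temp_like** — larger jitter (σ = 0.6 Å) plus a linear rigid
  separation ramp (default 10 Å) of the heavy chain, opening both
  inter-chain interfaces progressively while individual domains stay
  internally intact.

Replicate *r* of master seed *s* uses seed 1000·s + r, so replicate sets
are reproducible independently.  Ground truth (mode, seeds, ramps, and
the exact expected occurrence of every bridge) is attached to the
trajectories and written alongside fixture files as JSON.

The jitter is i.i.d. per atom — not physically correlated motion, no
force field, no thermostat.  That is sufficient to validate *metrics*
(they see coordinates, not physics) and orders of magnitude cheaper than
MD, but it means passing tests demonstrate correctness of the analysis
machinery, not realism of any simulation: real trajectories have
correlated, anharmonic fluctuations, solvent effects and slower relaxation
than anything generated here.  Published headline values from real Fab
simulations (e.g. domain RMSDs of ~2.6 Å, interface contact fractions of
~0.6 at high temperature, a 71% bridge occurrence) derive from six 100-ns
all-atom runs per condition and are treated as qualitative patterns only.

## Recovery studies and problem sizes

The test suite and the acceptance script run the full analysis on the
generator's output and check:

* **targeted-domain identification** — under the low-pH-like profile the
  target domain must rank first by both final ΔRMSD and Δ(native-contact
  fraction) versus reference, across 20 master seeds (3 replicates ×
  61 frames each: the signal-to-noise of the designed ramps makes longer
  runs unnecessary, and the whole 20-seed study completes in about a
  minute);
* **interface-first loss** — under the high-temperature-like profile both
  interfaces must lose a larger *fraction* of native contacts than any
  single domain, across the same 20 seeds;
* **exact occupancy recovery** — measured bridge occurrences equal the
  designed schedule to machine precision in every replicate;
* **APR exposure recovery** — the jittered 6-replicate estimate of each
  APR's relative SASA change lies within 5 percentage points of the
  noise-free (σ = 0) run of the same schedule, the honest ground truth
  for a quantity with no closed form.

The fixture used for the pipeline-level signature checks is 6 replicates
of 61 frames per condition — the package's desk-scale choice, stated here
once; the generator's own defaults keep the full-study cadence (1001
frames at 0.1 ns, 6 replicates).

## Numerical choices and degenerate inputs

* Kabsch requires ≥ 3 atoms and equal counts; the rotation is always
  proper (reflections corrected by the sign of the determinant).
* RMSF windows must cover at least two frames; fluctuations are taken
  about window means after fitting to the static reference.
* The soft-cutoff fraction of an *empty* contact set is an error, not 0 —
  an undefined fraction should never silently average into a report.
* Salt-bridge occurrences are sparse maps: pairs never formed are absent,
  not zero rows; aggregation fills zeros only when a pair was seen in at
  least one replicate.
* Kabsch–Sander energies with any inter-atom distance below 0.5 Å are
  clashes, set to −9.9 kcal/mol (the classical convention) and flagged.
* Score projection clamps to the PDB B-factor column range
  [−9.99, 999.99] with a warning; a round trip recovers two decimals.
* Replicate SEM uses the sample standard deviation (n − 1); a single
  replicate reports SEM 0 with a warning rather than NA, so tables stay
  numeric.
* Pipeline Δs are always stress − reference; replicates are paired by
  index when counts match, otherwise unpaired means are differenced and
  SEMs combined in quadrature with a warning.
* CSV output is fixed to 6 significant digits so identical inputs produce
  byte-identical reports.

## Limitations

* The generator's motion model is statistical, not physical (above).
* OSP absolute values depend on the ray-origin convention and are
  comparable only within this implementation.
* Only the β-strand (E) state of the secondary-structure alphabet is
  assigned; analyses needing helices or turns would need the full
  eight-state treatment.
* No periodic-boundary unwrapping: trajectory frames are assumed whole,
  as the generator produces and as typical post-processed MD exports are.
* mmCIF and compressed binary trajectory formats are not read; the
  exchange format is (multi-model) PDB.
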