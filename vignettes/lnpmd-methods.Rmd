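---
title: "Methods: bilayer shape descriptors and delivery statistics in lnpmd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bilayer shape descriptors and delivery statistics in lnpmd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lnpmd)
```

`lnpmd` quantifies the shape and mechanics of ionizable lipids in bilayer
trajectories and links those descriptors to lipid-nanoparticle (LNP)
delivery readouts. This vignette is the package's account of the methods:
the models and their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic-data generators do and do
not emulate, and the numerical and design choices made where the
underlying conventions are genuinely open.

## The critical packing parameter

The critical packing parameter CPP = V/(a₀·l_c) condenses a lipid's
geometry into one number: < 1 means a cone (head wider than tail,
positive-curvature preference), ≈ 1 a cylinder (lamellar), > 1 an
inverted cone (tail wider than head, negative-curvature preference —
the regime associated with inverse-hexagonal phases and the membrane
fusion events thought to drive endosomal escape). The package computes
it two ways from the same trajectory.

**Volume-based (`compute_cpp_v`).** Head atoms are those at the
membrane–water interface (amine and linker groups for typical ionizable
lipids); the head radius is half the maximum pairwise distance between
head atoms in the membrane (xy) plane, the tail radius the same over
terminal tail atoms, and l_c the mean 3D distance from the head-group
centroid to each terminal tail atom. The lipid is modeled as a truncated
cone, V = (π·l_c/3)(r_h² + r_h·r_t + r_t²), so CPP_V reduces to
(r_h² + r_h·r_t + r_t²)/(3 r_h²) and l_c cancels — a useful analytic
oracle that the test suite exercises over a thousand random geometries.
The half-max-pairwise radius estimator is upward-biased under positional
noise (it is an extreme-value statistic), but the bias enters head and
tail symmetrically and largely cancels in the ratio; the parameter
recovery test quantifies the net effect at realistic noise.

Averaging order matters for the dispersion: CPP_V is averaged over frames
per lipid first, then pooled across lipids, and the reported dispersion
is the SEM over lipid means. CPP_V mixes an extreme-value radius
estimator with a ratio, so it fluctuates strongly across lipids and time
steps; the SEM isolates the uncertainty of its central tendency. The
across-lipid variance is also exported, since the spread of lipid shapes
is itself an informative feature. Lipid-frames whose head collapses to a
point (r_head = 0) are flagged degenerate and excluded from the mean but
counted, never silently dropped.

**Gyration-based (`compute_cpp_rg`).** Per lipid-frame the head and tail
centers of mass define an orientation vector v; the lipid is translated
so the head/tail midpoint is at the origin and rotated (Rodrigues
rotation) so v is parallel to ẑ, and the mass-weighted planar radius of
gyration Rg = √(Σ mᵢ(xᵢ² + yᵢ²)/M) is computed for head and tail subsets.
Per lipid, Rg values are averaged over frames first and
CPP_Rg = ⟨Rg_tail⟩/⟨Rg_head⟩ — the ratio of averaged gyration radii, not
the average of ratios — then pooled over lipids with SD dispersion.
Lipid-frames with ‖v‖ below 10⁻⁶ Å (coincident centers: a lipid folded
exactly in half, or a zero-length construction) have no defined
orientation and are skipped with a warning; a lipid with no usable frame
is excluded and counted. CPP_Rg is exactly invariant under rigid
rotation/translation of a lipid and under uniform mass rescaling, both
asserted to 10⁻⁹ in the tests.

**Shape classes (`classify_shape`).** "Close to 1" is not quantified by
any convention we know of; the cylinder band defaults to |CPP − 1| ≤ 0.05
and is a parameter, not a claim.

## Membrane descriptors

**Leaflets, recentering, periodic boundaries.** z is the membrane normal.
The bilayer midplane is the mass-weighted center of mass of all membrane
atoms, recomputed per frame; density profiles recenter each frame so that
midplane sits at z = 0, and a lipid is in the upper leaflet iff its
reference z (reference atom, else lipid center of mass) exceeds the
midplane. Before any per-lipid in-plane measurement, lipids are made
whole by minimum-image unwrapping about their first atom in x and y —
pairwise head distances are meaningless across a wrap. z is never
unwrapped: escapes along the normal are signal, not artifact.

**Thickness (`compute_thickness`).** d_B(t) is the difference between
the mean z of reference atoms in the upper and lower leaflets, averaged
over the analysis window. Phosphate references are preferred when
present; otherwise all flagged reference atoms are used (cholesterol has
no phosphate — its hydroxyl oxygen serves, and the synthetic lipids use
their head reference). The quantity is exactly translation invariant.

**Torque density (`compute_torque_density`).** The lateral pressure
profile enters as a precomputed (z, p_xx, p_yy, p_zz) table in 0.2 Å
slabs — computing the pressure tensor from forces is out of scope.
p_T = (p_xx + p_yy)/2 and, by default, p_N = p_zz, the normal component
of the pressure tensor. A convention that instead sets p_N = p_xx makes
p(z) = (p_yy − p_xx)/2, which vanishes identically for laterally
isotropic stress; it is retained behind `normal = "pxx"` for comparison
but is not the default, because a first moment of an identically-zero
integrand carries no information. Leaflet torques are first moments over
[0, L_z/2] and [−L_z/2, 0] by composite trapezoid on bin centers with the
z = 0 node added (its integrand is exactly zero). Two means are
reported: the literal (τ_up + τ_low)/2, which is identically zero for any
symmetric profile because the integrand z·p(z) is odd, and the
leaflet-oriented (τ_up − τ_low)/2, which equals τ_up on symmetric
profiles and is the convention under which a nonzero per-monolayer torque
is meaningful. Both are returned so the caller can state which one a
correlation uses. Quadrature error on the analytic test profiles is
within 0.5% at 0.2 Å bins.

**Area compressibility (`compute_area_compressibility`).**
K_A = k_B·T·⟨A⟩/⟨(A−⟨A⟩)²⟩ with the population (1/n) variance — the
formula is a moment of the fluctuation distribution, not an inferential
estimate. Inputs in Å², output in mN/m (the conversion collapses to
K_A[mN/m] = 1.380649·T·⟨A⟩/var(A) for Å² inputs). A constant series is a
degenerate-fluctuation error, not K_A = ∞. T defaults to 310 K, body
temperature, matching the simulation conditions the estimator targets.

**Stability screen (`classify_stability`).** Bilayers that fail to hold
their ionizable lipids are not analyzable for CPP and are themselves a
delivery-relevant label. No quantitative escape criterion is standard, so
the package defines one and exposes its parameters: a lipid has escaped
when its center of mass is farther than d_B/2 + margin from the midplane
for at least `persistence` consecutive analysis frames, with margin 10 Å
and persistence 5 by default — far enough that head-group protrusions and
single-frame excursions do not trigger it. Any single escaped ionizable
lipid marks the bilayer unstable.

**Analysis window (`select_analysis_frames`).** Production analyses use
the final portion of a trajectory at a fixed stride (e.g. every 1 ns over
the final 500 ns of a 1.5 µs run), counted back from and including the
last frame.

## Ionizable-lipid chemistry

SMILES parsing, canonicalization, and protonated-SMILES emission are
delegated to OpenBabel (via ChemmineOB); the classification and decision
logic is the package's own. All graph quantities are computed on the
heavy-atom graph with unit bond lengths, and atom indices refer to the
canonical atom order, which makes the decision tree invariant to how the
input SMILES was written.

Each nitrogen gets exactly one class. Excluded: amide and sulfonamide
nitrogens (N–C(=O), N–S(=O)), quaternary or already-charged nitrogens,
nitrogens with non-aromatic multiple bonds (imines, nitriles, nitro), and
pyrrole-type aromatic nitrogens, whose lone pair is part of the aromatic
sextet and which are not basic. Pyridine-type ring nitrogens are classed
`imidazole` in five-membered rings and `pyridine` otherwise; an exocyclic
nitrogen bonded to an aromatic atom is an aromatic amine of its
substitution level. The selection hierarchy runs tertiary > secondary >
primary amine > imidazole > pyridine > tertiary > secondary > primary
aromatic amine; ties within a class go to the greatest graph eccentricity
(the candidate nearest the molecular periphery, where the protonated head
of an ionizable lipid sits), or, under the `tail_amine_central` rule used
for tail-amine lipids in combinatorial libraries, to the lowest mean
squared graph distance (the most central candidate). Graph rather than
Euclidean distance keeps both rules deterministic and
conformer-independent. Any remaining tie falls to the lowest canonical
atom index, purely for reproducibility.

One deliberate deviation from a literal reading of the single-nitrogen
shortcut: a molecule whose only nitrogen is excluded (an amide, say)
selects nothing rather than protonating it. Protonating an amide nitrogen
would contradict the exclusion rule's own chemistry, and the exclusion
invariant — no output ever protonates an amide, sulfonamide or quaternary
nitrogen — is asserted in the test suite over a randomized fixture sweep.

## Delivery-readout standardization

Raw delivery readouts are not comparable across screens: scales, assays,
and units differ between publications and between in vitro and in vivo
arms of the same study. Each (publication, delivery-context) group is
z-scored to mean 0 and standard deviation 1, with the sample (n−1) sd —
groups are small screens, and the choice is fixed and documented rather
than consequential. When the positive raw values of a group span at
least two orders of magnitude (max/min ≥ 100, the `log_trigger_ratio`
default; "several orders of magnitude" names no exact threshold, so this
is a configurable decision, not a fact), log10 is applied first so that
a z-score does not reduce the readout to its single largest value.
Constant groups are an error, not a silent zero. Standardization is
idempotent and invariant to positive affine rescaling of the raw values,
both asserted as properties.

## The synthetic-data generators

The generators exist so every estimator can be tested against analytic
ground truth without molecular dynamics. A synthetic lipid is a rigid
pseudo-atom construction: an even number of head atoms equally spaced on
a circle of radius r_h at the interface and terminal-tail atoms on a
circle of radius r_t at depth l, leaflets mirrored about z = 0, i.i.d.
Gaussian positional noise per atom per frame. Even counts place
antipodal pairs on each circle, so the half-max-pairwise radius estimator
is exact at zero noise; equal-mass atoms on a circle make the planar
gyration radius equal the circle radius, so CPP_Rg ground truth is
r_t/r_h and CPP_V ground truth is the reduced truncated-cone form. Escape
events are persistent z-offsets applied from a start frame onward —
the observable consequence of an escape, without kinetics.

Defaults emulate the conditions of an all-atom bilayer production
analysis: about 100 lipids per leaflet, frames every 1 ns, sub-angstrom
(0.1 Å) positional noise, cylindrical lipids of length 20 Å unless the
caller prescribes a cone. The delivery generator draws bivariate-normal
(feature, delivery) pairs with prescribed population correlation and
round-robin stratum labels. Every generator is a pure function of its
spec including the seed.

What they do **not** emulate — and therefore what passing tests do and do
not show: no internal conformational dynamics (lipids are rigid up to
noise, so l_c has no fluctuation structure), no head/tail asymmetry in
noise, no correlated fluctuations between lipids or frames, no
electrostatics (protonated vs neutral is a topology label only), no
undulations, no solvent. Tests against these fixtures validate the
estimators' correctness and calibration, not the biophysical fidelity of
any particular simulation.

## Test problem sizes

The suite's simulation scales are chosen as the smallest sizes at which
the asserted tolerances are comfortably non-marginal: parameter recovery
uses 50 lipids × 100 frames at 0.1 Å noise (CPP_V within 2%, CPP_Rg
within 5% of truth), K_A recovery a 5 000-point area series (within 5%),
statistical calibration 2 000 null replicates at n = 34 (rejection rate
in [0.03, 0.07] at α = 0.05) and 500 replicates at ρ = 0.7 (mean r within
0.05), and rigid-motion invariance 100 random rotations/translations at
10⁻⁹. Headline correlations from microsecond all-atom simulations of
dozens of bilayers are not desk-reproducible and are out of scope.

## Known limitations

- The CPP head/tail split is taken from the topology table; the package
  does not infer which atoms are interfacial.
- Terminal tail atoms are auto-flagged as the last tail atom per lipid
  when a topology CSV carries no flag — topology tables have no bond
  list, so chain termini cannot be found by connectivity. Flag them
  explicitly for branched tails.
- Ring-nitrogen classes beyond imidazole/pyridine (fused heteroaromatics,
  other azoles) fall to the `pyridine` class; no pKa prediction or
  multi-protonation states.
- Pressure profiles are inputs; the package never computes a virial.
- The rank-sum test is the default two-group comparison for independent
  stable/unstable groups; a paired signed-rank variant is available when
  a pairing exists, and the report names the test used.
- p-values are reported without multiple-testing correction by default,
  matching screening-stage practice; correct downstream when testing
  many features.
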