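---
title: "Structure-based pharmacophore screening with phorescreen: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based pharmacophore screening with phorescreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phorescreen)
```

## The problem

Protein-protein interfaces such as the CD147 dimerization interface are
shallow, polar, and poorly served by classical docking, but they can be
screened with a *structure-based pharmacophore*: an abstract 3D arrangement
of interaction features (hydrogen-bond donor, acceptor, hydrophobic) derived
from the protein's own chemistry, against which a compound library is
matched geometrically. phorescreen implements that cascade end to end —
interaction-map generation, hypothesis enumeration, feature matching and
superposition, pose energetics, funnel cuts and diversity selection — plus
the downstream experimental triage arithmetic (SPR response-unit and
MMP-2-inhibition thresholds, densitometry ratios, IC50 regression). The
crystal structure input is a user-supplied PDB file; every stage is equally
usable with the package's synthetic generators, so the whole pipeline is
testable offline.

## The interaction map

Site perception is a fixed rule table applied per residue, defined entirely
on heavy atoms so unprotonated crystal structures work:

* backbone N is a donor; its direction is N→H when an amide hydrogen is
  present and otherwise the idealized direction from N toward `2·CA − C`;
* backbone O is an acceptor with direction C→O;
* side chains follow standard hydrogen-bond chemistry: Ser/Thr/Tyr
  hydroxyls are both donor and acceptor; Lys NZ and Arg NE/NH1/NH2 are
  donors; Asp OD1/OD2 and Glu OE1/OE2 are acceptors (directions from the
  carboxylate carbon); Asn/Gln have a donor N and an acceptor O; His ring
  nitrogens carry both roles; Trp NE1 is a donor;
* Ala/Val/Leu/Ile/Phe/Met/Pro/Trp contribute one hydrophobic site at the
  centroid of their apolar side-chain carbons.

Unknown residue names contribute backbone sites only. Complementary
*ligand-side* features are projected into the pocket: a protein donor
projects an acceptor feature `d_hb = 2.9` Å along the donor direction (the
canonical heavy-atom hydrogen-bond length), a protein acceptor projects a
donor likewise, and a hydrophobic site projects a hydrophobic feature
`d_hp = 4.0` Å toward the pocket center. Features landing outside the
pocket sphere or within `clash_dist = 1.5` Å of a protein heavy atom are
discarded. Every protein heavy atom within the pocket radius plus a 2 Å
margin becomes an exclusion sphere of radius `r_excl = 1.4` Å — small
enough not to over-constrain the pocket, large enough to forbid
ligand-atom/protein-atom overlap. All of these are config-exposed; the
defaults are literature norms, since the source workflow names the feature
kinds but not its rules.

## Clustering and hypotheses

Projected features are condensed by complete-linkage agglomerative
clustering (cutoff 1.5 Å, one pharmacophore-tolerance radius), separately
per kind — kinds never merge. Each cluster is replaced by one feature at
the arithmetic-mean position with the renormalized mean direction, the
summed weight (so total weight is conserved), the mean tolerance, and the
union of residue provenance. Complete linkage bounds the cluster diameter,
which keeps the averaged center representative of its members. One
subtlety: averaging can bring two replacement centers within the cutoff of
each other, so a single linkage pass is not idempotent; phorescreen
therefore repeats passes until no merge occurs, making `cluster_features()`
a fixed point of itself.

Hypotheses are all subsets of 3–7 clustered features whose pairwise
distances are at least `min_pair_dist = 2` Å (preventing degenerate
near-duplicate queries), identified by their sorted feature indices and
enumerated in lexicographic order. How many features the original CD147
model had, or its clustering cutoff, is not recoverable; the defaults here
are declared, not inferred.

## Matching, fit and the funnel

A ligand matches a hypothesis through an injective, kind-compatible
assignment of its perceived features that survives the pairwise prune
`|d_lig(i,j) − d_hyp(i,j)| ≤ t_i + t_j`. Each assignment is realized in 3D
by Kabsch least-squares superposition of the matched feature points
(proper rotation only — reflections are never produced), the transformed
pose is rejected if any heavy atom falls strictly inside an exclusion
sphere (a point exactly on the surface passes), and scored with the
quadratic-falloff fit value `Σ w_i max(0, 1 − (d_i/t_i)²)`. This is a
Catalyst-style analog chosen because the commercial "fitting value" is
proprietary; it shares its qualitative behaviour (maximal at perfect
superposition, zero contribution at the tolerance) without claiming
numeric equivalence.

Ligand features follow medicinal-chemistry conventions: donors are O/N
bearing a hydrogen; acceptors are any O plus N with a free lone pair (not
quaternary, not amide-delocalized; aromatic N only without H — so a phenol
ring is simultaneously a hydrophobic ring, a donor and an acceptor, which
is exactly how AC-73 engages the interface glutamates); hydrophobic
features are carbocyclic ring centroids and centroids of acyclic runs of
three or more apolar carbons.

The funnel mirrors the published cascade — property filter (MW ≤ 500,
logP ≤ 5, logS ≥ −6 by default; the published thresholds are not printed,
only the funnel structure), best fit per compound, top-N by fit, rigid
in-situ minimization with energy re-ranking, top-N by energy, then leader
diversity selection. The published sizes were 5000 → 1000 → 100 from a
300k library; the desk-scale default is 20 → 10 → 5 on synthetic libraries
of 50. Ranking ties are always broken by compound id, so reruns are
byte-identical.

## The energy model

Pose energetics use an open, transparent analog of the proprietary scoring
functions: a Lennard-Jones 12-6 term with Lorentz-Berthelot combining over
a per-element parameter table, plus Coulomb electrostatics with the
distance-dependent dielectric ε(r) = 4r (a standard implicit-solvent
screening choice for pocket scoring), over all ligand-protein atom pairs
within 10 Å. Hydrogen uses a polar-hydrogen-like σ of 1.2 Å, as in
mainstream force fields, so that hydrogen-bond geometry (donor H ≈ 1.9 Å
from the acceptor) is not penalized sterically; the cost is that C–H
sterics are under-represented, which heavy-atom packing terms dominate
anyway. Partial charges are a simple documented increment scheme (version
pq-0.1): polar-group increments on O/N/S, their hydrogens and adjacent
carbons, resname-aware increments for protein side chains, with formal
charges spread half on the atom and half over its neighbours. **These
energies are not comparable with the published per-residue or binding-energy
values**, which come from closed commercial functions; the package instead
guarantees structural identities — the decomposition sums exactly to the
shell total, the pair term has its closed-form minimum of −ε at
r = 2^(1/6)σ, and energies are invariant under joint rigid motion — and the
qualitative behaviour that a residue placed to hydrogen-bond the ligand
dominates the decomposition, as the interface glutamate does in the
published per-residue table.

In-situ minimization is rigid-body only (3 translations + 3 rotations about
the ligand centroid), a greedy coordinate descent with a halving step
schedule (0.25 Å / 0.1 rad initial, terminating below 0.01 Å in the
pipeline). It is deterministic, its energy trace is non-increasing by
construction, and it performs the same role as the published "in situ
ligand minimization" of a docked pose; it does not relax torsions.

Hydrogen bonds are geometric: donor-heavy-atom to acceptor distance
≤ 3.5 Å and, when the donor carries an explicit hydrogen, a D-H···A angle
≥ 120°; both directions across the interface are reported. Protein donors
are assessed on distance only when the structure is unprotonated.

## Triage and dose-response

The experimental thresholds are applied exactly as printed: strict
RU > 20 for SPR binding and strict inhibition > 30% for MMP-2 suppression,
with the inhibition ratio defined as
`(1 − gray_treatment/gray_control) × 100%`. `triage_hits()` returns both
hit lists and their intersection and leaves any union policy to the caller,
because the published candidate table mixes compounds from both arms
without stating one.

IC50 comes from a four-parameter logistic fit,
`y = bottom + (top − bottom)/(1 + (x/ic50)^hill)`, by raw
Levenberg-Marquardt from the fixed initialization bottom = min(y),
top = max(y), hill = 1, ic50 = geometric-mean dose. The raw `nls.lm`
driver is used deliberately: the `nls`-object wrappers reject
zero-residual (noiseless) data, which the round-trip tests require. ic50
is log-parameterized so it stays positive, and a fit with bottom > top is
normalized by swapping them and negating the hill (the curve is
unchanged). Constant responses return an unconverged flat fit rather than
an error. The exact options of the original graphing software are unknown;
the model and initialization here are fixed and documented instead.

## What the synthetic generators emulate — and what they do not

`make_toy_pocket()` builds a 12-residue ring whose idealized side chains
point inward, lining a cleft of roughly 6.5 Å radius: two glutamates
(numbered 64 and 73, echoing the CD147 interface residues), Ser/Thr/Asn/Lys
donors, and Val/Leu/Ala/Met/Phe hydrophobics, with a seeded ±0.15 Å jitter.
It is a geometric test pocket, not a physical fold: bond lengths are
approximate, there is no secondary structure, and backbone connectivity
between residues is not modelled. `make_planted_library()` builds actives
whose perceived features cover a given hypothesis exactly (amine N-H for
donors, carbonyl O for acceptors, cyclopropane centroids for hydrophobics,
with one feature displaced by exactly the requested amount and hydrogens
oriented along the feature direction), varying linker lengths and a
decorating substituent so fingerprints distinguish them; decoys either omit
every group of one required kind — with substitutions chosen so no side
chemistry re-expresses the dropped kind (carbonyls never donate; a
protonated amine never accepts; placeholder carbons are never acceptors) —
or scale the geometry until every feature pair violates the match
tolerance. Consequently a passing enrichment test shows the funnel's
machinery is correct, not that it would enrich actives against
property-matched decoys on a real target: synthetic decoys are
constructions with known defects, real decoys are not.

`make_screen_table()` plants exact counts above strict thresholds with a
2 RU / 3-percentage-point margin, emulating the structure of the primary
screen (100 compounds, 5 RU hits, 7 inhibition hits, 1 overlap) without
modelling SPR kinetics or assay artifacts. `make_dose_response()` draws
Gaussian noise around an exact 4PL curve; the default dose design is the
standard 8-point half-log dilution series bracketing the IC50, and a
`replicates` argument repeats the design as replicate measurements.

On the dose-response recovery calibration: with all four parameters free,
a Cramér-Rao analysis of an 8-dose single-replicate design at noise σ = 5
on a 100-unit range bounds the achievable median |log(ic50 error)| near
0.14–0.19 regardless of dose spacing, so a calibration target of 0.07
requires replication. The package therefore calibrates recovery under the
assay design the original screen actually used — triplicate measurements of
three independent experiments, i.e. nine replicate responses per dose —
where the information bound is comfortably below the target. The
acceptance suite runs that design over 100 seeds.

## Numerical choices and determinism

* All ties are broken lexicographically by id or index; reruns of any stage
  are byte-identical, and generators are pure functions of their seed.
* Atom weights are IUPAC standard values at 4 decimals (table paw-2021);
  the logP table (plogp-0.1) and the ESOL-style logS coefficients
  (0.16 − 0.63·logP − 0.0062·MW + 0.066·RB − 0.74·AP) are versioned in the
  source.
* PDB parsing keeps the first model and alternate location 'A' or blank,
  skips waters, reads elements from columns 77–78 with atom-name fallback,
  and reports unparseable coordinate fields by line number. Residue
  numbering is taken verbatim from the file.
* Interaction maps serialize to JSON at 6-decimal precision and round-trip
  exactly at that precision.
* Boundary rules are explicit everywhere: pocket selection and property
  filters are inclusive; exclusion volumes use a strict interior; triage
  thresholds are strict, exactly as printed.
* Desk-scale problem sizes throughout the tests (12-residue pockets,
  50-compound libraries, funnel 20 → 10 → 5) keep the full suite and the
  acceptance script fast while exercising every stage.

## Limitations

* Fit values and energies are open analogs; no numeric agreement with
  commercial "fitting values", binding energies, or per-residue scores is
  claimed or attainable.
* Matching is rigid over supplied conformers — no on-the-fly flexing, no
  tautomer or protonation-state enumeration, and no stereochemistry-aware
  matching (AC-73's chiral centre is screened as drawn).
* The site rule table omits aromatic-stacking and charged-center feature
  kinds and water-mediated interactions; the energy model omits solvation
  and entropy and keeps protein side chains fixed.
* mmCIF, multi-model NMR ensembles, symmetry mates and assemblies are out
  of scope for the PDB reader.
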