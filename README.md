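# phorescreen

A desk-scale, fully scriptable re-implementation of the structure-based
pharmacophore screening cascade used to find small-molecule inhibitors of
protein-protein interfaces — the workflow that produced AC-73, the first
small-molecule inhibitor of CD147 dimerization — together with the
experimental hit-triage arithmetic that follows the computational funnel.
It is written for computational chemists and method developers who want an
open, deterministic, testable version of a pipeline that normally lives
inside commercial modeling suites.

## What it computes

**Interaction map.** From a protein structure (PDB) and an active-site
sphere, every pocket residue contributes hydrogen-bond donor, acceptor and
hydrophobic sites by a fixed rule table (backbone N/O; side-chain hydroxyls,
amines, carboxylates; apolar side-chain centroids). Each protein site
projects a *complementary* ligand feature into the pocket — a donor site
places an acceptor feature 2.9 Å along its idealized H direction, an
acceptor places a donor, a hydrophobic patch places a hydrophobic feature
4 Å inward — and every protein heavy atom near the pocket becomes a
forbidden exclusion sphere. Features are condensed by complete-linkage
clustering (iterated to a fixed point) and subsets of 3–7 features become
query pharmacophore hypotheses.

**Screening.** Ligands (SMILES/SDF; MW, logP, logS estimated by documented
additive schemes) are matched to each hypothesis by enumerating injective,
kind-compatible feature assignments under a pairwise distance-compatibility
prune, rigidly superposed by Kabsch least squares, checked against the
exclusion volumes, and scored with a quadratic-falloff fit value

    fit = Σᵢ wᵢ · max(0, 1 − (dᵢ/tᵢ)²)

(maximal when every matched ligand feature sits exactly on its hypothesis
feature of tolerance tᵢ). The funnel then mirrors the published cascade at
desk scale: top-N by fit → rigid-body in-situ minimization under an open
Lennard-Jones + Coulomb energy model (distance-dependent dielectric
ε(r) = 4r) → top-N by energy → leader-algorithm diversity selection on
hashed path fingerprints. The best pose gets a per-residue energy
decomposition over a 10 Å shell and a geometric hydrogen-bond report.

**Triage.** Experimental readouts are triaged exactly as in the published
screen: SPR response units with the strict threshold RU > 20, MMP-2
secretion inhibition ratio `(1 − gray_treatment/gray_control) × 100%` with
the strict threshold > 30%, and their intersection; densitometry dimer
fractions; and IC50 by four-parameter-logistic nonlinear regression
`y = bottom + (top − bottom)/(1 + (x/IC50)^hill)`.

**Synthetic data.** Deterministic generators build everything the pipeline
needs offline: a 12-residue toy pocket (with glutamates numbered 64 and 73,
echoing the CD147 dimer-interface residues) plus a ground-truth site
manifest, ligand libraries with actives planted onto a hypothesis and
kind-deficient / geometry-violating decoys, screen tables with planted hit
counts, and 4PL curves with known parameters.

## Worked example

```r
library(phorescreen)

# a deterministic toy pocket and its interaction map
pocket  <- make_toy_pocket(seed = 1)
protein <- parse_pdb(pocket$pdb, id = "toy-pocket")
sphere  <- pocket_sphere(pocket$center, pocket$radius)
pmap    <- interaction_map(protein, sphere)
pmap
#> <interaction_map> 15 features (6 acceptor, 4 donor, 5 hydrophobic), 55 exclusion spheres

# pick a 3-feature hypothesis with one feature of each kind
hyps <- enumerate_hypotheses(pmap$features, kmin = 3, kmax = 3, min_pair_dist = 3.5)
hyp  <- hyps$features[[which(sapply(hyps$features,
          function(f) length(unique(f$kind)) == 3))[1]]]

# a 50-compound library with 5 planted actives and 45 decoys, then the funnel
lib <- make_planted_library(hyp, n_active = 5, n_decoy = 45,
                            displacement = 0.5, seed = 1, avoid = pmap$exclusions)
run <- run_screen(lib$ligands, protein, sphere, hypotheses = hyp,
                  config = screen_config(top_fit = 20, top_energy = 10, n_final = 5))
run
#> <screen_run>
#>   library          50
#>   property_filter  50
#>   matched          5
#>   top_fit          5
#>   top_energy       5
#>   diverse          5
#>   top hit: ACT-004 (energy -8.807 kcal/mol, 1 H-bond(s))
```

Only the five actives survive matching (every decoy is missing a feature
kind or violates the hypothesis geometry), and all five reach the final
set. The per-residue decomposition of the top pose puts the hydrogen-bonded
glutamate first:

```r
head(run$top_hit$pose_score$per_residue[, c("residue", "energy")], 3)
#>   residue energy
#> 1 Glu64   -2.79
#> 2 Gly63   -1.03
#> 3 Ala66   -1.02
```

Triage of the five experimentally characterized candidate compounds from
the CD147 screen isolates AC-73 as the only compound passing both strict
thresholds, and AC-73 itself is rebuilt from its SMILES:

```r
triage_hits(cd147_candidates())
#> <triage_result> 5 records: 3 with RU > 20, 3 with inhibition > 30%, 1 in both
#>   intersection: AN-465/42834501

lig <- parse_smiles(ac73_smiles(), id = "AC-73")
lig
#> <ligand 'AC-73'> C21H21NO2, 45 atoms (24 heavy), 47 bonds, 1 conformer(s)
mol_weight(lig)
#> [1] 319.404    # printed library value: 319.36942 (0.011% apart)

fit <- fit_4pl(make_dose_response(bottom = 0, top = 100, hill = 1, ic50 = 10,
                                  replicates = 3, noise_sd = 5, seed = 2))
glance(fit)
#>    ic50  hill bottom   top   rss     n converged
#> 1  9.71  1.07   2.32  102.  767.    24 TRUE
```

`autoplot()` methods draw the funnel (`screen_run`), the RU/inhibition
scatter with thresholds (`triage_result`) and fitted dose-response curves
(`dose_response_fit`).

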