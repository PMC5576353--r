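# cgfold

Contact-guided coarse-grained protein structure reconstruction in R.

Residue–residue contacts are the workhorse of template-free protein
structure prediction: if the set of residue pairs whose Cβ atoms lie
within 8 Å of each other is known (or predicted), how accurately can the
three-dimensional fold be rebuilt — and what additional information
helps? `cgfold` implements a complete, tested pipeline for studying this
question at Cα/Cβ resolution:

* **Contact maps** — derive true contacts from a structure at any
  distance threshold *t* (contact ⇔ d(Cβᵢ, Cβⱼ) < *t*, Cα for glycine),
  classify pairs by sequence separation (local < 6, short 6–11, medium
  12–23, long ≥ 24), take exact non-contact complements, and read/write
  ranked predictions in the CASP RR format.
* **Restraints** — translate contacts into flat-bottom distance
  restraints (3.5 Å to *t* between Cβ atoms), non-contacts into
  repulsive restraints (*t*+2 Å to 200 Å), and 3-state secondary
  structure into Cα distance, hydrogen-bond-proxy and pseudo-dihedral
  restraints whose targets are measured from ideal helix/strand
  generators.
* **Reconstruction engine** — triangle-inequality bound smoothing,
  randomized metric embedding, gradient minimization of the soft-square
  penalty (compiled with Rcpp), mirror-image resolution via helix
  pseudo-dihedral handedness, and the two-stage protocol in which
  restraints grossly violated by the stage-1 best model are dropped
  before re-refinement.
* **Evaluation** — optimal-superposition RMSD (Kabsch, proper rotations
  only), TM-score with the standard d0 = 1.24·(L−15)^⅓ − 1.8
  normalization, GDT-TS on the 0–100 scale, and best-of-N selection.
* **Synthetic benchmarks** — deterministic generators for ideal helices,
  β-hairpins, up/down helix bundles and compact mixed folds, plus an
  emulator of noisy ranked contact predictions (controlled top-L
  precision, low-confidence decoy tail), so every experiment runs
  without downloading a single structure.
* **Experiments** — a condition runner that sweeps thresholds (8–20 Å),
  sequence-separation filters (0, 3, …, 51), secondary-structure and
  non-contact toggles, and top-xL selections (x = 0.1 … 4), with paired
  t-test comparisons and helix-content correlation reports.

## Worked example

Reconstruct a three-helix bundle from its own contacts, with and without
secondary structure:

```r
library(cgfold)

native <- make_helix_bundle(3, 18)        # 61 residues, ss3 known
map    <- derive_contact_map(native, t = 8, min_sep = 6)
map
#> contact_map bundle : L = 61 , 77 pairs, t = 8 A, min_sep = 6

set <- combine_restraints(
  contacts_to_restraints(map, native$sequence),
  chain_restraints(chain_length(native)),
  ss_to_restraints(native$ss3))

restraint_energy(native, set)$distance    # the native satisfies its own
#> [1] 0                                   # restraints exactly

ens  <- reconstruct_ensemble(set, n_models = 20, base_seed = 42,
                             sequence = native$sequence, ss3 = native$ss3)
best <- best_of_n(ens, native, metric = "tm")
round(unlist(best$eval[c("tm", "rmsd", "gdt_ts")]), 2)
#>     tm   rmsd gdt_ts
#>   0.86   1.42  91.39
```

The best of 20 models rebuilds the bundle to 1.4 Å; dropping the
`ss_to_restraints()` term and repeating collapses the TM-score to 0.24,
because contacts at separation ≥ 6 carry no information about helix
geometry — the central observation that motivates pairing contacts with
secondary-structure restraints. Adding
`noncontacts_to_restraints(derive_noncontacts(map, native), 8, 61)`
recovers much of that gap.

Batch experiments over a benchmark:

```r
targets <- make_benchmark(101)            # 10 targets, 60-150 residues
rows_c  <- run_condition(targets, experiment_condition(min_sep = 6), base_seed = 50)
rows_ss <- run_condition(targets, experiment_condition(min_sep = 6, use_ss = TRUE), base_seed = 50)
compare_conditions(rows_c, rows_ss)[c("mean_delta_tm", "frac_improved_or_equal", "p_value")]
#> $mean_delta_tm
#> [1] 0.2404
#> $frac_improved_or_equal
#> [1] 0.9
#> $p_value
#> [1] 0.01035
```

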