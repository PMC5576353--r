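# Reconstruction engine: bound smoothing, determinism, chirality,
# two-stage refinement, parameter recovery on a small target.

test_that("triangle smoothing tightens upper bounds and chains bonds", {
  set3 <- restraint_set("t", 3, distance = rbind(
    data.frame(i = 1, j = 2, atom_i = "CA", atom_j = "CA", lower = 3.5,
               upper = 4, weight = 1, tag = "contact"),
    data.frame(i = 2, j = 3, atom_i = "CA", atom_j = "CA", lower = 3.5,
               upper = 4, weight = 1, tag = "contact")))
  b <- build_smoothed_bounds(3, set3)
  expect_lte(b$upper[1, 3], 8)
  b10 <- build_smoothed_bounds(10, chain_restraints(10))
  expect_lte(b10$upper[1, 10], 9 * 3.9)
  expect_gte(b10$lower[1, 10], 0)
  expect_true(all(b10$lower <= b10$upper))
})

test_that("contradictory restraints raise an infeasibility error", {
  bad <- restraint_set("t", 4, distance = rbind(
    data.frame(i = 1, j = 2, atom_i = "CA", atom_j = "CA", lower = 0.5,
               upper = 3, weight = 1, tag = "contact"),
    data.frame(i = 1, j = 2, atom_i = "CA", atom_j = "CA", lower = 5,
               upper = 10, weight = 1, tag = "contact")))
  expect_error(build_smoothed_bounds(4, bad), "infeasible")
})

test_that("reconstruction is bit-identical for identical base seeds", {
  st <- make_helix_bundle(3, 10)
  L <- chain_length(st)
  map <- derive_contact_map(st, 8, 1)
  set <- combine_restraints(contacts_to_restraints(map, st$sequence),
                            chain_restraints(L), ss_to_restraints(st$ss3))
  ctrl <- engine_control(n_hops = 2)
  e1 <- reconstruct_ensemble(set, n_models = 3, base_seed = 11,
                             sequence = st$sequence, ss3 = st$ss3,
                             control = ctrl)
  e2 <- reconstruct_ensemble(set, n_models = 3, base_seed = 11,
                             sequence = st$sequence, ss3 = st$ss3,
                             control = ctrl)
  for (k in 1:3) {
    expect_identical(e1$models[[k]]$ca, e2$models[[k]]$ca)
    expect_identical(e1$models[[k]]$energy, e2$models[[k]]$energy)
  }
  seeds <- vapply(e1$models, `[[`, numeric(1), "seed")
  expect_equal(length(unique(seeds)), 3)  # unique seeds
  energies <- vapply(e1$models, `[[`, numeric(1), "energy")
  expect_true(all(diff(energies) >= 0))  # sorted ascending
})

test_that("model energy equals restraint_energy recomputed on its
           coordinates", {
  st <- make_helix_bundle(3, 10)
  map <- derive_contact_map(st, 8, 1)
  set <- combine_restraints(contacts_to_restraints(map, st$sequence),
                            chain_restraints(chain_length(st)),
                            ss_to_restraints(st$ss3))
  ens <- reconstruct_ensemble(set, n_models = 2, base_seed = 3,
                              sequence = st$sequence, ss3 = st$ss3,
                              control = engine_control(n_hops = 2))
  for (m in ens$models) {
    expect_equal(m$energy, restraint_energy(m, ens_set <- combine_restraints(
      set, chain_restraints(set$L)))$distance, tolerance = 1e-9)
  }
})

test_that("small parameter recovery: a compact target is reconstructed
           from its own full map plus secondary structure", {
  st <- make_helix_bundle(3, 12)
  L <- chain_length(st)
  map <- derive_contact_map(st, 8, 1)
  set <- combine_restraints(contacts_to_restraints(map, st$sequence),
                            chain_restraints(L), ss_to_restraints(st$ss3))
  ens <- reconstruct_ensemble(set, n_models = 8, base_seed = 5,
                              sequence = st$sequence, ss3 = st$ss3)
  best <- best_of_n(ens, st, "rmsd")
  expect_lt(best$eval$rmsd, 3.0)
  expect_lt(min(vapply(ens$models, `[[`, numeric(1), "energy")), 0.5)
})

test_that("an unconstrained chain satisfies bonds but not the fold", {
  st <- make_helix_bundle(3, 10)
  L <- chain_length(st)
  set <- chain_restraints(L)
  ens <- reconstruct_ensemble(set, n_models = 3, base_seed = 2,
                              sequence = st$sequence,
                              control = engine_control(n_hops = 2))
  for (m in ens$models) {
    e <- restraint_energy(m, set, tags = "chain")
    expect_lt(e$distance, 0.1)
    expect_lt(tm_score(m, st)$tm, 0.5)
  }
})

test_that("fix_chirality reflects left-handed models and leaves
           right-handed or signal-free models alone", {
  h <- make_ideal_helix(20)
  m_ok <- structure(list(ca = h$ca, cb = h$cb, seed = 1, stage = 1L,
                         energy = 0), class = "cg_model")
  out <- fix_chirality(m_ok, ss3 = h$ss3)
  expect_identical(out$ca, m_ok$ca)
  mir <- h$ca; mir[, 3] <- -mir[, 3]
  expect_lt(mean(pseudo_dihedrals(mir)), 0)
  m_bad <- structure(list(ca = mir, cb = NULL, seed = 1, stage = 1L,
                          energy = 0), class = "cg_model")
  fixed <- fix_chirality(m_bad, ss3 = h$ss3)
  th <- pseudo_dihedrals(fixed$ca)
  expect_gt(mean(th), 0)
  # all-coil model: warning, unchanged
  set.seed(8)
  coil <- matrix(cumsum(rnorm(45)), 15, 3)
  m_coil <- structure(list(ca = coil, cb = NULL, seed = 1, stage = 1L,
                           energy = 0), class = "cg_model")
  expect_warning(same <- fix_chirality(m_coil, ss3 = strrep("C", 15)),
                 "no helical signal")
  expect_identical(same$ca, coil)
})

test_that("stage 2 drops poisoned contact restraints and refines", {
  st <- make_helix_bundle(3, 10)
  L <- chain_length(st)
  map <- derive_contact_map(st, 8, 1)
  good <- combine_restraints(contacts_to_restraints(map, st$sequence),
                             chain_restraints(L),
                             ss_to_restraints(st$ss3))
  ctrl <- engine_control(n_hops = 2)
  e1 <- reconstruct_ensemble(good, n_models = 4, base_seed = 9,
                             sequence = st$sequence, ss3 = st$ss3,
                             control = ctrl)
  e2 <- stage2_refine(e1, good, base_seed = 9, control = ctrl,
                      ss3 = st$ss3)
  expect_equal(attr(e2, "dropped"), 0)  # all satisfiable: nothing dropped
  expect_lte(e2$models[[1]]$energy, e1$models[[1]]$energy + 1e-6)
  # poison: a false end-to-end contact on a straight helix, feasible
  # under bound smoothing but geometrically frustrated (the rigid helix
  # restraint network cannot close the ends without violating many
  # secondary-structure terms, so the single false contact stays
  # violated and is dropped at stage 2)
  hx <- make_ideal_helix(30)
  Lh <- chain_length(hx)
  hx_set <- combine_restraints(
    contacts_to_restraints(derive_contact_map(hx, 8, 1), hx$sequence),
    chain_restraints(Lh), ss_to_restraints(hx$ss3))
  poison <- hx_set
  poison$distance <- rbind(poison$distance, data.frame(
    i = 1, j = Lh, atom_i = "CB", atom_j = "CB", lower = 3.5, upper = 8,
    weight = 1, tag = "contact"))
  p1 <- reconstruct_ensemble(poison, n_models = 4, base_seed = 9,
                             sequence = hx$sequence, ss3 = hx$ss3,
                             control = ctrl)
  p2 <- stage2_refine(p1, poison, violation_cut = 0.5, base_seed = 9,
                      control = ctrl, ss3 = hx$ss3)
  expect_gte(attr(p2, "dropped"), 1)
  b1 <- best_of_n(p1, hx, "rmsd")$eval$rmsd
  b2 <- best_of_n(pool_ensembles(p1, p2), hx, "rmsd")$eval$rmsd
  expect_lte(b2, b1 + 1e-9)
})

test_that("ensembles serialize to multi-MODEL PDB and a manifest", {
  st <- make_ideal_helix(12)
  set <- combine_restraints(
    contacts_to_restraints(derive_contact_map(st, 8, 1), st$sequence),
    chain_restraints(12))
  ens <- reconstruct_ensemble(set, n_models = 2, base_seed = 1,
                              sequence = st$sequence,
                              control = engine_control(n_hops = 1))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble_pdb(ens, path)
  txt <- readLines(path)
  expect_equal(sum(grepl("^MODEL", txt)), 2)
  m1 <- read_pdb(path, model_index = 1)
  expect_equal(chain_length(m1), 12)
  mf <- ensemble_manifest(ens)
  expect_equal(nrow(mf), 2)
  expect_true(all(c("seed", "stage", "energy") %in% names(mf)))
})
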