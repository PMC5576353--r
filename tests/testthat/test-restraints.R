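# Restraint translation and the restraint-violation energy.

test_that("contact restraints carry the 3.5-to-t band on C-beta atoms
           (C-alpha for glycine)", {
  st <- random_chain(30, seed = 60)
  seq1 <- strsplit(st$sequence, "")[[1]]
  map <- derive_contact_map(st, 8, 6)
  rs <- contacts_to_restraints(map, st$sequence)
  expect_true(all(rs$distance$upper == 8))
  expect_true(all(rs$distance$lower <= 3.5))
  expect_true(all(rs$distance$tag == "contact"))
  gly_i <- rs$distance$i[seq1[rs$distance$i] == "G"]
  if (length(gly_i)) {
    expect_true(all(rs$distance$atom_i[seq1[rs$distance$i] == "G"] == "CA"))
  }
  expect_true(all(rs$distance$atom_i[seq1[rs$distance$i] != "G"] == "CB"))
  # parameterized upper bound at t = 12
  rs12 <- contacts_to_restraints(derive_contact_map(st, 12, 6), st$sequence)
  expect_true(all(rs12$distance$upper == 12))
})

test_that("non-contact restraints use [t + 2, 200] and honour the
           buffer-zone exclusion for true pairs", {
  pairs <- data.frame(i = c(1, 2, 3), j = c(50, 40, 30),
                      distance = c(25, 9.5, 11))
  rs <- noncontacts_to_restraints(pairs, t = 8, L = 60)
  # the pair at 9.5 A sits inside [8, 10) and is excluded
  expect_equal(nrow(rs$distance), 2)
  expect_true(all(rs$distance$lower == 10))
  expect_true(all(rs$distance$upper == 200))
  rs12 <- noncontacts_to_restraints(data.frame(i = 1, j = 50), t = 12,
                                    L = 60)
  expect_equal(rs12$distance$lower, 14)
  empty <- noncontacts_to_restraints(data.frame(i = integer(0),
                                                j = integer(0)),
                                     t = 8, L = 60)
  expect_equal(nrow(empty$distance), 0)
  expect_error(noncontacts_to_restraints(pairs, t = 6, L = 60))
})

test_that("secondary-structure restraints reproduce the ideal helix and
           strand geometry", {
  empty <- ss_to_restraints("CCCCC")
  expect_equal(nrow(empty$distance) + nrow(empty$dihedral), 0)
  h <- ss_to_restraints("HHHHHH")
  d15 <- h$distance[h$distance$j - h$distance$i == 4, ]
  expect_equal(unique(d15$tag), "ss_hbond")
  expect_equal(unique((d15$lower + d15$upper) / 2), 6.2, tolerance = 0.01)
  d14 <- h$distance[h$distance$j - h$distance$i == 3, ]
  expect_equal(unique((d14$lower + d14$upper) / 2), 5.05, tolerance = 0.01)
  d13 <- h$distance[h$distance$j - h$distance$i == 2, ]
  expect_equal(unique((d13$lower + d13$upper) / 2), 5.43, tolerance = 0.01)
  expect_true(all(h$dihedral$target > 0))  # right-handed
  e <- ss_to_restraints("EEEE")
  expect_true(all(abs(e$dihedral$target) >= 155))
  e13 <- e$distance[e$distance$j - e$distance$i == 2, ]
  expect_equal(unique((e13$lower + e13$upper) / 2), 6.7, tolerance = 0.01)
  # runs below the minimum length (4 for H, 3 for E) generate nothing
  short <- ss_to_restraints("HHHCEEC")
  expect_equal(nrow(short$distance) + nrow(short$dihedral), 0)
  expect_equal(nrow(ss_to_restraints("HHH")$distance), 0)
  expect_equal(nrow(ss_to_restraints("EE")$distance), 0)
})

test_that("chain restraints count bonds and steric pairs correctly", {
  r2 <- chain_restraints(2)
  expect_equal(nrow(r2$distance), 1)
  r5 <- chain_restraints(5)
  expect_equal(sum(r5$distance$tag == "chain"), 4)
  expect_equal(sum(r5$distance$tag == "steric"), 6)
  # the ideal helix satisfies them exactly
  h <- make_ideal_helix(25)
  e <- restraint_energy(h, chain_restraints(25))
  expect_equal(e$distance, 0)
})

test_that("restraint energy is the plain deviation sum and matches an
           independent recomputation", {
  st <- random_chain(8, seed = 61)
  rs <- restraint_set("t", 8, distance = data.frame(
    i = 1, j = 6, atom_i = "CA", atom_j = "CA",
    lower = 3.5, upper = 8, weight = 1, tag = "contact"))
  d <- sqrt(sum((st$ca[1, ] - st$ca[6, ])^2))
  e <- restraint_energy(st, rs)
  expect_equal(e$distance, max(0, d - 8) + max(0, 3.5 - d))
  # the documented arithmetic case: distance 10.62 against upper 8
  st2 <- st
  st2$ca[6, ] <- st2$ca[1, ] + c(10.62, 0, 0)
  expect_equal(restraint_energy(st2, rs)$distance, 2.62, tolerance = 1e-9)
  # oracle agreement on random models and mixed restraint sets
  for (seed in 62:71) {
    stR <- random_chain(20, seed = seed)
    map <- derive_contact_map(stR, 9, 3)
    set <- combine_restraints(contacts_to_restraints(map, stR$sequence),
                              chain_restraints(20))
    expect_equal(restraint_energy(stR, set)$distance,
                 oracle_energy(stR, set), tolerance = 1e-9)
  }
})

test_that("energy is zero iff all restraints are satisfied, and adding
           restraints never decreases it", {
  st <- make_helix_bundle(3, 12)
  L <- chain_length(st)
  map <- derive_contact_map(st, 8, 6)
  base <- contacts_to_restraints(map, st$sequence)
  expect_equal(restraint_energy(st, base)$distance, 0)
  more <- combine_restraints(base, chain_restraints(L),
                             ss_to_restraints(st$ss3))
  e <- restraint_energy(st, more)
  expect_equal(e$distance + e$dihedral, 0)
  # a violated restraint makes it strictly positive
  poisoned <- combine_restraints(base, restraint_set("t", L,
    distance = data.frame(i = 1, j = 2, atom_i = "CA", atom_j = "CA",
                          lower = 50, upper = 60, weight = 1,
                          tag = "contact")))
  expect_gt(restraint_energy(st, poisoned)$distance, 0)
  expect_gte(restraint_energy(st, poisoned)$distance,
             restraint_energy(st, base)$distance)
})

test_that("restraint sets derived from true structures have zero energy
           (keystone consistency)", {
  structures <- list(make_ideal_helix(30), make_beta_hairpin(16, 3),
                     make_helix_bundle(3, 14), make_random_fold(48, 7))
  for (st in structures) {
    L <- chain_length(st)
    for (t in c(8, 10, 12)) {
      map <- derive_contact_map(st, t, 6)
      set <- combine_restraints(
        contacts_to_restraints(map, st$sequence),
        noncontacts_to_restraints(derive_noncontacts(map, st), t, L,
                                  st$sequence),
        ss_to_restraints(st$ss3),
        chain_restraints(L))
      e <- restraint_energy(st, set)
      expect_equal(e$distance, 0, info = paste(st$chain_id, t))
      expect_equal(e$dihedral, 0, info = paste(st$chain_id, t))
    }
  }
})

test_that("restraint sets round-trip through the TSV serialization", {
  st <- make_random_fold(40, 9)
  map <- derive_contact_map(st, 8, 6)
  set <- combine_restraints(contacts_to_restraints(map, st$sequence),
                            ss_to_restraints(st$ss3),
                            chain_restraints(40))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_restraints(set, path)
  back <- read_restraints(path, L = 40)
  expect_equal(back$distance$lower, set$distance$lower)
  expect_equal(back$distance$upper, set$distance$upper)
  expect_equal(back$dihedral$target, set$dihedral$target)
  expect_equal(restraint_energy(st, back)$distance,
               restraint_energy(st, set)$distance)
})
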