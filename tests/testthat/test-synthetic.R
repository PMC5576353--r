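# Synthetic generators: ideal geometry, physical validity, determinism,
# emulated predictions.

test_that("the ideal helix has the closed-form geometry", {
  h <- make_ideal_helix(30)
  b <- validate_chain(h)$bond_lengths
  expect_equal(unique(round(b, 6)),
               round(sqrt((2 * 2.3 * sin(50 * pi / 180))^2 + 1.5^2), 6))
  d15 <- sqrt(sum((h$ca[5, ] - h$ca[1, ])^2))
  expect_equal(d15, sqrt((2 * 2.3 * sin(20 * pi / 180))^2 + 36),
               tolerance = 1e-9)
  expect_equal(round(d15, 2), 6.2)
  expect_gt(mean(pseudo_dihedrals(h$ca)), 0)  # right-handed
  expect_equal(h$ss3, strrep("H", 30))
  expect_error(make_ideal_helix(3), "n >= 4")
})

test_that("an isolated helix has no standard-definition contacts but a
           full map at min_sep 1", {
  h <- make_ideal_helix(30)
  expect_equal(nrow(derive_contact_map(h, 8, 6)$pairs), 0)
  full <- derive_contact_map(h, 8, 1)
  expect_gt(nrow(full$pairs), 0)
  expect_identical(full$pairs[, c("i", "j")],
                   oracle_contact_map(h, 8, 1)[, c("i", "j")])
})

test_that("the beta-hairpin pairs residues across strands as contacts", {
  hp <- make_beta_hairpin(10, 3)
  expect_equal(chain_length(hp), 23)
  expect_equal(hp$ss3, paste0(strrep("E", 10), "CCC", strrep("E", 10)))
  expect_true(validate_chain(hp)$valid)
  map <- derive_contact_map(hp, 8, 6)
  expect_gt(nrow(map$pairs), 0)
  expect_true(any(map$pairs$cls %in% c("medium", "long")))
  # the documented register: residue k pairs with 2n + turn + 1 - k
  expect_lt(sqrt(sum((hp$ca[2, ] - hp$ca[22, ])^2)), 5.01)
})

test_that("helix bundles pack without clashes and gain contacts with t", {
  hb <- make_helix_bundle(3, 14)
  expect_true(validate_chain(hb)$valid)
  expect_gte(cgfold:::cpp_min_pair_dist(hb$ca, hb$ca, 0, 2), 3.5)
  map8 <- derive_contact_map(hb, 8, 6)
  expect_true(any(map8$pairs$cls == "long"))
  counts <- vapply(seq(8, 20, by = 2), function(t) {
    nrow(derive_contact_map(hb, t, 6)$pairs)
  }, numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("random folds are deterministic, physically valid, and
           compact", {
  a <- make_random_fold(48, 31)
  b <- make_random_fold(48, 31)
  expect_identical(a$ca, b$ca)
  expect_identical(a$ss3, b$ss3)
  c2 <- make_random_fold(48, 32)
  expect_false(identical(a$ca, c2$ca))
  for (st in list(a, make_random_fold(72, 33))) {
    L <- chain_length(st)
    bonds <- validate_chain(st)$bond_lengths
    expect_true(all(bonds >= 3.7 - 1e-9 & bonds <= 3.9 + 1e-9))
    expect_gte(cgfold:::cpp_min_pair_dist(st$ca, st$ca, 0, 2), 3.5)
    rg <- sqrt(mean(rowSums(sweep(st$ca, 2, colMeans(st$ca))^2)))
    expect_lte(rg, 3.0 * L^0.34)
  }
})

test_that("perturb_structure is the identity at sigma 0 and degrades
           structures monotonically on average", {
  st <- make_helix_bundle(3, 12)
  expect_identical(perturb_structure(st, 0)$ca, st$ca)
  sigmas <- c(0.5, 1.5, 3)
  mean_rmsd <- mean_tm <- numeric(length(sigmas))
  for (k in seq_along(sigmas)) {
    r <- t <- numeric(6)
    for (s in 1:6) {
      p <- perturb_structure(st, sigmas[k], seed = s)
      bonds <- validate_chain(p)$bond_lengths
      expect_true(all(bonds >= 3.7 - 1e-9 & bonds <= 3.9 + 1e-9))
      r[s] <- rmsd_opt(p$ca, st$ca)
      t[s] <- tm_score(p$ca, st$ca)$tm
    }
    mean_rmsd[k] <- mean(r); mean_tm[k] <- mean(t)
  }
  expect_true(all(diff(mean_rmsd) > 0))
  expect_true(all(diff(mean_tm) < 0))
})

test_that("emulated predictions hit the requested top-L precision and
           their low tail is almost entirely true non-contacts", {
  st <- make_random_fold(110, 35)
  L <- chain_length(st)
  map <- derive_contact_map(st, 8, 6)
  key_true <- paste(map$pairs$i, map$pairs$j)
  spec <- emulated_prediction_spec(precision_topL = 0.7, seed = 4)
  rr <- emulate_predictions(st, spec)
  top <- rr$entries[seq_len(L), ]
  prec <- mean(paste(top$i, top$j) %in% key_true)
  expect_lt(abs(prec - 0.7), 0.05)
  nc <- select_noncontacts_from_predictions(rr, -1)
  expect_gt(nrow(nc), 0)
  frac_true_nc <- mean(!(paste(nc$i, nc$j) %in% key_true))
  expect_gte(frac_true_nc, 0.95)
  # mass below -2 as well, so both studied cutoffs are exercised
  expect_gt(nrow(select_noncontacts_from_predictions(rr, -2)), 0)
  # deterministic per seed
  rr2 <- emulate_predictions(st, spec)
  expect_identical(rr$entries, rr2$entries)
})

test_that("perfect predictions reduce to the true contact map", {
  st <- make_random_fold(90, 36)
  map <- derive_contact_map(st, 8, 6)
  expect_gte(nrow(map$pairs), chain_length(st))
  rr <- emulate_predictions(st, emulated_prediction_spec(
    precision_topL = 1.0, seed = 2))
  L <- chain_length(st)
  top <- select_top_xl(rr, 1.0, L)
  key_true <- paste(map$pairs$i, map$pairs$j)
  expect_true(all(paste(top$pairs$i, top$pairs$j) %in% key_true))
})

test_that("emulated predictions survive an RR round trip", {
  st <- make_random_fold(60, 37)
  rr <- emulate_predictions(st, emulated_prediction_spec(seed = 3))
  path <- withr::local_tempfile(fileext = ".rr")
  write_rr(rr, path)
  back <- read_rr(path)
  expect_equal(back$L, rr$L)
  expect_equal(back$entries$i, rr$entries$i)
  expect_equal(back$entries$confidence, rr$entries$confidence,
               tolerance = 1e-5)
})

test_that("the benchmark spans fold classes at the documented sizes", {
  targets <- make_benchmark(101)
  expect_length(targets, 10)
  L <- vapply(targets, function(t) chain_length(t$structure), numeric(1))
  expect_true(all(L >= 60 & L <= 150))
  ss <- vapply(targets, function(t) t$structure$ss3, character(1))
  has_h <- grepl("H", ss); has_e <- grepl("E", ss)
  expect_true(any(has_h & !has_e))   # all-alpha
  expect_true(any(has_e & !has_h))   # all-beta
  expect_true(any(has_h & has_e))    # mixed
})
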