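# Contact maps: separation classes, derivation vs brute force,
# non-contact partition, filters, RR I/O, ranked selections.

test_that("separation classes follow the standard boundaries", {
  expect_equal(classify_separation(c(1, 5)), c("local", "local"))
  expect_equal(classify_separation(c(6, 11)), c("short", "short"))
  expect_equal(classify_separation(c(12, 23)), c("medium", "medium"))
  expect_equal(classify_separation(c(24, 100)), c("long", "long"))
  expect_error(classify_separation(0), ">= 1")
})

test_that("derive_contact_map matches the brute-force oracle on random
           structures", {
  for (seed in 1:20) {
    st <- random_chain(sample(15:40, 1), seed = seed)
    t <- sample(c(6, 8, 10, 12), 1)
    ms <- sample(c(1, 3, 6), 1)
    got <- derive_contact_map(st, t, ms)$pairs
    want <- oracle_contact_map(st, t, ms)
    expect_identical(got[, c("i", "j")], want[, c("i", "j")],
                     info = paste("seed", seed))
    expect_equal(got$distance, want$distance, tolerance = 1e-12)
    expect_true(all(got$distance < t))
    expect_identical(got$cls, classify_separation(got$sep))
  }
})

test_that("contact inequality at the threshold is strict", {
  # two residues placed so their C-beta distance is exactly t
  st <- make_ideal_helix(12)
  d <- sqrt(sum((st$cb[2, ] - st$cb[8, ])^2))
  just_below <- derive_contact_map(st, d + 1e-9, 6)
  at_t <- derive_contact_map(st, d, 6)
  key <- function(m) paste(m$pairs$i, m$pairs$j)
  expect_true("2 8" %in% key(just_below))
  expect_false("2 8" %in% key(at_t))
})

test_that("contacts and non-contacts partition the candidate pairs", {
  for (seed in 21:30) {
    st <- random_chain(sample(15:35, 1), seed = seed)
    map <- derive_contact_map(st, 8, 6)
    nonc <- derive_noncontacts(map, st)
    L <- map$L
    n_cand <- sum(outer(seq_len(L), seq_len(L),
                        function(i, j) j - i >= 6 & j > i))
    expect_equal(nrow(map$pairs) + nrow(nonc), n_cand)
    expect_identical(nonc[, c("i", "j")],
                     oracle_noncontacts(st, 8, 6)[, c("i", "j")])
    expect_true(all(nonc$distance >= 8))
  }
})

test_that("derive_noncontacts enumerates the documented L = 10 example", {
  st <- random_chain(10, seed = 40)
  map <- derive_contact_map(st, 1e-6, 6)  # no contacts at a tiny threshold
  nonc <- derive_noncontacts(map)
  expect_equal(nrow(nonc), 10)
  expect_true(all(nonc$j - nonc$i >= 6))
})

test_that("filter_by_min_sep keeps sep >= s and is monotone over the
           studied sweep", {
  st <- random_chain(40, seed = 41)
  map <- derive_contact_map(st, 10, 1)
  expect_identical(filter_by_min_sep(map, 0)$pairs, map$pairs)
  expect_identical(filter_by_min_sep(map, 1)$pairs, map$pairs)
  f6 <- filter_by_min_sep(map, 6)
  expect_true(all(f6$pairs$sep >= 6))
  counts <- vapply(seq(0, 51, by = 3), function(s) {
    nrow(filter_by_min_sep(map, s)$pairs)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("contact count grows with t and shrinks with min_sep", {
  st <- make_helix_bundle(3, 14)
  counts_t <- vapply(8:20, function(t) {
    nrow(derive_contact_map(st, t, 6)$pairs)
  }, numeric(1))
  expect_true(all(diff(counts_t) >= 0))
  counts_s <- vapply(c(1, 6, 12, 24), function(s) {
    nrow(derive_contact_map(st, 8, s)$pairs)
  }, numeric(1))
  expect_true(all(diff(counts_s) <= 0))
})

test_that("RR files round-trip, normalize, and deduplicate", {
  path <- withr::local_tempfile(fileext = ".rr")
  writeLines(c("PFRMAT RR", "TARGET T0999", "MODEL 1", "MKVLAD",
               "1 9 0 8 0.73", "9 2 0 8 0.55", "3 9 0 8 -1.4", "END"), path)
  rr <- read_rr(path)
  expect_equal(rr$target_id, "T0999")
  expect_equal(rr$entries$i[1], 1)
  expect_equal(rr$entries$j[1], 9)
  expect_equal(rr$entries$confidence[1], 0.73)
  # i >= j normalized by swapping
  expect_true(all(rr$entries$i < rr$entries$j))
  out <- withr::local_tempfile(fileext = ".rr")
  write_rr(rr, out)
  back <- read_rr(out)
  expect_equal(back$entries, rr$entries)
  # malformed line reports its number
  bad <- withr::local_tempfile(fileext = ".rr")
  writeLines(c("1 9 0 8 0.73", "2 9 oops"), bad)
  expect_error(read_rr(bad), "line 2")
  # duplicates keep the highest confidence
  dup <- withr::local_tempfile(fileext = ".rr")
  writeLines(c("1 9 0 8 0.2", "1 9 0 8 0.9"), dup)
  expect_warning(rr2 <- read_rr(dup), "duplicated")
  expect_equal(nrow(rr2$entries), 1)
  expect_equal(rr2$entries$confidence, 0.9)
})

test_that("top-xL selection uses the floor rule and is nested in x", {
  st <- make_helix_bundle(3, 20)
  rr <- emulate_predictions(st, emulated_prediction_spec(seed = 5))
  L <- chain_length(st)
  expect_equal(nrow(select_top_xl(rr, 0.1, L)$pairs), floor(0.1 * L))
  expect_equal(nrow(select_top_xl(rr, 1.0, L)$pairs), L)
  expect_equal(nrow(select_top_xl(rr, 0.1, 97)$pairs), 9)
  expect_error(select_top_xl(rr, 0.001, 10), "no contacts")
  key <- function(m) paste(m$pairs$i, m$pairs$j)
  for (x in c(0.1, 0.5, 1, 2)) {
    expect_true(all(key(select_top_xl(rr, x, L)) %in%
                      key(select_top_xl(rr, min(4, x * 2), L))))
  }
})

test_that("confidence-threshold non-contact selection is strict and
           disjoint from top-L contacts", {
  e <- data.frame(i = c(1, 2, 3, 4), j = c(9, 10, 11, 12),
                  d_low = 0, d_high = 8,
                  confidence = c(0.9, -0.5, -1.5, -2.7))
  rr <- cgfold:::new_predicted_contact_list(e, "t", 20)
  got1 <- select_noncontacts_from_predictions(rr, -1)
  expect_equal(sort(got1$confidence), c(-2.7, -1.5))
  got2 <- select_noncontacts_from_predictions(rr, -2)
  expect_equal(got2$confidence, -2.7)
  expect_equal(nrow(select_noncontacts_from_predictions(rr, -5)), 0)
  top <- select_top_xl(rr, 0.1, 20)  # top 2
  expect_false(any(paste(got1$i, got1$j) %in%
                     paste(top$pairs$i, top$pairs$j)))
})

test_that("short chains yield an empty map with a warning, not an error", {
  st <- random_chain(4, seed = 50)
  expect_warning(m <- derive_contact_map(st, 8, 6), "short")
  expect_equal(nrow(m$pairs), 0)
})
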