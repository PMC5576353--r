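# Synthetic protein-like structure generators.
#
# These emulate the statistical structure of reconstruction benchmarks
# (mixed fold classes with known secondary structure and derivable contact
# maps) so the whole pipeline is testable without any downloaded data.
# The ideal helix/strand parameterizations here are the single source of
# truth for the secondary-structure restraint targets (see
# ideal_geometry()), so restraints and generators cannot drift apart.

# ideal alpha-helix: radius 2.3 A, rise 1.5 A/residue, twist 100 deg/residue
.helix_radius <- 2.3
.helix_rise <- 1.5
.helix_twist_deg <- 100

# ideal extended strand: 3.35 A axial step, zigzag amplitude such that the
# virtual bond length is 3.8 A; d(i, i+2) = 6.7 A
.strand_step <- 3.35
.strand_amp <- sqrt(3.8^2 - 3.35^2) / 2

helix_coords <- function(n, phase = 0) {
  i <- seq_len(n) - 1
  om <- .helix_twist_deg * pi / 180
  cbind(.helix_radius * cos(om * i + phase),
        .helix_radius * sin(om * i + phase),
        .helix_rise * i)
}

strand_coords <- function(n, parity = 0) {
  i <- seq_len(n) - 1
  cbind(.strand_step * i, .strand_amp * (-1)^(i + parity), 0)
}

#' Ideal C-alpha chain of an alpha-helix
#'
#' Right-handed helix with radius 2.3 Angstrom, rise 1.5 Angstrom per
#' residue and 100 degrees twist per residue (consecutive C-alpha distance
#' 3.83 Angstrom), with virtual C-beta atoms attached and `ss3 = "H..."`.
#'
#' @param n number of residues (>= 4).
#' @return a [chain_structure()].
#' @export
make_ideal_helix <- function(n) {
  if (n < 4) stop("an ideal helix needs n >= 4 residues")
  s <- chain_structure(sequence = strrep("A", n), ca = helix_coords(n),
                       ss3 = strrep("H", n), chain_id = "helix")
  virtual_cbeta(s)
}

#' Ideal antiparallel beta-hairpin
#'
#' Two ideal extended strands (3.35 Angstrom axial step, 3.8 Angstrom
#' virtual bonds) in parallel planes 5.0 Angstrom apart, joined by a
#' circular-arc turn with exact 3.8 Angstrom bonds.  Residues paired
#' across the strands sit exactly 5.0 Angstrom apart and are contacts at
#' the 8 Angstrom threshold.
#'
#' @param n_per_strand residues per strand (>= 3).
#' @param turn_len number of coil residues in the turn (default 3).
#' @return a [chain_structure()] with `ss3` = E-runs joined by a C-turn.
#' @export
make_beta_hairpin <- function(n_per_strand, turn_len = 3) {
  if (n_per_strand < 3) stop("n_per_strand must be >= 3")
  n <- n_per_strand
  s1 <- strand_coords(n)
  # second strand: same x/y positions traversed backwards, 5.0 A above
  i <- seq_len(n) - 1
  s2 <- cbind(.strand_step * (n - 1 - i),
              .strand_amp * (-1)^(n - 1 - i), 5.0)
  P <- s1[n, ]
  Q <- s2[1, ]
  turn <- arc_points(P, Q, n_seg = turn_len + 1, normal = c(1, 0, 0))
  ca <- rbind(s1, turn, s2)
  ss3 <- paste0(strrep("E", n), strrep("C", turn_len), strrep("E", n))
  seq1 <- paste0(strrep("V", n), strrep("S", turn_len), strrep("V", n))
  st <- chain_structure(sequence = seq1, ca = ca, ss3 = ss3,
                        chain_id = "hairpin")
  st <- virtual_cbeta(st)
  v <- validate_chain(st)
  if (!v$valid) stop("hairpin generator produced invalid bonds")
  st
}

#' Ideal up-down helix bundle
#'
#' `k` ideal helices of `n` residues packed on a circle at 10 Angstrom
#' inter-axis distance with alternating up/down orientation, joined by
#' coil linkers built as circular arcs with exact 3.8 Angstrom bonds.
#' The generator retries a grid of helix phase offsets until the chain is
#' clash-free (minimum non-bonded C-alpha distance >= 3.5 Angstrom).
#'
#' @param k number of helices (>= 2).
#' @param n residues per helix.
#' @return a [chain_structure()] with helical `ss3` runs and coil linkers.
#' @export
make_helix_bundle <- function(k, n) {
  if (k < 2) stop("a bundle needs k >= 2 helices")
  if (n < 6) stop("use n >= 6 residues per helix")
  axis_r <- if (k == 2) 5 else 10 / (2 * sin(pi / k))
  centers <- cbind(axis_r * cos(2 * pi * (seq_len(k) - 1) / k),
                   axis_r * sin(2 * pi * (seq_len(k) - 1) / k))
  for (delta in seq(0, 2 * pi - 1e-6, by = 0.3)) {
    ca <- NULL
    ss <- character(0)
    ok <- TRUE
    for (m in seq_len(k)) {
      h <- helix_coords(n, phase = delta + (m - 1) * 2.4)
      h[, 1] <- h[, 1] + centers[m, 1]
      h[, 2] <- h[, 2] + centers[m, 2]
      if (m %% 2 == 0) h <- h[n:1, , drop = FALSE]  # reversed = downward
      if (is.null(ca)) {
        ca <- h
        ss <- rep("H", n)
      } else {
        P <- ca[nrow(ca), ]
        Q <- h[1, ]
        d <- vnorm(Q - P)
        n_seg <- max(2, ceiling(d / 3.8) + 1)
        updown <- if (m %% 2 == 0) 1 else -1  # bulge above top / below bottom
        turn <- tryCatch(
          arc_points(P, Q, n_seg, normal = c(0, 0, updown)),
          error = function(e) NULL)
        if (is.null(turn)) { ok <- FALSE; break }
        new_pts <- rbind(turn, h)
        dmin <- cpp_min_pair_dist(ca, new_pts, offset = nrow(ca), min_sep = 2)
        dint <- cpp_min_pair_dist(new_pts, new_pts, offset = 0, min_sep = 2)
        if (min(dmin, dint) < 3.5) { ok <- FALSE; break }
        ca <- rbind(ca, new_pts)
        ss <- c(ss, rep("C", nrow(turn)), rep("H", n))
      }
    }
    if (!ok) next
    seq1 <- paste(ifelse(ss == "H", "A", "S"), collapse = "")
    st <- chain_structure(sequence = seq1, ca = ca,
                          ss3 = paste(ss, collapse = ""), chain_id = "bundle")
    st <- virtual_cbeta(st)
    if (validate_chain(st)$valid) return(st)
  }
  stop("helix-bundle packing failed after exhausting phase offsets")
}

# coil segment: seeded directed random walk with exact 3.8 A steps
coil_coords <- function(n, start_dir = c(1, 0, 0)) {
  pts <- matrix(0, n, 3)
  if (n < 2) return(pts)
  dir <- unit(start_dir)
  for (i in 2:n) {
    dir <- unit(0.6 * dir + rnorm(3, sd = 0.6))
    pts[i, ] <- pts[i - 1, ] + 3.8 * dir
  }
  pts
}

#' Random protein-like fold
#'
#' Assembles a self-avoiding chain from alternating secondary-structure
#' elements (ideal helices or strands) and coil segments, with clash
#' rejection (minimum non-bonded C-alpha distance >= 3.5 Angstrom),
#' compactness control (radius of gyration <= `rg_coef * L^0.34`), and
#' bond lengths in [3.7, 3.9] Angstrom.  Deterministic per seed.
#'
#' @param L number of residues (>= 20).
#' @param seed integer RNG seed.
#' @param rg_coef compactness coefficient (default 3.0); the exponent 0.34
#'   approximates globular scaling.
#' @param max_restarts whole-chain assembly attempts before failing.
#' @return a [chain_structure()] with mixed `ss3`.
#' @export
make_random_fold <- function(L, seed, rg_coef = 3.0, max_restarts = 80) {
  if (L < 20) stop("make_random_fold needs L >= 20")
  set.seed(as.integer(seed))
  target_rg <- rg_coef * L^0.34
  n_tries <- 80L  # placement attempts per segment
  aa_pool <- c("A", "L", "E", "K", "V", "I", "S", "T", "D", "N", "F", "R")
  for (attempt in seq_len(max_restarts)) {
    alpha <- min(0.9, 0.35 + 0.04 * attempt)  # centroid bias strength
    # --- segment plan: element, coil, element, coil, ... ---
    plan <- list()
    remaining <- L
    want_coil <- FALSE
    while (remaining > 0) {
      if (want_coil) {
        len <- min(remaining, sample(2:4, 1))
        plan[[length(plan) + 1]] <- list(type = "C", len = len)
      } else {
        type <- sample(c("H", "E"), 1, prob = c(0.55, 0.45))
        len <- if (type == "H") sample(6:12, 1) else sample(4:8, 1)
        len <- min(remaining, len)
        if (len < 4) type <- "C"
        plan[[length(plan) + 1]] <- list(type = type, len = len)
      }
      remaining <- remaining - plan[[length(plan)]]$len
      want_coil <- !want_coil
    }
    # --- geometric assembly ---
    ca <- NULL
    ss <- character(0)
    failed <- FALSE
    for (sg in plan) {
      # sample valid placements and keep the best-packed one (most new
      # long-range C-alpha pairs within 8 A), emulating the hydrophobic
      # collapse that makes real domains densely self-contacting
      best_cand <- NULL
      best_score <- -1
      for (try_k in seq_len(n_tries)) {
        local_pts <- switch(sg$type,
          H = helix_coords(sg$len),
          E = strand_coords(sg$len),
          C = coil_coords(sg$len))
        R <- random_rotation()
        pts <- local_pts %*% t(R)
        if (is.null(ca)) {
          cand <- pts
          dint <- if (nrow(cand) >= 3)
            cpp_min_pair_dist(cand, cand, 0, 2) else Inf
          if (dint >= 3.5) { best_cand <- cand; best_score <- 0; break }
          next
        }
        e <- ca[nrow(ca), ]
        centroid <- colMeans(ca)
        # attractor: random point in a ball around the running centroid
        att <- centroid + runif(1, 0, 0.5 * target_rg) * unit(rnorm(3))
        pull <- att - e
        pull <- if (vnorm(pull) > 1e-6) unit(pull) else unit(rnorm(3))
        # relax the inward pull as placement attempts accumulate
        aeff <- alpha * (1 - 0.6 * try_k / n_tries)
        u <- unit(aeff * pull + (1 - aeff) * unit(rnorm(3)))
        start <- e + 3.8 * u
        cand <- sweep(pts, 2, pts[1, ]) +
          matrix(start, nrow(pts), 3, byrow = TRUE)
        dvs <- cpp_min_pair_dist(ca, cand, offset = nrow(ca), min_sep = 2)
        din <- if (nrow(cand) >= 3)
          cpp_min_pair_dist(cand, cand, 0, 2) else Inf
        # soft compactness: reject placements that fly far outside
        ext <- max(sqrt(rowSums(sweep(cand, 2, centroid)^2)))
        if (!(dvs >= 3.5 && din >= 3.5 && ext <= 1.6 * target_rg)) next
        D2 <- outer(rowSums(cand^2), rowSums(ca^2), `+`) -
          2 * cand %*% t(ca)
        seps <- abs(outer(seq_len(nrow(cand)) + nrow(ca), seq_len(nrow(ca)),
                          `-`))
        score <- sum(D2 < 64 & seps >= 6)
        if (score > best_score) { best_score <- score; best_cand <- cand }
        if (try_k >= 25 && best_score >= 0) break
      }
      if (is.null(best_cand)) { failed <- TRUE; break }
      ca <- rbind(ca, best_cand)
      ss <- c(ss, rep(sg$type, sg$len))
    }
    if (failed) next
    rg <- sqrt(mean(rowSums(sweep(ca, 2, colMeans(ca))^2)))
    if (rg > target_rg) next
    seq1 <- paste(sample(aa_pool, L, replace = TRUE), collapse = "")
    st <- chain_structure(sequence = seq1, ca = ca,
                          ss3 = paste(ss, collapse = ""), chain_id = "fold")
    st <- virtual_cbeta(st)
    if (validate_chain(st)$valid) return(st)
  }
  stop("random-fold assembly failed after ", max_restarts, " restarts")
}

#' Perturb a structure with seeded isotropic noise
#'
#' Adds Gaussian noise of standard deviation `sigma` to every C-alpha,
#' then re-projects consecutive bonds into [3.7, 3.9] Angstrom with one
#' sequential pass.  `sigma = 0` returns the structure unchanged.
#' Virtual C-beta atoms are recomputed from the perturbed trace.
#'
#' @param structure a [chain_structure()].
#' @param sigma noise standard deviation in Angstrom (>= 0).
#' @param seed integer RNG seed.
#' @return a perturbed [chain_structure()].
#' @export
perturb_structure <- function(structure, sigma, seed = 1) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(structure)
  set.seed(as.integer(seed))
  ca <- structure$ca
  L <- nrow(ca)
  ca <- ca + matrix(rnorm(L * 3, sd = sigma), L, 3)
  for (i in 2:L) {
    v <- ca[i, ] - ca[i - 1, ]
    d <- vnorm(v)
    d2 <- min(max(d, 3.7), 3.9)
    if (d2 != d) ca[i, ] <- ca[i - 1, ] + v / d * d2
  }
  out <- chain_structure(sequence = structure$sequence, ca = ca,
                         ss3 = structure$ss3,
                         chain_id = structure$chain_id)
  virtual_cbeta(out)
}

#' Specification of an emulated contact-prediction experiment
#'
#' Parameters controlling [emulate_predictions()]: the realized precision
#' of the top-L ranked pairs, the number of additional low-ranked decoy
#' entries, and the confidence distributions assigned to true contacts and
#' decoys.  Default decoy confidences place mass both below -1 and below
#' -2 so confidence-threshold non-contact selection is exercised.
#'
#' @param precision_topL fraction of the top-L entries that are true
#'   contacts, in (0, 1].
#' @param n_decoys number of ranked entries below the top L (default 4L,
#'   set at generation time when `NULL`).
#' @param confidence_model list with components `true_range` (confidence
#'   range of top-L entries), `decoy_means`, `decoy_sds` and `decoy_probs`
#'   (mixture for the low-ranked tail), `missed_frac` (fraction of the
#'   tail drawn from true contacts, kept above -1).
#' @param seed integer RNG seed.
#' @return an object of class `emulated_prediction_spec`.
#' @export
emulated_prediction_spec <- function(precision_topL = 0.65, n_decoys = NULL,
                                     confidence_model = list(
                                       true_range = c(0.3, 2.0),
                                       decoy_means = c(-0.4, -1.4, -2.6),
                                       decoy_sds = c(0.25, 0.2, 0.3),
                                       decoy_probs = c(0.60, 0.25, 0.15),
                                       missed_frac = 0.02),
                                     seed = 1) {
  stopifnot(precision_topL > 0, precision_topL <= 1)
  x <- list(precision_topL = precision_topL, n_decoys = n_decoys,
            confidence_model = confidence_model, seed = as.integer(seed))
  class(x) <- "emulated_prediction_spec"
  x
}

#' Emulate a noisy ranked contact prediction for a structure
#'
#' Builds a ranked CASP-RR-style contact list in which a controlled
#' fraction of the top-L entries are true contacts (the rest decoys drawn
#' from true non-contact pairs), followed by a low-confidence tail whose
#' decoy confidences include mass below -1 and below -2.  True contacts
#' are derived at the 8 Angstrom / min_sep 6 standard definition.
#' Deterministic per seed.
#'
#' @param structure a [chain_structure()].
#' @param spec an [emulated_prediction_spec()].
#' @return a `predicted_contact_list` (see [read_rr()]).
#' @export
emulate_predictions <- function(structure, spec = emulated_prediction_spec()) {
  stopifnot(inherits(spec, "emulated_prediction_spec"))
  set.seed(spec$seed)
  cm <- spec$confidence_model
  map <- derive_contact_map(structure, t = 8, min_sep = 6)
  nonc <- derive_noncontacts(map, structure)
  L <- map$L
  true_pairs <- map$pairs
  n_top <- L
  n_true <- min(round(spec$precision_topL * n_top), nrow(true_pairs))
  n_false_top <- n_top - n_true
  n_decoys <- spec$n_decoys %||% (4L * L)
  n_missed <- floor(cm$missed_frac * n_decoys)
  need_nonc <- n_false_top + (n_decoys - n_missed)
  if (need_nonc > nrow(nonc)) {
    stop("requested decoys exceed available non-contact pairs (need ",
         need_nonc, ", have ", nrow(nonc), ")")
  }
  idx_true_top <- sample(nrow(true_pairs), n_true)
  idx_nonc <- sample(nrow(nonc), need_nonc)
  idx_false_top <- idx_nonc[seq_len(n_false_top)]
  idx_tail_nonc <- idx_nonc[setdiff(seq_len(need_nonc),
                                    seq_len(n_false_top))]
  rest_true <- setdiff(seq_len(nrow(true_pairs)), idx_true_top)
  idx_missed <- if (n_missed > 0 && length(rest_true))
    sample(rest_true, min(n_missed, length(rest_true))) else integer(0)

  top <- rbind(true_pairs[idx_true_top, c("i", "j")],
               nonc[idx_false_top, c("i", "j")])
  top <- top[sample(nrow(top)), , drop = FALSE]
  top$confidence <- sort(runif(nrow(top), cm$true_range[1], cm$true_range[2]),
                         decreasing = TRUE)
  tail_pairs <- rbind(nonc[idx_tail_nonc, c("i", "j")],
                      true_pairs[idx_missed, c("i", "j")])
  n_tail <- nrow(tail_pairs)
  comp <- sample(seq_along(cm$decoy_probs), n_tail, replace = TRUE,
                 prob = cm$decoy_probs)
  conf <- rnorm(n_tail, mean = cm$decoy_means[comp], sd = cm$decoy_sds[comp])
  # missed true contacts stay above the non-contact selection cutoff
  if (length(idx_missed)) {
    miss_rows <- seq(n_tail - length(idx_missed) + 1, n_tail)
    conf[miss_rows] <- pmax(conf[miss_rows], -0.9)
  }
  conf <- pmin(conf, cm$true_range[1] - 0.05)
  tail_pairs$confidence <- conf

  entries <- rbind(top, tail_pairs)
  entries$d_low <- 0
  entries$d_high <- 8
  new_predicted_contact_list(
    entries[, c("i", "j", "d_low", "d_high", "confidence")],
    target_id = structure$chain_id, L = L,
    sequence = structure$sequence)
}

#' Build the standard synthetic benchmark set
#'
#' Ten targets of 60--150 residues spanning all-alpha (helix bundles),
#' all-beta (hairpins), and mixed folds (random assemblies), each with
#' known coordinates and secondary structure.
#'
#' @param seed integer seed controlling the random folds.
#' @return list of targets; each element is `list(id, structure)`.
#' @export
make_benchmark <- function(seed = 101) {
  seed <- as.integer(seed)
  targets <- list(
    list(id = "bundle3a", structure = make_helix_bundle(3, 18)),
    list(id = "bundle4a", structure = make_helix_bundle(4, 15)),
    list(id = "bundle3b", structure = make_helix_bundle(3, 24)),
    list(id = "hairpin1", structure = make_beta_hairpin(28, 4)),
    list(id = "hairpin2", structure = make_beta_hairpin(34, 5)),
    list(id = "fold064", structure = make_random_fold(64, seed + 1)),
    list(id = "fold080", structure = make_random_fold(80, seed + 2)),
    list(id = "fold096", structure = make_random_fold(96, seed + 3)),
    list(id = "fold120", structure = make_random_fold(120, seed + 4)),
    list(id = "fold150", structure = make_random_fold(150, seed + 5))
  )
  for (k in seq_along(targets)) {
    targets[[k]]$structure$chain_id <- targets[[k]]$id
  }
  targets
}
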