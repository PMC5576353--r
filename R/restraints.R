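# Translation of contacts, non-contacts and secondary structure into typed
# flat-bottom restraints, plus the restraint-violation energy.

empty_distance_df <- function() {
  data.frame(i = integer(0), j = integer(0), atom_i = character(0),
             atom_j = character(0), lower = numeric(0), upper = numeric(0),
             weight = numeric(0), tag = character(0))
}

empty_dihedral_df <- function() {
  data.frame(i = integer(0), target = numeric(0), tolerance = numeric(0),
             weight = numeric(0), tag = character(0))
}

#' Construct a restraint set
#'
#' A `restraint_set` bundles distance restraints (rows: `i`, `j`,
#' `atom_i`, `atom_j` in \{CA, CB\}, `lower`, `upper` in Angstrom,
#' `weight`, `tag`) and C-alpha pseudo-dihedral restraints (rows: start
#' residue `i` of the quadruple (i, i+1, i+2, i+3), `target` and
#' `tolerance` in degrees, `weight`, `tag`).
#'
#' @param target_id identifier.
#' @param L chain length; every referenced index must lie in `[1, L]`.
#' @param distance data frame of distance restraints.
#' @param dihedral data frame of pseudo-dihedral restraints.
#' @return an object of class `restraint_set`.
#' @export
restraint_set <- function(target_id, L, distance = empty_distance_df(),
                          dihedral = empty_dihedral_df()) {
  L <- as.integer(L)
  if (nrow(distance)) {
    stopifnot(all(distance$i >= 1), all(distance$j >= 1),
              all(distance$i <= L), all(distance$j <= L),
              all(distance$i != distance$j),
              all(distance$lower > 0),
              all(distance$lower <= distance$upper),
              all(distance$weight >= 0))
  }
  if (nrow(dihedral)) {
    stopifnot(all(dihedral$i >= 1), all(dihedral$i + 3 <= L))
  }
  rownames(distance) <- rownames(dihedral) <- NULL
  x <- list(target_id = target_id, L = L, distance = distance,
            dihedral = dihedral)
  class(x) <- "restraint_set"
  x
}

#' @export
print.restraint_set <- function(x, ...) {
  tags <- table(x$distance$tag)
  cat("restraint_set", x$target_id, ": L =", x$L, ",", nrow(x$distance),
      "distance +", nrow(x$dihedral), "dihedral restraints\n")
  if (length(tags)) {
    cat("  ", paste(names(tags), tags, sep = ":", collapse = "  "), "\n")
  }
  invisible(x)
}

#' Merge restraint sets
#'
#' @param ... `restraint_set` objects over the same chain length.
#' @return the combined `restraint_set`.
#' @export
combine_restraints <- function(...) {
  sets <- list(...)
  sets <- sets[!vapply(sets, is.null, logical(1))]
  stopifnot(length(sets) >= 1)
  L <- unique(vapply(sets, function(s) s$L, integer(1)))
  stopifnot(length(L) == 1)
  restraint_set(sets[[1]]$target_id, L,
                distance = do.call(rbind, lapply(sets, `[[`, "distance")),
                dihedral = do.call(rbind, lapply(sets, `[[`, "dihedral")))
}

# ---------------------------------------------------------------------------
# Ideal secondary-structure geometry, measured once from the synthetic
# generators so restraint targets and generated structures cannot drift
# apart.  Cached per session.
ideal_geometry <- function() {
  g <- .cgfold_cache$ideal_geometry
  if (!is.null(g)) return(g)
  h <- helix_coords(8)
  s <- strand_coords(6)
  g <- list(
    helix_d13 = vnorm(h[3, ] - h[1, ]),
    helix_d14 = vnorm(h[4, ] - h[1, ]),
    helix_d15 = vnorm(h[5, ] - h[1, ]),
    helix_dihedral = dihedral_angle(h[1, ], h[2, ], h[3, ], h[4, ]),
    strand_d13 = vnorm(s[3, ] - s[1, ]),
    strand_dihedral = dihedral_angle(s[1, ], s[2, ], s[3, ], s[4, ]),
    bond = vnorm(h[2, ] - h[1, ])
  )
  .cgfold_cache$ideal_geometry <- g
  g
}

#' Translate a contact map into distance restraints
#'
#' One flat-bottom restraint per contact: C-beta atoms (C-alpha for
#' glycine when the sequence is known), lower bound 3.5 Angstrom (the
#' steric floor), upper bound equal to the map's derivation threshold `t`
#' (8 Angstrom at the standard definition), weight 1, tag `contact`.  For
#' true maps carrying distances, the rare pair closer than 3.5 Angstrom
#' keeps its own distance as the lower bound so that restraints derived
#' from a native structure are always satisfied by it.
#'
#' @param map a `contact_map` (true or predicted).
#' @param sequence optional one-letter sequence used to route glycine
#'   contacts to C-alpha.
#' @return a `restraint_set` with distance restraints only.
#' @export
contacts_to_restraints <- function(map, sequence = NULL) {
  stopifnot(inherits(map, "contact_map"))
  p <- map$pairs
  if (!nrow(p)) return(restraint_set(map$target_id, map$L))
  atom_of <- function(idx) {
    if (is.null(sequence)) return(rep("CB", length(idx)))
    ifelse(substring(sequence, idx, idx) == "G", "CA", "CB")
  }
  lower <- rep(3.5, nrow(p))
  if ("distance" %in% names(p)) {
    known <- !is.na(p$distance)
    lower[known] <- pmin(3.5, p$distance[known])
  }
  df <- data.frame(i = p$i, j = p$j, atom_i = atom_of(p$i),
                   atom_j = atom_of(p$j), lower = lower,
                   upper = map$threshold_t, weight = 1, tag = "contact")
  restraint_set(map$target_id, map$L, distance = df)
}

#' Translate non-contacts into repulsive distance restraints
#'
#' One lower-bound restraint per pair: bounds `[t + 2, 200]` Angstrom
#' between C-beta atoms (10--200 at the standard 8 Angstrom threshold),
#' weight 1, tag `noncontact`.  The 200 Angstrom upper bound is
#' effectively unbounded.  When true distances are attached (non-contacts
#' derived from a native structure), pairs inside the two-Angstrom buffer
#' zone `[t, t + 2)` are excluded so the restraint set remains exactly
#' satisfied by the source structure.
#'
#' @param pairs data frame with columns `i`, `j` (and optionally
#'   `distance`), e.g. from [derive_noncontacts()] or
#'   [select_noncontacts_from_predictions()].
#' @param t contact threshold in Angstrom (>= 8) the non-contacts
#'   complement.
#' @param L chain length.
#' @param sequence optional sequence for glycine C-alpha routing.
#' @param target_id identifier.
#' @return a `restraint_set` with distance restraints only.
#' @export
noncontacts_to_restraints <- function(pairs, t = 8, L, sequence = NULL,
                                      target_id = "target") {
  stopifnot(t >= 8)
  lower <- t + 2
  if (!nrow(pairs)) return(restraint_set(target_id, L))
  if ("distance" %in% names(pairs)) {
    known <- !is.na(pairs$distance)
    drop <- known & pairs$distance < lower
    if (any(drop)) {
      pairs <- pairs[!drop, , drop = FALSE]
    }
  }
  if (!nrow(pairs)) return(restraint_set(target_id, L))
  atom_of <- function(idx) {
    if (is.null(sequence)) return(rep("CB", length(idx)))
    ifelse(substring(sequence, idx, idx) == "G", "CA", "CB")
  }
  df <- data.frame(i = pairs$i, j = pairs$j, atom_i = atom_of(pairs$i),
                   atom_j = atom_of(pairs$j), lower = lower, upper = 200,
                   weight = 1, tag = "noncontact")
  restraint_set(target_id, L, distance = df)
}

# maximal runs of a given state in an ss3 string:
# returns data.frame(start, end, len)
ss_runs <- function(ss3, state) {
  r <- rle(strsplit(ss3, "")[[1]])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values == state
  data.frame(start = starts[keep], end = ends[keep], len = r$lengths[keep])
}

#' Translate 3-state secondary structure into geometric restraints
#'
#' For each maximal helix run of length >= 4: C-alpha (i, i+2), (i, i+3)
#' distance restraints and an (i, i+4) hydrogen-bond-proxy distance
#' restraint at the ideal-helix values with +/- `dist_tol` bands, plus
#' pseudo-dihedral restraints on interior C-alpha quadruples at the ideal
#' right-handed helix angle with `helix_dih_tol` tolerance.  For each
#' maximal strand run of length >= 3: extended (i, i+2) distance
#' restraints and pseudo-dihedral restraints at 180 degrees with
#' `strand_dih_tol` tolerance.  Coil generates nothing.  All target
#' values are measured from the package's ideal helix/strand generators.
#' Strand pairing is deliberately not inferred from secondary structure:
#' long-range sheet geometry must come from contacts.
#'
#' @param ss3 3-state string over \{H, E, C\}.
#' @param target_id identifier.
#' @param dist_tol half-width of the distance bands (default 0.3 A).
#' @param helix_dih_tol,strand_dih_tol dihedral tolerances in degrees
#'   (defaults 15 and 25).
#' @return a `restraint_set` fragment (distance + dihedral restraints).
#' @export
ss_to_restraints <- function(ss3, target_id = "target", dist_tol = 0.3,
                             helix_dih_tol = 15, strand_dih_tol = 25) {
  ss3 <- validate_ss3(ss3)
  L <- nchar(ss3)
  g <- ideal_geometry()
  dist <- list()
  dih <- list()
  band <- function(i, j, center, tag) {
    data.frame(i = i, j = j, atom_i = "CA", atom_j = "CA",
               lower = center - dist_tol, upper = center + dist_tol,
               weight = 1, tag = tag)
  }
  for (r in seq_len(nrow(h <- ss_runs(ss3, "H")))) {
    a <- h$start[r]; b <- h$end[r]
    if (b - a + 1 < 4) next
    i2 <- a:(b - 2)
    dist[[length(dist) + 1]] <- band(i2, i2 + 2, g$helix_d13, "ss_distance")
    i3 <- a:(b - 3)
    dist[[length(dist) + 1]] <- band(i3, i3 + 3, g$helix_d14, "ss_distance")
    if (b - a + 1 >= 5) {
      i4 <- a:(b - 4)
      dist[[length(dist) + 1]] <- band(i4, i4 + 4, g$helix_d15, "ss_hbond")
    }
    q <- a:(b - 3)
    dih[[length(dih) + 1]] <- data.frame(i = q, target = g$helix_dihedral,
                                         tolerance = helix_dih_tol,
                                         weight = 1, tag = "ss_dihedral")
  }
  for (r in seq_len(nrow(e <- ss_runs(ss3, "E")))) {
    a <- e$start[r]; b <- e$end[r]
    if (b - a + 1 < 3) next
    i2 <- a:(b - 2)
    dist[[length(dist) + 1]] <- band(i2, i2 + 2, g$strand_d13, "ss_distance")
    if (b - a + 1 >= 4) {
      q <- a:(b - 3)
      dih[[length(dih) + 1]] <- data.frame(i = q, target = g$strand_dihedral,
                                           tolerance = strand_dih_tol,
                                           weight = 1, tag = "ss_dihedral")
    }
  }
  restraint_set(target_id, L,
                distance = if (length(dist)) do.call(rbind, dist)
                           else empty_distance_df(),
                dihedral = if (length(dih)) do.call(rbind, dih)
                           else empty_dihedral_df())
}

#' Chain connectivity and steric restraints
#'
#' Bonded restraints C-alpha(i)--C-alpha(i+1) in [3.7, 3.9] Angstrom (tag
#' `chain`) and lower-bound-only steric restraints of 3.5 Angstrom for
#' every pair at separation >= 2 (tag `steric`).
#'
#' @param L chain length (>= 2).
#' @param target_id identifier.
#' @return a `restraint_set` with distance restraints only.
#' @export
chain_restraints <- function(L, target_id = "target") {
  stopifnot(L >= 2)
  i <- seq_len(L - 1)
  bonds <- data.frame(i = i, j = i + 1, atom_i = "CA", atom_j = "CA",
                      lower = 3.7, upper = 3.9, weight = 1, tag = "chain")
  steric <- NULL
  if (L >= 3) {
    idx <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
    idx <- idx[idx[, 2] - idx[, 1] >= 2, , drop = FALSE]
    steric <- data.frame(i = as.integer(idx[, 1]), j = as.integer(idx[, 2]),
                         atom_i = "CA", atom_j = "CA", lower = 3.5,
                         upper = Inf, weight = 1, tag = "steric")
  }
  restraint_set(target_id, L, distance = rbind(bonds, steric))
}

# ---------------------------------------------------------------------------
# coordinates of the named atom set for energy evaluation
atom_coords <- function(object, atom, idx) {
  ca <- if (inherits(object, "chain_structure")) object$ca else object$ca
  cb <- object$cb
  if (is.null(cb)) cb <- ca
  out <- ca[idx, , drop = FALSE]
  sel <- atom == "CB"
  if (any(sel)) out[sel, ] <- cb[idx[sel], , drop = FALSE]
  out
}

#' Restraint-violation energy of a model or structure
#'
#' The distance part is the plain (unweighted) sum over distance
#' restraints of `max(0, d - upper) + max(0, lower - d)` in Angstrom; the
#' dihedral part, reported separately in degrees, sums the wrapped
#' angular deviation beyond each restraint's tolerance.  Restricting to
#' `tags = "contact"` gives the classic "sum of distance deviation from
#' the threshold over all supplied contacts" bookkeeping used to verify
#' that low model accuracy reflects missing information rather than
#' unsatisfied restraints.
#'
#' @param model a `cg_model` or [chain_structure()] with coordinates for
#'   every referenced atom (virtual C-beta attached when needed).
#' @param set a `restraint_set`.
#' @param tags optional character vector restricting the evaluation to
#'   restraints with these tags.
#' @return list with `distance` (Angstrom), `dihedral` (degrees),
#'   `by_tag` (named distance-energy breakdown) and `n_violated`.
#' @export
restraint_energy <- function(model, set, tags = NULL) {
  stopifnot(inherits(set, "restraint_set"))
  obj <- if (inherits(model, "cg_model")) model else model
  ca <- obj$ca
  if (max(set$distance$i, set$distance$j, set$dihedral$i + 3, 0) > nrow(ca)) {
    stop("restraint index out of range for the supplied coordinates")
  }
  if (is.null(obj$cb)) {
    seq1 <- obj$sequence %||% strrep("A", nrow(ca))
    obj$cb <- cpp_virtual_cbeta(ca, strsplit(seq1, "")[[1]] == "G")
  }
  d <- set$distance
  q <- set$dihedral
  if (!is.null(tags)) {
    d <- d[d$tag %in% tags, , drop = FALSE]
    q <- q[q$tag %in% tags, , drop = FALSE]
  }
  dist_e <- 0
  n_viol <- 0L
  by_tag <- numeric(0)
  if (nrow(d)) {
    p1 <- atom_coords(obj, d$atom_i, d$i)
    p2 <- atom_coords(obj, d$atom_j, d$j)
    dd <- sqrt(rowSums((p1 - p2)^2))
    viol <- pmax(0, dd - d$upper) + pmax(0, d$lower - dd)
    dist_e <- sum(viol)
    n_viol <- sum(viol > 0)
    by_tag <- vapply(split(viol, d$tag), sum, numeric(1))
  }
  dih_e <- 0
  if (nrow(q)) {
    th <- vapply(q$i, function(i) {
      dihedral_angle(ca[i, ], ca[i + 1, ], ca[i + 2, ], ca[i + 3, ])
    }, numeric(1))
    dev <- pmax(0, abs(wrap_deg(th - q$target)) - q$tolerance)
    dih_e <- sum(dev)
    n_viol <- n_viol + sum(dev > 0)
  }
  list(distance = dist_e, dihedral = dih_e, by_tag = by_tag,
       n_violated = n_viol)
}

#' Serialize a restraint set to TSV
#'
#' One restraint per row with columns type (`dist`/`dihedral`), i, j,
#' atom_i, atom_j, lower, upper, target, tolerance, weight, tag.
#'
#' @param set a `restraint_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_restraints <- function(set, path) {
  d <- set$distance
  q <- set$dihedral
  rows <- rbind(
    if (nrow(d)) data.frame(type = "dist", i = d$i, j = d$j,
                            atom_i = d$atom_i, atom_j = d$atom_j,
                            lower = d$lower, upper = d$upper,
                            target = NA_real_, tolerance = NA_real_,
                            weight = d$weight, tag = d$tag),
    if (nrow(q)) data.frame(type = "dihedral", i = q$i, j = NA_integer_,
                            atom_i = "CA", atom_j = "CA",
                            lower = NA_real_, upper = NA_real_,
                            target = q$target, tolerance = q$tolerance,
                            weight = q$weight, tag = q$tag))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a restraint set written by [write_restraints()]
#'
#' @param path TSV path.
#' @param target_id identifier.
#' @param L chain length (default: largest referenced index).
#' @return a `restraint_set`.
#' @export
read_restraints <- function(path, target_id = "target", L = NULL) {
  rows <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  d <- rows[rows$type == "dist", , drop = FALSE]
  q <- rows[rows$type == "dihedral", , drop = FALSE]
  L <- L %||% max(d$j, d$i, q$i + 3, 0)
  restraint_set(target_id, L,
                distance = if (nrow(d))
                  data.frame(i = d$i, j = d$j, atom_i = d$atom_i,
                             atom_j = d$atom_j, lower = d$lower,
                             upper = d$upper, weight = d$weight,
                             tag = d$tag) else empty_distance_df(),
                dihedral = if (nrow(q))
                  data.frame(i = q$i, target = q$target,
                             tolerance = q$tolerance, weight = q$weight,
                             tag = q$tag) else empty_dihedral_df())
}
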