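# Contact maps: derivation from structures, separation classes,
# non-contacts, and sequence-separation filters.

new_contact_map <- function(pairs, target_id, L, threshold_t, min_sep,
                            atom = "CB") {
  rownames(pairs) <- NULL
  x <- list(target_id = target_id, L = as.integer(L), pairs = pairs,
            atom = atom, threshold_t = threshold_t,
            min_sep = as.integer(min_sep))
  class(x) <- "contact_map"
  x
}

#' @export
print.contact_map <- function(x, ...) {
  cat("contact_map", x$target_id, ": L =", x$L, ",", nrow(x$pairs),
      "pairs, t =", x$threshold_t, "A, min_sep =", x$min_sep, "\n")
  invisible(x)
}

#' Sequence-separation class of a contact
#'
#' Residue pairs separated by fewer than 6 positions are `local`, 6--11
#' `short`, 12--23 `medium`, and 24 or more `long`.
#'
#' @param sep integer vector of sequence separations `j - i` (>= 1).
#' @return character vector over \{local, short, medium, long\}.
#' @export
classify_separation <- function(sep) {
  sep <- as.integer(sep)
  if (any(sep < 1)) stop("sequence separation must be >= 1")
  cut_labels <- c("local", "short", "medium", "long")
  cls <- cut_labels[findInterval(sep, c(1, 6, 12, 24))]
  cls
}

# effective contact atoms: C-beta, C-alpha for glycine
contact_atoms <- function(structure) {
  structure <- virtual_cbeta(structure)
  structure$cb
}

#' Derive the true contact map of a structure
#'
#' Residue pairs are in contact when the distance between their C-beta
#' atoms (C-alpha in glycine) is strictly less than `t` Angstrom and the
#' sequence separation is at least `min_sep`.  Each pair carries its true
#' distance and separation class.
#'
#' @param structure a [chain_structure()]; virtual C-beta atoms are
#'   attached if absent.
#' @param t distance threshold in Angstrom (> 0); the widely used default
#'   is 8.
#' @param min_sep minimum sequence separation (>= 1); the standard contact
#'   definition uses 6, and `min_sep = 1` gives the complete contact map.
#' @return a `contact_map`.
#' @export
derive_contact_map <- function(structure, t = 8, min_sep = 6) {
  stopifnot(t > 0, min_sep >= 1)
  L <- chain_length(structure)
  if (L < min_sep + 1) {
    warning("chain too short for min_sep = ", min_sep, "; empty contact map")
    pairs <- data.frame(i = integer(0), j = integer(0), sep = integer(0),
                        cls = character(0), distance = numeric(0))
    return(new_contact_map(pairs, structure$chain_id, L, t, min_sep))
  }
  cb <- contact_atoms(structure)
  D <- as.matrix(stats::dist(cb))
  idx <- which(upper.tri(D), arr.ind = TRUE)
  sep <- idx[, 2] - idx[, 1]
  keep <- sep >= min_sep & D[idx] < t
  idx <- idx[keep, , drop = FALSE]
  pairs <- data.frame(i = as.integer(idx[, 1]), j = as.integer(idx[, 2]),
                      sep = as.integer(idx[, 2] - idx[, 1]),
                      distance = D[idx])
  pairs <- pairs[order(pairs$i, pairs$j), , drop = FALSE]
  pairs$cls <- if (nrow(pairs)) classify_separation(pairs$sep) else character(0)
  pairs <- pairs[, c("i", "j", "sep", "cls", "distance")]
  new_contact_map(pairs, structure$chain_id, L, t, min_sep)
}

#' Non-contacts of a true contact map
#'
#' Returns every residue pair at eligible sequence separation
#' (`sep >= min_sep` of the map) that is not a contact.  Together with the
#' contacts this partitions the candidate pair set exactly.  When the
#' source structure is supplied, true distances are attached (used to keep
#' restraint sets derived from a native structure self-consistent).
#'
#' @param map a `contact_map` derived from a true structure.
#' @param structure optional source [chain_structure()].
#' @return data frame with columns `i`, `j`, `sep` (and `distance` when
#'   `structure` is given).
#' @export
derive_noncontacts <- function(map, structure = NULL) {
  stopifnot(inherits(map, "contact_map"))
  L <- map$L
  idx <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  sep <- idx[, 2] - idx[, 1]
  idx <- idx[sep >= map$min_sep, , drop = FALSE]
  key_all <- paste(idx[, 1], idx[, 2])
  key_contact <- paste(map$pairs$i, map$pairs$j)
  keep <- !(key_all %in% key_contact)
  out <- data.frame(i = as.integer(idx[keep, 1]),
                    j = as.integer(idx[keep, 2]))
  out$sep <- out$j - out$i
  if (!is.null(structure)) {
    cb <- contact_atoms(structure)
    out$distance <- sqrt(rowSums((cb[out$i, , drop = FALSE] -
                                  cb[out$j, , drop = FALSE])^2))
  }
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter a contact map by minimum sequence separation
#'
#' Retains pairs with `sep >= s`; `s = 0` and `s = 1` both keep every
#' pair.  The retained pair count is non-increasing in `s`.
#'
#' @param map a `contact_map`.
#' @param s minimum sequence separation (>= 0).
#' @return the filtered `contact_map`.
#' @export
filter_by_min_sep <- function(map, s) {
  stopifnot(inherits(map, "contact_map"), s >= 0)
  s <- max(as.integer(s), 1L)
  pairs <- map$pairs[map$pairs$sep >= s, , drop = FALSE]
  new_contact_map(pairs, map$target_id, map$L, map$threshold_t,
                  max(map$min_sep, s), atom = map$atom)
}

#' Export a contact map as a 3-column table
#'
#' @param map a `contact_map`.
#' @param path output TSV path (columns i, j, value where value is the
#'   true distance or the prediction confidence).
#' @return `path`, invisibly.
#' @export
write_contact_tsv <- function(map, path) {
  p <- map$pairs
  value <- if ("distance" %in% names(p) && !all(is.na(p$distance))) {
    p$distance
  } else {
    p$confidence
  }
  utils::write.table(data.frame(i = p$i, j = p$j, value = value), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
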