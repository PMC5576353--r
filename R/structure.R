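# Structure data model: a single protein chain at C-alpha/C-beta resolution.

#' Construct a chain structure
#'
#' A `chain_structure` holds one protein chain at coarse-grained resolution:
#' the one-letter sequence, an L x 3 matrix of C-alpha coordinates, optional
#' C-beta and backbone coordinates, and an optional 3-state secondary
#' structure string over \{H, E, C\}.
#'
#' @param sequence one-letter amino-acid string of length L.
#' @param ca L x 3 numeric matrix of C-alpha coordinates (Angstrom).
#' @param cb optional L x 3 matrix of C-beta coordinates; rows may be `NA`
#'   for residues without an observed C-beta (see [virtual_cbeta()]).
#' @param ss3 optional secondary-structure string over \{H, E, C\}, length L.
#' @param chain_id chain identifier.
#' @param backbone optional named list of L x 3 matrices (`n`, `c`, `o`).
#' @param resno_author original author residue numbering (metadata only;
#'   all indices used by the package are contiguous and 1-based).
#' @return an object of class `chain_structure`.
#' @export
chain_structure <- function(sequence, ca, cb = NULL, ss3 = NULL,
                            chain_id = "A", backbone = NULL,
                            resno_author = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  L <- nchar(sequence)
  if (L < 1) stop("sequence must have length >= 1")
  ca <- as.matrix(ca)
  if (!is.numeric(ca) || ncol(ca) != 3 || nrow(ca) != L) {
    stop("ca must be an L x 3 numeric matrix (L = ", L, ")")
  }
  if (!is.null(cb)) {
    cb <- as.matrix(cb)
    if (ncol(cb) != 3 || nrow(cb) != L) stop("cb must be L x 3")
  }
  if (!is.null(ss3)) {
    ss3 <- validate_ss3(ss3)
    if (nchar(ss3) != L) stop("ss3 must have length L = ", L)
  }
  x <- list(chain_id = chain_id, sequence = sequence, ca = ca, cb = cb,
            ss3 = ss3, backbone = backbone,
            resno_author = resno_author %||% seq_len(L))
  class(x) <- "chain_structure"
  x
}

#' @export
print.chain_structure <- function(x, ...) {
  cat("chain_structure", x$chain_id, " L =", chain_length(x),
      if (!is.null(x$cb)) "(with CB)" else "(CA only)",
      if (!is.null(x$ss3)) paste0("ss3: ", substr(x$ss3, 1, 40)) else "",
      "\n")
  invisible(x)
}

#' Chain length
#' @param structure a [chain_structure()].
#' @return integer number of residues L.
#' @export
chain_length <- function(structure) nchar(structure$sequence)

# validate / normalize a 3-state SS string; errors on foreign characters
validate_ss3 <- function(ss3) {
  stopifnot(is.character(ss3), length(ss3) == 1L)
  ss3 <- toupper(ss3)
  bad <- setdiff(strsplit(ss3, "")[[1]], c("H", "E", "C"))
  if (length(bad)) stop("ss3 contains characters outside {H,E,C}: ",
                        paste(unique(bad), collapse = ""))
  ss3
}

#' Physical-validity check of a chain
#'
#' Flags (does not error on) consecutive C-alpha distances outside the
#' physically plausible 2.9--4.1 Angstrom window.
#'
#' @param structure a [chain_structure()].
#' @return list with `bond_lengths`, logical `bonds_ok` per bond, and
#'   overall flag `valid`.
#' @export
validate_chain <- function(structure) {
  ca <- structure$ca
  L <- nrow(ca)
  if (L < 2) return(list(bond_lengths = numeric(0), bonds_ok = logical(0),
                         valid = TRUE))
  b <- sqrt(rowSums((ca[-1, , drop = FALSE] - ca[-L, , drop = FALSE])^2))
  ok <- b >= 2.9 & b <= 4.1
  list(bond_lengths = b, bonds_ok = ok, valid = all(ok))
}

#' Reduce 8-state DSSP codes to 3-state secondary structure
#'
#' Alpha-helix (`H`) and strand (`E`) are kept; every other DSSP
#' assignment (`G`, `I`, `B`, `T`, `S`, blank, `-`) becomes coil (`C`).
#' Characters outside the DSSP alphabet also map to coil, with a warning.
#'
#' @param ss8 character string of per-residue DSSP codes.
#' @return 3-state string over \{H, E, C\}, same length as `ss8`.
#' @export
reduce_dssp_to_3state <- function(ss8) {
  stopifnot(is.character(ss8), length(ss8) == 1L)
  if (nchar(ss8) == 0) return("")
  ch <- strsplit(ss8, "")[[1]]
  known <- c("H", "G", "I", "E", "B", "T", "S", " ", "-", "C")
  unknown <- setdiff(unique(ch), known)
  if (length(unknown)) {
    warning("unknown secondary-structure codes mapped to coil: ",
            paste(unknown, collapse = ""))
  }
  out <- ifelse(ch == "H", "H", ifelse(ch == "E", "E", "C"))
  paste(out, collapse = "")
}

#' Read a 3-state secondary structure file
#'
#' Accepts either a plain text file whose first non-empty line is the
#' H/E/C string, or the PSIPRED SS2 dialect (columns: index, residue,
#' state, three probabilities); only the state column of an SS2 file is
#' used.
#'
#' @param path file path.
#' @return 3-state secondary-structure string.
#' @export
read_ss <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty secondary-structure file: ", path)
  body <- lines[!grepl("^#", lines)]
  fields <- strsplit(trimws(body), "\\s+")
  nf <- lengths(fields)
  if (all(nf >= 3) && all(grepl("^[0-9]+$", vapply(fields, `[`, "", 1L)))) {
    # SS2 dialect: one residue per line, third column is the state
    states <- vapply(fields, `[`, "", 3L)
    return(validate_ss3(paste(states, collapse = "")))
  }
  validate_ss3(gsub("\\s", "", body[1]))
}

# --- amino-acid code tables -------------------------------------------------

# parent mapping for common non-standard residues retained at read time
.nonstandard_parent <- c(MSE = "MET", SEC = "CYS", PYL = "LYS", HYP = "PRO",
                         SEP = "SER", TPO = "THR", PTR = "TYR", CSO = "CYS",
                         MLY = "LYS", M3L = "LYS", KCX = "LYS")

aa_three_to_one <- function(resid) {
  resid <- toupper(resid)
  parent <- .nonstandard_parent[resid]
  resid[!is.na(parent)] <- parent[!is.na(parent)]
  one <- bio3d::aa321(resid)
  one[is.na(one) | one == "X" | nchar(one) != 1] <- "X"
  one
}

aa_one_to_three <- function(one) {
  three <- bio3d::aa123(toupper(one))
  three[is.na(three) | three == "UNK" | nchar(three) != 3] <- "UNK"
  three
}

# --- PDB input --------------------------------------------------------------

#' Read one chain of a PDB file as a chain structure
#'
#' Reads ATOM/HETATM records, keeps altloc blank or 'A', selects one chain
#' and one MODEL, and returns a [chain_structure()] with C-alpha (required),
#' plus C-beta and backbone N/C/O where present.  Residues without a
#' C-alpha are dropped (with a message) and residue numbering is
#' re-indexed to contiguous 1-based positions; the author numbering is
#' kept as metadata.  Non-standard residues with a C-alpha (e.g. MSE) are
#' mapped to their parent amino acid where known, else 'X'.
#'
#' @param path PDB file path.
#' @param chain chain identifier; default takes the first chain in file.
#' @param model_index which MODEL of a multi-model file to read (default 1).
#' @return a [chain_structure()].
#' @export
read_pdb <- function(path, chain = NULL, model_index = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  at <- pdb$atom
  keep <- at$alt %in% c("", "A") | is.na(at$alt)
  at <- at[keep, , drop = FALSE]
  chains <- unique(at$chain)
  if (is.null(chain)) chain <- chains[1]
  if (!chain %in% chains) {
    stop("chain '", chain, "' not found in ", path,
         " (available: ", paste(chains, collapse = ", "), ")")
  }
  at <- at[at$chain == chain, , drop = FALSE]
  # coordinates of the requested MODEL
  xyz <- pdb$xyz
  if (is.matrix(xyz) && nrow(xyz) > 1) {
    if (model_index > nrow(xyz)) {
      stop("model_index ", model_index, " but file has ", nrow(xyz), " models")
    }
    coords <- matrix(xyz[model_index, ], ncol = 3, byrow = TRUE)
  } else {
    if (model_index != 1) stop("model_index ", model_index,
                               " but file has 1 model")
    coords <- matrix(as.numeric(xyz), ncol = 3, byrow = TRUE)
  }
  orig_rows <- as.integer(rownames(at))
  get_xyz <- function(rows) coords[orig_rows[rows], , drop = FALSE]

  reskey <- paste(at$resno, at$insert %||% "", sep = "_")
  res_order <- unique(reskey)
  ca_rows <- vapply(res_order, function(k) {
    idx <- which(reskey == k & at$elety == "CA")
    if (length(idx)) idx[1] else NA_integer_
  }, integer(1))
  has_ca <- !is.na(ca_rows)
  if (!any(has_ca)) stop("no C-alpha atoms found for chain ", chain)
  if (any(!has_ca)) {
    message(sum(!has_ca), " residue(s) without C-alpha dropped")
  }
  res_order <- res_order[has_ca]
  ca_rows <- ca_rows[has_ca]
  L <- length(res_order)

  atom_rows <- function(name) {
    vapply(res_order, function(k) {
      idx <- which(reskey == k & at$elety == name)
      if (length(idx)) idx[1] else NA_integer_
    }, integer(1))
  }
  fill <- function(rows) {
    m <- matrix(NA_real_, L, 3)
    ok <- !is.na(rows)
    if (any(ok)) m[ok, ] <- get_xyz(rows[ok])
    m
  }
  ca <- get_xyz(ca_rows)
  cb <- fill(atom_rows("CB"))
  bb <- list(n = fill(atom_rows("N")), c = fill(atom_rows("C")),
             o = fill(atom_rows("O")))
  seq1 <- paste(aa_three_to_one(at$resid[ca_rows]), collapse = "")
  if (all(is.na(cb))) cb <- NULL
  if (all(is.na(bb$n)) && all(is.na(bb$c))) bb <- NULL
  chain_structure(sequence = seq1, ca = ca, cb = cb, chain_id = chain,
                  backbone = bb, resno_author = at$resno[ca_rows])
}

# --- PDB output -------------------------------------------------------------

format_atom_record <- function(serial, name, resname, chain, resno, xyz) {
  pad_name <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, pad_name, resname, substr(chain, 1, 1), resno,
          xyz[1], xyz[2], xyz[3], 1.00, 0.00, substr(name, 1, 1))
}

# assemble the ATOM records of one chain_structure (used for single- and
# multi-model writers); returns character vector, and the final serial
chain_atom_records <- function(structure, serial0 = 0L) {
  L <- chain_length(structure)
  seq1 <- strsplit(structure$sequence, "")[[1]]
  res3 <- aa_one_to_three(seq1)
  lines <- character(0)
  serial <- serial0
  for (i in seq_len(L)) {
    put <- function(name, xyz) {
      serial <<- serial + 1L
      lines <<- c(lines, format_atom_record(serial, name, res3[i],
                                            structure$chain_id, i, xyz))
    }
    if (!is.null(structure$backbone) && !anyNA(structure$backbone$n[i, ])) {
      put("N", structure$backbone$n[i, ])
    }
    put("CA", structure$ca[i, ])
    if (!is.null(structure$backbone) && !anyNA(structure$backbone$c[i, ])) {
      put("C", structure$backbone$c[i, ])
    }
    if (!is.null(structure$backbone) && !is.null(structure$backbone$o) &&
        !anyNA(structure$backbone$o[i, ])) {
      put("O", structure$backbone$o[i, ])
    }
    if (!is.null(structure$cb) && !anyNA(structure$cb[i, ]) && seq1[i] != "G") {
      put("CB", structure$cb[i, ])
    }
  }
  list(lines = lines, serial = serial)
}

#' Write a chain structure as a PDB file
#'
#' Emits standard fixed-width ATOM records (C-alpha, plus C-beta and
#' backbone atoms when present) with contiguous 1-based residue numbering
#' and occupancy 1.00.
#'
#' @param structure a [chain_structure()] with C-alpha coordinates.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "chain_structure"))
  if (chain_length(structure) < 1 || is.null(structure$ca)) {
    stop("structure has no C-alpha coordinates")
  }
  allxyz <- c(structure$ca, structure$cb, unlist(structure$backbone))
  if (any(abs(allxyz) > 9999, na.rm = TRUE)) {
    stop("coordinates exceed the PDB fixed-width field limit (|x| > 9999)")
  }
  rec <- chain_atom_records(structure)
  writeLines(c(rec$lines, "TER", "END"), path)
  invisible(path)
}

#' Write an ensemble of models as a multi-MODEL PDB file
#'
#' @param ensemble a `cg_ensemble` (see [reconstruct_ensemble()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "cg_ensemble"))
  out <- character(0)
  for (k in seq_along(ensemble$models)) {
    m <- ensemble$models[[k]]
    s <- model_to_structure(m)
    rec <- chain_atom_records(s)
    out <- c(out, sprintf("MODEL     %4d", k), rec$lines, "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

# --- virtual C-beta ---------------------------------------------------------

# Known tetrahedral construction of CB from backbone N, CA, C coordinates.
tetrahedral_cbeta <- function(n, ca, c) {
  b <- ca - n
  cc <- c - ca
  a <- cross3(b, cc)
  -0.58273431 * a + 0.56802827 * b - 0.54067466 * cc + ca
}

#' Attach virtual C-beta atoms to a chain
#'
#' Fills missing C-beta coordinates.  For glycine the C-beta is the
#' C-alpha itself.  Residues with full backbone N/CA/C get the standard
#' tetrahedral construction.  For pure C-alpha traces the C-beta is placed
#' at 1.53 Angstrom from C-alpha(i) in the local frame of C-alpha(i-1),
#' C-alpha(i), C-alpha(i+1), pointing away from the local chain bisector;
#' terminal residues copy the orientation of their nearest interior
#' neighbour.  Existing (non-`NA`) C-beta rows are kept.  C-alpha
#' coordinates are never modified and the construction is deterministic.
#'
#' @param structure a [chain_structure()].
#' @return the structure with a complete `cb` matrix.
#' @export
virtual_cbeta <- function(structure) {
  stopifnot(inherits(structure, "chain_structure"))
  L <- chain_length(structure)
  seq1 <- strsplit(structure$sequence, "")[[1]]
  is_gly <- seq1 == "G"
  cb <- structure$cb
  if (is.null(cb)) cb <- matrix(NA_real_, L, 3)
  need <- apply(cb, 1, anyNA)
  if (!any(need)) return(structure)
  # tetrahedral placement where backbone is available
  if (!is.null(structure$backbone)) {
    bbok <- !apply(structure$backbone$n, 1, anyNA) &
      !apply(structure$backbone$c, 1, anyNA)
    use <- need & bbok & !is_gly
    for (i in which(use)) {
      cb[i, ] <- tetrahedral_cbeta(structure$backbone$n[i, ],
                                   structure$ca[i, ],
                                   structure$backbone$c[i, ])
    }
    need <- need & !use
  }
  cb[need & is_gly, ] <- structure$ca[need & is_gly, , drop = FALSE]
  need <- need & !is_gly
  if (any(need)) {
    if (L < 3) stop("C-alpha-only C-beta construction requires L >= 3")
    virt <- cpp_virtual_cbeta(structure$ca, is_gly)
    cb[need, ] <- virt[need, , drop = FALSE]
  }
  structure$cb <- cb
  structure
}
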