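# CASP RR contact-prediction format: read/write and ranked selections.

new_predicted_contact_list <- function(entries, target_id, L,
                                       sequence = NULL) {
  entries <- entries[order(-entries$confidence, entries$i, entries$j), ,
                     drop = FALSE]
  rownames(entries) <- NULL
  x <- list(target_id = target_id, L = as.integer(L),
            sequence = sequence, entries = entries)
  class(x) <- "predicted_contact_list"
  x
}

#' @export
print.predicted_contact_list <- function(x, ...) {
  cat("predicted_contact_list", x$target_id, ": L =", x$L, ",",
      nrow(x$entries), "ranked entries\n")
  invisible(x)
}

#' Read a CASP RR contact-prediction file
#'
#' Parses the standard RR dialect: optional `PFRMAT` / `TARGET` / `MODEL`
#' (and similar) header lines, optional plain sequence lines, then one
#' record per line: `i j d_low d_high confidence`.  Entries are returned
#' sorted by confidence (descending, ties by smaller i then j).  Records
#' with `i >= j` are normalized by swapping; duplicated pairs keep the
#' highest-confidence entry with a warning.
#'
#' @param path RR file path.
#' @param L chain length; inferred from the sequence lines (or the largest
#'   residue index) when missing.
#' @return a `predicted_contact_list`.
#' @export
read_rr <- function(path, L = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  target_id <- "unknown"
  sequence <- ""
  recs <- list()
  for (k in seq_along(lines)) {
    ln <- trimws(lines[k])
    if (!nzchar(ln)) next
    if (grepl("^(PFRMAT|MODEL|AUTHOR|METHOD|REMARK|END)", ln)) next
    if (grepl("^TARGET", ln)) {
      target_id <- trimws(sub("^TARGET", "", ln))
      next
    }
    if (grepl("^[A-Za-z]+$", ln)) {  # sequence line
      sequence <- paste0(sequence, ln)
      next
    }
    f <- strsplit(ln, "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(f))
    if (length(f) != 5 || anyNA(v)) {
      stop("malformed RR record at line ", k, ": '", lines[k], "'")
    }
    recs[[length(recs) + 1]] <- v
  }
  if (!length(recs)) stop("no RR records found in ", path)
  m <- do.call(rbind, recs)
  df <- data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]),
                   d_low = m[, 3], d_high = m[, 4], confidence = m[, 5])
  swap <- df$i >= df$j
  if (any(swap)) {
    tmp <- df$i[swap]
    df$i[swap] <- df$j[swap]
    df$j[swap] <- tmp
  }
  if (any(df$i == df$j)) stop("RR record with i == j")
  key <- paste(df$i, df$j)
  if (anyDuplicated(key)) {
    warning("duplicated residue pairs in RR file; keeping highest confidence")
    df <- df[order(-df$confidence), , drop = FALSE]
    df <- df[!duplicated(paste(df$i, df$j)), , drop = FALSE]
  }
  if (is.null(L)) {
    L <- if (nzchar(sequence)) nchar(sequence) else max(df$j)
  }
  new_predicted_contact_list(df, target_id = target_id, L = L,
                             sequence = if (nzchar(sequence)) sequence)
}

#' Write a predicted contact list in CASP RR format
#'
#' Numeric fields are written with 6 significant digits, so a
#' write/read round trip is stable.
#'
#' @param list a `predicted_contact_list`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rr <- function(list, path) {
  stopifnot(inherits(list, "predicted_contact_list"))
  out <- c("PFRMAT RR", paste("TARGET", list$target_id), "MODEL 1")
  if (!is.null(list$sequence)) {
    out <- c(out, substring(list$sequence,
                            seq(1, nchar(list$sequence), 50),
                            pmin(seq(1, nchar(list$sequence), 50) + 49,
                                 nchar(list$sequence))))
  }
  e <- list$entries
  out <- c(out, sprintf("%d %d %.6g %.6g %.6g",
                        e$i, e$j, e$d_low, e$d_high, e$confidence), "END")
  writeLines(out, path)
  invisible(path)
}

#' Select the top x*L predicted contacts
#'
#' Takes the `floor(x * L)` highest-confidence entries (ties at the cut
#' broken by smaller i, then smaller j) and returns them as a
#' `contact_map` carrying prediction confidences.
#'
#' @param list a `predicted_contact_list` (sorted by construction).
#' @param x positive selection factor; `x = 1` is the common top-L choice.
#' @param L chain length (default from the list).
#' @param t nominal contact threshold attached to the selection
#'   (default 8 Angstrom, the definition the predictions target).
#' @return a `contact_map` whose pairs carry `confidence`.
#' @export
select_top_xl <- function(list, x, L = NULL, t = 8) {
  stopifnot(inherits(list, "predicted_contact_list"), x > 0)
  L <- L %||% list$L
  n <- floor(x * L)
  if (n == 0) stop("floor(x * L) = 0: no contacts selected")
  e <- list$entries
  if (n > nrow(e)) {
    warning("requested ", n, " contacts but list has ", nrow(e))
    n <- nrow(e)
  }
  sel <- e[seq_len(n), , drop = FALSE]
  pairs <- data.frame(i = sel$i, j = sel$j, sep = sel$j - sel$i,
                      cls = classify_separation(sel$j - sel$i),
                      distance = NA_real_, confidence = sel$confidence)
  new_contact_map(pairs, list$target_id, L, threshold_t = t,
                  min_sep = min(pairs$sep))
}

#' Select predicted non-contacts by confidence cutoff
#'
#' Returns every entry with confidence strictly below `cutoff` (the
#' low-ranked tail of a ranked prediction, used as repulsive restraints).
#'
#' @param list a `predicted_contact_list`.
#' @param cutoff finite confidence cutoff; -1 and -2 are the studied
#'   values.
#' @param min_sep minimum sequence separation applied to the selection
#'   (default 6, matching the contact pair universe).
#' @return data frame with columns `i`, `j`, `sep`, `confidence` (possibly
#'   empty).
#' @export
select_noncontacts_from_predictions <- function(list, cutoff = -1,
                                                min_sep = 6) {
  stopifnot(inherits(list, "predicted_contact_list"), is.finite(cutoff))
  e <- list$entries
  sel <- e[e$confidence < cutoff & (e$j - e$i) >= min_sep, , drop = FALSE]
  data.frame(i = sel$i, j = sel$j, sep = sel$j - sel$i,
             confidence = sel$confidence, row.names = NULL)
}
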