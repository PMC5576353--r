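# Model-vs-reference quality metrics: optimal-superposition RMSD,
# TM-score, GDT-TS, and best-of-N selection.  Residue correspondence is
# positional (reconstruction of the same sequence), so no alignment step
# is involved, and only proper rotations are ever applied: the mirror
# image of a chiral structure scores strictly worse than the structure.

coords_of <- function(x) {
  if (inherits(x, "chain_structure")) return(x$ca)
  if (inherits(x, "cg_model")) return(x$ca)
  as.matrix(x)
}

#' Optimal rigid superposition (Kabsch)
#'
#' Finds the proper rotation (determinant +1; reflections never applied)
#' and translation of `B` minimizing the RMSD to `A`.
#'
#' @param A,B n x 3 coordinate matrices, n >= 3, equal sizes.
#' @return list with `R` (rotation applied to centred B), `rmsd`, and
#'   `Bfit` (B superposed onto A).
#' @export
kabsch_superpose <- function(A, B) {
  A <- coords_of(A); B <- coords_of(B)
  n <- nrow(A)
  if (n < 3 || nrow(B) != n) stop("need two equal coordinate sets, n >= 3")
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  if (max(svd(Ac)$d) < 1e-9) warning("degenerate (collapsed) coordinates")
  M <- t(Bc) %*% Ac
  s <- svd(M)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  Bfit <- sweep(Bc %*% R, 2, ca, `+`)
  list(R = R, rmsd = sqrt(mean(rowSums((A - Bfit)^2))), Bfit = Bfit)
}

#' Optimal-superposition RMSD
#'
#' @param A,B coordinate matrices or [chain_structure()] objects.
#' @return RMSD in Angstrom after Kabsch superposition.
#' @export
rmsd_opt <- function(A, B) kabsch_superpose(A, B)$rmsd

#' TM-score normalization length d0
#'
#' `d0 = 1.24 (L - 15)^(1/3) - 1.8`, clamped to >= 0.5 for short chains
#' (the formula goes non-positive below L of about 21, where TM-score is
#' known to be uninformative anyway).
#'
#' @param L reference length.
#' @return d0 in Angstrom.
#' @export
tm_d0 <- function(L) {
  max(0.5, 1.24 * (max(L - 15, 0))^(1 / 3) - 1.8)
}

# GDT seed windows: short fragments scanned at a stride that keeps the
# seed count roughly constant in L (LGA-style heuristic), plus global and
# half-length superpositions
gdt_seed_fragments <- function(L) {
  out <- list()
  for (len in unique(pmax(3, c(4, 7, floor(L / 2), L)))) {
    if (len > L) next
    stride <- if (len <= 8) max(2, floor(L / 12)) else max(1, floor(len / 2))
    offs <- unique(c(seq(1, L - len + 1, by = stride), L - len + 1))
    for (o in offs) out[[length(out) + 1]] <- c(o, len)
  }
  out
}

# tiny chains: every residue triple and quadruple as superposition
# seeds, so the search is effectively exhaustive where an exhaustive
# check is feasible
all_small_seeds <- function(L) {
  c(utils::combn(L, 3, simplify = FALSE),
    utils::combn(L, 4, simplify = FALSE),
    utils::combn(L, 5, simplify = FALSE))
}

# candidate seed fragments (start, length) for the iterative searches
seed_fragments <- function(L, lengths = NULL) {
  lengths <- lengths %||% unique(pmax(4, c(L, floor(L / 2), floor(L / 4))))
  out <- list()
  for (len in lengths) {
    if (len > L) next
    step <- max(1, floor(len / 2))
    offs <- unique(c(seq(1, L - len + 1, by = step), L - len + 1))
    for (o in offs) out[[length(out) + 1]] <- c(o, len)
  }
  out
}

# iterative superposition extension: from a seed subset, superpose,
# reselect residues within d_cut, repeat; returns the best value of
# `score_fn` (computed from all-residue distances) over the trajectory.
iterate_superpose <- function(mod, ref, seed_idx, d_cut, score_fn,
                              max_iter = 20) {
  idx <- seed_idx
  best <- -Inf
  for (it in seq_len(max_iter)) {
    if (length(idx) < 3) break
    fit <- kabsch_superpose(ref[idx, , drop = FALSE],
                            mod[idx, , drop = FALSE])
    # apply the same transform to the whole model
    cm <- colMeans(mod[idx, , drop = FALSE])
    cr <- colMeans(ref[idx, , drop = FALSE])
    allfit <- sweep(sweep(mod, 2, cm) %*% fit$R, 2, cr, `+`)
    d <- sqrt(rowSums((allfit - ref)^2))
    best <- max(best, score_fn(d))
    nidx <- which(d < d_cut)
    if (length(nidx) < 3) nidx <- order(d)[1:4]
    if (identical(nidx, idx)) break
    idx <- nidx
  }
  best
}

#' TM-score of a model against a reference
#'
#' `TM = max (1/L) sum 1 / (1 + (d_i / d0)^2)` over superpositions, with
#' `d0` from [tm_d0()] and L the reference length.  The maximization uses
#' the standard iterative search: contiguous seed fragments of length L,
#' L/2 and L/4 at staggered offsets, each followed by
#' superpose/reselect iterations at several distance cutoffs.
#'
#' @param model,reference [chain_structure()] objects or n x 3 matrices
#'   with identical length.
#' @return list with `tm`, `d0`, `n_common`.
#' @export
tm_score <- function(model, reference) {
  mod <- coords_of(model); ref <- coords_of(reference)
  L <- nrow(ref)
  if (nrow(mod) != L) stop("model/reference length mismatch")
  d0 <- tm_d0(L)
  score_fn <- function(d) mean(1 / (1 + (d / d0)^2))
  best <- 0
  # selection cutoffs span tight (near-d0) to permissive superpositions;
  # short chains (small d0) need the tight end to find the small,
  # accurately superposable subsets that dominate their TM-score
  cuts <- unique(pmax(0.8, c(8, 4.5, 3.5, 2, 1, d0 + 0.5)))
  lens <- if (L <= 20) unique(pmax(3, c(3, 4, floor(L / 2), L))) else NULL
  seeds <- lapply(seed_fragments(L, lengths = lens), function(fr) {
    fr[1]:(fr[1] + fr[2] - 1)
  })
  if (L <= 10) seeds <- c(seeds, all_small_seeds(L))
  for (idx in seeds) {
    for (dc in cuts) {
      best <- max(best, iterate_superpose(mod, ref, idx, dc, score_fn))
    }
  }
  list(tm = best, d0 = d0, n_common = L)
}

# GDT-style iteration with greedy prefix extension: from a seed subset,
# fit, rank residues by deviation, and try the k-closest prefixes around
# the within-cutoff selection, keeping the best-scoring subset as the
# next state.
gdt_iterate <- function(mod, ref, seed_idx, cut, max_iter = 10) {
  L <- nrow(ref)
  idx <- seed_idx
  best <- 0
  fit_count <- function(sub) {
    f <- kabsch_superpose(ref[sub, , drop = FALSE],
                          mod[sub, , drop = FALSE])
    cm <- colMeans(mod[sub, , drop = FALSE])
    cr <- colMeans(ref[sub, , drop = FALSE])
    allfit <- sweep(sweep(mod, 2, cm) %*% f$R, 2, cr, `+`)
    sqrt(rowSums((allfit - ref)^2))
  }
  for (it in seq_len(max_iter)) {
    d <- fit_count(idx)
    best <- max(best, sum(d <= cut))
    ord <- order(d)
    n_in <- sum(d <= cut)
    sizes <- unique(pmin(L, pmax(3, c(n_in, n_in + 1, n_in + 2))))
    cand <- lapply(sizes, function(k) sort(ord[seq_len(k)]))
    scores <- vapply(cand, function(s) sum(fit_count(s) <= cut),
                     numeric(1))
    best <- max(best, max(scores))
    nxt <- cand[[which.max(scores)]]
    if (identical(nxt, idx)) break
    idx <- nxt
  }
  best
}

#' GDT-TS of a model against a reference
#'
#' Mean over the cutoffs 1, 2, 4, 8 Angstrom of the maximum percentage of
#' C-alpha pairs superposable within the cutoff, each cutoff maximized
#' independently by multi-seed superposition extension.  Reported on the
#' 0--100 scale.
#'
#' @param model,reference [chain_structure()] objects or n x 3 matrices.
#' @return GDT-TS in [0, 100].
#' @export
gdt_ts <- function(model, reference) {
  mod <- coords_of(model); ref <- coords_of(reference)
  L <- nrow(ref)
  if (nrow(mod) != L) stop("model/reference length mismatch")
  seeds <- lapply(gdt_seed_fragments(L), function(fr) {
    fr[1]:(fr[1] + fr[2] - 1)
  })
  if (L <= 10) seeds <- c(seeds, all_small_seeds(L))
  total <- 0
  for (cut in c(1, 2, 4, 8)) {
    best <- 0
    for (idx in seeds) {
      best <- max(best, gdt_iterate(mod, ref, idx, cut))
    }
    total <- total + 100 * best / L
  }
  total / 4
}

#' Evaluate a model against a reference structure
#'
#' @param model a `cg_model`, [chain_structure()], or coordinate matrix.
#' @param reference the reference [chain_structure()] (same length).
#' @return one-row data frame with `rmsd`, `tm`, `gdt_ts`, `d0`,
#'   `n_common`.
#' @export
evaluate_model <- function(model, reference) {
  tm <- tm_score(model, reference)
  data.frame(rmsd = rmsd_opt(model, reference), tm = tm$tm,
             gdt_ts = gdt_ts(model, reference), d0 = tm$d0,
             n_common = tm$n_common)
}

#' Best model of an ensemble by a chosen metric
#'
#' Evaluates every model against the reference and returns the best by
#' the chosen metric (maximum for `tm` and `gdt`, minimum for `rmsd`);
#' ties are broken by lower energy, then lower seed.
#'
#' @param ensemble a `cg_ensemble` (possibly pooled over stages).
#' @param reference the reference [chain_structure()].
#' @param metric one of `"tm"`, `"rmsd"`, `"gdt"`.
#' @return list with `model`, `eval` (its evaluation row), `index`, and
#'   `evals` (all evaluation rows).
#' @export
best_of_n <- function(ensemble, reference, metric = c("tm", "rmsd", "gdt")) {
  metric <- match.arg(metric)
  stopifnot(inherits(ensemble, "cg_ensemble"))
  if (!length(ensemble$models)) stop("empty ensemble")
  # score every model by the selection metric; the full evaluation (all
  # three metrics) is computed for the winner only
  scores <- vapply(ensemble$models, function(m) {
    switch(metric,
           tm = tm_score(m, reference)$tm,
           gdt = gdt_ts(m, reference),
           rmsd = rmsd_opt(m, reference))
  }, numeric(1))
  key <- if (metric == "rmsd") scores else -scores
  en <- vapply(ensemble$models, `[[`, numeric(1), "energy")
  sd <- vapply(ensemble$models, `[[`, numeric(1), "seed")
  idx <- order(key, en, sd)[1]
  evals <- data.frame(metric = metric, score = scores)
  list(model = ensemble$models[[idx]],
       eval = evaluate_model(ensemble$models[[idx]], reference),
       index = idx, evals = evals)
}
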