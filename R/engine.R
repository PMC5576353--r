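# Distance-geometry reconstruction engine: bound smoothing, randomized
# metric embedding, flat-bottom penalty minimization, mirror-image
# resolution, and the two-stage refinement protocol.

#' Engine control parameters
#'
#' @param maxit maximum minimizer iterations per model (default 5000).
#' @param pgtol projected-gradient convergence tolerance (default 1e-4).
#' @param factr relative function-decrease stopping factor for L-BFGS-B.
#' @param tag_weights named multipliers applied to restraint weights per
#'   tag during minimization (the reported energy is always unweighted).
#' @param dihedral_weight weight of pseudo-dihedral penalty terms.
#' @param dihedral_scale angle-to-arc-length factor (Angstrom per radian)
#'   making angular and distance penalties commensurate.
#' @param default_upper distance bound used where no restraint applies
#'   (effectively unbounded, default 200 Angstrom).
#' @param chirality_maxit iterations of the brief re-minimization after a
#'   mirror flip.
#' @param stage2_jitter Gaussian jitter (Angstrom) applied to stage-2
#'   starting coordinates for seeds after the first.
#' @param n_hops perturb-and-reminimize rounds per model (basin hopping;
#'   the L-BFGS-B line search can stall on the piecewise-quadratic
#'   penalty, and seeded kicks of `hop_sigma` Angstrom followed by
#'   re-minimization reliably escape such points).
#' @param hop_sigma kick size in Angstrom for the hopping rounds.
#' @param embed_maxit iterations of the preliminary minimization against
#'   the full smoothed-bound matrices right after embedding.
#' @param huber violation width (Angstrom) beyond which the quadratic
#'   penalty switches to a linear asymptote (soft-square behaviour).
#' @return list of control parameters.
#' @export
engine_control <- function(maxit = 5000, pgtol = 1e-4, factr = 1e4,
                           tag_weights = c(chain = 10, steric = 2,
                                           contact = 1, noncontact = 1,
                                           ss_distance = 2, ss_hbond = 2),
                           dihedral_weight = 1, dihedral_scale = 3.8,
                           default_upper = 200, chirality_maxit = 500,
                           stage2_jitter = 0.05, n_hops = 6,
                           hop_sigma = 1.5, embed_maxit = 300,
                           huber = 2) {
  list(maxit = maxit, pgtol = pgtol, factr = factr,
       tag_weights = tag_weights, dihedral_weight = dihedral_weight,
       dihedral_scale = dihedral_scale, default_upper = default_upper,
       chirality_maxit = chirality_maxit, stage2_jitter = stage2_jitter,
       n_hops = n_hops, hop_sigma = hop_sigma, embed_maxit = embed_maxit,
       huber = huber)
}

# encode a restraint set into the flat vectors consumed by cpp_penalty
encode_terms <- function(set, sequence = NULL, control = engine_control()) {
  L <- set$L
  seq1 <- sequence %||% strrep("A", L)
  is_gly <- strsplit(seq1, "")[[1]] == "G"
  d <- set$distance
  w <- control$tag_weights[d$tag]
  w[is.na(w)] <- 1
  q <- set$dihedral
  list(L = L, is_gly = is_gly,
       d_i = as.integer(d$i - 1L), d_j = as.integer(d$j - 1L),
       d_ai = as.integer(d$atom_i == "CB"),
       d_aj = as.integer(d$atom_j == "CB"),
       d_lo = as.numeric(d$lower),
       d_hi = as.numeric(ifelse(is.finite(d$upper), d$upper, 1e8)),
       d_w = as.numeric(d$weight * w),
       q_i = as.integer(q$i - 1L),
       q_target = q$target * pi / 180,
       q_tol = q$tolerance * pi / 180,
       q_w = as.numeric(q$weight * control$dihedral_weight))
}

make_objective <- function(terms, control) {
  cache <- new.env(parent = emptyenv())
  compute <- function(par) {
    if (!is.null(cache$par) && identical(cache$par, par)) return(cache$val)
    v <- cpp_penalty(par, terms$is_gly, terms$d_i, terms$d_j, terms$d_ai,
                     terms$d_aj, terms$d_lo, terms$d_hi, terms$d_w,
                     terms$q_i, terms$q_target, terms$q_tol, terms$q_w,
                     control$dihedral_scale, control$huber)
    cache$par <- par
    cache$val <- v
    v
  }
  list(fn = function(par) compute(par)$energy,
       gr = function(par) compute(par)$grad)
}

minimize_coords <- function(ca0, terms, control, maxit = control$maxit,
                            n_hops = 0) {
  obj <- make_objective(terms, control)
  run <- function(par) {
    stats::optim(par, obj$fn, obj$gr, method = "L-BFGS-B",
                 control = list(maxit = maxit, pgtol = control$pgtol,
                                factr = control$factr))
  }
  opt <- run(as.vector(ca0))
  # basin hopping: seeded kicks + re-minimization with a shrinking kick
  # size, keeping the best minimum found
  sched <- c(1.3, 1, 0.8, 0.65, 0.5, 0.4, 0.35, 0.3)
  for (h in seq_len(n_hops)) {
    sig <- control$hop_sigma * sched[min(h, length(sched))]
    cand <- run(opt$par + rnorm(length(opt$par), sd = sig))
    if (cand$value < opt$value) opt <- cand
    if (opt$value < 1e-8) break
  }
  matrix(opt$par, ncol = 3)
}

# flat-bottom terms over every residue pair from smoothed bound matrices,
# used as a preliminary objective right after embedding (global topology)
bounds_terms <- function(bounds) {
  L <- nrow(bounds$lower)
  idx <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  lo <- bounds$lower[idx]
  keep <- lo > 0 | bounds$upper[idx] < Inf
  idx <- idx[keep, , drop = FALSE]
  list(L = L, is_gly = rep(FALSE, L),
       d_i = as.integer(idx[, 1] - 1L), d_j = as.integer(idx[, 2] - 1L),
       d_ai = integer(nrow(idx)), d_aj = integer(nrow(idx)),
       d_lo = bounds$lower[idx], d_hi = bounds$upper[idx],
       d_w = rep(1, nrow(idx)),
       q_i = integer(0), q_target = numeric(0), q_tol = numeric(0),
       q_w = numeric(0))
}

#' Smoothed distance-bound matrices for a restraint set
#'
#' Initializes per-pair lower/upper bound matrices from the distance
#' restraints (default upper `default_upper`; C-beta restraints are
#' mapped to C-alpha bounds with a 1.53 Angstrom pad per C-beta
#' endpoint), then tightens upper bounds with repeated triangle-inequality
#' passes (all-pairs shortest paths) and raises lower bounds with the
#' inverse triangle rule.  Contradictory restraints (lower > upper for
#' some pair, before or after smoothing) raise an infeasibility error.
#'
#' @param L chain length.
#' @param set a `restraint_set` including chain restraints.
#' @param control an [engine_control()] list.
#' @return list with L x L matrices `lower` and `upper`.
#' @export
build_smoothed_bounds <- function(L, set, control = engine_control()) {
  ub <- matrix(control$default_upper, L, L)
  lb <- matrix(0, L, L)
  diag(ub) <- diag(lb) <- 0
  d <- set$distance
  pad <- 1.53 * ((d$atom_i == "CB") + (d$atom_j == "CB"))
  lo <- pmax(0, d$lower - pad)
  hi <- ifelse(is.finite(d$upper), d$upper + pad, Inf)
  for (r in seq_len(nrow(d))) {
    i <- d$i[r]; j <- d$j[r]
    lb[i, j] <- lb[j, i] <- max(lb[i, j], lo[r])
    if (is.finite(hi[r])) ub[i, j] <- ub[j, i] <- min(ub[i, j], hi[r])
  }
  bad <- which(lb > ub, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("infeasible restraints: lower > upper for pair (",
         bad[1, 1], ", ", bad[1, 2], ")")
  }
  ub <- cpp_smooth_upper(ub)
  lb <- cpp_smooth_lower(lb, ub, passes = 2L)
  if (any(lb > ub + 1e-6)) {
    bad <- which(lb > ub + 1e-6, arr.ind = TRUE)
    stop("infeasible restraints after bound smoothing at pair (",
         bad[1, 1], ", ", bad[1, 2], ")")
  }
  list(lower = lb, upper = ub)
}

# Random embedding from smoothed bounds (consumes RNG).  The smoothed
# upper bounds behave like geodesic distance estimates (shortest paths
# through the contact graph), so the distance guess is the upper bound
# scaled by mild per-pair noise; this preserves global topology far
# better than uniform sampling between the bounds.
embed_from_bounds <- function(bounds) {
  L <- nrow(bounds$lower)
  W <- matrix(runif(L * L, 0.75, 1.0), L, L)
  W <- (W + t(W)) / 2
  D <- pmax(bounds$upper * W, bounds$lower)
  diag(D) <- 0
  D2 <- D^2
  # classical double-centering: B = -0.5 J D2 J
  rm <- rowMeans(D2); gm <- mean(D2)
  B <- -0.5 * (D2 - outer(rm, rep(1, L)) - outer(rep(1, L), rm) + gm)
  ev <- eigen(B, symmetric = TRUE)
  lam <- pmax(ev$values[1:3], 1e-6)
  ev$vectors[, 1:3, drop = FALSE] %*% diag(sqrt(lam), 3)
}

new_model <- function(ca, seq1, seed, stage, set) {
  cb <- cpp_virtual_cbeta(ca, strsplit(seq1, "")[[1]] == "G")
  m <- list(ca = ca, cb = cb, seed = seed, stage = stage, energy = NA_real_)
  class(m) <- "cg_model"
  e <- restraint_energy(m, set)
  m$energy <- e$distance
  m$dihedral_energy <- e$dihedral
  m
}

#' @export
print.cg_model <- function(x, ...) {
  cat("cg_model: L =", nrow(x$ca), ", seed =", x$seed, ", stage =", x$stage,
      ", energy =", signif(x$energy, 4), "A\n")
  invisible(x)
}

#' Convert a reconstructed model to a chain structure
#'
#' @param model a `cg_model`.
#' @param sequence optional sequence (default poly-alanine).
#' @param ss3 optional secondary-structure string.
#' @return a [chain_structure()].
#' @export
model_to_structure <- function(model, sequence = NULL, ss3 = NULL) {
  L <- nrow(model$ca)
  chain_structure(sequence = sequence %||% (model$sequence %||% strrep("A", L)),
                  ca = model$ca, cb = model$cb, ss3 = ss3,
                  chain_id = "A")
}

sort_models <- function(models) {
  ord <- order(vapply(models, `[[`, numeric(1), "energy"),
               vapply(models, `[[`, numeric(1), "seed"))
  models[ord]
}

new_ensemble <- function(models, target_id, sequence, stage, set_id = NULL) {
  x <- list(target_id = target_id, models = sort_models(models),
            sequence = sequence, stage = stage,
            restraint_set_id = set_id)
  class(x) <- "cg_ensemble"
  x
}

#' @export
print.cg_ensemble <- function(x, ...) {
  en <- vapply(x$models, `[[`, numeric(1), "energy")
  cat("cg_ensemble", x$target_id, ": ", length(x$models), " models (stage ",
      x$stage, "), energy ", signif(min(en), 3), "..",
      signif(max(en), 3), " A\n", sep = "")
  invisible(x)
}

#' Resolve the mirror image of a reconstructed model
#'
#' Distance restraints are mirror-symmetric, so embedding can return the
#' left-handed enantiomer.  The handedness statistic is the mean C-alpha
#' pseudo-dihedral over helix quadruples (from `ss3` when given, else
#' over all quadruples whose pseudo-dihedral magnitude falls in the
#' helical range 25--75 degrees).  If the mean is negative the
#' coordinates are reflected (and briefly re-minimized when a restraint
#' set is supplied).  With no helical signal the model is returned
#' unchanged with a warning.
#'
#' @param model a `cg_model` (L >= 4).
#' @param ss3 optional secondary-structure string.
#' @param set optional `restraint_set` used to re-minimize after a flip.
#' @param sequence optional sequence (glycine handling).
#' @param control an [engine_control()] list.
#' @param quiet suppress the no-signal warning.
#' @return the (possibly reflected) `cg_model`.
#' @export
fix_chirality <- function(model, ss3 = NULL, set = NULL, sequence = NULL,
                          control = engine_control(), quiet = FALSE) {
  ca <- model$ca
  L <- nrow(ca)
  if (L < 4) return(model)
  th <- pseudo_dihedrals(ca)
  if (!is.null(ss3)) {
    runs <- ss_runs(ss3, "H")
    sel <- unlist(lapply(seq_len(nrow(runs)), function(r) {
      if (runs$len[r] >= 4) runs$start[r]:(runs$end[r] - 3) else integer(0)
    }))
    stat <- th[sel]
  } else {
    stat <- th[abs(th) > 25 & abs(th) < 75]
  }
  if (!length(stat)) {
    if (!quiet) warning("no helical signal; chirality left unresolved")
    return(model)
  }
  if (mean(stat) >= 0) return(model)
  ca[, 3] <- -ca[, 3]
  if (!is.null(set)) {
    terms <- encode_terms(set, sequence, control)
    ca <- minimize_coords(ca, terms, control,
                          maxit = control$chirality_maxit)
    seq1 <- sequence %||% strrep("A", L)
    return(new_model(ca, seq1, model$seed, model$stage, set))
  }
  model$ca <- ca
  model$cb <- NULL
  seq1 <- sequence %||% strrep("A", L)
  model$cb <- cpp_virtual_cbeta(ca, strsplit(seq1, "")[[1]] == "G")
  model
}

#' Reconstruct an ensemble of coarse-grained models
#'
#' For each seed, samples a random distance matrix inside the smoothed
#' bounds, embeds it (classical metric embedding on the top three
#' eigenvectors), minimizes the flat-bottom quadratic penalty
#' `sum w * max(0, d - ub)^2 + sum w * max(0, lb - d)^2` plus wrapped
#' dihedral excesses with L-BFGS-B, resolves the mirror image, and
#' recomputes the unweighted restraint-violation energy.  Chain
#' connectivity restraints are added automatically when absent.  Fully
#' deterministic given `base_seed`.
#'
#' @param set a `restraint_set`.
#' @param n_models ensemble size (default 20).
#' @param base_seed integer base seed; model k uses `base_seed + k - 1`.
#' @param sequence optional one-letter sequence (glycine C-beta handling).
#' @param ss3 optional secondary structure for mirror resolution.
#' @param control an [engine_control()] list.
#' @return a `cg_ensemble` with models sorted by energy (ascending).
#' @export
reconstruct_ensemble <- function(set, n_models = 20, base_seed = 1,
                                 sequence = NULL, ss3 = NULL,
                                 control = engine_control()) {
  stopifnot(inherits(set, "restraint_set"), n_models >= 1)
  L <- set$L
  if (!any(set$distance$tag == "chain")) {
    set <- combine_restraints(set, chain_restraints(L, set$target_id))
  }
  seq1 <- sequence %||% strrep("A", L)
  bounds <- build_smoothed_bounds(L, set, control)
  terms <- encode_terms(set, seq1, control)
  bterms <- bounds_terms(bounds)
  models <- vector("list", n_models)
  for (k in seq_len(n_models)) {
    seed_k <- as.integer(base_seed + k - 1)
    set.seed(seed_k)
    x0 <- embed_from_bounds(bounds)
    x0 <- minimize_coords(x0, bterms, control, maxit = control$embed_maxit)
    ca <- minimize_coords(x0, terms, control, n_hops = control$n_hops)
    m <- new_model(ca, seq1, seed_k, 1L, set)
    m <- fix_chirality(m, ss3 = ss3, set = set, sequence = seq1,
                       control = control, quiet = TRUE)
    models[[k]] <- m
  }
  new_ensemble(models, set$target_id, seq1, stage = 1L)
}

# per-restraint distance violations of a model (Angstrom)
restraint_violations <- function(model, set) {
  d <- set$distance
  if (!nrow(d)) return(numeric(0))
  obj <- model
  if (is.null(obj$cb)) {
    obj$cb <- cpp_virtual_cbeta(obj$ca, rep(FALSE, nrow(obj$ca)))
  }
  p1 <- atom_coords(obj, d$atom_i, d$i)
  p2 <- atom_coords(obj, d$atom_j, d$j)
  dd <- sqrt(rowSums((p1 - p2)^2))
  pmax(0, dd - d$upper) + pmax(0, d$lower - dd)
}

#' Stage-2 refinement of a reconstructed ensemble
#'
#' Contact-tagged restraints violated by more than `violation_cut`
#' Angstrom in the stage-1 best (lowest-energy) model are dropped, and
#' each seed re-minimizes from the stage-1 best model's coordinates (with
#' a small seeded jitter for seeds after the first) under the filtered
#' set.  If nothing is dropped, stage 2 is a pure re-minimization.
#'
#' @param ensemble the stage-1 `cg_ensemble`.
#' @param set the `restraint_set` used for stage 1.
#' @param violation_cut violation threshold in Angstrom (default 2.0).
#' @param base_seed base seed for the stage-2 jitter (default: reuse the
#'   stage-1 seeds).
#' @param control an [engine_control()] list.
#' @param ss3 optional secondary structure for mirror resolution.
#' @return a stage-2 `cg_ensemble`; the number of dropped restraints is
#'   attached as attribute `dropped`.
#' @export
stage2_refine <- function(ensemble, set, violation_cut = 2.0,
                          base_seed = NULL, control = engine_control(),
                          ss3 = NULL) {
  stopifnot(inherits(ensemble, "cg_ensemble"))
  if (!any(set$distance$tag == "chain")) {
    set <- combine_restraints(set, chain_restraints(set$L, set$target_id))
  }
  best <- ensemble$models[[1]]
  viol <- restraint_violations(best, set)
  drop <- set$distance$tag == "contact" & viol > violation_cut
  set2 <- set
  set2$distance <- set$distance[!drop, , drop = FALSE]
  seq1 <- ensemble$sequence
  terms <- encode_terms(set2, seq1, control)
  n <- length(ensemble$models)
  models <- vector("list", n)
  for (k in seq_len(n)) {
    seed_k <- ensemble$models[[k]]$seed
    ca0 <- best$ca
    if (k > 1 && control$stage2_jitter > 0) {
      set.seed(as.integer((base_seed %||% 0) + seed_k))
      ca0 <- ca0 + matrix(rnorm(length(ca0), sd = control$stage2_jitter),
                          nrow(ca0), 3)
    }
    ca <- minimize_coords(ca0, terms, control, n_hops = 2)
    m <- new_model(ca, seq1, seed_k, 2L, set2)
    m <- fix_chirality(m, ss3 = ss3, set = set2, sequence = seq1,
                       control = control, quiet = TRUE)
    models[[k]] <- m
  }
  out <- new_ensemble(models, ensemble$target_id, seq1, stage = 2L)
  attr(out, "dropped") <- sum(drop)
  out
}

#' Pool the models of several ensembles
#'
#' @param ... `cg_ensemble` objects of the same target.
#' @return a `cg_ensemble` containing all models (sorted by energy).
#' @export
pool_ensembles <- function(...) {
  es <- list(...)
  models <- do.call(c, lapply(es, `[[`, "models"))
  new_ensemble(models, es[[1]]$target_id, es[[1]]$sequence,
               stage = NA_integer_)
}

#' Ensemble manifest
#'
#' @param ensemble a `cg_ensemble`.
#' @return data frame with seed, stage and energy per model.
#' @export
ensemble_manifest <- function(ensemble) {
  data.frame(seed = vapply(ensemble$models, `[[`, numeric(1), "seed"),
             stage = vapply(ensemble$models, `[[`, numeric(1), "stage"),
             energy = vapply(ensemble$models, `[[`, numeric(1), "energy"))
}
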