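# Independent brute-force oracles.  These deliberately avoid the package's
# own code paths (beyond trivial accessors) so that agreement is evidence,
# not tautology.

# effective contact atoms: CB rows, CA for glycine, via the package's
# public virtual_cbeta (the map derivation itself is re-done by hand)
oracle_atoms <- function(structure) {
  s <- virtual_cbeta(structure)
  s$cb
}

# all-pairs double loop contact map
oracle_contact_map <- function(structure, t, min_sep) {
  cb <- oracle_atoms(structure)
  L <- nrow(cb)
  out <- list()
  for (i in seq_len(L - 1)) {
    for (j in (i + 1):L) {
      if (j - i < min_sep) next
      d <- sqrt(sum((cb[i, ] - cb[j, ])^2))
      if (d < t) out[[length(out) + 1]] <- c(i, j, d)
    }
  }
  if (!length(out)) {
    return(data.frame(i = integer(0), j = integer(0), distance = numeric(0)))
  }
  m <- do.call(rbind, out)
  data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]),
             distance = m[, 3])
}

oracle_noncontacts <- function(structure, t, min_sep) {
  cb <- oracle_atoms(structure)
  L <- nrow(cb)
  out <- list()
  for (i in seq_len(L - 1)) {
    for (j in (i + 1):L) {
      if (j - i < min_sep) next
      d <- sqrt(sum((cb[i, ] - cb[j, ])^2))
      if (d >= t) out[[length(out) + 1]] <- c(i, j)
    }
  }
  if (!length(out)) return(data.frame(i = integer(0), j = integer(0)))
  m <- do.call(rbind, out)
  data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]))
}

# straight-line restraint-energy recomputation
oracle_energy <- function(structure, set) {
  s <- virtual_cbeta(structure)
  e <- 0
  d <- set$distance
  for (r in seq_len(nrow(d))) {
    p <- if (d$atom_i[r] == "CB") s$cb[d$i[r], ] else s$ca[d$i[r], ]
    q <- if (d$atom_j[r] == "CB") s$cb[d$j[r], ] else s$ca[d$j[r], ]
    dd <- sqrt(sum((p - q)^2))
    if (dd > d$upper[r]) e <- e + (dd - d$upper[r])
    if (dd < d$lower[r]) e <- e + (d$lower[r] - dd)
  }
  e
}

# rank-based Spearman from first principles (average ranks for ties)
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# paired t statistic from the textbook formula
oracle_paired_t <- function(a, b) {
  d <- b - a
  n <- length(d)
  tstat <- mean(d) / (sqrt(sum((d - mean(d))^2) / (n - 1)) / sqrt(n))
  p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  list(t = tstat, p = p)
}

# inline Procrustes used by the metric oracles (independent of
# kabsch_superpose): proper rotation only
.oracle_fit <- function(A, B, idx) {
  ca <- colMeans(A[idx, , drop = FALSE])
  cb <- colMeans(B[idx, , drop = FALSE])
  M <- t(sweep(B[idx, , drop = FALSE], 2, cb)) %*%
    sweep(A[idx, , drop = FALSE], 2, ca)
  s <- svd(M)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sweep(sweep(B, 2, cb) %*% R, 2, ca, `+`)
}

# brute-force quaternion-grid + polish RMSD oracle
oracle_rmsd <- function(A, B, n_grid = 4000, seed = 1) {
  set.seed(seed)
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  rot_from_q <- function(q) {
    q <- q / sqrt(sum(q^2))
    a <- q[1]; b <- q[2]; cc <- q[3]; d <- q[4]
    matrix(c(a^2 + b^2 - cc^2 - d^2, 2 * (b * cc + a * d), 2 * (b * d - a * cc),
             2 * (b * cc - a * d), a^2 - b^2 + cc^2 - d^2, 2 * (cc * d + a * b),
             2 * (b * d + a * cc), 2 * (cc * d - a * b),
             a^2 - b^2 - cc^2 + d^2), 3, 3)
  }
  score <- function(q) {
    R <- rot_from_q(q)
    sqrt(mean(rowSums((Ac - Bc %*% R)^2)))
  }
  best_q <- NULL; best <- Inf
  for (k in seq_len(n_grid)) {
    q <- rnorm(4)
    v <- score(q)
    if (v < best) { best <- v; best_q <- q }
  }
  o <- stats::optim(best_q, score, method = "Nelder-Mead",
                    control = list(maxit = 2000, reltol = 1e-14))
  min(best, o$value)
}

# exhaustive-subset TM-score oracle for tiny structures (n <= 10)
oracle_tm <- function(mod, ref) {
  L <- nrow(ref)
  d0 <- max(0.5, 1.24 * (max(L - 15, 0))^(1 / 3) - 1.8)
  best <- 0
  idxs <- seq_len(L)
  for (size in 3:L) {
    combs <- utils::combn(idxs, size, simplify = FALSE)
    for (idx in combs) {
      fit <- .oracle_fit(ref, mod, idx)
      d <- sqrt(rowSums((fit - ref)^2))
      best <- max(best, mean(1 / (1 + (d / d0)^2)))
    }
  }
  best
}

# exhaustive-subset GDT-TS oracle for tiny structures
oracle_gdt <- function(mod, ref) {
  L <- nrow(ref)
  idxs <- seq_len(L)
  total <- 0
  for (cut in c(1, 2, 4, 8)) {
    best <- 0
    for (size in 3:L) {
      combs <- utils::combn(idxs, size, simplify = FALSE)
      for (idx in combs) {
        fit <- .oracle_fit(ref, mod, idx)
        d <- sqrt(rowSums((fit - ref)^2))
        best <- max(best, sum(d <= cut))
      }
    }
    total <- total + 100 * best / L
  }
  total / 4
}

# small random chain-like structure for oracle comparisons (bonded walk,
# no clash guarantees: contact-map oracles only need coordinates)
random_chain <- function(L, seed) {
  set.seed(seed)
  ca <- matrix(0, L, 3)
  dir <- c(1, 0, 0)
  for (i in 2:L) {
    dir <- dir + rnorm(3, sd = 0.8)
    dir <- dir / sqrt(sum(dir^2))
    ca[i, ] <- ca[i - 1, ] + 3.8 * dir
  }
  aa <- c("A", "G", "L", "V", "K", "S")
  chain_structure(paste(sample(aa, L, TRUE), collapse = ""), ca)
}
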