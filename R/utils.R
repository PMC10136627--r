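# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored on exit. seed = NULL leaves the RNG stream alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Subtract the channel mean at every sample: maps as columns (channels x
# samples) -> average-referenced columns.
center_columns <- function(x) {
  sweep(x, 2L, colMeans(x), "-")
}

# Row-wise centering/unit-L2 normalisation for map matrices (maps x channels).
# Rows with zero variance are left as zero rows.
normalize_rows <- function(x) {
  x <- x - rowMeans(x)
  nrm <- sqrt(rowSums(x^2))
  nrm[nrm == 0] <- 1
  x / nrm
}

# Pearson correlation of every row of A (maps x ch) with every column-map of
# templates (ch x k); both average-referenced first, signed.
map_correlation <- function(maps, templates) {
  a <- normalize_rows(maps)
  b <- normalize_rows(t(templates))
  tcrossprod(a, b)
}

# Scale an average-referenced map vector (or columns of a matrix) to unit GFP.
scale_unit_gfp <- function(maps) {
  maps <- center_columns(maps)
  g <- sqrt(colMeans(maps^2))
  g[g == 0] <- 1
  sweep(maps, 2L, g, "/")
}

# All permutations of 1..k as a matrix (k! rows); k is small (microstate
# template counts), so exhaustive enumeration is fine up to k = 8.
all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(k - 1L)
  out <- vector("list", k)
  for (pos in seq_len(k)) {
    block <- cbind(sub, k)
    if (pos < k) {
      tmp <- block[, pos]
      block[, pos] <- k
      block[, ncol(block)] <- tmp
    }
    out[[pos]] <- block
  }
  do.call(rbind, out)
}

# Optimal one-to-one assignment of rows to columns of a score matrix,
# maximising the total score. Exhaustive for k <= 8, greedy with 2-opt
# improvement beyond that.
best_assignment <- function(score) {
  k <- nrow(score)
  stopifnot(ncol(score) == k)
  if (k <= 8L) {
    perms <- all_permutations(k)
    totals <- apply(perms, 1L, function(p) sum(score[cbind(seq_len(k), p)]))
    best <- which.max(totals)
    return(list(perm = perms[best, ], total = totals[best]))
  }
  perm <- integer(k)
  free <- rep(TRUE, k)
  for (i in seq_len(k)) {
    j <- which.max(ifelse(free, score[i, ], -Inf))
    perm[i] <- j
    free[j] <- FALSE
  }
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (a in seq_len(k - 1L)) for (b in seq((a + 1L), k)) {
      cur <- score[a, perm[a]] + score[b, perm[b]]
      swp <- score[a, perm[b]] + score[b, perm[a]]
      if (swp > cur + 1e-12) {
        tmp <- perm[a]; perm[a] <- perm[b]; perm[b] <- tmp
        improved <- TRUE
      }
    }
  }
  list(perm = perm, total = sum(score[cbind(seq_len(k), perm)]))
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
}
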