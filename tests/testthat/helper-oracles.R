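## independent brute-force oracles, deliberately written with naive scalar
## loops so they share no code path with the package implementations

## fuzzy c-means by direct evaluation of the update equations
bf_fcm <- function(x, c, m, u0, tol = 1e-6, max_iter = 200) {
  n <- nrow(x); d <- ncol(x)
  u <- u0 / rowSums(u0)
  v <- matrix(0, c, d)
  v_old <- NULL
  for (it in seq_len(max_iter)) {
    for (k in seq_len(c)) {
      num <- rep(0, d); den <- 0
      for (i in seq_len(n)) {
        w <- u[i, k]^m
        num <- num + w * x[i, ]
        den <- den + w
      }
      v[k, ] <- num / den
    }
    for (i in seq_len(n)) {
      d2 <- vapply(seq_len(c), function(k) sum((x[i, ] - v[k, ])^2),
                   numeric(1))
      if (any(d2 == 0)) {
        u[i, ] <- 0
        u[i, which(d2 == 0)[1]] <- 1
      } else {
        for (k in seq_len(c)) {
          u[i, k] <- 1 / sum((d2[k] / d2)^(1 / (m - 1)))
        }
      }
    }
    if (!is.null(v_old) && max(abs(v - v_old)) < tol) break
    v_old <- v
  }
  obj <- 0
  for (i in seq_len(n)) for (k in seq_len(c)) {
    obj <- obj + u[i, k]^m * sum((x[i, ] - v[k, ])^2)
  }
  list(centers = v, membership = u, objective = obj)
}

## direct evaluation of the fuzzy objective for a given partition
bf_fcm_objective <- function(x, centers, membership, m) {
  obj <- 0
  for (i in seq_len(nrow(x))) for (k in seq_len(nrow(centers))) {
    obj <- obj + membership[i, k]^m * sum((x[i, ] - centers[k, ])^2)
  }
  obj
}

## brute-force local alignment: enumerate alignments anchored on match
## columns; between consecutive matched pairs (i,j) -> (i',j') the skipped
## residues cost one affine gap per sequence. Optimal local alignments
## start and end on match columns, so this enumeration attains the optimum.
bf_smith_waterman <- function(a, b, sub, gap_open = 11, gap_extend = 1) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  if (n == 0 || m == 0) return(0)
  gap_cost <- function(p) if (p > 0) gap_open + p * gap_extend else 0
  ## F[i,j]: best score of an alignment whose first column matches a[i],b[j]
  F <- matrix(0, n, m)
  for (i in n:1) for (j in m:1) {
    best_cont <- 0
    if (i < n && j < m) {
      for (i2 in (i + 1):n) for (j2 in (j + 1):m) {
        cont <- F[i2, j2] - gap_cost(i2 - i - 1) - gap_cost(j2 - j - 1)
        if (cont > best_cont) best_cont <- cont
      }
    }
    F[i, j] <- sub[a[i], b[j]] + best_cont
  }
  max(0, max(F))
}

## substitution matrix used by oracle tests
blosum62_x0 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  mat <- e$BLOSUM62
  mat["X", ] <- 0L
  mat[, "X"] <- 0L
  mat
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

## small fcm_fit stand-in for assignment-rule tests
fake_fcm <- function(membership) {
  structure(list(membership = membership,
                 centers = matrix(0, ncol(membership), 2),
                 m = 2, iterations = 1, objective = 0),
            class = "fcm_fit")
}
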