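#' Fuzzy c-means clustering of standardized expression profiles
#'
#' Classic fuzzy c-means with Euclidean distances: alternating updates of
#' centers \eqn{v_k = \sum_i u_{ik}^m x_i / \sum_i u_{ik}^m} and memberships
#' \eqn{u_{ik} = 1 / \sum_j (d_{ik}/d_{jk})^{2/(m-1)}}, iterated until the
#' maximum center shift drops below \code{tol} or \code{max_iter} is
#' reached. A point coincident with a center receives membership 1 there
#' (the standard singularity rule). Memberships are initialized uniformly
#' at random and row-normalized; \code{restarts} independent starts are run
#' and the solution with the lowest objective
#' \eqn{\sum_{ik} u_{ik}^m d_{ik}^2} is kept. Deterministic for a fixed
#' \code{seed}.
#'
#' @param x standardized numeric matrix (points x dimensions).
#' @param c number of clusters (>= 2).
#' @param m fuzzifier (> 1), or \code{"auto"} to use
#'   \code{\link{estimate_fuzzifier}}.
#' @param tol convergence tolerance on the maximum center shift.
#' @param max_iter maximum iterations per start.
#' @param seed integer RNG seed.
#' @param restarts number of random initializations.
#' @param init optional initial membership matrix (points x c, rows summing
#'   to 1); when given, a single start from exactly this initialization is
#'   run (used for oracle comparisons).
#' @return object of class \code{fcm_fit}: \code{centers} (c x dims),
#'   \code{membership} (points x c), \code{m}, \code{iterations},
#'   \code{objective} and \code{objective_trace}.
#' @export
fuzzy_cmeans <- function(x, c = 12, m = "auto", tol = 1e-6, max_iter = 200,
                         seed = 1L, restarts = 5L, init = NULL) {
  x <- as.matrix(x)
  stop_if_not(c >= 2, "need at least 2 clusters")
  stop_if_not(nrow(x) >= c, "need at least as many points as clusters")
  if (identical(m, "auto")) m <- estimate_fuzzifier(x)
  stop_if_not(is.numeric(m) && m > 1, "fuzzifier m must be numeric > 1")

  run_once <- function(u) {
    v_old <- NULL
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      um <- u^m
      v <- (t(um) %*% x) / colSums(um)
      # squared Euclidean distances points x centers
      d2 <- outer(rowSums(x^2), rep(1, c)) - 2 * x %*% t(v) +
        outer(rep(1, nrow(x)), rowSums(v^2))
      d2[d2 < 0] <- 0
      trace <- base::c(trace, sum(um * d2))
      u <- .fcm_membership(d2, m)
      shift <- if (is.null(v_old)) Inf else max(abs(v - v_old))
      v_old <- v
      if (shift < tol) break
    }
    um <- u^m
    d2 <- outer(rowSums(x^2), rep(1, c)) - 2 * x %*% t(v_old) +
      outer(rep(1, nrow(x)), rowSums(v_old^2))
    d2[d2 < 0] <- 0
    list(centers = v_old, membership = u, iterations = it,
         objective = sum(um * d2), objective_trace = trace)
  }

  best <- NULL
  if (!is.null(init)) {
    stop_if_not(nrow(init) == nrow(x) && ncol(init) == c,
                "init must be points x c")
    best <- run_once(init / rowSums(init))
  } else {
    with_seed(seed, {
      for (r in seq_len(restarts)) {
        u0 <- matrix(runif(nrow(x) * c), nrow(x), c)
        u0 <- u0 / rowSums(u0)
        cand <- run_once(u0)
        if (is.null(best) || cand$objective < best$objective) best <- cand
      }
    })
  }
  rownames(best$membership) <- rownames(x)
  colnames(best$membership) <- paste0("cluster_", seq_len(c))
  rownames(best$centers) <- paste0("cluster_", seq_len(c))
  colnames(best$centers) <- colnames(x)
  best$m <- m
  class(best) <- "fcm_fit"
  best
}

## membership update from squared distances, with the d = 0 singularity rule
.fcm_membership <- function(d2, m) {
  p <- 1 / (m - 1)
  w <- d2^(-p)           # unnormalized memberships; Inf where d2 == 0
  sing <- !is.finite(w)
  u <- w / rowSums(w)
  bad <- rowSums(sing) > 0
  if (any(bad)) {
    u[bad, ] <- 0
    # membership 1 to the (first) coincident center
    first <- apply(sing[bad, , drop = FALSE], 1, which.max)
    u[cbind(which(bad), first)] <- 1
  }
  u
}

#' @export
print.fcm_fit <- function(x, ...) {
  cat(sprintf("fuzzy c-means fit: %d points, %d clusters, m = %.3f\n",
              nrow(x$membership), nrow(x$centers), x$m))
  cat(sprintf("  objective %.6g after %d iterations\n",
              x$objective, x$iterations))
  sizes <- table(factor(apply(x$membership, 1, which.max),
                        levels = seq_len(nrow(x$centers))))
  cat("  argmax cluster sizes:", paste(sizes, collapse = " "), "\n")
  invisible(x)
}

#' Empirical fuzzifier estimate
#'
#' The published empirical formula for choosing the fuzzy c-means fuzzifier
#' from the data dimensions,
#' \deqn{m = 1 + (1418/N + 22.05) D^{-2} +
#'   (12.33/N + 0.243) D^{-0.0406 \ln N - 0.1134},}
#' with N points and D dimensions, clipped to [1.05, 5].
#'
#' @param x numeric matrix (points x dimensions, >= 2 points).
#' @return the fuzzifier m.
#' @export
estimate_fuzzifier <- function(x) {
  N <- nrow(x)
  D <- ncol(x)
  stop_if_not(N >= 2, "need at least 2 points")
  m <- 1 + (1418 / N + 22.05) * D^(-2) +
    (12.33 / N + 0.243) * D^(-0.0406 * log(N) - 0.1134)
  min(max(m, 1.05), 5)
}

#' Core cluster assignments from a fuzzy partition
#'
#' A gene is assigned to its maximum-membership cluster if and only if that
#' membership is at least \code{acore} (inclusive); otherwise it is left
#' unassigned (\code{NA}). Ties at the maximum go to the lowest cluster
#' index and are logged.
#'
#' @param model an \code{fcm_fit}.
#' @param acore minimum core membership in (0, 1] (default 0.7).
#' @return named integer vector of cluster indices (NA = unassigned).
#' @export
core_assignments <- function(model, acore = 0.7) {
  stop_if_not(acore > 0 && acore <= 1, "acore must be in (0, 1]")
  u <- model$membership
  top <- apply(u, 1, max)
  # which.max takes the lowest index on ties
  k <- apply(u, 1, which.max)
  n_tied <- sum(apply(u, 1, function(r) sum(r == max(r)) > 1))
  if (n_tied > 0) hgo_log(n_tied, " tied argmax membership(s); lowest index used")
  out <- ifelse(top >= acore, k, NA_integer_)
  names(out) <- rownames(u)
  out
}
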