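# Nonmetric multidimensional scaling built from first principles:
# weighted pool-adjacent-violators monotone regression, Kruskal stress-1,
# classical scaling (PCoA) for initialization, iterative majorization
# (Guttman transform on disparities) with a monotone-stress safeguard,
# and Procrustes comparison of configurations.

#' Weighted monotone (isotonic) regression
#'
#' Pool-adjacent-violators: the weighted least-squares nondecreasing fit to
#' `values` in their given order. Preserves the weighted mean and is
#' idempotent.
#'
#' @param values Numeric vector (ordered by the rank of the quantity the fit
#'   must be monotone in).
#' @param weights Positive weights, recycled scalar allowed.
#' @return Numeric vector of fitted values, nondecreasing.
#' @export
monotone_regression <- function(values, weights = 1) {
  n <- length(values)
  if (n == 0) stop("empty input to monotone_regression")
  weights <- rep_len(weights, n)
  if (any(weights <= 0) || anyNA(weights)) stop("weights must be positive")
  means <- numeric(n); ws <- numeric(n); sizes <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    top <- top + 1L
    means[top] <- values[i]; ws[top] <- weights[i]; sizes[top] <- 1L
    while (top > 1L && means[top - 1L] > means[top]) {
      w <- ws[top - 1L] + ws[top]
      means[top - 1L] <- (means[top - 1L] * ws[top - 1L] + means[top] * ws[top]) / w
      ws[top - 1L] <- w
      sizes[top - 1L] <- sizes[top - 1L] + sizes[top]
      top <- top - 1L
    }
  }
  rep(means[seq_len(top)], sizes[seq_len(top)])
}

# Disparities for a configuration: monotone fit of configuration distances
# ordered by the dissimilarity ranks. Ties in the dissimilarities follow
# Kruskal's primary approach: within a tie block, distances are taken in
# ascending order so tied dissimilarities impose no order constraint.
# Returns list(dh = configuration distances (pair vector), theta = disparities).
nmds_disparities <- function(dvec, dh) {
  ord <- order(dvec, dh)
  theta <- numeric(length(dh))
  theta[ord] <- monotone_regression(dh[ord])
  list(dh = dh, theta = theta)
}

#' Kruskal stress-1 of a configuration
#'
#' `sqrt( sum((dhat - theta)^2) / sum(dhat^2) )` over point pairs, where
#' `dhat` are the configuration's Euclidean distances and `theta` their
#' monotone regression in the order of the observed dissimilarities.
#' Zero iff the configuration distances are already rank-concordant with the
#' dissimilarities. Invariant to rotation, reflection, translation and
#' uniform scaling of `coords`.
#'
#' @param D Dissimilarities ([dissimilarity_matrix] output, `dist`, or
#'   symmetric matrix); rows of `coords` align with its points.
#' @param coords Numeric matrix, one row per point.
#' @return Stress-1 in \[0, 1\].
#' @export
stress1 <- function(D, coords) {
  D <- as_edna_dist(D)
  coords <- as.matrix(coords)
  if (nrow(coords) != length(D$point_ids))
    stop("coords rows do not match distance matrix points")
  ut <- upper.tri(D$d)
  dvec <- D$d[ut]
  dh <- as.matrix(stats::dist(coords))[ut]
  ss <- sum(dh^2)
  if (ss == 0) stop("degenerate configuration: all points coincide")
  disp <- nmds_disparities(dvec, dh)
  sqrt(sum((dh - disp$theta)^2) / ss)
}

#' Principal coordinates analysis (classical scaling)
#'
#' Eigendecomposition of the double-centered matrix `-1/2 J D^2 J`; returns
#' the axes for the top positive eigenvalues (negative-eigenvalue axes are
#' dropped, so fewer than `k` columns may be returned for strongly
#' non-Euclidean dissimilarities).
#'
#' @param D Dissimilarities (as for [stress1]).
#' @param k Number of requested axes, `1 <= k < n`.
#' @return Matrix of coordinates (points x up to `k` axes), rownames are
#'   point IDs; eigenvalues attached as attribute `"eig"`.
#' @export
pcoa <- function(D, k = 2) {
  D <- as_edna_dist(D)
  n <- length(D$point_ids)
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < number of points")
  A <- -0.5 * D$d^2
  B <- A - outer(rowMeans(A), colMeans(A), "+") + mean(A)
  e <- eigen(B, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- which(e$values > tol)
  take <- pos[seq_len(min(k, length(pos)))]
  coords <- e$vectors[, take, drop = FALSE] %*%
    diag(sqrt(e$values[take]), length(take))
  rownames(coords) <- D$point_ids
  attr(coords, "eig") <- e$values
  coords
}

# One majorization run from a given start configuration.
# The Guttman update is accepted only when it lowers stress-1; otherwise the
# step is halved toward the update. This makes the per-iteration stress trace
# nonincreasing by construction.
nmds_single_run <- function(dvec, ut, X, max_iter, tol) {
  n <- nrow(X)
  pair_stress <- function(X) {
    dh <- as.matrix(stats::dist(X))[ut]
    ss <- sum(dh^2)
    if (ss == 0) return(list(stress = Inf, dh = dh, theta = dh))
    disp <- nmds_disparities(dvec, dh)
    list(stress = sqrt(sum((dh - disp$theta)^2) / ss), dh = dh,
         theta = disp$theta)
  }
  cur <- pair_stress(X)
  trace <- cur$stress
  for (iter in seq_len(max_iter)) {
    # Guttman transform with current disparities
    ratio <- matrix(0, n, n)
    r <- ifelse(cur$dh > 0, cur$theta / cur$dh, 0)
    ratio[ut] <- r
    ratio <- ratio + t(ratio)
    Xg <- (diag(rowSums(ratio)) - ratio) %*% X / n
    alpha <- 1
    accepted <- FALSE
    for (h in 1:12) {
      Xc <- X + alpha * (Xg - X)
      cand <- pair_stress(Xc)
      if (cand$stress <= trace[length(trace)]) { accepted <- TRUE; break }
      alpha <- alpha / 2
    }
    if (!accepted) break
    X <- Xc; cur <- cand
    trace <- c(trace, cur$stress)
    len <- length(trace)
    if (trace[len - 1] - trace[len] < tol) break
  }
  list(X = X, stress = trace[length(trace)], trace = trace)
}

#' Nonmetric multidimensional scaling
#'
#' Multi-start nMDS minimizing Kruskal stress-1. One start is initialized
#' from [pcoa] and the remaining `n_starts - 1` from seeded random normal
#' configurations; each start alternates monotone regression of the
#' configuration distances with a majorization (Guttman) update until the
#' stress change falls below `tol` or `max_iter` iterations. The
#' lowest-stress solution is returned, centered and rotated to its principal
#' axes. `converged` is TRUE when at least two starts agree to a Procrustes
#' RMSE below 1e-4.
#'
#' @param D Dissimilarities (as for [stress1]).
#' @param k Embedding dimension (default 2).
#' @param n_starts Number of starts (default 20).
#' @param seed Integer seed governing all randomness.
#' @param max_iter,tol Per-start iteration cap (default 500) and stress
#'   tolerance (default 1e-7).
#' @return An `edna_nmds` object: `point_ids`, `coords` (points x k,
#'   column means 0), `stress`, `n_starts`, `converged`, `seed`,
#'   `stress_per_start`, `trace` (stress sequence of the best start),
#'   `degenerate` flag.
#' @export
nmds <- function(D, k = 2, n_starts = 20, seed = 1, max_iter = 500,
                 tol = 1e-7) {
  D <- as_edna_dist(D)
  n <- length(D$point_ids)
  if (n < k + 2) stop("too few points (", n, ") for a ", k, "-dimensional nMDS")
  ut <- upper.tri(D$d)
  dvec <- D$d[ut]
  degenerate <- (max(dvec) - min(dvec)) < 1e-12
  if (degenerate)
    warning("degenerate dissimilarities: all pairwise values equal; ",
            "any configuration is rank-concordant")
  set.seed(as.integer(seed))
  runs <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    if (s == 1) {
      X <- pcoa(D, k = min(k, n - 1))
      attr(X, "eig") <- NULL
      if (ncol(X) < k)   # pad missing axes with small random noise
        X <- cbind(X, matrix(stats::rnorm(n * (k - ncol(X)), sd = 1e-4),
                             n, k - ncol(X)))
    } else {
      X <- matrix(stats::rnorm(n * k), n, k)
    }
    runs[[s]] <- nmds_single_run(dvec, ut, X, max_iter, tol)
  }
  stresses <- vapply(runs, `[[`, numeric(1), "stress")
  best <- which.min(stresses)
  X <- runs[[best]]$X
  X <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(X)
  coords <- X %*% sv$v
  dimnames(coords) <- list(D$point_ids, paste0("axis", seq_len(k)))
  agree <- vapply(seq_len(n_starts), function(s) {
    if (s == best) return(FALSE)
    procrustes_rmse(runs[[best]]$X, runs[[s]]$X) < 1e-4
  }, logical(1))
  structure(list(point_ids = D$point_ids, coords = coords,
                 stress = stresses[best], n_starts = n_starts,
                 converged = any(agree) || n_starts == 1, seed = as.integer(seed),
                 stress_per_start = stresses, trace = runs[[best]]$trace,
                 traces = lapply(runs, `[[`, "trace"),
                 degenerate = degenerate),
            class = "edna_nmds")
}

#' @export
print.edna_nmds <- function(x, ...) {
  cat("nMDS (", ncol(x$coords), "-D): stress-1 = ", signif(x$stress, 4),
      ", ", x$n_starts, " starts, converged = ", x$converged, "\n", sep = "")
  invisible(x)
}

#' Procrustes root-mean-square error between configurations
#'
#' RMSE (per point) between `A` and `B` after the optimal translation,
#' uniform scaling, and rotation/reflection of `B` onto `A`; zero iff the
#' configurations are similarity-equivalent.
#'
#' @param A,B Numeric matrices of the same shape (points x axes).
#' @return Nonnegative real.
#' @export
procrustes_rmse <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B))) stop("configurations differ in shape")
  Ac <- scale(A, center = TRUE, scale = FALSE)
  Bc <- scale(B, center = TRUE, scale = FALSE)
  ssB <- sum(Bc^2)
  if (ssB == 0) return(sqrt(sum(Ac^2) / nrow(A)))
  sv <- svd(t(Bc) %*% Ac)
  rot <- sv$u %*% t(sv$v)
  s <- sum(sv$d) / ssB
  sqrt(sum((Ac - s * Bc %*% rot)^2) / nrow(A))
}

#' Write an ordination as CSV
#'
#' @param ord An `edna_nmds` (or any object with `point_ids` and `coords`).
#' @param path Output CSV path with columns `point_id, axis1..axisk`.
#' @export
write_ordination_csv <- function(ord, path) {
  df <- data.frame(point_id = ord$point_ids,
                   as.data.frame(ord$coords, check.names = FALSE),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
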