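# Pairwise community dissimilarities and analytic rarefaction, implemented
# from the formulas. Double zeros (features absent from both points) do not
# enter either measure.

#' Jaccard distance between two detection vectors
#'
#' `1 - |A intersect B| / |A union B|` where A and B are the sets of features
#' with positive counts. Counts are binarized first, so the result depends
#' only on presence/absence.
#'
#' @param x,y Equal-length nonnegative count (or 0/1) vectors.
#' @return Distance in \[0, 1\]; 0 iff the detection sets are identical.
#' @export
jaccard <- function(x, y) {
  stopifnot(length(x) == length(y))
  a <- x > 0; b <- y > 0
  u <- sum(a | b)
  if (u == 0) stop("Jaccard distance undefined: both samples are all-zero")
  1 - sum(a & b) / u
}

#' Bray-Curtis dissimilarity between two count vectors
#'
#' `sum(|x_i - y_i|) / sum(x_i + y_i)`, the abundance-weighted measure.
#'
#' @param x,y Equal-length nonnegative count vectors.
#' @return Dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y))
  denom <- sum(x) + sum(y)
  if (denom == 0) stop("Bray-Curtis dissimilarity undefined: both samples are all-zero")
  sum(abs(x - y)) / denom
}

#' All pairwise dissimilarities between sampling points
#'
#' The `jaccard` method binarizes the table first (presence/absence); the
#' `bray_curtis` method uses counts, optionally converted to per-point
#' relative abundances. All-zero point columns are an error and are named,
#' since a dissimilarity from an empty sample is undefined.
#'
#' @param table Count matrix (features x points) or [edna_dataset].
#' @param method `"jaccard"` (default) or `"bray_curtis"`.
#' @param normalize For `bray_curtis` only: divide each column by its total
#'   before comparison (default FALSE, raw counts).
#' @return An `edna_dist`: list with `point_ids`, symmetric matrix `d` with
#'   zero diagonal and entries in \[0, 1\], and `method`.
#' @export
dissimilarity_matrix <- function(table, method = c("jaccard", "bray_curtis"),
                                 normalize = FALSE) {
  method <- match.arg(method)
  m <- get_counts(table)
  if (ncol(m) < 2) stop("need >= 2 sampling points")
  zero_cols <- colSums(m) == 0
  if (any(zero_cols))
    stop("all-zero sampling point(s) after filtering: ",
         paste(colnames(m)[zero_cols], collapse = ", "))
  n <- ncol(m)
  ids <- colnames(m)
  if (method == "jaccard") {
    b <- to_presence_absence(m)
    shared <- crossprod(b)                       # |A intersect B|
    sizes <- diag(shared)
    union <- outer(sizes, sizes, "+") - shared   # |A union B|
    d <- 1 - shared / union
  } else {
    x <- m
    storage.mode(x) <- "double"
    if (normalize) x <- sweep(x, 2, colSums(x), "/")
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      xi <- x[, i]
      for (j in (i + 1):n) {
        d[i, j] <- d[j, i] <- sum(abs(xi - x[, j])) / (sum(xi) + sum(x[, j]))
      }
    }
  }
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  new_edna_dist(ids, d, method)
}

new_edna_dist <- function(point_ids, d, method) {
  structure(list(point_ids = point_ids, d = d, method = method),
            class = "edna_dist")
}

#' @export
print.edna_dist <- function(x, ...) {
  cat("edna_dist (", x$method, "): ", length(x$point_ids), " points\n", sep = "")
  invisible(x)
}

# Coerce a user-supplied distance (edna_dist, dist, or symmetric matrix)
# to edna_dist, validating symmetry and zero diagonal.
as_edna_dist <- function(D, method = "unknown") {
  if (inherits(D, "edna_dist")) return(D)
  if (inherits(D, "dist")) {
    m <- as.matrix(D)
  } else if (is.matrix(D)) {
    m <- D
  } else stop("D must be an edna_dist, dist, or symmetric matrix")
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-12 || any(diag(m) != 0))
    stop("distance matrix must be symmetric with zero diagonal")
  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(m)))
  dimnames(m) <- list(ids, ids)
  new_edna_dist(ids, m, method)
}

#' Export a distance matrix as square CSV
#'
#' @param D An `edna_dist`.
#' @param path Output CSV path; point IDs form the header row and column.
#' @export
write_dist_csv <- function(D, path) {
  D <- as_edna_dist(D)
  df <- data.frame(point_id = D$point_ids,
                   as.data.frame(D$d, check.names = FALSE),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Expected richness under rarefaction to n reads
#'
#' The analytic (hypergeometric) expectation of the number of features seen
#' in a uniform random subsample of `n` reads without replacement:
#' `sum_i [1 - C(N - N_i, n) / C(N, n)]` with `N = sum(counts)`. Terms with
#' `N - N_i < n` contribute 1. Monotone nondecreasing in `n`;
#' at `n = N` it equals the observed richness.
#'
#' @param feature_counts Nonnegative count vector for one sampling point.
#' @param n Subsample size, `0 <= n <= sum(feature_counts)`.
#' @return Expected richness (real).
#' @export
rarefaction_expected_richness <- function(feature_counts, n) {
  stopifnot(all(feature_counts >= 0))
  N <- sum(feature_counts)
  if (n < 0) stop("subsample size n must be >= 0")
  if (n > N) stop("subsample size n exceeds total reads N = ", N)
  if (n == 0) return(0)
  Ni <- feature_counts[feature_counts > 0]
  # lchoose(N - Ni, n) is -Inf when N - Ni < n, so those terms contribute 1
  sum(1 - exp(lchoose(N - Ni, n) - lchoose(N, n)))
}

#' Rarefaction curves for every sampling point
#'
#' Evaluates [rarefaction_expected_richness] on the grid
#' `n = step, 2 step, ..., N` (the point's total N always included), used to
#' judge whether read depth is sufficient before comparative analyses.
#'
#' @param table Count matrix or [edna_dataset].
#' @param step Positive integer grid step.
#' @return Data frame with columns `point_id`, `n`, `expected_richness`.
#' @export
rarefaction_curve <- function(table, step = 1) {
  stopifnot(step >= 1)
  m <- get_counts(table)
  out <- lapply(colnames(m), function(pid) {
    counts <- m[, pid]
    N <- sum(counts)
    if (N == 0) return(NULL)
    ns <- unique(c(seq(step, N, by = step), N))
    data.frame(point_id = pid, n = ns,
               expected_richness = vapply(ns, function(k)
                 rarefaction_expected_richness(counts, k), numeric(1)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
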