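# One-way PERMANOVA on a distance matrix (Anderson's distance-based
# sum-of-squares decomposition with a permutation test) and agglomerative
# hierarchical clustering with Lance-Williams updates.

align_labels <- function(D, labels) {
  ids <- D$point_ids
  if (!is.null(names(labels))) {
    if (!setequal(names(labels), ids))
      stop("label names do not match distance matrix point IDs")
    labels <- labels[ids]
  }
  if (length(labels) != length(ids))
    stop("need one group label per point")
  factor(labels)
}

#' Pseudo-F statistic from a distance matrix
#'
#' Distance-based one-way decomposition:
#' `SS_total = (1/N) sum_{i<j} d_ij^2`,
#' `SS_within = sum_g (1/n_g) sum_{i<j in g} d_ij^2`,
#' `SS_among = SS_total - SS_within`, and
#' `F = (SS_among / (a-1)) / (SS_within / (N-a))` for `a` groups of `N`
#' points in total. Perfect separation (`SS_within = 0`) yields `F = Inf`.
#'
#' @param D Dissimilarities (as for [stress1]).
#' @param labels Group assignment, one per point (named vectors are matched
#'   to point IDs).
#' @return `list(f_stat, r2, ss_total, ss_within, ss_among, df_among,
#'   df_within)`.
#' @export
pseudo_f <- function(D, labels) {
  D <- as_edna_dist(D)
  labels <- align_labels(D, labels)
  N <- length(labels)
  a <- nlevels(labels)
  if (a < 2) stop("need >= 2 groups")
  if (N <= a) stop("need more points than groups")
  D2 <- D$d^2
  ss_total <- sum(D2[upper.tri(D2)]) / N
  ss_within <- 0
  for (g in levels(labels)) {
    idx <- which(labels == g)
    if (length(idx) > 1) {
      sub <- D2[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  ss_among <- ss_total - ss_within
  f <- if (ss_within == 0) Inf else
    (ss_among / (a - 1)) / (ss_within / (N - a))
  list(f_stat = f, r2 = if (ss_total > 0) ss_among / ss_total else 0,
       ss_total = ss_total, ss_within = ss_within, ss_among = ss_among,
       df_among = a - 1L, df_within = N - a)
}

# Pseudo-F for many label assignments at once. `assign_mat` is N x m with
# integer group codes 1..a; group sizes are constant across columns
# (permutations of one multiset).
pseudo_f_batch <- function(D2, assign_mat, ss_total) {
  N <- nrow(assign_mat)
  a <- max(assign_mat)
  ng <- tabulate(assign_mat[, 1], nbins = a)
  ss_within <- numeric(ncol(assign_mat))
  for (g in seq_len(a)) {
    P <- (assign_mat == g) + 0
    # colSums(P * (D2 %*% P)) = sum over ordered within-group pairs of d^2
    ss_within <- ss_within + colSums(P * (D2 %*% P)) / (2 * ng[g])
  }
  ss_among <- ss_total - ss_within
  ifelse(ss_within == 0, Inf,
         (ss_among / (a - 1)) / (ss_within / (N - a)))
}

# All distinct arrangements of the label multiset given by `counts`
# (integer vector of group sizes), as an N x m matrix of group codes.
multiset_permutations <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(matrix(integer(0), nrow = 0, ncol = 1))
  cols <- list()
  for (g in seq_along(counts)) {
    if (counts[g] > 0) {
      sub <- counts
      sub[g] <- sub[g] - 1L
      rest <- multiset_permutations(sub)
      cols[[length(cols) + 1L]] <- rbind(rep(g, ncol(rest)), rest)
    }
  }
  do.call(cbind, cols)
}

#' One-way PERMANOVA
#'
#' Tests whether community composition differs between groups by permuting
#' whole sampling points. When the number of distinct label assignments is
#' at most `exhaustive_limit` (and `exhaustive` is not FALSE), all
#' assignments are enumerated and the exact tail proportion
#' `#(F* >= F) / #assignments` is reported; otherwise `n_perm` sampled
#' permutations give `p = (1 + #(F* >= F)) / (1 + n_perm)`, which never
#' returns 0.
#'
#' @param D Dissimilarities (as for [stress1]).
#' @param labels Group assignment (>= 2 groups).
#' @param n_perm Number of sampled permutations (default 999).
#' @param seed Integer seed for the sampled path.
#' @param exhaustive `"auto"` (default), TRUE, or FALSE.
#' @param exhaustive_limit Enumeration cutoff (default 10000 assignments).
#' @return An `edna_permanova`: `f_stat`, `r2`, `p_value`, `n_perm`,
#'   `exhaustive`, `df_among`, `df_within`, `seed`, plus the observed sums
#'   of squares.
#' @export
permanova <- function(D, labels, n_perm = 999, seed = 1,
                      exhaustive = "auto", exhaustive_limit = 10000) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  D <- as_edna_dist(D)
  labels <- align_labels(D, labels)
  obs <- pseudo_f(D, labels)
  D2 <- D$d^2
  codes <- as.integer(labels)
  counts <- tabulate(codes, nbins = nlevels(labels))
  n_distinct <- round(exp(lfactorial(sum(counts)) - sum(lfactorial(counts))))
  do_exhaustive <- isTRUE(exhaustive) ||
    (identical(exhaustive, "auto") && n_distinct <= exhaustive_limit)
  # tolerate floating jitter when comparing permuted F to the observed F
  f_cut <- if (is.finite(obs$f_stat)) obs$f_stat - 1e-10 else Inf
  if (do_exhaustive) {
    assign_mat <- multiset_permutations(counts)
    f_all <- pseudo_f_batch(D2, assign_mat, obs$ss_total)
    p <- sum(f_all >= f_cut) / ncol(assign_mat)
    n_used <- ncol(assign_mat)
  } else {
    set.seed(as.integer(seed))
    assign_mat <- vapply(seq_len(n_perm), function(i) sample(codes),
                         integer(length(codes)))
    f_all <- pseudo_f_batch(D2, assign_mat, obs$ss_total)
    p <- (1 + sum(f_all >= f_cut)) / (1 + n_perm)
    n_used <- n_perm
  }
  structure(list(f_stat = obs$f_stat, r2 = obs$r2, p_value = p,
                 n_perm = n_used, exhaustive = do_exhaustive,
                 df_among = obs$df_among, df_within = obs$df_within,
                 seed = as.integer(seed), ss_total = obs$ss_total,
                 ss_within = obs$ss_within, ss_among = obs$ss_among),
            class = "edna_permanova")
}

#' @export
print.edna_permanova <- function(x, ...) {
  cat("PERMANOVA: pseudo-F = ", signif(x$f_stat, 4), " (df ", x$df_among,
      ", ", x$df_within, "), R2 = ", signif(x$r2, 4), ", p = ",
      signif(x$p_value, 4),
      if (x$exhaustive) " (exhaustive)" else paste0(" (", x$n_perm, " permutations)"),
      "\n", sep = "")
  invisible(x)
}

#' Agglomerative hierarchical clustering
#'
#' Standard bottom-up agglomeration with Lance-Williams distance updates for
#' single, complete (default), or average linkage. Ties are broken
#' deterministically: among equally close pairs, the pair whose clusters
#' contain the earliest points (in point-ID order of the distance matrix)
#' merges first.
#'
#' @param D Dissimilarities (as for [stress1]).
#' @param linkage `"complete"`, `"single"`, or `"average"`.
#' @return An `edna_dendrogram`: `merges` (step x 2 signed indices, negative
#'   for leaves), `heights`, `leaf_ids`, `linkage`. Convert with
#'   [as.hclust()] for plotting.
#' @export
hierarchical_cluster <- function(D, linkage = c("complete", "single", "average")) {
  linkage <- match.arg(linkage)
  D <- as_edna_dist(D)
  n <- length(D$point_ids)
  if (n < 2) stop("need >= 2 points to cluster")
  cd <- D$d
  active <- seq_len(n)
  id <- -seq_len(n)
  size <- rep(1L, n)
  minleaf <- seq_len(n)
  merges <- matrix(0L, n - 1, 2)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    act <- active[order(minleaf[active])]
    besta <- bestb <- 0L
    bestd <- Inf
    for (ii in seq_len(length(act) - 1)) {
      for (jj in (ii + 1):length(act)) {
        dij <- cd[act[ii], act[jj]]
        if (dij < bestd) { bestd <- dij; besta <- act[ii]; bestb <- act[jj] }
      }
    }
    merges[step, ] <- c(id[besta], id[bestb])
    heights[step] <- bestd
    for (cc in setdiff(active, c(besta, bestb))) {
      dac <- cd[besta, cc]; dbc <- cd[bestb, cc]
      newd <- switch(linkage,
                     single = min(dac, dbc),
                     complete = max(dac, dbc),
                     average = (size[besta] * dac + size[bestb] * dbc) /
                       (size[besta] + size[bestb]))
      cd[besta, cc] <- cd[cc, besta] <- newd
    }
    id[besta] <- step
    size[besta] <- size[besta] + size[bestb]
    minleaf[besta] <- min(minleaf[besta], minleaf[bestb])
    active <- setdiff(active, bestb)
  }
  structure(list(merges = merges, heights = heights,
                 leaf_ids = D$point_ids, linkage = linkage),
            class = "edna_dendrogram")
}

#' @export
print.edna_dendrogram <- function(x, ...) {
  cat("dendrogram (", x$linkage, " linkage): ", length(x$leaf_ids),
      " leaves\n", sep = "")
  invisible(x)
}

dendrogram_leaf_order <- function(tree) {
  rec <- function(node) {
    if (node < 0) return(-node)
    c(rec(tree$merges[node, 1]), rec(tree$merges[node, 2]))
  }
  rec(nrow(tree$merges))
}

#' @export
as.hclust.edna_dendrogram <- function(x, ...) {
  structure(list(merge = x$merges, height = x$heights,
                 order = dendrogram_leaf_order(x), labels = x$leaf_ids,
                 method = x$linkage, call = match.call(),
                 dist.method = "community dissimilarity"),
            class = "hclust")
}

#' Serialize a dendrogram to newick
#'
#' Nodes are placed at half their merge height (so the tree path length
#' between two leaves equals their cophenetic distance) and branch lengths
#' are elevation differences; a two-leaf tree of height h becomes
#' `(A:h/2,B:h/2);`.
#'
#' @param tree An `edna_dendrogram`.
#' @return A newick string (single line, terminated by `;`).
#' @export
dendrogram_to_newick <- function(tree) {
  stopifnot(inherits(tree, "edna_dendrogram"))
  rec <- function(node) {
    if (node < 0)
      return(list(str = tree$leaf_ids[-node], elev = 0))
    l <- rec(tree$merges[node, 1])
    r <- rec(tree$merges[node, 2])
    elev <- tree$heights[node] / 2
    list(str = sprintf("(%s:%.12g,%s:%.12g)",
                       l$str, elev - l$elev, r$str, elev - r$elev),
         elev = elev)
  }
  paste0(rec(nrow(tree$merges))$str, ";")
}
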