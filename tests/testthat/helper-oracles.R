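# Independent brute-force oracles and tiny dataset builders used across the
# suite. Each oracle is written from the defining formula or by exhaustive
# enumeration and never calls the implementation it checks.

# Jaccard by explicit set enumeration
oracle_jaccard <- function(x, y) {
  A <- which(x > 0); B <- which(y > 0)
  1 - length(intersect(A, B)) / length(union(A, B))
}

# Bray-Curtis by elementwise sums
oracle_bray <- function(x, y) sum(abs(x - y)) / (sum(x) + sum(y))

# Expected rarefied richness by exhaustive enumeration of all C(N, n)
# subsamples (feasible for N <= 12)
oracle_rarefaction <- function(counts, n) {
  reads <- rep(seq_along(counts), counts)
  subs <- utils::combn(length(reads), n)
  mean(apply(subs, 2, function(idx) length(unique(reads[idx]))))
}

# Monte-Carlo rarefaction: mean and standard error over `draws` subsamples
mc_rarefaction <- function(counts, n, draws = 10000) {
  reads <- rep(seq_along(counts), counts)
  rich <- replicate(draws, length(unique(sample(reads, n))))
  c(mean = mean(rich), se = stats::sd(rich) / sqrt(draws))
}

# Pseudo-F by naive double loops over all point pairs
oracle_pseudo_f <- function(d, labels) {
  labels <- as.character(labels)
  N <- length(labels)
  groups <- unique(labels)
  a <- length(groups)
  ss_tot <- 0
  for (i in seq_len(N - 1)) for (j in (i + 1):N) ss_tot <- ss_tot + d[i, j]^2
  ss_tot <- ss_tot / N
  ss_w <- 0
  for (g in groups) {
    idx <- which(labels == g)
    if (length(idx) > 1) {
      s <- 0
      for (ii in seq_len(length(idx) - 1)) for (jj in (ii + 1):length(idx))
        s <- s + d[idx[ii], idx[jj]]^2
      ss_w <- ss_w + s / length(idx)
    }
  }
  ss_a <- ss_tot - ss_w
  f <- if (ss_w == 0) Inf else (ss_a / (a - 1)) / (ss_w / (N - a))
  list(f = f, r2 = ss_a / ss_tot)
}

# Weighted monotone regression by exhaustive search over consecutive-block
# partitions (the optimum is piecewise constant on blocks); n <= ~12
oracle_pava <- function(values, weights = rep(1, length(values))) {
  n <- length(values)
  best <- NULL; best_obj <- Inf
  # enumerate block boundaries via bitmask over the n-1 gaps
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    starts <- c(1, cuts + 1)
    ends <- c(cuts, n)
    fit <- numeric(n)
    means <- numeric(length(starts))
    for (b in seq_along(starts)) {
      idx <- starts[b]:ends[b]
      means[b] <- sum(values[idx] * weights[idx]) / sum(weights[idx])
      fit[idx] <- means[b]
    }
    if (all(diff(means) >= -1e-12)) {
      obj <- sum(weights * (values - fit)^2)
      if (obj < best_obj - 1e-15) { best_obj <- obj; best <- fit }
    }
  }
  best
}

# Procrustes RMSE for 2-D configurations by grid search over rotation angle
# (both orientation branches), optimal scale in closed form per angle
oracle_procrustes_2d <- function(A, B, n_grid = 400000) {
  Ac <- scale(A, scale = FALSE); Bc <- scale(B, scale = FALSE)
  ssA <- sum(Ac^2); ssB <- sum(Bc^2); n <- nrow(A)
  M <- t(Bc) %*% Ac
  best <- Inf
  th <- seq(0, 2 * pi, length.out = n_grid)
  # rotation: tr(R(th)' M); reflection: flip B's second axis first
  for (refl in c(FALSE, TRUE)) {
    Mr <- if (refl) t(Bc %*% diag(c(1, -1))) %*% Ac else M
    q <- (Mr[1, 1] + Mr[2, 2]) * cos(th) + (Mr[2, 1] - Mr[1, 2]) * sin(th)
    s <- q / ssB
    rmse2 <- (ssA - 2 * s * q + s^2 * ssB) / n
    best <- min(best, min(rmse2))
  }
  sqrt(max(best, 0))
}

# small valid dataset builder
make_points <- function(ids, station = ids, lat = 30, lon = 130, depth = 10,
                        label = "ds", control = FALSE) {
  data.frame(point_id = ids, station_id = station,
             latitude = rep_len(lat, length(ids)),
             longitude = rep_len(lon, length(ids)),
             depth_m = rep_len(depth, length(ids)),
             dataset_label = rep_len(label, length(ids)),
             is_control = rep_len(control, length(ids)),
             stringsAsFactors = FALSE)
}

make_dataset <- function(counts, ...) {
  edna_dataset(counts, make_points(colnames(counts), ...))
}

random_dataset <- function(n_feat, n_pts, seed, max_count = 20) {
  set.seed(seed)
  m <- matrix(rpois(n_feat * n_pts, 3), n_feat, n_pts,
              dimnames = list(paste0("f", seq_len(n_feat)),
                              paste0("p", seq_len(n_pts))))
  # ensure no all-zero columns
  for (j in which(colSums(m) == 0)) m[sample(n_feat, 1), j] <- 1L
  storage.mode(m) <- "integer"
  make_dataset(m, lat = runif(n_pts, 25, 35), lon = runif(n_pts, 125, 140))
}

strip_attrs <- function(x) { attributes(x) <- NULL; x }
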