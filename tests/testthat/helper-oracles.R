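# Brute-force reference implementations, kept deliberately naive and
# independent of the package's code paths.

# a perfectly regular train: period in ms, 30 s unless stated
regular_train <- function(period_ms, duration = 30, offset = period_ms / 2) {
  spike_train(seq(offset, duration * 1000, by = period_ms) / 1000,
              cell_id = sprintf("reg%g", period_ms), duration = duration)
}

poisson_train <- function(rate_hz, duration = 30, seed = 1) {
  set.seed(seed)
  n <- rpois(1, rate_hz * duration)
  spike_train(sort(runif(n, 0, duration)), cell_id = "pois",
              duration = duration)
}

random_isis <- function(n, seed) {
  set.seed(seed)
  kind <- seed %% 3
  if (kind == 0) rgamma(n, shape = 2, scale = 8) + 0.5
  else if (kind == 1) rexp(n, rate = 1 / 12) + 0.1
  else ifelse(runif(n) < 0.1, rgamma(n, 2, scale = 80),
              rgamma(n, 5, scale = 3)) + 0.1
}

# loop-based scalar feature oracles (ISIs in ms)
oracle_cv2 <- function(isis) {
  s <- 0
  for (i in 2:length(isis))
    s <- s + 2 * abs(isis[i] - isis[i - 1]) / (isis[i] + isis[i - 1])
  s / (length(isis) - 1)
}

oracle_scalars <- function(isis) {
  n <- length(isis)
  inv <- numeric(n)
  for (i in seq_len(n)) inv[i] <- 1000 / isis[i]
  m <- sum(isis) / n
  cutoff <- 5 * m
  pauses <- isis[isis > cutoff]
  counts <- table(floor(isis))
  list(mean_ifr = sum(inv) / n,
       median_ifr = median(inv),
       cv = sqrt(sum((isis - m)^2) / (n - 1)) / m,
       cv2 = oracle_cv2(isis),
       isi25 = 100 * sum(isis > 25) / n,
       isi100 = 100 * sum(isis > 100) / n,
       interburst_pause = if (length(pauses)) sum(pauses) / length(pauses)
         else 0,
       mode_fraction = 100 * max(counts) / n)
}

# O(n^2) pair-counting autocorrelogram oracle
oracle_autocorr <- function(ts, bin_ms = 5, max_lag_ms = 1000) {
  nb <- max_lag_ms / bin_ms
  counts <- numeric(nb)
  d <- outer(ts, ts, `-`)
  lags <- d[d > 0 | (d == 0 & upper.tri(d))] * 1000
  lags <- lags[lags >= 0 & lags < max_lag_ms]
  for (l in lags) {
    k <- floor(l / bin_ms) + 1
    counts[k] <- counts[k] + 1
  }
  counts
}

# naive greedy coarse-tree oracle: explicit loops over leaves, features and
# midpoint thresholds; same fixed tie rules as documented (earlier feature,
# then smaller threshold, then earlier leaf)
oracle_tree <- function(X, y, max_splits = 3) {
  y <- as.character(y)
  gini_n <- function(labs) {
    tb <- table(labs)
    (1 - sum((tb / length(labs))^2)) * length(labs)
  }
  leaves <- list(list(idx = seq_len(nrow(X)), path = ""))
  splits <- list()
  for (s in seq_len(max_splits)) {
    best <- NULL
    for (li in seq_along(leaves)) {
      idx <- leaves[[li]]$idx
      if (length(unique(y[idx])) < 2) next
      parent <- gini_n(y[idx])
      for (j in seq_along(X)) {
        vals <- sort(unique(X[[j]][idx]))
        if (length(vals) < 2) next
        for (v in seq_len(length(vals) - 1)) {
          thr <- (vals[v] + vals[v + 1]) / 2
          left <- idx[X[[j]][idx] < thr]
          right <- idx[X[[j]][idx] >= thr]
          dec <- parent - gini_n(y[left]) - gini_n(y[right])
          if (is.null(best) || dec > best$dec + 1e-9)
            best <- list(dec = dec, j = j, thr = thr, li = li)
        }
      }
    }
    if (is.null(best) || best$dec <= 1e-9) break
    L <- leaves[[best$li]]
    splits[[s]] <- list(feature = names(X)[best$j], threshold = best$thr,
                        path = L$path)
    keep <- X[[best$j]][L$idx] < best$thr
    leaves <- c(leaves[-best$li],
                list(list(idx = L$idx[keep], path = paste0(L$path, "L")),
                     list(idx = L$idx[!keep], path = paste0(L$path, "R"))))
  }
  splits
}

# independent iterative descent through a fitted signature tree
oracle_walk <- function(tree, row) {
  nd <- tree$node
  repeat {
    if (identical(nd$type, "leaf")) return(nd$label)
    nd <- if (row[[nd$feature]] < nd$threshold) nd$left else nd$right
  }
}

fit_reference_tree <- function(seed = 20240101) {
  co <- generate_archetypal_cohort(seed = seed)
  f <- featurize_cohort(co$cohort)
  list(features = f,
       tree = train_coarse_tree(f[, feature_names()], f$group_label))
}
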