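#' Gini diversity index of a class-count vector
#'
#' @param class_counts Non-negative counts, positive sum.
#' @return `1 - sum(p^2)`, in `[0, 1)`.
#' @export
gini_impurity <- function(class_counts) {
  if (any(class_counts < 0) || sum(class_counts) <= 0)
    stop("class counts must be non-negative with a positive sum")
  p <- class_counts / sum(class_counts)
  1 - sum(p^2)
}

## best (threshold, decrease) of one feature at one node; counts-weighted
## impurity so that empirical class priors are implicit
.best_split_feature <- function(x, y_int, nlev, parent_imp_n) {
  n <- length(x)
  o <- order(x)                      # stable, so ties are deterministic
  xs <- x[o]; ys <- y_int[o]
  cum <- matrix(0, n, nlev)
  for (l in seq_len(nlev)) cum[, l] <- cumsum(ys == l)
  tot <- cum[n, ]
  cut <- which(diff(xs) > 0)
  if (length(cut) == 0) return(NULL)
  nl <- cut
  gl <- 1 - rowSums((cum[cut, , drop = FALSE] / nl)^2)
  cr <- matrix(tot, length(cut), nlev, byrow = TRUE) -
    cum[cut, , drop = FALSE]
  gr <- 1 - rowSums((cr / (n - nl))^2)
  dec <- parent_imp_n - gl * nl - gr * (n - nl)
  # ties within a feature go to the smallest threshold; the tolerance
  # absorbs float noise between algebraically equal decreases
  k <- which(dec > max(dec) - 1e-9)[1]
  list(threshold = (xs[cut[k]] + xs[cut[k] + 1]) / 2, decrease = max(dec))
}

.leaf_label <- function(counts, prior_counts, levels) {
  mx <- which(counts == max(counts))
  if (length(mx) > 1) {              # tie: larger training prior, then order
    pr <- prior_counts[mx]
    mx <- mx[pr == max(pr)]
  }
  levels[mx[1]]
}

#' Fit the coarse signature tree
#'
#' Greedy best-first CART with Gini's diversity index, at most `max_splits`
#' internal nodes (default 3, i.e. at most 4 leaves) and no surrogate
#' splits. At every step the split maximizing the count-weighted impurity
#' decrease over all current leaves, features and candidate thresholds is
#' taken; candidate thresholds are midpoints between consecutive distinct
#' sorted values. Exact ties in decrease are resolved to the feature
#' earliest in the column order of `x`, then to the smaller threshold --
#' fixed rules, so the fit is invariant to row order. `x < threshold` goes
#' left, `x >= threshold` goes right. Leaf labels are the majority class
#' (ties to the class with the larger training prior, then to the
#' control < ataxia < dystonia < tremor order). Growth stops early when no
#' split decreases impurity (e.g. constant features), with a warning if an
#' impure leaf remains.
#'
#' @param x Data frame of numeric feature columns (typically the twelve in
#'   [feature_names()] order).
#' @param y Class labels (character or factor), one per row of `x`.
#' @param max_splits Maximum number of internal nodes.
#' @return An object of class `"signature_tree"`.
#' @export
train_coarse_tree <- function(x, y, max_splits = 3) {
  x <- as.data.frame(x)
  stopifnot(nrow(x) > 0, all(vapply(x, is.numeric, logical(1))))
  if (anyNA(x)) stop("missing feature values are not supported")
  lev <- if (is.factor(y)) levels(y) else
    intersect(signature_levels(), unique(as.character(y)))
  if (length(lev) == 0) lev <- sort(unique(as.character(y)))
  y <- factor(as.character(y), levels = lev)
  if (length(y) != nrow(x)) stop("x and y lengths differ")
  if (nlevels(droplevels(y)) < 2)
    stop("at least 2 classes are required")
  nlev <- nlevels(y)
  y_int <- as.integer(y)
  prior <- tabulate(y_int, nlev)

  leaves <- list(list(idx = seq_len(nrow(x)), path = ""))
  splits <- list()
  for (s in seq_len(max_splits)) {
    best <- NULL
    for (li in seq_along(leaves)) {
      idx <- leaves[[li]]$idx
      cnt <- tabulate(y_int[idx], nlev)
      if (sum(cnt > 0) < 2) next
      par_imp_n <- gini_impurity(cnt) * length(idx)
      for (j in seq_along(x)) {
        b <- .best_split_feature(x[[j]][idx], y_int[idx], nlev, par_imp_n)
        if (is.null(b)) next
        if (is.null(best) || b$decrease > best$decrease + 1e-9) {
          best <- c(b, list(j = j, li = li))
        }
        # ties (within tolerance) keep the earlier feature / earlier leaf
      }
    }
    if (is.null(best) || best$decrease <= 1e-9) break
    L <- leaves[[best$li]]
    xv <- x[[best$j]][L$idx]
    splits[[s]] <- list(feature = names(x)[best$j],
                        threshold = best$threshold,
                        path = L$path,
                        decrease = best$decrease / nrow(x))
    leaves <- c(leaves[-best$li],
                list(list(idx = L$idx[xv < best$threshold],
                          path = paste0(L$path, "L")),
                     list(idx = L$idx[xv >= best$threshold],
                          path = paste0(L$path, "R"))))
  }
  if (length(splits) < max_splits) {
    impure <- any(vapply(leaves, function(L)
      sum(tabulate(y_int[L$idx], nlev) > 0) > 1, logical(1)))
    if (impure)
      warning("stopped after ", length(splits),
              " split(s): no further impurity-reducing split")
  }

  ## assemble the recursive node structure from the split paths
  build <- function(path) {
    hit <- Filter(function(s) identical(s$path, path), splits)
    if (length(hit)) {
      s <- hit[[1]]
      list(type = "split", feature = s$feature, threshold = s$threshold,
           left = build(paste0(path, "L")), right = build(paste0(path, "R")))
    } else {
      L <- Filter(function(l) identical(l$path, path), leaves)[[1]]
      cnt <- tabulate(y_int[L$idx], nlev)
      names(cnt) <- lev
      list(type = "leaf", label = .leaf_label(cnt, prior, lev), counts = cnt)
    }
  }
  structure(list(node = build(""),
                 features = names(x),
                 class_levels = lev,
                 class_counts = stats::setNames(prior, lev),
                 n_splits = length(splits),
                 splits = lapply(splits, function(s)
                   s[c("feature", "threshold", "path", "decrease")]),
                 metadata = list()),
            class = "signature_tree")
}

#' Features actually used by a fitted tree
#' @param tree A `signature_tree`.
#' @return Character vector of distinct split features, in growth order.
#' @export
tree_features <- function(tree) {
  unique(vapply(tree$splits, `[[`, character(1), "feature"))
}

#' @export
print.signature_tree <- function(x, ...) {
  cat(sprintf("<signature_tree> %d split(s)\n", x$n_splits))
  rec <- function(nd, indent) {
    pad <- strrep("  ", indent)
    if (nd$type == "leaf") {
      cat(pad, "* ", nd$label, " (",
          paste(sprintf("%s=%d", names(nd$counts), nd$counts),
                collapse = " "), ")\n", sep = "")
    } else {
      cat(pad, nd$feature, " < ", format(nd$threshold, digits = 4), "\n",
          sep = "")
      rec(nd$left, indent + 1)
      cat(pad, nd$feature, " >= ", format(nd$threshold, digits = 4), "\n",
          sep = "")
      rec(nd$right, indent + 1)
    }
  }
  rec(x$node, 0)
  invisible(x)
}

#' Assign a signature to one or more feature vectors
#'
#' Deterministic threshold descent: values below the node threshold go
#' left, values greater than or equal to it go right. There are no
#' surrogate splits, so a missing value for a feature the tree uses is an
#' error.
#'
#' @param tree A [train_coarse_tree()] fit (or one restored with
#'   [read_tree_json()]).
#' @param newdata Named numeric vector, or data frame with one row per cell
#'   containing at least the features the tree splits on.
#' @return Character vector of signature labels.
#' @export
predict_signature <- function(tree, newdata) {
  stopifnot(inherits(tree, "signature_tree"))
  if (is.numeric(newdata) && !is.null(names(newdata)))
    newdata <- as.data.frame(as.list(newdata))
  newdata <- as.data.frame(newdata)
  used <- tree_features(tree)
  miss <- setdiff(used, names(newdata))
  if (length(miss))
    stop("missing feature(s) required by the tree (no surrogate splits): ",
         paste(miss, collapse = ", "))
  if (anyNA(newdata[, used, drop = FALSE]))
    stop("missing value in feature(s) required by the tree")
  one <- function(row) {
    nd <- tree$node
    while (nd$type == "split") {
      nd <- if (row[[nd$feature]] < nd$threshold) nd$left else nd$right
    }
    nd$label
  }
  vapply(seq_len(nrow(newdata)), function(i) one(newdata[i, , drop = FALSE]),
         character(1))
}

#' Train/validation model selection over stratified splits
#'
#' Draws `n_splits` stratified train/validation partitions at the stated
#' per-class counts (without replacement within each split, independently
#' resampled across splits from seeds derived from `seed`), fits a coarse
#' tree on each training set, scores validation accuracy, and selects the
#' best model. Ties in accuracy go to the model using fewer distinct
#' features, then to the lower split id.
#'
#' @param features Data frame with `group_label` plus the feature columns.
#' @param n_splits Number of train/validation splits (12).
#' @param seed Master seed; per-split seeds are derived from it and
#'   recorded.
#' @param train_counts,val_counts Named per-class counts. Defaults: 25
#'   control + 20 per disease group for training, 8 + 4/4/4 for validation.
#' @param allow_scaled If the cohort is too small, scale both count vectors
#'   down proportionally instead of failing.
#' @param max_splits Tree size cap.
#' @return An object of class `"validation_report"`: `summary` data frame
#'   (split id, seed, accuracy, features used), `trees`, `selected` (id) and
#'   `selected_tree`.
#' @export
run_model_selection <- function(features, n_splits = 12, seed = 1,
                                train_counts = c(control = 25, ataxia = 20,
                                                 dystonia = 20, tremor = 20),
                                val_counts = c(control = 8, ataxia = 4,
                                               dystonia = 4, tremor = 4),
                                allow_scaled = FALSE, max_splits = 3) {
  stopifnot(is.data.frame(features), "group_label" %in% names(features))
  feats <- intersect(feature_names(), names(features))
  if (length(feats) == 0) stop("no feature columns found")
  y <- features$group_label
  avail <- table(factor(y, levels = names(train_counts)))
  need <- train_counts + val_counts
  short <- names(need)[avail < need]
  if (length(short)) {
    if (!allow_scaled)
      stop("insufficient cells for class(es): ",
           paste(short, collapse = ", "),
           " (need ", paste(need[short], collapse = ", "), ")")
    f <- min(avail / need)
    train_counts <- pmax(floor(train_counts * f), 2L)
    val_counts <- pmax(floor(val_counts * f), 1L)
    if (any(avail < train_counts + val_counts))
      stop("cohort too small even after scaling")
  }
  set.seed(seed)
  split_seeds <- sample.int(.Machine$integer.max - 1L, n_splits)
  trees <- vector("list", n_splits)
  rows <- vector("list", n_splits)
  for (i in seq_len(n_splits)) {
    set.seed(split_seeds[i])
    tr_idx <- va_idx <- integer()
    for (g in names(train_counts)) {
      pool <- which(y == g)
      pick <- sample(pool, train_counts[[g]] + val_counts[[g]])
      tr_idx <- c(tr_idx, pick[seq_len(train_counts[[g]])])
      va_idx <- c(va_idx, pick[-seq_len(train_counts[[g]])])
    }
    fit <- train_coarse_tree(features[tr_idx, feats, drop = FALSE],
                             y[tr_idx], max_splits = max_splits)
    pred <- predict_signature(fit, features[va_idx, feats, drop = FALSE])
    acc <- mean(pred == y[va_idx])
    trees[[i]] <- fit
    rows[[i]] <- data.frame(split_id = i, seed = split_seeds[i],
                            accuracy = acc,
                            n_features = length(tree_features(fit)),
                            features = paste(tree_features(fit),
                                             collapse = "+"))
  }
  summ <- do.call(rbind, rows)
  best <- which(summ$accuracy == max(summ$accuracy))
  if (length(best) > 1) {
    nf <- summ$n_features[best]
    best <- best[nf == min(nf)]
  }
  sel <- best[1]                      # lowest split id among remaining ties
  structure(list(summary = summ, trees = trees, selected = sel,
                 selected_tree = trees[[sel]],
                 rationale = sprintf(
                   "max validation accuracy %.3f; ties resolved by fewer features, then lower split id",
                   summ$accuracy[sel])),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  print(x$summary, row.names = FALSE)
  cat("selected model:", x$selected, "-", x$rationale, "\n")
  invisible(x)
}

#' Classify a cohort and tabulate origin group against assigned signature
#'
#' @param tree A fitted `signature_tree`.
#' @param features Data frame with `group_label` and the tree's features.
#' @return An object of class `"cohort_summary"`: integer `counts` matrix
#'   (origin group x signature) plus the per-cell `assignments`.
#' @export
classify_cohort <- function(tree, features) {
  stopifnot(is.data.frame(features), "group_label" %in% names(features))
  if (nrow(features) == 0) stop("empty cohort")
  pred <- predict_signature(tree, features)
  counts <- table(origin = features$group_label,
                  signature = factor(pred, levels = tree$class_levels))
  structure(list(counts = unclass(counts),
                 assignments = data.frame(
                   cell_id = if ("cell_id" %in% names(features))
                     features$cell_id else seq_len(nrow(features)),
                   group_label = features$group_label,
                   signature = pred, stringsAsFactors = FALSE)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary> counts (origin x signature)\n")
  print(x$counts)
  invisible(x)
}
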