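#' Canonical feature order of the twelve spike-train parameters
#'
#' The order matters: it is the column order of the feature table, and the
#' coarse tree breaks exact split ties in favor of the earlier column
#' (mirroring the column-order behavior of common tree toolboxes).
#'
#' @return Character vector of the twelve feature names.
#' @export
feature_names <- function() {
  c("firing_rate", "mean_ifr", "median_ifr", "cv", "cv2", "skewness",
    "isi25", "isi100", "interburst_pause", "mode_fraction",
    "rhythmicity_index", "oscillation_peaks")
}

#' The closed set of signature labels
#' @return Character vector: control, ataxia, dystonia, tremor.
#' @export
signature_levels <- function() c("control", "ataxia", "dystonia", "tremor")

.detect_sep <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (length(hdr) == 0) stop("no records in ", path)
  if (grepl("\t", hdr)) "\t" else ","
}

#' Read spike-timestamp tables
#'
#' The canonical format is a long delimited table (comma or tab, detected
#' from the header) with columns `cell_id` and `time_s`, plus optional
#' `mouse_id` and `group_label` columns carried per row. A directory of
#' per-cell files (one `time_s` column each, cell id from the file name) is
#' supported as a convenience.
#'
#' @param path File path (long table) or directory (per-cell files).
#' @param format `"long_table"` or `"per_cell_files"`.
#' @param duration Recording duration in seconds assigned to every train.
#' @return A [cohort_table()] with timestamps sorted per cell.
#' @export
read_spike_trains <- function(path, format = c("long_table", "per_cell_files"),
                              duration = 30) {
  format <- match.arg(format)
  if (format == "per_cell_files") {
    files <- list.files(path, full.names = TRUE)
    if (length(files) == 0) stop("no records in ", path)
    trains <- lapply(files, function(f) {
      d <- utils::read.table(f, header = TRUE, sep = .detect_sep(f))
      if (!"time_s" %in% names(d)) stop("missing time_s column in ", f)
      spike_train(sort(d$time_s), cell_id = sub("\\.[^.]*$", "", basename(f)),
                  duration = duration)
    })
    return(cohort_table(trains, provenance = path))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  d <- tryCatch(
    utils::read.table(path, header = TRUE, sep = .detect_sep(path),
                      stringsAsFactors = FALSE, comment.char = "#"),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e)))
  if (nrow(d) == 0) stop("no records in ", path)
  need <- c("cell_id", "time_s")
  if (!all(need %in% names(d)))
    stop("missing column(s): ", paste(setdiff(need, names(d)), collapse = ", "))
  if (!is.numeric(d$time_s)) {
    bad <- which(is.na(suppressWarnings(as.numeric(d$time_s))))[1]
    stop("parse error: non-numeric time_s at data line ", bad)
  }
  trains <- lapply(split(d, d$cell_id), function(g) {
    ts <- sort(g$time_s)
    if (any(diff(ts) == 0))
      stop("validation error: duplicate timestamps for cell ", g$cell_id[1])
    spike_train(ts, cell_id = g$cell_id[1],
                mouse_id = if ("mouse_id" %in% names(g))
                  as.character(g$mouse_id[1]) else NA_character_,
                group_label = if ("group_label" %in% names(g))
                  as.character(g$group_label[1]) else NA_character_,
                duration = duration)
  })
  cohort_table(trains[unique(d$cell_id)], provenance = path)
}

#' Write a cohort as a long spike table
#'
#' Output is always comma-separated with the canonical header
#' `cell_id,mouse_id,group_label,time_s`; timestamps keep microsecond
#' resolution and beyond.
#'
#' @param cohort A [cohort_table()].
#' @param path Output file path.
#' @export
write_spike_trains <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  rows <- do.call(rbind, lapply(cohort$trains, function(tr)
    data.frame(cell_id = tr$cell_id, mouse_id = tr$mouse_id,
               group_label = tr$group_label,
               time_s = format(tr$timestamps, digits = 15, trim = TRUE,
                               scientific = FALSE))))
  utils::write.table(rows, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read the per-cell feature table
#'
#' Column order is fixed: `cell_id`, `group_label`, then the twelve features
#' in [feature_names()] order. The round trip is lossless to at least 12
#' significant digits.
#'
#' @param features Data frame with the columns above (as produced by
#'   [featurize_cohort()]).
#' @param path File path.
#' @return `read_feature_table()` returns the data frame (possibly 0-row).
#' @export
write_feature_table <- function(features, path) {
  cols <- c("cell_id", "group_label", feature_names())
  miss <- setdiff(cols, names(features))
  if (length(miss))
    stop("schema error: missing feature column(s): ",
         paste(miss, collapse = ", "))
  out <- features[, cols, drop = FALSE]
  for (j in feature_names())
    out[[j]] <- format(out[[j]], digits = 15, trim = TRUE, scientific = TRUE)
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.table(path, header = TRUE, sep = .detect_sep(path),
                         stringsAsFactors = FALSE, comment.char = "#")
  cols <- c("cell_id", "group_label", feature_names())
  miss <- setdiff(cols, names(d))
  if (length(miss))
    stop("schema error: missing feature column(s): ",
         paste(miss, collapse = ", "))
  d <- d[, cols, drop = FALSE]
  for (j in feature_names()) d[[j]] <- as.numeric(d[[j]])
  d
}

#' Serialize / restore a fitted signature tree as JSON
#'
#' The model file stores the recursive node structure (feature name,
#' threshold, children, leaf label and class counts) plus training metadata,
#' so a fitted classifier can be applied to new cohorts without refitting.
#'
#' @param tree A [train_coarse_tree()] fit.
#' @param path JSON file path.
#' @return `read_tree_json()` returns the `signature_tree`.
#' @export
write_tree_json <- function(tree, path) {
  stopifnot(inherits(tree, "signature_tree"))
  jsonlite::write_json(
    list(node = tree$node, features = tree$features,
         class_levels = tree$class_levels, class_counts = tree$class_counts,
         n_splits = tree$n_splits,
         splits = tree$splits, metadata = tree$metadata),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_tree_json
#' @export
read_tree_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  fix <- function(nd) {
    if (identical(nd$type, "leaf")) {
      nd$counts <- unlist(nd$counts)
      return(nd)
    }
    nd$left <- fix(nd$left); nd$right <- fix(nd$right)
    nd
  }
  structure(list(node = fix(x$node), features = unlist(x$features),
                 class_levels = unlist(x$class_levels),
                 class_counts = unlist(x$class_counts),
                 n_splits = x$n_splits,
                 splits = x$splits, metadata = x$metadata),
            class = "signature_tree")
}
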