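#' Feature tables of volumetric parameters
#'
#' A `feature_table` holds a subjects-by-features matrix of named, numeric
#' (typically positive) volumetric parameters: per-region volumes in mm^3,
#' percentages of intracranial volume, or left-right asymmetry indices, one
#' row per subject. Group membership (0 = control, 1 = patient) lives in a
#' parallel `cohort_labels` vector.
#'
#' @param values numeric matrix, subjects in rows, features in columns.
#' @param subject_ids character vector of subject identifiers (defaults to
#'   rownames of `values`, or `S1..Sn`).
#' @param feature_names character vector of unique feature names (defaults to
#'   colnames of `values`).
#' @return An object of class `feature_table`: a list with elements
#'   `subject_ids`, `feature_names` and `values`.
#' @examples
#' ft <- feature_table(matrix(rlnorm(12), 4, 3))
#' dim(ft)
#' @export
feature_table <- function(values, subject_ids = NULL, feature_names = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop_named("evoselect_nonnumeric", "feature values must be numeric")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop_named("evoselect_missing_values",
               "feature table contains missing or non-finite values")
  }
  if (is.null(subject_ids)) {
    subject_ids <- rownames(values)
    if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(nrow(values)))
  }
  if (is.null(feature_names)) {
    feature_names <- colnames(values)
    if (is.null(feature_names)) feature_names <- paste0("F", seq_len(ncol(values)))
  }
  subject_ids <- as.character(subject_ids)
  feature_names <- as.character(feature_names)
  if (length(subject_ids) != nrow(values) ||
      length(feature_names) != ncol(values)) {
    stop_named("evoselect_dim_mismatch",
               "id/name lengths do not match matrix dimensions")
  }
  if (anyDuplicated(feature_names)) {
    stop_named("evoselect_duplicate_feature",
               paste0("duplicate feature names: ",
                      paste(unique(feature_names[duplicated(feature_names)]),
                            collapse = ", ")))
  }
  dimnames(values) <- list(subject_ids, feature_names)
  structure(list(subject_ids = subject_ids, feature_names = feature_names,
                 values = values),
            class = "feature_table")
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d subjects x %d features\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Binary cohort labels
#'
#' @param labels vector coercible to 0/1 integers (0 = control/CN,
#'   1 = patient/EMCI), one per subject.
#' @return Integer vector of class `cohort_labels` with a `group_counts`
#'   attribute `c(n0, n1)`.
#' @export
cohort_labels <- function(labels) {
  labels <- as.integer(labels)
  if (anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    stop_named("evoselect_bad_labels", "labels must be binary 0/1")
  }
  counts <- c(sum(labels == 0L), sum(labels == 1L))
  if (any(counts == 0L)) {
    stop_named("evoselect_single_class",
               "both classes must be non-empty")
  }
  structure(labels, group_counts = counts, class = "cohort_labels")
}

#' @export
print.cohort_labels <- function(x, ...) {
  gc <- attr(x, "group_counts")
  cat(sprintf("<cohort_labels> n = %d (class 0: %d, class 1: %d)\n",
              length(x), gc[1], gc[2]))
  invisible(x)
}

#' Read a feature table with labels from delimited text
#'
#' Expects a header row; one row per subject. A column named `subject_id`
#' (if present) supplies identifiers; `label_column` must contain exactly two
#' distinct values, mapped to 0/1 in sorted order (so e.g. `"CN" < "EMCI"`
#' maps CN to 0). All remaining columns are features. Missing values are
#' rejected, not imputed.
#'
#' @param path path to a CSV (or TSV, chosen by extension) file.
#' @param label_column name of the group-label column. Default `"group"`.
#' @return A list with elements `table` (a [feature_table]) and `labels`
#'   (a [cohort_labels]).
#' @seealso [write_feature_table()]
#' @export
read_feature_table <- function(path, label_column = "group") {
  if (!file.exists(path)) {
    stop_named("evoselect_missing_file", paste0("no such file: ", path))
  }
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!label_column %in% names(df)) {
    stop_named("evoselect_missing_label_column",
               paste0("label column not found: ", label_column))
  }
  raw_labels <- df[[label_column]]
  lev <- sort(unique(as.character(raw_labels)))
  if (length(lev) != 2L) {
    stop_named("evoselect_single_class",
               paste0("label column must have exactly 2 distinct values, got ",
                      length(lev)))
  }
  labels <- cohort_labels(match(as.character(raw_labels), lev) - 1L)
  ids <- if ("subject_id" %in% names(df)) as.character(df[["subject_id"]])
         else paste0("S", seq_len(nrow(df)))
  keep <- !(names(df) %in% c(label_column, "subject_id"))
  feat_names <- names(df)[keep]          # before `[.data.frame` uniquifies
  if (anyDuplicated(feat_names)) {
    stop_named("evoselect_duplicate_feature",
               paste0("duplicate feature names: ",
                      paste(unique(feat_names[duplicated(feat_names)]),
                            collapse = ", ")))
  }
  feat <- df[, keep, drop = FALSE]
  names(feat) <- feat_names
  not_num <- !vapply(feat, is.numeric, logical(1))
  if (any(not_num)) {
    stop_named("evoselect_nonnumeric",
               paste0("non-numeric feature column(s): ",
                      paste(names(feat)[not_num], collapse = ", ")))
  }
  tab <- feature_table(as.matrix(feat), subject_ids = ids,
                       feature_names = names(feat))
  list(table = tab, labels = labels)
}

#' Write a feature table with labels to CSV
#'
#' Inverse of [read_feature_table()]: writes `subject_id`, the label column,
#' then one column per feature, full double precision.
#'
#' @param table a [feature_table].
#' @param labels a [cohort_labels] (or 0/1 vector) of matching length.
#' @param path output file path.
#' @param label_column column name for the labels. Default `"group"`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, labels, path, label_column = "group") {
  stopifnot(inherits(table, "feature_table"))
  labels <- cohort_labels(labels)
  if (length(labels) != nrow(table$values)) {
    stop_named("evoselect_dim_mismatch", "labels length != subject count")
  }
  df <- data.frame(subject_id = table$subject_ids,
                   group = as.integer(labels),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[2] <- label_column
  vals <- as.data.frame(table$values, check.names = FALSE)
  df <- cbind(df, vals)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Z-score standardization fitted on the training split only
#'
#' Centers and scales every feature using mean and standard deviation
#' computed on `train_index` subjects alone, then applies the transform to
#' all subjects, so no information leaks from the validation split.
#' Training-constant features cannot be scaled; they are mapped to all-zeros
#' and recorded in the `flagged` attribute (with a warning).
#'
#' @param table a [feature_table].
#' @param train_index integer indices of the training subjects.
#' @return A standardized [feature_table] with attributes `center`, `scale`
#'   and `flagged` (names of zero-variance training features).
#' @export
standardize <- function(table, train_index) {
  stopifnot(inherits(table, "feature_table"))
  train_index <- as.integer(train_index)
  if (length(train_index) == 0L) {
    stop_named("evoselect_empty_train", "train_index must be non-empty")
  }
  tr <- table$values[train_index, , drop = FALSE]
  ctr <- colMeans(tr)
  scl <- apply(tr, 2, stats::sd)
  flagged <- table$feature_names[!is.finite(scl) | scl == 0]
  if (length(flagged)) {
    warning(sprintf("zero-variance training feature(s) mapped to zeros: %s",
                    paste(flagged, collapse = ", ")), call. = FALSE)
  }
  scl[!is.finite(scl) | scl == 0] <- Inf  # x/Inf -> 0 after centering
  out <- sweep(sweep(table$values, 2, ctr, "-"), 2, scl, "/")
  out[, table$feature_names %in% flagged] <- 0
  res <- feature_table(out, table$subject_ids, table$feature_names)
  attr(res, "center") <- ctr
  attr(res, "scale") <- scl
  attr(res, "flagged") <- flagged
  res
}

#' Specification of a stratified train/validation split
#'
#' @param train_fraction fraction of subjects used for training, in (0,1).
#'   Default 0.8 (the 80/20 split used throughout).
#' @param stratified keep per-class proportions? Default `TRUE`.
#' @param seed RNG seed for the split.
#' @return A list of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.8, stratified = TRUE, seed = 1L) {
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    stop_named("evoselect_bad_fraction",
               "train_fraction must be strictly inside (0, 1)")
  }
  stopifnot(is_flag(stratified), is_count(seed, 0L) || is.numeric(seed))
  structure(list(train_fraction = train_fraction, stratified = stratified,
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Stratified train/validation split
#'
#' Splits subjects into disjoint, exhaustive train and validation index
#' sets, preserving per-class proportions to within one subject. Clipping
#' guarantees both splits contain both classes.
#'
#' @param labels a [cohort_labels] (or 0/1 vector).
#' @param spec a [split_spec()].
#' @return List with integer vectors `train` and `validation`.
#' @export
stratified_split <- function(labels, spec = split_spec()) {
  labels <- cohort_labels(labels)
  stopifnot(inherits(spec, "split_spec"))
  gc <- attr(labels, "group_counts")
  if (any(gc < 2L)) {
    stop_named("evoselect_class_too_small",
               "each class needs >= 2 subjects to split")
  }
  with_seed(spec$seed, {
    train <- integer(0)
    classes <- if (spec$stratified) c(0L, 1L) else NA_integer_
    if (spec$stratified) {
      for (cl in classes) {
        idx <- which(unclass(labels) == cl)
        n_tr <- round(spec$train_fraction * length(idx))
        n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
        train <- c(train, sample(idx, n_tr))
      }
    } else {
      n <- length(labels)
      n_tr <- min(max(round(spec$train_fraction * n), 1L), n - 1L)
      train <- sample(seq_len(n), n_tr)
    }
    train <- sort(train)
    validation <- setdiff(seq_along(labels), train)
    ## unstratified draws can strand a class entirely in one split
    for (part in list(train, validation)) {
      if (length(unique(unclass(labels)[part])) < 2L && spec$stratified) {
        stop_named("evoselect_degenerate_split",
                   "split left a class empty")  # unreachable when stratified
      }
    }
    list(train = train, validation = validation)
  })
}
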