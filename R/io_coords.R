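#' A single experiment's reported foci
#'
#' The unit over which ALE aggregates: one study-group's contrast, with its
#' participant count and the activation foci it reported (MNI mm).
#'
#' @param study_id Opaque identifier; unique within a dataset.
#' @param n_subjects Positive integer number of participants.
#' @param foci Numeric matrix (n x 3) of MNI mm coordinates; non-empty, all
#'   finite, no exact duplicate triple.
#' @return An object of class `experiment`.
#' @export
experiment <- function(study_id, n_subjects, foci) {
  study_id <- as.character(study_id)
  if (length(study_id) != 1L || is.na(study_id) || !nzchar(study_id))
    stop("`study_id` must be a non-empty string")
  n_subjects <- as.integer(n_subjects)
  if (length(n_subjects) != 1L || is.na(n_subjects) || n_subjects < 1L)
    stop("`n_subjects` must be a positive integer (study ", study_id, ")")
  foci <- matrix(as.numeric(foci), ncol = 3,
                 dimnames = list(NULL, c("x", "y", "z")))
  if (nrow(foci) == 0L) stop("`foci` must be non-empty (study ", study_id, ")")
  if (any(!is.finite(foci))) stop("all foci must have 3 finite coordinates")
  if (anyDuplicated(apply(foci, 1, paste, collapse = "\r")))
    stop("`foci` contains exact duplicate coordinates (study ", study_id, ")")
  structure(list(study_id = study_id, n_subjects = n_subjects, foci = foci),
            class = "experiment")
}

#' A named collection of experiments for one condition or contrast
#'
#' @param label Condition name (e.g. "2-back > 0-back").
#' @param experiments List of [experiment] objects with unique `study_id`s.
#' @return An object of class `coordinate_dataset`.
#' @export
coordinate_dataset <- function(label, experiments) {
  if (length(experiments) < 1L) stop("at least 1 experiment required")
  if (!all(vapply(experiments, inherits, logical(1), "experiment")))
    stop("`experiments` must be a list of experiment objects")
  ids <- vapply(experiments, `[[`, character(1), "study_id")
  if (anyDuplicated(ids))
    stop("study_ids must be unique within a dataset: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(list(label = as.character(label), experiments = experiments),
            class = "coordinate_dataset")
}

#' @export
print.coordinate_dataset <- function(x, ...) {
  nf <- sum(vapply(x$experiments, function(e) nrow(e$foci), integer(1)))
  cat(sprintf("<coordinate_dataset> '%s': %d experiments, %d foci\n",
              x$label, length(x$experiments), nf))
  invisible(x)
}

#' Read a coordinate table
#'
#' Reads activation foci from the canonical CSV format (columns `study`,
#' `group`, `n`, `x`, `y`, `z`; header required) or from the Sleuth-style
#' text format, where each block of coordinate lines is preceded by `//`
#' header lines carrying the study label and `Subjects=N`, and blocks are
#' separated by blank lines. Coordinates must already be in MNI mm space;
#' Talairach input (Sleuth `// Reference=TAL`) is rejected, coordinate-space
#' conversion is out of scope.
#'
#' @param path File path.
#' @param format `"csv"` or `"sleuth"`.
#' @return A data.frame with columns `study`, `group`, `n`, `x`, `y`, `z`,
#'   one row per focus.
#' @export
read_coordinate_table <- function(path, format = c("csv", "sleuth")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") read_foci_csv(path) else read_foci_sleuth(path)
}

read_foci_csv <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e))
  )
  if (nrow(df) == 0L) stop("parse error: ", path, " contains no data rows")
  need <- c("study", "group", "n", "x", "y", "z")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("parse error: missing column(s) ", paste(missing_cols, collapse = ", "))
  df <- df[need]
  for (col in c("n", "x", "y", "z")) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals))
    if (length(bad))
      stop("parse error: malformed value in column '", col,
           "' at line ", bad[1] + 1L)  # +1 for header
    df[[col]] <- vals
  }
  if (any(df$n <= 0))
    stop("validation error: non-positive n at line ",
         which(df$n <= 0)[1] + 1L)
  df$study <- as.character(df$study)
  df$group <- as.character(df$group)
  df$n <- as.integer(df$n)
  df
}

read_foci_sleuth <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(trimws(lines)) || all(!nzchar(trimws(lines))))
    stop("parse error: ", path, " is empty")
  ref <- grep("^\\s*//\\s*Reference\\s*=", lines, value = TRUE)
  if (length(ref) && any(grepl("TAL", ref, ignore.case = TRUE)))
    stop("Talairach coordinates detected (Reference=TAL); inputs must be MNI ",
         "- coordinate-space conversion is not performed")
  rows <- list()
  header <- character(0)
  n_subj <- NA_integer_
  flush_ok <- function() length(header) > 0 || !is.na(n_subj)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) { header <- character(0); n_subj <- NA_integer_; next }
    if (grepl("^//", ln)) {
      body <- trimws(sub("^//", "", ln))
      if (grepl("Reference\\s*=", body, ignore.case = TRUE)) next
      m <- regmatches(body, regexec("(?:Subjects|n)\\s*=\\s*(\\d+)", body,
                                    ignore.case = TRUE))[[1]]
      if (length(m) == 2L) {
        n_subj <- as.integer(m[2])
        body <- trimws(sub("(?i)[,;]?\\s*(?:Subjects|n)\\s*=\\s*\\d+", "", body,
                           perl = TRUE))
      }
      if (nzchar(body)) header <- c(header, body)
      next
    }
    xyz <- suppressWarnings(as.numeric(strsplit(ln, "[,;\t ]+")[[1]]))
    if (length(xyz) != 3L || anyNA(xyz))
      stop("parse error: malformed coordinate row at line ", i)
    if (!flush_ok())
      stop("parse error: coordinates without a study header at line ", i)
    if (is.na(n_subj))
      stop("parse error: no 'Subjects=' count for block ending at line ", i)
    if (n_subj <= 0L)
      stop("validation error: non-positive n at line ", i)
    rows[[length(rows) + 1L]] <- data.frame(
      study = paste(header, collapse = " "), group = "1", n = n_subj,
      x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("parse error: no coordinate rows in ", path)
  do.call(rbind, rows)
}

#' Write a coordinate table as canonical CSV
#'
#' @param rows Data.frame with columns `study`, `group`, `n`, `x`, `y`, `z`,
#'   as returned by [read_coordinate_table()], or a [coordinate_dataset].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_coordinate_table <- function(rows, path) {
  if (inherits(rows, "coordinate_dataset")) rows <- dataset_to_rows(rows)
  utils::write.csv(rows[c("study", "group", "n", "x", "y", "z")], path,
                   row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Flatten a dataset back into coordinate-table rows
#'
#' @param dataset A [coordinate_dataset].
#' @return Data.frame with columns `study`, `group`, `n`, `x`, `y`, `z`.
#' @export
dataset_to_rows <- function(dataset) {
  do.call(rbind, lapply(dataset$experiments, function(e) {
    data.frame(study = e$study_id, group = "1", n = e$n_subjects,
               x = e$foci[, 1], y = e$foci[, 2], z = e$foci[, 3],
               stringsAsFactors = FALSE)
  }))
}

#' Pool coordinate rows into a dataset
#'
#' Rows sharing the same (study, group) are merged into one experiment whose
#' foci are the union of their foci with exact duplicates removed — multiple
#' contrasts of the same participants are pooled and treated as one
#' experiment. Rows from distinct groups of the same study become separate
#' experiments. When pooled rows disagree on `n`, the maximum is used (the
#' conservative choice: the kernel is never narrower than for any
#' constituent contrast) and a message is logged.
#'
#' @param rows Data.frame with columns `study`, `group`, `n`, `x`, `y`, `z`.
#' @param label Condition name for the resulting dataset.
#' @return A [coordinate_dataset].
#' @export
pool_to_dataset <- function(rows, label) {
  if (is.null(rows) || nrow(rows) == 0L) stop("`rows` must be non-empty")
  rows$study <- as.character(rows$study)
  rows$group <- as.character(rows$group)
  key <- paste(rows$study, rows$group, sep = "\r")
  groups_per_study <- tapply(rows$group, rows$study,
                             function(g) length(unique(g)))
  exps <- lapply(split(rows, factor(key, levels = unique(key))), function(r) {
    study <- r$study[1]; grp <- r$group[1]
    n_vals <- unique(r$n)
    if (length(n_vals) > 1L) {
      message("pooling '", study, "' (group ", grp, "): differing n (",
              paste(sort(n_vals), collapse = ", "), "), using max = ",
              max(n_vals))
    }
    foci <- unique(as.matrix(r[c("x", "y", "z")]))
    id <- if (groups_per_study[[study]] > 1L)
      sprintf("%s (group %s)", study, grp) else study
    experiment(id, max(r$n), foci)
  })
  names(exps) <- NULL
  coordinate_dataset(label, exps)
}
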