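#' Assemble and validate a two-visit trial table
#'
#' A trial is a tibble with one row per patient: a `patient_id`, an `arm`
#' (`"treatment"` or `"placebo"`), paired baseline/follow-up measurement
#' columns for the eight STAR instruments (`clin_essdai_base`,
#' `clin_essdai_fu`, `esspri_base`, ..., `rf_fu`), and any number of extra
#' numeric baseline covariate columns. Missing measurements are `NA`, never
#' zero — a zero unstimulated salivary flow is a real clinical value.
#'
#' @param data Data frame with at least `patient_id` and `arm`; measurement
#'   columns that are absent are created as all-`NA`.
#' @param trial_id Trial label.
#' @param expert_class One of `"positive"`, `"in_between"`, `"negative"` —
#'   the expert classification of the trial used to split meta-analyses.
#' @param evaluation_week Integer week of the follow-up visit.
#' @return A `star_trial` tibble carrying `trial_id`, `expert_class` and
#'   `evaluation_week` as attributes.
#' @export
trial_dataset <- function(data, trial_id, expert_class = "positive",
                          evaluation_week = 24L) {
  data <- as_tibble(data)
  if (!all(c("patient_id", "arm") %in% names(data))) {
    abort("`data` needs `patient_id` and `arm` columns",
          class = "sjstar_validation_error")
  }
  expert_class <- match.arg(expert_class, c("positive", "in_between", "negative"))
  data$patient_id <- as.character(data$patient_id)
  if (anyDuplicated(data$patient_id)) {
    abort(sprintf("duplicate patient_id: %s",
                  paste(unique(data$patient_id[duplicated(data$patient_id)]),
                        collapse = ", ")),
          class = "sjstar_validation_error")
  }
  data$arm <- as.character(data$arm)
  bad_arm <- setdiff(unique(data$arm), c("treatment", "placebo"))
  if (length(bad_arm)) {
    abort(sprintf("unknown arm label(s): %s", paste(bad_arm, collapse = ", ")),
          class = "sjstar_validation_error")
  }
  if (!all(c("treatment", "placebo") %in% data$arm)) {
    abort("both arms must be non-empty", class = "sjstar_validation_error")
  }
  for (col in measurement_columns()) {
    if (!col %in% names(data)) data[[col]] <- NA_real_
    data[[col]] <- as.double(data[[col]])
    check_instrument_range(data[[col]], sub("_(base|fu)$", "", col), where = col)
  }
  structure(data,
            class = c("star_trial", class(data)),
            trial_id = as.character(trial_id),
            expert_class = expert_class,
            evaluation_week = as.integer(evaluation_week))
}

#' @export
print.star_trial <- function(x, ...) {
  cat(sprintf("<star_trial %s>  n = %d  expert_class = %s  week = %d\n",
              attr(x, "trial_id"), nrow(x), attr(x, "expert_class"),
              attr(x, "evaluation_week")))
  NextMethod()
}

#' Trial metadata accessors
#' @param trial A `star_trial`.
#' @return The trial id, expert class or evaluation week.
#' @export
trial_id <- function(trial) attr(trial, "trial_id")

#' @rdname trial_id
#' @export
expert_class <- function(trial) attr(trial, "expert_class")

#' @rdname trial_id
#' @export
evaluation_week <- function(trial) attr(trial, "evaluation_week")

# Default file-column -> internal-column mapping: identity on internal names.
default_column_mapping <- function() {
  cols <- c("patient_id", "arm", measurement_columns())
  setNames(cols, cols)
}

#' Read a patient-level trial CSV
#'
#' Reads a one-row-per-patient CSV, applies an optional column-name mapping,
#' validates instrument ranges and returns a [trial_dataset()]. Empty cells
#' become `NA`. Eye-level Schirmer/OSS exports are supported: map
#' `schirmer_base_left`/`schirmer_base_right` (and the `_fu`, `oss_*`
#' analogues) and the two eyes are averaged on read, matching the convention
#' that the mean of both eyes is used for calculation.
#'
#' @param path CSV file.
#' @param trial_id,expert_class,evaluation_week Passed to [trial_dataset()].
#' @param mapping Either `NULL` (columns already use internal names), a named
#'   character vector `internal_name = "file_column"`, or the path to a
#'   YAML/JSON file holding such a map.
#' @return A `star_trial` tibble.
#' @export
read_trial_csv <- function(path, trial_id, expert_class = "positive",
                           evaluation_week = 24L, mapping = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "sjstar_io_error")
  }
  mapping <- load_column_mapping(mapping)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = c("", "NA"), progress = FALSE)
  out <- tibble(.rows = nrow(raw))
  for (internal in names(mapping)) {
    src <- mapping[[internal]]
    if (!src %in% names(raw)) next
    out[[internal]] <- raw[[src]]
  }
  if (!all(c("patient_id", "arm") %in% names(out))) {
    abort("mapped header must include patient_id and arm columns",
          class = "sjstar_io_error")
  }
  # average optional per-eye columns into the instrument column
  for (stem in c("schirmer_base", "schirmer_fu", "oss_base", "oss_fu")) {
    eyes <- paste0(stem, c("_left", "_right"))
    if (all(eyes %in% names(out))) {
      l <- parse_numeric_column(out[[eyes[1]]], eyes[1])
      r <- parse_numeric_column(out[[eyes[2]]], eyes[2])
      out[[stem]] <- rowMeans(cbind(l, r))
      out[[eyes[1]]] <- out[[eyes[2]]] <- NULL
    }
  }
  for (col in setdiff(names(out), c("patient_id", "arm"))) {
    out[[col]] <- parse_numeric_column(out[[col]], col)
  }
  # unmapped columns are carried through as baseline covariates (numeric
  # where they parse as such)
  used <- intersect(unname(mapping), names(raw))
  for (col in setdiff(names(raw), used)) {
    num <- suppressWarnings(as.double(raw[[col]]))
    out[[col]] <- if (any(!is.na(raw[[col]]) & is.na(num))) raw[[col]] else num
  }
  trial_dataset(out, trial_id = trial_id, expert_class = expert_class,
                evaluation_week = evaluation_week)
}

load_column_mapping <- function(mapping) {
  base <- default_column_mapping()
  if (is.null(mapping)) return(base)
  if (is.character(mapping) && length(mapping) == 1 && is.null(names(mapping))) {
    mapping <- if (grepl("\\.ya?ml$", mapping)) {
      unlist(yaml::read_yaml(mapping))
    } else {
      unlist(jsonlite::read_json(mapping, simplifyVector = TRUE))
    }
  }
  if (is.null(names(mapping)) || any(names(mapping) == "")) {
    abort("column mapping must be a named vector internal_name = file_column",
          class = "sjstar_validation_error")
  }
  out <- base
  out[names(mapping)] <- mapping
  out
}

parse_numeric_column <- function(x, col) {
  out <- suppressWarnings(as.double(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad)) {
    abort(sprintf("malformed numeric value %s in column %s, row %d",
                  dQuote(x[bad[1]]), col, bad[1]),
          class = "sjstar_io_error")
  }
  out
}

#' Write a trial table to CSV
#'
#' Missing values are serialised as empty cells so that
#' `read_trial_csv(write_trial_csv(d))` reproduces `d` field for field,
#' including the missingness pattern.
#'
#' @param trial A `star_trial`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  if (!inherits(trial, "star_trial")) {
    trial <- trial_dataset(trial, trial_id = "trial")
  }
  readr::write_csv(as_tibble(as.data.frame(trial)), path, na = "", progress = FALSE)
  invisible(path)
}
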