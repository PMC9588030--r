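#' Construct and validate a monitoring record
#'
#' A monitoring record holds time-aligned beat-summarized arterial blood
#' pressure (ABP) and intracranial pressure (ICP) series: the mean, systolic
#' and diastolic value per channel at a constant sampling period (canonically
#' 1 Hz). Missing values are encoded as `NA`.
#'
#' @param patient_id Single string identifying the patient/recording.
#' @param t Numeric vector of sample times in seconds since record start;
#'   strictly increasing with a constant step equal to `sample_period_s`.
#' @param sample_period_s Positive sampling period in seconds (default 1).
#' @param abp_mean,abp_sys,abp_dia Numeric mmHg series for the ABP channel.
#' @param icp_mean,icp_sys,icp_dia Numeric mmHg series for the ICP channel.
#'
#' @return An object of class `monitoring_record`: a list with the above
#'   fields, validated against the record invariants (equal lengths, constant
#'   time step, `sys >= mean >= dia` wherever all three are present).
#' @export
monitoring_record <- function(patient_id, t, sample_period_s = 1,
                              abp_mean, abp_sys, abp_dia,
                              icp_mean, icp_sys, icp_dia) {
  rec <- structure(
    list(patient_id = as.character(patient_id)[1],
         t = as.numeric(t),
         sample_period_s = as.numeric(sample_period_s)[1],
         abp_mean = as.numeric(abp_mean),
         abp_sys = as.numeric(abp_sys),
         abp_dia = as.numeric(abp_dia),
         icp_mean = as.numeric(icp_mean),
         icp_sys = as.numeric(icp_sys),
         icp_dia = as.numeric(icp_dia)),
    class = "monitoring_record")
  validate_monitoring_record(rec)
}

#' @rdname monitoring_record
#' @param record A `monitoring_record` object to validate.
#' @export
validate_monitoring_record <- function(record) {
  stopifnot(inherits(record, "monitoring_record"))
  n <- length(record$t)
  series <- c("abp_mean", "abp_sys", "abp_dia", "icp_mean", "icp_sys", "icp_dia")
  for (s in series) {
    if (length(record[[s]]) != n)
      stop("series '", s, "' has length ", length(record[[s]]),
           " but time axis has length ", n)
  }
  if (!is.finite(record$sample_period_s) || record$sample_period_s <= 0)
    stop("sample_period_s must be a positive number")
  if (n >= 2) {
    dt <- diff(record$t)
    if (any(dt <= 0)) stop("time axis must be strictly increasing")
    if (max(abs(dt - record$sample_period_s)) > 1e-6)
      stop("time step is not constant (within 1e-6 s) and equal to sample_period_s")
  }
  for (ch in c("abp", "icp")) {
    sys <- record[[paste0(ch, "_sys")]]
    mn <- record[[paste0(ch, "_mean")]]
    dia <- record[[paste0(ch, "_dia")]]
    ok <- is.na(sys) | is.na(mn) | is.na(dia) | (sys >= mn & mn >= dia)
    if (!all(ok)) {
      bad <- which(!ok)
      stop("channel '", ch, "' violates sys >= mean >= dia at row(s): ",
           paste(utils::head(bad, 5), collapse = ", "),
           if (length(bad) > 5) " ..." else "")
    }
  }
  record
}

#' Read and write monitoring CSV files
#'
#' The on-disk format is a comma-separated UTF-8 file with a header row and
#' columns `time_s, abp_mean, abp_sys, abp_dia, icp_mean, icp_sys, icp_dia`.
#' Empty cells become `NA`.
#'
#' @param path Path to the CSV file.
#' @param sample_period_s Expected sampling period in seconds (default 1).
#' @param patient_id Identifier attached to the returned record.
#' @return `read_monitoring_csv` returns a validated [monitoring_record()];
#'   `write_monitoring_csv` invisibly returns `path`.
#' @export
read_monitoring_csv <- function(path, sample_period_s = 1, patient_id = basename(path)) {
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  required <- c("time_s", "abp_mean", "abp_sys", "abp_dia",
                "icp_mean", "icp_sys", "icp_dia")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("monitoring CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  monitoring_record(
    patient_id = patient_id,
    t = df$time_s, sample_period_s = sample_period_s,
    abp_mean = df$abp_mean, abp_sys = df$abp_sys, abp_dia = df$abp_dia,
    icp_mean = df$icp_mean, icp_sys = df$icp_sys, icp_dia = df$icp_dia)
}

#' @rdname read_monitoring_csv
#' @param record A `monitoring_record`.
#' @export
write_monitoring_csv <- function(record, path) {
  stopifnot(inherits(record, "monitoring_record"))
  df <- data.frame(time_s = record$t,
                   abp_mean = record$abp_mean, abp_sys = record$abp_sys,
                   abp_dia = record$abp_dia, icp_mean = record$icp_mean,
                   icp_sys = record$icp_sys, icp_dia = record$icp_dia)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

ARTIFACT_LABELS <- c("artifact_free", "artifact_distorted", "unlabeled")
INFORMATIVE_LABELS <- c("informative", "noninformative", "unlabeled")

#' Construct and validate an annotation table
#'
#' Annotations attach the two reference labelings to 24-minute segments of
#' 2-hour windows: the artifact status (`artifact_free` / `artifact_distorted`)
#' and the informative status (`informative` / `noninformative`), each also
#' allowing `unlabeled`.
#'
#' @param window_id Character vector of window identifiers.
#' @param segment_index Integer vector in 0..4.
#' @param artifact_label Character vector over
#'   `c("artifact_free", "artifact_distorted", "unlabeled")`.
#' @param informative_label Character vector over
#'   `c("informative", "noninformative", "unlabeled")`.
#' @return A `data.frame` of class `annotation_table`.
#' @export
annotation_table <- function(window_id, segment_index, artifact_label,
                             informative_label) {
  df <- data.frame(window_id = as.character(window_id),
                   segment_index = as.integer(segment_index),
                   artifact_label = as.character(artifact_label),
                   informative_label = as.character(informative_label),
                   stringsAsFactors = FALSE)
  validate_annotation_table(df)
}

validate_annotation_table <- function(df) {
  required <- c("window_id", "segment_index", "artifact_label", "informative_label")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("annotation table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (any(!df$segment_index %in% 0:4))
    stop("segment_index must be in 0..4")
  bad_a <- setdiff(unique(df$artifact_label), ARTIFACT_LABELS)
  if (length(bad_a) > 0)
    stop("unknown artifact_label value(s): ", paste(bad_a, collapse = ", "))
  bad_i <- setdiff(unique(df$informative_label), INFORMATIVE_LABELS)
  if (length(bad_i) > 0)
    stop("unknown informative_label value(s): ", paste(bad_i, collapse = ", "))
  key <- paste(df$window_id, df$segment_index, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (window_id, segment_index) pair(s) in annotation table")
  class(df) <- c("annotation_table", "data.frame")
  df
}

#' Read and write segment annotation tables
#'
#' Annotations are stored as CSV (header
#' `window_id,segment_index,artifact_label,informative_label`) or as a JSON
#' array of objects with the same fields; the format is chosen by the file
#' extension.
#'
#' @param path File path ending in `.csv` or `.json`.
#' @return `read_annotations` returns a validated [annotation_table()];
#'   `write_annotations` invisibly returns `path`.
#' @export
read_annotations <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  } else {
    df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = c(window_id = "character"))
  }
  validate_annotation_table(df)
}

#' @rdname read_annotations
#' @param table An `annotation_table`.
#' @export
write_annotations <- function(table, path) {
  table <- validate_annotation_table(as.data.frame(table))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.data.frame(table), path, dataframe = "rows")
  } else {
    utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  }
  invisible(path)
}
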