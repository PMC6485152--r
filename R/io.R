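#' Read and write patient tables
#'
#' The on-disk patient table is a UTF-8 CSV with header
#' `patient_id,age,hlos,codes`; the `codes` field is a semicolon-joined
#' list of taxonomy code strings. In memory, `codes` is a list column of
#' character vectors.
#'
#' @param path file path.
#' @return `read_patients()` returns the patient data.frame;
#'   `write_patients()` returns `path` invisibly.
#' @export
read_patients <- function(path) {
  if (!file.exists(path)) stop("patient file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character",
                                       codes = "character"))
  .check_patients(df)
}

#' @rdname read_patients
#' @param patients a patient data.frame.
#' @export
write_patients <- function(patients, path) {
  patients <- .check_patients(patients)
  out <- data.frame(patient_id = patients$patient_id,
                    age = patients$age, hlos = patients$hlos,
                    codes = vapply(patients$codes, paste, "", collapse = ";"),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# repo-wide float formatting for reproducible CSV diffs
.fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.12g", x))
}

# write a square distance matrix as labelled CSV (first row/col are codes)
.write_dist_csv <- function(m, path) {
  df <- data.frame(code = rownames(m),
                   apply(m, 2L, .fmt_num),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
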