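#' CSV DVH exchange format
#'
#' One file per patient, UTF-8, with header row and columns
#' `structure, bin_lo_gy, bin_hi_gy, volume_fraction, absolute_volume_cm3`;
#' one row per differential DVH bin, bins contiguous within a structure
#' (`bin_lo` of a row equals `bin_hi` of the previous row). Doses are
#' written with 17 significant digits so a write/read round trip is
#' lossless.
#'
#' @param patient A [patient_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_patient_csv <- function(patient, path) {
  if (!inherits(patient, "patient_record")) stop("patient must be a patient_record")
  g17 <- function(x) sprintf("%.17g", x)
  rows <- lapply(names(patient$structures), function(role) {
    d <- dvh_differential(patient$structures[[role]])
    e <- d$bin_edges
    data.frame(structure = role,
               bin_lo_gy = g17(e[-length(e)]), bin_hi_gy = g17(e[-1]),
               volume_fraction = g17(d$values),
               absolute_volume_cm3 = g17(d$volume_cm3),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read one patient from the CSV DVH exchange format
#'
#' @param path CSV file path (see [write_patient_csv()] for the format).
#' @param plan A [plan_context()] for the patient's arm.
#' @param arm Arm label, `"CF"` or `"HF"`.
#' @param patient_id Identifier; defaults to the file name without
#'   extension.
#' @return A [patient_record()].
#' @export
read_patient_csv <- function(path, plan, arm = c("CF", "HF"),
                             patient_id = NULL) {
  arm <- match.arg(arm)
  if (is.null(patient_id))
    patient_id <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("structure", "bin_lo_gy", "bin_hi_gy", "volume_fraction",
            "absolute_volume_cm3")
  if (!all(need %in% names(df)))
    stop("malformed DVH CSV ", path, ": missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "))
  for (col in need[-1]) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(df[[col]]))
      stop("malformed DVH CSV ", path, ": non-numeric value in ", col)
  }
  sts <- lapply(split(df, factor(df$structure, unique(df$structure))),
                function(s) {
    if (nrow(s) > 1 && any(abs(s$bin_lo_gy[-1] - s$bin_hi_gy[-nrow(s)]) > 1e-9))
      stop("malformed DVH CSV ", path, ": non-contiguous bins for ",
           s$structure[1])
    dvh(s$structure[1], c(s$bin_lo_gy[1], s$bin_hi_gy), s$volume_fraction,
        s$absolute_volume_cm3[1])
  })
  patient_record(patient_id, arm, plan, sts)
}

#' Write a cohort as per-patient CSVs plus a JSON manifest
#'
#' The manifest (`manifest.json`) records the arm, plan, patient ids and
#' file names so the cohort can be re-read without external context.
#'
#' @param patients List of [patient_record()] objects (one arm).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(patients, dir) {
  if (!length(patients)) stop("empty cohort")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  arm <- patients[[1]]$arm
  plan <- patients[[1]]$plan
  files <- vapply(patients, function(p) {
    if (!identical(p$arm, arm)) stop("mixed arms in one cohort directory")
    f <- paste0(p$patient_id, ".csv")
    write_patient_csv(p, file.path(dir, f))
    f
  }, character(1))
  manifest <- list(arm = arm,
                   plan = list(total_dose = plan$total_dose,
                               n_fractions = plan$n_fractions),
                   n_patients = length(patients),
                   patient_ids = vapply(patients, `[[`, character(1),
                                        "patient_id"),
                   files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' Patient files that fail validation are skipped with a warning (or raise
#' an error with `on_error = "stop"`).
#'
#' @param dir Cohort directory containing `manifest.json`.
#' @param on_error `"warn"` (skip unreadable patients) or `"stop"`.
#' @return List of [patient_record()] objects; the number of skipped files
#'   is attached as attribute `"n_skipped"`.
#' @export
read_cohort <- function(dir, on_error = c("warn", "stop")) {
  on_error <- match.arg(on_error)
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  plan <- plan_context(manifest$plan$total_dose, manifest$plan$n_fractions)
  skipped <- 0L
  out <- list()
  for (i in seq_along(manifest$files)) {
    f <- file.path(dir, manifest$files[i])
    p <- tryCatch(
      read_patient_csv(f, plan, manifest$arm, manifest$patient_ids[i]),
      error = function(e) {
        if (on_error == "stop") stop(e)
        warning("skipping unreadable patient file ", f, ": ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    if (is.null(p)) skipped <- skipped + 1L else out[[length(out) + 1L]] <- p
  }
  attr(out, "n_skipped") <- skipped
  out
}

#' Ingest a patient from DICOM RT-structure / RT-dose files
#'
#' Adapter interface: DICOM parsing is delegated to a caller-supplied
#' `reader` function (typically wrapping established DICOM-RT tooling,
#' e.g. a Python dicompyler-core bridge or an external converter that
#' emits the CSV exchange format). The adapter validates that the reader
#' returned a well-formed [patient_record()]; nothing else in the package
#' depends on DICOM availability.
#'
#' @param rtstruct_path,rtdose_path Paths to the DICOM RT-structure and
#'   RT-dose files.
#' @param reader Function `(rtstruct_path, rtdose_path, ...)` returning a
#'   [patient_record()].
#' @param ... Passed through to `reader`.
#' @return A validated [patient_record()].
#' @export
read_patient_dicom <- function(rtstruct_path, rtdose_path, reader, ...) {
  if (!is.function(reader))
    stop("no DICOM reader supplied; provide a reader function or convert ",
         "to the CSV DVH exchange format")
  p <- reader(rtstruct_path, rtdose_path, ...)
  if (!inherits(p, "patient_record"))
    stop("DICOM reader must return a patient_record")
  for (s in p$structures) validate_dvh(s)
  p
}
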