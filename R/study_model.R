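#' @keywords internal
"_PACKAGE"

# -- Controlled vocabularies ---------------------------------------------------

#' Site tokens recognised in a sample manifest
#'
#' `FT_OVARY_LEFT` and `FT_OVARY_RIGHT` are distinct collection records but
#' both belong to the pooled analysis site class `"FTO"` (fallopian tube /
#' ovarian surface); all other sites are their own class. `BUFFER_CONTROL`
#' (sham DNA extraction) and `NO_TEMPLATE_CONTROL` (PCR water control) are
#' laboratory controls and carry no patient link.
#'
#' @format Character vector of valid site tokens.
#' @export
ft_sites <- c(
  "FT_OVARY_LEFT", "FT_OVARY_RIGHT", "CERVIX", "PARACOLIC_GUTTER",
  "LAPAROSCOPIC_PORT", "OR_AIR", "BUFFER_CONTROL", "NO_TEMPLATE_CONTROL"
)

lab_control_sites <- c("BUFFER_CONTROL", "NO_TEMPLATE_CONTROL")

cancer_status_levels <- c("CANCER", "NON_CANCER")
histology_levels     <- c("SEROUS", "NON_SEROUS", "NONE")
menopausal_levels    <- c("PRE", "POST", "UNKNOWN")
surgery_levels       <- c("LAPAROTOMY", "LAPAROSCOPY", "ROBOTIC")
washing_levels       <- c("POSITIVE", "NEGATIVE", "NA")
niche_levels         <- c("G", "O", "V", "S", "B")

#' Map collection sites to analysis site classes
#'
#' Left and right fallopian-tube/ovary swabs pool into the `"FTO"` class;
#' every other site maps to itself.
#'
#' @param site Character vector of site tokens (see [ft_sites]).
#' @return Character vector of site classes.
#' @export
#' @examples
#' site_class(c("FT_OVARY_LEFT", "CERVIX"))
site_class <- function(site) {
  bad <- !site %in% ft_sites
  if (any(bad)) {
    ft_abort(paste0("unknown site token(s): ",
                    paste(unique(site[bad]), collapse = ", ")),
             "ftmicro_value_error")
  }
  ifelse(site %in% c("FT_OVARY_LEFT", "FT_OVARY_RIGHT"), "FTO", site)
}

# -- Error helpers -------------------------------------------------------------

ft_abort <- function(msg, class) {
  stop(structure(
    class = c(class, "ftmicro_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# -- Study container -----------------------------------------------------------

#' Assemble and validate a study bundle
#'
#' A `ftmicro_study` bundles the sample manifest, the species-by-sample read
#' count matrix, the patient metadata table, and (optionally) the taxon niche
#' annotation and qPCR concentration tables, with referential integrity
#' enforced across all five.
#'
#' @param manifest data.frame with columns `sample_id`, `patient_id` (NA for
#'   laboratory controls), `site`, `batch`, `plate`.
#' @param counts Non-negative integer matrix, taxa in rows (rownames =
#'   `taxon_id`), samples in columns (colnames = `sample_id`).
#' @param patients data.frame with columns `patient_id`, `cancer_status`,
#'   `histology`, `stage`, `grade`, `menopausal`, `age_years`, `surgery`,
#'   `pelvic_washing`.
#' @param taxa Optional data.frame with columns `taxon_id`, `species_label`,
#'   `niche` (`G`/`O`/`V`/`S`/`B` or NA).
#' @param concentrations Optional data.frame with columns `sample_id`,
#'   `copies_per_ul` (16S rRNA gene copies per microlitre of DNA extract).
#' @return An object of class `ftmicro_study`.
#' @export
new_study <- function(manifest, counts, patients, taxa = NULL,
                      concentrations = NULL) {
  study <- structure(
    list(manifest = manifest, counts = counts, patients = patients,
         taxa = taxa, concentrations = concentrations),
    class = "ftmicro_study"
  )
  validate_study(study)
  study
}

#' @export
print.ftmicro_study <- function(x, ...) {
  cat("ftmicro study:", nrow(x$counts), "taxa x", ncol(x$counts), "samples;",
      nrow(x$patients), "patients\n")
  tab <- table(site_class(x$manifest$site))
  cat("  samples by site class:",
      paste(names(tab), unname(tab), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Validate a study bundle
#'
#' Checks the structural invariants: unique sample/taxon/patient identifiers,
#' valid enum tokens, laboratory controls without patient links, biological
#' samples with patient links resolving to the patient table, non-negative
#' integer counts, and referential closure of counts and concentrations onto
#' the manifest.
#'
#' @param study A `ftmicro_study`.
#' @return Invisibly, the study (errors on violation).
#' @export
validate_study <- function(study) {
  m <- study$manifest
  req <- c("sample_id", "patient_id", "site", "batch", "plate")
  miss <- setdiff(req, names(m))
  if (length(miss)) {
    ft_abort(paste0("manifest missing required column(s): ",
                    paste(miss, collapse = ", ")), "ftmicro_format_error")
  }
  if (anyDuplicated(m$sample_id)) {
    ft_abort(paste0("duplicate sample_id in manifest: ",
                    paste(unique(m$sample_id[duplicated(m$sample_id)]),
                          collapse = ", ")), "ftmicro_integrity_error")
  }
  bad_site <- !m$site %in% ft_sites
  if (any(bad_site)) {
    ft_abort(paste0("unknown site token(s): ",
                    paste(unique(m$site[bad_site]), collapse = ", ")),
             "ftmicro_value_error")
  }
  is_lab <- m$site %in% lab_control_sites
  if (any(is_lab & !is.na(m$patient_id))) {
    ft_abort("laboratory control samples must have missing patient_id",
             "ftmicro_integrity_error")
  }
  if (any(!is_lab & is.na(m$patient_id))) {
    ft_abort("biological samples must carry a patient_id",
             "ftmicro_integrity_error")
  }

  p <- study$patients
  reqp <- c("patient_id", "cancer_status", "histology", "stage", "grade",
            "menopausal", "age_years", "surgery", "pelvic_washing")
  missp <- setdiff(reqp, names(p))
  if (length(missp)) {
    ft_abort(paste0("patients table missing required column(s): ",
                    paste(missp, collapse = ", ")), "ftmicro_format_error")
  }
  if (anyDuplicated(p$patient_id)) {
    ft_abort("duplicate patient_id in patients table",
             "ftmicro_integrity_error")
  }
  chk_enum <- function(x, levels, what) {
    bad <- !is.na(x) & !x %in% levels
    if (any(bad)) {
      ft_abort(paste0("invalid ", what, " token(s): ",
                      paste(unique(x[bad]), collapse = ", ")),
               "ftmicro_value_error")
    }
  }
  chk_enum(p$cancer_status, cancer_status_levels, "cancer_status")
  chk_enum(p$histology, histology_levels, "histology")
  chk_enum(p$menopausal, menopausal_levels, "menopausal")
  chk_enum(p$surgery, surgery_levels, "surgery")
  chk_enum(p$pelvic_washing, washing_levels, "pelvic_washing")
  # borderline / benign cases are non-cancer and carry histology NONE
  mismatch <- (p$histology == "NONE") != (p$cancer_status == "NON_CANCER")
  if (any(mismatch, na.rm = TRUE)) {
    ft_abort("histology must be NONE exactly for NON_CANCER patients",
             "ftmicro_integrity_error")
  }
  if (any(!is.na(p$age_years) & p$age_years < 0)) {
    ft_abort("age_years must be non-negative", "ftmicro_value_error")
  }
  orphan <- setdiff(m$patient_id[!is.na(m$patient_id)], p$patient_id)
  if (length(orphan)) {
    ft_abort(paste0("manifest patient_id absent from patients table: ",
                    paste(orphan, collapse = ", ")),
             "ftmicro_integrity_error")
  }

  cnt <- study$counts
  if (!is.matrix(cnt)) {
    ft_abort("counts must be a matrix", "ftmicro_format_error")
  }
  if (anyDuplicated(rownames(cnt)) || anyDuplicated(colnames(cnt))) {
    ft_abort("duplicate taxon_id or sample_id in count matrix registries",
             "ftmicro_integrity_error")
  }
  if (length(cnt)) {
    if (anyNA(cnt) || any(cnt < 0)) {
      ft_abort("counts must be non-negative", "ftmicro_value_error")
    }
    if (any(cnt != floor(cnt))) {
      ft_abort("counts must be integers", "ftmicro_value_error")
    }
  }
  extra <- setdiff(colnames(cnt), m$sample_id)
  if (length(extra)) {
    ft_abort(paste0("count matrix sample(s) absent from manifest: ",
                    paste(extra, collapse = ", ")),
             "ftmicro_integrity_error")
  }

  if (!is.null(study$taxa)) {
    tt <- study$taxa
    reqt <- c("taxon_id", "species_label", "niche")
    if (length(setdiff(reqt, names(tt)))) {
      ft_abort(paste0("taxa table missing required column(s): ",
                      paste(setdiff(reqt, names(tt)), collapse = ", ")),
               "ftmicro_format_error")
    }
    if (anyDuplicated(tt$taxon_id)) {
      ft_abort("duplicate taxon_id in taxa table", "ftmicro_integrity_error")
    }
    chk_enum(tt$niche, niche_levels, "niche")
  }

  if (!is.null(study$concentrations)) {
    cc <- study$concentrations
    if (length(setdiff(c("sample_id", "copies_per_ul"), names(cc)))) {
      ft_abort("concentrations table needs columns sample_id, copies_per_ul",
               "ftmicro_format_error")
    }
    extra <- setdiff(cc$sample_id, m$sample_id)
    if (length(extra)) {
      ft_abort(paste0("concentration sample(s) absent from manifest: ",
                      paste(extra, collapse = ", ")),
               "ftmicro_integrity_error")
    }
    if (any(!is.na(cc$copies_per_ul) & cc$copies_per_ul < 0)) {
      ft_abort("concentrations must be non-negative", "ftmicro_value_error")
    }
  }
  invisible(study)
}

# -- TSV dialect ---------------------------------------------------------------
# Tab-delimited, UTF-8, header row, "NA" for missing, newline-terminated,
# fixed column order. Fields may not contain tabs or newlines.

num2str <- function(x) {
  s <- as.character(x)
  ok <- is.na(x) | vapply(seq_along(x), function(i) {
    identical(as.numeric(s[i]), as.numeric(x[i]))
  }, logical(1))
  s[!ok] <- sprintf("%.17g", x[!ok])
  s[is.na(x)] <- "NA"
  s
}

chr2str <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- "NA"
  bad <- grepl("[\t\n\r]", x)
  if (any(bad)) {
    ft_abort("fields may not contain tab or newline characters",
             "ftmicro_value_error")
  }
  x
}

write_tsv_file <- function(df, path, numeric_cols = character(0)) {
  cols <- lapply(names(df), function(nm) {
    if (nm %in% numeric_cols) num2str(df[[nm]]) else chr2str(df[[nm]])
  })
  header <- paste(names(df), collapse = "\t")
  body <- if (nrow(df)) do.call(paste, c(cols, sep = "\t")) else character(0)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(c(header, body)), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

read_tsv_file <- function(path, required = NULL) {
  if (!file.exists(path)) {
    ft_abort(paste0("file not found: ", path), "ftmicro_format_error")
  }
  # "NA" stays a literal token here; only fields where missingness is legal
  # (patient_id, niche, numeric fields) translate it, so enum tokens that
  # happen to be spelled "NA" (pelvic_washing) survive a round-trip
  df <- utils::read.delim(path, sep = "\t", quote = "", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = character(0),
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!is.null(required)) {
    miss <- setdiff(required, names(df))
    if (length(miss)) {
      ft_abort(paste0(basename(path), " missing required column(s): ",
                      paste(miss, collapse = ", ")), "ftmicro_format_error")
    }
  }
  df
}

na_token <- function(x) ifelse(x == "NA", NA_character_, x)

parse_num <- function(x, what) {
  out <- suppressWarnings(as.numeric(ifelse(x == "NA", NA, x)))
  bad <- is.na(out) & x != "NA"
  if (any(bad)) {
    ft_abort(paste0("non-numeric ", what, ": ",
                    paste(unique(x[bad]), collapse = ", ")),
             "ftmicro_value_error")
  }
  out
}

# -- Readers / writers ---------------------------------------------------------

#' Read a study from its on-disk TSV file set
#'
#' Loads and cross-validates the five study tables. All files are
#' tab-delimited UTF-8 with a header row and `NA` for missing values.
#'
#' @param manifest_path TSV with columns `sample_id`, `patient_id`, `site`,
#'   `batch`, `plate`.
#' @param counts_path TSV whose first column is `taxon_id` and remaining
#'   columns are one per `sample_id`.
#' @param patients_path TSV of patient metadata (see [new_study]).
#' @param taxa_path Optional TSV with `taxon_id`, `species_label`, `niche`.
#' @param concentrations_path Optional TSV with `sample_id`, `copies_per_ul`.
#' @return A validated `ftmicro_study`.
#' @export
read_study <- function(manifest_path, counts_path, patients_path,
                       taxa_path = NULL, concentrations_path = NULL) {
  manifest <- read_tsv_file(manifest_path,
                            c("sample_id", "patient_id", "site", "batch",
                              "plate"))
  manifest$patient_id <- na_token(manifest$patient_id)

  craw <- read_tsv_file(counts_path, "taxon_id")
  sample_ids <- setdiff(names(craw), "taxon_id")
  counts <- matrix(0L, nrow = nrow(craw), ncol = length(sample_ids),
                   dimnames = list(craw$taxon_id, sample_ids))
  for (sid in sample_ids) {
    v <- parse_num(craw[[sid]], paste0("count in sample ", sid))
    if (any(is.na(v)) || any(v < 0) || any(v != floor(v))) {
      ft_abort(paste0("negative, missing or non-integer count in sample ",
                      sid), "ftmicro_value_error")
    }
    counts[, sid] <- as.integer(v)
  }

  patients <- read_tsv_file(patients_path,
                            c("patient_id", "cancer_status", "histology",
                              "stage", "grade", "menopausal", "age_years",
                              "surgery", "pelvic_washing"))
  patients$histology <- patients$histology  # tokens kept verbatim
  patients$stage <- parse_num(patients$stage, "stage")
  patients$grade <- parse_num(patients$grade, "grade")
  patients$age_years <- parse_num(patients$age_years, "age_years")
  patients$menopausal <- patients$menopausal

  taxa <- NULL
  if (!is.null(taxa_path)) {
    taxa <- read_tsv_file(taxa_path, c("taxon_id", "species_label", "niche"))
    taxa$niche <- na_token(taxa$niche)
  }
  concentrations <- NULL
  if (!is.null(concentrations_path)) {
    concentrations <- read_tsv_file(concentrations_path,
                                    c("sample_id", "copies_per_ul"))
    concentrations$copies_per_ul <- parse_num(concentrations$copies_per_ul,
                                              "copies_per_ul")
  }
  new_study(manifest, counts, patients, taxa, concentrations)
}

#' Write a study to a directory as TSV files
#'
#' Serialization is bit-stable: fixed column order, tab-delimited UTF-8,
#' `NA` for missing, `\n` line endings, newline-terminated. `read_study()`
#' on the written files reproduces the study exactly.
#'
#' @param study A validated `ftmicro_study`.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a named character vector of the written file paths.
#' @export
write_study <- function(study, out_dir) {
  validate_study(study)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    ft_abort(paste0("cannot create output directory: ", out_dir),
             "ftmicro_io_error")
  }
  paths <- c(
    manifest = file.path(out_dir, "manifest.tsv"),
    counts = file.path(out_dir, "counts.tsv"),
    patients = file.path(out_dir, "patients.tsv")
  )
  m <- study$manifest[, c("sample_id", "patient_id", "site", "batch", "plate")]
  write_tsv_file(m, paths[["manifest"]])

  cnt <- study$counts
  cdf <- data.frame(taxon_id = rownames(cnt) %||% character(0),
                    check.names = FALSE, stringsAsFactors = FALSE)
  for (sid in colnames(cnt)) cdf[[sid]] <- as.integer(cnt[, sid])
  write_tsv_file(cdf, paths[["counts"]],
                 numeric_cols = colnames(cnt) %||% character(0))

  p <- study$patients[, c("patient_id", "cancer_status", "histology", "stage",
                          "grade", "menopausal", "age_years", "surgery",
                          "pelvic_washing")]
  write_tsv_file(p, paths[["patients"]],
                 numeric_cols = c("stage", "grade", "age_years"))

  if (!is.null(study$taxa)) {
    paths[["taxa"]] <- file.path(out_dir, "taxa.tsv")
    write_tsv_file(study$taxa[, c("taxon_id", "species_label", "niche")],
                   paths[["taxa"]])
  }
  if (!is.null(study$concentrations)) {
    paths[["concentrations"]] <- file.path(out_dir, "concentrations.tsv")
    write_tsv_file(study$concentrations[, c("sample_id", "copies_per_ul")],
                   paths[["concentrations"]],
                   numeric_cols = "copies_per_ul")
  }
  invisible(paths)
}

#' Read a study written by [write_study()]
#'
#' Convenience wrapper resolving the standard file names inside `dir`.
#'
#' @param dir Directory containing `manifest.tsv`, `counts.tsv`,
#'   `patients.tsv` and optionally `taxa.tsv`, `concentrations.tsv`.
#' @return A validated `ftmicro_study`.
#' @export
read_study_dir <- function(dir) {
  tx <- file.path(dir, "taxa.tsv")
  cc <- file.path(dir, "concentrations.tsv")
  read_study(file.path(dir, "manifest.tsv"),
             file.path(dir, "counts.tsv"),
             file.path(dir, "patients.tsv"),
             taxa_path = if (file.exists(tx)) tx else NULL,
             concentrations_path = if (file.exists(cc)) cc else NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
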