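# Staged, control-informed contamination filtering.
#
# Low-biomass specimens sit near the contamination floor of extraction kits,
# PCR reagents and ambient air, so taxon tables cannot be interpreted until
# taxa detected in the negative controls are removed. The filter applies a
# fixed, auditable sequence of rules and records, for every taxon, which
# step (if any) removed it.

#' Filtering configuration
#'
#' @param read_threshold Per-(taxon, sample) minimum read count; cells below
#'   it are zeroed before any other step. The canonical rule is 100 reads,
#'   applied as "keep >= threshold" (the boundary cell at exactly the
#'   threshold is kept).
#' @param control_presence_threshold Read count at which a taxon counts as
#'   present in a control sample; defaults to `read_threshold` so control
#'   presence follows the same universal rule.
#' @param require_cervix_copresence If `TRUE` (default), the final step keeps
#'   only taxa present in at least one cervical and one FTO sample; if
#'   `FALSE`, FTO presence alone suffices.
#' @param within_patient_copresence If `TRUE`, the cervix/FTO co-presence must
#'   occur within the same patient (sensitivity analysis); the default
#'   counts samples study-wide.
#' @param exclude_sites_as_controls Site classes used as exclusion tiers.
#'   Defaults to the laboratory controls plus operating-room air.
#' @param use_port_as_control If `TRUE`, laparoscopic-port swabs join the air
#'   exclusion tier. Off by default: port swabs are comparison samples, not
#'   an exclusion criterion.
#' @return A `ftmicro_filter_config` list.
#' @export
filter_config <- function(read_threshold = 100,
                          control_presence_threshold = read_threshold,
                          require_cervix_copresence = TRUE,
                          within_patient_copresence = FALSE,
                          exclude_sites_as_controls =
                            c("BUFFER_CONTROL", "NO_TEMPLATE_CONTROL",
                              "OR_AIR"),
                          use_port_as_control = FALSE) {
  if (read_threshold < 1 || control_presence_threshold < 1) {
    ft_abort("thresholds must be >= 1", "ftmicro_value_error")
  }
  bad <- setdiff(exclude_sites_as_controls,
                 c(lab_control_sites, "OR_AIR", "LAPAROSCOPIC_PORT"))
  if (length(bad)) {
    ft_abort(paste0("invalid control site class(es): ",
                    paste(bad, collapse = ", ")), "ftmicro_value_error")
  }
  structure(list(
    read_threshold = read_threshold,
    control_presence_threshold = control_presence_threshold,
    require_cervix_copresence = require_cervix_copresence,
    within_patient_copresence = within_patient_copresence,
    exclude_sites_as_controls = exclude_sites_as_controls,
    use_port_as_control = use_port_as_control
  ), class = "ftmicro_filter_config")
}

#' Zero out count cells below a read threshold
#'
#' Taxa represented by fewer than `read_threshold` reads in a sample are
#' excluded from that sample (the cell is set to zero); cells at or above
#' the threshold are unchanged. Applied per (taxon, sample) before merging.
#'
#' @param counts Non-negative integer matrix (taxa x samples).
#' @param read_threshold Minimum per-cell read count (default 100).
#' @return Matrix of the same shape.
#' @export
threshold_counts <- function(counts, read_threshold = 100) {
  if (read_threshold < 1) {
    ft_abort("read_threshold must be >= 1", "ftmicro_value_error")
  }
  counts[counts < read_threshold] <- 0L
  counts
}

#' Merge count columns by patient and analysis site class
#'
#' Columns from the same patient and the same site class (left and right FTO
#' swabs, repeated swabs of one site) are summed into one column. Laboratory
#' controls carry no patient and are merged only within identical
#' (site, batch); total reads are conserved.
#'
#' @param counts Taxa x samples matrix (typically thresholded).
#' @param manifest Sample manifest covering every column.
#' @return A list of class `ftmicro_merged` with elements `counts` (merged
#'   matrix) and `manifest` (data.frame: `sample_id`, `patient_id`,
#'   `site_class`, `batch`, `plate`).
#' @export
merge_by_patient_site <- function(counts, manifest) {
  idx <- match(colnames(counts), manifest$sample_id)
  if (anyNA(idx)) {
    ft_abort("count matrix contains samples absent from the manifest",
             "ftmicro_integrity_error")
  }
  mm <- manifest[idx, , drop = FALSE]
  scls <- site_class(mm$site)
  key <- ifelse(is.na(mm$patient_id),
                paste(mm$site, mm$batch, sep = "|"),
                paste(mm$patient_id, scls, sep = "|"))
  groups <- split(seq_along(key), key)
  ord <- order(vapply(groups, min, integer(1)))  # keep first-seen order
  groups <- groups[ord]
  merged <- vapply(groups, function(cols) {
    if (length(cols) == 1L) counts[, cols] else
      as.integer(rowSums(counts[, cols, drop = FALSE]))
  }, integer(nrow(counts)))
  if (is.null(dim(merged))) {              # single-taxon edge case
    merged <- matrix(merged, nrow = nrow(counts),
                     dimnames = list(rownames(counts), names(groups)))
  }
  collapse <- function(x) paste(sort(unique(x)), collapse = "+")
  man2 <- data.frame(
    sample_id = gsub("|", "_", names(groups), fixed = TRUE),
    patient_id = vapply(groups, function(cols) mm$patient_id[cols[1]],
                        character(1)),
    site_class = vapply(groups, function(cols) scls[cols[1]], character(1)),
    batch = vapply(groups, function(cols) collapse(mm$batch[cols]),
                   character(1)),
    plate = vapply(groups, function(cols) collapse(mm$plate[cols]),
                   character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  colnames(merged) <- man2$sample_id
  rownames(merged) <- rownames(counts)
  structure(list(counts = merged, manifest = man2), class = "ftmicro_merged")
}

#' Taxa present in a set of site classes
#'
#' A taxon is present when it reaches `presence_threshold` reads in at least
#' one sample whose site class belongs to `site_set`.
#'
#' @param merged A `ftmicro_merged` (see [merge_by_patient_site()]).
#' @param site_set Character vector of site classes (`FTO`, `CERVIX`,
#'   `PARACOLIC_GUTTER`, `LAPAROSCOPIC_PORT`, `OR_AIR`, `BUFFER_CONTROL`,
#'   `NO_TEMPLATE_CONTROL`).
#' @param presence_threshold Minimum read count (default 100).
#' @return Character vector of taxon ids (possibly empty).
#' @export
taxa_present_in <- function(merged, site_set, presence_threshold = 100) {
  valid <- unique(site_class(ft_sites))
  bad <- setdiff(site_set, valid)
  if (length(bad)) {
    ft_abort(paste0("unknown site class token(s): ",
                    paste(bad, collapse = ", ")), "ftmicro_value_error")
  }
  if (length(site_set) == 0) return(character(0))
  sel <- merged$manifest$site_class %in% site_set
  if (!any(sel)) return(character(0))
  sub <- merged$counts[, sel, drop = FALSE]
  rownames(sub)[apply(sub >= presence_threshold, 1, any)]
}

filter_step_names <- c("per_sample_read_threshold", "merge_patient_site",
                       "prune_zero_taxa", "remove_no_template_control",
                       "remove_buffer_control", "remove_air",
                       "require_cervix_ft_copresence")

#' Run the staged contamination filter
#'
#' Canonical step order:
#' 1. per-(taxon, sample) read threshold (cells below `read_threshold` set
#'    to zero);
#' 2. merge columns by (patient, site class);
#' 3. drop taxa with zero reads everywhere;
#' 4. remove taxa present in any no-template PCR control;
#' 5. remove taxa present in any buffer (sham extraction) control — the
#'    survivors of this step that carry reads in cervix, FTO or paracolic
#'    gutter samples form the *diversity set* used for Shannon analyses;
#' 6. remove taxa present in operating-room air swabs (and laparoscopic-port
#'    swabs when `use_port_as_control`);
#' 7. keep taxa present (at `read_threshold`) in at least one cervical and
#'    one FTO sample.
#'
#' The survivors are the candidate FT microbiota. A configured control tier
#' with no samples in the study becomes a no-op and is recorded as a warning
#' in the ledger rather than aborting the run.
#'
#' @param study A `ftmicro_study`.
#' @param config A `ftmicro_filter_config`.
#' @return A list of class `ftmicro_filter_result`: `survivors` (taxon ids),
#'   `diversity_set` (post-step-5 taxa restricted to cervix/FTO/paracolic),
#'   `counts` (merged, thresholded matrix over all input taxa), `manifest`
#'   (merged sample table), `filtered_counts` (survivor rows only), `ledger`
#'   (per-taxon status and removal step), `ledger_summary` (per-step taxa
#'   entering / removed), `warnings`, `config`.
#' @export
run_filter <- function(study, config = filter_config()) {
  validate_study(study)
  thr <- threshold_counts(study$counts, config$read_threshold)
  merged <- merge_by_patient_site(thr, study$manifest)

  taxa_all <- rownames(study$counts) %||% character(0)
  removal_step <- stats::setNames(rep(NA_integer_, length(taxa_all)),
                                  taxa_all)
  warnings <- character(0)
  alive <- taxa_all

  n_in <- integer(7); n_rm <- integer(7)
  mark <- function(step, removed) {
    n_in[step] <<- length(alive)
    removed <- intersect(removed, alive)
    n_rm[step] <<- length(removed)
    removal_step[removed] <<- step
    alive <<- setdiff(alive, removed)
  }
  mark(1, character(0))   # thresholding and merging remove no taxon rows
  mark(2, character(0))

  keep <- rownames(merged$counts)[rowSums(merged$counts) > 0]
  mark(3, setdiff(alive, keep))

  control_tier <- function(step, classes) {
    classes <- intersect(classes, config$exclude_sites_as_controls)
    present <- character(0)
    for (cl in classes) {
      if (!any(merged$manifest$site_class == cl)) {
        warnings <<- c(warnings,
                       sprintf("step %d: no %s samples in study; tier is a no-op",
                               step, cl))
      } else {
        present <- union(present,
                         taxa_present_in(merged, cl,
                                         config$control_presence_threshold))
      }
    }
    mark(step, present)
  }
  control_tier(4, "NO_TEMPLATE_CONTROL")
  control_tier(5, "BUFFER_CONTROL")

  # diversity set: post-step-5 survivors carrying reads at the three
  # biological comparison sites
  bio_sel <- merged$manifest$site_class %in%
    c("CERVIX", "FTO", "PARACOLIC_GUTTER")
  div_counts <- merged$counts[alive, bio_sel, drop = FALSE]
  diversity_set <- alive[rowSums(div_counts) > 0]

  air_classes <- "OR_AIR"
  if (isTRUE(config$use_port_as_control)) {
    air_classes <- c(air_classes, "LAPAROSCOPIC_PORT")
  }
  present_air <- character(0)
  for (cl in air_classes) {
    if (!any(merged$manifest$site_class == cl)) {
      warnings <- c(warnings,
                    sprintf("step 6: no %s samples in study; tier is a no-op",
                            cl))
    } else if (cl %in% config$exclude_sites_as_controls ||
               cl == "LAPAROSCOPIC_PORT") {
      present_air <- union(present_air,
                           taxa_present_in(merged, cl,
                                           config$control_presence_threshold))
    }
  }
  mark(6, present_air)

  if (isTRUE(config$require_cervix_copresence)) {
    fail7 <- setdiff(alive,
                     copresent_taxa(merged, config$read_threshold,
                                    config$within_patient_copresence))
  } else {
    fail7 <- setdiff(alive,
                     taxa_present_in(merged, "FTO", config$read_threshold))
  }
  missing_sites <- setdiff(c("CERVIX", "FTO"), merged$manifest$site_class)
  if (length(missing_sites)) {
    warnings <- c(warnings,
                  sprintf("step 7: no %s samples in study",
                          paste(missing_sites, collapse = "/")))
  }
  mark(7, fail7)

  ledger <- data.frame(
    taxon_id = taxa_all,
    status = ifelse(is.na(removal_step[taxa_all]), "SURVIVED", "REMOVED"),
    removal_step = as.integer(removal_step[taxa_all]),
    removal_step_name = ifelse(is.na(removal_step[taxa_all]), NA_character_,
                               filter_step_names[removal_step[taxa_all]]),
    row.names = NULL, stringsAsFactors = FALSE
  )
  ledger_summary <- data.frame(
    step = 1:7, step_name = filter_step_names,
    n_in = n_in, n_removed = n_rm, n_out = n_in - n_rm,
    stringsAsFactors = FALSE
  )
  structure(list(
    survivors = alive,
    diversity_set = diversity_set,
    counts = merged$counts,
    manifest = merged$manifest,
    filtered_counts = merged$counts[alive, , drop = FALSE],
    ledger = ledger,
    ledger_summary = ledger_summary,
    warnings = warnings,
    config = config
  ), class = "ftmicro_filter_result")
}

# taxa with >= threshold reads in >= 1 cervical and >= 1 FTO sample,
# optionally requiring both within the same patient
copresent_taxa <- function(merged, threshold, within_patient = FALSE) {
  man <- merged$manifest
  if (!within_patient) {
    return(intersect(taxa_present_in(merged, "CERVIX", threshold),
                     taxa_present_in(merged, "FTO", threshold)))
  }
  cvx <- merged$counts[, man$site_class == "CERVIX", drop = FALSE] >= threshold
  fto <- merged$counts[, man$site_class == "FTO", drop = FALSE] >= threshold
  cvx_pat <- man$patient_id[man$site_class == "CERVIX"]
  fto_pat <- man$patient_id[man$site_class == "FTO"]
  hit <- vapply(seq_len(nrow(merged$counts)), function(i) {
    length(intersect(cvx_pat[cvx[i, ]], fto_pat[fto[i, ]])) > 0
  }, logical(1))
  rownames(merged$counts)[hit]
}

#' @export
print.ftmicro_filter_result <- function(x, ...) {
  cat("ftmicro filter result:", length(x$survivors),
      "candidate FT taxa of", nrow(x$ledger), "input taxa;",
      length(x$diversity_set), "taxa in the diversity set\n")
  print(x$ledger_summary, row.names = FALSE)
  if (length(x$warnings)) cat("warnings:", paste(x$warnings, collapse = "; "),
                              "\n")
  invisible(x)
}
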