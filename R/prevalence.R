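# Per-individual prevalence of candidate FT taxa, cancer vs non-cancer
# ranking, niche composition of the top-ranked species, stratified
# sensitivity analyses and the cohort demographics summary.

round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Per-individual presence of surviving taxa
#'
#' A patient is positive for a taxon when their merged sample of the given
#' site class carries at least `read_threshold` reads of it. Patients
#' without any sample of the class are excluded from the table (and hence
#' from every prevalence denominator).
#'
#' @param merged_counts Merged, thresholded count matrix (e.g.
#'   `run_filter(...)$counts`).
#' @param merged_manifest Matching merged sample table
#'   (`run_filter(...)$manifest`).
#' @param survivors Character vector of taxon ids to report.
#' @param site_cls Site class defining presence (default `"FTO"`).
#' @param read_threshold Presence cut-off (default 100).
#' @return Logical matrix, patients in rows, taxa in columns. Empty survivor
#'   set yields a zero-column matrix.
#' @export
presence_by_individual <- function(merged_counts, merged_manifest, survivors,
                                   site_cls = "FTO", read_threshold = 100) {
  taxa <- intersect(rownames(merged_counts), survivors)
  sel <- merged_manifest$site_class == site_cls &
    !is.na(merged_manifest$patient_id)
  cnt <- merged_counts[taxa, sel, drop = FALSE]
  pats <- merged_manifest$patient_id[sel]
  pres <- t(cnt >= read_threshold)
  rownames(pres) <- pats
  colnames(pres) <- taxa
  pres
}

resolve_strata <- function(patients, stratifier) {
  switch(stratifier,
    cancer_status = list(
      a = patients$patient_id[patients$cancer_status == "CANCER"],
      b = patients$patient_id[patients$cancer_status == "NON_CANCER"],
      names = c("CANCER", "NON_CANCER")),
    histology = list(
      a = patients$patient_id[patients$cancer_status == "CANCER" &
                                patients$histology == "SEROUS"],
      b = patients$patient_id[patients$cancer_status == "CANCER" &
                                patients$histology == "NON_SEROUS"],
      names = c("SEROUS", "NON_SEROUS")),
    surgery = list(
      a = patients$patient_id[patients$surgery == "LAPAROTOMY"],
      b = patients$patient_id[patients$surgery %in%
                                c("LAPAROSCOPY", "ROBOTIC")],
      names = c("LAPAROTOMY", "MINIMALLY_INVASIVE")),
    ft_abort(paste0("unknown stratifier: ", stratifier),
             "ftmicro_value_error"))
}

#' Per-taxon prevalence by patient stratum, with difference ranking
#'
#' Prevalence is the percentage of individuals in a stratum positive for the
#' taxon (see [presence_by_individual()]); percentages are reported to one
#' decimal (rounding half away from zero). Taxa are ranked by the signed
#' prevalence difference (stratum A minus stratum B, descending); ties are
#' broken by species label ascending so the ranking is a strict total order.
#'
#' @param presence Logical patient x taxon matrix.
#' @param patients Patient metadata table.
#' @param stratifier `"cancer_status"` (cancer vs non-cancer),
#'   `"histology"` (serous vs non-serous within cancer) or `"surgery"`
#'   (laparotomy vs minimally invasive).
#' @param taxa Optional taxon annotation table (`taxon_id`, `species_label`,
#'   `niche`).
#' @return data.frame of class `ftmicro_prevalence`: `taxon_id`,
#'   `species_label`, `niche`, `prevalence_a`, `prevalence_b`,
#'   `difference`, `rank`; attributes `strata` (names) and `n` (denominator
#'   per stratum).
#' @export
prevalence_table <- function(presence, patients,
                             stratifier = "cancer_status", taxa = NULL) {
  st <- resolve_strata(patients, stratifier)
  in_a <- rownames(presence) %in% st$a
  in_b <- rownames(presence) %in% st$b
  if (!any(in_a)) {
    ft_abort(paste0("empty stratum: ", st$names[1]), "ftmicro_value_error")
  }
  if (!any(in_b)) {
    ft_abort(paste0("empty stratum: ", st$names[2]), "ftmicro_value_error")
  }
  prev_a <- round_half_away(100 * colMeans(presence[in_a, , drop = FALSE]))
  prev_b <- round_half_away(100 * colMeans(presence[in_b, , drop = FALSE]))
  ids <- colnames(presence)
  label <- ids
  niche <- rep(NA_character_, length(ids))
  if (!is.null(taxa)) {
    idx <- match(ids, taxa$taxon_id)
    label <- ifelse(is.na(idx), ids, taxa$species_label[idx])
    niche <- taxa$niche[idx]
  }
  diff <- prev_a - prev_b
  ord <- order(-diff, label)
  rank <- integer(length(ids))
  rank[ord] <- seq_along(ids)
  out <- data.frame(taxon_id = ids, species_label = label, niche = niche,
                    prevalence_a = unname(prev_a),
                    prevalence_b = unname(prev_b),
                    difference = unname(diff), rank = rank,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "strata") <- st$names
  attr(out, "n") <- c(sum(in_a), sum(in_b))
  class(out) <- c("ftmicro_prevalence", "data.frame")
  out
}

#' Niche composition of the top-ranked taxa
#'
#' Takes the `k` taxa with the largest signed prevalence difference
#' (`direction = "cancer"`, i.e. most enriched in stratum A) or the smallest
#' (`direction = "non_cancer"`) and tallies their niche codes. The
#' "outside the female reproductive tract" aggregate counts G + O + S
#' (broadly-present taxa have no predominant niche and are excluded from the
#' aggregate).
#'
#' @param prev_table A `ftmicro_prevalence` table whose taxa all carry a
#'   niche code.
#' @param k Number of top taxa (default 20).
#' @param direction `"cancer"`/`"positive"` for stratum-A enrichment,
#'   `"non_cancer"`/`"negative"` for stratum-B enrichment.
#' @return List of class `ftmicro_niche_composition`: `taxa` (ids in rank
#'   order), `counts` (named over G,O,V,S,B), `percentages`,
#'   `non_reproductive_pct`, `k`, `direction`.
#' @export
top_k_niche <- function(prev_table, k = 20,
                        direction = c("cancer", "non_cancer", "positive",
                                      "negative")) {
  direction <- match.arg(direction)
  positive <- direction %in% c("cancer", "positive")
  if (k > nrow(prev_table)) {
    ft_abort("k exceeds the number of taxa", "ftmicro_value_error")
  }
  tab <- prev_table[order(prev_table$rank), , drop = FALSE]
  sel <- if (positive) tab[seq_len(k), ] else tab[nrow(tab) - k:1 + 1, ]
  no_niche <- is.na(sel$niche)
  if (any(no_niche)) {
    ft_abort(paste0("taxa without niche code: ",
                    paste(sel$taxon_id[no_niche], collapse = ", ")),
             "ftmicro_value_error")
  }
  counts <- table(factor(sel$niche, levels = niche_levels))
  counts <- stats::setNames(as.integer(counts), niche_levels)
  pct <- round_half_away(100 * counts / k)
  structure(list(taxa = sel$taxon_id, counts = counts, percentages = pct,
                 non_reproductive_pct =
                   round_half_away(100 * sum(counts[c("G", "O", "S")]) / k),
                 k = k, direction = direction),
            class = "ftmicro_niche_composition")
}

#' @export
print.ftmicro_niche_composition <- function(x, ...) {
  cat(sprintf("top %d taxa (%s direction): ", x$k, x$direction))
  cat(paste(names(x$counts), x$counts, sep = "=", collapse = ", "), "\n")
  cat(sprintf("outside the reproductive tract (G+O+S): %.1f%%\n",
              x$non_reproductive_pct))
  invisible(x)
}

#' Surgery-type sensitivity analyses
#'
#' (a) repeats the cancer vs non-cancer prevalence comparison restricted to
#' laparotomy patients; (b) compares laparotomy against laparoscopic/robotic
#' cases within the non-cancer patients. For each restricted table a
#' rank-concordance summary (Spearman correlation of per-taxon prevalence
#' differences against the full cancer vs non-cancer table) is reported.
#' A restriction that empties a stratum skips that table with an explicit
#' notice instead of failing.
#'
#' @param presence Logical patient x taxon matrix.
#' @param patients Patient metadata table.
#' @param taxa Optional taxon annotation table.
#' @return List: `full` (unrestricted cancer vs non-cancer table),
#'   `laparotomy_only`, `surgery_within_noncancer` (either may be NULL),
#'   `concordance` (data.frame `table`, `spearman`), `notices`.
#' @export
stratified_sensitivity <- function(presence, patients, taxa = NULL) {
  full <- prevalence_table(presence, patients, "cancer_status", taxa)
  notices <- character(0)
  try_table <- function(pres, pats, stratifier, what) {
    tryCatch(prevalence_table(pres, pats, stratifier, taxa),
             ftmicro_value_error = function(e) {
               notices <<- c(notices, paste0(what, " skipped: ",
                                             conditionMessage(e)))
               NULL
             })
  }
  lap_ids <- patients$patient_id[patients$surgery == "LAPAROTOMY"]
  lap_pres <- presence[rownames(presence) %in% lap_ids, , drop = FALSE]
  lap_tab <- try_table(lap_pres, patients, "cancer_status",
                       "laparotomy-only comparison")
  nc <- patients[patients$cancer_status == "NON_CANCER", , drop = FALSE]
  nc_pres <- presence[rownames(presence) %in% nc$patient_id, , drop = FALSE]
  surg_tab <- try_table(nc_pres, nc, "surgery",
                        "surgery comparison within non-cancer")
  conc <- list()
  add_conc <- function(tab, name) {
    if (is.null(tab)) return()
    idx <- match(full$taxon_id, tab$taxon_id)
    conc[[length(conc) + 1]] <<- data.frame(
      table = name,
      spearman = suppressWarnings(
        stats::cor(full$difference, tab$difference[idx],
                   method = "spearman")),
      stringsAsFactors = FALSE)
  }
  add_conc(lap_tab, "laparotomy_only")
  add_conc(surg_tab, "surgery_within_noncancer")
  list(full = full, laparotomy_only = lap_tab,
       surgery_within_noncancer = surg_tab,
       concordance = if (length(conc)) do.call(rbind, conc) else NULL,
       notices = notices)
}

#' Cohort demographics summary with group comparison tests
#'
#' Per group (cancer / non-cancer): counts and percentages for every
#' categorical characteristic (menopausal status, stage, grade, histology,
#' surgery type, pelvic washing, plus any additional character columns
#' present, e.g. race or ethnicity) and means for age. Percentages are
#' 100 x count / group size at one decimal, rounding half away from zero.
#' Group comparisons use a two-sided Welch t-test for means and a chi-square
#' test for categorical variables, falling back to Fisher's exact test when
#' any expected cell is below 5; characteristics defined only within the
#' cancer group (stage, grade, histology) are summarised without a test.
#'
#' @param patients Patient metadata table.
#' @return List of class `ftmicro_cohort_summary`: `groups` (sizes),
#'   `categorical` (data.frame `variable`, `level`, `n_cancer`,
#'   `pct_cancer`, `n_noncancer`, `pct_noncancer`), `continuous`
#'   (`variable`, `mean_cancer`, `mean_noncancer`, `p_value`), `tests`
#'   (`variable`, `method`, `p_value`).
#' @export
summarize_cohort <- function(patients) {
  ca <- patients[patients$cancer_status == "CANCER", , drop = FALSE]
  nc <- patients[patients$cancer_status == "NON_CANCER", , drop = FALSE]
  if (!nrow(ca) || !nrow(nc)) {
    ft_abort("both cancer and non-cancer groups must be non-empty",
             "ftmicro_value_error")
  }
  core <- c("menopausal", "stage", "grade", "histology", "surgery",
            "pelvic_washing")
  extra <- setdiff(names(patients)[vapply(patients, is.character,
                                          logical(1))],
                   c("patient_id", "cancer_status", core))
  cancer_only <- c("stage", "grade", "histology")
  cat_rows <- list(); test_rows <- list()
  for (v in c(core, extra)) {
    xa <- ca[[v]]; xn <- nc[[v]]
    if (v %in% cancer_only) xn <- xn[0]
    levels <- sort(unique(stats::na.omit(c(as.character(xa),
                                           as.character(xn)))))
    if (!length(levels)) next
    for (lv in levels) {
      na_ <- sum(!is.na(xa) & as.character(xa) == lv)
      nn_ <- sum(!is.na(xn) & as.character(xn) == lv)
      cat_rows[[length(cat_rows) + 1]] <- data.frame(
        variable = v, level = lv,
        n_cancer = na_, pct_cancer = round_half_away(100 * na_ / nrow(ca)),
        n_noncancer = nn_,
        pct_noncancer = round_half_away(100 * nn_ / nrow(nc)),
        stringsAsFactors = FALSE)
    }
    if (v %in% cancer_only) {
      test_rows[[length(test_rows) + 1]] <- data.frame(
        variable = v, method = "none (cancer-only characteristic)",
        p_value = NA_real_, stringsAsFactors = FALSE)
      next
    }
    tab <- table(
      group = rep(c("CANCER", "NON_CANCER"), c(length(xa), length(xn))),
      level = factor(c(as.character(xa), as.character(xn)), levels = levels))
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    if (ncol(tab) < 2) {
      test_rows[[length(test_rows) + 1]] <- data.frame(
        variable = v, method = "none (single level)", p_value = NA_real_,
        stringsAsFactors = FALSE)
      next
    }
    chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    if (any(chi$expected < 5)) {
      p <- stats::fisher.test(tab, simulate.p.value = ncol(tab) > 5,
                              B = 1e4)$p.value
      method <- "fisher"
    } else {
      p <- chi$p.value
      method <- "chi-square"
    }
    test_rows[[length(test_rows) + 1]] <- data.frame(
      variable = v, method = method, p_value = p, stringsAsFactors = FALSE)
  }
  wt <- welch_t_stat(ca$age_years[!is.na(ca$age_years)],
                     nc$age_years[!is.na(nc$age_years)])
  continuous <- data.frame(
    variable = "age_years",
    mean_cancer = mean(ca$age_years, na.rm = TRUE),
    mean_noncancer = mean(nc$age_years, na.rm = TRUE),
    p_value = wt$p, stringsAsFactors = FALSE)
  test_rows[[length(test_rows) + 1]] <- data.frame(
    variable = "age_years",
    method = if (wt$zero_variance) "welch (degenerate variance)" else "welch",
    p_value = wt$p, stringsAsFactors = FALSE)
  structure(list(
    groups = c(CANCER = nrow(ca), NON_CANCER = nrow(nc)),
    categorical = do.call(rbind, cat_rows),
    continuous = continuous,
    tests = do.call(rbind, test_rows)
  ), class = "ftmicro_cohort_summary")
}

#' @export
print.ftmicro_cohort_summary <- function(x, ...) {
  cat("cohort:", paste(names(x$groups), x$groups, sep = "=",
                       collapse = ", "), "\n")
  print(x$categorical, row.names = FALSE)
  print(x$continuous, row.names = FALSE)
  invisible(x)
}
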