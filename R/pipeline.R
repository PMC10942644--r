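# End-to-end driver: simulate (optional) -> filter -> concentration ->
# diversity -> prevalence, with a reproducible run record.

write_table_tsv <- function(df, path) {
  num <- names(df)[vapply(df, is.numeric, logical(1))]
  for (nm in setdiff(names(df), num)) df[[nm]] <- as.character(df[[nm]])
  write_tsv_file(df, path, numeric_cols = num)
}

#' Build a pipeline run configuration
#'
#' Either `study_dir` (an on-disk study written by [write_study()]) or
#' `sim` (a [sim_config()] to generate one) must be given.
#'
#' @param out_dir Output directory.
#' @param study_dir Directory with the five study TSVs, or `NULL`.
#' @param sim A `ftmicro_sim_config`, or `NULL`.
#' @param filter A `ftmicro_filter_config`.
#' @param transform Ordination transform (see [ordinate()]).
#' @param k Number of ordination components.
#' @param topk Size of the niche-composition head (default 20).
#' @return A `ftmicro_run_config` list.
#' @export
run_config <- function(out_dir, study_dir = NULL, sim = NULL,
                       filter = filter_config(), transform = "hellinger",
                       k = 2, topk = 20) {
  if (is.null(study_dir) == is.null(sim)) {
    ft_abort("exactly one of study_dir or sim must be given",
             "ftmicro_value_error")
  }
  structure(list(out_dir = out_dir, study_dir = study_dir, sim = sim,
                 filter = filter, transform = transform, k = k,
                 topk = topk),
            class = "ftmicro_run_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Executes every stage and writes all declared outputs under
#' `config$out_dir`, together with `run_record.txt` (resolved configuration
#' and package version) and `input_hashes.tsv` (MD5 of every written file).
#' Reruns with the same configuration and seed are byte-identical.
#'
#' @param config A `ftmicro_run_config`.
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_all <- function(config) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  truth <- NULL
  if (!is.null(config$sim)) {
    simmed <- run_stage("simulate", simulate_study(config$sim))
    study <- simmed$study
    truth <- simmed$truth
    run_stage("write_study", write_study(study, file.path(out, "study")))
    write_table_tsv(truth, file.path(out, "study", "truth.tsv"))
  } else {
    study <- run_stage("read_study", read_study_dir(config$study_dir))
  }

  fr <- run_stage("filter", run_filter(study, config$filter))
  write_table_tsv(data.frame(taxon_id = fr$survivors,
                             stringsAsFactors = FALSE),
                  file.path(out, "survivors.tsv"))
  write_table_tsv(data.frame(taxon_id = fr$diversity_set,
                             stringsAsFactors = FALSE),
                  file.path(out, "diversity_set.tsv"))
  fc <- data.frame(taxon_id = rownames(fr$filtered_counts),
                   stringsAsFactors = FALSE)
  for (sid in colnames(fr$filtered_counts)) {
    fc[[sid]] <- fr$filtered_counts[, sid]
  }
  write_table_tsv(fc, file.path(out, "filtered_counts.tsv"))
  write_table_tsv(fr$ledger, file.path(out, "ledger.tsv"))
  write_table_tsv(fr$ledger_summary, file.path(out, "ledger_summary.tsv"))

  results <- list(study = study, truth = truth, filter = fr)

  if (!is.null(study$concentrations)) {
    conc <- run_stage("concentration", concentration_comparisons(study))
    write_table_tsv(conc, file.path(out, "concentration_comparisons.tsv"))
    results$concentration <- conc
  }

  div <- run_stage("diversity",
                   diversity_comparisons(study, fr$diversity_set,
                                         config$filter))
  write_table_tsv(div$shannon, file.path(out, "shannon.tsv"))
  if (!is.null(div$comparisons)) {
    write_table_tsv(div$comparisons,
                    file.path(out, "diversity_comparisons.tsv"))
  }
  results$diversity <- div

  if (length(fr$survivors) >= 2) {
    ord <- run_stage("ordination",
                     ordinate(study, fr$survivors, k = config$k,
                              transform = config$transform))
    write_table_tsv(ord$scores, file.path(out, "ordination_scores.tsv"))
    write_table_tsv(
      data.frame(component = seq_along(ord$explained_variance),
                 explained_variance = ord$explained_variance),
      file.path(out, "ordination_variance.tsv"))
    results$ordination <- ord
  }

  overview <- run_stage("overview",
                        export_overview(study, fr$survivors, config$filter))
  write_table_tsv(overview, file.path(out, "overview_long.tsv"))
  results$overview <- overview

  if (length(fr$survivors)) {
    pres <- run_stage("prevalence",
                      presence_by_individual(fr$counts, fr$manifest,
                                             fr$survivors,
                                             read_threshold =
                                               config$filter$read_threshold))
    prev <- run_stage("prevalence",
                      prevalence_table(pres, study$patients,
                                       "cancer_status", study$taxa))
    write_table_tsv(prev, file.path(out, "prevalence.tsv"))
    results$presence <- pres
    results$prevalence <- prev
    if (config$topk <= nrow(prev) && !anyNA(prev$niche)) {
      nk <- top_k_niche(prev, config$topk, "cancer")
      write_table_tsv(
        data.frame(niche = names(nk$counts), n = nk$counts,
                   pct = nk$percentages),
        file.path(out, "topk_niche.tsv"))
      results$topk_niche <- nk
    }
    strat <- run_stage("prevalence",
                       stratified_sensitivity(pres, study$patients,
                                              study$taxa))
    dir.create(file.path(out, "stratified"), showWarnings = FALSE)
    if (!is.null(strat$laparotomy_only)) {
      write_table_tsv(strat$laparotomy_only,
                      file.path(out, "stratified", "laparotomy_only.tsv"))
    }
    if (!is.null(strat$surgery_within_noncancer)) {
      write_table_tsv(strat$surgery_within_noncancer,
                      file.path(out, "stratified",
                                "surgery_within_noncancer.tsv"))
    }
    if (!is.null(strat$concordance)) {
      write_table_tsv(strat$concordance,
                      file.path(out, "stratified", "concordance.tsv"))
    }
    results$stratified <- strat
  }

  cs <- run_stage("cohort_summary", summarize_cohort(study$patients))
  write_table_tsv(cs$categorical, file.path(out, "cohort_summary.tsv"))
  write_table_tsv(cs$tests, file.path(out, "cohort_summary_tests.tsv"))
  results$cohort_summary <- cs

  record <- c(
    paste0("ftmicro version: ",
           as.character(utils::packageVersion("ftmicro"))),
    "resolved configuration:",
    utils::capture.output(utils::str(config, give.attr = FALSE))
  )
  con <- file(file.path(out, "run_record.txt"), "wb")
  writeLines(enc2utf8(record), con, sep = "\n", useBytes = TRUE)
  close(con)

  files <- sort(setdiff(list.files(out, recursive = TRUE),
                        "input_hashes.tsv"))
  hashes <- data.frame(file = files,
                       md5 = unname(tools::md5sum(file.path(out, files))),
                       stringsAsFactors = FALSE)
  write_table_tsv(hashes, file.path(out, "input_hashes.tsv"))
  invisible(results)
}
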