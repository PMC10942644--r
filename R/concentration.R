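# Bacterial-load comparisons from broad-range qPCR 16S copy concentrations.

conc_transform <- function(transform, pseudocount = 0.1) {
  if (is.function(transform)) return(transform)
  switch(transform,
         log10 = function(x) log10(x + pseudocount),
         identity = identity,
         ft_abort(paste0("unknown transform: ", transform),
                  "ftmicro_value_error"))
}

# per-(patient, site-class) mean concentration; one value per patient & class
patient_site_concentration <- function(conc, manifest) {
  idx <- match(conc$sample_id, manifest$sample_id)
  if (anyNA(idx)) {
    ft_abort("concentration samples absent from manifest",
             "ftmicro_integrity_error")
  }
  keep <- !is.na(conc$copies_per_ul) & !is.na(manifest$patient_id[idx])
  df <- data.frame(patient_id = manifest$patient_id[idx][keep],
                   site_class = site_class(manifest$site[idx][keep]),
                   value = conc$copies_per_ul[keep],
                   stringsAsFactors = FALSE)
  stats::aggregate(value ~ patient_id + site_class, data = df, FUN = mean)
}

#' Summarize qPCR concentrations for one site class
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of
#' copies/microlitre on the raw scale, over all samples of the class with a
#' measured concentration.
#'
#' @param conc data.frame with `sample_id`, `copies_per_ul`.
#' @param manifest Sample manifest.
#' @param site_cls One site class token, e.g. `"FTO"`.
#' @return List with `mean`, `sd` (NA when n < 2) and `n` (0 when no sample
#'   of the class carries a concentration; then `mean` is NA too).
#' @export
summarize_concentration <- function(conc, manifest, site_cls) {
  idx <- match(conc$sample_id, manifest$sample_id)
  if (anyNA(idx)) {
    ft_abort("concentration samples absent from manifest",
             "ftmicro_integrity_error")
  }
  sel <- site_class(manifest$site[idx]) == site_cls & !is.na(conc$copies_per_ul)
  v <- conc$copies_per_ul[sel]
  list(mean = if (length(v)) mean(v) else NA_real_,
       sd = if (length(v) >= 2) stats::sd(v) else NA_real_,
       n = length(v))
}

#' Paired t-test of concentrations between a site class and the FTO reference
#'
#' Patients contributing both a reference and a comparison value are paired;
#' multiple samples per (patient, site class) are averaged before pairing.
#' The test is a two-sided paired t-test on the transformed scale
#' (default log10 with a 0.1 pseudocount, since concentrations span orders
#' of magnitude). Degenerate cases are reported explicitly rather than
#' silently: fewer than two pairs yields an undefined test with `n_pairs`
#' reported; zero-variance differences yield `t = 0, p = 1` when all
#' differences are zero and an infinite t (`p = 0`) otherwise, flagged with
#' `zero_variance = TRUE`.
#'
#' @param conc data.frame with `sample_id`, `copies_per_ul`.
#' @param manifest Sample manifest.
#' @param other_site_cls Site class compared against the reference.
#' @param transform `"log10"` (default), `"identity"`, or a function.
#' @param reference Reference site class (default `"FTO"`).
#' @param alpha Significance level for the `significant` flag.
#' @param star_alpha Threshold for the `star` reporting flag (figure-style
#'   marking of p < 0.001).
#' @return List: `site_class`, `n_pairs`, `mean_ref`, `mean_other` (on the
#'   analysis scale), `t_statistic`, `df`, `p_value`, `significant`, `star`,
#'   `zero_variance`, `defined`.
#' @export
paired_site_test <- function(conc, manifest, other_site_cls,
                             transform = "log10", reference = "FTO",
                             alpha = 0.05, star_alpha = 0.001) {
  f <- conc_transform(transform)
  ps <- patient_site_concentration(conc, manifest)
  ref <- ps[ps$site_class == reference, ]
  oth <- ps[ps$site_class == other_site_cls, ]
  common <- intersect(ref$patient_id, oth$patient_id)
  out <- list(site_class = other_site_cls, reference = reference,
              n_pairs = length(common), mean_ref = NA_real_,
              mean_other = NA_real_, t_statistic = NA_real_, df = NA_real_,
              p_value = NA_real_, significant = NA, star = NA,
              zero_variance = FALSE, defined = FALSE)
  if (length(common) < 2) return(out)
  x <- f(ref$value[match(common, ref$patient_id)])
  y <- f(oth$value[match(common, oth$patient_id)])
  d <- y - x
  n <- length(d)
  out$mean_ref <- mean(x)
  out$mean_other <- mean(y)
  out$df <- n - 1
  if (stats::sd(d) == 0) {
    out$zero_variance <- TRUE
    out$defined <- TRUE
    if (mean(d) == 0) {
      out$t_statistic <- 0
      out$p_value <- 1
    } else {
      out$t_statistic <- sign(mean(d)) * Inf
      out$p_value <- 0
    }
  } else {
    t <- mean(d) / (stats::sd(d) / sqrt(n))
    out$t_statistic <- t
    out$p_value <- 2 * stats::pt(-abs(t), df = n - 1)
    out$defined <- TRUE
  }
  out$significant <- out$defined && out$p_value < alpha
  out$star <- out$defined && out$p_value < star_alpha
  out
}

#' Bacterial-load comparison of every sampled site class against FTO
#'
#' Runs [paired_site_test()] for each non-reference site class present in
#' the study that carries concentrations, plus per-class raw-scale summaries.
#'
#' @param study A `ftmicro_study` with a concentrations table.
#' @param transform Passed to [paired_site_test()].
#' @param alpha Significance level.
#' @return data.frame, one row per comparison site class.
#' @export
concentration_comparisons <- function(study, transform = "log10",
                                      alpha = 0.05) {
  if (is.null(study$concentrations)) {
    ft_abort("study has no concentrations table", "ftmicro_format_error")
  }
  classes <- setdiff(unique(site_class(study$manifest$site)),
                     c("FTO", lab_control_sites))
  # buffer controls carry concentrations but no patient, so they cannot be
  # paired; they are still summarised
  rows <- lapply(classes, function(cl) {
    tst <- paired_site_test(study$concentrations, study$manifest, cl,
                            transform = transform, alpha = alpha)
    smry <- summarize_concentration(study$concentrations, study$manifest, cl)
    data.frame(site_class = cl, n = smry$n, raw_mean = smry$mean,
               raw_sd = smry$sd, n_pairs = tst$n_pairs,
               mean_ref = tst$mean_ref, mean_other = tst$mean_other,
               t_statistic = tst$t_statistic, df = tst$df,
               p_value = tst$p_value,
               significant = tst$significant, star = tst$star,
               stringsAsFactors = FALSE)
  })
  ref <- summarize_concentration(study$concentrations, study$manifest, "FTO")
  out <- do.call(rbind, rows)
  attr(out, "reference_summary") <- ref
  out
}
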