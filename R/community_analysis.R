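# Alpha diversity and ordination of the filtered community.

#' Shannon diversity of a count vector
#'
#' `H = -sum(p_i * log(p_i))` in natural-log units (nats), with
#' `p_i = count_i / total` and zero-count taxa contributing nothing.
#'
#' @param x Non-negative numeric vector of read counts.
#' @return H in nats; `NA` (undefined) for an all-zero vector.
#' @export
#' @examples
#' shannon(c(50, 50))   # log(2)
#' shannon(c(100))      # 0
shannon <- function(x) {
  if (any(x < 0, na.rm = TRUE)) {
    ft_abort("counts must be non-negative", "ftmicro_value_error")
  }
  tot <- sum(x)
  if (is.na(tot) || tot <= 0) return(NA_real_)
  p <- x[x > 0] / tot
  -sum(p * log(p))
}

# paired t on a difference vector, with explicit degenerate handling
paired_t_stat <- function(d) {
  n <- length(d)
  if (n < 2) {
    return(list(t = NA_real_, df = NA_real_, p = NA_real_, n = n,
                zero_variance = FALSE, defined = FALSE))
  }
  s <- stats::sd(d)
  if (s == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, df = n - 1, p = 1, n = n, zero_variance = TRUE,
                  defined = TRUE))
    }
    return(list(t = sign(mean(d)) * Inf, df = n - 1, p = 0, n = n,
                zero_variance = TRUE, defined = TRUE))
  }
  t <- mean(d) / (s / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1), n = n,
       zero_variance = FALSE, defined = TRUE)
}

# Welch two-sample t with explicit degenerate handling
welch_t_stat <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) {
    return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                zero_variance = FALSE, defined = FALSE))
  }
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    eq <- mean(x) == mean(y)
    return(list(t = if (eq) 0 else sign(mean(x) - mean(y)) * Inf,
                df = nx + ny - 2, p = if (eq) 1 else 0,
                zero_variance = TRUE, defined = TRUE))
  }
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
       zero_variance = FALSE, defined = TRUE)
}

#' Per-sample Shannon diversity with between-group comparisons
#'
#' Computes H for every merged cervix / FTO / paracolic-gutter sample over
#' the diversity-set taxa (the post-step-5 survivors of [run_filter()]),
#' then compares (a) site classes pairwise with a patient-paired t-test and
#' (b) cancer versus non-cancer within each site class with an unpaired
#' Welch t-test (cross-patient strata cannot be paired). Strata with fewer
#' than two observations are skipped with a notice.
#'
#' @param study A `ftmicro_study`.
#' @param diversity_set Character vector of taxon ids (e.g.
#'   `run_filter(...)$diversity_set`).
#' @param config A `ftmicro_filter_config`; its `read_threshold` reproduces
#'   the thresholded, merged matrix the diversity set was derived from.
#' @return List of class `ftmicro_diversity`: `shannon` (per-sample table)
#'   and `comparisons` (test table with `comparison`, `site_class`,
#'   `group_a`, `group_b`, `n_a`, `n_b`, `statistic`, `df`, `p_value`,
#'   `note`).
#' @export
diversity_comparisons <- function(study, diversity_set,
                                  config = filter_config()) {
  validate_study(study)
  merged <- merge_by_patient_site(
    threshold_counts(study$counts, config$read_threshold), study$manifest)
  man <- merged$manifest
  sel <- man$site_class %in% c("CERVIX", "FTO", "PARACOLIC_GUTTER")
  taxa <- intersect(rownames(merged$counts), diversity_set)
  cnt <- merged$counts[taxa, sel, drop = FALSE]
  man <- man[sel, , drop = FALSE]
  H <- apply(cnt, 2, shannon)
  status <- stats::setNames(study$patients$cancer_status,
                            study$patients$patient_id)
  tab <- data.frame(sample_id = man$sample_id, patient_id = man$patient_id,
                    site_class = man$site_class,
                    cancer_status = unname(status[man$patient_id]),
                    shannon = unname(H), stringsAsFactors = FALSE)
  tab <- tab[!is.na(tab$shannon), , drop = FALSE]

  comps <- list()
  push <- function(...) comps[[length(comps) + 1]] <<- data.frame(
    ..., stringsAsFactors = FALSE)
  sites <- intersect(c("CERVIX", "FTO", "PARACOLIC_GUTTER"),
                     unique(tab$site_class))
  if (length(sites) >= 2) {
    for (i in seq_len(length(sites) - 1)) for (j in (i + 1):length(sites)) {
      a <- tab[tab$site_class == sites[i], ]
      b <- tab[tab$site_class == sites[j], ]
      common <- intersect(a$patient_id, b$patient_id)
      if (length(common) < 2) {
        push(comparison = "between_sites", site_class = NA_character_,
             group_a = sites[i], group_b = sites[j],
             n_a = length(common), n_b = length(common),
             statistic = NA_real_, df = NA_real_, p_value = NA_real_,
             note = "fewer than 2 complete pairs; skipped")
        next
      }
      d <- a$shannon[match(common, a$patient_id)] -
        b$shannon[match(common, b$patient_id)]
      r <- paired_t_stat(d)
      push(comparison = "between_sites", site_class = NA_character_,
           group_a = sites[i], group_b = sites[j],
           n_a = r$n, n_b = r$n, statistic = r$t, df = r$df, p_value = r$p,
           note = if (r$zero_variance) "zero-variance differences" else "")
    }
  }
  for (cl in sites) {
    x <- tab$shannon[tab$site_class == cl & tab$cancer_status == "CANCER"]
    y <- tab$shannon[tab$site_class == cl & tab$cancer_status == "NON_CANCER"]
    if (length(x) < 2 || length(y) < 2) {
      push(comparison = "cancer_vs_noncancer", site_class = cl,
           group_a = "CANCER", group_b = "NON_CANCER",
           n_a = length(x), n_b = length(y), statistic = NA_real_,
           df = NA_real_, p_value = NA_real_,
           note = "stratum with fewer than 2 samples; skipped")
      next
    }
    r <- welch_t_stat(x, y)
    push(comparison = "cancer_vs_noncancer", site_class = cl,
         group_a = "CANCER", group_b = "NON_CANCER",
         n_a = length(x), n_b = length(y), statistic = r$t, df = r$df,
         p_value = r$p,
         note = if (r$zero_variance) "zero-variance strata" else "")
  }
  structure(list(shannon = tab,
                 comparisons = if (length(comps)) do.call(rbind, comps)
                 else NULL),
            class = "ftmicro_diversity")
}

#' Principal component ordination of community profiles
#'
#' Merges raw counts by (patient, site class), restricts to `taxon_subset`
#' and to samples carrying at least one read of those taxa (and to the
#' biological comparison sites), transforms to relative abundances
#' (default Hellinger: square root of proportions) and runs PCA on the
#' covariance of the transformed matrix. Deterministic up to component sign;
#' signs are fixed by making the largest-magnitude loading of each component
#' positive.
#'
#' @param study A `ftmicro_study`.
#' @param taxon_subset Character vector of taxon ids (e.g. filter survivors).
#' @param k Number of components to report; truncated to the matrix rank
#'   with a notice when too large.
#' @param transform `"hellinger"` (default), `"prop"` or `"log1p"`.
#' @param sites Site classes admitted to the ordination.
#' @param min_reads Minimum total reads of the subset for a sample to enter
#'   (default 1).
#' @return List of class `ftmicro_ordination`: `scores` (sample table with
#'   PC columns), `loadings`, `explained_variance` (all components; sums to
#'   1), `k`, `transform`, `n_samples`, `note`.
#' @export
ordinate <- function(study, taxon_subset, k = 2,
                     transform = c("hellinger", "prop", "log1p"),
                     sites = c("CERVIX", "FTO", "PARACOLIC_GUTTER"),
                     min_reads = 1) {
  transform <- match.arg(transform)
  if (k < 1) ft_abort("k must be >= 1", "ftmicro_value_error")
  merged <- merge_by_patient_site(study$counts, study$manifest)
  man <- merged$manifest
  taxa <- intersect(rownames(merged$counts), taxon_subset)
  if (!length(taxa)) {
    ft_abort("taxon_subset shares no taxa with the study",
             "ftmicro_value_error")
  }
  sel <- man$site_class %in% sites
  cnt <- merged$counts[taxa, sel, drop = FALSE]
  man <- man[sel, , drop = FALSE]
  keep <- colSums(cnt) >= min_reads
  cnt <- cnt[, keep, drop = FALSE]
  man <- man[keep, , drop = FALSE]
  if (ncol(cnt) < 2) {
    ft_abort("fewer than two samples carry the taxon subset",
             "ftmicro_value_error")
  }
  X <- t(cnt)
  X <- switch(transform,
              prop = X / rowSums(X),
              hellinger = sqrt(X / rowSums(X)),
              log1p = log1p(X))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  total <- sum(pc$sdev^2)
  note <- ""
  if (total <= 0) {
    # identical samples: no variance to decompose; report zero scores
    ev <- rep(0, length(pc$sdev))
    rank <- 1L
    note <- "degenerate ordination: zero between-sample variance"
  } else {
    ev <- pc$sdev^2 / total
    rank <- sum(pc$sdev^2 > max(pc$sdev^2) * 1e-12)
  }
  if (k > rank) {
    if (!nzchar(note)) {
      note <- sprintf("k truncated from %d to matrix rank %d", k, rank)
    }
    k <- rank
  }
  # sign convention: largest-magnitude loading of each component positive
  for (j in seq_len(ncol(pc$rotation))) {
    lead <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[lead, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  scores <- data.frame(sample_id = man$sample_id,
                       patient_id = man$patient_id,
                       site_class = man$site_class,
                       stringsAsFactors = FALSE)
  for (j in seq_len(k)) scores[[paste0("PC", j)]] <- unname(pc$x[, j])
  structure(list(scores = scores,
                 loadings = pc$rotation[, seq_len(k), drop = FALSE],
                 explained_variance = ev, k = k, transform = transform,
                 n_samples = ncol(cnt), note = note),
            class = "ftmicro_ordination")
}

#' Heatmap-ready long table of candidate FT taxa by patient
#'
#' One row per (patient with a merged FTO sample, surviving taxon), carrying
#' presence (merged FTO count at or above the read threshold), the merged
#' read count, and patient metadata (processing batch, cancer status,
#' menopausal status, age binned by decade). Patients whose FTO sample
#' carries no surviving taxon keep their zero-presence rows, so the table is
#' complete. Optionally orders patients and taxa by hierarchical clustering
#' (correlation distance, average linkage) of the presence matrix.
#'
#' @param study A `ftmicro_study`.
#' @param survivors Character vector of surviving taxon ids.
#' @param config A `ftmicro_filter_config` (read threshold and merging).
#' @param cluster If `TRUE`, attach `patient_order` / `taxon_order`
#'   attributes from hierarchical clustering.
#' @return Long-format data.frame: `patient_id`, `taxon_id`,
#'   `species_label`, `present`, `reads`, `batch`, `cancer_status`,
#'   `menopausal`, `age_group`.
#' @export
export_overview <- function(study, survivors, config = filter_config(),
                            cluster = FALSE) {
  merged <- merge_by_patient_site(
    threshold_counts(study$counts, config$read_threshold), study$manifest)
  man <- merged$manifest
  fto <- man$site_class == "FTO"
  taxa <- intersect(rownames(merged$counts), survivors)
  cnt <- merged$counts[taxa, fto, drop = FALSE]
  pats <- man$patient_id[fto]
  p <- study$patients
  meta_idx <- match(pats, p$patient_id)
  age_group <- ifelse(is.na(p$age_years[meta_idx]), NA_character_,
                      sprintf("%d-%d",
                              (p$age_years[meta_idx] %/% 10) * 10,
                              (p$age_years[meta_idx] %/% 10) * 10 + 9))
  labels <- if (!is.null(study$taxa)) {
    stats::setNames(study$taxa$species_label, study$taxa$taxon_id)[taxa]
  } else stats::setNames(taxa, taxa)
  long <- data.frame(
    patient_id = rep(pats, each = length(taxa)),
    taxon_id = rep(taxa, times = length(pats)),
    species_label = rep(unname(labels), times = length(pats)),
    present = as.integer(as.vector(cnt >= config$read_threshold)),
    reads = as.vector(cnt),
    batch = rep(man$batch[fto], each = length(taxa)),
    cancer_status = rep(p$cancer_status[meta_idx], each = length(taxa)),
    menopausal = rep(p$menopausal[meta_idx], each = length(taxa)),
    age_group = rep(age_group, each = length(taxa)),
    stringsAsFactors = FALSE
  )
  if (cluster && length(taxa) >= 3 && length(pats) >= 3) {
    pres <- matrix(long$present, nrow = length(taxa),
                   dimnames = list(taxa, pats))
    cor_dist <- function(m) {
      cc <- suppressWarnings(stats::cor(t(m)))
      cc[is.na(cc)] <- 0
      stats::as.dist(1 - cc)
    }
    attr(long, "taxon_order") <-
      rownames(pres)[stats::hclust(cor_dist(pres), "average")$order]
    attr(long, "patient_order") <-
      colnames(pres)[stats::hclust(cor_dist(t(pres)), "average")$order]
  }
  long
}
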