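# Synthetic cohorts with planted ground truth.
#
# The generator emulates the architecture of an intraoperative low-biomass
# 16S survey: two patient groups (ovarian cancer / non-cancer), per-patient
# swabs from the fallopian tube & ovarian surface (FTO, typically left +
# right), cervix, paracolic gutter, laparoscopic port and operating-room air,
# plus patient-free laboratory controls (sham-extraction buffer controls and
# no-template PCR controls). Ground truth labels every taxon as true FT
# community member, vaginal-only, reagent contaminant or air contaminant, so
# filter recovery can be scored.

#' Build a simulation configuration
#'
#' @param n_cancer,n_noncancer Patients per group.
#' @param n_taxa_true_ft,n_taxa_vaginal,n_taxa_reagent_contam,n_taxa_air_contam
#'   Taxa per planted class.
#' @param cervix_biomass_factor Ratio of expected total cervical reads (and
#'   qPCR geometric-mean concentration) to the FTO level; the cervical
#'   per-cell negative-binomial mean is calibrated so the expected
#'   total-read ratio equals this factor.
#' @param ft_mean_depth Negative-binomial mean read count of an occupied
#'   (taxon, sample) cell at a low-biomass site. Defaults to
#'   `read_threshold_margin` times the canonical 100-read threshold so most
#'   occupied cells survive per-sample thresholding.
#' @param read_threshold_margin Multiple of the 100-read rule used to derive
#'   `ft_mean_depth` when the latter is not given.
#' @param cancer_effect Named numeric vector mapping niche codes
#'   (`G`,`O`,`V`,`S`,`B`) to additive FT-occupancy increments applied to
#'   true-FT taxa of that niche in cancer patients (clipped to `[0, 1]`).
#' @param site_samples Named integer vector of total swab counts per site
#'   class: `FTO`, `OR_AIR`, `CERVIX`, `LAPAROSCOPIC_PORT`,
#'   `PARACOLIC_GUTTER`, `BUFFER_CONTROL`, `NO_TEMPLATE_CONTROL`.
#' @param contam_leak Probability that a contaminant taxon also appears in
#'   any given biological sample.
#' @param dispersion Negative-binomial size parameter (fixed overdispersion).
#' @param seed Integer seed; a single RNG stream is seeded once and consumed
#'   in documented order (patients, swab allocation, occupancy, counts,
#'   concentrations).
#' @return A `ftmicro_sim_config` list.
#' @export
sim_config <- function(n_cancer = 20, n_noncancer = 26,
                       n_taxa_true_ft = 30, n_taxa_vaginal = 10,
                       n_taxa_reagent_contam = 12, n_taxa_air_contam = 8,
                       cervix_biomass_factor = 1000,
                       ft_mean_depth = NULL, read_threshold_margin = 5,
                       cancer_effect = c(G = 0.3, O = 0.3, V = 0, S = 0,
                                         B = 0),
                       site_samples = c(FTO = 91, OR_AIR = 32, CERVIX = 37,
                                        LAPAROSCOPIC_PORT = 20,
                                        PARACOLIC_GUTTER = 30,
                                        BUFFER_CONTROL = 9,
                                        NO_TEMPLATE_CONTROL = 27),
                       contam_leak = 0.02, dispersion = 2, seed = 1) {
  if (length(seed) != 1 || is.na(seed) || seed != as.integer(seed)) {
    ft_abort("seed must be a single integer", "ftmicro_value_error")
  }
  if (is.null(ft_mean_depth)) ft_mean_depth <- 100 * read_threshold_margin
  counts <- c(n_cancer, n_noncancer, n_taxa_true_ft, n_taxa_vaginal,
              n_taxa_reagent_contam, n_taxa_air_contam, site_samples)
  if (any(counts < 0)) {
    ft_abort("all counts must be non-negative", "ftmicro_value_error")
  }
  if (cervix_biomass_factor <= 1) {
    ft_abort("cervix_biomass_factor must exceed 1", "ftmicro_value_error")
  }
  eff <- c(G = 0, O = 0, V = 0, S = 0, B = 0)
  eff[names(cancer_effect)] <- cancer_effect
  if (any(eff < -1 | eff > 1)) {
    ft_abort("cancer_effect increments must lie in [-1, 1]",
             "ftmicro_value_error")
  }
  structure(list(
    n_cancer = as.integer(n_cancer), n_noncancer = as.integer(n_noncancer),
    n_taxa_true_ft = as.integer(n_taxa_true_ft),
    n_taxa_vaginal = as.integer(n_taxa_vaginal),
    n_taxa_reagent_contam = as.integer(n_taxa_reagent_contam),
    n_taxa_air_contam = as.integer(n_taxa_air_contam),
    cervix_biomass_factor = cervix_biomass_factor,
    ft_mean_depth = ft_mean_depth,
    read_threshold_margin = read_threshold_margin,
    cancer_effect = eff,
    site_samples = site_samples,
    contam_leak = contam_leak,
    dispersion = dispersion,
    # baseline occupancy probabilities by planted class and site class
    occupancy = list(
      true_ft = c(FTO = 0.35, CERVIX = 0.25, PARACOLIC_GUTTER = 0.25),
      vaginal_cervix = c(0.95, 0.5, 0.5, 0.3),   # 1st, 2nd, 3rd, rest
      vaginal_mult = c(40, 5, 2, 1),             # cervical abundance weights
      contam_control = 0.6
    ),
    seed = as.integer(seed)
  ), class = "ftmicro_sim_config")
}

#' Desk-scale preset (fast end-to-end runs)
#'
#' Roughly one quarter of the full cohort: 20 cancer + 26 non-cancer
#' patients, 60 taxa, swab counts scaled proportionally from the full-scale
#' architecture. A complete pipeline run finishes in seconds.
#'
#' @param seed Integer seed.
#' @return A `ftmicro_sim_config`.
#' @export
desk_preset <- function(seed = 1) sim_config(seed = seed)

#' Full-scale preset
#'
#' Reproduces the published sample architecture: 81 cancer and 106 non-cancer
#' patients; 369 FTO, 130 operating-room air, 152 cervical, 81 laparoscopic
#' port and 122 paracolic gutter swabs; 36 buffer controls and 111
#' no-template PCR controls (1001 sequenced units in total).
#'
#' @param seed Integer seed.
#' @return A `ftmicro_sim_config`.
#' @export
full_preset <- function(seed = 1) {
  sim_config(
    n_cancer = 81, n_noncancer = 106,
    n_taxa_true_ft = 60, n_taxa_vaginal = 20,
    n_taxa_reagent_contam = 24, n_taxa_air_contam = 16,
    site_samples = c(FTO = 369, OR_AIR = 130, CERVIX = 152,
                     LAPAROSCOPIC_PORT = 81, PARACOLIC_GUTTER = 122,
                     BUFFER_CONTROL = 36, NO_TEMPLATE_CONTROL = 111),
    seed = seed
  )
}

# deterministic niche allocation for true-FT taxa: a mix dominated by
# gastrointestinal, oral and vaginal species with a few skin / broad taxa
true_ft_niches <- function(n) {
  pool <- c("G", "O", "V", "S", "B")
  frac <- c(G = 0.3, O = 0.2, V = 0.3, S = 0.1, B = 0.1)
  k <- floor(frac * n)
  rem <- n - sum(k)
  if (rem > 0) k[seq_len(rem)] <- k[seq_len(rem)] + 1
  rep(pool, times = k[pool])
}

#' Simulate a study with planted ground truth
#'
#' Generative model: each taxon has a per-(patient-stratum, site-class)
#' occupancy probability determined by its planted class; occupied
#' (taxon, sample) cells draw reads from a negative binomial with a
#' site-class mean (`ft_mean_depth` at low-biomass sites;
#' `ft_mean_depth * cervix_biomass_factor`, richness-calibrated, at the
#' cervix) and fixed dispersion. True-FT taxa occupy FT, cervix and (at the
#' same reduced rate) the paracolic gutter, never laboratory controls or
#' air swabs. Reagent contaminants occupy buffer and no-template controls,
#' air contaminants occupy air swabs; both leak into biological samples with
#' probability `contam_leak`. Cancer-enriched taxa (true-FT taxa whose niche
#' has a positive `cancer_effect` increment) get raised FT occupancy in
#' cancer patients. qPCR concentrations are lognormal with site-class
#' geometric means ordered cervix >> {FTO, paracolic} > {port} > {air,
#' buffer}; no-template controls carry no concentration.
#'
#' @param config A `ftmicro_sim_config` (see [sim_config()]).
#' @return A list with elements `study` (a `ftmicro_study`) and `truth`
#'   (data.frame: `taxon_id`, `label` in
#'   TRUE_FT/VAGINAL_ONLY/REAGENT_CONTAM/AIR_CONTAM, `cancer_enriched`).
#' @export
simulate_study <- function(config) {
  if (!inherits(config, "ftmicro_sim_config")) {
    ft_abort("config must be created with sim_config()",
             "ftmicro_value_error")
  }
  set.seed(config$seed)
  n_pat <- config$n_cancer + config$n_noncancer

  ## -- patients (RNG block 1) -----------------------------------------------
  pid <- sprintf("P%03d", seq_len(n_pat))
  status <- rep(c("CANCER", "NON_CANCER"), c(config$n_cancer,
                                             config$n_noncancer))
  age <- ifelse(status == "CANCER",
                stats::rnorm(n_pat, 59.6, 10), stats::rnorm(n_pat, 51.6, 12))
  age <- round(pmin(pmax(age, 18), 95), 1)
  meno <- ifelse(stats::runif(n_pat) <
                   ifelse(status == "CANCER", 0.765, 0.453), "POST", "PRE")
  histology <- ifelse(status == "CANCER",
                      ifelse(stats::runif(n_pat) < 53 / 81, "SEROUS",
                             "NON_SEROUS"),
                      "NONE")
  stage <- ifelse(status == "CANCER",
                  sample(1:4, n_pat, TRUE, prob = c(19, 6, 39, 16)), NA)
  grade <- ifelse(status == "CANCER",
                  sample(1:4, n_pat, TRUE, prob = c(6, 3, 64, 1)), NA)
  surgery <- character(n_pat)
  surgery[status == "CANCER"] <-
    sample(surgery_levels, config$n_cancer, TRUE, prob = c(75, 3, 3))
  surgery[status == "NON_CANCER"] <-
    sample(surgery_levels, config$n_noncancer, TRUE, prob = c(28, 42, 36))
  washing <- character(n_pat)
  washing[status == "CANCER"] <-
    sample(washing_levels, config$n_cancer, TRUE, prob = c(43, 22, 16))
  washing[status == "NON_CANCER"] <-
    sample(washing_levels, config$n_noncancer, TRUE, prob = c(3, 99, 4))
  patients <- data.frame(
    patient_id = pid, cancer_status = status, histology = histology,
    stage = as.numeric(stage), grade = as.numeric(grade), menopausal = meno,
    age_years = age, surgery = surgery, pelvic_washing = washing,
    stringsAsFactors = FALSE
  )
  batch_of <- sample(paste0("B", 1:5), n_pat, TRUE)
  names(batch_of) <- pid

  ## -- swab allocation (RNG block 2) ----------------------------------------
  ss <- config$site_samples
  rows <- list()
  add <- function(sample_id, patient_id, site, batch, plate) {
    rows[[length(rows) + 1]] <<- data.frame(
      sample_id = sample_id, patient_id = patient_id, site = site,
      batch = batch, plate = plate, stringsAsFactors = FALSE)
  }
  low_plate <- function(n) sample(paste0("PL", 2:4), n, TRUE)

  n_ft <- ss[["FTO"]]
  left_pat <- if (n_ft >= n_pat) pid else sample(pid, n_ft)
  add(paste0(left_pat, "_FTL"), left_pat, "FT_OVARY_LEFT",
      batch_of[left_pat], low_plate(length(left_pat)))
  n_right <- max(0, min(n_ft - length(left_pat), n_pat))
  if (n_right > 0) {
    right_pat <- sample(pid, n_right)
    add(paste0(right_pat, "_FTR"), right_pat, "FT_OVARY_RIGHT",
        batch_of[right_pat], low_plate(n_right))
  }
  alloc_site <- function(site, n, eligible = pid, plate_hi = FALSE) {
    if (n == 0) return(invisible(NULL))
    if (length(eligible) < n) eligible <- pid
    pats <- if (n <= length(eligible)) sample(eligible, n) else
      c(eligible, sample(eligible, n - length(eligible)))
    sfx <- stats::ave(seq_along(pats), pats, FUN = seq_along)
    plate <- if (plate_hi) rep("PL1", n) else low_plate(n)
    add(sprintf("%s_%s%d", pats, abbreviate_site(site), sfx), pats, site,
        batch_of[pats], plate)
  }
  alloc_site("CERVIX", ss[["CERVIX"]], plate_hi = TRUE)
  alloc_site("OR_AIR", ss[["OR_AIR"]])
  alloc_site("PARACOLIC_GUTTER", ss[["PARACOLIC_GUTTER"]])
  minimally_invasive <- pid[surgery %in% c("LAPAROSCOPY", "ROBOTIC")]
  alloc_site("LAPAROSCOPIC_PORT", ss[["LAPAROSCOPIC_PORT"]],
             eligible = minimally_invasive)
  n_buf <- ss[["BUFFER_CONTROL"]]
  if (n_buf > 0) {
    add(sprintf("BUF_%03d", seq_len(n_buf)), NA_character_, "BUFFER_CONTROL",
        paste0("B", rep_len(1:5, n_buf)), low_plate(n_buf))
  }
  n_ntc <- ss[["NO_TEMPLATE_CONTROL"]]
  if (n_ntc > 0) {
    add(sprintf("NTC_%03d", seq_len(n_ntc)), NA_character_,
        "NO_TEMPLATE_CONTROL", paste0("B", rep_len(1:5, n_ntc)),
        paste0("PL", rep_len(1:4, n_ntc)))
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL

  ## -- taxa and truth ---------------------------------------------------------
  n_true <- config$n_taxa_true_ft
  n_vag <- config$n_taxa_vaginal
  n_rg <- config$n_taxa_reagent_contam
  n_air <- config$n_taxa_air_contam
  n_tax <- n_true + n_vag + n_rg + n_air
  taxon_id <- sprintf("T%03d", seq_len(n_tax))
  label <- rep(c("TRUE_FT", "VAGINAL_ONLY", "REAGENT_CONTAM", "AIR_CONTAM"),
               c(n_true, n_vag, n_rg, n_air))
  niche <- c(true_ft_niches(n_true), rep("V", n_vag),
             rep_len(c("S", "B"), n_rg), rep_len(c("B", "S"), n_air))
  taxa <- data.frame(
    taxon_id = taxon_id,
    species_label = sprintf("Species %03d (%s)", seq_len(n_tax),
                            tolower(label)),
    niche = niche, stringsAsFactors = FALSE
  )
  enriched <- label == "TRUE_FT" & config$cancer_effect[niche] > 0
  truth <- data.frame(taxon_id = taxon_id, label = label,
                      cancer_enriched = unname(enriched),
                      stringsAsFactors = FALSE)

  ## -- occupancy and mean matrices -------------------------------------------
  n_smp <- nrow(manifest)
  scls <- site_class(manifest$site)
  cancer_of <- stats::setNames(patients$cancer_status, patients$patient_id)
  smp_cancer <- !is.na(manifest$patient_id) &
    cancer_of[manifest$patient_id] == "CANCER"

  occ <- config$occupancy
  vag_p <- c(occ$vaginal_cervix[1:3],
             rep(occ$vaginal_cervix[4], max(0, n_vag - 3)))[seq_len(n_vag)]
  vag_m <- c(occ$vaginal_mult[1:3],
             rep(occ$vaginal_mult[4], max(0, n_vag - 3)))[seq_len(n_vag)]

  prob <- matrix(0, n_tax, n_smp, dimnames = list(taxon_id,
                                                  manifest$sample_id))
  mult <- matrix(1, n_tax, n_smp)
  is_true <- label == "TRUE_FT"
  is_vag <- label == "VAGINAL_ONLY"
  is_rg <- label == "REAGENT_CONTAM"
  is_air <- label == "AIR_CONTAM"
  biological <- !scls %in% lab_control_sites

  prob[is_true, scls == "FTO"] <- occ$true_ft[["FTO"]]
  prob[is_true, scls == "CERVIX"] <- occ$true_ft[["CERVIX"]]
  prob[is_true, scls == "PARACOLIC_GUTTER"] <-
    occ$true_ft[["PARACOLIC_GUTTER"]]
  if (any(enriched) && any(smp_cancer & scls == "FTO")) {
    bump <- pmin(pmax(occ$true_ft[["FTO"]] +
                        config$cancer_effect[niche[enriched]], 0), 1)
    prob[enriched, smp_cancer & scls == "FTO"] <- bump
  }
  if (n_vag > 0) {
    prob[is_vag, scls == "CERVIX"] <- vag_p
    mult[is_vag, scls == "CERVIX"] <- vag_m
  }
  prob[is_rg, scls %in% lab_control_sites] <- occ$contam_control
  prob[is_rg, biological] <- config$contam_leak
  prob[is_air, scls == "OR_AIR"] <- occ$contam_control
  prob[is_air, biological & scls != "OR_AIR"] <- config$contam_leak

  # calibrate the cervical per-cell mean so the expected total-read ratio of
  # a cervical to an FTO swab equals cervix_biomass_factor; the expected FT
  # occupancy includes the planted cancer effect weighted by group size
  frac_cancer <- config$n_cancer / max(n_pat, 1)
  e_ft <- n_true * occ$true_ft[["FTO"]] +
    frac_cancer * sum(pmin(pmax(config$cancer_effect[niche[enriched]], 0),
                           1 - occ$true_ft[["FTO"]]))
  e_cvx <- n_true * occ$true_ft[["CERVIX"]] + sum(vag_p * vag_m)
  cervix_cell_mean <- config$ft_mean_depth * config$cervix_biomass_factor *
    e_ft / max(e_cvx, 1e-9)

  mu <- matrix(config$ft_mean_depth, n_tax, n_smp)
  mu[, scls == "CERVIX"] <- cervix_cell_mean
  mu <- mu * mult

  ## -- counts (RNG block 3) ---------------------------------------------------
  ncell <- n_tax * n_smp
  occupied <- matrix(stats::rbinom(ncell, 1L, as.vector(prob)), n_tax, n_smp)
  reads <- matrix(stats::rnbinom(ncell, size = config$dispersion,
                                 mu = as.vector(mu)), n_tax, n_smp)
  counts <- occupied * reads
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(taxon_id, manifest$sample_id)

  ## -- qPCR concentrations (RNG block 4) --------------------------------------
  gm <- c(FTO = 1.2, PARACOLIC_GUTTER = 1.2,
          CERVIX = 1.2 * config$cervix_biomass_factor,
          LAPAROSCOPIC_PORT = 0.5, OR_AIR = 0.35, BUFFER_CONTROL = 0.35,
          NO_TEMPLATE_CONTROL = NA_real_)
  has_conc <- scls != "NO_TEMPLATE_CONTROL"
  conc <- data.frame(
    sample_id = manifest$sample_id[has_conc],
    copies_per_ul = round(stats::rlnorm(sum(has_conc),
                                        meanlog = log(gm[scls[has_conc]]),
                                        sdlog = 1.0), 4),
    stringsAsFactors = FALSE
  )

  study <- new_study(manifest, counts, patients, taxa, conc)
  list(study = study, truth = truth)
}

abbreviate_site <- function(site) {
  c(CERVIX = "CVX", OR_AIR = "AIR", PARACOLIC_GUTTER = "PG",
    LAPAROSCOPIC_PORT = "LP")[[site]]
}
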