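# Fixture builders and independent oracles, all constructed in code.

empty_patients <- function() {
  data.frame(patient_id = character(0), cancer_status = character(0),
             histology = character(0), stage = numeric(0),
             grade = numeric(0), menopausal = character(0),
             age_years = numeric(0), surgery = character(0),
             pelvic_washing = character(0), stringsAsFactors = FALSE)
}

make_patients <- function(ids, cancer = rep("NON_CANCER", length(ids)),
                          surgery = rep("LAPAROTOMY", length(ids)),
                          histology = NULL,
                          menopausal = rep("POST", length(ids)),
                          age = rep(55, length(ids)),
                          washing = rep("NEGATIVE", length(ids))) {
  if (is.null(histology)) {
    histology <- ifelse(cancer == "CANCER", "SEROUS", "NONE")
  }
  data.frame(patient_id = ids, cancer_status = cancer,
             histology = histology,
             stage = ifelse(cancer == "CANCER", 3, NA_real_),
             grade = ifelse(cancer == "CANCER", 3, NA_real_),
             menopausal = menopausal, age_years = age, surgery = surgery,
             pelvic_washing = washing, stringsAsFactors = FALSE)
}

# tiny 4-sample / 3-taxon study used by the reader round-trip tests
toy_study <- function() {
  manifest <- data.frame(
    sample_id = c("S1", "S2", "S3", "S4"),
    patient_id = c("P1", "P1", "P2", NA),
    site = c("FT_OVARY_LEFT", "CERVIX", "FT_OVARY_RIGHT",
             "NO_TEMPLATE_CONTROL"),
    batch = c("B1", "B1", "B1", "B1"),
    plate = c("PL1", "PL1", "PL1", "PL1"), stringsAsFactors = FALSE)
  counts <- matrix(c(150L, 0L, 20L,
                     200L, 110L, 0L,
                     0L, 0L, 99L,
                     0L, 130L, 0L),
                   nrow = 3, dimnames = list(c("TA", "TB", "TC"),
                                             c("S1", "S2", "S3", "S4")))
  patients <- make_patients(c("P1", "P2"), cancer = c("CANCER", "NON_CANCER"))
  taxa <- data.frame(taxon_id = c("TA", "TB", "TC"),
                     species_label = c("Alpha sp.", "Beta sp.", "Gamma sp."),
                     niche = c("G", "V", "O"), stringsAsFactors = FALSE)
  conc <- data.frame(sample_id = c("S1", "S2", "S3"),
                     copies_per_ul = c(2.5, 2500, 1.75),
                     stringsAsFactors = FALSE)
  new_study(manifest, counts, patients, taxa, conc)
}

# hand-derived six-taxon study exercising every removal tier:
#   A: cervix + FT high            -> survives
#   B: NTC + FT                    -> removed at step 4
#   C: FT only, 99 reads           -> zeroed at step 1, removed at step 3
#   D: air + FT                    -> removed at step 6
#   E: FT only (no cervix)         -> removed at step 7
#   F: cervix only (no FT)         -> removed at step 7
six_taxon_study <- function() {
  samples <- data.frame(
    sample_id = c("FT1", "CVX1", "NTC1", "AIR1", "BUF1"),
    patient_id = c("P1", "P1", NA, "P1", NA),
    site = c("FT_OVARY_LEFT", "CERVIX", "NO_TEMPLATE_CONTROL", "OR_AIR",
             "BUFFER_CONTROL"),
    batch = "B1", plate = "PL1", stringsAsFactors = FALSE)
  counts <- rbind(
    A = c(FT1 = 150L, CVX1 = 500L, NTC1 = 0L, AIR1 = 0L, BUF1 = 0L),
    B = c(130L, 0L, 120L, 0L, 0L),
    C = c(99L, 0L, 0L, 0L, 0L),
    D = c(140L, 180L, 0L, 160L, 0L),
    E = c(170L, 0L, 0L, 0L, 0L),
    F = c(0L, 210L, 0L, 0L, 0L))
  colnames(counts) <- samples$sample_id
  new_study(samples, counts, make_patients("P1"))
}

# random small study generator for property tests (valid by construction)
random_study <- function(n_taxa = sample(2:10, 1),
                         n_samples = sample(4:12, 1),
                         with_conc = TRUE) {
  sites <- sample(ft_sites, n_samples, replace = TRUE)
  pats <- paste0("P", sample(1:4, n_samples, replace = TRUE))
  pats[sites %in% c("BUFFER_CONTROL", "NO_TEMPLATE_CONTROL")] <- NA
  manifest <- data.frame(
    sample_id = sprintf("S%02d", seq_len(n_samples)),
    patient_id = pats, site = sites,
    batch = sample(c("B1", "B2"), n_samples, replace = TRUE),
    plate = sample(c("PL1", "PL2"), n_samples, replace = TRUE),
    stringsAsFactors = FALSE)
  counts <- matrix(
    as.integer(stats::rnbinom(n_taxa * n_samples, size = 0.6, mu = 120)),
    nrow = n_taxa,
    dimnames = list(sprintf("T%02d", seq_len(n_taxa)), manifest$sample_id))
  used <- unique(stats::na.omit(pats))
  patients <- make_patients(
    used,
    cancer = sample(c("CANCER", "NON_CANCER"), length(used), replace = TRUE),
    surgery = sample(c("LAPAROTOMY", "LAPAROSCOPY", "ROBOTIC"),
                     length(used), replace = TRUE),
    age = round(stats::runif(length(used), 30, 80), 1))
  taxa <- data.frame(
    taxon_id = rownames(counts),
    species_label = paste("Species", rownames(counts)),
    niche = sample(c("G", "O", "V", "S", "B"), n_taxa, replace = TRUE),
    stringsAsFactors = FALSE)
  conc <- NULL
  if (with_conc) {
    idx <- sort(sample(n_samples, max(2, n_samples %/% 2)))
    conc <- data.frame(sample_id = manifest$sample_id[idx],
                       copies_per_ul = round(stats::rlnorm(length(idx)), 4),
                       stringsAsFactors = FALSE)
  }
  new_study(manifest, counts, patients, taxa, conc)
}

# Independent brute-force re-implementation of the staged filter using
# long-format set logic; shares no code with run_filter().
brute_filter <- function(study, config = filter_config()) {
  long <- expand.grid(taxon = rownames(study$counts),
                      sample = colnames(study$counts),
                      stringsAsFactors = FALSE)
  long$reads <- mapply(function(t, s) study$counts[t, s],
                       long$taxon, long$sample)
  long$reads[long$reads < config$read_threshold] <- 0          # step 1
  man <- study$manifest
  long$patient <- man$patient_id[match(long$sample, man$sample_id)]
  long$site <- man$site[match(long$sample, man$sample_id)]
  long$batch <- man$batch[match(long$sample, man$sample_id)]
  long$class <- ifelse(long$site %in% c("FT_OVARY_LEFT", "FT_OVARY_RIGHT"),
                       "FTO", long$site)
  long$unit <- ifelse(is.na(long$patient),                     # step 2
                      paste(long$site, long$batch),
                      paste(long$patient, long$class))
  agg <- stats::aggregate(reads ~ taxon + unit + class, long, sum)

  present_in <- function(classes, thr) {
    unique(agg$taxon[agg$class %in% classes & agg$reads >= thr])
  }
  removal <- stats::setNames(rep(NA_integer_, nrow(study$counts)),
                             rownames(study$counts))
  alive <- rownames(study$counts)
  cut <- function(step, victims) {
    victims <- intersect(victims, alive)
    removal[victims] <<- step
    alive <<- setdiff(alive, victims)
  }
  nonzero <- unique(agg$taxon[agg$reads > 0])
  cut(3, setdiff(alive, nonzero))
  ct <- config$control_presence_threshold
  if ("NO_TEMPLATE_CONTROL" %in% config$exclude_sites_as_controls &&
      any(man$site == "NO_TEMPLATE_CONTROL")) {
    cut(4, present_in("NO_TEMPLATE_CONTROL", ct))
  }
  if ("BUFFER_CONTROL" %in% config$exclude_sites_as_controls &&
      any(man$site == "BUFFER_CONTROL")) {
    cut(5, present_in("BUFFER_CONTROL", ct))
  }
  air <- character(0)
  if ("OR_AIR" %in% config$exclude_sites_as_controls &&
      any(man$site == "OR_AIR")) {
    air <- present_in("OR_AIR", ct)
  }
  if (config$use_port_as_control && any(man$site == "LAPAROSCOPIC_PORT")) {
    air <- union(air, present_in("LAPAROSCOPIC_PORT", ct))
  }
  cut(6, air)
  if (config$require_cervix_copresence) {
    ok <- intersect(present_in("CERVIX", config$read_threshold),
                    present_in("FTO", config$read_threshold))
  } else {
    ok <- present_in("FTO", config$read_threshold)
  }
  cut(7, setdiff(alive, ok))
  list(survivors = sort(alive), removal_step = removal)
}
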