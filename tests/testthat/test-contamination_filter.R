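test_that("per-sample read threshold zeroes strictly sub-threshold cells", {
  m <- matrix(c(99L, 100L, 101L, 0L), 2, 2,
              dimnames = list(c("A", "B"), c("S1", "S2")))
  out <- threshold_counts(m, 100)
  expect_equal(out["A", "S1"], 0L)       # 99 reads are excluded
  expect_equal(out["B", "S1"], 100L)     # the boundary cell is kept
  expect_equal(out["A", "S2"], 101L)
  z <- matrix(0L, 2, 2, dimnames = dimnames(m))
  expect_identical(threshold_counts(z, 100), z)
})

test_that("merging pools same-patient same-site-class columns and conserves reads", {
  man <- data.frame(
    sample_id = c("L", "R", "C", "X"),
    patient_id = c("P1", "P1", "P1", "P2"),
    site = c("FT_OVARY_LEFT", "FT_OVARY_RIGHT", "CERVIX", "FT_OVARY_LEFT"),
    batch = "B1", plate = "PL1", stringsAsFactors = FALSE)
  m <- matrix(c(120L, 130L, 40L, 55L), 1, 4,
              dimnames = list("T1", man$sample_id))
  mg <- merge_by_patient_site(m, man)
  expect_equal(ncol(mg$counts), 3)
  expect_equal(unname(mg$counts["T1", mg$manifest$site_class == "FTO" &
                                  mg$manifest$patient_id == "P1"]),
               250L)                      # left 120 + right 130
  expect_equal(unname(mg$counts["T1", mg$manifest$patient_id == "P2"]), 55L)
  expect_equal(sum(mg$counts), sum(m))    # conservation

  # thresholding happens before merging: 150 and 60 -> 150 and 0 -> 150
  m2 <- matrix(c(150L, 60L), 1, 2, dimnames = list("T1", c("L", "R")))
  mg2 <- merge_by_patient_site(threshold_counts(m2, 100), man[1:2, ])
  expect_equal(unname(mg2$counts[1, 1]), 150L)

  # laboratory controls merge only within identical (site, batch)
  man3 <- data.frame(
    sample_id = c("N1", "N2", "N3"), patient_id = NA_character_,
    site = "NO_TEMPLATE_CONTROL", batch = c("B1", "B1", "B2"),
    plate = "PL1", stringsAsFactors = FALSE)
  m3 <- matrix(c(100L, 110L, 120L), 1, 3, dimnames = list("T1", man3$sample_id))
  mg3 <- merge_by_patient_site(m3, man3)
  expect_equal(ncol(mg3$counts), 2)
  expect_setequal(unname(mg3$counts[1, ]), c(210L, 120L))
})

test_that("taxa_present_in applies the presence threshold literally", {
  man <- data.frame(sample_id = c("N1", "F1"),
                    patient_id = c(NA, "P1"),
                    site = c("NO_TEMPLATE_CONTROL", "FT_OVARY_LEFT"),
                    batch = "B1", plate = "PL1", stringsAsFactors = FALSE)
  m <- rbind(A = c(100L, 0L), B = c(99L, 0L))
  colnames(m) <- man$sample_id
  mg <- merge_by_patient_site(m, man)
  expect_equal(taxa_present_in(mg, "NO_TEMPLATE_CONTROL", 100), "A")
  expect_equal(taxa_present_in(mg, character(0), 100), character(0))
  expect_error(taxa_present_in(mg, "LAB", 100), class = "ftmicro_value_error")
})

test_that("the six-taxon fixture removes each taxon at its hand-derived step", {
  fr <- run_filter(six_taxon_study())
  expect_equal(fr$survivors, "A")
  steps <- stats::setNames(fr$ledger$removal_step, fr$ledger$taxon_id)
  expect_equal(unname(steps[c("B", "C", "D", "E", "F")]), c(4, 3, 6, 7, 7))
  expect_true(is.na(steps["A"]))
  # C entered with 99 FT reads: zeroed by step 1, pruned at step 3
  expect_equal(fr$ledger$removal_step_name[fr$ledger$taxon_id == "C"],
               "prune_zero_taxa")
})

test_that("a study without controls degrades to co-presence filtering with notices", {
  s <- six_taxon_study()
  keep <- !s$manifest$site %in% c("NO_TEMPLATE_CONTROL", "BUFFER_CONTROL",
                                  "OR_AIR")
  s2 <- new_study(s$manifest[keep, ], s$counts[, s$manifest$sample_id[keep]],
                  s$patients)
  fr <- run_filter(s2)
  expect_setequal(fr$survivors, c("A", "D"))  # cervix & FT co-present
  expect_true(length(fr$warnings) >= 3)
  expect_equal(fr$ledger_summary$n_removed[4:6], c(0L, 0L, 0L))
})

test_that("ledger counts reconcile and filtering is monotone", {
  set.seed(99)
  for (i in 1:15) {
    s <- random_study()
    fr <- run_filter(s)
    ls <- fr$ledger_summary
    expect_equal(ls$n_out, ls$n_in - ls$n_removed)
    expect_equal(ls$n_in[-1], ls$n_out[-nrow(ls)])         # chain
    expect_equal(ls$n_in[1], nrow(s$counts))
    expect_equal(sum(ls$n_removed) + length(fr$survivors), nrow(s$counts))
    expect_true(all(fr$survivors %in% rownames(s$counts)))
    # each removed taxon has exactly one removal step
    removed <- fr$ledger[fr$ledger$status == "REMOVED", ]
    expect_false(anyNA(removed$removal_step))
    expect_true(all(is.na(fr$ledger$removal_step[
      fr$ledger$status == "SURVIVED"])))
    # every survivor carries cervix/FTO reads, so it sits in the
    # post-step-5 diversity set
    expect_true(all(fr$survivors %in% fr$diversity_set))
  }
})

test_that("raising the read threshold shrinks the co-presence survivor set", {
  # monotonicity holds for the biological criterion; the control tiers are
  # deliberately excluded here because thresholding also zeroes control
  # cells, which can rescue a weak contaminant at a higher threshold (see
  # the boundary test below)
  set.seed(7)
  no_controls <- function(t) filter_config(
    read_threshold = t, exclude_sites_as_controls = character(0))
  for (i in 1:8) {
    s <- random_study()
    lo <- run_filter(s, no_controls(60))
    hi <- run_filter(s, no_controls(140))
    expect_true(all(hi$survivors %in% lo$survivors))
  }
})

test_that("thresholding is applied to control samples too (boundary contract)", {
  # a contaminant with 99 reads in the only NTC escapes the control tier at
  # threshold 100 (its control cell is zeroed first) but not at threshold 60
  man <- data.frame(
    sample_id = c("FT1", "CVX1", "NTC1"), patient_id = c("P1", "P1", NA),
    site = c("FT_OVARY_LEFT", "CERVIX", "NO_TEMPLATE_CONTROL"),
    batch = "B1", plate = "PL1", stringsAsFactors = FALSE)
  counts <- matrix(c(150L, 150L, 99L), 1, 3, dimnames = list("K", man$sample_id))
  s <- new_study(man, counts, make_patients("P1"))
  expect_equal(run_filter(s, filter_config(read_threshold = 60))$survivors,
               character(0))
  expect_equal(run_filter(s, filter_config(read_threshold = 100))$survivors,
               "K")
})

test_that("run_filter matches an independent brute-force oracle", {
  set.seed(123)
  for (i in 1:25) {
    s <- random_study(n_taxa = sample(2:10, 1), n_samples = sample(4:12, 1))
    cfg <- filter_config(
      read_threshold = sample(c(50, 100, 150), 1),
      use_port_as_control = sample(c(TRUE, FALSE), 1))
    fr <- run_filter(s, cfg)
    oracle <- brute_filter(s, cfg)
    expect_setequal(fr$survivors, oracle$survivors)
    got <- stats::setNames(fr$ledger$removal_step, fr$ledger$taxon_id)
    expect_equal(unname(got[names(oracle$removal_step)]),
                 unname(oracle$removal_step))
  }
})

test_that("desk-scale simulations recover the planted truth", {
  sim <- simulate_study(desk_preset(seed = 2))
  fr <- run_filter(sim$study)
  tr <- sim$truth
  true_ft <- tr$taxon_id[tr$label == "TRUE_FT"]
  contam <- tr$taxon_id[tr$label %in% c("REAGENT_CONTAM", "AIR_CONTAM")]
  expect_gte(mean(true_ft %in% fr$survivors), 0.8)
  expect_gte(mean(!contam %in% fr$survivors), 0.95)
})
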