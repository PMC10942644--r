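test_that("Shannon index matches its closed forms", {
  expect_equal(shannon(c(50, 50)), log(2))
  expect_equal(shannon(100), 0)
  expect_equal(shannon(c(70, 20, 10)), 0.8018, tolerance = 1e-4)
  expect_true(is.na(shannon(c(0, 0))))        # undefined-diversity signal
  expect_error(shannon(c(-1, 5)), class = "ftmicro_value_error")
})

test_that("Shannon agrees with vegan and respects its invariants", {
  skip_if_not_installed("vegan")
  set.seed(8)
  for (i in 1:20) {
    x <- rnbinom(sample(2:12, 1), size = 1, mu = 50)
    if (sum(x) == 0) x[1] <- 1
    expect_equal(shannon(x), unname(vegan::diversity(x, index = "shannon")),
                 tolerance = 1e-12)
    expect_equal(shannon(x), shannon(x * 7), tolerance = 1e-12)  # scale-free
  }
  # H is maximal (= ln S) exactly at the uniform composition
  expect_equal(shannon(rep(13, 9)), log(9), tolerance = 1e-12)
  expect_lt(shannon(c(13, 13, 14)), log(3))
})

test_that("diversity comparisons handle identical compositions as a null", {
  man <- data.frame(
    sample_id = c("P1_F", "P1_C", "P2_F", "P2_C"),
    patient_id = c("P1", "P1", "P2", "P2"),
    site = c("FT_OVARY_LEFT", "CERVIX", "FT_OVARY_LEFT", "CERVIX"),
    batch = "B1", plate = "PL1", stringsAsFactors = FALSE)
  counts <- matrix(rep(c(200L, 200L), 4), 2, 4,
                   dimnames = list(c("T1", "T2"), man$sample_id))
  s <- new_study(man, counts, make_patients(c("P1", "P2")))
  dv <- diversity_comparisons(s, c("T1", "T2"))
  expect_true(all(abs(dv$shannon$shannon - log(2)) < 1e-12))
  sites <- dv$comparisons[dv$comparisons$comparison == "between_sites", ]
  expect_true(all(sites$p_value == 1 | sites$note != ""))
})

test_that("two-sample Shannon difference propagates to the table", {
  man <- data.frame(
    sample_id = c("P1_F", "P2_F"), patient_id = c("P1", "P2"),
    site = "FT_OVARY_LEFT", batch = "B1", plate = "PL1",
    stringsAsFactors = FALSE)
  counts <- matrix(c(100L, 100L, 200L, 0L), 2, 2,
                   dimnames = list(c("T1", "T2"), man$sample_id))
  s <- new_study(man, counts, make_patients(c("P1", "P2")))
  dv <- diversity_comparisons(s, c("T1", "T2"))
  h <- stats::setNames(dv$shannon$shannon, dv$shannon$patient_id)
  expect_equal(unname(h["P1"] - h["P2"]), log(2), tolerance = 1e-12)
})

test_that("simulated cervical communities are less diverse than FT", {
  dirs <- vapply(1:5, function(sd_) {
    sim <- simulate_study(desk_preset(seed = sd_))
    fr <- run_filter(sim$study)
    dv <- diversity_comparisons(sim$study, fr$diversity_set)
    m <- tapply(dv$shannon$shannon, dv$shannon$site_class, mean)
    m[["CERVIX"]] < m[["FTO"]]
  }, logical(1))
  expect_true(all(dirs))
})

test_that("PCA ordination matches an independent eigendecomposition", {
  man <- data.frame(
    sample_id = c("A", "B", "C"), patient_id = c("P1", "P2", "P3"),
    site = "FT_OVARY_LEFT", batch = "B1", plate = "PL1",
    stringsAsFactors = FALSE)
  counts <- matrix(c(100L, 20L, 5L,
                     10L, 80L, 30L,
                     1L, 40L, 90L), 3, 3, byrow = TRUE,
                   dimnames = list(c("T1", "T2", "T3"), man$sample_id))
  s <- new_study(man, counts, make_patients(c("P1", "P2", "P3")))
  ord <- ordinate(s, c("T1", "T2", "T3"), k = 2, sites = "FTO")
  # oracle: eigen-decompose the covariance of the Hellinger matrix directly
  X <- sqrt(t(counts) / colSums(counts))
  Xc <- scale(X, center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(Xc), symmetric = TRUE)$values
  expect_equal(ord$explained_variance[1:2], (ev / sum(ev))[1:2],
               tolerance = 1e-9)
  expect_equal(sum(ord$explained_variance), 1, tolerance = 1e-9)
  expect_true(all(diff(ord$explained_variance) < 1e-12))
})

test_that("degenerate ordinations behave as documented", {
  man <- data.frame(
    sample_id = c("A", "B", "C"), patient_id = c("P1", "P2", "P3"),
    site = "FT_OVARY_LEFT", batch = "B1", plate = "PL1",
    stringsAsFactors = FALSE)
  # two distinct samples: the centred cloud is rank 1, PC1 carries all
  # the variance and k is truncated with a notice
  counts <- matrix(c(10L, 200L,
                     20L, 50L,
                     70L, 10L), 3, 2, byrow = TRUE,
                   dimnames = list(c("T1", "T2", "T3"), man$sample_id[1:2]))
  s <- new_study(man[1:2, ], counts, make_patients(c("P1", "P2")))
  ord <- ordinate(s, rownames(counts), k = 2, sites = "FTO")
  expect_equal(ord$explained_variance[1], 1, tolerance = 1e-9)
  expect_equal(ord$k, 1)
  expect_match(ord$note, "truncated")

  # identical samples: all scores equal under proportions
  counts2 <- matrix(rep(c(10L, 30L, 60L), 3), 3, 3,
                    dimnames = list(c("T1", "T2", "T3"), man$sample_id))
  s2 <- new_study(man, counts2, make_patients(c("P1", "P2", "P3")))
  ord2 <- ordinate(s2, rownames(counts2), k = 1, sites = "FTO")
  expect_true(all(abs(ord2$scores$PC1 - ord2$scores$PC1[1]) < 1e-9))
})

test_that("ordination scores are invariant (up to nothing) to sample order", {
  sim <- simulate_study(desk_preset(seed = 6))
  fr <- run_filter(sim$study)
  skip_if(length(fr$survivors) < 3)
  s <- sim$study
  perm <- sample(ncol(s$counts))
  s2 <- new_study(s$manifest[perm, ], s$counts[, perm], s$patients, s$taxa,
                  s$concentrations)
  o1 <- ordinate(s, fr$survivors, k = 2)
  o2 <- ordinate(s2, fr$survivors, k = 2)
  m1 <- o1$scores[order(o1$scores$sample_id), c("PC1", "PC2")]
  m2 <- o2$scores[order(o2$scores$sample_id), c("PC1", "PC2")]
  expect_equal(as.matrix(m1), as.matrix(m2), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(o1$explained_variance, o2$explained_variance,
               tolerance = 1e-9)
})

test_that("the overview export is complete and correctly sized", {
  man <- data.frame(
    sample_id = c("P1_F", "P2_F"), patient_id = c("P1", "P2"),
    site = "FT_OVARY_LEFT", batch = c("B1", "B2"), plate = "PL1",
    stringsAsFactors = FALSE)
  counts <- matrix(c(150L, 0L, 0L, 0L), 2, 2,
                   dimnames = list(c("T1", "T2"), man$sample_id))
  s <- new_study(man, counts,
                 make_patients(c("P1", "P2"), cancer = c("CANCER",
                                                         "NON_CANCER"),
                               age = c(63, 47)))
  long <- export_overview(s, c("T1", "T2"))
  expect_equal(nrow(long), 4)                      # 2 patients x 2 taxa
  expect_equal(sum(long$present), 1)
  p2 <- long[long$patient_id == "P2", ]
  expect_true(all(p2$present == 0))                # zero rows retained
  expect_equal(unique(p2$age_group), "40-49")

  sim <- simulate_study(desk_preset(seed = 1))
  fr <- run_filter(sim$study)
  ov <- export_overview(sim$study, fr$survivors)
  n_pat_ft <- length(unique(sim$study$manifest$patient_id[
    site_class(sim$study$manifest$site) == "FTO"]))
  expect_equal(nrow(ov), n_pat_ft * length(fr$survivors))
})
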