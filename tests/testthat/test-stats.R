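test_that("complete-case enforcement drops subjects with missing angles", {
  withr::with_seed(1, tab <- random_study_table(c(3, 3)))
  out <- enforce_complete_cases(tab)
  expect_identical(out[, names(tab)], tab)  # complete table passes through
  drop <- tab[!(tab$subject_id == "A01" & tab$angle_deg == 90), ]
  out2 <- enforce_complete_cases(drop)
  expect_false("A01" %in% out2$subject_id)
  expect_identical(attr(out2, "removed_subjects"), "A01")
  # 9/8/9 with 1/0/3 incomplete subjects -> 8/8/6 retained
  withr::with_seed(2, big <- random_study_table(c(9, 8, 9)))
  incomplete <- c("A01", "C01", "C02", "C03")
  big <- big[!(big$subject_id %in% incomplete & big$angle_deg == 90), ]
  kept <- enforce_complete_cases(big)
  n <- tapply(kept$subject_id, kept$species, function(s) length(unique(s)))
  expect_equal(as.vector(n), c(8, 8, 6))
  # too few complete subjects
  tiny <- tab[tab$subject_id %in% c("A01", "B01", "B02"), ]
  expect_error(enforce_complete_cases(tiny), "insufficient")
})

test_that("mixed ANOVA reproduces the published degrees-of-freedom structure", {
  withr::with_seed(3, tab <- random_study_table(c(8, 8, 6)))
  an <- mixed_anova(tab, "peak_freq_hz")
  expect_equal(an$term, c("angle", "species", "interaction", "subjects",
                          "residual"))
  expect_equal(an$DF, c(2, 2, 4, 19, 38))
  expect_equal(an$DFn[1:4], c(2, 2, 4, 19))
  expect_equal(an$DFd[1:4], c(38, 19, 38, 38))
  # SS additivity against the total computed independently
  expect_equal(sum(an$SS), sum((tab$peak_freq_hz - mean(tab$peak_freq_hz))^2),
               tolerance = 1e-9)
  expect_error(mixed_anova(tab[-1, ], "peak_freq_hz"), "unbalanced")
})

test_that("constant data produce an all-zero decomposition", {
  withr::with_seed(4, tab <- random_study_table(c(3, 3)))
  tab$peak_freq_hz <- 7
  an <- mixed_anova(tab, "peak_freq_hz")
  expect_equal(an$SS, rep(0, 5))
})

test_that("sums of squares and F statistics match the aov error-stratum oracle", {
  withr::with_seed(11, {
    for (rep in 1:10) {
      sizes <- sample(2:5, sample(2:3, 1), replace = TRUE)
      tab <- random_study_table(sizes, effect = runif(1, 0, 3))
      an <- mixed_anova(tab, "peak_freq_hz")
      tab$subject <- factor(tab$subject_id)
      tab$sp <- factor(tab$species)
      tab$angle <- factor(tab$angle_deg)
      fit <- summary(stats::aov(peak_freq_hz ~ sp * angle + Error(subject),
                                data = tab))
      between <- fit[["Error: subject"]][[1]]
      within <- fit[["Error: Within"]][[1]]
      expect_equal(an$SS[an$term == "species"], between["sp", "Sum Sq"],
                   tolerance = 1e-8)
      expect_equal(an$SS[an$term == "subjects"],
                   between["Residuals", "Sum Sq"], tolerance = 1e-8)
      expect_equal(an$SS[an$term == "angle"], within["angle", "Sum Sq"],
                   tolerance = 1e-8)
      expect_equal(an$SS[an$term == "interaction"],
                   within["sp:angle", "Sum Sq"], tolerance = 1e-8)
      expect_equal(an$SS[an$term == "residual"],
                   within["Residuals", "Sum Sq"], tolerance = 1e-8)
      expect_equal(an$F[an$term == "angle"], within["angle", "F value"],
                   tolerance = 1e-8)
    }
  })
})

test_that("with one species the angle test reduces to a one-way repeated-measures ANOVA", {
  withr::with_seed(12, tab <- random_study_table(6, effect = 1.5))
  an <- mixed_anova(tab, "peak_freq_hz")
  tab$subject <- factor(tab$subject_id)
  tab$angle <- factor(tab$angle_deg)
  one_way <- summary(stats::aov(peak_freq_hz ~ angle + Error(subject),
                                data = tab))
  ref <- one_way[["Error: Within"]][[1]]["angle", "F value"]
  expect_equal(an$F[an$term == "angle"], ref, tolerance = 1e-8)
})

test_that("angle-effect type-I error is near nominal under the null", {
  withr::with_seed(21, frame <- random_study_table(c(8, 8, 6)))
  subject <- factor(frame$subject_id)
  species <- factor(frame$species)
  angle <- factor(frame$angle_deg)
  withr::with_seed(22, {
    hits <- replicate(500, {
      frame$peak_freq_hz <- rnorm(nrow(frame))
      mixed_anova(frame, "peak_freq_hz")$p[1] < 0.05
    })
  })
  expect_lt(abs(mean(hits) - 0.05), 0.025)
})

test_that("Tukey comparisons cover all angle pairs with sane limiting behaviour", {
  withr::with_seed(31, tab <- random_study_table(c(4, 4)))
  # zero within-species angle differences: subject means only
  flat <- tab
  subj_mean <- tapply(flat$peak_freq_hz, flat$subject_id, mean)
  flat$peak_freq_hz <- subj_mean[flat$subject_id]
  an <- mixed_anova(flat, "peak_freq_hz")
  tk <- tukey_within_species(flat, "peak_freq_hz", an)
  expect_equal(nrow(tk), 6)  # 3 pairs x 2 species
  expect_equal(tk$mean_diff, rep(0, 6))
  expect_true(all(tk$p_adj > 0.999))
  expect_true(all(table(tk$species) == 3))
})

test_that("a strong angle effect is detected by Tukey in nearly all replicates", {
  withr::with_seed(41, {
    hit <- replicate(40, {
      tab <- random_study_table(c(8))
      shift <- c(`0` = 200, `45` = 150, `90` = 100)
      tab$peak_freq_hz <- shift[as.character(tab$angle_deg)] +
        rnorm(nrow(tab), 0, 15)
      an <- mixed_anova(tab, "peak_freq_hz")
      tk <- tukey_within_species(tab, "peak_freq_hz", an)
      tk$p_adj[tk$comparison == "0 vs 90"] < 0.001
    })
  })
  expect_gte(mean(hit), 0.95)
})

test_that("Tukey family-wise error under the null is near nominal", {
  withr::with_seed(51, frame <- random_study_table(c(8)))
  withr::with_seed(52, {
    fwer <- replicate(400, {
      frame$peak_freq_hz <- rnorm(nrow(frame))
      an <- mixed_anova(frame, "peak_freq_hz")
      tk <- tukey_within_species(frame, "peak_freq_hz", an)
      any(tk$p_adj < 0.05)
    })
  })
  expect_lt(abs(mean(fwer) - 0.05), 0.03)
})

test_that("length regression recovers exact and null relationships", {
  tab <- data.frame(subject_id = sprintf("S%02d", 1:10), species = "A",
                    angle_deg = 0, length_cm = seq(6, 9, length.out = 10))
  tab$peak_freq_hz <- 2 * tab$length_cm + 1
  r <- length_regression(tab, "peak_freq_hz")
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 1)
  expect_equal(r$r_squared, 1)
  withr::with_seed(61, tab$peak_freq_hz <- rnorm(10, 100, 10))
  expect_lt(length_regression(tab, "peak_freq_hz")$r_squared, 0.35)
  tab$length_cm <- 7
  expect_error(length_regression(tab, "peak_freq_hz"), "distinct|variance")
})

test_that("a weak length effect is recovered on average across simulated cohorts", {
  # slope -20 Hz/cm with noise sized for r^2 ~ 0.07 at n = 26
  withr::with_seed(71, {
    fits <- replicate(200, {
      len <- rnorm(26, 7.7, 0.55)
      y <- 250 - 20 * len + rnorm(26, 0, 39)
      tab <- data.frame(subject_id = sprintf("S%02d", 1:26), species = "A",
                        angle_deg = 0, length_cm = len, peak_freq_hz = y)
      f <- length_regression(tab, "peak_freq_hz")
      c(f$slope, f$r_squared)
    })
  })
  expect_equal(mean(fits[1, ]), -20, tolerance = 5 / 20)
  expect_equal(median(fits[2, ]), 0.074, tolerance = 0.6)
})

test_that("group summaries report mean, SE and range per cell", {
  tab <- data.frame(subject_id = c("a", "b", "c", "d"), species = "A",
                    angle_deg = c(0, 0, 0, 45),
                    peak_freq_hz = c(100, 110, 120, 90))
  s <- summarize_groups(tab, "peak_freq_hz")
  cell <- s[s$angle_deg == 0, ]
  expect_equal(cell$mean, 110)
  expect_equal(cell$se, 10 / sqrt(3), tolerance = 1e-10)  # 5.7735
  expect_equal(c(cell$min, cell$max), c(100, 120))
  single <- s[s$angle_deg == 45, ]
  expect_equal(single$se, 0)
  expect_true(single$se_flag)
})
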