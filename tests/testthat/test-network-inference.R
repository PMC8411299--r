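# A hand-built hospital-level frame with known structure.
toy_frame <- function(n = 120, seed = 61, icu_effect = 0, noise = 1) {
  set.seed(seed)
  df <- data.frame(
    hospital_id = sprintf("H%03d", 1:n),
    state = paste0("S", rep_len(1:6, n)),
    bed_category = factor(sample(c("<100", "100-250", ">250"), n, TRUE),
                          levels = c("<100", "100-250", ">250")),
    icu_category = factor(sample(c("0-10", "11-25", ">25"), n, TRUE),
                          levels = c("0-10", "11-25", ">25")),
    teaching_status = factor(sample(c("nonteaching", "small", "large"), n, TRUE),
                             levels = c("nonteaching", "small", "large")),
    trauma_level = factor(sample(c("none", "3", "2", "1"), n, TRUE),
                          levels = c("none", "3", "2", "1")),
    fellowship = factor(sample(c("no", "yes"), n, TRUE), levels = c("no", "yes")),
    volume_quartile = factor(sample(paste0("Q", 1:4), n, TRUE), levels = paste0("Q", 1:4)),
    mortality_quartile = factor(sample(paste0("Q", 1:4), n, TRUE), levels = paste0("Q", 1:4)),
    ftr_quartile = factor(sample(paste0("Q", 1:4), n, TRUE), levels = paste0("Q", 1:4)),
    network_label = "all",
    stringsAsFactors = FALSE
  )
  df$log_centrality_ratio <- icu_effect * (df$icu_category == ">25") +
    rnorm(n, 0, noise)
  df
}

test_that("analysis frames categorize, drop undefined outcomes, and tally", {
  out <- small_sim(seed = 62, n_patients = 2500)
  eps <- filter_transfer_cohort(build_episodes(out$sim$encounters, pkg_codes()))
  cent <- log_transform_ratios(degree_centralities(build_network(eps$transfers, "all")))
  frame0 <- episode_outcomes(
    build_episodes(out$sim$encounters, pkg_codes()), pkg_codes(), pkg_comorbidity())
  ho <- hospital_outcomes(frame0)
  fr <- analysis_frame(cent, out$hospitals, ho)
  expect_s3_class(fr, "egs_analysis_frame")
  expect_false(anyNA(fr$log_centrality_ratio))
  expect_true(all(levels(fr$bed_category) == c("<100", "100-250", ">250")))
  dropped <- attr(fr, "dropped")
  expect_identical(sum(is.na(cent$log_centrality_ratio)),
                   as.integer(dropped[["undefined_log_ratio"]]))
  expect_identical(nrow(fr) + sum(dropped), nrow(cent))

  fr2 <- analysis_frame(cent, out$hospitals, outcomes = NULL)
  expect_true(all(is.na(fr2$volume_quartile)))
})

test_that("one-way ANOVA with pairwise contrasts matches closed forms", {
  # identical groups: difference 0, F = 0, p = 1
  fr <- data.frame(log_centrality_ratio = c(1, 2, 3, 1, 2, 3),
                   fellowship = factor(rep(c("no", "yes"), each = 3)))
  a <- anova_with_pairwise(fr, "fellowship")
  expect_equal(a$pairwise$difference, 0)
  expect_equal(a$f_statistic, 0)
  expect_equal(a$p_value, 1)
  expect_equal(a$pairwise$p_value, 1)

  # two-group identity F = t^2, difference oriented level2 - level1
  fr2 <- data.frame(log_centrality_ratio = c(0, 0, 1, 1, 1, 2),
                    fellowship = factor(rep(c("no", "yes"), each = 3)))
  a2 <- anova_with_pairwise(fr2, "fellowship", method = "none")
  tt <- t.test(log_centrality_ratio ~ fellowship, data = fr2, var.equal = TRUE)
  expect_equal(a2$f_statistic, unname(tt$statistic)^2)
  expect_equal(a2$p_value, tt$p.value)
  expect_equal(a2$pairwise$difference, 1)  # yes - no
  expect_equal(a2$pairwise$p_value, tt$p.value)

  # Tukey default agrees with stats::TukeyHSD
  fr3 <- toy_frame(60, seed = 63)
  a3 <- anova_with_pairwise(fr3, "icu_category")
  ref <- TukeyHSD(aov(log_centrality_ratio ~ icu_category, data = fr3))$icu_category
  expect_equal(a3$pairwise$difference, unname(ref[, "diff"]))
  expect_equal(a3$pairwise$conf_low, unname(ref[, "lwr"]))
  expect_equal(a3$pairwise$conf_high, unname(ref[, "upr"]))
  expect_equal(a3$pairwise$p_value, unname(ref[, "p adj"]), tolerance = 1e-6)

  # antisymmetry under group-order reversal
  fr4 <- fr3
  fr4$icu_category <- factor(fr4$icu_category, levels = rev(levels(fr3$icu_category)))
  a4 <- anova_with_pairwise(fr4, "icu_category")
  expect_equal(sort(a4$pairwise$difference), sort(-a3$pairwise$difference))

  # groups with < 2 observations are dropped with a warning
  fr5 <- rbind(fr3, transform(fr3[1, ], icu_category = NA))
  fr5$teaching_status <- as.character(fr5$teaching_status)
  fr5$teaching_status[1] <- "tiny"
  expect_warning(anova_with_pairwise(fr5, "teaching_status"), "tiny")
})

test_that("cluster-robust covariance equals the hand-coded sandwich", {
  set.seed(64)
  n <- 12
  df <- data.frame(x1 = rnorm(n), x2 = rnorm(n),
                   state = rep(c("S1", "S2", "S3"), each = 4))
  df$log_centrality_ratio <- 1 + 0.5 * df$x1 - 0.3 * df$x2 + rnorm(n)
  fit <- lm(log_centrality_ratio ~ x1 + x2, data = df)
  V_pkg <- sandwich::vcovCL(fit, cluster = df$state, type = "HC1", cadjust = TRUE)
  X <- model.matrix(fit)
  V_hand <- oracle_cluster_vcov(X, df$log_centrality_ratio, df$state)
  expect_lt(max(abs(V_pkg - V_hand)), 1e-10)

  # with one observation per cluster the estimator reduces to HC1
  df2 <- df; df2$state <- paste0("S", 1:n)
  fit2 <- lm(log_centrality_ratio ~ x1 + x2, data = df2)
  expect_equal(sandwich::vcovCL(fit2, cluster = df2$state, type = "HC1", cadjust = TRUE),
               sandwich::vcovHC(fit2, type = "HC1"), tolerance = 1e-12)
})

test_that("clustered regression recovers structure and tests blocks", {
  # noiseless outcome: exact recovery, degenerate CIs
  fr <- toy_frame(200, seed = 65, noise = 0, icu_effect = 0.7)
  fr$log_centrality_ratio <- 0.7 * (fr$icu_category == ">25") +
    0.3 * (fr$bed_category == ">250")
  reg <- clustered_regression(fr, blocks = c("icu_category", "bed_category"))
  co <- reg$coefficients
  expect_equal(co$estimate[co$term == "icu_category>25"], 0.7, tolerance = 1e-10)
  expect_equal(co$estimate[co$term == "bed_category>250"], 0.3, tolerance = 1e-10)
  expect_lt(max(co$conf_high - co$conf_low), 1e-8)

  # point estimates are invariant to cluster assignment
  fr6 <- toy_frame(150, seed = 66, icu_effect = 0.5)
  r1 <- clustered_regression(fr6)
  fr6b <- fr6; fr6b$state <- rep(paste0("S", 1:6), each = nrow(fr6b) / 6)
  r2 <- clustered_regression(fr6b)
  expect_equal(r1$coefficients$estimate, r2$coefficients$estimate)
  expect_false(isTRUE(all.equal(r1$coefficients$std_error, r2$coefficients$std_error)))

  # partial F of a single-level block equals that level's squared t statistic
  pf_fellow <- r1$partial_f[r1$partial_f$block == "fellowship", ]
  t_fellow <- r1$coefficients$statistic[r1$coefficients$term == "fellowshipyes"]
  expect_equal(pf_fellow$f_statistic, t_fellow^2, tolerance = 1e-10)

  # failure modes
  single <- fr6; single$state <- "S1"
  expect_error(clustered_regression(single), "clusters")
  collinear <- fr6; collinear$bed_category <- collinear$icu_category
  expect_error(clustered_regression(collinear), "rank deficient")
})

test_that("the sensitivity suite reruns one specification per subnetwork", {
  fr <- toy_frame(160, seed = 67, icu_effect = 1.2, noise = 0.5)
  null_fr <- toy_frame(160, seed = 68, icu_effect = 0, noise = 0.5)
  res <- run_sensitivity_suite(list(ip_ip = fr, ed_ip = null_fr,
                                    op = fr, empty = fr[0, ]))
  # idempotence: identical frames give identical results
  expect_equal(res$ip_ip$coefficients, res$op$coefficients)
  # planted effect: significant where planted, covered by CI where absent
  ip <- res$ip_ip$coefficients
  ed <- res$ed_ip$coefficients
  expect_gt(ip$conf_low[ip$term == "icu_category>25"], 0)
  expect_true(ed$conf_low[ed$term == "icu_category>25"] < 0 &&
                ed$conf_high[ed$term == "icu_category>25"] > 0)
  expect_true(isTRUE(res$empty$skipped))
})
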