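test_that("comorbidity index sums weights over distinct categories", {
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    weights = list(a = 7, b = -1),
    categories = list(X1 = "a", X2 = "a", Y1 = "b")
  ), tmp, auto_unbox = TRUE)
  cmb <- read_comorbidity_table(tmp)
  expect_equal(comorbidity_index(character(0), cmb), 0)
  expect_equal(comorbidity_index(c("X1", "X2"), cmb), 7)   # same category once
  expect_equal(comorbidity_index(c("X1", "Y1"), cmb), 6)   # 7 + (-1)
  expect_equal(comorbidity_index("X1;Y1;ZZZ", cmb), 6)     # unmapped contributes 0

  # vectorized path in episode_outcomes agrees with the scalar definition
  out <- small_sim(seed = 51, n_patients = 400)
  eps <- build_episodes(out$sim$encounters, pkg_codes())
  frame <- episode_outcomes(eps, pkg_codes(), pkg_comorbidity())
  ep <- eps$episodes[eps$episodes$egs & eps$episodes$has_ip, ]
  direct <- vapply(ep$dx_codes, comorbidity_index, numeric(1),
                   comorbidity = pkg_comorbidity(), USE.NAMES = FALSE)
  expect_equal(frame$comorbidity, direct)
})

test_that("EGS volume counts non-transferred inpatient EGS episodes", {
  codes <- pkg_codes()
  egs <- egs_code1()
  mk_ip <- function(pid, day) enc_row(pid, "A", "IP", sprintf("2016-02-%02d", day),
                                      sprintf("2016-02-%02d", day + 1), dx = egs)
  mk_tr <- function(pid, day) {
    rbind(enc_row(pid, "A", "IP", sprintf("2016-03-%02d", day),
                  sprintf("2016-03-%02d", day + 1), dx = egs),
          enc_row(pid, "B", "IP", sprintf("2016-03-%02d", day + 2),
                  sprintf("2016-03-%02d", day + 3), dx = egs))
  }
  enc <- rbind(mk_ip("P1", 1), mk_ip("P2", 5), mk_ip("P3", 9),
               mk_tr("P4", 1), mk_tr("P5", 10),
               enc_row("P6", "C", "ED", "2016-04-01", "2016-04-01", dx = egs))
  frame <- episode_outcomes(build_episodes(enc, codes), codes, pkg_comorbidity())
  vol <- compute_egs_volume(frame, c("A", "B", "C"))
  expect_identical(vol[["A"]], 3L)  # 5 EGS inpatient episodes, 2 transferred out
  expect_identical(vol[["B"]], 0L)  # only receives transfers
  expect_identical(vol[["C"]], 0L)  # ED-only is not an inpatient EGS episode

  # planted volumes recovered exactly on synthetic data
  out <- small_sim(seed = 52, n_patients = 3000)
  eps <- build_episodes(out$sim$encounters, codes)
  frame2 <- episode_outcomes(eps, codes, pkg_comorbidity())
  got <- compute_egs_volume(frame2, out$hospitals$hospital_id)
  truth <- out$sim$ground_truth$egs_volume
  expect_identical(as.integer(got[truth$hospital_id]), truth$egs_volume)
})

test_that("failure-to-rescue partitions episodes correctly", {
  expect_true(flag_failure_to_rescue(TRUE, TRUE, TRUE))
  expect_false(flag_failure_to_rescue(TRUE, TRUE, FALSE))
  expect_true(is.na(flag_failure_to_rescue(FALSE, TRUE, TRUE)))   # not operated
  expect_true(is.na(flag_failure_to_rescue(TRUE, FALSE, FALSE)))  # no complication

  out <- small_sim(seed = 53, n_patients = 2000)
  frame <- episode_outcomes(build_episodes(out$sim$encounters, pkg_codes()),
                            pkg_codes(), pkg_comorbidity())
  ftr <- flag_failure_to_rescue(frame$operated, frame$complication, frame$died)
  in_denominator <- sum(!is.na(ftr))
  not_operated <- sum(!frame$operated)
  no_complication <- sum(frame$operated & !frame$complication)
  expect_identical(in_denominator + not_operated + no_complication, nrow(frame))
})

test_that("risk models recover planted coefficients and reject degenerate input", {
  cfg <- sim_config(n_hospitals = 20, n_patients = 6000, egs_probability = 1,
                    ed_only_probability = 0, transfer_probability = 0,
                    quality_effect_sd = 0, complication_death_effect = 0,
                    seed = 54)
  h <- generate_hospitals(cfg)
  sim <- generate_encounters(h, cfg)
  frame <- episode_outcomes(build_episodes(sim$encounters, pkg_codes()),
                            pkg_codes(), pkg_comorbidity())
  model <- fit_risk_model(frame, "death")
  est <- summary(model$fit)$coefficients
  for (term_truth in list(c("age", cfg$age_effect),
                          c("sexM", cfg$sex_effect),
                          c("comorbidity", cfg$comorbidity_effect))) {
    term <- term_truth[1]; truth <- as.numeric(term_truth[2])
    expect_lt(abs(est[term, "Estimate"] - truth), 3 * est[term, "Std. Error"])
  }
  # score equation: observed events match expected events in aggregate
  expect_equal(sum(model$eligible$outcome), sum(model$eligible$expected))

  degenerate <- data.table::copy(frame)[, died := FALSE]
  expect_error(fit_risk_model(degenerate, "death"), "one outcome class")
  expect_error(fit_risk_model(frame[1:10], "death"), ">= 50")
})

test_that("indirect standardization follows observed/expected times overall rate", {
  fake <- structure(list(
    eligible = data.table::data.table(
      hospital_id = rep(c("A", "B"), each = 4),
      outcome = c(1, 1, 0, 0, 1, 0, 0, 0),
      expected = c(1, 1, 1, 1, 0.25, 0.25, 0.25, 0.25)
    ),
    overall_rate = 0.05, outcome = "death"), class = "egs_risk_model")
  rates <- hospital_adjusted_rate(fake)
  expect_equal(rates$adjusted_rate[rates$hospital_id == "A"], 2 / 4 * 0.05)  # 0.025
  expect_equal(rates$adjusted_rate[rates$hospital_id == "B"], 1 / 1 * 0.05)
  none <- hospital_adjusted_rate(fake, hospital_ids = c("A", "B", "Z"))
  expect_true(is.na(none$adjusted_rate[none$hospital_id == "Z"]))

  # relabeling hospitals permutes rates identically
  relabeled <- fake
  relabeled$eligible <- data.table::copy(fake$eligible)[
    , hospital_id := c(A = "B", B = "A")[hospital_id]]
  r2 <- hospital_adjusted_rate(relabeled)
  expect_equal(r2$adjusted_rate[r2$hospital_id == "B"],
               rates$adjusted_rate[rates$hospital_id == "A"])
})

test_that("an intercept-only population predicts the pooled rate for everyone", {
  set.seed(55)
  n <- 400
  frame <- data.table::data.table(
    episode_id = 1:n, patient_id = as.character(1:n), hospital_id = "A",
    state = "S1", age = 50, sex = "F", comorbidity = 0,
    egs_category = "appendicitis", transferred = FALSE, operated = TRUE,
    complication = TRUE, died = runif(n) < 0.3
  )
  model <- fit_risk_model(frame, "death")
  expect_equal(unname(model$eligible$expected), rep(mean(frame$died), n))
})

test_that("quartiles cut at empirical quartiles with ties going low", {
  expect_identical(assign_quartiles(1:8), rep(1:4, each = 2L))
  expect_warning(q <- assign_quartiles(rep(5, 10)), "identical")
  expect_identical(q, rep(1L, 10))
  expect_error(assign_quartiles(c(1, 2, NA, NA, 3)), ">= 4")
  expect_identical(assign_quartiles(c(1, NA, 2, 3, 4)),
                   c(1L, NA, 2L, 3L, 4L))
  set.seed(56)
  sizes <- table(assign_quartiles(runif(1000)))
  expect_true(all(abs(sizes - 250) <= 1))
})

test_that("null hospital effects shrink adjusted-rate spread toward the sampling floor", {
  cfg <- sim_config(n_hospitals = 20, n_patients = 8000, egs_probability = 1,
                    ed_only_probability = 0, transfer_probability = 0,
                    quality_effect_sd = 0, seed = 57)
  sim <- generate_encounters(generate_hospitals(cfg), cfg)
  frame <- episode_outcomes(build_episodes(sim$encounters, pkg_codes()),
                            pkg_codes(), pkg_comorbidity())
  model <- fit_risk_model(frame, "death")
  rates <- hospital_adjusted_rate(model)
  p <- model$overall_rate
  floor_sd <- sqrt(p * (1 - p) / 400)  # 400 episodes per hospital
  expect_lt(sd(rates$adjusted_rate), 2 * floor_sd)
})
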