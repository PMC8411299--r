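#' Simulation configuration for the synthetic claims generator
#'
#' Builds a validated configuration for [generate_hospitals()] and
#' [generate_encounters()]. Defaults describe the study conditions the
#' pipeline is validated under: eight states, a crude in-hospital mortality
#' near 5%, roughly 40% of episodes involving an operation or procedure, and
#' transfer destinations chosen preferentially toward resource-rich
#' hospitals.
#'
#' @param n_hospitals Number of hospitals (>= 2).
#' @param n_patients Number of patients; each patient contributes at most one
#'   episode of care.
#' @param n_states Number of states hospitals are spread over.
#' @param egs_probability Probability that a patient's episode carries an EGS
#'   diagnosis.
#' @param transfer_probability Probability that a patient's episode involves
#'   an interhospital transfer.
#' @param chain_probability Probability that a transferred patient is
#'   transferred a second time (a 3-hospital chain).
#' @param destination_preference_strength Multiplier on the latent hospital
#'   `resource_score` in the transfer-destination choice model; destination
#'   is drawn with probability proportional to
#'   `exp(strength * resource_score)`. 0 gives uniform destination choice.
#' @param ed_origin_probability Probability that a transfer originates from
#'   an ED-only encounter rather than an inpatient stay.
#' @param ed_only_probability Probability that a non-transferred episode is
#'   an ED-only visit (no inpatient admission).
#' @param operation_probability Per-inpatient-encounter probability of an
#'   operation or procedure (ED encounters use 30% of this rate).
#' @param baseline_death_logodds,baseline_complication_logodds Intercepts of
#'   the patient-level logistic models for in-hospital death and
#'   complication.
#' @param age_effect Log-odds increment per year of age (age centered at 60
#'   in the linear predictor; the slope is unaffected by centering).
#' @param sex_effect Log-odds increment for male vs female.
#' @param comorbidity_effect Log-odds increment per unit of the weighted
#'   comorbidity index.
#' @param complication_death_effect Log-odds increment on death when a
#'   complication occurred; sets the failure-to-rescue rate above the crude
#'   mortality rate.
#' @param quality_effect_sd SD of the per-hospital latent quality effect
#'   (additive log-odds shift on death and complication; 0 = homogeneous
#'   hospitals).
#' @param resource_noise_sd SD of the noise term in the latent
#'   `resource_score` (which is otherwise built from bed and ICU-bed counts).
#' @param comorbidity_rate Per-category probability of each comorbidity flag.
#' @param mean_los Mean length of stay in days (geometric, minimum 0).
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A list of class `egs_sim_config`.
#' @export
sim_config <- function(n_hospitals = 100,
                       n_patients = 10000,
                       n_states = 8,
                       egs_probability = 0.7,
                       transfer_probability = 0.3,
                       chain_probability = 0.05,
                       destination_preference_strength = 1,
                       ed_origin_probability = 0.55,
                       ed_only_probability = 0.2,
                       operation_probability = 0.4,
                       baseline_death_logodds = qlogis(0.05),
                       baseline_complication_logodds = qlogis(0.15),
                       age_effect = 0.03,
                       sex_effect = 0.1,
                       comorbidity_effect = 0.2,
                       complication_death_effect = 1.0,
                       quality_effect_sd = 0.3,
                       resource_noise_sd = 0.3,
                       comorbidity_rate = 0.12,
                       mean_los = 2,
                       seed = 1L) {
  config <- mget(names(formals()))
  validate_sim_config(config)
  config$seed <- as.integer(seed)
  structure(config, class = "egs_sim_config")
}

validate_sim_config <- function(config) {
  bad <- function(field, why) {
    stop("invalid simulation config: '", field, "' ", why, call. = FALSE)
  }
  num1 <- function(field) {
    v <- config[[field]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) bad(field, "must be a finite number")
    v
  }
  if (num1("n_hospitals") < 2) bad("n_hospitals", "must be >= 2")
  if (num1("n_patients") < 1) bad("n_patients", "must be >= 1")
  if (num1("n_states") < 2) bad("n_states", "must be >= 2")
  for (p in c("egs_probability", "transfer_probability", "chain_probability",
              "ed_origin_probability", "ed_only_probability",
              "operation_probability", "comorbidity_rate")) {
    v <- num1(p)
    if (v < 0 || v > 1) bad(p, "must be a probability in [0, 1]")
  }
  if (num1("destination_preference_strength") < 0) {
    bad("destination_preference_strength", "must be >= 0")
  }
  for (p in c("baseline_death_logodds", "baseline_complication_logodds",
              "age_effect", "sex_effect", "comorbidity_effect",
              "complication_death_effect")) num1(p)
  if (num1("quality_effect_sd") < 0) bad("quality_effect_sd", "must be >= 0")
  if (num1("resource_noise_sd") < 0) bad("resource_noise_sd", "must be >= 0")
  if (num1("mean_los") < 0) bad("mean_los", "must be >= 0")
  s <- config$seed
  if (!is.numeric(s) || length(s) != 1 || is.na(s) || abs(s) >= 2^31 - 10) {
    bad("seed", "must be an integer below 2^31 - 10")
  }
  invisible(config)
}

#' Generate a synthetic hospital table
#'
#' Hospitals carry the attributes the association analyses use (bed counts,
#' ICU beds, teaching status, trauma level, fellowship presence, state) plus
#' two latent quantities recorded as ground truth: `resource_score` (drives
#' transfer-destination attractiveness; built from log bed and log ICU-bed
#' counts plus noise, so it is positively correlated with size by
#' construction) and `quality_effect` (additive log-odds shift on death and
#' complication at the treating hospital). Categorical attributes are
#' assigned by size rank with noise at fixed proportions, so every level is
#' represented once the hospital count exceeds the number of levels.
#'
#' @param config An [sim_config()] object.
#' @return A data.frame with one row per hospital: `hospital_id`, `state`,
#'   `total_beds`, `icu_beds`, `teaching_status` (nonteaching/small/large),
#'   `trauma_level` (none/3/2/1), `fellowship` (logical), `resource_score`,
#'   `quality_effect`.
#' @export
generate_hospitals <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- as.integer(config$n_hospitals)
  n_states <- min(as.integer(config$n_states), n)

  total_beds <- pmax(10L, as.integer(round(exp(rnorm(n, log(150), 0.6)))))
  icu_beds <- pmin(total_beds, as.integer(round(total_beds * rbeta(n, 2, 12))))

  zb <- zscore(log(total_beds))
  zi <- zscore(log1p(icu_beds))
  resource_score <- 0.6 * zb + 1.0 * zi + rnorm(n, 0, config$resource_noise_sd)

  # Rank-with-noise assignment at fixed proportions: correlated with size,
  # and every level occupied whenever n exceeds the smallest bin.
  teaching_status <- rank_categories(
    log(total_beds) + rnorm(n, 0, 0.4),
    levels = c("nonteaching", "small", "large"),
    proportions = c(0.50, 0.30, 0.20)
  )
  trauma_level <- rank_categories(
    resource_score + rnorm(n, 0, 0.5),
    levels = c("none", "3", "2", "1"),
    proportions = c(0.45, 0.25, 0.18, 0.12)
  )
  fellowship <- rank_categories(
    log1p(icu_beds) + rnorm(n, 0, 0.5),
    levels = c("FALSE", "TRUE"),
    proportions = c(0.70, 0.30)
  ) == "TRUE"

  data.frame(
    hospital_id = sprintf("H%04d", seq_len(n)),
    state = paste0("S", rep_len(seq_len(n_states), n)),
    total_beds = total_beds,
    icu_beds = icu_beds,
    teaching_status = teaching_status,
    trauma_level = trauma_level,
    fellowship = fellowship,
    resource_score = as.numeric(resource_score),
    quality_effect = rnorm(n, 0, config$quality_effect_sd),
    stringsAsFactors = FALSE
  )
}

zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

rank_categories <- function(score, levels, proportions) {
  n <- length(score)
  cuts <- floor(cumsum(proportions / sum(proportions)) * n)
  cuts[length(cuts)] <- n
  r <- rank(score, ties.method = "first")
  idx <- findInterval(r, c(0, head(cuts, -1)) + 1L)
  levels[idx]
}

#' Generate synthetic encounters with recorded ground truth
#'
#' Each patient contributes one episode of care: a single ED-only or
#' inpatient encounter, or a transfer chain of 2 (one transfer) or 3 (two
#' transfers) encounters across distinct hospitals. Planted transfers
#' satisfy the temporal-adjacency rule by construction: the destination
#' admission falls on the same day as, or the day after, the origin
#' discharge, and all dates fall within one calendar year (2016). Transfer
#' destinations are drawn with probability proportional to
#' `exp(destination_preference_strength * resource_score)` among the other
#' hospitals. Death and complication flags come from logistic models with
#' the configured patient-level coefficients plus the treating (final
#' inpatient) hospital's `quality_effect`; the death flag is recorded on the
#' final encounter.
#'
#' @param hospitals Hospital table from [generate_hospitals()] (its
#'   `resource_score`/`quality_effect` columns may be overwritten to plant
#'   specific scenarios).
#' @param config An [sim_config()] object.
#' @param codes An `egs_code_set` (default: the packaged synthetic set).
#' @param comorbidity An `egs_comorbidity_table` (default: the packaged
#'   synthetic table).
#' @return A list of class `egs_simulation`: `encounters` (data.table in the
#'   claims schema: patient_id, hospital_id, state, setting ED/IP,
#'   admit_date, discharge_date, age, sex, dx_codes, proc_codes, died) and
#'   `ground_truth` (hospital latents, true model coefficients, the planted
#'   transfer list and ordered-pair counts, per-hospital non-transferred
#'   inpatient EGS volume, and per-patient flags).
#' @export
generate_encounters <- function(hospitals, config,
                                codes = read_code_set(egsnet_example("synthetic_code_set.json")),
                                comorbidity = read_comorbidity_table(egsnet_example("synthetic_comorbidity_weights.json"))) {
  validate_sim_config(config)
  stopifnot(is.data.frame(hospitals), nrow(hospitals) >= 2)
  set.seed(config$seed + 1L)

  n <- as.integer(config$n_patients)
  n_h <- nrow(hospitals)
  hid <- hospitals$hospital_id
  rs <- hospitals$resource_score
  qe <- hospitals$quality_effect

  patient_id <- sprintf("P%07d", seq_len(n))
  age <- pmin(100L, pmax(0L, as.integer(round(rnorm(n, 62, 18)))))
  sex <- ifelse(runif(n) < 0.521, "M", "F")

  # Comorbidity: independent category flags mapped to diagnosis codes;
  # the index used in the outcome models is the weighted category sum, the
  # same quantity comorbidity_index() recovers from the emitted codes.
  cats <- names(comorbidity$weights)
  flags <- matrix(runif(n * length(cats)) < config$comorbidity_rate, nrow = n)
  comorb_index <- as.numeric(flags %*% comorbidity$weights[cats])
  codes_by_cat <- split(names(comorbidity$category_of), comorbidity$category_of)[cats]
  hit <- which(flags, arr.ind = TRUE)
  hit_codes <- vapply(codes_by_cat, function(v) v[sample.int(length(v), 1L)], character(1))[hit[, 2]]
  comorb_str <- character(n)
  if (nrow(hit) > 0) {
    agg <- data.table::data.table(i = hit[, 1], code = hit_codes)[, .(s = paste(code, collapse = ";")), by = i]
    comorb_str[agg$i] <- agg$s
  }

  egs <- runif(n) < config$egs_probability
  egs_cats <- names(codes$egs_dx)
  egs_category <- sample(egs_cats, n, replace = TRUE)
  cat_idx <- match(egs_category, egs_cats)
  cat_len <- lengths(codes$egs_dx)[cat_idx]
  cat_offset <- cumsum(c(0L, lengths(codes$egs_dx)))[cat_idx]
  egs_code <- unlist(codes$egs_dx, use.names = FALSE)[
    cat_offset + 1L + floor(runif(n) * cat_len)]
  egs_category[!egs] <- NA_character_
  egs_code[!egs] <- NA_character_

  # Balanced home-hospital allocation (uniform expected volume per hospital).
  home <- sample(rep_len(seq_len(n_h), n))
  transferred <- runif(n) < config$transfer_probability
  chained <- transferred & runif(n) < config$chain_probability
  origin_ed <- transferred & runif(n) < config$ed_origin_probability
  ed_only <- !transferred & runif(n) < config$ed_only_probability

  dest1 <- sample_destinations(home, transferred, rs, config$destination_preference_strength)
  dest2 <- sample_destinations(dest1, chained, rs, config$destination_preference_strength)

  # Dates: admission day-of-year 1..300 and stays capped so a full
  # 3-hospital chain stays inside calendar 2016.
  year0 <- as.Date("2016-01-01")
  draw_los <- function(k) pmin(14L, rgeom(k, 1 / (1 + config$mean_los)))
  admit1 <- sample.int(300L, n, replace = TRUE)
  los1 <- draw_los(n)
  los1[ed_only | (transferred & origin_ed)] <- pmin(1L, los1[ed_only | (transferred & origin_ed)])
  gap1 <- sample(0:1, n, replace = TRUE)
  admit2 <- admit1 + los1 + gap1
  los2 <- draw_los(n)
  # A same-day transfer must end with a strictly later discharge at the
  # destination, or the two encounters' dates are indistinguishable and the
  # direction of transfer is no longer encoded in the record.
  same_day1 <- admit2 == admit1
  los2[same_day1] <- pmax(1L, los2[same_day1])
  gap2 <- sample(0:1, n, replace = TRUE)
  admit3 <- admit2 + los2 + gap2
  los3 <- draw_los(n)
  same_day2 <- admit3 == admit2
  los3[same_day2] <- pmax(1L, los3[same_day2])

  treating <- ifelse(chained, dest2, ifelse(transferred, dest1, home))
  has_ip <- !ed_only  # every transferred episode ends inpatient

  lin_common <- config$age_effect * (age - 60) +
    config$sex_effect * (sex == "M") +
    config$comorbidity_effect * comorb_index +
    qe[treating]
  complication <- has_ip &
    runif(n) < plogis(config$baseline_complication_logodds + lin_common)
  died <- has_ip &
    runif(n) < plogis(config$baseline_death_logodds + lin_common +
                        config$complication_death_effect * complication)

  # Operations/procedures: per-encounter indicator; ED encounters at 30% of
  # the inpatient rate. Incidental non-operative procedure codes are also
  # sprinkled in so operation flagging must consult the code set.
  op_code <- function(k) codes$operation_proc[sample.int(length(codes$operation_proc), k, replace = TRUE)]
  nonop_pool <- c("BW25YZZ", "B2111ZZ", "GZB4ZZZ", "4A023N7")
  proc_field <- function(k, is_ip) {
    has_op <- runif(k) < config$operation_probability * ifelse(is_ip, 1, 0.3)
    has_other <- runif(k) < 0.3
    out <- character(k)
    out[has_op] <- op_code(sum(has_op))
    other <- nonop_pool[sample.int(length(nonop_pool), k, replace = TRUE)]
    out[has_other] <- ifelse(nzchar(out[has_other]),
                             paste(out[has_other], other[has_other], sep = ";"),
                             other[has_other])
    list(field = out, op = has_op)
  }

  dx_field <- function(idx) {
    base <- comorb_str[idx]
    ec <- egs_code[idx]
    ifelse(is.na(ec), base,
           ifelse(nzchar(base), paste(ec, base, sep = ";"), ec))
  }

  mk_enc <- function(idx, hosp_idx, is_ip_enc, admit, los, died_here, extra_dx = NULL) {
    k <- length(idx)
    pr <- proc_field(k, is_ip_enc)
    dx <- dx_field(idx)
    if (!is.null(extra_dx)) {
      dx <- ifelse(nzchar(extra_dx), ifelse(nzchar(dx), paste(dx, extra_dx, sep = ";"), extra_dx), dx)
    }
    data.table::data.table(
      patient_id = patient_id[idx],
      hospital_id = hid[hosp_idx],
      state = hospitals$state[hosp_idx],
      setting = ifelse(is_ip_enc, "IP", "ED"),
      admit_date = year0 + (admit - 1L),
      discharge_date = year0 + (admit - 1L + los),
      age = age[idx],
      sex = sex[idx],
      dx_codes = dx,
      proc_codes = pr$field,
      died = as.integer(died_here),
      op = pr$op
    )
  }

  comp_code_of <- function(flagged) {
    out <- character(length(flagged))
    k <- sum(flagged)
    if (k > 0) out[flagged] <- codes$complication_dx[sample.int(length(codes$complication_dx), k, replace = TRUE)]
    out
  }

  idx_single <- which(!transferred)
  idx_tr <- which(transferred)
  idx_ch <- which(chained)

  # Single-encounter episodes: treating hospital is the home hospital, so
  # complication codes and the death flag land there.
  enc_single <- mk_enc(idx_single, home[idx_single], !ed_only[idx_single],
                       admit1[idx_single], los1[idx_single], died[idx_single],
                       extra_dx = comp_code_of(complication[idx_single]))

  # Transfer origins: death/complication attributed downstream, not here.
  enc_origin <- mk_enc(idx_tr, home[idx_tr], !origin_ed[idx_tr],
                       admit1[idx_tr], los1[idx_tr], rep(FALSE, length(idx_tr)))

  idx_mid <- idx_tr  # first destination: final for unchained patients
  final_here <- !chained[idx_mid]
  enc_dest1 <- mk_enc(idx_mid, dest1[idx_mid], rep(TRUE, length(idx_mid)),
                      admit2[idx_mid], los2[idx_mid],
                      died[idx_mid] & final_here,
                      extra_dx = comp_code_of(complication[idx_mid] & final_here))

  enc_dest2 <- mk_enc(idx_ch, dest2[idx_ch], rep(TRUE, length(idx_ch)),
                      admit3[idx_ch], los3[idx_ch], died[idx_ch],
                      extra_dx = comp_code_of(complication[idx_ch]))

  encounters <- data.table::rbindlist(list(enc_single, enc_origin, enc_dest1, enc_dest2))
  op_flags <- encounters$op
  encounters[, op := NULL]
  data.table::setkey(encounters, patient_id, admit_date)

  # Planted transfer list (leg 1 for all transferred, leg 2 for chains),
  # with any_operation derived from the op indicators actually emitted.
  op_groups <- c("single", "origin", "dest1", "dest2")
  op_by <- split(op_flags, factor(
    rep(op_groups, c(nrow(enc_single), nrow(enc_origin), nrow(enc_dest1), nrow(enc_dest2))),
    levels = op_groups))
  op_origin <- setNames(op_by$origin, patient_id[idx_tr])
  op_dest1 <- setNames(op_by$dest1, patient_id[idx_mid])
  op_dest2 <- setNames(op_by$dest2, patient_id[idx_ch])

  leg1 <- data.table::data.table(
    patient_id = patient_id[idx_tr],
    origin = hid[home[idx_tr]],
    destination = hid[dest1[idx_tr]],
    transfer_type = ifelse(origin_ed[idx_tr], "ED-IP", "IP-IP"),
    any_operation = op_origin[patient_id[idx_tr]] | op_dest1[patient_id[idx_tr]]
  )
  leg2 <- data.table::data.table(
    patient_id = patient_id[idx_ch],
    origin = hid[dest1[idx_ch]],
    destination = hid[dest2[idx_ch]],
    transfer_type = rep("IP-IP", length(idx_ch)),
    any_operation = op_dest1[patient_id[idx_ch]] | op_dest2[patient_id[idx_ch]]
  )
  planted <- data.table::rbindlist(list(leg1, leg2))
  data.table::setkey(planted, patient_id, origin, destination)

  pair_counts <- planted[, .N, by = .(origin, destination)]
  data.table::setnames(pair_counts, "N", "n_transfers")

  egs_volume_tab <- table(factor(hid[home[!transferred & !ed_only & egs]], levels = hid))

  ground_truth <- list(
    hospitals = data.frame(hospital_id = hid, resource_score = rs, quality_effect = qe,
                           stringsAsFactors = FALSE),
    coefficients = list(
      baseline_death_logodds = config$baseline_death_logodds,
      baseline_complication_logodds = config$baseline_complication_logodds,
      age_effect = config$age_effect,
      sex_effect = config$sex_effect,
      comorbidity_effect = config$comorbidity_effect,
      complication_death_effect = config$complication_death_effect,
      age_center = 60
    ),
    transfers = planted[],
    pair_counts = pair_counts[],
    egs_volume = data.frame(hospital_id = hid, egs_volume = as.integer(egs_volume_tab),
                            stringsAsFactors = FALSE),
    patients = data.frame(
      patient_id = patient_id, age = age, sex = sex,
      comorbidity_index = comorb_index, egs = egs,
      egs_category = egs_category, transferred = transferred,
      chained = chained, ed_only = ed_only,
      treating_hospital = hid[treating],
      complication = complication, died = died,
      stringsAsFactors = FALSE
    )
  )

  structure(list(encounters = encounters[], ground_truth = ground_truth),
            class = "egs_simulation")
}

# Vectorized destination choice: within each origin-hospital group, draw
# from the other hospitals with weights exp(strength * resource_score).
sample_destinations <- function(origin_idx, active, resource_score, strength) {
  n_h <- length(resource_score)
  w <- exp(strength * (resource_score - max(resource_score)))
  dest <- rep(NA_integer_, length(origin_idx))
  for (h in unique(origin_idx[active])) {
    rows <- which(active & origin_idx == h)
    pool <- setdiff(seq_len(n_h), h)
    dest[rows] <- pool[sample.int(length(pool), length(rows), replace = TRUE, prob = w[pool])]
  }
  dest
}

#' Run the generator and write its outputs to disk
#'
#' @param config An [sim_config()] object.
#' @param out_dir Output directory (created if needed); writes
#'   `hospitals.csv`, `encounters.csv`, `ground_truth.json`.
#' @param codes,comorbidity Passed to [generate_encounters()].
#' @return Invisibly, the `egs_simulation` plus the hospital table.
#' @export
simulate_claims <- function(config, out_dir,
                            codes = read_code_set(egsnet_example("synthetic_code_set.json")),
                            comorbidity = read_comorbidity_table(egsnet_example("synthetic_comorbidity_weights.json"))) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hospitals <- generate_hospitals(config)
  sim <- generate_encounters(hospitals, config, codes, comorbidity)
  write.csv(hospitals, file.path(out_dir, "hospitals.csv"), row.names = FALSE)
  enc <- data.table::copy(sim$encounters)
  enc[, admit_date := format(admit_date, "%Y-%m-%d")]
  enc[, discharge_date := format(discharge_date, "%Y-%m-%d")]
  data.table::fwrite(enc, file.path(out_dir, "encounters.csv"))
  gt <- sim$ground_truth
  gt$transfers <- as.data.frame(gt$transfers)
  gt$pair_counts <- as.data.frame(gt$pair_counts)
  jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(list(hospitals = hospitals, simulation = sim))
}
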