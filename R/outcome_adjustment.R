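#' Weighted comorbidity index
#'
#' Elixhauser-style index: the sum of category weights over the *distinct*
#' comorbidity categories represented among a patient's diagnosis codes.
#' Multiple codes in one category count that category once; codes mapping to
#' no category contribute 0.
#'
#' @param dx_codes Character vector of diagnosis codes (or a single
#'   semicolon-joined string).
#' @param comorbidity An `egs_comorbidity_table` (see
#'   [read_comorbidity_table()]).
#' @return Integer-valued numeric scalar.
#' @export
comorbidity_index <- function(dx_codes, comorbidity) {
  if (length(dx_codes) == 1 && grepl(";", dx_codes %||% "")) {
    dx_codes <- split_codes(dx_codes)[[1]]
  }
  dx_codes <- norm_codes(as.character(dx_codes[!is.na(dx_codes)]))
  cats <- unique(comorbidity$category_of[dx_codes[dx_codes %in% names(comorbidity$category_of)]])
  sum(comorbidity$weights[cats])
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

#' Episode-level outcome frame
#'
#' One row per inpatient EGS episode with the covariates the risk models
#' adjust for (age, sex, weighted comorbidity index, EGS diagnosis
#' category), the outcome flags (in-hospital death; complication, flagged
#' from diagnosis codes; operation), and the treating hospital the outcome
#' is attributed to (the last inpatient hospital of the episode — the
#' standard profiling attribution for transferred patients).
#'
#' @param episodes An `egs_episodes` object (the *full* episode set,
#'   transferred and non-transferred).
#' @param codes An `egs_code_set`.
#' @param comorbidity An `egs_comorbidity_table`.
#' @return data.table: `episode_id`, `patient_id`, `hospital_id` (treating),
#'   `state`, `age`, `sex`, `comorbidity`, `egs_category`, `transferred`,
#'   `operated`, `complication`, `died`.
#' @export
episode_outcomes <- function(episodes, codes, comorbidity) {
  stopifnot(inherits(episodes, "egs_episodes"))
  ep <- episodes$episodes[egs == TRUE & has_ip == TRUE]
  dx <- split_codes(ep$dx_codes)
  long <- data.table::data.table(row = rep(seq_len(nrow(ep)), lengths(dx)),
                                 code = unlist(dx, use.names = FALSE))
  # EGS category: first matching code in episode dx order.
  egs_cat <- rep(NA_character_, nrow(ep))
  hits <- long[code %in% names(codes$egs_category_of)][!duplicated(row)]
  egs_cat[hits$row] <- unname(codes$egs_category_of[hits$code])
  # Weighted comorbidity index: distinct categories per episode.
  comorb <- numeric(nrow(ep))
  chits <- long[code %in% names(comorbidity$category_of)]
  if (nrow(chits) > 0) {
    chits[, category := unname(comorbidity$category_of[code])]
    csum <- unique(chits, by = c("row", "category"))[
      , .(s = sum(comorbidity$weights[category])), by = row]
    comorb[csum$row] <- csum$s
  }
  complication <- logical(nrow(ep))
  complication[unique(long$row[long$code %in% codes$complication_dx])] <- TRUE
  out <- data.table::data.table(
    episode_id = ep$episode_id,
    patient_id = ep$patient_id,
    hospital_id = ep$treating_hospital,
    state = ep$state,
    age = ep$first_age,
    sex = ep$sex,
    comorbidity = comorb,
    egs_category = egs_cat,
    transferred = ep$n_transfers >= 1L,
    operated = ep$any_operation,
    complication = complication,
    died = ep$died
  )
  out[]
}

#' Hospital EGS volume
#'
#' Annual EGS volume is the number of inpatient EGS episodes treated at the
#' hospital that did *not* involve an interhospital transfer.
#'
#' @param outcome_frame From [episode_outcomes()].
#' @param hospital_ids Hospitals to report (default: those in the frame).
#' @return Named integer vector of volumes (0 for hospitals with none).
#' @export
compute_egs_volume <- function(outcome_frame, hospital_ids = NULL) {
  f <- as.data.table(outcome_frame)
  if (is.null(hospital_ids)) hospital_ids <- sort(unique(f$hospital_id))
  counts <- f[transferred == FALSE, .N, by = hospital_id]
  out <- setNames(integer(length(hospital_ids)), hospital_ids)
  out[counts$hospital_id[counts$hospital_id %in% hospital_ids]] <-
    counts$N[counts$hospital_id %in% hospital_ids]
  out
}

#' Failure-to-rescue flag for one episode
#'
#' Failure to rescue is in-hospital death following a complication among
#' *operated* episodes. Nonoperatively managed episodes are out of scope
#' (`NA`: not applicable); operated episodes without a complication are
#' excluded from the denominator (`NA` as well, tallied separately by
#' callers via the `complication` flag).
#'
#' @param operated,complication,died Logical (vectors).
#' @return Logical vector: `TRUE` (death after complication), `FALSE`
#'   (complication survived), `NA` (not in the FTR denominator).
#' @export
flag_failure_to_rescue <- function(operated, complication, died) {
  ifelse(operated & complication, died, NA)
}

#' Fit a patient-level logistic risk model
#'
#' Episode-level logistic regression of the outcome on age (linear, years),
#' sex, the weighted comorbidity index, and EGS diagnosis-category
#' indicators. For `outcome = "death"` the eligible population is all
#' inpatient EGS episodes; for `"ftr"` it is operated episodes with a
#' complication (death given complication). Receipt of an operation is
#' deliberately *not* adjusted for — it is potentially endogenous to
#' hospital quality.
#'
#' @param outcome_frame From [episode_outcomes()].
#' @param outcome `"death"` or `"ftr"`.
#' @param min_n Minimum eligible episodes (default 50).
#' @return A list of class `egs_risk_model`: the `glm` fit, the eligible
#'   frame with an `outcome` column, the `overall_rate`, and `outcome`.
#' @export
fit_risk_model <- function(outcome_frame, outcome = c("death", "ftr"), min_n = 50) {
  outcome <- match.arg(outcome)
  f <- as.data.table(outcome_frame)
  if (outcome == "death") {
    eligible <- f
  } else {
    eligible <- f[operated == TRUE & complication == TRUE]
  }
  if (nrow(eligible) < min_n) {
    stop("risk model for '", outcome, "' needs >= ", min_n,
         " eligible episodes; got ", nrow(eligible))
  }
  eligible <- data.table::copy(eligible)
  eligible[, outcome := as.integer(died)]
  if (length(unique(eligible$outcome)) < 2) {
    stop("risk model for '", outcome, "' is degenerate: only one outcome class present")
  }
  rhs <- c("age", "comorbidity")
  if (length(unique(eligible$sex)) > 1) rhs <- c(rhs, "sex")
  if (sum(!is.na(unique(eligible$egs_category))) > 1) rhs <- c(rhs, "egs_category")
  fit <- glm(as.formula(paste("outcome ~", paste(rhs, collapse = " + "))),
             family = binomial(), data = eligible)
  if (!fit$converged) stop("risk model for '", outcome, "' did not converge ",
                           "(possible complete separation)")
  if (any(abs(coef(fit)[-1]) > 15, na.rm = TRUE)) {
    stop("risk model for '", outcome, "' shows runaway coefficients ",
         "(possible complete separation)")
  }
  eligible[, expected := predict(fit, newdata = eligible, type = "response")]
  structure(list(fit = fit, eligible = eligible[],
                 overall_rate = mean(eligible$outcome), outcome = outcome),
            class = "egs_risk_model")
}

#' Risk-adjusted hospital rates by indirect standardization
#'
#' For each hospital: adjusted rate = (observed events / expected events
#' under the pooled risk model) x overall rate. Hospitals with no eligible
#' episodes get `NA`; a hospital with observed events but zero expected
#' events is undefined (`NA`, with a warning).
#'
#' @param model An `egs_risk_model`.
#' @param hospital_ids Hospitals to report (default: those with eligible
#'   episodes).
#' @return data.frame: `hospital_id`, `n_eligible`, `observed`, `expected`,
#'   `adjusted_rate`.
#' @export
hospital_adjusted_rate <- function(model, hospital_ids = NULL) {
  stopifnot(inherits(model, "egs_risk_model"))
  agg <- model$eligible[, .(n_eligible = .N, observed = sum(outcome),
                            expected = sum(expected)), by = hospital_id]
  if (is.null(hospital_ids)) hospital_ids <- sort(agg$hospital_id)
  out <- data.frame(hospital_id = hospital_ids, stringsAsFactors = FALSE)
  m <- match(out$hospital_id, agg$hospital_id)
  out$n_eligible <- ifelse(is.na(m), 0L, agg$n_eligible[m])
  out$observed <- ifelse(is.na(m), NA_integer_, agg$observed[m])
  out$expected <- ifelse(is.na(m), NA_real_, agg$expected[m])
  bad <- !is.na(out$expected) & out$expected == 0 & out$observed > 0
  if (any(bad)) {
    warning(sum(bad), " hospital(s) with observed events but zero expected events; ",
            "adjusted rate undefined")
  }
  out$adjusted_rate <- ifelse(
    out$n_eligible > 0 & out$expected > 0,
    out$observed / out$expected * model$overall_rate,
    NA_real_
  )
  out
}

#' Assign quartile labels
#'
#' Quartile 1 is the lowest; cut points are the 25th/50th/75th empirical
#' percentiles, and tied values fall in the lower quartile. `NA` values get
#' no label.
#'
#' @param values Numeric vector (may contain `NA`).
#' @return Integer vector in 1..4 (NA preserved).
#' @export
assign_quartiles <- function(values) {
  defined <- values[!is.na(values)]
  if (length(defined) < 4) stop("quartile assignment requires >= 4 defined values")
  cuts <- quantile(defined, c(0.25, 0.5, 0.75), names = FALSE)
  if (length(unique(defined)) == 1) {
    warning("all values identical; every hospital assigned quartile 1")
  }
  q <- 1L + (values > cuts[1]) + (values > cuts[2]) + (values > cuts[3])
  as.integer(q)
}

#' Hospital-level outcome table
#'
#' Combines EGS volume, risk-adjusted in-hospital mortality, risk-adjusted
#' failure to rescue, and their quartile labels (quartile 1 = lowest) into
#' one row per hospital.
#'
#' @param outcome_frame From [episode_outcomes()].
#' @param hospital_ids Hospitals to report (default: those in the frame).
#' @param min_n Passed to [fit_risk_model()].
#' @return data.frame of class `egs_hospital_outcomes` with the fitted
#'   models attached as attributes `death_model` and `ftr_model`.
#' @export
hospital_outcomes <- function(outcome_frame, hospital_ids = NULL, min_n = 50) {
  f <- as.data.table(outcome_frame)
  if (is.null(hospital_ids)) hospital_ids <- sort(unique(f$hospital_id))
  vol <- compute_egs_volume(f, hospital_ids)
  death_model <- fit_risk_model(f, "death", min_n = min_n)
  death_rates <- hospital_adjusted_rate(death_model, hospital_ids)
  ftr_model <- tryCatch(fit_risk_model(f, "ftr", min_n = min_n), error = function(e) NULL)
  ftr_rates <- if (!is.null(ftr_model)) hospital_adjusted_rate(ftr_model, hospital_ids) else NULL

  out <- data.frame(
    hospital_id = hospital_ids,
    egs_volume = as.integer(vol[hospital_ids]),
    adj_mortality = death_rates$adjusted_rate,
    adj_ftr = if (!is.null(ftr_rates)) ftr_rates$adjusted_rate else NA_real_,
    stringsAsFactors = FALSE
  )
  out$volume_quartile <- assign_quartiles(out$egs_volume)
  out$mortality_quartile <- assign_quartiles(out$adj_mortality)
  out$ftr_quartile <- if (sum(!is.na(out$adj_ftr)) >= 4) assign_quartiles(out$adj_ftr) else NA_integer_
  attr(out, "death_model") <- death_model
  attr(out, "ftr_model") <- ftr_model
  class(out) <- c("egs_hospital_outcomes", "data.frame")
  out
}
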