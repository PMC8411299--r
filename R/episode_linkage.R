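#' Temporal adjacency of two encounters
#'
#' Two encounters of one patient are temporally adjacent — the defining rule
#' for an interhospital transfer — when the discharge date of the first is
#' on the same day as, or the day before, the admission date of the second,
#' and the two encounters occurred at different hospitals.
#'
#' @param first,second Single-row data.frames (or lists) with at least
#'   `patient_id`, `hospital_id`, `admit_date`, `discharge_date`.
#' @return `TRUE` or `FALSE`.
#' @export
is_temporally_adjacent <- function(first, second) {
  if (!identical(as.character(first$patient_id), as.character(second$patient_id))) {
    stop("adjacency is defined only for encounters of the same patient")
  }
  gap <- as.integer(as.Date(second$admit_date) - as.Date(first$discharge_date))
  gap %in% c(0L, 1L) &&
    !identical(as.character(first$hospital_id), as.character(second$hospital_id))
}

#' Link encounters into episodes of care and extract transfers
#'
#' Per patient, encounters are sorted by admission date (ties broken by
#' discharge date, then hospital ID) and maximal chains of date-adjacent
#' encounters (gap of 0 or 1 days between one discharge and the next
#' admission) form episodes. Within an episode, every adjacent pair at
#' *different* hospitals whose downstream portion reaches an inpatient
#' encounter yields one transfer event, typed by the origin encounter's
#' setting (`ED-IP` or `IP-IP`); an ED-to-ED hop that continues into an
#' inpatient admission at the second hospital is therefore typed `ED-IP`.
#' Same-hospital date-adjacent encounters (e.g. an ED visit followed by
#' admission at the same hospital) stay in the episode but produce no
#' transfer. An episode carries EGS status if and only if at least one
#' *inpatient* encounter carries an EGS diagnosis code.
#'
#' Temporally overlapping encounters (the next admission strictly before the
#' current discharge, at a different hospital) are data anomalies: the pair
#' is not linked and is reported in the `anomalies` table.
#'
#' @param encounters data.frame/data.table in the claims schema
#'   (`patient_id`, `hospital_id`, `state`, `setting` in ED/IP,
#'   `admit_date`, `discharge_date`, `age`, `sex`, `dx_codes`, `proc_codes`,
#'   `died`); dates may be `Date` or ISO-8601 strings.
#' @param codes An `egs_code_set` (see [read_code_set()]).
#' @return A list of class `egs_episodes`: `encounters` (annotated with
#'   `episode_id`, `seq_in_episode`), `episodes` (one row per episode:
#'   patient, first-encounter age, EGS flag, death flag, transfer count,
#'   treating hospital = last inpatient hospital), `transfers` (origin,
#'   destination, transfer_type, any_operation, patient_id, episode_id), and
#'   `anomalies`.
#' @export
build_episodes <- function(encounters, codes) {
  enc <- as.data.table(encounters)
  required <- c("patient_id", "hospital_id", "setting", "admit_date",
                "discharge_date", "age", "dx_codes", "proc_codes", "died")
  missing_cols <- setdiff(required, names(enc))
  if (length(missing_cols) > 0) {
    stop("encounter table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  enc <- data.table::copy(enc)
  enc[, admit_date := parse_dates(admit_date, "admit_date")]
  enc[, discharge_date := parse_dates(discharge_date, "discharge_date")]
  if (any(enc$discharge_date < enc$admit_date)) {
    bad <- which(enc$discharge_date < enc$admit_date)
    stop("discharge before admission at row(s): ", paste(head(bad, 5), collapse = ", "))
  }
  if (!all(enc$setting %in% c("ED", "IP"))) {
    stop("setting must be 'ED' (ED-only) or 'IP' (inpatient)")
  }

  data.table::setorder(enc, patient_id, admit_date, discharge_date, hospital_id)

  # Chain scan: an episode break occurs at a new patient or a date gap
  # outside {0, 1}. Overlaps at a different hospital also break the chain
  # and are flagged.
  n <- nrow(enc)
  same_patient <- c(FALSE, enc$patient_id[-1] == enc$patient_id[-n])
  gap <- c(NA_integer_, as.integer(enc$admit_date[-1] - enc$discharge_date[-n]))
  diff_hosp <- c(FALSE, enc$hospital_id[-1] != enc$hospital_id[-n])
  linked <- same_patient & !is.na(gap) & gap >= 0L & gap <= 1L
  overlap <- same_patient & !is.na(gap) & gap < 0L & diff_hosp
  enc[, episode_id := cumsum(!linked)]
  ep_start <- which(!linked)
  enc[, seq_in_episode := seq_len(n) - rep(ep_start, diff(c(ep_start, n + 1L))) + 1L]

  anomalies <- if (any(overlap)) {
    idx <- which(overlap)
    data.table::data.table(
      patient_id = enc$patient_id[idx],
      hospital_id_first = enc$hospital_id[idx - 1L],
      hospital_id_second = enc$hospital_id[idx],
      discharge_first = enc$discharge_date[idx - 1L],
      admit_second = enc$admit_date[idx],
      reason = "overlapping encounters at different hospitals"
    )
  } else {
    data.table::data.table(patient_id = character(0), hospital_id_first = character(0),
                           hospital_id_second = character(0),
                           discharge_first = as.Date(character(0)),
                           admit_second = as.Date(character(0)), reason = character(0))
  }

  # EGS status: an inpatient encounter carrying >= 1 EGS diagnosis code.
  dx <- split_codes(enc$dx_codes)
  dx_long <- data.table::data.table(
    row = rep(seq_len(n), lengths(dx)),
    episode_id = rep(enc$episode_id, lengths(dx)),
    code = unlist(dx, use.names = FALSE)
  )
  enc_has_egs <- logical(n)
  enc_has_egs[unique(dx_long$row[dx_long$code %in% codes$egs_dx_flat])] <- TRUE
  enc[, is_ip := setting == "IP"]
  op_flag <- flag_operation(enc, codes)

  # Transfer events: within-episode adjacent cross-hospital pairs whose
  # downstream portion (second encounter onward) reaches an inpatient stay.
  # ip_downstream[i]: an inpatient encounter exists at or after row i within
  # the episode (computed from the episode's last inpatient row index).
  n_ep <- enc$episode_id[n]
  last_ip <- integer(n_ep)
  ip_rows <- which(enc$is_ip)
  last_ip[enc$episode_id[ip_rows]] <- ip_rows  # ascending, so max survives
  enc[, ip_downstream := last_ip[episode_id] >= seq_len(n)]
  pair_second <- which(linked & diff_hosp & enc$ip_downstream)
  transfers <- data.table::data.table(
    patient_id = enc$patient_id[pair_second - 1L],
    episode_id = enc$episode_id[pair_second - 1L],
    origin = enc$hospital_id[pair_second - 1L],
    destination = enc$hospital_id[pair_second],
    transfer_type = ifelse(enc$is_ip[pair_second - 1L], "IP-IP", "ED-IP"),
    any_operation = op_flag[pair_second - 1L] | op_flag[pair_second]
  )

  enc[, `:=`(egs_enc = enc_has_egs, op_enc = op_flag)]
  if (!"sex" %in% names(enc)) enc[, sex := NA_character_]
  if (!"state" %in% names(enc)) enc[, state := NA_character_]
  episodes <- enc[, .(
    patient_id = patient_id[1L],
    first_age = age[1L],
    sex = sex[1L],
    n_encounters = .N,
    egs = any(is_ip & egs_enc),
    has_ip = any(is_ip),
    died = any(died == 1L),
    any_operation = any(op_enc),
    treating_idx = if (any(is_ip)) max(which(is_ip)) else .N
  ), by = episode_id]
  first_rows <- which(!duplicated(enc$episode_id))
  treating_rows <- first_rows + episodes$treating_idx - 1L
  episodes[, treating_hospital := enc$hospital_id[treating_rows]]
  episodes[, state := enc$state[treating_rows]]
  episodes[, treating_idx := NULL]
  ep_dx <- dx_long[, .(dx_codes = paste(unique(code), collapse = ";")), by = episode_id]
  episodes[, dx_codes := ""]
  episodes[ep_dx, dx_codes := i.dx_codes, on = "episode_id"]
  episodes[, n_transfers := 0L]
  if (nrow(transfers) > 0) {
    tcount <- transfers[, .N, by = episode_id]
    episodes[tcount, n_transfers := i.N, on = "episode_id"]
  }

  enc[, c("is_ip", "ip_downstream", "egs_enc", "op_enc") := NULL]
  structure(list(encounters = enc[], episodes = episodes[],
                 transfers = transfers[], anomalies = anomalies[]),
            class = "egs_episodes")
}

parse_dates <- function(x, what) {
  if (inherits(x, "Date")) return(x)
  out <- as.Date(as.character(x), format = "%Y-%m-%d")
  if (anyNA(out)) {
    bad <- which(is.na(out))
    stop("unparseable ", what, " at row(s): ", paste(head(bad, 5), collapse = ", "))
  }
  out
}

#' Flag operations/procedures by code-set membership
#'
#' @param encounter A single encounter (list/one-row data.frame) or an
#'   encounter table; the `proc_codes` field is semicolon-joined.
#' @param codes An `egs_code_set`.
#' @return Logical (vector): any procedure code in `codes$operation_proc`.
#' @export
flag_operation <- function(encounter, codes) {
  if (length(codes$operation_proc) == 0) stop("operation_proc code set is empty")
  pc <- split_codes(if (is.data.frame(encounter)) encounter$proc_codes else encounter$proc_codes)
  vapply(pc, function(v) any(v %in% codes$operation_proc), logical(1))
}

#' Restrict to the adult EGS transfer cohort
#'
#' Keeps episodes that (1) carry EGS status (an EGS diagnosis on an
#' inpatient encounter), (2) involve at least one interhospital transfer,
#' and (3) belong to a patient aged 18 or older at the first encounter.
#'
#' @param episodes An `egs_episodes` object from [build_episodes()].
#' @param min_age Minimum age in years at the first encounter (default 18,
#'   inclusive).
#' @return An `egs_episodes` object restricted to the cohort; the
#'   `transfers` table is restricted to retained episodes. An `exclusions`
#'   attribute tallies episodes removed by each rule (applied in sequence).
#' @export
filter_transfer_cohort <- function(episodes, min_age = 18) {
  stopifnot(inherits(episodes, "egs_episodes"))
  ep <- episodes$episodes
  keep_egs <- ep$egs
  keep_tr <- ep$n_transfers >= 1L
  keep_age <- ep$first_age >= min_age
  keep <- keep_egs & keep_tr & keep_age
  exclusions <- c(
    not_egs = sum(!keep_egs),
    no_transfer = sum(keep_egs & !keep_tr),
    under_age = sum(keep_egs & keep_tr & !keep_age)
  )
  ids <- ep$episode_id[keep]
  out <- list(
    encounters = episodes$encounters[episode_id %in% ids],
    episodes = ep[keep],
    transfers = episodes$transfers[episode_id %in% ids],
    anomalies = episodes$anomalies
  )
  structure(out, class = "egs_episodes", exclusions = exclusions)
}
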