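#' Run the full transfer-network analysis pipeline
#'
#' Orchestrates simulate -> link -> network -> outcomes -> analyze on
#' synthetic claims (or on user-supplied encounter/hospital CSVs), writing
#' every stage's tabular outputs plus a JSON manifest with content hashes,
#' per-stage row counts and exclusion tallies. All randomness flows from the
#' single seed in the simulation config, so identical config and seed give
#' byte-identical outputs.
#'
#' @param config An [sim_config()] object (ignored when `encounters_csv` is
#'   supplied).
#' @param out_dir Output directory (created if needed).
#' @param stages Character subset of
#'   `c("simulate", "link", "network", "outcomes", "analyze")` to run,
#'   in pipeline order; later stages require earlier ones' outputs in
#'   `out_dir`.
#' @param encounters_csv,hospitals_csv Optional paths to pre-existing input
#'   tables; when given, the simulate stage is skipped.
#' @param codes_path,comorbidity_path Paths to the code-set and comorbidity
#'   JSONs (defaults: the packaged synthetic fixtures).
#' @param convention Degree-centrality convention, `"weighted"` or
#'   `"binary"`.
#' @param posthoc Post hoc method for the ANOVA stage.
#' @param min_age Cohort minimum age (default 18).
#' @return Invisibly, the manifest list (also written to `manifest.json`).
#' @export
run_pipeline <- function(config = sim_config(), out_dir,
                         stages = c("simulate", "link", "network", "outcomes", "analyze"),
                         encounters_csv = NULL, hospitals_csv = NULL,
                         codes_path = egsnet_example("synthetic_code_set.json"),
                         comorbidity_path = egsnet_example("synthetic_comorbidity_weights.json"),
                         convention = "weighted", posthoc = "tukey", min_age = 18) {
  all_stages <- c("simulate", "link", "network", "outcomes", "analyze")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  codes <- read_code_set(codes_path)
  comorbidity <- read_comorbidity_table(comorbidity_path)
  manifest <- list(seed = config$seed, convention = convention,
                   stages = list(), files = list())
  t_stage <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- expr
    list(value = v, seconds = round(proc.time()[["elapsed"]] - t0, 3))
  }
  record <- function(name, seconds, counts) {
    manifest$stages[[name]] <<- c(list(completed = TRUE, seconds = seconds), counts)
  }

  run <- function() {
    if ("simulate" %in% stages) {
      st <- t_stage(simulate_claims(config, out_dir, codes, comorbidity))
      record("simulate", st$seconds, list(
        n_hospitals = nrow(st$value$hospitals),
        n_encounters = nrow(st$value$simulation$encounters),
        n_planted_transfers = nrow(st$value$simulation$ground_truth$transfers)))
    }
    enc_path <- encounters_csv %||chr% file.path(out_dir, "encounters.csv")
    hosp_path <- hospitals_csv %||chr% file.path(out_dir, "hospitals.csv")

    if ("link" %in% stages) {
      st <- t_stage({
        enc <- data.table::fread(enc_path, colClasses = list(character = c("dx_codes", "proc_codes")))
        episodes <- build_episodes(enc, codes)
        cohort <- filter_transfer_cohort(episodes, min_age = min_age)
        tr <- cohort$transfers
        data.table::fwrite(tr[, .(origin, destination, transfer_type, any_operation, patient_id)],
                           file.path(out_dir, "transfers.csv"))
        data.table::fwrite(episodes$episodes, file.path(out_dir, "episodes.csv"))
        data.table::fwrite(episodes$anomalies, file.path(out_dir, "anomalies.csv"))
        list(episodes = episodes, cohort = cohort)
      })
      record("link", st$seconds, list(
        n_encounters_in = nrow(st$value$episodes$encounters),
        n_episodes = nrow(st$value$episodes$episodes),
        n_cohort_episodes = nrow(st$value$cohort$episodes),
        n_transfers = nrow(st$value$cohort$transfers),
        n_anomalies = nrow(st$value$episodes$anomalies),
        exclusions = as.list(attr(st$value$cohort, "exclusions"))))
      assign("link_result", st$value, envir = env)
    }

    if ("network" %in% stages) {
      st <- t_stage({
        tr <- data.table::fread(file.path(out_dir, "transfers.csv"))
        hosp <- read.csv(hosp_path, stringsAsFactors = FALSE)
        nets <- build_all_networks(tr, nodes = sort(unique(c(tr$origin, tr$destination))))
        cent <- lapply(nets, function(nw) {
          rec <- log_transform_ratios(degree_centralities(nw, convention = convention))
          data.table::fwrite(nw$edges, file.path(out_dir, paste0("edges_", nw$label, ".tsv")), sep = "\t")
          data.table::fwrite(rec, file.path(out_dir, paste0("centrality_", nw$label, ".csv")))
          rec
        })
        list(networks = nets, centrality = cent)
      })
      record("network", st$seconds, list(
        n_nodes = length(st$value$networks$all$nodes),
        edge_weight_totals = lapply(st$value$networks, function(nw) sum(nw$edges$weight))))
      assign("network_result", st$value, envir = env)
    }

    if ("outcomes" %in% stages) {
      st <- t_stage({
        link_result <- get0("link_result", envir = env)
        if (is.null(link_result)) {
          enc <- data.table::fread(enc_path, colClasses = list(character = c("dx_codes", "proc_codes")))
          link_result <- list(episodes = build_episodes(enc, codes))
        }
        # Adults only, as in the transfer cohort, but both transferred and
        # non-transferred episodes: volume and outcome denominators.
        frame <- episode_outcomes(link_result$episodes, codes, comorbidity)
        frame <- frame[age >= min_age]
        ho <- hospital_outcomes(frame)
        data.table::fwrite(ho, file.path(out_dir, "hospital_outcomes.csv"))
        dm <- attr(ho, "death_model")
        jsonlite::write_json(
          list(death = as.list(coef(dm$fit)), death_overall_rate = dm$overall_rate,
               ftr = if (!is.null(attr(ho, "ftr_model"))) as.list(coef(attr(ho, "ftr_model")$fit)),
               ftr_overall_rate = if (!is.null(attr(ho, "ftr_model"))) attr(ho, "ftr_model")$overall_rate),
          file.path(out_dir, "risk_models.json"), auto_unbox = TRUE, digits = NA)
        ho
      })
      record("outcomes", st$seconds, list(n_hospitals = nrow(st$value)))
      assign("outcomes_result", st$value, envir = env)
    }

    if ("analyze" %in% stages) {
      st <- t_stage({
        hosp <- read.csv(hosp_path, stringsAsFactors = FALSE)
        ho <- get0("outcomes_result", envir = env)
        if (is.null(ho)) {
          ho <- read.csv(file.path(out_dir, "hospital_outcomes.csv"), stringsAsFactors = FALSE)
        }
        cent <- get0("network_result", envir = env)$centrality
        if (is.null(cent)) {
          cent <- setNames(lapply(network_labels(), function(l) {
            read.csv(file.path(out_dir, paste0("centrality_", l, ".csv")), stringsAsFactors = FALSE)
          }), network_labels())
        }
        frames <- lapply(cent, analysis_frame, hospitals = hosp, outcomes = ho)
        main <- frames$all
        anovas <- lapply(characteristic_blocks(), function(ch) {
          tryCatch(anova_with_pairwise(main, ch, method = posthoc),
                   error = function(e) list(skipped = TRUE, reason = conditionMessage(e)))
        })
        names(anovas) <- characteristic_blocks()
        primary <- clustered_regression(main)
        sensitivity <- run_sensitivity_suite(frames[c("ed_ip", "ip_ip", "op", "no_op")])
        res <- list(
          anova = lapply(anovas, unclass_result),
          regression = unclass_result(primary),
          sensitivity = lapply(sensitivity, unclass_result),
          dropped = as.list(attr(main, "dropped"))
        )
        jsonlite::write_json(res, file.path(out_dir, "inference.json"),
                             auto_unbox = TRUE, digits = NA, dataframe = "columns")
        coef_rows <- do.call(rbind, lapply(c(list(all = primary), sensitivity), function(r) {
          if (isTRUE(r$skipped)) return(NULL)
          cbind(network_label = r$network_label, r$coefficients)
        }))
        write.csv(coef_rows, file.path(out_dir, "regression_coefficients.csv"), row.names = FALSE)
        list(frames = frames, anovas = anovas, regression = primary, sensitivity = sensitivity)
      })
      record("analyze", st$seconds, list(
        n_hospitals_analyzed = nrow(st$value$frames$all),
        n_clusters = st$value$regression$n_clusters))
      assign("analyze_result", st$value, envir = env)
    }
  }

  env <- new.env()
  ok <- tryCatch({ run(); TRUE }, error = function(e) {
    manifest$error <<- conditionMessage(e)
    FALSE
  })

  files <- setdiff(list.files(out_dir), "manifest.json")
  hashes <- tools::md5sum(file.path(out_dir, files))
  manifest$files <- as.list(setNames(unname(hashes), files))
  manifest$completed <- ok
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

`%||chr%` <- function(a, b) if (is.null(a)) b else a

# Strip non-serializable members (model fits, covariance) for JSON output.
unclass_result <- function(r) {
  if (isTRUE(r$skipped)) return(r)
  r <- unclass(r)
  r$fit <- NULL
  r$vcov <- NULL
  r
}
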