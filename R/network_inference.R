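#' Hospital characteristic blocks used in the association analyses
#'
#' @return Character vector naming the eight blocks of the multivariable
#'   model: total-bed category, ICU-bed category, teaching status, trauma
#'   level, fellowship, EGS-volume quartile, mortality quartile, FTR
#'   quartile.
#' @export
characteristic_blocks <- function() {
  c("bed_category", "icu_category", "teaching_status", "trauma_level",
    "fellowship", "volume_quartile", "mortality_quartile", "ftr_quartile")
}

#' Build the hospital-level analysis frame
#'
#' Joins centrality records, hospital attributes, and hospital outcomes on
#' hospital ID; categorizes bed counts (<100, 100-250, >250) and ICU beds
#' (0-10, 11-25, >25); turns quartiles and attributes into ordered factors
#' with the lowest-resource level as reference; and restricts to hospitals
#' with a defined log centrality ratio and complete characteristics
#' (listwise deletion, tallied in the `dropped` attribute).
#'
#' @param centrality An `egs_centrality` data.frame (after
#'   [log_transform_ratios()]).
#' @param hospitals Hospital attribute table (`hospital_id`, `state`,
#'   `total_beds`, `icu_beds`, `teaching_status`, `trauma_level`,
#'   `fellowship`).
#' @param outcomes An `egs_hospital_outcomes` data.frame, or `NULL` to build
#'   a frame with resource blocks only (no volume/outcome quartiles).
#' @param blocks Characteristic blocks to require/keep (default all eight).
#' @return data.frame of class `egs_analysis_frame`: `hospital_id`,
#'   `log_centrality_ratio`, `state`, the block factors, `network_label`.
#' @export
analysis_frame <- function(centrality, hospitals, outcomes,
                           blocks = characteristic_blocks()) {
  if (!"log_centrality_ratio" %in% names(centrality)) {
    centrality <- log_transform_ratios(centrality)
  }
  df <- merge(centrality[, c("hospital_id", "log_centrality_ratio", "network_label")],
              hospitals, by = "hospital_id")
  if (is.null(outcomes)) {
    blocks <- setdiff(blocks, c("volume_quartile", "mortality_quartile", "ftr_quartile"))
    df$volume_quartile <- df$mortality_quartile <- df$ftr_quartile <- NA_integer_
  } else {
    df <- merge(df, as.data.frame(outcomes)[, c("hospital_id", "volume_quartile",
                                                "mortality_quartile", "ftr_quartile")],
                by = "hospital_id", all.x = TRUE)
  }
  df$bed_category <- cut(df$total_beds, breaks = c(-Inf, 99.5, 250.5, Inf),
                         labels = c("<100", "100-250", ">250"))
  df$icu_category <- cut(df$icu_beds, breaks = c(-Inf, 10.5, 25.5, Inf),
                         labels = c("0-10", "11-25", ">25"))
  df$teaching_status <- factor(df$teaching_status, levels = c("nonteaching", "small", "large"))
  df$trauma_level <- factor(df$trauma_level, levels = c("none", "3", "2", "1"))
  df$fellowship <- factor(ifelse(df$fellowship, "yes", "no"), levels = c("no", "yes"))
  for (q in c("volume_quartile", "mortality_quartile", "ftr_quartile")) {
    df[[q]] <- factor(df[[q]], levels = 1:4, labels = paste0("Q", 1:4))
  }
  n_in <- nrow(df)
  no_outcome <- is.na(df$log_centrality_ratio)
  df <- df[!no_outcome, , drop = FALSE]
  complete <- complete.cases(df[, blocks, drop = FALSE])
  dropped <- c(undefined_log_ratio = sum(no_outcome),
               incomplete_characteristics = sum(!complete))
  df <- df[complete, c("hospital_id", "log_centrality_ratio", "state",
                       blocks, "network_label")]
  rownames(df) <- NULL
  attr(df, "dropped") <- dropped
  class(df) <- c("egs_analysis_frame", "data.frame")
  df
}

#' One-way ANOVA with post hoc pairwise contrasts
#'
#' Compares mean log centrality ratio across the levels of one hospital
#' characteristic: a one-way ANOVA F test plus all pairwise group
#' differences, oriented as (later level - earlier level) so that
#' higher-resource minus reference is positive when resources attract
#' transfers. The default post hoc method is Tukey's HSD (simultaneous 95%
#' CIs); unadjusted and Bonferroni-adjusted pairwise t contrasts (pooled
#' variance) are available.
#'
#' @param frame An `egs_analysis_frame`.
#' @param characteristic One column of [characteristic_blocks()].
#' @param method `"tukey"` (default), `"none"`, or `"bonferroni"`.
#' @param conf_level Confidence level (default 0.95).
#' @return A list of class `egs_anova`: `characteristic`, `f_statistic`,
#'   `df`, `p_value`, `group_means` and a `pairwise` data.frame
#'   (`contrast`, `difference`, `conf_low`, `conf_high`, `p_value`),
#'   `method`, `n`.
#' @export
anova_with_pairwise <- function(frame, characteristic,
                                method = c("tukey", "none", "bonferroni"),
                                conf_level = 0.95) {
  method <- match.arg(method)
  stopifnot(characteristic %in% names(frame))
  g <- droplevels(factor(frame[[characteristic]]))
  y <- frame$log_centrality_ratio
  keep <- !is.na(g) & !is.na(y)
  g <- g[keep]; y <- y[keep]
  small <- names(which(table(g) < 2))
  if (length(small) > 0) {
    warning("dropping group(s) with < 2 observations: ", paste(small, collapse = ", "))
    keep2 <- !g %in% small
    g <- droplevels(g[keep2]); y <- y[keep2]
  }
  if (nlevels(g) < 2) stop("ANOVA needs >= 2 groups with >= 2 observations")
  d <- data.frame(y = y, g = g)
  fit <- aov(y ~ g, data = d)
  an <- anova(fit)

  lev <- levels(g)
  means <- tapply(y, g, mean)
  ns <- tapply(y, g, length)
  mse <- an[["Mean Sq"]][2]
  df_resid <- an[["Df"]][2]
  pairs <- utils::combn(seq_along(lev), 2)
  contrast <- paste(lev[pairs[2, ]], "-", lev[pairs[1, ]])
  diff <- means[pairs[2, ]] - means[pairs[1, ]]
  se <- sqrt(mse * (1 / ns[pairs[2, ]] + 1 / ns[pairs[1, ]]))
  k <- nlevels(g)
  m <- ncol(pairs)
  if (method == "tukey") {
    crit <- ptukey_crit(conf_level, k, df_resid)
    p <- ptukey(abs(diff / se) * sqrt(2), k, df_resid, lower.tail = FALSE)
  } else {
    alpha <- (1 - conf_level) / if (method == "bonferroni") m else 1
    crit <- qt(1 - alpha / 2, df_resid)
    p <- 2 * pt(abs(diff / se), df_resid, lower.tail = FALSE)
    if (method == "bonferroni") p <- pmin(1, p * m)
  }
  pairwise <- data.frame(
    contrast = contrast,
    difference = as.numeric(diff),
    conf_low = as.numeric(diff - crit * se),
    conf_high = as.numeric(diff + crit * se),
    p_value = as.numeric(p),
    stringsAsFactors = FALSE
  )
  structure(list(
    characteristic = characteristic,
    f_statistic = an[["F value"]][1],
    df = c(an[["Df"]][1], df_resid),
    p_value = an[["Pr(>F)"]][1],
    group_means = data.frame(level = lev, n = as.integer(ns), mean = as.numeric(means),
                             sd = as.numeric(tapply(y, g, sd))),
    pairwise = pairwise,
    method = method,
    n = length(y)
  ), class = "egs_anova")
}

ptukey_crit <- function(conf_level, k, df) {
  stats::qtukey(conf_level, k, df) / sqrt(2)
}

#' Multivariable regression with state-clustered robust inference
#'
#' OLS of log centrality ratio on all characteristic blocks simultaneously,
#' with a cluster-robust (sandwich) covariance clustered on state. The
#' finite-cluster correction is the standard
#' `G/(G-1) * (N-1)/(N-K)` scaling, and confidence intervals and p-values
#' use the t distribution with G - 1 degrees of freedom — the conventional
#' small-cluster treatment. Per-block partial F tests are Wald tests on the
#' clustered covariance with (q, G - 1) degrees of freedom.
#'
#' @param frame An `egs_analysis_frame`.
#' @param blocks Blocks to include (default: those present in the frame).
#' @param cluster Cluster variable name (default `"state"`).
#' @param conf_level Confidence level (default 0.95).
#' @return A list of class `egs_regression`: `coefficients` data.frame
#'   (`term`, `estimate`, `std_error`, `statistic`, `p_value`, `conf_low`,
#'   `conf_high`), `partial_f` data.frame (`block`, `f_statistic`, `df1`,
#'   `df2`, `p_value`), `n`, `n_clusters`, `vcov`, `fit`,
#'   `network_label`.
#' @export
clustered_regression <- function(frame, blocks = NULL, cluster = "state",
                                 conf_level = 0.95) {
  if (is.null(blocks)) blocks <- intersect(characteristic_blocks(), names(frame))
  stopifnot(length(blocks) > 0, cluster %in% names(frame))
  cl <- factor(frame[[cluster]])
  g_n <- nlevels(droplevels(cl))
  if (g_n < 2) stop("clustered inference requires >= 2 clusters; got ", g_n)
  form <- as.formula(paste("log_centrality_ratio ~", paste(blocks, collapse = " + ")))
  df <- droplevels(frame)
  fit <- lm(form, data = df)
  if (anyNA(coef(fit))) {
    stop("design matrix is rank deficient; collinear terms: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  }
  # Stata-convention cluster-robust covariance: HC1-type scaling with the
  # G/(G-1) cluster adjustment.
  V <- sandwich::vcovCL(fit, cluster = cl, type = "HC1", cadjust = TRUE)
  b <- coef(fit)
  se <- sqrt(diag(V))
  df_t <- g_n - 1
  tstat <- b / se
  crit <- qt(1 - (1 - conf_level) / 2, df_t)
  coefs <- data.frame(
    term = names(b),
    estimate = as.numeric(b),
    std_error = as.numeric(se),
    statistic = as.numeric(tstat),
    p_value = 2 * pt(abs(tstat), df_t, lower.tail = FALSE),
    conf_low = as.numeric(b - crit * se),
    conf_high = as.numeric(b + crit * se),
    stringsAsFactors = FALSE
  )
  # assign is 0 for the intercept; offset by one so positions stay aligned
  # with the coefficient vector instead of silently dropping the 0 index.
  assign_block <- c("(Intercept)", attr(terms(fit), "term.labels"))[
    attr(model.matrix(fit), "assign") + 1L]
  partial_f <- do.call(rbind, lapply(blocks, function(blk) {
    idx <- which(assign_block == blk)
    if (length(idx) == 0) return(NULL)
    bb <- b[idx]
    Vb <- V[idx, idx, drop = FALSE]
    fstat <- as.numeric(crossprod(bb, solve(Vb, bb))) / length(idx)
    data.frame(block = blk, f_statistic = fstat, df1 = length(idx), df2 = df_t,
               p_value = pf(fstat, length(idx), df_t, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  structure(list(
    coefficients = coefs, partial_f = partial_f,
    n = nrow(df), n_clusters = g_n, vcov = V, fit = fit,
    network_label = if ("network_label" %in% names(frame)) frame$network_label[1] else NA_character_
  ), class = "egs_regression")
}

#' Sensitivity suite: the same model across subnetworks
#'
#' Applies the identical multivariable specification to each subnetwork's
#' analysis frame (ED-to-inpatient, inpatient-to-inpatient, with-operation,
#' without-operation). A frame that is empty or fails to fit yields a
#' structured skip record rather than an error.
#'
#' @param frames Named list of `egs_analysis_frame`s keyed by network label.
#' @param ... Passed to [clustered_regression()].
#' @return Named list: each element an `egs_regression` or a list
#'   `(skipped = TRUE, reason = <message>)`.
#' @export
run_sensitivity_suite <- function(frames, ...) {
  lapply(frames, function(fr) {
    if (is.null(fr) || nrow(fr) == 0) {
      return(list(skipped = TRUE, reason = "empty analysis frame"))
    }
    tryCatch(clustered_regression(fr, ...),
             error = function(e) list(skipped = TRUE, reason = conditionMessage(e)))
  })
}
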