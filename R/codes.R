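#' Path to a packaged example data file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path (or a character vector of file names).
#' @export
#' @examples
#' egsnet_example()
#' egsnet_example("synthetic_code_set.json")
egsnet_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "egsnet"))
  } else {
    system.file("extdata", file, package = "egsnet", mustWork = TRUE)
  }
}

#' Read a condition/complication/procedure code set
#'
#' A code set names the diagnosis codes that define EGS conditions
#' (`egs_dx`), the diagnosis codes that flag complications
#' (`complication_dx`), and the procedure codes that count as operations
#' (`operation_proc`). `egs_dx` may be either a flat array of codes or an
#' object mapping diagnosis-category names to code arrays; categories, when
#' present, are used as adjustment indicators in the risk models.
#'
#' @param path Path to a JSON file with keys `egs_dx`, `complication_dx`,
#'   `operation_proc`.
#' @return A list of class `egs_code_set` with elements `egs_dx` (named list
#'   of character vectors: category -> codes), `egs_dx_flat` (all EGS codes),
#'   `egs_category_of` (named character: code -> category),
#'   `complication_dx`, `operation_proc`.
#' @export
read_code_set <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (key in c("egs_dx", "complication_dx", "operation_proc")) {
    if (is.null(raw[[key]])) stop("code set is missing required key '", key, "'")
  }
  egs <- raw$egs_dx
  if (!is.list(egs)) egs <- list(egs = as.character(egs))
  egs <- lapply(egs, function(x) norm_codes(as.character(x)))
  flat <- unlist(egs, use.names = FALSE)
  if (anyDuplicated(flat)) stop("EGS diagnosis codes appear in more than one category")
  cat_of <- setNames(rep(names(egs), lengths(egs)), flat)
  out <- list(
    egs_dx = egs,
    egs_dx_flat = flat,
    egs_category_of = cat_of,
    complication_dx = norm_codes(as.character(raw$complication_dx)),
    operation_proc = norm_codes(as.character(raw$operation_proc))
  )
  for (key in c("egs_dx_flat", "complication_dx", "operation_proc")) {
    if (length(out[[key]]) == 0) stop("code set key '", key, "' is empty")
  }
  structure(out, class = "egs_code_set")
}

#' Read a comorbidity weight table
#'
#' The comorbidity index is a weighted sum over distinct comorbidity
#' categories present among a patient's diagnosis codes (an Elixhauser-style
#' index). The grouper itself is supplied as data, not hard-coded: the JSON
#' carries `weights` (category -> integer weight) and `categories`
#' (diagnosis code -> category).
#'
#' @param path Path to the JSON weight table.
#' @return A list of class `egs_comorbidity_table` with `weights` (named
#'   numeric) and `category_of` (named character, code -> category).
#' @export
read_comorbidity_table <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw$weights) || is.null(raw$categories)) {
    stop("comorbidity table must contain 'weights' and 'categories'")
  }
  weights <- unlist(raw$weights)
  category_of <- unlist(raw$categories)
  names(category_of) <- norm_codes(names(category_of))
  unknown <- setdiff(unique(category_of), names(weights))
  if (length(unknown) > 0) {
    stop("categories without weights: ", paste(unknown, collapse = ", "))
  }
  structure(list(weights = weights, category_of = category_of),
            class = "egs_comorbidity_table")
}

# Uppercase, strip whitespace and dots; code-set invariant.
norm_codes <- function(x) {
  toupper(gsub("[[:space:].]", "", x))
}

# Split semicolon-joined code fields into a list of character vectors.
# Normalization runs once on the full vector, not per row.
split_codes <- function(x) {
  x <- norm_codes(ifelse(is.na(x), "", as.character(x)))
  out <- strsplit(x, ";", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

join_codes <- function(codes) {
  vapply(codes, paste, character(1), collapse = ";")
}
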