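#' Network labels
#'
#' The analysis builds five networks from one transfer list: all transfers;
#' ED-to-inpatient transfers; inpatient-to-inpatient transfers; transfers
#' involving at least one operation or procedure; transfers involving none.
#'
#' @return Character vector of the five labels.
#' @export
network_labels <- function() c("all", "ed_ip", "ip_ip", "op", "no_op")

#' Build a weighted directed transfer network
#'
#' Hospitals are nodes; an edge from A to B is weighted by the number of
#' transfers from A to B in the selected subset. Hospitals with no transfers
#' in the subset remain as isolated nodes when listed in `nodes`, so the
#' normalizing node count reflects the full cohort.
#'
#' @param transfers Transfer table (columns `origin`, `destination`,
#'   `transfer_type` in ED-IP/IP-IP, `any_operation`), e.g. the `transfers`
#'   element of [build_episodes()].
#' @param label One of [network_labels()].
#' @param nodes Optional character vector of hospital IDs to include as
#'   nodes (isolates allowed); defaults to the hospitals appearing in the
#'   full transfer table.
#' @return A list of class `egs_network`: `label`, `nodes`, `edges`
#'   (origin, destination, weight) and `graph` (an igraph object).
#' @export
build_network <- function(transfers, label = "all", nodes = NULL) {
  label <- as.character(label)
  if (!label %in% network_labels()) {
    stop("unknown network label '", label, "'; expected one of: ",
         paste(network_labels(), collapse = ", "))
  }
  tr <- as.data.table(transfers)
  if (nrow(tr) > 0 && any(tr$origin == tr$destination)) {
    stop("self-loop transfer (origin == destination) in input")
  }
  if (is.null(nodes)) nodes <- sort(unique(c(tr$origin, tr$destination)))
  sub <- switch(label,
    all = tr,
    ed_ip = tr[transfer_type == "ED-IP"],
    ip_ip = tr[transfer_type == "IP-IP"],
    op = tr[any_operation == TRUE],
    no_op = tr[any_operation == FALSE]
  )
  edges <- if (nrow(sub) > 0) {
    e <- sub[, .(weight = .N), by = .(origin, destination)]
    data.table::setorder(e, origin, destination)
    e[]
  } else {
    data.table::data.table(origin = character(0), destination = character(0),
                           weight = integer(0))
  }
  graph <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                         vertices = data.frame(name = nodes))
  structure(list(label = label, nodes = nodes, edges = edges, graph = graph),
            class = "egs_network")
}

#' Build all five transfer networks
#'
#' @inheritParams build_network
#' @return Named list of `egs_network` objects, keyed by [network_labels()].
#' @export
build_all_networks <- function(transfers, nodes = NULL) {
  tr <- as.data.table(transfers)
  if (is.null(nodes)) nodes <- sort(unique(c(tr$origin, tr$destination)))
  setNames(lapply(network_labels(), build_network, transfers = tr, nodes = nodes),
           network_labels())
}

#' Degree centralities and centrality ratio per hospital
#'
#' Under the default `weighted` convention, in-degree centrality is the sum
#' of incoming edge weights normalized by the maximum possible,
#' `(n - 1) * W_max`, where `n` is the node count and `W_max` the largest
#' edge weight in the network; out-degree analogously. Both range over
#' \[0, 1\] and are scaled by 10,000. Under the `binary` convention the
#' numerator is the count of distinct in-/out-neighbors and the denominator
#' `n - 1`. The centrality ratio is in-degree divided by out-degree —
#' incoming transfers per outgoing transfer; under the weighted convention
#' the normalization cancels, so the ratio equals the raw transfer-count
#' ratio. The ratio is undefined (`NA`) when out-degree is 0.
#'
#' @param network An `egs_network` from [build_network()].
#' @param convention `"weighted"` (default) or `"binary"`.
#' @return data.frame of class `egs_centrality`: `hospital_id`,
#'   `in_degree_scaled`, `out_degree_scaled`, `centrality_ratio`,
#'   `network_label`, `convention`.
#' @export
degree_centralities <- function(network, convention = c("weighted", "binary")) {
  convention <- match.arg(convention)
  stopifnot(inherits(network, "egs_network"))
  n <- length(network$nodes)
  if (n < 2) stop("degenerate network: centrality requires at least 2 nodes")
  e <- network$edges
  if (convention == "weighted") {
    w_max <- if (nrow(e) > 0) max(e$weight) else 1
    s_in <- tapply_sum(e$weight, e$destination, network$nodes)
    s_out <- tapply_sum(e$weight, e$origin, network$nodes)
    denom <- (n - 1) * w_max
  } else {
    s_in <- tapply_sum(rep(1L, nrow(e)), e$destination, network$nodes)
    s_out <- tapply_sum(rep(1L, nrow(e)), e$origin, network$nodes)
    denom <- n - 1
  }
  in_scaled <- s_in / denom * 10000
  out_scaled <- s_out / denom * 10000
  out <- data.frame(
    hospital_id = network$nodes,
    in_degree_scaled = as.numeric(in_scaled),
    out_degree_scaled = as.numeric(out_scaled),
    centrality_ratio = centrality_ratio(in_scaled, out_scaled),
    network_label = network$label,
    convention = convention,
    stringsAsFactors = FALSE
  )
  class(out) <- c("egs_centrality", "data.frame")
  out
}

tapply_sum <- function(w, key, nodes) {
  out <- setNames(numeric(length(nodes)), nodes)
  if (length(w) > 0) {
    s <- tapply(as.numeric(w), factor(key, levels = nodes), sum)
    s[is.na(s)] <- 0
    out[names(s)] <- s
  }
  out
}

#' Centrality ratio
#'
#' In-degree centrality divided by out-degree centrality; higher values mean
#' more incoming transfers per outgoing transfer. Undefined (`NA`) when
#' out-degree is 0 — such hospitals are excluded from ratio analyses rather
#' than given a pseudo-count.
#'
#' @param in_degree,out_degree Numeric vectors (any common scaling; it
#'   cancels).
#' @return Numeric vector of ratios with `NA` where out-degree is 0.
#' @export
centrality_ratio <- function(in_degree, out_degree) {
  ifelse(out_degree > 0, in_degree / out_degree, NA_real_)
}

#' Log-transform centrality ratios
#'
#' The centrality ratio is right-skewed, so analyses run on its natural
#' logarithm. Hospitals with an undefined ratio (no outgoing transfers) or a
#' zero ratio (no incoming transfers) have no finite log and are excluded;
#' the exclusion tally is attached as an attribute and reported downstream.
#' An optional epsilon offset (`log(ratio + epsilon)`) is available but off
#' by default.
#'
#' @param records An `egs_centrality` data.frame.
#' @param epsilon Non-negative offset added inside the log; default 0.
#' @return The records with a `log_centrality_ratio` column (`NA` where
#'   excluded) and an `exclusions` attribute
#'   (`c(undefined_ratio=, zero_ratio=)`).
#' @export
log_transform_ratios <- function(records, epsilon = 0) {
  stopifnot(epsilon >= 0)
  r <- records$centrality_ratio
  shifted <- r + epsilon
  records$log_centrality_ratio <- ifelse(!is.na(shifted) & shifted > 0, log(shifted), NA_real_)
  attr(records, "exclusions") <- c(
    undefined_ratio = sum(is.na(r)),
    zero_ratio = sum(!is.na(shifted) & shifted <= 0)
  )
  records
}
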