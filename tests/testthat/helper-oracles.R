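# Independent oracles and small fixture builders. The oracles deliberately
# use naive edge-by-edge loops and textbook formulas so they share no code
# with the implementation they check.

pkg_codes <- function() read_code_set(egsnet_example("synthetic_code_set.json"))
pkg_comorbidity <- function() read_comorbidity_table(egsnet_example("synthetic_comorbidity_weights.json"))

# Brute-force degree centralities: iterate edges one at a time.
oracle_centrality <- function(nodes, edges, convention = "weighted") {
  n <- length(nodes)
  s_in <- setNames(numeric(n), nodes)
  s_out <- setNames(numeric(n), nodes)
  nb_in <- setNames(vector("list", n), nodes)
  nb_out <- setNames(vector("list", n), nodes)
  w_max <- 1
  if (nrow(edges) > 0) {
    for (i in seq_len(nrow(edges))) {
      o <- edges$origin[i]; d <- edges$destination[i]; w <- edges$weight[i]
      s_in[d] <- s_in[d] + w
      s_out[o] <- s_out[o] + w
      nb_in[[d]] <- union(nb_in[[d]], o)
      nb_out[[o]] <- union(nb_out[[o]], d)
      if (w > w_max) w_max <- w
    }
  }
  if (convention == "weighted") {
    data.frame(hospital_id = nodes,
               in_degree_scaled = s_in / ((n - 1) * w_max) * 10000,
               out_degree_scaled = s_out / ((n - 1) * w_max) * 10000,
               row.names = NULL)
  } else {
    data.frame(hospital_id = nodes,
               in_degree_scaled = lengths(nb_in) / (n - 1) * 10000,
               out_degree_scaled = lengths(nb_out) / (n - 1) * 10000,
               row.names = NULL)
  }
}

# Random weighted directed graph with n <= 20 nodes, weights <= 50; may
# include isolated nodes.
random_graph <- function(seed) {
  set.seed(seed)
  n <- sample(2:20, 1)
  nodes <- sprintf("H%02d", seq_len(n))
  max_edges <- n * (n - 1)
  m <- sample(0:min(max_edges, 40), 1)
  pairs <- expand.grid(origin = nodes, destination = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$origin != pairs$destination, ]
  pick <- pairs[sample(nrow(pairs), m), ]
  pick$weight <- sample(1:50, m, replace = TRUE)
  list(nodes = nodes, edges = pick)
}

# Hand-coded Stata-convention cluster-robust sandwich:
# c * (X'X)^-1 [sum_g (X_g' e_g)(X_g' e_g)'] (X'X)^-1, c = G/(G-1)*(N-1)/(N-K)
oracle_cluster_vcov <- function(X, y, cluster) {
  n <- nrow(X); k <- ncol(X)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  e <- as.numeric(y - X %*% beta)
  G <- length(unique(cluster))
  meat <- matrix(0, k, k)
  for (g in unique(cluster)) {
    idx <- which(cluster == g)
    sg <- t(X[idx, , drop = FALSE]) %*% e[idx]
    meat <- meat + sg %*% t(sg)
  }
  bread <- solve(t(X) %*% X)
  c_adj <- G / (G - 1) * (n - 1) / (n - k)
  c_adj * bread %*% meat %*% bread
}

# One encounter row in the claims schema.
enc_row <- function(patient_id, hospital_id, setting, admit, discharge,
                    age = 50, sex = "F", dx = "", proc = "", died = 0L,
                    state = "S1") {
  data.frame(patient_id = patient_id, hospital_id = hospital_id, state = state,
             setting = setting, admit_date = admit, discharge_date = discharge,
             age = age, sex = sex, dx_codes = dx, proc_codes = proc,
             died = died, stringsAsFactors = FALSE)
}

egs_code1 <- function() pkg_codes()$egs_dx_flat[1]
op_code1 <- function() pkg_codes()$operation_proc[1]

# A small simulated world reused across tests.
small_sim <- function(seed = 42, n_hospitals = 30, n_patients = 2000, ...) {
  cfg <- sim_config(n_hospitals = n_hospitals, n_patients = n_patients,
                    seed = seed, ...)
  h <- generate_hospitals(cfg)
  sim <- generate_encounters(h, cfg)
  list(cfg = cfg, hospitals = h, sim = sim)
}
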