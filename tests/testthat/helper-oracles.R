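# Independent brute-force oracles used to cross-check the implementation.
# Written deliberately as naive record-by-record / pair-by-pair loops.

# Evaluate the five single-cell QC rules independently for one record.
qc_oracle <- function(records, shape_group) {
  ok <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    vals <- c(r$shape_factor, r$nuclei_in_region, r$nucleus_min_distance,
              r$nucleus_area, r$calcium_centroid_x, r$calcium_centroid_y,
              r$hoechst_centroid_x, r$hoechst_centroid_y,
              r$post_centroid_x, r$post_centroid_y)
    if (anyNA(vals)) { ok[i] <- FALSE; next }
    rule_sf <- if (shape_group == "O") r$shape_factor >= 0.9 else
      (r$shape_factor >= 0.5 && r$shape_factor <= 0.85)
    rule_single <- r$nuclei_in_region == 1
    rule_dist <- r$nucleus_min_distance >= 20
    rule_area <- r$nucleus_area < 300
    d1 <- sqrt((r$calcium_centroid_x - r$hoechst_centroid_x)^2 +
                 (r$calcium_centroid_y - r$hoechst_centroid_y)^2)
    d2 <- sqrt((r$calcium_centroid_x - r$post_centroid_x)^2 +
                 (r$calcium_centroid_y - r$post_centroid_y)^2)
    d3 <- sqrt((r$hoechst_centroid_x - r$post_centroid_x)^2 +
                 (r$hoechst_centroid_y - r$post_centroid_y)^2)
    rule_cent <- !(max(d1, d2, d3) > 30)
    ok[i] <- rule_sf && rule_single && rule_dist && rule_area && rule_cent
  }
  ok
}

# Naive agglomerative average-linkage clustering on Manhattan distances
# between matrix rows; returns the partition into k groups.
bf_average_linkage <- function(mat, k) {
  n <- nrow(mat)
  d <- as.matrix(stats::dist(mat, method = "manhattan"))
  clusters <- as.list(seq_len(n))
  while (length(clusters) > k) {
    best <- c(NA, NA); best_d <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      dd <- mean(d[clusters[[a]], clusters[[b]]])
      if (dd < best_d) { best_d <- dd; best <- c(a, b) }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1L]] <- merged
  }
  part <- integer(n)
  for (g in seq_along(clusters)) part[clusters[[g]]] <- g
  part
}

# TRUE when two labelings describe the same partition of the elements.
partitions_equal <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}

# Random valid model parameters, kinetics comfortably inside the grid;
# wide amplitude coverage for model-math properties.
random_params <- function() {
  transient_params(
    tau_decay = 1 / exp(runif(1, log(30), log(1000))),
    tau_delta = exp(runif(1, log(1e-3), log(5e-2))),
    b = exp(runif(1, log(1), log(100))),
    c = exp(runif(1, log(0.5), log(50))))
}

# Parameters drawn from the cohort generator's default conditions (union
# of the O and L group ranges): decaying transients whose steady state
# sits well below the peak, as agonist-evoked calcium responses do.
cohort_params <- function() {
  transient_params(
    tau_decay = 1 / exp(runif(1, log(60), log(900))),
    tau_delta = exp(runif(1, log(0.01), log(0.05))),
    b = exp(runif(1, log(100), log(300))),
    c = exp(runif(1, log(20), log(80))))
}
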