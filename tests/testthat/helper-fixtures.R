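# shared fixture builders; everything is generated in code at test time

default_gating <- load_gating_config()

# cell table from a list of positive-marker sets, all other markers negative
cells_from_markers <- function(pos_list, region = "R1",
                               x = seq_along(pos_list),
                               y = rep(0, length(pos_list))) {
  n <- length(pos_list)
  cells <- data.frame(cell_id = paste0("c", seq_len(n)), region_id = region,
                      x_um = x, y_um = y, stringsAsFactors = FALSE)
  for (m in PANEL_MARKERS) {
    cells[[m]] <- vapply(pos_list, function(p) m %in% p, logical(1))
  }
  attr(cells, "markers") <- PANEL_MARKERS
  cells
}

# independent O(n^2) oracle for the radius search (full distance matrix,
# squared comparison, upper triangle)
bf_pairs <- function(x, y, r) {
  d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  w <- which(upper.tri(d2) & d2 <= r * r, arr.ind = TRUE)
  m <- cbind(i = w[, 1], j = w[, 2])
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# small generated cohort shared by ML-ish tests
small_cohort <- function(seed = 1, n_naive = 6, n_acd40 = 6,
                         regions = c(IA = 2), cells = 150,
                         effects = synth_effects(), n_long = 3) {
  generate_cohort(
    synth_config(seed = seed,
                 n_patients = c(naive = n_naive, aCD40 = n_acd40),
                 regions_per_patient = regions,
                 cells_per_region = cells, effects = effects,
                 dfs = list(long_meanlog = log(20), short_meanlog = log(5),
                            sdlog = 0.25, n_long = n_long)),
    default_gating)
}

phenotyped <- function(d) {
  assign_barcodes(assign_states(d$cells, default_gating), default_gating)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
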