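test_that("neighborhood composition counts the seed and the 60 um ball", {
  cells <- cells_from_markers(list(c("CD20"), c("CD20"), c("CD68")),
                              x = c(0, 0, 0), y = c(0, 50, 70))
  cells <- assign_states(cells, default_gating)  # B, B, Myeloid
  nb <- neighborhood_composition(cells, default_gating, radius_um = 60)
  # seed 1: itself + cell at 50 -> all B cell
  expect_equal(unname(nb$comp["c1", "B cell"]), 1)
  expect_identical(nb$n_neighbors[1], 2)
  # seed 2 sees both neighbors: 2/3 B, 1/3 Myeloid
  expect_equal(unname(nb$comp["c2", "B cell"]), 2 / 3)
  expect_equal(unname(nb$comp["c2", "Myeloid"]), 1 / 3)
  # isolated cell is a one-hot on its own state
  far <- assign_states(cells_from_markers(list(c("CD68")), x = 5000, y = 5000),
                       default_gating)
  far$cell_id <- "c9"
  both <- rbind(cells, far)
  attr(both, "markers") <- PANEL_MARKERS
  nb2 <- neighborhood_composition(both, default_gating, 60)
  expect_equal(unname(nb2$comp["c9", "Myeloid"]), 1)
  # proportions always sum to 1
  expect_equal(unname(rowSums(nb2$comp)), rep(1, 4))
})

test_that("elbow selection maximizes chord distance with documented tie-breaks", {
  expect_identical(elbow_k(c(100, 40, 20, 15, 13, 12), 2:7), 4L)
  # linear decay: all interior distances 0 -> first interior candidate
  expect_identical(elbow_k(seq(100, 0, length.out = 6), 2:7), 3L)
  expect_error(elbow_k(c(10, 5), 2:3), "3 candidates")
  expect_error(elbow_k(c(10, 12, 5), 2:4), "non-increasing")
})

test_that("K-means RCNs recover planted composition archetypes", {
  set.seed(81)
  leaves <- taxonomy_leaves(default_gating)
  arch1 <- stats::setNames(rep(0, 23), leaves); arch1["B cell"] <- 0.9
  arch1["Myeloid"] <- 0.1
  arch2 <- stats::setNames(rep(0, 23), leaves)
  arch2["Neoplastic epithelial"] <- 0.8; arch2["Mesenchymal"] <- 0.2
  noisy <- function(a) {
    v <- pmax(a + runif(23, 0, 0.03), 0)
    v / sum(v)
  }
  comp <- rbind(t(vapply(1:40, function(i) noisy(arch1), numeric(23))),
                t(vapply(1:40, function(i) noisy(arch2), numeric(23))))
  rownames(comp) <- paste0("c", 1:80)
  model <- fit_rcn(comp, k_range = 1:6, seed = 5)
  planted <- rep(1:2, each = 40)
  expect_gte(ari(model$assignments, planted), 0.8)
  # mean member compositions sit close to the planted archetypes
  sm <- rcn_summaries(model, data.frame(region_id = character(),
                                        patient_id = character()))
  expect_equal(unname(rowSums(sm$mean_composition)), rep(1, model$K),
               tolerance = 1e-9)
  # cluster means coincide with the planted group means (exact membership)
  planted_means <- rbind(colMeans(comp[1:40, ]), colMeans(comp[41:80, ]))
  for (k in seq_len(model$K)) {
    l1 <- min(sum(abs(sm$mean_composition[k, ] - planted_means[1, ])),
              sum(abs(sm$mean_composition[k, ] - planted_means[2, ])))
    expect_lt(l1, 0.05)
  }
})

test_that("degenerate and repeated fits behave deterministically", {
  comp <- matrix(1 / 23, 30, 23,
                 dimnames = list(paste0("c", 1:30),
                                 taxonomy_leaves(default_gating)))
  expect_warning(m1 <- fit_rcn(comp, k_range = 2:6, seed = 1), "single RCN")
  expect_identical(m1$K, 1L)

  set.seed(82)
  comp2 <- matrix(runif(30 * 23), 30, 23,
                  dimnames = list(paste0("c", 1:30), NULL))
  comp2 <- comp2 / rowSums(comp2)
  a <- fit_rcn(comp2, k_range = 2:6, seed = 9)
  b <- fit_rcn(comp2, k_range = 2:6, seed = 9)
  expect_identical(a$assignments, b$assignments)
  # best-of-restarts inertia is non-increasing in K
  expect_true(all(diff(a$inertia) <= 1e-8))
  expect_error(fit_rcn(comp2[1:3, ], k_range = 2:6), "at least")
})

test_that("every composed cell gets exactly one RCN and labels sort by size", {
  d <- small_cohort(seed = 83, n_naive = 0, n_acd40 = 4, cells = 150)
  cells <- phenotyped(d)
  nb <- neighborhood_composition(cells, default_gating, 60)
  model <- fit_rcn(nb, k_range = 2:6, seed = 1)
  expect_setequal(names(model$assignments), cells$cell_id)
  expect_identical(anyDuplicated(names(model$assignments)), 0L)
  expect_identical(model$sizes, sort(model$sizes, decreasing = TRUE))
  sm <- rcn_summaries(model, d$regions)
  expect_equal(unname(rowSums(sm$region_proportions)),
               rep(1, nrow(sm$region_proportions)))
  expect_true(all(c("n_regions", "n_patients", "recurrent") %in%
                    names(sm$presence)))
})

residency_fixture <- function() {
  # 2 RCNs; barcode X cells all in RCN1, Y in RCN2, Z split
  cells <- data.frame(
    cell_id = paste0("c", 1:10),
    region_id = "R1",
    state = "CD44+ Th",
    barcode = c(rep("X+", 4), rep("Y+", 4), "Z+", "Z+"),
    stringsAsFactors = FALSE)
  assignments <- stats::setNames(c(rep(1L, 4), rep(2L, 4), 1L, 2L),
                                 cells$cell_id)
  model <- structure(list(K = 2L, assignments = assignments), class = "rcn_model")
  regions <- data.frame(region_id = "R1", patient_id = "A1", cohort = "aCD40",
                        site = "IA", area_mm2 = 0.2, stringsAsFactors = FALSE)
  patients <- data.frame(patient_id = "A1", cohort = "aCD40",
                         dfs_label = "long", stringsAsFactors = FALSE)
  list(cells = cells, model = model, regions = regions, patients = patients)
}

test_that("barcode residency rows are RCN fractions that cluster by archetype", {
  fx <- residency_fixture()
  top <- data.frame(barcode = c("X+", "Y+", "Z+", "Q+"),
                    group = c("long", "long", "long", "long"),
                    stringsAsFactors = FALSE)
  expect_warning(res <- barcode_rcn_residency(fx$model, fx$cells, fx$regions,
                                              fx$patients, top), "Q\\+")
  expect_equal(unname(res$residency["X+ (long)", ]), c(1, 0))  # one-hot
  expect_equal(unname(res$residency["Z+ (long)", ]), c(0.5, 0.5))
  expect_equal(unname(rowSums(res$residency)), rep(1, 3))
  # the 2-group cut separates the opposite archetypes
  expect_false(res$cluster[["X+ (long)"]] == res$cluster[["Y+ (long)"]])
  expect_identical(nrow(res$profiles), 2L)
})

test_that("functional fractions conserve counts and respect T_REG exclusion", {
  cells <- data.frame(
    cell_id = paste0("c", 1:8),
    region_id = "R1",
    state = c(rep("CD44+ Th", 4), rep("mT_REG", 2), rep("B cell", 2)),
    stringsAsFactors = FALSE)
  cells$`Ki-67` <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE)
  cells$GrzB <- c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE)
  assignments <- stats::setNames(c(1L, 1L, 1L, 1L, 2L, 2L, 1L, 2L),
                                 cells$cell_id)
  model <- structure(list(K = 2L, assignments = assignments),
                     class = "rcn_model")
  ki <- functional_fraction_by_rcn(model, cells, default_gating, "Ki-67")
  expect_equal(ki$per_rcn$fraction[1], 0.5)  # 2 of 4 T cells in RCN1
  # conservation: sum of per-RCN positives equals the overall positive count
  expect_identical(sum(ki$per_rcn$n_pos), 3L)
  expect_equal(ki$baseline, 3 / 6)

  gz <- functional_fraction_by_rcn(model, cells, default_gating, "GrzB",
                                   exclude_treg = TRUE)
  expect_identical(gz$per_rcn$n_t[2], 0L)      # only T_REGs were in RCN2
  expect_true(is.na(gz$per_rcn$fraction[2]))
  expect_equal(gz$per_rcn$fraction[1], 0.25)
  expect_error(functional_fraction_by_rcn(model, cells[, 1:3], default_gating,
                                          "Ki-67"), "Ki-67")
})
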