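test_that("radius search handles the worked three-cell case and boundaries", {
  cells <- cells_from_markers(list(c("CD20"), c("CD68"), c("CD68")),
                              x = c(0, 15, 40), y = c(0, 0, 0))
  cells <- assign_states(cells, default_gating)  # B cell, Myeloid, Myeloid
  counts <- find_interactions(cells, radius_um = 20)
  expect_identical(counts[["B cell | Myeloid"]], 1L)  # A-B at 15
  expect_false("Myeloid | Myeloid" %in% names(counts))  # B-C at 25 > 20

  # inclusive boundary: exactly 20.0 um apart
  two <- cells_from_markers(list(c("CD20"), c("CD68")), x = c(0, 20), y = c(0, 0))
  two <- assign_states(two, default_gating)
  expect_identical(sum(find_interactions(two, 20)), 1L)

  one <- assign_states(cells_from_markers(list(c("CD20"))), default_gating)
  expect_length(find_interactions(one, 20), 0L)
})

test_that("grid-binned radius search equals the brute-force scan exactly", {
  set.seed(21)
  for (trial in 1:20) {
    n <- sample(2:300, 1)
    side <- runif(1, 50, 800)
    x <- runif(n, 0, side); y <- runif(n, 0, side)
    r <- runif(1, 5, 80)
    expect_identical(unname(radius_pairs(x, y, r)), unname(bf_pairs(x, y, r)))
  }
})

test_that("interaction counts are translation invariant", {
  set.seed(22)
  n <- 200
  cells <- cells_from_markers(
    replicate(n, sample(c("CD20", "CD68", "PanCK"), 1), simplify = FALSE),
    x = runif(n, 0, 400), y = runif(n, 0, 400))
  cells <- assign_states(cells, default_gating)
  shifted <- cells
  shifted$x_um <- shifted$x_um + 1234.5
  shifted$y_um <- shifted$y_um + 77.25
  expect_identical(find_interactions(cells, 20), find_interactions(shifted, 20))
})

test_that("densities are counts over area with conservation", {
  leaves <- taxonomy_leaves(default_gating)
  cells <- assign_states(
    cells_from_markers(rep(list("CD20"), 10), x = 1:10, y = 1:10),
    default_gating)
  d <- compute_state_densities(cells, 0.5, leaves)
  expect_identical(d[["B cell"]], 20)
  expect_equal(sum(d) * 0.5, 10)
  # empty region -> all-zero vector
  expect_true(all(compute_state_densities(cells[0, ], 0.5, leaves) == 0))
  expect_error(compute_state_densities(cells, 0, leaves), "positive")
})

test_that("barcode densities ignore non-T cells and conserve counts", {
  cells <- cells_from_markers(list(
    c("CD3", "CD8", "CD44"), c("CD3", "CD8", "CD44"),
    c("CD3", "CD8"), c("CD3", "CD8"), c("CD20")))
  cells <- assign_barcodes(assign_states(cells, default_gating), default_gating)
  bd <- compute_barcode_densities(cells, 2)
  expect_identical(bd[["CD44+"]], 1)       # 2 cells / 2 mm^2
  expect_identical(bd[["NEG"]], 1)
  expect_equal(sum(bd) * 2, 4)             # total T cells
  expect_length(compute_barcode_densities(cells[5, ], 2), 0L)
})

test_that("normalization divides by summed densities of the distinct states", {
  counts <- c("Myeloid | Neoplastic epithelial" = 4L, "B cell | B cell" = 3L,
              "Mesenchymal | Myeloid" = 0L)
  dens <- c("Myeloid" = 2, "Neoplastic epithelial" = 6, "B cell" = 2,
            "Mesenchymal" = 1)
  v <- normalize_interactions(counts, dens)
  expect_identical(v[["Myeloid | Neoplastic epithelial"]], 0.5)
  expect_identical(v[["B cell | B cell"]], 1.5)  # same-state: divide once
  expect_identical(v[["Mesenchymal | Myeloid"]], 0)
  expect_error(
    normalize_interactions(c("B cell | Myeloid" = 2L), c("B cell" = 0, "Myeloid" = 0)),
    "consistency")
})

test_that("feature matrix assembly fixes the column namespace and order", {
  leaves <- c("A", "B")
  dens <- list(R1 = c(A = 1, B = 0), R2 = c(A = 0, B = 2))
  bd <- list(R1 = c("CD44+" = 3), R2 = stats::setNames(numeric(), character()))
  iv <- list(R1 = c("A | B" = 0.5), R2 = c("A | A" = 1))
  fm <- assemble_feature_matrix(dens, bd, iv, leaves)
  expect_identical(colnames(fm),
                   c("density:A", "density:B", "barcode:CD44+",
                     "interaction:A | A", "interaction:A | B"))
  expect_identical(fm["R2", "barcode:CD44+"], 0)  # unobserved is 0, not NA
  expect_identical(fm["R1", "interaction:A | B"], 0.5)

  # shuffling region input order yields the same matrix after row alignment
  fm2 <- assemble_feature_matrix(dens[c(2, 1)], bd[c(2, 1)], iv[c(2, 1)], leaves)
  expect_identical(fm2[rownames(fm), ], fm)

  expect_error(assemble_feature_matrix(dens, bd[1], iv, leaves), "region sets")

  # explicit inventories pin the column count:
  # |leaves| + |barcodes| + |pairs|
  fm3 <- assemble_feature_matrix(dens, bd, iv, leaves,
                                 barcodes = paste0("b", 1:7),
                                 pairs = paste0("p", 1:5))
  expect_identical(ncol(fm3), 2L + 7L + 5L)
})

test_that("top barcodes rank by mean density with lexicographic ties", {
  fm <- matrix(c(5, 5, 3, 3, 1, 1), 2, 3,
               dimnames = list(c("R1", "R2"),
                               c("barcode:ZZ+", "barcode:AA+", "barcode:MM+")))
  colnames(fm) <- c("barcode:ZZ+", "barcode:AA+", "barcode:MM+")
  top <- top_barcodes_by_density(fm, c("R1", "R2"), k = 15)
  expect_identical(top$barcode, c("ZZ+", "AA+", "MM+"))

  tie <- matrix(c(2, 2, 2, 2), 2, 2,
                dimnames = list(c("R1", "R2"), c("barcode:B+", "barcode:A+")))
  expect_identical(top_barcodes_by_density(tie, c("R1", "R2"))$barcode,
                   c("A+", "B+"))
  expect_identical(nrow(top_barcodes_by_density(fm, c("R1", "R2"), k = 2)), 2L)
  expect_error(top_barcodes_by_density(fm, character()), "empty")
})
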