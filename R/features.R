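#' Cell state densities of one region
#'
#' Raw per-state cell counts divided by the region's tissue area; states
#' absent from the region get density 0.
#'
#' @param cells Cells of one region, with states assigned.
#' @param area_mm2 Tissue area of the region in mm^2 (> 0).
#' @param leaves Ordered taxonomy leaf labels.
#' @return Named numeric vector over `leaves`, cells/mm^2.
#' @export
compute_state_densities <- function(cells, area_mm2, leaves) {
  if (!is.finite(area_mm2) || area_mm2 <= 0) stop("area_mm2 must be positive")
  counts <- table(factor(cells$state, levels = leaves))
  stats::setNames(as.numeric(counts) / area_mm2, leaves)
}

#' Barcode densities of one region
#'
#' Per-barcode T cell counts divided by the region's tissue area; non-T
#' cells (barcode unset) are ignored.
#'
#' @param cells Cells of one region, with barcodes assigned.
#' @param area_mm2 Tissue area in mm^2 (> 0).
#' @return Named numeric vector over the barcodes observed in the region
#'   (empty when the region has no T cells).
#' @export
compute_barcode_densities <- function(cells, area_mm2) {
  if (!is.finite(area_mm2) || area_mm2 <= 0) stop("area_mm2 must be positive")
  bc <- cells$barcode[!is.na(cells$barcode)]
  if (!length(bc)) return(stats::setNames(numeric(), character()))
  counts <- table(bc)
  stats::setNames(as.numeric(counts) / area_mm2, names(counts))
}

#' Cell-cell spatial interaction counts of one region
#'
#' Counts unordered pairs of cells whose centroid distance is at most
#' `radius_um` (inclusive; 20 um by default), keyed by the unordered pair
#' of their states. Same-state pairs count each unordered cell pair once;
#' a cell never pairs with itself. Regions are independent tissue frames,
#' so interactions are never computed across regions.
#'
#' @param cells Cells of one region, with states assigned.
#' @param radius_um Inclusive interaction radius in microns.
#' @return Named integer vector: names are `"A | B"` with `A <= B`
#'   lexicographically; values are pair counts (only observed pairs).
#' @export
find_interactions <- function(cells, radius_um = 20) {
  if (nrow(cells) < 2L) return(stats::setNames(integer(), character()))
  p <- radius_pairs(cells$x_um, cells$y_um, radius_um)
  if (!nrow(p)) return(stats::setNames(integer(), character()))
  s1 <- cells$state[p[, 1]]
  s2 <- cells$state[p[, 2]]
  key <- ifelse(s1 <= s2, paste(s1, s2, sep = " | "), paste(s2, s1, sep = " | "))
  counts <- table(key)
  stats::setNames(as.integer(counts), names(counts))
}

#' Normalize interaction counts by the summed densities of the states involved
#'
#' Divides each pair count by the summed densities of the distinct cell
#' states involved in the interaction, so abundant states do not skew the
#' score: `{A,B}` with `A != B` divides by `density_A + density_B`;
#' same-state pairs `{A,A}` divide by `density_A` once.
#'
#' @param counts Named counts from [find_interactions()].
#' @param densities Named state density vector from
#'   [compute_state_densities()].
#' @return Named numeric vector of normalized interaction scores.
#' @export
normalize_interactions <- function(counts, densities) {
  if (!length(counts)) return(stats::setNames(numeric(), character()))
  out <- numeric(length(counts))
  for (i in seq_along(counts)) {
    st <- strsplit(names(counts)[i], " | ", fixed = TRUE)[[1]]
    st <- unique(st)
    denom <- sum(densities[st])
    if (counts[i] == 0) { out[i] <- 0; next }
    if (!is.finite(denom) || denom <= 0) {
      stop("internal consistency error: pair '", names(counts)[i],
           "' has count ", counts[i], " but zero summed density")
    }
    out[i] <- counts[i] / denom
  }
  stats::setNames(out, names(counts))
}

#' Assemble the region-by-feature matrix
#'
#' One row per region; columns are the three feature families in fixed
#' order: one density column per taxonomy leaf, then one column per barcode
#' observed anywhere in the dataset (lexicographic), then one column per
#' interaction pair observed anywhere (lexicographic). Entries unobserved
#' in a region are 0, never missing. Column names carry the family as a
#' `family:key` prefix.
#'
#' @param densities Named list, region_id -> state density vector.
#' @param barcode_densities Named list, region_id -> barcode density vector.
#' @param interactions Named list, region_id -> normalized interaction vector.
#' @param leaves Ordered taxonomy leaves.
#' @param barcodes,pairs Optional explicit column inventories (defaults:
#'   union of keys observed across regions).
#' @return Numeric matrix, rownames = region ids.
#' @export
assemble_feature_matrix <- function(densities, barcode_densities, interactions,
                                    leaves, barcodes = NULL, pairs = NULL) {
  regions <- names(densities)
  if (!setequal(regions, names(barcode_densities)) ||
      !setequal(regions, names(interactions))) {
    stop("feature families cover different region sets")
  }
  if (is.null(barcodes)) {
    barcodes <- sort(unique(unlist(lapply(barcode_densities, names))))
  }
  if (is.null(pairs)) {
    pairs <- sort(unique(unlist(lapply(interactions, names))))
  }
  cols <- c(paste0("density:", leaves),
            paste0("barcode:", barcodes),
            paste0("interaction:", pairs))
  m <- matrix(0, nrow = length(regions), ncol = length(cols),
              dimnames = list(regions, cols))
  fill <- function(r, prefix, v) {
    if (length(v)) m[r, paste0(prefix, names(v))] <<- as.numeric(v)
  }
  for (r in regions) {
    m[r, paste0("density:", leaves)] <- as.numeric(densities[[r]][leaves])
    bd <- barcode_densities[[r]]
    fill(r, "barcode:", bd[names(bd) %in% barcodes])
    iv <- interactions[[r]]
    fill(r, "interaction:", iv[names(iv) %in% pairs])
  }
  stopifnot(ncol(m) == length(leaves) + length(barcodes) + length(pairs))
  if (any(m < 0)) stop("feature matrix contains negative entries")
  m
}

#' Compute all three feature families for a dataset
#'
#' Convenience wrapper: per-region state densities, barcode densities and
#' density-normalized interaction scores, assembled with
#' [assemble_feature_matrix()]. Raw (untransformed) values are stored; the
#' log10+1 / minmax transform is a model-preprocessing step applied inside
#' each cross-validation fold, not here.
#'
#' @param cells Cell table with states and barcodes assigned.
#' @param regions Region metadata.
#' @param config A `gating_config`.
#' @param radius_um Interaction radius (microns).
#' @return Region-by-feature numeric matrix.
#' @export
build_feature_matrix <- function(cells, regions, config, radius_um = 20) {
  leaves <- taxonomy_leaves(config)
  by_region <- split(cells, factor(cells$region_id, levels = regions$region_id))
  dens <- list(); bdens <- list(); inter <- list()
  for (i in seq_len(nrow(regions))) {
    r <- regions$region_id[i]
    rc <- by_region[[r]]
    if (is.null(rc)) rc <- cells[0, , drop = FALSE]
    a <- regions$area_mm2[i]
    dens[[r]] <- compute_state_densities(rc, a, leaves)
    bdens[[r]] <- compute_barcode_densities(rc, a)
    inter[[r]] <- normalize_interactions(find_interactions(rc, radius_um),
                                         dens[[r]])
  }
  assemble_feature_matrix(dens, bdens, inter, leaves)
}

#' Rank barcodes by mean density within a region group
#'
#' Means are taken across the given regions' rows of the feature matrix;
#' ties are broken lexicographically by canonical barcode name.
#'
#' @param fm Feature matrix.
#' @param region_ids Regions forming the group (e.g. one cohort x site).
#' @param k Number of barcodes to return (fewer if fewer observed).
#' @return Data frame with `barcode` and `mean_density`, descending.
#' @export
top_barcodes_by_density <- function(fm, region_ids, k = 15) {
  region_ids <- intersect(region_ids, rownames(fm))
  if (!length(region_ids)) stop("empty region group")
  bc_cols <- grep("^barcode:", colnames(fm), value = TRUE)
  mu <- colMeans(fm[region_ids, bc_cols, drop = FALSE])
  names(mu) <- sub("^barcode:", "", names(mu))
  mu <- mu[mu > 0]
  ord <- order(-mu, names(mu))
  top <- utils::head(ord, k)
  data.frame(barcode = names(mu)[top], mean_density = as.numeric(mu[top]),
             stringsAsFactors = FALSE)
}
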