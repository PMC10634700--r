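#' Canonical tokens used throughout the package
#'
#' Case-sensitive canonical tokens for treatment cohorts, histopathologic
#' sites, and the antibody panel. All readers and generators validate
#' against these; downstream code never re-derives them.
#'
#' @details
#' `BARCODE_MARKERS` is the fixed, ordered 10-marker alphabet of the T cell
#' functionality barcode. Barcode bit order and canonical names are defined
#' over this order and must never be permuted. Ki-67 and GrzB are separate
#' functional flags and are deliberately not part of the barcode.
#'
#' @name constants
#' @aliases COHORTS SITES BARCODE_MARKERS LINEAGE_MARKERS FUNCTIONAL_FLAGS
#'   PANEL_MARKERS
NULL

#' @rdname constants
#' @export
COHORTS <- c("naive", "aCD40")

#' @rdname constants
#' @export
SITES <- c("T", "IA", "TAS", "NAP")

#' @rdname constants
#' @export
BARCODE_MARKERS <- c("TOX1", "TIM3", "TCF-1", "CD38", "PD-1",
                     "EOMES", "CD39", "CD44", "LAG-3", "T-BET")

#' @rdname constants
#' @export
LINEAGE_MARKERS <- c("CD3", "CD8", "FOXP3", "CD20", "CD68", "PanCK", "aSMA")

#' @rdname constants
#' @export
FUNCTIONAL_FLAGS <- c("Ki-67", "GrzB")

#' @rdname constants
#' @export
PANEL_MARKERS <- c(LINEAGE_MARKERS, BARCODE_MARKERS, FUNCTIONAL_FLAGS)

# DFS group labels (derived by median split of the treated cohort)
DFS_GROUPS <- c("long", "short")

# schema version stamped into every CSV this package writes
SCHEMA_VERSION <- 1L
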