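#' T-state profile of a predictive barcode
#'
#' Among T cells carrying the barcode within regions of the given
#' histopathologic site and of the group the barcode was predictive of
#' (a treatment cohort or a DFS group), counts the expressing cells per
#' T state and normalises to proportions.
#'
#' @param cells Cell table with states and barcodes assigned.
#' @param regions Region metadata.
#' @param config A `gating_config`.
#' @param barcode Canonical barcode name.
#' @param site Histopathologic site of the model the barcode came from.
#' @param group Cohort (`"naive"`/`"aCD40"`) or DFS group
#'   (`"long"`/`"short"`) the barcode was predictive of.
#' @param patients Patient table with `dfs_label`; required when `group`
#'   is a DFS group.
#' @return List with `barcode`, `site`, `group`, `n` (expressing cells),
#'   `proportions` over the T states (sums to 1), and `empty` flag.
#' @export
barcode_state_proportions <- function(cells, regions, config, barcode, site,
                                      group, patients = NULL) {
  t_states <- taxonomy_leaves(config, t_states_only = TRUE)
  if (group %in% COHORTS) {
    keep_regions <- regions$region_id[regions$site == site &
                                        regions$cohort == group]
  } else if (group %in% DFS_GROUPS) {
    if (is.null(patients) || !"dfs_label" %in% names(patients)) {
      stop("DFS groups need a patient table with dfs_label")
    }
    pats <- patients$patient_id[!is.na(patients$dfs_label) &
                                  patients$dfs_label == group]
    keep_regions <- regions$region_id[regions$site == site &
                                        regions$patient_id %in% pats]
  } else {
    stop("unknown group token '", group, "'")
  }
  sel <- !is.na(cells$barcode) & cells$barcode == barcode &
    cells$region_id %in% keep_regions & cells$state %in% t_states
  n <- sum(sel)
  counts <- table(factor(cells$state[sel], levels = t_states))
  props <- if (n > 0) as.numeric(counts) / n else rep(0, length(t_states))
  list(barcode = barcode, site = site, group = group, n = n,
       proportions = stats::setNames(props, t_states), empty = n == 0)
}

#' Correlate barcodes by their expressing-state profiles
#'
#' Pearson correlation between the T-state proportion vectors of each pair
#' of (non-empty) profiles; symmetric with unit diagonal. A zero-variance
#' profile has no defined correlation and is assigned 0 off-diagonal with
#' a warning.
#'
#' @param profiles List of profiles from [barcode_state_proportions()].
#' @return Correlation matrix with one row/column per profile, labelled
#'   `"barcode @ site/group"` to keep duplicate barcodes from different
#'   models distinct.
#' @export
correlate_barcodes <- function(profiles) {
  profiles <- Filter(function(p) !p$empty, profiles)
  if (length(profiles) < 2L) stop("need at least two non-empty profiles")
  P <- t(vapply(profiles, `[[`, numeric(length(profiles[[1]]$proportions)),
                "proportions"))
  rownames(P) <- vapply(profiles, function(p)
    sprintf("%s @ %s/%s", p$barcode, p$site, p$group), "")
  sds <- apply(P, 1, stats::sd)
  r <- matrix(0, nrow(P), nrow(P), dimnames = list(rownames(P), rownames(P)))
  ok <- sds > 0
  if (any(!ok)) warning("zero-variance profile(s); correlations set to 0")
  if (any(ok)) r[ok, ok] <- stats::cor(t(P[ok, , drop = FALSE]))
  diag(r) <- 1
  r
}

#' Cluster barcodes on profile correlation
#'
#' Agglomerative clustering with average linkage on the distance `1 - r`;
#' the cluster count is a parameter (inspection of real data is what sets
#' it), and the dendrogram leaf order is returned for heatmap rendering.
#'
#' @param r Correlation matrix from [correlate_barcodes()].
#' @param n_clusters Number of clusters to cut.
#' @return List with `cluster` (named integer vector), `order` (leaf order)
#'   and the `hclust` object.
#' @export
cluster_barcodes <- function(r, n_clusters = 4) {
  if (n_clusters > nrow(r)) {
    stop("n_clusters exceeds the number of profiles")
  }
  if (nrow(r) == 1L) {
    return(list(cluster = stats::setNames(1L, rownames(r)), order = 1L,
                hclust = NULL))
  }
  hc <- stats::hclust(stats::as.dist(1 - r), method = "average")
  list(cluster = stats::cutree(hc, k = n_clusters), order = hc$order,
       hclust = hc)
}
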