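#' Neighborhood composition vectors
#'
#' For every seed cell, counts all cells (the seed included; its own
#' distance is 0) whose centroid lies within `radius_um` and expresses the
#' counts as proportions over the taxonomy leaves. Neighborhoods are
#' computed within each region independently; regions are separate tissue
#' frames.
#'
#' @param cells Cell table with states assigned (one or more regions).
#' @param config A `gating_config`.
#' @param radius_um Neighborhood radius in microns (60 by default).
#' @param include_seed Count the seed cell in its own neighborhood.
#' @return List: `comp` (cells x leaves proportion matrix, rownames =
#'   cell ids), `n_neighbors` (cells counted per neighborhood), and
#'   `region_id` per row.
#' @export
neighborhood_composition <- function(cells, config, radius_um = 60,
                                     include_seed = TRUE) {
  leaves <- taxonomy_leaves(config)
  if (is.null(cells$state)) stop("states must be assigned first")
  out_comp <- list(); out_n <- list(); out_reg <- list(); out_id <- list()
  for (r in unique(cells$region_id)) {
    rc <- cells[cells$region_id == r, , drop = FALSE]
    n <- nrow(rc)
    st <- factor(rc$state, levels = leaves)
    cnt <- matrix(0, n, length(leaves), dimnames = list(NULL, leaves))
    if (include_seed) cnt[cbind(seq_len(n), as.integer(st))] <- 1
    if (n > 1L) {
      p <- radius_pairs(rc$x_um, rc$y_um, radius_um)
      if (nrow(p)) {
        cnt <- cnt +
          as.matrix(table(factor(p[, 1], levels = seq_len(n)), st[p[, 2]])) +
          as.matrix(table(factor(p[, 2], levels = seq_len(n)), st[p[, 1]]))
      }
    }
    tot <- rowSums(cnt)
    keep <- tot > 0
    props <- cnt[keep, , drop = FALSE] / tot[keep]
    out_comp[[r]] <- props
    out_n[[r]] <- tot[keep]
    out_reg[[r]] <- rep(r, sum(keep))
    out_id[[r]] <- rc$cell_id[keep]
  }
  comp <- do.call(rbind, out_comp)
  rownames(comp) <- unlist(out_id, use.names = FALSE)
  list(comp = comp,
       n_neighbors = unlist(out_n, use.names = FALSE),
       region_id = unlist(out_reg, use.names = FALSE),
       radius_um = radius_um)
}

#' Elbow selection on an inertia curve
#'
#' Chooses the candidate K at maximum perpendicular distance from the
#' chord joining the first and last points of the min-max normalized
#' inertia curve (kneedle-style). The chord anchors themselves are never
#' selected; on a perfectly linear decay every interior distance is 0 and
#' the smallest interior candidate wins (documented tie-break).
#'
#' @param inertia Non-increasing within-cluster sum of squares per K.
#' @param k_values Candidate K values (parallel to `inertia`).
#' @return The selected K.
#' @export
elbow_k <- function(inertia, k_values = seq_along(inertia) + 1L) {
  if (length(inertia) < 3L) stop("elbow selection needs at least 3 candidates")
  stopifnot(length(inertia) == length(k_values))
  if (any(diff(inertia) > 1e-8 * max(abs(inertia)))) {
    stop("inertia must be non-increasing in K")
  }
  t <- (k_values - k_values[1]) / (k_values[length(k_values)] - k_values[1])
  rng <- inertia[1] - inertia[length(inertia)]
  h <- if (rng == 0) rep(0, length(inertia)) else
    (inertia - inertia[length(inertia)]) / rng
  d <- abs(t + h - 1) / sqrt(2)
  interior <- seq(2L, length(inertia) - 1L)
  best <- interior[which.max(d[interior])]  # which.max: smallest index on ties
  k_values[best]
}

#' Fit recurrent cellular neighborhoods by K-means
#'
#' Runs K-means (best of `n_restarts` starts, fixed seed) on the pooled
#' neighborhood compositions for every candidate K, checks that the
#' best-of-restarts inertia curve is non-increasing (refitting offenders
#' with more restarts), selects K by [elbow_k()], and relabels the winning
#' clusters by descending member count so RCN1 is always the largest.
#'
#' @param nbhd Output of [neighborhood_composition()] (or a bare
#'   composition matrix).
#' @param k_range Candidate cluster counts.
#' @param seed Integer seed.
#' @param n_restarts K-means restarts per candidate.
#' @return An `rcn_model`: `K`, `centroids`, `assignments` (named by cell
#'   id), `inertia`, `k_range`, `sizes`, plus the composition matrix.
#' @export
fit_rcn <- function(nbhd, k_range = 2:12, seed = 1, n_restarts = 10) {
  comp <- if (is.list(nbhd)) nbhd$comp else nbhd
  region_id <- if (is.list(nbhd)) nbhd$region_id else NULL
  if (nrow(comp) < max(k_range)) {
    stop("need at least max(k_range) = ", max(k_range), " compositions")
  }
  if (all(apply(comp, 2, function(v) max(v) - min(v)) == 0)) {
    warning("all compositions identical; falling back to a single RCN")
    assignments <- stats::setNames(rep(1L, nrow(comp)), rownames(comp))
    return(structure(
      list(K = 1L, centroids = comp[1, , drop = FALSE],
           assignments = assignments, inertia = NULL, k_range = k_range,
           sizes = nrow(comp), comp = comp, region_id = region_id,
           radius_um = if (is.list(nbhd)) nbhd$radius_um else NA),
      class = "rcn_model"))
  }

  fits <- vector("list", length(k_range))
  inertia <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    set.seed(seed + k_range[i])
    fits[[i]] <- stats::kmeans(comp, centers = k_range[i],
                               nstart = n_restarts, iter.max = 100)
    inertia[i] <- fits[[i]]$tot.withinss
  }
  # best-of-restarts inertia must not increase with K; refit violations
  for (attempt in 1:3) {
    bad <- which(diff(inertia) > 0) + 1L
    if (!length(bad)) break
    for (i in bad) {
      set.seed(seed + k_range[i] + 1000L * attempt)
      refit <- stats::kmeans(comp, centers = k_range[i],
                             nstart = n_restarts * 5L, iter.max = 100)
      if (refit$tot.withinss < inertia[i]) {
        fits[[i]] <- refit
        inertia[i] <- refit$tot.withinss
      }
    }
  }

  K <- elbow_k(inertia, k_range)
  win <- fits[[match(K, k_range)]]
  # stable labels: sort clusters by descending size
  ord <- order(-win$size)
  relabel <- integer(K); relabel[ord] <- seq_len(K)
  assignments <- stats::setNames(relabel[win$cluster], rownames(comp))
  centroids <- win$centers[ord, , drop = FALSE]
  rownames(centroids) <- paste0("RCN", seq_len(K))

  structure(
    list(K = K, centroids = centroids, assignments = assignments,
         inertia = stats::setNames(inertia, k_range), k_range = k_range,
         sizes = as.integer(win$size[ord]), comp = comp,
         region_id = region_id,
         radius_um = if (is.list(nbhd)) nbhd$radius_um else NA),
    class = "rcn_model"
  )
}

#' @export
print.rcn_model <- function(x, ...) {
  cat(sprintf("Recurrent cellular neighborhoods: K = %d over %d cells\n",
              x$K, length(x$assignments)))
  cat("  sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.rcn_model <- function(object, ...) {
  print(object)
  cat("Mean composition of each RCN (top 3 states):\n")
  for (k in seq_len(object$K)) {
    v <- sort(object$centroids[k, ], decreasing = TRUE)[1:3]
    cat(sprintf("  RCN%d: %s\n", k,
                paste(sprintf("%s %.2f", names(v), v), collapse = ", ")))
  }
  invisible(object)
}

#' Summaries of a fitted RCN model
#'
#' Mean member composition per RCN, per-region RCN proportions, and
#' exclusivity flags (is each RCN present in at least two regions and at
#' least two patients).
#'
#' @param model An `rcn_model`.
#' @param regions Region metadata (maps regions to patients).
#' @return List with `mean_composition`, `region_proportions`,
#'   `presence` data frame.
#' @export
rcn_summaries <- function(model, regions) {
  K <- model$K
  mean_comp <- t(vapply(seq_len(K), function(k) {
    colMeans(model$comp[model$assignments == k, , drop = FALSE])
  }, numeric(ncol(model$comp))))
  rownames(mean_comp) <- paste0("RCN", seq_len(K))

  reg <- model$region_id
  if (is.null(reg)) {
    # model fitted from a bare composition matrix: no region mapping
    return(list(mean_composition = mean_comp, region_proportions = NULL,
                presence = NULL))
  }
  tab <- table(factor(reg), factor(model$assignments, levels = seq_len(K)))
  region_props <- sweep(as.matrix(tab), 1, rowSums(tab), "/")
  colnames(region_props) <- paste0("RCN", seq_len(K))

  pat <- stats::setNames(regions$patient_id, regions$region_id)
  presence <- data.frame(
    rcn = paste0("RCN", seq_len(K)),
    n_regions = vapply(seq_len(K), function(k)
      length(unique(reg[model$assignments == k])), 0L),
    n_patients = vapply(seq_len(K), function(k)
      length(unique(pat[reg[model$assignments == k]])), 0L)
  )
  presence$recurrent <- presence$n_regions >= 2 & presence$n_patients >= 2
  list(mean_composition = mean_comp, region_proportions = region_props,
       presence = presence)
}

#' RCN residency of predictive barcoded T cells
#'
#' For each (barcode, DFS group) entry, the proportions of the model's
#' RCNs that the barcode's T cells reside in, restricted to cells from
#' patients of that DFS group. Rows sum to 1 before the log10+1 transform;
#' the transformed rows are hierarchically clustered (Ward linkage,
#' Euclidean distance) and cut into two groups, and each group's average
#' RCN-fraction profile is reported.
#'
#' @param model An `rcn_model` fitted on the treated IA regions.
#' @param cells Cell table with states and barcodes.
#' @param regions Region metadata.
#' @param patients Patient table with `dfs_label`.
#' @param top_barcodes Data frame with columns `barcode` and `group`.
#' @return List with `residency` (raw fractions), `transformed`,
#'   `cluster` (2-group cut), `profiles` (per-cluster mean fractions),
#'   `n_cells`, and the `hclust` object.
#' @export
barcode_rcn_residency <- function(model, cells, regions, patients,
                                  top_barcodes) {
  K <- model$K
  pat_lab <- stats::setNames(patients$dfs_label, patients$patient_id)
  reg_pat <- stats::setNames(regions$patient_id, regions$region_id)
  in_model <- cells$cell_id %in% names(model$assignments)
  rows <- list(); ns <- integer(0)
  for (i in seq_len(nrow(top_barcodes))) {
    b <- top_barcodes$barcode[i]; g <- top_barcodes$group[i]
    sel <- in_model & !is.na(cells$barcode) & cells$barcode == b &
      !is.na(pat_lab[reg_pat[cells$region_id]]) &
      pat_lab[reg_pat[cells$region_id]] == g
    n <- sum(sel)
    if (n == 0) {
      warning("barcode '", b, "' (", g, ") has no cells in scope; row dropped")
      next
    }
    rcn <- model$assignments[cells$cell_id[sel]]
    rows[[paste0(b, " (", g, ")")]] <-
      as.numeric(table(factor(rcn, levels = seq_len(K)))) / n
    ns <- c(ns, n)
  }
  if (!length(rows)) stop("no barcode has cells in scope")
  res <- do.call(rbind, rows)
  colnames(res) <- paste0("RCN", seq_len(K))
  trans <- log10(res + 1)
  if (nrow(res) >= 2) {
    hc <- stats::hclust(stats::dist(trans), method = "ward.D2")
    cl <- stats::cutree(hc, k = min(2L, nrow(res)))
  } else {
    hc <- NULL
    cl <- stats::setNames(1L, rownames(res))
  }
  profiles <- t(vapply(sort(unique(cl)), function(k)
    colMeans(res[cl == k, , drop = FALSE]), numeric(K)))
  rownames(profiles) <- paste0("C", sort(unique(cl)))
  list(residency = res, transformed = trans, cluster = cl,
       profiles = profiles, n_cells = stats::setNames(ns, rownames(res)),
       hclust = hc)
}

#' Fraction of flag-positive T cells per RCN
#'
#' Per RCN, the proportion of in-scope T cells positive for the functional
#' flag (Ki-67 proliferation or GrzB cytotoxicity), alongside the overall
#' proportion across all in-scope cells regardless of RCN. T_REG states
#' can be excluded (used for the GrzB analysis). Raw counts are reported
#' with the fractions because low-count RCNs deserve caution; an RCN with
#' zero in-scope T cells gets an undefined (NA) fraction with count 0.
#'
#' @param model An `rcn_model`.
#' @param cells Cell table with states assigned and the flag marker
#'   present.
#' @param config A `gating_config`.
#' @param flag_marker `"Ki-67"` or `"GrzB"`.
#' @param exclude_treg Drop T_REG states from the analysis.
#' @return List with `per_rcn` data frame (`rcn`, `n_t`, `n_pos`,
#'   `fraction`) and `baseline` (overall fraction).
#' @export
functional_fraction_by_rcn <- function(model, cells, config, flag_marker,
                                       exclude_treg = FALSE) {
  if (!flag_marker %in% names(cells)) {
    stop("flag marker '", flag_marker, "' not in the cell table")
  }
  t_states <- taxonomy_leaves(config, t_states_only = TRUE)
  if (exclude_treg) t_states <- setdiff(t_states, treg_leaves(config))
  sel <- cells$state %in% t_states & cells$cell_id %in% names(model$assignments)
  sub <- cells[sel, , drop = FALSE]
  rcn <- model$assignments[sub$cell_id]
  flag <- as.logical(sub[[flag_marker]])
  per <- do.call(rbind, lapply(seq_len(model$K), function(k) {
    n <- sum(rcn == k); np <- sum(flag[rcn == k])
    data.frame(rcn = paste0("RCN", k), n_t = n, n_pos = np,
               fraction = if (n > 0) np / n else NA_real_)
  }))
  baseline <- if (nrow(sub)) mean(flag) else NA_real_
  list(per_rcn = per, baseline = baseline)
}
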