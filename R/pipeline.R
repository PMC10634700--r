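# small stable hash so report bundles can detect config drift between runs
.config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  format(h, scientific = FALSE)
}

.prepare_cells <- function(cells, regions, patients, config,
                           require_dfs = FALSE) {
  rep <- validate_dataset(cells, regions, patients, require_dfs = require_dfs)
  if (any(rep$severity == "error")) {
    stop("dataset validation failed:\n",
         paste(rep$message[rep$severity == "error"], collapse = "\n"))
  }
  if (is.null(cells$state)) cells <- assign_states(cells, config)
  if (is.null(cells$barcode)) cells <- assign_barcodes(cells, config)
  cells
}

# per-site modelling + interpretation shared by both analyses
.model_site <- function(fm, regions, patients, task, site, seed, top_n,
                        share_k, C) {
  model <- run_lopo(fm, regions, patients, task = task, site = site,
                    C = C, seed = seed)
  tf <- top_features(model, top_n)

  reg <- regions[regions$site == site & regions$region_id %in% rownames(fm), ]
  if (task == "dfs") {
    reg <- reg[reg$cohort == "aCD40", ]
    lab <- stats::setNames(patients$dfs_label, patients$patient_id)[reg$patient_id]
  } else {
    lab <- reg$cohort
  }
  mw <- mann_whitney_feature_test(fm[reg$region_id, , drop = FALSE],
                                  as.character(lab), tf$feature)
  adj <- bh_adjust(mw$p)
  mw$q <- adj$q
  mw$significant <- adj$significant

  list(model = model, top_features = tf,
       top30_share = top_importance_share(model, share_k), stats = mw)
}

# top barcode features -> expressing-state profiles, correlation, clusters
.barcode_interpretation <- function(site_results, cells, regions, patients,
                                    config, n_clusters = 4) {
  profiles <- list()
  for (site in names(site_results)) {
    tf <- site_results[[site]]$top_features
    model <- site_results[[site]]$model
    bc <- tf[startsWith(tf$feature, "barcode:"), , drop = FALSE]
    for (i in seq_len(nrow(bc))) {
      name <- sub("^barcode:", "", bc$feature[i])
      grp <- if (bc$direction[i] >= 0) model$positive_class else
        setdiff(unique(model$labels), model$positive_class)[1]
      profiles[[length(profiles) + 1L]] <-
        barcode_state_proportions(cells, regions, config, name, site, grp,
                                  patients = patients)
    }
  }
  profiles <- Filter(function(p) !p$empty, profiles)
  if (length(profiles) < 2L) {
    return(list(profiles = profiles, correlation = NULL, clusters = NULL))
  }
  r <- correlate_barcodes(profiles)
  cl <- cluster_barcodes(r, n_clusters = min(n_clusters, nrow(r)))
  list(profiles = profiles, correlation = r, clusters = cl)
}

.write_bundle <- function(bundle, out_dir, fm) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  metrics <- lapply(bundle$sites, function(s) {
    list(accuracy = s$model$accuracy, f1 = s$model$f1, auc = s$model$auc,
         top30_share = s$top30_share)
  })
  jsonlite::write_json(
    list(task = bundle$task, seed = bundle$seed,
         config_hash = bundle$config_hash, metrics = metrics),
    file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  write_feature_matrix(fm, file.path(out_dir, "features.csv"))
  imp <- do.call(rbind, lapply(names(bundle$sites), function(s) {
    tf <- bundle$sites[[s]]$top_features
    cbind(site = s, tf)
  }))
  .write_csv_schema(imp, file.path(out_dir, "importance.csv"))
  pq <- do.call(rbind, lapply(names(bundle$sites), function(s) {
    cbind(site = s, bundle$sites[[s]]$stats)
  }))
  .write_csv_schema(pq, file.path(out_dir, "pq.csv"))
  if (!is.null(bundle$rcn)) {
    rdir <- file.path(out_dir, "rcn")
    dir.create(rdir, showWarnings = FALSE)
    .write_csv_schema(
      data.frame(cell_id = names(bundle$rcn$model$assignments),
                 rcn = bundle$rcn$model$assignments),
      file.path(rdir, "assignments.csv"))
    .write_csv_schema(
      data.frame(rcn = rownames(bundle$rcn$model$centroids),
                 bundle$rcn$model$centroids, check.names = FALSE),
      file.path(rdir, "centroids.csv"))
    if (!is.null(bundle$rcn$residency)) {
      .write_csv_schema(
        data.frame(row = rownames(bundle$rcn$residency$residency),
                   bundle$rcn$residency$residency, check.names = FALSE),
        file.path(rdir, "residency.csv"))
    }
  }
  invisible(out_dir)
}

#' End-to-end treatment-status analysis
#'
#' Phenotypes the cells, computes the three feature families, fits one
#' leave-one-patient-out elastic-net model per histopathologic site to
#' predict treatment status, extracts the top features with their SHAP
#' directions and the top-30 importance share, tests the top features
#' between cohorts (Mann-Whitney with Benjamini-Hochberg correction), and
#' clusters the predictive barcodes by their expressing-state profiles.
#'
#' @param cells,regions,patients The three input tables.
#' @param config A `gating_config`.
#' @param seed Integer seed; with the inputs and parameters it fully
#'   determines the report bundle.
#' @param radius_um Interaction radius.
#' @param top_n Top features carried into stats and barcode stages.
#' @param share_k Features counted in the importance-share summary.
#' @param C Elastic-net inverse regularization strength.
#' @param sites Sites to model.
#' @param out_dir Optional directory for the written report bundle.
#' @return Report bundle (list) with per-site models and interpretation.
#' @export
run_treatment_analysis <- function(cells, regions, patients,
                                   config = load_gating_config(), seed = 1,
                                   radius_um = 20, top_n = 15, share_k = 30,
                                   C = 1, sites = SITES, out_dir = NULL) {
  cells <- .prepare_cells(cells, regions, patients, config)
  fm <- build_feature_matrix(cells, regions, config, radius_um)
  site_results <- lapply(stats::setNames(sites, sites), function(s)
    .model_site(fm, regions, patients, "treatment", s, seed, top_n,
                share_k, C))
  barcodes <- .barcode_interpretation(site_results, cells, regions, patients,
                                      config)
  bundle <- list(
    task = "treatment", seed = seed,
    config_hash = .config_hash(list(seed, radius_um, top_n, share_k, C,
                                    sites, taxonomy_leaves(config))),
    n_features = ncol(fm), n_regions = nrow(fm),
    sites = site_results, barcodes = barcodes
  )
  if (!is.null(out_dir)) .write_bundle(bundle, out_dir, fm)
  bundle
}

#' End-to-end disease-free-survival analysis of the treated cohort
#'
#' Labels treated patients long/short by the median DFS split, fits
#' per-site LOPO elastic-net models (T, IA, TAS; NAP has too few regions
#' and is never modelled), reports the same interpretation stages as the
#' treatment analysis, and then runs the spatial stage on the treated IA
#' regions: 60-um neighborhood compositions, K-means RCNs with elbow
#' selection, residency clustering of the IA model's top predictive
#' barcodes, and per-RCN Ki-67 / GrzB fractions (T_REGs excluded for
#' GrzB).
#'
#' @inheritParams run_treatment_analysis
#' @param rcn_radius_um Neighborhood radius for the RCN stage.
#' @param k_range Candidate K values for the RCN K-means.
#' @return Report bundle (list); the `rcn` element holds the spatial stage.
#' @export
run_dfs_analysis <- function(cells, regions, patients,
                             config = load_gating_config(), seed = 1,
                             radius_um = 20, top_n = 15, share_k = 30,
                             C = 1, rcn_radius_um = 60, k_range = 2:12,
                             out_dir = NULL) {
  patients <- derive_dfs_labels(patients)
  cells <- .prepare_cells(cells, regions, patients, config,
                          require_dfs = TRUE)
  fm <- build_feature_matrix(cells, regions, config, radius_um)
  sites <- setdiff(SITES, "NAP")
  site_results <- lapply(stats::setNames(sites, sites), function(s)
    .model_site(fm, regions, patients, "dfs", s, seed, top_n, share_k, C))
  barcodes <- .barcode_interpretation(site_results, cells, regions, patients,
                                      config)

  # spatial stage: treated IA regions only
  ia_regions <- regions$region_id[regions$site == "IA" &
                                    regions$cohort == "aCD40"]
  ia_cells <- cells[cells$region_id %in% ia_regions, , drop = FALSE]
  nbhd <- neighborhood_composition(ia_cells, config, rcn_radius_um)
  rcn_model <- fit_rcn(nbhd, k_range = k_range, seed = seed)
  summaries <- rcn_summaries(rcn_model, regions)

  tf_ia <- site_results[["IA"]]$top_features
  bc <- tf_ia[startsWith(tf_ia$feature, "barcode:"), , drop = FALSE]
  residency <- NULL
  if (nrow(bc) >= 1) {
    top_bc <- data.frame(
      barcode = sub("^barcode:", "", bc$feature),
      group = ifelse(bc$direction >= 0, "long", "short"),
      stringsAsFactors = FALSE)
    residency <- barcode_rcn_residency(rcn_model, ia_cells, regions,
                                       patients, top_bc)
  }
  ki67 <- functional_fraction_by_rcn(rcn_model, ia_cells, config, "Ki-67",
                                     exclude_treg = FALSE)
  grzb <- functional_fraction_by_rcn(rcn_model, ia_cells, config, "GrzB",
                                     exclude_treg = TRUE)

  bundle <- list(
    task = "dfs", seed = seed,
    config_hash = .config_hash(list(seed, radius_um, top_n, share_k, C,
                                    rcn_radius_um, k_range,
                                    taxonomy_leaves(config))),
    dfs_median = attr(patients, "dfs_median"),
    n_features = ncol(fm), n_regions = nrow(fm),
    sites = site_results, barcodes = barcodes,
    rcn = list(model = rcn_model, summaries = summaries,
               residency = residency, ki67 = ki67, grzb = grzb)
  )
  if (!is.null(out_dir)) .write_bundle(bundle, out_dir, fm)
  bundle
}
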