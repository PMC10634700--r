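#' Default planted effects for the synthetic cohort
#'
#' Multiplicative shifts applied to state frequencies and per-marker
#' barcode probabilities. `treatment` shifts apply to every aCD40 region
#' (relative to naive); `dfs` shifts apply to regions -- in the listed
#' sites -- of treated patients planted in the long-DFS group (relative to
#' short). Multipliers above 1 enrich the aCD40 / long group, below 1
#' deplete it, mirroring the effect directions the analysis is meant to
#' recover (e.g. CD44/T-BET enrichment under treatment, TOX1/PD-1
#' enrichment with short survival).
#'
#' @return Nested list understood by [synth_config()].
#' @export
synth_effects <- function() {
  list(
    treatment = list(
      state_mult = c("CD44+ Th1 T_OTHER" = 2.0, "Th1 T_EM" = 2.0,
                     "Mesenchymal" = 1.8, "T_EX" = 1.5, "CD44+ T_OTHER" = 1.5,
                     "B cell" = 0.6, "T_NAIVE" = 0.6),
      marker_mult = c("CD44" = 1.8, "T-BET" = 1.8, "CD39" = 1.6,
                      "TIM3" = 1.4, "TCF-1" = 1.4, "TOX1" = 0.5, "EOMES" = 0.5)
    ),
    dfs = list(
      state_mult = c("CD44+ Th1 T_OTHER" = 2.2, "Th1 T_EM" = 1.8),
      marker_mult = c("CD44" = 1.6, "CD38" = 1.5, "CD39" = 1.5, "TIM3" = 1.4,
                      "LAG-3" = 1.5, "TOX1" = 0.5, "PD-1" = 0.55),
      sites = "IA"
    )
  )
}

# site-specific baseline frequencies over the default 23-leaf taxonomy;
# T cell mass is split CD4:CD8 roughly 2:1 with most cells in the
# CD44-stratified "other" states, matching the structure of real mIHC data
.default_state_freq <- function(leaves) {
  lineage <- list(
    T   = c(epi = .52, mes = .14, mye = .10, b = .02, oth = .04, tc = .18),
    IA  = c(epi = .02, mes = .04, mye = .08, b = .25, oth = .04, tc = .57),
    TAS = c(epi = .20, mes = .22, mye = .16, b = .04, oth = .05, tc = .33),
    NAP = c(epi = .10, mes = .15, mye = .40, b = .03, oth = .07, tc = .25)
  )
  cd8 <- c("T_NAIVE" = .04, "T_EFF" = .02, "T_EM" = .03, "T_EMRA" = .02,
           "T_EX" = .05, "T_TEX" = .04, "CD44+ T_OTHER" = .35,
           "CD44- T_OTHER" = .45)
  cd4 <- c("Naive T_REG" = .08, "mT_REG" = .08, "T-BET+ T_REG" = .04,
           "Th1 T_EFF" = .02, "Th1 T_EM" = .05, "Th1 T_EMRA" = .02,
           "CD44+ Th1 T_OTHER" = .12, "CD44- Th1 T_OTHER" = .09,
           "CD44+ Th" = .25, "CD44- Th" = .25)
  tdist <- c(cd8 / sum(cd8) * (1 / 3), cd4 / sum(cd4) * (2 / 3))
  out <- lapply(lineage, function(l) {
    v <- stats::setNames(numeric(length(leaves)), leaves)
    v["Neoplastic epithelial"] <- l["epi"]
    v["Mesenchymal"] <- l["mes"]
    v["Myeloid"] <- l["mye"]
    v["B cell"] <- l["b"]
    v["Other"] <- l["oth"]
    v[names(tdist)] <- l["tc"] * tdist
    v / sum(v)
  })
  out
}

#' Configuration for the synthetic mIHC cohort generator
#'
#' Defaults describe the study conditions the package is validated under:
#' 18 treatment-naive and 11 aCD40-treated patients, a fixed complement of
#' regions per patient across the four histopathologic sites, clustered
#' spatial point patterns (Gaussian immune aggregates) in IA regions, and
#' the planted treatment/DFS effects of [synth_effects()].
#'
#' @param seed Master integer seed; every random draw descends from it.
#' @param n_patients Named counts per cohort.
#' @param regions_per_patient Named region counts per site for each patient.
#' @param area_mm2 Named tissue area per site (mm^2).
#' @param cells_per_region Cells generated per region (>= 1).
#' @param state_freq Optional list site -> probability vector over leaves
#'   (must sum to 1 within 1e-9); defaults to built-in frequencies.
#' @param barcode_p Baseline Bernoulli probability per barcode marker.
#' @param flag_p Baseline probabilities for the Ki-67 and GrzB flags.
#' @param lineage_noise_p Background positivity for unconstrained lineage
#'   markers.
#' @param spatial List site -> spatial model: `list(model = "uniform")` or
#'   `list(model = "clustered", n_clusters =, cluster_sd_um =)`.
#' @param effects Planted effect specification ([synth_effects()]) or
#'   `NULL` for a null cohort with no group differences.
#' @param dfs Log-normal DFS parameters for the planted long/short groups
#'   and the number of treated patients planted long.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1,
                         n_patients = c(naive = 18, aCD40 = 11),
                         regions_per_patient = c(T = 3, IA = 2, TAS = 2, NAP = 1),
                         area_mm2 = c(T = 0.6, IA = 0.25, TAS = 0.5, NAP = 0.7),
                         cells_per_region = 250,
                         state_freq = NULL,
                         barcode_p = c("TOX1" = .15, "TIM3" = .12, "TCF-1" = .20,
                                       "CD38" = .18, "PD-1" = .15, "EOMES" = .12,
                                       "CD39" = .15, "CD44" = .30, "LAG-3" = .08,
                                       "T-BET" = .20),
                         flag_p = c("Ki-67" = .15, "GrzB" = .08),
                         lineage_noise_p = 0.02,
                         spatial = NULL,
                         effects = synth_effects(),
                         dfs = list(long_meanlog = log(20),
                                    short_meanlog = log(5),
                                    sdlog = 0.25, n_long = 5)) {
  if (cells_per_region < 1) stop("config error: cells_per_region must be >= 1")
  if (any(area_mm2 <= 0)) stop("config error: area_mm2 must be positive")
  stopifnot(all(names(regions_per_patient) %in% SITES),
            all(names(n_patients) %in% COHORTS))
  if (is.null(spatial)) {
    spatial <- list(
      T = list(model = "uniform"),
      IA = list(model = "clustered", n_clusters = 3, cluster_sd_um = 40),
      TAS = list(model = "uniform"),
      NAP = list(model = "uniform")
    )
  }
  for (sp in spatial) {
    if (identical(sp$model, "clustered") &&
        (is.null(sp$cluster_sd_um) || sp$cluster_sd_um <= 0)) {
      stop("config error: cluster_sd_um must be positive")
    }
  }
  if (!is.null(state_freq)) {
    for (s in names(state_freq)) {
      v <- state_freq[[s]]
      if (any(v < 0) || any(v > 1) || abs(sum(v) - 1) > 1e-9) {
        stop("config error: state_freq[['", s,
             "']] is not a probability vector")
      }
    }
  }
  structure(
    list(seed = as.integer(seed), n_patients = n_patients,
         regions_per_patient = regions_per_patient, area_mm2 = area_mm2,
         cells_per_region = as.integer(cells_per_region),
         state_freq = state_freq, barcode_p = barcode_p, flag_p = flag_p,
         lineage_noise_p = lineage_noise_p, spatial = spatial,
         effects = effects, dfs = dfs),
    class = "synth_config"
  )
}

# clamp probabilities into [0,1]; warn when a planted shift pushed one out
.clamp_probs <- function(p) {
  if (any(p < 0 | p > 1)) {
    warning("barcode probability outside [0,1] after effect shift; clamped")
    p <- pmin(pmax(p, 0), 1)
  }
  p
}

# per-marker Bernoulli probabilities for one region's T cells
.region_marker_p <- function(cfg, cohort, dfs_label, site) {
  p <- cfg$barcode_p[BARCODE_MARKERS]
  ef <- cfg$effects
  if (!is.null(ef) && cohort == "aCD40" && !is.null(ef$treatment$marker_mult)) {
    mm <- ef$treatment$marker_mult
    p[names(mm)] <- p[names(mm)] * mm
  }
  if (!is.null(ef) && cohort == "aCD40" && !is.na(dfs_label) &&
      dfs_label == "long" && site %in% (ef$dfs$sites %||% SITES) &&
      !is.null(ef$dfs$marker_mult)) {
    mm <- ef$dfs$marker_mult
    p[names(mm)] <- p[names(mm)] * mm
  }
  .clamp_probs(p)
}

# state frequency vector for one region after planted multiplicative shifts
.region_state_freq <- function(cfg, freq, cohort, dfs_label, site) {
  f <- freq
  ef <- cfg$effects
  if (!is.null(ef) && cohort == "aCD40" && !is.null(ef$treatment$state_mult)) {
    sm <- ef$treatment$state_mult
    f[names(sm)] <- f[names(sm)] * sm
  }
  if (!is.null(ef) && cohort == "aCD40" && !is.na(dfs_label) &&
      dfs_label == "long" && site %in% (ef$dfs$sites %||% SITES) &&
      !is.null(ef$dfs$state_mult)) {
    sm <- ef$dfs$state_mult
    f[names(sm)] <- f[names(sm)] * sm
  }
  f / sum(f)
}

#' Sample one functionality barcode for a planted T state
#'
#' Independent per-marker Bernoulli draws at the (cohort, DFS, site)
#' adjusted probabilities; bits fixed by the state's gating predicate
#' (e.g. CD44 for "CD44+ T_OTHER") override the draw so the generated
#' positivity always satisfies the planted state.
#'
#' @param state A T-state leaf label.
#' @param cohort,dfs_label,site Region context.
#' @param cfg A `synth_config`.
#' @param config A `gating_config`.
#' @return Canonical barcode name.
#' @export
sample_barcode <- function(state, cohort, dfs_label, site, cfg, config) {
  tx <- config$taxonomy
  if (!state %in% tx$leaf[tx$t_state]) stop("'", state, "' is not a T state")
  p <- .region_marker_p(cfg, cohort, dfs_label, site)
  bits <- stats::runif(length(p)) < p
  names(bits) <- BARCODE_MARKERS
  con <- derive_state_constraints(config, state)
  bits[intersect(con$pos, BARCODE_MARKERS)] <- TRUE
  bits[intersect(con$neg, BARCODE_MARKERS)] <- FALSE
  barcode_name(bits)
}

#' Generate one region's cells
#'
#' States are drawn from the (effect-adjusted) site frequency vector;
#' coordinates come from the site's spatial model inside a square of the
#' region's area (clustered mode places Gaussian clusters emulating immune
#' aggregates, with T and B cells preferentially assigned to them); marker
#' positivity is Bernoulli at the adjusted probabilities with the planted
#' state's gating constraints forced, so phenotyping recovers every
#' planted state exactly.
#'
#' @param region One-row region metadata (id, site, area_mm2).
#' @param cohort,dfs_label Patient context for planted effects.
#' @param cfg A `synth_config`.
#' @param config A `gating_config`.
#' @param sub_seed Integer RNG stream seed for this region.
#' @param constraints Precomputed per-leaf constraints (internal reuse).
#' @return Cell table fragment; attribute `clusters` records the planted
#'   cluster centers and per-cell cluster assignment in clustered mode.
#' @export
generate_region <- function(region, cohort, dfs_label, cfg, config, sub_seed,
                            constraints = NULL) {
  site <- region$site
  if (region$area_mm2 <= 0) stop("config error: region area must be positive")
  set.seed(sub_seed)
  n <- cfg$cells_per_region
  leaves <- taxonomy_leaves(config)
  freq <- (cfg$state_freq %||% .default_state_freq(leaves))[[site]]
  freq <- .region_state_freq(cfg, freq[leaves], cohort, dfs_label, site)
  states <- sample(leaves, n, replace = TRUE, prob = freq)

  side <- sqrt(region$area_mm2) * 1000  # microns
  sp <- cfg$spatial[[site]] %||% list(model = "uniform")
  cluster_of <- rep(NA_integer_, n)
  centers <- NULL
  if (identical(sp$model, "clustered")) {
    ncl <- sp$n_clusters %||% 3
    sd <- sp$cluster_sd_um
    margin <- min(3 * sd, side / 2)
    centers <- cbind(stats::runif(ncl, margin, side - margin),
                     stats::runif(ncl, margin, side - margin))
    tx <- config$taxonomy
    aggregate_states <- c(tx$leaf[tx$t_state], "B cell")
    eligible <- states %in% aggregate_states
    in_cluster <- eligible & stats::runif(n) < 0.85
    cluster_of[in_cluster] <- sample.int(ncl, sum(in_cluster), replace = TRUE)
    x <- stats::runif(n, 0, side)
    y <- stats::runif(n, 0, side)
    ic <- which(in_cluster)
    if (length(ic)) {
      x[ic] <- centers[cluster_of[ic], 1] + stats::rnorm(length(ic), 0, sd)
      y[ic] <- centers[cluster_of[ic], 2] + stats::rnorm(length(ic), 0, sd)
      x[ic] <- pmin(pmax(x[ic], 0), side)
      y[ic] <- pmin(pmax(y[ic], 0), side)
    }
  } else {
    x <- stats::runif(n, 0, side)
    y <- stats::runif(n, 0, side)
  }

  panel <- config$panel
  p <- stats::setNames(rep(cfg$lineage_noise_p, length(panel)), panel)
  p[BARCODE_MARKERS] <- .region_marker_p(cfg, cohort, dfs_label, site)
  p[names(cfg$flag_p)] <- cfg$flag_p
  M <- matrix(stats::runif(n * length(panel)) <
                rep(p, each = n), n, length(panel),
              dimnames = list(NULL, panel))
  if (is.null(constraints)) {
    constraints <- lapply(stats::setNames(leaves, leaves),
                          derive_state_constraints, config = config)
  }
  for (s in unique(states)) {
    rows <- which(states == s)
    con <- constraints[[s]]
    if (length(con$pos)) M[rows, con$pos] <- TRUE
    if (length(con$neg)) M[rows, con$neg] <- FALSE
  }

  cells <- data.frame(
    cell_id = paste0(region$region_id, "_c", seq_len(n)),
    region_id = region$region_id,
    x_um = x, y_um = y,
    stringsAsFactors = FALSE
  )
  for (m in panel) cells[[m]] <- M[, m]
  attr(cells, "markers") <- panel
  attr(cells, "planted_state") <- states
  if (!is.null(centers)) {
    attr(cells, "clusters") <- list(centers = centers, cluster = cluster_of)
  }
  cells
}

#' Generate a full synthetic mIHC cohort
#'
#' Deterministic given the config seed: patient-level draws use the master
#' seed and each region uses a named sub-stream derived from its (patient,
#' site, replicate) triple, so adding a region never perturbs any other.
#' DFS months for treated patients are drawn from two shifted log-normals
#' so the median split recovers the planted long/short grouping.
#'
#' @param cfg A `synth_config`.
#' @param config A `gating_config` (defaults to the shipped hierarchy).
#' @return List with `cells`, `regions`, `patients` and `truth` (planted
#'   per-cell states, per-patient DFS groups, and the planted effect spec).
#' @export
generate_cohort <- function(cfg = synth_config(), config = load_gating_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  leaves <- taxonomy_leaves(config)
  constraints <- lapply(stats::setNames(leaves, leaves),
                        derive_state_constraints, config = config)

  set.seed(cfg$seed)
  pats <- list(); k <- 0L
  for (cohort in names(cfg$n_patients)) {
    for (i in seq_len(cfg$n_patients[[cohort]])) {
      k <- k + 1L
      pats[[k]] <- data.frame(
        patient_id = sprintf("%s%02d", if (cohort == "naive") "N" else "A", i),
        cohort = cohort, stringsAsFactors = FALSE)
    }
  }
  patients <- do.call(rbind, pats)
  patients$dfs_months <- NA_real_
  dfs_group <- stats::setNames(rep(NA_character_, nrow(patients)),
                               patients$patient_id)
  trt <- which(patients$cohort == "aCD40")
  if (length(trt)) {
    n_long <- min(cfg$dfs$n_long %||% ceiling(length(trt) / 2), length(trt))
    long_idx <- trt[seq_len(n_long)]
    short_idx <- setdiff(trt, long_idx)
    dfs_group[patients$patient_id[long_idx]] <- "long"
    dfs_group[patients$patient_id[short_idx]] <- "short"
    patients$dfs_months[long_idx] <-
      stats::rlnorm(length(long_idx), cfg$dfs$long_meanlog, cfg$dfs$sdlog)
    patients$dfs_months[short_idx] <-
      stats::rlnorm(length(short_idx), cfg$dfs$short_meanlog, cfg$dfs$sdlog)
  }

  regions <- list(); cells <- list(); planted <- list(); r <- 0L
  for (pi in seq_len(nrow(patients))) {
    pid <- patients$patient_id[pi]
    cohort <- patients$cohort[pi]
    for (si in seq_along(cfg$regions_per_patient)) {
      site <- names(cfg$regions_per_patient)[si]
      for (rep_i in seq_len(cfg$regions_per_patient[[si]])) {
        r <- r + 1L
        reg <- data.frame(
          region_id = sprintf("%s_%s_%d", pid, site, rep_i),
          patient_id = pid, cohort = cohort, site = site,
          area_mm2 = cfg$area_mm2[[site]], stringsAsFactors = FALSE)
        regions[[r]] <- reg
        sub_seed <- (abs(cfg$seed) * 7919L + pi * 1009L + si * 101L + rep_i) %%
          2147483629L
        frag <- generate_region(reg, cohort, dfs_group[[pid]], cfg, config,
                                sub_seed, constraints)
        cells[[r]] <- frag
        planted[[r]] <- data.frame(cell_id = frag$cell_id,
                                   state = attr(frag, "planted_state"),
                                   stringsAsFactors = FALSE)
      }
    }
  }
  regions <- do.call(rbind, regions)
  markers <- attr(cells[[1]], "markers")
  cells <- do.call(rbind, lapply(cells, function(f) {
    attr(f, "planted_state") <- NULL
    attr(f, "clusters") <- NULL
    f
  }))
  attr(cells, "markers") <- markers

  list(
    cells = cells, regions = regions, patients = patients,
    truth = list(states = do.call(rbind, planted),
                 dfs_group = dfs_group[!is.na(dfs_group)],
                 effects = cfg$effects)
  )
}

#' Feature keys carrying a planted effect
#'
#' Maps the planted effect specification onto feature-matrix column names:
#' density columns of shifted states and barcode columns containing a
#' shifted marker. Used by recovery tests to check that model
#' interpretation surfaces at least one genuinely planted feature.
#'
#' @param effects Effect spec (e.g. `truth$effects`).
#' @param feature_names Column names of a feature matrix.
#' @param task `"treatment"` or `"dfs"`.
#' @return Character vector of planted feature column names.
#' @export
planted_feature_keys <- function(effects, feature_names, task = "treatment") {
  ef <- effects[[task]]
  if (is.null(ef)) return(character())
  keys <- character()
  if (!is.null(ef$state_mult)) {
    keys <- c(keys, paste0("density:", names(ef$state_mult)))
  }
  if (!is.null(ef$marker_mult)) {
    bc <- grep("^barcode:", feature_names, value = TRUE)
    for (m in names(ef$marker_mult)) {
      keys <- c(keys, bc[grepl(paste0(m, "+"), bc, fixed = TRUE)])
    }
  }
  intersect(unique(keys), feature_names)
}
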