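# End-to-end orchestration: simulate a seascape and tracks, preprocess into
# trips, fit movement models and UDs per individual, quantify segregation,
# score glacier-front use, and run the inference suite.

#' Run the full segregation analysis on a synthetic study
#'
#' Executes the whole pipeline on data generated from a [sim_config()]:
#' simulation, trip segmentation (10-min subsampling, 80 km/h speed filter,
#' 200-m colony radius, 50-min minimum duration, over-land filter),
#' per-individual movement-model selection and AKDE (effective-sample-size
#' threshold 4.5), the pairwise segregation matrix with global/pairwise
#' ANOSIM and dispersion homogeneity, the binomial GLMM of front use
#' against colony-front distance with its likelihood-ratio test and
#' conditional R-squared, and the MRM of segregation against colony-size
#' difference, colony separation and front-use dissimilarity.
#'
#' @param config a [sim_config()].
#' @param n_perm permutations for all permutation tests, default 999.
#' @param seed seed for the inference-stage permutation engines (the
#'   simulation uses `config$seed`).
#' @param model_kinds candidate movement models, default all three.
#' @param narea_threshold minimum effective sample size, default 4.5.
#' @param cell UD grid cell size (m), default 500.
#' @param buffer_radius_m front buffer radius (m), default 400.
#' @param colony_radius_m,min_trip_min,vmax_kmh,land_threshold trip
#'   filters; defaults 200 m, 50 min, 80 km/h, 0.5.
#' @param dispersion_check run the simulation-based GLMM dispersion check
#'   (default TRUE).
#' @return list with the seascape, truth record, preprocessing log, fitted
#'   models, UDs, segregation matrix, ANOSIM results, GLMM results (fit,
#'   distance LRT, conditional R-squared, dispersion p), front-use profiles,
#'   DH matrix and MRM result.
#' @export
run_pipeline <- function(config, n_perm = 999, seed = 1L,
                         model_kinds = c("iid", "ou", "ouf"),
                         narea_threshold = 4.5, cell = 500,
                         buffer_radius_m = 400, colony_radius_m = 200,
                         min_trip_min = 50, vmax_kmh = 80,
                         land_threshold = 0.5, dispersion_check = TRUE) {
  seascape <- simulate_seascape(config)
  sim <- simulate_tracks(config, seascape)
  centre <- seascape$centre
  pre <- preprocess_fixes(sim$fixes, seascape$colonies, seascape$land,
                          interval_min = config$fix_interval,
                          vmax_kmh = vmax_kmh, radius_m = colony_radius_m,
                          min_duration_min = min_trip_min,
                          land_threshold = land_threshold)
  trips_by_ind <- split(pre$trips,
                        vapply(pre$trips, `[[`, "", "individual_id"))

  # movement models + UDs (consecutive complete trips concatenated; trip
  # fixes are already outside the colony area)
  uds <- list()
  models <- list()
  excluded <- character(0)
  for (id in names(trips_by_ind)) {
    trs <- trips_by_ind[[id]]
    fx <- do.call(rbind, lapply(trs, `[[`, "fixes"))
    fx <- fx[order(fx$time), , drop = FALSE]
    if (nrow(fx) < 10) {
      excluded <- c(excluded, id)
      next
    }
    xy <- to_local_xy(cbind(fx$lon, fx$lat), centre)
    cands <- fit_movement_models(xy, fx$time, model_kinds)
    mod <- tryCatch(select_model(cands), error = function(e) NULL)
    if (is.null(mod) || !is.finite(mod$N_area) ||
        mod$N_area < narea_threshold) {
      excluded <- c(excluded, id)
      next
    }
    models[[id]] <- mod
    uds[[id]] <- akde(xy, mod, cell = cell,
                      narea_threshold = narea_threshold)
  }

  truth_ind <- sim$truth$individuals
  colony_of <- function(ids) {
    truth_ind$colony_id[match(ids, truth_ind$individual_id)]
  }

  # segregation + ANOSIM (colonies with < 2 retained individuals cannot
  # enter the group test)
  seg <- NULL
  anosim_global <- NULL
  anosim_pairs <- NULL
  dispersion <- NULL
  if (length(uds) >= 2) {
    seg <- segregation_matrix(uds, colony_of(names(uds)))
    grp <- attr(seg, "colony")
    keep <- grp %in% names(which(table(grp) >= 2))
    if (sum(keep) >= 4 && length(unique(grp[keep])) >= 2) {
      sm <- as.matrix(seg)[keep, keep]
      anosim_global <- anosim(sm, grp[keep], n_perm, seed)
      anosim_pairs <- pairwise_anosim(sm, grp[keep], n_perm, seed + 1000L)
      dispersion <- tryCatch(
        dispersion_homogeneity(sm, grp[keep], n_perm, seed + 2000L),
        error = function(e) NULL)
    }
  }

  # glacier-front use scoring and the distance GLMM
  glmm <- NULL
  front_table <- NULL
  profiles <- NULL
  dh <- NULL
  mrm_res <- NULL
  if (length(seascape$fronts) > 0 && length(pre$trips) > 0) {
    d_cf <- colony_front_distances(seascape$colonies, seascape$fronts,
                                   centre)
    rows <- lapply(pre$trips, function(tr) {
      use <- trip_front_use(tr, seascape$fronts, centre, buffer_radius_m)
      data.frame(individual = tr$individual_id, trip_id = tr$trip_id,
                 colony = tr$colony_id, front_id = names(use),
                 used = as.integer(use),
                 distance_km = d_cf[tr$colony_id, names(use)],
                 stringsAsFactors = FALSE)
    })
    front_table <- do.call(rbind, rows)
    rownames(front_table) <- NULL
    front_table$sex <- truth_ind$sex[match(front_table$individual,
                                           truth_ind$individual_id)]
    glmm <- tryCatch(
      .fit_front_glmm(front_table, dispersion_check, seed + 3000L),
      error = function(e) list(error = conditionMessage(e)))

    profiles <- lapply(trips_by_ind, use_profile, fronts = seascape$fronts,
                       centre = centre, radius_m = buffer_radius_m)
    used_ids <- names(profiles)[!vapply(profiles, `[[`, TRUE, "excluded")]
    common <- intersect(used_ids, if (is.null(seg)) character(0)
                        else rownames(seg))
    if (length(common) >= 4) {
      dh <- dh_matrix(profiles[common])
      pm <- build_predictor_matrices(
        data.frame(individual_id = common,
                   colony_id = colony_of(common),
                   stringsAsFactors = FALSE),
        seascape$colonies, centre)
      mrm_res <- mrm(as.matrix(seg)[common, common],
                     list(size = pm$size, separation = pm$separation,
                          dh = dh[common, common]),
                     n_perm, seed + 4000L)
    }
  }

  list(config = config, seascape = seascape, truth = sim$truth,
       fixes = sim$fixes, preprocess = pre, models = models, uds = uds,
       excluded_individuals = excluded, segregation = seg,
       anosim_global = anosim_global, anosim_pairwise = anosim_pairs,
       dispersion = dispersion, front_table = front_table, glmm = glmm,
       profiles = profiles, dh = dh, mrm = mrm_res)
}

.fit_front_glmm <- function(front_table, dispersion_check, seed) {
  h1 <- fit_binomial_glmm(front_table, individual = "individual")
  h0_dist <- fit_binomial_glmm(front_table, individual = "individual",
                               include_distance = FALSE)
  h0_sex <- fit_binomial_glmm(front_table, individual = "individual",
                              include_sex = FALSE)
  lrt_distance <- lrt(h0_dist, h1)
  lrt_sex <- lrt(h0_sex, h1)
  slope <- unname(h1$fixef["distance_km"])
  se <- sqrt(diag(as.matrix(stats::vcov(h1$fit))))[
    names(h1$fixef) == "distance_km"]
  list(fit = h1, distance_slope = slope,
       distance_ci = slope + c(-1.96, 1.96) * se,
       lrt_distance = lrt_distance, lrt_sex = lrt_sex,
       conditional_r2 = conditional_r2(h1),
       dispersion_p = if (dispersion_check) {
         overdispersion_check(h1, n_sim = 200, seed = seed)
       } else NA_real_)
}
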