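manifest_columns <- c("image_id", "ref_path", "tag_path", "antibody_id",
                      "experiment_id", "fixative", "primary_conc_ng_per_ml",
                      "is_reference", "is_control")

#' Validate an experiment manifest
#'
#' A manifest maps each image to its antibody, independent experiment and
#' staining condition (fixative, primary-antibody concentration), and flags
#' the reference and irrelevant-control antibodies. Checks: required
#' columns; unique `image_id`; exactly one reference antibody per
#' experiment; at least one control row per (experiment, fixative,
#' concentration) condition; known fixative labels; positive
#' concentrations; optionally, readable image paths.
#'
#' @param manifest Data frame with columns `image_id`, `ref_path`,
#'   `tag_path`, `antibody_id`, `experiment_id`, `fixative`,
#'   `primary_conc_ng_per_ml`, `is_reference`, `is_control`.
#' @param check_files Verify that `ref_path`/`tag_path` exist.
#' @return Character vector of violations (with row numbers); empty if the
#'   manifest is valid.
#' @export
validate_manifest <- function(manifest, check_files = FALSE) {
  v <- character()
  missing_cols <- setdiff(manifest_columns, names(manifest))
  if (length(missing_cols))
    return(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  dup <- duplicated(manifest$image_id)
  if (any(dup))
    v <- c(v, paste0("duplicate image_id '", manifest$image_id[dup],
                     "' at row ", which(dup)))
  bad_fix <- !manifest$fixative %in% c("pfa", "methanol")
  if (any(bad_fix))
    v <- c(v, paste0("unknown fixative '", manifest$fixative[bad_fix],
                     "' at row ", which(bad_fix)))
  bad_conc <- !is.finite(manifest$primary_conc_ng_per_ml) |
    manifest$primary_conc_ng_per_ml <= 0
  if (any(bad_conc))
    v <- c(v, paste0("non-positive primary concentration at row ",
                     which(bad_conc)))
  for (exp_id in unique(manifest$experiment_id)) {
    rows <- which(manifest$experiment_id == exp_id)
    refs <- unique(manifest$antibody_id[rows][manifest$is_reference[rows]])
    if (length(refs) == 0L)
      v <- c(v, paste0("experiment '", exp_id, "': no reference antibody"))
    if (length(refs) > 1L)
      v <- c(v, paste0("experiment '", exp_id, "': multiple reference ",
                       "antibodies (", paste(refs, collapse = ", "),
                       ") at rows ",
                       paste(rows[manifest$is_reference[rows]], collapse = ", ")))
    conds <- unique(manifest[rows, c("fixative", "primary_conc_ng_per_ml")])
    for (k in seq_len(nrow(conds))) {
      in_cond <- rows[manifest$fixative[rows] == conds$fixative[k] &
                      manifest$primary_conc_ng_per_ml[rows] ==
                        conds$primary_conc_ng_per_ml[k]]
      if (!any(manifest$is_control[in_cond]))
        v <- c(v, paste0("experiment '", exp_id, "', condition ",
                         conds$fixative[k], "/",
                         conds$primary_conc_ng_per_ml[k],
                         " ng/mL: no irrelevant-antibody control"))
    }
  }
  if (check_files) {
    for (i in seq_len(nrow(manifest))) {
      for (p in c(manifest$ref_path[i], manifest$tag_path[i]))
        if (is.na(p) || !file.exists(p))
          v <- c(v, paste0("row ", i, ": unreadable image path '", p, "'"))
    }
  }
  v
}

#' Simulate a full antibody panel with a manifest
#'
#' Generates an experiment layout mirroring the staining design: every
#' antibody is imaged in every independent experiment under each (fixative,
#' concentration) condition, with several pictures per condition. Each
#' experiment gets its own overall staining intensity (log-normal jitter on
#' both channel gains), which within-experiment normalization must cancel.
#' Per-image seeds are derived deterministically from `seed`, so the same
#' seed reproduces the panel bit-identically.
#'
#' @param antibodies List of [antibody_model()] objects; exactly one id must
#'   equal `reference_id`.
#' @param reference_id `antibody_id` of the reference antibody (normalized
#'   to 100).
#' @param n_experiments Number of independent experiments.
#' @param images_per_condition Pictures per antibody per condition.
#' @param concs Primary-antibody concentrations (ng/mL) assayed.
#' @param fixatives Fixation condition labels.
#' @param config Base [simulation_config()]; `primary_conc` and `seed` are
#'   overridden per image.
#' @param experiment_gain_sd Log-scale SD of the per-experiment staining
#'   intensity factor.
#' @param seed Base seed for the whole panel.
#' @return List with `manifest` (data frame), `images` (named list of
#'   `image_pair` keyed by `image_id`) and `truths` (named list of
#'   `ground_truth`).
#' @export
simulate_panel <- function(antibodies, reference_id,
                           n_experiments = 3L, images_per_condition = 3L,
                           concs = 5000, fixatives = "pfa",
                           config = simulation_config(),
                           experiment_gain_sd = 0.15, seed = 1L) {
  ids <- vapply(antibodies, `[[`, character(1), "antibody_id")
  stopifnot(!anyDuplicated(ids), reference_id %in% ids)
  set.seed(seed)
  gain_factors <- stats::rlnorm(n_experiments, 0, experiment_gain_sd)
  rows <- list(); images <- list(); truths <- list()
  counter <- 0L
  for (e in seq_len(n_experiments)) {
    for (fx in fixatives) {
      for (conc in concs) {
        for (ab in antibodies) {
          for (img in seq_len(images_per_condition)) {
            counter <- counter + 1L
            img_seed <- (seed * 10000L + counter) %% .Machine$integer.max
            cfg <- config
            cfg$primary_conc <- conc
            cfg$seed <- img_seed
            cfg$gain_ref <- config$gain_ref * gain_factors[e]
            cfg$gain_tag <- config$gain_tag * gain_factors[e]
            image_id <- sprintf("exp%d_%s_c%g_%s_%d", e, fx, conc,
                                ab$antibody_id, img)
            sim <- simulate_image_pair(cfg, ab, image_id = image_id)
            images[[image_id]] <- sim$pair
            truths[[image_id]] <- sim$truth
            rows[[counter]] <- data.frame(
              image_id = image_id,
              ref_path = NA_character_, tag_path = NA_character_,
              antibody_id = ab$antibody_id,
              experiment_id = paste0("exp", e),
              fixative = fx, primary_conc_ng_per_ml = conc,
              is_reference = ab$antibody_id == reference_id,
              is_control = ab$is_control)
          }
        }
      }
    }
  }
  manifest <- do.call(rbind, rows)
  list(manifest = manifest, images = images, truths = truths)
}

#' Write a simulated panel to disk
#'
#' Writes every image pair as 16-bit TIFFs with ground-truth JSON sidecars,
#' plus `manifest.csv`, and returns the manifest with populated paths.
#'
#' @param panel Result of [simulate_panel()].
#' @param out_dir Output directory.
#' @return The manifest data frame with `ref_path`/`tag_path` filled in.
#' @export
write_panel <- function(panel, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- panel$manifest
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$image_id[i]
    paths <- write_image_pair(panel$images[[id]], out_dir, basename = id)
    write_ground_truth(panel$truths[[id]],
                       file.path(out_dir, paste0(id, ".truth.json")))
    manifest$ref_path[i] <- paths[["ref"]]
    manifest$tag_path[i] <- paths[["tag"]]
  }
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

#' Run the full quantification pipeline over a manifest
#'
#' For every image: select high-signal regions on the reference channel and
#' measure both channels. For every (antibody, experiment, condition):
#' pool the ROI measurements of that condition's pictures into one OLS fit.
#' Within every (experiment, condition): normalize slopes to the reference
#' antibody (set to 100). Per (antibody, condition): aggregate normalized
#' values across experiments (mean, SEM) and test specificity against the
#' irrelevant-antibody control. Per (antibody, fixative): classify as
#' good / fair / mediocre / nonspecific from the high- and (when assayed)
#' low-concentration results. Deterministic given inputs.
#'
#' @param manifest Experiment manifest (see [validate_manifest()]).
#' @param images Optional named list of in-memory `image_pair` objects keyed
#'   by `image_id`; when `NULL`, images are read from the manifest paths.
#' @param n_regions,region_size ROI sampling parameters (defaults 20, 30).
#' @param bit_depth Bit depth used for the saturation guard.
#' @param per_picture Fit one regression per picture instead of pooling the
#'   pictures of a condition (off by default).
#' @param out_dir If given, writes `roi_measurements.csv`,
#'   `efficiencies.csv`, `summary.csv` and `run_metadata.json` there.
#' @param seed Recorded in the run metadata (the pipeline itself is
#'   deterministic).
#' @return List with data frames `measurements`, `efficiencies` (per
#'   antibody x experiment x condition: slope, intercept, r_squared,
#'   n_points, normalized_value) and `summary` (per antibody x fixative:
#'   mean, sem, n_experiments, specific_high, specific_low, class_label,
#'   plus band/undetermined flags).
#' @export
run_pipeline <- function(manifest, images = NULL, n_regions = 20L,
                         region_size = 30L, bit_depth = 16L,
                         per_picture = FALSE, out_dir = NULL, seed = NULL) {
  violations <- validate_manifest(manifest, check_files = is.null(images))
  if (length(violations))
    stop("invalid manifest:\n  ", paste(violations, collapse = "\n  "),
         call. = FALSE)
  ceiling_val <- 2^bit_depth - 1

  meas_list <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$image_id[i]
    pair <- if (!is.null(images)) images[[id]] else
      read_image_pair(manifest$ref_path[i], manifest$tag_path[i],
                      image_id = id, bit_depth = bit_depth)
    if (is.null(pair)) stop("no image supplied for image_id '", id, "'",
                            call. = FALSE)
    regions <- select_regions(pair$ref, n = n_regions, size = region_size,
                              ceiling = ceiling_val)
    m <- measure_regions(pair, regions)
    m$antibody_id <- manifest$antibody_id[i]
    m$experiment_id <- manifest$experiment_id[i]
    m$fixative <- manifest$fixative[i]
    m$primary_conc_ng_per_ml <- manifest$primary_conc_ng_per_ml[i]
    meas_list[[i]] <- m
  }
  measurements <- do.call(rbind, meas_list)

  group_cols <- c("antibody_id", "experiment_id", "fixative",
                  "primary_conc_ng_per_ml")
  if (per_picture) group_cols <- c(group_cols, "image_id")
  key <- interaction(measurements[group_cols], drop = TRUE)
  fits <- do.call(rbind, lapply(split(measurements, key), function(g) {
    f <- fit_efficiency(g, antibody_id = g$antibody_id[1L],
                        experiment_id = g$experiment_id[1L])
    f$fixative <- g$fixative[1L]
    f$primary_conc_ng_per_ml <- g$primary_conc_ng_per_ml[1L]
    f
  }))
  rownames(fits) <- NULL

  ref_by_exp <- unique(manifest[manifest$is_reference,
                                c("experiment_id", "antibody_id")])
  cond_key <- interaction(fits$fixative, fits$primary_conc_ng_per_ml,
                          drop = TRUE)
  norm_key <- interaction(fits$experiment_id, cond_key, drop = TRUE)
  efficiencies <- do.call(rbind, lapply(split(fits, norm_key), function(g) {
    ref_id <- ref_by_exp$antibody_id[match(g$experiment_id[1L],
                                           ref_by_exp$experiment_id)]
    normalize_to_reference(g, ref_id)
  }))
  rownames(efficiencies) <- NULL

  control_ids <- unique(manifest$antibody_id[manifest$is_control])

  summarize_condition <- function(g) {
    by_ab <- split(g, g$antibody_id)
    ctrl_vals <- g$normalized_value[g$antibody_id %in% control_ids]
    ctrl_mean <- if (length(ctrl_vals)) mean(ctrl_vals) else NA_real_
    do.call(rbind, lapply(by_ab, function(a) {
      agg <- suppressMessages(summarize_replicates(a$normalized_value))
      spec <- if (is.na(ctrl_mean)) list(ratio = NA_real_, is_specific = NA)
        else specificity_ratio(max(agg$mean, 0), ctrl_mean)
      data.frame(antibody_id = a$antibody_id[1L],
                 fixative = a$fixative[1L],
                 primary_conc_ng_per_ml = a$primary_conc_ng_per_ml[1L],
                 mean = agg$mean, sem = agg$sem, n_experiments = agg$n,
                 specificity_ratio = spec$ratio,
                 is_specific = spec$is_specific)
    }))
  }
  eff_cond_key <- interaction(efficiencies$fixative,
                              efficiencies$primary_conc_ng_per_ml, drop = TRUE)
  cond_summary <- do.call(rbind, lapply(split(efficiencies, eff_cond_key),
                                        summarize_condition))
  rownames(cond_summary) <- NULL

  # classification per antibody x fixative: high = largest assayed
  # concentration, low = smallest (when more than one level was assayed)
  summary_rows <- list()
  for (fx in unique(cond_summary$fixative)) {
    sub <- cond_summary[cond_summary$fixative == fx, ]
    concs <- sort(unique(sub$primary_conc_ng_per_ml))
    hi <- max(concs); lo <- if (length(concs) > 1L) min(concs) else NA_real_
    for (ab in unique(sub$antibody_id)) {
      hrow <- sub[sub$antibody_id == ab & sub$primary_conc_ng_per_ml == hi, ]
      lrow <- if (!is.na(lo))
        sub[sub$antibody_id == ab & sub$primary_conc_ng_per_ml == lo, ]
        else NULL
      has_low <- !is.null(lrow) && nrow(lrow) == 1L
      label <- classify_antibody(
        high_value = max(hrow$mean, 0),
        low_value = if (has_low) max(lrow$mean, 0) else NA_real_,
        specific_high = isTRUE(hrow$is_specific),
        specific_low = if (has_low) lrow$is_specific else NA)
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        antibody_id = ab, fixative = fx,
        mean = hrow$mean, sem = hrow$sem, n_experiments = hrow$n_experiments,
        mean_low = if (has_low) lrow$mean else NA_real_,
        sem_low = if (has_low) lrow$sem else NA_real_,
        specific_high = isTRUE(hrow$is_specific),
        specific_low = if (has_low) isTRUE(lrow$is_specific) else NA,
        class_label = as.character(label),
        band_interpolated = as.character(label) == "mediocre" &&
          hrow$mean >= 25 && hrow$mean <= 50,
        low_undetermined = isTRUE(attr(label, "undetermined")))
    }
  }
  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL

  result <- list(measurements = measurements, efficiencies = efficiencies,
                 condition_summary = cond_summary, summary = summary)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(measurements,
                     file.path(out_dir, "roi_measurements.csv"),
                     row.names = FALSE)
    utils::write.csv(efficiencies, file.path(out_dir, "efficiencies.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    meta <- list(
      tool = "tagquant",
      version = as.character(utils::packageVersion("tagquant")),
      n_images = nrow(manifest), n_regions = n_regions,
      region_size = region_size, per_picture = per_picture,
      seed = seed, timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                         auto_unbox = TRUE, null = "null")
  }
  result
}
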