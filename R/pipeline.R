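# End-to-end driver: simulate the three phantom cohorts, run every analysis
# stage, and write a CSV-first report bundle with a provenance log. All
# randomness fans out from one global seed through mix_seed(), so any stage
# can be re-run in isolation.

#' Run configuration
#'
#' @param ... overrides for any default field. Unknown keys are rejected.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    out_dir = "results/run",
    n_tumors = c(mesenchymal_stiff = 6L, mesenchymal_soft = 6L,
                 non_mesenchymal = 6L),
    n_replicates = 3L,
    n_timepoints = NA_integer_,   # NA = use each preset's default
    map_size = 256L,
    pixel_spacing_mm = 0.1,
    soft_stiff_cut_kpa = 40,
    histogram_bin_width = 1,
    fiber_prune_px = 3,
    shg_images_per_group = 2L,
    stain_threshold = "auto",
    de_var_equal = TRUE,
    expr = list(n_mes = 8L, n_nonmes = 8L, n_genes = 2000L,
                signature_effect_sd = 2, n_de = 50L, de_log2fc = 1,
                noise_sd = 0.25),
    seed = 1L)
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
      stop("unknown config keys: ", paste(unknown, collapse = ", "))
    if (!is.null(dots$expr)) {
      cfg$expr[names(dots$expr)] <- dots$expr
      dots$expr <- NULL
    }
    cfg[names(dots)] <- dots
  }
  num <- c(cfg$n_replicates, cfg$map_size, cfg$pixel_spacing_mm,
           cfg$soft_stiff_cut_kpa, cfg$histogram_bin_width,
           cfg$fiber_prune_px, cfg$shg_images_per_group, cfg$n_tumors)
  if (any(!is.finite(num)) || any(num <= 0))
    stop("all numeric config options must be positive")
  class(cfg) <- "run_config"
  cfg
}

# Elastography stage over one preset cohort: per-measurement table, final
# histograms and radial decreases, cohort-level correlation.
analyze_cohort <- function(preset, n_tumors, cfg, seed) {
  meas <- list(); hists <- list(); radial <- list()
  for (i in seq_len(n_tumors)) {
    tumor_seed <- mix_seed(seed, i)
    ser <- generate_growth_series(preset, n_replicates = cfg$n_replicates,
                                  seed = tumor_seed, map_size = cfg$map_size,
                                  pixel_spacing_mm = cfg$pixel_spacing_mm)
    nt <- length(ser$timepoints)
    for (t in seq_len(nt)) {
      acq <- ser$timepoints[[t]]
      mk <- mean_tumor_stiffness(acq)
      meas[[length(meas) + 1L]] <- data.frame(
        model = preset$name, tumor_id = sprintf("%s_%02d", preset$name, i),
        day = acq$timepoint_days,
        mean_kpa = mk,
        area_mm2 = tumor_area(acq$rois[[1]], cfg$pixel_spacing_mm),
        label = classify_soft_stiff(mk, cfg$soft_stiff_cut_kpa),
        stringsAsFactors = FALSE)
    }
    final <- ser$timepoints[[nt]]
    rec <- radial_records(final$maps[[1]], final$rois[[1]])
    radial[[i]] <- data.frame(
      model = preset$name, tumor_id = sprintf("%s_%02d", preset$name, i),
      decrease_kpa = center_to_edge_decrease(rec),
      rho_radial = spearman(rec$r_norm, rec$stiffness_kpa)$rho,
      stringsAsFactors = FALSE)
    h <- stiffness_histogram(final$maps[[1]], final$rois[[1]],
                             bin_width = cfg$histogram_bin_width)
    h$model <- preset$name
    h$tumor_id <- sprintf("%s_%02d", preset$name, i)
    hists[[i]] <- h
  }
  meas <- do.call(rbind, meas)
  corr <- cohort_stiffness_growth_correlation(meas)
  list(measurements = meas,
       radial = do.call(rbind, radial),
       histograms = do.call(rbind, hists),
       correlation = data.frame(model = preset$name, rho = corr$rho,
                                p = corr$p, n = corr$n))
}

#' Run the full phantom study end to end
#'
#' Simulates the three phantom cohorts (two Mesenchymal presets, one
#' Non-Mesenchymal), runs the elastography, collagen and transcriptomics
#' stages, and writes a CSV + JSON report bundle mirroring the study's figure
#' panels: stiffness-growth correlations, percent-of-area histograms, radial
#' gradients, fiber morphometry with center/periphery comparison, collagen
#' densities, subtype assignments and DE counts. Fully reproducible from
#' `(config, seed)`.
#'
#' @param config a [run_config()].
#' @return the report bundle, invisibly; files are written under
#'   `config$out_dir`.
#' @export
run_end_to_end <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  stage <- "setup"
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  report <- list()
  tryCatch({
    # --- elastography over the three cohorts -------------------------------
    stage <- "elastography"
    presets <- lapply(names(config$n_tumors), function(nm) {
      if (is.na(config$n_timepoints)) swe_preset(nm)
      else swe_preset(nm, growth = list(n_timepoints = config$n_timepoints))
    })
    cohorts <- lapply(seq_along(presets), function(k) {
      analyze_cohort(presets[[k]], config$n_tumors[[k]], config,
                     seed = mix_seed(config$seed, 10, k))
    })
    meas <- do.call(rbind, lapply(cohorts, `[[`, "measurements"))
    radial <- do.call(rbind, lapply(cohorts, `[[`, "radial"))
    hists <- do.call(rbind, lapply(cohorts, `[[`, "histograms"))
    corrs <- do.call(rbind, lapply(cohorts, `[[`, "correlation"))
    utils::write.csv(meas, file.path(out, "swe_measurements.csv"),
                     row.names = FALSE)
    utils::write.csv(radial, file.path(out, "swe_radial_decrease.csv"),
                     row.names = FALSE)
    utils::write.csv(hists, file.path(out, "swe_histograms.csv"),
                     row.names = FALSE)
    utils::write.csv(corrs, file.path(out, "swe_growth_correlation.csv"),
                     row.names = FALSE)

    # --- SHG morphometry: center vs periphery of stiff tumors --------------
    stage <- "shg"
    shg_params <- list(  # stiff centers carry longer/thicker fibers
      center = list(length = c(60, 90), thickness = c(2.5, 4)),
      periphery = list(length = c(30, 50), thickness = c(1, 2)))
    fibers <- list()
    for (i in seq_len(config$shg_images_per_group)) {
      for (reg in names(shg_params)) {
        p <- shg_params[[reg]]
        g <- generate_shg_image(n_fibers = 6, length_range_um = p$length,
                                thickness_range_um = p$thickness,
                                seed = mix_seed(config$seed, 20, i,
                                                match(reg, names(shg_params))))
        ft <- fiber_table(max_intensity_projection(g$stack), g$pixel_size_um,
                          prune_px = config$fiber_prune_px, region = reg)
        ft$tumor_id <- sprintf("stiff_%02d", i)
        fibers[[length(fibers) + 1L]] <- ft
      }
    }
    fibers <- do.call(rbind, fibers)
    fib_summary <- stats::aggregate(
      cbind(length_um, thickness_um) ~ tumor_id + region, fibers, mean)
    long <- rbind(
      data.frame(tumor_id = fib_summary$tumor_id, region = fib_summary$region,
                 metric = "length_um", value = fib_summary$length_um),
      data.frame(tumor_id = fib_summary$tumor_id, region = fib_summary$region,
                 metric = "thickness_um", value = fib_summary$thickness_um))
    fib_stats <- compare_center_periphery(long)
    utils::write.csv(fibers, file.path(out, "shg_fibers.csv"),
                     row.names = FALSE)
    utils::write.csv(fib_stats, file.path(out, "shg_center_periphery.csv"),
                     row.names = FALSE)

    # --- trichrome collagen density and stroma percentage ------------------
    stage <- "trichrome"
    fractions <- c(stiff = 0.5, soft = 0.25, non_mesenchymal = 0.2)
    model <- masson_stain_model()
    imgs <- lapply(seq_along(fractions), function(k)
      generate_trichrome_image(fractions[[k]],
                               seed = mix_seed(config$seed, 30, k)))
    thr <- batch_collagen_threshold(lapply(imgs, `[[`, "rgb"), model)
    dens <- do.call(rbind, lapply(seq_along(imgs), function(k) {
      d <- collagen_density(imgs[[k]]$rgb, model, threshold = thr)
      data.frame(group = names(fractions)[k],
                 collagen_fraction_true = fractions[[k]],
                 integrated_density = d$integrated_density,
                 collagen_area_fraction = d$collagen_area_fraction,
                 stroma_percent = stroma_percentage(
                   imgs[[k]]$mask, matrix(TRUE, nrow(imgs[[k]]$mask),
                                          ncol(imgs[[k]]$mask))))
    }))
    utils::write.csv(dens, file.path(out, "trichrome_density.csv"),
                     row.names = FALSE)

    # --- transcriptomics ----------------------------------------------------
    stage <- "transcriptomics"
    ex <- do.call(generate_expression_dataset,
                  c(config$expr, list(seed = mix_seed(config$seed, 40))))
    human_log <- log2p1(ex$human)
    mouse_log <- log2p1(ex$mouse)
    cl <- cluster_subtypes(standardize_genes(human_log), ex$truth$signature)
    assign <- data.frame(sample_id = cl$sample_id, cluster = cl$cluster,
                         subtype_label = cl$subtype,
                         truth = ex$truth$samples$subtype)
    de <- de_contrast_suite(human_log, mouse_log,
                            var_equal = config$de_var_equal)
    de_counts <- data.frame(
      contrast = names(de),
      n_up = vapply(de, function(d) length(d$up), integer(1)),
      n_down = vapply(de, function(d) length(d$down), integer(1)),
      row.names = NULL)
    utils::write.csv(assign, file.path(out, "subtype_assignments.csv"),
                     row.names = FALSE)
    utils::write.csv(de_counts, file.path(out, "de_counts.csv"),
                     row.names = FALSE)

    # --- summary + provenance ----------------------------------------------
    stage <- "report"
    report <- list(
      provenance = list(
        package_version = as.character(utils::packageVersion("stiffpdx")),
        seed = config$seed,
        # hash of the scientific configuration; output paths excluded
        config_hash = hash_string(utils::capture.output(
          utils::str(config[setdiff(names(config), "out_dir")])))),
      swe = list(correlations = corrs,
                 max_mean_kpa_by_model = tapply(meas$mean_kpa, meas$model, max),
                 mean_decrease_kpa_by_model = tapply(radial$decrease_kpa,
                                                     radial$model, mean)),
      shg = list(center_periphery = fib_stats),
      trichrome = dens,
      transcriptomics = list(
        subtype_agreement = mean(assign$subtype_label == assign$truth),
        de_counts = de_counts))
    jsonlite::write_json(report, file.path(out, "summary.json"),
                         auto_unbox = TRUE, digits = 10, force = TRUE)
    invisible(report)
  }, error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Validate a cohort manifest
#'
#' A manifest row points one (tumor, timepoint, replicate) measurement at its
#' map prefix and contour file. Duplicate keys, missing files and unparseable
#' fields are reported together, not one at a time.
#'
#' @param manifest data.frame (or CSV path) with columns `tumor_id`,
#'   `timepoint_days`, `replicate`, `map`, `contour`, `model`.
#' @return the normalized manifest, or an error listing every problem.
#' @export
validate_manifest <- function(manifest) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest)
  if (nrow(manifest) == 0) stop("empty manifest")
  need <- c("tumor_id", "timepoint_days", "replicate", "map", "contour",
            "model")
  problems <- character(0)
  miss_cols <- setdiff(need, names(manifest))
  if (length(miss_cols)) {
    problems <- c(problems, paste("missing columns:",
                                  paste(miss_cols, collapse = ", ")))
  } else {
    key <- paste(manifest$tumor_id, manifest$timepoint_days,
                 manifest$replicate)
    dup <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    if (length(dup))
      problems <- c(problems, paste("duplicated (tumor, timepoint, replicate) in rows:",
                                    paste(sort(dup), collapse = ", ")))
    if (any(!is.finite(manifest$timepoint_days)))
      problems <- c(problems, "non-numeric timepoint_days")
    for (col in c("map", "contour")) {
      missing_files <- manifest[[col]][!file.exists(manifest[[col]])]
      if (length(missing_files))
        problems <- c(problems, paste0("missing ", col, " file(s): ",
                                       paste(missing_files, collapse = ", ")))
    }
  }
  if (length(problems))
    stop("invalid manifest:\n  - ", paste(problems, collapse = "\n  - "))
  manifest[order(manifest$tumor_id, manifest$timepoint_days,
                 manifest$replicate), , drop = FALSE]
}
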