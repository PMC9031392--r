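#' Default pipeline configuration
#'
#' The resolved configuration drives every pipeline stage and is embedded
#' in all JSON artifacts for provenance. Defaults describe the synthetic
#' study design: four PHB/BDF blends imaged in triplicate over 14 days
#' (15 time points), with faster degradation at higher plasticizer
#' fraction.
#'
#' @param config_file optional YAML (or `key: value`) file; values found
#'   there override the defaults.
#' @param ... further overrides (highest precedence), e.g. `seed = 7` or
#'   `threshold = c(0.6, 1)`.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(config_file = NULL, ...) {
  cfg <- list(
    out_dir = "phbdeg_out",
    seed = 1L,
    times = seq(0, 336, by = 24),
    blends = c(BDF5 = 250, BDF10 = 180, BDF20 = 108, BDF40 = 99),
    replicates = 3L,
    replicate_t50_cv = 0.05,
    steepness = 0.03,
    image = list(image_size = c(256L, 256L), n_grains = 40L,
                 grain_radius_range = c(4, 9), grain_intensity = 0.85,
                 agar_intensity = 0.15, mycelium_intensity = 0.55,
                 mycelium_growth_rate = 0.002, illumination_gradient = 0.08,
                 noise_sd = 0.02),
    threshold = "auto",
    max_degree = 6L, alpha = 0.05, level = 50,
    nmr = list(monomer_center = 4.20, polymer_center = 5.20,
               half_width = 0.15, linewidth = 0.015,
               baseline_level = 0.01, noise_sd = 0),
    write_frames = TRUE, write_masks = FALSE
  )
  if (!is.null(config_file)) {
    file_cfg <- yaml::read_yaml(config_file)
    cfg <- utils::modifyList(cfg, file_cfg)
  }
  cfg <- utils::modifyList(cfg, list(...))
  if (is.list(cfg$blends)) cfg$blends <- unlist(cfg$blends)
  validate_config(cfg)
  structure(cfg, class = c("pipeline_config", "list"))
}

validate_config <- function(cfg) {
  if (!is.numeric(cfg$times) || any(diff(cfg$times) <= 0))
    stop_phb("config: times must be strictly increasing")
  if (is.null(names(cfg$blends)) || !is.numeric(cfg$blends))
    stop_phb("config: blends must be a named numeric vector of true t50s")
  if (!identical(cfg$threshold, "auto")) {
    thr <- as.numeric(cfg$threshold)
    if (length(thr) != 2L) stop_phb("config: threshold must be 'auto' or c(low, high)")
    threshold_range(thr[1], thr[2])  # validates bounds
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop_phb("config: alpha must be in (0, 1)")
  invisible(cfg)
}

config_provenance <- function(cfg) {
  c(unclass(cfg),
    list(package = "phbdeg",
         version = as.character(utils::packageVersion("phbdeg"))))
}

log_msg <- function(log_file, fmt, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  message(line)
  if (!is.null(log_file)) cat(line, "\n", file = log_file, append = TRUE)
}

sample_grid <- function(cfg) {
  grid <- expand.grid(replicate = seq_len(cfg$replicates),
                      blend = names(cfg$blends),
                      stringsAsFactors = FALSE)
  grid$sample_id <- sprintf("%s_r%d", grid$blend, grid$replicate)
  grid$t50_true <- unname(cfg$blends[grid$blend])
  # one deterministic sub-seed per sample, derived from the master seed
  grid$seed <- (as.integer(cfg$seed) * 1000L + seq_len(nrow(grid))) %% .Machine$integer.max
  grid
}

simulate_study <- function(cfg, log_file = NULL) {
  grid <- sample_grid(cfg)
  # between-well biological variability: each replicate well degrades at
  # its own pace, lognormal around the blend's true t50
  jitter <- withr::with_seed(cfg$seed,
                             stats::rlnorm(nrow(grid), 0,
                                           cfg$replicate_t50_cv %||% 0))
  lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    sp <- do.call(scene_params, c(cfg$image, list(seed = g$seed)))
    tr <- logistic_trajectory(cfg$times, t50 = g$t50_true * jitter[i],
                              steepness = cfg$steepness)
    log_msg(log_file, "simulate %s (t50_true %s h)", g$sample_id,
            format(tr$t50_true))
    simulate_image_series(sp, tr, sample_id = g$sample_id,
                          blend_label = g$blend)
  })
}

analyse_series <- function(series, cfg, log_file = NULL) {
  thr <- if (identical(cfg$threshold, "auto")) suggest_threshold(series)
  else threshold_range(cfg$threshold[1], cfg$threshold[2])
  bin <- binarize_series(series, thr)
  curve <- degradation_curve(bin)
  log_msg(log_file, "binarize %s: threshold [%.3f, %.3f], WPt0 = %d",
          series$sample_id, thr$low, thr$high, bin$white_counts[1])
  list(threshold = thr, binary = bin, curve = curve)
}

fit_one <- function(curve, cfg, replicate, log_file = NULL) {
  fit <- tryCatch(
    t50_fit(curve, max_degree = cfg$max_degree, alpha = cfg$alpha,
            level = cfg$level),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    log_msg(log_file, "t50 %s: FAILED (%s)", curve$sample_id,
            conditionMessage(fit))
    return(data.frame(sample_id = curve$sample_id, blend = curve$blend_label,
                      replicate = replicate, degree = NA_integer_,
                      r2 = NA_real_, adj_r2 = NA_real_, f_pvalue = NA_real_,
                      t50 = NA_real_, censored = "no significant model"))
  }
  log_msg(log_file, "t50 %s: degree %d, t50 %s", curve$sample_id,
          fit$degree, if (is.na(fit$t50)) fit$censored else
            sprintf("%.1f h", fit$t50))
  data.frame(sample_id = curve$sample_id, blend = curve$blend_label,
             replicate = replicate, degree = fit$degree, r2 = fit$r2,
             adj_r2 = fit$adj_r2, f_pvalue = fit$f_pvalue, t50 = fit$t50,
             censored = fit$censored %||% NA_character_)
}

#' Run the degradation-monitoring pipeline
#'
#' Orchestrates the stages as subcommands. `"simulate"` writes synthetic
#' frames, manifests and truth tables; `"binarize"` thresholds every
#' sample with one shared interval per series and records white-pixel
#' counts; `"kinetics"` turns counts into remaining-% curves;
#' `"t50"` fits every curve and tabulates t50 by blend and replicate;
#' `"compare"` runs ANOVA + Tukey + letters on the t50 table;
#' `"nmr"` quantifies a spectra manifest; `"all"` chains
#' simulate, binarize, kinetics, t50 and compare end-to-end on synthetic
#' data. Failure of one sample is logged and does not abort the batch.
#'
#' All artifacts (CSV/JSON plus a run log) are written under
#' `config$out_dir`; each JSON embeds the resolved configuration and
#' package version.
#'
#' @param subcommand one of `"simulate"`, `"binarize"`, `"kinetics"`,
#'   `"t50"`, `"compare"`, `"nmr"`, `"all"`.
#' @param config a [pipeline_config()].
#' @param spectra_manifest CSV manifest for the `"nmr"` subcommand.
#' @return Invisibly, a list of in-memory results (kinetics table, t50
#'   table, comparison, paths).
#' @export
run_pipeline <- function(subcommand = c("all", "simulate", "binarize",
                                        "kinetics", "t50", "compare", "nmr"),
                         config = pipeline_config(),
                         spectra_manifest = NULL) {
  subcommand <- match.arg(subcommand)
  cfg <- config
  out <- cfg$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  log_file <- file.path(out, "run.log")
  jsonlite::write_json(config_provenance(cfg),
                       file.path(out, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  if (subcommand == "nmr") {
    if (is.null(spectra_manifest)) stop_phb("nmr subcommand needs spectra_manifest")
    spectra <- read_spectra(spectra_manifest)
    regions <- list(
      monomer = peak_region(cfg$nmr$monomer_center, cfg$nmr$half_width),
      polymer = peak_region(cfg$nmr$polymer_center, cfg$nmr$half_width))
    kin <- degradation_kinetic(spectra, regions)
    utils::write.csv(attr(kin, "details"),
                     file.path(out, "nmr_kinetics.csv"), row.names = FALSE)
    log_msg(log_file, "nmr: %d spectra quantified", length(spectra))
    return(invisible(list(nmr = kin)))
  }

  stages <- if (subcommand == "all")
    c("simulate", "binarize", "kinetics", "t50", "compare") else subcommand

  result <- list()
  series_list <- NULL

  if ("simulate" %in% stages) {
    series_list <- simulate_study(cfg, log_file)
    if (isTRUE(cfg$write_frames)) {
      img_dir <- file.path(out, "images")
      manifests <- vapply(series_list, write_image_series, character(1),
                          dir = img_dir)
      all_man <- do.call(rbind, lapply(manifests, utils::read.csv))
      utils::write.csv(all_man, file.path(out, "manifest.csv"),
                       row.names = FALSE)
      result$manifest <- file.path(out, "manifest.csv")
    }
    result$series <- series_list
  }

  if (any(c("binarize", "kinetics") %in% stages)) {
    if (is.null(series_list)) {
      man_path <- file.path(out, "manifest.csv")
      if (!file.exists(man_path))
        stop_phb("no simulated series in memory and no %s", man_path)
      man <- utils::read.csv(man_path, stringsAsFactors = FALSE)
      series_list <- lapply(split(man, man$sample_id), function(m) {
        p <- file.path(out, "images", sprintf("%s_manifest.csv",
                                              m$sample_id[1]))
        tryCatch(read_image_series(p), error = function(e) {
          log_msg(log_file, "sample %s FAILED: %s", m$sample_id[1],
                  conditionMessage(e))
          NULL
        })
      })
      series_list <- Filter(Negate(is.null), series_list)
    }
    kin_rows <- list(); thr_used <- list()
    for (s in series_list) {
      res <- tryCatch(analyse_series(s, cfg, log_file), error = function(e) e)
      if (inherits(res, "error")) {
        log_msg(log_file, "sample %s FAILED: %s", s$sample_id,
                conditionMessage(res))
        next
      }
      if (isTRUE(cfg$write_masks))
        write_masks(res$binary, file.path(out, "masks"))
      thr_used[[s$sample_id]] <- c(low = res$threshold$low,
                                   high = res$threshold$high)
      kin_rows[[s$sample_id]] <- data.frame(
        sample_id = s$sample_id, blend_label = s$blend_label,
        time_h = res$curve$times,
        wp_count = res$binary$white_counts,
        remaining_pct = res$curve$values)
    }
    if (length(kin_rows) == 0L) stop_phb("no sample could be analysed")
    kinetics <- do.call(rbind, kin_rows)
    rownames(kinetics) <- NULL
    utils::write.csv(kinetics, file.path(out, "kinetics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(thresholds = thr_used, config = config_provenance(cfg)),
      file.path(out, "thresholds.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    result$kinetics <- kinetics
  }

  if ("t50" %in% stages) {
    kinetics <- result$kinetics
    if (is.null(kinetics)) {
      kp <- file.path(out, "kinetics.csv")
      if (!file.exists(kp)) stop_phb("no kinetics table; run binarize first")
      kinetics <- utils::read.csv(kp, stringsAsFactors = FALSE)
    }
    rows <- lapply(split(kinetics, kinetics$sample_id), function(k) {
      k <- k[order(k$time_h), ]
      rep_id <- sub(".*_r", "", k$sample_id[1])
      curve <- kinetic_curve(k$time_h, k$remaining_pct,
                             sample_id = k$sample_id[1],
                             blend_label = k$blend_label[1],
                             replicate = rep_id)
      fit_one(curve, cfg, rep_id, log_file)
    })
    t50_table <- do.call(rbind, rows)
    rownames(t50_table) <- NULL
    utils::write.csv(t50_table, file.path(out, "t50.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(fits = t50_table, config = config_provenance(cfg)),
      file.path(out, "t50.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    result$t50 <- t50_table
  }

  if ("compare" %in% stages) {
    t50_table <- result$t50
    if (is.null(t50_table)) {
      tp <- file.path(out, "t50.csv")
      if (!file.exists(tp)) stop_phb("no t50 table; run t50 first")
      t50_table <- utils::read.csv(tp, stringsAsFactors = FALSE)
    }
    usable <- tapply(is.finite(t50_table$t50), t50_table$blend, sum)
    drop <- names(usable)[usable < 2]
    if (length(drop)) {
      log_msg(log_file,
              "compare: excluding blend(s) %s (fewer than 2 uncensored t50s)",
              paste(drop, collapse = ", "))
      t50_table <- t50_table[!t50_table$blend %in% drop, , drop = FALSE]
    }
    cmp <- compare_t50(data.frame(blend = t50_table$blend,
                                  t50 = t50_table$t50), alpha = cfg$alpha)
    utils::write.csv(
      data.frame(F = cmp$anova$F, p = cmp$anova$p,
                 df_between = cmp$anova$df["between"],
                 df_within = cmp$anova$df["within"]),
      file.path(out, "anova.csv"), row.names = FALSE)
    utils::write.csv(cmp$tukey, file.path(out, "tukey.csv"),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(blend = names(cmp$letters),
                 mean_t50_h = unname(cmp$means[names(cmp$letters)]),
                 letters = unname(cmp$letters)),
      file.path(out, "letters.csv"), row.names = FALSE)
    log_msg(log_file, "compare: F = %.3g, p = %.3g, %d letter group(s)",
            cmp$anova$F, cmp$anova$p,
            length(unique(strsplit(paste(cmp$letters, collapse = ""),
                                   "")[[1]])))
    result$comparison <- cmp
  }

  invisible(result)
}
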