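#' Default pipeline configuration
#'
#' Every parameter defaults to the value documented in its module;
#' override any subset via `...`. The `source` entry selects simulated
#' input (`type = "simulate"`, with walker parameter overrides under
#' `params`) or files (`type = "file"`, `paths` = canonical bout CSVs,
#' one per animal).
#'
#' @param ... Overrides of the default entries.
#' @return A config list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    species = "biped",
    source = list(type = "simulate", n_individuals = 5L, n_cycles = 200L,
                  params = list()),
    method = "extrema", segment_by = "onset", M = NULL,
    N_max = 8L, n_boot = 10000L, ci_level = 0.90, phi0 = 0.75,
    min_cycles_fit = 30L, seed = 1L, out_dir = NULL
  )
  over <- list(...)
  for (nm in names(over)) {
    cfg[[nm]] <- if (is.list(over[[nm]]) && is.list(cfg[[nm]]))
      utils::modifyList(cfg[[nm]], over[[nm]]) else over[[nm]]
  }
  cfg
}

# tiny FNV-1a string hash for the report's config fingerprint
config_hash <- function(cfg) {
  s <- paste(deparse(cfg[setdiff(names(cfg), "out_dir")]), collapse = "")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

ap_level <- function(leg) sub("_(left|right)$", "", leg)

#' Run the full inference pipeline
#'
#' Orchestrates: input acquisition (simulation or files), straightness
#' selection, heading alignment, contact detection, cycle segmentation
#' and normalization, feedforward fits and deviations, phase-resolved
#' feedback/baseline comparison, control magnitude, directional gains,
#' return-map stability, error reduction, decay timescales, and
#' limb-pair modularity comparisons. Every stage is recorded in the
#' report; a stage failure yields a partial report with a failure record.
#'
#' @param config A config list from [pipeline_config()].
#' @return A report list (also written as JSON to `config$out_dir` when
#'   set, together with the drop log).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  set.seed(config$seed)
  profile <- config$species
  if (is.character(profile))
    profile <- switch(profile, biped = profile_biped(),
                      quadruped = profile_quadruped(),
                      hexapod = profile_hexapod(),
                      read_species_profile(profile))
  report <- list(config_hash = config_hash(config), seed = config$seed,
                 species = profile$name, failures = list())
  log <- drop_log()
  fail <- function(stage, e) {
    report$failures[[length(report$failures) + 1L]] <<-
      list(stage = stage, message = conditionMessage(e))
    NULL
  }

  # --- input ------------------------------------------------------------
  cycles <- tryCatch({
    if (config$source$type == "simulate") {
      per <- lapply(seq_len(config$source$n_individuals), function(i) {
        params <- do.call(walker_params,
                          c(list(profile = profile), config$source$params))
        sim <- simulate_walker(params, n_cycles = config$source$n_cycles,
                               bout_id = sprintf("sim_%02d", i))
        bouts <- select_straight_bouts(list(sim$bout), log = log)
        bouts <- lapply(bouts, align_heading)
        build_cycles(bouts, profile, animal = sprintf("ind%02d", i),
                     method = config$method, M = config$M,
                     by = config$segment_by, log = log)
      })
      combine_cycles(per)
    } else {
      per <- lapply(seq_along(config$source$paths), function(i) {
        bouts <- load_bouts(config$source$paths[[i]], profile, log = log)
        bouts <- select_straight_bouts(bouts, log = log)
        bouts <- lapply(bouts, align_heading)
        an <- config$source$animals[[i]] %||% sprintf("animal%02d", i)
        build_cycles(bouts, profile, animal = an, method = config$method,
                     M = config$M, by = config$segment_by, log = log)
      })
      combine_cycles(per)
    }
  }, error = function(e) fail("processing", e))
  if (is.null(cycles)) return(finish_report(report, log, config))
  report$n_cycles <- nrow(cycles$meta)
  report$n_animals <- length(unique(cycles$meta$animal))

  # --- feedforward ------------------------------------------------------
  ff <- tryCatch({
    f <- fit_feedforward(cycles, min_cycles = config$min_cycles_fit)
    if (is.null(f$length_fits) || !nrow(f$length_fits))
      stop("no animal/leg reached ", config$min_cycles_fit, " cycles")
    f
  }, error = function(e) fail("feedforward", e))
  if (is.null(ff)) return(finish_report(report, log, config))
  lf <- ff$length_fits
  report$feedforward <- list(
    length_fits = lf,
    width_fits = ff$width_fits,
    length_slope_significant = stats::aggregate(
      p_slope ~ leg, data = lf, FUN = function(p) sum(p < 0.05)),
    duration = lapply(ff$by, function(b)
      list(animal = b$animal, leg = b$leg, beta = b$duration$beta,
           converged = b$duration$converged,
           amplitude_at_median_v = b$duration$amplitude_at_median_v)))

  dev <- tryCatch(compute_deviations(cycles, ff),
                  error = function(e) fail("deviations", e))
  if (is.null(dev)) return(finish_report(report, log, config))
  report$timing_width_independence <-
    tryCatch(timing_width_independence(dev, ff),
             error = function(e) fail("timing_width", e))

  # --- feedback ---------------------------------------------------------
  levels <- unique(vapply(profile$leg_labels, ap_level, character(1)))
  focal <- profile$leg_labels[ap_level(profile$leg_labels) == levels[1]]
  fb <- tryCatch({
    lat <- r2_phase_profile(dev, "lateral", leg = focal)
    fa <- r2_phase_profile(dev, "fore_aft", leg = focal)
    cm <- control_magnitude(lat)
    sw_idx <- phase_index(lat$phase, lat$swing_onset)
    list(lateral = lat, fore_aft = fa, control_magnitude = cm,
         swing_onset = lat$swing_onset,
         gain_at_swing_onset = lat$gain_profile[, sw_idx])
  }, error = function(e) fail("feedback", e))
  if (!is.null(fb)) {
    report$feedback <- list(
      swing_onset = fb$swing_onset,
      r2_body_median = fb$lateral$median_body,
      r2_base_median = fb$lateral$median_base,
      ks_p_lateral = fb$lateral$ks_p,
      ks_p_fore_aft = fb$fore_aft$ks_p,
      control_magnitude = fb$control_magnitude,
      gain_at_swing_onset = fb$gain_at_swing_onset)
    report$directional <- tryCatch({
      dg <- directional_gains(dev, leg = focal)
      list(per_animal = dg$per_animal, phi = dg$phi,
           p = dg$test$p %||% NA_real_, d = dg$test$d %||% NA_real_,
           test = dg$test$test %||% NA_character_)
    }, error = function(e) fail("directional", e))
  }

  # --- stability and timescale -----------------------------------------
  report$stability <- tryCatch({
    animals <- unique(dev$meta$animal)
    rm_per <- vapply(animals, function(an)
      fit_return_map(dev, phi0 = config$phi0, leg = focal[1],
                     animal = an)$spectral_radius, numeric(1))
    pooled <- fit_return_map(dev, phi0 = config$phi0, leg = focal[1])
    er <- error_reduction_analysis(dev, leg = focal)
    list(rho_per_animal = rm_per, rho_mean = mean(rm_per),
         rho_pooled = pooled$spectral_radius,
         eigenvalues_pooled = Mod(pooled$eigenvalues),
         error_reduction_slope = er$slope, error_reduction_p = er$p,
         error_reduction_n = er$n)
  }, error = function(e) fail("stability", e))

  report$timescale <- tryCatch({
    per_leg <- lapply(profile$leg_labels, function(lg) {
      prof <- lag_correlation_profile(dev, leg = lg, N_max = config$N_max)
      ts <- fit_decay_timescale(prof, n_boot = config$n_boot,
                                ci_level = config$ci_level)
      list(leg = lg, r = prof$r, lag = prof$lag, r0 = ts$r0, tau = ts$tau,
           tau_ci = ts$tau_ci, flag = ts$flag)
    })
    taus <- vapply(per_leg, `[[`, numeric(1), "tau")
    best <- which.max(taus)
    list(per_leg = per_leg, tau_max = taus[best],
         tau_max_leg = per_leg[[best]]$leg,
         tau_max_ci = per_leg[[best]]$tau_ci)
  }, error = function(e) fail("timescale", e))

  # --- limb modularity --------------------------------------------------
  report$modularity <- tryCatch({
    animals <- unique(dev$meta$animal)
    r1 <- matrix(NA_real_, length(animals), length(levels),
                 dimnames = list(animals, levels))
    for (ai in seq_along(animals)) {
      sub <- dev
      keep <- dev$meta$animal == animals[ai]
      sub$meta <- dev$meta[keep, , drop = FALSE]
      sub$dQ <- dev$dQ[keep, , , drop = FALSE]
      sub$dQt <- dev$dQt[keep, , , drop = FALSE]
      for (lv in levels) {
        legs_lv <- profile$leg_labels[ap_level(profile$leg_labels) == lv]
        rs <- vapply(legs_lv, function(lg) {
          pr <- suppressWarnings(
            lag_correlation_profile(sub, leg = lg, N_max = 1L))
          if (any(pr$lag == 1L)) pr$r[pr$lag == 1L] else NA_real_
        }, numeric(1))
        r1[ai, lv] <- mean(rs, na.rm = TRUE)
      }
    }
    cmp <- if (length(levels) >= 2L && nrow(r1) >= 3L)
      compare_groups(lapply(seq_along(levels), function(j) r1[, j]) |>
                       stats::setNames(levels),
                     paired = length(levels) == 2L)
    else NULL
    list(lag1_by_level = r1,
         test = cmp$test %||% NA_character_, p = cmp$p %||% NA_real_,
         d = cmp$d %||% NA_real_, posthoc = cmp$posthoc)
  }, error = function(e) fail("modularity", e))

  finish_report(report, log, config)
}

finish_report <- function(report, log, config) {
  report$drop_log <- lapply(log$records, identity)
  report$ok <- length(report$failures) == 0L
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report,
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE, na = "null")
  }
  invisible(report)
}
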