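#' Pipeline configuration
#'
#' Bundles every stage parameter of the end-to-end analysis: the simulation
#' config, screening and preprocessing settings, the dissimilarity and model
#' windows, and the permutation-test settings. Per-participant and per-stage
#' seeds are derived deterministically from the master `seed`, so a config
#' fully determines the outputs.
#'
#' @param n_participants simulated participants.
#' @param sim a [sim_config()] template; its `seed` and
#'   `spatial_pattern_seed` are re-derived per participant.
#' @param smooth_halfwidth epoch smoothing half width, ms.
#' @param fit_window,shift_bounds linear-model fit window and shift bounds.
#' @param variant linear-model variant.
#' @param cluster_threshold_p,cluster_n_perm cluster-test settings.
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(n_participants = 3,
                            sim = sim_config(n_trials_per_cell = 10,
                                             n_channels = 16),
                            smooth_halfwidth = 10,
                            fit_window = c(30, 330),
                            shift_bounds = c(-60, 60),
                            variant = "reduced",
                            cluster_threshold_p = 0.05,
                            cluster_n_perm = 1000,
                            seed = 1) {
  structure(list(n_participants = as.integer(n_participants), sim = sim,
                 smooth_halfwidth = smooth_halfwidth,
                 fit_window = fit_window, shift_bounds = shift_bounds,
                 variant = variant,
                 cluster_threshold_p = cluster_threshold_p,
                 cluster_n_perm = as.integer(cluster_n_perm),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @export
save_pipeline_config <- function(config, path) {
  writeLines(jsonlite::serializeJSON(config, digits = NA), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
load_pipeline_config <- function(path) {
  jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n"))
}

# Neural + feature dissimilarities of one condition cell.
condition_dissim <- function(epochs_pp, irve, vel, block, contrast,
                             upper_dir, lower_dir, seed,
                             neural_time_points = NULL) {
  m <- epochs_pp$meta
  in_cell <- m$block == block & abs(m$contrast - contrast) < 1e-9
  up <- in_cell & abs(m$target_dir - upper_dir) < 1e-9
  lo <- in_cell & abs(m$target_dir - lower_dir) < 1e-9
  if (sum(up) < 3 || sum(lo) < 3)
    stop(sprintf("condition %s/%s has < 3 trials per direction after screening",
                 block, format(contrast)), call. = FALSE)
  list(
    neural = crossval_dissimilarity(subset_epochs(epochs_pp, up),
                                    subset_epochs(epochs_pp, lo), seed = seed,
                                    time_points = neural_time_points),
    irve = feature_dissimilarity(subset_features(irve, up),
                                 subset_features(irve, lo), seed = seed),
    vel = feature_dissimilarity(subset_features(vel, up),
                                subset_features(vel, lo), seed = seed))
}

#' Run the full synthetic analysis pipeline
#'
#' Chains simulate -> screen -> behavior -> features -> dissimilarity ->
#' model fit -> residuals -> cluster test for `n_participants` simulated
#' participants, writes every artifact under `out_dir`, and returns a
#' manifest with the seeds used and an md5 hash of every written file.
#' Re-running with the same config reproduces identical hashes.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return the manifest (also written to `manifest.json`), listing per-stage
#'   status, outputs and hashes. On a stage failure the manifest records the
#'   failing stage and the error, and the function stops.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot_msg(inherits(config, "pipeline_config"),
                "config must be a pipeline_config")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, stages = list(), status = "running")
  files <- character()
  stage <- function(name, code) {
    res <- tryCatch(code, error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res))
      manifest$status <<- paste0("failed at stage ", name)
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(res)), call. = FALSE)
    }
    manifest$stages[[name]] <<- list(status = "ok")
    res
  }
  dirs <- sort(config$sim$directions)
  upper_dir <- max(dirs); lower_dir <- min(dirs)
  contrasts <- sort(config$sim$contrasts)
  ct_label <- function(ct) vapply(ct, function(z) trimws(format(100 * z)), "")

  ddy100 <- matrix(NA_real_, config$n_participants, length(contrasts),
                   dimnames = list(NULL, ct_label(contrasts)))
  resid_vmi <- lapply(contrasts, function(ct)
    matrix(NA_real_, config$n_participants,
           diff(config$fit_window) + 1L))
  names(resid_vmi) <- ct_label(contrasts)
  fits <- vector("list", config$n_participants)

  for (p in seq_len(config$n_participants)) {
    pseed <- config$seed + 1000L * p
    pdir <- file.path(out_dir, sprintf("participant%02d", p))
    scfg <- config$sim
    scfg$seed <- pseed
    scfg$spatial_pattern_seed <- pseed + 7L
    validate_sim_config(scfg)

    traces <- stage(sprintf("simulate_p%d", p), {
      tr <- simulate_eye_traces(scfg)
      files <- c(files, write_eye_traces(tr, file.path(pdir, "traces")))
      tr
    })
    epochs <- stage(sprintf("epochs_p%d", p), generate_epochs(traces, scfg))
    kept <- stage(sprintf("screen_p%d", p), {
      rep_ <- screen_saccades(traces)
      utils::write.csv(rep_$rejected,
                       file.path(pdir, "rejected_trials.csv"),
                       row.names = FALSE)
      files <- c(files, file.path(pdir, "rejected_trials.csv"))
      idx <- traces$meta$trial_id %in% rep_$kept_trial_ids
      list(traces = subset_traces(traces, idx),
           epochs = subset_epochs(epochs, idx))
    })
    stage(sprintf("behavior_p%d", p), {
      for (ci in seq_along(contrasts)) {
        ct <- contrasts[ci]
        sub <- subset_traces(kept$traces,
                             abs(kept$traces$meta$contrast - ct) < 1e-9)
        td <- rotate_and_distance(sub, upper_dir = upper_dir,
                                  lower_dir = lower_dir)
        ddy100[p, ci] <- td$value_at_100ms
        f <- file.path(pdir, sprintf("delta_y_contrast%s.csv", ct_label(ct)))
        utils::write.csv(data.frame(time = td$time, td$delta_y,
                                    delta_delta_y = td$delta_delta_y),
                         f, row.names = FALSE)
        files <- c(files, f)
      }
      NULL
    })
    feats <- stage(sprintf("features_p%d", p), {
      rve <- retinal_velocity_error(kept$traces,
                                    target_speed = scfg$target_speed)
      list(irve = integrate_rve(rve), vel = motor_features(kept$traces)$velocity)
    })
    dis <- stage(sprintf("dissim_p%d", p), {
      pp <- preprocess_epochs(kept$epochs,
                              smooth_halfwidth = config$smooth_halfwidth)
      out <- list()
      for (bl in c("valid", "invalid")) for (ct in contrasts) {
        key <- paste0(bl, "_", ct_label(ct))
        out[[key]] <- condition_dissim(pp, feats$irve, feats$vel, bl, ct,
                                       upper_dir, lower_dir,
                                       seed = pseed + 13L,
                                       neural_time_points =
                                         seq(config$fit_window[1],
                                             config$fit_window[2]))
        f <- file.path(pdir, paste0("dissim_neural_", key, ".csv"))
        write_dissim(out[[key]]$neural, f)
        files <- c(files, f)
      }
      out
    })
    fit <- stage(sprintf("fit_p%d", p), {
      des <- build_design(
        neural = lapply(dis, `[[`, "neural"),
        sensory = list(irve = lapply(dis, `[[`, "irve")),
        motor = list(eye_velocity = lapply(dis, `[[`, "vel")),
        window = config$fit_window)
      ft <- fit_dissim_model(des, variant = config$variant,
                             shift_bounds = config$shift_bounds)
      f <- file.path(pdir, "fit.json")
      write_fit_json(ft, f)
      files <- c(files, f)
      ft
    })
    fits[[p]] <- fit
    stage(sprintf("residuals_p%d", p), {
      rd <- residual_differences(fit)
      for (ct in names(rd$valid_minus_invalid))
        resid_vmi[[ct]][p, ] <- rd$valid_minus_invalid[[ct]]
      f <- file.path(pdir, "residuals.csv")
      utils::write.csv(cbind(time = rd$time, as.data.frame(t(rd$residuals))),
                       f, row.names = FALSE)
      files <- c(files, f)
      NULL
    })
  }

  stage("group_stats", {
    summ <- list(
      ddy_at_100ms = as.data.frame(ddy100),
      t_s = vapply(fits, `[[`, 0, "t_s"),
      t_m = vapply(fits, `[[`, 0, "t_m"),
      r_squared = vapply(fits, `[[`, 0, "r_squared"))
    if (config$n_participants >= 2) {
      for (ct in names(resid_vmi)) {
        cl <- cluster_test(resid_vmi[[ct]],
                           threshold_p = config$cluster_threshold_p,
                           n_perm = config$cluster_n_perm,
                           seed = config$seed + 17L,
                           time = seq(config$fit_window[1],
                                      config$fit_window[2]))
        f <- file.path(out_dir,
                       paste0("cluster_residual_vmi_", ct, ".json"))
        write_cluster_json(cl, f)
        files <- c(files, f)
      }
      if (ncol(ddy100) >= 2 && config$n_participants >= 2)
        summ$ddy_low_vs_high <- scalar_test(ddy100[, 1], ddy100[, ncol(ddy100)],
                                            kind = "two_sample")
    }
    f <- file.path(out_dir, "summary.json")
    jsonlite::write_json(summ, f, digits = NA, auto_unbox = TRUE,
                         force = TRUE)
    files <- c(files, f)
    NULL
  })

  manifest$status <- "complete"
  files <- unique(files)
  manifest$outputs <- data.frame(
    file = sub(paste0("^", out_dir, "/?"), "", files),
    md5 = unname(tools::md5sum(files)), stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
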