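#' Run configuration
#'
#' Assembles (or reads from YAML) the configuration of an end-to-end run:
#' either a phantom specification (the self-contained mode) or paths to
#' measured inputs, plus forward-model, motion and shim settings.
#'
#' @param phantom a [phantom_spec()] (self-contained mode), or `NULL` to read
#'   volumes from `paths`.
#' @param paths named list of input NIfTI paths (`ute`, `echo1_real`,
#'   `echo1_imag`, `echo2_real`, `echo2_imag`, `brain_mask`) used when no
#'   phantom is given; every referenced path must exist.
#' @param TE echo times s (file mode; phantom mode takes them from the spec).
#' @param sh_coeffs length-9 shim coefficients (file mode).
#' @param f0,pad_factor forward-model parameters.
#' @param transform a [rigid_transform()] for the motion stage.
#' @param deform_neck phantom-mode: deform the neck at the new position.
#' @param strategies subset of `c("transformed", "simulated", "combined")`.
#' @param mask_update use the new position's body mask for the simulated and
#'   combined strategies.
#' @param shim_downsample block factor for the shim stage.
#' @param out_dir output directory (`NULL` = nothing written).
#' @param seed seed for any stochastic stage.
#' @return a `run_config` list.
#' @export
run_config <- function(phantom = phantom_spec(), paths = NULL, TE = NULL,
                       sh_coeffs = NULL, f0 = 123.2e6, pad_factor = 3,
                       transform = rigid_transform(), deform_neck = FALSE,
                       strategies = c("transformed", "simulated", "combined"),
                       mask_update = FALSE, shim_downsample = 1L,
                       out_dir = NULL, seed = 1L) {
  if (is.null(phantom)) {
    need <- c("ute", "echo1_real", "echo1_imag", "echo2_real", "echo2_imag",
              "brain_mask")
    missing <- setdiff(need, names(paths))
    if (length(missing))
      stop("paths missing inputs: ", paste(missing, collapse = ", "))
    for (p in unlist(paths)) if (!file.exists(p)) stop("missing input: ", p)
    if (is.null(TE) || is.null(sh_coeffs))
      stop("file mode needs TE and sh_coeffs")
  }
  structure(list(phantom = phantom, paths = paths, TE = TE,
                 sh_coeffs = sh_coeffs, f0 = f0, pad_factor = pad_factor,
                 transform = transform, deform_neck = deform_neck,
                 strategies = strategies, mask_update = mask_update,
                 shim_downsample = as.integer(shim_downsample),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' Round-trips the serialisable fields of a [run_config()] (phantom spec,
#' transform parameters, scalars). Functions in neither direction touch
#' volumes.
#'
#' @param path YAML file path.
#' @param config a `run_config`.
#' @return `read_run_config` returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  ser <- config
  class(ser) <- NULL
  if (!is.null(ser$phantom)) {
    ph <- unclass(ser$phantom)
    ph$chi <- as.list(ph$chi); ph$ute_mean <- as.list(ph$ute_mean)
    ph$ute_sd <- as.list(ph$ute_sd); ph$gre_mag <- as.list(ph$gre_mag)
    ser$phantom <- ph
  }
  if (!is.null(ser$transform))
    ser$transform <- list(rot_deg = ser$transform$rot_deg,
                          trans_mm = ser$transform$trans_mm)
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  ph <- NULL
  if (!is.null(y$phantom)) {
    p <- y$phantom
    ph <- phantom_spec(
      n = p$n, vox = p$vox, f0 = p$f0, head_center = unlist(p$head_center),
      head_semiaxes = unlist(p$head_semiaxes),
      scalp_thickness = p$scalp_thickness,
      skull_thickness = p$skull_thickness, brain_margin = p$brain_margin,
      cavity_margin = p$cavity_margin,
      cavities = lapply(p$cavities, function(cv)
        list(center = unlist(cv$center), radius = cv$radius)),
      cavity_chi = if (is.null(p$cavity_chi)) NULL else unlist(p$cavity_chi),
      neck_radius = p$neck_radius, neck_center_xy = unlist(p$neck_center_xy),
      spine_radius = p$spine_radius, chi = unlist(p$chi),
      ute_mean = unlist(p$ute_mean), ute_sd = unlist(p$ute_sd),
      gre_mag = unlist(p$gre_mag), TE = unlist(p$TE),
      pe_slope_a = p$pe_slope_a,
      dipole = list(P = p$dipole$P, rd = unlist(p$dipole$rd)),
      sh = unlist(p$sh), b0_shift = p$b0_shift, noise_sd = p$noise_sd,
      deform = list(center = unlist(p$deform$center),
                    semiaxes = unlist(p$deform$semiaxes)),
      pad_factor = p$pad_factor, seed = p$seed)
  }
  run_config(phantom = ph, paths = y$paths, TE = unlist(y$TE),
             sh_coeffs = unlist(y$sh_coeffs), f0 = y$f0,
             pad_factor = y$pad_factor,
             transform = rigid_transform(unlist(y$transform$rot_deg),
                                         unlist(y$transform$trans_mm)),
             deform_neck = isTRUE(y$deform_neck),
             strategies = unlist(y$strategies),
             mask_update = isTRUE(y$mask_update),
             shim_downsample = y$shim_downsample,
             out_dir = y$out_dir, seed = y$seed)
}

stage <- function(name, log, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
  log(sprintf("stage=%s elapsed=%.1fs", name,
              as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full field-prediction pipeline
#'
#' Chains segmentation, the three-class forward calculation, the reference
#' decomposition, the multi-segment susceptibility fit, the position
#' predictions and the shim optimisation; writes every intermediate volume, a
#' JSON metrics report and a structured log when `out_dir` is set.
#'
#' In phantom mode the ground-truth moved measurement is simulated and every
#' prediction is scored against it; shim currents solved on each prediction
#' are cross-evaluated on the moved measured map.
#'
#' @param config a [run_config()].
#' @return the run report (named list), invisibly also written as JSON.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  logs <- character(0)
  log <- function(msg) {
    logs <<- c(logs, sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg))
  }
  log(sprintf("b0predict %s seed=%d",
              as.character(utils::packageVersion("b0predict")), config$seed))

  if (!is.null(config$phantom)) {
    truth <- stage("simulate", log, generate_phantom(config$phantom))
    echoes <- truth$echoes; TE <- truth$TE
    ute <- truth$ute; brain_mask <- truth$brain_mask
    vox <- truth$spec$vox; f0 <- truth$spec$f0
    sh_coeffs <- truth$sh_effective
  } else {
    ute <- read_volume(config$paths$ute)
    re1 <- read_volume(config$paths$echo1_real)
    im1 <- read_volume(config$paths$echo1_imag)
    re2 <- read_volume(config$paths$echo2_real)
    im2 <- read_volume(config$paths$echo2_imag)
    bm <- read_volume(config$paths$brain_mask)
    echoes <- list(complex(real = re1$data, imaginary = im1$data),
                   complex(real = re2$data, imaginary = im2$data))
    echoes <- lapply(echoes, array, dim = dim(re1$data))
    brain_mask <- bm$data > 0.5
    TE <- config$TE; vox <- ute$vox[1]; f0 <- config$f0
    sh_coeffs <- config$sh_coeffs
    truth <- NULL
  }
  dims <- dim(ute$data)
  pad <- config$pad_factor

  seg <- stage("segment", log, {
    x <- neg_log_transform(ute)
    fit <- fit_histogram_peaks(x)
    list(x = x, fit = fit,
         three = segment_three_class(x, fit),
         multi = segment_multi_class(x, fit, brain_mask))
  })
  chi3 <- assign_literature_chi(seg$three)
  B_SH <- sh_shim_field(sh_coeffs, dims, vox)
  Bchi3 <- stage("forward", log,
                 susceptibility_to_field(chi3, pad, f0))
  dec <- stage("decompose", log,
               decompose_reference(echoes, TE, B_SH, Bchi3, brain_mask, vox))
  log(sprintf("decompose: a=%.3f P=%.3g rd=(%.0f,%.0f,%.0f) shift=%.2fHz cost=%.3fHz",
              if (is.null(dec$pe_model)) NA else dec$pe_model$a,
              dec$dipole_fit$dipole$P, dec$dipole_fit$dipole$rd[1],
              dec$dipole_fit$dipole$rd[2], dec$dipole_fit$dipole$rd[3],
              dec$b0_shift, dec$dipole_fit$cost))

  voi <- if (!is.null(truth)) truth$voi else {
    fake <- list(spec = list(head_center = c(0, 0, 0), vox = vox),
                 body_mask = ute$data > 0.1 * max(ute$data),
                 labels = array(0L, dims))
    phantom_voi_partition(structure(fake, class = "phantom_truth"), 8L)
  }
  fitres <- stage("fit-chi", log, {
    design <- build_design_basis(seg$multi, voi, brain_mask, pad, f0)
    B_diff_m <- dec$measured - dec$B_SH - dec$Bchi_p - dec$Bk - dec$b0_shift
    fit_susceptibilities(B_diff_m, brain_mask, design)
  })
  log(sprintf("fit-chi: pairs=%d cost %.3f -> %.3f Hz",
              nrow(fitres$pairs), fitres$cost_init, fitres$cost_final))

  ref <- b0_reference(dec$measured, dec$B_SH, dec$Bk, dec$Bchi_p,
                      dec$b0_shift, fitres$chi_map, brain_mask,
                      if (!is.null(truth)) truth$body_mask else
                        ute$data > 0.1 * max(ute$data),
                      f0, pad, Bchi_m = fitres$Bchi_m)

  report <- list(
    seed = config$seed,
    segmentation = list(center_soft = seg$fit$center_soft,
                        fwhm_soft = seg$fit$fwhm_soft,
                        center_noise = seg$fit$center_noise,
                        fwhm_noise = seg$fit$fwhm_noise,
                        bone_interval = seg$three$interval),
    decomposition = list(ky_slope_a = if (is.null(dec$pe_model)) NA else
                           dec$pe_model$a,
                         dipole_P = dec$dipole_fit$dipole$P,
                         dipole_rd = dec$dipole_fit$dipole$rd,
                         b0_shift_hz = dec$b0_shift,
                         cost_hz = dec$dipole_fit$cost,
                         smr_rmse_hz = sqrt(mean(
                           dec$SMR$data[brain_mask & valid_mask(dec$SMR)]^2))),
    chi_fit = list(n_pairs = nrow(fitres$pairs),
                   cost_init_hz = fitres$cost_init,
                   cost_final_hz = fitres$cost_final,
                   mmr_rmse_hz = sqrt(mean(
                     ref$MMR$data[brain_mask & valid_mask(ref$MMR)]^2)))
  )

  preds <- list()
  if (length(config$strategies) > 0) {
    moved <- if (!is.null(truth))
      stage("move-truth", log,
            apply_motion(truth, config$transform, config$deform_neck))
    else NULL
    new_mask <- NULL
    measured_new <- NULL
    brain_new <- NULL
    if (!is.null(moved)) {
      measured_new <- compute_field_map(moved$echoes[[1]], moved$echoes[[2]],
                                        TE, vox)
      brain_new <- moved$brain_mask
      if (config$mask_update) {
        mag <- vvol(Mod(moved$echoes[[1]]), vox, "1")
        new_mask <- body_mask_from_magnitude(mag)
      }
    }
    preds <- stage("predict", log, {
      out <- list()
      for (s in config$strategies) {
        p <- switch(s,
                    transformed = predict_transformed_fm(ref, config$transform),
                    simulated = predict_simulated_fm(ref, config$transform,
                                                     new_mask),
                    combined = predict_combined_fm(ref, config$transform,
                                                   new_mask))
        rep_s <- if (!is.null(measured_new))
          score_prediction(p$fm, measured_new, brain_new, s) else NULL
        out[[s]] <- list(fm = p$fm, report = rep_s)
        if (!is.null(rep_s))
          log(sprintf("predict %s: RMSE=%.2fHz volSD meas=%.2f pred=%.2f",
                      s, rep_s$rmse_hz, rep_s$vol_sd_measured_hz,
                      rep_s$vol_sd_predicted_hz))
      }
      out
    })
    report$prediction <- lapply(preds, function(p)
      if (is.null(p$report)) NULL else unclass(p$report))

    if (!is.null(measured_new)) {
      shim <- stage("shim", log, {
        ds <- config$shim_downsample
        sys0 <- generate_coil_basis(dims = as.integer(ceiling(dims / ds)),
                                    vox = vox * ds)
        meas_ds <- downsample_for_shim(measured_new, ds)
        brain_ds <- downsample_for_shim(
          vvol(brain_new * 1, vox, "1"), ds)$data > 0.5
        base <- solve_shim_currents(meas_ds, brain_ds, sys0)
        out <- list(baseline = evaluate_shim(meas_ds, base$currents, sys0,
                                             brain_ds))
        out$baseline$currents <- base$currents
        for (s in names(preds)) {
          pred_ds <- downsample_for_shim(preds[[s]]$fm, ds)
          sol <- solve_shim_currents(pred_ds, brain_ds, sys0)
          ev <- evaluate_shim(meas_ds, sol$currents, sys0, brain_ds)
          ev$currents <- sol$currents
          out[[s]] <- ev
        }
        out
      })
      report$shim <- lapply(shim, function(e)
        e[c("vol_sd_before_hz", "vol_sd_after_hz", "pct_reduction",
            "currents")])
      for (s in names(report$shim))
        log(sprintf("shim %s: VolSD %.2f -> %.2f Hz (%.1f%%)",
                    s, report$shim[[s]]$vol_sd_before_hz,
                    report$shim[[s]]$vol_sd_after_hz,
                    report$shim[[s]]$pct_reduction))
    }
  }

  report$log <- logs
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wv <- function(v, name)
      write_volume(v, file.path(config$out_dir, paste0(name, ".nii.gz")))
    wv(ute, "ute")
    wv(seg$x, "ute_neglog")
    wv(vvol(seg$three$labels * 1, vox, "1"), "labels_three_class")
    wv(vvol(seg$multi$labels * 1, vox, "1"), "labels_multi_class")
    wv(chi3, "chi_three_class")
    wv(dec$measured, "fm_measured")
    wv(dec$B_SH, "b_sh"); wv(dec$Bchi, "b_chi"); wv(dec$Bk, "b_k")
    wv(dec$Bchi_p, "b_chi_prime"); wv(dec$SMR, "smr")
    wv(fitres$chi_map, "chi_fitted"); wv(fitres$Bchi_m, "b_chi_m")
    wv(ref$MMR, "mmr")
    for (s in names(preds)) wv(preds[[s]]$fm, paste0("fm_pred_", s))
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    writeLines(logs, file.path(config$out_dir, "run.log"))
  }
  report
}
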