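# End-to-end phantom pipeline: simulate -> fit-dti -> fit-noddi -> track (x2)
# -> [calibrate] -> quantify -> roc, with every artifact written to a run
# directory and a JSON manifest recording paths, parameters and the package
# version.  Stages are re-runnable individually: each reads its inputs back
# from the run directory and fails with the name of the stage to run first
# when an upstream artifact is missing.

#' Parse a plain-text run configuration
#'
#' One `key = value` pair per line; `#` starts a comment. Multi-valued keys
#' (e.g. `grid_shape = 40 40 40`) are whitespace-separated. Every random stage
#' draws its seed from the mandatory `seed` key.
#'
#' @param path config file
#' @return a validated named list (class `run_config`)
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  kv <- strsplit(lines, "\\s*=\\s*")
  cfg <- stats::setNames(lapply(kv, function(x) paste(x[-1], collapse = "=")),
                         vapply(kv, `[`, "", 1L))
  run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg named list of raw (string or numeric) settings
#' @export
run_config <- function(cfg = list()) {
  num <- function(key, default) {
    v <- cfg[[key]]
    if (is.null(v)) return(default)
    as.numeric(strsplit(trimws(as.character(v)), "\\s+")[[1]])
  }
  chr <- function(key, default) {
    v <- cfg[[key]]
    if (is.null(v)) default else trimws(as.character(v))
  }
  flag <- function(key, default) {
    v <- cfg[[key]]
    if (is.null(v)) return(default)
    tolower(trimws(as.character(v))) %in% c("1", "true", "yes")
  }
  if (is.null(cfg$seed))
    stop("validation error: config must set an explicit `seed`", call. = FALSE)
  out <- list(
    output_dir = chr("output_dir", "nodditract-run"),
    seed = as.integer(num("seed", NA)),
    grid_shape = as.integer(num("grid_shape", c(40, 40, 40))),
    voxel_size = num("voxel_size", 2.5),
    snr = num("snr", 30),
    edema_viso = num("edema_viso", 0.9),
    edema_mild_viso = num("edema_mild_viso", NA_real_),
    bundle_radius = num("bundle_radius", 3),
    bundle_bend = num("bundle_bend", 0),
    fa_threshold = num("fa_threshold", 0.20),
    odi_threshold = num("odi_threshold", 0.45),
    max_angle = num("max_angle", 60),
    step = num("step", 0.5),
    min_length = num("min_length", 30),
    max_length = num("max_length", 300),
    streamline_count = as.integer(num("streamline_count", 3000)),
    calibrate = flag("calibrate", FALSE),
    calibrate_thresholds = num("calibrate_thresholds", seq(0.2, 1, 0.05)),
    calibrate_count = as.integer(num("calibrate_count", 300)),
    log_level = chr("log_level", "info"))
  if (is.na(out$seed))
    stop("validation error: `seed` must be an integer", call. = FALSE)
  stopifnot(length(out$grid_shape) == 3L, out$step > 0,
            out$min_length < out$max_length, out$streamline_count > 0)
  structure(out, class = "run_config")
}

pipe_log <- function(cfg, fmt, ...) {
  msg <- sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...)
  if (!identical(cfg$log_level, "quiet")) message(msg)
  logfile <- file.path(cfg$output_dir, "run.log")
  if (dir.exists(cfg$output_dir)) cat(msg, "\n", file = logfile, append = TRUE)
  invisible(NULL)
}

need_artifact <- function(path, producing_stage) {
  if (!file.exists(path))
    stop(sprintf("missing artifact `%s`: run stage `%s` first",
                 basename(path), producing_stage), call. = FALSE)
  path
}

pipe_paths <- function(dir) {
  p <- function(...) file.path(dir, ...)
  list(dwi = p("dwi.nii.gz"), bval = p("dwi.bval"), bvec = p("dwi.bvec"),
       lesion = p("mask_lesion.nii.gz"), edema = p("mask_edema.nii.gz"),
       analysis = p("mask_analysis.nii.gz"),
       inc1 = p("roi_include_inferior.nii.gz"),
       inc2 = p("roi_include_superior.nii.gz"),
       exc1 = p("roi_exclude_left.nii.gz"), exc2 = p("roi_exclude_right.nii.gz"),
       gt_viso = p("gt_viso.nii.gz"), gt_odi = p("gt_odi.nii.gz"),
       fa = p("dti_fa.nii.gz"), md = p("dti_md.nii.gz"), e1 = p("dti_e1.nii.gz"),
       odi = p("noddi_odi.nii.gz"), mu = p("noddi_mu.nii.gz"),
       kappa = p("noddi_kappa.nii.gz"),
       vf_ic = p("noddi_vf_ic.nii.gz"), vf_ec = p("noddi_vf_ec.nii.gz"),
       vf_iso = p("noddi_vf_iso.nii.gz"),
       noddi_ok = p("noddi_fitted.nii.gz"),
       tck_dti = p("tract_dti.tck"), tck_noddi = p("tract_noddi.tck"),
       tmask_dti = p("tractmask_dti.nii.gz"),
       tmask_noddi = p("tractmask_noddi.nii.gz"),
       calib = p("calibration.tsv"), metrics = p("metrics.tsv"),
       roc = p("roc.tsv"), manifest = p("manifest.json"))
}

#' Run the phantom pipeline
#'
#' @param config a `run_config` (or path to a config file)
#' @param stages subset of
#'   `c("simulate", "fit-dti", "fit-noddi", "track", "calibrate", "quantify",
#'   "roc")` to execute, in pipeline order; defaults to all (calibration only
#'   when enabled in the config)
#' @return invisibly, the manifest list (also written as JSON)
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "fit-dti", "fit-noddi",
                                    "track", "calibrate", "quantify", "roc")) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  pp <- pipe_paths(cfg$output_dir)
  if (!cfg$calibrate) stages <- setdiff(stages, "calibrate")
  manifest <- list(package = "nodditract",
                   version = as.character(utils::packageVersion("nodditract")),
                   config = unclass(cfg), stages = stages, artifacts = list())
  add_art <- function(stage, ...) {
    manifest$artifacts[[stage]] <<- unlist(list(...))
  }

  spec <- phantom_spec(grid_shape = cfg$grid_shape,
                       voxel_size_mm = cfg$voxel_size[1],
                       bundle_radius_vox = cfg$bundle_radius[1],
                       bundle_bend_vox = cfg$bundle_bend[1],
                       edema_viso = cfg$edema_viso[1],
                       edema_mild_viso = cfg$edema_mild_viso[1],
                       snr = cfg$snr[1], rng_seed = cfg$seed)

  if ("simulate" %in% stages) {
    pipe_log(cfg, "simulate: %s grid, snr %g, seed %d",
             paste(cfg$grid_shape, collapse = "x"), cfg$snr, cfg$seed)
    gt <- build_phantom(spec)
    scheme <- make_protocol(seed = cfg$seed)
    dwi <- simulate_dwi(gt, scheme, snr = cfg$snr, rng_seed = cfg$seed + 1L)
    write_dwi(dwi, scheme, pp$dwi, pp$bval, pp$bvec)
    write_mask(gt$lesion, pp$lesion); write_mask(gt$edema, pp$edema)
    write_mask(gt$analysis, pp$analysis)
    write_mask(gt$include$inferior, pp$inc1)
    write_mask(gt$include$superior, pp$inc2)
    write_mask(gt$exclude$left, pp$exc1); write_mask(gt$exclude$right, pp$exc2)
    write_nifti_grid(image_grid(gt$viso, affine = gt$affine), pp$gt_viso)
    gt_odi <- array(NA_real_, dim = dim(gt$kappa))
    ok <- !is.na(gt$kappa)
    gt_odi[ok] <- odi_from_kappa(gt$kappa[ok])
    write_nifti_grid(image_grid(gt_odi, affine = gt$affine), pp$gt_odi)
    add_art("simulate", dwi = pp$dwi, bval = pp$bval, bvec = pp$bvec,
            lesion = pp$lesion, edema = pp$edema, analysis = pp$analysis,
            include = c(pp$inc1, pp$inc2), exclude = c(pp$exc1, pp$exc2),
            gt_viso = pp$gt_viso, gt_odi = pp$gt_odi)
  }

  if ("fit-dti" %in% stages) {
    need_artifact(pp$dwi, "simulate")
    pipe_log(cfg, "fit-dti: weighted log-linear fit, b < 1500")
    din <- read_dwi(pp$dwi, pp$bval, pp$bvec)
    mask <- read_mask(pp$analysis, din$dwi)
    tf <- fit_dti(din$dwi, din$scheme, mask = mask)
    write_nifti_grid(tf$fa, pp$fa); write_nifti_grid(tf$md, pp$md)
    write_nifti_grid(tf$e1, pp$e1)
    add_art("fit-dti", fa = pp$fa, md = pp$md, e1 = pp$e1)
  }

  if ("fit-noddi" %in% stages) {
    need_artifact(pp$dwi, "simulate")
    need_artifact(pp$e1, "fit-dti")
    pipe_log(cfg, "fit-noddi: grid init + Nelder-Mead refinement")
    din <- read_dwi(pp$dwi, pp$bval, pp$bvec)
    mask <- read_mask(pp$analysis, din$dwi)
    e1 <- read_nifti_grid(pp$e1)
    nf <- fit_noddi(din$dwi, din$scheme, mask, init_mu = e1$data)
    write_nifti_grid(nf$odi, pp$odi); write_nifti_grid(nf$mu, pp$mu)
    write_nifti_grid(nf$kappa, pp$kappa)
    write_nifti_grid(nf$vf_ic, pp$vf_ic); write_nifti_grid(nf$vf_ec, pp$vf_ec)
    write_nifti_grid(nf$vf_iso, pp$vf_iso)
    write_nifti_grid(image_grid(array(as.numeric(nf$fitted), dim = dim(nf$fitted)),
                                affine = nf$odi$affine), pp$noddi_ok)
    add_art("fit-noddi", odi = pp$odi, mu = pp$mu, kappa = pp$kappa,
            vf_ic = pp$vf_ic, vf_ec = pp$vf_ec, vf_iso = pp$vf_iso,
            fitted = pp$noddi_ok)
  }

  if ("track" %in% stages) {
    need_artifact(pp$fa, "fit-dti")
    need_artifact(pp$odi, "fit-noddi")
    ref <- read_nifti_grid(pp$fa)
    rois <- roi_set(include = list(read_mask(pp$inc1, ref),
                                   read_mask(pp$inc2, ref)),
                    exclude = list(read_mask(pp$exc1, ref),
                                   read_mask(pp$exc2, ref)))
    seed_mask <- read_mask(pp$inc1, ref)
    for (mode in c("dti", "noddi")) {
      tr <- track_mode(pp, mode, cfg, rois, seed_mask,
                       threshold = if (mode == "dti") cfg$fa_threshold
                                   else cfg$odi_threshold,
                       count = cfg$streamline_count,
                       rng_seed = cfg$seed + if (mode == "dti") 2L else 3L)
      tck <- if (mode == "dti") pp$tck_dti else pp$tck_noddi
      tm <- if (mode == "dti") pp$tmask_dti else pp$tmask_noddi
      write_tractogram(tr, tck)
      write_mask(tract_mask(tr, ref), tm)
      pipe_log(cfg, "track (%s): %d streamlines, %d attempts%s", mode,
               length(tr$streamlines), tr$provenance$attempts,
               if (tr$provenance$starved) " [starved]" else "")
    }
    add_art("track", tck = c(pp$tck_dti, pp$tck_noddi),
            masks = c(pp$tmask_dti, pp$tmask_noddi))
  }

  if ("calibrate" %in% stages) {
    need_artifact(pp$tmask_dti, "track")
    pipe_log(cfg, "calibrate: ODI sweep over %d thresholds",
             length(cfg$calibrate_thresholds))
    ref <- read_nifti_grid(pp$fa)
    rois <- roi_set(include = list(read_mask(pp$inc1, ref),
                                   read_mask(pp$inc2, ref)),
                    exclude = list(read_mask(pp$exc1, ref),
                                   read_mask(pp$exc2, ref)))
    seed_mask <- read_mask(pp$inc1, ref)
    tractor <- function(theta) {
      tract_mask(track_mode(pp, "noddi", cfg, rois, seed_mask,
                            threshold = theta, count = cfg$calibrate_count,
                            rng_seed = cfg$seed + 4L), ref)
    }
    sw <- calibrate_odi_threshold(list(read_mask(pp$tmask_dti, ref)),
                                  list(tractor),
                                  thresholds = cfg$calibrate_thresholds)
    utils::write.table(
      data.frame(threshold = sw$thresholds, mean_dice = sw$mean_dice),
      pp$calib, sep = "\t", row.names = FALSE, quote = FALSE)
    pipe_log(cfg, "calibrate: optimal ODI threshold %.2f", sw$optimal_threshold)
    add_art("calibrate", table = pp$calib)
  }

  if ("quantify" %in% stages) {
    need_artifact(pp$tmask_dti, "track")
    need_artifact(pp$edema, "simulate")
    ref <- read_nifti_grid(pp$fa)
    fit <- list(vf_ic = read_nifti_grid(pp$vf_ic),
                vf_ec = read_nifti_grid(pp$vf_ec),
                vf_iso = read_nifti_grid(pp$vf_iso),
                fitted = as_mask_array(read_nifti_grid(pp$noddi_ok)$data))
    class(fit) <- "noddi_fit"
    row <- quantify_tracts(read_mask(pp$tmask_dti, ref),
                           read_mask(pp$tmask_noddi, ref),
                           read_mask(pp$edema, ref),
                           read_mask(pp$lesion, ref), fit = fit)
    utils::write.table(row, pp$metrics, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    pipe_log(cfg, "quantify: LTD %.2f mm, N-only PIV %.4f",
             row$ltd_mm, row$n_only_piv)
    add_art("quantify", table = pp$metrics)
  }

  if ("roc" %in% stages) {
    tab <- read_table1()
    rows <- lapply(c(edema_volume_mm3 = "edema_volume_mm3", ltd_mm = "ltd_mm"),
                   function(col) {
      r <- roc(tab[[col]], tab$motor_decline, larger = "no")
      data.frame(index = col, auc = r$auc,
                 youden_threshold = r$youden_threshold, youden_j = r$youden_j)
    })
    out <- do.call(rbind, rows)
    utils::write.table(out, pp$roc, sep = "\t", row.names = FALSE, quote = FALSE)
    pipe_log(cfg, "roc: edema-volume AUC %.3f, LTD AUC %.3f",
             out$auc[1], out$auc[2])
    add_art("roc", table = pp$roc)
  }

  jsonlite::write_json(manifest, pp$manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  pipe_log(cfg, "manifest written to %s", pp$manifest)
  invisible(manifest)
}

# shared tracking-stage helper: loads maps, builds the stop rule and the
# NODDI validity guard, and runs the tracker
track_mode <- function(pp, mode, cfg, rois, seed_mask, threshold, count,
                       rng_seed) {
  if (mode == "dti") {
    metric <- read_nifti_grid(pp$fa)
    dirs <- read_nifti_grid(pp$e1)
    valid <- NULL
    rule_mode <- "floor"
  } else {
    metric <- read_nifti_grid(pp$odi)
    dirs <- read_nifti_grid(pp$mu)
    ok <- as_mask_array(read_nifti_grid(pp$noddi_ok)$data)
    viso <- read_nifti_grid(pp$vf_iso)$data
    guard <- ok & !is.na(viso) & viso < 0.95
    valid <- image_grid(array(as.numeric(guard), dim = dim(guard)),
                        affine = metric$affine)
    rule_mode <- "ceiling"
  }
  rule <- stop_rule(metric, mode = rule_mode, threshold = threshold,
                    max_angle_deg = cfg$max_angle, step_mm = cfg$step,
                    length_bounds_mm = c(cfg$min_length, cfg$max_length))
  track(dirs, rule, seed_mask, target_count = count, rng_seed = rng_seed,
        rois = rois, valid_mask = valid)
}
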