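#' Run the full registration and dose-fusion pipeline
#'
#' Orchestrates the end-to-end flow: preprocessing (reorientation, resampling
#' of the source onto the target grid, median denoising), coarse linear
#' registration, optionally the landmark-FFD phase (when a ROI and landmark
#' files are configured), intensity FFD, warping, evaluation, and optional
#' dose accumulation. All artifacts are written to the configured output
#' directory together with a machine-readable report, a per-iteration
#' objective log, and a manifest (config hash, seed, package version)
#' sufficient to reproduce the run.
#'
#' @param config path to a flat `key = value` parameter file, or an
#'   equivalent named list. Recognized keys: `target`, `source`, `out_dir`
#'   (required); `model` (`rigid`/`affine`/`ffd`/`multiphase`, default
#'   `ffd`); `coarse` (`affine`, `rigid`, `points`, `none`); `denoise_radius`;
#'   `denoise` (`true`/`false`); `metric`; `bins`; `levels`;
#'   `control_spacing`; `lffd_spacing`; `max_iter`; `interp`; `roi`
#'   (`x0,y0,z0,x1,y1,z1` mm); `target_landmarks`, `source_landmarks` (CSV
#'   paths); `init_transform` (path, `dof_in` analog); `reference_dose`,
#'   `source_dose` (paths); `labels_target`, `labels_source` (paths).
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with the report, the final transform and
#'   output paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  cfg_path <- NULL
  if (is.character(config) && length(config) == 1L) {
    cfg_path <- config
    config <- read_param_file(config)
  }
  if (!is.list(config)) stop("config must be a parameter-file path or a list")
  for (key in c("target", "source", "out_dir"))
    if (is.null(config[[key]]))
      stop("pipeline config is missing required key '", key, "'")
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.txt")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  say <- function(...) {
    msg <- paste0(...)
    writeLines(msg, log_con)
    if (!quiet) message(msg)
  }
  stage <- "setup"
  fail_marker <- file.path(out_dir, "FAILED")
  if (file.exists(fail_marker)) unlink(fail_marker)
  result <- tryCatch({
    num <- function(key, default) if (is.null(config[[key]])) default
                                  else as.numeric(config[[key]])
    str <- function(key, default) if (is.null(config[[key]])) default
                                  else as.character(config[[key]])
    flag <- function(key, default) if (is.null(config[[key]])) default
      else tolower(as.character(config[[key]])) %in% c("true", "1", "yes")

    stage <- "read"
    target <- read_volume(config$target)
    source <- read_volume(config$source)
    say("read: target ", paste(dim(target$voxels), collapse = "x"),
        ", source ", paste(dim(source$voxels), collapse = "x"))

    stage <- "preprocess"
    source <- reorient_to(source, target)
    source <- resample_to_reference(source, target,
                                    interp = str("interp", "linear"))
    if (flag("denoise", TRUE)) {
      r <- num("denoise_radius", 1)
      target_p <- median_denoise(target, r)
      source_p <- median_denoise(source, r)
      say("preprocess: median denoise radius ", r)
    } else {
      target_p <- target; source_p <- source
    }

    model <- str("model", "ffd")
    metric <- str("metric", "nmi")
    bins <- as.integer(num("bins", 64))
    levels <- as.integer(num("levels", 3))
    max_iter <- as.integer(num("max_iter", 20))
    interp <- str("interp", "linear")
    init_t <- if (!is.null(config$init_transform))
      read_transform(config$init_transform) else NULL

    roi <- NULL
    if (!is.null(config$roi)) {
      v <- as.numeric(strsplit(gsub("\\s", "", config$roi), ",")[[1]])
      if (length(v) != 6L) stop("roi must be 'x0,y0,z0,x1,y1,z1' in mm")
      roi <- roi_box(v[1:3], v[4:6])
    }
    P <- if (!is.null(config$target_landmarks))
      read_landmarks(config$target_landmarks) else NULL
    Q <- if (!is.null(config$source_landmarks))
      read_landmarks(config$source_landmarks) else NULL

    report <- list()
    report$cc_initial <- pearson_cc(target_p, source_p)
    report$nmi_initial <- nmi(target_p, source_p, bins = bins)

    stage <- "coarse"
    coarse <- str("coarse", if (model %in% c("rigid", "affine")) model else "affine")
    t_cur <- init_t
    if (coarse == "points") {
      if (is.null(P) || is.null(Q))
        stop("coarse=points requires target_landmarks and source_landmarks")
      t_cur <- composite_transform(global = fit_rigid_points(P, Q))
      say("coarse: point-based rigid fit")
    } else if (coarse %in% c("rigid", "affine")) {
      cfgl <- reg_config(metric = metric, bins = bins, max_iter = max_iter,
                         pyramid_levels = levels, interp = interp,
                         init_transform = t_cur)
      fit <- register_linear(target_p, source_p, coarse, cfgl)
      t_cur <- fit$transform
      say("coarse: intensity ", coarse, " metric ",
          signif(fit$initial_metric, 6), " -> ", signif(fit$final_metric, 6))
      log_states(fit$states, say)
    }

    stage <- "nonrigid"
    fit_nr <- NULL
    if (model == "multiphase") {
      if (is.null(roi) || is.null(P) || is.null(Q))
        stop("model=multiphase requires roi, target_landmarks and source_landmarks")
      cfg_lffd <- reg_config(control_spacing0 = num("lffd_spacing", 40),
                             pyramid_levels = levels, init_transform = t_cur)
      cfg_ffd <- reg_config(metric = metric, bins = bins, max_iter = max_iter,
                            pyramid_levels = levels, interp = interp,
                            control_spacing0 = num("control_spacing", 20))
      fit_nr <- register_multiphase(target_p, source_p, roi, P, Q,
                                    cfg_lffd, cfg_ffd)
      say("multiphase: landmark error ", signif(fit_nr$tre_before, 4),
          " mm -> ", signif(fit_nr$tre_after_lffd, 4), " mm after LFFD")
    } else if (model == "ffd") {
      cfg_ffd <- reg_config(metric = metric, bins = bins, max_iter = max_iter,
                            pyramid_levels = levels, interp = interp,
                            control_spacing0 = num("control_spacing", 20),
                            init_transform = t_cur)
      fit_nr <- register_ffd(target_p, source_p, cfg_ffd)
    }
    if (!is.null(fit_nr)) {
      t_cur <- fit_nr$transform
      say(model, ": metric ", signif(fit_nr$initial_metric, 6), " -> ",
          signif(fit_nr$final_metric, 6))
      log_states(fit_nr$states, say)
    }
    if (is.null(t_cur)) t_cur <- composite_transform()

    stage <- "warp"
    warped <- warp_image(source_p, t_cur, target_p, interp = interp)
    write_volume(warped, file.path(out_dir, "warped.nii.gz"))
    write_transform(t_cur, file.path(out_dir, "transform.tfm.json"))

    stage <- "evaluate"
    labels_t <- if (!is.null(config$labels_target))
      read_volume(config$labels_target) else NULL
    warped_labels <- NULL
    if (!is.null(config$labels_source)) {
      labels_s <- read_volume(config$labels_source)
      warped_labels <- warp_labels(labels_s, t_cur, target_p)
    }
    ev <- evaluate_registration(target_p, warped, labels_t, warped_labels,
                                transform = t_cur, bins = bins)
    report$cc_final <- ev$cc
    report$nmi_final <- ev$nmi
    report$jacobian_min <- ev$jacobian_min
    if (!is.null(ev$dice)) report$dice <- as.list(ev$dice)
    say("evaluate: cc ", signif(report$cc_initial, 6), " -> ",
        signif(report$cc_final, 6))

    stage <- "dose"
    if (!is.null(config$reference_dose) && !is.null(config$source_dose)) {
      dref <- read_dose(config$reference_dose, "reference")
      dsrc <- read_dose(config$source_dose, "fraction1")
      dwarp <- warp_dose(dsrc, t_cur, dref)
      dtotal <- accumulate_dose(dref, list(dwarp))
      write_dose(dwarp, file.path(out_dir, "dose_warped.nii.gz"))
      write_dose(dtotal, file.path(out_dir, "dose_total.nii.gz"))
      report$dose_total_max_gy <- max(dtotal$voxels)
      report$dose_total_mean_gy <- mean(dtotal$voxels)
      say("dose: accumulated max ", signif(report$dose_total_max_gy, 6), " Gy")
    }

    stage <- "report"
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest <- list(
      package = "rtfuse",
      version = as.character(utils::packageVersion("rtfuse")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      config = config[order(names(config))],
      config_hash = if (!is.null(cfg_path)) unname(tools::md5sum(cfg_path))
                    else unname(config_list_hash(config)),
      seed = num("seed", NA))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(list(report = report, transform = t_cur, out_dir = out_dir))
  }, error = function(e) {
    writeLines(c(paste("stage:", stage), conditionMessage(e)), fail_marker)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  result
}

log_states <- function(states, say) {
  for (i in seq_along(states)) {
    st <- states[[i]]
    if (is.null(st)) next
    h <- st$history
    for (r in seq_len(nrow(h)))
      say(sprintf("  level %d iter %d objective %.8f", i,
                  as.integer(h[r, 1]), h[r, 2]))
  }
}

# md5 of the canonicalized key=value text of an in-memory config
config_list_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  keys <- sort(names(config))
  writeLines(paste0(keys, "=", vapply(config[keys], function(x)
    paste(as.character(x), collapse = ","), "")), tf)
  tools::md5sum(tf)
}

#' Read a flat key = value parameter file
#'
#' Lines of the form `key = value`; blank lines and `#` comments are
#' ignored. This is the text analog of the GUI parameter panel (`par_in`).
#'
#' @param path parameter file path.
#' @return named list of character values.
#' @export
read_param_file <- function(path) {
  if (!file.exists(path)) stop("no such parameter file: ", path)
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop("malformed parameter line (need key = value): ", ln)
    out[[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
  }
  out
}
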