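#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end analysis with its conventional
#' default: the bone window 226 to 48,060 HU, the 4.0 mm local-best-fit
#' matching radius, the +/-5 mm deviation validity window, the 1 mm green
#' band, and the 1.5x / 3x IQR outlier fences. Inputs are either a
#' [phantom_spec()] (synthetic cohort mode) or file paths to a reference mesh
#' with region labels, rim polylines and landmarks plus per-subject meshes and
#' landmarks.
#'
#' @param output_dir run directory to create.
#' @param phantom a [phantom_spec()] for synthetic mode, or `NULL`.
#' @param paths named list for file mode: `reference` (STL/PLY), `regions`
#'   (JSON), `rims` (JSON), `landmarks` (JSON), `subjects` (character vector
#'   of mesh paths), `subject_landmarks` (JSON paths, same order).
#' @param resolution phantom resolution class.
#' @param hu_min,hu_max bone-window bounds (HU) used when segmenting volumes.
#' @param icp_radius local-best-fit matching radius, mm.
#' @param icp_tol,icp_max_iter ICP convergence controls.
#' @param refine run the ICP refinement after the 3-point alignment.
#' @param deviation_window validity window, mm.
#' @param deviation_method `"normal"` (normal projection; detects missing
#'   surface, the default here) or `"closest"` (closest point).
#' @param green_band false-colour green band half-width, mm.
#' @param iqr_normal,iqr_extreme Tukey fence multipliers.
#' @param k_clusters cluster count used in the cohort clustering (default 2,
#'   the favoured solution; the elbow scan is always reported as diagnostic).
#' @param k_max elbow scan upper bound.
#' @param seed run seed (phantom mode; also used for clustering restarts).
#' @param export_meshes write registered STL and false-colour PLY per subject.
#' @return a list of class `run_config`.
#' @export
pipeline_config <- function(output_dir,
                            phantom = phantom_spec(),
                            paths = NULL,
                            resolution = "coarse",
                            hu_min = 226, hu_max = 48060,
                            icp_radius = 4.0, icp_tol = 1e-6,
                            icp_max_iter = 100L, refine = TRUE,
                            deviation_window = 5.0,
                            deviation_method = c("normal", "closest"),
                            green_band = 1.0,
                            iqr_normal = 1.5, iqr_extreme = 3.0,
                            k_clusters = 2L, k_max = 6L,
                            seed = NULL, export_meshes = FALSE) {
  deviation_method <- match.arg(deviation_method)
  if (is.null(phantom) && is.null(paths)) {
    stop("either a phantom spec or input paths must be given")
  }
  if (!is.null(paths)) {
    need <- c("reference", "regions", "rims", "landmarks", "subjects",
              "subject_landmarks")
    miss <- setdiff(need, names(paths))
    if (length(miss)) stop("paths is missing: ", paste(miss, collapse = ", "))
    for (nm in setdiff(need, c("subjects", "subject_landmarks"))) {
      if (!file.exists(paths[[nm]])) {
        stop("input file for '", nm, "' not found: ", paths[[nm]])
      }
    }
  }
  if (is.null(seed)) seed <- if (!is.null(phantom)) phantom$seed else 1L
  structure(list(output_dir = output_dir, phantom = phantom, paths = paths,
                 resolution = resolution, hu_min = hu_min, hu_max = hu_max,
                 icp_radius = icp_radius, icp_tol = icp_tol,
                 icp_max_iter = icp_max_iter, refine = refine,
                 deviation_window = deviation_window,
                 deviation_method = deviation_method, green_band = green_band,
                 iqr_normal = iqr_normal, iqr_extreme = iqr_extreme,
                 k_clusters = as.integer(k_clusters),
                 k_max = as.integer(k_max), seed = as.integer(seed),
                 export_meshes = export_meshes),
            class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  ser <- config
  ser$output_dir <- NULL # the hash identifies the analysis, not its location
  ser$phantom <- unclass(ser$phantom)
  jsonlite::write_json(unclass(ser), tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

write_csv_hashed <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_csv_hashed <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Run the full analysis pipeline
#'
#' Orchestrates phantom generation (or input loading), registration of every
#' subject to the reference (3-point alignment + local best fit), region-wise
#' signed-deviation analysis with the seven summary parameters, landmark
#' construction and segment measurement, side pooling into the cutting-guide
#' template, and the cohort statistics. Every stage failure aborts with the
#' stage name and subject id.
#'
#' Artifacts written to the run directory: `reference.stl`, `regions.json`,
#' `reference_landmarks.json`, per-subject `transform_<id>.json` (plus
#' optional registered STL and false-colour PLY), `deviation_summary.csv`
#' (subject x region x side x 7 parameters), `measurements.csv`,
#' `region_summary.csv` (cohort mean/SD per region after excluding subjects
#' whose alveolar-region AVD is an extreme outlier), `template.csv`,
#' `cohort.csv`, `stats_report.json` and `run_log.txt`. All CSVs carry the
#' config hash in a leading comment line.
#'
#' @param config a [pipeline_config()].
#' @return the run directory path, invisibly; attributes carry the main
#'   in-memory results (`deviation`, `measurements`, `template`,
#'   `region_summary`, `stats`, `truth` in phantom mode).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop("config must be a pipeline_config()")
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  log_lines <- c(sprintf("maxillomorph %s",
                         as.character(utils::packageVersion("maxillomorph"))),
                 sprintf("R %s", as.character(getRversion())),
                 sprintf("seed: %d", config$seed),
                 sprintf("config_hash: %s", hash),
                 sprintf("started: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  stage <- function(name, id, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed for subject %s: %s",
                   name, as.character(id), conditionMessage(e)), call. = FALSE)
    })
  }

  # ---- inputs ----
  if (!is.null(config$phantom)) {
    cohort <- stage("phantom", "-", synthesize_cohort(
      config$phantom, resolution = config$resolution))
    reference <- cohort$reference
    ref_mesh <- reference$mesh
    regions <- reference$regions
    ref_landmarks <- reference$landmarks
    rims <- reference$rims
    subjects <- cohort$subjects
    truth <- cohort$truth
  } else {
    p <- config$paths
    ref_mesh <- stage("inputs", "-", read_mesh_any(p$reference))
    regions <- stage("inputs", "-", read_region_labels(p$regions))
    ref_landmarks <- stage("inputs", "-", read_landmarks(p$landmarks))
    rims <- stage("inputs", "-", lapply(
      jsonlite::read_json(p$rims, simplifyVector = TRUE),
      function(m) matrix(unlist(m), ncol = 3L, byrow = FALSE)))
    subjects <- lapply(seq_along(p$subjects), function(i) {
      list(mesh = read_mesh_any(p$subjects[[i]]),
           landmarks = read_landmarks(p$subject_landmarks[[i]]),
           regions = regions, rims = NULL,
           truth = list(subject_id = i, sex = NA_character_, age = NA_real_))
    })
    truth <- NULL
  }
  write_stl(ref_mesh, file.path(config$output_dir, "reference.stl"))
  write_region_labels(regions, file.path(config$output_dir, "regions.json"))
  write_landmarks(ref_landmarks,
                  file.path(config$output_dir, "reference_landmarks.json"))

  region_names <- paste0("R", 1:4)
  samples <- lapply(stats::setNames(names(regions), names(regions)),
                    function(rn) sample_region(ref_mesh, regions[[rn]]))

  dev_rows <- list()
  meas_rows <- list()
  for (si in seq_along(subjects)) {
    sub <- subjects[[si]]
    sid <- sub$truth$subject_id
    transform <- stage("registration", sid, register_subject(
      sub$mesh, ref_mesh, sub$landmarks, ref_landmarks,
      radius = config$icp_radius, refine = config$refine,
      tol = config$icp_tol, max_iter = config$icp_max_iter))
    write_transform(transform, file.path(
      config$output_dir, sprintf("transform_%03d.json", sid)))
    reg_mesh <- apply_transform(sub$mesh, transform)
    reg_landmarks <- apply_transform(sub$landmarks, transform)

    fields <- list()
    for (rn in names(regions)) {
      fld <- stage("deviation", sid, signed_deviation(
        samples[[rn]], reg_mesh, window = config$deviation_window,
        method = config$deviation_method))
      fields[[rn]] <- fld
      sm <- summarize_region(fld)
      parts <- strsplit(rn, "_", fixed = TRUE)[[1L]]
      dev_rows[[length(dev_rows) + 1L]] <-
        cbind(data.frame(subject_id = sid, region = parts[1L],
                         side = parts[2L]), sm)
    }
    if (config$export_meshes) {
      write_stl(reg_mesh, file.path(config$output_dir,
                                    sprintf("registered_%03d.stl", sid)))
      stage("export", sid, export_subject_ply(
        ref_mesh, regions, fields, config,
        file.path(config$output_dir, sprintf("deviation_%03d.ply", sid))))
    }

    reg_rims <- if (!is.null(sub$rims)) {
      lapply(sub$rims, function(pm) apply_transform(pm[, , drop = FALSE],
                                                    transform))
    } else {
      rims
    }
    lm <- stage("planner", sid, construct_landmarks(
      reg_mesh, sub$regions, reg_rims,
      annotations = reg_landmarks))
    for (side in c("left", "right")) {
      meas_rows[[length(meas_rows) + 1L]] <-
        stage("planner", sid, measure_segments(lm, side, subject_id = sid))
    }
  }
  deviation <- do.call(rbind, dev_rows)
  measurements <- do.call(rbind, meas_rows)
  write_csv_hashed(deviation,
                   file.path(config$output_dir, "deviation_summary.csv"), hash)
  write_csv_hashed(measurements,
                   file.path(config$output_dir, "measurements.csv"), hash)

  # ---- cohort level ----
  # exclusion rule: subjects whose alveolar-process (R4) AVD is an extreme
  # outlier are excluded from the R4 cohort summaries
  r4 <- deviation[deviation$region == "R4", ]
  excluded <- integer(0)
  if (nrow(r4) >= 4L) {
    fl <- iqr_outliers(r4$AVD, config$iqr_normal, config$iqr_extreme)
    excluded <- sort(unique(r4$subject_id[fl$flags == "extreme"]))
  }
  keep_dev <- !(deviation$region == "R4" &
                  deviation$subject_id %in% excluded)
  region_summary <- do.call(rbind, lapply(region_names, function(rg) {
    d <- deviation[keep_dev & deviation$region == rg, ]
    stats_cols <- c("Dmax", "Dmin", "Dmean", "DSD", "AVD", "ID", "IAD")
    out <- data.frame(region = rg, n = nrow(d))
    for (cl in stats_cols) {
      out[[paste0("mean_", cl)]] <- mean(d[[cl]], na.rm = TRUE)
      out[[paste0("sd_", cl)]] <- stats::sd(d[[cl]][!is.na(d[[cl]])])
    }
    out
  }))
  write_csv_hashed(region_summary,
                   file.path(config$output_dir, "region_summary.csv"), hash)

  template <- pool_sides(measurements)
  write_csv_hashed(as.data.frame(template),
                   file.path(config$output_dir, "template.csv"), hash)

  if (!is.null(truth)) {
    write_csv_hashed(truth, file.path(config$output_dir, "truth.csv"), hash)
    cohort_df <- data.frame(
      n = nrow(truth),
      male = report_count_pct(sum(truth$sex == "male"), nrow(truth)),
      female = report_count_pct(sum(truth$sex == "female"), nrow(truth)),
      age_mean = mean(truth$age), age_median = stats::median(truth$age),
      age_sd = stats::sd(truth$age),
      age_range = report_range(min(truth$age), max(truth$age)))
    write_csv_hashed(cohort_df, file.path(config$output_dir, "cohort.csv"),
                     hash)
  }

  stats_report <- cohort_statistics(deviation[keep_dev, ], truth, config)
  stats_report$excluded_subjects_R4 <- excluded
  stats_report$config_hash <- hash
  jsonlite::write_json(stats_report,
                       file.path(config$output_dir, "stats_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  log_lines <- c(log_lines,
                 sprintf("subjects: %d", length(subjects)),
                 sprintf("excluded_R4: %s",
                         paste(excluded, collapse = " ") ),
                 sprintf("finished: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  writeLines(log_lines, file.path(config$output_dir, "run_log.txt"))

  invisible(structure(config$output_dir, deviation = deviation,
                      measurements = measurements, template = template,
                      region_summary = region_summary, stats = stats_report,
                      truth = truth))
}

read_mesh_any <- function(path) {
  if (grepl("\\.ply$", path, ignore.case = TRUE)) read_ply(path)
  else read_stl(path)
}

export_subject_ply <- function(ref_mesh, regions, fields, config, path) {
  all_faces <- unlist(regions, use.names = FALSE)
  combined <- list(d = numeric(0), valid = logical(0),
                   area_weights = numeric(0),
                   window = config$deviation_window,
                   method = config$deviation_method)
  for (rn in names(regions)) {
    f <- fields[[rn]]
    combined$d <- c(combined$d, f$d)
    combined$valid <- c(combined$valid, f$valid)
    combined$area_weights <- c(combined$area_weights, f$area_weights)
  }
  class(combined) <- "deviation_field"
  export_colored_ply(ref_mesh, all_faces, combined, path,
                     green_band = config$green_band)
}

# per-region cohort statistics on the deviation table: sex differences of the
# mean distance (Welch), outlier counts by sex, k-means clustering with sex
# composition, elbow diagnostic
cohort_statistics <- function(deviation, truth, config) {
  out <- list()
  if (is.null(truth)) return(out)
  dv <- merge(deviation, truth[, c("subject_id", "sex", "age")],
              by = "subject_id")
  for (rg in paste0("R", 1:4)) {
    d <- dv[dv$region == rg & !is.na(dv$Dmean), ]
    # per-subject value: mean over sides (side affiliation not retained)
    agg <- stats::aggregate(d[, c("Dmean", "ID", "IAD", "AVD")],
                            by = list(subject_id = d$subject_id), FUN = mean)
    agg <- merge(agg, truth[, c("subject_id", "sex", "age")],
                 by = "subject_id")
    entry <- list(n = nrow(agg))
    m <- agg$Dmean[agg$sex == "male"]
    f <- agg$Dmean[agg$sex == "female"]
    if (length(m) >= 2L && length(f) >= 2L &&
        (stats::var(m) > 0 || stats::var(f) > 0)) {
      wt <- welch_t(m, f)
      entry$welch_Dmean_by_sex <- list(statistic = wt$statistic, df = wt$df,
                                       p_value = wt$p_value)
    }
    if (nrow(agg) >= 4L) {
      fl <- iqr_outliers(agg$Dmean, config$iqr_normal, config$iqr_extreme)
      entry$outliers_Dmean <- list(
        normal = sum(fl$flags == "normal"),
        extreme = sum(fl$flags == "extreme"),
        extreme_by_sex = table(agg$sex[fl$flags == "extreme"]))
      or <- tryCatch(pearson_r(agg$age, agg$Dmean), error = function(e) NA)
      entry$pearson_age_Dmean <- or
    }
    if (length(unique(agg$Dmean)) >= config$k_clusters) {
      cl <- kmeans_1d(agg$Dmean, config$k_clusters, seed = config$seed)
      entry$kmeans_Dmean <- list(
        k = cl$k, centers = cl$centers,
        composition = as.list(tapply(agg$sex, cl$assignments, function(s) {
          c(male = sum(s == "male"), female = sum(s == "female"))
        })))
    }
    if (length(unique(agg$Dmean)) >= config$k_max) {
      ek <- elbow_select(agg$Dmean, k_max = config$k_max, seed = config$seed)
      entry$elbow_Dmean <- list(k = as.integer(ek),
                                low_confidence = attr(ek, "low_confidence"))
    }
    out[[rg]] <- entry
  }
  out
}

#' Report-cell formatting helpers
#'
#' `report_count_pct(34, 50)` renders the cohort-characteristics cell
#' `"34 (68%)"`; `report_range(20, 89)` renders the age-range cell
#' `"69 (20-89)"` (range value = max - min).
#'
#' @param count,total non-negative counts, `total > 0`.
#' @return a character scalar.
#' @export
report_count_pct <- function(count, total) {
  if (total <= 0) stop("total must be positive")
  sprintf("%d (%d%%)", as.integer(count), as.integer(round(100 * count / total)))
}

#' @rdname report_count_pct
#' @param min,max range endpoints (`max >= min`).
#' @export
report_range <- function(min, max) {
  if (max < min) stop("max must be >= min")
  rng <- max - min
  fmt <- function(x) {
    if (abs(x - round(x)) < 1e-9) sprintf("%d", as.integer(round(x)))
    else sprintf("%.1f", x)
  }
  sprintf("%s (%s-%s)", fmt(rng), fmt(min), fmt(max))
}

#' Render a human-readable run report
#'
#' Reads the artifacts of a completed [run_pipeline()] directory and renders
#' the cohort characteristics, the region x parameter summary and the
#' cutting-guide template with two-decimal rounding.
#'
#' @param run_dir a completed run directory.
#' @return character vector of report lines (also printed).
#' @export
make_report <- function(run_dir) {
  need <- c("region_summary.csv", "template.csv", "deviation_summary.csv")
  have <- file.exists(file.path(run_dir, need))
  if (!dir.exists(run_dir) || !all(have)) {
    stop("incomplete run; missing artifacts: ",
         paste(need[!have], collapse = ", "))
  }
  lines <- c("maxillomorph run report", strrep("=", 40))
  cohort_path <- file.path(run_dir, "cohort.csv")
  if (file.exists(cohort_path)) {
    ch <- read_csv_hashed(cohort_path)
    lines <- c(lines, "Cohort characteristics",
               sprintf("  n: %d", ch$n),
               sprintf("  male: %s   female: %s", ch$male, ch$female),
               sprintf("  age mean (median): %.2f (%.2f)",
                       ch$age_mean, ch$age_median),
               sprintf("  age range (min-max): %s", ch$age_range),
               sprintf("  age SD: %.2f", ch$age_sd), "")
  }
  rs <- read_csv_hashed(file.path(run_dir, "region_summary.csv"))
  lines <- c(lines, "Region deviation summary (mean +/- SD, pooled sides)")
  for (i in seq_len(nrow(rs))) {
    lines <- c(lines, sprintf(
      "  %s (n=%d): Dmean %.2f (%.2f)  DSD %.2f (%.2f)  AVD %.2f (%.2f)  ID %.2f (%.2f)  IAD %.2f (%.2f)",
      rs$region[i], rs$n[i], rs$mean_Dmean[i], rs$sd_Dmean[i],
      rs$mean_DSD[i], rs$sd_DSD[i], rs$mean_AVD[i], rs$sd_AVD[i],
      rs$mean_ID[i], rs$sd_ID[i], rs$mean_IAD[i], rs$sd_IAD[i]))
  }
  tp <- read_csv_hashed(file.path(run_dir, "template.csv"))
  lines <- c(lines, "", "Cutting-guide template (segment measurements)")
  for (i in seq_len(nrow(tp))) {
    lines <- c(lines, sprintf(
      "  %-6s (n=%d): AX %.2f +/- %.2f mm   MX %.2f +/- %.2f mm   angle %.2f +/- %.2f deg",
      tp$cell[i], tp$n[i], tp$mean_length_AX_mm[i], tp$sd_length_AX_mm[i],
      tp$mean_length_MX_mm[i], tp$sd_length_MX_mm[i],
      tp$mean_angle_deg[i], tp$sd_angle_deg[i]))
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
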