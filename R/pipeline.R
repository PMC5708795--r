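#' Write an elevation map as CSV
#'
#' Simple text dialect: two header lines `# grid_spacing_mm=...` and
#' `# half_width_mm=...`, then the square sag matrix in um, comma-separated,
#' `NaN` for invalid samples. Values are written with full double precision
#' so a write/read round trip is lossless.
#'
#' @param map An `elevation_map` (or `prp_map`; values then in diopters).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_elevation_csv <- function(map, path) {
  vals <- map$sag %||% map$prp
  vals[!map$valid] <- NaN
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# grid_spacing_mm=%.17g", map$spacing),
    sprintf("# half_width_mm=%.17g", map$half_width)
  ), con)
  utils::write.table(
    format(vals, digits = 17, trim = TRUE, scientific = TRUE),
    con, sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  invisible(path)
}

read_grid_header <- function(lines) {
  get1 <- function(key) {
    hit <- grep(paste0("^#\\s*", key, "="), lines, value = TRUE)
    if (length(hit) != 1) stop(sprintf("missing or duplicated header '%s'", key))
    as.numeric(sub(paste0("^#\\s*", key, "="), "", hit))
  }
  list(spacing = get1("grid_spacing_mm"), half_width = get1("half_width_mm"))
}

#' Read an elevation map from CSV
#'
#' @param path Path to a file written by [write_elevation_csv()].
#' @return An `elevation_map`; `NaN` cells become the invalid mask.
#' @export
read_elevation_csv <- function(path) {
  lines <- readLines(path)
  hdr <- read_grid_header(lines)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  rows <- strsplit(body, ",")
  n <- length(rows)
  if (any(lengths(rows) != n)) stop("elevation matrix is not square")
  m <- matrix(as.numeric(unlist(rows)), nrow = n, byrow = TRUE)
  exp_hw <- (n - 1) / 2 * hdr$spacing
  if (abs(exp_hw - hdr$half_width) > 1e-6) {
    stop("half_width header inconsistent with matrix size and spacing")
  }
  elevation_map(m, hdr$spacing)
}

#' Read a PRP map from CSV
#'
#' Same dialect as [read_elevation_csv()], values interpreted as diopters.
#'
#' @param path Input path.
#' @param zone_diameter Grading zone diameter (mm).
#' @return A `prp_map`.
#' @export
read_prp_csv <- function(path, zone_diameter = 6) {
  lines <- readLines(path)
  hdr <- read_grid_header(lines)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  rows <- strsplit(body, ",")
  n <- length(rows)
  if (any(lengths(rows) != n)) stop("PRP matrix is not square")
  m <- matrix(as.numeric(unlist(rows)), nrow = n, byrow = TRUE)
  as_prp_map(m, hdr$spacing, zone_diameter)
}

#' Persist a cohort to disk
#'
#' Writes one elevation CSV per surface per record plus a manifest CSV
#' (`eye_id`, `group`, `timepoint`, demographics, `cct`, `bscva_z`, file
#' names) and the band/grid configuration as JSON. The written cohort can be
#' re-analyzed from disk alone.
#'
#' @param cohort An `ek_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ek_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (i in seq_along(cohort$records)) {
    rec <- cohort$records[[i]]
    cornea <- eye_cornea(cohort, i)
    stem <- sprintf("%s_%s", rec$eye_id, rec$timepoint)
    fa <- paste0(stem, "_anterior.csv")
    fp <- paste0(stem, "_posterior.csv")
    write_elevation_csv(cornea$anterior, file.path(dir, fa))
    write_elevation_csv(cornea$posterior, file.path(dir, fp))
    rows[[i]] <- data.frame(
      eye_id = rec$eye_id, group = rec$group, timepoint = rec$timepoint,
      age = rec$age, sex = rec$sex, eye = rec$eye, cct = rec$cct,
      bscva_z = rec$bscva_z, anterior_file = fa, posterior_file = fp
    )
  }
  utils::write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  cfg <- list(
    grid = cohort$config$grid,
    bscva = unclass(cohort$config$bscva),
    groups = lapply(cohort$config$groups, function(g) {
      list(n = g$n, timepoints = g$timepoints, group = g$preset$group)
    })
  )
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Re-load a cohort directory written by [write_cohort()]
#'
#' Surfaces are read back from the elevation CSVs; the returned cohort is
#' materialized (geometry in memory) and can be passed to
#' [analyze_cohort()].
#'
#' @param dir Cohort directory.
#' @param bscva A [bscva_model()] for downstream analysis.
#' @return An `ek_cohort`.
#' @export
read_cohort <- function(dir, bscva = bscva_model()) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  records <- vector("list", nrow(man))
  grid <- NULL
  for (i in seq_len(nrow(man))) {
    ant <- read_elevation_csv(file.path(dir, man$anterior_file[i]))
    post <- read_elevation_csv(file.path(dir, man$posterior_file[i]))
    if (is.null(grid)) {
      grid <- list(half_width = ant$half_width, n = nrow(ant$sag),
                   spacing = ant$spacing)
    }
    records[[i]] <- list(
      eye_id = man$eye_id[i], group = man$group[i],
      timepoint = man$timepoint[i], age = man$age[i], sex = man$sex[i],
      eye = man$eye[i], cct = man$cct[i], bscva_z = man$bscva_z[i],
      cornea = cornea_model(ant, post, man$cct[i])
    )
  }
  cfg <- structure(list(groups = list(), grid = grid, bscva = bscva),
                   class = "cohort_config")
  structure(list(records = records, config = cfg), class = "ek_cohort")
}

#' Study configuration
#'
#' @param cohort A [cohort_config()].
#' @param seed Integer seed for the generator.
#' @param zones Analysis zone diameters (mm).
#' @param bands A [band_config()].
#' @param alpha Significance level, in (0, 1).
#' @param adjust Dunn adjustment, `"bonferroni"` or `"none"`.
#' @return An object of class `study_config`.
#' @export
study_config <- function(cohort = cohort_config(), seed = 1L,
                         zones = c(4, 6), bands = band_config(),
                         alpha = 0.05, adjust = "bonferroni") {
  if (any(zones <= 0)) stop("zones must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(
    list(cohort = cohort, seed = as.integer(seed), zones = zones,
         bands = bands, alpha = alpha, adjust = adjust),
    class = "study_config"
  )
}

metric_cell <- function(v) sprintf("%.2f ± %.2f", mean(v), stats::sd(v))

#' Run the full synthetic study
#'
#' Generation -> wavefront/Zernike metrics -> posterior grading -> BSCVA ->
#' statistics, deterministically from the config seed. Emits the study-shaped
#' summaries: demographics (table1), the aberration profile with Dunn
#' pairwise p values (table2), BSCVA correlations (table3) and the grade
#' trajectories.
#'
#' @param config A [study_config()].
#' @param out_dir Optional directory; when given, the per-eye metrics table
#'   and the three summary tables are written as CSV and the config as JSON.
#' @return An object of class `study_report`: list with `metrics` (per-eye
#'   data.frame), `table1`, `table2`, `table3`, `grade_trajectories`.
#' @export
run_study <- function(config = study_config(), out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  cohort <- sample_cohort(config$cohort, seed = config$seed)
  met <- analyze_cohort(cohort, zones = config$zones, cfg = config$bands)

  groups <- unique(met$group)
  by_g <- function(df, col) split(df[[col]], df$group)[groups]

  # demographics / table 1 (one row per variable, preoperative records)
  pre <- met[met$timepoint == "pre", ]
  sex_tab <- table(pre$group, pre$sex)[groups, , drop = FALSE]
  eye_tab <- table(pre$group, pre$eye)[groups, , drop = FALSE]
  t1 <- data.frame(
    variable = c("eyes_n", "sex_male_female", "age", "eye_R_L",
                 "bscva_logmar", "cct_um"),
    stringsAsFactors = FALSE
  )
  fmt_tab <- function(tab) {
    apply(tab, 1, function(r) paste(rev(r), collapse = "/"))
  }
  for (g in groups) {
    gg <- pre[pre$group == g, ]
    t1[[g]] <- c(
      nrow(gg),
      paste(sum(gg$sex == "M"), sum(gg$sex == "F"), sep = "/"),
      sprintf("%.1f ± %.1f", mean(gg$age), stats::sd(gg$age)),
      paste(sum(gg$eye == "R"), sum(gg$eye == "L"), sep = "/"),
      metric_cell(gg$bscva), sprintf("%.0f ± %.0f", mean(gg$cct),
                                     stats::sd(gg$cct))
    )
  }
  t1$p <- c(
    NA,
    chi2_test(sex_tab)$p_value,
    kruskal_wallis(by_g(pre, "age"))$p_value,
    chi2_test(eye_tab)$p_value,
    kruskal_wallis(by_g(pre, "bscva"))$p_value,
    kruskal_wallis(by_g(pre, "cct"))$p_value
  )
  t1$test <- c(NA, "chi-squared", "Kruskal-Wallis", "chi-squared",
               "Kruskal-Wallis", "Kruskal-Wallis")

  # aberration profile / table 2: metric x surface x timepoint cells with
  # Dunn pairwise p values at each timepoint where all three groups exist
  zones6 <- 6
  cells <- expand.grid(
    metric = c("hoa", "sa", "coma"), surface = c("total", "anterior", "posterior"),
    timepoint = intersect(tp_levels, unique(met$timepoint)),
    stringsAsFactors = FALSE
  )
  t2_rows <- list()
  ctrl <- met[met$group == "control", ]
  for (k in seq_len(nrow(cells))) {
    cl <- cells[k, ]
    col <- paste0(cl$metric, "_", cl$surface, "_", zones6)
    sub <- met[met$timepoint == cl$timepoint & met$group != "control", ]
    if (nrow(sub) == 0) next
    samples <- split(sub[[col]], sub$group)
    if (nrow(ctrl) > 0) samples$control <- ctrl[[col]]
    row <- data.frame(metric = toupper(cl$metric), surface = cl$surface,
                      timepoint = cl$timepoint, stringsAsFactors = FALSE)
    for (g in names(samples)) row[[g]] <- metric_cell(samples[[g]])
    if (length(samples) >= 3) {
      dn <- dunn_posthoc(samples, adjust = config$adjust)
      for (nm in names(dn)) {
        row[[paste0("p_", gsub("/", "_", nm))]] <- dn[[nm]]$p_value
      }
    }
    t2_rows[[length(t2_rows) + 1]] <- row
  }
  t2 <- do.call(rbind, t2_rows)

  # correlations / table 3 over postoperative EK records
  post <- met[met$group != "control" & met$timepoint != "pre", ]
  t3 <- NULL
  if (nrow(post) >= 3) {
    vars <- c(
      grade = "grade",
      hoa_total = "hoa_total_6", hoa_anterior = "hoa_anterior_6",
      hoa_posterior = "hoa_posterior_6",
      sa_total = "sa_total_6", sa_anterior = "sa_anterior_6",
      sa_posterior = "sa_posterior_6",
      coma_total = "coma_total_6", coma_anterior = "coma_anterior_6",
      coma_posterior = "coma_posterior_6"
    )
    t3_rows <- lapply(names(vars), function(nm) {
      pr <- pearson_r(post$bscva, post[[vars[nm]]], c("bscva", nm))
      data.frame(variable = nm, r = pr$r, p = pr$p_value, n = pr$n)
    })
    surgery <- ifelse(post$group == "DMEK", 1, 2)
    if (length(unique(surgery)) > 1) {
      pr <- pearson_r(post$bscva, surgery, c("bscva", "surgery"))
      t3_rows[[length(t3_rows) + 1]] <-
        data.frame(variable = "surgery_dmek1_dsaek2", r = pr$r,
                   p = pr$p_value, n = pr$n)
    }
    t3 <- do.call(rbind, t3_rows)
  }

  traj <- stats::aggregate(
    cbind(grade, bscva) ~ group + timepoint, data = met,
    FUN = function(v) c(mean = mean(v), sd = stats::sd(v))
  )
  traj <- do.call(data.frame, traj)
  names(traj) <- c("group", "timepoint", "grade_mean", "grade_sd",
                   "bscva_mean", "bscva_sd")

  report <- structure(
    list(metrics = met, table1 = t1, table2 = t2, table3 = t3,
         grade_trajectories = traj, config = config),
    class = "study_report"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(met, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    utils::write.csv(t1, file.path(out_dir, "table1.csv"), row.names = FALSE)
    utils::write.csv(t2, file.path(out_dir, "table2.csv"), row.names = FALSE)
    if (!is.null(t3)) {
      utils::write.csv(t3, file.path(out_dir, "table3.csv"), row.names = FALSE)
    }
    utils::write.csv(traj, file.path(out_dir, "grade_trajectories.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(seed = config$seed, zones = config$zones,
           alpha = config$alpha, adjust = config$adjust,
           bands = unclass(config$bands),
           grid = config$cohort$grid,
           groups = lapply(config$cohort$groups, function(g) {
             list(group = g$preset$group, n = g$n, timepoints = g$timepoints)
           })),
      file.path(out_dir, "study_config.json"), auto_unbox = TRUE, digits = NA
    )
  }
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("EK study report: %d eye-records\n", nrow(x$metrics)))
  cat("\nGrade trajectories (mean / sd):\n")
  print(x$grade_trajectories, digits = 3)
  invisible(x)
}

#' Grade a PRP map file and print the result as JSON
#'
#' Command-style entry point: reads a PRP CSV (elevation dialect, values in
#' diopters), grades it, prints the JSON grade record.
#'
#' @param map_path Path to a PRP CSV.
#' @param yellow_center,yellow_width,red_threshold,red_background_fraction
#'   Band options, see [band_config()].
#' @param zone_diameter Grading zone (mm).
#' @param quiet Suppress printing.
#' @return The `grade_result`, invisibly.
#' @export
grade_command <- function(map_path, yellow_center = -6.3, yellow_width = 0.3,
                          red_threshold = -6.9,
                          red_background_fraction = 0.75,
                          zone_diameter = 6, quiet = FALSE) {
  cfg <- band_config(yellow_center, yellow_width, red_threshold,
                     red_background_fraction)
  m <- read_prp_csv(map_path, zone_diameter)
  g <- posterior_grade(m, cfg)
  if (!quiet) cat(grade_to_json(g), "\n")
  invisible(g)
}
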