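# Orchestration: synthetic multi-lake runs through slope, exposure,
# indices and community statistics into a per-transect master table.

#' Area of a lake shallower than a given depth
#'
#' Cell-counting estimate of the area enclosed by an isobath: cells with
#' depth <= `depth` times the cell area, in hectares.
#'
#' @param grid a [depth_grid()].
#' @param depth threshold depth (m), e.g. 2.5 for the ESMI iso2.5 area.
#' @return area in ha.
#' @export
iso_area_ha <- function(grid, depth) {
  sum(grid$values <= depth, na.rm = TRUE) * grid$cell_size^2 / 1e4
}

#' Configuration of a synthetic pipeline run
#'
#' The defaults emulate the scale of the national monitoring pool the
#' method was developed on: 16 lowland lakes carrying 8-27 transects each,
#' 260 transects in total, TP between 0.015 and 0.049 mg/l, 6 years of
#' hourly wind.
#'
#' @param n_lakes number of lakes.
#' @param transects_per_lake integer vector (recycled/truncated to
#'   `n_lakes`); the default sums to 260 over 16 lakes.
#' @param radius_range_m range lake radii are drawn from.
#' @param max_depth_range_m range of maximum depths.
#' @param cell_size depth-grid resolution (m) for the run; 4 m keeps a
#'   full 16-lake run light while leaving dozens of cells per transect
#'   zone.
#' @param tp_range_mgL trophic gradient across lakes.
#' @param trophic_effect TP effect on charophyte cover (see
#'   [community_spec()]).
#' @param log_base logarithm base of the exposure index.
#' @param half_angle toward-sector half-width (degrees).
#' @param slope_thresholds named `c(gentle =, steep =)` class boundaries
#'   in degrees.
#' @param n_permutations IndVal permutations.
#' @param wind_years years of hourly wind per lake.
#' @param seed master seed; all stage seeds derive from it.
#' @param out_dir optional directory; when set, [run_pipeline()] writes
#'   CSV tables, geometries, rasters and a run manifest there.
#' @return object of class `run_config`.
#' @export
run_config <- function(n_lakes = 16L,
                       transects_per_lake = c(8L, 10L, 11L, 12L, 13L, 14L,
                                              15L, 16L, 17L, 18L, 19L,
                                              20L, 21L, 22L, 24L, 20L),
                       radius_range_m = c(250, 450),
                       max_depth_range_m = c(6, 16),
                       cell_size = 4, tp_range_mgL = c(0.015, 0.049),
                       trophic_effect = -2, log_base = exp(1),
                       half_angle = 45,
                       slope_thresholds = c(gentle = 1.32, steep = 8.42),
                       n_permutations = 999L, wind_years = 6L,
                       seed = 1L, out_dir = NULL) {
  stopifnot(n_lakes >= 1, slope_thresholds[["gentle"]] <
              slope_thresholds[["steep"]], cell_size > 0)
  tpl <- rep_len(as.integer(transects_per_lake), n_lakes)
  structure(list(n_lakes = as.integer(n_lakes), transects_per_lake = tpl,
                 radius_range_m = radius_range_m,
                 max_depth_range_m = max_depth_range_m,
                 cell_size = cell_size, tp_range_mgL = tp_range_mgL,
                 trophic_effect = trophic_effect, log_base = log_base,
                 half_angle = half_angle,
                 slope_thresholds = slope_thresholds,
                 n_permutations = as.integer(n_permutations),
                 wind_years = as.integer(wind_years),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Run the full synthetic pipeline
#'
#' For each lake: generate geometry/bathymetry/transects, an hourly wind
#' series and a survey table; derive per-transect shallow and deep
#' littoral slopes, effective fetch and exposure (both depth conventions),
#' the macrophyte metric block and ESMI_TR; classify slopes; then run
#' IndVal (with permutation p-values), SIMPER, the Spearman correlation
#' table and Kruskal-Wallis comparisons across slope classes. Lake-level
#' rows carry the averaged slopes/exposures and the lake ESMI. The whole
#' run is a pure function of the configuration (and its seed).
#'
#' @param config a [run_config()].
#' @return object of class `littoral_run`: `transects` (master table, one
#'   row per transect), `lakes` (one row per lake), `indval`,
#'   `correlations`, `comparisons`, `simper`, `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  shapes <- c("circle", "ellipse", "irregular")
  profiles <- c("conic", "two-slope", "planar-shelf")
  master <- list(); lakes <- list(); surveys <- list()

  for (i in seq_len(config$n_lakes)) {
    lake_id <- sprintf("L%02d", i)
    pars <- .with_seed(config$seed + 17L * i, {
      list(radius = stats::runif(1, config$radius_range_m[1L],
                                 config$radius_range_m[2L]),
           depth = stats::runif(1, config$max_depth_range_m[1L],
                                config$max_depth_range_m[2L]),
           tp = stats::runif(1, config$tp_range_mgL[1L],
                             config$tp_range_mgL[2L]),
           wind_dir = stats::runif(1, 0, 360),
           shelf = stats::runif(1, 0.02, 0.25),
           s1 = stats::runif(1, 0.015, 0.08),
           s2 = stats::runif(1, 0.12, 0.35))
    })
    spec <- lake_spec(shape = shapes[(i - 1L) %% 3L + 1L],
                      radius_m = pars$radius, max_depth_m = pars$depth,
                      profile = profiles[(i - 1L) %% 3L + 1L],
                      shelf_slope = pars$shelf, slope1 = pars$s1,
                      slope2 = pars$s2,
                      n_transects = config$transects_per_lake[i],
                      n_vertices = 360L, seed = config$seed + i)
    lake <- make_lake(spec, cell_size = config$cell_size,
                      lake_id = lake_id)

    csp <- community_spec(tp_range_mgL = config$tp_range_mgL,
                          trophic_effect = config$trophic_effect,
                          seed = config$seed + 1000L + i)
    survey <- make_survey(lake, csp, tp = pars$tp)
    for (k in seq_along(lake$transects))
      lake$transects[[k]]$c_max_tr <- survey$transect_info$c_max_tr[k]

    wind <- make_wind(wind_spec(mean_direction_deg = pars$wind_dir,
                                concentration = 1.5,
                                years = config$wind_years,
                                seed = config$seed + 2000L + i),
                      station_id = sprintf("ST%02d", i))

    slopes <- transect_slopes(lake$transects, lake$geometry, lake$grid)
    expo <- transect_exposure(lake$transects, lake$geometry, wind,
                              half_angle = config$half_angle,
                              log_base = config$log_base)
    idx <- survey_indices(survey, z_max = lake$geometry$z_max)

    m <- merge(merge(slopes, expo[, setdiff(names(expo), "lake_id")],
                     by = "transect_id"),
               idx[, setdiff(names(idx), "lake_id")], by = "transect_id")
    m$slope_class <- as.character(
      classify_slope(m$sl_cmax_deg, thresholds = config$slope_thresholds))
    m$tp_mgL <- pars$tp
    master[[i]] <- m
    surveys[[i]] <- survey

    pooled <- tapply(survey$data$rel_cover_pct, survey$data$syntaxon_code,
                     sum)
    J_lake <- shannon_evenness(as.numeric(pooled))$J
    cmax_lake <- max(survey$transect_info$c_max_tr)
    N <- iso_area_ha(lake$grid, cmax_lake) *
      mean(survey$transect_info$total_cover_pct) / 100
    iso25 <- iso_area_ha(lake$grid, 2.5)
    lakes[[i]] <- data.frame(
      lake_id = lake_id, lake_area_ha = lake$geometry$lake_area_ha,
      z_max = lake$geometry$z_max, tp_mgL = pars$tp,
      n_transects = length(lake$transects),
      avg_sl_1m = mean(m$sl_1m_deg), avg_sl_cmax = mean(m$sl_cmax_deg),
      avg_exp_1m = mean(m$exp_1m), avg_exp_cmax = mean(m$exp_cmax),
      esmi = esmi_lake(J_lake, N, iso25, lake$geometry$lake_area_ha))
  }

  master <- do.call(rbind, master)
  lakes <- do.call(rbind, lakes)

  all_data <- do.call(rbind, lapply(surveys, `[[`, "data"))
  comm <- community_matrix(list(data = all_data) |>
                             structure(class = "survey_table"),
                           min_occurrences = 4L)
  comm <- comm[master$transect_id, , drop = FALSE]
  groups <- factor(master$slope_class,
                   levels = c("gentle", "moderate", "steep"))
  groups <- droplevels(groups)

  iv <- NULL; simp <- NULL
  if (nlevels(groups) >= 2L && all(table(groups) >= 1L)) {
    iv <- indval_pvalue(comm, groups, n_perm = config$n_permutations,
                        seed = config$seed + 5000L)
    simp <- simper(comm, groups)
  }
  metrics <- master[, c("total_cover_pct", "s_tot", "s_he", "s_hy",
                        "s_ch", "pn_hy", "pn_ch", "shannon_h", "esmi_tr")]
  env <- master[, c("sl_1m_deg", "sl_cmax_deg", "exp_1m", "exp_cmax")]
  corr <- correlation_table(metrics, env)
  comparisons <- lapply(
    stats::setNames(nm = c("total_cover_pct", "esmi_tr")),
    function(v) if (nlevels(groups) >= 2L)
      group_comparison(master[[v]], groups) else NULL)

  run <- structure(list(transects = master, lakes = lakes, indval = iv,
                        correlations = corr, comparisons = comparisons,
                        simper = simp, config = config),
                   class = "littoral_run")
  if (!is.null(config$out_dir)) .write_run(run, surveys, config$out_dir)
  run
}

#' @noRd
.write_run <- function(run, surveys, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$transects, file.path(out_dir, "transects.csv"),
                   row.names = FALSE)
  utils::write.csv(run$lakes, file.path(out_dir, "lakes.csv"),
                   row.names = FALSE)
  if (!is.null(run$indval))
    utils::write.csv(run$indval, file.path(out_dir, "indval.csv"),
                     row.names = FALSE)
  utils::write.csv(run$correlations,
                   file.path(out_dir, "correlations.csv"),
                   row.names = FALSE)
  manifest <- list(
    package = "littoral",
    seed = run$config$seed,
    n_lakes = run$config$n_lakes,
    n_transects = nrow(run$transects),
    cell_size = run$config$cell_size,
    slope_thresholds = as.list(run$config$slope_thresholds),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.littoral_run <- function(x, ...) {
  cat(sprintf("<littoral_run> %d transects in %d lakes (seed %d)\n",
              nrow(x$transects), nrow(x$lakes), x$config$seed))
  cat("  slope classes:",
      paste(sprintf("%s=%d", names(table(x$transects$slope_class)),
                    table(x$transects$slope_class)), collapse = ", "),
      "\n")
  if (!is.null(x$indval))
    cat(sprintf("  indicator syntaxa (IndVal >= 0.5, p < 0.05): %d\n",
                sum(x$indval$indicator)))
  invisible(x)
}

#' Validate input files for a pipeline run
#'
#' Schema and sanity checks for wind CSVs, survey CSVs and lake GeoJSON:
#' cover sums per transect, wind timestamp ordering and gaps, direction
#' and speed ranges, isobath depths against z_max.
#'
#' @param wind_csv,survey_csv,survey_info_csv,lake_geojson optional paths;
#'   checks run for whichever are given.
#' @return data frame of class `validation_report` with columns `file`,
#'   `level` (`"error"`/`"warning"`), `message`; zero error rows means the
#'   inputs parse.
#' @export
validate_inputs <- function(wind_csv = NULL, survey_csv = NULL,
                            survey_info_csv = NULL, lake_geojson = NULL) {
  items <- list()
  note <- function(file, level, message)
    items[[length(items) + 1L]] <<- data.frame(file = file, level = level,
                                               message = message)
  if (!is.null(wind_csv)) {
    w <- tryCatch(read_wind_csv(wind_csv), error = function(e) e)
    if (inherits(w, "error")) {
      note(wind_csv, "error", conditionMessage(w))
    } else {
      rec <- w$records
      if (anyNA(rec$timestamp))
        note(wind_csv, "error", "unparseable timestamps")
      else {
        if (is.unsorted(rec$timestamp, strictly = TRUE))
          note(wind_csv, "error", "timestamps not strictly increasing")
        gaps <- diff(as.numeric(rec$timestamp))
        if (length(gaps) && max(gaps) > 30 * 86400)
          note(wind_csv, "warning",
               sprintf("timestamp gap of %.1f days", max(gaps) / 86400))
      }
      if (any(rec$dir_deg < 0 | rec$dir_deg >= 360))
        note(wind_csv, "error", "wind directions outside [0, 360)")
      if (any(rec$speed_ms < 0))
        note(wind_csv, "error", "negative wind speeds")
      if (any(rec$speed_ms > 60))
        note(wind_csv, "warning", "wind speeds above 60 m/s")
    }
  }
  if (!is.null(survey_csv)) {
    d <- tryCatch(utils::read.csv(survey_csv), error = function(e) e)
    if (inherits(d, "error")) {
      note(survey_csv, "error", conditionMessage(d))
    } else {
      need <- c("lake_id", "transect_id", "syntaxon_code", "group",
                "rel_cover_pct")
      miss <- setdiff(need, names(d))
      if (length(miss)) {
        note(survey_csv, "error",
             paste("missing columns:", paste(miss, collapse = ", ")))
      } else {
        sums <- tapply(d$rel_cover_pct, d$transect_id, sum)
        bad <- names(sums)[abs(sums - 100) > 1e-6]
        for (b in bad)
          note(survey_csv, "error",
               sprintf("transect %s: relative covers sum to %.4f, not 100",
                       b, sums[[b]]))
        if (any(d$rel_cover_pct < 0))
          note(survey_csv, "error", "negative relative covers")
        known <- c("hydrophyte", "charophyte", "helophyte")
        if (!all(d$group %in% known))
          note(survey_csv, "error",
               paste("unknown growth groups:",
                     paste(setdiff(unique(d$group), known),
                           collapse = ", ")))
      }
    }
  }
  if (!is.null(survey_info_csv)) {
    info <- tryCatch(utils::read.csv(survey_info_csv),
                     error = function(e) e)
    if (inherits(info, "error"))
      note(survey_info_csv, "error", conditionMessage(info))
    else if ("c_max_tr" %in% names(info) && any(info$c_max_tr < 0))
      note(survey_info_csv, "error", "negative colonisation depths")
  }
  if (!is.null(lake_geojson)) {
    g <- tryCatch(read_lake_geojson(lake_geojson), error = function(e) e)
    if (inherits(g, "error"))
      note(lake_geojson, "error", conditionMessage(g))
  }
  out <- if (length(items)) do.call(rbind, items) else
    data.frame(file = character(0), level = character(0),
               message = character(0))
  class(out) <- c("validation_report", class(out))
  out
}

#' @export
print.validation_report <- function(x, ...) {
  if (!nrow(x)) {
    cat("validation: all inputs pass\n")
  } else {
    cat(sprintf("validation: %d error(s), %d warning(s)\n",
                sum(x$level == "error"), sum(x$level == "warning")))
    for (i in seq_len(nrow(x)))
      cat(sprintf("  [%s] %s: %s\n", x$level[i], x$file[i], x$message[i]))
  }
  invisible(x)
}
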