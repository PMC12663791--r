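# Readers and writers for the tabular formats (station/underway CSV,
# EcoTaxa-style and plain cell tables, occurrence TSV) and the end-to-end
# pipeline driver. Files carry umol/L nutrient concentrations (urea in
# nmol/L); everything is converted to nmol/L at ingest. Writers prepend a
# schema-version comment line which the readers skip.

.schema_comment <- "# osmolimit table schema v1"

.read_table_checked <- function(path, sep, required, label) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(label, " schema error: missing column(s) ",
         paste(missing, collapse = ", "), " in ", path, call. = FALSE)
  df
}

.num_col <- function(df, col, path) {
  v <- df[[col]]
  out <- suppressWarnings(as.numeric(v))
  bad <- which(is.na(out) & !(is.na(v) | v %in% c("NA", "")))
  if (length(bad))
    stop("unparseable value '", v[bad[1]], "' in column ", col,
         ", data row ", bad[1], " of ", path, call. = FALSE)
  out
}

#' Read a station biogeochemistry table
#'
#' CSV with header `station_id, lat, lon, temp_c, sal, nh4_umol_l,
#' no2_umol_l, no3_umol_l, dip_umol_l[, urea_nmol_l]`. Nutrients are
#' converted from umol/L to the internal nmol/L (x1000); row order (track
#' order) is preserved and the along-track distance is derived.
#'
#' @param path CSV file.
#' @return Station data.frame in internal units.
#' @export
read_station_table <- function(path) {
  req <- c("station_id", "lat", "lon", "temp_c", "sal",
           "nh4_umol_l", "no2_umol_l", "no3_umol_l", "dip_umol_l")
  df <- .read_table_checked(path, ",", req, "station table")
  out <- data.frame(station_id = as.character(df$station_id),
                    lat = .num_col(df, "lat", path),
                    lon = .num_col(df, "lon", path),
                    temp_c = .num_col(df, "temp_c", path),
                    sal = .num_col(df, "sal", path),
                    ammonium = .num_col(df, "nh4_umol_l", path) * 1000,
                    nitrite = .num_col(df, "no2_umol_l", path) * 1000,
                    nitrate = .num_col(df, "no3_umol_l", path) * 1000,
                    phosphate = .num_col(df, "dip_umol_l", path) * 1000,
                    urea = if ("urea_nmol_l" %in% names(df))
                             .num_col(df, "urea_nmol_l", path)
                           else NA_real_,
                    stringsAsFactors = FALSE)
  out$along_track_km <- along_track_distance(out$lat, out$lon)
  message("read ", nrow(out), " station(s) from ", path,
          " (umol/L converted to nmol/L)")
  out
}

#' Write a station table
#'
#' Inverse of [read_station_table()]: internal nmol/L back to umol/L file
#' units (urea stays nmol/L), stable column order, schema comment line.
#'
#' @param stations station data.frame (internal units).
#' @param path output CSV.
#' @export
write_station_table <- function(stations, path) {
  out <- data.frame(station_id = stations$station_id,
                    lat = stations$lat, lon = stations$lon,
                    temp_c = stations$temp_c, sal = stations$sal,
                    nh4_umol_l = stations$ammonium / 1000,
                    no2_umol_l = stations$nitrite / 1000,
                    no3_umol_l = stations$nitrate / 1000,
                    dip_umol_l = stations$phosphate / 1000,
                    urea_nmol_l = stations$urea)
  writeLines(.schema_comment, path)
  suppressWarnings(utils::write.table(out, path, sep = ",", row.names = FALSE,
                                      quote = FALSE, append = TRUE))
  invisible(path)
}

#' Read an underway observation table
#'
#' CSV with header `iso_time, lat, lon, sst_c, sal`; timestamps ISO-8601,
#' interpreted as UTC.
#'
#' @param path CSV file.
#' @return data.frame with POSIXct `time` plus `lat`, `lon`, `sst_c`, `sal`.
#' @export
read_underway_table <- function(path) {
  df <- .read_table_checked(path, ",", c("iso_time", "lat", "lon",
                                         "sst_c", "sal"), "underway table")
  tm <- as.POSIXct(df$iso_time, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  if (any(is.na(tm)))
    stop("unparseable iso_time in row ", which(is.na(tm))[1], " of ", path,
         call. = FALSE)
  if (any(diff(as.numeric(tm)) <= 0))
    stop("underway timestamps must be strictly increasing", call. = FALSE)
  data.frame(time = tm, lat = .num_col(df, "lat", path),
             lon = .num_col(df, "lon", path),
             sst_c = .num_col(df, "sst_c", path),
             sal = .num_col(df, "sal", path), stringsAsFactors = FALSE)
}

#' Write an underway table
#' @param underway underway data.frame.
#' @param path output CSV.
#' @export
write_underway_table <- function(underway, path) {
  out <- data.frame(iso_time = format(underway$time, "%Y-%m-%dT%H:%M:%S",
                                      tz = "UTC"),
                    lat = underway$lat, lon = underway$lon,
                    sst_c = underway$sst_c, sal = underway$sal)
  writeLines(.schema_comment, path)
  suppressWarnings(utils::write.table(out, path, sep = ",", row.names = FALSE,
                                      quote = FALSE, append = TRUE))
  invisible(path)
}

#' Read an imaged-cell feature table
#'
#' Two dialects. `ecotaxa_tsv`: tab-separated export with `object_`-prefixed
#' columns and a secondary type row (`[t]`/`[f]`) directly under the header,
#' which is skipped; extra columns are tolerated. `plain_csv`: comma-
#' separated with the internal column names. When `pixel_calibration` is
#' given the axes are taken as pixels and scaled to um.
#'
#' @param path input file.
#' @param dialect `"ecotaxa_tsv"` or `"plain_csv"`.
#' @param pixel_calibration um per pixel, or `NULL` when axes are um.
#' @return data.frame with `object_id`, `time`, `lat`, `lon`, `major_um`,
#'   `minor_um`, `taxon` (annotation hierarchy kept verbatim).
#' @export
read_cell_table <- function(path, dialect = c("ecotaxa_tsv", "plain_csv"),
                            pixel_calibration = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "ecotaxa_tsv") {
    df <- .read_table_checked(path, "\t",
                              c("object_id", "object_time", "object_lat",
                                "object_lon", "object_major", "object_minor",
                                "object_annotation_category"),
                              "cell table")
    if (nrow(df) > 0 && grepl("^\\[[tf]\\]$", df$object_id[1]))
      df <- df[-1, , drop = FALSE]                 # EcoTaxa type row
    out <- data.frame(object_id = as.character(df$object_id),
                      time = as.POSIXct(df$object_time, tz = "UTC",
                                        tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                                       "%Y-%m-%d %H:%M:%S")),
                      lat = .num_col(df, "object_lat", path),
                      lon = .num_col(df, "object_lon", path),
                      major_um = .num_col(df, "object_major", path),
                      minor_um = .num_col(df, "object_minor", path),
                      taxon = as.character(df$object_annotation_category),
                      stringsAsFactors = FALSE)
  } else {
    df <- .read_table_checked(path, ",",
                              c("object_id", "iso_time", "lat", "lon",
                                "major_um", "minor_um", "taxon"),
                              "cell table")
    out <- data.frame(object_id = as.character(df$object_id),
                      time = as.POSIXct(df$iso_time, tz = "UTC",
                                        tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                                       "%Y-%m-%d %H:%M:%S")),
                      lat = .num_col(df, "lat", path),
                      lon = .num_col(df, "lon", path),
                      major_um = .num_col(df, "major_um", path),
                      minor_um = .num_col(df, "minor_um", path),
                      taxon = as.character(df$taxon),
                      stringsAsFactors = FALSE)
  }
  if (any(is.na(out$time)))
    stop("unparseable time in cell table row ", which(is.na(out$time))[1],
         " of ", path, call. = FALSE)
  if (!is.null(pixel_calibration)) {
    out$major_um <- out$major_um * pixel_calibration
    out$minor_um <- out$minor_um * pixel_calibration
  }
  message("read ", nrow(out), " cell(s) from ", path)
  out
}

#' Write a cell table (plain CSV dialect)
#' @param cells cell feature table.
#' @param path output CSV.
#' @export
write_cell_table <- function(cells, path) {
  out <- data.frame(object_id = cells$object_id,
                    iso_time = format(cells$time, "%Y-%m-%dT%H:%M:%S",
                                      tz = "UTC"),
                    lat = cells$lat, lon = cells$lon,
                    major_um = cells$major_um, minor_um = cells$minor_um,
                    taxon = cells$taxon)
  writeLines(.schema_comment, path)
  suppressWarnings(utils::write.table(out, path, sep = ",", row.names = FALSE,
                                      quote = FALSE, append = TRUE))
  invisible(path)
}

#' Read a taxa-by-station occurrence table
#'
#' TSV with taxa as rows (first column `taxon`), stations as columns,
#' integer counts.
#'
#' @param path TSV file.
#' @return Integer matrix with dimnames.
#' @export
read_occurrence_table <- function(path) {
  df <- .read_table_checked(path, "\t", "taxon", "occurrence table")
  m <- as.matrix(df[, setdiff(names(df), "taxon"), drop = FALSE])
  storage.mode(m) <- "numeric"
  rownames(m) <- df$taxon
  .check_occurrence(m)
  m
}

#' Write an occurrence table
#' @param table taxa x stations matrix.
#' @param path output TSV.
#' @export
write_occurrence_table <- function(table, path) {
  df <- data.frame(taxon = rownames(table), table, check.names = FALSE)
  writeLines(.schema_comment, path)
  suppressWarnings(utils::write.table(df, path, sep = "\t", row.names = FALSE,
                                      quote = FALSE, append = TRUE))
  invisible(path)
}

#' Pipeline configuration
#'
#' Assembles and validates the configuration of [run_pipeline()]. Unknown
#' keys are rejected with a clear message.
#'
#' @param ... named configuration entries; recognised keys are `out_dir`,
#'   `seed`, `station_file`, `underway_file`, `cell_file`, `cell_dialect`,
#'   `occurrence_file`, `n_cells`, `n_taxa`, `endemism_k`, `endemism_draws`,
#'   `limited_threshold`, `model` (a [model_config()]) and `scenario`
#'   (a [cruise_scenario()], used when no input files are given).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(out_dir = ".", seed = 1,
                   station_file = NULL, underway_file = NULL,
                   cell_file = NULL, cell_dialect = "plain_csv",
                   occurrence_file = NULL,
                   n_cells = 2000, n_taxa = 500,
                   endemism_k = NULL, endemism_draws = 1000,
                   limited_threshold = 0.2,
                   model = model_config(), scenario = NULL)
  user <- list(...)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown pipeline config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, user)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the whole pipeline
#'
#' Loads (or simulates) the cruise, applies the diffusion model per cell,
#' writes the per-cell results, the growth-bin summary, the per-station
#' critical-size table, the endemism report and a run log to `out_dir`.
#' Deterministic for fixed inputs and seed.
#'
#' @param config a [pipeline_config()].
#' @return Invisible list with the in-memory results and output paths.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- character()
  say <- function(...) log <<- c(log, paste0(...))
  say("osmolimit ", as.character(utils::packageVersion("osmolimit")),
      " pipeline; seed=", cfg$seed)

  if (is.null(cfg$station_file)) {
    sc <- if (is.null(cfg$scenario)) cruise_scenario(seed = cfg$seed)
          else cfg$scenario
    cruise <- simulate_cruise(sc)
    stations <- cruise$stations; underway <- cruise$underway
    say("simulated cruise: ", nrow(stations), " stations, ",
        nrow(underway), " underway records")
  } else {
    stations <- read_station_table(cfg$station_file)
    underway <- read_underway_table(cfg$underway_file)
    cruise <- structure(list(stations = stations, underway = underway),
                        class = "osmo_cruise")
    say("read ", nrow(stations), " stations, ", nrow(underway),
        " underway records")
  }

  cells <- if (is.null(cfg$cell_file))
    simulate_cells(n_cells = cfg$n_cells, cruise = cruise, seed = cfg$seed)
  else read_cell_table(cfg$cell_file, cfg$cell_dialect)
  say("cells in: ", nrow(cells))

  results <- apply_model(cells, stations, underway, cfg$model)
  say("cells modeled: ", nrow(results), "; dropped: ",
      attr(results, "dropped"))

  summary_tab <- bin_and_summarize(results)
  limited <- limited_cell_strategy_summary(results, cfg$limited_threshold)
  say("limited cells (< ", cfg$limited_threshold, "/d): ", limited$n_limited,
      "; alternative-strategy share: ",
      round(limited$alternative_share_pct, 1), "%")

  thr <- cfg$model$growth_thresholds
  sizelim <- do.call(rbind, lapply(seq_len(nrow(stations)), function(i) {
    fld <- nutrient_field(stations$ammonium[i], stations$nitrite[i],
                          stations$nitrate[i], stations$phosphate[i],
                          stations$urea[i])
    data.frame(station_id = stations$station_id[i],
               region = classify_region(stations$temp_c[i]),
               t(vapply(thr, function(g)
                 critical_esd(g, fld, stations$temp_c[i], stations$sal[i],
                              config = cfg$model), numeric(1))))
  }))
  names(sizelim)[-(1:2)] <- paste0("critical_esd_um_at_", thr, "_per_d")

  occ <- if (is.null(cfg$occurrence_file))
    simulate_occurrences(cfg$n_taxa, stations,
                         frontal_endemic_fraction = 0.05, seed = cfg$seed)
  else read_occurrence_table(cfg$occurrence_file)
  front_ids <- stations$station_id[classify_region(stations$temp_c) == "front"]
  front_set <- if (is.null(cfg$endemism_k)) front_ids
               else utils::head(front_ids, cfg$endemism_k)
  if (length(front_set) == 0)
    stop("no front-region stations for the endemism statistic", call. = FALSE)
  endem <- endemism_null(occ, front_set, n_draws = cfg$endemism_draws,
                         seed = cfg$seed)
  say(sprintf("endemism: observed %.3f, null %.3f +/- %.3f (p = %.4g)",
              endem$observed_proportion, endem$null_mean, endem$null_sd,
              endem$empirical_p))

  paths <- list(
    per_cell = file.path(cfg$out_dir, "per_cell.csv"),
    summary = file.path(cfg$out_dir, "summary_bins.csv"),
    size_limits = file.path(cfg$out_dir, "size_limits.csv"),
    endemism = file.path(cfg$out_dir, "endemism.csv"),
    log = file.path(cfg$out_dir, "run_log.txt"))
  for (nm in c("per_cell", "summary", "size_limits", "endemism")) {
    obj <- switch(nm, per_cell = results, summary = summary_tab,
                  size_limits = sizelim,
                  endemism = data.frame(observed = endem$observed_proportion,
                                        null_mean = endem$null_mean,
                                        null_sd = endem$null_sd,
                                        empirical_p = endem$empirical_p,
                                        n_draws = endem$n_draws,
                                        k = endem$k, seed = endem$seed))
    writeLines(.schema_comment, paths[[nm]])
    suppressWarnings(utils::write.table(obj, paths[[nm]], sep = ",",
                                        row.names = FALSE, quote = FALSE,
                                        append = TRUE))
  }
  writeLines(log, paths$log)
  invisible(list(results = results, summary = summary_tab,
                 size_limits = sizelim, endemism = endem, paths = paths,
                 log = log))
}
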