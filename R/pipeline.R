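#' Read a flat key=value run configuration
#'
#' One `key = value` pair per line; `#` starts a comment; values that parse
#' as numbers become numeric. Unknown keys are kept (so stage-specific keys
#' coexist); known keys get defaults when absent.
#'
#' @param path Path to the config file, or `NULL` for pure defaults.
#' @param ... Named overrides applied after the file (the CLI flags).
#' @return A named list of class `tm_config`.
#' @export
read_run_config <- function(path = NULL, ...) {
  defaults <- list(
    input = NULL, landcover = NULL, out_dir = "trackmine-run",
    col_id = "id", col_timestamp = "timestamp", col_lat = "lat",
    col_lon = "lon", tz = "UTC",
    rst_radius = NA_real_, epsilon = 0.05, day_start = 6, day_end = 18,
    prox_radius = 200, time_window = 3600, dedup_interval = NA_real_,
    min_sup = 0.01, min_conf = 0.5,
    bandwidth = NA_real_, cells = 100, isopleth_p = 0.95, core_p = 0.5,
    n_fixes = 500, n_encounters = 5, seed = 1)
  cfg <- defaults
  if (!is.null(path)) {
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines[nzchar(trimws(lines))])
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) < 2L) stop("malformed config line: ", ln)
      key <- trimws(kv[1])
      val <- trimws(paste(kv[-1], collapse = "="))
      num <- suppressWarnings(as.numeric(val))
      cfg[[key]] <- if (!is.na(num)) num else val
    }
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "tm_config")
}

#' Apply a proximity radius preset
#'
#' The two analysis scales used throughout: a 200 m radius (a separation
#' suggesting a degree of sociability) and a 400 m radius (the sensitivity
#' re-run at a doubled limit).
#'
#' @param config A `tm_config` list.
#' @param preset `200` or `400`.
#' @return The config with `prox_radius` set.
#' @export
radius_preset <- function(config, preset = c(200, 400)) {
  preset <- match.arg(as.character(preset[1]), c("200", "400"))
  config$prox_radius <- as.numeric(preset)
  config
}

cfg_num <- function(x) if (is.null(x) || is.na(x)) NULL else as.numeric(x)

write_stage <- function(tables, out_dir, manifest_extra = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- purrr::imap_chr(tables, function(tab, name) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    readr::write_csv(tibble::as_tibble(tab), p, progress = FALSE, na = "NA")
    p
  })
  manifest <- file.path(out_dir, "manifest.txt")
  cat(c(manifest_extra, paste("file:", paths)), sep = "\n", file = manifest,
      append = file.exists(manifest))
  cat("\n", file = manifest, append = TRUE)
  paths
}

manifest_config <- function(config) {
  keep <- !purrr::map_lgl(config, is.null)
  paste0("config: ", names(config)[keep], " = ",
         purrr::map_chr(config[keep], \(v) paste(format(v), collapse = " ")))
}

load_config_fixes <- function(config) {
  if (is.null(config$input)) stop("config key `input` (fix table) is required")
  schema <- c(id = config$col_id, timestamp = config$col_timestamp,
              lat = config$col_lat, lon = config$col_lon)
  build_trajectories(read_fixes(config$input, schema = schema,
                                tz = config$tz))
}

#' Pipeline stage: individual behavioral states
#'
#' Reads the configured fix table, classifies behavioral states, and writes
#' the state series, bouts, per-month state matrices (long format), mean
#' bout durations and day/night frequencies, plus a manifest of the
#' resolved configuration.
#'
#' @param config A [read_run_config()] list.
#' @return Invisibly, the named vector of written file paths.
#' @export
cmd_states <- function(config = read_run_config()) {
  fixes <- load_config_fixes(config)
  states <- classify_behavior(fixes, radius = cfg_num(config$rst_radius),
                              epsilon = config$epsilon)
  bouts <- state_bouts(states, day_start = config$day_start,
                       day_end = config$day_end)
  months <- dplyr::distinct(add_month(states)[c("animal_id", "year", "month")])
  matrices <- purrr::pmap(months, function(animal_id, year, month) {
    m <- state_matrix(states[states$animal_id == animal_id, ], year, month)
    tibble::tibble(animal_id = animal_id, year = year, month = month,
                   day = m$day, hour = m$hour, state = m$state)
  }) |> dplyr::bind_rows()
  paths <- write_stage(
    list(state_series = states, state_bouts = bouts,
         state_matrix = matrices,
         mean_durations = mean_bout_durations(bouts),
         daynight_frequency = daynight_frequency(
           bouts, config$day_start, config$day_end)),
    config$out_dir, manifest_config(config))
  invisible(paths)
}

#' Pipeline stage: pairwise interactions
#'
#' Detects co-occurrence events at the configured radius/time window, mines
#' monthly animal-pair association rules, validates them with monthly
#' Cramer's V, and computes monthly pairwise home-range overlap on a shared
#' kernel grid. Requires at least two animals.
#'
#' @inheritParams cmd_states
#' @return Invisibly, the written file paths.
#' @export
cmd_interactions <- function(config = read_run_config()) {
  fixes <- load_config_fixes(config)
  if (length(unique(fixes$animal_id)) < 2L) {
    stop("interaction analysis needs >= 2 animals")
  }
  events <- detect_events(fixes, radius = config$prox_radius,
                          time_window = config$time_window,
                          dedup_interval = cfg_num(config$dedup_interval))
  tsets <- pair_transactions(events)
  rules <- purrr::map(tsets, mine_rules, min_sup = config$min_sup,
                      min_conf = config$min_conf) |>
    dplyr::bind_rows()
  cramer <- if (nrow(events)) cramer_by_month(events) else
    tibble::tibble(year = integer(), month = integer(),
                   n_events = integer(), cramers_v = numeric())

  overlaps <- ud_overlap_by_month(fixes, p = config$isopleth_p,
                                  cells = config$cells,
                                  bandwidth = cfg_num(config$bandwidth))
  events_out <- add_month(tibble::as_tibble(events))
  paths <- write_stage(
    list(events = events_out, pair_rules = rules, cramer = cramer,
         overlap = overlaps),
    config$out_dir, manifest_config(config))
  invisible(paths)
}

ud_overlap_by_month <- function(fixes, p = 0.95, cells = 100,
                                bandwidth = NULL, min_fixes = 5L) {
  purrr::imap(partition_by_month(fixes), function(df, key) {
    counts <- table(df$animal_id)
    ids <- names(counts)[counts >= min_fixes]
    if (length(ids) < 2L) return(NULL)
    spec <- ud_grid_spec(df[df$animal_id %in% ids, ], cells = cells)
    uds <- purrr::map(setNames(ids, ids), \(id)
      kernel_ud(df[df$animal_id == id, ], bandwidth = bandwidth,
                spec = spec))
    purrr::map(utils::combn(ids, 2L, simplify = FALSE), function(pr) {
      hr <- ud_overlap(uds[[pr[1]]], uds[[pr[2]]], p = p, method = "hr")
      vi <- ud_overlap(uds[[pr[1]]], uds[[pr[2]]], method = "vi")
      tibble::tibble(month_key = key, animal_a = pr[1], animal_b = pr[2],
                     hr_a_in_b = hr[["a_in_b"]], hr_b_in_a = hr[["b_in_a"]],
                     vi = vi)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

#' Pipeline stage: behavior-by-land-cover rules
#'
#' Classifies states, resolves the land-cover class under every fix, and
#' mines per-animal state-by-cover association rules.
#'
#' @inheritParams cmd_states
#' @return Invisibly, the written file paths.
#' @export
cmd_landcover <- function(config = read_run_config()) {
  if (is.null(config$landcover)) stop("config key `landcover` is required")
  if (!file.exists(config$landcover)) {
    stop("land-cover raster not found: ", config$landcover)
  }
  grid <- read_ascii_grid(config$landcover, legend = config_legend(config))
  fixes <- load_config_fixes(config)
  states <- classify_behavior(fixes, radius = cfg_num(config$rst_radius),
                              epsilon = config$epsilon)
  tsets <- state_landcover_transactions(states, grid)
  rules <- purrr::imap(tsets, function(ts, id) {
    r <- mine_rules(ts, min_sup = config$min_sup, min_conf = config$min_conf)
    # report state -> cover direction, one table block per animal
    r[r$antecedent %in% c("rest", "forage", "transit"), ]
  }) |> dplyr::bind_rows()
  dropped <- tibble::tibble(
    animal_id = names(tsets),
    n_off_grid = purrr::map_int(tsets, \(ts) attr(ts, "n_dropped") %||% 0L))
  paths <- write_stage(
    list(state_landcover_rules = rules, off_grid_fixes = dropped),
    config$out_dir, manifest_config(config))
  invisible(paths)
}

# legend entries are config keys like `legend_1 = forest`
config_legend <- function(config) {
  keys <- grep("^legend_", names(config), value = TRUE)
  if (!length(keys)) return(NULL)
  setNames(as.character(unlist(config[keys])), sub("^legend_", "", keys))
}

#' Pipeline stage: simulate a fixture data set
#'
#' Writes a two-animal attracted-pair track table, its true state labels,
#' the scripted encounter schedule, and a synthetic land-cover raster into
#' the run directory, in exactly the formats the other stages read.
#'
#' @inheritParams cmd_states
#' @return Invisibly, the written file paths.
#' @export
cmd_simulate <- function(config = read_run_config()) {
  sim <- simulate_pair(n_fixes = config$n_fixes,
                       n_encounters = config$n_encounters,
                       encounter_radius = config$prox_radius,
                       seed = as.integer(config$seed))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  fix_path <- file.path(config$out_dir, "fixes.csv")
  write_fixes(sim$fixes, fix_path)
  grid <- simulate_landscape(seed = as.integer(config$seed))
  asc_path <- file.path(config$out_dir, "landscape.asc")
  write_ascii_grid(grid, asc_path)
  paths <- write_stage(
    list(true_states = sim$states, encounters = sim$encounters),
    config$out_dir, manifest_config(config))
  invisible(c(paths, fixes = fix_path, landscape = asc_path))
}

#' Run the full three-stage pipeline
#'
#' Behavioral states, pairwise interactions, and land-cover association in
#' one call (the land-cover stage is skipped when no raster is configured).
#'
#' @inheritParams cmd_states
#' @return Invisibly, all written file paths.
#' @export
cmd_all <- function(config = read_run_config()) {
  p1 <- cmd_states(config)
  p2 <- cmd_interactions(config)
  p3 <- if (!is.null(config$landcover)) cmd_landcover(config) else NULL
  invisible(c(p1, p2, p3))
}
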