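#' Run the cohort pipeline from a config file
#'
#' The config is JSON:
#' \preformatted{
#' {
#'   "seed": 1,
#'   "min_lesions": 50,
#'   "output_dir": "results",
#'   "config": { "vessel_threshold": 60, ... },
#'   "eyes": [
#'     { "id": "eye01", "marked": "eye01/marked_ir.pgm",
#'       "cscan": "eye01/cscan.pgm", "exclusion": "eye01/exclusion.pgm" }
#'   ]
#' }
#' }
#' Relative paths resolve against the config file's directory. Each
#' eye is analyzed independently; eyes with fewer included lesions
#' than `min_lesions` (default 50) or with fatal per-eye errors are
#' skipped with the reason recorded in the manifest, and cohort
#' statistics are computed over the remaining eyes when at least two
#' survive. A failed eye never blocks the others.
#'
#' @param config_path path to the JSON config.
#' @return A list with `eyes` (per-eye `eye_result`s for analyzed
#'   eyes), `summary` (a `cohort_summary` or `NULL`), and `manifest`
#'   (per-eye status, seeds, software version). When `output_dir` is
#'   set, per-eye JSON, `cohort_summary.json`, `cohort.csv` and
#'   `manifest.json` are written there.
#' @export
run_cohort <- function(config_path) {
  if (!file.exists(config_path)) {
    stop(sprintf("config not found: %s", config_path))
  }
  cfg <- jsonlite::read_json(config_path, simplifyVector = FALSE)
  if (is.null(cfg$eyes) || length(cfg$eyes) < 1L) {
    stop("config lists no eyes")
  }
  base_dir <- dirname(normalizePath(config_path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base_dir, p)
  }
  master_seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  min_lesions <- if (is.null(cfg$min_lesions)) 50L else
    as.integer(cfg$min_lesions)
  acfg <- do.call(analysis_config, if (is.null(cfg$config)) list() else
    cfg$config)
  pixel_size <- if (is.null(cfg$pixel_size_um)) 10 else
    as.numeric(cfg$pixel_size_um)

  statuses <- list()
  results <- list()
  for (i in seq_along(cfg$eyes)) {
    eye <- cfg$eyes[[i]]
    id <- if (is.null(eye$id)) sprintf("eye%02d", i) else eye$id
    seed_i <- derive_seed(master_seed, i)
    st <- tryCatch({
      marked <- read_grayscale(resolve(eye$marked), pixel_size)
      cscan <- read_grayscale(resolve(eye$cscan), pixel_size)
      excl <- if (is.null(eye$exclusion)) NULL else
        read_mask(resolve(eye$exclusion), semantics = "exclusion")
      res <- analyze_eye(id, marked, cscan, excl, acfg, seed = seed_i)
      if (res$n_included < min_lesions) {
        list(status = "skipped",
             reason = sprintf("below min_lesions (%d < %d)",
                              res$n_included, min_lesions))
      } else {
        results[[id]] <- res
        list(status = "ok", reason = NULL)
      }
    }, error = function(e) {
      list(status = "skipped", reason = conditionMessage(e))
    })
    statuses[[i]] <- c(list(id = id, seed = seed_i), st)
  }

  summary <- NULL
  if (length(results) >= 2L) {
    summary <- summarize_cohort(unname(results))
  }
  manifest <- list(
    config_path = config_path,
    master_seed = master_seed,
    min_lesions = min_lesions,
    software_version =
      as.character(utils::packageVersion("choropoint")),
    n_eyes_listed = length(cfg$eyes),
    n_eyes_analyzed = length(results),
    cohort_status = if (!is.null(summary)) "ok" else
      if (length(results) == 1L) "insufficient-data" else "no-eligible-eyes",
    eyes = statuses
  )

  out_dir <- resolve(cfg$output_dir)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(results)) {
      write_eye_result(results[[id]], file.path(out_dir,
                                                sprintf("%s.json", id)))
    }
    if (!is.null(summary)) {
      jsonlite::write_json(unclass(summary),
                           file.path(out_dir, "cohort_summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      write.csv(cohort_table(unname(results)),
                file.path(out_dir, "cohort.csv"), row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (length(results) == 0L) {
    warning("no eligible eyes; cohort statistics not computed")
  }
  list(eyes = results, summary = summary, manifest = manifest)
}

#' One-row-per-eye cohort table
#'
#' @param eyes list of `eye_result` objects.
#' @return A data.frame with observed and control columns per eye.
#' @export
cohort_table <- function(eyes) {
  stopifnot(all(vapply(eyes, inherits, logical(1), "eye_result")))
  do.call(rbind, lapply(eyes, function(e) {
    data.frame(
      eye_id = e$eye_id,
      n_marked = e$n_marked, n_excluded = e$n_excluded,
      n_included = e$n_included,
      vessel_area_fraction = e$vessel_area_fraction,
      obs_pct_vessel = e$observed$pct_vessel,
      obs_pct_near_1_3 = e$observed$stroma_bins$pct[["near_1_3"]],
      obs_pct_mid_4_6 = e$observed$stroma_bins$pct[["mid_4_6"]],
      obs_pct_far_ge7 = e$observed$stroma_bins$pct[["far_ge7"]],
      ctl_pct_vessel = e$control$pct_vessel,
      ctl_pct_near_1_3 = e$control$stroma_bins$pct[["near_1_3"]],
      ctl_pct_mid_4_6 = e$control$stroma_bins$pct[["mid_4_6"]],
      ctl_pct_far_ge7 = e$control$stroma_bins$pct[["far_ge7"]]
    )
  }))
}
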