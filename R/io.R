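# Readers/writers and the config-driven pipeline runner.
#
# All tables are comma-separated UTF-8 CSV with a header and '.' decimal;
# coordinates are micrometres throughout and column names carry the unit
# (x_um, s_um, area_um2) because silent unit mixups are the main field
# hazard. Configs and fitted-model sidecars are JSON.

#' Read traced cell outlines from CSV
#'
#' Expects the tracing-export dialect written by [make_cohort()] /
#' [run_pipeline()]: one row per boundary point with `cell_id`,
#' `point_index`, `x_um`, `y_um`, `z_um` and optional metadata columns
#' (`group`, `vessel`, `region`, `stage_hpf`, `genotype`, `embryo_id`).
#' Rows are returned grouped by cell in `point_index` order.
#'
#' @param path CSV file path.
#' @return Outline tibble.
#' @export
read_outlines <- function(path) {
  if (!file.exists(path)) vm_stop(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  check_columns(df, c("cell_id", "point_index", "x_um", "y_um", "z_um"),
                sprintf("outline file '%s'", path))
  for (col in c("point_index", "x_um", "y_um", "z_um", "stage_hpf")) {
    if (!col %in% names(df)) next
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad)) {
      vm_stop(sprintf("non-numeric value in column '%s' at row %d of %s",
                      col, bad[1], path))
    }
    df[[col]] <- v
  }
  dup <- which(duplicated(df[c("cell_id", "point_index")]))
  if (length(dup)) {
    vm_stop(sprintf("duplicate (cell_id, point_index) at row %d of %s",
                    dup[1], path))
  }
  bad_coord <- which(!is.finite(df$x_um) | !is.finite(df$y_um) | !is.finite(df$z_um))
  if (length(bad_coord)) {
    vm_stop(sprintf("missing or non-finite coordinate at row %d of %s",
                    bad_coord[1], path))
  }
  df |> dplyr::arrange(.data$cell_id, .data$point_index)
}

# Reject config keys the pipeline does not know about.
check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    vm_stop(sprintf("unknown key(s) in %s: %s", where,
                    paste(unknown, collapse = ", ")))
  }
  invisible(x)
}

config_group <- function(g, i) {
  check_keys(g, c("name", "vessel_type", "region", "stage_hpf", "genotype",
                  "n_embryos", "vessel", "population"),
             sprintf("cohort group %d", i))
  check_keys(g$vessel, c("cross_section", "radius_y", "radius_z", "length",
                         "axis_direction", "axis_origin", "taper", "v_range"),
             sprintf("vessel of group %d", i))
  check_keys(g$population, c("n_cells", "mean_area", "area_cv",
                             "mean_elongation", "angle_mean", "angle_sd",
                             "area_effect_multiplier", "seed"),
             sprintf("population of group %d", i))
  vs <- do.call(vessel_spec, g$vessel)
  ps <- do.call(population_spec, g$population)
  cohort_group(name = g$name, vessel = vs, population = ps,
               vessel_type = g$vessel_type %||% "artery",
               region = g$region %||% "trunk",
               stage_hpf = g$stage_hpf %||% 72,
               genotype = g$genotype %||% "wt",
               n_embryos = g$n_embryos %||% 3)
}

md5_of_string <- function(s) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(s, f)
  unname(tools::md5sum(f))
}

conic_to_list <- function(m) {
  list(kind = m$kind, center = m$center, semi_axes = m$semi_axes,
       tilt = m$tilt, fit_rms = m$fit_rms, n_points = m$n_points)
}

#' Run the full morphometry pipeline from a config
#'
#' Chains synthesize (optional) -> unroll -> shapes -> embed/jsd, writing
#' every stage output plus a run manifest with per-file checksums. All
#' randomness flows from `config$seed`; re-running with an identical config
#' reproduces identical output checksums.
#'
#' @param config A named list or path to a JSON file. Keys: `seed` (int,
#'   required), `out_dir` (required), exactly one of `cohort` (list with
#'   `n_points`, `noise_sd`, `jitter_spacing`, `groups = [...]` mirroring
#'   [vessel_spec()] / [population_spec()] fields) or `input_csv`; optional
#'   `unroll` (`kind`, `fit_scope`, `radial_tol`, `by`), `shapes`
#'   (`area_from`), `embed` (`enabled`, `n_neighbors`, `min_dist`,
#'   `mass_fraction`), `jsd` (`enabled`, `normalize`, `log_base`).
#'   Unknown keys are rejected.
#' @return A `vm_manifest` (invisibly): tool version, config hash, per-stage
#'   outputs with checksums, timestamp.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) vm_stop(sprintf("config file not found: %s", config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  check_keys(config, c("seed", "out_dir", "cohort", "input_csv",
                       "unroll", "shapes", "embed", "jsd"), "config")
  if (is.null(config$seed)) vm_stop("config$seed is required (no silent nondeterminism)")
  if (is.null(config$out_dir)) vm_stop("config$out_dir is required")
  if (is.null(config$cohort) == is.null(config$input_csv)) {
    vm_stop("config must set exactly one of `cohort` or `input_csv`")
  }
  if (!is.null(config$input_csv) && !file.exists(config$input_csv)) {
    vm_stop(sprintf("input_csv not found: %s", config$input_csv))
  }
  check_keys(config$unroll %||% list(), c("kind", "fit_scope", "radial_tol", "by"), "config$unroll")
  check_keys(config$shapes %||% list(), "area_from", "config$shapes")
  check_keys(config$embed %||% list(),
             c("enabled", "n_neighbors", "min_dist", "mass_fraction"), "config$embed")
  check_keys(config$jsd %||% list(), c("enabled", "normalize", "log_base"), "config$jsd")

  seed <- as.integer(config$seed)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  stage_log <- list()
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    readr::write_csv(df, p)
    outputs <<- c(outputs, p)
    p
  }

  # stage 1: synthesize or ingest
  if (!is.null(config$cohort)) {
    co <- config$cohort
    check_keys(co, c("n_points", "noise_sd", "jitter_spacing", "groups"), "config$cohort")
    if (!length(co$groups)) vm_stop("config$cohort$groups must be non-empty")
    groups <- lapply(seq_along(co$groups), function(i) config_group(co$groups[[i]], i))
    cohort <- make_cohort(groups, n_points = co$n_points %||% 100,
                          noise_sd = co$noise_sd %||% 0.2, seed = seed,
                          jitter_spacing = isTRUE(co$jitter_spacing))
    outlines <- cohort$outlines
    emit(outlines, "outlines.csv")
    truth <- cohort$ground_truth
    attr(truth, "vessel") <- NULL
    emit(tibble::as_tibble(truth), "ground_truth.csv")
    stage_log$synthesize <- list(n_cells = dplyr::n_distinct(outlines$cell_id))
  } else {
    outlines <- read_outlines(config$input_csv)
    stage_log$ingest <- list(input = config$input_csv,
                             n_cells = dplyr::n_distinct(outlines$cell_id))
  }

  # stage 2: unroll
  un_cfg <- config$unroll %||% list()
  unrolled <- unroll_cohort(outlines, by = un_cfg$by,
                            kind = un_cfg$kind %||% "auto",
                            fit_scope = un_cfg$fit_scope %||% "vessel",
                            radial_tol = un_cfg$radial_tol %||% 0.2)
  emit(unrolled, "unrolled.csv")
  models <- attr(unrolled, "models")
  models_path <- file.path(out_dir, "cross_sections.json")
  jsonlite::write_json(lapply(models, conic_to_list), models_path,
                       auto_unbox = TRUE, digits = NA)
  outputs <- c(outputs, models_path)
  stage_log$unroll <- list(kind = un_cfg$kind %||% "auto",
                           fit_scope = un_cfg$fit_scope %||% "vessel",
                           n_models = length(models))

  # stage 3: shapes
  shapes <- compute_shapes(unrolled, area_from = (config$shapes %||% list())$area_from %||% "polygon")
  emit(shapes, "shapes.csv")
  stage_log$shapes <- list(
    n_cells = nrow(shapes),
    n_self_intersecting = sum(shapes$self_intersecting),
    n_low_confidence_angle = sum(shapes$angle_low_confidence))

  # stage 4: embed + jsd
  group_col <- if ("group" %in% names(shapes)) "group" else NULL
  em_cfg <- config$embed %||% list()
  if (!identical(em_cfg$enabled, FALSE) && !is.null(group_col)) {
    emb <- embed_shapes(shapes, group_col = group_col,
                        n_neighbors = em_cfg$n_neighbors %||% 15,
                        min_dist = em_cfg$min_dist %||% 0.1,
                        seed = seed,
                        mass_fraction = em_cfg$mass_fraction %||% 0.90)
    emit(emb$coords, "embedding.csv")
    ell_path <- file.path(out_dir, "ellipses.json")
    jsonlite::write_json(emb$ellipses, ell_path, auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, ell_path)
    stage_log$embed <- emb$settings
  }
  jsd_cfg <- config$jsd %||% list()
  if (!identical(jsd_cfg$enabled, FALSE) && !is.null(group_col) &&
      dplyr::n_distinct(shapes[[group_col]]) >= 2) {
    jm <- pairwise_shape_jsd(shapes, group_col = group_col,
                             normalize = jsd_cfg$normalize %||% TRUE,
                             log_base = jsd_cfg$log_base %||% 2)
    emit(jm$pairs, "jsd_matrix.csv")
    stage_log$jsd <- list(n_pairs = nrow(jm$pairs))
  }

  manifest <- list(
    tool = "vesselmorph",
    version = as.character(utils::packageVersion("vesselmorph")),
    config_hash = md5_of_string(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)),
    seed = seed,
    stages = stage_log,
    outputs = lapply(outputs, function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    }),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  class(manifest) <- "vm_manifest"
  invisible(manifest)
}

#' @export
print.vm_manifest <- function(x, ...) {
  cat(sprintf("<vm_manifest> vesselmorph %s, seed %d, %d output file(s)\n",
              x$version, x$seed, length(x$outputs)))
  for (o in x$outputs) cat(sprintf("  %s  %s\n", o$md5, o$file))
  invisible(x)
}
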