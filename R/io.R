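# File formats: GeoJSON-like polygon frames (canonical), 16-bit label
# TIFF + CSV sidecar (interchangeable), cohort manifests, report CSVs and
# run manifests. All writers are byte-deterministic for identical inputs
# (run-manifest timestamps excluded).

frame_to_geojson <- function(frame) {
  features <- lapply(frame$instances, function(inst) {
    coords <- rbind(inst$outline, inst$outline[1, , drop = FALSE])
    list(
      type = "Feature",
      properties = list(id = as.character(inst$id),
                        cell_class = inst$cell_class,
                        confidence = inst$confidence,
                        source = inst$source),
      geometry = list(type = "Polygon",
                      coordinates = list(lapply(seq_len(nrow(coords)),
                                                function(k) coords[k, ])))
    )
  })
  list(
    type = "FeatureCollection",
    metadata = list(frame_id = as.character(frame$frame_id),
                    width_px = frame$width_px, height_px = frame$height_px,
                    pixel_size_um = frame$pixel_size_um,
                    fixation = frame$fixation, panel = frame$panel),
    features = features
  )
}

geojson_to_frame <- function(gj) {
  md <- gj$metadata
  insts <- lapply(gj$features, function(ft) {
    cc <- ft$geometry$coordinates[[1]]
    m <- if (is.list(cc)) do.call(rbind, lapply(cc, unlist)) else as.matrix(cc)
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) {
      m <- m[-nrow(m), , drop = FALSE]
    }
    cell_instance(id = ft$properties$id,
                  cell_class = ft$properties$cell_class,
                  outline = m,
                  confidence = ft$properties$confidence,
                  source = ft$properties$source)
  })
  image_frame(frame_id = md$frame_id, width_px = md$width_px,
              height_px = md$height_px, pixel_size_um = md$pixel_size_um,
              fixation = md$fixation, panel = md$panel, instances = insts)
}

#' Write and read single frames as polygon JSON
#'
#' The canonical on-disk frame format: a GeoJSON-like FeatureCollection
#' whose features carry instance id, class, confidence and source, with
#' frame metadata (id, dimensions, pixel size, fixation, panel) at the top
#' level. Coordinates are continuous pixel units.
#'
#' @param frame an [image_frame()]
#' @param path output / input file path
#' @return `write_frame_json` returns the path invisibly;
#'   `read_frame_json` returns an [image_frame()]
#' @export
write_frame_json <- function(frame, path) {
  jsonlite::write_json(frame_to_geojson(frame), path, auto_unbox = TRUE,
                       digits = NA, pretty = FALSE)
  invisible(path)
}

#' @rdname write_frame_json
#' @export
read_frame_json <- function(path) {
  geojson_to_frame(jsonlite::read_json(path))
}

#' Write and read a frame as a 16-bit label TIFF with CSV sidecar
#'
#' The label image stores background as 0 and instance k's pixels as k
#' (16-bit, up to 65535 instances); the sidecar CSV maps each label to its
#' class, confidence, source and original instance id. Frame metadata that
#' the TIFF cannot carry is passed explicitly on read.
#'
#' @param frame an [image_frame()] (non-overlapping instances in strict
#'   mode; see [to_label_map()])
#' @param tiff_path,csv_path output / input paths
#' @param mode overlap handling, see [to_label_map()]
#' @param frame_id,pixel_size_um,fixation,panel metadata for the
#'   reconstructed frame
#' @return `write_frame_labelmap` returns the paths invisibly;
#'   `read_frame_labelmap` returns an [image_frame()]
#' @export
write_frame_labelmap <- function(frame, tiff_path, csv_path,
                                 mode = "strict") {
  lm <- to_label_map(frame, mode = mode)
  if (max(lm$labels) > 65535) {
    stop("more than 65535 instances cannot be stored in a 16-bit label map",
         call. = FALSE)
  }
  tiff::writeTIFF(lm$labels / 65535, tiff_path, bits.per.sample = 16,
                  compression = "none")
  utils::write.csv(lm$sidecar, csv_path, row.names = FALSE)
  invisible(c(tiff_path, csv_path))
}

#' @rdname write_frame_labelmap
#' @export
read_frame_labelmap <- function(tiff_path, csv_path, frame_id,
                                pixel_size_um, fixation, panel) {
  labels <- round(tiff::readTIFF(tiff_path) * 65535)
  sidecar <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  polygonize(labels, sidecar, frame_id = frame_id,
             pixel_size_um = pixel_size_um, fixation = fixation,
             panel = panel)
}

#' Write and read whole cohorts
#'
#' A cohort is a directory holding one polygon-JSON file per frame plus a
#' `cohort.json` manifest (name, role, fixation, pixel size, frame file
#' list). `read_cohort()` validates every instance-model invariant on load
#' and reports the frame id, instance id and violated rule on failure.
#'
#' @param cohort a [cohort_dataset()]
#' @param dir cohort directory
#' @param manifest_path path to a `cohort.json` manifest
#' @param validate check all invariants on load (default TRUE)
#' @return `write_cohort` returns the manifest path invisibly;
#'   `read_cohort` returns a [cohort_dataset()]
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(cohort$frames))
  for (k in seq_along(cohort$frames)) {
    f <- cohort$frames[[k]]
    files[k] <- paste0(f$frame_id, ".json")
    write_frame_json(f, file.path(dir, files[k]))
  }
  manifest <- list(
    name = cohort$name, role = cohort$role,
    fixation = if (length(cohort$frames)) cohort$frames[[1]]$fixation else NA,
    pixel_size_um = if (length(cohort$frames))
      cohort$frames[[1]]$pixel_size_um else NA,
    frames = as.list(files)
  )
  mp <- file.path(dir, "cohort.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mp)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(manifest_path, validate = TRUE) {
  if (!file.exists(manifest_path)) {
    stop("cohort manifest not found: ", manifest_path, call. = FALSE)
  }
  manifest <- jsonlite::read_json(manifest_path)
  dir <- dirname(manifest_path)
  frames <- lapply(manifest$frames, function(fn) {
    path <- file.path(dir, fn)
    if (!file.exists(path)) {
      stop("frame file referenced by manifest not found: ", path,
           call. = FALSE)
    }
    read_frame_json(path)
  })
  cohort <- cohort_dataset(name = manifest$name, frames = frames,
                           role = manifest$role)
  if (validate) validate_cohort(cohort)
  cohort
}

#' Build a run manifest describing one pipeline invocation
#'
#' Records the command, parameter list, input file hashes (MD5), seed,
#' package version and timestamp, so every output file can be traced to
#' the run that produced it.
#'
#' @param command subcommand name
#' @param params named list of parameters (thresholds, modes, ...)
#' @param inputs character vector of input file paths to hash
#' @param seed seed used, if any
#' @return a list of class `run_manifest`
#' @export
run_manifest <- function(command, params = list(), inputs = character(0),
                         seed = NULL) {
  hashes <- if (length(inputs)) {
    stats::setNames(as.list(unname(tools::md5sum(inputs))), basename(inputs))
  } else list()
  structure(
    list(command = command, params = params, input_md5 = hashes,
         seed = seed,
         tool = paste0("immunoseg ",
                       as.character(utils::packageVersion("immunoseg"))),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "run_manifest"
  )
}

#' @rdname run_manifest
#' @param manifest a `run_manifest`
#' @param path output file
#' @export
write_manifest_json <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write result objects to CSV reports
#'
#' Writes evaluation summaries, feature tables, comparison results or
#' population tables as CSV files with stable column order, full numeric
#' precision plus `*_printed` columns at the table's display precision
#' where applicable, and a JSON run manifest alongside.
#'
#' @param x an `eval_summary`, [cohort_features()] output,
#'   `comparison_result` or `population_table`
#' @param dir destination directory (created if needed)
#' @param manifest optional [run_manifest()] written as `manifest.json`
#' @return character vector of files written, invisibly
#' @export
write_reports <- function(x, dir, manifest = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  wcsv <- function(df, fn) {
    path <- file.path(dir, fn)
    utils::write.csv(df, path, row.names = FALSE)
    written <<- c(written, path)
  }
  if (inherits(x, "eval_summary")) {
    wcsv(x$per_class, "metrics_per_class.csv")
    ov <- x$overall
    ov$tau <- x$tau; ov$theta <- x$theta
    ov$specificity_definition <- x$specificity_definition
    wcsv(ov, "metrics_overall.csv")
  } else if (inherits(x, "population_table")) {
    df <- as.data.frame(x)
    df$dataset <- if (is.null(attr(x, "name"))) NA else attr(x, "name")
    df$total_cells <- attr(x, "total_cells")
    df$total_images <- attr(x, "total_images")
    df$avg_cells_per_image <- attr(x, "avg_cells_per_image")
    df$avg_cells_per_image_printed <- attr(x, "avg_cells_per_image_printed")
    wcsv(df, "population_table.csv")
  } else if (inherits(x, "comparison_result")) {
    wcsv(as.data.frame(x), "comparisons.csv")
  } else if (is.list(x) && !is.null(x$morphometry)) {
    wcsv(x$morphometry, "morphometry.csv")
    wcsv(x$proximity, "proximity.csv")
  } else {
    stop("unsupported report object of class ",
         paste(class(x), collapse = "/"), call. = FALSE)
  }
  if (!is.null(manifest)) {
    written <- c(written, write_manifest_json(manifest,
                                              file.path(dir, "manifest.json")))
  }
  invisible(written)
}

#' Read a tissue or degradation configuration from YAML or JSON
#'
#' Field names mirror [tissue_config()] / [degradation_config()]
#' arguments exactly.
#'
#' @param path config file (`.yaml`/`.yml` or `.json`)
#' @return a `tissue_config` or `degradation_config`
#' @export
read_tissue_config <- function(path) {
  cfg <- read_config_list(path)
  do.call(tissue_config, cfg)
}

#' @rdname read_tissue_config
#' @export
read_degradation_config <- function(path) {
  cfg <- read_config_list(path)
  if (!is.null(cfg$classes)) cfg$classes <- unlist(cfg$classes)
  for (nm in c("detect_prob", "fp_rate")) {
    if (!is.null(cfg[[nm]])) cfg[[nm]] <- unlist(cfg[[nm]])
  }
  if (!is.null(cfg$confusion)) {
    cfg$confusion <- do.call(rbind, lapply(cfg$confusion, unlist))
    rownames(cfg$confusion) <- colnames(cfg$confusion) <- cfg$classes
  }
  do.call(degradation_config, cfg)
}

read_config_list <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format: .", ext, call. = FALSE)
  }
  for (nm in c("class_mixture", "shape_irregularity")) {
    if (!is.null(cfg[[nm]])) cfg[[nm]] <- unlist(cfg[[nm]])
  }
  if (!is.null(cfg$area_um2)) {
    cfg$area_um2 <- lapply(cfg$area_um2, function(p) as.list(unlist(p)))
  }
  cfg
}
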