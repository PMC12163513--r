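#' Construct a morphotype label map
#'
#' A label map is a single-channel integer raster in which each pixel carries
#' a class index: 0 = background / non-tumor, 1--6 = the six morphotypes in
#' canonical order (see [morphotypes()]). It stands in for the output of an
#' upstream tissue-segmentation step.
#'
#' @param pixels Integer matrix with values in 0..6.
#' @param section_id,tumor_id Identifiers (strings).
#' @param role Anatomical role of the section, one of [section_roles()].
#' @param pixel_area Physical area per pixel (square micrometres); default 1,
#'   i.e. areas are reported in pixels.
#' @return An object of class `label_map`.
#' @export
label_map <- function(pixels, section_id, tumor_id, role, pixel_area = 1) {
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  if (nrow(pixels) < 1 || ncol(pixels) < 1) stop("label map must be at least 1x1")
  storage.mode(pixels) <- "integer"
  check_label_values(pixels)
  role <- match.arg(role, section_roles())
  structure(
    list(pixels = pixels, section_id = as.character(section_id),
         tumor_id = as.character(tumor_id), role = role,
         pixel_area = as.numeric(pixel_area)),
    class = "label_map"
  )
}

check_label_values <- function(pixels) {
  bad <- which(is.na(pixels) | pixels < 0L | pixels > 6L)
  if (length(bad) > 0) {
    i <- bad[1]
    rc <- arrayInd(i, dim(pixels))
    stop(sprintf(
      "label map contains invalid value %s at row %d, col %d (0-based: %d,%d); allowed values are 0..6 (%d offending pixel(s))",
      format(pixels[i]), rc[1], rc[2], rc[1] - 1L, rc[2] - 1L, length(bad)))
  }
  invisible(TRUE)
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> section %s (tumor %s, role %s): %d x %d, %d tumor px\n",
              x$section_id, x$tumor_id, x$role, nrow(x$pixels), ncol(x$pixels),
              sum(x$pixels > 0L)))
  invisible(x)
}

#' Read a morphotype label map from a PNG or TIFF file
#'
#' Rasters are single-channel 8-bit images whose pixel values are the class
#' indices 0--6 directly. Values outside 0..6 are rejected with the offending
#' value and location.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @inheritParams label_map
#' @return A [label_map()].
#' @export
read_label_map <- function(path, section_id, tumor_id, role, pixel_area = 1) {
  if (!file.exists(path)) stop("label map file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported raster format '.", ext, "' (use .png or .tif/.tiff): ", path)
  )
  if (length(dim(img)) == 3) {
    if (dim(img)[3] > 1) stop("raster is not single-channel: ", path)
    img <- img[, , 1]
  }
  vals <- round(img * 255)
  if (max(abs(img * 255 - vals)) > 1e-6) {
    stop("raster does not hold integer class values: ", path)
  }
  label_map(matrix(as.integer(vals), nrow(img), ncol(img)),
            section_id = section_id, tumor_id = tumor_id, role = role,
            pixel_area = pixel_area)
}

#' Write a label map to a PNG or TIFF file
#'
#' Inverse of [read_label_map()]: pixel values 0--6 are stored in an 8-bit
#' single-channel image; a write/read round trip reproduces the pixel array
#' exactly.
#'
#' @param map A [label_map()].
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(map, path) {
  stopifnot(inherits(map, "label_map"))
  img <- map$pixels / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    stop("unsupported raster format '.", ext, "'")
  )
  invisible(path)
}

clinical_levels <- list(
  gender = c("M", "F"),
  t_stage = c("T1", "T2", "T3", "T4"),
  n_stage = c("N0", "N1", "N2"),
  m_stage = c("M0", "M1"),
  ajcc_stage = c("I", "II", "III", "IV"),
  grade = c("1", "2", "3"),
  site = c("right", "transverse", "left", "rectosigmoid", "rectum"),
  msi = c("MSI", "MSS")
)

clinical_columns <- function() {
  c("tumor_id", "age", names(clinical_levels),
    "os_time", "rfs_time", "os_event", "rfs_event")
}

#' Read and validate a clinical table
#'
#' Expects a CSV with one row per tumor and columns `tumor_id, age, gender,
#' t_stage, n_stage, m_stage, ajcc_stage, grade, site, msi, os_time,
#' rfs_time, os_event, rfs_event`. Categorical columns have closed level
#' sets; survival times are in months and must be non-negative; events are
#' 0/1. Every violation is reported with its row number.
#'
#' @param path Path to `clinical.csv`.
#' @return A validated `data.frame` with factor-typed categorical columns.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("clinical table not found: ", path)
  # categorical columns are read verbatim: an all-"F" gender column must not
  # be type-guessed into a logical
  hdr <- names(utils::read.csv(path, nrows = 1))
  chr <- intersect(c("tumor_id", names(clinical_levels)), hdr)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = stats::setNames(rep("character", length(chr)), chr))
  validate_clinical(df)
}

#' @rdname read_clinical_table
#' @param df A data.frame already in memory with the same columns.
#' @export
validate_clinical <- function(df) {
  missing_cols <- setdiff(clinical_columns(), names(df))
  if (length(missing_cols) > 0) {
    stop("clinical table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  dup <- df$tumor_id[duplicated(df$tumor_id)]
  if (length(dup) > 0) {
    stop("duplicate tumor_id(s) in clinical table: ",
         paste(unique(dup), collapse = ", "))
  }
  for (col in names(clinical_levels)) {
    vals <- as.character(df[[col]])
    bad <- which(!vals %in% clinical_levels[[col]])
    if (length(bad) > 0) {
      stop(sprintf(
        "clinical table column '%s' has unknown level '%s' at row %d; allowed levels: %s",
        col, vals[bad[1]], bad[1], paste(clinical_levels[[col]], collapse = ", ")))
    }
    df[[col]] <- factor(vals, levels = clinical_levels[[col]])
  }
  for (col in c("os_time", "rfs_time")) {
    bad <- which(is.na(df[[col]]) | df[[col]] < 0)
    if (length(bad) > 0) {
      stop(sprintf("clinical table column '%s' is negative or missing at row %d",
                   col, bad[1]))
    }
  }
  for (col in c("os_event", "rfs_event")) {
    if (any(!df[[col]] %in% c(0, 1))) {
      stop("clinical table column '", col, "' must be 0/1")
    }
  }
  if (any(is.na(df$age) | df$age < 0)) stop("clinical table column 'age' must be non-negative")
  df$tumor_id <- as.character(df$tumor_id)
  df
}

#' Read the sections table
#'
#' A CSV linking each tumor to its sections: columns `tumor_id, section_id,
#' role, path`, where `role` is one of [section_roles()] and `path` points to
#' the section's label-map raster (relative paths are resolved against the
#' table's directory).
#'
#' @param path Path to `sections.csv`.
#' @return A validated `data.frame` with absolute raster paths.
#' @export
read_sections_table <- function(path) {
  if (!file.exists(path)) stop("sections table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("tumor_id", "section_id", "role", "path")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop("sections table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- which(!df$role %in% section_roles())
  if (length(bad) > 0) {
    stop(sprintf("sections table has unknown role '%s' at row %d; allowed: %s",
                 df$role[bad[1]], bad[1], paste(section_roles(), collapse = ", ")))
  }
  if (anyDuplicated(df$section_id)) stop("duplicate section_id in sections table")
  rel <- !grepl("^(/|[A-Za-z]:)", df$path)
  df$path[rel] <- file.path(dirname(path), df$path[rel])
  df$tumor_id <- as.character(df$tumor_id)
  df$section_id <- as.character(df$section_id)
  df
}

#' Read rater morphotype calls
#'
#' A CSV with columns `rater_id, section_id, morphotype, present, rank`
#' recording, per rater and section, whether a morphotype was seen and its
#' dominance rank (`dominant`, `secondary`, `tertiary` or `none`). A rank
#' other than `none` implies presence; at most one morphotype may hold a
#' given rank per rater and section.
#'
#' @param path Path to `rater_calls.csv`.
#' @return A validated `data.frame`.
#' @export
read_rater_calls <- function(path) {
  if (!file.exists(path)) stop("rater calls table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("rater_id", "section_id", "morphotype", "present", "rank")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop("rater calls table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$morphotype <- canonical_morphotype(df$morphotype)
  ranks <- c("dominant", "secondary", "tertiary", "none")
  if (any(!df$rank %in% ranks)) {
    stop("rater calls 'rank' must be one of: ", paste(ranks, collapse = ", "))
  }
  df$present <- as.logical(df$present)
  if (any(is.na(df$present))) stop("rater calls 'present' must be TRUE/FALSE")
  if (any(df$rank != "none" & !df$present)) {
    stop("rater calls: rank other than 'none' requires present = TRUE")
  }
  key <- df[df$rank != "none", c("rater_id", "section_id", "rank")]
  if (anyDuplicated(key)) {
    stop("rater calls: more than one morphotype holds the same rank for a rater/section")
  }
  df
}

#' Write the standard results bundle of a pipeline run
#'
#' Writes five files into `out_dir`: `sections_profiles.csv`,
#' `tumor_summary.csv`, `associations.csv`, `survival_strata.csv` and
#' `run_metadata.json` (seed, configuration hash, package version). Rows are
#' ordered deterministically, so re-running with identical inputs and seed
#' yields byte-identical tables.
#'
#' @param results A results list as produced by [run_all()]; missing
#'   components are written as header-only tables.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_results_bundle <- function(results, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok) stop("cannot create output directory: ", out_dir)
  empty <- function(cols) {
    as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols))
  }
  tabs <- list(
    sections_profiles.csv = results$section_profiles %||%
      empty(c("tumor_id", "section_id", "role", profile_cols(),
              "tumor_area_px", "retained_area_px", "n_regions_kept", "n_regions_dropped")),
    tumor_summary.csv = results$tumor_summary %||%
      empty(c("tumor_id", profile_cols(), "tumor_nsi", "nsi_class",
              "n_valid_sections", "dmc", "pattern_class", "cluster_id")),
    associations.csv = results$associations %||%
      empty(c("outcome", "covariate", "test", "statistic", "p_value",
              "p_adjusted", "significant", "n")),
    survival_strata.csv = results$survival %||%
      empty(c("morphotype", "endpoint", "subset", "cutoff", "n_low", "n_high",
              "logrank_statistic", "logrank_p", "exploratory"))
  )
  paths <- character(0)
  for (fn in names(tabs)) {
    p <- file.path(out_dir, fn)
    utils::write.csv(tabs[[fn]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  meta <- list(
    package = "morphohet",
    version = as.character(utils::packageVersion("morphohet")),
    seed = results$seed %||% NA,
    config = results$config %||% list(),
    config_hash = config_hash(results$config %||% list())
  )
  mp <- file.path(out_dir, "run_metadata.json")
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(paths, mp))
}

# md5 of the canonical JSON serialization of a config list
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
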