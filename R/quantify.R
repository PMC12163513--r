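#' Extract connected morphotype regions from a label map
#'
#' Decomposes the non-background pixels of a label map into connected
#' components ("fragments"), computed per morphotype label. Connectivity is
#' 4 (edge-sharing) or 8 (edge- or corner-sharing, the default used by the
#' pipeline for blob-like histology regions).
#'
#' @param map A [label_map()].
#' @param connectivity 4 or 8.
#' @return A `data.frame` with one row per region: `morphotype`,
#'   `label_value`, `fragment_id` (unique within the section), `area_px`,
#'   and the half-open, 0-based bounding box `row0, col0, row1, col1`.
#'   An all-background map yields zero rows.
#' @export
extract_regions <- function(map, connectivity = 8) {
  stopifnot(inherits(map, "label_map"))
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  px <- map$pixels
  nr <- nrow(px); nc <- ncol(px)
  out <- list()
  frag <- 0L
  for (lab in 1:6) {
    idx <- which(px == lab)
    if (length(idx) == 0) next
    comp <- label_components(idx, nr, nc, connectivity)
    for (cid in unique(comp)) {
      pix <- idx[comp == cid]
      rows <- (pix - 1L) %% nr
      cols <- (pix - 1L) %/% nr
      frag <- frag + 1L
      out[[frag]] <- data.frame(
        morphotype = MORPHOTYPE_CODES[lab], label_value = lab,
        fragment_id = frag, area_px = length(pix),
        row0 = min(rows), col0 = min(cols),
        row1 = max(rows) + 1L, col1 = max(cols) + 1L
      )
    }
  }
  if (frag == 0L) {
    return(data.frame(morphotype = character(0), label_value = integer(0),
                      fragment_id = integer(0), area_px = integer(0),
                      row0 = integer(0), col0 = integer(0),
                      row1 = integer(0), col1 = integer(0)))
  }
  do.call(rbind, out)
}

# Connected components of a pixel index set via the adjacency graph.
# idx: linear (column-major) indices into an nr x nc grid.
label_components <- function(idx, nr, nc, connectivity) {
  n <- length(idx)
  if (n == 1) return(1L)
  pos <- integer(nr * nc)
  pos[idx] <- seq_len(n)
  rows <- (idx - 1L) %% nr
  cols <- (idx - 1L) %/% nr
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  from <- integer(0); to <- integer(0)
  for (o in offs) {
    r2 <- rows + o[1]; c2 <- cols + o[2]
    ok <- r2 >= 0L & r2 < nr & c2 >= 0L & c2 < nc
    nb <- pos[c2[ok] * nr + r2[ok] + 1L]
    hit <- nb > 0L
    from <- c(from, which(ok)[hit])
    to <- c(to, nb[hit])
  }
  g <- igraph::make_graph(as.vector(rbind(from, to)), n = n, directed = FALSE)
  igraph::components(g)$membership
}

#' Drop regions smaller than a fraction of the tumor area
#'
#' Small predicted regions have a higher likelihood of being misclassified;
#' only regions occupying at least `min_frac` of the tumor area in the
#' section are retained (inclusive boundary). The filter is applied per
#' connected region, and the denominator is the total classified tumor area
#' before filtering.
#'
#' @param regions Region table from [extract_regions()].
#' @param tumor_area_px Total classified tumor area of the section, pixels.
#' @param min_frac Minimum area fraction; default 0.05.
#' @return The subset of `regions` meeting the threshold.
#' @export
filter_small_regions <- function(regions, tumor_area_px, min_frac = 0.05) {
  if (tumor_area_px <= 0) stop("tumor_area_px must be positive")
  if (min_frac < 0 || min_frac > 1) stop("min_frac must be in [0, 1]")
  # tolerance guards against float representation of min_frac * area
  keep <- regions$area_px >= min_frac * tumor_area_px - 1e-9
  regions[keep, , drop = FALSE]
}

#' Per-section morphotype proportion profile
#'
#' Proportions are computed over the retained (post-filter) area:
#' `p_k = retained area of morphotype k / total retained area`. A section
#' with no retained regions is flagged empty and is excluded from tumor
#' summaries downstream (with a warning at the pipeline level).
#'
#' @param map The [label_map()] the regions came from.
#' @param retained_regions Region table after [filter_small_regions()].
#' @param n_regions_dropped Optional count of regions removed by the filter
#'   (recorded in the output table).
#' @return One-row `data.frame`: `tumor_id, section_id, role, p_CT..p_SE,
#'   tumor_area_px, retained_area_px, n_regions_kept, n_regions_dropped,
#'   empty`.
#' @export
section_profile <- function(map, retained_regions, n_regions_dropped = NA_integer_) {
  stopifnot(inherits(map, "label_map"))
  tumor_area <- sum(map$pixels > 0L)
  areas <- stats::setNames(numeric(6), MORPHOTYPE_CODES)
  if (nrow(retained_regions) > 0) {
    agg <- tapply(retained_regions$area_px, retained_regions$morphotype, sum)
    areas[names(agg)] <- agg
  }
  retained <- sum(areas)
  props <- if (retained > 0) areas / retained else areas * 0
  out <- data.frame(
    tumor_id = map$tumor_id, section_id = map$section_id, role = map$role,
    as.list(stats::setNames(unname(props), profile_cols())),
    tumor_area_px = tumor_area, retained_area_px = as.integer(retained),
    n_regions_kept = nrow(retained_regions),
    n_regions_dropped = n_regions_dropped,
    empty = retained == 0
  )
  out
}

#' Quantify one section: regions, area filter, proportion profile
#'
#' Convenience wrapper chaining [extract_regions()],
#' [filter_small_regions()] and [section_profile()].
#'
#' @inheritParams extract_regions
#' @inheritParams filter_small_regions
#' @return As [section_profile()].
#' @export
quantify_section <- function(map, min_frac = 0.05, connectivity = 8) {
  regions <- extract_regions(map, connectivity = connectivity)
  tumor_area <- sum(map$pixels > 0L)
  if (tumor_area == 0) {
    return(section_profile(map, regions, n_regions_dropped = 0L))
  }
  kept <- filter_small_regions(regions, tumor_area, min_frac = min_frac)
  section_profile(map, kept, n_regions_dropped = nrow(regions) - nrow(kept))
}
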