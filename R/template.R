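# The virtual tissue template: labeled virtual cells (pixels), landmarks, and
# landmark-distance binning.
#
# A virtual cell is a pixel of a 2D tissue drawing carrying a cell-type label;
# one real single-cell profile is later projected onto each of them. For each
# spatially restricted cell type a landmark defines the spatial axis that
# stands in for pseudotime: either the unsigned x-distance to a vertical
# reference line (a differentiation wavefront such as the morphogenetic
# furrow), or the radial distance to a reference point (the center of a set of
# concentric rings).

#' Construct a landmark
#'
#' @param cell_types Character vector of spatial cell types this landmark
#'   covers.
#' @param mode `"axis_x"` (distance to the vertical line `x = x0`) or
#'   `"radial"` (Euclidean distance to the point `(x0, y0)`).
#' @param x0,y0 Reference coordinates (`y0` is required for radial mode).
#' @param direction `"increasing"` if pseudotime grows with distance from the
#'   reference (bin 1 = closest to the reference), `"decreasing"` otherwise.
#'   Orientation is biological knowledge and is always supplied by the user.
#' @return A list of class `landmark`.
#' @export
landmark <- function(cell_types, mode = c("axis_x", "radial"), x0, y0 = NULL,
                     direction = c("increasing", "decreasing")) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  if (mode == "radial" && is.null(y0)) stopf("radial landmark requires y0")
  structure(list(cell_types = cell_types, mode = mode, x0 = x0,
                 y0 = y0, direction = direction), class = "landmark")
}

#' Construct a virtual template
#'
#' @param cells data.frame with columns `vcell_id`, `x`, `y`, `cell_type`,
#'   `spatial` (logical; FALSE for appended non-spatial compartments).
#' @param landmarks List of [landmark()] objects. Every spatial cell type must
#'   be covered by exactly one landmark before distances are computed.
#' @return A list of class `virtual_template`.
#' @export
virtual_template <- function(cells, landmarks = list()) {
  need <- c("vcell_id", "x", "y", "cell_type", "spatial")
  if (!all(need %in% names(cells)))
    stopf("cells must have columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(cells$vcell_id)) stopf("duplicate vcell ids")
  if (nrow(cells) > 0) {
    if (any(!is.finite(cells$x)) || any(!is.finite(cells$y)))
      stopf("virtual cell coordinates must be finite")
    if (any(!nzchar(cells$cell_type))) stopf("cell_type must be non-empty")
  }
  structure(list(cells = cells, landmarks = landmarks), class = "virtual_template")
}

#' Build a template from an integer-label raster
#'
#' One virtual cell is created per non-background pixel, with coordinates
#' `(x, y) = (column, row)` in pixel units and `spatial = TRUE`. The raster
#' replaces image-based background removal: converting a drawing to integer
#' labels is a preprocessing step outside this package.
#'
#' @param grid Integer matrix (rows = y, columns = x).
#' @param label_map Named vector mapping label (as character) to cell type.
#' @param background Background label (default 0).
#' @param landmarks Optional landmark list to attach.
#' @return A `virtual_template`.
#' @export
template_from_label_grid <- function(grid, label_map, background = 0L,
                                     landmarks = list()) {
  labs <- setdiff(unique(as.vector(grid)), background)
  unmapped <- setdiff(as.character(labs), names(label_map))
  if (length(unmapped) > 0)
    stopf("label(s) without cell-type mapping: %s", paste(unmapped, collapse = ", "))
  idx <- which(grid != background, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  if (nrow(idx) == 0L)
    return(virtual_template(data.frame(vcell_id = character(0), x = numeric(0),
                                       y = numeric(0), cell_type = character(0),
                                       spatial = logical(0)), landmarks))
  cells <- data.frame(
    vcell_id = sprintf("v%05d", seq_len(nrow(idx))),
    x = as.numeric(idx[, 2]), y = as.numeric(idx[, 1]),
    cell_type = unname(label_map[as.character(grid[idx])]),
    spatial = TRUE
  )
  virtual_template(cells, landmarks)
}

#' Append a non-spatial (or circular) compartment to a template
#'
#' Places `n_cells` points uniformly inside a disc. Used for cell types with
#' no spatially restricted location in the tissue (e.g. glia, hemocytes),
#' which are drawn as circles next to the tissue proper and mapped without
#' binning.
#'
#' @param template A `virtual_template`.
#' @param cell_type Cell type of the new compartment.
#' @param center Numeric `(x, y)` center.
#' @param radius Disc radius (> 0).
#' @param n_cells Number of virtual cells to add.
#' @param spatial Spatial flag for the new cells (default FALSE).
#' @param seed Integer seed; the same seed reproduces identical coordinates.
#' @return The grown `virtual_template`.
#' @export
add_compartment <- function(template, cell_type, center, radius, n_cells,
                            spatial = FALSE, seed = 1L) {
  stopifnot(inherits(template, "virtual_template"), radius > 0, n_cells >= 0)
  pts <- withr::with_seed(seed, {
    r <- radius * sqrt(stats::runif(n_cells))
    th <- 2 * pi * stats::runif(n_cells)
    cbind(x = center[1] + r * cos(th), y = center[2] + r * sin(th))
  })
  new_cells <- data.frame(
    vcell_id = sprintf("c_%s_%04d", cell_type, seq_len(n_cells)),
    x = pts[, "x"], y = pts[, "y"], cell_type = cell_type, spatial = spatial
  )
  if (any(new_cells$vcell_id %in% template$cells$vcell_id))
    stopf("compartment '%s' already present (duplicate vcell ids)", cell_type)
  template$cells <- rbind(template$cells, new_cells)
  template
}

#' Interleave two cell types over their merged footprint
#'
#' Relabels the pixels of the two types alternately along the chosen axis
#' (ties broken by the other coordinate, then by vcell id), emulating tissues
#' where two cell types are physically intermixed (e.g. photoreceptors and
#' interommatidial cells posterior to the furrow). Resulting counts differ by
#' at most one.
#'
#' @param template A `virtual_template`.
#' @param type_a,type_b The two cell types to interleave (both must exist).
#' @param axis `"x"` or `"y"`: ordering axis for the alternation.
#' @return The relabeled `virtual_template`.
#' @export
interleave_types <- function(template, type_a, type_b, axis = c("x", "y")) {
  axis <- match.arg(axis)
  cells <- template$cells
  for (ty in c(type_a, type_b))
    if (!any(cells$cell_type == ty)) stopf("cell type '%s' absent from template", ty)
  sel <- which(cells$cell_type %in% c(type_a, type_b))
  main <- if (axis == "x") cells$x[sel] else cells$y[sel]
  other <- if (axis == "x") cells$y[sel] else cells$x[sel]
  ord <- sel[order(main, other, cells$vcell_id[sel], method = "radix")]
  cells$cell_type[ord] <- rep_len(c(type_a, type_b), length(ord))
  template$cells <- cells
  template
}

#' Landmark distances for all spatial virtual cells
#'
#' Every spatial cell type must be covered by exactly one landmark. axis_x
#' landmarks give the unsigned distance `|x - x0|`; radial landmarks give the
#' Euclidean distance to `(x0, y0)`. Non-spatial cells get no distance.
#'
#' @param template A `virtual_template` with landmarks attached.
#' @return Named numeric vector over spatial vcell ids.
#' @export
landmark_distances <- function(template) {
  stopifnot(inherits(template, "virtual_template"))
  cells <- template$cells
  spatial_types <- unique(cells$cell_type[cells$spatial])
  covered <- unlist(lapply(template$landmarks, `[[`, "cell_types"))
  if (anyDuplicated(covered))
    stopf("cell type(s) covered by more than one landmark: %s",
          paste(unique(covered[duplicated(covered)]), collapse = ", "))
  uncovered <- setdiff(spatial_types, covered)
  if (length(uncovered) > 0)
    stopf("spatial cell type(s) without landmark: %s", paste(uncovered, collapse = ", "))
  out <- numeric(0)
  for (lm in template$landmarks) {
    sel <- cells$spatial & cells$cell_type %in% lm$cell_types
    if (!any(sel)) next
    d <- if (lm$mode == "axis_x") {
      abs(cells$x[sel] - lm$x0)
    } else {
      sqrt((cells$x[sel] - lm$x0)^2 + (cells$y[sel] - lm$y0)^2)
    }
    out <- c(out, stats::setNames(d, cells$vcell_id[sel]))
  }
  out
}

#' Bin spatial virtual cells by landmark distance
#'
#' Within each spatial cell type, cells are divided into `n_bins` equal-count
#' (quantile) bins by landmark distance; bin sizes differ by at most one and
#' ties are broken by a stable sort on vcell id. Bin 1 corresponds to the
#' pseudotime-early end as set by the landmark's `direction`. Types with fewer
#' cells than bins collapse to one cell per bin with a warning.
#'
#' @param template A `virtual_template`.
#' @param distances Output of [landmark_distances()].
#' @param n_bins Number of bins per cell type (default 10).
#' @return data.frame (`vcell_id`, `cell_type`, `bin`); non-spatial cells get
#'   `bin = NA`.
#' @export
bin_virtual <- function(template, distances, n_bins = 10) {
  stopifnot(inherits(template, "virtual_template"), n_bins >= 1)
  cells <- template$cells
  dir_of <- list()
  for (lm in template$landmarks)
    for (ty in lm$cell_types) dir_of[[ty]] <- lm$direction
  bins <- rep(NA_integer_, nrow(cells))
  for (ty in sort(unique(cells$cell_type[cells$spatial]))) {
    sel <- which(cells$spatial & cells$cell_type == ty)
    ids <- cells$vcell_id[sel]
    if (!all(ids %in% names(distances)))
      stopf("missing landmark distance for cell type '%s'", ty)
    b <- equal_count_bins(ids, distances[ids], n_bins,
                          decreasing = identical(dir_of[[ty]], "decreasing"))
    bins[sel] <- b[ids]
  }
  data.frame(vcell_id = cells$vcell_id, cell_type = cells$cell_type, bin = bins)
}

#' Read and write template tables
#'
#' The template TSV carries one row per virtual cell (`vcell_id`, `x`, `y`,
#' `cell_type`, `spatial`); the landmark config has one landmark per line
#' (`cell_types` comma-separated, `mode`, `x0`, `y0`, `direction`).
#'
#' @param path,cells_path,landmarks_path File paths.
#' @param template A `virtual_template` (for the writer).
#' @return `read_template` returns a `virtual_template`.
#' @export
read_template <- function(cells_path, landmarks_path = NULL) {
  cells <- utils::read.delim(cells_path, stringsAsFactors = FALSE)
  cells$spatial <- as.logical(cells$spatial)
  lms <- list()
  if (!is.null(landmarks_path)) {
    df <- utils::read.delim(landmarks_path, stringsAsFactors = FALSE)
    lms <- lapply(seq_len(nrow(df)), function(i) {
      landmark(strsplit(df$cell_types[i], ",", fixed = TRUE)[[1]], df$mode[i],
               df$x0[i], if (is.na(df$y0[i])) NULL else df$y0[i], df$direction[i])
    })
  }
  virtual_template(cells, lms)
}

#' @rdname read_template
#' @export
write_template <- function(template, cells_path, landmarks_path = NULL) {
  utils::write.table(template$cells, cells_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(landmarks_path)) {
    df <- do.call(rbind, lapply(template$landmarks, function(lm) {
      data.frame(cell_types = paste(lm$cell_types, collapse = ","),
                 mode = lm$mode, x0 = lm$x0, y0 = lm$y0 %||% NA_real_,
                 direction = lm$direction)
    }))
    utils::write.table(df, landmarks_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(cells_path)
}
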