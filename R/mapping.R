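# Assigning real single-cell profiles to virtual cells: pseudotime binning of
# real cells, per-bin random assignment, and projection of data matrices.

#' Bin real cells by pseudotime within each cell type
#'
#' Identical contract to [bin_virtual()]: equal-count bins, sizes differing by
#' at most one, stable tie-breaking on cell id, warning + degenerate bins when
#' a type has fewer cells than bins. Bin 1 is the pseudotime-early end.
#'
#' @param pseudotime Named numeric vector of pseudotimes.
#' @param cell_type Named character vector of cell types (same cells).
#' @param n_bins Number of bins per cell type (default 10).
#' @return data.frame (`cell_id`, `cell_type`, `bin`).
#' @export
bin_real <- function(pseudotime, cell_type, n_bins = 10) {
  ids <- names(pseudotime)
  if (is.null(ids) || is.null(names(cell_type))) stopf("inputs must be named by cell id")
  if (!all(ids %in% names(cell_type))) stopf("cell types missing for some cells")
  out <- data.frame(cell_id = ids, cell_type = unname(cell_type[ids]),
                    bin = NA_integer_)
  for (ty in sort(unique(out$cell_type))) {
    sel <- which(out$cell_type == ty)
    b <- equal_count_bins(out$cell_id[sel], pseudotime[out$cell_id[sel]], n_bins)
    out$bin[sel] <- b[out$cell_id[sel]]
  }
  out
}

#' Assign one real cell to every virtual cell
#'
#' Per (cell type, bin): when at least as many real as virtual cells are
#' available, real cells are sampled without replacement; when there are fewer
#' real than virtual cells, each real cell is used `floor(nv/nr)` or
#' `ceiling(nv/nr)` times (so every real profile is used at least once) and
#' the assignment to virtual cells is a random permutation. Non-spatial cell
#' types (bin `NA` on the virtual side) are matched type-wide without binning.
#' A bin with zero real cells falls back to the whole-type pool with a
#' warning. All draws happen in deterministic (cell type, bin) lexicographic
#' order from a single RNG stream, so a seed fully reproduces the mapping.
#'
#' @param virtual_bins data.frame (`vcell_id`, `cell_type`, `bin`) from
#'   [bin_virtual()].
#' @param real_bins data.frame (`cell_id`, `cell_type`, `bin`) from
#'   [bin_real()].
#' @param seed Integer seed.
#' @return A data.frame of class `cell_mapping` (`vcell_id`, `cell_id`), with
#'   the seed stored as an attribute.
#' @export
assign_cells <- function(virtual_bins, real_bins, seed = 1L) {
  v_types <- unique(virtual_bins$cell_type)
  missing <- setdiff(v_types, unique(real_bins$cell_type))
  if (length(missing) > 0)
    stopf("cell type(s) in template but absent from real data: %s",
          paste(missing, collapse = ", "))
  res <- withr::with_seed(seed, {
    pieces <- list()
    for (ty in sort(v_types)) {
      v <- virtual_bins[virtual_bins$cell_type == ty, , drop = FALSE]
      r <- real_bins[real_bins$cell_type == ty, , drop = FALSE]
      if (all(is.na(v$bin))) {
        pieces[[ty]] <- assign_pool(sort(v$vcell_id), sort(r$cell_id))
      } else {
        sub <- list()
        for (b in sort(unique(v$bin))) {
          vids <- sort(v$vcell_id[v$bin == b])
          pool <- sort(r$cell_id[!is.na(r$bin) & r$bin == b])
          if (length(pool) == 0L) {
            warnf("cell type '%s' bin %d has no real cells; using whole-type pool", ty, b)
            pool <- sort(r$cell_id)
          }
          sub[[as.character(b)]] <- assign_pool(vids, pool)
        }
        pieces[[ty]] <- do.call(rbind, sub)
      }
    }
    do.call(rbind, pieces)
  })
  rownames(res) <- NULL
  attr(res, "seed") <- seed
  class(res) <- c("cell_mapping", "data.frame")
  res
}

# Assign a pool of real cell ids to a set of virtual cell ids (one each).
assign_pool <- function(vids, pool) {
  nv <- length(vids)
  nr <- length(pool)
  if (nr == 0L) stopf("empty real-cell pool")
  if (nr >= nv) {
    chosen <- sample(pool, nv)
  } else {
    reps <- nv %/% nr
    extra <- nv - reps * nr
    multiset <- c(rep(pool, reps), if (extra > 0) sample(pool, extra))
    chosen <- sample(multiset)
  }
  data.frame(vcell_id = vids, cell_id = chosen)
}

#' Project a data matrix onto the virtual cells
#'
#' The column for a virtual cell is an exact copy of the column of its mapped
#' real cell (profiles are copied, never interpolated), so any column-wise
#' statistic of the source cells is preserved.
#'
#' @param mapping A `cell_mapping`.
#' @param mat Matrix with real cells in columns.
#' @return Matrix with virtual cells in columns (same rows).
#' @export
project <- function(mapping, mat) {
  missing <- setdiff(unique(mapping$cell_id), colnames(mat))
  if (length(missing) > 0)
    stopf("mapped cell(s) missing from matrix columns: %s",
          paste(utils::head(missing, 3), collapse = ", "))
  out <- mat[, mapping$cell_id, drop = FALSE]
  colnames(out) <- mapping$vcell_id
  out
}

#' Map real cells onto a virtual template (orchestration)
#'
#' Runs the whole spatial-mapping stage: per-cell-type diffusion pseudotime on
#' the embedding (unless a pseudotime vector is supplied), equal-count binning
#' of real and virtual cells with the same number of bins, and per-bin random
#' assignment.
#'
#' @param template A `virtual_template` with landmarks.
#' @param cell_type Named character vector: real cell id -> cell type.
#' @param embedding Cells x dims matrix (needed unless `pseudotime` given).
#' @param roots Named character vector: cell type -> root cell id for the
#'   pseudotime of that type (required when pseudotime is computed here).
#' @param pseudotime Optional named pseudotime vector replacing the internal
#'   diffusion pseudotime.
#' @param n_bins Bins per cell type (default 10).
#' @param seed Integer seed for the assignment stage.
#' @param type_alias Optional named character vector renaming real cell types
#'   to template cell types (to assign several real clusters jointly).
#' @param k_neighbors,n_components Passed to [diffusion_pseudotime()].
#' @return A `cell_mapping`; the virtual and real bin tables are attached as
#'   attributes `virtual_bins` and `real_bins`.
#' @export
map_to_template <- function(template, cell_type, embedding = NULL, roots = NULL,
                            pseudotime = NULL, n_bins = 10, seed = 1L,
                            type_alias = NULL, k_neighbors = 15,
                            n_components = 10) {
  if (!is.null(type_alias)) {
    hit <- cell_type %in% names(type_alias)
    cell_type[hit] <- type_alias[cell_type[hit]]
  }
  spatial_types <- sort(unique(template$cells$cell_type[template$cells$spatial]))
  if (is.null(pseudotime)) {
    if (is.null(embedding)) stopf("supply either an embedding or a pseudotime vector")
    pseudotime <- numeric(0)
    for (ty in spatial_types) {
      ids <- names(cell_type)[cell_type == ty]
      if (length(ids) == 0L) stopf("cell type '%s' absent from real data", ty)
      root <- roots[[ty]] %||% stopf("no root cell supplied for cell type '%s'", ty)
      # a disconnected neighbour graph at the requested k is handled by
      # doubling k (graphs are always connected at k = n - 1)
      k <- min(k_neighbors, length(ids) - 1L)
      repeat {
        pt <- tryCatch(
          diffusion_pseudotime(embedding[ids, , drop = FALSE], root,
                               k_neighbors = k, n_components = n_components),
          error = function(e) {
            if (!grepl("disconnected", conditionMessage(e))) stop(e)
            NULL
          })
        if (!is.null(pt)) break
        k <- min(2L * k, length(ids) - 1L)
        message(sprintf("cell type '%s': neighbour graph disconnected; retrying with k = %d",
                        ty, k))
      }
      pseudotime <- c(pseudotime, pt)
    }
  }
  spatial_cells <- names(cell_type)[cell_type %in% spatial_types]
  rb <- bin_real(pseudotime[intersect(names(pseudotime), spatial_cells)],
                 cell_type, n_bins = n_bins)
  # non-spatial real cells enter the pool with bin NA
  nonspatial <- names(cell_type)[!cell_type %in% spatial_types]
  if (length(nonspatial) > 0)
    rb <- rbind(rb, data.frame(cell_id = nonspatial,
                               cell_type = unname(cell_type[nonspatial]),
                               bin = NA_integer_))
  vb <- bin_virtual(template, landmark_distances(template), n_bins = n_bins)
  mapping <- assign_cells(vb, rb, seed = seed)
  attr(mapping, "virtual_bins") <- vb
  attr(mapping, "real_bins") <- rb
  mapping
}
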