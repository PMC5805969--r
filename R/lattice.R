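#' Grid diameter in voxels
#'
#' Number of voxels across a circular well: the well diameter divided by the
#' voxel edge length, rounded to the nearest integer. A 15.6 mm well at
#' 9.6 um voxels gives 1625 voxels; a 34.8 mm well at 12 um gives 2900.
#'
#' @param well_diameter_mm well diameter in mm (> 0).
#' @param voxel_edge_um voxel edge length in um (> 0).
#' @return Integer voxel count across the well.
#' @export
grid_diameter_voxels <- function(well_diameter_mm, voxel_edge_um) {
  stopifnot(is.numeric(well_diameter_mm), is.numeric(voxel_edge_um))
  if (any(well_diameter_mm <= 0) || any(voxel_edge_um <= 0))
    stop("well diameter and voxel edge must be positive")
  as.integer(round(well_diameter_mm * 1000 / voxel_edge_um))
}

#' Circular occupancy lattice
#'
#' A 2-D square lattice masked to a circular well. A voxel belongs to the
#' well if its centre lies within the well radius (centre convention), which
#' makes the in-well voxel count reproducible from the diameter alone.
#' Occupancy maps each in-well voxel to a cell index (0 = empty).
#'
#' @param well_diameter_mm well diameter in mm.
#' @param voxel_edge_um voxel (= cell) edge length in um.
#' @param diameter_voxels optionally, the voxel diameter directly (overrides
#'   the physical sizes; used for scaled test grids).
#' @return A `ca_grid` object: list with `n` (side length in voxels), `mask`
#'   (logical n x n, in-well), `occ` (integer n x n occupancy, 0 empty),
#'   `capacity` (number of in-well voxels) and the physical sizes.
#' @examples
#' g <- ca_grid(diameter_voxels = 21)
#' g$capacity
#' @export
ca_grid <- function(well_diameter_mm = NULL, voxel_edge_um = NULL,
                    diameter_voxels = NULL) {
  if (is.null(diameter_voxels)) {
    if (is.null(well_diameter_mm) || is.null(voxel_edge_um))
      stop("give either physical sizes or diameter_voxels")
    diameter_voxels <- grid_diameter_voxels(well_diameter_mm, voxel_edge_um)
  }
  n <- as.integer(diameter_voxels)
  stopifnot(n >= 1L)
  r <- n / 2
  ctr <- (n + 1) / 2                      # centre in 1-based voxel coords
  xy <- seq_len(n) - ctr
  d2 <- outer(xy^2, xy^2, `+`)            # squared distance of voxel centres
  mask <- d2 <= r^2
  structure(
    list(n = n, mask = mask, occ = matrix(0L, n, n),
         capacity = sum(mask),
         well_diameter_mm = well_diameter_mm, voxel_edge_um = voxel_edge_um),
    class = "ca_grid")
}

#' @export
print.ca_grid <- function(x, ...) {
  cat(sprintf("Circular lattice: %d x %d voxels, %d in well, %d occupied\n",
              x$n, x$n, x$capacity, sum(x$occ > 0L)))
  invisible(x)
}

#' Well-plate presets
#'
#' Geometry presets for the plate formats used in monolayer growth assays:
#' `"24-well"` (15.6 mm well, 9.6 um voxels, 1625-voxel diameter) and
#' `"6-well"` (34.8 mm well, 12 um voxels, 2900-voxel diameter).
#'
#' @param preset `"24-well"` or `"6-well"`.
#' @return A list with `well_diameter_mm` and `voxel_edge_um`.
#' @export
plate_preset <- function(preset = c("24-well", "6-well")) {
  preset <- match.arg(preset)
  switch(preset,
         "24-well" = list(well_diameter_mm = 15.6, voxel_edge_um = 9.6),
         "6-well"  = list(well_diameter_mm = 34.8, voxel_edge_um = 12))
}

#' Neighbourhood specification
#'
#' @param kind `"vonneumann"` (edge-adjacent) or `"moore"` (edge- and
#'   diagonally adjacent).
#' @param order maximum neighbourhood order, 1-3. Order k means Manhattan
#'   radius k for Von Neumann and Chebyshev radius k for Moore.
#' @return A `nbhd_spec` object.
#' @export
nbhd_spec <- function(kind = c("vonneumann", "moore"), order = 3L) {
  kind <- match.arg(kind)
  order <- as.integer(order)
  if (!order %in% 1:3) stop("order must be 1, 2 or 3")
  structure(list(kind = kind, order = order), class = "nbhd_spec")
}

# offsets of neighbourhood shell at exactly order k, as an integer matrix
# (dx, dy); Von Neumann shell k = Manhattan distance k, Moore shell k =
# Chebyshev distance k
nbhd_shell <- function(kind, k) {
  d <- -k:k
  off <- as.matrix(expand.grid(dx = d, dy = d))
  if (kind == "moore") {
    off[pmax(abs(off[, 1]), abs(off[, 2])) == k, , drop = FALSE]
  } else {
    g <- as.matrix(expand.grid(dx = -k:k, dy = -k:k))
    g[abs(g[, 1]) + abs(g[, 2]) == k, , drop = FALSE]
  }
}

#' Free spaces around a position
#'
#' Enumerates empty in-well voxels around `pos`, grouped by neighbourhood
#' order (order-1 shell first, then order-2, then order-3). Within a shell
#' the enumeration order is fixed (row-major over offsets), so results are
#' deterministic.
#'
#' @param pos integer `c(x, y)` voxel coordinates (1-based).
#' @param grid a [ca_grid()].
#' @param spec a [nbhd_spec()].
#' @return A list with `xy` (matrix of free positions, nearest shells first)
#'   and `order` (shell order of each row). Zero-row matrix if none.
#' @export
free_spaces <- function(pos, grid, spec) {
  stopifnot(inherits(grid, "ca_grid"), inherits(spec, "nbhd_spec"))
  n <- grid$n
  out_xy <- NULL; out_ord <- integer(0)
  for (k in seq_len(spec$order)) {
    off <- nbhd_shell(spec$kind, k)
    x <- pos[1] + off[, 1]; y <- pos[2] + off[, 2]
    ok <- x >= 1 & x <= n & y >= 1 & y <= n
    x <- x[ok]; y <- y[ok]
    if (!length(x)) next
    idx <- cbind(x, y)
    free <- grid$mask[idx] & grid$occ[idx] == 0L
    if (any(free)) {
      out_xy <- rbind(out_xy, idx[free, , drop = FALSE])
      out_ord <- c(out_ord, rep.int(k, sum(free)))
    }
  }
  if (is.null(out_xy)) out_xy <- matrix(integer(0), 0, 2)
  colnames(out_xy) <- c("x", "y")
  list(xy = out_xy, order = out_ord)
}

#' Daughter-cell placement
#'
#' Division-space search: free voxels are taken from the lowest non-empty
#' neighbourhood shell (closest to the parent first) and one is chosen
#' uniformly at random. Returns `NULL` when no free voxel exists up to the
#' spec's order; the caller then sends the parent to G0.
#'
#' @inheritParams free_spaces
#' @param parent_pos integer `c(x, y)` of the dividing cell.
#' @return Integer `c(x, y)` of the chosen voxel, or `NULL`.
#' @export
place_daughter <- function(parent_pos, grid, spec) {
  fs <- free_spaces(parent_pos, grid, spec)
  if (!nrow(fs$xy)) return(NULL)
  lowest <- fs$order == min(fs$order)
  cand <- fs$xy[lowest, , drop = FALSE]
  cand[sample.int(nrow(cand), 1L), ]
}
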