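# Volumetric data model and mm-space geometry shared by all analysis stages.
# Conventions: voxel indices are 0-based triples (i, j, k); world coordinates
# are millimetres; the index -> mm map is mm = origin + index * voxel_size
# (axis-aligned grids only, no shear or rotation).

.CONDITIONS <- c("CF", "CO", "HeF", "HeO")

#' Define a voxel grid with millimetre geometry
#'
#' A grid couples an array shape with an axis-aligned affine: isotropic or
#' anisotropic voxel sizes in mm plus the mm position of voxel (0,0,0).
#'
#' @param shape Integer vector of length 3, voxels per axis.
#' @param voxel_size Numeric length 1 or 3, mm per voxel along each axis
#'   (default 2 mm isotropic, the template resolution the analyses assume).
#' @param origin Numeric length 3, mm coordinates of voxel (0,0,0).
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(shape, voxel_size = c(2, 2, 2), origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("'shape' must be 3 positive integers")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("'voxel_size' must be positive on all axes")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be 3 finite mm coordinates")
  structure(list(shape = shape, voxel_size = voxel_size, origin = origin),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("volume_grid:", paste(x$shape, collapse = " x "),
      "voxels,", paste(x$voxel_size, collapse = " x "),
      "mm, origin (", paste(x$origin, collapse = ", "), ") mm\n")
  invisible(x)
}

#' Convert 0-based voxel indices to mm coordinates (and back)
#'
#' The mapping is affine-diagonal and round-trips exactly on voxel centers.
#'
#' @param grid A [volume_grid()].
#' @param index Integer matrix (n x 3) of 0-based voxel indices.
#' @return `index_to_mm`: numeric n x 3 matrix of mm coordinates.
#' @export
index_to_mm <- function(grid, index) {
  index <- matrix(as.numeric(index), ncol = 3L)
  sweep(sweep(index, 2L, grid$voxel_size, "*"), 2L, grid$origin, "+")
}

#' @rdname index_to_mm
#' @param mm Numeric matrix (n x 3) of mm coordinates.
#' @return `mm_to_index`: integer n x 3 matrix of nearest 0-based voxel indices.
#' @export
mm_to_index <- function(grid, mm) {
  mm <- matrix(as.numeric(mm), ncol = 3L)
  idx <- sweep(sweep(mm, 2L, grid$origin, "-"), 2L, grid$voxel_size, "/")
  matrix(as.integer(round(idx)), ncol = 3L)
}

# 0-based (i,j,k) matrix -> 1-based linear index into an array of dim `shape`
.vox_linear <- function(index, shape) {
  1L + index[, 1L] + shape[1L] * (index[, 2L] + shape[2L] * index[, 3L])
}

# 1-based linear index -> 0-based (i,j,k)
.vox_unlinear <- function(lin, shape) {
  lin0 <- lin - 1L
  i <- lin0 %% shape[1L]
  j <- (lin0 %/% shape[1L]) %% shape[2L]
  k <- lin0 %/% (shape[1L] * shape[2L])
  cbind(i = i, j = j, k = k)
}

.in_grid <- function(index, shape) {
  index[, 1L] >= 0L & index[, 1L] < shape[1L] &
  index[, 2L] >= 0L & index[, 2L] < shape[2L] &
  index[, 3L] >= 0L & index[, 3L] < shape[3L]
}

#' Construct a scalar volume on a grid
#'
#' Holds one real value per voxel (beta, t/F statistic, classifier accuracy,
#' similarity rho, or preference label) plus an optional binary mask. Values
#' may be NaN/NA only outside the mask.
#'
#' @param values Numeric 3D array matching `grid$shape`, or a vector of
#'   length `prod(grid$shape)`.
#' @param grid A [volume_grid()].
#' @param mask Optional logical array/vector on the same grid.
#' @return An object of class `volume_map`.
#' @export
volume_map <- function(values, grid, mask = NULL) {
  stopifnot(inherits(grid, "volume_grid"))
  values <- array(as.numeric(values), dim = grid$shape)
  if (!is.null(mask)) {
    mask <- array(as.logical(mask), dim = grid$shape)
    if (anyNA(values[mask]))
      stop("values must be defined for every in-mask voxel")
  }
  structure(list(values = values, grid = grid, mask = mask),
            class = "volume_map")
}

#' @export
print.volume_map <- function(x, ...) {
  rng <- range(x$values, na.rm = TRUE)
  cat("volume_map on", paste(x$grid$shape, collapse = "x"),
      "grid; value range [", signif(rng[1], 4), ",", signif(rng[2], 4), "]",
      if (!is.null(x$mask)) paste0("; ", sum(x$mask), " in-mask voxels"), "\n")
  invisible(x)
}

.grid_from_xform <- function(aff, dims) {
  rot <- aff[1:3, 1:3]
  offdiag <- rot; diag(offdiag) <- 0
  if (any(abs(offdiag) > 1e-6))
    stop("affine has shear/rotation; only axis-aligned grids are supported")
  d <- diag(rot)
  if (any(d <= 0))
    stop("affine has non-positive scales; only positively oriented axis-aligned grids are supported")
  volume_grid(dims, voxel_size = d, origin = aff[1:3, 4])
}

.grid_affine <- function(grid) {
  aff <- diag(c(grid$voxel_size, 1))
  aff[1:3, 4] <- grid$origin
  aff
}

#' Read a NIfTI volume
#'
#' 3D images are returned as a [volume_map()]; 4D images as a `bold_run`
#' (list with 4D `data` array, `grid`, `tr_s`). Images with sheared or
#' rotated affines are rejected: all downstream geometry assumes
#' axis-aligned grids.
#'
#' @param path Path to a NIfTI-1/2 file.
#' @return A `volume_map` (3D) or `bold_run` (4D).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  dims <- dim(img)
  if (!(length(dims) %in% c(3L, 4L)))
    stop("expected a 3D or 4D NIfTI image, got ", length(dims), " dimensions")
  grid <- .grid_from_xform(structure(RNifti::xform(img), dim = c(4, 4)), dims[1:3])
  if (length(dims) == 3L) {
    volume_map(as.array(img), grid)
  } else {
    tr <- RNifti::pixdim(img)
    tr <- if (length(tr) >= 4L) tr[4L] else NA_real_
    bold_run(array(as.numeric(img), dim = dims), grid, tr_s = tr)
  }
}

#' Write a volume (or 4D run) as NIfTI
#'
#' Round-trips bitwise through [read_volume()]: data are stored as float64
#' and the grid geometry is encoded in the sform affine.
#'
#' @param x A `volume_map` or `bold_run`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "volume_map")) {
    arr <- x$values; grid <- x$grid; tr <- NULL
  } else if (inherits(x, "bold_run")) {
    arr <- x$data; grid <- x$grid; tr <- x$tr_s
  } else stop("'x' must be a volume_map or bold_run")
  pd <- grid$voxel_size
  if (!is.null(tr) && is.finite(tr)) pd <- c(pd, tr)
  img <- RNifti::asNifti(structure(arr, pixdim = pd), datatype = "double")
  aff <- .grid_affine(grid)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' A 4D BOLD run
#'
#' @param data Numeric 4D array (x, y, z, volume).
#' @param grid A [volume_grid()].
#' @param tr_s Repetition time in seconds.
#' @return Object of class `bold_run`.
#' @export
bold_run <- function(data, grid, tr_s) {
  stopifnot(length(dim(data)) == 4L, inherits(grid, "volume_grid"),
            all(dim(data)[1:3] == grid$shape))
  structure(list(data = data, grid = grid, tr_s = tr_s), class = "bold_run")
}

# bold_run -> volumes x voxels matrix, restricted to mask linear indices
.bold_matrix <- function(bold, mask_lin = NULL) {
  d <- dim(bold$data)
  m <- matrix(bold$data, nrow = prod(d[1:3]), ncol = d[4L])
  if (!is.null(mask_lin)) m <- m[mask_lin, , drop = FALSE]
  t(m)
}

#' Voxels within a millimetre sphere
#'
#' Returns the in-mask voxels whose center lies within Euclidean distance
#' `radius_mm` (boundary included) of `center_mm`. This is the searchlight
#' and ROI-sphere primitive: radius 4 mm on a 2 mm grid gives 33 voxels,
#' radius 8 mm gives 257.
#'
#' @param grid A [volume_grid()].
#' @param center_mm Numeric length-3 mm coordinates; must lie inside the grid.
#' @param radius_mm Sphere radius in mm (>= 0).
#' @param mask Optional logical array on the grid.
#' @return Integer n x 3 matrix of 0-based voxel indices, with attribute
#'   `"linear"` giving 1-based linear indices.
#' @export
sphere_voxels <- function(grid, center_mm, radius_mm, mask = NULL) {
  stopifnot(radius_mm >= 0)
  center_mm <- as.numeric(center_mm)
  cidx <- (center_mm - grid$origin) / grid$voxel_size
  if (any(cidx < -0.5) || any(cidx > grid$shape - 0.5))
    stop("sphere center lies outside the grid")
  lo <- pmax(0L, as.integer(ceiling(cidx - radius_mm / grid$voxel_size - 1e-9)))
  hi <- pmin(grid$shape - 1L, as.integer(floor(cidx + radius_mm / grid$voxel_size + 1e-9)))
  if (any(lo > hi)) {
    out <- matrix(integer(0), ncol = 3L, dimnames = list(NULL, c("i", "j", "k")))
    attr(out, "linear") <- integer(0)
    return(out)
  }
  cand <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3]))
  mm <- index_to_mm(grid, cand)
  d2 <- (mm[, 1] - center_mm[1])^2 + (mm[, 2] - center_mm[2])^2 + (mm[, 3] - center_mm[3])^2
  keep <- d2 <= radius_mm^2 + 1e-9
  cand <- cand[keep, , drop = FALSE]
  lin <- .vox_linear(cand, grid$shape)
  if (!is.null(mask)) {
    inm <- as.logical(mask)[lin]
    cand <- cand[inm, , drop = FALSE]
    lin <- lin[inm]
  }
  storage.mode(cand) <- "integer"
  attr(cand, "linear") <- as.integer(lin)
  cand
}

.neighbor_offsets <- function(connectivity = 18L) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  off <- as.matrix(expand.grid(i = -1:1, j = -1:1, k = -1:1))
  off <- off[rowSums(off != 0L) > 0L, , drop = FALSE]
  d <- rowSums(abs(off))
  if (connectivity == 6L) off[d == 1L, , drop = FALSE]
  else if (connectivity == 18L) off[d <= 2L, , drop = FALSE]
  else off
}

# Undirected adjacency edges among a voxel set: neighbor candidates from the
# half-offset set are matched against the sorted linear indices (no array
# allocation per offset; wrap-around is excluded by per-axis bounds checks).
.adjacency_edges <- function(index, lin, shape, connectivity = 18L) {
  offs <- .neighbor_offsets(connectivity)
  offs <- offs[offs[, 3L] > 0L | (offs[, 3L] == 0L & offs[, 2L] > 0L) |
               (offs[, 3L] == 0L & offs[, 2L] == 0L & offs[, 1L] > 0L), ,
               drop = FALSE]
  ord <- order(lin)
  lin_sorted <- lin[ord]
  i <- index[, 1L]; j <- index[, 2L]; k <- index[, 3L]
  from <- integer(0); to <- integer(0)
  for (o in seq_len(nrow(offs))) {
    di <- offs[o, 1L]; dj <- offs[o, 2L]; dk <- offs[o, 3L]
    ok <- i + di >= 0L & i + di < shape[1L] &
          j + dj >= 0L & j + dj < shape[2L] &
          k + dk >= 0L & k + dk < shape[3L]
    if (!any(ok)) next
    nl <- lin[ok] + di + shape[1L] * (dj + shape[2L] * dk)
    pos <- findInterval(nl, lin_sorted)
    hit <- pos > 0L & lin_sorted[pmax(pos, 1L)] == nl
    from <- c(from, which(ok)[hit])
    to <- c(to, ord[pos[hit]])
  }
  list(from = from, to = to)
}

# Connected-component labels for a set of voxels (0-based n x 3). Components
# are numbered in order of their smallest linear index.
.connected_components <- function(index, shape, connectivity = 18L) {
  n <- nrow(index)
  if (n == 0L) return(integer(0))
  lin <- .vox_linear(index, shape)
  e <- .adjacency_edges(index, lin, shape, connectivity)
  if (!length(e$from)) return(as.integer(rank(lin, ties.method = "first")))
  g <- igraph::make_graph(edges = as.vector(rbind(e$from, e$to)), n = n,
                          directed = FALSE)
  memb <- igraph::components(g)$membership
  comp_min <- tapply(lin, memb, min)
  rk <- rank(comp_min, ties.method = "first")
  as.integer(rk[match(memb, as.integer(names(comp_min)))])
}

# Max cluster size for many voxel sets at once (one graph over disjoint
# copies, a single igraph call): returns one max component size per set
# (0 for empty sets). Used by the permutation nulls.
.null_max_sizes <- function(supra_list, shape, connectivity = 18L) {
  n_sets <- length(supra_list)
  sizes <- vapply(supra_list, length, integer(1))
  out <- integer(n_sets)
  out[sizes == 1L] <- 1L
  todo <- which(sizes >= 2L)
  if (!length(todo)) return(out)
  # stack all sets into disjoint copies of the grid: linear indices offset by
  # set * prod(shape). In-bounds neighbor offsets can never cross copies, so
  # one adjacency pass and one components call cover every set.
  lin_all <- unlist(supra_list[todo])
  set_of_vertex <- rep.int(todo, sizes[todo])
  index <- .vox_unlinear(lin_all, shape)
  lin_off <- lin_all + (match(set_of_vertex, todo) - 1) * prod(shape)
  e <- .adjacency_edges(index, lin_off, shape, connectivity)
  n_all <- length(lin_all)
  if (!length(e$from)) {
    out[todo] <- 1L
    return(out)
  }
  g <- igraph::make_graph(edges = as.vector(rbind(e$from, e$to)), n = n_all,
                          directed = FALSE)
  comp <- igraph::components(g)
  comp_set <- set_of_vertex[match(seq_len(comp$no), comp$membership)]
  mx <- tapply(comp$csize, comp_set, max)
  out[as.integer(names(mx))] <- as.integer(mx)
  out
}

# Largest connected-component size among `lin` (1-based linear indices);
# sizes-only fast path for permutation loops.
.max_cluster_size <- function(lin, shape, connectivity = 18L) {
  n <- length(lin)
  if (n == 0L) return(0L)
  if (n == 1L) return(1L)
  index <- .vox_unlinear(lin, shape)
  e <- .adjacency_edges(index, lin, shape, connectivity)
  if (!length(e$from)) return(1L)
  g <- igraph::make_graph(edges = as.vector(rbind(e$from, e$to)), n = n,
                          directed = FALSE)
  as.integer(max(igraph::components(g)$csize))
}

#' Connected suprathreshold clusters
#'
#' Cluster-formation step for extent-based inference: voxels strictly above
#' `voxel_threshold` are grouped into connected components.
#'
#' @param stat_map A `volume_map` (or numeric 3D array with `grid`).
#' @param voxel_threshold Numeric scalar; voxels with value > threshold enter.
#' @param connectivity 6, 18 (default) or 26.
#' @param grid Grid, required when `stat_map` is a bare array.
#' @return List of clusters, each `list(voxels = <0-based n x 3>, size = n)`,
#'   ordered by size (desc) then smallest linear index.
#' @export
threshold_clusters <- function(stat_map, voxel_threshold, connectivity = 18L,
                               grid = NULL) {
  if (inherits(stat_map, "volume_map")) {
    vals <- stat_map$values; grid <- stat_map$grid; mask <- stat_map$mask
  } else {
    stopifnot(!is.null(grid))
    vals <- array(stat_map, dim = grid$shape); mask <- NULL
  }
  supra <- which(!is.na(vals) & vals > voxel_threshold)
  if (!is.null(mask)) supra <- supra[as.logical(mask)[supra]]
  if (!length(supra)) return(list())
  idx <- .vox_unlinear(supra, grid$shape)
  lab <- .connected_components(idx, grid$shape, connectivity)
  sizes <- tabulate(lab)
  seed_lin <- vapply(seq_along(sizes), function(l) min(supra[lab == l]), numeric(1))
  ord <- order(-sizes, seed_lin)
  lapply(ord, function(l) {
    rows <- which(lab == l)
    list(voxels = idx[rows, , drop = FALSE], size = sizes[l])
  })
}

#' Greedy peak selection with a minimum-distance rule
#'
#' Local maxima (>= all 26-neighbours) above `voxel_threshold` are visited in
#' descending statistic order; a candidate closer than `min_distance_mm`
#' (Euclidean, mm) to an already-selected peak is skipped. Equal statistics
#' are broken by smaller linear voxel index.
#'
#' @param stat_map A `volume_map`.
#' @param voxel_threshold Statistic threshold for candidacy.
#' @param min_distance_mm Minimum separation between reported peaks (mm).
#' @param connectivity Connectivity used for the cluster sizes reported
#'   alongside each peak.
#' @return A `data.frame` (class `peak_table`) with columns `label`, `x_mm`,
#'   `y_mm`, `z_mm`, `stat`, `cluster_voxels`, sorted by descending statistic.
#' @export
select_peaks <- function(stat_map, voxel_threshold, min_distance_mm = 16,
                         connectivity = 18L) {
  stopifnot(inherits(stat_map, "volume_map"), min_distance_mm >= 0)
  vals <- stat_map$values
  grid <- stat_map$grid
  mask <- if (is.null(stat_map$mask)) array(TRUE, grid$shape) else stat_map$mask
  cand_lin <- which(!is.na(vals) & vals > voxel_threshold & mask)
  empty <- data.frame(label = character(0), x_mm = numeric(0), y_mm = numeric(0),
                      z_mm = numeric(0), stat = numeric(0), cluster_voxels = integer(0))
  class(empty) <- c("peak_table", "data.frame")
  if (!length(cand_lin)) return(empty)
  offs <- .neighbor_offsets(26L)
  idx <- .vox_unlinear(cand_lin, grid$shape)
  is_max <- vapply(seq_along(cand_lin), function(r) {
    nb <- sweep(offs, 2L, as.integer(idx[r, ]), "+")
    nb <- nb[.in_grid(nb, grid$shape), , drop = FALSE]
    nl <- .vox_linear(nb, grid$shape)
    nl <- nl[mask[nl] & !is.na(vals[nl])]
    all(vals[cand_lin[r]] >= vals[nl])
  }, logical(1))
  cand_lin <- cand_lin[is_max]
  idx <- idx[is_max, , drop = FALSE]
  ord <- order(-vals[cand_lin], cand_lin)
  cand_lin <- cand_lin[ord]
  idx <- idx[ord, , drop = FALSE]
  mm <- index_to_mm(grid, idx)
  clusters <- threshold_clusters(stat_map, voxel_threshold, connectivity)
  clus_lab <- integer(prod(grid$shape))
  clus_size <- integer(length(clusters))
  for (ci in seq_along(clusters)) {
    clus_lab[.vox_linear(clusters[[ci]]$voxels, grid$shape)] <- ci
    clus_size[ci] <- clusters[[ci]]$size
  }
  sel <- integer(0)
  for (r in seq_along(cand_lin)) {
    if (length(sel)) {
      d <- sqrt(rowSums((mm[sel, , drop = FALSE] -
                         matrix(mm[r, ], length(sel), 3L, byrow = TRUE))^2))
      if (any(d < min_distance_mm)) next
    }
    sel <- c(sel, r)
  }
  out <- data.frame(
    label = paste0("peak_", seq_along(sel)),
    x_mm = mm[sel, 1], y_mm = mm[sel, 2], z_mm = mm[sel, 3],
    stat = vals[cand_lin[sel]],
    cluster_voxels = clus_size[clus_lab[cand_lin[sel]]]
  )
  class(out) <- c("peak_table", "data.frame")
  out
}

#' Write / read a peak or cluster table as TSV
#'
#' @param peaks A `peak_table` data frame.
#' @param path Output path.
#' @export
write_peaks <- function(peaks, path) {
  utils::write.table(peaks, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_peaks
#' @export
read_peaks <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("peak_table", "data.frame")
  out
}

#' Read / write BIDS-style event tables
#'
#' Tab-separated with columns `onset` (s), `duration` (s), `trial_type`.
#'
#' @param path File path.
#' @export
read_events <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(ev)))
    stop("events table must have columns onset, duration, trial_type")
  ev
}

#' @rdname read_events
#' @param events Events data frame.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write 6-column motion-parameter tables
#'
#' Whitespace-separated, no header: three translations (mm) then three
#' rotations (rad), one row per volume.
#'
#' @param path File path.
#' @export
read_motion <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) < 6L || !is.numeric(m)) stop("motion table must have 6 numeric columns")
  colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")[seq_len(ncol(m))]
  m[, 1:6, drop = FALSE]
}

#' @rdname read_motion
#' @param motion Numeric matrix with >= 6 columns.
#' @export
write_motion <- function(motion, path) {
  utils::write.table(motion, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
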