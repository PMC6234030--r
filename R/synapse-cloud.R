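## 3D synapse density mapping and density-based demarcation of
## glomerulus-like territories. Glomerular borders appear as local
## rarefactions in the synapse point cloud, so territories are recovered by
## smoothing a binned density map, thresholding, and connected components.

## Zero-padded separable convolution along the first array dimension.
conv1 <- function(a, kernel) {
  d <- dim(a)
  m <- matrix(a, nrow = d[1])
  kh <- (length(kernel) - 1L) / 2L
  n <- nrow(m)
  padded <- rbind(matrix(0, kh, ncol(m)), m, matrix(0, kh, ncol(m)))
  out <- matrix(0, n, ncol(m))
  for (i in seq_along(kernel)) {
    out <- out + kernel[i] * padded[i:(i + n - 1L), , drop = FALSE]
  }
  array(out, dim = d)
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

## Rotate array dimensions: dim order (1,2,3) -> (2,3,1).
rot_dims <- function(a) aperm(a, c(2, 3, 1))

#' Bin a synapse point cloud into a smoothed 3D density grid
#'
#' Points are histogrammed into cubic voxels of side `bin_size_nm` on a
#' half-open grid (`[origin + i*bin, origin + (i+1)*bin)`), then smoothed
#' with a separable Gaussian of standard deviation `smoothing_sigma_bins`
#' voxels. The grid is padded beyond the point extent by the kernel radius,
#' so the raw count sum equals the number of points inside the extent and
#' smoothing conserves total mass to numerical precision. The default origin
#' is the coordinate-wise minimum minus the padding, which makes the map
#' translation-equivariant: shifting all points (or points and an explicit
#' `origin` together) shifts the grid with them.
#'
#' @param points Numeric matrix `n x 3` of positions in nm.
#' @param bin_size_nm Voxel side in nm, default 1000 (1 um, i.e. 125 voxels
#'   of 8 nm imaging data per side).
#' @param smoothing_sigma_bins Gaussian sigma in voxels, default 2.
#' @param origin Optional explicit grid origin (nm, 3-vector); points below
#'   it are outside the grid.
#' @return Object of class `density_grid`: list with `origin`, `bin_size`,
#'   `dim`, `raw` (3D count array), `smoothed` (3D density array),
#'   `n_points`, `n_inside`.
#' @export
density_map <- function(points, bin_size_nm = 1000, smoothing_sigma_bins = 2,
                        origin = NULL) {
  points <- as.matrix(points)
  if (nrow(points) == 0) stop("empty point cloud")
  if (bin_size_nm <= 0) stop("bin_size_nm must be positive")
  if (smoothing_sigma_bins <= 0) stop("smoothing_sigma_bins must be positive")
  pad <- max(1L, ceiling(4 * smoothing_sigma_bins))
  if (is.null(origin)) {
    origin <- apply(points, 2, min) - pad * bin_size_nm
  }
  idx <- floor(sweep(points, 2, origin, "-") / bin_size_nm) + 1L
  hi <- apply(points, 2, max)
  dims <- as.integer(floor((hi - origin) / bin_size_nm) + 1L + pad)
  inside <- idx[, 1] >= 1 & idx[, 2] >= 1 & idx[, 3] >= 1 &
    idx[, 1] <= dims[1] & idx[, 2] <= dims[2] & idx[, 3] <= dims[3]
  idx_in <- idx[inside, , drop = FALSE]
  lin <- (idx_in[, 3] - 1L) * dims[1] * dims[2] +
    (idx_in[, 2] - 1L) * dims[1] + idx_in[, 1]
  raw <- array(tabulate(lin, nbins = prod(dims)), dim = dims)
  k <- gaussian_kernel(smoothing_sigma_bins)
  sm <- raw
  for (ax in 1:3) sm <- rot_dims(conv1(sm, k))
  structure(
    list(origin = as.numeric(origin), bin_size = bin_size_nm,
         dim = dims, raw = raw, smoothed = sm,
         n_points = nrow(points), n_inside = sum(inside)),
    class = "density_grid"
  )
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<density_grid> %d x %d x %d voxels of %.0f nm, %d/%d points binned\n",
              x$dim[1], x$dim[2], x$dim[3], x$bin_size, x$n_inside, x$n_points))
  invisible(x)
}

## 26-connected components over the foreground voxels of a 3D mask,
## via an igraph over forward neighbour offsets (13 of the 26, the rest are
## implied by symmetry).
label_components <- function(mask) {
  d <- dim(mask)
  fg <- which(mask)
  if (length(fg) == 0) return(array(0L, dim = d))
  comp_of <- integer(prod(d))
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  lin_off <- offsets[, 1] + offsets[, 2] * d[1] + offsets[, 3] * d[1] * d[2]
  forward <- offsets[lin_off > 0, , drop = FALSE]
  coords <- arrayInd(fg, d)
  edges_a <- integer(0)
  edges_b <- integer(0)
  in_fg <- logical(prod(d))
  in_fg[fg] <- TRUE
  for (r in seq_len(nrow(forward))) {
    nb <- sweep(coords, 2, forward[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
      nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb_lin <- (nb[ok, 3] - 1L) * d[1] * d[2] + (nb[ok, 2] - 1L) * d[1] + nb[ok, 1]
    both <- in_fg[nb_lin]
    edges_a <- c(edges_a, fg[ok][both])
    edges_b <- c(edges_b, nb_lin[both])
  }
  vid <- integer(prod(d))
  vid[fg] <- seq_along(fg)
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges_a) > 0) {
    g <- igraph::add_edges(g, rbind(vid[edges_a], vid[edges_b]))
  }
  comp <- igraph::components(g)$membership
  comp_of[fg] <- comp
  array(comp_of, dim = d)
}

#' Segment glomerulus-like territories from a density grid
#'
#' Voxels whose smoothed density exceeds a threshold are grouped into
#' 26-connected components; components holding fewer raw points than
#' `min_region_points` are merged into background. The default threshold is
#' the 60th percentile of the smoothed density over point-occupied voxels,
#' which places the cut inside the rarefied inter-glomerular gaps while
#' staying insensitive to how much empty padding surrounds the cloud. Labels
#' are assigned deterministically in descending order of region point count
#' (ties broken by smallest voxel index).
#'
#' @param grid A [density_map()] result.
#' @param threshold Absolute density threshold; overrides `quantile` when
#'   given.
#' @param quantile Quantile of occupied-voxel smoothed density used as
#'   threshold, default 0.6.
#' @param min_region_points Minimum raw points for a region to survive,
#'   default 10.
#' @return Object of class `region_labels`: list with `labels` (3D integer
#'   array, 0 = background), `summary` (`data.frame` of `label`, `n_voxels`,
#'   `n_points`, `centroid_x/y/z` in nm), `threshold`, plus grid metadata
#'   (`origin`, `bin_size`, `dim`). Zero regions triggers a warning.
#' @export
segment_regions <- function(grid, threshold = NULL, quantile = 0.6,
                            min_region_points = 10) {
  stopifnot(inherits(grid, "density_grid"))
  sm <- grid$smoothed
  if (is.null(threshold)) {
    ## quantile of the smoothed density where synapses actually sit
    ## (point-occupied voxels); quantiles over all nonzero smoothed voxels
    ## would be dominated by the near-zero smoothing halo and never cut the
    ## rarefied inter-glomerular gaps
    nz <- sm[grid$raw > 0]
    if (length(nz) == 0) {
      warning("density grid is empty; no regions")
      threshold <- Inf
    } else {
      threshold <- stats::quantile(nz, quantile, names = FALSE)
    }
  }
  mask <- sm > threshold
  labels <- label_components(mask)
  if (max(labels) == 0) {
    warning("no voxels above threshold; empty label set")
    return(structure(
      list(labels = labels,
           summary = data.frame(label = integer(), n_voxels = integer(),
                                n_points = numeric(), centroid_x = numeric(),
                                centroid_y = numeric(), centroid_z = numeric()),
           threshold = threshold, origin = grid$origin,
           bin_size = grid$bin_size, dim = grid$dim),
      class = "region_labels"
    ))
  }
  fg_idx <- which(labels > 0)
  comp_ids <- labels[fg_idx]
  pts_by <- tapply(grid$raw[fg_idx], comp_ids, sum)
  first_by <- tapply(fg_idx, comp_ids, min)
  n_comp <- max(labels)
  pts <- numeric(n_comp)
  first_vox <- rep(Inf, n_comp)
  pts[as.integer(names(pts_by))] <- pts_by
  first_vox[as.integer(names(first_by))] <- first_by
  keep <- which(pts >= min_region_points)
  if (length(keep) == 0) {
    warning("all regions below min_region_points; empty label set")
  }
  ## deterministic relabelling: descending point count, ties by first voxel
  keep <- keep[order(-pts[keep], first_vox[keep])]
  new_labels <- array(0L, dim = dim(labels))
  summaries <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    sel <- labels == keep[i]
    new_labels[sel] <- i
    vox <- arrayInd(which(sel), dim(labels))
    w <- grid$raw[sel]
    centroid <- if (sum(w) > 0) {
      colSums(vox * w) / sum(w)
    } else {
      colMeans(vox)
    }
    centroid_nm <- grid$origin + (centroid - 0.5) * grid$bin_size
    summaries[[i]] <- data.frame(
      label = i, n_voxels = sum(sel), n_points = sum(w),
      centroid_x = centroid_nm[1], centroid_y = centroid_nm[2],
      centroid_z = centroid_nm[3]
    )
  }
  summary <- if (length(summaries)) do.call(rbind, summaries) else
    data.frame(label = integer(), n_voxels = integer(), n_points = numeric(),
               centroid_x = numeric(), centroid_y = numeric(),
               centroid_z = numeric())
  structure(
    list(labels = new_labels, summary = summary, threshold = threshold,
         origin = grid$origin, bin_size = grid$bin_size, dim = grid$dim),
    class = "region_labels"
  )
}

#' @export
print.region_labels <- function(x, ...) {
  cat(sprintf("<region_labels> %d region(s), threshold %.4g\n",
              nrow(x$summary), x$threshold))
  invisible(x)
}

## Voxel label lookup for nm positions; 0 for background, NA outside grid.
lookup_labels <- function(points, labels) {
  points <- as.matrix(points)
  idx <- floor(sweep(points, 2, labels$origin, "-") / labels$bin_size) + 1L
  d <- labels$dim
  inside <- idx[, 1] >= 1 & idx[, 2] >= 1 & idx[, 3] >= 1 &
    idx[, 1] <= d[1] & idx[, 2] <= d[2] & idx[, 3] <= d[3]
  out <- rep(NA_integer_, nrow(points))
  lin <- (idx[inside, 3] - 1L) * d[1] * d[2] +
    (idx[inside, 2] - 1L) * d[1] + idx[inside, 1]
  out[inside] <- labels$labels[lin]
  out
}

#' Assign synapses to a segmented region of interest
#'
#' A synapse belongs to the ROI when its T-bar position falls in a voxel
#' carrying the target label. Accepts either a bare point matrix (returns a
#' logical membership vector) or a [glomerulus_dataset()] (returns the
#' dataset restricted to the T-bars inside the region, with their PSDs).
#' Points outside the grid extent are excluded with a warning.
#'
#' @param x Point matrix (`n x 3`, nm) or a [glomerulus_dataset()].
#' @param labels A [segment_regions()] result.
#' @param target_region Label id of the region of interest.
#' @return Logical vector (points) or filtered `glomerulus_dataset`.
#' @export
assign_to_roi <- function(x, labels, target_region) {
  stopifnot(inherits(labels, "region_labels"))
  if (!target_region %in% labels$summary$label) {
    stop("unknown region id: ", target_region)
  }
  if (inherits(x, "glomerulus_dataset")) {
    pts <- as.matrix(x$tbars[, c("x", "y", "z")])
    lab <- lookup_labels(pts, labels)
    if (anyNA(lab)) {
      warning(sum(is.na(lab)), " T-bar(s) outside grid extent; excluded")
    }
    keep <- !is.na(lab) & lab == target_region
    tbars <- x$tbars[keep, , drop = FALSE]
    psds <- x$psds[x$psds$tbar_id %in% tbars$tbar_id, , drop = FALSE]
    glomerulus_dataset(x$cells, tbars, psds, x$neuropile_volume_um3)
  } else {
    lab <- lookup_labels(x, labels)
    if (anyNA(lab)) {
      warning(sum(is.na(lab)), " point(s) outside grid extent; excluded")
    }
    !is.na(lab) & lab == target_region
  }
}
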