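#' Project full-sample SVM weights into voxel space
#'
#' Fits the linear SVM on all samples of a voxel feature matrix and places
#' each feature weight at its (i, j, k) voxel; all other voxels are zero.
#' Positive weights are associated with the positive class.
#'
#' @param features A `ran_features` of kind `"voxel"` (carries coordinates and
#'   grid dimensions).
#' @param labels Two-class label vector, one per row.
#' @param positive Positive class name.
#' @param config An [svm_config()].
#' @return 3D array of class `weight_map` with attributes `positive_class`
#'   and `b` (intercept).
#' @export
fit_weight_map <- function(features, labels, positive, config = svm_config()) {
  stopifnot(inherits(features, "ran_features"))
  if (features$kind != "voxel" || is.null(features$coords) ||
      is.null(features$grid_dim)) {
    stop("fit_weight_map needs a voxel feature matrix with coordinates")
  }
  fit <- svm_fit(features$values, labels, positive, config)
  dm <- features$grid_dim
  w <- array(0, dim = dm)
  lin <- features$coords[, 1] +
    dm[1] * ((features$coords[, 2] - 1) + dm[2] * (features$coords[, 3] - 1))
  w[lin] <- fit$w
  structure(w, class = "weight_map", positive_class = positive, b = fit$b)
}

#' Write a weight map to NIfTI
#' @param wmap A `weight_map`.
#' @param path Output path.
#' @export
write_weight_map <- function(wmap, path) {
  RNifti::writeNifti(RNifti::asNifti(array(wmap, dim = dim(wmap))), path)
  invisible(path)
}

#' Cluster threshold configuration
#'
#' @param min_extent Minimum cluster size in voxels (>= 1); default 50.
#' @param min_weight Minimum absolute voxel weight (>= 0); default 0.02.
#' @param connectivity Voxel adjacency: 6 (faces), 18 (faces + edges) or 26
#'   (faces + edges + corners, the default).
#' @param split_sign If `TRUE`, positive- and negative-weight voxels are
#'   clustered separately instead of on `|w|`.
#' @return A list of class `cluster_config`.
#' @export
cluster_config <- function(min_extent = 50, min_weight = 0.02,
                           connectivity = 26, split_sign = FALSE) {
  if (min_extent < 1) stop("min_extent must be >= 1")
  if (min_weight < 0) stop("min_weight must be >= 0")
  if (!connectivity %in% c(6, 18, 26)) stop("connectivity must be 6, 18 or 26")
  structure(list(min_extent = min_extent, min_weight = min_weight,
                 connectivity = connectivity, split_sign = split_sign),
            class = "cluster_config")
}

neighbor_offsets <- function(connectivity) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  ord <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord %in% 1:2, "26" = ord >= 1)
  g[keep, , drop = FALSE]
}

# connected components of a logical 3D mask via an adjacency graph
label_components <- function(mask, connectivity) {
  dm <- dim(mask)
  vox <- which(mask)
  if (length(vox) == 0) return(list(membership = integer(0), voxels = vox))
  coord <- arrayInd(vox, dm)
  id <- seq_along(vox)
  lut <- array(0L, dim = dm)
  lut[vox] <- id
  off <- neighbor_offsets(connectivity)
  half <- off[off$dx > 0 | (off$dx == 0 & off$dy > 0) |
                (off$dx == 0 & off$dy == 0 & off$dz > 0), , drop = FALSE]
  edges <- list()
  for (r in seq_len(nrow(half))) {
    ni <- coord[, 1] + half$dx[r]
    nj <- coord[, 2] + half$dy[r]
    nk <- coord[, 3] + half$dz[r]
    ok <- ni >= 1 & ni <= dm[1] & nj >= 1 & nj <= dm[2] & nk >= 1 & nk <= dm[3]
    if (!any(ok)) next
    nid <- lut[cbind(ni[ok], nj[ok], nk[ok])]
    hit <- nid > 0L
    if (any(hit)) edges[[length(edges) + 1L]] <- cbind(id[ok][hit], nid[hit])
  }
  g <- igraph::graph_from_edgelist(
    if (length(edges)) do.call(rbind, edges) else matrix(integer(0), ncol = 2),
    directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(vox) - igraph::vcount(g)))
  comp <- igraph::components(g)
  list(membership = comp$membership[seq_along(vox)], voxels = vox)
}

#' Extract suprathreshold clusters from a weight map
#'
#' Binarizes the map at `|w| >= min_weight` (or per sign if `split_sign`),
#' labels connected components under the configured adjacency, and keeps those
#' with at least `min_extent` voxels, sorted by size descending. Because
#' thresholding is on magnitude, a cluster may mix signs; the dominant sign is
#' reported per cluster.
#'
#' @param wmap A `weight_map` (or plain 3D array of signed weights).
#' @param config A [cluster_config()].
#' @return List of class `cluster_set`: `clusters` (each with `voxels`
#'   coordinate matrix, `size`, `mean_weight`, `peak_weight`, `peak_coord`,
#'   `dominant_sign`, `bounding_box`) and `table` (one row per cluster). An
#'   empty list is a valid result.
#' @export
threshold_clusters <- function(wmap, config = cluster_config()) {
  stopifnot(inherits(config, "cluster_config"))
  w <- array(as.numeric(wmap), dim = dim(wmap))
  masks <- if (config$split_sign) {
    list(w >= config$min_weight, w <= -config$min_weight)
  } else {
    list(abs(w) >= config$min_weight)
  }
  clusters <- list()
  for (mask in masks) {
    lc <- label_components(mask, config$connectivity)
    if (length(lc$voxels) == 0) next
    for (cid in unique(lc$membership)) {
      vox <- lc$voxels[lc$membership == cid]
      if (length(vox) < config$min_extent) next
      ww <- w[vox]
      coords <- arrayInd(vox, dim(w))
      colnames(coords) <- c("i", "j", "k")
      pk <- which.max(abs(ww))
      clusters[[length(clusters) + 1L]] <- list(
        voxels = coords, size = length(vox),
        mean_weight = mean(ww),
        peak_weight = ww[pk], peak_coord = coords[pk, ],
        dominant_sign = if (sum(ww > 0) >= sum(ww < 0)) 1L else -1L,
        bounding_box = apply(coords, 2, range))
    }
  }
  ord <- order(vapply(clusters, `[[`, integer(1), "size"), decreasing = TRUE)
  clusters <- clusters[ord]
  tab <- if (length(clusters) == 0) {
    data.frame(cluster = integer(0), size = integer(0), peak_weight = numeric(0),
               peak_i = integer(0), peak_j = integer(0), peak_k = integer(0),
               mean_weight = numeric(0), dominant_sign = integer(0))
  } else {
    data.frame(
      cluster = seq_along(clusters),
      size = vapply(clusters, `[[`, integer(1), "size"),
      peak_weight = vapply(clusters, `[[`, numeric(1), "peak_weight"),
      peak_i = vapply(clusters, function(cl) cl$peak_coord[["i"]], integer(1)),
      peak_j = vapply(clusters, function(cl) cl$peak_coord[["j"]], integer(1)),
      peak_k = vapply(clusters, function(cl) cl$peak_coord[["k"]], integer(1)),
      mean_weight = vapply(clusters, `[[`, numeric(1), "mean_weight"),
      dominant_sign = vapply(clusters, `[[`, integer(1), "dominant_sign"))
  }
  structure(list(clusters = clusters, table = tab, config = config),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("%d cluster(s) >= %d voxels at |w| >= %g (%d-connectivity)\n",
              length(x$clusters), x$config$min_extent, x$config$min_weight,
              x$config$connectivity))
  if (nrow(x$table)) print(x$table, row.names = FALSE)
  invisible(x)
}
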