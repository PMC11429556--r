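#' Parcellation constructor
#'
#' A parcellation is an integer label volume (0 = background, never part of
#' any region) plus a region table with one row per label: `label`, `name`,
#' `hemisphere` (`"L"`, `"R"` or `"midline"`) and `homolog_label` (the label of
#' the mirror-image region in the opposite hemisphere, or `NA` for midline
#' regions). Homolog links must be symmetric and cross hemispheres.
#'
#' @param labels 3D integer array of region labels.
#' @param regions Data frame with columns `label`, `name`, `hemisphere`,
#'   `homolog_label`.
#' @return An object of class `parcellation`.
#' @export
parcellation <- function(labels, regions) {
  stopifnot(length(dim(labels)) == 3)
  regions <- as.data.frame(regions, stringsAsFactors = FALSE)
  need <- c("label", "name", "hemisphere", "homolog_label")
  if (!all(need %in% names(regions))) {
    stop("region table needs columns: ", paste(need, collapse = ", "))
  }
  present <- setdiff(sort(unique(as.integer(labels))), 0L)
  missing <- setdiff(present, regions$label)
  if (length(missing) > 0) {
    stop("labels present in the volume but absent from the table: ",
         paste(missing, collapse = ", "))
  }
  regions$label <- as.integer(regions$label)
  regions$homolog_label <- as.integer(regions$homolog_label)
  hl <- regions$homolog_label
  for (r in seq_len(nrow(regions))) {
    if (is.na(hl[r])) next
    mate <- match(hl[r], regions$label)
    if (is.na(mate)) stop("homolog label not in table: ", hl[r])
    if (is.na(regions$homolog_label[mate]) ||
        regions$homolog_label[mate] != regions$label[r]) {
      stop("homolog link not symmetric for label ", regions$label[r])
    }
    if (regions$hemisphere[mate] == regions$hemisphere[r]) {
      stop("homolog pair in the same hemisphere: labels ",
           regions$label[r], ", ", hl[r])
    }
  }
  structure(list(labels = array(as.integer(labels), dim = dim(labels)),
                 regions = regions),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("Parcellation: %d regions on a %s grid (%d labeled voxels)\n",
              nrow(x$regions), paste(dim(x$labels), collapse = "x"),
              sum(x$labels != 0)))
  invisible(x)
}

#' Read a parcellation from a NIfTI label volume and a CSV region table
#'
#' @param nifti_path Integer-labeled NIfTI volume (0 = background).
#' @param csv_path CSV with columns `label,name,hemisphere,homolog_label`.
#' @return A `parcellation`.
#' @export
read_parcellation <- function(nifti_path, csv_path) {
  img <- RNifti::readNifti(nifti_path)
  regions <- read.csv(csv_path, stringsAsFactors = FALSE)
  parcellation(array(as.integer(round(img)), dim = dim(img)), regions)
}

#' Write a parcellation as NIfTI + CSV
#'
#' @param parc A `parcellation`.
#' @param nifti_path,csv_path Output paths.
#' @export
write_parcellation <- function(parc, nifti_path, csv_path) {
  RNifti::writeNifti(RNifti::asNifti(parc$labels), nifti_path)
  write.csv(parc$regions, csv_path, row.names = FALSE)
  invisible(parc)
}

#' Region-mean signal of a contrast map
#'
#' Arithmetic mean of the map over each region's voxels. Regions with no
#' voxels in the label volume get `NA` (never a silent zero) with a warning.
#'
#' @param map 3D array on the parcellation grid.
#' @param parc A `parcellation`.
#' @return Named numeric vector, names = region labels (as characters), in
#'   region-table order.
#' @export
region_means <- function(map, parc) {
  stopifnot(inherits(parc, "parcellation"))
  if (!identical(dim(map), dim(parc$labels))) {
    stop("map grid ", paste(dim(map), collapse = "x"),
         " does not match parcellation grid ",
         paste(dim(parc$labels), collapse = "x"))
  }
  lab <- as.vector(parc$labels)
  keep <- lab != 0L
  sums <- rowsum(as.vector(map)[keep], lab[keep])
  counts <- tabulate(lab[keep], nbins = max(parc$regions$label))
  out <- rep(NA_real_, nrow(parc$regions))
  names(out) <- as.character(parc$regions$label)
  have <- as.integer(rownames(sums))
  out[as.character(have)] <- sums[, 1] / counts[have]
  if (anyNA(out)) {
    warning("regions with zero voxels set to NA: ",
            paste(names(out)[is.na(out)], collapse = ", "))
  }
  out
}

sample_id <- function(subject, visit) paste(subject, visit, sep = "_")

check_maps_against_cohort <- function(maps, cohort) {
  ids <- sample_id(cohort$subject, cohort$visit)
  if (anyDuplicated(ids)) {
    stop("duplicate subject-visit rows in the cohort: ",
         paste(ids[duplicated(ids)], collapse = ", "))
  }
  absent <- setdiff(ids, names(maps))
  if (length(absent) > 0) {
    stop("no map for subject-visit: ", paste(absent, collapse = ", "))
  }
  ids
}

ran_features <- function(values, meta, kind, coords = NULL, grid_dim = NULL) {
  structure(list(values = values, meta = meta, kind = kind,
                 coords = coords, grid_dim = grid_dim),
            class = "ran_features")
}

#' @export
print.ran_features <- function(x, ...) {
  cat(sprintf("%s feature matrix: %d samples x %d features\n",
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Stack region-mean features across subject-visits
#'
#' One row per subject-visit in the cohort table, one column per region.
#' Rows are sorted by (subject, visit) so the result does not depend on the
#' order the maps are supplied in.
#'
#' @param maps Named list of 3D contrast maps; names are `subject_visit` ids.
#' @param parc A `parcellation`.
#' @param cohort Cohort data frame with `subject`, `group`, `visit` columns.
#' @return A `ran_features` object of kind `"region"`: `values` (matrix),
#'   `meta` (subject, visit, group per row).
#' @export
stack_region_features <- function(maps, parc, cohort) {
  ids <- check_maps_against_cohort(maps, cohort)
  ord <- order(cohort$subject, cohort$visit)
  cohort <- cohort[ord, , drop = FALSE]
  ids <- ids[ord]
  vals <- t(vapply(ids, function(id) region_means(maps[[id]], parc),
                   numeric(nrow(parc$regions))))
  rownames(vals) <- ids
  ran_features(vals,
               data.frame(sample = ids, subject = cohort$subject,
                          visit = cohort$visit, group = cohort$group,
                          stringsAsFactors = FALSE),
               kind = "region")
}

region_voxel_coords <- function(parc, region_set) {
  region_set <- unique(as.integer(region_set))
  unknown <- setdiff(region_set, parc$regions$label)
  if (length(unknown) > 0) {
    stop("regions not in the parcellation table: ", paste(unknown, collapse = ", "))
  }
  sel <- which(array(parc$labels %in% region_set, dim = dim(parc$labels)),
               arr.ind = TRUE)
  if (nrow(sel) == 0) stop("the requested regions contain no voxels")
  # fixed lexicographic (i, j, k) ordering so downstream weight maps are
  # reproducible bit-for-bit
  sel[order(sel[, 1], sel[, 2], sel[, 3]), , drop = FALSE]
}

#' Voxel features within a region set
#'
#' Columns are the union of the voxels of the listed regions (requesting a
#' region twice does not duplicate its voxels), ordered lexicographically by
#' (i, j, k); each column records its voxel coordinate.
#'
#' @inheritParams stack_region_features
#' @param region_set Integer vector of region labels.
#' @return A `ran_features` object of kind `"voxel"` carrying the voxel
#'   `coords` (n_features x 3) and the `grid_dim` of the source maps.
#' @export
voxel_features <- function(maps, parc, region_set, cohort) {
  if (length(region_set) == 0) stop("region_set must be nonempty")
  ids <- check_maps_against_cohort(maps, cohort)
  coords <- region_voxel_coords(parc, region_set)
  lin <- coords[, 1] +
    dim(parc$labels)[1] * ((coords[, 2] - 1) + dim(parc$labels)[2] * (coords[, 3] - 1))
  ord <- order(cohort$subject, cohort$visit)
  cohort <- cohort[ord, , drop = FALSE]
  ids <- ids[ord]
  vals <- t(vapply(ids, function(id) as.vector(maps[[id]])[lin],
                   numeric(length(lin))))
  rownames(vals) <- ids
  ran_features(vals,
               data.frame(sample = ids, subject = cohort$subject,
                          visit = cohort$visit, group = cohort$group,
                          stringsAsFactors = FALSE),
               kind = "voxel", coords = coords, grid_dim = dim(parc$labels))
}

#' Contralateral homolog of a region set
#'
#' Maps every region to its mirror-image region in the opposite hemisphere via
#' the parcellation's homolog links. Applying it twice returns the input.
#'
#' @param region_set Integer vector of region labels.
#' @param parc A `parcellation`.
#' @return Integer vector of homolog labels.
#' @export
contralateral_homolog <- function(region_set, parc) {
  region_set <- unique(as.integer(region_set))
  rows <- match(region_set, parc$regions$label)
  if (anyNA(rows)) {
    stop("regions not in the parcellation table: ",
         paste(region_set[is.na(rows)], collapse = ", "))
  }
  hl <- parc$regions$homolog_label[rows]
  if (anyNA(hl)) {
    stop("regions without a contralateral homolog: ",
         paste(region_set[is.na(hl)], collapse = ", "))
  }
  as.integer(hl)
}

#' Round-trip a feature matrix to CSV
#'
#' The CSV carries the sample metadata (subject, visit, group) as leading
#' columns; voxel coordinates, if present, are stored in a `#` header block.
#'
#' @param fm A `ran_features`.
#' @param path Output CSV path.
#' @export
write_features_csv <- function(fm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind: %s", fm$kind), con)
  if (!is.null(fm$grid_dim)) {
    writeLines(sprintf("# grid_dim: %s", paste(fm$grid_dim, collapse = " ")), con)
  }
  if (!is.null(fm$coords)) {
    writeLines(sprintf("# coords: %s",
                       paste(apply(fm$coords, 1, paste, collapse = ":"),
                             collapse = " ")), con)
  }
  df <- cbind(fm$meta, as.data.frame(fm$values, check.names = FALSE))
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @param path CSV written by [write_features_csv()].
#' @export
read_features_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kind <- sub("^# kind: ", "", grep("^# kind:", hdr, value = TRUE))
  grid_dim <- NULL
  gd <- grep("^# grid_dim:", hdr, value = TRUE)
  if (length(gd) == 1) {
    grid_dim <- as.integer(strsplit(sub("^# grid_dim: ", "", gd), " ")[[1]])
  }
  coords <- NULL
  cd <- grep("^# coords:", hdr, value = TRUE)
  if (length(cd) == 1) {
    triplets <- strsplit(sub("^# coords: ", "", cd), " ")[[1]]
    coords <- do.call(rbind, lapply(strsplit(triplets, ":"), as.integer))
    colnames(coords) <- c("dim1", "dim2", "dim3")
  }
  df <- read.csv(textConnection(lines[!grepl("^#", lines)]),
                 check.names = FALSE, stringsAsFactors = FALSE)
  meta <- df[, c("sample", "subject", "visit", "group")]
  vals <- as.matrix(df[, setdiff(names(df), names(meta)), drop = FALSE])
  rownames(vals) <- meta$sample
  ran_features(vals, meta, kind = kind, coords = coords, grid_dim = grid_dim)
}
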