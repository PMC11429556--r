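#' Build a RAN block-design timeline
#'
#' Models the acquisition schedule of a rapid automatized naming (RAN) run:
#' a lead-in rest, `n_cycles` repetitions of the condition cycle (each block
#' `block_s` seconds long), and a tail rest. With the defaults (10 s lead-in,
#' three cycles of NULL/COLOR/NUMBER/LETTER blocks of 20 s, 20 s tail, TR 2 s)
#' the run lasts 270 s and spans 135 volumes.
#'
#' @param lead_in_s Rest before the first block, seconds.
#' @param block_s Duration of every stimulus block, seconds.
#' @param cycle_order Character vector of condition names making up one cycle.
#' @param n_cycles Number of cycle repetitions.
#' @param tail_s Rest after the last block, seconds.
#' @param tr_s Repetition time (one volume), seconds.
#' @return An object of class `ran_timeline`: a list with the per-block
#'   schedule (`blocks`: condition, onset and offset in seconds), `total_s`,
#'   `n_volumes`, and `tr_s`. Block windows are half-open `[onset, offset)`.
#' @examples
#' tl <- build_timeline()
#' tl$total_s    # 270
#' tl$n_volumes  # 135
#' @export
build_timeline <- function(lead_in_s = 10, block_s = 20,
                           cycle_order = c("NULL", "COLOR", "NUMBER", "LETTER"),
                           n_cycles = 3, tail_s = 20, tr_s = 2) {
  stopifnot(length(cycle_order) >= 1, is.character(cycle_order))
  if (any(c(lead_in_s, block_s, tail_s, tr_s) <= 0) || n_cycles < 1) {
    stop("all durations and the cycle count must be positive")
  }
  total_s <- lead_in_s + n_cycles * length(cycle_order) * block_s + tail_s
  rem <- total_s %% tr_s
  if (rem > 1e-9) {
    stop(sprintf(
      "total duration %g s is not divisible by tr_s = %g s (remainder %g s)",
      total_s, tr_s, rem
    ))
  }
  onsets <- lead_in_s + block_s * seq(0, n_cycles * length(cycle_order) - 1)
  blocks <- data.frame(
    condition = rep(cycle_order, n_cycles),
    onset_s = onsets,
    offset_s = onsets + block_s,
    stringsAsFactors = FALSE
  )
  structure(
    list(blocks = blocks, total_s = total_s,
         n_volumes = as.integer(round(total_s / tr_s)), tr_s = tr_s,
         conditions = unique(cycle_order)),
    class = "ran_timeline"
  )
}

#' @export
print.ran_timeline <- function(x, ...) {
  cat(sprintf("RAN timeline: %d blocks (%s), %g s total, %d volumes at TR %g s\n",
              nrow(x$blocks), paste(x$conditions, collapse = "/"),
              x$total_s, x$n_volumes, x$tr_s))
  invisible(x)
}

#' Volume indices covered by a condition's blocks
#'
#' Returns the 0-based indices of the volumes acquired during each block of
#' `condition`, shifted forward by `hrf_shift_volumes` to account for
#' hemodynamic lag. Volume `i` covers time `[i * tr, (i + 1) * tr)`; a block
#' window is half-open, so a volume belongs to the block whose window contains
#' its acquisition onset. Shifted indices past the end of the run are dropped;
#' a shift larger than a block deliberately reaches into the following block
#' (no within-run clipping is applied).
#'
#' @param timeline A `ran_timeline`.
#' @param condition Condition name, one of `timeline$conditions`.
#' @param hrf_shift_volumes Non-negative integer shift, in volumes.
#' @return Sorted integer vector of 0-based volume indices.
#' @examples
#' tl <- build_timeline()
#' condition_volume_indices(tl, "COLOR", hrf_shift_volumes = 0)
#' @export
condition_volume_indices <- function(timeline, condition, hrf_shift_volumes = 2L) {
  stopifnot(inherits(timeline, "ran_timeline"))
  if (!condition %in% timeline$blocks$condition) {
    stop(sprintf("unknown condition '%s'; timeline has: %s", condition,
                 paste(timeline$conditions, collapse = ", ")))
  }
  if (hrf_shift_volumes < 0) stop("hrf_shift_volumes must be >= 0")
  tr <- timeline$tr_s
  rows <- timeline$blocks[timeline$blocks$condition == condition, , drop = FALSE]
  idx <- unlist(lapply(seq_len(nrow(rows)), function(r) {
    first <- ceiling(rows$onset_s[r] / tr - 1e-9)
    last <- ceiling(rows$offset_s[r] / tr - 1e-9) - 1L
    seq.int(first, last)
  }))
  idx <- sort(as.integer(idx)) + as.integer(hrf_shift_volumes)
  idx[idx <= timeline$n_volumes - 1L]
}

#' Voxel-wise temporal-average contrast between two conditions
#'
#' Computes, per voxel, the mean signal over the volumes of `cond_a` minus the
#' mean over the volumes of `cond_b` — the plain block-average Letter > Color
#' contrast by default, with no hemodynamic response convolution or GLM.
#'
#' @param series 4D numeric array (x, y, z, volume) or a path to a NIfTI file.
#' @param timeline A `ran_timeline` whose volume count matches the series.
#' @param cond_a,cond_b Condition names; the contrast is `mean(a) - mean(b)`.
#' @param hrf_shift_volumes Forward shift applied to both index sets.
#' @return 3D numeric array of the contrast, same spatial grid as the series.
#'   When `series` was read from NIfTI, its header is carried along so that
#'   [write_contrast_map()] preserves the affine.
#' @export
compute_contrast <- function(series, timeline, cond_a = "LETTER",
                             cond_b = "COLOR", hrf_shift_volumes = 2L) {
  hdr <- NULL
  if (is.character(series)) {
    series <- RNifti::readNifti(series)
    hdr <- series
  }
  dm <- dim(series)
  if (length(dm) != 4) stop("series must be a 4D array (x, y, z, volume)")
  if (dm[4] != timeline$n_volumes) {
    stop(sprintf("series has %d volumes but the timeline expects %d",
                 dm[4], timeline$n_volumes))
  }
  ia <- condition_volume_indices(timeline, cond_a, hrf_shift_volumes) + 1L
  ib <- condition_volume_indices(timeline, cond_b, hrf_shift_volumes) + 1L
  if (length(ia) == 0 || length(ib) == 0) {
    stop("a condition has no volumes left after shifting")
  }
  nvox <- prod(dm[1:3])
  m <- matrix(series, nrow = nvox, ncol = dm[4])
  out <- array(rowMeans(m[, ia, drop = FALSE]) - rowMeans(m[, ib, drop = FALSE]),
               dim = dm[1:3])
  if (!is.null(hdr)) attr(out, "nifti_header") <- RNifti::niftiHeader(hdr)
  out
}

#' Write a contrast map to NIfTI
#'
#' Propagates the header captured by [compute_contrast()] (if any) so the
#' affine of the source series is preserved.
#'
#' @param map 3D array, e.g. from [compute_contrast()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @export
write_contrast_map <- function(map, path) {
  hdr <- attr(map, "nifti_header")
  img <- if (is.null(hdr)) RNifti::asNifti(unclass(map)) else
    RNifti::asNifti(array(map, dim = dim(map)), reference = hdr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3D contrast map from NIfTI
#'
#' @param path NIfTI file with a single 3D volume.
#' @return 3D numeric array with the NIfTI header attached.
#' @export
read_contrast_map <- function(path) {
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) == 4 && dm[4] == 1) dim(img) <- dm[1:3]
  if (length(dim(img)) != 3) stop("expected a single 3D volume: ", path)
  out <- array(as.numeric(img), dim = dim(img))
  attr(out, "nifti_header") <- RNifti::niftiHeader(img)
  out
}
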