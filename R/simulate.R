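#' Synthetic cohort configuration
#'
#' Defines the study conditions the generator emulates: a two-group
#' (survivor/control) longitudinal design with nested attrition over three
#' annual visits, a group effect planted in a lateralized set of regions whose
#' magnitude grows across visits, and standardized reading scores linked to
#' the planted regional signal for three of the seven tests.
#'
#' Per subject-visit the contrast map is
#' `subject_effect[subject, region] + delta[visit] * sigma * planted + N(0, sigma^2)`
#' per voxel, where `planted` is the indicator of the planted regions and the
#' group shift applies to survivors only. The subject effect is a per-subject,
#' per-region offset (independent across regions, drawn once per subject and
#' held fixed across visits): stable individual differences in regional
#' responsiveness, the dominant between-subject noise in region-mean BOLD
#' contrasts. Scores follow
#' `100 + 15 * (rho * z + sqrt(1 - rho^2) * noise)` with `z` the standardized
#' planted-region mean of that subject-visit.
#'
#' @param dim Grid dimensions (default 32 x 32 x 32).
#' @param n_pairs Number of left/right homolog region pairs (default 15, i.e.
#'   30 regions).
#' @param region_size Region box size in voxels along (x, y, z); default
#'   c(4, 5, 6) = 120 voxels per region.
#' @param planted Labels of the regions carrying the group effect; default the
#'   four right-hemisphere occipital-role regions.
#' @param delta Named per-visit effect sizes in units of voxel noise SD
#'   (defaults 0, 0.4, 0.8 for TP1, TP2, TP3).
#' @param sigma Voxel noise SD.
#' @param subject_sd SD of the per-subject, per-region random offset (applied
#'   to every voxel of the region, constant across visits).
#' @param n_per_group Per-visit group sizes, nested (default 50, 36, 21).
#' @param rho Named per-test link strength between score and planted regional
#'   signal; defaults 0.5 for sound awareness, reading fluency and word attack,
#'   0 for the other four tests.
#' @param missing_frac Fraction of scores removed at random (default 0.05).
#' @param seed Master seed; all generator randomness flows from it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(dim = c(32, 32, 32), n_pairs = 15,
                         region_size = c(4, 5, 6),
                         planted = NULL,
                         delta = c(TP1 = 0, TP2 = 0.4, TP3 = 0.8),
                         sigma = 1, subject_sd = 0.6,
                         n_per_group = c(TP1 = 50, TP2 = 36, TP3 = 21),
                         rho = NULL, missing_frac = 0.05, seed = 1) {
  if (is.null(planted)) planted <- n_pairs + 1:4  # right-hemisphere labels
  if (is.null(rho)) {
    rho <- stats::setNames(rep(0, length(reading_tests)), reading_tests)
    rho[c("sound_awareness", "reading_fluency", "word_attack")] <- 0.5
  }
  if (any(diff(n_per_group) > 0)) stop("group sizes must be non-increasing (nested)")
  if (any(delta < 0)) stop("effect sizes must be >= 0")
  if (any(abs(rho) > 1)) stop("rho must lie in [-1, 1]")
  structure(list(dim = dim, n_pairs = n_pairs, region_size = region_size,
                 planted = planted, delta = delta, sigma = sigma,
                 subject_sd = subject_sd, n_per_group = n_per_group,
                 rho = rho, missing_frac = missing_frac, seed = seed),
            class = "synth_config")
}

synth_region_names <- function(n_pairs) {
  base <- c("superior occipital gyrus", "middle occipital gyrus",
            "inferior occipital gyrus", "occipital pole",
            "fusiform gyrus", "lingual gyrus", "cuneus", "calcarine cortex",
            "precuneus", "angular gyrus", "supramarginal gyrus",
            "superior parietal lobule", "inferior temporal gyrus",
            "middle temporal gyrus", "superior temporal gyrus")
  if (n_pairs <= length(base)) base[seq_len(n_pairs)]
  else c(base, sprintf("region %02d", seq_len(n_pairs - length(base))))
}

#' Generate a mirrored synthetic parcellation
#'
#' Tiles `n_pairs` rectangular regions into the left half of the grid and
#' mirrors them into the right half, producing symmetric homolog pairs. Left
#' regions get labels 1..n_pairs, their right homologs n_pairs+1..2*n_pairs.
#' The first four pairs play the occipital roles (superior/middle/inferior
#' occipital gyrus and occipital pole).
#'
#' @param config A [synth_config()].
#' @return A `parcellation`.
#' @export
generate_parcellation <- function(config = synth_config()) {
  dm <- config$dim; rs <- config$region_size; np <- config$n_pairs
  half <- dm[1] %/% 2
  # lay boxes on a y-z lattice inside the left hemisphere
  ny <- max(1, (dm[2] - 2) %/% (rs[2] + 1))
  nz <- ceiling(np / ny)
  if (rs[1] + 1 > half || 1 + nz * (rs[3] + 1) > dm[3] + 1) {
    stop("grid too small for the requested regions")
  }
  labels <- array(0L, dim = dm)
  for (r in seq_len(np)) {
    cy <- (r - 1) %% ny
    cz <- (r - 1) %/% ny
    xs <- 2:(1 + rs[1])
    ys <- (2 + cy * (rs[2] + 1)):(1 + cy * (rs[2] + 1) + rs[2])
    zs <- (2 + cz * (rs[3] + 1)):(1 + cz * (rs[3] + 1) + rs[3])
    if (max(ys) > dm[2] || max(zs) > dm[3]) stop("grid too small for the requested regions")
    labels[xs, ys, zs] <- r
    labels[dm[1] + 1L - xs, ys, zs] <- r + np  # mirror into the right hemisphere
  }
  nm <- synth_region_names(np)
  regions <- data.frame(
    label = c(seq_len(np), np + seq_len(np)),
    name = c(paste("left", nm), paste("right", nm)),
    hemisphere = rep(c("L", "R"), each = np),
    homolog_label = c(np + seq_len(np), seq_len(np)),
    stringsAsFactors = FALSE
  )
  parcellation(labels, regions)
}

#' Generate a synthetic two-group longitudinal cohort with contrast maps
#'
#' Enrolls `n_per_group[1]` survivors and controls, applies nested attrition
#' by dropping the last-enrolled subjects at later visits, and draws one
#' Letter > Color contrast map per subject-visit: a per-subject, per-region
#' random offset (drawn once per subject, fixed across visits), plus the
#' visit's planted effect (survivors only, planted regions only), plus i.i.d.
#' voxel noise. Reading scores are then filled in by [generate_scores()].
#'
#' @param config A [synth_config()].
#' @param parc Optional pre-built `parcellation` (defaults to
#'   [generate_parcellation()] of the same config).
#' @return List of class `synth_cohort`: `cohort` (table with scores), `maps`
#'   (named list of 3D arrays), `parcellation`, `signals` (planted-region mean
#'   per sample), `config`.
#' @export
generate_cohort <- function(config = synth_config(), parc = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(parc)) parc <- generate_parcellation(config)
  set.seed(config$seed)
  n0 <- config$n_per_group[1]
  subjects <- list(survivor = sprintf("MB%02d", seq_len(n0)),
                   control = sprintf("HC%02d", seq_len(n0)))
  all_subjects <- unlist(subjects)
  n_regions <- nrow(parc$regions)
  subject_effect <- matrix(
    rnorm(length(all_subjects) * n_regions, 0, config$subject_sd * config$sigma),
    nrow = length(all_subjects), ncol = n_regions,
    dimnames = list(all_subjects, NULL))
  lab_vec <- as.vector(parc$labels)
  labeled <- which(lab_vec != 0L)
  region_idx <- match(lab_vec[labeled], parc$regions$label)
  planted_mask <- array(parc$labels %in% config$planted, dim = config$dim)
  rows <- list(); maps <- list()
  for (v in seq_along(visit_levels)) {
    nv <- config$n_per_group[v]
    for (grp in c("survivor", "control")) {
      for (s in subjects[[grp]][seq_len(nv)]) {   # nested: first-enrolled stay
        id <- sample_id(s, visit_levels[v])
        shift <- if (grp == "survivor") config$delta[[v]] * config$sigma else 0
        m <- array(rnorm(prod(config$dim), 0, config$sigma), dim = config$dim)
        m[labeled] <- m[labeled] + subject_effect[s, region_idx]
        if (shift != 0) m[planted_mask] <- m[planted_mask] + shift
        maps[[id]] <- m
        rows[[id]] <- data.frame(subject = s, group = grp,
                                 visit = visit_levels[v],
                                 stringsAsFactors = FALSE)
      }
    }
  }
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  validate_cohort(cohort)
  signals <- vapply(sample_id(cohort$subject, cohort$visit),
                    function(id) mean(maps[[id]][planted_mask]), numeric(1))
  out <- structure(list(cohort = cohort, maps = maps, parcellation = parc,
                        signals = signals, config = config),
                   class = "synth_cohort")
  out$cohort <- generate_scores(config, out)
  out
}

#' Fill in linked standardized reading scores
#'
#' Scores follow `100 + 15 * (rho * z + sqrt(1 - rho^2) * eps)` where `z` is
#' the planted-region mean signal of the subject-visit, standardized within
#' its group (all visits pooled), and `eps` is standard normal. Tests with
#' `rho = 0` are pure noise. A `missing_frac` fraction of scores is removed at
#' random. Uses the RNG state as left by [generate_cohort()], so the whole
#' generation is reproducible from the master seed.
#'
#' @param config A [synth_config()].
#' @param synth A `synth_cohort` (needs `cohort` and `signals`).
#' @return The cohort table with the seven score columns filled in.
#' @export
generate_scores <- function(config, synth) {
  cohort <- synth$cohort[c("subject", "group", "visit")]
  z <- synth$signals
  for (grp in unique(cohort$group)) {
    g <- cohort$group == grp
    z[g] <- (z[g] - mean(z[g])) / sd(z[g])
  }
  n <- nrow(cohort)
  for (test in reading_tests) {
    rho <- config$rho[[test]]
    eps <- rnorm(n)
    score <- 100 + 15 * (rho * z + sqrt(1 - rho^2) * eps)
    if (config$missing_frac > 0) {
      score[runif(n) < config$missing_frac] <- NA_real_
    }
    cohort[[test]] <- score
  }
  cohort
}

#' Synthesize a block-design 4D series that realizes a given contrast map
#'
#' Optional end-to-end mode: emits a full BOLD series on the timeline where
#' LETTER blocks carry, per voxel, an amplitude equal to the target contrast
#' map (COLOR and the other conditions stay at baseline), plus i.i.d. noise.
#' With `noise_sd = 0`, [compute_contrast()] with the same shift recovers the
#' map exactly.
#'
#' @param target_map 3D array: the Letter > Color contrast to plant.
#' @param timeline A `ran_timeline`.
#' @param noise_sd SD of the additive volume noise.
#' @param baseline Constant baseline signal.
#' @param hrf_shift_volumes Shift at which the amplitude is planted (match the
#'   analysis shift to recover the map).
#' @return 4D array (x, y, z, volume).
#' @export
simulate_bold_series <- function(target_map, timeline, noise_sd = 0,
                                 baseline = 100, hrf_shift_volumes = 2L) {
  dm <- dim(target_map)
  n_vol <- timeline$n_volumes
  series <- array(baseline + rnorm(prod(dm) * n_vol, 0, noise_sd),
                  dim = c(dm, n_vol))
  letter <- condition_volume_indices(timeline, "LETTER", hrf_shift_volumes) + 1L
  for (t in letter) series[, , , t] <- series[, , , t] + target_map
  series
}

#' Write a synthetic cohort to disk
#'
#' Emits one NIfTI contrast map per subject-visit, the parcellation
#' (NIfTI + CSV), the cohort CSV, and a YAML manifest recording the
#' configuration and master seed.
#'
#' @param synth A `synth_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synth_cohort <- function(synth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "maps"), showWarnings = FALSE)
  for (id in names(synth$maps)) {
    RNifti::writeNifti(RNifti::asNifti(synth$maps[[id]]),
                       file.path(dir, "maps", paste0(id, ".nii.gz")))
  }
  write_parcellation(synth$parcellation,
                     file.path(dir, "parcellation.nii.gz"),
                     file.path(dir, "regions.csv"))
  write.csv(synth$cohort, file.path(dir, "cohort.csv"), row.names = FALSE)
  cfg <- synth$config
  cfg$delta <- as.list(cfg$delta); cfg$rho <- as.list(cfg$rho)
  cfg$n_per_group <- as.list(cfg$n_per_group)
  yaml::write_yaml(unclass(cfg), file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a synthetic cohort written by [write_synth_cohort()]
#' @param dir Directory containing `maps/`, `parcellation.nii.gz`,
#'   `regions.csv` and `cohort.csv`.
#' @return A list with `cohort`, `maps` and `parcellation`.
#' @export
read_synth_cohort <- function(dir) {
  cohort <- read_cohort(file.path(dir, "cohort.csv"))
  parc <- read_parcellation(file.path(dir, "parcellation.nii.gz"),
                            file.path(dir, "regions.csv"))
  files <- list.files(file.path(dir, "maps"), pattern = "\\.nii", full.names = TRUE)
  maps <- lapply(files, read_contrast_map)
  names(maps) <- sub("\\.nii(\\.gz)?$", "", basename(files))
  list(cohort = cohort, maps = maps, parcellation = parc)
}
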