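#' The seven standardized reading tests
#'
#' Column names used for the Woodcock-Johnson-style standardized reading
#' scores (population mean 100, SD 15) in a cohort table.
#' @export
reading_tests <- c("letter_word_identification", "reading_fluency",
                   "passage_comprehension", "word_attack",
                   "spelling_of_sounds", "sound_awareness",
                   "reading_vocabulary")

visit_levels <- c("TP1", "TP2", "TP3")

#' Validate a cohort table
#'
#' Checks the schema (subject, group in survivor/control, visit in
#' TP1/TP2/TP3, optional reading-score columns) and the nested-attrition
#' invariant: every subject present at a visit must have been present at all
#' earlier visits. Violations are hard errors.
#'
#' @param cohort Data frame.
#' @return The cohort, invisibly, with `visit` ordered.
#' @export
validate_cohort <- function(cohort) {
  need <- c("subject", "group", "visit")
  if (!all(need %in% names(cohort))) {
    stop("cohort needs columns: ", paste(need, collapse = ", "))
  }
  if (!all(cohort$group %in% c("survivor", "control"))) {
    stop("group must be 'survivor' or 'control'")
  }
  if (!all(cohort$visit %in% visit_levels)) {
    stop("visit must be one of ", paste(visit_levels, collapse = ", "))
  }
  if (anyDuplicated(paste(cohort$subject, cohort$visit))) {
    stop("duplicate subject-visit rows")
  }
  by_visit <- split(cohort$subject, factor(cohort$visit, levels = visit_levels))
  for (v in 2:3) {
    extra <- setdiff(by_visit[[v]], by_visit[[v - 1]])
    if (length(extra) > 0) {
      stop("visit nesting violated: present at ", visit_levels[v],
           " but not ", visit_levels[v - 1], ": ",
           paste(extra, collapse = ", "))
    }
  }
  invisible(cohort)
}

#' Read/write a cohort table
#' @param path CSV path with the [validate_cohort()] schema.
#' @export
read_cohort <- function(path) {
  cohort <- read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(cohort)
  cohort
}

#' Per-subject cluster-mean contrast, split by group
#'
#' Averages each subject's contrast map over the cluster's voxels at one
#' visit and splits the resulting scalars by group — the quantity compared
#' between survivors and controls per visit. The contralateral analysis is
#' this same function called with the homolog regions' voxels.
#'
#' @param maps Named list of 3D contrast maps (`subject_visit` ids).
#' @param cluster_voxels Voxel coordinate matrix (n x 3), e.g. a cluster's
#'   `voxels` from [threshold_clusters()] or [region_voxel_set()].
#' @param cohort Cohort table.
#' @param visit Visit id, e.g. `"TP3"`.
#' @return List with `survivor` and `control` numeric vectors (named by
#'   subject).
#' @export
cluster_mean_by_group <- function(maps, cluster_voxels, cohort, visit) {
  rows <- cohort[cohort$visit == visit, , drop = FALSE]
  if (nrow(rows) == 0) stop("no cohort rows at visit ", visit)
  ids <- sample_id(rows$subject, rows$visit)
  absent <- setdiff(ids, names(maps))
  if (length(absent) > 0) stop("no map for: ", paste(absent, collapse = ", "))
  cluster_voxels <- as.matrix(cluster_voxels)
  vals <- vapply(ids, function(id) mean(maps[[id]][cluster_voxels]), numeric(1))
  names(vals) <- rows$subject
  split(vals, rows$group)[c("survivor", "control")]
}

#' Voxel coordinates of a region set
#'
#' Convenience wrapper returning the (i, j, k) coordinates of all voxels in
#' the listed regions, in the package's fixed lexicographic order.
#'
#' @param parc A `parcellation`.
#' @param region_set Integer region labels.
#' @return Matrix (n x 3).
#' @export
region_voxel_set <- function(parc, region_set) {
  region_voxel_coords(parc, region_set)
}

#' Two-sided group difference test
#'
#' Welch's two-sample t-test by default (`var_equal = TRUE` gives the pooled
#' variance test). When both groups have zero variance and equal means, p = 1.
#'
#' @param values_a,values_b Numeric vectors (>= 2 each).
#' @param var_equal Assume equal variances.
#' @return Two-sided p-value.
#' @export
group_difference_test <- function(values_a, values_b, var_equal = FALSE) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop("each group needs at least 2 values")
  }
  if (var(values_a) == 0 && var(values_b) == 0) {
    return(if (mean(values_a) == mean(values_b)) 1 else 0)
  }
  t.test(values_a, values_b, var.equal = var_equal,
         alternative = "two.sided")$p.value
}

#' Group comparison of cluster-mean contrast across visits
#'
#' Runs [cluster_mean_by_group()] and [group_difference_test()] at every
#' visit present in the cohort.
#'
#' @inheritParams cluster_mean_by_group
#' @param var_equal Passed to [group_difference_test()].
#' @return Data frame: visit, per-group n, mean, sd, and the two-sided p.
#' @export
compare_groups_by_visit <- function(maps, cluster_voxels, cohort,
                                    var_equal = FALSE) {
  visits <- intersect(visit_levels, unique(cohort$visit))
  do.call(rbind, lapply(visits, function(v) {
    g <- cluster_mean_by_group(maps, cluster_voxels, cohort, v)
    data.frame(visit = v,
               n_survivor = length(g$survivor), n_control = length(g$control),
               mean_survivor = mean(g$survivor), mean_control = mean(g$control),
               sd_survivor = sd(g$survivor), sd_control = sd(g$control),
               p_value = group_difference_test(g$survivor, g$control,
                                               var_equal = var_equal))
  }))
}

#' Stratify patient visits into high and low performers
#'
#' Within the survivor group, pooling all visits, labels each subject-visit
#' with a non-missing score on `test` as `"high"` (score >= cutoff) or
#' `"low"`. A score of exactly 100 is a high performer under the default
#' cutoff. Visits with a missing score are dropped for that test.
#'
#' @param cohort Cohort table with reading-score columns.
#' @param test One of [reading_tests].
#' @param cutoff Standardized-scale cutoff (default 100).
#' @return Data frame: sample, subject, visit, score, label; attribute
#'   `sizes` holds the (high, low) counts. Empty (with a warning) if every
#'   score is missing.
#' @export
stratify_performers <- function(cohort, test, cutoff = 100) {
  if (!test %in% reading_tests) {
    stop("unknown test '", test, "'; expected one of: ",
         paste(reading_tests, collapse = ", "))
  }
  if (!test %in% names(cohort)) stop("cohort has no column '", test, "'")
  rows <- cohort[cohort$group == "survivor", , drop = FALSE]
  score <- rows[[test]]
  keep <- !is.na(score)
  if (!any(keep)) {
    warning("all scores missing for test '", test, "'")
    return(structure(data.frame(sample = character(0), subject = character(0),
                                visit = character(0), score = numeric(0),
                                label = character(0)),
                     sizes = c(high = 0L, low = 0L)))
  }
  rows <- rows[keep, , drop = FALSE]; score <- score[keep]
  label <- ifelse(score >= cutoff, "high", "low")
  structure(data.frame(sample = sample_id(rows$subject, rows$visit),
                       subject = rows$subject, visit = rows$visit,
                       score = score, label = label,
                       stringsAsFactors = FALSE),
            sizes = c(high = sum(label == "high"), low = sum(label == "low")))
}

#' High- vs low-performer classification on one reading test
#'
#' Leave-one-sample-out SVM classification of survivor visits (all visits
#' pooled; each subject-visit is one sample) into high and low performers on
#' `test`, using the supplied voxel features — by convention the voxels of
#' the regions selected in the survivor-vs-control analysis. Reports the usual
#' metrics and, optionally, the Monte Carlo permutation p.
#'
#' @param features A `ran_features` of kind `"voxel"` covering the survivor
#'   visits (extra samples are ignored; missing ones are an error).
#' @param cohort Cohort table with scores.
#' @param test One of [reading_tests].
#' @param config An [svm_config()].
#' @param cutoff Performer cutoff.
#' @param B Permutation count; 0 skips the permutation test.
#' @param seed Seed for the shuffles.
#' @return A `cv_result` with fields `test`, `sizes`, and (if `B > 0`)
#'   `permutation`.
#' @export
performer_classification <- function(features, cohort, test,
                                     config = svm_config(), cutoff = 100,
                                     B = 1000, seed = 1) {
  strat <- stratify_performers(cohort, test, cutoff)
  if (length(unique(strat$label)) < 2) {
    stop("only one performer class present for test '", test, "'")
  }
  idx <- match(strat$sample, features$meta$sample)
  if (anyNA(idx)) {
    stop("no features for survivor visits: ",
         paste(strat$sample[is.na(idx)], collapse = ", "))
  }
  x <- features$values[idx, , drop = FALSE]
  labels <- factor(strat$label, levels = c("high", "low"))
  res <- loo_cv(x, labels, positive = "high", config)
  res$test <- test
  res$sizes <- attr(strat, "sizes")
  if (B > 0) {
    res$permutation <- permutation_pvalue(x, labels, "high", config,
                                          B = B, seed = seed)
  }
  res
}
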