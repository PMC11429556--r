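#' Full-analysis run configuration
#'
#' Bundles every stage's settings with the study's canonical defaults:
#' linear SVM with C = 1, 1000 label shuffles, Fisher threshold grid
#' 0.16-0.26 in steps of 0.02 with any-visit survival, performer cutoff 100,
#' and weight-map cluster thresholds of 50 voxels at |w| >= 0.02.
#'
#' @param selection A [selection_config()].
#' @param svm An [svm_config()].
#' @param clusters A [cluster_config()].
#' @param B Permutation shuffles per classification analysis.
#' @param cutoff Performer score cutoff.
#' @param seed Seed from which all per-analysis shuffle seeds are derived.
#' @param out_dir Optional directory for CSV/NIfTI outputs.
#' @return A list of class `run_config`.
#' @export
run_config <- function(selection = selection_config(), svm = svm_config(),
                       clusters = cluster_config(), B = 1000, cutoff = 100,
                       seed = 1, out_dir = NULL) {
  structure(list(selection = selection, svm = svm, clusters = clusters,
                 B = B, cutoff = cutoff, seed = seed, out_dir = out_dir),
            class = "run_config")
}

cv_row <- function(res, label) {
  m <- res$metrics
  data.frame(analysis = label,
             n_pos = m$n_pos, n_neg = m$n_neg,
             accuracy = m$accuracy, sensitivity = m$sensitivity,
             specificity = m$specificity,
             balanced_accuracy = m$balanced_accuracy,
             k = if (is.null(res$permutation)) NA_integer_ else res$permutation$k,
             B = if (is.null(res$permutation)) NA_integer_ else res$permutation$B,
             p = if (is.null(res$permutation)) NA_real_ else res$permutation$p,
             stringsAsFactors = FALSE)
}

#' Run the full longitudinal MVPA analysis
#'
#' Executes the complete pipeline on a set of per-subject-visit Letter > Color
#' contrast maps: region-mean features, per-visit Fisher scores, threshold
#' sweep with LOO-accuracy optimization, per-visit survivor-vs-control LOO SVM
#' with permutation inference, full-sample weight maps with cluster-extent
#' thresholding, cluster-mean group statistics for the selected region set and
#' its contralateral homolog, and the seven high/low performer classifications
#' within survivors.
#'
#' @param maps Named list of 3D contrast maps (`subject_visit` ids), e.g. a
#'   `synth_cohort`'s `maps` or maps read from NIfTI.
#' @param parc A `parcellation`.
#' @param cohort Cohort table (validated).
#' @param config A [run_config()].
#' @return List of class `ran_report`: `selection` (threshold sweep),
#'   `scores_by_visit`, `svc` (per-visit classification table),
#'   `weight_clusters` (per-visit `cluster_set`s), `group_stats` (per-visit
#'   Welch tests, selected cluster and contralateral homolog), `performers`
#'   (per-test table), `config`.
#' @export
run_full_analysis <- function(maps, parc, cohort, config = run_config()) {
  validate_cohort(cohort)
  visits <- intersect(visit_levels, unique(cohort$visit))

  # region-mean features and per-visit Fisher scores
  region_fm <- stack_region_features(maps, parc, cohort)
  scores_by_visit <- lapply(visits, function(v) {
    sel <- region_fm$meta$visit == v
    score_regions(region_fm$values[sel, , drop = FALSE],
                  region_fm$meta$group[sel])
  })
  names(scores_by_visit) <- visits

  # threshold sweep: mean LOO accuracy across visits per surviving set
  evaluate <- function(region_set) {
    vf <- voxel_features(maps, parc, region_set, cohort)
    vapply(visits, function(v) {
      sel <- vf$meta$visit == v
      loo_cv(vf$values[sel, , drop = FALSE], vf$meta$group[sel],
             positive = "survivor", config$svm)$metrics$accuracy
    }, numeric(1))
  }
  selection <- sweep_thresholds(scores_by_visit, evaluate, config$selection)
  chosen <- selection$chosen_regions

  vf <- voxel_features(maps, parc, chosen, cohort)

  # per-visit survivor-vs-control classification with permutation inference
  svc_rows <- list(); weight_clusters <- list()
  for (v in visits) {
    sel <- vf$meta$visit == v
    xv <- vf$values[sel, , drop = FALSE]
    yv <- vf$meta$group[sel]
    res <- loo_cv(xv, yv, positive = "survivor", config$svm)
    if (config$B > 0) {
      res$permutation <- permutation_pvalue(
        xv, yv, "survivor", config$svm, B = config$B,
        seed = config$seed + match(v, visit_levels))
    }
    svc_rows[[v]] <- cv_row(res, v)
    vfv <- ran_features(xv, vf$meta[sel, , drop = FALSE], "voxel",
                        coords = vf$coords, grid_dim = vf$grid_dim)
    wm <- fit_weight_map(vfv, yv, positive = "survivor", config$svm)
    weight_clusters[[v]] <- threshold_clusters(wm, config$clusters)
  }
  svc <- do.call(rbind, svc_rows)
  rownames(svc) <- NULL

  # cluster-mean group statistics: selected regions and contralateral homolog
  sel_vox <- region_voxel_set(parc, chosen)
  stats_sel <- cbind(side = "selected",
                     compare_groups_by_visit(maps, sel_vox, cohort))
  homolog <- contralateral_homolog(chosen, parc)
  hom_vox <- region_voxel_set(parc, homolog)
  stats_hom <- cbind(side = "contralateral",
                     compare_groups_by_visit(maps, hom_vox, cohort))
  group_stats <- rbind(stats_sel, stats_hom)

  # high/low performer classification per reading test (survivor visits)
  surv <- cohort[cohort$group == "survivor", , drop = FALSE]
  vf_surv <- voxel_features(maps[sample_id(surv$subject, surv$visit)],
                            parc, chosen, surv)
  perf_rows <- lapply(seq_along(reading_tests), function(t) {
    res <- performer_classification(vf_surv, cohort, reading_tests[t],
                                    config$svm, cutoff = config$cutoff,
                                    B = config$B,
                                    seed = config$seed + 10 + t)
    cv_row(res, reading_tests[t])
  })
  performers <- do.call(rbind, perf_rows)
  rownames(performers) <- NULL

  report <- structure(
    list(selection = selection, scores_by_visit = scores_by_visit,
         svc = svc, weight_clusters = weight_clusters,
         group_stats = group_stats, performers = performers,
         chosen_regions = chosen, config = config),
    class = "ran_report")
  if (!is.null(config$out_dir)) write_report(report, vf, config$out_dir)
  report
}

write_report <- function(report, vf, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$selection$table, file.path(out_dir, "threshold_sweep.csv"),
            row.names = FALSE)
  scores <- do.call(rbind, lapply(names(report$scores_by_visit), function(v) {
    s <- report$scores_by_visit[[v]]
    data.frame(visit = v, region = names(s), score = unname(s),
               selected = names(s) %in% as.character(report$chosen_regions))
  }))
  write.csv(scores, file.path(out_dir, "fisher_scores.csv"), row.names = FALSE)
  write.csv(report$svc, file.path(out_dir, "group_classification.csv"),
            row.names = FALSE)
  write.csv(report$group_stats, file.path(out_dir, "cluster_group_stats.csv"),
            row.names = FALSE)
  write.csv(report$performers, file.path(out_dir, "performer_classification.csv"),
            row.names = FALSE)
  for (v in names(report$weight_clusters)) {
    write.csv(report$weight_clusters[[v]]$table,
              file.path(out_dir, sprintf("weight_clusters_%s.csv", v)),
              row.names = FALSE)
  }
  invisible(out_dir)
}

#' @export
print.ran_report <- function(x, ...) {
  cat("== Fisher threshold sweep ==\n"); print(x$selection)
  cat("\n== Survivor vs control (LOO SVM) ==\n")
  print(x$svc, row.names = FALSE)
  cat("\n== Cluster-mean group statistics ==\n")
  print(x$group_stats, row.names = FALSE)
  cat("\n== Performer classification ==\n")
  print(x$performers, row.names = FALSE)
  invisible(x)
}
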