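# Independent brute-force oracles and tiny fixtures. Oracles are written as
# plain loops over first principles and never call the package functions they
# check.

# ---- fixtures ----------------------------------------------------------

# hand-built 8x8x8 parcellation: three left/right homolog pairs of small boxes
tiny_parcellation <- function() {
  labels <- array(0L, dim = c(8, 8, 8))
  boxes <- list(list(x = 2:3, y = 2:3, z = 2:3),
                list(x = 2:3, y = 5:6, z = 2:4),
                list(x = 1:3, y = 2:4, z = 6:7))
  for (r in seq_along(boxes)) {
    b <- boxes[[r]]
    labels[b$x, b$y, b$z] <- r
    labels[9L - b$x, b$y, b$z] <- r + 3L
  }
  parcellation(labels, data.frame(
    label = 1:6,
    name = c(paste("left box", 1:3), paste("right box", 1:3)),
    hemisphere = rep(c("L", "R"), each = 3),
    homolog_label = c(4:6, 1:3)))
}

tiny_cohort <- function(n_subj = 4) {
  expand.grid(subject = sprintf("S%02d", seq_len(n_subj)),
              visit = "TP1", stringsAsFactors = FALSE)[, 1:2] |>
    transform(group = rep(c("survivor", "control"), length.out = n_subj))
}

tiny_maps <- function(cohort, dims = c(8, 8, 8), seed = 1) {
  set.seed(seed)
  ids <- paste(cohort$subject, cohort$visit, sep = "_")
  maps <- lapply(ids, function(id) array(rnorm(prod(dims)), dim = dims))
  names(maps) <- ids
  maps
}

# small synthetic config for pipeline-level tests: fewer/smaller subjects
fast_synth_config <- function(seed = 1, ...) {
  synth_config(n_per_group = c(TP1 = 14, TP2 = 10, TP3 = 8), seed = seed, ...)
}

# ---- oracles -----------------------------------------------------------

# region means by explicit voxel loop
oracle_region_means <- function(map, parc) {
  labs <- parc$regions$label
  sums <- stats::setNames(rep(0, length(labs)), as.character(labs))
  counts <- sums
  dm <- dim(map)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    l <- parc$labels[i, j, k]
    if (l != 0L) {
      key <- as.character(l)
      sums[key] <- sums[key] + map[i, j, k]
      counts[key] <- counts[key] + 1
    }
  }
  ifelse(counts > 0, sums / counts, NA_real_)
}

# two-class Fisher criterion recomputed from its definition
oracle_fisher <- function(a, b) {
  (mean(a) - mean(b))^2 / (var(a) + var(b))
}

# connected components by explicit flood fill
oracle_components <- function(mask, connectivity) {
  dm <- dim(mask)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  ord <- rowSums(abs(off))
  off <- off[switch(as.character(connectivity),
                    "6" = ord == 1, "18" = ord %in% 1:2, "26" = ord >= 1), ,
             drop = FALSE]
  comp <- array(0L, dim = dm)
  next_id <- 0L
  for (start in which(mask)) {
    if (comp[start] != 0L) next
    next_id <- next_id + 1L
    queue <- list(arrayInd(start, dm)[1, ])
    comp[start] <- next_id
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      for (r in seq_len(nrow(off))) {
        nb <- v + off[r, ]
        if (any(nb < 1) || any(nb > dm)) next
        if (mask[nb[1], nb[2], nb[3]] && comp[nb[1], nb[2], nb[3]] == 0L) {
          comp[nb[1], nb[2], nb[3]] <- next_id
          queue[[length(queue) + 1]] <- nb
        }
      }
    }
  }
  comp
}

# LOO predictions via e1071 (libsvm), the independent SVM implementation
oracle_loo_e1071 <- function(x, labels, positive) {
  labels <- as.character(labels)
  vapply(seq_len(nrow(x)), function(i) {
    fit <- e1071::svm(x[-i, , drop = FALSE],
                      factor(labels[-i], levels = c(positive,
                                                    setdiff(unique(labels), positive))),
                      kernel = "linear", cost = 1, scale = FALSE)
    as.character(predict(fit, x[i, , drop = FALSE]))
  }, character(1))
}
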