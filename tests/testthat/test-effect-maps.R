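make_voxel_features <- function(x, coords, grid_dim, groups) {
  ranmvpa:::ran_features(
    x,
    data.frame(sample = rownames(x),
               subject = rownames(x), visit = "TP1", group = groups),
    kind = "voxel", coords = coords, grid_dim = grid_dim)
}

test_that("weight maps place signed weights at their voxel coordinates", {
  set.seed(20)
  dm <- c(6, 6, 6)
  coords <- as.matrix(expand.grid(1:3, 1:3, 1))[1:5, ]
  colnames(coords) <- c("i", "j", "k")
  n <- 30
  x <- matrix(rnorm(n * 5, sd = 0.5), n, 5,
              dimnames = list(sprintf("S%02d_TP1", 1:n), NULL))
  groups <- rep(c("survivor", "control"), each = n / 2)
  x[groups == "survivor", 3] <- x[groups == "survivor", 3] + 3  # informative voxel
  vf <- make_voxel_features(x, coords, dm, groups)
  wm <- fit_weight_map(vf, groups, positive = "survivor")
  expect_equal(dim(wm), dm)
  # zero outside the feature voxels
  nz <- which(wm != 0, arr.ind = TRUE)
  expect_true(all(apply(nz, 1, function(v)
    any(apply(coords, 1, function(cc) all(cc == v))))))
  # the informative voxel carries the largest magnitude, positively signed
  expect_equal(which.max(abs(wm[coords])), 3L)
  expect_gt(wm[coords][3], 0)
  # flipping the class labels negates the map
  flipped <- ifelse(groups == "survivor", "control", "survivor")
  wm2 <- fit_weight_map(vf, flipped, positive = "survivor")
  expect_equal(as.vector(wm2), -as.vector(wm), tolerance = 1e-3)
})

test_that("the informative voxel dominates the weight map across seeds", {
  dm <- c(4, 4, 4)
  coords <- cbind(i = 1:4, j = 1, k = 1)
  wins <- 0
  for (s in 1:50) {
    set.seed(100 + s)
    n <- 24
    x <- matrix(rnorm(n * 4), n, 4,
                dimnames = list(sprintf("S%02d_TP1", 1:n), NULL))
    groups <- rep(c("survivor", "control"), each = n / 2)
    x[groups == "survivor", 2] <- x[groups == "survivor", 2] + 2.5
    vf <- make_voxel_features(x, coords, dm, groups)
    wm <- fit_weight_map(vf, groups, positive = "survivor")
    if (which.max(abs(wm[coords])) == 2L) wins <- wins + 1
  }
  expect_gte(wins, 45)
})

test_that("weight maps are invariant to feature column order", {
  set.seed(21)
  dm <- c(4, 4, 4)
  coords <- cbind(i = c(1, 2, 3), j = c(1, 1, 2), k = 1)
  x <- matrix(rnorm(20 * 3), 20, 3,
              dimnames = list(sprintf("S%02d_TP1", 1:20), NULL))
  groups <- rep(c("survivor", "control"), 10)
  x[groups == "survivor", ] <- x[groups == "survivor", ] + 1
  perm <- c(3, 1, 2)
  wm1 <- fit_weight_map(make_voxel_features(x, coords, dm, groups),
                        groups, "survivor")
  wm2 <- fit_weight_map(make_voxel_features(x[, perm], coords[perm, ], dm, groups),
                        groups, "survivor")
  expect_equal(as.vector(wm1), as.vector(wm2), tolerance = 1e-3)
})

test_that("cluster thresholding keeps only large suprathreshold components", {
  w <- array(0, dim = c(12, 12, 12))
  # a 60-voxel block and a separate 40-voxel block, both above threshold
  w[1:5, 1:4, 1:3] <- 0.05            # 60 voxels
  w[8:11, 8:11, 8:11][1:40] <- 0.05   # 40 voxels within a 4x4x4 corner
  cs <- threshold_clusters(w, cluster_config(min_extent = 50, min_weight = 0.02))
  expect_equal(length(cs$clusters), 1L)
  expect_equal(cs$clusters[[1]]$size, 60L)
  # everything below the magnitude threshold -> empty result
  expect_equal(length(threshold_clusters(array(0.019, dim = c(6, 6, 6)),
                                         cluster_config())$clusters), 0L)
  # two 30-voxel blocks touching face-to-face merge under any connectivity
  for (conn in c(6, 18, 26)) {
    w2 <- array(0, dim = c(10, 10, 10))
    w2[1:5, 1:3, 1:2] <- 0.1
    w2[6:10, 1:3, 1:2] <- -0.1   # negative side, same magnitude
    cs2 <- threshold_clusters(w2, cluster_config(min_extent = 50,
                                                 min_weight = 0.02,
                                                 connectivity = conn))
    expect_equal(length(cs2$clusters), 1L)
    expect_equal(cs2$clusters[[1]]$size, 60L)
  }
})

test_that("connected components agree with the flood-fill oracle", {
  set.seed(22)
  for (conn in c(6, 18, 26)) {
    for (rep in 1:4) {
      w <- array(runif(10 * 9 * 8) < 0.25, dim = c(10, 9, 8)) * 0.5
      cs <- threshold_clusters(w, cluster_config(min_extent = 1,
                                                 min_weight = 0.02,
                                                 connectivity = conn))
      comp <- oracle_components(w >= 0.02, conn)
      sizes_oracle <- sort(as.integer(table(comp[comp > 0])), decreasing = TRUE)
      sizes_pkg <- vapply(cs$clusters, `[[`, integer(1), "size")
      expect_equal(sizes_pkg, sizes_oracle, info = paste("conn", conn))
      # each reported cluster is one oracle component exactly
      for (cl in cs$clusters) {
        ids <- unique(comp[cl$voxels])
        expect_length(ids, 1)
        expect_equal(cl$size, sum(comp == ids))
      }
    }
  }
})

test_that("raising either threshold never grows the surviving voxel count", {
  set.seed(23)
  w <- array(rnorm(12^3, sd = 0.03), dim = c(12, 12, 12))
  total <- function(cs) sum(vapply(cs$clusters, `[[`, integer(1), "size"),
                            na.rm = TRUE)
  base <- threshold_clusters(w, cluster_config(min_extent = 5, min_weight = 0.02))
  expect_lte(total(threshold_clusters(w, cluster_config(min_extent = 10,
                                                        min_weight = 0.02))),
             total(base))
  expect_lte(total(threshold_clusters(w, cluster_config(min_extent = 5,
                                                        min_weight = 0.04))),
             total(base))
})

test_that("magnitude clustering can mix signs; sign-split mode separates them", {
  w <- array(0, dim = c(8, 8, 8))
  w[1:4, 1:2, 1] <- 0.5
  w[5:8, 1:2, 1] <- -0.5
  mixed <- threshold_clusters(w, cluster_config(min_extent = 4, min_weight = 0.1))
  expect_equal(length(mixed$clusters), 1L)
  expect_equal(mixed$clusters[[1]]$size, 16L)
  split <- threshold_clusters(w, cluster_config(min_extent = 4, min_weight = 0.1,
                                                split_sign = TRUE))
  expect_equal(length(split$clusters), 2L)
  expect_setequal(vapply(split$clusters, `[[`, integer(1), "dominant_sign"),
                  c(1L, -1L))
})
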