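test_that("region means agree with the voxel-loop oracle", {
  parc <- tiny_parcellation()
  set.seed(1)
  map <- array(rnorm(prod(dim(parc$labels))), dim = dim(parc$labels))
  expect_equal(region_means(map, parc), oracle_region_means(map, parc),
               tolerance = 1e-12)
  # constant map -> every region mean is that constant
  expect_equal(unname(region_means(array(2.5, dim = c(8, 8, 8)), parc)),
               rep(2.5, 6))
  # map equal to the label id at each voxel -> mean = own label
  expect_equal(unname(region_means(array(as.numeric(parc$labels),
                                         dim = dim(parc$labels)), parc)),
               as.numeric(1:6))
  expect_error(region_means(array(0, dim = c(4, 4, 4)), parc), "grid")
})

test_that("empty regions are missing, never silent zeros", {
  labels <- array(0L, dim = c(4, 4, 4))
  labels[1:2, 1, 1] <- 1L
  parc <- parcellation(labels, data.frame(
    label = 1:2, name = c("a", "b"), hemisphere = c("L", "R"),
    homolog_label = c(2, 1)))
  expect_warning(rm <- region_means(array(1, dim = c(4, 4, 4)), parc),
                 "zero voxels")
  expect_equal(unname(rm), c(1, NA))
})

test_that("parcellation validation enforces table coverage and homolog symmetry", {
  labels <- array(0L, dim = c(4, 4, 4)); labels[1, 1, 1] <- 7L
  expect_error(parcellation(labels, data.frame(
    label = 1, name = "a", hemisphere = "L", homolog_label = NA)),
    "absent from the table")
  expect_error(parcellation(array(0L, dim = c(4, 4, 4)), data.frame(
    label = 1:2, name = c("a", "b"), hemisphere = c("L", "R"),
    homolog_label = c(2, NA))), "not symmetric")
  expect_error(parcellation(array(0L, dim = c(4, 4, 4)), data.frame(
    label = 1:2, name = c("a", "b"), hemisphere = c("L", "L"),
    homolog_label = c(2, 1))), "same hemisphere")
})

test_that("feature stacking is order-invariant and checks the roster", {
  parc <- tiny_parcellation()
  cohort <- tiny_cohort(4)
  maps <- tiny_maps(cohort)
  fm <- stack_region_features(maps, parc, cohort)
  expect_equal(dim(fm$values), c(4L, 6L))
  # shuffled map and roster order produce the identical matrix
  perm <- c(3, 1, 4, 2)
  fm2 <- stack_region_features(maps[perm], parc, cohort[perm, ])
  expect_identical(fm$values, fm2$values)
  expect_identical(fm$meta, fm2$meta)
  expect_error(stack_region_features(maps[-1], parc, cohort), "S01_TP1")
  dup <- rbind(cohort, cohort[1, ])
  expect_error(stack_region_features(maps, parc, dup), "duplicate")
})

test_that("voxel features cover the requested union without duplication", {
  parc <- tiny_parcellation()
  cohort <- tiny_cohort(4)
  maps <- tiny_maps(cohort)
  n1 <- sum(parc$labels == 1)
  vf1 <- voxel_features(maps, parc, 1, cohort)
  expect_equal(ncol(vf1$values), n1)
  vf12 <- voxel_features(maps, parc, c(1, 2), cohort)
  expect_equal(ncol(vf12$values), n1 + sum(parc$labels == 2))
  # asking for the same region twice keeps set semantics
  expect_equal(ncol(voxel_features(maps, parc, c(1, 1, 2), cohort)$values),
               ncol(vf12$values))
  # values are the map values at the recorded coordinates
  id <- vf1$meta$sample[2]
  expect_equal(unname(vf1$values[2, ]), maps[[id]][vf1$coords])
  expect_error(voxel_features(maps, parc, integer(0), cohort), "nonempty")
})

test_that("per-region averaging of voxel features reproduces region features", {
  parc <- tiny_parcellation()
  cohort <- tiny_cohort(6)
  maps <- tiny_maps(cohort, seed = 2)
  rf <- stack_region_features(maps, parc, cohort)
  vf <- voxel_features(maps, parc, parc$regions$label, cohort)
  vox_labels <- parc$labels[vf$coords]
  recon <- t(apply(vf$values, 1, function(row) tapply(row, vox_labels, mean)))
  expect_equal(unname(recon[, as.character(parc$regions$label)]),
               unname(rf$values), tolerance = 1e-12)
})

test_that("contralateral homolog mapping is an involution", {
  parc <- tiny_parcellation()
  expect_equal(contralateral_homolog(c(4, 5, 6), parc), c(1, 2, 3))
  expect_equal(contralateral_homolog(contralateral_homolog(c(2, 3), parc), parc),
               c(2, 3))
  expect_error(contralateral_homolog(99, parc), "not in the parcellation")
  # midline regions without a homolog are rejected by name
  labels <- array(0L, dim = c(4, 4, 4)); labels[2, 2, 2] <- 1L
  parc_mid <- parcellation(labels, data.frame(
    label = 1, name = "mid", hemisphere = "midline", homolog_label = NA))
  expect_error(contralateral_homolog(1, parc_mid), "without a contralateral")
})

test_that("parcellation and feature matrices round-trip through disk", {
  parc <- tiny_parcellation()
  fn <- tempfile(fileext = ".nii.gz"); fc <- tempfile(fileext = ".csv")
  write_parcellation(parc, fn, fc)
  back <- read_parcellation(fn, fc)
  expect_equal(back$labels, parc$labels)
  expect_equal(back$regions$homolog_label, parc$regions$homolog_label)

  cohort <- tiny_cohort(3)
  maps <- tiny_maps(cohort, seed = 3)
  vf <- voxel_features(maps, parc, c(2, 5), cohort)
  f <- tempfile(fileext = ".csv")
  write_features_csv(vf, f)
  vf2 <- read_features_csv(f)
  expect_equal(unname(vf2$values), unname(vf$values), tolerance = 1e-12)
  expect_equal(vf2$meta$sample, vf$meta$sample)
  expect_equal(unname(as.matrix(vf2$coords)), unname(as.matrix(vf$coords)))
  expect_equal(vf2$grid_dim, dim(parc$labels))
})
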