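# Sample/table validation, cropping arithmetic, z-projection, splits, and
# annotation/volume round-trips.

test_that("sample and table constructors enforce invariants", {
  v <- array(0.5, c(2, 4, 8, 8))
  s <- volume_sample("c1", "p1", v, labels = c("membrane", "vesicles"),
                     grades = c(membrane = 3L, vesicles = 1L))
  expect_identical(s$grades, c(membrane = 3L, vesicles = 1L))
  expect_error(volume_sample("c1", "p1", v, labels = "membrane",
                             grades = c(membrane = 4L)), "\\{1,2,3\\}")
  expect_error(volume_sample("c1", "p1", v, labels = "membrane",
                             grades = c(vesicles = 2L)), "named")
  expect_error(volume_sample("c1", "p1", array(0, c(3, 4, 8, 8)),
                             labels = "membrane",
                             grades = c(membrane = 1L)), "2, z, y, x")
  expect_error(volume_sample("c1", "p1", -v, labels = "membrane",
                             grades = c(membrane = 1L)), "non-negative")
  expect_error(dataset_table(list(volume_sample("c", "p"))), "labels")
})

test_that("cropping centers, pads, and conserves intensity", {
  vol <- point_volume(z = 6, y = 16, x = 16, at = c(3, 8, 8))
  # interior crop with crop_xy == out_xy returns the exact sub-array
  cs <- crop_single_cells(vol, list(c(3, 8, 8)), crop_xy = 8, out_xy = 8,
                          protein_id = "p", labels = "membrane",
                          grades = c(membrane = 3L))
  expect_length(cs, 1)
  expect_equal(dim(cs[[1]]$volume), c(2, 6, 8, 8))
  expect_identical(cs[[1]]$volume, vol[, , 5:12, 5:12, drop = FALSE],
                   ignore_attr = TRUE)
  expect_equal(sum(cs[[1]]$volume[2, , , ]), sum(vol[2, , 5:12, 5:12]))
  # corner center: three of four quadrants are zero padding
  vol2 <- array(1, c(2, 3, 8, 8))
  cc <- crop_single_cells(vol2, list(c(0, 0, 0)), crop_xy = 4, out_xy = 4)
  cv <- cc[[1]]$volume
  expect_true(all(cv[, , 1:2, ] == 0))
  expect_true(all(cv[, , , 1:2] == 0))
  expect_true(all(cv[, , 3:4, 3:4] == 1))
  # resize path produces the requested plane size and keeps z
  cr <- crop_single_cells(vol2, list(c(1, 4, 4)), crop_xy = 6, out_xy = 12)
  expect_equal(dim(cr[[1]]$volume), c(2, 3, 12, 12))
  # out-of-bounds center names itself
  expect_error(crop_single_cells(vol2, list(c(0, 99, 0)), crop_xy = 4),
               "99")
  expect_identical(crop_single_cells(vol2, list(), crop_xy = 4), list())
})

test_that("z-projection takes the per-pixel max (or mean) over z", {
  v <- array(0, c(3, 2, 2))
  v[, 1, 1] <- c(1, 5, 3)
  expect_equal(project_z(v)[1, 1], 5)
  expect_equal(project_z(v, "mean")[1, 1], 3)
  # a single bright voxel projects to exactly its (y, x) position
  v2 <- array(0, c(4, 5, 6))
  v2[2, 3, 4] <- 7
  p <- project_z(v2)
  expect_equal(p[3, 4], 7)
  expect_equal(sum(p), 7)
  # constant volume projects to the constant
  expect_true(all(project_z(array(2.5, c(3, 4, 4))) == 2.5))
  # max projection commutes with monotone rescaling
  set.seed(2)
  v3 <- array(runif(60), c(3, 4, 5))
  f <- function(x) x^2 + 1
  expect_equal(project_z(f(v3)), f(project_z(v3)), tolerance = 1e-12)
  expect_error(project_z(matrix(0, 2, 2)), "3D")
})

test_that("protein-level splits match fractions and never leak proteins", {
  samples <- lapply(seq_len(100), function(i) {
    volume_sample(sprintf("c%03d", i), sprintf("p%03d", i),
                  labels = "membrane", grades = c(membrane = 3L))
  })
  tab <- dataset_table(samples)
  sp <- split_by_protein(tab, c(0.70, 0.15, 0.15), seed = 1)
  expect_equal(as.integer(table(sp$assignment)[c("train", "val", "test")]),
               c(70L, 15L, 15L))
  # determinism and seed sensitivity
  expect_identical(sp$assignment,
                   split_by_protein(tab, seed = 1)$assignment)
  expect_false(identical(sp$assignment,
                         split_by_protein(tab, seed = 2)$assignment))
  # cells inherit their protein's split
  tab2 <- apply_split(tab, sp)
  for (s in tab2$samples[1:5]) {
    expect_identical(s$split, unname(sp$assignment[s$protein_id]))
  }
  # degenerate fraction vectors
  all_train <- split_by_protein(tab, c(1, 0, 0), seed = 3)
  expect_true(all(all_train$assignment == "train"))
  small <- dataset_table(samples[1:2])
  expect_error(split_by_protein(small, c(0.7, 0.15, 0.15), seed = 1),
               "at least 3")
  expect_error(split_by_protein(tab, c(0.6, 0.3, 0.2), seed = 1), "sum to 1")
})

test_that("annotation CSV round-trips and rejects malformed rows", {
  sim <- tiny_dataset()
  d <- withr::local_tempdir()
  path <- file.path(d, "ann.csv")
  write_annotations(sim$table, path)
  back <- read_annotations(path)
  expect_identical(as_tibble(back), as_tibble(sim$table))
  # the documented parse contract
  writeLines(c("cell_id,protein_id,volume_path,labels,grades",
               "c1,p1,v.tif,membrane|vesicles,3|1"),
             file.path(d, "one.csv"))
  one <- read_annotations(file.path(d, "one.csv"))
  expect_setequal(one$samples[[1]]$labels, c("membrane", "vesicles"))
  expect_identical(one$samples[[1]]$grades,
                   c(membrane = 3L, vesicles = 1L))
  # grade out of range and ragged labels/grades are rejected
  writeLines(c("cell_id,protein_id,volume_path,labels,grades",
               "c1,p1,v.tif,membrane,4"), file.path(d, "bad.csv"))
  expect_error(read_annotations(file.path(d, "bad.csv")), "\\{1,2,3\\}")
  writeLines(c("cell_id,protein_id,volume_path,labels,grades",
               "c1,p1,v.tif,membrane|er,3"), file.path(d, "ragged.csv"))
  expect_error(read_annotations(file.path(d, "ragged.csv")), "lengths")
})

test_that("volumes round-trip through rds and TIFF stacks", {
  set.seed(8)
  v <- array(runif(2 * 3 * 6 * 6), c(2, 3, 6, 6))
  d <- withr::local_tempdir()
  write_volume(v, file.path(d, "v.rds"))
  expect_equal(read_volume(file.path(d, "v.rds")), v)
  # channel-last arrays are autodetected
  saveRDS(aperm(v, c(2, 3, 4, 1)), file.path(d, "cl.rds"))
  expect_equal(read_volume(file.path(d, "cl.rds")), v)
  write_volume(v, file.path(d, "v.tif"))
  expect_equal(read_volume(file.path(d, "v.tif")), v, tolerance = 1e-6)
})
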