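test_that("local-mean thresholding matches the double-loop oracle exactly", {
  set.seed(11)
  for (w in c(5L, 17L, 41L)) {
    m <- matrix(runif(64 * 64, 0, 100), 64, 64)
    expect_identical(local_mean_threshold(m, w), m > oracle_local_mean(m, w))
  }
  # non-square image with window cropped asymmetrically
  m <- matrix(runif(48 * 80, 0, 10), 48, 80)
  expect_identical(local_mean_threshold(m, 41L),
                   m > oracle_local_mean(m, 41L))
  # constant image: no pixel strictly exceeds its local mean
  expect_false(any(local_mean_threshold(matrix(3.7, 50, 50), 41L)))
  # a single bright pixel on zero background is foreground
  z <- matrix(0, 60, 60)
  z[30, 30] <- 100
  fg <- local_mean_threshold(z, 41L)
  expect_true(fg[30, 30])
  expect_equal(sum(fg), 1L)
  expect_error(local_mean_threshold(matrix(0, 10, 10), 41L), "larger than")
  expect_error(local_mean_threshold(matrix(0, 50, 50), 4L), "odd")
})

test_that("windowed SD matches the oracle and the mode estimator recovers sigma", {
  set.seed(12)
  m <- matrix(runif(40 * 40, 0, 100), 40, 40)
  expect_equal(qicyte:::.window_sd(m, 5L), oracle_window_sd(m, 5L),
               tolerance = 1e-9)
  sigma <- 5
  img <- matrix(rnorm(512 * 512, 100, sigma), 512, 512)
  est <- estimate_global_background_sd(img)
  expect_lt(abs(est - sigma) / sigma, 0.10)
  # bright noisy objects covering ~5% of the field do not move the mode
  img2 <- img
  obj <- make_disk(512, 512, 130, 130, 45) | make_disk(512, 512, 380, 300, 45)
  img2[obj] <- 2000 + rnorm(sum(obj), 0, 25)
  est2 <- estimate_global_background_sd(img2)
  expect_lt(abs(est2 - sigma) / sigma, 0.10)
  expect_warning(val <- estimate_global_background_sd(matrix(7, 20, 20)),
                 "constant")
  expect_identical(val, 0)
})

test_that("background model tracks flat and ramped backgrounds", {
  set.seed(13)
  b <- 50
  img <- matrix(rnorm(128 * 128, b, 2), 128, 128)
  bm <- build_background_model(img)
  expect_lt(max(abs(bm$local_background_mean - b)), 2)
  expect_gt(bm$global_background_sd, 0)
  # ramp 0 -> 100 across columns: local mean follows it within a window-width
  ramp <- matrix(seq(0, 100, length.out = 128), 128, 128, byrow = TRUE)
  img_r <- ramp + matrix(rnorm(128 * 128, 0, 1), 128, 128)
  bm_r <- build_background_model(img_r)
  interior <- 30:98
  expect_lt(max(abs(bm_r$local_background_mean[interior, interior] -
                      ramp[interior, interior])), 100 / 128 * 21 + 3)
  # degenerate constant image: model falls back gracefully, no crash
  bm_f <- build_background_model(matrix(5, 60, 60))
  expect_true(all(is.finite(bm_f$local_background_mean)))
  expect_equal(bm_f$local_background_mean[30, 30], 5)
  expect_identical(bm_f$global_background_sd, 0)
  # a field-filling bright object exercises the no-background fallback
  set.seed(99)
  big <- matrix(rnorm(128 * 128, 10, 2), 128, 128)
  big[make_disk(128, 128, 64, 64, 58)] <- 500
  bm_b <- build_background_model(big)
  expect_true(all(is.finite(bm_b$local_background_mean)))
})

test_that("cell segmentation recovers bright objects at 3 SD and ignores dim ones", {
  set.seed(14)
  b <- 10; sigma <- 2
  img <- matrix(rnorm(200 * 200, b, sigma), 200, 200)
  disk <- make_disk(200, 200, 100, 100, 18)
  img[disk] <- img[disk] + 20          # amplitude 20 = 10 sigma
  bm <- build_background_model(img)
  fg <- segment_cells(img, bm)
  # scattered single-pixel noise exceedances are expected at a ~3 SD rule;
  # the object itself is the largest connected component
  expect_lt(mean(fg & !disk), 0.02)
  lab <- qicyte:::.as_labels(label_objects(fg, 8L))
  sizes <- tabulate(lab[lab > 0L])
  main <- lab == which.max(sizes)
  iou <- sum(main & disk) / sum(main | disk)
  expect_gt(iou, 0.9)
  # object at 2 sigma stays below the 3-sigma rule
  img2 <- matrix(rnorm(200 * 200, b, sigma), 200, 200)
  img2[disk] <- img2[disk] + 2 * sigma
  fg2 <- segment_cells(img2, build_background_model(img2))
  expect_lt(sum(fg2 & disk) / sum(disk), 0.5)
})

test_that("segmentation of an object is insensitive to a bright neighbour", {
  set.seed(15)
  b <- 10; sigma <- 2
  base <- matrix(rnorm(200 * 200, b, sigma), 200, 200)
  diskA <- make_disk(200, 200, 100, 70, 20)
  img1 <- base; img1[diskA] <- img1[diskA] + 30
  diskB <- make_disk(200, 200, 100, 135, 20)
  img2 <- img1; img2[diskB] <- img2[diskB] + 500   # very bright neighbour
  maskA1 <- segment_cells(img1, build_background_model(img1)) & diskA
  maskA2 <- segment_cells(img2, build_background_model(img2)) & diskA
  expect_lt(sum(xor(maskA1, maskA2)) / sum(diskA), 0.05)
})

test_that("connected-component labelling respects connectivity", {
  m <- matrix(FALSE, 10, 10)
  m[2:4, 2:4] <- TRUE
  m[5:7, 5:7] <- TRUE          # touches the first block at one corner
  expect_equal(n_objects(label_objects(m, 8L)), 1L)
  expect_equal(n_objects(label_objects(m, 4L)), 2L)
  expect_equal(n_objects(label_objects(matrix(FALSE, 5, 5), 8L)), 0L)
  two <- matrix(FALSE, 20, 20)
  two[make_disk(20, 20, 5, 5, 3)] <- TRUE
  two[make_disk(20, 20, 14, 14, 3)] <- TRUE
  expect_equal(n_objects(label_objects(two, 8L)), 2L)
  # labels appear in raster-scan (row-major) discovery order
  lab <- qicyte:::.as_labels(label_objects(two, 8L))
  expect_equal(lab[5, 5], 1L)
  expect_equal(lab[14, 14], 2L)
})

test_that("limited watershed applies the 85% retention rule on 1-D profiles", {
  msk <- matrix(TRUE, 1, 5)
  # separating level 3: retained 38/41 = 0.927 > 0.85 -> split
  split1 <- limited_watershed_split(msk, matrix(c(10, 9, 3, 9, 10), 1))
  expect_equal(max(split1), 2L)
  expect_true(all(split1 > 0L))  # valley pixel reassigned, full partition
  # separating level 8: retained 38/46 = 0.826 < 0.85 -> no split
  split2 <- limited_watershed_split(msk, matrix(c(10, 9, 8, 9, 10), 1))
  expect_equal(max(split2), 1L)
})

test_that("a single-peak blob never splits; a bridged pair splits at the bridge", {
  xy <- expand.grid(r = 1:41, c = 1:41)
  g1 <- matrix(100 * exp(-((xy$r - 21)^2 + (xy$c - 21)^2) / 50), 41, 41)
  blob <- g1 > 5
  expect_equal(max(limited_watershed_split(blob, g1)), 1L)

  # two Gaussian nuclei joined by a thin dim bridge
  xy2 <- expand.grid(r = 1:41, c = 1:81)
  g2 <- matrix(100 * exp(-((xy2$r - 21)^2 + (xy2$c - 24)^2) / 40) +
                 100 * exp(-((xy2$r - 21)^2 + (xy2$c - 58)^2) / 40), 41, 81)
  g2[20:22, 33:49] <- pmax(g2[20:22, 33:49], 8)
  reg <- g2 > 5
  lab <- label_objects(reg, 8L)
  expect_equal(n_objects(lab), 1L)   # merged into one clump
  parts <- limited_watershed_split(reg, g2)
  expect_equal(max(parts), 2L)
  cent <- lapply(1:2, function(l) {
    w <- which(parts == l)
    c(mean((w - 1) %% 41 + 1), mean((w - 1) %/% 41 + 1))
  })
  peaks <- list(c(21, 24), c(21, 58))
  d <- sapply(cent, function(ct) min(sapply(peaks, function(p)
    sqrt(sum((ct - p)^2)))))
  expect_true(all(d < 2))
  # partition property: children tile the parent exactly
  expect_identical(parts > 0L, reg)
})

test_that("splitting is monotone: higher retention demands stronger saddles", {
  prof <- matrix(c(10, 9, 3, 9, 10), 1)
  msk <- matrix(TRUE, 1, 5)
  grid <- c(0.05, 0.3, 0.6, 0.85, 0.9, 0.99)
  n_parts <- vapply(grid, function(r)
    max(limited_watershed_split(msk, prof, retention = r)), integer(1))
  expect_true(all(diff(n_parts) <= 0L))
  # retained fraction is 0.927: splits below, not above
  expect_equal(n_parts[grid == 0.3], 2L)
  expect_equal(n_parts[grid == 0.99], 1L)
  # any separable object splits as retention -> 0
  expect_equal(max(limited_watershed_split(msk, matrix(c(10, 9, 8, 9, 10), 1),
                                           retention = 0.05)), 2L)
})

test_that("dim-object removal keeps cells and drops debris by the G1 mode", {
  set.seed(16)
  dims <- c(220, 220)
  dna <- matrix(0, dims[1], dims[2])
  lab <- matrix(0L, dims[1], dims[2])
  k <- 0L
  add_obj <- function(cr, cc, radius, level) {
    k <<- k + 1L
    d <- make_disk(dims[1], dims[2], cr, cc, radius)
    lab[d] <<- k
    dna[d] <<- level
  }
  centers <- expand.grid(seq(15, 205, by = 30), seq(15, 205, by = 30))
  # 30 G1-like objects (total ~ 100 * area), 10 G2-like (double), 9 debris
  for (i in 1:30) add_obj(centers[i, 1], centers[i, 2], 5, 100)
  for (i in 31:40) add_obj(centers[i, 1], centers[i, 2], 5, 200)
  for (i in 41:49) add_obj(centers[i, 1], centers[i, 2], 2, 20)
  out <- remove_dim_objects(lab, dna)
  expect_equal(n_objects(out), 40L)
  # all identical objects: none removed
  out2 <- remove_dim_objects(lab * as.integer(lab <= 30), dna)
  expect_equal(n_objects(out2), 30L)
  # min_fraction = 0 is the identity
  out3 <- remove_dim_objects(lab, dna, min_fraction = 0)
  expect_equal(n_objects(out3), 49L)
  # too few objects: filtering skipped with a warning
  lab_few <- matrix(0L, 50, 50)
  lab_few[make_disk(50, 50, 10, 10, 3)] <- 1L
  lab_few[make_disk(50, 50, 30, 30, 3)] <- 2L
  expect_warning(out4 <- remove_dim_objects(lab_few, matrix(1, 50, 50)),
                 "unreliable")
  expect_equal(n_objects(out4), 2L)
})

test_that("cell division assigns every foreground pixel to exactly one nucleus", {
  # one blob with two nuclei: cells tile the blob exactly
  blob <- make_disk(60, 60, 30, 30, 20)
  nuc <- matrix(0L, 60, 60)
  nuc[make_disk(60, 60, 30, 22, 5)] <- 1L
  nuc[make_disk(60, 60, 30, 38, 5)] <- 2L
  intensity <- matrix(10, 60, 60)
  cells <- divide_cell_mask(blob, nuc, intensity)
  cm <- qicyte:::.as_labels(cells)
  expect_identical(cm > 0L, blob)                 # union = blob
  expect_equal(sort(unique(cm[cm > 0L])), c(1L, 2L))
  # each cell contains its own whole nucleus
  expect_true(all(cm[nuc == 1L] == 1L))
  expect_true(all(cm[nuc == 2L] == 2L))
  # a blob without a nucleus is dropped
  blob2 <- blob | make_disk(60, 60, 10, 50, 6)
  cells2 <- divide_cell_mask(blob2, nuc, intensity)
  cm2 <- qicyte:::.as_labels(cells2)
  expect_true(all(cm2[make_disk(60, 60, 10, 50, 6) & !blob] == 0L))
  # a nucleus sticking out of the foreground is unioned in
  nuc3 <- matrix(0L, 60, 60)
  nuc3[make_disk(60, 60, 8, 8, 4)] <- 1L
  cells3 <- divide_cell_mask(matrix(FALSE, 60, 60), nuc3, intensity)
  expect_identical(qicyte:::.as_labels(cells3) > 0L, nuc3 > 0L)
})

test_that("identify_cells is deterministic and empty on blank noise", {
  g <- generate_field(synthetic_field_spec(n_cells = 15L, field_size_px = 256L,
                                           seed = 31))
  s1 <- suppressWarnings(identify_cells(g$field))
  s2 <- suppressWarnings(identify_cells(g$field))
  expect_identical(qicyte:::.as_labels(s1$cells), qicyte:::.as_labels(s2$cells))
  expect_identical(qicyte:::.as_labels(s1$nuclei), qicyte:::.as_labels(s2$nuclei))
  set.seed(32)
  blank <- field_image_set(matrix(pmax(rnorm(256^2, 100, 5), 0), 256, 256),
                           matrix(pmax(rnorm(256^2, 100, 5), 0), 256, 256))
  s0 <- suppressWarnings(identify_cells(blank))
  expect_equal(n_objects(s0$cells), 0L)
  expect_equal(n_objects(s0$nuclei), 0L)
})

test_that("every identified cell contains exactly one nucleus", {
  g <- generate_field(synthetic_field_spec(n_cells = 30L, field_size_px = 360L,
                                           touching_fraction = 0.4, seed = 33))
  seg <- identify_cells(g$field)
  cm <- qicyte:::.as_labels(seg$cells)
  nm <- qicyte:::.as_labels(seg$nuclei)
  ids <- sort(unique(cm[cm > 0L]))
  for (j in ids) {
    inside <- unique(nm[cm == j & nm > 0L])
    expect_length(inside, 1L)
    expect_equal(inside, j)      # labels are matched pairs
    expect_true(all(cm[nm == j] == j))  # nucleus fully inside its cell
  }
})
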