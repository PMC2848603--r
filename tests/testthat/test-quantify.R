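make_measure_fixture <- function() {
  # 64x64 field, one rectangular 10-px cell with a 4-px nucleus, antigen 2
  sz <- 64L
  cells <- matrix(0L, sz, sz)
  nuc <- matrix(0L, sz, sz)
  cells[30:34, 30:31] <- 1L      # 10 px
  nuc[31:32, 30:31] <- 1L        # 4 px
  ant <- matrix(0, sz, sz)
  ant[cells == 1L] <- 2
  nimg <- matrix(0, sz, sz); nimg[nuc == 1L] <- 50
  cimg <- matrix(0, sz, sz); cimg[cells == 1L] <- 10
  fld <- field_image_set(nimg, cimg, list(pERK = ant))
  list(field = fld, cells = label_mask(cells, "cellular"),
       nuclei = label_mask(nuc, "nuclear"))
}

test_that("per-cell sums equal the brute-force pixel summation", {
  fx <- make_measure_fixture()
  tab <- suppressWarnings(measure_cells(fx$field, fx$nuclei, fx$cells))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$total_pERK, 20)
  expect_equal(tab$nuclear_pERK, 8)
  expect_equal(tab$area_px, 10)
  expect_true(tab$nuclear_dna <= tab$total_dna)

  # random intensities: totals equal direct sums over the mask
  set.seed(21)
  g <- generate_field(synthetic_field_spec(n_cells = 8L, field_size_px = 200L,
                                           seed = 22))
  tab2 <- suppressWarnings(
    measure_cells(g$field, g$truth$nuclear_mask, g$truth$cell_mask))
  cm <- qicyte:::.as_labels(g$truth$cell_mask)
  ant <- g$field$antigens$pERK$pixels
  for (i in tab2$cell_id) {
    expect_equal(tab2$total_pERK[tab2$cell_id == i], sum(ant[cm == i]))
  }
  # antigen identically zero gives zero totals
  fz <- field_image_set(fx$field$nuclear$pixels, fx$field$cell$pixels,
                        list(pERK = matrix(0, 64, 64)))
  tz <- suppressWarnings(measure_cells(fz, fx$nuclei, fx$cells))
  expect_equal(tz$total_pERK, 0)
})

test_that("roundness is 1 for a circle, ~1.51 for a 3:1 ellipse, near 1 for a raster disk", {
  r <- 5
  expect_equal(roundness(perimeter = 2 * pi * r, area = pi * r^2), 1)
  # 3:1 ellipse, Ramanujan perimeter approximation
  a <- 3; b <- 1
  h <- ((a - b) / (a + b))^2
  P <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  rd <- roundness(perimeter = P, area = pi * a * b)
  expect_equal(rd, 1.5078, tolerance = 1e-3)
  expect_gt(rd, qic_params()$roundness_cutoff)   # filtered as multi-nucleated
  disk <- make_disk(71, 71, 36, 36, 30)
  expect_gt(roundness(disk), 0.95)
  expect_lt(roundness(disk), 1.15)
  expect_error(roundness(matrix(FALSE, 3, 3)), "nonempty")
})

test_that("NLI closed forms and invariances hold exactly", {
  # proportional channels -> 1
  v <- c(1, 4, 2, 7)
  expect_equal(nli(v, 3 * v), 1, tolerance = 1e-12)
  # disjoint supports -> 0
  expect_equal(nli(c(1, 1, 0, 0), c(0, 0, 2, 3)), 0)
  # uniform antigen over n pixels, nuclear stain on m: sqrt(m/n)
  m <- 25; n <- 100
  nuc <- c(rep(7, m), rep(0, n - m))
  ant <- rep(3, n)
  expect_equal(nli(nuc, ant), sqrt(m / n), tolerance = 1e-12)
  expect_equal(nli(nuc, ant), 0.5, tolerance = 1e-12)
  # scale invariance in both channels
  set.seed(23)
  for (i in 1:20) {
    x <- runif(50); y <- runif(50)
    v0 <- nli(x, y)
    expect_equal(nli(17.3 * x, y), v0, tolerance = 1e-12)
    expect_equal(nli(x, 0.004 * y), v0, tolerance = 1e-12)
    expect_gte(v0, 0); expect_lte(v0, 1)
  }
  expect_true(is.na(nli(rep(0, 5), runif(5))))
})

test_that("moving antigen into the nucleus raises both NLI and Circ/Ring", {
  # one-parameter family: fixed total, nuclear fraction rising
  sz <- 101L
  nuc <- make_disk(sz, sz, 51, 51, 12)
  cell <- make_disk(sz, sz, 51, 51, 26)
  nimg <- matrix(0, sz, sz); nimg[nuc] <- 100
  cimg <- matrix(0, sz, sz); cimg[cell] <- 50
  nuc_lab <- matrix(0L, sz, sz); nuc_lab[nuc] <- 1L
  total <- 1e4
  fr <- c(0.1, 0.35, 0.6, 0.85)
  nlis <- numeric(length(fr)); ratios <- numeric(length(fr))
  for (i in seq_along(fr)) {
    ant <- matrix(0, sz, sz)
    ant[cell] <- (1 - fr[i]) * total / sum(cell & !nuc)
    ant[nuc] <- fr[i] * total / sum(nuc)
    nlis[i] <- nli(nimg[cell], ant[cell])
    fld <- field_image_set(nimg, cimg, list(x = ant))
    h <- hcs_quantify(nuc_lab, fld)
    ratios[i] <- h$circ_ring_x
  }
  expect_true(all(diff(nlis) > 0))
  expect_true(all(diff(ratios) > 0))
  # fully nuclear antigen: ratio >> 1; uniform antigen: ratio ~ 1
  ant_u <- matrix(0, sz, sz); ant_u[cell] <- 3
  h_u <- hcs_quantify(nuc_lab, field_image_set(nimg, cimg, list(x = ant_u)))
  expect_lt(abs(h_u$circ_ring_x - 1), 0.05)
  ant_n <- matrix(0, sz, sz); ant_n[nuc] <- 5
  h_n <- hcs_quantify(nuc_lab, field_image_set(nimg, cimg, list(x = ant_n)))
  expect_gt(h_n$circ_ring_x, 3)
})

test_that("normalized NLI removes a shared cell-stain confounder", {
  # identical cell-stain NLI: correction is the identity
  x <- c(0.3, 0.5, 0.7)
  expect_equal(normalized_nli(x, rep(0.6, 3)), x)
  # doubling every cell-stain NLI together with its well mean changes nothing
  cs <- c(0.4, 0.5, 0.6)
  expect_equal(normalized_nli(x, cs), normalized_nli(x, 2 * cs))
  # simulated density confounder: a multiplicative nuisance hits both the
  # antigen NLI and the cell-stain NLI; the correction shrinks the spread
  set.seed(24)
  true_nli <- 0.55
  nuisance <- exp(rnorm(400, 0, 0.15))
  raw <- true_nli * nuisance
  cstain <- 0.62 * nuisance
  corrected <- normalized_nli(raw, cstain)
  expect_lt(sd(corrected), sd(raw) / 5)
  # well_mean strategy only rescales by the well average
  expect_equal(normalized_nli(x, cs, strategy = "well_mean"),
               x / mean(cs))
  # zero cell-stain NLI propagates NA
  expect_true(is.na(normalized_nli(c(0.5, 0.5), c(0.5, 0))[2]))
})

test_that("displaced cell staining is flagged as ill-identified", {
  expect_identical(detect_ill_identified(c(0.9, 0.1, NA), threshold = 0),
                   c(FALSE, FALSE, FALSE))
  # isolated synthetic cell, cell channel displaced past the cell diameter
  s0 <- synthetic_field_spec(n_cells = 4L, field_size_px = 220L,
                             touching_fraction = 0, seed = 25)
  s1 <- synthetic_field_spec(n_cells = 4L, field_size_px = 220L,
                             touching_fraction = 0,
                             chromatic_shift_px = c(45L, 0L), seed = 25)
  g0 <- generate_field(s0); g1 <- generate_field(s1)
  t0 <- suppressWarnings(
    measure_cells(g0$field, g0$truth$nuclear_mask, g0$truth$cell_mask))
  expect_true(all(!t0$flag_ill_identified))
  # use the unshifted truth masks so the vectors cover the true cell area
  t1 <- suppressWarnings(
    measure_cells(g1$field, g1$truth$nuclear_mask, g1$truth$cell_mask))
  expect_true(all(t1$coloc_hoechst_cellmask < t0$coloc_hoechst_cellmask))
  expect_true(all(t1$flag_ill_identified))
})

test_that("DNA histogram separates G1 and G2 modes at ratio ~2", {
  set.seed(26)
  T1 <- 1e5
  totals <- c(rnorm(1400, T1, 0.05 * T1), rnorm(600, 2 * T1, 0.1 * T1))
  h <- dna_histogram(totals)
  expect_length(h$modes, 2L)
  expect_gt(h$mode_ratio, 1.9)
  expect_lt(h$mode_ratio, 2.1)
  # all-G1 population: a single mode
  h1 <- dna_histogram(rnorm(800, T1, 0.05 * T1))
  expect_lt(max(h1$modes) / min(h1$modes), 1.2)
  expect_error(dna_histogram(numeric(0)), "no DNA")
})

test_that("HCS quantification contains the cell when isolated, contaminates when not", {
  sz <- 160L
  # zero background: an isolated cell is fully inside its dilated-nucleus ROI
  nuc <- make_disk(sz, sz, 60, 60, 8)
  cell <- make_disk(sz, sz, 60, 60, 20)
  ant <- matrix(0, sz, sz); ant[cell] <- 5
  nimg <- matrix(0, sz, sz); nimg[nuc] <- 100
  cimg <- matrix(0, sz, sz); cimg[cell] <- 40
  nuc_lab <- matrix(0L, sz, sz); nuc_lab[nuc] <- 1L
  fld <- field_image_set(nimg, cimg, list(x = ant))
  h <- hcs_quantify(nuc_lab, fld)
  expect_equal(h$hcs_total_x, sum(ant[cell]))   # ROI contains the whole cell
  # two nuclei 26 px apart: ROIs overlap and each sum exceeds the own-cell total
  nuc2 <- matrix(0L, sz, sz)
  nuc2[make_disk(sz, sz, 80, 67, 8)] <- 1L
  nuc2[make_disk(sz, sz, 80, 93, 8)] <- 2L
  cellA <- make_disk(sz, sz, 80, 67, 13)
  cellB <- make_disk(sz, sz, 80, 93, 13) & !cellA
  ant2 <- matrix(0, sz, sz); ant2[cellA] <- 10; ant2[cellB] <- 30
  nimg2 <- matrix(0, sz, sz); nimg2[nuc2 > 0L] <- 100
  cimg2 <- matrix(0, sz, sz); cimg2[cellA | cellB] <- 40
  h2 <- hcs_quantify(nuc2, field_image_set(nimg2, cimg2, list(x = ant2)))
  expect_gt(h2$hcs_total_x[1], sum(ant2[cellA]))   # picks up the neighbour
  expect_gt(h2$hcs_total_x[2], sum(ant2[cellB]))
  # tiny nucleus emptied by the Circ erosion is flagged
  nuc3 <- matrix(0L, sz, sz); nuc3[75:76, 75:76] <- 1L
  h3 <- hcs_quantify(nuc3, fld)
  expect_true(h3$flag_empty_circ[1])
  expect_true(is.na(h3$circ_ring_x[1]))
})
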