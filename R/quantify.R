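#' Crofton perimeter of a binary region
#'
#' Estimates the continuous-space perimeter from the 2x2 pixel-configuration
#' histogram using the 4-direction Crofton formula, the standard
#' integral-geometry estimator. Unlike a raw border-pixel count it is nearly
#' unbiased on smooth shapes: a rasterized disk of radius 30 px measures
#' within about 1% of 2*pi*r.
#'
#' @param mask Logical matrix (the region).
#' @return Perimeter estimate in pixel units.
#' @export
estimate_perimeter <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- matrix(0, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask * 1
  nr <- nrow(m); nc <- ncol(m)
  # 2x2 configuration code: 8*tl + 2*tr + 4*bl + 1*br
  code <- 8 * m[-nr, -nc] + 2 * m[-nr, -1] + 4 * m[-1, -nc] + 1 * m[-1, -1]
  h <- tabulate(code + 1, nbins = 16L)
  s2 <- sqrt(2)
  coefs <- c(0, pi / 4 * (1 + 1 / s2), pi / (4 * s2), pi / (2 * s2),
             0, pi / 4 * (1 + 1 / s2), 0, pi / (4 * s2),
             pi / 4, pi / 2, pi / (4 * s2), pi / (4 * s2),
             pi / 4, pi / 2, 0, 0)
  sum(coefs * h)
}

#' Roundness of a region
#'
#' Defined as \eqn{P^2 / (4 \pi A)} with perimeter \eqn{P} and area \eqn{A}:
#' 1 for a circle (the isoperimetric minimum) and increasing with
#' elongation or irregularity; a 3:1 ellipse measures about 1.5. Cells with
#' roundness below 1.2 are regarded as single-nucleus cells.
#'
#' @param region Logical matrix (the region), or `NULL` when `perimeter` and
#'   `area` are supplied directly.
#' @param perimeter,area Optional explicit geometry, bypassing estimation.
#' @return Dimensionless roundness.
#' @export
roundness <- function(region = NULL, perimeter = NULL, area = NULL) {
  if (is.null(perimeter) || is.null(area)) {
    if (is.null(region) || !any(region))
      stop("roundness needs a nonempty region or explicit perimeter and area",
           call. = FALSE)
    perimeter <- estimate_perimeter(region)
    area <- sum(region)
  }
  perimeter^2 / (4 * pi * area)
}

#' Nuclear localization index (NLI)
#'
#' The cosine between the per-pixel nuclear-stain and antigen-stain
#' intensity vectors of one cell:
#' \deqn{NLI = \frac{\sum_p N(p) A(p)}{\sqrt{\sum_p N(p)^2}\sqrt{\sum_p A(p)^2}}}
#' For non-negative intensities the index lies in [0, 1], moving from 0
#' (antigen disjoint from the nuclear stain, i.e. cytoplasmic) to 1
#' (antigen proportional to the nuclear stain, i.e. nuclear). It is
#' invariant to rescaling either channel, so it is unaffected by staining
#' level or antigen amount.
#'
#' @param nuclear Numeric vector of nuclear-stain intensities over the
#'   cell's pixels.
#' @param antigen Numeric vector of antigen intensities over the same
#'   pixels.
#' @return Scalar in [0, 1]; `NA` if either vector is all zero.
#' @export
nli <- function(nuclear, antigen) {
  stopifnot(length(nuclear) == length(antigen))
  nn <- sqrt(sum(nuclear^2))
  na <- sqrt(sum(antigen^2))
  if (nn == 0 || na == 0) return(NA_real_)
  min(1, sum(nuclear * antigen) / (nn * na))
}

#' Well-normalized NLI
#'
#' The raw NLI is slightly affected by cell density and staining level; the
#' cell-stain NLI of the same cell is affected by the same factors but not
#' by antigen localization, so it serves as a per-cell correction. The
#' default strategy rescales each cell's antigen NLI by the ratio of the
#' well-average cell-stain NLI to the cell's own cell-stain NLI:
#' \deqn{NLI^{norm} = NLI_{antigen} \cdot
#'   \langle NLI_{cellstain} \rangle_{well} / NLI_{cellstain}}
#' The `"well_mean"` strategy applies only the well-level division
#' \eqn{NLI_{antigen} / \langle NLI_{cellstain}\rangle_{well}}.
#'
#' @param nli_antigen Per-cell antigen NLI (vector).
#' @param nli_cellstain Per-cell cell-stain NLI (vector, same length).
#' @param well_mean Well average of the cell-stain NLI; computed from
#'   `nli_cellstain` when omitted.
#' @param strategy `"per_cell_ratio"` (default) or `"well_mean"`.
#' @return Vector of normalized NLIs; cells with zero or missing cell-stain
#'   NLI give `NA`.
#' @export
normalized_nli <- function(nli_antigen, nli_cellstain, well_mean = NULL,
                           strategy = c("per_cell_ratio", "well_mean")) {
  strategy <- match.arg(strategy)
  stopifnot(length(nli_antigen) == length(nli_cellstain))
  ok <- is.finite(nli_cellstain) & nli_cellstain > 0
  if (is.null(well_mean)) well_mean <- mean(nli_cellstain[ok])
  out <- rep(NA_real_, length(nli_antigen))
  if (strategy == "per_cell_ratio") {
    out[ok] <- nli_antigen[ok] * well_mean / nli_cellstain[ok]
  } else {
    out[ok] <- nli_antigen[ok] / well_mean
  }
  out
}

#' Hoechst-CellMask colocalization within a cell
#'
#' The mean-centred cosine (Pearson correlation) between the nuclear-stain
#' and cell-stain intensity vectors over the cell's pixels, clipped below at
#' zero. Centring matters: the shared background plane and any flat
#' positive noise would push a raw cosine towards a high floor regardless
#' of geometry, whereas the centred cosine responds only to co-varying
#' structure. When the apparent nucleus is displaced out of the cell body
#' (chromatic aberration between channels) the two intensity patterns stop
#' co-varying and the index collapses towards zero.
#'
#' @param nuclear,cellstain Raw intensity vectors over the cell's pixels.
#' @return Scalar in [0, 1]; `NA` if either vector is constant.
#' @export
channel_colocalization <- function(nuclear, cellstain) {
  stopifnot(length(nuclear) == length(cellstain))
  if (length(nuclear) < 3 || sd(nuclear) == 0 || sd(cellstain) == 0)
    return(NA_real_)
  max(0, cor(nuclear, cellstain))
}

#' Flag ill-identified cells
#'
#' A cell is ill-identified when its Hoechst-CellMask colocalization (see
#' [channel_colocalization()]) falls below `threshold`: the apparent nuclear
#' and cell-body positions disagree, typically from chromatic aberration.
#' With `threshold = 0` nothing is flagged.
#'
#' @param colocalization Per-cell colocalization values.
#' @param threshold Flagging threshold (default 0.3).
#' @return Logical vector of flags.
#' @export
detect_ill_identified <- function(colocalization, threshold = 0.3) {
  !is.na(colocalization) & colocalization < threshold
}

#' Per-cell measurements over matched masks
#'
#' For every cell (cell label = nucleus label) computes total and nuclear
#' summed intensities for each channel, area, perimeter, roundness, the NLI
#' of each antigen channel and of the cell stain, the Hoechst-CellMask
#' colocalization, the well-normalized NLI, and the QC flags
#' (`multi_nucleated` from the roundness cutoff, `ill_identified` from the
#' colocalization threshold, `low_dna` from the G1-mode criterion).
#'
#' @param field A [field_image_set()].
#' @param nuclei,cells Matched [label_mask()]s from [identify_cells()] (or
#'   ground truth).
#' @param params A [qic_params()].
#' @param nli_strategy Strategy passed to [normalized_nli()].
#' @return A data frame with one row per cell (the per-cell table).
#' @export
measure_cells <- function(field, nuclei, cells, params = qic_params(),
                          nli_strategy = "per_cell_ratio") {
  stopifnot(inherits(field, "field_image_set"))
  nuc <- .as_labels(nuclei)
  cel <- .as_labels(cells)
  stopifnot(identical(dim(nuc), dim(cel)))
  ids <- sort(unique(cel[cel > 0L]))
  ni <- field$nuclear$pixels
  ci <- field$cell$pixels
  channels <- c(list(ni, ci), lapply(field$antigens, function(a) a$pixels))
  ch_names <- c(field$nuclear$channel_name, field$cell$channel_name,
                vapply(field$antigens, function(a) a$channel_name, character(1)))
  ant_names <- ch_names[-(1:2)]

  base <- data.frame(cell_id = ids,
                     well_id = field$well_id,
                     field_index = field$field_index,
                     time_min = field$time_min,
                     treatment = field$treatment,
                     experiment_id = field$experiment_id,
                     stringsAsFactors = FALSE)
  if (length(ids) == 0) return(.empty_cell_table(base, ch_names, ant_names))

  cell_idx <- split(which(cel > 0L), cel[cel > 0L])[as.character(ids)]
  nuc_idx <- split(which(nuc > 0L), nuc[nuc > 0L])[as.character(ids)]

  for (k in seq_along(channels)) {
    v <- channels[[k]]
    base[[paste0("total_", ch_names[k])]] <-
      vapply(cell_idx, function(ix) sum(v[ix]), numeric(1))
    base[[paste0("nuclear_", ch_names[k])]] <-
      vapply(nuc_idx, function(ix) if (is.null(ix)) 0 else sum(v[ix]),
             numeric(1))
  }

  geom <- t(vapply(cell_idx, function(ix) {
    reg <- matrix(FALSE, nrow(cel), ncol(cel))
    reg[ix] <- TRUE
    p <- estimate_perimeter(reg)
    c(length(ix), p, p^2 / (4 * pi * length(ix)))
  }, numeric(3)))
  base$area_px <- geom[, 1]
  base$perimeter_px <- geom[, 2]
  base$roundness <- geom[, 3]

  for (a in ant_names) {
    av <- channels[[match(a, ch_names)]]
    base[[paste0("nli_", a)]] <-
      vapply(cell_idx, function(ix) nli(ni[ix], av[ix]), numeric(1))
  }
  base$nli_cellstain <-
    vapply(cell_idx, function(ix) nli(ni[ix], ci[ix]), numeric(1))

  base$coloc_hoechst_cellmask <- vapply(cell_idx, function(ix) {
    channel_colocalization(ni[ix], ci[ix])
  }, numeric(1))

  for (a in ant_names) {
    base[[paste0("normalized_nli_", a)]] <-
      normalized_nli(base[[paste0("nli_", a)]], base$nli_cellstain,
                     strategy = nli_strategy)
  }

  base$flag_multi_nucleated <- base$roundness >= params$roundness_cutoff
  base$flag_ill_identified <-
    detect_ill_identified(base$coloc_hoechst_cellmask,
                          params$ill_coloc_threshold)
  dna_tot <- base[[paste0("nuclear_", ch_names[1])]]
  base$flag_low_dna <- .flag_low_dna(dna_tot, params)
  rownames(base) <- NULL
  base
}

.flag_low_dna <- function(dna_totals, params) {
  if (length(dna_totals) == 0) return(logical(0))
  g1 <- params$g1_total
  if (is.null(g1)) {
    if (length(dna_totals) < params$min_objects_for_g1)
      return(rep(FALSE, length(dna_totals)))
    g1 <- .histogram_mode(dna_totals)
  }
  dna_totals < params$min_dna_fraction_of_g1 * g1
}

.empty_cell_table <- function(base, ch_names, ant_names) {
  for (k in seq_along(ch_names)) {
    base[[paste0("total_", ch_names[k])]] <- numeric(0)
    base[[paste0("nuclear_", ch_names[k])]] <- numeric(0)
  }
  base$area_px <- numeric(0)
  base$perimeter_px <- numeric(0)
  base$roundness <- numeric(0)
  for (a in ant_names) base[[paste0("nli_", a)]] <- numeric(0)
  base$nli_cellstain <- numeric(0)
  base$coloc_hoechst_cellmask <- numeric(0)
  for (a in ant_names) base[[paste0("normalized_nli_", a)]] <- numeric(0)
  base$flag_multi_nucleated <- logical(0)
  base$flag_ill_identified <- logical(0)
  base$flag_low_dna <- logical(0)
  base
}

#' DNA content histogram and its modes
#'
#' Histograms the per-cell total nuclear DNA intensity and locates the
#' dominant modes by kernel density. A healthy cycling population shows two
#' modes at a position ratio near 2 (G1 vs G2/M DNA content).
#'
#' @param table Per-cell table from [measure_cells()], or a numeric vector
#'   of per-cell DNA totals.
#' @param bins Number of histogram bins (default: Freedman-Diaconis).
#' @param dna_column Column holding the totals (default `"nuclear_dna"`).
#' @param n_modes Number of modes to report (default 2).
#' @return A list with `breaks`, `counts`, `modes` (positions, decreasing
#'   prominence) and `mode_ratio` (larger/smaller of the top two, `NA` if
#'   fewer than two modes).
#' @export
dna_histogram <- function(table, bins = NULL, dna_column = "nuclear_dna",
                          n_modes = 2L) {
  x <- if (is.numeric(table)) table else table[[dna_column]]
  if (is.null(x) || length(x) == 0)
    stop("no DNA totals to histogram", call. = FALSE)
  rng <- range(x)
  if (is.null(bins)) {
    bw <- 2 * IQR(x) / length(x)^(1 / 3)
    bins <- if (bw > 0 && diff(rng) > 0) max(1L, ceiling(diff(rng) / bw)) else 1L
  }
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  if (diff(rng) == 0) breaks <- c(rng[1] - 0.5, rng[1] + 0.5)
  idx <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  modes <- .density_modes(x, n_modes)
  ratio <- if (length(modes) >= 2) {
    s <- sort(modes[1:2])
    s[2] / s[1]
  } else NA_real_
  list(breaks = breaks, counts = counts, modes = modes, mode_ratio = ratio)
}

# Positions of local density maxima, strongest first.
.density_modes <- function(x, n_modes) {
  if (length(unique(x)) == 1) return(x[1])
  d <- density(x, n = 512)
  y <- d$y
  is_max <- c(FALSE, y[2:(length(y) - 1)] > y[1:(length(y) - 2)] &
                y[2:(length(y) - 1)] >= y[3:length(y)], FALSE)
  peaks <- which(is_max)
  peaks <- peaks[order(y[peaks], decreasing = TRUE)]
  d$x[head(peaks, n_modes)]
}

#' Conventional HCS quantification from nuclei alone
#'
#' The baseline high-content-screening scheme: no cell contour is
#' identified; each nucleus is dilated by `roi_dilation_px` into a region of
#' interest over which antigen amounts are summed. Neighbouring ROIs
#' overlap, and shared pixels count fully towards both cells — this is the
#' cross-contamination mechanism that narrows the apparent cell-to-cell
#' distribution. Nuclear translocation is measured as the Circ/Ring average
#' intensity ratio (eroded-nucleus disk over perinuclear annulus), with no
#' clipping to any cell boundary.
#'
#' @param nuclei Nuclear [label_mask()].
#' @param field A [field_image_set()].
#' @param params An [hcs_params()].
#' @return A data frame with, per nucleus: `cell_id`, per-channel
#'   `hcs_total_*` (ROI sums), `circ_ring_*` (average-intensity ratios for
#'   antigen channels) and `flag_empty_circ`.
#' @export
hcs_quantify <- function(nuclei, field, params = hcs_params()) {
  stopifnot(inherits(field, "field_image_set"))
  nuc <- .as_labels(nuclei)
  dims <- dim(nuc)
  ids <- sort(unique(nuc[nuc > 0L]))
  channels <- c(list(field$nuclear$pixels, field$cell$pixels),
                lapply(field$antigens, function(a) a$pixels))
  ch_names <- c(field$nuclear$channel_name, field$cell$channel_name,
                vapply(field$antigens, function(a) a$channel_name, character(1)))
  ant_names <- ch_names[-(1:2)]

  out <- data.frame(cell_id = ids)
  for (nm in ch_names) out[[paste0("hcs_total_", nm)]] <- NA_real_
  for (a in ant_names) out[[paste0("circ_ring_", a)]] <- NA_real_
  out$flag_empty_circ <- FALSE
  if (length(ids) == 0) return(out)

  margin <- params$roi_dilation_px + params$ring_outer_dilation_px + 1L
  for (i in seq_along(ids)) {
    w <- which(nuc == ids[i])
    rows <- (w - 1L) %% dims[1] + 1L
    cols <- (w - 1L) %/% dims[1] + 1L
    r1 <- max(1L, min(rows) - margin); r2 <- min(dims[1], max(rows) + margin)
    c1 <- max(1L, min(cols) - margin); c2 <- min(dims[2], max(cols) + margin)
    sub <- matrix(FALSE, r2 - r1 + 1L, c2 - c1 + 1L)
    sub[cbind(rows - r1 + 1L, cols - c1 + 1L)] <- TRUE

    roi <- .disk_dilate(sub, params$roi_dilation_px)
    circ <- .disk_erode(sub, params$circ_erosion_px)
    ring <- .disk_dilate(sub, params$ring_outer_dilation_px) &
      !.disk_erode(sub, params$ring_inner_erosion_px)

    for (k in seq_along(channels)) {
      v <- channels[[k]][r1:r2, c1:c2, drop = FALSE]
      out[[paste0("hcs_total_", ch_names[k])]][i] <- sum(v[roi])
    }
    if (!any(circ) || !any(ring)) {
      out$flag_empty_circ[i] <- TRUE
    } else {
      for (a in ant_names) {
        v <- channels[[match(a, ch_names)]][r1:r2, c1:c2, drop = FALSE]
        out[[paste0("circ_ring_", a)]][i] <- mean(v[circ]) / mean(v[ring])
      }
    }
  }
  out
}

.disk_brush <- function(r) EBImage::makeBrush(2L * as.integer(r) + 1L, "disc")

.disk_dilate <- function(mask, r) {
  if (r <= 0) return(mask)
  EBImage::dilate(mask * 1, .disk_brush(r)) > 0.5
}

.disk_erode <- function(mask, r) {
  if (r <= 0) return(mask)
  EBImage::erode(mask * 1, .disk_brush(r)) > 0.5
}
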