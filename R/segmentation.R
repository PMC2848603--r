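#' Local background model for cell-contour segmentation
#'
#' The presumable background is whatever local-mean thresholding with the
#' same window classifies as background. The local background mean at each
#' pixel is then the mean intensity of those background pixels within the
#' window centred on it; windows containing no background pixel fall back to
#' the global background mean. The global background SD comes from
#' [estimate_global_background_sd()]: the local SD is deliberately not used,
#' because it balloons wherever the window brushes a bright object.
#'
#' @param image A [channel_image()] or numeric matrix.
#' @param params A [qic_params()] (uses `background_window_px`,
#'   `local_sd_window_px`).
#' @return A list of class `"background_model"` with `local_background_mean`
#'   (matrix), `global_background_sd` (scalar) and `global_background_mean`
#'   (scalar fallback value).
#' @export
build_background_model <- function(image, params = qic_params()) {
  m <- .as_pixels(image)
  w <- params$background_window_px
  fg <- local_mean_threshold(m, w)
  bg <- !fg
  num <- .window_sum(m * bg, w)
  den <- .window_sum(bg + 0, w)
  gmean <- if (any(bg)) mean(m[bg]) else {
    warning("image has no presumable background; using the global mean",
            call. = FALSE)
    mean(m)
  }
  lbm <- num / den
  lbm[den < 0.5] <- gmean
  gsd <- suppressWarnings(
    estimate_global_background_sd(m, params$local_sd_window_px))
  structure(list(local_background_mean = lbm,
                 global_background_sd = gsd,
                 global_background_mean = gmean,
                 window_px = w),
            class = "background_model")
}

#' Segment the cell foreground against the background model
#'
#' A pixel is cell foreground when its intensity exceeds the local
#' background mean by `cell_sd_multiplier` (default 3) global background
#' SDs. Because both terms are background statistics, the threshold is
#' essentially independent of how bright nearby objects are.
#'
#' @param cell_image A [channel_image()] or matrix (the whole-cell stain).
#' @param model A [build_background_model()] fit on the same image.
#' @param params A [qic_params()].
#' @return Logical foreground matrix.
#' @export
segment_cells <- function(cell_image, model, params = qic_params()) {
  m <- .as_pixels(cell_image)
  if (!identical(dim(m), dim(model$local_background_mean)))
    stop("model was built on an image of different dimensions", call. = FALSE)
  thr <- model$local_background_mean +
    params$cell_sd_multiplier * model$global_background_sd
  m - thr > .threshold_tol(m)
}

#' Label connected foreground objects
#'
#' @param foreground Logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @param kind Mask kind for the result.
#' @return A [label_mask()]; labels run 1..n in row-major raster-scan
#'   discovery order.
#' @export
label_objects <- function(foreground, connectivity = 8L, kind = "nuclear") {
  stopifnot(is.matrix(foreground))
  mode(foreground) <- "logical"
  label_mask(cpp_label_components(foreground, as.integer(connectivity)),
             kind = kind)
}

#' Marker-controlled watershed
#'
#' Grows the seed regions over `mask`, admitting pixels in order of
#' decreasing `priority`, so the seeds flood the basins of the inverted
#' priority surface. Equal-priority ties are broken first-in-first-out and a
#' pixel joining several regions at once goes to the lowest-numbered one, so
#' the partition is fully deterministic. Masked pixels not reachable from
#' any seed remain 0.
#'
#' @param priority Numeric matrix; larger values are flooded first. Pass the
#'   image itself to split bright objects, or its negation to grow along
#'   dark valleys.
#' @param seeds Integer matrix of marker labels (0 elsewhere).
#' @param mask Logical matrix limiting the region to partition.
#' @param connectivity 4 or 8.
#' @return Integer label matrix.
#' @export
marker_watershed <- function(priority, seeds, mask, connectivity = 8L) {
  mode(mask) <- "logical"
  storage.mode(seeds) <- "integer"
  storage.mode(priority) <- "double"
  cpp_marker_watershed(priority, seeds, mask, as.integer(connectivity))
}

#' Limited-watershed splitting of intensity clumps
#'
#' Recursively separates an object into two (or more) sub-objects only when
#' the split is strongly supported by the intensity profile: the separating
#' watermark is the lowest intensity level at which thresholding the object
#' strictly above the level leaves at least two connected components, and
#' the split is accepted only if the summed intensity above that watermark
#' exceeds `retention` (default 0.85) of the object's total intensity.
#' Accepted splits are completed by a marker-controlled watershed with the
#' above-watermark components as markers, so the parent's area is fully
#' partitioned among the children; each child is then examined recursively.
#' An object with no admissible watermark — a single intensity peak —
#' is returned unsplit.
#'
#' @param mask Logical matrix selecting one connected region.
#' @param intensity Numeric matrix of the same dimensions.
#' @param retention Fraction of parental intensity that must survive above
#'   the watermark (default 0.85). At 1 or above nothing ever splits; near 0
#'   any separable object splits.
#' @param connectivity 4 or 8.
#' @param levels `"exact"` scans all unique intensities; `"quantized"` scans
#'   `n_levels` quantile levels.
#' @param n_levels Levels used in quantized mode.
#' @return Integer label matrix partitioning `mask` into the resulting
#'   sub-objects (labelled 1..k).
#' @export
limited_watershed_split <- function(mask, intensity, retention = 0.85,
                                    connectivity = 8L,
                                    levels = c("exact", "quantized"),
                                    n_levels = 256L) {
  levels <- match.arg(levels)
  stopifnot(is.matrix(mask), identical(dim(mask), dim(intensity)))
  mode(mask) <- "logical"
  out <- matrix(0L, nrow(mask), ncol(mask))
  if (!any(mask)) return(out)
  next_label <- 0L
  queue <- list(which(mask))
  while (length(queue) > 0) {
    idx <- queue[[1]]
    queue <- queue[-1]
    children <- .find_limited_split(idx, intensity, retention, connectivity,
                                    levels, n_levels, dim(mask))
    if (is.null(children)) {
      next_label <- next_label + 1L
      out[idx] <- next_label
    } else {
      queue <- c(children, queue)
    }
  }
  out
}

# Search the lowest separating watermark of the region given by linear
# indices `idx`; return NULL (no admissible split) or the list of child
# index vectors from the completing watershed.
.find_limited_split <- function(idx, intensity, retention, connectivity,
                                levels, n_levels, dims) {
  vals <- intensity[idx]
  total <- sum(vals)
  if (length(idx) < 2 || total <= 0) return(NULL)
  lv <- sort(unique(vals))
  if (levels == "quantized" && length(lv) > n_levels)
    lv <- unique(quantile(vals, probs = seq(0, 1, length.out = n_levels),
                          names = FALSE, type = 1))
  if (length(lv) < 2) return(NULL)

  # Work on the bounding box to keep labelling cheap.
  rows <- (idx - 1L) %% dims[1] + 1L
  cols <- (idx - 1L) %/% dims[1] + 1L
  r0 <- min(rows); c0 <- min(cols)
  bnr <- max(rows) - r0 + 1L; bnc <- max(cols) - c0 + 1L
  bidx <- (rows - r0) + (cols - c0) * bnr + 1L
  bmask <- matrix(FALSE, bnr, bnc)
  bmask[bidx] <- TRUE
  bint <- matrix(0, bnr, bnc)
  bint[bidx] <- vals

  for (L in lv[-length(lv)]) {
    above <- vals > L
    if (sum(above) < 2) break
    sub <- matrix(FALSE, bnr, bnc)
    sub[bidx[above]] <- TRUE
    lab <- cpp_label_components(sub, as.integer(connectivity))
    if (max(lab) >= 2L) {
      retained <- sum(vals[above])
      if (retained > retention * total) {
        part <- cpp_marker_watershed(bint, lab, bmask,
                                     as.integer(connectivity))
        child_of <- part[bidx]
        return(unname(split(idx, child_of)))
      }
      return(NULL)  # only the lowest separating watermark is examined
    }
  }
  NULL
}

#' Remove dim nuclear objects (debris, apoptotic fragments)
#'
#' Computes each object's total DNA intensity, estimates the typical G1-cell
#' total as the mode of the per-object total histogram (Freedman-Diaconis
#' binning), and removes objects below `min_fraction` (default 0.5) of that
#' mode. Pass `g1_total` to use a known absolute G1 level instead. With
#' fewer than `min_objects` objects the mode is unreliable and filtering is
#' skipped with a warning.
#'
#' @param mask A nuclear [label_mask()] or integer matrix.
#' @param dna_image The nuclear-stain [channel_image()] or matrix.
#' @param min_fraction Removal threshold as a fraction of the G1 mode.
#' @param min_objects Minimum object count for mode estimation (default 20).
#' @param g1_total Optional absolute typical G1 total intensity.
#' @return A [label_mask()] with surviving objects renumbered 1..k in
#'   raster-scan order.
#' @export
remove_dim_objects <- function(mask, dna_image, min_fraction = 0.5,
                               min_objects = 20L, g1_total = NULL) {
  m <- .as_labels(mask)
  dna <- .as_pixels(dna_image)
  stopifnot(identical(dim(m), dim(dna)))
  if (min_fraction <= 0) return(label_mask(m, kind = "nuclear"))
  totals <- .object_totals(m, dna)
  if (length(totals) == 0) return(label_mask(m, kind = "nuclear"))
  if (is.null(g1_total)) {
    if (length(totals) < min_objects) {
      warning(sprintf(paste0("only %d objects: G1 mode unreliable, ",
                             "dim-object filtering skipped"), length(totals)),
              call. = FALSE)
      return(label_mask(m, kind = "nuclear"))
    }
    g1_total <- .histogram_mode(totals)
  }
  keep <- as.integer(names(totals))[totals >= min_fraction * g1_total]
  .relabel_keep(m, keep)
}

# Per-label totals of `values` as a named vector (names = labels).
.object_totals <- function(labels, values) {
  pos <- labels > 0L
  if (!any(pos)) return(setNames(numeric(0), character(0)))
  vapply(split(values[pos], labels[pos]), sum, numeric(1))
}

# Keep the given labels, renumbering survivors 1..k in raster-scan order of
# first appearance (row-major).
.relabel_keep <- function(labels, keep) {
  out <- matrix(0L, nrow(labels), ncol(labels))
  if (length(keep) > 0) {
    tl <- t(labels)  # row-major first appearance
    first <- vapply(keep, function(l) which(tl == l)[1], numeric(1))
    keep <- keep[order(first)]
    map <- integer(max(labels))
    map[keep] <- seq_along(keep)
    sel <- labels > 0L
    mapped <- rep(0L, length(labels))
    mapped[sel] <- map[labels[sel]]
    out[] <- mapped
  }
  label_mask(out, kind = "nuclear")
}

#' Divide the cell foreground into one region per nucleus
#'
#' Nuclei are first unioned into the foreground (a nucleus protruding from
#' the stained cell body must still end up inside its cell), then each
#' foreground component is partitioned among the nuclei it contains by a
#' marker-controlled watershed descending the cell-stain intensity
#' (equivalently, flooding the inverted intensity from the nuclear markers).
#' Components containing no nucleus are discarded. Each surviving cell label
#' equals its nucleus label.
#'
#' @param cell_foreground Logical matrix from [segment_cells()].
#' @param nuclei Nuclear [label_mask()].
#' @param cell_image The cell-stain [channel_image()] or matrix.
#' @param connectivity 4 or 8.
#' @return A cellular [label_mask()].
#' @export
divide_cell_mask <- function(cell_foreground, nuclei, cell_image,
                             connectivity = 8L) {
  seeds <- .as_labels(nuclei)
  m <- .as_pixels(cell_image)
  stopifnot(identical(dim(seeds), dim(cell_foreground)),
            identical(dim(seeds), dim(m)))
  fg <- cell_foreground | seeds > 0L
  lab <- marker_watershed(m, seeds, fg, connectivity)
  label_mask(lab, kind = "cellular")
}

#' Identify individual cells in a field
#'
#' Runs the full cell-identification cascade on one field:
#' \enumerate{
#'   \item nuclear channel: local-mean thresholding (41 px window),
#'     connected-component labelling, and a bright-object check that drops
#'     labelled speckle whose mean intensity does not clear the local
#'     background by `bright_object_sd_multiplier` background SDs;
#'   \item limited-watershed splitting of nuclear clumps
#'     ([limited_watershed_split()]);
#'   \item removal of dim objects (debris, fragments) relative to the
#'     typical G1 DNA total ([remove_dim_objects()]);
#'   \item cell channel: background model and 3-SD thresholding
#'     ([build_background_model()], [segment_cells()]), logical union with
#'     the nuclear foreground, and marker-controlled division so every cell
#'     contains exactly one nucleus ([divide_cell_mask()]).
#' }
#'
#' @param field A [field_image_set()].
#' @param params A [qic_params()].
#' @return A list with elements `nuclei` and `cells` (matched
#'   [label_mask()]s: cell label k contains exactly nucleus label k) plus
#'   `background_models` (nuclear and cell channel models, reused by
#'   [measure_cells()]).
#' @export
identify_cells <- function(field, params = qic_params()) {
  stopifnot(inherits(field, "field_image_set"))
  conn <- params$connectivity
  ni <- field$nuclear$pixels
  ci <- field$cell$pixels
  if (min(dim(ni)) < max(params$nuclear_window_px, params$background_window_px))
    stop("field images are smaller than the analysis window", call. = FALSE)

  nuc_model <- build_background_model(ni, params)
  fg_n <- local_mean_threshold(ni, params$nuclear_window_px)
  lab_n <- .as_labels(label_objects(fg_n, conn, kind = "nuclear"))
  lab_n <- .filter_bright_objects(lab_n, ni, nuc_model,
                                  params$bright_object_sd_multiplier,
                                  params$min_object_px)

  # Split nuclear clumps object by object.
  split_lab <- matrix(0L, nrow(lab_n), ncol(lab_n))
  nl <- 0L
  for (l in sort(unique(lab_n[lab_n > 0L]))) {
    obj <- lab_n == l
    part <- limited_watershed_split(obj, ni,
                                    retention = params$watershed_retention,
                                    connectivity = conn,
                                    levels = params$watershed_levels,
                                    n_levels = params$watershed_n_levels)
    k <- max(part)
    split_lab[part > 0L] <- part[part > 0L] + nl
    nl <- nl + k
  }

  nuclei <- remove_dim_objects(split_lab, ni,
                               min_fraction = params$min_dna_fraction_of_g1,
                               min_objects = params$min_objects_for_g1,
                               g1_total = params$g1_total)

  cell_model <- build_background_model(ci, params)
  fg_c <- segment_cells(ci, cell_model, params)
  cells <- divide_cell_mask(fg_c, nuclei, ci, conn)
  list(nuclei = nuclei, cells = cells,
       background_models = list(nuclear = nuc_model, cell = cell_model))
}

# Drop labelled objects whose mean intensity does not exceed the local
# background mean by `k` global background SDs, or that are smaller than
# `min_px` pixels; relabel survivors. Both criteria target the noise speckle
# that strict local-mean thresholding admits in flat background.
.filter_bright_objects <- function(labels, image, model, k, min_px = 0L) {
  if (max(labels) == 0L) return(labels)
  pos <- labels > 0L
  grp <- split(image[pos], labels[pos])
  obj_mean <- vapply(grp, mean, numeric(1))
  obj_area <- lengths(grp)
  bg_mean <- vapply(split(model$local_background_mean[pos], labels[pos]),
                    mean, numeric(1))
  keep <- as.integer(names(obj_mean))[
    obj_mean > bg_mean + k * model$global_background_sd & obj_area >= min_px]
  .as_labels(.relabel_keep(labels, keep))
}
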