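#' End-to-end pipeline: segmentation, quantification, statistics
#'
#' Runs [identify_cells()] and [measure_cells()] (plus [hcs_quantify()] when
#' requested) on every field, applies the single-nucleus roundness filter
#' (and optionally drops ill-identified cells — by default they are kept, so
#' population averages stay comparable across quantification methods),
#' computes per-timepoint statistics when a channel pair is given, and
#' returns a machine-readable run report. The pipeline contains no
#' randomness: identical inputs and parameters give byte-identical output
#' tables.
#'
#' @param fields A list of [field_image_set()]s (one per acquired field).
#' @param params A [qic_params()].
#' @param mode `"qic"` (contour-based quantification), `"hcs"` (baseline
#'   dilated-nucleus quantification) or `"both"`.
#' @param exclude_ill_identified Drop flagged ill-identified cells before
#'   statistics (default `FALSE`: whole cells are used).
#' @param exclude_multi_nucleated Apply the roundness single-nucleus filter
#'   (default `TRUE`).
#' @param stats_channels Optional length-2 channel names for
#'   [timepoint_stats()].
#' @param nli_strategy Passed to [measure_cells()].
#' @param out_dir Optional directory: writes `cells.csv`, `stats.csv` (when
#'   computed), per-field label masks and `report.json`-style text.
#' @return A list of class `"qic_run"`: `cells` (filtered per-cell table),
#'   `cells_all` (unfiltered, with flags), `stats` (or `NULL`), `masks`
#'   (per-field nuclear/cellular label masks) and `report` (parameters and
#'   per-stage cell counts; each stage satisfies in = out + excluded).
#' @export
run_pipeline <- function(fields, params = qic_params(),
                         mode = c("qic", "hcs", "both"),
                         exclude_ill_identified = FALSE,
                         exclude_multi_nucleated = TRUE,
                         stats_channels = NULL,
                         nli_strategy = "per_cell_ratio",
                         out_dir = NULL) {
  mode <- match.arg(mode)
  if (inherits(fields, "field_image_set")) fields <- list(fields)
  stopifnot(length(fields) > 0,
            all(vapply(fields, inherits, logical(1), "field_image_set")))

  per_field <- vector("list", length(fields))
  masks <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    fld <- fields[[i]]
    seg <- identify_cells(fld, params)
    tab <- measure_cells(fld, seg$nuclei, seg$cells, params,
                         nli_strategy = nli_strategy)
    if (mode %in% c("hcs", "both")) {
      htab <- hcs_quantify(seg$nuclei, fld, params$hcs)
      tab <- merge(tab, htab, by = "cell_id", sort = TRUE)
    }
    per_field[[i]] <- tab
    masks[[i]] <- list(well_id = fld$well_id, field_index = fld$field_index,
                       nuclei = seg$nuclei, cells = seg$cells)
  }
  cells_all <- do.call(rbind, per_field)
  rownames(cells_all) <- NULL

  n_identified <- nrow(cells_all)
  keep <- rep(TRUE, n_identified)
  n_multi <- 0L
  if (exclude_multi_nucleated) {
    n_multi <- sum(cells_all$flag_multi_nucleated & keep)
    keep <- keep & !cells_all$flag_multi_nucleated
  }
  n_ill <- 0L
  if (exclude_ill_identified) {
    n_ill <- sum(cells_all$flag_ill_identified & keep, na.rm = TRUE)
    keep <- keep & !(cells_all$flag_ill_identified %in% TRUE)
  }
  cells <- cells_all[keep, , drop = FALSE]
  rownames(cells) <- NULL

  stats <- NULL
  if (!is.null(stats_channels))
    stats <- timepoint_stats(cells, stats_channels)

  report <- list(
    parameters = unclass(params),
    mode = mode,
    n_fields = length(fields),
    counts = list(identified = n_identified,
                  excluded_multi_nucleated = n_multi,
                  excluded_ill_identified = n_ill,
                  analyzed = nrow(cells)),
    flags = list(ill_identified_fraction =
                   if (n_identified > 0)
                     mean(cells_all$flag_ill_identified %in% TRUE) else NA_real_)
  )

  run <- structure(list(cells = cells, cells_all = cells_all, stats = stats,
                        masks = masks, report = report),
                   class = "qic_run")
  if (!is.null(out_dir)) .write_run(run, out_dir)
  run
}

#' @export
print.qic_run <- function(x, ...) {
  cnt <- x$report$counts
  cat(sprintf(paste0("<qic_run: %d field(s), %d cells identified, ",
                     "%d analyzed (%d multinucleated, %d ill-identified ",
                     "excluded)>\n"),
              x$report$n_fields, cnt$identified, cnt$analyzed,
              cnt$excluded_multi_nucleated, cnt$excluded_ill_identified))
  invisible(x)
}

.write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cell_table(run$cells, file.path(out_dir, "cells.csv"))
  write_cell_table(run$cells_all, file.path(out_dir, "cells_all.csv"))
  if (!is.null(run$stats))
    write_cell_table(run$stats, file.path(out_dir, "stats.csv"))
  for (m in run$masks) {
    stem <- sprintf("%s_f%02d", m$well_id, m$field_index)
    write_label_mask(m$nuclei, file.path(out_dir, paste0(stem, "_nuclei.tif")))
    write_label_mask(m$cells, file.path(out_dir, paste0(stem, "_cells.tif")))
  }
  rep <- run$report
  rep$parameters$hcs <- unclass(rep$parameters$hcs)
  writeLines(.to_json(rep), file.path(out_dir, "report.json"))
  invisible(out_dir)
}

# Minimal JSON serializer for the run report (scalars, vectors, lists).
.to_json <- function(x) {
  if (is.null(x)) return("null")
  if (is.list(x)) {
    if (is.null(names(x)))
      return(paste0("[", paste(vapply(x, .to_json, character(1)),
                               collapse = ","), "]"))
    return(paste0("{", paste(sprintf('"%s":%s', names(x),
                                     vapply(x, .to_json, character(1))),
                             collapse = ","), "}"))
  }
  if (length(x) != 1)
    return(paste0("[", paste(vapply(x, .to_json, character(1)),
                             collapse = ","), "]"))
  if (is.character(x)) return(sprintf('"%s"', x))
  if (is.logical(x)) return(if (is.na(x)) "null" else tolower(as.character(x)))
  if (is.na(x)) return("null")
  sprintf("%.17g", as.numeric(x))
}
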