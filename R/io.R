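#' Read one microscope field from per-channel image files
#'
#' Reads single-plane grayscale TIFF (or PNG) files, one per channel, into a
#' [field_image_set()]. Intensities are kept in the file's native units: a
#' 16-bit TIFF stored as integer counts comes back as those counts.
#' Alternatively a single multi-page TIFF may be given, whose pages are taken
#' as channels in the order nuclear, cell, antigens.
#'
#' @param nuclear,cell Paths to the nuclear-stain and cell-stain images.
#' @param antigens Named character vector of antigen image paths (names are
#'   the channel names, e.g. `c(pERK = "perk.tif")`).
#' @param stack Path to a multi-page TIFF holding all channels; used instead
#'   of the per-channel paths. `antigen_names` labels pages 3+.
#' @param antigen_names Channel names for the antigen pages of `stack`.
#' @param ... Metadata passed to [field_image_set()] (`well_id`,
#'   `field_index`, `time_min`, `treatment`, `experiment_id`).
#' @return A [field_image_set()].
#' @export
read_field <- function(nuclear = NULL, cell = NULL, antigens = character(),
                       stack = NULL, antigen_names = NULL, ...) {
  if (!is.null(stack)) {
    pages <- .read_gray(stack, all_pages = TRUE)
    if (length(pages) < 2)
      stop("multi-page stack must hold at least nuclear and cell channels",
           call. = FALSE)
    n_ant <- length(pages) - 2L
    if (is.null(antigen_names)) antigen_names <- paste0("antigen", seq_len(n_ant))
    ants <- if (n_ant > 0) setNames(pages[-(1:2)], antigen_names) else list()
    return(field_image_set(pages[[1]], pages[[2]], ants, ...))
  }
  if (is.null(nuclear) || is.null(cell))
    stop("both a nuclear and a cell channel are required", call. = FALSE)
  ants <- lapply(antigens, .read_gray)
  names(ants) <- names(antigens)
  field_image_set(.read_gray(nuclear), .read_gray(cell), ants, ...)
}

.read_gray <- function(path, all_pages = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  to_matrix <- function(a) {
    if (length(dim(a)) == 3) {
      if (dim(a)[3] > 1)
        stop(sprintf("%s is not single-plane grayscale", path), call. = FALSE)
      a <- a[, , 1]
    }
    storage.mode(a) <- "double"
    a
  }
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE, all = all_pages)
    if (all_pages) {
      if (!is.list(img)) img <- list(img)
      lapply(img, to_matrix)
    } else to_matrix(img)
  } else if (ext == "png") {
    img <- png::readPNG(path)
    to_matrix(img)
  } else {
    stop(sprintf("unsupported image format: %s", path), call. = FALSE)
  }
}

#' Write a label mask as a 16-bit TIFF
#'
#' Labels are stored as 16-bit integer pixel values (label / 65535 in the
#' file's normalized scale), so masks round-trip exactly for up to 65535
#' objects.
#'
#' @param mask A [label_mask()] or integer matrix.
#' @param path Output path (`.tif`).
#' @export
write_label_mask <- function(mask, path) {
  m <- .as_labels(mask)
  if (max(m) > 65535L) stop("more than 65535 labels", call. = FALSE)
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a label mask written by [write_label_mask()]
#' @param path Path to the 16-bit label TIFF.
#' @param kind `"nuclear"` or `"cellular"`.
#' @return A [label_mask()].
#' @export
read_label_mask <- function(path, kind = "nuclear") {
  m <- tiff::readTIFF(path, as.is = TRUE)
  label_mask(round(m), kind = kind)
}

# Column order of the per-cell table; kept stable so downstream consumers can
# rely on it. Channel-dependent columns are appended in channel order.
.cell_table_key_cols <- c("cell_id", "well_id", "field_index", "time_min",
                          "treatment", "experiment_id")

#' Write the per-cell table to CSV
#'
#' One row per cell; numeric fields are serialized with 17 significant
#' digits so that reading the file back reproduces them bit-exactly; flags
#' are written as TRUE/FALSE.
#'
#' @param table Per-cell data frame as produced by [measure_cells()] or
#'   [run_pipeline()].
#' @param path Output CSV path.
#' @export
write_cell_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  out <- table
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- NA
      out[[j]] <- v
    }
  }
  write.csv(out, path, row.names = FALSE, quote = TRUE, na = "NA")
  invisible(path)
}

#' Read a per-cell table written by [write_cell_table()]
#' @param path CSV path.
#' @return A data frame with the same column types as written.
#' @export
read_cell_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  int_cols <- c("cell_id", "field_index", "n_cells", "n_excluded")
  for (j in seq_along(df)) {
    nm <- names(df)[j]
    if (grepl("^flag_", nm)) {
      df[[j]] <- as.logical(df[[j]])
    } else if (is.integer(df[[j]]) && !(nm %in% int_cols)) {
      # measurement columns are doubles even when their values are integral
      df[[j]] <- as.double(df[[j]])
    } else if (is.logical(df[[j]]) && all(is.na(df[[j]])) &&
               nm %in% c("time_min")) {
      df[[j]] <- as.double(df[[j]])
    }
  }
  df
}

#' Read a plate layout CSV
#'
#' Expected columns: `well_id`, `treatment`, `time_min`, `experiment_id`.
#'
#' @param path CSV path.
#' @return A data frame keyed by `well_id`.
#' @export
read_layout <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("well_id", "treatment", "time_min", "experiment_id")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop(sprintf("layout is missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  if (anyDuplicated(df$well_id))
    stop("layout has duplicated well_id entries", call. = FALSE)
  df
}
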