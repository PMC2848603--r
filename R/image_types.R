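#' Single-channel fluorescence image
#'
#' Wraps one 2-D grayscale intensity matrix together with its channel role.
#' Intensities are carried in native arbitrary units; nothing is rescaled.
#'
#' @param pixels Numeric matrix of finite, non-negative intensities.
#' @param role One of `"nuclear"` (DNA stain), `"cell"` (whole-cell stain) or
#'   `"antigen"` (immunostain).
#' @param channel_name Free-text channel name, e.g. `"pERK"`. Defaults to the
#'   role.
#' @param pixel_size_um Optional physical pixel size in micrometers.
#' @return A list of class `"channel_image"` with elements `pixels`, `role`,
#'   `channel_name`, `pixel_size_um`.
#' @export
channel_image <- function(pixels, role = c("nuclear", "cell", "antigen"),
                          channel_name = NULL, pixel_size_um = NULL) {
  role <- match.arg(role)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix", call. = FALSE)
  storage.mode(pixels) <- "double"
  if (any(!is.finite(pixels)))
    stop("pixel intensities must all be finite", call. = FALSE)
  if (any(pixels < 0))
    stop("pixel intensities must all be >= 0", call. = FALSE)
  if (is.null(channel_name)) channel_name <- role
  structure(list(pixels = pixels, role = role,
                 channel_name = channel_name,
                 pixel_size_um = pixel_size_um),
            class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image '%s' (%s), %d x %d, range [%g, %g]>\n",
              x$channel_name, x$role, nrow(x$pixels), ncol(x$pixels),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

.as_pixels <- function(image) {
  if (inherits(image, "channel_image")) image$pixels
  else if (is.matrix(image) && is.numeric(image)) image
  else stop("expected a channel_image or a numeric matrix", call. = FALSE)
}

#' One microscope field with its aligned channels and metadata
#'
#' @param nuclear,cell [channel_image()]s (or bare matrices) for the nuclear
#'   and whole-cell stains.
#' @param antigens Named list of 0-2 antigen [channel_image()]s; bare
#'   matrices are wrapped, the list names becoming channel names.
#' @param well_id,field_index,time_min,treatment,experiment_id Acquisition
#'   metadata: well (e.g. `"B03"`), field number within the well, minutes
#'   since stimulation, treatment label, experiment identifier.
#' @return A list of class `"field_image_set"`.
#' @export
field_image_set <- function(nuclear, cell, antigens = list(),
                            well_id = "A01", field_index = 1L,
                            time_min = NA_real_, treatment = NA_character_,
                            experiment_id = "exp1") {
  wrap <- function(x, role, name) {
    if (inherits(x, "channel_image")) {
      if (x$role != role)
        stop(sprintf("channel '%s' must have role '%s'", x$channel_name, role),
             call. = FALSE)
      x
    } else channel_image(x, role = role, channel_name = name)
  }
  nuclear <- wrap(nuclear, "nuclear", "dna")
  cell <- wrap(cell, "cell", "cellstain")
  if (length(antigens) > 0) {
    if (is.null(names(antigens)) || any(!nzchar(names(antigens))))
      names(antigens) <- paste0("antigen", seq_along(antigens))
    antigens <- Map(wrap, antigens, "antigen", names(antigens))
  }
  if (length(antigens) > 2)
    stop("at most two antigen channels are supported", call. = FALSE)
  dims <- dim(nuclear$pixels)
  for (ch in c(list(cell), unname(antigens))) {
    if (!identical(dim(ch$pixels), dims))
      stop(sprintf("channel '%s' dimensions (%d x %d) differ from nuclear (%d x %d)",
                   ch$channel_name, nrow(ch$pixels), ncol(ch$pixels),
                   dims[1], dims[2]), call. = FALSE)
  }
  structure(list(nuclear = nuclear, cell = cell, antigens = antigens,
                 well_id = well_id, field_index = as.integer(field_index),
                 time_min = time_min, treatment = treatment,
                 experiment_id = experiment_id),
            class = "field_image_set")
}

#' @export
print.field_image_set <- function(x, ...) {
  cat(sprintf("<field_image_set well %s field %d (%d x %d), %d antigen channel(s)>\n",
              x$well_id, x$field_index, nrow(x$nuclear$pixels),
              ncol(x$nuclear$pixels), length(x$antigens)))
  invisible(x)
}

#' Integer-labelled segmentation mask
#'
#' A label mask is an integer matrix where 0 is background and each positive
#' label is one connected object.
#'
#' @param labels Integer matrix, 0 = background.
#' @param kind `"nuclear"` or `"cellular"`.
#' @return The integer matrix with class `"label_mask"` and a `kind`
#'   attribute.
#' @export
label_mask <- function(labels, kind = c("nuclear", "cellular")) {
  kind <- match.arg(kind)
  if (!is.matrix(labels)) stop("labels must be a matrix", call. = FALSE)
  storage.mode(labels) <- "integer"
  if (any(labels < 0L, na.rm = TRUE))
    stop("labels must be non-negative", call. = FALSE)
  structure(labels, class = c("label_mask", class(labels)), kind = kind)
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<%s label_mask %d x %d, %d object(s)>\n",
              attr(x, "kind"), nrow(x), ncol(x), n_objects(x)))
  invisible(x)
}

.as_labels <- function(x) {
  m <- unclass(x)
  attr(m, "kind") <- NULL
  storage.mode(m) <- "integer"
  m
}

#' Number of objects in a label mask
#' @param mask A [label_mask()] or integer matrix.
#' @return Number of distinct positive labels.
#' @export
n_objects <- function(mask) {
  m <- .as_labels(mask)
  length(unique(m[m > 0L]))
}
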