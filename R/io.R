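#' Write a synthetic image set to disk
#'
#' Each field is written as a multi-page 16-bit TIFF (pages ordered
#' channel-major: all z-planes of DAPI, then PCNT, then GTUB if present)
#' together with an OME-XML companion metadata file carrying the channel
#' names and the physical pixel/z calibration. The ground truth is written
#' as a CSV (one row per cell) and the configuration is echoed as JSON.
#'
#' @param set A `ccs_image_set` from [simulate_image_set()].
#' @param dir Output directory (created if needed).
#' @param max_count Full-scale camera count mapped to the 16-bit maximum.
#' @return Invisibly, the paths of the TIFF files written.
#' @export
write_image_set <- function(set, dir, max_count = 4096) {
  stopifnot(inherits(set, "ccs_image_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (f in seq_along(set$fields)) {
    stem <- sprintf("field_%03d", f)
    path <- file.path(dir, paste0(stem, ".ome.tif"))
    write_stack(set$fields[[f]], path, max_count = max_count)
    paths <- c(paths, path)
  }
  utils::write.csv(set$truth, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  if (nrow(set$decoys) > 0) {
    utils::write.csv(set$decoys, file.path(dir, "decoys.csv"), row.names = FALSE)
  }
  cfg <- set$config
  cfg$cell_class_mix <- as.list(cfg$cell_class_mix)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(paths)
}

#' @rdname write_image_set
#' @param stack A `ccs_image_stack`.
#' @param path Output TIFF path; the companion metadata file is written next
#'   to it with extension `.companion.ome.xml`.
#' @export
write_stack <- function(stack, path, max_count = 4096) {
  stopifnot(inherits(stack, "ccs_image_stack"))
  pages <- list()
  for (ch in names(stack$channels)) {
    arr <- stack$channels[[ch]]
    for (k in seq_len(dim(arr)[3])) {
      pages[[length(pages) + 1]] <- pmin(arr[, , k] / max_count, 1)
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "LZW")
  xml2::write_xml(build_ome_xml(stack), companion_path(path))
  invisible(path)
}

companion_path <- function(path) {
  sub("\\.(ome\\.)?tiff?$", ".companion.ome.xml", path, ignore.case = TRUE)
}

build_ome_xml <- function(stack) {
  d <- dim(stack$channels[[1]])
  doc <- xml2::xml_new_root(
    "OME", xmlns = "http://www.openmicroscopy.org/Schemas/OME/2016-06")
  img <- xml2::xml_add_child(doc, "Image", ID = "Image:0",
                             Name = stack$source %||% "image")
  px <- xml2::xml_add_child(
    img, "Pixels", ID = "Pixels:0", DimensionOrder = "XYZCT", Type = "uint16",
    SizeX = d[2], SizeY = d[1], SizeZ = d[3],
    SizeC = length(stack$channels), SizeT = 1,
    PhysicalSizeX = stack$pixel_size_um, PhysicalSizeXUnit = "um",
    PhysicalSizeY = stack$pixel_size_um, PhysicalSizeYUnit = "um",
    PhysicalSizeZ = stack$z_step_um, PhysicalSizeZUnit = "um")
  for (i in seq_along(stack$channels)) {
    xml2::xml_add_child(px, "Channel", ID = sprintf("Channel:0:%d", i - 1),
                        Name = names(stack$channels)[i], SamplesPerPixel = 1)
  }
  doc
}

parse_ome_xml <- function(x) {
  doc <- tryCatch(xml2::read_xml(x), error = function(e) NULL)
  if (is.null(doc)) return(NULL)
  xml2::xml_ns_strip(doc)
  px <- xml2::xml_find_first(doc, ".//Pixels")
  if (inherits(px, "xml_missing")) return(NULL)
  num <- function(a) {
    v <- xml2::xml_attr(px, a)
    if (is.na(v)) NA_real_ else as.numeric(v)
  }
  list(
    size = c(y = num("SizeY"), x = num("SizeX"), z = num("SizeZ"), c = num("SizeC")),
    pixel_size_um = num("PhysicalSizeX"),
    z_step_um = num("PhysicalSizeZ"),
    channels = xml2::xml_attr(xml2::xml_find_all(px, ".//Channel"), "Name")
  )
}

#' Load a multi-channel z-stack from a TIFF file
#'
#' Reads a multi-page TIFF (pages channel-major over z) and attaches channel
#' names and physical calibration from, in order of precedence: explicit
#' arguments, OME-XML embedded in the TIFF ImageDescription tag, or an
#' OME-XML companion file next to the TIFF. A DAPI and a PCNT channel are
#' required; GTUB is optional.
#'
#' @param path TIFF file path.
#' @param channel_map Optional named integer vector/list mapping channel
#'   names to 1-based channel indices, e.g. `c(DAPI = 1, PCNT = 2)`.
#'   Overrides metadata channel names.
#' @param pixel_size_um,z_step_um Optional calibration overrides; an explicit
#'   pixel size always wins over metadata (a message notes the override).
#' @param n_z Optional number of z-planes per channel when no metadata states
#'   it; defaults to all pages in one channel if only one channel is mapped.
#' @return A `ccs_image_stack`.
#' @export
load_stack <- function(path, channel_map = NULL, pixel_size_um = NULL,
                       z_step_um = NULL, n_z = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "ccs_input_error")
  }
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- NULL
  desc <- attr(pages[[1]], "description")
  if (!is.null(desc) && grepl("<OME", desc, fixed = TRUE)) {
    meta <- parse_ome_xml(desc)
  }
  comp <- companion_path(path)
  if (is.null(meta) && file.exists(comp)) meta <- parse_ome_xml(comp)

  if (is.null(channel_map)) {
    if (is.null(meta) || length(meta$channels) == 0) {
      abort("no channel metadata found; supply `channel_map`.",
            class = "ccs_input_error")
    }
    channel_map <- stats::setNames(seq_along(meta$channels), meta$channels)
  }
  channel_map <- unlist(channel_map)
  for (need in c("DAPI", "PCNT")) {
    if (!need %in% names(channel_map)) {
      abort(sprintf("required channel '%s' is missing from the stack.", need),
            class = "ccs_input_error")
    }
  }
  nz <- n_z
  if (is.null(nz) && !is.null(meta) && !is.na(meta$size[["z"]])) {
    nz <- meta$size[["z"]]
  }
  if (is.null(nz)) nz <- length(pages) / max(channel_map)
  if (nz != as.integer(nz) || length(pages) < max(channel_map) * nz) {
    abort("page count is inconsistent with the channel map / z size.",
          class = "ccs_input_error")
  }
  nz <- as.integer(nz)

  ps_meta <- if (!is.null(meta)) meta$pixel_size_um else NA_real_
  if (!is.null(pixel_size_um)) {
    if (!is.na(ps_meta) && abs(ps_meta - pixel_size_um) > 1e-12) {
      message(sprintf("pixel size override: using %.4g um/px instead of metadata %.4g um/px",
                      pixel_size_um, ps_meta))
    }
    ps <- pixel_size_um
  } else if (!is.na(ps_meta)) {
    ps <- ps_meta
  } else {
    abort("no pixel size in metadata and no `pixel_size_um` override supplied.",
          class = "ccs_calibration_error")
  }
  zs <- z_step_um %||% (if (!is.null(meta) && !is.na(meta$z_step_um)) meta$z_step_um else NA_real_)

  channels <- lapply(channel_map, function(ci) {
    planes <- pages[(ci - 1) * nz + seq_len(nz)]
    arr <- array(0, dim = c(nrow(planes[[1]]), ncol(planes[[1]]), nz))
    for (k in seq_len(nz)) arr[, , k] <- planes[[k]]
    arr
  })
  names(channels) <- names(channel_map)
  new_image_stack(channels, ps, zs, source = path)
}
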