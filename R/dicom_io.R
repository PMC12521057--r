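# Minimal single-frame CT DICOM support: explicit VR little endian only,
# which is also the only transfer syntax the writer emits. Enough of the
# standard to carry geometry, HU calibration and pixel data; sequences and
# compressed syntaxes are rejected with a clear error.

DCM_UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
DCM_UID_CT_STORAGE  <- "1.2.840.10008.5.1.4.1.1.2"

# deterministic numeric hash of a string -> digits usable inside a UID
dcm_uid_digits <- function(s) {
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 131 + v) %% 1e12
  sprintf("%.0f", h)
}

dcm_pad_even <- function(raw, pad = as.raw(0x20)) {
  if (length(raw) %% 2 == 1) c(raw, pad) else raw
}

dcm_uint16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
dcm_uint32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

# serialize one data element, explicit VR little endian
dcm_element <- function(group, element, vr, value) {
  body <- switch(vr,
    US = dcm_uint16(value),
    UL = dcm_uint32(value),
    UI = dcm_pad_even(charToRaw(value), as.raw(0x00)),
    OB = dcm_pad_even(value, as.raw(0x00)),
    OW = value,
    dcm_pad_even(charToRaw(value))  # DS/IS/CS/SH/LO and other string VRs
  )
  head <- c(dcm_uint16(group), dcm_uint16(element), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)), dcm_uint32(length(body)), body)
  } else {
    if (length(body) > 65534) stop("value too long for short-form VR ", vr)
    c(head, dcm_uint16(length(body)), body)
  }
}

dcm_ds <- function(x) paste(vapply(x, function(v) sprintf("%.10g", v), ""), collapse = "\\")

#' Write a CT volume as a DICOM series
#'
#' Writes one explicit-VR little-endian single-frame CT file per slice. Pixel
#' values are stored as signed 16-bit integers with the given rescale slope
#' and intercept, so `load_ct_series()` of the written directory reproduces
#' the HU array exactly whenever the HU values lie on the storage grid
#' `slope * k + intercept` (phantoms from [make_phantom()] do by
#' construction).
#'
#' @param volume A [ct_volume()].
#' @param directory_path Output directory, created if needed.
#' @param rescale_slope,rescale_intercept HU calibration of the stored
#'   integers: HU = stored * slope + intercept. The default 0.1 HU slope
#'   resolves sub-HU noise texture; an error is raised if the volume's HU
#'   range does not fit in 16 signed bits under the chosen calibration.
#' @return Invisibly, the character vector of files written.
#' @export
write_ct_series <- function(volume, directory_path,
                            rescale_slope = 0.1, rescale_intercept = -1024) {
  stopifnot(inherits(volume, "ct_volume"), rescale_slope > 0)
  dir.create(directory_path, recursive = TRUE, showWarnings = FALSE)
  d <- dim(volume$slices)
  stored_range <- range((range(volume$slices) - rescale_intercept) / rescale_slope)
  if (stored_range[1] < -32768 || stored_range[2] > 32767) {
    stop(sprintf(
      "HU range [%.1f, %.1f] is not representable as int16 with slope %g / intercept %g",
      min(volume$slices), max(volume$slices), rescale_slope, rescale_intercept),
      call. = FALSE)
  }
  study_uid  <- paste0("2.25.1.", dcm_uid_digits(volume$exam_id))
  series_uid <- paste0("2.25.2.", dcm_uid_digits(paste0(volume$exam_id, "/", volume$series_id)))
  files <- character(d[1])
  for (i in seq_len(d[1])) {
    sop_uid <- paste0(series_uid, ".", i)
    stored <- round((volume$slices[i, , ] - rescale_intercept) / rescale_slope)
    pix <- writeBin(as.integer(t(stored)), raw(), size = 2, endian = "little")

    meta <- c(
      dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
      dcm_element(0x0002, 0x0002, "UI", DCM_UID_CT_STORAGE),
      dcm_element(0x0002, 0x0003, "UI", sop_uid),
      dcm_element(0x0002, 0x0010, "UI", DCM_UID_EXPLICIT_LE),
      dcm_element(0x0002, 0x0012, "UI", "2.25.0.1")
    )
    dataset <- c(
      dcm_element(0x0008, 0x0008, "CS", "ORIGINAL\\PRIMARY\\AXIAL"),
      dcm_element(0x0008, 0x0016, "UI", DCM_UID_CT_STORAGE),
      dcm_element(0x0008, 0x0018, "UI", sop_uid),
      dcm_element(0x0008, 0x0060, "CS", "CT"),
      dcm_element(0x0008, 0x103E, "LO", volume$series_id),
      dcm_element(0x0018, 0x0050, "DS", dcm_ds(volume$slice_thickness_mm)),
      dcm_element(0x0020, 0x000D, "UI", study_uid),
      dcm_element(0x0020, 0x000E, "UI", series_uid),
      dcm_element(0x0020, 0x0010, "SH", volume$exam_id),
      dcm_element(0x0020, 0x0011, "IS", "1"),
      dcm_element(0x0020, 0x0013, "IS", sprintf("%d", i)),
      dcm_element(0x0020, 0x0032, "DS", dcm_ds(c(0, 0, volume$slice_positions_mm[i]))),
      dcm_element(0x0020, 0x0037, "DS", dcm_ds(c(1, 0, 0, 0, 1, 0))),
      dcm_element(0x0028, 0x0002, "US", 1),
      dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dcm_element(0x0028, 0x0010, "US", d[2]),
      dcm_element(0x0028, 0x0011, "US", d[3]),
      dcm_element(0x0028, 0x0030, "DS", dcm_ds(volume$pixel_spacing_mm)),
      dcm_element(0x0028, 0x0100, "US", 16),
      dcm_element(0x0028, 0x0101, "US", 16),
      dcm_element(0x0028, 0x0102, "US", 15),
      dcm_element(0x0028, 0x0103, "US", 1),
      dcm_element(0x0028, 0x1052, "DS", dcm_ds(rescale_intercept)),
      dcm_element(0x0028, 0x1053, "DS", dcm_ds(rescale_slope)),
      dcm_element(0x7FE0, 0x0010, "OW", pix)
    )
    group_len <- dcm_element(0x0002, 0x0000, "UL", length(meta))
    path <- file.path(directory_path,
                      sprintf("%s_%s_%04d.dcm", volume$exam_id, volume$series_id, i))
    con <- file(path, "wb")
    writeBin(c(raw(128), charToRaw("DICM"), group_len, meta, dataset), con)
    close(con)
    files[i] <- path
  }
  invisible(files)
}

# parse all elements of one explicit-VR-LE file into a named list keyed
# "GGGG,EEEE"; raw payloads, decoded lazily by callers
dcm_parse_file <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM") {
    stop("not a DICOM file (missing DICM magic): ", path, call. = FALSE)
  }
  out <- list()
  pos <- 133L
  n <- length(bytes)
  u16 <- function(i) readBin(bytes[i:(i + 1)], "integer", size = 2,
                             endian = "little", signed = FALSE)
  u32 <- function(i) readBin(bytes[i:(i + 3)], "integer", size = 4, endian = "little")
  while (pos + 7L <= n) {
    group <- u16(pos); element <- u16(pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr)) {
      stop("implicit VR or unsupported transfer syntax in ", path, call. = FALSE)
    }
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- u32(pos + 8L)
      if (len < 0) stop("undefined-length element (", vr, ") unsupported in ",
                        path, call. = FALSE)
      val_at <- pos + 12L
    } else {
      len <- u16(pos + 6L)
      val_at <- pos + 8L
    }
    key <- sprintf("%04X,%04X", group, element)
    out[[key]] <- list(vr = vr,
                       raw = if (len > 0) bytes[val_at:(val_at + len - 1L)] else raw(0))
    pos <- val_at + len
  }
  out
}

dcm_str <- function(el) {
  if (is.null(el)) return(NULL)
  trimws(rawToChar(el$raw[el$raw != as.raw(0)]))
}
dcm_num <- function(el) {
  if (is.null(el)) return(NULL)
  as.numeric(strsplit(dcm_str(el), "\\\\")[[1]])
}
dcm_us <- function(el) {
  if (is.null(el)) return(NULL)
  readBin(el$raw, "integer", size = 2, endian = "little", signed = FALSE)
}

dcm_require <- function(elts, key, name, path) {
  if (is.null(elts[[key]])) {
    stop(sprintf("DICOM attribute %s (%s) missing in %s", name, key, path),
         call. = FALSE)
  }
  elts[[key]]
}

#' Load a CT volume from a directory of DICOM files
#'
#' Reads every DICOM file in a directory, groups files by series instance
#' UID, calibrates stored pixels to HU (stored * slope + intercept), clamps
#' FOV padding below -1024 HU to -1024, and returns the slices sorted by
#' ascending axial position. The result does not depend on file discovery
#' order.
#'
#' @param directory_path Directory containing one axial CT series (or
#'   several, with `series` selecting one).
#' @param series Optional series selector, matched against the series
#'   instance UID or the series description.
#' @return A [ct_volume()].
#' @export
load_ct_series <- function(directory_path, series = NULL) {
  paths <- sort(list.files(directory_path, full.names = TRUE))
  paths <- paths[!dir.exists(paths)]
  if (length(paths) == 0) stop("no files in ", directory_path, call. = FALSE)
  parsed <- lapply(paths, dcm_parse_file)
  names(parsed) <- paths

  series_uid <- vapply(parsed, function(e) dcm_str(e[["0020,000E"]]) %||% "<none>", "")
  series_desc <- vapply(parsed, function(e) dcm_str(e[["0008,103E"]]) %||% "", "")
  if (!is.null(series)) {
    keep <- series_uid == series | series_desc == series
    if (!any(keep)) {
      stop("no series matching '", series, "'; present: ",
           paste(unique(series_uid), collapse = ", "), call. = FALSE)
    }
    parsed <- parsed[keep]
    series_uid <- series_uid[keep]
    series_desc <- series_desc[keep]
  }
  if (length(unique(series_uid)) > 1) {
    stop("directory mixes ", length(unique(series_uid)),
         " series and no `series` selector was given; present: ",
         paste(unique(series_uid), collapse = ", "), call. = FALSE)
  }
  if (length(parsed) < 2) {
    stop("single-slice series: adjacent-slice subtraction needs >= 2 slices",
         call. = FALSE)
  }

  slices <- vector("list", length(parsed))
  zpos <- numeric(length(parsed))
  inst <- numeric(length(parsed))
  have_pos <- TRUE
  spacing <- thickness <- NULL
  for (k in seq_along(parsed)) {
    e <- parsed[[k]]
    path <- names(parsed)[k]
    modality <- dcm_str(e[["0008,0060"]])
    if (!identical(modality, "CT")) {
      stop("not a CT object (Modality ", modality %||% "<missing>", "): ", path,
           call. = FALSE)
    }
    orient <- dcm_num(e[["0020,0037"]])
    if (!is.null(orient) && max(abs(orient - c(1, 0, 0, 0, 1, 0))) > 1e-4) {
      stop("non-axial image orientation in ", path, call. = FALSE)
    }
    rows <- dcm_us(dcm_require(e, "0028,0010", "Rows", path))
    cols <- dcm_us(dcm_require(e, "0028,0011", "Columns", path))
    sp <- dcm_num(dcm_require(e, "0028,0030", "PixelSpacing", path))
    slope <- dcm_num(dcm_require(e, "0028,1053", "RescaleSlope", path))
    icept <- dcm_num(dcm_require(e, "0028,1052", "RescaleIntercept", path))
    pix_el <- dcm_require(e, "7FE0,0010", "PixelData", path)
    signed <- isTRUE(dcm_us(e[["0028,0103"]]) == 1)
    stored <- readBin(pix_el$raw, "integer", n = rows * cols, size = 2,
                      endian = "little", signed = signed)
    hu <- matrix(stored * slope + icept, nrow = rows, ncol = cols, byrow = TRUE)
    if (is.null(spacing)) {
      spacing <- sp
      thickness <- dcm_num(e[["0018,0050"]]) %||% NA_real_
      first_dim <- c(rows, cols)
    } else if (!identical(c(rows, cols), first_dim)) {
      stop(sprintf("inconsistent in-plane dimensions: %dx%d vs %dx%d (%s)",
                   rows, cols, first_dim[1], first_dim[2], path), call. = FALSE)
    }
    slices[[k]] <- hu
    ipp <- dcm_num(e[["0020,0032"]])
    if (is.null(ipp)) have_pos <- FALSE else zpos[k] <- ipp[3]
    inst[k] <- dcm_num(e[["0020,0013"]]) %||% k
  }
  if (!have_pos) {
    warning("image position missing on some slices; ordering by instance number",
            call. = FALSE)
    ord <- order(inst)
    zpos <- inst
  } else {
    ord <- order(zpos)
  }
  zs <- zpos[ord]
  if (any(diff(zs) <= 0)) {
    stop("slice positions are not strictly monotone after sorting", call. = FALSE)
  }
  arr <- array(0, c(length(slices), first_dim[1], first_dim[2]))
  for (k in seq_along(ord)) arr[k, , ] <- slices[[ord[k]]]

  exam_id <- dcm_str(parsed[[1]][["0020,0010"]]) %||%
    dcm_str(parsed[[1]][["0020,000D"]]) %||% "exam-1"
  sid <- if (nzchar(series_desc[1])) series_desc[1] else series_uid[1]
  ct_volume(arr, spacing, if (is.na(thickness)) mean(diff(zs)) else thickness,
            slice_positions_mm = zs, series_id = sid, exam_id = exam_id)
}

#' List the series present in a DICOM directory
#'
#' @param directory_path Directory of DICOM files.
#' @return A tibble with one row per series: uid, description, file count.
#' @export
list_ct_series <- function(directory_path) {
  paths <- sort(list.files(directory_path, full.names = TRUE))
  paths <- paths[!dir.exists(paths)]
  info <- purrr::map(paths, function(p) {
    e <- dcm_parse_file(p)
    tibble::tibble(series_uid = dcm_str(e[["0020,000E"]]) %||% "<none>",
                   series_description = dcm_str(e[["0008,103E"]]) %||% "")
  })
  dplyr::count(dplyr::bind_rows(info), .data$series_uid,
               .data$series_description, name = "n_files")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
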