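#' File input / output
#'
#' Spectral datasets travel as wide CSV (first column the wavenumber, one
#' column per spectrum) with a companion metadata TSV; single spectra can
#' be read from JCAMP-DX, the interchange standard for vibrational
#' spectra; hyperspectral cubes are stored as raw little-endian float64
#' with a JSON sidecar describing shape, axis and pixel size.
#'
#' @name io
NULL

#' Write / read a spectral dataset as wide CSV (+ metadata TSV)
#'
#' @param ds spectral_dataset
#' @param path CSV path; the metadata TSV is written next to it as
#'   \code{<path>.meta.tsv} (or given explicitly)
#' @param meta_path optional metadata TSV path
#' @return invisible path
#' @export
write_wide_csv <- function(ds, path, meta_path = paste0(path, ".meta.tsv")) {
  stopifnot(inherits(ds, "spectral_dataset"))
  df <- data.frame(wavenumber = ds$wavenumber, t(ds$intensity),
                   check.names = FALSE)
  colnames(df) <- c("wavenumber", ds$meta$sample_id)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  utils::write.table(ds$meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_wide_csv
#' @param modality modality tag for the restored dataset (read from the
#'   metadata when present)
#' @export
read_wide_csv <- function(path, meta_path = paste0(path, ".meta.tsv"),
                          modality = NA_character_) {
  hdr <- utils::read.csv(path, check.names = FALSE, nrows = 1)
  ids <- colnames(hdr)[-1]
  if (anyDuplicated(ids)) {
    stop("duplicate sample column: ", ids[duplicated(ids)][1])
  }
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(vapply(df, is.numeric, logical(1)))) stop("non-numeric cells in ", path)
  meta <- if (file.exists(meta_path)) {
    utils::read.delim(meta_path, stringsAsFactors = FALSE)
  } else {
    data.frame(sample_id = ids)
  }
  meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) stop("metadata does not cover all sample columns")
  if (is.na(modality) && !is.null(meta$modality)) modality <- meta$modality[1]
  spectral_dataset(df[[1]], t(as.matrix(df[, -1, drop = FALSE])), meta,
                   modality = modality)
}

#' Read a single-spectrum JCAMP-DX file
#'
#' Supports XYDATA=(X++(Y..Y)) with plain (AFFN) numbers and XYPOINTS
#' records; the axis is reconstructed from FIRSTX/LASTX/NPOINTS and
#' intensities are scaled by YFACTOR. Compressed dialects (SQZ/DIF/DUP,
#' PAC) are not supported and raise an error naming the dialect.
#'
#' @param path JCAMP-DX file
#' @return spectrum (axis sorted ascending)
#' @export
read_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ldr <- function(name) {
    hit <- grep(paste0("^##", name, "\\s*="), lines, ignore.case = TRUE,
                value = TRUE)
    if (!length(hit)) return(NULL)
    trimws(sub("^##[^=]*=", "", hit[1]))
  }
  num <- function(name) { v <- ldr(name); if (is.null(v)) NULL else as.numeric(v) }
  title <- ldr("TITLE")
  yfactor <- num("YFACTOR"); if (is.null(yfactor)) yfactor <- 1
  xfactor <- num("XFACTOR"); if (is.null(xfactor)) xfactor <- 1

  xy_start <- grep("^##XYDATA\\s*=", lines, ignore.case = TRUE)
  pts_start <- grep("^##XYPOINTS\\s*=", lines, ignore.case = TRUE)
  block_end <- function(start) {
    ends <- grep("^##", lines)
    ends <- ends[ends > start]
    if (length(ends)) ends[1] - 1 else length(lines)
  }
  if (length(xy_start)) {
    form <- toupper(gsub("\\s", "", sub("^##XYDATA\\s*=", "", lines[xy_start[1]],
                                        ignore.case = TRUE)))
    if (form != "(X++(Y..Y))") stop("unsupported XYDATA form: ", form)
    body <- lines[(xy_start[1] + 1):block_end(xy_start[1])]
    body <- body[nzchar(trimws(body))]
    if (any(grepl("[A-DF-Za-df-z%@]", gsub("[eE][-+]?[0-9]+", "", body)))) {
      stop("unsupported compressed JCAMP dialect (SQZ/DIF/DUP)")
    }
    firstx <- num("FIRSTX"); lastx <- num("LASTX"); npts <- num("NPOINTS")
    if (is.null(npts)) stop("missing NPOINTS")
    if (is.null(firstx) || is.null(lastx)) stop("missing FIRSTX/LASTX")
    ys <- unlist(lapply(body, function(l) {
      v <- as.numeric(strsplit(trimws(l), "[ \t,;]+")[[1]])
      v[-1]  # first number on each line is the X start value
    }))
    if (length(ys) != npts) {
      stop("NPOINTS (", npts, ") does not match the data (", length(ys), ")")
    }
    x <- firstx * xfactor + (lastx - firstx) * xfactor * (seq_len(npts) - 1) / (npts - 1)
    y <- ys * yfactor
  } else if (length(pts_start)) {
    body <- lines[(pts_start[1] + 1):block_end(pts_start[1])]
    body <- body[nzchar(trimws(body))]
    vals <- as.numeric(unlist(strsplit(trimws(body), "[ \t,;]+")))
    x <- vals[seq(1, length(vals), 2)] * xfactor
    y <- vals[seq(2, length(vals), 2)] * yfactor
  } else {
    stop("no XYDATA or XYPOINTS block found")
  }
  o <- order(x)
  spectrum(x[o], y[o], meta = list(title = title, path = path))
}

#' Write / read a hyperspectral cube (raw float64 + JSON sidecar)
#'
#' The cube is stored little-endian in R's native column-major order
#' (rows fastest, wavenumber planes slowest); the sidecar (\code{<path>.json}) records shape, wavenumber axis,
#' pixel size and modality. \code{write_envi_header} emits an
#' ENVI-compatible header for interoperability with hyperspectral tools.
#'
#' @param image hyper_image
#' @param path binary output path (e.g. \code{cube.f64})
#' @return invisible path
#' @export
write_cube <- function(image, path) {
  stopifnot(inherits(image, "hyper_image"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(image$cube), con, size = 8, endian = "little")
  side <- list(shape = dim(image$cube), wavenumber = image$wavenumber,
               pixel_size_um = image$pixel_size, modality = image$modality,
               dtype = "float64", byte_order = "little")
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(side$shape)
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = n, size = 8, endian = "little")
  structure(list(cube = array(v, side$shape), wavenumber = side$wavenumber,
                 valid_mask = matrix(TRUE, side$shape[1], side$shape[2]),
                 pixel_size = side$pixel_size_um, modality = side$modality,
                 truth = NULL),
            class = "hyper_image")
}

#' @rdname write_cube
#' @export
write_envi_header <- function(image, path) {
  d <- dim(image$cube)
  hdr <- c("ENVI",
           sprintf("samples = %d", d[2]), sprintf("lines = %d", d[1]),
           sprintf("bands = %d", d[3]), "header offset = 0",
           "file type = ENVI Standard", "data type = 5", "interleave = bsq",
           "byte order = 0",
           paste0("wavelength = {", paste(format(image$wavenumber, trim = TRUE),
                                          collapse = ", "), "}"))
  writeLines(hdr, path)
  invisible(path)
}
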