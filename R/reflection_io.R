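## Reading and writing per-wedge unmerged reflection files.
##
## The on-disk format is a minimal XDS_ASCII dialect: "!"-prefixed
## header lines carrying the unit cell, space-group number, wavelength
## and an ITEM_* column map, followed by whitespace-separated data rows
## (h k l I sigma [frame]).

#' Construct a wedge dataset
#'
#' One small-wedge integration result: unit cell, nominal symmetry,
#' wavelength, frame range and a reflection table.
#'
#' @param id Dataset identifier (string).
#' @param cell A [unit_cell()].
#' @param reflections A data.frame/data.table with columns `h`, `k`,
#'   `l` (integer), `I`, `sigma` (> 0), `frame` (integer).
#' @param space_group_number Integer, 1 if unknown.
#' @param wavelength X-ray wavelength in Angstrom.
#' @param frame_start,frame_end First and last image number.
#' @param deg_per_frame Oscillation range per image in degrees.
#' @return A `wedge_dataset` object.
#' @export
wedge_dataset <- function(id, cell, reflections, space_group_number = 1L,
                          wavelength = 1.0, frame_start = 1L,
                          frame_end = NULL, deg_per_frame = 0.1) {
  cell <- as_unit_cell(cell)
  refl <- data.table::as.data.table(reflections)
  need <- c("h", "k", "l", "I", "sigma")
  if (!all(need %in% names(refl))) {
    stop("reflection table must have columns ", paste(need, collapse = ", "))
  }
  if (!("frame" %in% names(refl))) refl[, frame := as.integer(frame_start)]
  for (cn in c("h", "k", "l", "frame")) data.table::set(refl, j = cn, value = as.integer(refl[[cn]]))
  if (nrow(refl) > 0) {
    if (any(!is.finite(refl$I)) || any(!is.finite(refl$sigma))) {
      stop("non-finite intensity or sigma in reflection table")
    }
    if (any(refl$sigma <= 0)) stop("sigma must be > 0 for every reflection")
  }
  if (is.null(frame_end)) {
    frame_end <- if (nrow(refl) > 0) max(refl$frame) else frame_start
  }
  frame_start <- as.integer(frame_start); frame_end <- as.integer(frame_end)
  if (frame_end < frame_start) stop("frame_end must be >= frame_start")
  if (deg_per_frame <= 0) stop("deg_per_frame must be positive")
  width <- (frame_end - frame_start + 1) * deg_per_frame
  if (width < 0.1 || width > 360) {
    stop("wedge width ", round(width, 3), " degrees outside [0.1, 360]")
  }
  if (nrow(refl) > 0 &&
      (min(refl$frame) < frame_start || max(refl$frame) > frame_end)) {
    stop("frame numbers outside declared frame range")
  }
  structure(list(id = as.character(id), cell = cell,
                 space_group_number = as.integer(space_group_number),
                 wavelength = wavelength, frame_start = frame_start,
                 frame_end = frame_end, deg_per_frame = deg_per_frame,
                 reflections = refl[], extra_header = character(0)),
            class = "wedge_dataset")
}

#' @export
print.wedge_dataset <- function(x, ...) {
  cat(sprintf("wedge dataset '%s': %d reflections, frames %d..%d (%.2f deg)\n",
              x$id, nrow(x$reflections), x$frame_start, x$frame_end,
              (x$frame_end - x$frame_start + 1) * x$deg_per_frame))
  print(x$cell)
  invisible(x)
}

#' Read an XDS_ASCII-style reflection file
#'
#' Parses the minimal dialect: header lines start with `!`; required
#' keys are `UNIT_CELL_CONSTANTS`, `SPACE_GROUP_NUMBER`,
#' `X-RAY_WAVELENGTH` and an `ITEM_*` column map naming at least H, K,
#' L, IOBS, SIGMA(IOBS). The frame column is `ITEM_ZD` (image-centroid
#' z, rounded half-up to a frame id) or an explicit `ITEM_FRAME`; when
#' absent every row gets `frame_start`. Rows with sigma <= 0 are
#' dropped (count reported via a message). Unknown header keys are
#' preserved verbatim and re-emitted by [write_xds_ascii()].
#'
#' @param path File path.
#' @param id Dataset id; defaults to the file path.
#' @return A [wedge_dataset()].
#' @export
read_xds_ascii <- function(path, id = path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^!", lines)
  header <- lines[hdr]
  body_idx <- which(!hdr)
  keep <- nzchar(trimws(lines[body_idx]))
  body_idx <- body_idx[keep]
  body <- lines[body_idx]

  get_key <- function(key, required = TRUE) {
    pat <- paste0("^!", key, "\\s*=")
    hit <- grep(pat, header, value = TRUE)
    if (length(hit) == 0) {
      if (required) stop("format error: missing header key ", key)
      return(NULL)
    }
    trimws(sub(pat, "", hit[1]))
  }
  cellv <- as.numeric(strsplit(get_key("UNIT_CELL_CONSTANTS"), "\\s+")[[1]])
  if (length(cellv) != 6 || any(is.na(cellv))) {
    stop("format error: UNIT_CELL_CONSTANTS must hold six numbers")
  }
  sg <- as.integer(get_key("SPACE_GROUP_NUMBER"))
  wl <- as.numeric(get_key("X-RAY_WAVELENGTH"))

  item_lines <- grep("^!ITEM_", header, value = TRUE)
  items <- sub("^!ITEM_([^=]+)=.*$", "\\1", item_lines)
  cols <- as.integer(sub("^!ITEM_[^=]+=\\s*(\\d+).*$", "\\1", item_lines))
  names(cols) <- trimws(items)
  for (k in c("H", "K", "L", "IOBS", "SIGMA(IOBS)")) {
    if (!(k %in% names(cols))) stop("format error: missing header key ITEM_", k)
  }
  dr <- get_key("DATA_RANGE", required = FALSE)
  osc <- get_key("OSCILLATION_RANGE", required = FALSE)
  deg_per_frame <- if (is.null(osc)) 0.1 else as.numeric(osc)

  known <- c("FORMAT", "UNIT_CELL_CONSTANTS", "SPACE_GROUP_NUMBER",
             "X-RAY_WAVELENGTH", "DATA_RANGE", "OSCILLATION_RANGE",
             "END_OF_HEADER", "END_OF_DATA")
  is_known <- grepl(paste0("^!(", paste(c(known, "ITEM_.*"), collapse = "|"),
                           ")\\s*=?"), header) |
    header %in% c("!END_OF_HEADER", "!END_OF_DATA")
  extra <- header[!is_known]

  if (length(body) > 0) {
    parsed <- tryCatch(
      utils::read.table(text = body, header = FALSE),
      error = function(e) NULL)
    if (is.null(parsed) || any(!vapply(parsed, is.numeric, logical(1)))) {
      ## locate the first bad row for the error message
      for (i in seq_along(body)) {
        v <- suppressWarnings(as.numeric(strsplit(trimws(body[i]), "\\s+")[[1]]))
        if (any(is.na(v))) {
          stop("unparsable data row at line ", body_idx[i], " of ", path)
        }
      }
      stop("unparsable data section in ", path)
    }
    if (ncol(parsed) < max(cols)) {
      stop("data rows have fewer columns than the ITEM_ map requires")
    }
    frame_col <- if ("FRAME" %in% names(cols)) cols[["FRAME"]]
                 else if ("ZD" %in% names(cols)) cols[["ZD"]] else NA
    refl <- data.table::data.table(
      h = as.integer(parsed[[cols[["H"]]]]),
      k = as.integer(parsed[[cols[["K"]]]]),
      l = as.integer(parsed[[cols[["L"]]]]),
      I = as.numeric(parsed[[cols[["IOBS"]]]]),
      sigma = as.numeric(parsed[[cols[["SIGMA(IOBS)"]]]]))
    if (!is.na(frame_col)) {
      ## centroid z: round half-up to the nearest frame id
      refl[, frame := as.integer(floor(as.numeric(parsed[[frame_col]]) + 0.5))]
    }
  } else {
    refl <- data.table::data.table(h = integer(0), k = integer(0),
                                   l = integer(0), I = numeric(0),
                                   sigma = numeric(0), frame = integer(0))
  }
  n_raw <- nrow(refl)
  bad <- !is.finite(refl$sigma) | refl$sigma <= 0 | !is.finite(refl$I)
  if (any(bad)) {
    message(sum(bad), " reflections with sigma <= 0 or non-finite values ",
            "dropped from ", path)
    refl <- refl[!bad]
  }
  if (!is.null(dr)) {
    rng <- as.integer(strsplit(dr, "\\s+")[[1]])
    frame_start <- rng[1]; frame_end <- rng[2]
  } else if ("frame" %in% names(refl) && nrow(refl) > 0) {
    frame_start <- min(refl$frame); frame_end <- max(refl$frame)
  } else {
    frame_start <- 1L; frame_end <- 1L
  }
  if (!("frame" %in% names(refl))) refl[, frame := as.integer(frame_start)]
  ds <- wedge_dataset(id = id, cell = do.call(unit_cell, as.list(cellv)),
                      reflections = refl, space_group_number = sg,
                      wavelength = wl, frame_start = frame_start,
                      frame_end = frame_end, deg_per_frame = deg_per_frame)
  ds$extra_header <- extra
  ds$n_dropped <- sum(bad)
  ds
}

#' Write a wedge dataset as an XDS_ASCII-style file
#'
#' Emits a file that [read_xds_ascii()] parses back to an equal
#' dataset. Intensities and sigmas are written with three decimals;
#' writing twice produces bit-identical files.
#'
#' @param dataset A [wedge_dataset()].
#' @param path Output file path.
#' @export
write_xds_ascii <- function(dataset, path) {
  stopifnot(inherits(dataset, "wedge_dataset"))
  cl <- dataset$cell
  header <- c(
    "!FORMAT=XDS_ASCII    MERGE=FALSE",
    sprintf("!SPACE_GROUP_NUMBER= %d", dataset$space_group_number),
    sprintf("!UNIT_CELL_CONSTANTS= %.4f %.4f %.4f %.4f %.4f %.4f",
            cl[1], cl[2], cl[3], cl[4], cl[5], cl[6]),
    sprintf("!X-RAY_WAVELENGTH= %.5f", dataset$wavelength),
    sprintf("!DATA_RANGE= %d %d", dataset$frame_start, dataset$frame_end),
    sprintf("!OSCILLATION_RANGE= %.6f", dataset$deg_per_frame),
    dataset$extra_header,
    "!ITEM_H=1", "!ITEM_K=2", "!ITEM_L=3", "!ITEM_IOBS=4",
    "!ITEM_SIGMA(IOBS)=5", "!ITEM_ZD=6",
    "!END_OF_HEADER")
  r <- dataset$reflections
  rows <- if (nrow(r) > 0) {
    sprintf("%6d %6d %6d %14.3f %12.3f %8d", r$h, r$k, r$l, r$I, r$sigma,
            r$frame)
  } else character(0)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(header, rows, "!END_OF_DATA"), con)
  invisible(path)
}

#' Discover reflection files under a directory
#'
#' Recursively collects every parseable reflection file (sorted by
#' path); unparseable files are skipped with a message.
#'
#' @param root Directory to search.
#' @param pattern Filename pattern (default any `.HKL`/`.hkl` file).
#' @return List of [wedge_dataset()]s (possibly empty, with a warning).
#' @export
discover_datasets <- function(root, pattern = "\\.hkl$") {
  if (!dir.exists(root)) stop("no such directory: ", root)
  files <- sort(list.files(root, pattern = pattern, recursive = TRUE,
                           full.names = TRUE, ignore.case = TRUE))
  out <- list()
  for (f in files) {
    ds <- tryCatch(read_xds_ascii(f), error = function(e) {
      message("skipping unparseable file ", f, ": ", conditionMessage(e))
      NULL
    })
    if (!is.null(ds)) out[[length(out) + 1]] <- ds
  }
  if (length(out) == 0) warning("no parseable reflection files under ", root)
  out
}
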