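# Plain-text readers and writers for reflectivity curves (column and
# ORSO-style .ort dialects), isotherm tables and gridded GIXD maps.
# Numeric values are written with 17 significant digits so that
# write -> read round-trips are bit-exact for ASCII decimals.

#' Read a reflectivity curve from a text file
#'
#' Whitespace-separated columns `q R dR [dq]`, `#` comment lines skipped
#' (this also covers ORSO-style `.ort` headers). Units are assumed inverse
#' Angstrom and recorded in the returned object.
#'
#' @param path File path.
#' @param dialect `"columns"` or `"ort"` (both use the same column layout;
#'   the dialect governs the header written by [write_reflectivity()]).
#' @return A [reflectivity_curve()]; a `dq` column, when present, is
#'   attached and takes precedence over any global dq/q in later fitting.
#' @export
read_reflectivity <- function(path, dialect = c("columns", "ort")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (!length(rows)) stop("no data rows in ", path)
  vals <- lapply(rows, function(ln) {
    toks <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(toks))
    if (length(v) < 3 || anyNA(v))
      stop("malformed reflectivity row at line ", ln, " of ", path)
    v
  })
  ncols <- vapply(vals, length, integer(1))
  if (length(unique(ncols)) != 1)
    stop("inconsistent column count in ", path)
  m <- do.call(rbind, vals)
  ord <- order(m[, 1])
  if (is.unsorted(m[, 1], strictly = TRUE)) {
    warning("q not monotone in ", path, "; sorting")
    m <- m[ord, , drop = FALSE]
  }
  reflectivity_curve(m[, 1], m[, 2], dR = m[, 3],
                     dq = if (ncol(m) >= 4) m[, 4] else NULL,
                     contrast_label = basename(path))
}

#' Write a reflectivity curve to a text file
#'
#' @param curve A [reflectivity_curve()] (with `dR`; `dq` optional).
#' @param path Output path.
#' @param dialect `"columns"` writes a minimal `#` header; `"ort"` writes an
#'   ORSO-style header block.
#' @return `path`, invisibly.
#' @export
write_reflectivity <- function(curve, path, dialect = c("columns", "ort")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(curve, "reflectivity_curve"))
  if (is.null(curve$dR)) curve$dR <- rep(0, nrow(curve))
  cols <- c("Qz (1/angstrom)", "R", "sR",
            if (!is.null(curve$dq)) "sQz (FWHM, 1/angstrom)")
  hdr <- if (dialect == "ort") c(
    "# # ORSO reflectivity data file | 1.0 standard",
    paste0("# data_source: monofilm synthetic/analysis export"),
    paste0("# contrast: ", attr(curve, "contrast_label")),
    paste0("# columns: ", paste(cols, collapse = " | "))
  ) else c(
    paste0("# ", paste(c("q", "R", "dR", if (!is.null(curve$dq)) "dq"),
                       collapse = " "))
  )
  fmt <- function(x) formatC(x, format = "g", digits = 17)
  body <- if (is.null(curve$dq))
    paste(fmt(curve$q), fmt(curve$R), fmt(curve$dR))
  else paste(fmt(curve$q), fmt(curve$R), fmt(curve$dR), fmt(curve$dq))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an isotherm table from CSV
#'
#' First two columns are area per molecule (square Angstrom) and surface
#' pressure (mN/m); extra columns are ignored.
#'
#' @param path CSV path.
#' @param T_C Temperature metadata, Celsius.
#' @return An [isotherm()].
#' @export
read_isotherm_csv <- function(path, T_C = 19.5) {
  df <- utils::read.csv(path, comment.char = "#")
  if (ncol(df) < 2) stop("isotherm CSV needs at least area and pressure columns")
  isotherm(df[[1]], df[[2]], T_C = T_C, label = basename(path))
}

#' Write / read a gridded GIXD map as plain text
#'
#' Layout: `#`-comment header, a `QXY` line and a `QZ` line holding the axis
#' vectors, then one matrix row per `q_xy` value.
#'
#' @param image A [gixd_image()].
#' @param path File path.
#' @return `path` (writer, invisibly) or a [gixd_image()] (reader).
#' @export
write_gixd <- function(image, path) {
  stopifnot(inherits(image, "gixd_image"))
  fmt <- function(x) formatC(x, format = "g", digits = 17)
  writeLines(c("# monofilm GIXD map: QXY/QZ axis lines then counts rows",
               paste("QXY", paste(fmt(image$q_xy), collapse = " ")),
               paste("QZ", paste(fmt(image$q_z), collapse = " ")),
               apply(image$intensity, 1,
                     function(r) paste(fmt(r), collapse = " "))),
             path)
  invisible(path)
}

#' @rdname write_gixd
#' @export
read_gixd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  ax <- function(tag) {
    ln <- grep(paste0("^", tag, " "), lines, value = TRUE)
    if (length(ln) != 1) stop("missing ", tag, " axis line in ", path)
    as.numeric(strsplit(trimws(sub(paste0("^", tag, " "), "", ln)),
                        "\\s+")[[1]])
  }
  qxy <- ax("QXY"); qz <- ax("QZ")
  rows <- lines[!grepl("^(QXY|QZ) ", lines)]
  m <- do.call(rbind, lapply(rows, function(r)
    as.numeric(strsplit(trimws(r), "\\s+")[[1]])))
  gixd_image(qxy, qz, m)
}
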