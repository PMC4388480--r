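#' Read an angle field from delimited text
#'
#' Reads a CSV or TSV file (delimiter auto-detected from the header line)
#' with a required header. Accepted layouts: columns `x`, `y`, `angle`, or
#' a single `angle` column when coordinates are unavailable (e.g. masked
#' pixels are simply omitted from the file).
#'
#' @param path file path.
#' @param degrees if `TRUE`, angles in the file are degrees and are
#'   converted to radians on read.
#' @param label identifier attached to the field; defaults to the file
#'   name.
#' @return an [orientation_field()].
#' @export
read_angle_field <- function(path, degrees = FALSE, label = basename(path)) {
  df <- read_delimited(path)
  need_col(df, "angle", path)
  a <- as.numeric(df$angle)
  if (degrees) a <- a * pi / 180
  coords <- NULL
  if (all(c("x", "y") %in% names(df))) {
    coords <- cbind(x = as.numeric(df$x), y = as.numeric(df$y))
  }
  orientation_field(a, coords = coords, label = label)
}

#' Read a paired angle field from delimited text
#'
#' Layout: columns `angle_p` and `angle_q` (required), optional `x`, `y`
#' and `weight`.
#'
#' @inheritParams read_angle_field
#' @return a [paired_field()].
#' @export
read_paired_field <- function(path, degrees = FALSE, label = basename(path)) {
  df <- read_delimited(path)
  need_col(df, "angle_p", path)
  need_col(df, "angle_q", path)
  p <- as.numeric(df$angle_p)
  q <- as.numeric(df$angle_q)
  if (degrees) {
    p <- p * pi / 180
    q <- q * pi / 180
  }
  coords <- NULL
  if (all(c("x", "y") %in% names(df))) {
    coords <- cbind(x = as.numeric(df$x), y = as.numeric(df$y))
  }
  weights <- if ("weight" %in% names(df)) as.numeric(df$weight) else NULL
  paired_field(p, q, weights = weights, coords = coords, label = label)
}

#' Write a paired field to CSV
#'
#' Columns `angle_p`, `angle_q` plus `x`/`y` and `weight` when present.
#'
#' @param pf a [paired_field()].
#' @param path output path.
#' @param degrees write angles in degrees instead of radians.
#' @return `path`, invisibly.
#' @export
write_paired_field <- function(pf, path, degrees = FALSE) {
  stopifnot(inherits(pf, "paired_field"))
  f <- if (degrees) 180 / pi else 1
  df <- data.frame(angle_p = pf$p_angles * f, angle_q = pf$q_angles * f)
  if (!is.null(pf$coords)) {
    df <- cbind(x = pf$coords[, 1L], y = pf$coords[, 2L], df)
  }
  if (!is.null(pf$weights)) df$weight <- pf$weights
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write an angle field to CSV
#'
#' @param field an [orientation_field()].
#' @inheritParams write_paired_field
#' @return `path`, invisibly.
#' @export
write_angle_field <- function(field, path, degrees = FALSE) {
  stopifnot(inherits(field, "orientation_field"))
  f <- if (degrees) 180 / pi else 1
  df <- data.frame(angle = field$angles * f)
  if (!is.null(field$coords)) {
    df <- cbind(x = field$coords[, 1L], y = field$coords[, 2L], df)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

read_delimited <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) {
    stop(sprintf("%s: empty file", path), call. = FALSE)
  }
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE),
    error = function(e) {
      stop(sprintf("%s: parse error: %s", path, conditionMessage(e)),
           call. = FALSE)
    })
  names(df) <- tolower(names(df))
  df
}

need_col <- function(df, col, path) {
  if (!col %in% names(df)) {
    stop(sprintf("%s: missing required column '%s' (found: %s)",
                 path, col, paste(names(df), collapse = ", ")),
         call. = FALSE)
  }
  invisible(NULL)
}
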