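#' Write a point cloud as an ASCII PCD v0.7 file
#'
#' The Point Cloud Data format stores one point per line after a fixed
#' header. Files are written with `FIELDS x y z`, `TYPE F`, `WIDTH` equal
#' to the point count and `HEIGHT 1`; coordinates are printed with six
#' decimal places, so a write/read round trip reproduces positions to
#' better than 1e-6 A.
#'
#' @param cloud a [mol_cloud()] or coordinate matrix (nonempty).
#' @param path output file path.
#' @param digits decimal places for coordinates (default 6).
#' @return `path`, invisibly.
#' @export
write_pcd <- function(cloud, path, digits = 6L) {
  P <- as_points(cloud)
  if (nrow(P) == 0L) stop("cannot write an empty cloud")
  n <- nrow(P)
  header <- c(
    "# .PCD v0.7 - Point Cloud Data file format",
    "VERSION 0.7",
    "FIELDS x y z",
    "SIZE 4 4 4",
    "TYPE F F F",
    "COUNT 1 1 1",
    sprintf("WIDTH %d", n),
    "HEIGHT 1",
    "VIEWPOINT 0 0 0 1 0 0 0",
    sprintf("POINTS %d", n),
    "DATA ascii")
  fmt <- sprintf("%%.%df %%.%df %%.%df", digits, digits, digits)
  writeLines(c(header, sprintf(fmt, P[, 1L], P[, 2L], P[, 3L])), path)
  invisible(path)
}

#' Read an ASCII PCD point-cloud file
#'
#' Accepts PCD v0.5-0.7 headers with at least the fields x, y, z and
#' `DATA ascii`; extra fields on each record are ignored.
#'
#' @param path path to a PCD file.
#' @return a [mol_cloud()].
#' @export
read_pcd <- function(path) {
  if (!file.exists(path)) stop("PCD file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  hdr <- list()
  data_start <- NA_integer_
  keys <- c("VERSION", "FIELDS", "SIZE", "TYPE", "COUNT", "WIDTH",
            "HEIGHT", "VIEWPOINT", "POINTS", "DATA")
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (!toupper(tok[1L]) %in% keys) {
      if (is.na(data_start))
        stop("malformed PCD header at line: '", lines[i], "'")
      break
    }
    hdr[[toupper(tok[1L])]] <- tok[-1L]
    if (toupper(tok[1L]) == "DATA") { data_start <- i + 1L; break }
  }
  if (is.na(data_start)) stop("PCD header has no DATA line")
  if (tolower(hdr$DATA[1L]) != "ascii")
    stop("only DATA ascii is supported (got '", hdr$DATA[1L], "')")
  fields <- tolower(hdr$FIELDS)
  ix <- match(c("x", "y", "z"), fields)
  if (any(is.na(ix)))
    stop("PCD FIELDS must include x, y and z (got: ",
         paste(hdr$FIELDS, collapse = " "), ")")
  n <- as.integer(hdr$POINTS[1L])
  if (is.na(n)) stop("malformed PCD header: POINTS '", hdr$POINTS[1L], "'")
  body <- lines[seq(data_start, length.out = length(lines) - data_start + 1L)]
  if (length(body) < n)
    stop("PCD body has ", length(body), " records, header promises ", n)
  vals <- strsplit(trimws(body[seq_len(n)]), "\\s+")
  nf <- length(fields)
  bad <- which(vapply(vals, length, 1L) < nf)
  if (length(bad))
    stop("malformed PCD record at data line ", bad[1L], ": '",
         body[bad[1L]], "'")
  m <- matrix(as.numeric(unlist(lapply(vals, `[`, ix))),
              ncol = 3L, byrow = TRUE)
  if (anyNA(m)) stop("non-numeric coordinate in PCD body")
  mol_cloud(m)
}
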