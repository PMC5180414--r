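# Two-step dictionary search: a binary sidecar index over a sorted
# key-coordinate text database. The database is split, per key, into bins of
# X lines (default 10); the index records each bin's first coordinate and
# byte offset, plus a static key directory. A query locates the bin whose
# first coordinate brackets the requested start (step one), then reads
# sequentially from that bin (step two), so each lookup costs two random
# accesses plus at most X sequential line reads per bin touched.

TDS_MAGIC <- charToRaw("TDS1")
TDS_VERSION <- 1L

#' Build a two-step dictionary index over a sorted text database
#'
#' The database must be tab-delimited with column 1 a key (for example a
#' chromosome name -- any string works) and column 2 an integer coordinate,
#' sorted by key block then coordinate. The index is persisted as a binary
#' sidecar file and returned as an in-memory structure.
#'
#' @param db_path path to the sorted database.
#' @param bin_size lines per bin (default 10).
#' @param index_path where to persist the index (default `<db_path>.tds`).
#' @return an object of class `tds_index`.
#' @export
tds_build <- function(db_path, bin_size = 10L,
                      index_path = paste0(db_path, ".tds")) {
  bin_size <- as.integer(bin_size)
  if (is.na(bin_size) || bin_size < 1L) stop("bin_size must be >= 1")
  if (!file.exists(db_path)) stop("database not found: ", db_path)

  sz <- file.size(db_path)
  raw <- readBin(db_path, "raw", n = sz)
  nl <- which(raw == as.raw(10L))
  if (length(raw) && (length(nl) == 0L || nl[length(nl)] != length(raw)))
    nl <- c(nl, length(raw) + 1L)      # tolerate a missing final newline
  line_start <- c(1L, head(nl, -1L) + 1L)
  keep <- line_start < nl              # drop empty lines
  line_start <- line_start[keep]; line_end <- nl[keep]
  n_lines <- length(line_start)

  if (n_lines == 0L) {
    idx <- new_tds_index(db_path, bin_size, character(0),
                         integer(0), numeric(0), numeric(0), integer(0))
    tds_write_index(idx, index_path)
    return(idx)
  }

  txt <- vapply(seq_len(n_lines), function(i)
    rawToChar(raw[line_start[i]:(line_end[i] - 1L)]), character(1))
  f1 <- sub("\t.*$", "", txt)
  f2 <- sub("^[^\t]*\t", "", txt)
  coord <- suppressWarnings(as.integer(sub("\t.*$", "", f2)))
  if (anyNA(coord))
    stop("non-integer coordinate at database line ", which(is.na(coord))[1])

  key_rle <- rle(f1)
  keys <- key_rle$values
  if (anyDuplicated(keys)) {
    dup <- keys[duplicated(keys)][1]
    at <- sum(key_rle$lengths[seq_len(which(keys == dup)[2] - 1L)]) + 1L
    stop("database not sorted: key '", dup, "' reappears at line ", at)
  }
  bounds <- c(0L, cumsum(key_rle$lengths))
  for (k in seq_along(keys)) {
    cc <- coord[(bounds[k] + 1L):bounds[k + 1L]]
    if (is.unsorted(cc)) {
      off <- which(diff(cc) < 0)[1]
      stop("database not sorted: coordinate decreases at line ",
           bounds[k] + off + 1L)
    }
  }

  bin_first <- numeric(0); bin_offset <- numeric(0); bin_n <- integer(0)
  key_nbins <- integer(length(keys))
  for (k in seq_along(keys)) {
    lo <- bounds[k] + 1L; hi <- bounds[k + 1L]
    starts <- seq(lo, hi, by = bin_size)
    key_nbins[k] <- length(starts)
    ends <- pmin(starts + bin_size - 1L, hi)
    bin_first <- c(bin_first, as.numeric(coord[starts]))
    bin_offset <- c(bin_offset, as.numeric(line_start[starts] - 1L))
    bin_n <- c(bin_n, ends - starts + 1L)
  }

  idx <- new_tds_index(db_path, bin_size, keys, key_nbins,
                       bin_first, bin_offset, bin_n)
  tds_write_index(idx, index_path)
  idx
}

new_tds_index <- function(db_path, bin_size, keys, key_nbins,
                          bin_first, bin_offset, bin_n) {
  structure(
    list(db_path = db_path, bin_size = as.integer(bin_size),
         keys = keys, key_nbins = as.integer(key_nbins),
         bin_first = as.numeric(bin_first),
         bin_offset = as.numeric(bin_offset), bin_n = as.integer(bin_n)),
    class = "tds_index")
}

#' @export
print.tds_index <- function(x, ...) {
  cat("<tds_index>", x$db_path, "\n  bin size:", x$bin_size,
      " keys:", length(x$keys), " bins:", length(x$bin_first), "\n")
  invisible(x)
}

# on-disk layout (little endian): magic "TDS1", version int32, bin_size
# int32, n_keys int32; per key: name length int32 + utf8 bytes + n_bins
# int32; then n_bins_total x (first_coord double, offset double, n int32).
tds_write_index <- function(index, index_path) {
  con <- file(index_path, "wb")
  on.exit(close(con))
  writeBin(TDS_MAGIC, con)
  writeBin(c(TDS_VERSION, index$bin_size, length(index$keys)), con,
           size = 4L, endian = "little")
  for (k in seq_along(index$keys)) {
    nm <- charToRaw(index$keys[k])
    writeBin(length(nm), con, size = 4L, endian = "little")
    writeBin(nm, con)
    writeBin(index$key_nbins[k], con, size = 4L, endian = "little")
  }
  writeBin(index$bin_first, con, size = 8L, endian = "little")
  writeBin(index$bin_offset, con, size = 8L, endian = "little")
  writeBin(index$bin_n, con, size = 4L, endian = "little")
  invisible(index_path)
}

#' Load a persisted two-step dictionary index
#'
#' @param db_path path to the database the index belongs to.
#' @param index_path the sidecar index file (default `<db_path>.tds`).
#' @return a `tds_index` object.
#' @export
tds_load <- function(db_path, index_path = paste0(db_path, ".tds")) {
  if (!file.exists(index_path)) stop("index file not found: ", index_path)
  con <- file(index_path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 4L)
  if (!identical(magic, TDS_MAGIC)) stop("not a TDS index file: ", index_path)
  hdr <- readBin(con, "integer", n = 3L, size = 4L, endian = "little")
  if (hdr[1] != TDS_VERSION) stop("unsupported TDS index version ", hdr[1])
  n_keys <- hdr[3]
  keys <- character(n_keys); key_nbins <- integer(n_keys)
  for (k in seq_len(n_keys)) {
    len <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    keys[k] <- rawToChar(readBin(con, "raw", n = len))
    key_nbins[k] <- readBin(con, "integer", n = 1L, size = 4L,
                            endian = "little")
  }
  nb <- sum(key_nbins)
  bin_first <- readBin(con, "double", n = nb, size = 8L, endian = "little")
  bin_offset <- readBin(con, "double", n = nb, size = 8L, endian = "little")
  bin_n <- readBin(con, "integer", n = nb, size = 4L, endian = "little")
  new_tds_index(db_path, hdr[2], keys, key_nbins, bin_first, bin_offset, bin_n)
}

#' Query a two-step dictionary index
#'
#' Returns exactly the database lines whose key matches and whose coordinate
#' lies in `[start, end]`, in file order. An unknown key yields an empty
#' result.
#'
#' @param index a `tds_index`.
#' @param key key name (for example a chromosome).
#' @param start,end inclusive coordinate range (`start <= end`).
#' @return character vector of matching lines.
#' @export
tds_query <- function(index, key, start, end = start) {
  stopifnot(inherits(index, "tds_index"))
  if (start > end) stop("start must be <= end")
  k <- match(key, index$keys)
  if (is.na(k)) return(character(0))
  first_bin <- if (k == 1L) 1L else sum(index$key_nbins[seq_len(k - 1L)]) + 1L
  nb <- index$key_nbins[k]
  fc <- index$bin_first[first_bin:(first_bin + nb - 1L)]
  off <- index$bin_offset[first_bin:(first_bin + nb - 1L)]
  nli <- index$bin_n[first_bin:(first_bin + nb - 1L)]

  jlo <- findInterval(start, fc)     # last bin whose first coord <= start
  if (jlo == 0L) jlo <- 1L
  jhi <- findInterval(end, fc)       # bins after this start beyond `end`
  if (jhi == 0L) return(character(0))

  con <- file(index$db_path, "rb")
  on.exit(close(con))
  seek(con, off[jlo])
  out <- character(0)
  for (j in jlo:jhi) {
    lines <- readLines(con, n = nli[j], warn = FALSE)
    f2 <- sub("^[^\t]*\t", "", lines)
    coord <- as.integer(sub("\t.*$", "", f2))
    out <- c(out, lines[!is.na(coord) & coord >= start & coord <= end])
    if (length(coord) && coord[length(coord)] > end) break
  }
  out
}

#' Query the database by exact key and coordinate, parsed into fields
#'
#' Convenience wrapper over [tds_query()] that splits the matching lines on
#' tabs.
#'
#' @inheritParams tds_query
#' @return list of character vectors (one per matching line).
#' @export
tds_query_fields <- function(index, key, start, end = start) {
  strsplit(tds_query(index, key, start, end), "\t", fixed = TRUE)
}
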