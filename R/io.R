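#' Per-cell event table
#'
#' The canonical container for one sample's raw flow events: a data
#' frame with the four channels `fsc_a`, `ssc_a`, `gfp`, `mcherry` (in
#' that order, arbitrary scatter/fluorescence units) and attributes
#' `sample_id` and `provenance`.
#'
#' @param fsc_a,ssc_a,gfp,mcherry Numeric vectors of equal length, all
#'   values finite.
#' @param sample_id Sample name.
#' @param provenance Free-text source description (path + format, or the
#'   simulator call).
#' @return A data frame of class `event_table`.
#' @export
event_table <- function(fsc_a, ssc_a, gfp, mcherry,
                        sample_id = "sample", provenance = "in-memory") {
  n <- length(fsc_a)
  if (n < 1L) stop("an event_table needs at least one event", call. = FALSE)
  if (length(ssc_a) != n || length(gfp) != n || length(mcherry) != n) {
    stop("all four channels must have the same length", call. = FALSE)
  }
  vals <- cbind(fsc_a, ssc_a, gfp, mcherry)
  if (!all(is.finite(vals))) {
    stop("event_table channels must be finite", call. = FALSE)
  }
  structure(
    data.frame(fsc_a = as.numeric(fsc_a), ssc_a = as.numeric(ssc_a),
               gfp = as.numeric(gfp), mcherry = as.numeric(mcherry)),
    sample_id = as.character(sample_id),
    provenance = as.character(provenance),
    class = c("event_table", "data.frame")
  )
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table> sample '%s': %d events (%s)\n",
              attr(x, "sample_id"), nrow(x), attr(x, "provenance")))
  print(utils::head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat(sprintf("... %d more events\n", nrow(x) - 5L))
  invisible(x)
}

#' Number of events in an event table
#' @param table An `event_table`.
#' @return Integer event count.
#' @export
n_events <- function(table) nrow(table)

#' Write per-cell events to disk
#'
#' Writes the four channels under their instrument-style parameter names
#' (`FSC-A`, `SSC-A`, `GFP-A`, `mCherry-A`). `tsv` is a plain
#' tab-delimited table with header and round-trips at full double
#' precision; `fcs` is an FCS 3.1 list-mode file with float32 data, so a
#' round trip is exact only to single precision.
#'
#' @param table An [event_table()]; must be non-empty.
#' @param path Output file path.
#' @param format `"tsv"` or `"fcs"`.
#' @return `path`, invisibly.
#' @seealso [read_events()]
#' @export
write_events <- function(table, path, format = c("tsv", "fcs")) {
  format <- match.arg(format)
  if (!inherits(table, "event_table")) {
    stop("`table` must be an event_table", call. = FALSE)
  }
  if (nrow(table) == 0L) stop("refusing to write a zero-event table",
                              call. = FALSE)
  cmap <- default_channel_map()
  if (format == "tsv") {
    out <- as.data.frame(table)
    names(out) <- unname(cmap[CHANNELS])
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    write_fcs(as.matrix(as.data.frame(table)), unname(cmap[CHANNELS]), path)
  }
  invisible(path)
}

#' Read per-cell events from disk
#'
#' Reads an FCS 3.0/3.1 list-mode file or a delimited text table and
#' returns the four required channels in canonical order. The
#' `channel_map` resolves canonical keys to the parameter names used in
#' the file; a required channel that cannot be resolved is an error
#' naming the channel.
#'
#' @param path File to read.
#' @param format `"tsv"` or `"fcs"`.
#' @param channel_map Named character vector with entries `fsc_a`,
#'   `ssc_a`, `gfp`, `mcherry` giving the file parameter names; defaults
#'   to `FSC-A`, `SSC-A`, `GFP-A`, `mCherry-A`.
#' @param sample_id Sample name for the result; defaults to the file
#'   base name.
#' @return An [event_table()].
#' @export
read_events <- function(path, format = c("tsv", "fcs"),
                        channel_map = default_channel_map(),
                        sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  missing_keys <- setdiff(CHANNELS, names(channel_map))
  if (length(missing_keys)) {
    stop("channel_map lacks entries for: ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  if (format == "tsv") {
    raw <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE)
    cols <- colnames(raw)
  } else {
    parsed <- read_fcs(path)
    raw <- as.data.frame(parsed$data)
    cols <- parsed$names
    colnames(raw) <- cols
  }
  if (nrow(raw) == 0L) stop("no events in ", path, call. = FALSE)
  got <- match(unname(channel_map[CHANNELS]), cols)
  if (anyNA(got)) {
    stop("missing channel(s) in ", basename(path), ": ",
         paste(channel_map[CHANNELS][is.na(got)], collapse = ", "),
         call. = FALSE)
  }
  event_table(raw[[got[1]]], raw[[got[2]]], raw[[got[3]]], raw[[got[4]]],
              sample_id = sample_id,
              provenance = sprintf("%s (%s)", path, format))
}

# --- minimal FCS 3.1 list-mode writer/reader -------------------------------
#
# HEADER: 6-byte version, 4 spaces, then three pairs of 8-char ASCII
# offsets (TEXT begin/end, DATA begin/end, ANALYSIS 0/0). TEXT is a
# delimited keyword table; DATA is a packed list-mode matrix. We write
# float32 little-endian and read float32/float64/integer data in either
# byte order, which covers files produced by common acquisition software
# and by this package itself.

write_fcs <- function(mat, par_names, path) {
  n <- nrow(mat)
  p <- ncol(mat)
  delim <- "/"
  kw <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
          "$BEGINDATA", "@@@@@@@@", "$ENDDATA", "@@@@@@@@",
          "$DATATYPE", "F", "$MODE", "L", "$BYTEORD", "1,2,3,4",
          "$NEXTDATA", "0",
          "$PAR", as.character(p), "$TOT", as.character(n))
  for (j in seq_len(p)) {
    kw <- c(kw,
            sprintf("$P%dN", j), par_names[j],
            sprintf("$P%dB", j), "32",
            sprintf("$P%dE", j), "0,0",
            sprintf("$P%dR", j),
            as.character(max(1, ceiling(max(mat[, j], 0) + 1))))
  }
  build_text <- function(kw) paste0(delim, paste(kw, collapse = delim), delim)
  header_len <- 58L # "FCS3.1    " + 6 * 8 offset fields
  # Two passes: placeholder widths are fixed (%08d), so lengths are stable.
  text0 <- build_text(kw)
  text_begin <- header_len
  text_end <- text_begin + nchar(text0, type = "bytes") - 1L
  data_begin <- text_end + 1L
  data_end <- data_begin + 4L * n * p - 1L
  kw[kw == "@@@@@@@@"] <- sprintf("%08d", c(data_begin, data_end))
  text <- build_text(kw)
  stopifnot(nchar(text, type = "bytes") == nchar(text0, type = "bytes"))

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("FCS3.1    ", con, eos = NULL)
  writeChar(sprintf("%8d%8d%8d%8d%8d%8d",
                    text_begin, text_end, data_begin, data_end, 0L, 0L),
            con, eos = NULL)
  writeChar(text, con, eos = NULL)
  # list mode: events are rows, parameters interleaved within each event
  writeBin(as.numeric(t(mat)), con, size = 4L, endian = "little")
  invisible(path)
}

read_fcs <- function(path) {
  sz <- file.info(path)$size
  raw <- readBin(path, "raw", n = sz)
  version <- rawToChar(raw[1:6])
  if (!startsWith(version, "FCS3")) {
    stop("unsupported FCS version or corrupt file: ", path, call. = FALSE)
  }
  offs <- function(i) {
    s <- rawToChar(raw[(10 + (i - 1) * 8 + 1):(10 + i * 8)])
    as.integer(trimws(s))
  }
  text_begin <- offs(1); text_end <- offs(2)
  if (anyNA(c(text_begin, text_end)) || text_end <= text_begin) {
    stop("corrupt FCS header in ", path, call. = FALSE)
  }
  text <- rawToChar(raw[(text_begin + 1):(text_end + 1)])
  delim <- substr(text, 1L, 1L)
  parts <- strsplit(substring(text, 2L), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2L == 1L) parts <- parts[-length(parts)]
  kw <- stats::setNames(parts[seq(2, length(parts), 2)],
                        toupper(parts[seq(1, length(parts), 2)]))
  need <- c("$PAR", "$TOT", "$DATATYPE", "$BYTEORD")
  if (!all(need %in% names(kw))) {
    stop("FCS TEXT segment lacks required keywords in ", path, call. = FALSE)
  }
  p <- as.integer(kw[["$PAR"]])
  n <- as.integer(kw[["$TOT"]])
  data_begin <- as.integer(trimws(kw[["$BEGINDATA"]]))
  if (is.na(data_begin) || data_begin == 0L) data_begin <- offs(3)
  endian <- if (startsWith(kw[["$BYTEORD"]], "1")) "little" else "big"
  dtype <- toupper(kw[["$DATATYPE"]])
  bits <- as.integer(kw[[sprintf("$P%dB", 1L)]])
  what <- switch(dtype, F = "numeric", D = "numeric", I = "integer",
                 stop("unsupported $DATATYPE ", dtype, call. = FALSE))
  size <- switch(dtype, F = 4L, D = 8L, I = max(2L, bits %/% 8L))
  vals <- readBin(raw[(data_begin + 1):sz], what = what, n = n * p,
                  size = size, endian = endian,
                  signed = !(dtype == "I" && size <= 2L))
  if (length(vals) < n * p) {
    stop("FCS data segment truncated in ", path, call. = FALSE)
  }
  mat <- matrix(as.numeric(vals[seq_len(n * p)]), nrow = n, ncol = p,
                byrow = TRUE)
  pnames <- vapply(seq_len(p), function(j) {
    nm <- kw[[sprintf("$P%dN", j)]]
    if (is.null(nm)) sprintf("P%d", j) else nm
  }, character(1))
  list(data = mat, names = pnames, keywords = kw)
}
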