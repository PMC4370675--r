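# File I/O. Two interchange formats: FCS 3.1 (list mode, 32-bit float,
# the instrument-native container) and a delimited-text fallback whose
# header row carries the channel ids and whose first line records the
# panel. The FCS support here is deliberately minimal: mode L, datatype F,
# little- or big-endian, one data set per file.

#' Write an event table
#'
#' @param events An [event_table()].
#' @param path Output file.
#' @param format `"fcs"` (FCS 3.1, float data) or `"delim"` (tab-separated
#'   text with a `# panel:` comment line).
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, format = c("delim", "fcs")) {
  format <- rlang::arg_match(format)
  if (format == "delim") {
    writeLines(sprintf("# panel: %s", attr(events, "panel")), path)
    readr::write_tsv(as_tibble(as.data.frame(events)), path,
      append = TRUE,
      col_names = TRUE
    )
  } else {
    write_events_fcs(events, path)
  }
  invisible(path)
}

#' Read an event table
#'
#' @param path Input file (FCS 3.1 or delimited text written by
#'   [write_events()]).
#' @param format `"auto"` detects FCS by its magic bytes.
#' @param panel Panel name override; by default recovered from the file
#'   (FCS custom keyword / `# panel:` comment).
#' @return An [event_table()].
#' @export
read_events <- function(path, format = c("auto", "fcs", "delim"),
                        panel = NULL) {
  format <- rlang::arg_match(format)
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  if (format == "auto") {
    magic <- readChar(path, 6, useBytes = TRUE)
    format <- if (identical(magic, "FCS3.1")) "fcs" else "delim"
  }
  if (format == "fcs") {
    return(read_events_fcs(path, panel))
  }
  first <- readLines(path, n = 1)
  if (is.null(panel)) {
    if (!grepl("^# panel: ", first)) {
      abort("Delimited file lacks a '# panel:' line; pass `panel`.")
    }
    panel <- sub("^# panel: ", "", first)
  }
  values <- readr::read_tsv(path,
    comment = "#",
    col_types = readr::cols(.default = "d")
  )
  event_table(values, panel)
}

# ---- FCS 3.1 ----------------------------------------------------------

# TEXT delimiter: the ASCII record separator, which cannot occur in a
# keyword or value here (panel names contain "/").
FCS_DELIM <- "\x1e"

fcs_text_segment <- function(kv) {
  paste0(
    FCS_DELIM,
    paste(rbind(names(kv), unname(unlist(kv))), collapse = FCS_DELIM),
    FCS_DELIM
  )
}

write_events_fcs <- function(events, path) {
  m <- as.matrix(as.data.frame(events))
  n <- nrow(m)
  p <- ncol(m)
  cm <- attr(events, "channel_map")
  kv <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BEGINDATA" = "0000000000", "$ENDDATA" = "0000000000",
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0", "$TOT" = as.character(n), "$PAR" = as.character(p),
    "LEUKOGATE$PANEL" = attr(events, "panel")
  )
  for (i in seq_len(p)) {
    ch <- colnames(m)[i]
    kv[sprintf("$P%dN", i)] <- ch
    kv[sprintf("$P%dS", i)] <- cm$marker[cm$channel_id == ch]
    kv[sprintf("$P%dB", i)] <- "32"
    kv[sprintf("$P%dE", i)] <- "0,0"
    kv[sprintf("$P%dR", i)] <- as.character(ceiling(max(m[, i], 1)))
  }
  text <- fcs_text_segment(kv)
  text_start <- 58L
  text_end <- text_start + nchar(text) - 1L
  data_start <- text_end + 1L
  data_end <- data_start + 4L * n * p - 1L
  # the zero-padded offset placeholders keep the segment length fixed
  text <- sub("0000000000", sprintf("%010d", data_start), text, fixed = TRUE)
  text <- sub("0000000000", sprintf("%010d", data_end), text, fixed = TRUE)
  header <- sprintf(
    "FCS3.1    %8d%8d%8d%8d%8d%8d",
    text_start, text_end, data_start, data_end, 0L, 0L
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL, useBytes = TRUE)
  writeChar(text, con, eos = NULL, useBytes = TRUE)
  writeBin(as.vector(t(m)), con, size = 4, endian = "little")
  invisible(path)
}

read_events_fcs <- function(path, panel = NULL) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 58) abort("Truncated FCS file: no header.")
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58, useBytes = TRUE)
  if (!identical(substr(header, 1, 6), "FCS3.1")) {
    abort("Not an FCS 3.1 file.")
  }
  off <- function(i) {
    as.integer(trimws(substr(header, 11 + 8 * (i - 1), 10 + 8 * i)))
  }
  text_start <- off(1)
  text_end <- off(2)
  if (is.na(text_start) || is.na(text_end) || text_end > sz) {
    abort("Truncated FCS file: bad TEXT offsets.")
  }
  seek(con, text_start)
  text <- readChar(con, text_end - text_start + 1, useBytes = TRUE)
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 != 0) parts <- head(parts, -1)
  kv <- setNames(
    parts[seq(2, length(parts), 2)],
    parts[seq(1, length(parts), 2)]
  )
  if (!identical(kv[["$DATATYPE"]], "F") || !identical(kv[["$MODE"]], "L")) {
    abort("Only FCS list-mode float data is supported.")
  }
  endian <- if (identical(kv[["$BYTEORD"]], "4,3,2,1")) "big" else "little"
  n <- as.integer(kv[["$TOT"]])
  p <- as.integer(kv[["$PAR"]])
  data_start <- as.integer(kv[["$BEGINDATA"]])
  if (is.na(data_start) || data_start == 0) data_start <- off(3)
  if (data_start + 4 * n * p - 1 > sz) {
    abort("Truncated FCS file: data segment shorter than $TOT x $PAR.")
  }
  seek(con, data_start)
  vals <- readBin(con, "numeric", n = n * p, size = 4, endian = endian)
  if (length(vals) < n * p) abort("Truncated FCS file: short read.")
  m <- matrix(vals, nrow = n, ncol = p, byrow = TRUE)
  colnames(m) <- vapply(
    seq_len(p), function(i) kv[[sprintf("$P%dN", i)]], character(1)
  )
  if (is.null(panel)) panel <- kv[["LEUKOGATE$PANEL"]]
  if (is.null(panel)) abort("FCS file names no panel; pass `panel`.")
  event_table(m, panel)
}
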