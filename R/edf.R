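## European Data Format (EDF+) reader/writer.
##
## Implements the subset of EDF+C the package needs: 16-bit signals with
## per-signal physical scaling and one "EDF Annotations" channel carrying
## time-stamped annotation lists (TALs). Implemented natively because the
## surrounding R stack has no EDF package; the format is fixed-width ASCII
## headers plus little-endian int16 records.

edf_pad <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  assert_that(all(nchar(s) == width), "EDF header field overflow")
  s
}

edf_num <- function(x, width) {
  s <- vapply(x, function(v) {
    for (d in 7:1) {
      c <- formatC(v, format = "g", digits = d)
      if (nchar(c) <= width) return(c)
    }
    stop2("cannot format number within an EDF header field")
  }, character(1))
  edf_pad(s, width)
}

#' Write a recording as EDF+
#'
#' Serializes an [eeg_recording()] to a 16-bit EDF+C file with one
#' annotation channel holding the trial cues (onset, duration, label).
#' Physical scaling is chosen per channel from the data range, so samples
#' round-trip within one quantization step of
#' `(physical max - physical min) / 65535`.
#'
#' @param rec An [eeg_recording()] whose sampling rate yields an integer
#'   number of samples per 1-s data record.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  sf <- rec$sfreq
  assert_that(abs(sf - round(sf)) < 1e-9, "write_edf needs an integer sampling rate")
  sf <- round(sf)
  nch <- nrow(rec$data)
  n_rec <- ceiling(ncol(rec$data) / sf)
  pad_n <- n_rec * sf - ncol(rec$data)
  data <- if (pad_n > 0) cbind(rec$data, matrix(0, nch, pad_n)) else rec$data

  pmin_ <- apply(data, 1, min)
  pmax_ <- apply(data, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767

  ann_bytes <- 120  # per-record annotation payload (60 two-byte "samples")
  ann <- rec$annotations

  con <- file(path, "wb")
  on.exit(close(con))
  ns <- nch + 1
  header_bytes <- 256 * (1 + ns)
  writeChar(paste0(
    edf_pad("0", 8),
    edf_pad("X X X X", 80),
    edf_pad("Startdate X X X X", 80),
    "01.01.00", "00.00.00",
    edf_pad(header_bytes, 8),
    edf_pad("EDF+C", 44),
    edf_pad(n_rec, 8),
    edf_pad(1, 8),
    edf_pad(ns, 4)), con, eos = NULL)
  lab <- c(edf_pad(rec$channel_names, 16), edf_pad("EDF Annotations", 16))
  writeChar(paste0(
    paste(lab, collapse = ""),
    paste(edf_pad(rep("", ns), 80), collapse = ""),                 # transducer
    paste(edf_pad(c(rep("uV", nch), ""), 8), collapse = ""),        # phys dim
    paste(c(edf_num(pmin_, 8), edf_pad(-1, 8)), collapse = ""),     # phys min
    paste(c(edf_num(pmax_, 8), edf_pad(1, 8)), collapse = ""),      # phys max
    paste(edf_pad(rep(dmin, ns), 8), collapse = ""),                # dig min
    paste(edf_pad(rep(dmax, ns), 8), collapse = ""),                # dig max
    paste(edf_pad(rep("", ns), 80), collapse = ""),                 # prefilter
    paste(edf_pad(c(rep(sf, nch), ann_bytes / 2), 8), collapse = ""),
    paste(edf_pad(rep("", ns), 32), collapse = "")), con, eos = NULL)

  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * sf + 1):(r * sf)
    for (ch in seq_len(nch)) {
      dig <- round((data[ch, cols] - pmin_[ch]) / scale[ch]) + dmin
      writeBin(as.integer(pmin(dmax, pmax(dmin, dig))), con, size = 2,
               endian = "little")
    }
    # TALs are NUL-separated; NUL cannot appear in an R string, so the
    # payload is assembled as raw bytes
    tals <- sprintf("+%g\x14\x14", r - 1)  # record timestamp TAL
    if (!is.null(ann) && nrow(ann) > 0) {
      in_rec <- which(ann$onset >= r - 1 & ann$onset < r)
      tals <- c(tals, sprintf("+%g\x15%g\x14%s\x14", ann$onset[in_rec],
                              ann$duration[in_rec], ann$label[in_rec]))
    }
    raw_tal <- unlist(lapply(tals, function(s) c(charToRaw(s), as.raw(0))))
    assert_that(length(raw_tal) < ann_bytes,
                "annotation payload exceeds the per-record budget")
    writeBin(c(raw_tal, raw(ann_bytes - length(raw_tal))), con)
  }
  invisible(path)
}

#' Read an EDF/EDF+ file
#'
#' Parses the header, signal data (with physical scaling) and, if present,
#' the `EDF Annotations` channel into an [eeg_recording()]. Malformed files
#' raise a parse error naming the byte offset of the inconsistency.
#'
#' @param path An EDF file.
#' @return An [eeg_recording()] (annotation labels/onsets in
#'   `$annotations`; the timestamp-only TALs are dropped).
#' @export
read_edf <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    x <- readChar(con, n, useBytes = TRUE)
    assert_that(nchar(x, type = "bytes") == n,
                sprintf("EDF parse error: truncated header at byte %d", seek(con)))
    x
  }
  rd(8)                                   # version
  rd(80); rd(80); rd(8); rd(8)            # patient, recording, date, time
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  assert_that(is.finite(ns) && ns > 0, "EDF parse error: bad signal count at byte 252")
  fields <- function(w) vapply(seq_len(ns), function(i) trimws(rd(w)), character(1))
  labels <- fields(16)
  fields(80)
  fields(8)
  pmin_ <- as.numeric(fields(8)); pmax_ <- as.numeric(fields(8))
  dmin <- as.numeric(fields(8)); dmax <- as.numeric(fields(8))
  fields(80)
  spr <- as.integer(fields(8))
  fields(32)
  expect_hdr <- 256 * (1 + ns)
  assert_that(header_bytes == expect_hdr,
              sprintf("EDF parse error: header size %d != %d at byte 184",
                      header_bytes, expect_hdr))
  payload <- sz - header_bytes
  rec_bytes <- sum(spr) * 2
  assert_that(payload == n_rec * rec_bytes,
              sprintf("EDF parse error: payload %d bytes, expected %d (%d records x %d) after byte %d",
                      payload, n_rec * rec_bytes, n_rec, rec_bytes, header_bytes))

  is_ann <- labels == "EDF Annotations"
  sig_idx <- which(!is_ann)
  sf <- spr[sig_idx[1]] / rec_dur
  data <- matrix(0, length(sig_idx), n_rec * spr[sig_idx[1]])
  ann_text <- character(0)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      if (is_ann[s]) {
        bytes <- readBin(con, raw(), n = spr[s] * 2)
        bytes[bytes == as.raw(0)] <- as.raw(1)  # NUL -> sentinel (R strings cannot hold NUL)
        ann_text <- c(ann_text, rawToChar(bytes))
      } else {
        vals <- readBin(con, integer(), n = spr[s], size = 2, endian = "little")
        ch <- match(s, sig_idx)
        scale <- (pmax_[s] - pmin_[s]) / (dmax[s] - dmin[s])
        cols <- ((r - 1) * spr[s] + 1):(r * spr[s])
        data[ch, cols] <- (vals - dmin[s]) * scale + pmin_[s]
      }
    }
  }
  ann <- parse_tals(paste(ann_text, collapse = ""))
  eeg_recording(data, sf, labels[sig_idx], ann)
}

# Parse TAL annotation text (NULs replaced by \x01 sentinels) into an
# annotations data frame, dropping the bare record-timestamp TALs.
parse_tals <- function(txt) {
  out <- empty_annotations()
  for (tal in strsplit(txt, "\x01", fixed = TRUE)[[1]]) {
    if (tal == "" || !grepl("\x14", tal)) next
    parts <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
    label <- if (length(parts) >= 2) parts[2] else ""
    if (label == "") next
    od <- strsplit(parts[1], "\x15", fixed = TRUE)[[1]]
    out <- rbind(out, data.frame(onset = as.numeric(od[1]),
                                 duration = if (length(od) > 1) as.numeric(od[2]) else 0,
                                 label = label))
  }
  out
}
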