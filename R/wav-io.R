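# Minimal 16-bit PCM RIFF/WAV I/O for tag audio, with a JSON sidecar
# carrying the clip level (WAV files store normalised samples; the clip
# level maps full scale back to pascal).

#' Write tag audio as 16-bit PCM WAV
#'
#' Pressure samples are scaled so that the clip level maps to full scale,
#' quantised to 16 bits and written as a standard mono RIFF/WAV file. The
#' clip level and sampling rate are recorded in a JSON sidecar
#' (`<path>.json`) so the pressure scale can be recovered on read.
#'
#' @param audio A `tag_audio` object.
#' @param path Output path (`.wav`).
#' @return `path`, invisibly.
#' @export
write_tag_wav <- function(audio, path) {
  a <- as_audio(audio)
  clip_pa <- P_REF * 10^(a$clip_db / 20)
  x <- as.integer(round(pmin(pmax(a$pressure / clip_pa, -1), 1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_data <- length(x) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_data), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(a$fs), con, size = 4, endian = "little")
  writeBin(as.integer(a$fs * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_data, con, size = 4, endian = "little")
  writeBin(x, con, size = 2, endian = "little")
  jsonlite::write_json(list(clip_db = a$clip_db, fs = a$fs),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read tag audio from a 16-bit PCM WAV
#'
#' @param path Path to a WAV written by [write_tag_wav()] (or any mono
#'   16-bit PCM WAV). The JSON sidecar supplies the clip level; without it
#'   `clip_db` must be given.
#' @param clip_db Clip level (dB re 20 uPa) when no sidecar exists.
#' @return A `tag_audio` object with pressure in Pa.
#' @export
read_tag_wav <- function(path, clip_db = NULL) {
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    clip_db <- clip_db %||% meta$clip_db
  }
  if (is.null(clip_db)) abort("clip_db required (no sidecar found)")
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4); readBin(con, "integer", size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (riff != "RIFF" || wave != "WAVE") abort("not a RIFF/WAVE file")
  fs <- NULL; bits <- NULL; channels <- NULL; x <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", n = 2, size = 2, endian = "little")
      channels <- fmt[2]
      fs <- readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 4, endian = "little")
      block <- readBin(con, "integer", size = 2, endian = "little")
      bits <- readBin(con, "integer", size = 2, endian = "little")
      if (sz > 16) readBin(con, "raw", n = sz - 16)
    } else if (id == "data") {
      x <- readBin(con, "integer", n = sz / 2, size = 2, signed = TRUE,
                   endian = "little")
      break
    } else {
      readBin(con, "raw", n = sz)
    }
  }
  if (is.null(x)) abort("no data chunk found")
  if (!identical(bits, 16L) || !identical(channels, 1L))
    abort("only mono 16-bit PCM is supported")
  clip_pa <- P_REF * 10^(clip_db / 20)
  structure(list(pressure = x / 32767 * clip_pa, fs = fs, clip_db = clip_db,
                 clipped_fraction = mean(abs(x) >= 32767)),
            class = "tag_audio")
}
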