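#' Write a waveform to a WAV file
#'
#' Minimal RIFF/WAVE writer (mono, 32-bit IEEE float PCM). No R WAV package
#' is required at run time.
#'
#' @param x An [audio_stimulus()] or numeric vector.
#' @param path Output file path.
#' @param fs Sampling rate; taken from `x` when it is an `audio_stimulus`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, fs = NULL) {
  if (inherits(x, "audio_stimulus")) {
    fs <- x$fs
    x <- x$samples
  }
  if (is.null(fs)) abort("`fs` is required when `x` is a bare vector")
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(x)
  data_bytes <- 4L * n
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little") # IEEE float
  writeBin(1L, con, size = 2, endian = "little") # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 4L), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(32L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(as.numeric(x), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a WAV file
#'
#' Reads mono or multichannel RIFF/WAVE files in 16-bit integer or 32-bit
#' float PCM; multichannel input is averaged to mono.
#'
#' @param path WAV file path.
#' @param variant Variant tag for the returned [audio_stimulus()].
#' @return An [audio_stimulus()].
#' @export
read_wav <- function(path, variant = "clear") {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) abort("not a RIFF file")
  readBin(con, integer(), size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) abort("not a WAVE file")
  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || !nzchar(id)) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        format = readBin(con, integer(), size = 2, endian = "little"),
        channels = readBin(con, integer(), size = 2, endian = "little"),
        fs = readBin(con, integer(), size = 4, endian = "little")
      )
      readBin(con, raw(), n = sz - 8)
    } else if (identical(id, "data")) {
      if (is.null(fmt)) abort("malformed WAV: data before fmt")
      if (fmt$format == 3L) {
        samples <- readBin(con, numeric(),
          n = sz / 4, size = 4,
          endian = "little"
        )
      } else if (fmt$format == 1L) {
        raw16 <- readBin(con, integer(),
          n = sz / 2, size = 2,
          signed = TRUE, endian = "little"
        )
        samples <- raw16 / 32768
      } else {
        abort(paste0("unsupported WAV format code ", fmt$format))
      }
      break
    } else {
      readBin(con, raw(), n = sz)
    }
  }
  if (is.null(samples)) abort("malformed WAV: no data chunk")
  if (fmt$channels > 1L) {
    samples <- colMeans(matrix(samples, nrow = fmt$channels))
  }
  audio_stimulus(samples, fmt$fs, variant)
}

#' Serialize a simulated session to a directory of text files
#'
#' Writes the design and ratings as TSV, metadata (seed provenance,
#' sampling rates) as JSON, and EEG/pupil matrices as TSV, under a
#' documented directory structure: `design.tsv`, `meta.json`,
#' `training_eeg.tsv`, `training_envelope.tsv`,
#' `trials/trial<k>_pres<p>.tsv` and `pupil/trial<k>.tsv`. Everything is
#' plain text, so sessions round-trip across platforms; intended for
#' desk-scale sessions (full-scale sessions are better kept in memory).
#'
#' @param session A session from [simulate_session()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(session$design, file.path(dir, "design.tsv"),
    progress = FALSE
  )
  jsonlite::write_json(session$meta, file.path(dir, "meta.json"),
    auto_unbox = TRUE, digits = NA
  )
  write_mat <- function(m, path) {
    utils::write.table(format(m, digits = 10, trim = TRUE),
      path,
      sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE
    )
  }
  write_mat(session$training$eeg$data, file.path(dir, "training_eeg.tsv"))
  write_mat(
    matrix(session$training$envelope$samples, nrow = 1),
    file.path(dir, "training_envelope.tsv")
  )
  dir.create(file.path(dir, "trials"), showWarnings = FALSE)
  for (nm in names(session$trials)) {
    write_mat(
      session$trials[[nm]]$data,
      file.path(dir, "trials", paste0(nm, ".tsv"))
    )
  }
  if (!is.null(session$pupil)) {
    dir.create(file.path(dir, "pupil"), showWarnings = FALSE)
    for (nm in names(session$pupil)) {
      tr <- session$pupil[[nm]]
      readr::write_tsv(
        tibble::tibble(left = tr$left, right = tr$right),
        file.path(dir, "pupil", paste0(nm, ".tsv")),
        progress = FALSE
      )
    }
  }
  invisible(dir)
}
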