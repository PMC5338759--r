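# Readers and writers for the external formats: Praat TextGrid and TSV
# alignments, 16-bit PCM WAV, delimited EEG matrices and delimited
# spectrogram/PRP matrices with JSON headers. All delimited formats use
# "%.17g" formatting, which round-trips IEEE doubles exactly.

#' Write a phoneme alignment as TSV
#' @param alignment a [phoneme_alignment()].
#' @param path output path.
#' @export
write_alignment_tsv <- function(alignment, path) {
  df <- as.data.frame(alignment)
  df$onset <- format_full(df$onset)
  df$offset <- format_full(df$offset)
  utils::write.table(df[, c("label", "onset", "offset", "speaker",
                            "utterance")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a phoneme alignment from TSV
#'
#' Expects columns label, onset, offset, speaker, utterance; overlapping or
#' out-of-order intervals are rejected.
#'
#' @param path input path.
#' @return a [phoneme_alignment()].
#' @export
read_alignment_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(label = "character",
                                         speaker = "character"))
  need <- c("label", "onset", "offset", "speaker", "utterance")
  if (!all(need %in% names(df)))
    stop_invalid("alignment TSV must have columns: ",
                 paste(need, collapse = ", "))
  phoneme_alignment(df$label, df$onset, df$offset, df$speaker, df$utterance)
}

#' Write a phoneme alignment as a Praat TextGrid
#'
#' One interval tier ("phones") in long TextGrid format; interval labels
#' carry speaker and utterance as `"PHONE|speaker|utterance"`. Gaps between
#' tokens become empty-label intervals.
#'
#' @param alignment a [phoneme_alignment()].
#' @param path output path.
#' @export
write_textgrid <- function(alignment, path) {
  xmax <- if (nrow(alignment)) max(alignment$offset) else 0
  iv <- list()
  t <- 0
  for (i in seq_len(nrow(alignment))) {
    if (alignment$onset[i] > t + 1e-9)
      iv[[length(iv) + 1L]] <- c(t, alignment$onset[i], "")
    iv[[length(iv) + 1L]] <-
      c(alignment$onset[i], alignment$offset[i],
        paste(alignment$label[i], alignment$speaker[i],
              alignment$utterance[i], sep = "|"))
    t <- alignment$offset[i]
  }
  if (t < xmax - 1e-9 || length(iv) == 0L)
    iv[[length(iv) + 1L]] <- c(t, xmax, "")
  lines <- c(
    'File type = "ooTextFile"', 'Object class = "TextGrid"', "",
    "xmin = 0", sprintf("xmax = %s", format_full(xmax)),
    "tiers? <exists>", "size = 1", "item []:", "    item [1]:",
    '        class = "IntervalTier"', '        name = "phones"',
    "        xmin = 0", sprintf("        xmax = %s", format_full(xmax)),
    sprintf("        intervals: size = %d", length(iv)))
  for (j in seq_along(iv)) {
    lines <- c(lines,
               sprintf("        intervals [%d]:", j),
               sprintf("            xmin = %s",
                       format_full(as.numeric(iv[[j]][1]))),
               sprintf("            xmax = %s",
                       format_full(as.numeric(iv[[j]][2]))),
               sprintf('            text = "%s"', iv[[j]][3]))
  }
  writeLines(lines, path)
}

#' Read a phoneme alignment from a Praat TextGrid
#'
#' Parses the first interval tier of a long-format TextGrid. Labels of the
#' form `"PHONE|speaker|utterance"` populate the speaker/utterance fields;
#' empty labels are skipped. Malformed files raise a parse error naming the
#' offending line.
#'
#' @param path input path.
#' @return a [phoneme_alignment()].
#' @export
read_textgrid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("IntervalTier", lines)))
    stop_invalid("no interval tier found in ", path)
  ivs <- grep("intervals \\[[0-9]+\\]", lines)
  get_num <- function(i, key) {
    ln <- lines[i]
    if (!grepl(paste0(key, " ?="), ln))
      stop_invalid(sprintf("parse error at line %d: expected '%s'", i, key))
    as.numeric(sub(paste0(".*", key, " ?= ?"), "", ln))
  }
  lab <- character(0); on <- numeric(0); off <- numeric(0)
  for (i in ivs) {
    x0 <- get_num(i + 1L, "xmin")
    x1 <- get_num(i + 2L, "xmax")
    txt <- sub('.*text = "(.*)".*', "\\1", lines[i + 3L])
    if (!grepl("text", lines[i + 3L]))
      stop_invalid(sprintf("parse error at line %d: expected 'text'",
                           i + 3L))
    if (nzchar(txt)) {
      lab <- c(lab, txt); on <- c(on, x0); off <- c(off, x1)
    }
  }
  if (length(lab) == 0L) {
    warning("empty phone tier: empty alignment")
    return(phoneme_alignment(character(0), numeric(0), numeric(0),
                             character(0), integer(0)))
  }
  parts <- strsplit(lab, "|", fixed = TRUE)
  phone <- vapply(parts, `[`, "", 1L)
  speaker <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else "sp1",
                    "")
  utt <- vapply(parts, function(p)
    if (length(p) >= 3L) as.integer(p[3L]) else 1L, integer(1))
  phoneme_alignment(phone, on, off, speaker, utt)
}

#' Generic alignment reader
#' @param path input path.
#' @param dialect `"textgrid"` or `"tsv"` (default: guess from extension).
#' @return a [phoneme_alignment()].
#' @export
read_alignment <- function(path, dialect = c("auto", "textgrid", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.textgrid$", tolower(path))) "textgrid"
               else "tsv"
  switch(dialect, textgrid = read_textgrid(path),
         tsv = read_alignment_tsv(path))
}

#' Write a mono waveform as 16-bit PCM WAV
#' @param wave a `waveform` (samples in \[-1, 1\]; clipped otherwise).
#' @param path output path.
#' @export
write_wav <- function(wave, path) {
  x <- pmin(1, pmax(-1, wave$samples))
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")        # PCM
  writeBin(1L, con, size = 2, endian = "little")        # mono
  writeBin(as.integer(wave$fs), con, size = 4, endian = "little")
  writeBin(as.integer(wave$fs * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")        # block align
  writeBin(16L, con, size = 2, endian = "little")       # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#' @param path input path.
#' @return a `waveform`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop_invalid("not a RIFF/WAV file")
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop_invalid("not a WAV file")
  fs <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || !nzchar(id)) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (length(size) == 0L) break
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L)
        stop_invalid("only 16-bit PCM mono WAV is supported")
      fs <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, raw(), n = size - 8L))
    } else if (id == "data") {
      samples <- readBin(con, integer(), n = size / 2L, size = 2,
                         endian = "little")
      if (length(samples) < size / 2L)
        stop_invalid("truncated WAV data chunk")
      break
    } else {
      invisible(readBin(con, raw(), n = size))
    }
  }
  if (is.null(fs) || is.null(samples))
    stop_invalid("missing fmt/data chunk in WAV file")
  structure(list(samples = samples / 32767, fs = fs), class = "waveform")
}

# Delimited matrix with a '#'-prefixed JSON header. Used for EEG,
# spectrograms and flattened PRP arrays.
write_matrix_text <- function(values, meta, path) {
  header <- paste0("#", jsonlite::toJSON(meta, auto_unbox = TRUE,
                                         digits = I(17)))
  rows <- vapply(seq_len(nrow(values)), function(i)
    paste(format_full(values[i, ]), collapse = "\t"), character(1))
  writeLines(c(header, rows), path)
}

read_matrix_text <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#"))
    stop_invalid("missing JSON header line in ", path)
  meta <- jsonlite::fromJSON(substring(first, 2L))
  values <- as.matrix(utils::read.table(path, sep = "\t", skip = 1L,
                                        header = FALSE,
                                        colClasses = "numeric"))
  dimnames(values) <- NULL
  list(values = values, meta = meta)
}

#' Write an EEG recording as delimited text
#'
#' Tab-separated electrode x time matrix preceded by a JSON header line
#' (`fs`, `electrode_labels`, `reference`). Exact round trip.
#'
#' @param rec an [eeg_recording()].
#' @param path output path.
#' @export
write_eeg_text <- function(rec, path) {
  write_matrix_text(rec$values,
                    list(format = "prpkit-eeg", fs = rec$fs,
                         electrode_labels = rec$electrode_labels,
                         reference = rec$reference),
                    path)
}

#' Read an EEG recording from delimited text
#' @param path input path.
#' @return an [eeg_recording()].
#' @export
read_eeg_text <- function(path) {
  m <- read_matrix_text(path)
  if (is.null(m$meta$fs)) stop_invalid("EEG header lacks `fs`")
  labels <- m$meta$electrode_labels
  if (is.null(labels)) stop_invalid("EEG header lacks electrode labels")
  if (length(labels) != nrow(m$values))
    stop_invalid("EEG file truncated: ", nrow(m$values), " rows for ",
                 length(labels), " electrodes")
  eeg_recording(m$values, as.numeric(m$meta$fs), labels,
                m$meta$reference %||% "unknown")
}

#' Generic EEG reader
#' @param path input path.
#' @param format currently `"delimited"`.
#' @return an [eeg_recording()].
#' @export
read_eeg <- function(path, format = "delimited") {
  if (format != "delimited")
    stop_invalid("unsupported EEG format: ", format)
  read_eeg_text(path)
}

#' Write an auditory spectrogram as delimited text
#' @param spec an [auditory_spectrogram()].
#' @param path output path.
#' @export
write_spectrogram_text <- function(spec, path) {
  write_matrix_text(spec$values,
                    list(format = "prpkit-spectrogram",
                         center_frequencies = spec$center_frequencies,
                         frame_rate = spec$frame_rate),
                    path)
}

#' Read an auditory spectrogram from delimited text
#' @param path input path.
#' @return an [auditory_spectrogram()].
#' @export
read_spectrogram_text <- function(path) {
  m <- read_matrix_text(path)
  auditory_spectrogram(m$values, as.numeric(m$meta$center_frequencies),
                       as.numeric(m$meta$frame_rate))
}

#' Write a PRP set as delimited text
#'
#' The category x electrode x lag array is flattened to (category *
#' electrode) x lag rows; the JSON header records categories, counts,
#' electrodes and the lag grid.
#'
#' @param prp a `prp_set`.
#' @param path output path.
#' @export
write_prp_text <- function(prp, path) {
  k <- dim(prp$values)[1]; e <- dim(prp$values)[2]
  flat <- matrix(aperm(prp$values, c(2, 1, 3)), nrow = k * e)
  write_matrix_text(flat,
                    list(format = "prpkit-prp", categories = prp$categories,
                         counts = prp$counts, electrodes = prp$electrodes,
                         lag_ms = prp$lag_ms, subject = prp$subject),
                    path)
}

#' Read a PRP set from delimited text
#' @param path input path.
#' @return a `prp_set`.
#' @export
read_prp_text <- function(path) {
  m <- read_matrix_text(path)
  meta <- m$meta
  k <- length(meta$categories); e <- length(meta$electrodes)
  vals <- aperm(array(m$values, dim = c(e, k, length(meta$lag_ms))),
                c(2, 1, 3))
  dimnames(vals) <- list(meta$categories, meta$electrodes, NULL)
  new_prp_set(vals, as.integer(meta$counts), as.numeric(meta$lag_ms),
              meta$electrodes, meta$subject %||% NA)
}

#' Write a dendrogram in Newick format
#' @param cluster result of [upgma_cluster()].
#' @param path output path.
#' @export
write_newick <- function(cluster, path) {
  ape::write.tree(cluster$phylo, file = path)
  invisible(path)
}

#' Serialize ground truth to JSON
#' @param ground_truth a `ground_truth` from [gen_eeg()].
#' @param path output path.
#' @export
write_ground_truth <- function(ground_truth, path) {
  gt <- ground_truth
  obj <- list(
    kernel_spec = unclass(gt$kernel_spec),
    amplitudes = list(dim = dim(gt$amplitudes),
                      values = as.vector(gt$amplitudes)),
    montage = gt$montage, categories = gt$categories,
    manner = as.list(gt$manner), speaker_ids = gt$speaker_ids,
    fs = gt$fs, support_ms = gt$support_ms, noise = gt$noise,
    artifact_times = gt$artifact_times,
    artifact_width_s = gt$artifact_width_s,
    speaker_separation = gt$speaker_separation, seed = gt$seed)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17)), path)
}

#' Reload ground truth from JSON
#' @param path input path.
#' @return a `ground_truth`.
#' @export
read_ground_truth <- function(path) {
  obj <- jsonlite::fromJSON(paste(readLines(path, warn = FALSE),
                                  collapse = ""))
  ks <- obj$kernel_spec
  spec <- kernel_spec(ks$component_latencies, ks$component_widths,
                      as.matrix(ks$manner_gains), ks$acoustic_coupling,
                      ks$speaker_separation,
                      list(manner = ks$speaker_target$manner,
                           component = ks$speaker_target$component))
  amp <- array(obj$amplitudes$values, dim = obj$amplitudes$dim,
               dimnames = list(obj$categories, obj$speaker_ids,
                               obj$montage$labels, NULL))
  structure(list(kernel_spec = spec, amplitudes = amp,
                 montage = obj$montage, categories = obj$categories,
                 manner = unlist(obj$manner), speaker_ids = obj$speaker_ids,
                 fs = obj$fs, support_ms = obj$support_ms,
                 noise = obj$noise,
                 artifact_times = as.numeric(obj$artifact_times),
                 artifact_width_s = obj$artifact_width_s,
                 speaker_separation = obj$speaker_separation,
                 seed = obj$seed),
            class = "ground_truth")
}
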