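#' @keywords internal
"_PACKAGE"

## Waveform label set used throughout: NP nonprobing, C pathway, PD potential
## drop, E1 phloem salivation, E2 phloem ingestion, F penetration difficulty,
## G xylem ingestion, RPD repetitive potential drop.
epg_labels <- c("NP", "C", "PD", "E1", "E2", "F", "G", "RPD")

## Times are carried internally as integer milliseconds so that segment
## durations telescope exactly (no float drift in conservation checks).
.ms <- function(seconds) round(seconds * 1000)

#' Token-to-waveform code map for annotation files
#'
#' Annotation dialects differ between EPG software exports; a code map makes
#' the token vocabulary pluggable. The default maps lower-case waveform names
#' (`np`, `c`, `pd`, `e1`, `e2`, `f`, `g`, `rpd`) onto the label set and uses
#' `end` as the terminal marker closing a recording.
#'
#' @param tokens Named character vector: names are file tokens, values are
#'   waveform labels (a subset of `NP, C, PD, E1, E2, F, G, RPD`).
#' @param terminal Single token marking the final line (recording end time).
#' @return An object of class `epg_codemap`.
#' @export
epg_codemap <- function(tokens = c(np = "NP", c = "C", pd = "PD", e1 = "E1",
                                   e2 = "E2", f = "F", g = "G", rpd = "RPD"),
                        terminal = "end") {
  stopifnot(is.character(tokens), !is.null(names(tokens)),
            length(terminal) == 1L)
  if (!all(tokens %in% epg_labels))
    stop("unknown waveform label(s) in code map: ",
         paste(setdiff(tokens, epg_labels), collapse = ", "))
  if (anyDuplicated(tokens))
    stop("code map must be injective: duplicated label target")
  if (terminal %in% names(tokens))
    stop("terminal marker must not also be a waveform token")
  structure(list(tokens = tokens, terminal = terminal), class = "epg_codemap")
}

new_recording <- function(recording_id, genotype_id, labels, onset_ms,
                          offset_ms, total_ms) {
  structure(list(recording_id = as.character(recording_id),
                 genotype_id = as.character(genotype_id),
                 segments = data.frame(label = as.character(labels),
                                       onset_ms = as.numeric(onset_ms),
                                       offset_ms = as.numeric(offset_ms)),
                 total_ms = as.numeric(total_ms)),
            class = "epg_recording")
}

#' Construct an EPG recording from segment onsets
#'
#' Segments must partition `[0, total_duration_s)` contiguously. Adjacent
#' segments sharing a label are merged so bout counts are well defined.
#'
#' @param recording_id,genotype_id Identifiers.
#' @param labels Character vector of waveform labels.
#' @param onset_s,offset_s Segment bounds in seconds from recording start.
#' @param total_duration_s Recording length in seconds (default 28800 = 8 h).
#' @return An object of class `epg_recording`.
#' @export
epg_recording <- function(recording_id, genotype_id, labels, onset_s, offset_s,
                          total_duration_s = 28800) {
  rec <- new_recording(recording_id, genotype_id, labels,
                       .ms(onset_s), .ms(offset_s), .ms(total_duration_s))
  rec <- merge_adjacent(rec)
  problems <- validate_recording(rec)
  if (length(problems))
    stop("invalid recording: ", paste(problems, collapse = "; "))
  rec
}

merge_adjacent <- function(rec) {
  seg <- rec$segments
  if (nrow(seg) > 1L) {
    run <- cumsum(c(TRUE, seg$label[-1L] != seg$label[-nrow(seg)]))
    if (max(run) < nrow(seg)) {
      seg <- data.frame(label = tapply(seg$label, run, `[`, 1L),
                        onset_ms = tapply(seg$onset_ms, run, min),
                        offset_ms = tapply(seg$offset_ms, run, max),
                        row.names = NULL)
    }
  }
  rec$segments <- seg
  rec
}

#' Parse a time-stamped EPG waveform annotation file
#'
#' Reads a line-oriented annotation export: each line holds a waveform token
#' and its onset time in seconds (whitespace- or semicolon-delimited), with a
#' final terminal-marker line carrying the recording end time. Line `i` spans
#' `[t_i, t_{i+1})`; adjacent same-label segments are merged. Lines starting
#' with `#` and blank lines are ignored.
#'
#' @param source Path to a file, or a character vector of lines.
#' @param codemap An [epg_codemap()].
#' @param recording_id,genotype_id Identifiers attached to the recording.
#' @return An `epg_recording` covering `[0, end time)` contiguously.
#' @export
parse_annotation <- function(source, codemap = epg_codemap(),
                             recording_id = "rec", genotype_id = NA_character_) {
  stopifnot(inherits(codemap, "epg_codemap"))
  src_name <- "<text>"
  if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    src_name <- source
    source <- readLines(source, warn = FALSE)
  } else if (length(source) == 1L && grepl("\n", source)) {
    source <- strsplit(source, "\n", fixed = TRUE)[[1L]]
  }
  keep <- !grepl("^\\s*(#|$)", source)
  lines <- source[keep]
  lineno <- which(keep)
  if (!length(lines))
    stop("empty annotation source: ", src_name)

  parts <- strsplit(trimws(lines), "[;[:space:]]+")
  bad <- lengths(parts) != 2L
  if (any(bad))
    stop(sprintf("malformed annotation line %d in %s: '%s'",
                 lineno[which(bad)[1L]], src_name, lines[which(bad)[1L]]))
  token <- vapply(parts, `[`, "", 1L)
  time_s <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  if (anyNA(time_s))
    stop(sprintf("non-numeric time on line %d in %s",
                 lineno[which(is.na(time_s))[1L]], src_name))

  n <- length(token)
  if (token[n] != codemap$terminal)
    stop(sprintf("missing terminal marker '%s' in %s",
                 codemap$terminal, src_name))
  if (any(token[-n] == codemap$terminal))
    stop(sprintf("terminal marker before final line (line %d) in %s",
                 lineno[which(token == codemap$terminal)[1L]], src_name))
  unknown <- !(token[-n] %in% names(codemap$tokens))
  if (any(unknown))
    stop(sprintf("unknown waveform token '%s' on line %d in %s",
                 token[which(unknown)[1L]], lineno[which(unknown)[1L]],
                 src_name))
  t_ms <- .ms(time_s)
  if (any(diff(t_ms) <= 0))
    stop(sprintf("non-increasing time on line %d in %s",
                 lineno[which(diff(t_ms) <= 0)[1L] + 1L], src_name))
  if (t_ms[1L] != 0)
    stop(sprintf("first segment must start at 0 (got %s s) in %s",
                 time_s[1L], src_name))

  rec <- new_recording(recording_id, genotype_id,
                       labels = unname(codemap$tokens[token[-n]]),
                       onset_ms = t_ms[-n], offset_ms = t_ms[-1L],
                       total_ms = t_ms[n])
  merge_adjacent(rec)
}

#' Write an EPG recording back to annotation-file text
#'
#' Inverse of [parse_annotation()]: `parse_annotation(write_annotation(rec))`
#' reproduces `rec` exactly (labels, onsets, total duration).
#'
#' @param rec An `epg_recording`.
#' @param codemap An [epg_codemap()]; every label in `rec` must be covered.
#' @param path Optional file path; when given, lines are written there.
#' @return Character vector of annotation lines (invisibly when `path` given).
#' @export
write_annotation <- function(rec, codemap = epg_codemap(), path = NULL) {
  stopifnot(inherits(rec, "epg_recording"), inherits(codemap, "epg_codemap"))
  rev_map <- stats::setNames(names(codemap$tokens), codemap$tokens)
  missing <- setdiff(unique(rec$segments$label), names(rev_map))
  if (length(missing))
    stop("code map lacks token(s) for label(s): ",
         paste(missing, collapse = ", "))
  fmt <- function(ms) sub("\\.?0+$", "", sprintf("%.3f", ms / 1000))
  lines <- c(paste(rev_map[rec$segments$label], fmt(rec$segments$onset_ms)),
             paste(codemap$terminal, fmt(rec$total_ms)))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Check the structural invariants of an EPG recording
#'
#' @param rec An `epg_recording` (or anything shaped like one).
#' @return Character vector of violations (empty when the recording is valid);
#'   each entry names the offending segment index and the rule broken.
#' @export
validate_recording <- function(rec) {
  v <- character()
  seg <- rec$segments
  n <- nrow(seg)
  if (n == 0L) return("no segments")
  bad_label <- which(!(seg$label %in% epg_labels))
  for (i in bad_label)
    v <- c(v, sprintf("segment %d: unknown label '%s'", i, seg$label[i]))
  if (seg$onset_ms[1L] != 0)
    v <- c(v, "segment 1: first onset must be 0")
  nonpos <- which(seg$offset_ms <= seg$onset_ms)
  for (i in nonpos)
    v <- c(v, sprintf("segment %d: positive duration violated", i))
  if (n > 1L) {
    gaps <- which(seg$onset_ms[-1L] != seg$offset_ms[-n])
    for (i in gaps)
      v <- c(v, sprintf("segment %d: contiguity violated (offset %g != next onset %g)",
                        i, seg$offset_ms[i] / 1000, seg$onset_ms[i + 1L] / 1000))
    same <- which(seg$label[-1L] == seg$label[-n])
    for (i in same)
      v <- c(v, sprintf("segment %d: adjacent segments share label '%s'",
                        i, seg$label[i]))
  }
  if (seg$offset_ms[n] != rec$total_ms)
    v <- c(v, sprintf("segment %d: last offset %g != total duration %g",
                      n, seg$offset_ms[n] / 1000, rec$total_ms / 1000))
  v
}

#' @export
as.data.frame.epg_recording <- function(x, ...) {
  data.frame(recording_id = x$recording_id, genotype_id = x$genotype_id,
             label = x$segments$label,
             onset_s = x$segments$onset_ms / 1000,
             offset_s = x$segments$offset_ms / 1000,
             duration_s = (x$segments$offset_ms - x$segments$onset_ms) / 1000)
}

#' @export
print.epg_recording <- function(x, ...) {
  cat(sprintf("EPG recording '%s' (genotype %s): %d segments over %.1f min\n",
              x$recording_id, x$genotype_id, nrow(x$segments),
              x$total_ms / 60000))
  tab <- tapply((x$segments$offset_ms - x$segments$onset_ms) / 60000,
                factor(x$segments$label, levels = epg_labels), sum,
                default = 0)
  cat("minutes per waveform:\n")
  print(round(tab, 2))
  invisible(x)
}

#' Read a recording metadata table
#'
#' @param path CSV or TSV file with at least columns `recording_id`,
#'   `genotype_id` and `ct_class` (`high` or `low`).
#' @return A data frame.
#' @export
read_epg_metadata <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  md <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("recording_id", "genotype_id", "ct_class")
  miss <- setdiff(need, names(md))
  if (length(miss))
    stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(md$ct_class %in% c("high", "low")))
    stop("ct_class must be 'high' or 'low'")
  md
}
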