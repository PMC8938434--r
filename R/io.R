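# Readers and writers for the delimited-table dialects the analyzers
# consume, Sparky-style peak lists, and FASTA sequences.

#' Read a delimited table with schema validation
#'
#' Thin wrapper around [utils::read.csv()] that validates the header
#' against a set of required columns (missing columns are reported by
#' name) and checks that the columns declared numeric parse completely
#' (unparsable cells are reported with their row numbers).
#'
#' @param path Path to a CSV file with a header row.
#' @param required Character vector of required column names.
#' @param numeric_cols Columns that must be fully numeric (default: all
#'   required columns except obvious label columns is up to the caller;
#'   pass explicitly).
#' @param sep Field separator (default `","`).
#' @return A data frame.
#' @export
read_table_checked <- function(path, required, numeric_cols = character(0),
                               sep = ",") {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (col in numeric_cols) {
    v <- df[[col]]
    if (is.character(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(parsed) & !is.na(v) & nzchar(v))
      if (length(bad) > 0L) {
        stop(sprintf("%s: column '%s' has unparsable value(s) at row(s) %s",
                     path, col, paste(utils::head(bad, 5L), collapse = ", ")),
             call. = FALSE)
      }
      df[[col]] <- parsed
    }
  }
  df
}

#' Read a TRACT decay table
#'
#' CSV with columns `residue`, `state` (`alpha`/`beta`), `delay_s`,
#' `intensity`.
#'
#' @param path Path to the CSV file.
#' @return Data frame ready for [run_tract()].
#' @export
read_tract_table <- function(path) {
  read_table_checked(path,
                     required = c("residue", "state", "delay_s", "intensity"),
                     numeric_cols = c("delay_s", "intensity"))
}

#' Read a FRAP curve table
#'
#' CSV with columns `time_s`, `roi` and optionally `reference`.
#'
#' @param path Path to the CSV file.
#' @return Data frame.
#' @export
read_frap_table <- function(path) {
  df <- read_table_checked(path, required = c("time_s", "roi"),
                           numeric_cols = c("time_s", "roi"))
  if ("reference" %in% names(df)) {
    df$reference <- as.numeric(df$reference)
  }
  df
}

#' Read a DLS temperature-ramp table
#'
#' CSV with columns `temperature_c`, `radius_nm`.
#'
#' @param path Path to the CSV file.
#' @return Data frame.
#' @export
read_dls_ramp <- function(path) {
  read_table_checked(path, required = c("temperature_c", "radius_nm"),
                     numeric_cols = c("temperature_c", "radius_nm"))
}

#' Read a Sparky-style peak list
#'
#' Parses lines of the form `Assignment w1 w2 [Height]`; a `?`
#' assignment marks an unassigned peak, and a header line starting with
#' "Assignment" is skipped. Malformed lines are reported with their line
#' numbers.
#'
#' @param path Path to the peak-list text file.
#' @return Data frame with columns `assignment`, `w1`, `w2`,
#'   `intensity` (NA when no height column is present).
#' @export
read_sparky_peaklist <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (grepl("^Assignment", ln, ignore.case = TRUE)) next
    tok <- strsplit(ln, "[[:space:]]+")[[1L]]
    if (length(tok) < 3L || length(tok) > 4L) {
      stop(sprintf("%s: malformed line %d: '%s'", path, i, lines[i]),
           call. = FALSE)
    }
    w1 <- suppressWarnings(as.numeric(tok[2L]))
    w2 <- suppressWarnings(as.numeric(tok[3L]))
    h <- if (length(tok) == 4L) {
      suppressWarnings(as.numeric(tok[4L]))
    } else {
      NA_real_
    }
    if (is.na(w1) || is.na(w2) || (length(tok) == 4L && is.na(h))) {
      stop(sprintf("%s: malformed line %d: '%s'", path, i, lines[i]),
           call. = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(assignment = tok[1L],
                                            w1 = w1, w2 = w2,
                                            intensity = h)
  }
  if (length(rows) == 0L) {
    return(data.frame(assignment = character(), w1 = numeric(),
                      w2 = numeric(), intensity = numeric()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a single sequence from a FASTA file
#'
#' @param path Path to the FASTA file.
#' @return Named character scalar (uppercase amino-acid string).
#' @export
read_fasta_sequence <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE)
  if (length(seqs) == 0L) stop("no sequences in FASTA file", call. = FALSE)
  stats::setNames(toupper(as.character(seqs[[1L]])),
                  attr(seqs[[1L]], "name"))
}

#' Write a sequence to a FASTA file
#'
#' @param seq Amino-acid string or [build_repeat_sequence()] object.
#' @param path Output path.
#' @param name Sequence name for the FASTA header.
#' @return `path`, invisibly.
#' @export
write_fasta_sequence <- function(seq, path, name = "sequence") {
  seq <- .as_sequence_string(seq)
  seqinr::write.fasta(sequences = seq, names = name, file.out = path)
  invisible(path)
}
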