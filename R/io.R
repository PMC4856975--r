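#' Read an aligned FASTA file
#'
#' Parses a multi-record FASTA (wrapped or unwrapped) into an [msa()].
#' The label is the first whitespace-delimited token of the header; the
#' remainder is retained in `descriptions`. Symbols are upper-cased and
#' '.' is normalized to the gap symbol. Ragged records, symbols outside
#' the alphabet and duplicate labels are rejected with named errors.
#'
#' @param path FASTA file path.
#' @param alphabet A `bk_alphabet`; default DNA.
#' @return An `msa`.
#' @export
read_fasta <- function(path, alphabet = builtin_alphabets()$dna) {
  if (!file.exists(path)) bk_stop("io_error", "no such file: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e)
                    bk_stop("io_error", "cannot parse FASTA '%s': %s",
                            path, conditionMessage(e)))
  if (length(set) == 0L)
    bk_stop("io_error", "FASTA file '%s' contains no records", path)
  headers <- names(set)
  labels <- sub("\\s.*$", "", headers)
  desc <- sub("^\\S+\\s*", "", headers)
  msa(labels, as.character(set), alphabet, descriptions = desc)
}

#' Write an MSA to FASTA
#'
#' Round-trip guarantee: re-reading the file reproduces labels and rows
#' exactly. Lines are wrapped at 60 characters.
#'
#' @param x An `msa`.
#' @param path Output file path.
#' @export
write_fasta <- function(x, path) {
  if (!inherits(x, "msa")) bk_stop("io_error", "not an MSA")
  hdr <- x$labels
  if (!is.null(x$descriptions)) {
    has <- !is.na(x$descriptions) & x$descriptions != ""
    hdr[has] <- paste(x$labels[has], x$descriptions[has])
  }
  con <- tryCatch(file(path, "w"),
                  error = function(e) bk_stop("io_error",
                    "cannot open '%s' for writing", path))
  on.exit(close(con))
  for (i in seq_len(x$n_seq)) {
    writeLines(paste0(">", hdr[i]), con)
    s <- x$rows[i]
    starts <- seq(1L, nchar(s), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a Stockholm 1.0 alignment
#'
#' Sequence lines only; `#=GC`/`#=GR`/`#=GS` annotation lines are ignored.
#' Interleaved blocks are concatenated per label. Same contract as
#' [read_fasta()].
#'
#' @inheritParams read_fasta
#' @return An `msa`.
#' @export
read_stockholm <- function(path, alphabet = builtin_alphabets()$dna) {
  if (!file.exists(path)) bk_stop("io_error", "no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^# STOCKHOLM", lines[1]))
    bk_stop("io_error", "'%s' is not a Stockholm 1.0 file", path)
  seqs <- list()
  order <- character()
  for (ln in lines[-1]) {
    if (grepl("^\\s*$", ln) || startsWith(ln, "#") || startsWith(ln, "//"))
      next
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2L)
      bk_stop("io_error", "malformed Stockholm sequence line: '%s'", ln)
    lab <- parts[1]
    if (is.null(seqs[[lab]])) {
      seqs[[lab]] <- parts[2]
      order <- c(order, lab)
    } else {
      seqs[[lab]] <- paste0(seqs[[lab]], parts[2])
    }
  }
  if (!length(seqs))
    bk_stop("io_error", "Stockholm file '%s' contains no sequences", path)
  msa(order, unlist(seqs[order], use.names = FALSE), alphabet)
}
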