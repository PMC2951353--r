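#' Read a FASTA file into a named character vector
#'
#' Strict FASTA reader for the small amplicon / plasmid sequences this
#' package works with.  Headers start with `">"`; the record id is the
#' first whitespace-delimited token of the header.  Sequence lines may be
#' wrapped; whitespace inside sequence lines is stripped and bases are
#' upper-cased.  Only the alphabet `A`, `C`, `G`, `T`, `N` is accepted:
#' any other character (including other IUPAC ambiguity codes) is an
#' error, never a silent coercion, so that downstream mutation calls are
#' never made against characters the classifier cannot interpret.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of upper-case DNA sequences, in file
#'   order.  An empty file yields an empty vector.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(stats::setNames(character(0), character(0)))
  }
  is_header <- startsWith(lines, ">")
  if (!is_header[1L]) {
    stop("malformed FASTA: first non-blank line is not a '>' header in ",
         path, call. = FALSE)
  }
  rec_index <- cumsum(is_header)
  headers <- lines[is_header]
  ids <- vapply(headers, function(h) {
    tok <- strsplit(trimws(sub("^>", "", h)), "\\s+")[[1L]]
    if (length(tok) == 0L || !nzchar(tok[1L])) NA_character_ else tok[1L]
  }, character(1), USE.NAMES = FALSE)
  if (anyNA(ids)) {
    stop("malformed FASTA header (empty id) at record ",
         which(is.na(ids))[1L], " in ", path, call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  seqs <- vapply(seq_along(ids), function(i) {
    body <- lines[rec_index == i & !is_header]
    toupper(gsub("\\s+", "", paste(body, collapse = "")))
  }, character(1))
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[i])) {
      stop("empty FASTA record ", i, " (id '", ids[i], "') in ", path,
           call. = FALSE)
    }
    check_dna(seqs[i], what = paste0("record ", i, " (id '", ids[i], "')"))
  }
  stats::setNames(seqs, ids)
}

#' Write sequences to a FASTA file
#'
#' Inverse of [read_fasta()]: sequences are validated against the
#' `A/C/G/T/N` alphabet, upper-cased and written wrapped at `width`
#' columns, so `read_fasta(write_fasta(x))` is the identity on valid
#' records.
#'
#' @param seqs Named character vector of DNA sequences; names are ids.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), length(seqs) == 0L || !is.null(names(seqs)))
  if (anyDuplicated(names(seqs))) {
    stop("duplicate sequence ids", call. = FALSE)
  }
  out <- character(0)
  for (i in seq_along(seqs)) {
    s <- toupper(seqs[[i]])
    check_dna(s, what = paste0("sequence '", names(seqs)[i], "'"))
    body <- substring(s, seq(1L, nchar(s), by = width),
                      pmin(seq(1L, nchar(s), by = width) + width - 1L, nchar(s)))
    out <- c(out, paste0(">", names(seqs)[i]), body)
  }
  writeLines(out, path)
  invisible(path)
}

# Reject anything outside the A/C/G/T/N alphabet.
check_dna <- function(seq, what = "sequence") {
  bad <- gsub("[ACGTN]", "", seq)
  if (nzchar(bad)) {
    stop("invalid character(s) '", paste(unique(strsplit(bad, "")[[1L]]),
                                         collapse = "', '"),
         "' in ", what, " (only A/C/G/T/N are accepted)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Reverse-complement a DNA string
#'
#' @param seq A DNA string over `A/C/G/T/N`.
#' @return The reverse complement, upper case.
#' @export
revcomp <- function(seq) {
  check_dna(toupper(seq))
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(toupper(seq), "")[[1L]]),
                                 collapse = ""))
}
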