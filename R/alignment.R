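#' State alphabets
#'
#' DNA uses the four nucleotides; proteins the twenty standard amino acids
#' (one-letter codes, alphabetical).  Gaps (`-`), `?` and any ambiguity code
#' are collapsed to a single "missing / any state" code.
#'
#' @param alphabet `"dna"` or `"protein"`.
#' @return character vector of state letters.
#' @export
alphabet_states <- function(alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  switch(alphabet,
         dna = c("A", "C", "G", "T"),
         protein = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]])
}

new_alignment <- function(taxa, seqs, alphabet) {
  taxa <- as.character(taxa)
  seqs <- toupper(as.character(seqs))
  if (length(taxa) != length(seqs)) stop("taxa/sequence count mismatch")
  if (anyDuplicated(taxa)) stop("duplicate taxon labels")
  len <- unique(nchar(seqs))
  if (length(len) != 1L)
    stop("alignment format error: sequences have unequal lengths")
  structure(list(taxa = taxa, seqs = seqs, alphabet = alphabet,
                 n = length(taxa), length = len),
            class = "mp_alignment")
}

#' @export
print.mp_alignment <- function(x, ...) {
  cat(sprintf("%s alignment: %d taxa, %d sites\n",
              toupper(x$alphabet), x$n, x$length))
  invisible(x)
}

#' Read a multiple sequence alignment
#'
#' Supports FASTA and relaxed PHYLIP (sequential or interleaved; taxon names
#' are whitespace-delimited).  Characters are upper-cased; anything outside
#' the state alphabet (gaps, `?`, IUPAC ambiguity codes) becomes missing
#' data when the alignment is compressed into site patterns.
#'
#' @param path file path.
#' @param format `"fasta"` or `"phylip"`.
#' @param alphabet `"dna"` or `"protein"`.
#' @return an object of class `mp_alignment`.
#' @export
read_alignment <- function(path, format = c("fasta", "phylip"),
                           alphabet = c("dna", "protein")) {
  format <- match.arg(format)
  alphabet <- match.arg(alphabet)
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    taxa <- sub("\\s.*$", "", names(ss))
    new_alignment(taxa, as.character(ss), alphabet)
  } else {
    read_phylip(path, alphabet)
  }
}

# Relaxed PHYLIP: header "n L"; then either sequential records (name followed
# by sequence characters, possibly wrapped over lines) or interleaved blocks
# (first block carries names, later blocks append in taxon order).
read_phylip <- function(path, alphabet) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != ""]
  if (!length(lines)) stop("alignment format error: empty phylip file")
  hdr <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  if (length(hdr) < 2L || anyNA(suppressWarnings(as.integer(hdr[1:2]))))
    stop("alignment format error: bad phylip header")
  n <- as.integer(hdr[[1L]])
  L <- as.integer(hdr[[2L]])
  body <- lines[-1L]
  parse_seq_chunk <- function(x) gsub("\\s+", "", x)

  try_interleaved <- function() {
    if (length(body) %% n != 0L) return(NULL)
    taxa <- character(n)
    seqs <- character(n)
    nblock <- length(body) %/% n
    for (blk in seq_len(nblock)) {
      for (i in seq_len(n)) {
        ln <- body[[(blk - 1L) * n + i]]
        if (blk == 1L) {
          tok <- strsplit(trimws(ln), "\\s+")[[1L]]
          taxa[i] <- tok[[1L]]
          seqs[i] <- parse_seq_chunk(paste(tok[-1L], collapse = ""))
        } else {
          seqs[i] <- paste0(seqs[i], parse_seq_chunk(ln))
        }
      }
    }
    if (all(nchar(seqs) == L)) list(taxa = taxa, seqs = seqs) else NULL
  }

  try_sequential <- function() {
    tok <- strsplit(trimws(paste(body, collapse = " ")), "\\s+")[[1L]]
    taxa <- character(n)
    seqs <- character(n)
    pos <- 1L
    for (i in seq_len(n)) {
      if (pos > length(tok)) return(NULL)
      taxa[i] <- tok[[pos]]
      pos <- pos + 1L
      acc <- ""
      while (nchar(acc) < L) {
        if (pos > length(tok)) return(NULL)
        acc <- paste0(acc, tok[[pos]])
        pos <- pos + 1L
      }
      if (nchar(acc) != L) return(NULL)
      seqs[i] <- acc
    }
    if (pos != length(tok) + 1L) return(NULL)
    list(taxa = taxa, seqs = seqs)
  }

  res <- try_interleaved()
  if (is.null(res)) res <- try_sequential()
  if (is.null(res))
    stop("alignment format error: phylip body does not match header")
  new_alignment(res$taxa, res$seqs, alphabet)
}

#' Write an alignment as FASTA
#'
#' @param a an `mp_alignment`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(a, path) {
  writeLines(as.vector(rbind(paste0(">", a$taxa), a$seqs)), path)
  invisible(path)
}
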