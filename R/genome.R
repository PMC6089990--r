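#' Read a reference genome from FASTA
#'
#' Parses a (possibly line-wrapped) multi-record FASTA file into a `Genome`
#' object: a named character vector of uppercase chromosome sequences.
#' The sequence identifier is the first whitespace-delimited token of the
#' header line.
#'
#' @param path Path to a FASTA file.
#' @return A `Genome` object (named character vector, one element per
#'   chromosome, alphabet restricted to A/C/G/T/N).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chrI", "ACGT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  # BString (not DNAString) so we can report U / bad letters ourselves
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("FASTA parse error: no records in ", path)
  }
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) {
    stop("FASTA parse error: record ", which(!nzchar(ids))[1L],
         " has an empty header")
  }
  if (anyDuplicated(ids)) {
    stop("FASTA parse error: duplicate record id '",
         ids[duplicated(ids)][1L], "'")
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("FASTA parse error: empty sequence for record '",
         ids[empty][1L], "'")
  }
  if (any(grepl("U", seqs, fixed = TRUE))) {
    bad <- ids[grepl("U", seqs, fixed = TRUE)][1L]
    stop("RNA alphabet (U) not supported; offending record: '", bad, "'")
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("Non-ACGTN character in record '", ids[bad][1L], "'")
  }
  Genome(seqs)
}

#' Construct a Genome object
#'
#' @param sequences Named character vector of uppercase chromosome sequences.
#' @return A `Genome` object.
#' @export
Genome <- function(sequences) {
  stopifnot(is.character(sequences), length(sequences) > 0L)
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop("every chromosome needs a name")
  }
  if (anyDuplicated(names(sequences))) {
    stop("duplicate chromosome ids")
  }
  if (any(!nzchar(sequences))) stop("empty chromosome sequence")
  if (any(grepl("[^ACGTN]", sequences))) {
    stop("Genome alphabet restricted to A/C/G/T/N")
  }
  structure(sequences, class = "Genome")
}

#' @export
print.Genome <- function(x, ...) {
  cat("Genome with", length(x), "chromosome(s):\n")
  for (id in names(x)) {
    cat(sprintf("  %-12s %d bp\n", id, nchar(x[[id]])))
  }
  invisible(x)
}

#' Write a Genome to FASTA
#'
#' @param genome A `Genome` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  set <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

chrom_length <- function(genome, chrom) {
  if (!chrom %in% names(genome)) {
    stop("unknown chromosome '", chrom, "'")
  }
  nchar(genome[[chrom]])
}

genome_slice <- function(genome, chrom, start, end) {
  n <- chrom_length(genome, chrom)
  if (start < 1L || end > n || start > end) {
    stop("slice ", chrom, ":", start, "-", end,
         " outside chromosome bounds (1-", n, ")")
  }
  substr(genome[[chrom]], start, end)
}

#' Reverse-complement a nucleotide string
#'
#' @param x Character vector of A/C/G/T/N strings.
#' @return The reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    if (!nzchar(s)) return(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1L), USE.NAMES = FALSE)
}

comp_base <- function(x) {
  chartr("ACGTN", "TGCAN", x)
}

# standard nuclear genetic code, stop as "*"
.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc == "*"] # sanity use below
  gc
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Translate a coding sequence
#'
#' Translates with the standard nuclear genetic code. Translation never stops
#' early: internal stop codons are rendered `*` (and reported via a warning),
#' as is the terminal stop. Codons containing `N` translate to `X`.
#'
#' @param cds A `CodingSequence` object (see [extract_cds()]) or a nucleotide
#'   string whose length is divisible by 3.
#' @return Single amino-acid string, one character per codon.
#' @examples
#' translate_cds("ATGGCTTAA")
#' @export
translate_cds <- function(cds) {
  nt <- if (inherits(cds, "CodingSequence")) cds$nucleotides else cds
  stopifnot(is.character(nt), length(nt) == 1L)
  n <- nchar(nt)
  if (n %% 3L != 0L) {
    stop("CDS length ", n, " not divisible by 3")
  }
  codons <- substring(nt, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  k <- length(aa)
  if (k > 1L && any(aa[-k] == "*")) {
    warning("internal stop codon(s) at codon ",
            paste(which(aa[-k] == "*"), collapse = ","))
  }
  paste(aa, collapse = "")
}

translate_codon <- function(codon) {
  aa <- unname(Biostrings::GENETIC_CODE[codon])
  if (is.na(aa)) "X" else aa
}
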