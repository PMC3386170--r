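#' Reference genome container
#'
#' A minimal single-sequence reference: a name, a DNA string restricted to
#' the alphabet A/C/G/T/N, and its length.
#'
#' @param name sequence name.
#' @param sequence DNA string (character scalar).
#' @return An object of class `reference_genome`.
#' @export
reference_genome <- function(name, sequence) {
  stopifnot(is.character(name), length(name) == 1,
            is.character(sequence), length(sequence) == 1)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0) stop("reference sequence must be non-empty")
  if (grepl("[^ACGTN]", sequence)) stop("reference alphabet must be A/C/G/T/N")
  structure(list(name = name, sequence = sequence, length = nchar(sequence)),
            class = "reference_genome")
}

#' @export
print.reference_genome <- function(x, ...) {
  cat(sprintf("<reference_genome> %s: %s bp, GC %.3f\n",
              x$name, format(x$length, big.mark = ","), gc_content(x)))
  invisible(x)
}

#' GC fraction of a reference or DNA string
#'
#' @param x a `reference_genome` or a character DNA string.
#' @return GC fraction among non-N bases.
#' @export
gc_content <- function(x) {
  s <- if (inherits(x, "reference_genome")) x$sequence else x
  f <- Biostrings::alphabetFrequency(Biostrings::DNAString(s))
  acgt <- sum(f[c("A", "C", "G", "T")])
  if (acgt == 0) return(NA_real_)
  sum(f[c("G", "C")]) / acgt
}

#' Forge a random reference sequence
#'
#' Draws an i.i.d. base sequence with a target GC content. Deterministic for
#' a fixed seed; the realized GC of a 100 kb forge is within ~2% of the
#' request (binomial sampling error).
#'
#' @param length sequence length in bp (>= 10 kb).
#' @param gc target GC fraction, strictly inside (0, 1).
#' @param seed integer seed.
#' @param name sequence name.
#' @return A [reference_genome()].
#' @export
forge_reference <- function(length, gc = 0.42, seed = 1L, name = "chr7_toy") {
  stopifnot(length >= 10000)
  if (!is.numeric(gc) || gc <= 0 || gc >= 1) {
    stop("gc must lie strictly inside (0, 1)")
  }
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seq <- paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
  reference_genome(name, seq)
}

#' Reverse-complement of a DNA string
#'
#' @param x character DNA string.
#' @return Reverse-complemented character string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Extract reference sequence on a 0-based half-open interval
#'
#' @param ref a [reference_genome()].
#' @param start,end 0-based half-open interval.
#' @return Character substring.
#' @export
ref_subseq <- function(ref, start, end) {
  stopifnot(start >= 0, end <= ref$length, start < end)
  substr(ref$sequence, start + 1, end)
}

#' Read and write FASTA references
#'
#' Thin wrappers over Biostrings FASTA IO keeping the package's
#' `reference_genome` container.
#'
#' @param ref a [reference_genome()].
#' @param path file path.
#' @return `write_fasta` returns `path` invisibly; `read_fasta` returns a
#'   [reference_genome()] built from the first record.
#' @export
write_fasta <- function(ref, path) {
  x <- Biostrings::DNAStringSet(ref$sequence)
  names(x) <- ref$name
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  reference_genome(names(x)[1], as.character(x[[1]]))
}
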