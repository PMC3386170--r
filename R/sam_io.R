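#' Write mate-pair records as minimal SAM
#'
#' Emits the simulator's mate-pair records in the minimal SAM dialect the
#' package reads back: `@HD`/`@SQ` header, two alignment lines per pair
#' (QNAME FLAG RNAME POS MAPQ CIGAR RNEXT PNEXT TLEN SEQ QUAL), with truth
#' tags in optional fields (`XA:Z:` generating allele, `XJ:i:` spanned
#' junction index, `XI:i:` true fragment length). Coordinates are converted
#' to SAM's 1-based convention; unmapped reads carry flag 0x4 and POS 0.
#'
#' @param records `matepair_records` from [simulate_matepairs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, path) {
  rn <- attr(records, "ref_name")
  rl <- attr(records, "ref_length")
  model <- attr(records, "insert_model")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", rn, as.integer(rl)),
               sprintf("@CO\tinsert_model mu=%g sigma=%g read_len=%g orientation=%s",
                       model$mu, model$sigma, model$read_len,
                       model$expected_orientation)), con)
  line <- function(first, pos, end, strand, mapped, mpos, mstrand, mmapped,
                   seq, r) {
    flag <- 1L + if (first) 64L else 128L
    flag <- flag + ifelse(mapped, 0L, 4L) + ifelse(mmapped, 0L, 8L)
    flag <- flag + ifelse(mapped & strand == "-", 16L, 0L)
    flag <- flag + ifelse(mmapped & mstrand == "-", 32L, 0L)
    cigar <- ifelse(mapped, paste0(end - pos, "M"), "*")
    tlen <- ifelse(mapped & mmapped,
                   ifelse(pos <= mpos, r$span, -r$span), 0)
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t*\tXA:Z:%s\tXJ:i:%d\tXI:i:%d",
            r$pair_id, flag,
            ifelse(mapped, rn, "*"), ifelse(mapped, as.integer(pos) + 1L, 0L),
            ifelse(mapped, 60L, 0L), cigar,
            ifelse(mmapped, "=", "*"), ifelse(mmapped, as.integer(mpos) + 1L, 0L),
            as.integer(ifelse(is.na(tlen), 0, tlen)),
            seq, r$source_allele,
            ifelse(is.na(r$junction), -1L, r$junction), as.integer(r$insert))
  }
  writeLines(line(TRUE, records$pos1, records$end1, records$strand1,
                  records$mapped1, records$pos2, records$strand2,
                  records$mapped2, records$seq1, records), con)
  writeLines(line(FALSE, records$pos2, records$end2, records$strand2,
                  records$mapped2, records$pos1, records$strand1,
                  records$mapped1, records$seq2, records), con)
  invisible(path)
}

#' Read minimal SAM back into mate-pair records
#'
#' Inverse of [write_sam()]: reconstructs one record per pair, including the
#' truth tags and the insert model stored in the `@CO` header line.
#'
#' @param path SAM path written by [write_sam()].
#' @return A `matepair_records` data frame.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  aln <- lines[!startsWith(lines, "@")]
  sq <- strsplit(hdr[startsWith(hdr, "@SQ")][1], "\t")[[1]]
  rn <- sub("^SN:", "", sq[2])
  rl <- as.numeric(sub("^LN:", "", sq[3]))
  co <- hdr[startsWith(hdr, "@CO")][1]
  get <- function(key) as.numeric(sub(paste0(".*", key, "=([0-9.]+).*"), "\\1", co))
  model <- insert_size_model(mu = get("mu"), sigma = get("sigma"),
                             read_len = get("read_len"),
                             expected_orientation =
                               sub(".*orientation=(\\w+).*", "\\1", co))
  f <- strsplit(aln, "\t")
  qname <- vapply(f, `[[`, character(1), 1)
  flag <- as.integer(vapply(f, `[[`, character(1), 2))
  pos <- as.numeric(vapply(f, `[[`, character(1), 4)) - 1
  cigar <- vapply(f, `[[`, character(1), 6)
  seq <- vapply(f, `[[`, character(1), 10)
  tag <- function(prefix) vapply(f, function(x) {
    hit <- x[startsWith(x, prefix)]
    if (length(hit)) sub(prefix, "", hit[1]) else NA_character_
  }, character(1))
  mapped <- bitwAnd(flag, 4L) == 0L
  strand <- ifelse(bitwAnd(flag, 16L) != 0L, "-", "+")
  mlen <- rep(NA_real_, length(cigar))
  mlen[mapped] <- as.numeric(sub("M$", "", cigar[mapped]))
  first <- bitwAnd(flag, 64L) != 0L
  i1 <- which(first)[match(unique(qname), qname[first])]
  i2 <- which(!first)[match(unique(qname), qname[!first])]
  rec <- data.frame(
    pair_id = qname[i1],
    pos1 = ifelse(mapped[i1], pos[i1], NA_real_),
    end1 = ifelse(mapped[i1], pos[i1] + mlen[i1], NA_real_),
    strand1 = ifelse(mapped[i1], strand[i1], NA_character_),
    mapped1 = mapped[i1],
    pos2 = ifelse(mapped[i2], pos[i2], NA_real_),
    end2 = ifelse(mapped[i2], pos[i2] + mlen[i2], NA_real_),
    strand2 = ifelse(mapped[i2], strand[i2], NA_character_),
    mapped2 = mapped[i2],
    insert = as.numeric(tag("XI:i:")[i1]),
    source_allele = tag("XA:Z:")[i1],
    junction = as.integer(tag("XJ:i:")[i1]),
    seq1 = seq[i1], seq2 = seq[i2],
    stringsAsFactors = FALSE)
  rec$junction[rec$junction < 0] <- NA_integer_
  both <- rec$mapped1 & rec$mapped2
  rec$span <- ifelse(both,
                     pmax(rec$end1, rec$end2) - pmin(rec$pos1, rec$pos2),
                     NA_real_)
  attr(rec, "insert_model") <- model
  attr(rec, "ref_name") <- rn
  attr(rec, "ref_length") <- rl
  class(rec) <- c("matepair_records", class(rec))
  rec
}
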