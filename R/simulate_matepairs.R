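#' Mate-pair insert size model
#'
#' Describes a large-insert mate-pair library: Gaussian insert (outer
#' distance) with mean `mu` and sd `sigma`, fixed read length, and the
#' strand configuration expected for concordant pairs. SOLiD-style mate-pair
#' chemistry places both reads on the same strand (`"same_strand"`, the
#' default); `"opposite_strand"` emulates forward/reverse paired-end layout.
#'
#' @param mu mean insert size in bp.
#' @param sigma insert size standard deviation in bp (> 0).
#' @param read_len read length in bp.
#' @param expected_orientation `"same_strand"` or `"opposite_strand"`.
#' @return An object of class `insert_size_model`.
#' @export
insert_size_model <- function(mu = 3900, sigma = 390, read_len = 50,
                              expected_orientation = c("same_strand",
                                                       "opposite_strand")) {
  expected_orientation <- match.arg(expected_orientation)
  stopifnot(sigma > 0, mu > 2 * read_len)
  structure(list(mu = mu, sigma = sigma, read_len = read_len,
                 expected_orientation = expected_orientation),
            class = "insert_size_model")
}

#' @export
print.insert_size_model <- function(x, ...) {
  cat(sprintf("<insert_size_model> mu=%g sd=%g read_len=%g (%s)\n",
              x$mu, x$sigma, x$read_len, x$expected_orientation))
  invisible(x)
}

#' Pool specification for a sequenced sample of chromosomes
#'
#' @param ... named chromosome counts, e.g. `pool_spec(R1 = 4, R2 = 9, r = 3)`
#'   for the Le Mans pool of eight presumed-homozygous Rose-combed males.
#' @return Named numeric vector of class `pool_spec`.
#' @export
pool_spec <- function(...) {
  w <- c(...)
  if (is.null(names(w)) || any(names(w) == "") || any(w < 0) || sum(w) <= 0) {
    stop("pool_spec needs named non-negative counts with positive total")
  }
  structure(w, class = "pool_spec")
}

#' Simulate mate-pair sequencing of an allele pool
#'
#' Fragments are drawn per chromosome at equal per-base coverage (fragment
#' counts proportional to pool weight times allele length), placed uniformly
#' on the generating allele with Gaussian insert length, and each 50 bp end
#' is lifted independently to reference coordinates through the allele's
#' segment map. A read overlapping a junction by more than `clip_tol` bp
#' cannot be placed by a contiguous mapper and is flagged unmapped (its
#' mate's pair becomes one-end mapped); smaller overhangs are soft-clipped
#' onto the majority segment. Truth tags record the generating allele and,
#' where the fragment spans a rearrangement junction, which one.
#'
#' @param pool a [pool_spec()].
#' @param alleles named list of `rearrangement_allele` objects covering every
#'   pool entry.
#' @param model an [insert_size_model()].
#' @param coverage read-base coverage over the reference (the study emulated
#'   here used about 1x).
#' @param seed integer seed.
#' @param error_rate optional uniform substitution rate applied to read
#'   sequences (placement, not base calls, drives discordance calling).
#' @param clip_tol maximum junction overhang (bp) a read may have and still
#'   be soft-clipped onto its majority segment rather than dropped.
#' @return `data.frame` of class `matepair_records`, one row per pair:
#'   `pair_id`, `pos1`, `end1`, `strand1`, `mapped1` (same for mate 2;
#'   0-based half-open reference coordinates), `span` (outer distance when
#'   both ends map, else `NA`), `insert` (true fragment length on the
#'   allele), `source_allele`, `junction` (truth: allele junction index
#'   spanned by the fragment, `NA` if none), `seq1`, `seq2`.
#' @export
simulate_matepairs <- function(pool, alleles, model = insert_size_model(),
                               coverage = 1, seed = 1L, error_rate = 0,
                               clip_tol = 5L) {
  stopifnot(inherits(pool, "pool_spec"), coverage > 0)
  if (!all(names(pool) %in% names(alleles))) stop("pool names missing from alleles")
  set.seed(seed)
  use <- names(pool)[pool > 0]
  lens <- vapply(alleles[use], `[[`, numeric(1), "length")
  if (model$mu + 6 * model$sigma >= min(lens)) {
    stop("insert size too long for the shortest allele")
  }
  ref_len <- alleles[[use[1]]]$ref_length
  total_frags <- round(coverage * ref_len / (2 * model$read_len))
  frags <- round(total_frags * (pool[use] * lens) / sum(pool[use] * lens))
  rows <- list()
  for (al_name in use) {
    al <- alleles[[al_name]]
    n <- frags[[al_name]]
    if (n == 0) next
    ins <- round(stats::rnorm(n, model$mu, model$sigma))
    ins <- pmax(ins, 2 * model$read_len + 1)
    start <- floor(stats::runif(n, 0, al$length - ins))
    jx <- extract_junctions(al, flank = 20L)
    jpos <- jx$allele_position
    spanned <- rep(NA_integer_, n)
    if (length(jpos)) {
      for (j in seq_along(jpos)) {
        hit <- start < jpos[j] & start + ins > jpos[j]
        spanned[hit] <- j
      }
    }
    r1 <- place_read(al, start, model$read_len, clip_tol)
    r2 <- place_read(al, start + ins - model$read_len, model$read_len, clip_tol)
    rows[[al_name]] <- data.frame(
      pair_id = sprintf("%s_%06d", al_name, seq_len(n)),
      pos1 = r1$pos, end1 = r1$end, strand1 = r1$strand, mapped1 = r1$mapped,
      pos2 = r2$pos, end2 = r2$end, strand2 = r2$strand, mapped2 = r2$mapped,
      insert = ins, source_allele = al_name, junction = spanned,
      seq1 = read_seq(al, start, model$read_len, error_rate),
      seq2 = read_seq(al, start + ins - model$read_len, model$read_len,
                      error_rate),
      stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, rows)
  rownames(rec) <- NULL
  both <- rec$mapped1 & rec$mapped2
  rec$span <- ifelse(both,
                     pmax(rec$end1, rec$end2) - pmin(rec$pos1, rec$pos2),
                     NA_real_)
  rec <- rec[order(ifelse(rec$mapped1, rec$pos1, rec$pos2)), ]
  rownames(rec) <- NULL
  attr(rec, "insert_model") <- model
  attr(rec, "ref_name") <- alleles[[use[1]]]$ref_name
  attr(rec, "ref_length") <- ref_len
  class(rec) <- c("matepair_records", class(rec))
  rec
}

# Place one read of length rl starting at allele position `start` (vectorized).
# Reads overhanging a junction by more than clip_tol are unmapped; smaller
# overhangs are clipped onto the majority segment.
place_read <- function(allele, start, rl, clip_tol) {
  segs <- allele$segments
  idx1 <- findInterval(start, segs$allele_start)
  idx2 <- findInterval(start + rl - 1, segs$allele_start)
  n <- length(start)
  pos <- end <- rep(NA_real_, n)
  strand <- rep(NA_character_, n)
  mapped <- rep(FALSE, n)
  # overlap with each candidate segment; majority segment must hold >= rl - clip_tol
  o1 <- pmin(start + rl, segs$allele_end[idx1]) - start
  o2 <- (start + rl) - pmax(start, segs$allele_start[idx2])
  seg <- ifelse(o1 >= o2, idx1, idx2)
  keep <- pmax(o1, o2) >= rl - clip_tol
  # clipped allele interval inside the chosen segment
  lo <- pmax(start, segs$allele_start[seg])
  hi <- pmin(start + rl, segs$allele_end[seg])
  fwd <- segs$orientation[seg] == "forward"
  rpos <- ifelse(fwd, segs$start[seg] + (lo - segs$allele_start[seg]),
                 segs$end[seg] - (hi - segs$allele_start[seg]))
  rend <- rpos + (hi - lo)
  pos[keep] <- rpos[keep]
  end[keep] <- rend[keep]
  strand[keep] <- ifelse(fwd, "+", "-")[keep]
  mapped[keep] <- TRUE
  list(pos = pos, end = end, strand = strand, mapped = mapped)
}

read_seq <- function(allele, start, rl, error_rate) {
  s <- substring(allele$sequence, start + 1, start + rl)
  if (error_rate > 0) {
    s <- vapply(s, function(x) {
      b <- strsplit(x, "")[[1]]
      hit <- stats::runif(length(b)) < error_rate
      b[hit] <- sample(c("A", "C", "G", "T"), sum(hit), replace = TRUE)
      paste(b, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  s
}
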