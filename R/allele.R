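#' Segment table constructor
#'
#' Segments are 0-based half-open reference intervals with an orientation;
#' an allele is an ordered sequence of segments whose concatenation (with
#' reverse-orientation segments reverse-complemented) gives the allele
#' sequence.
#'
#' @param start,end numeric vectors, 0-based half-open reference intervals.
#' @param orientation character vector, `"forward"` or `"reverse"`.
#' @return A `data.frame` with columns `start`, `end`, `orientation`.
#' @export
segments <- function(start, end, orientation = "forward") {
  n <- max(length(start), length(end), length(orientation))
  df <- data.frame(start = as.numeric(rep_len(start, n)),
                   end = as.numeric(rep_len(end, n)),
                   orientation = rep_len(orientation, n),
                   stringsAsFactors = FALSE)
  if (!all(df$orientation %in% c("forward", "reverse"))) {
    stop("orientation must be 'forward' or 'reverse'")
  }
  if (any(df$start < 0) || any(df$start >= df$end)) {
    stop("segments must satisfy 0 <= start < end")
  }
  df
}

#' Total allele length implied by a segment table
#'
#' Pure segment algebra; usable at full printed coordinates without any
#' sequence in memory.
#'
#' @param segs segment table from [segments()].
#' @return Length in bp.
#' @export
allele_length <- function(segs) sum(segs$end - segs$start)

#' Build a rearranged allele from a reference and a segment table
#'
#' Concatenates reference substrings in order, reverse-complementing
#' reverse-orientation segments, and records the invertible per-segment map
#' between allele coordinates and reference coordinates.
#'
#' @param ref a [reference_genome()].
#' @param segs segment table from [segments()].
#' @param name allele name (e.g. `"r"`, `"R1"`, `"R2"`).
#' @param provenance optional free-text description of the generating event.
#' @return An object of class `rearrangement_allele` with fields `name`,
#'   `segments` (with added `allele_start`/`allele_end` columns), `sequence`,
#'   `length`, `ref_name`, `ref_length`, `provenance`.
#' @export
build_allele <- function(ref, segs, name, provenance = NULL) {
  stopifnot(inherits(ref, "reference_genome"))
  if (any(segs$end > ref$length)) stop("segment out of reference bounds")
  lens <- segs$end - segs$start
  segs$allele_end <- cumsum(lens)
  segs$allele_start <- segs$allele_end - lens
  pieces <- vapply(seq_len(nrow(segs)), function(i) {
    s <- ref_subseq(ref, segs$start[i], segs$end[i])
    if (segs$orientation[i] == "reverse") revcomp(s) else s
  }, character(1))
  structure(list(name = name,
                 segments = segs[, c("start", "end", "orientation",
                                     "allele_start", "allele_end")],
                 sequence = paste(pieces, collapse = ""),
                 length = sum(lens),
                 ref_name = ref$name, ref_length = ref$length,
                 provenance = provenance),
            class = "rearrangement_allele")
}

#' @export
print.rearrangement_allele <- function(x, ...) {
  cat(sprintf("<rearrangement_allele> %s: %s bp over %d segment(s) of %s\n",
              x$name, format(x$length, big.mark = ","), nrow(x$segments),
              x$ref_name))
  if (!is.null(x$provenance)) cat("  provenance:", x$provenance, "\n")
  segs <- x$segments
  for (i in seq_len(nrow(segs))) {
    cat(sprintf("  [%s] ref %s-%s %s -> allele %s-%s\n", i,
                format(segs$start[i], big.mark = ","),
                format(segs$end[i], big.mark = ","),
                segs$orientation[i],
                format(segs$allele_start[i], big.mark = ","),
                format(segs$allele_end[i], big.mark = ",")))
  }
  invisible(x)
}

#' Lift allele coordinates to reference coordinates
#'
#' For positions inside a forward segment the mapping is a shift; inside a
#' reverse segment it is mirrored and the orientation flips. Round trip
#' through [ref_to_allele()] is the identity within one segment.
#'
#' @param pos numeric vector of 0-based allele positions.
#' @param allele a `rearrangement_allele`.
#' @return `data.frame` with columns `ref` (0-based reference position) and
#'   `orientation`.
#' @export
liftover <- function(pos, allele) {
  segs <- allele$segments
  if (any(pos < 0 | pos >= allele$length)) stop("position outside allele")
  idx <- findInterval(pos, segs$allele_start)
  off <- pos - segs$allele_start[idx]
  fwd <- segs$orientation[idx] == "forward"
  ref <- ifelse(fwd, segs$start[idx] + off, segs$end[idx] - 1 - off)
  data.frame(ref = ref,
             orientation = ifelse(fwd, "forward", "reverse"),
             segment = idx)
}

#' Lift reference coordinates onto an allele
#'
#' A reference position may map to zero, one, or several allele positions
#' (duplicated segments map twice).
#'
#' @param pos scalar 0-based reference position.
#' @param allele a `rearrangement_allele`.
#' @return `data.frame` with one row per hit: `allele_pos`, `orientation`,
#'   `segment`.
#' @export
ref_to_allele <- function(pos, allele) {
  segs <- allele$segments
  hit <- which(segs$start <= pos & pos < segs$end)
  if (length(hit) == 0) {
    return(data.frame(allele_pos = numeric(0), orientation = character(0),
                      segment = integer(0)))
  }
  fwd <- segs$orientation[hit] == "forward"
  ap <- ifelse(fwd,
               segs$allele_start[hit] + (pos - segs$start[hit]),
               segs$allele_start[hit] + (segs$end[hit] - 1 - pos))
  data.frame(allele_pos = ap,
             orientation = ifelse(fwd, "forward", "reverse"),
             segment = hit)
}

contiguous_concordant <- function(left, right) {
  if (left$orientation != right$orientation) return(FALSE)
  if (left$orientation == "forward") left$end == right$start else left$start == right$end
}

#' Extract rearrangement junctions from an allele
#'
#' One junction is reported for every adjacent segment pair whose reference
#' sides are non-contiguous or orientation-discordant. A wild-type allele
#' yields none; the R1 inversion yields two (proximal and distal); the R2
#' duplication allele yields two sequence-detectable junctions whose four
#' reference cut positions recover all four printed R2 breakpoints (the
#' boundary where the duplicated 198 bp flank rejoins wild-type sequence is
#' reference-contiguous and therefore invisible at sequence level).
#'
#' @param allele a `rearrangement_allele`.
#' @param flank flank length k in bp for the extracted junction sequence
#'   (>= 20).
#' @return `data.frame` of class `junction_set`: `allele_position` (0-based
#'   cut on the allele), `ref_cut_left`/`ref_cut_right` (0-based half-open
#'   cut positions on the reference for each side), `orient_left`,
#'   `orient_right`, `left_flank`, `right_flank`.
#' @export
extract_junctions <- function(allele, flank = 500L) {
  stopifnot(flank >= 20)
  segs <- allele$segments
  out <- list()
  for (i in seq_len(nrow(segs) - 1)) {
    left <- segs[i, ]; right <- segs[i + 1, ]
    if (contiguous_concordant(left, right)) next
    pos <- left$allele_end
    k <- min(flank, pos, allele$length - pos)
    has_seq <- !is.null(allele$sequence)
    out[[length(out) + 1]] <- data.frame(
      allele_position = pos,
      ref_cut_left = if (left$orientation == "forward") left$end else left$start,
      ref_cut_right = if (right$orientation == "forward") right$start else right$end,
      orient_left = left$orientation,
      orient_right = right$orientation,
      left_flank = if (has_seq) substr(allele$sequence, pos - k + 1, pos)
                   else NA_character_,
      right_flank = if (has_seq) substr(allele$sequence, pos + 1, pos + k)
                    else NA_character_,
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(allele_position = numeric(0), ref_cut_left = numeric(0),
               ref_cut_right = numeric(0), orient_left = character(0),
               orient_right = character(0), left_flank = character(0),
               right_flank = character(0), stringsAsFactors = FALSE)
  class(res) <- c("junction_set", class(res))
  res
}

#' Reference context on both sides of a junction, oriented as on the allele
#'
#' For each side of a junction, returns the reference sequence spanning the
#' cut, read in the orientation in which the allele traverses that side, with
#' the cut at the middle of the string. These are the two parental sequences
#' whose agreement around the cut constitutes breakpoint microhomology; feed
#' them to [microhomology()] together with the junction sequence.
#'
#' @param junction one row of a [extract_junctions()] result.
#' @param ref the [reference_genome()] the allele was built from.
#' @param scan half-window in bp on each side of the cut.
#' @return list with `side_a`, `side_b` (character, length `2 * scan`, cut at
#'   the middle) and `junction` (same layout, taken from the allele flanks).
#' @export
junction_ref_sides <- function(junction, ref, scan = 50L) {
  stopifnot(nrow(junction) == 1)
  oriented <- function(cut, orientation) {
    s <- ref_subseq(ref, cut - scan, cut + scan)
    if (orientation == "reverse") revcomp(s) else s
  }
  jl <- junction$left_flank; jr <- junction$right_flank
  if (nchar(jl) < scan || nchar(jr) < scan) {
    stop("junction flanks shorter than scan window")
  }
  list(side_a = oriented(junction$ref_cut_left, junction$orient_left),
       side_b = oriented(junction$ref_cut_right, junction$orient_right),
       junction = paste0(substr(jl, nchar(jl) - scan + 1, nchar(jl)),
                         substr(jr, 1, scan)))
}

#' Derive a recombinant allele by unequal crossing over
#'
#' The recombinant is the prefix of `allele_a` up to `pos_a` joined to the
#' suffix of `allele_b` from `pos_b`, with the segment map composed
#' accordingly. Crossing over the wild-type allele and R1 at the positions
#' where the R2 event occurred reproduces the R2 structure exactly.
#'
#' @param allele_a,allele_b `rearrangement_allele` objects on one reference.
#' @param pos_a,pos_b 0-based cut positions on each allele.
#' @param ref the shared [reference_genome()].
#' @param name recombinant name.
#' @return A `rearrangement_allele`.
#' @export
unequal_crossover <- function(allele_a, allele_b, pos_a, pos_b, ref,
                              name = paste0(allele_a$name, "x", allele_b$name)) {
  if (pos_a < 0 || pos_a > allele_a$length) stop("pos_a outside allele_a")
  if (pos_b < 0 || pos_b > allele_b$length) stop("pos_b outside allele_b")
  segs <- rbind(slice_segments(allele_a, 0, pos_a),
                slice_segments(allele_b, pos_b, allele_b$length))
  build_allele(ref, segs, name,
               provenance = sprintf("unequal crossover %s[0,%s) x %s[%s,end)",
                                    allele_a$name, format(pos_a, big.mark = ","),
                                    allele_b$name, format(pos_b, big.mark = ",")))
}

# Segment table of an allele interval [from, to) in allele coordinates.
slice_segments <- function(allele, from, to) {
  segs <- allele$segments
  out <- list()
  for (i in seq_len(nrow(segs))) {
    lo <- max(from, segs$allele_start[i]); hi <- min(to, segs$allele_end[i])
    if (lo >= hi) next
    k1 <- lo - segs$allele_start[i]; k2 <- hi - segs$allele_start[i]
    if (segs$orientation[i] == "forward") {
      out[[length(out) + 1]] <- segments(segs$start[i] + k1, segs$start[i] + k2,
                                         "forward")
    } else {
      out[[length(out) + 1]] <- segments(segs$end[i] - k2, segs$end[i] - k1,
                                         "reverse")
    }
  }
  if (!length(out)) stop("empty allele slice")
  do.call(rbind, out)
}

#' Construct the Rose-comb allelic series on a reference
#'
#' Builds the wild-type allele `r`, the inversion allele `R1`
#' (`[0,a) + rev[a,b) + [b,L)`), and the duplication allele `R2`
#' (`[0,a) + rev[d,b) + [c,L)`: wild type with the distal-most 91 kb of the
#' inverted region reinserted in reverse at the proximal breakpoint, flanked
#' on both sides by the 198 bp fragment `[c,a)`).
#'
#' @param ref a [reference_genome()].
#' @param coords coordinate layout from [rosecomb_coords()].
#' @return Named list of `rearrangement_allele` objects `r`, `R1`, `R2`.
#' @export
rosecomb_alleles <- function(ref, coords = rosecomb_coords()) {
  stopifnot(ref$length >= coords$b)
  L <- ref$length
  r <- build_allele(ref, segments(0, L), "r", "wild-type chromosome 7")
  R1 <- build_allele(ref,
                     segments(c(0, coords$a, coords$b),
                              c(coords$a, coords$b, L),
                              c("forward", "reverse", "forward")),
                     "R1", "7.4 Mb inversion of the wild-type chromosome")
  R2 <- build_allele(ref,
                     segments(c(0, coords$d, coords$c),
                              c(coords$a, coords$b, L),
                              c("forward", "reverse", "forward")),
                     "R2",
                     "unequal crossover between wild-type and R1")
  list(r = r, R1 = R1, R2 = R2)
}

#' Export an allele's segment map as BED
#'
#' Writes one BED record per segment in reference coordinates, with the
#' segment orientation in the strand column.
#'
#' @param allele a `rearrangement_allele`.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
segments_to_bed <- function(allele, path) {
  segs <- allele$segments
  gr <- GenomicRanges::GRanges(
    seqnames = allele$ref_name,
    ranges = IRanges::IRanges(start = segs$start + 1, end = segs$end),
    strand = ifelse(segs$orientation == "forward", "+", "-"))
  gr$name <- sprintf("%s_seg%d", allele$name, seq_len(nrow(segs)))
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
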