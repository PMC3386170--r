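#' Score microhomology at a rearrangement junction
#'
#' Short sequence identity shared by the two joined parental sequences at a
#' junction makes the exact cut position ambiguous and implicates
#' microhomology-mediated repair. All three inputs are strings of equal even
#' length with the nominal cut at the middle: `ref_side_a` is the reference
#' context of the left-joined side read in its allele orientation,
#' `ref_side_b` the same for the right-joined side, and `junction_seq` the
#' observed allele sequence across the cut (see [junction_ref_sides()]).
#'
#' The junction bases left of the cut come from side A, so homology is
#' measured by how far side B's reference also carries them (extension `l`),
#' and symmetrically how far side A's reference carries the bases right of
#' the cut (extension `r`). The report maximizes the contiguous tract
#' `l + r` across the cut subject to at most `max_mismatch` mismatches.
#'
#' @param ref_side_a,ref_side_b,junction_seq equal-length strings, cut at the
#'   middle.
#' @param max_mismatch maximum mismatches tolerated inside the tract.
#' @param scan maximum extension scanned on each side of the cut.
#' @return list of class `microhomology_report`: `overlap_len`, `mismatches`
#'   (count used by the reported tract), `ambiguity_len` (tract length under
#'   zero mismatches; the breakpoint is unknowable within it), and `offsets`
#'   (`c(-l, r)` of the zero-mismatch tract relative to the nominal cut).
#' @export
microhomology <- function(ref_side_a, ref_side_b, junction_seq,
                          max_mismatch = 0L, scan = 50L) {
  n <- nchar(junction_seq)
  if (nchar(ref_side_a) != n || nchar(ref_side_b) != n || n %% 2 != 0) {
    stop("inputs must be equal-length strings of even length, cut at middle")
  }
  mid <- n / 2L
  if (mid < scan) stop("flanks shorter than requested scan window")
  jc <- strsplit(junction_seq, "")[[1]]
  sa <- strsplit(ref_side_a, "")[[1]]
  sb <- strsplit(ref_side_b, "")[[1]]
  # mismatch profile extending left of the cut (junction vs side B) and
  # right of the cut (junction vs side A)
  lmis <- cumsum(jc[mid - seq_len(scan) + 1] != sb[mid - seq_len(scan) + 1])
  rmis <- cumsum(jc[mid + seq_len(scan)] != sa[mid + seq_len(scan)])
  cl <- c(0, lmis); cr <- c(0, rmis)   # index i+1 = extension i
  best_len <- 0L; best_mis <- 0L
  for (l in 0:scan) {
    if (cl[l + 1] > max_mismatch) break
    budget <- max_mismatch - cl[l + 1]
    r <- max(c(0L, which(cr <= budget) - 1L))
    if (l + r > best_len || (l + r == best_len && cl[l + 1] + cr[r + 1] < best_mis)) {
      best_len <- l + r
      best_mis <- cl[l + 1] + cr[r + 1]
    }
  }
  l0 <- max(c(0L, which(cl == 0) - 1L))
  r0 <- max(c(0L, which(cr == 0) - 1L))
  structure(list(overlap_len = as.integer(best_len),
                 mismatches = as.integer(best_mis),
                 ambiguity_len = as.integer(l0 + r0),
                 offsets = c(-l0, r0)),
            class = "microhomology_report")
}

#' @export
print.microhomology_report <- function(x, ...) {
  cat(sprintf("<microhomology> overlap %d bp (%d mismatch%s); %d bp ambiguous cut interval\n",
              x$overlap_len, x$mismatches, if (x$mismatches == 1) "" else "es",
              x$ambiguity_len))
  invisible(x)
}

#' Microhomology reports for every junction of an allele
#'
#' Convenience wrapper: extracts junctions, builds the oriented reference
#' sides and junction sequence for each, and scores them.
#'
#' @param allele a `rearrangement_allele`.
#' @param ref the [reference_genome()] it was built from.
#' @param max_mismatch,scan passed to [microhomology()].
#' @return `data.frame` with one row per junction: cut coordinates plus
#'   `overlap_len`, `mismatches`, `ambiguity_len`.
#' @export
allele_microhomology <- function(allele, ref, max_mismatch = 1L, scan = 50L) {
  jx <- extract_junctions(allele, flank = max(500L, scan))
  if (nrow(jx) == 0) {
    return(cbind(jx[, c("allele_position", "ref_cut_left", "ref_cut_right")],
                 overlap_len = integer(0), mismatches = integer(0),
                 ambiguity_len = integer(0)))
  }
  rep <- lapply(seq_len(nrow(jx)), function(i) {
    sides <- junction_ref_sides(jx[i, ], ref, scan = scan)
    microhomology(sides$side_a, sides$side_b, sides$junction,
                  max_mismatch = max_mismatch, scan = scan)
  })
  data.frame(jx[, c("allele_position", "ref_cut_left", "ref_cut_right")],
             overlap_len = vapply(rep, `[[`, integer(1), "overlap_len"),
             mismatches = vapply(rep, `[[`, integer(1), "mismatches"),
             ambiguity_len = vapply(rep, `[[`, integer(1), "ambiguity_len"))
}
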