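#' Published breakpoint coordinates of the Rose-comb locus
#'
#' The galGal3 chromosome 7 coordinates that define the Rose-comb allelic
#' series. Coordinates are returned in the 1-based inclusive convention in
#' which they are conventionally printed; [to_zero_based()] converts them to
#' the package's internal 0-based half-open cut positions (numerically
#' identical for a cut placed *after* a printed base).
#'
#' @return A list with elements:
#'   \describe{
#'     \item{proximal}{R1/R2 proximal inversion breakpoint (16,499,781).}
#'     \item{distal}{R1 distal inversion breakpoint, left edge of the
#'       microhomology ambiguity interval (23,881,384).}
#'     \item{distal_hi}{right edge of the distal ambiguity interval
#'       (23,881,392).}
#'     \item{dup_flank}{left edge of the 198 bp duplicated flank
#'       (16,499,583).}
#'     \item{dup_start}{proximal edge of the 91 kb duplicated segment
#'       (23,790,414).}
#'     \item{sweep}{homozygosity sweep interval in R1R1 birds
#'       (16,424,096 - 23,854,241).}
#'     \item{gap_region}{assembly-artifact region (16,499,808 - 16,500,522,
#'       inclusive) containing a predicted 628 bp gap.}
#'     \item{gap_len}{predicted gap length inside \code{gap_region} (628).}
#'   }
#' @export
rosecomb_breakpoints <- function() {
  list(
    proximal  = 16499781,
    distal    = 23881384,
    distal_hi = 23881392,
    dup_flank = 16499583,
    dup_start = 23790414,
    sweep     = c(16424096, 23854241),
    gap_region = c(16499808, 16500522),
    gap_len   = 628
  )
}

#' Convert a printed 1-based breakpoint to a 0-based half-open cut position
#'
#' A breakpoint printed "at base p" (1-based, the last base belonging to the
#' left side) corresponds to the 0-based half-open cut position p: segments
#' `[., p)` and `[p, .)` meet there. The numeric value is unchanged; the
#' function exists so the convention is explicit at call sites.
#'
#' @param pos printed 1-based coordinate(s).
#' @return 0-based half-open cut position(s).
#' @export
to_zero_based <- function(pos) as.numeric(pos)

#' @rdname to_zero_based
#' @export
to_one_based <- function(pos) as.numeric(pos)

#' Breakpoint arithmetic of the Rose-comb allelic series
#'
#' Derives the headline size quantities from the printed breakpoint
#' coordinates under the half-open convention: the R1 inversion span, the R2
#' duplicated segment, the duplicated 198 bp flank, and the residual of the
#' assembly-artifact region after subtracting the predicted gap.
#'
#' @param bp breakpoint list, as returned by [rosecomb_breakpoints()].
#' @return A list with `inversion_bp`, `inversion_mb`, `duplication_bp`,
#'   `duplication_kb`, `flank_bp`, and `artifact_residual_bp`.
#' @export
breakpoint_arithmetic <- function(bp = rosecomb_breakpoints()) {
  inv  <- to_zero_based(bp$distal) - to_zero_based(bp$proximal)
  dup  <- to_zero_based(bp$distal) - to_zero_based(bp$dup_start)
  flk  <- to_zero_based(bp$proximal) - to_zero_based(bp$dup_flank)
  res  <- region_arithmetic(bp$gap_region, bp$gap_len)
  list(
    inversion_bp = inv,
    inversion_mb = inv / 1e6,
    duplication_bp = dup,
    duplication_kb = dup / 1e3,
    flank_bp = flk,
    artifact_residual_bp = res
  )
}

#' Coordinate layout for a Rose-comb reference, full scale or toy scale
#'
#' Maps the printed megabase-scale architecture onto a working reference.
#' At `scale_div = 1` the printed coordinates are used unchanged (the
#' reference must then span chromosome 7 past 23.9 Mb). At the default
#' `scale_div = 100` the architecture is compressed onto a ~300 kb toy
#' reference for fast simulation: the inversion scales 1/100 (73,816 bp).
#' Sub-insert-size features are deliberately not scaled to nothing: the
#' 198 bp duplicated flank keeps its natural size and the 91 kb duplicated
#' segment is floored at `dup_floor` (default 9,097 bp, a 1/10 scaling) so
#' that it stays larger than a mate-pair insert and junction-spanning
#' fragment geometry remains realistic.
#'
#' @param scale_div coordinate scale divisor (1 = printed coordinates).
#' @param ref_length reference length in bp at this scale.
#' @param proximal 0-based proximal cut position on the working reference
#'   (ignored at `scale_div = 1`, where the printed value is used).
#' @param dup_floor minimum duplicated-segment size at toy scale.
#' @return A list with 0-based half-open cut positions `a` (proximal), `b`
#'   (distal), `c` (flank start), `d` (duplication start), the distal
#'   ambiguity width `b_interval`, `ref_length`, and `scale_div`.
#' @export
rosecomb_coords <- function(scale_div = 100, ref_length = 300000L,
                            proximal = 110000L, dup_floor = 9097L) {
  stopifnot(scale_div >= 1, ref_length > 0)
  bp <- rosecomb_breakpoints()
  if (scale_div == 1) {
    a <- to_zero_based(bp$proximal)
    b <- to_zero_based(bp$distal)
    cc <- to_zero_based(bp$dup_flank)
    d <- to_zero_based(bp$dup_start)
    if (ref_length <= b) ref_length <- to_zero_based(bp$distal_hi) + 2e5
  } else {
    inv <- round((to_zero_based(bp$distal) - to_zero_based(bp$proximal)) / scale_div)
    dup <- max(round((to_zero_based(bp$distal) - to_zero_based(bp$dup_start)) / scale_div),
               dup_floor)
    a <- proximal
    b <- a + inv
    cc <- a - (to_zero_based(bp$proximal) - to_zero_based(bp$dup_flank))
    d <- b - dup
    if (b >= ref_length) stop("ref_length too small for the scaled architecture")
  }
  list(a = a, b = b, c = cc, d = d,
       b_interval = to_zero_based(bp$distal_hi) - to_zero_based(bp$distal),
       ref_length = as.numeric(ref_length), scale_div = scale_div)
}

#' Inclusive-region arithmetic
#'
#' Length of a 1-based inclusive region minus the sizes of known parts;
#' used e.g. to recover the 87 bp residual of the chr7:16,499,808-16,500,522
#' assembly-artifact region after subtracting its predicted 628 bp gap.
#'
#' @param region numeric length-2 vector, 1-based inclusive endpoints.
#' @param parts numeric vector of part sizes in bp.
#' @return Residual size in bp.
#' @export
region_arithmetic <- function(region, parts) {
  stopifnot(length(region) == 2, region[2] >= region[1], all(parts >= 0))
  len <- region[2] - region[1] + 1
  if (sum(parts) > len) stop("parts exceed region length")
  len - sum(parts)
}
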