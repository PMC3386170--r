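#' Estimate the insert size model from mapped pairs
#'
#' Takes pairs with both ends mapped in the expected orientation, trims the
#' span distribution to its 1%-99% quantiles, and returns the empirical mean
#' and standard deviation as an [insert_size_model()]. A zero-sd (degenerate)
#' distribution is flagged with a warning.
#'
#' @param records `matepair_records`.
#' @param expected_orientation concordant strand configuration; defaults to
#'   the model stored with the records.
#' @param min_pairs minimum usable pairs (default 1000).
#' @return An [insert_size_model()] with attribute `degenerate` if sd is 0.
#' @export
estimate_insert_model <- function(records, expected_orientation = NULL,
                                  min_pairs = 1000L) {
  stored <- attr(records, "insert_model")
  if (is.null(expected_orientation)) {
    expected_orientation <- if (!is.null(stored)) stored$expected_orientation
                            else "same_strand"
  }
  read_len <- if (!is.null(stored)) stored$read_len else
    stats::median(records$end1 - records$pos1, na.rm = TRUE)
  ok <- records$mapped1 & records$mapped2 &
    orientation_ok(records, expected_orientation)
  spans <- records$span[ok]
  if (length(spans) < min_pairs) stop("too few expected-orientation pairs")
  q <- stats::quantile(spans, c(0.01, 0.99))
  spans <- spans[spans >= q[1] & spans <= q[2]]
  s <- stats::sd(spans)
  if (s == 0) {
    warning("degenerate insert distribution: sd = 0")
    s <- .Machine$double.eps
    deg <- TRUE
  } else deg <- FALSE
  m <- insert_size_model(mu = mean(spans), sigma = s, read_len = read_len,
                         expected_orientation = expected_orientation)
  attr(m, "degenerate") <- deg
  m
}

orientation_ok <- function(records, expected) {
  same <- records$strand1 == records$strand2
  if (expected == "same_strand") same else !same
}

#' Classify each mate pair against the insert model
#'
#' A pair with an unmapped end is `one_end_unmapped`; a mapped pair whose
#' strands depart from the library's expected configuration is an
#' `orientation_anomaly` (inversion signature); otherwise a mapping distance
#' strictly exceeding `mu + sd_mult * sigma` (and, symmetrically, falling
#' strictly below `mu - sd_mult * sigma` when `symmetric = TRUE`) is a
#' `distance_anomaly` (deletion/duplication signature); everything else is
#' `concordant`. A span of exactly `mu + sd_mult * sigma` is concordant: the
#' rule is strict exceedance.
#'
#' @param records `matepair_records`.
#' @param model an [insert_size_model()].
#' @param sd_mult standard-deviation multiplier (default 10).
#' @param symmetric also flag short spans (default TRUE; the detection rule
#'   quoted for the emulated study names only the upper tail).
#' @return factor vector with levels `concordant`, `distance_anomaly`,
#'   `orientation_anomaly`, `one_end_unmapped`.
#' @export
classify_pairs <- function(records, model, sd_mult = 10, symmetric = TRUE) {
  out <- rep("concordant", nrow(records))
  both <- records$mapped1 & records$mapped2
  out[!both] <- "one_end_unmapped"
  bad_orient <- both & !orientation_ok(records, model$expected_orientation)
  out[bad_orient] <- "orientation_anomaly"
  hi <- model$mu + sd_mult * model$sigma
  lo <- model$mu - sd_mult * model$sigma
  far <- both & !bad_orient &
    (records$span > hi | (symmetric & records$span < lo))
  out[far] <- "distance_anomaly"
  factor(out, levels = c("concordant", "distance_anomaly",
                         "orientation_anomaly", "one_end_unmapped"))
}

#' Call structural variants from windowed mate-pair discordance
#'
#' Implements the windowed discordance rule: the reference is tiled in
#' non-overlapping windows (default 1.5 kb); each mapped end of a pair
#' contributes the pair to its window. A window is a candidate when at least
#' `min_frac` of its pairs are discordant (distance or orientation anomaly)
#' AND at least `min_frac` of its pairs have partner ends lying within
#' `cluster_radius` of each other (single-linkage chaining), with at least
#' `min_pairs` supporting pairs. Partner clusters are formed separately per
#' strand pattern so that the two reciprocal junctions of an inversion stay
#' distinct; candidate loci whose partner intervals are mutually reciprocal
#' are merged into one call, typed by majority strand pattern
#' (different-strand pairs: inversion; same-strand: deletion or duplication;
#' ties go to inversion). The call size is the distance between the two
#' partner-cluster midpoints.
#'
#' @param records `matepair_records` (any order; windowing sorts internally).
#' @param model an [insert_size_model()]; estimated from the records when
#'   `NULL`.
#' @param window window width in bp.
#' @param min_frac discordance and clustering fraction threshold.
#' @param cluster_radius single-linkage radius for partner clustering, bp.
#' @param min_pairs minimum discordant pairs supporting a candidate window.
#' @param sd_mult,symmetric passed to [classify_pairs()].
#' @return `data.frame` of class `sv_calls`: `type`, `a_lo`, `a_hi`, `b_lo`,
#'   `b_hi` (0-based breakpoint support intervals), `size`, `support`,
#'   `n_windows`.
#' @export
call_sv_windows <- function(records, model = NULL, window = 1500,
                            min_frac = 0.25, cluster_radius = 1000,
                            min_pairs = 4L, sd_mult = 10, symmetric = TRUE) {
  empty <- data.frame(type = character(0), a_lo = numeric(0), a_hi = numeric(0),
                      b_lo = numeric(0), b_hi = numeric(0), size = numeric(0),
                      support = integer(0), n_windows = integer(0))
  class(empty) <- c("sv_calls", class(empty))
  if (nrow(records) == 0) return(empty)
  if (is.null(model)) model <- estimate_insert_model(records)
  cls <- classify_pairs(records, model, sd_mult = sd_mult,
                        symmetric = symmetric)
  both <- records$mapped1 & records$mapped2
  disc <- both & cls %in% c("distance_anomaly", "orientation_anomaly")
  # long form: one row per mapped end (self position, partner position)
  ends <- rbind(
    data.frame(pair = seq_len(nrow(records)), self = records$pos1,
               partner = records$pos2, self_strand = records$strand1,
               partner_strand = records$strand2)[records$mapped1 & both, ],
    data.frame(pair = seq_len(nrow(records)), self = records$pos2,
               partner = records$pos1, self_strand = records$strand2,
               partner_strand = records$strand1)[records$mapped2 & both, ])
  ends$disc <- disc[ends$pair]
  ends$pattern <- ifelse(ends$self_strand == ends$partner_strand,
                         "same", "different")
  ends$win <- floor(ends$self / window)
  cand <- list()
  for (w in unique(ends$win)) {
    in_w <- ends[ends$win == w, ]
    n_all <- length(unique(in_w$pair))
    d <- in_w[in_w$disc, ]
    if (nrow(d) < min_pairs || nrow(d) / n_all < min_frac) next
    for (pat in unique(d$pattern)) {
      dp <- d[d$pattern == pat, ]
      if (nrow(dp) == 0) next
      cl <- single_linkage(dp$partner, cluster_radius)
      for (k in unique(cl)) {
        member <- dp[cl == k, ]
        if (nrow(member) < min_pairs || nrow(member) / n_all < min_frac) next
        cand[[length(cand) + 1]] <- data.frame(
          win = w, pattern = pat,
          self_lo = min(member$self), self_hi = max(member$self),
          partner_lo = min(member$partner), partner_hi = max(member$partner),
          support = nrow(member),
          pairs = I(list(sort(unique(member$pair)))))
      }
    }
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  # merge candidate windows whose (self, partner) loci overlap reciprocally
  merged <- merge_reciprocal(cand, cluster_radius)
  calls <- do.call(rbind, lapply(merged, function(g) {
    # a merged group carries both event loci (each member contributes its
    # self and its partner interval); re-cluster the boundary intervals to
    # recover them
    iv <- rbind(data.frame(lo = g$self_lo, hi = g$self_hi),
                data.frame(lo = g$partner_lo, hi = g$partner_hi))
    grp <- single_linkage((iv$lo + iv$hi) / 2, cluster_radius + window)
    loci <- do.call(rbind, lapply(split(iv, grp), function(x)
      data.frame(lo = min(x$lo), hi = max(x$hi))))
    loci$mid <- (loci$lo + loci$hi) / 2
    loci <- loci[order(loci$mid), ]
    a <- loci[1, ]
    b <- loci[nrow(loci), ]
    n_same <- sum(g$support[g$pattern == "same"])
    n_diff <- sum(g$support[g$pattern == "different"])
    type <- if (n_diff >= n_same) "inversion" else "deletion_or_duplication"
    data.frame(type = type, a_lo = a$lo, a_hi = a$hi, b_lo = b$lo, b_hi = b$hi,
               size = abs(b$mid - a$mid),
               support = length(unique(unlist(g$pairs))),
               n_windows = nrow(g))
  }))
  ord <- order(calls$a_lo)
  calls <- calls[ord, ]
  rownames(calls) <- NULL
  attr(calls, "pair_sets") <- lapply(merged, function(g)
    sort(unique(unlist(g$pairs))))[ord]
  attr(calls, "model") <- model
  class(calls) <- c("sv_calls", class(calls))
  calls
}

#' @export
print.sv_calls <- function(x, ...) {
  cat(sprintf("<sv_calls> %d call(s)\n", nrow(x)))
  if (nrow(x)) {
    print.data.frame(x, row.names = TRUE)
  }
  invisible(x)
}

# single-linkage clustering of 1-d positions with a chaining radius
single_linkage <- function(pos, radius) {
  o <- order(pos)
  gaps <- diff(pos[o])
  grp_sorted <- cumsum(c(1, as.integer(gaps > radius)))
  grp <- integer(length(pos))
  grp[o] <- grp_sorted
  grp
}

# group candidate windows: two candidates belong to one event when each one's
# partner locus overlaps (within radius) the other's self locus, or when they
# share the same (self, partner) loci; transitive closure via union-find
merge_reciprocal <- function(cand, radius) {
  n <- nrow(cand)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  near <- function(lo1, hi1, lo2, hi2) lo1 <= hi2 + radius & lo2 <= hi1 + radius
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (cand$pattern[i] != cand$pattern[j]) next
    same_locus <- near(cand$self_lo[i], cand$self_hi[i],
                       cand$self_lo[j], cand$self_hi[j]) &&
      near(cand$partner_lo[i], cand$partner_hi[i],
           cand$partner_lo[j], cand$partner_hi[j])
    recip <- near(cand$self_lo[i], cand$self_hi[i],
                  cand$partner_lo[j], cand$partner_hi[j]) &&
      near(cand$partner_lo[i], cand$partner_hi[i],
           cand$self_lo[j], cand$self_hi[j])
    if (same_locus || recip) parent[find(i)] <- find(j)
  }
  root <- vapply(seq_len(n), find, integer(1))
  lapply(split(seq_len(n), root), function(idx) cand[idx, , drop = FALSE])
}

#' Geometrically narrow the breakpoint intervals of a call
#'
#' Each side of a rearrangement junction is approached by its supporting
#' reads from one direction: from below (reads end just short of the
#' breakpoint) or from above (reads start just past it). The direction pair
#' is inferred from the fragment-length constraint — for the correct
#' directions the per-pair junction distances on the two sides must sum to
#' roughly `mu - 2 read_len` — and each side's interval is then the
#' intersection over supporting pairs of `[inner end, inner end +
#' (mu + 3 sigma - 2 read_len - gap)]` (mirrored for sides approached from
#' above), where `gap` is how far the pair's partner end sits back from the
#' partner-side support frontier. The result is never wider than the input
#' interval; an empty intersection falls back to the input and is flagged.
#'
#' @param call one row of an `sv_calls` result.
#' @param records the `matepair_records` the calls came from.
#' @param model an [insert_size_model()].
#' @param pairs integer indices of supporting pairs (taken from the call's
#'   `pair_sets` attribute when calling via [call_sv_windows()] results).
#' @return list with `a` and `b` intervals (`c(lo, hi)`), the inferred
#'   approach `directions`, and logical `fallback` per side.
#' @export
refine_breakpoints <- function(call, records, model, pairs) {
  if (length(pairs) < 3) stop("at least 3 supporting pairs required")
  rec <- records[pairs, ]
  a_is_1 <- rec$pos1 <= rec$pos2
  posA <- ifelse(a_is_1, rec$pos1, rec$pos2)
  endA <- ifelse(a_is_1, rec$end1, rec$end2)
  posB <- ifelse(a_is_1, rec$pos2, rec$pos1)
  endB <- ifelse(a_is_1, rec$end2, rec$end1)
  rl <- model$read_len
  slack <- model$mu + 3 * model$sigma - 2 * rl
  # Approach direction is determined by which fragment end a read is and its
  # strand: the fragment-leading read (first in pair) approaches its junction
  # side from below iff it maps '+'; the trailing read iff it maps '-' under
  # same-strand chemistry ('+' under opposite-strand chemistry). Majority
  # vote across the supporting pairs.
  trail_below <- if (model$expected_orientation == "same_strand") "-" else "+"
  dir_of <- function(is_first, strand) {
    ifelse(is_first, strand == "+", strand == trail_below)
  }
  sA <- ifelse(a_is_1, rec$strand1, rec$strand2)
  sB <- ifelse(a_is_1, rec$strand2, rec$strand1)
  belowA <- dir_of(a_is_1, sA)
  belowB <- dir_of(!a_is_1, sB)
  dirs <- list(a = if (mean(belowA) >= 0.5) "below" else "above",
               b = if (mean(belowB) >= 0.5) "below" else "above")
  dist_of <- function(pos, end, dir) {
    if (dir == "below") max(end) - end else pos - min(pos)
  }
  # the support frontier sits short of the true cut by roughly the local
  # read spacing; pad the slack bound accordingly
  margin <- 3 * (model$mu - 2 * rl) / length(pairs)
  refine_side <- function(pos, end, dir, gap, input_lo, input_hi) {
    if (dir == "below") {
      iv <- c(max(end), min(end + (slack - gap + margin)))
    } else {
      iv <- c(max(pos - (slack - gap + margin)), min(pos))
    }
    fallback <- iv[1] > iv[2]
    if (fallback) iv <- c(input_lo, input_hi)
    width_cap <- input_hi - input_lo
    if (diff(iv) > width_cap) {
      iv <- if (dir == "below") c(iv[1], iv[1] + width_cap)
            else c(iv[2] - width_cap, iv[2])
    }
    list(interval = iv, fallback = fallback)
  }
  gapA <- dist_of(posA, endA, dirs$a)
  gapB <- dist_of(posB, endB, dirs$b)
  a <- refine_side(posA, endA, dirs$a, gapB, call$a_lo, call$a_hi)
  b <- refine_side(posB, endB, dirs$b, gapA, call$b_lo, call$b_hi)
  list(a = a$interval, b = b$interval,
       directions = c(a = dirs$a, b = dirs$b),
       fallback = c(a = a$fallback, b = b$fallback))
}

#' Write SV calls as BEDPE-like TSV
#'
#' @param calls an `sv_calls` data frame.
#' @param path output path.
#' @param ref_name reference sequence name.
#' @return `path`, invisibly.
#' @export
write_sv_calls <- function(calls, path, ref_name = "ref") {
  df <- data.frame(chrom1 = ref_name, start1 = calls$a_lo, end1 = calls$a_hi,
                   chrom2 = ref_name, start2 = calls$b_lo, end2 = calls$b_hi,
                   name = sprintf("sv%02d_%s", seq_len(nrow(calls)), calls$type),
                   score = calls$support, strand1 = ".", strand2 = ".",
                   type = calls$type, size = calls$size)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
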