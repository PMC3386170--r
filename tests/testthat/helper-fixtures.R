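# Shared fixtures (built once per test run) and independent oracles.

toy_coords <- rosecomb_coords()
toy_ref <- forge_reference(toy_coords$ref_length, gc = 0.42, seed = 101)
toy_alleles <- rosecomb_alleles(toy_ref, toy_coords)

# random DNA string helper
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# Brute-force microhomology oracle: exhaustive O(k^2) enumeration of
# left/right extensions with explicit per-base comparison.
mh_brute <- function(side_a, side_b, junction, max_mismatch, scan = 50L) {
  mid <- nchar(junction) / 2
  jc <- strsplit(junction, "")[[1]]
  sa <- strsplit(side_a, "")[[1]]
  sb <- strsplit(side_b, "")[[1]]
  best <- c(len = 0L, mis = 0L)
  for (l in 0:scan) {
    ml <- if (l > 0) sum(jc[(mid - l + 1):mid] != sb[(mid - l + 1):mid]) else 0L
    if (ml > max_mismatch) next
    for (r in 0:scan) {
      mr <- if (r > 0) sum(jc[(mid + 1):(mid + r)] != sa[(mid + 1):(mid + r)]) else 0L
      if (ml + mr > max_mismatch) next
      if (l + r > best["len"] ||
          (l + r == best["len"] && ml + mr < best["mis"])) {
        best <- c(len = l + r, mis = ml + mr)
      }
    }
  }
  best
}

# Grid/optimize maximum-likelihood oracle for the two-point backcross LOD:
# maximize log10 binomial likelihood ratio over theta in [0, 0.5].
lod_grid_oracle <- function(r, n) {
  ll <- function(th) {
    l <- r * log10(th) + (n - r) * log10(1 - th) + n * log10(2)
    if (r == 0) l <- (n - r) * log10(1 - th) + n * log10(2)
    l
  }
  cand <- ll(c(1e-12, 0.5 - 1e-12))
  if (r > 0 && r < n) {
    opt <- stats::optimize(ll, c(1e-12, 0.5), maximum = TRUE, tol = 1e-12)
    cand <- c(cand, opt$objective)
  }
  if (r == 0) cand <- c(cand, n * log10(2))
  max(max(cand), 0)
}

# construct a junction triple (side_a, side_b, junction) with a planted
# homology tract of `l` bases left of the cut and `r` right of it, with
# `mm_left`/`mm_right` mismatches inside the tract, and guaranteed mismatch
# just beyond the tract on both sides
plant_homology <- function(l, r, mm_left = 0L, mm_right = 0L, scan = 50L,
                           seed = 1L) {
  set.seed(seed)
  n <- 2L * scan
  mid <- scan
  other <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  sa <- strsplit(rand_dna(n), "")[[1]]
  sb <- strsplit(rand_dna(n), "")[[1]]
  jc <- sa  # junction left half comes from side A
  # right half of the junction comes from side B
  jc[(mid + 1):n] <- sb[(mid + 1):n]
  # plant left tract: side B agrees with the junction's left bases
  if (l > 0) {
    idx <- (mid - l + 1):mid
    sb[idx] <- jc[idx]
    if (mm_left > 0) {
      flip <- sample(idx[-length(idx)], mm_left)  # keep tract edge matching
      sb[flip] <- vapply(jc[flip], other, character(1))
    }
  }
  # plant right tract: side A agrees with the junction's right bases
  if (r > 0) {
    idx <- (mid + 1):(mid + r)
    sa[idx] <- jc[idx]
    if (mm_right > 0) {
      flip <- sample(idx[-1], mm_right)
      sa[flip] <- vapply(jc[flip], other, character(1))
    }
  }
  # hard mismatches just beyond the tract
  if (l < scan) sb[mid - l] <- other(jc[mid - l])
  if (r < scan) sa[mid + r + 1] <- other(jc[mid + r + 1])
  list(side_a = paste(sa, collapse = ""), side_b = paste(sb, collapse = ""),
       junction = paste(jc, collapse = ""))
}
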