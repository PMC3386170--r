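test_that("insert model estimation recovers simulated parameters", {
  set.seed(3)
  n <- 10000
  spans <- stats::rnorm(n, 3900, 300)
  rec <- data.frame(pos1 = 1e5, end1 = 1e5 + 50, strand1 = "+", mapped1 = TRUE,
                    pos2 = 1e5 + spans - 50, end2 = 1e5 + spans, strand2 = "+",
                    mapped2 = TRUE, span = spans)
  m <- estimate_insert_model(rec, expected_orientation = "same_strand")
  expect_gte(m$mu, 3850); expect_lte(m$mu, 3950)
  expect_gte(m$sigma, 270); expect_lte(m$sigma, 330)
  # round trip through the simulator within 2%
  sim <- simulate_matepairs(pool_spec(r = 2), toy_alleles, coverage = 1,
                            seed = 4)
  m2 <- estimate_insert_model(sim)
  expect_lt(abs(m2$mu - 3900) / 3900, 0.02)
  # degenerate distribution flagged
  rec$span <- 3900
  expect_warning(m3 <- estimate_insert_model(rec,
                                             expected_orientation = "same_strand"),
                 "degenerate")
  expect_true(attr(m3, "degenerate"))
  expect_error(estimate_insert_model(rec[1:10, ],
                                     expected_orientation = "same_strand"),
               "too few")
})

test_that("pair classification uses strict exceedance and orientation first", {
  m <- insert_size_model(mu = 3900, sigma = 300)
  mk <- function(span, s1 = "+", s2 = "+", mapped2 = TRUE) {
    data.frame(pos1 = 0, end1 = 50, strand1 = s1, mapped1 = TRUE,
               pos2 = span - 50, end2 = span, strand2 = s2, mapped2 = mapped2,
               span = ifelse(mapped2, span, NA))
  }
  cls <- function(r) as.character(classify_pairs(r, m))
  expect_equal(cls(mk(3900)), "concordant")
  expect_equal(cls(mk(3900 + 10 * 300)), "concordant")      # boundary: not exceeding
  expect_equal(cls(mk(3900 + 10 * 300 + 1)), "distance_anomaly")
  expect_equal(cls(mk(3900, s2 = "-")), "orientation_anomaly")
  expect_equal(cls(mk(3900, mapped2 = FALSE)), "one_end_unmapped")
  # orientation anomaly takes precedence over distance
  expect_equal(cls(mk(90000, s2 = "-")), "orientation_anomaly")
  # short spans flagged symmetrically, but not when disabled
  expect_equal(cls(mk(300)), "distance_anomaly")
  expect_equal(as.character(classify_pairs(mk(300), m, symmetric = FALSE)),
               "concordant")
})

test_that("window candidacy follows the 25% discordance rule", {
  m <- insert_size_model(mu = 3900, sigma = 300)
  # one 1.5 kb tile of n_tot pairs, n_disc of them discordant with partners
  # at a far locus that also carries its own concordant background coverage
  mk_tile <- function(n_disc, n_tot, partner_spread = 100) {
    far <- 60000
    pos1 <- seq(100, 1400, length.out = n_tot)
    disc <- seq_len(n_tot) <= n_disc
    fg <- data.frame(pos1 = pos1, end1 = pos1 + 50,
                     strand1 = "+", mapped1 = TRUE,
                     pos2 = ifelse(disc, far + seq_len(n_tot) * partner_spread / n_tot,
                                   pos1 + 3800),
                     end2 = ifelse(disc, far + seq_len(n_tot) * partner_spread / n_tot + 50,
                                   pos1 + 3850),
                     strand2 = ifelse(disc, "-", "+"), mapped2 = TRUE)
    bgpos <- seq(far + 60, far + 1400, length.out = 12)
    bg <- data.frame(pos1 = bgpos, end1 = bgpos + 50, strand1 = "+",
                     mapped1 = TRUE, pos2 = bgpos + 3800, end2 = bgpos + 3850,
                     strand2 = "+", mapped2 = TRUE)
    r <- rbind(fg, bg)
    r$span <- pmax(r$end1, r$end2) - pmin(r$pos1, r$pos2)
    r
  }
  # 2 of 10 discordant: below the 25% threshold
  expect_equal(nrow(call_sv_windows(mk_tile(2, 10), m, min_pairs = 2)), 0)
  # 3 of 10 discordant with clustered partners: candidate ("at least 25%")
  expect_gt(nrow(call_sv_windows(mk_tile(3, 10), m, min_pairs = 2)), 0)
  # 3 of 10 discordant but partners more than 1 kb apart: chains broken
  scattered <- mk_tile(3, 10, partner_spread = 30000)
  expect_equal(nrow(call_sv_windows(scattered, m, min_pairs = 2,
                                    cluster_radius = 1000)), 0)
  # empty input gives an empty call set
  expect_equal(nrow(call_sv_windows(mk_tile(3, 10)[0, ], m)), 0)
})

test_that("a homozygous R1 pool yields two reciprocal inversion loci at truth size", {
  cc <- toy_coords
  rec <- simulate_matepairs(pool_spec(R1 = 2), toy_alleles, coverage = 1,
                            seed = 51)
  m <- estimate_insert_model(rec)
  calls <- call_sv_windows(rec, m)
  expect_equal(nrow(calls), 2)
  expect_true(all(calls$type == "inversion"))
  truth <- cc$b - cc$a
  expect_true(all(abs(calls$size - truth) <= 1500))
  # the two calls flank the true cuts reciprocally
  expect_true(calls$a_lo[1] < cc$a && cc$a <= calls$a_hi[1] + 1500)
  expect_true(calls$a_lo[2] >= cc$a - 1500)
})

test_that("no calls arise from wild-type pools across 20 seeds", {
  for (seed in 1:20) {
    rec <- simulate_matepairs(pool_spec(r = 2), toy_alleles, coverage = 1,
                              seed = 100 + seed)
    calls <- call_sv_windows(rec, estimate_insert_model(rec))
    expect_equal(nrow(calls), 0, info = sprintf("seed %d", seed))
  }
})

test_that("breakpoint refinement brackets the truth and narrows the call", {
  cc <- toy_coords
  contained <- 0L; total <- 0L
  for (seed in c(61, 62, 63)) {
    rec <- simulate_matepairs(pool_spec(R1 = 2), toy_alleles, coverage = 1,
                              seed = seed)
    m <- estimate_insert_model(rec)
    calls <- call_sv_windows(rec, m)
    sets <- attr(calls, "pair_sets")
    for (i in seq_len(nrow(calls))) {
      rb <- refine_breakpoints(calls[i, ], rec, m, sets[[i]])
      total <- total + 1L
      contained <- contained +
        (rb$a[1] <= cc$a && cc$a <= rb$a[2] &&
           rb$b[1] <= cc$b && cc$b <= rb$b[2])
      # never wider than mu + 3 sigma and never wider than the input locus
      expect_lte(diff(rb$a), m$mu + 3 * m$sigma)
      expect_lte(diff(rb$a), calls$a_hi[i] - calls$a_lo[i])
      expect_lte(diff(rb$b), calls$b_hi[i] - calls$b_lo[i])
    }
  }
  expect_equal(contained, total)
  # fewer than 3 supporting pairs is a precondition violation
  rec <- simulate_matepairs(pool_spec(R1 = 2), toy_alleles, coverage = 1,
                            seed = 61)
  m <- estimate_insert_model(rec)
  calls <- call_sv_windows(rec, m)
  expect_error(refine_breakpoints(calls[1, ], rec, m,
                                  attr(calls, "pair_sets")[[1]][1]),
               "3 supporting")
})

test_that("calls export as BEDPE-like TSV", {
  rec <- simulate_matepairs(pool_spec(R1 = 2), toy_alleles, coverage = 1,
                            seed = 51)
  calls <- call_sv_windows(rec, estimate_insert_model(rec))
  path <- tempfile(fileext = ".tsv")
  write_sv_calls(calls, path, "chr7_toy")
  back <- utils::read.delim(path)
  expect_equal(nrow(back), nrow(calls))
  expect_equal(back$start1, calls$a_lo)
  expect_equal(back$type, calls$type)
})
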