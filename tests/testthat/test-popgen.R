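test_that("heterozygosity follows 1 - sum(p^2)", {
  expect_equal(het_index(c(0.5, 0.5)), 0.5)
  expect_equal(het_index(rep(1 / 3, 3)), 2 / 3)
  expect_error(het_index(c(0.5, 0.6)), "simplex")
})

test_that("het_scan equals a brute-force per-locus recomputation", {
  set.seed(19)
  for (i in 1:5) {
    n <- 30; m <- 40
    g <- matrix(stats::rbinom(n * m, 2, stats::runif(m, 0.1, 0.9)[rep(1:m, each = n)]),
                nrow = n)
    pos <- sort(sample(1e6, m))
    prof <- het_scan(g, positions = pos, group = rep("all", n), window = 1e5)
    # oracle: explicit loops
    pl <- numeric(m)
    for (j in 1:m) {
      p <- mean(g[, j]) / 2
      pl[j] <- 1 - p^2 - (1 - p)^2
    }
    expect_equal(unname(prof$per_locus[, "all"]), pl)
    for (k in seq_len(nrow(prof$windows))) {
      in_w <- pos >= prof$windows$start[k] & pos < prof$windows$end[k]
      expect_equal(prof$windows$all[k], mean(pl[in_w]))
    }
  }
})

test_that("the homozygous sweep is recovered exactly at window resolution", {
  panel <- simulate_snp_panel(n_cases = 40, n_controls = 100, seed = 5)
  prof <- het_scan(panel)
  expect_equal(nrow(prof$runs), 1)
  # expected run: all windows lying entirely inside the sweep interval
  w <- prof$windows
  inside <- w$start >= panel$sweep[1] & w$end <= panel$sweep[2]
  expect_equal(prof$runs$start, min(w$start[inside]))
  expect_equal(prof$runs$end, max(w$end[inside]))
  expect_equal(prof$runs$n_windows, sum(inside))
})

test_that("fully linked backcross markers give LOD n*log10(2)", {
  res <- lod_from_counts(0, 378)
  expect_equal(round(res$lod, 1), 113.8)
  expect_equal(res$lod, 378 * log10(2))
  expect_equal(res$theta, 0)
  expect_equal(lod_from_counts(50, 100)$lod, 0)
  expect_equal(lod_from_counts(0, 0)$status, "no_data")
})

test_that("LOD matches grid-maximized binomial likelihood to 1e-6", {
  set.seed(23)
  for (i in 1:100) {
    n <- sample(50:400, 1)
    r <- sample(0:floor(n / 2), 1)
    expect_lt(abs(lod_from_counts(r, n)$lod - lod_grid_oracle(r, n)), 1e-6)
  }
  # monotone decreasing in r at fixed n below 0.5
  lods <- vapply(0:49, function(r) lod_from_counts(r, 100)$lod, numeric(1))
  expect_true(all(diff(lods) < 0))
})

test_that("pedigree linkage shows full linkage inside the suppressed region", {
  ped <- simulate_pedigree(seed = 9)
  lt <- two_point_lod(ped)
  inside <- lt$position >= 16077352 & lt$position <= 23443405
  expect_true(all(lt$theta[inside] == 0))
  expect_true(all(lt$lod[inside] > 100))
  expect_true(all(lt$lod[!inside] < lt$lod[inside][1]))
})

test_that("neutral parameters leave allele frequencies at Hardy-Weinberg", {
  eq <- rose_comb_equilibrium(rr_sire_fertility = 1, cull_rr = FALSE, q0 = 0.3)
  expect_equal(eq$q_star, 0.3, tolerance = 1e-9)
  expect_equal(eq$rr_fraction, 0.09, tolerance = 1e-9)
})

test_that("the default breeding recursion hits its closed-form fixed point", {
  eq <- rose_comb_equilibrium()
  q_closed <- (sqrt(17) - 1) / 8
  expect_equal(eq$q_star, q_closed, tolerance = 1e-8)
  expect_equal(eq$rr_fraction, q_closed / (2 * (1 + q_closed)),
               tolerance = 1e-8)
  expect_equal(eq$sire_gamete_q, 0.5)
  expect_true(eq$converged)
  # the genotype-resolved recursion has its own closed form
  eqg <- rose_comb_equilibrium(hardy_weinberg_offspring = FALSE)
  expect_equal(eqg$rr_fraction, (1 - sqrt(2) / 2) / 2, tolerance = 1e-8)
})

test_that("the equilibrium is a global attractor over starting frequencies", {
  q_closed <- (sqrt(17) - 1) / 8
  for (q0 in seq(0.02, 0.98, length.out = 50)) {
    eq <- rose_comb_equilibrium(q0 = q0)
    expect_equal(eq$q_star, q_closed, tolerance = 1e-7)
  }
})

test_that("the Monte-Carlo flock agrees with its deterministic fixed point", {
  eqg <- rose_comb_equilibrium(hardy_weinberg_offspring = FALSE)
  fl <- simulate_flock(n = 10000, generations = 200, seed = 17)
  last <- utils::tail(fl$rr_frac, 50)
  se <- stats::sd(last) / sqrt(length(last))
  expect_lt(abs(mean(last) - eqg$rr_fraction), 3 * se + 1e-4)
})
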