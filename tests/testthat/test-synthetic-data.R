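test_that("forged references are deterministic with controlled GC", {
  a <- forge_reference(1e5, 0.42, seed = 1)
  b <- forge_reference(1e5, 0.42, seed = 1)
  expect_identical(a$sequence, b$sequence)
  expect_error(forge_reference(1e5, 1.0), "strictly inside")
  expect_error(forge_reference(1e5, 0), "strictly inside")
  g <- forge_reference(1e6, 0.5, seed = 2)
  expect_gte(gc_content(g), 0.48)
  expect_lte(gc_content(g), 0.52)
})

test_that("wild-type pools are almost entirely concordant", {
  rec <- simulate_matepairs(pool_spec(r = 2), toy_alleles, coverage = 1,
                            seed = 21)
  model <- attr(rec, "insert_model")
  cls <- classify_pairs(rec, model)
  expect_gte(mean(cls == "concordant"), 0.99)
})

test_that("insert spans on the generating allele are normal (KS, 9/10 seeds)", {
  model <- insert_size_model()
  pass <- 0L
  for (seed in 1:10) {
    rec <- simulate_matepairs(pool_spec(r = 1), toy_alleles, model,
                              coverage = 10000 * 2 * 50 / toy_ref$length,
                              seed = seed)
    ins <- rec$insert
    p <- suppressWarnings(stats::ks.test(ins, "pnorm", model$mu,
                                         model$sigma))$p.value
    pass <- pass + (p > 0.01)
  }
  expect_gte(pass, 9)
})

test_that("junction-spanning fragments follow pool weights (13:4)", {
  # Le Mans pool: the proximal junction is carried by 13 of 16 chromosomes,
  # the R1-distal junction by 4; per-chromosome spanning rates are equal
  rec <- simulate_matepairs(pool_spec(R1 = 4, R2 = 9, r = 3), toy_alleles,
                            coverage = 40, seed = 31)
  n_prox <- sum(rec$junction == 1, na.rm = TRUE)
  n_dist <- sum(rec$junction == 2 & rec$source_allele == "R1", na.rm = TRUE)
  expect_gt(n_dist, 100)
  expect_lt(abs(n_prox / n_dist - 13 / 4), 0.1 * 13 / 4)
})

test_that("mate-pair simulation is seed-deterministic down to the SAM bytes", {
  rec1 <- simulate_matepairs(pool_spec(R1 = 1, r = 1), toy_alleles,
                             coverage = 0.3, seed = 5)
  rec2 <- simulate_matepairs(pool_spec(R1 = 1, r = 1), toy_alleles,
                             coverage = 0.3, seed = 5)
  f1 <- tempfile(); f2 <- tempfile()
  write_sam(rec1, f1); write_sam(rec2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("junction-overlapping reads are dropped as unmapped", {
  rec <- simulate_matepairs(pool_spec(R1 = 2), toy_alleles, coverage = 1,
                            seed = 8)
  one_end <- !(rec$mapped1 & rec$mapped2)
  # unmapped ends occur and only in junction-spanning fragments
  expect_gt(sum(one_end), 0)
  expect_true(all(!is.na(rec$junction[one_end])))
  # mapped reads never extend into the other segment beyond clip tolerance:
  # a mapped a-side read never crosses the proximal cut
  cc <- toy_coords
  crosses <- rec$mapped1 & rec$pos1 < cc$a & rec$end1 > cc$a
  expect_false(any(crosses))
})

test_that("insert longer than an allele is rejected", {
  small <- reference_genome("mini", rand_dna(10000))
  al <- list(mini = build_allele(small, segments(0, 10000), "mini"))
  expect_error(simulate_matepairs(pool_spec(mini = 1), al,
                                  insert_size_model(mu = 9000, sigma = 500),
                                  coverage = 1, seed = 1),
               "too long")
})

test_that("SNP panels put Hardy-Weinberg heterozygosity in controls and none in the sweep", {
  panel <- simulate_snp_panel(n_cases = 30, n_controls = 80, seed = 3)
  inside <- panel$positions >= panel$sweep[1] & panel$positions <= panel$sweep[2]
  cases <- panel$genotypes[panel$group == "R1R1", ]
  expect_true(all(cases[, inside] %in% c(0L, 2L)))
  # controls at p = 0.5: heterozygote fraction near 0.5
  het <- mean(panel$genotypes[panel$group == "rr", ] == 1L)
  n <- sum(panel$group == "rr") * ncol(panel$genotypes)
  expect_lt(abs(het - 0.5), 4 * sqrt(0.25 / n))
  # determinism and TSV round trip
  panel2 <- simulate_snp_panel(n_cases = 30, n_controls = 80, seed = 3)
  expect_identical(panel$genotypes, panel2$genotypes)
  path <- tempfile(fileext = ".tsv")
  write_snp_panel(panel, path)
  back <- read_snp_panel(path)
  expect_equal(unname(back$genotypes), unname(panel$genotypes))
  expect_equal(back$sweep, panel$sweep)
  expect_error(simulate_snp_panel(sweep = c(1, 2), seed = 1), "outside")
})

test_that("pedigrees segregate half Rose and suppress carrier recombination", {
  # theta = 0 everywhere: every progeny carries a parental haplotype
  ped0 <- simulate_pedigree(pedigree_design(theta = 0, missing_rate = 0),
                            seed = 1)
  mk <- names(pedigree_design()$marker_pos)
  hap <- as.matrix(ped0[, mk])
  expect_true(all(hap == ped0$trait))
  # markers inside the suppressed interval: zero recombinants vs trait
  ped <- simulate_pedigree(seed = 2)
  lt <- two_point_lod(ped)
  inside <- lt$position >= 16077352 & lt$position <= 23443405
  expect_true(all(lt$r[inside] == 0))
  expect_true(any(lt$r[!inside] > 0))
  # informative meioses vary with missingness
  expect_true(all(lt$n <= 383))
  # Rose fraction ~ 1/2: 95% binomial CI coverage over seeds
  hit <- 0L
  for (seed in 1:20) {
    p <- simulate_pedigree(seed = seed)
    z <- abs(mean(p$phenotype == "rose") - 0.5) / sqrt(0.25 / nrow(p))
    hit <- hit + (z <= 1.96)
  }
  expect_gte(hit, 16)
})
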