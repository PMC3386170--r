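test_that("inversion alleles conserve length and base composition", {
  expect_equal(toy_alleles$R1$length, toy_ref$length)
  f1 <- Biostrings::alphabetFrequency(Biostrings::DNAString(toy_alleles$R1$sequence))
  f0 <- Biostrings::alphabetFrequency(Biostrings::DNAString(toy_ref$sequence))
  # reverse-complementation swaps A<->T and C<->G inside the inverted
  # segment; whole-allele GC is conserved
  expect_equal(sum(f1[c("G", "C")]), sum(f0[c("G", "C")]))
  expect_equal(sum(f1), sum(f0))
})

test_that("single forward segment reproduces the reference identically", {
  expect_identical(toy_alleles$r$sequence, toy_ref$sequence)
})

test_that("R2 matches direct string construction and the expected length", {
  cc <- toy_coords
  expected <- paste0(
    substr(toy_ref$sequence, 1, cc$a),
    revcomp(substr(toy_ref$sequence, cc$d + 1, cc$b)),
    substr(toy_ref$sequence, cc$c + 1, toy_ref$length))
  expect_identical(toy_alleles$R2$sequence, expected)
  expect_equal(toy_alleles$R2$length,
               toy_ref$length + (cc$b - cc$d) + 198)
  # at full printed coordinates, by segment algebra alone
  full <- rosecomb_coords(scale_div = 1)
  segs <- segments(c(0, full$d, full$c), c(full$a, full$b, full$ref_length),
                   c("forward", "reverse", "forward"))
  expect_equal(allele_length(segs), full$ref_length + 90970 + 198)
})

test_that("allele sequence reconstructs byte-for-byte from its segment map", {
  for (al in toy_alleles) {
    segs <- al$segments
    pieces <- vapply(seq_len(nrow(segs)), function(i) {
      s <- ref_subseq(toy_ref, segs$start[i], segs$end[i])
      if (segs$orientation[i] == "reverse") revcomp(s) else s
    }, character(1))
    expect_identical(paste(pieces, collapse = ""), al$sequence)
  }
})

test_that("liftover follows the forward and mirrored reverse formulas", {
  al <- toy_alleles$R1
  segs <- al$segments
  # forward segment
  p <- segs$allele_start[1] + 1234
  lo <- liftover(p, al)
  expect_equal(lo$ref, segs$start[1] + 1234)
  expect_equal(lo$orientation, "forward")
  # reversed segment: ref = start + (end - 1 - offset), orientation flipped
  off <- 777
  p <- segs$allele_start[2] + off
  lo <- liftover(p, al)
  expect_equal(lo$ref, segs$start[2] + (segs$end[2] - segs$start[2] - 1 - off))
  expect_equal(lo$orientation, "reverse")
  expect_error(liftover(al$length, al), "outside")
})

test_that("liftover round-trips and is certified by 31-mer lookup", {
  set.seed(42)
  for (al in toy_alleles[c("R1", "R2")]) {
    pos <- sort(sample(al$length - 31, 1000))
    lifted <- liftover(pos, al)
    for (i in sample(1000, 60)) {
      # round trip allele -> ref -> allele within the owning segment
      back <- ref_to_allele(lifted$ref[i], al)
      expect_true(pos[i] %in% back$allele_pos)
      # the 31-mer at the allele position must occur at the lifted reference
      # position in the lifted orientation
      kmer <- substr(al$sequence, pos[i] + 1, pos[i] + 31)
      seg <- al$segments[lifted$segment[i], ]
      if (pos[i] + 31 > seg$allele_end) next  # k-mer crosses a junction
      if (lifted$orientation[i] == "forward") {
        expect_identical(ref_subseq(toy_ref, lifted$ref[i], lifted$ref[i] + 31),
                         kmer)
      } else {
        expect_identical(revcomp(ref_subseq(toy_ref, lifted$ref[i] - 30,
                                            lifted$ref[i] + 1)), kmer)
      }
    }
  }
})

test_that("junction extraction recovers the specified breakpoints exactly", {
  cc <- toy_coords
  expect_equal(nrow(extract_junctions(toy_alleles$r)), 0)
  j1 <- extract_junctions(toy_alleles$R1)
  expect_equal(nrow(j1), 2)
  expect_equal(j1$ref_cut_left, c(cc$a, cc$a))
  expect_equal(j1$ref_cut_right, c(cc$b, cc$b))
  expect_equal(j1$allele_position, c(cc$a, cc$b))
  j2 <- extract_junctions(toy_alleles$R2)
  expect_equal(nrow(j2), 2)
  # the four reference cut positions recover all four printed breakpoints
  expect_setequal(c(j2$ref_cut_left, j2$ref_cut_right),
                  c(cc$a, cc$b, cc$c, cc$d))
  expect_error(extract_junctions(toy_alleles$R1, flank = 10), "flank")
})

test_that("junction flanks agree with the allele sequence", {
  j <- extract_junctions(toy_alleles$R1, flank = 60)
  for (i in 1:2) {
    pos <- j$allele_position[i]
    expect_identical(j$left_flank[i],
                     substr(toy_alleles$R1$sequence, pos - 59, pos))
    expect_identical(j$right_flank[i],
                     substr(toy_alleles$R1$sequence, pos + 1, pos + 60))
  }
})

test_that("unequal crossover of wild type and R1 reproduces R2 byte-for-byte", {
  cc <- toy_coords
  # R1 cut 91 kb (scaled) into the inversion; wild type cut 198 bp upstream
  # of the proximal breakpoint
  pos_R1 <- cc$a + (cc$b - cc$d)
  rec <- unequal_crossover(toy_alleles$R1, toy_alleles$r, pos_R1, cc$c,
                           toy_ref)
  expect_identical(rec$sequence, toy_alleles$R2$sequence)
  expect_equal(rec$segments[, c("start", "end", "orientation")],
               toy_alleles$R2$segments[, c("start", "end", "orientation")])
})

test_that("crossover conserves length and self-crossover is the identity", {
  al <- toy_alleles$R1
  pos <- 12345
  self <- unequal_crossover(al, al, pos, pos, toy_ref)
  expect_identical(self$sequence, al$sequence)
  other <- toy_alleles$r
  rec <- unequal_crossover(al, other, 2000, 150000, toy_ref)
  expect_equal(rec$length, 2000 + (other$length - 150000))
  expect_error(unequal_crossover(al, other, -1, 0, toy_ref), "pos_a")
  expect_error(unequal_crossover(al, other, 0, other$length + 1, toy_ref),
               "pos_b")
})

test_that("segment maps export as stranded BED", {
  path <- tempfile(fileext = ".bed")
  segments_to_bed(toy_alleles$R1, path)
  bed <- utils::read.table(path, sep = "\t")
  expect_equal(nrow(bed), 3)
  expect_equal(bed$V2, toy_alleles$R1$segments$start)  # BED is 0-based
  expect_equal(bed$V6, c("+", "-", "+"))
})

test_that("build_allele rejects out-of-bounds segments", {
  expect_error(build_allele(toy_ref, segments(0, toy_ref$length + 1), "bad"),
               "bounds")
  expect_error(segments(10, 10), "start < end")
})

test_that("FASTA round trip preserves the reference", {
  path <- tempfile(fileext = ".fa")
  write_fasta(toy_ref, path)
  back <- read_fasta(path)
  expect_identical(back$sequence, toy_ref$sequence)
  expect_identical(back$name, toy_ref$name)
})
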