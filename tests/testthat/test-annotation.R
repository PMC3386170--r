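genes <- toy_gene_models(toy_coords)

test_that("proximal breakpoint annotation reproduces the published geometry", {
  ann <- annotate_breakpoint(toy_coords$a, genes)
  fk <- ann[ann$gene == "FKBP7", ]
  expect_equal(fk$feature, "5'UTR")
  expect_equal(fk$dist_start_codon, 72)
  pl <- ann[ann$gene == "PLEKHA3", ]
  expect_equal(pl$dist_utr5, 42)
  expect_equal(pl$dist_start_codon, 150)
  # 9 bp separate the two 5'UTRs
  expect_equal(genes$FKBP7$utr5[1] - genes$PLEKHA3$utr5[2], 9)
})

test_that("distal breakpoint falls in intron 3 with MNR2 3 kb inside", {
  ann <- annotate_breakpoint(toy_coords$b, genes)
  expect_equal(ann$feature[ann$gene == "CCDC108"], "intron 3")
  expect_equal(ann$dist_gene[ann$gene == "MNR2"], 3050)
  # intron numbering respects transcription order on the minus strand
  minus <- gene_model("m", "-", rbind(c(100, 200), c(300, 400), c(500, 600)),
                      cds_start = 550)
  expect_equal(annotate_breakpoint(450, list(minus))$feature, "intron 1")
  expect_equal(annotate_breakpoint(250, list(minus))$feature, "intron 2")
})

test_that("R1 disrupts the distal gene (exons 1-3 proximal) and relocates MNR2", {
  eff <- predict_gene_effects(toy_alleles$R1, genes)$effects
  cc <- eff[eff$gene == "CCDC108", ]
  expect_equal(cc$effect, "disrupted")
  expect_equal(cc$exons_proximal, 3)
  expect_equal(cc$exons_distal, 2)
  expect_true(cc$truncated_transcript)
  mn <- eff[eff$gene == "MNR2", ]
  expect_equal(mn$effect, "relocated")
  expect_equal(mn$full_copies, 1)
  fus <- predict_gene_effects(toy_alleles$R1, genes)$fusions
  expect_true(any(fus$gene_left == "PLEKHA3" & fus$gene_right == "CCDC108"))
})

test_that("R2 keeps the distal gene intact with a duplicated partial copy", {
  eff <- predict_gene_effects(toy_alleles$R2, genes)$effects
  cc <- eff[eff$gene == "CCDC108", ]
  expect_equal(cc$effect, "intact")
  expect_equal(cc$full_copies, 1)
  expect_gte(cc$partial_copies, 1)
  # MNR2 is duplicated whole and relocated near the proximal breakpoint
  mn <- eff[eff$gene == "MNR2", ]
  expect_equal(mn$full_copies, 2)
  expect_equal(mn$effect, "relocated")
})

test_that("wild type yields no disruptions or relocations", {
  eff <- predict_gene_effects(toy_alleles$r, genes)
  expect_true(all(eff$effects$effect == "intact"))
  expect_equal(nrow(eff$fusions), 0)
})

test_that("effects agree with a junction-only reimplementation", {
  # oracle: a gene is disrupted iff a junction reference cut falls strictly
  # inside its transcription span; exact for alleles without duplications
  # (on R2 a junction can cut a partial duplicated copy while an intact
  # full-length copy survives, which junction positions alone cannot see)
  for (al in toy_alleles[c("r", "R1")]) {
    jx <- extract_junctions(al, flank = 20)
    cuts <- unique(c(jx$ref_cut_left, jx$ref_cut_right))
    eff <- predict_gene_effects(al, genes)$effects
    for (g in names(genes)) {
      oracle <- any(cuts > genes[[g]]$span[1] & cuts < genes[[g]]$span[2])
      expect_equal(eff$effect[eff$gene == g] == "disrupted", oracle,
                   info = paste(al$name, g))
    }
  }
})

test_that("gene effects are invariant to the coordinate scale factor", {
  full_coords <- rosecomb_coords(scale_div = 1)
  full_genes <- toy_gene_models(full_coords)
  # distances replicate at printed coordinates without any sequence
  ann <- annotate_breakpoint(full_coords$a, full_genes)
  expect_equal(ann$dist_start_codon[ann$gene == "FKBP7"], 72)
  expect_equal(ann$dist_utr5[ann$gene == "PLEKHA3"], 42)
  skel <- list(segments(c(0, full_coords$a, full_coords$b),
                        c(full_coords$a, full_coords$b, full_coords$ref_length),
                        c("forward", "reverse", "forward")))
  al_full <- rosecomb:::skeleton_allele(skel[[1]], "R1")
  eff_full <- predict_gene_effects(al_full, full_genes)$effects
  eff_toy <- predict_gene_effects(toy_alleles$R1, genes)$effects
  expect_equal(eff_full$effect, eff_toy$effect)
  expect_equal(eff_full$exons_proximal, eff_toy$exons_proximal)
})

test_that("gene models survive a GFF3 round trip", {
  path <- tempfile(fileext = ".gff3")
  write_gene_models_gff3(genes, path)
  back <- read_gene_models_gff3(path)
  expect_setequal(names(back), names(genes))
  for (g in names(genes)) {
    expect_equal(unname(back[[g]]$exons), unname(genes[[g]]$exons), info = g)
    expect_equal(back[[g]]$strand, genes[[g]]$strand)
    expect_equal(back[[g]]$cds_start, genes[[g]]$cds_start)
    expect_equal(back[[g]]$utr5, genes[[g]]$utr5)
  }
})

test_that("gene model invariants are enforced", {
  expect_error(gene_model("x", "+", rbind(c(1, 100), c(50, 150)), 10),
               "non-overlapping")
  expect_error(gene_model("x", "+", rbind(c(1, 100)), 200), "start codon")
})
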