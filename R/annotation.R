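#' Gene model constructor
#'
#' A transcript model: strand, ordered exons (0-based half-open reference
#' intervals, in transcription order), the start-codon position, and
#' optional UTR intervals. Exons must be non-overlapping and the start codon
#' must fall inside an exon.
#'
#' @param gene_id gene identifier.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix or data.frame of 0-based half-open exon
#'   intervals, in transcription order (decreasing coordinates on `"-"`).
#' @param cds_start 0-based reference position of the start codon's first
#'   transcribed base.
#' @param utr5,utr3 optional 0-based half-open intervals.
#' @return list of class `gene_model`.
#' @export
gene_model <- function(gene_id, strand, exons, cds_start,
                       utr5 = NULL, utr3 = NULL) {
  exons <- as.matrix(exons)
  stopifnot(strand %in% c("+", "-"), ncol(exons) == 2,
            all(exons[, 1] < exons[, 2]))
  ord <- order(exons[, 1])
  if (any(exons[ord, 2][-nrow(exons)] > exons[ord, 1][-1])) {
    stop("exons must be non-overlapping")
  }
  tx_order <- if (strand == "+") ord else rev(ord)
  if (!all(tx_order == seq_len(nrow(exons)))) exons <- exons[tx_order, , drop = FALSE]
  in_exon <- any(exons[, 1] <= cds_start & cds_start < exons[, 2])
  if (!in_exon) stop("start codon must fall inside an exon")
  structure(list(gene_id = gene_id, strand = strand, exons = exons,
                 cds_start = cds_start, utr5 = utr5, utr3 = utr3,
                 span = c(min(exons[, 1]), max(exons[, 2]))),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %d exon(s), span %s-%s, start codon %s\n",
              x$gene_id, x$strand, nrow(x$exons),
              format(x$span[1], big.mark = ","), format(x$span[2], big.mark = ","),
              format(x$cds_start, big.mark = ",")))
  invisible(x)
}

#' Toy gene models with the breakpoint-locus geometry
#'
#' Four gene models reproducing the published geometry around the two
#' inversion breakpoints, at any coordinate scale: an FKBP7-like gene whose
#' 5'UTR contains the proximal breakpoint 72 bp upstream of its start codon;
#' a divergent PLEKHA3-like gene whose 5'UTR lies 42 bp and start codon
#' 150 bp from the breakpoint (9 bp separating the two UTRs); a
#' CCDC108-like gene disrupted in intron 3 by the distal breakpoint (exons
#' 1-3 proximal of the cut); and an intact single-exon MNR2-like gene 3 kb
#' inside the distal breakpoint.
#'
#' @param coords coordinate layout from [rosecomb_coords()].
#' @return Named list of [gene_model()]s.
#' @export
toy_gene_models <- function(coords = rosecomb_coords()) {
  a <- coords$a; b <- coords$b
  list(
    FKBP7 = gene_model("FKBP7", "+",
                       exons = rbind(c(a - 33, a + 200), c(a + 600, a + 900)),
                       cds_start = a + 72, utr5 = c(a - 33, a + 72)),
    PLEKHA3 = gene_model("PLEKHA3", "-",
                         exons = rbind(c(a - 400, a - 42), c(a - 900, a - 600)),
                         cds_start = a - 151, utr5 = c(a - 150, a - 42)),
    CCDC108 = gene_model("CCDC108", "+",
                         exons = rbind(c(b - 2900, b - 2601),
                                       c(b - 2200, b - 2001),
                                       c(b - 1200, b - 101),
                                       c(b + 400, b + 700),
                                       c(b + 1100, b + 1500)),
                         cds_start = b - 2850),
    MNR2 = gene_model("MNR2", "-",
                      exons = rbind(c(b - 6000, b - 3050)),
                      cds_start = b - 3200)
  )
}

#' Annotate a breakpoint against gene models
#'
#' Classifies the cut position by interval containment (5'UTR, 3'UTR,
#' exon k, intron k in transcription order, or intergenic) and reports
#' distances in bp along the reference from the cut to each gene's
#' landmarks. A cut at 0-based half-open position `p` sits between bases
#' `p-1` and `p`; the distance to a base at position `q` is `q - p` for
#' `q >= p` and `p - q - 1` otherwise (bases strictly between cut and
#' landmark).
#'
#' @param cut 0-based half-open breakpoint cut position.
#' @param models named list of [gene_model()]s.
#' @return `data.frame` with one row per gene: `gene`, `feature`,
#'   `dist_start_codon`, `dist_utr5`, `dist_gene` (0 when the cut is inside
#'   the gene span).
#' @export
annotate_breakpoint <- function(cut, models) {
  dist_to <- function(q) ifelse(q >= cut, q - cut, cut - q - 1)
  dist_iv <- function(iv) {
    if (is.null(iv)) return(NA_real_)
    if (iv[1] <= cut && cut < iv[2]) 0 else min(dist_to(iv[1]), dist_to(iv[2] - 1))
  }
  rows <- lapply(models, function(g) {
    inside <- g$span[1] < cut & cut < g$span[2]
    feature <- "intergenic"
    if (inside) {
      ex <- which(g$exons[, 1] <= cut & cut < g$exons[, 2])
      if (!is.null(g$utr5) && g$utr5[1] <= cut && cut < g$utr5[2]) {
        feature <- "5'UTR"
      } else if (!is.null(g$utr3) && g$utr3[1] <= cut && cut < g$utr3[2]) {
        feature <- "3'UTR"
      } else if (length(ex)) {
        feature <- sprintf("exon %d", ex)
      } else {
        # intron k follows exon k in transcription order
        ref_order <- order(g$exons[, 1])
        below <- sum(g$exons[ref_order, 2] <= cut)
        k <- if (g$strand == "+") below else nrow(g$exons) - below
        feature <- sprintf("intron %d", k)
      }
    }
    data.frame(gene = g$gene_id, feature = feature,
               dist_start_codon = dist_to(g$cds_start),
               dist_utr5 = dist_iv(g$utr5),
               dist_gene = dist_iv(g$span + c(0, 0)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Predict transcript-level consequences of a rearranged allele
#'
#' Lifts every gene through the allele's segment map. A gene with at least
#' one full-length contiguous, orientation-consistent copy on the allele is
#' intact (duplicated segments can add partial extra copies, reported as
#' `partial_copies`); a gene with no full copy is disrupted, with its exons
#' partitioned by the junction cutting it and a truncated transcript
#' predicted from the fragment retaining downstream exons but not the start
#' codon's side. Intact genes lying within `neighborhood` of a junction on
#' the allele, or carried on a reverse-orientation segment, are flagged
#' relocated. Genes within `neighborhood` on the two sides of one junction
#' are reported as candidate fusion pairs.
#'
#' @param allele a `rearrangement_allele`.
#' @param models named list of [gene_model()]s on the allele's reference.
#' @param neighborhood bp radius defining "near a junction" (default 10 kb).
#' @return list of class `gene_effects`: `effects` (data frame: `gene`,
#'   `effect` in disrupted/relocated/intact, `full_copies`, `partial_copies`,
#'   `exons_proximal`, `exons_distal`, `truncated_transcript`) and `fusions`
#'   (data frame of junction-adjacent gene pairs).
#' @export
predict_gene_effects <- function(allele, models, neighborhood = 10000) {
  segs <- allele$segments
  jx <- extract_junctions(allele, flank = 20L)
  gene_rows <- lapply(models, function(g) {
    cover <- which(segs$start < g$span[2] & segs$end > g$span[1])
    full <- cover[segs$start[cover] <= g$span[1] & segs$end[cover] >= g$span[2]]
    # allele positions of full copies (midpoint), for relocation distance
    full_pos <- vapply(full, function(i) {
      mid <- (g$span[1] + g$span[2]) / 2
      if (segs$orientation[i] == "forward") {
        segs$allele_start[i] + (mid - segs$start[i])
      } else {
        segs$allele_start[i] + (segs$end[i] - mid)
      }
    }, numeric(1))
    n_partial <- length(cover) - length(full)
    if (length(full) == 0) {
      # disrupted: partition exons by the junction cut inside the gene
      cuts <- sort(unique(c(segs$start[cover], segs$end[cover])))
      cuts <- cuts[cuts > g$span[1] & cuts < g$span[2]]
      cut <- cuts[1]
      below <- sum(g$exons[, 2] <= cut)
      n_ex <- nrow(g$exons)
      data.frame(gene = g$gene_id, effect = "disrupted",
                 full_copies = 0L, partial_copies = n_partial,
                 exons_proximal = below,
                 exons_distal = n_ex - below,
                 truncated_transcript = TRUE, stringsAsFactors = FALSE)
    } else {
      near_junction <- length(jx$allele_position) > 0 &&
        any(vapply(full_pos, function(p)
          min(abs(jx$allele_position - p)) <=
            neighborhood + (g$span[2] - g$span[1]) / 2, logical(1)))
      reversed <- any(segs$orientation[full] == "reverse")
      effect <- if (near_junction || (reversed && nrow(jx) > 0)) "relocated" else "intact"
      data.frame(gene = g$gene_id, effect = effect,
                 full_copies = length(full), partial_copies = n_partial,
                 exons_proximal = NA_integer_, exons_distal = NA_integer_,
                 truncated_transcript = FALSE, stringsAsFactors = FALSE)
    }
  })
  effects <- do.call(rbind, gene_rows)
  rownames(effects) <- NULL
  fusions <- fusion_candidates(allele, models, jx, neighborhood)
  structure(list(effects = effects, fusions = fusions,
                 allele = allele$name), class = "gene_effects")
}

# genes whose lifted material lies within `neighborhood` on either side of a
# junction form candidate fusion pairs across that junction
fusion_candidates <- function(allele, models, jx, neighborhood) {
  out <- data.frame(junction = integer(0), gene_left = character(0),
                    gene_right = character(0))
  if (nrow(jx) == 0) return(out)
  segs <- allele$segments
  lifted <- lapply(models, function(g) {
    cover <- which(segs$start < g$span[2] & segs$end > g$span[1])
    do.call(rbind, lapply(cover, function(i) {
      lo <- max(g$span[1], segs$start[i]); hi <- min(g$span[2], segs$end[i])
      if (segs$orientation[i] == "forward") {
        c(segs$allele_start[i] + (lo - segs$start[i]),
          segs$allele_start[i] + (hi - segs$start[i]))
      } else {
        c(segs$allele_start[i] + (segs$end[i] - hi),
          segs$allele_start[i] + (segs$end[i] - lo))
      }
    }))
  })
  for (j in seq_len(nrow(jx))) {
    pos <- jx$allele_position[j]
    side <- function(lo_side) {
      names(models)[vapply(lifted, function(iv) {
        if (is.null(iv)) return(FALSE)
        any(if (lo_side) iv[, 2] <= pos & iv[, 2] >= pos - neighborhood
            else iv[, 1] >= pos & iv[, 1] <= pos + neighborhood)
      }, logical(1))]
    }
    left <- side(TRUE); right <- side(FALSE)
    for (gl in left) for (gr in right) {
      if (gl == gr) next
      out <- rbind(out, data.frame(junction = j, gene_left = gl,
                                   gene_right = gr))
    }
  }
  out
}

#' @export
print.gene_effects <- function(x, ...) {
  cat(sprintf("<gene_effects> allele %s\n", x$allele))
  print.data.frame(x$effects, row.names = FALSE)
  if (nrow(x$fusions)) {
    cat("candidate fusions:\n")
    print.data.frame(x$fusions, row.names = FALSE)
  }
  invisible(x)
}

#' Write and read gene models as GFF3
#'
#' Writes gene/mRNA/exon/five_prime_UTR/CDS features; reading goes through
#' `rtracklayer::import` and rebuilds [gene_model()] objects.
#'
#' @param models named list of [gene_model()]s.
#' @param path GFF3 path.
#' @param seqname reference sequence name.
#' @return `path` invisibly; `read_gene_models_gff3` returns the model list.
#' @export
write_gene_models_gff3 <- function(models, path, seqname = "chr7_toy") {
  lines <- "##gff-version 3"
  for (g in models) {
    row <- function(type, lo, hi, id, parent = NULL) {
      attrs <- paste0("ID=", id, if (!is.null(parent)) paste0(";Parent=", parent))
      sprintf("%s\trosecomb\t%s\t%d\t%d\t.\t%s\t.\t%s", seqname, type,
              lo + 1, hi, g$strand, attrs)
    }
    lines <- c(lines,
               row("gene", g$span[1], g$span[2], g$gene_id),
               row("mRNA", g$span[1], g$span[2], paste0(g$gene_id, ".t1"),
                   g$gene_id))
    ref_order <- order(g$exons[, 1])
    for (i in seq_len(nrow(g$exons))) {
      e <- g$exons[i, ]
      lines <- c(lines, row("exon", e[1], e[2],
                            sprintf("%s.e%d", g$gene_id, i),
                            paste0(g$gene_id, ".t1")))
    }
    lines <- c(lines, row("CDS", g$cds_start, g$cds_start + 3,
                          paste0(g$gene_id, ".cds"), paste0(g$gene_id, ".t1")))
    if (!is.null(g$utr5)) {
      lines <- c(lines, row("five_prime_UTR", g$utr5[1], g$utr5[2],
                            paste0(g$gene_id, ".utr5"), paste0(g$gene_id, ".t1")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gene_models_gff3
#' @export
read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  genes <- gr[gr$type == "gene"]
  out <- lapply(seq_along(genes), function(i) {
    gid <- genes$ID[i]
    tx <- gr[gr$type == "mRNA" & vapply(gr$Parent, function(p)
      gid %in% p, logical(1))]
    kids <- gr[vapply(gr$Parent, function(p) any(tx$ID %in% p), logical(1))]
    ex <- kids[kids$type == "exon"]
    strand <- as.character(GenomicRanges::strand(genes[i]))
    exons <- cbind(GenomicRanges::start(ex) - 1, GenomicRanges::end(ex))
    if (strand == "-") exons <- exons[order(-exons[, 1]), , drop = FALSE]
    else exons <- exons[order(exons[, 1]), , drop = FALSE]
    cds <- kids[kids$type == "CDS"]
    utr5g <- kids[kids$type == "five_prime_UTR"]
    utr5 <- if (length(utr5g)) c(GenomicRanges::start(utr5g)[1] - 1,
                                 GenomicRanges::end(utr5g)[1]) else NULL
    gene_model(gid, strand, exons,
               cds_start = GenomicRanges::start(cds)[1] - 1, utr5 = utr5)
  })
  names(out) <- genes$ID
  out
}
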