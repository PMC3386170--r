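#' Diagnostic primer set for the Rose-comb breakpoint assay
#'
#' Five primers anchored around the locus breakpoints (positions relative to
#' the breakpoint cuts, so amplicon sizes are invariant under the coordinate
#' scale factor). Primers are positional anchors, not sequences: primer
#' thermodynamics is out of scope, and a primer is treated as a point whose
#' products are all convergent primer-pair spans below `max_len`.
#'
#' @param coords coordinate layout from [rosecomb_coords()].
#' @return `data.frame` of class `primer_set` with columns `name`, `ref_pos`
#'   (0-based), `strand`.
#' @export
rosecomb_primers <- function(coords = rosecomb_coords()) {
  p <- data.frame(
    name = c("P1", "P2", "P3", "P4", "P5"),
    ref_pos = c(coords$c - 100, coords$a + 150, coords$b - 450,
                coords$b + 700, coords$d + 250),
    strand = c("+", "-", "+", "-", "-"),
    stringsAsFactors = FALSE)
  class(p) <- c("primer_set", class(p))
  p
}

#' Predict PCR amplicons of a primer set on an allele
#'
#' Maps every primer onto the allele through its segment map (a primer may
#' anchor several times when its site is duplicated; a reverse-orientation
#' segment flips the primer's effective strand) and reports every convergent
#' primer pair within `max_len`.
#'
#' @param allele a `rearrangement_allele` (only the segment map is used).
#' @param primers a [rosecomb_primers()]-style primer table.
#' @param max_len maximum amplifiable product size in bp.
#' @return `data.frame` with one row per product: `fwd`, `rev` (primer
#'   names), `pair` (unordered pair key), `size`, `allele_start`,
#'   `allele_end`.
#' @export
predict_amplicons <- function(allele, primers, max_len = 2000) {
  sites <- do.call(rbind, lapply(seq_len(nrow(primers)), function(i) {
    hit <- ref_to_allele(primers$ref_pos[i], allele)
    if (nrow(hit) == 0) return(NULL)
    flip <- hit$orientation == "reverse"
    data.frame(name = primers$name[i],
               pos = hit$allele_pos,
               strand = ifelse(flip,
                               ifelse(primers$strand[i] == "+", "-", "+"),
                               primers$strand[i]),
               stringsAsFactors = FALSE)
  }))
  empty <- data.frame(fwd = character(0), rev = character(0),
                      pair = character(0), size = numeric(0),
                      allele_start = numeric(0), allele_end = numeric(0))
  if (is.null(sites)) return(empty)
  plus <- sites[sites$strand == "+", ]
  minus <- sites[sites$strand == "-", ]
  out <- list()
  for (i in seq_len(nrow(plus))) for (j in seq_len(nrow(minus))) {
    size <- minus$pos[j] - plus$pos[i] + 1
    if (size > 0 && size <= max_len) {
      out[[length(out) + 1]] <- data.frame(
        fwd = plus$name[i], rev = minus$name[j],
        pair = paste(sort(c(plus$name[i], minus$name[j])), collapse = "."),
        size = size, allele_start = plus$pos[i], allele_end = minus$pos[j] + 1,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- unique(do.call(rbind, out))
  rownames(res) <- NULL
  res
}

.genotypes6 <- c("rr", "R1R1", "R2R2", "R1R2", "R1r", "R2r")

genotype_alleles <- function(genotype) {
  switch(genotype,
         rr = c("r", "r"), R1R1 = c("R1", "R1"), R2R2 = c("R2", "R2"),
         R1R2 = c("R1", "R2"), R1r = c("R1", "r"), R2r = c("R2", "r"),
         stop("unknown genotype: ", genotype))
}

#' Build the five-band junction PCR assay and its genotype truth table
#'
#' Predicts the products of the five diagnostic primers on the wild-type,
#' R1, and R2 segment maps, names the five diagnostic amplicons (one per
#' locus breakpoint), and tabulates the expected band pattern for each of
#' the six diploid genotypes. The table must be injective over the six
#' genotypes, and all band sizes must be separated by more than twice the
#' matching tolerance; an assay violating either is rejected.
#'
#' @param coords coordinate layout from [rosecomb_coords()].
#' @param max_len maximum product size.
#' @param size_tol relative band-size matching tolerance.
#' @return list of class `junction_assay`: `primers`, `catalog` (amplicon id,
#'   primer pair, size), `allele_bands` (allele -> amplicon ids), `truth`
#'   (6 genotypes x amplicons logical matrix), `size_tol`.
#' @export
rosecomb_assay <- function(coords = rosecomb_coords(), max_len = 2000,
                           size_tol = 0.05) {
  primers <- rosecomb_primers(coords)
  L <- coords$ref_length
  maps <- list(
    r = skeleton_allele(segments(0, L), "r"),
    R1 = skeleton_allele(segments(c(0, coords$a, coords$b),
                                  c(coords$a, coords$b, L),
                                  c("forward", "reverse", "forward")), "R1"),
    R2 = skeleton_allele(segments(c(0, coords$d, coords$c),
                                  c(coords$a, coords$b, L),
                                  c("forward", "reverse", "forward")), "R2"))
  amp <- lapply(maps, predict_amplicons, primers = primers, max_len = max_len)
  id_of <- c(P1.P2 = "wt_proximal", P3.P4 = "wt_distal", P1.P3 = "R_proximal",
             P2.P4 = "R1_distal", P2.P5 = "R2_dup")
  catalog <- unique(do.call(rbind, amp)[, c("pair", "size")])
  if (any(!catalog$pair %in% names(id_of))) {
    stop("assay design error: unexpected primer product ",
         paste(setdiff(catalog$pair, names(id_of)), collapse = ", "))
  }
  catalog$id <- unname(id_of[catalog$pair])
  if (anyDuplicated(catalog$id)) stop("assay design error: ambiguous product sizes")
  catalog <- catalog[order(catalog$size), c("id", "pair", "size")]
  rownames(catalog) <- NULL
  sizes <- sort(catalog$size)
  if (any(diff(sizes) <= 2 * size_tol * sizes[-1])) {
    stop("assay design error: band sizes not separable at the matching tolerance")
  }
  allele_bands <- lapply(amp, function(a) unname(id_of[a$pair]))
  truth <- t(vapply(.genotypes6, function(g) {
    present <- unique(unlist(allele_bands[genotype_alleles(g)]))
    catalog$id %in% present
  }, logical(nrow(catalog))))
  colnames(truth) <- catalog$id
  if (anyDuplicated(apply(truth, 1, paste, collapse = "")) > 0) {
    stop("assay design error: truth table not injective over the six genotypes")
  }
  structure(list(primers = primers, catalog = catalog,
                 allele_bands = allele_bands, truth = truth,
                 size_tol = size_tol, max_len = max_len),
            class = "junction_assay")
}

# lightweight allele carrier for map-only operations (no sequence needed)
skeleton_allele <- function(segs, name) {
  lens <- segs$end - segs$start
  segs$allele_end <- cumsum(lens)
  segs$allele_start <- segs$allele_end - lens
  structure(list(name = name, segments = segs, length = sum(lens),
                 sequence = NULL), class = "rearrangement_allele")
}

#' @export
print.junction_assay <- function(x, ...) {
  cat("<junction_assay> five-breakpoint Rose-comb band assay\n")
  print.data.frame(x$catalog, row.names = FALSE)
  cat("truth table (bands x genotypes):\n")
  print(t(x$truth))
  invisible(x)
}

#' Expected band sizes of a diploid genotype
#'
#' @param genotype one of `rr`, `R1R1`, `R2R2`, `R1R2`, `R1r`, `R2r`.
#' @param assay a [rosecomb_assay()].
#' @return Named numeric vector of band sizes (bp) present for the genotype.
#' @export
expected_bands <- function(genotype, assay) {
  present <- assay$truth[genotype, ]
  stats::setNames(assay$catalog$size, assay$catalog$id)[present]
}

#' Call a diploid genotype from an observed band pattern
#'
#' Observed band sizes are matched to the assay catalog within the relative
#' size tolerance; the resulting presence pattern must match exactly one
#' truth-table row. Patterns matching no row (or containing unmatchable
#' bands) yield a no-call with a diagnostic, never a silent coercion.
#'
#' @param bands numeric vector of observed band sizes in bp (possibly noisy).
#' @param assay a [rosecomb_assay()].
#' @return list of class `genotype_call`: `genotype` (`NA` for no-call),
#'   `status` (`"ok"`, `"no_match"`, `"unknown_band"`), `junctions`
#'   (amplicon ids present), `detail`.
#' @export
call_genotype <- function(bands, assay) {
  ids <- character(0)
  for (b in bands) {
    rel <- abs(assay$catalog$size - b) / assay$catalog$size
    hit <- which(rel <= assay$size_tol)
    if (length(hit) != 1) {
      return(structure(list(genotype = NA_character_, status = "unknown_band",
                            junctions = ids,
                            detail = sprintf("band %g bp matches %d catalog entries",
                                             b, length(hit))),
                       class = "genotype_call"))
    }
    ids <- union(ids, assay$catalog$id[hit])
  }
  pattern <- assay$catalog$id %in% ids
  match_row <- which(apply(assay$truth, 1, function(x) all(x == pattern)))
  if (length(match_row) == 1) {
    structure(list(genotype = rownames(assay$truth)[match_row], status = "ok",
                   junctions = ids, detail = ""), class = "genotype_call")
  } else {
    structure(list(genotype = NA_character_, status = "no_match",
                   junctions = ids,
                   detail = sprintf("pattern {%s} matches %d genotypes",
                                    paste(ids, collapse = ","),
                                    length(match_row))),
              class = "genotype_call")
  }
}

#' @export
print.genotype_call <- function(x, ...) {
  cat(sprintf("<genotype_call> %s (%s) bands: %s\n",
              ifelse(is.na(x$genotype), "no-call", x$genotype), x$status,
              paste(x$junctions, collapse = ", ")))
  invisible(x)
}

#' Simulate a genotyped cohort through the band assay
#'
#' Draws bird genotypes, derives each bird's band pattern from the assay
#' (optionally jittered by multiplicative size noise), assigns the fully
#' dominant comb phenotype, and genotypes every bird back through
#' [call_genotype()].
#'
#' @param n cohort size.
#' @param assay a [rosecomb_assay()].
#' @param geno_freqs genotype sampling weights over the six genotypes.
#' @param band_noise sd of multiplicative band-size noise (e.g. 0.02).
#' @param seed integer seed.
#' @return `data.frame`: `bird`, `true_genotype`, `phenotype`, `called`,
#'   `status`, `concordant`.
#' @export
simulate_cohort <- function(n, assay, geno_freqs = c(rr = 0.35, R1R1 = 0.14,
                                                     R2R2 = 0.02, R1R2 = 0.01,
                                                     R1r = 0.45, R2r = 0.03),
                            band_noise = 0, seed = 1L) {
  set.seed(seed)
  gt <- sample(names(geno_freqs), n, replace = TRUE, prob = geno_freqs)
  calls <- lapply(gt, function(g) {
    b <- expected_bands(g, assay)
    if (band_noise > 0) b <- b * (1 + stats::rnorm(length(b), 0, band_noise))
    call_genotype(b, assay)
  })
  data.frame(bird = sprintf("bird%04d", seq_len(n)),
             true_genotype = gt,
             phenotype = ifelse(gt == "rr", "single", "rose"),
             called = vapply(calls, `[[`, character(1), "genotype"),
             status = vapply(calls, `[[`, character(1), "status"),
             concordant = !is.na(vapply(calls, `[[`, character(1), "genotype")) &
               gt == vapply(calls, `[[`, character(1), "genotype"),
             stringsAsFactors = FALSE)
}

#' Genotype-by-phenotype cohort summary with dominance concordance
#'
#' Tabulates genotype counts per (breed, phenotype) and reports the
#' dominance concordance: the fraction of R-carrying birds with a
#' rose/walnut comb plus `rr` birds with a single/pea comb, among records
#' with known phenotype. Unknown phenotype labels are excluded with a
#' warning and reported in the `excluded` count.
#'
#' @param df data frame with columns `genotype`, `phenotype`, and optionally
#'   `breed`.
#' @return list of class `cohort_summary`: `table` (counts), `concordance`,
#'   `excluded`, `n`.
#' @export
cohort_summary <- function(df) {
  if (nrow(df) < 1) stop("at least one record required")
  known <- c("rose", "single", "walnut", "pea")
  ok <- df$phenotype %in% known
  if (any(!ok)) {
    warning(sum(!ok), " record(s) with unknown phenotype excluded")
  }
  d <- df[ok, ]
  if (!"breed" %in% names(d)) d$breed <- "all"
  tab <- as.data.frame(table(breed = d$breed, phenotype = d$phenotype,
                             genotype = factor(d$genotype, levels = .genotypes6)))
  tab <- tab[tab$Freq > 0, ]
  rownames(tab) <- NULL
  carrier <- d$genotype != "rr"
  conc <- mean(ifelse(carrier, d$phenotype %in% c("rose", "walnut"),
                      d$phenotype %in% c("single", "pea")))
  structure(list(table = tab, concordance = conc, excluded = sum(!ok),
                 n = nrow(d)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d bird(s), dominance concordance %.3f (%d excluded)\n",
              x$n, x$concordance, x$excluded))
  print.data.frame(x$table, row.names = FALSE)
  invisible(x)
}

#' Write genotype calls as a minimal TSV
#'
#' @param df cohort data frame with at least `bird` and `called`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_calls <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
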