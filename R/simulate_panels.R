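#' Simulate a SNP genotype matrix with a homozygous sweep
#'
#' Emulates a 60K-array screen of Rose-comb homozygotes versus wild-type
#' birds: loci are biallelic with given reference-population allele
#' frequencies, wild-type (`rr`) birds are drawn at Hardy-Weinberg
#' proportions at every locus, and `R1R1` birds are completely homozygous at
#' every locus inside the sweep interval (the fixed inverted haplotype) and
#' Hardy-Weinberg elsewhere.
#'
#' @param n_cases number of `R1R1` birds.
#' @param n_controls number of wild-type birds.
#' @param positions numeric vector of locus positions in bp (sorted).
#' @param freqs per-locus allele frequencies in `[0, 1]`; recycled.
#' @param sweep length-2 interval (bp) fixed in cases; must lie within the
#'   map.
#' @param seed integer seed.
#' @return list of class `snp_panel`: `genotypes` (birds x loci matrix of
#'   alt-allele dosages 0/1/2), `positions`, `group` (`"R1R1"`/`"rr"`),
#'   `sweep`.
#' @export
simulate_snp_panel <- function(n_cases = 40, n_controls = 100,
                               positions = seq(12e6, 30e6, by = 1e4),
                               freqs = 0.5, sweep = rosecomb_breakpoints()$sweep,
                               seed = 1L) {
  stopifnot(n_cases >= 0, n_controls > 0)
  m <- length(positions)
  freqs <- rep_len(freqs, m)
  if (any(freqs < 0 | freqs > 1)) stop("allele frequencies must lie in [0,1]")
  if (sweep[1] < min(positions) || sweep[2] > max(positions)) {
    stop("sweep interval outside the marker map")
  }
  set.seed(seed)
  n <- n_cases + n_controls
  g <- matrix(stats::rbinom(n * m, 2L, rep(freqs, each = n)), nrow = n)
  group <- c(rep("R1R1", n_cases), rep("rr", n_controls))
  inside <- positions >= sweep[1] & positions <= sweep[2]
  if (n_cases > 0 && any(inside)) {
    # the fixed haplotype: one shared homozygous state per locus
    hap <- stats::rbinom(sum(inside), 1L, freqs[inside]) * 2L
    g[group == "R1R1", inside] <- matrix(hap, nrow = n_cases,
                                         ncol = sum(inside), byrow = TRUE)
  }
  colnames(g) <- sprintf("snp%05d", seq_len(m))
  structure(list(genotypes = g, positions = positions, group = group,
                 sweep = sweep),
            class = "snp_panel")
}

#' Write / read a SNP panel as TSV
#'
#' @param panel a `snp_panel`.
#' @param path file path.
#' @return `path` invisibly; `read_snp_panel` returns a `snp_panel`.
#' @export
write_snp_panel <- function(panel, path) {
  df <- data.frame(bird = sprintf("bird%04d", seq_len(nrow(panel$genotypes))),
                   group = panel$group, panel$genotypes,
                   check.names = FALSE)
  hdr <- sprintf("#sweep=%d-%d", panel$sweep[1], panel$sweep[2])
  pos <- paste0("#positions=", paste(panel$positions, collapse = ","))
  writeLines(c(hdr, pos), path)
  suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  invisible(path)
}

#' @rdname write_snp_panel
#' @export
read_snp_panel <- function(path) {
  hdr <- readLines(path, n = 2)
  sweep <- as.numeric(strsplit(sub("#sweep=", "", hdr[1]), "-")[[1]])
  positions <- as.numeric(strsplit(sub("#positions=", "", hdr[2]), ",")[[1]])
  df <- utils::read.delim(path, skip = 2, check.names = FALSE)
  structure(list(genotypes = as.matrix(df[, -(1:2)]), positions = positions,
                 group = df$group, sweep = sweep),
            class = "snp_panel")
}

#' Backcross pedigree design
#'
#' The linkage pedigree emulated here: heterozygous carrier sires
#' (`R1r`), each mated to homozygous wild-type (`rr`) dams, trait locus
#' inside the rearrangement. Recombination in carrier-sire meioses is
#' suppressed (theta forced to 0) across the inversion for marker intervals
#' inside `suppressed`.
#'
#' @param n_sires number of carrier sires.
#' @param n_dams_per_sire dams mated to each sire.
#' @param n_progeny total progeny across the design.
#' @param marker_pos named numeric vector of marker positions (bp), sorted.
#' @param trait_pos position of the trait locus (bp).
#' @param theta recombination fractions between adjacent loci (markers plus
#'   trait locus, in map order); recycled to the number of intervals.
#' @param suppressed length-2 interval (bp) with recombination suppression in
#'   carrier meioses.
#' @param missing_rate per-genotype missing-data rate at markers.
#' @return list of class `pedigree_design`.
#' @export
pedigree_design <- function(n_sires = 2, n_dams_per_sire = 8, n_progeny = 383,
                            marker_pos = c(MCW0120 = 11903615, ADL0107 = 12980283,
                                           C7C19.217 = 14557641, C7C19.249 = 16077352,
                                           C7C19.253 = 16434005, KIAA1715 = 17510907,
                                           PTD004 = 18268510, C7C19.442 = 18865430,
                                           C7C19.559 = 21118705, C7C107.36 = 23443405,
                                           C7C15.222 = 33000168),
                            trait_pos = 16499781,
                            theta = 0.05,
                            suppressed = c(16077352, 23443405),
                            missing_rate = 0.013) {
  stopifnot(n_sires >= 1, n_progeny >= 1, !is.unsorted(marker_pos))
  structure(list(n_sires = n_sires, n_dams_per_sire = n_dams_per_sire,
                 n_progeny = n_progeny, marker_pos = marker_pos,
                 trait_pos = trait_pos, theta = theta,
                 suppressed = suppressed, missing_rate = missing_rate),
            class = "pedigree_design")
}

#' Simulate phase-known backcross progeny under recombination suppression
#'
#' Each progeny receives one gamete from a carrier sire (`R1r`, phase known:
#' the R-carrying haplotype carries allele `1` at every marker, the wild-type
#' haplotype allele `0`) and one from an `rr` dam (uninformative, always
#' allele `0`). Sire gametes are built by a haplotype walk over the loci in
#' map order, switching parental haplotype between adjacent loci with the
#' interval's recombination fraction; intervals whose endpoints both lie in
#' the suppressed region have theta forced to 0 in carrier meioses. The comb
#' phenotype is fully dominant: Rose if the gamete carries the `R` trait
#' allele.
#'
#' @param design a [pedigree_design()].
#' @param seed integer seed.
#' @return `data.frame` of class `pedigree_genotypes`: one row per progeny
#'   with `sire`, `phenotype` (`"rose"`/`"single"`), `trait` (sire-gamete
#'   trait allele, 1 = R) and one column per marker holding the sire-gamete
#'   marker allele (0/1, `NA` if missing).
#' @export
simulate_pedigree <- function(design = pedigree_design(), seed = 1L) {
  stopifnot(all(design$theta >= 0 & design$theta <= 0.5))
  set.seed(seed)
  loci <- sort(c(design$marker_pos, .trait = design$trait_pos))
  n_loci <- length(loci)
  th <- rep_len(design$theta, n_loci - 1)
  inside <- loci >= design$suppressed[1] & loci <= design$suppressed[2]
  th[inside[-n_loci] & inside[-1]] <- 0   # suppression in carrier meioses
  n <- design$n_progeny
  sire <- rep(seq_len(design$n_sires), length.out = n)
  # haplotype walk: 0 = wild-type haplotype, 1 = R haplotype
  hap <- matrix(0L, nrow = n, ncol = n_loci)
  hap[, 1] <- stats::rbinom(n, 1L, 0.5)
  for (j in 2:n_loci) {
    sw <- stats::rbinom(n, 1L, th[j - 1])
    hap[, j] <- ifelse(sw == 1L, 1L - hap[, j - 1], hap[, j - 1])
  }
  colnames(hap) <- names(loci)
  trait <- hap[, ".trait"]
  geno <- hap[, colnames(hap) != ".trait", drop = FALSE]
  if (design$missing_rate > 0) {
    miss <- matrix(stats::runif(length(geno)) < design$missing_rate,
                   nrow = nrow(geno))
    geno[miss] <- NA_integer_
  }
  out <- data.frame(progeny = sprintf("F1_%03d", seq_len(n)), sire = sire,
                    phenotype = ifelse(trait == 1L, "rose", "single"),
                    trait = trait, geno, check.names = FALSE)
  attr(out, "design") <- design
  class(out) <- c("pedigree_genotypes", class(out))
  out
}

#' Write pedigree genotypes as TSV
#'
#' @param ped a `pedigree_genotypes` data frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  utils::write.table(ped, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
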