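#' Expected heterozygosity from allele frequencies
#'
#' `H = 1 - sum(p_i^2)` over the allele frequencies at a locus.
#'
#' @param p numeric vector of allele frequencies summing to 1.
#' @return Heterozygosity in `[0, 1]`.
#' @export
het_index <- function(p) {
  if (abs(sum(p) - 1) > 1e-8 || any(p < 0)) stop("frequencies must be a simplex")
  1 - sum(p^2)
}

#' Windowed heterozygosity scan with homozygous-run detection
#'
#' Per-locus heterozygosity is computed from sample allele frequencies as
#' `1 - p^2 - q^2` (biallelic dosage data) and averaged over the loci of
#' each window (tiled by default; set `stride < window` for sliding
#' windows). When case and control groups are present, maximal runs of
#' contiguous windows with `H = 0` in cases but `H > 0` in controls are
#' reported as candidate sweeps.
#'
#' @param panel a `snp_panel`, or a genotype dosage matrix (birds x loci).
#' @param positions locus positions (taken from the panel when omitted).
#' @param group group labels per bird (`"R1R1"` cases / `"rr"` controls).
#' @param window window width in bp (the emulated scan used 500 kb).
#' @param stride window stride in bp (defaults to `window`: tiled).
#' @return list of class `het_profile`: `windows` (data frame with window
#'   intervals and per-group mean H), `per_locus` (per-group per-locus H),
#'   `runs` (candidate sweep intervals).
#' @export
het_scan <- function(panel, positions = NULL, group = NULL, window = 5e5,
                     stride = window) {
  if (inherits(panel, "snp_panel")) {
    g <- panel$genotypes; positions <- panel$positions; group <- panel$group
  } else {
    g <- panel
    if (is.null(positions)) stop("positions required for a bare matrix")
    if (is.null(group)) group <- rep("all", nrow(g))
  }
  groups <- unique(group)
  per_locus <- vapply(groups, function(gr) {
    p <- colMeans(g[group == gr, , drop = FALSE], na.rm = TRUE) / 2
    1 - p^2 - (1 - p)^2
  }, numeric(ncol(g)))
  starts <- seq(floor(min(positions) / stride) * stride, max(positions),
                by = stride)
  win <- data.frame(start = starts, end = starts + window)
  win <- win[vapply(seq_len(nrow(win)), function(i)
    any(positions >= win$start[i] & positions < win$end[i]), logical(1)), ]
  H <- vapply(groups, function(gr) {
    vapply(seq_len(nrow(win)), function(i) {
      j <- positions >= win$start[i] & positions < win$end[i]
      mean(per_locus[j, gr])
    }, numeric(1))
  }, numeric(nrow(win)))
  colnames(H) <- groups
  windows <- cbind(win, H)
  rownames(windows) <- NULL
  runs <- data.frame(start = numeric(0), end = numeric(0), n_windows = integer(0))
  if (all(c("R1R1", "rr") %in% groups)) {
    flag <- windows$R1R1 == 0 & windows$rr > 0
    r <- rle(flag)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1
    hit <- which(r$values)
    runs <- data.frame(start = windows$start[idx_start[hit]],
                       end = windows$end[idx_end[hit]],
                       n_windows = r$lengths[hit])
  }
  structure(list(windows = windows, per_locus = per_locus, runs = runs,
                 window = window, stride = stride),
            class = "het_profile")
}

#' @export
print.het_profile <- function(x, ...) {
  cat(sprintf("<het_profile> %d window(s) of %g bp (stride %g)\n",
              nrow(x$windows), x$window, x$stride))
  if (nrow(x$runs)) {
    cat("candidate homozygous sweep(s) in cases:\n")
    print.data.frame(x$runs, row.names = FALSE)
  }
  invisible(x)
}

#' Two-point LOD score from backcross recombinant counts
#'
#' Phase-known backcross likelihood: with `r` recombinants among `n`
#' informative meioses, `theta_hat = r / n` and
#' `LOD = n * (theta_hat * log10(theta_hat) + (1 - theta_hat) *
#' log10(1 - theta_hat) + log10(2))`, with `0 * log10(0)` defined as 0.
#' Fully linked markers give `LOD = n * log10(2)`.
#'
#' @param r recombinant count.
#' @param n informative meioses (> 0; `n = 0` is reported as no-data).
#' @return list of class `linkage_result`: `r`, `n`, `theta`, `lod`.
#' @export
lod_from_counts <- function(r, n) {
  if (n == 0) {
    return(structure(list(r = r, n = n, theta = NA_real_, lod = NA_real_,
                          status = "no_data"), class = "linkage_result"))
  }
  stopifnot(r >= 0, r <= n)
  th <- r / n
  xlx <- function(x) ifelse(x > 0, x * log10(x), 0)
  lod <- n * (xlx(th) + xlx(1 - th) + log10(2))
  structure(list(r = r, n = n, theta = th, lod = max(lod, 0),
                 status = "ok"), class = "linkage_result")
}

#' @export
print.linkage_result <- function(x, ...) {
  cat(sprintf("<linkage_result> r=%s n=%s theta=%.3f LOD=%.1f\n",
              x$r, x$n, x$theta, x$lod))
  invisible(x)
}

#' Two-point linkage between each marker and the trait locus in a backcross
#'
#' Counts recombinants between the sire-gamete marker allele and the
#' sire-gamete trait allele over informative carrier-sire meioses (dams are
#' `rr`, uninformative), excluding missing marker genotypes so `n` varies by
#' marker, and evaluates the phase-known LOD.
#'
#' @param ped `pedigree_genotypes` from [simulate_pedigree()].
#' @param markers marker names (defaults to all marker columns).
#' @return `data.frame` of class `linkage_table`: `marker`, `position`, `r`,
#'   `n`, `theta`, `lod`.
#' @export
two_point_lod <- function(ped, markers = NULL) {
  design <- attr(ped, "design")
  if (is.null(markers)) markers <- names(design$marker_pos)
  rows <- lapply(markers, function(m) {
    ok <- !is.na(ped[[m]])
    r <- sum(ped[[m]][ok] != ped$trait[ok])
    res <- lod_from_counts(r, sum(ok))
    data.frame(marker = m, position = design$marker_pos[[m]],
               r = res$r, n = res$n, theta = res$theta, lod = res$lod)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("linkage_table", class(out))
  out
}

#' Deterministic Rose-comb sperm-competition breeding equilibrium
#'
#' Discrete non-overlapping generations of a closed Rose-comb flock:
#' single-combed (`rr`) offspring are culled from both parental sexes when
#' `cull_rr = TRUE`; homozygous Rose-comb sires contribute in proportion to
#' `rr_sire_fertility` (default 0: fully outcompeted by sperm competition
#' under flock mating); dams contribute at phenotype-culled Hardy-Weinberg
#' proportions; mating is otherwise random. Writing `q` for the wild-type
#' allele frequency among offspring, the default recursion is
#' `q' = (1/2 + q / (1 + q)) / 2`, whose fixed point is
#' `q* = (sqrt(17) - 1) / 8`; the equilibrium fraction of single-combed
#' offspring is `q*/2 * ...` evaluated as sire-gamete frequency times
#' dam-gamete frequency.
#'
#' @param rr_sire_fertility relative competitive fertility of `RR` sires in
#'   `[0, 1]`.
#' @param cull_rr cull single-combed breeders of both sexes.
#' @param q0 starting wild-type allele frequency in `(0, 1)`.
#' @param hardy_weinberg_offspring collapse each offspring generation to
#'   Hardy-Weinberg proportions at its mean allele frequency before selecting
#'   breeders (the default recursion above). With `FALSE` the recursion
#'   tracks the exact offspring genotype frequencies (sire and dam gamete
#'   pools differ, so offspring are not Hardy-Weinberg); this is the
#'   infinite-population limit of [simulate_flock()] and settles slightly
#'   higher, at about 14.6% single-combed offspring.
#' @param tol convergence tolerance on `q`.
#' @param max_generations generation cap; non-convergence is flagged.
#' @return list of class `comb_equilibrium`: `q_star` (offspring r-allele
#'   frequency), `rr_fraction` (equilibrium single-comb offspring fraction),
#'   `trajectory` (per-generation `q` and `rr`), `converged`, `generations`.
#' @export
rose_comb_equilibrium <- function(rr_sire_fertility = 0, cull_rr = TRUE,
                                  q0 = 0.5, hardy_weinberg_offspring = TRUE,
                                  tol = 1e-10, max_generations = 10000L) {
  stopifnot(rr_sire_fertility >= 0, rr_sire_fertility <= 1, q0 > 0, q0 < 1)
  gametes <- function(geno) {
    x <- geno[1]; y <- geno[2]; z <- geno[3]
    keep_rr <- if (cull_rr) 0 else z
    dam_q <- (y / 2 + keep_rr) / (x + y + keep_rr)
    sire_RR <- x * rr_sire_fertility
    sire_q <- (y / 2 + keep_rr) / (sire_RR + y + keep_rr)
    c(sire = sire_q, dam = dam_q)
  }
  hw <- function(q) c((1 - q)^2, 2 * q * (1 - q), q^2)
  geno <- hw(q0)
  q <- q0
  traj <- list()
  converged <- FALSE
  for (gen in seq_len(max_generations)) {
    gm <- gametes(geno)
    q_next <- mean(gm)
    geno <- if (hardy_weinberg_offspring) hw(q_next)
            else c((1 - gm[["sire"]]) * (1 - gm[["dam"]]),
                   gm[["sire"]] + gm[["dam"]] - 2 * gm[["sire"]] * gm[["dam"]],
                   gm[["sire"]] * gm[["dam"]])
    traj[[gen]] <- data.frame(generation = gen, q = q_next,
                              rr = unname(gm["sire"] * gm["dam"]))
    if (abs(q_next - q) < tol) {
      q <- q_next
      converged <- TRUE
      break
    }
    q <- q_next
  }
  if (!converged) warning("equilibrium recursion did not converge")
  gm <- gametes(geno)
  structure(list(q_star = q, rr_fraction = unname(gm["sire"] * gm["dam"]),
                 sire_gamete_q = unname(gm["sire"]),
                 dam_gamete_q = unname(gm["dam"]),
                 trajectory = do.call(rbind, traj),
                 converged = converged, generations = length(traj)),
            class = "comb_equilibrium")
}

#' @export
print.comb_equilibrium <- function(x, ...) {
  cat(sprintf(paste0("<comb_equilibrium> q* = %.5f after %d generation(s); ",
                     "single-comb offspring fraction %.4f (%.1f%%)\n"),
              x$q_star, x$generations, x$rr_fraction, 100 * x$rr_fraction))
  invisible(x)
}

#' Monte-Carlo flock under the sperm-competition breeding scheme
#'
#' Finite-flock counterpart of [rose_comb_equilibrium()]: each generation
#' draws `n` offspring genotypes from the sire and dam gamete pools implied
#' by the previous generation's genotype counts (culling `rr` breeders,
#' excluding `RR` sires in proportion to `1 - rr_sire_fertility`).
#'
#' @param n flock size per generation.
#' @param generations number of generations.
#' @param rr_sire_fertility,cull_rr as in [rose_comb_equilibrium()].
#' @param q0 founder allele frequency.
#' @param seed integer seed.
#' @return `data.frame`: per generation, genotype counts and the realized
#'   single-comb offspring fraction `rr_frac`.
#' @export
simulate_flock <- function(n = 10000L, generations = 200L,
                           rr_sire_fertility = 0, cull_rr = TRUE, q0 = 0.5,
                           seed = 1L) {
  set.seed(seed)
  counts <- stats::rmultinom(1, n, c(RR = (1 - q0)^2, Rr = 2 * q0 * (1 - q0),
                                     rr = q0^2))[, 1]
  out <- vector("list", generations)
  for (gen in seq_len(generations)) {
    nRR <- counts["RR"]; nRr <- counts["Rr"]; nrr <- counts["rr"]
    dam_rr <- if (cull_rr) 0 else nrr
    sire_rr <- if (cull_rr) 0 else nrr
    sire_RR <- nRR * rr_sire_fertility
    dam_q <- (nRr / 2 + dam_rr) / (nRR + nRr + dam_rr)
    sire_q <- (nRr / 2 + sire_rr) / (sire_RR + nRr + sire_rr)
    g_sire <- stats::rbinom(n, 1, sire_q)   # 1 = r gamete
    g_dam <- stats::rbinom(n, 1, dam_q)
    geno <- g_sire + g_dam                  # r-allele dosage
    counts <- c(RR = sum(geno == 0), Rr = sum(geno == 1), rr = sum(geno == 2))
    out[[gen]] <- data.frame(generation = gen, RR = counts["RR"],
                             Rr = counts["Rr"], rr = counts["rr"],
                             rr_frac = counts["rr"] / n)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
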