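#' Run configuration for the end-to-end demo
#'
#' Collects and validates every stage's parameters. All component
#' constructors are invoked here so an invalid configuration fails before
#' any stage runs.
#'
#' @param seed global seed.
#' @param scale_div coordinate scale divisor (see [rosecomb_coords()]).
#' @param ref_length,gc reference forge parameters.
#' @param pool chromosome counts, as [pool_spec()] input.
#' @param mu,sigma,read_len insert model parameters.
#' @param coverage read-base coverage.
#' @param window,min_frac,cluster_radius,min_pairs,sd_mult caller thresholds.
#' @param cohort_n genotyping cohort size.
#' @param out_dir output directory (`NULL`: no files written).
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, scale_div = 100, ref_length = 300000L,
                       gc = 0.42, pool = c(R1 = 4, R2 = 9, r = 3),
                       mu = 3900, sigma = 390, read_len = 50, coverage = 1,
                       window = 1500, min_frac = 0.25, cluster_radius = 1000,
                       min_pairs = 4L, sd_mult = 10, cohort_n = 200L,
                       out_dir = NULL) {
  if (coverage <= 0) stop("coverage must be positive")
  cfg <- list(seed = as.integer(seed), scale_div = scale_div,
              ref_length = ref_length, gc = gc, pool = do.call(pool_spec, as.list(pool)),
              model = insert_size_model(mu, sigma, read_len),
              coverage = coverage, window = window, min_frac = min_frac,
              cluster_radius = cluster_radius, min_pairs = min_pairs,
              sd_mult = sd_mult, cohort_n = as.integer(cohort_n),
              coords = rosecomb_coords(scale_div = scale_div,
                                       ref_length = ref_length),
              out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' The YAML file holds any subset of [run_config()]'s arguments (`pool` as a
#' named mapping). Unspecified fields keep their defaults.
#'
#' @param path YAML path.
#' @param seed optional seed override.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(seed)) y$seed <- seed
  if (!is.null(y$pool)) y$pool <- unlist(y$pool)
  do.call(run_config, y)
}

#' Run the end-to-end Rose-comb demo
#'
#' Executes the full chain on synthetic data: forge a toy reference, build
#' the r/R1/R2 alleles, simulate mate-pair sequencing of the configured
#' pool, estimate the insert model and call structural variants, refine
#' breakpoints and score junction microhomology, genotype a simulated cohort
#' through the five-band assay, annotate the toy gene models against R1,
#' run the heterozygosity scan and two-point linkage on simulated panels,
#' and iterate the breeding equilibrium. Deterministic for a fixed seed.
#'
#' @param config a [run_config()].
#' @return list of class `rosecomb_demo` with per-stage results and a
#'   `checks` data frame of internal truth comparisons.
#' @export
run_demo <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  coords <- config$coords
  t0 <- proc.time()[["elapsed"]]
  stage <- function(what, expr) {
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", what, conditionMessage(e)), call. = FALSE))
    res
  }
  ref <- stage("forge", forge_reference(config$ref_length, config$gc,
                                        seed = seed))
  alleles <- stage("alleles", rosecomb_alleles(ref, coords))
  records <- stage("matepairs",
                   simulate_matepairs(config$pool, alleles, config$model,
                                      coverage = config$coverage,
                                      seed = seed + 1L))
  model_hat <- stage("insert_model", estimate_insert_model(records))
  calls <- stage("sv_calls",
                 call_sv_windows(records, model_hat, window = config$window,
                                 min_frac = config$min_frac,
                                 cluster_radius = config$cluster_radius,
                                 min_pairs = config$min_pairs,
                                 sd_mult = config$sd_mult))
  refined <- stage("refine", {
    sets <- attr(calls, "pair_sets")
    lapply(seq_len(nrow(calls)), function(i) {
      if (length(sets[[i]]) < 3) return(NULL)
      refine_breakpoints(calls[i, ], records, model_hat, sets[[i]])
    })
  })
  micro <- stage("microhomology", {
    list(R1 = allele_microhomology(alleles$R1, ref),
         R2 = allele_microhomology(alleles$R2, ref))
  })
  assay <- stage("assay", rosecomb_assay(coords))
  cohort <- stage("cohort", simulate_cohort(config$cohort_n, assay,
                                            seed = seed + 2L))
  genes <- stage("gene_models", toy_gene_models(coords))
  effects <- stage("annotation", predict_gene_effects(alleles$R1, genes))
  panel <- stage("snp_panel", simulate_snp_panel(seed = seed + 3L))
  het <- stage("het_scan", het_scan(panel))
  ped <- stage("pedigree", simulate_pedigree(seed = seed + 4L))
  linkage <- stage("linkage", two_point_lod(ped))
  eq <- stage("equilibrium", rose_comb_equilibrium())
  truth_sizes <- c(coords$b - coords$a, coords$d - coords$c)
  inv_calls <- calls[calls$type == "inversion", ]
  checks <- data.frame(
    check = c("inversion_loci_called", "size_within_one_window",
              "cohort_concordance", "sweep_detected", "linked_marker_lod"),
    value = c(nrow(inv_calls),
              as.numeric(nrow(inv_calls) > 0 &&
                           all(vapply(inv_calls$size, function(s)
                             min(abs(s - truth_sizes)) <= config$window,
                             logical(1)))),
              mean(cohort$concordant),
              as.numeric(nrow(het$runs) > 0),
              max(linkage$lod)))
  out <- structure(list(config = config, reference = ref, alleles = alleles,
                        records_n = nrow(records), insert_model = model_hat,
                        calls = calls, refined = refined, micro = micro,
                        assay = assay, cohort = cohort, effects = effects,
                        het = het, linkage = linkage, equilibrium = eq,
                        checks = checks,
                        elapsed = proc.time()[["elapsed"]] - t0),
                   class = "rosecomb_demo")
  if (!is.null(config$out_dir)) write_demo_outputs(out, records)
  out
}

write_demo_outputs <- function(demo, records) {
  dir.create(demo$config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(demo$config$out_dir, f)
  write_fasta(demo$reference, p("reference.fa"))
  for (al in demo$alleles) segments_to_bed(al, p(sprintf("allele_%s.bed", al$name)))
  write_sam(records, p("pool.sam"))
  write_sv_calls(demo$calls, p("sv_calls.bedpe.tsv"), demo$reference$name)
  write_genotype_calls(demo$cohort, p("cohort_genotypes.tsv"))
  utils::write.table(demo$linkage, p("linkage_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(demo$het$windows, p("het_windows.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(q_star = demo$equilibrium$q_star,
                            rr_fraction = demo$equilibrium$rr_fraction,
                            trajectory = demo$equilibrium$trajectory),
                       p("equilibrium.json"), auto_unbox = TRUE, digits = NA)
  invisible(demo$config$out_dir)
}

#' @export
print.rosecomb_demo <- function(x, ...) {
  cat(sprintf("<rosecomb_demo> seed %d, 1/%g scale, %s pairs, %.1fs\n",
              x$config$seed, x$config$scale_div,
              format(x$records_n, big.mark = ","), x$elapsed))
  cat(sprintf("  insert model: mu=%.0f sd=%.0f\n", x$insert_model$mu,
              x$insert_model$sigma))
  cat(sprintf("  SV calls: %d (%s)\n", nrow(x$calls),
              paste(x$calls$type, collapse = ", ")))
  cat(sprintf("  cohort genotyping concordance: %.3f over %d birds\n",
              mean(x$cohort$concordant), nrow(x$cohort)))
  cat(sprintf("  het-scan sweep windows: %s\n",
              if (nrow(x$het$runs)) sprintf("%d-%d", x$het$runs$start[1],
                                            x$het$runs$end[1]) else "none"))
  cat(sprintf("  max linkage LOD: %.1f\n", max(x$linkage$lod)))
  cat(sprintf("  equilibrium single-comb fraction: %.4f\n",
              x$equilibrium$rr_fraction))
  cat("checks:\n")
  print.data.frame(x$checks, row.names = FALSE)
  invisible(x)
}
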