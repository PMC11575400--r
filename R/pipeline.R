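#' Built-in demonstration scenario configuration
#'
#' Parameter set used by [run_full_demo()] and shipped as the package's
#' worked example. It encodes a benzyl-alcohol -> benzoate commensal chain:
#' a cross-feeder ("Aj") consumes benzyl alcohol and leaks benzoate, which
#' feeds the focal consumer genotypes. The monoculture scenario gives the
#' consumer a small residual-carbon benzoate pulse (one order of magnitude
#' below the co-culture supply) and injects a high-yield mutant on day 6;
#' the co-culture scenario maintains two consumer morphotypes on partially
#' private resource pools (a deliberate phenomenological stand-in for the
#' unresolved coexistence mechanism — see the vignette). Kinetic constants
#' for the cross-feeder and the pool sizes are modelling choices, not
#' measured values.
#'
#' @return A nested list of scenario parameters.
#' @export
default_demo_config <- function() {
  list(
    od_to_cfu = 5e8,
    detection_limit = 1e2,
    days = 30,
    plating_noise_cv = 0.05,
    clone_sample_size = 60,
    clone_trait_sd = 0.002,
    ancestor = list(Y = 0.020, V = 20, K = 0.06),
    mutant = list(Y = 0.068, V = 20, K = 0.06),   # 3.4x yield
    small = list(Y = 0.023, V = 10, K = 0.06),
    crossfeeder = list(Y = 0.040, V = 8, K = 0.05, leak_fraction = 1.0),
    mono = list(benzoate0 = 0.12,      # residual-carbon pulse, 5x below co-culture
                inject_day = 6, inject_fraction = 1e-3,
                P0 = 2.4e-5),
    co = list(benzyl_alcohol0 = 0.6, private0 = 3.2,
              # private-niche capacity sets the morphotype ratio; 3.2 mM
              # substrate-equivalents puts the end point near 64:36
              # small:large, the composition with the large morphotype in
              # the minority
              A0 = 2.4e-4, large0 = 4e-4, small0 = 7e-6))
}

demo_genotypes <- function(cfg) {
  list(
    anc = genotype("ancestor", Y = cfg$ancestor$Y, V = cfg$ancestor$V,
                   K = cfg$ancestor$K, resource = "benzoate"),
    mut = genotype("high_yield_mutant", Y = cfg$mutant$Y, V = cfg$mutant$V,
                   K = cfg$mutant$K, resource = "benzoate"),
    large = genotype("large", Y = cfg$mutant$Y, V = cfg$mutant$V,
                     K = cfg$mutant$K, resource = "benzoate"),
    small = genotype("small", Y = cfg$small$Y, V = cfg$small$V,
                     K = cfg$small$K, resource = "residual"),
    aj = genotype("Aj", Y = cfg$crossfeeder$Y, V = cfg$crossfeeder$V,
                  K = cfg$crossfeeder$K, resource = "benzyl_alcohol",
                  produces = "benzoate",
                  leak_fraction = cfg$crossfeeder$leak_fraction))
}

#' Run the monoculture / co-culture serial-transfer scenarios
#'
#' Simulates the two demonstration scenarios under a given seed and
#' returns their transfer series.
#'
#' @param config Scenario configuration (default [default_demo_config()]).
#' @param seed Integer seed for observation noise.
#' @return List with `mono` and `co` transfer-series tibbles and the
#'   protocol used.
#' @export
run_demo_scenarios <- function(config = default_demo_config(), seed = 1) {
  g <- demo_genotypes(config)
  proto <- transfer_protocol(days = config$days,
                             detection_limit = config$detection_limit,
                             od_to_cfu = config$od_to_cfu)
  mono_state <- community_state(
    c(benzoate = config$mono$benzoate0),
    c(ancestor = config$mono$P0))
  mono <- run_serial_transfers(
    mono_state, list(g$anc), proto,
    injections = list(list(day = config$mono$inject_day,
                           parent = "ancestor", mutant = g$mut,
                           fraction = config$mono$inject_fraction)),
    plating_noise_cv = config$plating_noise_cv, seed = seed)
  co_state <- community_state(
    c(benzyl_alcohol = config$co$benzyl_alcohol0, benzoate = 0,
      residual = config$co$private0),
    c(Aj = config$co$A0, large = config$co$large0, small = config$co$small0))
  co <- run_serial_transfers(
    co_state, list(g$aj, g$large, g$small), proto,
    plating_noise_cv = config$plating_noise_cv, seed = seed + 1)
  list(mono = mono, co = co, protocol = proto)
}

sample_clone_yields <- function(series, genotype_Y, day, n, sd, exclude = NULL) {
  final <- series[series$day == day & !(series$label %in% exclude), ]
  final <- final[final$label %in% names(genotype_Y), ]
  probs <- final$cfu_per_ml / sum(final$cfu_per_ml)
  picked <- sample(final$label, n, replace = TRUE, prob = probs)
  stats::rnorm(n, mean = unlist(genotype_Y)[picked], sd = sd)
}

#' One-shot end-to-end demonstration
#'
#' Runs the full pipeline on synthetic data: serial-transfer simulation of
#' the monoculture and co-culture scenarios, trait estimation on simulated
#' noisy plate curves, mutation-table generation and the gene-parallelism
#' test, competition assays and invasion analysis, and the dip test on
#' end-point clone yields. Checks the three qualitative outcomes the
#' scenarios encode: (i) the injected high-yield mutant is classified
#' `fixed` in monoculture, (ii) both co-culture morphotypes stay above the
#' detection limit through the final day, and (iii) end-point clone yields
#' are bimodal in co-culture but not in monoculture.
#'
#' @param seed Integer seed controlling all randomness.
#' @param config Scenario configuration.
#' @param out_dir Optional directory; when given, transfer series, plates,
#'   mutation tables, assays, a JSON report and a run manifest are written
#'   there.
#' @param n_boot Bootstrap draws for the dip tests.
#' @return A list of class `xf_demo_report` with the intermediate results
#'   and an `assertions` tibble.
#' @export
run_full_demo <- function(seed = 1, config = default_demo_config(),
                          out_dir = NULL, n_boot = 2000) {
  set.seed(seed)
  g <- demo_genotypes(config)
  sc <- run_demo_scenarios(config, seed = seed)

  ## (i) monoculture sweep
  final_mono <- sc$mono[sc$mono$day == config$days, ]
  mut_freq <- final_mono$cfu_per_ml[final_mono$label == "high_yield_mutant"] /
    sum(final_mono$cfu_per_ml)
  sweep_tbl <- classify_sweeps(tibble::tibble(frequency = mut_freq))
  mutant_fixed <- sweep_tbl$sweep_class[1] == "fixed"

  ## (ii) co-culture persistence of both morphotypes
  morphs <- sc$co[sc$co$label %in% c("large", "small"), ]
  both_persist <- all(!morphs$censored)

  ## (iii) clone-yield bimodality
  yields <- list(anc = config$ancestor$Y, high_yield_mutant = config$mutant$Y,
                 ancestor = config$ancestor$Y,
                 large = config$mutant$Y, small = config$small$Y)
  co_clones <- sample_clone_yields(sc$co, yields, config$days,
                                   config$clone_sample_size,
                                   config$clone_trait_sd, exclude = "Aj")
  mono_clones <- sample_clone_yields(sc$mono, yields, config$days,
                                     config$clone_sample_size,
                                     config$clone_trait_sd)
  dip_co <- test_multimodality(co_clones, n_boot = n_boot)
  dip_mono <- test_multimodality(mono_clones, n_boot = n_boot)

  ## traits from simulated noisy plate curves (3 technical replicates each)
  t_grid <- seq(0, 24, by = 1 / 6)
  plate_curves <- function(geno, R0) {
    cv <- simulate_batch_growth(geno, R0 = R0, P0 = 0.005, t_grid = t_grid)
    purrr::map(1:3, function(i) add_od_noise(cv, cv = 0.02))
  }
  anc_cv <- plate_curves(g$anc, 0.6)
  mut_cv <- plate_curves(g$mut, 0.6)
  anc_traits <- estimate_traits(anc_cv[[1]], R0 = 0.6,
                                technical_replicates = anc_cv[-1])
  mut_traits <- estimate_traits(mut_cv[[1]], R0 = 0.6,
                                technical_replicates = mut_cv[-1])
  yield_fold <- mut_traits$Y / anc_traits$Y

  ## mutation tables and parallelism
  catalog <- tibble::tibble(
    gene = c("fleQ", "flgH", "gacS", "uvrY", "oplA", "tatB", "kauB", "cmoB"),
    length = c(1476, 699, 2754, 657, 3663, 774, 1479, 972))
  muts_mono <- generate_mutation_table(
    10, catalog, genome_size = 6181863,
    enriched_gene = list(gene = "fleQ", extra_hits = 2),
    line_id = "mono_sim", condition = "monoculture")
  muts_co <- generate_mutation_table(
    10, catalog, genome_size = 6181863,
    enriched_gene = list(gene = "fleQ", extra_hits = 2),
    line_id = "co_sim", condition = "co-culture")
  par_tbl <- gene_parallelism(list(muts_mono, muts_co), min_freq = 0)

  ## invasion analysis on simulated assays (equal-fitness morphotype pair
  ## on a shared pool: the null design)
  small_shared <- genotype("small_shared", Y = config$small$Y,
                           V = config$small$V, K = config$small$K,
                           resource = "benzoate")
  assays <- dplyr::bind_rows(
    generate_competition_assay(g$large, small_shared, noise_cv = 0.05,
                               condition = "co-culture"),
    generate_competition_assay(g$large, small_shared, noise_cv = 0.05,
                               condition = "monoculture"))
  inv <- invasion_analysis(assays)

  assertions <- tibble::tibble(
    check = c("monoculture mutant fixed",
              "co-culture morphotypes persist",
              "co-culture clone yields bimodal (p < 0.01)",
              "monoculture clone yields unimodal (p > 0.05)"),
    passed = c(mutant_fixed, both_persist,
               dip_co$p_value < 0.01, dip_mono$p_value > 0.05))

  report <- structure(
    list(series = sc, mutant_final_freq = mut_freq,
         dip_co = dip_co, dip_mono = dip_mono,
         anc_traits = anc_traits, mut_traits = mut_traits,
         yield_fold_change = yield_fold,
         parallelism = par_tbl, invasion = inv,
         mutation_tables = list(mono = muts_mono, co = muts_co),
         assays = assays, assertions = assertions, seed = seed),
    class = "xf_demo_report")

  if (!is.null(out_dir)) write_demo_outputs(report, config, out_dir)
  report
}

#' @export
print.xf_demo_report <- function(x, ...) {
  cat("<xf_demo_report> seed", x$seed, "\n")
  cat(sprintf("  mutant final frequency (monoculture): %.4f\n",
              x$mutant_final_freq))
  cat(sprintf("  dip p: co-culture %.4g, monoculture %.4g\n",
              x$dip_co$p_value, x$dip_mono$p_value))
  cat(sprintf("  estimated yield fold-change: %.2f\n", x$yield_fold_change))
  print(x$assertions)
  invisible(x)
}

write_demo_outputs <- function(report, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_transfer_tsv(report$series$mono, file.path(out_dir, "mono_series.tsv"))
  write_transfer_tsv(report$series$co, file.path(out_dir, "co_series.tsv"))
  write_mutation_tsv(report$mutation_tables$mono,
                     file.path(out_dir, "mutations_mono.tsv"))
  write_mutation_tsv(report$mutation_tables$co,
                     file.path(out_dir, "mutations_co.tsv"))
  readr::write_tsv(report$assays, file.path(out_dir, "assays.tsv"))
  jsonlite::write_json(
    list(seed = report$seed,
         mutant_final_freq = report$mutant_final_freq,
         dip_co_p = report$dip_co$p_value,
         dip_mono_p = report$dip_mono$p_value,
         yield_fold_change = report$yield_fold_change,
         assertions = report$assertions),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  write_manifest(file.path(out_dir, "manifest.json"),
                 command = "run_full_demo", config = config,
                 seed = report$seed,
                 outputs = c("mono_series.tsv", "co_series.tsv",
                             "mutations_mono.tsv", "mutations_co.tsv",
                             "assays.tsv", "report.json"))
  invisible(out_dir)
}

#' Write a reproducibility manifest
#'
#' Records the command, a hash of the configuration, the seed, package
#' version and output paths. Identical (config, seed) give identical
#' hashes and, since all randomness is seeded, identical outputs.
#'
#' @param path Output JSON path.
#' @param command Name of the command or function run.
#' @param config Configuration list.
#' @param seed Integer seed.
#' @param outputs Character vector of output paths.
#' @export
write_manifest <- function(path, command, config, seed, outputs) {
  jsonlite::write_json(
    list(command = command, config_hash = rlang::hash(config), seed = seed,
         parameters = config, outputs = outputs,
         package_version = as.character(utils::packageVersion("crossfeedr")),
         timestamp = format(Sys.time(), tz = "UTC")),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a scenario configuration from YAML
#'
#' @param path YAML file mirroring the structure of
#'   [default_demo_config()]; missing entries fall back to the defaults.
#' @return A configuration list.
#' @export
read_scenario <- function(path) {
  user <- yaml::read_yaml(path)
  utils::modifyList(default_demo_config(), user)
}
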