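#' Generate a synthetic mutation table under a uniform-per-bp null
#'
#' Places `n_mutations` point positions uniformly over the genome, assigns
#' each to the gene whose interval covers it (or "intergenic"), draws an
#' effect class and a population frequency, and optionally spikes one gene
#' with extra hits to emulate gene-level parallelism. Under no enrichment
#' the per-gene hit counts follow the binomial/Poisson null the parallelism
#' test assumes.
#'
#' @param n_mutations Number of background mutations placed uniformly.
#' @param gene_catalog Data frame with columns `gene` and `length` (bp);
#'   genes are laid out contiguously from position 1.
#' @param genome_size Genome size in bp; must be at least the summed gene
#'   lengths.
#' @param enriched_gene Optional `list(gene =, extra_hits =)`: that many
#'   additional mutations are placed uniformly within the named gene.
#' @param freq_distribution Function `n -> n frequencies in [0, 1]`
#'   (default: uniform on 0.05..1).
#' @param p_effect Named probabilities for the effect class of genic SNPs
#'   (default 80% nonsynonymous / 10% synonymous / 5% frameshift /
#'   5% nonsense, echoing the strong excess of amino-acid-changing hits in
#'   evolved lines).
#' @param line_id,condition Metadata stamped on every record.
#' @param seed Integer seed; same seed, same table.
#' @return A mutation table tibble (see [read_mutation_tsv()] for columns).
#' @export
generate_mutation_table <- function(n_mutations, gene_catalog, genome_size,
                                    enriched_gene = NULL,
                                    freq_distribution = NULL,
                                    p_effect = c(nonsynonymous = 0.8,
                                                 synonymous = 0.1,
                                                 frameshift = 0.05,
                                                 nonsense = 0.05),
                                    line_id = "sim", condition = "monoculture",
                                    seed = NULL) {
  stopifnot(n_mutations >= 0, is.data.frame(gene_catalog),
            all(c("gene", "length") %in% names(gene_catalog)))
  if (genome_size <= 0) stop("genome_size must be > 0", call. = FALSE)
  if (sum(gene_catalog$length) > genome_size) {
    stop("summed gene lengths exceed genome_size", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(freq_distribution)) {
    freq_distribution <- function(n) stats::runif(n, 0.05, 1)
  }
  gene_end <- cumsum(gene_catalog$length)
  gene_start <- c(1, utils::head(gene_end, -1) + 1)

  n_extra <- if (is.null(enriched_gene)) 0L else as.integer(enriched_gene$extra_hits)
  pos <- if (n_mutations > 0) sample.int(genome_size, n_mutations, replace = TRUE) else integer(0)
  if (n_extra > 0L) {
    gi <- match(enriched_gene$gene, gene_catalog$gene)
    if (is.na(gi)) stop("enriched_gene not in catalog", call. = FALSE)
    pos <- c(pos, gene_start[gi] +
               sample.int(gene_catalog$length[gi], n_extra, replace = TRUE) - 1L)
  }
  n_tot <- length(pos)
  if (n_tot == 0L) {
    return(empty_mutation_table(line_id, condition, genome_size))
  }
  gidx <- findInterval(pos, gene_start)
  genic <- gidx >= 1 & pos <= gene_end[pmax(gidx, 1)]
  gene <- ifelse(genic, gene_catalog$gene[pmax(gidx, 1)], "intergenic")
  gene_length <- ifelse(genic, gene_catalog$length[pmax(gidx, 1)], NA_real_)
  effect <- ifelse(genic,
                   sample(names(p_effect), n_tot, replace = TRUE, prob = p_effect),
                   "intergenic")
  mtype <- ifelse(effect == "frameshift",
                  sample(c("INS", "DEL"), n_tot, replace = TRUE), "SNP")
  size <- ifelse(mtype == "SNP", 1L, sample(1:30, n_tot, replace = TRUE))
  tbl <- tibble::tibble(
    line_id = line_id, condition = condition,
    position = as.integer(pos), mtype = mtype, size = as.integer(size),
    gene = gene, gene_length = gene_length, effect = effect,
    frequency = freq_distribution(n_tot), censored = FALSE,
    genome_size = genome_size)
  validate_mutation_table(tbl)
}

empty_mutation_table <- function(line_id = character(0),
                                 condition = character(0),
                                 genome_size = numeric(0)) {
  tibble::tibble(line_id = character(0), condition = character(0),
                 position = integer(0), mtype = character(0),
                 size = integer(0), gene = character(0),
                 gene_length = numeric(0), effect = character(0),
                 frequency = numeric(0), censored = logical(0),
                 genome_size = numeric(0))
}

#' Generate a reciprocal competition / invasion assay table
#'
#' Emulates the paired-genotype invasion design: for each starting frequency
#' and replicate, the two genotypes grow together for one 24-h cycle on a
#' shared resource pool (deterministic Monod co-growth), and initial/final
#' densities are recorded as CFU/mL with multiplicative lognormal count
#' noise. The default frequency panel `{0.05, 0.1, 0.5, 0.9, 0.95}` with
#' three replicates reproduces the pooled 15-rows-per-condition design
#' (d.f. 28 in a two-condition comparison).
#'
#' @param traits_i,traits_j [genotype()] objects for the two competitors;
#'   both must consume the same resource pool.
#' @param initial_frequencies Frequencies of genotype i at inoculation.
#' @param n_replicates Technical replicates per frequency.
#' @param R0 Shared resource concentration at inoculation, mM.
#' @param total_od0 Total inoculation density, OD.
#' @param duration_h Cycle length in hours (recorded in days in the output).
#' @param noise_cv Lognormal CV applied independently to every recorded
#'   density (0 = noiseless).
#' @param condition Condition label stamped on the rows.
#' @param od_to_cfu OD to CFU/mL conversion.
#' @param seed Integer seed.
#' @return A tibble with the assay columns used by [invasion_analysis()]:
#'   `genotype_i`, `genotype_j`, `condition`, `initial_freq_i`, `replicate`,
#'   `N0_i`, `Nf_i`, `N0_j`, `Nf_j`, `duration_days`.
#' @export
generate_competition_assay <- function(traits_i, traits_j,
                                       initial_frequencies = c(0.05, 0.1, 0.5, 0.9, 0.95),
                                       n_replicates = 3, R0 = 0.6,
                                       total_od0 = 0.005, duration_h = 24,
                                       noise_cv = 0, condition = "co-culture",
                                       od_to_cfu = 5e8, seed = NULL) {
  stopifnot(inherits(traits_i, "xf_genotype"), inherits(traits_j, "xf_genotype"),
            all(initial_frequencies > 0 & initial_frequencies < 1),
            n_replicates >= 1)
  if (!identical(traits_i$resource, traits_j$resource)) {
    stop("competitors must share a resource pool", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  pool <- traits_i$resource
  grid <- expand.grid(initial_freq_i = initial_frequencies,
                      replicate = seq_len(n_replicates))
  rows <- purrr::pmap(grid, function(initial_freq_i, replicate) {
    d0 <- c(total_od0 * initial_freq_i, total_od0 * (1 - initial_freq_i))
    names(d0) <- c(traits_i$label, traits_j$label)
    st <- community_state(stats::setNames(R0, pool), d0)
    traj <- simulate_crossfeed_cycle(st, list(traits_i, traits_j),
                                     cycle_length_h = duration_h,
                                     dt_out = duration_h)
    endrow <- traj[nrow(traj), ]
    obs <- c(d0[[1]], endrow[[traits_i$label]], d0[[2]], endrow[[traits_j$label]]) * od_to_cfu
    if (noise_cv > 0) obs <- obs * exp(stats::rnorm(4, 0, noise_cv))
    tibble::tibble(genotype_i = traits_i$label, genotype_j = traits_j$label,
                   condition = condition, initial_freq_i = initial_freq_i,
                   replicate = as.integer(replicate),
                   N0_i = obs[1], Nf_i = obs[2], N0_j = obs[3], Nf_j = obs[4],
                   duration_days = duration_h / 24)
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$initial_freq_i, .data$replicate)
}
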