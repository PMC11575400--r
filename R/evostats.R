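#' Generations of regrowth per serial-transfer cycle
#'
#' A 1:D dilution followed by regrowth to the previous density corresponds
#' to `log2(D)` doublings, with
#' `D = (transfer_volume + culture_volume) / transfer_volume`. The standard
#' 100 uL into 9.9 mL daily regime gives `log2(100) = 6.64`, i.e. ~6.6
#' generations per day and ~200 generations over 30 days.
#'
#' @param transfer_volume_ml,culture_volume_ml Volumes in mL (> 0).
#' @param days Optional number of days; when given, the total generation
#'   count is also returned.
#' @return A one-row tibble: `dilution`, `generations_per_cycle` and (when
#'   `days` is given) `days` and `total_generations`.
#' @examples
#' generations_per_cycle(0.1, 9.9, days = 30)
#' @export
generations_per_cycle <- function(transfer_volume_ml, culture_volume_ml,
                                  days = NULL) {
  stopifnot(transfer_volume_ml > 0, culture_volume_ml > 0)
  D <- (transfer_volume_ml + culture_volume_ml) / transfer_volume_ml
  out <- tibble::tibble(dilution = D, generations_per_cycle = log2(D))
  if (!is.null(days)) {
    out$days <- days
    out$total_generations <- days * log2(D)
  }
  out
}

#' Malthusian parameter of one growth cycle
#'
#' `m = ln(Nf / N0)`: the realised growth of a (sub)population over a
#' cycle, from initial and final densities. Invariant to the density unit.
#'
#' @param N0,Nf Initial and final densities (same unit, both > 0).
#' @return `m` (dimensionless per cycle). Vectorised.
#' @examples
#' malthusian(1e5, 1e7)  # ln 100
#' @export
malthusian <- function(N0, Nf) {
  if (any(!is.finite(N0)) || any(!is.finite(Nf)) || any(N0 <= 0) || any(Nf <= 0)) {
    stop("densities must be finite and > 0", call. = FALSE)
  }
  log(Nf / N0)
}

#' Selection rate constant between two competitors
#'
#' `r_ij = (m_i - m_j) / duration`: the difference of Malthusian parameters
#' per unit time. Positive values mean genotype i outgrows genotype j;
#' swapping the arguments flips the sign exactly.
#'
#' @param m_i,m_j Malthusian parameters of the competitors.
#' @param duration_days Assay duration in days (> 0), default 1.
#' @return `r_ij` in 1/day. Vectorised.
#' @export
selection_rate <- function(m_i, m_j, duration_days = 1) {
  stopifnot(all(duration_days > 0))
  (m_i - m_j) / duration_days
}

#' Invasion analysis of reciprocal competition assays
#'
#' For every row, computes the two Malthusian parameters and the selection
#' rate constant `r_ij` of genotype i against j. Per (condition, starting
#' frequency) cell, tests `r` against zero with a one-sample two-tailed t
#' test (replicates as units). A genotype can invade from rare when its `r`
#' at the rare frequencies is significantly positive; a pair is judged to
#' stably coexist when both genotypes invade when rare. When two conditions
#' are present, the per-replicate `r` values are pooled across frequencies
#' and compared between conditions with a Welch two-tailed t test (the
#' 15-vs-15 design gives ~28 degrees of freedom).
#'
#' @param assays Assay tibble (see [generate_competition_assay()] /
#'   [read_assays_tsv()] for columns).
#' @param alpha Significance level for invasion verdicts (default 0.05).
#' @param rare_threshold Starting frequencies `<=` this count as "rare"
#'   (default 0.10).
#' @return A list of class `invasion_analysis`:
#'   * `rates`: per-row tibble with `m_i`, `m_j`, `r_ij`;
#'   * `by_cell`: per (condition, frequency) tibble with mean `r`, its
#'     standard error, `n`, `t`, `p_two_tailed` (NA when n < 2);
#'   * `verdicts`: per condition: can i invade from rare, can j invade
#'     from rare (i.e. r_ij significantly negative at the common
#'     frequencies), and the verdict
#'     (`"stable coexistence"`, `"i excludes j"`, `"j excludes i"`,
#'     `"indeterminate"`);
#'   * `pooled`: two-condition comparison of pooled `r` (NULL when fewer
#'     than two conditions).
#' @export
invasion_analysis <- function(assays, alpha = 0.05, rare_threshold = 0.10) {
  req <- c("genotype_i", "genotype_j", "condition", "initial_freq_i",
           "replicate", "N0_i", "Nf_i", "N0_j", "Nf_j", "duration_days")
  missing_cols <- setdiff(req, names(assays))
  if (length(missing_cols)) {
    stop("assay table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  rates <- dplyr::mutate(
    tibble::as_tibble(assays),
    m_i = malthusian(.data$N0_i, .data$Nf_i),
    m_j = malthusian(.data$N0_j, .data$Nf_j),
    r_ij = selection_rate(.data$m_i, .data$m_j, .data$duration_days))

  test_cell <- function(r) {
    n <- length(r)
    if (n < 2 || stats::sd(r) == 0) {
      tibble::tibble(r_mean = mean(r), se = if (n < 2) NA_real_ else 0,
                     n = n, t = NA_real_,
                     p_two_tailed = if (n >= 2 && all(r == 0)) 1 else NA_real_)
    } else {
      ht <- stats::t.test(r, mu = 0)
      tibble::tibble(r_mean = mean(r), se = stats::sd(r) / sqrt(n), n = n,
                     t = unname(ht$statistic), p_two_tailed = ht$p.value)
    }
  }
  by_cell <- rates |>
    dplyr::group_by(.data$condition, .data$initial_freq_i) |>
    dplyr::group_modify(~ test_cell(.x$r_ij)) |>
    dplyr::ungroup()

  verdict_one <- function(cells) {
    rare_i <- cells[cells$initial_freq_i <= rare_threshold, ]
    rare_j <- cells[cells$initial_freq_i >= 1 - rare_threshold, ]
    sig_pos <- function(df) nrow(df) > 0 && any(
      !is.na(df$p_two_tailed) & df$p_two_tailed < alpha & df$r_mean > 0)
    sig_neg <- function(df) nrow(df) > 0 && any(
      !is.na(df$p_two_tailed) & df$p_two_tailed < alpha & df$r_mean < 0)
    i_invades <- sig_pos(rare_i)
    j_invades <- sig_neg(rare_j)   # r_ij < 0 when i is common = j grows faster
    verdict <- if (i_invades && j_invades) "stable coexistence"
      else if (i_invades && !j_invades && sig_pos(rare_j)) "i excludes j"
      else if (j_invades && !i_invades && sig_neg(rare_i)) "j excludes i"
      else "indeterminate"
    # sig_pos(rare_j): i also wins when common; sig_neg(rare_i): j wins
    # even where i is rare - the clean competitive-exclusion patterns
    tibble::tibble(i_invades_from_rare = i_invades,
                   j_invades_from_rare = j_invades, verdict = verdict)
  }
  verdicts <- by_cell |>
    dplyr::group_by(.data$condition) |>
    dplyr::group_modify(~ verdict_one(.x)) |>
    dplyr::ungroup()

  pooled <- NULL
  conds <- unique(rates$condition)
  if (length(conds) == 2) {
    r1 <- rates$r_ij[rates$condition == conds[1]]
    r2 <- rates$r_ij[rates$condition == conds[2]]
    ht <- stats::t.test(r1, r2, var.equal = FALSE)
    pooled <- tibble::tibble(condition_a = conds[1], condition_b = conds[2],
                             mean_a = mean(r1), mean_b = mean(r2),
                             t = unname(ht$statistic),
                             df = unname(ht$parameter),
                             p_two_tailed = ht$p.value,
                             n_a = length(r1), n_b = length(r2))
  }
  structure(list(rates = rates, by_cell = by_cell, verdicts = verdicts,
                 pooled = pooled),
            class = "invasion_analysis")
}

#' @export
print.invasion_analysis <- function(x, ...) {
  cat("<invasion_analysis>\n")
  print(x$verdicts)
  if (!is.null(x$pooled)) {
    cat(sprintf("pooled %s vs %s: t = %.3f, d.f. = %.1f, p = %.3g\n",
                x$pooled$condition_a, x$pooled$condition_b, x$pooled$t,
                x$pooled$df, x$pooled$p_two_tailed))
  }
  invisible(x)
}

#' @export
tidy.invasion_analysis <- function(x, ...) x$by_cell

#' @export
glance.invasion_analysis <- function(x, ...) {
  out <- x$verdicts
  if (!is.null(x$pooled)) out$pooled_p <- x$pooled$p_two_tailed
  out
}

#' Filter a mutation table by population frequency
#'
#' Keeps records at or above `min_freq` (default 5%, the conventional
#' polymorphism reporting threshold). Idempotent.
#'
#' @param table Mutation table tibble.
#' @param min_freq Minimum frequency kept, in `[0, 1]`.
#' @return The filtered table.
#' @export
filter_mutations <- function(table, min_freq = 0.05) {
  stopifnot(min_freq >= 0, min_freq <= 1, "frequency" %in% names(table))
  table[table$frequency >= min_freq, , drop = FALSE]
}

#' Non-synonymous to synonymous ratio of point mutations
#'
#' `(#nonsynonymous + #nonsense) / #synonymous`, counted over SNP records
#' only, pooled across the supplied tables. A ratio well above 1 (8.7 in a
#' typical strongly adapting experiment) signals positive selection on
#' amino-acid-changing mutations.
#'
#' @param tables A mutation table or list of tables.
#' @return One-row tibble: `n_nonsynonymous` (incl. nonsense),
#'   `n_synonymous`, `ratio` (Inf flagged via `no_synonymous`).
#' @export
ns_ratio <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  tbl <- dplyr::bind_rows(tables)
  snps <- tbl[tbl$mtype == "SNP", , drop = FALSE]
  n_ns <- sum(snps$effect %in% c("nonsynonymous", "nonsense"))
  n_s <- sum(snps$effect == "synonymous")
  tibble::tibble(n_nonsynonymous = n_ns, n_synonymous = n_s,
                 ratio = if (n_s == 0) Inf else n_ns / n_s,
                 no_synonymous = n_s == 0)
}

#' Poisson expectation for hits in one gene
#'
#' Under uniform-per-bp placement of `total_mutations` over a genome of
#' `genome_size` bp, the expected number falling in a gene of
#' `gene_length` bp is
#' `lambda = total_mutations / genome_size * gene_length`.
#'
#' @param total_mutations Total observed mutations (> 0 in normal use).
#' @param genome_size Genome size in bp (> 0).
#' @param gene_length Target gene length in bp (> 0).
#' @return `lambda` (expected hits).
#' @export
poisson_lambda <- function(total_mutations, genome_size, gene_length) {
  stopifnot(total_mutations >= 0, genome_size > 0, gene_length > 0)
  total_mutations / genome_size * gene_length
}

#' Upper-tail Poisson probability for gene-level parallelism
#'
#' `P(X >= observed_hits)` for `X ~ Poisson(lambda)`, computed by direct
#' stable summation of the complementary CDF in log space (so tails of
#' order 1e-11 keep full relative precision). `p = 1` when no hits are
#' required; strictly decreasing in the observed count for `lambda > 0`.
#'
#' @param observed_hits Non-negative integer count of mutations observed in
#'   the gene.
#' @param lambda Poisson expectation from [poisson_lambda()].
#' @return The upper-tail probability.
#' @examples
#' lam <- poisson_lambda(29, 6181863, 1476)
#' parallelism_pvalue(4, lam)  # ~9.6e-11
#' @export
parallelism_pvalue <- function(observed_hits, lambda) {
  stopifnot(observed_hits >= 0, lambda >= 0)
  x <- as.integer(round(observed_hits))
  if (x == 0) return(1)
  if (lambda == 0) return(0)
  # sum_{k >= x} e^-lambda lambda^k / k!, accumulated from k = x upward
  log_term <- -lambda + x * log(lambda) - lgamma(x + 1)
  total <- 0
  term <- exp(log_term)
  k <- x
  repeat {
    total <- total + term
    k <- k + 1
    term <- term * lambda / k
    if (term < total * 1e-17 || k > x + 1e6) break
  }
  min(total, 1)
}

#' Gene-level parallelism test across mutation tables
#'
#' Pools the filtered point mutations of all tables, counts hits per gene,
#' and reports the Poisson upper-tail probability of each gene's count
#' under uniform-per-bp placement. Indels are excluded from the mutation
#' total by default (toggle with `include_indels`); no multiplicity
#' correction is applied unless `bonferroni = TRUE`.
#'
#' @param tables Mutation table or list of tables (already frequency
#'   filtered, or pass `min_freq`).
#' @param genome_size Genome size in bp; taken from the tables'
#'   `genome_size` column when omitted.
#' @param min_freq Frequency filter applied first (default 0.05).
#' @param include_indels Count INS/DEL records in the totals (default
#'   FALSE).
#' @param bonferroni Multiply p values by the number of genes tested.
#' @return Tibble with one row per mutated gene: `gene`, `gene_length`,
#'   `hits`, `lambda`, `p_value`.
#' @export
gene_parallelism <- function(tables, genome_size = NULL, min_freq = 0.05,
                             include_indels = FALSE, bonferroni = FALSE) {
  if (is.data.frame(tables)) tables <- list(tables)
  tbl <- filter_mutations(dplyr::bind_rows(tables), min_freq)
  if (is.null(genome_size)) {
    gs <- unique(tbl$genome_size)
    if (length(gs) != 1 || !is.finite(gs)) {
      stop("supply genome_size (tables carry none or several)", call. = FALSE)
    }
    genome_size <- gs
  }
  if (!include_indels) tbl <- tbl[tbl$mtype == "SNP", , drop = FALSE]
  total <- nrow(tbl)
  genic <- tbl[tbl$gene != "intergenic" & !is.na(tbl$gene_length), , drop = FALSE]
  out <- genic |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(gene_length = .data$gene_length[1],
                     hits = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(
      lambda = poisson_lambda(total, genome_size, .data$gene_length),
      p_value = purrr::map2_dbl(.data$hits, .data$lambda, parallelism_pvalue))
  if (bonferroni) out$p_value <- pmin(out$p_value * nrow(out), 1)
  dplyr::arrange(out, .data$p_value)
}

#' Gene-set convergence between conditions
#'
#' Counts genes mutated in both conditions, in only one, and their
#' fractions of the union — the Venn summary of mutational convergence.
#'
#' @param tables List of mutation tables (each with a `condition` column).
#' @param min_freq Frequency filter applied first.
#' @return One-row tibble: `shared`, plus one count and fraction per
#'   condition, and `union_size`.
#' @export
convergence_summary <- function(tables, min_freq = 0.05) {
  if (is.data.frame(tables)) tables <- list(tables)
  if (length(tables) < 2 &&
      length(unique(dplyr::bind_rows(tables)$condition)) < 2) {
    stop("need tables from at least two conditions", call. = FALSE)
  }
  tbl <- filter_mutations(dplyr::bind_rows(tables), min_freq)
  tbl <- tbl[tbl$gene != "intergenic", , drop = FALSE]
  conds <- unique(tbl$condition)
  if (length(conds) != 2) stop("expected exactly two conditions", call. = FALSE)
  g1 <- unique(tbl$gene[tbl$condition == conds[1]])
  g2 <- unique(tbl$gene[tbl$condition == conds[2]])
  n_union <- length(union(g1, g2))
  n_shared <- length(intersect(g1, g2))
  n_a <- length(setdiff(g1, g2))
  n_b <- length(setdiff(g2, g1))
  tibble::tibble(
    condition_a = conds[1], condition_b = conds[2],
    shared = n_shared, only_a = n_a, only_b = n_b, union_size = n_union,
    frac_shared = n_shared / n_union,
    frac_only_a = n_a / n_union,
    frac_only_b = n_b / n_union)
}

#' Classify mutations as fixed, high- or low-frequency
#'
#' `fixed` at or above `fixed_threshold` (default 0.99, absorbing the
#' rounding of frequencies reported as 100%), `high` at or above 0.10,
#' otherwise `low`. Monotone in frequency.
#'
#' @param table Mutation table.
#' @param fixed_threshold Threshold for "fixed", in (0, 1].
#' @param high_threshold Threshold for "high" (default 0.10).
#' @return The table with a `sweep_class` factor column.
#' @export
classify_sweeps <- function(table, fixed_threshold = 0.99,
                            high_threshold = 0.10) {
  stopifnot(fixed_threshold > 0, fixed_threshold <= 1,
            high_threshold < fixed_threshold)
  cls <- ifelse(table$frequency >= fixed_threshold, "fixed",
                ifelse(table$frequency >= high_threshold, "high", "low"))
  out <- tibble::as_tibble(table)
  out$sweep_class <- factor(cls, levels = c("fixed", "high", "low"))
  out
}

#' Biofilm formation index
#'
#' Crystal-violet absorbance of attached cells normalised by the density of
#' the culture that seeded the well: `index = OD595 / OD600`. Higher values
#' mean more biofilm. With replicate vectors for two strains, a Welch
#' two-tailed t test of the indices is reported as well.
#'
#' @param od595_cv Crystal-violet OD595 of the stained biofilm (>= 0).
#' @param od600_culture OD600 of the planktonic culture (> 0).
#' @param ref_od595,ref_od600 Optional reference-strain replicates to test
#'   against.
#' @return Without a reference: the index (vectorised). With one: a list
#'   with `index`, `ref_index` and `test` (tibble from [compare_traits()]).
#' @export
biofilm_index <- function(od595_cv, od600_culture,
                          ref_od595 = NULL, ref_od600 = NULL) {
  if (any(od600_culture <= 0)) stop("OD600 must be > 0", call. = FALSE)
  if (any(od595_cv < 0)) stop("OD595 must be >= 0", call. = FALSE)
  idx <- od595_cv / od600_culture
  if (is.null(ref_od595)) return(idx)
  ref <- biofilm_index(ref_od595, ref_od600)
  list(index = idx, ref_index = ref, test = compare_traits(ref, idx))
}
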