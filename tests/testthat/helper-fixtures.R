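# shared fixtures built in code

t_grid_24h <- seq(0, 24, by = 1 / 6)   # 10-min sampling, 145 points

default_gene_catalog <- function() {
  tibble::tibble(
    gene = c("fleQ", "flgH", "gacS", "uvrY", "oplA", "tatB", "kauB", "cmoB"),
    length = c(1476, 699, 2754, 657, 3663, 774, 1479, 972))
}

# mutation table echoing the published single-clone table: a mix of fixed
# monoculture sweeps and high/low-frequency co-culture polymorphisms
table1_like <- function() {
  tibble::tibble(
    line_id = c("mono2", "mono2", "mono2", "mono4", "mono4",
                "co1", "co2", "co2", "co3", "co3", "co4"),
    condition = c(rep("monoculture", 5), rep("co-culture", 6)),
    position = c(4964741L, 5715528L, 6029059L, 1843830L, 4978570L,
                 4964681L, 4964300L, 3990098L, 4635453L, 3987689L, 4025185L),
    mtype = c("DEL", "SNP", "SNP", "SNP", "INS",
              "SNP", "SNP", "SNP", "SNP", "DEL", "SNP"),
    size = c(2L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L),
    gene = c("fleQ", "tatB", "kauB", "gacS", "flgH",
             "fleQ", "fleQ", "PP_RS18280", "uvrY", "oplA", "PP_RS18445"),
    gene_length = c(1476, 774, 1479, 2754, 699,
                    1476, 1476, 600, 657, 3663, 1000),
    effect = c("frameshift", "synonymous", "synonymous", "nonsynonymous",
               "frameshift", "nonsynonymous", "nonsynonymous",
               "nonsynonymous", "nonsense", "frameshift", "nonsynonymous"),
    frequency = c(1.00, 1.00, 1.00, 1.00, 1.00,
                  0.231, 0.356, 0.04, 0.04, 0.129, 0.04),
    censored = c(rep(FALSE, 7), TRUE, TRUE, FALSE, TRUE),
    genome_size = 6181863)
}

mk_genotype <- function(label = "g", Y = 0.05, V = 7, K = 0.06,
                        resource = "benzoate") {
  genotype(label, Y = Y, V = V, K = K, resource = resource)
}

noiseless_curve <- function(Y = 0.05, V = 7, K = 0.06, R0 = 0.6, P0 = 0.005) {
  simulate_batch_growth(mk_genotype(Y = Y, V = V, K = K),
                        R0 = R0, P0 = P0, t_grid = t_grid_24h)
}
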