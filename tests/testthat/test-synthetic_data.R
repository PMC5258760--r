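test_that("generators are pure functions of the config seed", {
  cfg <- sim_config(seed = 7)
  a <- simulate_counts(cfg); b <- simulate_counts(cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth, b$truth)
  p1 <- simulate_sssl_panel(cfg); p2 <- simulate_sssl_panel(cfg)
  expect_identical(p1$genotypes$codes, p2$genotypes$codes)
  expect_identical(p1$phenotypes, p2$phenotypes)
  t1 <- simulate_annotation_and_targets(cfg)
  t2 <- simulate_annotation_and_targets(cfg)
  expect_identical(t1$transcript_seqs, t2$transcript_seqs)
  expect_identical(t1$genes, t2$genes)
  # a different seed changes the data
  expect_false(identical(simulate_counts(sim_config(seed = 8))$counts$counts,
                         a$counts$counts))
})

test_that("null spike-free counts have equal expected depth per treatment", {
  cfg <- sim_config(seed = 21, n_mirnas = 500, n_de = 0, dispersion = 0,
                    genotypes = "GXN", timepoints = 6)
  sim <- simulate_counts(cfg)
  expect_equal(nrow(sim$truth), 0)
  tot <- colSums(sim$counts$counts)
  # Poisson totals around the common depth: 5 sd of sqrt(depth)
  expect_true(all(abs(tot - cfg$depth) < 5 * sqrt(cfg$depth)))
})

test_that("spiked miRNAs shift heat-library means by the planted fold change", {
  cfg <- sim_config(seed = 22, dispersion = 0, depth = 5e6)
  sim <- simulate_counts(cfg)
  tr <- unique(sim$truth[, c("mirna_id", "genotype", "log2fc")])
  meta <- sim$counts$meta
  for (i in seq_len(nrow(tr))) {
    heat <- meta$library_id[meta$genotype == tr$genotype[i] & meta$treatment == "heat"]
    ctrl <- meta$library_id[meta$genotype == tr$genotype[i] & meta$treatment == "control"]
    obs <- log2(sum(sim$counts$counts[tr$mirna_id[i], heat]) /
                sum(sim$counts$counts[tr$mirna_id[i], ctrl]))
    expect_equal(obs, tr$log2fc[i], tolerance = 0.35)
  }
})

test_that("generated data satisfy every reader invariant round-trip", {
  cfg <- sim_config(seed = 23)
  sim <- simulate_all(cfg)
  dir <- withr::local_tempdir()
  write_count_table(sim$counts, file.path(dir, "counts.tsv"),
                    file.path(dir, "meta.tsv"))
  cm <- read_count_table(file.path(dir, "counts.tsv"), file.path(dir, "meta.tsv"))
  expect_identical(cm$counts, sim$counts$counts)
  write_genotypes(sim$panel, file.path(dir, "map.tsv"), file.path(dir, "geno.tsv"))
  g <- read_genotypes(file.path(dir, "map.tsv"), file.path(dir, "geno.tsv"))
  expect_identical(g$genotypes$codes, sim$panel$genotypes$codes)
  write_gene_models_bed(sim$annotation$genes, file.path(dir, "genes.bed"))
  genes <- read_gene_models(file.path(dir, "genes.bed"))
  expect_equal(genes$gene_id, sim$annotation$genes$gene_id)
  expect_equal(genes$start_mb, sim$annotation$genes$start_mb, tolerance = 1e-6)
  write_fasta(sim$annotation$mirna_seqs, file.path(dir, "mirnas.fa"))
  expect_identical(read_fasta(file.path(dir, "mirnas.fa")),
                   sim$annotation$mirna_seqs)
})

test_that("panel truth carriers cover the planted QTL intervals", {
  cfg <- sim_config(seed = 24)
  panel <- simulate_sssl_panel(cfg)
  expect_equal(nrow(panel$truth), 4)
  expect_setequal(panel$truth$chrom, as.character(c(3, 6, 8, 12)))
  for (i in seq_len(nrow(panel$truth))) {
    seg <- segment_interval(panel$genotypes, panel$truth$line_id[i])
    expect_equal(seg$chrom, panel$truth$chrom[i])
    expect_lte(seg$start_mb, panel$truth$qtl_start_mb[i])
    expect_gte(seg$end_mb, panel$truth$qtl_end_mb[i])
  }
  # carrier line mean shifts by twice the additive effect
  line_means <- tapply(panel$phenotypes$value, panel$phenotypes$line_id, mean)
  for (i in seq_len(nrow(panel$truth)))
    expect_lt(abs(line_means[[panel$truth$line_id[i]]] - line_means[["HJX"]] -
                  2 * panel$truth$effect[i]), 2)
  expect_error(simulate_sssl_panel(sim_config(qtl_chroms = 1:5, n_lines = 4,
                                              qtl_effects = rep(1, 5))),
               "more planted QTLs than lines")
})

test_that("planted target sites are recoverable by construction", {
  cfg <- sim_config(seed = 25)
  ann <- simulate_annotation_and_targets(cfg)
  tp <- ann$truth_pairs
  expect_equal(nrow(tp), cfg$n_true_targets)
  expect_equal(sum(tp$in_qtl), round(cfg$frac_targets_in_qtl * cfg$n_true_targets))
  expect_equal(sum(!tp$expressed), cfg$n_unexpressed_targets)
  zero_mm <- tp[tp$n_mismatch == 0, ]
  for (i in seq_len(nrow(zero_mm))) {
    hits <- predict_targets(ann$mirna_seqs[zero_mm$mirna_id[i]],
                            ann$transcript_seqs[zero_mm$gene_id[i]])
    expect_true(any(hits$score == 0))
  }
  # in-QTL targets overlap a planted QTL interval; the rest overlap none
  panel <- simulate_sssl_panel(cfg)
  overlaps_qtl <- function(gid) {
    g <- ann$genes[ann$genes$gene_id == gid, ]
    any(panel$truth$chrom == g$chrom &
        g$start_mb < panel$truth$qtl_end_mb &
        panel$truth$qtl_start_mb < g$end_mb)
  }
  expect_true(all(vapply(tp$gene_id[tp$in_qtl], overlaps_qtl, logical(1))))
  expect_false(any(vapply(tp$gene_id[!tp$in_qtl], overlaps_qtl, logical(1))))
})
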