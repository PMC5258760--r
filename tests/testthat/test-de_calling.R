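test_that("miRNA confirmation threshold is inclusive and order-preserving", {
  cm <- toy_counts(rbind(c(10, 0), c(9, 3), c(0, 10), c(2, 2)))
  conf <- confirm_mirnas(cm, 10)
  expect_equal(rownames(conf$counts), c("miR1", "miR3"))
  expect_equal(rownames(confirm_mirnas(cm, 0)$counts), rownames(cm$counts))
  expect_warning(confirm_mirnas(cm, 1000), "no miRNA")
})

test_that("TPM normalisation follows count / total * 1e6", {
  cm <- toy_counts(rbind(c(2, 10), c(2, 0)))
  tpm <- tpm_normalize(cm)
  expect_equal(unname(tpm[, "L1"]), c(500000, 500000))
  expect_equal(unname(tpm[, "L2"]), c(1e6, 0))
  expect_equal(unname(colSums(tpm)), c(1e6, 1e6), tolerance = 1e-6)

  cm$meta$total_reads <- c(4, 10)
  expect_equal(unname(tpm_normalize(cm, total_from = "meta")[1, ]),
               c(500000, 1e6))
  zm <- toy_counts(rbind(c(1, 0)))
  expect_error(tpm_normalize(zm), "zero-total library: L2")
})

test_that("log2 fold change applies the pseudo-count as stated", {
  expect_equal(log2_fold_change(20, 5, 1e-12), 2, tolerance = 1e-9)
  expect_equal(log2_fold_change(5, 5, 0.25), 0)
  expect_equal(log2_fold_change(0, 8, 1), log2(1 / 9))
  expect_error(log2_fold_change(1, 1, 0), "pseudo")
})

test_that("Fisher p-values match known tables", {
  expect_equal(fisher_exact_2x2(5, 95, 5, 95), 1)
  expect_equal(fisher_exact_2x2(0, 10, 10, 0), 2 / choose(20, 10),
               tolerance = 1e-12)
  # deep-library regime against the enumeration oracle
  expect_equal(fisher_exact_2x2(10, 999990, 40, 999960),
               oracle_fisher(10, 999990, 40, 999960), tolerance = 1e-10)
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "negative")
})

test_that("Fisher equals exhaustive hypergeometric enumeration on random small tables", {
  withr::with_seed(402, {
    for (rep in 1:300) {
      m <- sample(1:30, 1); n <- sample(1:30, 1)
      a <- sample(0:m, 1); c <- sample(0:n, 1)
      p <- fisher_exact_2x2(a, m - a, c, n - c)
      expect_equal(p, oracle_fisher(a, m - a, c, n - c), tolerance = 1e-10)
    }
  })
})

test_that("Fisher agrees with stats::fisher.test as an independent cross-check", {
  withr::with_seed(403, {
    for (rep in 1:50) {
      m <- sample(1:25, 1); n <- sample(1:25, 1)
      a <- sample(0:m, 1); c <- sample(0:n, 1)
      expect_equal(fisher_exact_2x2(a, m - a, c, n - c),
                   stats::fisher.test(rbind(c(a, m - a), c(c, n - c)))$p.value,
                   tolerance = 1e-7)
    }
  })
})

test_that("BH adjustment reproduces hand step-up values and its invariants", {
  expect_equal(bh_adjust(c(0.05, 0.05, 0.05)), c(0.05, 0.05, 0.05))
  expect_equal(bh_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  withr::with_seed(404, {
    for (rep in 1:20) {
      p <- runif(sample(1:10, 1))
      adj <- bh_adjust(p)
      expect_equal(adj, oracle_bh(p))
      expect_true(all(adj >= p))
      perm <- sample(seq_along(p))
      expect_equal(bh_adjust(p[perm]), adj[perm])
    }
  })
})

test_that("DE direction requires all three gates", {
  # build a 3-miRNA contrast where gates fail one at a time:
  # miR1 passes all; miR2 has strong counts but |lfc| < 1; miR3 clears the
  # fold-change gate with counts too small for significance
  counts <- rbind(c(100, 420), c(1000, 1900), c(2, 8))
  # pad with null miRNAs so the FDR family is realistic
  pad <- matrix(rep(c(500L, 500L), 30), ncol = 2, byrow = TRUE)
  all_counts <- rbind(counts, pad)
  cm <- toy_counts(all_counts, mirnas = paste0("miR", seq_len(nrow(all_counts))))
  tpm <- tpm_normalize(cm)
  calls <- call_de(tpm, cm, "GXN", 6)
  expect_equal(calls$direction[1], "up")
  expect_true(calls$p_value[2] < 0.05 && abs(calls$log2_fold_change[2]) < 1)
  expect_equal(calls$direction[2], "ns")
  expect_true(calls$log2_fold_change[3] >= 1 && calls$p_value[3] > 0.05)
  expect_equal(calls$direction[3], "ns")
  expect_true(all(calls$fdr >= calls$p_value))
  expect_error(call_de(tpm, cm, "GXN", 24), "contrast error")
})

test_that("DE calling recovers spiked miRNAs on the seeded fixture", {
  cfg <- sim_config(seed = 7)
  sim <- simulate_counts(cfg)
  calls <- de_analysis(sim$counts)
  tr <- unique(sim$truth[, c("mirna_id", "genotype", "log2fc")])
  hit <- vapply(seq_len(nrow(tr)), function(i) {
    sub <- calls[calls$mirna_id == tr$mirna_id[i] &
                 calls$genotype == tr$genotype[i], ]
    any(sub$direction == ifelse(tr$log2fc[i] > 0, "up", "down"))
  }, logical(1))
  expect_gte(sum(hit), ceiling(0.9 * nrow(tr)))
})

test_that("four-category classification follows genotype sign patterns", {
  call_row <- function(id, g, tp, dir)
    data.frame(mirna_id = id, genotype = g, timepoint_hours = tp,
               log2_fold_change = 0, p_value = 0, fdr = 0, direction = dir,
               stringsAsFactors = FALSE)
  calls <- rbind(
    call_row("a", "GXN", 6, "down"), call_row("a", "HJX", 6, "down"),
    call_row("b", "GXN", 6, "up"),   call_row("b", "HJX", 6, "down"),
    call_row("c", "GXN", 1, "up"),   call_row("c", "HJX", 1, "ns"),
    call_row("d", "GXN", 1, "ns"),   call_row("d", "HJX", 24, "down"),
    # tie within GXN: up at 1 h, down at 6 h -> opposite-capable
    call_row("e", "GXN", 1, "up"), call_row("e", "GXN", 6, "down"),
    call_row("e", "HJX", 6, "down"))
  cat <- categorize_de(calls)
  got <- stats::setNames(cat$category, cat$mirna_id)
  expect_equal(got[["a"]], "co-regulated-same-direction")
  expect_equal(got[["b"]], "co-regulated-opposite")
  expect_equal(got[["c"]], "GXN-specific")
  expect_equal(got[["d"]], "HJX-specific")
  expect_equal(got[["e"]], "co-regulated-opposite")
  expect_equal(nrow(cat), 5)  # every DE miRNA categorised exactly once
  calls$genotype[1] <- "N22"
  expect_error(categorize_de(calls), "two genotypes")
})
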