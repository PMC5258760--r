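test_that("complementarity_score applies penalties and seed weighting", {
  L <- 21
  perfect <- rep("match", L)
  expect_equal(complementarity_score(perfect), 0)
  one_wobble <- perfect; one_wobble[5] <- "wobble"
  expect_equal(complementarity_score(one_wobble), 1)     # 0.5 x seed weight 2
  one_mm <- perfect; one_mm[20] <- "mismatch"
  expect_equal(complementarity_score(one_mm), 1)         # outside the seed
  seed_mm <- perfect; seed_mm[3] <- "mismatch"
  expect_equal(complementarity_score(seed_mm), 2)
  gap <- perfect; gap[15] <- "gap"
  expect_equal(complementarity_score(gap), 2)
  expect_error(complementarity_score(c("match", "weird")), "unknown")
})

test_that("adding a mismatch never decreases the score", {
  withr::with_seed(71, {
    for (rep in 1:20) {
      L <- 21
      states <- sample(c("match", "wobble", "mismatch"), L, TRUE,
                       prob = c(0.8, 0.1, 0.1))
      s0 <- complementarity_score(states)
      i <- sample(which(states != "mismatch"), 1)
      states[i] <- "mismatch"
      expect_gte(complementarity_score(states), s0)
    }
  })
})

test_that("a planted perfect site is found at score 0, wherever it sits", {
  withr::with_seed(72, {
    mir <- random_rna_str(21)
    site <- revcomp_str(mir)
    for (offset in c(0, 40, 179)) {
      tr <- paste0(random_rna_str(offset), site, random_rna_str(179 - offset))
      hits <- predict_targets(c(m = mir), c(t = tr))
      planted <- hits[hits$t_start == offset, ]
      expect_equal(nrow(planted), 1)
      expect_equal(planted$score, 0)
      expect_equal(planted$t_end, offset + 21)
      expect_equal(planted$gap_type, "none")
    }
  })
})

test_that("non-seed mismatches are scored as planted and nothing spurious survives", {
  withr::with_seed(73, {
    cfg <- sim_config(seed = 73)
    ann <- simulate_annotation_and_targets(cfg)
    tp <- ann$truth_pairs
    for (i in seq_len(nrow(tp))) {
      hits <- predict_targets(ann$mirna_seqs[tp$mirna_id[i]],
                              ann$transcript_seqs[tp$gene_id[i]])
      expect_equal(nrow(hits), 1)
      expect_equal(hits$score, tp$n_mismatch[i] * 1.0)
    }
  })
})

test_that("no hit is reported when no window clears the cutoff", {
  withr::with_seed(74, {
    mir <- random_rna_str(21)
    # poly-A transcript cannot pair a random miRNA well
    hits <- predict_targets(c(m = mir), c(t = strrep("A", 150)),
                            max_score = 0.5)
    expect_equal(nrow(hits), 0)
  })
  expect_warning(predict_targets(character(0), c(t = "ACGU")), "empty")
})

test_that("exhaustive search equals the naive all-windows oracle", {
  withr::with_seed(75, {
    scheme <- scoring_scheme()
    for (rep in 1:25) {
      mir <- random_rna_str(21)
      n <- sample(60:180, 1)
      tr <- random_rna_str(n)
      # plant a corrupted site half the time so hits actually occur
      if (rep %% 2 == 0) {
        site <- revcomp_str(mir)
        for (pos in sample(14:21, sample(0:2, 1)))
          site <- paste0(substr(site, 1, 21 - pos),
                         sample(c("A", "C", "G", "U"), 1),
                         substr(site, 21 - pos + 2, 21))
        at <- sample(0:(n - 21), 1)
        tr <- paste0(substr(tr, 1, at), site, substr(tr, at + 22, n))
      }
      got <- predict_targets(c(m = mir), c(t = tr), scheme, max_score = 4)
      want <- naive_predict(mir, tr, scheme, max_score = 4)
      expect_equal(nrow(got), nrow(want))
      if (nrow(got)) {
        got <- got[order(got$t_start), ]
        expect_equal(got$t_start, want$t_start)
        expect_equal(got$t_end, want$t_end)
        expect_equal(got$score, want$score)
        expect_equal(got$gap_type, want$gap_type)
      }
    }
  })
})

test_that("cleavage position sits opposite the miRNA 10/11 bond", {
  withr::with_seed(76, {
    mir <- random_rna_str(21)
    tr <- paste0(random_rna_str(100), revcomp_str(mir), random_rna_str(80))
    hit <- predict_targets(c(m = mir), c(t = tr))
    hit <- hit[hit$t_start == 100, ]
    expect_equal(hit$cleavage_pos, 111)
    expect_equal(cleavage_position(hit), 111)
    # translation invariance: site at the transcript start
    tr0 <- paste0(revcomp_str(mir), random_rna_str(80))
    hit0 <- predict_targets(c(m = mir), c(t = tr0))
    hit0 <- hit0[hit0$t_start == 0, ]
    expect_equal(hit0$cleavage_pos, 11)
  })
})

test_that("gapped sites place the cleavage by realised pairing", {
  withr::with_seed(77, {
    mir <- random_rna_str(21)
    site <- revcomp_str(mir)
    # remove the target base pairing miRNA position 15 -> target_gap at 15
    gap_site <- paste0(substr(site, 1, 6), substr(site, 8, 21))
    tr <- paste0(random_rna_str(50), gap_site, random_rna_str(50))
    hits <- predict_targets(c(m = mir), c(t = tr), max_score = 4)
    g <- hits[hits$gap_type == "target_gap", ]
    expect_equal(nrow(g), 1)
    expect_equal(g$t_start, 50)
    expect_equal(g$gap_mirna_pos, 15)
    expect_equal(g$score, 2)             # gap penalty, outside the seed
    # positions 1..10 pair the window tail: partner of pos 10 is s + L - 1 - 10
    expect_equal(g$cleavage_pos, 50 + 21 - 1 - 10)
    expect_equal(cleavage_position(g), g$cleavage_pos)
    mir10 <- random_rna_str(10)
    short <- predict_targets(c(m = mir10),
                             c(t = paste0(revcomp_str(mir10),
                                          random_rna_str(30))))
    expect_error(cleavage_position(short[1, ]), "11")
  })
})
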