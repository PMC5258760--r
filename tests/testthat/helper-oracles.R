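# Independent oracles, deliberately implemented apart from the package code
# paths they check.

# Two-sided Fisher p by explicit enumeration over the hypergeometric support,
# probabilities from log-binomial coefficients (not dhyper).
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (k == 0 || m == 0 || n == 0 || k == m + n) return(1)
  support <- max(0, k - n):min(k, m)
  logp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  p_obs <- exp(lchoose(m, a) + lchoose(n, k - a) - lchoose(m + n, k))
  min(1, sum(exp(logp)[exp(logp) <= p_obs * (1 + 1e-7)]))
}

# Step-up BH by hand: sort, p * m / rank, right-to-left running minimum.
oracle_bh <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(pmin(ranked, 1))))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Naive all-windows miRNA target scorer: string alignments built and scored
# with explicit loops, mirroring the documented scheme conventions.
naive_predict <- function(mirna, transcript, scheme = mirqtl::scoring_scheme(),
                          max_score = scheme$max_score) {
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  wob <- c(G = "U", U = "G")
  m <- strsplit(chartr("T", "U", toupper(mirna)), "")[[1]]
  t <- strsplit(chartr("T", "U", toupper(transcript)), "")[[1]]
  L <- length(m); nT <- length(t)
  w <- rep(1, L); w[scheme$seed_range[scheme$seed_range <= L]] <- scheme$seed_multiplier
  pair_pen <- function(mb, tb) {
    if (comp[[mb]] == tb) 0
    else if (!is.na(wob[mb]) && wob[[mb]] == tb) scheme$wobble
    else scheme$mismatch
  }
  gl <- scheme$gap_position_limit
  cand <- list()
  add <- function(s0, wl, sc, type, k) {
    cand[[length(cand) + 1L]] <<- data.frame(
      t_start = s0, t_end = s0 + wl, score = sc, gap_type = type,
      gap_mirna_pos = k, stringsAsFactors = FALSE)
  }
  # ungapped
  for (s0 in 0:(nT - L)) {
    if (s0 < 0) break
    sc <- 0
    for (i in 1:L) sc <- sc + w[i] * pair_pen(m[i], t[s0 + L - i + 1])
    if (sc <= max_score + 1e-9) add(s0, L, sc, "none", NA_integer_)
  }
  # one miRNA position unpaired (gap in target), internal, 3' of the limit
  for (k in seq_len(L)) {
    if (k <= gl || k >= L) next
    if (nT < L - 1) next
    for (s0 in 0:(nT - (L - 1))) {
      sc <- scheme$gap * w[k]
      for (i in 1:L) {
        if (i == k) next
        ti <- if (i < k) s0 + L - 1 - i else s0 + L - i
        sc <- sc + w[i] * pair_pen(m[i], t[ti + 1])
      }
      if (sc <= max_score + 1e-9) add(s0, L - 1L, sc, "target_gap", k)
    }
  }
  # one extra target base (bulge) at gap position k, 3' of the limit
  for (k in seq_len(L)) {
    if (k <= gl || k < 2) next
    if (nT < L + 1) next
    for (s0 in 0:(nT - (L + 1))) {
      sc <- scheme$gap * w[k]
      for (i in 1:L) {
        ti <- if (i <= k - 1) s0 + L + 1 - i else s0 + L - i
        sc <- sc + w[i] * pair_pen(m[i], t[ti + 1])
      }
      if (sc <= max_score + 1e-9) add(s0, L + 1L, sc, "bulge", k)
    }
  }
  if (!length(cand)) return(data.frame(t_start = integer(), t_end = integer(),
                                       score = numeric(), gap_type = character(),
                                       gap_mirna_pos = integer()))
  cand <- do.call(rbind, cand)
  # same locus-resolution rule, written independently: best score first,
  # ungapped preferred, leftmost; suppress overlapping alignments
  rank <- order(cand$score, match(cand$gap_type, c("none", "target_gap", "bulge")),
                cand$t_start)
  cand <- cand[rank, , drop = FALSE]
  kept <- cand[0, ]
  for (r in seq_len(nrow(cand))) {
    overlaps <- any(cand$t_start[r] < kept$t_end & kept$t_start < cand$t_end[r])
    if (!overlaps) kept <- rbind(kept, cand[r, ])
  }
  kept[order(kept$t_start), , drop = FALSE]
}

random_rna_str <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                                    collapse = "")
revcomp_str <- function(s) chartr("ACGU", "UGCA",
                                  paste(rev(strsplit(s, "")[[1]]), collapse = ""))
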