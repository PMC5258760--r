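# Plant-style miRNA-target complementarity scoring.
#
# The miRNA (5'->3') is slid along the transcript and paired against each
# window read 3'->5'. Penalties accumulate per miRNA position (match 0,
# G:U wobble, mismatch, gap), doubled inside the 5' seed region, and a site
# is reported when the total stays at or below the reporting cutoff. At most
# one gap is allowed per site, only 3' of the gap position limit, so the
# search over windows and gap placements is exhaustive.

RNA_ENC <- c(A = 1L, C = 2L, G = 3L, U = 4L)

# pair state, miRNA base x target base: 0 match, 1 wobble, 2 mismatch
PAIR_STATE <- local({
  m <- matrix(2L, 4, 4, dimnames = list(names(RNA_ENC), names(RNA_ENC)))
  m["A", "U"] <- 0L; m["U", "A"] <- 0L; m["G", "C"] <- 0L; m["C", "G"] <- 0L
  m["G", "U"] <- 1L; m["U", "G"] <- 1L
  m
})

encode_rna <- function(seq) {
  s <- chartr("Tt", "Uu", toupper(seq))
  enc <- RNA_ENC[strsplit(s, "")[[1]]]
  if (anyNA(enc)) stop("sequence contains characters outside {A,C,G,U/T}")
  unname(enc)
}

#' Scoring scheme for miRNA-target complementarity
#'
#' The numeric scheme is a documented reconstruction of common plant
#' target-prediction conventions, fully specified here: mismatch 1.0,
#' G:U wobble 0.5 and gap 2.0 penalty points, doubled within miRNA
#' positions 2-13 (the seed-weighted region); sites are reported up to a
#' total of 3.0 points by default, with a strict mode at 2.0; at most one
#' gap per site and none at or before miRNA position 10.
#'
#' @param mismatch,wobble,gap penalty points per event.
#' @param seed_range miRNA positions (1-based from the 5' end) whose
#'   penalties are multiplied by `seed_multiplier`.
#' @param seed_multiplier weight inside `seed_range`.
#' @param max_score reporting cutoff (total penalty points).
#' @param gap_position_limit no gap is allowed at or before this miRNA
#'   position.
#' @return list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(mismatch = 1, wobble = 0.5, gap = 2,
                           seed_range = 2:13, seed_multiplier = 2,
                           max_score = 3, gap_position_limit = 10) {
  if (any(c(mismatch, wobble, gap) < 0)) stop("penalties must be >= 0")
  structure(list(mismatch = mismatch, wobble = wobble, gap = gap,
                 seed_range = seed_range, seed_multiplier = seed_multiplier,
                 max_score = max_score, gap_position_limit = gap_position_limit),
            class = "scoring_scheme")
}

position_weights <- function(L, scheme) {
  seed <- scheme$seed_range[scheme$seed_range <= L]
  w <- rep(1, L); w[seed] <- scheme$seed_multiplier
  w
}

#' Score an alignment given per-position states
#'
#' @param states character vector over miRNA positions (5'->3'), values in
#'   `match`, `wobble`, `mismatch`, `gap` (a `gap` state means the miRNA
#'   position pairs a gap in the target).
#' @param scheme a [scoring_scheme()].
#' @return total penalty score (0 iff perfect complementarity).
#' @export
complementarity_score <- function(states, scheme = scoring_scheme()) {
  pen <- c(match = 0, wobble = scheme$wobble, mismatch = scheme$mismatch,
           gap = scheme$gap)
  if (!all(states %in% names(pen)))
    stop("unknown alignment state: ",
         paste(setdiff(states, names(pen)), collapse = ", "))
  sum(pen[states] * position_weights(length(states), scheme))
}

# Pairing target indices (0-based) for each miRNA position, one variant.
# variant: "none", "target_gap" (miRNA position `k` unpaired) or "bulge"
# (extra target base between the partners of positions k-1 and k, where
# k is the recorded gap position).
pairing_indices <- function(s, L, variant, k = NA) {
  i <- seq_len(L)
  if (variant == "none") {
    tidx <- s + L - i
  } else if (variant == "target_gap") {
    tidx <- ifelse(i < k, s + L - 1 - i, s + L - i)
    tidx[i == k] <- NA
  } else {                      # bulge: gap position k, extra base 3' of partner of k
    tidx <- ifelse(i <= k - 1, s + L + 1 - i, s + L - i)
  }
  tidx
}

window_length <- function(L, variant) {
  switch(variant, none = L, target_gap = L - 1L, bulge = L + 1L)
}

# score all windows of one variant, vectorised over window starts
variant_scores <- function(me, te, variant, k, pen_by_state, w, gap_pen) {
  L <- length(me); nT <- length(te)
  wl <- window_length(L, variant)
  nS <- nT - wl + 1
  if (nS < 1) return(numeric(0))
  sc <- rep(if (is.na(k)) 0 else gap_pen * w[k], nS)
  tidx0 <- pairing_indices(0L, L, variant, k)
  for (i in seq_len(L)) {
    if (is.na(tidx0[i])) next
    ti <- tidx0[i] + seq_len(nS)        # 1-based target indices across starts
    st <- PAIR_STATE[cbind(me[i], te[ti])]
    sc <- sc + w[i] * pen_by_state[st + 1L]
  }
  sc
}

#' Predict miRNA target sites by exhaustive seed-weighted alignment
#'
#' Every miRNA is aligned against every window of every transcript
#' (reverse-complement pairing, target read 3'->5'), including all single-gap
#' variants allowed by the scheme. Overlapping candidate alignments of the
#' same locus are resolved to the best-scoring one (ties: ungapped first,
#' then leftmost), so each reported site is a distinct locus; distinct loci
#' on one transcript are all reported. Results are sorted by score, then
#' transcript, then position.
#'
#' @param mirnas,transcripts named character vectors of sequences
#'   (`U`/`T` equivalent), e.g. from [read_fasta()].
#' @param scheme a [scoring_scheme()].
#' @param max_score reporting cutoff; defaults to the scheme's.
#' @return data.frame with one row per site: `mirna_id`, `gene_id`,
#'   `t_start`, `t_end` (0-based half-open on the transcript), `score`,
#'   `gap_type`, `gap_mirna_pos`, `n_mismatch`, `n_wobble`,
#'   `cleavage_pos`, `aln_mirna`, `aln_bond`, `aln_target`.
#' @export
predict_targets <- function(mirnas, transcripts, scheme = scoring_scheme(),
                            max_score = scheme$max_score) {
  if (length(mirnas) == 0 || length(transcripts) == 0) {
    warning("empty sequence set: no targets predicted")
    return(empty_hit_frame())
  }
  if (is.null(names(mirnas)) || is.null(names(transcripts)))
    stop("mirnas and transcripts must be named")
  pen_by_state <- c(0, scheme$wobble, scheme$mismatch)
  hits <- list()
  for (mid in names(mirnas)) {
    me <- encode_rna(mirnas[[mid]])
    L <- length(me)
    w <- position_weights(L, scheme)
    gl <- scheme$gap_position_limit
    variants <- list(list(variant = "none", k = NA_integer_))
    for (k in seq_len(L)) {                   # internal gaps only, 3' of the limit
      if (k > gl && k < L)
        variants <- c(variants, list(list(variant = "target_gap", k = k)))
      if (k > gl && k > 1 && k <= L)
        variants <- c(variants, list(list(variant = "bulge", k = k)))
    }
    for (tid in names(transcripts)) {
      te <- encode_rna(transcripts[[tid]])
      cand <- list()
      for (v in variants) {
        sc <- variant_scores(me, te, v$variant, v$k, pen_by_state, w, scheme$gap)
        ok <- which(sc <= max_score + 1e-9)
        if (length(ok))
          cand[[length(cand) + 1L]] <- data.frame(
            t_start = ok - 1L,
            t_end = ok - 1L + window_length(L, v$variant),
            score = sc[ok], gap_type = v$variant,
            gap_mirna_pos = if (is.na(v$k)) NA_integer_ else v$k,
            stringsAsFactors = FALSE)
      }
      if (!length(cand)) next
      cand <- do.call(rbind, cand)
      picked <- resolve_overlaps(cand)
      for (r in seq_len(nrow(picked)))
        hits[[length(hits) + 1L]] <- hit_details(mid, tid, me, te,
                                                 picked[r, ], scheme)
    }
  }
  if (!length(hits)) return(empty_hit_frame())
  out <- do.call(rbind, hits)
  out <- out[order(out$score, out$gene_id, out$t_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# greedy non-overlap resolution: best score wins its locus
resolve_overlaps <- function(cand) {
  gap_rank <- match(cand$gap_type, c("none", "target_gap", "bulge"))
  cand <- cand[order(cand$score, gap_rank, cand$t_start), , drop = FALSE]
  keep <- logical(nrow(cand))
  taken_s <- numeric(0); taken_e <- numeric(0)
  for (r in seq_len(nrow(cand))) {
    if (!any(cand$t_start[r] < taken_e & taken_s < cand$t_end[r])) {
      keep[r] <- TRUE
      taken_s <- c(taken_s, cand$t_start[r]); taken_e <- c(taken_e, cand$t_end[r])
    }
  }
  cand[keep, , drop = FALSE]
}

hit_details <- function(mid, tid, me, te, hit, scheme) {
  L <- length(me)
  tidx <- pairing_indices(hit$t_start, L, hit$gap_type, hit$gap_mirna_pos)
  states <- character(L)
  for (i in seq_len(L)) {
    states[i] <- if (is.na(tidx[i])) "gap"
    else c("match", "wobble", "mismatch")[PAIR_STATE[me[i], te[tidx[i] + 1L]] + 1L]
  }
  bases <- names(RNA_ENC)
  bond <- c(match = "|", wobble = "o", mismatch = " ", gap = "-")[states]
  target_line <- ifelse(is.na(tidx), "-", bases[te[ifelse(is.na(tidx), 1L, tidx + 1L)]])
  mirna_line <- bases[me]
  if (hit$gap_type == "bulge") {
    k <- hit$gap_mirna_pos
    bulge_idx <- hit$t_start + L + 1L - k      # 0-based index of the unpaired base
    mirna_line <- append(mirna_line, ".", after = k - 1L)
    bond <- append(bond, "-", after = k - 1L)
    target_line <- append(target_line, tolower(bases[te[bulge_idx + 1L]]),
                          after = k - 1L)
  }
  cleave <- if (L >= 11) as.integer(tidx[10]) else NA_integer_
  data.frame(mirna_id = mid, gene_id = tid,
             t_start = hit$t_start, t_end = hit$t_end, score = hit$score,
             gap_type = hit$gap_type, gap_mirna_pos = hit$gap_mirna_pos,
             n_mismatch = sum(states == "mismatch"),
             n_wobble = sum(states == "wobble"),
             cleavage_pos = cleave,
             aln_mirna = paste(mirna_line, collapse = ""),
             aln_bond = paste(bond, collapse = ""),
             aln_target = paste(target_line, collapse = ""),
             stringsAsFactors = FALSE)
}

empty_hit_frame <- function() {
  data.frame(mirna_id = character(), gene_id = character(),
             t_start = integer(), t_end = integer(), score = numeric(),
             gap_type = character(), gap_mirna_pos = integer(),
             n_mismatch = integer(), n_wobble = integer(),
             cleavage_pos = integer(), aln_mirna = character(),
             aln_bond = character(), aln_target = character(),
             stringsAsFactors = FALSE)
}

#' Predicted cleavage position of a target site
#'
#' The slicing bond lies opposite the bond between miRNA nucleotides 10 and
#' 11. The returned value is the 0-based transcript position of the base
#' pairing miRNA nucleotide 10; the cleaved phosphodiester bond is
#' immediately 5' of that base on the transcript (for a perfect 21-nt site
#' at `[100, 121)` the bond falls between transcript positions 110 and 111
#' and the function returns 111). With a gapped site the position follows
#' the realised pairing, not the raw window offset.
#'
#' @param hit one row of a [predict_targets()] result.
#' @param mirna_length length of the miRNA (recovered from the alignment
#'   string when omitted).
#' @return 0-based transcript coordinate.
#' @export
cleavage_position <- function(hit, mirna_length = NULL) {
  if (is.null(mirna_length))
    mirna_length <- nchar(gsub(".", "", hit$aln_mirna, fixed = TRUE))
  if (mirna_length < 11)
    stop("cleavage undefined: site pairs fewer than 11 miRNA positions")
  tidx <- pairing_indices(hit$t_start, mirna_length, hit$gap_type,
                          hit$gap_mirna_pos)
  as.integer(tidx[10])
}
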