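#' Intersect predicted target genes with QTL intervals
#'
#' A (miRNA, gene, QTL) candidate pair is emitted when the gene's interval
#' overlaps the QTL interval on the same chromosome. Both intervals are
#' half-open in Mb, so the default any-overlap rule is
#' `gene_start < qtl_end && qtl_start < gene_end`; `mode = "containment"`
#' requires the gene to lie fully inside the QTL. Pairs are deduplicated by
#' (miRNA, gene, QTL), keeping the best target score.
#'
#' @param hits data.frame from [predict_targets()] (columns `mirna_id`,
#'   `gene_id`, `score` are used).
#' @param genes data.frame of gene models (`gene_id`, `chrom`, `start_mb`,
#'   `end_mb`), coordinates on the same assembly as the QTLs.
#' @param qtls data.frame from [detect_qtls()] (`qtl_id`, `chrom`,
#'   `start_mb`, `end_mb`).
#' @param mode `"any"` (default, >= 1 bp overlap) or `"containment"`.
#' @return data.frame of candidate pairs: `mirna_id`, `gene_id`, `qtl_id`,
#'   `score`, `gene_start_mb`, `gene_end_mb`, `qtl_start_mb`, `qtl_end_mb`.
#' @export
intersect_targets_with_qtls <- function(hits, genes, qtls,
                                        mode = c("any", "containment")) {
  mode <- match.arg(mode)
  empty <- data.frame(mirna_id = character(), gene_id = character(),
                      qtl_id = character(), score = numeric(),
                      gene_start_mb = numeric(), gene_end_mb = numeric(),
                      qtl_start_mb = numeric(), qtl_end_mb = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(hits) == 0 || nrow(qtls) == 0 || nrow(genes) == 0) return(empty)
  gchr <- unique(genes$chrom); qchr <- unique(qtls$chrom)
  if (!length(intersect(gchr, qchr)))
    stop("chromosome label mismatch between annotations: genes use {",
         paste(gchr, collapse = ", "), "}, QTLs use {",
         paste(qchr, collapse = ", "), "}")
  gi <- match(hits$gene_id, genes$gene_id)
  rows <- list()
  for (h in which(!is.na(gi))) {
    g <- genes[gi[h], ]
    for (q in seq_len(nrow(qtls))) {
      if (g$chrom != qtls$chrom[q]) next
      ov <- if (mode == "any")
        g$start_mb < qtls$end_mb[q] && qtls$start_mb[q] < g$end_mb
      else g$start_mb >= qtls$start_mb[q] && g$end_mb <= qtls$end_mb[q]
      if (!ov) next
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = hits$mirna_id[h], gene_id = g$gene_id,
        qtl_id = qtls$qtl_id[q], score = hits$score[h],
        gene_start_mb = g$start_mb, gene_end_mb = g$end_mb,
        qtl_start_mb = qtls$start_mb[q], qtl_end_mb = qtls$end_mb[q],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$mirna_id, out$gene_id, out$qtl_id, out$score), , drop = FALSE]
  out <- out[!duplicated(out[, c("mirna_id", "gene_id", "qtl_id")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pearson correlation between a miRNA and a target expression profile
#'
#' Profiles are expression values over matched condition cells (by
#' convention log2 expression relative to the unstressed control in each
#' (genotype, timepoint) cell). When both vectors are named they are
#' aligned by cell name; at least three shared cells are required.
#'
#' @param mirna_profile,gene_profile numeric vectors (optionally named by
#'   condition cell).
#' @return Pearson r; `NA` with a warning if either profile has zero
#'   variance.
#' @export
anticorrelation <- function(mirna_profile, gene_profile) {
  if (!is.null(names(mirna_profile)) && !is.null(names(gene_profile))) {
    shared <- intersect(names(mirna_profile), names(gene_profile))
    mirna_profile <- mirna_profile[shared]
    gene_profile <- gene_profile[shared]
  } else if (length(mirna_profile) != length(gene_profile)) {
    stop("unnamed profiles must have equal length")
  }
  if (length(mirna_profile) < 3)
    stop("anticorrelation requires at least 3 shared condition cells")
  if (stats::sd(mirna_profile) == 0 || stats::sd(gene_profile) == 0) {
    warning("undefined correlation: zero-variance profile")
    return(NA_real_)
  }
  stats::cor(mirna_profile, gene_profile, method = "pearson")
}

#' Filter and rank candidate miRNA-target pairs
#'
#' Mirrors the qualitative candidate funnel: genes that are not expressed
#' (mean abundance below `expr_floor`, default 1 TPM) are dropped, pairs
#' whose expression correlation exceeds `r_max` (default 0, i.e. not
#' anti-correlated) are dropped, and the survivors are ranked by
#' anticorrelation (most negative first), breaking ties by target score
#' (best complementarity first).
#'
#' @param pairs data.frame from [intersect_targets_with_qtls()].
#' @param profiles long data.frame of expression profiles: columns `id`
#'   (miRNA or gene), `cell` (condition cell label), `log2fc` (log2
#'   expression relative to control).
#' @param abundance named numeric vector of mean gene abundance (TPM-like)
#'   used for the expressed filter.
#' @param expr_floor,r_max filter thresholds.
#' @return the surviving pairs with `anticorrelation` and `rank` columns;
#'   dropped pairs and their reasons are attached as attribute `"dropped"`.
#' @export
rank_candidates <- function(pairs, profiles, abundance,
                            expr_floor = 1, r_max = 0) {
  if (nrow(pairs) == 0) {
    pairs$anticorrelation <- numeric(0); pairs$rank <- integer(0)
    return(pairs)
  }
  prof <- function(id) {
    sub <- profiles[profiles$id == id, ]
    stats::setNames(sub$log2fc, sub$cell)
  }
  r <- vapply(seq_len(nrow(pairs)), function(i)
    anticorrelation(prof(pairs$mirna_id[i]), prof(pairs$gene_id[i])),
    numeric(1))
  pairs$anticorrelation <- r
  expressed <- !is.na(abundance[pairs$gene_id]) &
    abundance[pairs$gene_id] >= expr_floor
  anti <- !is.na(r) & r <= r_max
  dropped <- pairs[!(expressed & anti), , drop = FALSE]
  if (nrow(dropped)) {
    dropped$reason <- ifelse(!expressed[!(expressed & anti)],
                             "not expressed", "not anti-correlated")
  } else dropped$reason <- character(0)
  out <- pairs[expressed & anti, , drop = FALSE]
  out <- out[order(out$anticorrelation, out$score, out$mirna_id, out$gene_id), ,
             drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' End-to-end candidate funnel
#'
#' Convenience wrapper chaining the pipeline downstream of DE calling:
#' target prediction restricted to DE miRNAs, intersection of target genes
#' with QTL intervals, and anti-correlation ranking.
#'
#' @param de_calls data.frame from [de_analysis()].
#' @param mirna_seqs,transcript_seqs named sequence vectors; transcript
#'   names must match `genes$gene_id`.
#' @param genes gene models data.frame.
#' @param qtls data.frame from [detect_qtls()].
#' @param profiles,abundance see [rank_candidates()].
#' @param scheme a [scoring_scheme()].
#' @param ... passed to [rank_candidates()].
#' @return ranked candidate pairs (see [rank_candidates()]).
#' @export
candidate_funnel <- function(de_calls, mirna_seqs, transcript_seqs, genes,
                             qtls, profiles, abundance,
                             scheme = scoring_scheme(), ...) {
  de_ids <- unique(de_calls$mirna_id[de_calls$direction != "ns"])
  if (!length(de_ids)) {
    warning("no DE miRNA: empty candidate list")
    return(rank_candidates(intersect_targets_with_qtls(empty_hit_frame(),
                                                       genes, qtls),
                           profiles, abundance, ...))
  }
  hits <- predict_targets(mirna_seqs[intersect(de_ids, names(mirna_seqs))],
                          transcript_seqs, scheme)
  pairs <- intersect_targets_with_qtls(hits, genes, qtls)
  rank_candidates(pairs, profiles, abundance, ...)
}
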