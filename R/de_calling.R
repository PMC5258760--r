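#' Keep confirmed miRNAs
#'
#' A miRNA is "confirmed" when its raw read count reaches `min_reads` in at
#' least one library. The default of 10 reads is the conventional floor for
#' treating a mature small-RNA sequence as reliably observed. Row order is
#' preserved.
#'
#' @param counts a [count_matrix()].
#' @param min_reads inclusive threshold (default 10); `0` keeps everything.
#' @return a [count_matrix()] restricted to confirmed miRNAs.
#' @export
confirm_mirnas <- function(counts, min_reads = 10) {
  keep <- apply(counts$counts, 1, max) >= min_reads
  if (!any(keep)) warning("no miRNA reaches ", min_reads, " reads in any library")
  count_matrix(counts$counts[keep, , drop = FALSE], counts$meta)
}

library_totals <- function(counts, total_from = c("matrix", "meta")) {
  total_from <- match.arg(total_from)
  if (total_from == "meta") {
    if (!"total_reads" %in% colnames(counts$meta))
      stop("total_from = 'meta' requires a total_reads metadata column")
    tot <- stats::setNames(counts$meta$total_reads, counts$meta$library_id)
  } else {
    tot <- colSums(counts$counts)
  }
  zero <- names(tot)[tot <= 0]
  if (length(zero)) stop("zero-total library: ", paste(zero, collapse = ", "))
  tot
}

#' Transcripts-per-million normalisation
#'
#' `TPM = count / library_total * 1e6`. By default the library total is the
#' column sum of the supplied (confirmed) matrix; `total_from = "meta"` uses
#' the `total_reads` metadata column instead (total sequenced reads, when
#' the count matrix is a subset of the library).
#'
#' @param counts a [count_matrix()].
#' @param total_from `"matrix"` (column sums) or `"meta"`.
#' @return numeric matrix of TPM values, same dimnames as the counts.
#' @export
tpm_normalize <- function(counts, total_from = c("matrix", "meta")) {
  tot <- library_totals(counts, total_from)
  sweep(counts$counts, 2, tot[colnames(counts$counts)], "/") * 1e6
}

#' Log2 fold change with a pseudo-count
#'
#' `log2((tpm_treat + pseudo) / (tpm_ctrl + pseudo))`. The pseudo-count
#' (default 0.25 TPM) keeps the ratio finite when one side is zero; it is
#' small relative to the 10-read confirmation floor.
#'
#' @param tpm_treat,tpm_ctrl TPM values (vectors allowed).
#' @param pseudo positive pseudo-count in TPM units.
#' @return log2 fold change(s).
#' @export
log2_fold_change <- function(tpm_treat, tpm_ctrl, pseudo = 0.25) {
  if (pseudo <= 0) stop("pseudo must be > 0")
  if (any(tpm_treat < 0) || any(tpm_ctrl < 0)) stop("TPM values must be >= 0")
  log2((tpm_treat + pseudo) / (tpm_ctrl + pseudo))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The table is `rbind(c(a, b), c(c, d))`; in the DE pipeline row 1 is
#' (miRNA count in the heat library, heat library total minus that count)
#' and row 2 the same for control. The two-sided p-value is defined by
#' point-probability ordering: the sum of hypergeometric probabilities of
#' all tables with the same margins whose probability does not exceed that
#' of the observed table (ties included, guarded by a 1e-7 relative
#' tolerance as is conventional for this rule).
#'
#' @param a,b,c,d non-negative integer cells.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("negative cell in 2x2 table")
  if (any(cells != floor(cells))) stop("non-integer cell in 2x2 table")
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  if (k == 0 || k == m + n || m == 0 || n == 0) return(1)
  support <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  p <- sum(dens[dens <= obs * (1 + 1e-7)])
  min(1, p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, returned in input order, clipped at 1. This is a
#' validated front-end over `stats::p.adjust(method = "BH")`.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

contrast_libraries <- function(meta, genotype, timepoint) {
  heat <- meta$library_id[meta$genotype == genotype &
                          meta$timepoint_hours == timepoint &
                          meta$treatment == "heat"]
  ctrl <- meta$library_id[meta$genotype == genotype &
                          meta$timepoint_hours == timepoint &
                          meta$treatment == "control"]
  if (length(heat) != 1 || length(ctrl) != 1)
    stop(sprintf("contrast error: need exactly one heat and one control library for genotype '%s' at %g h",
                 genotype, timepoint))
  list(heat = heat, control = ctrl)
}

#' Call differential expression for one heat-vs-control contrast
#'
#' For every confirmed miRNA, the log2 fold change is computed on TPM
#' (heat over control, pseudo-counted) while Fisher's exact test runs on raw
#' counts against library totals; FDR is Benjamini-Hochberg within the
#' contrast. A miRNA is `up` when `log2FC >= lfc` with `p <= alpha` and
#' `fdr <= fdr_max`; `down` analogously with `log2FC <= -lfc`; otherwise
#' `ns`.
#'
#' @param tpm TPM matrix from [tpm_normalize()].
#' @param counts the matching [count_matrix()] of raw counts.
#' @param genotype,timepoint the contrast: one genotype, one timepoint.
#' @param lfc,alpha,fdr_max the three DE gates (defaults 1, 0.05, 0.05).
#' @param pseudo pseudo-count in TPM for the fold change.
#' @param total_from library total convention, see [tpm_normalize()].
#' @return data.frame with one row per miRNA: `mirna_id`, `genotype`,
#'   `timepoint_hours`, `log2_fold_change`, `p_value`, `fdr`, `direction`.
#' @export
call_de <- function(tpm, counts, genotype, timepoint,
                    lfc = 1, alpha = 0.05, fdr_max = 0.05,
                    pseudo = 0.25, total_from = c("matrix", "meta")) {
  libs <- contrast_libraries(counts$meta, genotype, timepoint)
  tot <- library_totals(counts, total_from)
  kh <- counts$counts[, libs$heat]
  kc <- counts$counts[, libs$control]
  th <- tot[[libs$heat]]
  tc <- tot[[libs$control]]
  l2fc <- log2_fold_change(tpm[, libs$heat], tpm[, libs$control], pseudo)
  p <- vapply(seq_along(kh),
              function(i) fisher_exact_2x2(kh[i], th - kh[i], kc[i], tc - kc[i]),
              numeric(1))
  fdr <- bh_adjust(p)
  direction <- rep("ns", length(p))
  sig <- p <= alpha & fdr <= fdr_max
  direction[sig & l2fc >= lfc] <- "up"
  direction[sig & l2fc <= -lfc] <- "down"
  data.frame(mirna_id = rownames(counts$counts),
             genotype = genotype, timepoint_hours = timepoint,
             log2_fold_change = unname(l2fc), p_value = p, fdr = fdr,
             direction = direction, stringsAsFactors = FALSE)
}

#' Call differential expression across every contrast in the design
#'
#' Runs [confirm_mirnas()], [tpm_normalize()] and [call_de()] for each
#' (genotype, timepoint) heat-vs-control pair present in the metadata.
#'
#' @inheritParams call_de
#' @param counts raw [count_matrix()].
#' @param min_reads confirmation threshold, see [confirm_mirnas()].
#' @return data.frame of stacked [call_de()] results.
#' @export
de_analysis <- function(counts, min_reads = 10, lfc = 1, alpha = 0.05,
                        fdr_max = 0.05, pseudo = 0.25,
                        total_from = c("matrix", "meta")) {
  conf <- confirm_mirnas(counts, min_reads)
  tpm <- tpm_normalize(conf, total_from)
  cells <- unique(conf$meta[, c("genotype", "timepoint_hours")])
  res <- lapply(seq_len(nrow(cells)), function(i)
    call_de(tpm, conf, cells$genotype[i], cells$timepoint_hours[i],
            lfc = lfc, alpha = alpha, fdr_max = fdr_max,
            pseudo = pseudo, total_from = total_from))
  do.call(rbind, res)
}

#' Classify DE miRNAs into four genotype categories
#'
#' With exactly two genotypes, every miRNA that is DE in at least one
#' contrast receives one category: DE in both genotypes with the same
#' (majority) sign in each is co-regulated in the same direction; DE in both
#' with differing signs (or an exact within-genotype up/down tie, which is
#' treated as opposite-capable) is co-regulated-opposite; DE in only one
#' genotype is that genotype's specific category.
#'
#' @param calls data.frame from [de_analysis()] (all contrasts).
#' @return data.frame with `mirna_id` and `category`.
#' @export
categorize_de <- function(calls) {
  genos <- unique(calls$genotype)
  if (length(genos) != 2)
    stop("categorize_de requires exactly two genotypes, got ", length(genos))
  de <- calls[calls$direction != "ns", , drop = FALSE]
  if (nrow(de) == 0)
    return(data.frame(mirna_id = character(), category = character(),
                      stringsAsFactors = FALSE))
  majority_sign <- function(dirs) {
    n_up <- sum(dirs == "up"); n_down <- sum(dirs == "down")
    if (n_up == n_down) return(NA_character_)   # tie: opposite-capable
    if (n_up > n_down) "up" else "down"
  }
  out <- lapply(unique(de$mirna_id), function(id) {
    sub <- de[de$mirna_id == id, , drop = FALSE]
    present <- intersect(genos, unique(sub$genotype))
    if (length(present) == 1) {
      cat <- paste0(present, "-specific")
    } else {
      s1 <- majority_sign(sub$direction[sub$genotype == genos[1]])
      s2 <- majority_sign(sub$direction[sub$genotype == genos[2]])
      cat <- if (!is.na(s1) && !is.na(s2) && s1 == s2)
        "co-regulated-same-direction" else "co-regulated-opposite"
    }
    data.frame(mirna_id = id, category = cat, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
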