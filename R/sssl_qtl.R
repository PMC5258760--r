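#' Substituted-segment interval and donor-genome-equivalent length
#'
#' From a line's graphical genotype: the stretch between two donor-type
#' markers (DD) counts as 100% donor, a stretch between a donor- and a
#' recipient-type marker (DR) as 50%, so the segment length is the DD core
#' span plus half of each DR flank. The interval runs from the recipient
#' marker before the first donor marker (or the chromosome start when the
#' donor run touches the first marker) to the recipient marker after the
#' last donor marker (or the chromosome end). When a donor run touches a
#' terminal marker, no recipient marker bounds the segment there; by the
#' default `terminal = "full"` convention the marker-to-end span counts as
#' fully donor, `terminal = "half"` counts it at 50%.
#'
#' @param genotypes a [genotype_matrix()].
#' @param line_id the line whose segment to estimate.
#' @param terminal `"full"` or `"half"`, see above.
#' @return one-row data.frame: `line_id`, `chrom`, `start_mb`, `end_mb`
#'   (half-open interval), `length_mb`, `flank_left`, `flank_right`
#'   (marker ids or `"Start"`/`"End"`).
#' @export
segment_interval <- function(genotypes, line_id, terminal = c("full", "half")) {
  terminal <- match.arg(terminal)
  codes <- genotypes$codes
  markers <- genotypes$markers
  if (!line_id %in% rownames(codes)) stop("unknown line: ", line_id)
  idx <- which(codes[line_id, ] == "D")
  if (length(idx) == 0)
    stop("no-segment error: line ", line_id, " carries no donor marker")
  chr <- markers$chrom[idx[1]]
  chr_idx <- which(markers$chrom == chr)
  pos <- markers$pos_mb[chr_idx]
  d_local <- match(idx, chr_idx)
  first_d <- min(d_local); last_d <- max(d_local)
  chrom_end <- attr(markers, "chrom_ends")[[chr]]
  core <- pos[last_d] - pos[first_d]
  term_w <- if (terminal == "full") 1 else 0.5
  if (first_d > 1) {
    start <- pos[first_d - 1]
    left_len <- 0.5 * (pos[first_d] - start)
    flank_left <- markers$marker_id[chr_idx[first_d - 1]]
  } else {
    start <- 0
    left_len <- term_w * pos[first_d]
    flank_left <- "Start"
  }
  if (last_d < length(chr_idx)) {
    end <- pos[last_d + 1]
    right_len <- 0.5 * (end - pos[last_d])
    flank_right <- markers$marker_id[chr_idx[last_d + 1]]
  } else {
    end <- chrom_end
    right_len <- term_w * (chrom_end - pos[last_d])
    flank_right <- "End"
  }
  data.frame(line_id = line_id, chrom = chr, start_mb = start, end_mb = end,
             length_mb = core + left_len + right_len,
             flank_left = flank_left, flank_right = flank_right,
             stringsAsFactors = FALSE)
}

#' Test one substitution line against the recurrent parent
#'
#' Two-sided two-sample t-test on replicate phenotype values. The default is
#' the pooled-variance form (equal variances assumed); `welch = TRUE`
#' switches to the Welch form. A QTL is declared when `p < alpha`.
#'
#' @param line_pheno,parent_pheno numeric replicate phenotype values
#'   (at least 2 each).
#' @param alpha declaration threshold (default 0.05).
#' @param welch use the Welch t-test instead of pooled variance.
#' @return list with `t_statistic`, `p_value`, `declared`.
#' @export
qtl_test <- function(line_pheno, parent_pheno, alpha = 0.05, welch = FALSE) {
  if (length(line_pheno) < 2 || length(parent_pheno) < 2)
    stop("qtl_test requires at least 2 replicates per group")
  if (stats::sd(line_pheno) == 0 && stats::sd(parent_pheno) == 0) {
    # degenerate: both samples constant; identical means -> no evidence
    if (mean(line_pheno) == mean(parent_pheno))
      return(list(t_statistic = 0, p_value = 1, declared = FALSE))
    return(list(t_statistic = Inf, p_value = 0, declared = 0 < alpha))
  }
  tt <- stats::t.test(line_pheno, parent_pheno, var.equal = !welch)
  list(t_statistic = unname(tt$statistic), p_value = tt$p.value,
       declared = tt$p.value < alpha)
}

#' QTL additive effect relative to the recurrent parent
#'
#' `effect = (line mean - parent mean) / 2` (the substituted segment carries
#' two donor allele doses), and `effect_pct = effect / parent mean * 100`.
#'
#' @param line_mean,parent_mean phenotype means.
#' @return list with `effect` and `effect_pct`.
#' @export
additive_effect <- function(line_mean, parent_mean) {
  effect <- (line_mean - parent_mean) / 2
  if (parent_mean == 0)
    stop("additive effect percentage undefined: parent phenotype is zero")
  list(effect = effect, effect_pct = effect / parent_mean * 100)
}

#' Detect heat-tolerance QTLs from an SSSL panel
#'
#' Every line with a donor segment is tested against the recurrent parent
#' with [qtl_test()]; declared lines are reported with their
#' [segment_interval()] and [additive_effect()]. Following the single-line
#' declaration rule, no multiple-testing correction is applied by default
#' (`adjust = "BH"` enables one). QTLs are named `qHT-<chromosome>`, with
#' suffixes `.2`, `.3`, ... when several declared lines on one chromosome
#' carry non-identical segments (identical segments share the name).
#'
#' @param genotypes a [genotype_matrix()] including the all-recipient parent.
#' @param phenotypes data.frame with columns `line_id` and `value`
#'   (replicate phenotype values, e.g. per-plant heat tolerance index or
#'   per-experiment means).
#' @param parent recurrent parent line id; by default the all-`R` line.
#' @param alpha declaration threshold.
#' @param welch,terminal,adjust see [qtl_test()], [segment_interval()].
#' @return data.frame with one row per declared line: `qtl_id`, `line_id`,
#'   `chrom`, `start_mb`, `end_mb`, `length_mb`, `flank_left`,
#'   `flank_right`, `t_statistic`, `p_value`, `additive_effect`,
#'   `additive_effect_pct`, `donor_direction`.
#' @export
detect_qtls <- function(genotypes, phenotypes, parent = NULL, alpha = 0.05,
                        welch = FALSE, terminal = c("full", "half"),
                        adjust = c("none", "BH")) {
  terminal <- match.arg(terminal); adjust <- match.arg(adjust)
  codes <- genotypes$codes
  if (is.null(parent)) {
    all_r <- rownames(codes)[apply(codes == "R", 1, all)]
    if (length(all_r) != 1)
      stop("could not identify a unique all-recipient parent line; pass `parent`")
    parent <- all_r
  }
  parent_pheno <- phenotypes$value[phenotypes$line_id == parent]
  if (length(parent_pheno) < 2)
    stop("missing or insufficient parent phenotype replicates for ", parent)
  lines <- setdiff(rownames(codes), parent)
  lines <- lines[apply(codes[lines, , drop = FALSE] == "D", 1, any)]
  rows <- lapply(lines, function(ln) {
    ph <- phenotypes$value[phenotypes$line_id == ln]
    if (length(ph) < 2) stop("insufficient phenotype replicates for line ", ln)
    tt <- qtl_test(ph, parent_pheno, alpha = alpha, welch = welch)
    seg <- segment_interval(genotypes, ln, terminal = terminal)
    eff <- additive_effect(mean(ph), mean(parent_pheno))
    cbind(seg, data.frame(t_statistic = tt$t_statistic, p_value = tt$p_value,
                          additive_effect = eff$effect,
                          additive_effect_pct = eff$effect_pct,
                          donor_direction = if (eff$effect >= 0)
                            "donor-increases" else "donor-decreases",
                          stringsAsFactors = FALSE))
  })
  res <- do.call(rbind, rows)
  if (is.null(res) || nrow(res) == 0) return(empty_qtl_frame())
  p_eff <- if (adjust == "BH") bh_adjust(res$p_value) else res$p_value
  res <- res[p_eff < alpha, , drop = FALSE]
  if (nrow(res) == 0) return(empty_qtl_frame())
  res <- res[order(suppressWarnings(as.numeric(res$chrom)), res$chrom,
                   res$start_mb), , drop = FALSE]
  res$qtl_id <- NA_character_
  for (chr in unique(res$chrom)) {
    i <- which(res$chrom == chr)
    seg_key <- paste(res$start_mb[i], res$end_mb[i])
    uniq <- match(seg_key, unique(seg_key))
    res$qtl_id[i] <- ifelse(uniq == 1, paste0("qHT-", chr),
                            paste0("qHT-", chr, ".", uniq))
  }
  rownames(res) <- NULL
  res[, c("qtl_id", setdiff(colnames(res), "qtl_id"))]
}

empty_qtl_frame <- function() {
  data.frame(qtl_id = character(), line_id = character(), chrom = character(),
             start_mb = numeric(), end_mb = numeric(), length_mb = numeric(),
             flank_left = character(), flank_right = character(),
             t_statistic = numeric(), p_value = numeric(),
             additive_effect = numeric(), additive_effect_pct = numeric(),
             donor_direction = character(), stringsAsFactors = FALSE)
}
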