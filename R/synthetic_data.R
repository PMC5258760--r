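# Synthetic inputs with the statistical structure the pipeline assumes:
# negative-binomial pooled small-RNA libraries with designated
# heat-responsive miRNAs, a substitution-line panel with planted QTL
# effects on a percent-scale heat phenotype, and a toy annotation placing
# planted target genes inside (and outside) the QTL intervals.

#' Simulation configuration
#'
#' Defaults echo the study design: two genotypes (heat-tolerant donor GXN,
#' heat-sensitive recurrent parent HJX) sampled at 1, 6 and 24 h of heat
#' stress; 23 substitution lines over 12 rice-sized chromosomes; four
#' planted QTLs on chromosomes 3, 6, 8 and 12 with additive effects 3.59,
#' 5.60, 9.24 and 2.72 on a percent-scale stress-fertility phenotype with
#' recurrent-parent mean 18.5 and replicate noise sd 1.5; overdispersed
#' count libraries (variance mu + phi mu^2, phi = 0.1) of one million reads
#' with 20 spiked heat-responsive miRNAs at |log2FC| = 2, three quarters of
#' them down-regulated, responding at all three timepoints of their
#' assigned genotype.
#'
#' @param seed integer seed; fixed seed gives identical output.
#' @param n_mirnas,n_de,spike_log2fc,spike_frac_down,depth,dispersion
#'   count-library parameters; `spike_log2fc` is recycled over the spiked
#'   miRNAs and gives each spike's magnitude.
#' @param genotypes,timepoints library design.
#' @param n_lines,markers_per_chrom,chrom_lengths_mb panel geometry.
#' @param qtl_chroms,qtl_effects planted QTLs (one carrier line each).
#' @param parent_mean,noise_sd,n_plants phenotype model.
#' @param n_genes,n_true_targets,frac_targets_in_qtl,n_unexpressed_targets,
#'   mirna_len,transcript_len,target_mismatches annotation/target model;
#'   planted sites carry 0-2 mismatches outside the seed region.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_mirnas = 200, n_de = 20, spike_log2fc = 2,
                       spike_frac_down = 0.75, depth = 1e6, dispersion = 0.1,
                       genotypes = c("GXN", "HJX"), timepoints = c(1, 6, 24),
                       n_lines = 23, markers_per_chrom = 8,
                       chrom_lengths_mb = c(43.3, 35.9, 36.4, 35.5, 29.9, 31.2,
                                            29.7, 28.4, 23.0, 23.2, 29.0, 27.5),
                       qtl_chroms = c(3, 6, 8, 12),
                       qtl_effects = c(3.59, 5.60, 9.24, 2.72),
                       parent_mean = 18.5, noise_sd = 1.5, n_plants = 10,
                       n_genes = 60, n_true_targets = 8,
                       frac_targets_in_qtl = 0.75, n_unexpressed_targets = 2,
                       mirna_len = 21, transcript_len = 300,
                       target_mismatches = 0:2) {
  if (depth <= 0) stop("library depth must be > 0")
  if (length(qtl_effects) != length(qtl_chroms))
    stop("qtl_effects and qtl_chroms must have equal length")
  if (length(qtl_chroms) > n_lines) stop("more planted QTLs than lines")
  if (n_de > n_mirnas) stop("more spiked miRNAs than miRNAs")
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

rnb <- function(n, mu, dispersion) {
  if (dispersion <= 0) stats::rpois(n, mu) else
    stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate pooled small-RNA count libraries with spiked heat responses
#'
#' Baseline miRNA abundances are log-normal; each library's expected counts
#' are the baseline scaled to the target depth, and observed counts are
#' negative-binomial (variance `mu + dispersion * mu^2`; the Poisson limit
#' at `dispersion = 0`). Spiked miRNAs -- drawn from the well-expressed
#' fraction (baseline expectation >= 50 reads) -- have their heat-library
#' means multiplied by `2^log2fc` at every timepoint of their assigned
#' genotype.
#'
#' @param config a [sim_config()].
#' @return list: `counts` (a [count_matrix()]), `truth` (data.frame
#'   `mirna_id`, `genotype`, `timepoint_hours`, `log2fc`).
#' @export
simulate_counts <- function(config) {
  withr::with_seed(config$seed, {
    n <- config$n_mirnas
    ids <- sprintf("syn-miR%03d", seq_len(n))
    base <- stats::rlnorm(n, meanlog = 0, sdlog = 1.25)
    base <- base / sum(base) * config$depth          # expected counts per library
    eligible <- which(base >= 50)
    if (length(eligible) < config$n_de)
      stop("too few well-expressed miRNAs to spike; increase depth or n_mirnas")
    spiked <- sort(sample(eligible, config$n_de))
    lfc_mag <- rep_len(abs(config$spike_log2fc), config$n_de)
    n_down <- round(config$spike_frac_down * config$n_de)
    sign <- sample(rep(c(-1, 1), c(n_down, config$n_de - n_down)))
    lfc <- lfc_mag * sign
    geno <- sample(config$genotypes, config$n_de, replace = TRUE)

    meta <- expand.grid(treatment = c("control", "heat"),
                        timepoint_hours = config$timepoints,
                        genotype = config$genotypes,
                        stringsAsFactors = FALSE)
    meta$library_id <- sprintf("%s_%gh_%s", meta$genotype,
                               meta$timepoint_hours,
                               ifelse(meta$treatment == "heat", "H", "C"))
    counts <- matrix(0L, n, nrow(meta), dimnames = list(ids, meta$library_id))
    for (j in seq_len(nrow(meta))) {
      mu <- base
      if (meta$treatment[j] == "heat") {
        hit <- spiked[geno == meta$genotype[j]]
        mu[hit] <- mu[hit] * 2^lfc[geno == meta$genotype[j]]
      }
      counts[, j] <- as.integer(rnb(n, mu, config$dispersion))
    }
    truth <- if (config$n_de == 0)
      data.frame(mirna_id = character(), genotype = character(),
                 timepoint_hours = numeric(), log2fc = numeric(),
                 stringsAsFactors = FALSE)
    else do.call(rbind, lapply(seq_len(config$n_de), function(i)
      data.frame(mirna_id = ids[spiked[i]], genotype = geno[i],
                 timepoint_hours = config$timepoints, log2fc = lfc[i],
                 stringsAsFactors = FALSE)))
    list(counts = count_matrix(counts, meta[, c("library_id", "genotype",
                                                "treatment", "timepoint_hours")]),
         truth = truth)
  })
}

#' Simulate a substitution-line panel with planted QTL effects
#'
#' Markers are evenly spaced on each chromosome; every line carries one
#' donor run, the runs tiling the genome, and one designated carrier line
#' per planted QTL has the QTL interval inside its donor core. Replicate
#' phenotypes are Normal(parent mean + 2 x effect for carriers, noise sd);
#' the all-recipient parent `HJX` is included.
#'
#' @param config a [sim_config()].
#' @return list: `markers` ([marker_map()]), `genotypes`
#'   ([genotype_matrix()]), `phenotypes` (data.frame `line_id`, `rep`,
#'   `value`), `truth` (data.frame `line_id`, `chrom`, `qtl_start_mb`,
#'   `qtl_end_mb`, `effect`), `parent` (line id).
#' @export
simulate_sssl_panel <- function(config) {
  withr::with_seed(config$seed + 1L, {
    n_chr <- length(config$chrom_lengths_mb)
    mpc <- config$markers_per_chrom
    map <- do.call(rbind, lapply(seq_len(n_chr), function(c) {
      len <- config$chrom_lengths_mb[c]
      pos <- round(seq(1, len - 1, length.out = mpc), 3)
      data.frame(marker_id = sprintf("SM%d_%d", c, seq_len(mpc)),
                 chrom = as.character(c), pos_mb = pos,
                 stringsAsFactors = FALSE)
    }))
    ends <- stats::setNames(config$chrom_lengths_mb, as.character(seq_len(n_chr)))
    mm <- marker_map(map, chrom_ends = ends)

    # donor runs of 2-3 markers tiling each chromosome; QTL carriers first
    run_len <- 3L
    slots_per_chr <- max(1L, mpc %/% run_len)
    line_chr <- integer(0); line_slot <- integer(0)
    for (pass in seq_len(ceiling(config$n_lines / n_chr))) {
      for (c in seq_len(n_chr)) {
        if (length(line_chr) >= config$n_lines) break
        slot <- ((pass - 1L) %% slots_per_chr) + 1L
        line_chr <- c(line_chr, c); line_slot <- c(line_slot, slot)
      }
    }
    # reorder so the first line on each planted-QTL chromosome is slot 1
    codes <- matrix("R", config$n_lines + 1L, nrow(mm),
                    dimnames = list(c(sprintf("SSSL%02d", seq_len(config$n_lines)),
                                      "HJX"), mm$marker_id))
    truth <- NULL
    qtl_carrier <- stats::setNames(rep(NA_character_, length(config$qtl_chroms)),
                                   as.character(config$qtl_chroms))
    for (i in seq_len(config$n_lines)) {
      c <- line_chr[i]; slot <- line_slot[i]
      idx_chr <- which(mm$chrom == as.character(c))
      lo <- (slot - 1L) * run_len + 1L
      hi <- min(lo + run_len - 1L, length(idx_chr))
      codes[i, idx_chr[lo:hi]] <- "D"
      key <- as.character(c)
      if (key %in% names(qtl_carrier) && is.na(qtl_carrier[key]) && slot == 1L)
        qtl_carrier[key] <- rownames(codes)[i]
    }
    if (anyNA(qtl_carrier)) stop("panel geometry failed to cover a planted QTL")
    gm <- genotype_matrix(codes, mm)

    effects <- stats::setNames(config$qtl_effects, as.character(config$qtl_chroms))
    truth <- do.call(rbind, lapply(names(qtl_carrier), function(key) {
      ln <- qtl_carrier[[key]]
      idx <- which(codes[ln, ] == "D")
      core <- range(mm$pos_mb[idx])
      data.frame(line_id = ln, chrom = key,
                 qtl_start_mb = core[1], qtl_end_mb = core[2],
                 effect = effects[[key]], stringsAsFactors = FALSE)
    }))
    line_effect <- stats::setNames(rep(0, config$n_lines + 1L), rownames(codes))
    line_effect[truth$line_id] <- truth$effect
    pheno <- do.call(rbind, lapply(rownames(codes), function(ln)
      data.frame(line_id = ln, rep = seq_len(config$n_plants),
                 value = stats::rnorm(config$n_plants,
                                      config$parent_mean + 2 * line_effect[[ln]],
                                      config$noise_sd),
                 stringsAsFactors = FALSE)))
    list(markers = mm, genotypes = gm, phenotypes = pheno, truth = truth,
         parent = "HJX")
  })
}

random_rna <- function(n_bases) {
  paste(sample(c("A", "C", "G", "U"), n_bases, replace = TRUE), collapse = "")
}

revcomp_rna <- function(seq) {
  chartr("ACGU", "UGCA", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

# replace the target base pairing miRNA position `pos` with a base that is
# neither the Watson-Crick partner nor a G:U wobble partner
mutate_site <- function(site, L, pos, mirna) {
  m <- substr(mirna, pos, pos)
  tpos <- L - pos + 1                       # site written 5'->3'
  partner <- chartr("ACGU", "UGCA", m)
  wobble <- switch(m, G = "U", U = "G", "")
  choices <- setdiff(c("A", "C", "G", "U"), c(partner, wobble))
  substr(site, tpos, tpos) <- sample(choices, 1)
  site
}

#' Simulate gene annotation, sequences and planted miRNA target sites
#'
#' Decoy genes are placed uniformly over the simulated genome; the planted
#' true-target genes are each assigned a distinct spiked miRNA and receive
#' an embedded target site (the reverse complement of the miRNA with 0-2
#' mismatches outside the seed region). A stated fraction of true targets
#' is placed inside the planted QTL intervals, the rest outside all of
#' them; some in-QTL targets are simulated as not expressed, so the
#' expression filter of the funnel is exercised. Gene expression profiles
#' over the (genotype, timepoint) cells are anti-correlated with the spike
#' profile of the paired miRNA for expressed true targets, and random noise
#' for decoys.
#'
#' @param config a [sim_config()]; the counts and panel are re-derived
#'   deterministically from the same config.
#' @return list: `genes` (gene models), `mirna_seqs`, `transcript_seqs`
#'   (named RNA vectors), `profiles` (long data.frame `id`, `cell`,
#'   `log2fc`), `abundance` (named TPM-like means), `truth_pairs`
#'   (data.frame `mirna_id`, `gene_id`, `in_qtl`, `expressed`,
#'   `n_mismatch`).
#' @export
simulate_annotation_and_targets <- function(config) {
  sim_counts <- simulate_counts(config)
  panel <- simulate_sssl_panel(config)
  withr::with_seed(config$seed + 2L, {
    if (config$transcript_len > min(config$chrom_lengths_mb) * 1e6)
      stop("gene longer than chromosome")
    spiked <- unique(sim_counts$truth$mirna_id)
    if (config$n_true_targets > length(spiked))
      stop("more true targets than spiked miRNAs")
    tgt_mirnas <- spiked[seq_len(config$n_true_targets)]
    mirna_seqs <- stats::setNames(
      vapply(rownames(sim_counts$counts$counts),
             function(i) random_rna(config$mirna_len), character(1)),
      rownames(sim_counts$counts$counts))

    n_chr <- length(config$chrom_lengths_mb)
    glen_mb <- config$transcript_len / 1e6
    place_uniform <- function(avoid_qtl) {
      repeat {
        c <- sample(n_chr, 1, prob = config$chrom_lengths_mb)
        start <- stats::runif(1, 0, config$chrom_lengths_mb[c] - glen_mb)
        if (!avoid_qtl) return(list(chrom = as.character(c), start = start))
        qt <- panel$truth[panel$truth$chrom == as.character(c), ]
        if (!nrow(qt) || all(start + glen_mb <= qt$qtl_start_mb |
                             start >= qt$qtl_end_mb))
          return(list(chrom = as.character(c), start = start))
      }
    }
    n_in <- round(config$frac_targets_in_qtl * config$n_true_targets)
    genes <- list(); seqs <- character(0); truth_pairs <- list()
    for (t in seq_len(config$n_true_targets)) {
      gid <- sprintf("SYNG_T%02d", t)
      in_qtl <- t <= n_in
      if (in_qtl) {
        q <- panel$truth[((t - 1) %% nrow(panel$truth)) + 1, ]
        start <- stats::runif(1, q$qtl_start_mb,
                              max(q$qtl_start_mb, q$qtl_end_mb - glen_mb))
        chrom <- q$chrom
      } else {
        p <- place_uniform(avoid_qtl = TRUE); chrom <- p$chrom; start <- p$start
      }
      mir <- mirna_seqs[[tgt_mirnas[t]]]
      site <- revcomp_rna(mir)
      n_mm <- sample(config$target_mismatches, 1)
      # mismatches only outside the seed-weighted region and off position 1
      free <- setdiff(seq_len(config$mirna_len), c(1, 2:13))
      for (pos in if (n_mm) sample(free, n_mm) else integer(0))
        site <- mutate_site(site, config$mirna_len, pos, mir)
      rest <- config$transcript_len - config$mirna_len
      at <- sample.int(rest - 1, 1)
      seq <- paste0(random_rna(at), site, random_rna(rest - at))
      seqs[gid] <- seq
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = gid, chrom = chrom, start_mb = start,
        end_mb = start + glen_mb,
        description = "synthetic planted target", stringsAsFactors = FALSE)
      truth_pairs[[length(truth_pairs) + 1L]] <- data.frame(
        mirna_id = tgt_mirnas[t], gene_id = gid, in_qtl = in_qtl,
        expressed = TRUE, n_mismatch = n_mm, stringsAsFactors = FALSE)
    }
    truth_pairs <- do.call(rbind, truth_pairs)
    # designated unexpressed targets: the first in-QTL ones
    if (config$n_unexpressed_targets > 0) {
      un <- which(truth_pairs$in_qtl)[seq_len(min(config$n_unexpressed_targets,
                                                  sum(truth_pairs$in_qtl)))]
      truth_pairs$expressed[un] <- FALSE
    }
    for (d in seq_len(config$n_genes)) {
      gid <- sprintf("SYNG_D%03d", d)
      p <- place_uniform(avoid_qtl = FALSE)
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = gid, chrom = p$chrom, start_mb = p$start,
        end_mb = p$start + glen_mb, description = "synthetic decoy gene",
        stringsAsFactors = FALSE)
      seqs[gid] <- random_rna(config$transcript_len)
    }
    genes <- do.call(rbind, genes)

    cells <- sprintf("%s_%gh", rep(config$genotypes, each = length(config$timepoints)),
                     rep(config$timepoints, length(config$genotypes)))
    mir_truth_profile <- function(mid) {
      pr <- stats::setNames(rep(0, length(cells)), cells)
      tr <- sim_counts$truth[sim_counts$truth$mirna_id == mid, ]
      if (nrow(tr))
        pr[sprintf("%s_%gh", tr$genotype, tr$timepoint_hours)] <- tr$log2fc
      pr
    }
    profiles <- list(); abundance <- numeric(0)
    for (i in seq_len(nrow(truth_pairs))) {
      gid <- truth_pairs$gene_id[i]
      pr <- -mir_truth_profile(truth_pairs$mirna_id[i]) +
        stats::rnorm(length(cells), 0, 0.2)
      profiles[[gid]] <- data.frame(id = gid, cell = cells, log2fc = pr,
                                    stringsAsFactors = FALSE)
      abundance[gid] <- if (truth_pairs$expressed[i]) 50 else 0
    }
    for (gid in grep("^SYNG_D", genes$gene_id, value = TRUE)) {
      profiles[[gid]] <- data.frame(id = gid, cell = cells,
                                    log2fc = stats::rnorm(length(cells), 0, 0.5),
                                    stringsAsFactors = FALSE)
      abundance[gid] <- stats::runif(1, 0, 30)
    }
    profiles <- do.call(rbind, c(profiles, list(make.row.names = FALSE)))
    list(genes = genes, mirna_seqs = mirna_seqs, transcript_seqs = seqs,
         profiles = profiles, abundance = abundance, truth_pairs = truth_pairs)
  })
}

#' Simulate every input of the pipeline at once
#'
#' @param config a [sim_config()].
#' @return list with elements `counts`, `counts_truth`, `panel`,
#'   `annotation`.
#' @export
simulate_all <- function(config) {
  sc <- simulate_counts(config)
  panel <- simulate_sssl_panel(config)
  ann <- simulate_annotation_and_targets(config)
  list(counts = sc$counts, counts_truth = sc$truth, panel = panel,
       annotation = ann)
}

#' Expression profiles of miRNAs measured from a TPM matrix
#'
#' Builds the log2 heat-over-control profile of each miRNA across the
#' (genotype, timepoint) cells of the design, on the same scale as the
#' simulated gene profiles (log2 relative to control).
#'
#' @param tpm TPM matrix from [tpm_normalize()].
#' @param meta library metadata (from a [count_matrix()]).
#' @param pseudo pseudo-count in TPM.
#' @return long data.frame `id`, `cell`, `log2fc`.
#' @export
mirna_expression_profiles <- function(tpm, meta, pseudo = 0.25) {
  cells <- unique(meta[, c("genotype", "timepoint_hours")])
  out <- list()
  for (i in seq_len(nrow(cells))) {
    g <- cells$genotype[i]; tp <- cells$timepoint_hours[i]
    heat <- meta$library_id[meta$genotype == g & meta$timepoint_hours == tp &
                            meta$treatment == "heat"]
    ctrl <- meta$library_id[meta$genotype == g & meta$timepoint_hours == tp &
                            meta$treatment == "control"]
    out[[i]] <- data.frame(id = rownames(tpm),
                           cell = sprintf("%s_%gh", g, tp),
                           log2fc = unname(log2_fold_change(tpm[, heat],
                                                            tpm[, ctrl], pseudo)),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
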