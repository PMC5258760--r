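# small in-code fixtures shared across test files

toy_meta <- function(libs = c("L1", "L2"), genotype = "GXN", timepoint = 6) {
  data.frame(library_id = libs, genotype = genotype,
             treatment = c("control", "heat"), timepoint_hours = timepoint,
             stringsAsFactors = FALSE)
}

toy_counts <- function(counts = rbind(c(10, 0), c(3, 7)),
                       mirnas = paste0("miR", seq_len(nrow(counts))),
                       libs = c("L1", "L2")) {
  dimnames(counts) <- list(mirnas, libs)
  count_matrix(counts, toy_meta(libs))
}

toy_marker_map <- function(pos = c(0, 1, 2, 3), chrom = "1", end = max(pos)) {
  marker_map(data.frame(marker_id = paste0("m", seq_along(pos)),
                        chrom = chrom, pos_mb = pos, stringsAsFactors = FALSE),
             stats::setNames(end, chrom))
}

toy_panel <- function(codes_str, pos = c(0, 1, 2, 3), end = max(pos)) {
  mm <- toy_marker_map(pos, end = end)
  codes <- do.call(rbind, lapply(codes_str, function(s) strsplit(s, "")[[1]]))
  rownames(codes) <- names(codes_str)
  colnames(codes) <- mm$marker_id
  genotype_matrix(codes, mm)
}
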