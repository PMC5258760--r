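#' @importFrom utils read.delim write.table
NULL

read_tsv_strict <- function(path, what = "table") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character")
  if (ncol(df) < 1) stop("malformed ", what, " file (no columns): ", path)
  df
}

as_count_integer <- function(x, row_id, col_id) {
  suppressWarnings(num <- as.numeric(x))
  if (is.na(num) || num < 0 || num != floor(num)) {
    stop(sprintf("count table format error: cell '%s' at miRNA '%s', library '%s' is not a non-negative integer",
                 x, row_id, col_id))
  }
  as.integer(num)
}

#' Construct and validate a miRNA count matrix
#'
#' Bundles an integer read-count matrix (miRNAs in rows, sequencing libraries
#' in columns) with per-library metadata: genotype label, treatment
#' (`control` or `heat`) and timepoint in hours after the start of heat
#' stress (1, 6 or 24, the sampling design used throughout).
#'
#' @param counts integer matrix with miRNA row names and library column names.
#' @param meta data.frame with columns `library_id`, `genotype`, `treatment`,
#'   `timepoint_hours`; an optional `total_reads` column carries the total
#'   sequenced reads per library for TPM normalisation.
#' @return an object of class `count_matrix`.
#' @export
count_matrix <- function(counts, meta) {
  if ((nrow(counts) > 0 && is.null(rownames(counts))) || is.null(colnames(counts)))
    stop("counts must have miRNA row names and library column names")
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  if (anyDuplicated(colnames(counts)))
    stop("library ids must be unique")
  if (anyDuplicated(rownames(counts)))
    stop("miRNA ids must be unique")
  storage.mode(counts) <- "integer"
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative integers")
  required <- c("library_id", "genotype", "treatment", "timepoint_hours")
  miss <- setdiff(required, colnames(meta))
  if (length(miss)) stop("library metadata missing columns: ", paste(miss, collapse = ", "))
  meta$timepoint_hours <- as.numeric(meta$timepoint_hours)
  absent <- setdiff(colnames(counts), meta$library_id)
  if (length(absent))
    stop("metadata error: no metadata for library ", paste(absent, collapse = ", "))
  meta <- meta[match(colnames(counts), meta$library_id), , drop = FALSE]
  rownames(meta) <- NULL
  if (!all(meta$treatment %in% c("control", "heat")))
    stop("treatment must be 'control' or 'heat'")
  if (!all(meta$timepoint_hours %in% c(1, 6, 24)))
    stop("timepoint_hours must be one of 1, 6, 24")
  cells <- unique(meta[, c("genotype", "timepoint_hours")])
  for (i in seq_len(nrow(cells))) {
    trt <- meta$treatment[meta$genotype == cells$genotype[i] &
                          meta$timepoint_hours == cells$timepoint_hours[i]]
    if (!all(c("control", "heat") %in% trt))
      stop(sprintf("library design error: genotype '%s' at %g h lacks a control/heat pair",
                   cells$genotype[i], cells$timepoint_hours[i]))
  }
  if ("total_reads" %in% colnames(meta))
    meta$total_reads <- as.numeric(meta$total_reads)
  structure(list(counts = counts, meta = meta), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d miRNAs x %d libraries (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$meta$genotype), collapse = ", ")))
  invisible(x)
}

#' Read a miRNA-by-library count table with library metadata
#'
#' Both files are tab-separated UTF-8 with a mandatory header; lines starting
#' with `#` are comments. Validation is strict: non-integer cells and
#' libraries without metadata raise errors naming the offending cell or
#' library, rather than being coerced silently.
#'
#' @param path count table: first column miRNA id, remaining columns one per
#'   library (header row carries library ids).
#' @param meta_path metadata table keyed by `library_id`.
#' @return a [count_matrix()].
#' @export
read_count_table <- function(path, meta_path) {
  df <- read_tsv_strict(path, "count")
  ids <- df[[1]]
  libs <- colnames(df)[-1]
  counts <- matrix(0L, nrow = nrow(df), ncol = length(libs),
                   dimnames = list(ids, libs))
  for (j in seq_along(libs)) {
    col <- df[[j + 1]]
    for (i in seq_along(col)) counts[i, j] <- as_count_integer(col[i], ids[i], libs[j])
  }
  meta <- read_tsv_strict(meta_path, "metadata")
  count_matrix(counts, meta)
}

#' Write a count matrix and its metadata to TSV
#'
#' @param x a [count_matrix()].
#' @param path,meta_path output files.
#' @export
write_count_table <- function(x, path, meta_path) {
  df <- data.frame(mirna_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' Construct and validate a marker map
#'
#' @param map data.frame with columns `marker_id`, `chrom`, `pos_mb`
#'   (megabases, non-negative).
#' @param chrom_ends named numeric vector of chromosome end coordinates in
#'   Mb; defaults to the last marker position per chromosome.
#' @return object of class `marker_map` (a data.frame with a `chrom_ends`
#'   attribute).
#' @export
marker_map <- function(map, chrom_ends = NULL) {
  required <- c("marker_id", "chrom", "pos_mb")
  miss <- setdiff(required, colnames(map))
  if (length(miss)) stop("marker map missing columns: ", paste(miss, collapse = ", "))
  map$pos_mb <- as.numeric(map$pos_mb)
  map$chrom <- as.character(map$chrom)
  if (anyNA(map$pos_mb) || any(map$pos_mb < 0))
    stop("marker positions must be non-negative numbers (Mb)")
  if (anyDuplicated(map$marker_id)) stop("marker ids must be unique")
  for (chr in unique(map$chrom)) {
    pos <- map$pos_mb[map$chrom == chr]
    if (any(diff(pos) <= 0))
      stop("marker ordering error: positions not strictly increasing on chromosome ", chr)
  }
  if (is.null(chrom_ends)) {
    chrom_ends <- tapply(map$pos_mb, map$chrom, max)
    chrom_ends <- stats::setNames(as.numeric(chrom_ends), names(chrom_ends))
  }
  for (chr in unique(map$chrom)) {
    if (!chr %in% names(chrom_ends))
      stop("no chromosome end given for chromosome ", chr)
    if (max(map$pos_mb[map$chrom == chr]) > chrom_ends[[chr]])
      stop("marker beyond chromosome end on chromosome ", chr)
  }
  rownames(map) <- NULL
  structure(map[, required], chrom_ends = chrom_ends, class = c("marker_map", "data.frame"))
}

#' Construct and validate an SSSL genotype matrix
#'
#' Each single-segment substitution line must carry exactly one maximal run
#' of donor (`D`) marker codes, contiguous within one chromosome; the
#' recurrent parent is all-`R`. Heterozygous or unknown codes are rejected
#' (the panel consists of fixed lines).
#'
#' @param codes character matrix of `D`/`R` codes, line ids in row names,
#'   marker ids in column names (in marker-map order).
#' @param markers a [marker_map()].
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(codes, markers) {
  if (is.null(rownames(codes)) || is.null(colnames(codes)))
    stop("genotype codes must have line row names and marker column names")
  if (!identical(colnames(codes), markers$marker_id))
    stop("genotype marker order must match the marker map")
  bad <- setdiff(unique(as.vector(codes)), c("D", "R"))
  if (length(bad))
    stop("genotype format error: unknown code(s) ", paste(bad, collapse = ", "),
         " (heterozygous and missing codes are not supported)")
  for (ln in rownames(codes)) {
    idx <- which(codes[ln, ] == "D")
    if (length(idx) == 0) next   # recurrent parent
    if (any(diff(idx) != 1) || length(unique(markers$chrom[idx])) != 1)
      stop("single-segment violation: line ", ln,
           " carries more than one donor run")
  }
  structure(list(codes = codes, markers = markers), class = "genotype_matrix")
}

#' Read marker map and SSSL genotype matrix
#'
#' @param map_path TSV with columns `marker_id`, `chrom`, `pos_mb` and an
#'   optional `chrom_end_mb` column (constant within a chromosome).
#' @param geno_path TSV, first column `line_id`, remaining columns one per
#'   marker with `D`/`R` codes.
#' @return list with elements `markers` ([marker_map()]) and `genotypes`
#'   ([genotype_matrix()]).
#' @export
read_genotypes <- function(map_path, geno_path) {
  map <- read_tsv_strict(map_path, "marker map")
  ends <- NULL
  if ("chrom_end_mb" %in% colnames(map)) {
    endv <- as.numeric(map$chrom_end_mb)
    ends <- tapply(endv, map$chrom, max)
    ends <- stats::setNames(as.numeric(ends), names(ends))
  }
  mm <- marker_map(map, chrom_ends = ends)
  g <- read_tsv_strict(geno_path, "genotype")
  codes <- as.matrix(g[, -1, drop = FALSE])
  rownames(codes) <- g[[1]]
  gm <- genotype_matrix(codes, mm)
  list(markers = mm, genotypes = gm)
}

#' Write marker map and genotype matrix to TSV
#' @param g list as returned by [read_genotypes()] or the simulator.
#' @param map_path,geno_path output files.
#' @export
write_genotypes <- function(g, map_path, geno_path) {
  mm <- g$markers
  out <- data.frame(mm, chrom_end_mb = attr(mm, "chrom_ends")[mm$chrom],
                    check.names = FALSE)
  write.table(out, map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  codes <- g$genotypes$codes
  df <- data.frame(line_id = rownames(codes), codes, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, geno_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(g)
}

#' Read per-plant spikelet counts
#'
#' Expected columns: `line_id`, `condition` (`control`/`heat`), `plant`,
#' `TSP` (total spikelets per plant), `FSP` (filled spikelets per plant).
#'
#' @param path TSV file.
#' @return validated data.frame of plant records.
#' @export
read_plant_records <- function(path) {
  df <- read_tsv_strict(path, "plant record")
  required <- c("line_id", "condition", "plant", "TSP", "FSP")
  miss <- setdiff(required, colnames(df))
  if (length(miss)) stop("plant records missing columns: ", paste(miss, collapse = ", "))
  df$TSP <- as.numeric(df$TSP); df$FSP <- as.numeric(df$FSP)
  validate_plant_records(df)
  df
}

validate_plant_records <- function(df) {
  if (!all(df$condition %in% c("control", "heat")))
    stop("plant condition must be 'control' or 'heat'")
  if (anyNA(df$TSP) || anyNA(df$FSP)) stop("non-numeric spikelet counts")
  if (any(df$TSP <= 0)) stop("TSP must be > 0 for every plant")
  if (any(df$FSP < 0 | df$FSP > df$TSP)) stop("FSP must satisfy 0 <= FSP <= TSP")
  invisible(df)
}

#' Read gene models from GFF3 or BED
#'
#' Coordinates are converted to the internal convention: 0-based, half-open,
#' in megabases. BED input is already 0-based half-open (base pairs); GFF3 is
#' 1-based closed. The annotation's own coordinate system is treated as
#' authoritative. For GFF3, only `gene`-type features are kept (all features
#' if none are typed `gene`).
#'
#' @param path file ending in `.gff3`/`.gff` or `.bed`.
#' @return data.frame with columns `gene_id`, `chrom`, `start_mb`, `end_mb`,
#'   `description`.
#' @export
read_gene_models <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!file.exists(path)) stop("file not found: ", path)
  empty <- data.frame(gene_id = character(), chrom = character(),
                      start_mb = numeric(), end_mb = numeric(),
                      description = character(), stringsAsFactors = FALSE)
  if (!nzchar(paste(readLines(path, warn = FALSE), collapse = ""))) {
    warning("empty gene model file: ", path)
    return(empty)
  }
  if (ext %in% c("gff3", "gff")) {
    gr <- rtracklayer::import(path, format = "gff3")
    if (length(gr) && "type" %in% colnames(S4Vectors::mcols(gr)) &&
        any(gr$type == "gene")) gr <- gr[gr$type == "gene"]
    ids <- if ("ID" %in% colnames(S4Vectors::mcols(gr))) as.character(gr$ID)
           else as.character(seq_along(gr))
    desc <- if ("description" %in% colnames(S4Vectors::mcols(gr)))
              as.character(gr$description) else rep("", length(gr))
    # GFF3 is 1-based closed: gene at 100..200 spans [99, 200) bp
    out <- data.frame(gene_id = ids,
                      chrom = as.character(GenomicRanges::seqnames(gr)),
                      start_mb = (GenomicRanges::start(gr) - 1) / 1e6,
                      end_mb = GenomicRanges::end(gr) / 1e6,
                      description = desc, stringsAsFactors = FALSE)
  } else if (ext == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    ids <- if ("name" %in% colnames(S4Vectors::mcols(gr))) as.character(gr$name)
           else as.character(seq_along(gr))
    # rtracklayer presents BED 1-based closed; undo to recover 0-based half-open bp
    out <- data.frame(gene_id = ids,
                      chrom = as.character(GenomicRanges::seqnames(gr)),
                      start_mb = (GenomicRanges::start(gr) - 1) / 1e6,
                      end_mb = GenomicRanges::end(gr) / 1e6,
                      description = "", stringsAsFactors = FALSE)
  } else {
    stop("gene model format error: unknown extension '", ext,
         "' (expected .gff3, .gff or .bed)")
  }
  if (any(out$start_mb >= out$end_mb)) stop("gene model with start >= end")
  rownames(out) <- NULL
  out
}

#' Write gene models as BED
#' @param genes data.frame as from [read_gene_models()].
#' @param path output `.bed` file.
#' @export
write_gene_models_bed <- function(genes, path) {
  bed <- data.frame(chrom = genes$chrom,
                    start = format(round(genes$start_mb * 1e6), scientific = FALSE, trim = TRUE),
                    end = format(round(genes$end_mb * 1e6), scientific = FALSE, trim = TRUE),
                    name = genes$gene_id)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(genes)
}

#' Read sequences from FASTA
#'
#' `T` and `U` are equivalent on input; sequences are returned in the RNA
#' alphabet, uppercased, as a named character vector.
#'
#' @param path FASTA file.
#' @return named character vector of RNA sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  seqs <- gsub("T", "U", seqs, fixed = TRUE)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Write sequences to FASTA
#' @param seqs named character vector (RNA or DNA alphabet).
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(seqs)
}
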