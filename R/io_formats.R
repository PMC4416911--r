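# File formats: FASTA haplotype alignments, segment/sample/Q-matrix/pileup
# TSVs, and the per-gene summary table.  All files use 1-based inclusive
# coordinates.

#' Read a segment annotation TSV
#'
#' Columns `kind` (`exon`/`intron`), `start`, `end`, 1-based inclusive.
#'
#' @param path File path.
#' @return Data frame of segments.
#' @export
read_segments <- function(path) {
  seg <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("kind", "start", "end") %in% names(seg)))
  seg
}

#' Read a phased haplotype alignment from FASTA
#'
#' Expects two records per individual with `_1`/`_2` suffixes; `N` and `-`
#' are preserved.  Invariant violations (length mismatch, odd haplotype
#' count) are errors naming the offender.
#'
#' @param path FASTA file.
#' @param annotation Optional segment TSV path (or data frame); the whole
#'   region is a single intron when absent.
#' @param gene_id Gene identifier (defaults to the file name).
#' @param outgroup_id Optional record name to split off as the outgroup.
#' @return A [hap_alignment()]; the outgroup sequence, when requested, is
#'   attached as attribute `outgroup`.
#' @export
read_alignment <- function(path, annotation = NULL, gene_id = NULL,
                           outgroup_id = NULL) {
  seqs <- as.character(Biostrings::readBStringSet(path))
  if (is.null(gene_id)) gene_id <- sub("\\.[^.]*$", "", basename(path))
  og <- NULL
  if (!is.null(outgroup_id) && outgroup_id %in% names(seqs)) {
    og <- unname(seqs[outgroup_id])
    seqs <- seqs[names(seqs) != outgroup_id]
  }
  gene <- NULL
  if (!is.null(annotation)) {
    seg <- if (is.data.frame(annotation)) annotation else
      read_segments(annotation)
    gene <- gene_region(gene_id, nchar(seqs[1L]), seg,
                        outgroup_id = if (is.null(outgroup_id))
                          NA_character_ else outgroup_id)
  }
  aln <- hap_alignment(seqs, gene)
  if (is.null(annotation)) aln$gene$gene_id <- gene_id
  attr(aln, "outgroup") <- og
  aln
}

#' Write a haplotype alignment (and optional outgroup) to FASTA
#'
#' @param aln A [hap_alignment()].
#' @param path Output path.
#' @param outgroup Optional outgroup sequence appended as a final record.
#' @return Invisibly, the path.
#' @export
write_alignment <- function(aln, path, outgroup = NULL) {
  seqs <- apply(aln$mat, 1L, paste, collapse = "")
  names(seqs) <- sprintf("%s_%d", aln$sample_id, aln$phase_index)
  if (!is.null(outgroup)) {
    nm <- if (is.na(aln$gene$outgroup_id)) "outgroup" else aln$gene$outgroup_id
    seqs <- c(seqs, stats::setNames(outgroup, nm))
  }
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 80L)
  invisible(path)
}

.sample_columns <- c("sample_id", "population_id", "altitude_class",
                     "latitude", "longitude", "elevation",
                     "temp_spring", "temp_summer", "prec_spring",
                     "prec_summer")

#' Read a sample metadata TSV
#'
#' Required columns: `sample_id`, `population_id`, `altitude_class` (H/L),
#' `latitude`, `longitude`, `elevation`, and the seasonal climate means
#' `temp_spring`, `temp_summer`, `prec_spring`, `prec_summer`.  Unknown
#' columns are ignored with a warning; invalid altitude classes or
#' out-of-range coordinates are errors.
#'
#' @param path File path.
#' @return Data frame of validated sample records (zero rows for an empty
#'   file).
#' @export
read_samples <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  extra <- setdiff(names(df), .sample_columns)
  if (length(extra) > 0L) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "))
    df <- df[, setdiff(names(df), extra), drop = FALSE]
  }
  missing_cols <- setdiff(.sample_columns[1:6], names(df))
  if (length(missing_cols) > 0L)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) return(df)
  if (!all(df$altitude_class %in% c("H", "L")))
    stop("altitude_class must be 'H' or 'L'; got: ",
         paste(unique(setdiff(df$altitude_class, c("H", "L"))), collapse = ", "))
  if (any(abs(df$latitude) > 90) || any(abs(df$longitude) > 180))
    stop("coordinates out of range")
  df
}

#' Write a sample metadata TSV
#'
#' @param samples Data frame of sample records.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_samples <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an ancestry (Q) matrix TSV
#'
#' Header `sample_id, Q1..QK`; each row must sum to 1 within 1e-6 with
#' proportions in `[0, 1]`.
#'
#' @param path File path.
#' @return Numeric matrix (rownames = sample ids).
#' @export
read_qmatrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(names(df)[1L] == "sample_id")
  q <- as.matrix(df[, -1L, drop = FALSE])
  rownames(q) <- df$sample_id
  if (any(q < 0 | q > 1)) stop("ancestry proportions must be in [0, 1]")
  if (any(abs(rowSums(q) - 1) > 1e-6))
    stop("ancestry rows must sum to 1 (tolerance 1e-6)")
  q
}

#' Write an ancestry (Q) matrix TSV
#'
#' @param q Matrix with sample ids as rownames.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_qmatrix <- function(q, path) {
  df <- data.frame(sample_id = rownames(q), q, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read aligned-read pileups from a TSV
#'
#' Columns `read_id`, `gene_id`, `sample_id`, `start`, `bases`; one
#' [read_pileup()] is built per gene x sample combination.
#'
#' @param path File path.
#' @param gene_lengths Named integer vector of region lengths per gene.
#' @return Named list (`gene:sample`) of [read_pileup()]s.
#' @export
read_pileups <- function(path, gene_lengths) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(bases = "character"))
  stopifnot(all(c("read_id", "gene_id", "sample_id", "start", "bases")
                %in% names(df)))
  out <- list()
  for (key in unique(paste(df$gene_id, df$sample_id, sep = ":"))) {
    parts <- strsplit(key, ":", fixed = TRUE)[[1L]]
    sub <- df[df$gene_id == parts[1L] & df$sample_id == parts[2L], ]
    out[[key]] <- read_pileup(parts[1L], parts[2L],
                              sub[, c("read_id", "start", "bases")],
                              gene_lengths[[parts[1L]]])
  }
  out
}

#' Write pileups to a TSV
#'
#' @param pileups List of [read_pileup()]s.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_pileups <- function(pileups, path) {
  df <- do.call(rbind, lapply(pileups, function(p)
    data.frame(read_id = p$reads$read_id, gene_id = p$gene_id,
               sample_id = p$sample_id, start = p$reads$start,
               bases = p$reads$bases)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a symmetric pairwise matrix TSV
#'
#' @param m Matrix with population dimnames.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(population_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
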