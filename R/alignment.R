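#' Gene region annotation
#'
#' Describes one sequenced gene region: its total alignment length `L` and an
#' ordered set of exon/intron segments that tile the region.  Coordinates in
#' files and in this object are 1-based inclusive.
#'
#' @param gene_id Character scalar, the orthologue tag naming the region.
#' @param length Integer, total alignment length in bp (`L`).
#' @param segments Data frame with columns `kind` (`"exon"` or `"intron"`),
#'   `start`, `end` (1-based inclusive).  Segments must tile `[1, length]`
#'   without gaps or overlap.
#' @param outgroup_id Character scalar naming the outgroup sequence, or `NA`.
#' @return An object of class `gene_region`.
#' @export
gene_region <- function(gene_id, length, segments, outgroup_id = NA_character_) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L)
  length <- as.integer(length)
  stopifnot(length >= 1L, is.data.frame(segments),
            all(c("kind", "start", "end") %in% names(segments)))
  segments <- segments[order(segments$start), , drop = FALSE]
  if (!all(segments$kind %in% c("exon", "intron")))
    stop("segment kind must be 'exon' or 'intron'")
  if (segments$start[1L] != 1L || segments$end[nrow(segments)] != length ||
      (nrow(segments) > 1L &&
       any(segments$start[-1L] != segments$end[-nrow(segments)] + 1L)))
    stop("segments must tile [1, length] without overlap in gene ", gene_id)
  structure(list(gene_id = gene_id, length = length,
                 segments = segments, outgroup_id = outgroup_id),
            class = "gene_region")
}

#' Phased haplotype alignment for one gene
#'
#' Container for a per-gene multiple alignment of phased haplotypes.  Each
#' diploid individual contributes exactly two rows (phases `_1`/`_2`, whose
#' order carries no meaning).  `N` is treated as missing data and `-` as an
#' alignment gap; both are excluded from effective sites downstream.
#'
#' @param seqs Named character vector of aligned sequences over
#'   `{A,C,G,T,N,-}`, two per individual; or a character matrix (rows =
#'   haplotypes, columns = positions).
#' @param gene A [gene_region()] annotation.  If `NULL`, the whole region is
#'   treated as a single intron.
#' @param sample_id,phase_index Optional vectors overriding the ids parsed
#'   from `names(seqs)` (suffixes `_1`/`_2`).
#' @return Object of class `hap_alignment` with elements `mat` (character
#'   matrix), `sample_id`, `phase_index`, `gene`, `n`.
#' @export
hap_alignment <- function(seqs, gene = NULL, sample_id = NULL, phase_index = NULL) {
  if (is.matrix(seqs)) {
    mat <- seqs
    ids <- rownames(mat)
  } else {
    ids <- names(seqs)
    if (is.null(ids)) stop("haplotype sequences must be named")
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) {
      bad <- ids[lens != stats::median(lens)][1L]
      stop("alignment length mismatch at record '", bad, "'")
    }
    mat <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(mat) <- ids
  }
  if (is.null(sample_id)) {
    sample_id <- sub("_[12]$", "", ids)
    phase_index <- ifelse(grepl("_2$", ids), 2L, 1L)
  }
  if (!all(mat %in% c("A", "C", "G", "T", "N", "-")))
    stop("sequences must be over {A,C,G,T,N,-}")
  tab <- table(sample_id)
  if (any(tab != 2L))
    stop("phase error: sample(s) ",
         paste(names(tab)[tab != 2L], collapse = ", "),
         " do not contribute exactly 2 haplotypes")
  if (is.null(gene)) {
    gene <- gene_region("region", ncol(mat),
                        data.frame(kind = "intron", start = 1L, end = ncol(mat)))
  }
  if (gene$length != ncol(mat))
    stop("alignment length ", ncol(mat), " does not match annotated L = ",
         gene$length)
  structure(list(mat = mat, sample_id = sample_id,
                 phase_index = as.integer(phase_index),
                 gene = gene, n = nrow(mat)),
            class = "hap_alignment")
}

#' @export
print.hap_alignment <- function(x, ...) {
  cat("<hap_alignment> gene", x$gene$gene_id, ":", x$n, "haplotypes x",
      x$gene$length, "bp,", sum(x$gene$segments$kind == "intron"),
      "intron segment(s)\n")
  invisible(x)
}

# Logical index of positions belonging to segments of `kind` ("intron",
# "exon", or "all").
segment_mask <- function(gene, kind = c("all", "intron", "exon")) {
  kind <- match.arg(kind)
  mask <- logical(gene$length)
  seg <- gene$segments
  if (kind != "all") seg <- seg[seg$kind == kind, , drop = FALSE]
  for (i in seq_len(nrow(seg))) mask[seg$start[i]:seg$end[i]] <- TRUE
  mask
}
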