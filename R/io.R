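#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased; the record identifier is the first
#' whitespace-delimited token of the header. Duplicate identifiers and empty
#' files are errors, as every downstream table is keyed by sequence id.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("format error: empty FASTA file at line 1")
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("format error: expected FASTA header at line ", first)
  }
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate sequence id: ", paste(unique(dup), collapse = ", "))
  }
  out <- toupper(as.character(seqs))
  names(out) <- ids
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("all sequences must be named")
  }
  x <- Biostrings::DNAStringSet(unname(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read transcript-model annotations
#'
#' Accepts a GFF3 table (1-based closed coordinates) or a BED6 table
#' (0-based half-open); the dialect is taken from the file extension
#' (`.gff`/`.gff3` vs `.bed`). Coordinates are normalized to the package's
#' single internal convention: 0-based half-open on the forward genomic
#' strand. Each model is joined to its spliced cDNA sequence.
#'
#' @param path Annotation file (GFF3 or BED6).
#' @param genome Named character vector of chromosome sequences.
#' @param cdna Named character vector of model cDNA sequences keyed by
#'   model id.
#' @return A `data.frame` with columns `model_id`, `chrom`, `strand`,
#'   `genomic_start`, `genomic_end` (0-based half-open), `cdna_seq`.
#' @export
read_models <- function(path, genome, cdna) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  id <- df$ID %||% df$Name %||% df$name
  if (is.null(id)) stop("annotation lacks a model identifier column")
  models <- data.frame(
    model_id = as.character(id),
    chrom = as.character(df$seqnames),
    strand = as.character(df$strand),
    genomic_start = df$start - 1L,  # GRanges is 1-based closed
    genomic_end = df$end,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(models$model_id)) {
    stop("duplicate model_id in annotation: ",
         paste(unique(models$model_id[duplicated(models$model_id)]),
               collapse = ", "))
  }
  if (!all(models$strand %in% c("+", "-"))) {
    stop("model strand must be '+' or '-'")
  }
  bad_chrom <- setdiff(models$chrom, names(genome))
  if (length(bad_chrom)) {
    stop("chromosome absent from genome: ", paste(bad_chrom, collapse = ", "))
  }
  clen <- nchar(genome)[models$chrom]
  if (any(models$genomic_start < 0L) || any(models$genomic_end > clen) ||
      any(models$genomic_start >= models$genomic_end)) {
    stop("coordinate error: model span outside chromosome bounds")
  }
  missing <- setdiff(models$model_id, names(cdna))
  if (length(missing)) {
    stop("model_id missing from cDNA FASTA: ",
         paste(missing, collapse = ", "))
  }
  models$cdna_seq <- toupper(unname(cdna[models$model_id]))
  too_long <- nchar(models$cdna_seq) >
    (models$genomic_end - models$genomic_start)
  if (any(too_long)) {
    stop("cDNA longer than genomic span for: ",
         paste(models$model_id[too_long], collapse = ", "))
  }
  models
}

#' Write transcript-model annotations as GFF3
#'
#' Internal 0-based half-open coordinates are converted back to the GFF
#' 1-based closed convention on write.
#'
#' @param models Model table as returned by [read_models()].
#' @param path Output path (`.gff3`).
#' @return Invisibly, `path`.
#' @export
write_models <- function(models, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = models$chrom,
    ranges = IRanges::IRanges(start = models$genomic_start + 1L,
                              end = models$genomic_end),
    strand = models$strand,
    type = "mRNA",
    ID = models$model_id
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read an observed DGE tag-count table
#'
#' Tab-separated with header columns `tag_id`, `tag_seq`, `count_CS`,
#' `count_CG`. Rows whose tag length differs from `tag_len` are dropped
#' with a warning reporting how many were rejected; negative counts and
#' duplicated tag sequences are errors.
#'
#' @param path TSV path.
#' @param tag_len Expected tag length.
#' @return `data.frame` with the four schema columns.
#' @export
read_tag_counts <- function(path, tag_len = 16L) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("tag_id", "tag_seq", "count_CS", "count_CG")
  if (!all(need %in% names(tab))) {
    stop("format error: tag table must have columns ",
         paste(need, collapse = ", "))
  }
  tab <- tab[need]
  tab$tag_seq <- toupper(tab$tag_seq)
  if (any(tab$count_CS < 0) || any(tab$count_CG < 0)) {
    stop("format error: negative tag count")
  }
  bad_len <- nchar(tab$tag_seq) != tag_len
  if (any(bad_len)) {
    warning(sum(bad_len), " row(s) dropped: tag length != ", tag_len)
    tab <- tab[!bad_len, , drop = FALSE]
  }
  if (anyDuplicated(tab$tag_seq)) {
    stop("duplicate tag_seq: ",
         paste(unique(tab$tag_seq[duplicated(tab$tag_seq)]), collapse = ", "))
  }
  rownames(tab) <- NULL
  tab
}

#' Write a result table as TSV
#'
#' Column order is preserved as given; numeric values are written with full
#' precision so that a write/read round trip reproduces values to 1e-9.
#'
#' @param x A `data.frame` (tag counts, expression records, test results).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(x, path) {
  stopifnot(is.data.frame(x))
  utils::write.table(format(x, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a TSV written by [write_results()]
#'
#' @param path TSV path.
#' @return `data.frame` with types inferred per column.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
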