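#' Reference genome container
#'
#' A single circular chromosome held as an upper-case A/C/G/T string.
#'
#' @param sequence Character scalar of A/C/G/T (case-insensitive).
#' @param name Sequence name (FASTA header).
#' @return An object of class `reference_genome` with fields `seq`,
#'   `length`, `name`.
#' @export
reference_genome <- function(sequence, name = "chr") {
  seq <- toupper(as.character(sequence))
  if (length(seq) != 1L || nchar(seq) == 0L) {
    stop("reference must be a single non-empty sequence", call. = FALSE)
  }
  bad <- gsub("[ACGT]", "", seq)
  if (nchar(bad) > 0L) {
    stop(sprintf("reference contains non-ACGT characters (first: '%s')",
                 substr(bad, 1, 1)), call. = FALSE)
  }
  structure(list(seq = seq, length = nchar(seq), name = as.character(name)),
            class = "reference_genome")
}

#' @export
print.reference_genome <- function(x, ...) {
  cat(sprintf("<reference_genome> %s: %d bp (circular)\n", x$name, x$length))
  invisible(x)
}

ref_base <- function(ref, pos) substring(ref$seq, pos, pos)

ref_slice <- function(ref, start, end) substr(ref$seq, start, end)

validate_gene_table <- function(genes, ref) {
  need <- c("name", "start", "end", "strand", "essential")
  if (!all(need %in% names(genes))) {
    stop("gene table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  genes$essential <- as.logical(as.integer(genes$essential) |
                                  genes$essential %in% c(TRUE, "TRUE"))
  if (any(genes$start > genes$end)) {
    bad <- genes$name[genes$start > genes$end][1L]
    stop(sprintf("gene '%s' has start > end", bad), call. = FALSE)
  }
  if (any(genes$start < 1L) || any(genes$end > ref$length)) {
    bad <- genes$name[genes$start < 1L | genes$end > ref$length][1L]
    stop(sprintf("gene '%s' extends outside the %d bp genome",
                 bad, ref$length), call. = FALSE)
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'", call. = FALSE)
  }
  len <- genes$end - genes$start + 1L
  if (any(len %% 3L != 0L)) {
    bad <- genes$name[len %% 3L != 0L][1L]
    stop(sprintf("CDS length of gene '%s' is not a multiple of 3", bad),
         call. = FALSE)
  }
  genes$coding_length <- len
  # overlapping CDS would make per-gene assignment ambiguous
  o <- order(genes$start)
  if (nrow(genes) > 1L &&
      any(genes$start[o][-1L] <= genes$end[o][-nrow(genes)])) {
    stop("gene models overlap; per-gene variant assignment requires disjoint CDS",
         call. = FALSE)
  }
  genes[, c("name", "start", "end", "strand", "essential", "coding_length")]
}

#' Load a reference genome and gene table
#'
#' Reads a single-sequence FASTA and a tab-delimited gene table with
#' columns `name`, `start`, `end` (1-based inclusive), `strand` (`+`/`-`)
#' and `essential` (0/1). Gene models are validated against the genome:
#' coordinates in range, CDS length divisible by 3, disjoint genes.
#' Minus-strand genes are later classified on the reverse complement.
#'
#' @param fasta_path Path to the reference FASTA (one sequence).
#' @param gene_table_path Path to the gene table TSV.
#' @return A list with `reference` (a `reference_genome`) and `genes`
#'   (validated data frame with an added `coding_length` column).
#' @export
load_annotation <- function(fasta_path, gene_table_path) {
  ss <- Biostrings::readDNAStringSet(fasta_path)
  if (length(ss) != 1L) {
    stop("expected exactly one sequence in the reference FASTA", call. = FALSE)
  }
  ref <- reference_genome(as.character(ss[[1L]]), name = names(ss)[1L])
  genes <- utils::read.delim(gene_table_path, stringsAsFactors = FALSE)
  genes <- validate_gene_table(genes, ref)
  list(reference = ref, genes = genes)
}

#' Coding-strand CDS sequence of a gene
#'
#' @param gene One row of a validated gene table.
#' @param ref A `reference_genome`.
#' @return Character scalar: the CDS read 5'->3' on the coding strand.
#' @export
gene_cds <- function(gene, ref) {
  s <- ref_slice(ref, gene$start, gene$end)
  if (gene$strand == "-") revcomp_chr(s) else s
}

#' Write a reference genome and gene table to disk
#'
#' @param reference A `reference_genome`.
#' @param genes Gene table data frame.
#' @param fasta_path,gene_table_path Output paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_reference <- function(reference, genes, fasta_path, gene_table_path) {
  ss <- Biostrings::DNAStringSet(reference$seq)
  names(ss) <- reference$name
  Biostrings::writeXStringSet(ss, fasta_path)
  out <- genes[, c("name", "start", "end", "strand", "essential")]
  out$essential <- as.integer(out$essential)
  utils::write.table(out, gene_table_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(list(fasta = fasta_path, genes = gene_table_path))
}
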