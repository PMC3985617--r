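#' @name classify
#' @rdname classify
#' @title Variant effect classification against gene models
#'
#' @description
#' Classifies each variant call into exactly one effect category by codon
#' arithmetic on the coding strand:
#' `start_lost`, `frameshift`, `inframe_indel`, `stop_gained`, `stop_lost`,
#' `nonsynonymous`, `synonymous`, or `intergenic` (variant not fully inside
#' any gene). Precedence: start_lost > frameshift/inframe_indel (indels,
#' by net length change mod 3) > stop_gained > stop_lost > nonsynonymous >
#' synonymous. Minus-strand genes are evaluated on the reverse complement;
#' translation uses the bacterial code (NCBI table 11). A substitution that
#' turns one valid initiation codon (ATG/GTG/TTG) into another is
#' synonymous (both initiate as Met); any change that leaves the first
#' codon outside the initiation set is `start_lost`.
NULL

MUTATION_CATEGORIES <- c("start_lost", "frameshift", "stop_gained",
                         "stop_lost", "inframe_indel", "nonsynonymous",
                         "synonymous", "intergenic")
LOF_CATEGORIES <- c("start_lost", "frameshift", "stop_gained")

# vectorised single-nucleotide substitution classification inside genes
classify_snv_vec <- function(pos, alt, start, end, strand, refseq) {
  gc <- genetic_code11()
  plus <- strand == "+"
  off <- ifelse(plus, pos - start, end - pos)          # 0-based coding offset
  codon_i <- off %/% 3L
  within <- off %% 3L
  cstart <- ifelse(plus, start + 3L * codon_i, end - 3L * codon_i - 2L)
  g_codon <- substring(refseq, cstart, cstart + 2L)
  codon <- ifelse(plus, g_codon,
                  chartr("ACGT", "TGCA",
                         paste0(substr(g_codon, 3, 3), substr(g_codon, 2, 2),
                                substr(g_codon, 1, 1))))
  alt_c <- ifelse(plus, alt, comp_base(alt))
  mut <- paste0(substr(codon, 1L, within), alt_c,
                substr(codon, within + 2L, 3L))

  old_stop <- codon %in% STOP_CODONS
  new_stop <- mut %in% STOP_CODONS
  cat <- ifelse(unname(gc[codon]) != unname(gc[mut]),
                "nonsynonymous", "synonymous")
  cat[!old_stop & new_stop] <- "stop_gained"
  cat[old_stop & !new_stop] <- "stop_lost"
  cat[old_stop & new_stop] <- "synonymous"
  first <- codon_i == 0L & codon %in% START_CODONS
  cat[first] <- ifelse(mut[first] %in% START_CODONS, "synonymous",
                       "start_lost")
  cat
}

# indels and multi-base substitutions, one variant at a time
classify_other <- function(pos, ref, alt, start, end, strand, refg) {
  gc <- genetic_code11()
  net <- nchar(alt) - nchar(ref)
  gs <- ref_slice(refg, start, end)
  rel <- pos - start + 1L
  mut_g <- paste0(substr(gs, 1L, rel - 1L), alt,
                  substr(gs, rel + nchar(ref), nchar(gs)))
  cds <- if (strand == "-") revcomp_chr(gs) else gs
  mut_cds <- if (strand == "-") revcomp_chr(mut_g) else mut_g

  if (substr(cds, 1, 3) %in% START_CODONS &&
      (nchar(mut_cds) < 3L || !(substr(mut_cds, 1, 3) %in% START_CODONS))) {
    return("start_lost")
  }
  if (net %% 3L != 0L) return("frameshift")
  if (net != 0L) return("inframe_indel")

  # equal-length multi-base substitution: compare the affected codon span
  if (strand == "+") {
    off1 <- pos - start
    off2 <- pos + nchar(ref) - 1L - start
  } else {
    off1 <- end - (pos + nchar(ref) - 1L)
    off2 <- end - pos
  }
  c0 <- off1 %/% 3L
  c1 <- off2 %/% 3L
  old_sp <- substr(cds, 3L * c0 + 1L, 3L * c1 + 3L)
  new_sp <- substr(mut_cds, 3L * c0 + 1L, 3L * c1 + 3L)
  starts_at <- 3L * seq(0L, c1 - c0) + 1L
  old_cod <- substring(old_sp, starts_at, starts_at + 2L)
  new_cod <- substring(new_sp, starts_at, starts_at + 2L)
  aa_old <- unname(gc[old_cod]); aa_new <- unname(gc[new_cod])
  if (c0 == 0L && old_cod[1L] %in% START_CODONS) {
    aa_old[1L] <- "M"
    aa_new[1L] <- "M"   # new first codon is in the start set (checked above)
  }
  if (any(aa_old != "*" & aa_new == "*")) return("stop_gained")
  if (any(aa_old == "*" & aa_new != "*")) return("stop_lost")
  if (any(aa_old != aa_new)) return("nonsynonymous")
  "synonymous"
}

# assign each call to the gene that fully contains it (NA = intergenic)
assign_genes <- function(calls, genes) {
  if (nrow(calls) == 0L) return(character(0))
  o <- order(genes$start)
  starts <- genes$start[o]; ends <- genes$end[o]; names_o <- genes$name[o]
  idx <- findInterval(calls$pos, starts)
  gene <- rep(NA_character_, nrow(calls))
  hit <- idx >= 1L
  vend <- calls$pos + nchar(calls$ref) - 1L
  inside <- hit & calls$pos >= starts[pmax(idx, 1L)] &
    vend <= ends[pmax(idx, 1L)]
  gene[inside] <- names_o[idx[inside]]
  gene
}

#' Classify a single variant
#'
#' @param pos 1-based genomic position (first base of `ref`).
#' @param ref,alt Reference and alternate alleles (A/C/G/T strings).
#' @param gene One row of a validated gene table, or `NULL` for a variant
#'   outside every gene.
#' @param reference A `reference_genome`.
#' @return A single category string (see [classify]).
#' @examples
#' \dontrun{classify_variant(10, "C", "T", genes[1, ], ref)}
#' @rdname classify
#' @export
classify_variant <- function(pos, ref, alt, gene, reference) {
  ref <- toupper(ref); alt <- toupper(alt)
  obs <- substr(reference$seq, pos, pos + nchar(ref) - 1L)
  if (obs != ref) {
    stop(sprintf("REF mismatch at position %d: expected '%s', genome has '%s'",
                 pos, ref, obs), call. = FALSE)
  }
  if (is.null(gene) || is.na(gene$name[1L])) return("intergenic")
  if (pos < gene$start || pos + nchar(ref) - 1L > gene$end) {
    return("intergenic")
  }
  if (nchar(ref) == 1L && nchar(alt) == 1L) {
    classify_snv_vec(pos, alt, gene$start, gene$end, gene$strand,
                     reference$seq)
  } else {
    classify_other(pos, ref, alt, gene$start, gene$end, gene$strand,
                   reference)
  }
}

#' Classify all calls of a cohort
#'
#' Adds `gene` (NA for intergenic) and `category` columns to the cohort's
#' call table. REF alleles are validated against the reference; a mismatch
#' raises an error naming the position.
#'
#' @param cohort A `variant_cohort`.
#' @param genes Validated gene table (see [load_annotation()]).
#' @param reference A `reference_genome`.
#' @return The cohort with classified calls, class `classified_cohort`.
#' @rdname classify
#' @export
classify_cohort <- function(cohort, genes, reference) {
  stopifnot(inherits(cohort, "variant_cohort"),
            inherits(reference, "reference_genome"))
  calls <- cohort$calls
  validate_refs(cohort, reference)
  calls$gene <- assign_genes(calls, genes)
  calls$category <- rep("intergenic", nrow(calls))
  inside <- !is.na(calls$gene)
  if (any(inside)) {
    gi <- match(calls$gene[inside], genes$name)
    is_snv <- nchar(calls$ref[inside]) == 1L & nchar(calls$alt[inside]) == 1L
    idx_snv <- which(inside)[is_snv]
    if (length(idx_snv) > 0L) {
      gs <- gi[is_snv]
      calls$category[idx_snv] <- classify_snv_vec(
        calls$pos[idx_snv], calls$alt[idx_snv],
        genes$start[gs], genes$end[gs], genes$strand[gs], reference$seq)
    }
    idx_oth <- which(inside)[!is_snv]
    for (j in seq_along(idx_oth)) {
      i <- idx_oth[j]
      g <- genes[match(calls$gene[i], genes$name), ]
      calls$category[i] <- classify_other(calls$pos[i], calls$ref[i],
                                          calls$alt[i], g$start, g$end,
                                          g$strand, reference)
    }
  }
  out <- variant_cohort(calls, clone_ids = cohort$clone_ids)
  class(out) <- c("classified_cohort", class(out))
  out
}
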