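#' Per-gene mutation recurrence tallies
#'
#' For every gene in the table, counts Distinct Mutations (unique
#' `(pos, ref, alt)` keys), Total Mutations (distinct times incidence,
#' i.e. the number of calls), the number of genomes hit (clones carrying at
#' least one mutation in the gene), and the loss-of-function fraction
#' (share of distinct mutations that are start_lost, frameshift or
#' stop_gained).
#'
#' @param cohort A `classified_cohort` (see [classify_cohort()]).
#' @param genes Validated gene table.
#' @return Data frame with one row per gene: `gene`, `coding_length`,
#'   `distinct`, `total`, `genomes_hit`, `lof_fraction`, sorted by
#'   `distinct` then `total` then `lof_fraction`, all descending.
#' @export
tally_genes <- function(cohort, genes) {
  stopifnot(inherits(cohort, "classified_cohort"))
  calls <- cohort$calls
  out <- data.frame(gene = genes$name,
                    coding_length = genes$coding_length,
                    distinct = 0L, total = 0L, genomes_hit = 0L,
                    lof_fraction = 0, stringsAsFactors = FALSE)
  ing <- calls[!is.na(calls$gene), , drop = FALSE]
  if (nrow(ing) > 0L) {
    key <- variant_key(ing)
    for (i in seq_len(nrow(out))) {
      g <- out$gene[i]
      sel <- ing$gene == g
      if (!any(sel)) next
      k <- key[sel]
      uk <- !duplicated(k)
      out$distinct[i] <- sum(uk)
      out$total[i] <- sum(sel)
      out$genomes_hit[i] <- length(unique(ing$clone_id[sel]))
      out$lof_fraction[i] <-
        sum(ing$category[sel][uk] %in% LOF_CATEGORIES) / sum(uk)
    }
  }
  out[order(-out$distinct, -out$total, -out$lof_fraction), , drop = FALSE]
}

#' Bin retained mutations along the genome
#'
#' Half-open genomic bins `[k*size, (k+1)*size)` from coordinate 0; a
#' position exactly on a boundary falls in the right-hand bin. Counts sum
#' to the number of calls binned.
#'
#' @param cohort A `variant_cohort` (classified or not).
#' @param bin_size Bin width in bp (default 2000).
#' @param genome_length Genome length in bp (defines the number of bins).
#' @return Data frame with `bin_start`, `bin_end`, `count`.
#' @export
window_bin <- function(cohort, bin_size = 2000L, genome_length) {
  stopifnot(inherits(cohort, "variant_cohort"))
  if (!is_count(bin_size) || bin_size < 1) {
    stop("`bin_size` must be a positive integer", call. = FALSE)
  }
  n_bins <- genome_length %/% bin_size + 1L
  idx <- cohort$calls$pos %/% bin_size           # 0-based bin index
  counts <- tabulate(idx + 1L, nbins = n_bins)
  data.frame(bin_start = (seq_len(n_bins) - 1L) * bin_size,
             bin_end = seq_len(n_bins) * bin_size,
             count = counts)
}

#' Mutation count in an arbitrary genomic window
#'
#' @param cohort A `variant_cohort`.
#' @param start,end Half-open window `[start, end)` in bp.
#' @return Integer count of calls with `start <= pos < end`.
#' @export
window_count <- function(cohort, start, end) {
  sum(cohort$calls$pos >= start & cohort$calls$pos < end)
}

#' Coding-length-normalized mutation enrichment per gene
#'
#' Within a scope of genes, each gene's expected share of mutations under
#' the uniform-per-coding-bp null is its coding length divided by the total
#' coding length of the scope. The observed share is its Total Mutations
#' over the scope total. A one-sided exact binomial test asks whether the
#' observed count exceeds expectation; Benjamini-Hochberg adjustment is
#' applied across the scope. Genes are ranked by distinct mutations, then
#' total, then LoF fraction (all descending).
#'
#' @param tallies Output of [tally_genes()].
#' @param scope Optional character vector restricting the scope (e.g. an
#'   operon); default is every gene in `tallies`.
#' @return Data frame with `gene`, `coding_length`, `distinct`, `total`,
#'   `lof_fraction`, `observed_share`, `expected_share`, `p_value`, `q_value`,
#'   `rank`.
#' @examples
#' \dontrun{gene_enrichment(tally_genes(cc, genes), scope = c("tolQ", "tolR", "tolA"))}
#' @export
gene_enrichment <- function(tallies, scope = NULL) {
  t <- if (is.null(scope)) tallies else tallies[tallies$gene %in% scope, ,
                                                drop = FALSE]
  if (nrow(t) == 0L) stop("empty gene scope", call. = FALSE)
  if (any(t$coding_length <= 0)) stop("scope coding lengths must be > 0",
                                      call. = FALSE)
  n_total <- sum(t$total)
  t$expected_share <- t$coding_length / sum(t$coding_length)
  t$observed_share <- if (n_total > 0) t$total / n_total else 0
  t$p_value <- vapply(seq_len(nrow(t)), function(i) {
    if (n_total == 0) return(1)
    stats::binom.test(t$total[i], n_total, t$expected_share[i],
                      alternative = "greater")$p.value
  }, numeric(1))
  t$q_value <- stats::p.adjust(t$p_value, method = "BH")
  o <- order(-t$distinct, -t$total, -t$lof_fraction)
  t <- t[o, , drop = FALSE]
  t$rank <- seq_len(nrow(t))
  rownames(t) <- NULL
  t
}

#' Fraction of clones carrying a mutation in a gene set
#'
#' @param cohort A `classified_cohort`.
#' @param gene_set Character vector of gene names (e.g. an operon).
#' @return A list with `fraction` (clones with >= 1 retained mutation in
#'   the set, over all clones), `n_hit`, `n_clones`, `hit_clones` and
#'   `missed_clones` (candidates for rare escape mechanisms).
#' @export
cohort_hit_fraction <- function(cohort, gene_set) {
  stopifnot(inherits(cohort, "classified_cohort"))
  calls <- cohort$calls
  hit <- unique(calls$clone_id[!is.na(calls$gene) &
                                 calls$gene %in% gene_set])
  missed <- setdiff(cohort$clone_ids, hit)
  list(fraction = length(hit) / cohort$n_clones,
       n_hit = length(hit), n_clones = cohort$n_clones,
       hit_clones = hit, missed_clones = missed)
}

# is circular interval [s, e] wholly inside the open arc (a, b) traversed
# forward (clockwise) from a to b? Intervals are assumed not to wrap.
arc_contains <- function(a, b, s, e, len) {
  if (a == b) return(FALSE)            # empty arc
  if (a < b) return(s > a & e < b)
  (s > a & e <= len) | (e < b & s >= 1)
}

#' Select duplication destination sites on a circular genome
#'
#' A duplicated operon protects against loss-of-function escape only while
#' both copies persist; a single crossover between the two identical copies
#' loops out one arc of the circular chromosome. A candidate destination is
#' therefore accepted only if each of the two arcs between the candidate
#' and the source locus contains at least one essential gene, so that
#' neither loop-out is viable. Candidates falling inside an annotated gene
#' are rejected with a reason.
#'
#' @param genes Validated gene table (with `essential` flags).
#' @param source_start,source_end Coordinates of the source locus (e.g. the
#'   wild-type operon) on the circular genome.
#' @param candidates Integer vector of candidate insertion positions.
#' @param genome_length Genome length in bp.
#' @return Data frame with `position`, `accepted`, `reason`.
#' @export
select_duplication_sites <- function(genes, source_start, source_end,
                                     candidates, genome_length) {
  ess <- genes[genes$essential, , drop = FALSE]
  res <- lapply(as.integer(candidates), function(pos) {
    if (pos < 1L || pos > genome_length) {
      return(data.frame(position = pos, accepted = FALSE,
                        reason = "outside genome"))
    }
    inside <- genes$start <= pos & pos <= genes$end
    if (any(inside)) {
      return(data.frame(position = pos, accepted = FALSE,
                        reason = sprintf("inside gene %s",
                                         genes$name[inside][1L])))
    }
    if (nrow(ess) == 0L) {
      return(data.frame(position = pos, accepted = FALSE,
                        reason = "no essential genes annotated"))
    }
    # forward arc source_end -> candidate, and candidate -> source_start
    arc1 <- any(mapply(arc_contains, s = ess$start, e = ess$end,
                       MoreArgs = list(a = source_end, b = pos,
                                       len = genome_length)))
    arc2 <- any(mapply(arc_contains, s = ess$start, e = ess$end,
                       MoreArgs = list(a = pos, b = source_start,
                                       len = genome_length)))
    if (arc1 && arc2) {
      data.frame(position = pos, accepted = TRUE, reason = "ok")
    } else {
      data.frame(position = pos, accepted = FALSE,
                 reason = paste0("no essential gene on ",
                                 if (!arc1 && !arc2) "either arc"
                                 else if (!arc1) "downstream arc"
                                 else "upstream arc"))
    }
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
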