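# Independent oracles used across the suite. These deliberately take a
# different computational route from the package internals.

BASES_ <- c("A", "C", "G", "T")
STARTS_ <- c("ATG", "GTG", "TTG")

# Exact genotype distribution after n_cycles of pattern resampling, by
# dynamic programming over all 2^L genotype states (L <= ~10 feasible,
# used here for L <= 3). Returns a probability vector indexed by genotype
# bitmask + 1 (locus 1 = most significant bit).
exact_pattern_distribution <- function(patterns, weights, n_cycles) {
  L <- ncol(patterns)
  nstate <- 2L^L
  pat_idx <- as.integer(patterns %*% 2^((L - 1):0))
  dist <- numeric(nstate)
  dist[1L] <- 1
  for (t in seq_len(n_cycles)) {
    new <- numeric(nstate)
    for (g in 0:(nstate - 1L)) {
      if (dist[g + 1L] == 0) next
      for (j in seq_along(pat_idx)) {
        gp <- bitwOr(g, pat_idx[j])
        new[gp + 1L] <- new[gp + 1L] + dist[g + 1L] * weights[j]
      }
    }
    dist <- new
  }
  dist
}

genotype_bitmask <- function(m) as.integer(m %*% 2^((ncol(m) - 1):0))

# Translate-and-diff classification oracle: reconstructs the full mutant
# CDS, translates reference and mutant with Biostrings (bacterial code),
# and derives the category from the protein diff and the length change.
oracle_classify <- function(pos, ref, alt, genes, refg) {
  n <- length(pos)
  out <- rep("intergenic", n)
  gidx <- rep(NA_integer_, n)
  vend <- pos + nchar(ref) - 1L
  for (k in seq_len(nrow(genes))) {
    sel <- pos >= genes$start[k] & vend <= genes$end[k]
    gidx[sel] <- k
  }
  inside <- which(!is.na(gidx))
  if (length(inside) == 0L) return(out)
  g <- genes[gidx[inside], , drop = FALSE]
  gseq <- substring(refg$seq, g$start, g$end)
  rel <- pos[inside] - g$start + 1L
  mut_g <- paste0(substr(gseq, 1L, rel - 1L), alt[inside],
                  substring(gseq, rel + nchar(ref[inside]), nchar(gseq)))
  rc <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  }
  minus <- g$strand == "-"
  cds <- ifelse(minus, rc(gseq), gseq)
  mut_cds <- ifelse(minus, rc(mut_g), mut_g)

  res <- character(length(inside))
  net <- nchar(mut_cds) - nchar(cds)
  sl <- substr(cds, 1, 3) %in% STARTS_ &
    (nchar(mut_cds) < 3L | !(substr(mut_cds, 1, 3) %in% STARTS_))
  res[sl] <- "start_lost"
  res[!sl & net %% 3L != 0L] <- "frameshift"
  res[!sl & net %% 3L == 0L & net != 0L] <- "inframe_indel"
  todo <- which(res == "")
  if (length(todo) > 0L) {
    gc11 <- Biostrings::getGeneticCode("11")
    p_old <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(cds[todo]), genetic.code = gc11))
    p_new <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(mut_cds[todo]), genetic.code = gc11))
    for (j in seq_along(todo)) {
      a <- strsplit(p_old[j], "", fixed = TRUE)[[1L]]
      b <- strsplit(p_new[j], "", fixed = TRUE)[[1L]]
      d <- which(a != b)
      res[todo[j]] <- if (length(d) == 0L) "synonymous"
        else if (any(b[d] == "*")) "stop_gained"
        else if (any(a[d] == "*")) "stop_lost"
        else "nonsynonymous"
    }
  }
  out[inside] <- res
  out
}

# Random VCF-style variants (SNVs, anchored indels, short multi-base
# substitutions) with REF taken from the genome.
random_variants <- function(refg, n, seed,
                            weights = c(snv = 0.6, del = 0.2,
                                        ins = 0.1, mnv = 0.1)) {
  withr::with_seed(seed, {
    type <- sample(names(weights), n, replace = TRUE, prob = weights)
    pos <- sample.int(refg$length - 6L, n, replace = TRUE)
    ref <- character(n); alt <- character(n)
    base_at <- function(p, w = 1L) substring(refg$seq, p, p + w - 1L)
    for (i in seq_len(n)) {
      if (type[i] == "snv") {
        ref[i] <- base_at(pos[i])
        alt[i] <- sample(setdiff(BASES_, ref[i]), 1L)
      } else if (type[i] == "del") {
        w <- sample(1:2, 1L)
        ref[i] <- base_at(pos[i], w + 1L)
        alt[i] <- base_at(pos[i])
      } else if (type[i] == "ins") {
        ref[i] <- base_at(pos[i])
        alt[i] <- paste0(ref[i],
                         paste(sample(BASES_, sample(1:3, 1L), replace = TRUE),
                               collapse = ""))
      } else {
        w <- sample(2:3, 1L)
        ref[i] <- base_at(pos[i], w)
        mb <- strsplit(ref[i], "", fixed = TRUE)[[1L]]
        j <- sample.int(w, 1L)
        mb[j] <- sample(setdiff(BASES_, mb[j]), 1L)
        alt[i] <- paste(mb, collapse = "")
      }
    }
    data.frame(pos = pos, ref = ref, alt = alt, type = type,
               stringsAsFactors = FALSE)
  })
}

# classify a variant table through the package's cohort path
classify_table <- function(variants, genes, refg) {
  co <- variant_cohort(data.frame(clone_id = sprintf("v%05d",
                                                     seq_len(nrow(variants))),
                                  variants[, c("pos", "ref", "alt")]))
  classify_cohort(co, genes, refg)$calls$category
}
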