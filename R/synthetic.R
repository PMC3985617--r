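#' Generate a synthetic circular reference genome with ORF gene models
#'
#' Builds a random circular chromosome of alternating-strand open reading
#' frames separated by random intergenic spacers. Each gene is a valid ORF:
#' an ATG start, stop-free internal codons and a single terminal stop
#' codon, so translation of every CDS yields a stop-free protein beginning
#' with M. Layout is spacer, then (gene, spacer) for each gene, so a
#' genome of `n` genes has `n + 1` spacers and each gene occupies
#' `3 * (codons_per_gene + 1)` bp (protein codons plus stop).
#'
#' @param n_genes Number of genes.
#' @param codons_per_gene Protein length in codons (scalar or vector,
#'   recycled); the CDS additionally carries one stop codon.
#' @param intergenic_bp Spacer length in bp (scalar or vector of length
#'   `n_genes + 1`).
#' @param essential_mask Logical vector flagging essential genes (recycled;
#'   default all `FALSE`).
#' @param seed Integer seed; the genome is deterministic per seed.
#' @return A list with `reference` (a `reference_genome`) and `genes`
#'   (validated gene table).
#' @examples
#' syn <- gen_reference(3, 100, 200, seed = 1)
#' syn$reference$length  # 3 * 303 + 4 * 200
#' @export
gen_reference <- function(n_genes, codons_per_gene, intergenic_bp,
                          essential_mask = FALSE, seed = NULL) {
  stopifnot(is_count(n_genes), n_genes >= 1)
  codons <- rep_len(as.integer(codons_per_gene), n_genes)
  spacers <- rep_len(as.integer(intergenic_bp), n_genes + 1L)
  if (any(codons < 2L) || any(spacers < 0L)) {
    stop("need >= 2 codons per gene and non-negative spacers", call. = FALSE)
  }
  essential <- rep_len(as.logical(essential_mask), n_genes)
  run_seeded(seed, {
    all_codons <- apply(expand.grid(BASES, BASES, BASES), 1L, paste,
                        collapse = "")
    sense_codons <- setdiff(all_codons, STOP_CODONS)
    rand_bases <- function(n) {
      if (n == 0L) "" else paste(sample(BASES, n, replace = TRUE),
                                 collapse = "")
    }
    parts <- character(0)
    rows <- vector("list", n_genes)
    at <- 0L   # bp emitted so far
    for (i in seq_len(n_genes)) {
      parts <- c(parts, rand_bases(spacers[i]))
      at <- at + spacers[i]
      orf <- paste0("ATG",
                    paste(sample(sense_codons, codons[i] - 1L,
                                 replace = TRUE), collapse = ""),
                    sample(STOP_CODONS, 1L))
      strand <- if (i %% 2L == 1L) "+" else "-"
      ins <- if (strand == "-") revcomp_chr(orf) else orf
      parts <- c(parts, ins)
      rows[[i]] <- data.frame(name = sprintf("gene%02d", i),
                              start = at + 1L, end = at + nchar(ins),
                              strand = strand, essential = essential[i],
                              stringsAsFactors = FALSE)
      at <- at + nchar(ins)
    }
    parts <- c(parts, rand_bases(spacers[n_genes + 1L]))
    ref <- reference_genome(paste(parts, collapse = ""), name = "synthetic_chr")
    genes <- validate_gene_table(do.call(rbind, rows), ref)
    list(reference = ref, genes = genes)
  })
}

# draw one causal mutation inside `gene`; returns list(pos, ref, alt)
# type: "frameshift" = 1-bp deletion mid-gene, "stop_gained", "start_lost",
# "nonsynonymous"
make_causal_mutation <- function(gene, ref, type) {
  cds <- gene_cds(gene, ref)
  n_codons <- nchar(cds) %/% 3L
  # coding-strand 0-based offset -> genomic position
  to_genomic <- function(off) {
    if (gene$strand == "+") gene$start + off else gene$end - off
  }
  if (type == "start_lost") {
    # mutate the second base of the start codon; ACG/GCG/TCG are never starts
    off <- 1L
    pos <- to_genomic(off)
    new_coding <- "C"
    alt <- if (gene$strand == "+") new_coding else comp_base(new_coding)
    return(list(pos = pos, ref = ref_base(ref, pos), alt = alt))
  }
  if (type == "frameshift") {
    # delete one base from the middle third, VCF-anchored on the previous base
    off <- sample(seq(n_codons, 2L * n_codons), 1L)  # coding offset of deleted base
    del_pos <- to_genomic(off)
    anchor <- del_pos - 1L
    return(list(pos = anchor,
                ref = ref_slice(ref, anchor, del_pos),
                alt = ref_base(ref, anchor)))
  }
  gc <- genetic_code11()
  # candidate internal codons (skip start and stop codons)
  cand <- sample(seq.int(2L, n_codons - 1L))
  for (ci in cand) {
    codon <- substr(cds, 3L * ci - 2L, 3L * ci)
    for (w in sample.int(3L)) {
      for (b in sample(setdiff(BASES, substr(codon, w, w)))) {
        mut <- codon
        substr(mut, w, w) <- b
        ok <- if (type == "stop_gained") {
          mut %in% STOP_CODONS
        } else {
          !(mut %in% STOP_CODONS) && gc[[mut]] != gc[[codon]]
        }
        if (ok) {
          off <- 3L * (ci - 1L) + (w - 1L)
          pos <- to_genomic(off)
          alt <- if (gene$strand == "+") b else comp_base(b)
          return(list(pos = pos, ref = ref_base(ref, pos), alt = alt))
        }
      }
    }
  }
  stop("no suitable codon found for causal mutation type ", type,
       call. = FALSE)
}

#' Generate a synthetic escape-clone cohort
#'
#' Emulates the statistical structure of a multi-clone counter-selection
#' escape experiment: each clone independently carries, with probability
#' `causal_hit_prob`, one causal mutation in a designated causal gene
#' (chosen with probability proportional to coding length; a
#' loss-of-function type -- frameshift, stop_gained or start_lost -- with
#' probability `causal_lof_bias`, otherwise a nonsynonymous SNV), plus a
#' Poisson(`passenger_rate`) number of passenger SNVs placed uniformly per
#' bp genome-wide, plus a fixed set of ancestral SNVs shared by every
#' clone (strain-background variants removable by [ancestral_filter()]).
#'
#' @param reference A `reference_genome`.
#' @param genes Validated gene table.
#' @param causal_genes Character vector of causal gene names.
#' @param n_clones Number of clones (default 96).
#' @param causal_hit_prob Probability a clone carries a causal mutation
#'   (default 0.93).
#' @param causal_lof_bias Fraction of causal mutations that are LoF types
#'   (default 0.75).
#' @param passenger_rate Expected passenger SNVs per clone (default 30,
#'   emulating a hypermutator background; scale with genome size).
#' @param ancestral_variants Number of shared ancestral SNVs (default 21).
#' @param seed Integer seed.
#' @return A `variant_cohort` with attributes `truth` (data frame:
#'   clone_id, causal_gene, causal_type; NA for clones without a causal
#'   hit) and `manifest` (list of all generation parameters).
#' @export
gen_escape_clones <- function(reference, genes, causal_genes,
                              n_clones = 96L, causal_hit_prob = 0.93,
                              causal_lof_bias = 0.75, passenger_rate = 30,
                              ancestral_variants = 21L, seed = NULL) {
  stopifnot(inherits(reference, "reference_genome"), is_count(n_clones),
            n_clones >= 1)
  assert_prob(causal_hit_prob, "causal_hit_prob")
  assert_prob(causal_lof_bias, "causal_lof_bias")
  if (!all(causal_genes %in% genes$name)) {
    stop("causal_genes must appear in the gene table", call. = FALSE)
  }
  run_seeded(seed, {
    cg <- genes[match(causal_genes, genes$name), , drop = FALSE]
    lof_types <- c("frameshift", "stop_gained", "start_lost")
    rand_snv <- function(n) {
      pos <- sample.int(reference$length, n, replace = TRUE)
      rb <- substring(reference$seq, pos, pos)
      alt <- vapply(rb, function(b) sample(setdiff(BASES, b), 1L),
                    character(1), USE.NAMES = FALSE)
      data.frame(pos = pos, ref = rb, alt = alt, stringsAsFactors = FALSE)
    }
    # ancestral SNVs are kept off the causal genes so a positional collision
    # cannot silently erase a planted causal mutation
    in_causal <- function(pos) {
      vapply(pos, function(p) any(cg$start <= p & p <= cg$end), logical(1))
    }
    ancestral <- if (ancestral_variants > 0L) {
      a <- rand_snv(ancestral_variants)
      a <- a[!duplicated(a$pos) & !in_causal(a$pos), , drop = FALSE]
      while (nrow(a) < ancestral_variants) {
        b <- rand_snv(ancestral_variants - nrow(a))
        a <- rbind(a, b[!in_causal(b$pos), , drop = FALSE])
        a <- a[!duplicated(a$pos), , drop = FALSE]
      }
      a
    } else {
      data.frame(pos = integer(), ref = character(), alt = character())
    }
    clone_ids <- sprintf("clone%03d", seq_len(n_clones))
    truth <- data.frame(clone_id = clone_ids,
                        causal_gene = NA_character_,
                        causal_type = NA_character_,
                        stringsAsFactors = FALSE)
    rows <- vector("list", n_clones)
    for (i in seq_len(n_clones)) {
      df <- ancestral
      if (nrow(cg) > 0L && stats::runif(1L) < causal_hit_prob) {
        g <- cg[sample.int(nrow(cg), 1L, prob = cg$coding_length), ]
        type <- if (stats::runif(1L) < causal_lof_bias) {
          sample(lof_types, 1L)
        } else "nonsynonymous"
        mut <- make_causal_mutation(g, reference, type)
        truth$causal_gene[i] <- g$name
        truth$causal_type[i] <- type
        df <- rbind(df, data.frame(pos = mut$pos, ref = mut$ref,
                                   alt = mut$alt, stringsAsFactors = FALSE))
      }
      k <- stats::rpois(1L, passenger_rate)
      if (k > 0L) df <- rbind(df, rand_snv(k))
      # one genotype per clone: drop secondary hits at an already-used position
      df <- df[!duplicated(df$pos), , drop = FALSE]
      df$clone_id <- rep(clone_ids[i], nrow(df))
      rows[[i]] <- df[, c("clone_id", "pos", "ref", "alt")]
    }
    cohort <- variant_cohort(do.call(rbind, rows), clone_ids = clone_ids)
    attr(cohort, "truth") <- truth
    attr(cohort, "manifest") <- list(
      n_clones = n_clones, causal_genes = causal_genes,
      causal_hit_prob = causal_hit_prob, causal_lof_bias = causal_lof_bias,
      passenger_rate = passenger_rate,
      ancestral_variants = nrow(ancestral), seed = seed)
    cohort
  })
}

#' Generate a synthetic selection quartet of growth curves
#'
#' Emulates kinetic monitoring of a selection experiment with a logistic
#' style growth model: cells grow exponentially after a lag with a fixed
#' doubling time, OD600 is proportional to cell count and saturates at a
#' carrying OD, and Gaussian noise is added per reading. Nonselective
#' cultures (RNS, CNS) grow from the full inoculum `n0`. The recombinant
#' selective culture (RS) grows from `n0 * recombinant_fraction`
#' (recombinants survive selection); the control selective culture (CS)
#' grows from its resistant (escape) subpopulation only, drawn as
#' Binomial(`n0`, `resistant_fraction`). Inocula below one cell yield no
#' growth within the horizon, so the curve is censored. The CS threshold
#' crossing trails CNS by about `doubling_time * log2(1/resistant_fraction)`
#' minutes.
#'
#' @param resistant_fraction Escape fraction of the control population
#'   under the counter-selective agent, in `[0, 1]`.
#' @param recombinant_fraction Surviving fraction of the recombinant
#'   population under selection (default 1).
#' @param n0 Inoculum cells per culture (default 1e6).
#' @param doubling_time Doubling time in minutes (default 30).
#' @param lag Lag phase in minutes (default 60).
#' @param carrying_od OD600 saturation (default 1.2).
#' @param od_per_cell OD600 per cell (default 1e-9, i.e. OD 1 ~ 1e9 cells).
#' @param noise_sd Gaussian reading noise SD in OD units (default 0.005;
#'   set 0 for deterministic curves).
#' @param horizon Kinetic horizon in minutes (default 2880, a 48 h course).
#' @param sample_interval Reading interval in minutes (default 10).
#' @param stochastic_inoculum Draw the CS resistant inoculum binomially
#'   (default); `FALSE` uses the expectation `n0 * resistant_fraction`.
#' @param seed Integer seed.
#' @return A named list of four `growth_curve` objects: `rs`, `cs`, `rns`,
#'   `cns`.
#' @examples
#' q <- gen_growth_quartet(1e-6, noise_sd = 0, seed = 1)
#' nsa(quartet_from_curves(q$rs, q$cs, q$rns, q$cns))
#' @export
gen_growth_quartet <- function(resistant_fraction, recombinant_fraction = 1,
                               n0 = 1e6, doubling_time = 30, lag = 60,
                               carrying_od = 1.2, od_per_cell = 1e-9,
                               noise_sd = 0.005, horizon = 2880,
                               sample_interval = 10,
                               stochastic_inoculum = TRUE, seed = NULL) {
  assert_prob(resistant_fraction, "resistant_fraction")
  assert_prob(recombinant_fraction, "recombinant_fraction")
  stopifnot(n0 > 0, doubling_time > 0, lag >= 0, carrying_od > 0,
            od_per_cell > 0, noise_sd >= 0, horizon > 0, sample_interval > 0)
  run_seeded(seed, {
    times <- seq(0, horizon, by = sample_interval)
    one_curve <- function(n_start, label) {
      n_t <- if (n_start < 1) {           # no viable founder cell
        rep(0, length(times))
      } else {
        pmin(n_start * 2^(pmax(times - lag, 0) / doubling_time),
             carrying_od / od_per_cell)
      }
      od <- pmin(carrying_od, od_per_cell * n_t)
      if (noise_sd > 0) od <- pmax(0, od + stats::rnorm(length(od), 0,
                                                        noise_sd))
      growth_curve(times, od, label = label)
    }
    n_cs <- if (stochastic_inoculum) {
      stats::rbinom(1L, size = as.integer(n0), prob = resistant_fraction)
    } else {
      n0 * resistant_fraction
    }
    list(rs = one_curve(n0 * recombinant_fraction, "RS"),
         cs = one_curve(n_cs, "CS"),
         rns = one_curve(n0, "RNS"),
         cns = one_curve(n0, "CNS"))
  })
}

#' Generate synthetic plating experiments
#'
#' Colony counts are Poisson with mean `true_frequency * cells_plated`
#' per replicate (the binomial limit appropriate when the expected count
#' is small and the number of cells plated is huge), capped at
#' `cells_plated`.
#'
#' @param true_frequency True escape frequency in `[0, 1]`.
#' @param cells_plated Cells plated per replicate.
#' @param n_replicates Number of independent replicates.
#' @param agents Character vector of agents (stored comma-joined).
#' @param strain Strain label.
#' @param seed Integer seed.
#' @return Data frame with columns `strain`, `agents`, `cells_plated`,
#'   `colonies`, `replicate`.
#' @export
gen_plating <- function(true_frequency, cells_plated, n_replicates = 4L,
                        agents = "colE1", strain = "synthetic",
                        seed = NULL) {
  assert_prob(true_frequency, "true_frequency")
  stopifnot(cells_plated > 0, is_count(n_replicates), n_replicates >= 1)
  run_seeded(seed, {
    colonies <- pmin(stats::rpois(n_replicates,
                                  true_frequency * cells_plated),
                     cells_plated)
    data.frame(strain = strain,
               agents = paste(agents, collapse = ","),
               cells_plated = cells_plated,
               colonies = colonies,
               replicate = seq_len(n_replicates),
               stringsAsFactors = FALSE)
  })
}

#' Generate a single-cycle genotype matrix from a conversion model
#'
#' Draws `n` single-cycle conversion patterns, the synthetic counterpart
#' of a mascPCR clone-by-locus genotyping table after one CoS-MAGE cycle.
#'
#' @param model A `conversion_model`.
#' @param n Number of clones.
#' @param seed Integer seed.
#' @return 0/1 integer matrix with locus column names `L01..`.
#' @export
gen_genotype_population <- function(model, n, seed = NULL) {
  m <- draw_patterns(model, n, seed = seed)
  colnames(m) <- sprintf("L%02d", seq_len(ncol(m)))
  rownames(m) <- sprintf("clone%04d", seq_len(nrow(m)))
  m
}

#' Read/write clone-by-locus genotype matrices as TSV
#'
#' TSV with a header row of locus names and one 0/1 row per clone (first
#' column `clone`).
#'
#' @param genotypes 0/1 matrix with locus column names.
#' @param path File path.
#' @return `write_genotype_matrix()` returns `path` invisibly;
#'   `read_genotype_matrix()` returns the 0/1 integer matrix.
#' @export
write_genotype_matrix <- function(genotypes, path) {
  df <- data.frame(clone = rownames(genotypes) %||%
                     sprintf("clone%04d", seq_len(nrow(genotypes))),
                   genotypes, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_genotype_matrix
#' @export
read_genotype_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"clone" %in% names(df)) {
    stop("genotype TSV must have a 'clone' column", call. = FALSE)
  }
  m <- as.matrix(df[, setdiff(names(df), "clone"), drop = FALSE])
  storage.mode(m) <- "integer"
  if (anyNA(m) || !all(m %in% c(0L, 1L))) {
    stop("genotype TSV cells must be 0/1 (ragged or non-binary rows?)",
         call. = FALSE)
  }
  rownames(m) <- df$clone
  m
}
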