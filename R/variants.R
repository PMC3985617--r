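#' Multi-clone variant cohort
#'
#' Container for per-clone variant calls against a shared reference. Calls
#' are keyed by `(pos, ref, alt)`; clones with zero calls are retained in
#' `clone_ids` so cohort-level fractions use the true denominator.
#'
#' @param calls Data frame with columns `clone_id`, `pos` (1-based),
#'   `ref`, `alt`.
#' @param clone_ids Character vector of all clone identifiers (defaults to
#'   the clones present in `calls`).
#' @return An object of class `variant_cohort` with fields `calls`,
#'   `clone_ids`, `n_clones`.
#' @export
variant_cohort <- function(calls, clone_ids = NULL) {
  need <- c("clone_id", "pos", "ref", "alt")
  if (!all(need %in% names(calls))) {
    stop("calls need columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  calls$clone_id <- as.character(calls$clone_id)
  calls$pos <- as.integer(calls$pos)
  calls$ref <- toupper(as.character(calls$ref))
  calls$alt <- toupper(as.character(calls$alt))
  if (nrow(calls) > 0L &&
      (any(!nzchar(calls$ref)) || any(!nzchar(calls$alt)))) {
    stop("ref/alt alleles must be non-empty", call. = FALSE)
  }
  clone_ids <- as.character(clone_ids %||% unique(calls$clone_id))
  if (length(clone_ids) < 1L) stop("cohort has no clones", call. = FALSE)
  if (!all(calls$clone_id %in% clone_ids)) {
    stop("calls reference clones missing from clone_ids", call. = FALSE)
  }
  rownames(calls) <- NULL
  structure(list(calls = calls, clone_ids = clone_ids,
                 n_clones = length(clone_ids)),
            class = "variant_cohort")
}

#' @export
print.variant_cohort <- function(x, ...) {
  cat(sprintf("<variant_cohort> %d calls across %d clones (%d distinct variants)\n",
              nrow(x$calls), x$n_clones,
              length(unique(variant_key(x$calls)))))
  invisible(x)
}

variant_key <- function(calls) {
  paste(calls$pos, calls$ref, calls$alt, sep = ":")
}

#' Load per-clone VCF files into a variant cohort
#'
#' Reads a VCF v4.x subset (CHROM, POS, ID, REF, ALT) per clone.
#' Multi-allelic records are split into one call per ALT allele; duplicate
#' records within a clone are deduplicated with a warning. When a
#' reference genome is supplied, every REF field is checked against it and
#' a mismatch raises an error naming the position.
#'
#' @param vcf_paths Character vector of VCF paths, one per clone. Names are
#'   used as clone ids (defaults to file base names).
#' @param reference Optional `reference_genome` for REF validation.
#' @return A `variant_cohort`.
#' @export
load_variants <- function(vcf_paths, reference = NULL) {
  if (length(vcf_paths) < 1L) stop("no VCF paths given", call. = FALSE)
  ids <- names(vcf_paths) %||% sub("\\.vcf(\\.gz)?$", "", basename(vcf_paths))
  if (is.null(names(vcf_paths))) names(vcf_paths) <- ids
  per_clone <- lapply(seq_along(vcf_paths), function(i) {
    v <- vcfR::read.vcfR(vcf_paths[[i]], verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                         dimnames = list(NULL, names(fix)))
    if (nrow(fix) == 0L) {
      return(data.frame(clone_id = character(), pos = integer(),
                        ref = character(), alt = character(),
                        stringsAsFactors = FALSE))
    }
    alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
    n_alt <- lengths(alts)
    df <- data.frame(clone_id = ids[i],
                     pos = rep(as.integer(fix[, "POS"]), n_alt),
                     ref = rep(fix[, "REF"], n_alt),
                     alt = unlist(alts, use.names = FALSE),
                     stringsAsFactors = FALSE)
    dup <- duplicated(variant_key(df))
    if (any(dup)) {
      warning(sprintf("clone %s: %d duplicate record(s) removed",
                      ids[i], sum(dup)), call. = FALSE)
      df <- df[!dup, , drop = FALSE]
    }
    df
  })
  calls <- do.call(rbind, per_clone)
  cohort <- variant_cohort(calls, clone_ids = ids)
  if (!is.null(reference)) validate_refs(cohort, reference)
  cohort
}

validate_refs <- function(cohort, reference) {
  calls <- cohort$calls
  if (nrow(calls) == 0L) return(invisible(TRUE))
  obs <- substring(reference$seq, calls$pos, calls$pos + nchar(calls$ref) - 1L)
  bad <- which(obs != calls$ref)
  if (length(bad) > 0L) {
    stop(sprintf("REF mismatch at position %d: VCF says '%s', genome has '%s'",
                 calls$pos[bad[1L]], calls$ref[bad[1L]], obs[bad[1L]]),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Write one VCF v4.2 file per clone
#'
#' Emits minimal single-sample VCFs (CHROM POS ID REF ALT QUAL FILTER
#' INFO), sorted by position, readable by any VCF parser.
#'
#' @param cohort A `variant_cohort`.
#' @param dir Output directory (created if needed).
#' @param reference A `reference_genome` (for the contig header line).
#' @return Named character vector of written paths (one per clone,
#'   including clones with zero calls).
#' @export
write_clone_vcfs <- function(cohort, dir, reference) {
  stopifnot(inherits(cohort, "variant_cohort"),
            inherits(reference, "reference_genome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s,length=%d>", reference$name,
                      reference$length),
              paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", sep = "\t"))
  paths <- vapply(cohort$clone_ids, function(id) {
    d <- cohort$calls[cohort$calls$clone_id == id, , drop = FALSE]
    d <- d[order(d$pos), , drop = FALSE]
    path <- file.path(dir, paste0(id, ".vcf"))
    lines <- if (nrow(d) > 0L) {
      paste(reference$name, d$pos, ".", d$ref, d$alt, ".", "PASS", ".",
            sep = "\t")
    } else character()
    writeLines(c(header, lines), path)
    path
  }, character(1))
  paths
}

#' Consensus variants across multiple caller outputs
#'
#' Keeps, per clone, the variants reported by at least `min_callers` of the
#' supplied callsets (matching on `(pos, ref, alt)`), the usual consensus
#' rule when several variant callers are run on the same alignments.
#'
#' @param callsets List of `variant_cohort` objects, one per caller, on the
#'   same clones and reference.
#' @param min_callers Minimum number of callsets a variant must appear in.
#' @return A `variant_cohort` of consensus calls.
#' @export
merge_callsets <- function(callsets, min_callers) {
  if (length(callsets) < 1L) stop("no callsets given", call. = FALSE)
  if (!all(vapply(callsets, inherits, logical(1), "variant_cohort"))) {
    stop("callsets must be variant_cohort objects", call. = FALSE)
  }
  if (!is_count(min_callers) || min_callers < 1 ||
      min_callers > length(callsets)) {
    stop(sprintf("min_callers must be in [1, %d]", length(callsets)),
         call. = FALSE)
  }
  clone_ids <- callsets[[1L]]$clone_ids
  keyed <- lapply(callsets, function(cs) {
    k <- paste(cs$calls$clone_id, variant_key(cs$calls), sep = "|")
    unique(k)
  })
  support <- table(unlist(keyed, use.names = FALSE))
  keep <- names(support)[support >= min_callers]
  # recover call rows from the first callset carrying each kept key
  all_calls <- do.call(rbind, lapply(callsets, `[[`, "calls"))
  all_keys <- paste(all_calls$clone_id, variant_key(all_calls), sep = "|")
  sel <- all_calls[match(keep, all_keys), , drop = FALSE]
  sel <- sel[order(sel$clone_id, sel$pos), , drop = FALSE]
  variant_cohort(sel, clone_ids = clone_ids)
}

#' Separate ancestral (strain-background) variants from a cohort
#'
#' Variants carried by more than `threshold_fraction` of clones are almost
#' certainly fixed in the shared ancestor rather than selected during
#' escape, and are removed from causal analysis and reported separately.
#'
#' @param cohort A `variant_cohort` with at least 2 clones.
#' @param threshold_fraction Carriage fraction above which a variant is
#'   called ancestral (default 0.5).
#' @return A list with `ancestral` (data frame: pos, ref, alt, n_carriers,
#'   carrier_fraction) and `cohort` (the filtered `variant_cohort`).
#' @export
ancestral_filter <- function(cohort, threshold_fraction = 0.5) {
  stopifnot(inherits(cohort, "variant_cohort"))
  if (cohort$n_clones < 2L) {
    stop("ancestral filtering needs >= 2 clones", call. = FALSE)
  }
  assert_prob(threshold_fraction, "threshold_fraction")
  calls <- cohort$calls
  key <- variant_key(calls)
  carriers <- tapply(calls$clone_id, key, function(x) length(unique(x)))
  frac <- carriers / cohort$n_clones
  anc_keys <- names(carriers)[frac > threshold_fraction]
  anc_idx <- match(anc_keys, key)
  ancestral <- data.frame(pos = calls$pos[anc_idx],
                          ref = calls$ref[anc_idx],
                          alt = calls$alt[anc_idx],
                          n_carriers = as.integer(carriers[anc_keys]),
                          carrier_fraction = as.numeric(frac[anc_keys]),
                          stringsAsFactors = FALSE)
  ancestral <- ancestral[order(ancestral$pos), , drop = FALSE]
  rownames(ancestral) <- NULL
  keep <- !(key %in% anc_keys)
  list(ancestral = ancestral,
       cohort = variant_cohort(calls[keep, , drop = FALSE],
                               clone_ids = cohort$clone_ids))
}
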