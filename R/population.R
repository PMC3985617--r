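#' Clonal population state for CoS-MAGE cycling
#'
#' A `population_state` holds the genotypes of a simulated clone population
#' as a binary lineages-by-loci matrix together with the number of
#' CoS-MAGE cycles applied so far.
#'
#' @param genotypes 0/1 integer matrix, one row per lineage, one column per
#'   target locus.
#' @param cycle_index Non-negative integer, cycles applied so far.
#' @return An object of class `population_state`.
#' @export
population_state <- function(genotypes, cycle_index = 0L) {
  g <- as.matrix(genotypes)
  storage.mode(g) <- "integer"
  if (nrow(g) < 1L || ncol(g) < 1L) {
    stop("population must be non-empty with L >= 1 loci", call. = FALSE)
  }
  if (anyNA(g) || !all(g %in% c(0L, 1L))) {
    stop("genotypes must be binary 0/1", call. = FALSE)
  }
  if (!is_count(cycle_index)) stop("cycle_index must be a non-negative integer",
                                   call. = FALSE)
  structure(list(genotypes = g, cycle_index = as.integer(cycle_index)),
            class = "population_state")
}

#' Start an all-unconverted population
#'
#' @param n_lineages Number of lineages.
#' @param L Number of target loci.
#' @return A `population_state` at cycle 0 with no conversions.
#' @export
new_population <- function(n_lineages, L) {
  population_state(matrix(0L, nrow = n_lineages, ncol = L), 0L)
}

#' @export
print.population_state <- function(x, ...) {
  s <- summarize_population(x)
  cat(sprintf(paste0("<population_state> %d lineages x %d loci, cycle %d\n",
                     "  mean conversions %.3f, unmodified %.1f%%, ",
                     "fully converted %.1f%%\n"),
              nrow(x$genotypes), ncol(x$genotypes), x$cycle_index,
              s$mean_conversions, 100 * s$unmodified_fraction,
              100 * s$fully_converted_fraction))
  invisible(x)
}

#' Apply one CoS-MAGE cycle to a population
#'
#' Each lineage independently acquires one draw from the per-cycle
#' conversion model, OR-ed onto its current genotype: conversions
#' accumulate and never revert. The cycle index increments by one.
#'
#' @param pop A `population_state`.
#' @param model A `conversion_model` with the same `L`.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return The updated `population_state`.
#' @export
simulate_cycle <- function(pop, model, seed = NULL) {
  stopifnot(inherits(pop, "population_state"),
            inherits(model, "conversion_model"))
  if (model$L != ncol(pop$genotypes)) {
    stop("model L does not match population locus count", call. = FALSE)
  }
  new <- draw_patterns(model, nrow(pop$genotypes), seed = seed)
  population_state(pmin(pop$genotypes + new, 1L), pop$cycle_index + 1L)
}

#' Subsample a population through an inoculum bottleneck
#'
#' Uniform sampling without replacement of `min(size, n)` lineages, the
#' sampling model for seeding a counter-selection from a small inoculum.
#' Small bottlenecks collapse genotype diversity; sampling is neutral in
#' expectation (hypergeometric).
#'
#' @param pop A `population_state`.
#' @param size Bottleneck size (positive integer). If `size >= n` the
#'   population is returned unchanged.
#' @param seed Optional integer seed.
#' @return A `population_state` at the same cycle index.
#' @export
apply_bottleneck <- function(pop, size, seed = NULL) {
  stopifnot(inherits(pop, "population_state"))
  if (!is_count(size) || size < 1) {
    stop("`size` must be a positive integer", call. = FALSE)
  }
  n <- nrow(pop$genotypes)
  if (size >= n) return(pop)
  keep <- run_seeded(seed, sample.int(n, size))
  population_state(pop$genotypes[keep, , drop = FALSE], pop$cycle_index)
}

#' Summarise conversion states of a population
#'
#' @param pop A `population_state`.
#' @return A list with `cycle`, `n`, `mean_conversions`, `count_histogram`
#'   (named counts over 0..L, summing to `n`), `fully_converted_fraction`
#'   and `unmodified_fraction`.
#' @export
summarize_population <- function(pop) {
  stopifnot(inherits(pop, "population_state"))
  counts <- rowSums(pop$genotypes)
  L <- ncol(pop$genotypes)
  n <- nrow(pop$genotypes)
  hist <- tabulate(counts + 1L, nbins = L + 1L)
  names(hist) <- 0:L
  list(cycle = pop$cycle_index,
       n = n,
       mean_conversions = mean(counts),
       count_histogram = hist,
       fully_converted_fraction = hist[[L + 1L]] / n,
       unmodified_fraction = hist[[1L]] / n)
}

#' Simulate an allele-conversion trajectory over repeated CoS-MAGE cycles
#'
#' Starts from an all-unconverted population and applies the per-cycle
#' conversion model `n_cycles` times, recording the population summary
#' after every cycle (including cycle 0). An optional bottleneck subsamples
#' the population before each cycle, emulating a counter-selection
#' inoculum.
#'
#' @param n_lineages Number of independent lineages (>= 1).
#' @param n_cycles Number of cycles (>= 0).
#' @param model A `conversion_model`.
#' @param seed Integer seed; the whole trajectory is reproducible for a
#'   fixed seed.
#' @param bottleneck Optional bottleneck size applied before every cycle.
#' @return An object of class `cosmage_trajectory`: a list with
#'   `per_cycle` (data frame: cycle, n, mean_conversions,
#'   unmodified_fraction, fully_converted_fraction), `count_histogram`
#'   (matrix, one row per recorded cycle, columns 0..L) and
#'   `final_population`.
#' @examples
#' m <- fit_conversion_model(2.87, 0.096, 10)
#' tr <- simulate_trajectory(2000, 10, m, seed = 1)
#' tr$per_cycle
#' @export
simulate_trajectory <- function(n_lineages, n_cycles, model, seed = NULL,
                                bottleneck = NULL) {
  stopifnot(inherits(model, "conversion_model"))
  if (!is_count(n_lineages) || n_lineages < 1) {
    stop("`n_lineages` must be a positive integer", call. = FALSE)
  }
  if (!is_count(n_cycles)) {
    stop("`n_cycles` must be a non-negative integer", call. = FALSE)
  }
  run_seeded(seed, {
    pop <- new_population(n_lineages, model$L)
    summaries <- vector("list", n_cycles + 1L)
    summaries[[1L]] <- summarize_population(pop)
    for (cy in seq_len(n_cycles)) {
      if (!is.null(bottleneck)) pop <- apply_bottleneck(pop, bottleneck)
      pop <- simulate_cycle(pop, model)
      summaries[[cy + 1L]] <- summarize_population(pop)
    }
    per_cycle <- data.frame(
      cycle = vapply(summaries, `[[`, integer(1), "cycle"),
      n = vapply(summaries, `[[`, numeric(1), "n"),
      mean_conversions = vapply(summaries, `[[`, numeric(1),
                                "mean_conversions"),
      unmodified_fraction = vapply(summaries, `[[`, numeric(1),
                                   "unmodified_fraction"),
      fully_converted_fraction = vapply(summaries, `[[`, numeric(1),
                                        "fully_converted_fraction"))
    hist <- do.call(rbind, lapply(summaries, `[[`, "count_histogram"))
    rownames(hist) <- per_cycle$cycle
    structure(list(per_cycle = per_cycle, count_histogram = hist,
                   final_population = pop),
              class = "cosmage_trajectory")
  })
}

#' @export
print.cosmage_trajectory <- function(x, ...) {
  cat("<cosmage_trajectory>\n")
  print(x$per_cycle, row.names = FALSE)
  invisible(x)
}
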