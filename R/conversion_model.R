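#' Per-cycle allele-conversion models
#'
#' A `conversion_model` describes the distribution of allele-replacement
#' (AR) events acquired by a single clone in one CoS-MAGE cycle across `L`
#' target loci. Three modes are supported:
#'
#' * `"empirical_pattern"`: resample whole observed conversion patterns
#'   (rows of a genotyped clone-by-locus matrix) with their observed
#'   frequencies.
#' * `"empirical_count"`: resample observed per-clone conversion counts and
#'   place that many conversions uniformly at random among the `L` loci
#'   (no positional dependence).
#' * `"parametric_zib"`: a zero-inflated binomial count distribution with
#'   zero-inflation mass `pi` and per-locus conversion probability `p`;
#'   counts are placed uniformly as above.
#'
#' @param mode One of `"empirical_pattern"`, `"empirical_count"`,
#'   `"parametric_zib"`.
#' @param L Number of target loci (positive integer).
#' @param pi,p Zero-inflation mass and per-locus conversion probability
#'   (parametric mode only).
#' @param patterns 0/1 integer matrix of distinct conversion patterns, one
#'   row per pattern with `L` columns (empirical pattern mode).
#' @param weights Numeric vector of pattern weights, same length as
#'   `nrow(patterns)`; must sum to 1 within `1e-9`.
#' @param count_probs Numeric vector of length `L + 1` giving the
#'   probability of acquiring `0..L` conversions in one cycle (empirical
#'   count mode); must sum to 1 within `1e-9`.
#'
#' @return An object of class `conversion_model`.
#' @seealso [fit_conversion_model()], [empirical_distribution()],
#'   [simulate_trajectory()]
#' @export
conversion_model <- function(mode = c("parametric_zib", "empirical_pattern",
                                      "empirical_count"),
                             L, pi = NULL, p = NULL,
                             patterns = NULL, weights = NULL,
                             count_probs = NULL) {
  mode <- match.arg(mode)
  if (!is_count(L) || L < 1) stop("`L` must be a positive integer", call. = FALSE)
  L <- as.integer(L)
  obj <- structure(list(mode = mode, L = L), class = "conversion_model")
  if (mode == "parametric_zib") {
    assert_prob(pi, "pi"); assert_prob(p, "p")
    obj$pi <- pi; obj$p <- p
  } else if (mode == "empirical_pattern") {
    patterns <- as.matrix(patterns)
    storage.mode(patterns) <- "integer"
    if (ncol(patterns) != L) stop("patterns must have L columns", call. = FALSE)
    if (!all(patterns %in% c(0L, 1L))) {
      stop("patterns must be binary 0/1", call. = FALSE)
    }
    if (length(weights) != nrow(patterns) || any(weights < 0) ||
        abs(sum(weights) - 1) > 1e-9) {
      stop("pattern weights must be non-negative and sum to 1", call. = FALSE)
    }
    obj$patterns <- patterns; obj$weights <- as.numeric(weights)
  } else {
    if (length(count_probs) != L + 1 || any(count_probs < 0) ||
        abs(sum(count_probs) - 1) > 1e-9) {
      stop("count_probs must have length L + 1, be non-negative and sum to 1",
           call. = FALSE)
    }
    obj$count_probs <- as.numeric(count_probs)
  }
  obj
}

#' @export
print.conversion_model <- function(x, ...) {
  cat("<conversion_model>", x$mode, sprintf("(L = %d)", x$L), "\n")
  if (x$mode == "parametric_zib") {
    cat(sprintf("  pi = %.4f, p = %.4f, mean = %.3f edits/clone/cycle\n",
                x$pi, x$p, (1 - x$pi) * x$L * x$p))
  } else if (x$mode == "empirical_pattern") {
    cat(sprintf("  %d distinct patterns\n", nrow(x$patterns)))
  } else {
    cat(sprintf("  mean = %.3f edits/clone/cycle\n",
                sum(0:x$L * x$count_probs)))
  }
  invisible(x)
}

#' Calibrate a zero-inflated binomial conversion model to printed summaries
#'
#' Solves for the zero-inflation mass `pi` and per-locus conversion
#' probability `p` of a zero-inflated binomial (ZIB) on `L` trials such that
#' the model reproduces a published single-cycle population summary: the
#' mean number of edits per clone and the fraction of unmodified (zero-edit)
#' clones. The two moment conditions are
#' \deqn{(1 - \pi) L p = m, \qquad \pi + (1 - \pi)(1 - p)^L = P_0,}
#' solved by 1-D bisection on `pi` after eliminating `p`.
#'
#' @param mean_conversions Published mean edits/clone/cycle (`m >= 0`).
#' @param unmodified_fraction Published fraction of clones with zero edits
#'   (`P0` in `[0, 1]`).
#' @param L Number of target loci.
#' @param tol Residual tolerance on the zero-fraction equation.
#'
#' @return A `conversion_model` of mode `"parametric_zib"`.
#'
#' @details The pair `(m, P0)` is attainable only when
#'   `(1 - m/L)^L <= P0 <= 1 - m/L`: the lower bound is the plain binomial
#'   zero fraction at the same mean (no zero-inflation), the upper bound is
#'   the zero-inflation mass at `p = 1`. Infeasible pairs raise an error
#'   naming the violated bound.
#'
#' @examples
#' fit_conversion_model(2.87, 0.096, 10)  # optimized-strain regime
#' fit_conversion_model(0.43, 0.72, 10)   # baseline regime
#' @export
fit_conversion_model <- function(mean_conversions, unmodified_fraction, L,
                                 tol = 1e-10) {
  m <- mean_conversions
  P0 <- unmodified_fraction
  if (!is.numeric(m) || length(m) != 1L || m < 0) {
    stop("`mean_conversions` must be a single non-negative number", call. = FALSE)
  }
  assert_prob(P0, "unmodified_fraction")
  if (!is_count(L) || L < 1) stop("`L` must be a positive integer", call. = FALSE)
  if (m > L) stop("mean_conversions cannot exceed L", call. = FALSE)

  if (m == 0) {
    if (abs(P0 - 1) > 1e-12) {
      stop("infeasible pair: mean 0 requires unmodified_fraction = 1",
           call. = FALSE)
    }
    return(conversion_model("parametric_zib", L = L, pi = 1, p = 0))
  }

  p0_min <- (1 - m / L)^L    # pi = 0 (plain binomial)
  pi_max <- 1 - m / L        # p = 1
  if (P0 < p0_min - 1e-12) {
    stop(sprintf(paste0("infeasible pair: unmodified_fraction %.4g is below ",
                        "the plain-binomial limit (1 - m/L)^L = %.4g"),
                 P0, p0_min), call. = FALSE)
  }
  if (P0 > pi_max + 1e-12) {
    stop(sprintf(paste0("infeasible pair: unmodified_fraction %.4g exceeds ",
                        "the p = 1 limit 1 - m/L = %.4g"),
                 P0, pi_max), call. = FALSE)
  }

  # residual of the zero-fraction equation with p eliminated via the mean
  g <- function(pi) {
    p <- m / ((1 - pi) * L)
    pi + (1 - pi) * (1 - p)^L - P0
  }
  lo <- 0
  hi <- pi_max * (1 - 1e-12)
  if (g(lo) > 0) {          # P0 == p0_min within tolerance
    pi_hat <- 0
  } else {
    for (i in seq_len(200L)) {
      mid <- (lo + hi) / 2
      if (g(mid) <= 0) lo <- mid else hi <- mid
      if (hi - lo < tol) break
    }
    pi_hat <- (lo + hi) / 2
  }
  p_hat <- min(1, m / ((1 - pi_hat) * L))
  if (abs(g(pi_hat)) > 1e-8) {
    stop("bisection failed to reach the requested residual", call. = FALSE)
  }
  conversion_model("parametric_zib", L = L, pi = pi_hat, p = p_hat)
}

#' Empirical conversion model from a genotyped clone population
#'
#' Builds a per-cycle conversion model from a binary clone-by-locus
#' genotype matrix (e.g. mascPCR calls after one CoS-MAGE cycle). In
#' `"pattern"` mode each distinct conversion pattern is weighted by its
#' relative frequency; in `"count"` mode only the per-clone conversion
#' counts are retained and conversions are later placed uniformly among
#' loci.
#'
#' @param genotypes 0/1 matrix or data frame, one row per clone, one column
#'   per target locus.
#' @param mode `"pattern"` or `"count"`.
#' @return A `conversion_model`.
#' @export
empirical_distribution <- function(genotypes, mode = c("pattern", "count")) {
  mode <- match.arg(mode)
  g <- as.matrix(genotypes)
  if (nrow(g) < 1L) stop("need at least one genotyped clone", call. = FALSE)
  storage.mode(g) <- "integer"
  if (anyNA(g) || !all(g %in% c(0L, 1L))) {
    stop("genotype matrix must be binary 0/1 with no missing values",
         call. = FALSE)
  }
  L <- ncol(g)
  if (mode == "pattern") {
    key <- apply(g, 1L, paste, collapse = "")
    tab <- table(key)
    pats <- do.call(rbind, lapply(names(tab), function(k) {
      as.integer(strsplit(k, "", fixed = TRUE)[[1L]])
    }))
    conversion_model("empirical_pattern", L = L, patterns = pats,
                     weights = as.numeric(tab) / nrow(g))
  } else {
    counts <- rowSums(g)
    probs <- tabulate(counts + 1L, nbins = L + 1L) / nrow(g)
    conversion_model("empirical_count", L = L, count_probs = probs)
  }
}

# Draw n single-cycle conversion patterns as an n x L 0/1 matrix.
# Count-based modes place k conversions uniformly without replacement,
# i.e. no positional dependence between loci.
draw_patterns <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "conversion_model"), is_count(n), n >= 1)
  run_seeded(seed, {
    L <- model$L
    if (model$mode == "empirical_pattern") {
      idx <- sample.int(nrow(model$patterns), n, replace = TRUE,
                        prob = model$weights)
      model$patterns[idx, , drop = FALSE]
    } else {
      k <- if (model$mode == "parametric_zib") {
        ifelse(stats::runif(n) < model$pi, 0L,
               stats::rbinom(n, L, model$p))
      } else {
        sample.int(L + 1L, n, replace = TRUE, prob = model$count_probs) - 1L
      }
      out <- matrix(0L, nrow = n, ncol = L)
      for (i in which(k > 0L)) {
        out[i, sample.int(L, k[i])] <- 1L
      }
      out
    }
  })
}
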