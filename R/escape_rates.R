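#' Counter-selection escape frequency from a single plating
#'
#' Point estimate `colonies / cells_plated` with an exact (Clopper-Pearson)
#' 95% binomial confidence interval. With zero colonies the point estimate
#' is 0 and the interval still yields an informative upper bound
#' (approximately `3.69 / cells_plated` at the 95% level). The exact
#' interval is used because escape frequencies run as low as 1e-11 with
#' 0-1 colonies, where normal approximations are meaningless.
#'
#' @param cells_plated Number of cells plated (> 0).
#' @param colonies Number of escape colonies counted (`<= cells_plated`).
#' @param agents Character vector of counter-selection agents applied
#'   (e.g. `c("colE1", "vancomycin")`).
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `escape_estimate`: a list with `frequency`,
#'   `ci_low`, `ci_high`, `n_replicates` (1), `sem` (`NA` for a single
#'   plating), `agents`, `cells_plated`, `colonies`.
#' @examples
#' escape_frequency(2.32e10, 1)  # ~4.3e-11
#' @export
escape_frequency <- function(cells_plated, colonies, agents = character(),
                             conf_level = 0.95) {
  if (!is.numeric(cells_plated) || cells_plated <= 0) {
    stop("`cells_plated` must be positive", call. = FALSE)
  }
  if (!is.numeric(colonies) || colonies < 0 || colonies > cells_plated) {
    stop("`colonies` must lie in [0, cells_plated]", call. = FALSE)
  }
  k <- colonies; n <- cells_plated
  alpha <- 1 - conf_level
  ci_low <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  ci_high <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  structure(list(frequency = k / n, ci_low = ci_low, ci_high = ci_high,
                 n_replicates = 1L, sem = NA_real_,
                 agents = as.character(agents),
                 cells_plated = n, colonies = k),
            class = "escape_estimate")
}

#' Pooled escape frequency across biological replicates
#'
#' Mean of per-replicate escape frequencies with the standard error of the
#' mean (sample SD / sqrt(n)), the reporting convention for multi-replicate
#' platings. A single replicate yields an undefined SEM, which is flagged.
#'
#' @param platings Data frame with columns `cells_plated` and `colonies`
#'   (one row per replicate), and optionally `agents` (must be uniform).
#' @param agents Agent set; taken from the data frame when omitted.
#' @return An `escape_estimate` with `frequency` = replicate mean, `sem`,
#'   `n_replicates`, and a normal-theory 95% interval about the mean
#'   (`NA` for a single replicate).
#' @export
pooled_escape_frequency <- function(platings, agents = NULL) {
  if (nrow(platings) < 1L) stop("need >= 1 replicate", call. = FALSE)
  if (!all(c("cells_plated", "colonies") %in% names(platings))) {
    stop("platings need columns cells_plated, colonies", call. = FALSE)
  }
  if (is.null(agents) && "agents" %in% names(platings)) {
    ag <- unique(platings$agents)
    if (length(ag) > 1L) {
      stop("mixed agent sets cannot be pooled: ",
           paste(ag, collapse = " vs "), call. = FALSE)
    }
    agents <- strsplit(ag, ",", fixed = TRUE)[[1L]]
  }
  if (any(platings$colonies > platings$cells_plated) ||
      any(platings$cells_plated <= 0)) {
    stop("invalid plating rows (colonies > cells_plated or no cells)",
         call. = FALSE)
  }
  f <- platings$colonies / platings$cells_plated
  n <- length(f)
  sem <- if (n > 1L) stats::sd(f) / sqrt(n) else NA_real_
  mu <- mean(f)
  structure(list(frequency = mu,
                 ci_low = if (n > 1L) max(0, mu - stats::qt(0.975, n - 1) * sem)
                          else NA_real_,
                 ci_high = if (n > 1L) mu + stats::qt(0.975, n - 1) * sem
                           else NA_real_,
                 n_replicates = n, sem = sem,
                 agents = as.character(agents %||% character()),
                 cells_plated = sum(platings$cells_plated),
                 colonies = sum(platings$colonies),
                 single_replicate = n == 1L),
            class = "escape_estimate")
}

#' @export
print.escape_estimate <- function(x, ...) {
  cat(sprintf("<escape_estimate> %s%s\n",
              format_frequency(x$frequency),
              if (length(x$agents)) paste0(" [",
                paste(x$agents, collapse = "+"), "]") else ""))
  if (x$n_replicates > 1L) {
    cat(sprintf("  mean of %d replicates, SEM %s\n", x$n_replicates,
                format_frequency(x$sem)))
  } else {
    cat(sprintf("  single plating: %g colonies / %g cells, 95%% CI [%s, %s]\n",
                x$colonies, x$cells_plated,
                format_frequency(x$ci_low), format_frequency(x$ci_high)))
  }
  invisible(x)
}

#' Round a frequency to the 2-significant-figure reporting convention
#'
#' @param f Frequency (or any non-negative number).
#' @return Character scalar like `"4.3e-11"`.
#' @export
format_frequency <- function(f) {
  if (is.na(f)) return("NA")
  format(signif(f, 2), scientific = TRUE)
}

#' Fold reduction in escape frequency between two conditions
#'
#' Ratio `baseline / improved` of two escape frequencies. When the improved
#' estimate is exactly zero the ratio is undefined; a lower bound is
#' reported instead using the upper confidence limit of the improved
#' estimate (when available).
#'
#' @param baseline,improved `escape_estimate` objects or bare frequencies.
#' @return A list with `fold` (`NA` when only a bound is available),
#'   `lower_bound` (the bound, or `NA`), and `bounded` (logical).
#' @examples
#' fold_reduction(3.4e-5, 8.5e-7)$fold  # 40
#' @export
fold_reduction <- function(baseline, improved) {
  fb <- if (inherits(baseline, "escape_estimate")) baseline$frequency
        else baseline
  fi <- if (inherits(improved, "escape_estimate")) improved$frequency
        else improved
  if (fb <= 0) stop("baseline frequency of 0 makes the ratio undefined",
                    call. = FALSE)
  if (fi > 0) {
    return(list(fold = fb / fi, lower_bound = NA_real_, bounded = FALSE))
  }
  hi <- if (inherits(improved, "escape_estimate")) improved$ci_high
        else NA_real_
  if (is.na(hi) || hi <= 0) {
    stop("improved frequency is 0 with no usable upper bound", call. = FALSE)
  }
  list(fold = NA_real_, lower_bound = fb / hi, bounded = TRUE)
}

#' Predicted joint escape frequency of two independent agents
#'
#' Under mechanistic independence, escaping two orthogonal
#' counter-selection agents applied together requires independent escape
#' from each, so the joint escape frequency is the product of the single
#' agent frequencies. When an observed joint estimate is supplied, the
#' deviation factor observed/predicted quantifies departure from
#' independence.
#'
#' @param p1,p2 Single-agent escape frequencies in `[0, 1]`.
#' @param observed Optional observed joint escape frequency.
#' @return A list with `predicted` and, when `observed` is given,
#'   `observed` and `deviation_factor`.
#' @examples
#' predicted_joint_escape(8.3e-2, 3.4e-5)$predicted  # 2.8e-6
#' @export
predicted_joint_escape <- function(p1, p2, observed = NULL) {
  assert_prob(p1, "p1"); assert_prob(p2, "p2")
  pred <- p1 * p2
  out <- list(predicted = pred)
  if (!is.null(observed)) {
    out$observed <- observed
    out$deviation_factor <- if (pred > 0) observed / pred else NA_real_
  }
  out
}

#' Read plating experiments from TSV
#'
#' Expects columns `strain`, `agents` (comma-joined), `cells_plated`,
#' `colonies`, `replicate`.
#'
#' @param path TSV file path.
#' @return A data frame of platings.
#' @export
read_platings <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("strain", "agents", "cells_plated", "colonies", "replicate")
  if (!all(need %in% names(df))) {
    stop("plating TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$colonies > df$cells_plated) || any(df$cells_plated <= 0)) {
    stop("invalid plating rows (colonies > cells_plated or no cells)",
         call. = FALSE)
  }
  df
}

#' Write plating experiments to TSV
#'
#' @param platings Data frame as returned by [gen_plating()] or
#'   [read_platings()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_platings <- function(platings, path) {
  utils::write.table(platings, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
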