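# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under an explicit RNG seed without touching global state;
# seed = NULL means "use the current RNG stream" (for nested simulation calls).
run_seeded <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")
# bacterial initiation codons (NCBI table 11 init set restricted to the common three)
START_CODONS <- c("ATG", "GTG", "TTG")

.dualmark_env <- new.env(parent = emptyenv())

# codon -> amino acid, bacterial/plastid code (NCBI table 11), stops as "*"
genetic_code11 <- function() {
  if (is.null(.dualmark_env$gc11)) {
    .dualmark_env$gc11 <- Biostrings::getGeneticCode("11")
  }
  .dualmark_env$gc11
}

comp_base <- function(x) chartr("ACGT", "TGCA", x)

# vectorised reverse complement of equal-workload short strings
revcomp_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(comp_base(strsplit(s, "", fixed = TRUE)[[1L]])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}
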