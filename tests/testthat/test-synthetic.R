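test_that("generated genomes follow the construction arithmetic and are ORFs", {
  syn <- gen_reference(3, 100, 200, seed = 1)
  expect_equal(syn$reference$length, 3 * 303 + 4 * 200)
  expect_equal(syn$genes$strand, c("+", "-", "+"))
  gc11 <- Biostrings::getGeneticCode("11")
  for (i in seq_len(3)) {
    cds <- gene_cds(syn$genes[i, ], syn$reference)
    prot <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                               genetic.code = gc11))
    expect_equal(substr(prot, 1, 1), "M")
    expect_equal(substr(prot, 101, 101), "*")
    expect_false(grepl("\\*", substr(prot, 1, 100)))
  }
  # deterministic per seed
  expect_identical(gen_reference(3, 100, 200, seed = 1)$reference$seq,
                   syn$reference$seq)
  expect_false(identical(gen_reference(3, 100, 200, seed = 2)$reference$seq,
                         syn$reference$seq))
})

test_that("escape cohorts carry planted causal, passenger and ancestral variants", {
  syn <- gen_reference(4, 80, 150, seed = 11)
  co <- gen_escape_clones(syn$reference, syn$genes,
                          causal_genes = c("gene01", "gene03"),
                          n_clones = 48, causal_hit_prob = 0.93,
                          causal_lof_bias = 0.75, passenger_rate = 2,
                          ancestral_variants = 21, seed = 12)
  truth <- attr(co, "truth")
  expect_equal(nrow(truth), 48L)
  # ancestral variants present in every clone and removable by the filter
  key <- paste(co$calls$pos, co$calls$alt)
  carriers <- tapply(co$calls$clone_id, key,
                     function(x) length(unique(x)))
  expect_equal(sum(carriers == 48), 21L)
  f <- ancestral_filter(co, 0.5)
  expect_equal(nrow(f$ancestral), 21L)
  # every VCF REF matches the genome (validated on write + load round trip)
  d <- withr::local_tempdir()
  paths <- write_clone_vcfs(co, d, syn$reference)
  expect_length(paths, 48L)
  back <- load_variants(paths, reference = syn$reference)
  expect_equal(nrow(back$calls), nrow(co$calls))

  # clones whose truth row names a causal gene actually hit it
  cc <- classify_cohort(f$cohort, syn$genes, syn$reference)
  hit <- cohort_hit_fraction(cc, c("gene01", "gene03"))
  planted <- sum(!is.na(truth$causal_gene))
  expect_gte(hit$n_hit, planted)  # passengers can add extra hits
})

test_that("pure-causal cohorts contain only causal-gene records", {
  syn <- gen_reference(3, 90, 100, seed = 13)
  co <- gen_escape_clones(syn$reference, syn$genes, causal_genes = "gene02",
                          n_clones = 30, causal_hit_prob = 1,
                          passenger_rate = 0, ancestral_variants = 0,
                          seed = 14)
  expect_equal(nrow(co$calls), 30L)
  g <- syn$genes[syn$genes$name == "gene02", ]
  expect_true(all(co$calls$pos >= g$start & co$calls$pos <= g$end))
  cc <- classify_cohort(co, syn$genes, syn$reference)
  expect_true(all(cc$calls$gene == "gene02"))
  expect_false(any(cc$calls$category %in% c("intergenic", "synonymous")))
})

test_that("planted causal mutation types classify as intended", {
  syn <- gen_reference(4, 120, 100, seed = 15)
  for (bias in c(1, 0)) {
    co <- gen_escape_clones(syn$reference, syn$genes,
                            causal_genes = c("gene02", "gene04"),
                            n_clones = 40, causal_hit_prob = 1,
                            causal_lof_bias = bias, passenger_rate = 0,
                            ancestral_variants = 0, seed = 16 + bias)
    cc <- classify_cohort(co, syn$genes, syn$reference)
    truth <- attr(co, "truth")
    got <- cc$calls$category[match(truth$clone_id, cc$calls$clone_id)]
    expect_identical(got, truth$causal_type)
  }
})

test_that("growth quartets encode the selective lag of the escape fraction", {
  # deterministic check: CS delay vs CNS ~ doubling_time * log2(1/f)
  q <- gen_growth_quartet(1e-6, n0 = 1e8, noise_sd = 0,
                          stochastic_inoculum = FALSE, horizon = 2880,
                          sample_interval = 5, seed = 1)
  d <- growth_delay(q$cs, q$cns)
  expect_equal(d$delay_min, 30 * log2(1e6), tolerance = 0.01)

  # full escape: recombinant and control behave alike -> NSA ~ 0
  q1 <- gen_growth_quartet(1, noise_sd = 0, stochastic_inoculum = FALSE,
                           seed = 2)
  expect_lt(abs(nsa(quartet_from_curves(q1$rs, q1$cs, q1$rns, q1$cns))$nsa),
            0.01)

  # no escapers in the inoculum: CS censored, NSA is a high lower bound
  q0 <- gen_growth_quartet(0, noise_sd = 0, seed = 3)
  tt <- time_to_threshold(q0$cs)
  expect_true(tt$censored)
  r0 <- nsa(quartet_from_curves(q0$rs, q0$cs, q0$rns, q0$cns))
  expect_gt(r0$nsa, 0.8)
  expect_true(r0$lower_bound)
})

test_that("NSA decreases monotonically with the control escape fraction", {
  fr <- 10^seq(-8, 0, by = 1)
  vals <- vapply(fr, function(f) {
    q <- gen_growth_quartet(f, noise_sd = 0, stochastic_inoculum = FALSE,
                            seed = 1)
    nsa(quartet_from_curves(q$rs, q$cs, q$rns, q$cns))$nsa
  }, numeric(1))
  expect_true(all(diff(vals) <= 1e-9))
  expect_lt(vals[length(vals)], 0.01)
  expect_gt(vals[1], 0.8)
})

test_that("plating counts are Poisson with the requested mean and seed-stable", {
  pl <- gen_plating(1e-5, 1e6, n_replicates = 2000, seed = 5)
  expect_identical(gen_plating(1e-5, 1e6, n_replicates = 2000, seed = 5),
                   pl)
  m <- mean(pl$colonies)
  expect_lt(abs(m - 10), 3 * sqrt(10 / 2000))
  expect_true(all(gen_plating(0, 1e8, 10, seed = 6)$colonies == 0))
  # estimator is unbiased over replicates
  est <- pl$colonies / pl$cells_plated
  expect_lt(abs(mean(est) - 1e-5), 3 * sqrt(1e-5 / 1e6 / 2000))
})

test_that("genotype populations round trip through TSV and refit", {
  mod <- fit_conversion_model(2.87, 0.096, 10)
  g <- gen_genotype_population(mod, 4000, seed = 8)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_matrix(g, path)
  back <- read_genotype_matrix(path)
  expect_identical(unname(back), unname(g))

  # refit of the count distribution matches the sampled histogram
  refit <- empirical_distribution(back, mode = "count")
  expect_equal(refit$count_probs,
               tabulate(rowSums(g) + 1L, nbins = 11) / 4000)
  # ZIB mean recovered within Monte-Carlo error
  expect_lt(abs(mean(rowSums(g)) - 2.87), 0.1)

  degenerate <- conversion_model("parametric_zib", L = 6, pi = 1, p = 0.5)
  expect_true(all(gen_genotype_population(degenerate, 50, seed = 9) == 0L))
})
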