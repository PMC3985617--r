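test_that("gene tallies count distinct, total and genomes hit", {
  tg_syn <- gen_reference(3, 60, 80, seed = 5)
  ref <- tg_syn$reference; genes <- tg_syn$genes
  g1 <- genes[1, ]
  # v1 shared by clones A and B, v2 private to B -> distinct 2, total 3
  p1 <- g1$start + 4L; p2 <- g1$start + 10L
  calls <- data.frame(
    clone_id = c("A", "B", "B"),
    pos = c(p1, p1, p2),
    ref = substring(ref$seq, c(p1, p1, p2), c(p1, p1, p2)),
    alt = "N")
  # choose alts that differ from ref
  calls$alt <- ifelse(calls$ref == "A", "G", "A")
  cc <- classify_cohort(variant_cohort(calls, clone_ids = c("A", "B", "C")),
                        genes, ref)
  t <- tally_genes(cc, genes)
  r1 <- t[t$gene == g1$name, ]
  expect_equal(r1$distinct, 2L)
  expect_equal(r1$total, 3L)
  expect_equal(r1$genomes_hit, 2L)
  expect_true(all(t$total >= t$distinct))
  zero <- t[t$gene != g1$name, ]
  expect_true(all(zero$distinct == 0 & zero$total == 0 & zero$genomes_hit == 0))
})

test_that("LoF fraction is the share of distinct LoF mutations", {
  syn <- gen_reference(2, 100, 120, seed = 6)
  co <- gen_escape_clones(syn$reference, syn$genes, causal_genes = "gene01",
                          n_clones = 40, causal_hit_prob = 1,
                          causal_lof_bias = 1, passenger_rate = 0,
                          ancestral_variants = 0, seed = 7)
  cc <- classify_cohort(co, syn$genes, syn$reference)
  t <- tally_genes(cc, syn$genes)
  expect_equal(t$lof_fraction[t$gene == "gene01"], 1)
})

test_that("genome binning is half-open from 0 with boundary positions going right", {
  calls <- data.frame(clone_id = "c", pos = c(774500L, 775100L, 777900L),
                      ref = "A", alt = "G")
  co <- variant_cohort(calls)
  b <- window_bin(co, 2000L, genome_length = 780000L)
  expect_equal(b$count[b$bin_start == 774000], 2L)
  expect_equal(b$count[b$bin_start == 776000], 1L)
  expect_equal(sum(b$count), 3L)

  edge <- variant_cohort(data.frame(clone_id = "c", pos = 2000L,
                                    ref = "A", alt = "G"))
  be <- window_bin(edge, 2000L, genome_length = 10000L)
  expect_equal(be$count[be$bin_start == 2000], 1L)
  expect_equal(be$count[be$bin_start == 0], 0L)

  empty <- variant_cohort(data.frame(clone_id = character(), pos = integer(),
                                     ref = character(), alt = character()),
                          clone_ids = "c")
  expect_equal(sum(window_bin(empty, 2000L, 10000L)$count), 0L)
  expect_equal(window_count(co, 774000, 778000), 3L)
})

test_that("binned, per-gene and intergenic counts conserve the cohort size", {
  syn <- gen_reference(5, 70, 90, seed = 31)
  co <- gen_escape_clones(syn$reference, syn$genes,
                          causal_genes = c("gene02", "gene04"),
                          n_clones = 30, passenger_rate = 4,
                          ancestral_variants = 3, seed = 32)
  cc <- classify_cohort(co, syn$genes, syn$reference)
  n_calls <- nrow(cc$calls)
  t <- tally_genes(cc, syn$genes)
  intergenic <- sum(is.na(cc$calls$gene))
  expect_equal(sum(t$total) + intergenic, n_calls)
  b <- window_bin(cc, 500L, genome_length = syn$reference$length)
  expect_equal(sum(b$count), n_calls)
})

test_that("coding-length enrichment reproduces share arithmetic and binomial p", {
  tallies <- data.frame(gene = c("tolA", "tolQ", "tolR"),
                        coding_length = c(1266L, 693L, 429L),
                        distinct = c(23L, 14L, 8L),
                        total = c(67L, 27L, 14L),
                        lof_fraction = c(0.87, 0.71, 0.63))
  en <- gene_enrichment(tallies)
  tolA <- en[en$gene == "tolA", ]
  expect_equal(round(100 * tolA$observed_share, 1), 62.0)
  expect_equal(round(100 * tolA$expected_share, 1), 53.0)
  expect_equal(tolA$rank, 1L)
  expect_equal(tolA$p_value,
               binom.test(67, 108, 1266 / 2388, "greater")$p.value)

  # all mutations in one of two equal-length genes: p = 0.5^n
  two <- data.frame(gene = c("g1", "g2"), coding_length = c(300L, 300L),
                    distinct = c(6L, 0L), total = c(6L, 0L),
                    lof_fraction = c(0.5, 0))
  en2 <- gene_enrichment(two)
  expect_equal(en2$p_value[en2$gene == "g1"], 0.5^6)

  # observed at expectation -> no enrichment signal
  null <- data.frame(gene = c("a", "b"), coding_length = c(500L, 500L),
                     distinct = c(5L, 5L), total = c(10L, 10L),
                     lof_fraction = 0)
  expect_true(all(gene_enrichment(null)$p_value > 0.3))
  expect_error(gene_enrichment(tallies, scope = "nope"), "empty")
})

test_that("cohort hit fraction tracks clones with mutations in a gene set", {
  syn <- gen_reference(3, 60, 80, seed = 41)
  co <- gen_escape_clones(syn$reference, syn$genes, causal_genes = "gene02",
                          n_clones = 25, causal_hit_prob = 1,
                          passenger_rate = 0, ancestral_variants = 0,
                          seed = 42)
  cc <- classify_cohort(co, syn$genes, syn$reference)
  hf <- cohort_hit_fraction(cc, "gene02")
  expect_equal(hf$fraction, 1)
  expect_equal(hf$missed_clones, character(0))
  expect_equal(cohort_hit_fraction(cc, character(0))$fraction, 0)
  expect_equal(cohort_hit_fraction(cc, "gene01")$n_hit +
                 length(cohort_hit_fraction(cc, "gene01")$missed_clones), 25L)
})

test_that("duplication sites require an essential gene on both arcs", {
  # circular 1000 bp map: source operon [100, 200], essentials vary
  genes <- data.frame(name = c("src", "essA", "essB", "noness"),
                      start = c(100L, 300L, 600L, 800L),
                      end = c(200L, 350L, 650L, 850L),
                      strand = "+",
                      essential = c(FALSE, TRUE, TRUE, FALSE),
                      coding_length = c(101L, 51L, 51L, 51L))
  res <- select_duplication_sites(genes, 100L, 200L,
                                  candidates = c(500L, 250L, 210L, 320L, 900L),
                                  genome_length = 1000L)
  expect_true(res$accepted[res$position == 500])   # essA left, essB right
  expect_false(res$accepted[res$position == 250])  # no essential on near arc
  expect_false(res$accepted[res$position == 210])  # adjacent: empty near arc
  expect_false(res$accepted[res$position == 320])  # inside essA
  expect_match(res$reason[res$position == 320], "inside gene")
  # 900: arc src_end->900 holds essA+essB; arc 900->src_start wraps with no
  # essential gene -> rejected
  expect_false(res$accepted[res$position == 900])

  # wrap-around acceptance: essential gene beyond the candidate on the far arc
  genes2 <- genes
  genes2$start[4] <- 900L; genes2$end[4] <- 950L; genes2$essential[4] <- TRUE
  res2 <- select_duplication_sites(genes2, 100L, 200L, candidates = 700L,
                                   genome_length = 1000L)
  expect_true(res2$accepted)
})
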