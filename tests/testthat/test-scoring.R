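test_that("word probability follows the zeroth-order composition model", {
  u <- utr_record("g", "AAAAACGGTT")   # composition A .5, C .1, G .2, T .2
  expect_equal(word_probability(u, "ACGT"), 0.5 * 0.1 * 0.2 * 0.2)
  expect_equal(word_probability(utr_record("g", "AAAA"), "AAAA"), 1)
  # uniform global composition gives 4^-k
  expect_equal(word_probability(u, "ACGTACG",
                                composition = c(A = 1, C = 1, G = 1, T = 1)),
               4^-7)
  # N is excluded from the composition counts
  expect_equal(word_probability(utr_record("g", "AANNTT"), "AT"), 0.25)
})

test_that("p_sh equals the direct binomial tail and is monotone", {
  expect_equal(p_sh(10, 0, 0.1), 1)
  expect_equal(p_sh(10, 2, 0.1), 1 - 0.9^10 - 10 * 0.1 * 0.9^9)
  expect_equal(p_sh(5, 5, 0.5), 0.03125)
  expect_error(p_sh(3, 4, 0.1), "exceed")
  for (t in c(3, 17, 30)) for (p in c(1e-3, 0.2, 0.7)) {
    vals <- p_sh(rep(t, t + 1), 0:t, p)
    expect_equal(vals, vapply(0:t, naive_psh, 0, t = t, p = p),
                 tolerance = 1e-13)
    expect_true(all(diff(vals) < 0))            # strictly decreasing in c
  }
  # strictly increasing in t for fixed c >= 1
  expect_true(all(diff(p_sh(5:30, 2, 0.05)) > 0))
  # tiny tails stay representable and positive
  expect_gt(p_sh(2000, 1900, 1e-4), 0)
})

test_that("filtered counts respect the filter mode and side inputs", {
  set.seed(41)
  word <- "CTACCTC"
  utr <- plant_matches(gen_utr("g", 100, rep(0.25, 4)), word, c(10L, 40L))
  pos <- find_seed_matches(utr, word)$positions
  expect_true(all(c(10L, 40L) %in% pos))

  none <- filtered_counts(utr, word, filter_config("none"))
  expect_equal(none$t_filter, total_windows(utr, 7))
  expect_equal(none$c_filter, length(pos))

  # accessibility keeps only the listed planted window
  prof <- gen_pfree_profile("g", 100, 10L)
  acc <- filtered_counts(utr, word, filter_config("access"), profile = prof)
  expect_equal(acc$c_filter, 1L)
  flags <- accessible_window_flags(prof, 7, 0.2)
  expect_equal(acc$t_filter, sum(flags))

  # conservation keeps only the conserved planted window
  aln <- gen_toy_alignment(utr, selected_species_ladder(4),
                           conserved_windows = 40L, k = 7,
                           mutation_rate_outside = 0.5)
  cons <- filtered_counts(utr, word, filter_config("cons"), aln = aln)
  expect_gte(cons$c_filter, 1L)

  both <- filtered_counts(utr, word, filter_config("cons+access"),
                          profile = prof, aln = aln)
  expect_lte(both$t_filter, min(cons$t_filter, acc$t_filter))
  expect_lte(both$c_filter, min(cons$c_filter, acc$c_filter))
  expect_lte(cons$t_filter, none$t_filter)
  expect_lte(acc$t_filter, none$t_filter)

  expect_error(filtered_counts(utr, word, filter_config("access")),
               "requires an unpaired-probability profile")
  expect_error(filtered_counts(utr, word, filter_config("cons")),
               "requires an alignment")
})

test_that("score_interaction composes the pipeline and flags non-predictions", {
  set.seed(77)
  m <- mirna("let7a", "UGAGGUAGUAGGUUGUAUAGUU")
  word <- seed_word(m)$word
  base <- gen_utr("gA", 300, rep(0.25, 4))
  base$sequence <- gsub("CTACCTC", "CTACCTG", base$sequence, fixed = TRUE)
  base <- utr_record("gA", base$sequence)

  # same sequence, same matches; gene A has all 3 sites conserved+accessible,
  # gene B only 1 of 3 -> A must score more significant under cons+access
  utrA <- plant_matches(base, word, c(20L, 100L, 200L))
  utrB <- utr_record("gB", utrA$sequence)
  profA <- gen_pfree_profile("gA", 300, c(20L, 100L, 200L))
  profB <- gen_pfree_profile("gB", 300, c(20L))
  alnA <- gen_toy_alignment(utrA, selected_species_ladder(4),
                            c(20L, 100L, 200L), k = 7,
                            mutation_rate_outside = 0.5)
  alnB <- gen_toy_alignment(utrB, selected_species_ladder(4), c(20L), k = 7,
                            mutation_rate_outside = 0.5)
  cfg <- filter_config("cons+access")
  sA <- score_interaction(m, utrA, cfg, profA, alnA)
  sB <- score_interaction(m, utrB, cfg, profB, alnB)
  expect_gte(sA$c_filter, 3L)
  expect_lt(sA$p_sh, sB$p_sh)

  # no matches -> non-prediction with p_sh 1
  none <- score_interaction(mirna("mx", "CCCCCCCCCCCCCCCCCCCCCC"),
                            utr_record("gC", strrep("A", 60)),
                            filter_config("none"))
  expect_false(none$prediction)
  expect_equal(none$p_sh, 1)

  # a stricter filter keeping all matches lowers p_sh (smaller t, same c)
  s_none <- score_interaction(m, utrA, filter_config("none"))
  expect_lt(sA$p_sh, s_none$p_sh)
})

test_that("batch scoring equals per-pair scoring", {
  set.seed(13)
  spec <- fixture_spec(rng_seed = 5, n_mirnas = 4, n_genes = 10,
                       n_functional = 10, utr_length_range = c(200L, 260L))
  b <- gen_benchmark(spec)
  cfg <- filter_config("cons+access")
  batch <- predict_targets(b$mirnas, b$utrs, cfg, b$profiles, b$alignments)
  expect_equal(nrow(batch), 4L * 10L)
  for (i in sample(nrow(batch), 8)) {
    row <- batch[i, ]
    single <- score_interaction(b$mirnas[[row$mirna_id]],
                                b$utrs[[row$gene_id]], cfg,
                                b$profiles[[row$gene_id]],
                                b$alignments[[row$gene_id]])
    expect_equal(row$t_filter, single$t_filter)
    expect_equal(row$c_filter, single$c_filter)
    expect_equal(row$p_sh, single$p_sh)
  }
})

test_that("ranking is by ascending p_sh with deterministic tie-breaks", {
  df <- data.frame(
    mirna_id = c("m2", "m1", "m1", "m3", "m1"),
    gene_id = c("gB", "gA", "gB", "gA", "gC"),
    t_filter = 50L, c_filter = c(2L, 3L, 2L, 0L, 2L),
    p_word = 1e-4, p_sh = c(1e-3, 1e-5, 1e-5, 1, 1e-3),
    prediction = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  r <- rank_predictions(df)
  expect_equal(nrow(r), 4L)                   # non-prediction dropped
  expect_equal(r$p_sh, sort(r$p_sh))
  # tie at 1e-5: c_filter 3 beats 2
  expect_equal(r$c_filter[1:2], c(3L, 2L))
  # tie at 1e-3 with equal c: gene_id ascending
  expect_equal(r$gene_id[3:4], c("gB", "gC"))
  expect_equal(r$rank, 1:4)
  expect_equal(nrow(rank_predictions(df[0, ])), 0L)
})
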