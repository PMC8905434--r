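test_that("inventories are reproducible and decompose as constructed", {
  cfg <- synth_config(n_words = 20, n_multiword = 10, n_subword = 4, seed = 9)
  inv1 <- make_inventory(cfg)
  inv2 <- make_inventory(cfg)
  expect_identical(inv1$chunk, inv2$chunk)
  expect_equal(nrow(inv1), 34L)
  # every multiword chunk decomposes into inventory words
  words <- sub(" $", "", inv1$chunk[inv1$type == "word"])
  multi <- inv1$chunk[inv1$type == "multiword"]
  parts <- strsplit(trimws(multi), " ")
  expect_true(all(unlist(parts) %in% words))
  # weights positive and Zipfian by rank
  expect_true(all(inv1$weight > 0))
  expect_equal(inv1$weight, 1 / inv1$rank^cfg$zipf_s)

  inv_w <- make_inventory(synth_config(n_words = 5, n_multiword = 0,
                                       n_subword = 0, seed = 2))
  expect_true(all(inv_w$type == "word"))
})

test_that("sampled corpora carry their true segmentation exactly", {
  world <- tiny_world(seed = 17, n_sequences = 50)
  expect_equal(nrow(world$corpus), 50L)
  expect_identical(segmentation_text(world$segmentation)$rendered,
                   world$corpus$rendered)
  # generator output is already normalised text
  renorm <- normalize_text(world$corpus$rendered)
  expect_identical(paste0(renorm, " "), world$corpus$rendered)
  # single chunk per sequence: one true unit each
  one <- synth_config(n_words = 6, n_multiword = 2, n_subword = 0,
                      n_sequences = 20, chunks_per_sequence = c(1L, 1L), seed = 3)
  w1 <- sample_corpus(make_inventory(one), one)
  expect_true(all(tapply(w1$segmentation$token_index,
                         w1$segmentation$sequence_id, max) == 1L))
})

test_that("chunk frequencies follow the Zipf weights", {
  cfg <- synth_config(n_words = 10, n_multiword = 5, n_subword = 0,
                      n_sequences = 2000, chunks_per_sequence = c(5L, 5L),
                      seed = 23)
  inv <- make_inventory(cfg)
  samp <- sample_corpus(inv, cfg)
  draws <- table(factor(samp$segmentation$form, levels = inv$chunk))
  n <- sum(draws)
  p <- inv$weight / sum(inv$weight)
  p_hat <- as.numeric(draws) / n
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(p_hat - p) <= 4 * se + 1e-9))
})

test_that("noiseless fixations close the loop and noise flips at rate p", {
  world <- tiny_world(seed = 29, n_sequences = 60)
  clean <- synth_fixations(world$segmentation, world$corpus, noise = 0)
  pred <- predict_fixation_counts(world$segmentation, world$corpus)
  expect_identical(clean, pred)
  expect_equal(weighted_f1(clean, pred), 100)
  expect_equal(sum(clean$fixation_count), nrow(world$segmentation))

  # with words only, every count is 1, so a perturbation always changes it:
  # the disagreement rate is Binomial(n, p)
  cfg <- synth_config(n_words = 12, n_multiword = 0, n_subword = 0,
                      n_sequences = 1500, chunks_per_sequence = c(5L, 8L),
                      seed = 31)
  w <- sample_corpus(make_inventory(cfg), cfg)
  base <- synth_fixations(w$segmentation, w$corpus, noise = 0)
  noisy <- synth_fixations(w$segmentation, w$corpus, noise = 0.3, seed = 8)
  n <- nrow(base)
  rate <- mean(noisy$fixation_count != base$fixation_count)
  expect_lt(abs(rate - 0.3), 4 * sqrt(0.3 * 0.7 / n))
  # flooring keeps counts nonnegative even at noise 1
  all_on <- synth_fixations(w$segmentation, w$corpus, noise = 1, seed = 9)
  expect_true(all(all_on$fixation_count >= 0))
})

test_that("lexicon recall counts inventory chunks near the lexicon front", {
  inv <- make_inventory(synth_config(n_words = 6, n_multiword = 4,
                                     n_subword = 2, seed = 41))
  targets <- inv$chunk[inv$type %in% c("multiword", "subword")]
  full <- new_lexicon(c(targets, letters[1:12]))
  expect_equal(lexicon_recall(full, inv, top_fraction = 1), 1)
  disjoint <- new_lexicon(c("zz ", "yy ", "xx "))
  expect_equal(lexicon_recall(disjoint, inv), 0)
  # 2 of 4 multiword chunks in the searched top fraction
  m <- inv$chunk[inv$type == "multiword"]
  lex <- new_lexicon(c(m[1:2], paste0("pad", 1:10, " "), m[3:4]))
  expect_equal(lexicon_recall(lex, inv, top_fraction = 2 / 14,
                              types = "multiword"), 0.5)
})
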