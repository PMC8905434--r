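test_that("unit centers fall on middle characters or middle boundaries", {
  # "i have": even effective length 6, center between 'h' and 'a'
  expect_equal(unit_center("i have ", 1L), 3.5)
  expect_equal(unit_center("a ", 1L), 1)
  expect_equal(unit_center("neuro", 1L), 3)
  # position covariance: shifting the unit shifts the center
  k <- 7L
  expect_equal(unit_center("neuro", 1L + k), unit_center("neuro", 1L) + k)
})

test_that("the center rule reproduces the worked fixation predictions", {
  corp <- new_corpus("i have")
  seg <- segment_corpus(new_lexicon("i have "), corp, evaluate = FALSE)
  pred <- predict_fixation_counts(seg, corp)
  expect_identical(pred$fixation_count, c(0L, 1L))

  corp2 <- new_corpus("neuroscience")
  seg2 <- tibble::tibble(sequence_id = 1L, token_index = 1:2,
                         form = c("neuro", "science "),
                         start = c(1L, 6L), end = c(5L, 13L), oov = FALSE)
  pred2 <- predict_fixation_counts(seg2, corp2)
  expect_identical(pred2$fixation_count, 2L)
})

test_that("predicted fixations conserve the token count and match word-by-word identity", {
  world <- tiny_world(seed = 5, n_sequences = 40)
  pred <- predict_fixation_counts(world$segmentation, world$corpus)
  totals <- tapply(pred$fixation_count, pred$sequence_id, sum)
  n_tokens <- tapply(world$segmentation$token_index, world$segmentation$sequence_id, length)
  expect_equal(as.integer(totals), as.integer(n_tokens))

  # the identity segmentation (every word its own unit) equals Word-by-Word
  corp <- new_corpus(c("one two three", "four five"))
  lex <- new_lexicon(c("one ", "two ", "three ", "four ", "five "))
  seg <- segment_corpus(lex, corp, evaluate = FALSE)
  expect_identical(predict_fixation_counts(seg, corp),
                   predict_word_by_word(corp))
})

test_that("a center on a space or word boundary goes to the dominant word, right on ties", {
  corp <- new_corpus("ab cd")
  # unit "ab cd": effective length 5, center on the space; tie 2 vs 2 -> right word
  seg <- tibble::tibble(sequence_id = 1L, token_index = 1L, form = "ab cd ",
                        start = 1L, end = 6L, oov = FALSE)
  expect_identical(predict_fixation_counts(seg, corp)$fixation_count, c(0L, 1L))
  # unit "a bcd": center on 'c' -> clear majority word
  corp2 <- new_corpus("a bcd")
  seg2 <- tibble::tibble(sequence_id = 1L, token_index = 1L, form = "a bcd ",
                         start = 1L, end = 6L, oov = FALSE)
  expect_identical(predict_fixation_counts(seg2, corp2)$fixation_count, c(0L, 1L))
})

test_that("hyphen-split model words merge back onto reference words", {
  raw <- list(c("forty-five", "men"))
  map <- build_hyphen_map(raw)
  expect_equal(nrow(map), 3L)
  model_counts <- tibble::tibble(sequence_id = 1L, word_index = 1:3,
                                 word = c("forty", "five", "men"),
                                 fixation_count = c(1L, 1L, 1L))
  ref <- align_reference_words(model_counts, map)
  expect_equal(ref$fixation_count[ref$word_index == 1L], 2L)

  model_counts$fixation_count <- c(0L, 1L, 1L)
  ref2 <- align_reference_words(model_counts, map)
  expect_equal(ref2$fixation_count[ref2$word_index == 1L], 1L)

  # no hyphens: identity mapping
  map2 <- build_hyphen_map(list(c("plain", "words")))
  expect_identical(map2$model_word_index, map2$ref_word_index)

  # an uncovered model word is an alignment error
  expect_error(
    align_reference_words(
      tibble::tibble(sequence_id = 1L, word_index = 1:4,
                     word = c("forty", "five", "men", "extra"),
                     fixation_count = 1L),
      map),
    "unalignable")
})

test_that("three-way labels split at zero, one, and more", {
  expect_identical(as.character(label3(c(0L, 1L, 3L))), c("Skip", "One", "More"))
  expect_error(label3(-1L), ">= 0")
})

test_that("observed unit length is rendered length over fixation count", {
  obs <- tibble::tibble(sequence_id = 1L, word_index = 1L, word = "abcde",
                        fixation_count = 2L)
  expect_equal(mean_observed_unit_length(obs, new_corpus("abcde")), 3)
  # word-by-word reading: mean unit length = mean word length + 1
  corp <- new_corpus(c("ab cde", "f ghij"))
  wbw <- predict_word_by_word(corp)
  expect_equal(mean_observed_unit_length(wbw, corp),
               mean(nchar(corpus_words(corp)$word)) + 1)
  # single word, single fixation: its rendered length
  obs1 <- tibble::tibble(sequence_id = 1L, word_index = 1L, word = "abc",
                         fixation_count = 1L)
  expect_equal(mean_observed_unit_length(obs1, new_corpus("abc")), 4)
  obs0 <- obs1
  obs0$fixation_count <- 0L
  expect_error(mean_observed_unit_length(obs0, new_corpus("abc")), "nonzero")
})
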