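test_that("candidate matching returns lexicon prefixes, longest first", {
  lex <- new_lexicon(c("ab", "a", "b"))
  expect_identical(match_candidates(lex, "ab ", 1L), c("ab", "a"))
  expect_identical(match_candidates(new_lexicon("a"), "z ", 1L), character(0))
  lex2 <- new_lexicon(c("to do ", "to ", "do "))
  expect_identical(match_candidates(lex2, "to do ", 1L), c("to do ", "to "))
  expect_error(match_candidates(lex, "a b ", 2L), "space")
})

test_that("greedy lookahead counts tokens on the stated paths", {
  lex <- new_lexicon(c("ab", "a", "b"))
  expect_equal(lookahead_token_count(lex, "aba ", 1L, "ab"), 2L)
  expect_equal(lookahead_token_count(lex, "aba ", 1L, "a"), 3L)
  expect_equal(lookahead_token_count(new_lexicon("abc "), "abc ", 1L, "abc "), 1L)
})

test_that("counterfactual selection keeps the largest type unless it costs tokens", {
  lex <- new_lexicon(c("ab", "a", "b"))
  ch <- choose_unit(lex, "aba ", 1L)
  expect_identical(ch$form, "ab")
  expect_identical(ch$verdict, "good")

  lex2 <- new_lexicon(c("abc", "ab", "c", "a", "b"))
  ch2 <- choose_unit(lex2, "abab ", 1L)
  expect_identical(ch2$form, "ab")
  expect_identical(ch2$verdict, "good")

  # tie on lookahead counts: the largest wins and is Good
  lex3 <- new_lexicon(c("ab", "a", "bc", "b", "c"))
  ch3 <- choose_unit(lex3, "abc ", 1L)
  expect_identical(ch3$form, "ab")
  expect_identical(ch3$verdict, "good")

  # a largest type that fragments the following input is Bad and rejected
  lex4 <- new_lexicon(c("ab", "a", "bcd ", "b", "c", "d"))
  ch4 <- choose_unit(lex4, "abcd ", 1L)
  expect_identical(ch4$verdict, "bad")
  expect_identical(ch4$verdict_form, "ab")
  expect_identical(ch4$form, "a")

  # only one candidate: selected without evaluation
  ch5 <- choose_unit(new_lexicon(c("ab")), "ab ", 1L)
  expect_identical(ch5$verdict, "none")
  expect_identical(ch5$form, "ab ")
})

test_that("segmentation covers the sequence exactly and matches the examples", {
  # empty lexicon: singleton out-of-lexicon tokens
  seg0 <- segment_corpus(new_lexicon(), new_corpus("ab"))
  expect_identical(seg0$form, c("a", "b "))
  expect_true(all(seg0$oov))

  lex <- new_lexicon(c("i ", "was ", "trying "))
  seg1 <- segment_sequence(lex, c("i", "was", "trying"))
  expect_equal(nrow(seg1), 3L)

  lex2 <- new_lexicon(c("i was ", "i ", "was ", "trying to ", "trying ",
                        "to ", "do ", "what "))
  seg2 <- segment_sequence(lex2, "i was trying to do ")
  expect_identical(seg2$form, c("i was ", "trying to ", "do "))
  expect_equal(nrow(seg2), 3L)
})

test_that("larger-first selection matches the brute-force oracle on random instances", {
  set.seed(401)
  for (i in 1:500) {
    inst <- random_instance()
    lex <- new_lexicon(inst$forms)
    seg <- segment_corpus(lex, new_corpus(stringr::str_trim(inst$rendered)),
                          evaluate = FALSE)
    expect_identical(seg$form, oracle_greedy_segment(inst$forms, inst$rendered))
    # coverage holds on every instance
    expect_identical(paste(seg$form, collapse = ""), inst$rendered)
  }
})

test_that("compiled selection agrees with the R reference under evaluation", {
  set.seed(402)
  for (i in 1:100) {
    inst <- random_instance()
    lex <- new_lexicon(inst$forms)
    seg <- segment_corpus(lex, new_corpus(stringr::str_trim(inst$rendered)),
                          evaluate = TRUE)
    pos <- 1L
    forms_r <- character(0)
    n <- nchar(inst$rendered)
    while (pos <= n && substr(inst$rendered, pos, pos) != " ") {
      ch <- choose_unit(lex, inst$rendered, pos, evaluate = TRUE)
      forms_r <- c(forms_r, ch$form)
      pos <- ch$end + 1L
    }
    expect_identical(seg$form, forms_r)
  }
})

test_that("the selected candidate never has a strictly worse lookahead count", {
  set.seed(403)
  for (i in 1:100) {
    inst <- random_instance()
    lex <- new_lexicon(inst$forms)
    seg <- segment_corpus(lex, new_corpus(stringr::str_trim(inst$rendered)),
                          evaluate = TRUE)
    v <- attr(seg, "verdicts")
    if (nrow(v) == 0L) next
    sel <- ifelse(v$verdict == "good", v$count_largest, v$count_second)
    rej <- ifelse(v$verdict == "good", v$count_second, v$count_largest)
    expect_true(all(sel <= rej))
  }
})

test_that("memorising appends sampled pairs and novel symbols at the end", {
  lex <- new_lexicon(c("i ", "have "))
  seg <- segment_sequence(lex, c("i", "have"), evaluate = FALSE)
  cfg <- lib_config(p_memorize = 1)
  set.seed(1)
  lex2 <- memorize_pairs(seg, lex, cfg)
  expect_identical(lex2$forms, c("i ", "have ", "i have "))
  # already present: size unchanged
  set.seed(1)
  lex3 <- memorize_pairs(seg, lex2, cfg)
  expect_equal(length(lex3$forms), 3L)
  # over the unit-length limit: not added
  lex4 <- new_lexicon(c("ab", "cdef"), max_unit_len = 4)
  seg4 <- segment_sequence(lex4, "abcdef", evaluate = FALSE)
  set.seed(1)
  lex5 <- memorize_pairs(seg4, lex4, lib_config(p_memorize = 1))
  expect_false("abcdef " %in% lex5$forms)
  # novel symbols always memorised, without their boundary space
  seg0 <- segment_corpus(new_lexicon(), new_corpus("ab"))
  lex6 <- memorize_pairs(seg0, new_lexicon(), lib_config(p_memorize = 0))
  expect_true(all(c("a", "b") %in% lex6$forms))
})

test_that("re-ranking moves Good forward and Bad backward multiplicatively", {
  forms <- paste0("u", 1:8, " ")
  lex <- new_lexicon(forms)
  cfg <- lib_config(promote_factor = 0.5, demote_factor = 2)
  up <- apply_rerank(lex, tibble::tibble(form = "u8 ", verdict = "good"), cfg)
  expect_equal(match("u8 ", up$forms), 4L)
  top <- apply_rerank(lex, tibble::tibble(form = "u1 ", verdict = "good"), cfg)
  expect_equal(match("u1 ", top$forms), 1L)
  lex5 <- new_lexicon(paste0("v", 1:5, " "))
  down <- apply_rerank(lex5, tibble::tibble(form = "v3 ", verdict = "bad"), cfg)
  expect_equal(match("v3 ", down$forms), 5L)
  expect_error(apply_rerank(lex, tibble::tibble(form = "zz ", verdict = "good"), cfg),
               "unknown form")
  # a Good verdict cancels probation
  lex$probation_age <- rep(2L, 8L)
  good <- apply_rerank(lex, tibble::tibble(form = "u8 ", verdict = "good"), cfg)
  expect_equal(good$probation_age[match("u8 ", good$forms)], 0L)
  expect_identical(good$last_verdict[match("u8 ", good$forms)], "good")
})

test_that("forgetting removes aged tail entries but never the alphabet", {
  cfg <- lib_config(probation_zone = 0.5, probation_period = 2)
  lex <- new_lexicon(c("keep ", "mid ", "ab", "cd", "e"))
  # age the tail for probation_period epochs
  lex <- apply_forgetting(lex, cfg)
  lex <- apply_forgetting(lex, cfg)
  expect_false(any(c("cd") %in% lex$forms))
  expect_true("e" %in% lex$forms)       # single symbol survives
  expect_true("keep " %in% lex$forms)   # front entries untouched
  # a Good tail entry is retained
  lex2 <- new_lexicon(c("keep ", "mid ", "ab", "cd", "e"))
  lex2$last_verdict[4] <- "good"
  lex2 <- apply_forgetting(lex2, cfg)
  lex2 <- apply_forgetting(lex2, cfg)
  expect_true("cd" %in% lex2$forms)
})

test_that("encoding bits follow the empirical Shannon code length", {
  expect_equal(encoding_bits(c("a", "a", "b", "b")), 4)
  expect_equal(encoding_bits(rep("x", 7)), 0)
  expect_equal(encoding_bits(c("a", "b", "c", "d")), 8)
  expect_error(encoding_bits(character(0)), "nonempty")
})

test_that("training is deterministic and stops on the bits plateau", {
  world <- tiny_world(seed = 71, n_sequences = 120)
  cfg <- lib_config(batch_size = 60, seed = 9, max_epochs = 60)
  fit1 <- lib_train(world$corpus, cfg)
  fit2 <- lib_train(world$corpus, cfg)
  expect_identical(fit1$lexicon$forms, fit2$lexicon$forms)
  expect_identical(fit1$report, fit2$report)
  if (fit1$stop_reason == "no-improvement") {
    expect_equal(nrow(fit1$report) - which.min(fit1$report$bits),
                 cfg$stop_patience)
  }
  # lexicon invariants hold after training
  expect_equal(anyDuplicated(fit1$lexicon$forms), 0L)
  alphabet <- unique(strsplit(gsub(" ", "", paste(world$corpus$rendered, collapse = "")), "")[[1]])
  expect_true(all(alphabet %in% fit1$lexicon$forms))
})

test_that("large-corpus mode consumes the material once and stops", {
  world <- tiny_world(seed = 72, n_sequences = 100)
  fit <- lib_train(world$corpus, lib_config(batch_size = 40, seed = 2),
                   large_corpus_mode = TRUE)
  expect_identical(fit$stop_reason, "material-exhausted")
  expect_equal(nrow(fit$report), 3L)  # 100 sequences in batches of 40
})

test_that("adding a matching multiword type never increases the token count", {
  base <- new_lexicon(c("my ", "mind ", "up ", "what "))
  rendered <- "up my mind "
  n_before <- nrow(segment_sequence(base, rendered, evaluate = FALSE))
  richer <- new_lexicon(c("my mind ", "my ", "mind ", "up ", "what "))
  n_after <- nrow(segment_sequence(richer, rendered, evaluate = FALSE))
  expect_lte(n_after, n_before)
})
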