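# Independent oracles and random-instance generators for property tests.
# These deliberately avoid the package's own matching/segmentation code
# paths: matching is done by raw substring comparison, F1 by the
# precision/recall route.

# Brute-force larger-first segmentation: at every position scan the whole
# lexicon by substring equality, take the longest match (or a singleton for
# unknown symbols), and absorb a following word-boundary space.
oracle_greedy_segment <- function(forms, rendered) {
  n <- nchar(rendered)
  out <- character(0)
  pos <- 1L
  while (pos <= n) {
    ch <- substr(rendered, pos, pos)
    if (ch == " ") {
      pos <- pos + 1L
      next
    }
    best_len <- 0L
    for (f in forms) {
      fl <- nchar(f)
      if (fl > best_len && pos + fl - 1L <= n &&
          substr(rendered, pos, pos + fl - 1L) == f) {
        best_len <- fl
      }
    }
    if (best_len == 0L) best_len <- 1L
    end <- pos + best_len - 1L
    if (end < n && substr(rendered, end + 1L, end + 1L) == " " &&
        substr(rendered, end, end) != " ") {
      end <- end + 1L
    }
    out <- c(out, substr(rendered, pos, end))
    pos <- end + 1L
  }
  out
}

# F1 through precision and recall (harmonic mean), not the direct formula.
oracle_f1 <- function(tp, fp, fn) {
  if (tp + fp == 0 || tp + fn == 0) return(0)
  p <- tp / (tp + fp)
  r <- tp / (tp + fn)
  if (p + r == 0) return(0)
  2 * p * r / (p + r)
}

# Random lexicon + rendered sequence over a tiny alphabet; forms include
# word-final (trailing space) and plain variants.
random_instance <- function(alphabet = c("a", "b", "c")) {
  n_words <- sample(1:4, 1)
  words <- replicate(n_words, paste(
    sample(alphabet, sample(1:4, 1), replace = TRUE), collapse = ""))
  rendered <- paste0(paste(words, collapse = " "), " ")
  pool <- unique(unlist(lapply(words, function(w) {
    ks <- seq_len(nchar(w))
    subs <- unlist(lapply(ks, function(k) {
      substring(w, seq_len(nchar(w) - k + 1), seq.int(k, nchar(w)))
    }))
    c(subs, paste0(w, " "))
  })))
  pool <- c(pool, paste(sample(words, min(2, length(words))), collapse = " "))
  forms <- unique(sample(pool, min(length(pool), sample(2:8, 1))))
  forms <- forms[!startsWith(forms, " ") & nchar(forms) > 0]
  list(forms = forms, rendered = rendered)
}

# Independent CBL pass over word sequences using data-frame counts; follows
# the definitional rule (merge when BTP strictly exceeds the running mean
# of all previous BTP evaluations) with none of the package's data
# structures.
oracle_cbl_mean_btp <- function(sequences) {
  uni <- list()
  bi <- list()
  btps <- numeric(0)
  inc <- function(l, k) { l[[k]] <- (l[[k]] %||% 0) + 1; l }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  for (words in sequences) {
    cur <- words[[1]]
    uni <- inc(uni, cur)
    for (w in words[-1]) {
      uni <- inc(uni, w)
      bk <- paste(cur, w, sep = "\r")
      bi <- inc(bi, bk)
      btp <- bi[[bk]] / uni[[w]]
      merge <- length(btps) > 0 && btp > mean(btps)
      btps <- c(btps, btp)
      if (merge) {
        chunk <- paste(cur, w)
        uni <- inc(uni, chunk)
        cur <- chunk
      } else {
        cur <- w
      }
    }
  }
  list(mean_btp = mean(btps), n = length(btps))
}

# Small deterministic synthetic world shared by several tests.
tiny_world <- function(seed = 303, n_sequences = 60, ...) {
  cfg <- synth_config(n_words = 10, n_multiword = 5, n_subword = 3,
                      n_sequences = n_sequences, seed = seed, ...)
  inv <- make_inventory(cfg)
  samp <- sample_corpus(inv, cfg)
  list(config = cfg, inventory = inv, corpus = samp$corpus,
       segmentation = samp$segmentation)
}
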