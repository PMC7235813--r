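test_that("corpus_spec enforces its invariants", {
  expect_error(default_corpus_spec(n_sentences = 0), "n_sentences")
  spec <- default_corpus_spec(n_sentences = 10)
  lex <- spec$entity_lexicons
  lex$Med <- character(0)
  expect_error(corpus_spec(lex, spec$context_alphabet, spec$templates, 10),
               "Med")
  lex2 <- spec$entity_lexicons
  lex2$Sym <- c(lex2$Sym, lex2$Dis[1]) # breaks disjointness
  expect_error(corpus_spec(lex2, spec$context_alphabet, spec$templates, 10),
               "disjoint")
  lex3 <- spec$entity_lexicons
  lex3$Dis <- c(lex3$Dis, "a\tb")
  expect_error(corpus_spec(lex3, spec$context_alphabet, spec$templates, 10),
               "separator")
  expect_error(corpus_spec(spec$entity_lexicons, spec$context_alphabet,
                           c("cce", "cxe"), 10), "templates")
  expect_error(corpus_spec(spec$entity_lexicons, spec$context_alphabet,
                           "eeee", 10, max_entities_per_sentence = 3),
               "max_entities")
})

test_that("generation is deterministic and records exact entity offsets", {
  spec <- default_corpus_spec(n_sentences = 200, seed = 99)
  c1 <- generate_corpus(spec)
  c2 <- generate_corpus(spec)
  expect_identical(c1, c2)
  expect_length(c1, 200L)
  # every recorded span, re-read off the emitted characters, is a lexicon
  # entry of the recorded type
  for (s in c1) {
    for (i in seq_len(nrow(s$entities))) {
      e <- s$entities[i, ]
      surface <- paste(s$tokens[(e$start + 1):e$end], collapse = "")
      expect_true(surface %in% spec$entity_lexicons[[e$type]])
    }
  }
})

test_that("a one-entry lexicon with a fixed template gives the expected span", {
  spec <- default_corpus_spec(n_sentences = 1)
  lex <- lapply(spec$entity_lexicons, function(x) x[1])
  lex$Dis <- "D"
  spec2 <- corpus_spec(lex, spec$context_alphabet, templates = "ccce",
                       n_sentences = 50, seed = 3)
  corp <- generate_corpus(spec2)
  dis <- Filter(function(s) s$entities$type[1] == "Dis", corp)
  expect_gt(length(dis), 0)
  for (s in dis) {
    expect_equal(s$entities$start, 3L)
    expect_equal(s$entities$end, 4L)
    expect_identical(s$tokens[4], "D")
  }
})

test_that("column file write/read roundtrips and rejects malformed input", {
  f <- withr::local_tempfile()
  # empty file -> empty corpus
  writeLines(character(0), f)
  expect_length(read_column_file(f), 0L)

  corp <- generate_corpus(default_corpus_spec(n_sentences = 1000, seed = 5))
  write_column_file(corp, f)
  back <- read_column_file(f)
  expect_identical(lapply(back, unclass), lapply(corp, unclass))
  # read -> write is also an identity on the file
  f2 <- withr::local_tempfile()
  write_column_file(back, f2)
  expect_identical(readLines(f2), readLines(f))

  writeLines(c("a\tB-Dis", "b\tB-Xyz"), f)
  expect_error(read_column_file(f), "line 2.*B-Xyz")
  writeLines(c("a\tB-Dis\textra"), f)
  expect_error(read_column_file(f), "parse error at line 1")
})

test_that("column files preserve non-ASCII characters", {
  f <- withr::local_tempfile()
  tokens <- c("病", "痛", "x")
  s <- annotated_sentence(tokens, entity_spans("Sym", 0, 2))
  write_column_file(list(s), f)
  back <- read_column_file(f)
  expect_identical(back[[1]]$tokens, tokens)
  expect_identical(unclass(back[[1]]$entities), unclass(s$entities))
})

test_that("split sizes follow largest-remainder rounding", {
  corp4000 <- generate_corpus(default_corpus_spec(n_sentences = 4000, seed = 2))
  sp <- split_corpus(corp4000, c(0.6, 0.2, 0.2), seed = 1)
  expect_identical(unname(lengths(sp)), c(2400L, 800L, 800L))

  sp10 <- split_corpus(as.list(1:10), c(0.6, 0.2, 0.2), seed = 1)
  expect_identical(unname(lengths(sp10)), c(6L, 2L, 2L))

  # independent largest-remainder oracle on small n
  lr_oracle <- function(n, fr) {
    base <- floor(n * fr)
    rem <- n - sum(base)
    fracs <- n * fr - base
    while (rem > 0) {
      k <- which(fracs == max(fracs))[1] # earliest split wins ties
      base[k] <- base[k] + 1
      fracs[k] <- -1
      rem <- rem - 1
    }
    as.integer(base)
  }
  for (n in c(1, 2, 3, 5, 7, 11, 123)) {
    sp_n <- split_corpus(as.list(seq_len(n)), c(0.6, 0.2, 0.2), seed = 4)
    expect_identical(unname(lengths(sp_n)), lr_oracle(n, c(0.6, 0.2, 0.2)),
                     label = paste("n =", n))
  }
  expect_identical(unname(lengths(split_corpus(as.list(1:5), c(0.6, 0.2, 0.2)))),
                   c(3L, 1L, 1L))
})

test_that("splits partition the corpus and are seed-deterministic", {
  corp <- as.list(1:237)
  s1 <- split_corpus(corp, seed = 11)
  s2 <- split_corpus(corp, seed = 11)
  expect_identical(s1, s2)
  all_items <- c(s1$train, s1$validation, s1$test)
  expect_setequal(unlist(all_items), 1:237)
  expect_length(all_items, 237L)
  expect_error(split_corpus(corp, c(0.5, 0.2, 0.2)), "sum to 1")
  expect_error(split_corpus(corp, c(0.8, 0.3, -0.1)), "positive")
})

test_that("entity-character fraction matches the template design", {
  spec <- default_corpus_spec(n_sentences = 1500, seed = 31)
  corp <- generate_corpus(spec)
  ent_chars <- sum(vapply(corp, function(s) {
    sum(s$entities$end - s$entities$start)
  }, numeric(1)))
  tot_chars <- sum(vapply(corp, function(s) length(s$tokens), numeric(1)))
  # expectation from the spec: templates uniform, types uniform, entries
  # uniform within type
  mean_entry_len <- mean(vapply(spec$entity_lexicons,
                                function(l) mean(nchar(l)), numeric(1)))
  tpl <- strsplit(spec$templates, "")
  e_slots <- vapply(tpl, function(x) sum(x == "e"), numeric(1))
  c_slots <- vapply(tpl, function(x) sum(x == "c"), numeric(1))
  expected <- mean(e_slots * mean_entry_len) /
    mean(e_slots * mean_entry_len + c_slots)
  expect_lt(abs(ent_chars / tot_chars - expected), 0.05)
})
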