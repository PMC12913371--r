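test_that("tokenizer keeps biomedical surface forms intact and peels punctuation", {
  tk <- tokenizeText("IL-2 level")
  expect_identical(tk$text, c("IL-2", "level"))
  expect_identical(tk$char_start, c(0L, 5L))
  expect_identical(tk$char_end, c(4L, 10L))
  expect_identical(tokenizeText("CD4+ T cells.")$text,
                   c("CD4+", "T", "cells", "."))
  expect_identical(tokenizeText("(TNF-alpha), and TCR/CD3")$text,
                   c("(", "TNF-alpha", ")", ",", "and", "TCR/CD3"))
  expect_identical(nrow(tokenizeText("")), 0L)
  ## offsets always slice the original text back out
  txt <- "a (b) c-d e."
  tk <- tokenizeText(txt)
  for (i in seq_len(nrow(tk)))
    expect_identical(substr(txt, tk$char_start[i] + 1, tk$char_end[i]),
                     tk$text[i])
})

test_that("character annotations align to minimal covering token spans", {
  doc <- tokenizeAndAlign("IL-2 level was high",
                          data.frame(char_start = 0, char_end = 4,
                                     label = "CYTOKINE"))
  expect_identical(mentions(doc)$start, 1L)
  expect_identical(mentions(doc)$end, 1L)
  expect_false(mentions(doc)$snapped)
  ## whole text
  doc <- tokenizeAndAlign("one two three",
                          data.frame(char_start = 0, char_end = 13,
                                     label = "X"))
  expect_identical(unlist(mentions(doc)[1, c("start", "end")],
                          use.names = FALSE), c(1L, 3L))
  ## boundary inside a token snaps outward and is flagged
  doc <- tokenizeAndAlign("interleukin six",
                          data.frame(char_start = 2, char_end = 11,
                                     label = "CYTOKINE"))
  expect_identical(mentions(doc)$start, 1L)
  expect_true(mentions(doc)$snapped)
  expect_error(tokenizeAndAlign("abc", data.frame(char_start = 1, char_end = 1,
                                                  label = "X")),
               "zero-length")
  expect_error(tokenizeAndAlign("abc", data.frame(char_start = 0, char_end = 9,
                                                  label = "X")),
               "beyond text")
})

test_that("PubTator blocks parse, align, and round-trip", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("123|t|Lupus study",
               "123|a|IL-2 was measured in lupus patients.",
               "123\t0\t5\tLupus\tDISEASE\tD008180",
               "123\t12\t16\tIL-2\tCYTOKINE\t-",
               "",
               "456|t|Title only",
               ""), f)
  docs <- readPubtator(f)
  expect_length(docs, 2)
  expect_identical(docId(docs[[1]]), "123")
  m <- mentions(docs[[1]])
  expect_identical(m$label, c("DISEASE", "CYTOKINE"))
  expect_identical(m$start[2], m$end[2])   # single-word annotation
  expect_identical(nrow(mentions(docs[[2]])), 0L)
  ## round trip preserves doc ids, token spans and labels
  f2 <- withr::local_tempfile(fileext = ".txt")
  writePubtator(docs, f2)
  docs2 <- readPubtator(f2)
  for (i in seq_along(docs))
    expect_true(nestNER:::sameAnnotations(docs[[i]], docs2[[i]]))
  ## malformed annotation lines are rejected with context
  writeLines(c("1|t|T", "1\t0\t3"), f)
  expect_error(readPubtator(f), "columns")
  writeLines(c("1|t|Txt", "1\t0\t99\tx\tY\t-"), f)
  expect_error(readPubtator(f), "outside text")
})

test_that("BRAT standoff documents parse and reject unsupported spans", {
  txt <- withr::local_tempfile(fileext = ".txt")
  ann <- withr::local_tempfile(fileext = ".ann")
  writeLines("lupus is chronic", txt, sep = "")
  writeLines("T1\tDisease 0 5\tlupus", ann)
  doc <- readBrat(txt, ann)
  expect_identical(mentions(doc)$label, "Disease")
  expect_identical(mentions(doc)$start, 1L)
  writeLines(character(0), ann)
  expect_identical(nrow(mentions(readBrat(txt, ann))), 0L)
  writeLines("T1\tDisease 10 5\tx", ann)
  expect_error(readBrat(txt, ann), "invalid offsets")
  writeLines("T1\tDisease 0 3;5 8\tx", ann)
  expect_error(readBrat(txt, ann), "discontinuous")
  writeLines("T1\tDisease 0 5\twrong", ann)
  expect_error(readBrat(txt, ann), "does not match")
})

test_that("CoNLL parsing converts tag runs to spans with lenient repair", {
  f <- withr::local_tempfile(fileext = ".conll")
  writeLines(c("the\tO", "cell\tO"), f)
  expect_identical(nrow(mentions(readConll(f)[[1]])), 0L)
  writeLines(c("rheumatoid\tB-DIS", "arthritis\tI-DIS", "worsened\tO"), f)
  m <- mentions(readConll(f)[[1]])
  expect_identical(unlist(m[1, c("start", "end")], use.names = FALSE),
                   c(1L, 2L))
  ## orphan continuation tags: lenient opens a span, strict errors
  writeLines(c("arthritis\tI-DIS", "worsened\tO"), f)
  m <- mentions(readConll(f)[[1]])
  expect_identical(m$label, "DIS")
  expect_identical(m$start, 1L)
  expect_error(readConll(f, strict = TRUE), "orphan")
  writeLines(c("x\tQ-DIS"), f)
  expect_error(readConll(f), "unknown tag prefix")
})

test_that("orphan-repair matches a hand-computed table over prefix bigrams", {
  ## expected spans for every (previous, current) tag pair under lenient
  ## repair, computed by hand from BIOES semantics
  cases <- list(
    list(tags = c("O", "I-X"),    spans = cbind(2L, 2L)),
    list(tags = c("O", "E-X"),    spans = cbind(2L, 2L)),
    list(tags = c("B-X", "I-Y"),  spans = rbind(c(1L, 1L), c(2L, 2L))),
    list(tags = c("B-X", "B-X"),  spans = rbind(c(1L, 1L), c(2L, 2L))),
    list(tags = c("S-X", "I-X"),  spans = rbind(c(1L, 1L), c(2L, 2L))),
    list(tags = c("E-X", "E-X"),  spans = rbind(c(1L, 1L), c(2L, 2L))),
    list(tags = c("B-X", "E-X"),  spans = cbind(1L, 2L)),
    list(tags = c("I-X", "I-X"),  spans = cbind(1L, 2L))
  )
  for (cs in cases) {
    sp <- bioesToSpans(cs$tags)
    expect_identical(unname(as.matrix(sp[, c("start", "end")])),
                     unname(cs$spans), info = paste(cs$tags, collapse = " "))
  }
})

test_that("BIOES conversion is exact on flat documents and rejects nesting", {
  doc <- annotatedDocument("d", "a b c d e",
                           mentions = data.frame(start = c(1, 3), end = c(1, 5),
                                                 label = c("GENE", "DISEASE")))
  tags <- spansToBioes(doc)
  expect_identical(tags, c("S-GENE", "O", "B-DISEASE", "I-DISEASE",
                           "E-DISEASE"))
  back <- bioesToSpans(tags)
  expect_identical(back$start, c(1L, 3L))
  expect_identical(back$label, c("GENE", "DISEASE"))
  expect_identical(spansToBioes(annotatedDocument("d", "a b c",
    mentions = data.frame(start = 2, end = 2, label = "X"))),
    c("O", "S-X", "O"))
  nested <- annotatedDocument("d", "a b c",
                              mentions = data.frame(start = c(1, 2),
                                                    end = c(3, 2),
                                                    label = c("A", "B")))
  expect_error(spansToBioes(nested), "not representable")
})

test_that("generated corpora round-trip through CoNLL, PubTator and JSON", {
  corpus <- generateCorpus(genConfig(n_docs = 4, nest_rate = 0, seed = 5),
                           toy_schema)
  ## CoNLL (flat only): tokens, spans and labels survive
  f <- withr::local_tempfile(fileext = ".conll")
  writeConll(corpus, f)
  back <- readConll(f)
  expect_length(back, length(corpus))
  for (i in seq_along(corpus)) {
    expect_identical(back[[i]]@tokens$text, corpus[[i]]@tokens$text)
    expect_identical(mentions(back[[i]])[c("start", "end", "label")],
                     mentions(corpus[[i]])[c("start", "end", "label")])
  }
  ## BIO scheme round-trips too
  writeConll(corpus, f, scheme = "bio")
  back <- readConll(f)
  for (i in seq_along(corpus))
    expect_identical(mentions(back[[i]])[c("start", "end", "label")],
                     mentions(corpus[[i]])[c("start", "end", "label")])
  ## PubTator with nested gold
  nested <- generateCorpus(genConfig(n_docs = 4, nest_rate = 1, seed = 5),
                           toy_schema)
  f2 <- withr::local_tempfile(fileext = ".txt")
  writePubtator(nested, f2)
  back <- readPubtator(f2)
  for (i in seq_along(nested))
    expect_true(nestNER:::sameAnnotations(nested[[i]], back[[i]]))
  ## internal JSON is the canonical interchange: exact identity
  f3 <- withr::local_tempfile(fileext = ".json")
  writeCorpusJSON(nested, f3)
  back <- readCorpusJSON(f3)
  for (i in seq_along(nested))
    expect_true(nestNER:::sameAnnotations(nested[[i]], back[[i]]))
})

test_that("alignment preserves order and contains the annotated substring", {
  txt <- "CD4+ T cells secrete IL-2 in lupus."
  ann <- data.frame(char_start = c(0, 21, 29), char_end = c(12, 25, 34),
                    label = c("CELL", "CYTOKINE", "DISEASE"))
  doc <- tokenizeAndAlign(txt, ann)
  m <- mentions(doc)
  expect_false(is.unsorted(m$start))
  for (i in seq_len(nrow(m))) {
    cs <- nestNER:::tokenSpanChars(doc, m$start[i], m$end[i])
    slice <- substr(txt, cs[1] + 1, cs[2])
    orig <- substr(txt, ann$char_start[i] + 1, ann$char_end[i])
    expect_true(grepl(orig, slice, fixed = TRUE))
  }
})
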