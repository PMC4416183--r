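test_that("read_fasta parses entries, folds case, and keeps headers as ids", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "GGGG"), path)
  records <- read_fasta(path)
  expect_equal(records$id, c("a", "b"))
  expect_equal(records$residues, c("ACGT", "GGGG"))

  writeLines(c(">low", "acgt"), path)
  expect_equal(read_fasta(path)$residues, "ACGT")

  writeLines(c(">multi", "ACGT", "TTAA", "", ">next", "CCGG"), path)
  multi <- read_fasta(path)
  expect_equal(multi$residues, c("ACGTTTAA", "CCGG"))

  writeLines(character(0), path)
  expect_equal(nrow(read_fasta(path)), 0L)
})

test_that("read_fasta rejects malformed input with a located error", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("ACGT", ">a", "ACGT"), path)
  expect_error(read_fasta(path), "line 1")

  writeLines(c(">a", "ACGT", ">b"), path)
  expect_error(read_fasta(path), "no residues")
})

test_that("extract_kmers returns L-k+1 ordered windows on clean sequences", {
  expect_equal(extract_kmers("ACGTAC", k = 2),
               c("AC", "CG", "GT", "TA", "AC"))
  # property: window count and reconstruction at original offsets
  set.seed(42)
  for (k in c(2L, 5L, 8L)) {
    res <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                 collapse = "")
    kmers <- extract_kmers(res, k)
    expect_length(kmers, nchar(res) - k + 1L)
    expect_true(all(nchar(kmers) == k))
    rebuilt <- paste0(substr(kmers[1], 1, k - 1),
                      paste(substring(kmers, k, k), collapse = ""))
    expect_equal(rebuilt, res)
  }
  expect_equal(extract_kmers("ACG", k = 8), character(0))
})

test_that("windows containing ambiguity codes are skipped entirely", {
  expect_equal(extract_kmers("ACNGT", k = 2), c("AC", "GT"))
  expect_equal(extract_kmers("NNNN", k = 2), character(0))
  # no window of a skipped region ever leaks through
  kmers <- extract_kmers("ACGTNRYACGT", k = 4)
  expect_false(any(grepl("[^ACGT]", kmers)))
  expect_equal(kmers, c("ACGT", "ACGT"))
})

test_that("build_corpus enumerates the vocabulary and encodes documents", {
  records <- data.frame(id = c("r1", "r2"),
                        residues = c("ACGT", "CGTA"),
                        stringsAsFactors = FALSE)
  corpus <- build_corpus(records, k = 3)
  # windows by hand: r1 -> ACG,CGT ; r2 -> CGT,GTA
  expect_setequal(corpus$vocabulary, c("ACG", "CGT", "GTA"))
  expect_equal(lengths(corpus$documents), c(r1 = 2L, r2 = 2L))
  expect_equal(corpus$vocabulary[corpus$documents$r1], c("ACG", "CGT"))

  one <- build_corpus(data.frame(id = "x", residues = "ACGTAC"), k = 6)
  expect_equal(lengths(one$documents), c(x = 1L))
})

test_that("a frozen vocabulary drops OOV k-mers and flags empty documents", {
  train <- data.frame(id = "t", residues = "AAAACAAA")
  corpus <- build_corpus(train, k = 4)
  test <- data.frame(id = c("ok", "oov"),
                     residues = c("AAAAC", "GGGGGG"))
  enc <- build_corpus(test, k = 4, vocabulary = corpus$vocabulary)
  expect_equal(enc$vocabulary, corpus$vocabulary)
  expect_gt(length(enc$documents$ok), 0L)
  expect_length(enc$documents$oov, 0L)
  expect_equal(enc$empty, c(ok = FALSE, oov = TRUE))
  expect_error(
    build_corpus(data.frame(id = "x", residues = "GGGG"), k = 4,
                 vocabulary = c("AAAA")),
    "empty")
})

test_that("pre-built and fresh vocabularies give identical token multisets", {
  set.seed(7)
  records <- data.frame(
    id = paste0("r", 1:5),
    residues = replicate(5, paste(
      sample(c("A", "C", "G", "T", "N"), 80, replace = TRUE,
             prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")),
    stringsAsFactors = FALSE)
  fresh <- build_corpus(records, k = 5)
  frozen <- build_corpus(records, k = 5, vocabulary = rev(fresh$vocabulary))
  for (i in seq_along(fresh$documents)) {
    expect_equal(sort(fresh$vocabulary[fresh$documents[[i]]]),
                 sort(frozen$vocabulary[frozen$documents[[i]]]))
  }
})

test_that("extract_fragment returns seeded verbatim substrings", {
  records <- data.frame(id = c("a", "b"),
                        residues = c(strrep("ACGT", 300), strrep("GATC", 250)),
                        stringsAsFactors = FALSE)
  set.seed(11)
  frag <- extract_fragment(records, 25)
  expect_equal(nchar(frag$residues), c(25L, 25L))
  expect_true(all(mapply(grepl, frag$residues, records$residues,
                         fixed = TRUE)))
  expect_equal(frag$id, c("a|frag25", "b|frag25"))

  set.seed(11)
  frag2 <- extract_fragment(records, 25)
  expect_identical(frag, frag2)

  whole <- extract_fragment(records[2, ], nchar(records$residues[2]))
  expect_equal(whole$residues, records$residues[2])

  expect_error(extract_fragment(records, 1500), "record a")
})

test_that("filter_dataset applies length, unclassified and taxon-size rules", {
  mk <- function(n, fam, len = 1300L) data.frame(
    id = paste0(fam, "_", seq_len(n)),
    residues = strrep("A", len),
    phylum = "P", class = "C", order = "O", family = fam,
    stringsAsFactors = FALSE)
  records <- rbind(mk(10, "keep"), mk(9, "small"), mk(12, "short", len = 800))
  records <- rbind(records,
                   data.frame(id = "uncl", residues = strrep("A", 1300),
                              phylum = "P", class = "C", order = "O",
                              family = NA_character_))
  out <- filter_dataset(records)
  # boundary: exactly 10 members retained, 9 dropped; short and
  # unclassified never reach the taxon-size count
  expect_setequal(unique(out$family), "keep")
  expect_equal(nrow(out), 10L)
  # a taxon that only clears min_per_taxon thanks to short sequences is
  # dropped: length filtering applies first
  mixed <- rbind(mk(6, "mix"), mk(6, "mix2", len = 900), mk(6, "mix"))
  expect_equal(nrow(filter_dataset(mixed)), 12L)
})

test_that("lineage files round-trip and attach to records", {
  path <- withr::local_tempfile(fileext = ".tsv")
  records <- data.frame(
    id = c("s1", "s2"), residues = c("ACGT", "GGTT"),
    phylum = c("P1", "P2"), class = c("C1", NA),
    order = c("O1", NA), family = c("F1", NA),
    stringsAsFactors = FALSE)
  write_lineage(records, path)
  lin <- read_lineage(path)
  expect_equal(lin$phylum, c("P1", "P2"))
  expect_true(is.na(lin$class[2]))
  reattached <- attach_lineage(records[c("id", "residues")], lin)
  expect_equal(reattached$family, records$family)
  # unmapped record: NA at every rank
  extra <- attach_lineage(data.frame(id = "s3", residues = "AA"), lin)
  expect_true(all(is.na(extra[TAXONOMIC_RANKS])))
})

test_that("FASTA writing round-trips records", {
  path <- withr::local_tempfile(fileext = ".fasta")
  records <- data.frame(id = c("x", "y"),
                        residues = c("ACGTACGT", "TTGGCCAA"))
  write_fasta(records, path)
  back <- read_fasta(path)
  expect_equal(back, records)
})
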