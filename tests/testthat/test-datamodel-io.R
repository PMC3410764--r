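test_that("read_fasta normalizes alphabet, wrapping and case", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">t1 some description", "acgu", ">t2", "AC", "gt", "ACGT"), f)
  dna <- read_fasta(f, "dna")
  expect_equal(dna$id, c("t1", "t2"))
  expect_equal(dna$seq, c("ACGT", "ACGTACGT"))
  rna <- read_fasta(f, "rna")
  expect_equal(rna$seq[1], "ACGU")

  # miRBase-style mature miRNA read as RNA
  f2 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">gma-miR160", "UGCCUGGCUCCCUGUAUGCCA"), f2)
  mi <- read_fasta(f2, "rna")
  expect_equal(nchar(mi$seq), 21L)
  expect_false(grepl("T", mi$seq))
})

test_that("read_fasta rejects duplicate ids and empty files", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "ACGT", ">x", "GGGG"), f)
  expect_error(read_fasta(f, "dna"), "duplicate.*x")
  f2 <- withr::local_tempfile(fileext = ".fa")
  file.create(f2)
  expect_error(read_fasta(f2, "dna"), "empty")
})

test_that("transcript_set and mirna_set enforce their invariants", {
  expect_error(transcript_set(c("a", "a"), c("ACGT", "ACGT")), "duplicate")
  expect_error(transcript_set("a", "ACGT", cds_start = 3, cds_end = 2),
               "CDS")
  expect_error(transcript_set("a", "ACGT", cds_start = 1, cds_end = 9),
               "CDS")
  ts <- transcript_set("a", "acgu")          # normalized to DNA
  expect_equal(ts$seq, "ACGT")
  expect_warning(mirna_set("short", "ACGUACGUACGUACG"), "19-24")
  ms <- mirna_set("m", "UGCCUGGCUCCCUGUAUGCCA")
  expect_equal(ms$seq, "TGCCTGGCTCCCTGTATGCCA")  # stored on DNA alphabet
})

test_that("read_cds_table handles TSV and GFF3, validates intervals", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("t1\t101\t400", "t2\t1\t90"), f)
  cds <- read_cds_table(f)
  expect_equal(cds$start[cds$id == "t1"], 101L)
  expect_equal(cds$end[cds$id == "t1"], 400L)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("t1\t400\t101", bad)
  expect_error(read_cds_table(bad), "start > end")
  nonint <- withr::local_tempfile(fileext = ".tsv")
  writeLines("t1\tx\t101", nonint)
  expect_error(read_cds_table(nonint), "non-integer")

  # GFF3: CDS features of one mRNA collapse to min-start/max-end
  g <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "t1\tsrc\tCDS\t150\t300\t.\t+\t0\tParent=t1.m",
               "t1\tsrc\tCDS\t101\t140\t.\t+\t0\tParent=t1.m",
               "t1\tsrc\texon\t1\t500\t.\t+\t.\tParent=t1.m"), g)
  cds2 <- read_cds_table(g)
  expect_equal(cds2, data.frame(id = "t1", start = 101L, end = 300L,
                                stringsAsFactors = FALSE))
})

test_that("attach_cds joins intervals and flags unknown ids", {
  ts <- transcript_set(c("t1", "t2"), c(strrep("A", 500), strrep("C", 100)))
  cds <- data.frame(id = c("t1", "ghost"), start = c(101L, 1L),
                    end = c(400L, 10L))
  expect_warning(ts2 <- attach_cds(ts, cds), "ghost")
  expect_equal(ts2$cds_start, c(101L, NA))
  expect_error(attach_cds(ts, data.frame(id = "t2", start = 1L, end = 400L)),
               "exceeds")
})

test_that("call table round-trips field-for-field with deterministic order", {
  calls <- data.frame(
    library = c("Cot100", "Cot100", "SC25"),
    mirna = c("gma-miR160", "gma-miR160", "gma-miR156"),
    target = c("Glyma11g20490.1", "Glyma11g20490.1", "Glyma02g13370.1"),
    c_site = c(1510L, 98L, 1219L),
    location = c("CDS", "5'UTR", "CDS"),
    category = c(0L, 2L, 0L),
    tp100m = c(12166.69, 3.141593, 92.52237),
    p_value = c(0.0071, 0.5, 0.0477),
    stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_call_table(calls, f)
  back <- read_call_table(f)
  # sorted ascending by c_site within (library, mirna, target)
  expect_equal(back$c_site[1:2], c(98L, 1510L))
  orig <- target_call_table(calls)
  expect_equal(as.data.frame(back)[names(back) != "score"],
               as.data.frame(orig)[names(orig) != "score"],
               tolerance = 1e-9)
  # header has the published 8 columns
  hdr <- strsplit(readLines(f, n = 1L), "\t")[[1]]
  expect_equal(hdr, c("miRNA", "Tissue", "Target", "C.Site", "Location",
                      "Category", "TP100M", "P-Value"))
})

test_that("empty call list writes a header-only file", {
  f <- withr::local_tempfile(fileext = ".tsv")
  empty <- data.frame(library = character(), mirna = character(),
                      target = character(), c_site = integer(),
                      location = character(), category = integer(),
                      tp100m = numeric(), p_value = numeric())
  write_call_table(empty, f)
  expect_length(readLines(f), 1L)
  expect_equal(nrow(read_call_table(f)), 0L)
})

test_that("target_call_table validates categories, p-values and locations", {
  base <- data.frame(library = "L", mirna = "m", target = "t", c_site = 5L,
                     location = "CDS", category = 0L, tp100m = 1,
                     p_value = 0.5)
  expect_s3_class(target_call_table(base), "target_call_table")
  bad <- base; bad$category <- 9L
  expect_error(target_call_table(bad))
  bad <- base; bad$p_value <- 0
  expect_error(target_call_table(bad))
  bad <- base; bad$location <- "intron"
  expect_error(target_call_table(bad))
})

test_that("read_library parses FASTQ with qualities and FASTA without", {
  fq <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGTACGTACGTACGTACGT", "+", strrep("I", 20),
               "@r2", "ACGTACGTACGTACGTACGTA", "+", strrep("#", 21)), fq)
  lib <- read_library(fq, "L1", "cotyledon")
  expect_equal(nrow(lib$reads), 2L)
  expect_false(anyNA(lib$reads$qual))
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">r1", "ACGTACGTACGTACGTACGT"), fa)
  lib2 <- read_library(fa, "L2", "seed_coat")
  expect_true(is.na(lib2$reads$qual[1]))
})
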