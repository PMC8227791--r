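# Four-orientation promoter scanning: variant compilation, overlapping
# occurrence counting, degenerate mask matching, FASTA input.

test_that("compile_variants returns the four labelled transforms", {
  v <- compile_variants("AACGT")
  expect_equal(v, c(original = "AACGT", complement = "TTGCA",
                    reverse = "TGCAA", reverse_complement = "ACGTT"))
  # palindromic word: original = reverse complement and, equivalently,
  # complement = reverse, so the four variants collapse to two
  expect_length(compile_variants("GAATTC", dedup = TRUE), 2L)
  expect_length(compile_variants("AT", dedup = TRUE), 2L)
  expect_length(compile_variants("AT"), 4L)
})

test_that("exact and mask needles count overlapping matches", {
  expect_equal(count_occurrences("GAGTGG", "GAGTGGAGTGG"), 2L)
  expect_equal(count_occurrences("GAGTGG", "GAGTGGAGTGG",
                                 overlapping = FALSE), 1L)
  expect_equal(count_occurrences("GAGTGGA", "GAGTGG"), 0L)  # needle > text
  expect_equal(count_occurrences(needle("SWSWSS", "mask"), "GAGTGGAA"), 1L)
  expect_equal(match_positions("GAGTGG", "GAGTGGAGTGG"), c(1L, 6L))
  expect_equal(count_occurrences(needle("SSSSSS", "mask"),
                                 paste(rep("A", 50), collapse = "")), 0L)
})

test_that("needle validation rejects mixed alphabets", {
  expect_error(needle("SWSWS1", kind = "mask"), "only W and S")
  expect_error(needle("GAGTGN"), "invalid base")
})

test_that("windows overlapping an N never match", {
  expect_equal(count_occurrences("GAGTGG", "GAGTGNGAGTGG"), 1L)
  expect_equal(count_occurrences(needle("WW", "mask"), "ANTA"), 1L)
  v <- compile_variants("GANTC")
  expect_equal(v[["complement"]], "CTNAG")
  expect_equal(v[["reverse_complement"]], "GANTC")
})

test_that("a count on the reverse-complement variant equals the count of the rc needle on the original", {
  set.seed(505)
  for (rep in 1:50) {
    text <- random_strand(80)
    x <- random_strand(sample(3:6, 1L))
    v <- compile_variants(text)
    expect_equal(count_occurrences(x, v[["reverse_complement"]]),
                 count_occurrences(reverse_complement(x), text))
    expect_equal(count_occurrences(x, v[["complement"]]),
                 count_occurrences(complement(x), text))
    expect_equal(count_occurrences(x, v[["reverse"]]),
                 count_occurrences(reverse(x), text))
  }
})

test_that("the scanner agrees with a brute-force sliding window on random cases", {
  set.seed(606)
  for (rep in 1:100) {
    text <- random_strand(sample(20:120, 1L))
    k <- sample(2:6, 1L)
    if (rep %% 2 == 0L) {
      pat <- random_strand(k)
      nd <- needle(pat)
      expect_equal(count_occurrences(nd, text), oracle_count(pat, text))
      # second, independent route: Biostrings exact matching
      expect_equal(count_occurrences(nd, text),
                   Biostrings::countPattern(pat, text))
    } else {
      pat <- paste(sample(c("W", "S"), k, replace = TRUE), collapse = "")
      nd <- needle(pat, kind = "mask")
      expect_equal(count_occurrences(nd, text),
                   oracle_count(pat, text, kind = "mask"))
      # W/S are IUPAC codes, so degenerate Biostrings matching must agree
      expect_equal(count_occurrences(nd, text),
                   Biostrings::countPattern(pat, Biostrings::DNAString(text),
                                            fixed = FALSE))
    }
  }
})

test_that("scan_promoters recovers planted counts and reports per variant", {
  gp <- generate_promoter(600, plants = list(plant_spec("GAGTGG", 3)),
                          seed = 17, gene = "CASP3")
  rep <- scan_promoters(list(needle("GAGTGG")), gp$record)
  expect_equal(rep$total, 3L)
  expect_equal(rep$original, 3L)
  expect_equal(rep$reverse_complement, 0L)

  allA <- data.frame(gene = "X",
                     sequence = paste(rep("A", 100), collapse = ""))
  repA <- scan_promoters(list(needle("SSSSSS", "mask", "allS")), allA)
  expect_equal(repA$total, 0L)
})

test_that("scanning is deterministic and ordered by needle then gene", {
  set.seed(707)
  proms <- data.frame(gene = c("B", "A"),
                      sequence = random_strand(200, 2))
  nds <- list(needle("SWSWSS", "mask"), needle("ACGT"))
  r1 <- scan_promoters(nds, proms)
  r2 <- scan_promoters(nds, proms)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_equal(r1$gene, c("A", "B", "A", "B"))
  f1 <- tempfile(); f2 <- tempfile()
  write_occurrence_report(r1, f1)
  write_occurrence_report(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("the biological-strands-only policy restricts the tally", {
  gp <- generate_promoter(300, plants = list(plant_spec("GAGTGG", 2,
                                                        variant = "reverse")),
                          seed = 23, gene = "G1")
  full <- scan_promoters(list(needle("GAGTGG")), gp$record)
  bio <- scan_promoters(list(needle("GAGTGG")), gp$record,
                        scan_policy(variants = "biological"))
  expect_equal(full$total, 2L)
  expect_equal(full$reverse, 2L)
  expect_equal(bio$total, 0L)
  expect_true(is.na(bio$reverse))
})

test_that("duplicate gene symbols are kept separate with a warning", {
  proms <- data.frame(gene = c("APOE", "APOE"),
                      sequence = c("GAGTGGAA", "TTTTTTTT"))
  expect_warning(rep <- scan_promoters(list(needle("GAGTGG")), proms),
                 "duplicate gene symbols")
  expect_equal(sort(rep$gene), c("APOE", "APOE.1"))
  expect_equal(rep$total[rep$gene == "APOE"], 1L)
})

test_that("read_promoters parses FASTA, uppercases and validates", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">CASP3 promoter window [-499,100]",
               "acgtACGT", "GAGTGG",
               ">TP53", "NNNACGT"), f)
  p <- read_promoters(f)
  expect_equal(p$gene, c("CASP3", "TP53"))
  expect_equal(p$sequence[1], "ACGTACGTGAGTGG")  # multi-line, uppercased
  expect_equal(p$sequence[2], "NNNACGT")
  expect_equal(p$source_id[1], "CASP3 promoter window [-499,100]")
  # a needle overlapping the N region never matches
  expect_equal(count_occurrences(needle("WWWW", "mask"), p$sequence[2]), 0L)

  writeLines(c(">X", "ACGU"), f)
  expect_error(read_promoters(f), "invalid sequence characters")
  writeLines(c(">X", "ACGR"), f)  # IUPAC code outside {A,C,G,T,N}
  expect_error(read_promoters(f), "record 1.*invalid character 'R'")
  expect_error(read_promoters(tempfile()), "not found")
})

test_that("needle lists round-trip through disk", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("label\tkind\tpattern",
               "EDR_best\texact\tGAGTGG",
               "EDR_mask\tmask\tSWSWSS"), f)
  nds <- read_needles(f)
  expect_length(nds, 2L)
  expect_equal(nds[[1]]$label, "EDR_best")
  expect_equal(nds[[2]]$kind, "mask")
  expect_error(read_needles(tempfile()), "not found")
})
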