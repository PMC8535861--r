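test_that("the longest forward-frame ORF is found with obligatory stop", {
  orf <- find_longest_orf("ATGAAATGA")
  expect_equal(orf$frame, 1L)
  expect_equal(orf$nt_length, 9L)
  expect_equal(orf$protein, "MK")
  expect_equal(orf$nt_length, 3L * (nchar(orf$protein) + 1L))

  # no stop codon: no ORF at all
  expect_equal(nrow(find_longest_orf("ATGAAAAAA")), 0L)
  # too short
  expect_equal(nrow(find_longest_orf("ATGAA")), 0L)
  # codons containing N neither start nor stop an ORF
  expect_equal(nrow(find_longest_orf("ANGAAATGA")), 0L)
  expect_equal(find_longest_orf("ATGAANTAATGA")$protein, "MX")
})

test_that("a longer ORF in a later frame beats an earlier shorter one", {
  # frame 1: ATG AAA TAA (9 nt); frame 2 carries a 15 nt ORF
  seq <- paste0("ATGAAATAA", "C", "ATGAAAAAACCCTGA")
  # frame 1 ORF: positions 1..9; frame 2: starts at position 11
  orf <- find_longest_orf(seq)
  ora <- oracle_longest_orf(seq)
  expect_equal(orf$nt_length, ora$nt_length)
  expect_equal(orf$frame, ora$frame)
  expect_equal(orf$start, ora$start)
  expect_gt(orf$nt_length, 9L)
})

test_that("random sequences: ORF finder agrees with the enumeration oracle", {
  set.seed(7)
  for (i in 1:40) {
    seq <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
    got <- find_longest_orf(seq)
    want <- oracle_longest_orf(seq)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$nt_length, want$nt_length)
      expect_equal(got$frame, want$frame)
      expect_equal(got$start, want$start)
      # re-translated ORF has no internal stop
      expect_false(grepl("\\*", got$protein))
    }
  }
})

test_that("the Fickett score matches a straight-line table-lookup oracle", {
  set.seed(13)
  for (i in 1:10) {
    seq <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
    expect_equal(fickett_score(seq), oracle_fickett(seq), tolerance = 1e-12)
  }
  # strong 3-periodicity scores higher than its shuffled counterpart
  periodic <- paste(rep("GCT", 100), collapse = "")
  expect_gt(fickett_score(periodic), fickett_score(paste(
    sample(strsplit(periodic, "")[[1]]),
    collapse = ""
  )))
  # case invariance
  expect_equal(fickett_score("acgtacgtacgt"), fickett_score("ACGTACGTACGT"))
  # repeated ACGT and its reverse complement are both finite and match the oracle
  s <- paste(rep("ACGT", 75), collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_equal(fickett_score(s), oracle_fickett(s))
  expect_equal(fickett_score(rc), oracle_fickett(rc))
  expect_error(fickett_score("ACGTACGT"), "at least 12")
})

test_that("isoelectric point solves the net-charge root", {
  # termini-only peptide against an independent uniroot-based oracle
  expect_equal(isoelectric_point("GGGG"), oracle_pi("GGGG"), tolerance = 1e-3)
  set.seed(5)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:10) {
    p <- paste(sample(aas, 30, replace = TRUE), collapse = "")
    expect_equal(isoelectric_point(p), oracle_pi(p), tolerance = 1e-3)
    # appending arginine never decreases pI
    expect_gte(isoelectric_point(paste0(p, "R")) - isoelectric_point(p), -1e-6)
  }
  expect_true(isoelectric_point("DDDDDD") < 7)
  expect_true(isoelectric_point("KKKKKK") > 7)
  expect_error(isoelectric_point(""), "non-empty")
  expect_error(isoelectric_point("ABZ"), "invalid")
})

test_that("the coding rule is exact on planted ORFs and rejects ATG-free RNA", {
  set.seed(3)
  # a planted >= 300 nt ORF is always called coding (rule clause 1)
  codons <- setdiff(
    apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"), c("A", "C", "G", "T")),
      1, paste,
      collapse = ""
    ),
    c("TAA", "TAG", "TGA")
  )
  orf <- paste0("ATG", paste(sample(codons, 120, replace = TRUE), collapse = ""), "TAA")
  out <- classify_coding(tibble::tibble(transcript_id = "t", sequence = orf))
  expect_true(out$coding)
  expect_gte(out$orf_nt_length, 300L)

  # a random 500-nt sequence with no ATG is noncoding
  noatg <- gsub("ATG", "ACG", paste(
    sample(c("A", "C", "G", "T"), 500, replace = TRUE),
    collapse = ""
  ))
  while (grepl("ATG", noatg, fixed = TRUE)) noatg <- gsub("ATG", "ACG", noatg)
  out2 <- classify_coding(tibble::tibble(transcript_id = "t", sequence = noatg))
  expect_false(out2$coding)
  expect_true(is.na(out2$orf_nt_length))
})

test_that("false-coding rate on random ATG-containing sequences stays low", {
  set.seed(17)
  seqs <- tibble::tibble(
    transcript_id = paste0("r", 1:100),
    sequence = vapply(
      1:100,
      function(i) paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = ""),
      character(1)
    )
  )
  out <- classify_coding(seqs)
  expect_lt(mean(out$coding), 0.10)
})

test_that("classify_coding is a pure function of sequence and thresholds", {
  seqs <- tibble::tibble(
    transcript_id = "t",
    sequence = paste(rep("ATGGCTGCTTAAACG", 30), collapse = "")
  )
  expect_identical(classify_coding(seqs), classify_coding(seqs))
  # thresholds are honoured: raising min_orf flips a borderline call
  orf150 <- paste0(
    "ATG", paste(rep("GCT", 48), collapse = ""), "TAA"
  )
  relaxed <- classify_coding(
    tibble::tibble(transcript_id = "t", sequence = orf150),
    min_orf = 120
  )
  strict <- classify_coding(
    tibble::tibble(transcript_id = "t", sequence = orf150),
    min_orf = 300, min_orf_supported = 300
  )
  expect_true(relaxed$coding)
  expect_false(strict$coding)
})
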