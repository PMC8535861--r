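# old annotation for the diff examples: two multi-exon genes and one
# mono-exon gene
old_annotation <- function() {
  dplyr::bind_rows(
    mk_tx("o1", "og1", "chr1", "+", c(201, 401), c(300, 500)),
    mk_tx("o2", "og2", "chr1", "-", c(1001, 1201), c(1100, 1300)),
    mk_tx("o3", "og3", "chr1", "+", 2001, 2400)
  )
}

with_codes <- function(tx, codes) {
  code_map <- tibble::tibble(
    transcript_id = unique(tx$transcript_id), class_code = codes
  )
  dplyr::left_join(tx, code_map, by = "transcript_id")
}

test_that("gene diff categories follow the rule cascade", {
  idx <- build_reference_index(old_annotation())

  # all transcripts "=" -> unchanged
  g <- categorize_genes(with_codes(
    mk_tx("t1", "G", "chr1", "+", c(151, 401), c(300, 550)), "="
  ), idx)
  expect_equal(g$category, "unchanged")

  # codes {=, j} -> novel_splice_variant
  tx <- dplyr::bind_rows(
    mk_tx("t1", "G", "chr1", "+", c(151, 401), c(300, 550)),
    mk_tx("t2", "G", "chr1", "+", c(151, 421), c(300, 550))
  )
  g <- categorize_genes(with_codes(tx, c("=", "j")), idx)
  expect_equal(g$category, "novel_splice_variant")

  # no transcript shares any junction, none "=" -> all_junctions_differ
  tx <- mk_tx("t1", "G", "chr1", "+", c(151, 411), c(310, 550))
  g <- categorize_genes(with_codes(tx, "o"), idx)
  expect_equal(g$category, "all_junctions_differ")

  # junction shared but no "=" -> all_transcripts_differ
  tx <- dplyr::bind_rows(
    mk_tx("t1", "G", "chr1", "+", c(151, 401, 601), c(300, 500, 700))
  )
  g <- categorize_genes(with_codes(tx, "j"), idx)
  expect_equal(g$category, "all_transcripts_differ")

  # all transcripts novel codes -> novel
  g <- categorize_genes(with_codes(
    mk_tx("t1", "G", "chr1", "+", 5000, 5400), "u"
  ), idx)
  expect_equal(g$category, "novel")

  # opposite strand reusing old junction coordinates -> flipped, even though
  # its class code (x) is a novel code
  g <- categorize_genes(with_codes(
    mk_tx("t1", "G", "chr1", "-", c(201, 401), c(300, 500)), "x"
  ), idx)
  expect_equal(g$category, "flipped")

  # mixture involving "o" with an "=" -> uncategorized
  tx <- dplyr::bind_rows(
    mk_tx("t1", "G", "chr1", "+", c(151, 401), c(300, 550)),
    mk_tx("t2", "G", "chr1", "+", 480, 700)
  )
  g <- categorize_genes(with_codes(tx, c("=", "o")), idx)
  expect_equal(g$category, "uncategorized")

  expect_error(categorize_genes(with_codes(empty_tx(), character(0)), idx), "at least one")
})

test_that("categories are UTR-invariant", {
  idx <- build_reference_index(old_annotation())
  tx1 <- dplyr::bind_rows(
    mk_tx("t1", "G", "chr1", "+", c(151, 401), c(300, 550)),
    mk_tx("t2", "G", "chr1", "+", c(151, 421), c(300, 550))
  )
  # extend every outer UTR end by 90 nt; junctions unchanged
  tx2 <- tx1
  tx2$start[c(1, 3)] <- tx2$start[c(1, 3)] - 90L
  tx2$end[c(2, 4)] <- tx2$end[c(2, 4)] + 90L
  g1 <- categorize_genes(with_codes(tx1, c("=", "j")), idx)
  g2 <- categorize_genes(with_codes(tx2, c("=", "j")), idx)
  expect_equal(g1$category, g2$category)
})

test_that("randomised small fixtures agree with the rule-by-rule oracle", {
  old <- old_annotation()
  idx <- build_reference_index(old)
  old_list <- refs_as_list(old)
  set.seed(23)
  for (rep in 1:30) {
    n_tx <- sample(1:3, 1)
    tx <- dplyr::bind_rows(lapply(seq_len(n_tx), function(i) {
      s <- sample(seq(100, 2300, by = 10), 1)
      strand <- sample(c("+", "-"), 1)
      if (sample(c(TRUE, FALSE), 1)) {
        # sometimes reuse old junction coordinates exactly
        mk_tx(paste0("t", i), "G", "chr1", strand, c(s, 401), c(300, s + 600))
      } else {
        mk_tx(
          paste0("t", i), "G", "chr1", strand,
          c(s, s + 200), c(s + 100, s + 320)
        )
      }
    }))
    tx <- tryCatch(as_transcripts(tx), error = function(e) NULL)
    if (is.null(tx)) next
    codes <- assign_class_codes(tx, idx)
    joined <- dplyr::left_join(
      tx, codes[, c("transcript_id", "class_code")],
      by = "transcript_id"
    )
    got <- categorize_genes(joined, idx)$category
    want <- oracle_gene_category(
      lapply(split(joined, joined$transcript_id), function(d) {
        list(
          chrom = d$chrom[1], strand = d$strand[1],
          class_code = d$class_code[1],
          exons = data.frame(start = d$start, end = d$end)
        )
      }),
      old_list
    )
    expect_equal(got, want)
  }
})

test_that("unexpressed old genes have no overlap with any merged transcript", {
  old <- old_annotation()
  old$biotype <- rep(c("coding", "coding", "noncoding"), times = c(2, 2, 1))
  # merged set touching og1 in sense and og2 only in antisense
  merged <- dplyr::bind_rows(
    mk_tx("m1", "x", "chr1", "+", c(151, 401), c(300, 550)),
    mk_tx("m2", "x", "chr1", "+", 1050, 1250) # antisense to og2: still detected
  )
  un <- detect_unexpressed(old, merged)
  expect_equal(un$gene_id, "og3")
  expect_equal(un$biotype, "noncoding")

  # empty merged set: every old gene is listed
  un_all <- detect_unexpressed(old, empty_tx())
  expect_setequal(un_all$gene_id, c("og1", "og2", "og3"))
})
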