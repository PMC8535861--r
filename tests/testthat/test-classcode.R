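# a toy reference used across the class-code examples: one 2-exon gene on
# "+", one mono-exon gene on "-", one 3-exon gene on "+"
toy_reference <- function() {
  dplyr::bind_rows(
    mk_tx("ref1", "rg1", "chr1", "+", c(201, 401), c(300, 500)),
    mk_tx("ref2", "rg2", "chr1", "-", 601, 700),
    mk_tx("ref3", "rg3", "chr1", "+", c(751, 821, 901), c(800, 860, 950))
  )
}

test_that("reference index holds every exon, intron, junction and gene once", {
  idx <- build_reference_index(toy_reference())
  expect_equal(nrow(idx$exons), 6L)
  expect_equal(nrow(idx$introns), 3L)
  expect_equal(length(idx$junction_keys), 3L)
  expect_equal(nrow(idx$genes), 3L)

  empty_idx <- build_reference_index(empty_tx())
  out <- assign_class_codes(
    mk_tx("q", "g", "chr1", "+", 1, 300), empty_idx
  )
  expect_equal(out$class_code, "u")
})

test_that("class codes follow the precedence rules on the worked examples", {
  idx <- build_reference_index(toy_reference())
  code_of <- function(tx) assign_class_codes(tx, idx)

  # identical intron chain, UTRs 100 nt longer each side -> "="
  eq <- code_of(mk_tx("q", "g", "chr1", "+", c(101, 401), c(300, 600)))
  expect_equal(eq$class_code, "=")
  expect_equal(eq$cmp_ref, "ref1")
  expect_false(eq$novel)

  # one junction kept, one shifted -> "j"
  j <- code_of(mk_tx("q", "g", "chr1", "+", c(751, 821, 911), c(800, 860, 950)))
  expect_equal(j$class_code, "j")
  expect_equal(j$cmp_ref, "ref3")

  # mono-exon query inside a reference intron, same strand -> "i"
  i <- code_of(mk_tx("q", "g", "chr1", "+", 320, 380))
  expect_equal(i$class_code, "i")

  # overlap with a reference exon on the opposite strand -> "x"
  x <- code_of(mk_tx("q", "g", "chr1", "-", 250, 320))
  expect_equal(x$class_code, "x")
  expect_true(x$novel)

  # no reference features -> "u"
  u <- code_of(mk_tx("q", "g", "chr1", "+", 1100, 1400))
  expect_equal(u$class_code, "u")
  expect_true(is.na(u$cmp_ref))

  # contained with a contiguous sub-chain -> "c"
  cc <- code_of(mk_tx("q", "g", "chr1", "+", c(780, 821), c(800, 840)))
  expect_equal(cc$class_code, "c")

  # containing the full reference chain plus an extra junction -> "k"
  k <- code_of(mk_tx("q", "g", "chr1", "+", c(180, 401, 551), c(300, 500, 600)))
  expect_equal(k$class_code, "k")

  # same-strand exon overlap without junction sharing -> "o"
  o <- code_of(mk_tx("q", "g", "chr1", "+", 280, 420))
  expect_equal(o$class_code, "o")

  # mono-exon vs mono-exon reference: >= 50% of the shorter -> "="
  meq <- code_of(mk_tx("q", "g", "chr1", "-", 650, 800))
  expect_equal(meq$class_code, "=")
  # below the mono-exon overlap fraction it degrades to "o"
  mo <- code_of(mk_tx("q", "g", "chr1", "-", 691, 900))
  expect_equal(mo$class_code, "o")

  # reference gene fully inside a query intron -> "y"
  y <- code_of(mk_tx("q", "g", "chr1", "-", c(550, 751), c(590, 790)))
  expect_equal(y$class_code, "y")
})

test_that("queries on chromosomes absent from the index warn and fall to u", {
  idx <- build_reference_index(toy_reference())
  expect_warning(
    out <- assign_class_codes(mk_tx("q", "g", "chrZ", "+", 1, 300), idx),
    "absent from reference"
  )
  expect_equal(out$class_code, "u")
})

test_that("novelty is exactly the i/u/y/x set", {
  expect_true(all(is_novel(c("i", "u", "y", "x"))))
  expect_false(any(is_novel(c("=", "j", "c", "k", "o"))))
  expect_error(is_novel("z"), "unknown")
})

test_that("random 2-exon queries agree with the brute-force oracle", {
  ref <- toy_reference()
  idx <- build_reference_index(ref)
  refs <- refs_as_list(ref)
  set.seed(42)
  n_cases <- 400
  qs <- tibble::tibble(
    transcript_id = paste0("q", seq_len(n_cases)),
    gene_id = "q",
    chrom = "chr1",
    strand = sample(c("+", "-"), n_cases, replace = TRUE),
    e1s = sample(1:900, n_cases, replace = TRUE),
    e1len = sample(c(20, 60, 100), n_cases, replace = TRUE),
    ilen = sample(c(30, 90, 250), n_cases, replace = TRUE),
    e2len = sample(c(20, 80), n_cases, replace = TRUE)
  )
  exons <- dplyr::bind_rows(
    dplyr::transmute(qs, .data$transcript_id, .data$gene_id, .data$chrom,
      .data$strand,
      start = .data$e1s, end = .data$e1s + .data$e1len - 1
    ),
    dplyr::transmute(qs, .data$transcript_id, .data$gene_id, .data$chrom,
      .data$strand,
      start = .data$e1s + .data$e1len + .data$ilen,
      end = .data$e1s + .data$e1len + .data$ilen + .data$e2len - 1
    )
  )
  got <- assign_class_codes(exons, idx)
  want <- vapply(seq_len(n_cases), function(i) {
    d <- exons[exons$transcript_id == paste0("q", i), ]
    oracle_class_code(
      list(chrom = d$chrom[1], strand = d$strand[1], exons = as.data.frame(d[, c("start", "end")])),
      refs
    )
  }, character(1))
  expect_equal(
    got$class_code[match(paste0("q", seq_len(n_cases)), got$transcript_id)],
    want
  )
})

test_that("the = relation is symmetric in intron chains", {
  a <- mk_tx("a", "g", "chr1", "+", c(101, 401), c(300, 600))
  b <- mk_tx("b", "g", "chr1", "+", c(151, 401), c(300, 520))
  ab <- assign_class_codes(a, build_reference_index(b))
  ba <- assign_class_codes(b, build_reference_index(a))
  expect_equal(ab$class_code, "=")
  expect_equal(ba$class_code, "=")
})
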