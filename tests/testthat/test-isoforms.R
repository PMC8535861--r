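test_that("pairwise similarity is identity-normalised and symmetric", {
  expect_equal(pairwise_similarity("MKVLA", "MKVLA"), 100)
  # one substitution over three aligned positions, gapless optimum
  expect_equal(pairwise_similarity("MKV", "MQV"), 100 * 2 / 3)
  set.seed(21)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:8) {
    a <- paste(sample(aas, sample(10:25, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aas, sample(10:25, 1), replace = TRUE), collapse = "")
    expect_equal(pairwise_similarity(a, b), pairwise_similarity(b, a))
    expect_true(pairwise_similarity(a, b) >= 0 && pairwise_similarity(a, b) <= 100)
  }
  expect_error(pairwise_similarity("", "MK"), "non-empty")
})

test_that("alignment scores agree with an independent DP oracle", {
  pairs <- list(
    c("MKV", "MQV"),
    c("MKVLA", "MVLA"),
    c("MKKKKVLA", "MVLA"),
    c("MAADEW", "MAAW"),
    c("WWWWW", "MMMMM")
  )
  for (p in pairs) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(p[1]), Biostrings::AAString(p[2]),
      type = "global", substitutionMatrix = get_blosum62(),
      gapOpening = 11, gapExtension = 1
    )
    expect_equal(Biostrings::score(aln), oracle_nw_score(p[1], p[2]))
  }
  # substitution-only pairs have a unique gapless optimum, so the percent
  # identity is forced: matches / length
  set.seed(9)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:6) {
    n <- 20
    a <- sample(aas, n, replace = TRUE)
    b <- a
    sub_at <- sample(n, 4)
    for (j in sub_at) b[j] <- sample(setdiff(aas, a[j]), 1)
    sim <- pairwise_similarity(paste(a, collapse = ""), paste(b, collapse = ""))
    expect_equal(sim, 100 * (n - length(sub_at)) / n)
  }
})

test_that("isoform groups are connectivity components within loci", {
  # planted chain: A-B and B-C similar, A-C not; all one group
  set.seed(61)
  base <- paste(
    sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 60, replace = TRUE),
    collapse = ""
  )
  prot <- tibble::tibble(
    locus = "L1",
    transcript_id = c("A", "B", "C"),
    protein = c(
      paste0(substr(base, 1, 40), paste(rep("G", 20), collapse = "")),
      base,
      paste0(paste(rep("P", 20), collapse = ""), substr(base, 21, 60))
    )
  )
  sc <- isoform_pair_scores(prot)
  ab <- sc$similarity[sc$id1 == "A" & sc$id2 == "B"]
  bc <- sc$similarity[sc$id1 == "B" & sc$id2 == "C"]
  ac <- sc$similarity[sc$id1 == "A" & sc$id2 == "C"]
  expect_gte(ab, 49)
  expect_gte(bc, 49)
  expect_lt(ac, 49)
  groups <- group_isoforms(prot)
  expect_equal(dplyr::n_distinct(groups$group_id), 1L)

  # loci are never merged even with identical proteins
  two_loci <- tibble::tibble(
    locus = c("L1", "L2"), transcript_id = c("A", "B"), protein = base
  )
  expect_equal(dplyr::n_distinct(group_isoforms(two_loci)$group_id), 2L)
})

test_that("the 49 cutoff accepts 49 and rejects 48", {
  prot <- tibble::tibble(
    locus = "L", transcript_id = c("A", "B"), protein = c("MK", "MK")
  )
  scores <- tibble::tibble(
    locus = "L", id1 = "A", id2 = "B", similarity = 49
  )
  expect_equal(
    dplyr::n_distinct(group_isoforms(prot, cutoff = 49, scores = scores)$group_id),
    1L
  )
  scores$similarity <- 48
  expect_equal(
    dplyr::n_distinct(group_isoforms(prot, cutoff = 49, scores = scores)$group_id),
    2L
  )
})

test_that("raising the cutoff only refines the grouping", {
  set.seed(31)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  base <- paste(sample(aas, 40, replace = TRUE), collapse = "")
  mutate_prot <- function(p, k) {
    ch <- strsplit(p, "")[[1]]
    at <- sample(length(ch), k)
    for (j in at) ch[j] <- sample(aas, 1)
    paste(ch, collapse = "")
  }
  prot <- tibble::tibble(
    locus = "L",
    transcript_id = paste0("t", 1:6),
    protein = c(
      base, mutate_prot(base, 4), mutate_prot(base, 12),
      mutate_prot(base, 22), mutate_prot(base, 30),
      paste(sample(aas, 40, replace = TRUE), collapse = "")
    )
  )
  scores <- isoform_pair_scores(prot)
  cuts <- c(10, 30, 49, 70, 90)
  memberships <- lapply(cuts, function(cutoff) {
    g <- group_isoforms(prot, cutoff = cutoff, scores = scores)
    stats::setNames(g$group_id, g$transcript_id)
  })
  for (i in seq_along(cuts)[-1]) {
    fine <- memberships[[i]]
    coarse <- memberships[[i - 1]]
    # refinement: same fine group implies same coarse group
    for (a in names(fine)) {
      for (b in names(fine)) {
        if (fine[[a]] == fine[[b]]) {
          expect_equal(coarse[[a]], coarse[[b]])
        }
      }
    }
  }
})

test_that("group representatives are the longest-protein members", {
  prot <- tibble::tibble(
    locus = "L", transcript_id = c("A", "B"),
    protein = c("MKLVAEWRDS", "MKLVAEWRDSMKLVAEWRDS")
  )
  scores <- tibble::tibble(locus = "L", id1 = "A", id2 = "B", similarity = 80)
  g <- group_isoforms(prot, scores = scores)
  expect_equal(g$transcript_id[g$representative], "B")
})

test_that("similarity histograms bin correctly and expose bimodality", {
  h <- similarity_score_histogram(c(10, 12, 90, 95), bin_width = 10)
  expect_equal(h$count[h$bin_start == 10], 2L)
  expect_equal(h$count[h$bin_start == 90], 2L)
  expect_equal(sum(h$count), 4L)
  # 100 falls into the last closed bin
  h2 <- similarity_score_histogram(c(100), bin_width = 10)
  expect_equal(h2$count[h2$bin_start == 90], 1L)
  expect_error(similarity_score_histogram(numeric(0)), "at least one")

  # planted isoforms (near-identical) plus unrelated neighbours: bimodal
  # with a valley in [40, 60]
  set.seed(41)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  scores <- c()
  for (i in 1:20) {
    base <- paste(sample(aas, 50, replace = TRUE), collapse = "")
    ch <- strsplit(base, "")[[1]]
    ch[sample(50, 3)] <- sample(aas, 3, replace = TRUE)
    iso <- paste(ch, collapse = "")
    unrelated <- paste(sample(aas, 50, replace = TRUE), collapse = "")
    scores <- c(
      scores,
      pairwise_similarity(base, iso),
      pairwise_similarity(base, unrelated)
    )
  }
  h3 <- similarity_score_histogram(scores, bin_width = 20)
  valley <- h3$count[h3$bin_start == 40]
  peak_low <- max(h3$count[h3$bin_start < 40])
  peak_high <- max(h3$count[h3$bin_start > 60])
  expect_lt(valley, peak_low / 2)
  expect_lt(valley, peak_high / 2)
})

test_that("borderline pairs are reported for review", {
  scores <- tibble::tibble(
    locus = "L", id1 = c("a", "c", "e"), id2 = c("b", "d", "f"),
    similarity = c(49, 55.5, 61)
  )
  b <- borderline_pairs(scores)
  expect_setequal(b$id1, c("a", "c"))
})

test_that("noncoding genes form by same-strand transitive overlap", {
  nc <- dplyr::bind_rows(
    mk_tx("a", "g", "chr1", "+", 100, 300),
    mk_tx("b", "g", "chr1", "+", 250, 500),
    mk_tx("c", "g", "chr1", "+", 450, 700), # chain a-b-c, a and c disjoint
    mk_tx("d", "g", "chr1", "-", 250, 500), # opposite strand
    mk_tx("e", "g", "chr2", "+", 100, 300)
  )
  g <- group_noncoding_by_overlap(nc)
  m <- stats::setNames(g$nc_gene_id, g$transcript_id)
  expect_equal(m[["a"]], m[["b"]])
  expect_equal(m[["a"]], m[["c"]])
  expect_false(m[["a"]] == m[["d"]])
  expect_false(m[["a"]] == m[["e"]])
  expect_equal(dplyr::n_distinct(g$nc_gene_id), 3L)
})
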