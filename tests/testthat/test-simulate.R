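test_that("configs are validated", {
  expect_error(sim_config(chrom_length = 0), "length >= 1")
  expect_error(sim_config(n_coding_genes = -1), "counts")
  expect_error(sim_config(junction_perturb_fraction = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(utr5_range = c(50, 20)), "increasing")
  expect_error(
    sim_config(n_coding_genes = 5, n_multi_isoform_genes = 10),
    "exceed"
  )
  # genes that cannot fit on the chromosome fail loudly
  expect_error(
    simulate_study(sim_config(
      chrom_length = 5000, n_coding_genes = 50, n_ref_noncoding = 0,
      n_lincRNA = 0, n_antisense = 0, n_intronic = 0, n_sense_overlap = 0,
      n_multi_isoform_genes = 0, n_flipped = 0, n_all_shifted = 0,
      n_unexpressed = 0
    )),
    "do not fit"
  )
})

test_that("genome generation is deterministic and sized as configured", {
  cfg <- sim_config(seed = 1, n_chroms = 2, chrom_length = 10000)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(as.character(g1), as.character(g2))
  expect_equal(length(g1), 2L)
  expect_equal(unique(Biostrings::width(g1)), 10000L)
  expect_false(identical(
    as.character(simulate_genome(sim_config(seed = 2, n_chroms = 2, chrom_length = 10000))),
    as.character(g1)
  ))
})

test_that("the whole study is byte-identical across reruns", {
  cfg <- sim_config(
    seed = 5, n_chroms = 1, chrom_length = 120000, n_coding_genes = 25,
    n_ref_noncoding = 1, n_lincRNA = 2, n_antisense = 2, n_intronic = 2,
    n_sense_overlap = 2, n_multi_isoform_genes = 3, n_flipped = 1,
    n_all_shifted = 1, n_unexpressed = 2, n_samples = 2
  )
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_study(simulate_study(cfg), d1)
  write_study(simulate_study(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(
      unname(tools::md5sum(file.path(d1, f))),
      unname(tools::md5sum(file.path(d2, f))),
      info = f
    )
  }
})

test_that("planted coding genes carry the promised ORF structure", {
  st <- small_study()
  ref <- st$reference[st$reference$biotype == "coding", 1:6]
  seqs <- spliced_sequence(ref, st$genome)
  lens <- tx_summary(ref)
  for (i in seq_len(nrow(seqs))) {
    orf <- find_longest_orf(seqs$sequence[i])
    expect_equal(nrow(orf), 1L)
    expect_gte(orf$nt_length, 300L)
    spliced_len <- lens$spliced_length[lens$transcript_id == seqs$transcript_id[i]]
    expect_gte(orf$nt_length / spliced_len, 0.6)
  }
  # noncoding reference genes have no ORF at all
  nc_ref <- st$reference[st$reference$biotype == "noncoding", 1:6]
  nc_seqs <- spliced_sequence(nc_ref, st$genome)
  for (s in nc_seqs$sequence) {
    expect_equal(nrow(find_longest_orf(s)), 0L)
  }
})

test_that("every emitted transcript carries exactly one truth label", {
  st <- small_study()
  for (nm in names(st$samples)) {
    ids <- unique(st$samples[[nm]]$transcript_id)
    emitted <- st$truth$emissions[st$truth$emissions$sample == nm, ]
    expect_setequal(ids, emitted$transcript_id)
    expect_equal(nrow(emitted), length(ids))
  }
  expect_false(anyNA(st$truth$transcripts$truth_label))
})

test_that("planted counts and fragment lengths match the configuration", {
  st <- small_study()
  tt <- st$truth$transcripts
  expect_equal(sum(tt$truth_label == "antisense_noncoding"), 3L)
  expect_equal(sum(tt$truth_label == "intronic_noncoding"), 3L)
  expect_equal(sum(tt$truth_label == "sense_overlap_noncoding"), 3L)
  expect_equal(sum(tt$truth_label == "intergenic_noncoding"), 4L)
  frag_ids <- tt$transcript_id[tt$truth_label == "fragment"]
  expect_equal(length(frag_ids), 4L) # 10% of 40 genes
  s1 <- tx_summary(st$samples$sample_1)
  expect_true(all(s1$spliced_length[s1$transcript_id %in% frag_ids] < 200))
})

test_that("zero-count requests produce an empty (but valid) study", {
  cfg <- sim_config(
    seed = 3, n_chroms = 1, chrom_length = 50000, n_coding_genes = 0,
    n_ref_noncoding = 0, n_lincRNA = 0, n_antisense = 0, n_intronic = 0,
    n_sense_overlap = 0, n_multi_isoform_genes = 0, n_flipped = 0,
    n_all_shifted = 0, n_unexpressed = 0,
    junction_perturb_fraction = 0, fragment_fraction = 0
  )
  st <- simulate_study(cfg)
  expect_equal(nrow(st$reference), 0L)
  expect_equal(nrow(st$truth$transcripts), 0L)
})
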