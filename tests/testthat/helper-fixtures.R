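# quick exon-table constructor: mk_tx("t1", "g1", "chr1", "+", c(101, 301), c(200, 400))
mk_tx <- function(transcript_id, gene_id, chrom, strand, starts, ends) {
  tibble::tibble(
    transcript_id = transcript_id, gene_id = gene_id,
    chrom = chrom, strand = strand,
    start = as.integer(starts), end = as.integer(ends)
  )
}

empty_tx <- function() {
  tibble::tibble(
    transcript_id = character(), gene_id = character(),
    chrom = character(), strand = character(),
    start = integer(), end = integer()
  )
}

# a small noise-free synthetic study used by several pipeline tests
# (memoised: the same study object is reused across test files)
.study_cache <- new.env(parent = emptyenv())

small_study <- function(seed = 11) {
  key <- paste0("study_", seed)
  if (!is.null(.study_cache[[key]])) {
    return(.study_cache[[key]])
  }
  .study_cache[[key]] <- simulate_study_small(seed)
  .study_cache[[key]]
}

small_result <- function(seed = 11) {
  key <- paste0("result_", seed)
  if (!is.null(.study_cache[[key]])) {
    return(.study_cache[[key]])
  }
  st <- small_study(seed)
  .study_cache[[key]] <- run_pipeline(st$genome, st$reference, st$samples)
  .study_cache[[key]]
}

simulate_study_small <- function(seed) {
  simulate_study(sim_config(
    seed = seed, n_chroms = 2, chrom_length = 200000, n_coding_genes = 40,
    n_ref_noncoding = 2, n_lincRNA = 4, n_antisense = 3, n_intronic = 3,
    n_sense_overlap = 3, n_multi_isoform_genes = 6, n_flipped = 2,
    n_all_shifted = 2, n_unexpressed = 3,
    junction_perturb_fraction = 0.1, fragment_fraction = 0.1, n_samples = 2
  ))
}

# map each merged transcript back to the planted structure(s) it came from
truth_of_merged <- function(result, truth) {
  prov <- dplyr::distinct(result$provenance[, c("transcript_id", "source_id")])
  dplyr::left_join(
    prov, truth$transcripts,
    by = c(source_id = "transcript_id")
  )
}
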