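#' Pipeline configuration
#'
#' Collects every tunable threshold of the annotation-refinement pipeline,
#' with the analysis' published values as defaults: the 200 nt minimum
#' transcript length, the 49 percent isoform-similarity cutoff, the coding
#' decision rule thresholds, the mono-exon match fraction and the flipped
#' junction tolerance.
#'
#' @param min_length Minimum spliced transcript length (nt); shorter
#'   transcripts are excluded. Default 200.
#' @param isoform_cutoff Protein similarity (percent) connecting isoforms.
#'   Default 49.
#' @param mono_overlap_frac Overlap fraction for mono-exon `=` calls.
#'   Default 0.5.
#' @param flipped_tolerance Junction coordinate tolerance (nt) for the
#'   flipped gene rule. Default 0.
#' @param min_orf,min_orf_supported,min_coverage,fickett_cutoff Coding
#'   decision rule, see [classify_coding()].
#' @param intronic_same_strand Strandedness of the `i` class code, see
#'   [assign_class_codes()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_length = 200L,
                            isoform_cutoff = 49,
                            mono_overlap_frac = 0.5,
                            flipped_tolerance = 0L,
                            min_orf = 300L,
                            min_orf_supported = 120L,
                            min_coverage = 0.5,
                            fickett_cutoff = 0.95,
                            intronic_same_strand = TRUE) {
  structure(
    list(
      min_length = as.integer(min_length),
      isoform_cutoff = isoform_cutoff,
      mono_overlap_frac = mono_overlap_frac,
      flipped_tolerance = as.integer(flipped_tolerance),
      min_orf = as.integer(min_orf),
      min_orf_supported = as.integer(min_orf_supported),
      min_coverage = min_coverage,
      fickett_cutoff = fickett_cutoff,
      intronic_same_strand = isTRUE(intronic_same_strand)
    ),
    class = "pipeline_config"
  )
}

#' Run the transcriptome-annotation pipeline end to end
#'
#' Executes all stages in order: merge the per-sample assemblies, apply the
#' minimum-length filter, assign class codes against the old annotation,
#' classify coding potential, positionally classify noncoding transcripts,
#' group noncoding transcripts into genes and coding transcripts into
#' isoform groups, categorize every new gene against the old annotation,
#' and detect unexpressed old genes. Deterministic for fixed inputs and
#' configuration.
#'
#' @param genome A named `DNAStringSet` (or named character vector), e.g.
#'   from [read_genome()].
#' @param reference A transcript table of the old annotation (optionally
#'   with a `biotype` column).
#' @param samples A named list of per-sample transcript tables.
#' @param config A [pipeline_config()].
#' @return An object of class `tx_annotation`: a list with
#'   * `transcripts` — one row per reliable merged transcript with its
#'     structure, class code, coding features, positional category and
#'     isoform group;
#'   * `genes` — one row per new-annotation locus with its diff category;
#'   * `nc_genes` — noncoding genes with positional categories;
#'   * `isoform_scores` — all within-locus protein similarity pairs;
#'   * `unexpressed` — old genes with no expression evidence;
#'   * `provenance`, `report`, `config`.
#' @export
run_pipeline <- function(genome, reference, samples, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  reference_tbl <- tibble::as_tibble(reference)
  ref_tx <- as_transcripts(reference_tbl[, c(
    "transcript_id", "gene_id", "chrom", "strand", "start", "end"
  )])

  merged <- merge_samples(samples)
  n_merged <- dplyr::n_distinct(merged$transcripts$transcript_id)
  filtered <- filter_by_length(merged, config$min_length)

  index <- build_reference_index(ref_tx)
  codes <- assign_class_codes(
    filtered$transcripts, index,
    mono_overlap_frac = config$mono_overlap_frac,
    intronic_same_strand = config$intronic_same_strand
  )

  tx <- tx_summary(filtered$transcripts)
  tx <- dplyr::left_join(tx, codes, by = "transcript_id")

  seqs <- spliced_sequence(filtered$transcripts, genome)
  feats <- classify_coding(
    seqs,
    min_orf = config$min_orf,
    min_orf_supported = config$min_orf_supported,
    min_coverage = config$min_coverage,
    fickett_cutoff = config$fickett_cutoff
  )
  tx <- dplyr::left_join(tx, feats, by = "transcript_id")

  coding_exons <- filtered$transcripts[
    filtered$transcripts$transcript_id %in% tx$transcript_id[tx$coding],
  ]
  nc_exons <- filtered$transcripts[
    filtered$transcripts$transcript_id %in% tx$transcript_id[!tx$coding],
  ]

  # noncoding: positional classification + gene grouping
  if (nrow(nc_exons) > 0) {
    nc_class <- classify_nc_transcripts(nc_exons, coding_exons)
    nc_map <- group_noncoding_by_overlap(nc_exons)
    nc_class <- dplyr::left_join(nc_class, nc_map, by = "transcript_id")
    nc_gene_cat <- classify_nc_genes(
      dplyr::rename(nc_class, gene_id = "nc_gene_id")
    )
    nc_gene_cat <- dplyr::rename(nc_gene_cat, nc_gene_id = "gene_id")
  } else {
    nc_class <- tibble::tibble(
      transcript_id = character(), nc_category = character(),
      sense_exon_overlap = logical(), antisense_exon_overlap = logical(),
      nc_gene_id = character()
    )
    nc_gene_cat <- tibble::tibble(nc_gene_id = character(), nc_category = character())
  }
  tx <- dplyr::left_join(
    tx, nc_class[, c("transcript_id", "nc_category", "nc_gene_id")],
    by = "transcript_id"
  )

  # coding: isoform groups within loci
  proteins <- tx[tx$coding & !is.na(tx$protein), ]
  proteins <- tibble::tibble(
    locus = proteins$gene_id,
    transcript_id = proteins$transcript_id,
    protein = proteins$protein
  )
  iso_scores <- isoform_pair_scores(proteins)
  iso <- group_isoforms(proteins, cutoff = config$isoform_cutoff, scores = iso_scores)
  tx <- dplyr::left_join(
    tx, iso[, c("transcript_id", "group_id", "representative")],
    by = "transcript_id"
  )

  genes <- if (nrow(filtered$transcripts) > 0) {
    categorize_genes(
      dplyr::left_join(
        filtered$transcripts,
        codes[, c("transcript_id", "class_code")],
        by = "transcript_id"
      ),
      index,
      junction_tolerance = config$flipped_tolerance
    )
  } else {
    tibble::tibble(
      gene_id = character(), category = character(),
      n_transcripts = integer(), n_eq = integer(), n_j = integer(),
      n_novel = integer(), n_shared_junctions = integer()
    )
  }
  gene_coding <- dplyr::summarise(
    dplyr::group_by(tx, .data$gene_id),
    any_coding = any(.data$coding),
    .groups = "drop"
  )
  genes <- dplyr::left_join(genes, gene_coding, by = "gene_id")

  unexpressed <- detect_unexpressed(reference_tbl, filtered)

  report <- build_report(tx, genes, nc_gene_cat, unexpressed, n_merged, index)

  structure(
    list(
      transcripts = tx,
      genes = genes,
      nc_genes = nc_gene_cat,
      isoform_scores = iso_scores,
      unexpressed = unexpressed,
      provenance = filtered$provenance,
      report = report,
      config = config
    ),
    class = "tx_annotation"
  )
}

# assemble the summary report; its internal consistency is asserted, not
# merely tested
build_report <- function(tx, genes, nc_gene_cat, unexpressed, n_merged, index) {
  n_tx <- nrow(tx)
  n_coding_tx <- sum(tx$coding)
  n_nc_tx <- sum(!tx$coding)
  code_counts <- table(factor(
    tx$class_code,
    levels = c("=", "j", "c", "k", "o", "i", "y", "x", "u")
  ))
  n_novel_tx <- sum(tx$novel)
  stopifnot(
    n_coding_tx + n_nc_tx == n_tx,
    sum(code_counts) == n_tx,
    sum(code_counts[c("i", "u", "y", "x")]) == n_novel_tx
  )
  coding_groups <- unique(tx$group_id[tx$coding])
  group_sizes <- table(tx$group_id[tx$coding])
  multi_groups <- names(group_sizes)[group_sizes >= 2]
  novel_loci <- genes$gene_id[genes$category == "novel"]
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_

  ref_lengths <- index$transcripts$spliced_length
  length_summary <- dplyr::bind_rows(
    tibble::tibble(
      set = "new_annotation",
      n = n_tx,
      min = if (n_tx) min(tx$spliced_length) else NA_real_,
      median = if (n_tx) stats::median(tx$spliced_length) else NA_real_,
      mean = if (n_tx) mean(tx$spliced_length) else NA_real_,
      max = if (n_tx) max(tx$spliced_length) else NA_real_
    ),
    tibble::tibble(
      set = "old_annotation",
      n = length(ref_lengths),
      min = if (length(ref_lengths)) min(ref_lengths) else NA_real_,
      median = if (length(ref_lengths)) stats::median(ref_lengths) else NA_real_,
      mean = if (length(ref_lengths)) mean(ref_lengths) else NA_real_,
      max = if (length(ref_lengths)) max(ref_lengths) else NA_real_
    )
  )

  list(
    n_transcripts_merged = n_merged,
    n_transcripts = n_tx,
    n_coding_transcripts = n_coding_tx,
    n_noncoding_transcripts = n_nc_tx,
    n_coding_genes = length(coding_groups),
    n_noncoding_genes = dplyr::n_distinct(tx$nc_gene_id[!tx$coding]),
    n_loci = nrow(genes),
    n_novel_transcripts = n_novel_tx,
    n_novel_genes = length(novel_loci),
    n_novel_coding_genes = sum(genes$any_coding[genes$category == "novel"]),
    n_novel_noncoding_genes = sum(!genes$any_coding[genes$category == "novel"]),
    class_code_counts = code_counts,
    nc_gene_category_counts = table(factor(
      nc_gene_cat$nc_category,
      levels = c(
        "intergenic", "antisense", "sense_overlap", "intronic",
        "sense_and_antisense"
      )
    )),
    gene_category_counts = table(factor(
      genes$category,
      levels = c(
        "unchanged", "novel_splice_variant", "all_transcripts_differ",
        "all_junctions_differ", "flipped", "novel", "uncategorized"
      )
    )),
    n_unexpressed = nrow(unexpressed),
    n_multi_isoform_genes = length(multi_groups),
    n_multi_isoform_transcripts = sum(tx$group_id %in% multi_groups, na.rm = TRUE),
    alt_splicing_percent = pct(length(multi_groups), length(coding_groups)),
    multi_isoform_transcript_percent = pct(
      sum(tx$group_id %in% multi_groups, na.rm = TRUE), n_coding_tx
    ),
    length_summary = length_summary
  )
}

#' Headline alternative-splicing percentage
#'
#' The fraction of coding genes with more than one isoform, as a
#' percentage. The headline figure is rounded half-up to an integer; the
#' unrounded value is reported alongside.
#'
#' @param multi_isoform_genes Number of genes with two or more isoforms.
#' @param coding_genes Total number of coding genes (must be >= 1 for a
#'   defined percentage).
#' @return A one-row tibble: `multi_isoform_genes`, `coding_genes`,
#'   `percent` (unrounded), `percent_rounded`.
#' @examples
#' alt_splicing_percent(1640, 7044) # 23
#' @export
alt_splicing_percent <- function(multi_isoform_genes, coding_genes) {
  if (coding_genes < 1) {
    return(tibble::tibble(
      multi_isoform_genes = multi_isoform_genes, coding_genes = coding_genes,
      percent = NA_real_, percent_rounded = NA_real_
    ))
  }
  p <- 100 * multi_isoform_genes / coding_genes
  tibble::tibble(
    multi_isoform_genes = multi_isoform_genes, coding_genes = coding_genes,
    percent = p, percent_rounded = floor(p + 0.5)
  )
}

#' Percentage of coding transcripts belonging to multi-isoform genes
#'
#' @param multi_isoform_transcripts Transcripts in genes with two or more
#'   isoforms.
#' @param coding_transcripts Total coding transcripts.
#' @return A one-row tibble with the unrounded percentage and the value
#'   rounded to one decimal.
#' @examples
#' multi_isoform_transcript_percent(4368, 9772) # 44.7
#' @export
multi_isoform_transcript_percent <- function(multi_isoform_transcripts,
                                             coding_transcripts) {
  if (coding_transcripts < 1) {
    return(tibble::tibble(
      multi_isoform_transcripts = multi_isoform_transcripts,
      coding_transcripts = coding_transcripts,
      percent = NA_real_, percent_rounded = NA_real_
    ))
  }
  p <- 100 * multi_isoform_transcripts / coding_transcripts
  tibble::tibble(
    multi_isoform_transcripts = multi_isoform_transcripts,
    coding_transcripts = coding_transcripts,
    percent = p, percent_rounded = round(p, 1)
  )
}

#' @export
print.tx_annotation <- function(x, ...) {
  r <- x$report
  cat("Refined transcriptome annotation\n")
  cat("  reliable transcripts:", r$n_transcripts, sprintf(
    "(%d coding, %d noncoding)\n", r$n_coding_transcripts,
    r$n_noncoding_transcripts
  ))
  cat(
    "  genes:", r$n_coding_genes, "coding,", r$n_noncoding_genes,
    "noncoding;", r$n_novel_genes, "novel loci\n"
  )
  cat(sprintf(
    "  alternatively spliced coding genes: %d (%.1f%%)\n",
    r$n_multi_isoform_genes,
    ifelse(is.na(r$alt_splicing_percent), 0, r$alt_splicing_percent)
  ))
  cat("  unexpressed old genes:", r$n_unexpressed, "\n")
  invisible(x)
}

#' Write the pipeline outputs to disk
#'
#' Emits the annotated GTF (`class_code`, `cmp_ref`, `category` tags), the
#' per-transcript and per-gene TSV tables, the isoform similarity pairs,
#' the unexpressed-gene list and a two-column summary report. Output is
#' byte-identical across repeated runs on the same inputs.
#'
#' @param annotation A `tx_annotation` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_annotation <- function(annotation, dir) {
  stopifnot(inherits(annotation, "tx_annotation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tx <- annotation$transcripts
  exon_rows <- purrr::pmap(
    tx[, c("transcript_id", "gene_id", "chrom", "strand", "start", "end", "chain")],
    function(transcript_id, gene_id, chrom, strand, start, end, chain) {
      b <- chain_bounds(chain, start, end)
      tibble::tibble(
        transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
        strand = strand, start = b$start, end = b$end
      )
    }
  )
  exons <- dplyr::bind_rows(exon_rows)
  cat_by_gene <- annotation$genes[, c("gene_id", "category")]
  attrs <- dplyr::left_join(
    tx[, c("transcript_id", "gene_id", "class_code", "cmp_ref")],
    cat_by_gene,
    by = "gene_id"
  )[, c("transcript_id", "class_code", "cmp_ref", "category")]
  write_gtf(exons, file.path(dir, "annotated.gtf"), attributes = attrs)
  readr::write_tsv(
    dplyr::select(tx, -dplyr::any_of("sequence")),
    file.path(dir, "transcripts.tsv")
  )
  readr::write_tsv(annotation$genes, file.path(dir, "genes.tsv"))
  readr::write_tsv(annotation$nc_genes, file.path(dir, "nc_genes.tsv"))
  readr::write_tsv(annotation$isoform_scores, file.path(dir, "isoform_scores.tsv"))
  readr::write_tsv(annotation$unexpressed, file.path(dir, "unexpressed.tsv"))
  r <- annotation$report
  flat <- c(
    r[c(
      "n_transcripts_merged", "n_transcripts", "n_coding_transcripts",
      "n_noncoding_transcripts", "n_coding_genes", "n_noncoding_genes",
      "n_loci", "n_novel_transcripts", "n_novel_genes",
      "n_novel_coding_genes", "n_novel_noncoding_genes", "n_unexpressed",
      "n_multi_isoform_genes", "n_multi_isoform_transcripts",
      "alt_splicing_percent", "multi_isoform_transcript_percent"
    )],
    stats::setNames(
      as.list(as.integer(r$class_code_counts)),
      paste0("class_", names(r$class_code_counts))
    ),
    stats::setNames(
      as.list(as.integer(r$nc_gene_category_counts)),
      paste0("nc_genes_", names(r$nc_gene_category_counts))
    ),
    stats::setNames(
      as.list(as.integer(r$gene_category_counts)),
      paste0("genes_", names(r$gene_category_counts))
    )
  )
  readr::write_tsv(
    tibble::tibble(
      metric = names(flat),
      value = vapply(flat, function(v) format(v, digits = 10), character(1))
    ),
    file.path(dir, "report.tsv")
  )
  invisible(dir)
}
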