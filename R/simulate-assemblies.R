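# ---- emitted transcript structures ----------------------------------------
# Each expressed gene yields one or more *structures* (distinct exon
# chains); every sample emits every structure, varying only the random UTR
# extensions. Fixing structures across samples keeps the merged
# transcriptome and the truth table in one-to-one correspondence.

# grow (delta > 0) or shrink (delta < 0) the 5'-UTR exon into/away from its
# adjacent intron, genomically
shift_utr5_junction <- function(exons, strand, delta) {
  if (strand == "+") {
    exons$end[1] <- exons$end[1] + delta
  } else {
    exons$start[nrow(exons)] <- exons$start[nrow(exons)] - delta
  }
  exons
}

shift_utr3_junction <- function(exons, strand, delta) {
  if (strand == "+") {
    exons$start[nrow(exons)] <- exons$start[nrow(exons)] - delta
  } else {
    exons$end[1] <- exons$end[1] + delta
  }
  exons
}

# retain the 5'-UTR intron: merge the UTR exon with its neighbour
retain_utr5_intron <- function(exons, strand) {
  k <- nrow(exons)
  if (strand == "+") {
    exons$end[1] <- exons$end[2]
    exons <- exons[-2, ]
  } else {
    exons$start[k] <- exons$start[k - 1]
    exons <- exons[-(k - 1), ]
  }
  exons
}

# a legal junction shift for a gene: 3-30 nt, keeping the UTR exon >= 3 nt
# and the intron >= 20 nt
draw_junction_shift <- function(exon_spliced_len, intron_len) {
  lo_shrink <- -min(9L, exon_spliced_len - 3L)
  hi_grow <- min(30L, intron_len - 20L)
  choices <- c(seq(lo_shrink, -3L), seq(3L, hi_grow))
  choices[sample.int(length(choices), 1L)]
}

# build the structure list (exon tables + truth labels) for one gene
gene_structures <- function(gn) {
  out <- list()
  add <- function(suffix, exons, strand, label, class, coding, group, nc, extend) {
    out[[length(out) + 1]] <<- list(
      transcript_id = paste0(gn$id, ".", suffix),
      gene_id = gn$id, chrom = gn$chrom, strand = strand,
      exons = exons, truth_label = label, expected_class = class,
      coding = coding, isoform_group = group, nc_category = nc,
      extend = extend
    )
  }
  m <- gn$model
  role <- gn$role
  if (role == "unexpressed") {
    return(out)
  }
  if (gn$kind == "ref_noncoding") {
    add(
      "i1", gn$exons, gn$strand, "reference_match", "=",
      FALSE, NA_character_, "intergenic", TRUE
    )
    return(out)
  }
  if (gn$kind == "lincRNA") {
    add(
      "i1", gn$exons, gn$strand, "intergenic_noncoding", "u",
      FALSE, NA_character_, "intergenic", FALSE
    )
    return(out)
  }
  group <- paste0(gn$id, ".grp")
  if (role == "flipped") {
    flip <- if (gn$strand == "+") "-" else "+"
    add(
      "i1", gn$exons, flip, "flipped", "x",
      FALSE, NA_character_, "intergenic", TRUE
    )
    return(out)
  }
  if (role == "all_shifted") {
    d1 <- draw_junction_shift(m$cuts[1], m$intron_len[1])
    d2 <- draw_junction_shift(m$spliced_len - m$cuts[2], m$intron_len[2])
    exons <- shift_utr3_junction(
      shift_utr5_junction(gn$exons, gn$strand, d1),
      gn$strand, d2
    )
    add(
      "i1", exons, gn$strand, "restructured", "o",
      TRUE, group, NA_character_, TRUE
    )
    return(out)
  }
  # every remaining role emits the faithful primary transcript
  add(
    "i1", gn$exons, gn$strand, "reference_match", "=",
    TRUE, group, NA_character_, TRUE
  )
  if (role == "multi_isoform") {
    add(
      "i2", retain_utr5_intron(gn$exons, gn$strand), gn$strand,
      "novel_splice", "j", TRUE, group, NA_character_, TRUE
    )
    if (sample(c(TRUE, FALSE), 1)) {
      d <- draw_junction_shift(m$cuts[1], m$intron_len[1])
      add(
        "i3", shift_utr5_junction(gn$exons, gn$strand, d), gn$strand,
        "novel_splice", "j", TRUE, group, NA_character_, TRUE
      )
    }
  }
  if (role == "perturb") {
    d <- draw_junction_shift(m$cuts[1], m$intron_len[1])
    add(
      "i2", shift_utr5_junction(gn$exons, gn$strand, d), gn$strand,
      "novel_splice", "j", TRUE, group, NA_character_, TRUE
    )
  }
  if (role == "intronic_host") {
    p <- m$intron_plant_local
    g <- local_to_genomic(
      p$local_start, p$local_end, gn$start, m$footprint_len, gn$strand
    )
    add(
      "nc1", tibble::tibble(start = g$start, end = g$end), gn$strand,
      "intronic_noncoding", "i", FALSE, NA_character_, "intronic", FALSE
    )
  }
  if (role %in% c("antisense_host", "sense_host")) {
    ov <- 30L
    ext <- rand_int(220L, 320L)
    if (gn$strand == "+") {
      span <- c(gn$end - ov + 1L, gn$end + ext)
    } else {
      span <- c(gn$start - ext, gn$start + ov - 1L)
    }
    if (role == "antisense_host") {
      add(
        "nc1", tibble::tibble(start = span[1], end = span[2]),
        if (gn$strand == "+") "-" else "+",
        "antisense_noncoding", "x", FALSE, NA_character_, "antisense", FALSE
      )
    } else {
      add(
        "nc1", tibble::tibble(start = span[1], end = span[2]), gn$strand,
        "sense_overlap_noncoding", "o", FALSE, NA_character_,
        "sense_overlap", FALSE
      )
    }
  }
  if (role == "fragment_host") {
    widths <- gn$exons$end - gn$exons$start + 1L
    j <- which.max(widths)
    flen <- min(150L, widths[j] - 12L)
    add(
      "frag1",
      tibble::tibble(
        start = gn$exons$start[j] + 6L,
        end = gn$exons$start[j] + 5L + flen
      ),
      gn$strand, "fragment", NA_character_, FALSE, NA_character_,
      NA_character_, FALSE
    )
  }
  out
}

#' Simulate per-sample assembled transcript sets
#'
#' Emits, for every sample, the transcript structures planted by
#' [simulate_reference()]: faithful reference transcripts with random UTR
#' extensions, junction-shifted and intron-retained isoforms, strand-flipped
#' models, the four kinds of noncoding plants, and sub-200 nt fragments.
#' Structures are fixed across samples (what an assembler would ideally
#' reconstruct in each replicate); only the UTR extension draws differ by
#' sample.
#'
#' @param ref_sim A `sim_reference` from [simulate_reference()].
#' @param config The same [sim_config()].
#' @return A list of class `sim_assemblies`: `samples` (named list of
#'   transcript tables), `truth` (list with `transcripts`, `genes`,
#'   `unexpressed`, `emissions` tibbles).
#' @export
simulate_assemblies <- function(ref_sim, config) {
  stopifnot(inherits(ref_sim, "sim_reference"), inherits(config, "sim_config"))
  local_seed(config$seed + 2L, {
    structures <- purrr::list_flatten(purrr::map(ref_sim$genes, gene_structures))

    empty_truth_tx <- tibble::tibble(
      transcript_id = character(), gene_id = character(),
      truth_label = character(), expected_class = character(),
      coding = logical(), isoform_group = character(),
      nc_category = character(), chain = character(),
      chrom = character(), strand = character()
    )
    truth_tx <- dplyr::bind_rows(empty_truth_tx, purrr::map(structures, function(st) {
      ex <- st$exons[order(st$exons$start), ]
      tibble::tibble(
        transcript_id = st$transcript_id, gene_id = st$gene_id,
        truth_label = st$truth_label, expected_class = st$expected_class,
        coding = st$coding, isoform_group = st$isoform_group,
        nc_category = st$nc_category,
        chain = chain_key(ex$start, ex$end),
        chrom = st$chrom, strand = st$strand
      )
    }))

    samples <- list()
    empty_sample <- tibble::tibble(
      transcript_id = character(), gene_id = character(),
      chrom = character(), strand = character(),
      start = integer(), end = integer()
    )
    for (s in seq_len(config$n_samples)) {
      rows <- purrr::map(structures, function(st) {
        exons <- dplyr::arrange(st$exons, .data$start)
        if (st$extend) {
          e5 <- rand_int(config$utr5_range[1], config$utr5_range[2])
          e3 <- rand_int(config$utr3_range[1], config$utr3_range[2])
          if (st$strand == "+") {
            exons$start[1] <- exons$start[1] - e5
            exons$end[nrow(exons)] <- exons$end[nrow(exons)] + e3
          } else {
            exons$start[1] <- exons$start[1] - e3
            exons$end[nrow(exons)] <- exons$end[nrow(exons)] + e5
          }
        }
        tibble::tibble(
          transcript_id = st$transcript_id, gene_id = st$gene_id,
          chrom = st$chrom, strand = st$strand,
          start = exons$start, end = exons$end
        )
      })
      samples[[paste0("sample_", s)]] <- as_transcripts(
        dplyr::bind_rows(empty_sample, rows)
      )
    }

    empty_truth_genes <- tibble::tibble(
      gene_id = character(), role = character(), category = character(),
      expressed = logical(), coding = logical()
    )
    truth_genes <- dplyr::bind_rows(empty_truth_genes, purrr::map(ref_sim$genes, function(gn) {
      category <- switch(gn$role,
        plain = "unchanged",
        intronic_host = "unchanged",
        antisense_host = "unchanged",
        fragment_host = "unchanged",
        ref_noncoding = "unchanged",
        sense_host = "uncategorized",
        multi_isoform = "novel_splice_variant",
        perturb = "novel_splice_variant",
        all_shifted = "all_junctions_differ",
        flipped = "flipped",
        lincRNA = "novel",
        unexpressed = NA_character_
      )
      tibble::tibble(
        gene_id = gn$id, role = gn$role, category = category,
        expressed = gn$role != "unexpressed",
        coding = gn$kind == "coding" &
          !gn$role %in% c("unexpressed", "flipped")
      )
    }))
    # each antisense/intronic noncoding plant (and every lincRNA) forms a
    # novel locus of its own; sense plants fold into their host's locus
    plant_loci <- truth_tx[
      truth_tx$truth_label %in% c("antisense_noncoding", "intronic_noncoding"),
    ]
    truth_loci <- dplyr::bind_rows(
      truth_genes[
        truth_genes$expressed & !is.na(truth_genes$category),
        c("gene_id", "category")
      ],
      tibble::tibble(gene_id = paste0(plant_loci$gene_id, ".nc"), category = "novel")
    )

    emissions <- tidyr::crossing(
      sample = paste0("sample_", seq_len(config$n_samples)),
      transcript_id = truth_tx$transcript_id
    )
    emissions <- dplyr::left_join(
      emissions,
      truth_tx[, c("transcript_id", "gene_id", "truth_label", "isoform_group")],
      by = "transcript_id"
    )

    structure(
      list(
        samples = samples,
        truth = list(
          transcripts = truth_tx,
          genes = truth_genes,
          loci = truth_loci,
          unexpressed = truth_genes$gene_id[truth_genes$role == "unexpressed"],
          emissions = emissions
        )
      ),
      class = "sim_assemblies"
    )
  })
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper: genome, planted reference annotation, per-sample
#' assemblies and ground truth in one call.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_study` with elements `genome`, `reference`,
#'   `samples`, `truth`, `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  genome0 <- simulate_genome(config)
  ref_sim <- simulate_reference(genome0, config)
  asm <- simulate_assemblies(ref_sim, config)
  structure(
    list(
      genome = ref_sim$genome,
      reference = ref_sim$reference,
      samples = asm$samples,
      truth = asm$truth,
      config = config
    ),
    class = "sim_study"
  )
}

#' @export
print.sim_study <- function(x, ...) {
  cat(
    "Synthetic study:", length(x$genome), "chromosome(s),",
    dplyr::n_distinct(x$reference$gene_id), "reference genes,",
    length(x$samples), "sample(s),",
    nrow(x$truth$transcripts), "planted transcript structures\n"
  )
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Emits `genome.fa`, `reference.gtf`, `sample_<k>.gtf` and `truth.tsv`
#' (one row per emitted transcript per sample: sample, transcript_id,
#' truth_label, gene_id, isoform_group).
#'
#' @param study A `sim_study` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "sim_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome(study$genome, file.path(dir, "genome.fa"))
  write_gtf(
    study$reference[, 1:6],
    file.path(dir, "reference.gtf"),
    attributes = dplyr::distinct(
      study$reference[, c("transcript_id", "biotype")]
    )
  )
  for (nm in names(study$samples)) {
    write_gtf(study$samples[[nm]], file.path(dir, paste0(nm, ".gtf")))
  }
  readr::write_tsv(study$truth$emissions, file.path(dir, "truth.tsv"))
  invisible(dir)
}
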