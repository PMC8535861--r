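#' Configuration for the synthetic transcriptome study
#'
#' Defines the conditions the synthetic-data generator emulates: a compact
#' fungal-style genome densely packed with intron-containing coding genes,
#' a reference annotation, and per-sample assembled transcript sets that
#' differ from the reference by UTR extensions, altered splice junctions,
#' planted noncoding transcripts in every positional category, short
#' assembly fragments, multi-isoform loci, strand-flipped gene models and
#' unexpressed reference genes. Every emitted transcript carries a ground
#' truth label, so the full pipeline can be checked against the plan.
#'
#' @param seed Integer seed; the whole study is deterministic given the
#'   configuration.
#' @param n_chroms,chrom_length Number and length (nt) of chromosomes.
#' @param n_coding_genes Coding reference genes (each with a planted
#'   ATG-initiated, stop-terminated ORF of at least 300 nt covering at
#'   least 60 percent of the spliced transcript).
#' @param n_ref_noncoding Noncoding reference genes (no planted ORF).
#' @param n_lincRNA,n_antisense,n_intronic,n_sense_overlap Planted novel
#'   noncoding transcripts per positional category.
#' @param n_multi_isoform_genes Coding genes emitting 2-3 isoforms sharing
#'   the planted ORF.
#' @param n_flipped Genes whose transcripts are emitted on the opposite
#'   strand while reusing the reference junction coordinates.
#' @param n_all_shifted Genes emitted with every splice junction moved
#'   (within the UTRs, so the ORF is preserved).
#' @param n_unexpressed Reference genes emitted in no sample.
#' @param utr5_range,utr3_range Ranges (nt, inclusive) for the per-sample
#'   random UTR extensions of expressed reference transcripts.
#' @param junction_perturb_fraction Fraction of coding genes that emit an
#'   additional isoform with one intron boundary shifted by 3-30 nt.
#' @param fragment_fraction Fraction of coding genes that also emit a
#'   sub-200 nt mono-exon fragment (removed by the length filter).
#' @param n_samples Number of per-sample assembled transcript sets.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_length = 500000L,
                       n_coding_genes = 160L,
                       n_ref_noncoding = 6L,
                       n_lincRNA = 12L,
                       n_antisense = 10L,
                       n_intronic = 8L,
                       n_sense_overlap = 8L,
                       n_multi_isoform_genes = 24L,
                       n_flipped = 3L,
                       n_all_shifted = 6L,
                       n_unexpressed = 8L,
                       utr5_range = c(20L, 120L),
                       utr3_range = c(20L, 120L),
                       junction_perturb_fraction = 0.15,
                       fragment_fraction = 0.05,
                       n_samples = 3L) {
  cfg <- list(
    seed = as.integer(seed), n_chroms = as.integer(n_chroms),
    chrom_length = as.integer(chrom_length),
    n_coding_genes = as.integer(n_coding_genes),
    n_ref_noncoding = as.integer(n_ref_noncoding),
    n_lincRNA = as.integer(n_lincRNA),
    n_antisense = as.integer(n_antisense),
    n_intronic = as.integer(n_intronic),
    n_sense_overlap = as.integer(n_sense_overlap),
    n_multi_isoform_genes = as.integer(n_multi_isoform_genes),
    n_flipped = as.integer(n_flipped),
    n_all_shifted = as.integer(n_all_shifted),
    n_unexpressed = as.integer(n_unexpressed),
    utr5_range = as.integer(utr5_range),
    utr3_range = as.integer(utr3_range),
    junction_perturb_fraction = junction_perturb_fraction,
    fragment_fraction = fragment_fraction,
    n_samples = as.integer(n_samples)
  )
  counts <- cfg[grepl("^n_", names(cfg))]
  if (any(unlist(counts) < 0)) {
    rlang::abort("all counts must be >= 0")
  }
  if (cfg$n_chroms < 1 || cfg$chrom_length < 1) {
    rlang::abort("need at least one chromosome of length >= 1")
  }
  if (cfg$n_samples < 1) {
    rlang::abort("need at least one sample")
  }
  for (f in c("junction_perturb_fraction", "fragment_fraction")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      rlang::abort(paste0(f, " must lie in [0, 1]"))
    }
  }
  for (r in c("utr5_range", "utr3_range")) {
    if (length(cfg[[r]]) != 2 || cfg[[r]][1] < 1 || cfg[[r]][1] > cfg[[r]][2]) {
      rlang::abort(paste0(r, " must be an increasing positive pair"))
    }
  }
  n_special <- cfg$n_multi_isoform_genes + cfg$n_flipped + cfg$n_all_shifted +
    cfg$n_unexpressed + cfg$n_intronic + cfg$n_antisense + cfg$n_sense_overlap
  if (n_special > cfg$n_coding_genes) {
    rlang::abort(paste0(
      "special gene roles (", n_special,
      ") exceed n_coding_genes (", cfg$n_coding_genes, ")"
    ))
  }
  structure(cfg, class = "sim_config")
}

# run code under a temporary RNG state seeded with `seed`
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

rand_int <- function(lo, hi) {
  if (hi < lo) rlang::abort("empty integer range")
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random DNA containing neither "ATG" nor "CAT", so the sequence can start
# no ORF when read in either orientation
random_dna_nostart <- function(n) {
  x <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  if (n < 3) {
    return(paste(x, collapse = ""))
  }
  repeat {
    i <- seq_len(n - 2L)
    bad <- which(
      (x[i] == "A" & x[i + 1L] == "T" & x[i + 2L] == "G") |
        (x[i] == "C" & x[i + 1L] == "A" & x[i + 2L] == "T")
    )
    if (length(bad) == 0) break
    x[bad + 1L] <- "C"
  }
  paste(x, collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# random in-frame coding sequence: ATG + non-stop codons + one stop
random_orf <- function(nt_length) {
  stopifnot(nt_length %% 3 == 0, nt_length >= 9)
  codons <- apply(
    expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"), c("A", "C", "G", "T")),
    1, paste,
    collapse = ""
  )
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  body <- sample(codons, nt_length / 3 - 2, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), sample(c("TAA", "TAG", "TGA"), 1))
}

#' Generate a random genome
#'
#' Deterministic for a fixed configuration: i.i.d. uniform A/C/G/T bases.
#' [simulate_reference()] later writes gene sequences into this backbone.
#'
#' @param config A [sim_config()].
#' @return A named [Biostrings::DNAStringSet] (`chr1`, `chr2`, ...).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  local_seed(config$seed, {
    seqs <- vapply(
      seq_len(config$n_chroms),
      function(i) random_dna(config$chrom_length),
      character(1)
    )
    names(seqs) <- paste0("chr", seq_len(config$n_chroms))
    Biostrings::DNAStringSet(seqs)
  })
}

# ---- internal gene-model construction -------------------------------------

# build one coding gene model in transcript-local space
# returns: u5/orf/u3 lengths, exon cuts (spliced coords), intron lengths,
# spliced sequence, intron sequences, local exon intervals, footprint string
build_gene_model <- function(role, intronic_plant = FALSE) {
  orf_len <- 3L * rand_int(100L, 260L)
  u5 <- rand_int(40L, min(100L, orf_len %/% 3L))
  u3 <- rand_int(40L, min(100L, orf_len %/% 3L))
  L <- u5 + orf_len + u3
  k <- switch(role,
    multi_isoform = rand_int(3L, 6L),
    perturb = rand_int(3L, 6L),
    all_shifted = 3L,
    intronic_host = rand_int(3L, 5L),
    fragment_host = rand_int(2L, 3L),
    flipped = rand_int(2L, 4L),
    antisense_host = rand_int(2L, 4L),
    sense_host = rand_int(2L, 4L),
    rand_int(1L, 8L)
  )
  cuts <- integer(0)
  if (k >= 2) {
    cuts <- rand_int(12L, u5 - 12L) # one splice site inside the 5' UTR
    if (role == "all_shifted") {
      cuts <- c(cuts, rand_int(L - u3 + 12L, L - 12L)) # and one in the 3' UTR
    } else if (k > 2) {
      grid <- seq(u5 + 15L, L - u3 - 15L, by = 15L)
      cuts <- c(cuts, sort(sample(grid, k - 2L)))
    }
  }
  n_introns <- length(cuts)
  intron_len <- if (n_introns > 0) {
    vapply(seq_len(n_introns), function(j) rand_int(60L, 200L), integer(1))
  } else {
    integer(0)
  }
  if (intronic_plant && n_introns >= 2) {
    intron_len[2] <- rand_int(300L, 420L)
  }
  spliced <- paste0(
    random_dna_nostart(u5), random_orf(orf_len), random_dna_nostart(u3)
  )
  introns <- vapply(intron_len, random_dna_nostart, character(1))

  # local exon intervals within the genomic footprint (transcript sense)
  bounds <- c(0L, cuts, L)
  exon_spliced_len <- diff(bounds)
  exon_local_start <- integer(k)
  exon_local_end <- integer(k)
  pieces <- character(0)
  pos <- 0L
  plant <- NULL
  for (j in seq_len(k)) {
    exon_local_start[j] <- pos + 1L
    pos <- pos + exon_spliced_len[j]
    exon_local_end[j] <- pos
    pieces <- c(pieces, substring(spliced, bounds[j] + 1L, bounds[j + 1L]))
    if (j <= n_introns) {
      ilocal_start <- pos + 1L
      if (intronic_plant && j == 2L) {
        plen <- rand_int(210L, intron_len[2] - 80L)
        off <- rand_int(30L, intron_len[2] - plen - 30L)
        plant <- list(
          local_start = ilocal_start + off,
          local_end = ilocal_start + off + plen - 1L
        )
      }
      pieces <- c(pieces, introns[j])
      pos <- pos + intron_len[j]
    }
  }
  list(
    u5 = u5, orf_len = orf_len, u3 = u3, spliced_len = L, k = k,
    cuts = cuts, intron_len = intron_len,
    spliced = spliced,
    exon_local_start = exon_local_start, exon_local_end = exon_local_end,
    footprint = paste(pieces, collapse = ""),
    footprint_len = pos,
    intron_plant_local = plant
  )
}

# map local (transcript-sense footprint) intervals to genomic coordinates
local_to_genomic <- function(local_start, local_end, gene_start, footprint_len, strand) {
  if (strand == "+") {
    list(
      start = gene_start + local_start - 1L,
      end = gene_start + local_end - 1L
    )
  } else {
    list(
      start = gene_start + footprint_len - local_end,
      end = gene_start + footprint_len - local_start
    )
  }
}

#' Plant a reference annotation into a genome
#'
#' Places coding and noncoding reference genes (plus the hidden scaffolding
#' for the noncoding plants and variant isoforms that [simulate_assemblies()]
#' will emit) onto the chromosomes without same-strand overlap, writes
#' their sequences into the genome, and records the per-gene ground truth.
#' Coding genes carry a planted in-frame ORF (ATG...stop, at least 300 nt,
#' at least 60 percent of the spliced transcript); untranscribed filler,
#' UTRs and introns are generated free of ATG start codons in both
#' orientations so that the planted ORF is provably the longest one in any
#' emitted transcript.
#'
#' @param genome A genome from [simulate_genome()].
#' @param config The same [sim_config()].
#' @return A list of class `sim_reference` with elements `genome` (the
#'   modified `DNAStringSet`), `reference` (transcript table of the old
#'   annotation, with a `biotype` column), `genes` (per-gene metadata used
#'   by [simulate_assemblies()]) and `config`.
#' @export
simulate_reference <- function(genome, config) {
  stopifnot(inherits(config, "sim_config"))
  local_seed(config$seed + 1L, {
    simulate_reference_impl(genome, config)
  })
}

simulate_reference_impl <- function(genome, config) {
  n <- config$n_coding_genes
  roles <- rep("plain", n)
  pool <- seq_len(n)
  take <- function(count) {
    picked <- if (count > 0) sort(sample(pool, count)) else integer(0)
    pool <<- setdiff(pool, picked)
    picked
  }
  roles[take(config$n_multi_isoform_genes)] <- "multi_isoform"
  roles[take(config$n_flipped)] <- "flipped"
  roles[take(config$n_all_shifted)] <- "all_shifted"
  roles[take(config$n_unexpressed)] <- "unexpressed"
  roles[take(config$n_intronic)] <- "intronic_host"
  roles[take(config$n_antisense)] <- "antisense_host"
  roles[take(config$n_sense_overlap)] <- "sense_host"
  n_perturb <- round(config$junction_perturb_fraction * n)
  n_perturb <- min(n_perturb, length(pool))
  roles[take(n_perturb)] <- "perturb"
  n_frag <- round(config$fragment_fraction * n)
  n_frag <- min(n_frag, length(pool))
  roles[take(n_frag)] <- "fragment_host"

  ext5_max <- config$utr5_range[2]
  ext3_max <- config$utr3_range[2]
  zone_len <- max(ext5_max, ext3_max) + 30L
  plant_zone_len <- 420L

  # build all genic elements in transcript-local space first
  elements <- list()
  for (g in seq_len(n)) {
    role <- roles[g]
    strand <- sample(c("+", "-"), 1)
    model <- build_gene_model(role, intronic_plant = role == "intronic_host")
    if (role == "flipped") {
      # the emitted transcript is the reverse-complement reading of this
      # gene; regenerate until that reading has no ORF that could be called
      # coding even at maximal UTR extension
      zoneL <- random_dna_nostart(zone_len)
      zoneR <- random_dna_nostart(zone_len)
      tries <- 0L
      repeat {
        E <- if (strand == "+") model$spliced else revcomp(model$spliced)
        widest <- paste0(
          substring(zoneL, nchar(zoneL) - zone_len + 1L, nchar(zoneL)), E, zoneR
        )
        flipped_seq <- if (strand == "+") revcomp(widest) else widest
        orf <- find_longest_orf(flipped_seq)
        if (nrow(orf) == 0 || orf$nt_length < 120) break
        tries <- tries + 1L
        if (tries > 50) {
          rlang::abort("could not construct a noncoding flipped gene; placement error")
        }
        model <- build_gene_model(role)
      }
      model$zoneL <- zoneL
      model$zoneR <- zoneR
    }
    elements[[length(elements) + 1]] <- list(
      kind = "coding", id = sprintf("RG%04d", g), role = role,
      strand = strand, model = model
    )
  }
  for (g in seq_len(config$n_ref_noncoding)) {
    len <- rand_int(260L, 520L)
    k <- sample(1:2, 1)
    strand <- sample(c("+", "-"), 1)
    if (k == 1) {
      model <- list(
        spliced = random_dna_nostart(len), spliced_len = len, k = 1L,
        exon_local_start = 1L, exon_local_end = len,
        footprint = NULL, footprint_len = len
      )
      model$footprint <- model$spliced
    } else {
      cut <- rand_int(60L, len - 60L)
      ilen <- rand_int(60L, 200L)
      s <- random_dna_nostart(len)
      model <- list(
        spliced = s, spliced_len = len, k = 2L,
        exon_local_start = c(1L, cut + ilen + 1L),
        exon_local_end = c(cut, len + ilen),
        footprint = paste0(
          substring(s, 1, cut), random_dna_nostart(ilen),
          substring(s, cut + 1L, len)
        ),
        footprint_len = len + ilen
      )
    }
    elements[[length(elements) + 1]] <- list(
      kind = "ref_noncoding", id = sprintf("RN%04d", g),
      role = "ref_noncoding", strand = strand, model = model
    )
  }
  for (g in seq_len(config$n_lincRNA)) {
    len <- rand_int(240L, 480L)
    strand <- sample(c("+", "-"), 1)
    model <- list(
      spliced = random_dna_nostart(len), spliced_len = len, k = 1L,
      exon_local_start = 1L, exon_local_end = len,
      footprint_len = len
    )
    model$footprint <- model$spliced
    elements[[length(elements) + 1]] <- list(
      kind = "lincRNA", id = sprintf("LNC%04d", g),
      role = "lincRNA", strand = strand, model = model
    )
  }

  # lay the elements out round-robin across chromosomes
  chrom_names <- names(genome)
  cursor <- stats::setNames(rep(200L, config$n_chroms), chrom_names)
  writes <- stats::setNames(
    replicate(config$n_chroms, list(), simplify = FALSE), chrom_names
  )
  genes <- list()
  for (i in seq_along(elements)) {
    el <- elements[[i]]
    chrom <- chrom_names[(i - 1L) %% config$n_chroms + 1L]
    # a wide start-codon-free zone on the transcript-3' side of
    # antisense/sense plant hosts, where the plant extends past the gene
    zl_len <- zone_len
    zr_len <- zone_len
    if (el$role %in% c("antisense_host", "sense_host")) {
      if (el$strand == "+") zr_len <- plant_zone_len else zl_len <- plant_zone_len
    }
    gap <- rand_int(600L, 1000L)
    gene_start <- cursor[chrom] + gap
    W <- el$model$footprint_len
    gene_end <- gene_start + W - 1L
    if (gene_end + zr_len + 200L > config$chrom_length) {
      rlang::abort(paste0(
        "genes do not fit on ", chrom, " (chrom_length too small for config)"
      ))
    }
    cursor[chrom] <- gene_end + zr_len

    # exon genomic coordinates
    gm <- local_to_genomic(
      el$model$exon_local_start, el$model$exon_local_end,
      gene_start, W, el$strand
    )
    ord <- order(gm$start)
    exons <- tibble::tibble(start = gm$start[ord], end = gm$end[ord])

    # genome writes: footprint plus ATG-free flank zones (the UTR-extension
    # landing zones, kept start-codon-free in both orientations)
    footprint_genomic <- if (el$strand == "+") {
      el$model$footprint
    } else {
      revcomp(el$model$footprint)
    }
    zoneL <- if (!is.null(el$model$zoneL)) {
      el$model$zoneL
    } else {
      random_dna_nostart(zl_len)
    }
    zoneR <- if (!is.null(el$model$zoneR)) {
      paste0(el$model$zoneR, random_dna_nostart(max(0L, zr_len - nchar(el$model$zoneR))))
    } else {
      random_dna_nostart(zr_len)
    }
    writes[[chrom]][[length(writes[[chrom]]) + 1]] <-
      list(start = gene_start - zl_len, seq = paste0(zoneL, footprint_genomic, zoneR))

    genes[[length(genes) + 1]] <- list(
      id = el$id, kind = el$kind, role = el$role, chrom = chrom,
      strand = el$strand, start = gene_start, end = gene_end,
      exons = exons, model = el$model
    )
  }

  # apply the writes
  genome_chr <- as.character(genome)
  for (chrom in chrom_names) {
    for (w in writes[[chrom]]) {
      substr(
        genome_chr[[chrom]], w$start, w$start + nchar(w$seq) - 1L
      ) <- w$seq
    }
  }
  genome <- Biostrings::DNAStringSet(genome_chr)

  # reference annotation: all coding + reference-noncoding genes
  ref_rows <- purrr::map(genes, function(gn) {
    if (!gn$kind %in% c("coding", "ref_noncoding")) {
      return(NULL)
    }
    tibble::tibble(
      transcript_id = paste0(gn$id, ".t1"), gene_id = gn$id,
      chrom = gn$chrom, strand = gn$strand,
      start = gn$exons$start, end = gn$exons$end,
      biotype = if (gn$kind == "coding") "coding" else "noncoding"
    )
  })
  reference <- dplyr::bind_rows(
    tibble::tibble(
      transcript_id = character(), gene_id = character(),
      chrom = character(), strand = character(),
      start = integer(), end = integer(), biotype = character()
    ),
    ref_rows
  )
  structure(
    list(
      genome = genome,
      reference = reference,
      genes = genes,
      config = config
    ),
    class = "sim_reference"
  )
}

#' @export
print.sim_reference <- function(x, ...) {
  cat(
    "Synthetic reference:", sum(purrr::map_chr(x$genes, "kind") == "coding"),
    "coding genes,", sum(purrr::map_chr(x$genes, "kind") == "ref_noncoding"),
    "noncoding genes on", length(x$genome), "chromosome(s)\n"
  )
  invisible(x)
}
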