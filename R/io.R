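#' Read a GTF file into a transcript table
#'
#' Parses the `exon` features of a GTF file (Ensembl attribute dialect:
#' `gene_id "..."; transcript_id "...";`) into a transcript table. Non-exon
#' feature lines are ignored. Any further attributes on exon lines (for
#' example `class_code` written by [write_gtf()]) come back as extra
#' character columns. Unstranded (`.`) exon records are rejected: strand is
#' load-bearing for antisense classification and guessing it would be worse
#' than failing.
#'
#' @param path Path to a GTF file.
#' @return A transcript table (see [as_transcripts()]), possibly with extra
#'   attribute columns.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("GTF file not found: ", path))
  }
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(as_transcripts(tibble::tibble(
      transcript_id = character(), gene_id = character(),
      chrom = character(), strand = character(),
      start = integer(), end = integer()
    )))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields != 9L)) {
    bad <- line_no[which(n_fields != 9L)[1]]
    rlang::abort(paste0(
      "malformed GTF line ", bad, ": expected 9 tab-separated columns, got ",
      n_fields[which(n_fields != 9L)[1]]
    ))
  }
  m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  is_exon <- m[, 3] == "exon"
  m <- m[is_exon, , drop = FALSE]
  line_no <- line_no[is_exon]
  if (nrow(m) == 0) {
    return(as_transcripts(tibble::tibble(
      transcript_id = character(), gene_id = character(),
      chrom = character(), strand = character(),
      start = integer(), end = integer()
    )))
  }
  start <- suppressWarnings(as.integer(m[, 4]))
  end <- suppressWarnings(as.integer(m[, 5]))
  bad <- which(is.na(start) | is.na(end) | end < start | start < 1L)
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "malformed GTF line ", line_no[bad[1]],
      ": exon coordinates must satisfy 1 <= start <= end"
    ))
  }
  bad <- which(!m[, 7] %in% c("+", "-"))
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "malformed GTF line ", line_no[bad[1]],
      ": exon strand must be '+' or '-', got '", m[bad[1], 7], "'"
    ))
  }
  attrs <- parse_gtf_attributes(m[, 9], line_no)
  if (!"transcript_id" %in% names(attrs) || anyNA(attrs$transcript_id)) {
    bad <- if (!"transcript_id" %in% names(attrs)) {
      line_no[1]
    } else {
      line_no[which(is.na(attrs$transcript_id))[1]]
    }
    rlang::abort(paste0("malformed GTF line ", bad, ": missing transcript_id"))
  }
  if (!"gene_id" %in% names(attrs) || anyNA(attrs$gene_id)) {
    bad <- if (!"gene_id" %in% names(attrs)) {
      line_no[1]
    } else {
      line_no[which(is.na(attrs$gene_id))[1]]
    }
    rlang::abort(paste0("malformed GTF line ", bad, ": missing gene_id"))
  }
  tx <- tibble::tibble(
    transcript_id = attrs$transcript_id,
    gene_id = attrs$gene_id,
    chrom = m[, 1],
    strand = m[, 7],
    start = start,
    end = end
  )
  extra <- attrs[setdiff(names(attrs), c("transcript_id", "gene_id"))]
  if (length(extra) > 0) {
    tx <- dplyr::bind_cols(tx, tibble::as_tibble(extra))
  }
  out <- as_transcripts(tx[, 1:6])
  if (length(extra) > 0) {
    key <- paste(tx$transcript_id, tx$start)
    out_key <- paste(out$transcript_id, out$start)
    for (nm in names(extra)) {
      out[[nm]] <- extra[[nm]][match(out_key, key)]
    }
  }
  out
}

# parse `key "value";` attribute strings into a named list of vectors
parse_gtf_attributes <- function(attr_strings, line_no) {
  pieces <- strsplit(attr_strings, ";", fixed = TRUE)
  parsed <- lapply(pieces, function(p) {
    p <- trimws(p)
    p <- p[nzchar(p)]
    keys <- sub("^(\\S+)\\s+.*$", "\\1", p)
    vals <- sub("^\\S+\\s+\"?([^\"]*)\"?$", "\\1", p)
    stats::setNames(vals, keys)
  })
  keys <- unique(unlist(lapply(parsed, names)))
  out <- lapply(keys, function(k) {
    vapply(parsed, function(p) {
      if (k %in% names(p)) p[[k]] else NA_character_
    }, character(1))
  })
  stats::setNames(out, keys)
}

#' Write a transcript table to a GTF file
#'
#' Emits one `exon` feature line per exon row, in the Ensembl attribute
#' dialect. Extra per-transcript tags (class codes, diff categories,
#' provenance) can be supplied and are written as additional GTF
#' attributes; [read_gtf()] recovers them, so the round trip is lossless.
#'
#' @param tx A transcript table.
#' @param path Output file path.
#' @param attributes Optional data frame with a `transcript_id` column plus
#'   any number of character columns to emit as per-transcript attributes.
#' @return Invisibly, the path written.
#' @export
write_gtf <- function(tx, path, attributes = NULL) {
  tx <- as_transcripts(tx)
  header <- "# GTF written by txrefine"
  extra <- rep("", nrow(tx))
  if (!is.null(attributes) && nrow(tx) > 0) {
    attributes <- tibble::as_tibble(attributes)
    stopifnot("transcript_id" %in% names(attributes))
    idx <- match(tx$transcript_id, attributes$transcript_id)
    for (nm in setdiff(names(attributes), "transcript_id")) {
      val <- as.character(attributes[[nm]])[idx]
      tag <- ifelse(is.na(val), "", sprintf(' %s "%s";', nm, val))
      extra <- paste0(extra, tag)
    }
  }
  lines <- if (nrow(tx) == 0) {
    character(0)
  } else {
    sprintf(
      '%s\ttxrefine\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";%s',
      tx$chrom, tx$start, tx$end, tx$strand, tx$gene_id, tx$transcript_id, extra
    )
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(header, lines), con)
  invisible(path)
}

#' Read and write genome FASTA files
#'
#' Thin wrappers over Biostrings FASTA I/O. `read_genome()` returns an
#' uppercase [Biostrings::DNAStringSet] named by the first whitespace-free
#' token of each header; `write_genome()` writes 60-column wrapped FASTA.
#'
#' @param path FASTA file path.
#' @return `read_genome()`: a named `DNAStringSet`.
#' @export
read_genome <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (anyDuplicated(names(genome))) {
    rlang::abort("genome FASTA has duplicated sequence names")
  }
  Biostrings::DNAStringSet(toupper(genome))
}

#' @param genome A named `DNAStringSet` (or named character vector).
#' @rdname read_genome
#' @export
write_genome <- function(genome, path) {
  if (is.character(genome)) {
    genome <- Biostrings::DNAStringSet(genome)
  }
  Biostrings::writeXStringSet(genome, path, width = 60L)
  invisible(path)
}

#' Extract spliced, strand-corrected transcript sequences
#'
#' Concatenates each transcript's exon substrings in genomic order and, for
#' minus-strand transcripts, reverse-complements the result — i.e. returns
#' the mature (sense-strand) transcript sequence.
#'
#' @param tx A transcript table.
#' @param genome A named `DNAStringSet` or named character vector of
#'   chromosome sequences.
#' @return A tibble with columns `transcript_id` and `sequence`.
#' @export
spliced_sequence <- function(tx, genome) {
  tx <- as_transcripts(tx)
  if (!is.character(genome)) {
    genome <- as.character(genome)
  }
  missing_chr <- setdiff(unique(tx$chrom), names(genome))
  if (length(missing_chr) > 0) {
    rlang::abort(paste0(
      "chromosome(s) absent from genome: ", paste(missing_chr, collapse = ", ")
    ))
  }
  chrom_len <- nchar(genome)
  too_far <- tx$end > chrom_len[tx$chrom]
  if (any(too_far)) {
    rlang::abort(paste0(
      "exon beyond chromosome end for transcript(s): ",
      paste(utils::head(unique(tx$transcript_id[too_far]), 5), collapse = ", ")
    ))
  }
  tx$piece <- substring(genome[tx$chrom], tx$start, tx$end)
  per_tx <- dplyr::summarise(
    dplyr::group_by(tx, .data$transcript_id),
    strand = .data$strand[1],
    sequence = paste(.data$piece, collapse = ""),
    .groups = "drop"
  )
  neg <- per_tx$strand == "-"
  if (any(neg)) {
    per_tx$sequence[neg] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(per_tx$sequence[neg]))
    )
  }
  per_tx[, c("transcript_id", "sequence")]
}
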