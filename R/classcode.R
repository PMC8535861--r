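#' Build a reference index for class-code assignment
#'
#' Precomputes the per-chromosome, per-strand feature sets of a reference
#' annotation — exons, introns, transcript spans, gene spans, and the
#' splice-junction set — so that many query transcripts can be classified
#' against it efficiently.
#'
#' @param reference A transcript table of the reference annotation.
#' @return An object of class `reference_index`.
#' @export
build_reference_index <- function(reference) {
  reference <- as_transcripts(reference)
  s <- tx_summary(reference)
  introns <- tx_introns(reference)
  genes <- if (nrow(s) > 0) {
    dplyr::summarise(
      dplyr::group_by(s, .data$gene_id),
      chrom = .data$chrom[1], strand = .data$strand[1],
      start = min(.data$start), end = max(.data$end),
      .groups = "drop"
    )
  } else {
    tibble::tibble(
      gene_id = character(), chrom = character(), strand = character(),
      start = integer(), end = integer()
    )
  }
  gr <- function(df) {
    GenomicRanges::GRanges(
      df$chrom, IRanges::IRanges(df$start, df$end),
      strand = df$strand
    )
  }
  structure(
    list(
      transcripts = s,
      exons = reference,
      introns = introns,
      genes = genes,
      exon_gr = gr(reference),
      intron_gr = gr(introns),
      span_gr = gr(s),
      gene_gr = gr(genes),
      junction_keys = unique(paste(
        introns$chrom, introns$strand, introns$start, introns$end
      ))
    ),
    class = "reference_index"
  )
}

#' @export
print.reference_index <- function(x, ...) {
  cat(
    "Reference index:", nrow(x$transcripts), "transcripts,",
    nrow(x$genes), "genes,", nrow(x$introns), "introns\n"
  )
  invisible(x)
}

#' Assign structural class codes against a reference annotation
#'
#' Relates each query transcript to the reference by a single-character
#' class code, the first matching rule in this precedence order (most
#' specific first):
#'
#' * `=` complete intron-chain match with a same-strand reference
#'   transcript (mono-exon queries: same-strand overlap with a mono-exon
#'   reference covering at least `mono_overlap_frac` of the shorter of the
#'   two);
#' * `c` query contained in a reference transcript, its intron chain a
#'   contiguous sub-chain of the reference's (mono-exon queries: contained
#'   within a single reference exon);
#' * `k` query contains a reference transcript's complete intron chain as
#'   a contiguous sub-chain of its own;
#' * `j` multi-exon query sharing at least one splice junction with a
#'   same-strand reference, chains not identical;
#' * `o` other same-strand exonic overlap;
#' * `i` query fully inside a single reference intron (same strand by
#'   default; see `intronic_same_strand`);
#' * `y` a reference gene span lies fully inside one of the query's
#'   introns (same strand);
#' * `x` exonic overlap with the reference on the opposite strand;
#' * `u` none of the above (intergenic).
#'
#' Codes `i`, `u`, `y` and `x` mark novel transcriptional loci (see
#' [is_novel()]). When several reference transcripts match at equal
#' precedence the one sharing the most junctions with the query wins, ties
#' broken by the lexicographically smallest reference identifier.
#'
#' @param query A transcript table of query (merged) transcripts.
#' @param index A `reference_index` from [build_reference_index()].
#' @param mono_overlap_frac Minimum overlap fraction (of the shorter
#'   transcript) for a mono-exon `=` call. Default 0.5.
#' @param intronic_same_strand If `TRUE` (default), `i` requires the query
#'   to be on the same strand as the surrounding reference intron;
#'   opposite-strand intron residents then fall through to `x` only if they
#'   overlap an exon, else `u`.
#' @return A tibble `transcript_id`, `class_code`, `cmp_ref` (the matched
#'   reference transcript, or for `i`/`y`/`x` the implicated reference
#'   gene; `NA` for `u`), `novel` (logical).
#' @export
assign_class_codes <- function(query, index, mono_overlap_frac = 0.5,
                               intronic_same_strand = TRUE) {
  stopifnot(inherits(index, "reference_index"))
  query <- as_transcripts(query)
  qs <- tx_summary(query)
  if (nrow(qs) == 0) {
    return(tibble::tibble(
      transcript_id = character(), class_code = character(),
      cmp_ref = character(), novel = logical()
    ))
  }
  unknown <- setdiff(unique(qs$chrom), unique(c(
    index$transcripts$chrom,
    character(0)
  )))
  if (length(unknown) > 0 && nrow(index$transcripts) > 0) {
    rlang::warn(paste0(
      "query chromosome(s) absent from reference index (classified 'u'): ",
      paste(unknown, collapse = ", ")
    ))
  }
  qi <- tx_introns(query)
  rs <- index$transcripts

  gr <- function(df) {
    GenomicRanges::GRanges(
      df$chrom, IRanges::IRanges(df$start, df$end),
      strand = df$strand
    )
  }
  q_span_gr <- gr(qs)
  q_exon_gr <- gr(query)
  q_intron_gr <- if (nrow(qi) > 0) gr(qi) else GenomicRanges::GRanges()

  # candidate hit list per rule: tibble(q = query row, ref = reference id)
  cand <- vector("list", 9)
  names(cand) <- c("=", "c", "k", "j", "o", "i", "y", "x", "u")
  empty_hits <- tibble::tibble(q = integer(), ref = character())
  for (nm in names(cand)) cand[[nm]] <- empty_hits

  if (nrow(rs) > 0) {
    # shared-junction pairs (used by "j" and for cmp_ref tie-breaking)
    shared <- empty_hits
    shared$n_shared <- integer()
    if (nrow(qi) > 0 && nrow(index$introns) > 0) {
      qkey <- tibble::tibble(
        key = paste(qi$chrom, qi$strand, qi$start, qi$end),
        q = match(qi$transcript_id, qs$transcript_id)
      )
      rkey <- tibble::tibble(
        key = paste(
          index$introns$chrom, index$introns$strand,
          index$introns$start, index$introns$end
        ),
        ref = index$introns$transcript_id
      )
      shared <- dplyr::count(
        dplyr::inner_join(qkey, rkey, by = "key", relationship = "many-to-many"),
        .data$q, .data$ref,
        name = "n_shared"
      )
    }

    # rule "=": identical chains (multi-exon)
    multi_q <- which(qs$n_exons > 1)
    if (length(multi_q) > 0) {
      eq <- dplyr::inner_join(
        tibble::tibble(
          q = multi_q,
          key = paste(qs$chrom, qs$strand, qs$chain)[multi_q]
        ),
        tibble::tibble(
          key = paste(rs$chrom, rs$strand, rs$chain)[rs$n_exons > 1],
          ref = rs$transcript_id[rs$n_exons > 1]
        ),
        by = "key", relationship = "many-to-many"
      )
      cand[["="]] <- eq[, c("q", "ref")]
    }
    # rule "=": mono-exon vs mono-exon with sufficient mutual overlap
    mono_q <- which(qs$n_exons == 1)
    mono_r <- which(rs$n_exons == 1)
    if (length(mono_q) > 0 && length(mono_r) > 0) {
      h <- suppressWarnings(GenomicRanges::findOverlaps(
        gr(qs[mono_q, ]), gr(rs[mono_r, ]),
        ignore.strand = FALSE
      ))
      if (length(h) > 0) {
        a <- mono_q[S4Vectors::queryHits(h)]
        b <- mono_r[S4Vectors::subjectHits(h)]
        ov <- pmin(qs$end[a], rs$end[b]) - pmax(qs$start[a], rs$start[b]) + 1L
        shorter <- pmin(
          qs$end[a] - qs$start[a] + 1L,
          rs$end[b] - rs$start[b] + 1L
        )
        keep <- ov >= mono_overlap_frac * shorter
        cand[["="]] <- dplyr::bind_rows(
          cand[["="]],
          tibble::tibble(q = a[keep], ref = rs$transcript_id[b[keep]])
        )
      }
    }

    # rule "c": query contained in a reference transcript
    h <- suppressWarnings(GenomicRanges::findOverlaps(
      q_span_gr, index$span_gr,
      type = "within", ignore.strand = FALSE
    ))
    if (length(h) > 0) {
      a <- S4Vectors::queryHits(h)
      b <- S4Vectors::subjectHits(h)
      multi_ok <- qs$n_exons[a] > 1 &
        is_subchain(qs$chain[a], rs$chain[b])
      cand[["c"]] <- tibble::tibble(
        q = a[multi_ok], ref = rs$transcript_id[b[multi_ok]]
      )
    }
    # mono-exon "c": query inside a single reference exon
    if (length(mono_q) > 0) {
      h <- suppressWarnings(GenomicRanges::findOverlaps(
        gr(qs[mono_q, ]), index$exon_gr,
        type = "within", ignore.strand = FALSE
      ))
      if (length(h) > 0) {
        cand[["c"]] <- dplyr::bind_rows(
          cand[["c"]],
          tibble::tibble(
            q = mono_q[S4Vectors::queryHits(h)],
            ref = index$exons$transcript_id[S4Vectors::subjectHits(h)]
          )
        )
      }
    }

    # rule "k": query contains a reference transcript's complete chain
    h <- suppressWarnings(GenomicRanges::findOverlaps(
      index$span_gr, q_span_gr,
      type = "within", ignore.strand = FALSE
    ))
    if (length(h) > 0) {
      b <- S4Vectors::queryHits(h) # reference row
      a <- S4Vectors::subjectHits(h) # query row
      ok <- rs$n_exons[b] > 1 & qs$n_exons[a] > 1 &
        is_subchain(rs$chain[b], qs$chain[a])
      cand[["k"]] <- tibble::tibble(q = a[ok], ref = rs$transcript_id[b[ok]])
    }

    # rule "j": shared junction, chains not identical
    if (nrow(shared) > 0) {
      eq_key <- paste(cand[["="]]$q, cand[["="]]$ref)
      jj <- shared[!paste(shared$q, shared$ref) %in% eq_key, ]
      cand[["j"]] <- jj[, c("q", "ref")]
    }

    # rule "o": same-strand exonic overlap
    h <- suppressWarnings(GenomicRanges::findOverlaps(q_exon_gr, index$exon_gr, ignore.strand = FALSE))
    if (length(h) > 0) {
      cand[["o"]] <- dplyr::distinct(tibble::tibble(
        q = match(
          query$transcript_id[S4Vectors::queryHits(h)],
          qs$transcript_id
        ),
        ref = index$exons$transcript_id[S4Vectors::subjectHits(h)]
      ))
    }

    # rule "i": query inside a single reference intron
    if (nrow(index$introns) > 0) {
      h <- suppressWarnings(GenomicRanges::findOverlaps(
        q_span_gr, index$intron_gr,
        type = "within", ignore.strand = !intronic_same_strand
      ))
      if (length(h) > 0) {
        ref_tx <- index$introns$transcript_id[S4Vectors::subjectHits(h)]
        cand[["i"]] <- dplyr::distinct(tibble::tibble(
          q = S4Vectors::queryHits(h),
          ref = rs$gene_id[match(ref_tx, rs$transcript_id)]
        ))
      }
    }

    # rule "y": reference gene span inside a query intron (same strand)
    if (nrow(qi) > 0 && nrow(index$genes) > 0) {
      h <- suppressWarnings(GenomicRanges::findOverlaps(
        index$gene_gr, q_intron_gr,
        type = "within", ignore.strand = FALSE
      ))
      if (length(h) > 0) {
        cand[["y"]] <- dplyr::distinct(tibble::tibble(
          q = match(
            qi$transcript_id[S4Vectors::subjectHits(h)],
            qs$transcript_id
          ),
          ref = index$genes$gene_id[S4Vectors::queryHits(h)]
        ))
      }
    }

    # rule "x": exonic overlap on the opposite strand
    h <- suppressWarnings(GenomicRanges::findOverlaps(q_exon_gr, index$exon_gr, ignore.strand = TRUE))
    if (length(h) > 0) {
      a <- S4Vectors::queryHits(h)
      b <- S4Vectors::subjectHits(h)
      opp <- query$strand[a] != index$exons$strand[b]
      ref_tx <- index$exons$transcript_id[b[opp]]
      cand[["x"]] <- dplyr::distinct(tibble::tibble(
        q = match(query$transcript_id[a[opp]], qs$transcript_id),
        ref = rs$gene_id[match(ref_tx, rs$transcript_id)]
      ))
    }
  } else {
    shared <- tibble::tibble(q = integer(), ref = character(), n_shared = integer())
  }

  # first rule with a hit wins; cmp_ref by most shared junctions, then id
  code <- rep("u", nrow(qs))
  cmp_ref <- rep(NA_character_, nrow(qs))
  assigned <- rep(FALSE, nrow(qs))
  for (nm in c("=", "c", "k", "j", "o", "i", "y", "x")) {
    hits <- cand[[nm]]
    hits <- hits[!assigned[hits$q], , drop = FALSE]
    if (nrow(hits) == 0) next
    hits$n_shared <- shared$n_shared[match(
      paste(hits$q, hits$ref),
      paste(shared$q, shared$ref)
    )]
    hits$n_shared[is.na(hits$n_shared)] <- 0L
    best <- dplyr::slice_head(
      dplyr::arrange(
        dplyr::group_by(hits, .data$q),
        dplyr::desc(.data$n_shared), .data$ref,
        .by_group = TRUE
      ),
      n = 1
    )
    best <- dplyr::ungroup(best)
    code[best$q] <- nm
    cmp_ref[best$q] <- best$ref
    assigned[best$q] <- TRUE
  }
  tibble::tibble(
    transcript_id = qs$transcript_id,
    class_code = code,
    cmp_ref = cmp_ref,
    novel = is_novel(code)
  )
}

# is `small` (an intron-chain key) a contiguous, proper-or-equal sub-chain
# of `big`? Vectorised over both arguments.
is_subchain <- function(small, big) {
  ok <- nzchar(small) & nzchar(big)
  res <- logical(length(small))
  res[ok] <- stringr::str_detect(
    paste0(";", big[ok], ";"),
    stringr::fixed(paste0(";", small[ok], ";"))
  )
  res
}

#' Is a class code novel?
#'
#' Class codes `i`, `u`, `y` and `x` mark transcripts at novel
#' transcriptional loci: they overlap no same-strand reference exons and
#' share no junctions with the reference.
#'
#' @param code A character vector of class-code symbols.
#' @return A logical vector.
#' @export
is_novel <- function(code) {
  if (!all(code %in% c("=", "j", "c", "k", "o", "i", "y", "x", "u"))) {
    rlang::abort("unknown class-code symbol")
  }
  code %in% c("i", "u", "y", "x")
}
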