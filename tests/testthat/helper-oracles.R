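# Independent straight-line oracles. These re-implement the operations by
# direct feature comparison (plain loops, no interval trees, no vectorised
# joins) so that agreement with the package's implementations is a real
# two-route check.

ora_introns <- function(ex) {
  ex <- ex[order(ex$start), ]
  k <- nrow(ex)
  if (k < 2) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  data.frame(start = ex$end[-k] + 1L, end = ex$start[-1] - 1L)
}

ora_overlap <- function(a1, a2, b1, b2) a1 <= b2 && b1 <= a2

# is chain `small` a contiguous sub-run of chain `big`? chains as data frames
ora_subchain <- function(small, big) {
  ns <- nrow(small)
  nb <- nrow(big)
  if (ns == 0 || ns > nb) {
    return(FALSE)
  }
  for (off in 0:(nb - ns)) {
    ok <- TRUE
    for (j in seq_len(ns)) {
      if (small$start[j] != big$start[off + j] || small$end[j] != big$end[off + j]) {
        ok <- FALSE
        break
      }
    }
    if (ok) {
      return(TRUE)
    }
  }
  FALSE
}

ora_chains_equal <- function(a, b) {
  nrow(a) == nrow(b) && ora_subchain(a, b)
}

# brute-force class code of one query against a list of reference
# transcripts; each transcript: list(transcript_id, gene_id, chrom, strand,
# exons = data.frame(start, end))
oracle_class_code <- function(q, refs, mono_overlap_frac = 0.5,
                              intronic_same_strand = TRUE) {
  qex <- q$exons[order(q$exons$start), ]
  qi <- ora_introns(qex)
  q_start <- min(qex$start)
  q_end <- max(qex$end)
  q_multi <- nrow(qex) > 1
  on_chrom <- Filter(function(r) r$chrom == q$chrom, refs)
  same <- Filter(function(r) r$strand == q$strand, on_chrom)
  opp <- Filter(function(r) r$strand != q$strand, on_chrom)

  # "="
  for (r in same) {
    rex <- r$exons[order(r$exons$start), ]
    if (q_multi && nrow(rex) > 1 && ora_chains_equal(qi, ora_introns(rex))) {
      return("=")
    }
    if (!q_multi && nrow(rex) == 1) {
      ov <- min(q_end, rex$end) - max(q_start, rex$start) + 1L
      shorter <- min(q_end - q_start + 1L, rex$end - rex$start + 1L)
      if (ov >= mono_overlap_frac * shorter) {
        return("=")
      }
    }
  }
  # "c"
  for (r in same) {
    rex <- r$exons[order(r$exons$start), ]
    within_span <- q_start >= min(rex$start) && q_end <= max(rex$end)
    if (q_multi) {
      if (within_span && ora_subchain(qi, ora_introns(rex))) {
        return("c")
      }
    } else {
      for (j in seq_len(nrow(rex))) {
        if (q_start >= rex$start[j] && q_end <= rex$end[j]) {
          return("c")
        }
      }
    }
  }
  # "k"
  if (q_multi) {
    for (r in same) {
      rex <- r$exons[order(r$exons$start), ]
      if (nrow(rex) > 1 &&
        min(rex$start) >= q_start && max(rex$end) <= q_end &&
        ora_subchain(ora_introns(rex), qi)) {
        return("k")
      }
    }
  }
  # "j"
  if (q_multi) {
    for (r in same) {
      ri <- ora_introns(r$exons)
      for (a in seq_len(nrow(qi))) {
        for (b in seq_len(nrow(ri))) {
          if (qi$start[a] == ri$start[b] && qi$end[a] == ri$end[b]) {
            return("j")
          }
        }
      }
    }
  }
  # "o"
  for (r in same) {
    for (a in seq_len(nrow(qex))) {
      for (b in seq_len(nrow(r$exons))) {
        if (ora_overlap(
          qex$start[a], qex$end[a], r$exons$start[b], r$exons$end[b]
        )) {
          return("o")
        }
      }
    }
  }
  # "i"
  i_candidates <- if (intronic_same_strand) same else on_chrom
  for (r in i_candidates) {
    ri <- ora_introns(r$exons)
    for (b in seq_len(nrow(ri))) {
      if (q_start >= ri$start[b] && q_end <= ri$end[b]) {
        return("i")
      }
    }
  }
  # "y": a same-strand reference gene span inside one query intron
  gene_ids <- unique(vapply(same, function(r) r$gene_id, character(1)))
  for (gid in gene_ids) {
    members <- Filter(function(r) r$gene_id == gid, same)
    g_start <- min(vapply(members, function(r) min(r$exons$start), integer(1)))
    g_end <- max(vapply(members, function(r) max(r$exons$end), integer(1)))
    for (a in seq_len(nrow(qi))) {
      if (g_start >= qi$start[a] && g_end <= qi$end[a]) {
        return("y")
      }
    }
  }
  # "x"
  for (r in opp) {
    for (a in seq_len(nrow(qex))) {
      for (b in seq_len(nrow(r$exons))) {
        if (ora_overlap(
          qex$start[a], qex$end[a], r$exons$start[b], r$exons$end[b]
        )) {
          return("x")
        }
      }
    }
  }
  "u"
}

# turn a transcript table into the oracle's reference list
refs_as_list <- function(tx) {
  tx <- as_transcripts(tx)
  lapply(split(tx, tx$transcript_id), function(d) {
    list(
      transcript_id = d$transcript_id[1], gene_id = d$gene_id[1],
      chrom = d$chrom[1], strand = d$strand[1],
      exons = data.frame(start = d$start, end = d$end)
    )
  })
}

# ---- alignment oracle ------------------------------------------------------

# global alignment score, affine gaps costing open + ext * length (a gap of
# length L costs open + L * ext), BLOSUM62 substitution scores
oracle_nw_score <- function(p1, p2, open = 11, ext = 1) {
  sub <- get_blosum62()
  a <- strsplit(p1, "")[[1]]
  b <- strsplit(p2, "")[[1]]
  n <- length(a)
  m <- length(b)
  neg <- -1e9
  M <- matrix(neg, n + 1, m + 1)
  X <- matrix(neg, n + 1, m + 1) # gap in p2 (consume a)
  Y <- matrix(neg, n + 1, m + 1) # gap in p1 (consume b)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -open - ext * (i - 1)
  for (j in 2:(m + 1)) Y[1, j] <- -open - ext * (j - 1)
  for (i in seq_len(n + 1)[-1]) {
    for (j in seq_len(m + 1)[-1]) {
      s <- sub[a[i - 1], b[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

get_blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

# ---- coding-feature oracles ------------------------------------------------

oracle_longest_orf <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  best <- NULL
  for (frame in 1:3) {
    pos <- frame
    while (pos + 2 <= n) {
      if (substring(seq, pos, pos + 2) == "ATG") {
        p <- pos + 3
        while (p + 2 <= n) {
          codon <- substring(seq, p, p + 2)
          if (codon %in% stops) {
            len <- p + 2 - pos + 1
            if (is.null(best) || len > best$nt_length) {
              best <- list(frame = frame, start = pos, nt_length = len)
            }
            break
          }
          p <- p + 3
        }
      }
      pos <- pos + 3
    }
  }
  best
}

oracle_fickett <- function(seq) {
  p <- fickett_parameters()
  ch <- strsplit(toupper(seq), "")[[1]]
  total <- sum(ch %in% c("A", "C", "G", "T"))
  score <- 0
  for (b in c("A", "C", "G", "T")) {
    cnt <- c(0, 0, 0)
    for (i in seq_along(ch)) {
      if (ch[i] == b) {
        cnt[(i - 1) %% 3 + 1] <- cnt[(i - 1) %% 3 + 1] + 1
      }
    }
    posv <- max(cnt) / (min(cnt) + 1)
    contv <- sum(cnt) / total
    pi <- 1
    while (posv < p$position_threshold[pi]) pi <- pi + 1
    ci <- 1
    while (contv < p$content_threshold[ci]) ci <- ci + 1
    score <- score + p$position_prob[b, pi] * p$position_weight[b] +
      p$content_prob[b, ci] * p$content_weight[b]
  }
  score
}

# pI by an independent root finder (uniroot) over the same pKa constants
oracle_pi <- function(protein) {
  pk <- pi_pka_set()
  aa <- strsplit(toupper(protein), "")[[1]]
  charge <- function(ph) {
    pos <- 1 / (1 + 10^(ph - pk$nterm))
    for (r in names(pk$positive)) {
      pos <- pos + sum(aa == r) / (1 + 10^(ph - pk$positive[[r]]))
    }
    neg <- 1 / (1 + 10^(pk$cterm - ph))
    for (r in names(pk$negative)) {
      neg <- neg + sum(aa == r) / (1 + 10^(pk$negative[[r]] - ph))
    }
    pos - neg
  }
  stats::uniroot(charge, c(0, 14), tol = 1e-9)$root
}

# ---- positional-category oracle --------------------------------------------

oracle_nc_category <- function(q, coding) {
  qex <- q$exons[order(q$exons$start), ]
  q_start <- min(qex$start)
  q_end <- max(qex$end)
  for (r in coding) {
    if (r$chrom != q$chrom) next
    ri <- ora_introns(r$exons)
    for (b in seq_len(nrow(ri))) {
      if (q_start >= ri$start[b] && q_end <= ri$end[b]) {
        return("intronic")
      }
    }
  }
  for (r in coding) {
    if (r$chrom != q$chrom || r$strand != q$strand) next
    for (a in seq_len(nrow(qex))) {
      for (b in seq_len(nrow(r$exons))) {
        if (ora_overlap(qex$start[a], qex$end[a], r$exons$start[b], r$exons$end[b])) {
          return("sense_overlap")
        }
      }
    }
  }
  for (r in coding) {
    if (r$chrom != q$chrom || r$strand == q$strand) next
    for (a in seq_len(nrow(qex))) {
      for (b in seq_len(nrow(r$exons))) {
        if (ora_overlap(qex$start[a], qex$end[a], r$exons$start[b], r$exons$end[b])) {
          return("antisense")
        }
      }
    }
  }
  "intergenic"
}

# ---- gene-category oracle --------------------------------------------------

# independent re-evaluation of the diff rules from raw coordinates
oracle_gene_category <- function(transcripts, old_refs) {
  # transcripts: list of list(exons, strand, chrom, class_code)
  old_junctions <- do.call(rbind, lapply(old_refs, function(r) {
    ri <- ora_introns(r$exons)
    if (nrow(ri) == 0) {
      return(NULL)
    }
    data.frame(chrom = r$chrom, strand = r$strand, start = ri$start, end = ri$end)
  }))
  codes <- vapply(transcripts, function(t) t$class_code, character(1))
  flipped <- FALSE
  for (t in transcripts) {
    t_start <- min(t$exons$start)
    t_end <- max(t$exons$end)
    opp_overlap <- FALSE
    for (gid in unique(vapply(old_refs, function(r) r$gene_id, character(1)))) {
      members <- Filter(function(r) r$gene_id == gid, old_refs)
      if (members[[1]]$chrom != t$chrom || members[[1]]$strand == t$strand) next
      g_start <- min(vapply(members, function(r) min(r$exons$start), integer(1)))
      g_end <- max(vapply(members, function(r) max(r$exons$end), integer(1)))
      if (ora_overlap(t_start, t_end, g_start, g_end)) {
        opp_overlap <- TRUE
      }
    }
    junction_reuse <- FALSE
    ti <- ora_introns(t$exons)
    if (!is.null(old_junctions) && nrow(ti) > 0) {
      for (a in seq_len(nrow(ti))) {
        hit <- any(
          old_junctions$chrom == t$chrom &
            old_junctions$start == ti$start[a] &
            old_junctions$end == ti$end[a]
        )
        if (hit) junction_reuse <- TRUE
      }
    }
    if (opp_overlap && junction_reuse) flipped <- TRUE
  }
  if (flipped) {
    return("flipped")
  }
  if (all(codes %in% c("u", "x", "i", "y"))) {
    return("novel")
  }
  if (all(codes == "=")) {
    return("unchanged")
  }
  if (any(codes == "=") && any(codes == "j")) {
    return("novel_splice_variant")
  }
  shares <- vapply(transcripts, function(t) {
    ti <- ora_introns(t$exons)
    if (is.null(old_junctions) || nrow(ti) == 0) {
      return(FALSE)
    }
    any(vapply(seq_len(nrow(ti)), function(a) {
      any(
        old_junctions$chrom == t$chrom &
          old_junctions$strand == t$strand &
          old_junctions$start == ti$start[a] &
          old_junctions$end == ti$end[a]
      )
    }, logical(1)))
  }, logical(1))
  if (!any(codes == "=") && !any(shares)) {
    return("all_junctions_differ")
  }
  if (!any(codes == "=") && any(shares)) {
    return("all_transcripts_differ")
  }
  "uncategorized"
}
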