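#' Find the longest forward-frame open reading frame
#'
#' Scans the three forward reading frames of a spliced transcript sequence
#' (never the reverse complement — assembled transcripts are already
#' strand-corrected) for ATG-initiated ORFs with an obligatory stop codon
#' and no internal stop. Returns the longest; ties break by frame order
#' 1 < 2 < 3, then by smaller start. Codons containing `N` never match the
#' start or a stop codon.
#'
#' @param seq A single DNA sequence (character scalar, case-insensitive).
#' @return A one-row tibble with columns `frame` (1, 2 or 3), `start` and
#'   `end` (1-based positions in `seq` of the first base of the ATG and the
#'   last base of the stop codon), `nt_length` (`end - start + 1`, a
#'   multiple of 3 including the stop) and `protein` (amino acids excluding
#'   the stop). A zero-row tibble if no ATG...stop ORF exists in any
#'   forward frame.
#' @examples
#' find_longest_orf("ATGAAATGA") # frame 1, 9 nt, protein "MK"
#' @export
find_longest_orf <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  seq <- toupper(seq)
  empty <- tibble::tibble(
    frame = integer(0), start = integer(0), end = integer(0),
    nt_length = integer(0), protein = character(0)
  )
  n <- nchar(seq)
  if (n < 6) {
    return(empty)
  }
  best <- NULL
  stops <- c("TAA", "TAG", "TGA")
  for (frame in 1:3) {
    n_codons <- (n - frame + 1L) %/% 3L
    if (n_codons < 2) next
    pos <- frame + 3L * (seq_len(n_codons) - 1L)
    codons <- substring(seq, pos, pos + 2L)
    is_start <- codons == "ATG"
    is_stop <- codons %in% stops
    if (!any(is_start) || !any(is_stop)) next
    stop_idx <- which(is_stop)
    start_idx <- which(is_start)
    # for each start codon, the first stop at or after it
    nxt <- stop_idx[findInterval(start_idx - 1L, stop_idx) + 1L]
    ok <- !is.na(nxt)
    if (!any(ok)) next
    start_idx <- start_idx[ok]
    nxt <- nxt[ok]
    len <- (nxt - start_idx + 1L) * 3L
    i <- which.max(len) # ties: earliest start wins (which.max takes first)
    cand <- list(
      frame = frame, start = pos[start_idx[i]],
      end = pos[nxt[i]] + 2L, nt_length = len[i]
    )
    if (is.null(best) || cand$nt_length > best$nt_length) {
      best <- cand
    }
  }
  if (is.null(best)) {
    return(empty)
  }
  orf_seq <- substring(seq, best$start, best$end - 3L)
  tibble::tibble(
    frame = best$frame, start = best$start, end = best$end,
    nt_length = best$nt_length, protein = translate_dna(orf_seq)
  )
}

# translate a DNA string (length a multiple of 3) to amino acids;
# codons with N or other ambiguity translate to X
translate_dna <- function(seq) {
  if (nchar(seq) == 0) {
    return("")
  }
  pos <- seq(1L, nchar(seq), by = 3L)
  codons <- substring(seq, pos, pos + 2L)
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Fickett TESTCODE lookup tables
#'
#' The published TESTCODE parameters: for each base, ten probability values
#' indexed by thresholds on the position parameter (the asymmetry of base
#' usage across the three codon positions) and on the content parameter
#' (overall base composition), plus the weight each of the eight
#' probabilities receives in the combined score. Exposed so that
#' independent reimplementations can share the same constants.
#'
#' @return A list with elements `position_prob`, `position_weight`,
#'   `position_threshold`, `content_prob`, `content_weight`,
#'   `content_threshold`.
#' @export
fickett_parameters <- function() {
  list(
    position_prob = rbind(
      A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
      C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
      G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
      T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09)
    ),
    position_weight = c(A = 0.26, C = 0.18, G = 0.31, T = 0.33),
    position_threshold = c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0.0),
    content_prob = rbind(
      A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
      C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.58, 0.44, 0.39, 0.31),
      G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
      T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58)
    ),
    content_weight = c(A = 0.11, C = 0.12, G = 0.15, T = 0.14),
    content_threshold = c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0.0)
  )
}

#' Fickett TESTCODE coding-potential score
#'
#' Computes the classic TESTCODE statistic: for each base, the asymmetry of
#' its usage across the three codon-frame positions (position parameter)
#' and its overall frequency (content parameter) are mapped to
#' probabilities through the published lookup tables and combined with the
#' published weights. Higher values indicate protein-coding character;
#' the conventional decision threshold is 0.95.
#'
#' @param seq A single DNA sequence of at least 12 nt (200 nt or more is
#'   recommended for a stable estimate). Case-insensitive; bases other than
#'   A/C/G/T are ignored in the counts.
#' @return A single finite numeric score.
#' @export
fickett_score <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  seq <- toupper(seq)
  if (nchar(seq) < 12) {
    rlang::abort("fickett_score() needs a sequence of at least 12 nt")
  }
  p <- fickett_parameters()
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  phase <- (seq_along(chars) - 1L) %% 3L
  score <- 0
  total <- sum(chars %in% c("A", "C", "G", "T"))
  if (total == 0) {
    rlang::abort("fickett_score() needs at least one unambiguous base")
  }
  for (base in c("A", "C", "G", "T")) {
    hits <- chars == base
    counts <- vapply(0:2, function(ph) sum(hits & phase == ph), numeric(1))
    position_value <- max(counts) / (min(counts) + 1)
    content_value <- sum(counts) / total
    pi <- which(position_value >= p$position_threshold)[1]
    ci <- which(content_value >= p$content_threshold)[1]
    score <- score +
      p$position_prob[base, pi] * p$position_weight[base] +
      p$content_prob[base, ci] * p$content_weight[base]
  }
  score
}

#' pKa constants used for isoelectric-point calculation
#'
#' A Bjellqvist-style fixed pKa set for the two termini and the seven
#' ionizable side chains, shipped in one place so that independent checks
#' can use identical constants.
#'
#' @return A named list with elements `nterm`, `cterm`, `positive` (named
#'   vector: H, K, R) and `negative` (named vector: D, E, C, Y).
#' @export
pi_pka_set <- function() {
  list(
    nterm = 7.50,
    cterm = 3.55,
    positive = c(H = 5.98, K = 10.00, R = 12.00),
    negative = c(D = 4.05, E = 4.45, C = 9.00, Y = 10.00)
  )
}

#' Isoelectric point of a protein
#'
#' Solves for the pH at which the Henderson-Hasselbalch net charge of the
#' protein (N-terminus, C-terminus, and the ionizable side chains D, E, C,
#' Y, H, K, R) vanishes, by bisection on \[0, 14\] to |charge| < 1e-4.
#'
#' @param protein A non-empty amino-acid string over the 20-letter alphabet.
#' @return The isoelectric point, a numeric value in \[0, 14\].
#' @export
isoelectric_point <- function(protein) {
  stopifnot(is.character(protein), length(protein) == 1)
  protein <- toupper(protein)
  if (nchar(protein) == 0) {
    rlang::abort("isoelectric_point() needs a non-empty protein")
  }
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  valid <- strsplit("ACDEFGHIKLMNPQRSTVWY", "", fixed = TRUE)[[1]]
  if (!all(aa %in% valid)) {
    rlang::abort(paste0(
      "invalid amino-acid letter(s): ",
      paste(unique(aa[!aa %in% valid]), collapse = ", ")
    ))
  }
  pk <- pi_pka_set()
  pos_counts <- table(factor(aa, levels = names(pk$positive)))
  neg_counts <- table(factor(aa, levels = names(pk$negative)))
  net_charge <- function(ph) {
    pos <- 1 / (1 + 10^(ph - pk$nterm)) +
      sum(as.numeric(pos_counts) / (1 + 10^(ph - pk$positive)))
    neg <- 1 / (1 + 10^(pk$cterm - ph)) +
      sum(as.numeric(neg_counts) / (1 + 10^(pk$negative - ph)))
    pos - neg
  }
  lo <- 0
  hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    q <- net_charge(mid)
    if (abs(q) < 1e-4 || (hi - lo) < 1e-9) {
      return(mid)
    }
    if (q > 0) lo <- mid else hi <- mid
  }
}

#' Classify transcripts as coding or noncoding from ORF features
#'
#' For each spliced transcript sequence, finds the longest forward-frame
#' ORF and computes the feature set the coding/noncoding decision uses: ORF
#' length, ORF coverage (ORF length over spliced length), the Fickett
#' TESTCODE score, and the isoelectric point of the predicted protein. A
#' transcript is called coding when its ORF is at least `min_orf` nt, or
#' when a shorter ORF of at least `min_orf_supported` nt covers at least
#' half the transcript and the Fickett score reaches `fickett_cutoff`.
#' The rule is transparent and exact on sequences with planted ORFs; no
#' trained classifier weights are involved.
#'
#' @param seqs A data frame with columns `transcript_id` and `sequence`
#'   (as returned by [spliced_sequence()]).
#' @param min_orf ORF length (nt, including the stop codon) that is
#'   sufficient on its own for a coding call. Default 300.
#' @param min_orf_supported Minimum ORF length for the supported clause.
#'   Default 120.
#' @param min_coverage Minimum ORF coverage for the supported clause.
#'   Default 0.5.
#' @param fickett_cutoff Minimum Fickett score for the supported clause.
#'   Default 0.95, the conventional TESTCODE decision threshold.
#' @return A tibble with one row per transcript: `transcript_id`, `coding`
#'   (logical), `orf_start`, `orf_nt_length`, `orf_coverage`,
#'   `fickett_score`, `isoelectric_point`, `protein`. ORF columns are `NA`
#'   (and `coding` is `FALSE`) when no forward-frame ORF exists.
#' @export
classify_coding <- function(seqs, min_orf = 300L, min_orf_supported = 120L,
                            min_coverage = 0.5, fickett_cutoff = 0.95) {
  seqs <- tibble::as_tibble(seqs)
  stopifnot(all(c("transcript_id", "sequence") %in% names(seqs)))
  if (nrow(seqs) == 0) {
    return(tibble::tibble(
      transcript_id = character(), coding = logical(),
      orf_start = integer(), orf_nt_length = integer(),
      orf_coverage = numeric(), fickett_score = numeric(),
      isoelectric_point = numeric(), protein = character()
    ))
  }
  rows <- purrr::map2(seqs$transcript_id, seqs$sequence, function(id, s) {
    orf <- find_longest_orf(s)
    fs <- if (nchar(s) >= 12) fickett_score(s) else NA_real_
    if (nrow(orf) == 0) {
      return(tibble::tibble(
        transcript_id = id, coding = FALSE,
        orf_start = NA_integer_, orf_nt_length = NA_integer_,
        orf_coverage = NA_real_, fickett_score = fs,
        isoelectric_point = NA_real_, protein = NA_character_
      ))
    }
    coverage <- orf$nt_length / nchar(s)
    has_x <- grepl("X", orf$protein, fixed = TRUE)
    coding <- orf$nt_length >= min_orf ||
      (orf$nt_length >= min_orf_supported && coverage >= min_coverage &&
        !is.na(fs) && fs >= fickett_cutoff)
    tibble::tibble(
      transcript_id = id, coding = coding,
      orf_start = orf$start, orf_nt_length = orf$nt_length,
      orf_coverage = coverage, fickett_score = fs,
      isoelectric_point = if (has_x || nchar(orf$protein) == 0) {
        NA_real_
      } else {
        isoelectric_point(orf$protein)
      },
      protein = orf$protein
    )
  })
  dplyr::bind_rows(rows)
}
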