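#' Call the largest complete ORF of a transcript under a genetic code
#'
#' Scans all six reading frames. Within a frame, candidate ORFs run from the
#' first ATG following an in-frame stop (or following the frame start) to the
#' next in-frame stop. Because ciliate lineages reassign stop codons, the
#' active genetic code determines where ORFs terminate: a TAA that ends an
#' ORF under the standard code is read through as glutamine under table 6.
#'
#' Only the single largest ORF of the transcript is returned, mirroring
#' transcriptome curation where each assembled transcript contributes at most
#' one coding sequence. Ties are broken by frame order (+1, +2, +3, -1, -2,
#' -3), then by the 5'-most start on the reading strand. ORFs shorter than
#' `min_aa` amino acids are dropped. The terminal stop codon is excluded from
#' the reported CDS, so `nchar(nt) == 3 * nchar(protein)`.
#'
#' @param transcript character scalar; IUPAC nucleotide symbols only.
#' @param code a [genetic_code()] or id (default 1).
#' @param min_aa minimum protein length retained (default 200).
#' @param complete_only if `TRUE` (default) an ORF needs both an ATG start
#'   and an in-frame stop; if `FALSE`, ORFs truncated by the transcript edge
#'   (missing start and/or stop) are also considered.
#' @param transcript_id,taxon identifiers copied into the output.
#' @return data.frame with zero or one row and columns `record_id`, `taxon`,
#'   `transcript_id`, `frame`, `start`, `end` (0-based half-open coordinates
#'   on the forward strand of the transcript), `nt`, `protein`.
#' @export
call_orfs <- function(transcript, code = 1, min_aa = 200,
                      complete_only = TRUE,
                      transcript_id = "transcript", taxon = NA_character_) {
  code <- genetic_code(code)
  empty <- orf_record_frame()
  if (length(transcript) != 1L || is.na(transcript)) stop("transcript must be a single string")
  transcript <- toupper(transcript)
  if (nchar(transcript) == 0L) return(empty)
  bad <- regexpr("[^ACGTURYSWKMBDHVN]", transcript)
  if (bad > 0L) {
    stop("non-IUPAC symbol '", substr(transcript, bad, bad),
         "' at position ", bad, " in ", transcript_id)
  }
  transcript <- gsub("U", "T", transcript, fixed = TRUE)

  cands <- frame_orf_candidates(transcript, code, complete_only)
  if (nrow(cands) == 0L) return(empty)
  cands <- cands[cands$aa_len >= min_aa, , drop = FALSE]
  if (nrow(cands) == 0L) return(empty)
  # largest; ties by frame order then 5'-most start on the reading strand
  ord <- order(-cands$aa_len, cands$frame_rank, cands$strand_start)
  best <- cands[ord[1L], , drop = FALSE]

  nt <- best$cds
  protein <- translate_cds(nt, code)
  data.frame(
    record_id = paste0(transcript_id, "_orf1"),
    taxon = taxon,
    transcript_id = transcript_id,
    frame = best$frame_label,
    start = best$fwd_start,
    end = best$fwd_end,
    nt = nt,
    protein = protein,
    stringsAsFactors = FALSE
  )
}

orf_record_frame <- function() {
  data.frame(record_id = character(), taxon = character(),
             transcript_id = character(), frame = character(),
             start = integer(), end = integer(),
             nt = character(), protein = character(),
             stringsAsFactors = FALSE)
}

# All candidate ORFs over the six frames (before the min length / largest
# selection). Positions are converted back to forward-strand coordinates.
frame_orf_candidates <- function(transcript, code, complete_only) {
  n <- nchar(transcript)
  rc <- revcomp(transcript)
  out <- vector("list", 6L)
  frames <- data.frame(label = c("+1", "+2", "+3", "-1", "-2", "-3"),
                       rank = 1:6,
                       offset = c(0L, 1L, 2L, 0L, 1L, 2L),
                       rev = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
                       stringsAsFactors = FALSE)
  for (i in seq_len(6L)) {
    seqi <- if (frames$rev[i]) rc else transcript
    off <- frames$offset[i]
    ncod <- (n - off) %/% 3L
    if (ncod < 1L) next
    starts <- off + 1L + 3L * (seq_len(ncod) - 1L)
    cods <- substring(seqi, starts, starts + 2L)
    is_stop <- cods %in% code$stop_codons
    is_atg <- cods == "ATG"
    segs <- orf_segments(is_stop, is_atg, complete_only)
    if (nrow(segs) == 0L) next
    # segment positions are codon indices [from, to] of the CDS (stop excluded)
    res <- lapply(seq_len(nrow(segs)), function(k) {
      from <- segs$from[k]; to <- segs$to[k]
      s_nt <- starts[from]                 # 1-based on reading strand
      e_nt <- starts[to] + 2L
      cds <- substr(seqi, s_nt, e_nt)
      if (frames$rev[i]) {
        fwd_start <- n - e_nt          # 0-based half-open on forward strand
        fwd_end <- n - s_nt + 1L
      } else {
        fwd_start <- s_nt - 1L
        fwd_end <- e_nt
      }
      data.frame(frame_label = frames$label[i], frame_rank = frames$rank[i],
                 strand_start = s_nt, fwd_start = fwd_start, fwd_end = fwd_end,
                 aa_len = to - from + 1L, cds = cds, stringsAsFactors = FALSE)
    })
    out[[i]] <- do.call(rbind, res)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    return(data.frame(frame_label = character(), frame_rank = integer(),
                      strand_start = integer(), fwd_start = integer(),
                      fwd_end = integer(), aa_len = integer(),
                      cds = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Codon-index segments of candidate ORFs within one frame.
orf_segments <- function(is_stop, is_atg, complete_only) {
  ncod <- length(is_stop)
  stop_pos <- which(is_stop)
  seg_starts <- c(1L, stop_pos + 1L)
  seg_ends <- c(stop_pos - 1L, ncod)       # last codon before the stop / frame end
  has_stop <- c(rep(TRUE, length(stop_pos)), FALSE)
  keep <- seg_starts <= seg_ends
  seg_starts <- seg_starts[keep]; seg_ends <- seg_ends[keep]
  has_stop <- has_stop[keep]
  res <- data.frame(from = integer(), to = integer())
  for (k in seq_along(seg_starts)) {
    a <- seg_starts[k]; b <- seg_ends[k]
    atg_in <- which(is_atg[a:b])
    from <- if (length(atg_in)) a + atg_in[1L] - 1L else NA_integer_
    if (complete_only) {
      if (!has_stop[k] || is.na(from)) next
    } else {
      # transcript-edge ORFs: allow a missing ATG only at the frame start
      if (is.na(from)) {
        if (k == 1L) from <- a else next
      }
    }
    res <- rbind(res, data.frame(from = from, to = b))
  }
  res
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Collapse putative allelic variants by greedy identity clustering
#'
#' Transcriptome assemblies of ciliate macronuclear genomes typically retain
#' both alleles of a locus as near-identical contigs. This collapses them by
#' greedy longest-first clustering: sequences are visited by decreasing
#' length (ties by id), and each joins the first existing cluster whose
#' founder aligns to it at `>= identity` over the full length of the shorter
#' sequence; otherwise it founds a new cluster. Cluster founders are the
#' representatives, so a representative is never shorter than any member.
#'
#' Identity is matches / alignment length over the aligned span of the
#' shorter sequence; gaps and ambiguous bases count as mismatches. The
#' shorter sequence is aligned end-to-end against the longer one
#' (global on the shorter, local on the longer), so the span of the shorter
#' sequence is always fully covered, satisfying the default
#' `cover_shorter = 1` contract.
#'
#' @param orfs data.frame with columns `record_id` and `nt` (one taxon's ORFs).
#' @param identity minimum identity fraction in (0, 1], default 0.97.
#' @param cover_shorter required coverage of the shorter sequence (the
#'   alignment strategy always covers it fully; values < 1 are accepted and
#'   behave conservatively).
#' @return list with `representatives` (subset of `orfs` rows) and
#'   `clusters` (data.frame `representative_id`, `member_id`).
#' @export
dedupe_allelic_variants <- function(orfs, identity = 0.97, cover_shorter = 1.00) {
  if (!is.numeric(identity) || identity <= 0 || identity > 1) {
    stop("identity must be in (0, 1]")
  }
  stopifnot(is.data.frame(orfs), all(c("record_id", "nt") %in% names(orfs)))
  if (nrow(orfs) == 0L) {
    return(list(representatives = orfs,
                clusters = data.frame(representative_id = character(),
                                      member_id = character())))
  }
  ord <- order(-nchar(orfs$nt), orfs$record_id)
  orfs <- orfs[ord, , drop = FALSE]
  rep_idx <- integer(0)
  assign_rep <- character(nrow(orfs))
  for (i in seq_len(nrow(orfs))) {
    joined <- FALSE
    for (r in rep_idx) {
      idn <- nt_identity(orfs$nt[i], orfs$nt[r])
      if (idn >= identity) {
        assign_rep[i] <- orfs$record_id[r]
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      rep_idx <- c(rep_idx, i)
      assign_rep[i] <- orfs$record_id[i]
    }
  }
  list(representatives = orfs[rep_idx, , drop = FALSE],
       clusters = data.frame(representative_id = assign_rep,
                             member_id = orfs$record_id,
                             stringsAsFactors = FALSE))
}

# Identity of the shorter sequence aligned end-to-end within the longer.
# Ambiguity codes are masked to N first and never count as matches.
nt_identity <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  a <- gsub("[^ACGT]", "N", toupper(a))
  b <- gsub("[^ACGT]", "N", toupper(b))
  mat <- nt_score_matrix()
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global-local",
                                       substitutionMatrix = mat,
                                       gapOpening = 5, gapExtension = 2)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  ps <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ok <- pa == ps & pa %in% c("A", "C", "G", "T")
  sum(ok) / length(pa)
}

nt_score_matrix <- function() {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(-1, 5, 5, dimnames = list(letters, letters))
  diag(m) <- 1
  m["N", "N"] <- -1
  m
}
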