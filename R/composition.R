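#' Codon-composition statistics: GC3s and Wright's effective number of codons
#'
#' GC3s is the G+C fraction at third positions of codons belonging to
#' four-fold degenerate codon boxes of the active genetic code (boxes whose
#' four third-position variants all encode the same amino acid). ENc is
#' Wright's effective number of codons, generalised so that degeneracy
#' classes are recomputed for the active code - under the ciliate code
#' (table 6) glutamine becomes four-fold degenerate and the theoretical
#' maximum rises to the code's sense-codon count.
#'
#' For each amino acid `a` with `k >= 2` synonymous codons and total usage
#' `n`, codon homozygosity is estimated as `F_a = (n * sum(p_i^2) - 1) / (n - 1)`
#' with `p_i` the usage proportions. Class averages `F_k` over observed
#' amino acids give `ENc = N_1 + sum_k N_k / F_k`, with `N_k` the number of
#' amino acids of degeneracy `k` under the code. Amino acids with fewer than
#' two observations or non-positive `F_a` are treated as unobserved; a class
#' with no observed amino acid has its average imputed from the nearest
#' observed classes (Wright's convention, e.g. `F_3` from the mean of `F_2`
#' and `F_4`). The estimate is clamped to the code's theoretical maximum.
#'
#' @param orf either an ORF record data.frame row (column `nt`) or a CDS
#'   string; length must be divisible by 3 and free of internal stops.
#' @param code a [genetic_code()] or id.
#' @return list of class `composition_stats`: `record_id`, `gc3s`, `enc`,
#'   `n_codons_used`, `f_bar` (named per degeneracy class present).
#' @export
composition_stats <- function(orf, code = 1) {
  code <- genetic_code(code)
  if (is.data.frame(orf)) {
    cds <- orf$nt[1L]
    record_id <- if ("record_id" %in% names(orf)) orf$record_id[1L] else NA_character_
  } else {
    cds <- orf
    record_id <- NA_character_
  }
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length not divisible by 3")
  cods <- substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
  if (any(cods %in% code$stop_codons)) {
    stop("internal stop codon in CDS; composition stats are defined on curated CDS only")
  }
  cods <- cods[cods %in% code$sense_codons]   # ambiguous codons excluded
  counts <- table(factor(cods, levels = code$sense_codons))

  # GC3s over four-fold boxes
  boxes <- fourfold_boxes(code)
  in_box <- substr(names(counts), 1L, 2L) %in% boxes
  third <- substr(names(counts), 3L, 3L)
  n4 <- sum(counts[in_box])
  gc3s <- if (n4 > 0) sum(counts[in_box & third %in% c("G", "C")]) / n4 else NA_real_

  enc <- wright_enc(counts, code)
  structure(list(record_id = record_id, gc3s = gc3s, enc = enc$enc,
                 n_codons_used = length(cods), f_bar = enc$f_bar),
            class = "composition_stats")
}

# Wright's ENc from sense-codon usage counts.
wright_enc <- function(counts, code) {
  classes <- degeneracy_classes(code)
  ks <- as.integer(names(classes))
  n1 <- if ("1" %in% names(classes)) length(classes[["1"]]) else 0L
  aa_of <- code$map[names(counts)]
  f_bar <- stats::setNames(rep(NA_real_, length(ks)), names(classes))
  for (kc in names(classes)) {
    k <- as.integer(kc)
    if (k < 2L) next
    fs <- c()
    for (aa in classes[[kc]]) {
      cnt <- counts[aa_of == aa]
      ntot <- sum(cnt)
      if (ntot < 2) next
      p <- as.numeric(cnt) / ntot
      fa <- (ntot * sum(p^2) - 1) / (ntot - 1)
      if (fa > 0) fs <- c(fs, fa)
    }
    if (length(fs)) f_bar[kc] <- mean(fs)
  }
  multi <- names(f_bar)[as.integer(names(f_bar)) >= 2L]
  if (all(is.na(f_bar[multi]))) {
    return(list(enc = NA_real_, f_bar = f_bar))
  }
  # impute missing class averages from the nearest observed classes
  kv <- as.integer(multi)
  for (kc in multi) {
    if (!is.na(f_bar[kc])) next
    k <- as.integer(kc)
    obs <- multi[!is.na(f_bar[multi])]
    below <- obs[as.integer(obs) < k]
    above <- obs[as.integer(obs) > k]
    nb <- if (length(below)) f_bar[below[length(below)]] else NA_real_
    na_ <- if (length(above)) f_bar[above[1L]] else NA_real_
    f_bar[kc] <- mean(c(nb, na_), na.rm = TRUE)
  }
  enc <- n1
  for (kc in multi) enc <- enc + length(classes[[kc]]) / f_bar[kc]
  enc <- min(enc, length(code$sense_codons))
  list(enc = enc, f_bar = f_bar)
}

#' @export
print.composition_stats <- function(x, ...) {
  cat(sprintf("composition_stats: %s  GC3s=%.4f  ENc=%.3f  (%d codons)\n",
              x$record_id, x$gc3s, x$enc, x$n_codons_used))
  invisible(x)
}

#' Composition statistics for a table of ORFs
#'
#' @param orfs data.frame with `record_id`, `nt` (and optionally `taxon`).
#' @param code a [genetic_code()] or id.
#' @return data.frame `record_id`, `taxon`, `n_codons`, `gc3s`, `enc`.
#' @export
composition_table <- function(orfs, code = 1) {
  code <- genetic_code(code)
  rows <- lapply(seq_len(nrow(orfs)), function(i) {
    st <- composition_stats(orfs[i, , drop = FALSE], code)
    data.frame(record_id = orfs$record_id[i],
               taxon = if ("taxon" %in% names(orfs)) orfs$taxon[i] else NA_character_,
               n_codons = st$n_codons_used, gc3s = st$gc3s, enc = st$enc,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    return(data.frame(record_id = character(), taxon = character(),
                      n_codons = integer(), gc3s = numeric(), enc = numeric()))
  }
  do.call(rbind, rows)
}

#' Percentile band of a reference GC3s distribution
#'
#' Candidate lineage-specific ORFs are compared against the composition of a
#' conserved-gene reference set: bounds are the `lower`/`upper` percentiles
#' (default 10 and 90) of the reference GC3s values, computed by linear
#' interpolation between order statistics.
#'
#' @param reference numeric vector of reference GC3s values (nonempty).
#' @param lower,upper percentiles in `[0, 100]`.
#' @return list of class `percentile_band`: `lower_pct`, `upper_pct`,
#'   `lower`, `upper`, `n_reference`.
#' @export
percentile_band <- function(reference, lower = 10, upper = 90) {
  if (length(reference) == 0L || all(is.na(reference))) {
    stop("reference GC3s set must be nonempty")
  }
  if (lower < 0 || upper > 100 || lower > upper) stop("invalid percentiles")
  qs <- stats::quantile(reference, probs = c(lower, upper) / 100,
                        na.rm = TRUE, names = FALSE, type = 7)
  structure(list(lower_pct = lower, upper_pct = upper,
                 lower = qs[1L], upper = qs[2L],
                 n_reference = sum(!is.na(reference))),
            class = "percentile_band")
}

#' Filter candidate ORFs by a reference GC3s band
#'
#' Keeps candidates whose GC3s lies inside the closed interval
#' `[band$lower, band$upper]`. Misidentified ORFs (contaminants, food
#' organisms) tend to carry a codon composition unlike the host's strongly
#' skewed GC3s, so this screen removes most of them without any database
#' search. Candidates with undefined GC3s (no four-fold codons) are
#' discarded with their own reason.
#'
#' @param candidates data.frame as returned by [composition_table()].
#' @param band a [percentile_band()]; alternatively pass `reference` to
#'   build the default 10-90 band.
#' @param reference optional numeric vector used when `band` is missing.
#' @param enc_band optional length-2 numeric: absolute ENc bounds applied in
#'   addition to the GC3s band. The default (`NULL`) keeps the retention
#'   rule on GC3s only; ENc is reported but not filtered.
#' @return list with `kept` and `discarded` data.frames; `discarded` gains a
#'   `reason` column (`gc3s_below`, `gc3s_above`, `gc3s_undefined`,
#'   `enc_out_of_band`).
#' @export
composition_band_filter <- function(candidates, band = NULL, reference = NULL,
                                    enc_band = NULL) {
  if (is.null(band)) {
    if (is.null(reference)) stop("either band or reference must be supplied")
    band <- percentile_band(reference)
  }
  g <- candidates$gc3s
  undef <- is.na(g)
  below <- !undef & g < band$lower
  above <- !undef & g > band$upper
  keep <- !undef & !below & !above
  reason <- ifelse(undef, "gc3s_undefined",
                   ifelse(below, "gc3s_below",
                          ifelse(above, "gc3s_above", "")))
  if (!is.null(enc_band)) {
    stopifnot(length(enc_band) == 2, enc_band[1] <= enc_band[2])
    enc_bad <- keep & (is.na(candidates$enc) |
                         candidates$enc < enc_band[1] |
                         candidates$enc > enc_band[2])
    keep <- keep & !enc_bad
    reason[enc_bad] <- "enc_out_of_band"
  }
  discarded <- candidates[!keep, , drop = FALSE]
  discarded$reason <- reason[!keep]
  list(kept = candidates[keep, , drop = FALSE], discarded = discarded,
       band = band)
}
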