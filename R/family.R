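#' Single-linkage protein clustering into gene families
#'
#' A deliberately simple stand-in for graph-based orthology clustering so
#' that simulated datasets can be run end to end: connected components over
#' pairs of proteins whose global alignment identity is at least
#' `threshold`. Identity is matches / alignment length; gaps and `X`
#' residues count as mismatches. Externally produced family maps (from any
#' orthology tool) can be supplied to downstream stages instead.
#'
#' A word (4-mer) prefilter skips pairs sharing almost no protein 4-mers,
#' the same shortcut CD-HIT-style tools use; pairs at alignment identities
#' near any practical threshold always share words, so the components are
#' unchanged while the quadratic alignment cost drops sharply. Set
#' `prefilter = FALSE` to force every pair through alignment.
#'
#' @param orfs data.frame with `record_id` and `protein`.
#' @param threshold identity fraction in (0, 1].
#' @param prefilter use the shared-word prefilter (default `TRUE`).
#' @return data.frame `family_id`, `record_id`; family ids are `GF00001`,
#'   ... numbered by the first member in input order (deterministic).
#' @export
cluster_orfs <- function(orfs, threshold = 0.4, prefilter = TRUE) {
  stopifnot(nrow(orfs) >= 1L)
  n <- nrow(orfs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  kmers <- if (prefilter) lapply(orfs$protein, protein_kmers) else NULL
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        if (find(i) == find(j)) next
        if (prefilter) {
          shared <- length(intersect(kmers[[i]], kmers[[j]]))
          if (shared / min(length(kmers[[i]]), length(kmers[[j]])) < 0.02) next
        }
        if (protein_identity(orfs$protein[i], orfs$protein[j]) >= threshold) {
          parent[find(j)] <- find(i)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  fam_index <- match(roots, unique(roots))
  data.frame(family_id = sprintf("GF%05d", fam_index),
             record_id = orfs$record_id, stringsAsFactors = FALSE)
}

protein_kmers <- function(p, k = 4L) {
  if (nchar(p) < k) return(p)
  unique(substring(p, seq_len(nchar(p) - k + 1L), seq_len(nchar(p) - k + 1L) + k - 1L))
}

protein_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  ps <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  sum(pa == ps & pa != "X" & pa != "-") / length(pa)
}

#' Refine a gene family by size band and composition criteria
#'
#' Two-step refinement. Step 1: the mean protein length is computed once
#' over the initial membership, and members outside
#' `[size_band[1] * mean, size_band[2] * mean]` (default 50-150%) are
#' dropped. Step 2: the surviving membership must satisfy, in order, a
#' minimum ciliate proportion (default 0.95), a minimum member count
#' (default 5) and a minimum number of distinct ciliate genera (default 2).
#' The first criterion violated is reported as the rejection reason.
#'
#' @param members data.frame for one family: `record_id`, `taxon`, `length`
#'   (protein length in aa).
#' @param taxa taxon metadata data.frame: `taxon`, `genus`, `class`,
#'   `category`, and optionally `is_ciliate` (default `TRUE`).
#' @param size_band numeric length-2 multiplier band on the mean length.
#' @param min_ciliate_prop,min_members,min_genera refinement thresholds.
#' @param proportion_first if `TRUE`, evaluate the ciliate proportion on the
#'   initial membership rather than after the length-band drop.
#' @return list: `kept` (logical), `members` (refined membership),
#'   `reason` (`NA` if kept, else `ciliate_proportion` / `min_members` /
#'   `min_genera`), `dropped_by_band` (record ids).
#' @export
refine_family <- function(members, taxa, size_band = c(0.5, 1.5),
                          min_ciliate_prop = 0.95, min_members = 5,
                          min_genera = 2, proportion_first = FALSE) {
  stopifnot(all(c("record_id", "taxon", "length") %in% names(members)))
  if (any(members$length <= 0)) stop("member lengths must be positive")
  taxa <- normalize_taxa(taxa)
  unknown <- setdiff(members$taxon, taxa$taxon)
  if (length(unknown)) stop("taxa missing from metadata: ", paste(unknown, collapse = ", "))
  info <- taxa[match(members$taxon, taxa$taxon), ]

  ciliate_prop <- function(flags) if (length(flags) == 0L) NA_real_ else mean(flags)
  prop0 <- ciliate_prop(info$is_ciliate)

  mean_len <- mean(members$length)
  in_band <- members$length >= size_band[1] * mean_len &
             members$length <= size_band[2] * mean_len
  refined <- members[in_band, , drop = FALSE]
  rinfo <- info[in_band, , drop = FALSE]
  dropped <- members$record_id[!in_band]

  reason <- NA_character_
  prop <- if (proportion_first) prop0 else ciliate_prop(rinfo$is_ciliate)
  n_gen <- length(unique(rinfo$genus[rinfo$is_ciliate]))
  if (nrow(refined) == 0L) {
    reason <- "min_members"
  } else if (!is.na(prop) && prop < min_ciliate_prop) {
    reason <- "ciliate_proportion"
  } else if (nrow(refined) < min_members) {
    reason <- "min_members"
  } else if (n_gen < min_genera) {
    reason <- "min_genera"
  }
  list(kept = is.na(reason), members = refined, reason = reason,
       dropped_by_band = dropped)
}

#' Refine every family of a membership map
#'
#' @param membership data.frame `family_id`, `record_id`, `taxon`, `length`.
#' @param taxa taxon metadata (see [refine_family()]).
#' @param ... thresholds passed to [refine_family()].
#' @return list: `members` (refined membership of kept families),
#'   `decisions` (data.frame `family_id`, `kept`, `reason`, `n_initial`,
#'   `n_refined`).
#' @export
refine_families <- function(membership, taxa, ...) {
  fams <- split(membership, membership$family_id)
  decisions <- lapply(names(fams), function(fid) {
    r <- refine_family(fams[[fid]], taxa, ...)
    data.frame(family_id = fid, kept = r$kept,
               reason = ifelse(is.na(r$reason), "", r$reason),
               n_initial = nrow(fams[[fid]]), n_refined = nrow(r$members),
               stringsAsFactors = FALSE)
  })
  decisions <- do.call(rbind, decisions)
  kept_ids <- decisions$family_id[decisions$kept]
  kept_members <- lapply(kept_ids, function(fid) {
    r <- refine_family(fams[[fid]], taxa, ...)
    cbind(family_id = fid, r$members[, c("record_id", "taxon", "length")])
  })
  members <- if (length(kept_members)) do.call(rbind, kept_members) else
    membership[0, c("family_id", "record_id", "taxon", "length")]
  list(members = members, decisions = decisions)
}

normalize_taxa <- function(taxa) {
  stopifnot(is.data.frame(taxa), all(c("taxon", "genus") %in% names(taxa)))
  if (!"is_ciliate" %in% names(taxa)) taxa$is_ciliate <- TRUE
  if (!"class" %in% names(taxa)) taxa$class <- NA_character_
  if (!"category" %in% names(taxa)) taxa$category <- NA_character_
  taxa
}

#' Presence/count matrix of families across taxa
#'
#' @param membership data.frame `family_id`, `record_id`, `taxon`.
#' @param taxa taxon metadata; fixes the column order.
#' @return list of class `presence_matrix`: `counts` (families x taxa member
#'   counts), `presence` (binary), `taxa` (metadata in column order).
#' @export
presence_matrix <- function(membership, taxa) {
  taxa <- normalize_taxa(taxa)
  fams <- sort(unique(membership$family_id))
  counts <- table(factor(membership$family_id, levels = fams),
                  factor(membership$taxon, levels = taxa$taxon))
  counts <- matrix(as.integer(counts), nrow = length(fams),
                   ncol = nrow(taxa), dimnames = list(fams, taxa$taxon))
  structure(list(counts = counts, presence = (counts > 0) * 1L, taxa = taxa),
            class = "presence_matrix")
}

#' Sharing summaries across architecture categories, classes and taxa
#'
#' For each family, records the set of genome-architecture categories and
#' taxonomic classes with at least one present taxon; aggregates upset-style
#' intersection counts over category sets, per-category family counts and
#' mean/median family sizes (member counts restricted to the category's
#' taxa), and per-taxon counts.
#'
#' @param pm a [presence_matrix()].
#' @return list: `family_sets` (family, categories, classes, n_categories),
#'   `upset` (category-set intersection counts; their sum equals the number
#'   of families), `category_summary`, `taxon_summary`.
#' @export
sharing_summary <- function(pm) {
  stopifnot(inherits(pm, "presence_matrix"))
  taxa <- pm$taxa
  cats <- taxa$category[match(colnames(pm$presence), taxa$taxon)]
  clss <- taxa$class[match(colnames(pm$presence), taxa$taxon)]
  cat_levels <- unique(stats::na.omit(cats))

  if (nrow(pm$presence) == 0L) {
    empty_cat <- data.frame(category = cat_levels,
                            n_families = 0L, mean_size = NA_real_,
                            median_size = NA_real_, stringsAsFactors = FALSE)
    return(list(
      family_sets = data.frame(family_id = character(), categories = character(),
                               classes = character(), n_categories = integer()),
      upset = data.frame(categories = character(), n_families = integer()),
      category_summary = empty_cat,
      taxon_summary = data.frame(taxon = colnames(pm$counts),
                                 n_families = 0L, mean_size = NA_real_)))
  }

  fam_sets <- lapply(rownames(pm$presence), function(f) {
    present <- pm$presence[f, ] > 0
    cset <- sort(unique(stats::na.omit(cats[present])))
    kset <- sort(unique(stats::na.omit(clss[present])))
    data.frame(family_id = f,
               categories = paste(cset, collapse = "+"),
               classes = paste(kset, collapse = "+"),
               n_categories = length(cset), stringsAsFactors = FALSE)
  })
  fam_sets <- do.call(rbind, fam_sets)

  upset <- as.data.frame(table(categories = fam_sets$categories),
                         stringsAsFactors = FALSE)
  names(upset)[2] <- "n_families"
  upset <- upset[order(-upset$n_families, upset$categories), , drop = FALSE]
  rownames(upset) <- NULL

  category_summary <- do.call(rbind, lapply(cat_levels, function(cc) {
    cols <- which(cats == cc)
    sizes <- rowSums(pm$counts[, cols, drop = FALSE])
    sizes <- sizes[sizes > 0]
    data.frame(category = cc, n_families = length(sizes),
               mean_size = if (length(sizes)) mean(sizes) else NA_real_,
               median_size = if (length(sizes)) stats::median(sizes) else NA_real_,
               stringsAsFactors = FALSE)
  }))

  taxon_summary <- data.frame(
    taxon = colnames(pm$counts),
    n_families = colSums(pm$presence),
    mean_size = apply(pm$counts, 2, function(v) {
      v <- v[v > 0]; if (length(v)) mean(v) else NA_real_
    }),
    stringsAsFactors = FALSE)
  rownames(taxon_summary) <- NULL

  list(family_sets = fam_sets, upset = upset,
       category_summary = category_summary, taxon_summary = taxon_summary)
}
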