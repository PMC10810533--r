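# End-to-end orchestration: curate -> composition -> families -> history ->
# selection -> report, with a manifest that fully determines the run.

#' Build a validated pipeline run configuration
#'
#' Exactly one of `simulate` or `inputs` must be supplied. `simulate`
#' generates the whole dataset with [simulate_species_tree()] and friends;
#' `inputs` points at existing files (per-taxon FASTA directory, taxon
#' metadata TSV, species tree Newick, optional family map and per-family
#' alignments/trees).
#'
#' @param out_dir output directory (created).
#' @param seed master seed for every stochastic step.
#' @param simulate list: `n_taxa`, `n_families`, `n_codons`, plus any
#'   [simulation_config()] arguments.
#' @param inputs list: `fasta_dir`, `taxon_table`, `species_tree`,
#'   optionally `family_map`, `alignment_dir`.
#' @param thresholds named overrides of the stage defaults (`min_aa`,
#'   `allele_identity`, `band_lower`, `band_upper`, `cluster_threshold`,
#'   `size_band`, `min_ciliate_prop`, `min_members`, `min_genera`,
#'   `q_threshold`, `bin_increment`, `code`).
#' @param fit_control optimizer budget for the selection stage.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1, simulate = NULL, inputs = NULL,
                       thresholds = list(), fit_control = list()) {
  if (is.null(simulate) == is.null(inputs)) {
    stop("exactly one of 'simulate' or 'inputs' must be given")
  }
  th <- utils::modifyList(list(
    min_aa = 200, allele_identity = 0.97, band_lower = 10, band_upper = 90,
    cluster_threshold = 0.4, size_band = c(0.5, 1.5), min_ciliate_prop = 0.95,
    min_members = 5, min_genera = 2, q_threshold = 0.1, bin_increment = 5,
    code = 6), thresholds)
  if (th$band_lower < 0 || th$band_upper > 100 || th$band_lower > th$band_upper)
    stop("invalid composition band")
  fc <- utils::modifyList(list(maxit_short = 60, maxit_final = 250,
                               n_starts = 2), fit_control)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = simulate, inputs = inputs, thresholds = th,
                 fit_control = fc),
            class = "run_config")
}

pipeline_stages <- c("simulate", "curate", "composition", "families",
                     "history", "selection", "report")

#' Run the pipeline end to end
#'
#' Executes the stages in order, writing each stage's outputs under
#' `out_dir` and a manifest (`manifest.json`) recording the configuration,
#' seed and per-stage record counts. Stages can be resumed from existing
#' intermediates via `from_stage`: earlier stages are then loaded from disk
#' instead of recomputed, and downstream outputs are reproduced exactly.
#'
#' @param config a [run_config()].
#' @param from_stage stage name to resume from (default `"simulate"` = full
#'   run).
#' @return the manifest (invisibly also written to
#'   `file.path(out_dir, "manifest.json")`).
#' @export
run_pipeline <- function(config, from_stage = "simulate") {
  stopifnot(inherits(config, "run_config"))
  from_i <- match(from_stage, pipeline_stages)
  if (is.na(from_i)) stop("unknown stage '", from_stage, "'")
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds
  counts <- list()
  # resumed runs keep the skipped stages' counts from the previous manifest
  prev_manifest <- file.path(out, "manifest.json")
  if (from_i > 1 && file.exists(prev_manifest)) {
    counts <- jsonlite::read_json(prev_manifest)$counts
  }
  run_stage <- function(i) from_i <= i

  log_path <- file.path(out, "pipeline.log")
  if (from_i == 1 || !file.exists(log_path)) cat("", file = log_path)
  log_line <- function(...) {
    msg <- paste0(...)
    message(msg)
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
  }

  stage_failed <- function(stage, e) {
    log_line("stage '", stage, "' FAILED: ", conditionMessage(e))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }

  # --- simulate ---------------------------------------------------------
  simdir <- file.path(out, "00_simulate")
  if (!is.null(config$simulate) && run_stage(1)) {
    tryCatch({
      counts$simulate <- stage_simulate(config, simdir)
      log_line("stage simulate: ", counts$simulate$n_records, " records from ",
               counts$simulate$n_taxa, " taxa")
    }, error = function(e) stage_failed("simulate", e))
  }

  # --- curate -----------------------------------------------------------
  curdir <- file.path(out, "01_curate")
  if (run_stage(2)) {
    tryCatch({
      counts$curate <- stage_curate(config, simdir, curdir)
      log_line("stage curate: ", counts$curate$n_orfs, " ORFs retained")
    }, error = function(e) stage_failed("curate", e))
  }

  # --- composition ------------------------------------------------------
  compdir <- file.path(out, "02_composition")
  if (run_stage(3)) {
    tryCatch({
      counts$composition <- stage_composition(config, curdir, compdir)
      log_line("stage composition: ", counts$composition$n_kept, "/",
               counts$composition$n_candidates, " kept")
    }, error = function(e) stage_failed("composition", e))
  }

  # --- families ---------------------------------------------------------
  famdir <- file.path(out, "03_families")
  if (run_stage(4)) {
    tryCatch({
      counts$families <- stage_families(config, compdir, curdir, famdir)
      log_line("stage families: ", counts$families$n_kept, "/",
               counts$families$n_initial, " families kept")
    }, error = function(e) stage_failed("families", e))
  }

  # --- history ----------------------------------------------------------
  histdir <- file.path(out, "04_history")
  if (run_stage(5)) {
    tryCatch({
      counts$history <- stage_history(config, famdir, simdir, histdir)
      log_line("stage history: ", counts$history$n_families_dated, " families dated")
    }, error = function(e) stage_failed("history", e))
  }

  # --- selection --------------------------------------------------------
  seldir <- file.path(out, "05_selection")
  if (run_stage(6)) {
    tryCatch({
      counts$selection <- stage_selection(config, famdir, simdir, seldir)
      log_line("stage selection: ", counts$selection$n_relax_tests, " RELAX tests")
    }, error = function(e) stage_failed("selection", e))
  }

  # --- report -----------------------------------------------------------
  repdir <- file.path(out, "06_report")
  tryCatch({
    counts$report <- write_report(out)
  }, error = function(e) stage_failed("report", e))

  manifest <- list(
    package = "lsgfevo",
    version = as.character(utils::packageVersion("lsgfevo")),
    seed = config$seed,
    thresholds = th,
    fit_control = config$fit_control,
    simulate = config$simulate,
    inputs = config$inputs,
    stages = pipeline_stages[-1],
    counts = counts)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# ---- stages --------------------------------------------------------------

stage_simulate <- function(config, simdir) {
  sc <- config$simulate
  dir.create(simdir, showWarnings = FALSE, recursive = TRUE)
  cfg_args <- sc[setdiff(names(sc), c("n_taxa", "n_families", "n_codons",
                                      "category_scheme"))]
  cfg <- do.call(simulation_config, c(cfg_args, list(seed = config$seed)))
  sim <- simulate_species_tree(
    sc$n_taxa,
    category_scheme = if (!is.null(sc$category_scheme)) sc$category_scheme
                      else c(EF = 0.4, NEF = 0.35, HE = 0.15, KA = 0.1),
    seed = config$seed)
  hist <- simulate_family_histories(sim, cfg, sc$n_families)
  names(hist) <- vapply(hist, `[[`, character(1), "family_id")
  alns <- list()
  for (h in hist) {
    if (is.null(h$gene_tree)) next
    alns[[h$family_id]] <- simulate_family_alignment(
      h, sim, cfg, sc$n_codons,
      seed = config$seed + 131L * match(h$family_id, names(hist)))
  }
  em <- emit_transcriptomes(alns, sim, cfg, out_dir = file.path(simdir, "fasta"),
                            histories = hist)
  ape::write.tree(sim$tree, file.path(simdir, "species_tree.nwk"))
  write_tsv(sim$taxa, file.path(simdir, "taxa.tsv"))
  write_tsv(family_truth_table(hist), file.path(simdir, "family_truth.tsv"))
  gt_dir <- file.path(simdir, "gene_trees")
  dir.create(gt_dir, showWarnings = FALSE)
  for (fid in names(alns)) {
    ape::write.tree(alns[[fid]]$gene_tree, file.path(gt_dir, paste0(fid, ".nwk")))
    write_fasta(alns[[fid]]$alignment, file.path(gt_dir, paste0(fid, ".fasta")))
  }
  ref <- simulate_reference_gc3s(200, mean = cfg$gc3s_ciliate, seed = config$seed)
  writeLines(sprintf("%.6f", ref), file.path(simdir, "reference_gc3s.txt"))
  list(n_taxa = nrow(sim$taxa), n_families = length(hist),
       n_families_surviving = sum(vapply(hist, `[[`, logical(1), "surviving")),
       n_records = nrow(em$truth))
}

family_truth_table <- function(hist) {
  do.call(rbind, lapply(hist, function(h) {
    data.frame(family_id = h$family_id, birth_node = h$birth_id,
               n_losses = h$n_losses, n_duplications = h$n_duplications,
               n_taxa = length(h$surviving_leaves),
               surviving = h$surviving, stringsAsFactors = FALSE)
  }))
}

stage_curate <- function(config, simdir, curdir) {
  th <- config$thresholds
  dir.create(curdir, showWarnings = FALSE, recursive = TRUE)
  fasta_dir <- if (!is.null(config$inputs)) config$inputs$fasta_dir
               else file.path(simdir, "fasta")
  files <- list.files(fasta_dir, pattern = "\\.fasta$|\\.fa$", full.names = TRUE)
  orfs <- list(); clusters <- list()
  for (fp in files) {
    tx <- tools::file_path_sans_ext(basename(fp))
    seqs <- read_fasta(fp)
    tx_orfs <- lapply(names(seqs), function(nm) {
      call_orfs(seqs[[nm]], th$code, min_aa = th$min_aa,
                transcript_id = nm, taxon = tx)
    })
    tx_orfs <- do.call(rbind, tx_orfs)
    if (is.null(tx_orfs) || nrow(tx_orfs) == 0) next
    tx_orfs$record_id <- tx_orfs$transcript_id    # one ORF per transcript
    dd <- dedupe_allelic_variants(tx_orfs, identity = th$allele_identity)
    orfs[[tx]] <- dd$representatives
    clusters[[tx]] <- dd$clusters
  }
  orfs <- do.call(rbind, c(orfs, list(NULL)))
  clusters <- do.call(rbind, c(clusters, list(NULL)))
  if (is.null(orfs)) stop("no ORFs passed curation")
  rownames(orfs) <- NULL
  write_tsv(orfs, file.path(curdir, "orfs.tsv"))
  write_tsv(clusters, file.path(curdir, "allele_clusters.tsv"))
  list(n_orfs = nrow(orfs),
       n_collapsed = if (is.null(clusters)) 0L else nrow(clusters) - nrow(orfs))
}

stage_composition <- function(config, curdir, compdir) {
  th <- config$thresholds
  dir.create(compdir, showWarnings = FALSE, recursive = TRUE)
  orfs <- read_tsv(file.path(curdir, "orfs.tsv"))
  ref_path <- if (!is.null(config$inputs) && !is.null(config$inputs$reference_gc3s))
    config$inputs$reference_gc3s
  else file.path(config$out_dir, "00_simulate", "reference_gc3s.txt")
  reference <- as.numeric(readLines(ref_path))
  comp <- composition_table(orfs, th$code)
  band <- percentile_band(reference, th$band_lower, th$band_upper)
  flt <- composition_band_filter(comp, band)
  comp$kept <- comp$record_id %in% flt$kept$record_id
  comp$reason <- ""
  comp$reason[match(flt$discarded$record_id, comp$record_id)] <- flt$discarded$reason
  write_tsv(comp, file.path(compdir, "composition.tsv"))
  jsonlite::write_json(unclass(band), file.path(compdir, "band.json"),
                       auto_unbox = TRUE, digits = NA)
  list(n_candidates = nrow(comp), n_kept = sum(comp$kept),
       n_discarded = sum(!comp$kept))
}

stage_families <- function(config, compdir, curdir, famdir) {
  th <- config$thresholds
  dir.create(famdir, showWarnings = FALSE, recursive = TRUE)
  orfs <- read_tsv(file.path(curdir, "orfs.tsv"))
  comp <- read_tsv(file.path(compdir, "composition.tsv"))
  orfs <- orfs[orfs$record_id %in% comp$record_id[comp$kept], , drop = FALSE]
  taxa <- pipeline_taxa(config)
  if (!is.null(config$inputs) && !is.null(config$inputs$family_map)) {
    membership <- read_tsv(config$inputs$family_map)
  } else {
    membership <- cluster_orfs(orfs, threshold = th$cluster_threshold)
  }
  membership <- merge(membership,
                      data.frame(record_id = orfs$record_id, taxon = orfs$taxon,
                                 length = nchar(orfs$protein)),
                      by = "record_id")
  membership <- membership[order(membership$family_id, membership$record_id), ]
  ref <- refine_families(membership, taxa,
                         size_band = th$size_band,
                         min_ciliate_prop = th$min_ciliate_prop,
                         min_members = th$min_members,
                         min_genera = th$min_genera)
  write_tsv(membership, file.path(famdir, "membership_initial.tsv"))
  write_tsv(ref$members, file.path(famdir, "membership.tsv"))
  write_tsv(ref$decisions, file.path(famdir, "decisions.tsv"))
  pm <- presence_matrix(ref$members, taxa)
  write_presence(pm, file.path(famdir, "presence.tsv"))
  sh <- sharing_summary(pm)
  write_tsv(sh$family_sets, file.path(famdir, "family_sets.tsv"))
  write_tsv(sh$upset, file.path(famdir, "upset.tsv"))
  write_tsv(sh$category_summary, file.path(famdir, "category_summary.tsv"))
  write_tsv(sh$taxon_summary, file.path(famdir, "taxon_summary.tsv"))
  list(n_initial = length(unique(membership$family_id)),
       n_kept = sum(ref$decisions$kept))
}

pipeline_taxa <- function(config) {
  if (!is.null(config$inputs)) {
    normalize_taxa(read_tsv(config$inputs$taxon_table))
  } else {
    normalize_taxa(read_tsv(file.path(config$out_dir, "00_simulate", "taxa.tsv")))
  }
}

pipeline_species_tree <- function(config) {
  path <- if (!is.null(config$inputs)) config$inputs$species_tree
          else file.path(config$out_dir, "00_simulate", "species_tree.nwk")
  ape::read.tree(path)
}

stage_history <- function(config, famdir, simdir, histdir) {
  dir.create(histdir, showWarnings = FALSE, recursive = TRUE)
  tree <- pipeline_species_tree(config)
  taxa <- pipeline_taxa(config)
  members <- read_tsv(file.path(famdir, "membership.tsv"))
  pm <- presence_matrix(members, taxa)
  dg <- suppressWarnings(dollo_gain_map(pm, tree))
  write_tsv(dg$births, file.path(histdir, "births.tsv"))

  events <- dg$branch_gains
  events$duplications <- 0L
  events$speciations <- 0L
  gt_dir <- file.path(simdir, "gene_trees")
  if (!is.null(config$inputs) && !is.null(config$inputs$gene_tree_dir)) {
    gt_dir <- config$inputs$gene_tree_dir
  }
  n_rec <- 0L
  for (fid in unique(members$family_id)) {
    gt <- family_gene_tree(members, fid, gt_dir)
    if (is.null(gt)) next
    rec <- reconcile_gene_tree(gt, tree)
    idx <- match(rec$branch_events$branch, events$branch)
    ok <- !is.na(idx)
    events$duplications[idx[ok]] <- events$duplications[idx[ok]] +
      rec$branch_events$duplications[ok]
    events$speciations[idx[ok]] <- events$speciations[idx[ok]] +
      rec$branch_events$speciations[ok]
    n_rec <- n_rec + 1L
  }
  write_tsv(events, file.path(histdir, "branch_events.tsv"))
  write_annotated_tree(tree, events, file.path(histdir, "species_tree_annotated.nwk"))
  list(n_families_dated = nrow(dg$births), n_reconciled = n_rec)
}

# locate the simulated/provided gene tree backing an inferred family: the
# majority source family among its member record ids
family_gene_tree <- function(members, fid, gt_dir) {
  recs <- members$record_id[members$family_id == fid]
  src <- sub("^[^|]*\\|", "", recs)
  src <- sub("\\|.*$", "", src)
  src <- src[grepl("^FAM", src)]
  if (!length(src)) return(NULL)
  best <- names(sort(table(src), decreasing = TRUE))[1]
  path <- file.path(gt_dir, paste0(best, ".nwk"))
  if (!file.exists(path)) return(NULL)
  tr <- ape::read.tree(path)
  attr(tr, "source_family") <- best
  tr
}

stage_selection <- function(config, famdir, simdir, seldir) {
  th <- config$thresholds
  dir.create(seldir, showWarnings = FALSE, recursive = TRUE)
  taxa <- pipeline_taxa(config)
  categories <- stats::setNames(taxa$category, taxa$taxon)
  members <- read_tsv(file.path(famdir, "membership.tsv"))
  gt_dir <- file.path(simdir, "gene_trees")
  if (!is.null(config$inputs) && !is.null(config$inputs$alignment_dir)) {
    gt_dir <- config$inputs$alignment_dir
  }
  rows <- list(); eds_rows <- list()
  for (fid in unique(members$family_id)) {
    gt <- family_gene_tree(members, fid, gt_dir)
    if (is.null(gt)) next
    src <- attr(gt, "source_family")
    fa <- file.path(gt_dir, paste0(src, ".fasta"))
    if (!file.exists(fa)) next
    aln <- codon_alignment(read_fasta(fa), th$code)
    part <- label_branches(gt, categories)
    ref <- choose_reference_group(part)
    if (!ref$testable) next
    rx <- fit_relax_groups(aln, gt, part, fit_descriptive = TRUE,
                           control = config$fit_control)
    for (g in names(rx$K)) {
      rows[[length(rows) + 1L]] <- data.frame(
        family_id = fid, source_family = src, group = g,
        reference = rx$reference, K = rx$K[[g]],
        lnl_null = rx$loglik_null, lnl_alt = rx$loglik_alt,
        lrt = rx$lrt, df = rx$df, p = rx$p_value,
        fit_check = rx$fit_check$relax_adequate,
        stringsAsFactors = FALSE)
    }
    for (g in ref$groups) {
      bs <- fit_busted_s(aln, gt, part, g, control = config$fit_control)
      eds_rows[[length(eds_rows) + 1L]] <- data.frame(
        family_id = fid, source_family = src, group = g,
        n_branches = bs$n_branches, omega3 = bs$omega3,
        omega3_weight = bs$omega3_weight, lrt = bs$lrt, p = bs$p_value,
        stringsAsFactors = FALSE)
    }
  }
  relax <- do.call(rbind, c(rows, list(NULL)))
  eds <- do.call(rbind, c(eds_rows, list(NULL)))
  if (!is.null(relax) && nrow(relax)) {
    fam_p <- unique(relax[, c("family_id", "p")])
    fam_p$q <- adjust_fdr(fam_p$p)
    relax$q <- fam_p$q[match(relax$family_id, fam_p$family_id)]
  } else {
    relax <- data.frame(family_id = character(), source_family = character(),
                        group = character(), reference = character(),
                        K = numeric(), lnl_null = numeric(), lnl_alt = numeric(),
                        lrt = numeric(), df = integer(), p = numeric(),
                        fit_check = logical(), q = numeric())
  }
  if (!is.null(eds) && nrow(eds)) {
    eds$q <- adjust_fdr(eds$p)
  } else {
    eds <- data.frame(family_id = character(), source_family = character(),
                      group = character(), n_branches = integer(),
                      omega3 = numeric(), omega3_weight = numeric(),
                      lrt = numeric(), p = numeric(), q = numeric())
  }
  write_tsv(relax, file.path(seldir, "relax.tsv"))
  write_tsv(eds, file.path(seldir, "busted.tsv"))
  # per-family JSON mirror of the combined tables
  per_family <- lapply(unique(c(relax$family_id, eds$family_id)), function(fid) {
    list(family_id = fid,
         relax = relax[relax$family_id == fid, , drop = FALSE],
         eds = eds[eds$family_id == fid, , drop = FALSE])
  })
  jsonlite::write_json(per_family, file.path(seldir, "selection.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  bins <- bin_eds_rates(eds, increment = th$bin_increment,
                        q_threshold = th$q_threshold)
  write_tsv(bins, file.path(seldir, "eds_bins.tsv"))
  list(n_relax_tests = length(unique(relax$family_id)),
       n_relax_significant = sum(unique(relax[, c("family_id", "q")])$q <= th$q_threshold),
       n_eds_tests = nrow(eds))
}

#' Assemble the report tables from stage outputs
#'
#' Re-reads the stage TSVs under `out_dir` (nothing is computed from
#' in-memory state, so every report number is recomputable from the
#' intermediates) and writes: per-category family counts and sizes, the
#' sharing/upset table, the per-branch gains/duplications table, and a
#' selection summary per group (genes tested, mean labelled branches,
#' count and proportion with episodic diversifying selection at the q
#' threshold). Group-size comparisons (one-way ANOVA and Kruskal-Wallis on
#' per-family sizes across categories) are attached as routine descriptive
#' statistics.
#'
#' @param out_dir pipeline output directory.
#' @return list of per-stage record counts for the manifest.
#' @export
write_report <- function(out_dir) {
  repdir <- file.path(out_dir, "06_report")
  dir.create(repdir, showWarnings = FALSE, recursive = TRUE)
  th_q <- 0.1
  man_path <- file.path(out_dir, "manifest.json")
  if (file.exists(man_path)) {
    th_q <- jsonlite::read_json(man_path)$thresholds$q_threshold
  }

  cat_sum <- read_tsv(file.path(out_dir, "03_families", "category_summary.tsv"))
  upset <- read_tsv(file.path(out_dir, "03_families", "upset.tsv"))
  events <- read_tsv(file.path(out_dir, "04_history", "branch_events.tsv"))
  eds <- read_tsv(file.path(out_dir, "05_selection", "busted.tsv"))

  write_tsv(cat_sum, file.path(repdir, "category_sizes.tsv"))
  write_tsv(upset, file.path(repdir, "sharing.tsv"))
  write_tsv(events[, c("branch", "gains", "duplications")],
            file.path(repdir, "branch_gains_duplications.tsv"))

  sel <- if (nrow(eds)) {
    groups <- sort(unique(eds$group))
    do.call(rbind, lapply(groups, function(g) {
      sub <- eds[eds$group == g, , drop = FALSE]
      n_pos <- sum(sub$q <= th_q)
      data.frame(group = g, genes = nrow(sub),
                 mean_branches = round(mean(sub$n_branches), 1),
                 positively_selected = n_pos,
                 proportion = round(n_pos / nrow(sub), 3),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(group = character(), genes = integer(),
               mean_branches = numeric(), positively_selected = integer(),
               proportion = numeric())
  }
  write_tsv(sel, file.path(repdir, "selection_summary.tsv"))

  # routine group-size comparisons on per-family-per-category sizes
  stats_json <- list(anova_p = NA, kruskal_p = NA)
  members <- read_tsv(file.path(out_dir, "03_families", "membership.tsv"))
  taxa_path <- file.path(out_dir, "00_simulate", "taxa.tsv")
  if (nrow(members) && file.exists(taxa_path)) {
    taxa <- normalize_taxa(read_tsv(taxa_path))
    members$category <- taxa$category[match(members$taxon, taxa$taxon)]
    sizes <- stats::aggregate(record_id ~ family_id + category, members, length)
    if (length(unique(sizes$category)) >= 2 && var(sizes$record_id) > 0) {
      stats_json$anova_p <- suppressWarnings(
        stats::anova(stats::aov(record_id ~ category, sizes))[["Pr(>F)"]][1])
      stats_json$kruskal_p <- suppressWarnings(
        stats::kruskal.test(record_id ~ category, sizes)$p.value)
    }
  }
  jsonlite::write_json(stats_json, file.path(repdir, "group_size_tests.json"),
                       auto_unbox = TRUE, digits = NA)
  list(n_report_tables = 4L)
}

# ---- small IO helpers ----------------------------------------------------

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "", comment.char = "")
}

write_presence <- function(pm, path) {
  df <- data.frame(family_id = rownames(pm$counts), pm$counts,
                   check.names = FALSE)
  write_tsv(df, path)
}
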