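#' Partition gene-tree branches into architecture groups
#'
#' Terminal branches take the genome-architecture category of their taxon
#' (EF, NEF, HE, KA); an internal branch is labelled with a category if and
#' only if every branch below it carries that same category, otherwise it is
#' `"unclassified"`. Unclassified branches are never tested; their omega
#' distribution is a nuisance parameter in the model fits.
#'
#' @param tree rooted `phylo` (typically a gene tree).
#' @param categories named character vector taxon -> category. Gene-tree tip
#'   labels of the form `taxon@copy` are resolved to `taxon`.
#' @return object of class `group_partition`: `edge_labels` (character per
#'   `tree$edge` row), `table` (edge, child id, label), `group_sizes`
#'   (branch counts per non-unclassified group), `tree`.
#' @export
label_branches <- function(tree, categories) {
  tipcat <- vapply(tree$tip.label, function(lab) {
    t1 <- if (lab %in% names(categories)) lab else sub("@[^@]*$", "", lab)
    if (!t1 %in% names(categories)) stop("no category for taxon '", lab, "'")
    categories[[t1]]
  }, character(1))
  ls <- node_leafsets(tree)
  ids <- node_ids(tree)
  edge_labels <- character(nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2]
    cats <- unique(tipcat[ls[ch, ]])
    edge_labels[e] <- if (length(cats) == 1L) cats else "unclassified"
  }
  tab <- data.frame(edge = seq_len(nrow(tree$edge)),
                    child = ids[tree$edge[, 2]], label = edge_labels,
                    stringsAsFactors = FALSE)
  sizes <- table(edge_labels[edge_labels != "unclassified"])
  structure(list(edge_labels = edge_labels, table = tab,
                 group_sizes = sizes, tree = tree),
            class = "group_partition")
}

#' @export
print.group_partition <- function(x, ...) {
  cat("group_partition:", paste(sprintf("%s=%d", names(x$group_sizes),
                                        as.integer(x$group_sizes)), collapse = " "),
      "unclassified =", sum(x$edge_labels == "unclassified"), "\n")
  invisible(x)
}

#' Choose the reference group for the selection-intensity test
#'
#' The reference is EF when EF branches are present, otherwise NEF,
#' otherwise HE, otherwise KA. A partition is testable when more than one
#' group is present with more than one branch per group; untestable
#' partitions are flagged, not raised as errors.
#'
#' @param partition a [label_branches()] result.
#' @return list: `reference` (label or `NA`), `testable`, `groups` (labels
#'   with >= 2 branches, reference first), `reason` when untestable.
#' @export
choose_reference_group <- function(partition) {
  sizes <- partition$group_sizes
  eligible <- names(sizes)[sizes >= 2]
  priority <- c("EF", "NEF", "HE", "KA")
  if (length(eligible) < 2) {
    return(list(reference = NA_character_, testable = FALSE,
                groups = eligible,
                reason = "fewer than two groups with more than one branch"))
  }
  ref <- priority[priority %in% eligible][1]
  if (is.na(ref)) ref <- sort(eligible)[1]
  list(reference = ref, testable = TRUE,
       groups = c(ref, setdiff(eligible, ref)), reason = NA_character_)
}

# ---- omega-distribution parameterisation ---------------------------------
#
# A 3-category distribution is encoded by 5 unconstrained parameters:
# omega_3 = exp(x3) (or plogis(x3) when capped at 1), omega_2 = omega_3 *
# plogis(x2), omega_1 = omega_2 * plogis(x1); weights by softmax(w1, w2, 0).
# The nesting keeps categories ascending by construction.

decode_dist <- function(par, ncat = 3, cap_last = FALSE) {
  xs <- par[seq_len(ncat)]
  ws <- par[ncat + seq_len(ncat - 1)]
  om <- numeric(ncat)
  om[ncat] <- if (cap_last) stats::plogis(xs[ncat]) else exp(xs[ncat])
  if (ncat > 1) {
    for (k in seq(ncat - 1, 1)) om[k] <- om[k + 1] * stats::plogis(xs[k])
  }
  ew <- exp(c(ws, 0))
  list(omega = pmin(om, 1e4), weight = ew / sum(ew))
}

encode_dist <- function(omega, weight, cap_last = FALSE) {
  ncat <- length(omega)
  omega <- pmax(pmin(omega, 1e4), 1e-8)
  xs <- numeric(ncat)
  xs[ncat] <- if (cap_last) stats::qlogis(min(max(omega[ncat], 1e-6), 1 - 1e-6))
              else log(omega[ncat])
  if (ncat > 1) {
    for (k in seq(ncat - 1, 1)) {
      r <- min(max(omega[k] / omega[k + 1], 1e-6), 1 - 1e-6)
      xs[k] <- stats::qlogis(r)
    }
  }
  ws <- log(pmax(weight[-ncat], 1e-9) / max(weight[ncat], 1e-9))
  c(xs, ws)
}

n_dist_par <- function(ncat = 3) 2L * ncat - 1L

default_dist_starts <- function() {
  list(list(omega = c(0.05, 0.35, 1.2), weight = c(0.6, 0.3, 0.1)),
       list(omega = c(0.2, 0.8, 1.0), weight = c(0.4, 0.4, 0.2)),
       list(omega = c(0.01, 0.1, 2.5), weight = c(0.75, 0.2, 0.05)))
}

# Multi-start Nelder-Mead: short exploratory runs from each start, then a
# long refinement from the best. Objective is -loglik.
fit_multistart <- function(obj, starts, maxit_short = 120, maxit_final = 500,
                           reltol = 1e-9) {
  best <- NULL
  for (s in starts) {
    f0 <- obj(s)
    if (!is.finite(f0)) next
    r <- stats::optim(s, obj, method = "Nelder-Mead",
                      control = list(maxit = maxit_short, reltol = 1e-7))
    if (is.null(best) || r$value < best$value) best <- r
  }
  if (is.null(best)) stop("all optimizer starts failed")
  fin <- stats::optim(best$par, obj, method = "Nelder-Mead",
                      control = list(maxit = maxit_final, reltol = reltol))
  if (fin$value > best$value) fin <- best
  fin$converged <- fin$convergence == 0
  fin
}

# ---- RELAX-style group-level selection-intensity test --------------------

#' Group-level RELAX-style test of selection intensity
#'
#' Fits branch-site random-effects codon models in which every labelled
#' group shares the reference 3-category omega distribution, raised to a
#' group-specific intensity exponent `K_G` (`omega_i^K`): `K < 1` relaxes
#' selection relative to the reference group, `K > 1` intensifies it. The
#' null model fixes `K_G = 1` for every group; the alternative frees `K_G`
#' for each non-reference group. Unclassified branches receive their own
#' nuisance omega distribution in both models. The likelihood-ratio
#' statistic is referred to a chi-squared distribution with `|G| - 1`
#' degrees of freedom. A partitioned descriptive model (a free omega
#' distribution per group) is also fitted, and an AICc comparison against
#' the alternative is recorded as a fit check.
#'
#' @param aln a [codon_alignment()].
#' @param tree rooted `phylo` with branch lengths (held fixed).
#' @param partition a [label_branches()] result for `tree`.
#' @param pi,rho model parameters; `pi` defaults to F3x4 from the alignment.
#' @param fit_descriptive fit the partitioned descriptive model (default
#'   `TRUE`; skipping it saves a third fit when only the LRT is needed).
#' @param control list: `maxit_short`, `maxit_final`, `n_starts` (1-3).
#' @return object of class `relax_result`: `testable`, `reference`, `K`
#'   (named estimates with Wald CIs), `loglik_null`, `loglik_alt`, `lrt`,
#'   `df`, `p_value`, `reference_dist`, `fit_check`, `converged`,
#'   `k_at_bound`.
#' @export
fit_relax_groups <- function(aln, tree, partition, pi = NULL, rho = rep(1, 6),
                             fit_descriptive = TRUE, control = list()) {
  ctl <- utils::modifyList(list(maxit_short = 120, maxit_final = 600,
                                n_starts = 3), control)
  ref <- choose_reference_group(partition)
  if (!ref$testable) {
    return(structure(list(testable = FALSE, reason = ref$reason), class = "relax_result"))
  }
  if (is.null(pi)) pi <- f3x4_frequencies(aln)
  groups <- ref$groups
  test_groups <- groups[-1]
  has_nuis <- any(partition$edge_labels == "unclassified") ||
    any(!partition$edge_labels %in% groups)
  # branches of labelled-but-too-small groups are treated as nuisance too
  labels <- ifelse(partition$edge_labels %in% groups,
                   partition$edge_labels, "unclassified")
  np <- n_dist_par()

  build_groups <- function(refdist, kvec, nuisdist) {
    g <- list()
    g[[groups[1]]] <- refdist
    for (i in seq_along(test_groups)) {
      g[[test_groups[i]]] <- apply_k(refdist, kvec[i])
    }
    if (has_nuis) g[["unclassified"]] <- nuisdist
    g
  }
  neg_ll <- function(refdist, kvec, nuisdist) {
    gl <- build_groups(refdist, kvec, nuisdist)
    -as.numeric(codon_likelihood(aln, tree, pi, rho, gl, labels))
  }

  # null: shared reference distribution, all K = 1
  obj_null <- function(par) {
    rd <- decode_dist(par[seq_len(np)])
    nd <- if (has_nuis) decode_dist(par[np + seq_len(np)]) else NULL
    neg_ll(rd, rep(1, length(test_groups)), nd)
  }
  starts <- lapply(default_dist_starts()[seq_len(ctl$n_starts)], function(d) {
    s <- encode_dist(d$omega, d$weight)
    if (has_nuis) s <- c(s, s)
    s
  })
  fit0 <- fit_multistart(obj_null, starts, ctl$maxit_short, ctl$maxit_final)
  ll_null <- -fit0$value

  # alternative: K free per non-reference group; started at the null optimum
  # with K = 1 so the LRT cannot go negative
  nk <- length(test_groups)
  obj_alt <- function(par) {
    rd <- decode_dist(par[seq_len(np)])
    off <- np
    nd <- NULL
    if (has_nuis) { nd <- decode_dist(par[off + seq_len(np)]); off <- off + np }
    kv <- pmin(pmax(exp(par[off + seq_len(nk)]), 1e-3), 50)
    neg_ll(rd, kv, nd)
  }
  alt_starts <- list(c(fit0$par, rep(0, nk)),
                     c(fit0$par, rep(log(0.5), nk)),
                     c(fit0$par, rep(log(2), nk)))[seq_len(max(2, ctl$n_starts))]
  fita <- fit_multistart(obj_alt, alt_starts, ctl$maxit_short, ctl$maxit_final)
  # guard: the null is nested, so enforce ll_alt >= ll_null up to tolerance
  if (-fita$value < ll_null - 1e-6) {
    fita <- stats::optim(c(fit0$par, rep(0, nk)), obj_alt, method = "Nelder-Mead",
                         control = list(maxit = ctl$maxit_final, reltol = 1e-10))
    fita$converged <- TRUE
  }
  ll_alt <- max(-fita$value, ll_null)

  off <- np + if (has_nuis) np else 0
  zk <- fita$par[off + seq_len(nk)]
  K <- pmin(pmax(exp(zk), 1e-3), 50)
  names(K) <- test_groups
  k_at_bound <- K <= 1e-3 | K >= 50
  # Wald CIs on log K from a finite-difference curvature
  ci <- t(vapply(seq_len(nk), function(i) {
    h <- 0.05
    f0 <- fita$value
    pp <- fita$par; pp[off + i] <- zk[i] + h
    pm <- fita$par; pm[off + i] <- zk[i] - h
    d2 <- (obj_alt(pp) - 2 * f0 + obj_alt(pm)) / h^2
    if (!is.finite(d2) || d2 <= 0) return(c(NA_real_, NA_real_))
    se <- 1 / sqrt(d2)
    exp(c(zk[i] - 1.96 * se, zk[i] + 1.96 * se))
  }, numeric(2)))
  dimnames(ci) <- list(test_groups, c("lower", "upper"))

  lrt <- max(0, 2 * (ll_alt - ll_null))
  df <- length(groups) - 1L
  p <- stats::pchisq(lrt, df = df, lower.tail = FALSE)

  fit_check <- NULL
  if (fit_descriptive) {
    desc <- fit_descriptive_model(aln, tree, labels, groups, has_nuis, pi, rho, ctl)
    n_eff <- aln$n_sites
    k_alt <- np + nk + if (has_nuis) np else 0
    k_desc <- np * length(groups) + if (has_nuis) np else 0
    aicc <- function(ll, k) {
      pen <- if (n_eff - k - 1 > 0) 2 * k * n_eff / (n_eff - k - 1) else Inf
      -2 * ll + pen
    }
    fit_check <- list(loglik_descriptive = desc$loglik,
                      aicc_relax = aicc(ll_alt, k_alt),
                      aicc_descriptive = aicc(desc$loglik, k_desc),
                      relax_adequate = aicc(ll_alt, k_alt) <= aicc(desc$loglik, k_desc))
  }

  structure(list(
    testable = TRUE, reference = groups[1], groups = groups, K = K,
    K_ci = ci, k_at_bound = k_at_bound,
    loglik_null = ll_null, loglik_alt = ll_alt, lrt = lrt, df = df,
    p_value = p,
    reference_dist = decode_dist(fita$par[seq_len(np)]),
    fit_check = fit_check,
    converged = fit0$converged && fita$converged
  ), class = "relax_result")
}

fit_descriptive_model <- function(aln, tree, labels, groups, has_nuis, pi, rho, ctl) {
  np <- n_dist_par()
  ng <- length(groups) + if (has_nuis) 1L else 0L
  all_labels <- c(groups, if (has_nuis) "unclassified")
  obj <- function(par) {
    gl <- list()
    for (i in seq_along(all_labels)) {
      gl[[all_labels[i]]] <- decode_dist(par[(i - 1) * np + seq_len(np)])
    }
    -as.numeric(codon_likelihood(aln, tree, pi, rho, gl, labels))
  }
  starts <- lapply(default_dist_starts()[seq_len(min(2, ctl$n_starts))], function(d) {
    rep(encode_dist(d$omega, d$weight), ng)
  })
  fit <- fit_multistart(obj, starts, ctl$maxit_short, ctl$maxit_final)
  list(loglik = -fit$value, par = fit$par)
}

#' @export
print.relax_result <- function(x, ...) {
  if (!isTRUE(x$testable)) {
    cat("relax_result: untestable (", x$reason, ")\n", sep = "")
    return(invisible(x))
  }
  cat("RELAX-style group test, reference =", x$reference, "\n")
  for (g in names(x$K)) {
    cat(sprintf("  K[%s] = %.3f  (%.3f, %.3f)\n", g, x$K[g],
                x$K_ci[g, 1], x$K_ci[g, 2]))
  }
  cat(sprintf("  lnL null = %.3f  alt = %.3f  LRT = %.3f  df = %d  p = %.4g\n",
              x$loglik_null, x$loglik_alt, x$lrt, x$df, x$p_value))
  invisible(x)
}

# ---- BUSTED-style episodic diversifying selection screen -----------------

#' BUSTED-style screen for episodic diversifying selection in one group
#'
#' Tests whether the branches of `group` place nonzero weight on
#' `omega > 1`. Every labelled group keeps its own free 3-category omega
#' distribution (other groups and unclassified branches act as nuisance
#' parameters); the unconstrained model lets the tested group's top
#' category exceed 1, the constrained model caps it at 1. Because the null
#' puts the parameter on the boundary, the LRT is referred to an even
#' mixture of a point mass at zero and a chi-squared with 2 degrees of
#' freedom (a conservative convention).
#'
#' An optional 3-category synonymous rate multiplier with mean 1
#' (`syn_variation = TRUE`) absorbs site-to-site synonymous rate variation;
#' it is off by default.
#'
#' @param aln,tree,partition,pi,rho,control as in [fit_relax_groups()].
#' @param group label of the tested group (must have >= 1 branch).
#' @param syn_variation logical; include the synonymous rate mixture.
#' @return object of class `busted_result`: `group`, `loglik_unconstrained`,
#'   `loglik_constrained`, `lrt`, `p_value`, `omega3`, `omega3_weight`,
#'   `n_branches`, `converged`.
#' @export
fit_busted_s <- function(aln, tree, partition, group, pi = NULL,
                         rho = rep(1, 6), syn_variation = FALSE,
                         control = list()) {
  ctl <- utils::modifyList(list(maxit_short = 120, maxit_final = 600,
                                n_starts = 2), control)
  labels0 <- partition$edge_labels
  n_branches <- sum(labels0 == group)
  if (n_branches < 1) stop("group '", group, "' has no labelled branches")
  if (is.null(pi)) pi <- f3x4_frequencies(aln)
  # all other labels collapse into nuisance classes: keep each labelled
  # group distinct, merge unclassified
  other <- setdiff(unique(labels0), group)
  all_labels <- c(group, other)
  np <- n_dist_par()

  obj_make <- function(cap_group) {
    function(par) {
      gl <- list()
      for (i in seq_along(all_labels)) {
        gl[[all_labels[i]]] <- decode_dist(par[(i - 1) * np + seq_len(np)],
                                           cap_last = cap_group && i == 1L)
      }
      nsyn <- if (syn_variation) 3L else 1L
      if (!syn_variation) {
        return(-as.numeric(codon_likelihood(aln, tree, pi, rho, gl, labels0)))
      }
      sv <- decode_syn(par[length(all_labels) * np + seq_len(4)])
      ll_mix <- 0
      site_mat <- sapply(seq_len(3), function(r) {
        tr <- tree; tr$edge.length <- tree$edge.length * sv$rate[r]
        attr(codon_likelihood(aln, tr, pi, rho, gl, labels0), "site_loglik")
      })
      m <- apply(site_mat, 1, max)
      -sum(m + log((exp(site_mat - m) %*% sv$weight)))
    }
  }
  n_par <- length(all_labels) * np + if (syn_variation) 4L else 0L

  base_starts <- lapply(default_dist_starts()[seq_len(ctl$n_starts)], function(d) {
    s <- rep(encode_dist(d$omega, d$weight), length(all_labels))
    if (syn_variation) s <- c(s, rep(0, 4))
    s
  })
  # constrained first, then unconstrained seeded from it (ensures nesting)
  obj_con <- obj_make(TRUE)
  con_starts <- lapply(base_starts, function(s) {
    d <- decode_dist(s[seq_len(np)])
    s[seq_len(np)] <- encode_dist(pmin(d$omega, 0.99), d$weight, cap_last = TRUE)
    s
  })
  fit_con <- fit_multistart(obj_con, con_starts, ctl$maxit_short, ctl$maxit_final)
  ll_con <- -fit_con$value

  obj_unc <- obj_make(FALSE)
  seed_par <- fit_con$par
  dcon <- decode_dist(seed_par[seq_len(np)], cap_last = TRUE)
  seed_par[seq_len(np)] <- encode_dist(dcon$omega, dcon$weight)
  unc_starts <- c(list(seed_par), lapply(base_starts[seq_len(max(1, ctl$n_starts - 1))],
                                         identity))
  fit_unc <- fit_multistart(obj_unc, unc_starts, ctl$maxit_short, ctl$maxit_final)
  ll_unc <- max(-fit_unc$value, ll_con)

  dunc <- decode_dist(fit_unc$par[seq_len(np)])
  lrt <- max(0, 2 * (ll_unc - ll_con))
  p <- 0.5 * stats::pchisq(lrt, df = 2, lower.tail = FALSE) +
       0.5 * as.numeric(lrt <= 1e-9)

  structure(list(group = group, n_branches = n_branches,
                 loglik_unconstrained = ll_unc, loglik_constrained = ll_con,
                 lrt = lrt, p_value = p,
                 omega3 = dunc$omega[3], omega3_weight = dunc$weight[3],
                 syn_variation = syn_variation,
                 converged = fit_con$converged && fit_unc$converged),
            class = "busted_result")
}

decode_syn <- function(par) {
  r <- exp(par[1:2])
  rates <- c(r[1], 1, r[2])
  ew <- exp(c(par[3:4], 0)); w <- ew / sum(ew)
  rates <- rates / sum(rates * w)   # mean-1 normalisation
  list(rate = rates, weight = w)
}

#' @export
print.busted_result <- function(x, ...) {
  cat(sprintf("BUSTED-style screen, group %s (%d branches): omega3 = %.3f (w = %.3f), LRT = %.3f, p = %.4g\n",
              x$group, x$n_branches, x$omega3, x$omega3_weight, x$lrt, x$p_value))
  invisible(x)
}

# ---- multiple testing and detection-rate binning -------------------------

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up BH q values via [stats::p.adjust()]; inputs outside `[0, 1]` are
#' rejected.
#'
#' @param p numeric vector of p values.
#' @return numeric vector of q values.
#' @export
adjust_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Bin episodic-diversifying-selection detection rates by branch count
#'
#' The power of the per-group screen grows with the number of branches
#' tested, so detection rates are compared within bins of
#' `floor(n_branches / increment)`.
#'
#' @param results data.frame with columns `group`, `n_branches`, `q`.
#' @param increment bin width in branches (default 5).
#' @param q_threshold detection threshold on the q value (default 0.1).
#' @return data.frame `group`, `bin`, `n_tests`, `n_detected`, `rate`.
#' @export
bin_eds_rates <- function(results, increment = 5, q_threshold = 0.1) {
  if (increment < 1) stop("increment must be >= 1")
  if (nrow(results) == 0L) {
    return(data.frame(group = character(), bin = integer(),
                      n_tests = integer(), n_detected = integer(),
                      rate = numeric()))
  }
  bin <- results$n_branches %/% increment
  agg <- stats::aggregate(list(n_tests = rep(1L, nrow(results)),
                               n_detected = as.integer(results$q <= q_threshold)),
                          by = list(group = results$group, bin = bin), FUN = sum)
  agg$rate <- agg$n_detected / agg$n_tests
  agg[order(agg$group, agg$bin), , drop = FALSE]
}
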