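#' Parameters for the synthetic expression generator
#'
#' Defaults emulate the design of a preconditioning-style microarray study:
#' five treatment conditions by five time points with four replicates per
#' cell plus six untreated baseline controls, groups of coexpressed genes
#' driven by latent module profiles, a handful of "bridge" genes mixing two
#' module profiles (the planted bottlenecks), pure-noise background genes,
#' and optional duplicate probesets per gene.
#'
#' @param n_modules Number of latent coexpression modules (default 5).
#' @param genes_per_module Genes per module (default 40).
#' @param n_bridge_genes Bridge genes mixing two module profiles (default 6).
#' @param n_peripheral_genes Satellite genes on the periphery of a single
#'   module: part module program, part private variation (default 40).
#'   Their one weak module link makes them the first nodes to lose all
#'   edges as the Z threshold rises, so the network's node count declines
#'   smoothly with the threshold as it does in real compendia.
#' @param n_singleton_genes Differentially regulated genes driven by
#'   private per-gene response patterns, members of no module (default 0;
#'   see the package vignette for why the default benchmark omits them).
#' @param n_background_genes Pure-noise genes (default 50).
#' @param conditions Condition labels (default 5 treatments).
#' @param timepoints Time labels (default 5 time points).
#' @param replicates Replicates per condition x time cell (default 4).
#' @param n_baseline_controls Untreated baseline samples (default 6).
#' @param noise_sd Per-gene, per-sample Gaussian noise sd in log2 units
#'   (default 0.4).
#' @param amplitude Scale of the latent module profiles in log2 units
#'   (default 3): profiles have standard deviation `amplitude / 2` across
#'   the condition x time grid, so peak deviations reach about
#'   +/- `amplitude` (an 8-fold induction at the default) and module genes
#'   clear a 2-fold-change filter comfortably.
#' @param bridge_mixing Optional list of named weight vectors (names =
#'   module ids, weights summing to 1), one per bridge. Default: bridge i
#'   mixes modules i and i+1 (cyclic) with weights 0.5/0.5. The weights
#'   give the fraction of condition x time cells each parent program
#'   governs (see Details of [generate_dataset()]).
#' @param duplicate_probe_fraction Fraction of genes measured by a second,
#'   independently noisy probeset (default 0).
#' @param baseline_level Additive log2 baseline expression (default 8).
#' @param seed Integer seed; every random draw in the generator flows from
#'   it.
#' @return Validated parameter list of class `synthetic_params`.
#' @export
synthetic_params <- function(n_modules = 5L,
                             genes_per_module = 40L,
                             n_bridge_genes = 6L,
                             n_peripheral_genes = 40L,
                             n_singleton_genes = 0L,
                             n_background_genes = 50L,
                             conditions = c("LPS", "CpG", "ischemia", "saline", "sham"),
                             timepoints = c("3h", "24h", "72h", "3h_post", "24h_post"),
                             replicates = 4L,
                             n_baseline_controls = 6L,
                             noise_sd = 0.4,
                             amplitude = 3,
                             bridge_mixing = NULL,
                             duplicate_probe_fraction = 0,
                             baseline_level = 8,
                             seed = 1L) {
  p <- list(n_modules = as.integer(n_modules),
            genes_per_module = as.integer(genes_per_module),
            n_bridge_genes = as.integer(n_bridge_genes),
            n_peripheral_genes = as.integer(n_peripheral_genes),
            n_singleton_genes = as.integer(n_singleton_genes),
            n_background_genes = as.integer(n_background_genes),
            conditions = as.character(conditions),
            timepoints = as.character(timepoints),
            replicates = as.integer(replicates),
            n_baseline_controls = as.integer(n_baseline_controls),
            noise_sd = noise_sd, amplitude = amplitude,
            bridge_mixing = bridge_mixing,
            duplicate_probe_fraction = duplicate_probe_fraction,
            baseline_level = baseline_level, seed = as.integer(seed))
  if (p$n_modules < 0L || p$genes_per_module < 0L || p$n_bridge_genes < 0L ||
      p$n_peripheral_genes < 0L || p$n_singleton_genes < 0L ||
      p$n_background_genes < 0L || p$replicates < 1L ||
      p$n_baseline_controls < 1L) {
    stop("counts must be non-negative (replicates and controls >= 1)")
  }
  if (p$n_bridge_genes > 0L && p$n_modules < 2L) {
    stop("bridge genes need at least 2 modules to mix")
  }
  if (p$noise_sd <= 0) stop("noise_sd must be > 0")
  if (p$duplicate_probe_fraction < 0 || p$duplicate_probe_fraction > 1) {
    stop("duplicate_probe_fraction must lie in [0, 1]")
  }
  if (is.null(p$bridge_mixing) && p$n_bridge_genes > 0L) {
    p$bridge_mixing <- lapply(seq_len(p$n_bridge_genes), function(i) {
      m1 <- (i - 1L) %% p$n_modules + 1L
      m2 <- i %% p$n_modules + 1L
      stats::setNames(c(0.5, 0.5), module_id(c(m1, m2)))
    })
  }
  if (!is.null(p$bridge_mixing)) {
    ok <- vapply(p$bridge_mixing, function(w) {
      length(w) >= 2L && abs(sum(w) - 1) < 1e-8 &&
        all(names(w) %in% module_id(seq_len(p$n_modules)))
    }, logical(1L))
    if (!all(ok)) stop("each bridge must mix >= 2 valid modules with weights summing to 1")
  }
  class(p) <- "synthetic_params"
  p
}

module_id <- function(m) sprintf("M%d", m)

# center and scale to unit sd; degenerate (constant) vectors map to zero
unit_scale <- function(v) {
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) return(v * 0)
  (v - mean(v)) / s
}

# One latent response program over the condition x time grid: condition
# main effects + time main effects + a smooth random-walk interaction
# component, normalized to unit sd. Main effects dominate so programs are
# detectable by a main-effects ANOVA (a pure walk over the grid can by
# chance be almost all interaction and invisible to it).
latent_program <- function(n_conditions, n_timepoints) {
  n_cells <- n_conditions * n_timepoints
  a <- stats::rnorm(n_conditions)
  b <- stats::rnorm(n_timepoints)
  rw <- cumsum(stats::rnorm(n_cells))
  p <- rep(a, each = n_timepoints) + rep(b, times = n_conditions) +
    0.5 * (rw - mean(rw)) / stats::sd(rw)
  p <- p - mean(p)
  p / stats::sd(p)
}

draw_module_profiles <- function(n_modules, n_conditions, n_timepoints,
                                 amplitude) {
  n_cells <- n_conditions * n_timepoints
  comp <- t(vapply(seq_len(2L * n_modules),
                   function(m) latent_program(n_conditions, n_timepoints),
                   numeric(n_cells)))
  # orthonormalize the component programs (Gram-Schmidt over the
  # mean-centered cell space) so the designed module correlation
  # structure is realized exactly rather than up to chance correlations
  # between short component vectors
  q <- qr.Q(qr(t(comp)))
  comp <- t(q) * sqrt(n_cells - 1)             # rows: orthogonal, unit sd
  own <- comp[seq_len(n_modules), , drop = FALSE]
  junction <- comp[n_modules + seq_len(n_modules), , drop = FALSE]
  # p_m = u_m + sqrt(2) (f_{m-1} + f_m): cor(p_m, p_{m+1}) = beta^2 /
  # (alpha^2 + 2 beta^2) = 0.4 for unit-variance components, 0 otherwise.
  # Profiles are scaled to a common standard deviation (amplitude/2, so
  # the largest cell deviations reach about +/- amplitude) — a fixed sd
  # keeps the mutual-information landscape comparable across modules.
  beta <- sqrt(2)
  t(vapply(seq_len(n_modules), function(m) {
    prev <- if (m == 1L) n_modules else m - 1L
    p <- own[m, ] + beta * (junction[prev, ] + junction[m, ])
    p <- p - mean(p)
    p / stats::sd(p) * amplitude / 2
  }, numeric(n_cells)))
}

#' Generate a synthetic expression dataset with planted structure
#'
#' Latent module profiles are smooth programs over the condition x time
#' grid (condition and time main effects plus a random-walk interaction
#' component); adjacent modules (cyclically) share "junction" factors so
#' consecutive programs correlate at exactly 0.4 while non-adjacent
#' programs are uncorrelated — the component programs are orthonormalized,
#' so this correlation structure is realized exactly. A module gene is its
#' module profile times a per-gene gain (uniform on 0.35-1.5) plus i.i.d.
#' Gaussian noise.
#'
#' A bridge gene is a context-switched member of its two parent modules:
#' each condition x time cell is governed by one parent (dealt in strict
#' rotation so both parents are represented in every condition and across
#' each profile's full dynamic range), and the bridge tracks the governing
#' parent's profile exactly in that cell. Its joint distribution with
#' either parent's genes therefore concentrates on a tight ridge over the
#' governed samples, giving it strong mutual information with BOTH
#' modules — the mechanism that makes bridges inter-module connectors with
#' high betweenness in the inferred network. A small private main-effect
#' input keeps every bridge detectable by the main-effects ANOVA filter.
#'
#' Peripheral satellite genes blend one module's program with private
#' cell-level variation; singleton responders (off by default) have fully
#' private response patterns; background genes are pure noise around a
#' flat baseline. Baseline-control samples sit at profile 0, and duplicate
#' probesets re-measure a gene with independent noise.
#'
#' @param params A `synthetic_params` object.
#' @return List with `expression` (probes x samples matrix), `design`
#'   (sample-design data frame), `annotation` (probe -> gene symbol), and
#'   `truth` (planted assignments: `gene_module`, `bridge_mixing`,
#'   `profiles`, `probe_gene`, `params`).
#' @export
generate_dataset <- function(params) {
  stopifnot(inherits(params, "synthetic_params"))
  p <- params
  set.seed(p$seed)

  cells <- expand.grid(time = p$timepoints, condition = p$conditions,
                       stringsAsFactors = FALSE)[, c("condition", "time")]
  n_cells <- nrow(cells)
  cell_label <- paste(cells$condition, cells$time, sep = "_")

  profiles <- draw_module_profiles(p$n_modules, length(p$conditions),
                                   length(p$timepoints), p$amplitude)
  dimnames(profiles) <- list(module_id(seq_len(p$n_modules)), cell_label)

  genes_mod <- unlist(lapply(seq_len(p$n_modules), function(m) {
    sprintf("%sG%02d", module_id(m), seq_len(p$genes_per_module))
  }))
  genes_br <- if (p$n_bridge_genes > 0L) sprintf("BRDG%02d", seq_len(p$n_bridge_genes)) else character(0)
  genes_per <- if (p$n_peripheral_genes > 0L) sprintf("PERI%02d", seq_len(p$n_peripheral_genes)) else character(0)
  genes_sng <- if (p$n_singleton_genes > 0L) sprintf("SNG%03d", seq_len(p$n_singleton_genes)) else character(0)
  genes_bg <- if (p$n_background_genes > 0L) sprintf("BKG%03d", seq_len(p$n_background_genes)) else character(0)
  genes <- c(genes_mod, genes_br, genes_per, genes_sng, genes_bg)

  gene_module <- c(
    stats::setNames(rep(module_id(seq_len(p$n_modules)), each = p$genes_per_module), genes_mod),
    stats::setNames(rep("bridge", length(genes_br)), genes_br),
    stats::setNames(rep("peripheral", length(genes_per)), genes_per),
    stats::setNames(rep("singleton", length(genes_sng)), genes_sng),
    stats::setNames(rep("background", length(genes_bg)), genes_bg)
  )
  bridge_mixing <- if (length(genes_br) > 0L) {
    stats::setNames(p$bridge_mixing[seq_along(genes_br)], genes_br)
  } else list()

  # per-gene latent profile over grid cells (0 for background); module
  # genes respond to their driver with heterogeneous gain, as real targets
  # of a shared program do — this keeps modules coherent but not uniform,
  # so the inferred module subgraphs are blobs rather than exact cliques
  loadings <- stats::setNames(stats::runif(length(genes_mod), 0.35, 1.5), genes_mod)
  gene_prof <- matrix(0, length(genes), n_cells,
                      dimnames = list(genes, cell_label))
  for (g in genes_mod) gene_prof[g, ] <- loadings[[g]] * profiles[gene_module[[g]], ]
  # bridge genes are context-dependent members of their parent modules:
  # each experimental condition is governed by one parent program, with
  # the mixing weights giving the fraction of conditions each parent
  # controls. Under the conditions a parent governs, the bridge tracks
  # that parent's profile exactly, so its joint distribution with either
  # module's genes concentrates on a tight ridge over half the samples —
  # a strong mutual-information relationship with BOTH modules. (A plain
  # weighted average of two module profiles can correlate with each
  # parent at most sqrt((1 + rho)/2) and would never compete with
  # within-module edges after CLR background correction.)
  for (g in genes_br) {
    w <- bridge_mixing[[g]]
    # deal cells to parents in proportion to the mixing weights in strict
    # rotation over the condition x time grid (a checkerboard for two
    # equal parents): every parent then owns cells in every condition and
    # at every time, which (a) preserves the condition/time main effects
    # that the differential filter tests, and (b) spans each parent's
    # full dynamic range so neither side's relationship is erased by an
    # unlucky split
    reps <- pmax(1L, round(unname(w) * length(w)))
    cycle <- rep(names(w), times = reps)
    owner <- rep(cycle, length.out = n_cells)
    prof <- profiles[cbind(match(owner, rownames(profiles)), seq_len(n_cells))]
    prof <- unit_scale(prof)
    # a small private condition/time input keeps the bridge detectable by
    # the main-effects ANOVA even when its parents' main effects happen
    # to cancel in the switched profile
    own <- rep(stats::rnorm(length(p$conditions)), each = length(p$timepoints)) +
      rep(stats::rnorm(length(p$timepoints)), times = length(p$conditions))
    own <- (own - mean(own)) / stats::sd(own)
    prof <- prof + 0.35 * own
    gene_prof[g, ] <- unit_scale(prof) * p$amplitude / 2
  }
  # peripheral satellite genes: partially co-regulated members of one
  # module's outer shell. A satellite's profile is a blend of its module
  # program (coupling c) and private cell-level variation, so its single
  # module link is genuinely weak: satellites are the first nodes to lose
  # all edges as the threshold rises, which is what gives the network's
  # node-count curve its smooth decline. Being dead ends, they carry no
  # shortest-path traffic and never compete with bridges for betweenness.
  peripheral_module <- list()
  for (g in genes_per) {
    m <- module_id(sample.int(p$n_modules, 1L))
    peripheral_module[[g]] <- m
    cc <- stats::runif(1L, 0.45, 0.8)
    priv <- stats::rnorm(n_cells)
    priv <- (priv - mean(priv)) / stats::sd(priv)
    pr <- cc * unit_scale(profiles[m, ]) + sqrt(1 - cc^2) * priv
    gene_prof[g, ] <- unit_scale(pr) * p$amplitude / 2 * stats::runif(1L, 0.5, 1)
  }

  # singleton responders: each differentially regulated by its own private
  # response pattern, belonging to no module — the long tail of the
  # regulated transcriptome. Their patterns are condition/time main
  # effects plus cell-level (interaction) variation with no smooth-walk
  # component: rough patterns keep chance profile correlations between
  # singletons low, so they attach to the network only weakly and the node
  # count declines smoothly with the Z threshold (as in real compendia)
  # instead of saturating at the module genes.
  n_cond <- length(p$conditions); n_time <- length(p$timepoints)
  for (g in genes_sng) {
    pr <- rep(stats::rnorm(n_cond), each = n_time) +
      rep(stats::rnorm(n_time), times = n_cond) +
      stats::rnorm(n_cells)
    pr <- pr - mean(pr)
    gene_prof[g, ] <- pr / max(abs(pr)) * p$amplitude * stats::runif(1L, 0.5, 1)
  }

  treat_ids <- unlist(lapply(seq_len(n_cells), function(ci) {
    sprintf("%s_r%d", cell_label[ci], seq_len(p$replicates))
  }))
  treat_cell <- rep(seq_len(n_cells), each = p$replicates)
  ctrl_ids <- sprintf("untreated_r%d", seq_len(p$n_baseline_controls))
  design <- data.frame(
    sample_id = c(treat_ids, ctrl_ids),
    condition = c(cells$condition[treat_cell], rep("untreated", length(ctrl_ids))),
    time = c(cells$time[treat_cell], rep("0h", length(ctrl_ids))),
    replicate = c(rep(seq_len(p$replicates), times = n_cells),
                  seq_len(p$n_baseline_controls)),
    is_baseline_control = c(rep(FALSE, length(treat_ids)),
                            rep(TRUE, length(ctrl_ids))),
    stringsAsFactors = FALSE
  )

  n_dup <- round(p$duplicate_probe_fraction * length(genes))
  dup_genes <- if (n_dup > 0L) sample(genes, n_dup) else character(0)
  probe_gene <- stats::setNames(c(genes, dup_genes),
                                sprintf("ps%04d_at", seq_len(length(genes) + n_dup)))

  n_samples <- nrow(design)
  signal <- cbind(gene_prof[, treat_cell, drop = FALSE],
                  matrix(0, length(genes), length(ctrl_ids)))
  mat <- p$baseline_level + signal[probe_gene, , drop = FALSE] +
    matrix(stats::rnorm(length(probe_gene) * n_samples, sd = p$noise_sd),
           length(probe_gene), n_samples)
  dimnames(mat) <- list(names(probe_gene), design$sample_id)

  list(
    expression = mat,
    design = design,
    annotation = stats::setNames(unname(probe_gene), names(probe_gene)),
    truth = list(gene_module = gene_module,
                 peripheral_module = peripheral_module,
                 bridge_mixing = bridge_mixing,
                 profiles = profiles,
                 probe_gene = probe_gene,
                 params = p)
  )
}

#' Gene sets matching the planted modules, plus size-matched decoys
#'
#' One term per planted module containing exactly its member genes (bridge
#' genes excluded), plus `n_decoys` decoy terms of random genes drawn from
#' the full gene universe with sizes matching the module terms.
#'
#' @param truth Truth list from [generate_dataset()].
#' @param n_decoys Number of decoy terms (default 10).
#' @param seed RNG seed (default: the generator seed + 1000).
#' @return Gene-set collection (named list, as from [read_gene_sets()]).
#' @export
generate_gene_sets <- function(truth, n_decoys = 10L,
                               seed = truth$params$seed + 1000L) {
  mods <- module_id(seq_len(truth$params$n_modules))
  sets <- lapply(mods, function(m) names(truth$gene_module)[truth$gene_module == m])
  names(sets) <- sprintf("MOD_%s", mods)
  set.seed(seed)
  all_genes <- names(truth$gene_module)
  sizes <- lengths(sets)
  decoys <- lapply(seq_len(n_decoys), function(i) {
    sample(all_genes, sizes[(i - 1L) %% length(sizes) + 1L])
  })
  names(decoys) <- sprintf("DECOY_%02d", seq_len(n_decoys))
  out <- c(sets, decoys)
  attr(out, "descriptions") <- stats::setNames(
    c(sprintf("planted module %s", mods), rep("random decoy set", n_decoys)),
    names(out))
  out
}

#' Synthetic regulator-knockdown response matrix
#'
#' Emulates a regulator-perturbation screen: each module is targeted by a
#' random subset of regulators; for a targeted (module, regulator) pair a
#' shared standard-normal effect is drawn, and a module gene's response to
#' a knockdown is that shared effect plus Gaussian noise. Bridge genes mix
#' their modules' effects by their planted weights; background genes are
#' noise only. Genes of one module therefore share response structure
#' (positive expected pairwise correlation) while background pairs are
#' uncorrelated.
#'
#' @param truth Truth list from [generate_dataset()].
#' @param n_regulators Number of knocked-down regulators (default 125).
#' @param seed RNG seed.
#' @param target_prob Probability that a regulator targets a given module
#'   (default 0.25; each module is guaranteed >= 1 regulator).
#' @return Gene x perturbation numeric matrix.
#' @export
generate_knockdown_matrix <- function(truth, n_regulators = 125L, seed = 1L,
                                      target_prob = 0.25) {
  stopifnot(n_regulators >= 1L)
  p <- truth$params
  set.seed(seed)
  mods <- module_id(seq_len(p$n_modules))
  targeted <- matrix(stats::runif(p$n_modules * n_regulators) < target_prob,
                     p$n_modules, n_regulators, dimnames = list(mods, NULL))
  for (m in seq_len(p$n_modules)) {
    if (!any(targeted[m, ])) targeted[m, sample.int(n_regulators, 1L)] <- TRUE
  }
  effects <- matrix(0, p$n_modules, n_regulators, dimnames = list(mods, NULL))
  effects[targeted] <- stats::rnorm(sum(targeted))

  genes <- names(truth$gene_module)
  resp <- matrix(stats::rnorm(length(genes) * n_regulators, sd = p$noise_sd),
                 length(genes), n_regulators,
                 dimnames = list(genes, sprintf("kd_reg%03d", seq_len(n_regulators))))
  for (g in genes) {
    gm <- truth$gene_module[[g]]
    if (gm %in% mods) {
      resp[g, ] <- resp[g, ] + effects[gm, ]
    } else if (gm == "bridge") {
      w <- truth$bridge_mixing[[g]]
      resp[g, ] <- resp[g, ] + colSums(effects[names(w), , drop = FALSE] * w)
    }
  }
  resp
}

#' Calibrate a CLR Z threshold against planted edge truth
#'
#' Mirrors how a CLR threshold is calibrated against a known reference
#' network: true pairs are same-module gene pairs plus bridge-to-parent-
#' module pairs, and the returned threshold maximizes the F1 score of edge
#' recovery over the grid (ties toward the larger, more conservative
#' threshold). Run this on a dedicated calibration dataset, then carry the
#' threshold (or the node count it produces) to the evaluation datasets.
#'
#' @param clr CLR Z-score matrix of a synthetic dataset's selected probes.
#' @param annot Probe annotation of that dataset.
#' @param truth Truth list from [generate_dataset()].
#' @param z_grid Candidate thresholds.
#' @return List: `threshold`, `f1`, `precision`, `recall` at the optimum.
#' @export
calibrate_edge_threshold <- function(clr, annot, truth,
                                     z_grid = seq(1, 10, by = 0.25)) {
  probes <- rownames(clr)
  grp <- truth$gene_module[probe_genes(annot, probes)]
  mods <- module_id(seq_len(truth$params$n_modules))
  same <- outer(grp, grp, "==") & outer(grp %in% mods, grp %in% mods, "&")
  shared_pair <- matrix(FALSE, length(grp), length(grp))
  for (i in which(grp == "bridge")) {
    parents <- names(truth$bridge_mixing[[probe_genes(annot, probes[i])]])
    shared_pair[i, grp %in% parents] <- TRUE
    shared_pair[grp %in% parents, i] <- TRUE
  }
  for (i in which(grp == "peripheral")) {
    parent <- truth$peripheral_module[[probe_genes(annot, probes[i])]]
    shared_pair[i, grp %in% parent] <- TRUE
    shared_pair[grp %in% parent, i] <- TRUE
  }
  ut <- upper.tri(clr)
  truth_edge <- (same | shared_pair)[ut]
  z <- clr[ut]
  stats <- vapply(z_grid, function(zm) {
    keep <- z >= zm
    tp <- sum(truth_edge & keep)
    pr <- if (sum(keep) > 0L) tp / sum(keep) else 0
    rc <- tp / sum(truth_edge)
    c(f1 = if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0, pr = pr, rc = rc)
  }, numeric(3L))
  best <- max(which(stats["f1", ] == max(stats["f1", ])))
  list(threshold = z_grid[best], f1 = stats["f1", best],
       precision = stats["pr", best], recall = stats["rc", best])
}

#' Score bottleneck recovery against the planted truth
#'
#' Planted bridge genes are the positives; genes with at least one
#' bottleneck-flagged probeset are the predictions. Precision and recall
#' are computed at the gene level.
#'
#' @param ranking Bottleneck ranking from [rank_bottlenecks()].
#' @param truth Truth list from [generate_dataset()].
#' @return List with `precision` (NA when nothing is predicted) and
#'   `recall`.
#' @export
evaluate_recovery <- function(ranking, truth) {
  if (!any(ranking$node %in% names(truth$probe_gene))) {
    stop("ranking and truth cover disjoint probe universes")
  }
  positives <- names(truth$gene_module)[truth$gene_module == "bridge"]
  flagged <- ranking$node[ranking$is_bottleneck]
  predicted <- unique(unname(truth$probe_gene[flagged]))
  tp <- length(intersect(predicted, positives))
  list(
    precision = if (length(predicted) > 0L) tp / length(predicted) else NA_real_,
    recall = if (length(positives) > 0L) tp / length(positives) else NA_real_
  )
}
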