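#' Run a replicated simulation experiment
#'
#' Regenerates panel and traits per replicate, runs each requested method,
#' and tabulates operating characteristics. Per-replicate seeds are derived
#' deterministically from the master seed, so results are bit-reproducible.
#'
#' Methods: `gleam1` is the stage-1-only scan (identified = all loci with
#' log10 BF > delta); `gleam2` is the full two-stage procedure (identified =
#' members of the top-ranked passing subset); `lasso` and `enet` are the
#' penalized comparators (identified = nonzero coefficients at the
#' cross-validation-minimizing penalty).
#'
#' For the two-locus design the summary table follows the regional
#' accounting of admixture-mapping resolution studies: REG1/REG2/REG3
#' columns are per-locus identification rates (identified loci in the region
#' over region size, averaged over replicates), where REG1/REG2 are the
#' high-LD windows flanking the causal loci (realized dosage correlation
#' above the threshold) and REG3 the low-LD remainder; Locus1/Locus2 are the
#' fractions of replicates where only that causal locus was identified and
#' Locus12 the fraction where both were.
#'
#' @param design a [sim_design()].
#' @param methods subset of c("gleam1", "gleam2", "lasso", "enet").
#' @param cfg a [scan_config()]; its family is overridden by the design's.
#'   The harness default uses `overflow = "truncate"` so a rare replicate
#'   with more stage-1 selections than `max_selected` carries its top
#'   selections into stage 2 instead of aborting the whole experiment.
#' @param seed master seed.
#' @return list of class `experiment_result`; for the two-locus design:
#'   `table` (method x columns as above), `per_replicate` (list of identified
#'   sets and region labels), `region_sizes` (average realized sizes). For
#'   the null design: `type1` (per-replicate genome-wide type I error rates
#'   over all trait sets), `median_type1`. For the single-locus design:
#'   `power` (per-method detection frequency of the causal locus),
#'   `per_replicate` details.
#' @export
run_experiment <- function(design, methods = c("gleam1", "gleam2"),
                           cfg = scan_config(overflow = "truncate"),
                           seed = 1L) {
  stopifnot(inherits(design, "sim_design"))
  methods <- match.arg(methods, c("gleam1", "gleam2", "lasso", "enet"),
                       several.ok = TRUE)
  cfg$family <- design$family
  R <- design$n_replicates
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, max(R, 1L))
  if (R == 0) {
    return(structure(list(table = data.frame(), per_replicate = list(),
                          design = design, seed = seed),
                     class = "experiment_result"))
  }

  if (design$kind == "null") {
    type1 <- matrix(NA_real_, R, 1)
    for (r in seq_len(R)) {
      set.seed(rep_seeds[r])
      panel <- sim_panel(design)
      hits <- 0L
      total <- 0L
      for (t in seq_len(design$n_trait_sets)) {
        tr <- sim_traits(panel, design, causal = character(0))
        scan <- stage1_scan(panel, tr$y, tr$E, cfg)
        ok <- is.na(scan$results$skipped_reason)
        hits <- hits + sum(scan$results$selected[ok])
        total <- total + sum(ok)
      }
      type1[r] <- hits / total
    }
    return(structure(list(type1 = as.numeric(type1),
                          median_type1 = stats::median(type1),
                          design = design, seed = seed),
                     class = "experiment_result"))
  }

  if (design$kind == "single_locus") {
    detected <- stats::setNames(rep(0, length(methods)), methods)
    per_rep <- vector("list", R)
    for (r in seq_len(R)) {
      set.seed(rep_seeds[r])
      panel <- sim_panel(design)
      tr <- sim_traits(panel, design)
      causal <- attr(panel, "causal")
      ids <- run_methods(panel, tr, methods, cfg, design, rep_seeds[r])
      for (m in methods) {
        detected[m] <- detected[m] + (causal %in% ids[[m]])
      }
      per_rep[[r]] <- list(causal = causal, identified = ids)
    }
    return(structure(list(power = detected / R, per_replicate = per_rep,
                          design = design, seed = seed),
                     class = "experiment_result"))
  }

  # two-locus artificial chromosome: panel + traits regenerated per
  # replicate; regions are re-classified on each realized panel so the
  # tabulated rates average over the panel distribution as well
  cols <- c("REG1", "REG2", "REG3", "Locus1", "Locus2", "Locus12")
  acc <- matrix(0, length(methods), length(cols),
                dimnames = list(methods, cols))
  sizes <- c(REG1 = 0, REG2 = 0, REG3 = 0)
  per_rep <- vector("list", R)
  for (r in seq_len(R)) {
    set.seed(rep_seeds[r])
    panel <- sim_panel(design)
    tr <- sim_traits(panel, design)
    causal <- attr(panel, "causal")
    regions <- classify_regions(panel, causal, design$r_threshold)
    lab <- regions$labels
    nreg <- table(lab)
    sizes <- sizes + nreg[c("REG1", "REG2", "REG3")]
    ids <- run_methods(panel, tr, methods, cfg, design, rep_seeds[r])
    for (m in methods) {
      found <- ids[[m]]
      found_lab <- lab[match(found, panel$loci$locus_id)]
      for (rg in c("REG1", "REG2", "REG3")) {
        if (nreg[rg] > 0) {
          acc[m, rg] <- acc[m, rg] + sum(found_lab == rg, na.rm = TRUE) / nreg[rg]
        }
      }
      has1 <- causal[1] %in% found
      has2 <- causal[2] %in% found
      acc[m, "Locus1"] <- acc[m, "Locus1"] + (has1 && !has2)
      acc[m, "Locus2"] <- acc[m, "Locus2"] + (has2 && !has1)
      acc[m, "Locus12"] <- acc[m, "Locus12"] + (has1 && has2)
    }
    per_rep[[r]] <- list(causal = causal, labels = lab, identified = ids)
  }
  tab <- as.data.frame(acc / R)
  tab <- cbind(method = methods, tab, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, per_replicate = per_rep,
                 region_sizes = sizes / R, design = design, seed = seed),
            class = "experiment_result")
}

# run each requested method on one replicate; returns list of identified sets
run_methods <- function(panel, tr, methods, cfg, design, rep_seed) {
  ids <- list()
  scan <- NULL
  if (any(c("gleam1", "gleam2") %in% methods)) {
    scan <- stage1_scan(panel, tr$y, tr$E, cfg)
  }
  if ("gleam1" %in% methods) {
    ids$gleam1 <- scan$results$locus_id[scan$results$selected]
  }
  if ("gleam2" %in% methods) {
    sel <- scan$results$locus_id[scan$results$selected]
    if (length(sel) > cfg$max_selected && cfg$overflow == "truncate") {
      keep <- order(-scan$results$log10_bf[scan$results$selected])
      sel <- sel[keep[seq_len(cfg$max_selected)]]
    }
    tau_gw <- if (cfg$tau_mode == "genomewide") scan$tau$tau_hat else NULL
    if (length(sel) <= 1) {
      ids$gleam2 <- sel
    } else {
      s2 <- stage2_joint(panel, tr$y, tr$E, sel, cfg, tau_genomewide = tau_gw)
      rep_obj <- list(selected = sel, stage2 = s2, delta = cfg$delta)
      ids$gleam2 <- identify_loci(structure(rep_obj, class = "mapping_report"))
    }
  }
  for (m in intersect(c("lasso", "enet"), methods)) {
    ps <- penalized_scan(panel, tr$y, tr$E, method = m,
                         family = design$family, seed = rep_seed)
    ids[[m]] <- ps$selected
  }
  ids
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("experiment_result (", x$design$kind, ", ", x$design$family, "), ",
      x$design$n_replicates, " replicates\n", sep = "")
  if (!is.null(x$median_type1)) {
    cat("  median per-replicate type I error:",
        format(x$median_type1, digits = 3), "\n")
  }
  if (!is.null(x$power)) {
    cat("  causal-locus detection frequency:\n")
    print(round(x$power, 3))
  }
  if (!is.null(x$table) && nrow(x$table)) {
    print(cbind(x$table[1], round(x$table[-1], 3)), row.names = FALSE)
  }
  invisible(x)
}

#' Largest simulated effect size of a design
#'
#' For effect multipliers c and the causal ancestry-proportion band, the
#' largest simulated effect is max(c) times the band's upper end (for the
#' default continuous single-locus design, 0.4 x 0.8817 = 0.35268).
#'
#' @param design a [sim_design()].
#' @param c_grid the multipliers considered (default: the design's `c_mult`).
#' @return largest beta.
#' @export
max_effect_size <- function(design, c_grid = design$c_mult) {
  max(c_grid) * design$causal_pa_range[2]
}
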