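#' Local-ancestry panel
#'
#' Container for a subjects-by-loci matrix of local-ancestry dosages (0, 1 or
#' 2 allele copies inherited from the high-risk ancestral population),
#' per-locus metadata, and optionally a set of multiple-imputation draws of
#' the same matrix.
#'
#' @param S integer matrix, subjects in rows and loci in columns; entries must
#'   be 0, 1 or 2. Row and column names are used as subject and locus ids
#'   (generated when absent).
#' @param loci optional data.frame of locus metadata with columns `locus_id`,
#'   `chrom`, `pos_bp` (1-based), `cM` and `p_a` (high-risk ancestry
#'   proportion). Loci must be sorted by (chrom, pos_bp).
#' @param imputations optional list of M dosage matrices with the same
#'   dimensions as `S`, each a posterior draw of the unobserved ancestries.
#'
#' @return An object of class `ancestry_panel`: a list with elements `S`,
#'   `loci`, `imputations`, `n_subjects`, `n_loci`.
#' @export
ancestry_panel <- function(S, loci = NULL, imputations = NULL) {
  S <- as.matrix(S)
  if (is.null(rownames(S))) rownames(S) <- paste0("subj", seq_len(nrow(S)))
  if (is.null(colnames(S))) colnames(S) <- paste0("locus", seq_len(ncol(S)))
  check_dosages(S)
  if (is.null(loci)) {
    loci <- data.frame(
      locus_id = colnames(S), chrom = 1L,
      pos_bp = seq_len(ncol(S)), cM = as.numeric(seq_len(ncol(S))),
      p_a = colMeans(S) / 2, stringsAsFactors = FALSE
    )
  } else {
    loci <- as.data.frame(loci)
    need <- c("locus_id", "chrom", "pos_bp", "cM", "p_a")
    miss <- setdiff(need, names(loci))
    if (length(miss)) stop("locus metadata lacks columns: ", paste(miss, collapse = ", "))
    if (!identical(as.character(loci$locus_id), colnames(S))) {
      extra  <- setdiff(colnames(S), loci$locus_id)
      absent <- setdiff(loci$locus_id, colnames(S))
      stop("locus metadata does not match dosage columns; only in matrix: [",
           paste(extra, collapse = ","), "]; only in metadata: [",
           paste(absent, collapse = ","), "]")
    }
    o <- order(loci$chrom, loci$pos_bp)
    if (is.unsorted(o)) {
      first <- which(o != seq_along(o))[1]
      stop("loci are not sorted by (chrom, pos_bp); first violation at row ", first)
    }
    if (any(loci$p_a < 0 | loci$p_a > 1)) stop("p_a must lie in [0, 1]")
  }
  if (!is.null(imputations)) {
    stopifnot(is.list(imputations), length(imputations) >= 1)
    for (m in seq_along(imputations)) {
      D <- as.matrix(imputations[[m]])
      if (!all(dim(D) == dim(S))) stop("imputation draw ", m, " has wrong dimensions")
      check_dosages(D)
      dimnames(D) <- dimnames(S)
      imputations[[m]] <- D
    }
  }
  structure(
    list(S = S, loci = loci, imputations = imputations,
         n_subjects = nrow(S), n_loci = ncol(S)),
    class = "ancestry_panel"
  )
}

check_dosages <- function(S) {
  bad <- which(!(S %in% c(0, 1, 2)) | is.na(S))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(S)) + 1
    j <- ((bad[1] - 1) %/% nrow(S)) + 1
    stop("invalid dosage value '", S[bad[1]], "' at row ", i, ", column ", j,
         " (must be 0, 1 or 2)")
  }
  invisible(TRUE)
}

#' Dosage draws to iterate over
#'
#' Returns the list of dosage matrices a scan should average over: the
#' imputation draws when present, otherwise the panel's single matrix.
#' @param panel an [ancestry_panel].
#' @return list of matrices.
#' @keywords internal
panel_draws <- function(panel) {
  if (is.null(panel$imputations)) list(panel$S) else panel$imputations
}

#' @export
print.ancestry_panel <- function(x, ...) {
  cat("ancestry_panel:", x$n_subjects, "subjects x", x$n_loci, "loci")
  if (!is.null(x$imputations)) cat(",", length(x$imputations), "imputation draws")
  cat("\n  chrom:", paste(unique(x$loci$chrom), collapse = ","),
      "  p_a range:", sprintf("%.3f-%.3f", min(x$loci$p_a), max(x$loci$p_a)), "\n")
  invisible(x)
}
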