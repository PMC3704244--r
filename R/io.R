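#' Write / read an ancestry panel as TSV
#'
#' The dosage matrix is written as a tab-delimited table with a `subject_id`
#' first column and locus ids as header; locus metadata goes to a sibling
#' file with suffix `.loci.tsv` (columns locus_id, chrom, pos_bp, cM, p_a);
#' imputation draws, when present, to sibling files suffixed `.imp<k>.tsv`.
#'
#' @param panel an [ancestry_panel].
#' @param path path of the dosage TSV.
#' @return `write_ancestry_tsv` returns `path` invisibly; `read_ancestry_tsv`
#'   returns an [ancestry_panel].
#' @export
write_ancestry_tsv <- function(panel, path) {
  stopifnot(inherits(panel, "ancestry_panel"))
  df <- data.frame(subject_id = rownames(panel$S), panel$S,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(panel$loci, meta_path(path), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(panel$imputations)) {
    for (m in seq_along(panel$imputations)) {
      dm <- data.frame(subject_id = rownames(panel$S), panel$imputations[[m]],
                       check.names = FALSE, stringsAsFactors = FALSE)
      utils::write.table(dm, imp_path(path, m), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
  }
  invisible(path)
}

meta_path <- function(path) sub("\\.tsv$", ".loci.tsv", path)
imp_path <- function(path, m) sub("\\.tsv$", sprintf(".imp%d.tsv", m), path)

read_dosage_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character")
  S <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(!(S %in% c("0", "1", "2")))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(S)) + 1
    j <- ((bad[1] - 1) %/% nrow(S)) + 1
    stop("malformed dosage '", S[bad[1]], "' in ", basename(path),
         " at data row ", i, ", locus column ", j)
  }
  storage.mode(S) <- "integer"
  rownames(S) <- df[[1]]
  S
}

#' @rdname write_ancestry_tsv
#' @export
read_ancestry_tsv <- function(path) {
  S <- read_dosage_matrix(path)
  loci <- utils::read.table(meta_path(path), header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  imps <- NULL
  m <- 1
  while (file.exists(imp_path(path, m))) {
    imps <- c(imps, list(read_dosage_matrix(imp_path(path, m))))
    m <- m + 1
  }
  ancestry_panel(S, loci, imputations = imps)
}

#' Read a phenotype TSV and align it with a panel
#'
#' The phenotype file needs a `subject_id` column; subjects missing from
#' either side are dropped with a message.
#'
#' @param path phenotype TSV path.
#' @param panel an [ancestry_panel] to align with.
#' @param trait_col name of the trait column.
#' @param covar_cols optional character vector of covariate columns.
#' @return list with `panel` (subset to shared subjects, original order
#'   preserved), `y`, `E` (matrix or NULL), `n_dropped`.
#' @export
read_phenotype_tsv <- function(path, panel, trait_col, covar_cols = NULL) {
  ph <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(ph)) stop("phenotype file lacks subject_id column")
  for (cc in c(trait_col, covar_cols)) {
    if (!cc %in% names(ph)) stop("phenotype file lacks column '", cc, "'")
    if (!is.numeric(ph[[cc]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(ph[[cc]]))))[1]
      stop("non-numeric value in column '", cc, "' at data row ", bad)
    }
  }
  shared <- intersect(rownames(panel$S), ph$subject_id)
  if (!length(shared)) stop("no overlapping subjects between panel and phenotypes")
  n_drop <- (panel$n_subjects - length(shared)) +
    (nrow(ph) - length(shared))
  if (n_drop > 0) message(n_drop, " unmatched subject record(s) dropped")
  keep <- rownames(panel$S) %in% shared
  sub_panel <- ancestry_panel(
    panel$S[keep, , drop = FALSE], panel$loci,
    imputations = if (is.null(panel$imputations)) NULL else
      lapply(panel$imputations, function(D) D[keep, , drop = FALSE])
  )
  ph <- ph[match(rownames(sub_panel$S), ph$subject_id), , drop = FALSE]
  E <- if (length(covar_cols)) as.matrix(ph[, covar_cols, drop = FALSE]) else NULL
  list(panel = sub_panel, y = ph[[trait_col]], E = E, n_dropped = n_drop)
}

#' Write a stage-1 scan result as TSV
#'
#' Columns locus_id, beta_hat, se, log10_bf (4 decimals; selection uses full
#' precision internally), selected, skipped_reason.
#' @param scan a [stage1_scan()] result.
#' @param path output path.
#' @export
write_scan_tsv <- function(scan, path) {
  out <- scan$results
  out$log10_bf <- round(out$log10_bf, 4)
  out$beta_hat <- signif(out$beta_hat, 6)
  out$se <- signif(out$se, 6)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
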