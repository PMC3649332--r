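#' Read a two-class expression matrix from TSV/CSV
#'
#' Expects genes in rows with a leading gene-id column and a header row of
#' sample names (use `transpose = TRUE` for the other orientation). Class
#' labels come either from a two-column labels file (sample id, class) or a
#' vector supplied directly; classes must be coded 0 (reference) and 1.
#' Genes with any missing value are dropped with a message.
#'
#' @param path expression file; `.csv` is read comma-separated, anything
#'   else tab-separated.
#' @param labels a labels file path (two columns: sample, class) or a
#'   vector of 0/1 labels in column order.
#' @param transpose set when samples are in rows.
#' @return A list of class `"odp_expression"`: `gene_ids`, `matrix`
#'   (genes x samples), `labels`.
#' @export
read_expression <- function(path, labels, transpose = FALSE) {
  if (!file.exists(path)) stop("cannot read expression file: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("expression file needs id column plus samples")
  ids <- as.character(tab[[1L]])
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  if (transpose) {
    sample_ids <- ids
    ids <- colnames(mat)
    mat <- t(mat)
    colnames(mat) <- sample_ids
  }
  if (anyDuplicated(ids)) stop("duplicate gene identifiers in ", path)
  rownames(mat) <- ids

  if (is.character(labels) && length(labels) == 1L && file.exists(labels)) {
    lsep <- if (grepl("\\.csv$", labels, ignore.case = TRUE)) "," else "\t"
    ltab <- utils::read.table(labels, header = TRUE, sep = lsep,
                              stringsAsFactors = FALSE)
    if (ncol(ltab) < 2L) stop("labels file needs columns: sample, class")
    idx <- match(colnames(mat), as.character(ltab[[1L]]))
    if (anyNA(idx))
      stop("labels file is missing samples: ",
           paste(colnames(mat)[is.na(idx)], collapse = ", "))
    lab <- as.integer(ltab[[2L]][idx])
  } else {
    lab <- as.integer(labels)
    if (length(lab) != ncol(mat))
      stop("labels length must match the number of samples")
  }
  if (!all(lab %in% c(0L, 1L))) stop("class labels must be 0/1")
  if (length(unique(lab)) < 2L)
    stop("input contains a single class; both classes are required")
  if (sum(lab == 0L) < 2L) stop("class 0 needs at least 2 samples")

  keep <- stats::complete.cases(mat) & apply(is.finite(mat), 1L, all)
  if (any(!keep)) {
    message(sum(!keep), " gene(s) dropped for missing/non-finite values")
    mat <- mat[keep, , drop = FALSE]
    ids <- ids[keep]
  }
  if (nrow(mat) == 0L) stop("no complete genes left after filtering")
  structure(list(gene_ids = ids, matrix = mat, labels = lab),
            class = "odp_expression")
}

#' Write per-gene results and the fitted hyperparameters
#'
#' Writes the results table as TSV and, alongside it, a JSON sidecar with
#' the full fitted `eta` (pi0, pi1, alpha, beta, grid, p), the final
#' log-likelihood and the iteration count, sufficient to re-apply the fit
#' to new data via [read_odp_eta()].
#'
#' @param fit an `"odp_fit"`.
#' @param path output TSV path.
#' @param sidecar JSON path for the hyperparameters (default
#'   `paste0(path, ".eta.json")`).
#' @return Invisibly, the sidecar path.
#' @export
write_odp_results <- function(fit, path, sidecar = paste0(path, ".eta.json")) {
  utils::write.table(fit$results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  eta <- fit$eta
  side <- list(pi0 = eta$pi0, pi1 = eta$pi1, alpha = eta$alpha,
               beta = eta$beta, grid = as.numeric(eta$grid), p = eta$p,
               loglik = if (length(fit$loglik_trace))
                 fit$loglik_trace[length(fit$loglik_trace)] else NA,
               n_iter = fit$n_iter)
  jsonlite::write_json(side, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read hyperparameters back from a sidecar JSON
#'
#' @param path a sidecar written by [write_odp_results()].
#' @return An `"odp_eta"`.
#' @export
read_odp_eta <- function(path) {
  side <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- structure(as.numeric(side$grid), class = "odp_grid")
  p <- as.numeric(side$p)
  p <- p / sum(p)  # guard against json round-off
  odp_eta(pi0 = side$pi0, p = p, alpha = side$alpha, beta = side$beta,
          grid = grid)
}

#' Write a simulated dataset as TSV files
#'
#' Emits the expression matrix in the same format [read_expression()]
#' reads (gene-id column + sample columns), a labels file, and a truth
#' table.
#'
#' @param sim output of [odp_simulate()].
#' @param prefix file prefix; writes `<prefix>_expr.tsv`,
#'   `<prefix>_labels.tsv`, `<prefix>_truth.tsv`.
#' @return Invisibly, the three paths.
#' @export
write_simulation <- function(sim, prefix) {
  pe <- paste0(prefix, "_expr.tsv")
  pl <- paste0(prefix, "_labels.tsv")
  pt <- paste0(prefix, "_truth.tsv")
  df <- data.frame(gene_id = rownames(sim$expr), sim$expr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, pe, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = colnames(sim$expr),
                                class = sim$labels),
                     pl, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, pt, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(expr = pe, labels = pl, truth = pt))
}
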