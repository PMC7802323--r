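# Fold-change filters for gene-expression and metabolite tables, and the
# node-table export feeding external network tools.

#' Symmetric fold-change filter for gene tables
#'
#' A gene passes when the treated/control ratio or its reciprocal exceeds
#' the cutoff (3-fold by default), i.e. up- and downregulation are treated
#' symmetrically on the linear ratio scale. Features with non-positive
#' levels are skipped (flag NA) with a warning reporting the count.
#'
#' @param table data frame with \code{control} and \code{treated} columns
#'   of positive expression levels.
#' @param gene_cutoff linear fold-change cutoff (default 3).
#' @return The table with \code{fold_change} (treated/control),
#'   \code{direction} ("up"/"down") and logical \code{passes_filter}.
#' @export
fold_change_filter <- function(table, gene_cutoff = 3) {
  stopifnot(all(c("control", "treated") %in% names(table)),
            gene_cutoff > 0)
  ok <- table$control > 0 & table$treated > 0
  if (any(!ok))
    warning(sprintf("%d feature(s) with non-positive levels skipped",
                    sum(!ok)))
  fc <- ifelse(ok, table$treated / table$control, NA_real_)
  table$fold_change <- fc
  table$direction <- ifelse(fc >= 1, "up", "down")
  table$passes_filter <- ifelse(ok, pmax(fc, 1 / fc) > gene_cutoff, NA)
  table
}

#' Relative-change filter for metabolite tables
#'
#' A metabolite passes when |treated - control| / control exceeds the
#' cutoff (20\% by default), in either direction.
#'
#' @param table data frame with positive \code{control} and \code{treated}
#'   columns.
#' @param cutoff relative-change cutoff (default 0.20).
#' @return The table with \code{relative_change}, \code{direction} and
#'   logical \code{passes_filter}.
#' @export
metabolite_change_filter <- function(table, cutoff = 0.20) {
  stopifnot(all(c("control", "treated") %in% names(table)), cutoff >= 0)
  ok <- table$control > 0
  if (any(!ok))
    warning(sprintf("%d feature(s) with non-positive control levels skipped",
                    sum(!ok)))
  rel <- ifelse(ok, (table$treated - table$control) / table$control,
                NA_real_)
  table$relative_change <- rel
  table$direction <- ifelse(rel >= 0, "up", "down")
  table$passes_filter <- ifelse(ok, abs(rel) > cutoff, NA)
  table
}

#' Export flagged features as a network node table
#'
#' One row per feature passing its filter, with class, direction and the
#' change magnitude (linear fold change for genes, relative change for
#' metabolites), suitable as input to external network-construction tools.
#'
#' @param gene_table output of \code{\link{fold_change_filter}}.
#' @param metabolite_table output of \code{\link{metabolite_change_filter}}.
#' @param path optional CSV path; the header is written even when no
#'   feature is flagged.
#' @return Data frame (id, class, direction, magnitude), invisibly when
#'   written to \code{path}.
#' @export
export_network_nodes <- function(gene_table = NULL, metabolite_table = NULL,
                                 path = NULL) {
  rows <- list()
  if (!is.null(gene_table)) {
    g <- gene_table[!is.na(gene_table$passes_filter) &
                    gene_table$passes_filter, , drop = FALSE]
    if (nrow(g)) rows$genes <- data.frame(
      id = g$feature_id, class = "gene", direction = g$direction,
      magnitude = g$fold_change)
  }
  if (!is.null(metabolite_table)) {
    m <- metabolite_table[!is.na(metabolite_table$passes_filter) &
                          metabolite_table$passes_filter, , drop = FALSE]
    if (nrow(m)) rows$metab <- data.frame(
      id = m$feature_id, class = "metabolite", direction = m$direction,
      magnitude = m$relative_change)
  }
  nodes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), class = character(),
               direction = character(), magnitude = numeric())
  rownames(nodes) <- NULL
  if (!is.null(path)) {
    utils::write.csv(nodes, path, row.names = FALSE)
    return(invisible(nodes))
  }
  nodes
}
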