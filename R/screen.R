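#' Tissue-specificity expression screen
#'
#' The candidate-gene filter applied to per-gene RPKM values in
#' circumvallate papillae (CvP) versus surrounding non-taste epithelium
#' (Epi): a gene passes when `rpkm_cvp > min_cvp` AND
#' `rpkm_cvp / rpkm_epi > min_ratio`, both strictly. A gene with
#' `rpkm_epi == 0` and a passing CvP value passes (its ratio is reported as
#' `Inf`). Input order is preserved.
#'
#' @param table Data frame with columns `gene_id` (unique), `rpkm_cvp`,
#'   `rpkm_epi` (finite, >= 0).
#' @param min_cvp CvP RPKM threshold (strict `>`); default 10.
#' @param min_ratio CvP/Epi ratio threshold (strict `>`); default 3.
#' @return Object of class `screen_result`: `passing` (gene ids),
#'   `table` (input plus `ratio` and `pass` columns), `thresholds`.
#' @examples
#' tab <- data.frame(gene_id = c("a", "b", "c"),
#'                   rpkm_cvp = c(50, 10, 12),
#'                   rpkm_epi = c(5, 1, 6))
#' screen_candidates(tab)$passing  # "a": 10.0 fails the strict >, c fails ratio
#' @export
screen_candidates <- function(table, min_cvp = 10, min_ratio = 3) {
  need <- c("gene_id", "rpkm_cvp", "rpkm_epi")
  if (!is.data.frame(table) || !all(need %in% names(table))) {
    stop("table must have columns gene_id, rpkm_cvp, rpkm_epi",
         call. = FALSE)
  }
  if (anyDuplicated(table$gene_id)) {
    stop("duplicate gene ids in the expression table", call. = FALSE)
  }
  rpkm <- c(table$rpkm_cvp, table$rpkm_epi)
  if (any(!is.finite(rpkm)) || any(rpkm < 0)) {
    stop("RPKM values must be finite and >= 0", call. = FALSE)
  }
  ratio <- ifelse(table$rpkm_epi == 0, Inf,
                  table$rpkm_cvp / table$rpkm_epi)
  pass <- table$rpkm_cvp > min_cvp & ratio > min_ratio
  out <- table
  out$ratio <- ratio
  out$pass <- pass
  structure(list(passing = as.character(table$gene_id[pass]),
                 table = out,
                 thresholds = c(min_cvp = min_cvp, min_ratio = min_ratio)),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("expression screen: %d / %d genes pass (CvP > %g, ratio > %g)\n",
              length(x$passing), nrow(x$table),
              x$thresholds[["min_cvp"]], x$thresholds[["min_ratio"]]))
  invisible(x)
}

#' Flag a gene family among the screen hits
#'
#' Intersects the passing set with a gene family, given either as an id
#' vector or as a prefix (e.g. `"Tmc"` to pull out the transmembrane
#' channel-like family).
#'
#' @param result A [screen_candidates()] result.
#' @param family Character vector of gene ids, or a single prefix when
#'   `prefix = TRUE`.
#' @param prefix Interpret `family` as an id prefix.
#' @return Character vector: the passing members of the family, in screen
#'   order.
#' @export
flag_family <- function(result, family, prefix = FALSE) {
  stopifnot(inherits(result, "screen_result"))
  if (prefix) {
    stopifnot(length(family) == 1)
    result$passing[startsWith(result$passing, family)]
  } else {
    result$passing[result$passing %in% family]
  }
}

#' Read/write the screen CSV dialect
#'
#' Plain CSV with columns `gene_id, rpkm_cvp, rpkm_epi`.
#'
#' @param path CSV path.
#' @return A data frame suitable for [screen_candidates()].
#' @export
read_expression_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_expression_csv
#' @param result A `screen_result`.
#' @export
write_screen_csv <- function(result, path) {
  utils::write.csv(result$table, path, row.names = FALSE)
  invisible(path)
}
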