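.pair_table_cols <- c("id1", "id2", "n_informative", "mean", "sd",
                      "p0", "p1", "p2", "k0", "k1", "k2", "loglik",
                      "z11", "z12")

#' Combined per-pair IBS + IBD statistics
#'
#' Joins [ibs_pairs()] and [ibd_pairs()] for every pair and appends the
#' `z1` ilr coordinates of the IBS proportions (after zero replacement) —
#' the row layout written by [write_pair_table()].
#'
#' @param G a [genotype_matrix()].
#' @param freqs optional `allele_freqs` (default: full-sample counting
#'   estimates).
#' @param ... passed to [ibd_pairs()].
#' @return A tibble with one row per pair.
#' @export
pair_statistics <- function(G, freqs = NULL, ...) {
  if (is.null(freqs)) freqs <- estimate_allele_freqs(G)
  ibs <- ibs_pairs(G)
  ibd <- ibd_pairs(G, freqs = freqs, ...)
  out <- dplyr::left_join(ibs, ibd, by = c("id1", "id2"),
                          suffix = c("", ".ibd"))
  z <- ilr(replace_zeros(as.matrix(out[, c("p0", "p1", "p2")]),
                         out$n_informative), "z1")
  dplyr::mutate(out, z11 = z$zb1, z12 = z$zb2)
}

#' Write / read the pairwise-statistics table
#'
#' TSV with a fixed, documented column order (`id1 id2 n_informative mean
#' sd p0 p1 p2 k0 k1 k2 loglik z11 z12`) and numeric values at 6 decimal
#' places, so a write/read round trip reproduces values exactly at that
#' precision. An empty record set writes a header-only file.
#'
#' @param records tibble holding (at least) the fixed columns; extra
#'   columns are dropped.
#' @param path output path.
#' @return `write_pair_table()`: the path, invisibly; `read_pair_table()`:
#'   a tibble.
#' @export
write_pair_table <- function(records, path) {
  missing_cols <- setdiff(.pair_table_cols, names(records))
  if (length(missing_cols)) {
    stop("records lack columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- records[, .pair_table_cols]
  num <- setdiff(.pair_table_cols, c("id1", "id2", "n_informative"))
  df <- dplyr::mutate(df, dplyr::across(dplyr::all_of(num),
                                        ~ sprintf("%.6f", .x)))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_pair_table
#' @export
read_pair_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    id1 = "c", id2 = "c", n_informative = "i",
                    .default = readr::col_double()))
}
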