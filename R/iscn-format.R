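#' Format a parsed karyotype back to ISCN text
#'
#' Produces the canonical spelling of a parsed karyotype: normalised case and
#' spacing, clones joined by `/`, cell counts in `[n]`, abnormality tokens in
#' their original order. Sex-chromosome aneuploidies implied by the header
#' (`45,X`, `47,XXY`) are carried by the sex designation and emit no token.
#' `parse_karyotype(format_karyotype(k))` equals `k` under
#' [karyotype_equal()].
#'
#' @param k An `iscn_karyotype` object.
#' @return A single ISCN string.
#' @export
#' @examples
#' format_karyotype(parse_karyotype("MOS 45,x[12] / 46,xx[18]"))
format_karyotype <- function(k) {
  stopifnot(inherits(k, "iscn_karyotype"))
  clone_txt <- vapply(k$clones, function(cl) {
    toks <- vapply(cl$abnormalities, `[[`, character(1), "raw_token")
    toks <- toks[!is.na(toks)]
    s <- paste(c(cl$modal_number, cl$sex_designation, toks), collapse = ",")
    if (!is.na(cl$cell_count)) s <- paste0(s, "[", cl$cell_count, "]")
    s
  }, character(1))
  prefix <- if (isTRUE(k$mos_prefix)) "mos " else if (isTRUE(k$chi_prefix)) "chi " else ""
  paste0(prefix, paste(clone_txt, collapse = "/"))
}
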