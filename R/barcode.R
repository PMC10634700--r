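#' T cell functionality barcodes
#'
#' A functionality barcode is the ordered 10-bit vector of positivity over
#' the fixed marker alphabet [BARCODE_MARKERS] (TOX1, TIM3, TCF-1, CD38,
#' PD-1, EOMES, CD39, CD44, LAG-3, T-BET). Its canonical name lists the
#' positive markers, each suffixed "+", in alphabet order -- e.g.
#' `"CD44+T-BET+"` -- or `"NEG"` when all ten are negative. At most
#' 2^10 = 1024 distinct barcodes exist.
#'
#' @param bits Logical vector of length 10 in the fixed marker order, or a
#'   logical matrix with 10 columns (one barcode per row).
#' @return Canonical barcode name(s).
#' @export
barcode_name <- function(bits) {
  if (is.matrix(bits)) {
    stopifnot(ncol(bits) == length(BARCODE_MARKERS))
    return(apply(bits, 1, function(b) barcode_name(as.logical(b))))
  }
  stopifnot(length(bits) == length(BARCODE_MARKERS))
  pos <- BARCODE_MARKERS[as.logical(bits)]
  if (!length(pos)) "NEG" else paste0(pos, "+", collapse = "")
}

#' @rdname barcode_name
#' @param name A canonical barcode name.
#' @return For `parse_barcode`, the logical 10-vector of bits.
#' @export
parse_barcode <- function(name) {
  if (identical(name, "NEG")) {
    return(stats::setNames(rep(FALSE, length(BARCODE_MARKERS)), BARCODE_MARKERS))
  }
  toks <- strsplit(name, "+", fixed = TRUE)[[1]]
  bad <- setdiff(toks, BARCODE_MARKERS)
  if (length(bad)) stop("unknown barcode marker(s): ", paste(bad, collapse = ", "))
  stats::setNames(BARCODE_MARKERS %in% toks, BARCODE_MARKERS)
}

#' Assign functionality barcodes to T cells
#'
#' Every cell in a T state receives the canonical barcode name derived from
#' its positivity over the 10 barcode markers; non-T cells are left unset
#' (`NA`). Ki-67 and GrzB are separate proliferation/cytotoxicity flags and
#' are not part of the barcode.
#'
#' @param cells Cell table with states assigned (see [assign_states()]).
#' @param config A `gating_config` (defines which leaves are T states).
#' @return `cells` with a `barcode` column added.
#' @export
assign_barcodes <- function(cells, config) {
  if (is.null(cells$state)) stop("states must be assigned before barcodes")
  missing <- setdiff(BARCODE_MARKERS, names(cells))
  if (length(missing)) {
    stop("barcode marker(s) missing from cell table: ",
         paste(missing, collapse = ", "))
  }
  t_states <- taxonomy_leaves(config, t_states_only = TRUE)
  is_t <- cells$state %in% t_states
  barcode <- rep(NA_character_, nrow(cells))
  if (any(is_t)) {
    B <- vapply(BARCODE_MARKERS, function(m) as.logical(cells[[m]][is_t]),
                logical(sum(is_t)))
    if (sum(is_t) == 1L) B <- matrix(B, nrow = 1)
    barcode[is_t] <- barcode_name(B)
  }
  cells$barcode <- barcode
  cells
}
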