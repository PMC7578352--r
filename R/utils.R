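## Shared helpers: residue identifiers, canonical pair ordering, validation.

#' Build a residue identifier string
#'
#' Residues are addressed throughout the package as `"chain:resseq"` or
#' `"chain:resseq:icode"` strings, using the author numbering of the source
#' PDB file (chain label, residue sequence number, insertion code).
#'
#' @param chain Chain label(s).
#' @param resseq Author residue number(s), integer.
#' @param icode Insertion code(s); `""` when absent.
#' @return Character vector of residue identifiers.
#' @examples
#' res_id("B", 230)
#' res_id("A", c(100, 100), c("", "A"))
#' @export
res_id <- function(chain, resseq, icode = "") {
  icode <- ifelse(is.na(icode) | icode == "", "", paste0(":", icode))
  paste0(chain, ":", resseq, icode)
}

#' Parse residue identifier strings
#'
#' @param x Character vector of `"chain:resseq[:icode]"` identifiers.
#' @return A tibble with columns `chain`, `resseq` (integer), `icode`.
#' @export
parse_res_id <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)
  bad <- lengths(parts) < 2L | lengths(parts) > 3L
  if (any(bad)) {
    abort(paste0("Malformed residue id(s): ",
                 paste(x[bad], collapse = ", ")))
  }
  tibble(
    chain = vapply(parts, `[[`, "", 1L),
    resseq = as.integer(vapply(parts, `[[`, "", 2L)),
    icode = vapply(parts, function(p) if (length(p) == 3L) p[[3L]] else "", "")
  )
}

## sortable key respecting the (chain, resseq, icode) total order; author
## resseq can be negative, offset keeps lexicographic == numeric order
res_sort_key <- function(chain, resseq, icode) {
  sprintf("%s%08d%s", chain, resseq + 10000L,
          ifelse(is.na(icode), "", icode))
}

## canonical unordered-pair orientation: side 1 is the smaller residue key
canonicalize_pairs <- function(pairs) {
  k1 <- res_sort_key(pairs$chain1, pairs$resseq1, pairs$icode1)
  k2 <- res_sort_key(pairs$chain2, pairs$resseq2, pairs$icode2)
  swap <- k2 < k1
  if (any(swap)) {
    c1 <- c("chain1", "resseq1", "icode1", "resname1")
    c2 <- c("chain2", "resseq2", "icode2", "resname2")
    c1 <- intersect(c1, names(pairs))
    c2 <- intersect(c2, names(pairs))
    tmp <- pairs[swap, c1]
    pairs[swap, c1] <- pairs[swap, c2]
    pairs[swap, c2] <- tmp
  }
  pairs
}

pair_cols <- c("chain1", "resseq1", "icode1", "chain2", "resseq2", "icode2")

## deterministic pair ordering used for all outputs
arrange_pairs <- function(pairs) {
  k1 <- res_sort_key(pairs$chain1, pairs$resseq1, pairs$icode1)
  k2 <- res_sort_key(pairs$chain2, pairs$resseq2, pairs$icode2)
  pairs[order(k1, k2), , drop = FALSE]
}

stop_if_missing_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    abort(paste0(what, " is missing required column(s): ",
                 paste(miss, collapse = ", ")))
  }
}
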