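## Difference maps, threshold annotation, net change, and perturbation
## beads.
##
## Sign convention: delta = freq(WT) - freq(MUT), so a contact LOST upon
## mutation is positive and a contact GAINED is negative. A pair is
## annotated when |delta| STRICTLY exceeds the threshold fraction
## (default 0.40): with 20-model ensembles that is "discordant in more
## than 8 of the 20 models", i.e. 9 or more.

#' Difference of two ensemble contact-frequency maps
#'
#' @param wt,mut `contact_freq` objects from [contact_frequency()] for the
#'   wild-type and mutant ensembles. Both must have been computed under
#'   identical contact parameters, and (when residue keys are attached)
#'   over identical residue-key universes; residue *names* may differ at
#'   mutation sites.
#' @param threshold Annotation fraction in (0, 1); a pair is annotated when
#'   `|delta| > threshold` strictly. Default 0.40.
#' @return A `contact_diff` tibble over the union of the two pair sets:
#'   pair identity columns, `freq_wt`, `freq_mut`, `delta`, `annotated`.
#'   Pairs with zero delta are retained but never annotated. Attributes
#'   record the per-ensemble model counts, labels, parameters and
#'   threshold.
#' @export
difference_map <- function(wt, mut, threshold = 0.40) {
  if (!inherits(wt, "contact_freq") || !inherits(mut, "contact_freq")) {
    abort("`wt` and `mut` must be contact_freq objects.")
  }
  if (threshold <= 0 || threshold >= 1) {
    abort("`threshold` must lie strictly in (0, 1).")
  }
  pw <- attr(wt, "params"); pm <- attr(mut, "params")
  if (!is.null(pw) && !is.null(pm) && !identical(unclass(pw), unclass(pm))) {
    abort("Ensembles were mapped under different contact parameters.")
  }
  check_key_universes(wt, mut)

  w <- as_tibble(wt)[, c(pair_cols, "resname1", "resname2", "freq")]
  m <- as_tibble(mut)[, c(pair_cols, "resname1", "resname2", "freq")]
  j <- dplyr::full_join(w, m, by = pair_cols, suffix = c("_wt", "_mut"))
  out <- tibble(
    chain1 = j$chain1, resseq1 = j$resseq1, icode1 = j$icode1,
    resname1 = dplyr::coalesce(j$resname1_wt, j$resname1_mut),
    chain2 = j$chain2, resseq2 = j$resseq2, icode2 = j$icode2,
    resname2 = dplyr::coalesce(j$resname2_wt, j$resname2_mut),
    freq_wt = dplyr::coalesce(j$freq_wt, 0),
    freq_mut = dplyr::coalesce(j$freq_mut, 0)
  )
  out$delta <- out$freq_wt - out$freq_mut
  out$annotated <- abs(out$delta) > threshold
  out <- arrange_pairs(out)
  structure(out,
            threshold = threshold,
            n_wt = attr(wt, "n_models"), n_mut = attr(mut, "n_models"),
            label_wt = attr(wt, "label"), label_mut = attr(mut, "label"),
            params = pw %||% pm,
            class = c("contact_diff", class(out)))
}

check_key_universes <- function(wt, mut) {
  kw <- attr(wt, "residue_keys"); km <- attr(mut, "residue_keys")
  if (is.null(kw) || is.null(km)) return(invisible(NULL))
  idw <- res_id(kw$chain, kw$resseq, kw$icode)
  idm <- res_id(km$chain, km$resseq, km$icode)
  only_w <- setdiff(idw, idm); only_m <- setdiff(idm, idw)
  if (length(only_w) + length(only_m) > 0) {
    abort(paste0(
      "Residue-key universes differ between ensembles. ",
      if (length(only_w)) paste0("Only in first: ",
        paste(head(only_w, 10), collapse = ", "), ". ") else "",
      if (length(only_m)) paste0("Only in second: ",
        paste(head(only_m, 10), collapse = ", "), ".") else ""))
  }
  invisible(NULL)
}

#' Annotated (threshold-exceeding) pairs of a difference map
#'
#' @param diff A `contact_diff` object.
#' @return Tibble of the pairs with `|delta|` strictly above the map's
#'   threshold, sorted by `|delta|` descending (ties by pair order), with a
#'   `direction` column: `"loss"` for positive delta, `"gain"` for
#'   negative.
#' @export
annotate_differences <- function(diff) {
  if (!inherits(diff, "contact_diff")) abort("`diff` must be a contact_diff.")
  out <- as_tibble(diff)[diff$annotated, , drop = FALSE]
  out$direction <- ifelse(out$delta > 0, "loss", "gain")
  k1 <- res_sort_key(out$chain1, out$resseq1, out$icode1)
  k2 <- res_sort_key(out$chain2, out$resseq2, out$icode2)
  out[order(-abs(out$delta), k1, k2), , drop = FALSE]
}

#' Net change in expected contact count
#'
#' Sums delta over a selected pair set. Over all pairs this equals the
#' difference between the mean per-model contact counts of the two
#' ensembles, so a value of +5 reads as "about five inter-residue contacts
#' lost upon mutation".
#'
#' @param diff A `contact_diff` object.
#' @param restrict `"all"` (default) or `"annotated"`.
#' @param chains Optional length-2 chain-label vector: additionally
#'   restrict to inter-chain pairs between the two chains (the complex
#'   interface).
#' @return Signed scalar; positive = net loss of contacts upon mutation.
#'   An empty selection returns 0 with a warning.
#' @export
net_contact_change <- function(diff, restrict = c("all", "annotated"),
                               chains = NULL) {
  if (!inherits(diff, "contact_diff")) abort("`diff` must be a contact_diff.")
  restrict <- match.arg(restrict)
  sel <- as_tibble(diff)
  if (restrict == "annotated") sel <- sel[sel$annotated, , drop = FALSE]
  if (!is.null(chains)) {
    if (length(chains) != 2) abort("`chains` must name exactly two chains.")
    keep <- (sel$chain1 == chains[[1]] & sel$chain2 == chains[[2]]) |
            (sel$chain1 == chains[[2]] & sel$chain2 == chains[[1]])
    sel <- sel[keep, , drop = FALSE]
  }
  if (nrow(sel) == 0) {
    warn("Empty pair selection; net contact change is 0.")
    return(0)
  }
  sum(sel$delta)
}

#' Red-white-blue color for a signed perturbation
#'
#' Linear interpolation in RWB space: `delta = +1` (complete loss) maps to
#' red `(1, 0, 0)`, `0` to white `(1, 1, 1)`, `-1` (complete gain) to blue
#' `(0, 0, 1)`.
#'
#' @param delta Numeric vector in `[-1, 1]`.
#' @return Tibble with columns `r`, `g`, `b` in `[0, 1]`.
#' @export
delta_color <- function(delta) {
  if (any(abs(delta) > 1 + 1e-12)) abort("`delta` must lie in [-1, 1].")
  delta <- pmin(1, pmax(-1, delta))
  pos <- pmax(delta, 0)
  neg <- pmax(-delta, 0)
  tibble(r = 1 - neg, g = 1 - pos - neg, b = 1 - pos)
}

#' Place perturbation beads in inter-residue space
#'
#' Each perturbed pair receives a pseudo-atom at the midpoint of the two
#' residues' heavy-atom centroids in a reference model, carrying the
#' signed delta and its red-white-blue color.
#'
#' @param pairs Tibble with pair identity columns and `delta` — typically
#'   [annotate_differences()] output.
#' @param reference Atom tibble of ONE model supplying coordinates (by
#'   convention the best-scoring wild-type model).
#' @return Bead tibble: `res1`, `res2`, `x`, `y`, `z`, `delta`, `r`, `g`,
#'   `b`.
#' @export
bead_geometry <- function(pairs, reference) {
  stop_if_missing_cols(pairs, c(pair_cols, "delta"), "Pair table")
  if (dplyr::n_distinct(reference$model_id) > 1) {
    abort("`reference` must contain a single model.")
  }
  heavy <- reference[reference$is_heavy & !reference$is_het, , drop = FALSE]
  cent <- heavy |>
    dplyr::group_by(.data$chain, .data$resseq, .data$icode) |>
    dplyr::summarise(cx = mean(.data$x), cy = mean(.data$y),
                     cz = mean(.data$z), .groups = "drop")
  j1 <- dplyr::left_join(
    pairs, cent,
    by = c(chain1 = "chain", resseq1 = "resseq", icode1 = "icode"))
  j2 <- dplyr::left_join(
    pairs, cent,
    by = c(chain2 = "chain", resseq2 = "resseq", icode2 = "icode"))
  missing <- is.na(j1$cx) | is.na(j2$cx)
  if (any(missing)) {
    bad <- unique(c(
      res_id(pairs$chain1, pairs$resseq1, pairs$icode1)[is.na(j1$cx)],
      res_id(pairs$chain2, pairs$resseq2, pairs$icode2)[is.na(j2$cx)]))
    abort(paste0("Residue(s) absent from reference model: ",
                 paste(head(bad, 10), collapse = ", ")))
  }
  cols <- delta_color(pairs$delta)
  tibble(
    res1 = res_id(pairs$chain1, pairs$resseq1, pairs$icode1),
    res2 = res_id(pairs$chain2, pairs$resseq2, pairs$icode2),
    x = (j1$cx + j2$cx) / 2,
    y = (j1$cy + j2$cy) / 2,
    z = (j1$cz + j2$cz) / 2,
    delta = pairs$delta,
    r = cols$r, g = cols$g, b = cols$b
  )
}
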