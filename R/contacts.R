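## Binary residue-residue contact maps under the strict heavy-atom
## distance criterion: two residues are in contact iff ANY two heavy atoms,
## one from each, are strictly closer than the cutoff (default 4.5 Angstrom).
## Distances are compared in squared form, in double precision, so the
## boundary is exact: a pair at exactly the cutoff is NOT a contact.

#' Contact parameters
#'
#' @param cutoff Heavy-atom distance cutoff in Angstrom; a pair of residues
#'   is in contact when some inter-residue heavy-atom distance is strictly
#'   below it. Default 4.5.
#' @param min_seq_sep Minimum `|resseq|` difference for two residues of the
#'   same chain to be eligible. The default 1 excludes only self-pairs and
#'   keeps sequence-adjacent pairs; difference maps cancel contacts that
#'   never change, so trivial neighbours are harmless. Set 2+ to drop them.
#' @param include_het Include heterogroup residues (cofactors, waters) in
#'   the map. Default `FALSE`: contact analysis concerns amino-acid
#'   residues.
#' @return A list of class `contact_params`.
#' @export
contact_params <- function(cutoff = 4.5, min_seq_sep = 1L,
                           include_het = FALSE) {
  if (!is.numeric(cutoff) || cutoff <= 0) abort("`cutoff` must be > 0.")
  if (min_seq_sep < 1) abort("`min_seq_sep` must be >= 1.")
  structure(list(cutoff = cutoff, min_seq_sep = as.integer(min_seq_sep),
                 include_het = isTRUE(include_het)),
            class = "contact_params")
}

#' Are two residues in contact?
#'
#' The primitive contact predicate: `TRUE` iff some heavy atom of `r1` lies
#' strictly closer than `cutoff` to some heavy atom of `r2`.
#'
#' @param r1,r2 Atom tibbles holding the atoms of one residue each.
#' @param params A [contact_params()] object.
#' @return Logical scalar. A residue with no heavy atoms yields `FALSE`
#'   with a warning.
#' @export
residue_contact <- function(r1, r2, params = contact_params()) {
  h1 <- r1[r1$is_heavy, , drop = FALSE]
  h2 <- r2[r2$is_heavy, , drop = FALSE]
  if (nrow(h1) == 0 || nrow(h2) == 0) {
    warn("Residue with zero heavy atoms: contact is FALSE by convention.")
    return(FALSE)
  }
  dx <- outer(h1$x, h2$x, "-")
  dy <- outer(h1$y, h2$y, "-")
  dz <- outer(h1$z, h2$z, "-")
  min(dx * dx + dy * dy + dz * dz) < params$cutoff^2
}

#' Compute residue contact maps for every model in an atom table
#'
#' Enumerates, per model, all unordered residue pairs with at least one
#' heavy-atom pair strictly closer than the cutoff. A cell-list spatial
#' binning (cell edge = cutoff, 27-neighbourhood search) accelerates the
#' search; it is definitionally equivalent to the all-pairs enumeration
#' and is pinned to it by a brute-force oracle in the test suite.
#'
#' @param atoms Atom tibble (any number of models).
#' @param params A [contact_params()] object.
#' @return Tibble with one row per (model, contact pair): `model_id`,
#'   `chain1`, `resseq1`, `icode1`, `resname1`, likewise `*2`, and
#'   `min_dist`, the minimal heavy-atom distance of the pair. Pair sides
#'   are ordered canonically by (chain, resseq, icode); rows are sorted by
#'   model then pair. Attributes carry the parameters and the chain set of
#'   the source.
#' @export
contact_maps <- function(atoms, params = contact_params()) {
  stop_if_missing_cols(atoms, ATOM_COLS, "Atom table")
  a <- atoms
  if (!params$include_het) a <- a[!a$is_het, , drop = FALSE]
  chains <- unique(a$chain)
  a <- a[a$is_heavy, , drop = FALSE]
  empty <- tibble(
    model_id = character(), chain1 = character(), resseq1 = integer(),
    icode1 = character(), resname1 = character(), chain2 = character(),
    resseq2 = integer(), icode2 = character(), resname2 = character(),
    min_dist = double())
  if (nrow(a) == 0) {
    return(structure(empty, params = params, chains = chains))
  }
  a$.aid <- seq_len(nrow(a))
  cw <- params$cutoff
  cx <- floor(a$x / cw); cy <- floor(a$y / cw); cz <- floor(a$z / cw)
  cell_of <- function(m, i, j, k) paste(m, i, j, k, sep = "\r")
  a$.cell <- cell_of(a$model_id, cx, cy, cz)

  ## replicate each atom over its 27 neighbouring cells and join back
  nb <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  n <- nrow(a)
  rep_idx <- rep(seq_len(n), each = nrow(nb))
  lhs <- tibble(
    .aid = a$.aid[rep_idx],
    .cell = cell_of(a$model_id[rep_idx],
                    cx[rep_idx] + nb$dx, cy[rep_idx] + nb$dy,
                    cz[rep_idx] + nb$dz)
  )
  rhs <- tibble(.aid2 = a$.aid, .cell = a$.cell)
  cand <- dplyr::inner_join(lhs, rhs, by = ".cell",
                            relationship = "many-to-many")
  cand <- cand[cand$.aid < cand$.aid2, c(".aid", ".aid2")]
  if (nrow(cand) == 0) {
    return(structure(empty, params = params, chains = chains))
  }
  d2 <- (a$x[cand$.aid] - a$x[cand$.aid2])^2 +
        (a$y[cand$.aid] - a$y[cand$.aid2])^2 +
        (a$z[cand$.aid] - a$z[cand$.aid2])^2
  keep <- d2 < cw^2
  cand <- cand[keep, , drop = FALSE]
  d2 <- d2[keep]
  if (nrow(cand) == 0) {
    return(structure(empty, params = params, chains = chains))
  }

  pairs <- tibble(
    model_id = a$model_id[cand$.aid],
    chain1 = a$chain[cand$.aid], resseq1 = a$resseq[cand$.aid],
    icode1 = a$icode[cand$.aid], resname1 = a$resname[cand$.aid],
    chain2 = a$chain[cand$.aid2], resseq2 = a$resseq[cand$.aid2],
    icode2 = a$icode[cand$.aid2], resname2 = a$resname[cand$.aid2],
    dist = sqrt(d2)
  )
  ## residue-level eligibility: no self-pairs; same chain needs
  ## |resseq difference| >= min_seq_sep
  same_res <- pairs$chain1 == pairs$chain2 &
    pairs$resseq1 == pairs$resseq2 & pairs$icode1 == pairs$icode2
  same_chain <- pairs$chain1 == pairs$chain2
  sep_ok <- !same_chain |
    abs(pairs$resseq1 - pairs$resseq2) >= params$min_seq_sep
  pairs <- pairs[!same_res & sep_ok, , drop = FALSE]
  if (nrow(pairs) == 0) {
    return(structure(empty, params = params, chains = chains))
  }
  pairs <- canonicalize_pairs(pairs)
  out <- pairs |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("model_id", pair_cols)))) |>
    dplyr::summarise(resname1 = .data$resname1[1], resname2 = .data$resname2[1],
                     min_dist = min(.data$dist), .groups = "drop")
  out <- out[, c("model_id", "chain1", "resseq1", "icode1", "resname1",
                 "chain2", "resseq2", "icode2", "resname2", "min_dist")]
  out <- out[order(out$model_id,
                   res_sort_key(out$chain1, out$resseq1, out$icode1),
                   res_sort_key(out$chain2, out$resseq2, out$icode2)), ]
  structure(out, params = params, chains = chains)
}

#' Restrict a contact map to the interface between two chains
#'
#' @param contacts Contact tibble from [contact_maps()].
#' @param chain_a,chain_b Chain labels; pairs with one residue in each are
#'   retained.
#' @return Filtered contact tibble (same attributes).
#' @export
interface_subset <- function(contacts, chain_a, chain_b) {
  known <- attr(contacts, "chains") %||%
    unique(c(contacts$chain1, contacts$chain2))
  for (ch in c(chain_a, chain_b)) {
    if (!ch %in% known) abort(paste0("Unknown chain label '", ch, "'."))
  }
  keep <- (contacts$chain1 == chain_a & contacts$chain2 == chain_b) |
          (contacts$chain1 == chain_b & contacts$chain2 == chain_a)
  out <- contacts[keep, , drop = FALSE]
  attr(out, "params") <- attr(contacts, "params")
  attr(out, "chains") <- known
  out
}
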