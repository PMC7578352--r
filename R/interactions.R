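## Hydrogen-bond and salt-bridge detection with explicit geometric
## criteria, plus residue-residue distance measurement.
##
## Criteria follow the X-ray convention (hydrogens usually absent): an
## H-bond is a donor-acceptor heavy-atom pair within 3.5 Angstrom; a salt
## bridge is a basic side-chain nitrogen within 4.0 Angstrom of an acidic
## side-chain oxygen. Histidine counts as basic through both of its
## protonation-ambiguous ring nitrogens.

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

## side-chain donor/acceptor atom names per residue type
SIDECHAIN_DONORS <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", HIS = c("ND1", "NE2"),
  TRP = "NE1", ASN = "ND2", GLN = "NE2", SER = "OG", THR = "OG1",
  TYR = "OH")
SIDECHAIN_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"))
BASIC_ATOMS <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                    HIS = c("ND1", "NE2"))
ACIDIC_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

#' Hydrogen-bond criteria
#'
#' @param max_da Maximum donor-acceptor heavy-atom distance, Angstrom
#'   (default 3.5). No angle term by default: modelled and crystal
#'   structures commonly lack hydrogens.
#' @param donors,acceptors Named lists mapping residue names to side-chain
#'   donor/acceptor atom names. Backbone N (except proline) is always a
#'   donor and backbone O (and OXT) always an acceptor.
#' @return List of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_da = 3.5, donors = SIDECHAIN_DONORS,
                           acceptors = SIDECHAIN_ACCEPTORS) {
  if (max_da <= 0) abort("`max_da` must be > 0.")
  structure(list(max_da = max_da, donors = donors, acceptors = acceptors),
            class = "hbond_criteria")
}

atom_role_table <- function(atoms, sidechain_sets, backbone_atom,
                            backbone_ok) {
  a <- atoms[atoms$is_heavy & !atoms$is_het, , drop = FALSE]
  sc <- purrr::imap(sidechain_sets, function(at, rn) {
    a[a$resname == rn & a$atom %in% at, , drop = FALSE]
  })
  bb <- a[a$atom %in% backbone_atom & backbone_ok(a$resname), , drop = FALSE]
  dplyr::bind_rows(c(sc, list(bb = bb)))
}

#' Detect hydrogen bonds
#'
#' Enumerates all donor-acceptor heavy-atom pairs within `max_da`,
#' classifying each bond by the backbone/side-chain membership of its two
#' endpoints. The backbone atom set is fixed to N, CA, C, O.
#'
#' @param atoms Atom tibble of ONE model (error otherwise).
#' @param criteria An [hbond_criteria()] object.
#' @param restrict Optional character vector of residue ids
#'   (`"chain:resseq[:icode]"`); only bonds touching these residues are
#'   returned.
#' @return Tibble, one row per bond, ordered by donor then acceptor key:
#'   donor and acceptor identity columns (`*_chain`, `*_resseq`,
#'   `*_icode`, `*_resname`, `*_atom`), `distance` (Angstrom) and `kind`
#'   (`"sidechain-sidechain"`, `"sidechain-backbone"`,
#'   `"backbone-backbone"`).
#' @export
find_hbonds <- function(atoms, criteria = hbond_criteria(), restrict = NULL) {
  if (dplyr::n_distinct(atoms$model_id) > 1) {
    abort("`atoms` must contain a single model.")
  }
  donors <- atom_role_table(atoms, criteria$donors, "N",
                            function(rn) rn != "PRO")
  acceptors0 <- atom_role_table(atoms, criteria$acceptors, c("O", "OXT"),
                                function(rn) rep(TRUE, length(rn)))
  empty <- tibble(
    donor_chain = character(), donor_resseq = integer(),
    donor_icode = character(), donor_resname = character(),
    donor_atom = character(),
    acceptor_chain = character(), acceptor_resseq = integer(),
    acceptor_icode = character(), acceptor_resname = character(),
    acceptor_atom = character(), distance = double(), kind = character())
  if (nrow(donors) == 0 || nrow(acceptors0) == 0) return(empty)

  di <- rep(seq_len(nrow(donors)), times = nrow(acceptors0))
  ai <- rep(seq_len(nrow(acceptors0)), each = nrow(donors))
  same_res <- donors$chain[di] == acceptors0$chain[ai] &
    donors$resseq[di] == acceptors0$resseq[ai] &
    donors$icode[di] == acceptors0$icode[ai]
  d2 <- (donors$x[di] - acceptors0$x[ai])^2 +
        (donors$y[di] - acceptors0$y[ai])^2 +
        (donors$z[di] - acceptors0$z[ai])^2
  keep <- !same_res & d2 <= criteria$max_da^2
  di <- di[keep]; ai <- ai[keep]
  out <- tibble(
    donor_chain = donors$chain[di], donor_resseq = donors$resseq[di],
    donor_icode = donors$icode[di], donor_resname = donors$resname[di],
    donor_atom = donors$atom[di],
    acceptor_chain = acceptors0$chain[ai],
    acceptor_resseq = acceptors0$resseq[ai],
    acceptor_icode = acceptors0$icode[ai],
    acceptor_resname = acceptors0$resname[ai],
    acceptor_atom = acceptors0$atom[ai],
    distance = sqrt(d2[keep]),
    kind = paste0(
      ifelse(donors$atom[di] %in% BACKBONE_ATOMS, "backbone", "sidechain"),
      "-",
      ifelse(acceptors0$atom[ai] %in% BACKBONE_ATOMS, "backbone",
             "sidechain"))
  )
  out$kind[out$kind == "backbone-sidechain"] <- "sidechain-backbone"
  if (!is.null(restrict)) {
    rk <- parse_res_id(restrict)
    ids <- res_id(rk$chain, rk$resseq, rk$icode)
    keep <- res_id(out$donor_chain, out$donor_resseq,
                   out$donor_icode) %in% ids |
            res_id(out$acceptor_chain, out$acceptor_resseq,
                   out$acceptor_icode) %in% ids
    out <- out[keep, , drop = FALSE]
  }
  out[order(res_sort_key(out$donor_chain, out$donor_resseq, out$donor_icode),
            res_sort_key(out$acceptor_chain, out$acceptor_resseq,
                         out$acceptor_icode),
            out$donor_atom, out$acceptor_atom), , drop = FALSE]
}

#' Detect salt bridges
#'
#' One bridge is reported per (basic residue, acidic residue) pair whose
#' minimal nitrogen-oxygen distance over the charged atom sets (Arg
#' NE/NH1/NH2, Lys NZ, His ND1/NE2 vs Asp OD1/OD2, Glu OE1/OE2) is at most
#' the cutoff.
#'
#' @param atoms Atom tibble of ONE model.
#' @param cutoff Bridge cutoff in Angstrom (default 4.0).
#' @return Tibble with basic and acidic residue identity columns and
#'   `min_no_distance`, ordered by basic then acidic key.
#' @export
find_salt_bridges <- function(atoms, cutoff = 4.0) {
  if (dplyr::n_distinct(atoms$model_id) > 1) {
    abort("`atoms` must contain a single model.")
  }
  basic <- atom_role_table(atoms, BASIC_ATOMS, character(),
                           function(rn) rep(FALSE, length(rn)))
  acidic <- atom_role_table(atoms, ACIDIC_ATOMS, character(),
                            function(rn) rep(FALSE, length(rn)))
  empty <- tibble(
    basic_chain = character(), basic_resseq = integer(),
    basic_icode = character(), basic_resname = character(),
    acidic_chain = character(), acidic_resseq = integer(),
    acidic_icode = character(), acidic_resname = character(),
    min_no_distance = double())
  if (nrow(basic) == 0 || nrow(acidic) == 0) return(empty)
  bi <- rep(seq_len(nrow(basic)), times = nrow(acidic))
  ai <- rep(seq_len(nrow(acidic)), each = nrow(basic))
  d <- sqrt((basic$x[bi] - acidic$x[ai])^2 +
            (basic$y[bi] - acidic$y[ai])^2 +
            (basic$z[bi] - acidic$z[ai])^2)
  out <- tibble(
    basic_chain = basic$chain[bi], basic_resseq = basic$resseq[bi],
    basic_icode = basic$icode[bi], basic_resname = basic$resname[bi],
    acidic_chain = acidic$chain[ai], acidic_resseq = acidic$resseq[ai],
    acidic_icode = acidic$icode[ai], acidic_resname = acidic$resname[ai],
    d = d) |>
    dplyr::group_by(dplyr::across(-"d")) |>
    dplyr::summarise(min_no_distance = min(.data$d), .groups = "drop") |>
    dplyr::filter(.data$min_no_distance <= cutoff)
  out[order(res_sort_key(out$basic_chain, out$basic_resseq, out$basic_icode),
            res_sort_key(out$acidic_chain, out$acidic_resseq,
                         out$acidic_icode)), , drop = FALSE]
}

#' Distance between two residues
#'
#' @param atoms Atom tibble of ONE model.
#' @param key_a,key_b Residue ids (`"chain:resseq[:icode]"`).
#' @param mode `"min"` (minimal heavy-atom distance, default), `"ca"`
#'   (CA-CA) or `"centroid"` (heavy-atom centroids).
#' @return Non-negative distance in Angstrom; symmetric in its arguments.
#' @export
residue_distance <- function(atoms, key_a, key_b,
                             mode = c("min", "ca", "centroid")) {
  mode <- match.arg(mode)
  if (dplyr::n_distinct(atoms$model_id) > 1) {
    abort("`atoms` must contain a single model.")
  }
  get_res <- function(key) {
    k <- parse_res_id(key)
    r <- atoms[atoms$chain == k$chain & atoms$resseq == k$resseq &
               atoms$icode == k$icode & atoms$is_heavy, , drop = FALSE]
    if (nrow(r) == 0) abort(paste0("Residue '", key, "' not found ",
                                   "(or has no heavy atoms)."))
    r
  }
  a <- get_res(key_a); b <- get_res(key_b)
  if (mode == "ca") {
    a <- a[a$atom == "CA", , drop = FALSE]
    b <- b[b$atom == "CA", , drop = FALSE]
    if (nrow(a) == 0 || nrow(b) == 0) {
      abort("CA-CA mode requires a CA atom in both residues.")
    }
  }
  if (mode == "centroid") {
    return(sqrt(sum((c(mean(a$x), mean(a$y), mean(a$z)) -
                     c(mean(b$x), mean(b$y), mean(b$z)))^2)))
  }
  dx <- outer(a$x, b$x, "-")
  dy <- outer(a$y, b$y, "-")
  dz <- outer(a$z, b$z, "-")
  sqrt(min(dx * dx + dy * dy + dz * dz))
}
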