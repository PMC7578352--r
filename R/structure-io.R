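## PDB reading/writing and the flat atom-table data model.
##
## A "model set" is a plain tibble with one row per atom and a `model_id`
## column; every downstream stage consumes this table. Parsing is delegated
## to bio3d; this module resolves alternate locations, flags hydrogens and
## heterogroups, and enforces the shared-residue-numbering invariant that
## ensemble comparison relies on.

ATOM_COLS <- c("model_id", "chain", "resseq", "icode", "resname", "atom",
               "element", "x", "y", "z", "occupancy", "bfactor", "altloc",
               "is_heavy", "is_het")

#' Read PDB structures into a flat atom table
#'
#' Reads one or more PDB files (plain paths or globs) into a single tibble
#' with one row per atom. Multi-MODEL files contribute one model per
#' MODEL/ENDMDL block; single-model files contribute one model each. All
#' models read in one call form an ensemble and must share an identical set
#' of residue keys (chain, author residue number, insertion code) over
#' standard residues — residue *names* may differ, which is exactly what a
#' point mutation looks like across wild-type and mutant models built on a
#' common template.
#'
#' Alternate locations are resolved by keeping the highest-occupancy
#' conformer (ties broken by altloc letter, 'A' first). Hydrogens are
#' retained but flagged `is_heavy = FALSE`; heterogroups (cofactors,
#' waters) are retained with `is_het = TRUE` and excluded from contact
#' analysis by default downstream.
#'
#' @param paths Character vector of file paths or glob patterns.
#' @param check_keys Validate that all models share one residue-key set
#'   (default `TRUE`). Disable when deliberately reading unrelated
#'   structures in one call.
#' @return A tibble with columns `model_id`, `chain`, `resseq`, `icode`,
#'   `resname`, `atom`, `element`, `x`, `y`, `z`, `occupancy`, `bfactor`,
#'   `altloc`, `is_heavy`, `is_het`.
#' @seealso [residue_keys()], [write_structures()]
#' @export
read_structures <- function(paths, check_keys = TRUE) {
  files <- unlist(lapply(paths, function(p) {
    hits <- Sys.glob(p)
    if (length(hits) == 0 && file.exists(p)) p else hits
  }))
  files <- unique(files)
  if (length(files) == 0) {
    abort(paste0("No files found for: ", paste(paths, collapse = ", ")))
  }
  atoms <- dplyr::bind_rows(lapply(files, read_one_pdb))
  if (nrow(atoms) == 0) {
    abort("No atoms parsed from any input file.")
  }
  if (check_keys) check_shared_keys(atoms)
  atoms
}

## MODEL blocks of one file must list identical atoms (names may differ
## only in the residue-name field); checked on the raw records because a
## multi-model container cannot represent diverging numbering
check_model_blocks <- function(file) {
  lines <- readLines(file, warn = FALSE)
  starts <- grep("^MODEL", lines)
  if (length(starts) < 2) return(invisible(NULL))
  ends <- grep("^ENDMDL", lines)
  if (length(ends) != length(starts)) {
    abort(paste0("Unbalanced MODEL/ENDMDL records in '", file, "'."))
  }
  res_keys <- function(i) {
    blk <- lines[starts[[i]]:ends[[i]]]
    at <- blk[grepl("^(ATOM|HETATM)", blk)]
    unique(paste0(trimws(substr(at, 22, 22)), ":",
                  trimws(substr(at, 23, 26)),
                  ifelse(substr(at, 27, 27) == " ", "",
                         paste0(":", substr(at, 27, 27)))))
  }
  ref <- res_keys(1)
  for (i in seq_along(starts)[-1]) {
    cur <- res_keys(i)
    extra <- setdiff(cur, ref); missing <- setdiff(ref, cur)
    if (length(extra) + length(missing) > 0) {
      abort(paste0(
        "MODEL blocks 1 and ", i, " of '", basename(file),
        "' do not share residue keys. ",
        if (length(missing)) paste0("Missing: ",
          paste(head(missing, 10), collapse = ", "), ". ") else "",
        if (length(extra)) paste0("Extra: ",
          paste(head(extra, 10), collapse = ", "), ".") else ""))
    }
  }
  invisible(NULL)
}

read_one_pdb <- function(file) {
  check_model_blocks(file)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(file, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) abort(paste0("Cannot parse PDB file '", file,
                                     "': ", conditionMessage(e)))
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) {
    abort(paste0("PDB file '", file, "' contains no ATOM/HETATM records."))
  }
  element <- infer_elements(at$elesy, at$elety, file)
  base <- tibble(
    chain = ifelse(is.na(at$chain), "", at$chain),
    resseq = as.integer(at$resno),
    icode = ifelse(is.na(at$insert), "", at$insert),
    resname = at$resid,
    atom = at$elety,
    element = element,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    bfactor = ifelse(is.na(at$b), 0, at$b),
    altloc = ifelse(is.na(at$alt), "", at$alt),
    is_heavy = !element %in% c("H", "D"),
    is_het = at$type == "HETATM"
  )
  keep <- resolve_altlocs(base)
  nmod <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  stem <- tools::file_path_sans_ext(basename(file))
  out <- lapply(seq_len(nmod), function(m) {
    xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[m, ] else as.numeric(pdb$xyz)
    crd <- matrix(xyz, ncol = 3, byrow = TRUE)
    df <- base
    df$x <- crd[, 1]
    df$y <- crd[, 2]
    df$z <- crd[, 3]
    df <- df[keep, , drop = FALSE]
    df$model_id <- if (nmod == 1L) stem else sprintf("%s#%d", stem, m)
    df[, ATOM_COLS]
  })
  dplyr::bind_rows(out)
}

## element column may be blank in model-pipeline output; fall back to the
## atom-name convention (leading digits stripped, H* means hydrogen)
infer_elements <- function(elesy, elety, file) {
  elesy <- ifelse(is.na(elesy), "", trimws(elesy))
  blank <- elesy == ""
  if (any(blank)) {
    nm <- gsub("^[0-9']+", "", trimws(elety[blank]))
    first <- toupper(substr(nm, 1, 1))
    elesy[blank] <- ifelse(first == "H", "H", first)
    inform(sprintf(
      "%s: element inferred from atom name for %d atom(s).",
      basename(file), sum(blank)))
  }
  toupper(elesy)
}

## one retained atom per (residue, atom name): highest occupancy wins,
## ties broken by altloc letter
resolve_altlocs <- function(base) {
  key <- paste(base$chain, base$resseq, base$icode, base$atom, sep = "\r")
  ord <- order(key, -base$occupancy, base$altloc)
  keep <- logical(nrow(base))
  keep[ord] <- !duplicated(key[ord])
  keep
}

check_shared_keys <- function(atoms) {
  std <- atoms[!atoms$is_het, , drop = FALSE]
  if (nrow(std) == 0) return(invisible(atoms))  # heterogroup-only input
  keysets <- split(res_id(std$chain, std$resseq, std$icode), std$model_id)
  keysets <- lapply(keysets, unique)
  ref_id <- names(keysets)[[1]]
  ref <- keysets[[1]]
  for (m in names(keysets)[-1]) {
    extra <- setdiff(keysets[[m]], ref)
    missing <- setdiff(ref, keysets[[m]])
    if (length(extra) + length(missing) > 0) {
      abort(paste0(
        "Models '", ref_id, "' and '", m, "' do not share residue keys. ",
        if (length(missing)) paste0("Missing in '", m, "': ",
          paste(head(missing, 10), collapse = ", "), ". ") else "",
        if (length(extra)) paste0("Extra in '", m, "': ",
          paste(head(extra, 10), collapse = ", "), ".") else ""))
    }
  }
  invisible(atoms)
}

#' List the residue keys of an atom table
#'
#' @param atoms Atom tibble from [read_structures()] or the synthetic
#'   generator.
#' @param include_het Include heterogroup residues (default `FALSE`).
#' @return Tibble with one row per distinct residue key: `chain`, `resseq`,
#'   `icode`, `resname`, in (chain, resseq, icode) order.
#' @export
residue_keys <- function(atoms, include_het = FALSE) {
  a <- if (include_het) atoms else atoms[!atoms$is_het, , drop = FALSE]
  out <- dplyr::distinct(a, .data$chain, .data$resseq, .data$icode,
                         .data$resname)
  out[order(res_sort_key(out$chain, out$resseq, out$icode)), , drop = FALSE]
}

#' Extract the atoms of one model
#'
#' @param atoms Atom tibble.
#' @param id Model id; defaults to the first model in the table.
#' @return Atom tibble restricted to one model.
#' @export
model_atoms <- function(atoms, id = NULL) {
  id <- id %||% atoms$model_id[[1]]
  out <- atoms[atoms$model_id == id, , drop = FALSE]
  if (nrow(out) == 0) abort(paste0("No model with id '", id, "'."))
  out
}

#' Write an atom table to PDB files, one per model
#'
#' @param atoms Atom tibble.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written (named by model id).
#' @export
write_structures <- function(atoms, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ids <- unique(atoms$model_id)
  paths <- vapply(ids, function(id) {
    a <- atoms[atoms$model_id == id, , drop = FALSE]
    path <- file.path(dir, paste0(gsub("[^A-Za-z0-9_.#-]", "_", id), ".pdb"))
    bio3d::write.pdb(
      file = path,
      xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
      type = ifelse(a$is_het, "HETATM", "ATOM"),
      eleno = seq_len(nrow(a)),
      elety = a$atom,
      resid = a$resname,
      chain = a$chain,
      resno = a$resseq,
      insert = ifelse(a$icode == "", NA, a$icode),
      o = a$occupancy,
      b = a$bfactor,
      elesy = a$element
    )
    path
  }, "")
  invisible(setNames(paths, ids))
}

#' Write perturbation beads as a PDB of pseudo-atoms
#'
#' Each bead becomes one HETATM pseudo-atom (residue name `BED`) whose
#' B-factor column carries the signed perturbation magnitude, rounded to
#' two decimals — the PDB convention that lets molecular viewers color the
#' beads directly. A companion TSV records the exact magnitude and the
#' red-white-blue RGB triple per bead.
#'
#' @param beads Bead tibble from [bead_geometry()] (columns `x`, `y`, `z`,
#'   `delta`, `r`, `g`, `b`, plus pair identity columns).
#' @param path Output PDB path.
#' @param colors_path Output TSV path; defaults to `<path>_colors.tsv`
#'   next to the PDB.
#' @return Invisibly, `path`.
#' @export
write_bead_pdb <- function(beads, path,
                           colors_path = paste0(
                             tools::file_path_sans_ext(path), "_colors.tsv")) {
  stop_if_missing_cols(beads, c("x", "y", "z", "delta"), "Bead table")
  if (nrow(beads) > 0 && any(abs(beads$delta) > 1 + 1e-12)) {
    abort("Bead magnitudes must lie in [-1, 1].")
  }
  if (nrow(beads) == 0) {
    writeLines(c("REMARK   perturbation beads (none)", "END"), path)
  } else {
    bio3d::write.pdb(
      file = path,
      xyz = as.numeric(t(as.matrix(beads[, c("x", "y", "z")]))),
      type = rep("HETATM", nrow(beads)),
      eleno = seq_len(nrow(beads)),
      elety = rep("BD", nrow(beads)),
      resid = rep("BED", nrow(beads)),
      chain = rep("X", nrow(beads)),
      resno = seq_len(nrow(beads)),
      o = rep(1, nrow(beads)),
      b = round(beads$delta, 2),
      elesy = rep("C", nrow(beads))
    )
  }
  cols <- intersect(c("res1", "res2", "x", "y", "z", "delta", "r", "g", "b"),
                    names(beads))
  readr::write_tsv(beads[, cols, drop = FALSE], colors_path)
  invisible(path)
}
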