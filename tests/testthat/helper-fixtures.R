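## Fixture builders and independent oracles shared across tests.

## one atom row in the package's flat atom-table shape
atom_row <- function(model = "m1", chain = "A", resseq = 1L, resname = "GLY",
                     atom = "CA", x = 0, y = 0, z = 0, element = NULL,
                     icode = "", is_het = FALSE) {
  element <- element %||% substr(atom, 1, 1)
  tibble::tibble(
    model_id = model, chain = chain, resseq = as.integer(resseq),
    icode = icode, resname = resname, atom = atom, element = element,
    x = x, y = y, z = z, occupancy = 1, bfactor = 0, altloc = "",
    is_heavy = !element %in% c("H", "D"), is_het = is_het)
}

`%||%` <- rlang::`%||%`

## raw PDB text line, independent of the package's writer
pdb_line <- function(serial, name, resname, chain, resseq, x, y, z,
                     occ = 1, b = 0, altloc = " ", icode = " ",
                     element = NULL, record = "ATOM") {
  element <- element %||% substr(name, 1, 1)
  sprintf("%-6s%5d  %-3s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, altloc, resname, chain, resseq, icode,
          x, y, z, occ, b, element)
}

write_pdb_fixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

## brute-force contact oracle: plain double loop over residue pairs and
## all heavy-atom pairs; no spatial binning, no shared code path
brute_contact_map <- function(atoms, cutoff = 4.5, min_seq_sep = 1,
                              include_het = FALSE) {
  a <- atoms[atoms$is_heavy, , drop = FALSE]
  if (!include_het) a <- a[!a$is_het, , drop = FALSE]
  out <- list()
  for (mid in unique(a$model_id)) {
    m <- a[a$model_id == mid, , drop = FALSE]
    keys <- unique(paste(m$chain, m$resseq, m$icode, sep = "|"))
    if (length(keys) < 2) next
    for (i in seq_len(length(keys) - 1)) {
      for (j in seq(i + 1, length(keys))) {
        ki <- strsplit(keys[[i]], "|", fixed = TRUE)[[1]]
        kj <- strsplit(keys[[j]], "|", fixed = TRUE)[[1]]
        if (ki[[1]] == kj[[1]] &&
            abs(as.integer(ki[[2]]) - as.integer(kj[[2]])) < min_seq_sep) {
          next
        }
        ri <- m[m$chain == ki[[1]] & m$resseq == as.integer(ki[[2]]) &
                m$icode == (if (length(ki) > 2) ki[[3]] else ""), ]
        rj <- m[m$chain == kj[[1]] & m$resseq == as.integer(kj[[2]]) &
                m$icode == (if (length(kj) > 2) kj[[3]] else ""), ]
        hit <- FALSE
        for (p in seq_len(nrow(ri))) {
          for (q in seq_len(nrow(rj))) {
            d <- sqrt((ri$x[[p]] - rj$x[[q]])^2 +
                      (ri$y[[p]] - rj$y[[q]])^2 +
                      (ri$z[[p]] - rj$z[[q]])^2)
            if (d < cutoff) { hit <- TRUE; break }
          }
          if (hit) break
        }
        if (hit) {
          pair <- sort(c(keys[[i]], keys[[j]]))
          out[[length(out) + 1]] <- paste(mid, pair[[1]], pair[[2]])
        }
      }
    }
  }
  out <- unlist(out)
  if (is.null(out)) character(0) else sort(out)
}

## residues as vertical atom stacks at random xy positions: every residue
## has an atom at z = 0, so the minimal inter-residue atom distance never
## exceeds the centroid distance (compact, axis-aligned geometry)
random_stack_model <- function(seed, n_res = 10, box = 25) {
  withr::with_seed(seed, {
    dplyr::bind_rows(lapply(seq_len(n_res), function(i) {
      k <- sample(1:4, 1)
      cx <- runif(1, 0, box); cy <- runif(1, 0, box)
      dplyr::bind_rows(lapply(seq_len(k), function(j) {
        atom_row(chain = "A", resseq = i,
                 atom = c("CA", "CB", "CG", "CD")[[j]],
                 x = cx, y = cy, z = (j - 1) * 1.2)
      }))
    }))
  })
}

## contact tibble -> comparable key strings matching the oracle's format
contact_keys <- function(cm) {
  if (nrow(cm) == 0) return(character())
  p1 <- paste(cm$chain1, cm$resseq1, cm$icode1, sep = "|")
  p2 <- paste(cm$chain2, cm$resseq2, cm$icode2, sep = "|")
  lo <- pmin(p1, p2); hi <- pmax(p1, p2)
  sort(paste(cm$model_id, lo, hi))
}

## random toy model: a few residues of 1-3 atoms scattered in a box small
## enough that contacts actually occur
random_toy_model <- function(seed, n_res = 15, box = 18) {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_res), function(i) {
      chain <- if (i <= n_res / 2) "A" else "B"
      resseq <- if (chain == "A") i else i - floor(n_res / 2)
      centre <- runif(3, 0, box)
      k <- sample(1:3, 1)
      dplyr::bind_rows(lapply(seq_len(k), function(j) {
        atom_row(chain = chain, resseq = resseq,
                 atom = c("CA", "CB", "CG")[[j]],
                 x = centre[[1]] + rnorm(1, 0, 0.8),
                 y = centre[[2]] + rnorm(1, 0, 0.8),
                 z = centre[[3]] + rnorm(1, 0, 0.8))
      }))
    })
    dplyr::bind_rows(rows)
  })
}

## two-atom system: single-carbon residues separated by d along x
two_atom_system <- function(d) {
  dplyr::bind_rows(
    atom_row(chain = "A", resseq = 1, x = 0),
    atom_row(chain = "B", resseq = 1, x = d))
}

## hand-built contact_freq from designed counts (count/n by construction)
freq_from_counts <- function(counts, n, label = "X") {
  ## counts: tibble res1, res2, k (models in contact)
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    if (counts$k[[i]] == 0) return(NULL)
    k1 <- contactdiff::parse_res_id(counts$res1[[i]])
    k2 <- contactdiff::parse_res_id(counts$res2[[i]])
    tibble::tibble(
      model_id = sprintf("%s_%02d", label, seq_len(counts$k[[i]])),
      chain1 = k1$chain, resseq1 = k1$resseq, icode1 = k1$icode,
      resname1 = "ALA",
      chain2 = k2$chain, resseq2 = k2$resseq, icode2 = k2$icode,
      resname2 = "ALA", min_dist = 3.8)
  })
  contacts <- dplyr::bind_rows(rows)
  attr(contacts, "params") <- contactdiff::contact_params()
  contactdiff::contact_frequency(contacts, n_models = n, label = label)
}

## Arg/Asp bidentate guanidino-carboxylate geometry: NH1-OD1 2.9 A and
## NH2-OD2 3.1 A; NE kept away from both oxygens
arg_asp_model <- function() {
  dplyr::bind_rows(
    atom_row(chain = "B", resseq = 230, resname = "ARG", atom = "NE",
             element = "N", x = 1, y = -2, z = 0),
    atom_row(chain = "B", resseq = 230, resname = "ARG", atom = "NH1",
             element = "N", x = 0, y = 0, z = 0),
    atom_row(chain = "B", resseq = 230, resname = "ARG", atom = "NH2",
             element = "N", x = 2, y = 0, z = 0),
    atom_row(chain = "B", resseq = 230, resname = "ARG", atom = "CZ",
             element = "C", x = 1, y = -0.8, z = 0),
    atom_row(chain = "B", resseq = 224, resname = "ASP", atom = "OD1",
             element = "O", x = 0, y = 2.9, z = 0),
    atom_row(chain = "B", resseq = 224, resname = "ASP", atom = "OD2",
             element = "O", x = 2, y = 3.1, z = 0),
    atom_row(chain = "B", resseq = 224, resname = "ASP", atom = "CG",
             element = "C", x = 1, y = 3.8, z = 0))
}
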