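## Deterministic toy complexes and wild-type/mutant model ensembles with
## designed contact perturbations.
##
## Geometry is engineered around the 4.5-Angstrom contact cutoff with wide
## safety margins: designed contacts sit at 3.8 Angstrom nearest-atom
## separation, broken states at 8, and all non-designed residue pairs at
## 10 or more. With the default coordinate jitter (sd 0.05 Angstrom) every
## designed relation stays >= 10 standard deviations from the boundary, so
## random jitter cannot flip a contact. Residues are coarse beads of 1-4
## carbon atoms stacked along z; residue centres live in the z = 0 plane,
## so nearest-atom separation equals centre separation.

RES_SPACING <- 10
CHAIN_SPACING <- 30
CONTACT_D <- 3.8
BROKEN_D <- 8
ATOM_Z_STEP <- 1.2
ATOM_NAMES <- c("CA", "CB", "CG", "CD")

#' Specify a synthetic model ensemble
#'
#' Describes a toy two-or-more-chain complex and a controlled perturbation
#' experiment: a set of residue pairs in contact in every wild-type model
#' ("conserved"), and a set of pairs each broken in exactly `m` of the
#' mutant models, so that the downstream difference map must report
#' delta = m / n_models on those pairs and 0 elsewhere.
#'
#' Each designed pair relocates its *second* residue next to its first;
#' a residue may therefore be the second member of at most one designed
#' pair, and may not also be the first member of another. Realizability of
#' the whole geometry (margins held in every model configuration) is
#' verified at construction time.
#'
#' @param n_models Models per ensemble (default 20).
#' @param chains Named integer vector of per-chain residue counts
#'   (default `c(A = 10, B = 10)`).
#' @param conserved_contacts List of length-2 residue-id vectors
#'   (`c("A:3", "B:4")`) in contact in all models of both ensembles.
#' @param perturbed_pairs Tibble with columns `res1`, `res2`, `m`, or a
#'   list of `list(pair = c(id1, id2), m =)`: each pair is in contact in
#'   all wild-type models and broken in exactly `m` mutant models.
#' @param jitter_sd Per-coordinate Gaussian noise, Angstrom (default
#'   0.05).
#' @param seed Random seed driving jitter and the choice of which mutant
#'   models break each pair.
#' @param atoms_per_residue Heavy atoms per residue, 1-4 (default 2).
#' @param mutation_site Optional residue id; named `ARG` in wild-type
#'   models and `HIS` in mutant models, mimicking a point mutation's
#'   residue-name difference at shared numbering.
#' @return List of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_models = 20L, chains = c(A = 10L, B = 10L),
                          conserved_contacts = list(),
                          perturbed_pairs = NULL,
                          jitter_sd = 0.05, seed = 1L,
                          atoms_per_residue = 2L,
                          mutation_site = NULL) {
  if (n_models < 1) abort("`n_models` must be >= 1.")
  if (is.null(names(chains)) || any(names(chains) == "")) {
    abort("`chains` must be a named vector of residue counts.")
  }
  if (atoms_per_residue < 1 || atoms_per_residue > 4) {
    abort("`atoms_per_residue` must be in 1..4.")
  }
  cons <- normalize_pairs(conserved_contacts)
  pert <- normalize_perturbed(perturbed_pairs)
  if (nrow(pert) > 0 && any(pert$m < 0 | pert$m > n_models)) {
    abort("Each perturbed-pair count m must satisfy 0 <= m <= n_models.")
  }
  spec <- structure(
    list(n_models = as.integer(n_models), chains = chains,
         conserved_contacts = cons, perturbed_pairs = pert,
         jitter_sd = jitter_sd, seed = as.integer(seed),
         atoms_per_residue = as.integer(atoms_per_residue),
         mutation_site = mutation_site),
    class = "ensemble_spec")
  spec$layout <- design_layout(spec)   # errors if unrealizable
  spec
}

normalize_pairs <- function(x) {
  if (is.null(x) || length(x) == 0) {
    return(tibble(res1 = character(), res2 = character()))
  }
  if (is.data.frame(x)) return(tibble(res1 = x$res1, res2 = x$res2))
  tibble(res1 = vapply(x, `[[`, "", 1L), res2 = vapply(x, `[[`, "", 2L))
}

normalize_perturbed <- function(x) {
  if (is.null(x) || length(x) == 0) {
    return(tibble(res1 = character(), res2 = character(), m = integer()))
  }
  if (is.data.frame(x)) {
    return(tibble(res1 = x$res1, res2 = x$res2, m = as.integer(x$m)))
  }
  tibble(res1 = vapply(x, function(p) p$pair[[1]], ""),
         res2 = vapply(x, function(p) p$pair[[2]], ""),
         m = vapply(x, function(p) as.integer(p$m), 1L))
}

## residue centres for the base (all-in-contact) layout plus the broken
## position of every moved residue; verifies all safety margins
design_layout <- function(spec) {
  chains <- spec$chains
  res <- tibble(
    chain = rep(names(chains), chains),
    resseq = unlist(lapply(chains, seq_len), use.names = FALSE)
  )
  res$id <- res_id(res$chain, res$resseq)
  ci <- match(res$chain, names(chains))
  res$x <- (res$resseq - 1) * RES_SPACING
  res$y <- (ci - 1) * CHAIN_SPACING
  res$z <- 0
  designed <- dplyr::bind_rows(
    spec$conserved_contacts[, c("res1", "res2")],
    spec$perturbed_pairs[, c("res1", "res2")])
  for (id in c(designed$res1, designed$res2)) {
    if (!id %in% res$id) abort(paste0("Designed pair names unknown residue '",
                                      id, "'."))
  }
  if (anyDuplicated(designed$res2)) {
    abort("A residue may be the moved (second) member of only one pair.")
  }
  if (any(designed$res2 %in% designed$res1)) {
    abort("A moved residue may not anchor another designed pair.")
  }
  ## relocate each moved residue next to its anchor; record its broken spot
  res$x_broken <- NA_real_; res$y_broken <- NA_real_
  for (i in seq_len(nrow(designed))) {
    a <- match(designed$res1[[i]], res$id)
    b <- match(designed$res2[[i]], res$id)
    res$x[[b]] <- res$x[[a]]
    res$y[[b]] <- res$y[[a]] + CONTACT_D
    res$z[[b]] <- res$z[[a]]
    if (designed$res2[[i]] %in% spec$perturbed_pairs$res2) {
      res$x_broken[[b]] <- res$x[[a]]
      res$y_broken[[b]] <- res$y[[a]] + BROKEN_D
    }
  }
  check_margins(res, designed, spec)
  res
}

## every pair of residues, over every combination of contact/broken
## placements, must respect the designed distance or the 6-Angstrom
## exclusion margin
check_margins <- function(res, designed, spec) {
  pos_sets <- lapply(seq_len(nrow(res)), function(i) {
    p <- list(c(res$x[[i]], res$y[[i]], res$z[[i]]))
    if (!is.na(res$x_broken[[i]])) {
      p <- c(p, list(c(res$x_broken[[i]], res$y_broken[[i]], res$z[[i]])))
    }
    p
  })
  dkey <- paste(designed$res1, designed$res2)
  pkey <- paste(spec$perturbed_pairs$res1, spec$perturbed_pairs$res2)
  for (i in seq_len(nrow(res) - 1)) {
    for (j in seq(i + 1, nrow(res))) {
      key_ij <- paste(res$id[[i]], res$id[[j]])
      key_ji <- paste(res$id[[j]], res$id[[i]])
      is_designed <- key_ij %in% dkey || key_ji %in% dkey
      for (si in seq_along(pos_sets[[i]])) {
        for (sj in seq_along(pos_sets[[j]])) {
          d <- sqrt(sum((pos_sets[[i]][[si]] - pos_sets[[j]][[sj]])^2))
          ok <- if (is_designed) {
            ## anchor is in its only position; moved residue state decides
            broken_state <- si > 1 || sj > 1
            if (broken_state) d > 4.6 else d < 4.4
          } else {
            d > 6
          }
          if (!ok) {
            abort(sprintf(
              "Unrealizable geometry: residues %s and %s at %.2f A violate the designed margins.",
              res$id[[i]], res$id[[j]], d))
          }
        }
      }
    }
  }
  invisible(TRUE)
}

## expand residue centres into the atom table of one model
expand_model <- function(res, spec, model_id, resnames, jitter) {
  k <- spec$atoms_per_residue
  nres <- nrow(res)
  idx <- rep(seq_len(nres), each = k)
  zoff <- rep((seq_len(k) - 1) * ATOM_Z_STEP, times = nres)
  out <- tibble(
    model_id = model_id,
    chain = res$chain[idx], resseq = res$resseq[idx], icode = "",
    resname = resnames[idx],
    atom = rep(ATOM_NAMES[seq_len(k)], times = nres),
    element = "C",
    x = res$x[idx], y = res$y[idx], z = res$z[idx] + zoff,
    occupancy = 1, bfactor = 0, altloc = "",
    is_heavy = TRUE, is_het = FALSE
  )
  if (spec$jitter_sd > 0) {
    out$x <- out$x + jitter[, 1]
    out$y <- out$y + jitter[, 2]
    out$z <- out$z + jitter[, 3]
  }
  out
}

site_resnames <- function(res, spec, mutant) {
  rn <- rep("ALA", nrow(res))
  if (!is.null(spec$mutation_site)) {
    i <- match(spec$mutation_site, res$id)
    if (is.na(i)) abort(paste0("Mutation site '", spec$mutation_site,
                               "' is not a residue of the complex."))
    rn[[i]] <- if (mutant) "HIS" else "ARG"
  }
  rn
}

draw_jitter <- function(spec) {
  n <- nrow(spec$layout) * spec$atoms_per_residue
  matrix(rnorm(3 * n, 0, spec$jitter_sd), ncol = 3)
}

#' Build one toy complex model
#'
#' All designed contacts (conserved and perturbed alike) are realized; the
#' model's contact map at default parameters is exactly the designed pair
#' set.
#'
#' @param spec An [ensemble_spec()].
#' @return Atom tibble of one model (`model_id = "toy"`).
#' @export
make_toy_complex <- function(spec) {
  withr::with_seed(spec$seed, {
    expand_model(spec$layout, spec, "toy",
                 site_resnames(spec$layout, spec, mutant = FALSE),
                 draw_jitter(spec))
  })
}

#' Generate paired wild-type and mutant model ensembles
#'
#' Wild-type models realize every designed contact. For each perturbed
#' pair `(res1, res2, m)`, exactly `m` mutant models — drawn without
#' replacement under the spec's seed — displace `res2` beyond the broken
#' margin; all other contacts are conserved. Both ensembles share one
#' residue-key set.
#'
#' @param spec An [ensemble_spec()].
#' @return List with `wt` and `mut` atom tibbles (model ids `wt_01`...,
#'   `mut_01`...) and `truth`, a tibble of the designed perturbations with
#'   the expected difference-map `delta_expected = m / n_models`.
#' @export
make_perturbed_ensembles <- function(spec) {
  res <- spec$layout
  n <- spec$n_models
  withr::with_seed(spec$seed, {
    broken_in <- lapply(seq_len(nrow(spec$perturbed_pairs)), function(i) {
      sort(sample.int(n, spec$perturbed_pairs$m[[i]]))
    })
    wt <- dplyr::bind_rows(lapply(seq_len(n), function(mdl) {
      expand_model(res, spec, sprintf("wt_%02d", mdl),
                   site_resnames(res, spec, mutant = FALSE),
                   draw_jitter(spec))
    }))
    mut <- dplyr::bind_rows(lapply(seq_len(n), function(mdl) {
      r <- res
      for (i in seq_len(nrow(spec$perturbed_pairs))) {
        if (mdl %in% broken_in[[i]]) {
          b <- match(spec$perturbed_pairs$res2[[i]], r$id)
          r$x[[b]] <- r$x_broken[[b]]
          r$y[[b]] <- r$y_broken[[b]]
        }
      }
      expand_model(r, spec, sprintf("mut_%02d", mdl),
                   site_resnames(res, spec, mutant = TRUE),
                   draw_jitter(spec))
    }))
  })
  truth <- spec$perturbed_pairs
  truth$delta_expected <- truth$m / n
  list(wt = wt, mut = mut, truth = truth)
}

#' Generate a synthetic model score table
#'
#' Stands in for the two model-quality score columns of a comparative
#' modelling run (both lower-is-better).
#'
#' @param n Number of models.
#' @param mode `"disjoint-tops"` (the top-k sets of the two scores are
#'   disjoint for any k <= n/2), `"identical"` (`score_b == score_a`) or
#'   `"random"` (both columns i.i.d. uniform).
#' @param seed Seed for `"random"` mode.
#' @return Tibble with `model_id`, `score_a`, `score_b`.
#' @export
make_score_table <- function(n, mode = c("disjoint-tops", "identical",
                                         "random"), seed = 1L) {
  mode <- match.arg(mode)
  if (n < 1) abort("`n` must be >= 1.")
  ids <- sprintf("m%04d", seq_len(n))
  switch(mode,
    "disjoint-tops" = tibble(model_id = ids,
                             score_a = as.numeric(seq_len(n)),
                             score_b = as.numeric(rev(seq_len(n)))),
    "identical" = tibble(model_id = ids,
                         score_a = as.numeric(seq_len(n)),
                         score_b = as.numeric(seq_len(n))),
    "random" = withr::with_seed(seed, {
      tibble(model_id = ids, score_a = runif(n), score_b = runif(n))
    })
  )
}
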