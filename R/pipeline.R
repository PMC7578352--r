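## Full analysis pipeline: select scored models, map contacts, average,
## difference, annotate, place beads, and report — with machine-readable
## outputs (diff.tsv, beads.pdb, report.json).

#' Configure a perturbation analysis run
#'
#' @param wt,mut Wild-type and mutant model sources: either atom tibbles
#'   (from [read_structures()] or the synthetic generator) or character
#'   paths/globs of PDB files.
#' @param scores_wt,scores_mut Optional model score tables (tibbles with
#'   `model_id`, `score_a`, `score_b`, lower is better) or TSV paths; when
#'   given, each ensemble is restricted to the models chosen by
#'   [select_models()].
#' @param k Per-criterion retention count for model selection (default
#'   10, i.e. a 20-model ensemble).
#' @param params [contact_params()] for the contact maps.
#' @param threshold Annotation fraction (default 0.40, strict).
#' @param chain_pairs Optional list of length-2 chain vectors for
#'   per-interface net-change reporting; defaults to all chain pairs of
#'   the complex.
#' @param mutation_site Optional residue id (`"chain:resseq"`); when
#'   given, the report carries each annotated pair's distance to this
#'   site.
#' @param distance_mode Mode for the mutation-site distance
#'   (see [residue_distance()]); default `"ca"`, matching the
#'   domain-scale reading of remoteness.
#' @param out_dir Output directory for `diff.tsv`, `beads.pdb` (+ colors
#'   TSV) and `report.json`; `NULL` writes no files.
#' @return List of class `run_config`, validated (referenced files must
#'   exist, threshold in (0,1)).
#' @export
perturbation_config <- function(wt, mut, scores_wt = NULL, scores_mut = NULL,
                                k = 10L, params = contact_params(),
                                threshold = 0.40, chain_pairs = NULL,
                                mutation_site = NULL,
                                distance_mode = "ca", out_dir = NULL) {
  if (threshold <= 0 || threshold >= 1) {
    abort("`threshold` must lie strictly in (0, 1).")
  }
  check_source <- function(x, what) {
    if (is.character(x)) {
      found <- unlist(lapply(x, function(p) {
        length(Sys.glob(p)) > 0 || file.exists(p)
      }))
      if (!all(found)) {
        abort(paste0(what, " file(s) not found: ",
                     paste(x[!found], collapse = ", ")))
      }
    } else if (!is.data.frame(x)) {
      abort(paste0(what, " must be an atom table or file path(s)."))
    }
  }
  check_source(wt, "Wild-type model"); check_source(mut, "Mutant model")
  check_scores <- function(x, what) {
    if (is.null(x)) return(invisible(NULL))
    if (is.character(x) && !file.exists(x)) {
      abort(paste0(what, " score table not found: ", x))
    }
    if (is.data.frame(x)) {
      stop_if_missing_cols(x, c("model_id", "score_a", "score_b"), what)
    }
  }
  check_scores(scores_wt, "Wild-type"); check_scores(scores_mut, "Mutant")
  structure(
    list(wt = wt, mut = mut, scores_wt = scores_wt, scores_mut = scores_mut,
         k = as.integer(k), params = params, threshold = threshold,
         chain_pairs = chain_pairs, mutation_site = mutation_site,
         distance_mode = distance_mode, out_dir = out_dir),
    class = "run_config")
}

load_ensemble <- function(src) {
  if (is.data.frame(src)) src else read_structures(src)
}

load_scores <- function(src) {
  if (is.null(src) || is.data.frame(src)) return(src)
  readr::read_tsv(src, show_col_types = FALSE)
}

#' Run the full contact-perturbation analysis
#'
#' Pipeline: (optionally) select the top-2k scored models per ensemble,
#' compute per-model contact maps, average into frequencies, difference
#' wild-type minus mutant, annotate pairs above the threshold, place
#' red-white-blue beads on a reference model (the best-`score_a`
#' wild-type model, or the first wild-type model when no scores are
#' given), and summarize net changes overall and per chain interface.
#'
#' @param config A [perturbation_config()] object.
#' @return Invisibly, a list of class `perturbation_report`:
#'   `difference_map` (the `contact_diff`), `annotated` (tibble), `beads`
#'   (tibble) and `report` (the JSON-serializable summary). When
#'   `out_dir` is set, writes `diff.tsv`, `beads.pdb`,
#'   `beads_colors.tsv` and `report.json` there.
#' @export
run_perturbation_analysis <- function(config) {
  if (!inherits(config, "run_config")) {
    abort("`config` must come from perturbation_config().")
  }
  wt_atoms <- load_ensemble(config$wt)
  mut_atoms <- load_ensemble(config$mut)
  scores_wt <- load_scores(config$scores_wt)
  scores_mut <- load_scores(config$scores_mut)

  pick <- function(atoms, scores, label) {
    if (is.null(scores)) {
      return(list(atoms = atoms, best = unique(atoms$model_id)[[1]]))
    }
    sel <- select_models(scores, k = config$k)
    missing <- setdiff(sel$model_id, unique(atoms$model_id))
    if (length(missing) > 0) {
      abort(paste0(label, ": selected model(s) absent from structures: ",
                   paste(head(missing, 5), collapse = ", ")))
    }
    list(atoms = atoms[atoms$model_id %in% sel$model_id, , drop = FALSE],
         best = sel$model_id[[which.min(sel$rank_a)]])
  }
  wt_sel <- pick(wt_atoms, scores_wt, "Wild-type")
  mut_sel <- pick(mut_atoms, scores_mut, "Mutant")

  cm_wt <- contact_maps(wt_sel$atoms, config$params)
  cm_mut <- contact_maps(mut_sel$atoms, config$params)
  n_wt <- dplyr::n_distinct(wt_sel$atoms$model_id)
  n_mut <- dplyr::n_distinct(mut_sel$atoms$model_id)
  f_wt <- contact_frequency(cm_wt, n_models = n_wt, label = "WT",
                            residue_keys = residue_keys(wt_sel$atoms))
  f_mut <- contact_frequency(cm_mut, n_models = n_mut, label = "MUT",
                             residue_keys = residue_keys(mut_sel$atoms))
  diff <- difference_map(f_wt, f_mut, threshold = config$threshold)
  ann <- annotate_differences(diff)

  ref <- model_atoms(wt_sel$atoms, wt_sel$best)
  beads <- bead_geometry(ann, ref)

  chains <- sort(unique(ref$chain[!ref$is_het]))
  chain_pairs <- config$chain_pairs %||% utils::combn(
    chains, min(2, length(chains)), simplify = FALSE)
  chain_pairs <- Filter(function(p) length(p) == 2, chain_pairs)
  interface_net <- lapply(chain_pairs, function(p) {
    list(chains = paste(p, collapse = "-"),
         net_all = net_contact_change(diff, "all", chains = p),
         net_annotated = suppressWarnings(
           net_contact_change(diff, "annotated", chains = p)))
  })

  site_dist <- NULL
  if (!is.null(config$mutation_site) && nrow(ann) > 0) {
    site_dist <- vapply(seq_len(nrow(ann)), function(i) {
      mean(c(
        residue_distance(ref, res_id(ann$chain1[[i]], ann$resseq1[[i]],
                                     ann$icode1[[i]]),
                         config$mutation_site, mode = config$distance_mode),
        residue_distance(ref, res_id(ann$chain2[[i]], ann$resseq2[[i]],
                                     ann$icode2[[i]]),
                         config$mutation_site, mode = config$distance_mode)))
    }, 0)
    ann$site_distance <- site_dist
  }

  mean_contacts <- function(cm, n) nrow(cm) / n
  report <- list(
    ensembles = list(
      wt = list(n_models = n_wt,
                mean_contact_count = mean_contacts(cm_wt, n_wt)),
      mut = list(n_models = n_mut,
                 mean_contact_count = mean_contacts(cm_mut, n_mut))),
    n_pairs = nrow(diff),
    n_annotated = nrow(ann),
    net_change = list(
      all = net_contact_change(diff, "all"),
      annotated = suppressWarnings(net_contact_change(diff, "annotated")),
      per_interface = interface_net),
    annotated_pairs = lapply(seq_len(nrow(ann)), function(i) {
      out <- list(
        res1 = res_id(ann$chain1[[i]], ann$resseq1[[i]], ann$icode1[[i]]),
        res2 = res_id(ann$chain2[[i]], ann$resseq2[[i]], ann$icode2[[i]]),
        freq_wt = ann$freq_wt[[i]], freq_mut = ann$freq_mut[[i]],
        delta = ann$delta[[i]], direction = ann$direction[[i]])
      if (!is.null(site_dist)) out$site_distance <- ann$site_distance[[i]]
      out
    }),
    config = list(
      cutoff = config$params$cutoff,
      min_seq_sep = config$params$min_seq_sep,
      include_het = config$params$include_het,
      k = config$k, threshold = config$threshold,
      mutation_site = config$mutation_site,
      distance_mode = config$distance_mode,
      reference_model = wt_sel$best),
    provenance = list(package = "contactdiff",
                      version = as.character(utils::packageVersion(
                        "contactdiff")))
  )
  validate_report(report)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    diff_out <- as_tibble(diff)
    diff_out$annotated <- as.integer(diff_out$annotated)
    readr::write_tsv(diff_out, file.path(config$out_dir, "diff.tsv"))
    write_bead_pdb(beads, file.path(config$out_dir, "beads.pdb"))
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(structure(
    list(difference_map = diff, annotated = ann, beads = beads,
         report = report),
    class = "perturbation_report"))
}

#' Check a run report against the shipped schema
#'
#' Verifies that every field required by
#' `inst/extdata/report-schema.json` is present with the right type.
#'
#' @param report Report list (the `report` element of
#'   [run_perturbation_analysis()] output, or parsed `report.json`).
#' @return Invisibly `TRUE`; errors describing missing/invalid fields
#'   otherwise.
#' @export
validate_report <- function(report) {
  schema_path <- system.file("extdata", "report-schema.json",
                             package = "contactdiff")
  schema <- jsonlite::read_json(schema_path)
  check_node <- function(node, spec, where) {
    for (field in names(spec$required)) {
      if (!field %in% names(node)) {
        abort(paste0("Report field missing: ", where, field))
      }
      want <- spec$required[[field]]
      if (is.list(want)) {
        check_node(node[[field]], want, paste0(where, field, "."))
      } else {
        val <- node[[field]]
        ok <- switch(want,
          number = is.numeric(val),
          string = is.character(val) || is.null(val),
          array = is.list(val) || is.vector(val),
          object = is.list(val),
          TRUE)
        if (!ok) {
          abort(paste0("Report field ", where, field,
                       " has wrong type (want ", want, ")."))
        }
      }
    }
  }
  check_node(report, schema, "")
  invisible(TRUE)
}

#' @export
print.perturbation_report <- function(x, ...) {
  r <- x$report
  cat("Contact-perturbation analysis\n")
  cat(sprintf("  ensembles: WT %d models (mean %.2f contacts), MUT %d models (mean %.2f contacts)\n",
              r$ensembles$wt$n_models, r$ensembles$wt$mean_contact_count,
              r$ensembles$mut$n_models, r$ensembles$mut$mean_contact_count))
  cat(sprintf("  pairs: %d total, %d annotated (|delta| > %.2f)\n",
              r$n_pairs, r$n_annotated, r$config$threshold))
  cat(sprintf("  net contact change: %+.3f (all pairs), %+.3f (annotated)\n",
              r$net_change$all, r$net_change$annotated))
  invisible(x)
}
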