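## Ensemble selection and contact-frequency averaging.
##
## Comparative-modelling pipelines score each model with two
## lower-is-better quality functions (a DOPE-like statistical potential
## and a molpdf-like objective). The analysed ensemble is the union of the
## top k models under each score — 2k models in the standard setup of
## k = 10 drawn from 1000.

#' Select the scored model ensemble
#'
#' Takes the top `k` models by `score_a` and the top `k` by `score_b`
#' (ascending: both scores are energies, lower is better) and returns
#' their union. If the two top-k sets overlap, the union is smaller than
#' 2k; with `backfill = TRUE` (default) the next-best models by `score_a`
#' rank are appended until 2k distinct models are selected, and a message
#' reports the backfill.
#'
#' @param scores Tibble with columns `model_id`, `score_a`, `score_b`.
#' @param k Per-criterion retention count (default 10).
#' @param backfill Restore the ensemble to 2k models when the top-k sets
#'   overlap (default `TRUE`).
#' @param lower_is_better Length-2 logical: orientation of `score_a` and
#'   `score_b` (default both `TRUE`).
#' @return Tibble of the selected models with `model_id`, `score_a`,
#'   `score_b`, `rank_a`, `rank_b`, `selected_by` (`"score_a"`,
#'   `"score_b"`, `"both"` or `"backfill"`), ordered by (`rank_a`,
#'   `rank_b`, `model_id`). Ranks are stable: ties broken by `model_id`.
#' @export
select_models <- function(scores, k = 10L, backfill = TRUE,
                          lower_is_better = c(TRUE, TRUE)) {
  stop_if_missing_cols(scores, c("model_id", "score_a", "score_b"),
                       "Score table")
  if (k < 1) abort("`k` must be >= 1.")
  if (anyDuplicated(scores$model_id)) {
    dup <- unique(scores$model_id[duplicated(scores$model_id)])
    abort(paste0("Duplicate model_id(s): ",
                 paste(head(dup, 5), collapse = ", ")))
  }
  if (!all(is.finite(scores$score_a)) || !all(is.finite(scores$score_b))) {
    abort("Scores must be finite.")
  }
  n <- nrow(scores)
  if (n < k) abort(sprintf("Need at least k = %d rows, got %d.", k, n))
  if (backfill && n < 2 * k) {
    abort(sprintf("Backfill to 2k = %d models needs >= 2k rows, got %d.",
                  2 * k, n))
  }
  sa <- if (lower_is_better[[1]]) scores$score_a else -scores$score_a
  sb <- if (lower_is_better[[2]]) scores$score_b else -scores$score_b
  rank_a <- integer(n); rank_a[order(sa, scores$model_id)] <- seq_len(n)
  rank_b <- integer(n); rank_b[order(sb, scores$model_id)] <- seq_len(n)

  in_a <- rank_a <= k
  in_b <- rank_b <= k
  sel <- in_a | in_b
  selected_by <- dplyr::case_when(
    in_a & in_b ~ "both",
    in_a ~ "score_a",
    in_b ~ "score_b",
    TRUE ~ NA_character_
  )
  if (backfill && sum(sel) < 2 * k) {
    need <- 2 * k - sum(sel)
    cand <- which(!sel)
    fill <- cand[order(rank_a[cand])][seq_len(need)]
    sel[fill] <- TRUE
    selected_by[fill] <- "backfill"
    inform(sprintf(
      "Top-%d sets overlap; backfilled %d model(s) by score_a rank.",
      k, need))
  }
  out <- tibble(
    model_id = scores$model_id, score_a = scores$score_a,
    score_b = scores$score_b, rank_a = rank_a, rank_b = rank_b,
    selected_by = selected_by
  )[sel, ]
  out[order(out$rank_a, out$rank_b, out$model_id), ]
}

#' Average contact maps into per-pair contact frequencies
#'
#' For each residue pair, the frequency is the exact fraction of models of
#' the ensemble in which the pair is in contact: an integer count divided
#' by the number of models. Pairs in contact in no model are omitted (their
#' frequency is 0 by convention).
#'
#' @param contacts Contact tibble from [contact_maps()] over all models of
#'   one ensemble.
#' @param n_models Number of models in the ensemble. Defaults to the
#'   number of distinct `model_id`s in `contacts`; pass it explicitly if
#'   some model has no contacts at all.
#' @param label Ensemble name (e.g. `"WT"`).
#' @param residue_keys Optional residue-key tibble from [residue_keys()];
#'   carried along so [difference_map()] can verify that two ensembles
#'   share one residue universe.
#' @return A `contact_freq` tibble: pair identity columns, `n_in_contact`
#'   (count of models), `freq` in `[0, 1]`.
#' @export
contact_frequency <- function(contacts, n_models = NULL, label = NULL,
                              residue_keys = NULL) {
  stop_if_missing_cols(contacts, c("model_id", pair_cols), "Contact table")
  n <- n_models %||% dplyr::n_distinct(contacts$model_id)
  if (n < 1) abort("Frequency needs at least one model.")
  out <- contacts |>
    dplyr::group_by(dplyr::across(dplyr::all_of(pair_cols))) |>
    dplyr::summarise(resname1 = .data$resname1[1],
                     resname2 = .data$resname2[1],
                     n_in_contact = dplyr::n_distinct(.data$model_id),
                     .groups = "drop") |>
    dplyr::mutate(freq = .data$n_in_contact / n)
  out <- out[, c("chain1", "resseq1", "icode1", "resname1",
                 "chain2", "resseq2", "icode2", "resname2",
                 "n_in_contact", "freq")]
  out <- arrange_pairs(out)
  structure(out,
            n_models = n, label = label,
            params = attr(contacts, "params"),
            residue_keys = residue_keys,
            class = c("contact_freq", class(out)))
}
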