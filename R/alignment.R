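## Residue-position mapping between homologs through a multiple sequence
## alignment, and percent identity/similarity. "Similar" follows the
## Clustal strong groups by default; the grouping is a convention, not a
## universal constant, so it is exposed as a parameter.

#' Read a multiple sequence alignment
#'
#' @param path Alignment file.
#' @param format `"fasta"` or `"clustal"`. Clustal conservation lines are
#'   ignored.
#' @return Tibble with columns `name` and `sequence` (gapped, upper-case,
#'   gap character `-`), in file order.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  if (format == "fasta") {
    set <- tryCatch(
      Biostrings::readBStringSet(path),
      error = function(e) abort(paste0("Cannot parse alignment '", path,
                                       "': ", conditionMessage(e))))
    nms <- vapply(strsplit(names(set), "\\s+"), `[[`, "", 1L)
    seqs <- as.character(set)
  } else {
    aln <- tryCatch(
      Biostrings::readAAMultipleAlignment(path, format = "clustal"),
      error = function(e) abort(paste0("Cannot parse alignment '", path,
                                       "': ", conditionMessage(e))))
    nms <- rownames(aln)
    seqs <- as.character(aln)
  }
  seqs <- toupper(gsub("[.~]", "-", unname(seqs)))
  if (length(seqs) < 2) abort("Alignment must contain at least 2 sequences.")
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1) {
    abort(paste0("Ragged alignment: sequence lengths ",
                 paste(unique(widths), collapse = ", "), "."))
  }
  tibble(name = nms, sequence = seqs)
}

#' Clustal "strong" similarity groups
#'
#' @return Character vector of residue groups whose members are treated as
#'   similar (plus identities).
#' @export
clustal_strong_groups <- function() {
  c("STA", "NEQK", "NHQK", "NDEQ", "QHRK", "MILV", "MILF", "HY", "FYW")
}

resolve_seq <- function(aln, which) {
  if (is.character(which)) {
    i <- match(which, aln$name)
    if (is.na(i)) abort(paste0("No sequence named '", which, "'."))
    return(i)
  }
  if (which < 1 || which > nrow(aln)) {
    abort(paste0("Sequence index ", which, " out of range."))
  }
  which
}

#' Percent identity and similarity between two aligned sequences
#'
#' Identity counts columns where both sequences carry the same residue;
#' similarity additionally counts columns whose two residues share a
#' similarity group. Columns where either sequence is gapped never count
#' as matches.
#'
#' @param aln Alignment tibble from [read_alignment()].
#' @param seq1,seq2 Sequence indices or names.
#' @param groups Similarity groups (default [clustal_strong_groups()]).
#' @param denominator `"aligned-columns"` (columns where neither sequence
#'   is gapped; default) or `"shorter-seq"` (length of the shorter
#'   ungapped sequence).
#' @return One-row tibble: `identity`, `similarity` (percent),
#'   `n_identical`, `n_similar`, `denominator_n`.
#' @export
identity_similarity <- function(aln, seq1 = 1, seq2 = 2,
                                groups = clustal_strong_groups(),
                                denominator = c("aligned-columns",
                                                "shorter-seq")) {
  denominator <- match.arg(denominator)
  i <- resolve_seq(aln, seq1); j <- resolve_seq(aln, seq2)
  if (i == j) abort("Select two distinct sequences.")
  a <- strsplit(aln$sequence[[i]], "")[[1]]
  b <- strsplit(aln$sequence[[j]], "")[[1]]
  both <- a != "-" & b != "-"
  if (!any(both)) abort("The two sequences share no aligned columns.")
  same <- both & a == b
  grp <- setNames(rep(seq_along(groups), nchar(groups)),
                  unlist(strsplit(groups, "")))
  ga <- grp[a]; gb <- grp[b]
  similar <- same | (both & !is.na(ga) & !is.na(gb) & ga == gb)
  den <- switch(denominator,
    "aligned-columns" = sum(both),
    "shorter-seq" = min(sum(a != "-"), sum(b != "-")))
  tibble(
    identity = 100 * sum(same) / den,
    similarity = 100 * sum(similar) / den,
    n_identical = sum(same),
    n_similar = sum(similar),
    denominator_n = den
  )
}

#' Map a residue position between aligned sequences
#'
#' Converts a 1-based position in one sequence's own numbering to the
#' corresponding position in another sequence via the shared alignment
#' column. Per-sequence numbering offsets translate between author
#' numbering and ungapped sequence index (author number = ungapped index
#' + offset).
#'
#' @param aln Alignment tibble from [read_alignment()].
#' @param position Position in `from`'s numbering.
#' @param from,to Sequence indices or names.
#' @param offsets Optional named numeric vector of per-sequence numbering
#'   offsets (names matching `aln$name`); default 0 for all.
#' @return The corresponding position in `to`'s numbering, or `NA` when
#'   the alignment column is a gap in `to`.
#' @export
map_position <- function(aln, position, from, to, offsets = NULL) {
  i <- resolve_seq(aln, from); j <- resolve_seq(aln, to)
  off <- function(k) {
    if (is.null(offsets)) return(0)
    o <- offsets[[aln$name[[k]]]]
    if (is.null(o) || is.na(o)) 0 else o
  }
  a <- strsplit(aln$sequence[[i]], "")[[1]]
  b <- strsplit(aln$sequence[[j]], "")[[1]]
  upos <- position - off(i)
  na <- sum(a != "-")
  if (upos < 1 || upos > na) {
    abort(sprintf("Position %s is outside sequence '%s' (1..%d + offset %s).",
                  position, aln$name[[i]], na, off(i)))
  }
  col <- which(a != "-")[[upos]]
  if (b[[col]] == "-") return(NA_integer_)
  as.integer(sum(b[seq_len(col)] != "-") + off(j))
}
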