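#' Exact-substring peptide mapping
#'
#' Internal stand-in for an external aligner: reports one hit per exact
#' substring occurrence of a peptide in a target protein, with
#' `pident = 100` and a fixed surrogate bitscore of twice the peptide
#' length. Leucine and isoleucine are treated as distinct.
#'
#' @param peptides Tibble with `peptide_id`, `sequence` (or a character
#'   vector of sequences, in which case IDs are generated).
#' @param proteome Tibble with `protein_id`, `sequence`.
#' @return Outfmt-6-shaped hit tibble (query = peptide_id).
#' @export
map_peptides_exact <- function(peptides, proteome) {
  if (is.character(peptides)) {
    peptides <- tibble::tibble(
      peptide_id = sprintf("pep%04d", seq_along(peptides)),
      sequence = peptides)
  }
  rows <- purrr::pmap(peptides[c("peptide_id", "sequence")],
                      function(peptide_id, sequence) {
    len <- nchar(sequence)
    hits <- purrr::map2(proteome$protein_id, proteome$sequence,
                        function(pid, pseq) {
      starts <- gregexpr(sequence, pseq, fixed = TRUE)[[1]]
      if (starts[1] == -1L) return(NULL)
      tibble::tibble(query = peptide_id, subject = pid, pident = 100,
                     length = len, mismatch = 0L, gapopen = 0L,
                     qstart = 1L, qend = len,
                     sstart = as.integer(starts),
                     send = as.integer(starts) + len - 1L,
                     evalue = 0, bitscore = 2 * len)
    })
    dplyr::bind_rows(hits)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::as_tibble(stats::setNames(
      c(list(character(), character()), rep(list(numeric()), 10)),
      outfmt6_cols))
  }
  out
}

#' Tiered reassignment of source proteins to a new reference proteome
#'
#' For each originally-assigned (source) protein, candidate target proteins
#' are ranked by a tie-break ladder over its aggregated peptide hits:
#' (1) number of distinct peptides hitting the target, descending;
#' (2) sum of bitscores over those hits, descending;
#' (3) median percent identity, descending;
#' (4) lexicographically smallest target ID (deterministic fallback).
#' `decided_at_tier` records the first level that uniquely ranked the
#' winner. The result is a pure function of the hit multiset: input row
#' order is irrelevant.
#'
#' @param hits Hit tibble with `peptide_id`, `source_protein`, `subject`
#'   (candidate target), `pident`, `bitscore` columns. A raw outfmt-6 table
#'   using the `peptideID|sourceProteinID` query convention is accepted and
#'   decoded via [split_query_ids()].
#' @param min_pident,max_evalue Optional pre-filters on hits (default off).
#' @return Tibble with `source_protein`, `chosen_target`,
#'   `n_distinct_peptides`, `bitscore_sum`, `median_pident`,
#'   `decided_at_tier` (integer 1-4, `NA` for unassigned). Source proteins
#'   whose hits are all filtered out come back `unassigned`.
#' @export
reassign <- function(hits, min_pident = NULL, max_evalue = NULL) {
  if (!"source_protein" %in% names(hits)) hits <- split_query_ids(hits)
  all_sources <- unique(hits$source_protein)
  if (!is.null(min_pident)) hits <- hits[hits$pident >= min_pident, ]
  if (!is.null(max_evalue) && "evalue" %in% names(hits)) {
    hits <- hits[hits$evalue <= max_evalue, ]
  }
  stats_tbl <- hits |>
    dplyr::group_by(.data$source_protein, .data$subject) |>
    dplyr::summarise(
      n_distinct_peptides = dplyr::n_distinct(.data$peptide_id),
      bitscore_sum = sum(.data$bitscore),
      median_pident = stats::median(.data$pident),
      .groups = "drop_last")

  pick <- stats_tbl |>
    dplyr::group_modify(~ rank_candidates(.x)) |>
    dplyr::ungroup()

  missing <- setdiff(all_sources, pick$source_protein)
  if (length(missing)) {
    pick <- dplyr::bind_rows(pick, tibble::tibble(
      source_protein = missing, chosen_target = "unassigned",
      n_distinct_peptides = 0L, bitscore_sum = 0,
      median_pident = NA_real_, decided_at_tier = NA_integer_))
  }
  dplyr::arrange(pick, .data$source_protein)
}

# Ladder ranking of one source protein's candidate table.
rank_candidates <- function(cand) {
  if (nrow(cand) == 0L) {
    return(tibble::tibble(chosen_target = character(),
                          n_distinct_peptides = integer(),
                          bitscore_sum = numeric(),
                          median_pident = numeric(),
                          decided_at_tier = integer()))
  }
  survivors <- seq_len(nrow(cand))
  tier_keys <- list(cand$n_distinct_peptides, cand$bitscore_sum,
                    cand$median_pident)
  decided <- 4L
  for (tier in 1:3) {
    key <- tier_keys[[tier]][survivors]
    survivors <- survivors[key == max(key)]
    if (length(survivors) == 1L) { decided <- tier; break }
  }
  winner <- survivors[order(cand$subject[survivors])][1]
  tibble::tibble(
    chosen_target = cand$subject[winner],
    n_distinct_peptides = cand$n_distinct_peptides[winner],
    bitscore_sum = cand$bitscore_sum[winner],
    median_pident = cand$median_pident[winner],
    decided_at_tier = decided)
}

#' Regenerate protein-level summaries under updated assignments
#'
#' Re-keys abundance rows from source proteins to their chosen targets,
#' preserving the original intensities. When several sources map to one
#' target, their rows are summed per sample (missing + value = value; all
#' missing stays missing). Unassigned rows are returned separately, never
#' dropped, so total intensity is conserved exactly.
#'
#' @param mat Abundance tibble keyed by source protein.
#' @param reassignments Tibble from [reassign()].
#' @return List with `assigned` (abundance tibble keyed by chosen target,
#'   with an `n_sources` audit column flagging collisions) and `unassigned`
#'   (rows whose source had no target).
#' @export
regenerate_summaries <- function(mat, reassignments) {
  idx <- match(mat$protein_id, reassignments$source_protein)
  if (anyNA(idx)) {
    stop("matrix row(s) without a reassignment record: ",
         paste(utils::head(mat$protein_id[is.na(idx)], 3), collapse = ", "))
  }
  target <- reassignments$chosen_target[idx]
  lost <- is.na(target) | target == "unassigned"

  sum_keep_na <- function(x) if (all(is.na(x))) NA_real_ else sum(x, na.rm = TRUE)
  assigned <- mat[!lost, ] |>
    dplyr::mutate(protein_id = target[!lost]) |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), sum_keep_na),
                     n_sources = dplyr::n(), .groups = "drop")
  list(assigned = assigned, unassigned = mat[lost, ])
}
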