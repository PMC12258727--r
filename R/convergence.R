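#' Aggregate protein-level fold changes to orthogroup level
#'
#' Within each species group, log2 fold changes of proteins belonging to the
#' same orthogroup are averaged into a single orthogroup-level fold change.
#' Proteins without orthogroup assignment, and untested proteins (no log2fc),
#' are excluded. An orthogroup carries a DAP flag when any member protein is
#' called up (resp. down).
#'
#' @param results Named list of `daa_result` tibbles, one per species group
#'   (names such as `"Tripsacum_2019"` are the species_group labels).
#' @param og Long orthogroup tibble ([read_orthogroups()]).
#' @return Tibble with columns `orthogroup_id`, `species_group`,
#'   `mean_log2fc`, `n_proteins`, `any_dap_up`, `any_dap_down`.
#' @export
aggregate_orthogroup_lfc <- function(results, og) {
  stopifnot(is.list(results), !is.null(names(results)))
  purrr::imap(results, function(res, grp) {
    res |>
      dplyr::mutate(orthogroup_id = orthogroup_of(og, .data$protein_id)) |>
      dplyr::filter(.data$orthogroup_id != "unassigned",
                    !is.na(.data$log2fc),
                    .data$call != "untested") |>
      dplyr::group_by(.data$orthogroup_id) |>
      dplyr::summarise(
        species_group = grp,
        mean_log2fc = mean(.data$log2fc),
        n_proteins = dplyr::n(),
        any_dap_up = any(.data$call == "up"),
        any_dap_down = any(.data$call == "down"),
        .groups = "drop")
  }) |>
    dplyr::bind_rows() |>
    dplyr::select("orthogroup_id", "species_group", "mean_log2fc",
                  "n_proteins", "any_dap_up", "any_dap_down")
}

#' Spearman correlation of orthogroup fold changes between two species groups
#'
#' Computed over orthogroups quantified in both groups (all shared
#' quantified orthogroups, not only DAPs), with average-rank tie handling.
#'
#' @param fc Orthogroup fold-change tibble from [aggregate_orthogroup_lfc()].
#' @param group_a,group_b Species group labels.
#' @return Tibble with one row: `group_a`, `group_b`, `rho`, `n`.
#' @export
pairwise_spearman <- function(fc, group_a, group_b) {
  a <- fc[fc$species_group == group_a, c("orthogroup_id", "mean_log2fc")]
  b <- fc[fc$species_group == group_b, c("orthogroup_id", "mean_log2fc")]
  shared <- dplyr::inner_join(a, b, by = "orthogroup_id",
                              suffix = c("_a", "_b"))
  if (nrow(shared) < 3) {
    stop("fewer than 3 shared orthogroups between ", group_a, " and ",
         group_b, "; Spearman correlation undefined")
  }
  tibble::tibble(
    group_a = group_a, group_b = group_b,
    rho = stats::cor(shared$mean_log2fc_a, shared$mean_log2fc_b,
                     method = "spearman"),
    n = nrow(shared))
}

#' All-pairs Spearman correlation matrix of orthogroup fold changes
#'
#' @param fc Orthogroup fold-change tibble.
#' @return Tibble with one row per unordered pair of species groups.
#' @export
spearman_matrix <- function(fc) {
  groups <- sort(unique(fc$species_group))
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  dplyr::bind_rows(purrr::map(pairs, ~ pairwise_spearman(fc, .x[1], .x[2])))
}

#' Cross-species co-occurrence of DAP orthogroups
#'
#' For each orthogroup flagged as a DAP in at least one species group in the
#' given direction, records its exact (exclusive) membership class over
#' species groups, then tallies class counts and sharing fractions.
#'
#' @param fc Orthogroup fold-change tibble with DAP flags.
#' @param direction `"up"` or `"down"`.
#' @return A `cooccurrence_summary` list: `direction`, `classes` (tibble
#'   `class` (labels joined by `&`), `n_species_groups`, `count`), `total`
#'   DAP orthogroups, `frac_shared_1plus` (flagged in >= 2 groups) and
#'   `frac_shared_2plus` (flagged in >= 3 groups).
#' @export
cooccurrence <- function(fc, direction = c("up", "down")) {
  direction <- match.arg(direction)
  flag <- if (direction == "up") fc$any_dap_up else fc$any_dap_down
  dap <- fc[flag, c("orthogroup_id", "species_group")]
  classes <- dap |>
    dplyr::group_by(.data$orthogroup_id) |>
    dplyr::summarise(
      class = paste(sort(unique(.data$species_group)), collapse = "&"),
      n_species_groups = dplyr::n_distinct(.data$species_group),
      .groups = "drop")
  tab <- classes |>
    dplyr::count(.data$class, .data$n_species_groups, name = "count") |>
    dplyr::arrange(dplyr::desc(.data$count))
  total <- nrow(classes)
  out <- list(
    direction = direction,
    classes = tab,
    total = total,
    frac_shared_1plus = if (total) mean(classes$n_species_groups >= 2) else 0,
    frac_shared_2plus = if (total) mean(classes$n_species_groups >= 3) else 0)
  class(out) <- "cooccurrence_summary"
  out
}

#' @export
tidy.cooccurrence_summary <- function(x, ...) {
  dplyr::mutate(x$classes, direction = x$direction)
}

#' @export
glance.cooccurrence_summary <- function(x, ...) {
  tibble::tibble(direction = x$direction, total = x$total,
                 frac_shared_1plus = x$frac_shared_1plus,
                 frac_shared_2plus = x$frac_shared_2plus)
}

#' @export
print.cooccurrence_summary <- function(x, ...) {
  cat("Co-occurrence of", x$direction, "DAP orthogroups:", x$total,
      "total;", sprintf("%.1f%%", 100 * x$frac_shared_1plus),
      "shared with >=1 other group,",
      sprintf("%.1f%%", 100 * x$frac_shared_2plus), "with >=2 others\n")
  print(x$classes, ...)
  invisible(x)
}

#' Bar chart of exclusive co-occurrence classes
#'
#' @param object A `cooccurrence_summary`.
#' @param ... Unused.
#' @return A ggplot object (UpSet-style intersection counts).
#' @export
autoplot.cooccurrence_summary <- function(object, ...) {
  df <- object$classes
  df$class <- stats::reorder(df$class, -df$count)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$count,
                                   fill = factor(.data$n_species_groups))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "orthogroups",
                  fill = "species groups",
                  title = paste0("Exclusive DAP orthogroup classes (",
                                 object$direction, ")")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Top-N most winter-upregulated proteins
#'
#' Selects the `n` proteins with `call == "up"` having the largest log2 fold
#' change; ties broken by smaller adjusted p, then lexicographic protein ID.
#'
#' @param results A `daa_result` tibble with calls populated.
#' @param n Number of proteins (default 50); fewer are returned if fewer
#'   up-DAPs exist.
#' @return Tibble of the selected rows, in rank order.
#' @export
top_n_up <- function(results, n = 50) {
  results |>
    dplyr::filter(.data$call == "up") |>
    dplyr::arrange(dplyr::desc(.data$log2fc), .data$p_adj,
                   .data$protein_id) |>
    dplyr::slice_head(n = n) |>
    tibble::as_tibble()
}
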