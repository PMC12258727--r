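#' The nine cold-related functional categories
#'
#' @return Character vector of category names, in priority order, ending
#'   with `"other/uncategorized"`.
#' @export
cold_categories <- function() {
  c("protein aggregation & membrane stability",
    "protein folding & chaperone activity",
    "metabolism & osmoregulation",
    "detoxification & ROS scavenging",
    "lipid metabolism",
    "antifreeze & cell wall modification",
    "cold signal transduction",
    "cytoskeletal organization",
    "other/uncategorized")
}

#' Default keyword map for cold-related categories
#'
#' Each category maps to a case-insensitive regular expression matched
#' against the concatenated protein description and GO terms. The first
#' matching category in priority order wins; no match assigns
#' `other/uncategorized`. The map is a documented, editable approximation of
#' manual curation, not a claim to reproduce any particular curator's
#' judgment. Ship-time defaults live in
#' `system.file("extdata", "cold_categories.tsv", package = "rhizoprot")`.
#'
#' @return Tibble with columns `category`, `pattern`.
#' @export
default_category_map <- function() {
  read_category_map(system.file("extdata", "cold_categories.tsv",
                                package = "rhizoprot"))
}

#' Read a category keyword map
#'
#' @param path TSV with header columns `category`, `pattern`; row order is
#'   the match priority.
#' @return Tibble with columns `category`, `pattern`.
#' @export
read_category_map <- function(path) {
  map <- readr::read_tsv(path, col_types = readr::cols(
    category = readr::col_character(), pattern = readr::col_character()),
    progress = FALSE)
  map <- strip_readr_attrs(map)
  if (!all(c("category", "pattern") %in% names(map))) {
    stop("category map needs columns 'category' and 'pattern'")
  }
  map
}

#' Assign proteins to cold-related functional categories
#'
#' @param annotations Tibble with `protein_id`, `description` and optionally
#'   `go_terms` (free text; empty strings allowed).
#' @param map Category map tibble (default [default_category_map()]).
#' @return The annotations tibble with a `category` column added;
#'   unmatched proteins get `"other/uncategorized"`. Deterministic given the
#'   map: the first category (in map row order) with a match wins.
#' @export
assign_categories <- function(annotations, map = default_category_map()) {
  stopifnot(all(c("protein_id", "description") %in% names(annotations)))
  text <- annotations$description
  if ("go_terms" %in% names(annotations)) {
    text <- paste(text, annotations$go_terms)
  }
  text[is.na(text)] <- ""
  cat_out <- rep("other/uncategorized", nrow(annotations))
  undecided <- rep(TRUE, nrow(annotations))
  for (i in seq_len(nrow(map))) {
    hit <- undecided & stringr::str_detect(
      text, stringr::regex(map$pattern[i], ignore_case = TRUE))
    cat_out[hit] <- map$category[i]
    undecided[hit] <- FALSE
  }
  dplyr::mutate(annotations, category = cat_out)
}

#' Species-group by category count table
#'
#' @param assigned Tibble with `species_group` and `category` columns.
#' @param drop_other Drop the `other/uncategorized` bin (default FALSE).
#' @return Integer matrix (species groups x categories).
#' @export
category_counts <- function(assigned, drop_other = FALSE) {
  df <- assigned
  if (drop_other) df <- df[df$category != "other/uncategorized", ]
  tab <- table(df$species_group, df$category)
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  m
}

#' Chi-square test of homogeneity for a category count table
#'
#' Pearson chi-square test of independence on an r x c count table (no
#' continuity correction), df = (r-1)(c-1). A warning is emitted when more
#' than 20% of expected counts fall below 5.
#'
#' @param table Integer matrix of counts (species groups x categories).
#' @return A `category_chisq` list: `chi2`, `df`, `p`, `expected`, `table`.
#' @export
chi_square_homogeneity <- function(table) {
  m <- as.matrix(table)
  if (nrow(m) < 2 || ncol(m) < 2) stop("table must be at least 2 x 2")
  if (any(rowSums(m) == 0)) stop("zero row margin in count table")
  if (any(colSums(m) == 0)) stop("zero column margin in count table")
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  expected <- ht$expected
  if (mean(expected < 5) > 0.2) {
    warning(sprintf("%.0f%% of expected counts are below 5; ",
                    100 * mean(expected < 5)),
            "chi-square approximation may be poor")
  }
  out <- list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
              p = ht$p.value, expected = expected, table = m)
  class(out) <- "category_chisq"
  out
}

#' @export
tidy.category_chisq <- function(x, ...) {
  tibble::tibble(chi2 = x$chi2, df = x$df, p = x$p)
}

#' @export
print.category_chisq <- function(x, ...) {
  cat(sprintf("Chi-square test of homogeneity: chi2[%d] = %.3g, p = %.3g\n",
              x$df, x$chi2, x$p))
  invisible(x)
}

#' Mosaic-style plot of category composition per species group
#'
#' @param object A `category_chisq` object.
#' @param ... Unused.
#' @return A ggplot object: within-group category proportions as stacked
#'   bars.
#' @export
autoplot.category_chisq <- function(object, ...) {
  df <- as.data.frame(as.table(object$table))
  names(df) <- c("species_group", "category", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$species_group,
                                   y = .data$count,
                                   fill = .data$category)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::labs(x = NULL, y = "proportion of proteins", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
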