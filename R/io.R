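#' Read a protein abundance matrix and its sample metadata
#'
#' The abundance table is tab-separated with a header row; the first column
#' holds protein identifiers and every remaining column one sample. The
#' companion metadata table has columns `sample_id`, `species`, `season`,
#' `year`, `batch`. Missing intensities may be written as empty cells or
#' `NA`; both are read as `NA`.
#'
#' @param path Path to the abundance TSV.
#' @param meta_path Path to the sample metadata TSV.
#' @return A list with `matrix` (tibble; `protein_id` plus one numeric column
#'   per sample) and `meta` (tibble of validated sample metadata, ordered as
#'   the matrix columns).
#' @export
read_abundance_tsv <- function(path, meta_path) {
  mat <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), na = c("", "NA"), progress = FALSE)
  mat <- strip_readr_attrs(mat)
  names(mat)[1] <- "protein_id"
  for (j in seq_along(mat)[-1]) {
    v <- suppressWarnings(as.numeric(mat[[j]]))
    if (any(is.na(v) & !is.na(mat[[j]]))) {
      stop("non-numeric intensity in column '", names(mat)[j], "' of ", path)
    }
    mat[[j]] <- v
  }
  if (anyDuplicated(mat$protein_id)) {
    dup <- mat$protein_id[duplicated(mat$protein_id)][1]
    stop("duplicate protein ID in ", path, ": ", dup)
  }
  vals <- as.matrix(mat[-1])
  if (any(vals < 0, na.rm = TRUE)) {
    stop("negative intensity values in ", path)
  }
  meta <- read_sample_metadata(meta_path)
  validate_abundance(mat, meta)
  meta <- meta[match(names(mat)[-1], meta$sample_id), ]
  list(matrix = mat, meta = meta)
}

#' Read a sample metadata table
#'
#' @param path TSV with columns sample_id, species, season, year, batch.
#' @return A tibble with `season` as a factor with levels winter, summer.
#' @export
read_sample_metadata <- function(path) {
  meta <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    species = readr::col_character(),
    season = readr::col_character(),
    year = readr::col_integer(),
    batch = readr::col_character()
  ), progress = FALSE)
  meta <- strip_readr_attrs(meta)
  validate_metadata(meta)
  meta$season <- factor(meta$season, levels = c("winter", "summer"))
  meta
}

# readr attaches spec/problems attributes; drop them so read results compare
# cleanly with in-memory tibbles
strip_readr_attrs <- function(x) {
  attr(x, "spec") <- NULL
  attr(x, "problems") <- NULL
  x
}

validate_metadata <- function(meta) {
  required <- c("sample_id", "species", "season", "year", "batch")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    stop("metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         meta$sample_id[duplicated(meta$sample_id)][1])
  }
  bad <- setdiff(unique(as.character(meta$season)), c("winter", "summer"))
  if (length(bad)) {
    stop("season must be 'winter' or 'summer'; found: ",
         paste(bad, collapse = ", "))
  }
  invisible(meta)
}

validate_abundance <- function(mat, meta) {
  samples <- names(mat)[-1]
  absent <- setdiff(samples, meta$sample_id)
  if (length(absent)) {
    stop("sample(s) in abundance matrix absent from metadata: ",
         paste(absent, collapse = ", "))
  }
  invisible(mat)
}

#' Write an abundance matrix (and optionally metadata) as TSV
#'
#' Missing values are written as `NA`.
#'
#' @param mat Abundance tibble (`protein_id` + sample columns).
#' @param path Output path for the matrix.
#' @param meta,meta_path Optional metadata tibble and its output path.
#' @return `path`, invisibly.
#' @export
write_abundance_tsv <- function(mat, path, meta = NULL, meta_path = NULL) {
  readr::write_tsv(mat, path, na = "NA", progress = FALSE)
  if (!is.null(meta)) {
    stopifnot(!is.null(meta_path))
    out <- meta
    out$season <- as.character(out$season)
    readr::write_tsv(out, meta_path, na = "NA", progress = FALSE)
  }
  invisible(path)
}

#' Read a protein FASTA file
#'
#' Header token up to the first whitespace is the protein ID (compared
#' case-sensitively). Sequences are upper-cased and a trailing `*` stop is
#' stripped.
#'
#' @param path FASTA file path.
#' @return Tibble with columns `protein_id`, `sequence`.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) {
    warning("empty FASTA file: ", path)
    return(tibble::tibble(protein_id = character(), sequence = character()))
  }
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop("duplicate protein ID in ", path, ": ", ids[duplicated(ids)][1])
  }
  seqs <- toupper(as.character(ss))
  seqs <- sub("\\*$", "", seqs)
  if (any(!nzchar(seqs))) stop("empty sequence in ", path)
  tibble::tibble(protein_id = unname(ids), sequence = unname(seqs))
}

#' Write protein records as FASTA
#'
#' @param proteins Tibble with `protein_id`, `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  ss <- Biostrings::BStringSet(proteins$sequence)
  names(ss) <- proteins$protein_id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read an OrthoFinder-style orthogroup table
#'
#' First column is the orthogroup ID; each remaining column is one species,
#' holding comma-separated protein IDs (possibly empty). Proteins must belong
#' to at most one orthogroup.
#'
#' @param path Path to an Orthogroups.tsv-dialect file.
#' @return Long tibble with columns `orthogroup_id`, `species`, `protein_id`.
#' @export
read_orthogroups <- function(path) {
  wide <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), na = character(), progress = FALSE)
  wide <- strip_readr_attrs(wide)
  names(wide)[1] <- "orthogroup_id"
  long <- tidyr::pivot_longer(wide, -"orthogroup_id",
                              names_to = "species", values_to = "proteins")
  long <- long[nzchar(trimws(long$proteins)), ]
  long <- tidyr::separate_rows(long, "proteins", sep = ",")
  long$protein_id <- trimws(long$proteins)
  long <- long[nzchar(long$protein_id), c("orthogroup_id", "species", "protein_id")]
  if (anyDuplicated(long$protein_id)) {
    dup <- long$protein_id[duplicated(long$protein_id)][1]
    stop("protein listed in more than one orthogroup: ", dup)
  }
  tibble::as_tibble(long)
}

#' Write an orthogroup table in OrthoFinder dialect
#'
#' @param og Long orthogroup tibble (`orthogroup_id`, `species`, `protein_id`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_orthogroups <- function(og, path) {
  wide <- og |>
    dplyr::group_by(.data$orthogroup_id, .data$species) |>
    dplyr::summarise(proteins = paste(.data$protein_id, collapse = ", "),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "species", values_from = "proteins",
                       values_fill = "") |>
    dplyr::arrange(.data$orthogroup_id)
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Look up orthogroup membership, with an "unassigned" sentinel
#'
#' @param og Long orthogroup tibble from [read_orthogroups()].
#' @param protein_ids Character vector of protein IDs.
#' @return Character vector of orthogroup IDs; proteins absent from the table
#'   get `"unassigned"`.
#' @export
orthogroup_of <- function(og, protein_ids) {
  idx <- match(protein_ids, og$protein_id)
  out <- og$orthogroup_id[idx]
  out[is.na(idx)] <- "unassigned"
  out
}

outfmt6_cols <- c("query", "subject", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")

#' Read a 12-column BLAST/DIAMOND tabular hit table
#'
#' Standard outfmt-6 columns: query, subject, pident, length, mismatch,
#' gapopen, qstart, qend, sstart, send, evalue, bitscore. The query field may
#' use the `peptideID|sourceProteinID` convention; [split_query_ids()]
#' decodes it.
#'
#' @param path Path to the tab-separated hit table (no header).
#' @return Tibble with the 12 typed columns.
#' @export
read_hit_table <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble::as_tibble(stats::setNames(
      c(list(character(), character()), rep(list(numeric()), 10)),
      outfmt6_cols)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    bad <- which(nf != 12L)[1]
    stop("hit table line ", bad, " has ", nf[bad], " columns; expected 12")
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  hits <- tibble::tibble(
    query = m[, 1], subject = m[, 2],
    pident = as.numeric(m[, 3]), length = as.integer(m[, 4]),
    mismatch = as.integer(m[, 5]), gapopen = as.integer(m[, 6]),
    qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
    sstart = as.integer(m[, 9]), send = as.integer(m[, 10]),
    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12])
  )
  if (any(is.na(hits$pident)) || any(hits$pident < 0 | hits$pident > 100)) {
    stop("pident outside [0, 100] in ", path)
  }
  if (any(is.na(hits$bitscore))) stop("non-numeric bitscore in ", path)
  hits
}

#' Write a hit table in 12-column tabular format
#'
#' @param hits Tibble with the outfmt-6 columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  readr::write_tsv(hits[outfmt6_cols], path, col_names = FALSE,
                   progress = FALSE)
  invisible(path)
}

#' Split `peptideID|sourceProteinID` query identifiers
#'
#' @param hits Hit tibble whose `query` column uses the pipe convention.
#' @return The tibble with `peptide_id` and `source_protein` columns added.
#' @export
split_query_ids <- function(hits) {
  parts <- stringr::str_split_fixed(hits$query, stringr::fixed("|"), 2)
  if (any(!nzchar(parts[, 2]))) {
    stop("query field is not in 'peptideID|sourceProteinID' form")
  }
  hits$peptide_id <- parts[, 1]
  hits$source_protein <- parts[, 2]
  hits
}
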