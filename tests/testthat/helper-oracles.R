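# Independent brute-force oracles used across the suite. These deliberately
# re-derive results from first principles, by enumeration or naive loops,
# and never call the implementation paths they check.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_aa <- function(n, alphabet = AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# --- motif grammar oracle ---------------------------------------------------
# Naive per-window check written independently of the package's matcher:
# explicit position tests, explicit enumeration of the two middle patterns,
# explicit mismatch bookkeeping; then greedy left-to-right selection over
# the full candidate list.
oracle_window_ok <- function(win, apolar = c("A","T","V","L","I","M","F"),
                             pos = c("K","R"), neg = c("D","E"),
                             allow = 0L, allow_at = 1L) {
  best_bad <- Inf
  best_where <- NULL
  for (pattern in c("pmp", "pqp")) {
    bad <- integer()
    for (p in c(1, 2, 5, 9)) if (!(win[p] %in% apolar)) bad <- c(bad, p)
    if (!(win[6] %in% pos)) bad <- c(bad, 6)
    if (pattern == "pmp") {
      if (!(win[7] %in% neg)) bad <- c(bad, 7)
    } else {
      if (win[7] != "Q") bad <- c(bad, 7)
    }
    if (!(win[8] %in% pos)) bad <- c(bad, 8)
    if (length(bad) < best_bad) { best_bad <- length(bad); best_where <- bad }
  }
  best_bad == 0 || (best_bad <= allow && all(best_where %in% allow_at))
}

oracle_detect <- function(sequence, allow = 0L, allow_at = 1L) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  L <- length(chars)
  if (L < 11) return(integer())
  candidates <- Filter(function(i)
    oracle_window_ok(chars[i:(i + 10)], allow = allow, allow_at = allow_at),
    seq_len(L - 10))
  chosen <- integer()
  last_end <- 0
  for (i in candidates) {
    if (i > last_end) { chosen <- c(chosen, i); last_end <- i + 10 }
  }
  chosen
}

# --- reassignment oracle ----------------------------------------------------
# Per source protein: aggregate candidate stats with base R, then take the
# single best row under the lexicographic key
# (-distinct peptides, -bitscore sum, -median pident, target id).
oracle_reassign <- function(hits) {
  sources <- sort(unique(hits$source_protein))
  out <- lapply(sources, function(src) {
    h <- hits[hits$source_protein == src, ]
    cand <- sort(unique(h$subject))
    stats <- t(vapply(cand, function(tg) {
      ht <- h[h$subject == tg, ]
      c(npep = length(unique(ht$peptide_id)),
        bsum = sum(ht$bitscore),
        mpid = median(ht$pident))
    }, numeric(3)))
    o <- order(-stats[, "npep"], -stats[, "bsum"], -stats[, "mpid"], cand)
    data.frame(source_protein = src, chosen_target = cand[o[1]])
  })
  do.call(rbind, out)
}

# --- alignment oracle -------------------------------------------------------
# Exhaustive recursive enumeration of global alignments with affine gaps:
# a gap run of length L costs open + L * extend; substitution scores from
# BLOSUM62. Feasible for sequences of <= 8 residues.
oracle_align_score <- function(a, b, open = 10, extend = 1) {
  sm <- get_blosum62()
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  rec <- function(i, j, state) {
    if (i > length(ca) && j > length(cb)) return(0)
    best <- -Inf
    if (i <= length(ca) && j <= length(cb)) {
      best <- max(best, sm[ca[i], cb[j]] + rec(i + 1, j + 1, "m"))
    }
    if (i <= length(ca)) {
      cost <- extend + if (state == "ga") 0 else open
      best <- max(best, -cost + rec(i + 1, j, "ga"))
    }
    if (j <= length(cb)) {
      cost <- extend + if (state == "gb") 0 else open
      best <- max(best, -cost + rec(i, j + 1, "gb"))
    }
    best
  }
  rec(1, 1, "m")
}

get_blosum62 <- local({
  sm <- NULL
  function() {
    if (is.null(sm)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      sm <<- e$BLOSUM62
    }
    sm
  }
})

# --- small data builders ----------------------------------------------------

make_matrix <- function(values, protein_ids = NULL, sample_ids = NULL) {
  values <- as.matrix(values)
  if (is.null(protein_ids)) protein_ids <- paste0("p", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(values)))
  df <- tibble::as_tibble(as.data.frame(values))
  names(df) <- sample_ids
  dplyr::bind_cols(tibble::tibble(protein_id = protein_ids), df)
}

make_meta <- function(sample_ids, seasons, species = "sp",
                      year = 2022L, batch = "b1") {
  tibble::tibble(sample_id = sample_ids, species = species,
                 season = factor(seasons, levels = c("winter", "summer")),
                 year = year, batch = batch)
}
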