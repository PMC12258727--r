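#' Dure 11-mer motif grammar
#'
#' The group-3 LEA motif is an 11-residue repeat with apolar residues at
#' positions 1, 2, 5 and 9 (the hydrophobic helix face) and a charged
#' arrangement at positions 6-8: either "+ - +" (alternating positive and
#' negative) or "+ Q +". Threonine substitutes for alanine at apolar
#' positions, hence T in the default apolar set. Histidine is excluded from
#' the charge sets by default (ambiguous protonation). Positions 3, 4, 10
#' and 11 are unconstrained.
#'
#' The `figure6` preset allows one deviation at motif position 1, matching
#' architectures in which the first motif of a run departs from the strict
#' grammar at that position.
#'
#' @param apolar_set Residues accepted at positions 1, 2, 5, 9.
#' @param pos_charge_set,neg_charge_set Residues counted as + and -.
#' @param mismatch_allowance Maximum grammar violations tolerated per
#'   window (default 0).
#' @param mismatch_positions Motif positions (1-11) at which violations may
#'   occur (default position 1).
#' @return A `motif_rule` list.
#' @export
motif_rule <- function(apolar_set = c("A", "T", "V", "L", "I", "M", "F"),
                       pos_charge_set = c("K", "R"),
                       neg_charge_set = c("D", "E"),
                       mismatch_allowance = 0L,
                       mismatch_positions = 1L) {
  rule <- list(apolar_set = apolar_set, pos_charge_set = pos_charge_set,
               neg_charge_set = neg_charge_set,
               mismatch_allowance = as.integer(mismatch_allowance),
               mismatch_positions = as.integer(mismatch_positions))
  class(rule) <- "motif_rule"
  rule
}

#' @rdname motif_rule
#' @param preset `"default"` or `"figure6"` (one tolerated deviation at
#'   motif position 1).
#' @export
motif_rule_preset <- function(preset = c("default", "figure6")) {
  preset <- match.arg(preset)
  if (preset == "figure6") {
    motif_rule(mismatch_allowance = 1L, mismatch_positions = 1L)
  } else {
    motif_rule()
  }
}

# Per-position grammar violations of one 11-residue window (character
# vector). Positions 6-8 are scored against whichever middle pattern
# ("+ - +" or "+ Q +") incurs fewer violations.
window_violations <- function(win, rule) {
  v <- logical(11)
  v[c(1, 2, 5, 9)] <- !(win[c(1, 2, 5, 9)] %in% rule$apolar_set)
  plus_ok <- win[c(6, 8)] %in% rule$pos_charge_set
  mid_charge <- c(!plus_ok[1], !(win[7] %in% rule$neg_charge_set),
                  !plus_ok[2])
  mid_q <- c(!plus_ok[1], win[7] != "Q", !plus_ok[2])
  v[6:8] <- if (sum(mid_charge) <= sum(mid_q)) mid_charge else mid_q
  v
}

window_matches <- function(win, rule) {
  v <- window_violations(win, rule)
  n_bad <- sum(v)
  n_bad == 0L || (n_bad <= rule$mismatch_allowance &&
                    all(which(v) %in% rule$mismatch_positions))
}

#' Detect Dure 11-mer motifs and their chain architecture
#'
#' Every 11-residue window satisfying the grammar is a candidate;
#' overlapping candidates are resolved by a greedy left-to-right
#' non-overlapping scan (a match at position i suppresses candidates
#' starting before i + 11). Inter-motif gaps and the maximal run of
#' consecutive (gap 0) motifs are derived from the accepted starts.
#'
#' @param sequence Amino-acid string (1-based coordinates throughout).
#' @param rule A [motif_rule()] (or [motif_rule_preset()]).
#' @return A `motif_chain` list: `starts` (1-based), `gaps` (residues
#'   between consecutive accepted motifs), `max_run` (longest run of
#'   consecutive motifs), `n_motifs`. Sequences shorter than 11 yield an
#'   empty chain with a warning.
#' @export
detect_motifs <- function(sequence, rule = motif_rule()) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  L <- length(chars)
  if (L < 11) {
    warning("sequence shorter than 11 residues; no motif possible")
    return(new_motif_chain(integer(), L))
  }
  starts <- integer()
  i <- 1L
  while (i <= L - 10L) {
    if (window_matches(chars[i:(i + 10L)], rule)) {
      starts <- c(starts, i)
      i <- i + 11L
    } else {
      i <- i + 1L
    }
  }
  new_motif_chain(starts, L)
}

new_motif_chain <- function(starts, seq_length) {
  gaps <- if (length(starts) > 1) diff(starts) - 11L else integer()
  run <- 1L; max_run <- if (length(starts)) 1L else 0L
  for (g in gaps) {
    run <- if (g == 0L) run + 1L else 1L
    max_run <- max(max_run, run)
  }
  out <- list(starts = starts, gaps = gaps, max_run = max_run,
              n_motifs = length(starts), seq_length = seq_length)
  class(out) <- "motif_chain"
  out
}

#' @export
print.motif_chain <- function(x, ...) {
  cat("Motif chain:", x$n_motifs, "motif(s)",
      if (x$n_motifs) paste0("at ", paste(x$starts, collapse = ", ")),
      "; max consecutive run", x$max_run, "\n")
  if (length(x$gaps)) cat("gaps:", paste(x$gaps, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.motif_chain <- function(x, ...) {
  tibble::tibble(start = x$starts,
                 gap_before = c(NA_integer_, x$gaps))
}

#' Detect motifs across a whole proteome
#'
#' @param proteins Tibble with `protein_id`, `sequence`.
#' @param rule A [motif_rule()].
#' @return Tibble with `protein_id`, `n_motifs`, `max_run`, `starts` and
#'   `gaps` list-columns.
#' @export
detect_motifs_all <- function(proteins, rule = motif_rule()) {
  chains <- purrr::map(proteins$sequence,
                       ~ suppressWarnings(detect_motifs(.x, rule)))
  tibble::tibble(
    protein_id = proteins$protein_id,
    n_motifs = purrr::map_int(chains, "n_motifs"),
    max_run = purrr::map_int(chains, "max_run"),
    starts = purrr::map(chains, "starts"),
    gaps = purrr::map(chains, "gaps"))
}

#' Hydrophobicity scales
#'
#' `kyte_doolittle` is the standard Kyte-Doolittle hydropathy index;
#' `eisenberg` the Eisenberg consensus scale.
#'
#' @param name Scale name.
#' @return Named numeric vector over the 20 standard residues.
#' @export
hydropathy_scale <- function(name = c("kyte_doolittle", "eisenberg")) {
  name <- match.arg(name)
  switch(name,
    kyte_doolittle = c(
      A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
      G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
      P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2),
    eisenberg = c(
      A = 0.62, R = -2.53, N = -0.78, D = -0.90, C = 0.29, Q = -0.85,
      E = -0.74, G = 0.48, H = -0.40, I = 1.38, L = 1.06, K = -1.50,
      M = 0.64, F = 1.19, P = 0.12, S = -0.18, T = -0.05, W = 0.81,
      Y = 0.26, V = 1.08))
}

#' Sliding-window hydropathy profile
#'
#' The score at residue i is the mean scale value over the window
#' `[i - (w-1)/2, i + (w-1)/2]`; positions where the window does not fit are
#' undefined. The default window of 11 matches the LEA3 motif length.
#'
#' @param sequence Amino-acid string.
#' @param scale Scale name (see [hydropathy_scale()]) or a named numeric
#'   vector for a custom scale.
#' @param window Odd window width >= 1.
#' @param on_missing What to do with residues absent from the scale (e.g.
#'   X): `"error"` (default) or `"skip"` (exclude them from window means).
#' @return A `hydropathy_profile` tibble with columns `position` (1-based)
#'   and `score` (`NA` at termini where the window does not fit).
#' @export
hydropathy <- function(sequence, scale = "kyte_doolittle", window = 11,
                       on_missing = c("error", "skip")) {
  on_missing <- match.arg(on_missing)
  if (window < 1 || window %% 2 == 0) stop("window must be odd and >= 1")
  sc <- if (is.character(scale)) hydropathy_scale(scale) else scale
  chars <- strsplit(toupper(sequence), "")[[1]]
  vals <- unname(sc[chars])
  if (anyNA(vals)) {
    if (on_missing == "error") {
      stop("residue(s) absent from the hydropathy scale: ",
           paste(unique(chars[is.na(vals)]), collapse = ", "))
    }
  }
  L <- length(vals)
  half <- (window - 1) / 2
  score <- rep(NA_real_, L)
  if (L >= window) {
    for (i in (1 + half):(L - half)) {
      score[i] <- mean(vals[(i - half):(i + half)], na.rm = TRUE)
    }
  }
  out <- tibble::tibble(position = seq_len(L), score = score)
  class(out) <- c("hydropathy_profile", class(out))
  attr(out, "window") <- window
  attr(out, "scale") <- if (is.character(scale)) scale else "custom"
  out
}

#' Line plot of a hydropathy profile
#'
#' @param object A `hydropathy_profile`.
#' @param ... Unused.
#' @return A ggplot object: windowed hydropathy along the sequence
#'   (positive = hydrophobic).
#' @export
autoplot.hydropathy_profile <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(tibble::as_tibble(object),
                                !is.na(.data$score)),
                  ggplot2::aes(x = .data$position, y = .data$score)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue position",
                  y = paste0("hydropathy (window ",
                             attr(object, "window"), ")")) +
    ggplot2::theme_minimal()
}

#' Mean hydropathy by motif position class
#'
#' Within a region, residues are binned by their position in the 11-residue
#' motif frame (position class of residue i is
#' `((i - frame_start) mod 11) + 1`), and the mean profile score of each
#' requested class is reported.
#'
#' @param profile A `hydropathy_profile`.
#' @param region Length-2 integer vector, 1-based inclusive.
#' @param frame_start Residue position at which motif position 1 falls.
#' @param positions Motif positions (subset of 1..11) to report.
#' @return Tibble with `motif_position`, `mean_score` (`NA` when a class is
#'   empty in the region), `n_residues`.
#' @export
position_class_stats <- function(profile, region, frame_start = region[1],
                                 positions = c(1, 2, 5, 9)) {
  stopifnot(length(region) == 2, region[1] <= region[2])
  idx <- region[1]:region[2]
  idx <- idx[idx >= 1 & idx <= nrow(profile)]
  cls <- ((idx - frame_start) %% 11) + 1
  score <- profile$score[idx]
  purrr::map_dfr(positions, function(p) {
    sel <- cls == p & !is.na(score)
    tibble::tibble(
      motif_position = p,
      mean_score = if (any(sel)) mean(score[sel]) else NA_real_,
      n_residues = sum(sel))
  })
}

#' Compare two hydropathy profiles over aligned positions
#'
#' Over paired positions falling in `region` (given in the coordinates of
#' profile `a`), computes the mean paired hydropathy difference
#' (`delta_hydro = mean(score_a - score_b)`) and the Pearson correlation of
#' the paired score vectors (`pattern_r`); a strongly negative `pattern_r`
#' flags a reversal of the hydrophobic/hydrophilic pattern.
#'
#' @param a,b `hydropathy_profile` tibbles.
#' @param pairing Tibble with `pos_a`, `pos_b` (from [align_pair()] or an
#'   external alignment; gapped columns already dropped).
#' @param region Length-2 interval in `a`'s coordinates.
#' @return Tibble with one row: `delta_hydro`, `pattern_r`, `n_pairs`.
#' @export
compare_profiles <- function(a, b, pairing, region) {
  sel <- pairing$pos_a >= region[1] & pairing$pos_a <= region[2]
  sa <- a$score[pairing$pos_a[sel]]
  sb <- b$score[pairing$pos_b[sel]]
  ok <- !is.na(sa) & !is.na(sb)
  sa <- sa[ok]; sb <- sb[ok]
  if (length(sa) < 3) {
    stop("fewer than 3 paired positions with defined scores in region; ",
         "pattern correlation undefined")
  }
  if (stats::sd(sa) == 0 || stats::sd(sb) == 0) {
    stop("zero variance in a paired score vector; correlation undefined")
  }
  tibble::tibble(delta_hydro = mean(sa - sb),
                 pattern_r = stats::cor(sa, sb),
                 n_pairs = length(sa))
}

#' Global pairwise alignment position map
#'
#' Needleman-Wunsch global alignment (BLOSUM62, gap opening 10, gap
#' extension 1) between two protein sequences, returning the aligned
#' position pairing with gapped columns dropped. An externally produced
#' aligned-FASTA pair can be converted with [pairing_from_alignment()].
#'
#' @param a,b Amino-acid strings.
#' @return Tibble with columns `pos_a`, `pos_b` (1-based matched positions).
#' @export
align_pair <- function(a, b) {
  stopifnot(nzchar(a), nzchar(b))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(a)), Biostrings::AAString(toupper(b)),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 1)
  pairing_from_strings(as.character(Biostrings::alignedPattern(aln)),
                       as.character(Biostrings::alignedSubject(aln)))
}

#' Position pairing from an aligned sequence pair
#'
#' @param aligned_a,aligned_b Gapped aligned strings of equal length
#'   (`-` for gaps).
#' @return Tibble `pos_a`, `pos_b` over columns where both are residues.
#' @export
pairing_from_strings <- function(aligned_a, aligned_b) {
  ca <- strsplit(aligned_a, "")[[1]]
  cb <- strsplit(aligned_b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  pos_a <- cumsum(ca != "-")
  pos_b <- cumsum(cb != "-")
  keep <- ca != "-" & cb != "-"
  tibble::tibble(pos_a = pos_a[keep], pos_b = pos_b[keep])
}

#' Position pairing from a two-record aligned FASTA file
#'
#' @param path Aligned FASTA with exactly two records.
#' @return Tibble `pos_a`, `pos_b`.
#' @export
pairing_from_alignment <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) != 2) stop("aligned FASTA must contain exactly 2 records")
  pairing_from_strings(as.character(ss[[1]]), as.character(ss[[2]]))
}
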