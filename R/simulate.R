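#' Simulation settings for a multi-species seasonal abundance dataset
#'
#' Intensities are log-normal on the log2 scale:
#' `log2(intensity) = baseline + effect * I(winter) + batch + noise`, so a
#' planted effect of e log2 units is exactly the expected log2 fold change.
#' Regulation is planted at the orthogroup level; a `shared_frac` subset of
#' regulated orthogroups is regulated with the same sign in every species,
#' the remainder in a single randomly chosen species.
#'
#' @param n_species Number of species (named species_1, ...).
#' @param n_orthogroups Orthogroups per species.
#' @param proteins_per_orthogroup Integer (constant) or integer vector to
#'   sample member counts from.
#' @param n_replicates_per_season Samples per season per species (>= 2).
#' @param frac_up,frac_down Proportions of orthogroups planted winter-up /
#'   winter-down (`frac_up + frac_down <= 1`).
#' @param effect_size_log2 Planted |log2 fold change| (>= 0).
#' @param shared_frac Proportion of regulated orthogroups regulated in all
#'   species with the same sign.
#' @param noise_sd_log2 Residual SD on the log2 scale.
#' @param batch_sd_log2 SD of per-sample additive batch offsets (log2 scale);
#'   two batches balanced across seasons.
#' @param missing_rate Proportion of entries set missing.
#' @param year Calendar year written into the metadata.
#' @param seed Integer seed; a fixed seed reproduces the dataset exactly.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_species = 5, n_orthogroups = 400,
                       proteins_per_orthogroup = 1,
                       n_replicates_per_season = 4,
                       frac_up = 0.1, frac_down = 0.1,
                       effect_size_log2 = 3, shared_frac = 0.2,
                       noise_sd_log2 = 0.3, batch_sd_log2 = 0,
                       missing_rate = 0, year = 2022L, seed = 1L) {
  cfg <- list(n_species = n_species, n_orthogroups = n_orthogroups,
              proteins_per_orthogroup = proteins_per_orthogroup,
              n_replicates_per_season = n_replicates_per_season,
              frac_up = frac_up, frac_down = frac_down,
              effect_size_log2 = effect_size_log2, shared_frac = shared_frac,
              noise_sd_log2 = noise_sd_log2, batch_sd_log2 = batch_sd_log2,
              missing_rate = missing_rate, year = as.integer(year),
              seed = as.integer(seed))
  props <- c(cfg$frac_up, cfg$frac_down, cfg$shared_frac, cfg$missing_rate)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  if (cfg$frac_up + cfg$frac_down > 1) stop("frac_up + frac_down must be <= 1")
  if (cfg$effect_size_log2 < 0) stop("effect_size_log2 must be >= 0")
  if (cfg$n_replicates_per_season < 2) {
    stop("at least 2 replicates per season are required")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a multi-species seasonal abundance dataset with ground truth
#'
#' @param config A [sim_config()] object.
#' @return A list with `matrices` (named list of abundance tibbles, one per
#'   species), `meta` (sample metadata for all species), `orthogroups`
#'   (long orthogroup table) and `truth` (list of tibbles: `proteins` with
#'   per-protein signed true effects, `orthogroups` with per-species
#'   regulation status).
#' @export
gen_abundance_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  species <- paste0("species_", seq_len(config$n_species))
  og_ids <- sprintf("OG%07d", seq_len(config$n_orthogroups))

  n_reg <- round((config$frac_up + config$frac_down) * config$n_orthogroups)
  reg_ogs <- sample(og_ids, n_reg)
  n_up <- round(config$frac_up * config$n_orthogroups)
  sign_of <- stats::setNames(
    sample(c(rep(1, n_up), rep(-1, n_reg - n_up))[seq_len(n_reg)]), reg_ogs)
  n_shared <- round(config$shared_frac * n_reg)
  shared_ogs <- if (n_reg) reg_ogs[seq_len(n_shared)] else character()
  private_species <- stats::setNames(
    sample(species, max(n_reg - n_shared, 0), replace = TRUE),
    setdiff(reg_ogs, shared_ogs))

  og_truth <- tidyr::expand_grid(orthogroup_id = og_ids, species = species)
  og_truth$direction <- "none"
  is_reg <- og_truth$orthogroup_id %in% reg_ogs &
    (og_truth$orthogroup_id %in% shared_ogs |
       private_species[og_truth$orthogroup_id] == og_truth$species)
  is_reg[is.na(is_reg)] <- FALSE
  og_truth$direction[is_reg] <-
    ifelse(sign_of[og_truth$orthogroup_id[is_reg]] > 0, "up", "down")

  ppo <- config$proteins_per_orthogroup
  matrices <- list(); metas <- list(); og_rows <- list(); prot_truth <- list()
  for (sp in species) {
    counts <- if (length(ppo) == 1L) rep(ppo, config$n_orthogroups) else
      sample(ppo, config$n_orthogroups, replace = TRUE)
    prot_og <- rep(og_ids, counts)
    prot_ids <- sprintf("%s_p%05d", sp, seq_along(prot_og))
    n_prot <- length(prot_ids)

    dir_sp <- og_truth$direction[og_truth$species == sp]
    names(dir_sp) <- og_ids
    eff <- c(none = 0, up = 1, down = -1)[dir_sp[prot_og]] *
      config$effect_size_log2

    nrep <- config$n_replicates_per_season
    sample_ids <- sprintf("%s_%s_%d", sp,
                          rep(c("winter", "summer"), each = nrep),
                          rep(seq_len(nrep), 2))
    season <- rep(c("winter", "summer"), each = nrep)
    batch <- paste0("b", rep_len(c(1, 2), nrep))[c(seq_len(nrep), seq_len(nrep))]
    batch_off <- stats::setNames(
      stats::rnorm(length(unique(batch)), 0, config$batch_sd_log2),
      unique(batch))

    baseline <- stats::rnorm(n_prot, mean = 20, sd = 2)
    log2m <- outer(baseline, rep(0, length(sample_ids)), `+`) +
      outer(eff, as.numeric(season == "winter")) +
      matrix(rep(batch_off[batch], each = n_prot), nrow = n_prot) +
      matrix(stats::rnorm(n_prot * length(sample_ids), 0,
                          config$noise_sd_log2), nrow = n_prot)
    vals <- 2^log2m
    if (config$missing_rate > 0) {
      vals[stats::runif(length(vals)) < config$missing_rate] <- NA
    }
    m <- tibble::as_tibble(as.data.frame(vals))
    names(m) <- sample_ids
    matrices[[sp]] <- dplyr::bind_cols(
      tibble::tibble(protein_id = prot_ids), m)
    metas[[sp]] <- tibble::tibble(
      sample_id = sample_ids, species = sp,
      season = factor(season, levels = c("winter", "summer")),
      year = config$year, batch = batch)
    og_rows[[sp]] <- tibble::tibble(orthogroup_id = prot_og, species = sp,
                                    protein_id = prot_ids)
    prot_truth[[sp]] <- tibble::tibble(
      species = sp, protein_id = prot_ids, orthogroup_id = prot_og,
      true_log2fc = unname(eff))
  }

  list(matrices = matrices,
       meta = dplyr::bind_rows(metas),
       orthogroups = dplyr::bind_rows(og_rows),
       truth = list(proteins = dplyr::bind_rows(prot_truth),
                    orthogroups = og_truth,
                    config = config))
}

# Residue alphabets used by the sequence generators. Filler residues are
# drawn from letters outside the default apolar and charge sets (and not Q),
# so filler regions cannot satisfy the motif grammar at any offset.
motif_filler_alphabet <- c("G", "S", "N", "P", "W", "C", "H")

random_filler <- function(n) {
  paste(sample(motif_filler_alphabet, n, replace = TRUE), collapse = "")
}

random_motif <- function(rule = motif_rule()) {
  pos <- character(11)
  pos[c(1, 2, 5, 9)] <- sample(rule$apolar_set, 4, replace = TRUE)
  middle <- sample(c("charge", "q"), 1)
  pos[6] <- sample(rule$pos_charge_set, 1)
  pos[7] <- if (middle == "q") "Q" else sample(rule$neg_charge_set, 1)
  pos[8] <- sample(rule$pos_charge_set, 1)
  pos[c(3, 4, 10, 11)] <- sample(motif_filler_alphabet, 4, replace = TRUE)
  paste(pos, collapse = "")
}

#' Generate a proteome with planted LEA3 11-mer motif architectures
#'
#' `n_with_chain` sequences carry a run of `chain_length` valid Dure 11-mers;
#' when `insertion_len > 0` the run is split once, after
#' `floor(chain_length / 2)` motifs, by an insertion of filler residues that
#' themselves form no motif. All remaining sequences and all filler regions
#' are motif-free by construction (filler letters lie outside the apolar and
#' charge alphabets).
#'
#' @param n_proteins Total sequences.
#' @param n_with_chain Sequences carrying a planted chain.
#' @param chain_length Motifs per chain (>= 1).
#' @param insertion_len Length of the single inter-motif insertion (0 = none).
#' @param seed Integer seed.
#' @param rule Motif rule used to draw valid motifs (default [motif_rule()]).
#' @return List with `proteins` (tibble `protein_id`, `sequence`) and `truth`
#'   (tibble `protein_id`, `motif_starts` list-column of 1-based starts).
#' @export
gen_motif_proteome <- function(n_proteins, n_with_chain, chain_length,
                               insertion_len = 0, seed = 1L,
                               rule = motif_rule()) {
  if (chain_length < 1) stop("chain_length must be >= 1")
  if (n_with_chain > n_proteins) stop("n_with_chain exceeds n_proteins")
  set.seed(as.integer(seed))
  ids <- sprintf("prot%04d", seq_len(n_proteins))
  seqs <- character(n_proteins)
  starts <- vector("list", n_proteins)
  split_after <- floor(chain_length / 2)
  for (i in seq_len(n_proteins)) {
    lead <- sample(15:40, 1)
    if (i <= n_with_chain) {
      motifs <- vapply(seq_len(chain_length), function(...) random_motif(rule),
                       character(1))
      if (insertion_len > 0 && chain_length > 1) {
        body <- paste0(paste(motifs[seq_len(split_after)], collapse = ""),
                       random_filler(insertion_len),
                       paste(motifs[-seq_len(split_after)], collapse = ""))
        st <- c((seq_len(split_after) - 1) * 11 + 1,
                split_after * 11 + insertion_len +
                  (seq_len(chain_length - split_after) - 1) * 11 + 1)
      } else {
        body <- paste(motifs, collapse = "")
        st <- (seq_len(chain_length) - 1) * 11 + 1
      }
      seqs[i] <- paste0(random_filler(lead), body, random_filler(lead))
      starts[[i]] <- st + lead
    } else {
      seqs[i] <- random_filler(sample(80:200, 1))
      starts[[i]] <- integer()
    }
  }
  list(proteins = tibble::tibble(protein_id = ids, sequence = seqs),
       truth = tibble::tibble(protein_id = ids, motif_starts = starts))
}

#' Generate a cross-proteome peptide reassignment scenario
#'
#' Emulates re-aligning peptides quantified against a mismatched reference
#' to the correct proteome. Each source protein has a unique true target.
#' When `decoy_similarity > 0`, every source also receives one decoy
#' competitor constructed so the tie-break ladder is resolved at a planted
#' tier (cycling 1..4 across source proteins): the decoy ties the true
#' target on all shallower tiers and, at the planted tier, strictly wins
#' with probability `decoy_similarity`, otherwise strictly loses. Recovery
#' of true targets is therefore 100% at `decoy_similarity = 0` and decreases
#' in expectation as `decoy_similarity` grows.
#'
#' @param n_proteins Number of source proteins.
#' @param peptides_per_protein Distinct peptides per source protein (>= 2).
#' @param decoy_similarity Probability in `[0, 1]` that a decoy wins at its
#'   planted tier; 0 disables decoys entirely.
#' @param seed Integer seed.
#' @return List with `hits` (outfmt-6 tibble, query =
#'   `peptideID|sourceProteinID`), `source_proteome`, `target_proteome`
#'   (tibbles of `protein_id`, `sequence`) and `truth` (tibble
#'   `source_protein`, `true_target`, `planted_tier`, `decoy_wins`).
#' @export
gen_peptide_scenario <- function(n_proteins, peptides_per_protein = 4,
                                 decoy_similarity = 0, seed = 1L) {
  if (decoy_similarity < 0 || decoy_similarity > 1) {
    stop("decoy_similarity must lie in [0, 1]")
  }
  if (peptides_per_protein < 2) stop("peptides_per_protein must be >= 2")
  set.seed(as.integer(seed))
  k <- peptides_per_protein
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

  src_ids <- sprintf("src%04d", seq_len(n_proteins))
  tgt_ids <- sprintf("tgtM%04d", seq_len(n_proteins))
  decoy_ids <- sprintf("tgtZ%04d", seq_len(n_proteins))
  # tier-4 decoys must be lexicographically smaller than the true target to
  # be able to win the deterministic fallback
  decoy_ids_small <- sprintf("tgtA%04d", seq_len(n_proteins))

  pep_len <- 9L
  tiers <- rep_len(1:4, n_proteins)
  use_decoy <- decoy_similarity > 0
  wins <- if (use_decoy) stats::runif(n_proteins) < decoy_similarity else
    rep(FALSE, n_proteins)

  hit_rows <- vector("list", n_proteins)
  tgt_seqs <- character(n_proteins)
  decoy_seqs <- character(n_proteins)
  truth <- vector("list", n_proteins)
  for (i in seq_len(n_proteins)) {
    tgt_seq <- paste(sample(aa20, k * pep_len + 20, replace = TRUE),
                     collapse = "")
    tgt_seqs[i] <- tgt_seq
    peps <- substring(tgt_seq, (seq_len(k) - 1) * pep_len + 1,
                      seq_len(k) * pep_len)
    pep_ids <- sprintf("%s_pep%02d", src_ids[i], seq_len(k))
    true_bits <- 2 * pep_len + seq_len(k)        # distinct, sum known
    true_pid <- 100 - seq_len(k)                 # distinct identities

    mk_row <- function(pid, tgt, pident, bits) tibble::tibble(
      query = paste0(pid, "|", src_ids[i]), subject = tgt,
      pident = pident, length = pep_len, mismatch = 0L, gapopen = 0L,
      qstart = 1L, qend = pep_len, sstart = 1L, send = pep_len,
      evalue = 1e-9, bitscore = bits)

    rows <- mk_row(pep_ids, tgt_ids[i], true_pid, true_bits)
    tier <- tiers[i]; win <- wins[i]
    decoy_id <- if (tier == 4 && win) decoy_ids_small[i] else decoy_ids[i]
    decoy_seqs[i] <- paste(sample(aa20, 40, replace = TRUE), collapse = "")
    if (use_decoy) {
      if (tier == 1) {
        n_dec <- if (win) k + 1 else k - 1
        dec_pep <- sprintf("%s_dpep%02d", src_ids[i], seq_len(n_dec))
        # inflated bitscores: tier 1 must decide despite a larger bitscore sum
        rows <- dplyr::bind_rows(rows, mk_row(
          dec_pep, decoy_id, rep(100, n_dec),
          rep(10 * pep_len, n_dec)))
      } else if (tier == 2) {
        delta <- if (win) 1 else -1
        rows <- dplyr::bind_rows(rows, mk_row(
          pep_ids, decoy_id, true_pid,
          true_bits + delta / k))
      } else if (tier == 3) {
        delta <- if (win) 0.5 else -0.5
        rows <- dplyr::bind_rows(rows, mk_row(
          pep_ids, decoy_id, pmin(100, pmax(0, true_pid + delta)),
          rev(true_bits)))            # same multiset, same sum
      } else {
        rows <- dplyr::bind_rows(rows, mk_row(
          pep_ids, decoy_id, true_pid, rev(true_bits)))
      }
    }
    hit_rows[[i]] <- rows
    truth[[i]] <- tibble::tibble(
      source_protein = src_ids[i], true_target = tgt_ids[i],
      planted_tier = if (use_decoy) tier else NA_integer_,
      decoy_wins = win)
  }

  target_proteome <- tibble::tibble(
    protein_id = c(tgt_ids,
                   if (use_decoy) ifelse(tiers == 4 & wins,
                                         decoy_ids_small, decoy_ids)),
    sequence = c(tgt_seqs, if (use_decoy) decoy_seqs))
  list(hits = dplyr::bind_rows(hit_rows),
       source_proteome = tibble::tibble(protein_id = src_ids,
                                        sequence = tgt_seqs),
       target_proteome = target_proteome,
       truth = dplyr::bind_rows(truth))
}
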