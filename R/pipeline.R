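#' Run the full seasonal convergence pipeline
#'
#' Orchestrates: (optionally) simulate a multi-species dataset, normalize,
#' filter to proteins quantified in both seasons, test seasonal differential
#' abundance per species group, call DAPs, aggregate fold changes to
#' orthogroup level, compute the cross-group Spearman matrix and
#' co-occurrence summaries, and (optionally) categorize top upregulated
#' proteins with a chi-square homogeneity test and profile a motif-bearing
#' proteome. All stage outputs are written under `out_dir` and a
#' machine-readable JSON run summary is produced.
#'
#' Per-stage seeds are derived deterministically from the master seed, so a
#' persisted configuration reproduces all deterministic outputs exactly.
#'
#' @param config A list with elements:
#'   * `seed`: master integer seed.
#'   * `sim`: list of [sim_config()] arguments (a dataset is simulated), or
#'     `NULL` with `matrices`/`meta`/`orthogroups` supplied directly.
#'   * `matrices`, `meta`, `orthogroups`: in-memory inputs (used when `sim`
#'     is `NULL`).
#'   * `adjust_for`: character subset of `c("batch", "year")` (default
#'     empty).
#'   * `lfc_min`, `alpha`, `min_per_season`: DAP thresholds (defaults 1,
#'     0.05, 2).
#'   * `annotations`: optional tibble (`protein_id`, `species_group`,
#'     `description`) enabling the category stage; `category_map`: optional
#'     map tibble (default [default_category_map()]).
#'   * `lea`: optional list of [gen_motif_proteome()] arguments plus
#'     `preset`, enabling the LEA stage.
#'   * `out_dir`: output directory (default `tempdir()` subdirectory).
#' @return The run summary (list), invisibly; also written as
#'   `summary.json` in `out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$adjust_for)) cfg$adjust_for <- character()
  if (is.null(cfg$lfc_min)) cfg$lfc_min <- 1
  if (is.null(cfg$alpha)) cfg$alpha <- 0.05
  if (is.null(cfg$min_per_season)) cfg$min_per_season <- 2
  out_dir <- cfg$out_dir %||% file.path(tempdir(), "rhizoprot_run")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_seed <- function(k) (as.integer(cfg$seed) * 101L + k) %% 2147483647L

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste("FAILED at stage:", name, "-", conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  data <- run_stage("input", {
    if (!is.null(cfg$sim)) {
      sim_args <- cfg$sim
      sim_args$seed <- sim_args$seed %||% stage_seed(1L)
      gen_abundance_dataset(do.call(sim_config, sim_args))
    } else {
      list(matrices = cfg$matrices, meta = cfg$meta,
           orthogroups = cfg$orthogroups, truth = NULL)
    }
  })

  results <- run_stage("abundance", {
    purrr::imap(data$matrices, function(mat, sp) {
      meta_sp <- data$meta[data$meta$species == sp, ]
      mat |>
        normalize_total() |>
        filter_both_seasons(meta_sp, min_per_season = cfg$min_per_season) |>
        seasonal_test(meta_sp, adjust_for = cfg$adjust_for) |>
        call_daps(lfc_min = cfg$lfc_min, alpha = cfg$alpha)
    })
  })
  for (sp in names(results)) {
    readr::write_tsv(tibble::as_tibble(results[[sp]]),
                     file.path(out_dir, paste0(sp, ".results.tsv")),
                     progress = FALSE)
  }

  conv <- run_stage("convergence", {
    fc <- aggregate_orthogroup_lfc(results, data$orthogroups)
    readr::write_tsv(fc, file.path(out_dir, "orthogroup_lfc.tsv"),
                     progress = FALSE)
    sp_mat <- spearman_matrix(fc)
    readr::write_tsv(sp_mat, file.path(out_dir, "spearman.tsv"),
                     progress = FALSE)
    co_up <- cooccurrence(fc, "up")
    co_down <- cooccurrence(fc, "down")
    readr::write_tsv(dplyr::bind_rows(tidy.cooccurrence_summary(co_up),
                                      tidy.cooccurrence_summary(co_down)),
                     file.path(out_dir, "cooccurrence.tsv"),
                     progress = FALSE)
    list(fc = fc, spearman = sp_mat, co_up = co_up, co_down = co_down)
  })

  top <- run_stage("top_n", {
    purrr::imap(results, function(res, sp) {
      t50 <- top_n_up(res, n = 50)
      readr::write_tsv(t50, file.path(out_dir, paste0(sp, ".top50.tsv")),
                       progress = FALSE)
      t50
    })
  })

  summary <- list(
    seed = cfg$seed,
    parameters = list(adjust_for = cfg$adjust_for, lfc_min = cfg$lfc_min,
                      alpha = cfg$alpha,
                      min_per_season = cfg$min_per_season),
    species_groups = purrr::imap(results, function(res, sp) {
      g <- glance.daa_result(res)
      list(n_proteins = g$n_proteins, n_tested = g$n_tested,
           n_up = g$n_up, n_down = g$n_down)
    }),
    spearman = conv$spearman,
    cooccurrence = list(
      up = glance.cooccurrence_summary(conv$co_up),
      down = glance.cooccurrence_summary(conv$co_down)))

  if (!is.null(cfg$annotations)) {
    summary$categories <- run_stage("categories", {
      map <- cfg$category_map %||% default_category_map()
      top_ids <- purrr::imap_dfr(top, ~ tibble::tibble(
        species_group = .y, protein_id = .x$protein_id))
      ann <- dplyr::inner_join(top_ids, cfg$annotations,
                               by = c("species_group", "protein_id"))
      assigned <- assign_categories(ann, map)
      counts <- category_counts(assigned)
      readr::write_tsv(tibble::as_tibble(as.data.frame(counts),
                                         rownames = "species_group"),
                       file.path(out_dir, "category_counts.tsv"),
                       progress = FALSE)
      ct <- chi_square_homogeneity(counts)
      list(chi2 = ct$chi2, df = ct$df, p = ct$p)
    })
  }

  if (!is.null(cfg$lea)) {
    summary$lea <- run_stage("lea", {
      lea_cfg <- cfg$lea
      preset <- lea_cfg$preset %||% "default"
      rule <- motif_rule_preset(preset)
      lea_cfg$preset <- NULL
      lea_cfg$seed <- lea_cfg$seed %||% stage_seed(2L)
      prot <- do.call(gen_motif_proteome, lea_cfg)
      arch <- detect_motifs_all(prot$proteins, rule)
      readr::write_tsv(
        dplyr::select(arch, "protein_id", "n_motifs", "max_run"),
        file.path(out_dir, "lea_architecture.tsv"), progress = FALSE)
      list(preset = preset,
           n_with_motifs = sum(arch$n_motifs > 0),
           max_run = max(arch$max_run))
    })
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
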