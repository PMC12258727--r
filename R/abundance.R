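#' Total-peptide-amount normalization
#'
#' Scales every sample column by a single factor so that all column sums
#' (over non-missing entries) equal the mean of the input column sums. This
#' mirrors the "total peptide amount" normalization used for TMT reporter
#' intensities: within-sample intensity ratios are preserved exactly.
#'
#' @param mat Abundance tibble (`protein_id` + numeric sample columns).
#' @return The normalized abundance tibble.
#' @export
normalize_total <- function(mat) {
  vals <- as.matrix(mat[-1])
  sums <- colSums(vals, na.rm = TRUE)
  if (any(sums <= 0)) {
    stop("sample(s) with zero total intensity: ",
         paste(names(mat)[-1][sums <= 0], collapse = ", "))
  }
  target <- mean(sums)
  scaled <- sweep(vals, 2, target / sums, `*`)
  out <- mat
  out[-1] <- as.data.frame(scaled)
  out
}

#' Keep proteins quantified in both seasons
#'
#' Differential testing requires replication in each season; proteins with
#' fewer than `min_per_season` non-missing intensities in either winter or
#' summer are dropped. The number removed is recorded as an attribute
#' `n_removed`.
#'
#' @param mat Abundance tibble.
#' @param meta Sample metadata covering every sample column.
#' @param min_per_season Minimum non-missing values required per season.
#' @return Filtered abundance tibble.
#' @export
filter_both_seasons <- function(mat, meta, min_per_season = 2) {
  validate_abundance(mat, meta)
  samples <- names(mat)[-1]
  season <- as.character(meta$season[match(samples, meta$sample_id)])
  vals <- as.matrix(mat[-1])
  nw <- rowSums(!is.na(vals[, season == "winter", drop = FALSE]))
  ns <- rowSums(!is.na(vals[, season == "summer", drop = FALSE]))
  keep <- nw >= min_per_season & ns >= min_per_season
  out <- mat[keep, ]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Per-protein seasonal differential abundance test
#'
#' Intensities are log2-transformed (zeros are treated as non-detections and
#' set missing). With no adjustment factors, each protein is tested by
#' one-way ANOVA on the two season groups, and the winter-summer contrast
#' p-value is taken from Tukey's honest significant difference, i.e. the
#' studentized-range distribution with k = 2 groups (at k = 2 this equals
#' both the pooled-variance t-test p and the ANOVA omnibus p). With
#' `adjust_for` non-empty, an additive fixed-effects linear model
#' (season + factors, no interactions) is fitted per protein and the season
#' coefficient tested on the residual degrees of freedom. p-values are
#' Benjamini-Hochberg adjusted over all tested proteins.
#'
#' The log2 fold change is winter minus summer on the log2 scale
#' (log2 of Winter/Summer), adjusted for the fitted factor effects when
#' `adjust_for` is non-empty.
#'
#' @param mat Abundance tibble.
#' @param meta Sample metadata.
#' @param adjust_for Character subset of `c("batch", "year")`.
#' @param p_source `"tukey"` (default, season-contrast p) or `"anova"`
#'   (omnibus F p). With exactly two seasons the two coincide; both are kept
#'   so the choice is explicit.
#' @return A `daa_result` tibble with columns `protein_id`, `log2fc`,
#'   `p_value`, `p_adj`, `call`, `n_winter`, `n_summer`. Proteins lacking
#'   two quantified replicates in either season are `untested` (`NA`
#'   p-values). `call` is `not_significant` until [call_daps()] is applied.
#' @export
seasonal_test <- function(mat, meta, adjust_for = character(),
                          p_source = c("tukey", "anova")) {
  p_source <- match.arg(p_source)
  bad <- setdiff(adjust_for, c("batch", "year"))
  if (length(bad)) stop("unknown adjustment factor(s): ",
                        paste(bad, collapse = ", "))
  validate_abundance(mat, meta)
  samples <- names(mat)[-1]
  meta <- meta[match(samples, meta$sample_id), ]
  season <- factor(as.character(meta$season), levels = c("summer", "winter"))

  vals <- as.matrix(mat[-1])
  rownames(vals) <- mat$protein_id
  lv <- log2(ifelse(!is.na(vals) & vals > 0, vals, NA))

  nw <- rowSums(!is.na(lv[, season == "winter", drop = FALSE]))
  ns <- rowSums(!is.na(lv[, season == "summer", drop = FALSE]))
  testable <- nw >= 2 & ns >= 2

  if (length(adjust_for) == 0L) {
    res <- season_contrast_unadjusted(lv, season, testable)
  } else {
    res <- season_contrast_adjusted(lv, season, meta, adjust_for, testable)
  }

  p_raw <- if (p_source == "tukey") res$p_tukey else res$p_anova
  p_adj <- rep(NA_real_, length(p_raw))
  p_adj[testable] <- stats::p.adjust(p_raw[testable], method = "BH")

  out <- tibble::tibble(
    protein_id = mat$protein_id,
    log2fc = unname(res$log2fc),
    p_value = unname(p_raw),
    p_adj = unname(p_adj),
    call = unname(ifelse(testable, "not_significant", "untested")),
    n_winter = unname(as.integer(nw)),
    n_summer = unname(as.integer(ns))
  )
  class(out) <- c("daa_result", class(out))
  attr(out, "adjust_for") <- adjust_for
  attr(out, "p_source") <- p_source
  out
}

# Vectorized two-group contrast: pooled-variance t, Tukey p via the
# studentized range with k = 2, omnibus F p (identical at k = 2).
season_contrast_unadjusted <- function(lv, season, testable) {
  w <- lv[, season == "winter", drop = FALSE]
  s <- lv[, season == "summer", drop = FALSE]
  nw <- rowSums(!is.na(w)); ns <- rowSums(!is.na(s))
  mw <- rowMeans(w, na.rm = TRUE); ms <- rowMeans(s, na.rm = TRUE)
  ssw <- rowSums((w - mw)^2, na.rm = TRUE)
  sss <- rowSums((s - ms)^2, na.rm = TRUE)
  df <- nw + ns - 2
  sp2 <- (ssw + sss) / pmax(df, 1)
  se <- sqrt(sp2 * (1 / nw + 1 / ns))
  tstat <- (mw - ms) / se
  # identical values in both groups: F = 0, p = 1
  tstat[is.na(tstat) | (se == 0 & mw == ms)] <- 0
  p_tukey <- rep(NA_real_, nrow(lv))
  p_anova <- rep(NA_real_, nrow(lv))
  idx <- which(testable)
  q <- sqrt(2) * abs(tstat[idx])
  p_tukey[idx] <- stats::ptukey(q, nmeans = 2, df = df[idx],
                                lower.tail = FALSE)
  p_anova[idx] <- stats::pf(tstat[idx]^2, 1, df[idx], lower.tail = FALSE)
  lfc <- mw - ms
  lfc[!testable & (nw == 0 | ns == 0)] <- NA_real_
  list(log2fc = lfc, p_tukey = p_tukey, p_anova = p_anova)
}

# Additive fixed-effects model per protein; proteins with complete data share
# one design and are solved in a single multi-response least-squares fit.
season_contrast_adjusted <- function(lv, season, meta, adjust_for, testable) {
  df_terms <- data.frame(season = season)
  for (f in adjust_for) {
    fac <- factor(meta[[f]])
    if (nlevels(fac) < 2) next  # constant factor: nothing to adjust for
    if (all(rowSums(table(fac, season) > 0) <= 1)) {
      stop("factor '", f, "' is confounded with season (collinear design)")
    }
    df_terms[[f]] <- fac
  }
  X <- stats::model.matrix(~ ., df_terms)
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient design; adjustment factors are collinear")
  }
  coef_idx <- which(colnames(X) == "seasonwinter")

  n <- nrow(lv)
  lfc <- rep(NA_real_, n); pt_ <- rep(NA_real_, n); pa_ <- rep(NA_real_, n)

  fit_one <- function(y, rows) {
    Xr <- X[rows, , drop = FALSE]
    if (qr(Xr)$rank < ncol(Xr)) return(c(NA_real_, NA_real_))
    fit <- stats::lm.fit(Xr, y[rows])
    rdf <- length(rows) - ncol(Xr)
    if (rdf <= 0) return(c(NA_real_, NA_real_))
    s2 <- sum(fit$residuals^2) / rdf
    XtXinv <- chol2inv(chol(crossprod(Xr)))
    se <- sqrt(s2 * XtXinv[coef_idx, coef_idx])
    b <- fit$coefficients[coef_idx]
    tval <- if (se == 0) 0 else b / se
    c(b, stats::ptukey(sqrt(2) * abs(tval), 2, rdf, lower.tail = FALSE))
  }

  complete <- rowSums(is.na(lv)) == 0L & testable
  if (any(complete)) {
    fit <- stats::lm.fit(X, t(lv[complete, , drop = FALSE]))
    rdf <- ncol(lv) - ncol(X)
    res2 <- colSums(fit$residuals^2)
    XtXinv <- chol2inv(chol(crossprod(X)))
    se <- sqrt(res2 / rdf * XtXinv[coef_idx, coef_idx])
    b <- fit$coefficients[coef_idx, ]
    tval <- ifelse(se == 0, 0, b / se)
    lfc[complete] <- b
    pt_[complete] <- stats::ptukey(sqrt(2) * abs(tval), 2, rdf,
                                   lower.tail = FALSE)
    pa_[complete] <- stats::pf(tval^2, 1, rdf, lower.tail = FALSE)
  }
  for (i in which(testable & !complete)) {
    rows <- which(!is.na(lv[i, ]))
    est <- fit_one(lv[i, ], rows)
    lfc[i] <- est[1]; pt_[i] <- est[2]
    pa_[i] <- est[2]  # identical at two season groups
  }
  # untested proteins still get an unadjusted descriptive log2fc when possible
  raw <- season_contrast_unadjusted(lv, season, testable)
  lfc[!testable] <- raw$log2fc[!testable]
  list(log2fc = lfc, p_tukey = pt_, p_anova = pa_)
}

#' Call differentially abundant proteins
#'
#' A protein is `up` when `log2fc >= lfc_min` and `p_adj < alpha`, `down`
#' when `log2fc <= -lfc_min` and `p_adj < alpha`; otherwise
#' `not_significant` (or `untested` when no test was possible).
#'
#' @param results A `daa_result` tibble from [seasonal_test()].
#' @param lfc_min Minimum absolute log2 fold change (default 1).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return The tibble with the `call` column populated; summary counts are
#'   attached as attribute `dap_counts`.
#' @export
call_daps <- function(results, lfc_min = 1, alpha = 0.05) {
  stopifnot("p_adj" %in% names(results))
  call <- dplyr::case_when(
    results$call == "untested" | is.na(results$p_adj) ~
      ifelse(results$call == "untested", "untested", "not_significant"),
    results$log2fc >= lfc_min & results$p_adj < alpha ~ "up",
    results$log2fc <= -lfc_min & results$p_adj < alpha ~ "down",
    TRUE ~ "not_significant"
  )
  out <- results
  out$call <- call
  attr(out, "dap_counts") <- c(up = sum(call == "up"),
                               down = sum(call == "down"))
  attr(out, "lfc_min") <- lfc_min
  attr(out, "alpha") <- alpha
  out
}

#' @export
glance.daa_result <- function(x, ...) {
  tibble::tibble(
    n_proteins = nrow(x),
    n_tested = sum(x$call != "untested"),
    n_up = sum(x$call == "up"),
    n_down = sum(x$call == "down"),
    adjust_for = paste(attr(x, "adjust_for"), collapse = ",")
  )
}

#' @export
tidy.daa_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Volcano plot of a seasonal differential abundance result
#'
#' @param object A `daa_result` tibble with calls populated.
#' @param ... Unused.
#' @return A ggplot object: log2 fold change (winter/summer) against
#'   -log10 adjusted p, coloured by call.
#' @export
autoplot.daa_result <- function(object, ...) {
  df <- dplyr::filter(tidy.daa_result(object), .data$call != "untested")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(.data$p_adj),
                                   colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(up = "#2166ac", down = "#b2182b",
                                            not_significant = "grey70")) +
    ggplot2::labs(x = expression(log[2] ~ "fold change (winter/summer)"),
                  y = expression(-log[10] ~ "adjusted p"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}
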