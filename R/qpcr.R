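#' Collapse technical qPCR replicates
#'
#' Averages detected technical-replicate Ct values within each
#' (condition, gene, biological replicate) group. Undetected wells (NA Ct)
#' are excluded from the mean; a group whose technical replicates are all
#' undetected is flagged and carries an NA Ct. No ceiling value is imputed.
#'
#' @param records long Ct table with columns `condition`, `gene`, `bio_rep`,
#'   `tech_rep`, `ct` (NA marks an undetected well).
#' @return tibble with one row per group: `condition`, `gene`, `bio_rep`,
#'   `ct` (mean of detected wells), `undetected` (logical).
#' @export
collapse_technical <- function(records) {
  assert_columns(records, c("condition", "gene", "bio_rep", "tech_rep", "ct"),
                 "Ct table")
  records <- tibble::as_tibble(records)
  key <- c("condition", "gene", "bio_rep")
  if (anyDuplicated(records[, c(key, "tech_rep")])) {
    stop_validation("(condition, gene, bio_rep, tech_rep) must be unique")
  }
  out <- dplyr::summarise(
    dplyr::group_by(records, dplyr::across(dplyr::all_of(key))),
    undetected = all(is.na(.data$ct)),
    ct = if (all(is.na(.data$ct))) NA_real_ else mean(.data$ct, na.rm = TRUE),
    .groups = "drop"
  )
  n_flag <- sum(out$undetected)
  if (n_flag > 0) {
    warning(n_flag, " group(s) undetected in all technical replicates; ",
            "excluded from downstream quantification", call. = FALSE)
  }
  out
}

#' Relative expression by the delta-delta-Ct method
#'
#' Computes, per biological replicate, the target Ct minus the arithmetic mean
#' of the reference-gene Cts (delta Ct), subtracts the mean control-condition
#' delta Ct (delta-delta Ct), and converts to a fold change as
#' \eqn{2^{-\Delta\Delta Ct}}. Assumes the amplification efficiencies of
#' target and references have been confirmed equivalent (see
#' [efficiency_check()]). Summary mean and standard deviation are computed on
#' the linear fold scale, matching the convention of plotting the mean of
#' three biological replicates with its SD.
#'
#' @param ct_table collapsed Ct table (see [collapse_technical()]), columns
#'   `condition`, `gene`, `bio_rep`, `ct`.
#' @param target_gene gene being quantified.
#' @param reference_genes one or more reference genes (e.g. RPL27, RPL13A,
#'   GAPDH); multiple references are combined by the arithmetic mean of their
#'   Cts.
#' @param control_condition condition whose mean delta Ct is the baseline.
#' @return object of class `ddct_result`: list with `per_replicate`
#'   (condition, bio_rep, delta_ct, delta_delta_ct, fold_change), `summary`
#'   (condition, n, mean_fold, sd_fold) and the labels used.
#' @export
delta_delta_ct <- function(ct_table, target_gene, reference_genes,
                           control_condition) {
  assert_columns(ct_table, c("condition", "gene", "bio_rep", "ct"), "Ct table")
  ct_table <- tibble::as_tibble(ct_table)
  ct_table <- ct_table[!is.na(ct_table$ct), , drop = FALSE]
  if (!control_condition %in% ct_table$condition) {
    stop_validation("control condition '", control_condition,
                    "' absent from the Ct table")
  }
  tgt <- ct_table[ct_table$gene == target_gene, , drop = FALSE]
  refs <- ct_table[ct_table$gene %in% reference_genes, , drop = FALSE]
  if (nrow(tgt) == 0) stop_validation("no Ct values for target gene ",
                                      target_gene)
  ref_mean <- dplyr::summarise(
    dplyr::group_by(refs, .data$condition, .data$bio_rep),
    ref_ct = mean(.data$ct), n_refs = dplyr::n(), .groups = "drop")
  if (any(ref_mean$n_refs != length(reference_genes))) {
    stop_validation("reference-gene Cts incomplete for some ",
                    "(condition, bio_rep) pairs")
  }
  per <- dplyr::inner_join(tgt[, c("condition", "bio_rep", "ct")], ref_mean,
                           by = c("condition", "bio_rep"))
  if (nrow(per) < nrow(tgt)) {
    stop_validation("target replicates without matching reference Cts")
  }
  per$delta_ct <- per$ct - per$ref_ct
  control_dct <- per$delta_ct[per$condition == control_condition]
  if (length(control_dct) == 0) {
    stop_validation("no complete control-condition replicates")
  }
  per$delta_delta_ct <- per$delta_ct - mean(control_dct)
  per$fold_change <- 2^(-per$delta_delta_ct)
  per <- per[order(per$condition, per$bio_rep),
             c("condition", "bio_rep", "delta_ct", "delta_delta_ct",
               "fold_change")]
  summary <- dplyr::summarise(
    dplyr::group_by(per, .data$condition),
    n = dplyr::n(),
    mean_fold = mean(.data$fold_change),
    sd_fold = stats::sd(.data$fold_change),
    .groups = "drop")
  structure(list(per_replicate = per, summary = summary,
                 target_gene = target_gene,
                 reference_genes = reference_genes,
                 control_condition = control_condition),
            class = "ddct_result")
}

#' @export
print.ddct_result <- function(x, ...) {
  cat("delta-delta-Ct result:", x$target_gene, "vs",
      paste(x$reference_genes, collapse = "/"),
      "(control:", paste0(x$control_condition, ")\n"))
  print(x$summary)
  invisible(x)
}

# U statistic of group 1 from pooled average ranks; ties get average ranks so
# U1 + U2 = n1*n2 always holds.
mw_u1 <- function(pooled, idx1) {
  r <- rank(pooled)
  sum(r[idx1]) - length(idx1) * (length(idx1) + 1) / 2
}

#' Exact two-tailed two-sample Mann-Whitney U test
#'
#' The exact method enumerates all `choose(n1 + n2, n1)` relabelings of the
#' observed pooled values (ties are handled naturally by the enumeration),
#' takes the one-sided tail as the fraction of relabelings whose U statistic
#' is at most the observed minimum of U1 and U2, and doubles it (capped at 1)
#' for the two-tailed p. With `method = "auto"` the exact path is used when
#' n1 + n2 <= 12 and a tie-corrected, continuity-corrected normal
#' approximation otherwise. With three replicates per group — the design used
#' throughout qPCR figure statistics — the exact two-tailed p can never go
#' below 2/choose(6,3) = 0.1.
#'
#' @param a,b numeric vectors, both non-empty.
#' @param method `"auto"`, `"exact"` or `"approx"`.
#' @return object of class `mw_result`: list with `u_statistic` (min of U1,
#'   U2), `n1`, `n2`, `p_two_tailed`, `method` used, `ties_present`.
#' @export
mann_whitney_two_tailed <- function(a, b, method = c("auto", "exact",
                                                     "approx")) {
  method <- match.arg(method)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) {
    stop_validation("both groups must be non-empty")
  }
  if (anyNA(a) || anyNA(b)) stop_validation("NA values not allowed")
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  u1 <- mw_u1(pooled, seq_len(n1))
  u2 <- n1 * n2 - u1
  u_min <- min(u1, u2)
  ties <- anyDuplicated(pooled) > 0
  if (method == "auto") {
    method <- if (n1 + n2 <= 12) "exact" else "approx"
  }
  if (method == "exact") {
    labelings <- utils::combn(n1 + n2, n1)
    eps <- 1e-9
    u_perm <- apply(labelings, 2, function(idx) mw_u1(pooled, idx))
    one_sided <- mean(u_perm <= u_min + eps)
    p <- min(1, 2 * one_sided)
  } else {
    n <- n1 + n2
    tie_tab <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) /
                                (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u1 - n1 * n2 / 2) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
  }
  structure(list(u_statistic = u_min, n1 = n1, n2 = n2, p_two_tailed = p,
                 method = if (method == "exact") "exact_enumeration"
                          else "normal_approx",
                 ties_present = ties),
            class = "mw_result")
}

#' @export
print.mw_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n1 = %d, n2 = %d), two-tailed p = %g [%s]\n",
              x$u_statistic, x$n1, x$n2, x$p_two_tailed, x$method))
  invisible(x)
}

#' ChIP-qPCR percent-input enrichment
#'
#' Expresses each immunoprecipitation as the percentage of input chromatin
#' recovered: the input Ct is first adjusted for the fraction of chromatin
#' used as input (subtracting \eqn{\log_2(1/f)} cycles), then
#' \deqn{\%input = 100 \times 2^{(Ct_{input,adj} - Ct_{IP})}.}
#' When IgG control rows are present, each specific antibody is compared to
#' IgG at every amplicon site with the exact two-tailed Mann-Whitney U test
#' over biological replicates. IgG is compared statistically, not subtracted.
#'
#' @param samples data frame with columns `site`, `antibody`, `bio_rep`,
#'   `ct_ip`, `ct_input`, `input_fraction`.
#' @param compare run the specific-vs-IgG comparison (default TRUE).
#' @param igg_label antibody label of the control pulldown (default "IgG").
#' @param alpha significance threshold for the reported flag (default 0.05).
#' @return object of class `chip_result`: list with `per_sample` (the input
#'   plus `percent_input`) and `tests` (site, antibody, U, n's, p,
#'   significant) — `tests` is NULL when `compare = FALSE`.
#' @export
chip_percent_input <- function(samples, compare = TRUE, igg_label = "IgG",
                               alpha = 0.05) {
  assert_columns(samples, c("site", "antibody", "bio_rep", "ct_ip",
                            "ct_input", "input_fraction"), "ChIP table")
  samples <- tibble::as_tibble(samples)
  if (any(samples$input_fraction <= 0 | samples$input_fraction > 1)) {
    stop_validation("input_fraction must lie in (0, 1]")
  }
  adj_input <- samples$ct_input - log2(1 / samples$input_fraction)
  samples$percent_input <- 100 * 2^(adj_input - samples$ct_ip)
  tests <- NULL
  if (compare) {
    specific <- setdiff(unique(samples$antibody), igg_label)
    if (!igg_label %in% samples$antibody) {
      stop_validation("comparison requested but no '", igg_label,
                      "' control rows present")
    }
    rows <- list()
    for (site in unique(samples$site)) {
      at_site <- samples[samples$site == site, , drop = FALSE]
      igg <- at_site$percent_input[at_site$antibody == igg_label]
      for (ab in intersect(specific, at_site$antibody)) {
        if (length(igg) == 0) {
          stop_validation("no '", igg_label, "' rows at site ", site)
        }
        sp <- at_site$percent_input[at_site$antibody == ab]
        mw <- mann_whitney_two_tailed(sp, igg)
        rows[[length(rows) + 1]] <- tibble::tibble(
          site = site, antibody = ab,
          n_specific = mw$n1, n_igg = mw$n2,
          u_statistic = mw$u_statistic, p_two_tailed = mw$p_two_tailed,
          method = mw$method, significant = mw$p_two_tailed <= alpha)
      }
    }
    tests <- dplyr::bind_rows(rows)
  }
  structure(list(per_sample = samples, tests = tests, alpha = alpha),
            class = "chip_result")
}

#' Amplification-efficiency check from a dilution series
#'
#' Fits mean Ct against log10 relative template amount per primer by least
#' squares; the amplification efficiency is \eqn{E = 10^{-1/slope} - 1}
#' (E = 1 means perfect doubling, slope -3.32). When a reference primer is
#' given, target/reference equivalence — the validity condition of the
#' delta-delta-Ct method — is declared when the slope of
#' (Ct_target - Ct_reference) against log10 amount is below `threshold` in
#' absolute value.
#'
#' @param dilutions data frame with columns `primer_id`, `amount` (relative
#'   template amount, > 0), `ct`; replicate wells per amount allowed.
#' @param reference optional reference primer_id for the equivalence check.
#' @param threshold maximum |delta-Ct slope| for equivalence (default 0.1
#'   cycles per 10-fold dilution).
#' @return tibble with one row per primer: `primer_id`, `slope`,
#'   `efficiency`, `delta_ct_slope` and `equivalence_ok` (NA without a
#'   reference; TRUE for the reference itself).
#' @export
efficiency_check <- function(dilutions, reference = NULL, threshold = 0.1) {
  assert_columns(dilutions, c("primer_id", "amount", "ct"), "dilution series")
  if (threshold <= 0) stop_validation("equivalence threshold must be > 0")
  dilutions <- tibble::as_tibble(dilutions)
  if (any(dilutions$amount <= 0)) {
    stop_validation("template amounts must be > 0")
  }
  mean_ct <- dplyr::summarise(
    dplyr::group_by(dilutions, .data$primer_id, .data$amount),
    ct = mean(.data$ct), .groups = "drop")
  mean_ct$log_amount <- log10(mean_ct$amount)

  fit_slope <- function(x, y) {
    if (length(x) < 3) {
      stop_validation("at least 3 dilution points required per primer")
    }
    if (stats::var(x) == 0) {
      stop_validation("dilution amounts must vary")
    }
    unname(stats::coef(stats::lm(y ~ x))[2])
  }
  primers <- unique(mean_ct$primer_id)
  if (!is.null(reference) && !reference %in% primers) {
    stop_validation("reference primer '", reference, "' not in the series")
  }
  res <- lapply(primers, function(p) {
    d <- mean_ct[mean_ct$primer_id == p, , drop = FALSE]
    slope <- fit_slope(d$log_amount, d$ct)
    dct_slope <- NA_real_
    if (!is.null(reference)) {
      r <- mean_ct[mean_ct$primer_id == reference, , drop = FALSE]
      m <- dplyr::inner_join(d[, c("amount", "log_amount", "ct")],
                             r[, c("amount", "ct")],
                             by = "amount", suffix = c("_t", "_r"))
      dct_slope <- fit_slope(m$log_amount, m$ct_t - m$ct_r)
    }
    tibble::tibble(primer_id = p, slope = slope,
                   efficiency = 10^(-1 / slope) - 1,
                   delta_ct_slope = dct_slope,
                   equivalence_ok = if (is.null(reference)) NA
                                    else abs(dct_slope) < threshold)
  })
  dplyr::bind_rows(res)
}
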