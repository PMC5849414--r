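make_ct <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) tibble::tibble(
    condition = r[[1]], gene = r[[2]], bio_rep = r[[3]], tech_rep = r[[4]],
    ct = r[[5]])))
}

test_that("technical collapse averages detected wells and flags undetected", {
  tab <- make_ct(list("C", "G", 1, 1, 20.0),
                 list("C", "G", 1, 2, 20.5),
                 list("C", "G", 2, 1, 25.0),
                 list("C", "H", 1, 1, NA),
                 list("C", "H", 1, 2, 30.0),
                 list("C", "H", 2, 1, NA))
  suppressWarnings(out <- collapse_technical(tab))
  expect_equal(out$ct[out$gene == "G" & out$bio_rep == 1], 20.25)
  expect_equal(out$ct[out$gene == "G" & out$bio_rep == 2], 25)  # identity
  expect_equal(out$ct[out$gene == "H" & out$bio_rep == 1], 30)  # detected only
  expect_true(is.na(out$ct[out$gene == "H" & out$bio_rep == 2]))
  expect_true(out$undetected[out$gene == "H" & out$bio_rep == 2])
  expect_warning(collapse_technical(tab), "undetected")
})

ddct_fixture <- function(shift_treated = 0, ref_shift = 0, n_rep = 3) {
  rows <- list()
  for (br in seq_len(n_rep)) {
    rows <- c(rows, list(
      list("CTRL", "TGT", br, 1, 28),
      list("CTRL", "R1", br, 1, 18), list("CTRL", "R2", br, 1, 20),
      list("TREAT", "TGT", br, 1, 28 + shift_treated),
      list("TREAT", "R1", br, 1, 18 + ref_shift),
      list("TREAT", "R2", br, 1, 20 + ref_shift)))
  }
  collapse_technical(do.call(make_ct, rows))
}

test_that("identical Cts give fold 1 and a one-cycle drop gives fold 2", {
  r0 <- delta_delta_ct(ddct_fixture(0), "TGT", c("R1", "R2"), "CTRL")
  expect_true(all(r0$per_replicate$fold_change == 1))
  r2 <- delta_delta_ct(ddct_fixture(-1), "TGT", c("R1", "R2"), "CTRL")
  expect_equal(r2$summary$mean_fold[r2$summary$condition == "TREAT"], 2)
  r8 <- delta_delta_ct(ddct_fixture(-3), "TGT", c("R1", "R2"), "CTRL")
  expect_equal(r8$summary$mean_fold[r8$summary$condition == "TREAT"], 8)
  expect_equal(r8$summary$sd_fold[r8$summary$condition == "TREAT"], 0)
})

test_that("fold changes are invariant to per-replicate global Ct shifts", {
  base <- ddct_fixture(-2)
  shifted <- base
  # shift every Ct of one biological replicate (target and references alike)
  pick <- shifted$bio_rep == 2
  shifted$ct[pick] <- shifted$ct[pick] + 1.7
  a <- delta_delta_ct(base, "TGT", c("R1", "R2"), "CTRL")
  b <- delta_delta_ct(shifted, "TGT", c("R1", "R2"), "CTRL")
  expect_equal(b$per_replicate$fold_change, a$per_replicate$fold_change)
})

test_that("control-condition folds have geometric mean exactly 1", {
  set.seed(6)
  tab <- ddct_fixture(-1)
  tab$ct <- tab$ct + rnorm(nrow(tab), 0, 0.4)  # arbitrary noisy table
  res <- delta_delta_ct(tab, "TGT", c("R1", "R2"), "CTRL")
  ctrl <- res$per_replicate$fold_change[res$per_replicate$condition == "CTRL"]
  expect_equal(exp(mean(log(ctrl))), 1, tolerance = 1e-9)
})

test_that("reference genes are combined by the arithmetic mean of their Cts", {
  # references move by +1 and -1; their mean is unchanged, so fold follows
  # the target alone
  tab <- make_ct(list("CTRL", "TGT", 1, 1, 28),
                 list("CTRL", "R1", 1, 1, 18),
                 list("CTRL", "R2", 1, 1, 20),
                 list("TREAT", "TGT", 1, 1, 27),
                 list("TREAT", "R1", 1, 1, 19),
                 list("TREAT", "R2", 1, 1, 19))
  res <- delta_delta_ct(collapse_technical(tab), "TGT", c("R1", "R2"), "CTRL")
  expect_equal(res$summary$mean_fold[res$summary$condition == "TREAT"], 2)
})

test_that("missing control condition or unpaired references raise errors", {
  tab <- ddct_fixture(0)
  expect_error(delta_delta_ct(tab, "TGT", c("R1", "R2"), "NOPE"),
               "control condition")
  broken <- tab[!(tab$gene == "R1" & tab$condition == "TREAT" &
                    tab$bio_rep == 1), ]
  expect_error(delta_delta_ct(broken, "TGT", c("R1", "R2"), "CTRL"),
               "incomplete")
})

test_that("amplification efficiency is recovered from a dilution series", {
  amounts <- 10^seq(0, -3, by = -1)
  perfect <- tibble::tibble(primer_id = "P", amount = amounts,
                            ct = 20 - log2(amounts))  # slope -1/log10(2)
  res <- efficiency_check(perfect)
  expect_equal(res$efficiency, 1, tolerance = 1e-9)
  expect_equal(res$slope, -1 / log10(2), tolerance = 1e-9)
  # generator round-trip at E = 0.9, sigma = 0
  E <- 0.9
  series <- tibble::tibble(primer_id = "Q", amount = amounts,
                           ct = 25 - log(amounts) / log(1 + E))
  expect_equal(efficiency_check(series)$efficiency, E, tolerance = 1e-6)
})

test_that("equivalence holds iff the delta-Ct slope stays under threshold", {
  amounts <- 10^seq(0, -3, by = -1)
  two <- dplyr::bind_rows(
    tibble::tibble(primer_id = "T", amount = amounts, ct = 28 - log2(amounts)),
    tibble::tibble(primer_id = "R", amount = amounts, ct = 18 - log2(amounts)))
  res <- efficiency_check(two, reference = "R")
  expect_true(res$equivalence_ok[res$primer_id == "T"])  # constant delta Ct
  skewed <- two
  skewed$ct[skewed$primer_id == "T"] <-
    28 - log2(amounts) + 0.3 * log10(amounts)
  res2 <- efficiency_check(skewed, reference = "R")
  expect_false(res2$equivalence_ok[res2$primer_id == "T"])
})

test_that("degenerate dilution series are rejected", {
  expect_error(efficiency_check(tibble::tibble(
    primer_id = "P", amount = c(1, 0.1), ct = c(20, 23))), "3 dilution")
  # replicate wells at one amount collapse to a single dilution point
  expect_error(efficiency_check(tibble::tibble(
    primer_id = "P", amount = c(1, 1, 1), ct = c(20, 20, 20))), "3 dilution")
})
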