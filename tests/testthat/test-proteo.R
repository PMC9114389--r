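make_psms <- function(peptides, ..., is_blank = FALSE) {
  psm_table(peptides, protein = "P1", start = 1L, ..., is_blank = is_blank)
}

test_that("PTM rate is the fraction of residue-bearing PSMs carrying the modification", {
  peps <- c(rep("ASKE", 10), rep("KKEE", 3))
  mods <- c(rep("2:Phospho", 3), rep("", 10))
  tb <- make_psms(peps, modifications = mods)
  r <- ptm_rate(tb, "Phospho", "S")
  expect_equal(r$rate_pct, 30)
  expect_equal(r$n_with_residue, 10)

  # no target residue anywhere: undefined, reported as such
  r0 <- ptm_rate(make_psms(c("KKE", "EEK")), "Phospho", "S")
  expect_true(r0$undefined)
  expect_true(is.na(r0$rate_pct))

  # deamidation over {N,Q}: equals a brute-force enumeration
  tb2 <- gen_psm_table(n_psm = 150, ptm_rates = c(Deamidation = 0.4), seed = 21)
  r2 <- ptm_rate(tb2, "Deamidation", c("N", "Q"))
  brute_den <- sum(grepl("[NQ]", tb2$peptide) & !tb2$is_blank)
  brute_num <- sum(purrr::map2_lgl(tb2$mods, tb2$peptide, function(m, p) {
    nrow(m) > 0 && any(m$val == "Deamidation" &
                         substr(p, m$pos, m$pos) %in% c("N", "Q"))
  }) & !tb2$is_blank & grepl("[NQ]", tb2$peptide))
  expect_equal(r2$rate_pct, 100 * brute_num / brute_den)
  # monotone non-decreasing as modified PSMs are added
  tb3 <- dplyr::bind_rows(tb, make_psms("SSSS", modifications = "1:Phospho"))
  class(tb3) <- class(tb)
  expect_gte(ptm_rate(tb3, "Phospho", "S")$rate_pct, r$rate_pct)
  expect_true(r$rate_pct >= 0 && r$rate_pct <= 100)
})

test_that("blank-run spectra never affect any statistic", {
  tb <- gen_psm_table(n_psm = 120, ptm_rates = c(Phospho = 0.3),
                      motif_enrichment = 0.5, seed = 22)
  tb_blank <- gen_psm_table(n_psm = 120, ptm_rates = c(Phospho = 0.3),
                            motif_enrichment = 0.5, n_blank = 15, seed = 22)
  expect_equal(ptm_rate(tb, "Phospho", "S"),
               ptm_rate(tb_blank, "Phospho", "S"))
  expect_equal(phospho_motif(tb)$sxe_fraction,
               phospho_motif(tb_blank)$sxe_fraction)
  panel <- synth_protein_set()$panel
  expect_equal(diagnostic_coverage(tb, panel)$call,
               diagnostic_coverage(tb_blank, panel)$call)
})

test_that("phospho-motif tally handles the S-x-E rule and peptide edges", {
  # all sites in SxE context
  tb <- make_psms(c("ASAE", "KSQEK"), modifications = c("2:Phospho", "2:Phospho"))
  pm <- phospho_motif(tb)
  expect_equal(pm$sxe_fraction, 1)
  # site at the C-terminus: +2 undefined, excluded from the denominator
  tb2 <- make_psms(c("AKS", "KSQEK"), modifications = c("3:Phospho", "2:Phospho"))
  pm2 <- phospho_motif(tb2)
  expect_equal(pm2$n_sites, 2)
  expect_equal(pm2$n_sites_with_plus2, 1)
  expect_equal(pm2$sxe_fraction, 1)
  # random contexts approach the generator enrichment
  tbr <- gen_psm_table(n_psm = 400, ptm_rates = c(Phospho = 0.5),
                       motif_enrichment = 1, seed = 23)
  expect_gt(phospho_motif(tbr)$sxe_fraction, 0.8)
  counts <- phospho_motif(tbr)$counts
  expect_true(all(counts$offset %in% -5:5))
  expect_error(phospho_motif(make_psms("KKK")), "no phosphorylated")
})

test_that("diagnostic site coverage applies the fragmentation-support gate and set logic", {
  ps <- synth_protein_set()
  # nothing supported: the hominin-vs-ape site cannot be called
  tb0 <- gen_psm_table(n_psm = 40, seed = 24)
  expect_match(diagnostic_coverage(tb0, ps$panel)$call, "indeterminate")
  # only the shared-hominin site supported: genus call, within-Homo open
  tb1 <- gen_psm_table(n_psm = 40, seed = 24,
                       diagnostic_sites_covered =
                         data.frame(protein = "ENAM_SYN", position = 5L))
  d1 <- diagnostic_coverage(tb1, ps$panel)
  expect_equal(d1$call, "genus Homo, within-Homo indeterminate")
  expect_setequal(d1$compatible, c("H_sapiens", "Neanderthal", "Denisovan",
                                   "Xiahe_Denisovan"))
  # adding a Denisovan-specific supported site narrows the call
  tb2 <- gen_psm_table(n_psm = 40, seed = 24,
                       diagnostic_sites_covered =
                         data.frame(protein = c("ENAM_SYN", "AMBN_SYN"),
                                    position = c(5L, 20L)))
  d2 <- diagnostic_coverage(tb2, ps$panel)
  expect_setequal(d2$compatible, c("Denisovan", "Xiahe_Denisovan"))
  # removing sites can only widen the call (monotone set logic)
  expect_true(all(d2$compatible %in% d1$compatible))
  # spanned but unsupported -> excluded; conflicting residues flagged
  tbc <- psm_table(c("MKTGS", "MKTGA"), protein = "ENAM_SYN", start = 1L,
                   site_support = c("5:1", "5:1"))
  dc <- diagnostic_coverage(tbc, ps$panel)
  s5 <- dc$sites[dc$sites$position == 5, ]
  expect_true(s5$conflict)
  expect_match(dc$call, "indeterminate|no supported")
})

test_that("AMELY screening never reports a bare female call", {
  ps <- synth_protein_set()
  tb_m <- gen_psm_table(n_psm = 30, amely_present = TRUE, seed = 25)
  scr_m <- amely_screen(tb_m, ps$amely_peptides)
  expect_true(scr_m$amely_detected)
  expect_equal(scr_m$inference, "male")

  tb_f <- gen_psm_table(n_psm = 30, amely_present = FALSE, seed = 25)
  scr_f <- amely_screen(tb_f, ps$amely_peptides)
  expect_false(scr_f$amely_detected)
  expect_equal(scr_f$inference, "female or degraded beyond detection")
  expect_false(identical(scr_f$inference, "female"))

  # AMELX/AMELY-shared peptide is not AMELY-specific
  shared <- make_psms("MPLPPHSAESMNRP")
  expect_false(amely_screen(shared, ps$amely_peptides)$amely_detected)
  # I/L equivalence in matching
  il <- make_psms("WYRPNDGEWITP") # L -> I variant of the Y-specific stretch
  expect_true(amely_screen(il, "WYRPNDGEWLTP")$amely_detected)
})

test_that("the pre-filter removes blanks, contaminants and single-peptide proteins", {
  tb <- psm_table(c("AAAK", "AAAK", "CCCK", "DDDK", "DDDR", "EEEK"),
                  protein = c("P1", "P1", "P1", "P2", "P2", "KERATIN"),
                  start = 1L, is_blank = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
  f <- filter_psms(tb, contaminants = "KERATIN")
  expect_setequal(unique(f$protein), c("P1", "P2"))
  tb2 <- psm_table(c("AAAK", "BBBK"), protein = c("P1", "P1"), start = 1L,
                   is_blank = c(FALSE, TRUE))
  # after blank removal P1 has one peptide -> dropped
  expect_equal(nrow(filter_psms(tb2)), 0)
})

test_that("the PSM reader parses modification and support strings", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    peptide = c("ASKE", "KKEE"), protein = "P1", start = c(1, 5),
    modifications = c("2:Phospho", ""), site_support = c("2:1", ""),
    is_blank = c(0, 0)), path)
  tb <- read_psm_tsv(path)
  expect_s3_class(tb, "psm_table")
  expect_equal(tb$mods[[1]]$pos, 2L)
  expect_equal(tb$mods[[1]]$val, "Phospho")
  expect_equal(nrow(tb$mods[[2]]), 0)
  expect_error(psm_table("ASK", "P1", modifications = "9:Phospho"),
               "outside")
})
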