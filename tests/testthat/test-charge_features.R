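test_that("residue charges follow the titration model", {
  # titration midpoint: His at its own pKa carries +0.5
  expect_equal(residue_charge("H", ph = 6.0), 0.5)
  expect_equal(residue_charge("G", ph = 7.4), 0)
  expect_equal(residue_charge("G", ph = 2.0), 0)
  # K at pH 7.4, pKa 10.5: 1/(1 + 10^(7.4 - 10.5))
  expect_equal(residue_charge("K", ph = 7.4), 0.99921, tolerance = 1e-5)
  expect_equal(residue_charge("D", ph = 12), -1, tolerance = 1e-4)
  expect_error(residue_charge("B", ph = 7.4), "invalid residue")

  expect_equal(residue_charge(c("K", "R"), 7.4, mode = "integer"), c(1, 1))
  expect_equal(residue_charge("H", 7.4, mode = "integer"), 0)
  expect_equal(residue_charge("H", 7.4, mode = "integer", his_charge = 1), 1)
})

test_that("net charge handles caps and termini", {
  expect_equal(net_charge(peptide_construct("GGGG", ph = 7.4)), 0)
  # p21(140-164), capped, integer mode, His neutral: 10 K/R minus one D
  p <- peptide_construct("RKRRQTSMTDFYHSKRRLIFSKRKP", ph = 7.4)
  expect_equal(net_charge(p, mode = "integer"), 9)
  # uncapped minus capped equals exactly the two terminal-group charges
  for (mode in c("fractional", "integer")) {
    cap <- peptide_construct("ADKLY", ph = 7.4)
    free <- peptide_construct("ADKLY", n_cap = FALSE, c_cap = FALSE, ph = 7.4)
    diff <- net_charge(free, mode = mode) - net_charge(cap, mode = mode)
    term <- pipflank:::terminal_charges(FALSE, FALSE, 7.4, default_pka(), mode)
    expect_equal(diff, sum(term))
  }
})

test_that("NCPR windows truncate at chain ends and normalize correctly", {
  # motif-only window: single D in 8 residues
  cp <- ncpr_window("QTSMTDFY", 1, 8, flank_len = 0, ph = 7.4,
                    mode = "integer")
  expect_equal(cp$net, -1)
  expect_equal(cp$ncpr, -1 / 8)
  expect_false(cp$window$left_truncated)

  # motif at the chain start: left flank empty, flagged truncated
  cp2 <- ncpr_window("QTSMTDFYHSKRRLI", 1, 8, flank_len = 7, mode = "integer")
  expect_true(cp2$window$left_truncated)
  expect_equal(cp2$window$start, 1)

  # D1.2 peptide: net -3 over its 18 residues
  cp3 <- ncpr_window("SESSQTSMTDFYHSESSL", 5, 12, flank_len = 7,
                     mode = "integer")
  expect_equal(cp3$net, -3)
  expect_equal(cp3$ncpr, -3 / 18)
})

test_that("appending charged residues moves NCPR monotonically", {
  base <- "SSSQTSMTDFYSSS"
  ncpr_of <- function(s) ncpr_window(s, 4, 11, flank_len = 7, ph = 7.4)$ncpr
  expect_gt(ncpr_of(paste0(base, "K")), ncpr_of(base))
  expect_lt(ncpr_of(paste0(base, "E")), ncpr_of(base))
})

test_that("fractional charges converge to integer mode far from every pKa", {
  seqs <- c("KRDEG", "QTSMTDFY", "RKRRQTSMTDFYHSKRRL")
  for (s in seqs) {
    p <- peptide_construct(s, ph = 7.4)
    frac <- net_charge(p, "fractional")
    int <- net_charge(p, "integer")
    # at pH 7.4 His (pKa 6.0) is the closest group at 1.4 units; all other
    # side chains sit >= 3 units away, so agreement is within the His tail
    expect_equal(frac, int, tolerance = 0.06 * nchar(s))
  }
  # a sequence without H/C/Y at pH >= 3 units from D/E/K/R pKas
  p <- peptide_construct("KKDDEERRGGSS", ph = 7.4)
  expect_equal(net_charge(p, "fractional"), net_charge(p, "integer"),
               tolerance = 1e-2)
})

test_that("p21 variant NCPR ordering matches the affinity series", {
  panel <- pcna_peptide_panel()
  variants <- c("p21_140_164", "p21_140_157", "p21_143_157", "S2", "S1", "D1.2")
  # whole-peptide NCPR, as tabulated for the variant series
  ncpr <- vapply(variants, function(nm) {
    r <- panel[panel$name == nm, ]
    ncpr_window(r$sequence, r$motif_start, r$motif_end,
                flank_len = nchar(r$sequence), ph = 7.4,
                mode = "integer")$ncpr
  }, numeric(1))
  expect_false(is.unsorted(rev(ncpr), strictly = TRUE)) # strictly decreasing
  expect_equal(unname(ncpr[1:3]), c(0.36, 1 / 3, 0.2))
})

test_that("fractional NCPR matches an independent implementation", {
  # expected values frozen from Biopython ProteinAnalysis.charge_at_pH
  # (free termini, Biopython pKa set) divided by length
  bj_pka <- c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0, H = 5.98, K = 10.0,
              R = 12.0, Nterm = 7.5, Cterm = 3.55)
  seqs <- c(p21_140_164 = "RKRRQTSMTDFYHSKRRLIFSKRKP",
            p21_140_157 = "RKRRQTSMTDFYHSKRRL",
            p21_143_157 = "RQTSMTDFYHSKRRL",
            S2 = "RKRRQTSMTDFYHSESSL",
            S1 = "SESSQTSMTDFYHSKRRL",
            D1.2 = "SESSQTSMTDFYHSESSL")
  ref <- c(0.343274, 0.310382, 0.172629, 0.088364, 0.015909, -0.206109)
  mine <- vapply(seqs, function(s) {
    net_charge(peptide_construct(s, n_cap = FALSE, c_cap = FALSE, ph = 7.4),
               "fractional", pka_set = bj_pka) / nchar(s)
  }, numeric(1))
  expect_lt(max(abs(mine - ref)), 0.02)
})

test_that("flank-length NCPR profile averages only complete windows", {
  entries <- tibble::tibble(
    full_seq = c("KKKQTSMTDFYEEEE", "SSSSQTSMTDFYKKKK"),
    motif_start = c(4, 5), motif_end = c(11, 12), ph = 7.4
  )
  prof <- ncpr_flank_profile(entries, flank_lens = 1:9, mode = "integer")
  # both entries complete at flank 3; only by-hand averages expected
  e1 <- ncpr_window(entries$full_seq[1], 4, 11, 3, mode = "integer")$ncpr
  e2 <- ncpr_window(entries$full_seq[2], 5, 12, 3, mode = "integer")$ncpr
  expect_equal(prof$mean_ncpr[prof$flank_len == 3], mean(c(e1, e2)))
  expect_equal(prof$n_complete[prof$flank_len == 3], 2)
  # entry 1 has only 3 upstream residues: excluded at flank >= 4
  expect_equal(prof$n_complete[prof$flank_len == 4], 1)
  # no entry is complete at flank >= 5: undefined, not zero
  expect_true(all(is.na(prof$mean_ncpr[prof$flank_len >= 5])))
})
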