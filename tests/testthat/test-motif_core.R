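test_that("position assignment anchors PIP and APIM motifs correctly", {
  p21 <- motif_entry("p21", context_seq = "RQTSMTDFYHSKRRL", motif_start = 2,
                     motif_end = 9, declared_class = "pip_degron")
  pmap <- assign_positions(p21)
  at <- function(k) pmap$residue[pmap$coord == k]
  expect_equal(at(1), "Q")
  expect_equal(at(4), "M")
  expect_equal(at(7), "F")
  expect_equal(at(8), "Y")
  expect_equal(pmap$coord[pmap$context_index == 1], -1) # upstream R
  expect_equal(pmap$label[pmap$context_index == 12], "+3") # K

  apim <- motif_entry("apim", context_seq = "MDRWLVKW", motif_start = 3,
                      motif_end = 7, declared_class = "apim")
  amap <- assign_positions(apim)
  expect_equal(amap$coord[3:7], c(6L, 7L, 8L, 9L, 10L))
  expect_equal(amap$label[6:7], c("+1", "+2"))
  # contiguous back-extension from coordinate 6
  expect_equal(amap$coord[1:2], c(4L, 5L))

  # motif starting at context index 1 has no negative coordinates
  flush <- motif_entry("flush", context_seq = "QTSMTDFYHS", motif_start = 1,
                       motif_end = 8)
  expect_true(all(assign_positions(flush)$coord > 0))

  expect_error(assign_positions(
    motif_entry("bad", context_seq = "QTSMTDF", motif_start = 1,
                motif_end = 7)), "span")
})

test_that("coordinates skip zero, map bijectively and round-trip", {
  e <- motif_entry("x", context_seq = "AAAQTSMTDFYAAA", motif_start = 4,
                   motif_end = 11)
  pmap <- assign_positions(e)
  expect_false(any(pmap$coord == 0))
  expect_false(is.unsorted(pmap$coord, strictly = TRUE))
  expect_equal(anyDuplicated(pmap$coord), 0L)
  expect_equal(coord_parse(coord_label(pmap$coord)), pmap$coord)
})

test_that("classification flags and degron rule behave monotonically", {
  p21 <- motif_entry("p21", context_seq = "RQTSMTDFYHSKRRL", motif_start = 2,
                     motif_end = 9, declared_class = "pip_degron")
  cl <- classify_motif(p21)
  expect_equal(cl$class, "pip_degron")
  expect_true(all(cl$flags[c("has_Q1", "has_hydrophobic4", "has_aromatic7",
                             "has_aromatic8", "degron_basic_plus4",
                             "degron_TD56")]))

  # mutating the +4 basic residue to Ser downgrades degron -> box
  mut <- p21
  mut$context_seq <- sub("^(.{12})R", "\\1S", "RQTSMTDFYHSKRRL") # +4 is index 13
  expect_equal(classify_motif(mut)$class, "pip_box")

  fen1 <- motif_entry("FEN1", context_seq = "TQGRLDDFFKVTGSL", motif_start = 2,
                      motif_end = 9)
  expect_equal(classify_motif(fen1)$class, "pip_box")

  srs2 <- motif_entry("Srs2", context_seq = "ASSQMDIF", motif_start = 1,
                      motif_end = 8)
  cs <- classify_motif(srs2)
  expect_equal(cs$class, "unknown")
  expect_false(cs$flags[["has_aromatic7"]])
  expect_true(cs$flags[["has_aromatic8"]])

  apim <- motif_entry("apim", context_seq = "MDRWLVKW", motif_start = 3,
                      motif_end = 7, declared_class = "apim")
  ca <- classify_motif(apim)
  expect_equal(ca$class, "apim")
  expect_true(ca$flags[["apim_consensus"]])
})

test_that("motif-set statistics count degeneracies and ignore entry order", {
  toy <- toy_motif_set()
  s <- motif_set_statistics(toy)
  expect_equal(s$total, 2)
  expect_equal(unname(s$fractions[["no_Q1"]]), 0.5)
  expect_equal(unname(s$percent[["no_Q1"]]), 50)

  # 10-entry fixture with known flags: brute-force count equals output
  mk <- function(id, m) motif_entry(id, context_seq = m, motif_start = 1,
                                    motif_end = 8)
  motifs <- c("QTSMTDFY", "ETSMTDFY", "QTSATDFY", "QTSMTDSY", "QTSMTDFS",
              "QTSMTDSS", "GTSSTDSS", "QTSLTDYY", "KTSVTDFF", "QTSITDFY")
  fx <- do.call(rbind, lapply(seq_along(motifs),
                              function(i) mk(paste0("m", i), motifs[i])))
  s10 <- motif_set_statistics(fx)
  has_q <- substr(motifs, 1, 1) == "Q"
  h4 <- substr(motifs, 4, 4) %in% c("L", "M", "I", "V")
  n_arom <- (substr(motifs, 7, 7) %in% c("Y", "F", "W")) +
    (substr(motifs, 8, 8) %in% c("Y", "F", "W"))
  expect_equal(unname(s10$counts),
               c(sum(!has_q), sum(!h4), sum(n_arom == 1), sum(n_arom == 0)))

  perm <- fx[c(7, 2, 10, 4, 1, 9, 3, 6, 5, 8), ]
  expect_equal(motif_set_statistics(perm)$fractions, s10$fractions)

  expect_error(motif_set_statistics(fx[0, ]), "empty")
})

test_that("logo information content spans its entropy bounds", {
  mk <- function(id, m) motif_entry(id, context_seq = m, motif_start = 1,
                                    motif_end = 8)
  # column 1 single-lettered, column 2 with frequencies 1/2, 1/4, 1/4
  fx <- rbind(mk("a", "QASMTDFY"), mk("b", "QLSMTDFY"),
              mk("c", "QAGMTDFY"), mk("d", "QTVMTDFY"))
  logo <- build_logo(fx, coords = 1:8)
  expect_equal(unname(colSums(logo$freq)), rep(1, 8), tolerance = 1e-9)
  expect_equal(unname(logo$information[["1"]]), log2(20))
  h2 <- -(0.5 * log2(0.5) + 0.25 * log2(0.25) + 0.25 * log2(0.25))
  expect_equal(unname(logo$information[["2"]]), log2(20) - h2)
  expect_true(all(logo$information >= 0 & logo$information <= log2(20)))

  # uniform column over the 20 types has zero information
  unif <- do.call(rbind, lapply(seq_len(20), function(i) {
    mk(paste0("u", i),
       paste0(pipflank:::AA_CANONICAL[i], "TSMTDFY"))
  }))
  expect_equal(unname(build_logo(unif, coords = 1)$information), 0,
               tolerance = 1e-12)

  # gaps are excluded; an all-gap column is undefined
  gap <- rbind(mk("g1", "QARL--PF"), mk("g2", "QARL--PF"))
  expect_error(build_logo(gap, coords = 5), "undefined")
})
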