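test_that("PWM construction normalizes and validates", {
  m <- matrix(c(8, 1, 1, 0), 4, 3)
  p <- pwm(m, "toy")
  expect_equal(unname(colSums(p$mat)), rep(1, 3), tolerance = 1e-9)
  expect_true(all(p$mat > 0))
  expect_error(pwm(matrix(1, 3, 4), "bad"), "4 x W")
  rc <- pwm_revcomp(pwm_from_consensus("TGACTCA"))
  expect_equal(pwm_width(rc), 7)
  expect_equal(unname(rc$mat["T", 1]),
               unname(pwm_from_consensus("TGACTCA")$mat["A", 7]))
})

test_that("the packaged library and MEME parsing round-trip", {
  lib <- example_motif_library()
  expect_s3_class(lib, "pwm_list")
  expect_gte(length(lib), 10)
  expect_true("AP1_A" %in% names(lib))
  expect_true(all(vapply(lib, function(m) {
    all(abs(colSums(m$mat) - 1) < 1e-6)
  }, logical(1))))

  meme <- c("MEME version 4", "", "ALPHABET= ACGT", "",
            "MOTIF m1 toy",
            "letter-probability matrix: alength= 4 w= 3 nsites= 20 E= 0",
            " 0.70 0.10 0.10 0.10",
            " 0.10 0.70 0.10 0.10",
            " 0.10 0.10 0.10 0.70")
  f <- tempfile(fileext = ".meme")
  writeLines(meme, f)
  got <- read_meme(f)
  expect_equal(names(got), "m1")
  expect_equal(unname(got[["m1"]]$mat["A", 1]), 0.7, tolerance = 1e-3)
  expect_equal(pwm_width(got[["m1"]]), 3)
  unlink(f)
})

test_that("scanning finds planted consensus sites on both strands", {
  ap1 <- pwm_from_consensus("TGACTCA", p = 0.97)
  s <- paste0(strrep("A", 20), "TGACTCA", strrep("A", 20))
  h <- scan_pwm(ap1, s)
  expect_identical(nrow(h), 1L)
  expect_equal(h$offset, 21L)
  expect_equal(h$strand, "+")

  s_rc <- paste0(strrep("A", 10), revcomp("TGACTCA"), strrep("A", 10))
  h_rc <- scan_pwm(ap1, s_rc)
  expect_identical(h_rc$strand, "-")
  expect_equal(h_rc$offset, 11L)

  gcm <- pwm_from_consensus("GGCCGGCC", p = 0.97)
  expect_identical(nrow(scan_pwm(gcm, strrep("A", 100))), 0L)
  # windows containing N are skipped
  expect_identical(nrow(scan_pwm(ap1, "TGANTCA")), 0L)
  expect_error(scan_pwm(ap1, ""), "non-empty")
})

test_that("scan_pwm agrees with naive per-offset rescoring", {
  set.seed(11)
  for (i in 1:20) {
    w <- sample(5:10, 1)
    x <- pwm(matrix(rexp(4 * w), 4, w), paste0("r", i))
    cons <- paste(rownames(x$mat)[apply(x$mat, 2, which.max)], collapse = "")
    s <- plant_motif(random_seq(1, 60), cons)
    got <- scan_pwm(x, s, score_fraction = 0.7)
    want <- oracle_scan(x, s, score_fraction = 0.7)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      o <- order(want$offset, want$strand)
      expect_equal(got$offset, want$offset[o])
      expect_equal(got$strand, want$strand[o])
      expect_equal(got$score, want$score[o], tolerance = 1e-10)
    }
  }
})

test_that("motif enrichment ranks a planted motif first", {
  set.seed(12)
  targets <- plant_motif(random_seq(200, 300), "TGACTCA", rate = 0.8)
  background <- plant_motif(random_seq(2000, 300), "TGACTCA", rate = 0.05)
  enr <- motif_enrichment(targets, background, example_motif_library())
  expect_equal(enr$motif[1], "AP1_A")
  expect_lt(enr$padj[1], 1e-10)
  expect_gt(enr$fold[1], 2)
  decoys <- enr[enr$motif != "AP1_A", ]
  expect_gte(mean(decoys$padj > 0.1), 0.9)

  # p agrees with the shared hypergeometric kernel on the same 2x2
  hg <- hypergeom_enrichment(k = enr$target_hits[1],
                             K = enr$target_hits[1] + enr$bg_hits[1],
                             n = enr$target_n[1],
                             N = enr$target_n[1] + enr$bg_n[1])
  expect_equal(enr$p[1], hg$p)

  # null: identical planting rates leave nothing enriched
  set.seed(13)
  t0 <- plant_motif(random_seq(150, 300), "TGACTCA", rate = 0.1)
  b0 <- plant_motif(random_seq(1500, 300), "TGACTCA", rate = 0.1)
  enr0 <- motif_enrichment(t0, b0, example_motif_library())
  expect_equal(sum(enr0$padj < 0.1, na.rm = TRUE), 0)
})

test_that("motif similarity is reflexive, reverse-complement aware and degenerate-safe", {
  a <- pwm_from_consensus("TGACTCAG")
  s_aa <- motif_similarity(a, a)
  expect_equal(s_aa$r, 1)
  expect_equal(s_aa$ncor, 1)
  expect_equal(s_aa$offset, 0L)
  expect_equal(s_aa$orientation, "+")

  s_rc <- motif_similarity(a, pwm_revcomp(a))
  expect_equal(s_rc$r, 1, tolerance = 1e-12)
  expect_equal(s_rc$orientation, "-")

  unif <- pwm(matrix(0.25, 4, 8), "unif")
  s_u <- motif_similarity(a, unif)
  expect_equal(s_u$r, 0)
  expect_equal(s_u$ncor, 0)

  b <- pwm_from_consensus("CCGGAATTGG")
  ab <- motif_similarity(a, b)
  ba <- motif_similarity(b, a)
  expect_equal(ab$ncor, ba$ncor, tolerance = 1e-12)
})

test_that("motif clustering groups identical motifs and respects thresholds", {
  m1 <- pwm_from_consensus("TGACTCAG", id = "m1")
  m2 <- pwm_from_consensus("TGACTCAG", id = "m2")
  m3 <- pwm_from_consensus("CCCGGGAA", id = "m3")
  cl <- cluster_motifs(list(m1, m2, m3))
  expect_equal(cl$cluster[cl$motif %in% c("m1", "m2")], c("m1", "m1"))
  expect_equal(cl$cluster[cl$motif == "m3"], "m3")
  # order invariance
  cl_rev <- cluster_motifs(list(m3, m2, m1))
  expect_identical(cl, cl_rev)
  # dissimilar library: all singletons
  lib <- list(pwm_from_consensus("AAAATTTT", id = "a"),
              pwm_from_consensus("CGCGCGCG", id = "b"),
              pwm_from_consensus("AGAGAGAG", id = "c"))
  cl2 <- cluster_motifs(lib)
  expect_identical(cl2$cluster, cl2$motif)
})
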