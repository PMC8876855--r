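test_that("fragment ladders have n-1 ions per series per charge", {
  withr::with_seed(41, {
    for (n in c(2, 5, 12)) {
      s <- peptide_sequence(random_peptide(n))
      fr <- fragment_ions(s, series = c("b", "y", "c", "z"), max_charge = 2)
      expect_equal(nrow(fr), 4L * 2L * (n - 1L))
      counts <- table(fr$series, fr$charge)
      expect_true(all(counts == n - 1L))
      expect_true(all(fr$mz > 0))
    }
  })
  expect_error(fragment_ions(peptide_sequence("G")), "at least 2 residues")
})

test_that("fragment m/z values match the series definitions", {
  # b1 of GG at charge 1: residue G + proton
  fr <- fragment_ions(peptide_sequence("GG"), series = "b")
  expect_equal(fr$mz[1L], 58.0287, tolerance = 1e-4)
  s <- peptide_sequence("SAMPLER")
  b <- fragment_ions(s, "b")$mz
  y <- fragment_ions(s, "y")$mz
  cc <- fragment_ions(s, "c")$mz
  z <- fragment_ions(s, "z")$mz
  # c = b + NH3 at every index
  expect_equal(cc - b, rep(17.026549, 6), tolerance = 1e-5)
  # z-dot = y - NH3 + H at every index
  expect_equal(y - z, rep(17.026549 - 1.007825, 6), tolerance = 1e-5)
  # classical z available on request
  zc <- fragment_ions(s, "z", zdot = FALSE)$mz
  expect_equal(y - zc, rep(17.026549, 6), tolerance = 1e-5)
  # doubly charged ions: mz2 = (mz1 + proton)/2
  b2 <- fragment_ions(s, "b", max_charge = 2)
  expect_equal(b2$mz[b2$charge == 2],
               (b + 1.00727646688) / 2, tolerance = 1e-9)
})

test_that("complementary b/y pairs reconstruct the precursor mass", {
  withr::with_seed(47, {
    for (k in 1:10) {
      s <- peptide_sequence(random_peptide(sample(3:15, 1)))
      b <- fragment_ions(s, "b")$mz
      y <- fragment_ions(s, "y")$mz
      m <- peptide_mass(s) + 2 * 1.00727646688
      expect_equal(b + rev(y), rep(m, length(b)), tolerance = 1e-9)
    }
  })
})

test_that("cuts that may sever a disulfide bridge are flagged, not guessed", {
  s <- peptide_sequence("ACGGGCA", n_disulfides = 1)  # Cys at 2 and 6
  fr <- fragment_ions(s, "b")
  # cuts 1 (before first Cys) and 6 (after last Cys) keep both Cys together
  expect_false(fr$crosslink_ambiguous[1L])
  expect_false(fr$crosslink_ambiguous[6L])
  # cuts 2..5 separate the pair: flagged with NA m/z
  expect_true(all(fr$crosslink_ambiguous[2:5]))
  expect_true(all(is.na(fr$mz[2:5])))
  expect_true(all(!is.na(fr$mz[c(1L, 6L)])))
  # without bridges nothing is flagged
  fr0 <- fragment_ions(peptide_sequence("ACGGGCA"), "b")
  expect_false(any(fr0$crosslink_ambiguous))
})

test_that("tryptic digestion follows the Keil rule", {
  digest_strings <- function(s, mc = 0)
    vapply(tryptic_digest(peptide_sequence(s), mc), `[[`, "", "residues")
  expect_equal(digest_strings("AAAA"), "AAAA")
  expect_equal(digest_strings("AKRPC"), c("AK", "RPC"))  # R-P protected
  expect_setequal(digest_strings("AKCR", 1), c("AK", "CR", "AKCR"))
  expect_equal(digest_strings("AKGKRC"), c("AK", "GK", "R", "C"))
  expect_setequal(digest_strings("AKGKRC", 2),
                  c("AK", "GK", "R", "C", "AKGK", "GKR", "RC",
                    "AKGKR", "GKRC"))
})

test_that("digestion conserves sequence and mass", {
  withr::with_seed(53, {
    for (k in 1:10) {
      s <- random_peptide(sample(10:40, 1))
      pep <- peptide_sequence(s)
      frags <- tryptic_digest(pep, 0)
      expect_equal(paste(vapply(frags, `[[`, "", "residues"),
                         collapse = ""), s)
      # sum of fragment masses = parent + (n_fragments - 1) * water
      msum <- sum(vapply(frags, peptide_mass, 1.0))
      expect_equal(msum,
                   peptide_mass(pep) + (length(frags) - 1) *
                     mass_table()$constants$water_mono,
                   tolerance = 1e-9)
    }
  })
})

test_that("peak matching is tolerance-aware, greedy, and reports coverage", {
  s <- peptide_sequence("SAMPLEPEPTIDEK")
  theo <- fragment_ions(s, series = c("b", "y"))
  exact <- peak_list(theo$mz, rep(100, nrow(theo)))
  m <- match_peaks(theo, exact, tol_ppm = 10)
  expect_equal(m$coverage, 1)
  expect_equal(m$n_matched, nrow(theo))
  expect_equal(max(abs(m$matches$ppm_error)), 0)
  # peaks offset by +20 ppm: invisible at 10 ppm, all matched at 30 ppm
  shifted <- peak_list(theo$mz * (1 + 20e-6), rep(100, nrow(theo)))
  expect_equal(match_peaks(theo, shifted, tol_ppm = 10)$n_matched, 0L)
  m30 <- match_peaks(theo, shifted, tol_ppm = 30)
  expect_equal(m30$n_matched, nrow(theo))
  expect_equal(median(m30$matches$ppm_error), 20, tolerance = 1e-6)
  # empty observed list: zero coverage, no matches
  m0 <- match_peaks(theo, peak_list())
  expect_equal(m0$coverage, 0)
  expect_equal(m0$n_matched, 0L)
  # each observed peak is used at most once
  one_peak <- peak_list(theo$mz[1L], 1)
  m1 <- match_peaks(theo, one_peak, tol_ppm = 10)
  expect_equal(m1$n_matched, 1L)
})

test_that("half-ladder coverage counts backbone sites from both termini", {
  s <- peptide_sequence("SAMPLEK")   # 7 residues, 6 sites
  theo <- fragment_ions(s, series = c("b", "y"))
  # observe only b1..b3 and y1..y2 -> sites {1,2,3} + {6,5} = 5 of 6
  keep <- (theo$series == "b" & theo$index <= 3) |
    (theo$series == "y" & theo$index <= 2)
  obs <- peak_list(theo$mz[keep], rep(1, sum(keep)))
  m <- match_peaks(theo, obs, tol_ppm = 5)
  expect_equal(m$coverage, 5 / 6)
})
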