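# independent oracle for the hand-workable case: explicit site and
# difference counting plus the Jukes-Cantor formula
test_that("the six-codon worked example matches explicit counting", {
  est <- nei_gojobori_dnds("TTTTTTTTTTTTTTTTTT", "TTCTTTTTTTTTTTTTTT")
  # TTT and TTC each have one third of a synonymous site at position 3
  expect_equal(est$S, 2)
  expect_equal(est$N, 16)
  expect_equal(est$Sd, 1)
  expect_equal(est$Nd, 0)
  expect_equal(est$ps, 0.5)
  expect_equal(est$dS, -0.75 * log(1 / 3), tolerance = 1e-9)
  expect_equal(est$dN, 0)
  expect_equal(est$omega, 0)
  expect_equal(est$status, "ZERO")
})

test_that("identical sequences give the zero sentinel", {
  s <- random_cds(100, seed = 81)
  est <- nei_gojobori_dnds(s, s)
  expect_equal(est$dN, 0)
  expect_equal(est$dS, 0)
  expect_equal(est$omega, 0)
  expect_equal(est$status, "ZERO")
})

test_that("the estimator is symmetric in its arguments", {
  set.seed(82)
  for (rep in 1:5) {
    z <- random_cds(150)
    w <- simulate_gametologue_pair(z, omega = 0.4,
                                   expected_subs_per_codon = 0.2)$w_cds
    a <- nei_gojobori_dnds(w, z)
    b <- nei_gojobori_dnds(z, w)
    expect_equal(a$dN, b$dN, tolerance = 1e-12)
    expect_equal(a$dS, b$dS, tolerance = 1e-12)
  }
})

test_that("invalid pairs are rejected", {
  expect_error(nei_gojobori_dnds("ATGAA", "ATGAA"), "divisible")
  expect_error(nei_gojobori_dnds("ATGTAAAAATTT", "ATGTAAAAATTT"),
               "internal stop")
  expect_error(nei_gojobori_dnds("ATGAAA", "ATG"), "equal length")
})

test_that("saturation raises the sentinel instead of a number", {
  # every codon differs at its synonymous position: ps = 1 > 3/4
  w <- paste(rep("TTT", 10), collapse = "")
  z <- paste(rep("TTC", 10), collapse = "")
  est <- nei_gojobori_dnds(w, z)
  expect_equal(est$status, "SATURATED")
  expect_true(is.na(est$omega))
})

test_that("simulated pairs recover their generative omega", {
  set.seed(83)
  for (om in c(0, 0.2, 0.6)) {
    ests <- replicate(30, {
      z <- random_cds(300)
      p <- simulate_gametologue_pair(z, omega = om,
                                     expected_subs_per_codon = 0.3)
      al <- codon_align(p$w_cds, p$z_cds)
      e <- nei_gojobori_dnds(al$w, al$z)
      if (e$status == "ZERO") 0 else e$omega
    })
    expect_lt(abs(mean(ests, na.rm = TRUE) - om), 0.1)
  }
})

test_that("purely synonymous evolution leaves dN at (essentially) zero", {
  # note: equal-weight pathway averaging can route a multi-hit codon
  # through a nonsynonymous intermediate, so dN is near zero rather than
  # exactly zero when codons accumulated two synonymous hits
  set.seed(84)
  for (rep in 1:10) {
    z <- random_cds(120)
    w <- simulate_gametologue_pair(z, omega = 0,
                                   expected_subs_per_codon = 0.2)$w_cds
    expect_identical(translate_cds(w), translate_cds(z))
    expect_lt(nei_gojobori_dnds(w, z)$dN, 0.02)
  }
})

test_that("codon alignment preserves frame and drops gapped codons", {
  z <- random_cds(100, seed = 85)
  # delete two codons from the middle of the W copy
  w <- paste0(substr(z, 1, 150), substr(z, 157, nchar(z)))
  al <- codon_align(w, z)
  expect_equal(nchar(al$w) %% 3, 0)
  expect_equal(nchar(al$w), nchar(al$z))
  expect_equal(nchar(al$z), nchar(z) - 3 - 6)  # stop + 2 deleted codons
  expect_false(grepl("-", paste0(al$w, al$z)))
  # aligned translations are stop-free
  expect_false(grepl("*", translate_cds(al$w), fixed = TRUE))
})

test_that("sliding windows track local divergence structure", {
  s <- random_cds(200, seed = 86)
  prof0 <- sliding_window_dnds(s, s)
  expect_true(all(prof0$status == "ZERO"))
  expect_true(all(diff(prof0$midpoint) > 0))
  # chimera: first half constrained (omega 0), second half free (omega 1)
  set.seed(87)
  z <- random_cds(300, terminal_stop = FALSE)
  half <- 450
  w1 <- simulate_gametologue_pair(substr(z, 1, half), omega = 0,
                                  expected_subs_per_codon = 0.3)$w_cds
  w2 <- simulate_gametologue_pair(substr(z, half + 1, 900), omega = 1,
                                  expected_subs_per_codon = 0.3)$w_cds
  prof <- sliding_window_dnds(paste0(w1, w2), z)
  first <- prof$omega[prof$midpoint < 130]
  second <- prof$omega[prof$midpoint > 170]
  expect_gt(mean(second, na.rm = TRUE), mean(first, na.rm = TRUE))
  # window omegas scatter around the whole-gene estimate under uniform
  # divergence (averaged over replicate genes, since single-window ratio
  # estimates are noisy)
  delta <- replicate(6, {
    p <- simulate_gametologue_pair(random_cds(300), omega = 0.3,
                                   expected_subs_per_codon = 0.3)
    whole <- nei_gojobori_dnds(p$w_cds, p$z_cds)
    prof2 <- sliding_window_dnds(p$w_cds, p$z_cds)
    mean(prof2$omega, na.rm = TRUE) - whole$omega
  })
  expect_lt(abs(mean(delta)), 0.1)
  # over-long window degrades to a single whole-gene window with a warning
  p <- simulate_gametologue_pair(random_cds(300), omega = 0.3,
                                 expected_subs_per_codon = 0.3)
  expect_warning(single <- sliding_window_dnds(p$w_cds, p$z_cds,
                                               window_codons = 1000L),
                 "single window")
  expect_equal(nrow(single), 1L)
})

test_that("gametologue evolution respects omega and the substitution budget", {
  z <- random_cds(200, seed = 88)
  same <- simulate_gametologue_pair(z, expected_subs_per_codon = 0)
  expect_identical(same$w_cds, z)
  syn_only <- simulate_gametologue_pair(z, omega = 0,
                                        expected_subs_per_codon = 0.3,
                                        seed = 89)
  expect_identical(translate_cds(syn_only$w_cds), translate_cds(z))
  expect_gt(syn_only$n_substitutions, 0)
  expect_error(simulate_gametologue_pair("ATGTAATTTAAA"), "internal stop")
  expect_error(simulate_gametologue_pair("ATGAA"), "divisible")
})
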