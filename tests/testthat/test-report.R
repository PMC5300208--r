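ref_free <- function() {
  dplyr::bind_rows(
    tibble::tibble(metric = "EED", n = 200, min = 22, q1 = 24, median = 25.5,
                   q3 = 27, max = 29, mean = 25.5, sd = 1.2),
    tibble::tibble(metric = "MVEE_volume", n = 200, min = 560, q1 = 600,
                   median = 650, q3 = 700, max = 760, mean = 650, sd = 35))
}

shift_free <- function(eed_shift, vol_shift) {
  s <- ref_free()
  is_eed <- s$metric == "EED"
  s[is_eed, c("min", "q1", "median", "q3", "max", "mean")] <-
    s[is_eed, c("min", "q1", "median", "q3", "max", "mean")] + eed_shift
  s[!is_eed, c("min", "q1", "median", "q3", "max", "mean")] <-
    s[!is_eed, c("min", "q1", "median", "q3", "max", "mean")] + vol_shift
  s
}

test_that("a failed leg short-circuits the sequential procedure", {
  fail1 <- free_state_verdict(shift_free(-16, -450), ref_free())
  expect_equal(fail1$status, "fail")
  rep <- mimicry_report("monomer_like", "HS06", fail1,
                        binding_site_check(docking_evidence("m", 90, TRUE),
                                           docking_evidence("HS06", 100, TRUE)),
                        NULL)
  expect_equal(rep$overall, "non_mimic")
  expect_equal(rep$legs$binding_site$status, "not_evaluated")
  expect_equal(rep$legs$bound_state$status, "not_evaluated")
})

test_that("inconclusive legs propagate to an inconclusive overall verdict", {
  pass1 <- free_state_verdict(ref_free(), ref_free())
  undocked <- binding_site_check(NULL, docking_evidence("HS06", 100, TRUE))
  rep <- mimicry_report("candidate", "HS06", pass1, undocked, NULL)
  expect_equal(rep$overall, "inconclusive")
  expect_equal(rep$legs$binding_site$status, "inconclusive")
})

test_that("candidates ranked against a common reference reproduce the expected
          mimicry order", {
  ref <- ref_free()
  dock_ref <- docking_evidence("HS06", 100.8, TRUE)
  occ_ref <- make_occupancy(c("Arg121", "Lys126", "Lys136"), c(92, 90, 85))
  en_ref <- make_energy(c("Gln135", "Arg121", "Lys135"),
                        c(-10.2, -9.0, -8.5), -74.0, 11.1)
  bound_ref <- shift_free(-2, -60)

  build <- function(label, free, dock, occ, en, bound) {
    leg1 <- free_state_verdict(free, ref)
    if (leg1$status != "pass") {
      return(mimicry_report(label, "HS06", leg1))
    }
    leg2 <- binding_site_check(dock, dock_ref)
    if (leg2$status != "pass") {
      return(mimicry_report(label, "HS06", leg1, leg2))
    }
    leg3 <- bound_state_verdict(bound, bound_ref, occ, occ_ref, en, en_ref)
    mimicry_report(label, "HS06", leg1, leg2, leg3)
  }

  # two dimer-like candidates pass everything, the better one more tightly;
  # a compact monomer-like and an oversized tetramer-like fail leg 1
  dimer_best <- build("G2.2_like", shift_free(0.2, 10),
                      docking_evidence("G2.2_like", 109.8, TRUE),
                      make_occupancy(c("Arg121", "Lys126", "Lys136"), c(90, 88, 80)),
                      make_energy(c("Gln135", "Arg121", "Lys126"),
                                  c(-10.0, -9.5, -9.0), -73.0, 10.0),
                      shift_free(-2.1, -55))
  dimer_ok <- build("G2.1_like", shift_free(1.2, 45),
                    docking_evidence("G2.1_like", 108.6, TRUE),
                    make_occupancy(c("Arg121", "Lys126", "Asn102"), c(88, 85, 70)),
                    make_energy(c("Lys126", "Arg121", "Lys120"),
                                c(-12.0, -11.1, -8.0), -73.5, 10.0),
                    shift_free(-2.5, -75))
  monomer <- build("monomer_like", shift_free(-16, -450), NULL, NULL, NULL, NULL)
  tetramer <- build("tetramer_like", shift_free(14, 900), NULL, NULL, NULL, NULL)

  ranking <- rank_candidates(list(monomer, dimer_ok, tetramer, dimer_best))
  expect_equal(ranking$candidate[1:2], c("G2.2_like", "G2.1_like"))
  expect_setequal(ranking$candidate[3:4], c("monomer_like", "tetramer_like"))
  expect_equal(ranking$legs_passed[1:2], c(3, 3))
  expect_equal(ranking$legs_passed[3:4], c(0, 0))
  expect_equal(ranking$overall[1], "mimic")
  expect_equal(ranking$overall[3:4], rep("non_mimic", 2))

  # leg-1 failures never had their later legs evaluated
  expect_equal(monomer$legs$binding_site$status, "not_evaluated")
  expect_equal(monomer$legs$bound_state$status, "not_evaluated")

  # singleton input stays a one-row ranking
  expect_equal(nrow(rank_candidates(list(dimer_best))), 1)

  # mixed references are refused
  other <- mimicry_report("x", "otherGAG", free_state_verdict(ref, ref))
  expect_error(rank_candidates(list(dimer_best, other)),
               class = "gagmimic_reference_mismatch")
})

test_that("improving a component can only improve or preserve the rank", {
  ref <- ref_free()
  better <- free_state_verdict(shift_free(0.1, 5), ref)
  worse <- free_state_verdict(shift_free(1.5, 60), ref)
  expect_gte(better$score, worse$score)
  r_better <- mimicry_report("cand", "HS06", better)
  r_worse <- mimicry_report("cand", "HS06", worse)
  expect_gte(r_better$overall_score, r_worse$overall_score)
})

test_that("reports serialize to structured text and reload with full
          fidelity", {
  ref <- ref_free()
  leg1 <- free_state_verdict(shift_free(0.2, 10), ref)
  leg2 <- binding_site_check(docking_evidence("c", 110, TRUE),
                             docking_evidence("HS06", 100.8, TRUE))
  rep <- mimicry_report("candidate", "HS06", leg1, leg2, NULL,
                        provenance = provenance_block(
                          clustering_seed = 17,
                          analysis_window = "(10000, 20000] ps, stride 10 ps"))
  path <- tempfile(fileext = ".json")
  write_mimicry_report(rep, path)
  back <- read_mimicry_report(path)
  expect_equal(back$candidate, rep$candidate)
  expect_equal(back$reference, rep$reference)
  expect_equal(back$overall, rep$overall)
  expect_equal(back$overall_score, rep$overall_score)
  for (nm in names(rep$legs)) {
    expect_equal(back$legs[[nm]]$status, rep$legs[[nm]]$status)
    expect_equal(back$legs[[nm]]$score, rep$legs[[nm]]$score)
    expect_equal(as.data.frame(back$legs[[nm]]$components),
                 as.data.frame(rep$legs[[nm]]$components))
  }
  # the provenance block survives and records the analysis conventions
  expect_equal(back$provenance$hbond_convention, "deviation_from_linearity_DHA")
  expect_equal(back$provenance$clustering_seed, 17)
  expect_equal(back$provenance$mvee_tolerance, 1e-6)
  expect_equal(back$provenance$eed_endpoints, "auto_max_extent")
})
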