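# a minimal receptor(amide N-H) / ligand(hydroxyl + sulfate) complex in which
# every geometric feature is placed by hand
handmade_complex <- function(da_dist = 2.9, dha_angle = 180) {
  at <- tibble::tibble(
    atom_name = c("N", "H", "C", "O3", "HO3", "S", "OS1", "OS2", "OS3", "OC"),
    element   = c("N", "H", "C", "O", "H", "S", "O", "O", "O", "O"),
    residue_name = c(rep("ALA", 3), rep("LIG", 7)),
    residue_id = c(rep(1L, 3), rep(1L, 7)),
    chain_id = c(rep("A", 3), rep("L", 7)))
  bonds <- rbind(c(1, 2), c(1, 3), c(4, 5), c(6, 7), c(6, 8), c(6, 9), c(6, 10))
  # acceptor O3 placed on the N-H axis at the requested distance, then swung
  # off-axis to set the D-H-A angle
  theta <- (180 - dha_angle) * pi / 180
  h <- c(1.0, 0, 0)
  # position acceptor so that |N-A| = da_dist and angle(D-H-A) = dha_angle
  # solve on the H-centred geometry: direction from H making angle theta with N->H extension
  r <- sqrt(da_dist^2 - (1.0 * sin(theta))^2) - 1.0 * cos(theta)  # |H-A|
  acc <- h + r * c(cos(theta), sin(theta), 0)
  xyz <- rbind(
    c(0, 0, 0), h, c(-1.4, 0, 0),            # N, H, C
    acc, acc + c(0, 0.97, 0),                 # O3, HO3
    c(20, 0, 0), c(20, 1.4, 0), c(20, -1.4, 0), c(21.2, 0, 0.8), c(18.8, 0, 0))
  list(topology = topology(at, bonds), xyz = xyz,
       receptor = 1:3, ligand = 4:10)
}

test_that("donor/acceptor assignment follows bonded-hydrogen chemistry", {
  cx <- handmade_complex()
  da <- assign_donors_acceptors(cx$topology)
  # hydroxyl oxygen O3 is both donor and acceptor
  expect_true(4 %in% da$donors$donor)
  expect_true(4 %in% da$acceptors)
  # amide: N-H donor; sulfate oxygens acceptors but never donors
  expect_true(1 %in% da$donors$donor)
  expect_true(all(c(7, 8, 9) %in% da$acceptors))
  expect_false(any(c(7, 8, 9) %in% da$donors$donor))
  # bonds are mandatory
  expect_error(assign_donors_acceptors(simple_topology(4)),
               class = "gagmimic_missing_bonds")
})

test_that("the distance and angle cutoffs gate detection exactly as stated", {
  # linear N-H...O at 2.9 A: detected
  cx <- handmade_complex(da_dist = 2.9, dha_angle = 180)
  hb <- detect_hbonds_frame(cx$xyz, cx$topology, cx$ligand, cx$receptor)
  expect_true(any(hb$donor == 1 & hb$acceptor == 4))
  expect_equal(hb$distance[hb$donor == 1 & hb$acceptor == 4], 2.9,
               tolerance = 1e-9)

  # stretched to 3.6 A: beyond the 3.5 A cutoff
  far <- handmade_complex(da_dist = 3.6, dha_angle = 180)
  hb_far <- detect_hbonds_frame(far$xyz, far$topology, far$ligand, far$receptor)
  expect_false(any(hb_far$donor == 1 & hb_far$acceptor == 4))

  # 2.9 A but DHA = 115 degrees (deviation 65): rejected by default convention
  bent <- handmade_complex(da_dist = 2.9, dha_angle = 115)
  hb_bent <- detect_hbonds_frame(bent$xyz, bent$topology, bent$ligand, bent$receptor)
  expect_false(any(hb_bent$donor == 1 & hb_bent$acceptor == 4))
  # ... and accepted at DHA = 125 (deviation 55)
  ok <- handmade_complex(da_dist = 2.9, dha_angle = 125)
  hb_ok <- detect_hbonds_frame(ok$xyz, ok$topology, ok$ligand, ok$receptor)
  expect_true(any(hb_ok$donor == 1 & hb_ok$acceptor == 4))

  # the alternative theta(DH, DA) convention is selectable and differs
  crit_theta <- hbond_criteria(angle_convention = "theta_DH_DA", angle_cutoff = 30)
  hb_theta <- detect_hbonds_frame(bent$xyz, bent$topology, bent$ligand,
                                  bent$receptor, crit_theta)
  expect_s3_class(hb_theta, "tbl_df")

  # overlapping selections are refused
  expect_error(detect_hbonds_frame(cx$xyz, cx$topology, 1:5, 4:10),
               class = "gagmimic_selection_overlap")
})

test_that("hydrogen-bond detection is rigid-motion invariant and symmetric in
          the ligand/receptor roles", {
  cx <- handmade_complex()
  hb <- detect_hbonds_frame(cx$xyz, cx$topology, cx$ligand, cx$receptor)
  set.seed(51)
  hb_moved <- detect_hbonds_frame(apply_rigid(cx$xyz), cx$topology,
                                  cx$ligand, cx$receptor)
  expect_equal(hb_moved[, c("donor", "hydrogen", "acceptor")],
               hb[, c("donor", "hydrogen", "acceptor")])
  expect_equal(hb_moved$distance, hb$distance, tolerance = 1e-9)

  swapped <- detect_hbonds_frame(cx$xyz, cx$topology, cx$receptor, cx$ligand)
  key <- function(x) sort(paste(x$donor, x$hydrogen, x$acceptor))
  expect_equal(key(swapped), key(hb))
})

test_that("occupancy is exact arithmetic on planted incidence and sits inside
          the binomial interval for planted probabilities", {
  p <- c(0, 0.25, 0.6, 1.0)
  nf <- 2000
  cx <- generate_complex_with_hbonds(4, p, nf, seed = 71)
  occ <- occupancy_table(cx$ensemble, cx$ligand, cx$receptor,
                         window = frame_window(-1, nf - 1, 1))
  # the p = 0 residue is absent (no zero rows); p = 1 is exactly 100
  expect_false("Res1" %in% occ$residue)
  expect_equal(occ$occupancy[occ$residue == "Res4"], 100)
  # measured occupancy equals the realized incidence exactly
  realized <- 100 * colMeans(cx$truth$incidence)
  for (i in c(2, 3)) {
    expect_equal(occ$occupancy[occ$residue == paste0("Res", i)], realized[i])
  }
  # and the realized incidence sits inside the 99% binomial band of p
  for (i in c(2, 3)) {
    half_width <- 2.576 * sqrt(p[i] * (1 - p[i]) / nf) * 100
    expect_lt(abs(realized[i] - 100 * p[i]), half_width)
  }
})

test_that("occupancy is monotone under tightening either cutoff", {
  nf <- 150
  cx <- generate_complex_with_hbonds(3, c(0.5, 0.7, 0.9), nf, seed = 81)
  # jitter the geometry so the cutoffs actually bite
  set.seed(82)
  jit <- cx$ensemble$coords + array(rnorm(length(cx$ensemble$coords), sd = 0.25),
                                    dim = dim(cx$ensemble$coords))
  ens <- conformer_ensemble(cx$ensemble$topology, jit, cx$ensemble$times)
  w <- frame_window(-1, nf - 1, 1)
  occ_at <- function(d, a) {
    o <- occupancy_table(ens, cx$ligand, cx$receptor,
                         hbond_criteria(d, a), w)
    total <- setNames(rep(0, 3), paste0("Res", 1:3))
    total[o$residue] <- o$occupancy
    total
  }
  base <- occ_at(3.5, 60)
  expect_true(all(occ_at(3.0, 60) <= base + 1e-9))
  expect_true(all(occ_at(3.5, 30) <= base + 1e-9))
  expect_true(all(occ_at(3.0, 30) <= pmin(occ_at(3.0, 60), occ_at(3.5, 30)) + 1e-9))
})

test_that("a ligand without polar atoms yields an empty occupancy table, and
          missing hydrogens are refused", {
  # carbon-only ligand: no donors or acceptors on its side
  at <- tibble::tibble(
    atom_name = c("N", "H", "C1", "C2"), element = c("N", "H", "C", "C"),
    residue_name = c("ALA", "ALA", "LIG", "LIG"), residue_id = c(1L, 1L, 2L, 2L),
    chain_id = c("A", "A", "L", "L"))
  top <- topology(at, rbind(c(1, 2), c(3, 4)))
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(3, 0, 0), c(4.4, 0, 0))
  ens <- conformer_ensemble(top, array(rep(xyz, each = 4), dim = c(4, 4, 3)))
  occ <- occupancy_table(ens, ligand = 3:4, receptor = 1:2,
                         window = frame_window(-1, 3, 1))
  expect_equal(nrow(occ), 0)

  # no hydrogens anywhere: explicit refusal, no distance-only fallback
  at2 <- tibble::tibble(atom_name = c("N", "C", "O", "C2"),
                        element = c("N", "C", "O", "C"),
                        residue_name = "X", residue_id = c(1L, 1L, 2L, 2L),
                        chain_id = c("A", "A", "L", "L"))
  top2 <- topology(at2, rbind(c(1, 2), c(3, 4)))
  expect_error(
    detect_hbonds_frame(matrix(rnorm(12), 4), top2, 3:4, 1:2),
    class = "gagmimic_no_hydrogens")
})
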