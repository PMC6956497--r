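test_that("shipped presets satisfy the parameter-set invariants", {
  expect_setequal(energy_presets(), c("default", "alt"))
  for (nm in energy_presets()) {
    p <- load_energy_parameters(nm)
    expect_length(p$stack, 36L)
    expect_true(all(is.finite(p$stack)))
    expect_gt(p$temperature, 0)
    expect_gte(p$loop_b, 0)  # loop cost non-decreasing in size
    # dyad table symmetric under reading the duplex from the other end
    rev_pair <- function(x) paste0(substr(x, 2, 2), substr(x, 1, 1))
    for (d in names(p$stack)) {
      ps <- strsplit(d, "/", fixed = TRUE)[[1]]
      mirror <- paste0(rev_pair(ps[2]), "/", rev_pair(ps[1]))
      expect_equal(p$stack[[d]], p$stack[[mirror]])
    }
  }
  # two presets differ in at least one stack entry
  expect_false(all(load_energy_parameters("default")$stack ==
                   load_energy_parameters("alt")$stack))
})

test_that("malformed or incomplete parameter files are rejected", {
  expect_error(load_energy_parameters("no-such-preset"), "unknown energy preset")
  src <- system.file("extdata", "energy", "default.tsv", package = "seedscan")
  lines <- readLines(src)
  crippled <- tempfile(fileext = ".tsv")
  writeLines(lines[!grepl("^CG/CG\t", lines)], crippled)
  expect_error(load_energy_parameters(crippled), "incomplete stacking table")
  garbled <- tempfile(fileext = ".tsv")
  writeLines(c(lines, "stray line without tab"), garbled)
  expect_error(load_energy_parameters(garbled), "malformed")
})

test_that("stacking energies reflect pair strength and are pure", {
  p <- default_params()
  expect_lt(stacking_energy(p, "CG", "CG"), stacking_energy(p, "AU", "AU"))
  expect_gt(stacking_energy(p, "GU", "UG"), stacking_energy(p, "CG", "GC"))
  expect_identical(stacking_energy(p, "GC", "AU"), stacking_energy(p, "GC", "AU"))
  expect_error(stacking_energy(p, "AC", "CG"), "non-canonical")
  expect_true(is_gu_pair("GU"))
  expect_true(is_gu_pair("UG"))
  expect_false(is_gu_pair("CG"))
})

test_that("GU substitution weakens every dyad and helix end", {
  p <- default_params()
  strong <- c("CG", "GC", "AU", "UA")
  for (gu in c("GU", "UG")) {
    for (q in c(strong, "GU", "UG")) {
      for (s in strong) {
        expect_gte(stacking_energy(p, gu, q), stacking_energy(p, s, q))
        expect_gte(stacking_energy(p, q, gu), stacking_energy(p, q, s))
      }
    }
    expect_gte(p$terminal[[gu]], max(p$terminal[strong]))
  }
})

test_that("hybridization energy sums initiation, stacks, loops and ends", {
  p <- default_params()
  # single CG pair: init only (zero terminal penalty for CG)
  e1 <- hybridization_energy(p, data.frame(pos1 = 1, pos2 = 8,
                                           nt1 = "C", nt2 = "G"))
  expect_equal(e1, p$init)
  # single AU pair carries the end penalty at both helix ends
  e2 <- hybridization_energy(p, data.frame(pos1 = 1, pos2 = 8,
                                           nt1 = "A", nt2 = "U"))
  expect_equal(e2, p$init + 2 * p$terminal[["AU"]])
  # perfect 7-pair helix: init + 6 stacks + end penalties, summed by hand
  nt1 <- c("G", "C", "A", "U", "G", "C", "G")
  nt2 <- c("C", "G", "U", "A", "C", "G", "C")
  pairs <- data.frame(pos1 = 1:7, pos2 = 20:14, nt1 = nt1, nt2 = nt2)
  pt <- paste0(nt1, nt2)
  by_hand <- p$init + p$terminal[[pt[1]]] + p$terminal[[pt[7]]] +
    sum(vapply(1:6, function(t) p$stack[[paste0(pt[t], "/", pt[t + 1])]],
               numeric(1)))
  expect_equal(hybridization_energy(p, pairs), by_hand)
  # splitting a helix by a 1x1 interior loop always costs energy
  split <- data.frame(pos1 = c(1:3, 5:7), pos2 = c(20:18, 16:14),
                      nt1 = nt1[-4], nt2 = nt2[-4])
  contiguous <- data.frame(pos1 = c(1:3, 4:6), pos2 = c(20:18, 17:15),
                           nt1 = nt1[-4], nt2 = nt2[-4])
  expect_gt(hybridization_energy(p, split), hybridization_energy(p, contiguous))
  # errors
  expect_error(hybridization_energy(p, pairs[0, ]), "empty pair list")
  bad <- pairs; bad$pos2 <- rev(bad$pos2)
  expect_error(hybridization_energy(p, bad), "crossing")
})

test_that("hybridization energy is invariant under duplex reversal", {
  p <- default_params()
  set.seed(42)
  comp <- c(A = "U", U = "A", C = "G", G = "C")
  wob <- c(G = "U", U = "G")
  for (t in 1:25) {
    m <- sample(3:8, 1)
    # random gapped duplex
    pos1 <- cumsum(c(1, sample(1:3, m - 1, TRUE)))
    pos2 <- rev(cumsum(c(1, sample(1:3, m - 1, TRUE))))
    nt1 <- sample(c("A", "C", "G", "U"), m, TRUE)
    nt2 <- vapply(nt1, function(x) {
      if (x %in% names(wob) && runif(1) < 0.3) wob[[x]] else comp[[x]]
    }, character(1))
    fwd <- data.frame(pos1 = pos1, pos2 = pos2, nt1 = nt1, nt2 = nt2)
    # read the same duplex from the other end: strands swap roles and the
    # coordinate flip already restores ascending order on the new RNA1
    rev_d <- data.frame(pos1 = max(pos2) + 1 - pos2,
                        pos2 = max(pos1) + 1 - pos1,
                        nt1 = nt2, nt2 = nt1)
    expect_equal(hybridization_energy(p, fwd), hybridization_energy(p, rev_d),
                 tolerance = 1e-12)
  }
})

test_that("hybridization energy is additive across an interior loop", {
  p <- default_params()
  # helix A + loop + helix B equals the init-corrected sum of the parts
  a <- data.frame(pos1 = 1:3, pos2 = 12:10,
                  nt1 = c("G", "C", "G"), nt2 = c("C", "G", "C"))
  b <- data.frame(pos1 = 6:8, pos2 = 7:5,
                  nt1 = c("A", "U", "G"), nt2 = c("U", "A", "C"))
  joined <- rbind(a, b)
  e_joined <- hybridization_energy(p, joined)
  e_a <- hybridization_energy(p, a)
  e_b <- hybridization_energy(p, b)
  seam <- loop_energy(p, 6 - 3 - 1, 10 - 7 - 1) -
    p$terminal[["GC"]] - p$terminal[["AU"]]  # interior ends lose their penalty
  expect_equal(e_joined, e_a + e_b - p$init + seam, tolerance = 1e-12)
})
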