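# Nernst / GHK solvers and permeability-ratio inversion.

test_that("Nernst potential matches hand evaluation and limits", {
  expect_equal(nernst_potential(+1, 500, 50, RTF), RTF * log(10),
               tolerance = 1e-12)
  expect_equal(nernst_potential(+1, 500, 50, RTF), 59.80, tolerance = 1e-3)
  expect_equal(nernst_potential(+2, 150, 15, RTF), RTF / 2 * log(10),
               tolerance = 1e-12)
  expect_equal(nernst_potential(+2, 150, 15, RTF), 29.90, tolerance = 1e-3)
  expect_identical(nernst_potential(+1, 120, 120, RTF), 0)
  # antisymmetric under swapping sides
  expect_equal(nernst_potential(-1, 500, 50, RTF),
               -nernst_potential(-1, 50, 500, RTF))
  expect_error(nernst_potential(0, 1, 1, RTF), class = "bl_domain_error")
  expect_error(nernst_potential(1, 0, 1, RTF), class = "bl_domain_error")
})

test_that("thermal voltage follows RT/F", {
  expect_equal(rt_over_f_mV(298.15), 25.693, tolerance = 1e-4)
  # 25.97 mV corresponds to ~301.4 K
  expect_equal(rt_over_f_mV(301.37), 25.97, tolerance = 1e-3)
})

test_that("monovalent GHK reproduces the published KCl reversal potential", {
  b <- kcl_bath(p_cl = 0.031482)
  expect_equal(ghk_reversal_monovalent(b), 52.77, tolerance = 1e-4)
})

test_that("monovalent GHK reduces to Nernst and respects symmetry", {
  expect_equal(ghk_reversal_monovalent(kcl_bath(p_cl = 0)),
               nernst_potential(1, 500, 50, RTF), tolerance = 1e-12)
  sym <- bath_from_salts(c(KCl = 150), c(KCl = 150),
                         permeabilities = c(K = 1, Cl = 0.3),
                         rt_over_f_mV = RTF)
  expect_equal(ghk_reversal_monovalent(sym), 0, tolerance = 1e-12)
  expect_error(ghk_reversal_monovalent(ca_bath()),
               class = "bl_unsupported_equation")
  expect_error(ghk_reversal_monovalent(kcl_bath(p_cl = 0) |>
                                         set_permeability("K", 0)),
               class = "bl_domain_error")
})

test_that("monovalent inversion recovers the published permeability ratios", {
  b <- kcl_bath()
  wt <- invert_monovalent_ratio(52.77, b)
  expect_equal(wt$ratio, 31.77, tolerance = 0.005)
  mut <- invert_monovalent_ratio(46.96, b)
  expect_equal(mut$ratio, 15.38, tolerance = 0.005)
  expect_identical(wt$numerator_species, "K")
  expect_identical(wt$denominator_species, "Cl")
})

test_that("monovalent inversion handles the attainable-interval edges", {
  b <- kcl_bath()
  # at the cation Nernst potential the anion permeability vanishes
  res <- invert_monovalent_ratio(nernst_potential(1, 500, 50, RTF), b)
  expect_identical(res$ratio, Inf)
  # beyond the attainable window there is no non-negative solution
  expect_error(invert_monovalent_ratio(80, b), class = "bl_no_solution")
})

test_that("extended GHK matches the analytic quadratic for the K/Ca mixture", {
  # with out 500 K + 10 Ca, in 50 K + 100 Ca, P_K = P_Ca = 1 the implicit
  # equation collapses to 450 u^2 - 450 u - 540 = 0
  u <- (1 + sqrt(1 + 4 * 540 / 450)) / 2
  expect_equal(ghk_reversal_extended(mix_bath()), RTF * log(u),
               tolerance = 1e-9)
  expect_equal(RTF * log(u), 13.84, tolerance = 1e-3)
})

test_that("extended GHK reduces to the monovalent solution and to symmetry", {
  b <- bath_pair(list(ion_species("K", 1, 500, 50, 1),
                      ion_species("Ca", 2, 0, 0, 1),
                      ion_species("Cl", -1, 500, 50, 0.2)),
                 rt_over_f_mV = RTF)
  mono <- bath_pair(list(ion_species("K", 1, 500, 50, 1),
                         ion_species("Cl", -1, 500, 50, 0.2)),
                    rt_over_f_mV = RTF)
  expect_equal(ghk_reversal_extended(b, include_anions = TRUE),
               ghk_reversal_monovalent(mono), tolerance = 1e-9)
  sym <- bath_pair(list(ion_species("K", 1, 100, 100, 1),
                        ion_species("Ca", 2, 10, 10, 1)),
                   rt_over_f_mV = RTF)
  expect_equal(ghk_reversal_extended(sym), 0, tolerance = 1e-9)
})

test_that("divalent inversion round-trips and hits the trivial limits", {
  b <- mix_bath()
  e <- ghk_reversal_extended(b)
  rt <- invert_divalent_ratio(e, b)
  expect_equal(rt$ratio, 1, tolerance = 1e-9)
  # at the monovalent-only prediction the divalent permeability is zero
  b0 <- mix_bath(p_ca = 0)
  mono_only <- bath_pair(list(ion_species("K", 1, 500, 50, 1)),
                         rt_over_f_mV = RTF)
  e0 <- ghk_reversal_monovalent(mono_only)
  expect_equal(invert_divalent_ratio(e0, b0)$ratio, 0, tolerance = 1e-9)
})

test_that("divalent closed form agrees with a brute-force bisection oracle", {
  # oracle: bracket the forward solver over a log grid of ratios, then
  # bisect on the ratio itself, independent of the linear closed form
  oracle <- function(e_rev, bath) {
    f <- function(p) {
      b <- set_permeability(bath, "Ca", p)
      ghk_reversal_extended(b) - e_rev
    }
    grid <- 10^seq(-4, 4, length.out = 65)
    fv <- vapply(grid, f, 0)
    k <- which(fv[-1] * fv[-length(fv)] <= 0)[1]
    lo <- grid[k]; hi <- grid[k + 1]
    for (i in 1:200) {
      mid <- sqrt(lo * hi)
      if (f(mid) * f(lo) <= 0) hi <- mid else lo <- mid
      if (hi / lo - 1 < 1e-12) break
    }
    sqrt(lo * hi)
  }
  set.seed(7)
  for (i in 1:5) {
    b <- bath_pair(list(
      ion_species("K", 1, runif(1, 50, 500), runif(1, 50, 500), 1),
      ion_species("Ca", 2, runif(1, 5, 150), runif(1, 5, 150),
                  10^runif(1, -1.5, 1.5))),
      rt_over_f_mV = RTF)
    e <- ghk_reversal_extended(b)
    p_true <- b$species$Ca$permeability
    closed <- invert_divalent_ratio(e, b)$ratio
    expect_equal(closed, p_true, tolerance = 1e-9)
    expect_equal(closed, oracle(e, b), tolerance = 1e-6)
  }
})

test_that("GHK forward/inverse round-trips over random monovalent baths", {
  set.seed(11)
  for (i in 1:10) {
    p_cl <- 10^runif(1, -3, 1)
    co <- runif(1, 20, 600); ci <- runif(1, 20, 600)
    b <- bath_pair(list(ion_species("K", 1, co, ci, 1),
                        ion_species("Cl", -1, co, ci, p_cl)),
                   rt_over_f_mV = RTF)
    e <- ghk_reversal_monovalent(b)
    expect_equal(invert_monovalent_ratio(e, b)$ratio, 1 / p_cl,
                 tolerance = 1e-9)
  }
})

test_that("reversal potentials are antisymmetric under swapping sides", {
  swap <- function(b) {
    b$species <- lapply(b$species, function(s) {
      tmp <- s$conc_out_mM; s$conc_out_mM <- s$conc_in_mM
      s$conc_in_mM <- tmp; s
    })
    b
  }
  b <- kcl_bath(p_cl = 0.031482)
  expect_equal(ghk_reversal_monovalent(swap(b)),
               -ghk_reversal_monovalent(b), tolerance = 1e-12)
  bm <- mix_bath(p_ca = 0.7)
  expect_equal(ghk_reversal_extended(swap(bm)),
               -ghk_reversal_extended(bm), tolerance = 1e-8)
})

test_that("monovalent reversal is monotone in the cation gradient", {
  ratios <- c(2, 5, 10, 20, 50)
  e <- vapply(ratios, function(r) {
    b <- bath_from_salts(c(KCl = 50 * r), c(KCl = 50),
                         permeabilities = c(K = 1, Cl = 0.05),
                         rt_over_f_mV = RTF)
    ghk_reversal_monovalent(b)
  }, 0)
  expect_true(all(diff(e) > 0))
})

test_that("the two published (E_rev, ratio) pairs imply the same RT/F", {
  implied_rtf <- function(e_rev, ratio) {
    stats::uniroot(function(rtf)
      invert_monovalent_ratio(e_rev, kcl_bath(rtf = rtf))$ratio - ratio,
      c(24, 30), tol = 1e-10)$root
  }
  r1 <- implied_rtf(52.77, 31.77)
  r2 <- implied_rtf(46.96, 15.38)
  expect_equal(r1, r2, tolerance = 0.005)
  expect_equal(r1, 25.97, tolerance = 0.005)
})

test_that("bath construction enforces its invariants", {
  expect_error(ion_species("K", 3, 10, 10), class = "bl_domain_error")
  expect_error(ion_species("K", 1, -1, 10), class = "bl_domain_error")
  expect_error(bath_from_salts(c(XYZ = 10), c(KCl = 10)),
               class = "bl_input_error")
  b <- bath_from_salts(c(CaCl2 = 150), c(CaCl2 = 15))
  expect_equal(b$species$Cl$conc_out_mM, 300)
  expect_equal(b$species$Ca$conc_out_mM, 150)
})
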