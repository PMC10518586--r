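ref_edp <- function() edp_params(c(333, 293, 163, 250), c(0.45, 1.35, 2.2),
                                 c(0.25, 0.3, 0.25))

test_that("the erf profile is even, tends to the solvent level, and hits the
           sharp-step piecewise limit", {
  e <- ref_edp()
  expect_equal(edp_evaluate(e, c(-50, 50)), c(333, 333), tolerance = 1e-12)
  set.seed(1)
  r <- runif(50, -4, 4)
  expect_equal(edp_evaluate(e, r), edp_evaluate(e, -r), tolerance = 1e-12)

  # sigma -> 0+ : piecewise-constant slabs; level derived independently from
  # the step decomposition (each term i contributes rho_i - rho_{i-1} inside R_i)
  es <- edp_params(e$rho, e$R, c(1e-6, 1e-6, 1e-6))
  piecewise <- function(r) {
    lev <- e$rho[1]
    for (i in 1:3) if (abs(r) < e$R[i]) lev <- lev + e$rho[i + 1] - e$rho[i]
    lev
  }
  probe <- c(0, 0.2, 0.6, 1.0, 1.7, 2.0, 2.4, 3.0)
  expect_equal(edp_evaluate(es, probe), vapply(probe, piecewise, numeric(1)),
               tolerance = 1e-9)
  expect_equal(edp_evaluate(es, 0), 250, tolerance = 1e-9)  # center = rho3
})

test_that("the closed-form form factor matches adaptive quadrature", {
  set.seed(33)
  q <- c(seq(0.05, 6, length.out = 25))
  for (k in 1:20) {
    e <- edp_params(rho = c(333, 333 + runif(3, -180, 120)),
                    R = sort(runif(3, 0.2, 2.8)),
                    sigma = runif(3, 0.15, 0.5))
    if (any(diff(e$R) < 0.05)) next
    Fc <- form_factor(e, q)
    Fq <- oracle_form_factor(e, q)
    expect_lt(max(abs(Fc - Fq) / pmax(abs(Fq), 1e-6)), 1e-6)
  }
})

test_that("form factor limits: integrated contrast at q = 0, zero at zero contrast", {
  e <- ref_edp()
  excess <- sum(2 * e$R * diff(e$rho))
  expect_equal(form_factor(e, 0), excess, tolerance = 1e-12)
  flat <- edp_params(c(300, 300, 300, 300), e$R, e$sigma)
  expect_equal(form_factor(flat, seq(0, 5, by = 0.5)), rep(0, 11))
})

test_that("the modified Caille factor has its closed-form limits", {
  expect_equal(mct_structure_factor(mct_params(1, 6.3, 0.2, 0), seq(0.1, 3, 0.1)),
               rep(1, 30))
  m0 <- mct_params(8, 6.3, 0, 0)
  q <- seq(0.15, 3, length.out = 120)
  ideal <- sin(8 * q * 6.3 / 2)^2 / sin(q * 6.3 / 2)^2
  expect_equal(mct_structure_factor(m0, q), ideal, tolerance = 1e-9)
  expect_equal(mct_structure_factor(m0, 2 * pi / 6.3), 64, tolerance = 1e-9)
})

test_that("increasing eta lowers and broadens the Bragg peak", {
  qb <- 2 * pi / 6.3
  etas <- seq(0, 0.5, by = 0.05)
  peak <- vapply(etas, function(h)
    mct_structure_factor(mct_params(10, 6.3, h, 0), qb), numeric(1))
  expect_true(all(diff(peak) < 0))
  # width: value at the peak shoulder relative to the peak grows with eta
  shoulder <- vapply(etas, function(h)
    mct_structure_factor(mct_params(10, 6.3, h, 0), qb + 0.06) /
      mct_structure_factor(mct_params(10, 6.3, h, 0), qb), numeric(1))
  expect_true(all(diff(shoulder) > 0))
})

test_that("intensity composition obeys its limiting cases", {
  e <- ref_edp()
  q <- seq(0.1, 4, by = 0.01)
  m_diffuse <- mct_params(10, 6.3, 0.1, 1)
  expect_equal(model_intensity(e, m_diffuse, q), form_factor(e, q)^2 / q^2,
               tolerance = 1e-12)
  m_uni <- mct_params(1, 6.3, 0.1, 0.3)
  expect_equal(model_intensity(e, m_uni, q), model_intensity(e, m_diffuse, q),
               tolerance = 1e-12)
  expect_error(model_intensity(e, m_uni, c(0, 1)), "q = 0")
})

test_that("the fit window must retain data and sigma_I must be positive", {
  e <- ref_edp()
  cv <- generate_saxs_curve(e, mct_params(5, 6.3, 0.1, 0.3),
                            seq(0.6, 2, by = 0.01), noise = 0.01, seed = 1)
  expect_error(fit_saxs(cv, q_window = c(4, 5)), "excludes all data")
})

test_that("a noiseless curve is an exact fixed point of the fit", {
  e <- edp_params(c(333, 250, 160, 270), c(0.6, 1.4, 2.15), c(0.30, 0.30, 0.28))
  m <- mct_params(10, 6.3, 0.1, 0.3)
  cv <- generate_saxs_curve(e, m, seq(0.05, 6, by = 0.0025), noise = 0,
                            scale = 1, seed = 3)
  ft <- suppressWarnings(fit_saxs(cv, list(edp = e, mct = m, scale = 1),
                                  q_window = c(0.05, 6), fit_scale = FALSE))
  expect_lt(max(abs(c(ft$edp$rho[2:4], ft$edp$R, ft$edp$sigma) -
                    c(e$rho[2:4], e$R, e$sigma)) /
                c(e$rho[2:4], e$R, e$sigma)), 1e-8)
  expect_lt(ft$reduced_chisq, 1e-12)
})

test_that("a perturbed start inside the local basin recovers the noiseless truth", {
  # the fit surface is rippled near the Bragg peaks (see the methods
  # vignette), so the inverse-crime start is perturbed by +-0.5%
  e <- edp_params(c(333, 250, 160, 270), c(0.6, 1.4, 2.15), c(0.30, 0.30, 0.28))
  m <- mct_params(10, 6.3, 0.1, 0.3)
  truth <- c(e$rho[2:4], e$R, e$sigma)
  for (s in c(2, 4, 5)) {
    cv <- generate_saxs_curve(e, m, seq(0.05, 6, by = 0.0025), noise = 0,
                              scale = 1, seed = s)
    set.seed(s + 40)
    pert <- function(x) x * (1 + runif(length(x), -0.005, 0.005))
    init <- list(edp = edp_params(c(333, pert(truth[1:3])), pert(truth[4:6]),
                                  pert(truth[7:9])),
                 mct = mct_params(10, pert(6.3), pert(0.1), 0.3), scale = 1)
    ft <- suppressWarnings(fit_saxs(cv, init, q_window = c(0.05, 6),
                                    fit_scale = FALSE,
                                    control = minpack.lm::nls.lm.control(
                                      maxiter = 2000, maxfev = 50000,
                                      ftol = 1e-14, ptol = 1e-13)))
    est <- c(ft$edp$rho[2:4], ft$edp$R, ft$edp$sigma)
    expect_lt(max(abs(est - truth) / truth), 1e-3)
  }
})

test_that("rescaling the curve rescales the fitted scale and nothing else", {
  e <- edp_params(c(333, 250, 160, 270), c(0.6, 1.4, 2.15), c(0.30, 0.30, 0.28))
  m <- mct_params(10, 6.3, 0.1, 0.3)
  cv <- generate_saxs_curve(e, m, seq(0.05, 6, by = 0.005), noise = 0.01,
                            scale = 1, seed = 6)
  init <- list(edp = e, mct = m, scale = 1)
  f1 <- suppressWarnings(fit_saxs(cv, init, q_window = c(0.05, 6)))
  cv10 <- cv; cv10$I <- 10 * cv10$I; cv10$sigma_I <- 10 * cv10$sigma_I
  init10 <- init; init10$scale <- 10
  f2 <- suppressWarnings(fit_saxs(cv10, init10, q_window = c(0.05, 6)))
  # identical up to the optimizer's stopping precision
  expect_equal(f2$scale / f1$scale, 10, tolerance = 1e-4)
  expect_equal(f2$edp$R, f1$edp$R, tolerance = 1e-4)
  expect_equal(f2$edp$sigma, f1$edp$sigma, tolerance = 1e-4)
  expect_equal(f2$edp$rho, f1$edp$rho, tolerance = 1e-4)
  expect_equal(f2$mct$d_spacing, f1$mct$d_spacing, tolerance = 1e-6)
})

test_that("profile reports flag a planted center-density contrast", {
  e1 <- ref_edp()
  e2 <- edp_params(c(333, 293, 163, 290), e1$R, e1$sigma)  # higher center
  rep2 <- edp_report(list(list(edp = e1), list(edp = e2)),
                     labels = c("control", "dda"))
  expect_gt(rep2$contrasts$d_center_density, 0)
  expect_lt(abs(rep2$contrasts$d_head_peak_position), 0.05)

  one <- edp_report(list(list(edp = e1)), labels = "only")
  expect_null(one$contrasts)
  expect_equal(ncol(one$profiles), 2)

  # descriptors match a dense-grid argmax oracle on the generator parameters
  dense_r <- seq(0, 4, length.out = 40001)
  dense <- edp_evaluate(e1, dense_r)
  expect_equal(one$descriptors$head_peak_position, dense_r[which.max(dense)],
               tolerance = 0.015)
  expect_equal(one$descriptors$center_density, edp_evaluate(e1, 0))
})
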