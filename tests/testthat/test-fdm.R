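test_that("FDM operator conserves current and uses harmonic-mean faces", {
  # homogeneous 3x3x3 block: row sums of the Laplacian are zero
  n <- c(3L, 3L, 3L)
  lab <- array(match("gray", tesplan:::TISSUES), dim = n)
  m <- structure(list(dim = n, spacing = 2, center = n, labels = lab,
                      tissues = tesplan:::TISSUES, sigma = NULL, table = NULL),
                 class = "voxel_head_model")
  m <- assign_conductivities(m)
  sys <- assemble_fdm_system(m)
  expect_lt(max(abs(Matrix::rowSums(sys$A))), 1e-15)
  expect_equal(max(abs(sys$A - Matrix::t(sys$A))), 0)

  # scalp/skull face: harmonic mean 2/(1/0.44 + 1/0.018)
  n2 <- c(2L, 1L, 1L)
  lab2 <- array(match(c("scalp", "skull"), tesplan:::TISSUES), dim = n2)
  m2 <- structure(list(dim = n2, spacing = 2, center = n2, labels = lab2,
                       tissues = tesplan:::TISSUES, sigma = NULL, table = NULL),
                  class = "voxel_head_model")
  m2 <- assign_conductivities(m2)
  sys2 <- assemble_fdm_system(m2)
  g <- -sys2$A[1, 2] / (2 / 1000)       # conductance / h_m = face sigma
  expect_equal(g, 2 / (1 / 0.44 + 1 / 0.018), tolerance = 1e-12)

  # air-adjacent faces carry no coupling: air voxel has no unknown at all
  lab3 <- array(c(match("scalp", tesplan:::TISSUES), 1L), dim = n2)
  m3 <- structure(list(dim = n2, spacing = 2, center = n2, labels = lab3,
                       tissues = tesplan:::TISSUES, sigma = NULL, table = NULL),
                  class = "voxel_head_model")
  m3 <- assign_conductivities(m3)
  sys3 <- assemble_fdm_system(m3)
  expect_equal(length(sys3$nodes), 1L)
  expect_equal(as.numeric(sys3$A), 0)
})

test_that("disconnected conducting regions are rejected with sizes", {
  n <- c(3L, 1L, 1L)
  lab <- array(c(match("gray", tesplan:::TISSUES), 1L,
                 match("gray", tesplan:::TISSUES)), dim = n)
  m <- structure(list(dim = n, spacing = 2, center = n, labels = lab,
                      tissues = tesplan:::TISSUES, sigma = NULL, table = NULL),
                 class = "voxel_head_model")
  m <- assign_conductivities(m)
  expect_error(assemble_fdm_system(m), "disconnected.*1, 1")
})

test_that("injection solves behave linearly and respect zero-sum", {
  model <- bar_model()
  sys <- assemble_fdm_system(model)
  es <- data.frame(id = c("A", "B"), x = c(5, 5), y = c(5, 5), z = c(1, 79),
                   area = 1)
  class(es) <- c("electrode_set", "data.frame")
  expect_error(solve_injection(sys, es, c(1, 1)), "sum to zero")
  f0 <- solve_injection(sys, es, c(0, 0))
  expect_true(all(f0$values == 0))
  f1 <- solve_injection(sys, es, c(100, -100))
  f2 <- solve_injection(sys, es, c(-100, 100))
  expect_equal(f1$values, -f2$values, tolerance = 1e-10)
  expect_equal(mean(f1$values), 0, tolerance = 1e-12)  # average reference
})

test_that("antipodal injection on a homogeneous sphere is antisymmetric", {
  stack <- homog_sphere_stack()
  es <- two_electrode_set(stack$model, rbind(c(0, 0, 92), c(0, 0, -92)))
  fld <- solve_injection(stack$system, es, c(1000, -1000), tol = 1e-10)
  phi <- fld$phi
  n <- dim(phi)
  flip <- phi[, , n[3]:1]
  ok <- !is.na(phi) & !is.na(flip)
  expect_lt(max(abs(phi[ok] + flip[ok])) / max(abs(phi[ok])), 1e-6)
})

test_that("current density obeys Ohm's law on a bar resistor", {
  model <- bar_model()
  sys <- assemble_fdm_system(model)
  fld <- solve_point_sources(sys, rbind(c(5, 5, 1), c(5, 5, 79)),
                             c(1e-3, -1e-3))
  J <- current_density(model, fld)
  jz <- J$jz[, , 15:25]                    # interior slab
  area_m2 <- (5 * 2 / 1000)^2
  expect_lt(max(abs(jz - mean(jz))) / abs(mean(jz)), 0.05)
  expect_equal(abs(mean(jz)), 1e-3 / area_m2, tolerance = 0.05)
  # constant potential -> zero current density
  cfld <- fld
  cfld$phi[!is.na(cfld$phi)] <- 3
  J0 <- current_density(model, cfld)
  expect_true(all(J0$magnitude == 0))
  # linearity in the source
  fldn <- solve_point_sources(sys, rbind(c(5, 5, 1), c(5, 5, 79)),
                              c(-1e-3, 1e-3))
  Jn <- current_density(model, fldn)
  expect_equal(Jn$jz, -J$jz, tolerance = 1e-9)
  # J is zero in air (none here) and re-referencing changes nothing
  fld2 <- fld
  fld2$phi <- fld2$phi + 0.37
  J2 <- current_density(model, fld2)
  expect_equal(J2$jz, J$jz, tolerance = 1e-12)
})

test_that("discrete boundary flux balances the injected current", {
  model <- bar_model()
  sys <- assemble_fdm_system(model)
  I <- 2e-3
  fld <- solve_point_sources(sys, rbind(c(5, 5, 1), c(5, 5, 79)), c(I, -I))
  # net current through the mid-plane equals the injected current
  J <- current_density(model, fld)
  h_m <- model$spacing / 1000
  through <- sum(J$jz[, , 20]) * h_m^2
  expect_equal(through, I, tolerance = 0.02 * I)
})
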